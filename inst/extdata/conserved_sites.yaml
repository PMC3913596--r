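# Conserved-residue requirements per amplicon target, 1-based amino acid
# coordinates in the translated amplicon. Phases are chosen so that the
# beta exon 3 disulfide cysteines land at aa sites 24 and 80. The termini
# binding residues for the alpha-1 domain amplicon are package defaults
# (the cited residue tables are not reprinted here) and may be overridden
# by the user.
IIa_ex2:
  phase: 0          # 171 nt -> 57 aa
  cys_pair: []
  termini_sites:
    "11": N
    "52": R
  cd4_region: []
IIa_ex3:
  phase: 0          # 240 nt -> 80 aa
  cys_pair: [24, 80]
  termini_sites: {}
  cd4_region: []
IIb_ex3:
  phase: 2          # 260 nt -> 86 aa
  cys_pair: [24, 80]
  termini_sites: {}
  cd4_region: [42, 66]
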