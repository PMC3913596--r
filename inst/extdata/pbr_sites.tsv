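exon_target	aa_site
IIb_ex2	9
IIb_ex2	11
IIb_ex2	13
IIb_ex2	26
IIb_ex2	28
IIb_ex2	30
IIb_ex2	32
IIb_ex2	37
IIb_ex2	38
IIb_ex2	47
IIb_ex2	56
IIb_ex2	57
IIb_ex2	60
IIb_ex2	61
IIb_ex2	65
IIb_ex2	67
IIb_ex2	70
IIb_ex2	71
IIb_ex2	74
IIb_ex2	78
IIb_ex2	81
IIb_ex2	82
IIb_ex2	85
IIb_ex2	86
IIb_ex2	89
IIb_ex2	90
IIa_ex2	9
IIa_ex2	11
IIa_ex2	22
IIa_ex2	24
IIa_ex2	31
IIa_ex2	43
IIa_ex2	52
IIa_ex2	53
IIa_ex2	54
IIa_ex2	55
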