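---
title: "Models and methods behind crocmhc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crocmhc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, conventions and design
choices in `crocmhc`, in the spirit of a methods section: what each
module assumes, which tunable parameters matter, what the simulator
emulates (and what it does not), and where the design was genuinely open
and a choice had to be made.

## 1. Clone validation

Clonal amplicon sequencing of a multigene family produces, per
individual and PCR, a few clone inserts read in both directions. The
validation model is:

1. **Strand consensus.** The reverse read is reverse-complemented and
   compared position-wise with the forward read. IUPAC-compatible
   positions (non-empty base-set intersection) agree and resolve to the
   intersection code; any incompatible position rejects the clone
   (`strand_mismatch`). Reads of unequal length are an error — the
   amplicons here are short enough that both reads span the insert.
2. **Support rule.** A distinct consensus sequence becomes a candidate
   variant when it occurs in at least `min_support = 2` clones of one
   individual, and/or is observed in more than one individual, within or
   across species. Cross-species rescue is deliberate: an identical
   sequence in two species is strong evidence against PCR artefact.
3. **Near-redundancy (< 3 bp) rule.** Within one PCR, a unique
   (single-clone) sequence fewer than 3 nucleotide differences away from
   a redundant (multi-clone) sequence of that PCR is discarded as a
   polymerase point-error derivative. Distance is Hamming on equal
   lengths and generalized edit distance otherwise (gaps count).
   *Open choice:* whether this rule applies before or after
   cross-individual rescue is not specified by the protocol the package
   follows; the default is **after** (rescued sequences are exempt),
   configurable via `exempt_rescued = FALSE`. Rationale: a sequence
   independently observed in another individual has evidence a
   point-error derivative cannot have.
4. **Within-individual chimeras.** PCR chimeras arise predominantly from
   a single template switch, so "combination of other sequences" is
   interpreted as one exact crossover: a sequence is removed iff it
   equals `P1[1..k] + P2[k+1..L]` for some `1 ≤ k < L` and two
   *support-accepted* sequences `P1 ≠ P2` of the same individual.
   Restricting eligible parents to accepted sequences is load-bearing:
   unsupported singleton clones are often themselves chimeric, and a
   pair of reciprocal artefacts (`A|B` and `B|A`) can otherwise
   "explain" the true parent `A` as their composition and delete it.
   Multi-breakpoint chimeras are out of scope of the default screen.
5. **Naming.** Accepted variants are named
   `<4-letter species prefix>-<DA|DB><2-digit id>` with a canonical
   order — descending clone support, then lexicographic sequence — so
   that names are reproducible under any input permutation.

Every input clone ends in exactly one place: a validated variant's
support or one rejection record with its rule and evidence.

## 2. ORF annotation

Amplicons are translated with a per-target reading phase shipped in
`inst/extdata/conserved_sites.yaml`; the β exon 3 phase (2) is chosen so
the disulfide-bridge cysteines land at amino acid sites 24 and 80, with
a CD4-binding region annotated at 42–66. A sequence is non-functional
iff it carries a premature stop, a frameshifting (length not divisible
by 3) indel relative to a functional reference of the same target, or
lacks a required conserved residue. *Open choice:* the exact residues
required at the peptide-termini binding sites of the α1 amplicon are not
reprinted in the sources this package follows; the shipped defaults
(N at 11, R at 52) are explicit package data, user-auditable and
overridable. Non-functional sequences are **retained** in TSP and
phylogenetic analyses — pseudogenes carry phylogenetic and trans-species
signal.

## 3. Trans-species polymorphism

A TSP cluster is one amino-acid string observed in two or more species
of one dataset. Identity is exact string equality over the **full
translated amplicon including `X` and `*`** — frameshifted and stopped
sequences can legitimately share a trans-species lesion, so pseudogenes
participate. Within-species repeats count once toward the species set.
Labels are global and deterministic: dataset order, then descending
species count, then lexicographic amino-acid string. *Open choice:*
identity over trimmed exon interiors instead of the full amplicon is
not the default because trimming rules would add a free parameter the
data do not constrain.

## 4. NG86 diversity statistics

Synonymous/nonsynonymous counting follows the classic equal-path
scheme, with two conventions documented because implementations differ:

- **Stop exclusion.** Per codon position, the site fraction counted as
  synonymous is the synonymous share of the *non-stop* single-nucleotide
  changes, and the nonsynonymous fraction is its complement, so
  n + s = 3 per codon. Mutational paths through a stop codon are
  excluded from the equal-weight average; if all paths are blocked,
  all paths are used with stop-passing steps counted nonsynonymous.
- **Pairwise deletion.** Codons containing gaps or ambiguity in either
  member of a pair, and stop codons themselves, are skipped for that
  pair only.

Proportions are Jukes–Cantor corrected
(d = −3/4 · ln(1 − 4p/3)), undefined (reported `NA`) when p ≥ 3/4.
The codon Z-test compares mean dN and mean dS over all sequence pairs on
a codon-column subset, with the standard error from bootstrap resampling
of codon columns; the statistic is signed so that support for the stated
alternative is positive, and the p-value is one-tailed normal.

## 5. Site-wise Bayesian ω

The sampler targets the posterior of {μ, κ, ω₁…ω_C} under a composite
likelihood that is a deliberate desk-scale simplification of a full
phylogenetic codon model:

- For each of `n_orderings` (default 10) random sequence orderings,
  each sequence is compared with its nearest predecessor in the
  ordering (a product-of-approximate-conditionals flavour); per codon
  site, synonymous and nonsynonymous difference counts (equal-path
  averaged) and κ-weighted opportunity counts are accumulated and
  averaged over orderings.
- Counts are modelled as Poisson with rates μ·S_j(κ) and
  μ·ω_j·N_j(κ); sites are independent given (μ, κ) — the "independent ω
  model", with no smoothing blocks and recombination handled in its own
  module.
- Priors: log-uniform ω on [0.01, 100], exponential(1) μ and κ. The
  sources this package follows do not state priors; these are
  deliberately weakly-informative and shipped as defaults.
- Defaults mirror the published analysis protocol: 5×10⁵ iterations,
  5×10⁴ burn-in, thinning 100, codon frequencies 1/61, ten orderings,
  two independent runs compared with `compare_runs()` before
  interpretation.

Per site the output is the posterior mean ω, 95 % highest-posterior-
density interval (shortest interval over sorted retained samples), and
PP(ω > 1) — exactly the fraction of retained samples above 1.
Significance labels use strict thresholds (PP > 0.95 significant,
PP > 0.99 highly significant; PP = 0.99 is *significant*, not highly).
PBR annotation marks sites within two codon columns of a shipped
PBR position map (`inst/extdata/pbr_sites.tsv`, a stand-in mapped from
human class II crystallography and explicitly replaceable).

**Known limitations.** The composite likelihood treats pairwise counts
as independent, so posteriors are somewhat overconfident; equal-path
counting attenuates very large ω (a site simulated at ω = 5 is typically
estimated around 3–4.5); and with zero observed differences the
posterior is close to, but not exactly, the prior (the shared μ leaves a
weak downward pull). Exact numeric reproduction of estimates from full
MCMC codon samplers is not promised; qualitative agreement — which sites
are diversifying, and how ω concentrates at and near the PBR — is the
design goal, and the recovery test quantifies it.

## 6. Recombination

Three detectors are shipped: (i) a max-χ² scan over sequence pairs —
the contrast of mismatch densities in windows left/right of each
candidate breakpoint, maximized over breakpoints, with a permutation
null obtained by shuffling the variable columns and Bonferroni
adjustment; (ii) a triplet scan testing, at parent-informative sites,
whether a sequence switches allegiance between its two nearest
neighbours; (iii) the exact single-crossover composition test.
A consensus call requires at least two supporting detectors and a score
above 60, with score = 100 · (supporting/run) · median(support), support
being 1 − adjusted p (1 for the exact test). The score formula is an
operational stand-in for the consensus score of the multi-algorithm
package it replaces; the decision rule (≥ 2 detectors, > 60) is the
criterion that matters.

θ is Watterson's estimator per alignment, S/a_{n−1}. ρ (4N_e·c across
the alignment) maximizes a pairwise composite likelihood of four-gamete
violations on a fixed grid (0 plus 50 log-spaced points on [0.01, 100]):
the probability that a recombination event separates two segregating
sites at scaled distance d is modelled as 1 − exp(−ρ·d·a_{n−1}). This
stand-in assumes infinite sites; recurrent mutation (homoplasy) at high
divergence also produces four-gamete violations and inflates ρ, which is
why the null-calibration tests run at shallow divergence. With no
violations the estimate sits at the grid minimum (0), and the verdict
"low recombination" is reported when ρ < θ.

## 7. Distance phylogenetics

Substitution models JC69, K80, HKY85 and TN93 with 4-category discrete-Γ
rate heterogeneity. Model selection computes the pruning likelihood of
each candidate on a fixed NJ starting topology (JC69 distances),
optimizing the model's free parameters (κ or the two transition rates,
Γ shape) with empirical base frequencies for HKY85/TN93; the best model
is chosen by BIC, with AIC reported. Parameter counts: JC69 0, K80 1,
HKY85 4, TN93 5, +1 for Γ.

Distances use the closed forms (via `ape::dist.dna`), with HKY85
approximated by the TN93 distance and Γ correction when the shape is
finite; saturated pairs come back `NA` with a warning. Neighbor joining
is implemented directly with a stated tie-break — on equal Q values the
lowest (row, column) pair is joined — making results deterministic; NJ
recovers any additive matrix's topology and branch lengths exactly, and
the suite verifies this on random trees. Bootstrap supports resample
alignment columns and count recovered bipartitions (canonical split
representation). Expected likelihood weights compare two topologies by
RELL resampling of per-site log-likelihoods; identical topologies split
the weight 0.5/0.5 and weights always sum to 1. *Open choice:* clade
assignments for diagnostic-site analysis are user-supplied rather than
inferred, because clade definitions belong to the analyst (they are
usually taken from a tree built with heavier machinery); diagnostic
sites are columns whose residue sets are disjoint between the two
clades, gaps excluded.

Full maximum-likelihood tree search and Bayesian tree inference are
intentionally out of scope: clade membership, topology comparison and
diagnostic sites are exercised without a search engine.

## 8. Coverage model

With m distinct variants sampled at frequencies p, the probability that
n clones reveal all of them is the inclusion–exclusion sum
Σ_S (−1)^|S| (1 − Σ_{i∈S} p_i)^n (zero when n < m), and the expected
detected fraction is Σ_i (1 − (1−p_i)^n)/m. Both are exposed because
published clone-coverage percentages computed with external tools may
denote either quantity; this package does not claim to reproduce any
particular published figure, only the model. The shipped preset for a
diploid two-locus family is four equifrequent haplotypes.
`min_clones_for_confidence()` increments n exactly (the probability is
nondecreasing in n).

## 9. The synthetic world

The simulator states a world and keeps it fixed:

- **Design:** 20 species in two family clades (taxonomy shipped as
  data), amplicons of 171/240/260 nt (phases 0/0/2), one α locus and two
  β loci, two individuals per species, 4–6 clones per individual, PCR
  point-error rate 0.002/nt, chimera rate 0.1/clone.
- **Species tree:** a deterministic ultrametric two-family caterpillar
  of root-to-tip depth 0.3 expected substitutions per codon — moderate
  divergence chosen once as realistic for a cross-family gene survey.
  Deeper or custom trees are a config entry.
- **Codon evolution:** continuous-time simulation on the 61 sense
  codons, change rate κ^[ts]·ω_site^[nonsyn], uniform codon frequencies.
  The generator is normalized by the **mean** leaving rate over the ω
  profile, so branch lengths are expected substitutions per codon
  averaged over sites and high-ω sites substitute proportionally faster
  — the standard codon-model scaling (per-site normalization would
  equalize substitution counts and destroy most of the ω signal).
- **ω profile:** background 0.2; elevated (4) at PBR columns of exon-2
  targets; 0 at conserved columns, which therefore never lose their
  required residues along the tree.
- **Within-species alleles:** each locus pool carries one evolved base
  allele plus derived alleles differing by two random codon-neighbour
  changes outside conserved columns. These changes are predominantly
  nonsynonymous — recent MHC allelic variation is — which is why even
  β exon 3 data show dN-rich shallow pairs in the worked example.
- **Trans-species retention:** with rate 0.2 per internal node and
  locus, the node's ancestral sequence is copied identically into 2–4
  descendant species' pools. This plants the observable the TSP
  definition tests (identical translated sequences across species)
  without multispecies-coalescent machinery. At shallow divergence
  sister species can also be identical *by chance*; the truth tables
  report clusters of the realized variant set, so tests of exactness
  compare against what is actually planted.
- **Pseudogenes:** with rate 0.1 per species and locus, one pool allele
  receives a premature stop (TAA) or a 1-bp deletion at a random
  interior codon.
- **Clones:** templates are the individual's diploid haplotypes across
  the target's loci; chimeric clones take a uniform breakpoint at least
  10 nt from either end (so detectors have flanking signal) between two
  equal-length templates; point errors are uniform base changes.

**What the simulator does not emulate:** base-quality and chromatogram
error structure, primer/amplification bias between loci, indel
sequencing errors, gene conversion, and coalescent gene-tree/species-
tree discordance. A green truth-recovery test therefore establishes the
correctness of the *algorithms* under the stated generative model, not
robustness to every artefact of real Sanger data.

## 10. Numerical and reproducibility choices

- All coordinates are 1-based inclusive; IUPAC codes are preserved in
  nucleotide space and translate to `X`.
- One master seed expands into per-stage seeds through a documented
  deterministic hash (`derive_seed`), kept below 2³¹; identical seeds
  give byte-identical simulator output and identical pipeline manifest
  hashes.
- HPD intervals use the shortest-window estimator on sorted samples.
- The test suite scales chain lengths and permutation counts down from
  the shipped defaults (e.g. 2×10⁴ MCMC iterations instead of 5×10⁵,
  200 permutations instead of 10⁴) to stay within its time budget; the
  acceptance thresholds themselves are never relaxed.
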