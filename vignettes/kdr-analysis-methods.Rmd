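---
title: "Methods: kdr genotyping, haplotype phasing and TN93 phylogenetics"
author: "kdrhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kdr genotyping, haplotype phasing and TN93 phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrhap)
```

## The problem

Pyrethroid resistance in *Aedes albopictus* is largely driven by point
mutations in the voltage-gated sodium channel (VGSC) — *kdr* ("knockdown
resistance") mutations, numbered against the *Musca domestica* protein
(V1016G, I1532T, F1534S/L/C, ...). Surveys genotype these codons by PCR
amplification of two short genomic fragments and direct Sanger sequencing of
the diploid template:

* **D2** (domain II): partial exon 20, the full intron 20, partial exon 21;
  spliced exon region 230 bp; hosts codons 989, 1000, 1011, 1016.
* **D3** (domain III): partial exon 28, the full intron 28, partial exon 29;
  spliced coding region 246 bp; hosts codons 1532 and 1534 in exon 29.

A heterozygous site appears as two superimposed peaks and is written as a
two-allele IUPAC code (`R Y S W K M`). `kdrhap` implements the full analysis
chain on such data: genotype calling, rule-based haplotype phasing backed by
clone sequencing, population tabulation, haplotype-origin inference, and
Tamura–Nei phylogenetics — together with a ground-truthed simulator used to
validate every stage.

## The amplicon model

An `amplicon_spec` fixes the coordinate system: a gapless reference
haplotype, exon intervals, a single intron, and a codon map anchored by one
(codon number, spliced offset) pair. Coordinates are 0-based half-open
throughout; codon numbers use the community numbering, decoupled from
amplicon coordinates. Intron boundaries are taken from annotation; a
validation warning (not an error) is emitted when they are not `GT...AG`.

The shipped D2/D3 reference haplotypes are **synthetic stand-ins** with the
documented structure (exon lengths 230/246 bp; intron defaults 91 and 83 bp,
the longest documented length variants). They are not database downloads, so
the package is fully testable offline; only structural properties, never the
specific bases, carry scientific meaning. Within D2 the literature does not
pin down whether codons 1000/1016 fall in exon 20 or 21; the anchor is
configurable and nothing downstream depends on the choice (the default
places them upstream of the intron). Because the stand-ins are random
sequences, the "coding" region is not an open reading frame — only the
mapped codons are ever translated.

## The synthetic-data generator

The generator emulates the statistical structure of the surveyed data:

* **Haplotype pools.** `study_haplotype_pool()` reproduces the catalogued
  diversity: 17 D2 haplotypes (intron 71–91 bp; one 1016G, one 1000Y) and 19
  D3 haplotypes (intron 67–83 bp; one 1532T, two 1534S on different wild
  backgrounds, one 1534L). Each background carries unique intron tag
  substitutions, every third background a silent exon SNP, so diversity
  spans exon and intron. The 1016G haplotype is built one substitution from
  its wild background, and the two 1534S haplotypes descend from different
  wild parents and differ in both exon and intron — the configuration behind
  the origin analysis. Haplotypes combining a 1532 and a 1534 mutation are
  refused: no such haplotype has been observed.
* **Populations.** `study_simulation_config()` uses the 17 surveyed sites
  with their published sample sizes (scaled proportionally when a different
  total is requested) and maps each site's published mutant allele
  frequencies onto the corresponding mutant haplotypes (1016G → D2H07;
  1000Y → D2H10, Tong Zhou only; 1532T → D3H01; 1534S → D3H03 in Tong Zhou,
  D3H13 elsewhere; 1534L → D3H12). The wild remainder is spread over the
  wild backgrounds with geometrically decaying weights (ratio 0.7) — a
  skewed frequency spectrum typical of haplotype surveys; the published
  tables do not constrain it.
* **Mating.** Individuals are formed by random union of gametes within each
  population (Hardy–Weinberg). The survey reports no mating structure; HW is
  the minimal neutral model for a stand-in.
* **Consensus reads.** Equal-length haplotype pairs merge position-wise into
  IUPAC codes. A heterozygous intron indel makes a Sanger trace unreadable
  past the indel, so such consensus records are truncated at the first indel
  position and flagged `length_het` — which forces those individuals down
  the clone path, as in the laboratory protocol.
* **Clone reads.** `render_clones()` copies one of the two haplotypes per
  clone, uniformly at random (both alleles present with probability
  `1 - 2 (1/2)^k`); the documented range is 3–10 clones per individual. At
  `k = 3` a heterozygote's clone set misses one allele a quarter of the
  time; the laboratory answer is to keep cloning until both alleles are
  seen, and the dataset generator emulates that completed protocol
  (`ensure_both = TRUE`) for every flagged heterozygote. An optional uniform
  per-base error (default 0) supports robustness tests.
* **Seeds.** One master seed derives per-population and per-individual
  streams deterministically; identical configurations yield byte-identical
  outputs.

What the generator does **not** emulate: chromatogram noise and quality
scores, PCR/cloning artefacts beyond uniform error, linkage between the two
amplicons (drawn independently), population structure beyond site-wise
frequencies, and partial amplicon coverage (every individual yields both
fragments by default). Passing recovery tests therefore demonstrate the
correctness of the algorithms under clean Sanger-like data, not robustness
to trace-level artefacts.

## Genotype calling

`anchor_align()` maps a consensus onto its amplicon reference: exact
one-to-one anchoring of exons, with any length difference absorbed as a
single contiguous gap inside the intron, placed to maximise flanking
identity (ties leftmost). Exon identity below 80% aborts the call — that
threshold separates same-locus variation (a few percent divergence) from a
wrong amplicon or species (~75% mismatches for unrelated sequence). A
general-purpose aligner is deliberately not used: for a fixed-locus amplicon
with one known intron, single-gap placement is fully specified, fast and
testable.

`call_codon_genotype()` extracts the three mapped symbols and enumerates
every decomposition of the ambiguity codes into two alleles (at most
2³ = 8): if all decompositions agree on one unordered amino-acid pair the
genotype is called; if they disagree the locus is `ambiguous`; gaps,
truncated positions or non-two-allele symbols give `missing` (with a
mixed-template flag), never an exception. Enumeration with an ambiguous
fallback is the only assumption-free policy for multi-het codons — and the
ambiguity is real: the 1534 L+S merge `TYS` decomposes both to
{TTG, TCC} = {L, S} and {TTC, TCG} = {F, S}, so no caller can settle it from
one trace. The dataset-level caller (`call_genotypes()`) resolves exactly
those cases through the individual's clone reads (such individuals carry at
least two heterozygous sites and are therefore clone-flagged), restoring
100% concordance with simulator truth at error rate 0. Codons downstream of
the intron in a truncated `length_het` record take the same clone path.

## Haplotype phasing

`phase_direct()` implements the two direct rules — read homozygotes
verbatim; split a heterozygote with exactly **one** heterozygous position in
the whole amplicon read (with two or more, phase is genuinely unknowable
from a single trace) — and defers everything else to clones.
`phase_with_clones()` deduplicates the clone sequences and accepts the
unique candidate pair whose IUPAC re-merge reproduces the observed consensus
at every readable position (the truncated prefix for `length_het`
individuals). Zero consistent pairs, or several among more than two distinct
clone sequences, surface as `inconsistent` for manual review; ambiguity is
never silently resolved.

`build_catalog()` names unique resolved sequences `D2H01, D2H02, ...` in
strict first-observation order. The input order is itself deterministic
(individuals in dataset order, first allele before second), so no secondary
sort is needed for reproducible names. Chromosome counts conserve:
they sum to twice the number of phased individuals per amplicon.

## Population tables

Allele frequencies use the standard diploid count
`p = (n_het + 2 n_hom) / (2n)`, kept exact internally and reported rounded
**half-up** to three decimals — the convention the published tables follow
(1/54 reports as 0.019, 22/34 as 0.647; banker's rounding would print
0.018). Codon 1534 is tri-allelic (F/S/L): each mutant allele is tabulated
separately and the genotype table carries every observed unordered genotype.
Blank cells are zeros, never missing. Triple-locus combinations at
(1016, 1532, 1534) are typed with Type 1 reserved for the triple wild
homozygote; the published type ordering beyond Type 1 follows no evident
rule, so the bundled fixture supplies it as data (a signature → type map)
rather than inferring it. Individuals missing any of the three calls are
excluded and reported.

The bundled fixture transcribes the published per-population genotype counts
and combination-type frequencies. Loading reconstructs individual-level
records (`count = round(freq × n)` half-up) and cross-checks the
reconstruction against the genotype-count marginals with zero tolerance —
the two tables are internally consistent, so any transcription slip fails
loudly.

## Origin analysis

`pairwise_differences()` compares haplotypes position-wise, aligning unequal
lengths with a single gap and counting the indel as one mutational event.
`nearest_wild_neighbors()` reports, for each mutant haplotype, the wild
haplotypes at minimal difference count (all ties): a mutant at distance 1
plausibly arose from that background through one mutational step.
`independent_origin_candidates()` flags pairs of haplotypes that share a
mutant residue yet lie at mutual distance ≥ 3 with disjoint nearest-wild
sets — more steps than a shared origin would leave, hence candidates for
independent origins (the pattern shown by the two 1534S haplotypes).
The threshold of 3 sits just above the 1–2 steps observed within
single-origin clusters.

## TN93 phylogenetics

All phylogenetic machinery is implemented from first principles on the
Tamura–Nei (TN93) model: unequal base frequencies, distinct A↔G (α₁) and
C↔T (α₂) transition rates, one transversion rate (β). With
`gR = gA + gG`, `gY = gC + gT`, the closed-form pairwise distance is

    d = -k1 log(w1) - k2 log(w2) - k3 log(w3)
    k1 = 2 gA gG / gR          w1 = 1 - P1/k1 - Q/(2 gR)
    k2 = 2 gC gT / gY          w2 = 1 - P2/k2 - Q/(2 gY)
    k3 = 2 (gR gY - gA gG gY/gR - gC gT gR/gY)
                               w3 = 1 - Q/(2 gR gY)

with `P1`, `P2`, `Q` the observed proportions of A↔G, C↔T and transversion
differences over shared ungapped columns (pairwise deletion). Any
`wᵢ ≤ 0` returns the `Inf` saturation sentinel with a warning. The same
decay factors give closed-form transition probabilities used by the
likelihood and the sequence simulator; rate ratios are estimated by
inverting the pooled expected proportions, and the rate matrix is normalised
to one expected substitution per site per unit branch length.

Numerical and design choices:

* **Trees** are `ape` "phylo" objects; Newick I/O wraps `ape`'s parser.
  Everything algorithmic — NJ, pruning, NNI, bootstrap — is this package's
  own code; `ape` and `phangorn` appear in the test suite as independent
  cross-checks only.
* **Neighbour joining** uses the classical Q-criterion with ties broken by
  the lowest-index pair (row-major scan); negative branch lengths are
  clamped to zero with the deficit moved to the sibling branch. Additive
  matrices are recovered exactly.
* **Likelihood** is Felsenstein pruning over compressed site patterns with
  uniform rates across sites (no gamma — none is warranted by the data
  model); gaps contribute all-ones partials. The model is reversible, so the
  value is invariant to root placement. Non-binary trees are resolved with
  zero-length branches, with a warning.
* **Branch lengths** are optimised coordinate-wise by bounded scalar search
  on [1e-9, 10] substitutions/site — the lower bound avoids `log(0)`
  pathologies, the upper bound is far beyond saturation for these data.
* **NNI search** evaluates both rearrangements of every internal edge,
  re-optimising branch lengths per candidate, and accepts improvements
  greater than 1e-6 log-units; the accepted log-likelihood trajectory is
  monotone by construction.
* **Bootstrap supports** resample alignment columns, rebuild each replicate
  with the same pipeline (NJ on TN93 distances by default), and report the
  percentage of replicates containing each internal bipartition of the
  reference tree, canonicalised so values are invariant to taxon order.
* The distance used to start the search is TN93 itself rather than a
  composite-likelihood variant, keeping the whole module on one coherent
  model; published log-likelihood values obtained from deposited alignments
  with other software are therefore not comparable numbers, and the
  package's correctness is established against analytic and brute-force
  oracles instead.

Two estimator-theory points surfaced by validation, recorded here because
the test suite relies on them. First, the closed-form TN93 distance is the
exact maximum-likelihood estimator of the *aggregated* multinomial (counts
of A↔G, C↔T, transversion differences and identities) — not of the full
16-cell pair table, from which it differs at order 1e-4 for 300-site pairs.
The numerical ML oracle in the tests therefore maximises the aggregated
likelihood (with matrix-exponential probabilities computed independently of
the closed form), and agreement is ~1e-8. That equivalence holds when the
optimum is interior, i.e. all three difference classes are observed; pairs
with an empty class (where the moment estimator implicitly fits a negative
rate) are excluded from the comparison. Second, TN93 reduces to the
Jukes–Cantor distance at equal frequencies when substitutions are uniform
over the twelve ordered changes — `P1 = P2 = Q/4`; the suite asserts that
algebraic limit to 1e-12.

## Problem sizes and runtime envelope

The validation suite exercises: a 1 000-individual simulated survey for the
genotype and phasing recovery checks (plus 40- and 200-individual datasets
for unit tests and a 10 000-individual single-amplicon draw for the
law-of-large-numbers check); 20 simulated 300-site pairs for the distance
oracle; 5-taxon, 500-column alignments for NNI recovery; ≤ 4-taxon,
10-column toys for brute-force likelihood enumeration; and 100 bootstrap
replicates on a 6-taxon, 206-column alignment. These sizes make every
stochastic check decisive (binomial standard errors well below the asserted
margins) while keeping the full suite near half a minute.

## Known limitations

* The genotype caller assumes two-allele sites; three/four-allele evidence
  is flagged and the locus dropped, with no attempt at mixture modelling.
* Phasing is deterministic and clone-backed, as in the protocol; no
  statistical (EM/LD-based) phasing is attempted, so individuals without
  clone coverage and with ≥ 2 heterozygous sites remain unresolved by
  design.
* The anchored aligner supports a single intron gap of at most ±30 bp; it is
  not a general aligner and will reject structurally rearranged input.
* Bootstrap supports and NNI search are exact re-implementations of the
  standard algorithms but make no attempt to reproduce any specific
  program's heuristics (initial-tree blends, branch-swap filters), so
  support values and searched topologies are comparable in kind, not in
  digit, with other software.
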