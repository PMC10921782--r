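---
title: "Reference bias in polyploid RNA-seq: models and methods"
author: "panquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference bias in polyploid RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panquant)
```

## Scope and model

`panquant` studies a single, sharply posed question: when RNA-seq reads
from one wheat-like cultivar are quantified against another cultivar's
transcriptome by k-mer pseudoalignment, how much expression signal is
lost, where, and how completely does a pantranscriptome reference (the
reference transcripts pooled with all 1-to-1 orthologous transcripts
from other cultivars) repair it?

The package answers this on synthetic data where the truth is known
exactly. Every component — genome simulation, read simulation,
pseudoalignment, aggregation, classification — is part of the tested
surface, not a fixture.

## The synthetic pangenome

`generate_pangenome()` builds an allohexaploid miniature: three
chromosomes (one per subgenome A, B, D), `n_triads` genes per
chromosome, each triad descending from a random ancestor CDS mutated
independently into the three homoeologues.

Parameters that matter, their defaults, and why:

* **Subgenome divergence, 0.04 / bp.** Homoeologues in hexaploid wheat
  differ by a few percent at the coding level; 4% per copy (≈ 7.8%
  pairwise) makes 31-mers essentially always able to distinguish
  homoeologues over a 400 bp fragment while leaving plenty of shared
  k-mers locally, matching the regime in which homoeologue-aware
  quantification is known to work well.
* **Baseline orthologue divergence, 4e-4 / bp.** Elite cultivars are
  nearly identical outside introgressed material; the background
  orthologue-pair identity distribution is dominated by pairs at or very
  near 100%. The default gives ≈ 99.95% mean identity and, under
  exact-compatibility pseudoalignment (below), a background
  misquantification rate of a few percent — the regime reported for
  real inter-cultivar comparisons. We deliberately model *mean* identity
  slightly above the often-quoted "≈ 99.9%", because that figure
  averages in genes that are atypically divergent; a uniform 1e-3 rate
  would put one or more substitutions in nearly every gene, which is not
  what near-isogenic elite material looks like.
* **Introgression divergence, per block (0.03 in the study fixture).**
  Donor species alleles run at roughly 97% coding identity to the
  recipient's allele. Block divergence is a free per-spec parameter
  because real donors vary; the distribution of divergence *within* an
  introgression is not modelled (uniform substitution rate per block).
* **Gene lengths U(900, 1500) bp, intergenic gap 500 bp.** Long enough
  for 1000 distinct 400 bp fragments per gene; short enough that a
  450-gene genome builds in under a second.
* **Missing orthologues (0.02) and tandem duplications (0.01).**
  Presence/absence and copy-number variation at low rates, so the
  1-to-1 orthology machinery (and its exclusions) is exercised without
  dominating the statistics.
* **Shared donor haplotypes.** Introgression specs carrying the same
  `donor` label produce byte-identical haplotypes in different
  cultivars, emulating a shared introgression with no recombination
  since entry — the property that lets a pantranscriptome lacking the
  read-source cultivar still rescue its introgressed genes via another
  carrier.

Substitutions are uniform single-nucleotide changes; there are no
indels. This is deliberate: the bias mechanism under study is CDS
divergence, and indel-free orthologues keep the exact-match oracle
(substring containment) and the alignment-based identity in exact
agreement. One global RNG stream is seeded per run, with sub-seeds
derived per cultivar and per donor so cultivars are reproducible
independently. All coordinates are 0-based half-open, in memory and on
disk (BED).

## Read simulation

`simulate_reads()` replicates the standard benchmarking protocol: from
each gene's (single, longest) transcript of length ≥ 500 bp, exactly
1000 pairs of 150 bp error-free reads at a fixed 400 bp insert, fragment
starts uniform on `[0, L − 400]`. The insert has no jitter — the common
simulator default adds a standard deviation, but a fixed insert keeps
every mate an exact (reverse-complemented) substring of its transcript,
which the pseudoalignment oracle exploits. Pair ids encode the source
gene and index, so truth counts need no side files. DNA coverage for the
introgression-scanning arm is simulated at window level
(`simulate_window_counts()`, Poisson with per-event multipliers) rather
than read level, because the deviation statistic only ever consumes
windowed counts.

## Pseudoalignment and even splitting

`build_index()` maps every canonical 31-mer (lexicographic minimum of
k-mer and reverse complement; the index is strand-agnostic because
paired-end protocols emit both orientations) to the equivalence class of
transcripts containing it. A mate's compatibility set is the
intersection of its k-mers' classes; a pair's set is the intersection
across mates; `quantify()` adds `1/|S|` to each member of the pair's set
`S`, and unassigned pairs are tallied.

The one genuinely open design choice is what an *absent* k-mer means.
`panquant` defaults to **strict exact compatibility**: a k-mer absent
from the index empties its mate's set, so a mate is compatible with a
transcript only if the transcript contains it exactly. This matches the
mechanistic reading of even splitting across "transcripts with an
identical match", makes the compatibility set provably equal to a
brute-force substring-containment oracle on non-repetitive sequence
(a property the test suite asserts read-by-read), and reproduces the
observed phenomenology of divergent alleles: most reads from a 3%
divergent gene carry no clean 31-mer-spanning window across both mates
and go unassigned, collapsing the gene's count. The alternative
(`missing_kmers = "skip"`), in which absent k-mers are ignored and
partially divergent reads are salvaged, is implemented and exposed;
under substitution-only divergence it retains ~97% of read pairs even
at 3% divergence, so single-reference bias largely disappears — useful
as a contrast, but not the default. Real pseudoaligners sit between
these poles; with error-free reads from indexed transcripts the two
semantics agree exactly.

There is no EM step: even splitting is the entire abundance model. This
is exactly the regime in which summing counts across a gene's redundant
transcripts is valid, which is what the pantranscriptome correction
relies on — adding an identical transcript moves half of each pair's
weight, and gene-level sums are unchanged to floating-point residue.
TPMs use plain transcript length (`tpm_t ∝ c_t / ℓ_t`, scaled to 1e6)
with no effective-length correction: with fixed-insert error-free
simulation, plain length is the honest normaliser. Real-data users
should note both deviations from kallisto-style estimation.

## Pantranscriptome correction

`build_pantranscriptome()` consumes orthology (it never infers it): a
cultivar transcript enters the pan reference iff its gene is in a
1-to-1 relationship with a reference gene, ids namespaced
`cultivar|transcript`. `sum_orthologue_counts()` collapses a
pan-reference quantification back onto reference gene ids by summation.
TPMs are summed exactly as counts are, without renormalisation — the
summed column is no longer a partition of 1e6; a `renormalize_tpm` flag
is provided (off by default) for users who want one. Many-to-one
orthology, novel genes and CNV representation are out of scope: the
correction addresses errors caused by *divergent* genes only.

## Bias metrics

With 1000 simulated pairs per gene, a gene is correct in `[500, 1500]`
(inclusive — the under/over definitions are strict inequalities),
underestimated below, overestimated above. Cultivar-vs-cultivar
comparisons use the 1.5× fold rule with explicit zero handling (0 vs
positive → incorrect; 0 vs 0 → correct). Windowed bias scores count
`(−1)` per underestimated and `(+1)` per overestimated gene per window;
genes are binned by start coordinate (windows tile each chromosome
independently). `cds_identity()` is global Needleman–Wunsch (match +1,
mismatch −1, gap open/extend −2/−1), identity = matches / alignment
length × 100; with full-length indel-free pairs this equals the
edit-distance identity and agrees with a blast-style best hit, which it
replaces for real data. The enrichment report uses the standard 2×2
chi-squared without continuity correction (matching the closed form);
degenerate margins are reported as undefined rather than raised.

## Triad balance

Normalisation is `a = A/(A+B+D)` etc.; zero-total triads are excluded,
not classified. The seven ideal vectors are taken at face value as
printed in the field's standard category table — Balanced is
(0.33, 0.33, 0.33), *not* (1/3, 1/3, 1/3); the 0.0033 shortfall is
preserved deliberately and is far too small to move any assignment.
Classification is argmin Euclidean distance with a fixed, documented
tie-break order (Balanced, suppressed A/B/D, dominant A/B/D); ties have
measure zero on real data and are flagged when they occur.
Classification uses read counts rather than TPMs because reads are
simulated evenly per gene; both enter the same code path. The SCC
measure computes Spearman correlation (average ranks on ties) for the
AB, AD and BD pairs across samples and keeps the minimum;
zero-variance vectors leave a pair undefined and drop out of the
minimum.

## Coverage deviation

The statistic is `d_i = C_i / (m_i · ε)` per line and window. The
published verbal definition of `ε` ("the median d value across the
genome for the line") is circular — `ε` appears inside `d` — and is
resolved here as the median of the pre-scaling ratios
`r_i = C_i / m_i`, the unique reading under which each line's median
`d` equals 1 exactly. Windows with zero across-line median have no
defined ratio; they are excluded from `ε` and reported separately.
Flagging is per line across its own genome (not per window across
lines): `z = (d − median(d)) / (1.4826 · MAD(d))`, two-sided at
`Φ⁻¹(0.99) ≈ 2.33` with direction labels, the convention of MAD-based
outlier scoring; introgression/deletion scanning filters on `below`.
`d` is exactly invariant to uniform per-line depth scaling, and to
shared per-window mappability effects when line totals are supplied as
the external mapped-read counts (the intended usage); when totals are
derived as the row sums of the window matrix itself, the per-window
invariance holds only approximately. On event-free Poisson counts the
empirical two-sided flag rate runs slightly above the nominal 2%
(≈ 2.5% at depth 200 with 40 lines × 150 windows) because the median
profile and `ε` are themselves estimated; the test suite asserts a band
around the nominal rate rather than a point value.

## Numerical and degenerate-input policy

Fractional counts are compared with tolerances, never string equality;
count conservation holds to 1e-6 and duplicate-invariance to 1e-9.
Zero-total triads, zero-count denominators in fold comparisons,
zero-median windows, zero-MAD lines and empty strata in the enrichment
table are all explicit, reported states rather than errors or NaNs.
Errors are reserved for contract violations (overlapping introgression
specs, ragged count matrices, unknown genes in orthology, malformed
BED).

## Problem sizes and what the tests show

The study fixture is 150 triads (450 reference genes), four cultivars,
1000 pairs per gene (450,000 pairs per arm), k = 31 — chosen so the full
four-arm experiment, including index builds, runs in well under a minute
on one CPU while leaving every rate estimated from hundreds of genes.
The acceptance script (`scripts/acceptance.R`) re-runs it from a single
seed. The coverage-deviation arm uses 40 lines × 150 windows of 5 kb at
depth 200 with a 10-window 0.3× event — window size scales with the
miniature genome; the field-standard 1 Mb windows apply to real
chromosomes.

What passing tests do show: exact self-mapping recovery, oracle-exact
compatibility sets, conservation and duplicate-invariance of even
splitting, concentration of misquantification in introgressed blocks
with recovery by the pantranscriptome, correct triad classification
against brute force, and exact recovery of engineered coverage events.
What they do not show: behaviour under sequencing error, indels,
annotation mismatch, alternative isoforms, fragment-length variation,
EM-based abundance estimation, or repeat-induced k-mer collisions —
real-data effects the generator intentionally omits. Conclusions about
real pipelines should treat these results as the clean-divergence limit.
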