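---
title: "Methods: scoring genomic concordance between cell lines and tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring genomic concordance between cell lines and tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lineconcord` quantifies how faithfully a panel of cancer cell lines
represents a tumor cohort at the genomic level. It was built with
cutaneous melanoma in mind — where tumor purity, UV mutagenesis, and a
small set of mutually exclusive driver genes (*BRAF*, *NRAS*, *NF1*,
*PTEN*, ...) dominate the comparison — but every statistic is generic.
This vignette explains each method, its assumptions, the tunable
parameters, and the deliberate numerical choices.

## Tumor purity from expression

Bulk tumor expression mixes tumor, stromal, and immune cells. Comparing
impure tumors to clonal cell lines biases every downstream statistic, so
tumors are scored and filtered first.

For a stromal and an immune signature gene set, each sample receives a
single-sample enrichment (ssGSEA) score. Genes are ranked by expression
within the sample (average ranks on ties; the highest expression gets the
highest rank). Walking the gene list from the top rank down, the score is

$$ES = \sum_{k=1}^{G} \left( P_{\mathrm{in}}(k) - P_{\mathrm{out}}(k) \right),$$

where $P_{\mathrm{in}}$ is the cumulative distribution of in-set genes
weighted by $\mathrm{rank}^\alpha$ and $P_{\mathrm{out}}$ the unweighted
cumulative distribution of out-of-set genes. We fix $\alpha = 0.25$, the
conventional exponent for this statistic. Because only ranks enter, the
score is invariant under any strictly monotone per-sample transformation
of expression — in particular, whether RNA-seq values are log-transformed
before scoring is immaterial.

The combined (stromal + immune) score maps to an estimated tumor-cell
fraction through the published cosine calibration

$$\mathrm{purity} = \cos\left(0.6049872018 + 0.0001467884 \cdot ES_{\mathrm{combined}}\right),$$

hard-coded because the calibration is external to this package and has no
free parameters here. Purity is strictly decreasing in the combined score
while the cosine argument stays below $\pi$; samples whose argument passes
$\pi/2$ (raw value below zero) are clamped to 0 and flagged rather than
dropped. Cohorts are filtered at a tumor-cell fraction of 0.60 by default,
boundary inclusive. Note the calibration was fit on genome-scale
expression matrices; on small simulated matrices the absolute purity
values compress toward $\cos(0.605) \approx 0.82$, but the *ordering* —
which is what the filter and all tests below rely on — is preserved, and
that ordering is what the test suite asserts.

The package does not bundle the published 141-gene stromal and immune
signature lists; `read_gene_set()` accepts them in a plain one-symbol-
per-line format with a name header. The files shipped under
`inst/extdata/` (`geneset_*_synthetic.txt`) are synthetic toy signatures
matched to the simulator's gene model, usable only for demonstrations and
tests.

## Fraction genome altered

For a segmented copy-number profile with segment lengths $L_i$ and
normalized log2 ratios $CN_i$,

$$\mathrm{FGA} = \frac{\sum_i L_i \,[\,|CN_i| > T\,]}{\sum_i L_i}$$

over autosomal segments. Choices worth stating:

* The default threshold is $T = 0.2$ on the log2 scale, the common
  convention for calling a segment altered; it is a parameter everywhere.
* The inequality is strict: a segment sitting exactly at $T$ is not
  altered.
* X/Y segments are excluded from numerator and denominator, so
  male- and female-derived samples are comparable.
* SEG coordinates are treated as 1-based inclusive, so
  $L_i = \mathrm{end} - \mathrm{start} + 1$; this makes FGA exactly
  invariant under splitting a segment into pieces with the same mean,
  which the suite verifies.

## Gene-level copy number and concordance

Segments are projected onto a gene-coordinate model: each gene's value is
the overlap-length-weighted mean of all segments intersecting its span
(a gene fully inside one segment inherits that segment's value; a gene
with no overlapping segment is missing). Weighting resolves the
boundary-spanning case that a "genes within a segment" rule leaves open.
X/Y genes are dropped by default for the same reason as in FGA.

Concordance is the Pearson correlation of gene-level values between each
cell line and each tumor (a cell-line × tumor matrix), and between each
cell line and the gene-wise mean of all tumors. Correlations use
pairwise-complete genes; cells with fewer than 3 usable genes or zero
variance are reported missing with an explicit reason, and the number of
genes used is reported per cell. Restricting the gene universe to genes
inside recurrent focal amplification/deletion peaks (a user-supplied
list, e.g. from a GISTIC analysis) concentrates the comparison on the
regions where selection acts; on cohorts where non-focal genes are noise
this raises concordance, a behavior the suite checks on simulated
cohorts. Correlation against the tumor *mean* profile averages out
patient-private noise and therefore runs systematically higher than the
mean of the pairwise correlations — both are reported because they answer
different questions (typical similarity to an individual tumor versus
similarity to the cohort's shared signal).

## Differential mutation

Mutation presence is binary per gene and sample: at least one
non-synonymous SNP/insertion/deletion passing the variant-allele-fraction
(VAF ≥ 0.1) and read-depth (≥ 8 reads) filters. Synonymous variants never
set a presence bit. Per gene, the two cohorts are compared with a
two-sided Fisher exact test — the sum of probabilities, at fixed margins,
of all tables no more likely than the observed one, with ties included up
to a relative error of $10^{-7}$ (the convention of `stats::fisher.test`,
kept so results are comparable with the standard tool). Genes with fewer
than 5 mutated samples in total across both cohorts are skipped; the
threshold is interpreted as a total because a per-cohort reading would
silently drop exactly the one-sided extremes the test exists to find.

Bonferroni adjustment multiplies by the size of the shared gene universe
(genes mutated in both cohorts), not merely the number of genes passing
the frequency filter: the universe is the family of hypotheses considered.
Both the universe and the multiplier can be overridden.

## Mutual exclusivity

For a gene pair, condition on both margins of the 2×2 joint-status table.
The number of samples mutated in both genes, $B$, is then hypergeometric,
and the test is the one-sided lower tail with the mid-p convention:

$$p = P(B < b_{\mathrm{obs}}) + \tfrac{1}{2} P(B = b_{\mathrm{obs}}),$$

which is the k = 2 case of the exact test popularized for driver-pair
analysis (the CoMEt exact test). The mid-p convention — half weight on
the observed table — is the single most consequential numerical choice in
this module and is therefore stated prominently: a plain lower tail or a
two-sided variant gives visibly different values in the third significant
digit and beyond. Co-occurring pairs yield p near 1; with an empty
margin, $B$ is forced to 0 and $p = \tfrac12$ exactly. Testing all
$k(k-1)/2$ pairs of a gene list uses the number of pairs as the
Bonferroni multiplier (28 for the classic 8-gene melanoma panel).

Both exact tests accumulate hypergeometric terms in log space
(`dhyper(log = TRUE)` plus a max-shifted log-sum-exp), so p-values down
to $10^{-50}$ and far below are exact to double precision. The test
suite checks both implementations against an independent exact-rational
enumeration (big-integer binomials via Pascal's triangle; probabilities
as integer numerators over $\binom{N}{m_2}$) across an exhaustive margin
grid for all $n \le 60$, requiring agreement to at least 10 significant
digits.

## Coverage-normalized mutational burden

Burden is mutations per megabase of sufficiently covered sequence:
$n / (\mathrm{breadth}/10^6)$, reported alongside $\log_2$ of that rate.
Unlike the presence matrix, the count *includes* synonymous variants —
burden measures mutagenic load, not functional impact — and uses the
stricter 14-read depth filter, matching the depth at which breadth is
defined. Breadth comes from either dialect of coverage track:

* BED intervals (0-based, half-open), taken as already thresholded by
  the producer: breadth $= \sum (\mathrm{end} - \mathrm{start})$;
* WIG per-position depth (fixedStep/variableStep, with span): breadth
  = count of positions with depth ≥ 14.

Using the same depth cutoff on both sides keeps tumor and cell-line
burdens comparable even when their coverage formats differ.

## UV signature

Substitutions (SNP records only) are strand-normalized to the pyrimidine
reference: a G>A call is counted as C>T with complemented, swapped
flanks. A sample is UV-positive when C>T transitions at dipyrimidine
sites make up at least 60% of substitutions, or CC>TT events at least 5%.
Two open points were settled as follows:

* *Which flank must be a pyrimidine?* Either flank qualifies by default
  (`flank_rule = "either"`), with a switch for the stricter 5′-only
  definition.
* *How is CC>TT represented?* Since records carry single-base classes,
  CC>TT events are detected as two strand-normalized C>T substitutions at
  adjacent positions in the same sample, counted once per adjacent pair.

C>T records whose dipyrimidine status cannot be decided from the
available flanks are excluded from numerator *and* denominator and
tallied separately (`n_context_unknown`), so missing annotation degrades
power rather than biasing the fraction.

## Group comparisons and clustering

Group-level differences (FGA, log2 burden) use classic equal-variance
one-way ANOVA followed by Tukey's honestly-significant-difference
procedure on all pairs; classic rather than Welch ANOVA because the
Tukey follow-up presumes the pooled-variance model, and groups may be
unbalanced. Heatmap orderings use Ward linkage (`ward.D2`, the
implementation that squares Euclidean distances as Ward's criterion
requires) on Euclidean distances; missing entries are imputed to column
means with a note, and a degenerate all-equal matrix returns the input
order with a warning.

## The synthetic-cohort generator

`simulate_cohort()` emits a complete paired cohort — gene model, SEG,
MAF, per-sample coverage (BED for tumors, WIG for cell lines),
expression, signature gene sets, a focal-peak list — with a ground-truth
table for every planted quantity. It emulates the statistical structure
the analyses assume, not the biology:

* **Copy number**: chromosomes partitioned at focal-event boundaries;
  Gaussian segment-mean noise (`background_cn_sd`, default 0.1 log2
  units); each focal event carried per group with its own probability
  and a ±1 log2 effect. Planted FGA is the carried event length over the
  genome length, so on a noise-free cohort `fga()` recovers it exactly.
* **Mutations**: counts Poisson in each sample's covered gene space;
  a fraction `uv_weight` of substitutions drawn as dipyrimidine C>T
  (CC>TT pairs at a sub-rate), the rest from non-UV substitution types;
  half of all records emitted on the opposite strand to exercise
  normalization; VAF ~ Beta(2, 4) and depth ~ negative binomial
  (mean 60, size 2), heavy-tailed enough that a known fraction fails the
  0.1 / 14 filters.
* **Exclusive pair**: each sample carries gene A xor B with probability
  `coverage_prob` (split by `balance`), both with `co_occurrence_prob`;
  driver records always pass the filters so planted margins are
  recovered exactly. Setting `co_occurrence_prob` to the product of the
  marginals yields the independent null with identical margins.
* **Expression**: purity-weighted convex mixture of a tumor archetype
  and stromal/immune archetypes (signature genes elevated by 6 units),
  plus Gaussian noise; cell lines are pure.

Defaults are desk-scale and were chosen once: 2 chromosomes × 1 Mb, 200
genes of 400 bp, 40 tumors, 12 cell lines, background rate 500 mutations
per covered megabase — on this small genome that yields a few dozen
variants per sample, the same per-sample information content a
whole-exome cohort has at typical melanoma rates. Each data type draws
from its own seeded substream, so adding a generator never perturbs the
others, and all outputs are byte-identical for a given seed.

What the generator does **not** emulate: real chromosome lengths and
gene density, mutational hotspots, signature spectra beyond the UV rule,
linkage between copy number and expression, or sample-quality artifacts.
Passing tests therefore demonstrate that the statistics recover what was
planted under the stated noise models — not that the pipeline is robust
to every property of real TCGA/CCLE data.

## Problem sizes and runtime

The test suite runs the full pipeline on cohorts of 40 + 12 samples
(seconds per run), the exclusivity power checks on 412-sample status
draws over 20 replicates, the UV recovery check on 200-sample cohorts,
and the exact-test oracle over every margin-grid table for $n \le 60$.
These sizes were picked so the whole suite completes in about a minute
while still exercising each statistic at the scale where its published
behavior is visible.

## Known limitations

* The cosine purity calibration is taken as given; no tumor-type
  recalibration is attempted, and absolute purities on small gene panels
  are compressed (ordering is reliable, levels are not).
* Exclusivity is pairwise only; no k ≥ 3 generalization.
* No signature deconvolution beyond the binary UV rule.
* Focal-peak discovery (GISTIC-style) is upstream: peak gene lists are
  consumed, never computed.
* MAF parsing covers the common TCGA/CCLE column spellings; exotic
  dialects may need renaming upstream.
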