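---
title: "Methods: gradient hexanediol elution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient hexanediol elution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chsms)
```

# The experiment and its model

A gradient hexanediol elution experiment washes a chromatin preparation
first with isotonic buffer (IB), removing nucleoplasmic and cytoplasmic
background, then with increasing concentrations of 1,6-hexanediol (2%,
5%, 10%). 1,6-hexanediol weakens the hydrophobic contacts that hold
liquid-like condensates together, so proteins held in condensates by
weak multivalent interactions elute at low concentrations, while
proteins bound through stable structured interfaces largely resist
elution and stay with the buffer-washed material. Label-free
quantification (peak areas) of each fraction yields a protein × sample
table; everything downstream of that table is this package.

The analysis makes three modelling commitments:

* **Sequential elution is conservative.** Each fraction is physically
  distinct material, so a protein's "hexanediol abundance" is the *sum*
  of its three concentration fractions, and the elution behaviour of a
  protein is summarized by shares of that sum. The alternative
  (`hd_pooling = "max"`) is available for sensitivity analysis.
* **Ratios live on the raw scale.** Abundance ratios and shares are
  computed from replicate means of raw peak areas, with 0 for a group
  in which the protein was never observed. Imputation exists to make
  normalization and Z-scoring well defined; letting imputed values leak
  into ratio denominators would manufacture abundance in fractions
  where a protein was absent.
* **Normalization is distributional.** Quantile normalization forces
  all sample columns onto the mean order-statistic distribution. It
  assumes most proteins do not change between samples — reasonable for
  the bulk of a chromatin proteome, but it will shrink genuine global
  shifts (see Limitations).

# The preprocessing chain

Order matters and is enforced on a stage ledger carried by the table
(each step refuses to run after a later one):

1. `filter_high_confidence()` — keep proteins with (unique ≥ 1 and
   strict ≥ 2) or strict > 2 peptides. The strict-peptide ion-score
   cutoff itself is applied upstream by the search engine; this package
   consumes the counts.
2. `filter_detected()` — keep proteins observed in at least
   `min_detected_samples` (default 1) samples.
3. `impute_min()` — replace each missing cell with the minimum observed
   value of its **sample column** (default). Per-column scope respects
   sample-specific detection floors; `scope = "global"` (matrix-wide
   minimum) is provided because the convention is genuinely ambiguous.
   Cell provenance (observed/imputed) is recorded.
4. `quantile_normalize()` — via `limma::normalizeQuantiles(ties =
   TRUE)`: ties within a column receive the mean of the reference
   quantiles of their tied ranks, the most common convention. The
   transform is idempotent and is tested against a brute-force
   sort/argsort oracle.
5. `log2_zscore_by_group()` — group abundance is the arithmetic mean of
   the group's replicate columns on the raw scale (replicate handling
   is otherwise unspecified by the protocol); Z-scores use the sample
   (n − 1) standard deviation, matching common statistical software.

# Elution classes

With shares $s_2, s_5, s_{10}$ of the summed hexanediol abundance, a
protein is **representative** of concentration $c$ iff $s_c > 0.5$
(strict inequality — "exceeding 50%" — so at most one fraction
qualifies and a 50/30/20 split is *not* representative), **common**
when $\max_c s_c \in [0.2, 0.5]$ (closed band, "between 20 and 50%"),
and **minor** below 0.2. Both thresholds are arguments. Classification
is invariant to rescaling all abundances, which the tests assert.

Set-wise ratios (`setwise_abundance_ratio()`) aggregate numerator and
denominator over a protein set before dividing, rather than averaging
per-protein ratios: the set-level statistic weights proteins by
abundance, which is the natural reading of "ratio of protein abundance
captured". The denominator excludes the IB control by default (the
share decomposition over concentrations); `include_ib = TRUE` gives the
hexanediol-vs-buffer decomposition.

# Sequence features

* **Low-complexity fraction.** A SEG-style two-threshold entropy scan:
  every length-`W` window (default 12) with Shannon compositional
  complexity ≤ `locut` (2.2 bits) triggers a segment; triggers extend
  over contiguous windows ≤ `hicut` (2.5 bits); overlapping extended
  regions merge. The published detector's final optimal-subsegment
  refinement (P0 minimization) is deliberately omitted: the quantity
  consumed downstream is the per-protein covered-length fraction, for
  which boundary refinement is second order, and omitting it keeps the
  algorithm exactly testable against a brute-force oracle (200 seeded
  60-mers enumerate every window and extend by explicit scanning).
  Absolute fractions can therefore differ slightly from other
  implementations. `X` residues are excluded from composition counts
  (window length shrinks); an all-`X` window has undefined complexity
  and never triggers.
* **Disorder fraction.** Disorder prediction is consumed, not
  performed: intervals arrive as BED-like 0-based half-open rows,
  cross-checked against sequence lengths, and the fraction is the
  union length over protein length (as is the low-complexity
  fraction).
* **Charged fraction.** Count of D, E, K, R over length; histidine is
  excluded, matching the usual convention of sequence-parameter
  calculators at physiological pH.
* **Hydropathy.** Mean of $(KD(a) + 4.5)/9$ — the Kyte–Doolittle index
  rescaled residue-wise to $[0,1]$, so 0 is maximally polar
  (arginine) and 1 maximally hydrophobic (isoleucine).

External predictor scores (pi-contact, granule propensity,
self-assembly/partner-dependent propensities) are joined as opaque
numeric columns; their internals are out of scope.

# Statistics

* Chi-square: Pearson, no continuity correction, on 2 × k composition
  tables; zero marginals are an error rather than a silent 0-statistic.
* t test: Welch by default — treatment groups have no reason to share a
  variance; pooled Student's is an option. Two constant samples with
  equal means give p = 1 by convention.
* Mann–Whitney: exact p by the null permutation distribution when the
  combined sample size is ≤ 12 with no ties (cheap and exact), else the
  normal approximation with tie and continuity corrections. Tested
  against full enumeration and, for the t test, a 10⁴-shuffle
  permutation oracle.
* Enrichment: upper-tail hypergeometric $P(X \ge k)$ per annotation set
  after intersecting each set with the quantified universe, with
  Benjamini–Hochberg q-values across sets. This replaces web enrichment
  services with a transparent test over user-supplied GMT sets.
* The "high- vs low-abundance" contrast is operationalized as top vs
  bottom quartile of the per-treatment Z-scores (`quartile_split()`,
  ties broken lexicographically by protein id for determinism);
  `split = "median"` is the coarser alternative. The choice of split is
  not dictated by the protocol, so it is an explicit option.

# The synthetic-data generator

`simulate_study()` is first-class, tested code, not a fixture. It
plants three classes — defaults: 30% `llps_like`, 40% `structured`,
30% `background` over 2,000 proteins, 2 replicates per group — with
mean elution-share vectors over (IB, 2%, 5%, 10%):

| class | IB | 2% | 5% | 10% |
|---|---|---|---|---|
| llps_like | 0.10 | 0.60 | 0.20 | 0.10 |
| structured | 0.70 | 0.15 | 0.10 | 0.05 |
| background | 0.40 | 0.25 | 0.20 | 0.15 |

Totals are log-normal (meanlog = log 10⁷, sdlog = 1.5 — a realistic
peak-area spread of several orders of magnitude); replicate noise is
multiplicative log-normal with sdlog 0.2; 15% of cells go missing with
probability decreasing linearly in abundance rank, a left-censored-like
mechanism that makes minimum imputation meaningful. Peptide evidence is
drawn so about 97% of proteins pass the high-confidence filter.
Sequences are 300–800 residues; `llps_like` proteins carry 1–3
contiguous blocks (30–60% of residues) drawn from a
serine/glycine/glutamine/proline-biased alphabet (entropy ≈ 1.8
bits, safely under the 2.2-bit trigger), with disorder intervals over
those blocks; `structured` proteins are near-uniform over the 20-letter
alphabet with < 10% disorder; `background` sits between. Everything is
deterministic given the seed.

What the generator does **not** emulate: peptide-level quantification
and shared peptides, correlated replicate structure (batch effects),
interaction-driven co-elution of complexes, compositional biases of
real proteomes, and real disorder predictors' errors. Passing recovery
tests therefore demonstrates that the pipeline's inferences are correct
*when its assumptions hold*, not that the assumptions hold for any
particular instrument run.

# Numerical choices and degenerate inputs

* Missing cells are empty strings or `NA` (case-insensitive) on disk;
  zeros are observed values, not missing.
* Shares must sum to 1 within 10⁻⁹; proteins with zero denominator get
  undefined ratios/shares and the class `undefined`, and are counted in
  messages rather than dropped silently.
* Z-scores error on zero spread rather than returning NaNs; imputation
  errors on an all-missing column; the hypergeometric test errors on an
  empty query or universe.
* TSV output writes doubles with 17 significant digits so round trips
  are bit-identical.
* Test and acceptance problem sizes: unit tests run on 1–30 protein
  tables and 60-residue sequences; generator tests at 150–300 proteins;
  recovery checks at the full default of 2,000 proteins. The whole
  suite is a desk-scale computation.

# Limitations

* Quantile normalization assumes comparable abundance distributions
  across fractions; a fraction that genuinely elutes far less total
  protein is partially renormalized away.
* The low-complexity detector omits boundary refinement (above), so
  segment edges — though not coverage fractions — can differ from other
  tools.
* Minimum imputation is a point estimate at the detection floor; it
  understates uncertainty for proteins missing in many samples.
* Elution classes are hard thresholds on noisy shares; proteins near
  0.5 flip classes between replicate draws. The thresholds are
  parameters precisely so users can probe that sensitivity.
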