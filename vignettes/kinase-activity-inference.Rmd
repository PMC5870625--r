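---
title: "Substrate-based kinase activity inference: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-based kinase activity inference: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ksinfer)
```

## The inference model

All methods in `ksinfer` share one premise: when a kinase is activated or
inhibited between two conditions, the phosphorylation of its substrate
sites changes coherently relative to the background of all quantified
phosphosites. The data are site-level log2 fold changes (one value per
phosphosite per condition, after peptide-level collapsing); the prior
knowledge is a kinase–substrate network assigning each kinase a regulon of
(protein, position) sites. Nothing in the model distinguishes direct
catalysis from faithful downstream propagation — the methods detect
coherent regulon shifts, whatever their mechanistic path.

Five statistics quantify that shift per (kinase, condition):

* **Z-test** (`activity_ztest`): a one-sample test of the regulon mean
  against the condition background, `z = (m_S - m_P) sqrt(n_S) / delta`,
  with `m_P` and `delta` the mean and *sample* SD of all fold changes in
  the condition (population vs sample SD is immaterial at the >= 1000
  quantified sites where the methods operate, but the contract is sample
  SD). The background deliberately includes the substrates themselves.
* **KS** (`activity_ks`) and **Wilcoxon** (`activity_wilcoxon`): two-sample
  tests of substrates against non-substrates.
* **Enrichment score** (`activity_ksea`): GSEA-style weighted running sum
  over the fold-change ranking (weight exponent 1), significance from an
  empirical permutation null.
* **Ridge MLR** (`activity_mlr`): all kinases of a condition fitted
  jointly, `argmin ||Y - X beta||^2 + lambda ||beta||^2`. The L2 penalty
  tempers collinearity between kinases that share substrates; `beta` is
  reported directly (no p-value).

P-value methods are folded into one number per cell, the signed score
`sign(m_S) * (-log10 p)`. The sign comes from the raw substrate mean, not
from the test statistic, so a kinase whose substrates fall scores negative
even for the sign-blind KS test.

## Tunable parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| `min_coverage` | 1000 sites | `preprocess_records` | conditions quantifying fewer sites give unstable backgrounds and are dropped |
| `n_perm` | 10,000 | `activity_ksea` | permutation-null resolution; the p floor is `1/(n_perm+1)` |
| `lambda` | 0.1 | `activity_mlr` | ridge penalty on the binary connectivity fit; unscaled by sample count |
| `min_substrates` (PWM) | 10 | `build_pwm_library` | below ~10 flanks a frequency matrix is mostly pseudocount |
| `pseudocount` | 0.01/cell | `build_pwm` | keeps the information vector finite for small regulons |
| `n_randomizations` | 60 | `run_benchmark` | negative-set resampling depth; medians over it are the summary |
| `n_repeats` | 25 | `downsample_substrates` | regulon down-sampling for evidence-class comparisons |
| minimum substrates per kinase | 3 | `filter_min_substrates` | below 3 sites a regulon mean is hardly distinguishable from noise |

## Numerical choices

* **Quantile normalization with missing values.** Each column's observed
  values are ranked (average ranks on ties) and mapped onto a reference
  distribution: the mean of per-column sorted values interpolated onto a
  common grid as long as the largest observed count. Missing entries stay
  missing. Columns with equal observed counts end up with identical sorted
  values; on complete matrices the result coincides with the classical
  procedure (cross-checked against `limma::normalizeQuantiles` in the
  tests).
* **Averaging order.** When records carry a peptide identity, fold changes
  are averaged first across replicates of the same peptide, then across
  peptides covering the same site; without peptide identity both collapse
  in one mean. The orders differ only when replicates carry unequal
  peptide counts.
* **KS p-value.** The asymptotic Kolmogorov tail is visibly conservative
  at regulon sizes of 10–30 against thousands of background sites —
  conservative enough to fail a null-calibration check. The default is
  therefore the exact two-sample p (`stats::psmirnov`) whenever the pooled
  values are tie-free, falling back to the asymptotic series (summed to
  1e-14) otherwise; `exact = FALSE` forces the asymptotic value.
* **Enrichment-score ties.** Sites are ranked by fold change descending
  with input order as a stable tie-break. The permutation p counts
  `|ES_null| >= |ES_obs| - 1e-12`: distinct substrate sets can tie in |ES|
  *exactly* (for instance through a shared pre-hit minimum), and the
  tolerance makes the count independent of floating-point summation order.
  Genuinely distinct |ES| values sit far above 1e-12 apart. The empirical
  p carries a +1 pseudo-count so it is never 0; exhaustive enumeration
  (`exhaustive = TRUE`) is available for small instances and carries no
  pseudo-count since the observed set is among those enumerated.
* **PWM alphabet.** 21 symbols: 20 amino acids plus `_` for positions
  beyond a protein terminus, natural log, so a single-letter column at
  pseudocount 0 has information ln(21). A consequence worth knowing:
  uniformly random flanks converge to information ln(21/20) ≈ 0.049 per
  position, not 0, because the padding symbol never occurs internally.
  The central phosphoacceptor column is included (it carries S/T versus Y
  information).
* **ROC convention.** Tied classifier scores are grouped into single
  threshold steps with trapezoidal interpolation, which makes the AUC
  equal the Mann–Whitney pairwise probability (ties count one half).
  Precision at recall 0.5 is read at the smallest achieved recall >= 0.5.
* **Randomness.** Every stochastic operation takes an explicit seed;
  `infer_activities` derives an independent child seed per
  (kinase, condition) permutation stream, and the C++ permutation loop
  draws from R's RNG, so a fixed seed reproduces results bit for bit.

## Design decisions that were genuinely open

* **Matching quant to network on (protein, position) only.** Residue
  annotations disagree across source databases often enough that requiring
  residue equality silently shrinks regulons; mismatches warn instead.
* **Autoregulatory exclusion by mapping.** Sites on the kinase's own
  protein are removed (given a kinase-to-protein mapping) because direct
  regulatory autophosphorylation would hand the methods a trivial
  self-signal.
* **Background composition.** The Z-test compares against *all* fold
  changes of the condition; KS/Wilcoxon compare substrates against
  *non-substrates*. Both conventions are kept as stated rather than
  harmonized, since each is the standard form of its test.
* **Weighted variants leave non-substrates untouched.** Only the regulon's
  fold changes are multiplied by their MSS; the background is unaltered,
  so a low-affinity substrate is shrunk toward 0 rather than re-ranked
  among background sites.
* **Classifier score is |signed score|.** The benchmark asks whether
  regulation is detected, not its direction; the gold-standard direction
  feeds a separate direction-accuracy report.
* **Negative sampling.** Negatives are drawn uniformly without replacement
  from the gold-standard kinases × conditions grid minus the positives,
  independently per randomization; each negative set has exactly the size
  of the positive set.

## What the generator emulates — and what it does not

`simulate_dataset()` produces the reference testbed used by the tests and
the acceptance script: 2000 sites, 20 kinases with regulons of 10–30
sites, 10 conditions with 2 regulated kinases each, additive shifts of
±2 on an N(0, 1) background, 20% missingness, and flanking windows that
match a per-kinase consensus at 90% of positions. These sizes mirror a
mid-sized perturbation study (a condition passing the 1000-site coverage
filter, regulons in the range where curated kinases actually live) and
give the statistics realistic substrate counts; with `scale_by_mss = TRUE`
each substrate's true shift is scaled by its MSS so that sequence-weighted
methods have honest signal to exploit. Every site sits at the center of
its own 15-residue synthetic protein, so flank extraction is exact;
terminal-padding paths are exercised on hand-built fixtures instead.

The generator is deliberately idealized: noise is i.i.d. Gaussian,
missingness is completely at random, shifts are additive and equal across
a regulon, there are no replicates, no intensity-dependent variance, no
correlated off-target signal, and evidence classes are uniform. Passing
tests therefore demonstrate correctness and calibration of the statistics
under the stated model — not robustness to the heavy-tailed, structured
noise of real MS data. Conversely, the idealized signal model means the
*power* results (near-perfect AUC at effect/noise = 2 with regulons of
>= 10) should be read as upper bounds.

## Validation summary

The test suite asserts, among others: exact agreement of every statistic
with independently coded oracles (closed-form z, ECDF double loop,
tie-corrected rank-sum, naive running sum, exhaustive subset enumeration,
augmented-QR ridge, Mann–Whitney AUC, dot-product MSS); uniform p-values
and chance-level AUC on pure-noise simulations; monotone power in
effect/noise; collapse to chance under degree-preserving network
randomization; no loss from MSS weighting on motif-scaled signal; the
hand-enumerated preprocessing contract; and byte-identical end-to-end
reruns under fixed seeds. `scripts/acceptance.R` recomputes the headline
quantities from scratch at the study sizes above (permutation nulls scaled
to 1000 draws there; the package default stays 10,000).

## Known limitations

* Kinase–substrate annotation quality dominates real-world performance;
  the package quantifies this only through its randomization and
  down-sampling controls, not through annotation curation.
* The MLR scores are raw ridge coefficients: comparable within a
  condition, but without a significance measure.
* The exact KS p is skipped whenever ties are present (real data rounded
  to few decimals can tie); the asymptotic fallback is conservative for
  small regulons.
* PWMs treat regulon flanks as one motif; kinases with composite or
  context-dependent specificity are averaged into a single matrix.
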