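---
title: "Methods: from a plasma lipidome to a lipid species ratio"
author: "lipidlsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a plasma lipidome to a lipid species ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidlsr)
```

`lipidlsr` condenses a subjects × lipid-species concentration matrix into a
single obesity marker, the lipid species ratio (LSR), through a fixed
sequence of stages. This vignette states the statistical model behind each
stage, the tunable parameters and why their defaults are what they are, what
the synthetic cohort generator does and does not emulate, and the numerical
decisions a maintainer should know about.

## Input model and preprocessing

The input is a wide table: one row per subject with metadata (`subject_id`,
`age` in years, `sex`, `ethnicity`, `bmi` in kg/m²) followed by one column
per lipid species, named in Lipidyzer/LIPID-MAPS shorthand and quantified in
µmol/L (or nmol/g plasma, converted by the identity under the 1 g ≈ 1 mL
plasma convention). Subjects with missing metadata are not accepted; they
must be excluded upstream, mirroring how such cohorts are curated.

Three preprocessing rules operate before any inference:

* **Blank correction** subtracts the reagent-blank signal and floors at
  zero: a corrected concentration is a physical quantity, so negative
  residues from subtraction are truncated rather than propagated.
* **QC batch exclusion** drops a whole measurement batch when its QC sample
  deviates from the nominal target by strictly more than the tolerance
  (default `qc_tolerance = 0.20`) for *any* monitored species. Two readings
  were possible here; the any-species rule is the conservative one and is
  the default (`rule = "all"` is available). A deviation of exactly 20 % is
  retained — the rule is a strict "outside".
* **Normality gating and two-step normalization.** Each species vector is
  Shapiro–Wilk tested; variables rejected at α = 0.05 are transformed by the
  two-step rank-based method: fractional ranks mapped through the inverse
  standard-normal quantile, then rescaled to the original sample mean and
  SD. The fractional-rank formula is Blom's, (r − 3/8)/(n + 1/4), because
  the naive r/n maps the top rank to 1 and hence to an infinite quantile;
  r/(n + 1) is available as an alternative. The normal scores are
  standardized before rescaling, which makes mean/SD preservation exact (to
  floating point) in the tie-free case. Ties receive mean ranks, so the
  transform preserves the input's weak ordering and is idempotent up to tie
  effects. Only lipid variables are gated and transformed by default; BMI
  and age enter the regressions untransformed.

## Class-level statistics

Per-subject class totals are sums of raw (untransformed) µmol/L values over
member species. Group comparisons use rank statistics, which are invariant
to monotone transforms, so normalization is deliberately not applied here:
Mann–Whitney U for pairwise category contrasts (exact when
n<sub>A</sub>·n<sub>B</sub> ≤ 400 and tie-free, otherwise tie-corrected
normal approximation) and the Jonckheere–Terpstra test for a monotone trend
across the ordered BMI categories.

The JT statistic counts concordant cross-group pairs (ties half-weighted).
Under the tie-free null it decomposes into a sum of independent Mann–Whitney
statistics of each group against the pooled earlier groups; the exact small-n
null distribution is therefore the convolution of Mann–Whitney null
distributions, used by default up to total n = 12. Tied data always use the
tie-corrected normal approximation (Hollander–Wolfe variance); the exactness
claim is limited to the tie-free case. The trend alternative defaults to
two-sided, since a direction should be a finding rather than an assumption;
one-sided alternatives are available.

## Species clustering

The species correlation matrix is eigen-decomposed via the SVD of the
standardized data matrix — with many more species than subjects the
correlation matrix is rank-deficient and the SVD route is both cheaper and
numerically cleaner; eigenvalues beyond the rank are exactly zero and simply
never pass retention. Correlation (not covariance) is used so the
eigenvalue ≥ 2 retention convention applies; the threshold
(`eigenvalue_threshold = 2.0`) is the conventional "a cluster should explain
at least two variables' worth of variance" rule.

Retained loadings are varimax-rotated. The rotation is Kaiser's classical
pairwise algorithm with the closed-form optimal angle per factor pair, on
Kaiser-normalized rows, iterated until the criterion improves by less than
10⁻⁶ (at most 1000 sweeps). The pairwise algorithm was chosen over the
SVD-projection iteration used elsewhere because the latter has a fixed point
at every rotation whenever the loading matrix is column-orthogonal (e.g. a
perfectly symmetric two-variable, two-factor configuration) and cannot leave
it; the pairwise closed form solves that case exactly. Orthogonality of the
rotation guarantees per-species communalities are conserved, which the test
suite asserts to 10⁻⁸.

Sign indeterminacy is removed by flipping each rotated factor so that its
largest-magnitude loading is positive, making traces reproducible run to
run. Subject scores use the regression (Thurstone) method with the
pseudo-inverse of the correlation matrix — the only well-defined choice at
p ≫ n.

Cluster–BMI association regresses BMI on each factor score plus sex, age and
ethnicity. BMI is the dependent variable; the reverse orientation is a
defensible alternative but the dependent-BMI form keeps every stage of the
pipeline (cluster screen, stepwise, greedy refits) on the same model family.
Species are then assigned to the unique cluster where |loading| > 0.5
(`loading_threshold`); species qualifying on several clusters are excluded
as `multi_cluster`, species qualifying nowhere as `low_loading`, and a
loading of exactly 0.5 does not qualify. The loading filter runs on all
retained clusters, not only the BMI-significant ones; both the association
table and the assignment are kept in the fitted object so either reading can
be audited.

## Stepwise selection and multiplicity

Within each cluster, forward-entry/backward-removal stepwise OLS of BMI on
the cluster's species runs with sex, age and ethnicity forced into every
model. Entry requires p < 0.05 and removal p > 0.10 — the defaults of the
major commercial stepwise implementations — and the procedure iterates to a
fixed point, choosing at each step the candidate with the smallest p (ties
broken by column order, so runs are deterministic). Candidates that would
make the design rank-deficient can never enter. Stepwise selection inflates
false positives relative to a single test at α; the test suite characterizes
this empirically on pure-noise candidates rather than pretending the rate
equals α.

The Bonferroni threshold is α divided by the number of independent stepwise
analyses. Two divisor conventions are defensible: the number of clusters
that yielded at least one nominally significant species (default) or the
number of clusters entering stepwise; both are supported
(`bonferroni_divisor`), and an explicit integer can be given. Only
Bonferroni-significant candidates feed the greedy stage by default
(`candidate_mode = "bonferroni"`; `"nominal"` is available).

## Greedy panel construction and the LSR

Within each direction of association, candidates are ranked by descending
−log₁₀(p) from the stepwise stage (ties broken lexicographically by species
name). The running sum starts at the top candidate — the reference lipid
molecule — and each subsequent candidate is tentatively added, the adjusted
OLS of BMI on the sum refitted, and the candidate kept only when the new
p-value is *strictly* smaller than the best so far; ties reject. Every
candidate is visited exactly once, so the trace has one row per candidate
and the final sum's p never exceeds the reference's — an invariant asserted
on every run. The per-step regressions are covariate-adjusted by default
(`adjusted_accumulation = FALSE` reproduces the unadjusted variant).

Accumulation sums *raw* µmol/L concentrations — panel sums are physical
quantities and the resulting cut-offs must be in concentration units — while
the association refits use the same adjusted OLS as the selection stage.
The LSR is the per-subject ratio of the positive over the negative panel
sum; it is undefined (and the subject dropped with a warning) when the
denominator is non-positive, which cannot occur with strictly positive
concentrations but can after aggressive blank correction.

## Reference cut-offs

ROC/Youden analysis contrasts normal-weight (BMI < 25) against obese
(BMI ≥ 30) subjects only; the overweight band is excluded so the cut-off
separates the two ends of the range. Candidate thresholds are the midpoints
between consecutive distinct values plus ±∞, evaluated in both positivity
directions; the returned direction makes J ≥ 0. When several thresholds tie
on J, the one with higher specificity wins — the more conservative positive
call. Cut-offs are reported on the raw measurement scale, with sensitivity
and specificity in percent and J = sens + spec − 1.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline assumes,
not the chemistry that produced it. Subjects: fixed category counts
57/31/48 (normal/overweight/obese; probabilistic sampling available), BMI
from truncated normals within each category band, age from a truncated
normal 45 ± 11 on [20, 64], sex and ethnicity at the cohort proportions
94/136 female and 71/136 HG. Species: a deterministic 550-name catalogue
(5 Cer, 14 CE, 12 DG, 8 FA, 2 HexCer, 9 LPC, 4 LPE, 40 PC, 28 PE, 4 SM,
424 TG), log-concentrations from a latent-factor model

log C<sub>s</sub> = µ<sub>s</sub> + λ F<sub>k(s)</sub> + γ<sub>s</sub> z(BMI) + σ ε,

exponentiated to right-skewed, strictly positive concentrations. Defaults:
10 latent clusters in contiguous class-ordered blocks, loading λ = 0.8 and
residual σ = 0.4, giving within-cluster correlations of 0.8 — the strong
co-regulation typical of lipid classes, and strong enough that the noise
bulk of the correlation spectrum stays below the retention threshold at
550 species × 136 subjects. Class-level µ<sub>s</sub> place class totals
near typical adult plasma levels (TGs in the low thousands of µmol/L, CEs
and PCs above a thousand, minor classes below ten).

The planted signal is 4 positive and 3 negative species at standardized
effect 0.4 on the log scale. Each planted species lives in its own latent
cluster — a panel concentrated in one cluster would collapse to a single
representative under within-cluster stepwise — and panel species share a
per-direction location scale (positives ≈ 0.5 µmol/L, negatives ≈ 25 µmol/L
per species) so each contributes measurably to its panel sum, as in a panel
whose members were individually accepted by the greedy rule. Latent factors
are independent of BMI by default, so the only BMI signal is the planted
one; `cluster_bmi_effect` optionally adds a signed factor-level effect to
the planted species' clusters for scenarios where whole clusters track BMI.

What the generator does *not* emulate: inter-lipid biochemical constraints
(chain-length/saturation gradients, shared synthesis pathways), instrument
drift, batch effects on the concentrations themselves (batches only carry
the QC/blank structure), heavy-tailed measurement error, or missingness.
Passing tests on these cohorts therefore demonstrate that the pipeline's
inferential machinery behaves as specified under its own assumptions — not
that the biological findings of any particular cohort transfer.

Batch structure: subjects are grouped in batches of 8 with QC measurements
around the nominal value (uniform ±10 %); a configurable fraction of batches
receives one species pushed 25–50 % off nominal, beyond the 20 % rule.

## Numerical choices and degenerate inputs

* OLS throughout is QR-based; rank-deficient designs are an error (or, in
  stepwise, the candidate simply cannot enter).
* p-values are floored at the smallest positive double before −log₁₀, so a
  numerically zero p prints as ≈ 307.65 rather than ∞.
* Constant species columns are rejected by name before PCA and
  normalization; constant vectors are errors for the Shapiro–Wilk gate and
  the two-step transform.
* Varimax: criterion tolerance 10⁻⁶, ≤ 1000 sweeps, rotations skipped below
  an angle of 10⁻¹⁴; the criterion reported by `varimax_criterion()` is the
  Kaiser-normalized form that the rotation maximizes.
* Score computation zeroes reciprocal eigenvalues below 10⁻⁸ instead of
  amplifying numerical noise.
* Greedy ties (new p exactly equal to the best) reject, by the strict
  reading of "a decrease in p".
* The exact JT path is limited to tie-free data and total n ≤ `exact_max`
  (default 12); everything else uses the tie-corrected normal
  approximation without continuity correction.

## Problem sizes in the test suite

The suite exercises the default cohort scale (136 × 550) for end-to-end
properties: 50 seeded replicates for planted-panel recovery and for the
LSR-versus-single-species comparison, 100 reduced cohorts (136 × 60) for the
greedy improvement invariant, 2000 null simulations for the trend test's
type-I error, exhaustive enumeration oracles for JT (all 3-group layouts
with n ≤ 9), Youden (100 random instances against brute force), and varimax
(dense 2-factor angle grids). These sizes give stable pass/fail behaviour
at conventional binomial tolerances while keeping a full run in the order of
a minute.

## Known limitations

* Stepwise selection is used because it is the procedure under study, not
  because it is recommended practice; its false-selection inflation is
  documented empirically in the tests.
* The greedy accumulation is order-dependent by construction; it makes no
  claim of finding the best subset, and the ranking key (stepwise
  −log₁₀(p)) is one of several defensible choices.
* The Bonferroni divisor is ambiguous between two cluster counts; both are
  implemented and the default documented above.
* Exact JT inference is unavailable under ties.
* ROC cut-offs come with no confidence intervals and no external
  validation; they describe the fitted cohort only.
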