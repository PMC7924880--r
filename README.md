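# lipidlsr

Hierarchical analysis of targeted plasma lipidomics cohorts, from a raw
subjects × lipid-species concentration table to a reference cut-off for an
obesity biomarker.

## The problem

Targeted lipidomics platforms quantify hundreds of lipid species (here 550
species across 13 classes: Cer, CE, DG, ACer, FA, HexCer, LacCer, LPC, LPE,
PC, PE, SM, TG) in each plasma sample. Class-level totals hide which
individual species track adiposity. `lipidlsr` implements a pipeline that
identifies the body-mass-index-associated species and condenses them into a
single interpretable marker, the **lipid species ratio (LSR)**:

```
        sum of concentrations of species positively associated with BMI
LSR = ------------------------------------------------------------------
        sum of concentrations of species negatively associated with BMI
```

computed per subject in µmol/L over µmol/L (dimensionless). The stages, in
fixed order:

1. **Preprocessing** — nmol/g → µmol/L unit conversion (1 g plasma ≡ 1 mL),
   blank correction, exclusion of whole measurement batches whose QC sample
   deviates > ±20 % from nominal, and a rank-based two-step normalization
   (fractional ranks by Blom's formula, inverse-normal quantiles, rescaled to
   the original mean/SD) applied per variable when Shapiro–Wilk rejects
   normality.
2. **Class statistics** — per-class totals with Mann–Whitney U pairwise
   comparisons and the Jonckheere–Terpstra ordered-trend test across BMI
   categories (normal < 25, overweight 25–29.9, obese ≥ 30 kg/m²).
3. **Species clustering** — principal component analysis of the species
   correlation matrix, components with eigenvalue ≥ 2 retained,
   varimax-rotated (Kaiser's pairwise algorithm), subject scores by the
   regression method; cluster–BMI association by OLS adjusted for sex, age,
   ethnicity; species assigned to the single cluster where |loading| > 0.5.
4. **Selection** — per-cluster forward/backward stepwise OLS of BMI on
   species (covariates forced in; entry p < 0.05, removal p > 0.10), with a
   Bonferroni threshold of 0.05 divided by the number of contributing
   clusters.
5. **Greedy panel construction** — per direction, candidates ranked by
   −log₁₀(p); the running concentration sum starts at the top candidate (the
   reference lipid molecule) and each further candidate is kept only if it
   strictly decreases the adjusted regression p-value of the sum.
6. **Reference values** — ROC analysis of the two panel sums and the LSR
   contrasting normal-weight vs obese subjects; the cut-off maximizes
   Youden's J = sensitivity + specificity − 1.

Because cohort lipidomics data of this kind are rarely shareable, the package
ships a synthetic cohort generator (`generate_cohort()`) with the matching
statistical structure — log-normal concentrations, latent correlation
clusters, planted positively/negatively associated species — so the whole
pipeline is testable end-to-end.

## Worked example

```r
library(lipidlsr)

coh <- generate_cohort(synthetic_config(), seed = 1)
fit <- lipid_lsr(coh$conc, coh$meta)
fit
#> Lipid species ratio pipeline
#>   subjects: 136, species: 550
#>   clusters retained (eigenvalue >= 2): 11 (82.61% variance)
#>   species assigned: 550 in 10 cluster(s)
#>   stepwise: 36 nominal, 22 Bonferroni-significant (p < 0.0071)
#>   panel: 3 positive + 6 negative species
#>   LSR ~ BMI (adjusted): beta = 133.1, -log10(p) = 15.025
```

136 subjects were analyzed; 11 principal-component clusters carried 82.6 % of
the species variance; stepwise selection found 36 nominally and 22
Bonferroni-significant BMI-associated species; greedy accumulation kept 3
positive and 6 negative species, and the resulting LSR associates with BMI at
p ≈ 10⁻¹⁵ after adjustment — stronger than any single species in the panel.
The recovered panel contains the planted ground-truth species
(`coh$truth$planted_positive`, `coh$truth$planted_negative`):

```r
fit$panel
#> $positive
#> [1] "TG 22:6_36:4"   "PE P-16:0/20:3" "TG 18:3_33:0"
#> $negative
#> [1] "LPC 18:2"             "Hex-Cer 18:1;O2/22:0" "PC 18:1_18:1"
#> [4] "FA 22:6"              "TG 17:1_28:0"         "TG 16:3_29:0"

fit$reference_values[, c("variable", "cutoff", "direction",
                         "sensitivity", "specificity", "youden_j")]
#>       variable  cutoff direction sensitivity specificity youden_j
#> 1 positive_sum  1.4060        >=        79.2        86.0    0.651
#> 2 negative_sum 82.5011         <        89.6        73.7    0.633
#> 3          lsr  0.0173        >=        89.6        91.2    0.808
```

An LSR at or above 0.017 calls a subject obese-positive with 89.6 %
sensitivity and 91.2 % specificity on this cohort. Standard methods are
available: `summary()`, `coef()` (adjusted LSR model coefficients),
`predict()` (panel sums and LSR for new concentration tables),
`residuals()`, `plot()` (scree and selection strength).

Lipid shorthand parsing is exposed directly:

```r
parse_lipid_name("TG 20:4_33:1")
#> <lipid_species> TG 20:4_33:1  [class TG, 53 C, 5 double bond(s)]
```

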