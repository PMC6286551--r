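# coxladder

Prognostic factors in breast cancer — age at diagnosis, tumor size, and
the number of positive lymph nodes — are continuous or integer-valued,
but clinical practice categorizes them. How much prognostic information
does categorization cost, and how much is regained by modeling
continuous, possibly non-linear effects? `coxladder` answers this with a
ladder of Cox proportional-hazards models of increasing complexity,
fitted to a common derivation cohort and externally validated by weight
transport, with everything testable against synthetic cohorts whose true
effects are known.

## The ladder

For patient *i* in stratum *s* (patient material), the hazard of distant
recurrence is

&nbsp;&nbsp;&nbsp;&nbsp;λᵢ(t) = λ₀ₛ(t) · exp{ Σⱼ fⱼ(xᵢⱼ)ᵀ βⱼ },

where the coding fⱼ of each factor defines the model class:

| class | coding per factor |
|---|---|
| `dichotomized` | one clinical cut-point (35 yr; 20 mm; any positive node) |
| `categorized` | 3–4 clinical groups (age <35/35–50/>50; T1/T2/T3; N0/N1–3/N4–9/N10+) |
| `fp` | fractional polynomials, powers from {−2, −1, −½, 0, ½, 1, 2, 3}, chosen by a closed-test procedure (MFP) at α = 0.05 |
| `rcs` | restricted cubic splines, 5 knots, linear beyond the boundary knots |

Estimation maximizes the stratified Cox partial likelihood
(Newton–Raphson, Breslow or Efron ties) — implemented from first
principles in `cox_fit()`. Discrimination is Harrell's concordance index
C (fraction of evaluable patient pairs in which the longer-surviving
patient has the lower predicted hazard; 0.5 = useless, 1.0 = perfect).
The prognostic index (PI) — the linear predictor centered at a reference
patient (35 yr, 20 mm, 0 nodes; relative hazard 1.00 by definition) — is
cut at its 16th/50th/84th percentiles into risk groups G1–G4, and the
frozen transforms, weights and cut-offs are transported to an independent
validation cohort.

## Worked example

```r
library(coxladder)
report <- run_study(study_config())   # synthetic derivation + validation
report
#> Model-comparison study: 4477 derivation / 1132 validation patients (1303 / 301 events)
#>   dichotomized C(derivation) = 0.665  C(validation) = 0.662
#>   categorized  C(derivation) = 0.713  C(validation) = 0.690
#>   fp           C(derivation) = 0.732  C(validation) = 0.718
#>   rcs          C(derivation) = 0.732  C(validation) = 0.719
```

Reading the numbers: allowing more than one cut-point per factor raises C
substantially (0.665 → 0.713); the further gain from fully continuous
FP or RCS codings is modest (≈ 0.02), and the two continuous codings are
practically indistinguishable — the qualitative pattern reported for the
real cohorts this package emulates. Drilling into the FP entry:

```r
fp <- report$models$fp
fp$model
#> Prognostic model (fp): age_years, tumor_size_mm, n_pos_nodes
#>   age_years: FP powers (1)
#>   tumor_size_mm: FP powers (1)
#>   n_pos_nodes: FP powers (0)
#>   ...
round(fp$group_fractions_validation, 2)
#> [1] 0.31 0.35 0.25 0.08
```

The selected transforms keep age linear and give the node count a
logarithmic shape; on the lower-risk validation draw the derivation PI
cut-offs put 31% of patients in G1 and only 8% in G4 instead of the
nominal 16/34/34/16 — the occupancy shift that external validation of a
frozen model is designed to expose. Per-covariate relative-hazard curves
with bootstrap bands (selection rerun inside every replicate), KM curves
per risk group, and PI histograms are available via
`plot_relative_hazard()`, `plot_km_groups()` and `plot_pi_hist()`.

A command-line wrapper with `simulate` / `fit` / `validate` / `report`
subcommands is installed at `inst/cli/coxladder.R`:

```sh
Rscript inst/cli/coxladder.R report --seed 1 --out report.json
```

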