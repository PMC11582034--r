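# rdmdea

Benchmarking drugs — or any decision-making units whose outcomes can be
negative — with the **range directional model (RDM)**, a data envelopment
analysis (DEA) variant built on the directional distance function.

## The problem

How much benefit and harm does a drug deliver *per dose*? For type-2
diabetes treatments the relevant factors point in different directions:
dose frequency (an input — fewer administrations are better), HbA1c
reduction and weight change (desirable outputs; weight change is negative
for drugs that cause weight gain), and all-cause mortality odds ratio
against placebo (an undesirable output — lower is better). Classical
radial DEA breaks down when outputs take negative values and when some
outputs are harms. The RDM handles both: each unit is moved toward the
best-practice frontier along its own *range of possible improvement*,

- inputs: `R_x[o,j] = x[o,j] − min_i x[i,j]`
- desirable outputs: `R_y[o,r] = max_i y[i,r] − y[o,r]`
- undesirable outputs: `R_z[o,f] = z[o,f] − min_i z[i,f]` (treated like an
  input: it improves downward)

These ranges are non-negative whatever the data's signs. The inefficiency
score `θ*` of unit `o` is the optimum of the linear program

```
max θ   s.t.  Σ_i λ_i x[i,j] + θ R_x[o,j] ≤ x[o,j]     (inputs)
              Σ_i λ_i y[i,r] − θ R_y[o,r] ≥ y[o,r]     (desirable outputs)
              Σ_i λ_i z[i,f] + θ R_z[o,f] ≤ z[o,f]     (undesirable outputs)
              Σ_i λ_i = 1,   λ ≥ 0,   0 ≤ θ ≤ 1
```

under variable returns to scale (the convexity constraint `Σλ = 1`).
Efficiency is `1 − θ*`, in `[0, 1]`; frontier units score 1. The score is
translation-invariant in the outputs and unit-invariant in every variable.
A second phase fixes `θ = θ*` and maximizes the sum of range-normalized
residual slacks, naming the variable (dose frequency, HbA1c, weight, ...)
that drives each unit's remaining inefficiency. The package also ranks
units (competition ranking with ties), contrasts mean efficiency across
approval eras, and generates synthetic drug-profile panels — including
planted-inefficiency instances with known ground truth — so the whole
pipeline is testable without any external data.

## Worked example

```r
library(rdmdea)

sch <- rdm_schema(
  c("dose_frequency", "hba1c_reduction", "weight_change"),
  c("input", "desirable_output", "desirable_output"),
  c("per day", "%", "%"))

drugs <- data.frame(
  id              = c("weekly_inj", "daily_pill", "old_tablet", "twice_daily"),
  approval_year   = c(2018, 2009, 1997, 2001),
  dose_frequency  = c(1/7, 1, 1, 2),      # weekly dosing = 1/7 per day
  hba1c_reduction = c(1.3, 0.6, 1.7, 0.45),
  weight_change   = c(5.1, 0.0, 0.0, -2.8))  # loss positive, gain negative

pan <- rdm_panel(drugs, sch)
as.data.frame(evaluate_all(pan))
#>            id theta_star efficiency  status         reference_set
#> 1  weekly_inj  0.0000000  1.0000000 optimal            weekly_inj
#> 2  daily_pill  0.7333333  0.2666667 optimal weekly_inj;old_tablet
#> 3  old_tablet  0.0000000  1.0000000 optimal            old_tablet
#> 4 twice_daily  0.7860514  0.2139486 optimal weekly_inj;old_tablet
```

`weekly_inj` and `old_tablet` span the frontier. `twice_daily` keeps only
21.4% efficiency; it is benchmarked against a linear combination of the
two frontier drugs:

```r
reference_weights(solve_rdm(pan, "twice_daily"), 0.01)
#> weekly_inj old_tablet
#>  0.6685894  0.3314106

compute_slacks(pan, "twice_daily", solve_rdm(pan, "twice_daily"))
#> <rdm_slacks> unit twice_daily
#>         variable          raw   normalized
#>   dose_frequency 1.132669e-01 6.098988e-02
#>  hba1c_reduction 0.000000e+00 0.000000e+00
#>    weight_change 1.769418e-15 2.239770e-16
#> largest normalized slack: dose_frequency
```

Even after the proportional move, `twice_daily` carries a residual dose
frequency slack of 0.113 doses/day — dosing burden, not glycemic effect,
drives its inefficiency. Ranking and era comparison:

```r
rank_units(evaluate_all(pan), pan)[, 1:5]
#>   rank          id approval_year efficiency theta_star
#> 1    1  old_tablet          1997  1.0000000  0.0000000
#> 2    1  weekly_inj          2018  1.0000000  0.0000000
#> 3    3  daily_pill          2009  0.2666667  0.7333333
#> 4    4 twice_daily          2001  0.2139486  0.7860514

era_compare(evaluate_all(pan), pan, 2010)
#> <rdm_era> split at 2010 (post era inclusive)
#>   pre : mean efficiency 0.4935 over 3 unit(s)
#>   post: mean efficiency 1 over 1 unit(s)
```

Synthetic panels with the class-level structure of FDA-labelled T2D drug
classes (9 classes, 38 drugs, weekly-to-thrice-daily dosing, weight-gain
classes, log-normal mortality ORs) come from `generate_panel(seed = ...)`;
`generate_recovery_instance()` builds panels whose inefficiency scores are
known by construction. A command-line front-end is installed at
`system.file("exec", "rdmdea", package = "rdmdea")` with subcommands
`efficiency`, `slacks`, `rank`, `era-compare` and `simulate`.

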