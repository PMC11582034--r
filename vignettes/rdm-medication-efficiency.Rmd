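---
title: "Range directional DEA for medication efficiency: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range directional DEA for medication efficiency: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmdea)
```

## The model

`rdmdea` scores decision-making units — in the motivating application,
type-2 diabetes drugs — by the range directional model (RDM), a
directional-distance DEA formulation that stays well-defined when outputs
take negative values and when some outputs are harms. A unit is described
by strictly positive inputs `x` (dose frequency per day; weekly dosing is
encoded as 1/7 ≈ 0.143), real-valued desirable outputs `y` (HbA1c
reduction in percentage points, coded positive; weight change with loss
positive and gain negative) and real-valued undesirable outputs `z`
(all-cause mortality odds ratio versus placebo, lower better).

For the evaluated unit `o` the model first computes its *ranges of
possible improvement*: per input, distance to the panel minimum; per
desirable output, distance to the panel maximum; per undesirable output,
distance to the panel minimum (an undesirable output improves downward,
so its range takes the input form). Ranges are non-negative by
construction regardless of data signs, and a range is zero exactly when
the unit already attains the panel extreme.

The inefficiency score θ\* is the optimum of a linear program with `n + 1`
decision variables (θ and one intensity weight per unit) that pushes `o`
along its own range direction as far as the variable-returns-to-scale
envelopment of the observed units allows; the convexity constraint
`Σλ = 1` encodes VRS. Efficiency is `1 − θ*`. Two properties make the
score robust for clinical outcome data and are enforced as tested
invariants: adding a constant to any output column leaves all scores
unchanged (translation invariance), and rescaling any variable column by
a positive factor leaves all scores unchanged (unit invariance).

The model is non-oriented: one θ simultaneously contracts inputs, expands
desirable outputs and contracts undesirable outputs. Treating the
undesirable output through its own input-like range is the
"harms-as-inputs" convention; it keeps the LP linear and the frontier
interpretation intact.

### Model configurations

The schema is data-driven, so the two configurations used in drug
benchmarking are just two schemas: a branded-level model (dose frequency
in; HbA1c reduction and weight change out) and a compound-level model
that adds the mortality odds ratio as an undesirable output.
`generate_panel(include_mortality = FALSE)` produces the former.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lp_eps` | 1e-9 | simplex pivot/feasibility tolerance |
| `efficiency_tol` | 1e-7 | θ\* below this is snapped to 0 (unit declared efficient); applied in stored results, not merely at display |
| `reference_tol` | 1e-6 | intensity weights above this enter the reported reference set |
| `zero_range_tol` | 1e-12 | ranges below this are treated as exactly zero |
| `threshold` (in `reference_weights`) | 0.01 | reporting cut for peer weights, renormalized to sum to 1 |
| `threshold_year` (in `era_compare`) | 2010 | era split; the post era includes the threshold year |

Efficiency values are ranked at full precision; the 3-decimal rounding
seen in `ranking.csv` is presentation only.

## Numerical choices

**LP kernel.** The envelopment programs are tiny (one row per variable
plus convexity and the θ ≤ 1 bound; one column per unit) but routinely
degenerate: identical units duplicate rows, zero ranges null out the θ
coefficient, and the phase-II program is equality-constrained. The
package therefore ships a dense two-phase primal simplex with Bland's
anti-cycling rule (`lp_solve`). Bland's rule guarantees termination on
degenerate programs and a deterministic pivot sequence, which the
bitwise-reproducibility contract of `evaluate_all()` requires; artificial
variables left basic at level zero after phase 1 are explicitly driven
out or their redundant rows dropped. At these problem sizes the cubic
cost of tableau pivoting is irrelevant.

**Row scaling.** Each envelopment row is divided by the evaluated unit's
range for that variable (or by the column's largest magnitude when the
range is zero). This makes the tableau literally identical under any
rescaling of a variable column, so unit invariance holds to machine
precision rather than merely to solver tolerance.

**Zero ranges and the ideal point.** A zero-range row keeps its place in
the LP as a pure envelopment constraint (no row dropping). If *every*
range of a unit is zero, the unit is the panel's ideal point, θ's
coefficient vanishes from all envelopment rows, and the LP would be free
to report any θ; the solver returns θ\* = 0 by convention — such a unit
must be efficient — with the unit as its own reference. The explicit
bounds 0 ≤ θ ≤ 1 are imposed as stated by the score's definition.

**Phase-II slacks.** The score alone does not say *which* variable keeps
a unit off the frontier. With θ fixed at θ\*, a second LP maximizes the
sum of slacks normalized by each variable's range. Normalization makes
slacks dimensionless — raw slacks in doses/day are not comparable with
slacks in HbA1c percentage points — so "largest slack" is well-defined
across variables; a zero-range variable has its normalized slack defined
as 0. Both raw and normalized slacks are reported. Because θ\* carries
solver tolerance, phase II retries with θ backed off by up to 1e-7 in the
rare case the fixed-θ program is reported infeasible at θ\* exactly.
Largest-slack ties within 1e-9 go to the variable earliest in schema
order and are logged.

**Alternate optima.** The optimal λ is generally non-unique; the solver
returns one optimal vertex, so a reference set is *an* optimal
decomposition, not the only one. Weights below the reporting threshold
are dropped and the rest renormalized.

**Degenerate-input behavior.** The LP is always feasible (λ_o = 1, θ = 0
satisfies every constraint), so an infeasible status is treated as an
internal error and raised, never returned as a score.

## The grid-search oracle

`brute_force_theta()` is a test oracle kept deliberately free of LP
machinery. For a fixed λ the largest feasible θ has a closed form (the
minimum over positive-range constraints of the scaled residual), so the
oracle searches λ over a regular lattice on the unit simplex. Full
enumeration is used whenever the lattice at the requested resolution is
small; otherwise a coarse full pass is refined with shrinking windows
around the incumbent down to the requested step. The per-λ objective is
concave piecewise-linear in λ, so window refinement with re-centering
retains the global maximum to within the lattice resolution; the
refinement path is cross-checked against exact enumeration in the test
suite. The oracle is a feasible-point search and therefore never exceeds
the LP optimum.

Validation uses 200 random instances with n ≤ 6 units, up to two
variables per role and outputs spanning negative values, at a final grid
step of 1/500; agreement within two grid steps is required on at least
99% of instances.

## The synthetic-data generator

Real per-drug values in this field are hand-extracted from regulatory
labels and meta-analyses, with no machine-readable deposit, so panels for
testing are synthetic. `generate_panel()` emulates the class-level
structure of FDA-approved T2D drug classes: nine classes with their
published dose-frequency supports (including 1/7 for weekly GLP-1
dosing), HbA1c means and standard deviations, and weight-change means and
standard deviations — several classes (Glinides, Thiazolidinediones,
Dopamine-D2 agonists) have negative weight-change means and so produce
weight-gain drugs, the case that motivates the RDM. Distribution shapes
are this package's choice, driven by positivity: HbA1c reduction is a
truncated normal (> 0, by rejection sampling), weight change a plain
normal, the mortality odds ratio log-normal. Class-level mortality
summaries are not published alongside the label data, so the log-OR
parameters (modestly protective means of −0.15 for GLP-1 and SGLT2
classes, near-null elsewhere, sd 0.05–0.08) are plausible values chosen
once, not estimates. Approval years are drawn uniformly over each class's
approval era. Class sizes sum to 38 units, matching the size of a
branded-level benchmark panel.

What the generator does *not* emulate: per-drug identities and their
actual label values, correlations between outcomes within a class,
meta-analytic sampling error, and any dependence of dose frequency on
outcomes. Passing tests on synthetic panels therefore demonstrate the
*solver and pipeline* are correct, not that published per-drug rankings
are reproduced — those depend on hand-curated inputs that only exist in
the original curation.

### Planted-inefficiency instances

`generate_recovery_instance()` provides ground truth the solver must
recover. It builds a frontier of vertices on a strictly concave curve
(`y = 4√x` on x ∈ [1, 4]) — consecutive vertices are mutually
non-dominated and every inter-vertex facet lies on the VRS frontier —
then, for each requested θ, draws a facet-interior anchor `p` and solves
the displacement fixed point per variable: for inputs and undesirables
`v = (p − θ·min)/(1 − θ)`, for desirables `v = (p − θ·max)/(1 − θ)`, so
that the planted unit moved by θ along its own range direction lands
exactly on `p`. Along that direction the gap to the concave envelope is a
concave function of θ that is positive at 0 and zero at the planted θ,
hence strictly negative beyond it: the solved θ\* equals the planted θ
exactly (recovery tolerance 1e-6 in tests). Anchoring at a *vertex*
instead only guarantees θ\* ≥ θ (the direction can continue along the
steeper neighboring facet), which is asserted as such. Planted units are
rejected if they would create a new panel extreme (that would change
every unit's ranges); the generator retries with a fresh anchor up to
100 times before erroring. The two-variable geometry is used because
facet-interior anchoring is constructive there; higher-dimensional solver
behavior is covered by the grid oracle and the invariance properties.

## Design decisions on open points

- **Slack definition.** Published slack analyses in this setting report
  slacks without defining their computation. This package adopts the
  standard two-phase procedure (maximal range-normalized slacks at fixed
  θ\*) and emits both raw and normalized values, so either reading can be
  reconstructed downstream.
- **"No significant change" entries.** Label text reporting no
  significant weight change is ingested as the value 0 (the conventional
  choice); `read_panel()` notes how many zeros it ingested rather than
  silently accepting them.
- **Era comparison.** The post era includes the threshold year
  (default 2010). No significance test is attached to the era difference;
  none is defined for it here.
- **Missing approval years** are allowed in the data, excluded from era
  and timeline analyses with a warning, and never imputed.

## Problem sizes used in validation

The shipped test-and-acceptance workload uses: 200 oracle-comparison
instances (n ≤ 6, final grid step 1/500); 50 panels of 6 units for each
invariance sweep (shifts −10, 3.7, 100; scalings 0.01, 7, 1000); just
over 1000 unit evaluations for boundedness, including identical-unit,
ideal-point and constant-column panels; 100 planted-score recoveries; 100
strict-domination pairs; and two full command-line pipeline runs on the
38-unit synthetic panel compared byte-for-byte. These sizes were chosen
so the whole suite exercises every code path while remaining quick enough
to run on a laptop in a couple of minutes.

## Known limitations

- Reference sets inherit the non-uniqueness of optimal bases; two valid
  solvers may report different (equally optimal) peer decompositions.
- The RDM score is relative to the panel: adding or removing units moves
  ranges and the frontier, and scores are not comparable across panels.
- Efficiency of 1 does not distinguish strongly from weakly efficient
  units; the phase-II slacks do (a weakly efficient unit carries positive
  slacks at θ\* = 0).
- The synthetic generator reproduces class-level marginals, not joint
  structure; it is a validation instrument, not a data substitute.
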