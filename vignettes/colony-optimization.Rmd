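---
title: "Colony-level optimization: model, solver, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony-level optimization: model, solver, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyopt)
```

## The model

`colonyopt` treats a mature, monogynous ant colony as an economic
optimizer. The colony has `n` ants, a set of tasks, and one or more
castes. Each ant performs at most one task at a time, so the task
fractions satisfy `sum(eps) <= 1`. Model assumptions, in the package's
terms:

* colonies are founded by a single queen and reach a stable size
  (time-independent `n`);
* task performance ability is a property of caste (morphology,
  physiology, behaviour), summarised by per-task work rates `omega`;
* the offspring types a queen produces, and their fractions, are
  heritable and mutable — so selection acts at the colony level, through
  the number of daughter colonies;
* subsistence energy is linear in `n` at fixed caste proportions;
* colony fitness is strictly increasing in per-capita net productivity
  `p = P/n`;
* task utilities show diminishing marginal returns past a threshold, and
  the marginal utility of the work component vanishes as performers
  saturate the task (resources around a colony are finite).

Two accountings coexist deliberately:

1. **The ledger** (`colony_ledger()`) is definitional bookkeeping over
   configured rates: per-ant usefulness `u = k_tau * omega`, task energy
   `e`, competence `u - e`, and the exact identity
   `G = sum_j U_j = sum_i c_i`. It is linear in performer counts and is
   the accounting in which per-capita quantities (and the biomass proxy)
   live.
2. **The utility families** (`evaluate_utility()`) are the behavioural
   model: concave functions of the performer count that encode crowding
   of finite resources. The equilibrium division of labor, perturbation
   analysis and the grid oracle operate on these.

## Utility families

With `x = n * eps` performers, the default family is

    U = k_tau * R * (1 - exp(-a * x)) - c * x

* `k_tau` (dimensionless, in (0, 1]) — task importance;
* `R` (energy units) — work capacity: the asymptote of the work term;
* `a` (per worker) — saturation rate; `a * n` controls how quickly the
  colony exhausts the task;
* `c` (energy units per performer per step) — task energy rate.

This is the simplest strictly concave family with closed-form value,
derivative, and derivative inverse (the solver exploits the last). Its
work component satisfies the vanishing-marginal limit exactly; the total
marginal tends to `-c * n` at saturation because the linear energy cost
keeps accruing. Whether task *energy* should also saturate is not
determined by the model's assumptions, so both readings ship:
`"saturating_satcost"` saturates the cost at the same rate (total
marginal tends to 0), and users choose per task. A `"logistic"` family
with an explicit concavity threshold `threshold_n0` is provided for
accelerating-then-saturating returns; the solver refuses it whenever
`threshold_n0 > 0` because a non-concave objective voids the
equal-marginal certificate. A `"linear"` family supports degenerate
checks and the per-capita accounting.

## The equilibrium solver

`solve_equilibrium()` maximises `P = sum_j U_j(n, eps_j) - E` over
`eps_j >= 0`, `sum(eps) <= 1`. For concave separable objectives the
optimum is a water-filling problem: every active task shares a common
marginal utility `lambda`, tasks whose opening marginal
`mu_j(0) <= lambda` are dropped, and either the constraint binds
(`lambda > 0`) or all active marginals are zero with idle slack. The
solver bisects on `lambda` (200 iterations, machine-precision interval),
using the analytic inverse of `mu` where available and `uniroot`
otherwise. This is exact at corner solutions — the case a pure
equal-marginal root-finder would mishandle — and the returned KKT
certificate (`kkt_ok`) re-verifies the equal-marginal condition and the
no-profitable-activation condition at `1e-6` relative tolerance.
Fractions below `1e-9` count as inactive.

`grid_oracle()` is an independent check: exhaustive search on a 0.01
grid over the constraint simplex, then zoom refinement (x10 per level)
down to a `1e-5` step. Zooming is valid because the objective is
concave, and the final step is chosen so the oracle brackets the optimum
to well under `1e-6` relative in `P` — a coarse 0.001 grid alone only
localises `P` to about `1e-3` under typical fixture curvatures.
Caste capability restricts *which* tasks enter the optimization (a task
no present caste can perform gets `eps = 0`); within the performable
set, caste identity does not cap task totals — the constraint is
colony-level. A deterministic specialists-first assignment provides
per-caste bookkeeping for the ledger and knockout reports and is flagged
if infeasible.

## Worker loss and redistribution

`redistribute_after_loss()` kills a fraction `delta_eps` of one task's
workers. `delta_eps` is the fraction *of that task's performers* (so
`0.2` always means "20% of them die", whatever the task's share of the
colony). The dead are removed from `n` and from their castes'
subsistence — workers are gone, not idle. Because marginal utility
depends on the performer count `x` (the `n` prefactor of `mu` cancels in
ratios), depleting a task strictly raises its MRS against every other
task at a binding equilibrium of strictly concave families; re-solving
on the survivors then satisfies
`P_original >= P_redistributed >= P_unredistributed`, strictly for
`delta_eps > 0`. The first inequality additionally requires workers to
be net contributors (`E_basal` below the marginal per-worker work value
`lambda*/n`); the fixture generator guarantees this by calibration (see
below). If subsistence exceeded the marginal work value, losing workers
could *raise* net productivity, and the buffering claim would not apply.

## Group selection and novel-caste invasion

`simulate_invasion()` runs lineages of colonies through non-overlapping
generations. Each colony holds a mutant trait position `x` and a mutant
offspring fraction `f`; its fitness is `w(p)` with
`p = (m * p_m + (n - m) * p_0) / n`, `m = round(f * n)`, and `p_m` read
off a trait landscape (sigmoid by default: deleterious below a
threshold in mutation-space, beneficial past it). Per generation a
colony leaves `Poisson(w)` daughters (`round(w)` in deterministic mode)
and dies; daughters perturb `x` by a Gaussian step (`mutation_sigma`)
and `f` by a *multiplicative* log-normal kernel (`fraction_sigma`). The
multiplicative kernel was chosen because an additive kernel clipped at
zero loses the trait by drift more readily at small initial fractions,
confounding the very monotonicity (fixation probability non-increasing
in the initial mutant fraction) the model predicts through fitness
alone.

Default study conditions: `n = 100`, `p_0 = 1`, sigmoid landscape
`p_lo = 0.2`, `p_hi = 1.6`, slope 2, threshold `x0 = 1`, start at
`x = 0` (so `p_m ≈ 0.37`, clearly deleterious), `mutation_sigma = 0.25`,
`fraction_sigma = 0.05`, linear fitness `w = max(0, 1 + (p - p_0))` — a
pure-resident colony sits exactly at replacement (`w0 = 1`), so
carrying deleterious mutants makes a lineage subcritical and the
novel caste can fix only by random-walking into the beneficial region
before the lineage dies. Horizon 150 generations; population ceiling
10,000 colonies with uniform seeded thinning.

Classification per lineage: extinction before the trait is ever
beneficial (`p_m < p_0` throughout) is **case 1**; any extinction after
the trait first reaches `p_m >= p_0` is **case 2** (including the rare
lineage that recovers above `w = 1` transiently and then dies — the
asymptotic "does not rise back quickly enough" condition is not
computable per lineage, so extinction timing is the operational
criterion). A lineage is **fixed** once the trait is beneficial, mean
fitness is at least 1, and at least 50 colonies persist (the extinction
probability of such a supercritical population is negligible, and
stopping there keeps fixed lineages from saturating the ceiling), or at
the horizon with mutants present and `w >= 1`. Anything else —
including the rare loss of the trait by fraction drift while the
lineage survives — is **censored**, never silently dropped.

Reproducibility: replicate `r` reseeds the global RNG at
`seed + r - 1`, so estimates are invariant to adding replicates and
identical seeds give bit-identical trajectories. The four-level
fixation-probability comparison deliberately reuses one base seed per
level (common random numbers), which sharpens the monotonicity
comparison without biasing any single estimate.

`phase_analysis()` measures `theta_minus` (first generation with
`p_m >= p_0`), `theta_plus` (generations from the fitness minimum back
to `w = 1`), and `delta_w`, the integral of `phi = dw/dt` over
`[0, theta]`. `phi` is computed as per-generation forward differences,
so the trapezoidal integral of the piecewise-linear fitness path
telescopes to `w(theta) - w(0)` exactly — the integral-consistency check
holds to rounding error by construction, which is the point: the
discrete simulation is internally consistent with the continuous-time
identity it discretises.

`mstar_hillclimb()` implements the prediction that mutant numbers grow
only until `p_m = p_0`. It is a growth dynamic, not an argmax: `m`
increases (with step halving) while mutants remain at least as
productive as residents. With `p_m(m)` depending on `m`, maximising `P`
over `m` would instead stop where `p_m + m * p_m' = p_0`; the model's
stopping condition is the marginal-recruit rule, so that is what is
implemented, against concave diminishing landscapes
`p_m(m) = b0 - b1 * (m/n)^gamma`.

## Biomass proxies and knockouts

For a monomorphic colony, equal marginal utilities across active tasks
translate, in the per-capita (ledger) accounting where
`U_j = n * eps_j * Ubar_j`, into equality of the per-capita utilities
`Ubar_j` — and hence proportionality of task utility to performer
biomass. For *strictly concave* families this *per-capita* equality
does not follow from equal marginals (average and marginal utility
differ), so `biomass_proxy()` works in the ledger accounting: it
verifies equal per-ant net task rates `k_tau * omega - c` (the
per-capita signature of the equilibrium) and then reports shares, which
are exact up to integer rounding of performer counts. Monomorphic
fixtures draw `omega_j = (g + c_j) / k_tau_j` for a common `g`,
i.e. their worker caste is already tuned to this equilibrium — the
premise that an evolved caste's realised work rates equalise per-capita
net contributions. Idle ants keep their biomass in the denominator, so
the share identity is exact when the allocation constraint binds (as it
does in the shipped fixtures).

`knockout_experiment()` removes a caste, re-solves, and reports
redistribution: some remaining caste strictly increasing its allocation
to an orphaned task. "Capable" means a positive work rate for the task;
absence of redistribution is falsifying evidence only when capable
castes remain. A full-caste knockout and a total worker loss on that
caste's tasks (via `redistribute_after_loss()` with `delta_eps = 1`)
produce identical reduced colonies — a cross-module consistency check
in the test suite.

## Fixture generation and calibration

`generate_fixture()` draws scenarios that satisfy the model's structural
assumptions by construction, with ranges chosen once as biologically
reasonable study conditions:

* `n` in 50–200 ants; `k_tau` in (0.3, 1]; `R` in (5, 20) energy units;
* `a * n` in (1.5, 6), so each task's zero-marginal point exceeds about
  `eps = 0.65` and the one-task-per-ant constraint binds for 2–4 tasks
  (an unbound equilibrium has zero marginal utilities and the MRS
  becomes 0/0 — the equal-marginal condition is only informative when
  labor is scarce);
* `c` at 0.2–2% of the initial marginal work rate `k_tau * R * a`;
* `E_basal` at 5–40% of the equilibrium marginal per-worker value
  `lambda*/n`, making workers strictly net-positive (a maturity
  condition required by the redistribution ordering, see above).

What the synthetic scenarios do **not** emulate: task interdependence
(utilities are separable), environmental fluctuation (parameters are
static), individual heterogeneity within a caste, age polyethism, and
any proximate mechanism of caste determination. Tests passing on these
fixtures show the analytic claims hold *in-model* under the stated
conditions; they are not evidence about real colonies.

## Problem sizes and numerical choices

The shipped test suite solves ~300 equilibria, cross-checks 20
scenarios against the grid oracle (2–3 tasks; the oracle is cubic in
grid resolution, so 4-task scenarios are certified by the KKT
conditions instead), evaluates 150 perturbations, and simulates 8,000
lineages for the fixation-monotonicity comparison (2,000 per initial
fraction at levels 0.01/0.05/0.2/0.5, the smallest design that
separates the levels' binomial intervals cleanly); the whole suite runs
in well under a minute on one core. Tolerances: solver KKT `1e-6`
relative; active-set threshold `1e-9`; MRS equality asserted at `1e-4`;
oracle agreement `1e-6` relative; phase-integral consistency `1e-8`.
Ties between identical tasks are resolved by the shared `lambda`
(symmetric allocations emerge from the analytic inverse, not a
tie-break rule); degenerate inputs — empty colonies, zero-performer
tasks, saturated denominators in MRS, empty trajectories — are
signalled explicitly rather than returning quiet zeros.

## Known limitations

* The equilibrium is colony-level; individual task-switching schedules
  are unmodelled (only the aggregate fractions matter).
* Polygynous colonies, haplodiploid genetics, and explicit dispersal
  are outside scope; daughter colonies found independently.
* The mutation-space is a scalar with Gaussian steps; real
  developmental trait spaces are higher-dimensional and the landscape
  families (sigmoid, piecewise-linear) name no mechanism.
* `k_tau` has no estimation procedure — it is a free configuration
  parameter, as is the functional form of task energy.
* Case-2 extinction is an operational per-lineage criterion, not the
  asymptotic condition on lineage growth rates.
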