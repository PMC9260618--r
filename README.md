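# colonyopt

Colony-level optimization of division of labor in eusocial insect
colonies — and the group-selection dynamics that let novel castes evolve
even though their first bearers are nearly useless.

## The problem

Most ants never reproduce, so a new worker caste cannot be selected for
at the individual level: its first, erratically produced members
("intercastes") are typically *less* functional than any existing
worker. `colonyopt` implements an economics-based model of the monogynous
colony as the unit of selection. Each task `τ_j` yields a concave utility
`U_j(n, ε_j)` (law of diminishing marginal utility: crowding a task's
finite resource with performers yields less and less), and the colony's
net productivity is

    P = Σ_j U_j(n, ε_j) − E ,     E = Σ_i E_i  (subsistence),

where `ε_j` is the fraction of the `n` ants performing task `j` and an
ant performs at most one task at a time (`Σ ε_j ≤ 1`). Per-capita net
productivity `p = P/n` is the maximand of colony-level selection: colony
fitness `w(p)` (daughter colonies per generation) is strictly increasing
in `p`.

The package provides, as testable code:

* **Productivity ledger** — usefulness `u_ij = k_τj ω_ij`, task energy
  `e_ij`, competence `c_i = Σ_j (u_ij − e_ij)`, task utility
  `U_j = Σ_i (u_ij − e_ij)`, and the exact double-accounting identity
  `G = Σ_j U_j = Σ_i c_i`, with `P = G − E` and `p = P/n`
  (`colony_ledger()`).
* **Equilibrium division of labor** — the allocation `ε*` maximising `P`
  is characterised by equal marginal utilities
  `μ_1 = μ_2 = … = μ_η` on active tasks, i.e. a marginal rate of
  substitution `M_ij = μ_i/μ_j = 1` for every active pair, under
  `Σ ε_j ≤ 1`. Solved exactly by water-filling with a KKT certificate
  and an exhaustive grid-search oracle (`solve_equilibrium()`, `mrs()`,
  `grid_oracle()`).
* **Worker-loss redistribution** — after a fraction of one task's
  workers die, that task's MRS against every other task exceeds 1, so
  re-allocating workers into it buffers (but never fully repays) the
  loss: `P_original ≥ P_redistributed ≥ P_unredistributed`
  (`redistribute_after_loss()`).
* **Novel-caste invasion** — a queen lineage producing a fraction of
  mutant ants whose trait performs a Gaussian random walk in
  mutation-space. With `P = m·p_m + (n − m)·p_0`, `dP/dm = p_m − p_0`:
  while deleterious the trait should be rare, once beneficial it should
  spread, and mutant numbers grow only until `p_m = p_0`. Lineages are
  simulated as branching processes of colonies and classified into
  fixation, extinction while still deleterious (case 1), or extinction
  before fitness recovers (case 2); waiting times `θ⁻`, `θ⁺` and the
  fitness integral `Δw = ∫φ dt` are extracted per trajectory
  (`simulate_invasion()`, `phase_analysis()`, `mstar_hillclimb()`).
* **Field proxies** — for monomorphic colonies at equilibrium, biomass
  shares equal utility shares, so colony biomass proxies gross
  productivity (`biomass_proxy()`); in-silico caste-knockout experiments
  test the model's falsifiable prediction of task redistribution
  (`knockout_experiment()`).

## Worked example

```r
library(colonyopt)

scn <- generate_fixture("monomorphic-3task", seed = 7, n = 100)
sol <- solve_equilibrium(scn$tasks, scn$castes, scn$colony$n)
sol
#> <allocation_result> n=100  P*=10.7951  lambda=7.91347  constraint binding
#>    task1    task2    task3
#> 0.501260 0.348124 0.150616
```

At the equilibrium roughly half the colony forages the richest task; the
common marginal utility `λ = 7.91` certifies that no ant could be moved
between tasks to raise net productivity (`P* = 10.80` energy units per
step), and every active-pair MRS equals 1.

```r
st <- equilibrium_state(scn$tasks, scn$castes, 100)
redistribute_after_loss(scn$tasks, scn$castes, st, "task1", 0.2)
#> <perturbation_report> task 'task1', 20% of its workers lost
#>   P original        10.7951
#>   P redistributed   10.223
#>   P unredistributed 10.1691
#>   MRS of depleted task vs others (before re-solving):
#>    task2    task3
#> 1.226581 1.226581
```

Killing 20% of task-1's workers raises its MRS to 1.23 against both
other tasks — the colony's cue to redistribute — and re-solving recovers
part, but not all, of the lost productivity.

```r
cfg <- evolution_config(replicates = 500, seed = 42, init_fraction = 0.01)
simulate_invasion(cfg, keep_trajectories = FALSE)
#> <invasion_summary> 500 lineages, seed 42, mode stochastic
#>
#>         fixed extinct_case1 extinct_case2      censored
#>             3           475            20             2
#>   fixation probability 0.0060 (95% CI 0.0012-0.0174)
```

A trait starting deleterious (`p_m ≈ 0.37` vs `p_0 = 1`) and expressed
in 1% of offspring occasionally random-walks into the beneficial region
before its lineage dies: 3 of 500 lineages fix the novel caste.

A command-line interface wraps the same functions
(`Rscript inst/cli/colonyopt.R allocate --config scenario.yaml --out dir`;
subcommands `allocate`, `perturb`, `evolve`, `proxy`, `knockout`,
`fixtures`), reading YAML scenarios and writing TSV reports with
provenance headers. See `vignettes/colony-optimization.Rmd` for the full
model description and design choices.

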