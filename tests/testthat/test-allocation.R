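# MRS, equilibrium solver, grid oracle, KKT certificates

test_that("MRS is 1 for identical tasks and matches analytic derivative ratios", {
  tasks <- twin_tasks()
  castes <- list(caste_spec("w", omega = c(left = 1, right = 1)))
  st <- colony_state(tasks, castes, n = 20, eps = c(left = 0.3, right = 0.3))
  expect_identical(mrs(tasks[[1]], tasks[[1]], st), 1)
  expect_equal(mrs(tasks[[1]], tasks[[2]], st), 1, tolerance = 1e-12)
  # heterogeneous pair at eps = (0.3, 0.2): ratio of closed-form derivatives
  ta <- task_spec("a", k_tau = 1, R = 10, a = 0.1, c = 0.02)
  tb <- task_spec("b", k_tau = 0.5, R = 15, a = 0.05, c = 0.01)
  st2 <- colony_state(list(ta, tb),
                      list(caste_spec("w", omega = c(a = 1, b = 1))),
                      n = 100, eps = c(a = 0.3, b = 0.2))
  want <- (1 * 10 * 0.1 * exp(-0.1 * 100 * 0.3) - 0.02) /
    (0.5 * 15 * 0.05 * exp(-0.05 * 100 * 0.2) - 0.01)
  expect_equal(mrs(ta, tb, st2), want, tolerance = 1e-12)
  # saturated denominator task -> undefined ratio is signalled
  tsat <- task_spec("sat", k_tau = 1, family = "saturating_satcost",
                    R = 10, a = 2, c = 0.1)
  st3 <- colony_state(list(ta, tsat),
                      list(caste_spec("w", omega = c(a = 1, sat = 1))),
                      n = 500, eps = c(a = 0.1, sat = 0.9))
  expect_error(mrs(ta, tsat, st3), "saturated denominator")
})

test_that("two identical tasks split the colony evenly at equilibrium", {
  tasks <- twin_tasks(k = 1, R = 10, a = 0.05, c = 0.01)
  sol <- solve_equilibrium(tasks, n = 20)
  # marginal utility at 0.5 is positive, so the constraint binds;
  # symmetry then forces the even split
  expect_true(sol$binding)
  expect_equal(unname(sol$eps_star), c(0.5, 0.5), tolerance = 1e-9)
  expect_gt(sol$lambda_common, 0)
})

test_that("a single still-profitable task takes the whole colony", {
  tsk <- task_spec("only", k_tau = 1, R = 50, a = 0.01, c = 0.001)
  expect_gt(marginal_utility(tsk, 30, 1)$mu, 0)
  sol <- solve_equilibrium(list(tsk), n = 30)
  expect_equal(unname(sol$eps_star), 1, tolerance = 1e-12)
})

test_that("idle slack appears when all marginals hit zero before the constraint", {
  # strong saturation: both tasks worthless past a small workforce
  tasks <- list(task_spec("x", k_tau = 1, R = 2, a = 0.5, c = 0.05),
                task_spec("y", k_tau = 1, R = 2, a = 0.5, c = 0.05))
  sol <- solve_equilibrium(tasks, n = 200)
  expect_false(sol$binding)
  expect_lt(sum(sol$eps_star), 1)
  expect_true(all(abs(sol$mu[sol$active_set]) < 1e-6))
})

test_that("solver matches the exhaustive grid oracle on random 3-task scenarios", {
  for (seed in 1:6) {
    scn <- generate_fixture("monomorphic-3task", seed = seed)
    sol <- solve_equilibrium(scn$tasks, scn$castes, scn$colony$n,
                             oracle_gap = TRUE)
    expect_gte(sol$P_star, grid_oracle(scn$tasks, scn$colony$n,
                                       castes = scn$castes,
                                       step = 0.01, final_step = 0.01)$P_best -
                 1e-6)
    expect_lt(abs(sol$oracle_gap), 1e-6 * max(1, abs(sol$P_star)))
  }
})

test_that("KKT certificate holds at every reported solution", {
  for (seed in 11:30) {
    kind <- sprintf("monomorphic-%dtask", 2L + seed %% 3L)
    scn <- generate_fixture(kind, seed = seed)
    sol <- solve_equilibrium(scn$tasks, scn$castes, scn$colony$n)
    expect_true(sol$converged)
    expect_true(sol$kkt_ok)
    act <- sol$active_set
    expect_true(all(abs(sol$mu[act] - sol$lambda_common) <=
                      1e-6 * max(1, sol$lambda_common)))
    inact <- setdiff(names(sol$eps_star), act)
    for (tid in intersect(inact, sol$performable)) {
      tk <- scn$tasks[[which(vapply(scn$tasks, `[[`, "", "id") == tid)]]
      expect_lte(marginal_utility(tk, scn$colony$n, 0)$mu,
                 sol$lambda_common + 1e-6 * max(1, sol$lambda_common))
    }
  }
})

test_that("a task whose opening marginal is below lambda is dropped", {
  tasks <- list(task_spec("rich", k_tau = 1, R = 20, a = 0.05, c = 0.001),
                task_spec("poor", k_tau = 0.3, R = 0.5, a = 0.05, c = 0.001))
  sol <- solve_equilibrium(tasks, n = 40)
  expect_true(sol$binding)
  expect_identical(sol$active_set, "rich")
  expect_identical(unname(sol$eps_star["poor"]), 0)
})

test_that("non-concave families are refused with a diagnostic", {
  bad <- task_spec("ramp", k_tau = 1, family = "logistic", R = 10, a = 0.2,
                   c = 0, threshold_n0 = 30)
  expect_error(solve_equilibrium(list(bad), n = 100), "non-concave")
  ok <- task_spec("ramp0", k_tau = 1, family = "logistic", R = 10, a = 0.2,
                  c = 0.01, threshold_n0 = 0)
  expect_s3_class(solve_equilibrium(list(ok), n = 100), "allocation_result")
})

test_that("capability restricts allocation to performable tasks", {
  tasks <- twin_tasks()
  castes <- list(caste_spec("lefty", omega = c(left = 1)))
  sol <- solve_equilibrium(tasks, castes, n = 30)
  expect_identical(sol$performable, "left")
  expect_identical(unname(sol$eps_star["right"]), 0)
})
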