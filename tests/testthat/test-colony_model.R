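# utility families, marginal utilities, ledger, reproductive usefulness

test_that("utility families evaluate to their closed forms and vanish at eps = 0", {
  tsk <- default_task()
  # independent closed-form evaluation: k R (1 - e^{-a n eps}) - c n eps
  expect_equal(evaluate_utility(tsk, n = 100, eps = 0.5),
               10 * (1 - exp(-5)) - 1, tolerance = 1e-12)
  for (fam in c("saturating", "saturating_satcost", "logistic", "linear")) {
    t2 <- task_spec("x", k_tau = 0.7, family = fam, R = 8, a = 0.04, c = 0.01)
    expect_identical(evaluate_utility(t2, n = 120, eps = 0), 0)
  }
  expect_error(evaluate_utility(tsk, n = 100, eps = 1.2), "\\[0, 1\\]")
  expect_error(evaluate_utility(tsk, n = -5, eps = 0.2), "non-negative")
  expect_error(task_spec("bad", k_tau = 1, family = "nope"), "unknown family")
})

test_that("every shipped concave family is concave in eps by finite differences", {
  set.seed(42)
  h <- 1e-4
  for (rep in 1:20) {
    tsk <- random_task()
    n <- sample(50:200, 1)
    eps <- sort(runif(20, h, 1 - h))
    d2 <- (evaluate_utility(tsk, n, eps + h) - 2 * evaluate_utility(tsk, n, eps) +
             evaluate_utility(tsk, n, eps - h)) / h^2
    expect_true(all(d2 < 0))
    # central differences of U are strictly decreasing in eps
    slope <- (evaluate_utility(tsk, n, eps + h) -
                evaluate_utility(tsk, n, eps - h)) / (2 * h)
    expect_true(all(diff(slope) < 0))
  }
})

test_that("fractional marginal utility converges to the analytic derivative", {
  set.seed(7)
  for (rep in 1:20) {
    tsk <- random_task()
    n <- sample(50:200, 1)
    eps <- runif(1, 0, 0.9)
    mm <- marginal_utility(tsk, n, eps, delta_eps = 1e-6)
    expect_lt(abs(mm$nu - mm$mu), 1e-4 * abs(mm$mu))
  }
  # linear family: nu = mu = slope for all eps
  lin <- task_spec("lin", k_tau = 0.5, family = "linear", R = 6, a = 1, c = 0.1)
  s <- 40 * (0.5 * 6 - 0.1)
  for (eps in c(0, 0.3, 0.9)) {
    mm <- marginal_utility(lin, 40, eps, delta_eps = 0.05)
    expect_equal(mm$nu, s, tolerance = 1e-10)
    expect_equal(mm$mu, s, tolerance = 1e-12)
  }
  expect_error(marginal_utility(lin, 40, 0.2, delta_eps = -0.1), "positive")
  expect_error(marginal_utility(lin, 40, 0.9, delta_eps = 0.2), "exceed 1")
})

test_that("at saturation the default family's marginal tends to -c*n", {
  tsk <- task_spec("sat", k_tau = 1, R = 10, a = 1, c = 0.02)
  mu1 <- marginal_utility(tsk, n = 100, eps = 1)$mu
  expect_equal(mu1, -0.02 * 100, tolerance = 1e-8)
  # the saturating-cost variant instead has mu -> 0 as performers saturate
  tsk2 <- task_spec("sat2", k_tau = 1, family = "saturating_satcost",
                    R = 10, a = 1, c = 0.02)
  expect_lt(abs(marginal_utility(tsk2, n = 100, eps = 1)$mu), 1e-8)
})

test_that("the ledger reproduces the hand-summed 4-ant colony exactly", {
  hc <- hand_colony()
  led <- colony_ledger(hc$tasks, hc$castes, hc$state)
  expect_equal(unname(led$U), c(1.9, 5.6), tolerance = 1e-14)
  expect_equal(led$G, 7.5, tolerance = 1e-14)
  expect_identical(led$E, 6)
  expect_equal(led$P, 1.5, tolerance = 1e-14)
  expect_equal(led$p, 0.375, tolerance = 1e-14)
  # double accounting: sum over ants of competence equals sum of task utilities
  expect_identical(sum(led$assign * led$competence), sum(led$U))
})

test_that("empty and subsistence-only colonies are handled explicitly", {
  tasks <- list(default_task())
  castes <- list(caste_spec("w", E_basal = 2, omega = c(forage = 1)))
  st0 <- colony_state(tasks, castes, n = 0)
  led0 <- colony_ledger(tasks, castes, st0)
  expect_identical(c(led0$G, led0$E, led0$P), c(0, 0, 0))
  expect_true(is.na(led0$p))
  expect_false(led0$p_defined)
  st1 <- colony_state(tasks, castes, n = 1)  # one ant, no task
  led1 <- colony_ledger(tasks, castes, st1)
  expect_identical(led1$G, 0)
  expect_identical(led1$P, -2)
})

test_that("ledger is invariant under permutations of ant (caste/task) ordering", {
  hc <- hand_colony()
  led <- colony_ledger(hc$tasks, hc$castes, hc$state)
  st_rev <- colony_state(rev(hc$tasks), rev(hc$castes), n = 4,
                         counts = c(B = 2, A = 2),
                         eps = c(t2 = 0.5, t1 = 0.25))
  led_rev <- colony_ledger(rev(hc$tasks), rev(hc$castes), st_rev)
  expect_identical(led_rev$G, led$G)
  expect_identical(led_rev$E, led$E)
  expect_identical(led_rev$U[names(led$U)], led$U)
})

test_that("subsistence is exactly linear in n at fixed eps and caste proportions", {
  hc <- hand_colony()
  led1 <- colony_ledger(hc$tasks, hc$castes, hc$state)
  st2 <- colony_state(hc$tasks, hc$castes, n = 8,
                      counts = c(A = 4, B = 4),
                      eps = c(t1 = 0.25, t2 = 0.5))
  led2 <- colony_ledger(hc$tasks, hc$castes, st2)
  expect_identical(led2$E, 2 * led1$E)
})

test_that("reproductive usefulness is the offspring ratio with guarded edges", {
  expect_identical(reproductive_usefulness(0, 50), 0)
  expect_identical(reproductive_usefulness(50, 50), 1)  # the foundress herself
  expect_identical(reproductive_usefulness(10, 40), 0.25)
  expect_error(reproductive_usefulness(10, 0), "undefined")
  expect_error(reproductive_usefulness(-1, 10), "non-negative")
})

test_that("colony_state enforces the one-task-per-ant constraint and count closure", {
  tasks <- twin_tasks()
  castes <- list(caste_spec("w", omega = c(left = 1, right = 1)))
  expect_error(colony_state(tasks, castes, n = 10,
                            eps = c(left = 0.7, right = 0.6)),
               "at most one task")
  expect_error(colony_state(tasks, castes, n = 10,
                            counts = c(w = 9)), "sum to n")
  st <- colony_state(tasks, castes, n = 11, eps = c(left = 0.5, right = 0.5))
  # largest-remainder rounding keeps the performer total consistent
  expect_identical(sum(st$task_counts), 11L)
})
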