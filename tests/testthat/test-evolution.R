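# productivity split, fitness maps, lineage stepping, invasion, phases

test_that("productivity split matches hand substitution and its m-derivative", {
  s0 <- productivity_split(m = 0, n = 100, p_m = 0.5, p_0 = 2)
  expect_identical(s0$P, 200)
  expect_identical(s0$dP_dm, 0.5 - 2)
  expect_identical(productivity_split(10, 100, 0.5, 2)$P, 185)
  expect_identical(productivity_split(10, 100, 0.5, 2)$dP_dm, -1.5)
  expect_identical(productivity_split(5, 10, 2, 2)$dP_dm, 0)  # neutral mutant
  expect_error(productivity_split(11, 10, 1, 1), "\\[0, n\\]")
})

test_that("the time derivative of P follows the two-term split rule", {
  expect_identical(productivity_rate(5, 0, 1, 0, 3), 0)
  expect_identical(productivity_rate(5, 2, 1, 0.1, 3), 0.5 + 2 * (1 - 3))
  # while the trait is deleterious, recruiting mutants lowers P
  expect_lt(productivity_rate(5, 2, 1, 0, 3), 0)
})

test_that("phase-1/phase-2 monotonicity of P in m follows from the accounting", {
  m <- 0:50
  P_del <- productivity_split(m, 100, p_m = 0.4, p_0 = 1)$P
  expect_true(all(diff(P_del) < 0))   # deleterious trait: P strictly decreasing
  P_ben <- productivity_split(m, 100, p_m = 1.7, p_0 = 1)$P
  expect_true(all(diff(P_ben) > 0))   # beneficial trait: strictly increasing
})

test_that("fitness maps are increasing in p and clamped at zero", {
  fm <- fitness_map("linear", w0 = 1.2, beta = 0.5, p_ref = 0)
  expect_identical(fitness_from_productivity(0, fm), 1.2)
  expect_identical(fitness_from_productivity(-3, fm), 0)  # 1.2 - 1.5 clamped
  p <- seq(-1, 3, by = 0.25)
  w <- fitness_from_productivity(p, fm)
  expect_true(all(diff(w[w > 0]) > 0))
  fe <- fitness_map("exponential", w0 = 1, beta = 0.3, p_ref = 1)
  expect_identical(fitness_from_productivity(1, fe), 1)
  expect_true(all(diff(fitness_from_productivity(p, fe)) > 0))
  expect_error(fitness_map("linear", beta = 0), "strictly increasing")
})

test_that("lineage stepping: extinction, faithful inheritance, deterministic broods", {
  cfg0 <- evolution_config(mutation_sigma = 0, fraction_sigma = 0,
                           fitness = fitness_map("linear", w0 = 1, beta = 1,
                                                 p_ref = 10),
                           seed = 1)
  # w = 0 for every colony -> next generation empty
  dead <- step_lineage(data.frame(trait_x = 0, frac = 0.5), cfg0)
  expect_identical(nrow(dead), 0L)
  # sigma = 0 and kernel off -> trait and fraction inherited unchanged
  cfg1 <- evolution_config(mutation_sigma = 0, fraction_sigma = 0,
                           mode = "deterministic",
                           landscape = pm_landscape("constant", value = 1))
  set.seed(1)
  nxt <- step_lineage(data.frame(trait_x = 0.3, frac = 0.2), cfg1)
  expect_identical(unique(nxt$trait_x), 0.3)
  expect_identical(unique(nxt$frac), 0.2)
  # deterministic mode: fitness exactly 2 -> exactly 2 daughters
  cfg2 <- evolution_config(mutation_sigma = 0, fraction_sigma = 0,
                           mode = "deterministic",
                           fitness = fitness_map("linear", w0 = 2, beta = 1,
                                                 p_ref = 1),
                           landscape = pm_landscape("constant", value = 1))
  two <- step_lineage(data.frame(trait_x = 0, frac = 0.1), cfg2)
  expect_identical(nrow(two), 2L)
})

test_that("a never-deleterious trait fixes immediately with theta_minus = 0", {
  cfg <- evolution_config(landscape = pm_landscape("constant", value = 1.5),
                          mode = "deterministic", mutation_sigma = 0,
                          fraction_sigma = 0, init_fraction = 0.05,
                          replicates = 1, seed = 4, horizon = 40)
  sim <- simulate_invasion(cfg)
  expect_identical(sim$replicates[[1]]$outcome, "fixed")
  expect_identical(sim$replicates[[1]]$theta_minus, 0L)
})

test_that("an immediately lethal landscape gives case-1 extinction", {
  cfg <- evolution_config(landscape = pm_landscape("constant", value = -30),
                          init_fraction = 1, replicates = 3, seed = 9)
  sim <- simulate_invasion(cfg)
  for (r in sim$replicates) expect_identical(r$outcome, "extinct_case1")
})

test_that("seeded re-runs reproduce the fixation estimate and trajectories exactly", {
  cfg <- evolution_config(replicates = 60, seed = 123, init_fraction = 0.1)
  s1 <- simulate_invasion(cfg)
  s2 <- simulate_invasion(cfg)
  expect_identical(s1$fixation_prob, s2$fixation_prob)
  expect_identical(s1$outcome_counts, s2$outcome_counts)
  expect_identical(s1$replicates[[17]]$trajectory,
                   s2$replicates[[17]]$trajectory)
})

test_that("phase analysis returns flat, recovering, and censored shapes correctly", {
  flat <- data.frame(w = rep(1.3, 10), pm = rep(2, 10), p0 = 1)
  ph <- phase_analysis(flat)
  expect_identical(ph$delta_w, 0)
  expect_identical(ph$theta_plus, 0L)
  expect_identical(ph$theta_minus, 0L)
  # monotone dip and recovery: integral telescopes to the endpoint change
  w <- c(1.5, 1.2, 0.8, 0.5, 0.7, 1.0, 1.4)
  pm <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4)
  tr <- data.frame(w = w, pm = pm, p0 = 1)
  ph2 <- phase_analysis(tr)
  expect_identical(ph2$theta_minus, 4L)   # first index with pm >= p0
  expect_identical(ph2$theta_plus, 2L)    # minimum at t=3, back to 1 at t=5
  theta <- ph2$theta
  expect_lt(abs(ph2$delta_w - (w[theta + 1] - w[1])), 1e-8)
  # trait never beneficial: horizon returned and flagged
  cen <- data.frame(w = rep(0.9, 5), pm = rep(0.3, 5), p0 = 1)
  ph3 <- phase_analysis(cen)
  expect_true(ph3$censored)
  expect_identical(ph3$theta_minus, 4L)
  expect_error(phase_analysis(data.frame(w = 1)), "columns")
})

test_that("hill-climbing m stops where mutant productivity meets the resident level", {
  ls <- pm_landscape("diminishing", b0 = 1.5, b1 = 0.8, gamma = 1.5, n = 100)
  hc <- mstar_hillclimb(ls, p0 = 1, n = 100)
  expect_identical(hc$boundary, "interior")
  expect_lt(abs(hc$pm_at_mstar - 1), 1e-3)
  # closed-form crossing of b0 - b1 (m/n)^gamma = p0
  expect_equal(hc$m_star, 100 * (0.5 / 0.8)^(1 / 1.5), tolerance = 1e-3)
  # boundary cases
  expect_identical(mstar_hillclimb(ls, p0 = 2, n = 100)$boundary, "none")
  expect_identical(mstar_hillclimb(ls, p0 = 0.5, n = 100)$boundary,
                   "all_mutant")
})

test_that("fixation probability falls as a deleterious trait starts more common", {
  probs <- vapply(c(0.02, 0.4), function(f) {
    cfg <- evolution_config(replicates = 300, seed = 55, init_fraction = f)
    simulate_invasion(cfg, keep_trajectories = FALSE)$fixation_prob
  }, numeric(1))
  expect_gte(probs[1], probs[2])
})
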