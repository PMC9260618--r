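#' Generate a randomized scenario fixture
#'
#' Draws a valid scenario from one of the shipped families, deterministic
#' given the seed. All draws respect the model's structural constraints by
#' construction: importance constants in (0, 1], strictly concave utility
#' families, non-negative energies, and a subsistence rate calibrated
#' below the marginal per-worker work value so that workers are net
#' contributors to colony productivity (a maturity condition; without it
#' the loss of a worker could *raise* net productivity and the
#' redistribution analysis would be vacuous).
#'
#' Families:
#' * `"monomorphic-2task"`, `"monomorphic-3task"`, `"monomorphic-4task"`:
#'   one worker caste, `k` tasks with the default saturating utility
#'   family. Saturation rates are scaled so the one-task-per-ant
#'   constraint binds at the equilibrium, and the caste's work rates are
#'   tuned so its per-capita net task rates are equal across tasks (the
#'   per-capita signature of an evolved equal-marginal equilibrium, which
#'   the biomass proxy presupposes).
#' * `"dimorphic"`: 3 tasks; a specialist caste able to perform only the
#'   first task plus a generalist caste able to perform all of them (the
#'   knockout-experiment setting).
#' * `"invasion-sigmoid"`: a minimal colony plus an [evolution_config()]
#'   with a sigmoid mutant-productivity landscape: the novel trait starts
#'   deleterious and becomes beneficial past a threshold in
#'   mutation-space.
#'
#' @param kind fixture family label.
#' @param seed integer seed; identical seeds yield identical scenarios.
#' @param n optional colony-size override (default: drawn from 50-200).
#' @return a validated [scenario()].
#' @export
generate_fixture <- function(kind, seed, n = NULL) {
  kinds <- c("monomorphic-2task", "monomorphic-3task", "monomorphic-4task",
             "dimorphic", "invasion-sigmoid")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop("unknown fixture family '", paste(kind, collapse = ","),
         "'; available: ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  switch(kind,
    "monomorphic-2task" = fixture_monomorphic(2L, seed, n),
    "monomorphic-3task" = fixture_monomorphic(3L, seed, n),
    "monomorphic-4task" = fixture_monomorphic(4L, seed, n),
    "dimorphic" = fixture_dimorphic(seed, n),
    "invasion-sigmoid" = fixture_invasion(seed, n))
}

# draw k tasks whose saturating utilities keep the constraint binding:
# the zero-marginal point of each task alone exceeds eps = 0.65
draw_tasks <- function(k, n) {
  lapply(seq_len(k), function(j) {
    kt <- stats::runif(1, 0.3, 1)
    R <- stats::runif(1, 5, 20)
    a <- stats::runif(1, 1.5, 6) / n
    cc <- kt * R * a * stats::runif(1, 0.002, 0.02)
    task_spec(paste0("task", j), k_tau = kt, R = R, a = a, c = cc)
  })
}

# calibrate basal metabolism to a modest fraction of the equilibrium
# marginal per-worker work value, so workers are strictly net-positive
calibrate_E_basal <- function(tasks, n, frac) {
  sol <- solve_equilibrium(tasks, castes = NULL, n = n)
  frac * sol$lambda_common / n
}

# work rates making per-capita net task rates (k*omega - c) equal
equalized_omega <- function(tasks) {
  g <- stats::runif(1, 0.5, 2)
  stats::setNames(
    vapply(tasks, function(t) (g + t$c) / t$k_tau, numeric(1)),
    task_ids(tasks))
}

fixture_monomorphic <- function(k, seed, n = NULL) {
  if (is.null(n)) n <- sample(50:200, 1)
  tasks <- draw_tasks(k, n)
  eb <- calibrate_E_basal(tasks, n, stats::runif(1, 0.05, 0.4))
  worker <- caste_spec("worker", E_basal = eb,
                       omega = equalized_omega(tasks),
                       mass_per_ant = stats::runif(1, 0.8, 1.2))
  scenario(tasks = tasks, castes = list(worker),
           colony = list(n = n),
           meta = list(name = sprintf("monomorphic-%dtask-%d", k, seed),
                       seed = seed, schema = 1L))
}

fixture_dimorphic <- function(seed, n = NULL) {
  if (is.null(n)) n <- sample(60:200, 1)
  tasks <- draw_tasks(3L, n)
  tids <- task_ids(tasks)
  eb <- calibrate_E_basal(tasks, n, stats::runif(1, 0.05, 0.4))
  omega_gen <- equalized_omega(tasks)
  specialist <- caste_spec(
    "specialist", E_basal = eb,
    omega = stats::setNames(omega_gen[[1L]] * stats::runif(1, 1, 1.5),
                            tids[1L]),
    mass_per_ant = stats::runif(1, 1.2, 2))
  generalist <- caste_spec("generalist", E_basal = eb, omega = omega_gen,
                           mass_per_ant = stats::runif(1, 0.8, 1.2))
  n_spec <- max(1L, round(stats::runif(1, 0.15, 0.3) * n))
  scenario(tasks = tasks, castes = list(specialist, generalist),
           colony = list(n = n,
                         counts = list(specialist = n_spec,
                                       generalist = n - n_spec)),
           meta = list(name = sprintf("dimorphic-%d", seed), seed = seed,
                       schema = 1L))
}

fixture_invasion <- function(seed, n = NULL) {
  if (is.null(n)) n <- 100L
  tasks <- draw_tasks(2L, n)
  worker <- caste_spec("worker", E_basal = 0.01,
                       omega = equalized_omega(tasks))
  evo <- evolution_config(
    n = n, p0 = 1,
    landscape = pm_landscape("sigmoid",
                             p_lo = 0.2,
                             p_hi = stats::runif(1, 1.4, 1.8),
                             s = stats::runif(1, 1.5, 2.5),
                             x0 = 1),
    mutation_sigma = stats::runif(1, 0.2, 0.3),
    fraction_sigma = 0.05,
    fitness = fitness_map("linear", w0 = 1, beta = 1, p_ref = 1),
    replicates = 1L, seed = seed, mode = "stochastic",
    horizon = 150L, init_fraction = 0.05, init_trait = 0)
  scenario(tasks = tasks, castes = list(worker),
           colony = list(n = n), evolution = evo,
           meta = list(name = sprintf("invasion-sigmoid-%d", seed),
                       seed = seed, schema = 1L))
}
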