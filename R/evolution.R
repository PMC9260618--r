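#' Split colony productivity between mutant and resident ants
#'
#' With exactly two kinds of ants — `m` mutants of per-capita productivity
#' `p_m` and `n - m` residents of per-capita productivity `p_0` — colony
#' net productivity decomposes as `P = m*p_m + (n - m)*p_0`, and its
#' derivative with respect to the mutant count is simply
#' `dP/dm = p_m - p_0`: while the mutant trait is worse than the resident's
#' (`p_m < p_0`) every additional mutant lowers colony productivity, and
#' once it is better, every additional mutant raises it.
#'
#' @param m mutant ant count, `0 <= m <= n`.
#' @param n colony size.
#' @param p_m per-capita net productivity of mutant ants.
#' @param p_0 per-capita net productivity of resident ants.
#' @return list with `P` (colony net productivity) and `dP_dm`.
#' @export
productivity_split <- function(m, n, p_m, p_0) {
  if (any(m < 0) || any(m > n)) {
    stop("mutant count 'm' must lie in [0, n]", call. = FALSE)
  }
  list(P = m * p_m + (n - m) * p_0, dP_dm = p_m - p_0)
}

#' Time derivative of split colony productivity
#'
#' Differentiating `P = m*p_m + (n - m)*p_0` with respect to time (at
#' fixed `n` and `p_0`) gives
#' `dP/dt = m * dpm_dt + dm_dt * (p_m - p_0)`.
#'
#' @param m mutant count.
#' @param dm_dt rate of change of the mutant count.
#' @param p_m mutant per-capita productivity.
#' @param dpm_dt rate of change of `p_m`.
#' @param p_0 resident per-capita productivity.
#' @return `dP/dt`.
#' @export
productivity_rate <- function(m, dm_dt, p_m, dpm_dt, p_0) {
  m * dpm_dt + dm_dt * (p_m - p_0)
}

#' Colony fitness map
#'
#' Maps per-capita net productivity `p` to absolute colony fitness `w`,
#' the expected number of daughter colonies per generation. The map must
#' be strictly increasing in `p` (selection favours productive colonies)
#' and is clamped below at 0 (a colony cannot produce a negative number of
#' daughters).
#'
#' @param form `"linear"`: `w = max(0, w0 + beta * (p - p_ref))`, or
#'   `"exponential"`: `w = w0 * exp(beta * (p - p_ref))`.
#' @param w0 basal fitness, daughter colonies per generation, at the
#'   reference productivity.
#' @param beta sensitivity of fitness to productivity, per energy unit;
#'   must be `> 0`.
#' @param p_ref reference per-capita productivity (typically the resident
#'   value `p_0`).
#' @return an object of class `fitness_map`.
#' @export
fitness_map <- function(form = c("linear", "exponential"), w0 = 1,
                        beta = 1, p_ref = 0) {
  form <- match.arg(form)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    stop("'beta' must be > 0: fitness must be strictly increasing in ",
         "productivity", call. = FALSE)
  }
  if (!is.numeric(w0) || length(w0) != 1L || is.na(w0) || w0 < 0) {
    stop("'w0' must be >= 0", call. = FALSE)
  }
  structure(list(form = form, w0 = w0, beta = beta, p_ref = p_ref),
            class = "fitness_map")
}

#' Fitness from per-capita productivity
#'
#' @param p per-capita net productivity (vectorised).
#' @param map a [fitness_map()].
#' @return fitness `w >= 0`, daughter colonies per generation.
#' @export
fitness_from_productivity <- function(p, map) {
  stopifnot(inherits(map, "fitness_map"))
  switch(map$form,
    linear = pmax(0, map$w0 + map$beta * (p - map$p_ref)),
    exponential = map$w0 * exp(map$beta * (p - map$p_ref))
  )
}

#' Mutant productivity landscape
#'
#' Maps the heritable trait position `x` of the mutant caste (a scalar
#' coordinate in mutation-space, explored by a Gaussian random walk across
#' colony generations) to the per-capita net productivity `p_m` of ants
#' carrying the trait.
#'
#' Forms:
#' * `"sigmoid"`: `p_m(x) = p_lo + (p_hi - p_lo) * sigm(s * (x - x0))` —
#'   the trait is deleterious below the threshold `x0` and becomes
#'   beneficial past it (the novel-caste invasion scenario).
#' * `"piecewise_linear"`: linear interpolation through `(xs, ps)` knots,
#'   constant beyond the end knots.
#' * `"constant"`: `p_m(x) = value`.
#' * `"diminishing"`: a function of the mutant *count* rather than the
#'   trait: `p_m(m) = b0 - b1 * (m/n)^gamma` with `gamma >= 1` — mutants
#'   work a diminishing-returns task, so their per-capita productivity
#'   falls (concavely) as more of them are produced. Used by
#'   [mstar_hillclimb()].
#'
#' @param form landscape family name.
#' @param ... family parameters (see above): `p_lo`, `p_hi`, `s`, `x0`;
#'   or `xs`, `ps`; or `value`; or `b0`, `b1`, `gamma`, `n`.
#' @return an object of class `pm_landscape`; call it via [pm_value()].
#' @export
pm_landscape <- function(form = c("sigmoid", "piecewise_linear", "constant",
                                  "diminishing"), ...) {
  form <- match.arg(form)
  pars <- list(...)
  defaults <- switch(form,
    sigmoid = list(p_lo = 0.2, p_hi = 1.6, s = 2, x0 = 1),
    piecewise_linear = list(xs = c(0, 1), ps = c(0, 1)),
    constant = list(value = 1),
    diminishing = list(b0 = 1.5, b1 = 0.8, gamma = 1.5, n = 100))
  unknown <- setdiff(names(pars), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s) for ", form, " landscape: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pars <- utils::modifyList(defaults, pars)
  if (form == "piecewise_linear" &&
      (length(pars$xs) != length(pars$ps) || length(pars$xs) < 2L)) {
    stop("piecewise_linear needs matching xs/ps with at least 2 knots",
         call. = FALSE)
  }
  if (form == "diminishing" && pars$gamma < 1) {
    stop("'gamma' must be >= 1 for a concave diminishing landscape",
         call. = FALSE)
  }
  structure(c(list(form = form), pars), class = "pm_landscape")
}

#' Evaluate a mutant productivity landscape
#'
#' @param landscape a [pm_landscape()].
#' @param x trait position (or mutant count, for the `"diminishing"` form);
#'   vectorised.
#' @return `p_m` value(s).
#' @export
pm_value <- function(landscape, x) {
  stopifnot(inherits(landscape, "pm_landscape"))
  switch(landscape$form,
    sigmoid = landscape$p_lo + (landscape$p_hi - landscape$p_lo) *
      .sigm(landscape$s * (x - landscape$x0)),
    piecewise_linear = stats::approx(landscape$xs, landscape$ps, xout = x,
                                     rule = 2)$y,
    constant = rep.int(landscape$value, length(x)),
    diminishing = landscape$b0 - landscape$b1 * (x / landscape$n)^landscape$gamma
  )
}

#' Evolutionary scenario configuration
#'
#' Study conditions for the invasion of a novel caste by colony-level
#' selection. A lineage starts from a single mature colony of size `n`
#' whose queen produces a fraction `init_fraction` of mutant offspring
#' carrying a novel heritable trait at position `init_trait` in
#' mutation-space. Each generation every colony produces
#' `Poisson(w)` daughter colonies (or exactly `round(w)` in deterministic
#' mode) and then dies; daughters inherit the trait position perturbed by
#' a Gaussian step of scale `mutation_sigma` and the mutant fraction
#' perturbed by a multiplicative log-normal kernel of scale
#' `fraction_sigma` (both the offspring types and their fractions are
#' heritable and mutable).
#'
#' @param n colony size (ants per mature colony).
#' @param p0 resident per-capita net productivity, energy units per step.
#' @param landscape a [pm_landscape()] giving mutant productivity from the
#'   trait position.
#' @param mutation_sigma random-walk step scale in mutation-space per
#'   colony generation, `>= 0`.
#' @param fraction_sigma log-normal perturbation scale of the mutant
#'   offspring fraction per generation, `>= 0`.
#' @param fitness a [fitness_map()]; its reference productivity defaults
#'   to `p0` so a pure-resident colony has fitness `w0`.
#' @param replicates number of independent lineages, `>= 1`.
#' @param seed RNG seed; replicate `r` uses the stream `seed + r - 1`.
#' @param mode `"stochastic"` (Poisson reproduction) or `"deterministic"`
#'   (`round(w)` daughters, for exact tests).
#' @param horizon maximum number of colony generations.
#' @param init_fraction initial mutant offspring fraction in `(0, 1]`.
#' @param init_trait initial trait position.
#' @param ceiling colony-population cap; uniform seeded thinning keeps the
#'   lineage at or below this size.
#' @param persist_colonies once the trait is beneficial and mean fitness
#'   is at least 1, a lineage holding at least this many colonies is
#'   classified as fixed (extinction risk is then negligible).
#' @return an object of class `evolution_config`.
#' @export
evolution_config <- function(n = 100, p0 = 1,
                             landscape = pm_landscape("sigmoid"),
                             mutation_sigma = 0.25, fraction_sigma = 0.05,
                             fitness = NULL,
                             replicates = 1L, seed = 1L,
                             mode = c("stochastic", "deterministic"),
                             horizon = 150L, init_fraction = 0.05,
                             init_trait = 0, ceiling = 10000L,
                             persist_colonies = 50L) {
  mode <- match.arg(mode)
  if (is.null(fitness)) fitness <- fitness_map("linear", w0 = 1, beta = 1,
                                               p_ref = p0)
  stopifnot(inherits(landscape, "pm_landscape"), inherits(fitness, "fitness_map"))
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  if (mutation_sigma < 0) stop("'mutation_sigma' must be >= 0", call. = FALSE)
  if (fraction_sigma < 0) stop("'fraction_sigma' must be >= 0", call. = FALSE)
  if (init_fraction <= 0 || init_fraction > 1) {
    stop("'init_fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  structure(
    list(n = as.integer(n), p0 = p0, landscape = landscape,
         mutation_sigma = mutation_sigma, fraction_sigma = fraction_sigma,
         fitness = fitness, replicates = as.integer(replicates),
         seed = as.integer(seed), mode = mode, horizon = as.integer(horizon),
         init_fraction = init_fraction, init_trait = init_trait,
         ceiling = as.integer(ceiling),
         persist_colonies = as.integer(persist_colonies)),
    class = "evolution_config")
}

# per-colony state columns: trait_x, frac
colony_stats <- function(colonies, config) {
  m <- round(colonies$frac * config$n)
  p_m <- pm_value(config$landscape, colonies$trait_x)
  p <- (m * p_m + (config$n - m) * config$p0) / config$n
  w <- fitness_from_productivity(p, config$fitness)
  list(m = m, p_m = p_m, p = p, w = w)
}

#' Advance a lineage of colonies by one generation
#'
#' Every colony produces daughters according to its fitness (Poisson in
#' stochastic mode, `round(w)` in deterministic mode) and then dies
#' (colony generations do not overlap). Each daughter perturbs the trait
#' position by a Gaussian step and the mutant fraction by a multiplicative
#' log-normal kernel, and the population is thinned uniformly at random
#' down to the configured ceiling. Randomness is drawn from the current R
#' RNG state; seed it for reproducibility.
#'
#' @param colonies data frame with columns `trait_x` and `frac`, one row
#'   per colony; must be non-empty.
#' @param config an [evolution_config()].
#' @return the next generation's data frame (possibly with zero rows:
#'   lineage extinction).
#' @export
step_lineage <- function(colonies, config) {
  stopifnot(inherits(config, "evolution_config"))
  if (nrow(colonies) == 0L) stop("lineage is already extinct", call. = FALSE)
  st <- colony_stats(colonies, config)
  off <- if (config$mode == "deterministic") round(st$w)
         else stats::rpois(nrow(colonies), st$w)
  idx <- rep.int(seq_len(nrow(colonies)), off)
  if (length(idx) == 0L) {
    return(data.frame(trait_x = numeric(), frac = numeric()))
  }
  trait <- colonies$trait_x[idx]
  frac <- colonies$frac[idx]
  if (config$mutation_sigma > 0) {
    trait <- trait + stats::rnorm(length(idx), 0, config$mutation_sigma)
  }
  if (config$fraction_sigma > 0) {
    frac <- pmin(1, frac * exp(stats::rnorm(length(idx), 0,
                                            config$fraction_sigma)))
  }
  out <- data.frame(trait_x = trait, frac = frac)
  if (nrow(out) > config$ceiling) {
    keep <- sample.int(nrow(out), config$ceiling)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

run_one_lineage <- function(config, keep_trajectory = TRUE) {
  colonies <- data.frame(trait_x = config$init_trait,
                         frac = config$init_fraction)
  H <- config$horizon
  traj <- matrix(NA_real_, nrow = H + 1L, ncol = 7L,
                 dimnames = list(NULL, c("step", "m", "pm", "p0", "P", "w",
                                         "N_colonies")))
  beneficial_seen <- FALSE
  outcome <- "censored"
  last <- 0L
  for (t in 0:H) {
    st <- colony_stats(colonies, config)
    traj[t + 1L, ] <- c(t, mean(st$m), mean(st$p_m), config$p0,
                        mean(st$m * st$p_m + (config$n - st$m) * config$p0),
                        mean(st$w), nrow(colonies))
    last <- t
    if (mean(st$p_m) >= config$p0) beneficial_seen <- TRUE
    if (beneficial_seen && mean(st$w) >= 1 &&
        nrow(colonies) >= config$persist_colonies && any(st$m >= 1)) {
      outcome <- "fixed"
      break
    }
    if (t == H) {
      if (any(st$m >= 1) && mean(st$w) >= 1) outcome <- "fixed"
      break
    }
    colonies <- step_lineage(colonies, config)
    if (nrow(colonies) == 0L) {
      outcome <- if (beneficial_seen) "extinct_case2" else "extinct_case1"
      traj[t + 2L, ] <- c(t + 1, 0, NA, config$p0, 0, 0, 0)
      last <- t + 1L
      break
    }
  }
  traj <- as.data.frame(traj[seq_len(last + 1L), , drop = FALSE])
  ph <- phase_analysis(traj)
  res <- list(outcome = outcome,
              theta_minus = ph$theta_minus, theta_plus = ph$theta_plus,
              delta_w = ph$delta_w, censored_theta = ph$censored,
              final_N = traj$N_colonies[nrow(traj)],
              m_star = if (config$mode == "deterministic")
                traj$m[nrow(traj)] else NA_real_,
              trajectory = if (keep_trajectory) traj else NULL)
  class(res) <- "invasion_result"
  res
}

#' Simulate the invasion of a novel caste under colony-level selection
#'
#' Runs `config$replicates` independent lineages, each seeded from its own
#' counter-split RNG stream, and classifies every lineage:
#'
#' * `extinct_case1` — the lineage dies out while the trait is still
#'   deleterious (during the waiting time `theta_minus`): the trait was
#'   too harmful, took too long to become beneficial, or was expressed in
#'   too many ants.
#' * `extinct_case2` — the trait became beneficial but the lineage died
#'   before its fitness recovered and the population rebounded.
#' * `fixed` — the trait is beneficial and the lineage persists with mean
#'   fitness at least 1 (declared early once the colony population exceeds
#'   the persistence threshold, or at the horizon).
#' * `censored` — the horizon was reached without any of the above.
#'
#' @param config an [evolution_config()].
#' @param keep_trajectories keep the per-step trajectory of every
#'   replicate (`TRUE`, default) or only its scalar summary (`FALSE`, for
#'   large replicate counts).
#' @return an object of class `invasion_summary`: list with `replicates`
#'   (list of per-lineage results), `outcome_counts`, `fixation_prob`,
#'   `fixation_ci` (exact binomial 95% CI), `mean_theta_minus`,
#'   `mean_theta_plus`, and the `config`.
#' @export
simulate_invasion <- function(config, keep_trajectories = TRUE) {
  stopifnot(inherits(config, "evolution_config"))
  reps <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed(config$seed + r - 1L)
    reps[[r]] <- run_one_lineage(config, keep_trajectory = keep_trajectories)
  }
  outcomes <- vapply(reps, `[[`, character(1), "outcome")
  counts <- table(factor(outcomes, levels = c("fixed", "extinct_case1",
                                              "extinct_case2", "censored")))
  nfix <- as.integer(counts[["fixed"]])
  ci <- as.numeric(stats::binom.test(nfix, config$replicates)$conf.int)
  structure(
    list(replicates = reps,
         outcome_counts = counts,
         fixation_prob = nfix / config$replicates,
         fixation_ci = ci,
         mean_theta_minus = mean(vapply(reps, `[[`, numeric(1), "theta_minus")),
         mean_theta_plus = mean(vapply(reps, `[[`, numeric(1), "theta_plus")),
         config = config),
    class = "invasion_summary")
}

#' @export
print.invasion_summary <- function(x, ...) {
  cat(sprintf("<invasion_summary> %d lineages, seed %d, mode %s\n",
              x$config$replicates, x$config$seed, x$config$mode))
  print(x$outcome_counts)
  cat(sprintf("  fixation probability %.4f (95%% CI %.4f-%.4f)\n",
              x$fixation_prob, x$fixation_ci[1], x$fixation_ci[2]))
  invisible(x)
}

#' Phase analysis of an invasion trajectory
#'
#' Extracts the waiting times and the integrated fitness change from a
#' per-generation trajectory:
#'
#' * `theta_minus` — the first generation at which the mutant per-capita
#'   productivity reaches the resident level (`pm >= p0`); if that never
#'   happens the horizon is returned and the result is flagged censored.
#' * `theta_plus` — generations from the fitness minimum until fitness is
#'   back at 1; 0 if fitness never dips below 1.
#' * `delta_w` — the integral of the fitness rate `phi = dw/dt` over
#'   `[0, theta]` with `theta = theta_minus + theta_plus`, computed as the
#'   sum of per-generation forward differences (the trapezoidal sum for a
#'   piecewise-linear fitness path), which telescopes to
#'   `w(theta) - w(0)`.
#'
#' @param trajectory data frame with columns `w`, `pm` and `p0` (and
#'   optionally `step`), one row per generation starting at 0.
#' @return list with `theta_minus`, `theta_plus`, `theta`, `delta_w`,
#'   `censored`.
#' @export
phase_analysis <- function(trajectory) {
  need <- c("w", "pm", "p0")
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0L ||
      !all(need %in% names(trajectory))) {
    stop("trajectory must be a non-empty data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  w <- trajectory$w
  horizon <- nrow(trajectory) - 1L
  ben <- which(!is.na(trajectory$pm) & trajectory$pm >= trajectory$p0)
  censored <- length(ben) == 0L
  theta_minus <- if (censored) horizon else ben[1L] - 1L
  if (min(w) >= 1) {
    theta_plus <- 0L
  } else {
    i_min <- which.min(w)
    rec <- which(w >= 1)
    rec <- rec[rec >= i_min]
    theta_plus <- if (length(rec)) rec[1L] - i_min else horizon - (i_min - 1L)
  }
  theta <- min(theta_minus + theta_plus, horizon)
  phi <- diff(w)                      # forward differences, dt = 1
  delta_w <- if (theta >= 1L) sum(phi[seq_len(theta)]) else 0
  list(theta_minus = theta_minus, theta_plus = as.integer(theta_plus),
       theta = theta, delta_w = delta_w, censored = censored)
}

#' Deterministic hill-climb of the mutant count
#'
#' Implements the model's prediction that the number of mutant-caste ants
#' should keep increasing only while they remain at least as productive as
#' resident workers, i.e. growth stops where `p_m(m*) = p_0`. Starting
#' from `m = 0`, the climb adds mutants in steps, halving the step
#' whenever adding it would push mutant per-capita productivity below the
#' resident level; with a concave, decreasing `p_m(m)` (mutants work a
#' diminishing-returns task) this converges monotonically to the unique
#' crossing point.
#'
#' @param pm_of_m function (or `"diminishing"` [pm_landscape()]) giving
#'   mutant per-capita productivity at mutant count `m`.
#' @param p0 resident per-capita productivity.
#' @param n colony size (upper bound for `m`).
#' @param tol stop once `|p_m(m) - p0| < tol`.
#' @return list with `m_star`, `pm_at_mstar`, `gap` (`p_m(m*) - p0`) and
#'   `boundary` (`"interior"`, `"all_mutant"` when `p_m(n) >= p0`, or
#'   `"none"` when even the first mutant is unproductive).
#' @export
mstar_hillclimb <- function(pm_of_m, p0, n, tol = 1e-6) {
  f <- if (inherits(pm_of_m, "pm_landscape")) {
    function(m) pm_value(pm_of_m, m)
  } else {
    match.fun(pm_of_m)
  }
  if (f(0) < p0) {
    return(list(m_star = 0, pm_at_mstar = f(0), gap = f(0) - p0,
                boundary = "none"))
  }
  if (f(n) >= p0) {
    return(list(m_star = n, pm_at_mstar = f(n), gap = f(n) - p0,
                boundary = "all_mutant"))
  }
  m <- 0
  step <- n / 8
  while (step > .Machine$double.eps * n) {
    if (abs(f(m) - p0) < tol) break
    if (f(m + step) >= p0) m <- m + step else step <- step / 2
  }
  list(m_star = m, pm_at_mstar = f(m), gap = f(m) - p0,
       boundary = "interior")
}
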