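#' Marginal rate of substitution between two tasks
#'
#' `M_ij = mu_i / mu_j`, the ratio of the marginal utilities of tasks `i`
#' and `j` at the current colony state: adding one more performer to task
#' `i` is `M_ij` times as useful as adding one to task `j`. At the
#' equilibrium division of labor every active pair satisfies `M_ij = 1`.
#'
#' @param task_i,task_j [task_spec()]s.
#' @param state a [colony_state()] supplying `n` and the task fractions.
#' @return dimensionless ratio.
#' @export
mrs <- function(task_i, task_j, state) {
  stopifnot(inherits(state, "colony_state"))
  mu_i <- marginal_utility_mu(task_i, state$n, state$eps[[task_i$id]])
  mu_j <- marginal_utility_mu(task_j, state$n, state$eps[[task_j$id]])
  if (mu_j == 0) {
    stop("MRS undefined: marginal utility of task '", task_j$id,
         "' is zero (saturated denominator task)", call. = FALSE)
  }
  mu_i / mu_j
}

# subsistence load given castes and per-caste counts (counts may be real
# during perturbation analysis)
subsistence_energy <- function(castes, counts) {
  if (length(castes) == 0L) return(0)
  eb <- vapply(castes, `[[`, numeric(1), "E_basal")
  sum(counts[caste_ids(castes)] * eb)
}

# tasks performable by at least one caste present (count > 0);
# castes = NULL means no capability restriction
performable_tasks <- function(tasks, castes, counts = NULL) {
  if (is.null(castes)) return(task_ids(tasks))
  present <- castes
  if (!is.null(counts)) {
    present <- castes[vapply(castes, function(cs) counts[[cs$id]] > 0, TRUE)]
  }
  can <- unique(unlist(lapply(present, `[[`, "performs")))
  intersect(task_ids(tasks), can)
}

#' Solve the equilibrium division of labor
#'
#' Maximises net productivity `P = sum_j U_j(n, eps_j) - E` over the task
#' fractions subject to `eps_j >= 0` and `sum(eps) <= 1` (an ant performs
#' at most one task at a time). For concave utility families the optimum is
#' characterised by the equal-marginal-utility condition: either all active
#' tasks share a common marginal utility `lambda > 0` and the constraint
#' binds (`sum(eps) = 1`), or every active task is worked to the point of
#' zero marginal utility and slack ants stay idle. Tasks whose marginal
#' utility at zero already falls below `lambda` receive no workers (the
#' task is dropped); the solver reports this classification explicitly.
#'
#' The solution is found by monotone water-filling: the allocation
#' `eps_j(lambda)` solving `mu_j(eps) = lambda` is non-increasing in
#' `lambda`, so bisection on `lambda` locates the binding multiplier to
#' machine precision. Non-concave families are refused because the
#' equal-marginal condition would not certify a global optimum.
#'
#' @param tasks list of [task_spec()]s; at least one.
#' @param castes optional list of [caste_spec()]s; restricts allocation to
#'   tasks some present caste can perform and supplies subsistence costs.
#' @param n colony size (`> 0`; may be non-integral during perturbation
#'   analyses).
#' @param counts optional named per-caste counts (defaults to all ants in a
#'   single caste).
#' @param active_tol fractions below this count as inactive.
#' @param oracle_gap if `TRUE` and there are at most 3 tasks, also runs the
#'   exhaustive [grid_oracle()] and reports `P_star` minus the oracle value
#'   as a diagnostic.
#' @return an object of class `allocation_result`: `eps_star`,
#'   `lambda_common`, `active_set`, `M` (full MRS matrix; entries with a
#'   zero-marginal denominator are `NaN`/`Inf`), `mu`, `G_star`, `E`,
#'   `P_star`, `binding`, `converged`, `kkt_ok`, `oracle_gap`.
#' @export
solve_equilibrium <- function(tasks, castes = NULL, n, counts = NULL,
                              active_tol = 1e-9, oracle_gap = FALSE) {
  if (length(tasks) < 1L) stop("at least one task is required", call. = FALSE)
  if (n <= 0) stop("colony size must be positive", call. = FALSE)
  tids <- task_ids(tasks)
  if (!is.null(castes) && is.null(counts)) {
    if (length(castes) == 1L) {
      counts <- stats::setNames(n, caste_ids(castes))
    } else {
      stop("'counts' is required when several castes are present", call. = FALSE)
    }
  }
  bad <- vapply(tasks, Negate(family_is_concave), TRUE)
  if (any(bad)) {
    stop("non-concave utility family for task(s) ",
         paste(tids[bad], collapse = ", "),
         ": the equal-marginal-utility condition does not certify a global ",
         "optimum; use a concave family or threshold_n0 = 0", call. = FALSE)
  }
  doable <- performable_tasks(tasks, castes, counts)
  eps <- stats::setNames(numeric(length(tids)), tids)
  sub <- tasks[tids %in% doable]
  if (length(sub)) {
    fill <- function(lambda) {
      vapply(sub, mu_inverse, numeric(1), n = n, lambda = lambda)
    }
    s0 <- sum(fill(0))
    if (s0 <= 1) {
      eps[doable] <- fill(0)          # idle slack: all active marginals zero
      lambda <- 0
      binding <- FALSE
    } else {
      lo <- 0
      hi <- max(vapply(sub, marginal_utility_mu, numeric(1), n = n, eps = 0))
      for (it in 1:200) {
        mid <- (lo + hi) / 2
        if (sum(fill(mid)) > 1) lo <- mid else hi <- mid
        if (hi - lo <= .Machine$double.eps * max(1, hi)) break
      }
      lambda <- (lo + hi) / 2
      e_raw <- fill(lambda)
      # remove the residual bisection slack proportionally on interior tasks
      tot <- sum(e_raw)
      interior <- e_raw > 0 & e_raw < 1
      if (abs(tot - 1) > 0 && any(interior)) {
        e_raw[interior] <- e_raw[interior] * (1 - sum(e_raw[!interior])) /
          sum(e_raw[interior])
      }
      eps[doable] <- e_raw
      binding <- TRUE
    }
  } else {
    lambda <- 0
    binding <- FALSE
  }
  mu <- stats::setNames(
    vapply(seq_along(tasks), function(i)
      marginal_utility_mu(tasks[[i]], n, eps[[i]]), numeric(1)), tids)
  active <- tids[eps > active_tol]
  U <- stats::setNames(
    vapply(seq_along(tasks), function(i)
      evaluate_utility(tasks[[i]], n, eps[[i]]), numeric(1)), tids)
  G <- sum(U)
  E <- if (is.null(castes)) 0 else subsistence_energy(castes, counts)
  M <- outer(mu, mu, "/")
  dimnames(M) <- list(tids, tids)
  lambda_common <- if (binding) lambda else 0
  kkt_ok <- all(abs(mu[active] - lambda_common) <=
                  1e-6 * max(1, abs(lambda_common))) &&
    all(vapply(tasks[!tids %in% active], function(tk)
      marginal_utility_mu(tk, n, 0) <= lambda_common +
        1e-6 * max(1, lambda_common) ||
        !(tk$id %in% doable), TRUE))
  res <- structure(
    list(eps_star = eps, lambda_common = lambda_common, active_set = active,
         M = M, mu = mu, U_star = U, G_star = G, E = E, P_star = G - E,
         binding = binding, performable = doable, n = n,
         converged = TRUE, kkt_ok = kkt_ok, oracle_gap = NA_real_),
    class = "allocation_result")
  if (isTRUE(oracle_gap) && length(sub) <= 3L) {
    or <- grid_oracle(tasks, n, castes = castes, counts = counts)
    res$oracle_gap <- res$P_star - or$P_best
  }
  res
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> n=%g  P*=%.6g  lambda=%.6g  %s\n",
              x$n, x$P_star, x$lambda_common,
              if (x$binding) "constraint binding" else "idle slack"))
  print(round(x$eps_star, 6))
  if (!is.na(x$oracle_gap)) cat(sprintf("  oracle gap: %.3g\n", x$oracle_gap))
  invisible(x)
}

#' Exhaustive grid-search oracle for the allocation problem
#'
#' Brute-force maximisation of `P` over a regular grid on the constraint
#' simplex, progressively refined around the incumbent down to
#' `final_step`. Intended as an independent check of [solve_equilibrium()]
#' on problems with at most 3 tasks; it evaluates the utility sum directly
#' and shares no code path with the water-filling solver.
#'
#' @inheritParams solve_equilibrium
#' @param step initial grid spacing on each `eps` coordinate.
#' @param final_step spacing at the last refinement level.
#' @return list with `P_best` and `eps_best`.
#' @export
grid_oracle <- function(tasks, n, castes = NULL, counts = NULL,
                        step = 0.01, final_step = 1e-5) {
  tids <- task_ids(tasks)
  if (!is.null(castes) && is.null(counts) && length(castes) == 1L) {
    counts <- stats::setNames(n, caste_ids(castes))
  }
  doable <- performable_tasks(tasks, castes, counts)
  sub <- tasks[tids %in% doable]
  d <- length(sub)
  if (d > 3L) stop("grid oracle supports at most 3 performable tasks",
                   call. = FALSE)
  E <- if (is.null(castes)) 0 else subsistence_energy(castes, counts)
  if (d == 0L) {
    return(list(P_best = -E,
                eps_best = stats::setNames(numeric(length(tids)), tids)))
  }
  objective <- function(grid) {  # grid: matrix, one column per task in sub
    tot <- 0
    for (i in seq_len(d)) tot <- tot + evaluate_utility(sub[[i]], n, grid[, i])
    tot
  }
  eval_box <- function(centre, h, by) {
    axes <- lapply(seq_len(d), function(i) {
      v <- seq(max(0, centre[i] - h), min(1, centre[i] + h), by = by)
      unique(pmin(1, pmax(0, v)))
    })
    grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    grid <- grid[rowSums(grid) <= 1 + 1e-12, , drop = FALSE]
    val <- objective(grid)
    best <- which.max(val)
    list(eps = grid[best, ], val = val[best])
  }
  cur <- eval_box(rep(0.5, d), 0.5, step)
  h <- step
  by <- step / 10
  while (by >= final_step / 1.0001) {
    cur <- eval_box(cur$eps, h, by)
    h <- by
    by <- by / 10
  }
  eps_best <- stats::setNames(numeric(length(tids)), tids)
  eps_best[doable] <- cur$eps
  list(P_best = cur$val - E, eps_best = eps_best)
}

#' Build the colony state at the solved equilibrium
#'
#' Convenience wrapper: solves the equilibrium and returns the
#' corresponding [colony_state()] (with integer performer counts and the
#' deterministic caste assignment).
#'
#' @inheritParams solve_equilibrium
#' @return a [colony_state()] with attribute `"allocation"` holding the
#'   [solve_equilibrium()] result.
#' @export
equilibrium_state <- function(tasks, castes, n, counts = NULL) {
  if (is.null(counts) && length(castes) == 1L) {
    counts <- stats::setNames(n, caste_ids(castes))
  }
  sol <- solve_equilibrium(tasks, castes, n, counts)
  st <- colony_state(tasks, castes, n, counts, eps = sol$eps_star)
  attr(st, "allocation") <- sol
  st
}
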