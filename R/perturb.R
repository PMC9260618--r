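#' Worker loss and task redistribution
#'
#' Starting from an equilibrium colony, kills a fraction `delta_eps` of the
#' workers currently performing task `task_i` (the dead are gone, so the
#' colony shrinks and its subsistence load falls accordingly) and reports:
#'
#' 1. the marginal rate of substitution of the depleted task against every
#'    other task *before* any re-allocation — strictly greater than 1 for
#'    strictly concave families at a binding equilibrium, which is exactly
#'    the signal that shifting workers into the depleted task would raise
#'    productivity;
#' 2. the re-solved equilibrium of the reduced workforce; and
#' 3. the productivity ordering
#'    `P_original >= P_redistributed >= P_unredistributed`: redistribution
#'    buffers, but cannot fully repay, the loss of the dead.
#'
#' @param tasks list of [task_spec()]s.
#' @param castes list of [caste_spec()]s.
#' @param state an equilibrium [colony_state()] (e.g. from
#'   [equilibrium_state()]).
#' @param task_i id of the task whose workers die.
#' @param delta_eps fraction of task-`i` workers lost, in `[0, 1]`
#'   (`delta_eps = 0.2` means 20% of that task's performers die).
#' @return an object of class `perturbation_report` with fields
#'   `delta_eps`, `M_before_redistribution` (named vector over the other
#'   tasks), `P_original`, `P_unredistributed`, `P_redistributed`,
#'   `eps_unredistributed`, `eps_redistributed`, `n_before`, `n_after`,
#'   `counts_after`.
#' @export
redistribute_after_loss <- function(tasks, castes, state, task_i, delta_eps) {
  stopifnot(inherits(state, "colony_state"))
  tids <- task_ids(tasks)
  if (!task_i %in% tids) stop("unknown task '", task_i, "'", call. = FALSE)
  if (length(delta_eps) != 1L || is.na(delta_eps) ||
      delta_eps < 0 || delta_eps > 1) {
    stop("'delta_eps' must be a fraction of task-", task_i,
         " workers in [0, 1]", call. = FALSE)
  }
  n <- state$n
  eps0 <- state$eps[tids]
  x0 <- n * eps0                       # performers per task (continuous view)
  dead <- delta_eps * x0[[task_i]]
  n_new <- n - dead
  if (n_new <= 0) stop("worker loss empties the colony", call. = FALSE)
  x1 <- x0
  x1[[task_i]] <- x1[[task_i]] - dead
  eps1 <- x1 / n_new                   # same survivors, smaller colony

  # the dead are drawn from castes in proportion to their presence on task i
  counts0 <- as.numeric(state$counts)
  names(counts0) <- names(state$counts)
  counts1 <- counts0
  on_task <- state$assign[, task_i]
  if (sum(on_task) > 0 && dead > 0) {
    counts1 <- counts0 - dead * on_task / sum(on_task)
  }

  E0 <- subsistence_energy(castes, counts0)
  E1 <- subsistence_energy(castes, counts1)
  util_sum <- function(nn, eps) {
    sum(vapply(seq_along(tasks), function(i)
      evaluate_utility(tasks[[i]], nn, eps[[i]]), numeric(1)))
  }
  P_original <- util_sum(n, eps0) - E0
  P_unredistributed <- util_sum(n_new, eps1) - E1

  mu1 <- stats::setNames(
    vapply(seq_along(tasks), function(i)
      marginal_utility_mu(tasks[[i]], n_new, eps1[[i]]), numeric(1)), tids)
  others <- setdiff(tids, task_i)
  M_before <- stats::setNames(
    ifelse(mu1[others] == 0, NA_real_, mu1[[task_i]] / mu1[others]), others)

  sol <- solve_equilibrium(tasks, castes, n_new, counts = counts1)

  structure(
    list(task_i = task_i, delta_eps = delta_eps,
         M_before_redistribution = M_before,
         P_original = P_original,
         P_unredistributed = P_unredistributed,
         P_redistributed = sol$P_star,
         eps_unredistributed = eps1,
         eps_redistributed = sol$eps_star,
         allocation = sol,
         n_before = n, n_after = n_new, counts_after = counts1),
    class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat(sprintf("<perturbation_report> task '%s', %.0f%% of its workers lost\n",
              x$task_i, 100 * x$delta_eps))
  cat(sprintf("  P original        %.6g\n", x$P_original))
  cat(sprintf("  P redistributed   %.6g\n", x$P_redistributed))
  cat(sprintf("  P unredistributed %.6g\n", x$P_unredistributed))
  cat("  MRS of depleted task vs others (before re-solving):\n")
  print(round(x$M_before_redistribution, 6))
  invisible(x)
}
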