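#' Biomass proxy for task utilities
#'
#' For a monomorphic colony (a single worker caste of identical ants) at
#' its equilibrium division of labor, per-capita task utilities are equal
#' across active tasks, so the utility of a task is proportional to the
#' number — and hence the total biomass — of ants performing it. The
#' biomass share of a task then estimates its utility share of gross
#' productivity, and total colony biomass serves as a field-measurable
#' proxy for gross productivity itself.
#'
#' The check is performed in the ledger (per-capita) accounting, where
#' task utility is performer count times the caste's net per-ant rate
#' `k_tau * omega - c`; the equal-marginal equilibrium condition then
#' amounts to equality of those per-ant rates across active tasks, which
#' this function verifies before reporting shares.
#'
#' @param tasks list of [task_spec()]s.
#' @param castes list containing exactly one worker [caste_spec()]; the
#'   proxy is derived for identical workers and is refused for
#'   polymorphic colonies.
#' @param state the equilibrium [colony_state()].
#' @param rtol relative tolerance for the equal-per-capita-utility check.
#' @return an object of class `proxy_report`: `per_task_biomass`,
#'   `total_biomass`, `per_capita_utility` (the common value),
#'   `proxy_utilities` (biomass-share estimates of each `U_i`),
#'   `true_utilities` (ledger `U_i`), `proportionality_error` (max
#'   relative gap between utility shares `U_i/G` and biomass shares
#'   `m_i/M` over active tasks).
#' @export
biomass_proxy <- function(tasks, castes, state, rtol = 1e-6) {
  stopifnot(inherits(state, "colony_state"))
  if (length(castes) != 1L) {
    stop("biomass proxy refused: colony is polymorphic (", length(castes),
         " castes); the proxy is derived for identical workers only",
         call. = FALSE)
  }
  led <- colony_ledger(tasks, castes, state)
  tids <- task_ids(tasks)
  counts <- state$task_counts[tids]
  active <- tids[counts > 0]
  if (length(active) == 0L) {
    stop("no active tasks: biomass proxy undefined", call. = FALSE)
  }
  ubar <- led$U[active] / counts[active]
  spread <- diff(range(ubar))
  if (mean(abs(ubar)) > 0 && spread > rtol * mean(abs(ubar))) {
    stop("biomass proxy refused: per-capita task utilities are unequal ",
         "(relative spread ", format(spread / mean(abs(ubar)), digits = 3),
         "); the colony is not at an equal-marginal equilibrium in the ",
         "per-capita accounting", call. = FALSE)
  }
  mass <- castes[[1L]]$mass_per_ant
  m_i <- counts * mass
  M <- state$n * mass
  G <- led$G
  u_share <- led$U[active] / G
  b_share <- m_i[active] / M
  structure(
    list(per_task_biomass = m_i, total_biomass = M,
         per_capita_utility = mean(ubar),
         proxy_utilities = (m_i / M) * G,
         true_utilities = led$U,
         active_set = active,
         proportionality_error = max(abs(u_share - b_share) / abs(u_share))),
    class = "proxy_report")
}

#' @export
print.proxy_report <- function(x, ...) {
  cat("<proxy_report>\n")
  cat(sprintf("  total biomass (gross-productivity proxy): %.6g\n",
              x$total_biomass))
  cat(sprintf("  common per-capita utility: %.6g\n", x$per_capita_utility))
  cat(sprintf("  max proportionality error: %.3g\n", x$proportionality_error))
  invisible(x)
}

#' In-silico caste knockout experiment
#'
#' Removes every member of one caste from an equilibrium colony, re-solves
#' the division of labor for the reduced colony, and looks for task
#' redistribution: remaining castes shifting into the tasks the removed
#' caste used to perform. Redistribution is the model's falsifiable
#' prediction — if capable castes remain (non-zero work rate for an
#' orphaned task) yet none increases its allocation to those tasks, the
#' report's `falsified_flag` is raised. If no remaining caste can perform
#' the orphaned tasks, the absence of redistribution is capability-limited
#' and is *not* evidence against the model.
#'
#' @param tasks list of [task_spec()]s.
#' @param castes list of [caste_spec()]s (at least two).
#' @param state the pre-knockout equilibrium [colony_state()].
#' @param caste_to_remove id of the caste to eliminate.
#' @return an object of class `knockout_report`: `removed_caste`,
#'   `orphaned_tasks`, `allocation_before`/`allocation_after` (colony task
#'   fractions), `per_caste_before`/`per_caste_after` (fraction of each
#'   caste's ants on each task), `redistribution_detected`,
#'   `capable_remaining`, `falsified_flag`, `reason`, `P_before`,
#'   `P_after`, `n_after`, and the post-knockout `allocation`
#'   ([solve_equilibrium()] result).
#' @export
knockout_experiment <- function(tasks, castes, state, caste_to_remove) {
  stopifnot(inherits(state, "colony_state"))
  cids <- caste_ids(castes)
  if (!caste_to_remove %in% cids) {
    stop("unknown caste '", caste_to_remove, "'", call. = FALSE)
  }
  if (length(castes) < 2L) {
    stop("knockout refused: removing the only caste leaves a degenerate ",
         "colony", call. = FALSE)
  }
  tids <- task_ids(tasks)
  keep <- cids != caste_to_remove
  castes_after <- castes[keep]
  counts_after <- state$counts[cids[keep]]
  n_after <- sum(counts_after)
  if (n_after <= 0) {
    stop("knockout refused: no ants remain after removal", call. = FALSE)
  }
  orphaned <- tids[state$assign[caste_to_remove, ] > 0]

  sol_before <- solve_equilibrium(tasks, castes, state$n,
                                  counts = state$counts)
  sol_after <- solve_equilibrium(tasks, castes_after, n_after,
                                 counts = counts_after)
  state_after <- colony_state(tasks, castes_after, n_after, counts_after,
                              eps = sol_after$eps_star)

  frac_of_caste <- function(assign, counts) {
    sweep(assign, 1, pmax(counts, 1L), "/")
  }
  pc_before <- frac_of_caste(state$assign, state$counts)[cids[keep], ,
                                                         drop = FALSE]
  pc_after <- frac_of_caste(state_after$assign, counts_after)

  capable <- vapply(castes_after, function(cs)
    any(orphaned %in% cs$performs), TRUE)
  shifted <- FALSE
  if (length(orphaned)) {
    shifted <- any(pc_after[, orphaned, drop = FALSE] >
                     pc_before[, orphaned, drop = FALSE] + 1e-12)
  }
  capable_remaining <- any(capable)
  reason <- if (!length(orphaned)) "removed caste performed no task"
            else if (!capable_remaining) "no capable caste"
            else if (shifted) "redistribution observed"
            else "no redistribution despite capable castes"
  structure(
    list(removed_caste = caste_to_remove,
         orphaned_tasks = orphaned,
         allocation_before = state$eps,
         allocation_after = sol_after$eps_star,
         per_caste_before = pc_before,
         per_caste_after = pc_after,
         redistribution_detected = shifted,
         capable_remaining = capable_remaining,
         falsified_flag = capable_remaining && length(orphaned) > 0 && !shifted,
         reason = reason,
         P_before = sol_before$P_star,
         P_after = sol_after$P_star,
         n_after = n_after,
         allocation = sol_after,
         state_after = state_after),
    class = "knockout_report")
}

#' @export
print.knockout_report <- function(x, ...) {
  cat(sprintf("<knockout_report> removed '%s' (orphaned: %s)\n",
              x$removed_caste,
              if (length(x$orphaned_tasks))
                paste(x$orphaned_tasks, collapse = ", ") else "none"))
  cat(sprintf("  redistribution detected: %s (%s)\n",
              x$redistribution_detected, x$reason))
  cat(sprintf("  P before %.6g -> after %.6g\n", x$P_before, x$P_after))
  invisible(x)
}
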