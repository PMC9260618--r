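#' Productivity ledger of a colony
#'
#' Tabulates the model's primitive quantities for a colony state: the
#' per-ant usefulness `u[c, j] = k_tau[j] * omega[c, j]` of an ant of caste
#' `c` performing task `j` (0 for ants not performing it), the per-ant task
#' energy `e[c, j]` (the task's configured energy rate), per-ant competence
#' `u - e`, per-task utility `U[j]`, and the colony totals: gross
#' productivity `G = sum(U) = sum over ants of competence`, subsistence
#' `E = sum of basal energies`, net productivity `P = G - E`, and
#' per-capita net productivity `p = P / n`.
#'
#' The double-accounting identity `G = sum_j U_j = sum_i c_i` holds exactly
#' by construction, and `E` is exactly linear in `n` at fixed `eps` and
#' fixed caste proportions.
#'
#' @param tasks list of [task_spec()]s.
#' @param castes list of [caste_spec()]s.
#' @param state a [colony_state()].
#' @return an object of class `productivity_report`: list with matrices
#'   `u`, `e`, `competence` (castes x tasks, per-ant), vector `U` (per
#'   task), scalars `G`, `E`, `P`, `p`, plus the assignment used. For an
#'   empty colony `p` is `NA` (per-capita productivity is undefined) and
#'   the report's `p_defined` flag is `FALSE`.
#' @export
colony_ledger <- function(tasks, castes, state) {
  stopifnot(inherits(state, "colony_state"))
  tids <- task_ids(tasks); cids <- caste_ids(castes)
  k <- stats::setNames(vapply(tasks, `[[`, numeric(1), "k_tau"), tids)
  ce <- stats::setNames(vapply(tasks, `[[`, numeric(1), "c"), tids)
  u <- matrix(0, nrow = length(cids), ncol = length(tids),
              dimnames = list(cids, tids))
  for (cs in castes) {
    shared <- intersect(names(cs$omega), tids)
    u[cs$id, shared] <- k[shared] * cs$omega[shared]
  }
  e <- matrix(rep(ce, each = length(cids)), nrow = length(cids),
              dimnames = list(cids, tids))
  comp <- u - e
  A <- state$assign
  U <- colSums(A * comp)
  G <- sum(U)
  E_basal <- stats::setNames(vapply(castes, `[[`, numeric(1), "E_basal"), cids)
  E <- sum(state$counts[cids] * E_basal)
  P <- G - E
  p_defined <- state$n > 0
  structure(
    list(u = u, e = e, competence = comp, U = U, mu = NULL,
         G = G, E = E, P = P,
         p = if (p_defined) P / state$n else NA_real_,
         p_defined = p_defined, assign = A, n = state$n,
         counts = state$counts),
    class = "productivity_report")
}

#' @export
print.productivity_report <- function(x, ...) {
  cat("<productivity_report>\n")
  cat(sprintf("  G = %.6g   E = %.6g   P = %.6g   p = %s\n",
              x$G, x$E, x$P,
              if (x$p_defined) sprintf("%.6g", x$p)
              else "undefined (empty colony)"))
  cat("  per-task utility U:\n")
  print(round(x$U, 6))
  invisible(x)
}

#' @export
as.data.frame.productivity_report <- function(x, ...) {
  A <- x$assign
  idx <- which(A >= 0, arr.ind = TRUE)  # all caste-task pairs, stable order
  out <- data.frame(
    caste = rownames(A)[idx[, 1]],
    task = colnames(A)[idx[, 2]],
    count = A[idx],
    u_per_ant = x$u[idx],
    e_per_ant = x$e[idx],
    competence_per_ant = x$competence[idx],
    contribution = A[idx] * x$competence[idx],
    stringsAsFactors = FALSE)
  out[order(out$caste, out$task), , drop = FALSE]
}

#' Reproductive usefulness of an ant
#'
#' For the reproduction task, usefulness is defined relative to the
#' foundress: the number of offspring produced by the focal ant divided by
#' the number produced by the queen. Sterile workers score 0; the queen
#' herself scores 1.
#'
#' @param offspring_focal offspring count of the focal ant, `>= 0`.
#' @param offspring_queen offspring count of the foundress queen, `> 0`.
#' @return dimensionless ratio `>= 0`.
#' @export
reproductive_usefulness <- function(offspring_focal, offspring_queen) {
  if (any(offspring_queen <= 0)) {
    stop("reproductive usefulness is undefined when the queen has no offspring",
         call. = FALSE)
  }
  if (any(offspring_focal < 0)) {
    stop("offspring counts must be non-negative", call. = FALSE)
  }
  offspring_focal / offspring_queen
}
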