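#' Define a colony task
#'
#' A task is any activity performed by an ant that benefits the colony
#' (foraging, defense, brood care, reproduction, ...). Its utility to the
#' colony is modelled by a concave utility family (see
#' [utility-families]) weighted by the task's importance constant.
#'
#' @param id task label (single string).
#' @param k_tau importance constant, dimensionless, in `(0, 1]`.
#' @param family utility family name; one of `"saturating"` (default),
#'   `"saturating_satcost"`, `"logistic"`, `"linear"`.
#' @param R work capacity of the task, energy units: the asymptotic work
#'   available as performers saturate the resource.
#' @param a saturation rate, per worker.
#' @param c task energy rate per performing ant, energy units per step.
#' @param threshold_n0 performer count past which diminishing marginal
#'   utility is asserted (only the logistic family uses a non-zero value).
#' @return an object of class `task_spec`.
#' @export
task_spec <- function(id, k_tau, family = "saturating", R = 1, a = 0.05,
                      c = 0, threshold_n0 = 0) {
  x <- structure(
    list(id = as.character(id), k_tau = as.numeric(k_tau),
         family = family, R = as.numeric(R), a = as.numeric(a),
         c = as.numeric(c), threshold_n0 = as.numeric(threshold_n0)),
    class = "task_spec")
  problems <- validate_task_spec(x)
  if (length(problems)) {
    stop("invalid task_spec '", id, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  x
}

validate_task_spec <- function(x) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(is.character(x$id) && length(x$id) == 1L && nzchar(x$id),
      "id must be a non-empty string")
  chk(is.numeric(x$k_tau) && length(x$k_tau) == 1L && !is.na(x$k_tau) &&
        x$k_tau > 0 && x$k_tau <= 1,
      sprintf("k_tau = %s outside (0, 1]", format(x$k_tau)))
  chk(is.character(x$family) && length(x$family) == 1L &&
        x$family %in% .family_names,
      sprintf("unknown family '%s'", paste(x$family, collapse = ",")))
  chk(is.numeric(x$R) && length(x$R) == 1L && !is.na(x$R) && x$R >= 0,
      "R must be >= 0")
  chk(is.numeric(x$a) && length(x$a) == 1L && !is.na(x$a) && x$a > 0,
      "a must be > 0")
  chk(is.numeric(x$c) && length(x$c) == 1L && !is.na(x$c) && x$c >= 0,
      "c must be >= 0")
  chk(is.numeric(x$threshold_n0) && length(x$threshold_n0) == 1L &&
        !is.na(x$threshold_n0) && x$threshold_n0 >= 0,
      "threshold_n0 must be >= 0")
  p
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec '%s'> family=%s k_tau=%g R=%g a=%g c=%g\n",
              x$id, x$family, x$k_tau, x$R, x$a, x$c))
  invisible(x)
}

#' Define a caste
#'
#' A caste is a morphologically and behaviourally specialised type of ant
#' performing a fixed set of tasks. `omega` measures how well an ant of
#' this caste performs each task (work done or saved per step); a task
#' absent from `omega`, or with rate 0, is not performable by the caste.
#'
#' @param id caste label.
#' @param E_basal subsistence energy per ant per step when performing no
#'   task (basal metabolic rate), energy units; `>= 0`.
#' @param omega named numeric vector of per-task work rates, all `>= 0`;
#'   names are task ids.
#' @param mass_per_ant biomass of one ant, mass units (used by the biomass
#'   proxy).
#' @return an object of class `caste_spec`.
#' @export
caste_spec <- function(id, E_basal = 0, omega = numeric(), mass_per_ant = 1) {
  omega <- unlist(omega)
  x <- structure(
    list(id = as.character(id), E_basal = as.numeric(E_basal),
         omega = stats::setNames(as.numeric(omega), names(omega)),
         performs = names(omega)[omega > 0],
         mass_per_ant = as.numeric(mass_per_ant)),
    class = "caste_spec")
  problems <- validate_caste_spec(x)
  if (length(problems)) {
    stop("invalid caste_spec '", id, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  x
}

validate_caste_spec <- function(x) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(is.character(x$id) && length(x$id) == 1L && nzchar(x$id),
      "id must be a non-empty string")
  chk(is.numeric(x$E_basal) && length(x$E_basal) == 1L &&
        !is.na(x$E_basal) && x$E_basal >= 0, "E_basal must be >= 0")
  chk(length(x$omega) == 0L ||
        (!is.null(names(x$omega)) && all(nzchar(names(x$omega)))),
      "omega must be a named vector (task ids)")
  chk(all(!is.na(x$omega)) && all(x$omega >= 0), "all omega values must be >= 0")
  chk(is.numeric(x$mass_per_ant) && length(x$mass_per_ant) == 1L &&
        !is.na(x$mass_per_ant) && x$mass_per_ant > 0,
      "mass_per_ant must be > 0")
  p
}

#' @export
print.caste_spec <- function(x, ...) {
  cat(sprintf("<caste_spec '%s'> E_basal=%g mass=%g performs: %s\n",
              x$id, x$E_basal, x$mass_per_ant,
              paste(x$performs, collapse = ", ")))
  invisible(x)
}

task_ids <- function(tasks) vapply(tasks, `[[`, character(1), "id")
caste_ids <- function(castes) vapply(castes, `[[`, character(1), "id")

# round fractional task demands to integer counts whose total matches
# round(n * sum(eps)) (largest-remainder apportionment)
largest_remainder_counts <- function(n, eps) {
  if (length(eps) == 0L) return(integer())
  raw <- n * eps
  base <- floor(raw)
  total <- round(n * sum(eps))
  short <- total - sum(base)
  if (short > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(eps))
}

# deterministic caste -> task assignment: specialists (fewest performable
# tasks) commit first; within a caste, tasks are filled in task-list order.
# Returns an integer matrix castes x tasks; unmet demand is left unfilled.
assign_castes <- function(tasks, castes, counts, task_counts) {
  tids <- task_ids(tasks); cids <- caste_ids(castes)
  A <- matrix(0L, nrow = length(cids), ncol = length(tids),
              dimnames = list(cids, tids))
  demand <- task_counts[tids]
  n_options <- vapply(castes, function(cs) sum(cs$performs %in% tids), 0L)
  for (ci in order(n_options)) {
    cs <- castes[[ci]]
    supply <- counts[[cs$id]]
    for (tid in tids[tids %in% cs$performs]) {
      if (supply <= 0) break
      take <- min(supply, demand[[tid]])
      if (take > 0) {
        A[cs$id, tid] <- A[cs$id, tid] + as.integer(take)
        supply <- supply - take
        demand[[tid]] <- demand[[tid]] - take
      }
    }
  }
  A
}

#' Colony state
#'
#' The demographic state of a mature colony: its size `n`, the ant count of
#' each caste, and the fraction `eps[j]` of the colony performing each task.
#' Because an ant performs at most one task at a time, `sum(eps) <= 1`;
#' slack corresponds to idle ants (who still consume subsistence energy).
#'
#' Integer performer counts are obtained by largest-remainder rounding of
#' `n * eps`, and a deterministic caste-to-task assignment (specialist
#' castes commit first) provides the bookkeeping used by the ledger; the
#' assignment is flagged infeasible if the castes present cannot staff the
#' requested fractions.
#'
#' @param tasks list of [task_spec()]s.
#' @param castes list of [caste_spec()]s.
#' @param n colony size, integer `>= 0`.
#' @param counts named vector of ant counts per caste (must sum to `n`);
#'   default puts all ants in the single caste.
#' @param eps named vector of task fractions in `[0, 1]` with
#'   `sum(eps) <= 1`; default 0 for all tasks.
#' @return an object of class `colony_state` with fields `n`, `counts`,
#'   `eps`, `task_counts`, `assign` (caste x task count matrix) and
#'   `feasible`.
#' @export
colony_state <- function(tasks, castes, n, counts = NULL, eps = NULL) {
  tids <- task_ids(tasks); cids <- caste_ids(castes)
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("colony size 'n' must be >= 0", call. = FALSE)
  if (is.null(counts)) {
    if (length(castes) != 1L) {
      stop("'counts' is required for a polymorphic colony", call. = FALSE)
    }
    counts <- stats::setNames(n, cids)
  }
  counts <- unlist(counts)
  if (!all(cids %in% names(counts))) {
    stop("'counts' must name every caste", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(counts[cids]), cids)
  if (any(counts < 0) || sum(counts) != n) {
    stop("caste counts must be non-negative and sum to n", call. = FALSE)
  }
  if (is.null(eps)) eps <- stats::setNames(numeric(length(tids)), tids)
  eps <- unlist(eps)
  missing_eps <- setdiff(tids, names(eps))
  if (length(missing_eps)) {
    eps <- c(eps, stats::setNames(numeric(length(missing_eps)), missing_eps))
  }
  if (!all(names(eps) %in% tids)) {
    stop("'eps' names unknown task(s): ",
         paste(setdiff(names(eps), tids), collapse = ", "), call. = FALSE)
  }
  eps <- stats::setNames(as.numeric(eps[tids]), tids)
  if (any(is.na(eps)) || any(eps < 0) || any(eps > 1)) {
    stop("all task fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(eps) > 1 + 1e-9) {
    stop("sum of task fractions exceeds 1 (an ant performs at most one task)",
         call. = FALSE)
  }
  task_counts <- largest_remainder_counts(n, eps)
  A <- assign_castes(tasks, castes, counts, task_counts)
  structure(
    list(n = n, counts = counts, eps = eps, task_counts = task_counts,
         assign = A, feasible = all(colSums(A) == task_counts)),
    class = "colony_state")
}

#' @export
print.colony_state <- function(x, ...) {
  cat(sprintf("<colony_state> n=%d, %d caste(s), sum(eps)=%.4f%s\n",
              x$n, length(x$counts), sum(x$eps),
              if (x$feasible) "" else " [assignment infeasible]"))
  print(x$assign)
  invisible(x)
}
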