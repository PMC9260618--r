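#' Tabular forms of model reports
#'
#' Every report class can be flattened to a data frame with a stable
#' column order for TSV export; [write_report()] adds a provenance header.
#'
#' @name report-tables
#' @keywords internal
NULL

#' @export
as.data.frame.allocation_result <- function(x, ...) {
  tids <- names(x$eps_star)
  data.frame(task = tids,
             eps_star = as.numeric(x$eps_star),
             mu = as.numeric(x$mu),
             U = as.numeric(x$U_star),
             active = tids %in% x$active_set,
             performable = tids %in% x$performable,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.perturbation_report <- function(x, ...) {
  tids <- names(x$eps_redistributed)
  data.frame(task = tids,
             eps_unredistributed = as.numeric(x$eps_unredistributed[tids]),
             eps_redistributed = as.numeric(x$eps_redistributed[tids]),
             M_before = as.numeric(
               ifelse(tids == x$task_i, 1,
                      x$M_before_redistribution[tids])),
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.proxy_report <- function(x, ...) {
  tids <- names(x$true_utilities)
  data.frame(task = tids,
             biomass = as.numeric(x$per_task_biomass[tids]),
             proxy_utility = as.numeric(x$proxy_utilities[tids]),
             true_utility = as.numeric(x$true_utilities[tids]),
             active = tids %in% x$active_set,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.knockout_report <- function(x, ...) {
  tids <- names(x$allocation_before)
  data.frame(task = tids,
             eps_before = as.numeric(x$allocation_before[tids]),
             eps_after = as.numeric(x$allocation_after[tids]),
             orphaned = tids %in% x$orphaned_tasks,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.invasion_summary <- function(x, ...) {
  data.frame(outcome = names(x$outcome_counts),
             count = as.integer(x$outcome_counts),
             stringsAsFactors = FALSE)
}

report_totals <- function(report) {
  if (inherits(report, "productivity_report")) {
    return(c(G = report$G, E = report$E, P = report$P,
             p = if (report$p_defined) report$p else NA_real_))
  }
  if (inherits(report, "allocation_result")) {
    return(c(P_star = report$P_star, lambda = report$lambda_common,
             sum_eps = sum(report$eps_star)))
  }
  if (inherits(report, "perturbation_report")) {
    return(c(P_original = report$P_original,
             P_redistributed = report$P_redistributed,
             P_unredistributed = report$P_unredistributed))
  }
  if (inherits(report, "invasion_summary")) {
    return(c(fixation_prob = report$fixation_prob,
             mean_theta_minus = report$mean_theta_minus,
             mean_theta_plus = report$mean_theta_plus))
  }
  NULL
}

fmt12 <- function(v) {
  if (is.double(v)) {
    out <- formatC(v, digits = 12, format = "g")
    out[is.na(v)] <- "NA"
    trimws(out)
  } else {
    as.character(v)
  }
}

#' Write a report as TSV with a provenance header
#'
#' Serialises any model report (or a plain data frame, e.g. a trajectory)
#' as a tab-separated table. A comment header carries the run record —
#' tool version, seed, subcommand, configuration hash and solver
#' tolerances; no timestamps, so identical inputs give byte-identical
#' files. Floats are written at 12 significant digits; report totals
#' (G/E/P/p and the like) are carried as additional `# total:` header
#' lines. An empty table yields a header-only file, not an error.
#'
#' @param report a report object with an `as.data.frame` method, or a
#'   data frame.
#' @param path output file path.
#' @param seed seed to record in the header (may be `NULL`).
#' @param subcommand label for the producing operation.
#' @param config object whose hash identifies the configuration (e.g. a
#'   [scenario()]); hashed with [rlang::hash()].
#' @param tolerances named numeric vector of solver tolerances to record.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path, seed = NULL, subcommand = "report",
                         config = NULL, tolerances = NULL) {
  df <- if (is.data.frame(report)) report else as.data.frame(report)
  header <- c(
    sprintf("# colonyopt %s",
            as.character(utils::packageVersion("colonyopt"))),
    sprintf("# subcommand: %s", subcommand),
    sprintf("# seed: %s", if (is.null(seed)) "none" else format(seed)),
    sprintf("# config_hash: %s",
            if (is.null(config)) "none" else rlang::hash(config)))
  if (!is.null(tolerances)) {
    header <- c(header, sprintf("# tolerance %s: %s", names(tolerances),
                                fmt12(as.numeric(tolerances))))
  }
  tot <- report_totals(report)
  if (!is.null(tot)) {
    header <- c(header, sprintf("# total %s: %s", names(tot), fmt12(tot)))
  }
  con <- file(path, open = "wb")  # binary mode: identical bytes everywhere
  on.exit(close(con))
  writeLines(header, con)
  cols <- vapply(df, function(col) paste(fmt12(col)), character(nrow(df)))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    if (is.null(dim(cols))) cols <- matrix(cols, nrow = nrow(df))
    writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read back a TSV report
#'
#' @param path file written by [write_report()].
#' @return a data frame (header comments are skipped).
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
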