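#' Scenario configuration
#'
#' A scenario bundles everything needed to run the model: the task list,
#' the caste list, the initial colony demography and (optionally) an
#' evolutionary configuration, plus metadata (name, seed, schema
#' version). Scenarios are read from and written to YAML with full
#' validation; every stochastic result in the package is reproducible
#' from (scenario, seed) alone.
#'
#' @param tasks list of [task_spec()]s.
#' @param castes list of [caste_spec()]s.
#' @param colony list with `n`, optional `counts`, optional `eps` (when
#'   `eps` is absent the allocation is left to the equilibrium solver).
#' @param evolution optional [evolution_config()].
#' @param meta list with `name`, `seed`, `schema`.
#' @return an object of class `scenario`.
#' @export
scenario <- function(tasks, castes, colony, evolution = NULL,
                     meta = list(name = "scenario", seed = 1L, schema = 1L)) {
  x <- structure(list(meta = meta, tasks = tasks, castes = castes,
                      colony = colony, evolution = evolution),
                 class = "scenario")
  errs <- validate_scenario_object(x)
  if (length(errs)) {
    stop("invalid scenario:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  x
}

validate_scenario_object <- function(x) {
  errs <- character()
  add <- function(where, msgs) {
    if (length(msgs)) errs <<- c(errs, paste0(where, ": ", msgs))
  }
  if (is.null(x$meta$seed)) add("meta.seed", "seed is mandatory")
  if (!length(x$tasks)) add("tasks", "at least one task is required")
  for (i in seq_along(x$tasks)) {
    add(sprintf("tasks[%d]", i), validate_task_spec(x$tasks[[i]]))
  }
  if (!length(x$castes)) add("castes", "at least one caste is required")
  for (i in seq_along(x$castes)) {
    add(sprintf("castes[%d]", i), validate_caste_spec(x$castes[[i]]))
  }
  tids <- tryCatch(task_ids(x$tasks), error = function(e) character())
  if (anyDuplicated(tids)) add("tasks", "duplicate task ids")
  cids <- tryCatch(caste_ids(x$castes), error = function(e) character())
  if (anyDuplicated(cids)) add("castes", "duplicate caste ids")
  for (i in seq_along(x$castes)) {
    extra <- setdiff(names(x$castes[[i]]$omega), tids)
    if (length(extra)) {
      add(sprintf("castes[%d].omega", i),
          paste0("unknown task(s): ", paste(extra, collapse = ", ")))
    }
  }
  if (is.null(x$colony$n) || !is.numeric(x$colony$n) || x$colony$n < 0) {
    add("colony.n", "colony size must be a non-negative number")
  }
  if (!is.null(x$colony$eps)) {
    eps <- unlist(x$colony$eps)
    if (any(eps < 0) || any(eps > 1)) {
      add("colony.eps", "task fractions must lie in [0, 1]")
    }
    if (sum(eps) > 1 + 1e-9) {
      add("colony.eps", "sum of task fractions exceeds 1")
    }
    extra <- setdiff(names(eps), tids)
    if (length(extra)) {
      add("colony.eps", paste0("unknown task(s): ",
                               paste(extra, collapse = ", ")))
    }
  }
  if (!is.null(x$colony$counts)) {
    cnt <- unlist(x$colony$counts)
    if (any(cnt < 0)) add("colony.counts", "counts must be non-negative")
    if (!is.null(x$colony$n) && is.numeric(x$colony$n) &&
        sum(cnt) != x$colony$n) {
      add("colony.counts", "counts must sum to colony.n")
    }
    extra <- setdiff(names(cnt), cids)
    if (length(extra)) {
      add("colony.counts", paste0("unknown caste(s): ",
                                  paste(extra, collapse = ", ")))
    }
  } else if (length(x$castes) > 1L) {
    add("colony.counts", "counts are required for a polymorphic colony")
  }
  if (!is.null(x$evolution) && !inherits(x$evolution, "evolution_config")) {
    add("evolution", "must be an evolution_config")
  }
  errs
}

.scenario_keys <- c("meta", "tasks", "castes", "colony", "evolution")
.task_keys <- c("id", "k_tau", "family", "R", "a", "c", "threshold_n0")
.caste_keys <- c("id", "E_basal", "omega", "mass_per_ant")
.colony_keys <- c("n", "counts", "eps")
.meta_keys <- c("name", "seed", "schema")
.evo_keys <- c("n", "p0", "landscape", "mutation_sigma", "fraction_sigma",
               "fitness", "replicates", "seed", "mode", "horizon",
               "init_fraction", "init_trait", "ceiling", "persist_colonies")

#' Load and validate a scenario from YAML
#'
#' Reads a scenario configuration, applies defaults, and validates it
#' fully: unknown keys are rejected and *all* violations are reported at
#' once (not just the first), each naming the offending field.
#'
#' @param path path to a YAML scenario file.
#' @return a validated [scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  # keep YAML-1.1 boolean-like scalars (notably the bare key "n") literal
  keep_literal <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  raw <- tryCatch(yaml::read_yaml(path, handlers = keep_literal),
                  error = function(e)
    stop("malformed YAML in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  scenario_from_list(numerify(raw))
}

# convert numeric-looking strings (full-precision serialized doubles) back
# to numbers, recursively; everything else is left untouched
numerify <- function(x) {
  if (is.list(x)) return(lapply(x, numerify))
  if (is.character(x) && length(x) &&
      all(grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x))) {
    return(as.numeric(x))
  }
  x
}

# serialize doubles losslessly as strings (YAML float emission truncates
# small values); integers and strings pass through
stringify_nums <- function(x) {
  if (is.list(x)) return(lapply(x, stringify_nums))
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    names(out) <- names(x)
    return(out)
  }
  x
}

#' Build a scenario from a plain list (parsed YAML/JSON)
#'
#' @param raw nested list following the scenario schema.
#' @return a validated [scenario()].
#' @export
scenario_from_list <- function(raw) {
  errs <- character()
  add <- function(where, msg) errs <<- c(errs, paste0(where, ": ", msg))
  reject_unknown <- function(x, keys, where) {
    extra <- setdiff(names(x), keys)
    if (length(extra)) {
      add(where, paste0("unknown key(s): ", paste(extra, collapse = ", ")))
    }
  }
  if (!is.list(raw)) {
    stop("invalid scenario:\n  - top level must be a mapping", call. = FALSE)
  }
  reject_unknown(raw, .scenario_keys, "scenario")
  meta <- utils::modifyList(list(name = "scenario", seed = NULL, schema = 1L),
                            if (is.list(raw$meta)) raw$meta else list())
  if (is.list(raw$meta)) reject_unknown(raw$meta, .meta_keys, "meta")
  if (is.null(meta$seed)) add("meta.seed", "seed is mandatory")

  build <- function(ctor, defaults, item, keys, where) {
    reject_unknown(item, keys, where)
    args <- utils::modifyList(defaults, item[names(item) %in% keys])
    tryCatch(do.call(ctor, args), error = function(e) {
      add(where, conditionMessage(e))
      NULL
    })
  }
  tasks <- lapply(seq_along(raw$tasks), function(i)
    build(task_spec,
          list(k_tau = 1, family = "saturating", R = 1, a = 0.05, c = 0,
               threshold_n0 = 0),
          raw$tasks[[i]], .task_keys, sprintf("tasks[%d]", i)))
  castes <- lapply(seq_along(raw$castes), function(i)
    build(caste_spec,
          list(E_basal = 0, omega = numeric(), mass_per_ant = 1),
          raw$castes[[i]], .caste_keys, sprintf("castes[%d]", i)))
  if (!length(raw$tasks)) add("tasks", "at least one task is required")
  if (!length(raw$castes)) add("castes", "at least one caste is required")
  colony <- if (is.list(raw$colony)) raw$colony else list()
  reject_unknown(colony, .colony_keys, "colony")

  evolution <- NULL
  if (!is.null(raw$evolution)) {
    ev <- raw$evolution
    reject_unknown(ev, .evo_keys, "evolution")
    if (!is.null(ev$landscape)) {
      ev$landscape <- tryCatch(
        do.call(pm_landscape, ev$landscape),
        error = function(e) { add("evolution.landscape",
                                  conditionMessage(e)); NULL })
    }
    if (!is.null(ev$fitness)) {
      ev$fitness <- tryCatch(
        do.call(fitness_map, ev$fitness),
        error = function(e) { add("evolution.fitness",
                                  conditionMessage(e)); NULL })
    }
    evolution <- tryCatch(
      do.call(evolution_config, ev[!vapply(ev, is.null, TRUE)]),
      error = function(e) { add("evolution", conditionMessage(e)); NULL })
  }
  if (length(errs)) {
    stop("invalid scenario:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  scenario(tasks = tasks, castes = castes, colony = colony,
           evolution = evolution, meta = meta)
}

#' Save a scenario to YAML
#'
#' Writes the scenario in the same schema [load_scenario()] reads, so
#' that a save/load round trip reproduces the scenario exactly.
#'
#' @param scn a [scenario()].
#' @param path output file path.
#' @export
save_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  as_plain <- function(x) lapply(x, function(v) if (is.null(v)) NULL else v)
  out <- list(
    meta = scn$meta,
    tasks = lapply(scn$tasks, function(t)
      list(id = t$id, k_tau = t$k_tau, family = t$family, R = t$R,
           a = t$a, c = t$c, threshold_n0 = t$threshold_n0)),
    castes = lapply(scn$castes, function(cs)
      list(id = cs$id, E_basal = cs$E_basal,
           omega = as.list(cs$omega), mass_per_ant = cs$mass_per_ant)),
    colony = as_plain(scn$colony))
  if (!is.null(scn$evolution)) {
    ev <- scn$evolution
    out$evolution <- list(
      n = ev$n, p0 = ev$p0,
      landscape = unclass(ev$landscape),
      mutation_sigma = ev$mutation_sigma,
      fraction_sigma = ev$fraction_sigma,
      fitness = unclass(ev$fitness),
      replicates = ev$replicates, seed = ev$seed, mode = ev$mode,
      horizon = ev$horizon, init_fraction = ev$init_fraction,
      init_trait = ev$init_trait, ceiling = ev$ceiling,
      persist_colonies = ev$persist_colonies)
  }
  yaml::write_yaml(stringify_nums(out), path)
  invisible(path)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'> %d task(s), %d caste(s), n=%s%s\n",
              x$meta$name, length(x$tasks), length(x$castes),
              format(x$colony$n),
              if (is.null(x$evolution)) "" else ", with evolution config"))
  invisible(x)
}
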