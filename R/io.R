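# Plain-text persistence: key=value config files for specifications and
# cohort configurations, long-format CSVs for draws and parameter states.

write_kv <- function(kv, path) {
  writeLines(paste0(names(kv), "=", vapply(kv, paste, "", collapse = ",")),
             path)
  invisible(path)
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  setNames(lapply(kv, function(x)
    strsplit(paste(x[-1], collapse = "="), ",", fixed = TRUE)[[1]]),
    vapply(kv, `[[`, "", 1))
}

#' Serialize model specifications and cohort configurations
#'
#' Plain-text `key=value` round trip for [hier_spec()] declarations
#' (tasks, groups and prior hyperparameters) and [cohort_config()]
#' objects (design sizes, generating means and spreads are restored from
#' defaults plus the recorded overrides).
#'
#' @param spec a [hier_spec] object.
#' @param path file path.
#' @return Writers return `path` invisibly; readers return the rebuilt
#'   object.
#' @export
write_spec_config <- function(spec, path) {
  stopifnot(inherits(spec, "hier_spec"))
  pr <- spec$priors
  kv <- list(tasks = spec$tasks, groups = spec$groups,
             z_rel = spec$fixed$z_rel, spread_sd = pr$spread_sd)
  for (p in names(pr$location))
    kv[[paste0("prior_", p)]] <- unlist(pr$location[[p]])
  write_kv(kv, path)
}

#' @rdname write_spec_config
#' @export
read_spec_config <- function(path) {
  kv <- read_kv(path)
  priors <- list(location = list(), spread_sd = as.numeric(kv$spread_sd))
  for (p in c("t", "a", "v")) {
    x <- as.numeric(kv[[paste0("prior_", p)]])
    priors$location[[p]] <- list(mean = x[1], sd = x[2], lower = x[3])
  }
  hier_spec(kv$tasks, kv$groups, priors = priors)
}

#' @rdname write_spec_config
#' @param config a [cohort_config] object.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  write_kv(list(
    groups = names(config$group_sizes),
    group_sizes = unname(config$group_sizes),
    tasks = config$tasks, trials_per_task = config$trials_per_task,
    deadline = config$deadline,
    contaminant_rate = config$contaminant_rate, seed = config$seed), path)
}

#' @rdname write_spec_config
#' @export
read_cohort_config <- function(path) {
  kv <- read_kv(path)
  cohort_config(
    group_sizes = setNames(as.numeric(kv$group_sizes), kv$groups),
    tasks = kv$tasks, trials_per_task = as.numeric(kv$trials_per_task),
    deadline = as.numeric(kv$deadline),
    contaminant_rate = as.numeric(kv$contaminant_rate),
    seed = as.integer(kv$seed))
}

#' Persist posterior draws as a long CSV
#'
#' Columnar per-chain storage: one row per (parameter, chain, iteration)
#' with the draw value and a burn-in flag.  For full desk-scale runs this
#' is millions of rows; `parameters` restricts the export (group-location
#' parameters are usually what downstream analyses need).
#'
#' @param samples a [posterior_samples] object.
#' @param path file path.
#' @param parameters parameter names to export (default: group locations
#'   and spreads).
#' @return `path`, invisibly.
#' @export
write_draws <- function(samples, path, parameters = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  parameters <- parameters %||%
    grep("^(mu|sigma)\\[", parameter_names(samples), value = TRUE)
  rows <- lapply(parameters, function(p) {
    x <- samples$draws[, p, , drop = FALSE]
    data.frame(parameter = p,
               chain = rep(seq_len(samples$n_chains),
                           each = samples$n_iterations),
               iteration = rep(seq_len(samples$n_iterations),
                               samples$n_chains),
               value = as.vector(x),
               retained = rep(seq_len(samples$n_iterations) >
                                samples$burn_in, samples$n_chains))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Snapshot a parameter state as CSV
#'
#' One row per (task, level, unit, parameter): levels are `theta`
#' (subjects), `mu` and `sigma` (groups).
#'
#' @param state a [parameter_state].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(state, path) {
  stopifnot(inherits(state, "parameter_state"))
  rows <- list()
  for (tk in names(state$tasks)) {
    st <- state$tasks[[tk]]
    for (lv in c("theta", "mu", "sigma")) {
      m <- st[[lv]]
      if (!nrow(m)) next
      for (p in colnames(m)) {
        rows[[length(rows) + 1]] <- data.frame(
          task = tk, level = lv, unit = rownames(m), param = p,
          value = m[, p], row.names = NULL)
      }
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
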