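#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis.  Two presets are
#' provided: `"paper"` (3 chains x 15,000 iterations, burn-in 5,000,
#' full-scale cohort sizes, 500 PPC replicates) matches the published
#' analysis protocol; `"desk"` (3 chains x 8,000, burn-in 3,000, 30
#' subjects per group, 200 PPC replicates) is the reduced profile used for
#' parameter-recovery studies and tests.  Explicit arguments override the
#' preset.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param tasks task labels to analyse.
#' @param group_sizes named subject counts per group (synthetic cohorts).
#' @param n_chains,n_iterations,burn_in MCMC settings.
#' @param n_rep posterior-predictive replicate count.
#' @param contaminant_rate passed to [cohort_config()].
#' @param rhat_threshold convergence criterion on R-hat.
#' @param seed master seed; stage seeds are derived from it.
#' @param trials optional observed trial table; when `NULL` a synthetic
#'   cohort is generated.
#' @param out_dir optional output directory for CSV tables and the JSON
#'   run manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("desk", "paper"),
                            tasks = c("letter", "lexical", "phonological",
                                      "semantic"),
                            group_sizes = NULL, n_chains = 3,
                            n_iterations = NULL, burn_in = NULL,
                            n_rep = NULL, contaminant_rate = 0,
                            rhat_threshold = 1.02, seed = 1,
                            trials = NULL, out_dir = NULL) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    group_sizes <- group_sizes %||% c(young = 384, high_old = 384,
                                      low_old = 1039)
    n_iterations <- n_iterations %||% 15000
    burn_in <- burn_in %||% 5000
    n_rep <- n_rep %||% 500
  } else {
    group_sizes <- group_sizes %||% c(young = 30, high_old = 30,
                                      low_old = 30)
    n_iterations <- n_iterations %||% 8000
    burn_in <- burn_in %||% 3000
    n_rep <- n_rep %||% 200
  }
  if (n_chains < 2)
    stop("at least 2 chains are required: convergence cannot be assessed ",
         "from a single chain")
  structure(list(preset = preset, tasks = tasks, group_sizes = group_sizes,
                 n_chains = n_chains, n_iterations = n_iterations,
                 burn_in = burn_in, n_rep = n_rep,
                 contaminant_rate = contaminant_rate,
                 rhat_threshold = rhat_threshold, seed = seed,
                 trials = trials, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Executes generate (or load) -> preprocess -> MAP -> MCMC -> convergence
#' diagnostics -> posterior-predictive check -> group comparison, and
#' returns the complete report bundle.  If any R-hat exceeds the threshold
#' the pipeline continues but the bundle and manifest are stamped
#' unconverged.  With `out_dir` set, all tables are written as CSV along
#' with a JSON run manifest (config snapshot, stage seeds, wall time).
#'
#' @param config a [pipeline_config].
#' @return A list of class `ddm_bundle` with elements `descriptives`,
#'   `preprocessing`, `map`, `samples`, `summary`, `convergence`, `ppc`,
#'   `comparison`, `truth` (synthetic cohorts only) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  seed <- config$seed
  stage_seeds <- list(generate = seed, fit = seed + 1L, ppc = seed + 2L)

  # stage: data
  truth <- NULL
  if (is.null(config$trials)) {
    cohort <- generate_cohort(cohort_config(
      group_sizes = config$group_sizes, tasks = config$tasks,
      contaminant_rate = config$contaminant_rate,
      seed = stage_seeds$generate))
    trials <- cohort$trials
    truth <- cohort$truth
  } else {
    trials <- config$trials
    validate_trials(trials)
  }

  # stage: preprocess
  pp <- preprocess_trials(trials)
  descriptives <- descriptive_table(pp$trials)

  # stage: fit
  spec <- hier_spec(config$tasks, intersect(.groups_all,
                                            unique(pp$trials$group)))
  map <- find_map(spec, pp$trials, seed = stage_seeds$fit)
  samples <- run_chains(spec, pp$trials, init = map,
                        n_chains = config$n_chains,
                        n_iterations = config$n_iterations,
                        burn_in = config$burn_in, seed = stage_seeds$fit)

  # stage: diagnose
  convergence <- convergence_report(samples, config$rhat_threshold)
  converged <- attr(convergence, "pass")
  posterior_summary <- summarize_traces(
    samples, grep("^mu\\[", parameter_names(samples), value = TRUE))

  # stage: ppc
  design <- ppc_design(pp$trials)
  reps <- simulate_replicates(samples, design, n_rep = config$n_rep,
                              seed = stage_seeds$ppc)
  ppc <- compare_quantiles(compute_rt_quantiles(pp$trials), reps)

  # stage: compare
  comparison <- compare_all(samples, spec)

  manifest <- list(
    preset = config$preset, tasks = config$tasks,
    group_sizes = as.list(config$group_sizes),
    n_chains = config$n_chains, n_iterations = config$n_iterations,
    burn_in = config$burn_in, n_rep = config$n_rep,
    seed = seed, stage_seeds = stage_seeds,
    n_trials_input = pp$n_input, n_trials_kept = pp$n_kept,
    converged = converged, max_rhat = max(convergence$rhat),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  bundle <- structure(
    list(descriptives = descriptives, preprocessing = pp$log, map = map,
         samples = samples, summary = posterior_summary,
         convergence = convergence, ppc = ppc, comparison = comparison,
         truth = truth, manifest = manifest),
    class = "ddm_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.ddm_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("ddm_bundle (%s preset): %s\n", m$preset,
              paste(m$tasks, collapse = ", ")))
  cat(sprintf("  trials kept: %d / %d\n", m$n_trials_kept,
              m$n_trials_input))
  cat(sprintf("  max R-hat: %.4f (%s)\n", m$max_rhat,
              if (m$converged) "converged" else "UNCONVERGED"))
  cat(sprintf("  PPC: r = %.3f, coverage = %.3f\n", x$ppc$correlation,
              x$ppc$coverage))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- if (bundle$manifest$converged) "" else "unconverged_"
  w <- function(df, name)
    write.csv(df, file.path(out_dir, paste0(stamp, name, ".csv")),
              row.names = FALSE)
  w(bundle$descriptives, "descriptives")
  w(bundle$preprocessing, "exclusion_log")
  w(bundle$summary, "posterior_summary")
  w(as.data.frame(bundle$convergence), "convergence")
  w(bundle$ppc$cells, "ppc_cells")
  w(bundle$ppc$groups, "ppc_groups")
  w(as.data.frame(bundle$comparison), "comparison")
  if (!is.null(bundle$truth)) w(bundle$truth, "ground_truth")
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Generate-fit-score recovery study
#'
#' Generates a synthetic cohort from the configured group means, fits the
#' hierarchical model at desk scale, and scores recovery of the
#' group-location parameters against the generating values.
#'
#' @param tasks task(s) to include.
#' @param n_per_group subjects per group.
#' @param n_chains,n_iterations,burn_in MCMC settings (desk preset
#'   defaults).
#' @param seed master seed.
#' @param groups group labels to include.
#' @return A list with the fitted `samples`, the `spec`, the generated
#'   cohort pieces, and `recovery`: a table of generating value, posterior
#'   mean and relative bias per (task, group, parameter).
#' @export
recovery_study <- function(tasks = "letter", n_per_group = 30,
                           n_chains = 3, n_iterations = 8000,
                           burn_in = 3000, seed = 1,
                           groups = c("young", "high_old", "low_old")) {
  sizes <- setNames(rep(n_per_group, length(groups)), groups)
  cohort <- generate_cohort(cohort_config(group_sizes = sizes,
                                          tasks = tasks, seed = seed))
  pp <- preprocess_trials(cohort$trials)
  spec <- hier_spec(tasks, groups)
  samples <- run_chains(spec, pp$trials, n_chains = n_chains,
                        n_iterations = n_iterations, burn_in = burn_in,
                        seed = seed + 1L)
  gp <- cohort$config$group_params
  rows <- list()
  for (i in seq_len(nrow(gp))) {
    for (p in c("t", "a", "v")) {
      post <- mean(group_location_draws(samples, gp$task[i], gp$group[i],
                                        p))
      gen <- gp[[p]][i]
      rows[[length(rows) + 1]] <- data.frame(
        task = gp$task[i], group = gp$group[i], param = p,
        generating = gen, posterior_mean = post,
        rel_bias = (post - gen) / abs(gen))
    }
  }
  list(samples = samples, spec = spec, trials = pp$trials,
       truth = cohort$truth, recovery = do.call(rbind, rows))
}
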