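#' Default group-level diffusion parameters
#'
#' Group-level posterior mean estimates of non-decision time (s), boundary
#' separation and drift rate for the three age groups (young,
#' high-performing older, low-performing older) in the four reading tasks,
#' as published for the large reading-aging cohort the synthetic generator
#' emulates.  These serve as the generating group means of synthetic
#' cohorts.
#'
#' @return Data frame with columns `task`, `group`, `t`, `a`, `v`.
#' @export
group_param_defaults <- function() {
  g <- rep(c("young", "high_old", "low_old"), times = 4)
  tk <- rep(c("letter", "lexical", "phonological", "semantic"), each = 3)
  data.frame(
    task = tk, group = g,
    t = c(0.376, 0.453, 0.459,
          0.426, 0.484, 0.506,
          0.537, 0.620, 0.641,
          0.430, 0.487, 0.505),
    a = c(1.62, 1.92, 1.99,
          1.59, 2.00, 1.97,
          2.08, 2.14, 2.17,
          1.59, 1.90, 1.88),
    v = c(3.58, 3.18, 3.04,
          2.52, 2.80, 2.42,
          1.29, 1.17, 1.10,
          2.84, 2.88, 2.61))
}

#' Configuration of a synthetic reading cohort
#'
#' Describes the study design the generator emulates: three age groups
#' (full-scale sizes 384 young, 384 high-performing older, 1039
#' low-performing older), four two-choice reading tasks with 80 trials
#' each (40 targets, 40 non-targets), a 3 s response deadline, and
#' group-level mean diffusion parameters defaulting to
#' [group_param_defaults()].  Individual subjects draw their `(t, a, v)`
#' per task from truncated normal distributions around the group means;
#' the between-subject spread defaults to 10% of the group mean (a
#' synthetic-only assumption: published group-level estimates do not pin
#' down between-subject heterogeneity).  Optionally a fraction of trials
#' is replaced by uniform-RT guesses to emulate contaminants.
#'
#' @param group_sizes named counts per group.
#' @param tasks subset of the four task labels.
#' @param trials_per_task trials per subject and task (split half target,
#'   half non-target).
#' @param group_params data frame like [group_param_defaults()].
#' @param between_subject_sd either `NULL` (10% of each group mean), a
#'   named numeric of relative sds per parameter, or a data frame with
#'   columns `task`, `group`, `t`, `a`, `v` of absolute sds.
#' @param deadline response deadline in seconds.
#' @param contaminant_rate fraction of trials replaced by guesses, in
#'   `[0, 0.2]`.
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(young = 384, high_old = 384,
                                          low_old = 1039),
                          tasks = c("letter", "lexical", "phonological",
                                    "semantic"),
                          trials_per_task = 80,
                          group_params = group_param_defaults(),
                          between_subject_sd = NULL,
                          deadline = 3, contaminant_rate = 0, seed = 1) {
  stopifnot(all(group_sizes >= 1), trials_per_task >= 2,
            trials_per_task %% 2 == 0, deadline > 0)
  if (is.null(names(group_sizes)))
    stop("'group_sizes' must be named by group")
  if (contaminant_rate < 0 || contaminant_rate > 0.2)
    stop("'contaminant_rate' must lie in [0, 0.2]")
  tasks <- match.arg(tasks, c("letter", "lexical", "phonological",
                              "semantic"), several.ok = TRUE)
  gp <- group_params[group_params$task %in% tasks &
                       group_params$group %in% names(group_sizes), ]
  if (is.null(between_subject_sd)) between_subject_sd <- c(t = 0.1, a = 0.1,
                                                           v = 0.1)
  if (!is.data.frame(between_subject_sd)) {
    bs <- gp
    for (p in c("t", "a", "v"))
      bs[[p]] <- abs(gp[[p]]) * between_subject_sd[[p]]
    between_subject_sd <- bs
  }
  structure(list(group_sizes = group_sizes, tasks = tasks,
                 trials_per_task = trials_per_task, group_params = gp,
                 between_subject_sd = between_subject_sd,
                 deadline = deadline, contaminant_rate = contaminant_rate,
                 seed = seed),
            class = "cohort_config")
}

# draw from a normal truncated below; redraw rather than clip
rtnorm1 <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  for (k in 1:100) {
    bad <- out < lower
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  if (any(out < lower))
    stop("truncated-normal redraws failed; check generator parameters")
  out
}

#' Generate a synthetic cohort
#'
#' Draws each subject's per-task diffusion parameters from truncated
#' normals around the configured group means, simulates every trial with
#' the first-passage sampler (unbiased start, fixed deadline), optionally
#' injects contaminant guess trials (uniform RT on `[0.2 s, deadline]`,
#' random correctness), and returns both the trial table and the
#' ground-truth parameter table for recovery scoring.  Deadline hits are
#' emitted as non-responses (`NA` RT) and dropped later by preprocessing.
#'
#' @param config a [cohort_config].
#' @return A list with `trials` (trial table, see [validate_trials()]),
#'   `truth` (per subject x task generating parameters) and `config`.
#' @examples
#' cfg <- cohort_config(group_sizes = c(young = 3, high_old = 3),
#'                      tasks = "letter", seed = 7)
#' cohort <- generate_cohort(cfg)
#' head(cohort$trials)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed %% .Machine$integer.max)
  lower <- c(t = 0, a = 1e-3, v = -Inf)

  trial_rows <- list(); truth_rows <- list()
  for (g in names(config$group_sizes)) {
    n_g <- config$group_sizes[[g]]
    ids <- sprintf("%s_%03d", g, seq_len(n_g))
    for (tk in config$tasks) {
      gp <- config$group_params
      bs <- config$between_subject_sd
      sel <- gp$task == tk & gp$group == g
      if (!any(sel))
        stop("no group parameters configured for ", g, " in task ", tk)
      th <- vapply(c("t", "a", "v"), function(p)
        rtnorm1(n_g, gp[[p]][sel], bs[[p]][bs$task == tk & bs$group == g],
                lower[[p]]), numeric(n_g))
      th <- matrix(th, nrow = n_g)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject_id = ids, group = g, task = tk,
        t = th[, 1], a = th[, 2], v = th[, 3])
      npt <- config$trials_per_task
      stim <- sample(rep(c("target", "nontarget"), each = npt / 2))
      for (s in seq_len(n_g)) {
        p <- ddm_params(t_nd = th[s, 1], a = th[s, 2], v = th[s, 3])
        sim <- simulate_trials(p, npt, deadline = config$deadline)
        correct <- ifelse(sim$responded, sim$boundary == "upper", NA)
        rt_ms <- sim$rt * 1000
        if (config$contaminant_rate > 0) {
          contam <- runif(npt) < config$contaminant_rate
          if (any(contam)) {
            rt_ms[contam] <- runif(sum(contam), 200, config$deadline * 1000)
            correct[contam] <- runif(sum(contam)) < 0.5
          }
        }
        trial_rows[[length(trial_rows) + 1]] <- data.frame(
          subject_id = ids[s], group = g, task = tk,
          stimulus_type = sample(stim), correct = correct, rt_ms = rt_ms)
      }
    }
  }
  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  validate_trials(trials)
  list(trials = trials, truth = truth, config = config)
}

#' Group x task descriptive table
#'
#' Mean RT (with trial-level SD) of correct responses and percentage
#' accuracy (with trial-level SD) for every task x group cell, the
#' conventional descriptive summary of a multi-task two-choice reading
#' study.  Missing cells are reported as `NA`, not zero.
#'
#' @param trials a (preprocessed) trial table.
#' @return Data frame with one row per task x group and columns
#'   `mean_rt_ms`, `sd_rt_ms`, `accuracy_pct`, `sd_accuracy_pct`, `n_trials`.
#' @export
descriptive_table <- function(trials) {
  validate_trials(trials)
  tasks <- unique(trials$task); groups <- unique(trials$group)
  rows <- list()
  for (tk in tasks) {
    for (g in groups) {
      sel <- trials$task == tk & trials$group == g & !is.na(trials$rt_ms)
      n <- sum(sel)
      if (n == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          task = tk, group = g, mean_rt_ms = NA_real_, sd_rt_ms = NA_real_,
          accuracy_pct = NA_real_, sd_accuracy_pct = NA_real_, n_trials = 0)
        next
      }
      corr <- trials$correct[sel]
      rt_c <- trials$rt_ms[sel][corr]
      rows[[length(rows) + 1]] <- data.frame(
        task = tk, group = g,
        mean_rt_ms = mean(rt_c), sd_rt_ms = sd(rt_c),
        accuracy_pct = 100 * mean(corr),
        sd_accuracy_pct = 100 * sd(corr), n_trials = n)
    }
  }
  do.call(rbind, rows)
}
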