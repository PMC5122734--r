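#' Per-subject RT quantiles of correct responses
#'
#' @param trials a trial table (see [validate_trials()]).
#' @param probs quantile probabilities (default the five conventional RT
#'   quantiles 0.1, 0.3, 0.5, 0.7, 0.9).
#' @return Data frame with columns `subject_id`, `group`, `task`, `prob`,
#'   `rt_ms`; subject x task cells without correct responses are flagged
#'   with `NA` quantiles.
#' @export
compute_rt_quantiles <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  validate_trials(trials)
  cells <- unique(trials[, c("subject_id", "group", "task")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$subject_id == cells$subject_id[i] &
      trials$task == cells$task[i] & !is.na(trials$rt_ms) &
      !is.na(trials$correct) & trials$correct
    q <- if (any(sel)) quantile(trials$rt_ms[sel], probs, names = FALSE)
         else rep(NA_real_, length(probs))
    data.frame(subject_id = cells$subject_id[i], group = cells$group[i],
               task = cells$task[i], prob = probs, rt_ms = q)
  })
  do.call(rbind, rows)
}

#' Simulate posterior-predictive replicate datasets
#'
#' For each replicate and each subject, draws one posterior sample
#' (uniformly over the retained draws, independently per subject) of that
#' subject's diffusion parameters and simulates the subject's full trial
#' set.  Only replicate-level summaries (correct-response RT quantiles and
#' accuracy per subject x task) are kept.
#'
#' @param samples a [posterior_samples] object from [run_chains()].
#' @param design data frame with one row per subject x task and columns
#'   `subject_id`, `group`, `task`, `n_trials`; use [ppc_design()] to
#'   derive it from the fitted trials.
#' @param n_rep number of replicate datasets (the conventional check uses
#'   500).
#' @param seed integer seed.
#' @param deadline response deadline in seconds applied to simulated
#'   trials.
#' @param probs quantile probabilities.
#' @param dt time-grid resolution (seconds) for the trial simulator; the
#'   default is coarser than the simulator's own because replicate
#'   quantiles average over hundreds of datasets.
#' @return An object of class `ppc_replicates` holding arrays
#'   `quantiles[rep, cell, prob]` (ms) and `accuracy[rep, cell]`, with the
#'   design as attribute.
#' @export
simulate_replicates <- function(samples, design, n_rep = 500, seed = 1,
                                deadline = 3,
                                probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                dt = 2e-3) {
  stopifnot(inherits(samples, "posterior_samples"), n_rep >= 1)
  need <- c("subject_id", "group", "task", "n_trials")
  if (!all(need %in% names(design)))
    stop("'design' needs columns ", paste(need, collapse = ", "))
  n_ret <- samples$n_iterations - samples$burn_in
  if (n_ret < 1) stop("no retained draws: remove burn-in before PPC")
  set.seed(seed %% .Machine$integer.max)

  pars <- parameter_names(samples)
  ncell <- nrow(design)
  qs <- array(NA_real_, c(n_rep, ncell, length(probs)))
  acc <- matrix(NA_real_, n_rep, ncell)
  # pre-extract the three theta trace matrices per cell
  theta <- lapply(seq_len(ncell), function(i) {
    nm <- sprintf("theta[%s,%s,%s]", design$task[i], design$subject_id[i],
                  c("t", "a", "v"))
    if (!all(nm %in% pars))
      stop("no posterior draws for subject ", design$subject_id[i],
           " in task ", design$task[i])
    lapply(nm, function(p) retained_draws(samples, p))
  })
  for (r in seq_len(n_rep)) {
    for (i in seq_len(ncell)) {
      it <- sample.int(n_ret, 1); ch <- sample.int(samples$n_chains, 1)
      p <- ddm_params(t_nd = theta[[i]][[1]][it, ch],
                      a = theta[[i]][[2]][it, ch],
                      v = theta[[i]][[3]][it, ch])
      sim <- simulate_trials(p, design$n_trials[i], deadline = deadline,
                             dt = dt)
      okc <- sim$responded & sim$boundary == "upper"
      acc[r, i] <- mean(sim$boundary[sim$responded] == "upper")
      qs[r, i, ] <- if (any(okc))
        quantile(sim$rt[okc] * 1000, probs, names = FALSE)
      else NA_real_
    }
  }
  structure(list(quantiles = qs, accuracy = acc, probs = probs,
                 design = design, n_rep = n_rep),
            class = "ppc_replicates")
}

#' Derive the PPC design from fitted trials
#'
#' @param trials the trial table the model was fitted to.
#' @return Design data frame for [simulate_replicates()].
#' @export
ppc_design <- function(trials) {
  validate_trials(trials)
  counts <- aggregate(list(n_trials = trials$rt_ms),
                      by = trials[, c("subject_id", "group", "task")],
                      FUN = length)
  counts[order(counts$task, counts$subject_id), , drop = FALSE]
}

#' Posterior-predictive quantile comparison
#'
#' Compares observed correct-response RT quantiles (per subject x task)
#' with the replicate distribution: the report holds the replicate mean and
#' equal-tailed 95% band per quantile, the Pearson correlation between
#' observed and replicate-mean quantiles pooled across all (subject, task,
#' quantile) cells in scope, the fraction of observed quantiles inside the
#' 95% band, and group-averaged quantile panels.  Cells without correct
#' responses are flagged and excluded from the correlation.
#'
#' @param observed_q observed quantiles from [compute_rt_quantiles()], on
#'   the same quantile grid as the replicates.
#' @param replicates a `ppc_replicates` object.
#' @return An object of class `ppc_report` with elements `cells` (per-cell
#'   table), `groups` (group-averaged panel table), `correlation`,
#'   `coverage`, `n_rep` and `mean_accuracy`.
#' @export
compare_quantiles <- function(observed_q, replicates) {
  stopifnot(inherits(replicates, "ppc_replicates"))
  des <- replicates$design
  probs <- replicates$probs
  rows <- list()
  for (i in seq_len(nrow(des))) {
    sim <- replicates$quantiles[, i, , drop = FALSE]
    for (j in seq_along(probs)) {
      x <- sim[, 1, j]
      obs <- observed_q$rt_ms[observed_q$subject_id == des$subject_id[i] &
                                observed_q$task == des$task[i] &
                                observed_q$prob == probs[j]]
      obs <- if (length(obs)) obs[1] else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = des$subject_id[i], group = des$group[i],
        task = des$task[i], prob = probs[j], observed = obs,
        sim_mean = mean(x, na.rm = TRUE),
        sim_lower = quantile(x, 0.025, na.rm = TRUE, names = FALSE),
        sim_upper = quantile(x, 0.975, na.rm = TRUE, names = FALSE))
    }
  }
  cells <- do.call(rbind, rows)
  ok <- complete.cases(cells[, c("observed", "sim_mean")])
  correlation <- if (sum(ok) > 2)
    cor(cells$observed[ok], cells$sim_mean[ok]) else NA_real_
  inside <- cells$observed >= cells$sim_lower &
    cells$observed <= cells$sim_upper
  coverage <- mean(inside[ok])
  groups <- aggregate(cbind(observed, sim_mean, sim_lower, sim_upper) ~
                        group + task + prob, data = cells[ok, ], FUN = mean)
  structure(list(cells = cells, groups = groups,
                 correlation = correlation, coverage = coverage,
                 n_rep = replicates$n_rep,
                 mean_accuracy = colMeans(replicates$accuracy, na.rm = TRUE),
                 scope = "pooled within task set, per-subject quantiles"),
            class = "ppc_report")
}

#' @export
print.ppc_report <- function(x, ...) {
  cat(sprintf(
    "Posterior-predictive check (%d replicates)\n  r(observed, simulated mean quantiles) = %.3f\n  coverage of 95%% band = %.3f\n",
    x$n_rep, x$correlation, x$coverage))
  invisible(x)
}

#' Observed-vs-simulated quantile plot
#'
#' Group-averaged observed quantile points over the simulated 95% bands,
#' one panel per task.
#'
#' @param report a `ppc_report`.
#' @export
plot_ppc <- function(report) {
  g <- report$groups
  tasks <- unique(g$task)
  old <- graphics::par(mfrow = c(1, length(tasks)))
  on.exit(graphics::par(old))
  for (tk in tasks) {
    gg <- g[g$task == tk, ]
    ord <- order(gg$group, gg$prob)
    gg <- gg[ord, ]
    xx <- seq_len(nrow(gg))
    graphics::plot(xx, gg$sim_mean, ylim = range(gg[, 4:7]), pch = 3,
                   xlab = "group x quantile", ylab = "RT (ms)", main = tk)
    graphics::arrows(xx, gg$sim_lower, xx, gg$sim_upper, angle = 90,
                     code = 3, length = 0.02, col = "grey60")
    graphics::points(xx, gg$observed, pch = 19, col = "firebrick")
  }
  invisible(NULL)
}
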