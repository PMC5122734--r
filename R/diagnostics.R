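#' Gelman-Rubin convergence statistic
#'
#' Classic (non-split, non-rank-normalised) potential scale reduction
#' factor computed from retained draws: with `m` chains of length `n`,
#' within-chain variance `W` (mean of the chain variances) and
#' between-chain variance `B` (`n` times the variance of the chain means),
#' the statistic is `sqrt((((n - 1) / n) * W + B / n) / W)`.  Values near 1
#' indicate that the chains have mixed; the conventional criterion used in
#' hierarchical diffusion modelling flags values above 1.02.
#'
#' @param samples a [posterior_samples] object with at least two chains.
#' @param parameter parameter name (see [parameter_names()]).
#' @return The scalar R-hat for that parameter.
#' @export
gelman_rubin <- function(samples, parameter) {
  x <- retained_draws(samples, parameter)
  if (!is.matrix(x) || ncol(x) < 2)
    stop("gelman_rubin needs at least 2 chains")
  n <- nrow(x)
  if (n < 10) stop("gelman_rubin needs at least 10 retained draws per chain")
  W <- mean(apply(x, 2, var))
  if (!is.finite(W) || W <= 0)
    stop("diagnostic error: zero within-chain variance (degenerate chains)")
  B <- n * var(colMeans(x))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence report across all parameters
#'
#' @param samples a [posterior_samples] object.
#' @param threshold pass criterion on R-hat (default 1.02).
#' @return An object of class `convergence_report`: data frame of per
#'   parameter R-hat and pass flag, with attributes `pass` (overall) and
#'   `threshold`.
#' @export
convergence_report <- function(samples, threshold = 1.02) {
  pars <- parameter_names(samples)
  rhat <- vapply(pars, function(p) gelman_rubin(samples, p), numeric(1))
  out <- data.frame(parameter = pars, rhat = rhat,
                    pass = rhat <= threshold, row.names = NULL)
  structure(out, threshold = threshold, pass = all(out$pass),
            class = c("convergence_report", "data.frame"))
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence report: %d parameters, R-hat threshold %.3f\n",
              nrow(x), attr(x, "threshold")))
  cat(sprintf("  max R-hat = %.4f; overall %s\n", max(x$rhat),
              if (attr(x, "pass")) "PASS" else "FAIL"))
  if (!attr(x, "pass")) {
    bad <- x[!x$pass, ]
    cat("  failing parameters:\n")
    print(utils::head(bad[order(-bad$rhat), ], 10))
  }
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, standard deviation and equal-tailed central 95% credibility
#' interval of the retained draws of every parameter, plus a formatted
#' `estimate` column of the form `"0.376 [0.371; 0.381]"`.
#'
#' @param samples a [posterior_samples] object.
#' @param parameters optional subset of parameter names.
#' @param digits significant digits for the formatted column.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`, `estimate`.
#' @export
summarize_traces <- function(samples, parameters = NULL, digits = 3) {
  pars <- parameters %||% parameter_names(samples)
  rows <- lapply(pars, function(p) {
    x <- as.vector(retained_draws(samples, p))
    q <- unname(quantile(x, c(0.025, 0.975), names = FALSE, type = 7))
    data.frame(parameter = p, mean = mean(x), sd = sd(x),
               lower = q[1], upper = q[2],
               estimate = format_estimate(mean(x), q[1], q[2], digits))
  })
  do.call(rbind, rows)
}

format_estimate <- function(mean, lower, upper, digits = 3) {
  f <- function(x) formatC(signif(x, digits), format = "fg", flag = "#",
                           digits = digits)
  trim <- function(s) sub("\\.$", "", sub("0+$", "", s))
  sprintf("%s [%s; %s]", trim(f(mean)), trim(f(lower)), trim(f(upper)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trace plot of a parameter
#'
#' @param samples a [posterior_samples] object.
#' @param parameter parameter name.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_trace <- function(samples, parameter, ...) {
  x <- retained_draws(samples, parameter)
  graphics::matplot(x, type = "l", lty = 1, xlab = "retained iteration",
                    ylab = parameter, ...)
  invisible(NULL)
}
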