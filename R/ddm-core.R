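#' Drift-diffusion process parameters
#'
#' Bundles the four quantities governing a single subject's decision process
#' in one task: non-decision time `t_nd` (seconds), boundary separation `a`
#' (evidence units), drift rate `v` (evidence units per second) and relative
#' starting point `z_rel` (fraction of `a`).  The diffusion scaling constant
#' is fixed at `s = 1`; on that scale typical fitted values for speeded
#' reading tasks are `a` around 1.6--2.2, `v` around 1.1--3.6 and `t_nd`
#' around 0.38--0.64 s.  Under accuracy coding the upper boundary is the
#' correct response.
#'
#' @param t_nd non-decision time in seconds, `>= 0`.
#' @param a boundary separation, `> 0`.
#' @param v drift rate (may be negative).
#' @param z_rel relative starting point in `(0, 1)`; `0.5` means no response
#'   bias and is the only value used in the hierarchical analyses here.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(t_nd = 0.376, a = 1.62, v = 3.58)
#' prob_upper(p)
#' @export
ddm_params <- function(t_nd, a, v, z_rel = 0.5) {
  stopifnot(length(t_nd) == 1, length(a) == 1, length(v) == 1,
            length(z_rel) == 1)
  if (!is.finite(t_nd) || t_nd < 0)
    stop("invalid ddm parameters: t_nd must be finite and >= 0")
  if (!is.finite(a) || a <= 0)
    stop("invalid ddm parameters: a must be finite and > 0")
  if (!is.finite(v))
    stop("invalid ddm parameters: v must be finite")
  if (!is.finite(z_rel) || z_rel <= 0 || z_rel >= 1)
    stop("invalid ddm parameters: z_rel must lie strictly in (0, 1)")
  structure(list(t_nd = t_nd, a = a, v = v, z_rel = z_rel, s = 1),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "ddm_params: t_nd = %.4g s, a = %.4g, v = %.4g, z_rel = %.3g (s = 1)\n",
    x$t_nd, x$a, x$v, x$z_rel))
  invisible(x)
}

check_ddm_params <- function(params) {
  if (!inherits(params, "ddm_params"))
    stop("'params' must be a ddm_params object")
  params
}

#' Log Wiener first-passage-time density
#'
#' Log of the defective first-passage-time density of a Wiener process with
#' drift `v`, absorbing boundaries at 0 and `a`, start `z_rel * a` and unit
#' diffusion coefficient, evaluated at decision time `rt - t_nd` for the
#' stated boundary.  The density is computed by switching between the
#' small-time and large-time series expansions, truncated so the absolute
#' density error is below `tol`.  Responses at or before the non-decision
#' time are impossible and get log-density `-Inf`.
#'
#' @param rt response times in seconds (full RT, including non-decision
#'   time); vectorised.
#' @param boundary `"upper"` or `"lower"` (recycled against `rt`); under
#'   accuracy coding `"upper"` is the correct response.
#' @param params a [ddm_params] object.
#' @param tol absolute truncation error allowed in the density, `> 0`.
#' @return Numeric vector of log densities.
#' @examples
#' p <- ddm_params(t_nd = 0.376, a = 1.62, v = 3.58)
#' wfpt_log_density(c(0.5, 0.7), "upper", p)
#' @export
wfpt_log_density <- function(rt, boundary, params, tol = 1e-7) {
  check_ddm_params(params)
  if (!is.numeric(tol) || length(tol) != 1 || !is.finite(tol) || tol <= 0)
    stop("'tol' must be a single positive number")
  boundary <- match.arg(boundary, c("upper", "lower"), several.ok = TRUE)
  upper <- rep_len(boundary == "upper", length(rt))
  wfpt_log_density_cpp(as.numeric(rt), upper, params$t_nd, params$a,
                       params$v, params$z_rel, tol)
}

#' Probability of absorption at the upper (correct) boundary
#'
#' Closed-form absorption probability of the diffusion process at the upper
#' boundary.  For an unbiased start (`z_rel = 0.5`) this reduces to
#' `1 / (1 + exp(-a * v))`; the limit at `v = 0` is `z_rel`.
#'
#' @inheritParams wfpt_log_density
#' @return A single probability.
#' @export
prob_upper <- function(params) {
  check_ddm_params(params)
  a <- params$a; v <- params$v; z <- params$z_rel * a
  if (abs(v) < 1e-12) return(params$z_rel)
  # P(hit a before 0) = (1 - exp(-2 v z)) / (1 - exp(-2 v a)), stable form
  expm1(-2 * v * z) / expm1(-2 * v * a)
}

#' Mean decision time of the unbiased diffusion process
#'
#' Closed-form mean first-passage time for `z_rel = 0.5`:
#' `(a / (2 v)) * tanh(a * v / 2)` for nonzero drift, with analytic limit
#' `a^2 / 4` at `v = 0` (unit diffusion coefficient).  Adding `t_nd` gives
#' the expected mean response time; for the unbiased process the mean
#' decision time conditional on either boundary equals the unconditional
#' mean.
#'
#' @inheritParams wfpt_log_density
#' @return Mean decision time in seconds (excluding non-decision time).
#' @export
mean_decision_time <- function(params) {
  check_ddm_params(params)
  if (abs(params$z_rel - 0.5) > 1e-12)
    stop("mean_decision_time supports only the unbiased case z_rel = 0.5")
  a <- params$a; v <- params$v
  if (abs(v) < 1e-9) return(a^2 / 4)
  (a / (2 * v)) * tanh(a * v / 2)
}

# Defective densities of both boundaries on a decision-time grid, with
# trapezoid cumulative masses; used for inverse-CDF trial sampling.
wfpt_grid <- function(params, t_max, dt = 5e-4, tol = 1e-9) {
  tt <- seq(dt, t_max, by = dt)
  rt <- tt + params$t_nd
  fu <- exp(wfpt_log_density_cpp(rt, rep(TRUE, length(rt)), params$t_nd,
                                 params$a, params$v, params$z_rel, tol))
  fl <- exp(wfpt_log_density_cpp(rt, rep(FALSE, length(rt)), params$t_nd,
                                 params$a, params$v, params$z_rel, tol))
  cum <- function(f) {
    f <- c(0, f)  # density is 0 at decision time 0
    c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dt))
  }
  list(td = c(0, tt), Fu = cum(fu), Fl = cum(fl))
}

#' Simulate diffusion-model trials
#'
#' Draws independent two-choice trials from the first-passage distribution
#' of the diffusion process by inverting the analytic defective
#' first-passage CDFs of both boundaries on a fine decision-time grid (joint
#' sampling of boundary and decision time, exact up to grid interpolation).
#' Trials whose response time would exceed `deadline` are flagged as
#' non-responses and carry no boundary or RT.
#'
#' @inheritParams wfpt_log_density
#' @param n number of trials, `>= 1`.
#' @param deadline response deadline in seconds (full RT scale), or `NULL`
#'   for no deadline.
#' @param seed optional integer seed for reproducibility.
#' @param dt grid resolution in seconds for CDF inversion.
#' @return A data frame with columns `boundary` (factor `upper`/`lower`,
#'   `NA` for non-responses), `rt` (seconds, `NA` for non-responses) and
#'   `responded` (logical).
#' @examples
#' p <- ddm_params(t_nd = 0.376, a = 1.62, v = 3.58)
#' head(simulate_trials(p, 5, deadline = 3, seed = 1))
#' @export
simulate_trials <- function(params, n, deadline = 3, seed = NULL,
                            dt = 5e-4) {
  check_ddm_params(params)
  stopifnot(n >= 1)
  if (!is.null(deadline) && deadline <= params$t_nd)
    stop("'deadline' must exceed the non-decision time")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(deadline)) {
    # expand the grid horizon until essentially all mass is captured
    t_max <- max(1, 8 * mean_decision_time_safe(params))
    repeat {
      g <- wfpt_grid(params, t_max, dt)
      mass <- g$Fu[length(g$Fu)] + g$Fl[length(g$Fl)]
      if (mass > 1 - 1e-9 || t_max > 400) break
      t_max <- t_max * 2
    }
  } else {
    g <- wfpt_grid(params, deadline - params$t_nd, dt)
  }

  nu <- length(g$Fu)
  pu <- g$Fu[nu]; pl <- g$Fl[nu]
  u <- runif(n)
  boundary <- factor(rep(NA_character_, n), levels = c("upper", "lower"))
  td <- rep(NA_real_, n)
  is_u <- u <= pu
  is_l <- !is_u & u <= pu + pl
  if (any(is_u))
    td[is_u] <- approx(g$Fu, g$td, xout = u[is_u], ties = "ordered")$y
  if (any(is_l))
    td[is_l] <- approx(g$Fl, g$td, xout = u[is_l] - pu, ties = "ordered")$y
  boundary[is_u] <- "upper"
  boundary[is_l] <- "lower"
  responded <- is_u | is_l
  data.frame(boundary = boundary,
             rt = ifelse(responded, td + params$t_nd, NA_real_),
             responded = responded)
}

# mean decision time usable for any z_rel (horizon heuristic only)
mean_decision_time_safe <- function(params) {
  if (abs(params$z_rel - 0.5) <= 1e-12) return(mean_decision_time(params))
  params$a^2 / 2
}
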