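# Parameter grid spanning the fitted ranges of the three age groups across
# the four reading tasks (plus a negative-drift case)
param_grid <- list(
  ddm_params(0.376, 1.62, 3.58),
  ddm_params(0.537, 2.08, 1.29),
  ddm_params(0.641, 2.17, 1.10),
  ddm_params(0.426, 1.59, -2.52)
)

quad_mass <- function(p, boundary) {
  integrate(Vectorize(function(rt) exp(wfpt_log_density(rt, boundary, p))),
            p$t_nd, Inf, rel.tol = 1e-9)$value
}

test_that("parameter domains are enforced", {
  expect_error(ddm_params(-0.1, 1.5, 2), "t_nd")
  expect_error(ddm_params(0.3, 0, 2), "a must")
  expect_error(ddm_params(0.3, 1.5, Inf), "v must")
  expect_error(ddm_params(0.3, 1.5, 2, z_rel = 1), "z_rel")
  expect_error(wfpt_log_density(0.5, "upper", ddm_params(0.3, 1.5, 2),
                                tol = 0), "tol")
})

test_that("density is zero at or before the non-decision time", {
  p <- ddm_params(0.376, 1.62, 3.58)
  expect_identical(wfpt_log_density(0.3, "upper", p), -Inf)
  expect_identical(wfpt_log_density(0.3, "lower", p), -Inf)
  expect_identical(wfpt_log_density(p$t_nd, "upper", p), -Inf)
  expect_true(is.finite(wfpt_log_density(p$t_nd + 0.05, "upper", p)))
})

test_that("densities are finite-or-zero and non-negative over an rt lattice", {
  rts <- c(1e-6, 0.05, 0.2, 0.5, 1, 2, 3, 10)
  for (p in param_grid) {
    for (b in c("upper", "lower")) {
      ld <- wfpt_log_density(rts, b, p)
      expect_false(any(is.nan(ld)))
      expect_true(all(ld <= 700))          # finite density after exp()
    }
  }
})

test_that("reflection symmetry holds for an unbiased start", {
  rts <- seq(0.05, 3, by = 0.11)
  for (av in list(c(1.62, 3.58), c(2.08, 1.29), c(1.8, 0))) {
    pp <- ddm_params(0, av[1], av[2])
    pm <- ddm_params(0, av[1], -av[2])
    expect_equal(wfpt_log_density(rts, "upper", pp),
                 wfpt_log_density(rts, "lower", pm), tolerance = 1e-12)
  }
})

test_that("upper plus lower density integrates to one", {
  for (p in param_grid) {
    expect_equal(quad_mass(p, "upper") + quad_mass(p, "lower"), 1,
                 tolerance = 1e-4)
  }
})

test_that("quadrature of the defective density matches prob_upper", {
  p1 <- ddm_params(0.376, 1.62, 3.58)
  expect_equal(quad_mass(p1, "upper"), prob_upper(p1), tolerance = 1e-6)
  expect_equal(prob_upper(p1), 0.997, tolerance = 1e-3)
  p2 <- ddm_params(0.537, 2.08, 1.29)
  expect_equal(quad_mass(p2, "upper"), prob_upper(p2), tolerance = 1e-6)
  expect_equal(prob_upper(p2), 0.936, tolerance = 1e-3)
})

test_that("prob_upper agrees with an independent Euler-Maruyama oracle", {
  for (av in list(c(1.62, 3.58), c(2.08, 1.29))) {
    p <- ddm_params(0, av[1], av[2])
    frac <- euler_choice_fraction(p, n = 4000, seed = 42)
    se <- sqrt(prob_upper(p) * (1 - prob_upper(p)) / 4000)
    expect_lt(abs(frac - prob_upper(p)), 3 * se + 0.002)
  }
  expect_equal(prob_upper(ddm_params(0.3, 1.8, 0)), 0.5)
})

test_that("mean decision time matches its analytic limit and quadrature", {
  expect_equal(mean_decision_time(ddm_params(0, 2, 1e-12)), 1)
  p <- ddm_params(0.376, 1.62, 3.58)
  quad_mean <- integrate(Vectorize(function(rt)
    (rt - p$t_nd) * (exp(wfpt_log_density(rt, "upper", p)) +
                       exp(wfpt_log_density(rt, "lower", p)))),
    p$t_nd, Inf, rel.tol = 1e-9)$value
  expect_equal(mean_decision_time(p), quad_mean, tolerance = 1e-6)
  # closed-form mean RTs line up with the published task means
  expect_equal(1000 * (p$t_nd + mean_decision_time(p)), 601, tolerance = 1e-3)
  p2 <- ddm_params(0.426, 1.59, 2.52)
  expect_equal(p2$t_nd + mean_decision_time(p2), 0.730, tolerance = 1e-3)
  expect_error(mean_decision_time(ddm_params(0.3, 1.5, 2, z_rel = 0.4)),
               "unbiased")
})

test_that("simulator choice fractions and moments match closed forms", {
  p <- ddm_params(0.376, 1.62, 3.58)
  s <- simulate_trials(p, 1e5, deadline = 3, seed = 101)
  expect_lt(abs(mean(s$boundary == "upper", na.rm = TRUE) - prob_upper(p)),
            0.005)
  sim_mdt <- mean(s$rt, na.rm = TRUE) - p$t_nd
  expect_lt(abs(sim_mdt / mean_decision_time(p) - 1), 0.02)
  expect_true(all(s$rt[s$responded] > p$t_nd))
})

test_that("simulation is reproducible under a fixed seed", {
  p <- ddm_params(0.45, 1.9, 3.2)
  s1 <- simulate_trials(p, 500, deadline = 3, seed = 7)
  s2 <- simulate_trials(p, 500, deadline = 3, seed = 7)
  expect_identical(s1, s2)
})

test_that("deadline non-response fraction matches the density tail", {
  # slowest fitted condition: the tail beyond the 3 s window is ~2.9%
  p <- ddm_params(0.641, 2.17, 1.10)
  tail_mass <- 1 -
    integrate(Vectorize(function(rt) exp(wfpt_log_density(rt, "upper", p))),
              p$t_nd, 3, rel.tol = 1e-9)$value -
    integrate(Vectorize(function(rt) exp(wfpt_log_density(rt, "lower", p))),
              p$t_nd, 3, rel.tol = 1e-9)$value
  s <- simulate_trials(p, 1e5, deadline = 3, seed = 11)
  expect_lt(abs(mean(!s$responded) - tail_mass), 0.004)
  # for the young-adult conditions the tail is well under 2%
  for (av in list(c(0.376, 1.62, 3.58), c(0.537, 2.08, 1.29),
                  c(0.426, 1.59, 2.52), c(0.430, 1.59, 2.84))) {
    sy <- simulate_trials(ddm_params(av[1], av[2], av[3]), 2e4,
                          deadline = 3, seed = 12)
    expect_lt(mean(!sy$responded), 0.02)
  }
})
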