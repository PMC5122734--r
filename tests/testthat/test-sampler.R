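empty_trials <- data.frame(subject_id = character(0), group = character(0),
                           task = character(0),
                           stimulus_type = character(0),
                           correct = logical(0), rt_ms = numeric(0))

tnorm_mean <- function(m, s, lower) {     # closed-form oracle
  a <- (lower - m) / s
  m + s * dnorm(a) / (1 - pnorm(a))
}

test_that("with no data the chains sample the prior (closed-form moments)", {
  spec <- hier_spec("letter", "young")
  fit <- run_chains(spec, empty_trials, n_chains = 3, n_iterations = 20000,
                    burn_in = 2000, seed = 3)
  m <- function(p) mean(retained_draws(fit, sprintf("mu[letter,young,%s]",
                                                    p)))
  s <- function(p) mean(retained_draws(fit,
                                       sprintf("sigma[letter,young,%s]",
                                               p)))
  expect_equal(m("t"), tnorm_mean(0.4, 0.3, 0), tolerance = 0.05)
  expect_equal(m("a"), tnorm_mean(2, 1.5, 0), tolerance = 0.25)
  expect_equal(m("v"), 2, tolerance = 0.2)
  expect_equal(sd(as.vector(retained_draws(fit, "mu[letter,young,v]"))), 3,
               tolerance = 0.3)
  # half-normal(0, 1) spread prior: mean sqrt(2/pi)
  for (p in c("t", "a", "v"))
    expect_equal(s(p), sqrt(2 / pi), tolerance = 0.12)
})

test_that("posterior moments tighten with chain length on the prior target", {
  spec <- hier_spec("letter", "young")
  err <- vapply(c(2000, 18000), function(n) {
    fit <- run_chains(spec, empty_trials, n_chains = 2, n_iterations = n,
                      burn_in = 500, seed = 8)
    abs(mean(retained_draws(fit, "mu[letter,young,v]")) - 2)
  }, numeric(1))
  expect_lte(err[2], err[1] + 0.05)
  expect_lt(err[2], 0.15)
})

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- small_cohort(n_per_group = 3, seed = 41)
      pp <- preprocess_trials(cohort$trials)
      spec <- hier_spec("letter", c("young", "high_old", "low_old"))
      cache <<- run_chains(spec, pp$trials, n_chains = 2,
                           n_iterations = 700, burn_in = 300, seed = 9)
    }
    cache
  }
})

test_that("runs are bit-identical under the same seed", {
  cohort <- small_cohort(n_per_group = 2, seed = 43)
  pp <- preprocess_trials(cohort$trials)
  spec <- hier_spec("letter", c("young", "high_old", "low_old"))
  f1 <- run_chains(spec, pp$trials, n_chains = 2, n_iterations = 300,
                   burn_in = 100, seed = 17)
  f2 <- run_chains(spec, pp$trials, n_chains = 2, n_iterations = 300,
                   burn_in = 100, seed = 17)
  expect_identical(f1$draws, f2$draws)
})

test_that("retained draw count and domains are exact", {
  fit <- small_fit()
  ret <- retained_draws(fit)
  expect_equal(dim(ret)[1] * dim(ret)[3],
               fit$n_chains * (fit$n_iterations - fit$burn_in))
  pn <- parameter_names(fit)
  t_pars <- grep("(mu|theta)\\[.*,t\\]$", pn, value = TRUE)
  a_pars <- grep("(mu|theta)\\[.*,a\\]$", pn, value = TRUE)
  s_pars <- grep("^sigma", pn, value = TRUE)
  expect_true(all(fit$draws[, t_pars, ] >= 0))
  expect_true(all(fit$draws[, a_pars, ] > 0))
  expect_true(all(fit$draws[, s_pars, ] > 0))
})

test_that("post-adaptation acceptance rates are in the workable band", {
  fit <- small_fit()
  rates <- unlist(fit$acceptance)
  rates <- rates[!is.na(rates)]
  expect_true(all(rates >= 0.1 & rates <= 0.6))
})

test_that("MAP with no data returns the prior mode", {
  spec <- hier_spec("letter", c("young", "high_old"))
  map <- find_map(spec, empty_trials, n_starts = 1, seed = 1)
  st <- map$state$tasks$letter
  expect_equal(unname(st$mu["young", ]), c(0.4, 2, 2), tolerance = 1e-8)
  expect_true(is.finite(map$value))
})

test_that("MAP recovers a single subject's parameters from 500 trials", {
  p_true <- ddm_params(0.4, 1.8, 2.5)
  s <- simulate_trials(p_true, 500, deadline = 3, seed = 77)
  tr <- make_trials(s$rt[s$responded] * 1000,
                    correct = s$boundary[s$responded] == "upper")
  spec <- hier_spec("letter", "young")
  map <- find_map(spec, tr, seed = 2)
  th <- map$state$tasks$letter$theta["s1", ]
  expect_lt(abs(th["t"] / 0.4 - 1), 0.10)
  expect_lt(abs(th["a"] / 1.8 - 1), 0.10)
  expect_lt(abs(th["v"] / 2.5 - 1), 0.10)
})

test_that("MAP value is stable across optimisation starts", {
  p_true <- ddm_params(0.45, 1.9, 3.0)
  s <- simulate_trials(p_true, 300, deadline = 3, seed = 78)
  tr <- make_trials(s$rt[s$responded] * 1000,
                    correct = s$boundary[s$responded] == "upper")
  spec <- hier_spec("letter", "young")
  m1 <- find_map(spec, tr, n_starts = 2, seed = 5)
  m2 <- find_map(spec, tr, n_starts = 2, seed = 55)
  expect_lt(abs(m1$value - m2$value), 0.1)
})
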