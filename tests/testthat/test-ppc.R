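point_mass_samples <- function(t0 = 0.376, a = 1.62, v = 3.58,
                               subject = "s1", task = "letter") {
  pars <- sprintf("theta[%s,%s,%s]", task, subject, c("t", "a", "v"))
  arr <- array(rep(c(t0, a, v), each = 100), c(100, 3, 2),
               dimnames = list(NULL, pars, NULL))
  posterior_samples(arr, burn_in = 0)
}

pm_design <- data.frame(subject_id = "s1", group = "young",
                        task = "letter", n_trials = 80)

test_that("a point-mass posterior reproduces simulator statistics", {
  smp <- point_mass_samples()
  reps <- simulate_replicates(smp, pm_design, n_rep = 120, seed = 5)
  acc <- mean(reps$accuracy)
  expect_equal(acc, prob_upper(ddm_params(0.376, 1.62, 3.58)),
               tolerance = 0.005)
  expect_equal(acc, 0.997, tolerance = 0.005)
  # replicate median of correct RTs matches a direct large-n simulation
  direct <- simulate_trials(ddm_params(0.376, 1.62, 3.58), 2e4,
                            deadline = 3, seed = 6)
  med_direct <- median(direct$rt[direct$responded &
                                   direct$boundary == "upper"]) * 1000
  expect_equal(mean(reps$quantiles[, 1, 3]), med_direct, tolerance = 15)
})

test_that("replicates are reproducible under a fixed seed", {
  smp <- point_mass_samples()
  r1 <- simulate_replicates(smp, pm_design, n_rep = 10, seed = 3)
  r2 <- simulate_replicates(smp, pm_design, n_rep = 10, seed = 3)
  expect_identical(r1$quantiles, r2$quantiles)
  expect_error(simulate_replicates(smp, pm_design[, -4], n_rep = 2),
               "design")
})

ppc_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      smp <- point_mass_samples()
      reps <- simulate_replicates(smp, pm_design, n_rep = 150, seed = 8)
      probs <- reps$probs
      # observed set equal to the replicate means -> perfect agreement
      obs <- data.frame(subject_id = "s1", group = "young",
                        task = "letter", prob = probs,
                        rt_ms = colMeans(reps$quantiles[, 1, ]))
      cache <<- list(reps = reps, obs = obs)
    }
    cache
  }
})

test_that("observed equal to simulated means gives r = 1, coverage = 1", {
  pp <- ppc_pair()
  rep1 <- compare_quantiles(pp$obs, pp$reps)
  expect_equal(rep1$correlation, 1, tolerance = 1e-9)
  expect_equal(rep1$coverage, 1)
})

test_that("a uniform observed shift kills coverage but not correlation", {
  pp <- ppc_pair()
  base <- compare_quantiles(pp$obs, pp$reps)
  shifted <- pp$obs
  shifted$rt_ms <- shifted$rt_ms + 1000
  rep2 <- compare_quantiles(shifted, pp$reps)
  expect_equal(rep2$correlation, base$correlation, tolerance = 1e-9)
  expect_equal(rep2$coverage, 0)
})

test_that("quantile summaries are monotone in the probability grid", {
  pp <- ppc_pair()
  rep1 <- compare_quantiles(pp$obs, pp$reps)
  for (cell in split(rep1$cells, rep1$cells$subject_id)) {
    cell <- cell[order(cell$prob), ]
    expect_true(all(diff(cell$sim_mean) >= 0))
    expect_true(all(diff(cell$observed) >= 0))
  }
  # empty correct-response cells are flagged, not dropped silently
  obs_na <- pp$obs
  obs_na$rt_ms[1] <- NA
  rep3 <- compare_quantiles(obs_na, pp$reps)
  expect_true(anyNA(rep3$cells$observed))
  expect_true(is.finite(rep3$correlation))
})

test_that("the ppc design mirrors the fitted trial counts", {
  cohort <- small_cohort(n_per_group = 2, seed = 12)
  des <- ppc_design(cohort$trials)
  expect_equal(sort(unique(des$n_trials)), 80)
  expect_equal(nrow(des), 6)
})
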