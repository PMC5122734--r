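test_that("cohort configuration is validated", {
  expect_error(cohort_config(group_sizes = c(4, 4)), "named")
  expect_error(cohort_config(group_sizes = c(young = 4),
                             contaminant_rate = 0.5), "contaminant_rate")
  expect_error(cohort_config(group_sizes = c(young = 4), tasks = "oddball"))
})

test_that("every subject-task block holds a 40/40 stimulus split", {
  cohort <- small_cohort(n_per_group = 2, tasks = c("letter", "lexical"),
                         seed = 51)
  counts <- table(cohort$trials$subject_id, cohort$trials$task,
                  cohort$trials$stimulus_type)
  expect_true(all(counts == 40))
})

test_that("generation is deterministic under the config seed", {
  c1 <- small_cohort(n_per_group = 2, seed = 52)
  c2 <- small_cohort(n_per_group = 2, seed = 52)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$truth, c2$truth)
})

test_that("zero-spread cohorts reproduce the closed-form RT and accuracy", {
  cfg <- cohort_config(group_sizes = c(young = 3), tasks = "letter",
                       trials_per_task = 2000,
                       between_subject_sd = c(t = 0, a = 0, v = 0),
                       seed = 53)
  cohort <- generate_cohort(cfg)
  resp <- cohort$trials[!is.na(cohort$trials$rt_ms), ]
  p <- ddm_params(0.376, 1.62, 3.58)
  mean_rt <- mean(resp$rt_ms[resp$correct])
  expect_equal(mean_rt, 1000 * (p$t_nd + mean_decision_time(p)),
               tolerance = 0.015 * 601)
  expect_equal(mean(resp$correct), prob_upper(p), tolerance = 0.005)
  expect_true(all(cohort$truth$t == 0.376))
})

test_that("ground-truth group means track the configured means", {
  cohort <- generate_cohort(cohort_config(group_sizes = c(young = 120),
                                          tasks = "letter", seed = 54))
  tru <- cohort$truth
  se <- function(p, m) 0.1 * m / sqrt(120)
  expect_lt(abs(mean(tru$t) - 0.376), 4 * se("t", 0.376))
  expect_lt(abs(mean(tru$a) - 1.62), 4 * se("a", 1.62))
  expect_lt(abs(mean(tru$v) - 3.58), 4 * se("v", 3.58))
  expect_true(all(tru$t >= 0 & tru$a > 0))
})

test_that("contaminants and deadlines shape the emitted table", {
  dirty <- small_cohort(n_per_group = 4, seed = 55,
                        contaminant_rate = 0.2,
                        tasks = "phonological")
  tr <- dirty$trials
  # contaminant guesses can be fast; the diffusion process itself cannot
  # produce sub-300 ms responses at these parameter values
  expect_gt(sum(tr$rt_ms < 300, na.rm = TRUE), 0)
  # the slow phonological conditions run into the 3 s deadline
  expect_gt(sum(is.na(tr$rt_ms)), 0)
  expect_true(all(tr$rt_ms <= 3000, na.rm = TRUE))
})

test_that("descriptive tables summarise cells and flag absences", {
  tr <- make_trials(c(400, 600))
  d <- descriptive_table(tr)
  expect_equal(d$mean_rt_ms, 500)
  expect_equal(d$accuracy_pct, 100)

  cohort <- small_cohort(n_per_group = 2, tasks = c("letter", "lexical"),
                         seed = 56)
  d2 <- descriptive_table(cohort$trials)
  expect_equal(nrow(d2), 6)
  expect_true(all(is.finite(d2$mean_rt_ms)))

  # an absent cell is reported as NA, not zero
  missing_cell <- cohort$trials[!(cohort$trials$group == "young" &
                                    cohort$trials$task == "lexical"), ]
  d3 <- descriptive_table(missing_cell)
  gone <- d3[d3$group == "young" & d3$task == "lexical", ]
  if (nrow(gone)) expect_true(is.na(gone$mean_rt_ms))
})

test_that("a full-default young cell lands on the published descriptives", {
  cohort <- generate_cohort(cohort_config(group_sizes = c(young = 40),
                                          tasks = "letter", seed = 57))
  pp <- preprocess_trials(cohort$trials)
  d <- descriptive_table(pp$trials)
  # generated from the fitted letter-task parameters, the young cell mean
  # RT sits near the published 599 ms (between-subject spread adds noise)
  expect_gt(d$mean_rt_ms, 570)
  expect_lt(d$mean_rt_ms, 630)
  expect_gt(d$accuracy_pct, 99)
})
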