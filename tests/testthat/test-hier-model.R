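all_tasks <- c("letter", "lexical", "phonological", "semantic")
all_groups <- c("young", "high_old", "low_old")

test_that("group-location parameter accounting", {
  expect_equal(n_group_locations(hier_spec(all_tasks, all_groups)), 36)
  expect_equal(n_group_locations(hier_spec("letter", all_groups)), 9)
  expect_equal(n_group_locations(hier_spec("letter", "young")), 3)
  expect_error(hier_spec(c("letter", "letter"), all_groups), "duplicate")
  expect_error(hier_spec(character(0), all_groups), "non-empty")
})

one_subject_state <- function(spec, theta = c(0.35, 1.7, 3.2),
                              mu = c(0.4, 1.8, 3.0),
                              sigma = c(0.05, 0.2, 0.4)) {
  parameter_state(spec,
                  data.frame(subject_id = "s1", group = "young"),
                  matrix(theta, 1), matrix(mu, 1), matrix(sigma, 1))
}

test_that("domain violations give -Inf, not errors", {
  spec <- hier_spec("letter", "young")
  tr <- make_trials(c(500, 650))
  bad <- one_subject_state(spec, theta = c(0.35, -1, 3.2))
  expect_identical(log_posterior(spec, bad, tr), -Inf)
  bad2 <- one_subject_state(spec, sigma = c(-0.1, 0.2, 0.4))
  expect_identical(log_posterior(spec, bad2, tr), -Inf)
})

test_that("log posterior decomposes into prior + group density + likelihood", {
  spec <- hier_spec("letter", "young")
  st <- one_subject_state(spec)
  tr <- make_trials(520, correct = TRUE)
  lp <- log_posterior(spec, st, tr)
  expect_equal(lp - log_prior(spec, st) - log_group_density(spec, st),
               as.numeric(wfpt_log_density(
                 0.52, "upper", ddm_params(0.35, 1.7, 3.2))),
               tolerance = 1e-10)
  # incorrect response maps to the lower boundary (accuracy coding)
  tr2 <- make_trials(520, correct = FALSE)
  expect_equal(log_posterior(spec, st, tr2) - lp,
               as.numeric(wfpt_log_density(0.52, "lower",
                                           ddm_params(0.35, 1.7, 3.2)) -
                            wfpt_log_density(0.52, "upper",
                                             ddm_params(0.35, 1.7, 3.2))),
               tolerance = 1e-10)
})

test_that("tasks contribute independently to the joint posterior", {
  spec2 <- hier_spec(c("letter", "lexical"), "young")
  subjects <- data.frame(subject_id = "s1", group = "young")
  th <- list(letter = matrix(c(0.35, 1.7, 3.2), 1),
             lexical = matrix(c(0.42, 1.6, 2.4), 1))
  mu <- list(letter = matrix(c(0.4, 1.8, 3.0), 1),
             lexical = matrix(c(0.45, 1.7, 2.5), 1))
  sg <- list(letter = matrix(c(0.05, 0.2, 0.4), 1),
             lexical = matrix(c(0.05, 0.2, 0.4), 1))
  st2 <- parameter_state(spec2, subjects, th, mu, sg)
  tr <- rbind(make_trials(c(500, 700), task = "letter"),
              make_trials(c(640, 820), task = "lexical"))
  joint <- log_posterior(spec2, st2, tr)
  per_task <- vapply(c("letter", "lexical"), function(tk) {
    s1 <- hier_spec(tk, "young")
    st1 <- parameter_state(s1, subjects, th[tk], mu[tk], sg[tk])
    log_posterior(s1, st1, tr[tr$task == tk, ])
  }, numeric(1))
  expect_equal(joint, sum(per_task), tolerance = 1e-10)
})

test_that("true parameters beat badly perturbed ones on simulated data", {
  spec <- hier_spec("letter", "young")
  p_true <- ddm_params(0.376, 1.62, 3.58)
  wins <- 0
  for (r in 1:10) {
    s <- simulate_trials(p_true, 200, deadline = 3, seed = 100 + r)
    tr <- make_trials(s$rt[s$responded] * 1000,
                      correct = s$boundary[s$responded] == "upper")
    ll <- function(v) {
      st <- one_subject_state(spec, theta = c(0.376, 1.62, v))
      log_likelihood(spec, st, tr)
    }
    wins <- wins + (ll(3.58) > ll(3.58 * 1.5))
  }
  expect_gte(wins, 9)
})

test_that("log posterior is NaN-free across a lattice of valid states", {
  spec <- hier_spec("letter", "young")
  tr <- make_trials(c(420, 500, 640, 900), correct = c(TRUE, TRUE, FALSE,
                                                       TRUE))
  for (t0 in c(0.05, 0.3, 0.41)) {
    for (a in c(0.8, 1.6, 2.2)) {
      for (v in c(-2, 0, 1.3, 3.6)) {
        lp <- log_posterior(spec, one_subject_state(spec,
                                                    theta = c(t0, a, v)),
                            tr)
        expect_false(is.nan(lp))
      }
    }
  }
})

test_that("subjects without parameters raise a coverage error", {
  spec <- hier_spec("letter", "young")
  st <- one_subject_state(spec)
  tr <- make_trials(c(500, 600), subject_id = "other")
  expect_error(log_likelihood(spec, st, tr), "coverage")
  expect_error(log_likelihood(spec, st, make_trials(500, task = "lexical")),
               "not in the specification")
})
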