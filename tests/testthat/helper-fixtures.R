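# Shared fixtures.  The desk-scale letter-identification recovery fit takes
# a few minutes, so it is computed once on first use and cached for every
# test that needs it (recovery scoring, convergence, exceedance, PPC).

.fixture_cache <- new.env(parent = emptyenv())

desk_letter_fit <- function() {
  if (is.null(.fixture_cache$letter)) {
    .fixture_cache$letter <- recovery_study(tasks = "letter",
                                            n_per_group = 30, seed = 11)
  }
  .fixture_cache$letter
}

# small trial table built by hand
make_trials <- function(rt_ms, correct = TRUE, subject_id = "s1",
                        group = "young", task = "letter",
                        stimulus_type = "target") {
  n <- length(rt_ms)
  data.frame(subject_id = rep_len(subject_id, n),
             group = rep_len(group, n), task = rep_len(task, n),
             stimulus_type = rep_len(stimulus_type, n),
             correct = rep_len(correct, n), rt_ms = rt_ms)
}

# quick synthetic cohort at reduced scale
small_cohort <- function(n_per_group = 4, tasks = "letter", seed = 7,
                         groups = c("young", "high_old", "low_old"), ...) {
  sizes <- stats::setNames(rep(n_per_group, length(groups)), groups)
  generate_cohort(cohort_config(group_sizes = sizes, tasks = tasks,
                                seed = seed, ...))
}

# independent Euler-Maruyama simulation of the diffusion process; used as
# a simulation oracle that shares no code with the package's sampler
euler_choice_fraction <- function(params, n = 4000, dt = 5e-4, seed = 1) {
  set.seed(seed)
  x <- rep(params$z_rel * params$a, n)
  active <- rep(TRUE, n)
  upper <- logical(n)
  sdt <- sqrt(dt)
  for (step in seq_len(20000)) {
    idx <- which(active)
    if (!length(idx)) break
    x[idx] <- x[idx] + params$v * dt + sdt * rnorm(length(idx))
    hit_up <- active & x >= params$a
    hit_lo <- active & x <= 0
    upper[hit_up] <- TRUE
    active[hit_up | hit_lo] <- FALSE
  }
  mean(upper[!active])
}
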