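# ---- per-task data bundle ---------------------------------------------------

# Precompute the per-task quantities the likelihood needs: RTs in seconds,
# accuracy-coded boundaries, subject indices and group membership.
task_data <- function(spec, trials, tk, subjects = NULL) {
  tr <- trials[trials$task == tk, , drop = FALSE]
  if (is.null(subjects)) {
    ids <- sort(unique(tr$subject_id))
    grp <- tr$group[match(ids, tr$subject_id)]
    subjects <- data.frame(subject_id = ids, group = as.character(grp))
  }
  si <- match(tr$subject_id, subjects$subject_id)
  list(rt = tr$rt_ms / 1000, upper = as.logical(tr$correct), si = si,
       subjects = subjects, S = nrow(subjects),
       gi = match(subjects$group, spec$groups), G = length(spec$groups),
       min_rt = vapply(seq_len(nrow(subjects)), function(s) {
         r <- tr$rt_ms[tr$subject_id == subjects$subject_id[s]]
         if (length(r)) min(r) / 1000 else Inf
       }, numeric(1)))
}

subject_loglik <- function(d, th, z_rel, tol) {
  wfpt_loglik_by_subject_cpp(d$rt, d$upper, d$si,
                             th[, 1], th[, 2], th[, 3], z_rel, tol)
}

# group-density log mass of each subject's parameter triple
subject_group_density <- function(d, th, mu, sg) {
  dtnorm_log(th[, 1], mu[d$gi, 1], sg[d$gi, 1], 0) +
    dtnorm_log(th[, 2], mu[d$gi, 2], sg[d$gi, 2], 0) +
    dtnorm_log(th[, 3], mu[d$gi, 3], sg[d$gi, 3], -Inf)
}

# ---- EZ-style moment initialisation ----------------------------------------

# Closed-form diffusion estimates from accuracy, mean and variance of
# correct RTs (unit diffusion coefficient); used only as starting values.
ez_estimates <- function(rt_s, correct) {
  n <- length(rt_s)
  fallback <- c(t = 0.3, a = 1.8, v = 1.5)
  if (n < 5) return(fallback)
  pc <- mean(correct)
  pc <- min(max(pc, 1 / (2 * n)), 1 - 1 / (2 * n))
  if (abs(pc - 0.5) < 1 / (2 * n)) pc <- 0.5 + 1 / (2 * n)
  mrt <- mean(rt_s[correct]); vrt <- var(rt_s[correct])
  if (!is.finite(vrt) || vrt <= 0) return(fallback)
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  if (!is.finite(x) || x <= 0) return(fallback)
  v <- sign(pc - 0.5) * x^(1 / 4)
  a <- L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  t0 <- mrt - mdt
  out <- c(t = t0, a = a, v = v)
  out["a"] <- min(max(out["a"], 0.3), 5)
  out["v"] <- min(max(out["v"], -8), 8)
  out["t"] <- min(max(out["t"], 0.05), min(rt_s) - 0.01)
  if (any(!is.finite(out))) fallback else out
}

# ---- MAP -------------------------------------------------------------------

#' Maximum-a-posteriori starting state
#'
#' Finds a high-posterior starting state by multi-start block coordinate
#' ascent: per-subject parameters start at closed-form moment (EZ-style)
#' estimates and are polished by bounded quasi-Newton steps against their
#' trial likelihood plus group-level shrinkage; group locations and
#' spreads are optimised against their conditionals; sweeps repeat until
#' the joint log posterior stabilises.  The group spread is floored at the
#' empirical scatter of the subject estimates: the exact joint posterior
#' of a centered hierarchy is unbounded along the collapsed direction
#' (spread to zero with individuals stacked on the location), so the
#' literal global maximiser is degenerate and useless as a chain start --
#' what is returned is the non-degenerate local maximiser that
#' initialisation needs.  Additional starts jitter the initial values; the
#' best final state is returned.  With no trials the optimum is the prior
#' mode (locations at the prior means, spreads at their lower bound).
#'
#' @param spec a [hier_spec] object.
#' @param trials preprocessed trial table (may be empty).
#' @param n_starts number of optimisation starts, `>= 1`.
#' @param seed integer seed controlling start jitter.
#' @param tol likelihood truncation tolerance.
#' @param max_sweeps maximum block-coordinate sweeps per start.
#' @return A list with `state` (a [parameter_state]), `value` (its log
#'   posterior) and `task_values`.
#' @export
find_map <- function(spec, trials, n_starts = 2, seed = 1, tol = 1e-7,
                     max_sweeps = 10) {
  stopifnot(inherits(spec, "hier_spec"), n_starts >= 1)
  validate_trials(trials)
  pr <- spec$priors

  # subjects: union over all tasks
  ids <- sort(unique(trials$subject_id))
  subjects <- data.frame(
    subject_id = ids,
    group = as.character(trials$group[match(ids, trials$subject_id)]))

  theta_l <- list(); mu_l <- list(); sigma_l <- list(); task_values <- c()
  for (tk in spec$tasks) {
    d <- task_data(spec, trials, tk, subjects)
    best <- NULL
    for (st_i in seq_len(n_starts)) {
      set.seed((seed %% 100000L) + malloc_seed(tk) + 613L * st_i)
      fit <- map_one_task(spec, d, jitter = (st_i > 1), tol = tol,
                          max_sweeps = max_sweeps)
      if (is.null(best) || fit$value > best$value) best <- fit
    }
    if (!is.finite(best$value))
      stop("initialization error: no finite-posterior point found for task ",
           tk)
    theta_l[[tk]] <- best$th; mu_l[[tk]] <- best$mu
    sigma_l[[tk]] <- best$sg
    task_values[tk] <- best$value
  }
  state <- parameter_state(spec, subjects, theta_l, mu_l, sigma_l)
  list(state = state, value = sum(task_values), task_values = task_values)
}

# deterministic small integer from a task label
malloc_seed <- function(tk) sum(utf8ToInt(tk)) %% 1000L

map_one_task <- function(spec, d, jitter = FALSE, tol = 1e-7,
                         max_sweeps = 10) {
  pr <- spec$priors
  S <- d$S; G <- d$G
  # EZ starts per subject
  th <- matrix(0, S, 3, dimnames = list(d$subjects$subject_id,
                                        spec$free_params))
  for (s in seq_len(S)) {
    idx <- d$si == s
    th[s, ] <- ez_estimates(d$rt[idx], d$upper[idx])
  }
  if (jitter && S > 0) {
    th <- th * matrix(exp(0.05 * rnorm(S * 3)), S, 3)
    th[, 1] <- pmin(th[, 1], d$min_rt - 0.01)
  }
  mu <- matrix(0, G, 3, dimnames = list(spec$groups, spec$free_params))
  sg <- mu
  for (p in 1:3) {
    for (g in seq_len(G)) {
      x <- th[d$gi == g, p]
      mu[g, p] <- if (length(x)) mean(x) else pr$location[[p]]$mean
      sg[g, p] <- if (length(x) > 1) max(sd(x), 0.01) else 0.1
    }
  }

  if (S == 0) { # no data: prior mode
    for (p in 1:3) mu[, p] <- pr$location[[p]]$mean
    sg[] <- 1e-3
    value <- task_logpost(spec, d, th, mu, sg, tol)
    return(list(th = th, mu = mu, sg = sg, value = value))
  }

  last <- -Inf
  for (sweep in seq_len(max_sweeps)) {
    # subjects given group level
    for (s in seq_len(S)) {
      idx <- d$si == s
      rt_s <- d$rt[idx]; up_s <- d$upper[idx]
      g <- d$gi[s]
      obj <- function(x) {
        ll <- sum(wfpt_log_density_cpp(rt_s, up_s, x[1], x[2], x[3],
                                       spec$fixed$z_rel, tol))
        gd <- dtnorm_log(x[1], mu[g, 1], sg[g, 1], 0) +
          dtnorm_log(x[2], mu[g, 2], sg[g, 2], 0) +
          dtnorm_log(x[3], mu[g, 3], sg[g, 3], -Inf)
        val <- ll + gd
        if (!is.finite(val)) 1e10 else -val
      }
      up_bound <- c(max(d$min_rt[s] - 1e-3, 2e-3), 10, 10)
      res <- tryCatch(
        optim(pmin(pmax(th[s, ], c(1e-3, 0.05, -10)), up_bound), obj,
              method = "L-BFGS-B", lower = c(1e-3, 0.05, -10),
              upper = up_bound, control = list(maxit = 40)),
        error = function(e) NULL)
      if (!is.null(res) && is.finite(res$value)) th[s, ] <- res$par
    }
    # group level given subjects; the spread is floored at the empirical
    # scatter of the subject estimates so the ascent cannot ratchet into
    # the degenerate sigma -> 0 mode of the centered hierarchy
    for (g in seq_len(G)) {
      for (p in 1:3) {
        x <- th[d$gi == g, p]
        lp <- pr$location[[p]]
        sg_floor <- max(0.01,
                        if (length(x) > 1) 0.8 * sd(x) else 0,
                        0.03 * abs(mean(x)))
        obj <- function(y) {
          val <- dtnorm_log(y[1], lp$mean, lp$sd, lp$lower) +
            dhalfnorm_log(y[2], pr$spread_sd) +
            sum(dtnorm_log(x, y[1], y[2], param_lower[[p]]))
          if (!is.finite(val)) 1e10 else -val
        }
        res <- tryCatch(
          optim(c(mu[g, p], max(sg[g, p], sg_floor)), obj,
                method = "L-BFGS-B",
                lower = c(if (is.finite(lp$lower)) lp$lower + 1e-4 else -10,
                          sg_floor),
                upper = c(10, 5), control = list(maxit = 40)),
          error = function(e) NULL)
        if (!is.null(res) && is.finite(res$value)) {
          mu[g, p] <- res$par[1]; sg[g, p] <- res$par[2]
        }
      }
    }
    value <- task_logpost(spec, d, th, mu, sg, tol)
    if (is.finite(value) && is.finite(last) && value - last < 0.01) break
    last <- value
  }
  list(th = th, mu = mu, sg = sg, value = value)
}

task_logpost <- function(spec, d, th, mu, sg, tol) {
  pr <- spec$priors
  prior <- 0
  for (p in 1:3) {
    lp <- pr$location[[p]]
    prior <- prior + sum(dtnorm_log(mu[, p], lp$mean, lp$sd, lp$lower)) +
      sum(dhalfnorm_log(sg[, p], pr$spread_sd))
  }
  if (d$S == 0) return(prior)
  prior + sum(subject_group_density(d, th, mu, sg)) +
    sum(subject_loglik(d, th, spec$fixed$z_rel, tol))
}

# ---- MCMC ------------------------------------------------------------------

#' Sample the hierarchical posterior with adaptive Metropolis-within-Gibbs
#'
#' Runs `n_chains` independent chains per task.  Each iteration updates (i)
#' every subject's `(t, a, v)` triple with a joint random-walk proposal
#' (subjects are conditionally independent given the group level, so this
#' block is vectorised across subjects), and (ii) each group location by a
#' scalar random walk and each group spread by a log-scale random walk
#' against their full conditionals.  Proposal scales adapt towards an
#' acceptance rate of 0.3 during burn-in only and are frozen afterwards,
#' preserving detailed balance in the retained draws.  Chains start from
#' the supplied (or MAP) state with 1% relative jitter, and are exactly
#' reproducible given `(seed, chain)`.
#'
#' @param spec a [hier_spec] object.
#' @param trials preprocessed trial table.
#' @param init optional list as returned by [find_map()] (or a
#'   [parameter_state]); computed by [find_map()] when `NULL`.
#' @param n_chains number of chains (use at least 2 if convergence is to be
#'   assessed).
#' @param n_iterations total iterations per chain, `> burn_in`.
#' @param burn_in iterations discarded as warm-up (stored but flagged).
#' @param seed integer master seed.
#' @param tol likelihood truncation tolerance.
#' @param adapt_target acceptance rate targeted during adaptation.
#' @return An object of class `posterior_samples`; see
#'   [posterior_samples()].
#' @export
run_chains <- function(spec, trials, init = NULL, n_chains = 3,
                       n_iterations = 15000, burn_in = 5000, seed = 1,
                       tol = 1e-7, adapt_target = 0.3) {
  stopifnot(inherits(spec, "hier_spec"), n_chains >= 1,
            n_iterations > burn_in, burn_in >= 1)
  validate_trials(trials)
  if (is.null(init)) init <- find_map(spec, trials, seed = seed, tol = tol)
  state <- if (inherits(init, "parameter_state")) init else init$state

  all_draws <- NULL
  acceptance <- list()
  for (ti in seq_along(spec$tasks)) {
    tk <- spec$tasks[ti]
    d <- task_data(spec, trials, tk, state$subjects)
    st <- state$tasks[[tk]]
    cn <- c(t(outer(spec$groups, spec$free_params,
                    function(g, p) sprintf("mu[%s,%s,%s]", tk, g, p))),
            t(outer(spec$groups, spec$free_params,
                    function(g, p) sprintf("sigma[%s,%s,%s]", tk, g, p))),
            t(outer(d$subjects$subject_id, spec$free_params,
                    function(s, p) sprintf("theta[%s,%s,%s]", tk, s, p))))
    task_draws <- array(
      NA_real_, c(n_iterations, length(cn), n_chains),
      dimnames = list(NULL, cn, paste0("chain", seq_len(n_chains))))
    for (ch in seq_len(n_chains)) {
      chain_seed <- (seed %% 1000000L) + 7919L * ch + 131L * ti
      res <- run_chain_task(spec, d, st, n_iterations, burn_in, chain_seed,
                            tol, adapt_target)
      task_draws[, , ch] <- res$draws
      acceptance[[sprintf("%s.chain%d", tk, ch)]] <- res$acceptance
    }
    all_draws <- if (is.null(all_draws)) task_draws else
      abind_params(all_draws, task_draws)
  }
  posterior_samples(all_draws, burn_in = burn_in, seed = seed,
                    acceptance = acceptance)
}

# bind two [iter, param, chain] arrays along the parameter dimension
abind_params <- function(x, y) {
  out <- array(NA_real_, c(dim(x)[1], dim(x)[2] + dim(y)[2], dim(x)[3]),
               dimnames = list(NULL, c(dimnames(x)[[2]], dimnames(y)[[2]]),
                               dimnames(x)[[3]]))
  out[, seq_len(dim(x)[2]), ] <- x
  out[, dim(x)[2] + seq_len(dim(y)[2]), ] <- y
  out
}

run_chain_task <- function(spec, d, st, n_iterations, burn_in, chain_seed,
                           tol, target) {
  set.seed(chain_seed %% .Machine$integer.max)
  S <- d$S; G <- d$G
  th <- st$theta[d$subjects$subject_id, , drop = FALSE]
  mu <- st$mu; sg <- st$sigma
  # 1% relative jitter around the starting state
  jit <- function(x) x * exp(0.01 * rnorm(length(x)))
  if (S > 0) {
    th[, 2:3] <- jit(th[, 2:3])
    th[, 1] <- pmin(jit(th[, 1]), d$min_rt - 1e-3)
  }
  mu <- matrix(jit(mu), G, 3, dimnames = dimnames(mu))
  sg <- matrix(pmax(jit(sg), 1e-3), G, 3, dimnames = dimnames(sg))

  pr <- spec$priors
  lowers <- c(0, 0, -Inf)
  # per-subject proposal: multivariate random walk whose covariance is
  # learned from the chain history during burn-in (refreshed Cholesky),
  # with a per-subject scale multiplier tuned towards the target rate
  base_sd <- c(0.01, 0.08, 0.25)
  L <- array(0, c(max(S, 1), 3, 3))
  for (j in 1:3) L[, j, j] <- base_sd[j]
  th_mult <- rep(2.38 / sqrt(3), S)  # per-subject scale multiplier
  run_m <- th                        # running mean of the chain history
  run_M2 <- array(0, c(max(S, 1), 3, 3))
  run_n <- 0
  refresh_every <- 25
  mu_scale <- matrix(0.05, G, 3)
  ls_scale <- matrix(0.25, G, 3)

  # per-group trial bundles for the ensemble (translation / rescale) moves
  grp <- lapply(seq_len(G), function(g) {
    members <- which(d$gi == g)
    rows <- which(d$gi[d$si] == g)
    list(members = members, n = length(members), rt = d$rt[rows],
         upper = d$upper[rows], si = match(d$si[rows], members))
  })
  tr_sd <- matrix(c(0.008, 0.04, 0.08), G, 3, byrow = TRUE)
  tr_mult <- rep(1, G)               # acceptance-tuned multiplier
  mu_run_m <- mu; mu_run_M2 <- matrix(0, G, 3); mu_run_n <- 0
  sc_scale <- matrix(0.15, G, 3)     # log-step of the rescale move
  mu_prior_log <- function(mvec) {
    s <- 0
    for (p in 1:3) {
      lp <- pr$location[[p]]
      s <- s + dtnorm_log(mvec[p], lp$mean, lp$sd, lp$lower)
    }
    s
  }

  curr_ll <- if (S > 0) subject_loglik(d, th, spec$fixed$z_rel, tol)
             else numeric(0)
  gd_curr <- if (S > 0) subject_group_density(d, th, mu, sg) else numeric(0)

  draws <- matrix(NA_real_, n_iterations, 6 * G + 3 * S)
  acc_n <- c(subject = 0, mu = 0, sigma = 0, shift = 0, scale = 0)
  acc_d <- c(subject = 0, mu = 0, sigma = 0, shift = 0, scale = 0)

  for (i in seq_len(n_iterations)) {
    adapting <- i <= burn_in
    gamma <- if (adapting) min(0.25, 5 / sqrt(i)) else 0

    if (S > 0) {
      for (rep in 1:3) {     # several sweeps: the triples dominate mixing
        z <- matrix(rnorm(S * 3), S, 3)
        eps <- matrix(0, S, 3)
        for (j in 1:3)
          eps[, j] <- (z[, 1] * L[, 1, j] + z[, 2] * L[, 2, j] +
                         z[, 3] * L[, 3, j]) * th_mult
        th_prop <- th + eps
        prop_ll <- subject_loglik(d, th_prop, spec$fixed$z_rel, tol)
        gd_prop <- subject_group_density(d, th_prop, mu, sg)
        logr <- prop_ll + gd_prop - curr_ll - gd_curr
        acc <- !is.na(logr) & log(runif(S)) < logr
        if (any(acc)) {
          th[acc, ] <- th_prop[acc, ]
          curr_ll[acc] <- prop_ll[acc]
          gd_curr[acc] <- gd_prop[acc]
        }
        if (adapting) {
          th_mult <- pmin(pmax(th_mult * exp(gamma * (acc - target)),
                               1e-3), 1e3)
        } else {
          acc_n["subject"] <- acc_n["subject"] + sum(acc)
          acc_d["subject"] <- acc_d["subject"] + S
        }
      }
      if (adapting) {
        # accumulate chain history moments for the proposal covariance
        run_n <- run_n + 1
        delta <- th - run_m
        run_m <- run_m + delta / run_n
        delta2 <- th - run_m
        for (jj in 1:3) for (kk in 1:3)
          run_M2[, jj, kk] <- run_M2[, jj, kk] + delta[, jj] * delta2[, kk]
        if (run_n > 50 && i %% refresh_every == 0) {
          for (s in seq_len(S)) {
            cv <- run_M2[s, , ] / (run_n - 1) + diag(1e-10, 3)
            ch <- tryCatch(chol(cv), error = function(e) NULL)
            if (!is.null(ch)) L[s, , ] <- ch
          }
        }
      }
    }

    for (g in seq_len(G)) {
      in_g <- which(d$gi == g)
      for (p in 1:3) {
        lp <- pr$location[[p]]
        x <- th[in_g, p]
        # location
        m0 <- mu[g, p]
        cond <- function(m) {
          dtnorm_log(m, lp$mean, lp$sd, lp$lower) +
            sum(dtnorm_log(x, m, sg[g, p], lowers[p]))
        }
        m1 <- m0 + rnorm(1) * mu_scale[g, p]
        logr <- cond(m1) - cond(m0)
        acc <- !is.na(logr) && log(runif(1)) < logr
        if (acc) mu[g, p] <- m1
        if (adapting)
          mu_scale[g, p] <- min(max(
            mu_scale[g, p] * exp(gamma * (acc - target)), 1e-5), 10)
        else {
          acc_n["mu"] <- acc_n["mu"] + acc; acc_d["mu"] <- acc_d["mu"] + 1
        }
        # spread (log-scale random walk, with Jacobian)
        s0 <- sg[g, p]
        conds <- function(s) {
          dhalfnorm_log(s, pr$spread_sd) +
            sum(dtnorm_log(x, mu[g, p], s, lowers[p]))
        }
        ly1 <- log(s0) + rnorm(1) * ls_scale[g, p]
        s1 <- exp(ly1)
        logr <- conds(s1) - conds(s0) + (ly1 - log(s0))
        acc <- !is.na(logr) && log(runif(1)) < logr
        if (acc) sg[g, p] <- s1
        if (adapting)
          ls_scale[g, p] <- min(max(
            ls_scale[g, p] * exp(gamma * (acc - target)), 1e-4), 10)
        else {
          acc_n["sigma"] <- acc_n["sigma"] + acc
          acc_d["sigma"] <- acc_d["sigma"] + 1
        }
      }
    }
    if (S > 0) gd_curr <- subject_group_density(d, th, mu, sg)

    # ensemble moves: the centered hierarchy's slow modes are the joint
    # drift of (mu, member thetas) and the joint rescaling of (sigma,
    # member deviations); scalar updates alone mix them too slowly
    if (S > 0) {
      for (g in seq_len(G)) {
        gb <- grp[[g]]
        if (gb$n == 0) next
        mem <- gb$members
        # joint translation of the group location and all member thetas
        delta <- rnorm(3) * tr_sd[g, ] * tr_mult[g]
        mu_p <- mu[g, ] + delta
        th_p <- th[mem, , drop = FALSE] +
          matrix(delta, gb$n, 3, byrow = TRUE)
        ll_p <- wfpt_loglik_by_subject_cpp(gb$rt, gb$upper, gb$si,
                                           th_p[, 1], th_p[, 2], th_p[, 3],
                                           spec$fixed$z_rel, tol)
        gd_p <- dtnorm_log(th_p[, 1], mu_p[1], sg[g, 1], 0) +
          dtnorm_log(th_p[, 2], mu_p[2], sg[g, 2], 0) +
          dtnorm_log(th_p[, 3], mu_p[3], sg[g, 3], -Inf)
        logr <- sum(ll_p) - sum(curr_ll[mem]) + sum(gd_p) -
          sum(gd_curr[mem]) + mu_prior_log(mu_p) - mu_prior_log(mu[g, ])
        acc <- !is.na(logr) && log(runif(1)) < logr
        if (acc) {
          mu[g, ] <- mu_p; th[mem, ] <- th_p
          curr_ll[mem] <- ll_p; gd_curr[mem] <- gd_p
        }
        if (adapting)
          tr_mult[g] <- min(max(tr_mult[g] * exp(gamma * (acc - target)),
                                1e-3), 1e3)
        else {
          acc_n["shift"] <- acc_n["shift"] + acc
          acc_d["shift"] <- acc_d["shift"] + 1
        }
        # joint rescale of each spread and the member deviations around mu
        for (p in 1:3) {
        eta <- rnorm(1) * sc_scale[g, p]
        cc <- exp(eta)
        sg_p <- sg[g, p] * cc
        th_p <- th[mem, , drop = FALSE]
        th_p[, p] <- mu[g, p] + cc * (th_p[, p] - mu[g, p])
        ll_p <- wfpt_loglik_by_subject_cpp(gb$rt, gb$upper, gb$si,
                                           th_p[, 1], th_p[, 2], th_p[, 3],
                                           spec$fixed$z_rel, tol)
        sg_new <- sg[g, ]; sg_new[p] <- sg_p
        gd_p <- dtnorm_log(th_p[, 1], mu[g, 1], sg_new[1], 0) +
          dtnorm_log(th_p[, 2], mu[g, 2], sg_new[2], 0) +
          dtnorm_log(th_p[, 3], mu[g, 3], sg_new[3], -Inf)
        logr <- sum(ll_p) - sum(curr_ll[mem]) + sum(gd_p) -
          sum(gd_curr[mem]) +
          dhalfnorm_log(sg_p, pr$spread_sd) -
          dhalfnorm_log(sg[g, p], pr$spread_sd) + (gb$n + 1) * eta
        acc <- !is.na(logr) && log(runif(1)) < logr
        if (acc) {
          sg[g, p] <- sg_p; th[mem, ] <- th_p
          curr_ll[mem] <- ll_p; gd_curr[mem] <- gd_p
        }
        if (adapting)
          sc_scale[g, p] <- min(max(
            sc_scale[g, p] * exp(gamma * (acc - target)), 1e-4), 10)
        else {
          acc_n["scale"] <- acc_n["scale"] + acc
          acc_d["scale"] <- acc_d["scale"] + 1
        }
        }
      }
      if (adapting) {
        # match the translation step to the location posterior spread
        mu_run_n <- mu_run_n + 1
        dmu <- mu - mu_run_m
        mu_run_m <- mu_run_m + dmu / mu_run_n
        mu_run_M2 <- mu_run_M2 + dmu * (mu - mu_run_m)
        if (mu_run_n > 50 && i %% refresh_every == 0)
          tr_sd <- pmax(1.4 * sqrt(mu_run_M2 / (mu_run_n - 1)),
                        matrix(c(0.002, 0.01, 0.02), G, 3, byrow = TRUE))
      }
    }

    draws[i, ] <- c(t(mu), t(sg), if (S > 0) as.vector(t(th)))
  }

  rates <- ifelse(acc_d > 0, acc_n / acc_d, NA)
  if (any(!is.na(rates) & rates < 0.01))
    stop("sampler diagnostic error: post-adaptation acceptance rate ",
         "below 1% (", paste(sprintf("%s=%.3f", names(rates), rates),
                             collapse = ", "), ")")
  list(draws = draws, acceptance = rates)
}

# ---- posterior samples container -------------------------------------------

#' Posterior samples container
#'
#' Stores per-chain MCMC draws with burn-in bookkeeping.  `draws` is an
#' `iterations x parameters x chains` array with parameter names of the
#' form `mu[task,group,param]`, `sigma[task,group,param]` and
#' `theta[task,subject,param]`.  Burn-in draws are stored but flagged:
#' every summary and diagnostic in the package uses only the retained
#' (post-burn-in) draws.
#'
#' @param draws 3-d array (or `iterations x chains` matrix for a single
#'   parameter) of draws with parameter dimnames.
#' @param burn_in number of leading iterations flagged as burn-in.
#' @param seed seed the run was made with (bookkeeping).
#' @param acceptance optional acceptance-rate log.
#' @return An object of class `posterior_samples`.
#' @export
posterior_samples <- function(draws, burn_in, seed = NA_integer_,
                              acceptance = NULL) {
  if (length(dim(draws)) == 2) {
    draws <- array(draws, c(nrow(draws), 1, ncol(draws)),
                   dimnames = list(NULL, "parameter", colnames(draws)))
  }
  stopifnot(length(dim(draws)) == 3, burn_in >= 0,
            burn_in < dim(draws)[1])
  structure(list(draws = draws, n_iterations = dim(draws)[1],
                 n_chains = dim(draws)[3], burn_in = burn_in, seed = seed,
                 acceptance = acceptance),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "posterior_samples: %d chain(s) x %d iterations (burn-in %d), %d parameters\n",
    x$n_chains, x$n_iterations, x$burn_in, dim(x$draws)[2]))
  cat(sprintf("retained draws: %d\n",
              x$n_chains * (x$n_iterations - x$burn_in)))
  invisible(x)
}

#' Retained (post-burn-in) draws
#'
#' @param samples a [posterior_samples] object.
#' @param parameter optional parameter name; if given, returns an
#'   `iterations x chains` matrix for that parameter, otherwise the full
#'   retained array.
#' @return Matrix or array of retained draws.
#' @export
retained_draws <- function(samples, parameter = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  keep <- (samples$burn_in + 1):samples$n_iterations
  if (is.null(parameter)) return(samples$draws[keep, , , drop = FALSE])
  if (!parameter %in% dimnames(samples$draws)[[2]])
    stop("unknown parameter: ", parameter)
  samples$draws[keep, parameter, ]
}

#' @rdname retained_draws
#' @export
parameter_names <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  dimnames(samples$draws)[[2]]
}

#' @rdname retained_draws
#' @param task,group,param components of a group-location parameter name.
#' @export
group_location_draws <- function(samples, task, group, param) {
  retained_draws(samples, sprintf("mu[%s,%s,%s]", task, group, param))
}
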