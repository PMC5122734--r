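# Truncated-normal log density (lower truncation only); x, mean, sd may be
# vectors of equal/recyclable length.  Returns -Inf below the bound and for
# non-positive sd.
dtnorm_log <- function(x, mean, sd, lower = -Inf) {
  sdp <- pmax(sd, .Machine$double.xmin)
  out <- dnorm(x, mean, sdp, log = TRUE) -
    pnorm(lower, mean, sdp, lower.tail = FALSE, log.p = TRUE)
  out[x < lower | !(sd > 0)] <- -Inf
  out
}

# Half-normal(0, sd) log density
dhalfnorm_log <- function(x, sd) {
  out <- dnorm(x, 0, sd, log = TRUE) + log(2)
  out[x <= 0] <- -Inf
  out
}

default_priors <- function() {
  list(location = list(t = list(mean = 0.4, sd = 0.3, lower = 0),
                       a = list(mean = 2.0, sd = 1.5, lower = 0),
                       v = list(mean = 2.0, sd = 3.0, lower = -Inf)),
       spread_sd = 1)
}

param_lower <- c(t = 0, a = 0, v = -Inf)

#' Declare a hierarchical diffusion-model specification
#'
#' One independent model per task.  Within each task, every individual has
#' free non-decision time `t`, boundary separation `a` and drift rate `v`,
#' drawn from normal distributions (truncated to the parameter domain)
#' whose location and spread are estimated per age group.  The starting
#' point is fixed at `z_rel = 0.5` for every individual and all
#' trial-to-trial variability parameters are fixed to 0.  The group-level
#' *location* parameters are the model's headline quantities: with 4 tasks
#' and 3 groups there are exactly 36 of them (12 per diffusion parameter);
#' the spread parameters are estimated but not part of that count.
#'
#' Priors are weakly informative: locations are truncated normals on each
#' parameter's natural domain (`t`: 0.4 +/- 0.3 s truncated at 0; `a`:
#' 2 +/- 1.5 truncated at 0; `v`: 2 +/- 3), spreads are half-normal(0, 1).
#'
#' @param tasks character vector of task labels (no duplicates).
#' @param groups character vector of group labels (no duplicates).
#' @param priors prior declarations; see `default_priors` in the package
#'   source for the structure.
#' @return An object of class `hier_spec`.
#' @examples
#' spec <- hier_spec(c("letter", "lexical", "phonological", "semantic"),
#'                   c("young", "high_old", "low_old"))
#' n_group_locations(spec) # 36
#' @export
hier_spec <- function(tasks, groups, priors = default_priors()) {
  tasks <- as.character(tasks); groups <- as.character(groups)
  if (!length(tasks) || !length(groups))
    stop("specification error: 'tasks' and 'groups' must be non-empty")
  if (anyDuplicated(tasks) || anyDuplicated(groups))
    stop("specification error: duplicate task or group labels")
  structure(list(tasks = tasks, groups = groups,
                 free_params = c("t", "a", "v"),
                 fixed = list(z_rel = 0.5, sv = 0, st = 0, sz = 0),
                 priors = priors),
            class = "hier_spec")
}

#' @rdname hier_spec
#' @param spec a `hier_spec` object.
#' @export
n_group_locations <- function(spec) {
  stopifnot(inherits(spec, "hier_spec"))
  length(spec$tasks) * length(spec$groups) * length(spec$free_params)
}

#' @export
print.hier_spec <- function(x, ...) {
  cat("Hierarchical diffusion-model specification\n")
  cat("  tasks:  ", paste(x$tasks, collapse = ", "), "\n")
  cat("  groups: ", paste(x$groups, collapse = ", "), "\n")
  cat("  free per individual: t, a, v; fixed: z_rel = 0.5,",
      "trial-to-trial variabilities = 0\n")
  cat("  group-location parameters:", n_group_locations(x), "\n")
  invisible(x)
}

#' Assemble a parameter state
#'
#' A parameter state holds, for every task in the specification, the
#' per-subject diffusion parameters (`theta`, subjects x `(t, a, v)`), the
#' group-level locations (`mu`, groups x parameters) and spreads (`sigma`).
#'
#' @param spec a [hier_spec] object.
#' @param subjects data frame with columns `subject_id` and `group`.
#' @param theta,mu,sigma either single matrices (recycled across tasks) or
#'   named lists of per-task matrices.  `theta` rows follow `subjects`,
#'   columns are `t, a, v`; `mu`/`sigma` rows follow `spec$groups`.
#' @return An object of class `parameter_state`.
#' @export
parameter_state <- function(spec, subjects, theta, mu, sigma) {
  stopifnot(inherits(spec, "hier_spec"))
  if (!all(c("subject_id", "group") %in% names(subjects)))
    stop("'subjects' needs columns subject_id and group")
  if (anyDuplicated(subjects$subject_id))
    stop("every subject must belong to exactly one group")
  if (!all(subjects$group %in% spec$groups))
    stop("unknown group label in 'subjects'")
  per_task <- function(x) {
    if (is.list(x) && !is.data.frame(x)) x
    else setNames(rep(list(x), length(spec$tasks)), spec$tasks)
  }
  theta <- per_task(theta); mu <- per_task(mu); sigma <- per_task(sigma)
  tasks <- setNames(lapply(spec$tasks, function(tk) {
    th <- as.matrix(theta[[tk]]); m <- as.matrix(mu[[tk]])
    sg <- as.matrix(sigma[[tk]])
    colnames(th) <- colnames(m) <- colnames(sg) <- spec$free_params
    rownames(th) <- subjects$subject_id
    rownames(m) <- rownames(sg) <- spec$groups
    list(theta = th, mu = m, sigma = sg)
  }), spec$tasks)
  structure(list(subjects = subjects[, c("subject_id", "group")],
                 tasks = tasks),
            class = "parameter_state")
}

# ---- log-posterior pieces ---------------------------------------------------

#' Log prior, group density and likelihood of a parameter state
#'
#' `log_posterior()` is the sum of three pieces: (i) the Wiener
#' first-passage log-likelihood of every trial under its subject's
#' diffusion parameters (accuracy coding: a correct response is an
#' upper-boundary passage), (ii) the log density of each individual
#' parameter under its group's truncated-normal distribution, and (iii) the
#' log prior of the group-level locations and spreads.  States violating a
#' parameter domain give `-Inf`.
#'
#' @param spec a [hier_spec] object.
#' @param state a [parameter_state] covering every subject in `trials`.
#' @param trials a preprocessed trial table (see [validate_trials()]).
#' @param tol density truncation tolerance passed to the likelihood.
#' @return A single log density.
#' @export
log_posterior <- function(spec, state, trials, tol = 1e-7) {
  log_prior(spec, state) + log_group_density(spec, state) +
    log_likelihood(spec, state, trials, tol)
}

#' @rdname log_posterior
#' @export
log_prior <- function(spec, state) {
  pr <- spec$priors
  total <- 0
  for (tk in spec$tasks) {
    st <- state$tasks[[tk]]
    for (p in spec$free_params) {
      lp <- pr$location[[p]]
      total <- total + sum(dtnorm_log(st$mu[, p], lp$mean, lp$sd, lp$lower)) +
        sum(dhalfnorm_log(st$sigma[, p], pr$spread_sd))
    }
  }
  total
}

#' @rdname log_posterior
#' @export
log_group_density <- function(spec, state) {
  total <- 0
  for (tk in spec$tasks) {
    st <- state$tasks[[tk]]
    gi <- match(state$subjects$group, spec$groups)
    for (p in spec$free_params) {
      total <- total + sum(dtnorm_log(st$theta[, p], st$mu[gi, p],
                                      st$sigma[gi, p], param_lower[[p]]))
    }
  }
  total
}

#' @rdname log_posterior
#' @export
log_likelihood <- function(spec, state, trials, tol = 1e-7) {
  validate_trials(trials)
  missing_subj <- setdiff(unique(trials$subject_id),
                          state$subjects$subject_id)
  if (length(missing_subj))
    stop("coverage error: no parameters for subject(s) ",
         paste(missing_subj, collapse = ", "))
  unknown <- setdiff(unique(trials$task), spec$tasks)
  if (length(unknown))
    stop("trials contain task(s) not in the specification: ",
         paste(unknown, collapse = ", "))
  total <- 0
  for (tk in intersect(spec$tasks, unique(trials$task))) {
    tr <- trials[trials$task == tk, ]
    st <- state$tasks[[tk]]
    si <- match(tr$subject_id, state$subjects$subject_id)
    ll <- wfpt_loglik_by_subject_cpp(
      tr$rt_ms / 1000, tr$correct, si,
      st$theta[, "t"], st$theta[, "a"], st$theta[, "v"],
      spec$fixed$z_rel, tol)
    # subjects with no trials in this task contribute 0, not their init of 0
    present <- seq_along(state$subjects$subject_id) %in% si
    total <- total + sum(ll[present])
  }
  total
}
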