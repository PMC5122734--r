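#' Trial table format
#'
#' Long-format trial tables have one row per trial with columns
#' `subject_id` (character), `group` (one of `young`, `high_old`,
#' `low_old`), `task` (one of `letter`, `lexical`, `phonological`,
#' `semantic`), `stimulus_type` (`target`/`nontarget`), `correct` (logical)
#' and `rt_ms` (milliseconds; `NA` for deadline non-responses).  Internal
#' model code works in seconds; the trial tables are the millisecond I/O
#' layer.
#'
#' @param trials a data frame to validate.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_trials <- function(trials) {
  need <- c("subject_id", "group", "task", "stimulus_type", "correct",
            "rt_ms")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols))
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  responded <- !is.na(trials$rt_ms)
  if (any(trials$rt_ms[responded] <= 0))
    stop("trial table contains non-positive RTs")
  if (any(is.na(trials$correct) & responded))
    stop("responded trials must have non-missing 'correct'")
  invisible(trials)
}

#' Read / write trial tables
#'
#' Plain CSV round trip for the trial table format described in
#' [validate_trials()].
#'
#' @param path file path.
#' @param trials a trial table.
#' @return `read_trials` returns the trial table; `write_trials` returns
#'   `path` invisibly.
#' @export
read_trials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  trials$correct <- as.logical(trials$correct)
  validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Remove fast guesses
#'
#' Excludes trials with response times strictly below `floor_ms` (default
#' 300 ms), the conventional guard against fast guesses contaminating
#' diffusion-model fits.  A 300 ms response is kept; 299 ms is removed.
#'
#' @param trials a trial table (see [validate_trials()]).
#' @param floor_ms exclusion floor in milliseconds, `> 0`.
#' @return A list with `trials` (kept rows, original order) and `n_removed`.
#' @export
exclude_fast_guesses <- function(trials, floor_ms = 300) {
  validate_trials(trials)
  stopifnot(floor_ms > 0)
  drop <- !is.na(trials$rt_ms) & trials$rt_ms < floor_ms
  list(trials = trials[!drop, , drop = FALSE], n_removed = sum(drop))
}

#' Remove per-cell standard-deviation outliers
#'
#' Within each subject x task x stimulus-type cell, computes the cell mean
#' and sample (n - 1) standard deviation once -- including any candidate
#' outliers -- and removes trials deviating from the cell mean by more than
#' `k` standard deviations (default 2.5).  The rule is applied in a single
#' pass, never iterated; cells with fewer than two trials are left
#' untouched.
#'
#' @inheritParams exclude_fast_guesses
#' @param k standard-deviation multiplier, `> 0`.
#' @return A list with `trials` (kept rows, original order), `n_removed`
#'   and `log` (per-cell removal counts for cells that lost trials).
#' @export
exclude_sd_outliers <- function(trials, k = 2.5) {
  validate_trials(trials)
  stopifnot(k > 0)
  cell <- interaction(trials$subject_id, trials$task, trials$stimulus_type,
                      drop = TRUE)
  drop <- logical(nrow(trials))
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    rts <- trials$rt_ms[idx]
    if (length(idx) < 2 || anyNA(rts)) next
    m <- mean(rts); s <- sd(rts)
    if (s == 0) next
    drop[idx[abs(rts - m) > k * s]] <- TRUE
  }
  removed_cells <- table(cell[drop])
  removed_cells <- removed_cells[removed_cells > 0]
  log <- data.frame(rule = rep("sd_outlier", length(removed_cells)),
                    cell = names(removed_cells),
                    n_removed = as.integer(removed_cells),
                    row.names = NULL)
  list(trials = trials[!drop, , drop = FALSE], n_removed = sum(drop),
       log = log)
}

#' Full trial-exclusion pipeline
#'
#' Drops deadline non-responses (logged, not an exclusion rule), then
#' applies the fast-guess floor, then the per-cell standard-deviation rule,
#' in that order.
#'
#' @inheritParams exclude_fast_guesses
#' @inheritParams exclude_sd_outliers
#' @return A list with `trials` (cleaned table), `n_input`, `n_kept` and
#'   `log` (data frame of rule, cell, n_removed).
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   group_sizes = c(young = 2, high_old = 2, low_old = 2),
#'   tasks = "letter", seed = 1))
#' pp <- preprocess_trials(cohort$trials)
#' pp$log
#' @export
preprocess_trials <- function(trials, floor_ms = 300, k = 2.5) {
  validate_trials(trials)
  n_input <- nrow(trials)
  nonresp <- is.na(trials$rt_ms)
  trials <- trials[!nonresp, , drop = FALSE]
  fg <- exclude_fast_guesses(trials, floor_ms)
  so <- exclude_sd_outliers(fg$trials, k)
  log <- rbind(
    data.frame(rule = "non_response", cell = "(all)",
               n_removed = sum(nonresp)),
    data.frame(rule = "fast_guess", cell = "(all)",
               n_removed = fg$n_removed),
    so$log)
  list(trials = so$trials, n_input = n_input, n_kept = nrow(so$trials),
       log = log)
}
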