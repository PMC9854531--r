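#' Signed prediction error
#'
#' `PE_t = target_t - estimate_t`: the gap between the revealed target and
#' the estimate the agent had committed to on that trial. Exact arithmetic,
#' no rounding.
#'
#' @param target,estimate Numeric vectors on the 0-50 bar.
#' @return `target - estimate`.
#' @examples
#' compute_prediction_error(32, 22)  # 10
#' @export
compute_prediction_error <- function(target, estimate) {
  target - estimate
}

#' Signed update
#'
#' `update_{t+1} = estimate_{t+1} - estimate_t`: the belief revision made
#' after observing the trial-`t` prediction error.
#'
#' @param estimate_next,estimate_now Numeric vectors on the 0-50 bar.
#' @return `estimate_next - estimate_now`.
#' @export
compute_update <- function(estimate_next, estimate_now) {
  estimate_next - estimate_now
}

#' Empirical per-trial learning rate
#'
#' The ratio `update / pe`, the per-trial proportionality between belief
#' revision and the preceding prediction error. Undefined (returned as
#' `NA`) when `|pe|` is below `epsilon_pe`: a ratio against a zero error
#' carries no information and is excluded from rate summaries.
#'
#' @param update,pe Numeric vectors (paired `update_{t+1}`, `pe_t`).
#' @param epsilon_pe Guard below which the ratio is undefined.
#' @return Numeric vector; `NA` where undefined.
#' @export
empirical_learning_rate <- function(update, pe, epsilon_pe = 1e-9) {
  out <- ifelse(abs(pe) >= epsilon_pe, update / pe, NA_real_)
  as.numeric(out)
}

#' Flag reaction times for exclusion
#'
#' Latencies strictly greater than `max_rt` seconds (default 3) are flagged
#' excluded; the boundary value itself is kept. Negative latencies are a
#' data error.
#'
#' @param table A `data.frame` with an `rt` column (seconds).
#' @param max_rt Exclusion threshold in seconds.
#' @return The table with a logical `rt_included` column; the number of
#'   exclusions is recorded in attribute `n_rt_excluded`.
#' @export
exclude_rts <- function(table, max_rt = 3) {
  stopifnot(is.data.frame(table), "rt" %in% names(table))
  if (any(table$rt < 0, na.rm = TRUE))
    stop("negative reaction times are not valid data", call. = FALSE)
  table$rt_included <- table$rt <= max_rt
  attr(table, "n_rt_excluded") <- sum(!table$rt_included, na.rm = TRUE)
  table
}

#' Code trial conditions as a baseline-referenced factor
#'
#' Builds the four-level condition factor with the randomly fluctuating
#' trials of the gradual block as reference, plus explicit dummy columns
#' for the other three levels (`d_gradually_changed`, `d_fluct_abrupt`,
#' `d_abruptly_changed`).
#'
#' @param table A `data.frame` with a character or factor `condition`
#'   column.
#' @return The table with `condition` converted to the ordered-level factor
#'   and the three dummy columns appended.
#' @export
code_conditions <- function(table) {
  stopifnot(is.data.frame(table), "condition" %in% names(table))
  lev <- condition_levels()
  cond <- as.character(table$condition)
  bad <- setdiff(unique(cond), lev)
  if (length(bad) > 0)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  table$condition <- factor(cond, levels = lev)
  for (l in lev[-1]) table[[paste0("d_", l)]] <- as.integer(cond == l)
  table
}

# Inverse of the dummy coding; used for round-trip checks.
decode_conditions <- function(table) {
  lev <- condition_levels()
  d <- as.matrix(table[paste0("d_", lev[-1])])
  idx <- 1L + as.integer(d %*% seq_len(3))
  lev[idx]
}

#' Build the trial-level analysis table
#'
#' Turns a raw cohort table into the table the models are fit on:
#' * pairs each trial's prediction error `pe_t` with the following update
#'   `update_{t+1}` (column `update_next`); the last trial of each
#'   participant-block has no paired update and carries `NA` there,
#' * adds absolute transforms `abs_pe` and `abs_update`,
#' * adds the guarded empirical learning rate,
#' * applies the reaction-time exclusion ([exclude_rts()]),
#' * codes the condition factor and dummies ([code_conditions()]).
#'
#' @param cohort A cohort table from [simulate_cohort()] (or a CSV read
#'   back by [read_cohort_csv()]).
#' @param max_rt RT exclusion threshold in seconds.
#' @param epsilon_pe Guard for the empirical learning rate.
#' @return An `analysis_table` (`data.frame`), ordered by participant,
#'   block and trial.
#' @export
build_analysis_table <- function(cohort, max_rt = 3, epsilon_pe = 1e-9) {
  stopifnot(is.data.frame(cohort),
            all(c("participant_id", "block", "trial", "target", "estimate",
                  "pe", "rt", "condition") %in% names(cohort)))
  tab <- as.data.frame(cohort)
  tab <- tab[order(tab$participant_id, tab$block, tab$trial), , drop = FALSE]

  key <- paste(tab$participant_id, tab$block)
  last_of_block <- c(key[-1] != key[-length(key)], TRUE)
  nxt_estimate <- c(tab$estimate[-1], NA_real_)
  tab$update_next <- ifelse(last_of_block, NA_real_,
                            compute_update(nxt_estimate, tab$estimate))

  tab$abs_pe <- abs(tab$pe)
  tab$abs_update <- abs(tab$update_next)
  tab$empirical_lr <- empirical_learning_rate(tab$update_next, tab$pe,
                                              epsilon_pe)
  tab <- exclude_rts(tab, max_rt = max_rt)
  tab <- code_conditions(tab)
  rownames(tab) <- NULL
  class(tab) <- c("analysis_table", "data.frame")
  tab
}
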