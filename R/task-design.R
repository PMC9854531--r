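#' Segment specification for a block schedule
#'
#' A segment is a run of trials whose target values share one generating
#' Gaussian. The trend tag says how the segment behaves within the block:
#' `randomly_fluctuate` segments have no within-segment ordering,
#' `gradually_increase`/`gradually_decrease` segments are reordered to show a
#' fluctuating monotone trend, and `abruptly_increase`/`abruptly_decrease`
#' segments mark the single trial on which the generating mean jumps.
#'
#' @param mean Mean of the generating Gaussian, on the 0-50 estimation bar.
#' @param sd Standard deviation of the generating Gaussian (> 0).
#' @param n_trials Number of trials in the segment (>= 1).
#' @param trend One of `"randomly_fluctuate"`, `"gradually_increase"`,
#'   `"gradually_decrease"`, `"abruptly_increase"`, `"abruptly_decrease"`.
#' @return A one-row `data.frame` with columns `mean`, `sd`, `n_trials`,
#'   `trend`.
#' @export
segment_spec <- function(mean, sd, n_trials, trend) {
  trends <- c("randomly_fluctuate", "gradually_increase", "gradually_decrease",
              "abruptly_increase", "abruptly_decrease")
  trend <- match.arg(trend, trends)
  if (!is.numeric(mean) || mean < 0 || mean > 50)
    stop("segment mean must lie on the 0-50 estimation bar", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0)
    stop("segment sd must be positive", call. = FALSE)
  if (n_trials < 1 || n_trials != round(n_trials))
    stop("n_trials must be a positive integer", call. = FALSE)
  data.frame(mean = mean, sd = sd, n_trials = as.integer(n_trials),
             trend = trend, stringsAsFactors = FALSE)
}

#' Block schedule: an ordered list of segments
#'
#' @param block_kind `"gradual"` or `"abrupt"`.
#' @param segments A `data.frame` of stacked [segment_spec()] rows.
#' @return An object of class `block_schedule` with elements `block_kind`,
#'   `segments` and `total_trials`.
#' @export
block_schedule <- function(block_kind = c("gradual", "abrupt"), segments) {
  block_kind <- match.arg(block_kind)
  stopifnot(is.data.frame(segments),
            all(c("mean", "sd", "n_trials", "trend") %in% names(segments)))
  structure(
    list(block_kind = block_kind,
         segments = segments,
         total_trials = sum(segments$n_trials)),
    class = "block_schedule"
  )
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule: %s block, %d trials, %d segments>\n",
              x$block_kind, x$total_trials, nrow(x$segments)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Canonical two-block task schedules
#'
#' Returns the fixed schedule of the estimation task. Both blocks have 100
#' trials of Gaussian targets with SD 1.7 on a 0-50 bar. In the gradual
#' block the mean follows 25 (20 trials) then 30, 35, 30, 25, 20, 15, 20, 25
#' in 10-trial segments, alternating fluctuation and gradual drift. In the
#' abrupt block the mean stays at 25 for 29 trials and then jumps to 35, 25,
#' 15 and back to 25, each jump landing on a single abruptly changed trial
#' (1-based trials 30, 50, 70 and 90) followed by a fluctuation run.
#'
#' @param block_kind `"gradual"` or `"abrupt"`.
#' @return A [block_schedule()].
#' @examples
#' canonical_schedule("gradual")$total_trials  # 100
#' @export
canonical_schedule <- function(block_kind = c("gradual", "abrupt")) {
  block_kind <- match.arg(block_kind)
  sd0 <- 1.7
  if (block_kind == "gradual") {
    seg <- rbind(
      segment_spec(25, sd0, 20, "randomly_fluctuate"),
      segment_spec(30, sd0, 10, "gradually_increase"),
      segment_spec(35, sd0, 10, "randomly_fluctuate"),
      segment_spec(30, sd0, 10, "gradually_decrease"),
      segment_spec(25, sd0, 10, "randomly_fluctuate"),
      segment_spec(20, sd0, 10, "gradually_decrease"),
      segment_spec(15, sd0, 10, "randomly_fluctuate"),
      segment_spec(20, sd0, 10, "gradually_increase"),
      segment_spec(25, sd0, 10, "randomly_fluctuate")
    )
  } else {
    # Each abrupt jump is its own single-trial segment so that exactly the
    # first trial of the new distribution carries the abrupt label.
    seg <- rbind(
      segment_spec(25, sd0, 29, "randomly_fluctuate"),
      segment_spec(35, sd0, 1,  "abruptly_increase"),
      segment_spec(35, sd0, 19, "randomly_fluctuate"),
      segment_spec(25, sd0, 1,  "abruptly_decrease"),
      segment_spec(25, sd0, 19, "randomly_fluctuate"),
      segment_spec(15, sd0, 1,  "abruptly_decrease"),
      segment_spec(15, sd0, 19, "randomly_fluctuate"),
      segment_spec(25, sd0, 1,  "abruptly_increase"),
      segment_spec(25, sd0, 10, "randomly_fluctuate")
    )
  }
  block_schedule(block_kind, seg)
}

#' Condition labels for every trial of a schedule
#'
#' Deterministic labelling: fluctuation segments are labelled
#' `fluct_gradual`/`fluct_abrupt` according to the block, gradual drift
#' segments `gradually_changed`, and single abrupt-jump trials
#' `abruptly_changed`.
#'
#' @param schedule A [block_schedule()].
#' @return Character vector of length `total_trials`, one label per trial
#'   (1-based trial order).
#' @export
label_trials <- function(schedule) {
  stopifnot(inherits(schedule, "block_schedule"))
  seg <- schedule$segments
  lab <- vapply(seg$trend, function(tr) {
    switch(tr,
      randomly_fluctuate = if (schedule$block_kind == "gradual")
        "fluct_gradual" else "fluct_abrupt",
      gradually_increase = ,
      gradually_decrease = "gradually_changed",
      abruptly_increase = ,
      abruptly_decrease = "abruptly_changed")
  }, character(1))
  rep(unname(lab), seg$n_trials)
}

#' Sample a target sequence from a block schedule
#'
#' Draws each segment's targets i.i.d. from its Gaussian, clips to the
#' 0-50 bar and rounds to one decimal. Within the gradual block,
#' consecutive targets are constrained to differ by at most `max_step`
#' units (the pseudo-random smoothness constraint that prevents a gradual
#' block from containing an incidental abrupt jump); violating draws are
#' resampled from the segment distribution truncated to the admissible
#' window. Abrupt-block transitions are never step-constrained.
#'
#' With the default `trend_realization = "iid"` every trial of a segment
#' is an independent draw from the segment Gaussian, exactly as the
#' schedule table states; the gradual trend is carried by the inserted
#' intermediate distribution (the segment means rise 25, 30, 35 while
#' consecutive distributions overlap). The alternative `"sorted"`
#' realization additionally reorders each drifting segment's draws to be
#' monotone (plus `trend_jitter` noise), producing a strictly monotone
#' within-segment path at the cost of the per-trial marginal distribution:
#' sorted draws are order statistics with much lower local variability
#' than the segment Gaussian.
#'
#' @param schedule A [block_schedule()].
#' @param seed Integer seed; the sequence is reproducible given the seed.
#' @param max_step Largest admissible absolute difference between
#'   consecutive targets in a gradual block (default 6 target units).
#' @param trend_realization `"iid"` (default) or `"sorted"`; see Details.
#' @param trend_jitter SD of the jitter added after sorting trend segments
#'   (`"sorted"` realization only, default 0.5).
#' @param max_attempts Resampling attempts per trial before failing.
#' @return A `task_sequence`: a `data.frame` with columns `trial` (1-based),
#'   `target`, `condition`, plus attributes `block_kind`, `seed` and
#'   `raw_draws` (the i.i.d. segment draws before trend reordering, clipping
#'   and rounding, for distributional diagnostics).
#' @export
sample_targets <- function(schedule, seed, max_step = 6,
                           trend_realization = c("iid", "sorted"),
                           trend_jitter = 0.5, max_attempts = 100L) {
  trend_realization <- match.arg(trend_realization)
  stopifnot(inherits(schedule, "block_schedule"))
  if (!is.numeric(max_step) || max_step <= 0)
    stop("max_step must be positive", call. = FALSE)
  set.seed(substream_seed(seed, "targets"))
  seg <- schedule$segments
  raw <- vector("list", nrow(seg))
  vals <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    n <- seg$n_trials[i]
    draws <- rnorm(n, seg$mean[i], seg$sd[i])
    raw[[i]] <- draws
    x <- if (trend_realization == "sorted") {
      switch(seg$trend[i],
        gradually_increase = sort(draws) + rnorm(n, 0, trend_jitter),
        gradually_decrease = sort(draws, decreasing = TRUE) +
          rnorm(n, 0, trend_jitter),
        draws)
    } else draws
    vals[[i]] <- round(clip01(x), 1)
  }
  targets <- unlist(vals, use.names = FALSE)

  if (schedule$block_kind == "gradual") {
    seg_of <- rep(seq_len(nrow(seg)), seg$n_trials)
    for (t in 2:length(targets)) {
      attempts <- 0L
      while (abs(targets[t] - targets[t - 1]) > max_step) {
        attempts <- attempts + 1L
        mu <- seg$mean[seg_of[t]]
        s <- seg$sd[seg_of[t]]
        lo <- max(0, targets[t - 1] - max_step)
        hi <- min(50, targets[t - 1] + max_step)
        pa <- stats::pnorm(lo, mu, s)
        pb <- stats::pnorm(hi, mu, s)
        if (attempts > max_attempts || pb - pa < 1e-12)
          stop(sprintf(
            "could not satisfy max_step = %g in segment %d of the gradual block",
            max_step, seg_of[t]), call. = FALSE)
        # segment Gaussian truncated to the admissible window
        cand <- stats::qnorm(runif(1, pa, pb), mu, s)
        targets[t] <- round(clip01(cand), 1)
      }
    }
  }

  out <- data.frame(trial = seq_along(targets), target = targets,
                    condition = label_trials(schedule),
                    stringsAsFactors = FALSE)
  attr(out, "block_kind") <- schedule$block_kind
  attr(out, "seed") <- seed
  attr(out, "raw_draws") <- raw
  class(out) <- c("task_sequence", "data.frame")
  out
}

#' @export
print.task_sequence <- function(x, ...) {
  cat(sprintf("<task_sequence: %s block, %d trials, seed %s>\n",
              attr(x, "block_kind"), nrow(x), format(attr(x, "seed"))))
  print(head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat(sprintf("... %d more trials\n", nrow(x) - 8))
  invisible(x)
}
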