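#' Generative update-rule parameters
#'
#' Parameters of the delta-rule updater that turns a trial's prediction
#' error into the next estimate change. Two modes are supported:
#'
#' * `"linear"`: the expected absolute update is
#'   `intercept_c + lr_c * |PE|` with a separate intercept and learning rate
#'   per trial condition. The defaults are the condition composites of the
#'   fitted condition-by-PE mixed model (baseline intercept 1.017 and
#'   learning rate 0.528; gradually changed 1.039 / 0.533; fluctuating
#'   trials of the abrupt block 0.756 / 0.595; abruptly changed 2.548 /
#'   0.693).
#' * `"segmented"`: the expected absolute update is a continuous broken
#'   line in `|PE|`, `beta0 + beta1 * |PE| + delta * max(0, |PE| - psi)`:
#'   below the breakpoint `psi` the learning rate is `beta1`, above it the
#'   rate increases by `delta` (surprise-gated updating). Defaults
#'   `beta0 = 0.916`, `beta1 = 0.536`, `delta = 0.536`, `psi = 5.337`.
#'
#' The realized signed update is `sign(PE) * m(|PE|)` plus Gaussian noise,
#' and with probability `p_no_update` a trial's update is exactly zero
#' (a minority of trials show no belief revision at all).
#'
#' @param mode `"linear"` or `"segmented"`.
#' @param intercept_by_condition,lr_by_condition Named numeric vectors over
#'   the four conditions (linear mode).
#' @param beta0,beta1,delta,psi Broken-line parameters (segmented mode);
#'   `psi` is in absolute-PE units.
#' @param update_noise_sd SD of additive update noise, in target units.
#' @param p_no_update Probability that a trial's update is exactly 0.
#' @return An object of class `update_rule_params`.
#' @export
update_rule_params <- function(mode = c("linear", "segmented"),
                               intercept_by_condition = c(
                                 fluct_gradual = 1.017,
                                 gradually_changed = 1.039,
                                 fluct_abrupt = 0.756,
                                 abruptly_changed = 2.548),
                               lr_by_condition = c(
                                 fluct_gradual = 0.528,
                                 gradually_changed = 0.533,
                                 fluct_abrupt = 0.595,
                                 abruptly_changed = 0.693),
                               beta0 = 0.916, beta1 = 0.536,
                               delta = 0.536, psi = 5.337,
                               update_noise_sd = 1.5, p_no_update = 0.05) {
  mode <- match.arg(mode)
  lev <- condition_levels()
  stopifnot(all(lev %in% names(intercept_by_condition)),
            all(lev %in% names(lr_by_condition)))
  if (any(lr_by_condition < 0 | lr_by_condition > 1.5))
    stop("learning rates must lie in [0, 1.5]", call. = FALSE)
  if (psi <= 0) stop("psi must be positive", call. = FALSE)
  if (update_noise_sd < 0) stop("update_noise_sd must be >= 0", call. = FALSE)
  if (p_no_update < 0 || p_no_update >= 1)
    stop("p_no_update must lie in [0, 1)", call. = FALSE)
  structure(
    list(mode = mode,
         intercept_by_condition = intercept_by_condition[lev],
         lr_by_condition = lr_by_condition[lev],
         beta0 = beta0, beta1 = beta1, delta = delta, psi = psi,
         update_noise_sd = update_noise_sd, p_no_update = p_no_update),
    class = "update_rule_params"
  )
}

# Expected absolute update as a function of absolute PE and condition,
# with optional per-agent shifts of intercept and slope.
update_mean_fn <- function(params, abs_pe, condition,
                           intercept_shift = 0, lr_shift = 0) {
  if (params$mode == "linear") {
    (params$intercept_by_condition[condition] + intercept_shift) +
      (params$lr_by_condition[condition] + lr_shift) * abs_pe
  } else {
    (params$beta0 + intercept_shift) +
      (params$beta1 + lr_shift) * abs_pe +
      params$delta * pmax(0, abs_pe - params$psi)
  }
}

#' Generative reaction-time parameters
#'
#' The secondary letter-discrimination task yields one latency per trial.
#' The generative model is condition-mean based: surprise enters through a
#' raised mean on abruptly changed trials. Defaults are the observed
#' condition means (0.883, 0.850, 0.855 and 1.105 s). Each agent gets a
#' random latency intercept; a small fraction of trials receive an
#' exponential slow tail (attentional lapses) which exercises the 3-second
#' exclusion rule downstream. Latencies are truncated below at `rt_floor`.
#'
#' @param mean_by_condition Named numeric vector of mean RTs (seconds).
#' @param rt_noise_sd Trial-level Gaussian RT noise SD (seconds).
#' @param participant_rt_sd SD of the per-agent latency intercept (seconds).
#' @param p_lapse Probability of adding an exponential slow tail to a trial.
#' @param lapse_mean Mean of the exponential tail (seconds).
#' @param rt_floor Lower truncation for generated RTs (seconds).
#' @return An object of class `rt_params`.
#' @export
rt_params <- function(mean_by_condition = c(fluct_gradual = 0.883,
                                            gradually_changed = 0.850,
                                            fluct_abrupt = 0.855,
                                            abruptly_changed = 1.105),
                      rt_noise_sd = 0.3, participant_rt_sd = 0.15,
                      p_lapse = 0.02, lapse_mean = 2, rt_floor = 0.15) {
  lev <- condition_levels()
  stopifnot(all(lev %in% names(mean_by_condition)))
  if (any(mean_by_condition <= 0)) stop("RT means must be positive", call. = FALSE)
  if (rt_noise_sd < 0 || participant_rt_sd < 0)
    stop("RT noise sds must be >= 0", call. = FALSE)
  if (p_lapse < 0 || p_lapse >= 1) stop("p_lapse must lie in [0, 1)", call. = FALSE)
  structure(
    list(mean_by_condition = mean_by_condition[lev],
         rt_noise_sd = rt_noise_sd, participant_rt_sd = participant_rt_sd,
         p_lapse = p_lapse, lapse_mean = lapse_mean, rt_floor = rt_floor),
    class = "rt_params"
  )
}

#' Cohort specification
#'
#' @param n_agents Number of simulated participants (default 109).
#' @param seed Integer seed governing every random draw of the cohort.
#' @param participant_lr_sd SD of the per-agent learning-rate (slope)
#'   perturbation.
#' @param participant_intercept_sd SD of the per-agent update-intercept
#'   perturbation.
#' @param counterbalance If `TRUE` (default), half the agents see the
#'   abrupt block first (alternating deterministically by agent index).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_agents = 109, seed = 1,
                        participant_lr_sd = 0.1,
                        participant_intercept_sd = 0.3,
                        counterbalance = TRUE) {
  if (n_agents < 1 || n_agents != round(n_agents))
    stop("n_agents must be a positive integer", call. = FALSE)
  if (participant_lr_sd < 0 || participant_intercept_sd < 0)
    stop("random-effect sds must be >= 0", call. = FALSE)
  structure(
    list(n_agents = as.integer(n_agents), seed = seed,
         participant_lr_sd = participant_lr_sd,
         participant_intercept_sd = participant_intercept_sd,
         counterbalance = isTRUE(counterbalance)),
    class = "cohort_spec"
  )
}

#' Simulate one agent on one task sequence
#'
#' The agent starts at the bar midpoint (estimate 25), computes the signed
#' prediction error `PE_t = target_t - estimate_t` on every trial, and
#' moves its estimate by `sign(PE_t) * m(|PE_t|) + noise`, where `m` is the
#' mode's mean function ([update_rule_params()]); with probability
#' `p_no_update` the move is exactly zero. Estimates are clipped to the
#' 0-50 bar and the stored update is always the realized estimate change,
#' so estimates telescope exactly. RTs follow the condition mean plus agent
#' and trial noise, with occasional exponential lapses.
#'
#' @param task A `task_sequence` from [sample_targets()].
#' @param update_params An [update_rule_params()] object.
#' @param rt_params_ An [rt_params()] object.
#' @param agent_effects List with numeric elements `intercept`, `lr`, `rt`:
#'   this agent's deviations from the population parameters.
#' @param seed Integer seed.
#' @return A `data.frame` with one row per trial: `trial`, `condition`,
#'   `target`, `estimate`, `pe`, `update` (realized change from the previous
#'   trial, `NA` on trial 1), `rt`, `letter`, `response`.
#' @export
simulate_agent <- function(task, update_params = update_rule_params(),
                           rt_params_ = rt_params(),
                           agent_effects = list(intercept = 0, lr = 0, rt = 0),
                           seed = 1) {
  stopifnot(inherits(task, "task_sequence"),
            inherits(update_params, "update_rule_params"),
            inherits(rt_params_, "rt_params"))
  n <- nrow(task)
  set.seed(substream_seed(seed, "agent"))
  upd_noise <- rnorm(n, 0, update_params$update_noise_sd)
  no_update <- runif(n) < update_params$p_no_update
  # direction is undefined at PE exactly 0 (the mean function still gives a
  # positive magnitude); break the tie at random
  dir_tie <- sample(c(-1, 1), n, replace = TRUE)
  rt_noise <- rnorm(n, 0, rt_params_$rt_noise_sd)
  lapse <- runif(n) < rt_params_$p_lapse
  lapse_amt <- rexp(n, rate = 1 / rt_params_$lapse_mean)
  letter <- sample(c("L", "R"), n, replace = TRUE)

  estimate <- numeric(n)
  pe <- numeric(n)
  estimate[1] <- 25
  for (t in seq_len(n)) {
    pe[t] <- task$target[t] - estimate[t]
    if (t < n) {
      if (no_update[t]) {
        step <- 0
      } else {
        m <- update_mean_fn(update_params, abs(pe[t]), task$condition[t],
                            agent_effects$intercept, agent_effects$lr)
        dir <- if (pe[t] == 0) dir_tie[t] else sign(pe[t])
        step <- dir * m + upd_noise[t]
      }
      estimate[t + 1] <- clip01(estimate[t] + step)
    }
  }

  rt <- rt_params_$mean_by_condition[task$condition] + agent_effects$rt +
    rt_noise + ifelse(lapse, lapse_amt, 0)
  rt <- pmax(rt_params_$rt_floor, rt)

  data.frame(
    trial = task$trial,
    condition = task$condition,
    target = task$target,
    estimate = estimate,
    pe = pe,
    update = c(NA_real_, diff(estimate)),
    rt = as.numeric(rt),
    letter = letter,
    response = ifelse(letter == "L", "left", "right"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of agents on the two-block task
#'
#' Each agent receives its own sampled target sequences (fresh draws from
#' the canonical schedules), a once-drawn triple of random effects
#' (update intercept, learning-rate slope, RT intercept), and a
#' counterbalanced block order. All randomness derives from `spec$seed`
#' through fixed substreams, so the cohort is fully reproducible.
#'
#' @param spec A [cohort_spec()].
#' @param update_params An [update_rule_params()] object.
#' @param rt_params_ An [rt_params()] object.
#' @param schedules Named list with elements `gradual` and `abrupt`
#'   ([block_schedule()] objects); defaults to the canonical schedules.
#' @param max_step Smoothness constraint passed to [sample_targets()].
#' @return A `cohort_table`: a `data.frame` with columns `participant_id`,
#'   `block`, `order` (1 = seen first), `trial`, `condition`, `target`,
#'   `estimate`, `pe`, `update`, `rt`, `letter`, `response`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_agents = 2, seed = 42))
#' nrow(cohort)  # 2 agents x 2 blocks x 100 trials = 400
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            update_params = update_rule_params(),
                            rt_params_ = rt_params(),
                            schedules = NULL, max_step = 6) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(schedules)) {
    schedules <- list(gradual = canonical_schedule("gradual"),
                      abrupt = canonical_schedule("abrupt"))
  }
  stopifnot(all(c("gradual", "abrupt") %in% names(schedules)))

  set.seed(substream_seed(spec$seed, "effects"))
  eff_int <- rnorm(spec$n_agents, 0, spec$participant_intercept_sd)
  eff_lr <- rnorm(spec$n_agents, 0, spec$participant_lr_sd)
  eff_rt <- rnorm(spec$n_agents, 0, rt_params_$participant_rt_sd)

  id_width <- max(3L, nchar(as.character(spec$n_agents)))
  rows <- vector("list", spec$n_agents * 2L)
  k <- 0L
  for (i in seq_len(spec$n_agents)) {
    order_blocks <- if (spec$counterbalance && i %% 2L == 0L)
      c("abrupt", "gradual") else c("gradual", "abrupt")
    for (j in seq_along(order_blocks)) {
      bk <- order_blocks[j]
      task <- sample_targets(schedules[[bk]],
                             seed = substream_seed(spec$seed, paste0("task_", bk), i),
                             max_step = max_step)
      tr <- simulate_agent(task, update_params, rt_params_,
                           agent_effects = list(intercept = eff_int[i],
                                                lr = eff_lr[i],
                                                rt = eff_rt[i]),
                           seed = substream_seed(spec$seed, paste0("sim_", bk), i))
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(participant_id = sprintf(paste0("S%0", id_width, "d"), i),
                   block = bk, order = j, stringsAsFactors = FALSE),
        tr
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  attr(out, "update_params") <- update_params
  attr(out, "rt_params") <- rt_params_
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<cohort_table: %d rows, %d agents, seed %s>\n",
              nrow(x), length(unique(x$participant_id)),
              if (is.null(sp)) "?" else format(sp$seed)))
  print(head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Zero-noise parameter presets
#'
#' Convenience constructors for noise-free deterministic cohorts used in
#' identifiability checks: no update noise, no non-updating trials, no
#' participant heterogeneity, no RT noise or lapses.
#'
#' @param mode Update-rule mode passed to [update_rule_params()].
#' @param ... Overrides passed through to the underlying constructor.
#' @return A list with elements `update`, `rt` and a `spec_args` list to
#'   splice into [cohort_spec()].
#' @export
zero_noise_params <- function(mode = c("linear", "segmented"), ...) {
  mode <- match.arg(mode)
  list(
    update = update_rule_params(mode = mode, update_noise_sd = 0,
                                p_no_update = 0, ...),
    rt = rt_params(rt_noise_sd = 0, participant_rt_sd = 0, p_lapse = 0),
    spec_args = list(participant_lr_sd = 0, participant_intercept_sd = 0)
  )
}
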