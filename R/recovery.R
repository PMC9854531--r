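#' Parameter recovery on synthetic cohorts
#'
#' Simulates `n_replicates` cohorts from known generative parameters,
#' refits the matching update model on each (the condition-by-PE model for
#' linear-mode cohorts, the segmented breakpoint model for segmented-mode
#' cohorts), and tabulates bias, RMSE and confidence-interval coverage per
#' parameter. This is the validation surface for estimators whose human
#' target data are not reproducible.
#'
#' @param spec A [cohort_spec()]; its `seed` is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param update_params Generative [update_rule_params()]; its `mode`
#'   selects the refitted model.
#' @param rt_params_ Generative [rt_params()].
#' @param n_replicates Number of simulate-fit replicates (>= 1).
#' @param seed Master seed; replicate `r` uses a fixed substream of it.
#' @param conf_level Coverage level for the per-parameter intervals
#'   (Wald for regression coefficients, profile for the breakpoint).
#' @param ... Passed to [fit_segmented_model()] (e.g. `psi_step`).
#' @return An object of class `recovery_report`: `summary` (data.frame
#'   with parameter, truth, mean_estimate, bias, rmse, coverage, n_ok),
#'   `replicates` (per-replicate estimates), `seeds`, `n_failed`.
#' @export
run_recovery <- function(spec = cohort_spec(),
                         update_params = update_rule_params(),
                         rt_params_ = rt_params(),
                         n_replicates = 10, seed = 1,
                         conf_level = 0.95, ...) {
  stopifnot(n_replicates >= 1)
  seeds <- vapply(seq_len(n_replicates),
                  function(r) substream_seed(seed, "recovery", r), integer(1))
  zcrit <- -stats::qnorm((1 - conf_level) / 2)

  if (update_params$mode == "linear") {
    truth <- c(setNames(update_params$lr_by_condition,
                        paste0("lr_", condition_levels())))
  } else {
    truth <- c(beta0 = update_params$beta0, beta1 = update_params$beta1,
               delta = update_params$delta, psi = update_params$psi)
  }

  reps <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    sp <- spec
    sp$seed <- seeds[r]
    res <- tryCatch({
      cohort <- simulate_cohort(sp, update_params, rt_params_)
      tab <- build_analysis_table(cohort)
      if (update_params$mode == "linear") {
        fit <- fit_condition_lr_model(tab)
        est <- setNames(fit$composite_lr, names(truth))
        se <- fit$composite_lr_se
        lo <- est - zcrit * se
        hi <- est + zcrit * se
      } else {
        fit <- suppressWarnings(
          fit_segmented_model(tab, conf_level = conf_level, ...))
        co <- fit$coefficients
        est <- c(beta0 = fit$beta0, beta1 = fit$beta1, delta = fit$delta,
                 psi = fit$psi)
        se <- c(co$se[co$term == "(Intercept)"], co$se[co$term == "abs_pe"],
                co$se[co$term == "(abs_pe - psi)+"], NA)
        lo <- est - zcrit * se
        hi <- est + zcrit * se
        lo["psi"] <- fit$psi_ci[1]
        hi["psi"] <- fit$psi_ci[2]
      }
      data.frame(replicate = r, seed = seeds[r], parameter = names(truth),
                 truth = as.numeric(truth), estimate = as.numeric(est),
                 ci_lo = as.numeric(lo), ci_hi = as.numeric(hi),
                 row.names = NULL, stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else reps[[r]] <- res
  }
  reps <- do.call(rbind, reps)
  if (is.null(reps)) stop("every recovery replicate failed", call. = FALSE)

  summarize <- function(d) {
    err <- d$estimate - d$truth
    cov <- !is.na(d$ci_lo) & !is.na(d$ci_hi) &
      d$truth >= d$ci_lo & d$truth <= d$ci_hi
    data.frame(parameter = d$parameter[1], truth = d$truth[1],
               mean_estimate = mean(d$estimate), bias = mean(err),
               rmse = sqrt(mean(err^2)),
               coverage = mean(cov), n_ok = nrow(d),
               stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, lapply(split(reps, reps$parameter), summarize))
  summary <- summary[match(names(truth), summary$parameter), , drop = FALSE]
  rownames(summary) <- NULL

  structure(list(summary = summary, replicates = reps, seeds = seeds,
                 n_replicates = n_replicates, n_failed = n_failed,
                 mode = update_params$mode, conf_level = conf_level),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery (%s mode, %d replicates, %d failed)\n",
              x$mode, x$n_replicates, x$n_failed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
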