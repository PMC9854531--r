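## Mixed-model backbone shared by the inference battery.
##
## All update/RT models are linear mixed models with a participant random
## intercept, estimated by maximum likelihood (REML = FALSE) so that
## log-likelihoods are comparable across fixed-effect structures (needed by
## the breakpoint profile). Inference on fixed effects uses Wald statistics
## with a normal reference. Noise-free cohorts make the variance components
## unidentifiable (residual variance ~ 0); in that degenerate case the fit
## falls back to ordinary least squares, flagged engine = "ols".

fit_mm <- function(fixed_formula, data, group = "participant_id",
                   degenerate_tol = 1e-6) {
  mf <- stats::model.frame(fixed_formula, data = data, na.action = stats::na.omit)
  ols <- lm(fixed_formula, data = data)
  degenerate <- sigma(ols) < degenerate_tol
  if (degenerate) {
    return(list(engine = "ols", fit = ols, logLik = as.numeric(logLik(ols)),
                ranef_var = 0, converged = TRUE, singular = TRUE,
                nobs = nrow(mf)))
  }
  full <- stats::update(fixed_formula,
                        paste(". ~ . +", sprintf("(1 | %s)", group)))
  fit <- lme4::lmer(full, data = data, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      optCtrl = list(ftol_abs = 1e-8, xtol_abs = 1e-8)))
  msgs <- fit@optinfo$conv$lme4$messages
  list(engine = "lmer", fit = fit, logLik = as.numeric(logLik(fit)),
       ranef_var = as.numeric(lme4::VarCorr(fit)[[group]][1, 1]),
       converged = is.null(msgs) || !any(grepl("failed to converge", msgs)),
       singular = lme4::isSingular(fit), nobs = stats::nobs(fit))
}

# Fixed-effect table with Wald z statistics (normal reference).
tidy_fixef <- function(mm) {
  if (mm$engine == "ols") {
    est <- coef(mm$fit)
    # suppress the "essentially perfect fit" warning on noise-free data
    se <- sqrt(diag(suppressWarnings(vcov(mm$fit))))
  } else {
    est <- lme4::fixef(mm$fit)
    se <- sqrt(diag(as.matrix(vcov(mm$fit))))
  }
  z <- est / se
  data.frame(term = names(est), estimate = as.numeric(est),
             se = as.numeric(se), z = as.numeric(z),
             p = 2 * pnorm(-abs(z)), row.names = NULL,
             stringsAsFactors = FALSE)
}

fixef_vcov <- function(mm) {
  as.matrix(suppressWarnings(vcov(mm$fit)))
}

check_analysis_table <- function(table, need_levels = TRUE, min_participants = 2L) {
  stopifnot(is.data.frame(table))
  req <- c("participant_id", "abs_pe", "abs_update",
           if (need_levels) "condition")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("analysis table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(table$participant_id)) < min_participants)
    stop("at least ", min_participants, " participants are required",
         call. = FALSE)
  if (need_levels) {
    present <- unique(as.character(table$condition))
    absent <- setdiff(condition_levels(), present)
    if (length(absent))
      stop("condition level(s) absent from the data: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

#' Condition-by-prediction-error learning-rate model
#'
#' Fits the mixed linear model
#' `abs_update ~ abs_pe * condition + (1 | participant)` by maximum
#' likelihood: the absolute update regressed on the absolute prediction
#' error, the change-mode condition (baseline: randomly fluctuating trials
#' of the gradual block) and their interaction. The coefficient on `abs_pe`
#' is the baseline learning rate; each interaction adds that condition's
#' learning-rate offset. Composite per-condition learning rates
#' (`beta1 + interaction`) and intercepts are returned alongside the raw
#' coefficient table.
#'
#' @param table An analysis table from [build_analysis_table()].
#' @return An object of class `condition_fit`: list with `coefficients`
#'   (term/estimate/se/z/p), `composite_lr` and `composite_intercept`
#'   (named over the four conditions), `composite_lr_se`, `ranef_var`,
#'   `engine`, `converged`, `nobs`.
#' @export
fit_condition_lr_model <- function(table) {
  check_analysis_table(table)
  dat <- table[!is.na(table$abs_update) & !is.na(table$abs_pe), , drop = FALSE]
  dat$condition <- factor(as.character(dat$condition),
                          levels = condition_levels())
  mm <- fit_mm(abs_update ~ abs_pe * condition, dat)
  co <- tidy_fixef(mm)
  est <- setNames(co$estimate, co$term)
  V <- fixef_vcov(mm)
  lev <- condition_levels()
  lr <- numeric(4); names(lr) <- lev
  lr_se <- numeric(4); names(lr_se) <- lev
  ic <- numeric(4); names(ic) <- lev
  lr[1] <- est["abs_pe"]
  lr_se[1] <- sqrt(V["abs_pe", "abs_pe"])
  ic[1] <- est["(Intercept)"]
  for (l in lev[-1]) {
    it <- paste0("abs_pe:condition", l)
    mt <- paste0("condition", l)
    lr[l] <- est["abs_pe"] + est[it]
    lr_se[l] <- sqrt(V["abs_pe", "abs_pe"] + V[it, it] + 2 * V["abs_pe", it])
    ic[l] <- est["(Intercept)"] + est[mt]
  }
  structure(list(coefficients = co, composite_lr = lr,
                 composite_lr_se = lr_se, composite_intercept = ic,
                 ranef_var = mm$ranef_var, engine = mm$engine,
                 converged = mm$converged, singular = mm$singular,
                 nobs = mm$nobs),
            class = "condition_fit")
}

#' @export
print.condition_fit <- function(x, ...) {
  cat("Condition-by-PE mixed learning-rate model",
      sprintf("(engine %s, n = %d)\n", x$engine, x$nobs))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat("\nComposite learning rates (slope + interaction):\n")
  print(round(x$composite_lr, 4))
  invisible(x)
}

#' Quadratic nonlinearity check
#'
#' Fits `abs_update ~ abs_pe + abs_pe^2 + (1 | participant)`. A positive
#' and significant quadratic coefficient indicates that updating
#' accelerates with the size of the prediction error, the signature that
#' motivates the segmented model.
#'
#' @param table An analysis table from [build_analysis_table()].
#' @return An object of class `quadratic_fit` with the coefficient table,
#'   the quadratic coefficient `beta2` and its Wald z, plus fit metadata.
#' @export
fit_quadratic_model <- function(table) {
  check_analysis_table(table, need_levels = FALSE)
  dat <- table[!is.na(table$abs_update) & !is.na(table$abs_pe), , drop = FALSE]
  mm <- fit_mm(abs_update ~ abs_pe + I(abs_pe^2), dat)
  co <- tidy_fixef(mm)
  q <- co[co$term == "I(abs_pe^2)", ]
  structure(list(coefficients = co, beta2 = q$estimate, beta2_z = q$z,
                 beta2_p = q$p, ranef_var = mm$ranef_var, engine = mm$engine,
                 converged = mm$converged, nobs = mm$nobs),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat("Quadratic nonlinearity check",
      sprintf("(engine %s, n = %d)\n", x$engine, x$nobs))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

# Fit the broken-line mixed model at a fixed breakpoint. Returns NULL when
# too few points lie on either side of the candidate.
segmented_fixed_psi <- function(dat, psi, min_side = 10L) {
  above <- sum(dat$abs_pe > psi)
  if (above < min_side || nrow(dat) - above < min_side) return(NULL)
  dat$.u <- pmax(0, dat$abs_pe - psi)
  fit_mm(abs_update ~ abs_pe + .u, dat)
}

#' Segmented (broken-line) mixed model with unknown breakpoint
#'
#' Estimates the surprise-gated updating model
#' `abs_update = beta0 + beta1 * abs_pe + delta * (abs_pe - psi)_+` with a
#' participant random intercept, where `psi` is the unknown breakpoint in
#' absolute-PE units and `delta` the learning-rate increment above it. The
#' fitted broken line is continuous at `psi` by construction.
#'
#' Estimation profiles the ML log-likelihood over a `psi` grid (coarse pass
#' over `psi_bounds`, then a fine pass at resolution `psi_step` around the
#' coarse peak), takes the smallest maximizing `psi` (flat-profile
#' tie-break), and polishes it with Muggeo-style linearization steps: refit
#' with the gap covariates `U = (x - psi)_+` and `V = -1[x > psi]` and move
#' `psi` by `coef(V)/coef(U)` until the step is below `1e-6`.
#'
#' Confidence intervals for `psi` come either from profile-likelihood
#' inversion (chi-square 1 cutoff, interpolated on the grid) or from a
#' nonparametric bootstrap over participants.
#'
#' @param table An analysis table from [build_analysis_table()].
#' @param psi_bounds Numeric length 2: the searched breakpoint range
#'   (default 1 to 12 absolute-PE units, spanning the gradual and abrupt
#'   error regimes).
#' @param psi_step Fine-grid resolution (default 0.05).
#' @param coarse_step Coarse-grid resolution (default 0.25).
#' @param min_side Minimum number of observations required on each side of
#'   a candidate breakpoint; sparser candidates are skipped.
#' @param refine Run the linearization polish (default `TRUE`).
#' @param ci_method `"profile"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param boot_seed Seed for the participant bootstrap.
#' @return An object of class `segmented_fit`: `psi` (estimate), `psi_grid`
#'   (grid maximizer before polish), `psi_ci`, `coefficients` (beta0,
#'   beta1, delta with SEs), `slope_below`, `slope_above`, `profile`
#'   (data.frame psi/logLik), flags (`boundary`, `flat`, `converged`),
#'   `engine`, `nobs`.
#' @export
fit_segmented_model <- function(table, psi_bounds = c(1, 12), psi_step = 0.05,
                                coarse_step = 0.25, min_side = 10L,
                                refine = TRUE,
                                ci_method = c("profile", "bootstrap"),
                                conf_level = 0.95, n_boot = 50L,
                                boot_seed = NULL) {
  ci_method <- match.arg(ci_method)
  check_analysis_table(table, need_levels = FALSE)
  stopifnot(length(psi_bounds) == 2, psi_bounds[1] > 0,
            psi_bounds[2] > psi_bounds[1])
  dat <- table[!is.na(table$abs_update) & !is.na(table$abs_pe),
               c("participant_id", "abs_pe", "abs_update"), drop = FALSE]
  if (sum(dat$abs_pe > psi_bounds[1]) < min_side ||
      sum(dat$abs_pe <= psi_bounds[2]) < min_side)
    stop("abs_pe does not span the searched breakpoint range", call. = FALSE)

  profile_at <- function(psis) {
    ll <- rep(NA_real_, length(psis))
    for (i in seq_along(psis)) {
      mm <- segmented_fixed_psi(dat, psis[i], min_side)
      if (!is.null(mm)) ll[i] <- mm$logLik
    }
    data.frame(psi = psis, logLik = ll)
  }

  coarse <- profile_at(seq(psi_bounds[1], psi_bounds[2], by = coarse_step))
  if (all(is.na(coarse$logLik)))
    stop("no admissible breakpoint candidates in the searched range",
         call. = FALSE)
  peak <- coarse$psi[which.max(coarse$logLik)]
  fine_lo <- max(psi_bounds[1], peak - 2 * coarse_step)
  fine_hi <- min(psi_bounds[2], peak + 2 * coarse_step)
  fine <- profile_at(setdiff(seq(fine_lo, fine_hi, by = psi_step), coarse$psi))
  prof <- rbind(coarse, fine)
  prof <- prof[order(prof$psi), , drop = FALSE]
  rownames(prof) <- NULL

  ok <- !is.na(prof$logLik)
  ll_max <- max(prof$logLik[ok])
  # smallest psi attaining the maximum (within numerical noise)
  at_max <- ok & prof$logLik >= ll_max - 1e-9
  psi_grid_hat <- min(prof$psi[at_max])
  flat <- is.finite(ll_max) &&
    (max(prof$logLik[ok]) - min(prof$logLik[ok])) < 1e-4
  if (flat)
    warning("profile likelihood is nearly flat; breakpoint weakly identified",
            call. = FALSE)
  boundary <- psi_grid_hat <= min(prof$psi[ok]) + 1e-12 ||
    psi_grid_hat >= max(prof$psi[ok]) - 1e-12
  if (boundary)
    warning("profile maximum lies on the boundary of the searched range",
            call. = FALSE)

  psi_hat <- psi_grid_hat
  refine_converged <- NA
  if (refine && !flat) {
    psi_cur <- psi_grid_hat
    refine_converged <- FALSE
    for (it in seq_len(30L)) {
      d2 <- dat
      d2$.u <- pmax(0, d2$abs_pe - psi_cur)
      d2$.v <- -as.numeric(d2$abs_pe > psi_cur)
      if (sum(d2$.v != 0) < min_side) break
      mm <- fit_mm(abs_update ~ abs_pe + .u + .v, d2)
      co <- tidy_fixef(mm)
      bu <- co$estimate[co$term == ".u"]
      bv <- co$estimate[co$term == ".v"]
      if (!length(bu) || !is.finite(bu) || abs(bu) < 1e-8) break
      step <- bv / bu
      psi_new <- min(max(psi_cur + step, psi_bounds[1]), psi_bounds[2])
      moved <- abs(psi_new - psi_cur)
      psi_cur <- psi_new
      if (moved < 1e-6) { refine_converged <- TRUE; break }
    }
    # accept the polished value only if it does not lose likelihood
    mm_ref <- segmented_fixed_psi(dat, psi_cur, min_side)
    if (!is.null(mm_ref) && mm_ref$logLik >= ll_max - 1e-6) {
      psi_hat <- psi_cur
    }
  }

  mm_final <- segmented_fixed_psi(dat, psi_hat, min_side)
  co <- tidy_fixef(mm_final)
  names(co$term) <- NULL
  co$term[co$term == ".u"] <- "(abs_pe - psi)+"
  est <- setNames(co$estimate, co$term)
  beta0 <- est[["(Intercept)"]]
  beta1 <- est[["abs_pe"]]
  delta <- est[["(abs_pe - psi)+"]]

  psi_ci <- c(NA_real_, NA_real_)
  if (ci_method == "profile") {
    # cutoff anchored at the grid profile maximum: the refined psi is a
    # polish of the same profile, and anchoring at the grid keeps the peak
    # grid point above the cutoff by construction
    cut <- ll_max - qchisq(conf_level, 1) / 2
    if (!is.finite(cut)) {
      # perfect (noise-free) fit: the profile is infinitely peaked
      psi_ci <- c(psi_hat, psi_hat)
      cut <- NA_real_
    }
    pok <- prof[ok & is.finite(prof$logLik), , drop = FALSE]
    if (is.finite(cut) && nrow(pok) >= 2) {
      below <- pok$logLik < cut
      i_pk <- which.max(pok$logLik)
      cross <- function(j1, j2) {
        # linear interpolation of the psi at which the profile crosses cut
        l1 <- pok$logLik[j1]; l2 <- pok$logLik[j2]
        if (l2 == l1) return(pok$psi[j2])
        pok$psi[j1] + (cut - l1) * (pok$psi[j2] - pok$psi[j1]) / (l2 - l1)
      }
      # walk left/right from the grid peak to the first crossing
      if (any(below[seq_len(i_pk)]) && i_pk > 1) {
        j <- max(which(below[seq_len(i_pk)]))
        lo <- cross(j, j + 1)
      } else lo <- min(pok$psi)
      if (any(below[i_pk:nrow(pok)]) && i_pk < nrow(pok)) {
        j <- i_pk - 1L + min(which(below[i_pk:nrow(pok)]))
        hi <- cross(j - 1, j)
      } else hi <- max(pok$psi)
      psi_ci <- range(c(lo, hi, psi_hat))[c(1, 2)]
    }
  } else {
    ids <- unique(dat$participant_id)
    if (!is.null(boot_seed)) set.seed(substream_seed(boot_seed, "boot"))
    stats_b <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      db <- do.call(rbind, lapply(seq_along(take), function(k) {
        d <- dat[dat$participant_id == take[k], , drop = FALSE]
        d$participant_id <- paste0("b", k)
        d
      }))
      fb <- suppressWarnings(tryCatch(
        fit_segmented_model(db, psi_bounds = psi_bounds, psi_step = psi_step,
                            coarse_step = coarse_step, min_side = min_side,
                            refine = refine, ci_method = "profile",
                            conf_level = conf_level),
        error = function(e) NULL))
      if (!is.null(fb)) stats_b[b] <- fb$psi
    }
    psi_ci <- as.numeric(quantile(stats_b,
                                  c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                                  na.rm = TRUE))
  }

  structure(list(psi = psi_hat, psi_grid = psi_grid_hat, psi_ci = psi_ci,
                 ci_method = ci_method, conf_level = conf_level,
                 coefficients = co, beta0 = beta0, beta1 = beta1,
                 delta = delta, slope_below = beta1,
                 slope_above = beta1 + delta, profile = prof,
                 logLik = mm_final$logLik, ranef_var = mm_final$ranef_var,
                 boundary = boundary, flat = flat,
                 refine_converged = refine_converged,
                 converged = mm_final$converged, engine = mm_final$engine,
                 nobs = mm_final$nobs),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented mixed model (participant random intercept)\n")
  cat(sprintf("  breakpoint psi = %.3f  [%s %.0f%% CI %.3f, %.3f]\n",
              x$psi, x$ci_method, 100 * x$conf_level,
              x$psi_ci[1], x$psi_ci[2]))
  cat(sprintf("  slope below = %.3f, increment delta = %.3f, above = %.3f\n",
              x$slope_below, x$delta, x$slope_above))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (x$flat) cat("  note: near-flat profile\n")
  if (x$boundary) cat("  note: grid boundary maximum\n")
  invisible(x)
}

#' Threshold-exceedance logistic regression
#'
#' Models the odds that the absolute prediction error exceeds a threshold
#' (by default the estimated breakpoint, 5.337) as a function of trial
#' condition: `1[abs_pe > threshold] ~ condition`, maximum-likelihood
#' logistic fit. In synthetic cohorts abruptly changed trials exceed the
#' threshold almost surely, so the abrupt log-odds are quasi-separated;
#' this is detected and flagged rather than suppressed.
#'
#' @param table An analysis table from [build_analysis_table()].
#' @param threshold Positive exceedance threshold in absolute-PE units.
#' @return An object of class `logistic_fit`: coefficient table with
#'   `exp_estimate`, per-condition exceedance rates, `separation` flag and
#'   the threshold used.
#' @export
fit_threshold_logistic <- function(table, threshold = 5.337) {
  check_analysis_table(table)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  dat <- table[!is.na(table$abs_pe), , drop = FALSE]
  dat$condition <- factor(as.character(dat$condition),
                          levels = condition_levels())
  y <- as.integer(dat$abs_pe > threshold)
  if (all(y == 0) || all(y == 1))
    stop("outcome is constant: every trial is on the same side of the threshold",
         call. = FALSE)
  rates <- tapply(y, dat$condition, mean)
  separated <- any(rates == 0 | rates == 1)
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ condition, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  co <- data.frame(term = names(est), estimate = as.numeric(est),
                   se = as.numeric(se), z = as.numeric(z),
                   p = 2 * pnorm(-abs(z)),
                   exp_estimate = exp(as.numeric(est)),
                   row.names = NULL, stringsAsFactors = FALSE)
  separated <- separated || warned || any(abs(est) > 15)
  structure(list(coefficients = co, threshold = threshold,
                 exceedance_rate = rates, separation = separated,
                 nobs = nrow(dat)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Threshold logistic regression (threshold %.3f, n = %d)\n",
              x$threshold, x$nobs))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat("Exceedance rates: ")
  cat(paste(names(x$exceedance_rate),
            sprintf("%.3f", x$exceedance_rate), collapse = ", "), "\n")
  if (x$separation)
    cat("note: quasi-separation detected; coefficients unstable\n")
  invisible(x)
}

#' Reaction-time mixed model
#'
#' Fits `rt ~ condition + (1 | participant)` on included latencies
#' (`rt_included`, see [exclude_rts()]): baseline mean RT plus condition
#' offsets. The abrupt offset indexes surprise on abruptly changed trials.
#'
#' @param table An analysis table from [build_analysis_table()]. If the
#'   `rt_included` flags are absent they are computed with the default
#'   3-second rule.
#' @return An object of class `rt_fit` with the coefficient table,
#'   `baseline` intercept, named `offsets`, exclusion count and fit
#'   metadata.
#' @export
fit_rt_model <- function(table) {
  check_analysis_table(table)
  if (!"rt" %in% names(table)) stop("rt column required", call. = FALSE)
  if (!"rt_included" %in% names(table)) table <- exclude_rts(table)
  dat <- table[table$rt_included & !is.na(table$rt), , drop = FALSE]
  dat$condition <- factor(as.character(dat$condition),
                          levels = condition_levels())
  mm <- fit_mm(rt ~ condition, dat)
  co <- tidy_fixef(mm)
  est <- setNames(co$estimate, co$term)
  offsets <- est[paste0("condition", condition_levels()[-1])]
  names(offsets) <- condition_levels()[-1]
  structure(list(coefficients = co, baseline = est[["(Intercept)"]],
                 offsets = offsets, n_excluded = sum(!table$rt_included),
                 ranef_var = mm$ranef_var, engine = mm$engine,
                 converged = mm$converged, nobs = mm$nobs),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("RT mixed model (engine %s, n = %d, %d excluded > 3 s)\n",
              x$engine, x$nobs, x$n_excluded))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
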