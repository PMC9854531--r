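#' Cohort CSV input/output
#'
#' Cohort tables are exchanged as plain CSV with the fixed column set
#' `participant_id, block, order, trial, condition, target, estimate, pe,
#' update, rt, letter, response`.
#'
#' @param cohort A cohort table.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("participant_id", "block", "order", "trial", "condition",
            "target", "estimate", "pe", "update", "rt", "letter", "response")
  stopifnot(all(cols %in% names(cohort)))
  write.csv(as.data.frame(cohort)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character",
                                 block = "character",
                                 condition = "character",
                                 letter = "character",
                                 response = "character"))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Default pipeline configuration
#'
#' A fully serializable nested list describing one reproducible run:
#' schedules, agent generative parameters, the analyses to run, and an
#' optional recovery stage. A run is determined by the config plus its
#' seed alone.
#'
#' @return Named list with sections `seed`, `schedules`, `agents`,
#'   `analysis`, `recovery`, `output`.
#' @export
default_config <- function() {
  list(
    seed = 1,
    schedules = list(block = "both", max_step = 6),
    agents = list(
      mode = "linear",
      n_agents = 109,
      counterbalance = TRUE,
      participant_lr_sd = 0.1,
      participant_intercept_sd = 0.3,
      update_noise_sd = 1.5,
      p_no_update = 0.05,
      rt_noise_sd = 0.3,
      participant_rt_sd = 0.15,
      p_lapse = 0.02
    ),
    analysis = list(
      models = c("condition", "quadratic", "segmented", "logistic", "rt"),
      psi_bounds = c(1, 12),
      psi_step = 0.05,
      rt_threshold = 3,
      logistic_threshold = 5.337
    ),
    recovery = list(run = FALSE, replicates = 10),
    output = list(dir = "fiplearn-run")
  )
}

#' Validate a pipeline configuration
#'
#' Checks the nested structure against [default_config()]: unknown keys at
#' any level are rejected, and basic types/ranges are enforced. Missing
#' keys inherit defaults.
#'
#' @param config Nested list (e.g. from [read_run_config()]).
#' @return The merged, validated config.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  merge_checked <- function(cfg, tmpl, path = "") {
    if (!is.list(cfg)) stop("config section '", path, "' must be a mapping",
                            call. = FALSE)
    unknown <- setdiff(names(cfg), names(tmpl))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
    for (k in names(cfg)) {
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]]))) {
        tmpl[[k]] <- merge_checked(cfg[[k]], tmpl[[k]], paste0(path, k, "/"))
      } else {
        tmpl[[k]] <- cfg[[k]]
      }
    }
    tmpl
  }
  out <- merge_checked(config, ref)
  if (!out$schedules$block %in% c("gradual", "abrupt", "both"))
    stop("schedules/block must be gradual, abrupt or both", call. = FALSE)
  if (!out$agents$mode %in% c("linear", "segmented"))
    stop("agents/mode must be linear or segmented", call. = FALSE)
  bad <- setdiff(out$analysis$models,
                 c("condition", "quadratic", "segmented", "logistic", "rt"))
  if (length(bad))
    stop("unknown analysis model(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file whose keys mirror [default_config()].
#' @return The merged, validated config list.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

config_objects <- function(config) {
  ag <- config$agents
  list(
    spec = cohort_spec(n_agents = ag$n_agents, seed = config$seed,
                       participant_lr_sd = ag$participant_lr_sd,
                       participant_intercept_sd = ag$participant_intercept_sd,
                       counterbalance = ag$counterbalance),
    update = update_rule_params(mode = ag$mode,
                                update_noise_sd = ag$update_noise_sd,
                                p_no_update = ag$p_no_update),
    rt = rt_params(rt_noise_sd = ag$rt_noise_sd,
                   participant_rt_sd = ag$participant_rt_sd,
                   p_lapse = ag$p_lapse)
  )
}

fit_as_list <- function(fit) {
  out <- unclass(fit)
  out$profile <- NULL  # large; the fit JSON keeps coefficients + estimates
  lapply(out, function(el) {
    if (is.data.frame(el)) el else if (is.numeric(el) || is.character(el) ||
                                       is.logical(el)) el else NULL
  })
}

#' Run the full simulate-analyze-report pipeline
#'
#' Executes the stages in order (simulate cohort, build analysis table,
#' fit the requested models, optional parameter recovery), writes every
#' artifact under `out_dir` (`cohort.csv`, `analysis.csv`, `fit_*.json`,
#' `recovery.json`, `report.md`, `config.json`, `manifest.json`) and
#' returns the manifest. Outputs are byte-reproducible from config + seed.
#'
#' @param config A config list (see [default_config()], [read_run_config()]).
#' @param out_dir Output directory; defaults to `config$output$dir`.
#' @param quiet Suppress stage messages.
#' @return The manifest (invisibly): config hash, seeds, package version,
#'   per-stage row counts, exclusion counts and the output file inventory.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  config <- validate_config(config)
  if (is.null(out_dir)) out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "configure"
  files <- character(0)
  manifest <- list(package_version = as.character(packageVersion("fiplearn")),
                   seed = config$seed)

  result <- tryCatch({
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, "config.json")
    manifest$config_hash <- unname(tools::md5sum(cfg_path))

    stage <- "simulate"
    say("[simulate] %d agents, %s mode, seed %s", config$agents$n_agents,
        config$agents$mode, format(config$seed))
    obj <- config_objects(config)
    cohort <- simulate_cohort(obj$spec, obj$update, obj$rt)
    if (config$schedules$block != "both")
      cohort <- cohort[cohort$block == config$schedules$block, , drop = FALSE]
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    files <- c(files, "cohort.csv")
    manifest$n_cohort_rows <- nrow(cohort)

    stage <- "metrics"
    tab <- build_analysis_table(cohort, max_rt = config$analysis$rt_threshold)
    write.csv(as.data.frame(tab), file.path(out_dir, "analysis.csv"),
              row.names = FALSE)
    files <- c(files, "analysis.csv")
    manifest$n_analysis_rows <- nrow(tab)
    manifest$n_rt_excluded <- sum(!tab$rt_included)
    say("[metrics] %d rows, %d RTs excluded (> %g s)", nrow(tab),
        manifest$n_rt_excluded, config$analysis$rt_threshold)

    stage <- "inference"
    fits <- list()
    for (m in config$analysis$models) {
      say("[inference] fitting %s model", m)
      fits[[m]] <- switch(m,
        condition = fit_condition_lr_model(tab),
        quadratic = fit_quadratic_model(tab),
        segmented = suppressWarnings(fit_segmented_model(
          tab, psi_bounds = config$analysis$psi_bounds,
          psi_step = config$analysis$psi_step)),
        logistic = fit_threshold_logistic(
          tab, threshold = config$analysis$logistic_threshold),
        rt = fit_rt_model(tab))
      fp <- paste0("fit_", m, ".json")
      jsonlite::write_json(fit_as_list(fits[[m]]), file.path(out_dir, fp),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, fp)
    }

    stage <- "recovery"
    if (isTRUE(config$recovery$run)) {
      say("[recovery] %d replicates", config$recovery$replicates)
      rec <- run_recovery(obj$spec, obj$update, obj$rt,
                          n_replicates = config$recovery$replicates,
                          seed = config$seed)
      jsonlite::write_json(list(summary = rec$summary, seeds = rec$seeds,
                                n_failed = rec$n_failed),
                           file.path(out_dir, "recovery.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, "recovery.json")
    }

    stage <- "report"
    render_report(fits, file.path(out_dir, "report.md"))
    files <- c(files, "report.md")

    manifest$files <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  say("[done] %d files in %s", length(result$files) + 1L, out_dir)
  invisible(result)
}

#' Render fitted models as a markdown report
#'
#' Writes a plain-markdown summary of the fitted models, one coefficient
#' table per model, mirroring the layout of the standard results tables
#' (condition model, quadratic check, segmented model, logistic, RT).
#'
#' @param fits Named list of fit objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
render_report <- function(fits, path) {
  md_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.4g", x))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, body, "")
  }
  lines <- c("# fiplearn model report", "")
  titles <- c(condition = "Condition-by-PE learning-rate model",
              quadratic = "Quadratic nonlinearity check",
              segmented = "Segmented breakpoint model",
              logistic = "Threshold-exceedance logistic model",
              rt = "Reaction-time model")
  for (m in names(fits)) {
    f <- fits[[m]]
    lines <- c(lines, paste0("## ", ifelse(m %in% names(titles), titles[m], m)), "")
    if (m == "segmented")
      lines <- c(lines, sprintf(
        "Breakpoint psi = %.3f (%s %.0f%% CI %.3f-%.3f); slope %.3f below, +%.3f above.",
        f$psi, f$ci_method, 100 * f$conf_level, f$psi_ci[1], f$psi_ci[2],
        f$slope_below, f$delta), "")
    if (m == "condition") {
      lr <- data.frame(condition = names(f$composite_lr),
                       learning_rate = as.numeric(f$composite_lr),
                       intercept = as.numeric(f$composite_intercept))
      lines <- c(lines, md_table(lr))
    }
    if (m == "logistic" && f$separation)
      lines <- c(lines,
                 "Note: quasi-separation; exponentiated coefficients unstable.",
                 "")
    lines <- c(lines, md_table(f$coefficients))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate the miniature fixture cohorts
#'
#' Writes three small cohorts used by the test suite and examples: a
#' 5-agent default (noisy, linear-mode) cohort, and 5-agent noise-free
#' cohorts in each update mode. All are synthetic data produced by the
#' package's own generator.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixtures <- function(seed = 101, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mini = file.path(dir, "mini_cohort.csv"),
             zero_linear = file.path(dir, "zero_noise_linear_cohort.csv"),
             zero_segmented = file.path(dir, "zero_noise_segmented_cohort.csv"))
  write_cohort_csv(
    simulate_cohort(cohort_spec(n_agents = 5, seed = substream_seed(seed, "fix_mini"))),
    paths["mini"])
  for (mode in c("linear", "segmented")) {
    zp <- zero_noise_params(mode)
    sp <- do.call(cohort_spec,
                  c(list(n_agents = 5,
                         seed = substream_seed(seed, paste0("fix_", mode))),
                    zp$spec_args))
    write_cohort_csv(simulate_cohort(sp, zp$update, zp$rt),
                     paths[[paste0("zero_", substr(mode, 1, 100))]])
  }
  invisible(paths)
}
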