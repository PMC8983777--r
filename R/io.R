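#' Read a trial table from TSV
#'
#' Expects a tab-separated file with header columns `trial_id`, `direction`,
#' `target_speed_degps`, `target_size_deg`, `eye_speed_degps` (leading `#`
#' comment lines, e.g. provenance headers, are skipped). Extra columns are
#' preserved untouched. Validation errors name the offending row and column.
#'
#' @param path Path to the TSV file.
#' @return Trial data frame.
#' @export
read_pursuit_trials <- function(path) {
  required <- c("trial_id", "direction", "target_speed_degps",
                "target_size_deg", "eye_speed_degps")
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in c("target_speed_degps", "target_size_deg", "eye_speed_degps")) {
    bad <- which(!is.na(df[[col]]) & !is.finite(suppressWarnings(
      as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, bad[1]))
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("target_speed_degps", "target_size_deg")) {
    bad <- which(df[[col]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive value in column '%s' at data row %d",
                   col, bad[1]))
  }
  df
}

#' Write a trial table as TSV with a provenance header
#'
#' @param trials Trial data frame.
#' @param path Output path.
#' @param seed Seed recorded in the provenance comment (optional).
#' @return `path`, invisibly.
#' @export
write_pursuit_trials <- function(trials, path, seed = NA) {
  header <- sprintf("# pursuitgain %s | seed=%s | written=%s",
                    as.character(utils::packageVersion("pursuitgain")),
                    seed, format(Sys.time(), "%Y-%m-%d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write eye-speed traces as CSV plus a JSON metadata sidecar
#'
#' The CSV has `trial_id` as its first column followed by one column per
#' sample; the sidecar records the sample interval and the convention that
#' the first sample column is target-motion onset (t = 0).
#'
#' @param x A `pursuit_traces` object.
#' @param path Output CSV path; metadata goes to `<path>_meta.json`.
#' @return `path`, invisibly.
#' @export
write_pursuit_traces <- function(x, path) {
  stopifnot(inherits(x, "pursuit_traces"))
  df <- data.frame(trial_id = x$trials$trial_id, x$traces)
  names(df) <- c("trial_id", paste0("t", x$time))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sample_interval_ms = x$config$sample_interval,
               t0 = "first sample column is target-motion onset",
               duration_ms = x$config$duration)
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), "_meta.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Default run configuration for the analysis pipeline
#'
#' @param seed Global seed; per-stage streams are derived with
#'   [stage_seed()].
#' @param n_per_condition Trials per condition for the synthetic generator.
#' @param params A [gain_noise_params()] object for the generator.
#' @param traces If `TRUE`, generate traces and run exclusion, alignment and
#'   time-averaging; otherwise generate scalar trials directly.
#' @param n_boot Bootstrap replicates for the model comparisons.
#' @param direction Pursuit direction analysed (`"right"` or `"left"`).
#' @return A list of class `run_config` that round-trips losslessly through
#'   [write_run_config()] / [read_run_config()].
#' @export
run_config <- function(seed = 1, n_per_condition = 200,
                       params = gain_noise_params(), traces = FALSE,
                       n_boot = 500, direction = "right") {
  structure(list(seed = seed, n_per_condition = n_per_condition,
                 params = params, traces = traces, n_boot = n_boot,
                 direction = direction),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path (JSON; `.yaml`/`.yml` uses YAML when the yaml
#'   package is available).
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$params <- unclass(plain$params)
  plain$params$gains <- as.list(plain$params$gains)
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  plain <- if (grepl("\\.ya?ml$", path) &&
               requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  params <- gain_noise_params(w_s = plain$params$w_s, w_m = plain$params$w_m,
                              sigma = plain$params$sigma,
                              gains = unlist(plain$params$gains))
  run_config(seed = plain$seed, n_per_condition = plain$n_per_condition,
             params = params, traces = plain$traces, n_boot = plain$n_boot,
             direction = plain$direction)
}

#' Run the full behavioral analysis pipeline
#'
#' Synthesise trials (optionally as traces, then exclude, align and
#' time-average), compute condition statistics and gain regressions, fit all
#' four variance models, run the two bootstrap model comparisons
#' (flexible vs fixed Weber fraction; gain noise vs none) and write TSV
#' tables plus a JSON report to `out_dir`.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return The report, invisibly: a list with elements `stats`, `gains`,
#'   `fits` (coefficient lists), `comparisons` and `seed`.
#' @export
run_pursuit_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  conds <- pursuit_conditions(
    sizes = as.numeric(names(config$params$gains)),
    directions = config$direction)
  if (isTRUE(config$traces)) {
    tr <- simulate_pursuit_traces(config$params, conds,
                                  config$n_per_condition,
                                  seed = stage_seed(config$seed, "synthetic"))
    kept <- exclude_trials(tr)$kept
    al <- align_latency(kept)
    trials <- time_average(al$traces)
  } else {
    trials <- simulate_pursuit_trials(config$params, conds,
                                      config$n_per_condition,
                                      seed = stage_seed(config$seed,
                                                        "synthetic"))
  }
  st <- condition_stats(trials)
  gains <- fit_gain_regression(trials)
  models <- c("fixed_w", "flexible_w", "no_gain_noise", "gain_noise")
  fits <- lapply(models, function(mm) fit_variance_model(st, mm))
  names(fits) <- models
  cmp_w <- bootstrap_compare(trials, "flexible_w", "fixed_w",
                             n_boot = config$n_boot,
                             seed = stage_seed(config$seed, "boot_w"))
  cmp_g <- bootstrap_compare(trials, "gain_noise", "no_gain_noise",
                             n_boot = config$n_boot,
                             seed = stage_seed(config$seed, "boot_g"))
  report <- list(
    seed = config$seed,
    n_trials = nrow(trials),
    stats = st,
    gains = gains,
    fits = lapply(fits, function(f)
      list(model = f$model, coefficients = as.list(f$coefficients),
           sse = f$sse, rmse_test = tryCatch(
             score_rmse(f, st), error = function(e) NA_real_))),
    comparisons = list(
      flexible_vs_fixed = list(t = cmp_w$t_statistic, p = cmp_w$p_value,
                               dof = cmp_w$dof),
      gain_noise_vs_none = list(t = cmp_g$t_statistic, p = cmp_g$p_value,
                                dof = cmp_g$dof)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pursuit_trials(trials, file.path(out_dir, "trials.tsv"),
                         seed = config$seed)
    utils::write.table(st, file.path(out_dir, "condition_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gains, file.path(out_dir, "gain_regression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report[c("seed", "n_trials", "fits", "comparisons")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(report)
}
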