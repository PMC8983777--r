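#' Split-half bootstrap comparison of two variance models
#'
#' Repeatedly samples half of the trials in every condition (stratified by
#' target size x speed), fits both variance models to the condition statistics
#' of that half, and scores each on the statistics of the held-out half by
#' [score_rmse()] over all target speeds. The per-replicate difference
#' `RMSE(model_a) - RMSE(model_b)` forms a bootstrap distribution; the
#' t-statistic is its mean divided by its standard deviation and the paired
#' t-test uses `n_boot - 1` degrees of freedom. The one-sided alternative
#' tests whether `model_a` predicts better (smaller RMSE) than `model_b`.
#'
#' @param trials Trial data frame (single pursuit direction) with
#'   `eye_speed_degps` filled.
#' @param model_a,model_b Model names as in [fit_variance_model()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param split Fraction of trials per condition used for fitting
#'   (default 0.5).
#' @param seed Optional integer seed.
#' @param alternative `"less"` (one-sided: model_a better) or `"two.sided"`.
#' @param weber_max Passed to [fit_variance_model()].
#' @return An object of class `boot_compare`: list with `rmse_differences`,
#'   `t_statistic`, `p_value`, `dof`, `n_boot`, `n_skipped`, `models`,
#'   `alternative`.
#' @export
bootstrap_compare <- function(trials, model_a = "flexible_w",
                              model_b = "fixed_w", n_boot = 1000,
                              split = 0.5, seed = NULL,
                              alternative = c("less", "two.sided"),
                              weber_max = 2) {
  alternative <- match.arg(alternative)
  stopifnot(n_boot >= 2, split > 0, split < 1)
  if ("direction" %in% names(trials) &&
      length(unique(trials$direction)) > 1)
    stop("compare models within a single pursuit direction")
  grp <- interaction(trials$target_size_deg, trials$target_speed_degps,
                     drop = TRUE)
  idx_by_cond <- split(seq_len(nrow(trials)), grp)
  if (any(lengths(idx_by_cond) < 4))
    stop("need >= 4 trials per condition so both halves yield variances")
  meta <- trials[!duplicated(grp), c("target_size_deg", "target_speed_degps")]
  meta <- meta[order(as.integer(grp[!duplicated(grp)])), ]
  speed <- trials$eye_speed_degps

  half_stats <- function(values_by_cond) {
    data.frame(target_size_deg = meta$target_size_deg,
               target_speed_degps = meta$target_speed_degps,
               mean_degps = vapply(values_by_cond, mean, numeric(1)),
               var_degps2 = vapply(values_by_cond, stats::var, numeric(1)))
  }

  with_seed(seed, {
    diffs <- rep(NA_real_, n_boot)
    skipped <- 0L
    for (b in seq_len(n_boot)) {
      train <- lapply(idx_by_cond, function(ix)
        sample(ix, size = floor(length(ix) * split)))
      test <- Map(setdiff, idx_by_cond, train)
      st_train <- half_stats(lapply(train, function(ix) speed[ix]))
      st_test <- half_stats(lapply(test, function(ix) speed[ix]))
      if (anyNA(st_train$var_degps2) || anyNA(st_test$var_degps2)) {
        skipped <- skipped + 1L
        next
      }
      fa <- fit_variance_model(st_train, model_a, train_speeds = NULL,
                               weber_max = weber_max)
      fb <- fit_variance_model(st_train, model_b, train_speeds = NULL,
                               weber_max = weber_max)
      diffs[b] <- score_rmse(fa, st_test, test_speeds = NULL) -
        score_rmse(fb, st_test, test_speeds = NULL)
    }
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) < 2) stop("too few successful bootstrap replicates")
    sdd <- stats::sd(diffs)
    # identical models give a degenerate zero-spread distribution: no evidence
    tstat <- if (sdd == 0) 0 else mean(diffs) / sdd
    dof <- n_boot - 1
    p <- switch(alternative,
                less = stats::pt(tstat, dof),
                two.sided = 2 * stats::pt(-abs(tstat), dof))
    structure(list(rmse_differences = diffs, t_statistic = tstat,
                   p_value = p, dof = dof, n_boot = n_boot,
                   n_skipped = skipped, split_fraction = split,
                   models = c(a = model_a, b = model_b),
                   alternative = alternative),
              class = "boot_compare")
  })
}

#' @export
print.boot_compare <- function(x, ...) {
  cat(sprintf("Split-half bootstrap model comparison: %s vs %s\n",
              x$models["a"], x$models["b"]))
  cat(sprintf("  replicates: %d (skipped %d), split fraction %.2f\n",
              x$n_boot, x$n_skipped, x$split_fraction))
  cat(sprintf("  mean RMSE difference (a - b): %.4g (deg/s)^2\n",
              mean(x$rmse_differences)))
  cat(sprintf("  t(%d) = %.3f, %s p = %.4g\n", x$dof, x$t_statistic,
              if (x$alternative == "less") "one-sided" else "two-sided",
              x$p_value))
  invisible(x)
}
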