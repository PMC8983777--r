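#' Exclude trials containing saccade-like transients
#'
#' Screens each trace within a window after target-motion onset (default
#' 0-250 ms) and discards trials whose absolute sample-to-sample acceleration
#' exceeds a threshold. The acceleration criterion is a configurable stand-in
#' for a full saccade detector: the half-cosine synthetic traces stay well
#' under the default threshold while injected velocity spikes exceed it by
#' orders of magnitude.
#'
#' @param x A `pursuit_traces` object.
#' @param accel_threshold Threshold on `|diff(speed)| / dt` in deg/s^2.
#' @param window Screening window in ms, default `c(0, 250)`.
#' @return A list with elements `kept` (a `pursuit_traces` object),
#'   `excluded` (trial ids) and `log` (per-excluded-trial peak acceleration).
#' @export
exclude_trials <- function(x, accel_threshold = 5000, window = c(0, 250)) {
  stopifnot(inherits(x, "pursuit_traces"))
  if (nrow(x$traces) == 0) stop("no trials to screen")
  dt <- x$config$sample_interval / 1000  # s
  cols <- which(x$time >= window[1] & x$time <= window[2])
  acc <- abs(t(diff(t(x$traces[, cols, drop = FALSE])))) / dt
  peak <- apply(acc, 1, max)
  bad <- peak > accel_threshold
  if (all(bad)) stop("all trials excluded by the saccade criterion")
  kept <- x
  kept$trials <- x$trials[!bad, , drop = FALSE]
  kept$traces <- x$traces[!bad, , drop = FALSE]
  list(kept = kept,
       excluded = x$trials$trial_id[bad],
       log = data.frame(trial_id = x$trials$trial_id[bad],
                        peak_accel_degps2 = peak[bad]))
}

#' Align trial latencies to the conditional mean trace
#'
#' For each condition (direction x size x speed) the mean trace over 0-250 ms
#' is computed from the raw traces. Each trial is then matched to its
#' conditional mean by exhaustive grid search over a time lag, a matching
#' gain and a speed offset, minimising the summed squared error between
#' `gain * trace(t + lag) + offset` and the mean trace over the window.
#' Only the recovered lag is applied to the data (the realigned trace is
#' `trace(t + lag)`): the gain and offset are matching nuisance parameters.
#' Applying them would scale away exactly the trial-to-trial amplitude
#' variance the downstream analysis measures. Samples shifted out of the
#' trace's support are dropped from the objective, not zero-padded.
#'
#' @param x A `pursuit_traces` object with at least 2 trials per condition.
#' @param lag_range Search range for the lag in ms, default `c(-40, 50)`.
#' @param lag_step Lag step in ms (default 1).
#' @param gain_range,gain_step Matching-gain grid, default 0.2-1.9 by 0.05.
#' @param offset_range,offset_step Speed-offset grid in deg/s, default
#'   -2 to 2 by 0.25.
#' @param window Matching window in ms, default `c(0, 250)`.
#' @param refine_iterations Number of times the conditional mean is
#'   re-estimated from realigned traces and the search repeated (default 0:
#'   the mean is computed once from raw traces).
#' @return A list with `traces` (realigned `pursuit_traces`; shifted-in
#'   samples beyond the original support are `NA`) and `alignment` (data frame
#'   of `trial_id`, `lag_ms`, `match_gain`, `match_offset`, `objective`).
#' @export
align_latency <- function(x, lag_range = c(-40, 50), lag_step = 1,
                          gain_range = c(0.2, 1.9), gain_step = 0.05,
                          offset_range = c(-2, 2), offset_step = 0.25,
                          window = c(0, 250), refine_iterations = 0) {
  stopifnot(inherits(x, "pursuit_traces"))
  if (max(x$time) < window[2] - x$config$sample_interval)
    stop("traces do not cover the matching window")
  lags <- seq(lag_range[1], lag_range[2], by = lag_step)
  gains <- seq(gain_range[1], gain_range[2], by = gain_step)
  offsets <- seq(offset_range[1], offset_range[2], by = offset_step)
  win_cols <- which(x$time >= window[1] & x$time <= window[2])
  nsamp <- ncol(x$traces)
  dt <- x$config$sample_interval
  cond <- interaction(x$trials$direction, x$trials$target_size_deg,
                      x$trials$target_speed_degps, drop = TRUE)
  if (any(table(cond) < 2)) stop("need >= 2 trials per condition to align")

  # per-lag column indices into the trace for each window sample (NA = out of support)
  lag_cols <- lapply(lags, function(L) {
    ic <- win_cols + as.integer(round(L / dt))
    ic[ic < 1 | ic > nsamp] <- NA_integer_
    ic
  })
  g2 <- gains^2
  o1 <- offsets

  search_pass <- function(mean_traces) {
    res <- data.frame(trial_id = x$trials$trial_id, lag_ms = NA_real_,
                      match_gain = NA_real_, match_offset = NA_real_,
                      objective = NA_real_)
    for (k in seq_len(nrow(x$traces))) {
      m_full <- mean_traces[[as.character(cond[k])]]
      tr <- x$traces[k, ]
      best <- Inf; best_lag <- NA; best_g <- NA; best_o <- NA
      for (li in seq_along(lags)) {
        ic <- lag_cols[[li]]
        ok <- !is.na(ic)
        xx <- tr[ic[ok]]
        mm <- m_full[ok]
        sxx <- sum(xx * xx); sx <- sum(xx); sxm <- sum(xx * mm)
        sm <- sum(mm); smm <- sum(mm * mm); n <- length(xx)
        # SSE(g, o) = g^2 Sxx + 2 g o Sx - 2 g Sxm + n o^2 - 2 o Sm + Smm
        sse <- outer(g2 * sxx - 2 * gains * sxm,
                     n * o1^2 - 2 * o1 * sm, `+`) +
          2 * outer(gains * sx, o1) + smm
        j <- which.min(sse)
        if (sse[j] < best) {
          best <- sse[j]
          best_lag <- lags[li]
          best_g <- gains[(j - 1) %% length(gains) + 1]
          best_o <- offsets[(j - 1) %/% length(gains) + 1]
        }
      }
      res$lag_ms[k] <- best_lag
      res$match_gain[k] <- best_g
      res$match_offset[k] <- best_o
      res$objective[k] <- best
    }
    res
  }

  mean_by_cond <- function(traces) {
    out <- lapply(levels(cond), function(cl)
      colMeans(traces[cond == cl, win_cols, drop = FALSE], na.rm = TRUE))
    names(out) <- levels(cond)
    out
  }

  res <- search_pass(mean_by_cond(x$traces))
  shift_traces <- function(res) {
    shifted <- x$traces
    for (k in seq_len(nrow(x$traces))) {
      off <- as.integer(round(res$lag_ms[k] / dt))
      ic <- seq_len(nsamp) + off
      bad <- ic < 1 | ic > nsamp
      ic[bad] <- 1L
      row <- x$traces[k, ic]
      row[bad] <- NA_real_
      shifted[k, ] <- row
    }
    shifted
  }
  for (it in seq_len(refine_iterations)) {
    res <- search_pass(mean_by_cond(shift_traces(res)))
  }
  out <- x
  out$traces <- shift_traces(res)
  list(traces = out, alignment = res)
}

#' Time-average eye speed within the open-loop analysis window
#'
#' Computes the arithmetic mean of the samples in the closed window
#' (default 110-190 ms after target-motion onset) for every trial and fills
#' `eye_speed_degps` in the trial table.
#'
#' @param x A `pursuit_traces` object (typically realigned), or a numeric
#'   trace with sample times supplied via `time`.
#' @param window Averaging window in ms, default `c(110, 190)`.
#' @param time Sample times in ms when `x` is a bare numeric trace.
#' @return For a `pursuit_traces` object, its trial data frame with
#'   `eye_speed_degps` filled; for a numeric trace, the scalar average.
#' @export
time_average <- function(x, window = c(110, 190), time = NULL) {
  if (is.numeric(x)) {
    if (is.null(time)) stop("supply 'time' for a bare numeric trace")
    cols <- time >= window[1] & time <= window[2]
    if (!any(cols)) stop("averaging window outside trace support")
    if (anyNA(x[cols])) stop("averaging window not fully covered by the trace")
    return(mean(x[cols]))
  }
  stopifnot(inherits(x, "pursuit_traces"))
  cols <- x$time >= window[1] & x$time <= window[2]
  if (!any(cols)) stop("averaging window outside trace support")
  vals <- x$traces[, cols, drop = FALSE]
  if (anyNA(vals)) stop("averaging window not fully covered by all traces")
  trials <- x$trials
  trials$eye_speed_degps <- rowMeans(vals)
  trials
}

#' Per-condition mean and variance of single-trial eye speed
#'
#' Groups trials by (direction, target size, target speed) and reports the
#' number of trials, the mean and the unbiased (n-1) variance of
#' `eye_speed_degps`. Conditions with a single trial get `NA` variance with a
#' warning.
#'
#' @param trials Trial data frame with `eye_speed_degps` filled.
#' @return Data frame with columns `direction`, `target_size_deg`,
#'   `target_speed_degps`, `n`, `mean_degps`, `var_degps2`.
#' @export
condition_stats <- function(trials) {
  stopifnot(is.data.frame(trials), "eye_speed_degps" %in% names(trials))
  if (anyNA(trials$eye_speed_degps))
    stop("eye_speed_degps contains NA; run the pipeline first")
  grp <- interaction(trials$direction, trials$target_size_deg,
                     trials$target_speed_degps, drop = TRUE)
  sp <- split(trials, grp)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(direction = d$direction[1],
               target_size_deg = d$target_size_deg[1],
               target_speed_degps = d$target_speed_degps[1],
               n = nrow(d),
               mean_degps = mean(d$eye_speed_degps),
               var_degps2 = if (nrow(d) >= 2) stats::var(d$eye_speed_degps)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (anyNA(out$var_degps2))
    warning("variance omitted for condition(s) with fewer than 2 trials")
  out[order(out$direction, out$target_size_deg, out$target_speed_degps), ,
      drop = FALSE]
}

#' Per-size regression of eye speed on target speed
#'
#' Ordinary least squares of single-trial eye speed on target speed, fitted
#' separately for each (direction, target size). The slope estimates the gain
#' of visuomotor transmission for that size.
#'
#' @param trials Trial data frame with `eye_speed_degps` filled.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return Data frame with columns `direction`, `target_size_deg`, `slope`,
#'   `intercept`, `slope_se`, `ci_halfwidth`, `n`.
#' @export
fit_gain_regression <- function(trials, conf_level = 0.95) {
  stopifnot(is.data.frame(trials))
  grp <- interaction(trials$direction, trials$target_size_deg, drop = TRUE)
  out <- do.call(rbind, lapply(split(trials, grp), function(d) {
    if (length(unique(d$target_speed_degps)) < 2)
      stop("need >= 2 distinct target speeds per size to fit a gain")
    fit <- stats::lm(eye_speed_degps ~ target_speed_degps, data = d)
    sm <- summary(fit)$coefficients
    se <- sm["target_speed_degps", "Std. Error"]
    data.frame(direction = d$direction[1],
               target_size_deg = d$target_size_deg[1],
               slope = unname(stats::coef(fit)["target_speed_degps"]),
               intercept = unname(stats::coef(fit)["(Intercept)"]),
               slope_se = se,
               ci_halfwidth = se * stats::qt(1 - (1 - conf_level) / 2,
                                             df = fit$df.residual),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$direction, out$target_size_deg), , drop = FALSE]
}
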