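#' Fit signal-dependent-noise (Weber fraction) variance models
#'
#' Fits one of four variance models to per-condition statistics of
#' single-trial eye speed, by minimising the sum of squared errors between
#' observed and predicted condition variances,
#' \deqn{SSE = \sum_i \sum_j (\sigma^2_{obs,ij} - \sigma^2_{pre,ij})^2,}
#' over target sizes \eqn{i} and the training target speeds \eqn{j}
#' (default 4, 12 and 20 deg/s):
#' \describe{
#'   \item{`fixed_w`}{\eqn{\sigma^2_{pre,ij} = w^2 \mu_{ij}^2} with one Weber
#'     fraction shared across sizes (the null hypothesis).}
#'   \item{`flexible_w`}{\eqn{\sigma^2_{pre,ij} = w_i^2 \mu_{ij}^2} with a
#'     Weber fraction per size.}
#'   \item{`gain_noise`}{\eqn{\sigma^2_{pre,ij} = w_s^2 \mu_{ij}^2 +
#'     (\sigma^2 + \sigma^2 w_s^2) s_j^2}: the gain cancels, leaving
#'     \eqn{w_s} and \eqn{\sigma} as the only free parameters.}
#'   \item{`no_gain_noise`}{the gain-noise form with \eqn{\sigma} pinned to 0
#'     (equivalent in form to `fixed_w`, kept distinct for model comparison).}
#' }
#'
#' Every model is linear in transformed parameters (`w^2`, or
#' `(w_s^2, sigma^2 (1 + w_s^2))`), so the SSE is minimised exactly by
#' non-negatively constrained linear least squares; no iterative optimiser or
#' starting values are involved. Weber fractions are bounded to
#' `[0, weber_max]` by clipping.
#'
#' @param stats Condition statistics for a single pursuit direction, as from
#'   [condition_stats()] (columns `target_size_deg`, `target_speed_degps`,
#'   `mean_degps`, `var_degps2`).
#' @param model One of `"flexible_w"`, `"fixed_w"`, `"gain_noise"`,
#'   `"no_gain_noise"`.
#' @param train_speeds Target speeds used for fitting; default `c(4, 12, 20)`.
#'   Use `NULL` for all speeds present.
#' @param weber_max Upper bound on fitted Weber fractions (default 2).
#' @return An object of class `weber_fit` with components `model`,
#'   `coefficients`, `sse`, `fitted`, `stats`, `train_speeds`.
#' @seealso [score_rmse()], [bootstrap_compare()], [infer_effective_weber()]
#' @export
fit_variance_model <- function(stats,
                               model = c("flexible_w", "fixed_w",
                                         "gain_noise", "no_gain_noise"),
                               train_speeds = c(4, 12, 20), weber_max = 2) {
  model <- match.arg(model)
  stats <- validate_stats(stats)
  if (is.null(train_speeds)) train_speeds <- unique(stats$target_speed_degps)
  tr <- stats[stats$target_speed_degps %in% train_speeds, , drop = FALSE]
  if (nrow(tr) < 2) stop("need at least two training conditions")
  v <- tr$var_degps2
  u <- tr$mean_degps^2
  a_max <- weber_max^2

  coefs <- switch(model,
    fixed_w = {
      a <- min(max(sum(u * v) / sum(u * u), 0), a_max)
      c(w = sqrt(a))
    },
    no_gain_noise = {
      a <- min(max(sum(u * v) / sum(u * u), 0), a_max)
      c(w_s = sqrt(a), sigma = 0)
    },
    flexible_w = {
      sizes <- sort(unique(tr$target_size_deg))
      w <- vapply(sizes, function(sz) {
        i <- tr$target_size_deg == sz
        a <- min(max(sum(u[i] * v[i]) / sum(u[i]^2), 0), a_max)
        sqrt(a)
      }, numeric(1))
      stats::setNames(w, paste0("w_", sizes))
    },
    gain_noise = {
      s2 <- tr$target_speed_degps^2
      ab <- nnls2(cbind(u, s2), v)
      a <- min(ab[1], a_max)
      b <- ab[2]
      c(w_s = sqrt(a), sigma = sqrt(b / (1 + a)))
    })

  obj <- structure(list(model = model, coefficients = coefs,
                        train_speeds = sort(unique(tr$target_speed_degps)),
                        stats = stats, weber_max = weber_max,
                        call = match.call()),
                   class = "weber_fit")
  obj$fitted <- predict(obj, newdata = tr)
  obj$sse <- sum((v - obj$fitted)^2)
  obj
}

# exact non-negative least squares for two columns: try the unconstrained
# normal-equation solution, else the better of the two single-column fits
nnls2 <- function(X, y) {
  b <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                error = function(e) matrix(c(-1, -1)))
  if (all(b >= 0)) return(as.numeric(b))
  fit1 <- max(sum(X[, 1] * y) / sum(X[, 1]^2), 0)
  fit2 <- max(sum(X[, 2] * y) / sum(X[, 2]^2), 0)
  sse1 <- sum((y - X[, 1] * fit1)^2)
  sse2 <- sum((y - X[, 2] * fit2)^2)
  if (sse1 <= sse2) c(fit1, 0) else c(0, fit2)
}

validate_stats <- function(stats) {
  need <- c("target_size_deg", "target_speed_degps", "mean_degps",
            "var_degps2")
  if (!all(need %in% names(stats)))
    stop("stats must have columns ", paste(need, collapse = ", "))
  if ("direction" %in% names(stats) &&
      length(unique(stats$direction)) > 1)
    stop("fit one pursuit direction at a time; subset 'stats' by direction")
  stats <- stats[!is.na(stats$var_degps2), , drop = FALSE]
  if (any(!is.finite(stats$var_degps2)) || any(!is.finite(stats$mean_degps)))
    stop("non-finite condition statistics")
  stats
}

#' Predict condition variances from a fitted variance model
#'
#' @param object A `weber_fit` object.
#' @param newdata Condition statistics (same columns as for
#'   [fit_variance_model()]); defaults to the data the model was fitted on.
#' @param ... Ignored.
#' @return Numeric vector of predicted variances, (deg/s)^2.
#' @export
predict.weber_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$stats
  newdata <- validate_stats(newdata)
  u <- newdata$mean_degps^2
  cf <- object$coefficients
  switch(object$model,
    fixed_w = cf[["w"]]^2 * u,
    no_gain_noise = cf[["w_s"]]^2 * u,
    gain_noise = cf[["w_s"]]^2 * u +
      (cf[["sigma"]]^2 + cf[["sigma"]]^2 * cf[["w_s"]]^2) *
      newdata$target_speed_degps^2,
    flexible_w = {
      key <- paste0("w_", newdata$target_size_deg)
      if (!all(key %in% names(cf)))
        stop("no fitted Weber fraction for size(s): ",
             paste(unique(newdata$target_size_deg[!key %in% names(cf)]),
                   collapse = ", "))
      unname(cf[key]^2 * u)
    })
}

#' @export
coef.weber_fit <- function(object, ...) object$coefficients

#' @export
residuals.weber_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$stats
  newdata <- validate_stats(newdata)
  newdata$var_degps2 - predict(object, newdata)
}

#' @export
print.weber_fit <- function(x, ...) {
  cat(sprintf("Variance model '%s' (trained on speeds %s deg/s)\n",
              x$model, paste(x$train_speeds, collapse = ", ")))
  cat("Coefficients:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("Training SSE: %.5g (deg/s)^4\n", x$sse))
  invisible(x)
}

#' @export
summary.weber_fit <- function(object, test_speeds = c(8, 16), ...) {
  tab <- object$stats
  tab$predicted_var <- predict(object, tab)
  tab$residual <- tab$var_degps2 - tab$predicted_var
  rmse <- tryCatch(score_rmse(object, object$stats, test_speeds),
                   error = function(e) NA_real_)
  structure(list(fit = object, table = tab, test_speeds = test_speeds,
                 rmse_test = rmse),
            class = "summary.weber_fit")
}

#' @export
print.summary.weber_fit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$rmse_test))
    cat(sprintf("Held-out RMSE (speeds %s): %.4g (deg/s)^2\n",
                paste(x$test_speeds, collapse = ", "), x$rmse_test))
  cat("\nPer-condition fit:\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Variance-versus-mean plot of a fitted variance model
#'
#' Plots observed condition variance against mean eye speed, one colour per
#' target size, with the model's predicted variance drawn as curves.
#'
#' @param x A `weber_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.weber_fit <- function(x, ...) {
  st <- x$stats
  sizes <- sort(unique(st$target_size_deg))
  cols <- stats::setNames(grDevices::hcl.colors(max(3, length(sizes)),
                                                "Dark 3")[seq_along(sizes)],
                          sizes)
  graphics::plot(st$mean_degps, st$var_degps2,
                 col = cols[as.character(st$target_size_deg)], pch = 19,
                 xlab = "Mean eye speed (deg/s)",
                 ylab = expression(Variance ~ ((deg/s)^2)),
                 main = sprintf("Variance model: %s", x$model), ...)
  for (sz in sizes) {
    sub <- st[st$target_size_deg == sz, ]
    sub <- sub[order(sub$mean_degps), ]
    graphics::lines(sub$mean_degps, predict(x, sub),
                    col = cols[as.character(sz)])
  }
  graphics::legend("topleft", legend = paste(sizes, "deg"),
                   col = cols, pch = 19, bty = "n")
  invisible(x)
}

#' Held-out root-mean-squared error of predicted variances
#'
#' Evaluates \deqn{RMSE = \sqrt{\frac{1}{MN} \sum_i \sum_j
#' (\sigma^2_{obs,ij} - \sigma^2_{pre,ij})^2}} over all sizes at the held-out
#' target speeds (default 8 and 16 deg/s).
#'
#' @param fit A `weber_fit` object.
#' @param stats Condition statistics containing the held-out speeds.
#' @param test_speeds Held-out speeds; default `c(8, 16)`. Use `NULL` for all
#'   speeds present in `stats`.
#' @return RMSE in (deg/s)^2.
#' @export
score_rmse <- function(fit, stats, test_speeds = c(8, 16)) {
  stats <- validate_stats(stats)
  if (!is.null(test_speeds)) {
    missing <- setdiff(test_speeds, stats$target_speed_degps)
    if (length(missing))
      stop("held-out speed(s) absent from stats: ",
           paste(missing, collapse = ", "))
    stats <- stats[stats$target_speed_degps %in% test_speeds, , drop = FALSE]
  }
  sqrt(mean((stats$var_degps2 - predict(fit, stats))^2))
}

#' Effective Weber fractions implied by a gain-noise fit
#'
#' Combines the fitted `(w_s, sigma)` of a `gain_noise` (or `no_gain_noise`)
#' model with per-size gains obtained from linear regression of eye speed on
#' target speed, evaluating the effective Weber fraction
#' \eqn{w_{eff}(G_i) = \sqrt{w_s^2 + (\sigma^2 + \sigma^2 w_s^2)/G_i^2}}
#' at each size's gain. With \eqn{\sigma = 0} every size maps to the same
#' value; with \eqn{\sigma > 0} the effective Weber fraction decreases with
#' increasing gain.
#'
#' @param fit A `weber_fit` of model `gain_noise` or `no_gain_noise`.
#' @param gains Either a data frame from [fit_gain_regression()] (single
#'   direction) or a named numeric vector of gains keyed by target size.
#' @return Data frame with columns `target_size_deg`, `gain`, `w_eff`.
#' @export
infer_effective_weber <- function(fit, gains) {
  stopifnot(inherits(fit, "weber_fit"))
  if (!fit$model %in% c("gain_noise", "no_gain_noise"))
    stop("effective Weber fractions require a gain_noise-family fit")
  if (is.data.frame(gains)) {
    if ("direction" %in% names(gains) &&
        length(unique(gains$direction)) > 1)
      stop("supply gains for a single direction")
    gv <- stats::setNames(gains$slope, gains$target_size_deg)
  } else gv <- gains
  if (any(gv <= 0)) stop("all gains must be > 0")
  fitted_sizes <- unique(fit$stats$target_size_deg)
  if (!all(fitted_sizes %in% as.numeric(names(gv))))
    stop("gains missing for size(s): ",
         paste(setdiff(fitted_sizes, as.numeric(names(gv))), collapse = ", "))
  cf <- fit$coefficients
  p <- gain_noise_params(w_s = cf[["w_s"]], w_m = 0, sigma = cf[["sigma"]],
                         gains = gv)
  data.frame(target_size_deg = as.numeric(names(gv)),
             gain = unname(gv),
             w_eff = effective_weber(p, unname(gv)))
}

#' Per-size Weber fractions with trial-resampling bootstrap intervals
#'
#' Fits the per-size (flexible) Weber-fraction model to the full trial set,
#' then resamples trials with replacement within each condition and refits to
#' form percentile confidence intervals. Also reports whether the Weber
#' fractions are strictly ordered by decreasing target size with pairwise
#' non-overlapping intervals -- the separation flag used to contrast
#' behavior with and without gain noise.
#'
#' @param trials Trial data frame (single direction) with `eye_speed_degps`.
#' @param n_boot Bootstrap replicates (default 200).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return List with `w` (named point estimates, largest size last), `ci`
#'   (2 x sizes matrix of bounds) and `separated` (logical: adjacent sizes
#'   ordered `w(small) > w(large)` with non-overlapping intervals).
#' @export
weber_size_cis <- function(trials, n_boot = 200, level = 0.95, seed = NULL) {
  grp <- interaction(trials$target_size_deg, trials$target_speed_degps,
                     drop = TRUE)
  idx <- split(seq_len(nrow(trials)), grp)
  fitw <- function(rows) {
    st <- condition_stats(trials[rows, , drop = FALSE])
    stats::coef(fit_variance_model(st, "flexible_w", train_speeds = NULL))
  }
  w <- fitw(seq_len(nrow(trials)))
  with_seed(seed, {
    B <- replicate(n_boot, fitw(unlist(lapply(idx, function(ix)
      sample(ix, replace = TRUE)))))
    alpha <- (1 - level) / 2
    ci <- apply(B, 1, stats::quantile, c(alpha, 1 - alpha))
    sizes <- sort(as.numeric(sub("^w_", "", names(w))))
    ord <- paste0("w_", sizes)
    sep <- all(vapply(seq_len(length(ord) - 1), function(k)
      ci[1, ord[k]] > ci[2, ord[k + 1]], logical(1)))
    list(w = w[ord], ci = ci[, ord, drop = FALSE], separated = sep)
  })
}
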