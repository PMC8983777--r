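#' Parameters of the generative gain-noise model of pursuit initiation
#'
#' The simple model describes the open-loop eye speed on a single trial as
#' \deqn{E = (G + \eta_G)(\hat{s} + \eta_s) + \eta_m,}
#' where \eqn{\hat{s} = s} is the (unbiased) sensory estimate of target speed,
#' \eqn{G} is the gain of visuomotor transmission for the target size shown,
#' and the three noise sources are independent zero-mean Gaussians:
#' sensory noise \eqn{\eta_s} with variance \eqn{w_s^2 s^2}, motor noise
#' \eqn{\eta_m} with variance \eqn{w_m^2 \mu^2} (with \eqn{\mu = G s} the mean
#' output), and gain noise \eqn{\eta_G} with variance \eqn{\sigma^2}.
#'
#' @param w_s Sensory Weber fraction (unitless, \eqn{\ge 0}).
#' @param w_m Motor Weber fraction (unitless, \eqn{\ge 0}).
#' @param sigma Standard deviation of the multiplicative gain noise
#'   (unitless, \eqn{\ge 0}).
#' @param gains Named numeric vector mapping target size (deg, as names) to
#'   the visuomotor gain \eqn{G_i > 0}; defaults to the monkey-R estimates,
#'   see [monkey_gains()].
#' @return An object of class `gain_noise_params`.
#' @seealso [simulate.gain_noise_params()], [effective_weber_sq()]
#' @examples
#' p <- gain_noise_params(w_s = 0.1, w_m = 0.05, sigma = 0.05)
#' effective_weber(p, G = p$gains)
#' @export
gain_noise_params <- function(w_s = 0.1, w_m = 0.05, sigma = 0.05,
                              gains = monkey_gains("R")) {
  stopifnot(w_s >= 0, w_m >= 0, sigma >= 0)
  gains <- unlist(gains)
  if (is.null(names(gains)) || any(!nzchar(names(gains))))
    stop("'gains' must be a named vector, names giving target sizes in deg")
  if (any(gains <= 0)) stop("all gains must be > 0")
  structure(list(w_s = w_s, w_m = w_m, sigma = sigma, gains = gains),
            class = "gain_noise_params")
}

#' Reported per-size pursuit gains for the two monkeys
#'
#' Slopes of single-trial eye speed versus target speed for 2, 6 and 20 deg
#' dot patches: 0.31/0.52/0.62 (monkey R) and 0.46/0.77/0.80 (monkey X).
#'
#' @param monkey `"R"` or `"X"`.
#' @return Named numeric vector of gains keyed by target size in deg.
#' @export
monkey_gains <- function(monkey = c("R", "X")) {
  monkey <- match.arg(monkey)
  if (monkey == "R") c(`2` = 0.31, `6` = 0.52, `20` = 0.62)
  else c(`2` = 0.46, `6` = 0.77, `20` = 0.80)
}

#' @export
print.gain_noise_params <- function(x, ...) {
  cat("Gain-noise model parameters\n")
  cat(sprintf("  w_s = %.4g, w_m = %.4g, sigma = %.4g\n", x$w_s, x$w_m, x$sigma))
  cat("  gains (by target size, deg):\n")
  print(x$gains)
  invisible(x)
}

#' Squared effective Weber fraction of the gain-noise model
#'
#' The variance of the model's output is \eqn{w_{eff}^2 \mu^2} with
#' \deqn{w_{eff}^2 = (w_s^2 + w_m^2) + \frac{\sigma^2 + \sigma^2 w_s^2}{G^2},}
#' i.e. the variance-to-squared-mean ratio. It depends on the gain \eqn{G}
#' if and only if \eqn{\sigma^2 > 0}.
#'
#' @param params A [gain_noise_params()] object.
#' @param G Gain(s) of visuomotor transmission, all `> 0`.
#' @return Numeric vector of squared effective Weber fractions.
#' @export
effective_weber_sq <- function(params, G) {
  stopifnot(inherits(params, "gain_noise_params"))
  if (any(G <= 0)) stop("G must be > 0")
  (params$w_s^2 + params$w_m^2) +
    (params$sigma^2 + params$sigma^2 * params$w_s^2) / G^2
}

#' @rdname effective_weber_sq
#' @export
effective_weber <- function(params, G) sqrt(effective_weber_sq(params, G))
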