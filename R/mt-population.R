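#' Configuration of the model MT population
#'
#' Collects the tuning-range, receptive-field and noise-correlation constants
#' of the biomimetic middle-temporal population. Defaults follow the
#' physiological literature: threshold `omega = 0`, exponent `n_exp = 1` and
#' surround-suppression strength `beta = 1`; correlation decay constants
#' `lambda_theta = 0.40`, `lambda_s = 0.30`, `lambda_c = 0.30` with peak
#' correlation `r_max = 0.55`. The normalisation constant `epsilon = 0.5` is
#' forced by requiring the surround-normalised response to lie in [0, 1] when
#' `beta = 1`.
#'
#' @param n_total Total number of model neurons (default 1280).
#' @param n_foveal Number of neurons with foveal receptive fields
#'   (default 180).
#' @param foveal_ecc_range Eccentricity range of foveal neurons in deg,
#'   default `c(0.25, 1)` (sampled uniformly).
#' @param peripheral_ecc_range Eccentricity range of the remaining neurons,
#'   default `c(1, 30)` (sampled from density proportional to ecc^-0.9).
#' @param omega,n_exp Threshold and exponent of the receptive-field summation
#'   nonlinearity (`0 <= omega < 1`, `n_exp > 0`).
#' @param beta Surround-suppression strength in [0, 1].
#' @param epsilon Normalisation constant (default 0.5).
#' @param lambda_theta,lambda_s,lambda_c Correlation decay constants for
#'   preferred-direction, preferred-speed and receptive-field-centre distance.
#' @param r_max Peak pairwise noise correlation (default 0.55).
#' @param dpd_max,dps_max,dc_max Nominal maxima of the three tuning distances:
#'   180 deg (largest wrapped direction difference), 9 octaves
#'   (log2 256 - log2 0.5), 60 deg (diameter of the 30-deg eccentricity
#'   field). Fixed so the correlation structure does not depend on the
#'   particular population sample.
#' @param surround_full_disc If `TRUE`, surround overlap is normalised by the
#'   full surround disc area instead of the annulus outside the classical
#'   receptive field (default `FALSE`).
#' @return An object of class `mt_config`.
#' @export
mt_config <- function(n_total = 1280, n_foveal = 180,
                      foveal_ecc_range = c(0.25, 1),
                      peripheral_ecc_range = c(1, 30),
                      omega = 0, n_exp = 1, beta = 1, epsilon = 0.5,
                      lambda_theta = 0.40, lambda_s = 0.30, lambda_c = 0.30,
                      r_max = 0.55, dpd_max = 180, dps_max = 9, dc_max = 60,
                      surround_full_disc = FALSE) {
  stopifnot(n_total > n_foveal, n_foveal >= 0,
            omega >= 0, omega < 1, n_exp > 0,
            beta >= 0, beta <= 1, epsilon > 0,
            r_max >= 0, r_max < 1,
            diff(foveal_ecc_range) > 0, diff(peripheral_ecc_range) > 0)
  structure(as.list(environment()), class = "mt_config")
}

#' Sample a model MT population
#'
#' Receptive-field eccentricities follow the cortical magnification of MT:
#' `n_foveal` neurons uniform on the foveal range and the remainder drawn by
#' inverse-CDF sampling from a density proportional to eccentricity^-0.9 on
#' the peripheral range. Polar angles are uniform on the full circle. Tuning
#' parameters are sampled uniformly: preferred direction on (-180, 180] deg,
#' direction width on [20, 90] deg, preferred speed uniform in log2 units
#' over [0.5, 256] deg/s, speed width on [0.64, 2.8] octaves, response
#' amplitude on [20, 200] spikes/s. Receptive-field diameter grows with
#' eccentricity as `(0.69 ecc + 1) / sqrt(pi)` and the suppressive surround
#' radius is three times the classical receptive-field radius.
#'
#' @param config An [mt_config()] object.
#' @param seed Optional integer seed.
#' @return A data frame of class `mt_population` (one row per neuron) with
#'   columns `id`, `pref_dir`, `dir_width`, `pref_speed`, `speed_width`,
#'   `amplitude`, `ecc`, `x`, `y`, `rf_diameter`, `surround_radius`; the
#'   configuration is attached as attribute `"config"`.
#' @export
mt_population <- function(config = mt_config(), seed = NULL) {
  stopifnot(inherits(config, "mt_config"))
  with_seed(seed, {
    n <- config$n_total
    nf <- config$n_foveal
    ecc_f <- runif(nf, config$foveal_ecc_range[1], config$foveal_ecc_range[2])
    ecc_p <- sample_peripheral_ecc(n - nf, config$peripheral_ecc_range)
    ecc <- c(ecc_f, ecc_p)
    ang <- runif(n, 0, 360)
    rf_diam <- (0.69 * ecc + 1) / sqrt(pi)
    pop <- data.frame(
      id = seq_len(n),
      pref_dir = runif(n, -180, 180),
      dir_width = runif(n, 20, 90),
      pref_speed = 2^runif(n, log2(0.5), log2(256)),
      speed_width = runif(n, 0.64, 2.8),
      amplitude = runif(n, 20, 200),
      ecc = ecc,
      x = ecc * cos(ang * pi / 180),
      y = ecc * sin(ang * pi / 180),
      rf_diameter = rf_diam,
      surround_radius = 3 * rf_diam / 2)
    attr(pop, "config") <- config
    class(pop) <- c("mt_population", "data.frame")
    pop
  })
}

# inverse-CDF draw from density proportional to ecc^-0.9 on [lo, hi]
sample_peripheral_ecc <- function(n, range) {
  lo <- range[1]; hi <- range[2]
  u <- runif(n)
  (u * (hi^0.1 - lo^0.1) + lo^0.1)^10
}

#' @export
print.mt_population <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Model MT population: %d neurons (%d foveal, ecc %g-%g deg)\n",
              nrow(x), cfg$n_foveal, min(x$ecc), max(x$ecc)))
  cat(sprintf("  omega = %g, n = %g, beta = %g; r_max = %g\n",
              cfg$omega, cfg$n_exp, cfg$beta, cfg$r_max))
  invisible(x)
}

#' Direction tuning of model MT neurons
#'
#' Gaussian tuning on the circular direction difference (wrapped to
#' (-180, 180]): `exp(-d^2 / (2 tau_theta^2))`.
#'
#' @param neurons An `mt_population` data frame (or any data frame with
#'   `pref_dir` and `dir_width` columns).
#' @param theta Target direction in deg (scalar).
#' @return Numeric vector of tuning factors in [0, 1].
#' @export
direction_tuning <- function(neurons, theta) {
  d <- wrap_angle(theta - neurons$pref_dir)
  exp(-d^2 / (2 * neurons$dir_width^2))
}

#' Speed tuning of model MT neurons
#'
#' Log-Gaussian tuning: `exp(-log2(s / s')^2 / (2 tau_s^2))`.
#'
#' @param neurons An `mt_population` data frame.
#' @param s Target speed in deg/s (`> 0`).
#' @return Numeric vector of tuning factors in [0, 1].
#' @export
speed_tuning <- function(neurons, s) {
  if (any(s <= 0)) stop("target speed must be > 0")
  exp(-log2(s / neurons$pref_speed)^2 / (2 * neurons$speed_width^2))
}

# intersection area of two discs with radii r1, r2 and centre distance d
circle_overlap_area <- function(r1, r2, d) {
  r1 <- pmax(r1, 0); r2 <- pmax(r2, 0)
  out <- numeric(length(d))
  contained <- d <= abs(r1 - r2)
  disjoint <- d >= r1 + r2
  partial <- !contained & !disjoint
  out[contained] <- pi * pmin(r1, r2)[contained]^2
  if (any(partial)) {
    dd <- d[partial]; a <- r1[partial]; b <- r2[partial]
    d1 <- (dd^2 + a^2 - b^2) / (2 * dd)
    d2 <- dd - d1
    out[partial] <-
      a^2 * acos(pmin(pmax(d1 / a, -1), 1)) -
      d1 * sqrt(pmax(a^2 - d1^2, 0)) +
      b^2 * acos(pmin(pmax(d2 / b, -1), 1)) -
      d2 * sqrt(pmax(b^2 - d2^2, 0))
  }
  out
}

#' Overlap of the stimulus with classical receptive field and surround
#'
#' Computes, by exact circle-circle lens geometry, the fraction `z` of each
#' neuron's classical receptive field covered by a stimulus disc of diameter
#' `rho` centred at the fovea, and the fraction `z_sur` of the suppressive
#' surround covered. By default the surround region is the annulus between
#' the classical receptive-field radius and three times that radius,
#' normalised by annulus area; set `surround_full_disc` in [mt_config()] to
#' normalise by the full surround disc instead.
#'
#' @param neurons An `mt_population` data frame.
#' @param rho Stimulus (patch) diameter in deg (`> 0`).
#' @param config An [mt_config()]; defaults to the population's attribute.
#' @return A list with numeric vectors `z` and `z_sur`, both in [0, 1].
#' @export
rf_overlap <- function(neurons, rho, config = attr(neurons, "config")) {
  if (rho <= 0) stop("stimulus diameter must be > 0")
  if (is.null(config)) config <- mt_config()
  r_stim <- rho / 2
  r_crf <- neurons$rf_diameter / 2
  r_sur <- neurons$surround_radius
  d <- sqrt(neurons$x^2 + neurons$y^2)
  a_crf <- circle_overlap_area(rep(r_stim, length(d)), r_crf, d)
  a_out <- circle_overlap_area(rep(r_stim, length(d)), r_sur, d)
  z <- a_crf / (pi * r_crf^2)
  z_sur <- if (isTRUE(config$surround_full_disc)) {
    a_out / (pi * r_sur^2)
  } else {
    (a_out - a_crf) / (pi * (r_sur^2 - r_crf^2))
  }
  list(z = pmin(pmax(z, 0), 1), z_sur = pmin(pmax(z_sur, 0), 1))
}

#' Threshold nonlinearity of receptive-field summation
#'
#' `([sqrt(z) - omega]+ / (1 - omega))^n`, applied identically to classical
#' receptive field and surround overlaps.
#'
#' @param z Overlap fraction(s) in [0, 1].
#' @param omega Threshold in [0, 1).
#' @param n_exp Exponent (`> 0`).
#' @return Thresholded response(s) in [0, 1].
#' @export
thresholded_response <- function(z, omega = 0, n_exp = 1) {
  if (omega >= 1) stop("omega must be < 1")
  if (any(z < 0 | z > 1)) stop("overlap fraction must lie in [0, 1]")
  (pmax(sqrt(z) - omega, 0) / (1 - omega))^n_exp
}

#' Divisive surround normalisation
#'
#' `f_rho = r_crf / ((1 - beta) + beta (epsilon + (r_crf + r_sur) / 2))`.
#' With `epsilon = 0.5` the output lies in [0, 1] when `beta = 1`.
#'
#' @param r_crf,r_sur Thresholded centre and surround responses in [0, 1].
#' @param beta Suppression strength in [0, 1].
#' @param epsilon Normalisation constant (`> 0`).
#' @return Size factor(s) `f_rho`.
#' @export
surround_normalization <- function(r_crf, r_sur, beta = 1, epsilon = 0.5) {
  den <- (1 - beta) + beta * (epsilon + (r_crf + r_sur) / 2)
  if (any(den == 0)) stop("zero denominator in surround normalisation")
  r_crf / den
}

#' Deterministic mean response of the population to a stimulus
#'
#' `f_i = A_i f_theta f_s f_rho` in spikes/s, combining direction tuning,
#' speed tuning and the surround-normalised size factor.
#'
#' @param neurons An `mt_population` data frame.
#' @param condition A list or one-row data frame with `direction` (label or
#'   angle in deg), `target_speed_degps` and `target_size_deg`.
#' @param config An [mt_config()]; defaults to the population's attribute.
#' @return Numeric vector of mean firing rates, one per neuron.
#' @export
mean_response <- function(neurons, condition,
                          config = attr(neurons, "config")) {
  if (is.null(config)) config <- mt_config()
  theta <- direction_angle(condition$direction)
  ov <- rf_overlap(neurons, condition$target_size_deg, config)
  r_crf <- thresholded_response(ov$z, config$omega, config$n_exp)
  r_sur <- thresholded_response(ov$z_sur, config$omega, config$n_exp)
  f_rho <- surround_normalization(r_crf, r_sur, config$beta, config$epsilon)
  neurons$amplitude *
    direction_tuning(neurons, theta) *
    speed_tuning(neurons, condition$target_speed_degps) *
    f_rho
}

#' Pairwise noise-correlation matrix of the population
#'
#' Correlations decay with the (wrapped) difference in preferred direction,
#' the difference in preferred speed (log2 units) and the Euclidean distance
#' between receptive-field centres:
#' \deqn{r_{ij} = r_{max}\, e^{-\Delta PD^2 / (\Delta PD_{max}^2
#'   \lambda_\theta^2)}\, e^{-\Delta PS^2 / (\Delta PS_{max}^2 \lambda_s^2)}
#'   \, e^{-\Delta C^2 / (\Delta C_{max}^2 \lambda_C^2)},}
#' with the diagonal set to 1. If the result has an eigenvalue below
#' `-1e-10` it is projected to the nearest valid correlation matrix
#' (negative eigenvalues clipped, diagonal rescaled to 1); the Frobenius norm
#' of the adjustment is attached as attribute `"repair_frobenius"` (0 when no
#' repair was needed).
#'
#' @param neurons An `mt_population` data frame.
#' @param config An [mt_config()]; defaults to the population's attribute.
#' @return A symmetric unit-diagonal correlation matrix.
#' @export
mt_correlations <- function(neurons, config = attr(neurons, "config")) {
  if (is.null(config)) config <- mt_config()
  if (nrow(neurons) < 2) stop("need at least 2 neurons")
  dpd <- wrap_angle(outer(neurons$pref_dir, neurons$pref_dir, `-`))
  dps <- outer(log2(neurons$pref_speed), log2(neurons$pref_speed), `-`)
  dc2 <- outer(neurons$x, neurons$x, `-`)^2 +
    outer(neurons$y, neurons$y, `-`)^2
  R <- config$r_max *
    exp(-dpd^2 / (config$dpd_max^2 * config$lambda_theta^2)) *
    exp(-dps^2 / (config$dps_max^2 * config$lambda_s^2)) *
    exp(-dc2 / (config$dc_max^2 * config$lambda_c^2))
  diag(R) <- 1
  repair <- 0
  # cheap PD probe; full eigen decomposition only if factorisation fails
  ok <- !inherits(tryCatch(chol(R), error = function(e) e), "error")
  if (!ok) {
    ed <- eigen(R, symmetric = TRUE)
    vals <- pmax(ed$values, 0)
    R2 <- ed$vectors %*% (vals * t(ed$vectors))
    dsc <- 1 / sqrt(diag(R2))
    R2 <- R2 * tcrossprod(dsc)
    repair <- sqrt(sum((R2 - R)^2))
    R <- R2
  }
  attr(R, "repair_frobenius") <- repair
  R
}

#' Sample correlated single-trial population responses
#'
#' Draws trial rates `MT_i = f_i + eta_i` where `eta` is zero-mean
#' multivariate Gaussian with covariance
#' `Sigma_ij = r_ij sqrt(f_i) sqrt(f_j)`, i.e. Poisson-like variance equal to
#' the mean rate with the prescribed correlation structure. Neurons with zero
#' mean rate receive no noise. Negative rates are rectified to zero unless
#' `rectify = FALSE`. The matched first and second moments stand in for an
#' explicit correlated point-process sampler; this is the place to swap in a
#' copula-based alternative.
#'
#' @param neurons An `mt_population` data frame.
#' @param condition Stimulus condition; see [mean_response()].
#' @param n_trials Number of trials (`>= 1`).
#' @param config An [mt_config()]; defaults to the population's attribute.
#' @param seed Optional integer seed.
#' @param chol_corr Optional pre-computed upper Cholesky factor of the
#'   correlation matrix (reused across conditions for speed).
#' @param rectify Rectify negative rates to 0 (default `TRUE`).
#' @return A list with `rates` (n_trials x n_neurons matrix, spikes/s),
#'   `mean_rates` (the deterministic rates `f`) and `condition`.
#' @export
sample_responses <- function(neurons, condition, n_trials,
                             config = attr(neurons, "config"), seed = NULL,
                             chol_corr = NULL, rectify = TRUE) {
  stopifnot(n_trials >= 1)
  if (is.null(config)) config <- mt_config()
  if (is.null(chol_corr)) {
    R <- mt_correlations(neurons, config)
    chol_corr <- tryCatch(chol(R), error = function(e)
      stop("correlation matrix not factorizable after PSD repair"))
  }
  f <- mean_response(neurons, condition, config)
  with_seed(seed, {
    Z <- matrix(rnorm(n_trials * nrow(neurons)), n_trials)
    eta <- (Z %*% chol_corr) * rep(sqrt(f), each = n_trials)
    rates <- eta + rep(f, each = n_trials)
    if (rectify) rates <- pmax(rates, 0)
    list(rates = rates, mean_rates = f, condition = condition)
  })
}
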