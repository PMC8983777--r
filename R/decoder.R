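#' Configuration of the two-pathway pursuit decoder
#'
#' The decoder reads the MT population along two parallel pathways: a
#' vector-average estimate of log2 target speed (regularised by `nu`) and a
#' vector-sum gain signal normalised by `c`. The simulated eye speed on each
#' trial is `m = (G_MT + eta_G) * s_hat` with `eta_G ~ N(0, sigma^2)`.
#'
#' The default `sigma = 0.30` is not a published constant: it was chosen once
#' as the smallest value on a coarse grid (0.05 to 0.50 in steps of 0.05) for
#' which the simulated behavior's per-size Weber fractions separate cleanly by
#' target size across independent population draws (see the shipped script
#' `scripts/choose-gain-noise-sd.R`); it is documented as derived, not
#' published.
#'
#' @param nu Regulariser of the vector-average denominator (default 0.05).
#' @param c_norm Gain normaliser; `NA` until calibrated with
#'   [calibrate_decoder()].
#' @param sigma Standard deviation of the additive gain noise (default 0.30).
#' @param calibration_target Mean eye speed the calibration enforces for the
#'   20-deg patch averaged across speeds, in deg/s (default 10).
#' @param calibration_size Patch size used for calibration (default 20 deg).
#' @param calibration_speeds Speeds averaged during calibration.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(nu = 0.05, c_norm = NA_real_, sigma = 0.30,
                           calibration_target = 10, calibration_size = 20,
                           calibration_speeds = c(4, 8, 12, 16, 20)) {
  stopifnot(nu > 0, sigma >= 0, calibration_target > 0)
  structure(list(nu = nu, c_norm = c_norm, sigma = sigma,
                 calibration_target = calibration_target,
                 calibration_size = calibration_size,
                 calibration_speeds = calibration_speeds),
            class = "decoder_config")
}

#' Vector-average estimate of log2 target speed
#'
#' \deqn{\hat{s}_h = \frac{\sum_i \cos\theta'_i\, MT_i \log_2 s'_i}
#'   {\nu + \sum_i MT_i},} analogously with sine for \eqn{\hat{s}_v}, and
#' \eqn{\hat{s} = \sqrt{\hat{s}_h^2 + \hat{s}_v^2}} (log2 deg/s units).
#'
#' @param rates Trials x neurons rate matrix (or a single rate vector).
#' @param neurons An `mt_population` data frame.
#' @param nu Regulariser (`> 0`).
#' @return Data frame with columns `s_hat_h`, `s_hat_v`, `s_hat`.
#' @export
vector_average_speed <- function(rates, neurons, nu = 0.05) {
  if (is.vector(rates)) rates <- matrix(rates, nrow = 1)
  w <- log2(neurons$pref_speed)
  th <- neurons$pref_dir * pi / 180
  den <- nu + rowSums(rates)
  s_h <- as.numeric(rates %*% (cos(th) * w)) / den
  s_v <- as.numeric(rates %*% (sin(th) * w)) / den
  data.frame(s_hat_h = s_h, s_hat_v = s_v, s_hat = sqrt(s_h^2 + s_v^2))
}

#' Vector-sum gain pathway
#'
#' `G_MT = (1 / c) * sum_i MT_i log2 s'_i`: an unnormalised sum over the
#' population, direction-blind as specified, linear in the rates.
#'
#' @param rates Trials x neurons rate matrix (or a single rate vector).
#' @param neurons An `mt_population` data frame.
#' @param c_norm Gain normaliser (`> 0`).
#' @return Numeric vector of gains, one per trial.
#' @export
gain_pathway <- function(rates, neurons, c_norm) {
  if (is.na(c_norm) || c_norm <= 0) stop("c_norm must be calibrated and > 0")
  if (is.vector(rates)) rates <- matrix(rates, nrow = 1)
  as.numeric(rates %*% log2(neurons$pref_speed)) / c_norm
}

#' Calibrate the gain normaliser c
#'
#' Simulates the calibration patch (default 20 deg) at all calibration speeds
#' with gain noise disabled and solves for the `c` that makes the mean
#' simulated eye speed across trials and speeds equal `calibration_target`.
#' Because the gain pathway is linear in `1/c`, the solution is a closed-form
#' rescale of the uncalibrated mean and does not depend on any initial guess.
#'
#' @param neurons An `mt_population` data frame.
#' @param config A [decoder_config()].
#' @param n_calibration_trials Trials per speed (default 1000).
#' @param seed Optional integer seed.
#' @param direction Target direction used during calibration
#'   (default "right").
#' @return The input `decoder_config` with `c_norm` set.
#' @export
calibrate_decoder <- function(neurons, config = decoder_config(),
                              n_calibration_trials = 1000, seed = NULL,
                              direction = "right") {
  stopifnot(inherits(config, "decoder_config"))
  pop_cfg <- attr(neurons, "config")
  R <- mt_correlations(neurons, pop_cfg)
  U <- chol(R)
  with_seed(seed, {
    tot <- 0
    n_tot <- 0L
    for (s in config$calibration_speeds) {
      cond <- list(direction = direction, target_speed_degps = s,
                   target_size_deg = config$calibration_size)
      resp <- sample_responses(neurons, cond, n_calibration_trials,
                               pop_cfg, chol_corr = U)
      est <- vector_average_speed(resp$rates, neurons, config$nu)
      g_unscaled <- gain_pathway(resp$rates, neurons, c_norm = 1)
      tot <- tot + sum(g_unscaled * est$s_hat)
      n_tot <- n_tot + n_calibration_trials
    }
    uncal_mean <- tot / n_tot
    if (uncal_mean == 0) stop("uncalibrated mean output is zero; cannot calibrate")
    config$c_norm <- uncal_mean / config$calibration_target
    config
  })
}

#' Simulate pursuit behavior from the biomimetic circuit
#'
#' For each trial: sample a correlated MT population response, decode the
#' vector-average speed estimate and the vector-sum gain, draw gain noise
#' `eta_G ~ N(0, sigma^2)` and emit the simulated eye speed
#' `m = (G_MT + eta_G) * s_hat`.
#'
#' @param neurons An `mt_population` data frame.
#' @param config A calibrated [decoder_config()].
#' @param conditions Condition grid as from [pursuit_conditions()].
#' @param n_per_condition Trials per condition.
#' @param seed Optional integer seed.
#' @param keep_rates If `TRUE`, the per-condition rate matrices are attached
#'   as attribute `"rates"` (a list indexed by condition row), for
#'   neuron-behavior correlation analyses.
#' @return A trial data frame with columns `trial_id`, `direction`,
#'   `target_speed_degps`, `target_size_deg`, `s_hat_h`, `s_hat_v`, `s_hat`,
#'   `g_mt`, `eta_g`, `eye_speed_degps`.
#' @export
simulate_pursuit_behavior <- function(neurons, config, conditions,
                                      n_per_condition, seed = NULL,
                                      keep_rates = FALSE) {
  stopifnot(inherits(config, "decoder_config"))
  if (is.na(config$c_norm)) stop("decoder not calibrated; run calibrate_decoder()")
  pop_cfg <- attr(neurons, "config")
  R <- mt_correlations(neurons, pop_cfg)
  U <- chol(R)
  with_seed(seed, {
    out <- vector("list", nrow(conditions))
    rates_kept <- if (keep_rates) vector("list", nrow(conditions)) else NULL
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, , drop = FALSE]
      resp <- sample_responses(neurons, as.list(cond), n_per_condition,
                               pop_cfg, chol_corr = U)
      est <- vector_average_speed(resp$rates, neurons, config$nu)
      g <- gain_pathway(resp$rates, neurons, config$c_norm)
      eta <- if (config$sigma > 0) rnorm(n_per_condition, 0, config$sigma)
             else numeric(n_per_condition)
      out[[ci]] <- data.frame(
        direction = cond$direction,
        target_speed_degps = cond$target_speed_degps,
        target_size_deg = cond$target_size_deg,
        s_hat_h = est$s_hat_h, s_hat_v = est$s_hat_v, s_hat = est$s_hat,
        g_mt = g, eta_g = eta,
        eye_speed_degps = (g + eta) * est$s_hat,
        stringsAsFactors = FALSE)
      if (keep_rates) rates_kept[[ci]] <- resp$rates
    }
    trials <- do.call(rbind, out)
    trials <- cbind(trial_id = seq_len(nrow(trials)), trials)
    if (keep_rates) attr(trials, "rates") <- rates_kept
    trials
  })
}

#' Weber-fraction analysis of simulated behavior
#'
#' Routes the simulated eye speeds through the same analysis applied to real
#' behavior: per-condition statistics, per-size (flexible) and gain-noise
#' variance-model fits.
#'
#' @param sim_trials Output of [simulate_pursuit_behavior()] (single
#'   direction).
#' @param train_speeds Speeds used for fitting (default all, as the
#'   simulated-behavior analysis has no held-out requirement).
#' @return List with `stats` (condition statistics), `flexible` and
#'   `gain_noise` (`weber_fit` objects).
#' @export
analyze_simulated_weber <- function(sim_trials, train_speeds = NULL) {
  st <- condition_stats(sim_trials)
  list(stats = st,
       flexible = fit_variance_model(st, "flexible_w",
                                     train_speeds = train_speeds),
       gain_noise = fit_variance_model(st, "gain_noise",
                                       train_speeds = train_speeds))
}

#' Trial-by-trial MT-pursuit correlations
#'
#' For neurons whose preferred direction lies within +/-45 deg of the target
#' direction (preferred class) or within +/-45 deg of its opposite (null
#' class), computes the Pearson correlation between the neuron's single-trial
#' rate and the simulated eye speed across trials of one fixed condition,
#' with the p-value from the standard correlation t-test.
#'
#' @param rates Trials x neurons rate matrix for a single condition.
#' @param m Simulated eye speeds for the same trials.
#' @param neurons An `mt_population` data frame.
#' @param condition The stimulus condition (for the target direction and the
#'   speed-ratio covariate).
#' @return Data frame with one row per selected neuron: `id`, `class`
#'   (`"preferred"`/`"null"`), `correlation`, `p_value`,
#'   `log2_speed_ratio` (log2 of target speed over preferred speed) and
#'   `zero_variance` flag (correlation `NA` when the neuron never varies).
#' @export
mt_pursuit_correlations <- function(rates, m, neurons, condition) {
  if (nrow(rates) < 50)
    stop("need >= 50 trials of one condition for neuron-behavior correlations")
  stopifnot(nrow(rates) == length(m))
  theta <- direction_angle(condition$direction)
  dpd <- abs(wrap_angle(neurons$pref_dir - theta))
  cls <- ifelse(dpd <= 45, "preferred",
                ifelse(dpd >= 135, "null", NA_character_))
  sel <- which(!is.na(cls))
  out <- lapply(sel, function(i) {
    x <- rates[, i]
    if (stats::sd(x) == 0)
      return(data.frame(id = neurons$id[i], class = cls[i],
                        correlation = NA_real_, p_value = NA_real_,
                        log2_speed_ratio =
                          log2(condition$target_speed_degps /
                                 neurons$pref_speed[i]),
                        zero_variance = TRUE))
    ct <- stats::cor.test(x, m)
    data.frame(id = neurons$id[i], class = cls[i],
               correlation = unname(ct$estimate), p_value = ct$p.value,
               log2_speed_ratio = log2(condition$target_speed_degps /
                                         neurons$pref_speed[i]),
               zero_variance = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
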