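#' Build the grid of pursuit stimulus conditions
#'
#' The default grid mirrors the behavioral task: target speeds drawn from five
#' values evenly spaced between 4 and 20 deg/s, dot-patch diameters of 2, 6
#' and 20 deg, and leftward or rightward motion.
#'
#' @param speeds Target speeds in deg/s (all `> 0`).
#' @param sizes Patch diameters in deg (all `> 0`).
#' @param directions Character vector from `c("right", "left")`.
#' @return A data frame with columns `direction`, `target_speed_degps`,
#'   `target_size_deg`, one row per condition.
#' @export
pursuit_conditions <- function(speeds = c(4, 8, 12, 16, 20),
                               sizes = c(2, 6, 20),
                               directions = c("right", "left")) {
  stopifnot(all(speeds > 0), all(sizes > 0),
            all(directions %in% c("right", "left")))
  out <- expand.grid(direction = directions,
                     target_speed_degps = speeds,
                     target_size_deg = sizes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[order(out$direction, out$target_size_deg, out$target_speed_degps), ,
      drop = FALSE]
}

#' Simulate single-trial eye speeds from the gain-noise model
#'
#' Draws, for each trial, \eqn{E = (G_i + \eta_G)(s + \eta_s) + \eta_m} with
#' \eqn{\eta_G \sim N(0, \sigma^2)}, \eqn{\eta_s \sim N(0, w_s^2 s^2)} and
#' \eqn{\eta_m \sim N(0, w_m^2 \mu^2)}, \eqn{\mu = G_i s}, all independent.
#' The gain \eqn{G_i} is looked up in `params$gains` by target size.
#'
#' @param params A [gain_noise_params()] object.
#' @param conditions Condition grid as from [pursuit_conditions()].
#' @param n_per_condition Number of trials per condition (`>= 1`).
#' @param seed Optional integer seed; fixing it reproduces trials exactly.
#' @return A data frame of trials with columns `trial_id`, `direction`,
#'   `target_speed_degps`, `target_size_deg`, `eye_speed_degps`.
#' @examples
#' p <- gain_noise_params(sigma = 0, w_s = 0, w_m = 0, gains = c(`20` = 0.62))
#' tr <- simulate_pursuit_trials(p, pursuit_conditions(speeds = 20, sizes = 20,
#'                                                     directions = "right"),
#'                               n_per_condition = 3, seed = 1)
#' tr$eye_speed_degps  # exactly 12.4 deg/s
#' @export
simulate_pursuit_trials <- function(params, conditions = pursuit_conditions(),
                                    n_per_condition = 100, seed = NULL) {
  stopifnot(inherits(params, "gain_noise_params"), n_per_condition >= 1)
  key <- as.character(conditions$target_size_deg)
  if (!all(key %in% names(params$gains)))
    stop("no gain configured for target size(s): ",
         paste(unique(key[!key %in% names(params$gains)]), collapse = ", "))
  idx <- rep(seq_len(nrow(conditions)), each = n_per_condition)
  s <- conditions$target_speed_degps[idx]
  G <- unname(params$gains[key[idx]])
  mu <- G * s
  n <- length(s)
  with_seed(seed, {
    eta_g <- rnorm(n, 0, params$sigma)
    eta_s <- rnorm(n, 0, params$w_s * s)
    eta_m <- rnorm(n, 0, params$w_m * mu)
    data.frame(trial_id = seq_len(n),
               direction = conditions$direction[idx],
               target_speed_degps = s,
               target_size_deg = conditions$target_size_deg[idx],
               eye_speed_degps = (G + eta_g) * (s + eta_s) + eta_m,
               stringsAsFactors = FALSE)
  })
}

#' Simulate trials from a gain-noise parameter object
#'
#' `simulate()` method wrapping [simulate_pursuit_trials()]: `nsim` is the
#' number of trials per condition.
#'
#' @param object A [gain_noise_params()] object.
#' @param nsim Trials per condition.
#' @param seed Optional integer seed.
#' @param conditions Condition grid, default [pursuit_conditions()] restricted
#'   to the sizes with configured gains.
#' @param ... Ignored.
#' @return A trial data frame; see [simulate_pursuit_trials()].
#' @export
simulate.gain_noise_params <- function(object, nsim = 100, seed = NULL,
                                       conditions = NULL, ...) {
  if (is.null(conditions))
    conditions <- pursuit_conditions(sizes = as.numeric(names(object$gains)))
  simulate_pursuit_trials(object, conditions, n_per_condition = nsim,
                          seed = seed)
}
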