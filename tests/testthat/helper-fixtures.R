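# Shared fixtures, all built in code at test time.

# small MT population for fast decoder tests
small_population <- function(n = 160, n_foveal = 30, seed = 101) {
  mt_population(mt_config(n_total = n, n_foveal = n_foveal), seed = seed)
}

# a pair of identically tuned neurons at the same RF centre, high mean rate
identical_pair <- function(ecc = 0.3, amplitude = 100) {
  rf <- (0.69 * ecc + 1) / sqrt(pi)
  pop <- data.frame(
    id = 1:2, pref_dir = 0, dir_width = 60, pref_speed = 16,
    speed_width = 2, amplitude = amplitude, ecc = ecc, x = ecc, y = 0,
    rf_diameter = rf, surround_radius = 3 * rf / 2)
  attr(pop, "config") <- mt_config()
  class(pop) <- c("mt_population", "data.frame")
  pop
}

# deterministic traces built directly from the template for alignment tests
template_traces <- function(onsets, plateaus, cfg = trace_config(
                              latency_jitter_halfwidth = 0),
                            direction = "right", speed = 10, size = 20) {
  time <- seq(0, cfg$duration - cfg$sample_interval, by = cfg$sample_interval)
  traces <- t(vapply(seq_along(onsets), function(k)
    pursuitgain:::trace_template(time, onsets[k], cfg$rise_time, plateaus[k]),
    numeric(length(time))))
  trials <- data.frame(trial_id = seq_along(onsets), direction = direction,
                       target_speed_degps = speed, target_size_deg = size,
                       eye_speed_degps = NA_real_,
                       plateau_degps = plateaus,
                       true_latency_offset_ms = onsets - cfg$nominal_latency,
                       saccade_injected = FALSE)
  structure(list(trials = trials, traces = traces, time = time, config = cfg),
            class = "pursuit_traces")
}

# condition statistics that follow sigma^2 = w_i^2 mu^2 exactly
exact_weber_stats <- function(w_by_size, gains = monkey_gains("R"),
                              speeds = c(4, 8, 12, 16, 20)) {
  sizes <- as.numeric(names(w_by_size))
  grid <- expand.grid(target_size_deg = sizes, target_speed_degps = speeds)
  mu <- unname(gains[as.character(grid$target_size_deg)]) *
    grid$target_speed_degps
  w <- unname(w_by_size[as.character(grid$target_size_deg)])
  data.frame(grid, n = 1000, mean_degps = mu, var_degps2 = w^2 * mu^2)
}
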