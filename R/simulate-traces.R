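#' Configuration of synthetic eye-speed traces
#'
#' Traces are zero before pursuit onset, rise along a half-cosine ramp of
#' length `rise_time` beginning at `nominal_latency + delta` (with the
#' per-trial latency offset `delta ~ Uniform(-h, +h)`), and then hold a
#' plateau equal to the trial's scalar eye speed. The trace template is
#' deliberately simple: any smooth monotone onset with a known ground-truth
#' latency suffices to exercise the latency-alignment machinery. The default
#' latency and rise time put the (unjittered) plateau onset at 105 ms, just
#' before the 110-190 ms averaging window, so that after realignment the
#' window average recovers the plateau exactly.
#'
#' @param sample_interval Sampling interval in ms (`> 0`).
#' @param duration Trace duration in ms; column 1 is target-motion onset (t = 0).
#' @param nominal_latency Mean pursuit latency in ms (`0 < latency < duration`).
#' @param rise_time Ramp duration in ms.
#' @param latency_jitter_halfwidth Halfwidth `h` of the uniform latency jitter
#'   in ms; must stay `<= 40` so jittered onsets remain inside the alignment
#'   search grid.
#' @param sample_noise_sd Optional additive white measurement noise per sample
#'   (deg/s); default 0 (off).
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(sample_interval = 1, duration = 300,
                         nominal_latency = 75, rise_time = 30,
                         latency_jitter_halfwidth = 20,
                         sample_noise_sd = 0) {
  stopifnot(sample_interval > 0, nominal_latency > 0,
            nominal_latency < duration, rise_time >= 0,
            latency_jitter_halfwidth >= 0, sample_noise_sd >= 0)
  if (latency_jitter_halfwidth > 40)
    stop("latency_jitter_halfwidth must be <= 40 ms to stay inside the alignment grid")
  structure(list(sample_interval = sample_interval, duration = duration,
                 nominal_latency = nominal_latency, rise_time = rise_time,
                 latency_jitter_halfwidth = latency_jitter_halfwidth,
                 sample_noise_sd = sample_noise_sd),
            class = "trace_config")
}

# half-cosine onset template: 0 before `onset`, plateau after onset + rise
trace_template <- function(time, onset, rise, plateau) {
  y <- numeric(length(time))
  ramp <- time >= onset & time < onset + rise
  y[ramp] <- plateau * 0.5 * (1 - cos(pi * (time[ramp] - onset) / rise))
  y[time >= onset + rise] <- plateau
  y
}

#' Simulate time-resolved eye-speed traces
#'
#' Generates scalar trial speeds with [simulate_pursuit_trials()] and wraps
#' each in a jittered half-cosine onset trace. The per-trial latency offset is
#' recorded as ground truth (`true_latency_offset_ms`), enabling direct checks
#' of the alignment algorithm.
#'
#' @inheritParams simulate_pursuit_trials
#' @param trace_cfg A [trace_config()] object.
#' @return An object of class `pursuit_traces`: a list with elements
#'   `trials` (trial table; `eye_speed_degps` is `NA` until the pipeline fills
#'   it, `plateau_degps` holds the generated scalar), `traces` (trials x
#'   samples matrix of eye speed in deg/s), `time` (sample times in ms, first
#'   column is target-motion onset) and `config`.
#' @export
simulate_pursuit_traces <- function(params, conditions = pursuit_conditions(),
                                    n_per_condition = 100, seed = NULL,
                                    trace_cfg = trace_config()) {
  stopifnot(inherits(trace_cfg, "trace_config"))
  with_seed(seed, {
    trials <- simulate_pursuit_trials(params, conditions, n_per_condition)
    n <- nrow(trials)
    time <- seq(0, trace_cfg$duration - trace_cfg$sample_interval,
                by = trace_cfg$sample_interval)
    h <- trace_cfg$latency_jitter_halfwidth
    delta <- if (h > 0) runif(n, -h, h) else numeric(n)
    traces <- matrix(0, n, length(time))
    for (k in seq_len(n)) {
      traces[k, ] <- trace_template(time,
                                    trace_cfg$nominal_latency + delta[k],
                                    trace_cfg$rise_time,
                                    trials$eye_speed_degps[k])
    }
    if (trace_cfg$sample_noise_sd > 0)
      traces <- traces + matrix(rnorm(length(traces), 0,
                                      trace_cfg$sample_noise_sd),
                                nrow = n)
    trials$plateau_degps <- trials$eye_speed_degps
    trials$eye_speed_degps <- NA_real_
    trials$true_latency_offset_ms <- delta
    trials$saccade_injected <- FALSE
    structure(list(trials = trials, traces = traces, time = time,
                   config = trace_cfg),
              class = "pursuit_traces")
  })
}

#' @export
print.pursuit_traces <- function(x, ...) {
  cat(sprintf("Pursuit traces: %d trials x %d samples (%g ms interval, %g ms duration)\n",
              nrow(x$traces), ncol(x$traces),
              x$config$sample_interval, x$config$duration))
  cat(sprintf("  conditions: %d; latency %g +/- %g ms, rise %g ms\n",
              nrow(unique(x$trials[c("direction", "target_speed_degps",
                                     "target_size_deg")])),
              x$config$nominal_latency, x$config$latency_jitter_halfwidth,
              x$config$rise_time))
  invisible(x)
}

#' Inject saccade-like velocity spikes into selected trials
#'
#' Adds a one-sample velocity transient to the chosen trials and marks them in
#' the trial table, purely so the saccade-exclusion step can be tested against
#' ground truth.
#'
#' @param x A `pursuit_traces` object.
#' @param trial_ids Trial ids to contaminate.
#' @param amplitude Spike amplitude in deg/s (default 200).
#' @param at_ms Spike time in ms (default 150, inside the screening window).
#' @return The modified `pursuit_traces` object.
#' @export
inject_saccades <- function(x, trial_ids, amplitude = 200, at_ms = 150) {
  stopifnot(inherits(x, "pursuit_traces"))
  col <- which.min(abs(x$time - at_ms))
  rows <- match(trial_ids, x$trials$trial_id)
  if (anyNA(rows)) stop("unknown trial id(s)")
  x$traces[rows, col] <- x$traces[rows, col] + amplitude
  x$trials$saccade_injected[rows] <- TRUE
  x
}
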