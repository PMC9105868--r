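#' Configuration for the gait-like pressure simulator
#'
#' The simulator emulates the statistical structure of intra-socket strip
#' recordings during level walking: every sensor in a redundancy group
#' follows one latent periodic gait waveform (scaled by a per-sensor gain,
#' plus sensor noise, clamped at the device ceiling), and different groups
#' follow waveforms that load at different phases of the same stride.
#'
#' The latent waveform per gait cycle is a raised, asymmetric pulse: a
#' rectified sinusoid taken to a power over the stance fraction of the
#' cycle (peaky stance), flat at the baseline over swing. Trough to trough
#' is one full gait cycle. Cycle periods get small independent jitter so
#' that the number of cycles per 5 s frame varies (four to five at the
#' default cadence), as in real self-selected-speed walking.
#'
#' @param group_assignment integer/character vector, one group id per
#'   sensor; its length is the number of sensors.
#' @param sensor_labels labels, default `"1".."n"`.
#' @param sampling_rate Hz; default 100.
#' @param duration seconds; default 30 (3000 samples at 100 Hz).
#' @param cadence gait cycles per second; default 0.9 (4--5 cycles per
#'   5 s frame).
#' @param period_jitter per-cycle uniform period jitter as a fraction of
#'   the nominal period; default 0.05.
#' @param base_amplitude named numeric, pulse amplitude (kPa) per group.
#' @param baseline named numeric, swing-phase pressure (kPa) per group.
#' @param phase named numeric, phase offset per group as a fraction of
#'   the cycle.
#' @param stance_fraction fraction of the cycle under load; default 0.6.
#' @param pulse_power exponent sharpening the stance pulse; default 2.
#' @param gain per-sensor multiplicative factor; default `NULL` draws one
#'   per sensor uniformly in \[0.9, 1.1\] from `seed` (adjacent sensors
#'   under one region read similar magnitudes).
#' @param noise_sd iid Gaussian sensor noise sd in kPa; default 2.
#' @param ceiling saturation ceiling in kPa; default 64.
#' @param seed integer seed driving all randomness.
#' @return a list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(group_assignment,
                            sensor_labels = as.character(seq_along(group_assignment)),
                            sampling_rate = 100, duration = 30,
                            cadence = 0.9, period_jitter = 0.05,
                            base_amplitude = NULL, baseline = NULL,
                            phase = NULL, stance_fraction = 0.6,
                            pulse_power = 2, gain = NULL, noise_sd = 2,
                            ceiling = 64, seed = 1L) {
  n <- length(group_assignment)
  if (n < 1) stop_config("need at least one sensor")
  if (length(sensor_labels) != n) stop_config("one label per sensor required")
  if (cadence <= 0) stop_config("cadence must be positive")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  groups <- unique(as.character(group_assignment))
  g <- length(groups)
  named_per_group <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.null(names(x))) {
      x <- rep_len(x, g)
      names(x) <- groups
    }
    if (!all(groups %in% names(x))) stop_config("missing per-group parameter")
    x[groups]
  }
  structure(
    list(group_assignment = as.character(group_assignment),
         sensor_labels = as.character(sensor_labels),
         groups = groups,
         sampling_rate = sampling_rate, duration = duration,
         cadence = cadence, period_jitter = period_jitter,
         base_amplitude = named_per_group(base_amplitude,
                                          seq(40, 70, length.out = max(g, 2))[seq_len(g)]),
         baseline = named_per_group(baseline, 5),
         phase = named_per_group(phase,
                                 seq(0, 0.9, length.out = g + 1)[seq_len(g)]),
         stance_fraction = stance_fraction, pulse_power = pulse_power,
         gain = gain, noise_sd = noise_sd, ceiling = ceiling,
         seed = as.integer(seed)),
    class = "gait_sim_config")
}

# Raised asymmetric stance pulse on phase u in [0, 1).
gait_pulse <- function(u, stance_fraction, pulse_power) {
  p <- numeric(length(u))
  s <- u < stance_fraction
  p[s] <- sin(pi * u[s] / stance_fraction)^pulse_power
  p
}

#' Simulate a multi-sensor gait pressure recording
#'
#' Sensor s in group g reads
#' `clamp(gain_s * w_g(t) + eps_s(t), 0, ceiling)` where `w_g` is the
#' group's latent waveform and `eps` is iid Gaussian noise. Identical
#' `(cfg, seed)` gives identical output.
#'
#' @param cfg a [gait_sim_config()].
#' @return a [sensor_recording()] with `reading_range = c(0, ceiling)`.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  n_samples <- round(cfg$duration * cfg$sampling_rate)
  t <- (seq_len(n_samples) - 1) / cfg$sampling_rate
  n_sensors <- length(cfg$group_assignment)

  with_seed(cfg$seed, {
    # shared stride timing: every sensor sees the same (jittered) gait
    nominal <- 1 / cfg$cadence
    n_cycles <- ceiling(cfg$duration * cfg$cadence) + 2L
    durations <- nominal *
      (1 + stats::runif(n_cycles, -cfg$period_jitter, cfg$period_jitter))
    starts <- c(0, cumsum(durations))
    cyc <- findInterval(t, starts)
    u <- (t - starts[cyc]) / durations[cyc]

    waves <- sapply(cfg$groups, function(g) {
      ug <- (u + cfg$phase[[g]]) %% 1
      cfg$baseline[[g]] + cfg$base_amplitude[[g]] *
        gait_pulse(ug, cfg$stance_fraction, cfg$pulse_power)
    })

    gain <- cfg$gain
    if (is.null(gain)) gain <- stats::runif(n_sensors, 0.9, 1.1)
    gain <- rep_len(gain, n_sensors)

    readings <- waves[, match(cfg$group_assignment, cfg$groups), drop = FALSE]
    readings <- sweep(readings, 2, gain, `*`)
    if (cfg$noise_sd > 0) {
      readings <- readings +
        matrix(stats::rnorm(n_samples * n_sensors, sd = cfg$noise_sd),
               n_samples, n_sensors)
    }
    readings <- pmin(pmax(readings, 0), cfg$ceiling)
    sensor_recording(readings, cfg$sensor_labels,
                     sampling_rate = cfg$sampling_rate,
                     reading_range = c(0, cfg$ceiling))
  })
}

#' Reference two-group synthetic fixture
#'
#' A ready-made stand-in for the (unavailable) clinical strip data: 10
#' sensors labeled "1".."10", 3000 samples at 100 Hz, redundancy groups
#' `{1,2,6}` and `{3,4,5,7,8,9,10}`, moderate sensor noise, with the
#' larger group's waveform amplitude driving some sensors into saturation
#' at 64 kPa.
#'
#' @param seed integer seed; the same seed reproduces the recording
#'   exactly.
#' @param noise_sd Gaussian noise sd in kPa; default 2.
#' @return a [sensor_recording()].
#' @export
demo_recording <- function(seed = 1L, noise_sd = 2) {
  cfg <- gait_sim_config(
    group_assignment = c("a", "a", "b", "b", "b", "a", "b", "b", "b", "b"),
    sensor_labels = as.character(1:10),
    base_amplitude = c(a = 40, b = 75),
    baseline = c(a = 4, b = 8),
    phase = c(a = 0, b = 0.45),
    noise_sd = noise_sd,
    seed = seed)
  simulate_recording(cfg)
}
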