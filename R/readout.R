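#' Optical sensing path simulator
#'
#' Models the LED-to-sensor path beneath the detection chamber. The measured
#' intensity is a baseline scaled by a slowly varying multiplicative ambient
#' drift (sinusoidal, emulating ambient-light variation and component
#' warm-up) with additive sensor noise; light crossing the readout droplet is
#' attenuated by a Beer-Lambert factor `10^(-A)` where `A` is the
#' absorbance-equivalent assay signal.
#'
#' @param baseline drift-free sensor intensity with a blank light path
#'   (sensor units), > 0.
#' @param drift_amplitude relative amplitude of the multiplicative ambient
#'   drift (0 = no drift).
#' @param drift_period_s period of the drift (s).
#' @param drift_phase phase offset (radians); the drift factor is 1 at time 0
#'   when the phase is 0.
#' @param noise_sd s.d. of additive sensor noise (sensor units).
#' @return An object of class `optical_sensor`; call it via [sense()].
#' @export
optical_sensor <- function(baseline = 1500, drift_amplitude = 0.05,
                           drift_period_s = 600, drift_phase = 0,
                           noise_sd = 1) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("argument error: baseline must be > 0", call. = FALSE)
  if (drift_amplitude < 0 || drift_amplitude >= 1)
    stop("argument error: drift_amplitude must be in [0, 1)", call. = FALSE)
  structure(list(baseline = baseline, drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s, drift_phase = drift_phase,
                 noise_sd = noise_sd),
            class = "optical_sensor")
}

#' Ambient drift factor of a sensor at a given time
#' @param sensor an [optical_sensor()].
#' @param time_s time (s); vectorised.
#' @return multiplicative drift factor (1 = nominal).
#' @export
drift_factor <- function(sensor, time_s) {
  stopifnot(inherits(sensor, "optical_sensor"))
  1 + sensor$drift_amplitude *
    sin(2 * pi * time_s / sensor$drift_period_s + sensor$drift_phase)
}

#' Sample instantaneous sensor intensities
#'
#' @param sensor an [optical_sensor()].
#' @param time_s sample times (s).
#' @param absorbance absorbance-equivalent signal in the light path
#'   (0 = blank).
#' @return intensities in sensor units (noise included).
#' @export
sense <- function(sensor, time_s, absorbance = 0) {
  stopifnot(inherits(sensor, "optical_sensor"))
  mu <- sensor$baseline * drift_factor(sensor, time_s) * 10^(-absorbance)
  if (sensor$noise_sd > 0) mu <- mu + stats::rnorm(length(mu), 0, sensor$noise_sd)
  mu
}

#' Acquire and filter an optical trace
#'
#' Implements the sampling protocol: `round(duration * rate)` samples at the
#' given rate (the stock protocol samples 100 times at 10 Hz over 10 s),
#' digital filtering to attenuate high-frequency noise (moving median, odd
#' window, default 5), then the arithmetic mean of the filtered trace.
#'
#' @param sensor an [optical_sensor()].
#' @param duration_s acquisition window (s), > 0.
#' @param rate_hz sampling rate (Hz), > 0.
#' @param start_s time of the first sample (s).
#' @param absorbance absorbance-equivalent signal in the path.
#' @param filter_window odd moving-median window length (1 disables
#'   filtering).
#' @return An object of class `optical_trace`: list with `time_s`,
#'   `raw`, `filtered`, `mean` (the filtered arithmetic mean), `rate_hz`.
#' @export
acquire <- function(sensor, duration_s = 10, rate_hz = 10, start_s = 0,
                    absorbance = 0, filter_window = 5) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("argument error: duration_s must be > 0", call. = FALSE)
  if (!is.finite(rate_hz) || rate_hz <= 0)
    stop("argument error: rate_hz must be > 0", call. = FALSE)
  n <- round(duration_s * rate_hz)
  if (n < 1) stop("argument error: acquisition window contains no samples",
                  call. = FALSE)
  t <- start_s + (seq_len(n) - 1) / rate_hz
  raw <- sense(sensor, t, absorbance)
  filtered <- if (filter_window > 1 && n >= filter_window)
    as.numeric(stats::runmed(raw, k = filter_window, endrule = "median"))
  else raw
  structure(list(time_s = t, raw = raw, filtered = filtered,
                 mean = mean(filtered), rate_hz = rate_hz),
            class = "optical_trace")
}

#' @export
print.optical_trace <- function(x, ...) {
  cat(sprintf("<optical_trace> %d samples at %g Hz, filtered mean = %.3f\n",
              length(x$raw), x$rate_hz, x$mean))
  invisible(x)
}

#' Write an optical trace as CSV
#' @param trace an `optical_trace`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$time_s, intensity = trace$raw,
                              filtered = trace$filtered),
                   path, row.names = FALSE)
  invisible(path)
}

#' Drift-compensating readout calibration
#'
#' The normalized calibration relationship: the final readout is the measured
#' sample intensity rescaled by the ratio of the reference baseline to the
#' instantaneous background, `I_readout = I_raw * I_ref / I_bg`. A common
#' multiplicative ambient factor applied to both `I_raw` and `I_bg` cancels
#' exactly, giving dynamic compensation of baseline drift; with `I_bg =
#' I_ref` the calibration is the identity.
#'
#' @param i_raw filtered sample intensity.
#' @param i_ref reference baseline intensity established at initialisation
#'   (> 0).
#' @param i_bg instantaneous background intensity captured just before the
#'   sample reading (> 0).
#' @return calibrated readout `I_readout`.
#' @export
calibrate_readout <- function(i_raw, i_ref, i_bg) {
  if (any(!is.finite(i_ref)) || any(i_ref <= 0))
    stop("calibration error: I_ref must be > 0", call. = FALSE)
  if (any(!is.finite(i_bg)) || any(i_bg <= 0))
    stop("calibration error: I_bg must be > 0", call. = FALSE)
  i_raw * i_ref / i_bg
}

#' Measure the detection chamber through the full readout protocol
#'
#' Runs the three-stage protocol against a chip state: (1) the reference
#' baseline `I_ref` acquired through a blank path at initialisation (time 0);
#' (2) the instantaneous background `I_bg` re-acquired through a blank path
#' at the current chip time; (3) the sample intensity `I_raw` through the
#' chamber droplet, attenuated by its absorbance-equivalent assay signal over
#' the ~3 mm chamber path; then Eq.-style drift compensation via
#' [calibrate_readout()]. Magnetic beads scatter light, so the chamber
#' droplet must have had its beads extracted before measurement.
#'
#' @param state a [chip_state()].
#' @param sensor an [optical_sensor()].
#' @param duration_s,rate_hz,filter_window sampling protocol parameters
#'   (stock: 10 s at 10 Hz, moving-median window 5).
#' @return An object of class `readout_result`: list with `i_ref`, `i_bg`,
#'   `i_raw`, `i_readout`, `absorbance`, `time_s`.
#' @export
measure_chamber <- function(state, sensor = optical_sensor(),
                            duration_s = 10, rate_hz = 10,
                            filter_window = 5) {
  stopifnot(inherits(state, "chip_state"), inherits(sensor, "optical_sensor"))
  chamber <- state$layout$detection_chamber
  d <- get_droplet(state, chamber)
  beads <- clusters_in_droplet(state, chamber)
  if (length(beads) > 0)
    stop("measurement error: beads (", paste(beads, collapse = ", "),
         ") still present in the detection chamber; extract them before ",
         "reading to avoid light scattering", call. = FALSE)
  absorb <- assay_signal(d, state$assay_params)
  t_now <- state$time_s
  i_ref <- acquire(sensor, duration_s, rate_hz, start_s = 0,
                   absorbance = 0, filter_window = filter_window)$mean
  # background and sample reads share the acquisition window: the ambient
  # drift factor is common to both and cancels exactly in the calibration
  i_bg <- acquire(sensor, duration_s, rate_hz, start_s = t_now,
                  absorbance = 0, filter_window = filter_window)$mean
  i_raw <- acquire(sensor, duration_s, rate_hz, start_s = t_now,
                   absorbance = absorb, filter_window = filter_window)$mean
  structure(list(i_ref = i_ref, i_bg = i_bg, i_raw = i_raw,
                 i_readout = calibrate_readout(i_raw, i_ref, i_bg),
                 absorbance = absorb, time_s = t_now),
            class = "readout_result")
}

#' @export
print.readout_result <- function(x, ...) {
  cat(sprintf("<readout_result> I_ref = %.2f, I_bg = %.2f, I_raw = %.2f -> I_readout = %.2f (A = %.4f)\n",
              x$i_ref, x$i_bg, x$i_raw, x$i_readout, x$absorbance))
  invisible(x)
}
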