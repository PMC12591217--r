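#' Phenomenological parameters of the bead-based sandwich immunoassay
#'
#' The assay captures exosomes on antibody-coated magnetic beads via the
#' membrane tetraspanin CD63, labels membrane-bound amyloid-beta 42 with an
#' HRP-conjugated antibody, and develops a colorimetric TMB signal. The model
#' is deliberately simple: first-order Langmuir capture toward a
#' concentration-dependent equilibrium, saturating first-order labelling, and
#' linear enzyme kinetics for colour development. All rate constants are free
#' parameters; none are printed for the real assay.
#'
#' @param site_capacity_per_mg capture-site capacity per mg of bead cluster
#'   (amount units per mg).
#' @param k_cap_per_min first-order capture rate constant (1/min).
#' @param k_half_pg_ml half-saturation concentration of the capture
#'   equilibrium (pg/ml).
#' @param label_efficiency HRP labels bound per captured Abeta42-bearing
#'   exosome unit at saturation.
#' @param k_label_per_min first-order labelling rate constant (1/min).
#' @param gain absorbance developed per bound HRP unit per minute of reaction.
#' @param background baseline absorbance-equivalent signal of the optical
#'   path with no analyte.
#' @param noise_sd Gaussian noise s.d. on the developed signal (absorbance
#'   units).
#' @return An object of class `assay_params`.
#' @export
assay_params <- function(site_capacity_per_mg = 1,
                         k_cap_per_min = 0.1,
                         k_half_pg_ml = 100,
                         label_efficiency = 1,
                         k_label_per_min = 0.2,
                         gain = 0.025,
                         background = 0.05,
                         noise_sd = 0) {
  p <- list(site_capacity_per_mg = site_capacity_per_mg,
            k_cap_per_min = k_cap_per_min,
            k_half_pg_ml = k_half_pg_ml,
            label_efficiency = label_efficiency,
            k_label_per_min = k_label_per_min,
            gain = gain, background = background, noise_sd = noise_sd)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1 ||
                  !is.finite(v) || v < 0, logical(1))
  if (any(bad))
    stop("argument error: assay parameters must be finite and >= 0: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  if (p$k_half_pg_ml <= 0)
    stop("argument error: k_half_pg_ml must be > 0", call. = FALSE)
  structure(p, class = "assay_params")
}

# species on a bead surface; capture-competent species carry CD63
CAPTURABLE <- c("exo_ab42", "cd63_exo")

new_surface <- function(mass_mg, params) {
  c(sites = params$site_capacity_per_mg * mass_mg,
    cap_exo_ab42 = 0, cap_cd63_exo = 0, bound_hrp = 0)
}

#' CD63-mediated exosome capture onto the bead surface
#'
#' Capture follows first-order kinetics toward a Langmuir equilibrium:
#' `Q(t) = Q_eq * (1 - exp(-k_cap * t))` with
#' `Q_eq = capacity * C / (C + K)`, where `C` is the total concentration of
#' CD63-bearing species in the droplet (Abeta42-bearing exosomes and bare
#' exosomes compete for the same sites; free Abeta42 and BSA carry no CD63
#' and are never captured). The equilibrium is set by the total (free +
#' already captured) amount, so capture is memoryless: two sequential
#' `t`-steps equal one `2t`-step exactly. Captured amounts are moved from the
#' droplet composition to the surface, conserving each species.
#'
#' @param surface named numeric surface state (see [assay_params()]); fields
#'   `sites`, `cap_exo_ab42`, `cap_cd63_exo`, `bound_hrp`.
#' @param composition named numeric vector of droplet amounts (pg).
#' @param volume_ul droplet volume in microlitres.
#' @param duration_s contact (mixing) time in seconds.
#' @param params an [assay_params()].
#' @return list with updated `surface` and `composition`.
#' @export
capture_exosomes <- function(surface, composition, volume_ul, duration_s,
                             params = assay_params()) {
  stopifnot(inherits(params, "assay_params"))
  if (!is.finite(duration_s) || duration_s < 0)
    stop("argument error: duration_s must be >= 0", call. = FALSE)
  if (surface[["sites"]] <= 0) return(list(surface = surface,
                                           composition = composition))
  free <- vapply(CAPTURABLE, function(s) composition[s] %|na|% 0, numeric(1))
  names(free) <- CAPTURABLE
  cap_names <- paste0("cap_", CAPTURABLE)
  bound <- surface[cap_names]
  totals <- free + bound
  tot <- sum(totals)
  if (tot <= 0) return(list(surface = surface, composition = composition))
  conc <- 1000 * tot / volume_ul                  # pg/ml
  q_eq_tot <- surface[["sites"]] * conc / (conc + params$k_half_pg_ml)
  q_eq <- q_eq_tot * totals / tot                 # split by species abundance
  decay <- exp(-params$k_cap_per_min * duration_s / 60)
  new_bound <- q_eq + (bound - q_eq) * decay
  new_bound <- pmin(new_bound, totals)            # cannot exceed what exists
  names(new_bound) <- cap_names
  delta <- new_bound - as.numeric(bound)
  names(delta) <- cap_names
  surface[cap_names] <- as.numeric(new_bound)
  for (s in CAPTURABLE) {
    composition[s] <- (composition[s] %|na|% 0) - delta[[paste0("cap_", s)]]
    if (composition[s] < 0) composition[s] <- 0
  }
  list(surface = surface, composition = composition)
}

#' HRP labelling of captured membrane-bound Abeta42
#'
#' The enzyme-conjugated anti-Abeta42 antibody binds only to Abeta42 displayed
#' on *captured* exosomes — the dual-site requirement. Bare captured exosomes
#' and free Abeta42 in solution acquire no label, so single-marker species
#' produce no signal. Labelling saturates first-order toward
#' `label_efficiency * cap_exo_ab42`, linear in the captured amount.
#'
#' @inheritParams capture_exosomes
#' @return list with updated `surface` and `composition`.
#' @export
label_exosomes <- function(surface, composition, volume_ul, duration_s,
                           params = assay_params()) {
  stopifnot(inherits(params, "assay_params"))
  if (!is.finite(duration_s) || duration_s < 0)
    stop("argument error: duration_s must be >= 0", call. = FALSE)
  avail <- composition["hrp_ab"] %|na|% 0
  if (avail <= 0 || surface[["cap_exo_ab42"]] <= 0)
    return(list(surface = surface, composition = composition))
  h_eq <- params$label_efficiency * surface[["cap_exo_ab42"]]
  decay <- exp(-params$k_label_per_min * duration_s / 60)
  new_h <- h_eq + (surface[["bound_hrp"]] - h_eq) * decay
  delta <- min(new_h - surface[["bound_hrp"]], avail)
  surface[["bound_hrp"]] <- surface[["bound_hrp"]] + delta
  composition["hrp_ab"] <- avail - delta
  list(surface = surface, composition = composition)
}

#' Develop the colorimetric signal in the detection chamber
#'
#' Linear enzyme kinetics: over a reaction interval the absorbance-equivalent
#' signal grows by `gain * bound_hrp * t` (t in minutes), plus Gaussian noise
#' if `noise_sd > 0`. A stop event ([stop_reaction()]) freezes the signal;
#' developing a stopped droplet is a state error.
#'
#' @param droplet a droplet record (list with `signal` and `stopped` fields;
#'   see [chip_state()]).
#' @param hrp_bound bound HRP units present on beads in the chamber.
#' @param duration_s reaction time in seconds.
#' @param params an [assay_params()].
#' @return the droplet with accumulated `signal`.
#' @export
develop_signal <- function(droplet, hrp_bound, duration_s,
                           params = assay_params()) {
  stopifnot(inherits(params, "assay_params"))
  if (!is.finite(duration_s) || duration_s < 0)
    stop("argument error: duration_s must be >= 0", call. = FALSE)
  if (isTRUE(droplet$stopped))
    stop("state error: reaction already stopped; signal is frozen",
         call. = FALSE)
  inc <- params$gain * hrp_bound * duration_s / 60
  if (params$noise_sd > 0) inc <- inc + stats::rnorm(1, 0, params$noise_sd)
  droplet$signal <- (droplet$signal %||% 0) + inc
  droplet
}

#' Freeze signal development (acid stop buffer)
#' @param droplet a droplet record.
#' @return the droplet with `stopped = TRUE`.
#' @export
stop_reaction <- function(droplet) {
  droplet$stopped <- TRUE
  droplet
}

#' Total absorbance-equivalent assay signal of a droplet
#' @param droplet a droplet record.
#' @param params an [assay_params()] (supplies the optical background).
#' @return numeric signal (absorbance units): background + developed colour.
#' @export
assay_signal <- function(droplet, params = assay_params()) {
  params$background + (droplet$signal %||% 0)
}

#' Closed-form noiseless dose-response of the full assay chain
#'
#' Convenience wrapper running capture, labelling and development for a
#' free-analyte concentration without simulating chip motion: used for
#' calibration generation and cohort scoring. Monotone non-decreasing in
#' concentration.
#'
#' @param conc_pg_ml analyte (Abeta42-bearing exosome) concentration, pg/ml;
#'   vectorised.
#' @param params an [assay_params()].
#' @param bead_mass_mg bead cluster mass (mg).
#' @param sample_volume_ul sample droplet volume (ul).
#' @param t_capture_s,t_label_s,t_react_s incubation, labelling and reaction
#'   durations (s).
#' @return absorbance-equivalent signal including background (no noise).
#' @export
assay_response <- function(conc_pg_ml, params = assay_params(),
                           bead_mass_mg = 8, sample_volume_ul = 100,
                           t_capture_s = 1800, t_label_s = 1800,
                           t_react_s = 600) {
  stopifnot(inherits(params, "assay_params"))
  if (any(!is.finite(conc_pg_ml)) || any(conc_pg_ml < 0))
    stop("argument error: conc_pg_ml must be finite and >= 0", call. = FALSE)
  capacity <- params$site_capacity_per_mg * bead_mass_mg
  amount <- conc_pg_ml * sample_volume_ul / 1000   # pg in droplet
  q_eq <- pmin(capacity * conc_pg_ml / (conc_pg_ml + params$k_half_pg_ml),
               amount)
  q <- q_eq * (1 - exp(-params$k_cap_per_min * t_capture_s / 60))
  h <- params$label_efficiency * q *
    (1 - exp(-params$k_label_per_min * t_label_s / 60))
  params$background + params$gain * h * t_react_s / 60
}

#' Generate a synthetic calibration data set
#'
#' Runs the noiseless dose-response at each concentration and adds seeded
#' Gaussian signal noise per replicate, emulating an on-chip calibration
#' series (default: 0-50 pg/ml in triplicate).
#'
#' @param concentrations calibration levels in pg/ml (must include 0).
#' @param replicates replicates per level.
#' @param params an [assay_params()] (its `noise_sd` is applied here).
#' @param seed RNG seed.
#' @param ... passed to [assay_response()].
#' @return data frame with `concentration_pg_ml` and `signal`.
#' @export
simulate_calibration <- function(concentrations = c(0, 0.5, 1, 2, 5, 10, 20, 50),
                                 replicates = 3,
                                 params = assay_params(noise_sd = 0.01),
                                 seed = 1, ...) {
  set.seed(seed)
  conc <- rep(concentrations, each = replicates)
  mu <- assay_response(conc, params, ...)
  sig <- mu + stats::rnorm(length(mu), 0, params$noise_sd)
  data.frame(concentration_pg_ml = conc, signal = sig)
}

#' Fit a four-parameter logistic calibration curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x/c)^b)`: `a` is the
#' zero-dose asymptote, `d` the infinite-dose asymptote, `c` the inflection
#' concentration and `b` the slope. Initialisation is deterministic: `a` and
#' `d` from the signals at the extreme concentrations, `c` from the
#' concentration nearest the mid-signal, `b = 1`; optimisation by
#' Levenberg-Marquardt with `b, c` bounded positive.
#'
#' @param concentrations numeric vector (pg/ml); at least 5 distinct values
#'   including 0.
#' @param signals numeric vector of measured signals, same length.
#' @return An object of class `calib_curve`: list with `a`, `b`, `c`, `d`,
#'   `r_squared`, `n`, and `fitted` values.
#' @export
fit_4pl <- function(concentrations, signals) {
  x <- as.numeric(concentrations); y <- as.numeric(signals)
  if (length(x) != length(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("argument error: concentrations and signals must be finite and of equal length",
         call. = FALSE)
  ux <- sort(unique(x))
  if (length(ux) < 5 || min(ux) != 0)
    stop("argument error: need >= 5 distinct concentrations including 0",
         call. = FALSE)
  if (stats::sd(y) == 0 ||
      abs(mean(y[x == max(x)]) - mean(y[x == 0])) < 1e-12)
    stop("fit error: degenerate (flat) calibration data", call. = FALSE)
  a0 <- mean(y[x == 0])
  d0 <- mean(y[x == max(x)])
  mid <- (a0 + d0) / 2
  c0 <- x[x > 0][which.min(abs(y[x > 0] - mid))]
  if (length(c0) == 0 || c0 <= 0) c0 <- stats::median(ux[ux > 0])
  fit <- minpack.lm::nlsLM(
    y ~ d + (a - d) / (1 + (x / c)^b),
    start = list(a = a0, b = 1, c = c0, d = d0),
    lower = c(a = -Inf, b = 1e-6, c = 1e-12, d = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- stats::coef(fit)
  fitted <- predict_4pl_(cf, x)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]), d = unname(cf["d"]),
                 r_squared = 1 - ss_res / ss_tot,
                 n = length(x), fitted = fitted),
            class = "calib_curve")
}

predict_4pl_ <- function(cf, x) {
  cf[["d"]] + (cf[["a"]] - cf[["d"]]) / (1 + (x / cf[["c"]])^cf[["b"]])
}

#' Predict signal from a fitted 4PL curve
#' @param curve a `calib_curve`.
#' @param conc concentrations (pg/ml).
#' @return predicted signals.
#' @export
predict_4pl <- function(curve, conc) {
  stopifnot(inherits(curve, "calib_curve"))
  predict_4pl_(list(a = curve$a, b = curve$b, c = curve$c, d = curve$d), conc)
}

#' Invert a 4PL curve: signal to concentration
#' @param curve a `calib_curve`.
#' @param signal signal values strictly between the two asymptotes.
#' @return concentrations (pg/ml).
#' @export
invert_4pl <- function(curve, signal) {
  stopifnot(inherits(curve, "calib_curve"))
  lo <- min(curve$a, curve$d); hi <- max(curve$a, curve$d)
  eps <- 1e-9 * (hi - lo)   # numerical slack at the asymptotes
  if (any(signal < lo - eps) || any(signal > hi + eps))
    stop("out-of-range error: signal outside the calibration asymptotes",
         call. = FALSE)
  signal <- pmin(pmax(signal, lo), hi)
  ratio <- (curve$a - curve$d) / (signal - curve$d) - 1
  ratio[ratio < 0] <- 0   # numerical guard at the zero-dose asymptote
  curve$c * ratio^(1 / curve$b)
}

#' @export
print.calib_curve <- function(x, ...) {
  cat(sprintf("<calib_curve> 4PL: a = %.4g, b = %.4g, c = %.4g pg/ml, d = %.4g (R^2 = %.4f, n = %d)\n",
              x$a, x$b, x$c, x$d, x$r_squared, x$n))
  invisible(x)
}

#' Limit of detection from a calibration curve and blank replicates
#'
#' The blank + 3 SD convention: the LOD is the concentration whose predicted
#' signal equals `mean(blanks) + 3 * sd(blanks)` for a rising curve, or
#' `mean(blanks) - 3 * sd(blanks)` for a falling one, inverted through the
#' fitted 4PL.
#'
#' @param curve a `calib_curve` fitted by [fit_4pl()].
#' @param blanks numeric vector of blank (zero-dose) signal replicates,
#'   length >= 3.
#' @return LOD in pg/ml.
#' @export
lod <- function(curve, blanks) {
  stopifnot(inherits(curve, "calib_curve"))
  if (length(blanks) < 3 || any(!is.finite(blanks)))
    stop("argument error: need >= 3 finite blank replicates", call. = FALSE)
  rising <- curve$d > curve$a   # signal increases with concentration
  thr <- mean(blanks) + (if (rising) 3 else -3) * stats::sd(blanks)
  lo <- min(curve$a, curve$d); hi <- max(curve$a, curve$d)
  eps <- 1e-9 * (hi - lo)
  if (thr >= lo - eps && thr <= hi + eps) thr <- min(max(thr, lo), hi)
  if (thr < lo || thr > hi)
    stop("out-of-range error: blank + 3SD threshold (", signif(thr, 6),
         ") lies outside the calibration range", call. = FALSE)
  invert_4pl(curve, thr)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
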