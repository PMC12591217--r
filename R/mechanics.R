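#' Force-balance parameters for bead/droplet actuation
#'
#' Three lumped forces govern what the stepping magnet can move. The magnetic
#' force on the bead cluster grows linearly with the bead loading mass,
#' `F_mag = k_mag * m`. The restoring force from deformation of the droplet's
#' water-oil interface peaks at a value proportional to the cluster's
#' circumference, hence to the cube root of its mass,
#' `F_int_max = k_int * m^(1/3)`. Sliding friction on the droplet grows
#' linearly with transport speed, `F_fric = k_fric * v`. Units are fixed
#' internally to uN, mg and mm/s; the three coefficients are free parameters
#' with unit defaults.
#'
#' @param k_mag magnetic-force coefficient (uN per mg), > 0.
#' @param k_int interfacial coefficient (uN per mg^(1/3)), > 0.
#' @param k_fric friction coefficient (uN per mm/s), > 0.
#' @return An object of class `force_params`.
#' @examples
#' p <- force_params()
#' classify_zone(8, 5, p)  # "BEAD_OP"
#' @export
force_params <- function(k_mag = 1, k_int = 1, k_fric = 1) {
  for (nm in c("k_mag", "k_int", "k_fric")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("argument error: ", nm, " must be a finite positive scalar",
           call. = FALSE)
  }
  structure(list(k_mag = k_mag, k_int = k_int, k_fric = k_fric),
            class = "force_params")
}

#' @export
print.force_params <- function(x, ...) {
  cat(sprintf("<force_params> k_mag = %g uN/mg, k_int = %g uN/mg^(1/3), k_fric = %g uN/(mm/s)\n",
              x$k_mag, x$k_int, x$k_fric))
  invisible(x)
}

#' Lumped actuation forces at an operation point
#'
#' @param mass bead loading mass in mg (>= 0); vectorised.
#' @param speed programmed motor speed in mm/s (>= 0); vectorised.
#' @param params a [force_params()].
#' @return data frame with columns `F_mag`, `F_int_max`, `F_fric` (uN).
#' @export
forces <- function(mass, speed, params = force_params()) {
  stopifnot(inherits(params, "force_params"))
  if (any(!is.finite(mass)) || any(mass < 0))
    stop("argument error: mass must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(speed)) || any(speed < 0))
    stop("argument error: speed must be finite and >= 0", call. = FALSE)
  data.frame(F_mag     = params$k_mag * mass,
             F_int_max = params$k_int * mass^(1/3),
             F_fric    = params$k_fric * speed)
}

#' Classify an operation point into an actuation regime
#'
#' The (mass, speed) quadrant splits into three mutually exclusive zones:
#'
#' * `DROPLET_OP` — friction does not exceed either driving force
#'   (`F_fric <= min(F_mag, F_int_max)`): interface deformation transmits the
#'   pull and the whole droplet (beads inside) follows the motor steadily.
#' * `BEAD_OP` — friction pins the droplet (`F_fric > F_int_max`) while the
#'   magnetic force strictly exceeds the maximal interfacial restoring force
#'   (`F_mag > F_int_max`): the cluster is torn through the water-oil
#'   interface and extracted, the droplet stays behind.
#' * `NO_ENGAGEMENT` — otherwise: the field can move neither beads nor droplet.
#'
#' Ties resolve toward the less energetic regime: equality of friction with
#' the driving forces still transports the droplet, while bead extraction
#' demands strict excess over the interfacial maximum.
#'
#' @inheritParams forces
#' @return character vector of zone labels (`"NO_ENGAGEMENT"`, `"DROPLET_OP"`,
#'   `"BEAD_OP"`), one per input point.
#' @export
classify_zone <- function(mass, speed, params = force_params()) {
  f <- forces(mass, speed, params)
  droplet <- f$F_fric <= pmin(f$F_mag, f$F_int_max)
  bead <- !droplet & f$F_fric > f$F_int_max & f$F_mag > f$F_int_max
  ifelse(droplet, "DROPLET_OP", ifelse(bead, "BEAD_OP", "NO_ENGAGEMENT"))
}

#' Analytical zone boundaries
#'
#' The three zones meet at the critical mass `m* = (k_int/k_mag)^(3/2)`, where
#' the magnetic force equals the maximal interfacial force. Below `m*` the
#' droplet-transport region is bounded above by `v = (k_mag/k_fric) * m`
#' (droplet / no-engagement line); above `m*` it is bounded by
#' `v = (k_int/k_fric) * m^(1/3)` (droplet / bead curve). The two curves meet
#' at the triple point `(m*, k_mag * m* / k_fric)`.
#'
#' @param params a [force_params()].
#' @param mass_range length-2 numeric, positive mass interval (mg).
#' @param n number of evaluation points per curve.
#' @return An object of class `zone_boundaries`: list with `m_star`,
#'   `v_star`, vectorised boundary functions `v_ne(m)` (valid for `m <= m*`)
#'   and `v_db(m)` (valid for `m >= m*`), and a data frame `curves`
#'   (`mass`, `speed`, `boundary`).
#' @export
zone_boundaries <- function(params = force_params(),
                            mass_range = c(0.01, 10), n = 200) {
  stopifnot(inherits(params, "force_params"))
  if (length(mass_range) != 2 || any(!is.finite(mass_range)) ||
      any(mass_range <= 0) || diff(mass_range) <= 0)
    stop("argument error: mass_range must be a positive increasing interval",
         call. = FALSE)
  m_star <- (params$k_int / params$k_mag)^(3/2)
  v_ne <- function(m) params$k_mag * m / params$k_fric
  v_db <- function(m) params$k_int * m^(1/3) / params$k_fric
  v_star <- v_ne(m_star)
  grid_lo <- seq(mass_range[1], min(m_star, mass_range[2]), length.out = n)
  grid_hi <- seq(max(m_star, mass_range[1]), mass_range[2], length.out = n)
  curves <- rbind(
    data.frame(mass = grid_lo, speed = v_ne(grid_lo),
               boundary = "droplet/no-engagement"),
    data.frame(mass = grid_hi, speed = v_db(grid_hi),
               boundary = "droplet/bead"))
  structure(list(m_star = m_star, v_star = v_star,
                 v_ne = v_ne, v_db = v_db, curves = curves,
                 params = params),
            class = "zone_boundaries")
}

#' @export
print.zone_boundaries <- function(x, ...) {
  cat(sprintf("<zone_boundaries> m* = %g mg, triple point speed v* = %g mm/s\n",
              x$m_star, x$v_star))
  invisible(x)
}

#' Operation-zone phase diagram
#'
#' Classifies every point of a (mass, speed) grid and attaches the analytical
#' boundary curves, reproducing the three-zone operation diagram used to pick
#' actuation speeds.
#'
#' @param params a [force_params()].
#' @param mass_grid strictly increasing vector of bead masses (mg).
#' @param speed_grid strictly increasing vector of motor speeds (mm/s).
#' @return An object of class `zone_diagram`: list with `mass_grid`,
#'   `speed_grid`, `labels` (matrix, rows = mass, cols = speed), `table`
#'   (long data frame `mass`, `speed`, `zone`) and `boundaries`.
#' @export
phase_diagram <- function(params = force_params(),
                          mass_grid = seq(0.1, 10, length.out = 60),
                          speed_grid = seq(0.1, 10, length.out = 60)) {
  stopifnot(inherits(params, "force_params"))
  if (length(mass_grid) < 1 || is.unsorted(mass_grid, strictly = TRUE))
    stop("argument error: mass_grid must be strictly increasing", call. = FALSE)
  if (length(speed_grid) < 1 || is.unsorted(speed_grid, strictly = TRUE))
    stop("argument error: speed_grid must be strictly increasing", call. = FALSE)
  pts <- expand.grid(mass = mass_grid, speed = speed_grid,
                     KEEP.OUT.ATTRS = FALSE)
  pts$zone <- classify_zone(pts$mass, pts$speed, params)
  labels <- matrix(pts$zone, nrow = length(mass_grid),
                   dimnames = list(mass = signif(mass_grid, 6),
                                   speed = signif(speed_grid, 6)))
  mr <- range(pmax(mass_grid, 1e-9))
  if (diff(mr) <= 0) mr <- mr * c(0.5, 1.5)  # degenerate 1-point grid
  structure(list(mass_grid = mass_grid, speed_grid = speed_grid,
                 labels = labels, table = pts,
                 boundaries = zone_boundaries(params, mr),
                 params = params),
            class = "zone_diagram")
}

#' @export
print.zone_diagram <- function(x, ...) {
  tab <- table(x$table$zone)
  cat(sprintf("<zone_diagram> %d x %d points; zones: %s\n",
              length(x$mass_grid), length(x$speed_grid),
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.zone_diagram <- function(x, ...) x$table

#' Plot an operation-zone diagram
#'
#' Filled zone map with the analytical boundary curves overlaid.
#'
#' @param x a `zone_diagram`.
#' @param ... passed to [graphics::image()].
#' @export
plot.zone_diagram <- function(x, ...) {
  zone_levels <- c("NO_ENGAGEMENT", "DROPLET_OP", "BEAD_OP")
  z <- matrix(match(x$labels, zone_levels), nrow = length(x$mass_grid))
  graphics::image(x$mass_grid, x$speed_grid, z,
                  col = c("#f2d359", "#f4a6c0", "#8ecae6"), zlim = c(1, 3),
                  xlab = "bead loading mass (mg)",
                  ylab = "motor speed (mm/s)", ...)
  b <- x$boundaries
  lo <- b$curves[b$curves$boundary == "droplet/no-engagement", ]
  hi <- b$curves[b$curves$boundary == "droplet/bead", ]
  graphics::lines(lo$mass, lo$speed, lwd = 2)
  graphics::lines(hi$mass, hi$speed, lwd = 2, lty = 2)
  graphics::points(b$m_star, b$v_star, pch = 19)
  graphics::legend("topright", bty = "n",
                   fill = c("#f2d359", "#f4a6c0", "#8ecae6"),
                   legend = c("no engagement", "droplet operation",
                              "bead operation"))
  invisible(x)
}
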