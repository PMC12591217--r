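#' Electromagnetic coil-matrix navigation grid
#'
#' A `coil_grid` models the actuation layer of the platform: a planar matrix of
#' individually addressable four-turn coils, each 2 mm x 2 mm with a 0.1 mm gap
#' to its neighbours (pitch 2.1 mm centre to centre), driven at 0.4 A DC. The
#' default layout holds 165 active elements arranged 11 x 15. Energising a coil
#' creates a localised field that attracts a small permanent-magnet motor
#' sliding beneath the fluidic chip; sequential activation of adjacent coils
#' steps the motor across the lattice.
#'
#' Cells are 0-based `(row, col)` coordinates; coil ids are 0-based row-major
#' indices. Coil centres sit on the pitch lattice: `x = col * pitch`,
#' `y = row * pitch` (mm).
#'
#' @param rows,cols grid dimensions (positive integers).
#' @param pitch_mm centre-to-centre coil spacing in mm.
#' @param side_mm coil side length in mm; must not exceed the pitch.
#' @param current_a drive current per coil in ampere (>= 0).
#' @return An object of class `coil_grid` with fields `elements` (data frame:
#'   `id`, `row`, `col`, `x_mm`, `y_mm`), `rows`, `cols`, `pitch_mm`,
#'   `side_mm`, `current_a` and `active` (integer vector of energised ids).
#' @examples
#' g <- coil_grid(3, 3)
#' g <- activate(g, 4)
#' @export
coil_grid <- function(rows, cols, pitch_mm = 2.1, side_mm = 2.0,
                      current_a = 0.4) {
  stopifnot(length(rows) == 1, length(cols) == 1)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1 || cols < 1)
    stop("layout error: rows and cols must be positive integers", call. = FALSE)
  if (!is.finite(pitch_mm) || pitch_mm <= 0)
    stop("layout error: pitch_mm must be positive", call. = FALSE)
  if (!is.finite(side_mm) || side_mm <= 0 || side_mm > pitch_mm)
    stop("layout error: side_mm must lie in (0, pitch_mm] (coils must not overlap)",
         call. = FALSE)
  if (!is.finite(current_a) || current_a < 0)
    stop("layout error: current_a must be >= 0", call. = FALSE)
  idx <- seq_len(rows * cols) - 1L
  elements <- data.frame(
    id  = idx,
    row = idx %/% cols,
    col = idx %% cols
  )
  elements$x_mm <- elements$col * pitch_mm
  elements$y_mm <- elements$row * pitch_mm
  structure(
    list(elements = elements, rows = rows, cols = cols,
         pitch_mm = pitch_mm, side_mm = side_mm, current_a = current_a,
         active = integer(0)),
    class = "coil_grid")
}

#' Default 165-element coil layout
#'
#' The stock navigation matrix: 165 coils arranged 11 x 15 on a 2.1 mm pitch
#' (2 mm coil side + 0.1 mm gap), 0.4 A per element.
#'
#' @return A [coil_grid()].
#' @export
default_coil_grid <- function() coil_grid(11, 15)

#' @export
print.coil_grid <- function(x, ...) {
  cat(sprintf("<coil_grid> %d x %d = %d elements, pitch %.2f mm, %.2f A\n",
              x$rows, x$cols, nrow(x$elements), x$pitch_mm, x$current_a))
  cat(sprintf("  active coils: %s\n",
              if (length(x$active)) paste(x$active, collapse = ", ") else "none"))
  invisible(x)
}

#' Number of coil elements in a grid
#' @param grid a [coil_grid()].
#' @return integer count.
#' @export
n_coils <- function(grid) {
  stopifnot(inherits(grid, "coil_grid"))
  nrow(grid$elements)
}

cell_to_id <- function(grid, cell) {
  r <- cell[[1]]; c <- cell[[2]]
  if (r < 0 || r >= grid$rows || c < 0 || c >= grid$cols)
    stop("addressing error: cell (", r, ",", c, ") outside grid", call. = FALSE)
  as.integer(r * grid$cols + c)
}

id_to_cell <- function(grid, id) {
  if (length(id) != 1 || is.na(id) || id < 0 || id >= n_coils(grid))
    stop("addressing error: unknown coil id ", id, call. = FALSE)
  c(row = as.integer(id) %/% grid$cols, col = as.integer(id) %% grid$cols)
}

#' Energise a coil
#'
#' In the default single-active mode, energising a coil de-energises any other
#' active coil: the switch matrix routes the drive current to exactly one
#' element at a time. Multi-coil activation is available with
#' `exclusive = FALSE` but is unused by the stock protocol.
#'
#' @param grid a [coil_grid()].
#' @param coil_id coil id (0-based).
#' @param exclusive if `TRUE` (default), deactivate all other coils first.
#' @return the updated grid.
#' @export
activate <- function(grid, coil_id, exclusive = TRUE) {
  stopifnot(inherits(grid, "coil_grid"))
  coil_id <- as.integer(coil_id)
  if (length(coil_id) != 1 || is.na(coil_id) ||
      coil_id < 0 || coil_id >= n_coils(grid))
    stop("addressing error: unknown coil id ", coil_id, call. = FALSE)
  grid$active <- if (exclusive) coil_id else sort(unique(c(grid$active, coil_id)))
  grid
}

#' De-energise a coil (or all coils)
#' @param grid a [coil_grid()].
#' @param coil_id coil id, or `NULL` to switch everything off.
#' @return the updated grid.
#' @export
deactivate <- function(grid, coil_id = NULL) {
  stopifnot(inherits(grid, "coil_grid"))
  grid$active <- if (is.null(coil_id)) integer(0) else
    setdiff(grid$active, as.integer(coil_id))
  grid
}

#' Switch-IC address map
#'
#' Assigns every coil to one port of one programmable switch device, packing
#' ports densely so the device count is minimal: `ceiling(n_coils /
#' ports_per_device)`. The stock configuration (165 coils, 8 ports per device)
#' needs 21 devices.
#'
#' @param n_coils number of coils to address (>= 1).
#' @param ports_per_device output ports per switch device (>= 1, default 8).
#' @return An object of class `address_map`: data frame with columns
#'   `coil_id`, `device`, `port` (all 0-based) and attribute `n_devices`.
#' @examples
#' am <- address_map(165, 8)
#' attr(am, "n_devices")  # 21
#' @export
address_map <- function(n_coils, ports_per_device = 8) {
  n_coils <- as.integer(n_coils)
  ports_per_device <- as.integer(ports_per_device)
  if (is.na(n_coils) || n_coils < 1)
    stop("argument error: n_coils must be >= 1", call. = FALSE)
  if (is.na(ports_per_device) || ports_per_device < 1)
    stop("argument error: ports_per_device must be >= 1", call. = FALSE)
  idx <- seq_len(n_coils) - 1L
  map <- data.frame(
    coil_id = idx,
    device  = idx %/% ports_per_device,
    port    = idx %% ports_per_device
  )
  structure(map, class = c("address_map", "data.frame"),
            n_devices = as.integer(ceiling(n_coils / ports_per_device)),
            ports_per_device = ports_per_device)
}

#' Magnet-motor state
#'
#' Position of the permanent-magnet motor on the coil lattice. The continuous
#' position (mm) always coincides with a lattice cell centre because the motor
#' settles on the energised coil.
#'
#' @param grid a [coil_grid()].
#' @param cell starting cell `c(row, col)` (0-based).
#' @param time_s clock time in seconds.
#' @return An object of class `motor_state` with `position` (x, y in mm),
#'   `cell` and `time_s`.
#' @export
motor_state <- function(grid, cell = c(0, 0), time_s = 0) {
  stopifnot(inherits(grid, "coil_grid"))
  id <- cell_to_id(grid, cell)  # validates
  structure(
    list(position = c(x = cell[[2]] * grid$pitch_mm,
                      y = cell[[1]] * grid$pitch_mm),
         cell = c(row = as.integer(cell[[1]]), col = as.integer(cell[[2]])),
         time_s = time_s),
    class = "motor_state")
}

#' @export
print.motor_state <- function(x, ...) {
  cat(sprintf("<motor_state> cell (%d,%d), position (%.2f, %.2f) mm, t = %.3f s\n",
              x$cell[["row"]], x$cell[["col"]],
              x$position[["x"]], x$position[["y"]], x$time_s))
  invisible(x)
}

#' Step the motor toward the energised coil
#'
#' One actuation step: the motor relocates to the cell of the single energised
#' coil and dwells there for `dwell_s` seconds. The step-motion mechanism only
#' reaches the 4-neighbourhood (or the current cell); an energised coil further
#' away is an actuation fault — the motor cannot jump cells. With no coil
#' energised the motor stays put while time advances. An adjacent move at dwell
#' `tau` implies a commanded speed of `pitch / tau` mm/s.
#'
#' @param motor a [motor_state()].
#' @param grid a [coil_grid()] with at most one active coil.
#' @param dwell_s dwell time for this step in seconds (> 0).
#' @return the updated `motor_state`.
#' @export
step_motor <- function(motor, grid, dwell_s) {
  stopifnot(inherits(motor, "motor_state"), inherits(grid, "coil_grid"))
  if (!is.finite(dwell_s) || dwell_s <= 0)
    stop("argument error: dwell_s must be > 0", call. = FALSE)
  if (length(grid$active) == 0) {
    motor$time_s <- motor$time_s + dwell_s
    return(motor)
  }
  if (length(grid$active) > 1)
    stop("actuation fault: more than one coil energised during a motor step",
         call. = FALSE)
  target <- id_to_cell(grid, grid$active)
  dist <- abs(target[["row"]] - motor$cell[["row"]]) +
    abs(target[["col"]] - motor$cell[["col"]])
  if (dist > 1)
    stop("actuation fault: energised coil at (", target[["row"]], ",",
         target[["col"]], ") is not adjacent to motor cell (",
         motor$cell[["row"]], ",", motor$cell[["col"]],
         "); the motor cannot jump cells", call. = FALSE)
  motor$cell <- target
  motor$position <- c(x = target[["col"]] * grid$pitch_mm,
                      y = target[["row"]] * grid$pitch_mm)
  motor$time_s <- motor$time_s + dwell_s
  motor
}

#' Read a coil-layout configuration file
#'
#' Layout files are YAML with keys `rows`, `cols`, `pitch_mm`, `side_mm`,
#' `current_a`, and optionally an `elements` table (`id`, `row`, `col`) which,
#' when present, must agree with the row/col lattice — overlapping or
#' off-lattice elements are rejected.
#'
#' @param path file path.
#' @return a [coil_grid()].
#' @export
read_coil_layout <- function(path) {
  if (!file.exists(path))
    stop("config error: layout file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  req <- c("rows", "cols")
  if (!all(req %in% names(cfg)))
    stop("layout error: missing keys: ",
         paste(setdiff(req, names(cfg)), collapse = ", "), call. = FALSE)
  grid <- coil_grid(cfg$rows, cfg$cols,
                    pitch_mm = cfg$pitch_mm %||% 2.1,
                    side_mm = cfg$side_mm %||% 2.0,
                    current_a = cfg$current_a %||% 0.4)
  if (!is.null(cfg$elements)) {
    el <- do.call(rbind, lapply(cfg$elements, as.data.frame))
    if (anyDuplicated(el$id) || anyDuplicated(el[c("row", "col")]))
      stop("layout error: duplicate (overlapping) elements", call. = FALSE)
    if (nrow(el) != nrow(grid$elements))
      stop("layout error: element table size disagrees with rows x cols",
           call. = FALSE)
    expect_id <- el$row * grid$cols + el$col
    if (any(el$row < 0 | el$row >= grid$rows | el$col < 0 | el$col >= grid$cols))
      stop("layout error: element off the lattice", call. = FALSE)
    if (!all(el$id == expect_id))
      stop("layout error: element ids are not row-major lattice positions",
           call. = FALSE)
  }
  grid
}

#' Write a coil-layout configuration file
#' @param grid a [coil_grid()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_coil_layout <- function(grid, path) {
  stopifnot(inherits(grid, "coil_grid"))
  yaml::write_yaml(list(rows = grid$rows, cols = grid$cols,
                        pitch_mm = grid$pitch_mm, side_mm = grid$side_mm,
                        current_a = grid$current_a), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
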