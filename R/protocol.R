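#' Shortest-path routing on the coil lattice
#'
#' Breadth-first search with 4-connectivity and a deterministic row-major
#' neighbour order (up, left, right, down), the simplest complete algorithm
#' matching the microcontroller's embedded path-finder. On an obstacle-free
#' grid the path length equals the Manhattan distance.
#'
#' @param grid a [coil_grid()].
#' @param start_cell,goal_cell `c(row, col)` cells (0-based).
#' @param blocked list of blocked cells (each `c(row, col)`), e.g. cells
#'   occupied by other droplets.
#' @return matrix of cells (columns `row`, `col`), one row per visited cell
#'   including start and goal; a single row when `start == goal`.
#' @export
find_path <- function(grid, start_cell, goal_cell, blocked = list()) {
  stopifnot(inherits(grid, "coil_grid"))
  start <- cell_to_id(grid, start_cell)
  goal <- cell_to_id(grid, goal_cell)
  blocked_ids <- vapply(blocked, function(cl) cell_to_id(grid, cl), integer(1))
  if (goal %in% blocked_ids)
    stop("routing error: goal cell is blocked", call. = FALSE)
  n <- n_coils(grid)
  if (start == goal)
    return(matrix(id_to_cell(grid, start), nrow = 1,
                  dimnames = list(NULL, c("row", "col"))))
  parent <- rep(NA_integer_, n)
  visited <- logical(n)
  visited[blocked_ids + 1L] <- TRUE  # never enter blocked cells
  visited[start + 1L] <- TRUE
  queue <- start
  cols <- grid$cols; rows <- grid$rows
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    r <- cur %/% cols; c <- cur %% cols
    # row-major neighbour order: (r-1,c), (r,c-1), (r,c+1), (r+1,c)
    nbr <- integer(0)
    if (r > 0)        nbr <- c(nbr, cur - cols)
    if (c > 0)        nbr <- c(nbr, cur - 1L)
    if (c < cols - 1) nbr <- c(nbr, cur + 1L)
    if (r < rows - 1) nbr <- c(nbr, cur + cols)
    for (nb in nbr) {
      if (!visited[nb + 1L]) {
        visited[nb + 1L] <- TRUE
        parent[nb + 1L] <- cur
        if (nb == goal) {
          path <- nb
          while (!is.na(parent[path[1] + 1L]))
            path <- c(parent[path[1] + 1L], path)
          m <- cbind(row = path %/% cols, col = path %% cols)
          return(m)
        }
        queue <- c(queue, nb)
      }
    }
  }
  stop("routing error: no path from (", start_cell[[1]], ",", start_cell[[2]],
       ") to (", goal_cell[[1]], ",", goal_cell[[2]], ")", call. = FALSE)
}

PROTOCOL_VERBS <- c("MOVE_MOTOR", "MIX", "MOVE_DROPLET", "MOVE_BEADS",
                    "INSERT_BEADS", "MERGE", "INCUBATE", "READ")

#' Build a protocol command
#' @param verb one of `MOVE_MOTOR`, `MIX`, `MOVE_DROPLET`, `MOVE_BEADS`,
#'   `INSERT_BEADS`, `MERGE`, `INCUBATE`, `READ`.
#' @param ... named arguments for the verb (targets, destinations, durations).
#' @return a `protocol_command`.
#' @export
command <- function(verb, ...) {
  verb <- match.arg(verb, PROTOCOL_VERBS)
  args <- list(...)
  need <- switch(verb,
                 MIX = c("droplet", "duration"),
                 MOVE_DROPLET = c("droplet", "to"),
                 MOVE_BEADS = c("cluster", "from", "to"),
                 INSERT_BEADS = c("cluster", "into"),
                 MERGE = c("a", "b"),
                 INCUBATE = c("droplet", "duration"),
                 MOVE_MOTOR = "to",
                 READ = character(0))
  miss <- setdiff(need, names(args))
  if (length(miss))
    stop("argument error: ", verb, " requires ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(c(list(verb = verb), args), class = "protocol_command")
}

#' Assemble a protocol program
#' @param commands list of [command()]s.
#' @param name,version program metadata.
#' @return a `protocol_program`.
#' @export
program <- function(commands, name = "unnamed", version = "1") {
  stopifnot(all(vapply(commands, inherits, logical(1), "protocol_command")))
  structure(list(commands = commands, name = name, version = version),
            class = "protocol_program")
}

#' @export
print.protocol_program <- function(x, ...) {
  cat(sprintf("<protocol_program> '%s' v%s, %d commands\n",
              x$name, x$version, length(x$commands)))
  for (cmd in x$commands) cat(" ", format_command(cmd), "\n")
  invisible(x)
}

format_command <- function(cmd) {
  args <- cmd[setdiff(names(cmd), "verb")]
  paste(cmd$verb, paste(sprintf("%s=%s", names(args),
                                vapply(args, as.character, character(1))),
                        collapse = " "))
}

#' Parse a protocol script
#'
#' One command per line, `VERB key=value ...`; `#` starts a comment; blank
#' lines ignored. Numeric-looking values are converted to numbers.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param name,version program metadata.
#' @return a `protocol_program`.
#' @export
parse_program <- function(text, name = "parsed", version = "1") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cmds <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    verb <- tok[1]
    if (!(verb %in% PROTOCOL_VERBS))
      stop("parse error: unknown verb '", verb, "'", call. = FALSE)
    args <- list()
    for (kv in tok[-1]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2)
        stop("parse error: malformed argument '", kv, "'", call. = FALSE)
      val <- suppressWarnings(as.numeric(parts[2]))
      args[[parts[1]]] <- if (is.na(val)) parts[2] else val
    }
    do.call(command, c(list(verb = verb), args))
  })
  program(cmds, name = name, version = version)
}

#' Serialise a program to protocol-script text
#' @param prog a `protocol_program`.
#' @param path optional file; when given, the text is written there.
#' @return character vector of lines (invisibly if written to file).
#' @export
write_program <- function(prog, path = NULL) {
  stopifnot(inherits(prog, "protocol_program"))
  lines <- c(sprintf("# protocol: %s v%s", prog$name, prog$version),
             vapply(prog$commands, format_command, character(1)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' The stock six-step assay program
#'
#' Compiles the automated bead-based sandwich assay against a biochip layout:
#' (1) beads join the sample droplet and are mixed to capture exosomes;
#' (2) bead extraction across the water-oil interface into a wash droplet;
#' (3) transfer into the labelling droplet where the HRP-conjugated antibody
#' binds membrane-bound Abeta42; (4) exactly three wash transfers to strip
#' unbound label, then delivery into the detection chamber where the TMB
#' substrate reacts; (5) the stop-buffer droplet (carrying its own transport
#' beads) is driven to the chamber and merged to freeze and amplify the
#' colour; (6) all beads are parked outside the chamber and the optical
#' readout is taken.
#'
#' @param layout a [biochip_layout()]; must declare a sample reservoir, at
#'   least four wash reservoirs, labelling, detection-chamber and stop
#'   reservoirs.
#' @param t_capture_s,t_label_s,t_wash_s,t_react_s step durations (s).
#' @return a `protocol_program`.
#' @export
default_ime_program <- function(layout = default_biochip_layout(),
                                t_capture_s = 1800, t_label_s = 1800,
                                t_wash_s = 30, t_react_s = 600) {
  stopifnot(inherits(layout, "biochip_layout"))
  nm <- layout$reservoirs$name
  washes <- grep("^wash", nm, value = TRUE)
  if (length(washes) < 4)
    stop("compilation error: layout declares ", length(washes),
         " wash reservoirs; the stock program needs 4", call. = FALSE)
  for (need in c("sample", "bead_res", "label_res", "stop_res",
                 layout$detection_chamber))
    if (!(need %in% nm))
      stop("compilation error: layout missing reservoir '", need, "'",
           call. = FALSE)
  det <- layout$detection_chamber
  cl <- "bead_res_beads"
  cmds <- list(
    # step 1: capture
    command("MOVE_BEADS", cluster = cl, from = "bead_res", to = "sample"),
    command("MIX", droplet = "sample", duration = t_capture_s),
    # step 2: extraction + first wash
    command("MOVE_BEADS", cluster = cl, from = "sample", to = washes[1]),
    command("MIX", droplet = washes[1], duration = t_wash_s),
    # step 3: labelling
    command("MOVE_BEADS", cluster = cl, from = washes[1], to = "label_res"),
    command("MIX", droplet = "label_res", duration = t_label_s),
    # step 4: three washes, then delivery to the substrate chamber
    command("MOVE_BEADS", cluster = cl, from = "label_res", to = washes[2]),
    command("MIX", droplet = washes[2], duration = t_wash_s),
    command("MOVE_BEADS", cluster = cl, from = washes[2], to = washes[3]),
    command("MIX", droplet = washes[3], duration = t_wash_s),
    command("MOVE_BEADS", cluster = cl, from = washes[3], to = washes[4]),
    command("MIX", droplet = washes[4], duration = t_wash_s),
    command("MOVE_BEADS", cluster = cl, from = washes[4], to = det),
    command("INCUBATE", droplet = det, duration = t_react_s),
    # step 5: stop and amplify
    command("MOVE_DROPLET", droplet = "stop_res", to = det),
    command("MERGE", a = "stop_res", b = det),
    # step 6: clear beads, then read
    command("MOVE_BEADS", cluster = cl, from = det, to = "cell:9,1"),
    command("MOVE_BEADS", cluster = "stop_res_beads", from = det,
            to = "cell:9,3"),
    command("READ"))
  program(cmds, name = "ime_assay", version = "1")
}

#' Count wash transfers between labelling and chamber delivery
#' @param prog a `protocol_program`.
#' @return integer.
#' @export
count_post_label_washes <- function(prog) {
  stopifnot(inherits(prog, "protocol_program"))
  moves <- Filter(function(cmd) cmd$verb == "MOVE_BEADS", prog$commands)
  from <- vapply(moves, `[[`, character(1), "from")
  to <- vapply(moves, function(m) as.character(m$to), character(1))
  i_label <- which(from == "label_res")
  if (length(i_label) == 0) return(0L)
  # bead transfers into wash droplets after leaving the labelling droplet
  sum(grepl("^wash", to[seq_along(to) >= i_label[1]]))
}

parse_cell_ref <- function(x) {
  if (is.character(x) && grepl("^cell:", x)) {
    rc <- as.integer(strsplit(sub("^cell:", "", x), ",")[[1]])
    if (length(rc) != 2 || any(is.na(rc)))
      stop("parse error: malformed cell reference '", x, "'", call. = FALSE)
    return(rc)
  }
  NULL
}

# symbolic compile-time fluid state: where clusters and droplets sit
compile_state <- function(layout) {
  res <- layout$reservoirs
  droplets <- list()
  clusters <- list()
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    if (r$volume_ul > 0 || r$name == "sample")
      droplets[[r$name]] <- c(r$row, r$col)
    if (r$bead_mass_mg > 0)
      clusters[[paste0(r$name, "_beads")]] <-
        list(mass = r$bead_mass_mg,
             carrier = if (r$volume_ul > 0) r$name else "oil",
             cell = c(r$row, r$col))
  }
  list(droplets = droplets, clusters = clusters)
}

choose_speed <- function(verb, mass, fp, v_min, v_cap, step = NA) {
  at <- if (is.na(step)) "" else paste0(" (program step ", step, ")")
  if (verb == "MOVE_DROPLET") {
    if (mass <= 0)
      stop("compilation error", at, ": droplet has no embedded beads; no ",
           "magnetic handle for droplet transport", call. = FALSE)
    v_max <- min(fp$k_mag * mass, fp$k_int * mass^(1/3)) / fp$k_fric
    if (v_max <= v_min)
      stop("compilation error", at, ": no feasible droplet-transport speed ",
           "above the minimum practical speed ", v_min, " mm/s",
           call. = FALSE)
    return(sqrt(v_min * v_max))   # log-scale midpoint of (v_min, v_max)
  }
  # bead extraction: requires F_mag > F_int_max, i.e. mass > m*
  m_star <- (fp$k_int / fp$k_mag)^(3/2)
  if (mass <= m_star)
    stop("compilation error", at, ": bead mass ", mass, " mg does not exceed",
         " the critical mass m* = ", signif(m_star, 6),
         " mg; extraction is infeasible at any speed", call. = FALSE)
  v_lo <- fp$k_int * mass^(1/3) / fp$k_fric   # droplet/bead boundary
  if (v_cap <= v_lo)
    stop("compilation error", at, ": bead-extraction boundary speed ",
         signif(v_lo, 6), " mm/s exceeds the motor speed cap ", v_cap,
         " mm/s", call. = FALSE)
  sqrt(v_lo * v_cap)              # log-scale midpoint of (v_lo, v_cap)
}

free_neighbor <- function(grid, cell, occupied) {
  cand <- list(c(cell[1] - 1, cell[2]), c(cell[1], cell[2] - 1),
               c(cell[1], cell[2] + 1), c(cell[1] + 1, cell[2]))
  for (cc in cand) {
    if (cc[1] < 0 || cc[1] >= grid$rows || cc[2] < 0 || cc[2] >= grid$cols)
      next
    if (!any(vapply(occupied, function(o) all(o == cc), logical(1))))
      return(cc)
  }
  stop("routing error: no free cell adjacent to (", cell[1], ",", cell[2],
       ")", call. = FALSE)
}

#' Compile a program into a timed coil-activation schedule
#'
#' Routes every motion command with [find_path()] (other droplets are
#' obstacles), selects per-command speeds so the force-balance regime matches
#' the verb — droplet transport strictly inside the droplet-operation zone,
#' bead extraction strictly inside the bead-operation zone, each at the
#' geometric midpoint of its feasible speed interval on a log scale — and
#' emits timed on/off coil events with dwell `pitch / speed` per step.
#'
#' @param prog a `protocol_program`.
#' @param layout a [biochip_layout()].
#' @param grid a [coil_grid()].
#' @param fp a [force_params()].
#' @param v_min_mm_s minimum practical transport speed (mm/s).
#' @param v_cap_mm_s motor speed cap (mm/s).
#' @param travel_speed_mm_s speed for an unloaded motor repositioning.
#' @return An object of class `activation_schedule`: list with `events`
#'   (data frame `time_s`, `coil_id`, `action`), `segments` (one row per
#'   command: `step`, `verb`, `mass_mg`, `speed_mm_s`, `zone`, `n_steps`,
#'   `duration_s`) and `runtime_s`.
#' @export
compile_program <- function(prog, layout = default_biochip_layout(),
                            grid = default_coil_grid(),
                            fp = force_params(),
                            v_min_mm_s = 0.05, v_cap_mm_s = 50,
                            travel_speed_mm_s = 20) {
  stopifnot(inherits(prog, "protocol_program"),
            inherits(layout, "biochip_layout"),
            inherits(grid, "coil_grid"))
  st <- compile_state(layout)
  known <- c(names(st$droplets), names(st$clusters))
  motor <- c(0, 0)
  t <- 0
  events <- list(); segments <- list()
  emit_motion <- function(path, dwell, t0) {
    if (nrow(path) < 2) return(data.frame(time_s = numeric(0),
                                          coil_id = integer(0),
                                          action = character(0)))
    ids <- path[-1, 1] * grid$cols + path[-1, 2]
    on_t <- t0 + (seq_along(ids) - 1) * dwell
    data.frame(time_s = c(rbind(on_t, on_t + dwell)),
               coil_id = as.integer(rep(ids, each = 2)),
               action = rep(c("on", "off"), length(ids)))
  }
  blocked_for <- function(exclude) {
    occ <- st$droplets[setdiff(names(st$droplets), exclude)]
    unname(occ)
  }
  for (i in seq_along(prog$commands)) {
    cmd <- prog$commands[[i]]
    seg <- list(step = i, verb = cmd$verb, mass_mg = NA_real_,
                speed_mm_s = NA_real_, zone = NA_character_,
                n_steps = 0L, duration_s = 0)
    t0 <- t
    if (cmd$verb %in% c("MIX", "INCUBATE")) {
      d <- cmd$droplet
      if (!(d %in% names(st$droplets)))
        stop("compilation error (program step ", i, "): unknown droplet '",
             d, "'", call. = FALSE)
      t <- t + cmd$duration
    } else if (cmd$verb == "MOVE_MOTOR") {
      dest <- parse_cell_ref(cmd$to)
      path <- find_path(grid, motor, dest, blocked_for(character(0)))
      dwell <- grid$pitch_mm / travel_speed_mm_s
      events[[length(events) + 1L]] <- emit_motion(path, dwell, t)
      t <- t + (nrow(path) - 1) * dwell
      motor <- dest
      seg$n_steps <- nrow(path) - 1L
      seg$speed_mm_s <- travel_speed_mm_s
    } else if (cmd$verb == "MOVE_DROPLET") {
      d <- cmd$droplet
      if (!(d %in% names(st$droplets)))
        stop("compilation error (program step ", i, "): unknown droplet '",
             d, "'", call. = FALSE)
      mass <- sum(vapply(st$clusters, function(cl)
        if (identical(cl$carrier, d)) cl$mass else 0, numeric(1)))
      speed <- choose_speed("MOVE_DROPLET", mass, fp, v_min_mm_s,
                            v_cap_mm_s, i)
      from <- st$droplets[[d]]
      dest <- parse_cell_ref(cmd$to)
      if (is.null(dest)) {
        if (!(cmd$to %in% names(st$droplets)))
          stop("compilation error (program step ", i,
               "): unknown destination '", cmd$to, "'", call. = FALSE)
        dest <- free_neighbor(grid, st$droplets[[cmd$to]],
                              blocked_for(d))
      }
      # unloaded approach to the droplet, then loaded drag
      approach <- find_path(grid, motor, from, blocked_for(d))
      dwell_a <- grid$pitch_mm / travel_speed_mm_s
      events[[length(events) + 1L]] <- emit_motion(approach, dwell_a, t)
      t <- t + (nrow(approach) - 1) * dwell_a
      path <- find_path(grid, from, dest, blocked_for(d))
      dwell <- grid$pitch_mm / speed
      events[[length(events) + 1L]] <- emit_motion(path, dwell, t)
      t <- t + (nrow(path) - 1) * dwell
      motor <- dest
      st$droplets[[d]] <- dest
      for (cn in names(st$clusters))
        if (identical(st$clusters[[cn]]$carrier, d))
          st$clusters[[cn]]$cell <- dest
      seg$mass_mg <- mass; seg$speed_mm_s <- speed
      seg$zone <- classify_zone(mass, speed, fp)
      seg$n_steps <- nrow(path) - 1L
    } else if (cmd$verb == "MOVE_BEADS") {
      cn <- cmd$cluster
      if (!(cn %in% names(st$clusters)))
        stop("compilation error (program step ", i, "): unknown cluster '",
             cn, "'", call. = FALSE)
      if (!(cmd$from %in% names(st$droplets)))
        stop("compilation error (program step ", i, "): unknown droplet '",
             cmd$from, "'", call. = FALSE)
      mass <- st$clusters[[cn]]$mass
      speed <- choose_speed("MOVE_BEADS", mass, fp, v_min_mm_s, v_cap_mm_s, i)
      from <- st$droplets[[cmd$from]]
      dest <- parse_cell_ref(cmd$to)
      into <- NULL
      if (is.null(dest)) {
        if (!(cmd$to %in% names(st$droplets)))
          stop("compilation error (program step ", i,
               "): unknown destination '", cmd$to, "'", call. = FALSE)
        into <- cmd$to
        dest <- st$droplets[[into]]
      }
      approach <- find_path(grid, motor, from,
                            blocked_for(cmd$from))
      dwell_a <- grid$pitch_mm / travel_speed_mm_s
      events[[length(events) + 1L]] <- emit_motion(approach, dwell_a, t)
      t <- t + (nrow(approach) - 1) * dwell_a
      path <- find_path(grid, from, dest,
                        blocked_for(c(cmd$from, into)))
      dwell <- grid$pitch_mm / speed
      events[[length(events) + 1L]] <- emit_motion(path, dwell, t)
      t <- t + (nrow(path) - 1) * dwell
      motor <- dest
      st$clusters[[cn]]$carrier <- if (is.null(into)) "oil" else into
      st$clusters[[cn]]$cell <- dest
      seg$mass_mg <- mass; seg$speed_mm_s <- speed
      seg$zone <- classify_zone(mass, speed, fp)
      seg$n_steps <- nrow(path) - 1L
    } else if (cmd$verb == "INSERT_BEADS") {
      cn <- cmd$cluster
      if (!(cn %in% names(st$clusters)) ||
          !(cmd$into %in% names(st$droplets)))
        stop("compilation error (program step ", i,
             "): unknown cluster or droplet", call. = FALSE)
      st$clusters[[cn]]$carrier <- cmd$into
      st$clusters[[cn]]$cell <- st$droplets[[cmd$into]]
    } else if (cmd$verb == "MERGE") {
      if (!(cmd$a %in% names(st$droplets)) ||
          !(cmd$b %in% names(st$droplets)))
        stop("compilation error (program step ", i, "): unknown droplet in ",
             "MERGE", call. = FALSE)
      for (cn in names(st$clusters))
        if (identical(st$clusters[[cn]]$carrier, cmd$a))
          st$clusters[[cn]]$carrier <- cmd$b
      st$droplets[[cmd$a]] <- NULL
    } # READ: no schedule footprint
    seg$duration_s <- t - t0
    segments[[i]] <- as.data.frame(seg)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(0), coil_id = integer(0),
               action = character(0))
  structure(list(events = events, segments = do.call(rbind, segments),
                 runtime_s = t, program = prog),
            class = "activation_schedule")
}

#' @export
print.activation_schedule <- function(x, ...) {
  cat(sprintf("<activation_schedule> %d coil events, runtime %.1f s over %d commands\n",
              nrow(x$events), x$runtime_s, nrow(x$segments)))
  invisible(x)
}

#' Write an activation schedule as CSV
#' @param schedule an `activation_schedule`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "activation_schedule"))
  utils::write.csv(schedule$events, path, row.names = FALSE)
  invisible(path)
}

#' Execute a program against the simulated chip
#'
#' Compiles the program, then replays it on the fluidic state: motion
#' commands step the magnet motor coil by coil (via [step_motor()]) and apply
#' the corresponding fluidic events with runtime zone re-classification —
#' a regime that drifted from its compile-time assumption raises an actuation
#' fault naming the program step. `READ` triggers the full drift-compensated
#' optical measurement. Deterministic given `(program, layout, params,
#' seed)`.
#'
#' @param prog a `protocol_program`.
#' @param state a [chip_state()]; load the sample first ([load_sample()]).
#' @param grid a [coil_grid()].
#' @param sensor an [optical_sensor()] for `READ` commands.
#' @param seed integer seed for all stochastic elements.
#' @param ... passed to [compile_program()].
#' @return An object of class `run_record`: list with `state` (final),
#'   `schedule`, `readout` (a `readout_result` or `NULL`), `log` (the chip
#'   event log), `runtime_s`, `seed`.
#' @export
execute_program <- function(prog, state = NULL, grid = default_coil_grid(),
                            sensor = optical_sensor(), seed = 1, ...) {
  stopifnot(inherits(prog, "protocol_program"))
  if (is.null(state)) state <- chip_state()
  stopifnot(inherits(state, "chip_state"))
  set.seed(seed)
  sched <- compile_program(prog, state$layout, grid, state$force_params, ...)
  motor <- motor_state(grid, c(0, 0))
  readout <- NULL
  run_motion <- function(path, speed) {
    dwell <- grid$pitch_mm / speed
    for (k in seq_len(nrow(path))[-1]) {
      grid <<- activate(grid, path[k, "row"] * grid$cols + path[k, "col"])
      motor <<- step_motor(motor, grid, dwell)
    }
  }
  for (i in seq_along(prog$commands)) {
    cmd <- prog$commands[[i]]
    seg <- sched$segments[i, ]
    step_fail <- function(e)
      stop("actuation fault at program step ", i, " (", cmd$verb, "): ",
           conditionMessage(e), call. = FALSE)
    tryCatch({
      if (cmd$verb == "MIX") {
        state <- mix_droplet(state, cmd$droplet, cmd$duration)
      } else if (cmd$verb == "INCUBATE") {
        state <- incubate_droplet(state, cmd$droplet, cmd$duration)
      } else if (cmd$verb == "MOVE_DROPLET") {
        d <- get_droplet(state, cmd$droplet)
        dest <- parse_cell_ref(cmd$to)
        if (is.null(dest))
          dest <- free_neighbor(grid, get_droplet(state, cmd$to)$cell,
                                lapply(state$droplets, `[[`, "cell"))
        occ <- lapply(state$droplets[setdiff(names(state$droplets),
                                             cmd$droplet)], `[[`, "cell")
        appr <- find_path(grid, motor$cell, d$cell, unname(occ))
        run_motion(appr, 20)
        path <- find_path(grid, d$cell, dest, unname(occ))
        state <- move_droplet(state, cmd$droplet, dest, seg$speed_mm_s)
        run_motion(path, seg$speed_mm_s)
        state$time_s <- state$time_s + (nrow(appr) - 1) * grid$pitch_mm / 20 +
          (nrow(path) - 1) * grid$pitch_mm / seg$speed_mm_s
      } else if (cmd$verb == "MOVE_BEADS") {
        cl <- get_cluster(state, cmd$cluster)
        from_cell <- cl$cell
        dest <- parse_cell_ref(cmd$to)
        into <- NULL
        if (is.null(dest)) {
          into <- cmd$to
          dest <- get_droplet(state, into)$cell
        }
        occ_appr <- lapply(state$droplets[setdiff(names(state$droplets),
                                                  cmd$from)], `[[`, "cell")
        appr <- find_path(grid, motor$cell, from_cell, unname(occ_appr))
        run_motion(appr, 20)
        state <- extract_beads(state, cmd$cluster, seg$speed_mm_s)
        occ <- lapply(state$droplets[setdiff(names(state$droplets), into)],
                      `[[`, "cell")
        path <- find_path(grid, from_cell, dest, unname(occ))
        state <- move_cluster(state, cmd$cluster, dest)
        if (!is.null(into)) state <- insert_beads(state, cmd$cluster, into)
        run_motion(path, seg$speed_mm_s)
        state$time_s <- state$time_s + (nrow(appr) - 1) * grid$pitch_mm / 20 +
          (nrow(path) - 1) * grid$pitch_mm / seg$speed_mm_s
      } else if (cmd$verb == "INSERT_BEADS") {
        state <- insert_beads(state, cmd$cluster, cmd$into)
      } else if (cmd$verb == "MERGE") {
        state <- merge_droplets(state, cmd$a, cmd$b)
      } else if (cmd$verb == "MOVE_MOTOR") {
        dest <- parse_cell_ref(cmd$to)
        occ <- lapply(state$droplets, `[[`, "cell")
        path <- find_path(grid, motor$cell, dest, unname(occ))
        run_motion(path, 20)
      } else if (cmd$verb == "READ") {
        readout <- measure_chamber(state, sensor)
        state <- log_event(state, "read",
                           i_readout = readout$i_readout,
                           absorbance = readout$absorbance)
      }
    }, error = step_fail)
  }
  structure(list(state = state, schedule = sched, readout = readout,
                 log = state$log, runtime_s = sched$runtime_s, seed = seed),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> seed %d, runtime %.1f s, %d events%s\n",
              x$seed, x$runtime_s, length(x$log),
              if (!is.null(x$readout))
                sprintf(", I_readout = %.2f", x$readout$i_readout) else ""))
  invisible(x)
}
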