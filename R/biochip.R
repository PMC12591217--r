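#' Reagent layout of the exosome-detection biochip
#'
#' The sealed fluidic chip holds reagent droplets in an oil-filled cavity on
#' top of the coil matrix. The stock layout carries one 8 ul bead droplet,
#' four 50 ul wash droplets, one 50 ul HRP-conjugated antibody (labelling)
#' droplet, one 50 ul TMB substrate droplet sitting in the detection chamber,
#' and one 50 ul stop-buffer droplet with its own transport beads — 358 ul of
#' reagents in total — plus a sample position where the user loads up to
#' ~100 ul of plasma. Chamber height is about 3 mm.
#'
#' @param reservoirs data frame with columns `name`, `row`, `col`,
#'   `volume_ul`, `species` (character, `""` for buffer), `amount_pg`
#'   (initial amount of that species), `bead_mass_mg` (0 for none).
#' @param detection_chamber name of the reservoir in the detection chamber.
#' @param chamber_height_mm cavity height (mm), the optical path length.
#' @return An object of class `biochip_layout`.
#' @export
biochip_layout <- function(reservoirs, detection_chamber = "detect",
                           chamber_height_mm = 3) {
  req <- c("name", "row", "col", "volume_ul", "species", "amount_pg",
           "bead_mass_mg")
  if (!all(req %in% names(reservoirs)))
    stop("layout error: reservoir table missing columns: ",
         paste(setdiff(req, names(reservoirs)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(reservoirs$name))
    stop("layout error: duplicate reservoir names", call. = FALSE)
  if (anyDuplicated(reservoirs[c("row", "col")]))
    stop("layout error: overlapping reservoirs", call. = FALSE)
  if (!(detection_chamber %in% reservoirs$name))
    stop("layout error: detection chamber reservoir '", detection_chamber,
         "' not declared", call. = FALSE)
  if (any(reservoirs$volume_ul < 0))
    stop("layout error: negative reservoir volume", call. = FALSE)
  structure(list(reservoirs = reservoirs,
                 detection_chamber = detection_chamber,
                 chamber_height_mm = chamber_height_mm),
            class = "biochip_layout")
}

#' Stock biochip layout on the default coil grid
#'
#' @param hrp_amount_pg,tmb_amount_pg,stop_amount_pg initial reagent amounts
#'   (arbitrary excess).
#' @param bead_mass_mg assay bead-cluster mass (mg), ballasted for extraction.
#' @param stop_bead_mass_mg mass of the inert transport beads in the
#'   stop-buffer droplet.
#' @return a [biochip_layout()].
#' @export
default_biochip_layout <- function(hrp_amount_pg = 1e6, tmb_amount_pg = 1e6,
                                   stop_amount_pg = 1e6, bead_mass_mg = 8,
                                   stop_bead_mass_mg = 8) {
  res <- data.frame(
    name = c("sample", "bead_res", "wash1", "wash2", "wash3", "wash4",
             "label_res", "detect", "stop_res"),
    row  = c(1, 1, 3, 3, 3, 3, 5, 5, 7),
    col  = c(4, 1, 1, 4, 7, 10, 1, 13, 10),
    volume_ul = c(0, 8, 50, 50, 50, 50, 50, 50, 50),
    species = c("", "", "", "", "", "", "hrp_ab", "tmb", "stop"),
    amount_pg = c(0, 0, 0, 0, 0, 0, hrp_amount_pg, tmb_amount_pg,
                  stop_amount_pg),
    bead_mass_mg = c(0, bead_mass_mg, 0, 0, 0, 0, 0, 0, stop_bead_mass_mg))
  biochip_layout(res)
}

#' @export
print.biochip_layout <- function(x, ...) {
  cat(sprintf("<biochip_layout> %d reservoirs, %g ul reagents, detection chamber '%s' (height %g mm)\n",
              nrow(x$reservoirs), sum(x$reservoirs$volume_ul),
              x$detection_chamber, x$chamber_height_mm))
  invisible(x)
}

#' Fluidic state of the chip
#'
#' Builds the runtime state from a layout: one droplet per non-empty
#' reservoir and one bead cluster per reservoir that declares beads. Droplets
#' are point objects on the coil lattice carrying a volume and a composition
#' map (species -> amount in pg); bead clusters carry a mass and a surface
#' state, and are either embedded in a droplet or travelling through oil.
#'
#' @param layout a [biochip_layout()].
#' @param force_params a [force_params()] used for zone checks.
#' @param assay_params an [assay_params()] governing binding chemistry.
#' @param carryover fraction of a droplet's free species dragged along per
#'   bead extraction (default 0.01).
#' @return An object of class `chip_state`.
#' @export
chip_state <- function(layout = default_biochip_layout(),
                       force_params = magdrop::force_params(),
                       assay_params = magdrop::assay_params(),
                       carryover = 0.01) {
  stopifnot(inherits(layout, "biochip_layout"))
  if (!is.finite(carryover) || carryover < 0 || carryover >= 1)
    stop("argument error: carryover must be in [0, 1)", call. = FALSE)
  droplets <- list(); clusters <- list()
  for (i in seq_len(nrow(layout$reservoirs))) {
    r <- layout$reservoirs[i, ]
    if (r$volume_ul > 0) {
      comp <- numeric(0)
      if (nzchar(r$species) && r$amount_pg > 0) {
        comp <- stats::setNames(r$amount_pg, r$species)
      }
      droplets[[r$name]] <- list(id = r$name,
                                 cell = c(row = r$row, col = r$col),
                                 volume_ul = r$volume_ul,
                                 composition = comp,
                                 signal = 0, stopped = FALSE)
    }
    if (r$bead_mass_mg > 0) {
      cl_id <- paste0(r$name, "_beads")
      clusters[[cl_id]] <- list(
        id = cl_id, mass_mg = r$bead_mass_mg,
        surface = if (r$name == "bead_res")
          new_surface(r$bead_mass_mg, assay_params)
        else  # inert ballast beads: no capture sites
          c(sites = 0, cap_exo_ab42 = 0, cap_cd63_exo = 0, bound_hrp = 0),
        carried = numeric(0),
        carrier = if (r$volume_ul > 0) r$name else "oil",
        cell = c(row = r$row, col = r$col))
    }
  }
  structure(list(layout = layout, droplets = droplets, clusters = clusters,
                 force_params = force_params, assay_params = assay_params,
                 carryover = carryover, time_s = 0, log = list()),
            class = "chip_state")
}

#' @export
print.chip_state <- function(x, ...) {
  cat(sprintf("<chip_state> %d droplets (%g ul), %d bead clusters, t = %.1f s, %d events\n",
              length(x$droplets),
              sum(vapply(x$droplets, `[[`, numeric(1), "volume_ul")),
              length(x$clusters), x$time_s, length(x$log)))
  invisible(x)
}

log_event <- function(state, event, ...) {
  state$log[[length(state$log) + 1L]] <-
    c(list(time_s = state$time_s, event = event), list(...))
  state
}

get_droplet <- function(state, id) {
  d <- state$droplets[[id]]
  if (is.null(d)) stop("state error: no droplet '", id, "'", call. = FALSE)
  d
}

get_cluster <- function(state, id) {
  cl <- state$clusters[[id]]
  if (is.null(cl)) stop("state error: no bead cluster '", id, "'",
                        call. = FALSE)
  cl
}

clusters_in_droplet <- function(state, droplet_id) {
  keep <- vapply(state$clusters, function(cl) identical(cl$carrier, droplet_id),
                 logical(1))
  names(state$clusters)[keep]
}

droplet_bead_mass <- function(state, droplet_id) {
  ids <- clusters_in_droplet(state, droplet_id)
  sum(vapply(state$clusters[ids], `[[`, numeric(1), "mass_mg"))
}

#' Load a plasma sample onto the chip
#'
#' Fills the sample reservoir with a droplet containing the analyte
#' (Abeta42-bearing exosomes) and optionally interfering species.
#'
#' @param state a [chip_state()].
#' @param conc_pg_ml analyte concentration (pg/ml).
#' @param volume_ul sample volume (default 100 ul).
#' @param extra_species named numeric vector of additional amounts (pg), e.g.
#'   `c(free_ab42 = 500, bsa = 1e4)`.
#' @return the updated state.
#' @export
load_sample <- function(state, conc_pg_ml, volume_ul = 100,
                        extra_species = NULL) {
  stopifnot(inherits(state, "chip_state"))
  if (!is.finite(conc_pg_ml) || conc_pg_ml < 0)
    stop("argument error: conc_pg_ml must be >= 0", call. = FALSE)
  r <- state$layout$reservoirs
  r <- r[r$name == "sample", ]
  if (nrow(r) == 0)
    stop("layout error: layout declares no sample reservoir", call. = FALSE)
  comp <- c(exo_ab42 = conc_pg_ml * volume_ul / 1000)
  if (!is.null(extra_species)) comp <- c(comp, extra_species)
  comp <- comp[comp > 0]
  state$droplets[["sample"]] <- list(
    id = "sample", cell = c(row = r$row, col = r$col),
    volume_ul = volume_ul, composition = comp, signal = 0, stopped = FALSE)
  log_event(state, "load_sample", conc_pg_ml = conc_pg_ml,
            volume_ul = volume_ul)
}

#' Transport a droplet (beads inside) across the chip
#'
#' Valid only in the droplet-operation regime for the droplet's embedded bead
#' mass at the commanded speed; the whole droplet follows the motor. A
#' droplet with no embedded beads offers no magnetic handle and cannot move.
#'
#' @param state a [chip_state()].
#' @param droplet_id droplet to move.
#' @param dest_cell destination `c(row, col)`.
#' @param speed_mm_s commanded motor speed (mm/s).
#' @return the updated state.
#' @export
move_droplet <- function(state, droplet_id, dest_cell, speed_mm_s) {
  stopifnot(inherits(state, "chip_state"))
  d <- get_droplet(state, droplet_id)
  mass <- droplet_bead_mass(state, droplet_id)
  zone <- classify_zone(mass, speed_mm_s, state$force_params)
  if (zone != "DROPLET_OP")
    stop("actuation error: droplet transport of '", droplet_id,
         "' at mass ", mass, " mg, speed ", speed_mm_s,
         " mm/s falls in zone ", zone, ", not DROPLET_OP", call. = FALSE)
  dest <- c(row = as.integer(dest_cell[[1]]), col = as.integer(dest_cell[[2]]))
  state$droplets[[droplet_id]]$cell <- dest
  for (cl in clusters_in_droplet(state, droplet_id))
    state$clusters[[cl]]$cell <- dest
  log_event(state, "move_droplet", droplet = droplet_id,
            dest = unname(dest), speed_mm_s = speed_mm_s)
}

#' Extract a bead cluster across the water-oil interface
#'
#' Valid only in the bead-operation regime for the cluster mass at the
#' commanded speed: the magnet tears the cluster through the interface into
#' the oil while the droplet stays behind with its volume unchanged. A
#' configurable carryover fraction of every free (unbound) species in the
#' droplet travels with the wet cluster.
#'
#' @param state a [chip_state()].
#' @param cluster_id bead cluster to extract.
#' @param speed_mm_s commanded motor speed (mm/s).
#' @param carryover overrides the state's carryover fraction if not `NULL`.
#' @return the updated state.
#' @export
extract_beads <- function(state, cluster_id, speed_mm_s, carryover = NULL) {
  stopifnot(inherits(state, "chip_state"))
  cl <- get_cluster(state, cluster_id)
  if (identical(cl$carrier, "oil"))
    stop("state error: cluster '", cluster_id, "' is already in oil",
         call. = FALSE)
  zone <- classify_zone(cl$mass_mg, speed_mm_s, state$force_params)
  if (zone != "BEAD_OP")
    stop("actuation error: bead extraction of '", cluster_id,
         "' at mass ", cl$mass_mg, " mg, speed ", speed_mm_s,
         " mm/s falls in zone ", zone, ", not BEAD_OP", call. = FALSE)
  f <- if (is.null(carryover)) state$carryover else carryover
  d_id <- cl$carrier
  comp <- state$droplets[[d_id]]$composition
  carried <- comp * f
  state$droplets[[d_id]]$composition <- comp - carried
  state$clusters[[cluster_id]]$carried <- carried[carried > 0]
  state$clusters[[cluster_id]]$carrier <- "oil"
  log_event(state, "extract_beads", cluster = cluster_id, from = d_id,
            speed_mm_s = speed_mm_s, carryover = f)
}

#' Insert a bead cluster from oil into a droplet
#'
#' The cluster's carried free species dissolve into the target droplet.
#'
#' @param state a [chip_state()].
#' @param cluster_id cluster currently in oil.
#' @param droplet_id target droplet.
#' @return the updated state.
#' @export
insert_beads <- function(state, cluster_id, droplet_id) {
  stopifnot(inherits(state, "chip_state"))
  cl <- get_cluster(state, cluster_id)
  d <- get_droplet(state, droplet_id)
  if (!identical(cl$carrier, "oil"))
    stop("state error: cluster '", cluster_id,
         "' is already inside droplet '", cl$carrier, "'", call. = FALSE)
  comp <- d$composition
  for (s in names(cl$carried))
    comp[s] <- (comp[s] %|na|% 0) + cl$carried[[s]]
  state$droplets[[droplet_id]]$composition <- comp
  state$clusters[[cluster_id]]$carried <- numeric(0)
  state$clusters[[cluster_id]]$carrier <- droplet_id
  state$clusters[[cluster_id]]$cell <- d$cell
  log_event(state, "insert_beads", cluster = cluster_id, into = droplet_id)
}

#' Relocate a bead cluster travelling through oil
#'
#' Motion through the oil phase carries no droplet and no zone constraint;
#' the extraction step is where the regime check lives.
#'
#' @param state a [chip_state()].
#' @param cluster_id cluster in oil.
#' @param dest_cell destination `c(row, col)`.
#' @return the updated state.
#' @export
move_cluster <- function(state, cluster_id, dest_cell) {
  stopifnot(inherits(state, "chip_state"))
  cl <- get_cluster(state, cluster_id)
  if (!identical(cl$carrier, "oil"))
    stop("state error: cluster '", cluster_id,
         "' is embedded in droplet '", cl$carrier,
         "'; extract it before moving through oil", call. = FALSE)
  state$clusters[[cluster_id]]$cell <-
    c(row = as.integer(dest_cell[[1]]), col = as.integer(dest_cell[[2]]))
  log_event(state, "move_cluster", cluster = cluster_id,
            dest = c(dest_cell[[1]], dest_cell[[2]]))
}

#' Merge two droplets
#'
#' Volumes and species amounts add; mixing is instantaneous and perfect, so
#' concentrations follow from amount / volume. Clusters embedded in the
#' absorbed droplet transfer to the merged one. If the merged composition
#' contains stop buffer, signal development is frozen.
#'
#' @param state a [chip_state()].
#' @param droplet_a droplet absorbed into `droplet_b` (removed).
#' @param droplet_b surviving droplet.
#' @return the updated state.
#' @export
merge_droplets <- function(state, droplet_a, droplet_b) {
  stopifnot(inherits(state, "chip_state"))
  if (identical(droplet_a, droplet_b))
    stop("argument error: cannot merge a droplet with itself", call. = FALSE)
  a <- get_droplet(state, droplet_a)
  b <- get_droplet(state, droplet_b)
  if (sum(abs(a$cell - b$cell)) > 1)
    stop("state error: droplets '", droplet_a, "' and '", droplet_b,
         "' are not adjacent or co-located", call. = FALSE)
  comp <- b$composition
  for (s in names(a$composition))
    comp[s] <- (comp[s] %|na|% 0) + a$composition[[s]]
  b$composition <- comp
  b$volume_ul <- a$volume_ul + b$volume_ul
  b$signal <- (a$signal %||% 0) + (b$signal %||% 0)
  if ((comp["stop"] %|na|% 0) > 0) b$stopped <- TRUE
  state$droplets[[droplet_b]] <- b
  for (cl in clusters_in_droplet(state, droplet_a)) {
    state$clusters[[cl]]$carrier <- droplet_b
    state$clusters[[cl]]$cell <- b$cell
  }
  state$droplets[[droplet_a]] <- NULL
  log_event(state, "merge", absorbed = droplet_a, into = droplet_b,
            volume_ul = b$volume_ul)
}

#' Magnetically mix beads within their droplet
#'
#' Mixing advances the binding clock: every embedded cluster undergoes CD63
#' capture and (if labelling antibody is present) HRP labelling for the given
#' duration. A droplet without beads cannot be mixed.
#'
#' @param state a [chip_state()].
#' @param droplet_id droplet containing beads.
#' @param duration_s mixing time (s).
#' @return the updated state.
#' @export
mix_droplet <- function(state, droplet_id, duration_s) {
  stopifnot(inherits(state, "chip_state"))
  d <- get_droplet(state, droplet_id)
  cl_ids <- clusters_in_droplet(state, droplet_id)
  if (length(cl_ids) == 0)
    stop("state error: no beads present in droplet '", droplet_id,
         "'; nothing to mix", call. = FALSE)
  if (!is.finite(duration_s) || duration_s < 0)
    stop("argument error: duration_s must be >= 0", call. = FALSE)
  for (cl in cl_ids) {
    surf <- state$clusters[[cl]]$surface
    res <- capture_exosomes(surf, state$droplets[[droplet_id]]$composition,
                            state$droplets[[droplet_id]]$volume_ul,
                            duration_s, state$assay_params)
    res <- c(label_exosomes(res$surface, res$composition,
                            state$droplets[[droplet_id]]$volume_ul,
                            duration_s, state$assay_params))
    state$clusters[[cl]]$surface <- res$surface
    state$droplets[[droplet_id]]$composition <- res$composition
  }
  state$time_s <- state$time_s + duration_s
  log_event(state, "mix", droplet = droplet_id, duration_s = duration_s)
}

#' Let the chamber reaction run for a time interval
#'
#' If the droplet holds TMB substrate and HRP-labelled beads and has not been
#' stopped, colour develops linearly in bound HRP and time; otherwise time
#' simply advances.
#'
#' @param state a [chip_state()].
#' @param droplet_id droplet to incubate.
#' @param duration_s interval (s).
#' @return the updated state.
#' @export
incubate_droplet <- function(state, droplet_id, duration_s) {
  stopifnot(inherits(state, "chip_state"))
  d <- get_droplet(state, droplet_id)
  if (!is.finite(duration_s) || duration_s < 0)
    stop("argument error: duration_s must be >= 0", call. = FALSE)
  hrp <- sum(vapply(state$clusters[clusters_in_droplet(state, droplet_id)],
                    function(cl) cl$surface[["bound_hrp"]], numeric(1)))
  if ((d$composition["tmb"] %|na|% 0) > 0 && hrp > 0 && !isTRUE(d$stopped)) {
    state$droplets[[droplet_id]] <-
      develop_signal(d, hrp, duration_s, state$assay_params)
  }
  state$time_s <- state$time_s + duration_s
  log_event(state, "incubate", droplet = droplet_id, duration_s = duration_s)
}

#' Per-species totals across the whole chip
#'
#' Sums droplet compositions, cluster-carried free amounts, and
#' surface-bound amounts mapped back to their solution species
#' (`cap_exo_ab42` to `exo_ab42`, `cap_cd63_exo` to `cd63_exo`,
#' `bound_hrp` to `hrp_ab`), so totals are conserved by every fluidic event
#' and by the binding reactions, which only relocate material.
#'
#' @param state a [chip_state()].
#' @return named numeric vector of total amounts (pg).
#' @export
species_totals <- function(state) {
  stopifnot(inherits(state, "chip_state"))
  tot <- numeric(0)
  add <- function(tot, v) {
    for (s in names(v)) tot[s] <- (tot[s] %|na|% 0) + v[[s]]
    tot
  }
  for (d in state$droplets) tot <- add(tot, d$composition)
  for (cl in state$clusters) {
    tot <- add(tot, cl$carried)
    tot <- add(tot, c(exo_ab42 = cl$surface[["cap_exo_ab42"]],
                      cd63_exo = cl$surface[["cap_cd63_exo"]],
                      hrp_ab   = cl$surface[["bound_hrp"]]))
  }
  tot[tot != 0]
}

#' Total droplet volume on the chip
#' @param state a [chip_state()].
#' @return numeric, ul.
#' @export
total_volume <- function(state) {
  sum(vapply(state$droplets, `[[`, numeric(1), "volume_ul"))
}

#' Write the event log as JSON lines
#' @param state a [chip_state()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(state, path) {
  stopifnot(inherits(state, "chip_state"))
  lines <- vapply(state$log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}
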