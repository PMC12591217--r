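test_that("the stock layout carries the full reagent set", {
  lay <- default_biochip_layout()
  vols <- lay$reservoirs$volume_ul
  names(vols) <- lay$reservoirs$name
  expect_equal(unname(vols[c("bead_res", "wash1", "wash2", "wash3", "wash4",
                             "label_res", "detect", "stop_res")]),
               c(8, 50, 50, 50, 50, 50, 50, 50))
  expect_equal(sum(vols), 358)
  expect_equal(lay$chamber_height_mm, 3)

  st <- chip_state(lay)
  expect_equal(total_volume(st), 358)
  expect_length(st$clusters, 2)       # assay beads + stop transport beads
  expect_error(biochip_layout(lay$reservoirs, detection_chamber = "nope"),
               "layout error")
})

test_that("droplet transport preserves volume and rejects wrong regimes", {
  st <- mini_chip()
  v0 <- total_volume(st)
  # stop_res droplet carries 8 mg transport beads; unit params: v <= 2 is
  # droplet operation
  st2 <- move_droplet(st, "stop_res", c(7, 8), 0.5)
  expect_equal(total_volume(st2), v0)
  expect_equal(unname(st2$droplets$stop_res$cell), c(7L, 8L))
  expect_equal(unname(st2$clusters$stop_res_beads$cell), c(7L, 8L))
  # zero-distance move leaves composition identical
  st3 <- move_droplet(st2, "stop_res", c(7, 8), 0.5)
  expect_identical(st3$droplets$stop_res$composition,
                   st2$droplets$stop_res$composition)
  # speed above the droplet/bead boundary: error names the computed zone
  expect_error(move_droplet(st, "stop_res", c(7, 8), 10), "BEAD_OP")
  # droplet without beads has no magnetic handle
  expect_error(move_droplet(st, "wash1", c(3, 2), 0.5), "NO_ENGAGEMENT")
})

test_that("bead extraction leaves the droplet behind and carries f of free species", {
  st <- mini_chip(carryover = 0.05)
  st <- extract_beads(st, "bead_res_beads", 10)
  st <- move_cluster(st, "bead_res_beads", c(1, 4))
  st <- insert_beads(st, "bead_res_beads", "sample")
  a0 <- st$droplets$sample$composition[["exo_ab42"]]
  st2 <- extract_beads(st, "bead_res_beads", 10)
  expect_equal(st2$droplets$sample$volume_ul, 100)            # volume stays
  expect_equal(st2$clusters$bead_res_beads$carrier, "oil")
  expect_false("bead_res_beads" %in%
                 magdrop:::clusters_in_droplet(st2, "sample"))
  expect_equal(st2$clusters$bead_res_beads$carried[["exo_ab42"]], 0.05 * a0)
  expect_equal(st2$droplets$sample$composition[["exo_ab42"]], 0.95 * a0)
  # wrong regime: droplet-operation speed cannot extract
  expect_error(extract_beads(st, "bead_res_beads", 0.5), "DROPLET_OP")
  # extracting from oil is a state error
  expect_error(extract_beads(st2, "bead_res_beads", 10), "state error")
})

test_that("extract/insert round trip with zero carryover is the identity", {
  st <- mini_chip(carryover = 0)
  st <- extract_beads(st, "bead_res_beads", 10)
  st <- insert_beads(st, "bead_res_beads", "sample")
  before <- st$droplets$sample$composition
  st2 <- extract_beads(st, "bead_res_beads", 10)
  expect_length(st2$clusters$bead_res_beads$carried, 0)
  st2 <- insert_beads(st2, "bead_res_beads", "sample")
  expect_equal(st2$droplets$sample$composition, before)
  expect_error(insert_beads(st2, "bead_res_beads", "wash1"), "state error")
})

test_that("three sequential wash transfers leave a carryover^3 residual", {
  f <- 0.02
  st <- mini_chip(carryover = f)
  st <- extract_beads(st, "bead_res_beads", 10)
  st <- insert_beads(st, "bead_res_beads", "sample")
  # contaminate the bead-bearing droplet with a known free-species amount
  st$droplets$sample$composition["free_ab42"] <- 1000
  # each transfer drags fraction f of the current droplet's contaminant
  for (w in c("wash1", "wash2", "wash3")) {
    st <- extract_beads(st, "bead_res_beads", 10)
    st <- insert_beads(st, "bead_res_beads", w)
  }
  expect_equal(st$droplets$wash3$composition[["free_ab42"]], 1000 * f^3)
  expect_equal(st$droplets$wash1$composition[["free_ab42"]],
               1000 * f * (1 - f))
})

test_that("merging adds volumes and amounts and dilutes concentrations", {
  st <- mini_chip()
  st <- move_droplet(st, "stop_res", c(5, 12), 0.5)   # adjacent to detect
  tot0 <- species_totals(st)
  st2 <- merge_droplets(st, "stop_res", "detect")
  expect_null(st2$droplets$stop_res)
  expect_equal(st2$droplets$detect$volume_ul, 100)    # 50 + 50
  # stop buffer now present: signal development frozen
  expect_true(st2$droplets$detect$stopped)
  # concentrations dilute by the volume ratio: tmb amount fixed, volume x2
  expect_equal(st2$droplets$detect$composition[["tmb"]] /
                 st2$droplets$detect$volume_ul,
               st$droplets$detect$composition[["tmb"]] /
                 st$droplets$detect$volume_ul / 2)
  # every species total conserved
  tot1 <- species_totals(st2)
  expect_equal(tot1[sort(names(tot1))], tot0[sort(names(tot0))],
               tolerance = 1e-14)
  expect_error(merge_droplets(st, "detect", "detect"), "argument error")
  expect_error(merge_droplets(st, "wash1", "detect"), "not adjacent")
})

test_that("mixing requires beads and advances capture additively", {
  st <- mini_chip()
  expect_error(mix_droplet(st, "wash1", 60), "state error")
  st <- extract_beads(st, "bead_res_beads", 10)
  st <- insert_beads(st, "bead_res_beads", "sample")

  one <- mix_droplet(st, "sample", 1200)
  two <- mix_droplet(mix_droplet(st, "sample", 600), "sample", 600)
  expect_equal(two$clusters$bead_res_beads$surface[["cap_exo_ab42"]],
               one$clusters$bead_res_beads$surface[["cap_exo_ab42"]],
               tolerance = 1e-9)
  # duration 0: no binding progress
  zero <- mix_droplet(st, "sample", 0)
  expect_equal(zero$clusters$bead_res_beads$surface[["cap_exo_ab42"]], 0)
  # droplet without capturable or labelling species: surface unchanged
  st2 <- mini_chip()
  st2 <- extract_beads(st2, "bead_res_beads", 10)
  st2 <- insert_beads(st2, "bead_res_beads", "wash1")
  mixed <- mix_droplet(st2, "wash1", 600)
  expect_equal(mixed$clusters$bead_res_beads$surface,
               st2$clusters$bead_res_beads$surface)
})

test_that("species totals and volumes are conserved across random event walks", {
  set.seed(31)
  for (rep in 1:25) {
    st <- mini_chip(carryover = stats::runif(1, 0, 0.1),
                    conc_pg_ml = stats::runif(1, 1, 50))
    st$droplets$sample$composition["bsa"] <- stats::runif(1, 0, 1e4)
    tot0 <- species_totals(st); v0 <- total_volume(st)
    in_oil <- FALSE; here <- "bead_res"
    for (k in 1:8) {
      op <- sample(c("extract", "insert", "mix"), 1)
      if (op == "extract" && !in_oil) {
        st <- extract_beads(st, "bead_res_beads", 10)
        in_oil <- TRUE
      } else if (op == "insert" && in_oil) {
        here <- sample(c("sample", "wash1", "wash2", "label_res"), 1)
        st <- insert_beads(st, "bead_res_beads", here)
        in_oil <- FALSE
      } else if (op == "mix" && !in_oil) {
        st <- mix_droplet(st, here, stats::runif(1, 0, 600))
      }
    }
    tot1 <- species_totals(st)
    expect_equal(total_volume(st), v0)
    for (s in names(tot0))
      expect_equal(tot1[[s]], tot0[[s]], tolerance = 1e-12)
  }
})

test_that("the event log serialises as JSON lines", {
  st <- mini_chip()
  st <- move_droplet(st, "stop_res", c(7, 8), 0.5)
  path <- tempfile(fileext = ".jsonl")
  write_event_log(st, path)
  lines <- readLines(path)
  expect_length(lines, length(st$log))
  parsed <- jsonlite::fromJSON(lines[length(lines)])
  expect_equal(parsed$event, "move_droplet")
})
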