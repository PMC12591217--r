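surface0 <- function(mass = 8, ap = assay_params())
  magdrop:::new_surface(mass, ap)

test_that("capture follows the Langmuir saturating time course", {
  ap <- assay_params(site_capacity_per_mg = 1, k_cap_per_min = 0.1,
                     k_half_pg_ml = 100)
  comp <- c(exo_ab42 = 500)   # 500 pg in 100 ul = 5000 pg/ml
  # t = 0: nothing captured
  r0 <- capture_exosomes(surface0(ap = ap), comp, 100, 0, ap)
  expect_equal(r0$surface[["cap_exo_ab42"]], 0)
  # long time, C >> K: capture approaches the site capacity
  rinf <- capture_exosomes(surface0(ap = ap), comp, 100, 3600 * 24, ap)
  q_eq <- 8 * 5000 / (5000 + 100)
  expect_equal(rinf$surface[["cap_exo_ab42"]], q_eq, tolerance = 1e-9)
  expect_lt(rinf$surface[["cap_exo_ab42"]], 8)  # capacity bound
  # amounts move, never appear: droplet loses what the surface gains
  expect_equal(rinf$composition[["exo_ab42"]] +
                 rinf$surface[["cap_exo_ab42"]], 500)
})

test_that("capture accumulation is memoryless: one 2t step equals two t steps", {
  ap <- assay_params()
  comp <- c(exo_ab42 = 1.2, cd63_exo = 0.8)
  whole <- capture_exosomes(surface0(ap = ap), comp, 100, 2400, ap)
  half1 <- capture_exosomes(surface0(ap = ap), comp, 100, 1200, ap)
  half2 <- capture_exosomes(half1$surface, half1$composition, 100, 1200, ap)
  expect_close(whole$surface, half2$surface, tol = 1e-9)
  expect_close(unlist(whole$composition), unlist(half2$composition),
               tol = 1e-9)
})

test_that("only CD63-bearing species are captured", {
  ap <- assay_params()
  r <- capture_exosomes(surface0(ap = ap),
                        c(free_ab42 = 100, bsa = 1000), 100, 3600, ap)
  expect_equal(r$surface[["cap_exo_ab42"]], 0)
  expect_equal(r$surface[["cap_cd63_exo"]], 0)
  expect_equal(r$composition[["free_ab42"]], 100)
})

test_that("labelling is dual-site: needs captured Abeta42-bearing exosomes", {
  ap <- assay_params()
  # no capture: no labels regardless of antibody excess
  r <- label_exosomes(surface0(ap = ap), c(hrp_ab = 1e6), 50, 3600, ap)
  expect_equal(r$surface[["bound_hrp"]], 0)
  # bare captured exosomes (CD63 only) acquire no label
  s <- surface0(ap = ap); s[["cap_cd63_exo"]] <- 2
  r2 <- label_exosomes(s, c(hrp_ab = 1e6), 50, 3600, ap)
  expect_equal(r2$surface[["bound_hrp"]], 0)
  # linear regime: doubling the captured amount doubles the labels
  s1 <- surface0(ap = ap); s1[["cap_exo_ab42"]] <- 1
  s2 <- surface0(ap = ap); s2[["cap_exo_ab42"]] <- 2
  h1 <- label_exosomes(s1, c(hrp_ab = 1e6), 50, 600, ap)$surface[["bound_hrp"]]
  h2 <- label_exosomes(s2, c(hrp_ab = 1e6), 50, 600, ap)$surface[["bound_hrp"]]
  expect_equal(h2 / h1, 2, tolerance = 1e-9)
  # labels come out of the antibody pool
  expect_equal(label_exosomes(s1, c(hrp_ab = 1e6), 50, 600,
                              ap)$composition[["hrp_ab"]], 1e6 - h1)
})

test_that("signal development is linear in HRP and time and freezes on stop", {
  ap <- assay_params(gain = 0.02, background = 0.05, noise_sd = 0)
  d <- list(signal = 0, stopped = FALSE)
  d <- develop_signal(d, hrp_bound = 3, duration_s = 600, ap)
  expect_equal(assay_signal(d, ap), 0.05 + 0.02 * 3 * 10)   # bg + g*h*t_min
  # zero HRP: background only
  d0 <- develop_signal(list(signal = 0, stopped = FALSE), 0, 600, ap)
  expect_equal(assay_signal(d0, ap), 0.05)
  # stop freezes: developing afterwards is a state error
  d <- stop_reaction(d)
  s_frozen <- assay_signal(d, ap)
  expect_error(develop_signal(d, 3, 600, ap), "state error")
  expect_equal(assay_signal(d, ap), s_frozen)
})

test_that("the closed-form dose-response is monotone and matches the chip simulation", {
  ap <- assay_params()
  conc <- c(0, 0.5, 1, 2, 5, 10, 20, 50)
  resp <- assay_response(conc, ap)
  expect_true(all(diff(resp) > 0))
  expect_equal(resp[1], ap$background)
  # the full on-chip run (zero carryover) reproduces the closed form
  st <- chip_state(default_biochip_layout(), assay_params = ap,
                   carryover = 0)
  st <- load_sample(st, 10)
  rec <- execute_program(default_ime_program(), st, seed = 1)
  expect_equal(rec$readout$absorbance, assay_response(10, ap),
               tolerance = 1e-6)
})

test_that("4PL fitting recovers known parameters from noiseless data", {
  truth <- list(a = 0.05, b = 1.3, c = 18, d = 1.9)
  x <- c(0, 0.5, 1, 2, 5, 10, 20, 50, 100)
  y <- truth$d + (truth$a - truth$d) / (1 + (x / truth$c)^truth$b)
  cv <- fit_4pl(x, y)
  for (p in names(truth))
    expect_equal(cv[[p]], truth[[p]], tolerance = 1e-6)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  # prediction and inversion are mutual inverses
  expect_equal(invert_4pl(cv, predict_4pl(cv, 7)), 7, tolerance = 1e-6)
})

test_that("degenerate calibration inputs are rejected", {
  x <- c(0, 1, 2, 5, 10)
  expect_error(fit_4pl(x, rep(0.3, 5)), "fit error")
  expect_error(fit_4pl(c(1, 2, 5, 10, 20), 1:5 / 10), "including 0")
  expect_error(fit_4pl(c(0, 1, 2), c(1, 2, 3)), "5 distinct")
})

test_that("LOD matches a brute-force grid inversion of the fitted curve", {
  cal <- simulate_calibration(params = assay_params(noise_sd = 0.01),
                              seed = 4)
  cv <- fit_4pl(cal$concentration_pg_ml, cal$signal)
  blanks <- cal$signal[cal$concentration_pg_ml == 0]
  got <- lod(cv, blanks)
  thr <- mean(blanks) + 3 * stats::sd(blanks)
  # independent oracle: dense grid + root refinement on the 4PL formula
  grid <- seq(1e-6, 50, length.out = 200001)
  pred <- cv$d + (cv$a - cv$d) / (1 + (grid / cv$c)^cv$b)
  i <- which.min(abs(pred - thr))
  f <- function(cc) cv$d + (cv$a - cv$d) / (1 + (cc / cv$c)^cv$b) - thr
  oracle <- stats::uniroot(f, c(grid[max(1, i - 2)], grid[min(length(grid),
                                                              i + 2)]),
                           tol = 1e-12)$root
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("LOD grows with blank noise and collapses to zero without it", {
  cal <- simulate_calibration(params = assay_params(noise_sd = 0),
                              seed = 4)
  cv <- fit_4pl(cal$concentration_pg_ml, cal$signal)
  base <- cal$signal[cal$concentration_pg_ml == 0][1]
  lods <- vapply(c(0.002, 0.01, 0.05), function(s)
    lod(cv, base + c(-s, 0, s)), numeric(1))
  expect_true(all(diff(lods) > 0))
  expect_lt(lod(cv, rep(base, 3)), 1e-6)
  expect_error(lod(cv, base + c(-10, 0, 10)), "out-of-range")
  expect_error(lod(cv, c(base, base)), "argument error")
})

test_that("single-marker inputs give background-level end-to-end signal", {
  ap <- assay_params(noise_sd = 0)
  run_with <- function(extra) {
    st <- chip_state(default_biochip_layout(), assay_params = ap)
    st <- load_sample(st, 0, extra_species = extra)
    execute_program(default_ime_program(), st, seed = 1)$readout$absorbance
  }
  target <- {
    st <- load_sample(chip_state(default_biochip_layout(),
                                 assay_params = ap), 25)
    execute_program(default_ime_program(), st, seed = 1)$readout$absorbance
  }
  off_target <- c(free_ab42 = run_with(c(free_ab42 = 2500)),
                  cd63_exo = run_with(c(cd63_exo = 2500)),
                  bsa = run_with(c(bsa = 2500)))
  expect_close(off_target, rep(ap$background, 3), tol = 1e-9)
  expect_gt(target, ap$background + 0.1)
})
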