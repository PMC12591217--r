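# shared fixtures and independent oracles, built in code

# independent zone oracle: evaluates the three force inequalities directly,
# without going through forces()/classify_zone()
oracle_zone <- function(mass, speed, k_mag, k_int, k_fric) {
  f_mag <- k_mag * mass
  f_int <- k_int * mass^(1/3)
  f_fric <- k_fric * speed
  if (f_fric <= min(f_mag, f_int)) return("DROPLET_OP")
  if (f_fric > f_int && f_mag > f_int) return("BEAD_OP")
  "NO_ENGAGEMENT"
}

# brute-force device packing: fill ports one coil at a time
oracle_device_count <- function(n_coils, ports) {
  devices <- 0L; free <- 0L
  for (i in seq_len(n_coils)) {
    if (free == 0L) { devices <- devices + 1L; free <- ports }
    free <- free - 1L
  }
  devices
}

# exact two-sided Mann-Whitney p by direct relabelling of the observed data
# (counts ties pairwise; independent of the package's rank-based route)
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  u_of <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * n2 / 2
  obs <- abs(u_of(x, y) - mu)
  sel <- utils::combn(n1 + n2, n1)
  us <- apply(sel, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= obs - 1e-9)
}

# a tiny chip state with one analyte droplet, one functionalised cluster and
# spare wash droplets, for conservation / washing experiments
mini_chip <- function(carryover = 0.01, conc_pg_ml = 10,
                      ap = assay_params(), fp = force_params()) {
  st <- chip_state(default_biochip_layout(), force_params = fp,
                   assay_params = ap, carryover = carryover)
  load_sample(st, conc_pg_ml)
}

expect_close <- function(x, y, tol = 1e-9) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max |diff| = %g", max(abs(x - y))))
}
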