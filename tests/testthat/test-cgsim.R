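test_that("topology counts follow the chain and dye specifications", {
  seq57 <- paste(sample(c("G", "S", "E", "K", "A"), 57, replace = TRUE),
                 collapse = "")
  full <- paste0("GSGSC", seq57, "CTLGPR")
  top <- build_topology(full)
  expect_equal(nrow(top$beads), 68)
  expect_equal(nrow(top$bonds), 67)
  expect_equal(nrow(top$angles), 0)
  expect_null(top$dye_center)

  # adding a 5-bead dye at one Cys: +5 beads, +5 bonds (incl. attachment),
  # angle terms only on the non-linker dye beads
  dye5 <- list(name = "probe",
               beads = data.frame(label = c("L1", "L2", "C1", "C2", "C3"),
                                  type = c("Lin", "Lin", "Neu", "Neg",
                                           "Neu")),
               bonds = data.frame(from = c("ATT", "L1", "L2", "C1", "C2"),
                                  to = c("L1", "L2", "C1", "C2", "C3")),
               angles = data.frame(a = c("L2", "C1"), b = c("C1", "C2"),
                                   c = c("C2", "C3"),
                                   theta0 = c(pi, pi)),
               center = "C2")
  con <- fret_construct(full, sites = c(5, 63), dyes = c("probe", "probe"),
                        R0 = 5, id = "c1")
  top2 <- build_topology(con, dye_specs = list(probe = dye5))
  expect_equal(nrow(top2$beads), 68 + 10)
  expect_equal(nrow(top2$bonds), 67 + 10)
  expect_equal(nrow(top2$angles), 4)
  expect_length(top2$dye_center, 2)
  # angle centers are all chromophore (non-linker) beads
  expect_true(all(top2$beads$type[top2$angles$j] %in% c("Neu", "Neg")))
  # non-Cys sites warn (one warning per site), configurable to error
  w <- capture_warnings(build_topology(
    fret_construct("GGGG", c(1, 4), c("probe", "probe"), R0 = 5),
    dye_specs = list(probe = dye5)))
  expect_length(w, 2)
  expect_match(w, "not Cys", all = TRUE)
  expect_error(build_topology(
    fret_construct("GGGG", c(1, 4), c("probe", "probe"), R0 = 5),
    dye_specs = list(probe = dye5), on_noncys = "error"), "not Cys")
})

test_that("dye specifications round-trip through YAML", {
  spec <- default_dye_specs()$CF660R
  path <- withr::local_tempfile(fileext = ".yaml")
  write_dye_spec(spec, path)
  back <- read_dye_spec(path)
  expect_equal(back$beads, spec$beads)
  expect_equal(back$bonds, spec$bonds)
  expect_equal(back$angles, spec$angles)
  expect_equal(back$center, spec$center)
  con1 <- fret_construct(strrep("C", 10), c(1, 10), c("CF660R", "CF660R"))
  t1 <- build_topology(con1)
  t2 <- build_topology(con1, dye_specs = list(CF660R = back))
  expect_equal(t1$beads, t2$beads)
  expect_equal(t1$bonds, t2$bonds)
})

test_that("pair potential reproduces the Ashbaugh-Hatch limits", {
  params <- hps_params()
  tab <- params$table
  # lambda = 1 pair at the LJ minimum: exactly -eps
  p1 <- params; p1$table[c("F", "F"), "lambda"] <- 1
  sij <- tab["F", "sigma"]
  expect_equal(pair_energy(2^(1 / 6) * sij, "F", "F", p1),
               -params$eps, tolerance = 1e-10)
  # lambda = 0: pure WCA, non-negative everywhere, zero beyond 2^(1/6) sigma
  p0 <- set_lambda(params, c(G = 0))
  sg <- tab["G", "sigma"]
  r <- seq(0.05, 2, by = 0.002)
  u <- pair_energy(r, "G", "G", p0)
  expect_true(all(u >= -1e-12))
  expect_true(all(u[r >= 2^(1 / 6) * sg] == 0))
  expect_error(pair_energy(0, "G", "G", params), "positive")
})

test_that("pair potential is continuous at the crossover for any lambda", {
  params <- hps_params()
  for (lam in c(0, 0.3, 0.75, 1, 1.5)) {
    p <- set_lambda(params, c(A = lam))
    sij <- params$table["A", "sigma"]
    rmin <- 2^(1 / 6) * sij
    left <- pair_energy(rmin * (1 - 1e-10), "A", "A", p)
    right <- pair_energy(rmin * (1 + 1e-10), "A", "A", p)
    # analytic limit from both sides is -lambda * eps
    expect_equal(left, -lam * params$eps, tolerance = 1e-7)
    expect_equal(right, -lam * params$eps, tolerance = 1e-7)
    expect_lt(abs(left - right), 1e-6)
  }
})

test_that("screened Coulomb term matches the Debye-Hueckel form", {
  params <- hps_params(ionic_strength = 165)
  lD <- debye_length(165, 300, 80)
  # physical screening length ~0.75 nm at 165 mM, 300 K, eps_r 80
  expect_equal(lD, 0.75, tolerance = 0.02)
  # beyond the LJ minimum the K-K pair is lambda*Phi_LJ plus screened
  # Coulomb; independent arithmetic from the published constants
  r <- 1.2
  sij <- params$table["K", "sigma"]
  lam <- params$table["K", "lambda"]
  phi <- 4 * params$eps * ((sij / r)^12 - (sij / r)^6)
  dh <- 1.602176634e-19^2 * 6.02214076e23 /
    (4 * pi * 8.8541878128e-12 * 80) * 1e6 *  # J m -> kJ nm / mol
    exp(-r / lD) / r
  expect_equal(pair_energy(r, "K", "K", params), lam * phi + dh,
               tolerance = 1e-6)
  # opposite charges attract: E-K Coulomb part is negative
  u_ek <- pair_energy(r, "E", "K", params)
  lam_ek <- mean(params$table[c("E", "K"), "lambda"])
  s_ek <- mean(params$table[c("E", "K"), "sigma"])
  phi_ek <- 4 * params$eps * ((s_ek / r)^12 - (s_ek / r)^6)
  expect_lt(u_ek - lam_ek * phi_ek, 0)
})

test_that("single free bead satisfies equipartition", {
  top <- build_topology("G")
  tr <- run_langevin(top, steps = 1e6, seed = 1, stride = 1000)
  expect_equal(tr$mean_kinetic, 1.5 * 0.00831446 * 300, tolerance = 0.02)
})

test_that("harmonic dimer samples the Boltzmann bond distribution", {
  top <- build_topology("GG")
  # move the beads out of LJ range? bonded pair is excluded from
  # nonbonded terms, so the bond is a clean harmonic oscillator
  tr <- run_langevin(top, steps = 1e6, seed = 2, stride = 50)
  r <- sqrt(rowSums((tr$frames[, 1, ] - tr$frames[, 2, ])^2))
  kT <- 0.00831446 * 300
  # oracle: exact 1D Boltzmann with the r^2 Jacobian by quadrature
  dens <- function(x) x^2 * exp(-481.4 * (x - 0.38)^2 / (2 * kT))
  Z <- integrate(dens, 0, 2)$value
  m1 <- integrate(function(x) x * dens(x) / Z, 0, 2)$value
  m2 <- integrate(function(x) x^2 * dens(x) / Z, 0, 2)$value
  expect_equal(mean(r), m1, tolerance = 0.01)
  expect_equal(sd(r), sqrt(m2 - m1^2), tolerance = 0.03)
  # the Gaussian-variance approximation kBT/k is recovered to ~5%
  expect_equal(sd(r), sqrt(kT / 481.4), tolerance = 0.05)
})

test_that("identical seeds give bit-identical trajectories", {
  top <- homopolymer_topology(12)
  a <- run_langevin(top, steps = 2e4, seed = 42, stride = 100)
  b <- run_langevin(top, steps = 2e4, seed = 42, stride = 100)
  expect_identical(a$frames, b$frames)
  expect_identical(a$potential, b$potential)
  c <- run_langevin(top, steps = 2e4, seed = 43, stride = 100)
  expect_false(identical(a$frames, c$frames))
})

test_that("simulator potential matches an independent double-loop oracle", {
  con <- fret_construct(paste0("C", strrep("EKGS", 4), "C"), c(1, 18))
  top <- build_topology(con, on_noncys = "ignore")
  params <- hps_params(ionic_strength = 185)
  tr <- run_langevin(top, params, steps = 2e4, seed = 3, stride = 2000,
                     equil_frac = 0)
  b <- top$beads
  bonded <- paste(top$bonds$i, top$bonds$j)
  for (f in seq_along(tr$potential)) {
    x <- tr$frames[f, , ]
    u <- 0
    for (i in seq_len(nrow(b) - 1)) for (j in (i + 1):nrow(b)) {
      if (paste(i, j) %in% bonded) next
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      u <- u + pair_energy(r, b$type[i], b$type[j], params)
    }
    for (bb in seq_len(nrow(top$bonds))) {
      r <- sqrt(sum((x[top$bonds$i[bb], ] - x[top$bonds$j[bb], ])^2))
      u <- u + 0.5 * top$bonds$k[bb] * (r - top$bonds$r0[bb])^2
    }
    for (aa in seq_len(nrow(top$angles))) {
      v1 <- x[top$angles$i[aa], ] - x[top$angles$j[aa], ]
      v2 <- x[top$angles$k_idx[aa], ] - x[top$angles$j[aa], ]
      th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
      u <- u + 0.5 * top$angles$k[aa] * (th - top$angles$theta0[aa])^2
    }
    expect_equal(u, tr$potential[f], tolerance = 1e-8)
  }
})

test_that("trajectory FRET observables follow the Forster formula", {
  top <- homopolymer_topology(4)
  top$dye_center <- c(1L, 4L); top$R0 <- 6
  tr <- run_langevin(top, steps = 1000, seed = 4, stride = 500)
  # overwrite with hand-built frames
  tr$frames <- array(0, c(2, 4, 3))
  tr$frames[1, 4, 1] <- 3     # r = 0.5 R0
  tr$frames[2, 4, 1] <- 12    # r = 2 R0
  fr <- fret_from_trajectory(tr)
  expect_equal(fr$E, c(1 / (1 + 0.5^6), 1 / (1 + 2^6)), tolerance = 1e-12)
  expect_equal(fr$mean_E, 0.5, tolerance = 1e-9)
  tr$frames[, 4, 1] <- c(6, 6)
  expect_equal(fret_from_trajectory(tr)$mean_E, 0.5, tolerance = 1e-12)
  top$dye_center <- NULL
  tr$topology <- top
  expect_error(fret_from_trajectory(tr), "dye-center")
})

test_that("mean efficiency decreases with chain length at fixed R0", {
  params <- wca_params()
  Es <- vapply(c(14, 28, 42), function(N) {
    top <- homopolymer_topology(N, params = params)
    top$dye_center <- c(1L, N); top$R0 <- 2.5
    tr <- run_langevin(top, params, steps = 8e5, seed = 5 + N,
                       stride = 400, friction = 0.3)
    fret_from_trajectory(tr)$mean_E
  }, numeric(1))
  expect_true(all(diff(Es) < 0))
})

test_that("xyz trajectory round-trips", {
  top <- homopolymer_topology(6)
  tr <- run_langevin(top, steps = 1e4, seed = 6, stride = 2000)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr, path)
  back <- read_trajectory_xyz(path)
  expect_equal(back, tr$frames, tolerance = 1e-5, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$seed, 6)
})
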