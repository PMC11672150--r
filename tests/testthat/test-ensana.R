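test_that("internal scaling recovers rod and ideal-chain exponents", {
  # collinear rod: <R>(s) = b s exactly, nu = 1, A0 = b
  rod <- gen_ensemble(50, n_residues = 30, b = 0.38, model = "rod",
                      seed = 51)
  isc <- internal_scaling(rod)
  expect_equal(unname(coef(isc)["nu"]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(isc)["A0"]), 0.38, tolerance = 1e-6)
  expect_equal(isc$R_mean[5], 5 * 0.38, tolerance = 1e-9)
  # Gaussian chain: nu = 0.50 +/- 0.02
  gc <- gen_ensemble(8000, n_residues = 40, b = 0.38, seed = 52)
  nu <- unname(coef(internal_scaling(gc))["nu"])
  expect_equal(nu, 0.5, tolerance = 0.02)
  expect_error(internal_scaling(rod, window = c(5, 6.5)), "fewer than 3")
})

test_that("weighting by frame duplication equals uniform weighting", {
  ens <- gen_ensemble(200, n_residues = 20, seed = 53)
  dup <- conformational_ensemble(ens$coords[c(1:200, 1:100), , ])
  w <- c(rep(2, 100), rep(1, 100))
  prof_w <- internal_scaling(ens, weights = w)
  prof_d <- internal_scaling(dup)
  expect_equal(prof_w$R_mean, prof_d$R_mean, tolerance = 1e-10)
})

test_that("scaled distance map self-normalizes and finds planted compaction", {
  gc <- gen_ensemble(6000, n_residues = 50, seed = 54)
  fit <- internal_scaling(gc)
  m <- scaled_distance_map(gc, fit = fit, min_spacing = 10)
  expect_true(all(is.na(m[abs(row(m) - col(m)) < 10])))
  vals <- m[!is.na(m)]
  expect_equal(mean(vals), 1, tolerance = 0.02)
  expect_equal(max(abs(m - t(m)), na.rm = TRUE), 0, tolerance = 1e-12)
  # plant a compact subdomain: contract residues 20-35 toward their center
  comp <- gc$coords
  for (f in seq_len(dim(comp)[1])) {
    seg <- comp[f, 20:35, ]
    ctr <- colMeans(seg)
    comp[f, 20:35, ] <- sweep(sweep(seg, 2, ctr), 1, 0.35, "*") +
      rep(ctr, each = 16)
  }
  m2 <- scaled_distance_map(conformational_ensemble(comp),
                            fit = fit, min_spacing = 10)
  inside <- m2[20:35, 20:35]
  expect_lt(mean(inside, na.rm = TRUE), 0.6)
})

test_that("contact map equals the brute-force per-frame scan", {
  ens <- gen_ensemble(100, n_residues = 15, b = 0.3, seed = 55)
  cm <- contact_map(ens, threshold = 0.8)
  # O(N^2 x frames) oracle
  ref <- matrix(0, 15, 15)
  for (f in 1:100) {
    d <- as.matrix(dist(ens$coords[f, , ]))
    ref <- ref + (d < 0.8 & row(d) != col(d)) / 100
  }
  expect_equal(cm, ref, tolerance = 1e-12, ignore_attr = TRUE)
  # bonded neighbors at fixed 0.38 nm are always in contact at 1 nm
  expect_true(all(diag(cm[-1, -15]) >= 0))
  # extended rod has no contacts beyond |i-j| > 3 at 1.0 nm threshold
  rod <- gen_ensemble(10, n_residues = 15, b = 0.38, model = "rod",
                      seed = 56)
  cr <- contact_map(rod, threshold = 1.0)
  sep <- abs(row(cr) - col(cr))
  expect_true(all(cr[sep > 3] == 0))
  expect_true(all(cr[sep == 1] == 1))
})

test_that("closest-heavy mode uses the site-to-residue mapping", {
  # 2 residues x 2 sites each; only one cross-site pair is close
  coords <- array(0, c(1, 4, 3))
  coords[1, 1, ] <- c(0, 0, 0);   coords[1, 2, ] <- c(0.5, 0, 0)
  coords[1, 3, ] <- c(3, 0, 0);   coords[1, 4, ] <- c(1.2, 0, 0)
  ens <- conformational_ensemble(coords, site_residue = c(1, 1, 2, 2))
  cm <- contact_map(ens, threshold = 1.0, mode = "closest-heavy")
  expect_equal(cm[1, 2], 1)  # sites 2 and 4 are 0.7 apart
  expect_error(contact_map(ens, mode = "bead"), "one site per residue")
})

test_that("contact network thresholds edges at a fraction of the maximum", {
  cmap <- matrix(0.02, 12, 12)
  cmap[4, 9] <- cmap[9, 4] <- 0.6    # dominant pair
  cmap[3, 10] <- cmap[10, 3] <- 0.3  # above 0.35 * 0.6 = 0.21
  g <- contact_network(cmap, edge_fraction = 0.35)
  expect_equal(igraph::ecount(g), 2)
  g2 <- contact_network(cmap, edge_fraction = 0.9)
  expect_equal(igraph::ecount(g2), 1)
  # edge count is non-increasing in the threshold fraction
  counts <- vapply(seq(0.05, 1, by = 0.05), function(fr)
    igraph::ecount(contact_network(cmap, edge_fraction = fr)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # near-diagonal pairs never make edges
  cmap2 <- matrix(0.5, 6, 6)
  g3 <- contact_network(cmap2, edge_fraction = 0.35)
  ends <- igraph::as_edgelist(g3)
  expect_true(all(abs(as.numeric(ends[, 1]) - as.numeric(ends[, 2])) > 2))
  # residue class coloring metadata
  g4 <- contact_network(cmap, labels = rep(c("G", "R", "F"), 4))
  expect_setequal(unique(igraph::V(g4)$class), c("Gly", "basic", "aromatic"))
})

test_that("shape metrics: rod, cube, and ideal-chain ratio", {
  # perfect rod: asphericity 1
  rod <- gen_ensemble(5, n_residues = 20, model = "rod", seed = 57)
  expect_equal(shape_metrics(rod)$asphericity, 1, tolerance = 1e-9)
  # cube corners: isotropic gyration tensor, asphericity 0
  cube <- array(0, c(1, 8, 3))
  cube[1, , ] <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(shape_metrics(conformational_ensemble(cube))$asphericity,
               0, tolerance = 1e-12)
  # Gaussian chain: <R^2>/<Rg^2> = 6 +/- 0.2
  gc <- gen_ensemble(8000, n_residues = 50, seed = 58)
  sm <- shape_metrics(gc)
  ratio <- sm$R^2 / sum(gc$weights * sm$Rg_frame^2)
  expect_equal(ratio, 6, tolerance = 0.2 / 6)
})

test_that("Debye profile matches the two-scatterer closed form", {
  d <- 2.5
  coords <- array(0, c(1, 2, 3)); coords[1, 2, 3] <- d
  ens <- conformational_ensemble(coords)
  q <- seq(0.05, 3, by = 0.05)
  prof <- saxs_profile(ens, q)
  ref <- (2 + 2 * sin(q * d) / (q * d)) / 4
  expect_equal(prof$I, ref, tolerance = 1e-10)
  expect_error(saxs_profile(ens, numeric(0)), "empty q grid")
})

test_that("Guinier Rg agrees with the gyration tensor for a compact ensemble", {
  set.seed(59)
  # compact blob: Gaussian cloud of beads
  nf <- 300; n <- 40
  coords <- array(rnorm(nf * n * 3, sd = 0.5), c(nf, n, 3))
  ens <- conformational_ensemble(coords)
  sm <- shape_metrics(ens)
  rg_t <- sqrt(sum(ens$weights * sm$Rg_frame^2))
  prof <- saxs_profile(ens, seq(0.02, 2, by = 0.02))
  expect_equal(guinier_rg(prof), rg_t, tolerance = 0.03)
  # Guinier behavior: monotone decreasing at small q
  low <- prof$I[prof$q < 1 / rg_t]
  expect_true(all(diff(low) < 0))
})

test_that("regression suite matches a normal-equations oracle", {
  set.seed(60)
  X <- data.frame(a = rnorm(16), b = rnorm(16), c = rnorm(16))
  # exact linear function of one feature
  y1 <- 2 + 3 * X$a
  rs1 <- regression_suite(X, y1, max_order = 1)
  expect_equal(rs1$table$rho2[rs1$table$combo == "a"], 1, tolerance = 1e-10)
  # random response: rho2 from the pseudoinverse for the triple model
  y <- rnorm(16)
  rs <- regression_suite(X, y)
  M <- cbind(1, as.matrix(X))
  yhat <- M %*% solve(crossprod(M), crossprod(M, y))
  rho2_ref <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(rs$table$rho2[rs$table$combo == "a+b+c"], rho2_ref,
               tolerance = 1e-10)
  expect_length(rs$loo[[1]], 16)
})

test_that("Lin's concordance penalizes offset and scale", {
  set.seed(61)
  x <- rnorm(50)
  expect_equal(lin_ccc(x, x), 1)
  expect_lt(lin_ccc(x, x + 0.1), 1)
  expect_lt(lin_ccc(x, 2 * x), 1)
  # frozen small case computed by the definition
  a <- c(1, 2, 3, 4); b <- c(1.1, 2.0, 2.9, 4.2)
  n <- 4
  sxy <- cov(a, b) * 3 / 4
  ref <- 2 * sxy / (var(a) * 3 / 4 + var(b) * 3 / 4 + (mean(a) - mean(b))^2)
  expect_equal(lin_ccc(a, b), ref, tolerance = 1e-12)
})
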