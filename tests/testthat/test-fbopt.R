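test_that("two-frame toy ensemble matches the hand-computed covariance", {
  # frames with observable E = {0.2, 0.8} and per-type derivatives
  E <- c(0.2, 0.8)
  u <- matrix(c(-1, -3,   # type 1
                -2, -2),  # type 2 (no covariance with E)
              nrow = 2)
  beta <- 0.4
  g <- linear_response_dEdlambda(E, u, beta)
  # cov(E, u1) = mean(Ec * u1) with Ec = {-0.3, +0.3}: 0.3*(-3+1)/2 = -0.3
  expect_equal(g[1], -beta * (-0.3), tolerance = 1e-12)
  expect_equal(g[2], 0, tolerance = 1e-12)
})

test_that("matched targets at the starting point are a stationary point", {
  lam <- c(G = 0.5, S = 0.3)
  lg <- fb_loss_gradient(E_mean = c(0.6, 0.4),
                         dEdlam = matrix(rnorm(4), 2,
                                         dimnames = list(NULL, names(lam))),
                         targets = c(0.6, 0.4), lambda = lam,
                         lambda0 = lam, alpha = 1e-4)
  expect_equal(lg$loss, 0)
  expect_equal(unname(lg$gradient), c(0, 0))
  # regularization limit: with huge alpha the gradient pins lambda at
  # lambda0
  lg2 <- fb_loss_gradient(c(0.6), matrix(0.1, 1, 2,
                                         dimnames = list(NULL, names(lam))),
                          c(0.4), lam + 0.1, lam, alpha = 1e8)
  dir <- lg2$gradient / sqrt(sum(lg2$gradient^2))
  expect_equal(unname(dir), c(1, 1) / sqrt(2), tolerance = 1e-4)
})

test_that("linear-response slope agrees with a reweighting oracle", {
  # short stored trajectory of a two-type chain; perturb lambda_G by
  # +/- delta and compare the reweighted means with the linear slope
  params <- hps_params()
  top <- build_topology(strrep("GS", 8), params = params)
  top$dye_center <- c(1L, 16L); top$R0 <- 2
  tr <- run_langevin(top, params, steps = 6e5, seed = 61, stride = 100,
                     friction = 0.5)
  E <- fret_from_trajectory(tr)$E
  types <- c("G", "S")
  ti <- match(top$beads$type, types) - 1L
  u <- hps_dudlam_frames(idrscope:::frames_flat(tr$frames), ti,
                         top$beads$sigma,
                         as.matrix(top$bonds[, c("i", "j")]),
                         params$eps, params$cutoff, 2L)
  beta <- 1 / (0.00831446 * 300)
  slope <- linear_response_dEdlambda(E, u, beta)[1]
  delta <- 0.01
  rw <- function(d) {
    lw <- -beta * d * u[, 1]
    w <- exp(lw - max(lw)); w <- w / sum(w)
    sum(w * E)
  }
  fd <- (rw(delta) - rw(-delta)) / (2 * delta)
  expect_equal(slope, fd, tolerance = 0.05)
})

test_that("frozen entries receive zero updates and alpha pins lambda", {
  params <- hps_params()
  mk <- function(seqstr) {
    top <- build_topology(seqstr, params = params)
    top$dye_center <- c(1L, nchar(seqstr)); top$R0 <- 2
    top
  }
  tops <- list(mk(strrep("GS", 6)))
  lam0 <- c(G = 0.4, S = 0.6)
  fb <- force_balance(tops, data.frame(id = 1, E = 0.9),
                      params = params, free = "G", lambda0 = lam0,
                      eta = 1, steps_per_iter = 1e5, stride = 100,
                      friction = 0.5, seed = 62, max_iter = 3)
  lam_hist <- t(vapply(fb$history, function(h) h$lambda, lam0))
  expect_true(all(lam_hist[, "S"] == 0.6))
  expect_false(all(lam_hist[, "G"] == 0.4))
  # alpha -> infinity keeps even the free entry at its start
  fb2 <- force_balance(tops, data.frame(id = 1, E = 0.9),
                       params = params, free = "G", lambda0 = lam0,
                       eta = 1e-9, alpha = 1e9,
                       steps_per_iter = 1e5, stride = 100,
                       friction = 0.5, seed = 63, max_iter = 3)
  expect_equal(unname(coef(fb2)["G"]), 0.4, tolerance = 1e-3)
})

test_that("single-construct single-lambda descent reduces the loss", {
  params <- hps_params()
  top <- build_topology(strrep("G", 14), params = params)
  top$dye_center <- c(1L, 14L); top$R0 <- 2.2
  # target generated at lambda_G = 0.8; start at 0.45
  ref <- run_langevin(set_lambda(top, c(G = 0.8)),
                      set_lambda(params, c(G = 0.8)),
                      steps = 1.5e6, seed = 64, stride = 200,
                      friction = 0.5)
  target <- fret_from_trajectory(ref)$mean_E
  fb <- force_balance(list(top), data.frame(id = 1, E = target),
                      params = params, free = "G",
                      lambda0 = c(G = 0.45), eta = 2,
                      steps_per_iter = 6e5, stride = 200,
                      friction = 0.5, seed = 65, max_iter = 6,
                      tol = 1e-5)
  expect_lt(min(fb$trace$loss), fb$trace$loss[1])
  # lambda moved toward the generating value
  expect_gt(unname(coef(fb)["G"]), 0.5)
})

test_that("grid search returns the loss-minimizing dye/linker pair", {
  params <- hps_params()
  con <- fret_construct(paste0("C", strrep("G", 8), "C"), c(1, 10),
                        c("Cy3B", "CF660R"), R0 = 2.5)
  gs <- grid_search_dye_lambda(list(con), data.frame(id = 1, E = 0.6),
                               params = params, grid = c(0.2, 0.8),
                               steps_per_iter = 1e5, stride = 200,
                               friction = 0.5, seed = 66)
  expect_true(gs$dye %in% c(0.2, 0.8))
  expect_true(gs$linker %in% c(0.2, 0.8))
  expect_equal(nrow(gs$grid), 4)
  expect_equal(min(gs$grid$loss), gs$loss)
})
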