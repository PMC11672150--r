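# Force-balance optimization of HPS stickiness parameters against target
# mean transfer efficiencies: gradients from linear response on stored
# frames, gradient descent with learning-rate adaptation, and L2
# regularization toward the starting parameter set.

#' Linear-response sensitivity of a trajectory mean to lambda
#'
#' For a stored ensemble with per-frame observable `E` and per-frame
#' potential derivative \eqn{u_k = \partial U / \partial \lambda_k}
#' (columns of `u`), the linear-response estimate of the sensitivity of
#' the ensemble mean is
#' \eqn{\partial \langle E \rangle / \partial \lambda_k =
#' -\beta (\langle E u_k \rangle - \langle E \rangle \langle u_k \rangle)}.
#'
#' @param E Per-frame observable values.
#' @param u Frames x types matrix of potential derivatives (kJ/mol).
#' @param beta Inverse temperature 1/(kB T) in mol/kJ.
#' @return Numeric vector, one sensitivity per type (column of `u`).
#' @export
linear_response_dEdlambda <- function(E, u, beta) {
  stopifnot(length(E) == nrow(u))
  Ec <- E - mean(E)
  -beta * colMeans(Ec * u)
}

#' Force-balance loss and gradient
#'
#' Loss is the squared mismatch between simulated and target means plus
#' L2 starting-point regularization:
#' \eqn{L = \sum_c (\langle E \rangle_c - E^{t}_c)^2 +
#' \alpha \sum_k (\lambda_k - \lambda^0_k)^2}. The gradient combines the
#' per-construct linear-response sensitivities with the regularization
#' term \eqn{2\alpha(\lambda_k - \lambda^0_k)}.
#'
#' @param E_mean Simulated mean observable per construct.
#' @param dEdlam Constructs x types matrix of sensitivities.
#' @param targets Target means per construct.
#' @param lambda,lambda0 Current and starting type parameters (named).
#' @param alpha Regularization strength.
#' @return List `loss`, `gradient` (named by type).
#' @export
fb_loss_gradient <- function(E_mean, dEdlam, targets, lambda, lambda0,
                             alpha) {
  mis <- E_mean - targets
  loss <- sum(mis^2) + alpha * sum((lambda - lambda0)^2)
  grad <- drop(2 * mis %*% dEdlam) + 2 * alpha * (lambda - lambda0)
  names(grad) <- names(lambda)
  list(loss = loss, gradient = grad)
}

# simulate every construct at the current parameters and collect the
# per-frame observables and potential derivatives
fb_simulate <- function(topologies, params, lambda, steps, stride,
                        friction, equil_frac, seed, iter, R0s) {
  types <- names(lambda)
  p <- set_lambda(params, lambda)
  lapply(seq_along(topologies), function(ci) {
    top <- set_lambda(topologies[[ci]], lambda)
    traj <- run_langevin(top, p, steps = steps, stride = stride,
                         friction = friction, equil_frac = equil_frac,
                         seed = seed + 7919 * iter + ci)
    fr <- fret_from_trajectory(traj, R0 = R0s[ci])
    ti <- match(top$beads$type, types)
    if (anyNA(ti)) stop("bead type missing from lambda vector")
    u <- hps_dudlam_frames(frames_flat(traj$frames), ti - 1L,
                           top$beads$sigma,
                           as.matrix(top$bonds[, c("i", "j")]),
                           p$eps, p$cutoff, length(types))
    colnames(u) <- types
    list(E = fr$E, mean_E = fr$mean_E, u = u)
  })
}

#' Force-balance optimization of stickiness parameters
#'
#' Iterates the per-type short-range parameters \eqn{\lambda} (residue
#' and dye bead types in one vector) to minimize the mismatch between
#' simulated and target mean transfer efficiencies. Each iteration
#' re-simulates every construct at the current parameters, estimates the
#' gradient by linear response on the stored frames, and takes a
#' gradient-descent step \eqn{\lambda \leftarrow \lambda - \eta \nabla L}
#' on the free entries. On a streak of loss increases the learning rate
#' is halved (aborting at a floor); optimization stops when the relative
#' loss change stays below `tol` over `patience` iterations or at
#' `max_iter`.
#'
#' @param constructs List of [fret_construct()]s or prebuilt
#'   `cg_topology` objects.
#' @param targets `data.frame` with columns `id`, `E` and optionally
#'   `error` (per-construct target mean efficiency).
#' @param params An [hps_params()] providing everything but lambda.
#' @param free Character vector of bead types to optimize; all other
#'   entries stay frozen at their starting values.
#' @param lambda0 Named starting values (default: from `params`); also
#'   the L2 regularization anchor.
#' @param eta Learning rate (default 5.0).
#' @param alpha L2 starting-point regularization strength (default 1e-4).
#' @param steps_per_iter Integration steps per construct per iteration.
#' @param stride Frame stride for the stored trajectory.
#' @param friction Langevin friction (1/ps).
#' @param equil_frac Equilibration fraction discarded per run.
#' @param seed Base RNG seed (iteration and construct offsets added).
#' @param max_iter Maximum iterations.
#' @param patience Plateau window (iterations).
#' @param tol Relative loss-change tolerance defining the plateau.
#' @param eta_floor Abort threshold for the adapted learning rate.
#' @return Object of class `force_balance`: final `lambda`, `lambda_avg`
#'   (mean over the last five iterations, damping stochastic-gradient
#'   noise), `history` (per-iteration loss, eta, lambda, simulated
#'   means), `status`.
#' @export
force_balance <- function(constructs, targets, params = hps_params(),
                          free, lambda0 = NULL, eta = 5.0, alpha = 1e-4,
                          steps_per_iter = 5e5, stride = 200L,
                          friction = 1.0, equil_frac = 0.2, seed = 1,
                          max_iter = 20L, patience = 3L, tol = 1e-3,
                          eta_floor = 1e-4) {
  topologies <- lapply(constructs, function(cc)
    if (inherits(cc, "cg_topology")) cc else
      build_topology(cc, params = params, on_noncys = "ignore"))
  R0s <- vapply(topologies, function(tp) tp$R0, numeric(1))
  if (any(!is.finite(R0s))) stop("every construct needs a Forster radius")
  types <- unique(unlist(lapply(topologies, function(tp) tp$beads$type)))
  if (is.null(lambda0))
    lambda0 <- setNames(params$table[types, "lambda"], types)
  lambda0 <- lambda0[types]
  stopifnot(all(free %in% types))
  lambda <- lambda0
  beta <- 1 / (KB_KJ * params$temperature)
  tvec <- targets$E

  history <- list()
  best_loss <- Inf
  inc_streak <- 0L
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    sims <- fb_simulate(topologies, params, lambda, steps_per_iter,
                        stride, friction, equil_frac, seed, it, R0s)
    E_mean <- vapply(sims, `[[`, 0, "mean_E")
    dEdlam <- t(vapply(sims, function(s)
      linear_response_dEdlambda(s$E, s$u, beta), numeric(length(types))))
    colnames(dEdlam) <- types
    lg <- fb_loss_gradient(E_mean, dEdlam, tvec, lambda, lambda0, alpha)
    history[[it]] <- list(iter = it, loss = lg$loss, eta = eta,
                          lambda = lambda, E_mean = E_mean,
                          gradient = lg$gradient)
    if (lg$loss > best_loss * (1 + 1e-12)) {
      inc_streak <- inc_streak + 1L
      if (inc_streak >= 2L) {
        eta <- eta / 2
        inc_streak <- 0L
        if (eta < eta_floor) { status <- "eta_floor"; break }
      }
    } else inc_streak <- 0L
    best_loss <- min(best_loss, lg$loss)
    if (it > patience) {
      recent <- vapply(history[(it - patience):it], `[[`, 0, "loss")
      if (max(abs(diff(recent))) / max(recent[1], 1e-12) < tol) {
        status <- "plateau"; break
      }
    }
    step <- eta * lg$gradient
    step[!(types %in% free)] <- 0
    lambda <- lambda - step
  }
  hist_df <- data.frame(
    iter = vapply(history, `[[`, 0, "iter"),
    loss = vapply(history, `[[`, 0, "loss"),
    eta = vapply(history, `[[`, 0, "eta"))
  # tail average damps the stochastic-gradient noise in the estimate
  tail_n <- min(5L, length(history))
  lam_tail <- Reduce(`+`, lapply(tail(history, tail_n), `[[`, "lambda")) /
    tail_n
  structure(list(lambda = lambda, lambda_avg = lam_tail,
                 lambda0 = lambda0, free = free,
                 history = history, trace = hist_df, status = status,
                 targets = targets,
                 E_final = history[[length(history)]]$E_mean),
            class = "force_balance")
}

#' @export
print.force_balance <- function(x, ...) {
  cat(sprintf("<force_balance> %d iterations (%s)\n",
              nrow(x$trace), x$status))
  cat(sprintf("  loss %.5g -> %.5g\n", x$trace$loss[1],
              min(x$trace$loss)))
  cat("  optimized lambda:\n")
  print(round(x$lambda[x$free], 4))
  invisible(x)
}

#' @export
coef.force_balance <- function(object, ...) object$lambda

#' @export
plot.force_balance <- function(x, ...) {
  plot(x$trace$iter, x$trace$loss, type = "b", xlab = "iteration",
       ylab = "loss", log = "y", ...)
  invisible(x)
}

#' Coarse grid search over dye and linker stickiness
#'
#' Evaluates the unregularized mismatch loss on a grid of (chromophore,
#' linker) lambda pairs using short simulations, returning the pair that
#' minimizes the initial loss. Used to seed the dye bead types before
#' force balance.
#'
#' @inheritParams force_balance
#' @param grid Candidate lambda values for both roles.
#' @param dye_types Bead types set to the chromophore value.
#' @param linker_types Bead types set to the linker value.
#' @return List `dye`, `linker`, `loss`, and the full `grid` data.frame.
#' @export
grid_search_dye_lambda <- function(constructs, targets,
                                   params = hps_params(),
                                   grid = seq(0, 1.2, by = 0.2),
                                   dye_types = c("Neg", "Neu", "Pos"),
                                   linker_types = "Lin",
                                   steps_per_iter = 1e5, stride = 200L,
                                   friction = 1.0, equil_frac = 0.2,
                                   seed = 1) {
  topologies <- lapply(constructs, function(cc)
    if (inherits(cc, "cg_topology")) cc else
      build_topology(cc, params = params, on_noncys = "ignore"))
  R0s <- vapply(topologies, function(tp) tp$R0, numeric(1))
  types <- unique(unlist(lapply(topologies, function(tp) tp$beads$type)))
  lambda <- setNames(params$table[types, "lambda"], types)
  cases <- expand.grid(dye = grid, linker = grid)
  cases$loss <- NA_real_
  for (r in seq_len(nrow(cases))) {
    lam <- lambda
    lam[intersect(dye_types, types)] <- cases$dye[r]
    lam[intersect(linker_types, types)] <- cases$linker[r]
    sims <- fb_simulate(topologies, params, lam, steps_per_iter, stride,
                        friction, equil_frac, seed, r, R0s)
    E_mean <- vapply(sims, `[[`, 0, "mean_E")
    cases$loss[r] <- sum((E_mean - targets$E)^2)
  }
  best <- cases[which.min(cases$loss), ]
  list(dye = best$dye, linker = best$linker, loss = best$loss,
       grid = cases)
}
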