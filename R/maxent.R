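# Maximum-entropy reweighting of conformational ensembles against a single
# measured ensemble average (e.g. a mean FRET transfer efficiency), in the
# COPER spirit: the posterior is the minimum Kullback-Leibler perturbation
# of the prior that satisfies the experimental constraint within its error.

#' Maximum-entropy reweighting to match a measured mean
#'
#' Finds posterior frame weights \eqn{w_i \propto w^0_i \exp(-\theta E_i)}
#' with the Lagrange multiplier \eqn{\theta} chosen so that the reweighted
#' mean \eqn{\sum_i w_i E_i} equals the target. The experimental error is
#' treated as an inequality relaxation: if the prior mean already lies
#' within `tolerance` of the target, \eqn{\theta = 0}; otherwise the
#' constraint is solved to the nearer edge of the tolerance band, which is
#' the minimum-divergence feasible point.
#'
#' @param E Per-frame observable values (e.g. frame transfer efficiencies).
#' @param target Measured ensemble mean to match.
#' @param tolerance Experimental error on the target (one-sided band
#'   half-width); 0 enforces the mean exactly.
#' @param prior Prior weights (default uniform); normalized internally.
#' @param floor Weights below this value are floored and the vector
#'   renormalized, for numerical stability.
#' @return Object of class `maxent_fit`: `weights`, `theta`, `kl`
#'   (divergence in nats), `mean` (posterior mean), plus the inputs.
#'   Supports `print`, `weights`.
#' @export
maxent <- function(E, target, tolerance = 0, prior = NULL,
                   floor = 1e-12) {
  E <- as.numeric(E)
  n <- length(E)
  if (n < 1L) stop("empty ensemble")
  if (is.null(prior)) prior <- rep(1 / n, n)
  if (length(prior) != n) stop("prior length mismatch")
  if (any(prior < 0)) stop("negative prior weights")
  prior <- prior / sum(prior)
  lo <- min(E); hi <- max(E)
  if (target < lo - tolerance || target > hi + tolerance)
    stop(sprintf(
      "target %.6g unreachable: achievable range is [%.6g, %.6g]",
      target, lo, hi))

  prior_mean <- sum(prior * E)
  if (abs(prior_mean - target) <= tolerance) {
    theta <- 0
    w <- prior
  } else {
    # solve to the nearer edge of the tolerance band
    goal <- if (prior_mean > target) target + tolerance else target - tolerance
    goal <- min(max(goal, lo), hi)
    # mean under theta; log-sum-exp guarded
    mean_at <- function(theta) {
      lw <- log(prior) - theta * E
      lw <- lw - max(lw)
      wt <- exp(lw); wt <- wt / sum(wt)
      sum(wt * E)
    }
    f <- function(theta) mean_at(theta) - goal
    # mean_at is strictly decreasing in theta; expand a bracket then root-find
    span <- 1 / max(sd(E), 1e-12)
    lo_t <- -span; hi_t <- span
    for (k in 1:60) {
      if (f(lo_t) > 0 && f(hi_t) < 0) break
      if (f(lo_t) <= 0) lo_t <- lo_t * 2
      if (f(hi_t) >= 0) hi_t <- hi_t * 2
    }
    theta <- uniroot(f, c(lo_t, hi_t), tol = 1e-14)$root
    lw <- log(prior) - theta * E
    lw <- lw - max(lw)
    w <- exp(lw); w <- w / sum(w)
  }
  if (any(w < floor)) {
    w <- pmax(w, floor)
    w <- w / sum(w)
  }
  structure(list(weights = w, theta = theta,
                 kl = kl_divergence(w, prior),
                 mean = sum(w * E), prior_mean = prior_mean,
                 target = target, tolerance = tolerance,
                 E = E, prior = prior),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat("Maximum-entropy reweighting\n")
  cat(sprintf("  frames      : %d\n", length(x$weights)))
  cat(sprintf("  prior mean  : %.6f\n", x$prior_mean))
  cat(sprintf("  target      : %.6f (+/- %.4g)\n", x$target, x$tolerance))
  cat(sprintf("  post. mean  : %.6f\n", x$mean))
  cat(sprintf("  theta       : %.6g\n", x$theta))
  cat(sprintf("  KL div      : %.6g nats\n", x$kl))
  invisible(x)
}

#' Extract posterior weights from a reweighting fit
#' @param object A `maxent_fit`.
#' @param ... Unused.
#' @importFrom stats weights
#' @export
weights.maxent_fit <- function(object, ...) object$weights

#' Kullback-Leibler divergence between weight vectors
#'
#' \eqn{D_{KL}(w \| w^0) = \sum_i w_i \ln(w_i / w^0_i)} in nats, with the
#' convention \eqn{0 \ln 0 = 0}. Requires absolute continuity: a positive
#' posterior weight on a zero-prior frame is an error.
#'
#' @param w Posterior weights (normalized internally).
#' @param w0 Prior weights.
#' @return Non-negative scalar; 0 iff `w == w0`.
#' @export
kl_divergence <- function(w, w0) {
  w <- w / sum(w); w0 <- w0 / sum(w0)
  if (any(w > 0 & w0 == 0))
    stop("absolute continuity violated: posterior mass on zero-prior frame")
  pos <- w > 0
  sum(w[pos] * log(w[pos] / w0[pos]))
}

#' Partition reweighting results by divergence cutoff
#'
#' Splits a set of reweighting results into those whose prior needed only
#' minimal perturbation (\eqn{D_{KL} \le} cutoff) and those requiring
#' substantial reweighting, as used to decide which ensembles are analyzed
#' further.
#'
#' @param results Named list of `maxent_fit` objects (or numeric KL values).
#' @param cutoff Divergence cutoff in nats (default 0.1).
#' @return List with `pass`, `flagged` (character vectors of names) and
#'   `kl` (named numeric vector).
#' @export
flag_high_divergence <- function(results, cutoff = 0.1) {
  kl <- vapply(results, function(r)
    if (inherits(r, "maxent_fit")) r$kl else as.numeric(r), numeric(1))
  if (is.null(names(kl))) names(kl) <- seq_along(kl)
  list(pass = names(kl)[kl <= cutoff],
       flagged = names(kl)[kl > cutoff],
       kl = kl)
}
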