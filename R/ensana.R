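# Weighted-ensemble structural analytics: internal scaling profiles,
# homopolymer fits, scaled distance maps, contact maps and networks,
# gyration-tensor shape metrics, Debye-formula SAXS profiles, and the
# regression / concordance statistics used to relate sequence features to
# chain dimensions.

#' A weighted conformational ensemble
#'
#' @param coords Array `frames x sites x 3` of coordinates (nm), or a list
#'   of `sites x 3` matrices.
#' @param weights Per-frame weights (default uniform); normalized.
#' @param labels Optional per-residue labels (one-letter codes).
#' @param site_residue Integer vector mapping each site to a residue index
#'   (default 1:1, i.e. one bead per residue; several sites per residue
#'   enable closest-heavy contact analysis).
#' @return Object of class `conformational_ensemble`.
#' @export
conformational_ensemble <- function(coords, weights = NULL, labels = NULL,
                                    site_residue = NULL) {
  if (is.list(coords)) {
    nf <- length(coords)
    ns <- nrow(coords[[1]])
    arr <- array(NA_real_, c(nf, ns, 3))
    for (f in seq_len(nf)) arr[f, , ] <- coords[[f]]
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  nf <- dim(coords)[1]; ns <- dim(coords)[2]
  if (is.null(weights)) weights <- rep(1 / nf, nf)
  stopifnot(length(weights) == nf, all(weights >= 0))
  weights <- weights / sum(weights)
  if (is.null(site_residue)) site_residue <- seq_len(ns)
  structure(list(coords = coords, weights = weights, labels = labels,
                 site_residue = as.integer(site_residue),
                 n_residues = max(site_residue)),
            class = "conformational_ensemble")
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat(sprintf("<conformational_ensemble> %d frames x %d sites (%d residues)\n",
              dim(x$coords)[1], dim(x$coords)[2], x$n_residues))
  invisible(x)
}

ens_weights <- function(ens, weights) {
  w <- if (is.null(weights)) ens$weights else weights / sum(weights)
  stopifnot(length(w) == dim(ens$coords)[1])
  w
}

# weighted RMS inter-residue distance matrix: sqrt(E_w[r_ij^2]) over sites
# reduced to residues by taking the first site of each residue (the
# inner-average convention); for bead models sites == residues.
rms_distance_matrix <- function(ens, weights = NULL) {
  w <- ens_weights(ens, weights)
  first_site <- match(seq_len(ens$n_residues), ens$site_residue)
  fl <- frames_flat(ens$coords[, first_site, , drop = FALSE])
  sqrt(ens_mean_sq_dist(fl, w))
}

#' Internal scaling profile with homopolymer fit
#'
#' For each sequence separation \eqn{s = |i - j|}, the profile is the mean
#' over all residue pairs at that separation of the weighted RMS distance
#' \eqn{\langle r_{ij}^2 \rangle^{1/2}} (inner average over conformations,
#' outer average over pairs). The standard homopolymer relationship
#' \eqn{\langle R_{i,j} \rangle = A_0 |i-j|^\nu} is then fit by nonlinear
#' least squares over the configured window to extract the prefactor
#' \eqn{A_0} (persistence-length scale) and the apparent scaling exponent
#' \eqn{\nu}.
#'
#' @param ens A [conformational_ensemble()].
#' @param weights Optional posterior weights (e.g. from [maxent()]).
#' @param window Separation window `c(min, max)` for the fit; default
#'   `c(5, N - 5)`.
#' @return Object of class `internal_scaling`: `separation`, `R_mean`
#'   (nm), `A0`, `nu`, `window`.
#' @export
internal_scaling <- function(ens, weights = NULL, window = NULL) {
  dm <- rms_distance_matrix(ens, weights)
  n <- nrow(dm)
  seps <- seq_len(n - 1)
  prof <- vapply(seps, function(s) {
    i <- seq_len(n - s)
    mean(dm[cbind(i, i + s)])
  }, numeric(1))
  if (is.null(window)) window <- c(5, max(6, n - 5))
  sel <- seps >= window[1] & seps <= window[2]
  if (sum(sel) < 3) stop("fewer than 3 separations in fit window")
  df <- data.frame(s = seps[sel], R = prof[sel])
  ll <- lm(log(R) ~ log(s), data = df)
  fit <- minpack.lm::nlsLM(R ~ A0 * s^nu, data = df,
                           start = list(A0 = unname(exp(coef(ll)[1])),
                                        nu = unname(coef(ll)[2])))
  structure(list(separation = seps, R_mean = prof,
                 A0 = unname(coef(fit)["A0"]), nu = unname(coef(fit)["nu"]),
                 window = window),
            class = "internal_scaling")
}

#' @export
print.internal_scaling <- function(x, ...) {
  cat(sprintf(
    "<internal_scaling> separations 1..%d; fit |i-j| in [%g, %g]: A0 = %.4f nm, nu = %.4f\n",
    max(x$separation), x$window[1], x$window[2], x$A0, x$nu))
  invisible(x)
}

#' @export
coef.internal_scaling <- function(object, ...)
  c(A0 = object$A0, nu = object$nu)

#' @export
plot.internal_scaling <- function(x, ...) {
  plot(x$separation, x$R_mean, xlab = "|i - j|", ylab = "<R> (nm)",
       pch = 16, cex = 0.6, ...)
  curve(x$A0 * t^x$nu, xname = "t", add = TRUE, lty = 2, col = "grey40")
  invisible(x)
}

#' Scaled inter-residue distance map
#'
#' Each entry is the weighted RMS distance between residues i and j
#' divided by the best-fit homopolymer prediction \eqn{A_0 |i-j|^\nu};
#' values below 1 mark local compaction, above 1 local expansion.
#' Pairs closer in sequence than `min_spacing` are masked (`NA`).
#'
#' @param ens A [conformational_ensemble()].
#' @param weights Optional posterior weights.
#' @param fit An [internal_scaling()] fit (computed if `NULL`).
#' @param min_spacing Minimum sequence separation retained.
#' @return Symmetric matrix of class `scaled_distance_map`.
#' @export
scaled_distance_map <- function(ens, weights = NULL, fit = NULL,
                                min_spacing = 10) {
  if (is.null(fit)) fit <- internal_scaling(ens, weights)
  if (!inherits(fit, "internal_scaling")) stop("fit must be internal_scaling")
  dm <- rms_distance_matrix(ens, weights)
  n <- nrow(dm)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  ref <- fit$A0 * sep^fit$nu
  out <- dm / ref
  out[sep < min_spacing] <- NA_real_
  class(out) <- c("scaled_distance_map", class(out))
  out
}

#' Weighted contact probability map
#'
#' Probability (weighted fraction of frames) that two residues are in
#' contact, i.e. that the minimal distance between their sites is below
#' the threshold. With one site per residue (`mode = "bead"`) this is the
#' bead distance; with several sites per residue (`mode =
#' "closest-heavy"`) the closest-heavy-atom convention.
#'
#' @param ens A [conformational_ensemble()].
#' @param weights Optional posterior weights.
#' @param threshold Contact distance (nm); default 1.0 (10 Angstrom).
#' @param mode `"bead"` or `"closest-heavy"`; must match the ensemble's
#'   site-to-residue mapping.
#' @return Symmetric matrix of contact probabilities in `[0, 1]`.
#' @export
contact_map <- function(ens, weights = NULL, threshold = 1.0,
                        mode = c("bead", "closest-heavy")) {
  mode <- match.arg(mode)
  if (mode == "bead" && any(duplicated(ens$site_residue)))
    stop("bead mode requires one site per residue")
  w <- ens_weights(ens, weights)
  ens_contact_prob(frames_flat(ens$coords), ens$site_residue,
                   ens$n_residues, threshold, w)
}

RESIDUE_CLASSES <- list(
  Gly = "G", polar = c("S", "T", "N", "Q"), basic = c("R", "K", "H"),
  acidic = c("D", "E"), aromatic = c("F", "W", "Y"),
  aliphatic = c("M", "V", "I", "L", "A"), Pro = "P", Cys = "C")

residue_class <- function(labels) {
  out <- rep(NA_character_, length(labels))
  for (cl in names(RESIDUE_CLASSES))
    out[labels %in% RESIDUE_CLASSES[[cl]]] <- cl
  out
}

#' Contact network from a contact map
#'
#' Residues become nodes sized by their mean contact probability with all
#' residues more than two positions away in sequence; edges connect pairs
#' whose contact probability is at least `edge_fraction` of the maximum
#' contact probability in the map (near-diagonal pairs excluded).
#'
#' @param cmap Contact probability matrix from [contact_map()].
#' @param edge_fraction Fraction of the per-chain maximum contact
#'   probability required for an edge (default 0.35).
#' @param labels Optional residue one-letter codes, stored as node class
#'   metadata (Gly / polar / basic / acidic / aromatic / aliphatic / Pro /
#'   Cys).
#' @param min_separation Near-diagonal exclusion: pairs with
#'   `|i - j| <=` this are ignored (default 2).
#' @return An `igraph` graph with vertex attributes `size` (mean contact
#'   probability) and `class`, edge attribute `weight` (contact
#'   probability).
#' @export
contact_network <- function(cmap, edge_fraction = 0.35, labels = NULL,
                            min_separation = 2) {
  n <- nrow(cmap)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  m <- cmap
  m[sep <= min_separation] <- NA_real_
  node_size <- rowMeans(m, na.rm = TRUE)
  node_size[!is.finite(node_size)] <- 0
  thr <- edge_fraction * max(m, na.rm = TRUE)
  adj <- !is.na(m) & m >= thr
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  ij <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ij))
    g <- igraph::add_edges(g, t(ij), weight = m[ij])
  igraph::V(g)$size <- node_size
  igraph::V(g)$name <- as.character(seq_len(n))
  if (!is.null(labels)) {
    igraph::V(g)$residue <- labels
    igraph::V(g)$class <- residue_class(labels)
  }
  g
}

#' Ensemble shape metrics
#'
#' Per-frame gyration tensor eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge
#' \lambda_3} give \eqn{R_g = \sqrt{\lambda_1 + \lambda_2 + \lambda_3}}
#' and the asphericity \eqn{\delta = 1 - 3(\lambda_1\lambda_2 +
#' \lambda_2\lambda_3 + \lambda_3\lambda_1)/(\lambda_1 + \lambda_2 +
#' \lambda_3)^2} (0 for a sphere, 1 for a rod). Ensemble values are
#' weighted averages; `R` is the weighted RMS distance between the first
#' and last residue.
#'
#' @param ens A [conformational_ensemble()].
#' @param weights Optional posterior weights.
#' @return List: `Rg` (nm), `asphericity`, `R` (nm), and the per-frame
#'   vectors `Rg_frame`, `asph_frame`, `ree_frame`.
#' @export
shape_metrics <- function(ens, weights = NULL) {
  w <- ens_weights(ens, weights)
  nf <- dim(ens$coords)[1]
  rg <- asph <- ree <- numeric(nf)
  first_site <- match(seq_len(ens$n_residues), ens$site_residue)
  e1 <- first_site[1]; e2 <- first_site[length(first_site)]
  for (f in seq_len(nf)) {
    x <- ens$coords[f, , ]
    xc <- sweep(x, 2, colMeans(x))
    S <- crossprod(xc) / nrow(xc)
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    tr <- sum(ev)
    rg[f] <- sqrt(tr)
    asph[f] <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / tr^2
    ree[f] <- sqrt(sum((x[e1, ] - x[e2, ])^2))
  }
  list(Rg = sum(w * rg), asphericity = sum(w * asph),
       R = sqrt(sum(w * ree^2)),
       Rg_frame = rg, asph_frame = asph, ree_frame = ree)
}

#' Normalized SAXS profile by the Debye formula
#'
#' \eqn{I(q) = \langle \sum_{i,j} f_i f_j \,
#' \mathrm{sinc}(q r_{ij})\rangle_w}, returned normalized to the
#' simulation value at \eqn{q = 0} (so the profile starts at 1).
#'
#' @param ens A [conformational_ensemble()].
#' @param q q grid (1/nm); must be non-empty.
#' @param weights Optional posterior weights.
#' @param form_factors Per-site scattering factors (default 1 per bead).
#' @return `data.frame` with `q` and `I` (\eqn{I(q)/I(0)}).
#' @export
saxs_profile <- function(ens, q, weights = NULL, form_factors = NULL) {
  if (length(q) == 0) stop("empty q grid")
  w <- ens_weights(ens, weights)
  ns <- dim(ens$coords)[2]
  if (is.null(form_factors)) form_factors <- rep(1, ns)
  fl <- frames_flat(ens$coords)
  qq <- unique(sort(c(0, q)))
  I <- ens_debye_saxs(fl, form_factors, qq, w)
  I0 <- I[qq == 0]
  data.frame(q = q, I = I[match(q, qq)] / I0)
}

#' Radius of gyration from the Guinier region
#'
#' Fits \eqn{\ln I(q) = \ln I(0) - q^2 R_g^2 / 3} over the low-q region
#' where \eqn{q R_g \le} `qRg_max`.
#'
#' @param profile Output of [saxs_profile()].
#' @param qRg_max Guinier validity bound (default 1.0).
#' @return Estimated `Rg` (nm).
#' @export
guinier_rg <- function(profile, qRg_max = 1.0) {
  # iterate: initial fit on the lowest quarter, then restrict to q Rg <= bound
  sel <- profile$q <= quantile(profile$q, 0.25)
  for (it in 1:5) {
    fit <- lm(log(I) ~ I(q^2), data = profile[sel, ])
    rg <- sqrt(-3 * coef(fit)[2])
    sel_new <- profile$q * rg <= qRg_max
    if (sum(sel_new) < 3 || identical(sel_new, sel)) break
    sel <- sel_new
  }
  unname(rg)
}

#' Lin's concordance correlation coefficient
#'
#' \eqn{\rho_c = 2\,\mathrm{cov}(x, y) / (\sigma_x^2 + \sigma_y^2 +
#' (\bar x - \bar y)^2)}: combines correlation (precision) with deviation
#' from the identity line (accuracy).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  sx <- var(x) * (n - 1) / n
  sy <- var(y) * (n - 1) / n
  sxy <- cov(x, y) * (n - 1) / n
  2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
}

#' Regression suite over sequence-feature combinations
#'
#' Ordinary least squares of the response on every single, double, and
#' triple combination of the candidate features, reporting the
#' coefficient of determination \eqn{\rho^2} per combination, a
#' leave-one-out distribution of \eqn{\rho^2} for the best combinations,
#' and Lin's concordance \eqn{\rho_c} between fitted and observed values.
#'
#' @param features `data.frame` of candidate regressors (columns).
#' @param response Numeric response vector (e.g. mean transfer
#'   efficiencies).
#' @param max_order Largest combination size (default 3).
#' @param loo_top Number of top combinations for which leave-one-out
#'   distributions are computed.
#' @return Object of class `regression_suite`: `table` (combo, order,
#'   rho2, rho_c), `loo` (named list of leave-one-out rho2 vectors).
#' @export
regression_suite <- function(features, response, max_order = 3,
                             loo_top = 5) {
  stopifnot(nrow(features) == length(response))
  vars <- names(features)
  combos <- unlist(lapply(seq_len(min(max_order, length(vars))),
                          function(k) combn(vars, k, simplify = FALSE)),
                   recursive = FALSE)
  dat <- cbind(features, .y = response)
  rho2_of <- function(fit, y) 1 - sum(residuals(fit)^2) /
    sum((y - mean(y))^2)
  one <- function(cb) {
    fml <- stats::reformulate(cb, ".y")
    fit <- lm(fml, data = dat)
    c(rho2 = rho2_of(fit, dat$.y),
      rho_c = lin_ccc(fitted(fit), response))
  }
  res <- t(vapply(combos, one, c(rho2 = 0, rho_c = 0)))
  tab <- data.frame(combo = vapply(combos, paste, "", collapse = "+"),
                    order = lengths(combos),
                    rho2 = res[, "rho2"], rho_c = res[, "rho_c"],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$rho2), ]
  rownames(tab) <- NULL
  loo <- list()
  for (r in seq_len(min(loo_top, nrow(tab)))) {
    cb <- strsplit(tab$combo[r], "+", fixed = TRUE)[[1]]
    fml <- stats::reformulate(cb, ".y")
    loo[[tab$combo[r]]] <- vapply(seq_len(nrow(dat)), function(i) {
      fit <- lm(fml, data = dat[-i, ])
      rho2_of(fit, dat$.y[-i])
    }, numeric(1))
  }
  structure(list(table = tab, loo = loo), class = "regression_suite")
}

#' @export
print.regression_suite <- function(x, n = 10, ...) {
  cat("<regression_suite> top combinations by rho^2:\n")
  print(head(x$table, n), digits = 3)
  invisible(x)
}
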