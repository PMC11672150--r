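# Seeded generators for every input class of the pipeline: synthetic IDR
# sequences spanning hydrophobicity / charge-patterning space, weighted
# conformational ensembles with known end-to-end statistics, photon
# streams with known true transfer efficiency, and a miniature rotamer
# library. Each generator is deterministic under its seed and carries a
# truth attribute consumed by tests.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state, so generators are
#' deterministic without disturbing the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return Value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# neutral residue pool for generated IDRs: Trp excluded (dye quenching)
# and Cys reserved for labeling sites
NEUTRAL_POOL <- c("A", "F", "G", "H", "I", "L", "M", "N", "P", "Q",
                  "S", "T", "V", "Y")

#' Generate composition-constrained synthetic IDR sequences
#'
#' Builds random sequences of the requested length with prescribed
#' fraction of charged residues (FCR) and net charge per residue (NCPR);
#' when a kappa band is requested, charge positions are rearranged by
#' accept/reject swaps until the charge-patterning parameter falls in the
#' band. Feasibility is checked up front (e.g. a kappa target needs at
#' least two charges). Mirrors the study design of same-length IDR
#' panels with diverse composition.
#'
#' @param n Number of sequences.
#' @param length Residues per sequence (default 57).
#' @param fcr,ncpr Scalars or length-`n` vectors of targets (fractions).
#' @param kappa_band Optional `c(lo, hi)` target band for kappa.
#' @param neutral_weights Optional named sampling weights over the
#'   neutral residue pool.
#' @param overhangs Add the GSGSC / CTLGPR expression overhangs (masked
#'   for feature calculation).
#' @param seed Mandatory seed.
#' @return List of [sequence_record()]s; attribute `truth` holds the
#'   requested targets.
#' @export
gen_sequences <- function(n = 16, length = 57, fcr = 0.25, ncpr = 0,
                          kappa_band = NULL, neutral_weights = NULL,
                          overhangs = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  fcr <- rep_len(fcr, n); ncpr <- rep_len(ncpr, n)
  if (any(abs(ncpr) > fcr + 1e-12))
    stop("infeasible targets: |NCPR| cannot exceed FCR")
  pool <- NEUTRAL_POOL
  wts <- if (is.null(neutral_weights)) rep(1, length(pool)) else
    neutral_weights[pool]
  with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      npos <- round(length * (fcr[i] + ncpr[i]) / 2)
      nneg <- round(length * (fcr[i] - ncpr[i]) / 2)
      if (npos + nneg > length) stop("infeasible charge counts")
      if (!is.null(kappa_band) && npos + nneg < 2)
        stop("infeasible targets: kappa band requires >= 2 charged residues")
      chars <- c(sample(c("K", "R"), npos, replace = TRUE),
                 sample(c("D", "E"), nneg, replace = TRUE),
                 sample(pool, length - npos - nneg, replace = TRUE,
                        prob = wts))
      chars <- sample(chars)
      if (!is.null(kappa_band)) {
        rec <- sequence_record("tmp", paste(chars, collapse = ""))
        k <- kappa_patterning(rec)
        for (it in seq_len(20000)) {
          if (k >= kappa_band[1] && k <= kappa_band[2]) break
          sw <- sample.int(length, 2)
          cand <- chars
          cand[sw] <- cand[rev(sw)]
          k2 <- kappa_patterning(
            sequence_record("tmp", paste(cand, collapse = "")))
          # accept swaps moving kappa toward the band
          tgt <- mean(kappa_band)
          if (abs(k2 - tgt) < abs(k - tgt)) { chars <- cand; k <- k2 }
        }
        if (k < kappa_band[1] || k > kappa_band[2])
          stop("kappa band not reachable for this composition")
      }
      seq <- paste(chars, collapse = "")
      if (overhangs) seq <- paste0("GSGSC", seq, "CTLGPR")
      sequence_record(sprintf("synth%02d", i), seq,
                      mask_overhangs = overhangs)
    })
    attr(recs, "truth") <- list(fcr = fcr, ncpr = ncpr,
                                kappa_band = kappa_band, seed = seed)
    recs
  })
}

#' Analytic end-to-end density of a Gaussian chain
#'
#' \eqn{P(r) = 4\pi r^2 (3 / (2\pi R^2))^{3/2} \exp(-3 r^2 / (2 R^2))}
#' with \eqn{R^2 = \langle r^2 \rangle} the mean squared end-to-end
#' distance.
#'
#' @param r Distances (nm).
#' @param R Root-mean-squared end-to-end distance (nm).
#' @export
gaussian_chain_density <- function(r, R) {
  4 * pi * r^2 * (3 / (2 * pi * R^2))^1.5 * exp(-3 * r^2 / (2 * R^2))
}

#' Generate a conformational ensemble with known statistics
#'
#' Models: `"gaussian"` — ideal-chain frames with i.i.d. Gaussian bond
#' vectors of variance \eqn{b^2/3} per axis, so the exact mean squared
#' end-to-end distance is \eqn{(N-1) b^2}; `"rod"` — straight rods of
#' spacing `b` with a random orientation per frame.
#'
#' @param n_frames Number of frames.
#' @param n_residues Beads per chain (default 60).
#' @param b Bond length (nm); default 0.38 to match the CG model.
#' @param model `"gaussian"` or `"rod"`.
#' @param weights Optional per-frame weights.
#' @param seed Mandatory seed.
#' @return A [conformational_ensemble()]; attribute `truth` holds the
#'   generative `R2`, `b`, and model name.
#' @export
gen_ensemble <- function(n_frames, n_residues = 60, b = 0.38,
                         model = c("gaussian", "rod"), weights = NULL,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  model <- match.arg(model)
  arr <- with_seed(seed, {
    a <- array(0, c(n_frames, n_residues, 3))
    if (model == "gaussian") {
      for (f in seq_len(n_frames)) {
        steps <- matrix(rnorm((n_residues - 1) * 3, sd = b / sqrt(3)),
                        ncol = 3)
        a[f, , ] <- rbind(0, apply(steps, 2, cumsum))
      }
    } else {
      for (f in seq_len(n_frames)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        a[f, , ] <- outer((seq_len(n_residues) - 1) * b, u)
      }
    }
    a
  })
  ens <- conformational_ensemble(arr, weights = weights)
  attr(ens, "truth") <- list(
    R2 = if (model == "gaussian") (n_residues - 1) * b^2 else
      ((n_residues - 1) * b)^2,
    b = b, model = model, seed = seed)
  ens
}

#' Generate a photon stream with known ground truth
#'
#' Bursts are planted as clusters of exponentially spaced photons
#' separated by long gaps. Within each burst, donor-excitation photons
#' are assigned to the acceptor channel with probability
#' \eqn{E_{true} + (1 - E_{true})\,ct} (transfer plus spectral crosstalk
#' misassignment); acceptor-excitation photons probe the acceptor
#' directly, and direct-excitation counts leak into the donor-excitation
#' acceptor channel. Uniform background photons are added per channel.
#' The attribute `truth` carries the generative values and the exactly
#' matching [fret_corrections()] (crosstalk coefficient
#' \eqn{ct/(1-ct)}, gamma \eqn{1/(1-ct)}).
#'
#' @param n_bursts Number of planted bursts.
#' @param E_true True transfer efficiency.
#' @param brightness Mean photons per burst in the donor-excitation
#'   period (Poisson).
#' @param f_aex Acceptor-excitation photon yield relative to brightness.
#' @param crosstalk Channel-misassignment probability for donor photons.
#' @param direct_exc Direct-excitation leak fraction.
#' @param bg_khz Background rate (kHz) applied to each of the three
#'   channels (Dex/D, Dex/A, Aex/A).
#' @param interphoton_us Mean interphoton time within bursts
#'   (microseconds).
#' @param gap_ms Mean gap between bursts (milliseconds).
#' @param seed Mandatory seed.
#' @return A [photon_stream()] with attribute `truth`.
#' @export
gen_photons <- function(n_bursts, E_true, brightness = 100, f_aex = 0.6,
                        crosstalk = 0, direct_exc = 0, bg_khz = 0,
                        interphoton_us = 10, gap_ms = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  with_seed(seed, {
    ticks_per_us <- 1e6 / TICK_PS
    t <- 0
    acc_t <- vector("list", n_bursts)
    acc_c <- vector("list", n_bursts)
    acc_p <- vector("list", n_bursts)
    for (b in seq_len(n_bursts)) {
      # floor on the inter-burst gap keeps planted bursts separable
      t <- t + (gap_ms * 500 + rexp(1, 2 / (gap_ms * 1000))) * ticks_per_us
      n_dex <- rpois(1, brightness)
      n_aex <- rpois(1, brightness * f_aex)
      n_dir <- rpois(1, direct_exc * n_aex)
      ntot <- n_dex + n_aex + n_dir
      if (ntot == 0) next
      gaps <- rexp(ntot, 1 / (interphoton_us * ticks_per_us))
      tt <- t + cumsum(gaps)
      t <- tt[ntot]
      p_acc <- E_true + (1 - E_true) * crosstalk
      kind <- sample(rep(c("dex", "aex", "dir"),
                         c(n_dex, n_aex, n_dir)))
      ch <- ifelse(kind == "dex",
                   ifelse(runif(ntot) < p_acc, "A", "D"), "A")
      pe <- ifelse(kind == "aex", "Aex", "Dex")
      acc_t[[b]] <- tt; acc_c[[b]] <- ch; acc_p[[b]] <- pe
    }
    times <- unlist(acc_t); chan <- unlist(acc_c); per <- unlist(acc_p)
    if (is.null(times)) times <- numeric(0)
    if (is.null(chan)) chan <- character(0)
    if (is.null(per)) per <- character(0)
    if (bg_khz > 0 && t > 0) {
      span <- t
      for (cfg in list(c("D", "Dex"), c("A", "Dex"), c("A", "Aex"))) {
        nb <- rpois(1, bg_khz * 1e3 * span * TICK_PS * 1e-12)
        if (nb > 0) {
          times <- c(times, runif(nb, 0, span))
          chan <- c(chan, rep(cfg[1], nb))
          per <- c(per, rep(cfg[2], nb))
        }
      }
    }
    ord <- order(times)
    stream <- photon_stream(round(times[ord]), chan[ord], per[ord])
    attr(stream, "truth") <- list(
      E_true = E_true, n_bursts = n_bursts, crosstalk = crosstalk,
      direct_exc = direct_exc, bg_khz = bg_khz, seed = seed,
      corrections = fret_corrections(
        bg_DexD = bg_khz, bg_DexA = bg_khz, bg_AexA = bg_khz,
        crosstalk = crosstalk / (1 - crosstalk),
        direct_exc = direct_exc, gamma = 1 / (1 - crosstalk)))
    stream
  })
}

#' Generate a miniature synthetic rotamer library
#'
#' Small random dye rotamers (bent atom chains extending along the
#' attachment axis) for testing dye attachment; this is a synthetic
#' stand-in, not a measured rotamer set. The last atom of each rotamer is
#' the dye center.
#'
#' @param dyes Dye names.
#' @param n_rotamers Rotamers per dye.
#' @param n_atoms Atoms per rotamer.
#' @param extent Approximate dye length (nm).
#' @param seed Mandatory seed.
#' @return Named list per dye: `rotamers` (list of atom matrices, local
#'   frame with the anchor at the origin and the attachment axis +z) and
#'   `center` (atom index).
#' @export
gen_rotamer_library <- function(dyes = c("A488", "A594"), n_rotamers = 8,
                                n_atoms = 4, extent = 0.8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  with_seed(seed, {
    out <- lapply(dyes, function(d) {
      rotamers <- lapply(seq_len(n_rotamers), function(r) {
        z <- seq(extent / n_atoms, extent, length.out = n_atoms)
        jit <- matrix(rnorm(n_atoms * 2, sd = 0.12), ncol = 2)
        cbind(jit[, 1], jit[, 2], z)
      })
      list(rotamers = rotamers, center = n_atoms)
    })
    names(out) <- dyes
    out
  })
}

#' Truth attribute of a generated object
#'
#' @param x Object produced by a generator in this package.
#' @return The `truth` attribute (list), or `NULL`.
#' @export
generator_truth <- function(x) attr(x, "truth")

#' Write a generator truth sidecar as JSON
#'
#' @param x Generated object carrying a `truth` attribute.
#' @param path Output JSON path.
#' @export
write_truth_sidecar <- function(x, path) {
  tr <- generator_truth(x)
  if (is.null(tr)) stop("object carries no truth attribute")
  tr <- lapply(tr, function(v) if (inherits(v, "fret_corrections"))
    unclass(v) else v)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
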