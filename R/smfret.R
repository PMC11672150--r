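# Photon-level single-molecule FRET burst analysis under pulsed
# interleaved excitation: burst search on interphoton times, dual-channel
# filtering, count corrections, stoichiometry / transfer-efficiency
# scoring, and Gaussian peak fitting of efficiency histograms.

TICK_PS <- 16  # timing resolution of the photon records, ps per tick

#' Photon stream record table
#'
#' @param time_tick Integer arrival times in ticks (16 ps resolution);
#'   must be non-decreasing.
#' @param channel Detection channel, `"D"` (donor emission) or `"A"`
#'   (acceptor emission).
#' @param period Excitation period under pulsed interleaving, `"Dex"`
#'   (donor excitation) or `"Aex"` (acceptor excitation).
#' @return `data.frame` of class `photon_stream`.
#' @export
photon_stream <- function(time_tick, channel, period) {
  channel <- as.character(channel); period <- as.character(period)
  stopifnot(all(channel %in% c("D", "A")), all(period %in% c("Dex", "Aex")))
  if (is.unsorted(time_tick)) stop("photon times must be non-decreasing")
  structure(data.frame(time_tick = as.numeric(time_tick),
                       channel = channel, period = period,
                       stringsAsFactors = FALSE),
            class = c("photon_stream", "data.frame"))
}

#' Read / write a photon stream as TSV
#'
#' Columns `time_tick`, `channel`, `period`.
#' @param path File path.
#' @export
read_photon_stream <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  photon_stream(d$time_tick, d$channel, d$period)
}

#' @rdname read_photon_stream
#' @param stream A [photon_stream()].
#' @export
write_photon_stream <- function(stream, path) {
  write.table(stream, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# maximal runs of photons with successive gaps strictly below the
# threshold; returns start/end indices of runs meeting the count minimum
photon_runs <- function(times, max_gap_ticks, min_photons) {
  n <- length(times)
  if (n == 0) return(data.frame(first = integer(), last = integer()))
  brk <- which(diff(times) >= max_gap_ticks)
  first <- c(1L, brk + 1L)
  last <- c(brk, n)
  keep <- (last - first + 1L) >= min_photons
  data.frame(first = first[keep], last = last[keep])
}

#' Burst search on interphoton times
#'
#' Identifies photon bursts as maximal contiguous intervals of emission in
#' which successive interphoton times stay below `max_interphoton_us`;
#' runs with at least `min_photons` photons are kept. Counts per
#' (channel, period) are tabulated for each burst.
#'
#' @param stream A [photon_stream()].
#' @param max_interphoton_us Interphoton time threshold (microseconds).
#' @param min_photons Minimum photons per burst.
#' @return `data.frame` of class `burst_table`: start/stop ticks, total
#'   photon count `n`, and raw counts `DexD`, `DexA`, `AexD`, `AexA`.
#' @export
find_bursts <- function(stream, max_interphoton_us = 150,
                        min_photons = 50) {
  gap_ticks <- max_interphoton_us * 1e6 / TICK_PS
  empty <- data.frame(start = numeric(), stop = numeric(),
                      first = integer(), last = integer(), n = integer(),
                      DexD = integer(), DexA = integer(),
                      AexD = integer(), AexA = integer())
  times <- stream$time_tick
  n <- length(times)
  if (n == 0)
    return(structure(empty, class = c("burst_table", "data.frame")))
  run_id <- cumsum(c(1, diff(times) >= gap_ticks))
  sizes <- tabulate(run_id)
  keep <- which(sizes >= min_photons)
  if (!length(keep))
    return(structure(empty, class = c("burst_table", "data.frame")))
  firsts <- which(!duplicated(run_id))
  lasts <- c(firsts[-1] - 1L, n)
  pc <- paste0(stream$period, stream$channel)
  counts <- function(tag) {
    v <- integer(max(run_id))
    t <- tapply(pc == tag, run_id, sum)
    v[as.integer(names(t))] <- as.integer(t)
    v
  }
  DexD <- counts("DexD"); DexA <- counts("DexA")
  AexD <- counts("AexD"); AexA <- counts("AexA")
  res <- data.frame(start = times[firsts[keep]], stop = times[lasts[keep]],
                    first = firsts[keep], last = lasts[keep],
                    n = sizes[keep],
                    DexD = DexD[keep], DexA = DexA[keep],
                    AexD = AexD[keep], AexA = AexA[keep])
  structure(res, class = c("burst_table", "data.frame"))
}

#' Dual-channel burst filter
#'
#' A burst is retained only if it independently satisfies the burst
#' criterion in the photons of the donor-excitation period and in those
#' of the acceptor-excitation period: in each period the burst's photons
#' must number at least the per-period minimum, have no internal gap
#' reaching the per-period interphoton threshold, and start/end within
#' that threshold of the burst boundaries (which rejects bursts whose
#' acceptor dies mid-burst through bleaching or blinking). The per-period
#' threshold defaults to 300 us, looser than the burst-search threshold
#' because each period sees only a thinned subset of the burst's photons.
#'
#' @param bursts A [find_bursts()] table.
#' @param stream The originating [photon_stream()].
#' @param min_photons_dex,min_photons_aex Per-period photon minima.
#' @param max_interphoton_us Per-period interphoton threshold
#'   (microseconds).
#' @return Filtered `burst_table`.
#' @export
dual_channel_filter <- function(bursts, stream, min_photons_dex = 25,
                                min_photons_aex = 10,
                                max_interphoton_us = 300) {
  gap_ticks <- max_interphoton_us * 1e6 / TICK_PS
  ok <- vapply(seq_len(nrow(bursts)), function(b) {
    idx <- bursts$first[b]:bursts$last[b]
    t <- stream$time_tick[idx]; pe <- stream$period[idx]
    per_ok <- function(period, minp) {
      tp <- t[pe == period]
      if (length(tp) < minp) return(FALSE)
      # pad with burst boundaries so early/late absence counts as a gap
      all(diff(c(t[1], tp, t[length(t)])) < gap_ticks)
    }
    per_ok("Dex", min_photons_dex) && per_ok("Aex", min_photons_aex)
  }, logical(1))
  bursts[ok, , drop = FALSE]
}

#' Correction set for burst counts
#'
#' @param bg_DexD,bg_DexA,bg_AexA Background rates (kHz) in the
#'   donor-excitation donor channel, donor-excitation acceptor channel,
#'   and acceptor-excitation acceptor channel.
#' @param crosstalk Spectral crosstalk coefficient: acceptor-channel
#'   counts per corrected donor count.
#' @param direct_exc Direct acceptor excitation coefficient: spurious
#'   acceptor counts in the donor-excitation period per corrected
#'   acceptor-excitation count.
#' @param gamma Detection-efficiency / quantum-yield ratio applied to the
#'   donor counts.
#' @return List of class `fret_corrections`.
#' @export
fret_corrections <- function(bg_DexD = 0, bg_DexA = 0, bg_AexA = 0,
                             crosstalk = 0, direct_exc = 0, gamma = 1) {
  stopifnot(gamma > 0, crosstalk >= 0, direct_exc >= 0,
            bg_DexD >= 0, bg_DexA >= 0, bg_AexA >= 0)
  structure(list(bg_DexD = bg_DexD, bg_DexA = bg_DexA, bg_AexA = bg_AexA,
                 crosstalk = crosstalk, direct_exc = direct_exc,
                 gamma = gamma),
            class = "fret_corrections")
}

#' Read a correction set from YAML
#' @param path YAML file with any of the [fret_corrections()] fields.
#' @export
read_corrections <- function(path) {
  do.call(fret_corrections, yaml::read_yaml(path))
}

#' Correct burst counts and score E and S
#'
#' Correction order: background subtraction (rates times burst duration),
#' then crosstalk and direct-excitation removal, then the gamma factor on
#' the donor counts. The stoichiometry
#' \eqn{S = n_{tot,Dex} / (n_{tot,Dex} + n_{tot,Aex})} is computed from
#' the corrected totals, and the transfer efficiency
#' \eqn{E = n_A / (n_A + n_D)} from the corrected (gamma-scaled) counts.
#' Bursts outside \eqn{0.2 < S < 0.8} (strict) are flagged `excluded`;
#' bursts whose corrected denominators are non-positive are flagged
#' `invalid` rather than dropped.
#'
#' @param bursts A burst table.
#' @param corrections A [fret_corrections()] (identity by default).
#' @param s_range Open stoichiometry acceptance interval.
#' @return The burst table with columns `nD`, `nA`, `nTotDex`, `nTotAex`,
#'   `E`, `S`, `excluded`, `invalid` added.
#' @export
correct_and_score <- function(bursts, corrections = fret_corrections(),
                              s_range = c(0.2, 0.8)) {
  co <- corrections
  dur_ms <- (bursts$stop - bursts$start) * TICK_PS * 1e-9  # ticks -> ms
  bgDD <- co$bg_DexD * dur_ms; bgDA <- co$bg_DexA * dur_ms
  bgAA <- co$bg_AexA * dur_ms
  nD <- bursts$DexD - bgDD
  nAex <- bursts$AexA - bgAA
  nA <- bursts$DexA - bgDA - co$crosstalk * nD - co$direct_exc * nAex
  nD <- co$gamma * nD
  nTotDex <- nD + nA
  nTotAex <- nAex
  invalid <- (nTotDex + nTotAex) <= 0 | nTotDex <= 0
  S <- ifelse(invalid, NA_real_, nTotDex / (nTotDex + nTotAex))
  E <- ifelse(invalid, NA_real_, nA / (nA + nD))
  E <- pmin(pmax(E, 0), 1)
  excluded <- is.na(S) | S <= s_range[1] | S >= s_range[2]
  cbind(bursts, data.frame(nD = nD, nA = nA, nTotDex = nTotDex,
                           nTotAex = nTotAex, E = E, S = S,
                           excluded = excluded, invalid = invalid))
}

#' Full burst pipeline
#'
#' Burst search, dual-channel filter, correction and scoring in one call.
#'
#' @inheritParams find_bursts
#' @inheritParams correct_and_score
#' @param dual_channel Apply [dual_channel_filter()]?
#' @param ... Passed to [dual_channel_filter()].
#' @return Scored burst table.
#' @export
burst_pipeline <- function(stream, corrections = fret_corrections(),
                           max_interphoton_us = 150, min_photons = 50,
                           dual_channel = TRUE, ...) {
  b <- find_bursts(stream, max_interphoton_us, min_photons)
  if (dual_channel && nrow(b))
    b <- dual_channel_filter(b, stream, ...)
  correct_and_score(b, corrections)
}

#' Gaussian peak fit of a transfer-efficiency histogram
#'
#' Histograms the burst efficiencies on fixed bins and fits a sum of
#' `n_peaks` Gaussians to the counts by nonlinear least squares, seeded
#' from the highest histogram modes.
#'
#' @param E Burst transfer efficiencies (>= 100 values recommended).
#' @param n_peaks Number of Gaussian components.
#' @param bin_width Histogram bin width on the efficiency axis.
#' @param range Histogram range.
#' @return Object of class `fret_hist_fit`: `peaks` (data.frame `mean`,
#'   `sd`, `amplitude`, ordered by mean), `histogram` (mids, counts),
#'   `converged`.
#' @export
fit_histogram <- function(E, n_peaks = 1, bin_width = 0.02,
                          range = c(-0.1, 1.1)) {
  E <- E[is.finite(E)]
  breaks <- seq(range[1], range[2], by = bin_width)
  E <- E[E >= range[1] & E <= range[2]]
  h <- hist(E, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  # seed means from separated local maxima
  ord <- order(-df$y)
  seeds <- numeric(0)
  for (i in ord) {
    if (length(seeds) >= n_peaks) break
    if (!length(seeds) || all(abs(df$x[i] - seeds) > 5 * bin_width))
      seeds <- c(seeds, df$x[i])
  }
  while (length(seeds) < n_peaks)
    seeds <- c(seeds, mean(range))
  seeds <- sort(seeds)
  start <- list()
  fml_terms <- character(n_peaks)
  for (p in seq_len(n_peaks)) {
    start[[paste0("A", p)]] <- max(df$y) * 0.9
    start[[paste0("m", p)]] <- seeds[p]
    start[[paste0("s", p)]] <- max(sd(E) / n_peaks, 2 * bin_width)
    fml_terms[p] <- sprintf("A%d * exp(-(x - m%d)^2 / (2 * s%d^2))", p, p, p)
  }
  fml <- stats::as.formula(paste("y ~", paste(fml_terms, collapse = " + ")))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(peaks = NULL, histogram = df, converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "fret_hist_fit"))
  }
  cf <- coef(fit)
  peaks <- data.frame(
    mean = cf[paste0("m", seq_len(n_peaks))],
    sd = abs(cf[paste0("s", seq_len(n_peaks))]),
    amplitude = cf[paste0("A", seq_len(n_peaks))])
  peaks <- peaks[order(peaks$mean), ]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, histogram = df, converged = TRUE,
                 fit = fit), class = "fret_hist_fit")
}

#' @export
print.fret_hist_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fret_hist_fit> fit did not converge:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat("<fret_hist_fit> Gaussian peak fit\n")
  print(x$peaks, digits = 4)
  invisible(x)
}

#' @export
plot.fret_hist_fit <- function(x, ...) {
  with(x$histogram, plot(x, y, type = "h", xlab = "E", ylab = "bursts", ...))
  if (x$converged) {
    xs <- seq(min(x$histogram$x), max(x$histogram$x), length.out = 400)
    ys <- rowSums(sapply(seq_len(nrow(x$peaks)), function(p)
      x$peaks$amplitude[p] *
        exp(-(xs - x$peaks$mean[p])^2 / (2 * x$peaks$sd[p]^2))))
    lines(xs, ys, col = "red3")
  }
  invisible(x)
}
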