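#' @useDynLib idrscope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cov fitted lm median nls optim predict quantile
#'   rbinom residuals rexp rnorm rpois runif sd setNames uniroot var
#'   weighted.mean
#' @importFrom utils combn head read.csv read.delim tail write.csv
#'   write.table
#' @importFrom graphics abline curve hist lines plot
"_PACKAGE"

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte-Doolittle hydropathy indices, range [-4.5, 4.5]
KD_SCALE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Side-chain charges at neutral pH; His treated as neutral, termini uncharged
AA_CHARGE <- setNames(numeric(20), AA1)
AA_CHARGE[c("D", "E")] <- -1
AA_CHARGE[c("K", "R")] <- +1

AA_GROUPS <- list(
  aromatic  = c("F", "W", "Y"),
  aliphatic = c("A", "I", "L", "M", "V"),
  polar     = c("N", "Q", "S", "T"),
  KR        = c("K", "R"),
  DE        = c("D", "E")
)

#' Create a sequence record
#'
#' A `sequence_record` couples an identifier with a one-letter amino-acid
#' string and an optional logical mask marking residues excluded from
#' feature calculation (e.g. cloning overhangs flanking the region of
#' interest).
#'
#' @param id Character identifier.
#' @param seq One-letter amino-acid string (20 canonical residues).
#' @param mask Optional logical vector, `TRUE` for residues to exclude.
#'   Defaults to all `FALSE`.
#' @param mask_overhangs If `TRUE`, mask a leading `GSGSC` and trailing
#'   `CTLGPR` overhang when present (the expression-tag remnants flanking
#'   the labeled constructs).
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, seq, mask = NULL, mask_overhangs = FALSE) {
  seq <- toupper(gsub("\\s", "", seq))
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("mask length must equal sequence length")
  if (mask_overhangs) {
    if (startsWith(seq, "GSGSC")) mask[1:5] <- TRUE
    if (endsWith(seq, "CTLGPR")) mask[(n - 5):n] <- TRUE
  }
  structure(list(id = as.character(id), seq = seq, chars = chars,
                 mask = mask),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d aa, %d masked)\n",
              x$id, length(x$chars), sum(x$mask)))
  cat(" ", x$seq, "\n")
  invisible(x)
}

as_sequence_record <- function(x, ...) {
  if (inherits(x, "sequence_record")) return(x)
  sequence_record("seq", as.character(x), ...)
}

# unmasked residue characters, validated against the canonical alphabet
active_residues <- function(rec) {
  rec <- as_sequence_record(rec)
  chars <- rec$chars[!rec$mask]
  if (length(chars) == 0L)
    stop("sequence '", rec$id, "' is empty after masking")
  bad <- which(!(chars %in% AA1))
  if (length(bad))
    stop("non-canonical residue '", chars[bad[1]], "' at unmasked position ",
         which(!rec$mask)[bad[1]], " in '", rec$id, "'")
  chars
}

#' Normalized Kyte-Doolittle hydrophobicity
#'
#' Mean Kyte-Doolittle index over unmasked residues, rescaled from
#' \eqn{[-4.5, 4.5]} to \eqn{[0, 1]}:
#' \eqn{H = (1/N)\sum_i (KD_i + 4.5)/9}.
#'
#' @param rec A [sequence_record()] or plain string.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
normalized_hydrophobicity <- function(rec) {
  chars <- active_residues(rec)
  mean((KD_SCALE[chars] + 4.5) / 9)
}

#' Fraction of charged residues and net charge per residue
#'
#' With \eqn{f_+} and \eqn{f_-} the fractions of positively (K, R) and
#' negatively (D, E) charged residues, returns
#' \eqn{FCR = f_+ + f_-} and \eqn{NCPR = f_+ - f_-}.
#' Histidine is treated as neutral and termini are uncharged.
#'
#' @inheritParams normalized_hydrophobicity
#' @return Named numeric vector `c(FCR=, NCPR=)`.
#' @export
charge_fractions <- function(rec) {
  q <- AA_CHARGE[active_residues(rec)]
  fp <- mean(q > 0)
  fm <- mean(q < 0)
  c(FCR = fp + fm, NCPR = fp - fm)
}

# charge vector (+1/-1/0) of the unmasked sequence
charge_vector <- function(rec) unname(AA_CHARGE[active_residues(rec)])

# blob-averaged squared deviation of local charge asymmetry for one window g
delta_blob <- function(q, g) {
  n <- length(q)
  if (n < g) return(NA_real_)
  fp <- mean(q > 0); fm <- mean(q < 0)
  sig_glob <- if (fp + fm > 0) (fp - fm)^2 / (fp + fm) else 0
  nb <- n - g + 1L
  sig <- numeric(nb)
  for (i in seq_len(nb)) {
    w <- q[i:(i + g - 1L)]
    wp <- mean(w > 0); wm <- mean(w < 0)
    sig[i] <- if (wp + wm > 0) (wp - wm)^2 / (wp + wm) else 0
  }
  mean((sig - sig_glob)^2)
}

# most charge-segregated arrangement of the same composition:
# all positives, then neutrals, then all negatives
segregated_arrangement <- function(q) {
  c(rep(1, sum(q > 0)), rep(0, sum(q == 0)), rep(-1, sum(q < 0)))
}

#' Charge patterning parameter kappa
#'
#' Das-Pappu blob-based measure of charge segregation: the mean squared
#' deviation of the local charge asymmetry
#' \eqn{\sigma = (f_+ - f_-)^2/(f_+ + f_-)} in sliding blobs of 5 and 6
#' residues from its global value, normalized by the same quantity for the
#' most segregated arrangement of identical composition (all positive
#' charges, then neutrals, then all negative charges), and averaged over
#' the two blob sizes. Fully overlapping windows (step 1) are used, so
#' terminal residues enter fewer blobs than interior ones.
#'
#' @inheritParams normalized_hydrophobicity
#' @return Scalar in \eqn{[0, 1]}, or `NA` if the sequence carries fewer
#'   than two charged residues.
#' @export
kappa_patterning <- function(rec) {
  q <- charge_vector(rec)
  if (sum(q != 0) < 2L) return(NA_real_)
  qmax <- segregated_arrangement(q)
  ks <- vapply(c(5L, 6L), function(g) {
    dmax <- delta_blob(qmax, g)
    if (!is.finite(dmax) || dmax == 0) return(NA_real_)
    delta_blob(q, g) / dmax
  }, numeric(1))
  mean(ks, na.rm = TRUE)
}

#' Sequence charge decoration (SCD)
#'
#' \eqn{SCD = (1/N) \sum_{i<j} q_i q_j \sqrt{j - i}}, a signed
#' charge-patterning statistic; blocky arrangements of opposite charges
#' give strongly negative values.
#'
#' @inheritParams normalized_hydrophobicity
#' @return Signed scalar.
#' @export
scd <- function(rec) {
  q <- charge_vector(rec)
  n <- length(q)
  idx <- which(q != 0)
  if (length(idx) < 2L) return(0)
  tot <- 0
  for (a in seq_len(length(idx) - 1L)) {
    i <- idx[a]
    j <- idx[(a + 1L):length(idx)]
    tot <- tot + sum(q[i] * q[j] * sqrt(j - i))
  }
  tot / n
}

#' Per-residue and group composition fractions
#'
#' Fractions of each of the 20 amino-acid types over unmasked residues,
#' plus grouped fractions (aromatic F/W/Y; aliphatic A/I/L/M/V; polar
#' N/Q/S/T; K+R; D+E).
#'
#' @inheritParams normalized_hydrophobicity
#' @return Named numeric vector (`f_A` ... `f_Y`, then group fractions).
#' @export
composition_features <- function(rec) {
  chars <- active_residues(rec)
  f <- vapply(AA1, function(a) mean(chars == a), numeric(1))
  names(f) <- paste0("f_", AA1)
  g <- vapply(AA_GROUPS, function(set) sum(f[paste0("f_", set)]), numeric(1))
  names(g) <- paste0("f_", names(AA_GROUPS))
  c(f, g)
}

#' All sequence descriptors for one record
#'
#' @inheritParams normalized_hydrophobicity
#' @return Named list with `N`, `H`, `FCR`, `NCPR`, `kappa`, `SCD` and the
#'   composition fractions.
#' @export
sequence_features <- function(rec) {
  rec <- as_sequence_record(rec)
  chars <- active_residues(rec)
  cf <- charge_fractions(rec)
  c(list(id = rec$id, N = length(chars),
         H = normalized_hydrophobicity(rec),
         FCR = unname(cf["FCR"]), NCPR = unname(cf["NCPR"]),
         kappa = kappa_patterning(rec), SCD = scd(rec)),
    as.list(composition_features(rec)))
}

#' Feature table for a set of sequences
#'
#' @param recs List of [sequence_record()]s (e.g. from [read_fasta_records()]).
#' @param file Optional path; when given, the table is also written as TSV.
#' @return `data.frame`, one row per sequence, fixed column order.
#' @export
feature_table <- function(recs, file = NULL) {
  rows <- lapply(recs, function(r) as.data.frame(sequence_features(r)))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(file))
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' Read amino-acid FASTA into sequence records
#'
#' @param path FASTA file (multi-record, wrapped lines).
#' @param mask_overhangs Passed to [sequence_record()].
#' @return List of `sequence_record`s.
#' @export
read_fasta_records <- function(path, mask_overhangs = FALSE) {
  aa <- Biostrings::readAAStringSet(path)
  mapply(function(nm, s) sequence_record(nm, s, mask_overhangs = mask_overhangs),
         names(aa), as.character(aa), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write sequence records as FASTA
#'
#' @param recs List of [sequence_record()]s.
#' @param path Output file.
#' @export
write_fasta_records <- function(recs, path) {
  aa <- Biostrings::AAStringSet(vapply(recs, `[[`, "", "seq"))
  names(aa) <- vapply(recs, `[[`, "", "id")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
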