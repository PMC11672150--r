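# shared fixtures built in code

# Kyte-Doolittle values used by independent oracles in tests
kd_oracle <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
               H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
               P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
               W = -0.9, Y = -1.3)

# brute-force blob-based kappa, written independently of the package
kappa_oracle <- function(chars) {
  q <- ifelse(chars %in% c("K", "R"), 1, ifelse(chars %in% c("D", "E"), -1, 0))
  delta <- function(qv, g) {
    sig <- function(w) {
      fp <- mean(w > 0); fm <- mean(w < 0)
      if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
    }
    sg <- sig(qv)
    mean(sapply(seq_len(length(qv) - g + 1), function(i)
      (sig(qv[i:(i + g - 1)]) - sg)^2))
  }
  qmax <- c(rep(1, sum(q > 0)), rep(0, sum(q == 0)), rep(-1, sum(q < 0)))
  mean(sapply(5:6, function(g) delta(q, g) / delta(qmax, g)))
}

# small WCA-only parameter set (lambda = 0, q = 0) used across cg tests
wca_params <- function(...) {
  tab <- hps_default_table()
  tab$lambda[] <- 0
  tab$q[] <- 0
  hps_params(tab, ...)
}

homopolymer_topology <- function(n, res = "G", params = hps_params()) {
  build_topology(paste(rep(res, n), collapse = ""), params = params)
}
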