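test_that("normalized hydrophobicity hits the scale limits and the Gly value", {
  expect_equal(normalized_hydrophobicity(strrep("I", 20)), 1.0)
  expect_equal(normalized_hydrophobicity(strrep("R", 20)), 0.0)
  # frozen from the Kyte-Doolittle table: (-0.4 + 4.5)/9
  expect_equal(normalized_hydrophobicity(strrep("G", 12)),
               (kd_oracle[["G"]] + 4.5) / 9, tolerance = 1e-12)
  # random sequences: equals the direct table average, and stays in [0,1]
  set.seed(41)
  for (i in 1:20) {
    chars <- sample(names(kd_oracle), 30, replace = TRUE)
    h <- normalized_hydrophobicity(paste(chars, collapse = ""))
    expect_equal(h, mean((kd_oracle[chars] + 4.5) / 9), tolerance = 1e-12)
    expect_true(h >= 0 && h <= 1)
  }
})

test_that("sequence validation rejects bad input with position information", {
  expect_error(normalized_hydrophobicity("ACDXE"), "position 4")
  expect_error(charge_fractions(sequence_record("s", "GSGSC",
                                                mask_overhangs = TRUE)),
               "empty after masking")
})

test_that("charge fractions obey FCR/NCPR identities", {
  expect_equal(unname(charge_fractions("EEEE")), c(1, -1))
  expect_equal(unname(charge_fractions("GGGG")), c(0, 0))
  expect_equal(unname(charge_fractions("EKEKEK")), c(1, 0))
  # H is neutral
  expect_equal(unname(charge_fractions("HHHH")), c(0, 0))
  set.seed(42)
  for (i in 1:25) {
    chars <- sample(names(kd_oracle), 57, replace = TRUE)
    cf <- charge_fractions(paste(chars, collapse = ""))
    expect_true(abs(cf["NCPR"]) <= cf["FCR"] + 1e-12)
    expect_true(cf["FCR"] >= 0 && cf["FCR"] <= 1)
  }
})

test_that("kappa is 1 for the fully segregated block and matches the blob oracle", {
  block <- paste0(strrep("E", 25), strrep("K", 25))
  expect_equal(kappa_patterning(block), 1.0, tolerance = 1e-12)
  # brute-force minimum over shuffles exceeds or equals the alternating value
  alt <- strrep("EK", 25)
  k_alt <- kappa_patterning(alt)
  set.seed(7)
  chars <- strsplit(alt, "")[[1]]
  shuffled <- replicate(300, kappa_patterning(
    paste(sample(chars), collapse = "")))
  expect_true(all(shuffled >= k_alt - 1e-12))
  expect_true(all(shuffled >= 0 & shuffled <= 1 + 1e-12))
  # agreement with the independently coded oracle on mixed sequences
  set.seed(8)
  for (i in 1:10) {
    chars <- sample(c("E", "K", "G", "S", "A"), 40, replace = TRUE)
    if (sum(chars %in% c("E", "K", "D", "R")) < 2) next
    expect_equal(kappa_patterning(paste(chars, collapse = "")),
                 kappa_oracle(chars), tolerance = 1e-12)
  }
  expect_true(is.na(kappa_patterning("GGGGGG")))
})

test_that("kappa is invariant under sequence reversal", {
  set.seed(9)
  for (i in 1:10) {
    chars <- sample(c("E", "K", "G", "A"), 50, replace = TRUE)
    s <- paste(chars, collapse = "")
    r <- paste(rev(chars), collapse = "")
    expect_equal(kappa_patterning(s), kappa_patterning(r),
                 tolerance = 1e-12)
  }
})

test_that("SCD matches direct evaluation and is charge-flip invariant", {
  expect_equal(scd("EK"), -0.5)
  expect_equal(scd("GGGG"), 0)
  block <- paste0(strrep("E", 25), strrep("K", 25))
  expect_lt(scd(block), scd(strrep("EK", 25)))
  # pairwise-sum oracle on random sequences; flip invariance
  set.seed(10)
  for (i in 1:10) {
    chars <- sample(c("E", "K", "D", "R", "G", "S"), 30, replace = TRUE)
    q <- ifelse(chars %in% c("K", "R"), 1,
                ifelse(chars %in% c("D", "E"), -1, 0))
    ref <- 0
    for (a in 1:29) for (b in (a + 1):30)
      ref <- ref + q[a] * q[b] * sqrt(b - a)
    s <- paste(chars, collapse = "")
    expect_equal(scd(s), ref / 30, tolerance = 1e-12)
    flipped <- chartr("EKDR", "KERD", s)  # E<->K, D<->R flips all charges
    expect_equal(scd(flipped), scd(s), tolerance = 1e-12)
  }
})

test_that("composition fractions sum to one and groups aggregate correctly", {
  f <- composition_features("GGGG")
  expect_equal(unname(f["f_G"]), 1)
  expect_equal(sum(f[paste0("f_", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])]), 1)
  f2 <- composition_features("GAGA")
  expect_equal(unname(f2[c("f_G", "f_A")]), c(0.5, 0.5))
  set.seed(11)
  chars <- sample(names(kd_oracle), 57, replace = TRUE)
  f3 <- composition_features(paste(chars, collapse = ""))
  expect_equal(sum(f3[1:20]), 1, tolerance = 1e-12)
  expect_equal(unname(f3["f_KR"]), unname(f3["f_K"] + f3["f_R"]))
})

test_that("overhang masking changes only the counted residues", {
  core <- "EKEKGSTAEKEK"
  full <- paste0("GSGSC", core, "CTLGPR")
  rec <- sequence_record("x", full, mask_overhangs = TRUE)
  feats_masked <- sequence_features(rec)
  feats_core <- sequence_features(core)
  expect_equal(feats_masked$N, nchar(core))
  for (k in c("H", "FCR", "NCPR", "kappa", "SCD"))
    expect_equal(feats_masked[[k]], feats_core[[k]], tolerance = 1e-12)
})

test_that("FASTA round trip and feature table preserve records", {
  recs <- gen_sequences(4, length = 30, fcr = 0.3, ncpr = 0.1, seed = 12)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_records(recs, path)
  back <- read_fasta_records(path)
  expect_equal(vapply(back, `[[`, "", "seq"),
               vapply(recs, `[[`, "", "seq"), ignore_attr = TRUE)
  tab <- feature_table(recs, file = withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(tab), 4)
  expect_true(all(c("H", "FCR", "NCPR", "kappa", "SCD") %in% names(tab)))
})
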