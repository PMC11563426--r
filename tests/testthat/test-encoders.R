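pep <- "RPFERDISNVPFS"  # worked example peptide used throughout

test_that("amino-acid composition matches hand counts and normalises", {
  v <- encode_aac(pep)
  expect_length(v, 20)
  expect_equal(unname(v[paste0("AAC.", c("R", "P", "F", "S"))]),
               rep(2 / 13, 4))
  expect_equal(unname(v[paste0("AAC.", c("D", "E", "I", "N", "V"))]),
               rep(1 / 13, 5))
  expect_equal(sum(v), 1)
  expect_equal(sum(v > 0), 9)

  v2 <- encode_aac("AAAA")
  expect_equal(unname(v2["AAC.A"]), 1)
  expect_equal(sum(v2), 1)
})

test_that("dipeptide composition counts adjacent ordered pairs", {
  v <- encode_dpc(pep)
  expect_length(v, 400)
  expect_equal(unname(v["DPC.PF"]), 2 / 12)   # positions 2-3 and 11-12
  expect_equal(unname(v["DPC.RP"]), 1 / 12)
  expect_equal(sum(v), 1)
  expect_equal(unname(encode_dpc("AAAA")["DPC.AA"]), 1)
  expect_error(encode_dpc("A"), "length >= 2")
})

test_that("tripeptide composition counts adjacent ordered triples", {
  expect_equal(unname(encode_tpc("AAAA")["TPC.AAA"]), 1)
  v <- encode_tpc("ACD")
  expect_length(v, 8000)
  expect_equal(unname(v["TPC.ACD"]), 1)
  expect_equal(sum(v != 0), 1)
  expect_error(encode_tpc("AC"), "length >= 3")
})

test_that("k-spaced pair composition enumerates every gap block", {
  v <- encode_cksaap("ACAC", gap_max = 1)
  expect_length(v, 800)
  expect_equal(unname(v["CKSAAP.g0.AC"]), 2 / 3)
  expect_equal(unname(v["CKSAAP.g0.CA"]), 1 / 3)
  expect_equal(unname(v["CKSAAP.g1.AA"]), 1 / 2)
  expect_equal(unname(v["CKSAAP.g1.CC"]), 1 / 2)

  v2 <- encode_cksaap("AAAA", gap_max = 1)
  expect_equal(unname(v2[c("CKSAAP.g0.AA", "CKSAAP.g1.AA")]), c(1, 1))

  expect_length(encode_cksaap(pep), 1600)     # default gap_max = 3
  expect_error(encode_cksaap("ACD", gap_max = 3), "too short")
})

test_that("AAC/DPC/TPC/CKSAAP agree with brute-force counters on short sequences", {
  seqs <- all_sequences(c("A", "C", "D"), 6)
  expect_length(seqs, 3 + 9 + 27 + 81 + 243 + 729)
  check <- seqs[nchar(seqs) >= 3]
  # exhaustive check on a deterministic subsample + all length <= 4
  sub <- c(check[nchar(check) <= 4],
           check[nchar(check) > 4][seq(1, sum(nchar(check) > 4), by = 13)])
  for (s in sub) {
    expect_equal(unname(encode_aac(s)), unname(oracle_kmer_freq(s, 1)))
    expect_equal(unname(encode_dpc(s)), unname(oracle_kmer_freq(s, 2)))
    expect_equal(unname(encode_tpc(s)), unname(oracle_kmer_freq(s, 3)))
    g_max <- min(3, nchar(s) - 2)
    v <- encode_cksaap(s, gap_max = g_max)
    for (g in 0:g_max) {
      block <- v[grepl(paste0("^CKSAAP\\.g", g, "\\."), names(v))]
      expect_equal(unname(block), unname(oracle_gapped_pair_freq(s, g)))
    }
  }
})

test_that("pseudo compositions match frozen hand-derived values and the AAC limit", {
  # frozen oracle values: direct formula evaluation for "ACD", lambda 1, w 0.05
  p <- encode_paac("ACD", lambda = 1)
  expect_length(p, 21)
  expect_equal(unname(p["PAAC.A"]), 0.313718341743664, tolerance = 1e-12)
  expect_equal(unname(p["PAAC.lambda1"]), 0.0588449747690088, tolerance = 1e-12)
  expect_equal(sum(p), 1)

  a <- encode_apaac("ACD", lambda = 1)
  expect_length(a, 22)
  expect_equal(unname(a["APAAC.A"]), 0.339571940913435, tolerance = 1e-12)
  expect_equal(unname(a["APAAC.hb.lambda1"]), -0.00208053205657745, tolerance = 1e-12)
  expect_equal(unname(a["APAAC.hl.lambda1"]), -0.0166352906837285, tolerance = 1e-12)

  expect_length(encode_paac(pep), 22)   # default lambda = 2
  expect_length(encode_apaac(pep), 24)

  for (s in c(pep, "ACDKLM")) {
    expect_equal(unname(encode_paac(s, lambda = 0)), unname(encode_aac(s)))
    expect_equal(unname(encode_apaac(s, lambda = 0)), unname(encode_aac(s)))
  }
  expect_error(encode_paac("AC", lambda = 2), "lambda")
})

test_that("CTD composition partitions residues into valid property groups", {
  groups <- pepstack:::ctd_groups()
  expect_length(groups, 13)
  for (prop in names(groups)) {
    expect_identical(sort(unlist(groups[[prop]])), AA_ALPHABET)
  }
  v <- encode_ctdc(pep)
  expect_length(v, 39)
  for (prop in names(groups)) {
    block <- v[grepl(paste0("^CTDC\\.", prop, "\\."), names(v))]
    expect_equal(sum(block), 1)
  }
  h <- encode_ctdc("AAAAA")
  expect_true(all(h %in% c(0, 1)))
  expect_equal(sum(h == 1), 13)   # one winning group per property
})

test_that("conjoint triad counts class-label windows with both normalisations", {
  v <- encode_ctriad("AAA")
  expect_length(v, 343)
  expect_equal(sum(v != 0), 1)
  raw <- encode_ctriad(pep, normalize = "frequency")
  expect_equal(sum(raw) * (nchar(pep) - 2), nchar(pep) - 2)  # sums to 1
  mm <- encode_ctriad(pep)
  expect_true(all(mm >= 0 & mm <= 1))
  expect_error(encode_ctriad("AC"), "length >= 3")
  # the 7 classes partition the alphabet
  expect_identical(sort(unlist(pepstack:::ctriad_classes())), AA_ALPHABET)
})

test_that("Moran autocorrelation matches direct formula evaluation", {
  # alternating hydrophobicity gives perfect negative lag-1 autocorrelation
  v <- encode_moran("ACACAC")
  expect_length(v, 2)
  expect_equal(unname(v), c(-1, 1))
  # zero-variance convention
  expect_equal(unname(encode_moran("AAAAAA")), c(0, 0))
  # independent recomputation for a mixed peptide
  s <- "RPFERD"
  p <- pepstack:::standardize_property(paac_properties()$hydrophobicity)
  x <- p[strsplit(s, "")[[1]]]
  xb <- mean(x); den <- mean((x - xb)^2)
  o <- vapply(1:2, function(d) {
    i <- seq_len(length(x) - d)
    mean((x[i] - xb) * (x[i + d] - xb)) / den
  }, numeric(1))
  expect_equal(unname(encode_moran(s)), unname(o))
  expect_error(encode_moran("AC", nlag = 2), "nlag")
})

test_that("reduced-alphabet composition uses a valid 4-cluster partition", {
  expect_identical(sort(unname(unlist(raac_scheme("four")))), AA_ALPHABET)
  v <- encode_raacc(pep)
  expect_length(v, 4)
  expect_equal(sum(v), 1)
  h <- encode_raacc("AAAA")
  expect_equal(unname(h["RAACC.small_hydro"]), 1)
  expect_error(raac_scheme("nope"), "unknown")
})

test_that("encoders are deterministic and nonnegative composition blocks sum to 1", {
  d <- small_dataset(n_pos = 4, n_neg = 4, seed = 33)
  for (s in d$residues) {
    for (enc in c(encode_aac, encode_dpc, encode_raacc)) {
      v <- enc(s)
      expect_identical(v, enc(s))
      expect_true(all(v >= 0))
      expect_equal(sum(v), 1, tolerance = 1e-9)
    }
  }
})

test_that("dataset encoding concatenates named blocks in spec order", {
  d <- peptide_dataset(c("p1", "n1"), c("RPFERDISNVPFS", "SHLVEALYLVAGERG"),
                       c(1, 0))
  m <- encode_dataset(d, "AAC")
  expect_identical(dim(m), c(2L, 20L))
  expect_identical(rownames(m), c("p1", "n1"))

  m2 <- encode_dataset(d, c("AAC", "DPC"))
  expect_identical(ncol(m2), 420L)
  expect_identical(colnames(m2)[1:20], paste0("AAC.", AA_ALPHABET))
  expect_true(startsWith(colnames(m2)[21], "DPC."))

  expect_error(encode_dataset(d, character(0)), "empty")
  expect_error(encode_dataset(d, "BLAH"), "unknown")
  # per-sequence length preconditions name the offending ids
  d2 <- peptide_dataset(c("ok", "short"), c("ACDEFG", "AC"), c(1, 0))
  expect_error(encode_dataset(d2, "TPC"), "short")
  # parameter overrides flow through
  m3 <- encode_dataset(d, list(CKSAAP = list(gap_max = 1L)))
  expect_identical(ncol(m3), 800L)
})
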