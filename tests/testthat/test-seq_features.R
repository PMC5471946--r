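test_that("composition fractions match hand counts and sum to one", {
  expect_equal(composition("AAAA")$aa[["A"]], 1)
  expect_equal(sum(composition("AAAA")$aa), 1)

  cm <- composition("KRDE")
  expect_equal(cm$groups[["charged"]], 1)
  expect_equal(cm$groups[["hydrophobic"]], 0)

  # hand count for ACDEFG: each residue 1/6
  cm2 <- composition("ACDEFG")
  expect_equal(unname(cm2$aa[c("A", "C", "D", "E", "F", "G")]),
               rep(1 / 6, 6))
  # groups by hand from the grouping table
  expect_equal(cm2$groups[["acidic"]], 2 / 6)     # D, E
  expect_equal(cm2$groups[["aromatic"]], 1 / 6)   # F
  expect_equal(cm2$groups[["tiny"]], 3 / 6)       # A, C, G

  set.seed(2)
  for (i in 1:25) {
    cm3 <- composition(random_peptide(sample(5:200, 1)))
    expect_equal(sum(cm3$aa), 1, tolerance = 1e-12)
    expect_true(all(cm3$groups >= 0 & cm3$groups <= 1))
  }
})

test_that("nonstandard residues are excluded, empty result rejected", {
  expect_equal(composition("AXAX")$aa[["A"]], 1)
  expect_error(composition("XXX"), "no standard residues")
})

test_that("hydrophobic moment matches the closed-form trig oracle", {
  # delta = 0: all unit vectors aligned, moment = |sum H_i| per window
  h <- targetprops:::EISENBERG_SCALE
  expect_equal(hydrophobic_moment("ILVA", window = 4, angle_deg = 0),
               abs(h[["I"]] + h[["L"]] + h[["V"]] + h[["A"]]))

  # homopolymer at 100 degrees: H_L times the magnitude of the unit-vector
  # geometric sum, computed by direct trigonometric summation
  ang <- (0:9) * 100 * pi / 180
  oracle <- h[["L"]] * sqrt(sum(sin(ang))^2 + sum(cos(ang))^2)
  expect_equal(hydrophobic_moment(strrep("L", 10), window = 10,
                                  angle_deg = 100),
               oracle, tolerance = 1e-12)

  # window 1: maximum absolute single-residue hydrophobicity
  expect_equal(hydrophobic_moment("LKV", window = 1, angle_deg = 100),
               max(abs(h[c("L", "K", "V")])))

  # full-length window at delta = 0 is reversal invariant
  set.seed(9)
  s <- random_peptide(30)
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(hydrophobic_moment(s, window = 30, angle_deg = 0),
               hydrophobic_moment(rev_s, window = 30, angle_deg = 0))

  expect_error(hydrophobic_moment("MK", window = 10), "shorter than window")
})

test_that("pI solver hits closed forms and the grid-scan oracle", {
  pka <- default_pka_table()
  # glycine: no ionizable side chain, pI is the termini midpoint
  expect_equal(isoelectric_point("G"), (pka$nterm + pka$cterm) / 2,
               tolerance = 1e-3)

  # appending a basic residue never decreases pI
  set.seed(3)
  for (i in 1:10) {
    s <- random_peptide(sample(5:50, 1))
    expect_gte(isoelectric_point(paste0(s, "K")) + 1e-3,
               isoelectric_point(s))
  }

  # brute-force grid scan oracle at step 1e-5
  grid_pi <- function(seq) {
    counts <- table(factor(strsplit(seq, "")[[1]],
                           levels = targetprops:::AA20))
    ph <- seq(0, 14, by = 1e-5)
    nb <- counts[["K"]] / (1 + 10^(ph - pka$K)) +
      counts[["R"]] / (1 + 10^(ph - pka$R)) +
      counts[["H"]] / (1 + 10^(ph - pka$H)) +
      1 / (1 + 10^(ph - pka$nterm))
    na <- counts[["D"]] / (1 + 10^(pka$D - ph)) +
      counts[["E"]] / (1 + 10^(pka$E - ph)) +
      counts[["C"]] / (1 + 10^(pka$C - ph)) +
      counts[["Y"]] / (1 + 10^(pka$Y - ph)) +
      1 / (1 + 10^(pka$cterm - ph))
    ph[which.min(abs(nb - na))]
  }
  expect_equal(isoelectric_point("DDKK"), grid_pi("DDKK"), tolerance = 1e-3)
})

test_that("solubility is composition-driven, bounded, and matches the
          canonical-variable hand evaluation", {
  set.seed(4)
  for (i in 1:10) {
    s <- random_peptide(sample(20:100, 1))
    sc <- solubility(s)
    expect_true(sc >= 0 && sc <= 1)
    # repetition leaves composition, hence score, unchanged
    expect_equal(solubility(strrep(s, 2)), sc)
  }

  # independent re-derivation on a fixed 20-mer
  s <- "NNGGPPSSRRKKDDEEAALL"
  n <- 20
  turn <- 8 / n                       # N, G, P, S: two of each
  charge <- (2 + 2 - 2 - 2) / n       # R + K - D - E
  cv <- 15.43 * turn - 29.56 * abs(charge - 0.03) - 1.71
  prob <- 0.4934 + 0.276 * abs(cv) - 0.0392 * cv^2
  expected <- if (cv < 0) prob else 1 - prob
  expect_equal(solubility(s), expected, tolerance = 1e-12)
})

test_that("PEST candidacy rules match the published constraints", {
  # no D/E/P/S/T at all -> no candidates
  expect_equal(nrow(find_pest("KLKLKLKLKLKLKLKL")), 0L)
  # flanked stretch of length 11 -> below the 12-residue minimum
  expect_equal(nrow(find_pest(paste0("K", "EPESTDSEPES", "R"))), 0L)
  # minimal valid candidate
  p <- find_pest(paste0("K", "EPESTDSEPESTDA", "R"))
  expect_equal(nrow(p), 1L)
  expect_equal(p$start, 2L)
  expect_equal(p$end, 15L)
  expect_true(p$valid)
})

test_that("PEST score matches an independent loop-based reimplementation", {
  oracle_score <- function(stretch) {
    res <- strsplit(stretch, "")[[1]]
    masses <- targetprops:::RESIDUE_MASS
    kd <- targetprops:::KYTE_DOOLITTLE
    total <- 0; depst <- 0; hydro <- 0
    for (r in res) {
      total <- total + masses[[r]]
      if (r %in% c("D", "E", "P", "S", "T")) depst <- depst + masses[[r]]
      hydro <- hydro + (10 * kd[[r]] + 45)
    }
    rm1 <- masses[["P"]] +
      (if (grepl("E", stretch)) masses[["E"]] else masses[["D"]]) +
      (if (grepl("S", stretch)) masses[["S"]] else masses[["T"]])
    0.55 * (100 * max(depst - rm1, 0) / total) -
      0.5 * (hydro / length(res))
  }
  stretch <- "EPESTDSEPESTDA"
  p <- find_pest(paste0("K", stretch, "R"))
  expect_equal(p$score, unname(oracle_score(stretch)), tolerance = 1e-10)

  set.seed(6)
  for (i in 1:10) {
    s <- random_peptide(80)
    p <- find_pest(s)
    if (nrow(p) == 0) next
    for (j in seq_len(nrow(p))) {
      stretch <- substr(s, p$start[j], p$end[j])
      expect_equal(p$score[j], unname(oracle_score(stretch)),
                   tolerance = 1e-10)
    }
  }
})

test_that("PEST candidates avoid internal K/R/H and survive K padding", {
  set.seed(7)
  for (i in 1:15) {
    s <- random_peptide(120)
    p <- find_pest(s)
    if (nrow(p) > 0) {
      for (j in seq_len(nrow(p))) {
        inner <- strsplit(substr(s, p$start[j], p$end[j]), "")[[1]]
        expect_false(any(inner %in% c("K", "R", "H")))
      }
    }
    padded <- find_pest(paste0("K", s, "K"))
    expect_equal(sum(padded$valid), sum(p$valid))
    expect_equal(nrow(padded), nrow(p))
  }
})
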