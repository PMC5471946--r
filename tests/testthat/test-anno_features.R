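make_calls <- function(acc, src, type, loc) {
  data.frame(accession = acc, source = src, source_type = type,
             location = loc, stringsAsFactors = FALSE)
}

test_that("prediction votes need at least 3 of 5 agreeing tools", {
  calls <- make_calls("P1",
                      c("cello", "ptarget", "pa", "wolfpsort", "multiloc"),
                      "predicted",
                      c("nucleus", "nucleus", "nucleus",
                        "cytoplasm", "cytoplasm"))
  out <- consensus_localization(calls)
  expect_equal(out$locations[["P1"]], "nucleus")
  expect_equal(unname(out$provenance["P1"]), "prediction_vote")

  split221 <- make_calls("P2",
                         c("cello", "ptarget", "pa", "wolfpsort",
                           "multiloc"),
                         "predicted",
                         c("nucleus", "nucleus", "cytoplasm", "cytoplasm",
                           "extracellular"))
  expect_length(consensus_localization(split221)$locations[["P2"]], 0)
})

test_that("curated calls win outright over predictions", {
  calls <- rbind(
    make_calls("P1", "locate", "curated", "extracellular"),
    make_calls("P1", c("cello", "ptarget", "pa"), "predicted", "nucleus"))
  out <- consensus_localization(calls)
  expect_equal(out$locations[["P1"]], "extracellular")
  expect_equal(unname(out$provenance["P1"]), "curated")
})

test_that("more than five prediction sources is an error", {
  calls <- make_calls("P1", paste0("tool", 1:6), "predicted", "nucleus")
  expect_error(consensus_localization(calls), "more than 5")
})

test_that("PTM proportions count distinct positions over sequence length", {
  none <- data.frame(accession = character(), position = integer(),
                     residue = character(), type = character())
  pf <- ptm_features(none, rep(50L, 100), 100)
  expect_true(all(unlist(pf[paste0("ptm_", ptm_types())]) == 0))

  two <- data.frame(accession = "P1", position = c(10L, 20L),
                    residue = "S", type = "phosphorylation")
  pf2 <- ptm_features(two, rep(80L, 100), 100, exposure_threshold = 25)
  expect_equal(pf2$ptm_phosphorylation, 0.02)
  expect_equal(pf2$ptm_phosphorylation_acc, 0.02)

  # threshold filter verified against a brute-force filter
  prof <- rep(0L, 100); prof[c(1, 2, 3)] <- c(10L, 30L, 90L)
  three <- data.frame(accession = "P1", position = 1:3, residue = "S",
                      type = "phosphorylation")
  pf3 <- ptm_features(three, prof, 100, exposure_threshold = 25)
  brute <- sum(prof[1:3] >= 25)
  expect_equal(brute, 2L)
  expect_equal(pf3$ptm_phosphorylation_acc, brute / 100)

  expect_error(ptm_features(data.frame(accession = "P1", position = 101L,
                                       residue = "S",
                                       type = "phosphorylation"),
                            rep(1L, 100), 100, accession = "P1"),
               "beyond sequence length.*P1")
})

test_that("accessible PTM proportion never exceeds the overall one", {
  set.seed(12)
  for (i in 1:20) {
    len <- sample(50:200, 1)
    n_sites <- sample(1:15, 1)
    sites <- data.frame(accession = "P", residue = "S",
                        position = sort(sample(len, n_sites)),
                        type = sample(ptm_types(), n_sites, replace = TRUE))
    prof <- sample(0:99, len, replace = TRUE)
    pf <- ptm_features(sites, prof, len)
    for (type in ptm_types())
      expect_lte(pf[[paste0("ptm_", type, "_acc")]],
                 pf[[paste0("ptm_", type)]])
  }
})

test_that("tau hits its closed forms and respects the floor", {
  vals <- matrix(rep(500, 79), nrow = 1,
                 dimnames = list("p1", sprintf("t%02d", 1:79)))
  ex <- make_expression("p1", "g1", FALSE, vals)
  out <- expression_features(ex, "g1")
  expect_equal(out$expr_tau, 0)
  expect_equal(out$expr_level, 500)

  # one spike at 102400, the rest below the floor of 100
  spike <- matrix(c(rep(50, 78), 102400), nrow = 1,
                  dimnames = list("p1", sprintf("t%02d", 1:79)))
  ex2 <- make_expression("p1", "g1", FALSE, spike)
  out2 <- expression_features(ex2, "g1")
  closed <- 1 - log2(100) / log2(102400)
  # independent summation oracle over the flooring definition
  sj <- pmax(spike[1, ], 100)
  oracle <- sum(1 - log2(sj) / log2(max(sj))) / 78
  expect_equal(out2$expr_tau, closed, tolerance = 1e-12)
  expect_equal(out2$expr_tau, oracle, tolerance = 1e-12)

  # raising a sub-floor value to another sub-floor value changes nothing
  spike2 <- spike; spike2[1, 1] <- 80
  out3 <- expression_features(make_expression("p1", "g1", FALSE, spike2),
                              "g1")
  expect_equal(out3$expr_tau, out2$expr_tau)
})

test_that("probe handling: multi-gene probes dropped, highest-mean kept,
          ties to lowest probe id", {
  vals <- matrix(c(rep(10, 79), rep(1000, 79), rep(1000, 79)),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("a_low", "z_hi", "b_hi"),
                                 sprintf("t%02d", 1:79)))
  ex <- make_expression(c("a_low", "z_hi", "b_hi"), rep("g1", 3),
                        c(FALSE, FALSE, FALSE), vals)
  # tie between z_hi and b_hi resolved to the lexicographically lower probe
  out <- expression_features(ex, "g1")
  expect_equal(out$expr_level, 1000)

  ex_multi <- make_expression(c("p1", "p2"), c("g1", "g1"),
                              c(TRUE, TRUE), vals[1:2, ])
  out2 <- expression_features(ex_multi, "g1")
  expect_true(is.na(out2$expr_level) && is.na(out2$expr_tau))
})

test_that("tau is nondecreasing in the top tissue with others at floor", {
  base <- rep(100, 79)
  taus <- vapply(c(200, 800, 3200, 128000), function(top) {
    v <- base; v[1] <- top
    m <- matrix(v, nrow = 1, dimnames = list("p", sprintf("t%02d", 1:79)))
    expression_features(make_expression("p", "g", FALSE, m), "g")$expr_tau
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
  expect_true(all(taus >= 0 & taus <= 1))
})

test_that("essentiality maps to the two indicator columns", {
  out <- essentiality_features(c("essential", "nonessential", "unknown"))
  expect_equal(out$essential, c(1, 0, 0))
  expect_equal(out$nonessential, c(0, 1, 0))
})
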