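test_that("class balancing keeps targets and downsamples nontargets", {
  lab <- c(rep("target", 5), rep("nontarget", 20))
  keep <- balance_classes(lab, seed = 3)
  expect_length(keep, 10L)
  expect_equal(sum(lab[keep] == "target"), 5L)
  expect_equal(sum(lab[keep] == "nontarget"), 5L)
  expect_true(all(which(lab == "target") %in% keep))

  expect_identical(balance_classes(lab, seed = 3),
                   balance_classes(lab, seed = 3))

  expect_error(balance_classes(c("target", "target", "nontarget"), 1),
               "cannot balance")
})

test_that("repeated reseeded balancing eventually covers all nontargets", {
  lab <- c(rep("target", 5), rep("nontarget", 6))
  seen <- integer(0)
  for (s in 1:50)
    seen <- union(seen, setdiff(balance_classes(lab, s), 1:5))
  expect_setequal(seen, 6:11)
})

test_that("min-max scaler maps training to [0,1], clamps and zeroes
          constant columns", {
  x <- cbind(a = c(2, 4, 6), b = c(7, 7, 7))
  sc <- fit_scaler(x)
  scaled <- apply_scaler(sc, x)
  expect_equal(scaled[, "a"], c(0, 0.5, 1))
  expect_equal(scaled[, "b"], c(0, 0, 0))

  test <- cbind(a = c(8, 0), b = c(9, 5))
  scaled_test <- apply_scaler(sc, test)
  expect_equal(scaled_test[, "a"], c(1, 0))   # clamped
  expect_equal(scaled_test[, "b"], c(0, 0))
})

test_that("feature selection keeps label-aligned features and honors alpha", {
  set.seed(61)
  n <- 200
  lab <- rep(c("target", "nontarget"), each = n / 2)
  vals <- data.frame(signal = as.numeric(lab == "target"),
                     noise = rnorm(n))
  kinds <- c(signal = "discrete", noise = "continuous")
  expect_true("signal" %in% select_features(vals, lab, kinds))
  expect_length(select_features(vals, lab, kinds, alpha = 0), 0L)

  # pure-noise features are selected at about the alpha rate
  sel_frac <- mean(vapply(1:30, function(s) {
    set.seed(s)
    nv <- data.frame(matrix(rnorm(n * 10), nrow = n))
    k <- stats::setNames(rep("continuous", 10), names(nv))
    length(select_features(nv, lab, k)) / 10
  }, numeric(1)))
  expect_gt(sel_frac, 0.005)
  expect_lt(sel_frac, 0.15)
})

test_that("confusion metrics follow the defining formulas", {
  m <- compute_metrics(TP = 3, FP = 1, TN = 5, FN = 1)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)

  expect_equal(compute_metrics(0, 4, 5, 3)$f1, 0)

  m2 <- compute_metrics(10, 10, 0, 10)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$f1, 0.5)
})

test_that("the squared-hinge linear SVM separates separable data", {
  set.seed(71)
  x <- rbind(matrix(rnorm(100, mean = 2), ncol = 2),
             matrix(rnorm(100, mean = -2), ncol = 2))
  y <- c(rep(1, 50), rep(-1, 50))
  fit <- fit_linear_svm(x, y)
  expect_equal(unname(predict(fit, x)), y)
  # decision boundary direction points toward the positive class
  expect_true(all(fit$w > 0))
})

test_that("mtry follows floor(log2(p + 1)) capped by feature count", {
  expect_equal(rf_mtry(67), 6L)
  expect_equal(rf_mtry(1), 1L)
  expect_equal(rf_mtry(2), 1L)
  expect_equal(rf_mtry(1000), 9L)
})

test_that("a label-equal feature drives cross-validated F1 to 1", {
  set.seed(81)
  n <- 120
  lab <- sample(rep(c("target", "nontarget"), each = n / 2))
  vals <- data.frame(oracle = as.numeric(lab == "target"),
                     noise = rnorm(n))
  kinds <- c(oracle = "discrete", noise = "continuous")
  for (cfg in list(svm_config(), rf_config())) {
    cv <- run_cv(vals, lab, cfg, scheme = "5-fold", seed = 4, kinds = kinds)
    expect_equal(cv$pooled$f1, 1.0)
    expect_equal(cv$pooled$TP + cv$pooled$FN, n / 2)
  }
})

test_that("identical seeds give identical cv_results, fold counts pool", {
  set.seed(91)
  n <- 80
  lab <- sample(rep(c("target", "nontarget"), each = n / 2))
  vals <- data.frame(x1 = rnorm(n) + (lab == "target"), x2 = rnorm(n))
  kinds <- c(x1 = "continuous", x2 = "continuous")
  cv1 <- run_cv(vals, lab, svm_config(), scheme = "5-fold", seed = 11,
                kinds = kinds)
  cv2 <- run_cv(vals, lab, svm_config(), scheme = "5-fold", seed = 11,
                kinds = kinds)
  expect_identical(serialize(cv1, NULL), serialize(cv2, NULL))

  pooled <- colSums(do.call(rbind, lapply(cv1$folds, function(f)
    unlist(f$metrics[c("TP", "FP", "TN", "FN")]))))
  expect_equal(unname(pooled["TP"]), cv1$pooled$TP)
  expect_equal(unname(pooled["FN"]), cv1$pooled$FN)
})

test_that("10x10 cross-validation reports repetition spread", {
  set.seed(101)
  n <- 60
  lab <- sample(rep(c("target", "nontarget"), each = n / 2))
  vals <- data.frame(x1 = rnorm(n) + 1.5 * (lab == "target"))
  cv <- run_cv(vals, lab, svm_config(), scheme = "10x10-fold", seed = 2,
               kinds = c(x1 = "continuous"))
  expect_length(cv$folds, 100L)
  expect_false(is.na(cv$f1_sd))
  expect_equal(cv$selection$n_folds[1], 100L)
})

test_that("held-out rows never influence selection or scaling", {
  set.seed(111)
  n <- 100
  lab <- rep(c("target", "nontarget"), each = n / 2)
  vals <- data.frame(x1 = rnorm(n) + (lab == "target"), x2 = rnorm(n),
                     x3 = rbinom(n, 1, 0.5 + 0.3 * (lab == "target")))
  kinds <- c(x1 = "continuous", x2 = "continuous", x3 = "discrete")

  # fix a fold; permute the held-out labels; training-side selection and
  # scaler parameters must not move
  test_idx <- sample(n, 20)
  tr_idx <- setdiff(seq_len(n), test_idx)
  sel_before <- select_features(vals[tr_idx, ], lab[tr_idx], kinds)
  sc_before <- fit_scaler(as.matrix(vals[tr_idx, ]))
  lab_perm <- lab
  lab_perm[test_idx] <- sample(lab[test_idx])
  sel_after <- select_features(vals[tr_idx, ], lab_perm[tr_idx], kinds)
  sc_after <- fit_scaler(as.matrix(vals[tr_idx, ]))
  expect_identical(sel_before, sel_after)
  expect_identical(sc_before, sc_after)

  # corrupting held-out feature values must not change any fold's selected
  # feature set (selection sees training rows only)
  cv_a <- run_cv(vals, lab, svm_config(), scheme = "5-fold", seed = 5,
                 kinds = kinds)
  vals_b <- vals
  # recover the rows of fold 1 of the balanced set deterministically
  keep <- balance_classes(lab, seed = 5)
  set.seed(5 + 1L)
  fold <- targetprops:::stratified_folds(lab[keep], 5L)
  corrupt <- keep[fold == 1]
  vals_b[corrupt, "x1"] <- vals_b[corrupt, "x1"] + 1e6
  cv_b <- run_cv(vals_b, lab, svm_config(), scheme = "5-fold", seed = 5,
                 kinds = kinds)
  expect_identical(lapply(cv_a$folds[1], `[[`, "selected"),
                   lapply(cv_b$folds[1], `[[`, "selected"))
})
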