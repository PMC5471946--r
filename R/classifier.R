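# The prediction protocol: class balancing by downsampling, per-fold feature
# selection (raw p < 0.05 on the training split only), min-max scaling fit on
# training folds, linear squared-hinge SVM and random forest, stratified
# k-fold cross-validation and pooled confusion metrics.

#' Balance classes by downsampling the majority nontarget group
#'
#' All targets are kept; nontargets are sampled uniformly without
#' replacement down to the target count. Seeded and reproducible.
#'
#' @param labels character vector of target/nontarget
#' @param seed integer seed
#' @return sorted integer indices of the retained rows
#' @export
balance_classes <- function(labels, seed) {
  t_idx <- which(labels == "target")
  n_idx <- which(labels == "nontarget")
  if (length(t_idx) > length(n_idx))
    stop("more targets than nontargets; cannot balance by downsampling")
  set.seed(seed)
  keep_n <- sample(n_idx, length(t_idx))
  sort(c(t_idx, keep_n))
}

#' Min-max feature scaler
#'
#' `fit_scaler` records per-feature training minima and maxima;
#' `apply_scaler` maps values into [0, 1], clamping out-of-range test values
#' and mapping constant training columns to 0.
#'
#' @param x numeric matrix (training rows only for fitting)
#' @return `fit_scaler`: list with `min` and `max` vectors
#' @export
fit_scaler <- function(x) {
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' @rdname fit_scaler
#' @param params scaler parameters from [fit_scaler()]
#' @export
apply_scaler <- function(params, x) {
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, "-")
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(out, 2, rng, "/")
  out[, const] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Per-fold univariate feature selection
#'
#' Runs the two-group screen ([property_table()]) on the training split only
#' and keeps features with raw p below `alpha`. An empty selection is
#' allowed (and reported by the caller).
#'
#' @param values data.frame of feature values (training rows only)
#' @param labels training labels
#' @param kinds named kind vector (discrete/continuous)
#' @param alpha selection threshold on the raw p-value (default 0.05)
#' @return character vector of selected feature names
#' @export
select_features <- function(values, labels, kinds, alpha = 0.05) {
  pt <- property_table(values, labels, kinds = kinds)
  pt$feature[!pt$untestable & pt$p_value < alpha]
}

#' Confusion-count metrics
#'
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' F1 = 2 recall precision / (recall + precision); each defined as 0 when
#' its denominator is 0.
#'
#' @param TP,FP,TN,FN confusion counts
#' @return list with the counts, recall, precision and f1
#' @export
compute_metrics <- function(TP, FP, TN, FN) {
  TP <- unname(TP); FP <- unname(FP); TN <- unname(TN); FN <- unname(FN)
  recall <- if (TP + FN == 0) 0 else TP / (TP + FN)
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  f1 <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       recall = recall, precision = precision, f1 = f1)
}

#' Linear SVM with squared hinge loss (L2-regularized L2-loss SVC)
#'
#' Minimizes 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (w x_i + b))^2 over (w, b)
#' with an unregularized intercept, by L-BFGS-B on the smooth primal
#' objective; `epsilon` is the solver's stopping tolerance (projected
#' gradient).
#'
#' @param x numeric matrix (rows = samples)
#' @param y labels coded +1 / -1
#' @param C error cost (default 1.3)
#' @param epsilon stopping tolerance (default 0.01)
#' @return list with `w`, `b` of class `linear_svm`
#' @export
fit_linear_svm <- function(x, y, C = 1.3, epsilon = 0.01) {
  stopifnot(all(y %in% c(-1, 1)), C > 0)
  p <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    m <- pmax(0, 1 - y * (drop(x %*% w) + b))
    0.5 * sum(w^2) + C * sum(m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    m <- pmax(0, 1 - y * (drop(x %*% w) + b))
    gm <- -2 * C * y * m
    c(w + drop(crossprod(x, gm)), sum(gm))
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 1000, pgtol = epsilon))
  out <- list(w = fit$par[seq_len(p)], b = fit$par[p + 1])
  class(out) <- "linear_svm"
  out
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  ifelse(drop(newdata %*% object$w) + object$b >= 0, 1, -1)
}

#' SVM and random forest configuration
#'
#' @param C SVM error cost (default 1.3)
#' @param epsilon SVM solver stopping tolerance (default 0.01)
#' @return named list
#' @export
svm_config <- function(C = 1.3, epsilon = 0.01) {
  stopifnot(C > 0)
  list(model = "svm", C = C, epsilon = epsilon)
}

#' @rdname svm_config
#' @param n_trees number of trees (default 100)
#' @export
rf_config <- function(n_trees = 100L) {
  stopifnot(n_trees >= 1)
  list(model = "rf", n_trees = n_trees)
}

#' mtry rule for the random forest
#'
#' floor(log2(n_features + 1)), capped at the available feature count and
#' floored at 1.
#' @param n_features number of features entering the forest
#' @export
rf_mtry <- function(n_features) {
  max(1L, min(floor(log2(n_features + 1)), n_features))
}

train_model <- function(x, y01, config) {
  if (config$model == "svm") {
    fit_linear_svm(x, ifelse(y01 == 1, 1, -1),
                   C = config$C, epsilon = config$epsilon)
  } else {
    randomForest::randomForest(
      x = x, y = factor(y01, levels = c(0, 1)),
      ntree = config$n_trees, mtry = rf_mtry(ncol(x)))
  }
}

predict_model <- function(fit, x, config) {
  if (config$model == "svm") {
    as.integer(predict(fit, x) == 1)
  } else {
    as.integer(as.character(predict(fit, x)))
  }
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated classification of drug targetability
#'
#' The full protocol: per repetition, downsample nontargets to the target
#' count; stratified k-fold split; within each fold select features at raw
#' p < `alpha` on the training split, impute missing values with training
#' medians, fit the min-max scaler on the training split, train the model
#' and predict the held-out fold. Held-out rows never influence selection,
#' imputation or scaling. The headline recall/precision/F1 come from
#' confusion counts pooled over folds; per-fold metrics are reported too.
#' `"10x10-fold"` repeats 10-fold CV ten times with fresh downsampling and
#' partitions, reporting mean and standard deviation of the per-repetition
#' pooled F1. If a fold selects no feature, all candidate features are used
#' for that fold (recorded in the fold entry).
#'
#' @param features `feature_matrix` or data.frame of values
#' @param labels character vector target/nontarget, parallel to rows
#' @param config model configuration from [svm_config()] or [rf_config()]
#' @param feature_set character vector of candidate feature names (default:
#'   all columns)
#' @param scheme `"5-fold"`, `"10-fold"` or `"10x10-fold"`
#' @param seed integer seed driving downsampling and fold assignment
#' @param alpha per-fold selection threshold (default 0.05)
#' @param kinds named kind vector when `features` is a plain data.frame
#' @return object of class `cv_result`: list with `scheme`, `pooled`
#'   (metrics over all folds), `folds` (per-fold metrics + selected
#'   features), `f1_mean`/`f1_sd` (across repetitions), `selection` (per
#'   feature: folds selected in, total folds, `"always"`/`"partially"`/
#'   `"never"`), `seed`
#' @export
run_cv <- function(features, labels, config, feature_set = NULL,
                   scheme = c("5-fold", "10-fold", "10x10-fold"),
                   seed = 1L, alpha = 0.05, kinds = NULL) {
  scheme <- match.arg(scheme)
  vals <- if (inherits(features, "feature_matrix")) features$values else features
  if (is.null(kinds)) {
    if (!inherits(features, "feature_matrix"))
      stop("kinds required for plain data.frame input")
    kinds <- features$kinds
  }
  if (is.null(feature_set)) feature_set <- names(vals)
  missing_feats <- setdiff(feature_set, names(vals))
  if (length(missing_feats))
    stop("feature(s) not in matrix: ", paste(missing_feats, collapse = ", "))
  vals <- vals[feature_set]
  stopifnot(length(labels) == nrow(vals))

  k <- if (scheme == "5-fold") 5L else 10L
  n_rep <- if (scheme == "10x10-fold") 10L else 1L

  folds_out <- list()
  rep_f1 <- numeric(n_rep)
  tot <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  sel_count <- stats::setNames(integer(length(feature_set)), feature_set)

  for (rep_i in seq_len(n_rep)) {
    rep_seed <- seed + (rep_i - 1L) * 10007L
    keep <- balance_classes(labels, seed = rep_seed)
    v <- vals[keep, , drop = FALSE]
    lab <- labels[keep]
    set.seed(rep_seed + 1L)
    fold <- stratified_folds(lab, k)
    rep_counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(lab[!tr])) < 2L || length(unique(lab[tr])) < 2L)
        stop("fold with a single class; increase sample size")
      selected <- select_features(v[tr, , drop = FALSE], lab[tr],
                                  kinds = kinds[feature_set], alpha = alpha)
      used <- if (length(selected)) selected else feature_set
      xtr <- as.matrix(v[tr, used, drop = FALSE])
      xte <- as.matrix(v[!tr, used, drop = FALSE])
      med <- apply(xtr, 2, stats::median, na.rm = TRUE)
      med[is.na(med)] <- 0
      for (j in seq_along(used)) {
        xtr[is.na(xtr[, j]), j] <- med[j]
        xte[is.na(xte[, j]), j] <- med[j]
      }
      scaler <- fit_scaler(xtr)
      xtr <- apply_scaler(scaler, xtr)
      xte <- apply_scaler(scaler, xte)
      ytr <- as.integer(lab[tr] == "target")
      yte <- as.integer(lab[!tr] == "target")
      set.seed(rep_seed + 100L + f)
      fit <- train_model(xtr, ytr, config)
      pred <- predict_model(fit, xte, config)
      cts <- c(TP = sum(pred == 1 & yte == 1), FP = sum(pred == 1 & yte == 0),
               TN = sum(pred == 0 & yte == 0), FN = sum(pred == 0 & yte == 1))
      rep_counts <- rep_counts + cts
      sel_count[selected] <- sel_count[selected] + 1L
      folds_out[[length(folds_out) + 1L]] <- list(
        repetition = rep_i, fold = f,
        selected = selected, selection_empty = length(selected) == 0L,
        metrics = compute_metrics(cts["TP"], cts["FP"], cts["TN"], cts["FN"]))
    }
    tot <- tot + rep_counts
    rep_f1[rep_i] <- compute_metrics(rep_counts["TP"], rep_counts["FP"],
                                     rep_counts["TN"], rep_counts["FN"])$f1
  }

  n_folds <- k * n_rep
  selection <- data.frame(
    feature = feature_set,
    folds_selected = unname(sel_count),
    n_folds = n_folds,
    status = ifelse(sel_count == n_folds, "always",
                    ifelse(sel_count == 0L, "never", "partially")),
    stringsAsFactors = FALSE)

  out <- list(scheme = scheme,
              pooled = compute_metrics(tot["TP"], tot["FP"],
                                       tot["TN"], tot["FN"]),
              folds = folds_out,
              f1_mean = mean(rep_f1),
              f1_sd = if (n_rep > 1L) stats::sd(rep_f1) else NA_real_,
              selection = selection, seed = seed)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$pooled
  cat(sprintf("cv_result (%s, seed %d): recall %.4f  precision %.4f  F1 %.4f\n",
              x$scheme, x$seed, m$recall, m$precision, m$f1))
  if (!is.na(x$f1_sd))
    cat(sprintf("  F1 across repetitions: %.4f +/- %.4f\n",
                x$f1_mean, x$f1_sd))
  invisible(x)
}
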