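# Two-group feature screening: Pearson chi-square for discrete features,
# Wilcoxon rank-sum for continuous ones, and a generic one-sided exact
# (hypergeometric) enrichment test for category tables.

#' Pearson chi-square test on a 2x2 table
#'
#' One degree of freedom, no continuity correction by default (a flag
#' enables Yates' correction); p from the upper chi-square tail.
#'
#' @param a,b,c,d cell counts: rows are groups, columns presence/absence
#' @param correct apply Yates' continuity correction (default FALSE)
#' @return list with `statistic` and `p_value`
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: zero margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties; exact p-value when min(n, m) <= 8 and the data are
#' untied, normal approximation with tie correction otherwise; two-sided.
#'
#' @param x,y numeric samples (non-empty)
#' @return list with `statistic` (Mann-Whitney U for x) and `p_value`
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- min(length(x), length(y)) <= 8L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' One-sided exact enrichment of categories in a foreground set
#'
#' Per category, the hypergeometric upper-tail probability of drawing at
#' least the observed number of category members when sampling the
#' foreground from the background without replacement; reported with
#' -log2(p).
#'
#' @param category_table data.frame with columns `accession`, `category`
#' @param foreground,background character vectors of accessions; foreground
#'   must be a subset of background
#' @return data.frame: category, n_category, n_foreground, overlap,
#'   p_value, neg_log2_p
#' @export
enrich_categories <- function(category_table, foreground, background) {
  if (!all(foreground %in% background))
    stop("foreground is not a subset of background")
  background <- unique(background)
  foreground <- unique(foreground)
  cats <- split(category_table$accession, category_table$category)
  rows <- lapply(names(cats), function(cat) {
    members <- intersect(unique(cats[[cat]]), background)
    k <- length(intersect(members, foreground))
    m <- length(members)
    p <- if (m == 0L) 1 else
      stats::phyper(k - 1, m, length(background) - m, length(foreground),
                    lower.tail = FALSE)
    data.frame(category = cat, n_category = m,
               n_foreground = length(foreground), overlap = k,
               p_value = p, neg_log2_p = -log2(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Feature-by-feature comparison of targets vs nontargets
#'
#' Discrete (0/1) features are tested with the 2x2 chi-square on presence
#' counts, continuous features with the Wilcoxon rank-sum test. Missing
#' values are dropped pairwise per feature. Features with fewer than two
#' distinct observed values (or an empty group) are flagged untestable
#' rather than raising. Benjamini-Hochberg q-values are added as an
#' extension; downstream selection consumes the raw p-values.
#'
#' @param features `feature_matrix` (or a plain data.frame of values with a
#'   `kinds` attribute supplied via `kinds`)
#' @param labels character vector parallel to the rows, values
#'   target/nontarget
#' @param kinds optional named kind vector overriding `features$kinds`
#' @return data.frame: feature, kind, test, statistic, p_value, q_value,
#'   summary_target, summary_nontarget (proportion for discrete, median for
#'   continuous), n_target, n_nontarget, untestable
#' @export
property_table <- function(features, labels, kinds = NULL) {
  vals <- if (inherits(features, "feature_matrix")) features$values else features
  if (is.null(kinds))
    kinds <- if (inherits(features, "feature_matrix")) features$kinds
             else stop("kinds required for plain data.frame input")
  stopifnot(length(labels) == nrow(vals))
  is_t <- labels == "target"
  rows <- lapply(names(vals), function(feat) {
    v <- vals[[feat]]
    ok <- !is.na(v)
    x <- v[ok & is_t]; y <- v[ok & !is_t]
    kind <- kinds[[feat]]
    base <- data.frame(feature = feat, kind = kind, test = NA_character_,
                       statistic = NA_real_, p_value = NA_real_,
                       summary_target = NA_real_,
                       summary_nontarget = NA_real_,
                       n_target = length(x), n_nontarget = length(y),
                       untestable = FALSE, stringsAsFactors = FALSE)
    if (length(x) == 0L || length(y) == 0L ||
        length(unique(c(x, y))) < 2L) {
      base$untestable <- TRUE
      return(base)
    }
    if (kind == "discrete") {
      base$test <- "chi_square"
      base$summary_target <- mean(x)
      base$summary_nontarget <- mean(y)
      tab <- c(sum(x == 1), sum(x == 0), sum(y == 1), sum(y == 0))
      if (sum(x == 1) + sum(y == 1) == 0 || sum(x == 0) + sum(y == 0) == 0) {
        base$untestable <- TRUE
        return(base)
      }
      res <- chi_square_2x2(tab[1], tab[2], tab[3], tab[4])
    } else {
      base$test <- "wilcoxon"
      base$summary_target <- stats::median(x)
      base$summary_nontarget <- stats::median(y)
      res <- wilcoxon_rank_sum(x, y)
    }
    base$statistic <- res$statistic
    base$p_value <- res$p_value
    base
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$q_value <- NA_real_
  testable <- !out$untestable
  out$q_value[testable] <- stats::p.adjust(out$p_value[testable],
                                           method = "BH")
  out
}
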