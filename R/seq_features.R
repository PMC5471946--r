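# Sequence-derived physicochemical descriptors.
#
# Nonstandard residues (X, B, Z, U) are excluded from composition
# denominators and from pI / PEST / moment scoring; a sequence that becomes
# empty after exclusion is rejected.

split_residues <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

standard_residues <- function(sequence) {
  r <- split_residues(sequence)
  r[r %in% AA20]
}

#' Amino-acid composition and group fractions
#'
#' Fractions of the 20 standard residues (summing to 1 over the standard
#' residues of the sequence) plus the nine physicochemical group fractions.
#'
#' @param sequence amino-acid string
#' @param groups grouping table, a named list of residue sets
#'   (default [default_aa_groups()])
#' @return list with `aa` (20 named fractions) and `groups` (named fractions)
#' @export
composition <- function(sequence, groups = default_aa_groups()) {
  r <- standard_residues(sequence)
  if (length(r) == 0L)
    stop("no standard residues left in sequence after exclusions")
  counts <- table(factor(r, levels = AA20))
  aa <- as.numeric(counts) / length(r)
  names(aa) <- AA20
  grp <- vapply(groups, function(g) sum(aa[g]), numeric(1))
  list(aa = aa, groups = grp)
}

#' Hydrophobic moment
#'
#' Amphipathicity statistic: residues of a window are placed at successive
#' angular increments delta around a helical wheel and their hydrophobicities
#' summed as vectors,
#' muH = sqrt((sum Hi sin(i delta))^2 + (sum Hi cos(i delta))^2),
#' i = 0..window-1. The per-protein score is the maximum over all windows.
#'
#' @param sequence amino-acid string (nonstandard residues excluded first)
#' @param scale named hydrophobicity scale (default Eisenberg normalized
#'   consensus)
#' @param window window length in residues (default 10); must not exceed the
#'   effective sequence length
#' @param angle_deg angular increment in degrees (default 100, alpha helix)
#' @return maximum window moment (numeric scalar)
#' @export
hydrophobic_moment <- function(sequence, scale = EISENBERG_SCALE,
                               window = 10L, angle_deg = 100) {
  if (window < 1L) stop("window must be >= 1")
  r <- standard_residues(sequence)
  if (length(r) < window)
    stop("sequence shorter than window (", length(r), " < ", window, ")")
  h <- unname(scale[r])
  delta <- angle_deg * pi / 180
  ang <- (seq_len(window) - 1L) * delta
  n_win <- length(h) - window + 1L
  idx <- outer(seq_len(n_win) - 1L, seq_len(window), "+")
  hw <- matrix(h[idx], nrow = n_win)
  sin_part <- hw %*% sin(ang)
  cos_part <- hw %*% cos(ang)
  max(sqrt(sin_part^2 + cos_part^2))
}

net_charge_at_ph <- function(ph, counts, pka) {
  basic <- c(nterm = 1, K = counts["K"], R = counts["R"], H = counts["H"])
  acidic <- c(cterm = 1, D = counts["D"], E = counts["E"],
              C = counts["C"], Y = counts["Y"])
  pkb <- c(pka$nterm, pka$K, pka$R, pka$H)
  pka_ <- c(pka$cterm, pka$D, pka$E, pka$C, pka$Y)
  sum(basic / (1 + 10^(ph - pkb))) - sum(acidic / (1 + 10^(pka_ - ph)))
}

#' Isoelectric point by bisection
#'
#' Solves net charge(pH) = 0 on [0, 14], where the net charge is the
#' Henderson-Hasselbalch sum over the termini (always counted once each) and
#' the ionizable side chains K, R, H (basic) and D, E, C, Y (acidic). The net
#' charge is strictly decreasing in pH, so the root is unique.
#'
#' @param sequence amino-acid string
#' @param pka pKa table from [default_pka_table()]
#' @param tol bisection tolerance on pH (default 1e-4)
#' @return pH value
#' @export
isoelectric_point <- function(sequence, pka = default_pka_table(),
                              tol = 1e-4) {
  r <- standard_residues(sequence)
  if (length(r) == 0L)
    stop("no standard residues left in sequence after exclusions")
  counts <- table(factor(r, levels = AA20))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(mid, counts, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Solubility on overexpression (Wilkinson-Harrison model)
#'
#' Two-parameter canonical-variable model of the probability of soluble
#' expression (the improbability of inclusion-body formation): the canonical
#' variable combines the turn-forming residue fraction (N, G, P, S) and the
#' absolute deviation of the mean charge (R + K - D - E)/n from 0.03,
#' CV = lambda1 (N+G+P+S)/n + lambda2 |charge/n - 0.03|,
#' and the discriminant CV' = CV - midpoint is mapped through the published
#' quadratic to a probability, reported for the soluble side and clamped to
#' [0, 1]. Depends on composition only, so it is invariant to sequence
#' repetition.
#'
#' @param sequence amino-acid string
#' @param lambda1,lambda2,midpoint model coefficients (defaults 15.43,
#'   -29.56, 1.71)
#' @return probability-like score in [0, 1]; higher = more soluble
#' @export
solubility <- function(sequence, lambda1 = 15.43, lambda2 = -29.56,
                       midpoint = 1.71) {
  r <- standard_residues(sequence)
  if (length(r) == 0L)
    stop("no standard residues left in sequence after exclusions")
  n <- length(r)
  turn <- sum(r %in% c("N", "G", "P", "S")) / n
  charge <- (sum(r == "R") + sum(r == "K") - sum(r == "D") - sum(r == "E")) / n
  cv <- lambda1 * turn + lambda2 * abs(charge - 0.03)
  cvp <- cv - midpoint
  prob <- 0.4934 + 0.276 * abs(cvp) - 0.0392 * cvp^2
  score <- if (cvp < 0) prob else 1 - prob
  min(max(score, 0), 1)
}

pest_hydro_index <- function() 10 * KYTE_DOOLITTLE + 45

score_pest_stretch <- function(residues) {
  mass <- RESIDUE_MASS[residues]
  total_mass <- sum(mass)
  depst <- residues %in% c("D", "E", "P", "S", "T")
  depst_mass <- sum(mass[depst])
  # one equivalent each of P, D/E and S/T is required for candidacy and is
  # removed from the enrichment numerator
  remove <- RESIDUE_MASS[["P"]]
  remove <- remove + if (any(residues == "E")) RESIDUE_MASS[["E"]] else RESIDUE_MASS[["D"]]
  remove <- remove + if (any(residues == "S")) RESIDUE_MASS[["S"]] else RESIDUE_MASS[["T"]]
  depst_pct <- 100 * max(depst_mass - remove, 0) / total_mass
  hi <- pest_hydro_index()
  hydro <- sum(hi[residues]) / length(residues)
  0.55 * depst_pct - 0.5 * hydro
}

#' Find PEST regions
#'
#' Candidate PEST regions are internal stretches of at least 12 residues
#' bounded by K/R/H (or the sequence termini), free of internal K/R/H, and
#' containing at least one P, one D or E, and one S or T. Each candidate is
#' scored as 0.55 x (mass percent of D/E/P/S/T after removing one required
#' equivalent each of P, D/E and S/T) minus 0.5 x (mean Kyte-Doolittle
#' hydropathy rescaled to [0, 90]); a region is valid when its score reaches
#' the threshold (default +5.0).
#'
#' @param sequence amino-acid string
#' @param threshold validity threshold on the score (default 5.0)
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   coordinates of the internal stretch), `score`, `valid`
#' @export
find_pest <- function(sequence, threshold = 5.0) {
  r <- split_residues(sequence)
  if (length(r) == 0L) stop("empty sequence")
  flank <- r %in% c("K", "R", "H")
  bounds <- c(0L, which(flank), length(r) + 1L)
  out <- data.frame(start = integer(), end = integer(),
                    score = numeric(), valid = logical())
  for (b in seq_len(length(bounds) - 1L)) {
    s <- bounds[b] + 1L
    e <- bounds[b + 1L] - 1L
    if (e - s + 1L < 12L) next
    stretch <- r[s:e]
    stretch <- stretch[stretch %in% AA20]
    if (length(stretch) < 12L) next
    if (!any(stretch == "P")) next
    if (!any(stretch %in% c("D", "E"))) next
    if (!any(stretch %in% c("S", "T"))) next
    sc <- score_pest_stretch(stretch)
    out <- rbind(out, data.frame(start = s, end = e, score = sc,
                                 valid = sc >= threshold))
  }
  out
}
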