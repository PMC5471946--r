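# Annotation-derived features: subcellular-location consensus, PTM
# proportions (overall and solvent-accessible), mean accessibility,
# essentiality flags, expression level and tissue-specificity tau.

#' Consensus subcellular localization
#'
#' Curated sources win outright: if any curated call exists for a protein,
#' its assigned locations are the union of curated calls (a protein's first
#' curated source takes precedence conceptually, but unions are reported, so
#' order does not change the assignment set). Otherwise a location is
#' assigned iff at least 3 of the (up to 5) prediction tools call it.
#' Proteins may end with no location.
#'
#' @param calls long data.frame: accession, source, source_type
#'   (curated/predicted), location (ten-term vocabulary)
#' @param min_votes prediction agreement threshold (default 3)
#' @return list with `locations` (named list accession -> character vector)
#'   and `provenance` (named character: "curated" or "prediction_vote")
#' @export
consensus_localization <- function(calls, min_votes = 3L) {
  locations <- list()
  provenance <- character()
  by_acc <- split(seq_len(nrow(calls)), calls$accession)
  for (a in names(by_acc)) {
    sub <- calls[by_acc[[a]], , drop = FALSE]
    cur <- sub[sub$source_type == "curated", , drop = FALSE]
    if (nrow(cur) > 0L) {
      locations[[a]] <- sort(unique(cur$location))
      provenance[a] <- "curated"
    } else {
      n_src <- length(unique(sub$source))
      if (n_src > 5L)
        stop("more than 5 predicted localization sources for ", a)
      votes <- table(unique(sub[c("source", "location")])$location)
      hit <- names(votes)[votes >= min_votes]
      locations[[a]] <- sort(hit)
      provenance[a] <- "prediction_vote"
    }
  }
  list(locations = locations, provenance = provenance)
}

#' PTM proportions and mean solvent accessibility for one protein
#'
#' Per PTM type the proportion of modified residues is the number of distinct
#' modified positions divided by the sequence length; the solvent-accessible
#' variant restricts to positions whose accessibility score reaches the
#' exposure threshold. A residue carrying two PTM types counts once per type.
#'
#' @param sites data.frame of PTM sites for this protein (position, type)
#' @param profile per-residue accessibility scores (0-99) or NULL if the
#'   protein has no profile; accessible variants and mean accessibility are
#'   then NA
#' @param sequence_length protein length in residues
#' @param exposure_threshold minimum score to count a residue as exposed
#'   (default 25)
#' @param accession identifier used in error messages
#' @return named list: ptm_<type>, ptm_<type>_acc for the three types, and
#'   mean_accessibility
#' @export
ptm_features <- function(sites, profile, sequence_length,
                         exposure_threshold = 25, accession = "?") {
  if (nrow(sites) > 0L && any(sites$position > sequence_length))
    stop("PTM position beyond sequence length for ", accession)
  if (!is.null(profile) && length(profile) != sequence_length)
    stop("accessibility profile length mismatch for ", accession)
  out <- list()
  for (type in ptm_types()) {
    pos <- unique(sites$position[sites$type == type])
    out[[paste0("ptm_", type)]] <- length(pos) / sequence_length
    out[[paste0("ptm_", type, "_acc")]] <-
      if (is.null(profile)) NA_real_
      else sum(profile[pos] >= exposure_threshold) / sequence_length
  }
  out$mean_accessibility <- if (is.null(profile)) NA_real_ else mean(profile)
  out
}

#' Expression level and tissue-specificity tau for one gene
#'
#' Probes flagged as hitting multiple genes are discarded; among the
#' remaining probes for the gene the one with the highest mean across tissues
#' is used (ties broken by lowest probe identifier). The expression level S
#' is the mean across tissues. Tau floors each tissue value at `floor`
#' (default 100) to damp microarray noise, then
#' tau = sum_j (1 - log2 S(j) / log2 Smax) / (n - 1),
#' giving 0 for uniform expression and approaching 1 for single-tissue
#' expression.
#'
#' @param expression `expression_matrix`
#' @param gene gene identifier
#' @param floor expression floor applied inside tau (default 100)
#' @return list with `expr_level` and `expr_tau`; both NA if the gene is hit
#'   only by multi-gene probes or not at all
#' @export
expression_features <- function(expression, gene, floor = 100) {
  pg <- expression$probe_gene
  probes <- pg$probe[pg$gene == gene & !pg$multi_gene]
  if (length(probes) == 0L)
    return(list(expr_level = NA_real_, expr_tau = NA_real_))
  vals <- expression$values[probes, , drop = FALSE]
  means <- rowMeans(vals)
  best <- probes[order(-means, probes)][1]
  s <- expression$values[best, ]
  sj <- pmax(s, floor)
  smax <- max(sj)
  n <- length(sj)
  tau <- sum(1 - log2(sj) / log2(smax)) / (n - 1)
  list(expr_level = mean(s), expr_tau = tau)
}

#' Essentiality flags
#'
#' Maps the three-valued essentiality annotation to two 0/1 indicator
#' columns; unknown maps to (0, 0).
#' @param essentiality character vector of
#'   essential/nonessential/unknown
#' @return list with numeric vectors `essential` and `nonessential`
#' @export
essentiality_features <- function(essentiality) {
  list(essential = as.numeric(essentiality == "essential"),
       nonessential = as.numeric(essentiality == "nonessential"))
}
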