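# Construction of the four nested datasets controlling paralog redundancy:
#   A  all labeled proteins
#   B  one representative per gene family within each label group
#      (longest CDS; ties by lexicographically smallest accession)
#   C  A with all nontarget members of mixed-label families removed
#   D  B with nontarget representatives of mixed-label families removed
# A mixed family has at least one target and one nontarget member; mixing is
# evaluated on dataset A membership, so only nontargets are ever excluded and
# target counts are preserved A -> C and B -> D.

#' Group proteins into gene families
#'
#' A family requires at least two members: proteins with no `family_id`, and
#' families with a single member, are treated as singletons.
#'
#' @param records `protein_records`
#' @return character vector of effective family ids, parallel to records;
#'   singletons get the unique id `"singleton:<accession>"`
#' @export
define_families <- function(records) {
  fam <- records$family_id
  fam[is.na(fam) | !nzchar(fam)] <- NA_character_
  counts <- table(fam[!is.na(fam)])
  single <- is.na(fam) | fam %in% names(counts)[counts < 2L]
  fam[single] <- paste0("singleton:", records$accession[single])
  fam
}

#' Build datasets A, B, C and D
#'
#' @param records `protein_records`; every record must be labeled. For
#'   multi-member families lacking `cds_length`, 3 x protein length
#'   substitutes, preserving the longest-CDS ordering intent.
#' @param families effective family ids from [define_families()] (computed
#'   if omitted)
#' @return object of class `dataset_quad`: list with `datasets` (named list
#'   A/B/C/D, each with character vectors `targets` and `nontargets`),
#'   `counts` (Table-1-shaped data.frame) and `provenance` (data.frame of
#'   removed accessions with dataset and reason)
#' @export
build_datasets <- function(records, families = define_families(records)) {
  if (any(is.na(records$label)))
    stop("unlabeled record(s): ",
         paste(records$accession[is.na(records$label)], collapse = ", "))
  acc <- records$accession
  lab <- records$label
  cds <- records$cds_length
  cds[is.na(cds)] <- 3 * nchar(records$sequence[is.na(cds)])

  is_target <- lab == "target"
  fam_has_t <- tapply(is_target, families, any)
  fam_has_n <- tapply(!is_target, families, any)
  mixed_fams <- names(fam_has_t)[fam_has_t & fam_has_n]

  # representative per (label, family): longest CDS, ties to smallest accession
  key <- paste(lab, families, sep = "\r")
  ord <- order(key, -cds, acc)
  rep_idx <- ord[!duplicated(key[ord])]
  in_b <- logical(length(acc))
  in_b[rep_idx] <- TRUE

  in_mixed <- families %in% mixed_fams
  sets <- list(
    A = list(targets = acc[is_target], nontargets = acc[!is_target]),
    B = list(targets = acc[is_target & in_b],
             nontargets = acc[!is_target & in_b]),
    C = list(targets = acc[is_target],
             nontargets = acc[!is_target & !in_mixed]),
    D = list(targets = acc[is_target & in_b],
             nontargets = acc[!is_target & in_b & !in_mixed]))

  prov_entry <- function(accessions, dataset, reason) {
    data.frame(accession = accessions,
               dataset = rep_len(dataset, length(accessions)),
               reason = rep_len(reason, length(accessions)),
               stringsAsFactors = FALSE)
  }
  prov <- rbind(
    prov_entry(acc[!in_b], "B",
               "family deduplication (not longest CDS)"),
    prov_entry(acc[!is_target & in_mixed], "C",
               "nontarget in mixed-label family"),
    prov_entry(acc[!is_target & in_b & in_mixed], "D",
               "nontarget representative of mixed-label family"))

  counts <- data.frame(
    dataset = names(sets),
    n_target = vapply(sets, function(s) length(s$targets), integer(1)),
    n_nontarget = vapply(sets, function(s) length(s$nontargets), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  out <- list(datasets = sets, counts = counts, provenance = prov)
  class(out) <- "dataset_quad"
  out
}

#' @export
print.dataset_quad <- function(x, ...) {
  cat("dataset_quad (targets / nontargets):\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %s: %d / %d\n", x$counts$dataset[i],
                x$counts$n_target[i], x$counts$n_nontarget[i]))
  invisible(x)
}
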