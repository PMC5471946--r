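# Data model and file I/O shared by all pipeline stages.
#
# On-disk formats: FASTA for sequences; tab-delimited UTF-8 TSV with a header
# row for annotations, PTM sites, accessibility profiles and expression; the
# feature matrix is TSV plus a JSON sidecar recording each column's kind.

#' Assemble a protein record table
#'
#' The central record type of the pipeline: one row per protein with its
#' sequence, target label, optional gene-family id and optional CDS length.
#'
#' @param accession character vector of unique identifiers
#' @param sequence amino-acid strings (20 standard letters, optionally
#'   X/B/Z/U); uppercased, `*` stop characters stripped
#' @param label `"target"` or `"nontarget"`, recycled if length 1
#' @param family_id gene-family identifier or `NA` (singleton family)
#' @param cds_length coding-sequence length in nucleotides or `NA`
#' @return data.frame of class `protein_records`
#' @export
protein_records <- function(accession, sequence, label,
                            family_id = NA_character_,
                            cds_length = NA_real_) {
  accession <- as.character(accession)
  sequence <- toupper(gsub("*", "", as.character(sequence), fixed = TRUE))
  if (anyDuplicated(accession))
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for: ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYXBZU]*$", sequence)
  if (any(bad))
    stop("non-amino-acid characters in sequence of: ",
         paste(accession[bad], collapse = ", "))
  label <- rep_len(as.character(label), length(accession))
  if (!all(label %in% c("target", "nontarget")))
    stop("label must be 'target' or 'nontarget'")
  out <- data.frame(accession = accession, sequence = sequence,
                    label = label,
                    family_id = rep_len(as.character(family_id),
                                        length(accession)),
                    cds_length = rep_len(as.numeric(cds_length),
                                         length(accession)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a FASTA file of protein sequences
#'
#' Sequences are uppercased and `*` stop characters stripped; record order is
#' preserved. Duplicate accessions and malformed leading content are errors.
#'
#' @param path FASTA file
#' @return data.frame with columns `accession`, `sequence`
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L)
    return(data.frame(accession = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("malformed FASTA: line ", nonempty[1],
         " is not a header ('>') record")
  set <- Biostrings::readBStringSet(path)
  acc <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  data.frame(accession = acc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param records data.frame with `accession` and `sequence` columns
#' @param path output file
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$accession
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Localization column convention in the annotation TSV: `loc_curated_<src>`
# and `loc_pred_<src>` hold semicolon-separated vocabulary terms.
parse_loc_columns <- function(df) {
  loc_cols <- grep("^loc_(curated|pred)_", names(df), value = TRUE)
  vocab <- location_vocabulary()
  out <- list()
  for (col in loc_cols) {
    type <- if (grepl("^loc_curated_", col)) "curated" else "predicted"
    src <- sub("^loc_(curated|pred)_", "", col)
    vals <- as.character(df[[col]])
    has <- !is.na(vals) & nzchar(vals)
    if (!any(has)) next
    terms <- strsplit(vals[has], ";", fixed = TRUE)
    long <- data.frame(
      accession = rep(df$accession[has], lengths(terms)),
      source = src, source_type = type,
      location = trimws(unlist(terms)),
      stringsAsFactors = FALSE)
    bad <- setdiff(unique(long$location), vocab)
    if (length(bad))
      stop("unknown subcellular location term(s) in column '", col, "': ",
           paste(bad, collapse = ", "))
    out[[col]] <- long
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(accession = character(), source = character(),
                  source_type = character(), location = character(),
                  stringsAsFactors = FALSE)
}

#' Read the per-protein annotation table
#'
#' Expects a TSV with header and columns `accession`, `ec` (semicolon-joined
#' primary EC classes 1-6), `signal_peptide` (0/1), `tm_helix_count`,
#' `ss_helix`, `ss_strand`, `ss_coil`, `essentiality`
#' (essential/nonessential/empty), plus any number of localization columns
#' `loc_curated_<source>` / `loc_pred_<source>` holding semicolon-separated
#' terms from the ten-term vocabulary. Missing cells become `NA`/unknown;
#' unknown location terms are an error.
#'
#' @param path TSV file
#' @return object of class `annotation_table` with elements `proteins`
#'   (per-accession data.frame), `ec` (named list of integer vectors) and
#'   `localization` (long data.frame: accession, source, source_type,
#'   location)
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  if (!"accession" %in% names(df)) stop("annotation TSV lacks 'accession'")
  annotation_table_from_df(df)
}

annotation_table_from_df <- function(df) {
  n <- nrow(df)
  getcol <- function(name) if (name %in% names(df)) df[[name]] else rep("", n)
  num_or_na <- function(x) {
    x[!nzchar(x)] <- NA_character_
    as.numeric(x)
  }
  ess <- getcol("essentiality")
  ess[!nzchar(ess)] <- "unknown"
  if (!all(ess %in% c("essential", "nonessential", "unknown")))
    stop("invalid essentiality value(s): ",
         paste(setdiff(unique(ess),
                       c("essential", "nonessential", "unknown")),
               collapse = ", "))
  sp <- getcol("signal_peptide")
  sp_val <- rep(NA, n)
  sp_val[sp %in% c("1", "TRUE", "true")] <- TRUE
  sp_val[sp %in% c("0", "FALSE", "false")] <- FALSE
  ec_raw <- getcol("ec")
  ec <- lapply(ec_raw, function(x) {
    if (!nzchar(x)) return(integer(0))
    v <- suppressWarnings(as.integer(strsplit(x, ";", fixed = TRUE)[[1]]))
    if (anyNA(v) || any(v < 1L | v > 6L))
      stop("invalid EC class specification: '", x, "'")
    sort(unique(v))
  })
  names(ec) <- df$accession
  ssf <- cbind(num_or_na(getcol("ss_helix")), num_or_na(getcol("ss_strand")),
               num_or_na(getcol("ss_coil")))
  ok <- is.na(ssf) | (ssf >= 0 & ssf <= 1)
  if (!all(ok)) stop("secondary-structure fractions must lie in [0,1]")
  proteins <- data.frame(
    accession = df$accession,
    signal_peptide = sp_val,
    tm_helix_count = num_or_na(getcol("tm_helix_count")),
    ss_helix = ssf[, 1], ss_strand = ssf[, 2], ss_coil = ssf[, 3],
    essentiality = ess, stringsAsFactors = FALSE)
  out <- list(proteins = proteins, ec = ec,
              localization = parse_loc_columns(df))
  class(out) <- "annotation_table"
  out
}

#' Read PTM sites (TSV: accession, position, residue, type)
#'
#' Types are restricted to phosphorylation / ubiquitination / acetylation;
#' phosphorylation residues must be S, T or Y. Positions are 1-based.
#' @param path TSV file
#' @return data.frame with columns accession, position, residue, type
#' @export
read_ptm_sites <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("accession", "position", "residue", "type")
  if (!all(need %in% names(df)))
    stop("PTM TSV needs columns: ", paste(need, collapse = ", "))
  df$position <- as.integer(df$position)
  if (any(df$position < 1L)) stop("PTM positions must be >= 1")
  bad <- setdiff(unique(df$type), ptm_types())
  if (length(bad)) stop("unknown PTM type(s): ", paste(bad, collapse = ", "))
  phos <- df$type == "phosphorylation"
  if (any(phos & !df$residue %in% c("S", "T", "Y")))
    stop("phosphorylation sites must be on S, T or Y")
  df[need]
}

#' Read per-residue solvent-accessibility profiles
#'
#' TSV columns accession, position (1-based), score (integer 0-99, 0 fully
#' buried and 99 fully exposed). Returns one numeric vector per accession,
#' ordered by position.
#' @param path TSV file
#' @return named list of integer vectors
#' @export
read_accessibility <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("accession", "position", "score")
  if (!all(need %in% names(df)))
    stop("accessibility TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$score < 0 | df$score > 99))
    stop("accessibility scores must lie in [0, 99]")
  df <- df[order(df$accession, df$position), ]
  profs <- split(as.integer(df$score), df$accession)
  pos <- split(as.integer(df$position), df$accession)
  ok <- vapply(pos, function(p) identical(p, seq_along(p)), logical(1))
  if (!all(ok))
    stop("non-contiguous accessibility positions for: ",
         paste(names(profs)[!ok], collapse = ", "))
  profs
}

#' Read a probe-level expression matrix
#'
#' TSV columns: `probe`, `gene`, `multi_gene` (0/1 flag marking probes that
#' hit more than one gene), then one column per tissue.
#' @param path TSV file
#' @return object of class `expression_matrix`: list with `values` (probe x
#'   tissue numeric matrix), `probe_gene` (probe, gene, multi_gene) and
#'   `n_tissues`
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe", "gene", "multi_gene")
  if (!all(need %in% names(df)))
    stop("expression TSV needs columns: ", paste(need, collapse = ", "))
  tissue_cols <- setdiff(names(df), need)
  vals <- as.matrix(df[tissue_cols])
  if (any(vals < 0)) stop("expression values must be non-negative")
  rownames(vals) <- df$probe
  out <- list(values = vals,
              probe_gene = data.frame(probe = df$probe, gene = df$gene,
                                      multi_gene = df$multi_gene == 1,
                                      stringsAsFactors = FALSE),
              n_tissues = length(tissue_cols))
  class(out) <- "expression_matrix"
  out
}

#' Default feature registry
#'
#' The 67 named descriptors the pipeline computes by default: 47 continuous
#' (length; 20 amino-acid fractions; 9 group fractions; hydrophobic moment;
#' pI; solubility; PEST count; TM helix count; 3 secondary-structure
#' fractions; 6 PTM proportions, overall and solvent-accessible, for the
#' three PTM types; mean accessibility; expression level; tau) and 20
#' discrete 0/1 flags (enzyme + 6 EC classes; signal peptide; 10 subcellular
#' locations; essential; nonessential).
#'
#' @return data.frame with columns `name` and `kind`
#'   (`"continuous"`/`"discrete"`), in the canonical column order
#' @export
default_feature_registry <- function() {
  loc_flags <- paste0("loc_", gsub(" ", "_", location_vocabulary()))
  cont <- c("length",
            paste0("frac_", AA20),
            paste0("grp_", names(default_aa_groups())),
            "hmoment", "pI", "solubility", "pest_count",
            "tm_helix_count", "ss_helix", "ss_strand", "ss_coil",
            paste0("ptm_", ptm_types()),
            paste0("ptm_", ptm_types(), "_acc"),
            "mean_accessibility", "expr_level", "expr_tau")
  disc <- c("is_enzyme", paste0("ec_", 1:6), "signal_peptide",
            loc_flags, "essential", "nonessential")
  data.frame(name = c(cont, disc),
             kind = c(rep("continuous", length(cont)),
                      rep("discrete", length(disc))),
             stringsAsFactors = FALSE)
}

#' Named feature subsets used by the classifier
#'
#' `W` are the widely used descriptors (sequence-derived plus EC, signal
#' peptide, location and secondary structure); `N` the newly proposed ones
#' (PTM proportions, mean solvent accessibility, expression level, tissue
#' specificity tau and the two essentiality flags). `WN` is their union.
#' @return named list of character vectors of registry names
#' @export
feature_sets <- function() {
  reg <- default_feature_registry()$name
  N <- c(paste0("ptm_", ptm_types()), paste0("ptm_", ptm_types(), "_acc"),
         "mean_accessibility", "expr_level", "expr_tau",
         "essential", "nonessential")
  W <- setdiff(reg, N)
  list(W = W, N = N, WN = reg)
}

#' Pipeline configuration defaults
#'
#' Tunables consumed by the feature computations: hydrophobic-moment window
#' and helix angle, hydrophobicity scale, pKa table, amino-acid grouping
#' table, solubility-model coefficients, PEST validity threshold, PTM
#' exposure threshold and the tau floor/tissue count.
#' @param ... name = value overrides of any default
#' @return named list
#' @export
default_config <- function(...) {
  cfg <- list(
    hmoment_window = 10L, hmoment_angle = 100,
    hydrophobicity_scale = EISENBERG_SCALE,
    pka = default_pka_table(),
    aa_groups = default_aa_groups(),
    solubility_lambda1 = 15.43, solubility_lambda2 = -29.56,
    solubility_midpoint = 1.71,
    pest_threshold = 5.0,
    exposure_threshold = 25,
    tau_floor = 100, n_tissues = 79L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Assemble the feature matrix for a set of proteins
#'
#' Computes every requested registry feature for every record. Features whose
#' underlying table lacks a protein are `NA` (missing, not zero); requesting
#' a feature whose input table was not supplied at all is an error naming the
#' feature.
#'
#' @param records `protein_records`
#' @param tables named list with any of `annotations` (annotation_table),
#'   `ptm` (PTM site data.frame), `accessibility` (named list of profiles),
#'   `expression` (expression_matrix). The expression `gene` identifiers are
#'   matched against record accessions.
#' @param features character vector of registry names (default: all 67)
#' @param config list from [default_config()]
#' @return object of class `feature_matrix`: list with `values` (data.frame,
#'   rownames = accessions) and `kinds` (named character)
#' @export
build_feature_matrix <- function(records, tables = list(),
                                 features = default_feature_registry()$name,
                                 config = default_config()) {
  reg <- default_feature_registry()
  unknown <- setdiff(features, reg$name)
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  needs <- function(pat) any(grepl(pat, features))
  if (needs("^(is_enzyme|ec_|signal_peptide|loc_|essential|nonessential|tm_helix_count|ss_)") &&
      is.null(tables$annotations))
    stop("feature(s) ",
         paste(grep("^(is_enzyme|ec_|signal_peptide|loc_|essential|nonessential|tm_helix_count|ss_)",
                    features, value = TRUE), collapse = ", "),
         " require the 'annotations' table")
  if (needs("^ptm_") && is.null(tables$ptm))
    stop("feature(s) ", paste(grep("^ptm_", features, value = TRUE),
                              collapse = ", "),
         " require the 'ptm' table")
  if (needs("^(ptm_.*_acc$|mean_accessibility)") &&
      is.null(tables$accessibility))
    stop("feature(s) ",
         paste(grep("^(ptm_.*_acc$|mean_accessibility)", features,
                    value = TRUE), collapse = ", "),
         " require the 'accessibility' table")
  if (needs("^expr_") && is.null(tables$expression))
    stop("feature(s) ", paste(grep("^expr_", features, value = TRUE),
                              collapse = ", "),
         " require the 'expression' table")

  n <- nrow(records)
  acc <- records$accession
  vals <- matrix(NA_real_, nrow = n, ncol = length(features),
                 dimnames = list(acc, features))

  seq_feats <- intersect(features,
                         c("length", paste0("frac_", AA20),
                           paste0("grp_", names(config$aa_groups)),
                           "hmoment", "pI", "solubility", "pest_count"))
  if (length(seq_feats)) {
    for (i in seq_len(n)) {
      s <- records$sequence[i]
      if ("length" %in% seq_feats)
        vals[i, "length"] <- nchar(s)
      comp_feats <- grep("^(frac_|grp_)", seq_feats, value = TRUE)
      if (length(comp_feats)) {
        cm <- composition(s, groups = config$aa_groups)
        both <- c(stats::setNames(cm$aa, paste0("frac_", names(cm$aa))),
                  stats::setNames(cm$groups, paste0("grp_", names(cm$groups))))
        vals[i, comp_feats] <- both[comp_feats]
      }
      if ("hmoment" %in% seq_feats)
        vals[i, "hmoment"] <- hydrophobic_moment(
          s, scale = config$hydrophobicity_scale,
          window = config$hmoment_window, angle_deg = config$hmoment_angle)
      if ("pI" %in% seq_feats)
        vals[i, "pI"] <- isoelectric_point(s, pka = config$pka)
      if ("solubility" %in% seq_feats)
        vals[i, "solubility"] <- solubility(
          s, lambda1 = config$solubility_lambda1,
          lambda2 = config$solubility_lambda2,
          midpoint = config$solubility_midpoint)
      if ("pest_count" %in% seq_feats)
        vals[i, "pest_count"] <- sum(find_pest(
          s, threshold = config$pest_threshold)$valid)
    }
  }

  if (!is.null(tables$annotations)) {
    ann <- tables$annotations
    idx <- match(acc, ann$proteins$accession)
    present <- !is.na(idx)
    put <- function(feat, v) if (feat %in% features) vals[present, feat] <<- v
    put("tm_helix_count", ann$proteins$tm_helix_count[idx[present]])
    put("ss_helix", ann$proteins$ss_helix[idx[present]])
    put("ss_strand", ann$proteins$ss_strand[idx[present]])
    put("ss_coil", ann$proteins$ss_coil[idx[present]])
    put("signal_peptide",
        as.numeric(ann$proteins$signal_peptide[idx[present]]))
    ess <- essentiality_features(ann$proteins$essentiality[idx[present]])
    put("essential", ess$essential)
    put("nonessential", ess$nonessential)
    ecs <- ann$ec[acc[present]]
    put("is_enzyme", as.numeric(lengths(ecs) > 0))
    for (k in 1:6)
      put(paste0("ec_", k),
          vapply(ecs, function(e) as.numeric(k %in% e), numeric(1)))
    if (any(grepl("^loc_", features))) {
      cons <- consensus_localization(ann$localization)
      vocab <- location_vocabulary()
      loc_names <- paste0("loc_", gsub(" ", "_", vocab))
      has_src <- acc %in% ann$localization$accession
      flag_mat <- matrix(0, nrow = length(cons$locations), ncol = 10,
                         dimnames = list(names(cons$locations), vocab))
      for (a in names(cons$locations))
        flag_mat[a, cons$locations[[a]]] <- 1
      row_idx <- match(acc, rownames(flag_mat))
      for (j in seq_along(loc_names)) {
        if (!loc_names[j] %in% features) next
        assigned <- ifelse(is.na(row_idx), 0, flag_mat[cbind(row_idx, j)])
        assigned[!present & !has_src] <- NA_real_
        vals[, loc_names[j]] <- assigned
      }
    }
  }

  if (!is.null(tables$ptm)) {
    ptm_feats <- grep("^ptm_", features, value = TRUE)
    if (length(ptm_feats)) {
      ptm_by_acc <- split(seq_len(nrow(tables$ptm)), tables$ptm$accession)
      for (i in seq_len(n)) {
        sites <- tables$ptm[ptm_by_acc[[acc[i]]], , drop = FALSE]
        prof <- tables$accessibility[[acc[i]]]
        pf <- ptm_features(sites, prof, nchar(records$sequence[i]),
                           exposure_threshold = config$exposure_threshold,
                           accession = acc[i])
        keep <- intersect(names(pf), ptm_feats)
        vals[i, keep] <- unlist(pf)[keep]
      }
    }
  }

  if (!is.null(tables$accessibility) && "mean_accessibility" %in% features) {
    for (i in seq_len(n)) {
      prof <- tables$accessibility[[acc[i]]]
      if (!is.null(prof)) vals[i, "mean_accessibility"] <- mean(prof)
    }
  }

  if (!is.null(tables$expression)) {
    ef <- intersect(c("expr_level", "expr_tau"), features)
    if (length(ef)) {
      for (i in seq_len(n)) {
        ex <- expression_features(tables$expression, acc[i],
                                  floor = config$tau_floor)
        if ("expr_level" %in% ef) vals[i, "expr_level"] <- ex$expr_level
        if ("expr_tau" %in% ef) vals[i, "expr_tau"] <- ex$expr_tau
      }
    }
  }

  kinds <- stats::setNames(reg$kind[match(features, reg$name)], features)
  out <- list(values = as.data.frame(vals), kinds = kinds)
  class(out) <- "feature_matrix"
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$values), " proteins x ",
      ncol(x$values), " features (",
      sum(x$kinds == "continuous"), " continuous, ",
      sum(x$kinds == "discrete"), " discrete)\n", sep = "")
  invisible(x)
}

#' Write / read a feature matrix (TSV + JSON sidecar of column kinds)
#' @param fm `feature_matrix`
#' @param path TSV path; the sidecar is written to `<path>.kinds.json`
#' @export
write_feature_matrix <- function(fm, path) {
  df <- cbind(accession = rownames(fm$values), fm$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(fm$kinds), paste0(path, ".kinds.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  kinds <- unlist(jsonlite::read_json(paste0(path, ".kinds.json")))
  vals <- df[setdiff(names(df), "accession")]
  rownames(vals) <- df$accession
  out <- list(values = vals, kinds = kinds[names(vals)])
  class(out) <- "feature_matrix"
  out
}
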