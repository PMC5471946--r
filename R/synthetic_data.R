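# Fully synthetic input bundles (sequences, annotations, PTM sites,
# accessibility profiles, 79-tissue expression, gene families) with planted
# class effects, so every pipeline stage is testable without external
# databases. Class-dependent parameters are length-2 vectors
# (target, nontarget); setting both entries equal removes the effect and
# makes the classes exchangeable.

# Background amino-acid frequencies (Swiss-Prot-like), renormalized.
BASE_AA_FREQ <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292)

#' Synthetic-bundle configuration
#'
#' Class-dependent parameters are `c(target, nontarget)` pairs. Defaults
#' mirror the group statistics the analysis is designed to detect: mean
#' lengths 418 vs 342 residues, signal-peptide rates 0.452 vs 0.226, enzyme
#' rates 0.571 vs 0.152, a mild compositional shift toward hydrophobic
#' residues in targets, membrane/extracellular/mitochondrial localization
#' preference for targets vs nucleus/cytoplasm for nontargets, higher PTM
#' density with exposure bias, and a higher, more tissue-specific expression
#' profile for targets.
#'
#' @param n_target,n_nontarget class sizes (default 1000 each)
#' @param seed integer seed
#' @param length_mean mean protein lengths in residues
#' @param length_sdlog log-normal sd of lengths
#' @param hydrophobic_shift log-scale multiplier applied to hydrophobic
#'   residue frequencies, `c(target, nontarget)`
#' @param dirichlet_conc concentration of the per-protein composition draw
#' @param signal_peptide_rate,enzyme_rate,essential_rate,nonessential_rate
#'   class rates in [0,1]
#' @param tm_lambda Poisson means of the TM helix count
#' @param ss_alpha list of two length-3 Dirichlet alphas
#'   (helix/strand/coil) per class
#' @param ptm_rate list per PTM type of expected sites per residue
#' @param exposure_odds sampling-odds multiplier for placing PTM sites on
#'   exposed residues
#' @param exposed_fraction fraction of residues drawn from the exposed
#'   accessibility component
#' @param loc_weight_target,loc_weight_nontarget sampling weights over the
#'   ten-term location vocabulary
#' @param curated_fraction fraction of proteins with a curated localization
#'   source
#' @param predictor_fidelity probability a predictor reports the protein's
#'   drawn location
#' @param expr_baseline_mean baseline tissue expression mean
#' @param expr_spike_tissues number of elevated tissues per class
#' @param expr_spike_mean mean expression in elevated tissues per class
#' @param n_tissues tissue count (default 79)
#' @param family_fraction fraction of proteins placed in multi-member
#'   families
#' @param family_sizes candidate family sizes
#' @param mixed_family_fraction fraction of families drawing members from
#'   both classes
#' @param multi_probe_fraction fraction of genes measured by two probes
#' @param multi_gene_fraction fraction of genes whose only probe is flagged
#'   multi-gene (their expression features are missing downstream)
#' @return named list of class `synthetic_config`
#' @export
synthetic_config <- function(
    n_target = 1000L, n_nontarget = 1000L, seed = 1L,
    length_mean = c(418, 342), length_sdlog = 0.45,
    hydrophobic_shift = c(0.12, 0), dirichlet_conc = 150,
    signal_peptide_rate = c(0.452, 0.226),
    enzyme_rate = c(0.571, 0.152),
    essential_rate = c(0.20, 0.10),
    nonessential_rate = c(0.25, 0.15),
    tm_lambda = c(1.2, 0.6),
    ss_alpha = list(c(3.4, 2.0, 4.6), c(3.0, 2.2, 4.8)),
    ptm_rate = list(phosphorylation = c(0.020, 0.012),
                    ubiquitination = c(0.007, 0.004),
                    acetylation = c(0.004, 0.0025)),
    exposure_odds = 4, exposed_fraction = 0.45,
    loc_weight_target = c(cytoplasm = 1.5, cytoskeleton = 0.4,
                          `endoplasmic reticulum` = 0.8, extracellular = 1.6,
                          `Golgi apparatus` = 0.5, lysosome = 0.4,
                          mitochondrion = 1.3, nucleus = 1.0,
                          peroxisome = 0.2, `plasma membrane` = 2.3),
    loc_weight_nontarget = c(cytoplasm = 2.2, cytoskeleton = 0.5,
                             `endoplasmic reticulum` = 0.7,
                             extracellular = 0.8, `Golgi apparatus` = 0.5,
                             lysosome = 0.3, mitochondrion = 0.9,
                             nucleus = 2.6, peroxisome = 0.2,
                             `plasma membrane` = 1.3),
    curated_fraction = 0.43, predictor_fidelity = 0.7,
    expr_baseline_mean = 80,
    expr_spike_tissues = c(8L, 25L),
    expr_spike_mean = c(2000, 800),
    n_tissues = 79L,
    family_fraction = 0.5, family_sizes = 2:5,
    mixed_family_fraction = 0.15,
    multi_probe_fraction = 0.10, multi_gene_fraction = 0.02) {
  cfg <- as.list(environment())
  rates <- c(cfg$signal_peptide_rate, cfg$enzyme_rate, cfg$essential_rate,
             cfg$nonessential_rate, cfg$curated_fraction,
             cfg$predictor_fidelity, cfg$family_fraction,
             cfg$mixed_family_fraction, unlist(cfg$ptm_rate))
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_target < 2L || cfg$n_nontarget < 2L)
    stop("class sizes must be >= 2")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Null configuration with no class effects
#'
#' Every class-dependent parameter is set to its nontarget value for both
#' classes, making the two classes exchangeable.
#' @param ... overrides passed to [synthetic_config()]
#' @export
null_synthetic_config <- function(...) {
  cfg <- synthetic_config(...)
  for (f in c("length_mean", "hydrophobic_shift", "signal_peptide_rate",
              "enzyme_rate", "essential_rate", "nonessential_rate",
              "tm_lambda", "expr_spike_tissues", "expr_spike_mean"))
    cfg[[f]][1] <- cfg[[f]][2]
  cfg$ss_alpha[[1]] <- cfg$ss_alpha[[2]]
  for (t in names(cfg$ptm_rate)) cfg$ptm_rate[[t]][1] <- cfg$ptm_rate[[t]][2]
  cfg$loc_weight_target <- cfg$loc_weight_nontarget
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic input bundle
#'
#' Draws labeled proteins with class-shifted Dirichlet-multinomial
#' compositions and log-normal lengths, gene families with a configured
#' mixed-label fraction, annotations, exposure-biased PTM sites,
#' per-residue accessibility profiles and a 79-tissue expression matrix
#' with class-dependent level and spike structure. Deterministic under the
#' config seed.
#'
#' @param config from [synthetic_config()]
#' @return list of class `synthetic_bundle`: `records`
#'   (`protein_records`), `annotations` (`annotation_table`), `ptm`,
#'   `accessibility`, `expression`, `manifest` (see [truth_manifest()]),
#'   `config`
#' @export
generate_bundle <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n_t <- config$n_target; n_n <- config$n_nontarget
  n <- n_t + n_n
  acc <- c(sprintf("T%05d", seq_len(n_t)), sprintf("N%05d", seq_len(n_n)))
  label <- c(rep("target", n_t), rep("nontarget", n_n))
  cls <- ifelse(label == "target", 1L, 2L)

  # families: blocks of proteins sharing a family id, some mixed-label
  fam <- rep(NA_character_, n)
  n_in_fam <- round(config$family_fraction * n)
  pool_t <- sample(which(label == "target"))
  pool_n <- sample(which(label == "nontarget"))
  fam_id <- 0L
  while (n_in_fam >= 2L && (length(pool_t) >= 2L || length(pool_n) >= 2L)) {
    size <- sample(config$family_sizes, 1L)
    size <- min(size, n_in_fam)
    if (size < 2L) break
    fam_id <- fam_id + 1L
    mixed <- stats::runif(1) < config$mixed_family_fraction &&
      length(pool_t) >= 1L && length(pool_n) >= size - 1L
    if (mixed) {
      k_t <- sample(seq_len(min(size - 1L, length(pool_t))), 1L)
      k_n <- size - k_t
      members <- c(pool_t[seq_len(k_t)], pool_n[seq_len(k_n)])
      pool_t <- pool_t[-seq_len(k_t)]
      pool_n <- pool_n[-seq_len(k_n)]
    } else {
      use_t <- length(pool_t) >= size &&
        (length(pool_n) < size || stats::runif(1) < length(pool_t) / n)
      if (use_t) {
        members <- pool_t[seq_len(size)]
        pool_t <- pool_t[-seq_len(size)]
      } else if (length(pool_n) >= size) {
        members <- pool_n[seq_len(size)]
        pool_n <- pool_n[-seq_len(size)]
      } else break
    }
    fam[members] <- sprintf("FAM%04d", fam_id)
    n_in_fam <- n_in_fam - length(members)
  }

  # sequences: class-shifted Dirichlet-multinomial composition
  hydro <- default_aa_groups()$hydrophobic
  seqs <- character(n)
  lens <- integer(n)
  for (i in seq_len(n)) {
    mu <- config$length_mean[cls[i]]
    L <- max(30L, round(stats::rlnorm(
      1, meanlog = log(mu) - config$length_sdlog^2 / 2,
      sdlog = config$length_sdlog)))
    base <- BASE_AA_FREQ
    base[hydro] <- base[hydro] * exp(config$hydrophobic_shift[cls[i]])
    p <- rdirichlet1(config$dirichlet_conc * base / sum(base))
    seqs[i] <- paste(sample(AA20, L, replace = TRUE, prob = p),
                     collapse = "")
    lens[i] <- L
  }
  records <- protein_records(acc, seqs, label, family_id = fam,
                             cds_length = 3 * (lens + 1))

  # accessibility profiles: buried/exposed mixture per residue
  accessibility <- vector("list", n)
  names(accessibility) <- acc
  for (i in seq_len(n)) {
    exposed <- stats::runif(lens[i]) < config$exposed_fraction
    sc <- ifelse(exposed, stats::rnorm(lens[i], 70, 12),
                 stats::rnorm(lens[i], 15, 10))
    accessibility[[i]] <- as.integer(pmin(99, pmax(0, round(sc))))
  }

  # PTM sites: candidate residues by type, exposure-biased placement
  ptm_rows <- list()
  cand_res <- list(phosphorylation = c("S", "T", "Y"),
                   ubiquitination = "K", acetylation = "K")
  for (i in seq_len(n)) {
    res <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    prof <- accessibility[[i]]
    for (type in ptm_types()) {
      cand <- which(res %in% cand_res[[type]])
      if (!length(cand)) next
      rate <- config$ptm_rate[[type]][cls[i]]
      n_sites <- min(length(cand), stats::rpois(1, rate * lens[i]))
      if (n_sites == 0L) next
      w <- ifelse(prof[cand] >= 25, config$exposure_odds, 1)
      pos <- sort(cand[sample.int(length(cand), n_sites, prob = w)])
      ptm_rows[[length(ptm_rows) + 1L]] <- data.frame(
        accession = acc[i], position = pos, residue = res[pos],
        type = type, stringsAsFactors = FALSE)
    }
  }
  ptm <- if (length(ptm_rows))
    do.call(rbind, c(ptm_rows, make.row.names = FALSE))
  else data.frame(accession = character(), position = integer(),
                  residue = character(), type = character(),
                  stringsAsFactors = FALSE)

  # annotations
  sp <- stats::rbinom(n, 1, config$signal_peptide_rate[cls])
  enz <- stats::rbinom(n, 1, config$enzyme_rate[cls]) == 1
  ec <- character(n)
  ec[enz] <- vapply(which(enz), function(i) {
    k <- sample(1:6, 1L + (stats::runif(1) < 0.15))
    paste(sort(unique(k)), collapse = ";")
  }, character(1))
  tm <- stats::rpois(n, config$tm_lambda[cls])
  ss <- t(vapply(cls, function(cl)
    0.95 * rdirichlet1(config$ss_alpha[[cl]]), numeric(3)))
  u <- stats::runif(n)
  ess <- ifelse(u < config$essential_rate[cls], "essential",
                ifelse(u < config$essential_rate[cls] +
                         config$nonessential_rate[cls],
                       "nonessential", ""))
  vocab <- location_vocabulary()
  w_loc <- list(config$loc_weight_target, config$loc_weight_nontarget)
  true_loc <- vapply(cls, function(cl)
    sample(vocab, 1L, prob = w_loc[[cl]][vocab]), character(1))
  curated <- stats::runif(n) < config$curated_fraction
  loc_cols <- list(
    loc_curated_locate = ifelse(curated, true_loc, ""),
    loc_pred_cello = character(n), loc_pred_ptarget = character(n),
    loc_pred_pa = character(n), loc_pred_wolfpsort = character(n),
    loc_pred_multiloc = character(n))
  pred_names <- grep("^loc_pred_", names(loc_cols), value = TRUE)
  for (i in which(!curated)) {
    for (pn in pred_names) {
      call <- if (stats::runif(1) < config$predictor_fidelity) true_loc[i]
              else sample(setdiff(vocab, true_loc[i]), 1L)
      loc_cols[[pn]][i] <- call
    }
  }
  ann_df <- data.frame(
    accession = acc, ec = ec, signal_peptide = sp,
    tm_helix_count = tm,
    ss_helix = round(ss[, 1], 4), ss_strand = round(ss[, 2], 4),
    ss_coil = round(ss[, 3], 4),
    essentiality = ess, stringsAsFactors = FALSE)
  for (cn in names(loc_cols)) ann_df[[cn]] <- loc_cols[[cn]]
  annotations <- annotation_table_from_df(ann_df)

  # expression: one gene per protein; occasional second probe; a small
  # fraction of genes covered only by a multi-gene probe
  nt <- config$n_tissues
  tissues <- sprintf("tissue_%02d", seq_len(nt))
  probe_rows <- list()
  multi_only <- stats::runif(n) < config$multi_gene_fraction
  two_probe <- !multi_only & stats::runif(n) < config$multi_probe_fraction
  # per-protein heterogeneity: baseline level, spiked-tissue count and spike
  # magnitude all vary between proteins of a class, so the class
  # distributions of expression level and tau overlap as on real arrays
  gene_expr <- function(i) {
    baseline_i <- stats::rlnorm(1, meanlog = log(config$expr_baseline_mean),
                                sdlog = 0.5)
    base <- stats::rlnorm(nt, meanlog = log(baseline_i), sdlog = 0.4)
    k <- min(nt, stats::rpois(1, config$expr_spike_tissues[cls[i]]))
    if (k > 0) {
      spike <- sample(nt, k)
      spike_mean_i <- stats::rlnorm(
        1, meanlog = log(config$expr_spike_mean[cls[i]]), sdlog = 0.5)
      base[spike] <- stats::rlnorm(k, meanlog = log(spike_mean_i),
                                   sdlog = 0.3)
    }
    round(base, 2)
  }
  for (i in seq_len(n)) {
    n_probes <- if (two_probe[i]) 2L else 1L
    for (j in seq_len(n_probes)) {
      probe_rows[[length(probe_rows) + 1L]] <- c(
        probe = sprintf("%s_at%d", acc[i], j), gene = acc[i],
        multi_gene = as.integer(multi_only[i] && j == 1L),
        stats::setNames(gene_expr(i) * stats::runif(1, 0.8, 1.2), tissues))
    }
  }
  pr <- do.call(rbind, probe_rows)
  expr_vals <- matrix(as.numeric(pr[, tissues]), nrow = nrow(pr),
                      dimnames = list(pr[, "probe"], tissues))
  expression <- structure(
    list(values = round(expr_vals, 2),
         probe_gene = data.frame(probe = pr[, "probe"], gene = pr[, "gene"],
                                 multi_gene = pr[, "multi_gene"] == "1",
                                 stringsAsFactors = FALSE),
         n_tissues = nt),
    class = "expression_matrix")

  bundle <- list(records = records, annotations = annotations, ptm = ptm,
                 accessibility = accessibility, expression = expression,
                 config = config)
  bundle$manifest <- truth_manifest(bundle)
  class(bundle) <- "synthetic_bundle"
  bundle
}

#' Planted-effect manifest of a synthetic bundle
#'
#' Machine-readable record of which features carry planted class effects and
#' their directions, derived from the generating configuration (a zero
#' effect yields no entry). Directions are `"target_higher"` /
#' `"target_enriched"` or the nontarget counterparts.
#'
#' @param bundle from [generate_bundle()]
#' @return data.frame with columns `feature`, `direction`
#' @export
truth_manifest <- function(bundle) {
  cfg <- bundle$config
  rows <- list()
  add <- function(feature, target_val, nontarget_val, kind) {
    if (isTRUE(all.equal(target_val, nontarget_val))) return()
    dir <- if (target_val > nontarget_val)
      if (kind == "discrete") "target_enriched" else "target_higher"
    else
      if (kind == "discrete") "nontarget_enriched" else "nontarget_higher"
    rows[[length(rows) + 1L]] <<- data.frame(feature = feature,
                                             direction = dir,
                                             stringsAsFactors = FALSE)
  }
  add("length", cfg$length_mean[1], cfg$length_mean[2], "continuous")
  add("grp_hydrophobic", cfg$hydrophobic_shift[1], cfg$hydrophobic_shift[2],
      "continuous")
  add("signal_peptide", cfg$signal_peptide_rate[1],
      cfg$signal_peptide_rate[2], "discrete")
  add("is_enzyme", cfg$enzyme_rate[1], cfg$enzyme_rate[2], "discrete")
  add("essential", cfg$essential_rate[1], cfg$essential_rate[2], "discrete")
  add("nonessential", cfg$nonessential_rate[1], cfg$nonessential_rate[2],
      "discrete")
  add("tm_helix_count", cfg$tm_lambda[1], cfg$tm_lambda[2], "continuous")
  for (type in names(cfg$ptm_rate))
    add(paste0("ptm_", type), cfg$ptm_rate[[type]][1],
        cfg$ptm_rate[[type]][2], "continuous")
  # expression level follows baseline + spikes; tau follows spike sparsity
  s_level <- function(cl) {
    k <- cfg$expr_spike_tissues[cl]
    (cfg$expr_baseline_mean * (cfg$n_tissues - k) +
       cfg$expr_spike_mean[cl] * k) / cfg$n_tissues
  }
  add("expr_level", s_level(1), s_level(2), "continuous")
  # fewer spiked tissues concentrate expression, raising tau
  add("expr_tau", -cfg$expr_spike_tissues[1], -cfg$expr_spike_tissues[2],
      "continuous")
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(feature = character(), direction = character(),
                  stringsAsFactors = FALSE)
}

#' Write / read a synthetic bundle as plain-text files
#'
#' Writes `sequences.fasta`, `records.tsv` (accession, label, family_id,
#' cds_length), `annotations.tsv`, `ptm.tsv`, `accessibility.tsv`,
#' `expression.tsv` and `manifest.json` into `dir`.
#' @param bundle from [generate_bundle()]
#' @param dir output directory (created if missing)
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$records, p("sequences.fasta"))
  utils::write.table(
    bundle$records[c("accession", "label", "family_id", "cds_length")],
    p("records.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- bundle$annotations
  loc <- ann$localization
  ann_df <- ann$proteins
  ann_df$ec <- vapply(ann$ec[ann_df$accession],
                      function(e) paste(e, collapse = ";"), character(1))
  ann_df$signal_peptide <- as.integer(ann_df$signal_peptide)
  ann_df$essentiality[ann_df$essentiality == "unknown"] <- ""
  for (src in unique(loc$source)) {
    sub <- loc[loc$source == src, , drop = FALSE]
    type <- sub$source_type[1]
    col <- paste0(if (type == "curated") "loc_curated_" else "loc_pred_", src)
    agg <- tapply(sub$location, sub$accession,
                  function(v) paste(sort(v), collapse = ";"))
    ann_df[[col]] <- ""
    ann_df[[col]][match(names(agg), ann_df$accession)] <- unname(agg)
  }
  utils::write.table(ann_df, p("annotations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(bundle$ptm, p("ptm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  acc_df <- data.frame(
    accession = rep(names(bundle$accessibility),
                    lengths(bundle$accessibility)),
    position = unlist(lapply(bundle$accessibility, seq_along)),
    score = unlist(bundle$accessibility), row.names = NULL)
  utils::write.table(acc_df, p("accessibility.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ex <- bundle$expression
  ex_df <- cbind(ex$probe_gene, as.data.frame(ex$values))
  ex_df$multi_gene <- as.integer(ex_df$multi_gene)
  utils::write.table(ex_df, p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  fa <- read_fasta(p("sequences.fasta"))
  meta <- utils::read.delim(p("records.tsv"), sep = "\t",
                            stringsAsFactors = FALSE, na.strings = "NA")
  stopifnot(identical(fa$accession, meta$accession))
  records <- protein_records(fa$accession, fa$sequence, meta$label,
                             family_id = meta$family_id,
                             cds_length = meta$cds_length)
  list(records = records,
       annotations = read_annotations(p("annotations.tsv")),
       ptm = read_ptm_sites(p("ptm.tsv")),
       accessibility = read_accessibility(p("accessibility.tsv")),
       expression = read_expression(p("expression.tsv")))
}
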