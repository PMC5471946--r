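# Shared fixtures built in code.

random_peptide <- function(len) {
  paste(sample(targetprops:::AA20, len, replace = TRUE), collapse = "")
}

# Minimal record set: 8 proteins, 3 families (one mixed-label), used by the
# dataset-builder tests.
eight_protein_fixture <- function() {
  protein_records(
    accession = c("t1", "t2", "t3", "n1", "n2", "n3", "n4", "n5"),
    sequence = rep("MKVLAAEPSTDL", 8),
    label = c("target", "target", "target",
              "nontarget", "nontarget", "nontarget", "nontarget",
              "nontarget"),
    #   famX: t1 (900), t2 (600)        -> pure target family
    #   famY: t3 (300), n1 (450)        -> mixed family
    #   famZ: n2 (500), n3 (700)        -> pure nontarget family
    #   n4, n5 singletons
    family_id = c("famX", "famX", "famY", "famY", "famZ", "famZ", NA, NA),
    cds_length = c(900, 600, 300, 450, 500, 700, NA, NA))
}

# Random labeled records with random family structure, for property-style
# dataset-builder tests.
random_records <- function(n, p_family = 0.6, n_families = 6) {
  lab <- sample(c("target", "nontarget"), n, replace = TRUE,
                prob = c(0.3, 0.7))
  fam <- ifelse(runif(n) < p_family,
                paste0("F", sample.int(n_families, n, replace = TRUE)),
                NA_character_)
  protein_records(
    accession = sprintf("P%03d", seq_len(n)),
    sequence = vapply(sample(40:80, n, replace = TRUE), random_peptide,
                      character(1)),
    label = lab, family_id = fam,
    cds_length = sample(300:3000, n, replace = TRUE))
}

# One small expression matrix: values is a single-probe row per gene.
make_expression <- function(probes, genes, multi, values) {
  structure(list(values = values,
                 probe_gene = data.frame(probe = probes, gene = genes,
                                         multi_gene = multi,
                                         stringsAsFactors = FALSE),
                 n_tissues = ncol(values)),
            class = "expression_matrix")
}

small_bundle <- function(n = 60, seed = 1, null = FALSE) {
  cfg_fun <- if (null) null_synthetic_config else synthetic_config
  generate_bundle(cfg_fun(n_target = n, n_nontarget = n, seed = seed))
}

bundle_tables <- function(b) {
  list(annotations = b$annotations, ptm = b$ptm,
       accessibility = b$accessibility, expression = b$expression)
}
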