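# Fixture builders shared across test files.

TAXA <- c("S_viminalis", "S_suchowensis", "P_tremula", "P_tremuloides",
          "P_trichocarpa")

# alignment in which every taxon carries `base_seq` (a codon vector), with
# per-taxon overrides given as list(taxon = list(codon_index = "XYZ", ...))
make_alignment <- function(base_seq, overrides = list(), id = "g1") {
  mat <- matrix(rep(base_seq, each = length(TAXA)), nrow = length(TAXA),
                dimnames = list(TAXA, NULL))
  for (tx in names(overrides)) {
    for (ci in names(overrides[[tx]])) {
      mat[tx, as.integer(ci)] <- overrides[[tx]][[ci]]
    }
  }
  codon_alignment(id, mat, stripped = TRUE)
}

# repeat a small codon set n times
rep_codons <- function(codons, n) rep(codons, n)

# a minimal site table: one row per (site, individual); coverage defaults
# high so the coverage rule passes, alt counts zero unless specified.
# snps: data.frame(codon_index, position_in_codon, alt_base, alt_counts =
# list of per-individual alt read counts)
make_site_table <- function(gene, n_codons, coverage = 30,
                            individuals = c("M1", "M2", "M3",
                                            "F1", "F2", "F3"),
                            snps = NULL) {
  sexes <- substr(individuals, 1, 1)
  nsite <- n_codons * 3
  df <- expand.grid(individual = individuals,
                    site = seq_len(nsite), stringsAsFactors = FALSE)
  df$gene <- gene
  df$codon_index <- (df$site - 1) %/% 3 + 1
  df$position_in_codon <- (df$site - 1) %% 3 + 1
  df$sex <- sexes[match(df$individual, individuals)]
  df$coverage <- if (length(coverage) == 1) coverage else
    coverage[match(df$individual, individuals)]
  df$alt_count <- 0L
  df$alt_base <- NA_character_
  if (!is.null(snps)) {
    for (i in seq_len(nrow(snps))) {
      sel <- df$codon_index == snps$codon_index[i] &
        df$position_in_codon == snps$position_in_codon[i]
      df$alt_base[sel] <- snps$alt_base[i]
      alt <- snps$alt_counts[[i]]
      df$alt_count[sel] <- alt[match(df$individual[sel], individuals)]
    }
  }
  df$ref_count <- df$coverage - df$alt_count
  df[, c("gene", "codon_index", "position_in_codon", "individual", "sex",
         "coverage", "ref_count", "alt_count", "alt_base")]
}

# small expression table with explicit counts
make_expression_table <- function(counts, lengths_bp = NULL) {
  ni <- ncol(counts) / 4
  ind <- c(paste0("M", 1:ni), paste0("F", 1:ni))
  meta <- data.frame(
    sample = colnames(counts),
    individual = rep(ind, 2),
    sex = rep(rep(c("M", "F"), each = ni), 2),
    tissue = rep(c("catkin", "leaf"), each = 2 * ni),
    stringsAsFactors = FALSE)
  if (is.null(lengths_bp))
    lengths_bp <- stats::setNames(rep(900, nrow(counts)), rownames(counts))
  expression_table(counts, lengths_bp, meta)
}
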