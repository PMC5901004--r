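# End-to-end convenience wrapper over the module functions, and plain-text
# writers for the intermediate tables.

#' Run the full analysis pipeline on simulated data
#'
#' Generates alignments, expression counts and site tables from one
#' configuration, classifies sex bias in catkin, prepares alignments
#' (gap stripping, two-pass masking, length filter), builds the matched
#' divergence + polymorphism table, applies the saturation check, and
#' computes the category summary table, McDonald-Kreitman/DoS contrasts,
#' ENC contrasts and the expression regression.
#'
#' @param config a [sim_config()].
#' @param reps bootstrap/permutation replicates for the summary tables.
#' @param min_bp minimum alignment length (bp).
#' @return object of class `sexbias_analysis`.
#' @export
sexbias_pipeline <- function(config = sim_config(), reps = 1000,
                             min_bp = 300) {
  sim <- simulate_ortholog_set(config)
  expr <- simulate_expression(config, genes = sim$truth$genes)
  st <- simulate_site_table(sim$alignments, sim$truth, config)

  calls <- classify_sex_bias(expr, tissue = "catkin")
  categories <- stats::setNames(calls$category, calls$gene)

  alns <- prepare_alignments(sim$alignments, min_bp = min_bp)
  genes <- mk_input_table(alns, st$sites)
  genes <- genes[saturation_check(genes), , drop = FALSE]
  genes <- genes[genes$gene %in% names(categories), , drop = FALSE]

  mk <- mk_test(genes)
  encs <- enc_table(alns[mk$gene])
  mk$Nc <- encs$Nc[match(mk$gene, encs$gene)]

  set.seed(config$seed + 3L)
  cat_tab <- category_table(mk, categories, reps = reps)
  sel <- category_selection_contrasts(mk, categories)
  enc_con <- enc_category_contrast(encs, categories, reps = reps)

  rpkm <- compute_rpkm(expr)
  expr_cov <- mean_expression(rpkm, expr$sample_meta, "catkin")
  fc_classes <- stats::setNames(calls$fc_class, calls$gene)
  reg <- dnds_regression(mk, expr_cov, fc_classes)
  quart <- quartile_dnds(mk, expr_cov, categories, reps = reps)

  structure(
    list(config = config, truth = st$truth, calls = calls, genes = mk,
         category_table = cat_tab, selection_contrasts = sel,
         enc_table = encs, enc_contrasts = enc_con,
         regression = reg, quartiles = quart),
    class = "sexbias_analysis")
}

#' @export
print.sexbias_analysis <- function(x, ...) {
  cat("sexbias_analysis\n")
  cat(sprintf("  genes analysed: %d (of %d simulated)\n",
              nrow(x$genes), nrow(x$truth$genes)))
  tb <- table(x$calls$category)
  cat(sprintf("  catkin calls: %s\n",
              paste(names(tb), tb, sep = "=", collapse = " ")))
  cat("  category dN/dS:\n")
  ct <- x$category_table
  sub <- ct[ct$statistic == "dN_dS", c("category", "n_genes", "estimate",
                                       "ci_low", "ci_high")]
  print(sub, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.sexbias_analysis <- function(object, ...) {
  print(object)
  cat("\nSelection contrasts:\n")
  print(object$selection_contrasts, digits = 3, row.names = FALSE)
  cat("\nENC contrasts:\n")
  print(object$enc_contrasts, digits = 4, row.names = FALSE)
  cat("\nExpression regression:\n")
  print(object$regression)
  invisible(object)
}

#' Write simulated data as plain-text files
#'
#' Writes per-ortholog FASTA files, the Newick species tree, the counts and
#' sample-meta TSVs, the site-table TSV and the ground-truth TSVs into a
#' directory.
#'
#' @param sim output of [simulate_ortholog_set()].
#' @param expr an `expression_table`.
#' @param sites site table data frame.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_simulated_data <- function(sim, expr, sites, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_codon_alignments(sim$alignments, file.path(dir, "alignments"))
  ape::write.tree(species_tree(), file.path(dir, "species_tree.nwk"))
  cts <- data.frame(gene = rownames(expr$counts),
                    length_bp = expr$gene_length_bp[rownames(expr$counts)],
                    expr$counts, check.names = FALSE)
  utils::write.table(cts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$sample_meta, file.path(dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sites, file.path(dir, "site_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$substitutions,
                     file.path(dir, "truth_substitutions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write valid SNPs as a minimal VCF
#'
#' CHROM is the gene id, POS the 1-based position in the coding sequence,
#' and INFO carries the synonymous/nonsynonymous annotation.
#'
#' @param snps classified SNPs ([classify_polymorphism()] output with
#'   `ref_codon` etc.).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_snps_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=EFF,Number=1,Type=String,Description=\"SYN or NONSYN\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps)) {
    pos <- (snps$codon_index - 1L) * 3L + snps$position_in_codon
    ref <- substring(snps$ref_codon, snps$position_in_codon,
                     snps$position_in_codon)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tEFF=%s",
                       snps$gene, pos, ref, snps$alt_base,
                       ifelse(snps$type == "syn", "SYN", "NONSYN")), con)
  }
  invisible(path)
}
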