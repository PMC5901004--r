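# Synonymous codon usage bias via the effective number of codons (ENC).

# amino-acid family degeneracies under the universal code (stops excluded):
# 2 single-codon families (Met, Trp), 9 twofold, 1 threefold (Ile),
# 5 fourfold, 3 sixfold (Leu, Ser, Arg)
.AA_FAMILY <- local({
  fam <- table(.GENETIC_CODE[.SENSE_CODONS])
  stats::setNames(as.integer(fam), names(fam))
})

#' Effective number of codons (ENC) of one coding sequence
#'
#' Wright's ENC: for each amino-acid family with `n` observed codons and
#' usage proportions `p_i`, the homozygosity is
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`; family classes are averaged by
#' degeneracy and `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61. ENC
#' runs from 20 (extreme bias: one codon per amino acid) to 61 (no bias:
#' uniform usage within every family) and is not biased by sequence length.
#'
#' Families observed with fewer than 2 codons are dropped from their class
#' average. A missing threefold class (Ile absent) is recovered as
#' `F3 = (F2 + F4)/2`; if the twofold, fourfold or sixfold class has no
#' usable family the statistic is undefined (`Nc = NA`, flagged) and the
#' gene is excluded from category means.
#'
#' @param seq coding sequence: a nucleotide string (length divisible by 3)
#'   or a character vector of codons. Codons containing ambiguity
#'   characters are skipped; stop codons are excluded.
#' @param gene optional gene id for the result.
#' @return object of class `enc_result`: list with `gene`, `codon_counts`,
#'   `F_bar` (named by degeneracy class), `Nc`, `flagged`.
#' @export
enc <- function(seq, gene = NA_character_) {
  if (length(seq) == 1L && nchar(seq) > 3) {
    if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
    seq <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  }
  seq <- toupper(seq)
  codons <- seq[seq %in% .SENSE_CODONS]
  counts <- table(factor(codons, levels = .SENSE_CODONS))

  aa <- .GENETIC_CODE[.SENSE_CODONS]
  F_by_aa <- rep(NA_real_, length(.AA_FAMILY))
  names(F_by_aa) <- names(.AA_FAMILY)
  for (a in names(.AA_FAMILY)) {
    cts <- counts[aa == a]
    n <- sum(cts)
    if (n < 2) next                       # F undefined for n < 2
    p <- cts / n
    F_by_aa[[a]] <- (n * sum(p^2) - 1) / (n - 1)
  }
  deg <- .AA_FAMILY
  F_bar <- vapply(c(2, 3, 4, 6), function(k) {
    vals <- F_by_aa[deg == k & !is.na(F_by_aa)]
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
  names(F_bar) <- c("F2", "F3", "F4", "F6")
  if (is.na(F_bar[["F3"]]) &&
      !is.na(F_bar[["F2"]]) && !is.na(F_bar[["F4"]]))
    F_bar[["F3"]] <- (F_bar[["F2"]] + F_bar[["F4"]]) / 2

  flagged <- any(is.na(F_bar)) || any(F_bar == 0, na.rm = TRUE)
  Nc <- if (flagged) NA_real_ else
    min(2 + 9 / F_bar[["F2"]] + 1 / F_bar[["F3"]] +
          5 / F_bar[["F4"]] + 3 / F_bar[["F6"]], 61)
  structure(list(gene = gene, codon_counts = counts, F_bar = F_bar,
                 Nc = Nc, flagged = flagged),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("ENC%s: Nc = %s (%d codons%s)\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              if (is.na(x$Nc)) "undefined" else sprintf("%.2f", x$Nc),
              sum(x$codon_counts),
              if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' Per-gene ENC table for a set of alignments
#'
#' Computes ENC on the focal-taxon sequence of each alignment (masked and
#' ambiguous codons skipped).
#'
#' @param alignments named list of [codon_alignment()].
#' @param focal taxon whose sequence is scored.
#' @return data frame `gene`, `Nc`, `flagged`.
#' @export
enc_table <- function(alignments, focal = "S_viminalis") {
  rows <- lapply(alignments, function(a) {
    codons <- a$codons[focal, ]
    codons[a$mask[focal, ]] <- "NNN"
    r <- enc(codons, gene = a$id)
    data.frame(gene = a$id, Nc = r$Nc, flagged = r$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation contrast of mean ENC between categories
#'
#' Difference of mean Nc between two categories with a label-permutation
#' p-value, as in [permutation_contrast()]. Genes with undefined Nc are
#' excluded.
#'
#' @param enc_df [enc_table()] output.
#' @param categories named category vector (gene -> UB/MB/FB).
#' @param pairs category pairs to contrast.
#' @param reps permutation replicates.
#' @param seed optional integer seed.
#' @return data frame `contrast`, `mean_a`, `mean_b`, `observed`, `p`.
#' @export
enc_category_contrast <- function(enc_df, categories,
                                  pairs = list(c("MB", "UB"), c("FB", "UB"),
                                               c("MB", "FB")),
                                  reps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  categories <- categories[enc_df$gene]
  enc_df <- enc_df[!is.na(enc_df$Nc) & !is.na(categories), , drop = FALSE]
  categories <- categories[enc_df$gene]
  rows <- lapply(pairs, function(pair) {
    a <- enc_df[categories == pair[1], , drop = FALSE]
    b <- enc_df[categories == pair[2], , drop = FALSE]
    ct <- permutation_contrast(a, b, "ENC_mean", reps = reps)
    data.frame(contrast = paste(pair, collapse = "_vs_"),
               mean_a = mean(a$Nc), mean_b = mean(b$Nc),
               observed = ct$observed, p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
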