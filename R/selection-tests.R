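# McDonald-Kreitman tests, the direction-of-selection (DoS) statistic, and
# category-level selection contrasts.

#' Per-gene McDonald-Kreitman tests
#'
#' For each gene builds the 2x2 contingency table of fixed substitutions vs
#' polymorphisms, nonsynonymous vs synonymous, and applies a two-sided
#' Fisher's exact test. Pathway-averaged (fractional) substitution counts
#' are rounded to the nearest integer (ties up) for the table; polymorphism
#' counts are already integers. Genes are excluded (`included = FALSE`)
#' when any row or column sum of the table is below `min_margin`. A gene is
#' flagged under positive selection when it is included, the Fisher p-value
#' is below `alpha`, and dN/dS exceeds pN/pS. DoS is computed from the
#' same table and is `NA` when either denominator is zero.
#'
#' @param genes per-gene table ([mk_input_table()] output).
#' @param alpha Fisher significance threshold (default 0.05).
#' @param min_margin minimum row/column sum for inclusion (default 6;
#'   margins below 6 excluded).
#' @return `genes` with columns added: `DN_int`, `DS_int`, `fisher_p`,
#'   `included`, `positive_selection`, `DoS`.
#' @export
mk_test <- function(genes, alpha = 0.05, min_margin = 6) {
  dn <- floor(genes$DN + 0.5)   # round half up
  ds <- floor(genes$DS + 0.5)
  pn <- genes$PN
  ps <- genes$PS
  included <- (dn + ds) >= min_margin & (pn + ps) >= min_margin &
              (dn + pn) >= min_margin & (ds + ps) >= min_margin
  fisher_p <- vapply(seq_along(dn), function(i) {
    stats::fisher.test(matrix(c(dn[i], ds[i], pn[i], ps[i]), 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  dnds <- ifelse(genes$N > 0 & genes$DS > 0 & genes$S > 0,
                 (genes$DN / genes$N) / (genes$DS / genes$S), NA_real_)
  pnps <- ifelse(genes$N > 0 & genes$PS > 0 & genes$S > 0,
                 (genes$PN / genes$N) / (genes$PS / genes$S), NA_real_)
  positive <- included & fisher_p < alpha &
              !is.na(dnds) & !is.na(pnps) & dnds > pnps
  genes$DN_int <- dn
  genes$DS_int <- ds
  genes$fisher_p <- fisher_p
  genes$included <- included
  genes$positive_selection <- positive
  genes$DoS <- dos(dn, ds, pn, ps)
  genes
}

#' Direction of selection statistic
#'
#' `DoS = DN/(DN + DS) - PN/(PN + PS)`: positive values indicate positive
#' selection, zero neutral evolution, negative values purifying selection
#' with segregating deleterious variants. `NA` when either denominator
#' is zero.
#'
#' @param dn,ds fixed nonsynonymous / synonymous substitution counts.
#' @param pn,ps nonsynonymous / synonymous polymorphism counts.
#' @return numeric vector in `[-1, 1]` (or `NA`).
#' @export
dos <- function(dn, ds, pn, ps) {
  ifelse(dn + ds > 0 & pn + ps > 0,
         dn / (dn + ds) - pn / (pn + ps), NA_real_)
}

#' Category-level selection contrasts
#'
#' Compares sex-biased categories with unbiased genes for (a) the
#' proportion of genes under positive selection (Fisher's exact test), (b)
#' the proportion with DoS > 0 (Fisher's exact test), and (c) the per-gene
#' DoS distribution (two-sided Wilcoxon rank-sum test). Contrasts with an
#' empty category are skipped with a flag.
#'
#' @param mk [mk_test()] output.
#' @param categories named category vector (gene -> UB/MB/FB).
#' @param pairs list of category pairs to compare.
#' @return data frame: `contrast`, `test`, `x_a`, `n_a`, `x_b`, `n_b`, `p`,
#'   `skipped`.
#' @export
category_selection_contrasts <- function(mk, categories,
                                         pairs = list(c("MB", "UB"),
                                                      c("FB", "UB"))) {
  categories <- categories[mk$gene]
  rows <- list()
  for (pair in pairs) {
    a <- mk[!is.na(categories) & categories == pair[1], , drop = FALSE]
    b <- mk[!is.na(categories) & categories == pair[2], , drop = FALSE]
    lab <- paste(pair, collapse = "_vs_")
    skipped <- !nrow(a) || !nrow(b)

    fisher_on <- function(xa, na, xb, nb) {
      if (skipped || na == 0 || nb == 0) return(NA_real_)
      stats::fisher.test(matrix(c(xa, na - xa, xb, nb - xb), 2,
                                byrow = TRUE))$p.value
    }
    ai <- a[a$included, , drop = FALSE]; bi <- b[b$included, , drop = FALSE]
    rows[[paste(lab, "pos")]] <- data.frame(
      contrast = lab, test = "positive_selection_fisher",
      x_a = sum(ai$positive_selection), n_a = nrow(ai),
      x_b = sum(bi$positive_selection), n_b = nrow(bi),
      p = fisher_on(sum(ai$positive_selection), nrow(ai),
                    sum(bi$positive_selection), nrow(bi)),
      skipped = skipped || !nrow(ai) || !nrow(bi),
      stringsAsFactors = FALSE)

    da <- a$DoS[!is.na(a$DoS)]; db <- b$DoS[!is.na(b$DoS)]
    rows[[paste(lab, "dospos")]] <- data.frame(
      contrast = lab, test = "dos_positive_fisher",
      x_a = sum(da > 0), n_a = length(da),
      x_b = sum(db > 0), n_b = length(db),
      p = fisher_on(sum(da > 0), length(da), sum(db > 0), length(db)),
      skipped = skipped || !length(da) || !length(db),
      stringsAsFactors = FALSE)

    w_skip <- length(da) < 2 || length(db) < 2
    rows[[paste(lab, "wilcox")]] <- data.frame(
      contrast = lab, test = "dos_wilcoxon",
      x_a = NA_real_, n_a = length(da), x_b = NA_real_, n_b = length(db),
      # normal approximation with tie correction (DoS values tie at 0)
      p = if (!w_skip) stats::wilcox.test(da, db, exact = FALSE)$p.value
          else NA_real_,
      skipped = w_skip, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
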