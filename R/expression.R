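# Expression quantification, filtering, normalization and sex-bias
# classification.  Normalization factors and per-gene dispersions/p-values
# come from edgeR (TMM + exact negative-binomial test); fold changes and the
# category rule are applied here.

#' Construct an expression table
#'
#' @param counts gene x sample matrix of non-negative integer counts.
#' @param gene_length_bp named numeric vector of gene lengths in bp.
#' @param sample_meta data frame with columns `sample`, `individual`,
#'   `sex` (`"M"`/`"F"`) and `tissue` (`"catkin"`/`"leaf"`).
#' @return an `expression_table`.
#' @export
expression_table <- function(counts, gene_length_bp, sample_meta) {
  stopifnot(all(c("sample", "individual", "sex", "tissue") %in%
                  names(sample_meta)),
            all(colnames(counts) == sample_meta$sample))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(gene_length_bp[rownames(counts)] <= 0, na.rm = TRUE) ||
      any(is.na(gene_length_bp[rownames(counts)])))
    stop("every gene needs a positive length")
  structure(list(counts = counts,
                 gene_length_bp = gene_length_bp[rownames(counts)],
                 sample_meta = sample_meta),
            class = "expression_table")
}

#' Read an expression table from TSV files
#'
#' @param counts_file TSV with gene ids in the first column, one column per
#'   sample, plus a `length_bp` column.
#' @param meta_file TSV with columns `sample`, `individual`, `sex`, `tissue`.
#' @return an `expression_table`.
#' @export
read_expression_table <- function(counts_file, meta_file) {
  ct <- utils::read.delim(counts_file, row.names = 1, check.names = FALSE)
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  len <- stats::setNames(ct$length_bp, rownames(ct))
  ct <- as.matrix(ct[, setdiff(colnames(ct), "length_bp"), drop = FALSE])
  expression_table(ct[, meta$sample, drop = FALSE], len, meta)
}

#' RPKM matrix
#'
#' Reads per kilobase of gene per million mapped reads:
#' `1e9 * count / (length_bp * library_size)`.
#'
#' @param table an `expression_table`.
#' @return gene x sample numeric matrix.
#' @export
compute_rpkm <- function(table) {
  lib <- colSums(table$counts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(table$counts)[lib == 0], collapse = ", "))
  1e9 * sweep(table$counts / table$gene_length_bp, 2, lib, "/")
}

#' Minimum-expression filter
#'
#' A gene is retained in a tissue if, in at least one sex, at least half of
#' the individuals (ceiling; 2 of 3 at n = 3) have RPKM at or above the
#' threshold (inclusive).
#'
#' @param rpkm matrix from [compute_rpkm()].
#' @param sample_meta the sample metadata.
#' @param tissue tissue to filter in.
#' @param threshold minimum RPKM (default 2).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(rpkm, sample_meta, tissue, threshold = 2) {
  meta <- sample_meta[sample_meta$tissue == tissue, ]
  keep <- rep(FALSE, nrow(rpkm))
  for (sx in c("M", "F")) {
    cols <- meta$sample[meta$sex == sx]
    if (length(cols) < 2) stop("need >= 2 individuals per sex")
    need <- ceiling(length(cols) / 2)
    keep <- keep | rowSums(rpkm[, cols, drop = FALSE] >= threshold) >= need
  }
  rownames(rpkm)[keep]
}

#' TMM normalization factors for one tissue
#'
#' Trimmed-mean-of-M-values scaling factors (reference sample chosen by
#' count-fraction upper quartile, 30% trim on M, 5% on A, factors rescaled
#' to geometric mean 1), computed with edgeR.
#'
#' @param table an `expression_table`.
#' @param tissue tissue whose samples are normalized.
#' @param genes optional gene subset (typically the expression-filtered set).
#' @return named numeric vector of per-sample scaling factors.
#' @export
tmm_normalize <- function(table, tissue, genes = NULL) {
  cols <- table$sample_meta$sample[table$sample_meta$tissue == tissue]
  if (length(cols) < 2) stop("need >= 2 samples in tissue ", tissue)
  cts <- table$counts[, cols, drop = FALSE]
  if (!is.null(genes)) cts <- cts[genes, , drop = FALSE]
  if (any(colSums(cts) == 0))
    stop("all-zero sample(s) in tissue ", tissue, ": ",
         paste(cols[colSums(cts) == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(cts, method = "TMM")
  stats::setNames(as.numeric(f), cols)
}

#' Classify sex-biased expression in one tissue
#'
#' Applies the expression filter, TMM normalization and a per-gene exact
#' negative-binomial test of male vs female counts (edgeR), then labels
#' genes: male-biased (MB) if log2 M:F fold change > `fc` with BH-adjusted
#' p < `alpha`, female-biased (FB) if log2 fold change < `-fc` with adjusted
#' p < `alpha`, otherwise unbiased (UB). The log2 fold change is computed
#' from TMM-normalized mean abundances with a pseudo-offset of 0.25 counts.
#' Genes are additionally binned into five fold-change classes
#' (FC <= -3, -3 < FC <= -1, -1 < FC < 1, 1 <= FC < 3, FC >= 3).
#'
#' @param table an `expression_table`.
#' @param tissue tissue analysed (default `"catkin"`).
#' @param fc log2 fold-change threshold (default 1, i.e. twofold).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param rpkm_threshold minimum-expression threshold passed to
#'   [filter_expressed()].
#' @return data frame of class `sexbias_calls`: `gene`, `log2fc`, `p`,
#'   `p_adj`, `category`, `fc_class`.
#' @export
classify_sex_bias <- function(table, tissue = "catkin", fc = 1, alpha = 0.05,
                              rpkm_threshold = 2) {
  meta <- table$sample_meta[table$sample_meta$tissue == tissue, ]
  if (any(table(meta$sex) < 2)) stop("need >= 2 individuals per sex")
  genes <- filter_expressed(compute_rpkm(table), table$sample_meta, tissue,
                            rpkm_threshold)
  cts <- table$counts[genes, meta$sample, drop = FALSE]

  dge <- edgeR::DGEList(counts = cts, group = factor(meta$sex, c("F", "M")))
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  dge <- suppressMessages(edgeR::estimateDisp(dge))
  et <- edgeR::exactTest(dge, pair = c("F", "M"))
  p <- et$table$PValue

  # fold change from normalized abundances with a 0.25-count pseudo-offset
  eff_lib <- dge$samples$lib.size * dge$samples$norm.factors
  norm_ab <- sweep(cts + 0.25, 2, eff_lib, "/") * 1e6
  m_mean <- rowMeans(norm_ab[, meta$sex == "M", drop = FALSE])
  f_mean <- rowMeans(norm_ab[, meta$sex == "F", drop = FALSE])
  log2fc <- log2(m_mean / f_mean)

  p_adj <- stats::p.adjust(p, method = "BH")
  category <- ifelse(log2fc > fc & p_adj < alpha, "MB",
                     ifelse(log2fc < -fc & p_adj < alpha, "FB", "UB"))
  out <- data.frame(
    gene = genes, log2fc = log2fc, p = p, p_adj = p_adj,
    category = category,
    fc_class = fc_class(log2fc),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("sexbias_calls", class(out))
  out
}

#' Five-level fold-change class
#'
#' @param log2fc numeric log2 male:female fold changes.
#' @return ordered factor with levels `FB_high` (FC <= -3), `FB_low`
#'   (-3 < FC <= -1), `UB` (-1 < FC < 1), `MB_low` (1 <= FC < 3),
#'   `MB_high` (FC >= 3).
#' @export
fc_class <- function(log2fc) {
  cut(log2fc, breaks = c(-Inf, -3, -1, 1, 3, Inf),
      labels = c("FB_high", "FB_low", "UB", "MB_low", "MB_high"),
      right = FALSE,
      include.lowest = TRUE) -> cl
  # boundary semantics: FC <= -3 is FB_high and FC >= 3 is MB_high, FC = -1
  # belongs to FB_low and FC = 1 to MB_low
  cl[log2fc == -3] <- "FB_high"
  cl[log2fc == -1] <- "FB_low"
  factor(cl, levels = c("FB_high", "FB_low", "UB", "MB_low", "MB_high"),
         ordered = TRUE)
}

#' Per-class expression summaries with Wilcoxon contrasts
#'
#' For each fold-change class (and a set of sliding fold-change thresholds)
#' computes the average male and female expression -- the per-gene mean over
#' individuals of log2(RPKM + 1), averaged over genes -- plus two-sided
#' Wilcoxon rank-sum contrasts: male vs female expression within each class,
#' MB male expression vs FB female expression, and FB male expression vs MB
#' female expression. Classes with fewer than 2 genes are reported with the
#' test skipped (`test_skipped = TRUE`).
#'
#' @param calls a `sexbias_calls` data frame.
#' @param rpkm RPKM matrix.
#' @param sample_meta sample metadata.
#' @param tissue tissue summarized.
#' @param thresholds sliding |log2 FC| thresholds for the threshold table.
#' @return list with `by_class`, `by_threshold` and `contrasts` data frames.
#' @export
expression_summaries <- function(calls, rpkm, sample_meta,
                                 tissue = "catkin",
                                 thresholds = c(1, 1.5, 2, 2.5, 3)) {
  meta <- sample_meta[sample_meta$tissue == tissue, ]
  lr <- log2(rpkm[calls$gene, meta$sample, drop = FALSE] + 1)
  m_expr <- rowMeans(lr[, meta$sex == "M", drop = FALSE])
  f_expr <- rowMeans(lr[, meta$sex == "F", drop = FALSE])

  summarize <- function(idx, label) {
    n <- length(idx)
    skip <- n < 2
    # exact p is impossible under ties; fall back to the normal
    # approximation with tie correction
    p <- if (!skip)
      suppressWarnings(stats::wilcox.test(m_expr[idx], f_expr[idx])$p.value)
    else NA_real_
    data.frame(class = label, n_genes = n,
               male_mean = if (n) mean(m_expr[idx]) else NA_real_,
               female_mean = if (n) mean(f_expr[idx]) else NA_real_,
               wilcox_p = p, test_skipped = skip,
               stringsAsFactors = FALSE)
  }

  by_class <- do.call(rbind, lapply(levels(calls$fc_class), function(cl)
    summarize(which(calls$fc_class == cl), cl)))
  by_thr <- do.call(rbind, lapply(thresholds, function(th) {
    rbind(summarize(which(calls$log2fc >= th), sprintf("MB_fc%.1f", th)),
          summarize(which(calls$log2fc <= -th), sprintf("FB_fc%.1f", th)))
  }))

  mb <- which(calls$category == "MB"); fb <- which(calls$category == "FB")
  contrast <- function(x, y, label) {
    skip <- length(x) < 2 || length(y) < 2
    data.frame(contrast = label,
               p = if (!skip) stats::wilcox.test(x, y)$p.value else NA_real_,
               test_skipped = skip, stringsAsFactors = FALSE)
  }
  contrasts <- rbind(
    contrast(m_expr[mb], f_expr[fb], "MB_male_vs_FB_female"),
    contrast(m_expr[fb], f_expr[mb], "FB_male_vs_MB_female")
  )
  list(by_class = by_class, by_threshold = by_thr, contrasts = contrasts)
}
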