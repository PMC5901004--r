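# Expression-level confounder analyses: dN/dS by expression quartile, and
# multiple regression of per-gene dN/dS on expression level and degree of
# sex bias.

#' Mean expression per gene
#'
#' The per-gene mean over samples of `log2(RPKM + 1)` in one tissue -- the
#' expression covariate used by the quartile and regression analyses.
#'
#' @param rpkm RPKM matrix.
#' @param sample_meta sample metadata.
#' @param tissue tissue averaged over.
#' @return named numeric vector.
#' @export
mean_expression <- function(rpkm, sample_meta, tissue = "catkin") {
  cols <- sample_meta$sample[sample_meta$tissue == tissue]
  rowMeans(log2(rpkm[, cols, drop = FALSE] + 1))
}

#' Sum-aggregated dN/dS by expression quartile and bias class
#'
#' Cuts genes into quartiles of mean expression (breaks computed over all
#' genes) and computes the sum-aggregated dN/dS with a percentile bootstrap
#' CI per quartile x category cell. Empty cells are skipped with a flag.
#'
#' @param genes per-gene divergence table (columns `DN`, `N`, `DS`, `S`).
#' @param expression named mean-expression vector ([mean_expression()]).
#' @param categories named category vector (gene -> UB/MB/FB).
#' @param reps bootstrap replicates.
#' @param seed integer seed.
#' @return data frame: `category`, `quartile`, `n_genes`, `dN_dS`,
#'   `ci_low`, `ci_high`, `skipped`.
#' @export
quartile_dnds <- function(genes, expression, categories, reps = 1000,
                          seed = 1L) {
  set.seed(seed)
  expr <- expression[genes$gene]
  categories <- categories[genes$gene]
  qs <- stats::quantile(expr, probs = seq(0, 1, 0.25), na.rm = TRUE)
  quart <- cut(expr, breaks = qs, labels = paste0("Q", 1:4),
               include.lowest = TRUE)
  rows <- list()
  for (cat in intersect(c("UB", "MB", "FB"), unique(categories))) {
    for (q in paste0("Q", 1:4)) {
      idx <- which(categories == cat & quart == q)
      sub <- genes[idx, , drop = FALSE]
      skipped <- nrow(sub) < 2
      est <- if (nrow(sub)) category_statistic(sub, "dN_dS") else NA_real_
      ci <- if (!skipped) bootstrap_ci(sub, "dN_dS", reps = reps)
            else c(NA_real_, NA_real_)
      rows[[paste(cat, q)]] <- data.frame(
        category = cat, quartile = q, n_genes = nrow(sub), dN_dS = est,
        ci_low = ci[[1]], ci_high = ci[[2]], skipped = skipped,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinal degree-of-sex-bias code
#'
#' Maps the five fold-change classes to an ordinal code. The default
#' `signed` coding runs -2 (highly female-biased, FC <= -3) to +2 (highly
#' male-biased, FC >= 3), so a negative regression coefficient means lower
#' dN/dS toward male bias; `magnitude` codes bias strength 0 (unbiased),
#' 1 (twofold), 2 (eightfold) regardless of direction.
#'
#' @param fc_class factor from [fc_class()].
#' @param coding `"signed"` or `"magnitude"`.
#' @return integer vector.
#' @export
bias_degree <- function(fc_class, coding = c("signed", "magnitude")) {
  coding <- match.arg(coding)
  signed <- as.integer(fc_class) - 3L   # FB_high..MB_high -> -2..2
  if (coding == "signed") signed else abs(signed)
}

#' Multiple regression of dN/dS on expression and sex-bias degree
#'
#' Ordinary least squares of the per-gene dN/dS ratio on mean log2 RPKM
#' expression, the ordinal degree of sex bias, and their interaction.
#' Genes with undefined dN/dS (dS = 0) are excluded and counted.
#'
#' @param genes per-gene divergence table.
#' @param expression named mean-expression vector.
#' @param fc_classes named [fc_class()] factor (gene -> class).
#' @param coding bias-degree coding, see [bias_degree()].
#' @return object of class `dnds_regression`: list with `coefficients`
#'   data frame (`term`, `beta`, `p`), `adj_r_squared`, `r_squared`,
#'   `n_genes`, `n_excluded`, `fit` (the `lm` object).
#' @export
dnds_regression <- function(genes, expression, fc_classes,
                            coding = c("signed", "magnitude")) {
  coding <- match.arg(coding)
  df <- data.frame(
    gene = genes$gene,
    dnds = ifelse(genes$DS > 0 & genes$S > 0 & genes$N > 0,
                  (genes$DN / genes$N) / (genes$DS / genes$S), NA_real_),
    expr = as.numeric(expression[genes$gene]),
    bias = bias_degree(fc_classes[genes$gene], coding),
    stringsAsFactors = FALSE)
  excluded <- sum(is.na(df$dnds))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::lm(dnds ~ expr * bias, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient regression; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(coefficients = data.frame(term = rownames(co), beta = co[, 1],
                                   p = co[, 4], row.names = NULL,
                                   stringsAsFactors = FALSE),
         r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared,
         n_genes = nrow(df), n_excluded = excluded, fit = fit),
    class = "dnds_regression")
}

#' @export
print.dnds_regression <- function(x, ...) {
  cat(sprintf("dN/dS regression on %d genes (%d excluded, dS = 0)\n",
              x$n_genes, x$n_excluded))
  print(x$coefficients, digits = 3)
  cat(sprintf("r^2 = %.4f, adjusted r^2 = %.4f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}
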