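# The category-level inferential engine: sum-aggregated statistics,
# percentile bootstrap confidence intervals, and permutation contrasts, all
# resampling genes as the unit.

# statistic definitions on a per-gene table: each is a ratio of summed
# numerators to summed denominators (never a mean of per-gene ratios, which
# blows up for low-dS genes), or a plain mean for DoS and ENC
.STAT_DEFS <- list(
  dN     = list(num = "DN", den = "N"),
  dS     = list(num = "DS", den = "S"),
  pN     = list(num = "PN", den = "N"),
  pS     = list(num = "PS", den = "S"),
  dN_dS  = list(ratio = c("dN", "dS")),
  pN_pS  = list(ratio = c("pN", "pS")),
  DoS_mean = list(mean = "DoS"),
  ENC_mean = list(mean = "Nc")
)

#' Sum-aggregated ratio over a gene set
#'
#' Computes `sum(numerator) / sum(denominator)` over genes -- the
#' aggregation used for all category-level divergence and polymorphism
#' statistics, which avoids the unstable per-gene ratios of low-dS genes.
#'
#' @param genes per-gene data frame.
#' @param num,den column names of the numerator and denominator.
#' @return numeric scalar (`NA` with a message if the denominator sums
#'   to 0).
#' @export
aggregate_ratio <- function(genes, num, den) {
  dsum <- sum(genes[[den]], na.rm = TRUE)
  if (dsum <= 0) {
    message(sprintf("aggregate_ratio: sum(%s) = 0, statistic undefined", den))
    return(NA_real_)
  }
  sum(genes[[num]], na.rm = TRUE) / dsum
}

#' Category statistic of a gene table
#'
#' Evaluates one of the supported statistics on a per-gene table:
#' `dN`, `dS`, `pN`, `pS` (sum-aggregated ratios), `dN_dS`, `pN_pS`
#' (ratios of those aggregates), `DoS_mean`, `ENC_mean` (means over genes
#' with the quantity defined).
#'
#' @param genes per-gene data frame (columns as produced by
#'   [mk_input_table()], plus `DoS`/`Nc` where needed).
#' @param statistic statistic name.
#' @return numeric scalar.
#' @export
category_statistic <- function(genes, statistic) {
  def <- .STAT_DEFS[[statistic]]
  if (is.null(def)) stop("unknown statistic: ", statistic)
  if (!is.null(def$mean)) return(mean(genes[[def$mean]], na.rm = TRUE))
  if (!is.null(def$ratio)) {
    a <- category_statistic(genes, def$ratio[1])
    b <- category_statistic(genes, def$ratio[2])
    return(if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b)
  }
  aggregate_ratio(genes, def$num, def$den)
}

#' Percentile bootstrap confidence interval for a category statistic
#'
#' Resamples genes with replacement, recomputes the sum-aggregated
#' statistic, and returns the percentile interval.
#'
#' @param genes per-gene data frame (>= 2 rows).
#' @param statistic statistic name (see [category_statistic()]).
#' @param reps bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @return named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(genes, statistic, reps = 1000, level = 0.95,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genes)
  if (n < 2) stop("bootstrap_ci needs >= 2 genes")
  vals <- vapply(seq_len(reps), function(i) {
    category_statistic(genes[sample.int(n, n, replace = TRUE), , drop = FALSE],
                       statistic)
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Permutation contrast between two gene categories
#'
#' Two-sided permutation test of the difference in a sum-aggregated
#' statistic between two gene sets: category labels are shuffled preserving
#' group sizes, and `p = (1 + #{|diff_perm| >= |diff_obs|}) / (reps + 1)`.
#'
#' @param genes_a,genes_b per-gene data frames for the two categories.
#' @param statistic statistic name (see [category_statistic()]).
#' @param reps permutation replicates (default 1000).
#' @param seed optional integer seed.
#' @return object of class `contrast_result`: list with `statistic`,
#'   `observed` (difference a - b), `p`, `method`, `reps`.
#' @export
permutation_contrast <- function(genes_a, genes_b, statistic, reps = 1000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(genes_a) || !nrow(genes_b)) stop("both groups must be nonempty")
  obs <- category_statistic(genes_a, statistic) -
         category_statistic(genes_b, statistic)
  pool <- rbind(genes_a[, intersect(names(genes_a), names(genes_b)),
                        drop = FALSE],
                genes_b[, intersect(names(genes_a), names(genes_b)),
                        drop = FALSE])
  na <- nrow(genes_a); ntot <- nrow(pool)
  exceed <- 0L
  for (i in seq_len(reps)) {
    idx <- sample.int(ntot, na)
    d <- category_statistic(pool[idx, , drop = FALSE], statistic) -
         category_statistic(pool[-idx, , drop = FALSE], statistic)
    if (!is.na(d) && abs(d) >= abs(obs)) exceed <- exceed + 1L
  }
  structure(list(statistic = statistic, observed = obs,
                 p = (1 + exceed) / (reps + 1),
                 method = "permutation", reps = reps),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s contrast (%s): observed difference %.4g, p = %.4g (%d reps)\n",
              x$statistic, x$method, x$observed, x$p, x$reps))
  invisible(x)
}

#' Assign genes to genomic strata
#'
#' Splits genes into the autosomal + recombining-Z stratum and the
#' nonrecombining-Z stratum by overlap of the gene interval with a set of
#' nonrecombining regions (for the willow Z chromosome, the 3.5-8.8 Mbp
#' region).
#'
#' @param gene_coords data frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based).
#' @param regions nonrecombining intervals: a `GRanges`, a data frame with
#'   `chrom`, `start`, `end`, or the path of a BED file.
#' @param genes optional gene ids to stratify; genes absent from
#'   `gene_coords` are excluded with a message.
#' @return named factor (levels `autosomal`, `nonrecombining_Z`) indexed by
#'   gene id.
#' @export
stratify <- function(gene_coords, regions, genes = gene_coords$gene) {
  missing <- setdiff(genes, gene_coords$gene)
  if (length(missing))
    message("stratify: no coordinates, excluding: ",
            paste(missing, collapse = ", "))
  gene_coords <- gene_coords[gene_coords$gene %in% genes, , drop = FALSE]
  if (is.character(regions)) {
    regions <- rtracklayer::import(regions, format = "BED")
  } else if (is.data.frame(regions)) {
    regions <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start, regions$end))
  }
  gr <- GenomicRanges::GRanges(
    gene_coords$chrom,
    IRanges::IRanges(gene_coords$start, gene_coords$end))
  hits <- GenomicRanges::countOverlaps(gr, regions) > 0
  stats::setNames(
    factor(ifelse(hits, "nonrecombining_Z", "autosomal"),
           levels = c("autosomal", "nonrecombining_Z")),
    gene_coords$gene)
}

#' Category summary table with bootstrap CIs and permutation contrasts
#'
#' Builds the headline stratum x category x statistic table: point
#' estimates of the sum-aggregated statistics with percentile bootstrap
#' confidence intervals, and permutation p-values for the MB-UB, FB-UB and
#' MB-FB contrasts (no multiplicity adjustment).
#'
#' @param genes per-gene table ([mk_input_table()] output, optionally with
#'   `DoS` and `Nc` columns).
#' @param categories named category factor/character (gene -> UB/MB/FB).
#' @param strata optional named stratum factor (gene -> stratum); a single
#'   stratum is assumed when omitted.
#' @param statistics statistic names to tabulate.
#' @param reps bootstrap and permutation replicates.
#' @param seed integer seed.
#' @return data frame of class `category_table`.
#' @export
category_table <- function(genes, categories,
                           strata = NULL,
                           statistics = c("dN", "dS", "dN_dS",
                                          "pN", "pS", "pN_pS"),
                           reps = 1000, seed = 1L) {
  set.seed(seed)
  categories <- categories[genes$gene]
  if (is.null(strata)) {
    strata <- stats::setNames(
      factor(rep("all", nrow(genes))), genes$gene)
  } else {
    strata <- strata[genes$gene]
  }
  rows <- list()
  for (st in levels(droplevels(strata))) {
    idx_st <- which(strata == st & !is.na(categories))
    for (stat in statistics) {
      pieces <- list()
      for (cat in c("UB", "MB", "FB")) {
        gsub_ <- genes[idx_st, ][categories[idx_st] == cat, , drop = FALSE]
        if (!nrow(gsub_)) next
        est <- category_statistic(gsub_, stat)
        ci <- if (nrow(gsub_) >= 2)
          bootstrap_ci(gsub_, stat, reps = reps) else c(NA_real_, NA_real_)
        pieces[[cat]] <- data.frame(
          stratum = st, statistic = stat, category = cat,
          n_genes = nrow(gsub_), estimate = est,
          ci_low = ci[[1]], ci_high = ci[[2]], stringsAsFactors = FALSE)
      }
      # permutation contrasts vs UB and MB vs FB
      get_genes <- function(cat) {
        genes[idx_st, ][categories[idx_st] == cat, , drop = FALSE]
      }
      for (pair in list(c("MB", "UB"), c("FB", "UB"), c("MB", "FB"))) {
        nm <- paste0("p_", pair[1], "_vs_", pair[2])
        ga <- get_genes(pair[1]); gb <- get_genes(pair[2])
        pval <- if (nrow(ga) && nrow(gb))
          permutation_contrast(ga, gb, stat, reps = reps)$p else NA_real_
        for (cat in names(pieces)) pieces[[cat]][[nm]] <- pval
      }
      rows <- c(rows, pieces)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("category_table", class(out))
  out
}
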