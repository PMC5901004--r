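# RPKM, expression filtering, TMM normalization and sex-bias
# classification.

test_that("RPKM follows its definition and is scale invariant", {
  samples <- c(paste0(c("M1", "M2", "M3", "F1", "F2", "F3"), "_catkin"),
               paste0(c("M1", "M2", "M3", "F1", "F2", "F3"), "_leaf"))
  counts <- matrix(rep(c(10, 1e6 - 10), 12), nrow = 2,
                   dimnames = list(c("g1", "g2"), samples))
  tab <- make_expression_table(counts, lengths_bp = c(g1 = 1000, g2 = 1000))
  # library size 1e6, length 1000 bp, count 10 -> RPKM 10
  r <- compute_rpkm(tab)
  expect_equal(r["g1", 1], 10)
  # zero count -> zero RPKM
  tab$counts["g1", 2] <- 0
  expect_equal(compute_rpkm(tab)["g1", 2], 0)
  # doubling all counts of a sample leaves its RPKM unchanged
  tab2 <- tab
  tab2$counts[, 3] <- tab2$counts[, 3] * 2
  expect_equal(compute_rpkm(tab2)[, 3], compute_rpkm(tab)[, 3])
  # zero library size errors with the sample name
  tab3 <- tab
  tab3$counts[, 4] <- 0
  expect_error(compute_rpkm(tab3), colnames(tab3$counts)[4])
})

test_that("expression filter keeps genes with >= ceil(n/2) individuals at threshold in one sex", {
  rpkm <- rbind(
    keep_m  = c(2.5, 2.1, 0.5, 0, 0, 0),       # 2 of 3 males >= 2
    drop    = c(1.9, 1.9, 1.9, 1.9, 1.9, 1.9), # nobody reaches 2
    boundary = c(2.0, 2.0, 0, 0, 0, 0),        # exactly 2.0 in 2 males
    keep_f  = c(0, 0, 0, 8, 9, 0))
  colnames(rpkm) <- paste0(c("M1", "M2", "M3", "F1", "F2", "F3"), "_catkin")
  meta <- data.frame(sample = colnames(rpkm),
                     individual = sub("_catkin", "", colnames(rpkm)),
                     sex = rep(c("M", "F"), each = 3),
                     tissue = "catkin", stringsAsFactors = FALSE)
  kept <- filter_expressed(rpkm, meta, "catkin")
  expect_setequal(kept, c("keep_m", "boundary", "keep_f"))
})

test_that("TMM factors behave on identical, scaled and spiked samples", {
  set.seed(11)
  base <- rnbinom(2000, mu = 200, size = 5) + 1
  counts <- cbind(A = base, B = base, C = base, D = base)
  rownames(counts) <- paste0("g", seq_along(base))
  meta <- data.frame(sample = colnames(counts),
                     individual = colnames(counts),
                     sex = c("M", "M", "F", "F"), tissue = "catkin",
                     stringsAsFactors = FALSE)
  tab <- expression_table(counts, stats::setNames(rep(1000, nrow(counts)),
                                                  rownames(counts)), meta)
  expect_equal(unname(tmm_normalize(tab, "catkin")), rep(1, 4),
               tolerance = 1e-9)
  # doubling a sample count-wise changes no M-value: factors stay equal
  tab2 <- tab; tab2$counts[, "B"] <- tab2$counts[, "B"] * 2L
  f2 <- tmm_normalize(tab2, "catkin")
  expect_equal(unname(f2), rep(1, 4), tolerance = 1e-9)
  # spiking 5% of genes 10x in one sample: trimming keeps the effective
  # library size (library x factor) of that sample essentially unchanged,
  # i.e. unspiked genes stay comparably normalized
  tab3 <- tab
  spike <- sample(nrow(counts), nrow(counts) * 0.05)
  tab3$counts[spike, "B"] <- tab3$counts[spike, "B"] * 10L
  f3 <- tmm_normalize(tab3, "catkin")
  # (factors are rescaled to geometric mean 1, so compare B relative to A)
  rel_before <- (sum(tab$counts[, "B"]) * f2[["B"]]) /
    (sum(tab$counts[, "A"]) * f2[["A"]])
  rel_after <- (sum(tab3$counts[, "B"]) * f3[["B"]]) /
    (sum(tab3$counts[, "A"]) * f3[["A"]])
  expect_lt(abs(rel_after - rel_before) / rel_before, 0.05)
  # an all-zero sample is an error
  tab4 <- tab; tab4$counts[, "C"] <- 0L
  expect_error(tmm_normalize(tab4, "catkin"), "all-zero")
})

test_that("strong injected bias is classified with the right sign and label", {
  cfg <- sim_config(seed = 17, n_genes_per_category = 60,
                    gene_length_codons = 200, sexbias_log2fc = 3,
                    nb_dispersion = 0.05)
  expr <- simulate_expression(cfg)
  calls <- classify_sex_bias(expr, "catkin")
  truth <- rep(c("UB", "MB", "FB"), each = 60)
  names(truth) <- rownames(expr$counts)
  tab <- table(truth[calls$gene], calls$category)
  # power ~ 1 at log2FC = 3 with low dispersion
  expect_gt(tab["MB", "MB"] / sum(tab["MB", ]), 0.95)
  expect_gt(tab["FB", "FB"] / sum(tab["FB", ]), 0.95)
  expect_gt(tab["UB", "UB"] / sum(tab["UB", ]), 0.9)
})

test_that("null expression data yields few significant calls", {
  cfg <- sim_config(seed = 19, n_genes_per_category = 1200,
                    gene_length_codons = 200, sexbias_log2fc = 0)
  expr <- simulate_expression(cfg)
  calls <- classify_sex_bias(expr, "catkin")
  expect_lt(mean(calls$category != "UB"), 0.05)
})

test_that("swapping sex labels negates log2fc and maps MB to FB", {
  cfg <- sim_config(seed = 23, n_genes_per_category = 40,
                    gene_length_codons = 200)
  expr <- simulate_expression(cfg)
  calls <- classify_sex_bias(expr, "catkin")
  swapped <- expr
  swapped$sample_meta$sex <- c(M = "F", F = "M")[swapped$sample_meta$sex]
  calls2 <- classify_sex_bias(swapped, "catkin")
  m <- merge(calls, calls2, by = "gene")
  expect_equal(m$log2fc.x, -m$log2fc.y, tolerance = 1e-9)
  expect_identical(as.character(m$category.x),
                   c(MB = "FB", FB = "MB", UB = "UB")[as.character(m$category.y)],
                   ignore_attr = TRUE)
})

test_that("category thresholds and BH adjustment hold for every call", {
  cfg <- sim_config(seed = 29, n_genes_per_category = 80,
                    gene_length_codons = 200)
  expr <- simulate_expression(cfg)
  calls <- classify_sex_bias(expr, "catkin")
  # partition is exhaustive and disjoint
  expect_true(all(calls$category %in% c("MB", "FB", "UB")))
  # category rule matches the thresholds exactly
  expect_identical(calls$category,
                   ifelse(calls$log2fc > 1 & calls$p_adj < .05, "MB",
                          ifelse(calls$log2fc < -1 & calls$p_adj < .05,
                                 "FB", "UB")))
  # BH: p_adj >= p, and monotone non-decreasing in raw-p order
  expect_true(all(calls$p_adj >= calls$p - 1e-12))
  ord <- order(calls$p)
  expect_true(all(diff(calls$p_adj[ord]) >= -1e-12))
})

test_that("fold-change classes use the documented boundaries", {
  fc <- c(-3.5, -3, -2, -1, -0.5, 0.99, 1, 2.5, 3, 5)
  expect_identical(as.character(fc_class(fc)),
                   c("FB_high", "FB_high", "FB_low", "FB_low", "UB", "UB",
                     "MB_low", "MB_low", "MB_high", "MB_high"))
})

test_that("expression summaries report class means and skip degenerate tests", {
  cfg <- sim_config(seed = 37, n_genes_per_category = 50,
                    gene_length_codons = 200, sexbias_log2fc = 2)
  expr <- simulate_expression(cfg)
  calls <- classify_sex_bias(expr, "catkin")
  rpkm <- compute_rpkm(expr)
  sm <- expression_summaries(calls, rpkm, expr$sample_meta, "catkin")
  mb <- sm$by_class[sm$by_class$class %in% c("MB_low", "MB_high"), ]
  mb <- mb[mb$n_genes > 0, ]
  expect_true(all(mb$male_mean > mb$female_mean))
  fb <- sm$by_class[sm$by_class$class %in% c("FB_low", "FB_high"), ]
  fb <- fb[fb$n_genes > 0, ]
  expect_true(all(fb$male_mean < fb$female_mean))
  # identical male and female expression vectors -> p near 1
  calls1 <- calls[calls$category == "UB", ][1:20, ]
  rp <- rpkm
  meta <- expr$sample_meta
  rp[, meta$sample[meta$tissue == "catkin" & meta$sex == "F"]] <-
    rp[, meta$sample[meta$tissue == "catkin" & meta$sex == "M"]]
  sm2 <- expression_summaries(calls1, rp, meta, "catkin")
  ub_row <- sm2$by_class[sm2$by_class$class == "UB", ]
  expect_gt(ub_row$wilcox_p, 0.99)
  # a single-gene class is summarized but its test is skipped
  single <- calls[1, , drop = FALSE]
  sm3 <- expression_summaries(single, rpkm, meta, "catkin")
  row <- sm3$by_class[sm3$by_class$n_genes == 1, ]
  expect_true(all(row$test_skipped))
  expect_false(any(is.na(row$male_mean)))
})
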