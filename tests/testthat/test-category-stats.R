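# Sum-aggregated statistics, bootstrap intervals, permutation contrasts
# and genomic stratification.

test_that("aggregate ratio is the ratio of sums, not the mean of ratios", {
  genes <- data.frame(DN = c(1, 3), N = c(100, 300))
  expect_equal(aggregate_ratio(genes, "DN", "N"), 4 / 400)
  expect_equal(aggregate_ratio(genes[1, ], "DN", "N"), 0.01)
  expect_message(
    expect_true(is.na(aggregate_ratio(data.frame(DN = 1, N = 0), "DN", "N"))),
    "undefined")
})

test_that("the aggregate of a union lies between the group aggregates", {
  set.seed(5)
  for (i in 1:20) {
    a <- data.frame(DN = rpois(10, 3), N = runif(10, 100, 500))
    b <- data.frame(DN = rpois(15, 5), N = runif(15, 100, 500))
    u <- aggregate_ratio(rbind(a, b), "DN", "N")
    bounds <- range(aggregate_ratio(a, "DN", "N"),
                    aggregate_ratio(b, "DN", "N"))
    expect_gte(u, bounds[1]); expect_lte(u, bounds[2])
  }
})

test_that("dN/dS statistic equals the concatenated category estimate", {
  set.seed(6)
  genes <- data.frame(gene = paste0("g", 1:12),
                      N = runif(12, 200, 400), S = runif(12, 80, 150),
                      DN = rpois(12, 2), DS = rpois(12, 4) + 1)
  expect_equal(category_statistic(genes, "dN_dS"),
               concatenated_category_estimate(genes, rep("UB", 12))$omega)
})

test_that("bootstrap interval is degenerate for identical genes and deterministic", {
  genes <- data.frame(DN = rep(2, 10), N = rep(300, 10),
                      DS = rep(4, 10), S = rep(120, 10))
  ci <- bootstrap_ci(genes, "dN_dS", reps = 200, seed = 42)
  point <- category_statistic(genes, "dN_dS")
  expect_equal(unname(ci), c(point, point))
  set.seed(1)
  genes2 <- data.frame(DN = rpois(20, 3), N = runif(20, 200, 400),
                       DS = rpois(20, 5) + 1, S = runif(20, 80, 160))
  ci_a <- bootstrap_ci(genes2, "dN_dS", reps = 500, seed = 7)
  ci_b <- bootstrap_ci(genes2, "dN_dS", reps = 500, seed = 7)
  expect_identical(ci_a, ci_b)
  expect_lte(ci_a[["low"]], category_statistic(genes2, "dN_dS"))
  expect_gte(ci_a[["high"]], category_statistic(genes2, "dN_dS"))
})

test_that("bootstrap interval width shrinks roughly as 1/sqrt(n)", {
  set.seed(8)
  mk <- function(n) data.frame(DN = rpois(n, 3), N = rep(300, n),
                               DS = rpois(n, 6), S = rep(120, n))
  w <- vapply(c(50, 800), function(n) {
    ci <- bootstrap_ci(mk(n), "dN_dS", reps = 400, seed = 3)
    ci[["high"]] - ci[["low"]]
  }, numeric(1))
  expect_gt(w[1] / w[2], 2)   # 16x genes -> ~4x narrower
})

test_that("permutation contrast of a set against itself gives p = 1", {
  genes <- data.frame(DN = rpois(15, 3), N = rep(300, 15),
                      DS = rpois(15, 5), S = rep(120, 15))
  ct <- permutation_contrast(genes, genes, "dN_dS", reps = 99, seed = 5)
  expect_equal(ct$p, 1)
  expect_equal(ct$observed, 0)
})

test_that("permutation p respects its attainable range and detects real differences", {
  set.seed(12)
  a <- data.frame(DN = rpois(100, 1), N = rep(300, 100),
                  DS = rpois(100, 5), S = rep(120, 100))
  b <- data.frame(DN = rpois(100, 6), N = rep(300, 100),
                  DS = rpois(100, 5), S = rep(120, 100))
  ct <- permutation_contrast(a, b, "dN_dS", reps = 199, seed = 5)
  expect_gte(ct$p, 1 / 200)
  expect_lte(ct$p, 1)
  expect_lt(ct$p, 0.05)
  expect_lt(ct$observed, 0)
})

test_that("stratification assigns genes by interval overlap and partitions", {
  coords <- data.frame(
    gene = c("gZ1", "gZ2", "gA1", "gA2", "gZedge"),
    chrom = c("Z", "Z", "chr2", "chr3", "Z"),
    start = c(4e6, 8.0e6, 4e6, 1e5, 8.9e6),
    end = c(4.01e6, 8.1e6, 4.01e6, 1.1e5, 9.0e6))
  regions <- data.frame(chrom = "Z", start = 3.5e6, end = 8.8e6)
  s <- stratify(coords, regions)
  expect_equal(as.character(s[c("gZ1", "gZ2")]),
               rep("nonrecombining_Z", 2))
  expect_equal(as.character(s[c("gA1", "gA2", "gZedge")]),
               rep("autosomal", 3))
  expect_equal(sum(table(s)), nrow(coords))
  expect_message(stratify(coords, regions, genes = c(coords$gene, "gX")),
                 "gX")
})

test_that("category table reports estimates, CIs and contrast p-values", {
  set.seed(15)
  genes <- data.frame(gene = paste0("g", 1:60),
                      N = runif(60, 200, 400), S = runif(60, 80, 160),
                      DN = rpois(60, 2), DS = rpois(60, 5),
                      PN = rpois(60, 2), PS = rpois(60, 5))
  cats <- stats::setNames(rep(c("UB", "MB", "FB"), each = 20), genes$gene)
  tab <- category_table(genes, cats, reps = 99, seed = 2)
  expect_true(all(c("estimate", "ci_low", "ci_high",
                    "p_MB_vs_UB", "p_FB_vs_UB", "p_MB_vs_FB") %in%
                    names(tab)))
  expect_true(all(tab$ci_low <= tab$estimate + 1e-12))
  expect_true(all(tab$ci_high >= tab$estimate - 1e-12))
  expect_true(all(tab$p_MB_vs_UB >= 1 / 100 & tab$p_MB_vs_UB <= 1))
})
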