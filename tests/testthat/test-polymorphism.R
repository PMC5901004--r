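# SNP validity rules, synonymous/nonsynonymous classification, and the
# divergence/polymorphism codon-matching filter.

test_that("the coverage rule boundary is >= 20 in at least half of one sex", {
  snp <- data.frame(codon_index = 2, position_in_codon = 3,
                    alt_base = "C",
                    alt_counts = I(list(c(10, 10, 10, 0, 0, 0))))
  # coverage 19 everywhere -> rejected
  st19 <- make_site_table("g1", 4, coverage = 19, snps = snp)
  expect_equal(nrow(filter_snps(st19)), 0)
  # coverage 20 everywhere -> accepted (pooled MAF 30/120 = 0.25)
  st20 <- make_site_table("g1", 4, coverage = 20, snps = snp)
  expect_equal(nrow(filter_snps(st20)), 1)
  # coverage 25 in 2 of 3 males only -> coverage rule satisfied; MAF pools
  # the passing individuals only (20/50 = 0.4)
  st2 <- make_site_table("g1", 4, coverage = c(25, 25, 19, 19, 19, 19),
                         snps = data.frame(
                           codon_index = 2, position_in_codon = 3,
                           alt_base = "C",
                           alt_counts = I(list(c(10, 10, 0, 0, 0, 0)))))
  expect_equal(nrow(filter_snps(st2)), 1)
})

test_that("the MAF rule boundary is a pooled minor allele frequency of 0.20", {
  mk <- function(alt_per_ind) {
    make_site_table("g1", 4, coverage = 20,
                    snps = data.frame(codon_index = 2, position_in_codon = 3,
                                      alt_base = "C",
                                      alt_counts = I(list(alt_per_ind))))
  }
  # pooled 18/120 = 0.15 -> rejected
  expect_equal(nrow(filter_snps(mk(rep(3, 6)))), 0)
  # pooled 24/120 = 0.20 -> accepted (inclusive)
  expect_equal(nrow(filter_snps(mk(rep(4, 6)))), 1)
})

test_that("the supporting-read rule requires >= 3 pooled alternate reads", {
  mk <- function(alt_per_ind, cov = 20) {
    make_site_table("g1", 4, coverage = cov,
                    snps = data.frame(codon_index = 2, position_in_codon = 3,
                                      alt_base = "C",
                                      alt_counts = I(list(alt_per_ind))))
  }
  # 2 alt reads pooled: fails min_reads even with min_maf lowered
  expect_equal(nrow(filter_snps(mk(c(2, 0, 0, 0, 0, 0)), min_maf = 0)), 0)
  expect_equal(nrow(filter_snps(mk(c(3, 0, 0, 0, 0, 0)), min_maf = 0)), 1)
})

test_that("filter_snps is monotone in its thresholds", {
  cfg <- sim_config(seed = 71, n_genes_per_category = 3,
                    gene_length_codons = 100, snp_rate_per_site = 0.05,
                    coverage_mean = 25)
  sim <- simulate_ortholog_set(cfg)
  st <- simulate_site_table(sim$alignments, sim$truth, cfg)
  base <- nrow(filter_snps(st$sites, min_cov = 15, min_maf = 0.1))
  stricter_cov <- nrow(filter_snps(st$sites, min_cov = 25, min_maf = 0.1))
  stricter_maf <- nrow(filter_snps(st$sites, min_cov = 15, min_maf = 0.3))
  expect_lte(stricter_cov, base)
  expect_lte(stricter_maf, base)
})

test_that("SNPs are classified against the reading frame", {
  ref <- list(g1 = c("GTT", "TAT", "AAA"))
  snps <- data.frame(
    gene = "g1",
    codon_index = c(1, 1, 2),
    position_in_codon = c(3, 1, 3),
    alt_base = c("C", "A", "A"),
    stringsAsFactors = FALSE)
  out <- classify_polymorphism(snps, ref)
  expect_equal(out$type, c("syn", "nonsyn", "nonsyn"))  # GTT>GTC, GTT>ATT, TAT>TAA
  expect_equal(out$creates_stop, c(FALSE, FALSE, TRUE))
  # two variants in codon 1 are flagged as multi-variant
  expect_equal(out$multi_variant, c(TRUE, TRUE, FALSE))
})

test_that("codon matching requires full coverage, no gaps and no masking", {
  base <- rep_codons(c("GTT", "GCA"), 10)
  aln <- make_alignment(base)
  # site 3 of codon 4 has coverage 19 everywhere -> codon 4 unmatched
  st <- make_site_table("g1", 20, coverage = 30)
  st$coverage[st$codon_index == 4 & st$position_in_codon == 3] <- 19
  st$ref_count <- st$coverage
  matched <- match_codons(aln, st)
  expect_false(4 %in% matched)
  expect_setequal(matched, setdiff(1:20, 4))
  # a masked codon drops out even with full coverage
  aln2 <- aln; aln2$mask["P_trichocarpa", 7] <- TRUE
  expect_false(7 %in% match_codons(aln2, make_site_table("g1", 20,
                                                         coverage = 30)))
  # matched N + S = 3 x matched codons
  res <- focal_branch_substitutions(aln, codons = matched)
  expect_equal(res$N + res$S, 3 * length(matched))
})

test_that("zero SNP input gives PN = PS = 0 and the MK table is consistent", {
  cfg <- sim_config(seed = 73, n_genes_per_category = 2,
                    gene_length_codons = 110, snp_rate_per_site = 0,
                    coverage_mean = 40)
  sim <- simulate_ortholog_set(cfg)
  st <- simulate_site_table(sim$alignments, sim$truth, cfg)
  tab <- mk_input_table(sim$alignments, st$sites)
  expect_true(all(tab$PN == 0))
  expect_true(all(tab$PS == 0))
  expect_equal(tab$N + tab$S, 3 * tab$n_matched_codons)
})

test_that("recovered polymorphism counts track the injected truth", {
  cfg <- sim_config(seed = 79, n_genes_per_category = 15,
                    gene_length_codons = 200, snp_rate_per_site = 0.03,
                    coverage_mean = 40)
  sim <- simulate_ortholog_set(cfg)
  st <- simulate_site_table(sim$alignments, sim$truth, cfg)
  tab <- mk_input_table(sim$alignments, st$sites)
  # the filtered table keeps only MAF >= .2 truth SNPs in matched codons;
  # compare the syn:nonsyn ratio with the truth restricted the same way
  truth <- st$truth$snps[st$truth$snps$true_maf >= 0.25, ]
  ratio_truth <- sum(truth$type == "nonsyn") / sum(truth$type == "syn")
  ratio_est <- sum(tab$PN) / sum(tab$PS)
  expect_gt(sum(tab$PN) + sum(tab$PS), 50)
  expect_lt(abs(ratio_est - ratio_truth), 0.15)
})
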