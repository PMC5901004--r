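# Synthetic-data generator: configuration validation, ground-truth
# consistency, and the statistical structure of the simulated data.

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(n_individuals_per_sex = 1), "individuals")
  expect_error(sim_config(omega_by_category = c(UB = -1, MB = .2, FB = .2)),
               "omega")
  expect_error(sim_config(branch_lengths = c(
    S_viminalis = 2.5, S_suchowensis = .01, salix_stem = .01,
    populus_stem = .01, aspen_stem = .01, P_tremula = .01,
    P_tremuloides = .01, P_trichocarpa = .01)), "saturation")
  expect_error(sim_config(coverage_mean = 0), "coverage")
  # omega = 0 is a legitimate boundary (complete constraint)
  expect_s3_class(sim_config(omega_by_category = c(UB = .2, MB = 0, FB = .2)),
                  "sim_config")
})

test_that("omega = 0 on the focal branch yields no focal nonsynonymous changes", {
  cfg <- sim_config(seed = 5, n_genes_per_category = 5,
                    gene_length_codons = 120,
                    omega_by_category = c(UB = 0, MB = 0, FB = 0))
  sim <- simulate_ortholog_set(cfg)
  foc <- sim$truth$substitutions[
    sim$truth$substitutions$branch == "S_viminalis", ]
  expect_true(all(foc$type == "syn"))
})

test_that("zero branch lengths give five identical tip sequences", {
  bl <- c(S_viminalis = 0, S_suchowensis = 0, salix_stem = 0,
          populus_stem = 0, aspen_stem = 0, P_tremula = 0,
          P_tremuloides = 0, P_trichocarpa = 0)
  cfg <- sim_config(seed = 2, n_genes_per_category = 2,
                    gene_length_codons = 50, branch_lengths = bl)
  sim <- simulate_ortholog_set(cfg)
  expect_equal(nrow(sim$truth$substitutions), 0)
  for (aln in sim$alignments) {
    expect_true(all(apply(aln$codons, 2, function(x) length(unique(x)) == 1)))
    expect_equal(unname(aln$codons[1, ]), sim$truth$root_seqs[[aln$id]])
  }
})

test_that("replaying the substitution log reproduces every tip sequence", {
  cfg <- sim_config(seed = 9, n_genes_per_category = 4,
                    gene_length_codons = 150)
  sim <- simulate_ortholog_set(cfg)
  paths <- list(
    S_viminalis = c("salix_stem", "S_viminalis"),
    S_suchowensis = c("salix_stem", "S_suchowensis"),
    P_trichocarpa = c("populus_stem", "P_trichocarpa"),
    P_tremula = c("populus_stem", "aspen_stem", "P_tremula"),
    P_tremuloides = c("populus_stem", "aspen_stem", "P_tremuloides"))
  for (aln in sim$alignments) {
    sub <- sim$truth$substitutions[sim$truth$substitutions$gene == aln$id, ]
    for (taxon in names(paths)) {
      seqv <- sim$truth$root_seqs[[aln$id]]
      for (br in paths[[taxon]]) {
        s2 <- sub[sub$branch == br, ]
        for (i in seq_len(nrow(s2))) {
          expect_identical(seqv[s2$codon[i]], s2$from_codon[i])
          seqv[s2$codon[i]] <- s2$to_codon[i]
        }
      }
      expect_identical(seqv, unname(aln$codons[taxon, ]))
    }
  }
})

test_that("all simulated codons are sense codons", {
  cfg <- sim_config(seed = 13, n_genes_per_category = 5,
                    gene_length_codons = 100)
  sim <- simulate_ortholog_set(cfg)
  for (aln in sim$alignments)
    expect_true(all(aln$codons %in% SENSE))
})

test_that("expression simulation injects bias in catkin only", {
  cfg <- sim_config(seed = 21, n_genes_per_category = 150,
                    gene_length_codons = 100, sexbias_log2fc = 2)
  expr <- simulate_expression(cfg)
  genes <- data.frame(gene = rownames(expr$counts),
                      category = rep(c("UB", "MB", "FB"), each = 150))
  meta <- expr$sample_meta
  mean_by <- function(tissue, sex, cat) {
    cols <- meta$sample[meta$tissue == tissue & meta$sex == sex]
    rowMeans(expr$counts[genes$category == cat, cols])
  }
  # catkin: MB genes ~4x male excess, leaf: none
  mb_ratio_catkin <- median(log2((mean_by("catkin", "M", "MB") + 1) /
                                 (mean_by("catkin", "F", "MB") + 1)))
  mb_ratio_leaf <- median(log2((mean_by("leaf", "M", "MB") + 1) /
                               (mean_by("leaf", "F", "MB") + 1)))
  expect_gt(mb_ratio_catkin, 1.2)
  expect_lt(abs(mb_ratio_leaf), 0.5)
  # FB genes mirror
  fb_ratio_catkin <- median(log2((mean_by("catkin", "M", "FB") + 1) /
                                 (mean_by("catkin", "F", "FB") + 1)))
  expect_lt(fb_ratio_catkin, -1.2)
})

test_that("site-table simulation is deterministic and respects snp_rate = 0", {
  cfg <- sim_config(seed = 31, n_genes_per_category = 2,
                    gene_length_codons = 60)
  sim <- simulate_ortholog_set(cfg)
  st1 <- simulate_site_table(sim$alignments, sim$truth, cfg)
  st2 <- simulate_site_table(sim$alignments, sim$truth, cfg)
  expect_identical(st1$sites, st2$sites)
  expect_identical(st1$truth$snps, st2$truth$snps)

  cfg0 <- sim_config(seed = 31, n_genes_per_category = 2,
                     gene_length_codons = 60, snp_rate_per_site = 0)
  st0 <- simulate_site_table(sim$alignments, sim$truth, cfg0)
  expect_equal(sum(st0$sites$alt_count), 0)
  expect_equal(nrow(st0$truth$snps), 0)
})

test_that("low simulated coverage fails the downstream coverage rule", {
  cfg <- sim_config(seed = 41, n_genes_per_category = 1,
                    gene_length_codons = 40, coverage_mean = 5)
  sim <- simulate_ortholog_set(cfg)
  st <- simulate_site_table(sim$alignments, sim$truth, cfg)
  matched <- match_codons(sim$alignments[[1]], st$sites, min_cov = 20)
  expect_length(matched, 0)
})

test_that("injected SNP truth is consistent with the genetic code", {
  cfg <- sim_config(seed = 51, n_genes_per_category = 5,
                    gene_length_codons = 200, snp_rate_per_site = 0.05)
  sim <- simulate_ortholog_set(cfg)
  st <- simulate_site_table(sim$alignments, sim$truth, cfg)
  snps <- st$truth$snps
  expect_gt(nrow(snps), 10)
  for (i in seq_len(nrow(snps))) {
    ref <- sim$alignments[[snps$gene[i]]]$codons["S_viminalis",
                                                 snps$codon_index[i]]
    alt <- ref
    substring(alt, snps$position_in_codon[i], snps$position_in_codon[i]) <-
      snps$alt_base[i]
    same_aa <- translate_codons(alt) == translate_codons(ref)
    expect_identical(unname(ifelse(same_aa, "syn", "nonsyn")), snps$type[i])
  }
})
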