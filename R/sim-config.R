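# Simulation configuration with validation.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults are chosen
#' to mirror the magnitudes observed in the willow/poplar system the package
#' targets: a focal (S. viminalis) terminal branch with synonymous divergence
#' around 0.013-0.016, category dN/dS near 0.20-0.22, polymorphism levels
#' giving pN/pS near 0.25, a log2 fold-change injection of 2 for sex-biased
#' genes in the reproductive tissue only, and 3 sequenced individuals per
#' sex.
#'
#' Branch lengths are expected attempted mutations per nucleotide site; under
#' the generator's acceptance rule the expected synonymous divergence d_S on
#' a branch equals its length, and expected d_N equals omega times the
#' length (see the methods vignette).
#'
#' @param seed integer seed; all generator functions derive their RNG state
#'   from it (alignments use `seed`, expression `seed + 1`, site tables
#'   `seed + 2`).
#' @param n_genes_per_category genes simulated per category (UB, MB, FB).
#' @param gene_length_codons codons per gene.
#' @param omega_by_category named numeric, dN/dS on the focal branch per
#'   category; non-focal branches evolve at the UB value.
#' @param branch_lengths named numeric of attempted mutations per site for
#'   the 8 branches of the rooted 5-taxon tree.
#' @param ts_tv_ratio transition/transversion proposal weight; 1 keeps the
#'   counting estimator exactly calibrated.
#' @param sexbias_log2fc log2 male:female fold change injected into MB genes
#'   (and its negative into FB genes) in catkin.
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param n_individuals_per_sex sequenced individuals per sex (>= 2).
#' @param snp_rate_per_site expected synonymous polymorphisms per synonymous
#'   site.
#' @param poly_omega ratio of per-site nonsynonymous to synonymous
#'   polymorphism rates (pN/pS of the generating process).
#' @param coverage_mean mean per-site per-individual read coverage (Poisson).
#' @param codon_bias_profile named numeric, relative weight of each family's
#'   preferred codon in the root sequence, per category; larger = stronger
#'   codon usage bias (lower ENC).
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_category = 100L,
                       gene_length_codons = 300L,
                       omega_by_category = c(UB = 0.22, MB = 0.195, FB = 0.21),
                       branch_lengths = c(
                         S_viminalis = 0.0135, S_suchowensis = 0.0165,
                         salix_stem = 0.06, populus_stem = 0.06,
                         aspen_stem = 0.02, P_tremula = 0.008,
                         P_tremuloides = 0.008, P_trichocarpa = 0.04),
                       ts_tv_ratio = 1,
                       sexbias_log2fc = 2,
                       nb_dispersion = 0.1,
                       n_individuals_per_sex = 3L,
                       snp_rate_per_site = 0.011,
                       poly_omega = 0.25,
                       coverage_mean = 30,
                       codon_bias_profile = c(UB = 2, MB = 1.4, FB = 2)) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes_per_category = as.integer(n_genes_per_category),
    gene_length_codons = as.integer(gene_length_codons),
    omega_by_category = omega_by_category,
    branch_lengths = branch_lengths,
    ts_tv_ratio = ts_tv_ratio,
    sexbias_log2fc = sexbias_log2fc,
    nb_dispersion = nb_dispersion,
    n_individuals_per_sex = as.integer(n_individuals_per_sex),
    snp_rate_per_site = snp_rate_per_site,
    poly_omega = poly_omega,
    coverage_mean = coverage_mean,
    codon_bias_profile = codon_bias_profile
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  req_cats <- c("UB", "MB", "FB")
  if (!all(req_cats %in% names(cfg$omega_by_category)))
    stop("omega_by_category must name UB, MB and FB")
  if (any(!is.finite(cfg$omega_by_category)) || any(cfg$omega_by_category < 0))
    stop("omega values must be finite and >= 0")
  req_br <- c("S_viminalis", "S_suchowensis", "salix_stem", "populus_stem",
              "aspen_stem", "P_tremula", "P_tremuloides", "P_trichocarpa")
  if (!all(req_br %in% names(cfg$branch_lengths)))
    stop("branch_lengths must name all 8 branches of the species tree")
  if (any(!is.finite(cfg$branch_lengths)) || any(cfg$branch_lengths < 0))
    stop("branch lengths must be finite and >= 0")
  # Expected focal-branch d_S equals the focal branch length; beyond 2 the
  # counting approach is saturated and downstream analyses would drop every
  # gene, so such configurations are rejected outright.
  if (cfg$branch_lengths[["S_viminalis"]] > 2)
    stop("expected focal-branch d_S exceeds 2 (saturation); shorten S_viminalis branch")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$n_individuals_per_sex < 2) stop("need >= 2 individuals per sex")
  if (cfg$ts_tv_ratio <= 0) stop("ts_tv_ratio must be > 0")
  if (cfg$snp_rate_per_site < 0 || cfg$poly_omega < 0)
    stop("polymorphism rates must be >= 0")
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (any(!is.finite(cfg$codon_bias_profile)) || any(cfg$codon_bias_profile < 0))
    stop("codon_bias_profile weights must be finite and >= 0")
  if (cfg$gene_length_codons < 1 || cfg$n_genes_per_category < 1)
    stop("gene counts and lengths must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_genes_per_category, "genes/category x",
      x$gene_length_codons, "codons; seed", x$seed, "\n")
  cat("  omega:", paste(names(x$omega_by_category),
                        x$omega_by_category, sep = "=", collapse = " "), "\n")
  cat("  focal branch length:", x$branch_lengths[["S_viminalis"]], "\n")
  invisible(x)
}
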