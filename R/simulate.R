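# Synthetic-data generators: codon alignments with recorded substitution
# ground truth, negative-binomial expression counts with injected sex bias,
# and per-site polymorphism tables.
#
# Mutation model: on a branch of length l, each nucleotide site receives
# Poisson(l) attempted mutations; each attempt proposes one of the non-stop
# single-nucleotide neighbours of the current codon (transition/transversion
# weighted) and is accepted with probability 1 if synonymous and omega if
# nonsynonymous.  With ts/tv weight 1 this makes E[d_S] = l and
# E[d_N] = omega * l under the NG86 site definition, so the downstream
# counting estimator is exactly calibrated against the generator.

# fast neighbour lookup: [[codon]][[pos]] -> list(alt bases, to codons, type, ts)
.nb_by_pos <- local({
  out <- lapply(.codon_neighbours, function(nb) {
    lapply(1:3, function(p) {
      at <- nb[nb$pos == p & nb$type != "stop", , drop = FALSE]
      list(alt = at$alt, to = at$to, syn = at$type == "syn", ts = at$is_ts)
    })
  })
  out
})

# per codon x position: synonymous / nonsynonymous site fractions (s/k and
# (k-s)/k over non-stop neighbours), used by the polymorphism generator
.site_frac <- local({
  syn <- matrix(0, length(.SENSE_CODONS), 3,
                dimnames = list(.SENSE_CODONS, NULL))
  non <- syn
  for (cod in .SENSE_CODONS) {
    for (p in 1:3) {
      nb <- .nb_by_pos[[cod]][[p]]
      k <- length(nb$alt)
      if (k > 0) {
        syn[cod, p] <- sum(nb$syn) / k
        non[cod, p] <- sum(!nb$syn) / k
      }
    }
  }
  list(syn = syn, non = non)
})

# preferred codon per synonymous family: alphabetically first C-ending codon,
# else first G-ending, else first (plant codon bias tends to C/G-ending)
.preferred_codons <- local({
  fam <- split(.SENSE_CODONS, .GENETIC_CODE[.SENSE_CODONS])
  vapply(fam, function(cods) {
    cods <- sort(cods)
    c3 <- substring(cods, 3, 3)
    if (any(c3 == "C")) cods[c3 == "C"][1]
    else if (any(c3 == "G")) cods[c3 == "G"][1]
    else cods[1]
  }, character(1))
})

.root_codon_weights <- function(bias_weight) {
  w <- stats::setNames(rep(1, length(.SENSE_CODONS)), .SENSE_CODONS)
  w[.preferred_codons] <- bias_weight
  w / sum(w)
}

# flat neighbour arrays for vectorised mutation proposals: row index
# (codon - 1) * 3 + pos, up to 3 non-stop alternatives per row
.nb_flat <- local({
  nr <- length(.SENSE_CODONS) * 3L
  to <- matrix(NA_character_, nr, 3)
  syn <- matrix(NA, nr, 3)
  w_ts <- matrix(0, nr, 3)
  k <- integer(nr)
  for (ci in seq_along(.SENSE_CODONS)) {
    for (p in 1:3) {
      nb <- .nb_by_pos[[.SENSE_CODONS[ci]]][[p]]
      r <- (ci - 1L) * 3L + p
      kk <- length(nb$alt)
      k[r] <- kk
      if (kk) {
        to[r, seq_len(kk)] <- nb$to
        syn[r, seq_len(kk)] <- nb$syn
        w_ts[r, seq_len(kk)] <- nb$ts
      }
    }
  }
  list(to = to, syn = syn, w_ts = w_ts, k = k)
})

# evolve a codon vector along one branch; returns new codons + change log.
# Codons hit by a single attempted mutation (the vast majority) are handled
# vectorised; codons hit several times are replayed sequentially.
.evolve_branch <- function(codons, len, omega, kappa) {
  L <- length(codons)
  n_att <- stats::rpois(1, 3 * L * len)
  out_ci <- integer(0); out_cp <- integer(0)
  out_from <- character(0); out_to <- character(0); out_syn <- logical(0)
  if (n_att > 0) {
    sites <- sample.int(3 * L, n_att, replace = TRUE)
    acc_u <- stats::runif(n_att)
    pick_u <- stats::runif(n_att)
    ci <- (sites - 1L) %/% 3L + 1L
    cp <- (sites - 1L) %% 3L + 1L
    hits <- tabulate(ci, nbins = L)
    single <- which(hits[ci] == 1L)

    if (length(single)) {
      sci <- ci[single]; scp <- cp[single]
      row <- (match(codons[sci], .SENSE_CODONS) - 1L) * 3L + scp
      k <- .nb_flat$k[row]
      w1 <- ifelse(k >= 1, ifelse(.nb_flat$w_ts[row, 1] > 0, kappa, 1), 0)
      w2 <- ifelse(k >= 2, ifelse(.nb_flat$w_ts[row, 2] > 0, kappa, 1), 0)
      w3 <- ifelse(k >= 3, ifelse(.nb_flat$w_ts[row, 3] > 0, kappa, 1), 0)
      r <- pick_u[single] * (w1 + w2 + w3)
      j <- 1L + (r > w1) + (r > w1 + w2)
      ok <- k > 0
      idx <- cbind(row, j)
      is_syn <- .nb_flat$syn[idx]
      accept <- ok & (is_syn | acc_u[single] < omega)
      if (any(accept)) {
        out_ci <- sci[accept]; out_cp <- scp[accept]
        out_from <- codons[out_ci]
        out_to <- .nb_flat$to[idx[accept, , drop = FALSE]]
        out_syn <- is_syn[accept]
        codons[out_ci] <- out_to
      }
    }

    multi <- which(hits[ci] > 1L)
    for (i in multi) {
      nb <- .nb_by_pos[[codons[ci[i]]]][[cp[i]]]
      k <- length(nb$alt)
      if (k == 0L) next
      w <- ifelse(nb$ts, kappa, 1)
      j <- 1L + findInterval(pick_u[i] * sum(w), cumsum(w)[-k])
      if (nb$syn[j] || acc_u[i] < omega) {
        out_ci <- c(out_ci, ci[i]); out_cp <- c(out_cp, cp[i])
        out_from <- c(out_from, codons[ci[i]])
        out_to <- c(out_to, nb$to[j]); out_syn <- c(out_syn, nb$syn[j])
        codons[ci[i]] <- nb$to[j]
      }
    }
  }
  changes <- if (length(out_ci)) {
    data.frame(codon = out_ci, pos = out_cp, from_codon = out_from,
               to_codon = out_to,
               type = ifelse(out_syn, "syn", "nonsyn"),
               stringsAsFactors = FALSE)
  } else NULL
  list(codons = codons, changes = changes)
}

#' Simulate a five-taxon ortholog set with known ground truth
#'
#' Evolves codon sequences from a random root down the fixed species tree.
#' The focal `S_viminalis` terminal branch uses the per-category omega from
#' the configuration; all other branches use the UB omega. Every accepted
#' substitution is recorded, so tip sequences can be reproduced exactly by
#' replaying the log.
#'
#' @param config a [sim_config()].
#' @return list with elements `alignments` (named list of
#'   [codon_alignment()]) and `truth` (class `sim_truth`: `genes` data frame
#'   with true categories, `substitutions` log, `root_seqs`).
#' @export
simulate_ortholog_set <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cats <- c("UB", "MB", "FB")
  n <- config$n_genes_per_category
  L <- config$gene_length_codons
  kappa <- config$ts_tv_ratio
  bl <- config$branch_lengths
  om_ub <- config$omega_by_category[["UB"]]

  genes <- data.frame(
    gene = sprintf("g%04d", seq_len(3 * n)),
    category = rep(cats, each = n),
    length_codons = L,
    stringsAsFactors = FALSE
  )

  # branch -> (parent node, omega source); evolution proceeds root -> tips
  paths <- list(
    salix_stem = "root", S_viminalis = "salix_anc", S_suchowensis = "salix_anc",
    populus_stem = "root", P_trichocarpa = "populus_anc",
    aspen_stem = "populus_anc", P_tremula = "aspen_anc",
    P_tremuloides = "aspen_anc"
  )
  child_of <- c(salix_stem = "salix_anc", S_viminalis = "S_viminalis",
                S_suchowensis = "S_suchowensis", populus_stem = "populus_anc",
                P_trichocarpa = "P_trichocarpa", aspen_stem = "aspen_anc",
                P_tremula = "P_tremula", P_tremuloides = "P_tremuloides")
  taxa <- c("S_viminalis", "S_suchowensis", "P_tremula", "P_tremuloides",
            "P_trichocarpa")

  alignments <- vector("list", nrow(genes))
  names(alignments) <- genes$gene
  root_seqs <- vector("list", nrow(genes))
  names(root_seqs) <- genes$gene
  sub_log <- list()

  for (g in seq_len(nrow(genes))) {
    cat_g <- genes$category[g]
    w <- .root_codon_weights(config$codon_bias_profile[[cat_g]])
    root <- sample(.SENSE_CODONS, L, replace = TRUE, prob = w)
    nodes <- list(root = root)
    for (br in names(paths)) {
      omega <- if (br == "S_viminalis") config$omega_by_category[[cat_g]] else om_ub
      ev <- .evolve_branch(nodes[[paths[[br]]]], bl[[br]], omega, kappa)
      nodes[[child_of[[br]]]] <- ev$codons
      if (!is.null(ev$changes)) {
        ev$changes$gene <- genes$gene[g]
        ev$changes$branch <- br
        sub_log[[length(sub_log) + 1L]] <- ev$changes
      }
    }
    mat <- do.call(rbind, nodes[taxa])
    rownames(mat) <- taxa
    alignments[[g]] <- codon_alignment(genes$gene[g], mat, stripped = TRUE)
    root_seqs[[g]] <- root
  }

  subs <- if (length(sub_log)) {
    do.call(rbind, sub_log)[, c("gene", "branch", "codon", "pos",
                                "from_codon", "to_codon", "type")]
  } else {
    data.frame(gene = character(), branch = character(), codon = integer(),
               pos = integer(), from_codon = character(),
               to_codon = character(), type = character())
  }
  truth <- structure(
    list(genes = genes, substitutions = subs, root_seqs = root_seqs,
         config = config),
    class = "sim_truth"
  )
  list(alignments = alignments, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d genes (%s), %d recorded substitutions\n",
              nrow(x$genes),
              paste(names(table(x$genes$category)),
                    table(x$genes$category), sep = "=", collapse = " "),
              nrow(x$substitutions)))
  invisible(x)
}

#' True substitution counts on one branch
#'
#' Tallies the recorded synonymous/nonsynonymous substitutions per gene on a
#' branch of the simulated tree -- the oracle against which the counting
#' estimator is validated.
#'
#' @param truth a `sim_truth`.
#' @param branch branch name (default the focal terminal branch).
#' @return data frame with columns `gene`, `true_DN`, `true_DS`.
#' @export
true_branch_counts <- function(truth, branch = "S_viminalis") {
  sub <- truth$substitutions[truth$substitutions$branch == branch, ]
  out <- data.frame(gene = truth$genes$gene, stringsAsFactors = FALSE)
  tn <- table(factor(sub$gene[sub$type == "nonsyn"], levels = out$gene))
  ts <- table(factor(sub$gene[sub$type == "syn"], levels = out$gene))
  out$true_DN <- as.integer(tn)
  out$true_DS <- as.integer(ts)
  out
}

#' Simulate an expression count table with injected sex bias
#'
#' Generates negative-binomial counts for `n_individuals_per_sex` male and
#' female individuals in two tissues (catkin, leaf). MB genes receive a
#' +`sexbias_log2fc` male:female log2 fold change in catkin (split
#' symmetrically between the sexes), FB genes the negative; leaf carries no
#' injected bias.
#'
#' @param config a [sim_config()].
#' @param genes optional data frame with columns `gene` and `category` (and
#'   optionally `length_codons`), e.g. `truth$genes`; generated from the
#'   config when omitted.
#' @return an `expression_table`: list with `counts` (gene x sample integer
#'   matrix), `gene_length_bp`, and `sample_meta` (sample, individual, sex,
#'   tissue).
#' @export
simulate_expression <- function(config, genes = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  if (is.null(genes)) {
    n <- config$n_genes_per_category
    genes <- data.frame(
      gene = sprintf("g%04d", seq_len(3 * n)),
      category = rep(c("UB", "MB", "FB"), each = n),
      length_codons = config$gene_length_codons,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(genes$length_codons)) genes$length_codons <- config$gene_length_codons
  ng <- nrow(genes)
  ni <- config$n_individuals_per_sex
  ind <- c(paste0("M", seq_len(ni)), paste0("F", seq_len(ni)))
  sex <- rep(c("M", "F"), each = ni)
  meta <- data.frame(
    sample = c(paste0(ind, "_catkin"), paste0(ind, "_leaf")),
    individual = rep(ind, 2),
    sex = rep(sex, 2),
    tissue = rep(c("catkin", "leaf"), each = 2 * ni),
    stringsAsFactors = FALSE
  )
  base_mu <- stats::rlnorm(ng, meanlog = log(150), sdlog = 1)
  fc <- config$sexbias_log2fc
  # symmetric split of the injected fold change between the sexes
  mult_m <- ifelse(genes$category == "MB", 2^(fc / 2),
                   ifelse(genes$category == "FB", 2^(-fc / 2), 1))
  mult_f <- 1 / mult_m
  counts <- matrix(0L, ng, nrow(meta),
                   dimnames = list(genes$gene, meta$sample))
  size <- 1 / config$nb_dispersion
  for (s in seq_len(nrow(meta))) {
    mult <- if (meta$tissue[s] == "catkin") {
      if (meta$sex[s] == "M") mult_m else mult_f
    } else rep(1, ng)
    counts[, s] <- stats::rnbinom(ng, mu = base_mu * mult, size = size)
  }
  structure(
    list(counts = counts,
         gene_length_bp = stats::setNames(3 * genes$length_codons, genes$gene),
         sample_meta = meta),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$sample_meta$tissue), collapse = "/")))
  invisible(x)
}

#' Simulate a per-site coverage and allele-count table
#'
#' For every nucleotide site of the focal (`S_viminalis`) sequence of each
#' alignment, draws per-individual Poisson coverage and injects segregating
#' variants: a site carries a synonymous SNP with probability
#' `snp_rate_per_site` times its synonymous site fraction, and a
#' nonsynonymous SNP with probability `snp_rate_per_site * poly_omega` times
#' its nonsynonymous fraction. The derived-allele count among the 2n
#' haplotypes is uniform on 1..n (so both MAF-passing and MAF-failing sites
#' occur); read counts are binomial in the individual's allele dosage.
#'
#' @param alignments list of [codon_alignment()] (focal taxon row required).
#' @param truth a `sim_truth`; the injected SNPs are appended as the
#'   `snps` element of the returned truth.
#' @param config a [sim_config()].
#' @return list with `sites` (the long site table data frame) and `truth`
#'   (input truth with a `snps` data frame added).
#' @export
simulate_site_table <- function(alignments, truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  ni <- config$n_individuals_per_sex
  ind <- c(paste0("M", seq_len(ni)), paste0("F", seq_len(ni)))
  sex <- rep(c("M", "F"), each = ni)
  n_ind <- 2L * ni
  n_hap <- 2L * n_ind
  rate <- config$snp_rate_per_site
  pomega <- config$poly_omega

  acc <- list()
  snp_acc <- list()
  for (aln in alignments) {
    codons <- aln$codons["S_viminalis", ]
    L <- length(codons)
    nsite <- 3L * L
    codon_index <- rep(seq_len(L), each = 3L)
    pos_in_codon <- rep(1:3, L)
    ref_base <- unlist(strsplit(codons, ""), use.names = FALSE)

    ci_all <- match(rep(codons, each = 3), .SENSE_CODONS)
    p_syn <- rate * .site_frac$syn[cbind(ci_all, pos_in_codon)]
    p_non <- rate * pomega * .site_frac$non[cbind(ci_all, pos_in_codon)]
    u <- stats::runif(nsite)
    is_syn_snp <- u < p_syn
    is_non_snp <- !is_syn_snp & u < p_syn + p_non
    snp_sites <- which(is_syn_snp | is_non_snp)

    alt_base <- rep(NA_character_, nsite)
    dosage <- matrix(0L, nsite, n_ind)
    if (length(snp_sites)) {
      for (s in snp_sites) {
        nb <- .nb_by_pos[[codons[codon_index[s]]]][[pos_in_codon[s]]]
        altset <- nb$alt[if (is_syn_snp[s]) nb$syn else !nb$syn]
        if (!length(altset)) { is_syn_snp[s] <- is_non_snp[s] <- FALSE; next }
        alt_base[s] <- altset[sample.int(length(altset), 1)]
        k <- sample.int(n_ind, 1)             # derived copies among haplotypes
        haps <- sample.int(n_hap, k)
        dosage[s, ] <- tabulate((haps - 1L) %/% 2L + 1L, nbins = n_ind)
      }
      snp_sites <- which(is_syn_snp | is_non_snp)
    }
    cov <- matrix(stats::rpois(nsite * n_ind, config$coverage_mean),
                  nsite, n_ind)
    alt_ct <- matrix(0L, nsite, n_ind)
    if (length(snp_sites)) {
      for (j in seq_len(n_ind)) {
        sel <- snp_sites[dosage[snp_sites, j] > 0]
        if (length(sel))
          alt_ct[sel, j] <- stats::rbinom(length(sel), cov[sel, j],
                                          dosage[sel, j] / 2)
      }
    }
    acc[[aln$id]] <- data.frame(
      gene = aln$id,
      codon_index = rep(codon_index, n_ind),
      position_in_codon = rep(pos_in_codon, n_ind),
      individual = rep(ind, each = nsite),
      sex = rep(sex, each = nsite),
      coverage = as.vector(cov),
      ref_count = as.vector(cov - alt_ct),
      alt_count = as.vector(alt_ct),
      alt_base = rep(alt_base, n_ind),
      stringsAsFactors = FALSE
    )
    if (length(snp_sites)) {
      snp_acc[[aln$id]] <- data.frame(
        gene = aln$id,
        codon_index = codon_index[snp_sites],
        position_in_codon = pos_in_codon[snp_sites],
        ref_base = ref_base[snp_sites],
        alt_base = alt_base[snp_sites],
        type = ifelse(is_syn_snp[snp_sites], "syn", "nonsyn"),
        true_maf = pmin(rowSums(dosage[snp_sites, , drop = FALSE]) / n_hap,
                        1 - rowSums(dosage[snp_sites, , drop = FALSE]) / n_hap),
        stringsAsFactors = FALSE
      )
    }
  }
  sites <- do.call(rbind, acc)
  rownames(sites) <- NULL
  snps <- if (length(snp_acc)) do.call(rbind, snp_acc) else
    data.frame(gene = character(), codon_index = integer(),
               position_in_codon = integer(), ref_base = character(),
               alt_base = character(), type = character(),
               true_maf = numeric())
  rownames(snps) <- NULL
  truth$snps <- snps
  list(sites = sites, truth = truth)
}
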