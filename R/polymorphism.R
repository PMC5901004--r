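# Polymorphism analysis: SNP validity filtering from per-site coverage and
# allele-count tables, synonymous/nonsynonymous classification against the
# reading frame, and the codon-matching filter that puts divergence and
# polymorphism on an identical site basis for the McDonald-Kreitman test.

# per-gene, per-site coverage-rule pass: coverage >= min_cov in at least
# ceil(n/2) individuals of at least one sex
.site_coverage_pass <- function(sites, min_cov) {
  key <- paste(sites$gene, sites$codon_index, sites$position_in_codon)
  ukeys <- unique(key)
  pass <- stats::setNames(rep(FALSE, length(ukeys)), ukeys)
  for (sx in c("M", "F")) {
    sel <- sites$sex == sx
    if (!any(sel)) next
    n_ind <- tapply(sites$individual[sel], key[sel],
                    function(x) length(unique(x)))
    n_cov <- tapply(sites$coverage[sel] >= min_cov, key[sel], sum)
    ok <- n_cov >= ceiling(n_ind / 2)
    pass[names(ok)] <- pass[names(ok)] | ok
  }
  data.frame(key = names(pass), pass = unname(pass),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter candidate SNPs by coverage, allele frequency and read support
#'
#' A site is a valid SNP iff (a) its coverage is at least `min_cov` in at
#' least half (ceiling) of the individuals of one sex, (b) the minor allele
#' frequency, computed from read counts pooled across the individuals
#' passing the coverage rule, is at least `min_maf`, and (c) the alternate
#' allele is supported by at least `min_reads` pooled reads.
#'
#' @param sites site table data frame (columns `gene`, `codon_index`,
#'   `position_in_codon`, `individual`, `sex`, `coverage`, `ref_count`,
#'   `alt_count`, `alt_base`).
#' @param min_cov minimum per-individual coverage (default 20).
#' @param min_maf minimum pooled minor allele frequency (default 0.20).
#' @param min_reads minimum pooled alternate-supporting reads (default 3).
#' @return data frame of valid SNPs, one row per site: `gene`,
#'   `codon_index`, `position_in_codon`, `alt_base`, `maf`, `alt_reads`.
#' @export
filter_snps <- function(sites, min_cov = 20, min_maf = 0.20, min_reads = 3) {
  stopifnot(all(sites$coverage >= sites$ref_count + sites$alt_count))
  cand <- sites[!is.na(sites$alt_base), , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(gene = character(), codon_index = integer(),
                      position_in_codon = integer(), alt_base = character(),
                      maf = numeric(), alt_reads = numeric()))
  cov_pass <- .site_coverage_pass(sites, min_cov)
  key <- paste(cand$gene, cand$codon_index, cand$position_in_codon)
  cand <- cand[key %in% cov_pass$key[cov_pass$pass], , drop = FALSE]
  key <- paste(cand$gene, cand$codon_index, cand$position_in_codon)

  # pool read counts across the individuals that pass the coverage rule
  ind_ok <- cand$coverage >= min_cov
  alt <- tapply(cand$alt_count[ind_ok], key[ind_ok], sum)
  ref <- tapply(cand$ref_count[ind_ok], key[ind_ok], sum)
  maf <- pmin(alt, ref) / (alt + ref)
  keep <- !is.na(maf) & maf >= min_maf & alt >= min_reads

  info <- cand[!duplicated(key), c("gene", "codon_index",
                                   "position_in_codon", "alt_base")]
  rownames(info) <- key[!duplicated(key)]
  out <- info[names(keep)[keep], , drop = FALSE]
  out$maf <- as.numeric(maf[keep])
  out$alt_reads <- as.numeric(alt[keep])
  rownames(out) <- NULL
  out[order(out$gene, out$codon_index, out$position_in_codon), , drop = FALSE]
}

#' Classify SNPs as synonymous or nonsynonymous
#'
#' Substitutes the alternate base into the reference codon at the SNP
#' position and compares amino acids. Alternate alleles creating a stop
#' codon are nonsynonymous and flagged. Each variant is classified against
#' the reference codon; codons carrying several variants are flagged
#' (`multi_variant`).
#'
#' @param snps data frame from [filter_snps()].
#' @param ref_codons named list of reference codon vectors per gene
#'   (e.g. the focal-taxon row of each alignment).
#' @return `snps` with `ref_codon`, `alt_codon`, `type` (`"syn"`/`"nonsyn"`),
#'   `creates_stop` and `multi_variant` columns added.
#' @export
classify_polymorphism <- function(snps, ref_codons) {
  if (!nrow(snps)) {
    snps$ref_codon <- snps$alt_codon <- snps$type <- character(0)
    snps$creates_stop <- snps$multi_variant <- logical(0)
    return(snps)
  }
  ref <- mapply(function(g, ci) ref_codons[[g]][ci],
                snps$gene, snps$codon_index)
  alt <- ref
  substring(alt, snps$position_in_codon, snps$position_in_codon) <- snps$alt_base
  aa_ref <- translate_codons(ref)
  aa_alt <- translate_codons(alt)
  if (any(is.na(aa_ref)))
    stop("SNP in a codon with ambiguity characters; filter first")
  snps$ref_codon <- unname(ref)
  snps$alt_codon <- unname(alt)
  snps$creates_stop <- aa_alt == "*"
  snps$type <- ifelse(aa_alt == aa_ref, "syn", "nonsyn")
  ckey <- paste(snps$gene, snps$codon_index)
  snps$multi_variant <- ckey %in% ckey[duplicated(ckey)]
  snps
}

#' Codons comparable between divergence and polymorphism analyses
#'
#' A codon is matched iff all three of its sites pass the coverage rule,
#' the codon survived gap stripping, and it is unmasked and ambiguity-free
#' in every taxon of the alignment. All downstream statistics (N, S, DN,
#' DS, PN, PS) are recomputed over matched codons only, so divergence and
#' polymorphism share an identical site basis.
#'
#' @param aln a masked, gap-stripped [codon_alignment()].
#' @param sites site table restricted to (or containing) this gene.
#' @param min_cov minimum coverage (as in [filter_snps()]).
#' @return integer vector of matched codon indices (possibly empty).
#' @export
match_codons <- function(aln, sites, min_cov = 20) {
  if (is.null(sites)) return(integer(0))
  st <- sites[sites$gene == aln$id, , drop = FALSE]
  if (!nrow(st)) return(integer(0))
  cov_pass <- .site_coverage_pass(st, min_cov)
  pass_key <- cov_pass$key[cov_pass$pass]
  keys <- do.call(rbind, strsplit(pass_key, " "))
  cod <- as.integer(keys[, 2])
  npass <- tabulate(cod, nbins = n_codons(aln))
  covered <- which(npass == 3L)
  intersect(covered, clean_columns(aln))
}

#' Per-gene polymorphism counts over matched codons
#'
#' Runs [filter_snps()] and [classify_polymorphism()], restricts SNPs to the
#' matched codon set of each gene, and tallies PN and PS. Codons carrying
#' several segregating sites contribute each variant independently.
#'
#' @param alignments named list of [codon_alignment()].
#' @param sites full site table.
#' @param matched named list of matched codon indices per gene (from
#'   [match_codons()]).
#' @param min_cov,min_maf,min_reads SNP validity thresholds.
#' @param focal focal taxon (reference for the reading frame).
#' @return data frame: `gene`, `PN`, `PS`.
#' @export
polymorphism_table <- function(alignments, sites, matched,
                               min_cov = 20, min_maf = 0.20, min_reads = 3,
                               focal = "S_viminalis") {
  snps <- filter_snps(sites, min_cov, min_maf, min_reads)
  ref_codons <- lapply(alignments, function(a) a$codons[focal, ])
  snps <- snps[snps$gene %in% names(alignments), , drop = FALSE]
  snps <- classify_polymorphism(snps, ref_codons)
  keep <- mapply(function(g, ci) ci %in% matched[[g]],
                 snps$gene, snps$codon_index)
  snps <- snps[as.logical(keep), , drop = FALSE]
  genes <- names(alignments)
  pn <- table(factor(snps$gene[snps$type == "nonsyn"], levels = genes))
  ps <- table(factor(snps$gene[snps$type == "syn"], levels = genes))
  data.frame(gene = genes, PN = as.integer(pn), PS = as.integer(ps),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the matched divergence + polymorphism gene table
#'
#' The central per-gene table for selection analyses: matched codons are
#' determined per gene, divergence (N, S, DN, DS) is recomputed over them,
#' polymorphism counts (PN, PS) are tallied over them, and genes with no
#' matched codons are excluded (logged). Per-gene ratios use the shared
#' N and S.
#'
#' @param alignments named list of prepared [codon_alignment()].
#' @param sites site table.
#' @param tree,focal passed to [divergence_table()].
#' @param min_cov,min_maf,min_reads SNP validity thresholds.
#' @return data frame: `gene`, `n_matched_codons`, `N`, `S`, `DN`, `DS`,
#'   `PN`, `PS`, `dN`, `dS`, `pN`, `pS`.
#' @export
mk_input_table <- function(alignments, sites, tree = species_tree(),
                           focal = "S_viminalis",
                           min_cov = 20, min_maf = 0.20, min_reads = 3) {
  sites_by_gene <- split(sites, sites$gene)
  matched <- lapply(alignments, function(a)
    match_codons(a, sites_by_gene[[a$id]], min_cov = min_cov))
  names(matched) <- names(alignments)
  empty <- vapply(matched, length, integer(1)) == 0
  if (any(empty))
    message("mk_input_table: no matched codons, excluding: ",
            paste(names(matched)[empty], collapse = ", "))
  alignments <- alignments[!empty]
  matched <- matched[!empty]
  div <- divergence_table(alignments, tree, focal, codons = matched)
  pol <- polymorphism_table(alignments, sites, matched,
                            min_cov, min_maf, min_reads, focal)
  out <- merge(div, pol, by = "gene", sort = FALSE)
  out$n_matched_codons <- vapply(matched[out$gene], length, integer(1))
  out$pN <- ifelse(out$N > 0, out$PN / out$N, NA_real_)
  out$pS <- ifelse(out$S > 0, out$PS / out$S, NA_real_)
  out
}
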