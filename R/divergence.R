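# Branch-specific divergence estimation: parsimony reconstruction of the
# focal ancestor from the sister species and the outgroup triple, then
# NG86-style pathway counting of the focal-branch substitutions, with site
# totals taken on the reconstructed ancestor.

# Fitch reconstruction of the codon at the Salix ancestor node, vectorised
# over codon columns and performed per nucleotide position.  The node joins
# three subtrees: the focal tip, the sister tip and the outgroup clade
# ((a, b), c); per position, a state present in at least two of the three
# child Fitch sets wins.  Reconstructing per nucleotide rather than per
# codon matters: a focal-branch change and an outgroup-path change in the
# same codon almost always hit different positions, and position-wise
# parsimony then recovers the ancestor exactly where codon-level 0/1
# parsimony is hopelessly tied.  The focal tip must participate: without
# it, a change on the long stem path and one on the short sister branch
# produce identical site patterns and every tie-break misattributes one
# class of deep substitutions to the focal branch.
.BASE_BIT <- c(T = 1L, C = 2L, A = 4L, G = 8L)
.BIT_BASE <- c(`1` = "T", `2` = "C", `4` = "A", `8` = "G")

# Ancestor reconstruction with tied positions retained as candidate pairs.
# A tied position always has exactly the focal and the sister base as its
# most-parsimonious candidates (an outgroup-only base would require changes
# on both short terminal branches).  Columns with a single tied position
# return the two candidate codons, averaged downstream with equal weight
# (the equal-weight average over most-parsimonious assignments); columns
# with 2+ tied positions, or whose candidates are stop codons, are skipped.
# Returns list(a, b): both NA = column skipped; a == b = fully resolved.
.fitch_ancestor_pairs <- function(foc, sis, a, b, c3) {
  n <- length(foc)
  pos_a <- matrix(NA_character_, n, 3)
  pos_b <- matrix(NA_character_, n, 3)
  tied <- matrix(FALSE, n, 3)
  for (p in 1:3) {
    fch <- substring(foc, p, p); sch <- substring(sis, p, p)
    fb <- .BASE_BIT[fch]; sb <- .BASE_BIT[sch]
    ab <- .BASE_BIT[substring(a, p, p)]
    bb <- .BASE_BIT[substring(b, p, p)]
    cb <- .BASE_BIT[substring(c3, p, p)]
    Tset <- ifelse(ab == bb, ab, bitwOr(ab, bb))
    inter <- bitwAnd(cb, Tset)
    Pset <- ifelse(inter > 0L, inter, bitwOr(cb, Tset))
    res <- rep(NA_character_, n)
    hits <- integer(n)
    for (bit in c(1L, 2L, 4L, 8L)) {
      cnt <- (bitwAnd(fb, bit) > 0L) + (bitwAnd(sb, bit) > 0L) +
             (bitwAnd(Pset, bit) > 0L)
      sel <- cnt >= 2L
      res[sel & hits == 0L] <- .BIT_BASE[[as.character(bit)]]
      hits <- hits + as.integer(sel)
    }
    ok <- hits == 1L
    pos_a[ok, p] <- res[ok]
    pos_b[ok, p] <- res[ok]
    pos_a[!ok, p] <- fch[!ok]
    pos_b[!ok, p] <- sch[!ok]
    tied[, p] <- !ok
  }
  n_tied <- rowSums(tied)
  anc_a <- paste0(pos_a[, 1], pos_a[, 2], pos_a[, 3])
  anc_b <- paste0(pos_b[, 1], pos_b[, 2], pos_b[, 3])
  drop <- n_tied >= 2L
  # tied candidates that are stops: fall back to the sense one, else drop
  a_stop <- anc_a %in% .STOP_CODONS
  b_stop <- anc_b %in% .STOP_CODONS
  anc_a[a_stop & !b_stop] <- anc_b[a_stop & !b_stop]
  anc_b[b_stop & !a_stop] <- anc_a[b_stop & !a_stop]
  drop <- drop | (a_stop & b_stop)
  anc_a[drop] <- NA_character_
  anc_b[drop] <- NA_character_
  list(a = anc_a, b = anc_b)
}

#' Focal-branch substitution counts for one alignment
#'
#' Reconstructs the ancestral codon of the focal lineage at each column by
#' position-wise Fitch parsimony over the five taxa. Columns whose
#' most-parsimonious ancestor is tied at one position contribute both
#' candidate codons with weight 1/2 (the equal-weight average over
#' most-parsimonious assignments); columns tied at two or more positions
#' are skipped and logged. Focal-tip vs ancestor codon differences are then
#' classified with NG86 pathway averaging.
#' Site totals N and S are counted on the reconstructed ancestor sequence.
#' Columns containing a gap, an ambiguity character or a masked codon in any
#' taxon are excluded from both substitutions and sites.
#'
#' @param aln a [codon_alignment()] (gap-stripped).
#' @param tree species tree (`phylo` or Newick string); defaults to
#'   [species_tree()].
#' @param focal focal taxon name.
#' @param codons optional integer vector restricting counting to these codon
#'   columns (used for divergence/polymorphism codon matching).
#' @return one-row data frame: `gene`, `N`, `S`, `DN`, `DS`, `dN`, `dS`,
#'   `n_codons` (columns counted), `n_unresolved` (tied columns skipped).
#' @export
focal_branch_substitutions <- function(aln, tree = species_tree(),
                                       focal = "S_viminalis",
                                       codons = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  roles <- tree_roles(tree, focal)
  need <- c(roles$focal, roles$sister, roles$out_pair, roles$out_far)
  if (!all(need %in% rownames(aln$codons)))
    stop(sprintf("alignment %s lacks taxa: %s", aln$id,
                 paste(setdiff(need, rownames(aln$codons)), collapse = ", ")))

  usable <- clean_columns(aln)
  if (!is.null(codons)) usable <- intersect(usable, codons)
  res <- data.frame(gene = aln$id, N = 0, S = 0, DN = 0, DS = 0,
                    dN = NA_real_, dS = NA_real_,
                    n_codons = 0L, n_unresolved = 0L,
                    stringsAsFactors = FALSE)
  if (!length(usable)) return(res)

  tipcod <- aln$codons[, usable, drop = FALSE]
  if (any(is_stop_codon(as.vector(tipcod))))
    stop(sprintf("gene %s: in-frame stop codon in alignment", aln$id))
  anc <- .fitch_ancestor_pairs(tipcod[roles$focal, ],
                               tipcod[roles$sister, ],
                               tipcod[roles$out_pair[1], ],
                               tipcod[roles$out_pair[2], ],
                               tipcod[roles$out_far, ])
  ok <- !is.na(anc$a)
  res$n_unresolved <- sum(!ok)
  if (!any(ok)) return(res)

  # columns with a tied position contribute each candidate ancestor with
  # weight 1/2, both to the site totals and to the substitution counts
  tip <- tipcod[roles$focal, ok]
  anc_a <- anc$a[ok]; anc_b <- anc$b[ok]
  split <- anc_a != anc_b
  anc_all <- c(anc_a[!split], anc_a[split], anc_b[split])
  tip_all <- c(tip[!split], tip[split], tip[split])
  w_all <- c(rep(1, sum(!split)), rep(0.5, 2 * sum(split)))
  if (any(is_stop_codon(anc_all)))
    stop(sprintf("gene %s: stop codon in reconstructed ancestor", aln$id))
  S <- sum(w_all * .codon_sites$S[anc_all])
  pc <- codon_path_counts(anc_all, tip_all)
  res$N <- 3 * sum(ok) - S; res$S <- S
  res$DN <- sum(w_all * pc$nonsyn); res$DS <- sum(w_all * pc$syn)
  res$n_codons <- sum(ok)
  res$dN <- if (res$N > 0) res$DN / res$N else NA_real_
  res$dS <- if (res$S > 0) res$DS / res$S else NA_real_
  res
}

#' Per-gene divergence table for a set of alignments
#'
#' Applies [focal_branch_substitutions()] to every alignment and row-binds
#' the results.
#'
#' @inheritParams focal_branch_substitutions
#' @param alignments list of [codon_alignment()].
#' @param codons optional named list of matched codon indices per gene.
#' @return data frame, one row per gene.
#' @export
divergence_table <- function(alignments, tree = species_tree(),
                             focal = "S_viminalis", codons = NULL) {
  rows <- lapply(alignments, function(aln)
    focal_branch_substitutions(aln, tree, focal,
                               codons = codons[[aln$id]]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synonymous saturation check
#'
#' Flags genes whose synonymous divergence exceeds the saturation threshold;
#' such genes are excluded from downstream analyses.
#'
#' @param counts data frame with a `dS` column (e.g. [divergence_table()]).
#' @param max_ds saturation threshold (default 2; `dS > 2` fails, `dS == 2`
#'   passes).
#' @return logical vector, `TRUE` = pass.
#' @export
saturation_check <- function(counts, max_ds = 2) {
  pass <- is.na(counts$dS) | counts$dS <= max_ds
  if (any(!pass))
    message(sprintf("saturation_check: %d gene(s) with dS > %g excluded: %s",
                    sum(!pass), max_ds,
                    paste(counts$gene[!pass], collapse = ", ")))
  pass
}

#' Concatenated per-category omega
#'
#' Estimates omega for each gene category from the concatenation of its
#' genes: (sum DN / sum N) / (sum DS / sum S). With a counting estimator
#' this is algebraically identical to the sum-aggregated mean dN/dS, and is
#' emitted as a cross-check column.
#'
#' @param counts per-gene divergence data frame (`N`, `S`, `DN`, `DS`).
#' @param categories factor/character of gene categories aligned with
#'   `counts` rows.
#' @return data frame `category`, `n_genes`, `omega` (`NA` with a message
#'   when sum DS is zero).
#' @export
concatenated_category_estimate <- function(counts, categories) {
  stopifnot(length(categories) == nrow(counts))
  out <- lapply(split(seq_len(nrow(counts)), categories), function(idx) {
    dn <- sum(counts$DN[idx]); ds <- sum(counts$DS[idx])
    n <- sum(counts$N[idx]); s <- sum(counts$S[idx])
    omega <- if (ds > 0 && n > 0) (dn / n) / (ds / s) else NA_real_
    data.frame(n_genes = length(idx), omega = omega)
  })
  res <- do.call(rbind, out)
  res <- cbind(category = rownames(res), res)
  rownames(res) <- NULL
  if (any(is.na(res$omega)))
    message("concatenated_category_estimate: omega undefined (sum DS = 0) for: ",
            paste(res$category[is.na(res$omega)], collapse = ", "))
  res
}
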