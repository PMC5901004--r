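# Alignment cleaning: column-wise gap stripping, two-pass sliding-window
# masking of nonsynonymous-dense regions (sequencing and alignment error
# control), and the minimum-length filter.

#' Remove gap-containing codon columns
#'
#' Drops every codon column in which any taxon carries a gap character, so
#' the reading frame is preserved.
#'
#' @param aln a [codon_alignment()].
#' @return the gap-stripped alignment (`stripped` flag set). An alignment
#'   whose columns are all gapped is returned with zero codons.
#' @export
strip_gaps <- function(aln) {
  has_gap <- apply(matrix(grepl("-", aln$codons, fixed = TRUE),
                          nrow(aln$codons)), 2, any)
  keep <- which(!has_gap)
  out <- codon_alignment(aln$id,
                         aln$codons[, keep, drop = FALSE],
                         mask = aln$mask[, keep, drop = FALSE],
                         stripped = TRUE)
  if (!length(keep))
    message(sprintf("strip_gaps: alignment %s empty after gap removal", aln$id))
  out
}

# Per-taxon indicator of an amino-acid mismatch against the column majority
# of the OTHER taxa.  NA marks codons that cannot be judged (ambiguity or
# mask anywhere needed, or a majority tie -- conservative, not counted).
.mismatch_matrix <- function(aln) {
  codons <- aln$codons
  codons[aln$mask] <- NA_character_
  codons[!matrix(grepl("^[TCAG]{3}$", codons), nrow(codons))] <- NA_character_
  aas <- matrix(translate_codons(codons), nrow(codons),
                dimnames = dimnames(codons))
  nt <- nrow(aas)
  out <- matrix(NA, nt, ncol(aas), dimnames = dimnames(aas))
  for (j in seq_len(ncol(aas))) {
    col <- aas[, j]
    tab <- table(col, useNA = "no")
    for (t in seq_len(nt)) {
      if (is.na(col[t])) next
      tab_t <- tab
      tab_t[col[t]] <- tab_t[col[t]] - 1L  # majority over the OTHER taxa
      tab_t <- tab_t[tab_t > 0L]
      if (!length(tab_t)) next
      top <- names(tab_t)[tab_t == max(tab_t)]
      # majority tie -> not counted as a mismatch (conservative)
      out[t, j] <- if (length(top) == 1L) col[t] != top else FALSE
    }
  }
  out
}

# one masking pass: windows of `window` codons sliding by 1; a window with
# more than `max_nonsyn` countable mismatches is masked wholesale for that
# taxon (strict inequality; overlapping masked windows union)
.mask_pass <- function(aln, window, max_nonsyn) {
  mm <- .mismatch_matrix(aln)
  L <- ncol(mm)
  w <- min(window, L)
  if (w < 1L) return(aln)
  mask <- aln$mask
  cnt <- matrix(0L, nrow(mm), ncol(mm))
  cnt[!is.na(mm) & mm] <- 1L
  for (t in seq_len(nrow(mm))) {
    run <- cumsum(cnt[t, ])
    for (start in seq_len(L - w + 1L)) {
      n_mm <- run[start + w - 1L] - if (start > 1L) run[start - 1L] else 0L
      if (n_mm > max_nonsyn) mask[t, start:(start + w - 1L)] <- TRUE
    }
  }
  codon_alignment(aln$id, aln$codons, mask = mask, stripped = aln$stripped)
}

#' Two-pass sliding-window masking of nonsynonymous-dense regions
#'
#' For each taxon, slides a window along the alignment and counts codons
#' whose amino acid differs from the majority amino acid of the other taxa
#' at that column; windows with more than `max_nonsyn` mismatches are masked
#' wholesale for that taxon (strict inequality). The first pass (default 15
#' codons, >7 mismatches) targets alignment error from exon-structure
#' variation; the second pass (default 4 codons, >2) targets short error
#' stretches. The second pass runs on the output of the first, with
#' already-masked codons excluded from the counts. Masking is idempotent.
#'
#' Codons containing ambiguity characters, and majority ties, are never
#' counted as mismatches. A window longer than the alignment is clipped to
#' the alignment length.
#'
#' @param aln a gap-stripped [codon_alignment()].
#' @param window1,max_nonsyn1 first-pass window size and mismatch threshold.
#' @param window2,max_nonsyn2 second-pass window size and mismatch threshold.
#' @return the alignment with its mask extended.
#' @export
mask_two_pass <- function(aln, window1 = 15, max_nonsyn1 = 7,
                          window2 = 4, max_nonsyn2 = 2) {
  if (!aln$stripped)
    stop("mask_two_pass() expects a gap-stripped alignment; run strip_gaps()")
  out <- .mask_pass(aln, window1, max_nonsyn1)
  .mask_pass(out, window2, max_nonsyn2)
}

#' Minimum alignment length filter
#'
#' A gene passes if its unmasked, ungapped, ambiguity-free alignment length
#' is at least `min_bp` (inclusive: exactly `min_bp` passes). Failing genes
#' are excluded from all downstream analyses.
#'
#' @param aln a masked, gap-stripped [codon_alignment()].
#' @param min_bp minimum retained length in base pairs (default 300).
#' @return logical scalar.
#' @export
length_filter <- function(aln, min_bp = 300) {
  3L * length(clean_columns(aln)) >= min_bp
}

#' Clean, mask and filter a set of alignments
#'
#' Convenience wrapper: gap-strips, applies [mask_two_pass()] and drops
#' genes failing [length_filter()].
#'
#' @param alignments list of [codon_alignment()].
#' @param min_bp minimum retained length in bp.
#' @param ... passed to [mask_two_pass()].
#' @return named list of processed alignments that pass the length filter.
#' @export
prepare_alignments <- function(alignments, min_bp = 300, ...) {
  out <- lapply(alignments, function(a) mask_two_pass(strip_gaps(a), ...))
  keep <- vapply(out, length_filter, logical(1), min_bp = min_bp)
  if (any(!keep))
    message(sprintf("prepare_alignments: %d gene(s) below %d bp removed",
                    sum(!keep), min_bp))
  out[keep]
}
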