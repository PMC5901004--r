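# Codon alignment container and FASTA input/output.

#' Construct a codon alignment
#'
#' A `codon_alignment` holds the aligned coding sequences of one ortholog
#' group as a taxa x codons character matrix, together with a per-taxon,
#' per-codon mask (masked codons are written as `NNN` on output and are
#' excluded from all counting).
#'
#' @param id ortholog/gene identifier.
#' @param seqs named character vector of aligned nucleotide sequences (equal
#'   length, divisible by 3), or a taxa x codons character matrix of codons.
#' @param mask optional logical matrix (same dimensions as the codon matrix);
#'   `TRUE` marks masked codons.
#' @param stripped logical; `TRUE` once gap columns have been removed.
#' @return an object of class `codon_alignment`.
#' @export
codon_alignment <- function(id, seqs, mask = NULL, stripped = FALSE) {
  if (is.matrix(seqs)) {
    codons <- seqs
  } else {
    lens <- unique(nchar(seqs))
    if (length(lens) != 1)
      stop(sprintf("alignment %s: sequences differ in length", id))
    if (lens %% 3 != 0)
      stop(sprintf("alignment %s: length %d not divisible by 3", id, lens))
    codons <- t(vapply(
      seqs,
      function(s) substring(s, seq(1, lens, 3), seq(3, lens, 3)),
      character(lens / 3)
    ))
    if (lens == 3) codons <- matrix(codons, ncol = 1,
                                    dimnames = list(names(seqs), NULL))
    rownames(codons) <- names(seqs)
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(codons), ncol(codons),
                   dimnames = dimnames(codons))
  }
  stopifnot(identical(dim(mask), dim(codons)))
  structure(
    list(id = id, codons = toupper(codons), mask = mask, stripped = stripped),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment '%s': %d taxa x %d codons (%s, %d codons masked)\n",
              x$id, nrow(x$codons), ncol(x$codons),
              if (x$stripped) "gap-stripped" else "not gap-stripped",
              sum(x$mask)))
  invisible(x)
}

#' Number of codons in an alignment
#' @param aln a `codon_alignment`.
#' @return integer codon count.
#' @export
n_codons <- function(aln) ncol(aln$codons)

# Columns usable for counting: no gap, no ambiguity, no mask in any taxon.
#' @keywords internal
clean_columns <- function(aln) {
  ok_codon <- matrix(grepl("^[TCAG]{3}$", aln$codons),
                     nrow(aln$codons), ncol(aln$codons))
  which(apply(ok_codon & !aln$mask, 2, all))
}

#' Read codon alignments from FASTA files
#'
#' @param files character vector of FASTA paths, one ortholog per file; the
#'   file base name (without extension) is used as the ortholog id.
#' @return named list of `codon_alignment` objects.
#' @export
read_codon_alignments <- function(files) {
  out <- lapply(files, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    id <- sub("\\.[^.]*$", "", basename(f))
    codon_alignment(id, stats::setNames(as.character(ss), names(ss)))
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write codon alignments to FASTA
#'
#' Masked codons are written as `NNN`.
#'
#' @param alignments list of `codon_alignment` objects.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_codon_alignments <- function(alignments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(alignments, function(aln) {
    codons <- aln$codons
    codons[aln$mask] <- "NNN"
    seqs <- apply(codons, 1, paste, collapse = "")
    path <- file.path(dir, paste0(aln$id, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(seqs), path)
    path
  }, character(1))
  invisible(paths)
}

#' The fixed five-taxon species tree
#'
#' Rooted topology `((S_viminalis,S_suchowensis),((P_tremula,P_tremuloides),
#' P_trichocarpa))` used throughout: two willow species, with three poplar
#' species as outgroup. Branch substitutions are estimated on the
#' `S_viminalis` terminal branch.
#'
#' @return an [ape::read.tree()] `phylo` object.
#' @export
species_tree <- function() {
  ape::read.tree(text = "((S_viminalis,S_suchowensis),((P_tremula,P_tremuloides),P_trichocarpa));")
}

# Resolve taxon roles from a 5-taxon tree of shape ((focal, sister),
# ((a, b), c)): returns the focal tip, its sister, the outgroup cherry pair
# and the remaining outgroup.
#' @keywords internal
tree_roles <- function(tree = species_tree(), focal = "S_viminalis") {
  tips <- tree$tip.label
  if (!(focal %in% tips)) stop("focal taxon not in tree")
  if (length(tips) != 5) stop("expected a 5-taxon tree")
  # sister = the tip forming a cherry with the focal taxon
  focal_id <- match(focal, tips)
  parent <- tree$edge[tree$edge[, 2] == focal_id, 1]
  sib_ids <- tree$edge[tree$edge[, 1] == parent & tree$edge[, 2] != focal_id, 2]
  sib_tips <- sib_ids[sib_ids <= length(tips)]
  if (length(sib_tips) != 1)
    stop("focal taxon must form a cherry with its sister species")
  sister <- tips[sib_tips]
  rest <- setdiff(tips, c(focal, sister))
  # cherry within the outgroup triple
  pair <- NULL
  for (i in 1:2) for (j in (i + 1):3) {
    ids <- match(rest[c(i, j)], tips)
    p <- tree$edge[match(ids, tree$edge[, 2]), 1]
    if (p[1] == p[2]) pair <- rest[c(i, j)]
  }
  if (is.null(pair)) stop("could not resolve outgroup cherry")
  list(focal = focal, sister = sister,
       out_pair = pair, out_far = setdiff(rest, pair))
}
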