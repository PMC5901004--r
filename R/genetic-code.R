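# Codon-level lookup tables shared by the simulator, the divergence counter,
# the polymorphism classifier and the ENC calculator.  Everything here is
# precomputed once at install time from the universal genetic code.

.BASES <- c("T", "C", "A", "G")
.TRANSITION <- c(T = "C", C = "T", A = "G", G = "A")

.GENETIC_CODE <- Biostrings::GENETIC_CODE
.ALL_CODONS <- names(.GENETIC_CODE)
.SENSE_CODONS <- .ALL_CODONS[.GENETIC_CODE != "*"]
.STOP_CODONS <- .ALL_CODONS[.GENETIC_CODE == "*"]

#' Translate codons to amino acids
#'
#' Vectorised lookup in the universal genetic code. Codons containing
#' ambiguity characters return `NA`.
#'
#' @param codons character vector of 3-letter codons (T/C/A/G alphabet).
#' @return character vector of one-letter amino acids (`"*"` for stops,
#'   `NA` for codons outside the code).
#' @export
translate_codons <- function(codons) {
  unname(.GENETIC_CODE[codons])
}

#' @keywords internal
is_stop_codon <- function(codons) {
  codons %in% .STOP_CODONS
}

# All 9 single-nucleotide neighbours of each codon, with the classification
# of the change.  Used by the simulator (mutation proposals), the site
# counter and the per-SNP classifier.
.codon_neighbours <- local({
  out <- vector("list", length(.SENSE_CODONS))
  names(out) <- .SENSE_CODONS
  for (cod in .SENSE_CODONS) {
    aa <- .GENETIC_CODE[[cod]]
    chars <- strsplit(cod, "")[[1]]
    pos <- integer(0); alt <- character(0); to <- character(0)
    for (p in 1:3) {
      for (b in setdiff(.BASES, chars[p])) {
        nb <- chars
        nb[p] <- b
        pos <- c(pos, p); alt <- c(alt, b); to <- c(to, paste(nb, collapse = ""))
      }
    }
    aa2 <- unname(.GENETIC_CODE[to])
    type <- ifelse(aa2 == "*", "stop", ifelse(aa2 == aa, "syn", "nonsyn"))
    out[[cod]] <- data.frame(
      pos = pos, alt = alt, to = to, type = type,
      is_ts = alt == .TRANSITION[chars[pos]],
      stringsAsFactors = FALSE
    )
  }
  out
})

# NG86-style site counts per sense codon.  Position i contributes s_i / k_i
# synonymous sites, where k_i is the number of non-stop single-nucleotide
# neighbours at that position and s_i the synonymous ones; changes to stop
# codons are excluded from numerator and denominator.  N + S = 3 per codon.
.codon_sites <- local({
  S <- numeric(length(.SENSE_CODONS))
  names(S) <- .SENSE_CODONS
  for (cod in .SENSE_CODONS) {
    nb <- .codon_neighbours[[cod]]
    s <- 0
    for (p in 1:3) {
      at <- nb[nb$pos == p & nb$type != "stop", , drop = FALSE]
      k <- nrow(at)
      if (k > 0) s <- s + sum(at$type == "syn") / k
    }
    S[[cod]] <- s
  }
  list(S = S, N = 3 - S)
})

#' NG86 synonymous and nonsynonymous site counts
#'
#' Counts synonymous (S) and nonsynonymous (N) sites for a vector of sense
#' codons. Each codon position contributes a fractional synonymous site equal
#' to the fraction of its single-nucleotide changes that are synonymous;
#' changes creating stop codons are excluded from both numerator and
#' denominator, so every codon contributes exactly 3 sites in total.
#'
#' Codons containing `N` (or other non-ACGT characters) are skipped. A stop
#' codon in frame is an error.
#'
#' @param codons character vector of codons.
#' @param gene optional gene id used in error messages.
#' @return named numeric vector `c(N = ..., S = ...)`.
#' @export
count_sites <- function(codons, gene = NULL) {
  clean <- grepl("^[TCAG]{3}$", codons)
  if (any(is_stop_codon(codons[clean]))) {
    at <- which(clean & is_stop_codon(codons))[1]
    stop(sprintf("in-frame stop codon %s at codon %d%s",
                 codons[at], at,
                 if (is.null(gene)) "" else paste0(" of gene ", gene)))
  }
  S <- sum(.codon_sites$S[codons[clean]])
  c(N = 3 * sum(clean) - S, S = S)
}

# Pathway-averaged substitution counts between two sense codons (NG86).
# All orders of the differing positions are enumerated; orders passing
# through a stop codon are discarded and the remaining paths are averaged
# with equal weights.  If every order hits a stop (cannot happen between
# sense codons differing at <= 3 positions under the universal code, but
# guarded anyway), all orders are used with stop intermediates counted as
# nonsynonymous steps.
.PERMS <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

.path_counts <- function(from, to) {
  f <- strsplit(from, "")[[1]]
  t <- strsplit(to, "")[[1]]
  d <- which(f != t)
  nd <- length(d)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  syn <- numeric(0); nonsyn <- numeric(0); clean <- logical(0)
  for (ord in .PERMS[[as.character(nd)]]) {
    cur <- f
    ns <- 0; nn <- 0; ok <- TRUE
    for (p in d[ord]) {
      aa_cur <- .GENETIC_CODE[[paste(cur, collapse = "")]]
      cur[p] <- t[p]
      nxt <- paste(cur, collapse = "")
      aa_nxt <- .GENETIC_CODE[[nxt]]
      if (aa_nxt == "*") ok <- FALSE
      if (identical(aa_nxt, aa_cur)) ns <- ns + 1 else nn <- nn + 1
    }
    syn <- c(syn, ns); nonsyn <- c(nonsyn, nn); clean <- c(clean, ok)
  }
  if (any(clean)) {
    c(syn = mean(syn[clean]), nonsyn = mean(nonsyn[clean]))
  } else {
    c(syn = mean(syn), nonsyn = mean(nonsyn))
  }
}

# 61 x 61 lookup of pathway-averaged (syn, nonsyn) substitution counts.
.codon_subs <- local({
  n <- length(.SENSE_CODONS)
  DS <- matrix(0, n, n, dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  DN <- DS
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pc <- .path_counts(.SENSE_CODONS[i], .SENSE_CODONS[j])
      DS[i, j] <- pc[["syn"]]
      DN[i, j] <- pc[["nonsyn"]]
    }
  }
  list(DS = DS, DN = DN)
})

#' Pathway-averaged substitution counts between codon pairs
#'
#' For each pair of sense codons, returns the expected number of synonymous
#' and nonsynonymous single-nucleotide steps, averaged with equal weights
#' over all mutational orderings that avoid stop codons (the NG86
#' convention).
#'
#' @param from,to character vectors of sense codons (recycled to common
#'   length).
#' @return data.frame with columns `syn` and `nonsyn`.
#' @export
codon_path_counts <- function(from, to) {
  n <- max(length(from), length(to))
  from <- rep_len(from, n); to <- rep_len(to, n)
  bad <- !(from %in% .SENSE_CODONS) | !(to %in% .SENSE_CODONS)
  if (any(bad)) stop("codon_path_counts() requires sense codons")
  data.frame(
    syn = .codon_subs$DS[cbind(from, to)],
    nonsyn = .codon_subs$DN[cbind(from, to)]
  )
}
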