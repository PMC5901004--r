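# Independent oracles used to validate the package implementations.
# These deliberately use different algorithms from the package code paths.

GC <- Biostrings::GENETIC_CODE
SENSE <- names(GC)[GC != "*"]
BASES <- c("T", "C", "A", "G")

# --- brute-force NG86 site counter: enumerate all 9 single-nucleotide
# neighbours of a codon directly ---------------------------------------
oracle_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  S <- 0
  for (p in 1:3) {
    syn <- 0; tot <- 0
    for (b in setdiff(BASES, chars[p])) {
      nb <- chars; nb[p] <- b
      nbc <- paste(nb, collapse = "")
      if (GC[[nbc]] == "*") next
      tot <- tot + 1
      if (GC[[nbc]] == GC[[codon]]) syn <- syn + 1
    }
    if (tot > 0) S <- S + syn / tot
  }
  c(N = 3 - S, S = S)
}

# --- brute-force pathway enumerator: recursively expand every mutational
# ordering between two codons, discard paths through stops, average the
# rest with equal weights (all paths if none is stop-free) --------------
oracle_paths <- function(from, to) {
  f <- strsplit(from, "")[[1]]
  t <- strsplit(to, "")[[1]]
  walk <- function(cur, remaining) {
    if (!length(remaining))
      return(list(list(syn = 0, nonsyn = 0, clean = TRUE)))
    out <- list()
    for (p in remaining) {
      nxt <- cur; nxt[p] <- t[p]
      nxtc <- paste(nxt, collapse = "")
      step_stop <- GC[[nxtc]] == "*"
      step_syn <- !step_stop && GC[[nxtc]] == GC[[paste(cur, collapse = "")]]
      for (tail in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- list(
          syn = tail$syn + as.numeric(step_syn),
          nonsyn = tail$nonsyn + as.numeric(!step_syn && !step_stop) +
            as.numeric(step_stop),
          clean = tail$clean && !step_stop)
      }
    }
    out
  }
  paths <- walk(f, which(f != t))
  clean <- vapply(paths, `[[`, logical(1), "clean")
  use <- if (any(clean)) paths[clean] else paths
  c(syn = mean(vapply(use, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
}

# --- two-sided Fisher exact p by direct hypergeometric enumeration.
# Probabilities within a 1e-7 relative band of the observed table's are
# treated as ties (floating-point safety on near-symmetric tables). ------
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # first row total
  n <- c + d
  k <- a + c          # first column total
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# --- closed-form OLS via the normal equations --------------------------
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
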