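# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals.  Used for all
#' report-facing ratios so that printed tables are stable across
#' platforms (base \code{round} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Kyte-Doolittle hydropathy index.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

.aa20 <- names(.KD)

.hydropathy <- function(residues) {
  v <- .KD[residues]
  v[is.na(v)] <- 0
  unname(v)
}

# Reverse complement on plain character vectors.
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate plain nucleotide strings; codons containing N (or any
# ambiguity) become X, stops are '*'.  Trailing incomplete codons are
# dropped.
.translateNt <- function(x) {
  x <- as.character(x)
  n <- nchar(x) %/% 3L * 3L
  x <- substr(x, 1L, n)
  empty <- n == 0L
  out <- character(length(x))
  if (any(!empty)) {
    out[!empty] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[!empty]),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  out
}

# Split a protein string into single residues.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Union components for a list of index groups; returns component labels
# renumbered 1..k in order of first appearance.
.componentsFromGroups <- function(n, groups) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (g in groups) {
    if (length(g) < 2L) next
    r <- find(g[1L])
    for (j in g[-1L]) {
      rj <- find(j)
      if (rj != r) parent[rj] <- r
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

# All substrings of length w (character vector), empty if too short.
.words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0L))
  substring(s, 1:(n - w + 1L), w:n)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
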