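# PROSITE-style motif patterns in the dashed grammar:
# elements separated by '-', each a literal residue set ("D", "[FL]")
# or a wildcard "x", with an optional repeat "(n)" or range "(n,m)".
# Example: "[FL]-x(2)-[LVMI]-[VLI]-x(9)-D-P-[LM]".

#' Parse a PROSITE-style motif pattern
#'
#' @param patternText pattern in the dashed grammar with \code{[..]}
#'   residue sets, \code{x} wildcards, \code{x(n)} repeats and
#'   \code{x(n,m)} ranges.
#' @return a \code{MotifPattern}: list of elements, each with
#'   \code{residues} (character vector or NULL for wildcard),
#'   \code{min} and \code{max} repeat counts.
#' @export
parseMotif <- function(patternText) {
  patternText <- as.character(patternText)[[1L]]
  if (!nzchar(patternText)) .stopf("empty motif pattern")
  tokens <- strsplit(patternText, "-", fixed = TRUE)[[1L]]
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!nzchar(tok))
      .stopf("motif parse error at element %d: empty element", i)
    m <- regmatches(tok, regexec(
      "^(\\[([A-Za-z]+)\\]|[A-Za-z])(\\((\\d+)(,(\\d+))?\\))?$", tok))[[1L]]
    if (length(m) == 0L)
      .stopf("motif parse error at element %d: cannot parse '%s'", i, tok)
    lit <- m[2L]; set <- m[3L]; nmin <- m[5L]; nmax <- m[7L]
    residues <- if (nzchar(set)) {
      toupper(.chars(set))
    } else if (identical(toupper(lit), "X")) {
      NULL
    } else {
      toupper(lit)
    }
    lo <- if (nzchar(nmin)) as.integer(nmin) else 1L
    hi <- if (nzchar(nmax)) as.integer(nmax) else lo
    if (lo > hi)
      .stopf("motif parse error at element %d: range %d > %d", i, lo, hi)
    if (!is.null(residues) && length(residues) == 0L)
      .stopf("motif parse error at element %d: empty residue set", i)
    elements[[i]] <- list(residues = residues, min = lo, max = hi)
  }
  structure(list(elements = elements, text = patternText),
            class = "MotifPattern")
}

#' @export
print.MotifPattern <- function(x, ...) {
  cat("MotifPattern:", x$text, "-", length(x$elements), "elements\n")
  invisible(x)
}

#' Scan a protein for a motif pattern
#'
#' Reports all matches, including overlapping ones; for range elements
#' every admissible span length is enumerated, so a start position can
#' yield several end positions.
#'
#' @param protein amino-acid string.
#' @param pattern a \code{MotifPattern} from \code{\link{parseMotif}}
#'   or pattern text.
#' @return data.frame with 0-based half-open columns \code{start},
#'   \code{end} (one row per match span), ordered by start then end.
#' @export
scanMotif <- function(protein, pattern) {
  if (is.character(pattern)) pattern <- parseMotif(pattern)
  protein <- toupper(as.character(protein)[[1L]])
  aa <- .chars(protein)
  n <- length(aa)
  els <- pattern$elements
  nel <- length(els)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  # endsFrom(pos, k): set of 0-based end offsets reachable matching
  # elements k..nel starting at 0-based position pos
  endsFrom <- function(pos, k) {
    if (k > nel) return(pos)
    key <- paste(pos, k)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- integer(0)
    el <- els[[k]]
    for (cnt in el$min:el$max) {
      if (pos + cnt > n) break
      ok <- if (is.null(el$residues)) TRUE else
        cnt == 0L || all(aa[(pos + 1L):(pos + cnt)] %in% el$residues)
      if (ok) res <- c(res, endsFrom(pos + cnt, k + 1L))
    }
    res <- sort(unique(res))
    memo[[key]] <- res
    res
  }
  out <- list()
  for (s in 0:max(0L, n - 1L)) {
    if (n == 0L) break
    ends <- endsFrom(s, 1L)
    if (length(ends) > 0L)
      out[[length(out) + 1L]] <- data.frame(start = s, end = ends)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}
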