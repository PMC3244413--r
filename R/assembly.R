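# Iterative clusterization and assembly: group sequences sharing exact
# words of decreasing length, assemble each group to a quality-weighted
# consensus, and feed consensuses (with derived qualities) to the next
# round.

#' AssemblySchedule: parameters of the decreasing word-size strategy
#'
#' @slot wordSizes nonincreasing integer vector of exact-word seed
#'   lengths, one per clusterization round.
#' @slot maxMatchesPerQuery cap on enumerated matches per query
#'   (mirrors a blastn \code{-v} limit; the partition itself is the
#'   transitive closure, so capped neighbors remain reachable
#'   transitively).
#' @slot minOverlapNt minimum overlap length for merging two sequences.
#' @slot minOverlapIdentity minimum overlap identity in (0, 1].
#' @export
setClass("AssemblySchedule", representation(wordSizes = "integer",
                                            maxMatchesPerQuery = "integer",
                                            minOverlapNt = "integer",
                                            minOverlapIdentity = "numeric"))

setValidity("AssemblySchedule", function(object) {
  w <- object@wordSizes
  if (length(w) == 0L || any(w <= 0L)) return("wordSizes must be positive")
  if (is.unsorted(rev(w))) return("wordSizes must be nonincreasing")
  if (object@minOverlapIdentity <= 0 || object@minOverlapIdentity > 1)
    return("minOverlapIdentity must lie in (0, 1]")
  TRUE
})

#' Construct an assembly schedule
#'
#' Defaults follow the decreasing word-size inclusion strategy: rounds
#' at word sizes 200, 134, 90, 60 and two rounds at 40, with up to 1000
#' matches enumerated per query.
#'
#' @param wordSizes nonincreasing integer vector of word sizes.
#' @param maxMatchesPerQuery match enumeration cap per query.
#' @param minOverlapNt minimum merge overlap (nt).
#' @param minOverlapIdentity minimum merge overlap identity.
#' @return an \code{\linkS4class{AssemblySchedule}}.
#' @export
assemblySchedule <- function(wordSizes = c(200L, 134L, 90L, 60L, 40L, 40L),
                             maxMatchesPerQuery = 1000L,
                             minOverlapNt = 40L,
                             minOverlapIdentity = 0.9) {
  new("AssemblySchedule", wordSizes = as.integer(wordSizes),
      maxMatchesPerQuery = as.integer(maxMatchesPerQuery),
      minOverlapNt = as.integer(minOverlapNt),
      minOverlapIdentity = minOverlapIdentity)
}

#' Group sequences by shared exact words
#'
#' Two sequences belong to the same group iff they are connected by a
#' chain of pairs sharing at least one exact word of length
#' \code{wordSize} (on either strand when \code{bothStrands}).
#' Sequences shorter than the word size are singletons.  The result is
#' the transitive closure of word sharing, so it is independent of
#' input order and of any work partitioning; the per-query match cap
#' only limits enumeration, never reachability.
#'
#' @param sequences named character vector (or \code{DNAStringSet}) of
#'   sequences over A, C, G, T, N.  Words containing N never seed a
#'   match.
#' @param wordSize exact word length (at least 4).
#' @param bothStrands also match words against the reverse complement.
#' @param maxMatchesPerQuery kept for interface compatibility with the
#'   blastn-style \code{-v} cap; does not change the partition.
#' @return a list of character vectors: the groups, in order of first
#'   appearance of their members.
#' @export
sharedWordGroups <- function(sequences, wordSize, bothStrands = TRUE,
                             maxMatchesPerQuery = 1000L) {
  if (is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0L) return(list())
  if (wordSize < 4L) .stopf("wordSize must be at least 4")
  ids <- names(sequences)
  if (is.null(ids)) .stopf("sequences must be named")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    .stopf("sequence '%s' contains symbols outside {A,C,G,T,N}",
           ids[which(bad)[1L]])
  wordLists <- lapply(sequences, function(s) {
    w <- unique(.words(s, wordSize))
    w[!grepl("N", w, fixed = TRUE)]
  })
  nw <- lengths(wordLists)
  words <- unlist(wordLists, use.names = FALSE)
  if (length(words) > 0L && bothStrands) {
    rc <- .revcomp(words)
    words <- ifelse(words < rc, words, rc)
  }
  seqIdx <- rep(seq_along(sequences), nw)
  buckets <- split(seqIdx, words)
  comp <- .componentsFromGroups(length(sequences), buckets)
  unname(split(ids, factor(comp, levels = unique(comp))))
}

## ---- internal contig items --------------------------------------------

# A contig item is a list(tally, cons, quals, members): `tally` is a
# 5 x L numeric matrix of summed phred evidence (rows A,C,G,T,-),
# column-parallel to the consensus string `cons`.

.baseRows <- c("A", "C", "G", "T", "-")

.itemFromRead <- function(base, qual, members) {
  ch <- .chars(base)
  L <- length(ch)
  tally <- matrix(0, nrow = 5L, ncol = L, dimnames = list(.baseRows, NULL))
  known <- ch %in% c("A", "C", "G", "T")
  if (any(known))
    tally[cbind(match(ch[known], .baseRows), which(known))] <- qual[known]
  list(tally = tally, cons = base, quals = as.integer(qual),
       members = members)
}

# Quality-weighted majority consensus: per column the base (or gap)
# with the highest summed phred wins; ties go to the alphabetically
# first base, gaps lose ties to bases.  Gap-winning columns are removed;
# evidence-free columns call N.  Consensus quality is the winning sum
# capped at 60.
.finalizeItem <- function(tally, members) {
  L <- ncol(tally)
  if (L == 0L) .stopf("cannot finalize an empty contig")
  idx <- max.col(t(tally), ties.method = "first")
  win <- .baseRows[idx]
  tot <- colSums(tally)
  win[tot == 0] <- "N"
  keep <- win != "-"
  q <- pmin(60, tally[cbind(idx, seq_len(L))])
  list(tally = tally[, keep, drop = FALSE],
       cons = paste(win[keep], collapse = ""),
       quals = as.integer(round(q[keep])),
       members = members)
}

.rcItem <- function(item) {
  tally <- item$tally[c("T", "G", "C", "A", "-"), rev(seq_len(ncol(item$tally))), drop = FALSE]
  rownames(tally) <- .baseRows
  list(tally = tally, cons = .revcomp(item$cons),
       quals = rev(item$quals), members = item$members)
}

.dnaSubMat <- function() {
  nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = FALSE,
                               type = "DNA")
}

# Merge item j into item i given the chosen orientation of j; the
# dovetail layout comes from an ends-free alignment of the consensuses.
.mergeItems <- function(ci, cj, rc) {
  if (rc) cj <- .rcItem(cj)
  aln <- pairwiseAlignment(pattern = cj$cons, subject = ci$cons,
                           type = "overlap",
                           substitutionMatrix = .dnaSubMat(),
                           gapOpening = 5, gapExtension = 2)
  P <- .chars(as.character(pattern(aln)))
  S <- .chars(as.character(subject(aln)))
  ps <- start(pattern(aln)); ss <- start(subject(aln))
  ti <- ci$tally; tj <- cj$tally
  Li <- ncol(ti); Lj <- ncol(tj)
  blocks <- list()
  if (ss > 1L) blocks <- c(blocks, list(ti[, 1:(ss - 1L), drop = FALSE]))
  if (ps > 1L) blocks <- c(blocks, list(tj[, 1:(ps - 1L), drop = FALSE]))
  spos <- ss; ppos <- ps
  mid <- matrix(0, nrow = 5L, ncol = length(P),
                dimnames = list(.baseRows, NULL))
  for (k in seq_along(P)) {
    cs <- S[k]; cp <- P[k]
    if (cs != "-" && cp != "-") {
      mid[, k] <- ti[, spos] + tj[, ppos]
      spos <- spos + 1L; ppos <- ppos + 1L
    } else if (cp == "-") {
      gv <- if (ppos > 1L) cj$quals[ppos - 1L] else 15L
      mid[, k] <- ti[, spos]
      mid["-", k] <- mid["-", k] + max(1L, gv)
      spos <- spos + 1L
    } else {
      gv <- if (spos > 1L) ci$quals[spos - 1L] else 15L
      mid[, k] <- tj[, ppos]
      mid["-", k] <- mid["-", k] + max(1L, gv)
      ppos <- ppos + 1L
    }
  }
  blocks <- c(blocks, list(mid))
  if (spos <= Li) blocks <- c(blocks, list(ti[, spos:Li, drop = FALSE]))
  if (ppos <= Lj) blocks <- c(blocks, list(tj[, ppos:Lj, drop = FALSE]))
  .finalizeItem(do.call(cbind, blocks), union(ci$members, cj$members))
}

# Greedy overlap-layout-consensus over a group of items: repeatedly
# merge the pair with the longest qualifying overlap (ties: identity,
# then lexicographically smallest member-id pair), in either
# orientation.  Unmergeable items remain singletons.
.assembleItems <- function(items, minOverlapNt, minOverlapIdentity) {
  n <- length(items)
  if (n <= 1L) return(items)
  cons <- vapply(items, `[[`, "", "cons")
  minMember <- vapply(items, function(x) min(x$members), "")
  ovCols <- matrix(0, n, n)
  ovId <- matrix(0, n, n)
  ovRc <- matrix(FALSE, n, n)
  active <- rep(TRUE, n)
  mat <- .dnaSubMat()
  scorePairs <- function(i, js) {
    pats <- DNAStringSet(cons[js])
    alnF <- pairwiseAlignment(pattern = pats, subject = cons[i],
                              type = "overlap", substitutionMatrix = mat,
                              gapOpening = 5, gapExtension = 2)
    alnR <- pairwiseAlignment(pattern = reverseComplement(pats),
                              subject = cons[i],
                              type = "overlap", substitutionMatrix = mat,
                              gapOpening = 5, gapExtension = 2)
    colsF <- nchar(as.character(pattern(alnF)))
    colsR <- nchar(as.character(pattern(alnR)))
    idF <- ifelse(colsF > 0L, nmatch(alnF) / colsF, 0)
    idR <- ifelse(colsR > 0L, nmatch(alnR) / colsR, 0)
    useR <- (colsR > colsF) | (colsR == colsF & idR > idF)
    for (k in seq_along(js)) {
      j <- js[k]
      cc <- if (useR[k]) colsR[k] else colsF[k]
      ii <- if (useR[k]) idR[k] else idF[k]
      ovCols[i, j] <<- cc; ovCols[j, i] <<- cc
      ovId[i, j] <<- ii; ovId[j, i] <<- ii
      ovRc[i, j] <<- useR[k]; ovRc[j, i] <<- useR[k]
    }
  }
  for (i in 2:n) scorePairs(i, seq_len(i - 1L))
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    sub <- ovCols[act, act, drop = FALSE]
    idsub <- ovId[act, act, drop = FALSE]
    elig <- which(upper.tri(sub) & sub >= minOverlapNt &
                  idsub >= minOverlapIdentity, arr.ind = TRUE)
    if (nrow(elig) == 0L) break
    cc <- sub[elig]; ii <- idsub[elig]
    keykey <- vapply(seq_len(nrow(elig)), function(r) {
      m <- sort(c(minMember[act[elig[r, 1L]]], minMember[act[elig[r, 2L]]]))
      paste(m, collapse = "\r")
    }, "")
    o <- order(-cc, -ii, keykey)
    r <- o[1L]
    i <- act[elig[r, 1L]]; j <- act[elig[r, 2L]]
    items[[i]] <- .mergeItems(items[[i]], items[[j]], ovRc[i, j])
    cons[i] <- items[[i]]$cons
    minMember[i] <- min(items[[i]]$members)
    active[j] <- FALSE
    others <- setdiff(which(active), i)
    if (length(others) > 0L) scorePairs(i, others)
  }
  items[active]
}

.itemsFromReadSet <- function(reads) {
  b <- as.character(bases(reads))
  q <- quals(reads)
  ids <- names(bases(reads))
  lapply(seq_along(b), function(i) .itemFromRead(b[i], q[[i]], ids[i]))
}

.contigSetFromItems <- function(items) {
  nr <- vapply(items, function(x) length(x$members), 0L)
  mm <- vapply(items, function(x) min(x$members), "")
  o <- order(-nr, mm)
  items <- items[o]
  ids <- sprintf("ctg%05d", seq_along(items))
  new("ContigSet",
      consensus = setNames(DNAStringSet(vapply(items, `[[`, "", "cons")), ids),
      quals = setNames(lapply(items, `[[`, "quals"), ids),
      members = setNames(lapply(items, `[[`, "members"), ids))
}

#' Assemble a group of reads to consensus contigs
#'
#' Greedy overlap-layout-consensus: the pair with the longest overlap
#' of at least \code{minOverlapNt} nucleotides at identity at least
#' \code{minOverlapIdentity} (in either orientation) is merged first;
#' the consensus takes, per column, the base with the highest summed
#' phred quality (ties go to the alphabetically first base).  Reads
#' that never qualify remain singleton contigs.
#'
#' @param reads a \code{\linkS4class{ReadSet}}.
#' @param minOverlapNt minimum overlap length (nt).
#' @param minOverlapIdentity minimum overlap identity.
#' @return a \code{\linkS4class{ContigSet}}, ordered by descending read
#'   count then id.
#' @export
assembleGroup <- function(reads, minOverlapNt = 40L,
                          minOverlapIdentity = 0.9) {
  stopifnot(is(reads, "ReadSet"), length(reads) > 0L)
  items <- .assembleItems(.itemsFromReadSet(reads), minOverlapNt,
                          minOverlapIdentity)
  .contigSetFromItems(items)
}

#' Iterative decreasing word-size clusterization and assembly
#'
#' One round per scheduled word size: sequences sharing an exact word
#' are grouped (\code{\link{sharedWordGroups}}), each group is
#' assembled to consensus (\code{\link{assembleGroup}} machinery), and
#' the consensuses, with their derived per-column qualities and
#' accumulated read memberships, become the input of the next round.
#' Every input read id ends up in exactly one final contig, and the
#' number of contigs never increases across rounds.
#'
#' @param reads a \code{\linkS4class{ReadSet}}.
#' @param schedule an \code{\linkS4class{AssemblySchedule}}.
#' @return a \code{\linkS4class{ContigSet}}.
#' @export
iterativeClusterize <- function(reads, schedule = assemblySchedule()) {
  stopifnot(is(reads, "ReadSet"), is(schedule, "AssemblySchedule"))
  if (length(reads) == 0L)
    return(new("ContigSet", consensus = DNAStringSet(), quals = list(),
               members = list()))
  items <- .itemsFromReadSet(reads)
  names(items) <- names(bases(reads))
  for (w in schedule@wordSizes) {
    cons <- vapply(items, `[[`, "", "cons")
    groups <- sharedWordGroups(cons, w, bothStrands = TRUE,
                               maxMatchesPerQuery = schedule@maxMatchesPerQuery)
    nxt <- list()
    for (g in groups) {
      sub <- items[g]
      if (length(sub) > 1L) {
        # re-seed each round from consensus + derived quality, as if a
        # fresh FASTA/qual pair were handed to the assembler
        sub <- lapply(sub, function(x)
          .itemFromRead(x$cons, x$quals, x$members))
        sub <- .assembleItems(sub, schedule@minOverlapNt,
                              schedule@minOverlapIdentity)
      }
      nxt <- c(nxt, sub)
    }
    names(nxt) <- vapply(nxt, function(x) min(x$members), "")
    items <- nxt
  }
  .contigSetFromItems(items)
}

#' Filter contigs by length and read support
#'
#' Keeps contigs whose consensus is at least \code{minLenNt}
#' nucleotides long (the default keeps sequences larger than 149 nt)
#' and supported by at least \code{minReads} reads.  Output is ordered
#' by descending read count, then id.
#'
#' @param contigs a \code{\linkS4class{ContigSet}}.
#' @param minLenNt minimum consensus length.
#' @param minReads minimum member read count.
#' @return the filtered \code{\linkS4class{ContigSet}}.
#' @export
filterContigs <- function(contigs, minLenNt = 150L, minReads = 1L) {
  stopifnot(is(contigs, "ContigSet"), minLenNt >= 0L, minReads >= 0L)
  keep <- width(consensus(contigs)) >= minLenNt &
    lengths(contigMembers(contigs)) >= minReads
  cs <- consensus(contigs)[keep]
  qs <- quals(contigs)[keep]
  ms <- contigMembers(contigs)[keep]
  o <- order(-lengths(ms), names(cs))
  new("ContigSet", consensus = cs[o], quals = qs[o], members = ms[o])
}
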