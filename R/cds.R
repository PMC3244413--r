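# Coding-sequence extraction: six-frame translation, ungapped local
# translated-homology search against reference proteins, HSP chaining,
# and frameshift repair by N-bridging (adding or subtracting one N so
# the downstream alignment returns to frame).

.STOPS <- c("TAA", "TAG", "TGA")

# Karlin-Altschul style significance surrogate: only its ordering and
# thresholding behaviour matter to the pipeline; constants are the
# conventional ungapped BLOSUM62 values and are surfaced here.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

.evalueLike <- function(score, m, n) {
  .KA_K * m * n * exp(-.KA_LAMBDA * score)
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six frames under the
#' standard genetic code; codons containing N become X and stops are
#' \code{*}.
#'
#' @param x a contig consensus: character scalar, \code{DNAString}, or
#'   a \code{\linkS4class{ContigSet}} of length 1.
#' @return named character vector of the six translations, frames
#'   \code{+1,+2,+3,-1,-2,-3}.
#' @export
sixFrameTranslate <- function(x) {
  s <- .asSingleSequence(x)
  if (nchar(s) < 3L) .stopf("sequence shorter than one codon")
  rc <- .revcomp(s)
  fr <- c(substring(s, 1:3), substring(rc, 1:3))
  out <- .translateNt(fr)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

.asSingleSequence <- function(x) {
  if (is(x, "ContigSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(consensus(x))[[1L]])
  }
  as.character(x)[[1L]]
}

#' Methionine-started candidate peptides
#'
#' For each frame translation, emits the segment running from every
#' methionine within the first \code{windowAa} predicted residues to
#' the first stop codon (or the end of the translation).
#'
#' @param translations named character vector of frame translations
#'   (e.g. from \code{\link{sixFrameTranslate}}).
#' @param windowAa Met search window in residues.
#' @return data.frame with columns \code{frame}, \code{metPos}
#'   (1-based residue index) and \code{peptide}.
#' @export
metSegments <- function(translations, windowAa = 300L) {
  stopifnot(windowAa >= 1L)
  if (is.null(names(translations)))
    names(translations) <- seq_along(translations)
  out <- list()
  for (f in names(translations)) {
    aa <- .chars(translations[[f]])
    mets <- which(aa == "M")
    mets <- mets[mets <= windowAa]
    for (m in mets) {
      stops <- which(aa == "*")
      stopAfter <- stops[stops > m]
      end <- if (length(stopAfter)) stopAfter[1L] - 1L else length(aa)
      out[[length(out) + 1L]] <- data.frame(
        frame = f, metPos = m,
        peptide = paste(aa[m:end], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = character(0), metPos = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Translated homology search of contigs against reference proteins
#'
#' For each of the six frame translations of each contig, computes
#' ungapped local alignments (BLOSUM62) against every reference
#' protein.  All distinct segments scoring at or above \code{minScore}
#' are reported per frame (found by iteratively masking each reported
#' span), as HSPs with 0-based half-open coordinates; query coordinates
#' are nucleotide positions on the strand used by the frame.  Gap
#' penalties are set prohibitively high on purpose: a sequencing indel
#' splits the homology into two HSPs in different frames, which is
#' exactly the signal the frameshift repair consumes.
#'
#' @param contigs a \code{\linkS4class{ContigSet}} or named character
#'   vector of nucleotide sequences.
#' @param db a \code{\linkS4class{ReferenceDb}} or \code{AAStringSet}.
#' @param minScore minimum raw alignment score reported.
#' @param dbName database label recorded with each HSP.
#' @return data.frame of HSPs: \code{queryId}, \code{db},
#'   \code{subjectId}, \code{frame}, \code{qStart}, \code{qEnd},
#'   \code{sStart}, \code{sEnd}, \code{identities}, \code{score},
#'   \code{evalue}; ordered by query, then descending score, then
#'   subject id.
#' @export
searchTranslated <- function(contigs, db, minScore = 50, dbName = "ref") {
  seqs <- if (is(contigs, "ContigSet")) {
    setNames(as.character(consensus(contigs)), names(consensus(contigs)))
  } else {
    setNames(as.character(contigs), names(contigs))
  }
  if (is.null(names(seqs))) .stopf("contigs must be named")
  prots <- if (is(db, "ReferenceDb")) refProteins(db) else db
  if (length(prots) == 0L) .stopf("reference database is empty")
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  qid <- character(0); qframe <- character(0); qaa <- character(0)
  for (id in names(seqs)) {
    if (nchar(seqs[[id]]) < 3L) next
    tr <- sixFrameTranslate(seqs[[id]])
    ok <- nchar(tr) > 0L
    qid <- c(qid, rep(id, sum(ok)))
    qframe <- c(qframe, frames[ok])
    qaa <- c(qaa, unname(tr[ok]))
  }
  if (length(qaa) == 0L) return(.emptyHsps())
  qlen <- nchar(qaa)
  res <- list()
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  for (sid in names(prots)) {
    subj <- prots[[sid]]
    # A single local alignment yields only the best-scoring segment per
    # frame; weaker same-frame segments (e.g. upstream of a double
    # frameshift) would be shadowed.  Report all segments above the
    # threshold by masking each reported span with X and re-searching.
    curPat <- qaa
    active <- seq_along(curPat)
    for (iter in 1:25) {
      aln <- pairwiseAlignment(pattern = AAStringSet(curPat[active]),
                               subject = subj, type = "local",
                               substitutionMatrix = B62,
                               gapOpening = 1e4, gapExtension = 1e4)
      sc <- score(aln)
      keep <- which(sc >= minScore)
      if (length(keep) == 0L) break
      as1 <- start(pattern(aln))[keep]; ae1 <- end(pattern(aln))[keep]
      ss1 <- start(subject(aln))[keep]; se1 <- end(subject(aln))[keep]
      gi <- active[keep]
      off <- abs(as.integer(substr(qframe[gi], 2L, 2L))) - 1L
      res[[length(res) + 1L]] <- data.frame(
        queryId = qid[gi], db = dbName, subjectId = sid,
        frame = as.integer(paste0(substr(qframe[gi], 1L, 1L),
                                  substr(qframe[gi], 2L, 2L))),
        qStart = off + 3L * (as1 - 1L), qEnd = off + 3L * ae1,
        sStart = ss1 - 1L, sEnd = se1,
        identities = nmatch(aln)[keep], score = sc[keep],
        evalue = .evalueLike(sc[keep], qlen[gi], nchar(subj)),
        stringsAsFactors = FALSE)
      for (j in seq_along(keep)) {
        substr(curPat[gi[j]], as1[j], ae1[j]) <-
          strrep("X", ae1[j] - as1[j] + 1L)
      }
      active <- gi
    }
  }
  if (length(res) == 0L) return(.emptyHsps())
  hsps <- do.call(rbind, res)
  hsps[order(hsps$queryId, -hsps$score, hsps$subjectId), , drop = FALSE]
}

.emptyHsps <- function() {
  data.frame(queryId = character(0), db = character(0),
             subjectId = character(0), frame = integer(0),
             qStart = integer(0), qEnd = integer(0), sStart = integer(0),
             sEnd = integer(0), identities = integer(0), score = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Chain HSPs of one query to its best subject
#'
#' Picks the subject/strand pair with the highest summed score, then
#' assembles a consistent chain: subject coordinates strictly
#' increasing, query coordinates strictly increasing, limited subject
#' overlap, and query gaps of at most \code{maxQueryGapNt} nucleotides
#' so that repairs remain local.  Higher-scoring HSPs are placed first.
#'
#' @param hsps HSP data.frame (rows for a single query).
#' @param maxQueryGapNt maximum allowed nucleotide gap on the query
#'   between adjacent chained HSPs.
#' @param maxSubjectOverlapAa tolerated subject-coordinate overlap
#'   between adjacent HSPs (trimmed away during extraction).
#' @return the chained subset of \code{hsps}, ordered by subject start;
#'   attribute \code{subjectId} names the chained subject.
#' @export
chainHsps <- function(hsps, maxQueryGapNt = 90L, maxSubjectOverlapAa = 30L) {
  if (nrow(hsps) == 0L) return(hsps)
  if (length(unique(hsps$queryId)) != 1L)
    .stopf("chainHsps expects HSPs of a single query")
  strand <- ifelse(hsps$frame > 0L, "+", "-")
  grp <- paste(hsps$db, hsps$subjectId, strand)
  tot <- tapply(hsps$score, grp, sum)
  best <- names(tot)[order(-tot, names(tot))][1L]
  cand <- hsps[grp == best, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$sStart), , drop = FALSE]
  chain <- cand[1L, , drop = FALSE]
  if (nrow(cand) > 1L) {
    for (r in 2:nrow(cand)) {
      h <- cand[r, , drop = FALSE]
      trial <- rbind(chain, h)
      trial <- trial[order(trial$sStart), , drop = FALSE]
      ok <- TRUE
      for (k in seq_len(nrow(trial) - 1L)) {
        a <- trial[k, ]; b <- trial[k + 1L, ]
        if (b$sStart < a$sEnd - maxSubjectOverlapAa ||
            b$sEnd <= a$sEnd ||
            b$qStart <= a$qStart ||
            b$qStart - a$qEnd > maxQueryGapNt) { ok <- FALSE; break }
      }
      if (ok) chain <- trial
    }
  }
  chain <- chain[order(chain$sStart), , drop = FALSE]
  attr(chain, "subjectId") <- chain$subjectId[1L]
  chain
}

#' Extract a frameshift-repaired coding sequence
#'
#' The CDS spans from the chain's first to last query coordinate,
#' extended upstream to the most distant in-frame methionine reachable
#' without crossing a stop codon (within \code{windowAa} codons), and
#' downstream in frame to the first stop codon.  Between adjacent HSPs
#' whose frames differ, the bridging nucleotides are replaced by N's
#' and the bridge length is adjusted by +1 or -1 (whichever is the
#' smaller edit that restores the reading frame) so the downstream HSP
#' returns to frame; each frame change counts as one repair.
#'
#' @param contig query nucleotide sequence (character,
#'   \code{DNAString}, or single-contig \code{\linkS4class{ContigSet}}).
#' @param hspChain HSP chain from \code{\link{chainHsps}}: all rows for
#'   one subject, one strand, subject coordinates increasing.
#' @param subject the reference protein (character or \code{AAString}).
#' @param windowAa upstream Met search window (codons).
#' @return a list: \code{cds} (nucleotide string, N's at repairs),
#'   \code{protein} (translation, N codons as X), \code{repairs},
#'   \code{coverage} (fraction of the subject covered by the chain),
#'   \code{alignedRanges} (matrix of 1-based residue ranges of
#'   \code{protein} covered by the chain), \code{strand}.
#' @export
extractCds <- function(contig, hspChain, subject, windowAa = 300L) {
  s <- .asSingleSequence(contig)
  subject <- as.character(subject)[[1L]]
  if (nrow(hspChain) == 0L) .stopf("empty HSP chain")
  strand <- unique(ifelse(hspChain$frame > 0L, "+", "-"))
  if (length(strand) != 1L)
    .stopf("HSP chain mixes strands for query '%s'", hspChain$queryId[1L])
  if (nrow(hspChain) > 1L &&
      (any(diff(hspChain$sStart) <= 0L) || any(diff(hspChain$qStart) <= 0L)))
    .stopf("HSP chain has out-of-order coordinates for query '%s'",
           hspChain$queryId[1L])
  qseq <- if (strand == "+") s else .revcomp(s)
  n <- nchar(qseq)
  qs <- hspChain$qStart; qe <- hspChain$qEnd
  ss <- hspChain$sStart; se <- hspChain$sEnd
  subjAa <- .chars(subject)
  nHsp <- nrow(hspChain)
  if (nHsp > 1L) {
    # Local alignments drift a few residues past a frameshift.  Trim
    # junction-facing HSP ends until the terminal two residues match
    # the subject, then remove residual subject and query overlap, so
    # that the repair bridge covers the true break.
    hspAa <- function(k) .chars(.translateNt(substr(qseq, qs[k] + 1L, qe[k])))
    tailBad <- function(k) {
      aa <- hspAa(k); L <- length(aa)
      L < 2L || aa[L] != subjAa[se[k]] || aa[L - 1L] != subjAa[se[k] - 1L]
    }
    headBad <- function(k) {
      aa <- hspAa(k); L <- length(aa)
      L < 2L || aa[1L] != subjAa[ss[k] + 1L] || aa[2L] != subjAa[ss[k] + 2L]
    }
    trimTail <- function(k) { qe[k] <<- qe[k] - 3L; se[k] <<- se[k] - 1L }
    trimHead <- function(k) { qs[k] <<- qs[k] + 3L; ss[k] <<- ss[k] + 1L }
    trimCap <- 30L
    for (k in seq_len(nHsp)) {
      if (k < nHsp) {
        t <- 0L
        while (t < trimCap && qe[k] - qs[k] > 6L && tailBad(k)) {
          trimTail(k); t <- t + 1L
        }
      }
      if (k > 1L) {
        t <- 0L
        while (t < trimCap && qe[k] - qs[k] > 6L && headBad(k)) {
          trimHead(k); t <- t + 1L
        }
      }
    }
    for (k in 2:nHsp) {
      # contested subject overlap: both HSPs claim the same subject
      # residues; keep the copy that matches the subject better
      ov <- se[k - 1L] - ss[k]
      if (ov > 0L) {
        aaPrev <- hspAa(k - 1L); aaCur <- hspAa(k)
        ov <- min(ov, length(aaPrev) - 2L, length(aaCur) - 2L)
      }
      if (ov > 0L) {
        # the true break can sit anywhere inside the contested region:
        # split it where total subject agreement is maximal
        subjOv <- subjAa[(se[k - 1L] - ov + 1L):se[k - 1L]]
        tailRes <- aaPrev[(length(aaPrev) - ov + 1L):length(aaPrev)]
        subjOv2 <- subjAa[(ss[k] + 1L):(ss[k] + ov)]
        headRes <- aaCur[1:ov]
        prevCum <- c(0L, cumsum(tailRes == subjOv))
        curCum <- c(0L, cumsum(headRes == subjOv2))
        splitScore <- prevCum + (curCum[ov + 1L] - curCum)
        t <- which.max(splitScore) - 1L
        if (ov - t > 0L) for (r in seq_len(ov - t)) trimTail(k - 1L)
        if (t > 0L) for (r in seq_len(t)) trimHead(k)
      }
      # query overlap, in frame-preserving steps
      while (qs[k] < qe[k - 1L]) trimHead(k)
      if (qs[k] >= qe[k]) .stopf("HSP %d fully overlaps its predecessor", k)
    }
  }
  codonAt <- function(p0) substr(qseq, p0 + 1L, p0 + 3L)
  # upstream extension to the most distant in-frame Met before a stop
  upStart <- qs[1L]
  bestMet <- NA_integer_
  p <- qs[1L] - 3L
  steps <- 0L
  while (p >= 0L && steps < windowAa) {
    cod <- codonAt(p)
    if (cod %in% .STOPS) break
    if (cod == "ATG") bestMet <- p
    p <- p - 3L
    steps <- steps + 1L
  }
  if (!is.na(bestMet)) upStart <- bestMet
  # downstream extension in frame to the first stop codon
  downEnd <- qe[nrow(hspChain)]
  p <- downEnd
  steps <- 0L
  while (p + 3L <= n && steps < windowAa) {
    cod <- codonAt(p)
    if (cod %in% .STOPS) break
    p <- p + 3L
    steps <- steps + 1L
  }
  downEnd <- p
  # assemble: upstream + HSP pieces with N-bridges at frame changes
  pieces <- substr(rep(qseq, nrow(hspChain)), qs + 1L, qe)
  parts <- substr(qseq, upStart + 1L, qe[1L])
  aaCursor <- (qe[1L] - upStart) %/% 3L
  hspAaStart <- (qs[1L] - upStart) %/% 3L + 1L
  ranges <- matrix(c(hspAaStart, aaCursor), ncol = 2L)
  repairs <- 0L
  if (nrow(hspChain) > 1L) {
    for (k in 2:nrow(hspChain)) {
      bridge <- qs[k] - qe[k - 1L]
      sameFrame <- (bridge %% 3L) == 0L
      if (sameFrame) {
        parts <- paste0(parts, substr(qseq, qe[k - 1L] + 1L, qs[k]))
        nAa <- bridge %/% 3L
      } else {
        delta <- if (bridge %% 3L == 1L) -1L else 1L
        nN <- bridge + delta
        parts <- paste0(parts, strrep("N", nN))
        nAa <- nN %/% 3L
        repairs <- repairs + 1L
      }
      pieceAa <- (qe[k] - qs[k]) %/% 3L
      ranges <- rbind(ranges, c(aaCursor + nAa + 1L,
                                aaCursor + nAa + pieceAa))
      parts <- paste0(parts, pieces[k])
      aaCursor <- aaCursor + nAa + pieceAa
    }
  }
  parts <- paste0(parts, substr(qseq, qe[nrow(hspChain)] + 1L, downEnd))
  covered <- sum(se - ss)
  list(cds = parts,
       protein = .translateNt(parts),
       repairs = repairs,
       coverage = min(1, covered / nchar(subject)),
       alignedRanges = ranges,
       strand = strand)
}

# Ungapped local search of a restricted query window against a
# restricted subject region, reporting all segments whose e-value --
# computed for this reduced search space -- passes maxEvalue.  Scores
# far below the genome-wide reporting threshold are significant here
# because m and n are tiny.  Coordinates are returned on the full
# strand-oriented query / full subject.
.searchRegionHsps <- function(qseq, q0, q1, subject, s0, s1, strandSign,
                              queryId, db, subjectId, maxEvalue = 0.05,
                              maxIter = 8L) {
  win <- substr(qseq, q0 + 1L, q1)
  sreg <- substr(subject, s0 + 1L, s1)
  if (nchar(win) < 12L || nchar(sreg) < 4L) return(NULL)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  rows <- list()
  for (o in 1:3) {
    cur <- .translateNt(substr(win, o, nchar(win)))
    if (nchar(cur) < 4L) next
    m <- nchar(cur)
    for (iter in seq_len(maxIter)) {
      aln <- pairwiseAlignment(pattern = cur, subject = sreg,
                               type = "local", substitutionMatrix = B62,
                               gapOpening = 1e4, gapExtension = 1e4)
      sc <- score(aln)
      as1 <- start(pattern(aln)); ae1 <- end(pattern(aln))
      ev <- .evalueLike(sc, m, nchar(sreg))
      if (sc <= 0 || ev > maxEvalue) break
      if (ae1 - as1 + 1L >= 4L) {
        ss1 <- start(subject(aln)); se1 <- end(subject(aln))
        qStart <- q0 + (o - 1L) + 3L * (as1 - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          queryId = queryId, db = db, subjectId = subjectId,
          frame = strandSign * ((qStart %% 3L) + 1L),
          qStart = qStart, qEnd = q0 + (o - 1L) + 3L * ae1,
          sStart = s0 + ss1 - 1L, sEnd = s0 + se1,
          identities = nmatch(aln), score = sc, evalue = ev,
          stringsAsFactors = FALSE)
      }
      substr(cur, as1, ae1) <- strrep("X", ae1 - as1 + 1L)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# Terminal rescue of an HSP chain.  When the chain leaves an uncovered
# subject prefix or suffix and the query extends far enough to encode
# it, the missing homology is usually a short fragment cut off from the
# global search by an indel close to the sequence end: too short to
# reach the genome-wide score threshold, yet unambiguous in a targeted
# re-search of just the uncovered region.  Any rescued fragments are
# folded back through chainHsps so ordering constraints still hold.
.rescueTerminalHsps <- function(chain, qseq, subject, maxQueryGapNt = 90L,
                                maxEvalue = 0.05) {
  n <- nchar(qseq)
  L <- nchar(subject)
  strandSign <- if (chain$frame[1L] > 0L) 1L else -1L
  cand <- NULL
  ss1 <- chain$sStart[1L]; qs1 <- chain$qStart[1L]
  if (ss1 >= 3L && qs1 >= 12L) {
    q0 <- max(0L, qs1 - 3L * ss1 - 18L)
    cand <- rbind(cand, .searchRegionHsps(
      qseq, q0, qs1, subject, 0L, ss1, strandSign,
      chain$queryId[1L], chain$db[1L], chain$subjectId[1L], maxEvalue))
  }
  seL <- chain$sEnd[nrow(chain)]; qeL <- chain$qEnd[nrow(chain)]
  if (L - seL >= 3L && n - qeL >= 12L) {
    q1 <- min(n, qeL + 3L * (L - seL) + 18L)
    cand <- rbind(cand, .searchRegionHsps(
      qseq, qeL, q1, subject, seL, L, strandSign,
      chain$queryId[1L], chain$db[1L], chain$subjectId[1L], maxEvalue))
  }
  if (is.null(cand) || nrow(cand) == 0L) return(chain)
  chainHsps(rbind(chain, cand), maxQueryGapNt = maxQueryGapNt)
}

#' Extract coding sequences for all contigs against one or more databases
#'
#' Runs the translated homology search for every database, keeps
#' contigs whose best chained hit covers at least
#' \code{minSubjectCoverage} of the subject protein, and extracts the
#' frameshift-repaired CDS keyed to the overall best hit.  Before
#' extraction the chain's ends are rescued: when an uncovered subject
#' prefix or suffix is still encoded by the query, a targeted re-search
#' of just that region (significance judged against its reduced search
#' space) recovers terminal fragments cut off by near-end indels, so
#' start-proximal features such as signal peptides survive repair.
#' Per-database best hits are recorded for every extracted CDS.
#'
#' @param contigs a \code{\linkS4class{ContigSet}} (already filtered to
#'   the desired minimum read support).
#' @param dbs a \code{\linkS4class{ReferenceDb}} or a named list of them.
#' @param minSubjectCoverage minimum fraction of the subject protein
#'   covered by the HSP chain.
#' @param minScore minimum HSP score.
#' @param maxQueryGapNt maximum chained query gap (nt).
#' @param windowAa upstream Met search window (codons).
#' @return a \code{\linkS4class{CdsSet}}.
#' @export
extractAllCds <- function(contigs, dbs, minSubjectCoverage = 0.5,
                          minScore = 50, maxQueryGapNt = 90L,
                          windowAa = 300L) {
  stopifnot(is(contigs, "ContigSet"))
  if (is(dbs, "ReferenceDb")) dbs <- list(ref = dbs)
  if (is.null(names(dbs))) .stopf("databases must be named")
  allHsps <- list()
  for (dn in names(dbs)) {
    allHsps[[dn]] <- searchTranslated(contigs, dbs[[dn]],
                                      minScore = minScore, dbName = dn)
  }
  hsps <- do.call(rbind, allHsps)
  ids <- character(0); cds <- character(0); prot <- character(0)
  cid <- character(0); rc <- integer(0); rep_ <- integer(0)
  aligned <- list()
  hitRows <- list()
  rcounts <- readCounts(contigs)
  for (cg in names(consensus(contigs))) {
    h <- hsps[hsps$queryId == cg, , drop = FALSE]
    if (nrow(h) == 0L) next
    # best chain per database; extraction keyed to the overall best
    chains <- list()
    for (dn in unique(h$db)) {
      hd <- h[h$db == dn, , drop = FALSE]
      ch <- chainHsps(hd, maxQueryGapNt = maxQueryGapNt)
      subj <- refProteins(dbs[[dn]])[[attr(ch, "subjectId")]]
      cov <- min(1, sum(ch$sEnd - ch$sStart) / nchar(as.character(subj)))
      chains[[dn]] <- list(chain = ch, coverage = cov,
                           evalue = min(ch$evalue), score = sum(ch$score))
    }
    sc <- vapply(chains, `[[`, 0, "score")
    bestDb <- names(chains)[order(-sc, names(chains))][1L]
    bc <- chains[[bestDb]]
    if (bc$coverage < minSubjectCoverage) next
    subjId <- attr(bc$chain, "subjectId")
    subj <- as.character(refProteins(dbs[[bestDb]])[[subjId]])
    s <- as.character(consensus(contigs))[[cg]]
    qseq <- if (bc$chain$frame[1L] > 0L) s else .revcomp(s)
    rescued <- .rescueTerminalHsps(bc$chain, qseq, subj,
                                   maxQueryGapNt = maxQueryGapNt)
    if (nrow(rescued) != nrow(bc$chain)) {
      bc$chain <- rescued
      bc$coverage <- min(1, sum(rescued$sEnd - rescued$sStart) /
                           nchar(subj))
      bc$score <- sum(rescued$score)
      chains[[bestDb]] <- bc
    }
    rec <- extractCds(s, bc$chain, subj, windowAa = windowAa)
    id <- sub("^ctg", "cds", cg)
    ids <- c(ids, id)
    cds <- c(cds, rec$cds)
    prot <- c(prot, rec$protein)
    cid <- c(cid, cg)
    rc <- c(rc, unname(rcounts[cg]))
    rep_ <- c(rep_, rec$repairs)
    aligned[[length(aligned) + 1L]] <- rec$alignedRanges
    for (dn in names(chains)) {
      hitRows[[length(hitRows) + 1L]] <- data.frame(
        id = id, db = dn, subject = attr(chains[[dn]]$chain, "subjectId"),
        coverage = chains[[dn]]$coverage, evalue = chains[[dn]]$evalue,
        score = chains[[dn]]$score, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hitRows)) do.call(rbind, hitRows) else
    data.frame(id = character(0), db = character(0), subject = character(0),
               coverage = numeric(0), evalue = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  new("CdsSet",
      cds = setNames(DNAStringSet(cds), ids),
      protein = setNames(AAStringSet(prot), ids),
      contigId = cid, readCount = as.integer(rc), repairs = rep_,
      hits = hits, alignedRanges = aligned)
}

#' Coverage and significance tallies over a CDS set
#'
#' Counts coding sequences whose best-hit subject coverage is strictly
#' greater than \code{coverageThreshold}, and those whose best
#' significance surrogate is at most \code{evalueThreshold}.
#'
#' @param cdsSet a \code{\linkS4class{CdsSet}}.
#' @param coverageThreshold strict lower bound on best coverage.
#' @param evalueThreshold upper bound on best e-value surrogate.
#' @return named integer vector \code{c(nHighCoverage=, nLowEvalue=)}.
#' @export
coverageTally <- function(cdsSet, coverageThreshold = 0.75,
                          evalueThreshold = 1e-15) {
  h <- cdsHits(cdsSet)
  if (nrow(h) == 0L)
    return(c(nHighCoverage = 0L, nLowEvalue = 0L))
  bestCov <- tapply(h$coverage, h$id, max)
  bestEv <- tapply(h$evalue, h$id, min)
  c(nHighCoverage = sum(bestCov > coverageThreshold),
    nLowEvalue = sum(bestEv <= evalueThreshold))
}
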