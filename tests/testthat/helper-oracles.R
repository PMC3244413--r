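# Independent oracles and tiny fixture builders.  Every oracle here is
# written from the definition, not from the implementation it checks.

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomProtein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

allWords <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  unique(substring(s, 1:(n - w + 1), w:n))
}

# Brute-force shared-word partition: all-pairs k-mer set intersection
# (both strands), then repeated-pass transitive closure.
oracleSharedGroups <- function(seqs, w) {
  ids <- names(seqs)
  n <- length(seqs)
  sets <- lapply(seqs, function(s) {
    k <- allWords(s, w)
    unique(c(k, revcompChr(k)))
  })
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    adj[i, i] <- TRUE
    if (i < n) for (j in (i + 1):n) {
      if (length(intersect(sets[[i]], sets[[j]])) > 0) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1
    front <- i
    comp[i] <- cur
    while (length(front) > 0) {
      nxt <- integer(0)
      for (f in front) {
        nb <- which(adj[f, ] & is.na(comp))
        comp[nb] <- cur
        nxt <- c(nxt, nb)
      }
      front <- nxt
    }
  }
  unname(split(ids, comp))
}

# Canonical form of a partition (list of id vectors) for comparison.
partitionKey <- function(groups) {
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = ","), "")))
}

# Brute-force ungapped local alignment score: best scoring contiguous
# diagonal segment over all offsets.
oracleUngappedLocal <- function(a, b, mat) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- 0
  for (off in (-(length(A) - 1)):(length(B) - 1)) {
    run <- 0
    for (i in seq_along(A)) {
      j <- i + off
      if (j < 1 || j > length(B)) next
      run <- max(0, run + mat[A[i], B[j]])
      best <- max(best, run)
    }
  }
  best
}

# Brute-force connected components over a thresholded identity matrix.
oracleComponents <- function(idMat, covMat, thresholdPct, minCoverage) {
  n <- nrow(idMat)
  link <- idMat >= thresholdPct / 100 & covMat >= minCoverage
  diag(link) <- TRUE
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1
    stack <- i
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(link[v, ] & is.na(comp)))
    }
  }
  unname(split(rownames(idMat), comp))
}

# Exhaustive motif matcher: enumerate every combination of element
# span lengths at every start position and check residues directly.
oracleMotifMatches <- function(protein, elements) {
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  lens <- lapply(elements, function(e) e$min:e$max)
  combos <- expand.grid(lens)
  out <- list()
  for (s in 0:max(0, n - 1)) {
    if (n == 0) break
    for (r in seq_len(nrow(combos))) {
      pos <- s
      ok <- TRUE
      for (k in seq_along(elements)) {
        cnt <- combos[r, k]
        if (pos + cnt > n) { ok <- FALSE; break }
        res <- elements[[k]]$residues
        if (!is.null(res) && cnt > 0 &&
            !all(aa[(pos + 1):(pos + cnt)] %in% res)) { ok <- FALSE; break }
        pos <- pos + cnt
      }
      if (ok) out[[length(out) + 1]] <- c(s, pos)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  m <- unique(do.call(rbind, out))
  df <- data.frame(start = m[, 1], end = m[, 2])
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random PROSITE-style pattern for property tests.
randomMotifPattern <- function(nElements = 4) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  toks <- vapply(seq_len(nElements), function(i) {
    kind <- sample(c("set", "single", "x"), 1)
    base <- switch(kind,
      set = paste0("[", paste(sample(alphabet, sample(2:3, 1)),
                              collapse = ""), "]"),
      single = sample(alphabet, 1),
      x = "x")
    rep <- sample(c("", "(2)", "(1,3)", "(0,2)"), 1,
                  prob = c(0.55, 0.15, 0.15, 0.15))
    paste0(base, rep)
  }, "")
  paste(toks, collapse = "-")
}

# Table-driven codon translator (independent of Biostrings::translate).
oracleTranslate <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(nt) %/% 3 * 3
  if (n == 0) return("")
  codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  aa <- ifelse(grepl("N", codons), "X", unname(gc[codons]))
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Single-contig ContigSet wrapper around a bare sequence.
asContig <- function(seq, id = "ctg00001", reads = "r1") {
  new("ContigSet",
      consensus = setNames(Biostrings::DNAStringSet(seq), id),
      quals = setNames(list(rep(40L, nchar(seq))), id),
      members = setNames(list(reads), id))
}

# ContigSet from a character vector of sequences (one read each).
asContigSet <- function(seqs) {
  ids <- sprintf("ctg%05d", seq_along(seqs))
  new("ContigSet",
      consensus = setNames(Biostrings::DNAStringSet(unname(seqs)), ids),
      quals = setNames(lapply(nchar(seqs), function(L) rep(40L, L)), ids),
      members = setNames(lapply(seq_along(seqs), function(i)
        sprintf("r%d", i)), ids))
}

# Positions (on the extracted protein) of mismatches against the truth
# protein that lie inside HSP-covered regions yet farther than 2
# residues from any repair mark (X residue or inter-range junction).
repairViolations <- function(extracted, truth, alignedRanges) {
  aln <- Biostrings::pairwiseAlignment(extracted, truth, type = "overlap",
                                       substitutionMatrix = blosum62,
                                       gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ppos <- cumsum(pa != "-") + Biostrings::start(Biostrings::pattern(aln)) - 1
  xpos <- which(strsplit(extracted, "")[[1]] == "X")
  marks <- xpos
  if (nrow(alignedRanges) > 1) {
    for (r in 2:nrow(alignedRanges)) {
      marks <- c(marks, alignedRanges[r - 1, 2], alignedRanges[r, 1])
    }
  }
  inAligned <- function(pos)
    any(pos >= alignedRanges[, 1] & pos <= alignedRanges[, 2])
  bad <- which(pa != sa & pa != "-" & sa != "-" & pa != "X")
  viol <- integer(0)
  for (b in bad) {
    if (!inAligned(ppos[b])) next
    if (length(marks) == 0 || min(abs(ppos[b] - marks)) > 2)
      viol <- c(viol, ppos[b])
  }
  viol
}

blosum62 <- local({
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
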