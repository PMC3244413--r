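# Multi-evidence functional classification into Secreted /
# Housekeeping / Unknown / Transposable-element classes with a
# configurable subcategory vocabulary.  Sequence-signal predictions
# (signal peptide, membrane helices, O-glycosylation, furin sites) use
# documented built-in heuristics; externally computed verdicts can be
# substituted through plain tab-separated files.

#' Built-in signal peptide heuristic
#'
#' A protein is flagged as bearing a signal peptide when, within
#' residues 1-35, there is a window of at least 8 residues with mean
#' Kyte-Doolittle hydropathy >= 1.6 (the hydrophobic core), followed
#' within 6 residues by a small residue (A, G, S, C or T) marking the
#' cleavage position.  This mimics the behaviour, not the internals, of
#' HMM-based signal predictors.
#'
#' @param protein amino-acid string starting with Met.
#' @return list with \code{flag} (logical) and \code{cleavagePos}
#'   (1-based residue index of the cleavage site, NA when no signal).
#' @export
predictSignalPeptide <- function(protein) {
  protein <- as.character(protein)[[1L]]
  if (nchar(protein) == 0L) .stopf("empty protein")
  aa <- .chars(protein)
  n <- length(aa)
  h <- .hydropathy(aa)
  lim <- min(35L, n)
  small <- c("A", "G", "S", "C", "T")
  # enumerate every window of >= 8 residues inside 1..35; first
  # qualifying (start, end, cleavage) in scan order wins
  if (lim >= 8L) {
    for (w in seq_len(lim - 7L)) {
      for (end in (w + 7L):lim) {
        if (mean(h[w:end]) < 1.6) next
        if (end + 1L > n) next
        ps <- (end + 1L):min(end + 6L, n)
        hitp <- ps[aa[ps] %in% small]
        if (length(hitp) > 0L)
          return(list(flag = TRUE, cleavagePos = hitp[1L]))
      }
    }
  }
  list(flag = FALSE, cleavagePos = NA_integer_)
}

#' Built-in transmembrane helix counter
#'
#' Counts disjoint windows of at least 19 residues with mean
#' Kyte-Doolittle hydropathy >= 1.6, scanning the sequence after the
#' signal peptide cleavage site (when one is present).
#'
#' @param protein amino-acid string.
#' @param cleavagePos optional 1-based signal cleavage position; the
#'   scan starts after it.
#' @return nonnegative integer count.
#' @export
countTmHelices <- function(protein, cleavagePos = NA_integer_) {
  aa <- .chars(as.character(protein)[[1L]])
  from <- if (!is.na(cleavagePos)) cleavagePos + 1L else 1L
  if (from > length(aa)) return(0L)
  h <- .hydropathy(aa[from:length(aa)])
  n <- length(h)
  count <- 0L
  i <- 1L
  while (i + 18L <= n) {
    if (mean(h[i:(i + 18L)]) >= 1.6) {
      count <- count + 1L
      i <- i + 19L
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Built-in mucin-type O-glycosylation site counter
#'
#' Counts serine/threonine residues whose surrounding 11-mer (truncated
#' at the sequence ends) contains at least 5 residues from {S, T, P} --
#' the low-complexity density characteristic of mucin domains.
#'
#' @param protein amino-acid string.
#' @return nonnegative integer count.
#' @export
countOglycSites <- function(protein) {
  aa <- .chars(as.character(protein)[[1L]])
  n <- length(aa)
  stp <- aa %in% c("S", "T", "P")
  count <- 0L
  for (i in which(aa %in% c("S", "T"))) {
    lo <- max(1L, i - 5L); hi <- min(n, i + 5L)
    if (sum(stp[lo:hi]) >= 5L) count <- count + 1L
  }
  count
}

#' Furin cleavage site finder
#'
#' Matches the basic pro-protein processing motif R-X-[KR]-R
#' (overlapping occurrences included) and reports the position of the
#' final arginine of each match.
#'
#' @param protein amino-acid string.
#' @return integer vector of 1-based positions (empty when none).
#' @export
findFurinSites <- function(protein) {
  protein <- as.character(protein)[[1L]]
  m <- gregexpr("(?=R.[KR]R)", protein, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0L))
  as.integer(m) + 3L
}

#' Default classification rules table
#'
#' Keyword to (class, subcategory) rules with per-rule maximum e-value,
#' covering the recurrent secreted salivary protein families of hard
#' ticks (protease inhibitors, enzymes, lipocalins, mucins,
#' tick-specific families), common housekeeping roles, and
#' transposable-element signatures.  Users can extend or replace the
#' table (\code{\link{readRules}}).
#'
#' @return data.frame with columns \code{keyword}, \code{class},
#'   \code{subcategory}, \code{maxEvalue}.
#' @export
defaultRules <- function() {
  S <- function(kw, sub) data.frame(keyword = kw, class = "S",
                                    subcategory = sub, maxEvalue = 1e-5,
                                    stringsAsFactors = FALSE)
  H <- function(kw, sub) data.frame(keyword = kw, class = "H",
                                    subcategory = sub, maxEvalue = 1e-5,
                                    stringsAsFactors = FALSE)
  TE <- function(kw, sub) data.frame(keyword = kw, class = "TE",
                                     subcategory = sub, maxEvalue = 1e-5,
                                     stringsAsFactors = FALSE)
  rbind(
    TE("transposase", "transposable element - class II"),
    TE("retrovirus", "transposable element - class I"),
    TE("pogo", "transposable element - class II"),
    TE("tc1", "transposable element - class II"),
    S("kunitz", "protease inhibitor - Kunitz"),
    S("til", "protease inhibitor - TIL"),
    S("thyropin", "protease inhibitor - thyropin"),
    S("cystatin", "protease inhibitor - cystatin"),
    S("serpin", "protease inhibitor - serpin"),
    S("kazal", "protease inhibitor - Kazal"),
    S("carboxypeptidase inhibitor", "protease inhibitor - carboxypeptidase"),
    S("pebp", "phosphatidylethanolamine-binding protein"),
    S("metalloprotease", "enzyme - metalloprotease"),
    S("serine protease", "enzyme - serine protease"),
    S("legumain", "enzyme - legumain"),
    S("endonuclease", "enzyme - endonuclease"),
    S("apyrase", "enzyme - 5'-nucleotidase/apyrase"),
    S("lipase", "enzyme - lipase/esterase"),
    S("glycosidase", "enzyme - glycosidase"),
    S("sulfatase", "enzyme - sulfatase"),
    S("lipocalin", "lipocalin"),
    S("antigen-5", "antigen-5/CRISP"),
    S("prokineticin", "prokineticin domain"),
    S("serum amyloid", "serum amyloid"),
    S("mucin", "mucin"),
    S("defensin", "immunity/antimicrobial"),
    S("glycine-rich", "glycine-rich/cement"),
    S("ggy", "GGY family"),
    S("ixodegrin", "ixodegrin"),
    S("disintegrin", "disintegrin"),
    S("salp15", "Salp15-like"),
    S("basic-tail", "basic tail/18.3-kDa"),
    S("23-kda", "23-kDa family"),
    S("8.9-kda", "8.9-kDa family"),
    S("ixostatin", "ixostatin"),
    S("one-of-each", "one-of-each family"),
    S("evasin", "evasin"),
    S("dap-36", "DAP-36 immunosuppressant"),
    S("13-kda", "metastriate 13-kDa family"),
    H("ribosomal protein", "protein synthesis"),
    H("cytochrome", "energy metabolism"),
    H("tubulin", "cytoskeleton"),
    H("actin", "cytoskeleton"),
    H("histone", "nuclear regulation"),
    H("proteasome", "proteasome machinery"),
    H("chaperone", "protein modification"),
    H("transcription factor", "transcription machinery"),
    H("kinase", "signal transduction"),
    H("transporter", "transport"))
}

#' Read / write a classification rules table
#'
#' Tab-separated with header: keyword, class, subcategory, maxEvalue.
#' Classes must be S, H, TE or U; anything else is rejected at load
#' time.
#'
#' @param path file path.
#' @return data.frame of rules.
#' @export
readRules <- function(path) {
  r <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  stringsAsFactors = FALSE)
  need <- c("keyword", "class", "subcategory", "maxEvalue")
  if (!all(need %in% names(r)))
    .stopf("rules table must have columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(r$class), c("S", "H", "TE", "U"))
  if (length(bad) > 0L)
    .stopf("unknown class in rules table: %s", paste(bad, collapse = ", "))
  r
}

#' @rdname readRules
#' @param rules rules data.frame.
#' @export
writeRules <- function(rules, path) {
  write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gather the evidence bundle for one protein
#'
#' @param protein amino-acid string.
#' @param hits data.frame of per-database best hits with columns
#'   \code{db}, \code{subject}, \code{keyword}, \code{evalue},
#'   \code{coverage}.
#' @param contaminantHit optional contaminant call ("rRNA" or "mito").
#' @param signalCall optional externally supplied list(flag,
#'   cleavagePos); the built-in heuristic is used when NULL.
#' @return evidence list consumed by \code{\link{classifyEvidence}}.
#' @export
gatherEvidence <- function(protein, hits, contaminantHit = NA_character_,
                           signalCall = NULL) {
  sig <- if (is.null(signalCall)) predictSignalPeptide(protein) else signalCall
  list(hits = hits,
       signal = sig,
       tmCount = countTmHelices(protein, sig$cleavagePos),
       oglycCount = countOglycSites(protein),
       furinSites = findFurinSites(protein),
       contaminantHit = contaminantHit)
}

#' Classify one evidence bundle
#'
#' Deterministic precedence: (1) a contaminant hit is Housekeeping
#' "rRNA-mito"; (2) a transposon keyword hit within its rule's e-value
#' is a Transposable Element; (3) a signal peptide with at most one
#' membrane helix is Secreted when a secreted-family keyword matches,
#' or "putative secreted, unknown family" when nothing informative
#' matched at all; (4) any housekeeping keyword hit is Housekeeping;
#' (5) otherwise Unknown.  Keyword hits are matched case-insensitively
#' against the hit keyword strings; among hits matching the same rule
#' step, the lowest e-value wins.  The rationale lists every rule fired
#' or skipped, so the outcome is auditable and independent of database
#' order.
#'
#' @param evidence list from \code{\link{gatherEvidence}}.
#' @param rules rules table (\code{\link{defaultRules}}).
#' @param informativeEvalue hits at or below this e-value count as
#'   informative for the "no informative hit" branch of rule 3.
#' @return list with \code{topClass} (one of S, H, U, TE),
#'   \code{subcategory}, and \code{rationale} (character vector).
#' @export
classifyEvidence <- function(evidence, rules = defaultRules(),
                             informativeEvalue = 1e-5) {
  if (nrow(rules) == 0L) .stopf("rules table is empty")
  rationale <- character(0)
  hits <- evidence$hits
  matchRules <- function(classWanted) {
    if (is.null(hits) || nrow(hits) == 0L) return(NULL)
    rr <- rules[rules$class == classWanted, , drop = FALSE]
    best <- NULL
    for (k in seq_len(nrow(rr))) {
      m <- grepl(tolower(rr$keyword[k]), tolower(hits$keyword), fixed = TRUE)
      m <- m & hits$evalue <= rr$maxEvalue[k]
      if (!any(m)) next
      ev <- min(hits$evalue[m])
      if (is.null(best) || ev < best$evalue)
        best <- list(rule = rr[k, ], evalue = ev)
    }
    best
  }
  # (1) contaminant screen
  if (!is.na(evidence$contaminantHit)) {
    rationale <- c(rationale, sprintf("contaminant hit (%s): class H",
                                      evidence$contaminantHit))
    return(list(topClass = "H", subcategory = "rRNA-mito",
                rationale = rationale))
  }
  rationale <- c(rationale, "no contaminant hit")
  # (2) transposable element keywords
  te <- matchRules("TE")
  if (!is.null(te)) {
    rationale <- c(rationale, sprintf("TE keyword '%s' at evalue %.2g",
                                      te$rule$keyword, te$evalue))
    return(list(topClass = "TE", subcategory = te$rule$subcategory,
                rationale = rationale))
  }
  rationale <- c(rationale, "no transposon keyword hit")
  # (3) secretion evidence
  sigOk <- isTRUE(evidence$signal$flag) && evidence$tmCount <= 1L
  if (sigOk) {
    sec <- matchRules("S")
    if (!is.null(sec)) {
      rationale <- c(rationale,
                     sprintf("signal peptide + secreted keyword '%s'",
                             sec$rule$keyword))
      return(list(topClass = "S", subcategory = sec$rule$subcategory,
                  rationale = rationale))
    }
    informative <- !is.null(hits) && nrow(hits) > 0L &&
      any(hits$evalue <= informativeEvalue)
    if (!informative) {
      rationale <- c(rationale,
                     "signal peptide, no informative hit: putative secreted")
      return(list(topClass = "S",
                  subcategory = "putative secreted, unknown family",
                  rationale = rationale))
    }
    rationale <- c(rationale,
                   "signal peptide but informative non-secreted hit")
  } else {
    rationale <- c(rationale, "no secretion signal (or >1 membrane helix)")
  }
  # (4) housekeeping keywords
  hk <- matchRules("H")
  if (!is.null(hk)) {
    rationale <- c(rationale, sprintf("housekeeping keyword '%s'",
                                      hk$rule$keyword))
    return(list(topClass = "H", subcategory = hk$rule$subcategory,
                rationale = rationale))
  }
  rationale <- c(rationale, "no housekeeping keyword hit: unknown")
  list(topClass = "U", subcategory = "unknown", rationale = rationale)
}

#' Screen contigs against a contaminant nucleotide set
#'
#' A contig is called a contaminant when it shares an exact word of
#' \code{wordSize} nucleotides (either strand) with a contaminant
#' record; the call is the record class parsed from its id prefix
#' (\code{rrna_*} or \code{mito_*}).
#'
#' @param contigs a \code{\linkS4class{ContigSet}}.
#' @param contamDb named \code{DNAStringSet} of contaminant records.
#' @param wordSize exact word length.
#' @return named character vector per contig: "rRNA", "mito" or NA.
#' @export
detectContaminant <- function(contigs, contamDb, wordSize = 40L) {
  ids <- names(consensus(contigs))
  out <- setNames(rep(NA_character_, length(ids)), ids)
  if (length(contamDb) == 0L) return(out)
  seqs <- c(setNames(as.character(consensus(contigs)), ids),
            setNames(as.character(contamDb), names(contamDb)))
  groups <- sharedWordGroups(seqs, wordSize, bothStrands = TRUE)
  for (g in groups) {
    contam <- g[grepl("^(rrna|mito)_", g)]
    if (length(contam) == 0L) next
    cls <- if (grepl("^rrna", contam[1L])) "rRNA" else "mito"
    out[intersect(g, ids)] <- cls
  }
  out
}

#' Annotate and classify a CDS set
#'
#' Builds the evidence bundle for every coding sequence (database best
#' hits with their reference keywords, built-in or supplied signal
#' peptide calls, membrane helix / O-glycosylation / furin heuristics,
#' contaminant screen) and applies the rule-based classifier.
#'
#' @param cdsSet a \code{\linkS4class{CdsSet}}.
#' @param dbs the \code{\linkS4class{ReferenceDb}} (or named list)
#'   used for extraction; supplies keyword tags for hit subjects.
#' @param rules classification rules table.
#' @param contaminantCalls optional named vector of contaminant calls
#'   per contig id (from \code{\link{detectContaminant}}).
#' @param signalCalls optional data.frame (id, flag, cleavagePos) of
#'   externally computed signal predictions replacing the built-in
#'   heuristic.
#' @param informativeEvalue informative-hit threshold of the classifier.
#' @return data.frame with one row per CDS: id, contig, class,
#'   subcategory, signal flag and cleavage position, membrane helix
#'   count, O-glycosylation count, furin site count, best subject /
#'   keyword / coverage / e-value, read count, repairs, and the
#'   rationale (semicolon-joined).
#' @export
annotateCds <- function(cdsSet, dbs, rules = defaultRules(),
                        contaminantCalls = NULL, signalCalls = NULL,
                        informativeEvalue = 1e-5) {
  stopifnot(is(cdsSet, "CdsSet"))
  if (is(dbs, "ReferenceDb")) dbs <- list(ref = dbs)
  kwMaps <- lapply(dbs, refKeywords)
  hits <- cdsHits(cdsSet)
  ids <- names(cdsNt(cdsSet))
  prots <- as.character(cdsProteins(cdsSet))
  rcount <- readCounts(cdsSet)
  reps <- nRepairs(cdsSet)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    h <- hits[hits$id == id, , drop = FALSE]
    h$keyword <- vapply(seq_len(nrow(h)), function(r)
      unname(kwMaps[[h$db[r]]][h$subject[r]]), "")
    contam <- NA_character_
    if (!is.null(contaminantCalls)) {
      cg <- cdsSet@contigId[i]
      if (cg %in% names(contaminantCalls)) contam <- contaminantCalls[[cg]]
    }
    sigCall <- NULL
    if (!is.null(signalCalls) && id %in% signalCalls$id) {
      r <- signalCalls[signalCalls$id == id, , drop = FALSE][1L, ]
      sigCall <- list(flag = as.logical(r$flag),
                      cleavagePos = as.integer(r$cleavagePos))
    }
    ev <- gatherEvidence(prots[i], h, contaminantHit = contam,
                         signalCall = sigCall)
    cl <- classifyEvidence(ev, rules, informativeEvalue)
    bi <- if (nrow(h)) which.min(h$evalue) else NA_integer_
    rows[[i]] <- data.frame(
      id = id, contig = cdsSet@contigId[i],
      class = cl$topClass, subcategory = cl$subcategory,
      signal = isTRUE(ev$signal$flag),
      cleavagePos = if (is.null(ev$signal$cleavagePos)) NA_integer_ else
        ev$signal$cleavagePos,
      tmCount = ev$tmCount, oglycCount = ev$oglycCount,
      furinCount = length(ev$furinSites),
      bestSubject = if (is.na(bi)) NA_character_ else h$subject[bi],
      bestKeyword = if (is.na(bi)) NA_character_ else h$keyword[bi],
      bestCoverage = if (is.na(bi)) NA_real_ else h$coverage[bi],
      bestEvalue = if (is.na(bi)) NA_real_ else h$evalue[bi],
      readCount = unname(rcount[id]), repairs = unname(reps[id]),
      rationale = paste(cl$rationale, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(0), contig = character(0),
                      class = character(0), subcategory = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
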