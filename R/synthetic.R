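# Synthetic 454-style sialotranscriptome generator: ground-truth
# multigene transcript families at controlled amino-acid divergence,
# planted signal peptides, expression-level skew, and
# homopolymer-biased indel errors.  Every planted feature is recorded
# so downstream stages can be scored against the truth.

# Controlled vocabulary used when auto-assigning planted family roles.
.secretedRoles <- c("kunitz", "til", "cystatin", "serpin", "kazal",
                    "lipocalin", "mucin", "evasin", "metalloprotease",
                    "antigen-5", "basic-tail", "8.9-kda", "glycine-rich")
.housekeepingRoles <- c("ribosomal protein", "cytochrome", "tubulin",
                        "actin", "histone", "proteasome", "chaperone",
                        "transcription factor")

.randomResidues <- function(n) {
  paste(sample(.aa20, n, replace = TRUE), collapse = "")
}

# Hydrophobic leader + small-residue cleavage site; the same grammar the
# built-in signal peptide predictor recognises.
.signalLeader <- function() {
  k <- sample(10:14, 1L)
  core <- sample(c("L", "V", "I", "F"), k, replace = TRUE,
                 prob = c(0.55, 0.2, 0.15, 0.1))
  small <- sample(c("A", "G", "S"), 1L)
  list(leader = paste(c(core, small), collapse = ""),
       cleavagePos = 1L + k + 1L)
}

# TRUE when the first 35 residues contain a hydrophobic window that
# the leader grammar would accept (8 consecutive residues with mean
# Kyte-Doolittle hydropathy >= 1.6).
.hasLeaderWindow <- function(protein) {
  h <- .hydropathy(.chars(protein))
  n <- min(35L, length(h))
  if (n < 8L) return(FALSE)
  for (w in 1:(n - 7L)) {
    if (mean(h[w:(w + 7L)]) >= 1.6) return(TRUE)
  }
  FALSE
}

# Per-site substitution rate so that two copies mutated independently
# from a common ancestor show the requested pairwise p-distance:
# q = 2p - p^2 (coincident identical replacements are negligible).
.siteRateForDivergence <- function(d) 1 - sqrt(1 - d)

#' Mutate a protein by per-site residue substitution
#'
#' Each residue beyond a frozen prefix is replaced, with probability
#' \code{siteRate}, by a different residue drawn uniformly from the 19
#' alternatives.  Used to derive family members from a common ancestor;
#' two independent copies at rate p are separated by a p-distance of
#' about 2p - p^2.
#'
#' @param protein a single amino-acid string.
#' @param siteRate per-site substitution probability in [0, 1).
#' @param frozenPrefix number of leading residues never mutated (the
#'   initiator Met and any planted signal peptide).
#' @return the mutated protein string.
#' @export
mutateProtein <- function(protein, siteRate, frozenPrefix = 1L) {
  aa <- .chars(protein)
  n <- length(aa)
  if (frozenPrefix >= n) return(protein)
  idx <- (frozenPrefix + 1L):n
  hit <- idx[runif(length(idx)) < siteRate]
  for (i in hit) {
    aa[i] <- sample(setdiff(.aa20, aa[i]), 1L)
  }
  paste(aa, collapse = "")
}

# Random synonymous back-translation of a protein (no stop codon is
# appended: the transcript is the coding region).
.codonTable <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

.backTranslate <- function(protein) {
  aa <- .chars(protein)
  codons <- vapply(aa, function(a) {
    ch <- .codonTable[[a]]
    ch[sample.int(length(ch), 1L)]
  }, character(1L))
  paste(codons, collapse = "")
}

#' Generate ground-truth transcript families
#'
#' Builds \code{nFamilies} multigene families of
#' \code{copiesPerFamily} transcripts each.  Family members descend
#' from a common ancestral protein by per-codon substitution tuned so
#' that the realized within-family pairwise amino-acid p-distance
#' approximates \code{targetAaDivergence}.  A fraction of families
#' carries an N-terminal signal peptide (hydrophobic leader followed by
#' a small-residue cleavage site); each family is assigned a functional
#' role keyword which later drives ground-truth classification:
#' signal-bearing families draw secreted-protein roles, the remainder
#' housekeeping roles or (with probability \code{teFraction})
#' \code{"transposase"}.  Families without a signal are constructed so
#' that their N-terminal region does not contain the leader grammar,
#' keeping the planted truth self-consistent.
#'
#' @param nFamilies number of families.
#' @param copiesPerFamily transcripts per family.
#' @param targetAaDivergence target within-family pairwise amino-acid
#'   p-distance, in [0, 1).
#' @param meanCdsLenNt mean coding-sequence length in nucleotides;
#'   must be at least 90 and divisible by 3.
#' @param signalFraction fraction of families with a planted signal
#'   peptide.
#' @param utrLenNt approximate untranslated-region length added on each
#'   side of the coding sequence (the 5' UTR is padded to a codon
#'   multiple and ends in an in-frame stop; the 3' UTR begins with the
#'   stop codon), emulating the UTRs of real cDNA reads.
#' @param seed RNG seed; output is deterministic for a fixed seed.
#' @param familyRoles optional character vector of role keywords,
#'   recycled across families; overrides automatic role assignment.
#' @param teFraction probability that a non-signal family is a
#'   transposable element.
#' @return a \code{\linkS4class{TruthSet}}.
#' @export
generateFamilies <- function(nFamilies, copiesPerFamily,
                             targetAaDivergence = 0.2,
                             meanCdsLenNt = 450, signalFraction = 0.5,
                             utrLenNt = 60L, seed = 1L,
                             familyRoles = NULL, teFraction = 0.15) {
  if (meanCdsLenNt < 90 || meanCdsLenNt %% 3L != 0L)
    .stopf("meanCdsLenNt must be >= 90 and divisible by 3 (got %d): codons are the unit of divergence", meanCdsLenNt)
  if (targetAaDivergence < 0 || targetAaDivergence >= 1)
    .stopf("targetAaDivergence must lie in [0, 1)")
  .withSeed(seed, {
    meanAa <- meanCdsLenNt %/% 3L
    utr5 <- max(0L, as.integer(utrLenNt) %/% 3L * 3L)
    ids <- character(0); fam <- character(0); kw <- character(0)
    sig <- logical(0); cpos <- integer(0); wts <- numeric(0)
    cds <- character(0); prot <- character(0); txs <- character(0)
    randNt <- function(n) if (n <= 0L) "" else
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    for (f in seq_len(nFamilies)) {
      famId <- sprintf("F%03d", f)
      # length variation bounded to +/-20% so no family falls below
      # a usable transcript length
      lenAa <- max(30L, round(meanAa * min(1.2, max(0.8, rnorm(1L, 1, 0.1)))))
      hasSig <- runif(1L) < signalFraction
      role <- if (!is.null(familyRoles)) {
        familyRoles[(f - 1L) %% length(familyRoles) + 1L]
      } else if (hasSig) {
        sample(.secretedRoles, 1L)
      } else if (runif(1L) < teFraction) {
        "transposase"
      } else {
        sample(.housekeepingRoles, 1L)
      }
      if (hasSig) {
        sl <- .signalLeader()
        frozen <- sl$cleavagePos
        ancestor <- paste0("M", sl$leader,
                           .randomResidues(lenAa - 1L - nchar(sl$leader)))
        cleavage <- sl$cleavagePos
      } else {
        frozen <- 1L
        # a "no signal" transcript must not accidentally contain the
        # leader grammar, or the planted truth would be mislabeled
        repeat {
          ancestor <- paste0("M", .randomResidues(lenAa - 1L))
          if (!.hasLeaderWindow(ancestor)) break
        }
        cleavage <- NA_integer_
      }
      # Rescale the per-site rate so the frozen prefix does not dilute
      # the realized whole-protein divergence.
      tAdj <- min(0.95, targetAaDivergence * lenAa / (lenAa - frozen))
      p <- .siteRateForDivergence(tAdj)
      for (k in seq_len(copiesPerFamily)) {
        pk <- mutateProtein(ancestor, p, frozen)
        # the planted "no signal" label must stay true for every family
        # member, not just the ancestor: re-draw mutation sets that
        # happen to create a leader-grammar window
        if (!hasSig) {
          while (.hasLeaderWindow(pk)) pk <- mutateProtein(ancestor, p, frozen)
        }
        ids <- c(ids, sprintf("%s_T%02d", famId, k))
        fam <- c(fam, famId); kw <- c(kw, role)
        sig <- c(sig, hasSig); cpos <- c(cpos, cleavage)
        wts <- c(wts, rlnorm(1L, 0, 1))
        prot <- c(prot, pk)
        ck <- .backTranslate(pk)
        cds <- c(cds, ck)
        # 5' UTR ends in an in-frame stop; 3' UTR starts with the stop
        u5 <- if (utr5 >= 3L) paste0(randNt(utr5 - 3L), "TAA") else ""
        txs <- c(txs, paste0(u5, ck, "TAA", randNt(utrLenNt)))
      }
    }
    new("TruthSet",
        transcript = setNames(DNAStringSet(txs), ids),
        utr5Len = rep(utr5, length(ids)),
        cds = setNames(DNAStringSet(cds), ids),
        protein = setNames(AAStringSet(prot), ids),
        familyId = fam, keyword = kw, hasSignal = sig,
        cleavagePos = cpos, expressionWeight = wts)
  })
}

# Apply 454-style errors to one read (character scalar).  The indel
# probability at a base scales with the length of the homopolymer run
# it belongs to: rate * (1 + bias * (runlength - 1)).  Returns the
# errored sequence and the planted edit ledger (positions are original
# read coordinates).
.apply454Errors <- function(seq, subRate, indelRate, bias) {
  ch <- .chars(seq)
  n <- length(ch)
  r <- rle(ch)
  runlen <- rep(r$lengths, r$lengths)
  pos <- integer(0); type <- character(0)
  if (subRate > 0) {
    hit <- which(runif(n) < subRate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    pos <- c(pos, hit); type <- c(type, rep("sub", length(hit)))
  }
  reps <- rep(1L, n)
  if (indelRate > 0) {
    pIndel <- pmin(0.5, indelRate * (1 + bias * (runlen - 1)))
    hit <- which(runif(n) < pIndel)
    if (length(hit) > 0L) {
      ins <- runif(length(hit)) < 0.5
      reps[hit[ins]] <- 2L    # 454 overcall: extra copy of the base
      reps[hit[!ins]] <- 0L   # undercall: base dropped
      pos <- c(pos, hit)
      type <- c(type, ifelse(ins, "ins", "del"))
    }
  }
  o <- order(pos)
  list(seq = paste(rep(ch, reps), collapse = ""),
       edits = data.frame(pos = pos[o], type = type[o],
                          stringsAsFactors = FALSE))
}

#' Simulate 454-style reads from a TruthSet
#'
#' Reads are sampled from transcripts proportionally to their
#' expression weights, from both strands, with normally distributed
#' lengths around \code{meanReadLen}, substitution errors at
#' \code{subRate} and insertion/deletion errors whose per-base
#' probability grows with homopolymer run length as
#' \code{indelRate * (1 + homopolymerBias * (runlength - 1))}.
#' Per-base phred qualities start at 30 and decay by 0.02 per base
#' toward the read end.  Every planted edit is recorded in the origins
#' ledger.
#'
#' @param truth a \code{\linkS4class{TruthSet}}.
#' @param meanReadLen mean read length (nt); must not exceed the
#'   shortest transcript.
#' @param depth mean fold coverage; the total read count is
#'   \code{round(depth * total transcript length / meanReadLen)}.
#' @param indelRate per-base indel probability before homopolymer
#'   scaling.
#' @param subRate per-base substitution probability.
#' @param homopolymerBias nonnegative homopolymer indel multiplier.
#' @param seed RNG seed.
#' @return a list with elements \code{reads}
#'   (a \code{\linkS4class{ReadSet}}) and \code{origins} (a data.frame
#'   with one row per read: transcript, start, end, strand and the
#'   planted edit list).
#' @export
simulateReads454 <- function(truth, meanReadLen = 344, depth = 15,
                             indelRate = 0.01, subRate = 0.005,
                             homopolymerBias = 2, seed = 1L) {
  stopifnot(is(truth, "TruthSet"), length(truth) > 0L)
  tlen <- width(truth@transcript)
  if (meanReadLen > min(tlen))
    .stopf("meanReadLen (%d) exceeds the shortest transcript (%d nt)",
           meanReadLen, min(tlen))
  nReads <- round(depth * sum(tlen) / meanReadLen)
  if (nReads < 1L)
    .stopf("depth %g yields zero reads for this truth set", depth)
  .withSeed(seed, {
    tseq <- as.character(truth@transcript)
    tids <- names(truth@transcript)
    w <- truth@expressionWeight
    pick <- sample.int(length(truth), nReads, replace = TRUE, prob = w)
    rl <- pmax(40L, round(rnorm(nReads, meanReadLen, 0.1 * meanReadLen)))
    rl <- pmin(rl, tlen[pick])
    start <- floor(runif(nReads) * (tlen[pick] - rl + 1L)) + 1L
    strand <- sample(c("+", "-"), nReads, replace = TRUE)
    seqs <- character(nReads)
    origins <- vector("list", nReads)
    ids <- sprintf("r%06d", seq_len(nReads))
    for (i in seq_len(nReads)) {
      s <- substr(tseq[pick[i]], start[i], start[i] + rl[i] - 1L)
      if (strand[i] == "-") s <- .revcomp(s)
      err <- .apply454Errors(s, subRate, indelRate, homopolymerBias)
      seqs[i] <- err$seq
      e <- err$edits
      origins[[i]] <- data.frame(
        readId = ids[i], transcriptId = tids[pick[i]],
        start = start[i], end = start[i] + rl[i] - 1L,
        strand = strand[i],
        nSub = sum(e$type == "sub"), nIns = sum(e$type == "ins"),
        nDel = sum(e$type == "del"),
        edits = paste(sprintf("%d:%s", e$pos, e$type), collapse = ";"),
        stringsAsFactors = FALSE)
    }
    quals <- lapply(nchar(seqs), function(L)
      pmax(2L, as.integer(round(30 - 0.02 * (seq_len(L) - 1L)))))
    list(reads = ReadSet(setNames(seqs, ids), quals),
         origins = do.call(rbind, origins))
  })
}

#' Build a protein reference database from a TruthSet
#'
#' Every truth protein is present verbatim under its transcript id and
#' planted role keyword; decoy records (random proteins) are added,
#' each carrying exactly one role tag.
#'
#' @param truth a \code{\linkS4class{TruthSet}}.
#' @param nDecoysPerRole decoy records per role.
#' @param roles nonempty character vector of decoy role tags.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{ReferenceDb}}.
#' @export
makeReferenceDb <- function(truth, nDecoysPerRole = 2L,
                            roles = c("transposase", "ribosomal protein",
                                      "hypothetical"),
                            seed = 1L) {
  if (length(roles) == 0L)
    .stopf("roles must be a nonempty keyword list")
  .withSeed(seed, {
    lenAa <- max(30L, round(stats::median(width(truth@protein))))
    prot <- as.character(truth@protein)
    ids <- names(truth@protein)
    kw <- truth@keyword
    decoy <- rep(FALSE, length(prot))
    for (role in roles) {
      for (i in seq_len(nDecoysPerRole)) {
        prot <- c(prot, paste0("M", .randomResidues(lenAa - 1L)))
        ids <- c(ids, sprintf("decoy_%s_%d", gsub("[^A-Za-z0-9]", "_", role), i))
        kw <- c(kw, role)
        decoy <- c(decoy, TRUE)
      }
    }
    new("ReferenceDb", proteins = setNames(AAStringSet(prot), ids),
        keyword = kw, isDecoy = decoy)
  })
}

#' Simulate contaminant nucleotide records
#'
#' Random rRNA-like and mitochondrial-like nucleotide sequences used to
#' exercise the contaminant screen of the classifier.
#'
#' @param nRrna,nMito number of records per class.
#' @param lenNt record length.
#' @param seed RNG seed.
#' @return a named \code{DNAStringSet} (names \code{rrna_i}, \code{mito_i}).
#' @export
simulateContaminants <- function(nRrna = 2L, nMito = 2L, lenNt = 600L,
                                 seed = 1L) {
  .withSeed(seed, {
    n <- nRrna + nMito
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), lenNt, replace = TRUE),
            collapse = ""), character(1L))
    names(seqs) <- c(sprintf("rrna_%d", seq_len(nRrna)),
                     sprintf("mito_%d", seq_len(nMito)))
    DNAStringSet(seqs)
  })
}

#' Generate a hierarchical gene-family truth set
#'
#' Builds one protein family containing \code{nGenes} genes, each with
#' \code{copiesPerGene} allelic copies: gene ancestors diverge from a
#' common family ancestor to a pairwise p-distance of about
#' \code{betweenDivergence}, and copies within a gene to about
#' \code{withinDivergence}.  Used to calibrate and test gene-count
#' estimation from divergence thresholds.
#'
#' @param nGenes number of distinct genes.
#' @param copiesPerGene allelic copies per gene.
#' @param withinDivergence target pairwise p-distance within a gene.
#' @param betweenDivergence target pairwise p-distance between genes.
#' @param lengthAa protein length in residues.
#' @param seed RNG seed.
#' @return a list with \code{proteins} (named \code{AAStringSet}) and
#'   \code{geneId} (character vector of planted gene assignments).
#' @export
generateGeneFamilies <- function(nGenes, copiesPerGene,
                                 withinDivergence = 0.10,
                                 betweenDivergence = 0.40,
                                 lengthAa = 150L, seed = 1L) {
  .withSeed(seed, {
    ancestor <- paste0("M", .randomResidues(lengthAa - 1L))
    pB <- .siteRateForDivergence(betweenDivergence)
    pW <- .siteRateForDivergence(withinDivergence)
    prot <- character(0); gene <- character(0); ids <- character(0)
    for (g in seq_len(nGenes)) {
      ga <- mutateProtein(ancestor, pB, 1L)
      for (k in seq_len(copiesPerGene)) {
        prot <- c(prot, mutateProtein(ga, pW, 1L))
        gene <- c(gene, sprintf("G%02d", g))
        ids <- c(ids, sprintf("G%02d_a%02d", g, k))
      }
    }
    list(proteins = setNames(AAStringSet(prot), ids), geneId = gene)
  })
}
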