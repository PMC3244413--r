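#' ReadSet: pyrosequencing reads with per-base qualities
#'
#' A set of nucleotide reads, each with a vector of phred quality
#' scores of the same length as the read.  This is the unit of input to
#' the clusterization/assembly stage and the output of
#' \code{\link{simulateReads454}}.
#'
#' @slot bases a \code{DNAStringSet}, one entry per read, named by read id.
#' @slot quals a list of integer vectors, parallel to \code{bases}.
#' @export
setClass("ReadSet", representation(bases = "DNAStringSet", quals = "list"))

setValidity("ReadSet", function(object) {
  if (length(object@bases) != length(object@quals))
    return("bases and quals have different lengths")
  if (length(object@bases) > 0L && is.null(names(object@bases)))
    return("reads must be named")
  w <- width(object@bases)
  ql <- lengths(object@quals)
  if (any(w != ql))
    return("each quality vector must match its read length")
  if (any(w == 0L))
    return("reads must be nonempty")
  TRUE
})

#' Construct a ReadSet
#'
#' @param bases a named \code{DNAStringSet} or named character vector.
#' @param quals a list of integer phred vectors, one per read.  If
#'   missing, a flat phred 30 profile is assumed.
#' @return a \code{\linkS4class{ReadSet}}.
#' @export
ReadSet <- function(bases, quals = NULL) {
  if (!is(bases, "DNAStringSet")) bases <- DNAStringSet(bases)
  if (is.null(quals)) quals <- lapply(width(bases), function(w) rep(30L, w))
  quals <- lapply(quals, as.integer)
  names(quals) <- names(bases)
  new("ReadSet", bases = bases, quals = quals)
}

#' ContigSet: consensus sequences with read membership
#'
#' Assembled contigs: consensus bases, per-column consensus qualities,
#' and the identities of the member reads.  Singleton contigs are
#' unassembled reads.
#'
#' @slot consensus a \code{DNAStringSet} named by contig id.
#' @slot quals list of integer vectors, per-column consensus quality.
#' @slot members list of character vectors of member read ids.
#' @export
setClass("ContigSet", representation(consensus = "DNAStringSet",
                                     quals = "list", members = "list"))

setValidity("ContigSet", function(object) {
  n <- length(object@consensus)
  if (length(object@quals) != n || length(object@members) != n)
    return("consensus, quals and members must be parallel")
  if (n > 0L && is.null(names(object@consensus)))
    return("contigs must be named")
  if (any(width(object@consensus) != lengths(object@quals)))
    return("consensus qualities must match consensus length")
  if (any(lengths(object@members) == 0L))
    return("every contig must have at least one member read")
  TRUE
})

#' TruthSet: ground-truth transcript families
#'
#' The output of \code{\link{generateFamilies}}: transcript coding
#' sequences grouped into families, with planted signal peptides,
#' functional role keywords and expression weights.  Serves as the
#' oracle for every downstream recovery test.
#'
#' @slot transcript \code{DNAStringSet} of full transcripts
#'   (5' UTR + CDS + stop codon + 3' UTR), the substrate reads are
#'   sampled from.
#' @slot utr5Len integer, 5' UTR length of each transcript (a multiple
#'   of 3, ending in an in-frame stop, so upstream extension during CDS
#'   extraction halts at the true initiator Met).
#' @slot cds \code{DNAStringSet} of transcript coding sequences, named
#'   by transcript id.
#' @slot protein \code{AAStringSet} of the encoded proteins.
#' @slot familyId character, family of each transcript.
#' @slot keyword character, planted functional role of each family
#'   (e.g. \code{"kunitz"}, \code{"ribosomal protein"}, \code{"transposase"}).
#' @slot hasSignal logical, whether a signal peptide was planted.
#' @slot cleavagePos integer, 1-based signal cleavage residue (NA if none).
#' @slot expressionWeight numeric, positive sampling weight.
#' @export
setClass("TruthSet", representation(transcript = "DNAStringSet",
                                    utr5Len = "integer",
                                    cds = "DNAStringSet",
                                    protein = "AAStringSet",
                                    familyId = "character",
                                    keyword = "character",
                                    hasSignal = "logical",
                                    cleavagePos = "integer",
                                    expressionWeight = "numeric"))

setValidity("TruthSet", function(object) {
  n <- length(object@cds)
  if (length(object@transcript) != n || length(object@utr5Len) != n ||
      length(object@protein) != n || length(object@familyId) != n ||
      length(object@keyword) != n || length(object@hasSignal) != n ||
      length(object@cleavagePos) != n || length(object@expressionWeight) != n)
    return("all transcript slots must be parallel")
  if (any(width(object@cds) %% 3L != 0L))
    return("coding sequences must have length divisible by 3")
  if (any(object@expressionWeight <= 0))
    return("expression weights must be positive")
  bad <- object@hasSignal & (is.na(object@cleavagePos) |
                             object@cleavagePos < 1L | object@cleavagePos > 40L)
  if (any(bad))
    return("signal cleavage positions must lie in residues 1..40")
  TRUE
})

#' ReferenceDb: annotated protein reference set
#'
#' A protein database with one functional keyword per record, standing
#' in for annotated reference collections (NR/Swissprot-like) during
#' homology search and keyword classification.
#'
#' @slot proteins \code{AAStringSet} named by record id.
#' @slot keyword character, one keyword tag per record.
#' @slot isDecoy logical, TRUE for generated decoy records.
#' @export
setClass("ReferenceDb", representation(proteins = "AAStringSet",
                                       keyword = "character",
                                       isDecoy = "logical"))

setValidity("ReferenceDb", function(object) {
  n <- length(object@proteins)
  if (length(object@keyword) != n || length(object@isDecoy) != n)
    return("proteins, keyword and isDecoy must be parallel")
  if (n > 0L && anyDuplicated(names(object@proteins)))
    return("duplicate record ids are not allowed")
  TRUE
})

#' CdsSet: frameshift-repaired coding sequences
#'
#' Coding sequences extracted from contigs by translated homology, with
#' the repaired nucleotide sequence (N's mark frameshift repairs), the
#' deduced protein, read support, database hits and repair counts.
#'
#' @slot cds \code{DNAStringSet} named by CDS id.
#' @slot protein \code{AAStringSet}, deduced proteins (N codons as X).
#' @slot contigId character, source contig of each CDS.
#' @slot readCount integer, reads supporting the source contig.
#' @slot repairs integer, number of frameshift repair events.
#' @slot hits data.frame of per-database best hits (columns \code{id},
#'   \code{db}, \code{subject}, \code{coverage}, \code{evalue},
#'   \code{score}).
#' @slot alignedRanges list of two-column matrices giving 1-based
#'   start/end residue ranges of the deduced protein covered by the
#'   homology alignment chain.
#' @export
setClass("CdsSet", representation(cds = "DNAStringSet",
                                  protein = "AAStringSet",
                                  contigId = "character",
                                  readCount = "integer",
                                  repairs = "integer",
                                  hits = "data.frame",
                                  alignedRanges = "list"))

setValidity("CdsSet", function(object) {
  n <- length(object@cds)
  if (length(object@protein) != n || length(object@contigId) != n ||
      length(object@readCount) != n || length(object@repairs) != n ||
      length(object@alignedRanges) != n)
    return("all CDS slots must be parallel")
  if (any(object@repairs < 0L))
    return("repair counts must be nonnegative")
  TRUE
})

## ---- generics and accessors -------------------------------------------

#' @describeIn ReadSet number of reads
#' @param x,object a ReadSet
#' @export
setMethod("length", "ReadSet", function(x) length(x@bases))

#' Sequence bases
#' @param x an object holding sequences.
#' @return a \code{DNAStringSet}.
#' @export
setGeneric("bases", function(x) standardGeneric("bases"))

#' Per-base qualities
#' @param x an object holding qualities.
#' @return a list of integer vectors.
#' @export
setGeneric("quals", function(x) standardGeneric("quals"))

#' Consensus sequences
#' @param x a ContigSet.
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' Member read ids of each contig
#' @param x a ContigSet.
#' @export
setGeneric("contigMembers", function(x) standardGeneric("contigMembers"))

#' Number of member reads per contig
#' @param x a ContigSet or CdsSet.
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname bases
#' @export
setMethod("bases", "ReadSet", function(x) x@bases)

#' @rdname quals
#' @export
setMethod("quals", "ReadSet", function(x) x@quals)

#' @describeIn ContigSet number of contigs
#' @param x a ContigSet
#' @export
setMethod("length", "ContigSet", function(x) length(x@consensus))

#' @rdname consensus
#' @export
setMethod("consensus", "ContigSet", function(x) x@consensus)

#' @rdname quals
#' @export
setMethod("quals", "ContigSet", function(x) x@quals)

#' @rdname contigMembers
#' @export
setMethod("contigMembers", "ContigSet", function(x) x@members)

#' @rdname readCounts
#' @export
setMethod("readCounts", "ContigSet", function(x)
  setNames(lengths(x@members), names(x@consensus)))

#' Transcript proteins of a TruthSet
#' @param x a TruthSet or ReferenceDb.
#' @export
setGeneric("truthProteins", function(x) standardGeneric("truthProteins"))

#' @rdname truthProteins
#' @export
setMethod("truthProteins", "TruthSet", function(x) x@protein)

#' Transcript coding sequences of a TruthSet
#' @param x a TruthSet.
#' @export
setGeneric("truthCds", function(x) standardGeneric("truthCds"))

#' @rdname truthCds
#' @export
setMethod("truthCds", "TruthSet", function(x) x@cds)

#' Full transcript sequences of a TruthSet (UTRs included)
#' @param x a TruthSet.
#' @export
setGeneric("truthTranscripts", function(x) standardGeneric("truthTranscripts"))

#' @rdname truthTranscripts
#' @export
setMethod("truthTranscripts", "TruthSet", function(x) x@transcript)

#' Transcript metadata table of a TruthSet
#'
#' @param x a TruthSet.
#' @return a data.frame with one row per transcript (id, familyId,
#'   keyword, hasSignal, cleavagePos, expressionWeight).
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname truthTable
#' @export
setMethod("truthTable", "TruthSet", function(x) {
  data.frame(id = names(x@cds), familyId = x@familyId, keyword = x@keyword,
             hasSignal = x@hasSignal, cleavagePos = x@cleavagePos,
             expressionWeight = x@expressionWeight, utr5Len = x@utr5Len,
             cdsLen = width(x@cds), transcriptLen = width(x@transcript),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @describeIn TruthSet number of transcripts
#' @param x a TruthSet
#' @export
setMethod("length", "TruthSet", function(x) length(x@cds))

#' Reference proteins
#' @param x a ReferenceDb.
#' @export
setGeneric("refProteins", function(x) standardGeneric("refProteins"))

#' @rdname refProteins
#' @export
setMethod("refProteins", "ReferenceDb", function(x) x@proteins)

#' Reference record keywords
#' @param x a ReferenceDb.
#' @return a named character vector of keyword tags.
#' @export
setGeneric("refKeywords", function(x) standardGeneric("refKeywords"))

#' @rdname refKeywords
#' @export
setMethod("refKeywords", "ReferenceDb", function(x)
  setNames(x@keyword, names(x@proteins)))

#' @describeIn ReferenceDb number of records
#' @param x a ReferenceDb
#' @export
setMethod("length", "ReferenceDb", function(x) length(x@proteins))

#' Coding sequences of a CdsSet
#' @param x a CdsSet.
#' @export
setGeneric("cdsNt", function(x) standardGeneric("cdsNt"))

#' @rdname cdsNt
#' @export
setMethod("cdsNt", "CdsSet", function(x) x@cds)

#' Deduced proteins of a CdsSet
#' @param x a CdsSet.
#' @export
setGeneric("cdsProteins", function(x) standardGeneric("cdsProteins"))

#' @rdname cdsProteins
#' @export
setMethod("cdsProteins", "CdsSet", function(x) x@protein)

#' Database hits of a CdsSet
#' @param x a CdsSet.
#' @export
setGeneric("cdsHits", function(x) standardGeneric("cdsHits"))

#' @rdname cdsHits
#' @export
setMethod("cdsHits", "CdsSet", function(x) x@hits)

#' Frameshift repair counts
#' @param x a CdsSet.
#' @export
setGeneric("nRepairs", function(x) standardGeneric("nRepairs"))

#' @rdname nRepairs
#' @export
setMethod("nRepairs", "CdsSet", function(x) setNames(x@repairs, names(x@cds)))

#' @rdname readCounts
#' @export
setMethod("readCounts", "CdsSet", function(x) setNames(x@readCount, names(x@cds)))

#' @describeIn CdsSet number of coding sequences
#' @param x a CdsSet
#' @export
setMethod("length", "CdsSet", function(x) length(x@cds))

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet of", length(object), "reads")
  if (length(object) > 0L)
    cat("; mean length", round(mean(width(object@bases)), 1), "nt")
  cat("\n")
})

setMethod("show", "ContigSet", function(object) {
  cat("ContigSet of", length(object), "contigs")
  if (length(object) > 0L) {
    rc <- lengths(object@members)
    cat("; ", sum(rc), " reads; ", sum(rc == 1L), " singletons", sep = "")
  }
  cat("\n")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet of", length(object), "transcripts in",
      length(unique(object@familyId)), "families;",
      sum(object@hasSignal), "with signal peptide\n")
})

setMethod("show", "ReferenceDb", function(object) {
  cat("ReferenceDb of", length(object), "proteins (",
      sum(object@isDecoy), "decoys )\n")
})

setMethod("show", "CdsSet", function(object) {
  cat("CdsSet of", length(object), "coding sequences;",
      sum(object@repairs > 0L), "with frameshift repairs\n")
})
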