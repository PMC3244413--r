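# Summary accounting: per-class CDS/read table, global read
# percentages, and the end-to-end pipeline orchestrator.

.classOrder <- c("S", "H", "U", "TE")
.classNames <- c(S = "Secreted", H = "Housekeeping", U = "Unknown",
                 TE = "Transposable Elements")

#' Per-class CDS and read summary table
#'
#' One row per class in the fixed order Secreted, Housekeeping,
#' Unknown, Transposable Elements, plus a totals row.  Reads/CDS and
#' the percentage of total reads are rounded half away from zero to one
#' decimal; the percentage denominator is the summed reads of all
#' classified CDS.
#'
#' @param classes character vector of per-CDS classes (values in
#'   S, H, U, TE), or the annotation data.frame from
#'   \code{\link{annotateCds}} (columns \code{class}, \code{readCount}).
#' @param readCounts numeric vector of per-CDS read counts, parallel to
#'   \code{classes} (ignored when \code{classes} is a data.frame).
#' @return data.frame with columns \code{class}, \code{nCds},
#'   \code{nReads}, \code{readsPerCds}, \code{pctOfTotalReads}; last
#'   row is the totals row.
#' @export
summarizeClasses <- function(classes, readCounts = NULL) {
  if (is.data.frame(classes)) {
    readCounts <- classes$readCount
    ids <- classes$id
    classes <- classes$class
  } else {
    ids <- names(classes)
    if (is.null(ids)) ids <- sprintf("cds%05d", seq_along(classes))
  }
  if (length(classes) != length(readCounts))
    .stopf("classes and readCounts must be parallel")
  bad <- is.na(classes) | !(classes %in% .classOrder)
  if (any(bad))
    .stopf("unclassified CDS: %s", paste(ids[bad], collapse = ", "))
  totalReads <- sum(readCounts)
  rows <- lapply(.classOrder, function(cl) {
    sel <- classes == cl
    nCds <- sum(sel)
    nReads <- sum(readCounts[sel])
    data.frame(class = unname(.classNames[cl]), nCds = nCds,
               nReads = nReads,
               readsPerCds = if (nCds > 0L)
                 roundHalfUp(nReads / nCds, 1) else NA_real_,
               pctOfTotalReads = if (totalReads > 0)
                 roundHalfUp(100 * nReads / totalReads, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(class = "Total", nCds = sum(out$nCds),
                        nReads = sum(out$nReads), readsPerCds = NA_real_,
                        pctOfTotalReads = NA_real_,
                        stringsAsFactors = FALSE))
}

#' Global read accounting
#'
#' Percentages (of all sequenced reads) captured by the long-contig
#' subset and by the extracted CDS set, and the mean read length, all
#' rounded half away from zero to integers.
#'
#' Inputs may be raw counts or the pipeline objects themselves: pass
#' either the four totals, or a \code{\linkS4class{ReadSet}} with a
#' filtered \code{\linkS4class{ContigSet}} and a
#' \code{\linkS4class{CdsSet}}.
#'
#' @param nReadsTotal total read count, or a \code{ReadSet}.
#' @param nBasesTotal total sequenced bases (ignored if a ReadSet was
#'   given).
#' @param nReadsGt149 reads contained in the length-filtered contig
#'   subset, or a \code{ContigSet}.
#' @param nReadsInCds reads contained in the extracted CDS set, or a
#'   \code{CdsSet}.
#' @return named list: \code{pctReadsGt149}, \code{pctReadsInCds},
#'   \code{meanReadLen}.
#' @export
globalReadAccounting <- function(nReadsTotal, nBasesTotal = NULL,
                                 nReadsGt149, nReadsInCds) {
  if (is(nReadsTotal, "ReadSet")) {
    nBasesTotal <- sum(width(bases(nReadsTotal)))
    nReadsTotal <- length(nReadsTotal)
  }
  if (is(nReadsGt149, "ContigSet"))
    nReadsGt149 <- sum(lengths(contigMembers(nReadsGt149)))
  if (is(nReadsInCds, "CdsSet"))
    nReadsInCds <- sum(readCounts(nReadsInCds))
  list(pctReadsGt149 = as.integer(roundHalfUp(100 * nReadsGt149 / nReadsTotal)),
       pctReadsInCds = as.integer(roundHalfUp(100 * nReadsInCds / nReadsTotal)),
       meanReadLen = as.integer(roundHalfUp(nBasesTotal / nReadsTotal)))
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#}
#' comments ignored.  Values are converted to numbers where possible.
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3L) .stopf("bad config line: %s", m[1L])
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full synthetic-to-summary pipeline
#'
#' Generates ground-truth families and 454-style reads, assembles them
#' by the decreasing word-size schedule, filters contigs, extracts
#' frameshift-repaired CDS against the reference database built from
#' the truth, classifies every CDS, clusters the deduced proteins into
#' families, and produces the summary tables.  Every stage's output is
#' returned (and written under \code{outDir} when given) together with
#' a machine-readable run log of seeds and thresholds.
#'
#' @param nFamilies,copiesPerFamily,targetAaDivergence,meanCdsLenNt,signalFraction
#'   truth-set parameters (see \code{\link{generateFamilies}}).
#' @param meanReadLen,depth,indelRate,subRate,homopolymerBias read
#'   simulator parameters (see \code{\link{simulateReads454}}).
#' @param nDecoysPerRole decoys per role in the reference database.
#' @param schedule an \code{\linkS4class{AssemblySchedule}}.
#' @param minContigLen,minReads contig filters applied before CDS
#'   extraction.
#' @param minSubjectCoverage CDS extraction coverage threshold.
#' @param rules classification rules table.
#' @param clusterThresholdPct identity threshold for the family
#'   clustering of deduced proteins.
#' @param seed master RNG seed (stage seeds are derived from it).
#' @param outDir optional output directory for all artifact files.
#' @return list with elements \code{truth}, \code{reads},
#'   \code{origins}, \code{refdb}, \code{contigs}, \code{filtered},
#'   \code{cds}, \code{annotation}, \code{families},
#'   \code{classSummary}, \code{accounting}, \code{runLog}.
#' @export
runPipeline <- function(nFamilies = 20L, copiesPerFamily = 3L,
                        targetAaDivergence = 0.2, meanCdsLenNt = 450L,
                        signalFraction = 0.5,
                        meanReadLen = 344L, depth = 15, indelRate = 0.01,
                        subRate = 0.005, homopolymerBias = 2,
                        nDecoysPerRole = 2L,
                        schedule = assemblySchedule(),
                        minContigLen = 150L, minReads = 5L,
                        minSubjectCoverage = 0.5,
                        rules = defaultRules(),
                        clusterThresholdPct = 40L,
                        seed = 1L, outDir = NULL) {
  seed <- as.integer(seed)
  truth <- generateFamilies(nFamilies, copiesPerFamily, targetAaDivergence,
                            meanCdsLenNt, signalFraction, seed = seed)
  sim <- simulateReads454(truth, meanReadLen = meanReadLen, depth = depth,
                          indelRate = indelRate, subRate = subRate,
                          homopolymerBias = homopolymerBias,
                          seed = seed + 1L)
  refdb <- makeReferenceDb(truth, nDecoysPerRole = nDecoysPerRole,
                           seed = seed + 2L)
  contigs <- iterativeClusterize(sim$reads, schedule)
  filtered <- filterContigs(contigs, minLenNt = minContigLen,
                            minReads = minReads)
  cds <- extractAllCds(filtered, refdb,
                       minSubjectCoverage = minSubjectCoverage)
  annotation <- annotateCds(cds, refdb, rules = rules)
  families <- if (length(cds) > 0L) {
    clusterAt(setNames(as.character(cdsProteins(cds)), names(cdsNt(cds))),
              readCounts(cds), thresholdPct = clusterThresholdPct)
  } else {
    NULL
  }
  classSummary <- if (nrow(annotation) > 0L) summarizeClasses(annotation)
                  else NULL
  accounting <- globalReadAccounting(sim$reads, nReadsGt149 = filtered,
                                     nReadsInCds = cds)
  runLog <- list(package = as.character(packageVersion("SialoKit")),
                 seed = seed,
                 wordSizes = schedule@wordSizes,
                 minContigLen = minContigLen, minReads = minReads,
                 minSubjectCoverage = minSubjectCoverage,
                 clusterThresholdPct = clusterThresholdPct,
                 nReads = length(sim$reads),
                 nContigs = length(contigs),
                 nFiltered = length(filtered),
                 nCds = length(cds))
  out <- list(truth = truth, reads = sim$reads, origins = sim$origins,
              refdb = refdb, contigs = contigs, filtered = filtered,
              cds = cds, annotation = annotation, families = families,
              classSummary = classSummary, accounting = accounting,
              runLog = runLog)
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

#' Write all pipeline artifacts to a directory
#'
#' @param result list from \code{\link{runPipeline}}.
#' @param outDir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outDir, ...)
  writeFastaQual(result$reads, fp("reads.fasta"), fp("reads.qual"))
  writeTruthTable(result$truth, fp("truth.tsv"))
  write.table(result$origins, fp("read_origins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeReferenceDb(result$refdb, fp("refdb.fasta"))
  writeFastaQual(result$contigs, fp("contigs.fasta"), fp("contigs.qual"))
  writeMembershipTable(result$contigs, fp("contig_members.tsv"))
  if (length(result$cds) > 0L) {
    writeXStringSet(cdsNt(result$cds), fp("cds_nt.fasta"))
    writeXStringSet(cdsProteins(result$cds), fp("cds_protein.fasta"))
    write.table(cdsHits(result$cds), fp("cds_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (nrow(result$annotation) > 0L)
    write.table(result$annotation, fp("annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(result$families))
    writeClusterTable(result$families, fp("families.tsv"))
  if (!is.null(result$classSummary))
    write.table(result$classSummary, fp("class_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  logLines <- vapply(names(result$runLog), function(k)
    sprintf("%s = %s", k, paste(result$runLog[[k]], collapse = ",")), "")
  writeLines(logLines, fp("run_log.txt"))
  invisible(outDir)
}
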