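# FASTA + sibling qual file input/output (454 dialect: whitespace
# separated integer phreds under the same ids, in the same order) and
# the tab-separated export tables.

#' Write reads or contigs as FASTA plus sibling qual file
#'
#' @param x a \code{\linkS4class{ReadSet}} or \code{\linkS4class{ContigSet}}.
#' @param fastaPath output FASTA path.
#' @param qualPath output qual path; integer phreds, whitespace
#'   separated, same ids and order as the FASTA.
#' @return invisibly, the two paths.
#' @export
writeFastaQual <- function(x, fastaPath, qualPath) {
  seqs <- if (is(x, "ReadSet")) bases(x) else consensus(x)
  qs <- quals(x)
  writeXStringSet(seqs, filepath = fastaPath)
  con <- file(qualPath, open = "wt")
  on.exit(close(con))
  ids <- names(seqs)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    writeLines(paste(qs[[i]], collapse = " "), con)
  }
  invisible(c(fastaPath, qualPath))
}

#' Read FASTA plus sibling qual file into a ReadSet
#'
#' @param fastaPath FASTA path.
#' @param qualPath qual path (whitespace separated integer phreds); if
#'   NULL a flat phred 30 profile is assumed.
#' @return a \code{\linkS4class{ReadSet}}.
#' @export
readFastaQual <- function(fastaPath, qualPath = NULL) {
  seqs <- readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(qualPath)) return(ReadSet(seqs))
  lines <- readLines(qualPath)
  hdr <- grepl("^>", lines)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  grp <- cumsum(hdr)
  body <- tapply(lines[!hdr], grp[!hdr], paste, collapse = " ")
  quals <- lapply(body, function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1L]]))
  names(quals) <- ids
  if (!identical(ids, names(seqs)))
    .stopf("qual file ids do not match FASTA ids")
  ReadSet(seqs, quals)
}

#' Write the contig membership table
#'
#' Tab-separated: contig id, read count, comma-joined member read ids.
#'
#' @param contigs a \code{\linkS4class{ContigSet}}.
#' @param path output path.
#' @export
writeMembershipTable <- function(contigs, path) {
  df <- data.frame(contig = names(consensus(contigs)),
                   read_count = unname(readCounts(contigs)),
                   reads = vapply(contigMembers(contigs), paste,
                                  character(1L), collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a protein reference database as annotated FASTA
#'
#' Headers carry the keyword tag and decoy flag as
#' \code{id keyword=<tag> decoy=<0|1>}, parseable by
#' \code{\link{readReferenceDb}}.
#'
#' @param db a \code{\linkS4class{ReferenceDb}}.
#' @param path output FASTA path.
#' @export
writeReferenceDb <- function(db, path) {
  seqs <- refProteins(db)
  names(seqs) <- sprintf("%s keyword=%s decoy=%d", names(seqs),
                         db@keyword, as.integer(db@isDecoy))
  writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read an annotated protein reference database
#'
#' @param path FASTA path written by \code{\link{writeReferenceDb}}.
#' @return a \code{\linkS4class{ReferenceDb}}.
#' @export
readReferenceDb <- function(path) {
  seqs <- readAAStringSet(path)
  hdr <- names(seqs)
  ids <- sub("\\s.*$", "", hdr)
  kw <- sub(".*keyword=(.*) decoy=.*", "\\1", hdr)
  decoy <- sub(".*decoy=([01]).*", "\\1", hdr) == "1"
  names(seqs) <- ids
  new("ReferenceDb", proteins = seqs, keyword = kw, isDecoy = decoy)
}

#' Write the truth transcript table
#'
#' Tab-separated with a header line; one row per ground-truth transcript.
#'
#' @param truth a \code{\linkS4class{TruthSet}}.
#' @param path output path.
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truthTable(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
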