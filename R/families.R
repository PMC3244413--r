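# Progressive identity-threshold protein family clustering, abundance
# ranking and family labels, and gene-count estimation from amino-acid
# divergence.

#' Pairwise protein identity and coverage
#'
#' Global alignment with free end gaps (BLOSUM62); identity is the
#' fraction of matching columns among aligned columns (terminal free
#' gaps excluded, internal gaps count as mismatches), coverage is the
#' aligned span over the length of the longer sequence.
#'
#' @param a,b amino-acid strings.
#' @return named numeric vector \code{c(identity=, coverage=)}.
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a)[[1L]]; b <- as.character(b)[[1L]]
  if (nchar(a) == 0L || nchar(b) == 0L) .stopf("empty protein")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  aln <- pairwiseAlignment(pattern = a, subject = b, type = "overlap",
                           substitutionMatrix = B62,
                           gapOpening = 10, gapExtension = 0.5)
  cols <- nchar(as.character(pattern(aln)))
  if (cols == 0L) return(c(identity = 0, coverage = 0))
  c(identity = nmatch(aln) / cols,
    coverage = cols / max(nchar(a), nchar(b)))
}

#' Pairwise identity/coverage matrices for a protein set
#'
#' @param proteins named character vector or \code{AAStringSet}.
#' @return list of two symmetric matrices, \code{identity} and
#'   \code{coverage}, with unit diagonal.
#' @export
identityMatrix <- function(proteins) {
  if (is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  n <- length(proteins)
  ids <- names(proteins)
  if (is.null(ids)) .stopf("proteins must be named")
  idm <- diag(1, n); cov <- diag(1, n)
  dimnames(idm) <- dimnames(cov) <- list(ids, ids)
  if (n >= 2L) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    B62 <- get("BLOSUM62", envir = environment())
    for (i in seq_len(n - 1L)) {
      js <- (i + 1L):n
      aln <- pairwiseAlignment(pattern = AAStringSet(proteins[js]),
                               subject = proteins[[i]], type = "overlap",
                               substitutionMatrix = B62,
                               gapOpening = 10, gapExtension = 0.5)
      cols <- nchar(as.character(pattern(aln)))
      idv <- ifelse(cols > 0L, nmatch(aln) / cols, 0)
      cv <- ifelse(cols > 0L,
                   cols / pmax(nchar(proteins[js]), nchar(proteins[[i]])), 0)
      idm[i, js] <- idv; idm[js, i] <- idv
      cov[i, js] <- cv; cov[js, i] <- cv
    }
  }
  list(identity = idm, coverage = cov)
}

#' Single-linkage family clustering at an identity threshold
#'
#' Two proteins are linked when their pairwise identity is at least
#' \code{thresholdPct} percent over at least \code{minCoverage} of the
#' length of the longer sequence; families are the connected
#' components.  Clusters are ranked by total member read count
#' (descending, ties by smallest member id) and labelled
#' \code{"<threshold>-<rank>"}, so e.g. the 33rd most abundant cluster
#' at the 40\% level is \code{"40-33"}.
#'
#' @param proteins named character vector or \code{AAStringSet}.
#' @param readCounts named numeric vector of member read counts
#'   (defaults to 1 per protein).
#' @param thresholdPct identity threshold in percent (1-100).
#' @param minCoverage minimum aligned coverage of the longer sequence.
#' @param mat optional precomputed result of
#'   \code{\link{identityMatrix}} (reused across a threshold sweep).
#' @return data.frame with one row per cluster: \code{threshold},
#'   \code{rank}, \code{label}, \code{nMembers}, \code{totalReads},
#'   \code{members} (comma-joined ids).
#' @export
clusterAt <- function(proteins, readCounts = NULL, thresholdPct,
                      minCoverage = 0.5, mat = NULL) {
  if (is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  if (thresholdPct < 1 || thresholdPct > 100)
    .stopf("thresholdPct must lie in [1, 100]")
  ids <- names(proteins)
  if (is.null(readCounts)) readCounts <- setNames(rep(1, length(ids)), ids)
  if (is.null(mat)) mat <- identityMatrix(proteins)
  link <- mat$identity >= thresholdPct / 100 & mat$coverage >= minCoverage
  n <- length(ids)
  edges <- which(link & upper.tri(link), arr.ind = TRUE)
  comp <- .componentsFromGroups(n, split(c(edges), rep(seq_len(nrow(edges)), 2L)))
  groups <- split(ids, comp)
  totReads <- vapply(groups, function(g) sum(readCounts[g]), 0)
  minId <- vapply(groups, min, "")
  o <- order(-totReads, minId)
  groups <- groups[o]; totReads <- totReads[o]
  data.frame(threshold = thresholdPct, rank = seq_along(groups),
             label = sprintf("%d-%d", as.integer(thresholdPct),
                             seq_along(groups)),
             nMembers = lengths(groups), totalReads = unname(totReads),
             members = vapply(groups, paste, "", collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Progressive clustering sweep over identity thresholds
#'
#' Runs \code{\link{clusterAt}} over a vector of thresholds (default
#' every integer from 25 to 99 percent), computing the pairwise
#' identity matrix once.  Because linkage is single, clusters at a
#' higher threshold always refine those at a lower one.
#'
#' @inheritParams clusterAt
#' @param thresholds integer vector of identity thresholds (percent).
#' @return data.frame of all clusters (rows of \code{\link{clusterAt}}
#'   across thresholds).
#' @export
clusterSweep <- function(proteins, readCounts = NULL,
                         thresholds = 25:99, minCoverage = 0.5) {
  mat <- identityMatrix(proteins)
  do.call(rbind, lapply(thresholds, function(t)
    clusterAt(proteins, readCounts, t, minCoverage, mat = mat)))
}

#' Estimate the number of genes behind a protein family
#'
#' Counts single-linkage clusters at the 80\% identity level: sequences
#' more than 20\% divergent at the amino-acid level are taken to derive
#' from different genes, while members within a cluster are interpreted
#' as alleles or near-identical copies.
#'
#' @param members named character vector or \code{AAStringSet} of the
#'   family's proteins.
#' @param identityPct identity threshold (percent) above which members
#'   are treated as the same gene.
#' @param minCoverage minimum aligned coverage of the longer sequence.
#' @return positive integer gene-count estimate.
#' @export
estimateGeneCount <- function(members, identityPct = 80, minCoverage = 0.5) {
  if (is(members, "AAStringSet"))
    members <- setNames(as.character(members), names(members))
  if (length(members) == 0L) .stopf("empty member set")
  if (is.null(names(members)))
    names(members) <- sprintf("m%03d", seq_along(members))
  nrow(clusterAt(members, thresholdPct = identityPct,
                 minCoverage = minCoverage))
}

#' Write a family cluster table
#'
#' Tab-separated: threshold, label, member count, total reads,
#' comma-joined member ids.
#'
#' @param clusters data.frame from \code{\link{clusterAt}} or
#'   \code{\link{clusterSweep}}.
#' @param path output path.
#' @export
writeClusterTable <- function(clusters, path) {
  write.table(clusters, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
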