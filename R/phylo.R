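# Progressive multiple alignment, p-distance matrices, neighbor-joining
# trees, bootstrap supports and supported-clade counting.

#' Progressive multiple protein alignment
#'
#' Guide order from average-linkage clustering of pairwise identities;
#' profiles are merged by globally aligning their consensus sequences
#' (BLOSUM62, free internal gaps) and propagating the resulting gap
#' pattern to every member row.  Deterministic for a fixed input.
#'
#' @param proteins named character vector or \code{AAStringSet} (>= 1).
#' @return an aligned \code{AAStringSet} (rows padded with \code{-}).
#' @export
progressiveAlign <- function(proteins) {
  if (is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  n <- length(proteins)
  if (n == 0L) .stopf("no sequences to align")
  if (is.null(names(proteins)))
    names(proteins) <- sprintf("s%03d", seq_len(n))
  if (n == 1L) return(AAStringSet(proteins))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  profCons <- function(rows) {
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    apply(m, 2L, function(col) {
      col <- col[col != "-"]
      if (length(col) == 0L) return("X")
      tb <- sort(table(col), decreasing = TRUE)
      names(tb)[1L]
    })
  }
  mergeProfiles <- function(pa, pb) {
    ca <- paste(profCons(pa), collapse = "")
    cb <- paste(profCons(pb), collapse = "")
    aln <- pairwiseAlignment(pattern = ca, subject = cb, type = "global",
                             substitutionMatrix = B62,
                             gapOpening = 10, gapExtension = 0.5)
    A <- .chars(as.character(pattern(aln)))
    B <- .chars(as.character(subject(aln)))
    expand <- function(rows, tmpl) {
      vapply(rows, function(r) {
        ch <- .chars(r); p <- 0L
        paste(vapply(tmpl, function(t) {
          if (t == "-") "-" else { p <<- p + 1L; ch[p] }
        }, ""), collapse = "")
      }, "", USE.NAMES = TRUE)
    }
    c(expand(pa, A), expand(pb, B))
  }
  if (n == 2L) {
    msa <- mergeProfiles(proteins[1L], proteins[2L])
    return(AAStringSet(msa[names(proteins)]))
  }
  im <- identityMatrix(proteins)$identity
  hc <- hclust(as.dist(1 - im), method = "average")
  profiles <- lapply(seq_along(proteins), function(i) proteins[i])
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0L) profiles[[-v]] else merged[[v]]
    merged[[k]] <- mergeProfiles(pick(hc$merge[k, 1L]),
                                 pick(hc$merge[k, 2L]))
  }
  msa <- merged[[nrow(hc$merge)]]
  AAStringSet(msa[names(proteins)])
}

#' Pairwise p-distance matrix from an alignment
#'
#' The p-distance between two rows is the fraction of differing
#' residues over the columns where both rows are non-gap.  Pairs with
#' no shared columns get distance 1.
#'
#' @param msa aligned \code{AAStringSet} or named character vector of
#'   equal-length gapped strings.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pdistanceMatrix <- function(msa) {
  if (is(msa, "AAStringSet"))
    msa <- setNames(as.character(msa), names(msa))
  n <- length(msa)
  if (n == 0L) .stopf("empty alignment")
  if (length(unique(nchar(msa))) != 1L)
    .stopf("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- m[i, ] != "-" & m[j, ] != "-"
        d[i, j] <- d[j, i] <- if (!any(ok)) 1 else
          mean(m[i, ok] != m[j, ok])
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining on a distance matrix; recovers the
#' generating tree exactly on additive distances.
#'
#' @param d symmetric distance matrix (or \code{dist}) over >= 3 taxa.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) .stopf("neighbor joining needs at least 3 leaves")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- sprintf("t%d", seq_len(nrow(d)))
  ape::nj(as.dist(d))
}

#' Bootstrap supports for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' from the p-distances of each replicate, and reports for each
#' internal edge of the original tree the percentage of replicates
#' containing the same bipartition.  Supports are stored as internal
#' node labels.
#'
#' @param msa aligned \code{AAStringSet} (or gapped character vector).
#' @param nReplicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @return the NJ tree of the full alignment with node labels set to
#'   integer support percentages (root label empty).
#' @export
bootstrapSupport <- function(msa, nReplicates = 1000L, seed = 1L) {
  if (is(msa, "AAStringSet"))
    msa <- setNames(as.character(msa), names(msa))
  if (length(msa) < 3L) .stopf("need at least 3 sequences")
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  ref <- njTree(pdistanceMatrix(msa))
  L <- ncol(m)
  boots <- .withSeed(seed, {
    lapply(seq_len(nReplicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      mm <- m[, cols, drop = FALSE]
      rows <- setNames(apply(mm, 1L, paste, collapse = ""), rownames(m))
      njTree(pdistanceMatrix(rows))
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / nReplicates))
  lab <- as.character(support)
  lab[1L] <- ""   # root of the (arbitrarily rooted) stored topology
  ref$node.label <- lab
  ref
}

#' Count supported clades
#'
#' Counts maximal internal edges whose bootstrap support is strictly
#' greater than \code{minSupportPct} and whose leafward side contains
#' at least \code{minSize} leaves; a supported clade nested inside
#' another supported clade is represented by its outermost ancestor
#' only, so members are never double-counted.
#'
#' @param tree \code{ape::phylo} with numeric internal node labels as
#'   produced by \code{\link{bootstrapSupport}}.
#' @param minSupportPct support threshold in percent (strict).
#' @param minSize minimum number of leaves in a counted clade.
#' @return list with \code{count} and \code{clades} (list of leaf-label
#'   character vectors of the maximal supported clades).
#' @export
countSupportedClades <- function(tree, minSupportPct, minSize = 2L) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) .stopf("tree has no support labels")
  support <- suppressWarnings(as.numeric(lab))
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tipsUnder <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tipsUnder))
  }
  supported <- function(node) {
    node != root && !is.na(support[node - ntip]) &&
      support[node - ntip] > minSupportPct
  }
  clades <- list()
  walk <- function(node) {
    if (node <= ntip) return(invisible())
    if (supported(node)) {
      tips <- tipsUnder(node)
      if (length(tips) >= minSize) {
        clades[[length(clades) + 1L]] <<- tips
        return(invisible())   # maximality: do not descend further
      }
    }
    for (k in kids[[as.character(node)]]) walk(k)
    invisible()
  }
  walk(root)
  list(count = length(clades), clades = clades)
}
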