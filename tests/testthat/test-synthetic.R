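test_that("zero divergence yields identical family members with distinct ids", {
  t0 <- generateFamilies(2, 3, targetAaDivergence = 0, meanCdsLenNt = 300,
                         signalFraction = 0, seed = 3)
  prot <- as.character(truthProteins(t0))
  tt <- truthTable(t0)
  for (f in unique(tt$familyId)) {
    members <- prot[tt$familyId == f]
    expect_length(unique(unname(members)), 1L)
  }
  t1 <- generateFamilies(5, 1, targetAaDivergence = 0.1,
                         meanCdsLenNt = 300, seed = 4)
  expect_length(truthCds(t1), 5L)
  expect_length(unique(truthTable(t1)$familyId), 5L)
})

test_that("coding sequences translate to the stated proteins, no internal stop", {
  t0 <- generateFamilies(4, 2, 0.2, meanCdsLenNt = 450, seed = 11)
  cds <- as.character(truthCds(t0))
  prot <- as.character(truthProteins(t0))
  expect_true(all(nchar(cds) %% 3 == 0))
  for (i in seq_along(cds)) {
    expect_identical(oracleTranslate(cds[[i]]), prot[[i]])
  }
  expect_false(any(grepl("*", prot, fixed = TRUE)))
})

test_that("rejects coding lengths not divisible by 3", {
  expect_error(generateFamilies(1, 1, meanCdsLenNt = 301, seed = 1),
               "divisible by 3")
  expect_error(generateFamilies(1, 1, targetAaDivergence = 1, seed = 1))
})

test_that("realized within-family divergence approximates the target", {
  # independent check by pairwise alignment of the generated proteins
  t0 <- generateFamilies(6, 4, targetAaDivergence = 0.20,
                         meanCdsLenNt = 600, signalFraction = 0.5, seed = 7)
  tt <- truthTable(t0)
  prot <- as.character(truthProteins(t0))
  pd <- c()
  for (f in unique(tt$familyId)) {
    m <- prot[tt$familyId == f]
    for (i in 1:(length(m) - 1)) for (j in (i + 1):length(m)) {
      aln <- Biostrings::pairwiseAlignment(m[i], m[j], type = "global",
                                           substitutionMatrix = blosum62,
                                           gapOpening = 10, gapExtension = 0.5)
      cols <- nchar(as.character(Biostrings::pattern(aln)))
      pd <- c(pd, 1 - Biostrings::nmatch(aln) / cols)
    }
  }
  expect_gt(mean(pd), 0.15)
  expect_lt(mean(pd), 0.25)
})

test_that("generator output is deterministic and byte-identical for a fixed seed", {
  a <- generateFamilies(3, 2, 0.2, 300, 0.5, seed = 42)
  b <- generateFamilies(3, 2, 0.2, 300, 0.5, seed = 42)
  expect_identical(as.character(truthCds(a)), as.character(truthCds(b)))
  sa <- simulateReads454(a, 200, depth = 4, seed = 9)
  sb <- simulateReads454(b, 200, depth = 4, seed = 9)
  fa <- tempfile(); qa <- tempfile(); fb <- tempfile(); qb <- tempfile()
  writeFastaQual(sa$reads, fa, qa)
  writeFastaQual(sb$reads, fb, qb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(readLines(qa), readLines(qb))
})

test_that("error-free reads are exact substrings of their source transcript", {
  t0 <- generateFamilies(3, 2, 0.1, 450, 0.5, seed = 5)
  sim <- simulateReads454(t0, 300, depth = 3, indelRate = 0, subRate = 0,
                          seed = 6)
  txs <- as.character(truthTranscripts(t0))
  b <- as.character(bases(sim$reads))
  for (i in seq_along(b)) {
    o <- sim$origins[i, ]
    src <- txs[[o$transcriptId]]
    hit <- grepl(b[i], src, fixed = TRUE) ||
      grepl(revcompChr(b[i]), src, fixed = TRUE)
    expect_true(hit)
    # the recorded origin window reproduces the read exactly
    expect_identical(substr(src, o$start, o$end),
                     if (o$strand == "+") b[[i]] else revcompChr(b[[i]]))
  }
})

test_that("read origins are a total accounting and lengths match the target", {
  t0 <- generateFamilies(4, 2, 0.2, 900, 0.5, seed = 21)
  sim <- simulateReads454(t0, 344, depth = 25, indelRate = 0, subRate = 0,
                          seed = 22)
  expect_identical(nrow(sim$origins), length(sim$reads))
  expect_identical(sort(sim$origins$readId), sort(names(bases(sim$reads))))
  n <- length(sim$reads)
  expect_gte(n, 400L)  # depth 25 over 8 ~1 kb transcripts at 344 nt/read
  lens <- sim$origins$end - sim$origins$start + 1L
  se <- sd(lens) / sqrt(n)
  expect_lt(abs(mean(lens) - 344), 3 * se)
})

test_that("planted indel counts follow the configured rate (no homopolymer bias)", {
  t0 <- generateFamilies(3, 2, 0.2, 900, 0.5, seed = 31)
  sim <- simulateReads454(t0, 344, depth = 20, indelRate = 0.01,
                          subRate = 0, homopolymerBias = 0, seed = 32)
  B <- sum(sim$origins$end - sim$origins$start + 1L)
  planted <- sum(sim$origins$nIns + sim$origins$nDel)
  expect_lt(abs(planted - B * 0.01), 4 * sqrt(B * 0.01))
})

test_that("degenerate read simulations fail loudly", {
  t0 <- generateFamilies(1, 1, 0, 300, 0, seed = 1)
  expect_error(simulateReads454(t0, meanReadLen = 5000, seed = 1),
               "exceeds the shortest")
  expect_error(simulateReads454(t0, meanReadLen = 100, depth = 1e-9,
                                seed = 1), "zero reads")
})

test_that("reference database carries truth proteins verbatim plus tagged decoys", {
  t0 <- generateFamilies(3, 1, 0, 300, 0.5, seed = 13)
  db0 <- makeReferenceDb(t0, nDecoysPerRole = 0, seed = 14)
  expect_identical(as.character(refProteins(db0)),
                   as.character(truthProteins(t0)))
  db <- makeReferenceDb(t0, nDecoysPerRole = 2, roles = "transposase",
                        seed = 14)
  kw <- refKeywords(db)
  expect_identical(sum(kw == "transposase" & db@isDecoy), 2L)
  expect_error(makeReferenceDb(t0, 1, roles = character(0)), "nonempty")
  # round trip through annotated FASTA
  p <- tempfile(fileext = ".fasta")
  writeReferenceDb(db, p)
  back <- readReferenceDb(p)
  expect_identical(refKeywords(back), refKeywords(db))
  expect_identical(as.character(refProteins(back)),
                   as.character(refProteins(db)))
})

test_that("every truth protein's best self-search hit is itself at full identity", {
  t0 <- generateFamilies(3, 1, 0, 300, 0.5, seed = 17)
  db <- makeReferenceDb(t0, nDecoysPerRole = 1, seed = 18)
  cds <- setNames(as.character(truthCds(t0)), names(truthCds(t0)))
  hsps <- searchTranslated(cds, db)
  for (id in names(cds)) {
    h <- hsps[hsps$queryId == id, ]
    top <- h[which.max(h$score), ]
    expect_identical(top$subjectId, id)
    expect_identical(top$identities, top$sEnd - top$sStart)
    expect_identical(top$sEnd - top$sStart,
                     nchar(as.character(truthProteins(t0))[[id]]))
  }
})

test_that("hierarchical gene families hit their divergence design", {
  g <- generateGeneFamilies(3, 3, withinDivergence = 0.10,
                            betweenDivergence = 0.40, lengthAa = 200,
                            seed = 8)
  expect_length(g$proteins, 9L)
  m <- identityMatrix(g$proteins)$identity
  within <- c(); between <- c()
  for (i in 1:8) for (j in (i + 1):9) {
    d <- 1 - m[i, j]
    if (g$geneId[i] == g$geneId[j]) within <- c(within, d)
    else between <- c(between, d)
  }
  expect_lt(mean(within), 0.2)
  expect_gt(mean(between), 0.3)
})
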