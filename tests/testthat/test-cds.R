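test_that("six-frame translation matches a table-driven oracle", {
  expect_identical(unname(sixFrameTranslate("ATG")["+1"]), "M")
  expect_identical(unname(sixFrameTranslate("CAT")["-1"]), "M")
  expect_error(sixFrameTranslate("AT"), "shorter")
  set.seed(3)
  s <- randomDna(300)
  tr <- sixFrameTranslate(s)
  rc <- revcompChr(s)
  expect_identical(unname(tr[["+1"]]), oracleTranslate(s))
  expect_identical(unname(tr[["+2"]]), oracleTranslate(substr(s, 2, 300)))
  expect_identical(unname(tr[["+3"]]), oracleTranslate(substr(s, 3, 300)))
  expect_identical(unname(tr[["-1"]]), oracleTranslate(rc))
  expect_identical(unname(tr[["-2"]]), oracleTranslate(substr(rc, 2, 300)))
  expect_identical(unname(tr[["-3"]]), oracleTranslate(substr(rc, 3, 300)))
  # N codons become X
  expect_identical(unname(sixFrameTranslate("ATGNNNTGA")["+1"]), "MX*")
})

test_that("Met-started segments respect the search window", {
  seg <- metSegments(c(f = "MAAA*"))
  expect_identical(seg$peptide, "MAAA")
  # Met beyond the window is not a start
  far <- paste0(strrep("A", 300), "MKKK")
  expect_identical(nrow(metSegments(c(f = far), windowAa = 300)), 0L)
  expect_identical(metSegments(c(f = far), windowAa = 301)$peptide, "MKKK")
  two <- metSegments(c(f = "MAMW*"))
  expect_identical(two$peptide, c("MAMW", "MW"))
  expect_true(endsWith(two$peptide[1], two$peptide[2]))
})

test_that("an exact in-frame encoding is found at full coverage and identity", {
  t0 <- generateFamilies(2, 1, 0, 300, 1, seed = 61)
  db <- makeReferenceDb(t0, 0, seed = 62)
  id <- names(truthCds(t0))[1]
  h <- searchTranslated(setNames(as.character(truthCds(t0))[1], id), db)
  top <- h[1, ]
  L <- nchar(as.character(truthProteins(t0))[[id]])
  expect_identical(top$subjectId, id)
  expect_identical(c(top$sStart, top$sEnd), c(0L, L))
  expect_identical(top$identities, L)
  expect_identical(top$frame, 1L)
})

test_that("toy HSP scores equal a brute-force ungapped local alignment", {
  set.seed(71)
  for (rep in 1:12) {
    prot <- randomProtein(10)
    qprot <- randomProtein(10)
    # encode the query protein so frame +1 carries it
    nt <- paste(vapply(strsplit(qprot, "")[[1]], function(a) {
      cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
      cods[1]
    }, ""), collapse = "")
    db <- new("ReferenceDb",
              proteins = Biostrings::AAStringSet(c(p1 = prot)),
              keyword = "x", isDecoy = FALSE)
    h <- searchTranslated(c(q = nt), db, minScore = 1)
    got <- if (nrow(h) == 0) 0 else max(h$score)
    frames <- sixFrameTranslate(nt)
    want <- max(vapply(frames[nchar(frames) > 0], function(f)
      oracleUngappedLocal(f, prot, blosum62), 0))
    if (want >= 1) expect_equal(got, want) else expect_identical(nrow(h), 0L)
  }
})

test_that("random nucleotide queries score below the reporting threshold", {
  set.seed(81)
  db <- new("ReferenceDb",
            proteins = Biostrings::AAStringSet(
              setNames(vapply(1:5, function(i) randomProtein(150), ""),
                       sprintf("d%d", 1:5))),
            keyword = rep("x", 5), isDecoy = rep(TRUE, 5))
  h <- searchTranslated(setNames(vapply(1:5, function(i) randomDna(300), ""),
                                 sprintf("q%d", 1:5)), db)
  expect_identical(nrow(h), 0L)
})

test_that("significance surrogate is monotone decreasing in score", {
  sc <- seq(20, 200, by = 5)
  ev <- SialoKit:::.evalueLike(sc, 150, 200)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev >= 0))
})

test_that("exact contigs extract unmodified coding sequences with zero repairs", {
  t0 <- generateFamilies(3, 1, 0, 450, 0.5, seed = 91)
  db <- makeReferenceDb(t0, 1, seed = 92)
  cdsStr <- as.character(truthCds(t0))
  cs <- extractAllCds(asContigSet(cdsStr), db)
  expect_length(cs, 3L)
  expect_identical(unname(as.character(cdsNt(cs))), unname(cdsStr))
  expect_identical(unname(nRepairs(cs)), rep(0L, 3))
  expect_identical(unname(as.character(cdsProteins(cs))),
                   unname(as.character(truthProteins(t0))))
})

test_that("planted single indels are repaired and translation stays in frame", {
  t0 <- generateFamilies(6, 1, 0, 450, 0.5, seed = 95)
  db <- makeReferenceDb(t0, 0, seed = 96)
  cdsStr <- as.character(truthCds(t0))
  prots <- as.character(truthProteins(t0))
  set.seed(97)
  for (i in seq_along(cdsStr)) {
    s <- cdsStr[[i]]
    mid <- sample(seq(60L, nchar(s) - 60L), 1)
    mode <- if (i %% 2 == 0) "del" else "ins"
    mut <- if (mode == "del") {
      paste0(substr(s, 1, mid - 1), substr(s, mid + 1, nchar(s)))
    } else {
      paste0(substr(s, 1, mid), "A", substr(s, mid + 1, nchar(s)))
    }
    cset <- extractAllCds(asContig(mut), db)
    expect_length(cset, 1L)
    expect_identical(unname(nRepairs(cset)), 1L)
    p <- as.character(cdsProteins(cset))[[1]]
    rg <- cset@alignedRanges[[1]]
    # no stop inside aligned regions
    for (r in seq_len(nrow(rg)))
      expect_false(grepl("*", substr(p, rg[r, 1], rg[r, 2]), fixed = TRUE))
    # identity to truth outside a <=2 residue window at the repair
    expect_identical(repairViolations(p, prots[[i]], rg), integer(0))
  }
})

test_that("mixed strands and out-of-order chains are rejected", {
  chain <- data.frame(queryId = "q", db = "ref", subjectId = "s",
                      frame = c(1L, -2L), qStart = c(0L, 100L),
                      qEnd = c(90L, 190L), sStart = c(0L, 40L),
                      sEnd = c(30L, 70L), identities = c(30L, 30L),
                      score = c(100, 100), evalue = c(1e-20, 1e-20))
  expect_error(extractCds(randomDna(300), chain, randomProtein(80)),
               "strand")
  chain$frame <- c(1L, 2L)
  chain$sStart <- c(40L, 0L); chain$sEnd <- c(70L, 30L)
  expect_error(extractCds(randomDna(300), chain, randomProtein(80)),
               "out-of-order")
})

test_that("coverage and significance tallies use strict and inclusive bounds", {
  mkCds <- function(hits) {
    new("CdsSet", cds = Biostrings::DNAStringSet(),
        protein = Biostrings::AAStringSet(), contigId = character(0),
        readCount = integer(0), repairs = integer(0), hits = hits,
        alignedRanges = list())
  }
  empty <- mkCds(data.frame(id = character(0), db = character(0),
                            subject = character(0), coverage = numeric(0),
                            evalue = numeric(0), score = numeric(0)))
  expect_identical(coverageTally(empty),
                   c(nHighCoverage = 0L, nLowEvalue = 0L))
  h <- data.frame(id = c("a", "b", "c"), db = "ref", subject = "s",
                  coverage = c(0.75, 0.76, 0.9),
                  evalue = c(1e-15, 1e-14, 1e-30), score = 100)
  tal <- coverageTally(mkCds(h))
  expect_identical(unname(tal["nHighCoverage"]), 2L)  # 0.75 is not > 0.75
  expect_identical(unname(tal["nLowEvalue"]), 2L)     # 1e-15 is <= 1e-15
})
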