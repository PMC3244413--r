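test_that("signal peptide heuristic follows the leader grammar", {
  lead <- paste0("M", strrep("L", 12), "AGA", randomProtein(60))
  got <- predictSignalPeptide(lead)
  expect_true(got$flag)
  expect_identical(got$cleavagePos, 14L)  # first small residue after core
  charged <- paste0("M", strrep("D", 20), randomProtein(40))
  expect_false(predictSignalPeptide(charged)$flag)
  expect_error(predictSignalPeptide(""), "empty")
})

test_that("planted signals are recovered with high sensitivity and specificity", {
  t0 <- generateFamilies(40, 2, 0.2, 450, signalFraction = 0.5, seed = 111)
  tt <- truthTable(t0)
  called <- vapply(as.character(truthProteins(t0)),
                   function(p) predictSignalPeptide(p)$flag, TRUE)
  sens <- mean(called[tt$hasSignal])
  spec <- mean(!called[!tt$hasSignal])
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("membrane helix counting scans after the cleavage site", {
  expect_identical(countTmHelices(strrep("D", 100)), 0L)
  sig <- paste0("M", strrep("L", 12), "AG")
  expect_identical(countTmHelices(paste0(sig, strrep("D", 60)),
                                  cleavagePos = 14L), 0L)
  withTm <- paste0(strrep("D", 30), strrep("L", 23), strrep("D", 30))
  expect_gte(countTmHelices(withTm), 1L)
})

test_that("O-glycosylation counting needs local S/T/P density", {
  expect_identical(countOglycSites(strrep("ADGH", 20)), 0L)
  expect_identical(countOglycSites("SSSSSSSSSSS"), 11L)
  oneT <- paste0(strrep("A", 20), "T", strrep("A", 20))
  expect_identical(countOglycSites(oneT), 0L)
})

test_that("furin sites match R-X-[KR]-R including overlaps", {
  expect_identical(findFurinSites("AARAKRAA"), 6L)
  expect_identical(findFurinSites("AAAADEDE"), integer(0))
  expect_identical(findFurinSites("RKRRKRR"), c(4L, 6L, 7L))
})

test_that("classifier precedence follows the documented rule order", {
  rules <- defaultRules()
  mkHits <- function(kw, ev) data.frame(db = "ref", subject = "s",
                                        keyword = kw, evalue = ev,
                                        coverage = 0.9)
  sigProt <- paste0("M", strrep("L", 12), "AG", randomProtein(100))
  # transposase beats everything but contaminants, even with a signal
  ev <- gatherEvidence(sigProt, mkHits("transposase", 1e-40))
  expect_identical(classifyEvidence(ev, rules)$topClass, "TE")
  # contaminant wins over transposase
  ev2 <- gatherEvidence(sigProt, mkHits("transposase", 1e-40),
                        contaminantHit = "rRNA")
  got2 <- classifyEvidence(ev2, rules)
  expect_identical(got2$topClass, "H")
  expect_identical(got2$subcategory, "rRNA-mito")
  # signal + secreted keyword
  ev3 <- gatherEvidence(sigProt, mkHits("kunitz", 1e-30))
  got3 <- classifyEvidence(ev3, rules)
  expect_identical(got3$topClass, "S")
  expect_identical(got3$subcategory, "protease inhibitor - Kunitz")
  # signal + no informative hit at all
  ev4 <- gatherEvidence(sigProt, mkHits("hypothetical", 1))
  got4 <- classifyEvidence(ev4, rules)
  expect_identical(got4$topClass, "S")
  expect_identical(got4$subcategory, "putative secreted, unknown family")
  # signal + informative housekeeping hit falls through to H
  ev5 <- gatherEvidence(sigProt, mkHits("ribosomal protein", 1e-30))
  expect_identical(classifyEvidence(ev5, rules)$topClass, "H")
  # nothing informative, no signal: unknown
  noSig <- paste0("M", strrep("D", 30), randomProtein(60))
  ev6 <- gatherEvidence(noSig, mkHits("hypothetical", 1))
  expect_identical(classifyEvidence(ev6, rules)$topClass, "U")
  expect_error(classifyEvidence(ev6, rules[0, ]), "empty")
})

test_that("classification is independent of database order", {
  rules <- defaultRules()
  sigProt <- paste0("M", strrep("L", 12), "AG", randomProtein(80))
  hits <- data.frame(db = c("nr", "sprot", "tick"),
                     subject = c("a", "b", "c"),
                     keyword = c("kunitz", "ribosomal protein", "serpin"),
                     evalue = c(1e-30, 1e-10, 1e-20), coverage = 0.9)
  base <- classifyEvidence(gatherEvidence(sigProt, hits), rules)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    got <- classifyEvidence(gatherEvidence(sigProt, hits[perm, ]), rules)
    expect_identical(got$topClass, base$topClass)
    expect_identical(got$subcategory, base$subcategory)
  }
})

test_that("TE and S are never confused when keyword tags are unambiguous", {
  t0 <- generateFamilies(12, 2, 0.15, 450, signalFraction = 0.5,
                         seed = 121, teFraction = 0.5)
  tt <- truthTable(t0)
  rules <- defaultRules()
  for (i in seq_len(nrow(tt))) {
    hits <- data.frame(db = "ref", subject = tt$id[i],
                       keyword = tt$keyword[i], evalue = 1e-40,
                       coverage = 1)
    got <- classifyEvidence(gatherEvidence(
      as.character(truthProteins(t0))[[i]], hits), rules)
    if (tt$keyword[i] == "transposase") {
      expect_identical(got$topClass, "TE")
    } else if (tt$hasSignal[i]) {
      expect_identical(got$topClass, "S")
    } else {
      expect_false(got$topClass %in% c("TE", "S"))
    }
  }
})

test_that("rules tables round-trip and reject unknown classes", {
  p <- tempfile(fileext = ".tsv")
  writeRules(defaultRules(), p)
  back <- readRules(p)
  expect_identical(back$keyword, defaultRules()$keyword)
  bad <- defaultRules()
  bad$class[1] <- "Z"
  writeRules(bad, p)
  expect_error(readRules(p), "unknown class")
})

test_that("contaminant screen flags contigs sharing words with the contaminant set", {
  contam <- simulateContaminants(1, 1, 600, seed = 33)
  clean <- randomDna(300)
  dirty <- paste0(randomDna(50), substr(as.character(contam)[[1]], 100, 300),
                  randomDna(50))
  cs <- asContigSet(c(clean, dirty))
  calls <- detectContaminant(cs, contam, wordSize = 40)
  expect_true(is.na(calls[["ctg00001"]]))
  expect_identical(unname(calls[["ctg00002"]]), "rRNA")
})
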