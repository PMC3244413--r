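test_that("pairwise identity handles identical, disjoint and offset pairs", {
  p <- randomProtein(40)
  got <- pairwiseIdentity(p, p)
  expect_equal(unname(got["identity"]), 1)
  expect_equal(unname(got["coverage"]), 1)
  a <- strrep("AC", 10); b <- strrep("WY", 10)
  expect_equal(unname(pairwiseIdentity(a, b)["identity"]), 0)
  # free end gaps: a proper suffix aligns at full identity, partial coverage
  got2 <- pairwiseIdentity("MKLVWHHEDY", "KLVWHHEDY")
  expect_equal(unname(got2["identity"]), 1)
  expect_equal(unname(got2["coverage"]), 0.9)
  # equal-length substitution-only toys equal direct mismatch counting
  set.seed(131)
  for (rep in 1:5) {
    x <- randomProtein(30)
    y <- x
    flip <- sample(30, 6)
    ych <- strsplit(y, "")[[1]]
    for (f in flip) ych[f] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      ych[f])[1]
    y <- paste(ych, collapse = "")
    got <- pairwiseIdentity(x, y)
    expect_equal(unname(got["identity"]), 1 - 6 / 30, tolerance = 1e-12)
  }
})

test_that("single-linkage clustering equals the connected-components oracle", {
  set.seed(141)
  for (rep in 1:8) {
    g <- generateGeneFamilies(sample(2:4, 1), sample(2:3, 1),
                              withinDivergence = 0.08,
                              betweenDivergence = runif(1, 0.3, 0.6),
                              lengthAa = 120, seed = 1000 + rep)
    prots <- setNames(as.character(g$proteins), names(g$proteins))
    m <- identityMatrix(prots)
    for (thr in c(40, 60, 80)) {
      got <- clusterAt(prots, thresholdPct = thr, mat = m)
      gotGroups <- lapply(strsplit(got$members, ","), sort)
      want <- oracleComponents(m$identity, m$coverage, thr, 0.5)
      expect_identical(sort(vapply(gotGroups, paste, "", collapse = ",")),
                       sort(vapply(lapply(want, sort), paste, "",
                                   collapse = ",")))
    }
  }
})

test_that("clusters are ranked by read mass and labelled threshold-rank", {
  set.seed(151)
  # unrelated proteins so every cluster is a singleton
  prots <- setNames(vapply(1:35, function(i) randomProtein(80), ""),
                    sprintf("p%02d", 1:35))
  counts <- setNames(seq(3500, 100, by = -100), names(prots))
  cl <- clusterAt(prots, counts, thresholdPct = 40)
  expect_identical(nrow(cl), 35L)
  expect_identical(cl$label[33], "40-33")
  expect_identical(cl$members[33], "p33")
  expect_true(all(diff(cl$totalReads) <= 0))
  one <- clusterAt(setNames(rep(randomProtein(50), 3), c("a", "b", "c")),
                   thresholdPct = 99)
  expect_identical(nrow(one), 1L)
  expect_identical(one$label, "99-1")
  expect_error(clusterAt(prots, counts, thresholdPct = 0), "\\[1, 100\\]")
})

test_that("threshold sweep is nested: higher thresholds refine lower ones", {
  g <- generateGeneFamilies(4, 3, 0.10, 0.45, 130, seed = 161)
  sweep <- clusterSweep(g$proteins, thresholds = seq(25, 99, by = 6))
  thr <- sort(unique(sweep$threshold))
  for (k in seq_along(thr)[-1]) {
    lo <- strsplit(sweep$members[sweep$threshold == thr[k - 1]], ",")
    hi <- strsplit(sweep$members[sweep$threshold == thr[k]], ",")
    for (h in hi) {
      inside <- vapply(lo, function(l) all(h %in% l), TRUE)
      expect_identical(sum(inside), 1L)
    }
  }
})

test_that("gene counts come from the >20% divergence rule", {
  p <- randomProtein(100)
  expect_identical(estimateGeneCount(c(a = p, b = p, c = p)), 1L)
  # two sequences at ~50% identity are different genes
  q <- strsplit(p, "")[[1]]
  flip <- sample(100, 50)
  for (f in flip) q[f] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                  q[f])[1]
  expect_identical(estimateGeneCount(c(a = p, b = paste(q, collapse = ""))),
                   2L)
  expect_error(estimateGeneCount(character(0)), "empty")
})

test_that("gene-count estimates recover planted gene numbers and ignore duplicates", {
  set.seed(171)
  hits <- 0
  for (rep in 1:10) {
    nG <- sample(2:6, 1)
    g <- generateGeneFamilies(nG, sample(2:3, 1), 0.10, 0.40, 150,
                              seed = 2000 + rep)
    if (estimateGeneCount(g$proteins) == nG) hits <- hits + 1
    # duplicating any member never changes the estimate
    p <- setNames(as.character(g$proteins), names(g$proteins))
    dup <- c(p, setNames(p[1], "dup1"))
    expect_identical(estimateGeneCount(dup), estimateGeneCount(p))
  }
  expect_gte(hits, 9L)
})
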