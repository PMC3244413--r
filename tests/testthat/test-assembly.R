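test_that("shared-word grouping handles the basic cases", {
  s <- randomDna(250)
  g <- sharedWordGroups(c(a = s, b = s), 200)
  expect_identical(partitionKey(g), "a,b")
  # too short to contain a word of 200
  g2 <- sharedWordGroups(c(a = randomDna(150), b = randomDna(150)), 200)
  expect_identical(partitionKey(g2), c("a", "b"))
  expect_identical(sharedWordGroups(character(0), 40), list())
  expect_error(sharedWordGroups(c(x = "ACGTU"), 4), "x")
  expect_error(sharedWordGroups(c(x = "ACGT"), 3), "at least 4")
})

test_that("reverse-complement words connect sequences across strands", {
  set.seed(21)
  s <- randomDna(120)
  g <- sharedWordGroups(c(f = s, r = revcompChr(s)), 60)
  expect_identical(partitionKey(g), "f,r")
  g1 <- sharedWordGroups(c(f = s, r = revcompChr(s)), 60, bothStrands = FALSE)
  expect_length(g1, 2L)
})

test_that("shared-word partition equals the brute-force oracle and ignores order", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    w <- sample(c(20L, 40L, 90L), 1)
    seqs <- setNames(vapply(seq_len(n), function(i) randomDna(300), ""),
                     sprintf("s%02d", seq_len(n)))
    # plant some shared words
    core <- randomDna(w)
    for (k in sample(n, min(5, n))) {
      s <- seqs[[k]]
      pos <- sample(nchar(s) - w, 1)
      substr(s, pos, pos + w - 1) <- core
      seqs[[k]] <- s
    }
    got <- sharedWordGroups(seqs, w)
    want <- oracleSharedGroups(seqs, w)
    expect_identical(partitionKey(got), partitionKey(want))
    shuf <- sample(seqs)
    expect_identical(partitionKey(sharedWordGroups(shuf, w)),
                     partitionKey(got))
  }
})

test_that("identical reads collapse to one contig equal to the read", {
  set.seed(5)
  s <- randomDna(300)
  reads <- ReadSet(setNames(rep(s, 5), sprintf("r%d", 1:5)))
  ct <- assembleGroup(reads)
  expect_length(ct, 1L)
  expect_identical(as.character(consensus(ct))[[1]], s)
  expect_identical(unname(readCounts(ct)), 5L)
  expect_setequal(contigMembers(ct)[[1]], sprintf("r%d", 1:5))
})

test_that("two overlapping reads merge into a contig of the combined length", {
  set.seed(6)
  full <- randomDna(500)
  reads <- ReadSet(c(r1 = substr(full, 1, 300), r2 = substr(full, 201, 500)))
  ct <- assembleGroup(reads, minOverlapNt = 40)
  expect_length(ct, 1L)
  expect_identical(nchar(as.character(consensus(ct))[[1]]), 500L)
  expect_identical(as.character(consensus(ct))[[1]], full)
})

test_that("consensus takes the higher-phred base at a disagreeing column", {
  set.seed(7)
  s <- randomDna(200)
  s2 <- s
  substr(s2, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s, 100, 100))[1]
  reads <- ReadSet(c(hi = s2, lo = s),
                   quals = list(rep(40L, 200), rep(10L, 200)))
  ct <- assembleGroup(reads)
  expect_length(ct, 1L)
  expect_identical(substr(as.character(consensus(ct))[[1]], 100, 100),
                   substr(s2, 100, 100))
})

test_that("reverse-complement reads assemble with forward reads", {
  set.seed(8)
  full <- randomDna(400)
  reads <- ReadSet(c(f = substr(full, 1, 250),
                     r = revcompChr(substr(full, 151, 400))))
  ct <- assembleGroup(reads)
  expect_length(ct, 1L)
  cons <- as.character(consensus(ct))[[1]]
  expect_true(cons == full || cons == revcompChr(full))
})

test_that("iterative clusterization conserves reads and never splits", {
  t0 <- generateFamilies(4, 2, 0.2, 450, 0.5, seed = 51)
  sim <- simulateReads454(t0, 300, depth = 6, indelRate = 0.01,
                          subRate = 0.005, seed = 52)
  ct <- iterativeClusterize(sim$reads)
  got <- sort(unname(unlist(contigMembers(ct))))
  expect_identical(got, sort(names(bases(sim$reads))))
  # re-running the final consensuses at word 40 cannot increase contigs
  reads2 <- ReadSet(consensus(ct), quals(ct))
  ct2 <- iterativeClusterize(reads2, assemblySchedule(wordSizes = 40L))
  expect_lte(length(ct2), length(ct))
  # empty input
  expect_length(iterativeClusterize(ReadSet(Biostrings::DNAStringSet())), 0L)
})

test_that("contig filters enforce the >149 nt and read-support thresholds", {
  cs <- new("ContigSet",
            consensus = Biostrings::DNAStringSet(
              c(a = randomDna(149), b = randomDna(150), c = randomDna(400))),
            quals = list(a = rep(30L, 149), b = rep(30L, 150),
                         c = rep(30L, 400)),
            members = list(a = sprintf("x%d", 1:9), b = sprintf("y%d", 1:4),
                           c = sprintf("z%d", 1:5)))
  f1 <- filterContigs(cs, minLenNt = 150, minReads = 1)
  expect_identical(names(consensus(f1)), c("c", "b"))  # 149 nt excluded
  f2 <- filterContigs(cs, minLenNt = 0, minReads = 5)
  expect_identical(names(consensus(f2)), c("a", "c")) # 4 reads excluded
  f3 <- filterContigs(cs, minLenNt = 0, minReads = 0)
  expect_length(f3, 3L)
  expect_identical(names(consensus(f3))[1], "a")      # ordered by reads
})

test_that("assembly schedule validates its invariants", {
  expect_error(assemblySchedule(wordSizes = c(40, 90)), "nonincreasing")
  expect_error(assemblySchedule(minOverlapIdentity = 1.5), "\\(0, 1\\]")
  s <- assemblySchedule()
  expect_identical(s@wordSizes, c(200L, 134L, 90L, 60L, 40L, 40L))
  expect_identical(s@maxMatchesPerQuery, 1000L)
})
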