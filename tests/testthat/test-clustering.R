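# vOTU clustering, prokaryotic dereplication, protein clustering.

test_that("greedy vOTU clustering joins near-identical genomes only", {
  set.seed(10)
  A <- rseq(10000)
  B <- mutateExactly(A, 300)   # 97% ANI to A
  C <- rseq(10000)
  g <- Biostrings::DNAStringSet(c(A = A, B = B, C = C))
  cl <- clusterViralPopulations(g)
  map <- clusterMap(cl)
  expect_equal(unname(map["B"]), unname(map["A"]))
  expect_false(unname(map["C"]) == unname(map["A"]))
  expect_equal(length(unique(map)), 2L)
})

test_that("both thresholds must hold: ANI 96 with AF 50 stays separate", {
  set.seed(11)
  A <- rseq(10000)
  halfB <- mutateExactly(substr(A, 1, 5000), 200)  # 96% over half of A
  B <- paste0(halfB, rseq(5000))
  aa <- computeAniAf(A, B)
  expect_gt(aa$ani, 95)
  expect_lt(aa$af, 85)
  cl <- clusterViralPopulations(Biostrings::DNAStringSet(c(A = A, B = B)))
  expect_equal(length(unique(cl$representative)), 2L)
})

test_that("identical genomes collapse to one cluster and empty input is empty", {
  x <- rseq(10000, seed = 12)
  g <- Biostrings::DNAStringSet(stats::setNames(rep(x, 4), paste0("g", 1:4)))
  cl <- clusterViralPopulations(g)
  expect_equal(length(unique(cl$representative)), 1L)
  expect_equal(nrow(clusterViralPopulations(Biostrings::DNAStringSet())), 0L)
})

test_that("clustering is invariant to input order and members meet thresholds", {
  sq <- tinySeqs()
  g <- sq$viruses
  cl1 <- clusterViralPopulations(g)
  set.seed(13)
  cl2 <- clusterViralPopulations(g[sample(length(g))])
  m1 <- clusterMap(cl1); m2 <- clusterMap(cl2)
  expect_true(partitionAgreement(m1, m2[names(m1)])$identical)
  # brute-force check: every member satisfies both thresholds vs its rep
  seqs <- as.character(g)
  mem <- cl1[cl1$member != cl1$representative, ]
  for (i in seq_len(nrow(mem))) {
    aa <- computeAniAf(seqs[[mem$member[i]]], seqs[[mem$representative[i]]])
    expect_gte(aa$ani, 95)
    expect_gte(aa$af, 85)
  }
})

test_that("single-linkage option groups the same near-identical pairs", {
  set.seed(14)
  A <- rseq(10000)
  g <- Biostrings::DNAStringSet(c(A = A, B = mutateExactly(A, 200),
                                  C = rseq(10000)))
  cl <- clusterViralPopulations(g, linkage = "single")
  map <- clusterMap(cl)
  expect_equal(unname(map["A"]), unname(map["B"]))
  expect_equal(length(unique(map)), 2L)
})

test_that("prokaryote dereplication picks the completeness - 4x contamination winner", {
  set.seed(15)
  X <- rseq(12000)
  Y <- mutateExactly(X, 120)  # 99% ANI, full AF
  g <- Biostrings::DNAStringSet(c(X = X, Y = Y))
  cl <- dereplicateProkaryoteGenomes(g, completeness = c(X = 90, Y = 95),
                                     contamination = c(X = 2, Y = 10))
  expect_equal(length(unique(cl$representative)), 1L)
  expect_equal(unique(cl$representative), "X")  # 82 beats 55
  expect_equal(sort(cl$score), c(55, 82))
})

test_that("AF below 70 keeps prokaryote genomes in separate populations", {
  set.seed(16)
  X <- rseq(10000)
  Y <- paste0(mutateExactly(substr(X, 1, 6000), 60), rseq(4000))  # AF ~60
  g <- Biostrings::DNAStringSet(c(X = X, Y = Y))
  cl <- dereplicateProkaryoteGenomes(g, completeness = c(X = 90, Y = 90),
                                     contamination = c(X = 1, Y = 1))
  expect_equal(length(unique(cl$representative)), 2L)
})

test_that("dereplication validates quality fields and handles singletons", {
  g <- Biostrings::DNAStringSet(c(X = rseq(10000, seed = 17)))
  expect_error(dereplicateProkaryoteGenomes(g), "completeness")
  cl <- dereplicateProkaryoteGenomes(g, completeness = c(X = 80),
                                     contamination = c(X = 3))
  expect_equal(cl$representative, "X")
})

test_that("protein clustering follows the 60% identity / 80% coverage rule", {
  p1 <- raa(100, seed = 18)
  ident <- Biostrings::AAStringSet(c(a = p1, b = p1))
  expect_equal(length(unique(clusterProteins(ident)$representative)), 1L)
  # ~50% identity over full length: below threshold
  set.seed(19)
  ch <- strsplit(p1, "")[[1L]]
  pos <- sample(100, 50)
  ch[pos] <- vapply(ch[pos], function(a)
    setdiff(c("A", "L", "V", "G"), a)[1L], "")
  p2 <- paste(ch, collapse = "")
  two <- clusterProteins(Biostrings::AAStringSet(c(a = p1, b = p2)))
  expect_equal(length(unique(two$representative)), 2L)
  # exact 70-aa fragment: identity and coverage of the shorter are 100%
  frag <- substr(p1, 16, 85)
  one <- clusterProteins(Biostrings::AAStringSet(c(a = p1, b = frag)))
  expect_equal(length(unique(one$representative)), 1L)
  expect_equal(unique(one$representative), "a")  # longest-first
})
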