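# CRISPR detection, spacer matching, homology and prophage linkage,
# population-level aggregation.

makeArray <- function(repSeq, spacers) {
  paste0(repSeq, paste0(spacers, repSeq, collapse = ""))
}

test_that("a constructed CRISPR array yields exactly its spacers, in order", {
  set.seed(30)
  repSeq <- rseq(30)
  spacers <- c(rseq(35), rseq(35), rseq(35))
  left <- rseq(700); right <- rseq(700)
  scaf <- paste0(left, makeArray(repSeq, spacers), right)
  res <- detectCrisprArrays(scaf, scaffoldId = "sc1")
  expect_equal(nrow(res), 3L)
  expect_equal(res$spacer_seq, spacers)
  expect_equal(res$spacer_index, 1:3)
  # 0-based half-open coordinates slice the spacer back out
  for (i in 1:3)
    expect_equal(substr(scaf, res$start[i] + 1, res$end[i]), spacers[i])
})

test_that("random sequence and two-repeat layouts yield no array", {
  expect_equal(nrow(detectCrisprArrays(rseq(10000, seed = 31))), 0L)
  set.seed(32)
  repSeq <- rseq(30)
  two <- paste0(rseq(500), repSeq, rseq(35), repSeq, rseq(500))
  expect_equal(nrow(detectCrisprArrays(two)), 0L)
  expect_equal(nrow(detectCrisprArrays(rseq(100, seed = 33))), 0L)
})

test_that("spacer matching is exact, full-length, and strand-aware", {
  set.seed(34)
  vir <- Biostrings::DNAStringSet(c(v1 = rseq(10000), v2 = rseq(10000)))
  spacer <- substr(as.character(vir[["v1"]]), 501, 535)
  hits <- matchSpacers(c(sp1 = spacer), vir)
  expect_equal(hits$virus, "v1")
  # one substitution defeats the zero-mismatch rule
  mut <- mutateExactly(spacer, 1)
  expect_equal(nrow(matchSpacers(c(sp = mut), vir)), 0L)
  # reverse complement matches by default, not with forward-only
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spacer)))
  expect_equal(matchSpacers(c(sp = rc), vir)$virus, "v1")
  expect_equal(nrow(matchSpacers(c(sp = rc), vir, bothStrands = FALSE)), 0L)
  expect_warning(matchSpacers(c(sp = "ACGTACGTACGT"), vir), "rejected")
})

test_that("spacer matching is strand-symmetric over whole genome sets", {
  set.seed(35)
  vir <- Biostrings::DNAStringSet(
    stats::setNames(vapply(1:3, function(i) rseq(5000), ""),
                    paste0("v", 1:3)))
  spacers <- c(a = substr(as.character(vir[[1]]), 101, 135),
               b = substr(as.character(vir[[3]]), 4001, 4040))
  h1 <- matchSpacers(spacers, vir)
  h2 <- matchSpacers(spacers, Biostrings::reverseComplement(vir))
  expect_equal(h1[order(h1$spacer_seq), c("spacer_seq", "virus")],
               h2[order(h2$spacer_seq), c("spacer_seq", "virus")],
               ignore_attr = TRUE)
})

test_that("genome-homology linkage applies all four thresholds", {
  base <- data.frame(qseqid = "v", sseqid = "h", pident = 85, length = 3000,
                     mismatch = 450, gapopen = 0, qstart = 1, qend = 3000,
                     sstart = 1, send = 3000, evalue = 1e-20,
                     bitscore = 2000)
  expect_equal(nrow(linkByGenomeHomology(base)), 1L)
  for (mod in list(c("length", 2000), c("pident", 65),
                   c("evalue", 1e-2), c("bitscore", 40))) {
    h <- base
    h[[mod[1]]] <- as.numeric(mod[2])
    expect_equal(nrow(linkByGenomeHomology(h)), 0L)
  }
  # duplicate hits collapse to one pair
  expect_equal(nrow(linkByGenomeHomology(rbind(base, base))), 1L)
  expect_equal(nrow(linkByGenomeHomology(base[0, ])), 0L)
  bad <- base; bad$pident <- NA
  expect_error(linkByGenomeHomology(bad), "malformed")
  expect_error(linkByGenomeHomology(base[, 1:3]), "missing")
})

test_that("prophage provenance links provirus to its binned scaffold", {
  vm <- data.frame(id = c("vPro", "vFree", "vLost"),
                   source_scaffold = c("scf1", NA, "scfX"))
  bins <- data.frame(scaffold = c("scf1", "scf2"),
                     host_genome = c("magA", "magB"))
  expect_warning(res <- linkByProphageOrigin(vm, bins), "unbinned")
  expect_equal(res, data.frame(virus = "vPro", host = "magA"),
               ignore_attr = TRUE)
  none <- linkByProphageOrigin(vm[2, , drop = FALSE], bins)
  expect_equal(nrow(none), 0L)
})

test_that("population aggregation unions evidence and counts support", {
  pairs <- data.frame(
    virus = c("v1", "v2", "v1", "v1"),
    host = c("h1", "h2", "h1", "h2"),
    evidence = c("homology", "homology", "crispr", "homology"))
  votu <- c(v1 = "V", v2 = "V")
  hp <- c(h1 = "H", h2 = "H")
  res <- aggregatePopulationLinks(pairs, votu, hp)
  expect_equal(nrow(res), 1L)
  expect_equal(res$evidence, "crispr+homology")
  expect_equal(res$support, 3L)  # distinct genome pairs behind the link
  expect_lte(nrow(res), nrow(unique(pairs[c("virus", "host")])))
  expect_equal(nrow(aggregatePopulationLinks(pairs[0, ], votu, hp)), 0L)
  expect_error(aggregatePopulationLinks(pairs, votu[1], hp), "missing")
})

test_that("planted arrays in simulated hosts are recovered exactly", {
  sq <- tinySeqs()
  found <- extractSpacers(sq$hosts)
  planted <- sq$spacers
  expect_equal(nrow(found), nrow(planted))
  key <- function(d) sort(paste(d$host_scaffold, d$spacer_seq))
  expect_equal(key(found), key(planted))
})
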