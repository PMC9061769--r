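# Synthetic-data generator: configuration, sequences, ecology, round-trip.

test_that("configuration invariants are enforced", {
  expect_error(simConfig(genome_length_range = c(5000, 9000)), "10000")
  expect_error(simConfig(divergence_levels = c(0.03, 0.6)), "0.5")
  expect_error(simConfig(divergence_levels = -0.1), "0.5")
  expect_error(simConfig(prophage_fraction = 1.2), "proportions")
  expect_error(simConfig(noise_sd = -1), "non-negative")
  expect_error(simConfig(planted_vhr = c(-1, 2)), "positive")
  expect_warning(simConfig(divergence_levels = 0.45), "background")
})

test_that("same configuration gives a byte-identical dataset", {
  cfg <- tinyConfig(seed = 21)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- writeDataset(simulateDataset(cfg), d1)
  m2 <- writeDataset(simulateDataset(cfg), d2)
  expect_equal(m1$md5, m2$md5)
  # manifest checksum changes iff content changes
  f <- file.path(d2, "metadata.tsv")
  writeLines(c(readLines(f), "tampered"), f)
  m3 <- tools::md5sum(f)
  expect_false(unname(m3) == m2$md5[m2$file == "metadata.tsv"])
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted prophages are exact embedded copies at recorded coordinates", {
  sq <- tinySeqs()
  pro <- sq$truth$prophages
  expect_gt(nrow(pro), 0)
  hosts <- as.character(sq$hosts)
  vir <- as.character(sq$viruses)
  for (i in seq_len(nrow(pro))) {
    emb <- substr(hosts[[pro$host_scaffold[i]]],
                  pro$start[i] + 1, pro$end[i])
    expect_identical(emb, vir[[pro$virus[i]]])
    expect_lte(pro$end[i], nchar(hosts[[pro$host_scaffold[i]]]))
  }
})

test_that("empirical ANI of simulated pairs is within 1 point of 100(1 - d)", {
  sq <- tinySeqs()
  cfg <- tinyConfig()
  vir <- as.character(sq$viruses)
  for (cl in sq$truth$clusters) {
    anc <- vir[[cl$ancestor]]
    for (k in seq_along(cfg$divergence_levels)) {
      copy <- vir[[cl$members[k + 1L]]]
      ani <- 100 * sum(charToRaw(anc) == charToRaw(copy)) / nchar(anc)
      expect_lt(abs(ani - 100 * (1 - cfg$divergence_levels[k])), 1)
    }
  }
})

test_that("divergence 0 plants an identical duplicate in the same vOTU", {
  cfg <- tinyConfig(seed = 5)
  cfg$divergence_levels <- c(0, 0.10)
  sq <- simulateSequences(cfg)
  cl <- sq$truth$clusters[[1]]
  vir <- as.character(sq$viruses)
  expect_identical(vir[[cl$members[2]]], vir[[cl$ancestor]])
  memb <- sq$truth$votu_membership
  expect_equal(unname(memb[cl$members[2]]), unname(memb[cl$ancestor]))
  expect_false(unname(memb[cl$members[3]]) == unname(memb[cl$ancestor]))
})

test_that("crispr_fraction 0 plants no repeat-spacer arrays", {
  cfg <- tinyConfig(seed = 6, crispr_fraction = 0)
  sq <- simulateSequences(cfg)
  expect_equal(nrow(sq$spacers), 0L)
  expect_equal(nrow(extractSpacers(sq$hosts)), 0L)
  expect_false(any(grepl("crispr", sq$truth$links$evidence)))
})

test_that("noise-free one-to-one communities reproduce planted VHRs exactly", {
  cfg <- simConfig(seed = 31, n_sites = 3, samples_per_site = 2,
                   n_host_phyla = 2, hosts_per_phylum = 1,
                   noise_sd = 0, lat_richness_gradient = 0,
                   n_background_viruses = 0,
                   divergence_levels = 0.03)
  sq <- simulateSequences(cfg)
  eco <- simulateEcology(cfg, sq)
  links <- unique(sq$truth$links[c("virus_population", "host_population")])
  links$host_population <-
    unname(sq$truth$host_representative[links$host_population])
  pm <- sq$truth$phylum_map
  res <- lineageVhr(eco$virusAbundance, eco$hostAbundance, links, pm)
  for (ph in res$phylum) {
    expect_equal(res$mean_log10_vhr[res$phylum == ph],
                 log10(cfg$planted_vhr[[ph]]), tolerance = 1e-10)
  }
  expect_equal(unname(eco$truth$true_mean_log10_vhr[res$phylum]),
               unname(res$mean_log10_vhr), tolerance = 1e-10)
})

test_that("a zero target slope yields a flat distance-decay relationship", {
  cfg <- tinyConfig(seed = 41, ddr_slope = 0, noise_sd = 0.2)
  sq <- tinySeqs()
  eco <- simulateEcology(cfg, sq)
  va <- t(abundance(eco$virusAbundance))
  bc <- communityDissimilarity(communityTransform(va, "hellinger"),
                               "bray_curtis")
  co <- eco$metadata[, c("lat", "lon")]
  rownames(co) <- eco$metadata$sample
  f <- fitDistanceDecay(geographicDistance(co), bc)
  ov <- f$fits[f$fits$scale == "overall", ]
  expect_lt(abs(ov$slope), 2 * ov$slope_se + 0.02)
})

test_that("richness declines away from the equatorward edge", {
  cfg <- simConfig(seed = 51, lat_richness_gradient = 1.5, noise_sd = 0.1)
  sq <- simulateSequences(cfg)
  eco <- simulateEcology(cfg, sq)
  rich <- colSums(abundance(eco$hostAbundance) > 0)
  expect_lt(cor(eco$metadata$lat, rich), -0.5)
})

test_that("planted structural-equation edges are recovered by OLS", {
  spec <- readPathSpec(c("MAT -> host_abundance 0.9"))
  dat <- simulatePathData(spec, n = 500, seed = 61)
  b <- unname(coef(lm(host_abundance ~ MAT, dat))[2])
  expect_equal(b, 0.9, tolerance = 0.05 / 0.9)
})

test_that("datasets round-trip: FASTA byte-exact, truth and matrices preserved", {
  cfg <- tinyConfig(seed = 71)
  ds <- simulateDataset(cfg)
  dir <- file.path(tempdir(), "roundtrip")
  writeDataset(ds, dir)
  back <- readDataset(dir)
  expect_identical(as.character(back$viruses),
                   as.character(ds$sequences$viruses))
  expect_identical(as.character(back$hosts),
                   as.character(ds$sequences$hosts))
  expect_equal(unlist(as.list(ds$sequences$truth$votu_membership)),
               back$truth$votu_membership)
  expect_equal(abundance(back$virusAbundance),
               abundance(ds$ecology$virusAbundance), tolerance = 1e-9)
  # depth tracks reproduce the abundance matrix through the coverage path
  cov <- coverageFromDepthRuns(back$depthRuns)
  am <- buildAbundanceMatrix(cov, back$librarySizes)
  vir <- intersect(rownames(abundance(am)),
                   rownames(abundance(back$virusAbundance)))
  expect_equal(abundance(am)[vir, ],
               abundance(back$virusAbundance)[vir, ], tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("unwritable output directories raise an I/O error", {
  ds <- simulateDataset(tinyConfig(seed = 81))
  target <- "/proc/no_such_dir/x"
  suppressWarnings(expect_error(writeDataset(ds, target)))
})
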