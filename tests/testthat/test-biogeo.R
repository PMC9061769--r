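# Transforms, dissimilarities, geographic distance, PCoA, Mantel,
# FDR-controlled correlations, distance-decay regression.

test_that("hellinger and standardize transforms follow their formulas", {
  h <- communityTransform(rbind(s1 = c(1, 3)), "hellinger")
  expect_equal(unname(h[1, ]), c(0.5, sqrt(0.75)), tolerance = 1e-6)
  onehot <- rbind(s1 = c(0, 1, 0))
  expect_equal(unname(communityTransform(onehot, "hellinger")[1, ]),
               c(0, 1, 0))
  zero <- rbind(s1 = c(0, 0), s2 = c(1, 1))
  expect_equal(unname(communityTransform(zero, "hellinger")[1, ]), c(0, 0))
  z <- communityTransform(cbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                          "standardize")
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  expect_equal(mean(z[, "a"]), 0)
  expect_equal(sd(z[, "a"]), 1)
  expect_error(communityTransform(rbind(c(-1, 2)), "hellinger"),
               "non-negative")
})

test_that("Bray-Curtis follows its formula and edge conventions", {
  m <- rbind(s1 = c(1, 2), s2 = c(2, 1), s3 = c(1, 2))
  d <- as.matrix(communityDissimilarity(m, "bray_curtis"))
  expect_equal(d["s1", "s2"], 1 / 3, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  disj <- rbind(a = c(2, 0), b = c(0, 2))
  expect_equal(as.vector(communityDissimilarity(disj, "bray_curtis")), 1)
  zz <- rbind(a = c(0, 0), b = c(0, 0))
  expect_warning(dz <- communityDissimilarity(zz, "bray_curtis"),
                 "all-zero")
  expect_equal(as.vector(dz), 0)
})

test_that("geographic distance is haversine on a 6371 km sphere", {
  co <- data.frame(lat = c(0, 1), lon = c(0, 0),
                   row.names = c("a", "b"))
  d <- as.matrix(geographicDistance(co))
  expect_equal(d["a", "b"], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(d["a", "a"], 0)
  set.seed(70)
  co2 <- data.frame(lat = runif(5, -60, 60), lon = runif(5, -170, 170))
  m <- as.matrix(geographicDistance(co2))
  expect_equal(m, t(m))
  expect_error(geographicDistance(data.frame(lat = 95, lon = 0)), "range")
})

test_that("PCoA recovers collinear configurations and distances", {
  x <- c(0, 1, 3)
  d <- dist(x)
  dm <- as.matrix(d)
  rownames(dm) <- colnames(dm) <- letters[1:3]
  res <- pcoaOrdination(dm)
  expect_equal(as.vector(dist(res$coordinates[, 1])), as.vector(d),
               tolerance = 1e-8)
  expect_lt(max(abs(res$eigenvalues[-1])), 1e-8)
  # reconstruction for a Euclidean-embeddable matrix
  set.seed(71)
  pts <- matrix(rnorm(20), 5, 4)
  rownames(pts) <- paste0("s", 1:5)
  d2 <- dist(pts)
  r2 <- pcoaOrdination(d2)
  expect_equal(as.matrix(dist(r2$coordinates)), as.matrix(d2),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: the largest loading on each axis is positive
  expect_true(all(apply(r2$coordinates, 2, function(v)
    v[which.max(abs(v))] > 0)))
  # agreement with classical scaling up to sign
  cs <- cmdscale(d2, k = ncol(r2$coordinates))
  expect_equal(abs(unname(r2$coordinates)), abs(unname(cs)),
               tolerance = 1e-6)
  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(pcoaOrdination(zero)$coordinates),
               matrix(0, 3, 1))
  expect_error(pcoaOrdination(dist(1:2)), "3")
})

test_that("Mantel r is Pearson on the lower triangles, p has the add-one form", {
  set.seed(72)
  pts <- matrix(rnorm(24), 8)
  d1 <- dist(pts)
  res <- mantelTest(d1, d1, nPerm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  # invariance under positive-affine transforms of one matrix
  d2 <- as.matrix(d1) * 3 + 2; diag(d2) <- 0
  res2 <- mantelTest(d1, as.dist(d2), nPerm = 9, seed = 1)
  expect_equal(res2$r, 1)
  # agreement with the vegan implementation of the statistic
  dA <- dist(matrix(rnorm(30), 10))
  dB <- dist(matrix(rnorm(30), 10))
  expect_equal(mantelTest(dA, dB, nPerm = 9, seed = 1)$r,
               unname(vegan::mantel(dA, dB, permutations = 0)$statistic),
               tolerance = 1e-12)
  expect_error(mantelTest(dist(1:3), dist(1:3)), "n >= 4")
})

test_that("BH step-up reproduces the worked example and matches p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.03), 0.03)  # m = 1: q = p
  set.seed(73)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
  }
  # q-values are monotone non-decreasing in sorted p order
  p <- runif(15)
  q <- bhAdjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("correlation matrices carry r, analytic p, and BH q", {
  set.seed(74)
  x <- rnorm(30)
  df <- data.frame(x = x, y = 2 * x + 1, z = rnorm(30), w = rep(1, 30))
  res <- correlationMatrixBH(df)
  expect_equal(res$r["x", "y"], 1, tolerance = 1e-12)
  expect_true(all(is.na(res$r["w", c("x", "y", "z")])))  # zero variance
  expect_equal(res$q["x", "z"], res$q["z", "x"])
  ut <- upper.tri(res$p)
  ok <- !is.na(res$p[ut])
  expect_equal(res$q[ut][ok], bhAdjust(res$p[ut])[ok])
})

test_that("distance-decay regression recovers exact and two-regime slopes", {
  # exact linear input: similarity = 0.9 - 0.10 log10(km)
  set.seed(75)
  co <- data.frame(lat = runif(10, 20, 30), lon = runif(10, 100, 110))
  rownames(co) <- paste0("s", 1:10)
  geo <- geographicDistance(co)
  sim <- 0.9 - 0.10 * log10(as.matrix(geo))
  diag(sim) <- 1
  comm <- as.dist(1 - sim)
  f <- suppressWarnings(fitDistanceDecay(geo, comm))  # exact input
  expect_equal(f$fits$slope[f$fits$scale == "overall"], -0.10,
               tolerance = 1e-10)
  # two regimes split at 1 km
  co2 <- data.frame(
    lat = c(25 + c(0, 1, 2, 3, 4) * 0.002, 25 + c(0.5, 1, 1.5, 2, 2.5)),
    lon = rep(105, 10))
  rownames(co2) <- paste0("s", 1:10)
  g2 <- geographicDistance(co2)
  km <- as.matrix(g2)
  simm <- ifelse(km <= 1, 0.8 - 0.3 * log10(pmax(km, 1e-6)),
                 0.9 - 0.1 * log10(km))
  diag(simm) <- 1
  f2 <- suppressWarnings(fitDistanceDecay(g2, as.dist(1 - simm)))
  expect_equal(f2$fits$slope[f2$fits$scale == "local"], -0.3,
               tolerance = 1e-6)
  expect_equal(f2$fits$slope[f2$fits$scale == "regional"], -0.1,
               tolerance = 1e-6)
  # shuffled similarities: slope within 2 SE of zero
  set.seed(76)
  v <- as.matrix(comm)[lower.tri(as.matrix(comm))]
  shuf <- matrix(0, 10, 10, dimnames = dimnames(km))
  shuf[lower.tri(shuf)] <- sample(v)
  shuf <- shuf + t(shuf)
  f3 <- fitDistanceDecay(geo, as.dist(shuf))
  ov <- f3$fits[f3$fits$scale == "overall", ]
  expect_lt(abs(ov$slope), 2 * ov$slope_se + 1e-12)
})

test_that("the Lingoes correction removes negative eigenvalues", {
  set.seed(77)
  m <- rbind(s1 = c(5, 0, 2, 1), s2 = c(0, 4, 1, 3),
             s3 = c(2, 2, 0, 0), s4 = c(1, 3, 4, 0), s5 = c(3, 1, 1, 2))
  d <- communityDissimilarity(m, "bray_curtis")  # typically non-Euclidean
  plain <- pcoaOrdination(d)
  fixed <- pcoaOrdination(d, correction = "lingoes")
  expect_gte(min(fixed$eigenvalues), -1e-8)
  expect_equal(fixed$correction, "lingoes")
  # with a Euclidean-embeddable input the correction is a no-op
  dE <- dist(matrix(rnorm(20), 5))
  expect_equal(pcoaOrdination(dE, correction = "lingoes")$coordinates,
               pcoaOrdination(dE)$coordinates, tolerance = 1e-10)
})
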