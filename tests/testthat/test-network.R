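# Bipartite network construction, BRIM modularity, NODF, permutation nulls.

test_that("buildNetwork collapses duplicate links into a binary incidence", {
  links <- data.frame(
    virus_population = c("v1", "v1", "v2", "v2"),
    host_population = c("h1", "h1", "h1", "h2"))
  net <- buildNetwork(links)
  expect_equal(dim(incidence(net)), c(2L, 2L))
  expect_equal(sum(incidence(net)), 3)
  expect_equal(virusNodes(net), c("v1", "v2"))
  empty <- buildNetwork(links[0, ])
  expect_equal(dim(incidence(empty)), c(0L, 0L))
  expect_error(barberModularity(empty), "zero-edge")
})

test_that("extractSubnetwork induces on present nodes", {
  links <- data.frame(virus_population = c("v1", "v2", "v2"),
                      host_population = c("h1", "h1", "h2"))
  net <- buildNetwork(links)
  full <- extractSubnetwork(net, c("v1", "v2"), c("h1", "h2"))
  expect_equal(incidence(full), incidence(net))
  sub <- extractSubnetwork(net, c("v1", "v2"), "h1")
  expect_equal(colnames(incidence(sub)), "h1")
  expect_equal(sum(incidence(sub)), 2)
  expect_error(extractSubnetwork(net, "vX", "h1"), "unknown")
})

test_that("BRIM reproduces exact small-graph optima", {
  # two disconnected single-edge components: Q = 1/2
  d2 <- diag(2); dimnames(d2) <- list(c("v1", "v2"), c("h1", "h2"))
  expect_equal(barberModularity(BipartiteNetwork(d2), seed = 1)$q, 0.5)
  # complete bipartite K22: Q = 0
  k22 <- matrix(1, 2, 2, dimnames = list(c("v1", "v2"), c("h1", "h2")))
  expect_equal(barberModularity(BipartiteNetwork(k22), seed = 1)$q, 0)
  # single edge: Q = 0
  e1 <- matrix(1, 1, 1, dimnames = list("v1", "h1"))
  expect_equal(barberModularity(BipartiteNetwork(e1), seed = 1)$q, 0)
})

test_that("reported Q equals the Barber formula on the stored partition", {
  set.seed(60)
  for (i in 1:10) {
    A <- randomBipartite(4, 5, 0.4)
    res <- barberModularity(BipartiteNetwork(A), seed = i)
    m <- sum(A)
    B <- A - outer(rowSums(A), colSums(A)) / m
    g <- res$virusModule[rownames(A)]
    h <- res$hostModule[colnames(A)]
    keep <- !is.na(g); keepC <- !is.na(h)
    q <- sum(B[keep, keepC, drop = FALSE] *
               outer(g[keep], h[keepC], "==")) / m
    expect_equal(res$q, q, tolerance = 1e-12)
  }
})

test_that("BRIM matches exhaustive search on small random graphs", {
  set.seed(61)
  for (i in 1:20) {
    A <- randomBipartite(sample(2:5, 1), sample(2:5, 1), runif(1, 0.25, 0.7))
    got <- barberModularity(BipartiteNetwork(A), nRestarts = 50, seed = i)$q
    expect_equal(got, bruteBarberQ(A), tolerance = 1e-10)
  }
})

test_that("best Q is non-decreasing in the number of restarts", {
  set.seed(62)
  A <- randomBipartite(8, 8, 0.3)
  net <- BipartiteNetwork(A)
  qs <- vapply(c(1, 5, 10, 20), function(r)
    barberModularity(net, nRestarts = r, seed = 7)$q, 0)
  expect_true(all(diff(qs) >= -1e-12))
})

test_that("NODF matches hand-computed values", {
  st <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(paste0("v", 1:3), paste0("h", 1:3)))
  expect_equal(nodf(BipartiteNetwork(st))$nodf, 100)
  id3 <- diag(3); dimnames(id3) <- list(paste0("v", 1:3), paste0("h", 1:3))
  expect_equal(nodf(BipartiteNetwork(id3))$nodf, 0)
  tb <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("v1", "v2"), c("h1", "h2")))
  expect_equal(nodf(BipartiteNetwork(tb))$nodf, 100)
  e1 <- matrix(1, 1, 1, dimnames = list("v1", "h1"))
  expect_error(nodf(BipartiteNetwork(e1)), "single-row")
})

test_that("NODF is invariant to transposition and node permutation", {
  set.seed(63)
  for (i in 1:10) {
    A <- randomBipartite(5, 6, 0.5)
    n1 <- nodf(BipartiteNetwork(A))$nodf
    tA <- t(A)
    expect_equal(nodf(BipartiteNetwork(tA))$nodf, n1)
    P <- A[sample(nrow(A)), sample(ncol(A))]
    expect_equal(nodf(BipartiteNetwork(P))$nodf, n1)
    # independent oracle: vegan implementation
    v <- unname(vegan::nestednodf(A, order = TRUE, weighted = FALSE
                                  )$statistic["NODF"])
    expect_equal(n1, v, tolerance = 1e-9)
  }
})

test_that("Q is invariant under row/column permutation", {
  set.seed(64)
  A <- randomBipartite(5, 5, 0.4)
  q1 <- barberModularity(BipartiteNetwork(A), nRestarts = 20, seed = 1)$q
  P <- A[sample(nrow(A)), sample(ncol(A))]
  q2 <- barberModularity(BipartiteNetwork(P), nRestarts = 20, seed = 2)$q
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("permutation p-values respect the add-one bounds", {
  set.seed(65)
  A <- randomBipartite(4, 4, 0.5)
  res <- permutationNull(BipartiteNetwork(A), "nodf", nPerm = 99, seed = 3)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
  expect_equal(res$n_permutations, 99L)
})

test_that("a strongly nested matrix is significant under the equiprobable null", {
  n <- 8
  A <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("h", 1:n)))
  for (i in 1:n) A[i, 1:(n - i + 1)] <- 1
  res <- permutationNull(BipartiteNetwork(A), "nodf", nPerm = 500, seed = 4)
  expect_lte(res$p, 0.01)
})

test_that("degree-preserving null preserves both margins", {
  set.seed(66)
  A <- randomBipartite(6, 7, 0.4)
  sh <- amdvir:::.checkerboardShuffle(A, nSwaps = 500)
  expect_equal(rowSums(sh), rowSums(A))
  expect_equal(colSums(sh), colSums(A))
  expect_false(identical(sh, A))  # 500 swap attempts should move something
})

test_that("richness regressions recover exact linear structure", {
  met <- data.frame(modularity = 2 * (1:10), nodf = 50 - (1:10))
  ric <- data.frame(prokaryotic_richness = 1:10,
                    viral_richness = rep(3, 10))
  res <- suppressWarnings(richnessStructureRegression(met, ric))  # exact fit
  row <- res[res$metric == "modularity" &
               res$predictor == "prokaryotic_richness", ]
  expect_equal(row$slope, 2)
  expect_equal(row$adj_r2, 1)
  zv <- res[res$predictor == "viral_richness", ]
  expect_true(all(is.na(zv$slope)))  # zero-variance predictor flagged
  expect_error(richnessStructureRegression(met[1:2, ], ric[1:2, ]), "3")
})
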