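# Lineage-level virus-host dynamics.

toyLinks <- function() data.frame(
  virus_population = c("v1", "v2"),
  host_population = c("h1", "h2"),
  evidence = "homology", support = 1L)

test_that("VHR is the ratio of per-sample sums, reported on log10 scale", {
  va <- toyAbundance(matrix(c(12, 8, 6, 4), 2, 2,
                            dimnames = list(c("v1", "v2"), c("s1", "s2"))))
  ha <- toyAbundance(matrix(c(6, 4, 5, 0), 2, 2,
                            dimnames = list(c("h1", "h2"), c("s1", "s2"))))
  pm <- c(h1 = "PhyA", h2 = "PhyA")
  res <- lineageVhr(va, ha, toyLinks(), pm)
  vhr <- attr(res, "vhr")$PhyA
  expect_equal(unname(vhr["s1"]), 2)      # 20 / 10
  expect_equal(unname(vhr["s2"]), 2)      # 10 / 5
  expect_equal(res$mean_log10_vhr, log10(2), tolerance = 1e-12)
  expect_equal(res$n_samples, 2L)
})

test_that("samples with a zero host sum are excluded", {
  va <- toyAbundance(matrix(c(10, 10), 1, 2,
                            dimnames = list("v1", c("s1", "s2"))))
  ha <- toyAbundance(matrix(c(5, 0), 1, 2,
                            dimnames = list("h1", c("s1", "s2"))))
  links <- data.frame(virus_population = "v1", host_population = "h1",
                      evidence = "crispr", support = 1L)
  res <- lineageVhr(va, ha, links, c(h1 = "PhyA"))
  expect_equal(res$n_samples, 1L)
  expect_equal(names(attr(res, "vhr")$PhyA), "s1")
})

test_that("VHR is scale-equivariant in the viral abundances", {
  set.seed(50)
  m <- matrix(runif(8, 1, 10), 2, 4,
              dimnames = list(c("v1", "v2"), paste0("s", 1:4)))
  h <- matrix(runif(8, 1, 10), 2, 4,
              dimnames = list(c("h1", "h2"), paste0("s", 1:4)))
  pm <- c(h1 = "P", h2 = "P")
  links <- toyLinks()
  r1 <- attr(lineageVhr(toyAbundance(m), toyAbundance(h), links, pm),
             "vhr")$P
  r2 <- attr(lineageVhr(toyAbundance(3 * m), toyAbundance(h), links, pm),
             "vhr")$P
  expect_equal(r2, 3 * r1)
})

test_that("a phylum with no linked viruses is omitted with a warning", {
  va <- toyAbundance(matrix(1, 1, 2, dimnames = list("v1", c("s1", "s2"))))
  ha <- toyAbundance(matrix(1, 2, 2,
                            dimnames = list(c("h1", "h2"), c("s1", "s2"))))
  links <- data.frame(virus_population = "v1", host_population = "h1",
                      evidence = "homology", support = 1L)
  expect_warning(res <- lineageVhr(va, ha, links,
                                   c(h1 = "PhyA", h2 = "PhyB")), "PhyB")
  expect_equal(res$phylum, "PhyA")
})

test_that("abundance correlation is Pearson over co-detected samples", {
  h <- matrix(c(1, 2, 3, 4, 5), 1, 5,
              dimnames = list("h1", paste0("s", 1:5)))
  v <- 2 * h; rownames(v) <- "v1"
  links <- data.frame(virus_population = "v1", host_population = "h1",
                      evidence = "homology", support = 1L)
  res <- lineageAbundanceCorrelation(toyAbundance(v), toyAbundance(h),
                                     links, c(h1 = "P"))
  expect_equal(res$r, 1)
  expect_lt(res$p, 0.05)
  # constant host vector: undefined, flagged
  hc <- matrix(5, 1, 5, dimnames = list("h1", paste0("s", 1:5)))
  set.seed(51)
  vr <- matrix(runif(5, 1, 2), 1, 5,
               dimnames = list("v1", paste0("s", 1:5)))
  res2 <- lineageAbundanceCorrelation(toyAbundance(vr), toyAbundance(hc),
                                      links, c(h1 = "P"))
  expect_true(is.na(res2$r))
  # < 3 co-detected samples: undefined
  h2 <- matrix(c(1, 2, 0, 0, 0), 1, 5,
               dimnames = list("h1", paste0("s", 1:5)))
  res3 <- lineageAbundanceCorrelation(toyAbundance(v), toyAbundance(h2),
                                      links, c(h1 = "P"))
  expect_true(is.na(res3$r))
})

test_that("host range and viral range count distinct partners", {
  links <- data.frame(
    virus_population = c("v1", "v1", "v2"),
    host_population = c("h1", "h2", "h1"),
    evidence = "homology", support = 1L)
  pm <- c(h1 = "P", h2 = "P")
  res <- hostViralRange(links, pm)
  expect_equal(res$host_range_mean, 1.5)   # v1 -> 2 hosts, v2 -> 1
  expect_equal(res$viral_range_mean, 1.5)  # h1 <- 2 viruses, h2 <- 1
  one <- hostViralRange(data.frame(virus_population = c("v1", "v2"),
                                   host_population = c("h1", "h2"),
                                   evidence = "x", support = 1L), pm)
  expect_equal(one$host_range_mean, 1)
  expect_equal(one$viral_range_mean, 1)
  expect_equal(nrow(hostViralRange(links[0, ], pm)), 0L)
})

test_that("lifestyle relative abundances are class shares of total viral abundance", {
  m <- matrix(c(3, 3, 2, 6, 1, 1), 3, 2,
              dimnames = list(c("v1", "v2", "v3"), c("s1", "s2")))
  am <- toyAbundance(m)
  ls <- c(v1 = "virulent", v2 = "temperate", v3 = "virulent")
  pt <- c(s1 = 10, s2 = 20)
  res <- lifestyleRatioTrend(am, ls, pt)
  expect_equal(res$per_sample$virulent + res$per_sample$temperate,
               c(1, 1))  # no unknowns: shares sum to 1
  # virulent = v1 + v3: (3 + 2)/8 in s1, (6 + 1)/8 in s2
  expect_equal(res$per_sample$virulent, c(5 / 8, 7 / 8))
  # all virulent: share 1 everywhere, zero slope
  all_v <- lifestyleRatioTrend(am, c(v1 = "virulent", v2 = "virulent",
                                     v3 = "virulent"), pt)
  expect_equal(all_v$per_sample$virulent, c(1, 1))
  expect_equal(all_v$trend$slope[all_v$trend$class == "virulent"], 0)
  # two equal-abundance classes -> both 0.5
  m2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("v1", "v2"), "s1"))
  eq <- lifestyleRatioTrend(toyAbundance(m2),
                            c(v1 = "virulent", v2 = "temperate"),
                            c(s1 = 1))
  expect_equal(eq$per_sample$virulent, 0.5)
  expect_equal(eq$per_sample$temperate, 0.5)
  expect_error(lifestyleRatioTrend(am, c(v1 = "unknown", v2 = "unknown",
                                         v3 = "unknown"), pt), "unknown")
})

test_that("virulent:temperate ratios support an unpaired Wilcoxon comparison", {
  set.seed(52)
  m <- matrix(runif(40, 1, 10), 4, 10,
              dimnames = list(c("v1", "v2", "v3", "v4"), paste0("s", 1:10)))
  m[1, ] <- m[1, ] * 20  # phylum A dominated by its virulent virus
  am <- toyAbundance(m)
  links <- data.frame(
    virus_population = c("v1", "v2", "v3", "v4"),
    host_population = c("h1", "h1", "h2", "h2"),
    evidence = "homology", support = 1L)
  pm <- c(h1 = "A", h2 = "B")
  ls <- c(v1 = "virulent", v2 = "temperate",
          v3 = "virulent", v4 = "temperate")
  res <- virulentTemperateRatio(am, ls, links, pm, compare = c("A", "B"))
  expect_named(res$ratios, c("A", "B"))
  expect_s3_class(res$wilcox, "htest")
  expect_lt(res$wilcox$p.value, 0.05)
})

test_that("the abundance-abundance polynomial fit captures a peaked pattern", {
  set.seed(53)
  x <- stats::setNames(seq(1, 10, length.out = 30), paste0("s", 1:30))
  y <- stats::setNames(5 + 4 * x - 0.4 * x^2 + rnorm(30, 0, 0.1), names(x))
  fit <- abundanceRelationshipFit(x, y)
  expect_equal(fit$degree, 2L)
  expect_equal(fit$coefficients, c(5, 4, -0.4), tolerance = 0.1)
  expect_gt(fit$adj_r2, 0.99)
  lin <- suppressWarnings(  # exact linear input
    abundanceRelationshipFit(x, stats::setNames(2 * x, names(x)),
                             degree = 1L))
  expect_equal(lin$coefficients[2], 2, tolerance = 1e-8)
  expect_error(abundanceRelationshipFit(x[1:3], y[1:3]), "samples")
})
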