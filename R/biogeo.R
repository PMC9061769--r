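# Distance-based biogeography: transforms, dissimilarities, great-circle
# distances, PCoA, Mantel tests, FDR-controlled correlation matrices, and
# scale-partitioned distance-decay regression.

#' Community / environment matrix transforms
#'
#' `hellinger`: row-wise square root of relative abundance (samples in
#' rows), the standard pre-processing before Bray-Curtis analyses of
#' community data. `standardize`: column-wise z-scores, for environmental
#' variables. All-zero rows (hellinger) and zero-variance columns
#' (standardize) come out as zeros.
#'
#' @param x Numeric matrix, samples in rows.
#' @param method `"hellinger"` or `"standardize"`.
#' @return Transformed matrix.
#' @export
#' @examples
#' communityTransform(rbind(s1 = c(1, 3)), "hellinger")
communityTransform <- function(x, method = c("hellinger", "standardize")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (method == "hellinger") {
    if (any(x < 0)) stop("hellinger requires non-negative entries")
    rs <- rowSums(x)
    # zero rows are defined to transform to zero rows
    out <- suppressWarnings(vegan::decostand(x, method = "hellinger"))
    out[rs == 0, ] <- 0
    out
  } else {
    # zero-variance columns are defined to come out as zeros
    out <- suppressWarnings(vegan::decostand(x, method = "standardize"))
    out[, apply(x, 2L, stats::sd) == 0] <- 0
    out
  }
}

#' Pairwise sample dissimilarity
#'
#' Bray-Curtis for community matrices, Euclidean for environmental ones
#' (samples in rows). A Bray-Curtis comparison of two all-zero rows is
#' defined as 0 with a warning.
#'
#' @param x Numeric matrix, samples in rows.
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @return A [stats::dist] with sample labels.
#' @export
communityDissimilarity <- function(x, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  d <- suppressWarnings(
    vegan::vegdist(x, method = if (metric == "bray_curtis") "bray"
                               else "euclidean"))
  if (anyNA(d)) {
    warning("all-zero row pair(s) under bray_curtis; distance set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Great-circle distance matrix (km)
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param coords `data.frame`/matrix with columns `lat`, `lon` in decimal
#'   degrees; rownames are sample labels.
#' @return A [stats::dist] in kilometres.
#' @export
#' @examples
#' geographicDistance(data.frame(lat = c(0, 1), lon = c(0, 0)))
geographicDistance <- function(coords) {
  coords <- as.data.frame(coords)
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  n <- nrow(coords)
  p <- cbind(coords$lon, coords$lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(p[i, ], p, r = 6371000) / 1000
  }
  m <- (m + t(m)) / 2
  rownames(m) <- colnames(m) <- rownames(coords)
  stats::as.dist(m)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and returns
#' coordinates (eigenvectors scaled by the square root of their
#' eigenvalues) for the positive eigenvalues, sorted descending. Negative
#' eigenvalues are reported but their axes dropped by default (the plain
#' PCoA convention); a Lingoes correction is available behind
#' `correction`. Axis signs are fixed so each axis's largest-magnitude
#' loading is positive.
#'
#' @param d Distance matrix ([stats::dist] or symmetric matrix); n >= 3.
#' @param correction `"none"` (default, plain PCoA) or `"lingoes"`, which
#'   adds the smallest constant to all squared off-diagonal distances
#'   that makes the configuration Euclidean-embeddable before
#'   re-decomposing.
#' @return List: `coordinates` (n x k matrix, axes `PC1..PCk`),
#'   `eigenvalues` (all n, descending), `relative_inertia` (positive
#'   eigenvalues / their sum), `correction`.
#' @export
pcoaOrdination <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) stop("PCoA needs at least 3 samples")
  if (correction == "lingoes") {
    e0 <- eigen(.gowerCenter(D), symmetric = TRUE, only.values = TRUE)
    c1 <- -min(e0$values, 0)
    if (c1 > 1e-12) {
      D2 <- D^2 + 2 * c1
      diag(D2) <- 0
      D <- sqrt(D2)
    }
  }
  e <- eigen(.gowerCenter(D), symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-9)
  if (!length(pos)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(D), "PC1"))
    return(list(coordinates = coords, eigenvalues = e$values,
                relative_inertia = numeric(0)))
  }
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(D), paste0("PC", seq_len(ncol(coords))))
  list(coordinates = coords, eigenvalues = e$values,
       relative_inertia = e$values[pos] / sum(e$values[pos]),
       correction = correction)
}

.gowerCenter <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - 1 / n
  G <- J %*% A %*% J
  (G + t(G)) / 2
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the strictly-lower-triangle entries, with a
#' one-sided permutation p obtained by jointly relabeling one matrix's rows
#' and columns: \eqn{p = (1 + \#\{r_{perm} \ge r\}) / (1 + nPerm)}.
#'
#' @param d1,d2 [stats::dist] objects or symmetric matrices with matching
#'   labels; n >= 4.
#' @param nPerm Number of permutations.
#' @param seed Integer seed.
#' @return List: `r`, `p`, `n_permutations`.
#' @export
mantelTest <- function(d1, d2, nPerm = 999L, seed = 1L) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2)))
      stop("distance matrices have mismatched labels")
    m2 <- m2[rownames(m1), rownames(m1)]
  } else if (nrow(m1) != nrow(m2)) {
    stop("distance matrices have mismatched sizes")
  }
  n <- nrow(m1)
  if (n < 4L) stop("Mantel test needs n >= 4")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  r <- stats::cor(v1, m2[lt])
  perm <- numeric(nPerm)
  withSeed(seed, {
    for (i in seq_len(nPerm)) {
      p <- sample.int(n)
      perm[i] <- stats::cor(v1, m2[p, p][lt])
    }
  })
  list(r = r, p = (1 + sum(perm >= r)) / (1 + nPerm),
       n_permutations = nPerm)
}

#' Pairwise Pearson correlations with BH false-discovery-rate control
#'
#' Pearson r with analytic two-tailed p for every variable pair, and
#' Benjamini-Hochberg step-up q-values computed across all pairs.
#' Zero-variance variables are flagged undefined (NA row/column).
#'
#' @param x `data.frame` or matrix of numeric variables (observations in
#'   rows; >= 3 complete observations per pair).
#' @return List of matrices `r`, `p`, `q`.
#' @export
correlationMatrixBH <- function(x) {
  x <- as.matrix(x)
  pn <- colnames(x)
  k <- ncol(x)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(pn, pn))
  diag(r) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      ok <- stats::complete.cases(x[, c(i, j)])
      if (sum(ok) < 3L) next
      if (stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) next
      ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  ut <- upper.tri(p)
  q <- p
  q[ut] <- bhAdjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(r = r, p = p, q = q)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1; NAs pass
#' through without counting toward m.
#'
#' @param p Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bhAdjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(q)
  o <- order(p[ok])
  ps <- p[ok][o]
  qs <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  q[ok[o]] <- qs
  q
}

#' Scale-partitioned distance-decay regression
#'
#' Regresses community similarity (1 - Bray-Curtis dissimilarity) on
#' log10-transformed geographic distance (km) over all pairs, and
#' separately over local (distance <= `breakpointKm`) and regional
#' (> `breakpointKm`) pairs. Zero-distance pairs are set to half the
#' smallest positive distance before the log (flagged in the output).
#'
#' @param geo Geographic [stats::dist] in km.
#' @param comm Community dissimilarity [stats::dist] with matching labels.
#' @param breakpointKm Scale split, km.
#' @return List of class `"ddrFit"`: per-scale `data.frame` `fits`
#'   (scale, slope, p, adj_r2, n_pairs), `breakpoint_km`,
#'   `n_zero_distance`, and `pairs` (the regression table).
#' @export
fitDistanceDecay <- function(geo, comm, breakpointKm = 1) {
  mg <- as.matrix(geo); mc <- as.matrix(comm)
  if (!is.null(rownames(mg)) && !is.null(rownames(mc))) {
    if (!setequal(rownames(mg), rownames(mc)))
      stop("distance matrices have mismatched labels")
    mc <- mc[rownames(mg), rownames(mg)]
  }
  lt <- lower.tri(mg)
  km <- mg[lt]
  sim <- 1 - mc[lt]
  nz <- sum(km == 0)
  if (nz) {
    posMin <- min(km[km > 0])
    km[km == 0] <- posMin / 2
  }
  x <- log10(km)
  fitOne <- function(scale, idx) {
    if (sum(idx) < 3L || stats::sd(x[idx]) == 0)
      return(data.frame(scale = scale, slope = NA_real_, p = NA_real_,
                        adj_r2 = NA_real_, n_pairs = sum(idx)))
    f <- stats::lm(sim[idx] ~ x[idx])
    s <- summary(f)
    data.frame(scale = scale, slope = unname(stats::coef(f)[2L]),
               slope_se = s$coefficients[2L, 2L],
               p = s$coefficients[2L, 4L], adj_r2 = s$adj.r.squared,
               n_pairs = sum(idx))
  }
  all_ <- fitOne("overall", rep(TRUE, length(x)))
  loc <- fitOne("local", mg[lt] <= breakpointKm)
  reg <- fitOne("regional", mg[lt] > breakpointKm)
  if (!"slope_se" %in% names(all_)) all_$slope_se <- NA_real_
  if (!"slope_se" %in% names(loc)) loc$slope_se <- NA_real_
  if (!"slope_se" %in% names(reg)) reg$slope_se <- NA_real_
  cols <- c("scale", "slope", "slope_se", "p", "adj_r2", "n_pairs")
  fits <- rbind(all_[cols], loc[cols], reg[cols])
  rownames(fits) <- NULL
  structure(list(fits = fits, breakpoint_km = breakpointKm,
                 n_zero_distance = nz,
                 pairs = data.frame(log10_km = x, similarity = sim)),
            class = "ddrFit")
}
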