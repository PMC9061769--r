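# Bipartite virus-host interaction structure: Barber modularity via BRIM,
# NODF nestedness, permutation nulls, and richness regressions.

#' Build a bipartite network from population-level links
#'
#' @param links `data.frame` with columns virus_population, host_population
#'   (duplicate links collapse to one edge).
#' @return A [BipartiteNetwork-class] with lexicographically ordered nodes.
#' @export
buildNetwork <- function(links) {
  v <- sort(unique(as.character(links$virus_population)))
  h <- sort(unique(as.character(links$host_population)))
  m <- matrix(0, length(v), length(h), dimnames = list(v, h))
  if (nrow(links))
    m[cbind(match(links$virus_population, v),
            match(links$host_population, h))] <- 1
  BipartiteNetwork(m)
}

#' Extract the sub-network induced by present populations
#'
#' Keeps edges between viruses and hosts detected in a sample; nodes in the
#' presence sets are retained in the node lists even if isolated (metrics
#' drop zero-degree nodes internally).
#'
#' @param net Meta-network ([BipartiteNetwork-class]).
#' @param presentViruses,presentHosts Character vectors, subsets of the
#'   meta-network node sets.
#' @return A [BipartiteNetwork-class].
#' @export
extractSubnetwork <- function(net, presentViruses, presentHosts) {
  m <- incidence(net)
  badV <- setdiff(presentViruses, rownames(m))
  badH <- setdiff(presentHosts, colnames(m))
  if (length(badV) || length(badH))
    stop("unknown node id(s): ", paste(c(badV, badH), collapse = ", "))
  BipartiteNetwork(m[presentViruses, presentHosts, drop = FALSE])
}

# Drop zero-degree rows/columns before metric computation.
.metricMatrix <- function(net) {
  m <- incidence(net)
  m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
}

# Barber modularity of a given joint partition.
.barberQ <- function(A, g, h) {
  m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  sum(B * outer(g, h, "==")) / m
}

#' Barber bipartite modularity via BRIM
#'
#' Maximizes Barber's bipartite modularity
#' \deqn{Q = \frac{1}{m}\sum_{ij}\left(A_{ij} - \frac{k_i d_j}{m}\right)
#'   \delta(g_i, h_j)}
#' by BRIM label iteration: alternately assign each row to its best module
#' given the column labels and vice versa until Q stops improving, restarted
#' from `nRestarts` random initial labelings with
#' \eqn{\lceil\sqrt{\min(r,c)}\rceil} initial modules (labels may merge).
#' Deterministic given `seed`.
#'
#' @param net [BipartiteNetwork-class] with at least one edge.
#' @param nRestarts Random restarts.
#' @param seed Integer seed.
#' @return List of class `"modularityResult"`: `q`, `virusModule`,
#'   `hostModule` (named integer module labels; NA for zero-degree nodes),
#'   `nRestarts`, `seed`.
#' @export
barberModularity <- function(net, nRestarts = 20L, seed = 1L) {
  A <- .metricMatrix(net)
  if (sum(A) == 0) stop("modularity undefined on a zero-edge network")
  nr <- nrow(A); nc <- ncol(A)
  m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  c0 <- max(2L, ceiling(sqrt(min(nr, nc))))
  cmax <- max(c0, min(nr, nc))  # spare labels let modules split and merge
  best <- list(q = -Inf)
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      # restart 1: deterministic maximal-spread labeling (lets modules
      # merge down to the optimum); then alternate sqrt-rule and
      # full-width random initial labelings — narrow starts converge
      # fast, wide starts reach optima needing more modules
      h <- if (r == 1L) rep(seq_len(cmax), length.out = nc)
           else sample.int(if (r %% 2L) c0 else cmax, nc, replace = TRUE)
      g <- rep(1L, nr)
      qPrev <- -Inf
      for (it in seq_len(200L)) {
        H <- outer(h, seq_len(cmax), "==") * 1
        g <- max.col(B %*% H, ties.method = "first")
        G <- outer(g, seq_len(cmax), "==") * 1
        h <- max.col(t(B) %*% G, ties.method = "first")
        q <- sum(B * outer(g, h, "==")) / m
        if (q <= qPrev + 1e-12) break
        qPrev <- q
      }
      q <- sum(B * outer(g, h, "==")) / m
      if (q > best$q + 1e-12) best <- list(q = q, g = g, h = h)
    }
  })
  # canonical module labels by order of first appearance
  lab <- unique(c(best$g, best$h))
  g <- match(best$g, lab)
  h <- match(best$h, lab)
  mAll <- incidence(net)
  vm <- stats::setNames(rep(NA_integer_, nrow(mAll)), rownames(mAll))
  hm <- stats::setNames(rep(NA_integer_, ncol(mAll)), colnames(mAll))
  vm[rownames(A)] <- g
  hm[colnames(A)] <- h
  structure(list(q = best$q, virusModule = vm, hostModule = hm,
                 nRestarts = nRestarts, seed = seed),
            class = "modularityResult")
}

#' NODF nestedness
#'
#' Nestedness metric based on overlap and decreasing fill: for every
#' ordered pair of rows with strictly decreasing marginal totals, the
#' paired overlap is the percentage of the poorer row's presences also
#' found in the richer row (0 for equal totals); likewise over columns.
#' NODF is the mean over all row and column pairs, in \eqn{[0, 100]}.
#'
#' @param net [BipartiteNetwork-class]; needs >= 1 edge and >= 2 rows or
#'   >= 2 columns after dropping zero-degree nodes.
#' @return List of class `"nestednessResult"`: `nodf`, `row_component`,
#'   `col_component`, `n_row_pairs`, `n_col_pairs`.
#' @export
nodf <- function(net) {
  A <- .metricMatrix(net)
  if (sum(A) == 0) stop("NODF undefined on a zero-edge network")
  if (nrow(A) < 2L && ncol(A) < 2L)
    stop("NODF undefined for a single-row-and-single-column network")
  pairSum <- function(M) {
    n <- nrow(M)
    if (n < 2L) return(c(sum = 0, pairs = 0L))
    fill <- unname(rowSums(M))
    tot <- 0
    np <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        np <- np + 1L
        hi <- i; lo <- j
        if (fill[j] > fill[i]) { hi <- j; lo <- i }
        if (fill[hi] > fill[lo] && fill[lo] > 0)
          tot <- tot + 100 * sum(M[hi, ] * M[lo, ]) / fill[lo]
      }
    }
    c(sum = tot, pairs = np)
  }
  rows <- pairSum(A)
  cols <- pairSum(t(A))
  npairs <- rows[["pairs"]] + cols[["pairs"]]
  structure(list(
    nodf = (rows[["sum"]] + cols[["sum"]]) / npairs,
    row_component = if (rows[["pairs"]]) rows[["sum"]] / rows[["pairs"]] else NA,
    col_component = if (cols[["pairs"]]) cols[["sum"]] / cols[["pairs"]] else NA,
    n_row_pairs = rows[["pairs"]], n_col_pairs = cols[["pairs"]]),
    class = "nestednessResult")
}

#' Permutation null for a bipartite metric
#'
#' Generates `nPerm` random binary matrices under the chosen null model
#' (`equiprobable`: i.i.d. Bernoulli at the observed fill, redrawn if
#' metric-degenerate; `degree-preserving`: checkerboard swaps preserving
#' both margins), recomputes the metric, and returns the add-one one-sided
#' empirical p-value \eqn{p = (1 + \#\{null \ge obs\}) / (1 + nPerm)}.
#'
#' @param net [BipartiteNetwork-class].
#' @param metric `"modularity"` or `"nodf"`.
#' @param nPerm Number of permutations (>= 1).
#' @param nullModel `"equiprobable"` or `"degree-preserving"`.
#' @param seed Integer seed.
#' @param nRestarts BRIM restarts used inside the null (modularity only).
#' @return List: `p`, `observed`, `null_mean`, `null_sd`, `n_permutations`,
#'   `null_model`, `seed`.
#' @export
permutationNull <- function(net, metric = c("modularity", "nodf"),
                            nPerm = 1000L,
                            nullModel = c("equiprobable", "degree-preserving"),
                            seed = 1L, nRestarts = 5L) {
  metric <- match.arg(metric)
  nullModel <- match.arg(nullModel)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  A <- .metricMatrix(net)
  evalMetric <- function(M, s) {
    net2 <- BipartiteNetwork(
      matrix(M, nrow(M), ncol(M),
             dimnames = list(paste0("v", seq_len(nrow(M))),
                             paste0("h", seq_len(ncol(M))))))
    if (metric == "modularity")
      barberModularity(net2, nRestarts = nRestarts, seed = s)$q
    else nodf(net2)$nodf
  }
  obs <- evalMetric(A, seed)
  fill <- mean(A)
  nulls <- numeric(nPerm)
  withSeed(deriveSeed(seed, "null"), {
    for (i in seq_len(nPerm)) {
      if (nullModel == "equiprobable") {
        repeat {
          M <- matrix(stats::rbinom(length(A), 1L, fill), nrow(A), ncol(A))
          ok <- sum(M) > 0 && (sum(rowSums(M) > 0) >= 2 ||
                                 sum(colSums(M) > 0) >= 2)
          if (ok) break
        }
      } else {
        M <- .checkerboardShuffle(A, nSwaps = 5L * sum(A))
      }
      nulls[i] <- evalMetric(M, i)
    }
  })
  list(p = (1 + sum(nulls >= obs)) / (1 + nPerm), observed = obs,
       null_mean = mean(nulls), null_sd = stats::sd(nulls),
       n_permutations = nPerm, null_model = nullModel, seed = seed)
}

# Degree-preserving randomization by 2x2 checkerboard swaps.
.checkerboardShuffle <- function(A, nSwaps) {
  nr <- nrow(A); nc <- ncol(A)
  for (s in seq_len(nSwaps)) {
    i <- sample.int(nr, 2L)
    j <- sample.int(nc, 2L)
    sub <- A[i, j]
    if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] &&
        sub[1, 1] != sub[1, 2]) {
      A[i, j] <- sub[, 2:1]
    }
  }
  A
}

#' Regress network structure on richness
#'
#' OLS of per-sample modularity and nestedness on prokaryotic and viral
#' richness, reporting slope, two-tailed p, and adjusted R-squared for each
#' metric-predictor combination.
#'
#' @param metrics `data.frame` with per-sample columns among `modularity`,
#'   `nodf`.
#' @param richness `data.frame` with per-sample columns among
#'   `prokaryotic_richness`, `viral_richness` (same row order as
#'   `metrics`; >= 3 samples).
#' @return `data.frame`: metric, predictor, slope, p, adj_r2. Zero-variance
#'   predictors are flagged with NA.
#' @export
richnessStructureRegression <- function(metrics, richness) {
  if (nrow(metrics) < 3L) stop("at least 3 samples required")
  rows <- list()
  for (mName in intersect(c("modularity", "nodf"), names(metrics))) {
    for (rName in intersect(c("prokaryotic_richness", "viral_richness"),
                            names(richness))) {
      y <- metrics[[mName]]
      x <- richness[[rName]]
      ok <- is.finite(y) & is.finite(x)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mName, predictor = rName, slope = NA_real_,
          p = NA_real_, adj_r2 = NA_real_)
        next
      }
      f <- stats::lm(y[ok] ~ x[ok])
      s <- summary(f)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mName, predictor = rName,
        slope = unname(stats::coef(f)[2L]),
        p = s$coefficients[2L, 4L], adj_r2 = s$adj.r.squared)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
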