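# Shared fixtures: deterministic sequences, a small planted community, and
# a brute-force Barber modularity oracle.

rseq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

raa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}

# Substitute exactly k positions (each to a different base), optionally
# restricted to [from, to]. Returns the mutated string.
mutateExactly <- function(x, k, from = 1L, to = nchar(x)) {
  ch <- strsplit(x, "")[[1L]]
  pos <- sample(seq(from, to), k)
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  ch[pos] <- nxt[ch[pos]]
  paste(ch, collapse = "")
}

tinyConfig <- function(seed = 11, ...) {
  simConfig(seed = seed, n_sites = 4, samples_per_site = 3,
            n_host_phyla = 2, hosts_per_phylum = 2, viruses_per_host = 1,
            genome_length_range = c(10000, 11000),
            divergence_levels = c(0.03, 0.10),
            n_background_viruses = 1, ...)
}

# Lazy caches so expensive fixtures are built once per test run.
.fixtureCache <- new.env(parent = emptyenv())

tinySeqs <- function() {
  if (is.null(.fixtureCache$tinySeqs))
    .fixtureCache$tinySeqs <- simulateSequences(tinyConfig())
  .fixtureCache$tinySeqs
}

toyAbundance <- function(m) {
  AbundanceMatrix(m, stats::setNames(rep(1e6, ncol(m)), colnames(m)))
}

# Random incidence with no zero-degree nodes (the metric-matrix contract
# drops isolated nodes, so oracle comparisons use full-margin matrices).
randomBipartite <- function(nr, nc, p = 0.5) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc,
                dimnames = list(paste0("v", seq_len(nr)),
                                paste0("h", seq_len(nc))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Exhaustive Barber modularity: enumerate all row partitions (restricted
# growth strings); for fixed row labels the optimal column assignment
# decomposes per column (a column takes its best row-label, or a fresh
# label contributing 0).
bruteBarberQ <- function(A) {
  nr <- nrow(A); nc <- ncol(A); m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  best <- -Inf
  labels <- integer(nr)
  recurse <- function(i, maxLab) {
    if (i > nr) {
      q <- 0
      for (j in seq_len(nc)) {
        contrib <- max(0, max(vapply(seq_len(maxLab), function(c_)
          sum(B[labels == c_, j]), 0)))
        q <- q + contrib
      }
      best <<- max(best, q / m)
      return(invisible())
    }
    for (lab in seq_len(maxLab + 1L)) {
      labels[i] <<- lab
      recurse(i + 1L, max(maxLab, lab))
    }
  }
  recurse(1L, 0L)
  best
}
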