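# Read-alignment filtering, trimmed-mean per-base coverage, and normalized
# abundance matrices.

#' Filter read alignments by identity and aligned length
#'
#' Keeps records with percent identity >= `idMin` and aligned length at
#' least `lenFrac` of the read length (the mapping filter applied before
#' coverage is computed).
#'
#' @param alignments `data.frame` with columns `read_length`,
#'   `aligned_length` and `identity` (percent); extra columns pass through.
#' @param idMin Percent identity threshold.
#' @param lenFrac Required aligned fraction of each read.
#' @return The filtered `data.frame`.
#' @export
#' @examples
#' aln <- data.frame(read_length = c(100, 100), aligned_length = c(80, 70),
#'                   identity = c(96, 99))
#' filterReadAlignments(aln)
filterReadAlignments <- function(alignments, idMin = 95, lenFrac = 0.75) {
  need <- c("read_length", "aligned_length", "identity")
  miss <- setdiff(need, names(alignments))
  if (length(miss))
    stop("alignment records missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(alignments)) return(alignments)
  if (anyNA(alignments$read_length))
    stop("alignment records missing read length")
  keep <- alignments$identity >= idMin &
    alignments$aligned_length >= lenFrac * alignments$read_length
  alignments[keep, , drop = FALSE]
}

#' Trimmed-mean ("tpmean") per-base coverage
#'
#' Sorts per-base depths, drops the `floor(trim * L)` lowest and highest
#' positions, and returns the mean of the remainder. With `trim = 0` this is
#' the plain mean.
#'
#' @param depth Non-negative numeric vector of per-base depths (or an
#'   [S4Vectors::Rle]).
#' @param trim Proportion trimmed from each tail; must be < 0.5.
#' @return Trimmed mean coverage (scalar).
#' @export
#' @examples
#' tpmeanCoverage(c(rep(10, 90), rep(0, 5), rep(1000, 5)))
tpmeanCoverage <- function(depth, trim = 0.05) {
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  if (methods::is(depth, "Rle")) depth <- as.numeric(depth)
  L <- length(depth)
  if (L == 0L) stop("empty depth vector")
  if (any(depth < 0)) stop("depths must be non-negative")
  k <- floor(trim * L)
  if (k == 0L) return(mean(depth))
  s <- sort(depth)
  mean(s[(k + 1L):(L - k)])
}

#' Build a normalized abundance matrix from per-sample coverages
#'
#' The abundance of an entity in a sample is its (trimmed-mean) coverage
#' divided by the sample's library read count and multiplied by the mean
#' library read count over all samples, so values are comparable across
#' libraries of unequal depth. Entities absent from a sample get 0.
#'
#' @param coverage Long-format `data.frame` with columns `entity`, `sample`,
#'   `coverage`.
#' @param librarySizes Positive numeric vector of reads per sample, named by
#'   sample; every sample present in `coverage` must appear.
#' @return An [AbundanceMatrix-class].
#' @export
#' @examples
#' cov <- data.frame(entity = "g1", sample = "s1", coverage = 2)
#' buildAbundanceMatrix(cov, c(s1 = 1e6, s2 = 2e6))
buildAbundanceMatrix <- function(coverage, librarySizes) {
  need <- c("entity", "sample", "coverage")
  miss <- setdiff(need, names(coverage))
  if (length(miss))
    stop("coverage table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(names(librarySizes)))
    stop("librarySizes must be named by sample")
  unknown <- setdiff(unique(coverage$sample), names(librarySizes))
  if (length(unknown))
    stop("samples without library sizes: ", paste(unknown, collapse = ", "))
  entities <- sort(unique(as.character(coverage$entity)))
  samples <- names(librarySizes)
  m <- matrix(0, length(entities), length(samples),
              dimnames = list(entities, samples))
  idx <- cbind(match(as.character(coverage$entity), entities),
               match(as.character(coverage$sample), samples))
  m[idx] <- coverage$coverage
  meanLib <- mean(librarySizes)
  m <- sweep(m, 2L, librarySizes, "/") * meanLib
  AbundanceMatrix(m, librarySizes)
}

#' Roll abundances up to groups (protein clusters, populations, phyla)
#'
#' Sums (or averages) the rows of an abundance matrix within groups, e.g.
#' member genes to a protein cluster or member genomes to a population.
#'
#' @param x An [AbundanceMatrix-class].
#' @param groups Named character vector mapping entity id to group id (as
#'   from [clusterMap()]). Entities absent from `groups` are dropped.
#' @param fun `"sum"` (default; the only roll-up consistent with read
#'   counting) or `"mean"`.
#' @return An [AbundanceMatrix-class] with one row per group.
#' @export
aggregateAbundance <- function(x, groups, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  m <- abundance(x)
  keep <- intersect(rownames(m), names(groups))
  m <- m[keep, , drop = FALSE]
  g <- factor(groups[keep])
  agg <- rowsum(m, g)
  if (fun == "mean") agg <- agg / as.vector(table(g))
  AbundanceMatrix(agg, librarySizes(x))
}

#' Compute coverages from a run-length encoded depth table
#'
#' Depth tracks are stored long-form as runs (`entity`, `sample`, `length`,
#' `depth`); this expands each (entity, sample) track and applies
#' [tpmeanCoverage()].
#'
#' @param depthRuns `data.frame` with columns entity, sample, length, depth.
#' @param trim Tail proportion for the trimmed mean.
#' @return Long-format coverage `data.frame` (entity, sample, coverage)
#'   suitable for [buildAbundanceMatrix()].
#' @export
coverageFromDepthRuns <- function(depthRuns, trim = 0.05) {
  need <- c("entity", "sample", "length", "depth")
  miss <- setdiff(need, names(depthRuns))
  if (length(miss))
    stop("depth table missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(depthRuns$entity, depthRuns$sample, drop = TRUE)
  parts <- split(depthRuns, key)
  out <- lapply(parts, function(d) {
    data.frame(entity = d$entity[1L], sample = d$sample[1L],
               coverage = tpmeanCoverage(rep(d$depth, d$length), trim))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
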