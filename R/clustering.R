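# Genome and protein clustering: vOTUs (95% ANI / 85% AF of the shorter
# sequence), prokaryotic populations (97% ANI / 70% AF, single linkage,
# representative maximizing completeness - 4 x contamination), and greedy
# protein clusters (60% identity / 80% coverage of the shorter sequence).

# Canonical processing order: length descending, ties broken by id.
.canonicalOrder <- function(genomes) {
  ids <- names(genomes)
  w <- Biostrings::width(genomes)
  order(-w, ids, method = "radix")
}

.pairAniAf <- function(seqs, i, j, cache) {
  key <- paste(sort(c(i, j)), collapse = "\r")
  if (!is.null(cache[[key]])) return(cache[[key]])
  res <- computeAniAf(seqs[[i]], seqs[[j]])
  cache[[key]] <- res
  res
}

#' Cluster viral genomes into vOTUs
#'
#' Species-level viral populations at the standard 95% ANI / 85%
#' alignment-fraction (of the shorter sequence) thresholds. The default is
#' greedy centroid clustering: genomes are processed longest-first (ties by
#' id) and each joins the first representative meeting both thresholds, else
#' founds a new cluster. `linkage = "single"` instead groups connected
#' components of the threshold graph.
#'
#' @param genomes Named [Biostrings::DNAStringSet] (viral genomes,
#'   >= 10 kb intended).
#' @param aniMin,afMin Percent thresholds.
#' @param linkage `"centroid"` (default) or `"single"`.
#' @param hits Optional named list of precomputed hit tables; entry
#'   `"idA\ridB"` (ids sorted) used in place of the built-in aligner.
#' @return `data.frame` with columns member, representative, ani, af; one
#'   row per input genome. Representatives map to themselves with
#'   ani = af = 100.
#' @export
clusterViralPopulations <- function(genomes, aniMin = 95, afMin = 85,
                                    linkage = c("centroid", "single"),
                                    hits = NULL) {
  linkage <- match.arg(linkage)
  if (length(genomes) == 0L)
    return(data.frame(member = character(0), representative = character(0),
                      ani = numeric(0), af = numeric(0)))
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must carry unique names")
  seqs <- as.character(genomes)
  ids <- names(genomes)[.canonicalOrder(genomes)]
  cache <- new.env(parent = emptyenv())
  pair <- function(i, j) {
    if (!is.null(hits)) {
      key <- paste(sort(c(i, j)), collapse = "\r")
      if (!is.null(hits[[key]])) {
        h <- hits[[key]]
        # external hits are stored with the first (sorted) id as query
        q <- sort(c(i, j))[1L]
        return(computeAniAf(seqs[[q]], seqs[[setdiff(c(i, j), q)]], hits = h))
      }
    }
    .pairAniAf(seqs, i, j, cache)
  }
  if (linkage == "centroid") {
    reps <- character(0)
    out <- vector("list", length(ids))
    for (n in seq_along(ids)) {
      id <- ids[n]
      placed <- FALSE
      for (r in reps) {
        aa <- pair(id, r)
        if (aa$ani >= aniMin && aa$af >= afMin) {
          out[[n]] <- data.frame(member = id, representative = r,
                                 ani = aa$ani, af = aa$af)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps <- c(reps, id)
        out[[n]] <- data.frame(member = id, representative = id,
                               ani = 100, af = 100)
      }
    }
    res <- do.call(rbind, out)
  } else {
    res <- .singleLinkage(seqs, ids, aniMin, afMin, pair,
                          repRule = "longest")
  }
  rownames(res) <- NULL
  res[order(res$representative, res$member), , drop = FALSE]
}

# Single-linkage grouping over the pairwise threshold graph.
.singleLinkage <- function(seqs, ids, aniMin, afMin, pair, repRule,
                           quality = NULL) {
  n <- length(ids)
  edges <- list(); eani <- list()
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (.kmerContainment(seqs[[ids[i]]], seqs[[ids[j]]]) < 0.02) next
      aa <- pair(ids[i], ids[j])
      if (aa$ani >= aniMin && aa$af >= afMin) {
        k <- k + 1L
        edges[[k]] <- c(ids[i], ids[j])
        eani[[k]] <- c(aa$ani, aa$af)
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (k > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, lapply(edges, identity))))
  comp <- igraph::components(g)$membership
  out <- lapply(split(ids, comp[ids]), function(mem) {
    mem <- sort(mem)
    if (repRule == "longest") {
      w <- nchar(unlist(seqs[mem]))
      rep_ <- mem[order(-w, mem)][1L]
    } else {
      sc <- quality[mem]
      rep_ <- mem[order(-sc, mem)][1L]
    }
    aa <- t(vapply(mem, function(m) {
      if (m == rep_) c(100, 100)
      else unlist(pair(m, rep_))
    }, numeric(2)))
    data.frame(member = mem, representative = rep_,
               ani = aa[, 1L], af = aa[, 2L])
  })
  do.call(rbind, out)
}

#' Dereplicate prokaryotic genomes into populations
#'
#' Genomes sharing > 97% ANI over > 70% alignment fraction are grouped by
#' single linkage; each population's representative is the member with the
#' highest quality score, completeness minus four times contamination (ties
#' by id). Inputs are expected to be pre-filtered to >= 50% completeness and
#' < 10% contamination.
#'
#' @param genomes Named [Biostrings::DNAStringSet].
#' @param completeness,contamination Numeric vectors in \eqn{[0, 100]},
#'   named by genome or in genome order. Taken from
#'   `S4Vectors::mcols(genomes)` when omitted.
#' @param aniMin,afMin Percent thresholds.
#' @return `data.frame` with columns member, representative, ani, af, score.
#' @export
dereplicateProkaryoteGenomes <- function(genomes, completeness = NULL,
                                         contamination = NULL,
                                         aniMin = 97, afMin = 70) {
  if (length(genomes) == 0L)
    return(data.frame(member = character(0), representative = character(0),
                      ani = numeric(0), af = numeric(0), score = numeric(0)))
  mc <- S4Vectors::mcols(genomes)
  if (is.null(completeness)) completeness <- mc$completeness
  if (is.null(contamination)) contamination <- mc$contamination
  if (is.null(completeness) || is.null(contamination) ||
      anyNA(completeness) || anyNA(contamination))
    stop("completeness and contamination are required for every genome")
  ids <- names(genomes)
  if (is.null(names(completeness))) names(completeness) <- ids
  if (is.null(names(contamination))) names(contamination) <- ids
  score <- completeness[ids] - 4 * contamination[ids]
  seqs <- as.character(genomes)
  cache <- new.env(parent = emptyenv())
  pair <- function(i, j) .pairAniAf(seqs, i, j, cache)
  res <- .singleLinkage(seqs, sort(ids), aniMin, afMin, pair,
                        repRule = "quality", quality = score)
  res$score <- unname(score[res$member])
  rownames(res) <- NULL
  res[order(res$representative, res$member), , drop = FALSE]
}

#' Greedy protein clustering
#'
#' cd-hit-style greedy longest-first clustering of amino-acid sequences: a
#' protein joins the first representative with global percent identity
#' (identities over the shorter sequence length) >= `idMin` and alignment
#' coverage of the shorter sequence >= `covMin`. The resulting clusters are
#' the protein clusters ("PCs") counted and quantified downstream.
#'
#' @param proteins Named [Biostrings::AAStringSet].
#' @param idMin,covMin Percent thresholds.
#' @return `data.frame` with columns member, representative.
#' @export
clusterProteins <- function(proteins, idMin = 60, covMin = 80) {
  if (length(proteins) == 0L)
    return(data.frame(member = character(0), representative = character(0)))
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must carry unique names")
  ids <- names(proteins)[.canonicalOrder(proteins)]
  seqs <- proteins
  lens <- stats::setNames(Biostrings::width(proteins), names(proteins))
  reps <- character(0)
  out <- vector("list", length(ids))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  for (n in seq_along(ids)) {
    id <- ids[n]
    placed <- FALSE
    for (r in reps) {
      lenS <- min(lens[[id]], lens[[r]])
      aln <- Biostrings::pairwiseAlignment(seqs[[id]], seqs[[r]],
                                           type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 10, gapExtension = 0.5)
      idPct <- 100 * Biostrings::nmatch(aln) / lenS
      covPct <- 100 * min(Biostrings::nchar(aln), lenS) / lenS
      if (idPct >= idMin && covPct >= covMin) {
        out[[n]] <- data.frame(member = id, representative = r)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      out[[n]] <- data.frame(member = id, representative = id)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$representative, res$member), , drop = FALSE]
}

#' Cluster membership as a named vector
#'
#' @param clusters `data.frame` from a clustering function.
#' @return Named character vector mapping member id to representative id.
#' @export
clusterMap <- function(clusters) {
  stats::setNames(as.character(clusters$representative),
                  as.character(clusters$member))
}

#' Agreement between two partitions of the same items
#'
#' Rand index (pair-counting agreement) plus an exact-equality flag,
#' comparing e.g. a recovered vOTU partition against a truth table.
#'
#' @param a,b Named vectors mapping item to cluster label; must cover the
#'   same items.
#' @return List: `rand` (Rand index in \eqn{[0, 1]}), `identical`
#'   (TRUE when the partitions coincide).
#' @export
partitionAgreement <- function(a, b) {
  items <- names(a)
  if (!setequal(items, names(b))) stop("partitions cover different items")
  b <- b[items]
  n <- length(items)
  if (n < 2L) return(list(rand = 1, identical = TRUE))
  sameA <- outer(a, a, "==")
  sameB <- outer(b, b, "==")
  ut <- upper.tri(sameA)
  agree <- sum(sameA[ut] == sameB[ut])
  list(rand = agree / sum(ut), identical = all(sameA[ut] == sameB[ut]))
}
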