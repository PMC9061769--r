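# Virus-host linkage: CRISPR array detection, zero-mismatch spacer
# matching, genome-homology filtering, prophage provenance, and aggregation
# of genome-level pairs to population-level links.

#' Detect CRISPR repeat-spacer arrays in a scaffold
#'
#' Minimal CRT-like detector for exact repeats: finds >= `minRepeats`
#' consecutive identical repeats of `repLen[1]`-`repLen[2]` bp whose
#' inter-repeat gaps (the spacers) are `spacerLen[1]`-`spacerLen[2]` bp and
#' mutually distinct, and emits the spacers in array order. Degenerate
#' (mismatch-containing) repeats are out of scope.
#'
#' @param scaffold Character or [Biostrings::DNAString] sequence
#'   (>= 150 bp).
#' @param scaffoldId Id recorded in the output.
#' @param minRepeats Minimum number of repeat copies.
#' @param repLen Length bounds of the repeat, bp.
#' @param spacerLen Length bounds of each spacer, bp.
#' @return `data.frame` with one row per spacer: host_scaffold, array_index,
#'   spacer_index, spacer_seq, start, end (0-based half-open coordinates on
#'   the scaffold). Zero rows when no array is found.
#' @export
detectCrisprArrays <- function(scaffold, scaffoldId = "scaffold",
                               minRepeats = 3L, repLen = c(19L, 47L),
                               spacerLen = c(20L, 58L)) {
  empty <- data.frame(host_scaffold = character(0), array_index = integer(0),
                      spacer_index = integer(0), spacer_seq = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  s <- as.character(scaffold)
  L <- nchar(s)
  if (L < 150L) return(empty)
  k <- repLen[1L]
  kms <- .seedsOf(s, k)
  tab <- split(seq_along(kms), kms)
  tab <- tab[lengths(tab) >= minRepeats]
  if (!length(tab)) return(empty)
  gapMin <- repLen[1L] + spacerLen[1L]
  gapMax <- repLen[2L] + spacerLen[2L]
  arrays <- list()
  for (pos in tab) {
    pos <- sort(pos)
    d <- diff(pos)
    okgap <- d >= gapMin & d <= gapMax
    # maximal runs of consecutive occurrences with admissible gaps
    r <- rle(okgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= (minRepeats - 1L))) {
      run <- pos[starts[ri]:(ends[ri] + 1L)]
      arrays[[length(arrays) + 1L]] <- run
    }
  }
  if (!length(arrays)) return(empty)
  # extend each seed run to the maximal exact repeat (left and right),
  # honoring the repeat/spacer length bounds
  expanded <- lapply(arrays, function(run) {
    n <- length(run)
    gaps <- diff(run)
    maxRep <- min(repLen[2L], gaps - spacerLen[1L])
    # left extension
    lext <- 0L
    while (run[1L] - lext - 1L >= 1L && k + lext < maxRep) {
      ch <- substr(s, run[1L] - lext - 1L, run[1L] - lext - 1L)
      same <- all(vapply(run[-1L], function(p)
        substr(s, p - lext - 1L, p - lext - 1L) == ch, logical(1L)))
      if (!same) break
      lext <- lext + 1L
    }
    run <- run - lext
    replen <- k + lext
    # right extension
    while (replen < min(repLen[2L], min(diff(run)) - spacerLen[1L])) {
      ch <- substr(s, run[1L] + replen, run[1L] + replen)
      same <- all(vapply(run[-1L], function(p)
        substr(s, p + replen, p + replen) == ch, logical(1L))) &&
        run[length(run)] + replen <= L
      if (!same) break
      replen <- replen + 1L
    }
    list(pos = run, replen = replen)
  })
  # dedupe seed runs that converge to the same array
  keys <- vapply(expanded, function(a)
    paste(c(a$replen, a$pos), collapse = ","), "")
  expanded <- expanded[!duplicated(keys)]
  # drop arrays nested inside a larger-span one
  spans <- t(vapply(expanded, function(a)
    c(a$pos[1L], a$pos[length(a$pos)] + a$replen - 1L), numeric(2)))
  o <- order(spans[, 2L] - spans[, 1L], decreasing = TRUE)
  kept <- list()
  keptSpan <- matrix(numeric(0), 0, 2)
  for (i in o) {
    if (nrow(keptSpan) &&
        any(spans[i, 1L] >= keptSpan[, 1L] & spans[i, 2L] <= keptSpan[, 2L]))
      next
    kept[[length(kept) + 1L]] <- expanded[[i]]
    keptSpan <- rbind(keptSpan, spans[i, ])
  }
  kept <- kept[order(vapply(kept, function(a) a$pos[1L], numeric(1)))]
  out <- list()
  ai <- 0L
  for (a in kept) {
    pos <- a$pos; replen <- a$replen
    spStart <- pos[-length(pos)] + replen     # 1-based
    spEnd <- pos[-1L] - 1L
    lens <- spEnd - spStart + 1L
    if (any(lens < spacerLen[1L] | lens > spacerLen[2L])) next
    seqs <- substring(s, spStart, spEnd)
    if (anyDuplicated(seqs)) next  # repeats must flank distinct spacers
    ai <- ai + 1L
    out[[ai]] <- data.frame(
      host_scaffold = scaffoldId, array_index = ai,
      spacer_index = seq_along(seqs), spacer_seq = seqs,
      start = spStart - 1L, end = spEnd,  # 0-based half-open
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract CRISPR spacers from a set of scaffolds
#'
#' @param scaffolds Named [Biostrings::DNAStringSet].
#' @param ... Passed to [detectCrisprArrays()].
#' @return Combined spacer `data.frame` (see [detectCrisprArrays()]).
#' @export
extractSpacers <- function(scaffolds, ...) {
  out <- lapply(names(scaffolds), function(id)
    detectCrisprArrays(scaffolds[[id]], scaffoldId = id, ...))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match CRISPR spacers against viral genomes
#'
#' A hit requires an exact, full-length match of the spacer (or, by
#' default, its reverse complement) within a viral genome — the
#' zero-mismatch protospacer criterion. Spacers shorter than `minLen` bp
#' cannot meet the stringent E-value bound this criterion stands in for and
#' are dropped with a warning.
#'
#' @param spacers Spacer `data.frame` (from [extractSpacers()]) or a named
#'   character vector of spacer sequences.
#' @param viralGenomes Named [Biostrings::DNAStringSet].
#' @param bothStrands Match the reverse complement too (default TRUE).
#' @param minLen Minimum spacer length in bp.
#' @return `data.frame` with columns host_scaffold (NA for bare vectors),
#'   spacer_seq, virus.
#' @export
matchSpacers <- function(spacers, viralGenomes, bothStrands = TRUE,
                         minLen = 20L) {
  if (is.data.frame(spacers)) {
    seqs <- spacers$spacer_seq
    scaff <- spacers$host_scaffold
  } else {
    seqs <- as.character(spacers)
    scaff <- if (is.null(names(spacers))) rep(NA_character_, length(seqs))
             else names(spacers)
  }
  short <- nchar(seqs) < minLen
  if (any(short)) {
    warning(sum(short), " spacer(s) shorter than ", minLen,
            " bp rejected")
    seqs <- seqs[!short]; scaff <- scaff[!short]
  }
  out <- list()
  vnames <- names(viralGenomes)
  for (i in seq_along(seqs)) {
    n1 <- Biostrings::vcountPattern(seqs[i], viralGenomes, fixed = TRUE)
    hit <- n1 > 0L
    if (bothStrands) {
      n2 <- Biostrings::vcountPattern(revComp(seqs[i]), viralGenomes,
                                      fixed = TRUE)
      hit <- hit | n2 > 0L
    }
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        host_scaffold = scaff[i], spacer_seq = seqs[i],
        virus = vnames[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(host_scaffold = character(0),
                      spacer_seq = character(0), virus = character(0),
                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Genome-homology virus-host pairs from tabular alignment hits
#'
#' Keeps virus-vs-host nucleotide hits passing all four thresholds
#' (E-value, bit score, alignment length, identity) and collapses them to
#' one pair per (virus, host).
#'
#' @param hits `data.frame` with columns qseqid (virus), sseqid (host
#'   scaffold/genome), pident, length, evalue, bitscore (the 12-column
#'   tabular alignment layout; see [readBlastTab()]).
#' @param evalueMax,bitMin,lenMin,idMin Thresholds.
#' @return `data.frame` with columns virus, host.
#' @export
linkByGenomeHomology <- function(hits, evalueMax = 1e-3, bitMin = 50,
                                 lenMin = 2500, idMin = 70) {
  need <- c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(hits[need]))
  if (length(bad))
    stop("malformed hit row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  keep <- hits$evalue <= evalueMax & hits$bitscore >= bitMin &
    hits$length >= lenMin & hits$pident >= idMin
  res <- unique(data.frame(virus = as.character(hits$qseqid[keep]),
                           host = as.character(hits$sseqid[keep]),
                           stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Prophage-provenance virus-host pairs
#'
#' A provirus (a viral genome excised from a host scaffold) is linked to
#' every host genome whose scaffold set contains its source scaffold.
#'
#' @param viralMeta `data.frame` with columns id, source_scaffold (NA for
#'   free viruses).
#' @param scaffoldToGenome `data.frame` with columns scaffold, host_genome
#'   (the binning map).
#' @return `data.frame` with columns virus, host.
#' @export
linkByProphageOrigin <- function(viralMeta, scaffoldToGenome) {
  pro <- viralMeta[!is.na(viralMeta$source_scaffold), , drop = FALSE]
  if (!nrow(pro))
    return(data.frame(virus = character(0), host = character(0),
                      stringsAsFactors = FALSE))
  m <- merge(pro[, c("id", "source_scaffold")], scaffoldToGenome,
             by.x = "source_scaffold", by.y = "scaffold", all.x = TRUE)
  orphan <- is.na(m$host_genome)
  if (any(orphan))
    warning(sum(orphan), " provirus(es) reference unbinned scaffolds; ",
            "no prophage link emitted for them")
  res <- unique(data.frame(virus = m$id[!orphan],
                           host = m$host_genome[!orphan],
                           stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Aggregate genome-level virus-host pairs to population-level links
#'
#' Maps genome-level pairs through vOTU and host-population membership,
#' unions evidence flags, and counts the distinct genome-level pairs behind
#' each population pair as its support.
#'
#' @param pairs `data.frame` with columns virus, host, evidence (one of
#'   "homology", "prophage", "crispr"); one row per genome-level pair and
#'   evidence type.
#' @param votuMap Named vector, viral genome -> virus population (see
#'   [clusterMap()]).
#' @param hostMap Named vector, host genome -> host population.
#' @return `data.frame` with columns virus_population, host_population,
#'   evidence (sorted, "+"-collapsed union) and support.
#' @export
aggregatePopulationLinks <- function(pairs, votuMap, hostMap) {
  empty <- data.frame(virus_population = character(0),
                      host_population = character(0),
                      evidence = character(0), support = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  missV <- setdiff(unique(pairs$virus), names(votuMap))
  missH <- setdiff(unique(pairs$host), names(hostMap))
  if (length(missV) || length(missH))
    stop("genomes missing from clustering: ",
         paste(c(missV, missH), collapse = ", "))
  vp <- unname(votuMap[pairs$virus])
  hp <- unname(hostMap[pairs$host])
  key <- paste(vp, hp, sep = "\r")
  out <- lapply(split(seq_len(nrow(pairs)), key), function(i) {
    data.frame(
      virus_population = vp[i[1L]], host_population = hp[i[1L]],
      evidence = paste(sort(unique(pairs$evidence[i])), collapse = "+"),
      support = length(unique(paste(pairs$virus[i], pairs$host[i]))),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$virus_population, res$host_population), , drop = FALSE]
  rownames(res) <- NULL
  res
}
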