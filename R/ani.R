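# Pairwise nucleotide comparison: built-in aligner and ANI/AF summary.
#
# Near-identical equal-length pairs use a band-0 banded global alignment
# (positionwise comparison; exact under a substitution-only divergence
# model, accepted only when the resulting identity is high). Other pairs use
# exact 15-mer seed-and-extend chaining on single diagonals, with identity
# computed exactly over the chained ungapped span, and a Needleman-Wunsch
# fallback for similar-length pairs the fast paths reject. External tabular
# hits (BLAST-style 12-column format) may be supplied instead.

.seedsOf <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character(0))
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

# Fraction of the shorter sequence's k-mers present in the longer one,
# on either strand.
.kmerContainment <- function(a, b, k = 15L) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  qa <- .seedsOf(a, k)
  if (!length(qa)) return(0)
  tab <- unique(.seedsOf(b, k))
  max(mean(qa %in% tab), mean(.seedsOf(revComp(a), k) %in% tab))
}

.forwardSeedHits <- function(q, s, seedLen, maxGap, minLen) {
  qk <- .seedsOf(q, seedLen)
  sk <- .seedsOf(s, seedLen)
  if (!length(qk) || !length(sk)) return(NULL)
  spos <- split(seq_along(sk), sk)
  hitlist <- spos[qk]
  nper <- lengths(hitlist)
  keep <- nper > 0L
  if (!any(keep)) return(NULL)
  qpos <- rep.int(seq_along(qk)[keep], nper[keep])
  sposv <- unlist(hitlist[keep], use.names = FALSE)
  dg <- qpos - sposv
  o <- order(dg, qpos)
  qpos <- qpos[o]; sposv <- sposv[o]; dg <- dg[o]
  newrun <- c(TRUE, diff(dg) != 0L | diff(qpos) > (maxGap + seedLen))
  run <- cumsum(newrun)
  qs <- tapply(qpos, run, min); qe <- tapply(qpos, run, max) + seedLen - 1L
  ss <- tapply(sposv, run, min); se <- tapply(sposv, run, max) + seedLen - 1L
  len <- qe - qs + 1L
  ok <- len >= minLen
  if (!any(ok)) return(NULL)
  qs <- qs[ok]; qe <- qe[ok]; ss <- ss[ok]; se <- se[ok]; len <- len[ok]
  matches <- mapply(function(a1, a2, b1, b2)
    hammingMatches(substr(q, a1, a2), substr(s, b1, b2)), qs, qe, ss, se)
  data.frame(qstart = as.integer(qs), qend = as.integer(qe),
             sstart = as.integer(ss), send = as.integer(se),
             length = as.integer(len),
             pident = 100 * matches / len,
             mismatch = as.integer(len - matches),
             gapopen = 0L, strand = "+",
             stringsAsFactors = FALSE)
}

#' Find local nucleotide hits between two sequences
#'
#' Exact-seed (15-mer) chained ungapped hits on both strands, reported in
#' BLAST-like tabular columns with 1-based inclusive coordinates
#' (`sstart > send` on the minus strand). Identity is exact over each
#' chained span. Bit scores and E-values use blastn-style +2/-3 ungapped
#' Karlin-Altschul statistics.
#'
#' @param a,b Query and subject sequences (character or
#'   [Biostrings::DNAString]).
#' @param seedLen Exact seed length in bp.
#' @param maxGap Maximum bp between chained seeds on one diagonal.
#' @param minLen Minimum reported hit span in bp.
#' @return `data.frame` with columns qstart, qend, sstart, send, length,
#'   pident, mismatch, gapopen, strand, bitscore, evalue. Zero rows when
#'   nothing aligns.
#' @export
#' @examples
#' v <- strrep("ACGTTGCA", 400)
#' findNucleotideHits(substr(v, 101, 1400), v)
findNucleotideHits <- function(a, b, seedLen = 15L, maxGap = 400L,
                               minLen = 60L) {
  a <- as.character(a); b <- as.character(b)
  fw <- .forwardSeedHits(a, b, seedLen, maxGap, minLen)
  rcB <- revComp(b)
  rv <- .forwardSeedHits(a, rcB, seedLen, maxGap, minLen)
  if (!is.null(rv)) {
    Lb <- nchar(b)
    os <- rv$sstart; oe <- rv$send
    rv$sstart <- Lb - os + 1L  # minus strand: sstart > send
    rv$send <- Lb - oe + 1L
    rv$strand <- "-"
  }
  hits <- rbind(fw, rv)
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      length = integer(0), pident = numeric(0),
                      mismatch = integer(0), gapopen = integer(0),
                      strand = character(0), bitscore = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  ka <- kaStats(round(hits$length * hits$pident / 100), hits$mismatch,
                nchar(a), nchar(b))
  hits$bitscore <- ka$bits
  hits$evalue <- ka$evalue
  hits[order(-hits$bitscore), , drop = FALSE]
}

#' Average nucleotide identity and alignment fraction of a genome pair
#'
#' ANI is the alignment-length-weighted mean percent identity over
#' non-redundant local hits; AF is the fraction of the shorter sequence
#' covered by non-overlapping aligned intervals, in percent. A pair with no
#' alignable region returns `(0, 0)`.
#'
#' @param a,b Sequences (character or [Biostrings::DNAString]).
#' @param hits Optional precomputed hit table (as from
#'   [findNucleotideHits()] or an external 12-column tabular alignment file
#'   read with [readBlastTab()]), with `a` as query and `b` as subject.
#' @return List with elements `ani` and `af`, both percentages in
#'   \eqn{[0, 100]}.
#' @export
#' @examples
#' x <- strrep("ACGGTTCA", 1500)
#' computeAniAf(x, x)
computeAniAf <- function(a, b, hits = NULL) {
  a <- as.character(a); b <- as.character(b)
  La <- nchar(a); Lb <- nchar(b)
  Lshort <- min(La, Lb)
  if (is.null(hits)) {
    # band-0 global fast path for equal-length, near-identical pairs
    if (La == Lb) {
      pid <- 100 * hammingMatches(a, b) / La
      if (pid >= 85) {
        return(list(ani = pid, af = 100))
      }
    }
    frac <- .kmerContainment(a, b)
    if (frac < 0.02) return(list(ani = 0, af = 0))
    hits <- findNucleotideHits(a, b)
    if (!nrow(hits) && min(La, Lb) / max(La, Lb) >= 0.8 && max(La, Lb) <= 3e4) {
      aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
      nid <- Biostrings::nmatch(aln)
      wid <- Biostrings::nchar(aln)
      return(list(ani = 100 * nid / wid, af = 100))
    }
  }
  if (!nrow(hits)) return(list(ani = 0, af = 0))
  # intervals on the shorter sequence
  if (La <= Lb) {
    st <- pmin(hits$qstart, hits$qend); en <- pmax(hits$qstart, hits$qend)
  } else {
    st <- pmin(hits$sstart, hits$send); en <- pmax(hits$sstart, hits$send)
  }
  o <- order(-(hits$length * hits$pident))
  covered <- IRanges::IRanges()
  keep <- logical(nrow(hits))
  for (i in o) {
    r <- IRanges::IRanges(st[i], en[i])
    ov <- sum(IRanges::width(IRanges::intersect(r, covered)))
    if (ov <= 0.5 * IRanges::width(r)) {
      keep[i] <- TRUE
      covered <- IRanges::reduce(c(covered, r))
    }
  }
  kept <- hits[keep, , drop = FALSE]
  ani <- sum(kept$pident * kept$length) / sum(kept$length)
  af <- min(100, 100 * sum(IRanges::width(covered)) / Lshort)
  list(ani = ani, af = af)
}

#' Read a 12-column tabular alignment file
#'
#' Standard BLAST `-outfmt 6` layout: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path File path.
#' @return `data.frame` with those columns.
#' @export
readBlastTab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 12L)
    stop("expected 12 tab-separated columns, found ", ncol(x))
  names(x) <- cols
  x
}

#' Search nucleotide homology between two genome sets
#'
#' All-vs-all hit search (viral genomes as queries against host genomes)
#' with a shared-k-mer prefilter, returning one combined 12-column tabular
#' hit table suitable for [linkByGenomeHomology()].
#'
#' @param queries,subjects Named [Biostrings::DNAStringSet] objects.
#' @param minContainment Shared 15-mer fraction below which a pair is
#'   skipped without alignment.
#' @param ... Passed to [findNucleotideHits()].
#' @return `data.frame` in 12-column tabular layout (qseqid, sseqid,
#'   pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#'   evalue, bitscore).
#' @export
searchHomology <- function(queries, subjects, minContainment = 0.02, ...) {
  qs <- as.character(queries)
  ss <- as.character(subjects)
  sKmerSets <- lapply(ss, function(s) unique(.seedsOf(s, 15L)))
  out <- list()
  for (qn in names(qs)) {
    qk <- .seedsOf(qs[[qn]], 15L)
    qkr <- .seedsOf(revComp(qs[[qn]]), 15L)
    for (sn in names(ss)) {
      if (!length(qk) ||
          max(mean(qk %in% sKmerSets[[sn]]),
              mean(qkr %in% sKmerSets[[sn]])) < minContainment)
        next
      h <- findNucleotideHits(qs[[qn]], ss[[sn]], ...)
      if (nrow(h)) {
        out[[length(out) + 1L]] <- data.frame(
          qseqid = qn, sseqid = sn, pident = h$pident, length = h$length,
          mismatch = h$mismatch, gapopen = h$gapopen, qstart = h$qstart,
          qend = h$qend, sstart = h$sstart, send = h$send,
          evalue = h$evalue, bitscore = h$bitscore,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
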