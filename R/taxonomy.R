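# Majority-rule lowest-common-ancestor taxonomy from per-protein hits.
# Lineages are root-to-leaf semicolon paths, e.g.
# "Caudovirales;Myoviridae".

.splitLineage <- function(x) strsplit(x, ";", fixed = TRUE)

#' Lowest common ancestor of a set of lineages
#'
#' Returns the deepest lineage prefix shared by all inputs; an empty shared
#' prefix yields `""` (unclassified).
#'
#' @param lineages Character vector of semicolon-separated root-to-leaf
#'   lineage paths.
#' @return Single lineage string (possibly `""`).
#' @export
#' @examples
#' lowestCommonAncestor(c("Caudovirales;Myoviridae",
#'                        "Caudovirales;Siphoviridae"))
lowestCommonAncestor <- function(lineages) {
  if (!length(lineages)) stop("non-empty lineage list required")
  parts <- .splitLineage(lineages)
  depth <- min(lengths(parts))
  out <- character(0)
  for (d in seq_len(depth)) {
    tax <- vapply(parts, `[[`, "", d)
    if (length(unique(tax)) != 1L) break
    out <- c(out, tax[1L])
  }
  paste(out, collapse = ";")
}

#' Classify a viral genome from its annotated proteins
#'
#' Majority-rule LCA: assigns the deepest taxon supported by more than
#' `minFraction` of the genome's annotated proteins, walking up ranks until
#' the support test passes. With `minFraction = 1` this reduces to the
#' strict LCA of all hits. Genomes with no annotated proteins are
#' unclassified.
#'
#' @param proteinLineages Character vector, one best-hit lineage per
#'   annotated protein (bit score and E-value filtering happens upstream).
#' @param minFraction Required support fraction in (0, 1].
#' @return Lineage string (possibly `""` for unclassified).
#' @export
#' @examples
#' classifyGenome(c(rep("Caudovirales;Myoviridae", 8),
#'                  rep("Caudovirales;Siphoviridae", 2)))
classifyGenome <- function(proteinLineages, minFraction = 0.5) {
  if (minFraction <= 0 || minFraction > 1)
    stop("minFraction must be in (0, 1]")
  proteinLineages <- proteinLineages[!is.na(proteinLineages) &
                                       nzchar(proteinLineages)]
  n <- length(proteinLineages)
  if (n == 0L) return("")
  parts <- .splitLineage(proteinLineages)
  maxDepth <- max(lengths(parts))
  for (d in rev(seq_len(maxDepth))) {
    paths <- vapply(parts, function(p) {
      if (length(p) < d) NA_character_
      else paste(p[seq_len(d)], collapse = ";")
    }, "")
    tab <- table(paths[!is.na(paths)])
    if (!length(tab)) next
    best <- which.max(tab)
    supp <- if (minFraction == 1) tab[best] >= n else tab[best] > minFraction * n
    if (supp) return(names(tab)[best])
  }
  ""
}
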