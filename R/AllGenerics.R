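#' Extract the abundance matrix
#'
#' @param x An [AbundanceMatrix-class].
#' @return Numeric matrix of normalized coverages (entities x samples).
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname abundance
#' @export
setMethod("abundance", "AbundanceMatrix", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' Per-sample library sizes (reads)
#'
#' @param x An [AbundanceMatrix-class].
#' @return Named numeric vector of read counts per sample.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "AbundanceMatrix", function(x) {
  ls <- SummarizedExperiment::colData(x)$library_size
  names(ls) <- colnames(x)
  ls
})

#' Incidence matrix of a bipartite network
#'
#' @param x A [BipartiteNetwork-class].
#' @return Binary matrix, viruses in rows, hosts in columns.
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname incidence
#' @export
setMethod("incidence", "BipartiteNetwork", function(x) x@incidence)

#' Virus node ids of a bipartite network
#' @param x A [BipartiteNetwork-class].
#' @return Character vector.
#' @export
setGeneric("virusNodes", function(x) standardGeneric("virusNodes"))

#' @rdname virusNodes
#' @export
setMethod("virusNodes", "BipartiteNetwork", function(x) rownames(x@incidence))

#' Host node ids of a bipartite network
#' @param x A [BipartiteNetwork-class].
#' @return Character vector.
#' @export
setGeneric("hostNodes", function(x) standardGeneric("hostNodes"))

#' @rdname hostNodes
#' @export
setMethod("hostNodes", "BipartiteNetwork", function(x) colnames(x@incidence))
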