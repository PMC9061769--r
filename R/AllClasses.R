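#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

#' AbundanceMatrix: entities-by-samples normalized coverage
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay, `"abundance"` (non-negative normalized coverage), with per-sample
#' sequencing depths in `colData()$library_size`. Rows are genomes, genes, or
#' protein clusters; columns are samples.
#'
#' @slot . inherits all slots from `SummarizedExperiment`.
#' @seealso [buildAbundanceMatrix()], [abundance()], [librarySizes()]
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!"abundance" %in% a)
    return("assay 'abundance' is required")
  v <- SummarizedExperiment::assay(object, "abundance")
  if (!is.numeric(v)) return("abundance values must be numeric")
  if (any(!is.finite(v))) return("abundance values must be finite")
  if (any(v < 0)) return("abundance values must be non-negative")
  ls <- SummarizedExperiment::colData(object)$library_size
  if (is.null(ls)) return("colData()$library_size is required")
  if (any(!is.finite(ls)) || any(ls <= 0))
    return("library sizes must be positive and finite")
  TRUE
})

#' Construct an AbundanceMatrix
#'
#' @param values Non-negative numeric matrix, entities in rows and samples in
#'   columns, with dimnames.
#' @param librarySizes Positive numeric vector of per-sample read counts,
#'   named by sample or in column order.
#' @return An [AbundanceMatrix-class] object.
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' AbundanceMatrix(m, librarySizes = c(s1 = 1e6, s2 = 2e6, s3 = 1e6))
AbundanceMatrix <- function(values, librarySizes) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry entity rownames and sample colnames")
  if (!is.null(names(librarySizes))) {
    miss <- setdiff(colnames(values), names(librarySizes))
    if (length(miss))
      stop("library sizes missing for samples: ", paste(miss, collapse = ", "))
    librarySizes <- librarySizes[colnames(values)]
  } else if (length(librarySizes) != ncol(values)) {
    stop("librarySizes length must match the number of samples")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    colData = S4Vectors::DataFrame(library_size = unname(librarySizes),
                                   row.names = colnames(values))
  )
  methods::new("AbundanceMatrix", se)
}

#' BipartiteNetwork: binary virus-host incidence
#'
#' Virus populations in rows, host populations in columns; an entry of 1
#' records at least one predicted infection link.
#'
#' @slot incidence Binary matrix (viruses x hosts) with unique dimnames.
#' @seealso [buildNetwork()], [barberModularity()], [nodf()]
#' @export
setClass("BipartiteNetwork", representation(incidence = "matrix"))

setValidity("BipartiteNetwork", function(object) {
  m <- object@incidence
  if (!is.numeric(m)) return("incidence must be numeric")
  if (length(m) && !all(m %in% c(0, 1))) return("incidence entries must be 0/1")
  if (length(m) && (is.null(rownames(m)) || is.null(colnames(m))))
    return("incidence must carry virus rownames and host colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    return("node ids must be unique")
  TRUE
})

#' Construct a BipartiteNetwork from an incidence matrix
#'
#' @param incidence Binary matrix, viruses in rows, hosts in columns.
#' @return A [BipartiteNetwork-class].
#' @export
BipartiteNetwork <- function(incidence) {
  methods::new("BipartiteNetwork", incidence = as.matrix(incidence))
}

setMethod("show", "BipartiteNetwork", function(object) {
  m <- object@incidence
  cat("BipartiteNetwork:", nrow(m), "virus x", ncol(m), "host populations,",
      sum(m), "links\n")
})

setMethod("show", "AbundanceMatrix", function(object) {
  cat("AbundanceMatrix:", nrow(object), "entities x", ncol(object),
      "samples (normalized coverage)\n")
  methods::callNextMethod()
})
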