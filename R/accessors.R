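#' Accessors for GBS containers
#'
#' `depthA()` / `depthB()` return the per-allele depth matrices, `totalDepth()`
#' their sum, `snpAlleles()` the per-SNP allele pair, `genotypeCalls()` the
#' genotype matrix, `filterLabel()` the filter that produced a genotype set,
#' and `sampleInfo()` the sample table stored in `colData()`.
#'
#' @param x a [GBSDepthSet-class] or [GBSGenotypes-class] object.
#' @name gbs-accessors
NULL

#' @rdname gbs-accessors
#' @export
setGeneric("depthA", function(x) standardGeneric("depthA"))
#' @rdname gbs-accessors
#' @export
setGeneric("depthB", function(x) standardGeneric("depthB"))
#' @rdname gbs-accessors
#' @export
setGeneric("totalDepth", function(x) standardGeneric("totalDepth"))
#' @rdname gbs-accessors
#' @export
setGeneric("snpAlleles", function(x) standardGeneric("snpAlleles"))
#' @rdname gbs-accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname gbs-accessors
#' @export
setGeneric("filterLabel", function(x) standardGeneric("filterLabel"))
#' @rdname gbs-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname gbs-accessors
setMethod("depthA", "GBSDepthSet", function(x) assay(x, "depthA"))
#' @rdname gbs-accessors
setMethod("depthB", "GBSDepthSet", function(x) assay(x, "depthB"))
#' @rdname gbs-accessors
setMethod("totalDepth", "GBSDepthSet",
          function(x) assay(x, "depthA") + assay(x, "depthB"))
#' @rdname gbs-accessors
setMethod("snpAlleles", "GBSDepthSet", function(x)
  as.data.frame(rowData(x)[, c("allele1", "allele2"), drop = FALSE]))
#' @rdname gbs-accessors
setMethod("snpAlleles", "GBSGenotypes", function(x) {
  rd <- rowData(x)
  if (!all(c("allele1", "allele2") %in% colnames(rd))) return(NULL)
  as.data.frame(rd[, c("allele1", "allele2"), drop = FALSE])
})
#' @rdname gbs-accessors
setMethod("genotypeCalls", "GBSGenotypes", function(x) assay(x, "genotype"))
#' @rdname gbs-accessors
setMethod("filterLabel", "GBSGenotypes",
          function(x) metadata(x)$filter %||% "none")
#' @rdname gbs-accessors
setMethod("sampleInfo", "GBSDepthSet", function(x) as.data.frame(colData(x)))
#' @rdname gbs-accessors
setMethod("sampleInfo", "GBSGenotypes", function(x) as.data.frame(colData(x)))

setMethod("show", "GBSDepthSet", function(object) {
  cat(sprintf("GBSDepthSet: %d SNPs x %d samples\n",
              nrow(object), ncol(object)))
  td <- totalDepth(object)
  cat(sprintf("  mean total depth %.2f; %.1f%% zero-depth cells\n",
              mean(td), 100 * mean(td == 0)))
  if ("population_id" %in% colnames(colData(object)))
    cat("  populations:",
        paste(unique(colData(object)$population_id), collapse = ", "), "\n")
})

setMethod("show", "GBSGenotypes", function(object) {
  g <- assay(object, "genotype")
  cat(sprintf("GBSGenotypes (filter '%s'): %d SNPs x %d samples\n",
              filterLabel(object), nrow(object), ncol(object)))
  cat(sprintf("  %.1f%% missing (NN), %.1f%% ambiguous (?)\n",
              100 * mean(g == "NN"),
              100 * mean(grepl("?", g, fixed = TRUE))))
})
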