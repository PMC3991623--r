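#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

GENOTYPE_ALPHABET <- c("A", "C", "G", "T", "?", "N")
GENOTYPE_CELL_RE <- "^[ACGT?N][ACGT?N]$"

## A cell is valid iff both characters are in the alphabet, "N" occurs only as
## the fully-missing "NN", and "?" never co-occurs with "N".
validGenotypeCells <- function(cells) {
  ok <- grepl(GENOTYPE_CELL_RE, cells)
  hasN <- grepl("N", cells, fixed = TRUE)
  ok & (!hasN | cells == "NN")
}

#' Per-SNP allele read depths for a set of samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two integer assays,
#' `depthA` and `depthB`, holding the read depth of each SNP's first and second
#' allele in each sample. `rowData()` carries at least `allele1` and `allele2`
#' (single nucleotides); tag-pair metadata (`tag1`, `tag2`, `offset`) is kept
#' when the object originates from tag-based SNP calling. `colData()` holds the
#' sample table (`sample_id`, `individual_id`, `population_id`, `region_id`)
#' when one is available.
#'
#' @export
setClass("GBSDepthSet", contains = "SummarizedExperiment")

setValidity("GBSDepthSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("depthA", "depthB") %in% an))
    return("assays 'depthA' and 'depthB' are required")
  dA <- assay(object, "depthA"); dB <- assay(object, "depthB")
  if (any(dA < 0, na.rm = TRUE) || any(dB < 0, na.rm = TRUE))
    return("allele depths must be non-negative")
  rd <- rowData(object)
  if (!all(c("allele1", "allele2") %in% colnames(rd)))
    return("rowData must carry 'allele1' and 'allele2'")
  if (any(!rd$allele1 %in% c("A", "C", "G", "T")) ||
      any(!rd$allele2 %in% c("A", "C", "G", "T")))
    return("alleles must be single nucleotides A/C/G/T")
  TRUE
})

#' Construct a GBSDepthSet
#'
#' @param depthA,depthB integer matrices (SNP x sample) of read depths for each
#'   SNP's first and second allele. Dimnames of `depthA` are used for SNP and
#'   sample identifiers.
#' @param alleles data.frame-like with columns `allele1`, `allele2` (and
#'   optionally `tag1`, `tag2`, `offset`, `chrom`, `pos`), one row per SNP.
#' @param sampleTable optional sample table (see [readSampleTable()]) whose
#'   `sample_id` column matches the depth-matrix columns.
#' @return a [GBSDepthSet-class] object.
#' @export
GBSDepthSet <- function(depthA, depthB, alleles, sampleTable = NULL) {
  depthA <- as.matrix(depthA)
  depthB <- as.matrix(depthB)
  stopifnot(identical(dim(depthA), dim(depthB)))
  storage.mode(depthA) <- "integer"
  storage.mode(depthB) <- "integer"
  rd <- DataFrame(alleles)
  cd <- if (is.null(sampleTable)) {
    DataFrame(sample_id = colnames(depthA) %||% paste0("S", seq_len(ncol(depthA))))
  } else {
    st <- as.data.frame(sampleTable)
    idx <- match(colnames(depthA), st$sample_id)
    if (anyNA(idx))
      stop("sample table does not cover samples: ",
           paste(colnames(depthA)[is.na(idx)], collapse = ", "))
    DataFrame(st[idx, , drop = FALSE])
  }
  rownames(cd) <- colnames(depthA)
  se <- SummarizedExperiment(
    assays = list(depthA = depthA, depthB = depthB),
    rowData = rd, colData = cd)
  new("GBSDepthSet", se)
}

#' Called genotypes for a set of SNPs and samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one character assay,
#' `genotype`, of two-character cells over `{A,C,G,T,?,N}`. `"NN"` marks a
#' fully missing cell; `"?"` marks a deliberately unasserted second allele
#' (only the ambiguity filter produces it). `metadata()$filter` records which
#' filtering strategy produced the calls.
#'
#' @export
setClass("GBSGenotypes", contains = "SummarizedExperiment")

setValidity("GBSGenotypes", function(object) {
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotype' is required")
  g <- assay(object, "genotype")
  bad <- !validGenotypeCells(g)
  if (any(bad)) {
    i <- which(bad)[1L]
    rc <- arrayInd(i, dim(g))
    return(sprintf("invalid genotype cell '%s' at row %d, column %d",
                   g[i], rc[1L], rc[2L]))
  }
  TRUE
})

#' Construct a GBSGenotypes object
#'
#' @param genotype character matrix (SNP x sample) of two-character genotype
#'   cells.
#' @param alleles optional data.frame-like with per-SNP `allele1`, `allele2`.
#' @param sampleTable optional sample table matched on `sample_id`.
#' @param filter label of the filtering strategy that produced the calls
#'   (`"none"`, `"tf"`, `"af"`, `"maff"` or a free-form label).
#' @return a [GBSGenotypes-class] object.
#' @export
GBSGenotypes <- function(genotype, alleles = NULL, sampleTable = NULL,
                         filter = "none") {
  genotype <- as.matrix(genotype)
  rd <- if (is.null(alleles)) DataFrame(row.names = rownames(genotype))
        else DataFrame(alleles)
  cd <- if (is.null(sampleTable)) {
    DataFrame(sample_id = colnames(genotype) %||% paste0("S", seq_len(ncol(genotype))))
  } else {
    st <- as.data.frame(sampleTable)
    idx <- match(colnames(genotype), st$sample_id)
    if (anyNA(idx))
      stop("sample table does not cover samples: ",
           paste(colnames(genotype)[is.na(idx)], collapse = ", "))
    DataFrame(st[idx, , drop = FALSE])
  }
  rownames(cd) <- colnames(genotype)
  se <- SummarizedExperiment(assays = list(genotype = genotype),
                             rowData = rd, colData = cd)
  out <- new("GBSGenotypes", se)
  metadata(out)$filter <- filter
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
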