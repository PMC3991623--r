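#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that upper-cases
#' sequences, keeps IUPAC letters, and rejects duplicate or empty records.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readFastaGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ## readDNAStringSet keeps the full header; the id is the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) == 0) stop("FASTA file has no records: ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0))
    stop("empty sequence record in FASTA: ",
         paste(names(seqs)[Biostrings::width(seqs) == 0], collapse = ", "))
  seqs
}

#' Read gene intervals from a GFF3 file
#'
#' Selects features of type `"gene"` and returns intervals in the package's
#' internal 0-based half-open convention. This is the only place where the
#' 1-based closed GFF convention is converted.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `scaffold`, `start` (0-based), `end`
#'   (half-open exclusive), `gene_id`.
#' @export
readGffGenes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0)
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), gene_id = character()))
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
    stop("GFF3 gene with end < start")
  ids <- gr$ID
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene_id = as.character(ids))
}

#' Read and write the HapMap genotype dialect
#'
#' Tab-delimited table with header columns `rs#`, `alleles`, `chrom`, `pos`,
#' `strand`, then one column per sample. Genotype cells are two-character
#' strings over `{A,C,G,T,?,N}`; a fully missing cell is written `"NN"`.
#' `writeHapMap()` followed by `readHapMap()` is the identity on genotype
#' content.
#'
#' @param path file path.
#' @param x a [GBSGenotypes-class] object.
#' @param sampleTable optional sample table attached to the result.
#' @return `readHapMap()` returns a [GBSGenotypes-class]; `writeHapMap()`
#'   returns `path` invisibly.
#' @export
readHapMap <- function(path, sampleTable = NULL) {
  if (!file.exists(path)) stop("HapMap file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "")
  fixed <- c("rs#", "alleles", "chrom", "pos", "strand")
  if (!all(fixed %in% colnames(tab)))
    stop("HapMap header must start with columns: ", paste(fixed, collapse = ", "))
  sampleCols <- setdiff(colnames(tab), fixed)
  if (length(sampleCols) == 0) stop("HapMap file has no sample columns")
  g <- as.matrix(tab[, sampleCols, drop = FALSE])
  rownames(g) <- tab[["rs#"]]
  bad <- !validGenotypeCells(g)
  if (any(bad)) {
    i <- which(bad)[1L]
    rc <- arrayInd(i, dim(g))
    stop(sprintf("invalid genotype cell '%s' at data row %d, sample column '%s'",
                 g[i], rc[1L], sampleCols[rc[2L]]))
  }
  al <- strsplit(tab$alleles, "/", fixed = TRUE)
  if (any(lengths(al) != 2))
    stop("alleles column must list two alleles separated by '/'")
  alleles <- DataFrame(
    allele1 = vapply(al, `[`, "", 1L),
    allele2 = vapply(al, `[`, "", 2L),
    chrom = tab$chrom, pos = as.integer(tab$pos), strand = tab$strand)
  GBSGenotypes(g, alleles = alleles, sampleTable = sampleTable)
}

#' @rdname readHapMap
#' @export
writeHapMap <- function(x, path) {
  stopifnot(is(x, "GBSGenotypes"))
  g <- genotypeCalls(x)
  rd <- rowData(x)
  al <- if (all(c("allele1", "allele2") %in% colnames(rd)))
    paste0(rd$allele1, "/", rd$allele2) else rep("N/N", nrow(g))
  out <- data.frame(
    `rs#` = rownames(g) %||% paste0("snp", seq_len(nrow(g))),
    alleles = al,
    chrom = if ("chrom" %in% colnames(rd)) as.character(rd$chrom) else "0",
    pos = if ("pos" %in% colnames(rd)) as.integer(rd$pos) else seq_len(nrow(g)),
    strand = if ("strand" %in% colnames(rd)) as.character(rd$strand) else "+",
    check.names = FALSE)
  out <- cbind(out, as.data.frame(g, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the tag-count (allele depth) dialect
#'
#' TSV with columns `snp_id`, `tag1_seq`, `tag2_seq`, `snp_offset` (0-based
#' position of the single difference within the tag), then one `"d1|d2"` cell
#' per sample giving the read depth of the tag1 and tag2 alleles.
#'
#' @param path file path.
#' @param x a [GBSDepthSet-class] with tag metadata in `rowData()`.
#' @param sampleTable optional sample table attached to the result.
#' @return `readTagCounts()` returns a [GBSDepthSet-class]; `writeTagCounts()`
#'   returns `path` invisibly.
#' @export
readTagCounts <- function(path, sampleTable = NULL) {
  if (!file.exists(path)) stop("tag-count file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "")
  fixed <- c("snp_id", "tag1_seq", "tag2_seq", "snp_offset")
  if (!all(fixed %in% colnames(tab)))
    stop("tag-count header must contain columns: ", paste(fixed, collapse = ", "))
  sampleCols <- setdiff(colnames(tab), fixed)
  if (length(sampleCols) == 0) stop("tag-count file has no sample columns")
  off <- as.integer(tab$snp_offset)
  if (any(nchar(tab$tag1_seq) != nchar(tab$tag2_seq)))
    stop("tag sequences must be equal length")
  a1 <- substr(tab$tag1_seq, off + 1L, off + 1L)
  a2 <- substr(tab$tag2_seq, off + 1L, off + 1L)
  for (i in seq_len(nrow(tab))) {
    d <- which(strsplit(tab$tag1_seq[i], "")[[1]] != strsplit(tab$tag2_seq[i], "")[[1]])
    if (!identical(d, off[i] + 1L))
      stop("tags of '", tab$snp_id[i],
           "' must differ at exactly the snp_offset position")
  }
  parse1 <- function(cells, which) {
    parts <- strsplit(cells, "|", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("depth cells must be 'd1|d2'")
    v <- as.integer(vapply(parts, `[`, "", which))
    if (anyNA(v) || any(v < 0)) stop("depths must be non-negative integers")
    v
  }
  dA <- sapply(sampleCols, function(s) parse1(tab[[s]], 1L))
  dB <- sapply(sampleCols, function(s) parse1(tab[[s]], 2L))
  dA <- matrix(dA, nrow = nrow(tab), dimnames = list(tab$snp_id, sampleCols))
  dB <- matrix(dB, nrow = nrow(tab), dimnames = list(tab$snp_id, sampleCols))
  GBSDepthSet(dA, dB,
              alleles = DataFrame(allele1 = a1, allele2 = a2,
                                  tag1 = tab$tag1_seq, tag2 = tab$tag2_seq,
                                  offset = off),
              sampleTable = sampleTable)
}

#' @rdname readTagCounts
#' @export
writeTagCounts <- function(x, path) {
  stopifnot(is(x, "GBSDepthSet"))
  rd <- rowData(x)
  if (!all(c("tag1", "tag2", "offset") %in% colnames(rd)))
    stop("rowData must carry tag1/tag2/offset to write tag counts")
  dA <- depthA(x); dB <- depthB(x)
  cells <- matrix(paste0(dA, "|", dB), nrow = nrow(dA),
                  dimnames = dimnames(dA))
  out <- data.frame(snp_id = rownames(dA) %||% paste0("snp", seq_len(nrow(dA))),
                    tag1_seq = rd$tag1, tag2_seq = rd$tag2,
                    snp_offset = rd$offset, check.names = FALSE)
  out <- cbind(out, as.data.frame(cells, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' TSV with columns `sample_id`, `individual_id`, `population_id`,
#' `region_id`. Replicate samples of one individual share `individual_id`;
#' every population must map to exactly one region.
#'
#' @param path file path.
#' @return data.frame with the four columns above.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  validateSampleTable(tab)
}

validateSampleTable <- function(tab) {
  need <- c("sample_id", "individual_id", "population_id", "region_id")
  if (!all(need %in% colnames(tab)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in sample table")
  p2r <- unique(tab[, c("population_id", "region_id")])
  if (anyDuplicated(p2r$population_id))
    stop("a population maps to more than one region")
  tab
}

#' Write or read restriction-site / locus coordinates as BED
#'
#' BED is 0-based half-open; site records are written as 5-bp motif intervals,
#' locus sets as the motif-start coordinate. `readLocusBed()` returns locus
#' identifiers of the form `"scaffold:start0"` for use as a replicate locus
#' set.
#'
#' @param catalog a site catalog from [findRestrictionSites()].
#' @param path file path.
#' @return `readLocusBed()` returns a character vector of locus ids.
#' @export
writeSiteBed <- function(catalog, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(catalog)),
    start = GenomicRanges::start(catalog) - 1L,
    end = GenomicRanges::end(catalog),
    name = if (!is.null(catalog$in_gene))
      ifelse(catalog$in_gene, "in_gene", "intergenic") else ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteBed
#' @export
readLocusBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  paste0(tab[[1]], ":", as.integer(tab[[2]]))
}

#' Express a count ratio as the percentage a report would print
#'
#' Reporting utility used by the pipeline's summaries: `percentOf(212376,
#' 462987)` is the in-gene percentage of in silico restriction sites.
#'
#' @param numerator,denominator non-negative counts.
#' @return numeric percentage (0-100), unrounded.
#' @export
percentOf <- function(numerator, denominator) {
  stopifnot(denominator > 0, numerator >= 0)
  100 * numerator / denominator
}
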