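#' Trim reads and collapse identical tags
#'
#' Reads are truncated to their first `tagLength` bases; shorter reads and
#' reads containing non-ACGT characters are discarded (counts logged as
#' attributes). Identical trimmed reads are collated into tags with per-sample
#' counts.
#'
#' @param readsPerSample named list of character vectors of reads (one vector
#'   per sample), or of [Biostrings::DNAStringSet] objects.
#' @param tagLength tag length in bases (default 64).
#' @return integer matrix of tag counts (tags x samples) with tag sequences as
#'   rownames; attributes `n_short` and `n_bad_base` record discarded reads.
#' @export
trimAndCollapse <- function(readsPerSample, tagLength = 64) {
  stopifnot(length(readsPerSample) > 0, tagLength > 0)
  if (is.null(names(readsPerSample)))
    names(readsPerSample) <- paste0("S", seq_along(readsPerSample))
  nShort <- 0L; nBad <- 0L
  perSample <- lapply(readsPerSample, function(rd) {
    rd <- toupper(as.character(rd))
    short <- nchar(rd) < tagLength
    nShort <<- nShort + sum(short)
    rd <- substr(rd[!short], 1L, tagLength)
    bad <- grepl("[^ACGT]", rd)
    nBad <<- nBad + sum(bad)
    table(rd[!bad])
  })
  tags <- sort(unique(unlist(lapply(perSample, names), use.names = FALSE)))
  out <- matrix(0L, nrow = length(tags), ncol = length(perSample),
                dimnames = list(tags, names(readsPerSample)))
  for (j in seq_along(perSample)) {
    t <- perSample[[j]]
    out[names(t), j] <- as.integer(t)
  }
  out <- out[rowSums(out) > 0, , drop = FALSE]
  attr(out, "n_short") <- nShort
  attr(out, "n_bad_base") <- nBad
  out
}

## All unordered pairs of tags at Hamming distance exactly 1, found via the
## two-half partition trick: distance-1 pairs agree exactly on at least one
## half of the sequence.
hamming1Pairs <- function(tags) {
  n <- length(tags)
  if (n < 2) return(matrix(integer(), ncol = 2))
  L <- nchar(tags[1])
  half <- L %/% 2
  left <- substr(tags, 1L, half)
  right <- substr(tags, half + 1L, L)
  cand <- list()
  for (key in list(left, right)) {
    grp <- split(seq_len(n), key)
    grp <- grp[lengths(grp) > 1]
    for (g in grp)
      cand[[length(cand) + 1L]] <- t(utils::combn(g, 2L))
  }
  if (length(cand) == 0) return(matrix(integer(), ncol = 2))
  cand <- unique(do.call(rbind, cand))
  m <- do.call(rbind, strsplit(tags, ""))
  d <- vapply(seq_len(nrow(cand)), function(i)
    sum(m[cand[i, 1], ] != m[cand[i, 2], ]), 0L)
  cand[d == 1L, , drop = FALSE]
}

#' Pair tags into candidate SNPs
#'
#' Tag pairs at Hamming distance exactly 1 become candidate SNPs. Network
#' resolution: a tag participating in more than one distance-1 pair is
#' excluded entirely, together with every pair it belongs to, so only
#' reciprocally unique pairs yield SNPs.
#'
#' @param tagTable tag-count matrix from [trimAndCollapse()].
#' @param sampleTable optional sample table for the result's `colData`.
#' @return a [GBSDepthSet-class] whose rows are candidate SNPs; `rowData`
#'   carries `tag1`, `tag2`, `offset` (0-based) and the two alleles.
#' @export
pairTags <- function(tagTable, sampleTable = NULL) {
  stopifnot(nrow(tagTable) > 0)
  tags <- rownames(tagTable)
  prs <- hamming1Pairs(tags)
  if (nrow(prs) > 0) {
    deg <- tabulate(c(prs[, 1], prs[, 2]), nbins = length(tags))
    keep <- deg[prs[, 1]] == 1L & deg[prs[, 2]] == 1L
    prs <- prs[keep, , drop = FALSE]
  }
  if (nrow(prs) == 0) {
    empty <- matrix(integer(), nrow = 0, ncol = ncol(tagTable),
                    dimnames = list(NULL, colnames(tagTable)))
    return(GBSDepthSet(empty, empty,
                       alleles = DataFrame(allele1 = character(),
                                           allele2 = character(),
                                           tag1 = character(),
                                           tag2 = character(),
                                           offset = integer()),
                       sampleTable = sampleTable))
  }
  ## order each pair lexicographically so output is input-order invariant
  swap <- tags[prs[, 1]] > tags[prs[, 2]]
  prs[swap, ] <- prs[swap, c(2, 1)]
  prs <- prs[order(tags[prs[, 1]]), , drop = FALSE]
  t1 <- tags[prs[, 1]]; t2 <- tags[prs[, 2]]
  off <- mapply(function(a, b) {
    which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) - 1L
  }, t1, t2, USE.NAMES = FALSE)
  dA <- tagTable[prs[, 1], , drop = FALSE]
  dB <- tagTable[prs[, 2], , drop = FALSE]
  ids <- paste0("snp", seq_len(nrow(prs)))
  dimnames(dA) <- list(ids, colnames(tagTable))
  dimnames(dB) <- list(ids, colnames(tagTable))
  GBSDepthSet(dA, dB,
              alleles = DataFrame(
                allele1 = substr(t1, off + 1L, off + 1L),
                allele2 = substr(t2, off + 1L, off + 1L),
                tag1 = t1, tag2 = t2, offset = off),
              sampleTable = sampleTable)
}

#' Remove SNPs exceeding the read-depth cap
#'
#' Removes candidate SNPs whose depth exceeds `cap`, to eliminate loci with
#' multiple genomic copies. With `scope = "sample"` (default) a SNP is removed
#' if any single sample's summed allele depth `d1 + d2` exceeds the cap; with
#' `scope = "total"` the cap applies to the depth summed across samples.
#'
#' @param x a [GBSDepthSet-class].
#' @param cap maximum allowed depth (default 127).
#' @param scope `"sample"` or `"total"`.
#' @return the filtered [GBSDepthSet-class]; removed-row count in
#'   `metadata()$n_removed_depth_cap`.
#' @export
depthCapFilter <- function(x, cap = 127, scope = c("sample", "total")) {
  stopifnot(cap > 0)
  scope <- match.arg(scope)
  td <- totalDepth(x)
  drop <- if (scope == "sample") apply(td, 1, max) > cap
          else rowSums(td) > cap
  out <- x[!drop, ]
  metadata(out)$n_removed_depth_cap <- sum(drop)
  out
}

#' Remove SNPs with low population minor allele frequency
#'
#' The minor allele frequency is computed from allele depths summed over all
#' samples: `min(sum d1, sum d2) / sum(d1 + d2)`. SNPs with MAF strictly below
#' `minMaf` are removed; SNPs with zero total depth are removed and counted
#' separately.
#'
#' @param x a [GBSDepthSet-class].
#' @param minMaf minimum minor allele frequency (default 0.05).
#' @return the filtered [GBSDepthSet-class]; metadata records
#'   `n_removed_maf` and `n_removed_zero_depth`.
#' @export
mafPrefilter <- function(x, minMaf = 0.05) {
  stopifnot(minMaf >= 0, minMaf <= 0.5)
  s1 <- rowSums(depthA(x)); s2 <- rowSums(depthB(x))
  tot <- s1 + s2
  zero <- tot == 0
  maf <- ifelse(zero, NA_real_, pmin(s1, s2) / tot)
  drop <- zero | (!zero & maf < minMaf)
  out <- x[!drop, ]
  metadata(out)$n_removed_maf <- sum(!zero & maf < minMaf)
  metadata(out)$n_removed_zero_depth <- sum(zero)
  out
}

#' Reference-free tag-pair SNP calling
#'
#' Full calling pipeline: trim reads to `tagLength` and collapse into tags,
#' pair tags differing at a single base (with network resolution), remove
#' SNPs over the depth cap, and remove SNPs below the population minor allele
#' frequency threshold.
#'
#' @param readsPerSample named list of per-sample read vectors.
#' @param tagLength tag length (default 64).
#' @param depthCap per-sample depth cap (default 127).
#' @param minMaf MAF pre-filter threshold (default 0.05).
#' @param capScope see [depthCapFilter()].
#' @param sampleTable optional sample table.
#' @return a [GBSDepthSet-class] of called SNPs.
#' @export
callSNPs <- function(readsPerSample, tagLength = 64, depthCap = 127,
                     minMaf = 0.05, capScope = "sample", sampleTable = NULL) {
  tt <- trimAndCollapse(readsPerSample, tagLength = tagLength)
  x <- pairTags(tt, sampleTable = sampleTable)
  x <- depthCapFilter(x, cap = depthCap, scope = capScope)
  mafPrefilter(x, minMaf = minMaf)
}
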