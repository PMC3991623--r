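#' Call genotypes from allele depths under a filtering strategy
#'
#' Converts each allele-depth cell `(d1, d2)` into a two-character genotype:
#'
#' * `"none"` (unfiltered): both alleles observed → heterozygote; exactly one
#'   observed → homozygote; no reads → `"NN"`.
#' * `"tf"` (threshold filter, depth threshold `t`): an allele with fewer than
#'   `t` reads is treated as unobserved; both remaining → heterozygote, one →
#'   homozygote, none (or total depth below `t`) → `"NN"`.
#' * `"af"` (ambiguity filter): as TF, but a single-allele call backed by
#'   `t` to `2t - 1` reads is scored `"X?"` — the second allele is left
#'   unasserted — while `2t` or more reads score the full homozygote.
#' * `"maff"` (within-genotype minor-allele-fraction filter, threshold 0.45):
#'   with `m = min(d1, d2) / (d1 + d2)`, `m >= threshold` → heterozygote,
#'   otherwise homozygote for the majority allele; nothing is discarded for
#'   low depth, only `(0, 0)` is `"NN"`. Ties (`m = 0.5`) are heterozygous.
#'
#' @param x a [GBSDepthSet-class].
#' @param filter one of `"none"`, `"tf"`, `"af"`, `"maff"`.
#' @param depthThreshold per-allele depth threshold `t` for TF/AF (default 4).
#' @param homThreshold depth required for an unambiguous AF homozygote
#'   (default `2 * depthThreshold`).
#' @param maffThreshold minor-allele-fraction heterozygote threshold for MAFF
#'   (default 0.45).
#' @return a [GBSGenotypes-class] carrying the filter label in `metadata()`.
#' @export
callGenotypes <- function(x, filter = c("none", "tf", "af", "maff"),
                          depthThreshold = 4,
                          homThreshold = 2 * depthThreshold,
                          maffThreshold = 0.45) {
  filter <- match.arg(filter)
  d1 <- depthA(x); d2 <- depthB(x)
  al <- snpAlleles(x)
  a1 <- matrix(al$allele1, nrow = nrow(d1), ncol = ncol(d1))
  a2 <- matrix(al$allele2, nrow = nrow(d1), ncol = ncol(d1))
  g <- switch(filter,
    none = callCellsUnfiltered(d1, d2, a1, a2),
    tf = callCellsTF(d1, d2, a1, a2, depthThreshold),
    af = callCellsAF(d1, d2, a1, a2, depthThreshold, homThreshold),
    maff = callCellsMAFF(d1, d2, a1, a2, maffThreshold))
  dimnames(g) <- dimnames(d1)
  out <- GBSGenotypes(g, alleles = rowData(x),
                      sampleTable = as.data.frame(colData(x)),
                      filter = filter)
  metadata(out)$params <- list(depthThreshold = depthThreshold,
                               homThreshold = homThreshold,
                               maffThreshold = maffThreshold)
  out
}

callCellsUnfiltered <- function(d1, d2, a1, a2) {
  g <- matrix("NN", nrow = nrow(d1), ncol = ncol(d1))
  het <- d1 > 0 & d2 > 0
  hom1 <- d1 > 0 & d2 == 0
  hom2 <- d2 > 0 & d1 == 0
  g[het] <- paste0(a1[het], a2[het])
  g[hom1] <- paste0(a1[hom1], a1[hom1])
  g[hom2] <- paste0(a2[hom2], a2[hom2])
  g
}

callCellsTF <- function(d1, d2, a1, a2, t) {
  g <- matrix("NN", nrow = nrow(d1), ncol = ncol(d1))
  keep1 <- d1 >= t; keep2 <- d2 >= t
  het <- keep1 & keep2
  hom1 <- keep1 & !keep2
  hom2 <- keep2 & !keep1
  g[het] <- paste0(a1[het], a2[het])
  g[hom1] <- paste0(a1[hom1], a1[hom1])
  g[hom2] <- paste0(a2[hom2], a2[hom2])
  g
}

callCellsAF <- function(d1, d2, a1, a2, t, homT) {
  g <- matrix("NN", nrow = nrow(d1), ncol = ncol(d1))
  keep1 <- d1 >= t; keep2 <- d2 >= t
  het <- keep1 & keep2
  g[het] <- paste0(a1[het], a2[het])
  solo1 <- keep1 & !keep2
  solo2 <- keep2 & !keep1
  hom1 <- solo1 & d1 >= homT
  amb1 <- solo1 & d1 < homT
  hom2 <- solo2 & d2 >= homT
  amb2 <- solo2 & d2 < homT
  g[hom1] <- paste0(a1[hom1], a1[hom1])
  g[amb1] <- paste0(a1[amb1], "?")
  g[hom2] <- paste0(a2[hom2], a2[hom2])
  g[amb2] <- paste0(a2[amb2], "?")
  g
}

callCellsMAFF <- function(d1, d2, a1, a2, threshold) {
  g <- matrix("NN", nrow = nrow(d1), ncol = ncol(d1))
  tot <- d1 + d2
  pos <- tot > 0
  m <- ifelse(pos, pmin(d1, d2) / tot, NA_real_)
  het <- pos & m >= threshold
  hom1 <- pos & m < threshold & d1 >= d2
  hom2 <- pos & m < threshold & d2 > d1
  g[het] <- paste0(a1[het], a2[het])
  g[hom1] <- paste0(a1[hom1], a1[hom1])
  g[hom2] <- paste0(a2[hom2], a2[hom2])
  g
}

#' Remove SNPs and samples dominated by missing genotypes
#'
#' Removes SNP rows whose fraction of `"NN"` cells is at least `threshold`,
#' then sample columns whose `"NN"` fraction — computed on the surviving rows
#' — is at least `threshold`. After a filtering strategy has been applied the
#' row pass is repeated alone (`what = "rows"`).
#'
#' @param x a [GBSGenotypes-class].
#' @param threshold missingness fraction at or above which a row/column is
#'   dropped (default 0.9, i.e. "90% or more").
#' @param what `"both"` for the row-then-column pass, `"rows"` for rows only.
#' @return the reduced [GBSGenotypes-class]; `metadata()$missingness_log`
#'   records removed counts. If everything is removed the returned object has
#'   zero rows and `metadata()$empty` is `TRUE`.
#' @export
dropMissing <- function(x, threshold = 0.9, what = c("both", "rows")) {
  what <- match.arg(what)
  stopifnot(threshold > 0, threshold <= 1)
  g <- genotypeCalls(x)
  if (length(g) == 0) stop("empty genotype matrix")
  rowFrac <- rowMeans(g == "NN")
  keepRows <- rowFrac < threshold
  out <- x[keepRows, ]
  nColsDropped <- 0L
  if (what == "both" && sum(keepRows) > 0) {
    g2 <- genotypeCalls(out)
    colFrac <- colMeans(g2 == "NN")
    keepCols <- colFrac < threshold
    nColsDropped <- sum(!keepCols)
    out <- out[, keepCols]
  }
  metadata(out)$missingness_log <- list(
    n_snps_removed = sum(!keepRows),
    n_samples_removed = nColsDropped,
    threshold = threshold)
  metadata(out)$empty <- nrow(out) == 0 || ncol(out) == 0
  out
}

#' Tally genotype classes in a call matrix
#'
#' Counts homozygous, heterozygous, ambiguous (`"X?"`) and missing (`"NN"`)
#' cells. The heterozygous fraction is reported among assigned cells
#' (non-`NN`); ambiguous cells count as assigned but not heterozygous.
#'
#' @param x a [GBSGenotypes-class].
#' @return list with `counts` (named integer vector summing to the cell
#'   count), `fractions` (over all cells), `het_fraction_assigned`, and
#'   `assigned_fraction`.
#' @export
genotypeTallies <- function(x) {
  g <- genotypeCalls(x)
  if (length(g) == 0) stop("empty genotype matrix")
  nn <- g == "NN"
  amb <- grepl("?", g, fixed = TRUE) & !nn
  a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
  het <- !nn & !amb & a1 != a2
  hom <- !nn & !amb & a1 == a2
  counts <- c(homozygous = sum(hom), heterozygous = sum(het),
              ambiguous = sum(amb), missing = sum(nn))
  nAssigned <- sum(!nn)
  list(counts = counts,
       fractions = counts / length(g),
       het_fraction_assigned = if (nAssigned) sum(het) / nAssigned else NA_real_,
       assigned_fraction = nAssigned / length(g))
}

#' Run the full post-calling filtering pipeline
#'
#' The pipeline applied to population data: drop rows/columns with at least
#' 90% missing cells under unfiltered calls, apply the chosen filtering
#' strategy to the surviving allele depths, then repeat the row-missingness
#' pass on the filtered genotypes.
#'
#' @param x a [GBSDepthSet-class].
#' @param filter filtering strategy (see [callGenotypes()]).
#' @param missingThreshold missingness threshold (default 0.9).
#' @param ... passed to [callGenotypes()].
#' @return a [GBSGenotypes-class] after both missingness passes;
#'   `metadata()$pipeline_log` records counts removed at each stage.
#' @export
filterPipeline <- function(x, filter = "none", missingThreshold = 0.9, ...) {
  pre <- callGenotypes(x, filter = "none")
  pre <- dropMissing(pre, threshold = missingThreshold, what = "both")
  log1 <- metadata(pre)$missingness_log
  kept <- x[rownames(pre), colnames(pre)]
  called <- callGenotypes(kept, filter = filter, ...)
  post <- dropMissing(called, threshold = missingThreshold, what = "rows")
  log2 <- metadata(post)$missingness_log
  metadata(post)$pipeline_log <- list(
    pre_snps_removed = log1$n_snps_removed,
    pre_samples_removed = log1$n_samples_removed,
    post_snps_removed = log2$n_snps_removed,
    n_snps_retained = nrow(post),
    n_samples_retained = ncol(post))
  post
}
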