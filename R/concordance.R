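#' Count allele mismatches between two genotype calls
#'
#' Genotypes are compared as multisets of alleles: `"GA"` vs `"GG"` is one
#' difference (single mismatch), `"GG"` vs `"AA"` two (double mismatch).
#' Ambiguous (`"?"`) alleles are never counted as mismatches — only the
#' asserted alleles of an ambiguous genotype are compared — and a comparison
#' touching a `"?"` is flagged ambiguous. A pair where either cell is `"NN"`
#' is not comparable.
#'
#' Vectorised over equal-length genotype vectors.
#'
#' @param g1,g2 character vectors of two-character genotype cells.
#' @return data.frame with `mismatches` (0/1/2, `NA` when not comparable),
#'   `ambiguous`, `comparable`.
#' @export
alleleMismatches <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  comparable <- g1 != "NN" & g2 != "NN"
  x1 <- substr(g1, 1, 1); x2 <- substr(g1, 2, 2)
  y1 <- substr(g2, 1, 1); y2 <- substr(g2, 2, 2)
  ambiguous <- comparable &
    (x1 == "?" | x2 == "?" | y1 == "?" | y2 == "?")
  mism <- rep(NA_integer_, length(g1))
  ## full 2-vs-2 multiset comparison
  full <- comparable & !ambiguous
  ## best alignment of the two unordered pairs
  s_direct <- (x1 == y1) + (x2 == y2)
  s_cross <- (x1 == y2) + (x2 == y1)
  ## partial overlap: one allele of g1 present in g2
  s_any <- pmax((x1 == y1 | x1 == y2) + 0L, 0L) + pmax((x2 == y1 | x2 == y2) + 0L, 0L)
  ## multiset intersection size is min(2, best matching); for 2-element
  ## multisets max(s_direct, s_cross) is the exact matching size except the
  ## {G,G} vs {G,A} case where s_any would overcount, so cap by it
  inter <- pmin(pmax(s_direct, s_cross), s_any)
  mism[full] <- 2L - inter[full]
  ## ambiguous cells: compare only the asserted alleles, min-length pairing
  if (any(ambiguous)) {
    ia <- which(ambiguous)
    for (i in ia) {
      u <- setdiff(c(x1[i], x2[i]), "?")
      v <- setdiff(c(y1[i], y2[i]), "?")
      k <- min(length(u), length(v))
      if (k == 0L) { mism[i] <- 0L; next }
      ## count how many of the shorter side find a partner in the longer
      mcount <- 0L
      vv <- v
      for (a in u[seq_len(min(length(u), k))]) {
        j <- match(a, vv)
        if (!is.na(j)) { mcount <- mcount + 1L; vv <- vv[-j] }
      }
      mism[i] <- k - min(mcount, k)
    }
  }
  data.frame(mismatches = mism, ambiguous = ambiguous,
             comparable = comparable)
}

#' Replicate groups from a sample table
#'
#' @param sampleTable a sample table (see [readSampleTable()]).
#' @return named list (by `individual_id`) of sample-id vectors, restricted to
#'   individuals with at least two replicate samples.
#' @export
replicateGroups <- function(sampleTable) {
  grp <- split(sampleTable$sample_id, sampleTable$individual_id)
  grp[lengths(grp) >= 2]
}

#' Replicate genotype mismatch summary
#'
#' Scores every unordered within-group replicate pair over all SNPs (all
#' three pairs of a triplicate). The pooled mismatch rate is the number of
#' differing alleles over `2 x` the number of SNP-by-pair comparisons in the
#' matrix; `denominator = "comparable"` restricts the denominator to
#' comparisons where neither genotype is `"NN"`.
#'
#' @param x a [GBSGenotypes-class].
#' @param groups replicate groups from [replicateGroups()] (or a named list of
#'   sample-id vectors).
#' @param denominator `"all"` (2 x SNPs x pairs) or `"comparable"`.
#' @return list with pooled counts (`n_matches`, `n_single`, `n_double`,
#'   `n_ambiguous_comparisons`, `n_not_comparable`), `mismatch_rate`, and a
#'   per-pair data.frame `per_pair` with each pair's rate.
#' @export
mismatchRate <- function(x, groups, denominator = c("all", "comparable")) {
  denominator <- match.arg(denominator)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) stop("no replicate groups with >= 2 members")
  g <- genotypeCalls(x)
  missing <- setdiff(unlist(groups), colnames(g))
  if (length(missing))
    groups <- lapply(groups, setdiff, missing)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) stop("replicate groups not present in genotype matrix")
  tot <- c(n_matches = 0L, n_single = 0L, n_double = 0L,
           n_ambiguous_comparisons = 0L, n_not_comparable = 0L)
  nMismAlleles <- 0
  nComparisons <- 0L
  nComparable <- 0L
  perPair <- list()
  for (ind in names(groups)) {
    members <- sort(groups[[ind]])
    prs <- utils::combn(members, 2L)
    for (j in seq_len(ncol(prs))) {
      s1 <- prs[1, j]; s2 <- prs[2, j]
      mm <- alleleMismatches(g[, s1], g[, s2])
      nc <- sum(!mm$comparable)
      amb <- sum(mm$ambiguous)
      m0 <- sum(mm$comparable & !mm$ambiguous & mm$mismatches == 0L)
      m1 <- sum(mm$comparable & !mm$ambiguous & mm$mismatches == 1L)
      m2 <- sum(mm$comparable & !mm$ambiguous & mm$mismatches == 2L)
      nAll <- sum(mm$mismatches, na.rm = TRUE)
      tot <- tot + c(m0, m1, m2, amb, nc)
      nMismAlleles <- nMismAlleles + nAll
      nComparisons <- nComparisons + nrow(mm)
      nComparable <- nComparable + sum(mm$comparable)
      den <- if (denominator == "all") 2 * nrow(mm) else 2 * sum(mm$comparable)
      perPair[[length(perPair) + 1L]] <- data.frame(
        individual_id = ind, sample1 = s1, sample2 = s2,
        n_mismatch_alleles = nAll,
        rate = if (den > 0) nAll / den else NA_real_)
    }
  }
  den <- if (denominator == "all") 2 * nComparisons else 2 * nComparable
  list(n_matches = unname(tot["n_matches"]),
       n_single = unname(tot["n_single"]),
       n_double = unname(tot["n_double"]),
       n_ambiguous_comparisons = unname(tot["n_ambiguous_comparisons"]),
       n_not_comparable = unname(tot["n_not_comparable"]),
       mismatch_rate = if (den > 0) nMismAlleles / den else NA_real_,
       denominator = denominator,
       per_pair = do.call(rbind, perPair))
}

#' Depth records for replicate comparisons
#'
#' For every replicate pair and SNP with two unambiguous non-missing calls,
#' classifies the comparison as `dropout_pair` (one heterozygote, one
#' homozygote sharing an allele — the allelic-dropout pattern),
#' `hom_hom_mismatch` (two homozygotes for different alleles) or
#' `hom_hom_match`, with each member's total read depth.
#'
#' @param genotypes a [GBSGenotypes-class].
#' @param depths the matching [GBSDepthSet-class] (same SNPs and samples).
#' @param groups replicate groups.
#' @return data.frame with `snp`, `individual_id`, `class`, `depth1`,
#'   `depth2`, and for dropout pairs `het_depth` / `hom_depth`.
#' @export
depthComparisonRecords <- function(genotypes, depths, groups) {
  g <- genotypeCalls(genotypes)
  td <- totalDepth(depths)
  td <- td[rownames(g), colnames(g), drop = FALSE]
  groups <- groups[lengths(groups) >= 2]
  recs <- list()
  for (ind in names(groups)) {
    members <- sort(intersect(groups[[ind]], colnames(g)))
    if (length(members) < 2) next
    prs <- utils::combn(members, 2L)
    for (j in seq_len(ncol(prs))) {
      s1 <- prs[1, j]; s2 <- prs[2, j]
      g1 <- g[, s1]; g2 <- g[, s2]
      usable <- g1 != "NN" & g2 != "NN" &
        !grepl("?", g1, fixed = TRUE) & !grepl("?", g2, fixed = TRUE)
      het1 <- usable & substr(g1, 1, 1) != substr(g1, 2, 2)
      het2 <- usable & substr(g2, 1, 1) != substr(g2, 2, 2)
      hom1 <- usable & !het1
      hom2 <- usable & !het2
      mm <- alleleMismatches(g1, g2)$mismatches
      drp <- (het1 & hom2 & mm == 1L) | (het2 & hom1 & mm == 1L)
      hhMis <- hom1 & hom2 & mm == 2L
      hhMat <- hom1 & hom2 & mm == 0L
      addRec <- function(idx, class) {
        if (!any(idx)) return(NULL)
        data.frame(snp = rownames(g)[idx], individual_id = ind,
                   sample1 = s1, sample2 = s2, class = class,
                   depth1 = td[idx, s1], depth2 = td[idx, s2],
                   het_depth = if (class == "dropout_pair")
                     ifelse(het1[idx], td[idx, s1], td[idx, s2]) else NA_real_,
                   hom_depth = if (class == "dropout_pair")
                     ifelse(het1[idx], td[idx, s2], td[idx, s1]) else NA_real_)
      }
      recs <- c(recs, list(addRec(drp, "dropout_pair"),
                           addRec(hhMis, "hom_hom_mismatch"),
                           addRec(hhMat, "hom_hom_match")))
    }
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0)
    return(data.frame(snp = character(), individual_id = character(),
                      sample1 = character(), sample2 = character(),
                      class = character(), depth1 = numeric(),
                      depth2 = numeric(), het_depth = numeric(),
                      hom_depth = numeric()))
  do.call(rbind, recs)
}

#' Paired depth test for allelic-dropout mismatches
#'
#' Wilcoxon signed-rank test of the per-pair difference in total read depth
#' between the heterozygous and the homozygous member of each dropout pair,
#' with class mean depths and the fraction of pairs in which the homozygote
#' has the lower depth.
#'
#' @param records output of [depthComparisonRecords()].
#' @param alternative passed to [stats::wilcox.test()] (default
#'   `"two.sided"`).
#' @return list with `statistic`, `p.value`, `mean_het_depth`,
#'   `mean_hom_depth`, `fraction_hom_lower`, `n_pairs`.
#' @export
dropoutDepthTest <- function(records, alternative = "two.sided") {
  d <- records[records$class == "dropout_pair", , drop = FALSE]
  if (nrow(d) == 0) stop("no dropout pairs in records")
  diffs <- d$het_depth - d$hom_depth
  if (all(diffs == 0)) {
    warning("all depth differences are zero")
    return(list(statistic = NA_real_, p.value = 1,
                mean_het_depth = mean(d$het_depth),
                mean_hom_depth = mean(d$hom_depth),
                fraction_hom_lower = 0, n_pairs = nrow(d)))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(d$het_depth, d$hom_depth, paired = TRUE,
                       alternative = alternative))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       mean_het_depth = mean(d$het_depth),
       mean_hom_depth = mean(d$hom_depth),
       fraction_hom_lower = mean(d$hom_depth < d$het_depth),
       n_pairs = nrow(d))
}

#' Depth test for homozygote-homozygote mismatches
#'
#' Mann-Whitney (Wilcoxon rank-sum) test comparing pooled per-cell read
#' depths of mismatched homozygote pairs against matched homozygote pairs.
#'
#' @param records output of [depthComparisonRecords()].
#' @return list with `statistic` (U), `p.value`, `mean_mismatched_depth`,
#'   `mean_matched_depth`, group sizes.
#' @export
homozygoteMismatchDepthTest <- function(records) {
  mis <- records[records$class == "hom_hom_mismatch", , drop = FALSE]
  mat <- records[records$class == "hom_hom_match", , drop = FALSE]
  if (nrow(mis) == 0 || nrow(mat) == 0)
    stop("both mismatched and matched homozygote groups are required")
  misD <- c(mis$depth1, mis$depth2)
  matD <- c(mat$depth1, mat$depth2)
  wt <- suppressWarnings(stats::wilcox.test(misD, matD))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       mean_mismatched_depth = mean(misD),
       mean_matched_depth = mean(matD),
       n_mismatched = length(misD), n_matched = length(matD))
}

#' Choose one representative sample per individual
#'
#' Picks, for each individual, the replicate with the greatest read depth
#' summed over all SNPs; exact ties go to the lexicographically smallest
#' sample id.
#'
#' @param depths a [GBSDepthSet-class].
#' @param sampleTable sample table covering the depth-set samples.
#' @return character vector of chosen sample ids, named by individual.
#' @export
chooseRepresentative <- function(depths, sampleTable) {
  td <- colSums(totalDepth(depths))
  st <- sampleTable[sampleTable$sample_id %in% names(td), , drop = FALSE]
  grp <- split(st$sample_id, st$individual_id)
  vapply(grp, function(ids) {
    ids <- sort(ids)
    ids[which.max(td[ids])]
  }, "")
}
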