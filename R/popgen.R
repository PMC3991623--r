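#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic locus: given the observed allele
#' counts, the probability of each compatible heterozygote count h is
#' `P(h) = n! / (n_AA! n_Aa! n_aa!) * 2^h / C(2n, n_minor)`, and the p-value
#' sums `P(h)` over all outcomes no more probable than the observed one.
#'
#' @param nAA,nAa,naa observed genotype counts for the locus's two alleles.
#' @return the exact p-value.
#' @export
hweExactP <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be non-negative")
  if (any(c(nAA, nAa, naa) != round(c(nAA, nAa, naa))))
    stop("genotype counts must be integers")
  n <- nAA + nAa + naa
  if (n < 1) stop("at least one genotype is required")
  nA <- 2 * nAA + nAa
  minor <- min(nA, 2 * n - nA)
  if (minor == 0) return(1)
  hs <- seq(minor %% 2, minor, by = 2)
  homMinor <- (minor - hs) / 2
  homMajor <- n - hs - homMinor
  logp <- lfactorial(n) - lfactorial(homMinor) - lfactorial(homMajor) -
    lfactorial(hs) + hs * log(2) - lchoose(2 * n, minor)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- min(nAa, minor)  # nAa determines the configuration
  pObs <- p[match(nAa, hs)]
  if (is.na(pObs)) stop("genotype counts are inconsistent with allele counts")
  sum(p[p <= pObs * (1 + 1e-9)])
}

## Per-population genotype counts for every SNP. Cells containing "?" or "N"
## are treated as missing. Returns arrays (SNP x pop) of nAA, nAa, naa where
## A is the SNP's allele1.
genotypeCountsByPop <- function(x) {
  g <- genotypeCalls(x)
  al <- snpAlleles(x)
  if (is.null(al)) stop("genotype object carries no allele annotation")
  st <- sampleInfo(x)
  if (!"population_id" %in% colnames(st))
    stop("colData must carry population_id")
  pops <- unique(st$population_id)
  a1 <- matrix(substr(g, 1, 1), nrow(g)); a2 <- matrix(substr(g, 2, 2), nrow(g))
  usable <- matrix(!grepl("[?N]", g), nrow(g))
  A1 <- matrix(al$allele1, nrow = nrow(g), ncol = ncol(g))
  isHet <- usable & a1 != a2
  isAA <- usable & a1 == a2 & a1 == A1
  isaa <- usable & a1 == a2 & a1 != A1
  res <- lapply(pops, function(p) {
    cols <- st$population_id == p
    cbind(nAA = rowSums(isAA[, cols, drop = FALSE]),
          nAa = rowSums(isHet[, cols, drop = FALSE]),
          naa = rowSums(isaa[, cols, drop = FALSE]))
  })
  names(res) <- pops
  res
}

#' Pooled Hardy-Weinberg summary across populations
#'
#' Computes the exact HWE p-value for every SNP in every eligible population
#' (populations with at least `minPopN` samples in the genotype matrix),
#' restricted to SNP-population combinations that are polymorphic with at
#' least one non-missing genotype, and pools the p-values.
#'
#' @param x a [GBSGenotypes-class] with population assignments in `colData`.
#' @param alpha significance threshold used for the reported proportion
#'   (default 0.05).
#' @param minPopN minimum number of samples for a population to be tested
#'   (default 10).
#' @return list with `p_values` (pooled vector), `proportion_above_alpha`,
#'   `quantiles`, `n_tests`, `populations_tested`, `populations_excluded`.
#' @export
pooledHweSummary <- function(x, alpha = 0.05, minPopN = 10) {
  st <- sampleInfo(x)
  popSizes <- table(st$population_id)
  eligible <- names(popSizes)[popSizes >= minPopN]
  excluded <- setdiff(names(popSizes), eligible)
  if (length(eligible) == 0) stop("no population meets the minimum size")
  counts <- genotypeCountsByPop(x)
  ps <- list()
  for (p in eligible) {
    cn <- counts[[p]]
    n <- rowSums(cn)
    nA <- 2 * cn[, "nAA"] + cn[, "nAa"]
    poly <- n > 0 & nA > 0 & nA < 2 * n
    idx <- which(poly)
    if (length(idx))
      ps[[p]] <- vapply(idx, function(i)
        hweExactP(cn[i, "nAA"], cn[i, "nAa"], cn[i, "naa"]), 0)
  }
  pv <- unlist(ps, use.names = FALSE)
  if (is.null(pv)) pv <- numeric()
  list(p_values = pv,
       proportion_above_alpha = if (length(pv)) mean(pv > alpha) else NA_real_,
       quantiles = if (length(pv)) stats::quantile(pv, c(.05, .25, .5, .75, .95))
                   else NULL,
       n_tests = length(pv),
       populations_tested = eligible,
       populations_excluded = excluded)
}

## Core gene-diversity computation (Nei 1987 with small-sample correction,
## hierfstat basic.stats conventions). Returns per-locus Ho, Hs, Ht, Fst and
## per-population per-locus n, p, Ho, Hs.
neiBasicStats <- function(x, populations = NULL) {
  g <- genotypeCalls(x)
  al <- snpAlleles(x)
  st <- sampleInfo(x)
  pops <- populations %||% unique(st$population_id)
  a1 <- matrix(substr(g, 1, 1), nrow(g)); a2 <- matrix(substr(g, 2, 2), nrow(g))
  usable <- matrix(!grepl("[?N]", g), nrow(g))
  A1 <- matrix(al$allele1, nrow = nrow(g), ncol = ncol(g))
  cnt1 <- (a1 == A1) + (a2 == A1)   # copies of allele1 per cell
  cnt1[!usable] <- NA
  het <- usable & a1 != a2
  nk <- pk <- hok <- matrix(NA_real_, nrow(g), length(pops),
                            dimnames = list(rownames(g), pops))
  for (j in seq_along(pops)) {
    cols <- which(st$population_id == pops[j])
    nkj <- rowSums(usable[, cols, drop = FALSE])
    nk[, j] <- nkj
    pk[, j] <- ifelse(nkj > 0,
                      rowSums(cnt1[, cols, drop = FALSE], na.rm = TRUE) / (2 * nkj),
                      NA_real_)
    hok[, j] <- ifelse(nkj > 0,
                       rowSums(het[, cols, drop = FALSE]) / nkj, NA_real_)
  }
  present <- nk > 0
  np <- rowSums(present)
  mHo <- rowMeans(ifelse(present, hok, NA), na.rm = TRUE)
  sp2 <- pk^2 + (1 - pk)^2
  msp2 <- rowMeans(ifelse(present, sp2, NA), na.rm = TRUE)
  ntilde <- np / rowSums(ifelse(present, 1 / nk, NA), na.rm = TRUE)
  Hs <- ifelse(ntilde > 1,
               ntilde / (ntilde - 1) * (1 - msp2 - mHo / (2 * ntilde)),
               NA_real_)
  pbar <- rowMeans(ifelse(present, pk, NA), na.rm = TRUE)
  Ht <- 1 - (pbar^2 + (1 - pbar)^2) + Hs / (ntilde * np) - mHo / (2 * ntilde * np)
  Fst <- ifelse(np >= 2 & Ht > 0, (Ht - Hs) / Ht, NA_real_)
  ## per-population per-locus Hs with small-sample correction
  HsK <- ifelse(nk > 1,
                nk / (nk - 1) * (1 - sp2 - hok / (2 * nk)), NA_real_)
  list(perLocus = data.frame(Ho = mHo, Hs = Hs, Ht = Ht, Fst = Fst,
                             np = np, row.names = rownames(g)),
       nk = nk, pk = pk, HoK = hok, HsK = HsK, populations = pops)
}

#' Observed and expected heterozygosity and F_ST
#'
#' Nei (1987) gene-diversity statistics with small-sample correction. Per
#' locus: `Ho` is the mean over populations of the observed heterozygote
#' fraction; `Hs` the corrected mean within-population gene diversity; `Ht`
#' the corrected total diversity from mean allele frequencies; and
#' `F_ST = (Ht - Hs) / Ht`. The overall F_ST is formed from the per-locus
#' means of Ht and Hs; negative per-locus values are retained, never
#' truncated. Genotypes containing `"?"` or `"N"` are treated as missing;
#' loci observed in fewer than two populations are dropped from Ht/F_ST.
#'
#' @param x a [GBSGenotypes-class] with population assignments.
#' @param populations optional subset of populations to use.
#' @return list with `per_population` (mean Ho/Hs per population),
#'   `per_locus` data.frame, and `overall` (`Ho`, `Hs`, `Ht`, `Fst`).
#' @export
diversityStats <- function(x, populations = NULL) {
  bs <- neiBasicStats(x, populations)
  if (length(bs$populations) < 2)
    stop("at least two populations are required")
  perPop <- data.frame(
    population = bs$populations,
    Ho = colMeans(ifelse(bs$nk > 0, bs$HoK, NA), na.rm = TRUE),
    Hs = colMeans(bs$HsK, na.rm = TRUE),
    n_mean = colMeans(bs$nk),
    row.names = NULL)
  pl <- bs$perLocus
  mHs <- mean(pl$Hs, na.rm = TRUE)
  mHt <- mean(pl$Ht[pl$np >= 2], na.rm = TRUE)
  overall <- list(Ho = mean(pl$Ho, na.rm = TRUE),
                  Hs = mHs, Ht = mHt,
                  Fst = (mHt - mean(pl$Hs[pl$np >= 2], na.rm = TRUE)) / mHt)
  list(per_population = perPop, per_locus = pl, overall = overall)
}

#' Pairwise F_ST with region contrasts
#'
#' Computes the gene-diversity F_ST for every population pair (the same
#' estimator as [diversityStats()], restricted to the pair) and averages the
#' pairwise values over between-region and within-region pairs.
#'
#' @param x a [GBSGenotypes-class] with `population_id` and `region_id` in
#'   `colData` (or supply `regions`).
#' @param regions optional named character vector mapping population to
#'   region.
#' @return list with `matrix` (symmetric pairwise F_ST, `NA` diagonal),
#'   `pairs` data.frame, `mean_between_regions`, `mean_within_regions`.
#' @export
pairwiseFst <- function(x, regions = NULL) {
  st <- sampleInfo(x)
  pops <- unique(st$population_id)
  if (length(pops) < 2) stop("at least two populations are required")
  if (is.null(regions)) {
    if (!"region_id" %in% colnames(st))
      stop("regions must be supplied or present in colData")
    map <- unique(st[, c("population_id", "region_id")])
    regions <- stats::setNames(map$region_id, map$population_id)
  }
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  pairs <- list()
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    keep <- st$population_id %in% pops[c(i, j)]
    xs <- x[, keep]
    fst <- diversityStats(xs)$overall$Fst
    m[i, j] <- m[j, i] <- fst
    pairs[[length(pairs) + 1L]] <- data.frame(
      pop1 = pops[j], pop2 = pops[i], fst = fst,
      contrast = if (regions[pops[i]] == regions[pops[j]])
        "within" else "between")
  }
  pairs <- do.call(rbind, pairs)
  list(matrix = m, pairs = pairs,
       mean_between_regions = mean(pairs$fst[pairs$contrast == "between"],
                                   na.rm = TRUE),
       mean_within_regions = if (any(pairs$contrast == "within"))
         mean(pairs$fst[pairs$contrast == "within"], na.rm = TRUE)
       else NA_real_)
}
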