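test_that("HWE exact test matches enumeration and is relabelling-invariant", {
  expect_equal(hweExactP(5, 0, 0), 1)
  expect_equal(hweExactP(1, 0, 1), 1 / 3)
  expect_error(hweExactP(-1, 2, 0), "non-negative")

  ## spot-check moderate counts against the enumeration oracle
  for (cnt in list(c(3, 1, 4), c(0, 5, 2), c(2, 2, 2), c(6, 1, 0))) {
    expect_equal(hweExactP(cnt[1], cnt[2], cnt[3]),
                 hweEnumOracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10)
    expect_equal(hweExactP(cnt[1], cnt[2], cnt[3]),
                 hweExactP(cnt[3], cnt[2], cnt[1]), tolerance = 1e-12)
  }
  ## a large configuration stays numerically stable in log space
  expect_gte(hweExactP(300, 500, 200), 0)
  expect_lte(hweExactP(300, 500, 200), 1)
})

test_that("HWE exact p-values are super-uniform under the null", {
  set.seed(81)
  n <- 25
  ps <- vapply(1:2000, function(i) {
    p <- runif(1, 0.2, 0.8)
    g <- rbinom(n, 2, p)
    hweExactP(sum(g == 2), sum(g == 1), sum(g == 0))
  }, 0)
  for (a in c(0.01, 0.05, 0.1))
    expect_lte(mean(ps <= a), a + 2 * sqrt(a * (1 - a) / 2000) + 0.005)
})

test_that("pooled HWE summary excludes small populations and flags dropout", {
  cfg <- simulationConfig(seed = 82, nSnps = 250,
                          nIndividualsPerPopulation = 15,
                          meanDepth = 40, depthDispersion = 10,
                          sequencingErrorRate = 0)
  st <- simulateStudy(cfg)
  g <- callGenotypes(st$depths, "none")
  ## high depth, HWE truth: most tests should not reject
  hw <- pooledHweSummary(g, minPopN = 10)
  expect_gt(hw$proportion_above_alpha, 0.85)
  expect_equal(sort(hw$populations_tested), sort(paste0("P", 1:6)))

  ## a population below the threshold is excluded
  stab <- sampleInfo(g)
  small <- stab$sample_id[stab$population_id == "P6"][1:6]
  keep <- stab$sample_id[stab$population_id != "P6"]
  gsub <- g[, c(keep, small)]
  hw2 <- pooledHweSummary(gsub, minPopN = 10)
  expect_false("P6" %in% hw2$populations_tested)
  expect_true("P6" %in% hw2$populations_excluded)
  expect_error(pooledHweSummary(g, minPopN = 1000), "minimum size")

  ## shallow depth drives allelic dropout: excess mass near 0
  cfgLow <- simulationConfig(seed = 83, nSnps = 400,
                             nIndividualsPerPopulation = 15,
                             meanDepth = 3, sequencingErrorRate = 0)
  stLow <- simulateStudy(cfgLow)
  hwLow <- pooledHweSummary(callGenotypes(stLow$depths, "none"), minPopN = 10)
  expect_gt(mean(hwLow$p_values <= 0.05), 0.15)
})

test_that("diversity statistics hit the analytic extremes", {
  st <- makeSampleTable(paste0("s", 1:8),
                        rep(c("P1", "P2"), each = 4),
                        rep(c("N", "SW"), each = 4))
  ## populations fixed for alternate alleles -> F_ST = 1
  g <- rbind(c(rep("AA", 4), rep("GG", 4)),
             c(rep("AA", 4), rep("GG", 4)))
  colnames(g) <- st$sample_id
  x <- makeGenotypes(g, sampleTable = st)
  ds <- diversityStats(x)
  expect_equal(ds$overall$Fst, 1)
  expect_equal(ds$overall$Ho, 0)

  ## all-heterozygote population -> Ho = 1
  g2 <- matrix("AG", 2, 8, dimnames = list(NULL, st$sample_id))
  ds2 <- diversityStats(makeGenotypes(g2, sampleTable = st))
  expect_equal(ds2$overall$Ho, 1)
  expect_equal(ds2$per_population$Ho, c(1, 1))

  expect_error(diversityStats(makeGenotypes(
    g2[, 1:4], sampleTable = st[1:4, ])), "two populations")
})

test_that("F_ST is near zero without differentiation and recovers targets", {
  ## identical allele frequencies, large n
  cfg0 <- simulationConfig(seed = 84, nSnps = 1000,
                           nIndividualsPerPopulation = 100,
                           populationsPerRegion = 1,
                           targetFstBetweenRegions = 0,
                           targetFstWithinRegions = 0,
                           replicateFraction = 0)
  tr0 <- simulatePopulationStructure(cfg0)
  expect_lt(abs(tr0$realizedFst), 0.02)

  ## Balding-Nichols recovery at the study targets
  cfg <- simulationConfig(seed = 85, nSnps = 2000,
                          nIndividualsPerPopulation = 25,
                          replicateFraction = 0)
  tr <- simulatePopulationStructure(cfg)
  pw <- pairwiseFst(truthGenotypes(tr))
  expect_lt(abs(pw$mean_between_regions - 0.15), 0.03)
  expect_lt(abs(pw$mean_within_regions - 0.02), 0.03)
  expect_gt(pw$mean_between_regions, pw$mean_within_regions)
})

test_that("pairwise F_ST separates regions and handles undefined contrasts", {
  cfg <- simulationConfig(seed = 86, nSnps = 400,
                          nIndividualsPerPopulation = 12,
                          replicateFraction = 0)
  tr <- simulatePopulationStructure(cfg)
  x <- truthGenotypes(tr)
  pw <- pairwiseFst(x)
  expect_true(isSymmetric(unname(pw$matrix)))
  expect_true(all(is.na(diag(pw$matrix))))
  expect_equal(nrow(pw$pairs), choose(6, 2))
  expect_equal(sum(pw$pairs$contrast == "between"), 9L)

  ## three near-identical populations -> all pairwise about 0
  cfg0 <- simulationConfig(seed = 87, nSnps = 600,
                           nIndividualsPerPopulation = 40,
                           nRegions = 1, populationsPerRegion = 3,
                           targetFstBetweenRegions = 0,
                           targetFstWithinRegions = 0,
                           replicateFraction = 0)
  tr0 <- simulatePopulationStructure(cfg0)
  pw0 <- pairwiseFst(truthGenotypes(tr0),
                     regions = c(P1 = "R1", P2 = "R1", P3 = "R1"))
  expect_true(all(abs(pw0$pairs$fst) < 0.02))
  ## single region: between-region mean undefined
  expect_true(is.nan(pw0$mean_between_regions) ||
              is.na(pw0$mean_between_regions))
})

test_that("ambiguous alleles are treated as missing in genotype counts", {
  st <- makeSampleTable(paste0("s", 1:4), rep(c("P1", "P2"), each = 2),
                        rep(c("N", "SW"), each = 2))
  g <- matrix(c("AA", "A?", "AG", "NN"), 1, 4,
              dimnames = list("snp1", st$sample_id))
  x <- makeGenotypes(g, sampleTable = st)
  cnt <- gbstk:::genotypeCountsByPop(x)
  expect_equal(unname(cnt$P1[1, ]), c(1, 0, 0))   # "A?" excluded
  expect_equal(unname(cnt$P2[1, ]), c(0, 1, 0))   # NN excluded
})

test_that("filter choice shifts heterozygosity in the reported direction", {
  cfg <- simulationConfig(seed = 88, nSnps = 500,
                          nIndividualsPerPopulation = 15,
                          meanDepth = 6)
  st <- simulateStudy(cfg)
  hetAmongCalled <- function(x) {
    h <- genotypeTallies(x)$counts
    unname(h["heterozygous"] / (h["heterozygous"] + h["homozygous"]))
  }
  truH <- hetAmongCalled(truthGenotypes(st$truth))
  hets <- vapply(c("none", "tf", "af", "maff"), function(f)
    hetAmongCalled(callGenotypes(st$depths, f)), 0)
  expect_lt(hets["maff"], hets["tf"])
  expect_lt(hets["tf"], hets["none"])
  expect_lt(hets["none"], truH)

  ## in the sparse, strongly overdispersed depth regime characteristic of
  ## highly multiplexed GBS, the ambiguity filter is the least biased: its
  ## "X?" cells absorb exactly the genotypes dropout corrupts
  cfgSp <- simulationConfig(seed = 89, nSnps = 500,
                            nIndividualsPerPopulation = 15,
                            meanDepth = 3, depthDispersion = 0.7)
  sp <- simulateStudy(cfgSp)
  truSp <- hetAmongCalled(truthGenotypes(sp$truth))
  hetsSp <- vapply(c("none", "tf", "af", "maff"), function(f)
    hetAmongCalled(callGenotypes(sp$depths, f)), 0)
  expect_equal(names(which.min(abs(hetsSp - truSp))), "af")
})
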