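test_that("allele mismatch scoring follows the single/double/ambiguous rules", {
  mm <- alleleMismatches(c("GA", "GG", "G?", "AG", "NN", "AA", "A?"),
                         c("GG", "AA", "GG", "GA", "AA", "AA", "G?"))
  expect_equal(mm$mismatches, c(1L, 2L, 0L, 0L, NA, 0L, 1L))
  expect_equal(mm$ambiguous, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(mm$comparable, c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  ## symmetric
  mm2 <- alleleMismatches(c("GG", "AA"), c("GA", "GG"))
  expect_equal(mm2$mismatches, c(1L, 2L))
})

test_that("pooled mismatch rate uses 2 x SNPs x pairs and scores all pairs", {
  st <- makeSampleTable(c("a1", "a2"), c("P1", "P1"), c("N", "N"),
                        individuals = c("i1", "i1"))
  g <- matrix("AG", 50, 2, dimnames = list(NULL, c("a1", "a2")))
  x <- makeGenotypes(g, sampleTable = st)
  mm <- mismatchRate(x, replicateGroups(st))
  expect_equal(mm$mismatch_rate, 0)
  expect_equal(mm$n_matches, 50L)

  ## planted single mismatch among 50 SNPs, one pair -> 1/100
  g[27, 2] <- "AA"
  x <- makeGenotypes(g, sampleTable = st)
  mm <- mismatchRate(x, replicateGroups(st))
  expect_equal(mm$mismatch_rate, 1 / 100)
  expect_equal(mm$n_single, 1L)

  ## NN cells stay in the literal denominator but not the comparable one
  g[1:10, 1] <- "NN"
  x <- makeGenotypes(g, sampleTable = st)
  expect_equal(mismatchRate(x, replicateGroups(st))$mismatch_rate, 1 / 100)
  expect_equal(mismatchRate(x, replicateGroups(st),
                            denominator = "comparable")$mismatch_rate, 1 / 80)
})

test_that("triplicate groups score all three pairwise comparisons", {
  st <- makeSampleTable(c("a1", "a2", "a3"), rep("P1", 3), rep("N", 3),
                        individuals = rep("i1", 3))
  g <- matrix("AA", 20, 3, dimnames = list(NULL, c("a1", "a2", "a3")))
  g[5, 3] <- "AG"   # divergent genotype in one replicate
  x <- makeGenotypes(g, sampleTable = st)
  mm <- mismatchRate(x, replicateGroups(st))
  expect_equal(nrow(mm$per_pair), 3L)
  expect_equal(mm$n_single, 2L)             # a1-a3 and a2-a3
  expect_equal(mm$mismatch_rate, 2 / (2 * 20 * 3))
})

test_that("mismatch rate is invariant to SNP and sample order", {
  set.seed(71)
  st <- makeSampleTable(c("a1", "a2", "b1", "b2"),
                        rep("P1", 4), rep("N", 4),
                        individuals = c("i1", "i1", "i2", "i2"))
  g <- matrix(sample(c("AA", "AG", "GG", "NN", "A?"), 120, replace = TRUE),
              30, 4, dimnames = list(paste0("s", 1:30),
                                     c("a1", "a2", "b1", "b2")))
  x <- makeGenotypes(g, sampleTable = st)
  r1 <- mismatchRate(x, replicateGroups(st))$mismatch_rate
  perm <- sample(30)
  x2 <- makeGenotypes(g[perm, , drop = FALSE], sampleTable = st)
  r2 <- mismatchRate(x2, replicateGroups(st))$mismatch_rate
  x3 <- makeGenotypes(g[, c(3, 4, 1, 2)], sampleTable = st)
  r3 <- mismatchRate(x3, replicateGroups(st))$mismatch_rate
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("ambiguity relabelling cannot create new mismatches (AF <= TF)", {
  set.seed(72)
  for (i in 1:6) {
    st <- makeSampleTable(c("a1", "a2"), c("P1", "P1"), c("N", "N"),
                          individuals = c("i1", "i1"))
    d1 <- matrix(rnbinom(80, mu = 5, size = 1.5), 40, 2,
                 dimnames = list(NULL, c("a1", "a2")))
    d2 <- matrix(rnbinom(80, mu = 4, size = 1.5), 40, 2,
                 dimnames = list(NULL, c("a1", "a2")))
    x <- makeDepthSet(d1, d2, sampleTable = st)
    tfR <- mismatchRate(callGenotypes(x, "tf"), replicateGroups(st))
    afR <- mismatchRate(callGenotypes(x, "af"), replicateGroups(st))
    expect_lte(afR$mismatch_rate, tfR$mismatch_rate)
  }
})

test_that("dropout depth test matches the textbook signed-rank computation", {
  recs <- data.frame(snp = paste0("s", 1:6), individual_id = "i1",
                     sample1 = "a1", sample2 = "a2",
                     class = "dropout_pair",
                     depth1 = 0, depth2 = 0,
                     het_depth = c(9, 7, 12, 5, 8, 11),
                     hom_depth = c(4, 6, 3, 6, 2, 5))
  res <- dropoutDepthTest(recs)
  d <- recs$het_depth - recs$hom_depth        # 5 1 9 -1 6 6
  r <- rank(abs(d))
  V <- sum(r[d > 0])                          # textbook V statistic
  expect_equal(res$statistic, V)
  expect_equal(res$fraction_hom_lower, 5 / 6)
  expect_equal(res$mean_het_depth, mean(recs$het_depth))

  ## extreme case: hom always lower -> small one-sided p
  res1 <- dropoutDepthTest(recs[recs$het_depth > recs$hom_depth, ],
                           alternative = "greater")
  expect_lt(res1$p.value, 0.05)
  expect_equal(res1$fraction_hom_lower, 1)

  ## all-zero differences -> p = 1 with warning
  recs0 <- recs; recs0$hom_depth <- recs0$het_depth
  expect_warning(res0 <- dropoutDepthTest(recs0), "zero")
  expect_equal(res0$p.value, 1)
})

test_that("symmetric dropout depth differences give well-calibrated p-values", {
  set.seed(73)
  ps <- vapply(1:200, function(i) {
    het <- rpois(15, 8); hom <- rpois(15, 8)
    recs <- data.frame(snp = paste0("s", 1:15), individual_id = "i",
                       sample1 = "a", sample2 = "b", class = "dropout_pair",
                       depth1 = 0, depth2 = 0,
                       het_depth = het, hom_depth = hom)
    if (all(het == hom)) return(1)
    suppressWarnings(dropoutDepthTest(recs)$p.value)
  }, 0)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
})

test_that("homozygote mismatch depth test equals the hand-computed U", {
  recs <- rbind(
    data.frame(snp = "s1", individual_id = "i", sample1 = "a", sample2 = "b",
               class = "hom_hom_mismatch", depth1 = c(1, 2, 1),
               depth2 = c(2, 1, 3), het_depth = NA, hom_depth = NA),
    data.frame(snp = "s2", individual_id = "i", sample1 = "a", sample2 = "b",
               class = "hom_hom_match", depth1 = c(5, 7, 4),
               depth2 = c(6, 8, 9), het_depth = NA, hom_depth = NA))
  res <- homozygoteMismatchDepthTest(recs)
  mis <- c(1, 2, 1, 2, 1, 3); mat <- c(5, 7, 4, 6, 8, 9)
  U <- sum(outer(mis, mat, ">")) + 0.5 * sum(outer(mis, mat, "=="))
  expect_equal(res$statistic, U)
  expect_lt(res$p.value, 0.01)
  expect_lt(res$mean_mismatched_depth, res$mean_matched_depth)
  expect_error(homozygoteMismatchDepthTest(recs[recs$class != "hom_hom_match", ]),
               "required")
})

test_that("dropout records classify replicate comparisons with their depths", {
  st <- makeSampleTable(c("a1", "a2"), c("P1", "P1"), c("N", "N"),
                        individuals = c("i1", "i1"))
  g <- matrix(c("AG", "AA",     # dropout pair
                "AA", "GG",     # hom-hom mismatch
                "AA", "AA",     # hom-hom match
                "A?", "AA",     # ambiguous: skipped
                "NN", "AA"),    # not comparable: skipped
              ncol = 2, byrow = TRUE,
              dimnames = list(paste0("s", 1:5), c("a1", "a2")))
  d1 <- matrix(c(5L, 3L, 4L, 0L, 2L, 2L, 5L, 8L, 0L, 4L), ncol = 2,
               byrow = TRUE, dimnames = dimnames(g))
  d2 <- matrix(c(4L, 0L, 0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L), ncol = 2,
               byrow = TRUE, dimnames = dimnames(g))
  gt <- makeGenotypes(g, sampleTable = st)
  dp <- makeDepthSet(d1, d2, sampleTable = st)
  rec <- depthComparisonRecords(gt, dp, replicateGroups(st))
  expect_equal(nrow(rec), 3L)
  dr <- rec[rec$class == "dropout_pair", ]
  expect_equal(dr$het_depth, 9)
  expect_equal(dr$hom_depth, 3)
  expect_equal(rec$class[rec$snp == "s2"], "hom_hom_mismatch")
  expect_equal(rec$class[rec$snp == "s3"], "hom_hom_match")
})

test_that("replicate mismatch rates fall as simulated depth grows", {
  depths <- c(2, 4, 8, 16, 32)
  rates <- vapply(seq_along(depths), function(k) {
    mean(vapply(1:10, function(r) {
      cfg <- simulationConfig(seed = 1000 + 37 * k + r, nSnps = 120,
                              nIndividualsPerPopulation = 4,
                              populationsPerRegion = 1,
                              meanDepth = depths[k],
                              sequencingErrorRate = 0,
                              replicateFraction = 0.5)
      st <- simulateStudy(cfg)
      g <- callGenotypes(st$depths, "none")
      ## the comparable-pair denominator isolates discordance from
      ## missingness, which also rises at low depth
      mismatchRate(g, st$truth$replicate_groups,
                   denominator = "comparable")$mismatch_rate
    }, 0))
  }, 0)
  expect_true(all(diff(rates) < 0))
})

test_that("representative choice maximises summed depth with lexicographic ties", {
  st <- makeSampleTable(c("b", "a", "c1", "c2", "d2", "d1"),
                        rep("P1", 6), rep("N", 6),
                        individuals = c("i1", "i1", "i2", "i2", "i3", "i3"))
  d1 <- matrix(c(60, 50, 40, 45, 30, 30), nrow = 1,
               dimnames = list("s1", st$sample_id))
  d2 <- matrix(0L, 1, 6, dimnames = dimnames(d1))
  x <- makeDepthSet(d1, d2, sampleTable = st)
  rep <- chooseRepresentative(x, st)
  expect_equal(unname(rep["i1"]), "b")     # 60 > 50
  expect_equal(unname(rep["i2"]), "c2")    # 45 > 40
  expect_equal(unname(rep["i3"]), "d1")    # tie -> lexicographic
  ## singleton group
  st2 <- makeSampleTable("solo", "P1", "N", "i9")
  x2 <- makeDepthSet(matrix(5L, 1, 1, dimnames = list("s1", "solo")),
                     matrix(0L, 1, 1, dimnames = list("s1", "solo")),
                     sampleTable = st2)
  expect_equal(unname(chooseRepresentative(x2, st2)), "solo")
})
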