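#' Configuration for the synthetic GBS study generator
#'
#' Defaults emulate the study design the package is built to assess: two
#' regional clusters of populations, hierarchical differentiation with a
#' stronger between-region than within-region component, overdispersed
#' per-cell read depths around a low mean (so allelic dropout is active), a
#' small sequencing error rate, and a fraction of individuals run as
#' technical replicates from the same DNA.
#'
#' @param nRegions number of regional clusters.
#' @param populationsPerRegion populations per region.
#' @param nIndividualsPerPopulation individuals per population.
#' @param nSnps number of biallelic SNP loci.
#' @param targetFstBetweenRegions,targetFstWithinRegions Balding-Nichols
#'   differentiation targets for the region and population levels.
#' @param meanDepth mean total read depth per SNP per sample.
#' @param depthDispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param sequencingErrorRate per-read probability of being mis-assigned to
#'   the other allele.
#' @param replicateFraction fraction of individuals sequenced twice; about a
#'   sixth of those are sequenced three times.
#' @param tagLength tag length for read emission.
#' @param genomeLength,nGenes,nScaffolds genome fixture dimensions.
#' @param inGeneSiteSamplingProb,intergenicSiteSamplingProb per-library
#'   probability that a restriction site inside / outside a gene yields a
#'   locus (the in-gene excess emulates methylation sensitivity).
#' @param nReplicateLibraries number of digest replicate libraries.
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return a list of class `gbs_sim_config`.
#' @export
simulationConfig <- function(nRegions = 2,
                             populationsPerRegion = 3,
                             nIndividualsPerPopulation = 17,
                             nSnps = 2000,
                             targetFstBetweenRegions = 0.15,
                             targetFstWithinRegions = 0.02,
                             meanDepth = 8,
                             depthDispersion = 2,
                             sequencingErrorRate = 0.01,
                             replicateFraction = 0.2,
                             tagLength = 64,
                             genomeLength = 200000,
                             nGenes = 120,
                             nScaffolds = 6,
                             inGeneSiteSamplingProb = 0.41,
                             intergenicSiteSamplingProb = 0.15,
                             nReplicateLibraries = 16,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(nRegions = nRegions,
              populationsPerRegion = populationsPerRegion,
              nIndividualsPerPopulation = nIndividualsPerPopulation,
              nSnps = nSnps,
              targetFstBetweenRegions = targetFstBetweenRegions,
              targetFstWithinRegions = targetFstWithinRegions,
              meanDepth = meanDepth,
              depthDispersion = depthDispersion,
              sequencingErrorRate = sequencingErrorRate,
              replicateFraction = replicateFraction,
              tagLength = tagLength,
              genomeLength = genomeLength,
              nGenes = nGenes,
              nScaffolds = nScaffolds,
              inGeneSiteSamplingProb = inGeneSiteSamplingProb,
              intergenicSiteSamplingProb = intergenicSiteSamplingProb,
              nReplicateLibraries = nReplicateLibraries,
              seed = as.integer(seed))
  stopifnot(cfg$targetFstBetweenRegions >= 0, cfg$targetFstBetweenRegions < 1,
            cfg$targetFstWithinRegions >= 0, cfg$targetFstWithinRegions < 1,
            cfg$inGeneSiteSamplingProb >= 0, cfg$inGeneSiteSamplingProb <= 1,
            cfg$intergenicSiteSamplingProb >= 0,
            cfg$intergenicSiteSamplingProb <= 1)
  if (cfg$targetFstWithinRegions > cfg$targetFstBetweenRegions)
    warning("within-region F_ST target exceeds the between-region target")
  class(cfg) <- "gbs_sim_config"
  cfg
}

## Balding-Nichols draw: one frequency per element of p, differentiation F
bnDraw <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

## The F_ST targets are expected *pairwise Nei F_ST* values. Two populations
## at Balding-Nichols divergence F from a common ancestor show
## E[(Ht - Hs)/Ht] = F / (2 - F) (the averaged frequencies halve the
## between-population variance), so a pairwise target t needs a beta
## parameter F = 2t/(1 + t). Hierarchically, region and population draws
## compose as F_tot = F_B + F_W (1 - F_B).
bnParamsFromTargets <- function(tBetween, tWithin) {
  fW <- 2 * tWithin / (1 + tWithin)
  fTot <- 2 * tBetween / (1 + tBetween)
  fB <- max((fTot - fW) / (1 - fW), 0)
  list(region = fB, population = fW)
}

#' Simulate hierarchical population structure and true genotypes
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); region
#' frequencies are Balding-Nichols draws around them at the between-region
#' F_ST target, population frequencies Balding-Nichols draws around the
#' region frequency at the within-region target. Genotypes are drawn in HWE
#' within populations. Technical replicates share the individual's genotypes
#' exactly.
#'
#' @param config a [simulationConfig()].
#' @return a list (`gbs_sim_truth`): `alleles` (per-SNP allele1/allele2),
#'   `popFreqs` (SNP x population matrix of allele1 frequencies),
#'   `genotypes` (SNP x individual copies of allele1, 0/1/2),
#'   `sampleTable` (one row per sequenced sample, replicates included),
#'   `replicate_groups`, and `realizedFst` (Nei estimate on the true
#'   genotypes).
#' @export
simulatePopulationStructure <- function(config) {
  cfg <- config
  withSeed(cfg$seed, {
    nPop <- cfg$nRegions * cfg$populationsPerRegion
    popNames <- paste0("P", seq_len(nPop))
    regNames <- paste0("R", rep(seq_len(cfg$nRegions),
                                each = cfg$populationsPerRegion))
    anc <- stats::runif(cfg$nSnps, 0.05, 0.95)
    bn <- bnParamsFromTargets(cfg$targetFstBetweenRegions,
                              cfg$targetFstWithinRegions)
    regFreq <- sapply(seq_len(cfg$nRegions), function(r)
      bnDraw(anc, bn$region))
    regFreq <- matrix(regFreq, ncol = cfg$nRegions)
    popFreq <- sapply(seq_len(nPop), function(k) {
      r <- (k - 1) %/% cfg$populationsPerRegion + 1
      bnDraw(regFreq[, r], bn$population)
    })
    colnames(popFreq) <- popNames
    nInd <- nPop * cfg$nIndividualsPerPopulation
    indPop <- rep(popNames, each = cfg$nIndividualsPerPopulation)
    indIds <- sprintf("I%03d", seq_len(nInd))
    geno <- matrix(0L, cfg$nSnps, nInd,
                   dimnames = list(paste0("snp", seq_len(cfg$nSnps)), indIds))
    for (k in seq_len(nPop)) {
      cols <- which(indPop == popNames[k])
      geno[, cols] <- stats::rbinom(cfg$nSnps * length(cols), 2,
                                    popFreq[, k])
    }
    ## allele identities per SNP
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, cfg$nSnps, replace = TRUE)
    shift <- sample(1:3, cfg$nSnps, replace = TRUE)
    a2 <- bases[(match(a1, bases) - 1L + shift) %% 4L + 1L]
    ## replicate structure: ~replicateFraction of individuals duplicated,
    ## about a sixth of those triplicated
    nDup <- max(1L, round(cfg$replicateFraction * nInd))
    dupInd <- sample(indIds, nDup)
    nTrip <- max(if (nDup >= 6) 1L else 0L, round(nDup / 6))
    tripInd <- if (nTrip > 0) sample(dupInd, nTrip) else character()
    nCopies <- stats::setNames(rep(1L, nInd), indIds)
    nCopies[dupInd] <- 2L
    nCopies[tripInd] <- 3L
    sampleTable <- do.call(rbind, lapply(indIds, function(id) {
      k <- nCopies[[id]]
      data.frame(sample_id = if (k == 1) id else paste0(id, "_r", seq_len(k)),
                 individual_id = id,
                 population_id = indPop[match(id, indIds)],
                 region_id = regNames[match(indPop[match(id, indIds)],
                                            popNames)])
    }))
    rownames(sampleTable) <- NULL
  })
  truth <- list(alleles = data.frame(allele1 = a1, allele2 = a2,
                                     row.names = rownames(geno)),
                popFreqs = popFreq,
                genotypes = geno,
                sampleTable = validateSampleTable(sampleTable),
                replicate_groups = replicateGroups(sampleTable),
                config = cfg)
  truth$realizedFst <- diversityStats(truthGenotypes(truth))$overall$Fst
  class(truth) <- "gbs_sim_truth"
  truth
}

#' True genotypes as a GBSGenotypes object
#'
#' Expands the per-individual true genotypes onto the sequenced samples
#' (replicates share their individual's genotypes) for comparison with called
#' genotypes.
#'
#' @param truth output of [simulatePopulationStructure()].
#' @return a [GBSGenotypes-class] labelled `"truth"`.
#' @export
truthGenotypes <- function(truth) {
  st <- truth$sampleTable
  geno <- truth$genotypes[, st$individual_id, drop = FALSE]
  a1 <- truth$alleles$allele1
  a2 <- truth$alleles$allele2
  g <- matrix("NN", nrow(geno), ncol(geno),
              dimnames = list(rownames(geno), st$sample_id))
  for (v in 0:2) {
    idx <- geno == v
    cell <- switch(as.character(v),
                   "0" = paste0(a2, a2), "1" = paste0(a1, a2),
                   "2" = paste0(a1, a1))
    g[idx] <- matrix(cell, nrow(geno), ncol(geno))[idx]
  }
  GBSGenotypes(g, alleles = truth$alleles, sampleTable = st,
               filter = "truth")
}

#' Simulate per-cell allele read depths
#'
#' Total depth per SNP per sample is negative binomial with mean
#' `meanDepth` and size `depthDispersion`. Reads are assigned to the
#' individual's true alleles (binomial 1/2 split for heterozygotes) and then
#' mis-assigned to the other allele independently at `sequencingErrorRate`.
#' Replicate samples draw independent reads from their shared genotypes.
#'
#' @param truth output of [simulatePopulationStructure()].
#' @param config the same [simulationConfig()]; a derived seed keeps depth
#'   noise independent of the structure draw.
#' @return a [GBSDepthSet-class] over all sequenced samples.
#' @export
simulateDepthMatrix <- function(truth, config = truth$config) {
  cfg <- config
  st <- truth$sampleTable
  geno <- truth$genotypes[, st$individual_id, drop = FALSE]
  nr <- nrow(geno); nc <- ncol(geno)
  withSeed(cfg$seed + 1L, {
    tot <- matrix(stats::rnbinom(nr * nc, mu = cfg$meanDepth,
                                 size = cfg$depthDispersion), nr, nc)
    pTrue <- geno / 2  # fraction of reads from allele1 before error
    d1true <- matrix(stats::rbinom(nr * nc, tot, pTrue), nr, nc)
    err <- cfg$sequencingErrorRate
    flip12 <- matrix(stats::rbinom(nr * nc, d1true, err), nr, nc)
    flip21 <- matrix(stats::rbinom(nr * nc, tot - d1true, err), nr, nc)
    d1 <- d1true - flip12 + flip21
  })
  d2 <- tot - d1
  dimnames(d1) <- dimnames(d2) <- list(rownames(geno), st$sample_id)
  GBSDepthSet(d1, d2, alleles = truth$alleles, sampleTable = st)
}

#' Emit per-sample reads from simulated depths
#'
#' Generates a random distance-1 tag pair for each SNP and emits, for every
#' sample, `d1` copies of the allele-1 tag and `d2` copies of the allele-2
#' tag, shuffled. The result feeds [callSNPs()] end to end.
#'
#' @param depths a [GBSDepthSet-class] from [simulateDepthMatrix()].
#' @param tagLength tag length (default from the depth set's SNPs or 64).
#' @param seed seed for tag generation and shuffling.
#' @return list with `reads` (named list of per-sample read vectors) and
#'   `tags` (per-SNP tag1/tag2/offset data.frame).
#' @export
simulateTagReads <- function(depths, tagLength = 64, seed = 1) {
  al <- snpAlleles(depths)
  n <- nrow(depths)
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    tags <- vapply(seq_len(n), function(i) {
      paste(sample(bases, tagLength, replace = TRUE), collapse = "")
    }, "")
    off <- sample.int(tagLength, n, replace = TRUE) - 1L
    tag1 <- tag2 <- tags
    substr(tag1, off + 1L, off + 1L) <- al$allele1
    substr(tag2, off + 1L, off + 1L) <- al$allele2
    d1 <- depthA(depths); d2 <- depthB(depths)
    reads <- lapply(seq_len(ncol(depths)), function(j) {
      r <- c(rep(tag1, d1[, j]), rep(tag2, d2[, j]))
      if (length(r) > 1) sample(r) else r
    })
    names(reads) <- colnames(depths)
  })
  list(reads = reads,
       tags = data.frame(tag1 = tag1, tag2 = tag2, offset = off,
                         row.names = rownames(depths)))
}

#' Simulate a full synthetic GBS study
#'
#' Convenience wrapper: population structure, true genotypes, and an allele
#' depth matrix, ready for the filtering, concordance and popgen modules.
#'
#' @param config a [simulationConfig()].
#' @return list with `truth` and `depths`.
#' @export
simulateStudy <- function(config) {
  truth <- simulatePopulationStructure(config)
  list(truth = truth, depths = simulateDepthMatrix(truth, config))
}

#' Simulate a genome fixture for digest assessment
#'
#' Builds a random multi-scaffold genome, annotates non-overlapping gene
#' intervals, plants degenerate restriction sites (`GCWGC`) inside and
#' outside genes, then has each replicate library sample each realised site
#' independently — with the in-gene probability for sites inside genes and
#' the intergenic probability otherwise — emulating the methylation-driven
#' bias toward coding regions.
#'
#' @param config a [simulationConfig()].
#' @param inGeneSiteDensity,intergenicSiteDensity planted sites per base
#'   inside / outside genes.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (0-based half-open data.frame), `catalog` (realised site catalog with
#'   gene flags, from a full rescan so chance hits are included), and
#'   `locusSets` (per-library locus-id sets).
#' @export
simulateGenomeFixture <- function(config,
                                  inGeneSiteDensity = 1 / 400,
                                  intergenicSiteDensity = 1 / 400) {
  cfg <- config
  withSeed(cfg$seed + 2L, {
    bases <- c("A", "C", "G", "T")
    lens <- rep(cfg$genomeLength %/% cfg$nScaffolds, cfg$nScaffolds)
    lens[1] <- lens[1] + cfg$genomeLength %% cfg$nScaffolds
    scafNames <- paste0("scaffold", seq_len(cfg$nScaffolds))
    seqs <- lapply(lens, function(L)
      sample(bases, L, replace = TRUE))
    ## non-overlapping gene intervals, allocated proportionally to length
    geneCounts <- pmax(1L, round(cfg$nGenes * lens / sum(lens)))
    genes <- list()
    for (s in seq_len(cfg$nScaffolds)) {
      L <- lens[s]; k <- geneCounts[s]
      gLen <- pmin(L %/% (2 * k), 1500L)
      starts <- sort(sample.int(L - gLen, k))
      ## push apart to avoid overlap
      starts <- pmin(starts + (seq_len(k) - 1L) * 0L, L - gLen)
      keep <- c(TRUE, diff(starts) >= gLen)
      starts <- starts[keep]
      genes[[s]] <- data.frame(scaffold = scafNames[s],
                               start = starts - 1L,
                               end = starts - 1L + gLen,
                               gene_id = paste0("g", s, "_", seq_along(starts)))
    }
    genes <- do.call(rbind, genes)
    ## plant motifs
    motifs <- c("GCAGC", "GCTGC")
    for (s in seq_len(cfg$nScaffolds)) {
      L <- lens[s]
      gHere <- genes[genes$scaffold == scafNames[s], , drop = FALSE]
      inGeneMask <- logical(L)
      for (i in seq_len(nrow(gHere)))
        inGeneMask[(gHere$start[i] + 1L):gHere$end[i]] <- TRUE
      candIn <- which(inGeneMask[seq_len(L - 5L)])
      candOut <- which(!inGeneMask[seq_len(L - 5L)])
      nIn <- stats::rbinom(1, length(candIn), inGeneSiteDensity * 5)
      nOut <- stats::rbinom(1, length(candOut), intergenicSiteDensity * 5)
      plant <- function(pos1) {
        for (p in pos1) {
          m <- sample(motifs, 1)
          seqs[[s]][p:(p + 4L)] <<- strsplit(m, "")[[1]]
        }
      }
      if (nIn > 0) plant(sample(candIn, min(nIn, length(candIn))))
      if (nOut > 0) plant(sample(candOut, min(nOut, length(candOut))))
    }
    genome <- Biostrings::DNAStringSet(
      vapply(seqs, paste, "", collapse = ""))
    names(genome) <- scafNames
    catalog <- findRestrictionSites(genome, "GCWGC")
    catalog <- intersectWithGenes(catalog, genes)
    siteIds <- paste0(as.character(GenomicRanges::seqnames(catalog)), ":",
                      GenomicRanges::start(catalog) - 1L)
    pSamp <- ifelse(catalog$in_gene, cfg$inGeneSiteSamplingProb,
                    cfg$intergenicSiteSamplingProb)
    locusSets <- lapply(seq_len(cfg$nReplicateLibraries), function(r)
      siteIds[stats::runif(length(siteIds)) < pSamp])
    names(locusSets) <- paste0("rep", seq_len(cfg$nReplicateLibraries))
  })
  list(genome = genome, genes = genes, catalog = catalog,
       locusSets = locusSets)
}

#' Write a genome fixture to disk
#'
#' Emits the FASTA genome, a GFF3 of gene features (1-based closed, as the
#' format requires) and one BED file of sampled loci per replicate library.
#'
#' @param fixture output of [simulateGenomeFixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeGenomeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(fixture$genome, fa)
  gff <- file.path(dir, "genes.gff3")
  g <- fixture$genes
  writeLines(c("##gff-version 3",
               sprintf("%s\tgbstk\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       g$scaffold, g$start + 1L, g$end, g$gene_id)), gff)
  beds <- vapply(names(fixture$locusSets), function(r) {
    path <- file.path(dir, paste0(r, ".bed"))
    ids <- fixture$locusSets[[r]]
    scf <- sub(":.*$", "", ids)
    pos <- as.integer(sub("^.*:", "", ids))
    utils::write.table(data.frame(scf, pos, pos + 5L), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    path
  }, "")
  invisible(c(fa, gff, beds))
}
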