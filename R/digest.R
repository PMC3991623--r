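#' In silico restriction digest of a genome
#'
#' Scans every scaffold for matches to an IUPAC restriction motif (default
#' *Ape*KI, `GCWGC`, W = A or T). The motif is palindromic, so scanning is
#' strand-agnostic and each site is reported once, on the forward strand.
#' Overlapping matches are all reported.
#'
#' @param genome a named [Biostrings::DNAStringSet] or named character vector
#'   of scaffold sequences.
#' @param motif IUPAC motif string.
#' @return a [GenomicRanges::GRanges] of motif hits (1-based start, motif
#'   width); use [writeSiteBed()] for 0-based half-open export.
#' @export
findRestrictionSites <- function(genome, motif = "GCWGC") {
  if (!is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  if (length(genome) == 0) stop("genome is empty")
  if (is.null(names(genome))) stop("genome scaffolds must be named")
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!all(strsplit(toupper(motif), "")[[1]] %in% iupac))
    stop("motif contains non-IUPAC characters: ", motif)
  pat <- Biostrings::DNAString(toupper(motif))
  hits <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern(pat, genome[[i]], fixed = FALSE)
    if (length(m) == 0) return(integer())
    ## an ambiguous base in the assembly never counts as a cut site: keep
    ## only matches whose genome letters are plain A/C/G/T
    plain <- rowSums(Biostrings::letterFrequency(m, c("A", "C", "G", "T"))) ==
      nchar(motif)
    Biostrings::start(m)[plain]
  })
  out <- GenomicRanges::GRanges(
    S4Vectors::Rle(factor(rep(names(genome), lengths(hits)),
                          levels = names(genome))),
    IRanges::IRanges(unlist(hits, use.names = FALSE) %||% integer(),
                     width = nchar(motif)))
  out <- sort(out)
  mcols(out)$in_gene <- rep(NA, length(out))
  out
}

#' Flag restriction sites falling within annotated genes
#'
#' A site is `in_gene` iff its motif start position lies within a gene
#' interval (0-based half-open; the half-open end excludes a site starting at
#' the gene end). Gene membership is decided by the motif start alone.
#'
#' @param catalog a site catalog from [findRestrictionSites()].
#' @param genes gene intervals from [readGffGenes()] (`scaffold`, `start`,
#'   `end` 0-based half-open, `gene_id`).
#' @return the catalog with `in_gene` filled in and counts in `metadata()`:
#'   `n_total`, `n_in_gene`, `fraction_in_gene`.
#' @export
intersectWithGenes <- function(catalog, genes) {
  pos0 <- GenomicRanges::start(catalog) - 1L
  inGene <- rep(FALSE, length(catalog))
  if (nrow(genes) > 0) {
    ## point query: start0 in [gene start, gene end)
    q <- GenomicRanges::GRanges(GenomicRanges::seqnames(catalog),
                                IRanges::IRanges(pos0 + 1L, width = 1L))
    s <- GenomicRanges::GRanges(genes$scaffold,
                                IRanges::IRanges(genes$start + 1L, genes$end))
    inGene <- IRanges::overlapsAny(q, s)
  }
  mcols(catalog)$in_gene <- inGene
  S4Vectors::metadata(catalog) <- list(
    n_total = length(catalog),
    n_in_gene = sum(inGene),
    fraction_in_gene = if (length(catalog)) sum(inGene) / length(catalog) else 0)
  catalog
}

#' Test enrichment of sampled loci in genes
#'
#' One-degree-of-freedom goodness-of-fit chi-square comparing observed
#' in-gene / out-of-gene counts among sampled loci against the genome-wide
#' background fraction of in-gene restriction sites (a "simple contingency
#' test" of gene-region sampling bias).
#'
#' @param observedInGene number of sampled loci inside genes.
#' @param observedTotal total sampled loci.
#' @param backgroundFraction genome-wide in-gene fraction of sites.
#' @return list with `statistic`, `df`, `p.value`, `observed_fraction`.
#' @export
geneEnrichmentTest <- function(observedInGene, observedTotal,
                               backgroundFraction) {
  stopifnot(observedTotal > 0,
            backgroundFraction >= 0, backgroundFraction <= 1)
  if (observedInGene > observedTotal)
    stop("observedInGene exceeds observedTotal")
  expected <- observedTotal * c(backgroundFraction, 1 - backgroundFraction)
  observed <- c(observedInGene, observedTotal - observedInGene)
  if (any(expected == 0)) {
    stat <- if (all(observed[expected == 0] == 0)) 0 else Inf
  } else {
    stat <- sum((observed - expected)^2 / expected)
  }
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       observed_fraction = observedInGene / observedTotal)
}

#' Per-scaffold gene-sampling table
#'
#' For each scaffold: the number of genes containing at least one restriction
#' site, the number of those genes sampled (a gene counts as sampled if any of
#' its sites appears in any replicate locus set), and the expected number
#' under even sampling — the scaffold's gene count times the overall pooled
#' proportion of site-containing genes sampled.
#'
#' @param catalog site catalog with gene flags from [intersectWithGenes()].
#' @param genes gene intervals from [readGffGenes()].
#' @param locusSets list of per-replicate locus-id sets (`"scaffold:start0"`),
#'   e.g. from [readLocusBed()] or [simulateGenomeFixture()].
#' @return data.frame with one row per scaffold: `scaffold`, `n_sites`,
#'   `n_apeki_genes`, `observed_sampled_genes`, `expected_sampled_genes`.
#' @export
scaffoldSamplingTable <- function(catalog, genes, locusSets) {
  pos0 <- GenomicRanges::start(catalog) - 1L
  scf <- as.character(GenomicRanges::seqnames(catalog))
  siteId <- paste0(scf, ":", pos0)
  sampled <- siteId %in% unique(unlist(locusSets, use.names = FALSE))
  ## map each site to the genes containing it (sites can hit several genes)
  q <- GenomicRanges::GRanges(scf, IRanges::IRanges(pos0 + 1L, width = 1L))
  s <- GenomicRanges::GRanges(genes$scaffold,
                              IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  geneHasSite <- unique(S4Vectors::subjectHits(ov))
  geneSampled <- unique(S4Vectors::subjectHits(ov)[sampled[S4Vectors::queryHits(ov)]])
  overallProp <- if (length(geneHasSite)) length(geneSampled) / length(geneHasSite) else 0
  scaffolds <- unique(scf)
  nSites <- table(factor(scf, levels = scaffolds))
  nGenes <- table(factor(genes$scaffold[geneHasSite], levels = scaffolds))
  nObs <- table(factor(genes$scaffold[geneSampled], levels = scaffolds))
  data.frame(scaffold = scaffolds,
             n_sites = as.integer(nSites),
             n_apeki_genes = as.integer(nGenes),
             observed_sampled_genes = as.integer(nObs),
             expected_sampled_genes = as.integer(nGenes) * overallProp,
             row.names = NULL)
}

#' Chi-square test of even gene sampling across scaffolds
#'
#' Goodness-of-fit chi-square of observed versus expected sampled-gene counts
#' over scaffolds containing more than `minSites` restriction sites, with
#' `df = n_scaffolds - 1`. The asymptotic distribution is used; expected
#' counts below 1 raise a warning, not a correction.
#'
#' @param samplingTable output of [scaffoldSamplingTable()].
#' @param minSites scaffolds must have strictly more sites than this.
#' @return list with `statistic`, `df`, `p.value`, `n_scaffolds`.
#' @export
scaffoldSamplingTest <- function(samplingTable, minSites = 5) {
  tab <- samplingTable[samplingTable$n_sites > minSites, , drop = FALSE]
  if (nrow(tab) < 2)
    stop("fewer than two scaffolds exceed the site threshold")
  o <- tab$observed_sampled_genes
  e <- tab$expected_sampled_genes
  if (any(e == 0))
    stop("expected count of zero for scaffold(s) ",
         paste(tab$scaffold[e == 0], collapse = ", "),
         "; exclude these scaffolds")
  if (any(e < 1))
    warning("expected counts below 1; asymptotic p-value may be inaccurate")
  stat <- sum((o - e)^2 / e)
  df <- nrow(tab) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       n_scaffolds = nrow(tab))
}

#' Locus accumulation curve over replicate libraries
#'
#' Average, over random orderings of the replicate libraries, of the number of
#' unique loci recovered after adding the first k libraries. The final step
#' always equals the size of the union.
#'
#' @param locusSets named list of per-replicate locus-id vectors.
#' @param nPermutations number of random orderings to average over.
#' @param seed integer seed for the orderings.
#' @return data.frame with `step`, `mean_loci`, `sd_loci`.
#' @export
accumulationCurve <- function(locusSets, nPermutations = 1000, seed = 1) {
  if (length(locusSets) == 0) stop("no replicate locus sets supplied")
  sets <- lapply(locusSets, unique)
  uni <- unique(unlist(sets, use.names = FALSE))
  idx <- lapply(sets, match, uni)
  n <- length(sets)
  counts <- matrix(0, nrow = nPermutations, ncol = n)
  withSeed(seed, {
    for (p in seq_len(nPermutations)) {
      ord <- sample.int(n)
      seen <- logical(length(uni))
      tot <- 0L
      for (k in seq_len(n)) {
        new <- idx[[ord[k]]]
        newMask <- !seen[new]
        tot <- tot + sum(newMask)
        seen[new[newMask]] <- TRUE
        counts[p, k] <- tot
      }
    }
  })
  data.frame(step = seq_len(n),
             mean_loci = colMeans(counts),
             sd_loci = apply(counts, 2, stats::sd))
}

#' Replicate presence spectrum
#'
#' For k = 1..n replicates, the number and fraction of loci (over the union)
#' detected in exactly k replicate libraries.
#'
#' @param locusSets named list of per-replicate locus-id vectors.
#' @return data.frame with `k`, `n_loci`, `fraction`.
#' @export
replicatePresenceSpectrum <- function(locusSets) {
  if (length(locusSets) == 0) stop("no replicate locus sets supplied")
  sets <- lapply(locusSets, unique)
  cnt <- table(unlist(sets, use.names = FALSE))
  k <- factor(as.integer(cnt), levels = seq_along(sets))
  tab <- table(k)
  data.frame(k = seq_along(sets),
             n_loci = as.integer(tab),
             fraction = as.integer(tab) / length(cnt))
}

## Run code under a local RNG state seeded with `seed`, restoring the caller's
## state afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
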