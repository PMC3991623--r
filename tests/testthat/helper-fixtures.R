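suppressPackageStartupMessages({
  library(S4Vectors)
  library(SummarizedExperiment)
})

## Build a small GBSDepthSet from two depth matrices (alleles default A/G).
makeDepthSet <- function(d1, d2, allele1 = "A", allele2 = "G",
                         sampleTable = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (is.null(rownames(d1))) {
    rownames(d1) <- rownames(d2) <- paste0("snp", seq_len(nrow(d1)))
  }
  if (is.null(colnames(d1))) {
    colnames(d1) <- colnames(d2) <- paste0("S", seq_len(ncol(d1)))
  } else colnames(d2) <- colnames(d1)
  rownames(d2) <- rownames(d1)
  GBSDepthSet(d1, d2,
              alleles = data.frame(
                allele1 = rep_len(allele1, nrow(d1)),
                allele2 = rep_len(allele2, nrow(d1))),
              sampleTable = sampleTable)
}

## Build a GBSGenotypes from a character matrix (alleles default A/G).
makeGenotypes <- function(g, allele1 = "A", allele2 = "G",
                          sampleTable = NULL, filter = "none") {
  g <- as.matrix(g)
  if (is.null(rownames(g))) rownames(g) <- paste0("snp", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- paste0("S", seq_len(ncol(g)))
  GBSGenotypes(g,
               alleles = data.frame(allele1 = rep_len(allele1, nrow(g)),
                                    allele2 = rep_len(allele2, nrow(g))),
               sampleTable = sampleTable, filter = filter)
}

## Sample table for n samples split over populations/regions.
makeSampleTable <- function(samples, populations, regions,
                            individuals = samples) {
  data.frame(sample_id = samples, individual_id = individuals,
             population_id = populations, region_id = regions)
}

## Independent brute-force sliding-window motif scan (no regex, no
## Biostrings): returns 0-based positions per scaffold.
bruteForceSiteScan <- function(seqs, motif = "GCWGC") {
  expand <- list(A = "A", C = "C", G = "G", T = "T", W = c("A", "T"))
  pat <- strsplit(motif, "")[[1]]
  lapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch); m <- length(pat)
    hits <- integer()
    for (i in seq_len(max(L - m + 1L, 0L))) {
      ok <- TRUE
      for (j in seq_len(m))
        if (!ch[i + j - 1L] %in% expand[[pat[j]]]) { ok <- FALSE; break }
      if (ok) hits <- c(hits, i - 1L)
    }
    hits
  })
}

## Exact enumeration oracle for the HWE conditional test: integer-weight
## computation straight from the definition, independent of the package's
## log-space implementation.
hweEnumOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  minor <- min(nA, 2 * n - nA)
  if (minor == 0) return(1)
  hs <- seq(minor %% 2, minor, by = 2)
  w <- vapply(hs, function(h) {
    hm <- (minor - h) / 2
    hM <- n - h - hm
    factorial(n) / (factorial(hm) * factorial(hM) * factorial(h)) * 2^h
  }, 0)
  probs <- w / sum(w)
  pObs <- probs[match(nAa, hs)]
  sum(probs[probs <= pObs + 1e-12])
}

## All-pairs Hamming-distance-1 scan used as the tag-pairing oracle.
bruteForcePairs <- function(tags) {
  n <- length(tags)
  out <- matrix(integer(), ncol = 2)
  if (n < 2) return(out)
  sp <- strsplit(tags, "")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sum(sp[[i]] != sp[[j]]) == 1L)
      out <- rbind(out, c(i, j))
  }
  out
}
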