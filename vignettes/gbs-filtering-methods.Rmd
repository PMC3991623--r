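---
title: "Models and methods behind gbstk: digest bias, depth-aware filtering, and replicate error"
author: "gbstk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbstk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbstk)
```

This vignette explains the statistical models and the procedural choices
implemented in `gbstk`: what each component assumes, which parameters
matter, how the synthetic-data generator is constructed, and where the
design was genuinely open and a choice had to be made.

## 1. The measurement problem

A GBS library reduces a genome to fragments anchored at the recognition
sites of a restriction enzyme and sequences them shallowly across many
barcoded samples. Two consequences drive everything in this package:

* **Sampling bias.** A methylation-sensitive enzyme (*Ape*KI, `GCWGC`)
  preferentially cuts unmethylated DNA, so recovered loci over-represent
  genic regions relative to an in silico digest, which is agnostic to
  methylation.
* **Allelic dropout.** With a handful of reads per locus per individual,
  a true heterozygote often shows reads from only one allele. The
  probability that a heterozygote at total depth $d$ shows a single allele
  is $2 \cdot (1/2)^d$ (1/8 at $d = 4$). Dropout inflates homozygosity,
  depresses observed heterozygosity $H_O$, and produces heterozygote-
  deficit departures from Hardy–Weinberg equilibrium.

## 2. In silico digest assessment

`findRestrictionSites()` scans every scaffold with the IUPAC motif
expanded (`matchPattern(..., fixed = FALSE)`), reporting all, including
overlapping, matches. Because `GCWGC` is palindromic, scanning is
strand-agnostic and each site is reported once on the forward strand. A
match whose *genome* letters include an ambiguity code is discarded: an
`N` or `W` in the assembly is not evidence of a cut site. On genomes up to
1 Mb the scan is verified in the test suite against a position-by-position
sliding-window oracle.

A site belongs to a gene iff its motif start lies inside the gene interval
(0-based half-open; conversion from GFF3's 1-based closed coordinates
happens only in `readGffGenes()`). Membership by the start coordinate
alone is a deliberate single-point rule: partial-overlap handling has no
canonical definition, and a point rule is unambiguous at both gene
boundaries.

Two chi-square tests summarise sampling:

* `geneEnrichmentTest()` is a 1-df goodness-of-fit test of the sampled
  in-gene/out-of-gene split against the genome-wide in-gene fraction of
  sites. Enrichment is judged **per replicate library**: pooling libraries
  saturates intergenic sites (a site present in any one of n libraries
  counts) and dilutes the bias being measured.
* `scaffoldSamplingTest()` compares observed sampled-gene counts per
  scaffold with `n_genes × overall sampled proportion`, over scaffolds
  with more than five sites, on `df = n_scaffolds − 1`. The asymptotic
  distribution is used; expected counts below 1 warn and are not
  corrected. Calibration caveat: the statistic is calibrated against a
  multinomial allocation null. When genes are instead sampled
  independently with a high per-gene probability $p$, the per-scaffold
  variance is $np(1-p) < np$, and the test is conservative (it
  under-rejects); the test suite demonstrates both behaviours.

`accumulationCurve()` averages the cumulative count of unique loci over
random orderings of the replicate libraries (default 1000 permutations,
explicit seed, default 1). Exactness at tiny scale is tested against the
full average over all 3! orderings of three sets. `replicatePresenceSpectrum()`
tabulates how many loci appear in exactly k of n libraries.

## 3. Reference-free SNP calling

The calling model follows the UNEAK idea: reads are truncated to a fixed
tag length (64 bp, minimising the influence of error-prone read tails),
identical reads collapse into tags with per-sample counts, and a tag pair
at Hamming distance exactly 1 is a candidate biallelic SNP.

*Network resolution.* A tag participating in more than one distance-1 pair
is excluded together with all its pairs; only reciprocally unique pairs
yield SNPs. This is the conservative reading of a network filter: a hub
tag connected to several variants more likely reflects a repeat family or
recurrent error than a clean biallelic site. Pair search uses a two-half
partition index (a distance-1 pair agrees exactly on at least one half of
the sequence), and the contract — equality with a brute-force all-pairs
Hamming scan — is asserted in the tests.

Two pre-filters follow. The depth cap (default 127) removes SNPs whose
depth in **any single sample** exceeds the cap, flagging multi-copy loci;
`--depth-cap-scope total` (argument `scope = "total"`) applies the cap to
the depth summed across samples instead, since which scope the historical
limit refers to is ambiguous. The MAF pre-filter computes the minor-allele
frequency from depths summed over all samples, `min(Σd₁, Σd₂)/Σ(d₁+d₂)` —
at this stage no genotypes exist, so a depth-based frequency is the only
option — and removes SNPs strictly below 0.05.

## 4. Genotype filtering strategies

Filtering operates on each allele-depth cell $(d_1, d_2)$; SNP-level
pruning is a separate concern handled by missingness (below). With
threshold $t = 4$ (configurable) and homozygote threshold $2t$:

| strategy | heterozygote | homozygote | ambiguous | missing |
|---|---|---|---|---|
| unfiltered | $d_1>0, d_2>0$ | one allele observed | — | $d_1=d_2=0$ |
| TF | both $\ge t$ | one $\ge t$ | — | otherwise |
| AF | both $\ge t$ | one $\ge 2t$ | one in $[t, 2t)$ → `A?` | otherwise |
| MAFF | $m \ge 0.45$ | $m < 0.45$, majority allele | — | $d_1=d_2=0$ |

with $m = \min(d_1,d_2)/(d_1+d_2)$. Design notes:

* The TF is implemented per allele (each asserted allele needs $\ge t$
  reads), which reconciles "a heterozygote needs $t$ reads of each allele"
  with a cell-level minimum of $t$; both thresholds are configurable.
* The AF exists because the TF is asymmetric: $t$ reads suffice for a
  homozygote but $2t$ are implicitly required of a heterozygote. The AF
  makes the second allele's status explicit — `A?` says "one allele is A;
  the other is unknown", and every downstream statistic treats `?` as
  missing information, never as a mismatch.
* MAFF ties ($d_1 = d_2$, so $m = 0.5 \ge 0.45$) are heterozygotes.
* MAFF has a structural property worth stating plainly: a true
  heterozygote's reads split $\mathrm{Bin}(d, 1/2)$, so the probability
  that $m \ge 0.45$ is only ~0.5 at $d = 40$ and approaches 1 only at
  depths (~10³) no GBS design reaches. MAFF therefore under-calls
  heterozygotes at *any* realistic depth — the mechanism behind its
  collapsed $H_O$ — while being essentially exact on homozygotes.

`dropMissing()` removes SNP rows with $\ge$ 90% `NN`, then sample columns
judged on the surviving rows (the order matters and is tested), and the
row pass is repeated after filtering. `filterPipeline()` chains the
pre-pass on unfiltered calls, the chosen strategy, and the post-pass, and
logs counts removed at each stage. Because TF and AF differ only in how a
single-allele call is labelled, their `NN` patterns — and hence their
retained SNP/sample sets — are provably identical.

## 5. Replicate concordance and depth tests

Technical replicates (same DNA, independent libraries) provide an indirect
error assay. Genotypes are compared as allele multisets: `GA` vs `GG` is
one mismatch, `GG` vs `AA` two; `?` and `N` alleles never count as
mismatches, and a comparison touching `?` is tallied separately as
ambiguous. For triplicates all three pairwise comparisons are scored (the
symmetric choice). The pooled rate divides mismatching alleles by
$2 \times \mathrm{SNPs} \times \mathrm{pairs}$; a `comparable` denominator
(excluding `NN` comparisons) is available because the literal denominator
conflates missingness with discordance — at very low depth the literal
rate first *rises* with depth while the comparable rate falls
monotonically, which is the cleaner statement of the depth–error
association.

Dropout pairs (one heterozygote, one homozygote sharing an allele) feed a
Wilcoxon signed-rank test of heterozygote-minus-homozygote total depth
(`stats::wilcox.test`, exact for small n without ties, normal
approximation with tie correction otherwise), plus the fraction of pairs
where the homozygote is the shallower member. Mismatched vs matched
homozygote pairs feed a Mann–Whitney test on pooled per-cell depths. For
population analyses each individual is represented once, by the replicate
with the greatest summed depth; exact ties break to the lexicographically
smallest sample id so results are deterministic.

## 6. Population statistics

`hweExactP()` implements the conditional exact test for a biallelic locus:
given $n$ individuals and the observed minor-allele count, each compatible
heterozygote count $h$ has probability
$P(h) = \frac{n!}{n_{AA}!\,n_{Aa}!\,n_{aa}!} 2^h \big/ \binom{2n}{n_A}$,
and the p-value sums $P(h)$ over outcomes no more probable than the
observed one. Computation is in log space with a $(1 + 10^{-9})$ relative
tolerance on the "no more probable" comparison; the suite verifies exact
agreement with full enumeration for **all** genotype configurations with
$n \le 10$ and allele-relabelling invariance. Pooled summaries test each
SNP in each population with at least `min_pop_n = 10` samples (small
populations are excluded rather than hard-coded by name) and restrict to
SNP × population combinations that are polymorphic — a monomorphic sample
yields the degenerate p = 1 and would only dilute the pooled
distribution.

Diversity follows the Nei (1987) gene-diversity formulation with
small-sample correction (the conventions of hierfstat's basic statistics):
per locus, $H_O$ is the unweighted mean over populations of the observed
heterozygote fraction; $H_S = \frac{\tilde n}{\tilde n - 1}\left(1 -
\overline{\sum_i p_i^2} - \frac{H_O}{2\tilde n}\right)$ with $\tilde n$
the harmonic mean sample size; $H_T$ adds the correction terms on the mean
allele frequencies; and $F_{ST} = (H_T - H_S)/H_T$ is formed from the
per-locus means of $H_T$ and $H_S$. Negative per-locus values are retained
in all means — truncation would bias small contrasts upward, and genuinely
undifferentiated population pairs should be allowed to average below zero.
Genotypes containing `?` contribute nothing (treated fully missing) rather
than half-information; the Weir–Cockerham estimator was considered and the
gene-diversity estimator chosen as the default because it is the
convention of the basic-statistics workflow this package mirrors.
`pairwiseFst()` applies the same estimator to each population pair and
averages pairs within and between regions separately; a region with a
single population simply has no within-region pairs and reports `NA`.

## 7. The synthetic-data generator

The generator exists so that every pipeline stage is testable without any
external download, with the statistical structure the analyses assume:

* **Structure.** Ancestral frequencies uniform on (0.05, 0.95); region
  then population frequencies via hierarchical Balding–Nichols beta draws.
  The configured targets are *expected pairwise Nei F_ST* values. Two
  populations at beta-divergence $F$ from a common ancestor have
  $E[(H_T - H_S)/H_T] = F/(2 - F)$ (averaging frequencies halves the
  between-population variance), so targets $t$ are converted via
  $F = 2t/(1+t)$ and composed hierarchically
  ($F_{tot} = F_B + F_W(1 - F_B)$) before drawing. With 2,000 loci the
  realised pairwise means recover 0.15/0.02 within ±0.03.
* **Genotypes** are drawn in HWE within populations; replicates share the
  individual's genotypes exactly ("same DNA"), and draw independent reads.
* **Depths.** Total cell depth is negative binomial (default mean 8, size
  2) — Poisson sampling is too regular for GBS, where barcode efficiency
  and fragment representation vary — with a binomial 1/2 allele split for
  heterozygotes and symmetric per-read mis-assignment at the configured
  error rate (default 1%).
* **Study shape** mirrors a two-cluster range-wide design: 2 regions × 3
  populations × 17 individuals (~102 individuals, in the spirit of a
  ~100-genet study across six populations), a fifth of individuals
  duplicated and about a sixth of those triplicated, 64-bp tags.
* **Genome fixture.** A random multi-scaffold genome with non-overlapping
  gene intervals and `GCWGC` motifs planted at controlled densities inside
  and outside genes; the catalog used downstream comes from a full rescan,
  so chance hits are included. Each replicate library samples each site
  independently with probability 0.41 (in-gene) or 0.15 (intergenic) —
  values derived from a per-replicate sampling rate of 27% combined with a
  69.8% in-gene share against a 45.9% in-gene background.

What the generator deliberately does **not** emulate: per-site cutting
heterogeneity (every in-gene site shares one sampling probability, so with
16 libraries essentially no locus appears in *all* libraries, whereas real
digests show a U-shaped presence spectrum with a sizeable always-recovered
class); PCR duplicates and fragment-size selection; methylation
biochemistry itself (only its sampling consequence); and linkage — loci
are independent. Passing tests therefore validate the estimators and the
filtering logic under the stated model, not the full error structure of a
real sequencing run.

Two regime notes that matter when interpreting simulations:

* With base-call error present, deeper data convert error reads into
  spurious heterozygotes; the error-free depth series is the clean way to
  see the dropout-driven heterozygote deficit shrink with depth.
* Which filter's $H_O$ lands closest to the truth depends on the depth
  regime. At moderate depth (mean ~6–8, mild overdispersion) unfiltered
  calls are nearly unbiased. In the sparse, strongly overdispersed regime
  of heavily multiplexed GBS (mean ~3, NB size < 1), the ambiguity
  filter is the least biased, because its `?` cells absorb exactly the
  genotypes dropout corrupts — this is the regime where the real data's
  behaviour is reproduced.

## 8. Numerical and procedural conventions

* All interval logic is 0-based half-open internally; GFF3 import is the
  single 1-based conversion point. BED output is 0-based half-open.
* HapMap cells are two characters so the `?` allele is representable;
  `N` appears only as `NN`, and `?` never co-occurs with `N`.
* Every stochastic routine takes an explicit seed and runs on a local RNG
  state, leaving the caller's `.Random.seed` untouched; a simulation
  config makes the seed mandatory.
* Chi-square p-values use the asymptotic distribution throughout, with a
  warning (not a correction) on expected counts below 1.
* Problem sizes in the test suite (hundreds of SNPs, ~100 individuals,
  100-run property loops at 600–1,000 loci, one 1-Mb oracle genome) were
  chosen as the smallest scales at which the tested contrasts are
  statistically unambiguous.

## 9. Known limitations

* The scaffold-uniformity chi-square inherits the conservativeness
  described above whenever per-gene sampling is close to independent with
  high probability.
* The exact HWE test is binomial/biallelic; multi-allelic sites never
  arise in the tag-pair model.
* Mismatch classification treats any comparison involving `?` as
  "ambiguous" even when the asserted alleles differ; the definite-allele
  differences still enter the pooled numerator.
* The archived genotype deposit of the motivating study can be analysed by
  the same functions (`readHapMap`, sample table, the popgen module), but
  no network access is assumed anywhere; absent the deposit, the synthetic
  study is the reference workload.
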