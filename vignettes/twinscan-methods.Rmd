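---
title: "Methods: selection scans and rare-variant screening for a twinning trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans and rare-variant screening for a twinning trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinscan)
```

## The problem

Twin calving in cattle is a rare, low-heritability reproductive trait. A
cohort of cows with twin-calving records can be contrasted against
non-twinning controls to look for genomic regions under selection (or
enrichment) for the trait, and — because causal variants for a rare trait
are expected to be rare in general populations while enriched in carriers —
for individual alleles that are rare everywhere except the twin cohort.
`twinscan` implements that full chain on diploid biallelic SNP genotypes:
cohort QC, population-structure summaries, a windowed two-statistic
selection scan, and a cross-population rare-allele screen with gene-context
annotation, plus a synthetic-cohort generator that provides planted ground
truth for end-to-end validation.

## Statistics

### Relatedness

The identity-by-state *distance* between samples $i$ and $j$ is

$$D_{ij} = 1 - \frac{\sum_l \left(2 - |x_{il} - x_{jl}|\right)}{2\,m_{ij}},$$

over the $m_{ij}$ loci genotyped in both samples, $x \in \{0,1,2\}$ the
alternate-allele dosage. The distance orientation (unrelated pairs large,
duplicates zero) is deliberate: heatmap summaries of cohorts read distant
pairs as high values. The genomic relationship matrix is the
allele-frequency-standardized (VanRaden-style) form

$$G_{ik} = \frac{1}{m_{ik}}\sum_j \frac{(x_{ij} - 2p_j)(x_{kj} - 2p_j)}{2p_j(1-p_j)},$$

with $p_j$ estimated from the analyzed table itself and missing genotypes
excluded pairwise. A consequence of in-sample frequencies worth knowing
when reading $G$: unrelated pairs center at $-1/(n-1)$, not exactly 0 (the
standardized columns sum to approximately zero). PCA standardizes each
variant by $1/\sqrt{2p(1-p)}$, mean-imputes missing dosages and takes the
top singular vectors scaled by their singular values; this is identical to
an eigendecomposition of the genomic covariance. Neighbor-joining trees use
the Saitou–Nei Q-criterion (via `ape::nj`); negative branch lengths, an NJ
artifact on noisy non-additive matrices, are clamped to zero with the
deficit transferred to sibling branches.

### Runs of homozygosity

ROH detection follows the PLINK sliding-window semantics with the standard
parameter set (window of 50 SNPs tolerating 3 heterozygous and 5 missing
calls; a SNP is "in run" when at least 5% of the windows covering it are
homozygous-compatible; runs are split at inter-SNP gaps above 100 kb and
must hold ≥ 50 SNPs, span ≥ 500 kb and average ≤ 50 kb per SNP). Segment
coordinates are SNP-delimited. Byte-matching PLINK is *not* a goal — the
hit-rate rule tends to extend run boundaries a few SNPs into heterozygous
flanks, exactly as PLINK does — and the package's acceptance surface is
truth recovery on planted tracts instead. The genomic inbreeding
coefficient is $F_{ROH} = \sum L_{ROH} / L_{genome}$ with the cattle
autosome total 2,489.39 Mb as the default denominator (stored as a double:
the constant exceeds the 32-bit integer range). Chromosomes holding fewer
SNPs than one window are evaluated with a single truncated window.

### Linkage disequilibrium

$r^2$ is the squared Pearson correlation of dosage vectors over jointly
called samples — genotype LD, since phase is never assumed for unphased
resequencing input — for all intra-chromosome pairs within 500 kb. The
decay curve averages $r^2$ in 1-kb distance bins by default; bins are
half-open $((b{-}1)w, bw]$ so they tile the cap. The null expectation for
independent markers is $\approx 1/n$, which the tests exercise. A simple
window-based pruner (`ld_prune()`) is provided as a utility for structure
analyses.

### The selection scan

Sites are scored with the Weir–Cockerham (1984) two-population variance
components $a$ (among populations), $b$ (among individuals) and $c$
(within individuals), computed from per-group sample sizes, allele
frequencies and observed heterozygosities. Windows of 50 kb advanced by
20 kb tile each chromosome from position 1; the window estimate is the
**ratio of sums** $\sum a / \sum(a+b+c)$, never the mean of per-site
ratios (the two differ, and a test asserts the difference on a constructed
case). Monomorphic sites contribute zero components; windows with no
informative site are undefined and excluded from quantiles; negative
estimates are retained so the empirical threshold is not distorted.

Nucleotide diversity per site is the unbiased pairwise heterozygosity
$\pi = 2 n_{alt} n_{ref} / (n(n-1))$ over the group's called alleles;
window diversity sums site values and divides by the window span in bp.
The diversity contrast is $\log_2(\pi_{control}/\pi_{twin})$: the
orientation puts diversity *loss in the twin cohort* on the positive side,
so one-sided top-quantile selection targets twin-cohort sweeps. The
orientation is a package design choice (a positive published threshold
with a "selection in twins" reading forces it operationally); both
statistics use the empirical type-7 quantile over defined windows and
**strict** `>` selection, so an all-equal degenerate input selects
nothing.

Selected windows are merged (overlapping or book-ended) into regions;
intersection and union of the Fst and ratio region sets are both computed.
The union maximizes the search scope for rare-variant screening — the
default in `run_pipeline()` — while the intersection is the conservative
"both signals" set. Venn-style counts are reported at both window and
merged-region granularity, since the two differ once windows merge.

### The rare-allele screen

A candidate SNP must satisfy a pure conjunction: (i) lie in the selected
regions, (ii) have alternate-allele frequency strictly below 0.05 in
*every* control population where the frequency is defined, (iii) have twin
minor-allele count ≥ 10, and (iv) twin genotype missing rate ≤ 0.1. The
count gate is *at least* 10 (not "more than 10"): at 57 fully genotyped
diploids the minimum admissible frequency is then $10/114 = 0.0877193$,
which is the modal frequency a boundary candidate prints. The missingness
gate is expressed as a missing *rate* of 0.1 — equivalent to the VCFtools
convention of requiring ≥ 90% of genotypes called.

Annotation classifies each candidate against gene spans: overlap is
`genic` (a BED4 model carries no exon structure, so exonic/intronic are
collapsed; a GFF3 model is read the same way), a 1-kb strand-aware flank
gives `upstream`/`downstream`, and otherwise the nearest gene within
100 kb is reported with its distance (the radius accommodates regulatory
associations tens of kb away, e.g. a fertility gene ~70 kb from a
significant SNP). Distance is the base-pair offset to the gene boundary
(`start - pos` or `pos - end`), one more than the inter-range gap.

## Quality control

Site filters run in a fixed order with first-failing attribution:
biallelic, missingness (≤ 0.20), MAF (≥ 0.05, computed on non-missing
alleles, ties retained), HWE (exact two-sided test, no mid-p; p > 1e-6
retained). The exact test is used rather than chi-square because the
package's whole point is the rare-frequency regime where the asymptotic
test fails; it is tested against a full-enumeration oracle to 1e-12.
HWE is pooled by default with a per-population option (the stricter of
the two intents; the choice is exposed, not guessed). Samples with > 10%
missing genotypes are then removed, and a second site pass applies the
stricter 5% missingness cap of the format-conversion step — re-applying
the MAF/HWE gates as well, because the sample removal in between changes
per-site statistics; this makes the cascade idempotent.

One deliberate asymmetry in `run_pipeline()`: the structure summaries
(kinship, PCA, ROH, LD) use the full cascade, but the sweep scan and the
screen run on a table filtered *without* the MAF floor. A pooled MAF ≥
0.05 gate would delete precisely the alleles the screen is designed to
find — a variant carried by 10 of 114 twin haplotypes and almost absent
elsewhere is pooled-rare by construction.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the analyses assume, and its
defaults are those study conditions: six populations (90 source-population
animals of which 57 form the twin cohort and 21 the control cohort, plus
five populations of 20–22), five ancestral components, two 5-Mb
chromosomes with 5,000 SNPs each, 2% genotype missingness, three planted
sweeps and twelve planted rare twin-enriched SNPs inside them, and six
planted autozygous tracts of 1.2–1.5 Mb.

Mechanism: ancestral frequencies are drawn per SNP, drifted per ancestry
component (Balding–Nichols, F = 0.08), mixed through population-specific
admixture weights (one dominant component per population), and drifted
again per population (F = 0.02). Each population carries a founder
haplotype pool (12–60 haplotypes; fewer founders give stronger LD), and
every individual's two haplotypes are founder mosaics with ~500-kb
expected segment length — so LD decays with distance and differs between
populations by effective size, populations separate on PCs, and windows
have realistic Fst noise. The drift levels and founder counts are chosen
once to give population differentiation and LD decay scales a cattle
geneticist would call plausible for within-breed geographic populations
(window Fst background of a few percent, $r^2$ halving within ~100 kb).

Planted features are injected after background generation:

* **Sweeps** replace each twin haplotype in the interval by the source
  population's majority haplotype with probability `diversity_reduction`
  (0.8) and nudge the remaining twin haplotypes sitewise toward it with
  probability `fst_shift` (0.3) — raising window Fst and depressing twin
  diversity simultaneously, as a sweep does.
* **Rare variants** are deterministic genotype edits with exact counts:
  all samples are cleared, the twin cohort receives exactly `twin_count`
  alternate alleles (10–13), and each control population large enough to
  keep a single carrier under `max_control_freq` receives one heterozygote
  — so screen recall has an exact denominator, and a configuration whose
  demanded control frequency reaches the 0.05 rarity threshold is rejected
  as infeasible up front.
* **Autozygous tracts** copy one haplotype onto the other across the
  interval, preserving allelic variation along the tract (true
  autozygosity, not an artificial constant stretch).

Everything is deterministic under the single integer seed (R's
Mersenne-Twister; no hash-order dependence), and the emitted truth record
is recomputable from the genotype table — a test recounts it.

What the generator does **not** emulate: realistic cattle demography and
recombination maps, variant-calling artifacts (all genotypes are clean
post-calling calls; the upstream caller-metric filters are out of scope),
allele-frequency spectra of real resequencing (background sites are
deliberately common so QC retains them), linkage between chromosomes, and
phenotype misclassification in the control cohort. Passing recovery tests
therefore demonstrate the statistical machinery is correct and the design
is recoverable under its stated assumptions — not that real data of this
design would yield the same power.

## Numerical choices and degenerate inputs

* Base-pair positions and genome lengths are doubles throughout (cattle
  autosome totals exceed 2^31).
* Quantiles are type-7; selection is strict `>`; ties at QC thresholds are
  retained (inclusive comparisons), except HWE which retains `p >`
  threshold.
* The HWE exact test guards probability comparison with a 1e-12 relative
  tolerance when summing the tail, the standard protection against
  floating-point equality on the observed configuration's probability.
* A site with all genotypes missing is removed under missingness, never
  divided by zero; a group with no called genotype makes Weir–Cockerham
  components undefined (`NA`, window-excluded and counted) rather than
  zero; zero-variance LD pairs are skipped and counted.
* Interval work (merging, union/intersection, overlap, nearest) is
  delegated to GenomicRanges/IRanges; tests hold it against per-base-pair
  membership and linear-scan oracles.
* `combine_regions()` rejects inputs whose chromosome labels mix naming
  dialects (`chr1` vs `1`); otherwise labels are opaque strings and no
  normalization is attempted.
* NJ on an all-equal distance matrix resolves ties deterministically
  through `ape`'s implementation; the result is a valid tree with
  non-negative branch lengths.

## Test problem sizes

The recovery suites run at desk scale by design: the end-to-end cohort is
the generator default (192 samples × 10,000 SNPs), module-level property
checks use 1–3 seeded replicates of 600–1,500-SNP cohorts, the planted
sweep-maximum property uses ten 600-SNP replicates, and brute-force oracle
comparisons use ≤ 50-sample instances where enumeration is exact. These
sizes are the package's choice of a fast, fully reproducible validation
scale; the statistics themselves are O(n·m) matrix operations that run
unchanged on much larger tables.

## Known limitations

* ADMIXTURE-style ancestry estimation and its cross-validation model
  selection are out of scope (external tool); the generator still plants a
  K = 5-like structure so PCA/NJ summaries have something real to find.
* GO/KEGG enrichment of candidate genes is out of scope (external,
  database-versioned services).
* The ROH detector reproduces PLINK's semantics, not its bytes; segment
  boundaries can extend a few SNPs beyond a true tract.
* The GRM is not intended to byte-match GCTA's missing-data handling.
* Haplotype-based scan statistics (XP-EHH, iHS) are not implemented; the
  scan is the Fst / θπ-ratio pair.
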