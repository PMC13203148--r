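# Independent brute-force oracles. These deliberately use naive
# enumeration / direct transcription, not the package's code paths.

# exact HWE p by direct enumeration over heterozygote counts with plain
# factorials (valid for totals <= ~50)
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  rare <- min(2 * nAA + nAa, 2 * naa + nAa)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- sapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    factorial(n) / (factorial(homr) * factorial(h) * factorial(homc)) * 2^h
  })
  prob <- prob / sum(prob)
  pobs <- prob[hets == nAa]
  sum(prob[prob <= pobs * (1 + 1e-9)])
}

# Weir-Cockerham (1984) two-population components, transcribed with the
# explicit number-of-populations r from sample sizes, frequencies and
# heterozygosities
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  setNames(unname(c(a, b, hbar / 2)), c("a", "b", "c"))
}

# summary stats of a dosage vector, for feeding wc_oracle
dos_stats <- function(g) {
  g <- g[!is.na(g)]
  c(n = length(g), p = sum(g) / (2 * length(g)), h = mean(g == 1))
}

# per-site nucleotide diversity by enumerating all unordered allele pairs
pi_pair_oracle <- function(g) {
  g <- g[!is.na(g)]
  alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diff <- diff + (alleles[i] != alleles[j])
  }
  diff / choose(n, 2)
}

# per-base-pair membership oracle for interval union/intersection on a toy
# chromosome of length L
region_membership <- function(regions, chrom, L) {
  mem <- rep(FALSE, L)
  rr <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rr))) mem[rr$start[i]:rr$end[i]] <- TRUE
  mem
}

# brute-force nearest-gene scan mirroring the documented distance
# convention (offset to the gene boundary)
annotate_oracle <- function(pos, chr, model, near_bp, flank_bp) {
  g <- model[model$chrom == chr, , drop = FALSE]
  if (nrow(g) == 0) return(list(relation = "unannotated", distance = NA))
  inside <- pos >= g$start & pos <= g$end
  if (any(inside)) return(list(relation = "genic", distance = 0))
  d <- ifelse(pos < g$start, g$start - pos, pos - g$end)
  i <- which.min(d)
  if (d[i] > near_bp) return(list(relation = "unannotated", distance = NA))
  before <- pos < g$start[i]
  rel <- if (d[i] <= flank_bp) {
    if (before == (g$strand[i] == "+")) "upstream" else "downstream"
  } else "intergenic-nearest"
  list(relation = rel, distance = d[i])
}
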