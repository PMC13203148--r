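# compact builders for in-code fixtures

toy_geno <- function(dosage, chrom = "1", pos = NULL, pops = "P1",
                     cohorts = "none", parity = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  variants <- tibble::tibble(
    chrom = rep_len(chrom, m), pos = pos,
    ref = "A", alt = "G"
  )
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = rep_len(pops, n),
    cohort = rep_len(cohorts, n),
    parity = if (is.null(parity)) rep(4, n) else rep_len(parity, n)
  )
  geno_table(variants, samples, dosage)
}

rand_geno <- function(n, m, seed = 1, missing = 0, chrom = "1") {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (missing > 0) dos[matrix(runif(n * m) < missing, n)] <- NA
  toy_geno(dos, chrom = chrom)
}

# a small structured simulation without planted features
sim_simple <- function(pops, seed = 1, n_chrom = 1, m = 500, L = 1e6,
                       n_twin = 0, n_control = 0, twin_source = NULL, ...) {
  empty_sweeps <- tibble::tibble(chrom = character(), start = numeric(),
                                 end = numeric(), fst_shift = numeric(),
                                 diversity_reduction = numeric())
  empty_roh <- tibble::tibble(sample_id = character(), chrom = character(),
                              start = numeric(), end = numeric())
  simulate_cohort(sim_config(
    seed = seed, n_chrom = n_chrom, chrom_length_bp = L,
    n_snps_per_chrom = m, populations = pops,
    twin_source = twin_source %||% pops$label[1],
    n_twin = n_twin, n_control = n_control,
    sweeps = empty_sweeps, roh_plants = empty_roh, ...
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
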