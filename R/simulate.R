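#' Configuration for the synthetic cohort generator
#'
#' The defaults reproduce the study design the analyses assume: six
#' geographic populations with K = 5-like ancestry structure, a 57-animal
#' twin cohort and a 21-animal control cohort drawn from the source
#' population, two 5-Mb chromosomes with 5,000 SNPs each, three planted
#' selective sweeps, twelve planted twin-enriched rare variants inside the
#' sweeps, planted long homozygous tracts, and 2 percent genotype
#' missingness.
#'
#' @param seed integer RNG seed; the whole cohort is deterministic under it
#' @param n_chrom,chrom_length_bp,n_snps_per_chrom genome geometry
#' @param populations tibble `label`, `n_samples`, `founders` (founder
#'   haplotype count per population; fewer founders mean stronger LD)
#' @param ancestry_components number of ancestral components (default 5)
#' @param twin_source population the twin/control cohorts are drawn from
#' @param n_twin,n_control cohort sizes (57 and 21)
#' @param sweeps tibble `chrom`, `start`, `end`, `fst_shift`,
#'   `diversity_reduction` of planted sweeps (twin cohort only)
#' @param rare_plants tibble `chrom`, `pos`, `twin_count`,
#'   `max_control_freq` of planted rare twin-enriched variants
#' @param roh_plants tibble `sample_id`, `chrom`, `start`, `end` of planted
#'   autozygous tracts
#' @param missing_rate genotype missing probability
#' @param component_fst Balding-Nichols drift of component frequencies
#'   around the ancestral frequency
#' @param population_fst extra per-population drift on top of the admixture
#' @param segment_length_bp expected founder-mosaic segment length (bp)
#' @return a `sim_config` list.
#' @export
sim_config <- function(
    seed = 20260521,
    n_chrom = 2, chrom_length_bp = 5e6, n_snps_per_chrom = 5000,
    populations = NULL,
    ancestry_components = 5,
    twin_source = "Xinjiang", n_twin = 57, n_control = 21,
    sweeps = NULL, rare_plants = NULL, roh_plants = NULL,
    missing_rate = 0.02,
    component_fst = 0.08, population_fst = 0.02,
    segment_length_bp = 5e5) {
  populations <- populations %||% tibble::tibble(
    label = c("Xinjiang", "Gansu", "InnerMongolia", "US", "Canada", "Huaxi"),
    n_samples = c(90, 20, 20, 20, 20, 22),
    founders = c(60, 40, 40, 12, 16, 30)
  )
  sweeps <- sweeps %||% tibble::tibble(
    chrom = c("1", "1", "2"),
    start = c(1000001, 3000001, 2000001),
    end = c(1200000, 3200000, 2200000),
    fst_shift = 0.3, diversity_reduction = 0.8
  )
  if (is.null(rare_plants)) {
    rare_plants <- tibble::tibble(
      chrom = rep(sweeps$chrom, each = 4),
      pos = rep(sweeps$start, each = 4) + rep(c(40000, 80000, 120000, 160000),
                                              nrow(sweeps)),
      twin_count = rep(c(10, 11, 12, 13), nrow(sweeps)),
      max_control_freq = 0.04
    )
  }
  roh_plants <- roh_plants %||% tibble::tibble(
    sample_id = c("Gansu_001", "Gansu_002", "Gansu_003",
                  "US_001", "US_002", "US_003"),
    chrom = c("1", "2", "1", "2", "1", "2"),
    start = c(500001, 3000001, 3000001, 1000001, 2000001, 500001),
    end = c(2000000, 4500000, 4200000, 2500000, 3500000, 1800000)
  )

  cfg <- list(seed = seed, n_chrom = n_chrom,
              chrom_length_bp = chrom_length_bp,
              n_snps_per_chrom = n_snps_per_chrom,
              populations = tibble::as_tibble(populations),
              ancestry_components = ancestry_components,
              twin_source = twin_source, n_twin = n_twin,
              n_control = n_control,
              sweeps = tibble::as_tibble(sweeps),
              rare_plants = tibble::as_tibble(rare_plants),
              roh_plants = tibble::as_tibble(roh_plants),
              missing_rate = missing_rate, component_fst = component_fst,
              population_fst = population_fst,
              segment_length_bp = segment_length_bp)

  if (any(unlist(cfg$populations[c("n_samples", "founders")]) <= 0) ||
      n_chrom < 1 || n_snps_per_chrom < 1) {
    abort("counts in sim_config must be positive")
  }
  src <- cfg$populations$n_samples[cfg$populations$label == twin_source]
  if (length(src) != 1 || src < n_twin + n_control) {
    abort("twin_source population must exist and hold the twin + control cohorts")
  }
  if (nrow(cfg$rare_plants)) {
    if (any(cfg$rare_plants$max_control_freq >= 0.05)) {
      abort("infeasible rare plant: max_control_freq must be < 0.05")
    }
    if (any(cfg$rare_plants$twin_count > 2 * n_twin)) {
      abort("infeasible rare plant: twin_count exceeds 2 x twin cohort size")
    }
  }
  for (tb in list(cfg$sweeps, cfg$rare_plants)) {
    if (nrow(tb) && (any(!tb$chrom %in% as.character(seq_len(n_chrom))) ||
                     any(tb[[2]] > chrom_length_bp) || any(tb[[2]] < 1))) {
      abort("planted coordinates must lie within chromosome bounds")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a structured cohort with planted truth
#'
#' Background genotypes arise from founder-haplotype copying: per population
#' a pool of founder haplotypes is drawn at population allele frequencies
#' (ancestral frequencies drifted per ancestry component, mixed by
#' population-specific admixture weights, then drifted again per
#' population), and each individual's two haplotypes are mosaics of
#' founders with approximately geometric segment lengths. This induces LD
#' that decays with distance and is stronger for smaller founder pools, plus
#' Fst and PCA separation between populations. Planted features (sweeps via
#' haplotype replacement in the twin cohort, exact-count rare variants,
#' autozygous tracts) are injected after background generation; rare plants
#' are deterministic genotype edits, so recovery rates have an exact
#' denominator.
#'
#' @param config a [sim_config()]
#' @return list with `geno` (a [geno_table()]), `gene_model` (tibble), and
#'   `truth` (planted sweeps/rare variants/ROH tracts with realized values,
#'   plus realized per-population allele frequencies).
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  K <- config$ancestry_components
  pops <- config$populations
  npop <- nrow(pops)
  chroms <- as.character(seq_len(config$n_chrom))
  m_per <- config$n_snps_per_chrom
  M <- m_per * config$n_chrom

  pos_list <- lapply(chroms, function(ch) {
    sort(sample.int(config$chrom_length_bp, m_per))
  })
  pos <- as.numeric(unlist(pos_list))
  chrom <- rep(chroms, each = m_per)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))

  # allele frequencies: ancestral -> component drift -> admixture -> pop drift
  p0 <- 0.05 + 0.9 * rbeta(M, 0.8, 0.8)
  compP <- if (config$component_fst > 0) {
    Fk <- config$component_fst
    matrix(rbeta(K * M, rep(p0, each = K) * (1 - Fk) / Fk,
                 rep(1 - p0, each = K) * (1 - Fk) / Fk), K, M)
  } else {
    matrix(rep(p0, each = K), K, M)
  }
  main <- ((seq_len(npop) - 1) %% K) + 1
  W <- matrix(0.3 / (K - 1), npop, K)
  W[cbind(seq_len(npop), main)] <- 0.7
  P <- W %*% compP
  if (config$population_fst > 0) {
    Fp <- config$population_fst
    P <- matrix(rbeta(npop * M, c(P) * (1 - Fp) / Fp,
                      (1 - c(P)) * (1 - Fp) / Fp), npop, M)
  }
  P <- pmin(pmax(P, 1e-4), 1 - 1e-4)

  sprob <- lapply(pos_list, function(p) {
    pmin(0.5, diff(p) / config$segment_length_bp)
  })

  n_total <- sum(pops$n_samples)
  sample_ids <- unlist(lapply(seq_len(npop), function(i) {
    sprintf("%s_%03d", pops$label[i], seq_len(pops$n_samples[i]))
  }))
  population <- rep(pops$label, pops$n_samples)

  H1 <- matrix(0L, n_total, M)
  H2 <- matrix(0L, n_total, M)
  row <- 0
  for (pi in seq_len(npop)) {
    Fh <- pops$founders[pi]
    founders <- matrix(rbinom(Fh * M, 1, rep(P[pi, ], each = Fh)), Fh, M)
    for (s in seq_len(pops$n_samples[pi])) {
      row <- row + 1
      for (h in 1:2) {
        hap <- integer(M)
        off <- 0
        for (ci in seq_len(config$n_chrom)) {
          cols <- (off + 1):(off + m_per)
          seg <- cumsum(c(0L, as.integer(runif(m_per - 1) < sprob[[ci]])))
          fidx <- sample.int(Fh, max(seg) + 1, replace = TRUE)[seg + 1]
          hap[cols] <- founders[cbind(fidx, cols)]
          off <- off + m_per
        }
        if (h == 1) H1[row, ] <- hap else H2[row, ] <- hap
      }
    }
  }

  cohort <- rep("none", n_total)
  src_rows <- which(population == config$twin_source)
  twin_rows <- src_rows[seq_len(config$n_twin)]
  control_rows <- src_rows[config$n_twin + seq_len(config$n_control)]
  cohort[twin_rows] <- "twin"
  cohort[control_rows] <- "control"
  parity <- sample(1:8, n_total, replace = TRUE)
  parity[control_rows] <- sample(4:9, length(control_rows), replace = TRUE)

  # planted sweeps: per twin haplotype, replace by the majority haplotype of
  # the source population with prob diversity_reduction; remaining twin
  # haplotypes are nudged sitewise toward it with prob fst_shift
  src_pi <- which(pops$label == config$twin_source)
  for (sw in seq_len(nrow(config$sweeps))) {
    s <- config$sweeps[sw, ]
    cols <- which(chrom == s$chrom & pos >= s$start & pos <= s$end)
    if (length(cols) == 0) next
    target <- as.integer(P[src_pi, cols] >= 0.5)
    for (hm in 1:2) {
      H <- if (hm == 1) H1 else H2
      swept <- runif(length(twin_rows)) < s$diversity_reduction
      if (any(swept)) {
        H[twin_rows[swept], cols] <- rep(target, each = sum(swept))
      }
      ns <- twin_rows[!swept]
      if (length(ns) && s$fst_shift > 0) {
        mask <- matrix(runif(length(ns) * length(cols)) < s$fst_shift,
                       length(ns))
        tgt <- matrix(rep(target, each = length(ns)), length(ns))
        sub <- H[ns, cols, drop = FALSE]
        sub[mask] <- tgt[mask]
        H[ns, cols] <- sub
      }
      if (hm == 1) H1 <- H else H2 <- H
    }
  }

  # planted autozygous tracts: copy haplotype 1 onto haplotype 2
  for (rp in seq_len(nrow(config$roh_plants))) {
    r <- config$roh_plants[rp, ]
    si <- match(r$sample_id, sample_ids)
    if (is.na(si)) abort(paste0("roh plant names unknown sample ", r$sample_id))
    cols <- which(chrom == r$chrom & pos >= r$start & pos <= r$end)
    H2[si, cols] <- H1[si, cols]
  }

  dosage <- H1 + H2
  storage.mode(dosage) <- "double"
  dosage[matrix(runif(n_total * M) < config$missing_rate, n_total)] <- NA_real_

  # planted rare twin-enriched variants: deterministic genotype edits at the
  # SNP nearest each requested position
  rare_truth <- NULL
  if (nrow(config$rare_plants)) {
    used <- integer(0)
    rows <- lapply(seq_len(nrow(config$rare_plants)), function(ri) {
      r <- config$rare_plants[ri, ]
      cand <- which(chrom == r$chrom)
      cand <- setdiff(cand[order(abs(pos[cand] - r$pos))], used)
      j <- cand[1]
      used <<- c(used, j)
      dosage[, j] <<- 0
      for (pi in seq_len(npop)) {
        mem <- which(population == pops$label[pi] & cohort == "none")
        if (length(mem) && 1 / (2 * length(mem)) <= r$max_control_freq) {
          dosage[mem[1], j] <<- 1
        }
      }
      ct <- r$twin_count
      n_hom <- max(0, ct - length(twin_rows))
      n_het <- ct - 2 * n_hom
      carriers <- sample(twin_rows, n_hom + n_het)
      if (n_hom > 0) dosage[carriers[seq_len(n_hom)], j] <<- 2
      if (n_het > 0) dosage[carriers[n_hom + seq_len(n_het)], j] <<- 1
      tibble::tibble(chrom = r$chrom, pos_requested = r$pos, pos = pos[j],
                     twin_count = ct,
                     max_control_freq = r$max_control_freq)
    })
    rare_truth <- dplyr::bind_rows(rows)
  }

  variants <- tibble::tibble(
    chrom = chrom, pos = pos,
    id = sprintf("snp_%s_%s", chrom,
                 format(pos, scientific = FALSE, trim = TRUE)),
    ref = ref, alt = alt
  )
  samples <- tibble::tibble(sample_id = sample_ids, population = population,
                            cohort = cohort, parity = as.numeric(parity))
  geno <- geno_table(variants, samples, dosage)

  # realized per-population frequencies (population members outside cohorts)
  pop_freqs <- t(vapply(pops$label, function(lb) {
    mem <- which(population == lb & cohort == "none")
    colSums(geno$dosage[mem, , drop = FALSE], na.rm = TRUE) /
      pmax(2 * colSums(!is.na(geno$dosage[mem, , drop = FALSE])), 1)
  }, numeric(M)))

  if (!is.null(rare_truth)) {
    key <- match(paste(rare_truth$chrom, rare_truth$pos),
                 paste(geno$variants$chrom, geno$variants$pos))
    rare_truth$realized_twin_count <- colSums(
      geno$dosage[twin_rows, key, drop = FALSE], na.rm = TRUE)
    rare_truth$realized_control_freq_max <- apply(
      pop_freqs[, key, drop = FALSE], 2, max)
    if (any(rare_truth$realized_control_freq_max >= 0.05)) {
      abort("planted rare variant realized control frequency >= 0.05")
    }
  }

  gene_model <- .sim_gene_model(chroms, config$chrom_length_bp)

  list(
    geno = geno,
    gene_model = gene_model,
    truth = list(sweeps = config$sweeps,
                 rare = rare_truth %||% tibble::tibble(),
                 roh = config$roh_plants,
                 pop_freqs = pop_freqs)
  )
}

# uniformly spaced 20-kb genes every 50 kb (~40% genic coverage), so both
# genic and nearest-gene annotation paths are exercised
.sim_gene_model <- function(chroms, L, gene_bp = 20000, period_bp = 50000) {
  purrr::map_dfr(chroms, function(ch) {
    starts <- seq(10001, L - gene_bp, by = period_bp)
    tibble::tibble(
      gene = sprintf("GENE%s_%03d", ch, seq_along(starts)),
      chrom = ch, start = starts, end = starts + gene_bp - 1,
      strand = rep(c("+", "-"), length.out = length(starts))
    )
  })
}

#' Write a simulated cohort as a fixture file set
#'
#' VCF + sample sheet + BED6 gene model + truth JSON, all plain text and all
#' readable back by the package's own readers with zero loss (the truth
#' JSON omits the full realized frequency matrix; planted truth is
#' complete).
#'
#' @param sim output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return named character vector of the paths written.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.bed"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$geno, paths["vcf"])
  write_sample_sheet(sim$geno, paths["samples"])
  gm <- sim$gene_model
  writeLines(paste(gm$chrom,
                   format(gm$start - 1, scientific = FALSE, trim = TRUE),
                   format(gm$end, scientific = FALSE, trim = TRUE),
                   gm$gene, 0, gm$strand, sep = "\t"), paths["genes"])
  jsonlite::write_json(
    list(sweeps = sim$truth$sweeps, rare = sim$truth$rare,
         roh = sim$truth$roh),
    paths["truth"], digits = NA
  )
  paths
}
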