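# a twin cohort of 57 fully genotyped diploids with controlled alt counts
twin_table <- function(alt_counts, missing_per_site = 0) {
  n <- 57
  dos <- sapply(alt_counts, function(ct) {
    v <- c(rep(1, ct), rep(0, n - ct))
    if (missing_per_site > 0) v[n - seq_len(missing_per_site) + 1] <- NA
    v
  })
  toy_geno(dos, cohorts = "twin")
}

test_that("allele frequencies reproduce the boundary candidate values", {
  g <- twin_table(c(10, 0))
  fr <- allele_freq(g)
  expect_equal(fr$freq[1], 10 / 114, tolerance = 1e-12)
  expect_equal(round(fr$freq[1], 7), 0.0877193)
  expect_equal(fr$freq[2], 0)
  # one missing genotype among 57, alt count 11 -> 11/112
  g2 <- twin_table(11, missing_per_site = 1)
  expect_equal(allele_freq(g2)$freq[1], 11 / 112, tolerance = 1e-12)
  expect_equal(round(allele_freq(g2)$freq[1], 7), 0.0982143)
  # zero non-missing alleles -> undefined, flagged
  g3 <- toy_geno(matrix(NA_real_, 3, 1))
  expect_true(is.na(allele_freq(g3)$freq))
  expect_equal(allele_freq(g3)$n_alleles, 0)
})

test_that("rare-in-all-controls applies the all-quantifier strictly", {
  mk <- function(freqs) {
    tibble::tibble(population = paste0("P", seq_along(freqs)),
                   chrom = "1", pos = 100, freq = freqs)
  }
  expect_equal(nrow(rare_in_all_controls(mk(rep(0.04, 6)))), 1)
  expect_equal(nrow(rare_in_all_controls(mk(c(rep(0.04, 5), 0.06)))), 0)
  expect_equal(nrow(rare_in_all_controls(mk(c(0.05, 0.01)))), 0)  # strict <
  expect_equal(nrow(rare_in_all_controls(mk(rep(NA_real_, 3)))), 0)
  expect_equal(nrow(rare_in_all_controls(mk(c(NA, 0.01)))), 1)
  expect_error(rare_in_all_controls(mk(numeric(0))), "empty")

  set.seed(47)
  tb <- tidyr::expand_grid(population = paste0("P", 1:6), pos = 1:50) |>
    dplyr::mutate(chrom = "1", freq = ifelse(runif(300) < 0.1, NA,
                                             runif(300, 0, 0.12)))
  got <- rare_in_all_controls(tb, 0.05)
  oracle <- sapply(1:50, function(ps) {
    f <- tb$freq[tb$pos == ps]
    any(!is.na(f)) && all(f[!is.na(f)] < 0.05)
  })
  expect_setequal(got$pos, (1:50)[oracle])
})

test_that("the candidate screen is a strict four-gate conjunction", {
  # sites: passes all; mac 9 (fails); outside region; not rare; too missing
  g <- twin_table(c(10, 9, 12, 12, 14), missing_per_site = 0)
  g$dosage[1:7, 5] <- NA  # 7/57 = 12.3% missing at site 5
  g <- geno_table(g$variants, g$samples, g$dosage)
  regions <- region_set(c("1", "1"), c(500, 3500), c(2500, 5500))  # 3000 out
  rare <- tibble::tibble(chrom = "1", pos = c(1000, 2000, 3000, 5000))
  cands <- screen_candidates(g, regions, rare, mac = 10, max_missing = 0.1)
  expect_equal(cands$pos, 1000)
  expect_equal(cands$twin_freq, 10 / 114, tolerance = 1e-12)

  # oracle: intersect the four independently recomputed gates
  fr <- allele_freq(g)
  minor <- pmin(fr$n_alt, fr$n_alleles - fr$n_alt)
  oracle <- fr$pos[in_regions(g$variants, regions) &
                     fr$pos %in% rare$pos &
                     minor >= 10 &
                     (1 - fr$n_alleles / (2 * 57)) <= 0.1]
  expect_equal(cands$pos, oracle)
  gates <- attr(cands, "gate_counts")
  expect_true(all(diff(unname(gates)) <= 0))  # non-increasing along the screen

  expect_warning(none <- screen_candidates(g, region_set(character(0),
                                                         numeric(0),
                                                         numeric(0)),
                                           rare), "empty region")
  expect_equal(nrow(none), 0)
})

test_that("candidate frequencies are reproducible from the genotype table", {
  g <- twin_table(c(10, 11, 13))
  regions <- region_set("1", 1, 10000)
  rare <- g$variants[c("chrom", "pos")]
  cands <- screen_candidates(g, regions, rare)
  refr <- allele_freq(g, cohort_ids(g, "twin"))
  expect_equal(cands$twin_freq,
               refr$freq[match(cands$pos, refr$pos)], tolerance = 1e-12)
})

test_that("gene-context annotation handles genic, flank and nearest cases", {
  model <- tibble::tibble(
    gene = c("G1", "G2", "G3"),
    chrom = c("1", "1", "2"),
    start = c(100000, 400000, 50000),
    end = c(120000, 420000, 70000),
    strand = c("+", "-", "+")
  )
  snps <- tibble::tibble(
    chrom = c("1", "1", "1", "1", "1", "3"),
    pos = c(110000,            # inside G1 -> genic
            99500,             # 500 bp before G1 (+) -> upstream
            420900,            # 900 bp after G2 (-) -> upstream (strand-aware)
            330000,            # 70 kb before G2 -> intergenic-nearest
            999000,            # far from everything -> unannotated
            1000)              # chromosome absent from model
  )
  ann <- annotate_snps(snps, model, near_bp = 100000, flank_bp = 1000)
  expect_equal(ann$relation,
               c("genic", "upstream", "upstream", "intergenic-nearest",
                 "unannotated", "unannotated"))
  expect_equal(ann$distance_bp[1:4], c(0, 500, 900, 70000))
  expect_equal(attr(ann, "n_unannotated"), 2)

  genes <- candidate_genes(ann)
  expect_true(all(genes$n_snps >= 1))
  expect_setequal(genes$gene, c("G1", "G2"))
  expect_equal(genes$n_snps[genes$gene == "G2"], 2)
})

test_that("annotation agrees with a brute-force nearest-interval scan", {
  set.seed(53)
  for (rep in 1:3) {
    model <- tibble::tibble(
      gene = paste0("G", 1:15),
      chrom = sample(c("1", "2"), 15, TRUE),
      start = sort(sample.int(9e5, 15)),
      end = NA, strand = sample(c("+", "-"), 15, TRUE)
    )
    model$end <- model$start + sample.int(20000, 15)
    model <- model[order(model$chrom, model$start), ]
    snps <- tibble::tibble(chrom = sample(c("1", "2"), 40, TRUE),
                           pos = sample.int(1e6, 40))
    ann <- annotate_snps(snps, model, near_bp = 50000, flank_bp = 1000)
    for (i in seq_len(nrow(snps))) {
      ref <- annotate_oracle(snps$pos[i], snps$chrom[i], model, 50000, 1000)
      expect_identical(ann$relation[i], ref$relation)
      if (!is.na(ann$distance_bp[i])) {
        expect_equal(ann$distance_bp[i], ref$distance)
      }
    }
  }
})

test_that("candidate report attaches control frequency ranges", {
  g <- twin_table(10)
  pf <- tibble::tibble(population = c("A", "B"), chrom = "1", pos = 1000,
                       freq = c(0, 0.0192308))
  cands <- screen_candidates(g, region_set("1", 1, 2000),
                             tibble::tibble(chrom = "1", pos = 1000))
  out <- candidate_report(cands, pf)
  expect_equal(out$control_freq_range, "0~0.0192308")
})
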