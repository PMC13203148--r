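test_that("Weir-Cockerham components: no-differentiation and fixation cases", {
  # p = 0.5, h = 0.5, n = 20 in both groups -> a <= 0
  grp <- c(rep(0, 5), rep(1, 10), rep(2, 5))
  comp <- site_fst_components(grp, grp)
  expect_lte(comp["a"], 0)

  # fixed difference -> Fst = 1
  comp2 <- site_fst_components(rep(0, 10), rep(2, 10))
  expect_equal(unname(comp2["a"] / sum(comp2)), 1)

  # monomorphic overall -> all components zero
  expect_equal(unname(site_fst_components(rep(0, 8), rep(0, 6))),
               c(0, 0, 0))

  # one group entirely missing -> undefined
  expect_true(all(is.na(site_fst_components(rep(NA, 5), c(0, 1, 2)))))
})

test_that("Weir-Cockerham components match an independent transcription", {
  # nA=6, pA=1/3, hA=1/3; nB=4, pB=3/4, hB=1/2
  a_dos <- c(2, 1, 1, 0, 0, 0)
  b_dos <- c(2, 2, 1, 1)
  sa <- dos_stats(a_dos)
  sb <- dos_stats(b_dos)
  expect_equal(unname(sa), c(6, 1 / 3, 1 / 3))
  expect_equal(unname(sb), c(4, 3 / 4, 1 / 2))
  expect_equal(site_fst_components(a_dos, b_dos),
               wc_oracle(sa["n"], sa["p"], sa["h"], sb["n"], sb["p"], sb["h"]),
               tolerance = 1e-12)

  set.seed(29)
  for (i in 1:25) {
    ga <- rbinom(sample(5:40, 1), 2, runif(1, 0.05, 0.95))
    gb <- rbinom(sample(5:40, 1), 2, runif(1, 0.05, 0.95))
    sa <- dos_stats(ga)
    sb <- dos_stats(gb)
    ours <- site_fst_components(ga, gb)
    ref <- wc_oracle(sa["n"], sa["p"], sa["h"], sb["n"], sb["p"], sb["h"])
    if (sa["p"] + sb["p"] > 0 && sa["p"] + sb["p"] < 2) {
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  }
})

test_that("window tiling covers every bp 1..ceil(size/step) times", {
  g <- rand_geno(10, 50, seed = 1)
  g$variants$pos <- sort(sample.int(123456, 50))
  g <- geno_table(g$variants, g$samples, g$dosage)
  win <- window_fst(g, paste0("S", sprintf("%03d", 1:5)),
                    paste0("S", sprintf("%03d", 6:10)),
                    chrom_lengths = c("1" = 123456))
  probe <- c(1, 2, 19999, 20000, 50000, 50001, 60000, 123456)
  cover <- sapply(probe, function(b) sum(win$start <= b & win$end >= b))
  expect_true(all(cover >= 1 & cover <= ceiling(50000 / 20000)))
  # interior positions are covered by floor(size/step) or ceiling(size/step)
  expect_true(all(cover[probe > 50000 & probe < 123456 - 50000] %in% 2:3))
})

test_that("window Fst is the ratio of sums, not the mean of ratios", {
  # two sites in one window with very different component magnitudes
  A <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1), c(0, 0), c(0, 0),
             c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  B <- rbind(c(2, 0), c(2, 0), c(2, 1), c(1, 0), c(2, 0), c(2, 0),
             c(2, 0), c(2, 0), c(2, 0), c(2, 0))
  g <- toy_geno(rbind(A, B), pos = c(100, 200))
  ga <- paste0("S", sprintf("%03d", 1:10))
  gb <- paste0("S", sprintf("%03d", 11:20))
  win <- window_fst(g, ga, gb, size_bp = 1000, step_bp = 1000)
  c1 <- site_fst_components(A[, 1], B[, 1])
  c2 <- site_fst_components(A[, 2], B[, 2])
  ratio_of_sums <- (c1["a"] + c2["a"]) / (sum(c1) + sum(c2))
  mean_of_ratios <- mean(c(c1["a"] / sum(c1), c2["a"] / sum(c2)))
  expect_equal(win$fst[1], unname(ratio_of_sums), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ratio_of_sums, mean_of_ratios,
                                tolerance = 1e-3)))
  # a window holding one site equals the site ratio
  win1 <- window_fst(subset_variants(g, 1), ga, gb,
                     size_bp = 1000, step_bp = 1000)
  expect_equal(win1$fst[1], unname(c1["a"] / sum(c1)), tolerance = 1e-12)
})

test_that("window pi matches the allele-pair counting oracle", {
  # one site, two samples, both heterozygous: pi_site = 8/12
  g <- toy_geno(matrix(c(1, 1), 2, 1), pos = 25000)
  win <- window_pi(g, c("S001", "S002"), size_bp = 50000, step_bp = 50000,
                   chrom_lengths = c("1" = 50000))
  expect_equal(win$pi[1], (8 / 12) / 50000, tolerance = 1e-12)
  expect_equal(8 / 12, pi_pair_oracle(c(1, 1)), tolerance = 1e-12)

  set.seed(37)
  for (i in 1:10) {
    dos <- rbinom(sample(3:8, 1), 2, runif(1, 0.2, 0.8))
    g1 <- toy_geno(matrix(dos, ncol = 1), pos = 100)
    w <- window_pi(g1, g1$samples$sample_id, size_bp = 1000, step_bp = 1000,
                   chrom_lengths = c("1" = 1000))
    ref <- pi_pair_oracle(dos)
    if (!is.na(ref)) expect_equal(w$pi[1], ref / 1000, tolerance = 1e-10)
  }

  # windows with no variants have pi = 0
  gwide <- toy_geno(matrix(c(1, 1), 2, 1), pos = 10)
  w <- window_pi(gwide, c("S001", "S002"), size_bp = 100, step_bp = 100,
                 chrom_lengths = c("1" = 1000))
  expect_equal(w$pi[-1], rep(0, 9))
})

test_that("duplicating every sample changes pi by the finite-sample factor", {
  dos <- c(0, 1, 2, 1, 0)
  pi_n <- pi_pair_oracle(dos)
  pi_2n <- pi_pair_oracle(rep(dos, 2))
  g2 <- toy_geno(matrix(rep(dos, 2), ncol = 1), pos = 100)
  w <- window_pi(g2, g2$samples$sample_id, size_bp = 1000, step_bp = 1000,
                 chrom_lengths = c("1" = 1000))
  expect_equal(w$pi[1] * 1000, pi_2n, tolerance = 1e-12)
  n <- 2 * length(dos)
  expect_equal(pi_2n, pi_n * (n * (n - 1)) / 1 * (1 / (2 * n * (2 * n - 1))) * 4,
               tolerance = 1e-12)
})

test_that("log2 pi-ratio orientation and degenerate windows", {
  expect_equal(log2_pi_ratio(1e-4, 1e-4), 0)
  expect_equal(log2_pi_ratio(2e-4, 1e-4), 1)   # diversity loss in twins -> +
  expect_true(is.na(log2_pi_ratio(0, 1e-4)))
  expect_true(is.na(log2_pi_ratio(1e-4, 0)))
})

test_that("top-window selection equals a brute-force sort-and-slice", {
  set.seed(41)
  w <- tibble::tibble(chrom = "1", start = (0:999) * 1000 + 1,
                      end = (0:999) * 1000 + 1000, fst = rnorm(1000))
  sel <- select_top_windows(w, "fst", 0.95)
  # independent type-7 quantile: sorted interpolation at h = (n-1)q + 1
  v <- sort(w$fst)
  h <- (1000 - 1) * 0.95 + 1
  thr <- v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  expect_equal(sel$threshold, thr, tolerance = 1e-12)
  expect_setequal(sel$windows$start, w$start[w$fst > thr])

  # 100 distinct values -> exactly 5 selected
  w100 <- w[1:100, ]
  w100$fst <- seq_len(100)
  expect_equal(nrow(select_top_windows(w100, "fst", 0.95)$windows), 5)

  # all-equal values -> empty selection with a warning
  w100$fst <- 1
  expect_warning(empty <- select_top_windows(w100, "fst", 0.95),
                 "degenerate")
  expect_equal(nrow(empty$windows), 0)
  expect_error(select_top_windows(w100[1:10, ], "fst"), ">= 20")
})

test_that("region combination matches per-bp membership on a toy chromosome", {
  A <- region_set("1", 100, 200, "fst")
  B <- region_set("1", 150, 250, "pi_ratio")
  expect_equal(combine_regions(A, B, "intersection")[, c("start", "end")],
               tibble::tibble(start = 150, end = 200), ignore_attr = TRUE)
  expect_equal(combine_regions(A, B, "union")[, c("start", "end")],
               tibble::tibble(start = 100, end = 250), ignore_attr = TRUE)
  disj <- combine_regions(region_set("1", 1, 10), region_set("1", 50, 60),
                          "intersection")
  expect_equal(nrow(disj), 0)

  set.seed(43)
  L <- 1e4  # scaled-down toy chromosome for the per-bp oracle
  mk <- function() {
    s <- sort(sample.int(L, 20))
    region_set("1", s, pmin(L, s + sample.int(500, 20)))
  }
  for (i in 1:5) {
    A <- mk(); B <- mk()
    for (mode in c("union", "intersection")) {
      got <- combine_regions(A, B, mode)
      memb <- if (mode == "union") {
        region_membership(A, "1", L) | region_membership(B, "1", L)
      } else {
        region_membership(A, "1", L) & region_membership(B, "1", L)
      }
      expect_identical(region_membership(got, "1", L), memb)
    }
  }
  expect_error(combine_regions(region_set("chr1", 1, 5), region_set("1", 1, 5)),
               "dialects")
})

test_that("a planted frequency-shifted window carries the maximum Fst", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    m <- 600
    L <- 1.2e6
    pos <- sort(sample.int(L, m))
    p <- runif(m, 0.2, 0.8)
    shift <- ifelse(pos >= 500001 & pos <= 550000,
                    pmin(0.95, p + 0.35) - p, 0)
    A <- matrix(rbinom(n * m, 2, rep(p + shift, each = n)), n, m)
    B <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
    g <- toy_geno(rbind(A, B), pos = pos)
    win <- window_fst(g, g$samples$sample_id[1:n],
                      g$samples$sample_id[(n + 1):(2 * n)],
                      chrom_lengths = c("1" = L))
    best <- win[which.max(win$fst), ]
    if (best$start <= 550000 && best$end >= 500001) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("sweep_scan ties the pieces together with consistent counts", {
  pops <- tibble::tibble(label = "A", n_samples = 60, founders = 40)
  sim <- sim_simple(pops, seed = 3, m = 1500, L = 3e6, n_twin = 25,
                    n_control = 20)
  sc <- sweep_scan(sim$geno, chrom_lengths = c("1" = 3e6))
  td <- tidy(sc)
  expect_equal(sum(td$top_fst), sc$counts$windows_top_fst)
  expect_equal(sum(td$top_ratio), sc$counts$windows_top_ratio)
  gl <- glance(sc)
  expect_equal(gl$n_windows, nrow(sc$windows))
  # union regions contain the intersection regions
  L <- 3e6
  mu <- region_membership(sc$regions$union, "1", L)
  mi <- region_membership(sc$regions$intersection, "1", L)
  expect_true(all(mu[mi]))
})
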