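test_that("IBS distance: identity, hand-counted case, and range", {
  g <- toy_geno(rbind(c(0, 2), c(0, 2), c(2, 2)))
  d <- ibs_distance_matrix(g)
  expect_equal(d$D[1, 2], 0)            # identical samples
  # (0,2) vs (2,2): shared alleles 0 + 2 of 4 -> distance 0.5
  expect_equal(d$D[1, 3], 0.5)
  expect_equal(d$n_pairs, 3)

  gr <- rand_geno(12, 80, seed = 5, missing = 0.1)
  dr <- ibs_distance_matrix(gr)$D
  expect_equal(dr, t(dr))
  expect_true(all(dr >= 0 & dr <= 1, na.rm = TRUE))
  expect_equal(unname(diag(dr)), rep(0, 12))
})

test_that("pairs with no jointly genotyped locus are flagged NA", {
  dos <- rbind(c(0, NA), c(NA, 2), c(1, 1))
  expect_warning(d <- ibs_distance_matrix(toy_geno(dos)), "no genotyped locus")
  expect_true(is.na(d$D[1, 2]))
  expect_equal(d$n_flagged_pairs, 1)
})

test_that("GRM matches elementwise formula evaluation and row identity", {
  g <- toy_geno(rbind(c(0, 2), c(1, 1), c(2, 0)))
  G <- suppressWarnings(grm(g))$G
  # brute-force: p per site from the table, entry = mean over sites
  dos <- rbind(c(0, 2), c(1, 1), c(2, 0))
  p <- colSums(dos) / 6
  brute <- matrix(0, 3, 3)
  for (i in 1:3) for (k in 1:3) {
    brute[i, k] <- mean((dos[i, ] - 2 * p) * (dos[k, ] - 2 * p) /
                          (2 * p * (1 - p)))
  }
  expect_equal(unname(G), brute, tolerance = 1e-12)

  g2 <- toy_geno(rbind(c(0, 2, 1), c(0, 2, 1), c(2, 0, 1)))
  G2 <- grm(g2)$G
  expect_equal(G2[1, 2], G2[1, 1])      # identical genotype rows
})

test_that("GRM is invariant to variant order and duplication", {
  g <- rand_geno(10, 60, seed = 9)
  G <- suppressWarnings(grm(g))$G
  perm <- sample(60)
  gp <- subset_variants(g, order(perm))  # any permutation before re-sorting
  expect_equal(suppressWarnings(grm(gp))$G, G, tolerance = 1e-12)
  gd <- toy_geno(cbind(g$dosage, g$dosage),
                 pos = c(g$variants$pos, g$variants$pos + 1e6))
  expect_equal(suppressWarnings(grm(gd))$G, G, tolerance = 1e-12)
})

test_that("GRM off-diagonal centers at its no-relatedness expectation", {
  set.seed(21)
  n <- 60
  m <- 2000
  p <- runif(m, 0.1, 0.9)
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  G <- grm(toy_geno(dos))$G
  off <- G[upper.tri(G)]
  # with frequencies estimated from the sample itself, unrelated pairs have
  # expectation -1/(n-1), not 0 (the standardized columns sum to ~0)
  se <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) + 1 / (n - 1)), 3 * se + 1e-3)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
})

test_that("PCA: identical samples coincide; SVD equals eigen route", {
  g <- toy_geno(rbind(c(0, 2, 1), c(0, 2, 1), c(2, 0, 1), c(1, 1, 0)))
  pc <- suppressWarnings(geno_pca(g, k = 2))
  expect_equal(pc$scores$PC1[1], pc$scores$PC1[2], tolerance = 1e-10)

  g2 <- rand_geno(15, 100, seed = 13)
  pc2 <- geno_pca(g2, k = 4)
  # independent eigen route on the same standardization
  X <- g2$dosage
  p <- colMeans(X) / 2
  Z <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  e <- eigen(Z %*% t(Z), symmetric = TRUE)
  for (k in 1:4) {
    ref <- e$vectors[, k] * sqrt(e$values[k])
    got <- pc2$scores[[paste0("PC", k)]]
    expect_equal(abs(got), abs(ref), tolerance = 1e-8)
  }
  expect_true(all(diff(pc2$var_frac) <= 1e-12))
  expect_lte(sum(pc2$var_frac), 1)
})

test_that("PC1 separates two diverged populations", {
  set.seed(31)
  m <- 400
  p0 <- runif(m, 0.2, 0.8)
  Fd <- 0.1
  pa <- rbeta(m, p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd)
  pb <- rbeta(m, p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd)
  dos <- rbind(
    matrix(rbinom(30 * m, 2, rep(pa, each = 30)), 30, m),
    matrix(rbinom(30 * m, 2, rep(pb, each = 30)), 30, m)
  )
  g <- toy_geno(dos, pops = rep(c("A", "B"), each = 30))
  pc1 <- geno_pca(g, k = 2)$scores$PC1
  between <- abs(mean(pc1[1:30]) - mean(pc1[31:60]))
  within <- mean(c(sd(pc1[1:30]), sd(pc1[31:60])))
  expect_gt(between / within, 3)
})

test_that("NJ solves the 3-taxon system and reproduces additive distances", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(D3)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.5, 1.5, 2.5))

  # 4-taxon additive matrix from a known tree (edges a=1,b=2,c=3,d=4,int=1)
  D4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- nj_tree(D4)
  path <- ape::cophenetic.phylo(tr4)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(path, D4, tolerance = 1e-10)
  # output parses as valid Newick
  expect_s3_class(ape::read.tree(text = nj_newick(D4)), "phylo")
})

test_that("NJ degenerate and error cases behave", {
  Deq <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(Deq) <- 0
  tr <- nj_tree(Deq)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))

  Dna <- Deq
  Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(nj_tree(Dna), "complete")
  expect_error(nj_tree(Deq[1:2, 1:2]), ">= 3")
})
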