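#' Identity-by-state distance matrix
#'
#' For each unordered pair, the IBS *distance* is one minus the proportion of
#' alleles shared identical-by-state over loci genotyped in both samples:
#' `D[i,j] = 1 - sum_l (2 - |x_il - x_jl|) / (2 m_ij)` with `m_ij` the count
#' of jointly non-missing loci. The distance orientation means unrelated
#' pairs take large values and duplicates take 0. Pairs with no jointly
#' genotyped locus are set `NA` and counted in `n_flagged_pairs`.
#'
#' @param x a `geno_table` with at least 2 samples and 1 variant
#' @return an `ibs_dist` object: symmetric matrix `D` in \[0, 1\] with zero
#'   diagonal, `sample_id`, `n_pairs = n(n-1)/2`, `n_flagged_pairs`.
#' @export
ibs_distance_matrix <- function(x) {
  if (n_samples(x) < 2 || n_variants(x) < 1) {
    abort("IBS distance needs >= 2 samples and >= 1 variant")
  }
  X <- x$dosage
  N <- (!is.na(X)) * 1
  I0 <- (X == 0 & !is.na(X)) * 1
  I1 <- (X == 1 & !is.na(X)) * 1
  I2 <- (X == 2 & !is.na(X)) * 1
  M <- N %*% t(N)
  sum_diff <- (I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1)) +
    2 * (I0 %*% t(I2) + I2 %*% t(I0))
  D <- sum_diff / (2 * M)
  D[M == 0] <- NA_real_
  diag(D) <- 0
  n <- nrow(D)
  flagged <- sum(is.na(D[upper.tri(D)]))
  if (flagged > 0) {
    warn(sprintf("%d sample pair(s) share no genotyped locus (distance NA)", flagged))
  }
  dimnames(D) <- list(x$samples$sample_id, x$samples$sample_id)
  structure(list(D = D, sample_id = x$samples$sample_id,
                 n_pairs = n * (n - 1) / 2, n_flagged_pairs = flagged),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat(sprintf("<ibs_dist> %d samples, %d unique pairs", length(x$sample_id),
              x$n_pairs))
  if (x$n_flagged_pairs) cat(sprintf(" (%d flagged NA)", x$n_flagged_pairs))
  cat("\n")
  invisible(x)
}

#' @export
tidy.ibs_dist <- function(x, ...) {
  .tidy_pair_matrix(x$D, x$sample_id, "distance")
}

.tidy_pair_matrix <- function(M, ids, value_name) {
  ut <- which(upper.tri(M), arr.ind = TRUE)
  out <- tibble::tibble(
    sample_1 = ids[ut[, 1]],
    sample_2 = ids[ut[, 2]],
    value = M[ut]
  )
  names(out)[3] <- value_name
  out
}

#' Genomic relationship matrix (allele-frequency standardized)
#'
#' VanRaden/GCTA-style GRM: `G[i,k]` is the mean over variants of
#' `(x_ij - 2 p_j)(x_kj - 2 p_j) / (2 p_j (1 - p_j))`, with allele
#' frequencies `p_j` estimated from the table's non-missing alleles. Missing
#' genotypes are excluded pairwise (each pair is averaged over its jointly
#' non-missing variants). Monomorphic sites are skipped with a warning.
#'
#' @param x a `geno_table`
#' @return a `grm` object: symmetric matrix `G`, `sample_id`,
#'   `n_sites_used`, `n_monomorphic_skipped`.
#' @export
grm <- function(x) {
  X <- x$dosage
  n_called <- colSums(!is.na(X))
  p <- colSums(X, na.rm = TRUE) / (2 * pmax(n_called, 1))
  poly <- n_called > 0 & p > 0 & p < 1
  if (!all(poly)) {
    warn(sprintf("%d monomorphic or all-missing site(s) skipped in GRM",
                 sum(!poly)))
  }
  if (!any(poly)) abort("GRM needs at least one polymorphic site")
  Xp <- X[, poly, drop = FALSE]
  pp <- p[poly]
  Z <- sweep(sweep(Xp, 2, 2 * pp), 2, sqrt(2 * pp * (1 - pp)), "/")
  N <- (!is.na(Z)) * 1
  Z[is.na(Z)] <- 0
  M <- N %*% t(N)
  G <- (Z %*% t(Z)) / M
  G[M == 0] <- NA_real_
  dimnames(G) <- list(x$samples$sample_id, x$samples$sample_id)
  structure(list(G = G, sample_id = x$samples$sample_id,
                 n_sites_used = sum(poly),
                 n_monomorphic_skipped = sum(!poly)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d samples, %d sites used (%d skipped)\n",
              length(x$sample_id), x$n_sites_used, x$n_monomorphic_skipped))
  invisible(x)
}

#' @export
tidy.grm <- function(x, ...) {
  .tidy_pair_matrix(x$G, x$sample_id, "relationship")
}

#' Principal components of standardized genotypes
#'
#' Each variant is centered at twice its allele frequency and scaled by
#' `1/sqrt(2 p (1 - p))`; missing dosages are mean-imputed (zero after
#' centering). Coordinates are the top-k left singular vectors scaled by
#' their singular values — identical (to sign) to projecting on the
#' eigenvectors of the genomic relationship covariance.
#'
#' @param x a `geno_table` with at least `k + 1` samples
#' @param k number of components to keep (truncated to the rank, with a
#'   warning, when it exceeds it)
#' @return a `geno_pca` object: `scores` tibble (sample metadata + `PC1..k`),
#'   `var_frac` explained-variance fractions, `k`.
#' @export
geno_pca <- function(x, k = 10) {
  if (n_samples(x) < k + 1) abort("need at least k + 1 samples for k components")
  X <- x$dosage
  n_called <- colSums(!is.na(X))
  p <- colSums(X, na.rm = TRUE) / (2 * pmax(n_called, 1))
  poly <- n_called > 0 & p > 0 & p < 1
  Xp <- X[, poly, drop = FALSE]
  pp <- p[poly]
  Z <- sweep(sweep(Xp, 2, 2 * pp), 2, sqrt(2 * pp * (1 - pp)), "/")
  Z[is.na(Z)] <- 0
  s <- svd(Z)
  rank <- sum(s$d > s$d[1] * 1e-10)
  if (k > rank) {
    warn(sprintf("k = %d exceeds rank %d; truncated", k, rank))
    k <- rank
  }
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  var_frac <- (s$d^2 / sum(s$d^2))[seq_len(k)]
  structure(
    list(scores = dplyr::bind_cols(x$samples, tibble::as_tibble(scores)),
         var_frac = var_frac, k = k),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), x$k, 100 * x$var_frac[1],
              if (x$k > 1) 100 * x$var_frac[2] else NA))
  invisible(x)
}

#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' @export
glance.geno_pca <- function(x, ...) {
  tibble::tibble(k = x$k, pc1_var = x$var_frac[1],
                 pc2_var = if (x$k > 1) x$var_frac[2] else NA_real_,
                 total_var = sum(x$var_frac))
}

#' Neighbor-joining tree from an IBS distance matrix
#'
#' Saitou–Nei neighbor joining (via ape); for additive distances the tree's
#' path lengths reproduce the input exactly. Negative branch lengths — an
#' NJ artifact on non-additive noisy matrices — are clamped to zero with the
#' deficit transferred to the sibling branch(es) sharing the same parent
#' node, preserving total tree length approximately.
#'
#' @param d an `ibs_dist`, `dist`, or square symmetric matrix with >= 3
#'   samples and no missing entries
#' @param clamp_negative clamp-and-transfer negative branch lengths
#'   (default TRUE)
#' @return an `ape::phylo` tree (unrooted); serialize with [nj_newick()].
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  D <- if (inherits(d, "ibs_dist")) d$D else as.matrix(d)
  if (nrow(D) < 3) abort("neighbor joining needs >= 3 samples")
  if (anyNA(D)) abort("distance matrix has missing entries; NJ requires a complete matrix")
  tr <- ape::nj(stats::as.dist(D))
  if (clamp_negative) {
    len <- tr$edge.length
    for (e in which(len < 0)) {
      par <- tr$edge[e, 1]
      sibs <- setdiff(which(tr$edge[, 1] == par), e)
      if (length(sibs)) {
        len[sibs] <- pmax(0, len[sibs] + len[e] / length(sibs))
      }
      len[e] <- 0
    }
    tr$edge.length <- len
  }
  tr
}

#' @rdname nj_tree
#' @param ... passed to [nj_tree()]
#' @return `nj_newick()`: the tree as a Newick string.
#' @export
nj_newick <- function(d, ...) {
  ape::write.tree(nj_tree(d, ...))
}
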