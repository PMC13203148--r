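#' Pairwise genotype r-squared within a distance cap
#'
#' For every intra-chromosome SNP pair within `max_dist_bp`, the squared
#' Pearson correlation of the dosage vectors over jointly non-missing
#' samples — genotype (not haplotype) LD, so phase is never assumed. Pairs
#' with zero dosage variance are skipped and counted in
#' `attr(, "n_skipped")`. Compute per population: pass the population's
#' sample ids, or subset the table first.
#'
#' @param x a `geno_table`
#' @param max_dist_bp maximum pair distance in bp (default 500 kb)
#' @param samples optional sample ids restricting the computation
#' @param chunk_size internal column-block size for the correlation calls
#' @return tibble: `chrom`, `pos1`, `pos2`, `dist`, `r2`.
#' @export
pairwise_r2 <- function(x, max_dist_bp = 500000, samples = NULL,
                        chunk_size = 512) {
  if (!is.null(samples)) x <- subset_samples(x, samples)
  res <- list()
  n_skipped <- 0
  for (ch in unique(x$variants$chrom)) {
    idx <- which(x$variants$chrom == ch)
    m <- length(idx)
    if (m < 2) next
    pos <- x$variants$pos[idx]
    X <- x$dosage[, idx, drop = FALSE]
    jmax <- findInterval(pos + max_dist_bp, pos)
    for (a in seq(1, m - 1, by = chunk_size)) {
      b <- min(a + chunk_size - 1, m - 1)
      hi <- max(jmax[a:b])
      if (hi <= a) next
      sub <- a:hi
      C <- suppressWarnings(stats::cor(X[, sub, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      cnt <- pmax(0, jmax[a:b] - (a:b))
      if (sum(cnt) == 0) next
      ii <- rep(a:b, cnt)
      jj <- sequence(cnt, from = (a:b) + 1)
      r2 <- C[cbind(ii - a + 1, jj - a + 1)]^2
      bad <- is.na(r2)
      n_skipped <- n_skipped + sum(bad)
      if (all(bad)) next
      res[[length(res) + 1]] <- tibble::tibble(
        chrom = ch, pos1 = pos[ii[!bad]], pos2 = pos[jj[!bad]],
        dist = pos[jj[!bad]] - pos[ii[!bad]], r2 = r2[!bad]
      )
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else tibble::tibble(
    chrom = character(), pos1 = numeric(), pos2 = numeric(),
    dist = numeric(), r2 = numeric()
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Binned LD-decay curve
#'
#' Mean r-squared per distance bin; bin `b` covers the half-open interval
#' `((b-1) w, b w]` so the bins tile `(0, max_dist_bp]`. Empty bins are kept
#' with `n_pairs = 0` and `mean_r2 = NA`.
#'
#' @param pairs output of [pairwise_r2()] (needs `dist`, `r2`)
#' @param bin_width_bp bin width in bp (> 0; default 1 kb)
#' @param max_dist_bp upper end of the binning range (default: largest
#'   observed distance)
#' @return tibble: `bin_start`, `bin_end`, `mean_r2`, `n_pairs`.
#' @export
ld_decay_curve <- function(pairs, bin_width_bp = 1000, max_dist_bp = NULL) {
  if (bin_width_bp <= 0) abort("bin_width_bp must be positive")
  if (nrow(pairs) == 0) abort("empty pair stream")
  max_dist_bp <- max_dist_bp %||% max(pairs$dist)
  nb <- ceiling(max_dist_bp / bin_width_bp)
  bin <- pmin(nb, ceiling(pairs$dist / bin_width_bp))
  sums <- tapply(pairs$r2, factor(bin, levels = seq_len(nb)), sum)
  cnts <- tapply(pairs$r2, factor(bin, levels = seq_len(nb)), length)
  cnts[is.na(cnts)] <- 0
  tibble::tibble(
    bin_start = (seq_len(nb) - 1) * bin_width_bp,
    bin_end = seq_len(nb) * bin_width_bp,
    mean_r2 = as.numeric(ifelse(cnts > 0, sums / cnts, NA_real_)),
    n_pairs = as.numeric(cnts)
  )
}

#' Per-population LD decay
#'
#' Convenience wrapper running [pairwise_r2()] and [ld_decay_curve()] for
#' each population label in the sample sheet.
#'
#' @param x a `geno_table`
#' @param max_dist_bp,bin_width_bp see [pairwise_r2()] / [ld_decay_curve()]
#' @param populations population labels to include (default: all)
#' @return tibble with a `population` column prepended to the curve columns.
#' @export
ld_decay_by_population <- function(x, max_dist_bp = 500000,
                                   bin_width_bp = 1000, populations = NULL) {
  populations <- populations %||% unique(x$samples$population)
  purrr::map_dfr(populations, function(popn) {
    ids <- x$samples$sample_id[x$samples$population == popn]
    if (length(ids) < 2) return(NULL)
    pr <- pairwise_r2(x, max_dist_bp, samples = ids)
    if (nrow(pr) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(population = popn),
                     ld_decay_curve(pr, bin_width_bp, max_dist_bp))
  })
}

#' Window-based r-squared pruner
#'
#' Greedy utility for thinning correlated markers before structure analyses:
#' within sliding windows of `window_snps` SNPs (advanced by `step_snps`),
#' the later SNP of any pair with `r2 > r2_max` is dropped.
#'
#' @param x a `geno_table`
#' @param window_snps,step_snps window geometry in SNP counts
#' @param r2_max pruning threshold
#' @return a pruned `geno_table`.
#' @export
ld_prune <- function(x, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  keep <- rep(TRUE, n_variants(x))
  for (ch in unique(x$variants$chrom)) {
    idx <- which(x$variants$chrom == ch)
    m <- length(idx)
    a <- 1
    while (a <= m) {
      b <- min(a + window_snps - 1, m)
      win <- idx[a:b]
      act <- win[keep[win]]
      if (length(act) > 1) {
        C <- suppressWarnings(stats::cor(x$dosage[, act, drop = FALSE],
                                         use = "pairwise.complete.obs"))^2
        for (i in seq_along(act)) {
          if (!keep[act[i]]) next
          hit <- which(C[i, ] > r2_max & seq_along(act) > i)
          keep[act[hit]] <- FALSE
        }
      }
      if (b == m) break
      a <- a + step_snps
    }
  }
  subset_variants(x, keep)
}
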