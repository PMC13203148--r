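#' Parameters for run-of-homozygosity detection
#'
#' Defaults mirror the standard PLINK sliding-window flags:
#' `--homozyg-snp 50 --homozyg-kb 500 --homozyg-window-snp 50
#' --homozyg-window-het 3 --homozyg-window-missing 5
#' --homozyg-window-threshold 0.05 --homozyg-gap 100 --homozyg-density 50`.
#'
#' @param min_snps_per_run minimum SNPs in a reported run
#' @param min_run_kb minimum run length (kb)
#' @param window_snps SNPs per scanning window
#' @param window_max_het maximum heterozygous calls tolerated in a window
#' @param window_max_missing maximum missing calls tolerated in a window
#' @param hit_threshold minimum fraction of covering windows that must be
#'   homozygous-compatible for a SNP to be in-run, in (0, 1\]
#' @param max_gap_kb runs are split at inter-SNP gaps larger than this (kb)
#' @param min_density_kb_per_snp maximum average spacing (kb per SNP) of a run
#' @return a `roh_params` list.
#' @export
roh_params <- function(min_snps_per_run = 50, min_run_kb = 500,
                       window_snps = 50, window_max_het = 3,
                       window_max_missing = 5, hit_threshold = 0.05,
                       max_gap_kb = 100, min_density_kb_per_snp = 50) {
  p <- list(min_snps_per_run = min_snps_per_run, min_run_kb = min_run_kb,
            window_snps = window_snps, window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            hit_threshold = hit_threshold, max_gap_kb = max_gap_kb,
            min_density_kb_per_snp = min_density_kb_per_snp)
  if (min_snps_per_run <= 0 || min_run_kb <= 0 || window_snps <= 0 ||
      max_gap_kb <= 0 || min_density_kb_per_snp <= 0) {
    abort("roh_params lengths and counts must be positive")
  }
  if (window_max_het < 0 || window_max_missing < 0) {
    abort("window tolerances must be non-negative")
  }
  if (hit_threshold <= 0 || hit_threshold > 1) abort("hit_threshold must be in (0, 1]")
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Per sample and chromosome, a window of `window_snps` consecutive SNPs
#' slides one SNP at a time; a window is homozygous-compatible when it holds
#' at most `window_max_het` heterozygous and `window_max_missing` missing
#' calls. A SNP is in-run when the fraction of windows covering it that are
#' compatible reaches `hit_threshold`. Maximal in-run stretches are then
#' split at inter-SNP gaps above `max_gap_kb`, and filtered by
#' `min_snps_per_run`, `min_run_kb` and density
#' (`length/n_snps <= min_density_kb_per_snp`). Run coordinates are
#' SNP-delimited: the first and last SNP of the surviving stretch.
#' Chromosomes with fewer SNPs than `window_snps` are evaluated with one
#' truncated window spanning all their SNPs.
#'
#' @param x a `geno_table` (sorted; enforced by construction)
#' @param params a [roh_params()]
#' @return tibble of segments: `sample_id`, `chrom`, `start`, `end`,
#'   `n_snps`, `length_bp`.
#' @export
detect_roh <- function(x, params = roh_params()) {
  out <- list()
  chroms <- unique(x$variants$chrom)
  for (ch in chroms) {
    idx <- which(x$variants$chrom == ch)
    pos <- x$variants$pos[idx]
    S <- length(idx)
    if (S == 0) next
    gap_split <- which(diff(pos) > params$max_gap_kb * 1000)
    for (si in seq_len(n_samples(x))) {
      g <- x$dosage[si, idx]
      inrun <- .roh_inrun(g, params)
      if (!any(inrun)) next
      r <- rle(inrun)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        i1 <- starts[k]; i2 <- ends[k]
        cuts <- gap_split[gap_split >= i1 & gap_split < i2]
        bounds <- cbind(c(i1, cuts + 1), c(cuts, i2))
        for (b in seq_len(nrow(bounds))) {
          a <- bounds[b, 1]; z <- bounds[b, 2]
          n_snps <- z - a + 1
          len <- pos[z] - pos[a] + 1
          if (n_snps >= params$min_snps_per_run &&
              len >= params$min_run_kb * 1000 &&
              (len / 1000) / n_snps <= params$min_density_kb_per_snp) {
            out[[length(out) + 1]] <- tibble::tibble(
              sample_id = x$samples$sample_id[si], chrom = ch,
              start = pos[a], end = pos[z], n_snps = n_snps, length_bp = len
            )
          }
        }
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    sample_id = character(), chrom = character(), start = numeric(),
    end = numeric(), n_snps = numeric(), length_bp = numeric()
  )
  attr(res, "params") <- params
  res
}

# in-run flags for one sample on one chromosome (dosage vector g)
.roh_inrun <- function(g, params) {
  S <- length(g)
  het <- !is.na(g) & g == 1
  mis <- is.na(g)
  w <- min(params$window_snps, S)
  K <- S - w + 1
  ch <- c(0, cumsum(het))
  cm <- c(0, cumsum(mis))
  i <- seq_len(K)
  comp <- (ch[i + w] - ch[i]) <= params$window_max_het &
    (cm[i + w] - cm[i]) <= params$window_max_missing
  cc <- c(0, cumsum(comp))
  j <- seq_len(S)
  lo <- pmax(1, j - w + 1)
  lo <- pmin(lo, K)
  hi <- pmin(j, K)
  ncov <- hi - lo + 1
  ncomp <- cc[hi + 1] - cc[lo]
  ncomp / ncov >= params$hit_threshold
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` is the summed ROH length of a sample divided by the autosomal
#' genome length. The default genome length is the cattle autosomal total of
#' 2,489.39 Mb. Segments must be disjoint within a sample (overlap is an
#' invariant violation and errors).
#'
#' @param segments a segment tibble from [detect_roh()]
#' @param genome_length_bp total autosome length in bp (> 0)
#' @param sample_ids optional full sample-id vector, so samples without any
#'   segment are reported with `f_roh = 0`
#' @return tibble: `sample_id`, `n_segments`, `sum_roh_bp`, `f_roh`.
#' @export
froh <- function(segments, genome_length_bp = 2489390000,
                 sample_ids = NULL) {
  if (!is.numeric(genome_length_bp) || genome_length_bp <= 0) {
    abort("genome_length_bp must be positive")
  }
  if (nrow(segments)) {
    chk <- segments |>
      dplyr::arrange(.data$sample_id, .data$chrom, .data$start) |>
      dplyr::group_by(.data$sample_id, .data$chrom) |>
      dplyr::summarise(
        overlap = any(.data$start[-1] <= .data$end[-dplyr::n()]),
        .groups = "drop"
      )
    if (any(chk$overlap, na.rm = TRUE)) {
      abort("ROH segments overlap within a sample; segments must be disjoint")
    }
  }
  res <- segments |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_segments = dplyr::n(),
                     sum_roh_bp = sum(.data$length_bp), .groups = "drop")
  if (!is.null(sample_ids)) {
    res <- dplyr::left_join(tibble::tibble(sample_id = sample_ids), res,
                            by = "sample_id") |>
      dplyr::mutate(n_segments = dplyr::coalesce(.data$n_segments, 0L),
                    sum_roh_bp = dplyr::coalesce(.data$sum_roh_bp, 0))
  }
  dplyr::mutate(res, f_roh = .data$sum_roh_bp / genome_length_bp)
}
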