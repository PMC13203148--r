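#' Weir-Cockerham variance components for one site, two populations
#'
#' The 1984 moment estimator for two populations: from per-group sample
#' sizes `n`, alternate-allele frequencies `p` and observed heterozygote
#' fractions `h`, the among-population (`a`), among-individual (`b`) and
#' within-individual (`c`) components. Site Fst is `a / (a + b + c)`; a
#' window estimate must be the ratio of summed components (weighted), never
#' the mean of per-site ratios. Sites monomorphic across both groups return
#' `a = b = c = 0`. A group with no called genotype (or a pooled sample of
#' one per group) makes the estimator undefined: `NA` components.
#'
#' @param dosages_a,dosages_b dosage vectors (0/1/2/NA) of the two groups at
#'   one site
#' @return named numeric `c(a=, b=, c=)`.
#' @export
site_fst_components <- function(dosages_a, dosages_b) {
  comp <- .wc_components(matrix(dosages_a, ncol = 1),
                         matrix(dosages_b, ncol = 1))
  c(a = comp$a[1], b = comp$b[1], c = comp$c[1])
}

# vectorized WC84 components over the columns of two dosage matrices
.wc_components <- function(A, B) {
  n1 <- colSums(!is.na(A))
  n2 <- colSums(!is.na(B))
  p1 <- colSums(A, na.rm = TRUE) / (2 * pmax(n1, 1))
  p2 <- colSums(B, na.rm = TRUE) / (2 * pmax(n2, 1))
  h1 <- colSums(A == 1, na.rm = TRUE) / pmax(n1, 1)
  h2 <- colSums(B == 1, na.rm = TRUE) / pmax(n2, 1)

  nbar <- (n1 + n2) / 2
  nt <- n1 + n2
  nc <- nt - (n1^2 + n2^2) / nt
  pbar <- (n1 * p1 + n2 * p2) / nt
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / nt

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  undef <- n1 == 0 | n2 == 0 | nbar <= 1
  mono <- !undef & (pbar == 0 | pbar == 1) & hbar == 0
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  a[undef] <- NA_real_; b[undef] <- NA_real_; cc[undef] <- NA_real_
  list(a = a, b = b, c = cc, undef = undef)
}

# window anchors: 1, 1 + step, 1 + 2 step, ... up to chromosome length L;
# trailing partial windows keep their true (clipped) span
.make_windows <- function(chrom, L, size, step) {
  k <- 0:floor((L - 1) / step)
  tibble::tibble(chrom = chrom, win = k, start = 1 + k * step,
                 end = pmin(k * step + size, L))
}

# window indices (k) covering each position; returns expanded (site, k) rows
.site_window_keys <- function(pos, size, step) {
  kmax <- floor((pos - 1) / step)
  kmin <- pmax(0, ceiling((pos - size) / step))
  noff <- ceiling(size / step)
  site <- integer(0); k <- integer(0)
  for (o in 0:(noff - 1)) {
    kk <- kmax - o
    ok <- kk >= kmin
    site <- c(site, which(ok))
    k <- c(k, kk[ok])
  }
  list(site = site, k = k)
}

.chrom_lengths <- function(x, chrom_lengths = NULL) {
  chroms <- unique(x$variants$chrom)
  if (is.null(chrom_lengths)) {
    vapply(chroms, function(ch) max(x$variants$pos[x$variants$chrom == ch]),
           numeric(1))
  } else {
    if (!all(chroms %in% names(chrom_lengths))) {
      abort("chrom_lengths must name every chromosome in the table")
    }
    chrom_lengths[chroms]
  }
}

#' Sliding-window Weir-Cockerham Fst between two groups
#'
#' Windows of `size_bp` advanced by `step_bp` tile each chromosome from
#' position 1; a site contributes to every window containing it. The window
#' estimate is the ratio of sums, `sum(a) / sum(a + b + c)` over the
#' window's sites; windows with no informative site carry `NA`. Negative
#' estimates are retained (clamping would distort downstream empirical
#' quantiles).
#'
#' @param x a `geno_table`
#' @param group_a,group_b disjoint sample-id vectors (e.g. twin and control
#'   cohorts)
#' @param size_bp,step_bp window geometry (`step_bp <= size_bp`); defaults
#'   50 kb / 20 kb
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   defaults to the last SNP position per chromosome
#' @return tibble: `chrom`, `start`, `end`, `n_snps`, `fst`.
#' @export
window_fst <- function(x, group_a, group_b, size_bp = 50000, step_bp = 20000,
                       chrom_lengths = NULL) {
  .check_window(size_bp, step_bp)
  ia <- .sample_rows(x, group_a, "group_a")
  ib <- .sample_rows(x, group_b, "group_b")
  if (length(intersect(ia, ib))) abort("groups must be disjoint")
  comp <- .wc_components(x$dosage[ia, , drop = FALSE],
                         x$dosage[ib, , drop = FALSE])
  num <- comp$a
  den <- comp$a + comp$b + comp$c
  .window_aggregate(x, chrom_lengths, size_bp, step_bp,
                    function(sites, span) {
                      nn <- sum(!is.na(num[sites]))
                      d <- sum(den[sites], na.rm = TRUE)
                      c(n_snps = length(sites),
                        fst = if (nn > 0 && d > 0)
                          sum(num[sites], na.rm = TRUE) / d else NA_real_)
                    }, c("n_snps", "fst"))
}

#' Sliding-window nucleotide diversity
#'
#' Per site, the unbiased heterozygosity `pi = 2 n_alt n_ref / (n (n - 1))`
#' with `n` the non-missing allele count in the group (sites with `n < 2`
#' are skipped); the window value sums site pi over the window and divides
#' by the window span in bp, giving per-bp diversity. Windows without
#' variants have `pi = 0`.
#'
#' @inheritParams window_fst
#' @param group sample-id vector of the group
#' @return tibble: `chrom`, `start`, `end`, `n_snps`, `pi`.
#' @export
window_pi <- function(x, group, size_bp = 50000, step_bp = 20000,
                      chrom_lengths = NULL) {
  .check_window(size_bp, step_bp)
  ig <- .sample_rows(x, group, "group")
  G <- x$dosage[ig, , drop = FALSE]
  n <- 2 * colSums(!is.na(G))
  alt <- colSums(G, na.rm = TRUE)
  pi_site <- ifelse(n >= 2, 2 * alt * (n - alt) / (n * (n - 1)), NA_real_)
  .window_aggregate(x, chrom_lengths, size_bp, step_bp,
                    function(sites, span) {
                      c(n_snps = sum(!is.na(pi_site[sites])),
                        pi = sum(pi_site[sites], na.rm = TRUE) / span)
                    }, c("n_snps", "pi"))
}

.check_window <- function(size_bp, step_bp) {
  if (size_bp <= 0 || step_bp <= 0 || step_bp > size_bp) {
    abort("window needs 0 < step_bp <= size_bp")
  }
}

# shared window machinery: applies f(site_indices, span_bp) per window
.window_aggregate <- function(x, chrom_lengths, size_bp, step_bp, f, stat_names) {
  lens <- .chrom_lengths(x, chrom_lengths)
  out <- list()
  for (ch in names(lens)) {
    win <- .make_windows(ch, lens[[ch]], size_bp, step_bp)
    idx <- which(x$variants$chrom == ch)
    keys <- .site_window_keys(x$variants$pos[idx], size_bp, step_bp)
    by_k <- split(idx[keys$site], keys$k)
    span <- win$end - win$start + 1
    stats <- t(vapply(seq_len(nrow(win)), function(r) {
      sites <- by_k[[as.character(win$win[r])]]
      f(if (is.null(sites)) integer(0) else sites, span[r])
    }, numeric(length(stat_names))))
    colnames(stats) <- stat_names
    out[[ch]] <- dplyr::bind_cols(win[c("chrom", "start", "end")],
                                  tibble::as_tibble(stats))
  }
  dplyr::bind_rows(out)
}

#' Log2 diversity ratio, control over twin
#'
#' `log2(pi_control / pi_twin)`: positive values flag diversity loss in the
#' twin group. Defined only when both diversities are positive; otherwise
#' `NA` (the callers exclude and count such windows).
#'
#' @param pi_control,pi_twin per-window diversity vectors
#' @return numeric vector.
#' @export
log2_pi_ratio <- function(pi_control, pi_twin) {
  ifelse(pi_control > 0 & pi_twin > 0, log2(pi_control / pi_twin), NA_real_)
}

#' Select the top quantile of windows and merge them into regions
#'
#' The threshold is the empirical (type-7) quantile of the chosen statistic
#' over windows where it is defined; windows strictly above the threshold
#' are selected and merged (overlapping or book-ended) into a region set.
#'
#' @param windows a window tibble with `chrom`, `start`, `end` and the
#'   statistic column
#' @param field statistic column name (e.g. `"fst"`, `"log2_ratio"`)
#' @param quantile quantile level (default 0.95, the top 5 percent)
#' @return list: `threshold`, `windows` (selected rows), `regions`
#'   (a [region_set()]).
#' @export
select_top_windows <- function(windows, field, quantile = 0.95) {
  v <- windows[[field]]
  if (is.null(v)) abort(paste0("no column ", field))
  def <- !is.na(v)
  if (sum(def) < 20) abort("need >= 20 windows with a defined statistic")
  thr <- stats::quantile(v[def], quantile, type = 7, names = FALSE)
  sel <- def & v > thr
  if (!any(sel)) warn("no window strictly above the threshold (degenerate selection)")
  list(
    threshold = thr,
    windows = windows[sel, , drop = FALSE],
    regions = region_set(windows$chrom[sel], windows$start[sel],
                         windows$end[sel], provenance = field)
  )
}

#' Region set: merged genomic intervals
#'
#' Builds a sorted, non-overlapping interval set (1-based inclusive) by
#' merging overlapping and adjacent input intervals.
#'
#' @param chrom,start,end parallel interval vectors
#' @param provenance label recorded on the set (`fst`, `pi_ratio`,
#'   `intersection`, `union`, ...)
#' @return tibble (`chrom`, `start`, `end`) with a `provenance` attribute.
#' @export
region_set <- function(chrom, start, end, provenance = "region") {
  if (length(chrom) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    gr <- GenomicRanges::reduce(.to_granges(chrom, start, end))
    out <- .from_granges(gr)
  }
  attr(out, "provenance") <- provenance
  out
}

.to_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

.from_granges <- function(gr) {
  gr <- BiocGenerics::sort(gr)
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = as.numeric(BiocGenerics::start(gr)),
                 end = as.numeric(BiocGenerics::end(gr)))
}

#' Combine two region sets
#'
#' Interval union or intersection; the result is merged and sorted. Sets
#' whose chromosome labels come from different naming dialects (one uses a
#' `chr` prefix, the other does not) are rejected.
#'
#' @param A,B region tibbles (from [region_set()] or [select_top_windows()])
#' @param mode `"intersection"` or `"union"`
#' @return a [region_set()] with provenance = `mode`.
#' @export
combine_regions <- function(A, B, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  pref_a <- grepl("^chr", A$chrom)
  pref_b <- grepl("^chr", B$chrom)
  if ((any(pref_a) && nrow(B) && !any(pref_b)) ||
      (any(pref_b) && nrow(A) && !any(pref_a))) {
    abort("region sets use mixed chromosome naming dialects")
  }
  ga <- .to_granges(A$chrom, A$start, A$end)
  gb <- .to_granges(B$chrom, B$start, B$end)
  suppressWarnings({
    gr <- if (mode == "union") GenomicRanges::union(ga, gb)
          else GenomicRanges::intersect(ga, gb)
  })
  out <- if (length(gr)) .from_granges(GenomicRanges::reduce(gr)) else
    tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  attr(out, "provenance") <- mode
  out
}

#' Total length of a region set in bp
#' @param regions a region tibble
#' @return numeric total.
#' @export
regions_total_bp <- function(regions) {
  if (nrow(regions) == 0) return(0)
  sum(regions$end - regions$start + 1)
}

#' Which variants fall inside a region set
#' @param variants a variant tibble (`chrom`, `pos`)
#' @param regions a region tibble
#' @return logical vector along `variants`.
#' @export
in_regions <- function(variants, regions) {
  if (nrow(regions) == 0 || nrow(variants) == 0) {
    return(rep(FALSE, nrow(variants)))
  }
  gv <- .to_granges(variants$chrom, variants$pos, variants$pos)
  gr <- .to_granges(regions$chrom, regions$start, regions$end)
  suppressWarnings(GenomicRanges::countOverlaps(gv, gr) > 0)
}

#' Joint Fst / diversity-ratio selection scan
#'
#' Runs [window_fst()] and [window_pi()] for the twin and control groups on
#' a shared window grid, forms `log2(pi_control / pi_twin)`, selects the top
#' quantile of each statistic, and combines the two region sets by
#' intersection and union. The returned object carries the realized
#' thresholds, the selected windows, both combinations, and Venn-style
#' counts at window and merged-region granularity.
#'
#' @param x a `geno_table`
#' @param twin,control sample-id vectors; default to the table's `twin` and
#'   `control` cohorts
#' @param size_bp,step_bp window geometry (50 kb / 20 kb defaults)
#' @param quantile top-quantile level (default 0.95)
#' @param chrom_lengths optional named chromosome lengths
#' @return a `sweep_scan` object; see [tidy.sweep_scan()] /
#'   [glance.sweep_scan()].
#' @export
sweep_scan <- function(x, twin = NULL, control = NULL, size_bp = 50000,
                       step_bp = 20000, quantile = 0.95,
                       chrom_lengths = NULL) {
  twin <- twin %||% cohort_ids(x, "twin")
  control <- control %||% cohort_ids(x, "control")
  fst <- window_fst(x, twin, control, size_bp, step_bp, chrom_lengths)
  pit <- window_pi(x, twin, size_bp, step_bp, chrom_lengths)
  pic <- window_pi(x, control, size_bp, step_bp, chrom_lengths)
  windows <- fst |>
    dplyr::mutate(pi_twin = pit$pi, pi_control = pic$pi,
                  log2_ratio = log2_pi_ratio(pic$pi, pit$pi))
  top_fst <- select_top_windows(windows, "fst", quantile)
  top_ratio <- select_top_windows(windows, "log2_ratio", quantile)
  inter <- combine_regions(top_fst$regions, top_ratio$regions, "intersection")
  uni <- combine_regions(top_fst$regions, top_ratio$regions, "union")
  key <- function(w) paste(w$chrom, w$start)
  structure(list(
    windows = windows,
    thresholds = c(fst = top_fst$threshold, log2_ratio = top_ratio$threshold),
    top = list(fst = top_fst, pi_ratio = top_ratio),
    regions = list(fst = top_fst$regions, pi_ratio = top_ratio$regions,
                   intersection = inter, union = uni),
    counts = list(
      windows_total = nrow(windows),
      windows_fst_defined = sum(!is.na(windows$fst)),
      windows_ratio_defined = sum(!is.na(windows$log2_ratio)),
      windows_top_fst = nrow(top_fst$windows),
      windows_top_ratio = nrow(top_ratio$windows),
      windows_in_both = length(intersect(key(top_fst$windows),
                                         key(top_ratio$windows))),
      regions_intersection = nrow(inter),
      regions_union = nrow(uni)
    ),
    quantile = quantile,
    window_spec = c(size_bp = size_bp, step_bp = step_bp)
  ), class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("<sweep_scan> %d windows (%.0f kb / %.0f kb step), top %.0f%%\n",
              x$counts$windows_total, x$window_spec["size_bp"] / 1000,
              x$window_spec["step_bp"] / 1000, 100 * (1 - x$quantile)))
  cat(sprintf("  thresholds: Fst > %.4g, log2(pi-ratio) > %.4g\n",
              x$thresholds["fst"], x$thresholds["log2_ratio"]))
  cat(sprintf("  selected windows: %d (Fst), %d (ratio), %d in both\n",
              x$counts$windows_top_fst, x$counts$windows_top_ratio,
              x$counts$windows_in_both))
  cat(sprintf("  merged regions: %d intersection, %d union\n",
              x$counts$regions_intersection, x$counts$regions_union))
  invisible(x)
}

#' Tidy a sweep scan: one row per window
#' @param x a `sweep_scan`
#' @param ... unused
#' @return the window tibble with selection flags.
#' @export
tidy.sweep_scan <- function(x, ...) {
  thr <- x$thresholds
  dplyr::mutate(
    x$windows,
    top_fst = !is.na(.data$fst) & .data$fst > thr["fst"],
    top_ratio = !is.na(.data$log2_ratio) & .data$log2_ratio > thr["log2_ratio"]
  )
}

#' One-row summary of a sweep scan
#' @param x a `sweep_scan`
#' @param ... unused
#' @return tibble with thresholds and counts.
#' @export
glance.sweep_scan <- function(x, ...) {
  tibble::tibble(
    fst_threshold = unname(x$thresholds["fst"]),
    log2_ratio_threshold = unname(x$thresholds["log2_ratio"]),
    n_windows = x$counts$windows_total,
    n_top_fst = x$counts$windows_top_fst,
    n_top_ratio = x$counts$windows_top_ratio,
    n_windows_in_both = x$counts$windows_in_both,
    n_regions_intersection = x$counts$regions_intersection,
    n_regions_union = x$counts$regions_union
  )
}
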