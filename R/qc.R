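#' Exact test of Hardy-Weinberg equilibrium
#'
#' Plain two-sided exact test on one biallelic site: conditioning on the
#' observed allele counts, the p-value is the summed probability of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (no mid-p correction). The exact test stays calibrated
#' at the rare-allele frequencies this package screens, where the chi-square
#' approximation fails. Symmetric under allele relabeling.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative; total >= 1)
#' @return p-value in (0, 1]; monomorphic sites return 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) abort("HWE test undefined: all genotype counts are zero")
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (rare + hets) / 2) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Site-filter criteria
#'
#' Defaults are the standard resequencing-QC values: minor allele
#' frequency at least 0.05, site missing rate at most 0.20, HWE exact
#' p-value above 1e-6, biallelic only.
#' Ties at a threshold are retained (inclusive comparisons), except the HWE
#' gate which is strict (`p > hwe_p_min` retained).
#'
#' @param maf_min minimum minor allele frequency, in \[0, 0.5\]
#' @param site_missing_max maximum per-site genotype missing fraction
#' @param hwe_p_min sites with exact-test p-value `<= hwe_p_min` are removed
#' @param biallelic_only reject non-biallelic records (always true for tables
#'   built by [read_vcf()]; kept as an explicit reported criterion)
#' @return a `site_filter_criteria` list.
#' @export
site_filter_criteria <- function(maf_min = 0.05, site_missing_max = 0.20,
                                 hwe_p_min = 1e-6, biallelic_only = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) abort("maf_min must be in [0, 0.5]")
  if (site_missing_max < 0 || site_missing_max > 1) abort("site_missing_max must be in [0, 1]")
  if (hwe_p_min < 0 || hwe_p_min >= 1) abort("hwe_p_min must be in [0, 1)")
  structure(list(maf_min = maf_min, site_missing_max = site_missing_max,
                 hwe_p_min = hwe_p_min, biallelic_only = isTRUE(biallelic_only)),
            class = "site_filter_criteria")
}

#' Filter sites of a genotype table
#'
#' Applies the criteria of [site_filter_criteria()]. MAF is computed from
#' non-missing alleles only; a site with all genotypes missing is removed
#' under the missingness criterion (missing fraction 1). Removal is
#' attributed to the first failing criterion, evaluated in the order
#' biallelic, missingness, MAF, HWE.
#'
#' @param x a `geno_table`
#' @param criteria a [site_filter_criteria()]
#' @param hwe_mode `"pooled"` tests all samples together; `"per_population"`
#'   tests within each population and removes a site if any population fails.
#' @return `list(table = filtered geno_table, report = tibble)`; the report
#'   has one row per criterion with the count removed, plus `sites_in` /
#'   `sites_out` attributes.
#' @export
filter_sites <- function(x, criteria = site_filter_criteria(),
                         hwe_mode = c("pooled", "per_population")) {
  hwe_mode <- match.arg(hwe_mode)
  dos <- x$dosage
  m <- n_variants(x)
  fail <- rep(NA_character_, m)

  if (m > 0) {
    if (criteria$biallelic_only) {
      bad <- grepl(",", x$variants$alt, fixed = TRUE)
      fail[is.na(fail) & bad] <- "biallelic"
    }
    miss <- colMeans(is.na(dos))
    fail[is.na(fail) & miss > criteria$site_missing_max] <- "missingness"

    n_called <- colSums(!is.na(dos))
    alt <- colSums(dos, na.rm = TRUE)
    f <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
    maf <- pmin(f, 1 - f)
    fail[is.na(fail) & (!is.na(maf) & maf < criteria$maf_min)] <- "maf"

    if (criteria$hwe_p_min > 0) {
      todo <- which(is.na(fail) & n_called > 0)
      if (length(todo)) {
        pvals <- vapply(todo, function(j) {
          col <- dos[, j]
          if (hwe_mode == "pooled") {
            .hwe_p_from_col(col)
          } else {
            min(vapply(split(col, x$samples$population), .hwe_p_from_col,
                       numeric(1)), na.rm = TRUE)
          }
        }, numeric(1))
        fail[todo[pvals <= criteria$hwe_p_min]] <- "hwe"
      }
    }
  }

  keep <- is.na(fail)
  report <- tibble::tibble(
    criterion = c("biallelic", "missingness", "maf", "hwe"),
    removed = unname(vapply(c("biallelic", "missingness", "maf", "hwe"),
                            function(k) sum(fail == k, na.rm = TRUE),
                            numeric(1)))
  )
  attr(report, "sites_in") <- m
  attr(report, "sites_out") <- sum(keep)
  list(table = subset_variants(x, keep), report = report)
}

.hwe_p_from_col <- function(col) {
  n0 <- sum(col == 0, na.rm = TRUE)
  n1 <- sum(col == 1, na.rm = TRUE)
  n2 <- sum(col == 2, na.rm = TRUE)
  if (n0 + n1 + n2 == 0) return(1)
  hwe_exact_test(n0, n1, n2)
}

#' Filter samples by genotype missing rate
#'
#' Removes samples whose missing fraction (over the table's current variants,
#' i.e. post site filtering when called in the standard order) exceeds the
#' threshold.
#'
#' @param x a `geno_table`
#' @param sample_missing_max maximum per-sample missing fraction (default 0.10)
#' @return `list(table, report)`; errors if no sample survives.
#' @export
filter_samples <- function(x, sample_missing_max = 0.10) {
  miss <- if (n_variants(x) > 0) rowMeans(is.na(x$dosage)) else rep(0, n_samples(x))
  keep <- miss <= sample_missing_max
  if (!any(keep)) abort("sample filter removed every sample (empty cohort)")
  report <- tibble::tibble(criterion = "sample_missingness", removed = sum(!keep))
  attr(report, "samples_in") <- n_samples(x)
  attr(report, "samples_out") <- sum(keep)
  list(table = subset_samples(x, x$samples$sample_id[keep]), report = report)
}

#' Full QC cascade
#'
#' The two-regime filter order used throughout the package: (1) site filters
#' (biallelic, missing <= `site_missing_max`, MAF, HWE); (2) sample filter
#' (missing <= `sample_missing_max`); (3) a second site pass at the stricter
#' `second_site_missing_max`, mirroring the common detection-then-conversion
#' workflow (missing <= 0.20 at SNP detection, <= 0.05 at format
#' conversion). The second pass re-applies the MAF and HWE gates too, since
#' the sample filter in between can change per-site statistics; this makes
#' the whole cascade idempotent.
#'
#' @param x a `geno_table`
#' @param maf_min,site_missing_max,hwe_p_min passed to [site_filter_criteria()]
#' @param sample_missing_max passed to [filter_samples()]
#' @param second_site_missing_max site missing-rate cap of the second pass
#' @param hwe_mode passed to [filter_sites()]
#' @return `list(table, reports = list(sites, samples, sites2))`.
#' @export
qc_filter <- function(x, maf_min = 0.05, site_missing_max = 0.20,
                      hwe_p_min = 1e-6, sample_missing_max = 0.10,
                      second_site_missing_max = 0.05,
                      hwe_mode = c("pooled", "per_population")) {
  hwe_mode <- match.arg(hwe_mode)
  s1 <- filter_sites(x, site_filter_criteria(maf_min, site_missing_max,
                                             hwe_p_min), hwe_mode)
  s2 <- filter_samples(s1$table, sample_missing_max)
  s3 <- filter_sites(
    s2$table,
    site_filter_criteria(maf_min = maf_min,
                         site_missing_max = second_site_missing_max,
                         hwe_p_min = hwe_p_min),
    hwe_mode
  )
  list(table = s3$table,
       reports = list(sites = s1$report, samples = s2$report, sites2 = s3$report))
}
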