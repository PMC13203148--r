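#' Genotype table: samples by biallelic variants
#'
#' The central container of the package: a set of biallelic SNPs with 1-based
#' coordinates, a sample sheet (population, cohort, parity), and a dosage
#' matrix (samples in rows, variants in columns) coding the number of copies
#' of the alternate allele as 0/1/2 with `NA` for missing genotypes.
#'
#' Variants are sorted by chromosome (order of first appearance) and strictly
#' increasing position within a chromosome; duplicate positions on one
#' chromosome are rejected. Ploidy is fixed at two: the study organisms are
#' diploid cattle.
#'
#' @param variants data frame with columns `chrom` (character), `pos`
#'   (1-based bp, numeric), `ref`, `alt` (single alleles, `ref != alt`) and
#'   optionally `id`.
#' @param samples data frame with columns `sample_id` (unique), `population`,
#'   `cohort` (one of `"twin"`, `"control"`, `"none"`) and `parity`
#'   (non-negative integer; required for `cohort == "control"`).
#' @param dosage numeric matrix, `nrow(samples)` x `nrow(variants)`, entries
#'   in `{0, 1, 2, NA}`.
#' @return An object of class `geno_table`.
#' @export
geno_table <- function(variants, samples, dosage) {
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  req_v <- c("chrom", "pos", "ref", "alt")
  if (!all(req_v %in% names(variants))) {
    abort(paste0("variants must have columns: ", paste(req_v, collapse = ", ")))
  }
  if (!"id" %in% names(variants)) variants$id <- NA_character_
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.numeric(variants$pos)
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1)) abort("variant positions must be >= 1")
    if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
    if (any(grepl(",", variants$alt, fixed = TRUE))) {
      abort("multi-allelic variants are not allowed in a geno_table")
    }
  }
  if (!"sample_id" %in% names(samples)) abort("samples must have a sample_id column")
  if (anyDuplicated(samples$sample_id)) abort("sample_id values must be unique")
  if (!"population" %in% names(samples)) samples$population <- NA_character_
  if (!"cohort" %in% names(samples)) samples$cohort <- "none"
  if (!"parity" %in% names(samples)) samples$parity <- NA_real_
  bad_cohort <- setdiff(unique(samples$cohort), c("twin", "control", "none"))
  if (length(bad_cohort)) {
    abort(paste0("cohort must be one of twin/control/none, got: ",
                 paste(bad_cohort, collapse = ", ")))
  }
  ctl <- samples$cohort == "control"
  if (any(ctl & (is.na(samples$parity) | samples$parity < 0))) {
    abort("control-cohort samples must carry a recorded non-negative parity")
  }

  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(variants)) {
    abort(sprintf(
      "dosage must be %d samples x %d variants, got %d x %d",
      nrow(samples), nrow(variants), nrow(dosage), ncol(dosage)
    ))
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    abort("dosage entries must be 0, 1, 2 or NA")
  }

  if (nrow(variants) > 0) {
    chrom_lev <- unique(variants$chrom)
    ord <- order(match(variants$chrom, chrom_lev), variants$pos)
    variants <- variants[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
    dup <- unlist(tapply(variants$pos, factor(variants$chrom, chrom_lev),
                         function(p) duplicated(p)), use.names = FALSE)
    if (any(dup)) abort("positions within a chromosome must be strictly increasing")
  }
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- NULL

  structure(
    list(variants = variants, samples = samples, dosage = dosage),
    class = "geno_table"
  )
}

#' @export
print.geno_table <- function(x, ...) {
  cat(sprintf(
    "<geno_table> %d samples x %d variants on %d chromosome(s)\n",
    n_samples(x), n_variants(x), length(unique(x$variants$chrom))
  ))
  miss <- if (length(x$dosage)) mean(is.na(x$dosage)) else 0
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  coh <- table(x$samples$cohort)
  cat("  cohorts:", paste(names(coh), coh, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of samples / variants in a genotype table
#' @param x a `geno_table`
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a genotype table
#'
#' @param x a `geno_table`
#' @param sample_ids character vector of sample ids to keep (order preserved
#'   as given).
#' @param variant_idx integer or logical index into the variant list.
#' @return a `geno_table`.
#' @export
subset_samples <- function(x, sample_ids) {
  idx <- match(sample_ids, x$samples$sample_id)
  if (anyNA(idx)) {
    abort(paste0("unknown sample ids: ",
                 paste(sample_ids[is.na(idx)], collapse = ", ")))
  }
  geno_table(x$variants, x$samples[idx, , drop = FALSE],
             x$dosage[idx, , drop = FALSE])
}

#' @rdname subset_samples
#' @export
subset_variants <- function(x, variant_idx) {
  geno_table(x$variants[variant_idx, , drop = FALSE], x$samples,
             x$dosage[, variant_idx, drop = FALSE])
}

#' Sample ids belonging to a cohort
#' @param x a `geno_table`
#' @param cohort `"twin"`, `"control"` or `"none"`
#' @return character vector of sample ids.
#' @export
cohort_ids <- function(x, cohort) {
  x$samples$sample_id[x$samples$cohort == cohort]
}

# internal: resolve a sample-id vector to row indices, with checks
.sample_rows <- function(x, ids, what = "group") {
  if (is.null(ids)) abort(paste0(what, " sample ids must be supplied"))
  idx <- match(ids, x$samples$sample_id)
  if (anyNA(idx)) abort(paste0("unknown ", what, " sample ids"))
  if (length(idx) == 0) abort(paste0(what, " is empty"))
  idx
}
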