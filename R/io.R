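#' Read a VCF and sample sheet into a genotype table
#'
#' Reads a VCF v4.x with GT fields via vcfR and pairs it with a headered TSV
#' sample sheet (`sample_id`, `population`, `cohort`, `parity`). Dosage is the
#' count of alternate alleles; `./.` (or `.`) becomes `NA`. Phase separators
#' are ignored (`0|1` equals `0/1`). Multi-allelic records are skipped with a
#' count (the analyses are biallelic-only) or rejected, per `multiallelic`.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param sample_sheet path to the sample-sheet TSV covering all VCF samples.
#' @param multiallelic `"skip"` (default; skipped count in
#'   `attr(, "n_multiallelic_skipped")`) or `"error"`.
#' @return a [geno_table()].
#' @export
read_vcf <- function(path, sample_sheet, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  sheet <- read_sample_sheet(sample_sheet)

  fix_mat <- vcfR::getFIX(vcf)
  if (!is.matrix(fix_mat)) {   # single-record VCFs drop to a named vector
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  vcf_samples <- colnames(vcf@gt)[-1]
  missing_meta <- setdiff(vcf_samples, sheet$sample_id)
  if (length(missing_meta)) {
    abort(paste0("samples in VCF absent from sample sheet: ",
                 paste(missing_meta, collapse = ", ")))
  }
  sheet <- sheet[match(vcf_samples, sheet$sample_id), , drop = FALSE]

  if (n_rec == 0) {
    out <- geno_table(
      tibble::tibble(chrom = character(), pos = numeric(), id = character(),
                     ref = character(), alt = character()),
      sheet, matrix(numeric(), nrow = length(vcf_samples), ncol = 0)
    )
    attr(out, "n_multiallelic_skipped") <- 0L
    return(out)
  }

  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi) && multiallelic == "error") {
    abort(sprintf("%d multi-allelic or ALT-less record(s) present", sum(multi)))
  }

  if (!all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    abort("VCF records lack a GT FORMAT field")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  code <- gsub("|", "/", gt, fixed = TRUE)
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "./." = NA_real_, "." = NA_real_)
  dos <- lut[code]
  unknown <- is.na(dos) & !(code %in% c("./.", ".")) & !is.na(code)
  if (any(unknown)) {
    abort(paste0("unsupported GT value (non-diploid or non-biallelic): ",
                 paste(unique(code[unknown])[1:min(3, sum(unknown))],
                       collapse = ", ")))
  }
  dos <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))

  variants <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID),
    ref = fix$REF,
    alt = fix$ALT
  )
  out <- geno_table(variants, sheet, t(dos))
  attr(out, "n_multiallelic_skipped") <- sum(multi)
  out
}

#' Write a genotype table as a plain-text VCF v4.2
#'
#' Emits GT-only records; missing dosages become `./.`. Reading the file back
#' with [read_vcf()] reproduces the dosage matrix, coordinates and sample
#' order exactly.
#'
#' @param x a `geno_table`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_table"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=twinscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n_variants(x) > 0) {
    gt_str <- matrix("./.", nrow = nrow(x$dosage), ncol = ncol(x$dosage))
    ok <- !is.na(x$dosage)
    gt_str[ok] <- c("0/0", "0/1", "1/1")[x$dosage[ok] + 1]
    body <- paste(
      x$variants$chrom,
      format(x$variants$pos, scientific = FALSE, trim = TRUE),
      ifelse(is.na(x$variants$id), ".", x$variants$id),
      x$variants$ref, x$variants$alt, ".", ".", ".", "GT",
      apply(gt_str, 2, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}

#' Read the sample sheet
#'
#' Headered TSV with columns `sample_id`, `population`, `cohort`
#' (twin/control/none) and `parity`.
#'
#' @param path TSV path
#' @return tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    population = readr::col_character(),
    cohort = readr::col_character(),
    parity = readr::col_double()
  ))
  req <- c("sample_id", "population", "cohort", "parity")
  if (!all(req %in% names(sheet))) {
    abort(paste0("sample sheet must have columns: ", paste(req, collapse = ", ")))
  }
  sheet
}

#' Write the sample sheet of a genotype table
#' @param x a `geno_table`
#' @param path TSV path
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x$samples, path)
  invisible(path)
}

#' Read a gene model from BED4/BED6 or GFF3
#'
#' Coordinates are normalized to 1-based inclusive internally: BED's 0-based
#' half-open intervals are shifted at the boundary, so the BED line
#' `1  999  2000  GENEX` and a GFF3 `gene` feature at 1000..2000 yield the
#' same entry. Parsing goes through rtracklayer; for GFF3 only `gene`-type
#' features are kept and the name is taken from `Name`, `ID` or `gene_id`.
#' Unstranded features are treated as forward-strand.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`
#' @return tibble with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_model <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff3\\.gz)$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if ("type" %in% names(md)) gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
    nm <- NULL
    for (col in c("Name", "ID", "gene_id", "gene_name")) {
      if (col %in% names(md) && !all(is.na(md[[col]]))) { nm <- as.character(md[[col]]); break }
    }
    if (is.null(nm)) abort("GFF3 gene features carry no usable name attribute")
  } else {
    if (!"name" %in% names(md)) abort("BED gene model requires a name column (BED4+)")
    nm <- as.character(md$name)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  out <- tibble::tibble(
    gene = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(BiocGenerics::start(gr)),
    end = as.numeric(BiocGenerics::end(gr)),
    strand = strand
  )
  if (any(out$end < out$start)) abort("gene model has end < start after normalization")
  if (anyDuplicated(out$gene)) abort("gene names must be unique")
  out
}

#' Write a region set as BED (0-based half-open)
#' @param regions a region tibble (`chrom`, `start`, `end`, 1-based inclusive)
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- paste(regions$chrom,
                 format(regions$start - 1, scientific = FALSE, trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
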