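#' Alternate-allele frequencies in a sample group
#'
#' Per variant: alternate-allele count over the group's non-missing alleles.
#' Variants with no called genotype in the group have `freq = NA` (flagged
#' by `n_alleles = 0`).
#'
#' @param x a `geno_table`
#' @param samples sample ids of the group (default: all samples)
#' @return tibble: variant columns + `n_alleles`, `n_alt`, `freq`.
#' @export
allele_freq <- function(x, samples = NULL) {
  samples <- samples %||% x$samples$sample_id
  ig <- .sample_rows(x, samples, "group")
  G <- x$dosage[ig, , drop = FALSE]
  n <- 2 * colSums(!is.na(G))
  alt <- colSums(G, na.rm = TRUE)
  dplyr::bind_cols(
    x$variants,
    tibble::tibble(n_alleles = n, n_alt = alt,
                   freq = ifelse(n > 0, alt / n, NA_real_))
  )
}

#' Allele frequencies per control population
#'
#' One [allele_freq()] table per population label, stacked long. By default
#' only samples outside the twin/control cohorts count as population
#' members, matching the study design where the cohorts are drawn out of
#' the source population before the population-level frequency comparison.
#'
#' @param x a `geno_table`
#' @param populations population labels to include (default: all labels)
#' @param exclude_cohorts cohorts whose members are excluded from their
#'   population (default `c("twin", "control")`)
#' @return long tibble with a `population` column.
#' @export
population_freqs <- function(x, populations = NULL,
                             exclude_cohorts = c("twin", "control")) {
  populations <- populations %||% unique(x$samples$population)
  if (length(populations) == 0) abort("empty population map")
  purrr::map_dfr(populations, function(popn) {
    ids <- x$samples$sample_id[x$samples$population == popn &
                                 !(x$samples$cohort %in% exclude_cohorts)]
    if (length(ids) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(population = popn), allele_freq(x, ids))
  })
}

#' Variants rare in every control population
#'
#' Keeps variants whose alternate-allele frequency is strictly below
#' `threshold` in *every* population where the frequency is defined;
#' variants undefined in all populations are excluded.
#'
#' @param pop_freqs long frequency tibble from [population_freqs()]
#' @param threshold rarity cutoff (strict `<`; default 0.05)
#' @return tibble of variant keys: `chrom`, `pos`.
#' @export
rare_in_all_controls <- function(pop_freqs, threshold = 0.05) {
  if (nrow(pop_freqs) == 0) abort("empty population frequency table")
  pop_freqs |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      rare = any(!is.na(.data$freq)) && all(.data$freq[!is.na(.data$freq)] < threshold),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$rare) |>
    dplyr::select("chrom", "pos")
}

#' Screen candidate SNPs in the twin cohort
#'
#' A pure conjunction of four gates: the variant (i) lies in the selected
#' regions, (ii) is rare in all control populations (`rare` key set),
#' (iii) has twin-cohort minor allele count `>= mac`, and (iv) twin-cohort
#' genotype missing rate `<= max_missing`. `mac = 10` corresponds to a
#' minimum attainable twin frequency of 10/114 = 0.0877193 at 57 fully
#' genotyped diploids. `max_missing` is a missing *rate* (0.1 means at
#' least 90 percent of twin genotypes called).
#'
#' @param x a `geno_table`
#' @param regions region tibble from the sweep scan
#' @param rare variant-key tibble from [rare_in_all_controls()]
#' @param twin twin sample ids (default: the `twin` cohort)
#' @param mac minimum twin minor-allele count (default 10)
#' @param max_missing maximum twin genotype missing rate (default 0.1)
#' @return tibble of candidates ordered by coordinate: variant columns +
#'   `twin_freq`, `twin_minor_count`, `twin_missing_rate`; gate counts in
#'   `attr(, "gate_counts")`.
#' @export
screen_candidates <- function(x, regions, rare, twin = NULL, mac = 10,
                              max_missing = 0.1) {
  twin <- twin %||% cohort_ids(x, "twin")
  ig <- .sample_rows(x, twin, "twin")
  if (nrow(regions) == 0) {
    warn("empty region set: no candidates")
  }
  fr <- allele_freq(x, twin)
  minor <- pmin(fr$n_alt, fr$n_alleles - fr$n_alt)
  miss_rate <- 1 - fr$n_alleles / (2 * length(ig))

  g_region <- in_regions(x$variants, regions)
  g_rare <- paste(fr$chrom, fr$pos) %in% paste(rare$chrom, rare$pos)
  g_mac <- !is.na(fr$freq) & minor >= mac
  g_miss <- miss_rate <= max_missing
  keep <- g_region & g_rare & g_mac & g_miss

  out <- fr[keep, , drop = FALSE] |>
    dplyr::mutate(twin_freq = .data$freq,
                  twin_minor_count = minor[keep],
                  twin_missing_rate = miss_rate[keep]) |>
    dplyr::select("chrom", "pos", "id", "ref", "alt", "twin_freq",
                  "twin_minor_count", "twin_missing_rate")
  attr(out, "gate_counts") <- c(
    total = nrow(fr), in_regions = sum(g_region),
    in_regions_rare = sum(g_region & g_rare),
    in_regions_rare_mac = sum(g_region & g_rare & g_mac),
    candidates = sum(keep)
  )
  out
}

#' Attach control-population frequency ranges to candidates
#'
#' Adds the min–max alternate-allele frequency across control populations,
#' in the `low~high` display form used for reporting candidate loci.
#'
#' @param candidates output of [screen_candidates()]
#' @param pop_freqs output of [population_freqs()]
#' @return the candidate tibble with `control_freq_min`, `control_freq_max`
#'   and `control_freq_range` columns.
#' @export
candidate_report <- function(candidates, pop_freqs) {
  rng <- pop_freqs |>
    dplyr::filter(!is.na(.data$freq)) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(control_freq_min = min(.data$freq),
                     control_freq_max = max(.data$freq), .groups = "drop")
  candidates |>
    dplyr::left_join(rng, by = c("chrom", "pos")) |>
    dplyr::mutate(control_freq_range = paste0(
      signif(.data$control_freq_min, 6), "~", signif(.data$control_freq_max, 6)
    ))
}

#' Annotate SNPs against a gene model
#'
#' Classifies each SNP by its gene context: overlapping a gene span is
#' `genic` (a BED4 model carries no exon structure, so exonic/intronic are
#' collapsed); within `flank_bp` of a gene it is `upstream`/`downstream`
#' relative to the gene's strand; otherwise the nearest gene within
#' `near_bp` is reported as `intergenic-nearest` with its distance. SNPs on
#' chromosomes absent from the model, or farther than `near_bp` from any
#' gene, are `unannotated` (counted in `attr(, "n_unannotated")`).
#'
#' @param snps tibble with `chrom`, `pos` (e.g. [screen_candidates()] output)
#' @param model gene-model tibble from [read_gene_model()]
#' @param near_bp nearest-gene search radius (default 100 kb)
#' @param flank_bp strand-aware upstream/downstream flank (default 1 kb)
#' @return per-SNP tibble: input columns + `gene`, `relation`,
#'   `distance_bp`.
#' @export
annotate_snps <- function(snps, model, near_bp = 100000, flank_bp = 1000) {
  if (nrow(model) == 0) abort("empty gene model")
  if (nrow(snps) == 0) {
    return(dplyr::mutate(snps, gene = character(0), relation = character(0),
                         distance_bp = numeric(0)))
  }
  gs <- .to_granges(snps$chrom, snps$pos, snps$pos)
  gg <- GenomicRanges::GRanges(
    model$chrom, IRanges::IRanges(model$start, model$end),
    strand = model$strand
  )
  gene <- rep(NA_character_, nrow(snps))
  relation <- rep("unannotated", nrow(snps))
  distance <- rep(NA_real_, nrow(snps))

  ov <- suppressWarnings(GenomicRanges::findOverlaps(gs, gg, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(ov)
  first <- !duplicated(qh)
  gene[qh[first]] <- model$gene[S4Vectors::subjectHits(ov)[first]]
  relation[qh[first]] <- "genic"
  distance[qh[first]] <- 0

  left <- which(relation == "unannotated")
  if (length(left)) {
    nr <- suppressWarnings(
      GenomicRanges::distanceToNearest(gs[left], gg, ignore.strand = TRUE)
    )
    qi <- left[S4Vectors::queryHits(nr)]
    gi <- S4Vectors::subjectHits(nr)
    # distance as base-pair offset to the gene boundary (start - pos or
    # pos - end), one more than the inter-range gap
    before <- snps$pos[qi] < model$start[gi]
    d <- ifelse(before, model$start[gi] - snps$pos[qi],
                snps$pos[qi] - model$end[gi])
    ok <- d <= near_bp
    qi <- qi[ok]; gi <- gi[ok]; d <- d[ok]; before <- before[ok]
    if (length(qi)) {
      plus <- model$strand[gi] == "+"
      rel <- ifelse(d <= flank_bp,
                    ifelse(before == plus, "upstream", "downstream"),
                    "intergenic-nearest")
      gene[qi] <- model$gene[gi]
      relation[qi] <- rel
      distance[qi] <- d
    }
  }
  out <- dplyr::mutate(snps, gene = gene, relation = relation,
                       distance_bp = distance)
  attr(out, "n_unannotated") <- sum(relation == "unannotated")
  out
}

#' Aggregate annotated SNPs to candidate genes
#'
#' Deduplicates genes, aggregating their supporting SNPs; every reported
#' gene has at least one supporting SNP.
#'
#' @param annotated output of [annotate_snps()]
#' @return tibble: `gene`, `chrom`, `n_snps`, `relations`,
#'   `min_distance_bp`, `snps` (comma-separated `chrom:pos`).
#' @export
candidate_genes <- function(annotated) {
  annotated |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::group_by(.data$gene, .data$chrom) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      relations = paste(sort(unique(.data$relation)), collapse = ","),
      min_distance_bp = min(.data$distance_bp),
      snps = paste0(.data$chrom, ":",
                    format(.data$pos, scientific = FALSE, trim = TRUE),
                    collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$min_distance_bp)
}
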