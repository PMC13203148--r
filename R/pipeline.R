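#' Assemble a pipeline configuration
#'
#' Every parameter carries the pipeline's standard default; unknown keys are
#' rejected. Inputs may be given as file paths (`vcf`, `sample_sheet`,
#' `gene_model_path`) or as in-memory objects (`geno`, `gene_model`).
#'
#' @param ... named overrides of the defaults listed below.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    vcf = NULL, sample_sheet = NULL, gene_model_path = NULL,
    geno = NULL, gene_model = NULL,
    out_dir = NULL,
    maf_min = 0.05, site_missing_max = 0.20, hwe_p_min = 1e-6,
    sample_missing_max = 0.10, second_site_missing_max = 0.05,
    window_size_bp = 50000, window_step_bp = 20000,
    quantile = 0.95, combine = "union",
    rare_threshold = 0.05, mac = 10, max_missing = 0.1,
    near_bp = 100000, flank_bp = 1000,
    control_populations = NULL, chrom_lengths = NULL,
    genome_length_bp = NULL,
    summaries = TRUE, ld_max_dist_bp = 500000, ld_bin_width_bp = 1000,
    pca_k = 10
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown run_config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$combine %in% c("union", "intersection")) {
    abort("combine must be 'union' or 'intersection'")
  }
  structure(cfg, class = "run_config")
}

#' Run the full screening pipeline
#'
#' Orchestrates QC, relatedness/inbreeding/LD summaries, the joint
#' Fst / diversity-ratio sweep scan, the cross-population rare-allele
#' screen and gene annotation from one configuration. Two QC regimes feed
#' the stages: the full cascade (including the MAF gate) for the
#' structure summaries, and a rare-preserving cascade (missingness + HWE
#' only) for the sweep scan and screen — a pooled MAF floor would delete
#' precisely the rare twin-enriched alleles the screen targets.
#'
#' The run is deterministic: identical configuration and inputs give
#' byte-identical outputs. When `out_dir` is set, stage tables are written
#' as TSV/BED plus a JSON run report, and any stage failure removes the
#' partial outputs before rethrowing with the stage name.
#'
#' @param config a [run_config()]
#' @return the run report (list): realized thresholds, gate counts, result
#'   tibbles (`candidates`, `genes`, `froh`, ...), and the file manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) {
    config <- do.call(run_config, as.list(config))
  }
  manifest <- character(0)
  stage <- "input"
  emit <- function(obj, name, writer) {
    if (is.null(config$out_dir)) return(invisible(NULL))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    manifest <<- c(manifest, path)
  }
  tsv <- function(obj, path) readr::write_tsv(obj, path)

  withCallingHandlers(
    tryCatch({
      geno <- config$geno %||% read_vcf(config$vcf, config$sample_sheet)
      gene_model <- config$gene_model %||%
        (if (!is.null(config$gene_model_path))
          read_gene_model(config$gene_model_path) else NULL)

      stage <- "qc"
      qc_full <- qc_filter(geno, maf_min = config$maf_min,
                           site_missing_max = config$site_missing_max,
                           hwe_p_min = config$hwe_p_min,
                           sample_missing_max = config$sample_missing_max,
                           second_site_missing_max = config$second_site_missing_max)
      qc_rare <- qc_filter(geno, maf_min = 0,
                           site_missing_max = config$site_missing_max,
                           hwe_p_min = config$hwe_p_min,
                           sample_missing_max = config$sample_missing_max,
                           second_site_missing_max = config$second_site_missing_max)
      g_struct <- qc_full$table
      g_scan <- qc_rare$table
      emit(dplyr::bind_rows(full = qc_full$reports$sites,
                            rare_preserving = qc_rare$reports$sites,
                            .id = "regime"), "filter_report.tsv", tsv)

      summaries <- NULL
      if (isTRUE(config$summaries)) {
        stage <- "kinship"
        ibs <- ibs_distance_matrix(g_struct)
        pca <- geno_pca(g_struct, k = min(config$pca_k,
                                          n_samples(g_struct) - 1))
        emit(tidy(ibs), "ibs_distance.tsv", tsv)
        emit(tidy(pca), "pca_scores.tsv", tsv)

        stage <- "roh"
        segs <- detect_roh(g_struct)
        gl <- config$genome_length_bp %||%
          sum(.chrom_lengths(g_struct, config$chrom_lengths))
        fr <- froh(segs, gl, sample_ids = g_struct$samples$sample_id)
        emit(segs, "roh_segments.tsv", tsv)
        emit(fr, "froh.tsv", tsv)

        stage <- "ld"
        ld <- ld_decay_by_population(g_struct,
                                     max_dist_bp = config$ld_max_dist_bp,
                                     bin_width_bp = config$ld_bin_width_bp)
        emit(ld, "ld_decay.tsv", tsv)
        summaries <- list(ibs = ibs, pca = pca, roh = segs, froh = fr,
                          ld_decay = ld)
      }

      stage <- "sweepscan"
      scan <- sweep_scan(g_scan, size_bp = config$window_size_bp,
                         step_bp = config$window_step_bp,
                         quantile = config$quantile,
                         chrom_lengths = config$chrom_lengths)
      regions <- scan$regions[[config$combine]]
      emit(tidy(scan), "window_stats.tsv", tsv)
      emit(regions, "regions.bed", write_regions_bed)

      stage <- "twinscreen"
      pf <- population_freqs(g_scan, config$control_populations)
      rare <- rare_in_all_controls(pf, config$rare_threshold)
      cands <- screen_candidates(g_scan, regions, rare,
                                 mac = config$mac,
                                 max_missing = config$max_missing)
      cands <- candidate_report(cands, pf)
      emit(cands, "candidate_snps.tsv", tsv)

      genes <- NULL
      if (!is.null(gene_model) && nrow(cands)) {
        stage <- "annotation"
        ann <- annotate_snps(cands, gene_model, near_bp = config$near_bp,
                             flank_bp = config$flank_bp)
        genes <- candidate_genes(ann)
        emit(ann, "candidate_snps_annotated.tsv", tsv)
        emit(genes, "candidate_genes.tsv", tsv)
      }

      stage <- "report"
      gates <- attr(cands, "gate_counts") %||%
        c(total = NA, in_regions = NA, in_regions_rare = NA,
          in_regions_rare_mac = NA, candidates = nrow(cands))
      report <- list(
        package_version = as.character(utils::packageVersion("twinscan")),
        thresholds = as.list(scan$thresholds),
        counts = c(
          list(sites_in = n_variants(geno),
               sites_structural_qc = n_variants(g_struct),
               sites_scan_qc = n_variants(g_scan),
               samples = n_samples(g_scan)),
          scan$counts,
          as.list(gates),
          list(candidate_snps = nrow(cands),
               candidate_genes = if (is.null(genes)) NA_integer_
               else nrow(genes))
        ),
        combine = config$combine,
        regions = regions,
        windows = scan$windows,
        scan = scan,
        candidates = cands,
        genes = genes,
        summaries = summaries,
        manifest = manifest
      )
      if (!is.null(config$out_dir)) {
        path <- file.path(config$out_dir, "report.json")
        jsonlite::write_json(
          list(package_version = report$package_version,
               thresholds = report$thresholds, counts = report$counts,
               combine = report$combine,
               manifest = basename(manifest)),
          path, auto_unbox = TRUE, digits = NA
        )
        report$manifest <- c(manifest, path)
      }
      report
    }, error = function(e) {
      if (length(manifest)) unlink(manifest)
      abort(paste0("pipeline failed at stage '", stage, "': ",
                   conditionMessage(e)))
    }),
    warning = function(w) invokeRestart("muffleWarning")
  )
}
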