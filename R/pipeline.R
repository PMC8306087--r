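#' Run the end-to-end mapping pipeline
#'
#' Orchestrates the full analysis from one configuration: data
#' acquisition (gene-drop simulation or VCF + sample sheet + annotation
#' table), genotype QC, inbreeding coefficients, PCA, GRM, the LMM
#' association scan with Bonferroni threshold, ROH detection with the
#' case/control autozygosity contrast and candidate-region delineation,
#' the recessive variant-filtering funnel, and genotype-by-status
#' statistics for the retained variants.  Per-stage tables are written
#' to `output_dir` together with a JSON run report; the run is
#' deterministic under `seed`.
#'
#' @param config nested list or path to a YAML file.  Recognized blocks:
#'   `simulate` (arguments of [sim_config()]) or `inputs`
#'   (`vcf`, `sample_sheet`, `annotation` paths); `qc`, `roh`, `scan`,
#'   `filter`, `thresholds` (`alpha`, `case_min`, `control_max`,
#'   `pad_bp`); required top-level `output_dir` and `seed`.
#' @return the run report, invisibly (list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("output_dir", "seed"))
    if (is.null(config[[field]]))
      stop("config validation: missing required field \"", field, "\"")
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config validation: need a \"simulate\" or \"inputs\" block")
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  thr <- modifyList(list(alpha = 0.05, case_min = 0.7, control_max = 0.2,
                         pad_bp = 0), config$thresholds %||% list())

  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config,
                   modifyList(config$simulate, list(seed = config$seed)))
    sim <- simulate_study(cfg)
    gm <- sim$wgs
    annotation <- sim$annotation
  } else {
    set.seed(config$seed)
    gm <- read_vcf(config$inputs$vcf, config$inputs$sample_sheet)
    annotation <- read_annotation(config$inputs$annotation)
    sim <- NULL
  }

  qc <- do.call(qc_filter, c(list(gm), config$qc %||% list()))
  gm_qc <- qc$gm
  f_tab <- inbreeding_f(gm_qc)
  utils::write.table(f_tab, file.path(out, "inbreeding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pcs <- pca_scores(gm_qc, k = 2)
  utils::write.table(data.frame(sample_id = rownames(pcs), pcs),
                     file.path(out, "pca.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grm <- grm_standardized(gm_qc)

  scan <- do.call(lmm_scan, c(list(gm_qc, grm = grm),
                              config$scan %||% list()))
  scan$results$bonferroni <- bonferroni_threshold(
    thr$alpha, nrow(scan$results))
  utils::write.table(scan$results, file.path(out, "gwas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rp <- do.call(roh_params, config$roh %||% list())
  segments <- call_roh(gm_qc, rp)
  utils::write.table(segments, file.path(out, "roh_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  track <- autozygosity_track(segments, gm_qc)
  utils::write.table(track, file.path(out, "autozygosity_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  regions <- contrast_candidate_regions(
    track, case_min = thr$case_min, control_max = thr$control_max,
    pad_bp = thr$pad_bp, merge_gap_bp = rp$max_gap_bp)
  if (nrow(regions)) write_regions_bed(regions,
                                       file.path(out, "regions.bed"))

  funnel <- NULL; retained <- NULL; risk <- list()
  if (nrow(regions)) {
    # the mapping candidate is the region harbouring the strongest
    # association signal (as in combining the GWAS and ROH evidence);
    # fall back to the widest region if no region contains the top SNP
    top <- scan$results[which.min(scan$results$p), ]
    in_r <- regions$chrom == top$chrom & regions$start_bp <= top$pos &
      regions$end_bp >= top$pos
    r <- if (any(in_r)) regions[which(in_r)[1], ] else
      regions[which.max(regions$end_bp - regions$start_bp), ]
    fcfg <- config$filter %||% list()
    funnel_res <- do.call(run_funnel, c(
      list(annotation = annotation, gm = gm, region = r), fcfg))
    funnel <- as.list(funnel_res$funnel)
    retained <- funnel_res$retained
    utils::write.table(retained, file.path(out, "retained_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_len(nrow(retained))) {
      key <- paste0(retained$chrom[i], ":", retained$pos[i])
      j <- match(paste(retained$chrom[i], retained$pos[i],
                       retained$ref[i], retained$alt[i], sep = ":"),
                 variant_key(gm))
      tab <- genotype_status_table(gm$dosage[, j], gm$samples$status)
      rr <- try(relative_risk(tab, "AA", "RR"), silent = TRUE)
      risk[[key]] <- list(
        table = unclass(tab),
        rr_hom = if (inherits(rr, "try-error")) NA else rr$rr,
        fisher_p = fisher_exact(tab[rowSums(tab) > 0, , drop = FALSE]))
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("rohmap")),
    seed = config$seed,
    parameters = list(qc = config$qc, roh = config$roh,
                      scan = config$scan, thresholds = thr,
                      filter = config$filter),
    qc_report = qc$report,
    mean_inbreeding_f = mean(f_tab$F, na.rm = TRUE),
    lambda = scan$lambda,
    bonferroni_minus_log10 = bonferroni_threshold(thr$alpha,
                                                  nrow(scan$results)),
    top_associations = utils::head(
      scan$results[order(scan$results$p),
                   c("chrom", "pos", "beta", "p")], 5),
    candidate_regions = regions,
    funnel = funnel,
    retained_variants = if (!is.null(retained) && nrow(retained))
      paste0(retained$chrom, ":", retained$pos) else character(0),
    risk = risk)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
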