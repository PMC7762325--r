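#' Per-sample metric table
#'
#' Runs the full per-sample metric stack — somatic filtering, SNV/indel
#' burden, wGII, CAER, copy-number amplitude, chromothripsis and
#' double-minute calling — and returns one row per sample.
#'
#' @param variants Cohort variant data frame (unfiltered; the VAF/depth
#'   filters are applied here).
#' @param segments Cohort segment data frame.
#' @param sv Cohort SV data frame (may be empty or NULL).
#' @param genome A `genome_model`.
#' @param oncogenes Oncogene annotation.
#' @param samples Sample ids to report; default the union of ids seen in
#'   `variants` and `segments`.
#' @param log2_threshold Alteration cutoff on |log2 ratio|. Default 0.25.
#' @param drop_acrocentric_p CAER arm-inventory flag.
#' @param ct_window_mb,ct_min_switches,ct_lr_threshold Chromothripsis caller
#'   settings.
#' @param dm_min_ratio,dm_merge_gap,dm_sv_tolerance,dm_min_length
#'   Double-minute caller settings.
#' @return Data frame: `sample`, `n_snv_pass`, `n_indel_pass`, `snv_burden`,
#'   `indel_burden`, `wgii`, `caer`, `cn_amplitude`, `ct_present`,
#'   `dm_present`, `dm_rule`, `dm_oncogenes`.
#' @export
compute_sample_metrics <- function(variants, segments, sv = NULL, genome,
                                   oncogenes = toy_oncogenes(),
                                   samples = NULL, log2_threshold = 0.25,
                                   drop_acrocentric_p = FALSE,
                                   ct_window_mb = 10, ct_min_switches = 10,
                                   ct_lr_threshold = 8, dm_min_ratio = 5,
                                   dm_merge_gap = 1e6, dm_sv_tolerance = 1e4,
                                   dm_min_length = 1e6) {
  if (is.null(samples))
    samples <- sort(unique(c(variants$sample, segments$sample)))
  pass <- filter_somatic(variants)
  burdens <- compute_burdens(pass, genome)
  rows <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    svi <- if (is.null(sv)) NULL else sv[sv$sample == s, , drop = FALSE]
    w <- wgii(seg, genome, threshold = log2_threshold)
    ca <- caer(seg, genome, threshold = log2_threshold,
               drop_acrocentric_p = drop_acrocentric_p)
    amp <- build_amplicons(seg, oncogenes, svi, min_ratio = dm_min_ratio,
                           merge_gap = dm_merge_gap,
                           sv_tolerance = dm_sv_tolerance)
    dm <- call_dm(amp, min_length = dm_min_length)
    ct <- call_chromothripsis(seg, genome, window_mb = ct_window_mb,
                              min_switches = ct_min_switches,
                              lr_threshold = ct_lr_threshold,
                              threshold = log2_threshold)
    b <- burdens[burdens$sample == s, , drop = FALSE]
    data.frame(
      sample = s,
      n_snv_pass = if (nrow(b)) b$n_snv_pass else 0L,
      n_indel_pass = if (nrow(b)) b$n_indel_pass else 0L,
      snv_burden = if (nrow(b)) b$snv_burden else 0,
      indel_burden = if (nrow(b)) b$indel_burden else 0,
      wgii = w$wgii, caer = ca$caer, cn_amplitude = cn_amplitude(seg),
      ct_present = nrow(ct) > 0, dm_present = dm$is_dm, dm_rule = dm$rule,
      dm_oncogenes = paste(dm$oncogenes, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Collects input paths and every threshold of the analysis in one place.
#' NULL paths for `capture_bed`/`cytoband` fall back to the bundled toy
#' genome, and a NULL `oncogenes_bed` to the toy oncogene set.
#'
#' @param variants,segments,sv,sample_sheet,capture_bed,cytoband,
#'   oncogenes_bed,catalogs,signatures Input file paths (sv, catalogs,
#'   signatures optional).
#' @param out_dir Output directory.
#' @param seed Integer seed (recorded for provenance; the pipeline itself is
#'   deterministic).
#' @param vaf,t_depth,n_depth Somatic filter cutoffs (all exclusive).
#' @param log2_threshold Alteration cutoff.
#' @param dm_ratio,dm_length,dm_merge_gap,dm_sv_tolerance Double-minute
#'   settings.
#' @param ct_window_mb,ct_min_switches,ct_lr_threshold Chromothripsis
#'   settings.
#' @param signature_accept Signature acceptance fraction (inclusive).
#' @param alpha Significance level for the statistics stage.
#' @param drop_acrocentric_p CAER arm-inventory flag.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(variants, segments, sample_sheet, sv = NULL,
                            capture_bed = NULL, cytoband = NULL,
                            oncogenes_bed = NULL, catalogs = NULL,
                            signatures = NULL, out_dir = tempfile("run"),
                            seed = 17, vaf = 0.05, t_depth = 20,
                            n_depth = 10, log2_threshold = 0.25, dm_ratio = 5,
                            dm_length = 1e6, dm_merge_gap = 1e6,
                            dm_sv_tolerance = 1e4, ct_window_mb = 10,
                            ct_min_switches = 10, ct_lr_threshold = 8,
                            signature_accept = 0.10, alpha = 0.05,
                            drop_acrocentric_p = FALSE) {
  stopifnot(vaf > 0, t_depth > 0, n_depth > 0, log2_threshold > 0,
            dm_ratio > 0, dm_length > 0, signature_accept > 0, alpha > 0)
  structure(mget(names(formals()), envir = environment()),
            class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' simulate/read -> filter -> metrics -> event callers -> signature refit ->
#' subset classification -> cohort statistics. All stage outputs are written
#' under `config$out_dir` as TSV, plus a `report.yaml` embedding the resolved
#' configuration, the package version and the seed. Reruns with the same
#' configuration produce identical files.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with `metrics`, `subsets`, `exposures` (or
#'   NULL), `summary`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  genome <- stage("genome", {
    if (!is.null(config$cytoband) && !is.null(config$capture_bed))
      genome_from_cytoband(config$cytoband, config$capture_bed)
    else if (!is.null(config$capture_bed)) {
      g <- toy_genome()
      genome_model(g$chrom_names, g$chrom_lengths, g$centromere_pos,
                   read_capture_bed(config$capture_bed))
    } else toy_genome()
  })
  oncogenes <- stage("oncogenes", {
    if (is.null(config$oncogenes_bed)) toy_oncogenes() else
      read_oncogenes(config$oncogenes_bed)
  })
  variants <- stage("variants", read_variants(config$variants))
  segments <- stage("segments", read_segments(config$segments))
  sv <- stage("sv", if (is.null(config$sv)) NULL else read_sv(config$sv))
  sheet <- stage("sample_sheet", read_sample_sheet(config$sample_sheet))

  metrics <- stage("metrics", compute_sample_metrics(
    variants, segments, sv, genome, oncogenes,
    samples = sheet$analysis_id, log2_threshold = config$log2_threshold,
    drop_acrocentric_p = config$drop_acrocentric_p,
    ct_window_mb = config$ct_window_mb,
    ct_min_switches = config$ct_min_switches,
    ct_lr_threshold = config$ct_lr_threshold,
    dm_min_ratio = config$dm_ratio, dm_merge_gap = config$dm_merge_gap,
    dm_sv_tolerance = config$dm_sv_tolerance,
    dm_min_length = config$dm_length))

  subsets <- stage("classify", classify_subset(sheet))
  metrics$subset <- subsets$subset[match(metrics$sample,
                                         subsets$analysis_id)]
  metrics$primary_status <- sheet$primary_status[match(metrics$sample,
                                                       sheet$analysis_id)]
  metrics$age <- sheet$age[match(metrics$sample, sheet$analysis_id)]

  exposures <- stage("signatures", {
    if (is.null(config$catalogs) || is.null(config$signatures)) NULL else
      refit_cohort(read_catalogs(config$catalogs),
                   read_signature_matrix(config$signatures),
                   accept_min = config$signature_accept)
  })

  summary <- stage("stats", summarize_metrics(metrics, group_by = "subset"))
  comparisons <- stage("stats", {
    out <- list()
    for (m in c("snv_burden", "indel_burden", "wgii", "caer",
                "cn_amplitude")) {
      if (length(unique(metrics$subset)) == 2 &&
          min(table(metrics$subset)) >= 2) {
        cg <- compare_groups(metrics, m, "subset")
        out[[length(out) + 1]] <- data.frame(
          metric = m, grouping = "subset", p_value = cg$p_value,
          method = cg$method)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain(metrics, file.path(config$out_dir, "metrics.tsv"))
  write_tsv_plain(subsets, file.path(config$out_dir, "subset_calls.tsv"))
  write_tsv_plain(summary, file.path(config$out_dir, "summary.tsv"))
  if (!is.null(comparisons))
    write_tsv_plain(comparisons, file.path(config$out_dir,
                                           "comparisons.tsv"))
  if (!is.null(exposures))
    write_tsv_plain(exposures, file.path(config$out_dir, "exposures.tsv"))

  cfg_plain <- lapply(unclass(config), function(x)
    if (is.null(x)) NULL else unname(x))
  report <- list(
    package = "gliomaburden",
    version = as.character(utils::packageVersion("gliomaburden")),
    seed = config$seed,
    n_samples = nrow(metrics),
    config = cfg_plain)
  yaml::write_yaml(report, file.path(config$out_dir, "report.yaml"))
  invisible(list(metrics = metrics, subsets = subsets, exposures = exposures,
                 summary = summary, comparisons = comparisons,
                 report = report))
}
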