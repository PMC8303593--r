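# End-to-end study pipeline: phantom generation (or file ingestion) ->
# partition -> occupancy -> morphometry -> conversion -> report.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a phantom cohort) or `"files"`
#'   (read volumes and landmarks from disk via a manifest).
#' @param n_subjects cohort size in synthetic mode.
#' @param seed integer seed (required in synthetic mode).
#' @param distributions [cohort_distributions()] for synthetic mode.
#' @param base_params [phantom_params()] template for synthetic mode.
#' @param sites character vector of sites to evaluate.
#' @param partition_rule passed to [build_partition()].
#' @param occupancy_threshold visibility threshold (default 0.5).
#' @param stratify_by `"retention_label"` or `"none"`.
#' @param segmentation list of [segment_structure()] options.
#' @param alpha significance level for the Wilcoxon comparisons.
#' @param zero_handling zero handling for the signed-rank test.
#' @param manifest,landmarks file paths (files mode).
#' @param out_dir optional output directory for [write_report()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            n_subjects = 19L, seed = 1L,
                            distributions = cohort_distributions(),
                            base_params = phantom_params(),
                            sites = c("M3", "M2"),
                            partition_rule = "chord_thirds",
                            occupancy_threshold = 0.5,
                            stratify_by = "retention_label",
                            segmentation = list(),
                            alpha = 0.05, zero_handling = "drop",
                            manifest = NULL, landmarks = NULL,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop_parameter("alpha must lie in (0, 1)")
  if (mode == "synthetic" && (is.null(seed) || !is.finite(seed)))
    stop_parameter("synthetic mode requires a seed")
  if (mode == "files" && (is.null(manifest)))
    stop_parameter("files mode requires a manifest")
  structure(list(mode = mode, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), distributions = distributions,
                 base_params = base_params, sites = sites,
                 partition_rule = partition_rule,
                 occupancy_threshold = occupancy_threshold,
                 stratify_by = stratify_by, segmentation = segmentation,
                 alpha = alpha, zero_handling = zero_handling,
                 manifest = manifest, landmarks = landmarks,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar options map directly onto [pipeline_config()] arguments; the
#' nested `base_params` block is forwarded to [phantom_params()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$base_params)) y$base_params <-
      do.call(phantom_params, y$base_params)
  do.call(pipeline_config, y)
}

# Process one subject side: segmentation, per-site occupancy + diameters.
process_side <- function(bundle, subject_id, side, retention_label, cfg) {
  occ <- list(); diam <- list(); failures <- list()
  masks <- NULL
  for (site in cfg$sites) {
    ms <- measure_site(bundle, site, cfg$segmentation, masks = masks)
    masks <- ms$masks   # reuse segmentations across sites
    for (nm in names(ms$errors))
      failures[[paste(subject_id, side, site, nm, sep = "/")]] <-
        ms$errors[[nm]]
    if (!is.null(ms$diameters)) {
      d <- ms$diameters
      d$subject <- subject_id; d$side <- side
      diam[[site]] <- d
    }
    rec <- tryCatch(
      score_side_occupancy(bundle, masks, site, subject_id,
                           retention_label, cfg),
      iansegmap_error = function(e) {
        failures[[paste(subject_id, side, site, "occupancy",
                        sep = "/")]] <<- conditionMessage(e)
        NULL
      })
    if (!is.null(rec)) occ[[site]] <- rec
  }
  list(occupancy = occ, diameters = diam, failures = failures)
}

# Build the reference slice at one site from the MRI volume and the
# segmented canal, extract the nerve mask and score occupancy.
score_side_occupancy <- function(bundle, masks, site, subject_id,
                                 retention_label, cfg) {
  if (is.null(masks$iac_mri))
    stop_segmentation("no canal segmentation available on MRI")
  lm <- if (!is.null(bundle$truth)) bundle$truth$landmarks[[site]]
        else bundle$landmarks[[site]]
  mri <- bundle$mri
  iz <- mm_to_index(lm$z_mm, mri$spacing, dim(mri$data)[3])
  iac2d <- masks$iac_mri$mask[, , iz]
  if (!any(iac2d)) stop_segmentation("empty canal cross-section at site")
  side_label <- if (!is.null(bundle$truth)) bundle$truth$side
                else bundle$side
  slice <- reference_slice(
    iac_mask = iac2d, spacing = rep(mri$spacing, 2), side = side_label,
    site = site, crest_mm = lm$crest_mm,
    nerve_midpoint_mm = lm$nerve_midpoint_mm,
    intensity = mri$data[, , iz])
  partition <- build_partition(slice, rule = cfg$partition_rule)
  nerve2d <- extract_nerve_mask(slice)
  score_occupancy(partition, nerve2d, threshold = cfg$occupancy_threshold,
                  subject_id = subject_id,
                  retention_label = retention_label)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic cohort (or on files listed in a
#' manifest), building per-site occupancy tables (pooled and stratified),
#' diameter summaries, conversion-factor summaries (per observation and
#' side-averaged) and per-plane Wilcoxon comparisons. Per-record failures
#' are logged and excluded, never imputed. In synthetic mode the report is
#' a deterministic function of the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param verbose print progress messages.
#' @return An object of class `study_report`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sides <- if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$n_subjects, config$distributions,
                              config$seed, config$base_params)
    lapply(cohort$sides, function(b) {
      vols <- generate_subject_side(b$params, b$side, b$subject_id,
                                    b$retention_label)
      c(vols, b["subject_id"], b["side"], b["retention_label"])
    })
  } else {
    read_manifest_sides(config)
  }
  occ_records <- list()
  diam_rows <- list()
  failures <- list()
  for (b in sides) {
    if (verbose) message("processing ", b$subject_id, "/", b$side)
    res <- process_side(b, b$subject_id, b$side, b$retention_label, config)
    occ_records <- c(occ_records, unname(res$occupancy))
    diam_rows <- c(diam_rows, unname(res$diameters))
    failures <- c(failures, res$failures)
  }
  if (length(occ_records) == 0 && length(diam_rows) == 0)
    ian_stop("no usable records in the cohort", "pipeline_error")
  diameters <- do.call(rbind, c(diam_rows, list(make.row.names = FALSE)))
  occupancy_tables <- list()
  for (site in config$sites) {
    recs <- Filter(function(r) r$site == site, occ_records)
    if (length(recs))
      occupancy_tables[[site]] <-
        stratify_cooccurrence(recs, site, config$stratify_by)
  }
  diameter_summary <- stats::aggregate(
    diameter_mm ~ site + structure + modality + plane, data = diameters,
    FUN = function(v) c(n = length(v), mean = mean(v), sd = stats::sd(v)))
  diameter_summary <- cbind(
    diameter_summary[1:4],
    as.data.frame(diameter_summary$diameter_mm))
  observations <- compute_observations(diameters)
  conversion_summary <- summarize_factors(observations)
  side_averaged <- side_average(observations)
  wilcoxon <- list()
  for (site in unique(observations$site))
    for (plane in c("axial", "sagittal", "coronal")) {
      w <- tryCatch(
        compare_factors(observations, site, plane,
                        zero_handling = config$zero_handling,
                        alpha = config$alpha),
        iansegmap_error = function(e) NULL)
      if (!is.null(w)) wilcoxon[[paste(site, plane, sep = "_")]] <- w
    }
  report <- structure(list(
    config = config,
    n_sides = length(sides),
    n_occupancy_records = length(occ_records),
    occupancy_records = occ_records,
    occupancy_tables = occupancy_tables,
    diameters = diameters,
    diameter_summary = diameter_summary,
    observations = observations,
    conversion_summary = conversion_summary,
    side_averaged = side_averaged,
    wilcoxon = wilcoxon,
    failures = failures,
    provenance = list(
      package_version = as.character(utils::packageVersion("iansegmap")),
      r_version = R.version.string,
      config_hash = config_hash(config))), class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Stable hash of the configuration (provenance only).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  sides evaluated: %d, occupancy records: %d, failures: %d\n",
              x$n_sides, x$n_occupancy_records, length(x$failures)))
  for (site in names(x$occupancy_tables)) {
    tab <- x$occupancy_tables[[site]]$pooled
    cat(sprintf("  %s marginal %%: %s (n = %d)\n", site,
                paste(sprintf("%.1f", tab$marginal), collapse = " "),
                tab$n_records))
  }
  if (length(x$wilcoxon)) {
    cat("  Wilcoxon comparisons (CBCT vs MRI factor):\n")
    for (nm in names(x$wilcoxon))
      cat(sprintf("    %-12s p = %.4g%s\n", nm, x$wilcoxon[[nm]]$p_value,
                  if (x$wilcoxon[[nm]]$reject) " *" else ""))
  }
  invisible(x)
}

#' Summarize a study report
#'
#' @param object a `study_report`.
#' @param ... unused.
#' @return Invisibly, a list with the key tables.
#' @export
summary.study_report <- function(object, ...) {
  print(object)
  cat("\nDiameter summary (mm):\n")
  ds <- object$diameter_summary
  ds$mean <- round(ds$mean, 2); ds$sd <- round(ds$sd, 2)
  print(ds, row.names = FALSE)
  cat("\n")
  print(object$conversion_summary)
  invisible(list(diameters = object$diameter_summary,
                 conversion = object$conversion_summary,
                 wilcoxon = object$wilcoxon))
}
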