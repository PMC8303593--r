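# Standard-format I/O: NIfTI volumes, landmark JSON, manifests, reports.

#' Read an image volume from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality `"MRI"` or `"CBCT"`.
#' @param reference_slices optional named integer vector of reference
#'   coronal slice indices per site.
#' @return An `image_volume`. Fails with a metadata error when the header
#'   carries no usable voxel spacing (never a silent default).
#' @export
read_volume <- function(path, modality = c("MRI", "CBCT"),
                        reference_slices = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop_metadata(sprintf(
                    "cannot read NIfTI header of %s: %s", path,
                    conditionMessage(e))))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop_metadata(sprintf("missing or invalid voxel spacing in %s", path))
  if (abs(max(sp[1:3]) - min(sp[1:3])) > 1e-6 * max(sp[1:3]))
    warning("anisotropic spacing: only the per-axis values are preserved")
  data <- as.array(img)
  vol <- new_image_volume(data, sp[1], modality, reference_slices)
  vol$spacing_per_axis <- sp[1:3]
  vol
}

#' Write an image volume to NIfTI
#'
#' @param volume an `image_volume`.
#' @param path output path (`.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- rep(volume$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write phantom truth and landmarks as JSON
#'
#' @param truth a `phantom_truth`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  lm <- lapply(truth$landmarks, function(l) l[c("site", "z_mm", "crest_mm",
                                                "nerve_midpoint_mm",
                                                "canal_seed_mm")])
  out <- list(
    subject_id = truth$subject_id, side = truth$side,
    retention_label = truth$retention_label,
    canal_center_mm = truth$geometry$canal_center,
    canal_semiaxes_mm = truth$geometry$canal_semiaxes,
    nerve_radius_mm = truth$geometry$nerve_radius,
    zrange_mm = truth$geometry$zrange,
    landmarks = lm,
    true_diameters = truth$true_diameters)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a landmark JSON file
#'
#' Expects the per-site structure written by [write_truth_json()] (fields
#' `site`, `z_mm`, `crest_mm`, `nerve_midpoint_mm`, `canal_seed_mm`).
#'
#' @param path JSON path.
#' @return Named list of per-site landmark lists.
#' @export
read_landmarks_json <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("landmark file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- j$landmarks
  if (is.null(lm)) stop_metadata(sprintf("no landmarks block in %s", path))
  lapply(lm, function(l) {
    l$crest_mm <- as.numeric(l$crest_mm)
    l$nerve_midpoint_mm <- as.numeric(l$nerve_midpoint_mm)
    l$canal_seed_mm <- as.numeric(l$canal_seed_mm)
    l
  })
}

#' Export a synthetic cohort to disk
#'
#' Writes per-side NIfTI volumes, truth/landmark JSON and a cohort
#' manifest CSV (subject, side, retention label, file paths) so a
#' synthetic study can be re-analyzed through the files-mode pipeline.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$sides, function(b) {
    vols <- generate_subject_side(b$params, b$side, b$subject_id,
                                  b$retention_label)
    stem <- file.path(dir, paste(b$subject_id, b$side, sep = "_"))
    write_volume(vols$mri, paste0(stem, "_mri.nii.gz"))
    write_volume(vols$cbct, paste0(stem, "_cbct.nii.gz"))
    write_truth_json(vols$truth, paste0(stem, "_truth.json"))
    data.frame(subject_id = b$subject_id, side = b$side,
               retention_label = b$retention_label,
               mri_path = paste0(stem, "_mri.nii.gz"),
               cbct_path = paste0(stem, "_cbct.nii.gz"),
               landmarks_path = paste0(stem, "_truth.json"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

# Load subject-side bundles from a files-mode manifest.
read_manifest_sides <- function(config) {
  man_path <- config$manifest
  if (!file.exists(man_path))
    stop_io(sprintf("manifest not found: %s", man_path))
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  req <- c("subject_id", "side", "mri_path", "landmarks_path")
  if (!all(req %in% names(man)))
    stop_input(paste("manifest must have columns:",
                     paste(req, collapse = ", ")))
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    for (p in c(row$mri_path, row$landmarks_path))
      if (!file.exists(p)) stop_io(sprintf("missing file: %s", p))
    bundle <- list(
      subject_id = row$subject_id, side = row$side,
      retention_label = row$retention_label %||% "none",
      mri = read_volume(row$mri_path, "MRI"),
      landmarks = read_landmarks_json(row$landmarks_path))
    if (!is.null(row$cbct_path) && !is.na(row$cbct_path) &&
        nzchar(row$cbct_path)) {
      if (!file.exists(row$cbct_path))
        stop_io(sprintf("missing file: %s", row$cbct_path))
      bundle$cbct <- read_volume(row$cbct_path, "CBCT")
    }
    bundle
  })
}

#' Write a study report to disk
#'
#' Emits the tidy CSV set (occupancy records, per-site co-occurrence
#' tables in the published layout, diameters and their summary, conversion
#' summary) plus `report.json` with full numeric precision and the
#' provenance block. CSV percentages are rounded to one decimal place.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE)
  w(occupancy_records_df(report$occupancy_records), "occupancy_records.csv")
  for (site in names(report$occupancy_tables))
    w(as.data.frame(report$occupancy_tables[[site]]$pooled),
      sprintf("cooccurrence_%s.csv", site))
  w(report$diameters, "diameters.csv")
  ds <- report$diameter_summary
  ds$mean <- round(ds$mean, 3); ds$sd <- round(ds$sd, 3)
  w(ds, "diameter_summary.csv")
  cs <- as.data.frame(report$conversion_summary)
  cs$mean <- round(cs$mean, 3); cs$sd <- round(cs$sd, 3)
  w(cs, "conversion_summary.csv")
  json <- list(
    n_sides = report$n_sides,
    n_occupancy_records = report$n_occupancy_records,
    diameter_summary = report$diameter_summary,
    conversion_summary = as.data.frame(report$conversion_summary),
    wilcoxon = lapply(report$wilcoxon, function(x)
      x[c("site", "plane", "n_subjects", "statistic", "p_value",
          "zero_handling", "reject")]),
    failures = report$failures,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
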