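# Per-segment nerve occupancy scoring and co-occurrence tables.
#
# A segment counts as "visible" (nerve-occupied) when at least half of its
# area contains hyperintense nerve signal; the rule is inclusive at exactly
# one half. Scoring is 2D on the single coronal reference slice.

new_occupancy_record <- function(subject_id, side, site, fractions,
                                 threshold, retention_label = "none",
                                 method = NA_character_,
                                 empty_segments = integer(0)) {
  stopifnot(length(fractions) == 6)
  structure(list(
    subject_id = subject_id, side = side, site = site,
    fractions = as.numeric(fractions),
    visible = as.numeric(fractions) >= threshold,
    threshold_used = threshold,
    retention_label = retention_label,
    method = method,
    empty_segments = empty_segments), class = "occupancy_record")
}

#' @export
print.occupancy_record <- function(x, ...) {
  cat(sprintf("<occupancy_record> %s/%s site %s (threshold %.2f)\n",
              x$subject_id, x$side, x$site, x$threshold_used))
  cat("  fractions:", paste(sprintf("%.3f", x$fractions), collapse = " "), "\n")
  cat("  visible:  ", paste(ifelse(x$visible, "yes", "no "), collapse = " "),
      "\n")
  invisible(x)
}

#' Score per-segment nerve occupancy
#'
#' Computes, for each of the six canal segments, the fraction of the
#' segment's area covered by the nerve mask, and applies the inclusive
#' half-area visibility rule (`fraction >= threshold` is visible).
#'
#' @param partition a `segment_partition` from [build_partition()].
#' @param nerve_mask logical matrix on the same grid as the partition.
#' @param threshold visibility threshold in (0, 1]; default 0.5.
#' @param subject_id,retention_label metadata carried into the record.
#' @return An object of class `occupancy_record`. Segments with zero area
#'   get fraction 0 and are listed in `empty_segments` (with a warning).
#' @export
score_occupancy <- function(partition, nerve_mask, threshold = 0.5,
                            subject_id = NA_character_,
                            retention_label = "none") {
  stopifnot(inherits(partition, "segment_partition"))
  if (!is.matrix(nerve_mask) ||
      !all(dim(nerve_mask) == dim(partition$labels)))
    stop_shape("nerve_mask grid does not match the partition grid")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop_parameter("threshold must lie in (0, 1]")
  nerve_mask <- nerve_mask & TRUE
  seg_n <- partition$pixel_counts
  hit_n <- tabulate(partition$labels[nerve_mask], 6L)
  empty <- which(seg_n == 0L)
  frac <- ifelse(seg_n > 0L, hit_n / pmax(seg_n, 1L), 0)
  if (length(empty))
    warning(sprintf("segments with zero area scored as 0: %s",
                    paste(empty, collapse = ", ")))
  new_occupancy_record(
    subject_id = subject_id, side = partition$side, site = partition$site,
    fractions = frac, threshold = threshold,
    retention_label = retention_label,
    method = sprintf("raster(rule=%s)", partition$rule),
    empty_segments = empty)
}

#' Extract the hyperintense nerve mask from a reference slice
#'
#' Operationalizes the visual hyperintensity read-out: a global intensity
#' threshold at the midpoint between the canal-interior background level
#' (median inside the canal mask) and the nerve peak (upper quantile),
#' followed by selection of the connected component containing the nerve
#' midpoint.
#'
#' @param slice a [reference_slice()] carrying `intensity`.
#' @param min_contrast minimum peak-minus-background contrast (intensity
#'   units) below which extraction fails; keep it above about five times
#'   the image noise SD so a uniform noisy canal is rejected.
#' @param peak_quantile quantile inside the canal used as the nerve peak
#'   estimate.
#' @param bg_quantile low quantile inside the canal used as the background
#'   level (robust even when the nerve fills most of the canal).
#' @return Logical matrix (the nerve mask), with attribute `threshold`.
#'   Signals a `segmentation_failure` condition when the canal shows no
#'   hyperintense class or no component contains the nerve midpoint.
#' @export
extract_nerve_mask <- function(slice, min_contrast = 30,
                               peak_quantile = 0.995, bg_quantile = 0.10) {
  stopifnot(inherits(slice, "reference_slice"))
  if (is.null(slice$intensity))
    stop_input("reference slice carries no intensity plane")
  vals <- slice$intensity[slice$iac_mask]
  bg <- stats::quantile(vals, bg_quantile, names = FALSE)
  peak <- stats::quantile(vals, peak_quantile, names = FALSE)
  if (!is.finite(peak - bg) || (peak - bg) < min_contrast)
    stop_segmentation(sprintf(
      "no hyperintense class inside the canal (contrast %.1f < %.1f)",
      peak - bg, min_contrast))
  thr <- (bg + peak) / 2
  cand <- slice$intensity >= thr & slice$iac_mask
  lab <- EBImage::bwlabel(cand)
  i <- mm_to_index(slice$nerve_midpoint_mm[1], slice$spacing[1], nrow(cand))
  j <- mm_to_index(slice$nerve_midpoint_mm[2], slice$spacing[2], ncol(cand))
  id <- lab[i, j]
  if (id == 0)
    stop_segmentation("no hyperintense component contains the nerve midpoint")
  mask <- lab == id
  attr(mask, "threshold") <- thr
  attr(mask, "background") <- bg
  attr(mask, "peak") <- peak
  mask
}

#' Marginal and conditional segment co-occurrence table
#'
#' From a set of occupancy records at one site, computes for each segment
#' the marginal visibility percentage ("Generally Yes") and, for each pair
#' (i, j), the conditional percentage of segment j being visible given
#' segment i is visible ("If Segment i Yes").
#'
#' @param records list of `occupancy_record`s.
#' @param site `"M3"` or `"M2"`; records at other sites are rejected.
#' @return An object of class `cooccurrence_table` with `n_records`, joint
#'   `counts` (6x6), `marginal` (percent) and `conditional` (6x6 percent,
#'   diagonal `NA`, undefined rows `NA`).
#' @export
build_cooccurrence <- function(records, site) {
  if (length(records) == 0) stop_input("empty record list")
  ok <- vapply(records, function(r) inherits(r, "occupancy_record"), TRUE)
  if (!all(ok)) stop_input("records must be occupancy_records")
  sites <- vapply(records, `[[`, "", "site")
  if (!all(sites == site))
    stop_input(sprintf("records at sites other than '%s' supplied", site))
  V <- t(vapply(records, function(r) as.numeric(r$visible), numeric(6)))
  counts <- t(V) %*% V                      # joint visible counts
  n <- nrow(V)
  marg_counts <- diag(counts)
  marginal <- 100 * marg_counts / n
  conditional <- matrix(NA_real_, 6, 6)
  for (i in 1:6) {
    if (marg_counts[i] > 0)
      conditional[i, ] <- 100 * counts[i, ] / marg_counts[i]
  }
  diag(conditional) <- NA_real_
  dimnames(counts) <- dimnames(conditional) <-
    list(paste0("seg", 1:6), paste0("seg", 1:6))
  names(marginal) <- paste0("seg", 1:6)
  structure(list(site = site, n_records = n, counts = counts,
                 marginal = marginal, conditional = conditional),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf("<cooccurrence_table> site %s, n = %d\n", x$site, x$n_records))
  tab <- rbind(`Generally Yes` = x$marginal, x$conditional)
  rownames(tab)[-1] <- sprintf("If Segment %d Yes", 1:6)
  print(round(tab, 1), na.print = "-")
  invisible(x)
}

#' Convert a co-occurrence table to a data frame
#'
#' Mirrors the published table layout: a "Generally Yes" row followed by
#' six "If Segment i Yes" rows, one column per segment.
#'
#' @param x a `cooccurrence_table`.
#' @param digits decimal places for the percentages (default 1).
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.cooccurrence_table <- function(x, digits = 1, ...) {
  tab <- rbind(x$marginal, x$conditional)
  df <- data.frame(row = c("Generally Yes", sprintf("If Segment %d Yes", 1:6)),
                   round(tab, digits), check.names = FALSE,
                   row.names = NULL)
  names(df)[-1] <- sprintf("Segment %d", 1:6)
  df
}

#' Stratified co-occurrence tables
#'
#' Builds one table per stratum of the retention label plus the pooled
#' table; pooled joint counts equal the element-wise sum over strata.
#'
#' @param records list of `occupancy_record`s at one site.
#' @param site site label.
#' @param by `"retention_label"` or `"none"`.
#' @return Named list of `cooccurrence_table`s, always containing `pooled`.
#' @export
stratify_cooccurrence <- function(records, site, by = c("retention_label",
                                                        "none")) {
  by <- match.arg(by)
  out <- list(pooled = build_cooccurrence(records, site))
  if (by == "retention_label") {
    labs <- vapply(records, `[[`, "", "retention_label")
    for (l in sort(unique(labs)))
      out[[l]] <- build_cooccurrence(records[labs == l], site)
  }
  out
}

#' Flatten occupancy records to a tidy data frame
#'
#' One row per nerve/site with fill fractions `f1..f6`, visibility flags
#' `v1..v6`, the threshold and the retention label.
#'
#' @param records list of `occupancy_record`s.
#' @return A data frame.
#' @export
occupancy_records_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    row <- data.frame(subject = r$subject_id, side = r$side, site = r$site,
                      stringsAsFactors = FALSE)
    f <- as.list(r$fractions); names(f) <- paste0("f", 1:6)
    v <- as.list(r$visible);   names(v) <- paste0("v", 1:6)
    cbind(row, as.data.frame(f), as.data.frame(v),
          data.frame(threshold = r$threshold_used,
                     retention_label = r$retention_label))
  }))
}
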