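# Six-segment partition of the canal cross-section on a coronal
# reference slice.
#
# Construction: a "horizontal" baseline through the alveolar crest of the
# buccal cortical plate fixes the orientation; the parallel midline runs
# through the nerve midpoint. The midline's chord across the canal mask
# (the intraosseous canal diameter) is cut into equal thirds by two
# perpendiculars. Each canal pixel is then labeled by
# (superior/inferior of the midline) x (buccal/middle/lingual third):
# 1 upper buccal, 2 upper middle, 3 upper lingual, 4 lower buccal,
# 5 lower middle, 6 lower lingual.
#
# Tie-break convention (deterministic tiling): pixels exactly on the
# midline go to the inferior band; pixels exactly on a perpendicular go
# to the middle third.

#' Construct a coronal reference slice
#'
#' @param iac_mask logical matrix, canal cross-section mask
#'   (axis 1 buccolingual, axis 2 superoinferior with +y superior).
#' @param spacing numeric length-2, pixel size in mm.
#' @param side `"left"` or `"right"` (resolves the buccal direction:
#'   +x on the left side, -x on the right).
#' @param site `"M3"` or `"M2"`.
#' @param crest_mm 2D point (mm), alveolar crest of the buccal cortical
#'   plate; must lie superior to every mask pixel.
#' @param nerve_midpoint_mm 2D point (mm), midpoint of the nerve; must lie
#'   inside `iac_mask`.
#' @param intensity optional numeric matrix of MRI intensities on the same
#'   grid (needed for [extract_nerve_mask()]).
#' @param baseline_angle_deg baseline orientation relative to the image
#'   row direction, degrees.
#' @return An object of class `reference_slice`.
#' @export
reference_slice <- function(iac_mask, spacing, side, site,
                            crest_mm, nerve_midpoint_mm,
                            intensity = NULL, baseline_angle_deg = 0) {
  if (!is.matrix(iac_mask)) stop_shape("iac_mask must be a matrix")
  iac_mask <- iac_mask & TRUE
  if (!any(iac_mask)) stop_geometry("iac_mask is empty")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  if (any(spacing <= 0)) stop_parameter("spacing must be positive")
  if (!side %in% c("left", "right"))
    stop_parameter("side must be 'left' or 'right'")
  if (!is.null(intensity) && !all(dim(intensity) == dim(iac_mask)))
    stop_shape("intensity and iac_mask grids differ")
  i <- mm_to_index(nerve_midpoint_mm[1], spacing[1], nrow(iac_mask))
  j <- mm_to_index(nerve_midpoint_mm[2], spacing[2], ncol(iac_mask))
  if (!iac_mask[i, j])
    stop_landmark("nerve_midpoint_mm does not lie inside iac_mask")
  th <- baseline_angle_deg * pi / 180
  nvec <- c(-sin(th), cos(th))  # superior normal candidate
  px <- (row(iac_mask)[iac_mask] - 0.5) * spacing[1]
  py <- (col(iac_mask)[iac_mask] - 0.5) * spacing[2]
  d <- (crest_mm[1] - px) * nvec[1] + (crest_mm[2] - py) * nvec[2]
  if (!all(d > 0))
    stop_landmark("crest_mm must lie superior to every iac_mask pixel")
  structure(list(
    iac_mask = iac_mask, spacing = spacing, side = side, site = site,
    crest_mm = as.numeric(crest_mm),
    nerve_midpoint_mm = as.numeric(nerve_midpoint_mm),
    intensity = intensity,
    baseline_angle_deg = baseline_angle_deg,
    buccal_direction = if (side == "left") c(1, 0) else c(-1, 0)),
    class = "reference_slice")
}

#' @export
print.reference_slice <- function(x, ...) {
  cat(sprintf(
    "<reference_slice> %s side, site %s, %d x %d px @ %.3g x %.3g mm\n",
    x$side, x$site, nrow(x$iac_mask), ncol(x$iac_mask),
    x$spacing[1], x$spacing[2]))
  invisible(x)
}

# March along the midline in fine steps and return the chord parameter
# range (t along the buccal unit vector, origin at the nerve midpoint).
midline_chord <- function(slice, ub) {
  m <- slice$iac_mask; sp <- slice$spacing
  mid <- slice$nerve_midpoint_mm
  diag_mm <- sqrt(sum((dim(m) * sp)^2))
  step <- 0.25 * min(sp)
  t <- seq(-diag_mm, diag_mm, by = step)
  qx <- mid[1] + t * ub[1]
  qy <- mid[2] + t * ub[2]
  i <- floor(qx / sp[1]) + 1
  j <- floor(qy / sp[2]) + 1
  ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
  ok[ok] <- m[cbind(i[ok], j[ok])]
  if (!any(ok)) stop_geometry("empty chord: midline misses the canal mask")
  range(t[ok])
}

#' Build the six-segment partition of a reference slice
#'
#' Implements the two-line/two-perpendicular construction described above.
#' Every canal pixel receives exactly one label in 1..6 (disjoint, exact
#' cover of `iac_mask`).
#'
#' @param slice a [reference_slice()].
#' @param rule `"chord_thirds"` (default; perpendiculars at equal thirds of
#'   the midline chord through the mask) or `"bbox_thirds"` (thirds of the
#'   mask's full projected extent along the baseline direction).
#' @return An object of class `segment_partition` with the label matrix
#'   (`labels`, 0 outside the canal), the line descriptors, per-segment
#'   pixel counts and areas (mm^2).
#' @export
build_partition <- function(slice, rule = c("chord_thirds", "bbox_thirds")) {
  rule <- match.arg(rule)
  stopifnot(inherits(slice, "reference_slice"))
  m <- slice$iac_mask; sp <- slice$spacing
  mid <- slice$nerve_midpoint_mm
  th <- slice$baseline_angle_deg * pi / 180
  u <- c(cos(th), sin(th))
  nvec <- c(-sin(th), cos(th))
  if (sum(nvec * (slice$crest_mm - mid)) < 0) nvec <- -nvec
  bd <- slice$buccal_direction
  ub <- if (sum(u * bd) >= 0) u else -u   # buccal-pointing baseline vector
  px <- (row(m) - 0.5) * sp[1]
  py <- (col(m) - 0.5) * sp[2]
  d <- (px - mid[1]) * nvec[1] + (py - mid[2]) * nvec[2]
  t <- (px - mid[1]) * ub[1] + (py - mid[2]) * ub[2]
  tr <- if (rule == "chord_thirds") midline_chord(slice, ub) else range(t[m])
  cuts <- tr[1] + diff(tr) * c(1, 2) / 3
  lateral <- ifelse(t > cuts[2], 1L, ifelse(t < cuts[1], 3L, 2L))
  labels <- ifelse(m, ifelse(d > 0, lateral, lateral + 3L), 0L)
  counts <- tabulate(labels[labels > 0L], 6L)
  structure(list(
    labels = labels, spacing = sp, side = slice$side, site = slice$site,
    rule = rule,
    baseline = list(point = slice$crest_mm, angle_deg = slice$baseline_angle_deg),
    midline = list(point = mid, angle_deg = slice$baseline_angle_deg),
    chord_t = tr, perpendicular_t = cuts,
    buccal_direction = bd,
    pixel_counts = counts,
    areas_mm2 = counts * sp[1] * sp[2]),
    class = "segment_partition")
}

#' Extract one segment mask from a partition
#'
#' @param partition a `segment_partition`.
#' @param segment integer in 1..6.
#' @return Logical matrix.
#' @export
segment_mask <- function(partition, segment) {
  stopifnot(segment %in% 1:6)
  partition$labels == as.integer(segment)
}

#' @export
print.segment_partition <- function(x, ...) {
  cat(sprintf("<segment_partition> %s side, site %s, rule %s\n",
              x$side, x$site, x$rule))
  cat("  pixels per segment:", paste(x$pixel_counts, collapse = " "), "\n")
  invisible(x)
}

#' Mirror a partition across the buccolingual axis
#'
#' Flips the label map left-right and updates side and buccal direction so
#' that segments 1/4 remain buccal and 3/6 lingual on the mirrored side
#' (the anatomical numbering travels with the anatomy, so no label values
#' change). Applying the operation twice restores the input exactly.
#'
#' @param p a `segment_partition`.
#' @param side target side label for the mirrored partition; defaults to
#'   the opposite of `p$side`.
#' @return A `segment_partition`.
#' @export
mirror_partition <- function(p, side = NULL) {
  stopifnot(inherits(p, "segment_partition"))
  side <- side %||% if (p$side == "left") "right" else "left"
  width <- nrow(p$labels) * p$spacing[1]
  lab <- p$labels[rev(seq_len(nrow(p$labels))), , drop = FALSE]
  mirror_pt <- function(pt) c(width - pt[1], pt[2])
  q <- p
  q$labels <- lab
  q$side <- side
  q$baseline$point <- mirror_pt(p$baseline$point)
  q$midline$point <- mirror_pt(p$midline$point)
  q$buccal_direction <- c(-p$buccal_direction[1], p$buccal_direction[2])
  q$pixel_counts <- tabulate(lab[lab > 0L], 6L)
  q$areas_mm2 <- q$pixel_counts * p$spacing[1] * p$spacing[2]
  q
}

#' Rasterize a reference slice from phantom ground truth
#'
#' Renders the coronal reference slice of a phantom at an arbitrary pixel
#' size directly from the analytic descriptors (independently of the 3D
#' volumes), together with the rasterized true nerve mask. Used for
#' resolution-convergence studies of the occupancy pipeline.
#'
#' @param truth a `phantom_truth`.
#' @param site `"M3"` or `"M2"`.
#' @param spacing pixel size in mm (scalar, isotropic in-plane).
#' @param margin_mm extra margin around the canal, mm.
#' @param noise_sd additive Gaussian intensity noise SD (default 0).
#' @param seed seed for the noise stream.
#' @return A list with `slice` (a [reference_slice()] with MRI-like
#'   intensities), `nerve_mask` (logical matrix, rasterized true nerve) and
#'   `origin_mm` (offset of the slice grid in the volume frame).
#' @export
rasterize_reference_slice <- function(truth, site = "M3", spacing = 0.05,
                                      margin_mm = 1.5, noise_sd = 0,
                                      seed = 1L) {
  geom <- truth$geometry
  lm <- truth$landmarks[[site]]
  if (is.null(lm)) stop_parameter(sprintf("unknown site '%s'", site))
  ax <- geom$canal_semiaxes[["MRI"]]
  axo <- ax + truth$params$cortical_thickness
  c0 <- geom$canal_center
  origin <- c(c0[1] - axo[1] - margin_mm, c0[2] - axo[2] - margin_mm)
  ext <- 2 * (axo + margin_mm)
  n <- ceiling(ext / spacing)
  xs <- origin[1] + axis_centers(n[1], spacing)
  ys <- origin[2] + axis_centers(n[2], spacing)
  X <- matrix(xs, n[1], n[2])
  Y <- matrix(ys, n[1], n[2], byrow = TRUE)
  in_inner <- ((X - c0[1]) / ax[1])^2 + ((Y - c0[2]) / ax[2])^2 <= 1
  in_outer <- ((X - c0[1]) / axo[1])^2 + ((Y - c0[2]) / axo[2])^2 <= 1
  nx <- lm$nerve_midpoint_mm[1]; ny <- lm$nerve_midpoint_mm[2]
  r <- geom$nerve_radius
  nerve <- r > 0 & ((X - nx)^2 + (Y - ny)^2 <= r^2)
  I <- truth$params$intensities
  intensity <- matrix(I$mri_background, n[1], n[2])
  intensity[in_outer & !in_inner] <- I$mri_cortical
  intensity <- intensity + (I$mri_nerve - I$mri_background) *
    gauss_blur2d(nerve + 0, truth$params$nerve_blur_sigma / spacing)
  if (noise_sd > 0)
    intensity <- intensity + with_seed(seed,
      matrix(stats::rnorm(n[1] * n[2], 0, noise_sd), n[1], n[2]))
  slice <- reference_slice(
    iac_mask = in_inner, spacing = c(spacing, spacing),
    side = truth$side, site = site,
    crest_mm = geom$crest - origin,
    nerve_midpoint_mm = c(nx, ny) - origin,
    intensity = intensity)
  list(slice = slice, nerve_mask = nerve, origin_mm = origin)
}
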