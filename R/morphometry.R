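# Structure segmentation and maximum-diameter morphometry.
#
# The canal (both modalities) and nerve (MRI only) are segmented by seeded
# region growing with an intensity interval derived from local statistics
# around the seed, followed by slice-wise hole filling and morphological
# closing. Diameters are the maximum Feret diameter (maximum caliper width
# over all in-plane directions) of the structure's 2D cross-section through
# the site center in the axial, sagittal and coronal planes.

#' Maximum Feret diameter of a 2D point set
#'
#' Maximum pairwise Euclidean distance, computed over the convex hull.
#' When `pixel_size` is given the points are taken as pixel centers and
#' each is expanded to the four corners of its pixel square before the
#' hull is formed, so that a rasterized mask supports its full footprint;
#' the value then deviates from the underlying region diameter by at most
#' about one pixel diagonal in either direction.
#'
#' @param points numeric matrix with two columns (mm).
#' @param pixel_size optional pixel edge length(s) (mm, scalar or pair);
#'   when supplied, pixel squares rather than bare points are measured.
#' @return The maximum caliper diameter (mm); 0 for a single bare point.
#' @export
feret_diameter <- function(points, pixel_size = NULL) {
  points <- as.matrix(points)
  if (nrow(points) == 0) return(0)
  if (!is.null(pixel_size)) {
    h <- rep(pixel_size, length.out = 2) / 2
    points <- points[unique(grDevices::chull(points)), , drop = FALSE]
    points <- rbind(
      cbind(points[, 1] - h[1], points[, 2] - h[2]),
      cbind(points[, 1] - h[1], points[, 2] + h[2]),
      cbind(points[, 1] + h[1], points[, 2] - h[2]),
      cbind(points[, 1] + h[1], points[, 2] + h[2]))
  }
  if (nrow(points) < 2) return(0)
  h <- grDevices::chull(points)
  hp <- points[h, , drop = FALSE]
  if (nrow(hp) == 1) return(0)
  if (nrow(hp) <= 1500) {
    d2 <- outer(hp[, 1], hp[, 1], "-")^2 + outer(hp[, 2], hp[, 2], "-")^2
    return(sqrt(max(d2)))
  }
  # chunked pairwise maximum for degenerate hulls with many collinear points
  best <- 0
  for (i in seq(1, nrow(hp), by = 1000)) {
    blk <- i:min(i + 999, nrow(hp))
    d2 <- outer(hp[blk, 1], hp[, 1], "-")^2 +
      outer(hp[blk, 2], hp[, 2], "-")^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Default region-growing intensity criteria. On MRI the canal contents
# (interior plus nerve, any brightness) are bounded by the dark cortical
# ring, so the lower bound sits halfway between the volume's dark tail
# and its median ("volume_mid") - robust to where inside the canal the
# seed lands. On CBCT and for the nerve, bounds relative to the local
# seed mean suffice (the seed tissue is the target class itself).
default_growth_criterion <- function(structure, modality) {
  key <- paste(structure, modality, sep = "_")
  switch(key,
    IAC_MRI  = list(mode = "volume_mid"),
    IAC_CBCT = list(mode = "seed_frac", lo = -Inf, hi = 1.35),
    IAN_MRI  = list(mode = "seed_frac", lo = 0.72, hi = Inf),
    stop_parameter(sprintf("no growth defaults for %s on %s",
                           structure, modality)))
}

# Vectorized 6-connected BFS flood from a seed voxel over `inside`.
flood3d <- function(inside, seed_idx, max_voxels) {
  dims <- dim(inside)
  nx <- dims[1]; nxy <- dims[1] * dims[2]; nvox <- prod(dims)
  visited <- array(FALSE, dims)
  visited[seed_idx] <- TRUE
  frontier <- seed_idx
  count <- 1L
  while (length(frontier)) {
    ix <- ((frontier - 1L) %% nx) + 1L
    iy <- (((frontier - 1L) %/% nx) %% dims[2]) + 1L
    iz <- ((frontier - 1L) %/% nxy) + 1L
    nb <- c(frontier[ix > 1L] - 1L, frontier[ix < dims[1]] + 1L,
            frontier[iy > 1L] - nx, frontier[iy < dims[2]] + nx,
            frontier[iz > 1L] - nxy, frontier[iz < dims[3]] + nxy)
    nb <- unique(nb)
    nb <- nb[inside[nb] & !visited[nb]]
    visited[nb] <- TRUE
    count <- count + length(nb)
    if (count > max_voxels) return(structure(visited, leaked = TRUE))
    frontier <- nb
  }
  structure(visited, leaked = FALSE)
}

#' Segment a structure by seeded region growing
#'
#' Grows a 6-connected region from the seed over voxels whose intensity
#' lies in an interval derived from the local seed statistics (3x3x3 mean
#' times structure-specific fractions), fills in-plane holes (so the canal
#' mask includes the nerve it contains), applies slice-wise morphological
#' closing, and returns the seed's connected component.
#'
#' @param volume an `image_volume`.
#' @param seed_mm 3D point (mm) inside the target structure.
#' @param structure `"IAC"` or `"IAN"`; the nerve can only be segmented on
#'   MRI (CBCT carries no nerve contrast).
#' @param config list of options: `lo_frac`/`hi_frac` override the interval
#'   fractions, `closing_radius_px` (default 1), `fill_holes` (default TRUE
#'   for the canal), `max_fraction` (default 0.25) aborts runaway growth.
#' @return An object of class `structure_mask` carrying the logical mask,
#'   spacing, and the parameters used.
#' @export
segment_structure <- function(volume, seed_mm, structure = c("IAC", "IAN"),
                              config = list()) {
  structure_ <- match.arg(structure)
  stopifnot(inherits(volume, "image_volume"))
  if (structure_ == "IAN" && volume$modality != "MRI")
    stop_modality("the nerve cannot be segmented on CBCT (no nerve contrast)")
  dims <- dim(volume$data)
  s <- volume$spacing
  idx <- vapply(1:3, function(k) mm_to_index(seed_mm[k], s, dims[k]), 1L)
  crit <- default_growth_criterion(structure_, volume$modality)
  if (!is.null(config$lo_frac) || !is.null(config$hi_frac))
    crit <- list(mode = "seed_frac",
                 lo = config$lo_frac %||% -Inf,
                 hi = config$hi_frac %||% Inf)
  closing_radius <- config$closing_radius_px %||% 1L
  fill_holes <- config$fill_holes %||% (structure_ == "IAC")
  max_fraction <- config$max_fraction %||% 0.25
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ni <- pmin(pmax(idx[1] + nb$dx, 1L), dims[1])
  nj <- pmin(pmax(idx[2] + nb$dy, 1L), dims[2])
  nk <- pmin(pmax(idx[3] + nb$dz, 1L), dims[3])
  m <- mean(volume$data[cbind(ni, nj, nk)])
  if (crit$mode == "volume_mid") {
    q <- stats::quantile(volume$data, c(0.01, 0.5), names = FALSE)
    lo <- mean(q); hi <- Inf
  } else {
    lo <- if (is.finite(crit$lo)) crit$lo * m else -Inf
    hi <- if (is.finite(crit$hi)) crit$hi * m else Inf
  }
  inside <- volume$data >= lo & volume$data <= hi
  seed_lin <- idx[1] + (idx[2] - 1L) * dims[1] +
    (idx[3] - 1L) * dims[1] * dims[2]
  if (!inside[seed_lin])
    stop_segmentation("seed voxel fails its own growth criterion")
  grown <- flood3d(inside, seed_lin, max_fraction * prod(dims))
  if (attr(grown, "leaked"))
    stop_leakage(sprintf(
      "region growing flooded more than %.0f%% of the volume",
      100 * max_fraction))
  mask <- grown & TRUE
  brush <- if (closing_radius > 0)
    EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
  for (k in seq_len(dims[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    if (fill_holes) sl <- EBImage::fillHull(sl) > 0
    if (closing_radius > 0) sl <- EBImage::closing(sl, brush) > 0
    mask[, , k] <- sl
  }
  # keep the seed's connected component after morphology
  mask <- flood3d(mask, seed_lin, prod(dims) + 1) & TRUE
  structure(list(
    mask = mask, spacing = s, structure = structure_,
    modality = volume$modality, seed_mm = as.numeric(seed_mm),
    params_used = list(local_mean = m, lo = lo, hi = hi,
                       criterion = crit,
                       closing_radius_px = closing_radius,
                       fill_holes = fill_holes,
                       max_fraction = max_fraction)),
    class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s on %s: %d voxels @ %.3g mm\n",
              x$structure, x$modality, sum(x$mask), x$spacing))
  invisible(x)
}

# Extract the 2D cross-section of a 3D mask for one plane orientation.
# Returns pixel-center coordinates (mm) of the in-plane mask points.
plane_section <- function(mask, spacing, site_center_mm, plane,
                          slab_halfwidth_mm = 0) {
  dims <- dim(mask)
  fix_axis <- switch(plane, coronal = 3L, axial = 2L, sagittal = 1L)
  keep_axes <- setdiff(1:3, fix_axis)
  i0 <- mm_to_index(site_center_mm[fix_axis], spacing, dims[fix_axis])
  hw <- max(0L, floor(slab_halfwidth_mm / spacing))
  sel <- max(1L, i0 - hw):min(dims[fix_axis], i0 + hw)
  section <- switch(plane,
    coronal  = apply(mask[, , sel, drop = FALSE], c(1, 2), any),
    axial    = apply(mask[, sel, , drop = FALSE], c(1, 3), any),
    sagittal = apply(mask[sel, , , drop = FALSE], c(2, 3), any))
  pts <- which(section, arr.ind = TRUE)
  if (nrow(pts) == 0) return(NULL)
  (pts - 0.5) * spacing
}

#' Maximum per-plane diameters of a segmented structure
#'
#' For each plane orientation (axial: fixed superoinferior level;
#' sagittal: fixed buccolingual level; coronal: fixed mesiodistal level),
#' takes the cross-section through the site center and returns its maximum
#' Feret diameter in mm.
#'
#' @param smask a `structure_mask`.
#' @param site_center_mm 3D point (mm) at which the three planes intersect.
#' @param slab_halfwidth_mm optional half-width (mm) of a slab projected
#'   into each plane before measuring (0 = single slice, the default).
#' @return An object of class `diameter_set` with fields `d_axial`,
#'   `d_sagittal`, `d_coronal` (mm).
#' @export
max_plane_diameters <- function(smask, site_center_mm,
                                slab_halfwidth_mm = 0) {
  stopifnot(inherits(smask, "structure_mask"))
  if (!any(smask$mask)) stop_site("structure mask is empty")
  d <- vapply(c("axial", "sagittal", "coronal"), function(pl) {
    pts <- plane_section(smask$mask, smask$spacing, site_center_mm, pl,
                         slab_halfwidth_mm)
    if (is.null(pts))
      stop_site(sprintf("empty %s cross-section at the site center", pl))
    feret_diameter(pts, pixel_size = smask$spacing)
  }, numeric(1))
  structure(list(structure = smask$structure, modality = smask$modality,
                 site_center_mm = as.numeric(site_center_mm),
                 d_axial = d[["axial"]], d_sagittal = d[["sagittal"]],
                 d_coronal = d[["coronal"]]),
            class = "diameter_set")
}

#' @export
print.diameter_set <- function(x, ...) {
  cat(sprintf(
    "<diameter_set> %s on %s: axial %.2f, sagittal %.2f, coronal %.2f mm\n",
    x$structure, x$modality, x$d_axial, x$d_sagittal, x$d_coronal))
  invisible(x)
}

#' Measure all structures of one subject side at one site
#'
#' Segments the canal on CBCT (when present) and on MRI, and the nerve on
#' MRI, then measures the three per-plane maximum diameters of each at the
#' site. Per-structure failures (e.g. absent nerve contrast) are surfaced
#' in the `errors` element without aborting the remaining measurements.
#'
#' @param bundle a list with `mri`, optionally `cbct`, and `truth` (or a
#'   `landmarks` list providing `canal_seed_mm`, `nerve_midpoint_mm` and
#'   `z_mm` per site).
#' @param site `"M3"` or `"M2"`.
#' @param config segmentation options passed to [segment_structure()];
#'   `config$ian_contrast_ratio` (default 1.3) is the minimum seed-local
#'   nerve/canal intensity ratio for attempting nerve segmentation.
#' @param masks optional pre-computed list of `structure_mask`s (named
#'   `iac_cbct`, `iac_mri`, `ian_mri`) to reuse across sites.
#' @return A list with `diameters` (a data frame: structure, modality,
#'   plane, diameter_mm), `masks`, `errors` and `provenance`.
#' @export
measure_site <- function(bundle, site = "M3", config = list(),
                         masks = NULL) {
  lm <- if (!is.null(bundle$truth)) bundle$truth$landmarks[[site]]
        else bundle$landmarks[[site]]
  if (is.null(lm)) stop_parameter(sprintf("no landmarks for site '%s'", site))
  errors <- list()
  ratio_min <- config$ian_contrast_ratio %||% 1.3
  canal_seed <- lm$canal_seed_mm
  nerve_seed <- c(lm$nerve_midpoint_mm, lm$z_mm)
  if (is.null(masks)) masks <- list()
  grab <- function(name, fun) {
    if (!is.null(masks[[name]])) return(masks[[name]])
    tryCatch(fun(), iansegmap_error = function(e) {
      errors[[name]] <<- conditionMessage(e); NULL
    })
  }
  if (!is.null(bundle$cbct))
    masks$iac_cbct <- grab("iac_cbct", function()
      segment_structure(bundle$cbct, canal_seed, "IAC", config))
  masks$iac_mri <- grab("iac_mri", function()
    segment_structure(bundle$mri, canal_seed, "IAC", config))
  masks$ian_mri <- grab("ian_mri", function() {
    check_ian_contrast(bundle$mri, nerve_seed, canal_seed, ratio_min)
    segment_structure(bundle$mri, nerve_seed, "IAN", config)
  })
  rows <- list()
  for (name in names(masks)) {
    sm <- masks[[name]]
    if (is.null(sm)) next
    center <- if (sm$structure == "IAN") nerve_seed
              else c(canal_seed[1:2], lm$z_mm)
    # measure the canal at its own center (landmark seed is offset off
    # the nerve): recentre on the mask centroid in-plane
    center <- recentre_on_mask(sm, center)
    ds <- tryCatch(max_plane_diameters(sm, center, config$slab_halfwidth_mm
                                       %||% 0),
                   iansegmap_error = function(e) {
                     errors[[name]] <<- conditionMessage(e); NULL
                   })
    if (is.null(ds)) next
    rows[[name]] <- data.frame(
      structure = ds$structure, modality = ds$modality, site = site,
      plane = c("axial", "sagittal", "coronal"),
      diameter_mm = c(ds$d_axial, ds$d_sagittal, ds$d_coronal),
      stringsAsFactors = FALSE)
  }
  list(diameters = if (length(rows)) do.call(rbind, c(rows,
         list(make.row.names = FALSE))) else NULL,
       masks = masks, errors = errors,
       provenance = list(site = site, z_mm = lm$z_mm, config = config))
}

# In-plane centroid of the mask at the site's coronal slice, so planes cut
# through the structure's own center rather than the seed offset.
recentre_on_mask <- function(sm, center) {
  dims <- dim(sm$mask)
  iz <- mm_to_index(center[3], sm$spacing, dims[3])
  sl <- sm$mask[, , iz]
  if (!any(sl)) return(center)
  pts <- which(sl, arr.ind = TRUE)
  c((mean(pts[, 1]) - 0.5) * sm$spacing,
    (mean(pts[, 2]) - 0.5) * sm$spacing, center[3])
}

# Minimum seed-local contrast check before attempting nerve segmentation:
# a vanished nerve leaves no hyperintense class at the seed.
check_ian_contrast <- function(volume, nerve_seed, canal_seed, ratio_min) {
  local_mean <- function(p) {
    dims <- dim(volume$data)
    idx <- vapply(1:3, function(k)
      mm_to_index(p[k], volume$spacing, dims[k]), 1L)
    nb <- expand.grid(dx = -1:1, dy = -1:1, dz = 0)
    mean(volume$data[cbind(pmin(pmax(idx[1] + nb$dx, 1L), dims[1]),
                           pmin(pmax(idx[2] + nb$dy, 1L), dims[2]),
                           rep(idx[3], nrow(nb)))])
  }
  m_n <- local_mean(nerve_seed)
  m_ref <- stats::median(volume$data)   # bone/interior reference level
  if (!is.finite(m_n / m_ref) || m_n < ratio_min * m_ref)
    stop_segmentation(sprintf(
      "no hyperintense nerve signal at the seed (ratio %.2f < %.2f)",
      m_n / m_ref, ratio_min))
  invisible(TRUE)
}
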