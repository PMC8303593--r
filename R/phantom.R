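# Synthetic paired CBCT/MRI phantom of the inferior alveolar canal and nerve.
#
# Coordinate frame (all physical units in mm):
#   axis 1 (x): buccolingual, axis 2 (y): superoinferior (+y = superior),
#   axis 3 (z): mesiodistal. Coronal slices are x-y planes at fixed z,
#   axial planes fix y, sagittal planes fix x. Voxel i covers
#   ((i-1)*s, i*s] with center (i-0.5)*s.
#
# The canal is a finite elliptical tube along z surrounded by a cortical
# ring; the nerve is a circular tube inside it (optionally undulating in
# the buccolingual direction). MRI shows a dark cortical ring and a
# hyperintense nerve; CBCT shows a bright cortical ring and no nerve
# contrast. Left and right sides are mirror images about the volume's
# buccolingual midline.

PHANTOM_EXTENT_XY <- c(14, 18)   # mm, in-plane physical extent of a volume
CANAL_CENTER_XY   <- c(7, 6)     # mm, canal axis position in every slice

#' Parameters of one synthetic subject side
#'
#' Bundles the geometric and imaging parameters of a single phantom
#' subject side and validates their invariants. Geometric defaults are
#' calibrated to published canal/nerve morphometry (canal semiaxes
#' 1.95 x 2.65 mm giving axial/coronal canal diameters of 3.9/5.3 mm,
#' nerve radius 1.3 mm), spacings to typical 3D-DESS MRI (0.75 mm
#' isotropic) and CBCT (0.16 mm) acquisitions.
#'
#' @param canal_semiaxes numeric length-2, canal semiaxes in mm
#'   (buccolingual, superoinferior).
#' @param nerve_radius numeric, nerve radius in mm.
#' @param nerve_offset numeric length-2, nerve center minus canal center in
#'   mm (buccal-positive, superior-positive).
#' @param crest_height numeric, height of the alveolar crest landmark above
#'   the canal center, mm.
#' @param cortical_thickness numeric, thickness of the cortical ring, mm.
#'   Keep above one MRI voxel diagonal so the ring rasterizes closed.
#' @param mri_spacing,cbct_spacing numeric, isotropic voxel size per
#'   modality, mm.
#' @param modality_scale named numeric pair `c(cbct=, mri=)`, multiplicative
#'   canal-size distortion applied per modality.
#' @param noise_sd numeric, SD of additive Gaussian intensity noise.
#' @param n_slices integer, number of MRI coronal slices; the mesiodistal
#'   extent is `n_slices * mri_spacing`.
#' @param tube_length numeric, mesiodistal length of canal and nerve, mm.
#' @param undulation_amplitude,undulation_wavelength numeric, optional
#'   sinusoidal buccolingual undulation of the nerve course, mm.
#' @param nerve_blur_sigma numeric, Gaussian blur SD (mm) applied to the
#'   nerve top-hat signal on MRI.
#' @param protruding logical; allow the nerve to protrude from the canal.
#' @param intensities named list of modality intensity levels.
#' @param seed integer seed for the noise stream.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(canal_semiaxes = c(1.95, 2.65),
                           nerve_radius = 1.3,
                           nerve_offset = c(0.3, -0.6),
                           crest_height = 8,
                           cortical_thickness = 1.2,
                           mri_spacing = 0.75,
                           cbct_spacing = 0.16,
                           modality_scale = c(cbct = 1, mri = 1),
                           noise_sd = 5,
                           n_slices = 14L,
                           tube_length = 8,
                           undulation_amplitude = 0,
                           undulation_wavelength = 6,
                           nerve_blur_sigma = 0.2,
                           protruding = FALSE,
                           intensities = list(
                             mri_background = 100, mri_cortical = 30,
                             mri_nerve = 220, cbct_background = 100,
                             cbct_cortical = 220, cbct_interior = 60),
                           seed = 1L) {
  p <- list(canal_semiaxes = as.numeric(canal_semiaxes),
            nerve_radius = as.numeric(nerve_radius),
            nerve_offset = as.numeric(nerve_offset),
            crest_height = as.numeric(crest_height),
            cortical_thickness = as.numeric(cortical_thickness),
            mri_spacing = as.numeric(mri_spacing),
            cbct_spacing = as.numeric(cbct_spacing),
            modality_scale = modality_scale,
            noise_sd = as.numeric(noise_sd),
            n_slices = as.integer(n_slices),
            tube_length = as.numeric(tube_length),
            undulation_amplitude = as.numeric(undulation_amplitude),
            undulation_wavelength = as.numeric(undulation_wavelength),
            nerve_blur_sigma = as.numeric(nerve_blur_sigma),
            protruding = isTRUE(protruding),
            intensities = intensities,
            seed = as.integer(seed))
  validate_phantom_params(p)
  class(p) <- "phantom_params"
  p
}

validate_phantom_params <- function(p) {
  if (length(p$canal_semiaxes) != 2 || any(!is.finite(p$canal_semiaxes)) ||
      any(p$canal_semiaxes <= 0))
    stop_parameter("canal_semiaxes must be two positive lengths (mm)")
  if (!is.finite(p$nerve_radius) || p$nerve_radius < 0)
    stop_parameter("nerve_radius must be a non-negative length (mm)")
  if (length(p$nerve_offset) != 2 || any(!is.finite(p$nerve_offset)))
    stop_parameter("nerve_offset must be two finite displacements (mm)")
  if (p$mri_spacing <= 0 || p$cbct_spacing <= 0)
    stop_parameter("voxel spacings must be strictly positive")
  if (p$noise_sd < 0)
    stop_parameter("noise_sd must be non-negative")
  if (p$cortical_thickness <= 0)
    stop_parameter("cortical_thickness must be positive")
  if (p$n_slices < 4)
    stop_parameter("n_slices must be at least 4")
  if (p$tube_length <= 0 ||
      p$tube_length > p$n_slices * p$mri_spacing)
    stop_parameter("tube_length must be positive and fit the volume")
  if (!p$protruding) {
    amp <- abs(p$undulation_amplitude)
    fits <- (abs(p$nerve_offset[1]) + amp + p$nerve_radius <=
               p$canal_semiaxes[1] + 1e-9) &&
            (abs(p$nerve_offset[2]) + p$nerve_radius <=
               p$canal_semiaxes[2] + 1e-9)
    if (!fits)
      stop_parameter(paste0(
        "nerve does not fit inside the canal: |offset| + radius must not ",
        "exceed the canal semiaxis along each axis (set protruding = TRUE ",
        "to override)"))
  }
  invisible(p)
}

# --- Geometry descriptors (the analytic ground truth) ---------------------

# World-frame geometry for one side. The buccal direction is +x on the
# left side and -x on the right (mirroring about the volume midline).
phantom_geometry <- function(params, side) {
  bs <- if (identical(side, "left")) 1 else -1
  ext <- c(PHANTOM_EXTENT_XY, params$n_slices * params$mri_spacing)
  zc <- ext[3] / 2
  z0 <- zc - params$tube_length / 2
  z1 <- zc + params$tube_length / 2
  cx <- CANAL_CENTER_XY[1]
  cy <- CANAL_CENTER_XY[2]
  nerve_x0 <- cx + bs * params$nerve_offset[1]
  nerve_y  <- cy + params$nerve_offset[2]
  list(
    side = side, buccal_sign = bs, extent = ext,
    canal_center = c(cx, cy), zrange = c(z0, z1),
    canal_semiaxes = list(
      CBCT = params$canal_semiaxes * params$modality_scale[["cbct"]],
      MRI  = params$canal_semiaxes * params$modality_scale[["mri"]]),
    nerve_radius = params$nerve_radius,
    nerve_y = nerve_y,
    # buccolingual nerve-center course along z
    nerve_x = function(z) {
      nerve_x0 + bs * params$undulation_amplitude *
        sin(2 * pi * (z - z0) / params$undulation_wavelength)
    },
    crest = c(cx + bs * (params$canal_semiaxes[1] +
                           params$cortical_thickness + 1.0),
              cy + params$crest_height),
    site_z = c(M3 = zc + 0.25 * params$tube_length,
               M2 = zc - 0.25 * params$tube_length)
  )
}

# Fine boundary sampling of a structure's cross-section in one plane,
# returning 2D points (mm) whose convex hull supports the Feret diameter.
plane_section_points <- function(geom, structure, modality, plane,
                                 n_samp = 501L) {
  ax <- geom$canal_semiaxes[[modality]]
  z <- seq(geom$zrange[1], geom$zrange[2], length.out = n_samp)
  if (structure == "IAC") {
    cxy <- geom$canal_center
    switch(plane,
      coronal = {
        th <- seq(0, 2 * pi, length.out = n_samp)
        cbind(cxy[1] + ax[1] * cos(th), cxy[2] + ax[2] * sin(th))
      },
      axial = rbind(cbind(cxy[1] - ax[1], z), cbind(cxy[1] + ax[1], z)),
      sagittal = rbind(cbind(cxy[2] - ax[2], z), cbind(cxy[2] + ax[2], z)))
  } else {
    r <- geom$nerve_radius
    xs <- geom$nerve_x(z)
    switch(plane,
      coronal = {
        th <- seq(0, 2 * pi, length.out = n_samp)
        zs <- mean(geom$site_z)
        cbind(geom$nerve_x(zs) + r * cos(th), geom$nerve_y + r * sin(th))
      },
      axial = rbind(cbind(xs - r, z), cbind(xs + r, z)),
      sagittal = {
        # plane x = nerve center at the site; undulation can move the
        # course out of plane, shrinking the in-plane half-width
        x0 <- geom$nerve_x(mean(geom$site_z))
        dx <- xs - x0
        keep <- abs(dx) <= r
        if (!any(keep)) return(NULL)
        w <- sqrt(pmax(r^2 - dx[keep]^2, 0))
        rbind(cbind(geom$nerve_y - w, z[keep]),
              cbind(geom$nerve_y + w, z[keep]))
      })
  }
}

# Analytic maximum Feret diameter per structure/modality/plane.
analytic_true_diameters <- function(geom) {
  rows <- list()
  combos <- rbind(
    data.frame(structure = "IAC", modality = c("CBCT", "MRI")),
    data.frame(structure = "IAN", modality = "MRI"))
  for (k in seq_len(nrow(combos))) {
    st <- combos$structure[k]; mo <- combos$modality[k]
    for (pl in c("axial", "sagittal", "coronal")) {
      pts <- plane_section_points(geom, st, mo, pl)
      d <- if (is.null(pts)) NA_real_ else feret_diameter(pts)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = st, modality = mo, plane = pl, diameter_mm = d,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# --- Rasterization ---------------------------------------------------------

new_image_volume <- function(data, spacing, modality, reference_slices) {
  structure(list(
    data = data, spacing = spacing,
    axis_labels = c(x = "buccolingual", y = "superoinferior",
                    z = "mesiodistal"),
    modality = modality,
    reference_slices = reference_slices), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %s voxels, %.3g mm isotropic\n",
              x$modality, paste(dim(x$data), collapse = " x "),
              x$spacing))
  invisible(x)
}

rasterize_volume <- function(params, geom, modality) {
  s <- if (modality == "MRI") params$mri_spacing else params$cbct_spacing
  ext <- geom$extent
  n <- c(round(ext[1] / s), round(ext[2] / s),
         if (modality == "MRI") params$n_slices else round(ext[3] / s))
  xs <- axis_centers(n[1], s); ys <- axis_centers(n[2], s)
  zs <- axis_centers(n[3], s)
  ax <- geom$canal_semiaxes[[modality]]
  axo <- ax + params$cortical_thickness
  cx <- geom$canal_center[1]; cy <- geom$canal_center[2]
  I <- params$intensities
  bg <- if (modality == "MRI") I$mri_background else I$cbct_background
  vol <- array(bg, dim = n)
  X <- matrix(xs, n[1], n[2])
  Y <- matrix(ys, n[1], n[2], byrow = TRUE)
  in_outer <- ((X - cx) / axo[1])^2 + ((Y - cy) / axo[2])^2 <= 1
  in_inner <- ((X - cx) / ax[1])^2 + ((Y - cy) / ax[2])^2 <= 1
  ring <- in_outer & !in_inner
  sigma_px <- params$nerve_blur_sigma / s
  cap <- c(geom$zrange[1] - params$cortical_thickness,
           geom$zrange[2] + params$cortical_thickness)
  cort <- if (modality == "MRI") I$mri_cortical else I$cbct_cortical
  for (k in seq_len(n[3])) {
    z <- zs[k]
    if (z < cap[1] || z > cap[2]) next
    if (z < geom$zrange[1] || z > geom$zrange[2]) {
      # cortical end caps close the canal mesiodistally
      sl <- matrix(bg, n[1], n[2])
      sl[in_outer] <- cort
      vol[, , k] <- sl
      next
    }
    sl <- matrix(bg, n[1], n[2])
    if (modality == "MRI") {
      sl[ring] <- I$mri_cortical
      if (params$nerve_radius > 0) {
        nx <- geom$nerve_x(z)
        nerve <- (X - nx)^2 + (Y - geom$nerve_y)^2 <= geom$nerve_radius^2
        sl <- sl + (I$mri_nerve - bg) * gauss_blur2d(nerve + 0, sigma_px)
      }
    } else {
      sl[in_inner] <- I$cbct_interior
      sl[ring] <- I$cbct_cortical
    }
    vol[, , k] <- sl
  }
  ref <- vapply(geom$site_z, function(z) mm_to_index(z, s, n[3]), 1L)
  new_image_volume(vol, s, modality, ref)
}

#' Generate one synthetic subject side
#'
#' Renders the paired MRI-like and CBCT-like volumes of a single subject
#' side together with its fully known ground truth (analytic region
#' descriptors, landmarks and true per-plane maximum diameters). The MRI
#' volume shows a dark cortical ring and a hyperintense nerve; the CBCT
#' volume shows a bright cortical ring and no nerve contrast. Output is
#' deterministic given `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @param side `"left"` or `"right"`; the right side mirrors the
#'   buccolingual axis.
#' @param subject_id identifier stored in the truth.
#' @param retention_label opaque stratification category.
#' @return A list with elements `mri`, `cbct` (class `image_volume`) and
#'   `truth` (class `phantom_truth`).
#' @export
generate_subject_side <- function(params, side = "left", subject_id = "S01",
                                  retention_label = "none") {
  validate_phantom_params(params)
  if (!side %in% c("left", "right"))
    stop_parameter("side must be 'left' or 'right'")
  geom <- phantom_geometry(params, side)
  mri  <- rasterize_volume(params, geom, "MRI")
  cbct <- rasterize_volume(params, geom, "CBCT")
  if (params$noise_sd > 0) {
    with_seed(params$seed, {
      mri$data  <- mri$data +
        array(stats::rnorm(length(mri$data), 0, params$noise_sd),
              dim = dim(mri$data))
      cbct$data <- cbct$data +
        array(stats::rnorm(length(cbct$data), 0, params$noise_sd),
              dim = dim(cbct$data))
    })
  }
  landmarks <- lapply(names(geom$site_z), function(site) {
    z <- geom$site_z[[site]]
    list(site = site, z_mm = z,
         crest_mm = geom$crest,
         nerve_midpoint_mm = c(geom$nerve_x(z), geom$nerve_y),
         canal_seed_mm = canal_seed_point(params, geom, z))
  })
  names(landmarks) <- names(geom$site_z)
  truth <- structure(list(
    params = params, side = side, subject_id = subject_id,
    retention_label = retention_label,
    geometry = geom,
    canal_region = list(center = geom$canal_center,
                        semiaxes = geom$canal_semiaxes,
                        zrange = geom$zrange),
    nerve_region = list(x = geom$nerve_x, y = geom$nerve_y,
                        radius = geom$nerve_radius, zrange = geom$zrange),
    landmarks = landmarks,
    true_diameters = analytic_true_diameters(geom)),
    class = "phantom_truth")
  list(mri = mri, cbct = cbct, truth = truth)
}

# A canal-interior seed point away from the nerve and the cortical ring:
# search candidates on shrunken ellipses and maximize the clearance from
# the nerve boundary.
canal_seed_point <- function(params, geom, z_mm) {
  ax <- geom$canal_semiaxes[["MRI"]]
  c0 <- geom$canal_center
  nx <- geom$nerve_x(z_mm); ny <- geom$nerve_y
  r <- params$nerve_radius
  th <- seq(0, 2 * pi, length.out = 17L)[-17L]
  cand <- do.call(rbind, lapply(c(0, 0.35, 0.5, 0.65), function(f)
    cbind(c0[1] + f * ax[1] * cos(th), c0[2] + f * ax[2] * sin(th))))
  clearance <- sqrt((cand[, 1] - nx)^2 + (cand[, 2] - ny)^2) - r
  best <- which.max(clearance)
  c(cand[best, ], z_mm)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> subject %s, %s side, retention '%s'\n",
              x$subject_id, x$side, x$retention_label))
  cat(sprintf("  canal semiaxes (CBCT) %.2f x %.2f mm, nerve radius %.2f mm\n",
              x$geometry$canal_semiaxes$CBCT[1],
              x$geometry$canal_semiaxes$CBCT[2], x$geometry$nerve_radius))
  invisible(x)
}

# --- Cohort generation -----------------------------------------------------

#' Default cohort parameter distributions
#'
#' Gaussian subject-level distributions for the phantom parameters,
#' calibrated to published canal/nerve morphometry (canal 3.9 +/- 0.85 mm
#' buccolingually and 5.3 +/- 1.03 mm superoinferiorly, i.e. semiaxis SDs
#' of about 0.42/0.52 mm). `asymmetry_sd` jitters the two sides of one
#' subject independently; `missing_side_prob` models absent third molars
#' (2 of 38 sides by default). Draws violating the nerve-fit invariant are
#' clamped back inside the canal.
#'
#' @param canal_semiaxes,nerve_radius,nerve_offset,crest_height lists with
#'   `mean` and `sd` entries (vectors where the parameter is a pair).
#' @param asymmetry_sd numeric, SD (mm) of the left/right anatomical jitter.
#' @param missing_side_prob probability that a side is absent.
#' @param retention_levels,retention_probs stratification label distribution
#'   for present sides.
#' @return A list of distribution specifications for [generate_cohort()].
#' @export
cohort_distributions <- function(
    canal_semiaxes = list(mean = c(1.95, 2.65), sd = c(0.42, 0.52)),
    nerve_radius = list(mean = 1.3, sd = 0.25),
    nerve_offset = list(mean = c(0.3, -0.5), sd = c(0.45, 0.45)),
    crest_height = list(mean = 8, sd = 1),
    undulation_amplitude = list(mean = 0.3, sd = 0.15),
    asymmetry_sd = 0.1,
    missing_side_prob = 2 / 38,
    retention_levels = c("type3", "type4", "type5", "none"),
    retention_probs = c(11, 19, 2, 4) / 36) {
  d <- list(canal_semiaxes = canal_semiaxes, nerve_radius = nerve_radius,
            nerve_offset = nerve_offset, crest_height = crest_height,
            undulation_amplitude = undulation_amplitude,
            asymmetry_sd = asymmetry_sd,
            missing_side_prob = missing_side_prob,
            retention_levels = retention_levels,
            retention_probs = retention_probs)
  sds <- c(canal_semiaxes$sd, nerve_radius$sd, nerve_offset$sd,
           crest_height$sd, asymmetry_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop_parameter("distribution SDs must be non-negative")
  if (missing_side_prob < 0 || missing_side_prob >= 1)
    stop_parameter("missing_side_prob must be in [0, 1)")
  d
}

# Clamp sampled geometry back to the nerve-fit invariant.
clamp_side_params <- function(a, b, r, off, amp = 0) {
  a <- max(a, 0.8); b <- max(b, 0.8)
  r <- min(max(r, 0.2), 0.85 * min(a, b))
  amp <- min(max(amp, 0), max(a - r - 0.1, 0) / 2)
  off[1] <- sign(off[1]) * min(abs(off[1]), a - r - amp - 0.05)
  off[2] <- sign(off[2]) * min(abs(off[2]), b - r - 0.05)
  list(a = a, b = b, r = r, off = off, amp = amp)
}

#' Generate a reproducible phantom cohort
#'
#' Draws subject-level anatomy from `distributions`, realizes up to two
#' sides per subject (left/right mirrored, with independent asymmetry
#' jitter and an optional missing-side probability), and assigns each
#' present side a retention label and a private volume seed. Volumes are
#' realized lazily with [generate_subject_side()] so a cohort object stays
#' small.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param distributions a [cohort_distributions()] list.
#' @param seed integer cohort seed.
#' @param base_params a [phantom_params()] object supplying all
#'   non-sampled parameters (spacings, noise, intensities, ...).
#' @return An object of class `phantom_cohort`: a list with `sides` (one
#'   entry per present subject side, each carrying `subject_id`, `side`,
#'   `retention_label` and a ready `phantom_params`), plus bookkeeping.
#' @export
generate_cohort <- function(n_subjects, distributions = cohort_distributions(),
                            seed = 1L, base_params = phantom_params()) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_parameter("n_subjects must be >= 1")
  n_subjects <- as.integer(n_subjects)
  d <- distributions
  sides <- list()
  with_seed(seed, {
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", i)
      a0 <- stats::rnorm(1, d$canal_semiaxes$mean[1], d$canal_semiaxes$sd[1])
      b0 <- stats::rnorm(1, d$canal_semiaxes$mean[2], d$canal_semiaxes$sd[2])
      r0 <- stats::rnorm(1, d$nerve_radius$mean, d$nerve_radius$sd)
      off0 <- stats::rnorm(2, d$nerve_offset$mean, d$nerve_offset$sd)
      ch0 <- stats::rnorm(1, d$crest_height$mean, d$crest_height$sd)
      amp0 <- if (is.null(d$undulation_amplitude)) 0 else
        stats::rnorm(1, d$undulation_amplitude$mean,
                     d$undulation_amplitude$sd)
      for (side in c("left", "right")) {
        present <- stats::runif(1) >= d$missing_side_prob
        jit <- stats::rnorm(6, 0, d$asymmetry_sd)
        ret <- sample(d$retention_levels, 1, prob = d$retention_probs)
        vseed <- sample.int(.Machine$integer.max - 1L, 1)
        if (!present) next
        g <- clamp_side_params(a0 + jit[1], b0 + jit[2], r0 + jit[3],
                               off0 + jit[4:5], amp0)
        p <- base_params
        p$canal_semiaxes <- c(g$a, g$b)
        p$nerve_radius <- g$r
        p$nerve_offset <- g$off
        p$undulation_amplitude <- g$amp
        p$crest_height <- max(ch0 + jit[6], 4)
        p$seed <- vseed
        validate_phantom_params(p)
        sides[[length(sides) + 1L]] <- list(
          subject_id = sid, side = side, retention_label = ret, params = p)
      }
    }
  })
  structure(list(sides = sides, n_subjects = n_subjects, seed = seed,
                 distributions = d, base_params = base_params),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, %d evaluated sides (seed %d)\n",
              x$n_subjects, length(x$sides), x$seed))
  invisible(x)
}

# --- Analytic occupancy oracle --------------------------------------------

#' Ground-truth segment occupancy by quadrature
#'
#' Computes the per-segment nerve fill fractions of a phantom truth at one
#' site by fine-grid numerical integration over the analytic canal ellipse
#' and nerve disk, using the analytic chord of the midline through the
#' ellipse (solved in closed form) rather than any rasterized mask. This
#' is the independent oracle for the raster occupancy pipeline.
#'
#' @param truth a `phantom_truth`.
#' @param site `"M3"` or `"M2"`.
#' @param partition_rule `"chord_thirds"` (equal thirds of the midline
#'   chord) or `"bbox_thirds"` (thirds of the projected extent; identical
#'   for an ellipse).
#' @param n_grid quadrature grid resolution per axis.
#' @return An `occupancy_record` whose fractions carry an
#'   `integration_tolerance` attribute (an upper bound from the boundary
#'   cell count).
#' @export
truth_occupancy <- function(truth, site = "M3",
                            partition_rule = "chord_thirds",
                            n_grid = 1200L) {
  geom <- truth$geometry
  lm <- truth$landmarks[[site]]
  if (is.null(lm)) stop_parameter(sprintf("unknown site '%s'", site))
  ax <- geom$canal_semiaxes[["MRI"]]
  c0 <- geom$canal_center
  nx <- lm$nerve_midpoint_mm[1]; ny <- lm$nerve_midpoint_mm[2]
  r <- geom$nerve_radius
  xs <- seq(c0[1] - ax[1], c0[1] + ax[1], length.out = n_grid)
  ys <- seq(c0[2] - ax[2], c0[2] + ax[2], length.out = n_grid)
  X <- matrix(xs, n_grid, n_grid)
  Y <- matrix(ys, n_grid, n_grid, byrow = TRUE)
  in_canal <- ((X - c0[1]) / ax[1])^2 + ((Y - c0[2]) / ax[2])^2 <= 1
  in_nerve <- r > 0 & ((X - nx)^2 + (Y - ny)^2 <= r^2)
  # analytic chord: intersection of the midline (through the nerve
  # midpoint, horizontal baseline orientation) with the ellipse
  if (abs(ny - c0[2]) >= ax[2])
    stop_geometry("midline does not intersect the canal ellipse")
  half <- if (identical(partition_rule, "bbox_thirds")) ax[1] else
    ax[1] * sqrt(1 - ((ny - c0[2]) / ax[2])^2)
  bs <- geom$buccal_sign
  # t measured along the buccal direction from the nerve midpoint
  t_ends <- sort(bs * (c(c0[1] - half, c0[1] + half) - nx))
  cuts <- t_ends[1] + diff(t_ends) * c(1, 2) / 3
  t <- bs * (X - nx)
  lateral <- ifelse(t > cuts[2], 1L, ifelse(t < cuts[1], 3L, 2L))
  seg <- ifelse(Y - ny > 0, lateral, lateral + 3L)
  frac <- numeric(6)
  for (s in 1:6) {
    in_seg <- in_canal & seg == s
    ns <- sum(in_seg)
    frac[s] <- if (ns == 0) 0 else sum(in_seg & in_nerve) / ns
  }
  # boundary-cell bound: O(n_grid) straddling cells against a one-sixth
  # share of the O(n_grid^2) canal area
  tol <- 16 / n_grid
  attr(frac, "integration_tolerance") <- tol
  new_occupancy_record(
    subject_id = truth$subject_id, side = truth$side, site = site,
    fractions = frac, threshold = 0.5,
    retention_label = truth$retention_label,
    method = sprintf("quadrature(n_grid=%d, rule=%s)", n_grid,
                     partition_rule))
}
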