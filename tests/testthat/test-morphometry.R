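# Region-growing segmentation and Feret-diameter morphometry.

make_mask <- function(arr, spacing, structure = "IAC", modality = "CBCT") {
  structure(list(mask = arr, spacing = spacing, structure = structure,
                 modality = modality, seed_mm = c(0, 0, 0),
                 params_used = list()), class = "structure_mask")
}

test_that("analytic shapes give their known diameters", {
  s <- 0.1
  n <- 61
  xs <- (seq_len(n) - 0.5) * s
  ctr <- rep(n / 2 * s, 3)
  # sphere of radius r: all three diameters = 2r within a pixel diagonal
  r <- 2.2
  X <- array(xs, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  sphere <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= r^2
  d <- max_plane_diameters(make_mask(sphere, s), ctr)
  for (v in c(d$d_axial, d$d_sagittal, d$d_coronal))
    expect_lt(abs(v - 2 * r), sqrt(2) * s)
  # axis-aligned elliptical tube: coronal diameter = 2a
  a <- 2.5; b <- 1.4
  tube <- (X - ctr[1])^2 / a^2 + (Y - ctr[2])^2 / b^2 <= 1
  d2 <- max_plane_diameters(make_mask(tube, s), ctr)
  expect_lt(abs(d2$d_coronal - 2 * a), sqrt(2) * s)
})

test_that("feret matches the pairwise-corner-distance oracle exactly", {
  set.seed(5)
  s <- 0.1
  for (rep_i in 1:6) {
    n <- 40
    xs <- (seq_len(n) - 0.5) * s
    X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
    th <- stats::runif(1, 0, pi)
    a <- stats::runif(1, 0.6, 1.8); b <- stats::runif(1, 0.4, 1.2)
    ctr <- c(2, 2)
    Xr <- (X - ctr[1]) * cos(th) + (Y - ctr[2]) * sin(th)
    Yr <- -(X - ctr[1]) * sin(th) + (Y - ctr[2]) * cos(th)
    mask <- (Xr / a)^2 + (Yr / b)^2 <= 1
    pts <- which(mask, arr.ind = TRUE)
    impl <- feret_diameter((pts - 0.5) * s, pixel_size = s)
    expect_equal(impl, brute_force_feret(mask, c(s, s)), tolerance = 1e-12)
  }
})

test_that("rotated ellipsoid diameters match the brute-force oracle", {
  s <- 0.12; n <- 45
  xs <- (seq_len(n) - 0.5) * s
  X <- array(xs, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  ctr <- rep(n / 2 * s, 3)
  th <- 0.5
  Xr <- (X - ctr[1]) * cos(th) + (Z - ctr[3]) * sin(th)
  Zr <- -(X - ctr[1]) * sin(th) + (Z - ctr[3]) * cos(th)
  ell <- (Xr / 2)^2 + ((Y - ctr[2]) / 1.1)^2 + (Zr / 1.6)^2 <= 1
  sm <- make_mask(ell, s)
  d <- max_plane_diameters(sm, ctr)
  iz <- iansegmap:::mm_to_index(ctr[3], s, n)
  iy <- iansegmap:::mm_to_index(ctr[2], s, n)
  ix <- iansegmap:::mm_to_index(ctr[1], s, n)
  expect_equal(d$d_coronal, brute_force_feret(ell[, , iz], c(s, s)),
               tolerance = 1e-12)
  expect_equal(d$d_axial, brute_force_feret(ell[, iy, ], c(s, s)),
               tolerance = 1e-12)
  expect_equal(d$d_sagittal, brute_force_feret(ell[ix, , ], c(s, s)),
               tolerance = 1e-12)
})

test_that("nerve segmentation is refused on CBCT", {
  p <- phantom_params()
  v <- generate_subject_side(p, "left", "S01")
  expect_error(
    segment_structure(v$cbct, v$truth$landmarks$M3$nerve_midpoint_mm,
                      "IAN"),
    class = "modality_error")
})

test_that("background seeds leak or fail, canal seeds segment cleanly", {
  p <- phantom_params(noise_sd = 0)
  v <- generate_subject_side(p, "left", "S01")
  expect_error(
    segment_structure(v$mri, c(1, 16, 5), "IAC"),
    class = "leakage_error")
  sm <- segment_structure(v$mri, v$truth$landmarks$M3$canal_seed_mm, "IAC")
  expect_true(sm$mask[
    iansegmap:::mm_to_index(sm$seed_mm[1], sm$spacing),
    iansegmap:::mm_to_index(sm$seed_mm[2], sm$spacing),
    iansegmap:::mm_to_index(sm$seed_mm[3], sm$spacing)])
})

test_that("noiseless canal segmentation overlaps the true raster", {
  p <- phantom_params(noise_sd = 0)
  v <- generate_subject_side(p, "left", "S01")
  geom <- v$truth$geometry
  for (mod in c("cbct", "mri")) {
    vol <- v[[mod]]
    sm <- segment_structure(vol, v$truth$landmarks$M3$canal_seed_mm, "IAC")
    s <- vol$spacing
    dims <- dim(vol$data)
    ax <- geom$canal_semiaxes[[toupper(mod)]]
    xs <- (seq_len(dims[1]) - 0.5) * s
    ys <- (seq_len(dims[2]) - 0.5) * s
    zs <- (seq_len(dims[3]) - 0.5) * s
    X <- matrix(xs, dims[1], dims[2])
    Y <- matrix(ys, dims[1], dims[2], byrow = TRUE)
    in2d <- ((X - geom$canal_center[1]) / ax[1])^2 +
      ((Y - geom$canal_center[2]) / ax[2])^2 <= 1
    truth <- array(FALSE, dims)
    for (k in which(zs >= geom$zrange[1] & zs <= geom$zrange[2]))
      truth[, , k] <- in2d
    dice <- 2 * sum(sm$mask & truth) / (sum(sm$mask) + sum(truth))
    expect_gte(dice, 0.95)
  }
})

test_that("nerve diameters never exceed canal diameters on phantoms", {
  for (seed in c(2, 9)) {
    coh <- generate_cohort(1, seed = seed)
    b <- coh$sides[[1]]
    v <- generate_subject_side(b$params, b$side, b$subject_id)
    ms <- measure_site(v, "M3")
    d <- ms$diameters
    for (pl in c("axial", "sagittal", "coronal")) {
      ian <- d$diameter_mm[d$structure == "IAN" & d$plane == pl]
      iac <- d$diameter_mm[d$structure == "IAC" & d$modality == "MRI" &
                             d$plane == pl]
      expect_lte(ian, iac + 1e-9)
    }
  }
})

test_that("vanished nerve surfaces an error while the canal is measured", {
  p <- phantom_params(nerve_radius = 0, noise_sd = 0)
  v <- generate_subject_side(p, "left", "S01")
  ms <- measure_site(v, "M3")
  expect_true("ian_mri" %in% names(ms$errors))
  expect_true(all(c("IAC") %in% ms$diameters$structure))
  expect_false("IAN" %in% ms$diameters$structure)
})

test_that("measured diameters track truth within a voxel across planes", {
  p <- phantom_params(noise_sd = 0,
                      canal_semiaxes = c(1.95, 5.49 / 2))
  v <- generate_subject_side(p, "left", "S01")
  ms <- measure_site(v, "M3")
  d <- ms$diameters
  td <- v$truth$true_diameters
  for (k in seq_len(nrow(d))) {
    tv <- td$diameter_mm[td$structure == d$structure[k] &
                           td$modality == d$modality[k] &
                           td$plane == d$plane[k]]
    vox <- if (d$modality[k] == "CBCT") p$cbct_spacing else p$mri_spacing
    expect_lt(abs(d$diameter_mm[k] - tv), sqrt(2) * vox + 1e-9)
  }
  # the 5.49 mm coronal canal calibration case, within one MRI voxel
  m_cor <- d$diameter_mm[d$structure == "IAC" & d$modality == "MRI" &
                           d$plane == "coronal"]
  expect_lt(abs(m_cor - 5.49), 0.75 + 1e-9)
})

test_that("diameter error shrinks as the grid is refined", {
  p1 <- phantom_params(noise_sd = 0, cbct_spacing = 0.32)
  p2 <- phantom_params(noise_sd = 0, cbct_spacing = 0.16)
  err <- vapply(list(p1, p2), function(p) {
    v <- generate_subject_side(p, "left", "S01")
    sm <- segment_structure(v$cbct, v$truth$landmarks$M3$canal_seed_mm,
                            "IAC")
    ds <- max_plane_diameters(sm, c(v$truth$geometry$canal_center,
                                    v$truth$landmarks$M3$z_mm))
    td <- v$truth$true_diameters
    tv <- td$diameter_mm[td$structure == "IAC" & td$modality == "CBCT" &
                           td$plane == "coronal"]
    abs(ds$d_coronal - tv)
  }, numeric(1))
  expect_lt(err[1], sqrt(2) * 0.32)
  expect_lt(err[2], sqrt(2) * 0.16)
})
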