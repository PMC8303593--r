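# Independent oracles and fixture builders, deliberately written as plain
# scalar loops so they share no code path with the vectorized
# implementation they check.

# Brute-force per-pixel three-line classifier: for every canal pixel,
# evaluate the midline side test and the two perpendicular tests with
# scalar arithmetic, using the same chord definition (fine marching along
# the midline) implemented independently.
brute_force_partition <- function(slice, rule = "chord_thirds") {
  m <- slice$iac_mask
  sp <- slice$spacing
  mid <- slice$nerve_midpoint_mm
  th <- slice$baseline_angle_deg * pi / 180
  u <- c(cos(th), sin(th))
  nv <- c(-sin(th), cos(th))
  if ((nv[1] * (slice$crest_mm[1] - mid[1]) +
       nv[2] * (slice$crest_mm[2] - mid[2])) < 0) nv <- -nv
  bd <- slice$buccal_direction
  ub <- if ((u[1] * bd[1] + u[2] * bd[2]) >= 0) u else -u
  # chord endpoints by scalar marching
  diag_mm <- sqrt((nrow(m) * sp[1])^2 + (ncol(m) * sp[2])^2)
  step <- 0.25 * min(sp)
  tlo <- NA; thi <- NA
  for (t in seq(-diag_mm, diag_mm, by = step)) {
    qx <- mid[1] + t * ub[1]; qy <- mid[2] + t * ub[2]
    i <- floor(qx / sp[1]) + 1; j <- floor(qy / sp[2]) + 1
    if (i >= 1 && i <= nrow(m) && j >= 1 && j <= ncol(m) && m[i, j]) {
      if (is.na(tlo)) tlo <- t
      thi <- t
    }
  }
  if (rule == "bbox_thirds") {
    tlo <- Inf; thi <- -Inf
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (!m[i, j]) next
      t <- ((i - 0.5) * sp[1] - mid[1]) * ub[1] +
           ((j - 0.5) * sp[2] - mid[2]) * ub[2]
      if (t < tlo) tlo <- t
      if (t > thi) thi <- t
    }
  }
  c1 <- tlo + (thi - tlo) / 3
  c2 <- tlo + 2 * (thi - tlo) / 3
  labels <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!m[i, j]) next
    px <- (i - 0.5) * sp[1]; py <- (j - 0.5) * sp[2]
    d <- (px - mid[1]) * nv[1] + (py - mid[2]) * nv[2]
    t <- (px - mid[1]) * ub[1] + (py - mid[2]) * ub[2]
    lat <- if (t > c2) 1L else if (t < c1) 3L else 2L
    labels[i, j] <- if (d > 0) lat else lat + 3L
  }
  labels
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the observed |differences| (zeros dropped).
enumerate_signed_rank_p <- function(d) {
  x <- d[d != 0]
  n <- length(x)
  r <- rank(abs(x))
  W_obs <- sum(r[x > 0])
  W_all <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    w <- 0
    for (k in seq_len(n)) if (bitwAnd(code, bitwShiftL(1L, k - 1L)) != 0)
      w <- w + r[k]
    W_all[code + 1] <- w
  }
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force Feret diameter: maximum pairwise distance over every
# boundary-pixel corner (matching the pixel-square support).
brute_force_feret <- function(section_mask, spacing) {
  pts <- NULL
  nr <- nrow(section_mask); nc <- ncol(section_mask)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!section_mask[i, j]) next
    boundary <- i == 1 || j == 1 || i == nr || j == nc ||
      !section_mask[i - 1, j] || !section_mask[i + 1, j] ||
      !section_mask[i, j - 1] || !section_mask[i, j + 1]
    if (boundary)
      pts <- rbind(pts,
                   cbind((i - 1 + c(0, 0, 1, 1)) * spacing[1],
                         (j - 1 + c(0, 1, 0, 1)) * spacing[2]))
  }
  if (is.null(pts) || nrow(pts) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    d2 <- (pts[-(1:i), 1] - pts[i, 1])^2 + (pts[-(1:i), 2] - pts[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Random elliptical reference slices for property tests.
random_reference_slice <- function(seed, spacing = NULL, angle = NULL) {
  set.seed(seed)
  sp <- spacing %||% stats::runif(1, 0.08, 0.25)
  a <- stats::runif(1, 0.9, 3)
  b <- stats::runif(1, 0.9, 3)
  th <- (angle %||% stats::runif(1, -30, 30)) * pi / 180
  margin <- 0.5
  ext <- 2 * (max(a, b) + margin)
  n <- ceiling(ext / sp)
  c0 <- c(ext / 2, ext / 2)
  xs <- (seq_len(n) - 0.5) * sp
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  # ellipse rotated by th
  Xr <- (X - c0[1]) * cos(th) + (Y - c0[2]) * sin(th)
  Yr <- -(X - c0[1]) * sin(th) + (Y - c0[2]) * cos(th)
  mask <- (Xr / a)^2 + (Yr / b)^2 <= 1
  # midpoint: random interior point (in the rotated frame), snapped inside
  repeat {
    mr <- c(stats::runif(1, -0.6 * a, 0.6 * a),
            stats::runif(1, -0.6 * b, 0.6 * b))
    mid <- c0 + c(mr[1] * cos(th) - mr[2] * sin(th),
                  mr[1] * sin(th) + mr[2] * cos(th))
    i <- floor(mid[1] / sp) + 1; j <- floor(mid[2] / sp) + 1
    if (i >= 1 && i <= n && j >= 1 && j <= n && mask[i, j]) break
  }
  nv <- c(-sin(th), cos(th))
  crest <- mid + (max(a, b) + 2) * nv
  reference_slice(iac_mask = mask, spacing = c(sp, sp),
                  side = if (seed %% 2 == 0) "left" else "right",
                  site = "M3", crest_mm = crest, nerve_midpoint_mm = mid,
                  baseline_angle_deg = th * 180 / pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small occupancy record for table tests.
make_record <- function(visible, subject = "S01", side = "left",
                        site = "M3", retention = "none") {
  frac <- ifelse(as.logical(visible), 1, 0)
  score_record <- iansegmap:::new_occupancy_record(
    subject_id = subject, side = side, site = site, fractions = frac,
    threshold = 0.5, retention_label = retention)
  score_record
}
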