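# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so that seeded generation
#' inside the package never disturbs the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Physical coordinate of pixel/voxel centers along one axis (1-based index).
axis_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# Map a physical coordinate (mm) to the 1-based index of the containing voxel.
mm_to_index <- function(x_mm, spacing, n = NULL) {
  i <- floor(x_mm / spacing) + 1L
  if (!is.null(n)) i <- pmin(pmax(i, 1L), as.integer(n))
  as.integer(i)
}

# Condition constructors: all package errors share the "iansegmap_error"
# class so callers can catch pipeline-stage failures uniformly.
ian_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "iansegmap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_parameter    <- function(msg) ian_stop(msg, "parameter_error")
stop_landmark     <- function(msg) ian_stop(msg, "landmark_error")
stop_geometry     <- function(msg) ian_stop(msg, "geometry_error")
stop_shape        <- function(msg) ian_stop(msg, "shape_error")
stop_modality     <- function(msg) ian_stop(msg, "modality_error")
stop_leakage      <- function(msg) ian_stop(msg, "leakage_error")
stop_segmentation <- function(msg) ian_stop(msg, "segmentation_failure")
stop_site         <- function(msg) ian_stop(msg, "site_error")
stop_data         <- function(msg) ian_stop(msg, "data_error")
stop_input        <- function(msg) ian_stop(msg, "input_error")
stop_io           <- function(msg) ian_stop(msg, "io_error")
stop_metadata     <- function(msg) ian_stop(msg, "metadata_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable 2D Gaussian smoothing on a matrix (zero-padded borders).
# Used for the blurred top-hat nerve signal; a no-op for tiny sigma.
gauss_blur2d <- function(m, sigma_px) {
  if (!is.finite(sigma_px) || sigma_px < 0.15) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  pad_conv <- function(v) {
    out <- numeric(length(v))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_along(v) + off
      ok <- src >= 1L & src <= length(v)
      out[ok] <- out[ok] + k[j] * v[src[ok]]
    }
    out
  }
  m2 <- matrix(apply(m, 2, pad_conv), nr, nc)
  t(matrix(apply(m2, 1, pad_conv), nc, nr))
}
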