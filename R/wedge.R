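#' Missing-wedge Fourier mask
#'
#' Builds the scalar Fourier-domain mask describing the information captured
#' by a single-axis tilt series with tilt axis y. A frequency voxel
#' `(kx, ky, kz)` is covered when some tilt angle in `[tilt_min, tilt_max]`
#' samples it, i.e. when `atan(-kz / kx)` (folded into (-90, 90]) lies inside
#' the tilt range; `ky` is unconstrained. The mask is Friedel symmetric and,
#' for a hard edge, binary with covered fraction
#' `(tilt_max - tilt_min) / 180`.
#'
#' The array is stored in the package's centred spectral layout (DC at
#' `floor(n/2) + 1`).
#'
#' @param tilt_min,tilt_max tilt range in degrees, `-90 < tilt_min <
#'   tilt_max < 90`.
#' @param shape grid dimensions (length 1 or 3).
#' @param soft_edge soft-edge width in voxels (cosine ramp along the wedge
#'   boundary, scaled with spatial frequency radius).
#' @return object of class `wedge_mask` with elements `tilt_min`, `tilt_max`,
#'   `shape`, `soft_edge`, `w` (the mask array).
#' @export
wedge_mask <- function(tilt_min, tilt_max, shape, soft_edge = 0) {
  if (!(tilt_min > -90 && tilt_max < 90 && tilt_min < tilt_max))
    stop("need -90 < tilt_min < tilt_max < 90", call. = FALSE)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  k <- freq_grids(shape)
  w <- wedge_values(k$kx, k$ky, k$kz, tilt_min, tilt_max, soft_edge)
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max, shape = shape,
                 soft_edge = soft_edge, w = array(w, shape)),
            class = "wedge_mask")
}

#' Angular coverage fraction of a wedge mask
#'
#' Fraction of covered Fourier voxels inside the inscribed Nyquist cylinder
#' of the (kx, kz) plane, where the angular measure is uniform; for a hard
#' mask this equals `(tilt_max - tilt_min) / 180` up to voxelization.
#'
#' @param wm a [wedge_mask()].
#' @return covered fraction in `[0, 1]`.
#' @export
wedge_coverage <- function(wm) {
  k <- freq_grids(wm$shape)
  r <- sqrt(k$kx^2 + k$kz^2)
  inside <- r <= min(wm$shape[c(1, 3)]) / 2 & r > 0
  mean(wm$w[inside])
}

# Analytic wedge weight at arbitrary frequency coordinates (any shape of
# numeric input, recycled elementwise). Used both to build masks and to
# evaluate a pose-rotated wedge exactly without interpolation.
wedge_values <- function(kx, ky, kz, tilt_min, tilt_max, soft_edge = 0) {
  theta <- atan2(-kz, kx) * 180 / pi
  theta[theta > 90] <- theta[theta > 90] - 180
  theta[theta <= -90] <- theta[theta <= -90] + 180
  dist_deg <- pmax(tilt_min - theta, theta - tilt_max, 0)
  # the wedge is 180-degree periodic in theta; consider the wrapped copy
  theta2 <- ifelse(theta > 0, theta - 180, theta + 180)
  dist2 <- pmax(tilt_min - theta2, theta2 - tilt_max, 0)
  dist_deg <- pmin(dist_deg, dist2)
  if (soft_edge <= 0) return(as.numeric(dist_deg == 0))
  r_xz <- sqrt(kx^2 + kz^2)
  arc <- r_xz * dist_deg * pi / 180   # boundary distance in voxels
  v <- 0.5 * (1 + cos(pi * pmin(arc / soft_edge, 1)))
  v[dist_deg == 0] <- 1
  v
}

# Wedge mask of a particle whose pose (reference -> particle) is R, expressed
# in the reference frame: W_ref(k) = W(R %*% k). Exact (analytic), no
# interpolation. Returns an array matching wm$shape.
wedge_array_rotated <- function(wm, R = NULL) {
  if (is.null(R)) return(wm$w)
  k <- freq_grids(wm$shape)
  kk <- rbind(as.vector(k$kx), as.vector(k$ky), as.vector(k$kz))
  kr <- R %*% kk
  array(wedge_values(kr[1, ], kr[2, ], kr[3, ],
                     wm$tilt_min, wm$tilt_max, wm$soft_edge), wm$shape)
}

# Apply a wedge filter to a real-space volume (returns density_volume)
apply_wedge <- function(v, wm) {
  stopifnot_volume(v)
  if (!all(dim(v$data) == wm$shape))
    stop("wedge shape does not match volume", call. = FALSE)
  density_volume(isfft(sfft(v$data) * wm$w), voxel_size = v$voxel_size,
                 origin = v$origin)
}
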