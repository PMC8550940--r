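# Real-space resampling built on the compiled kernel. All operations are
# about the grid centre (floor(n/2) + 1), the package-wide origin.

# "cubic" is an order-3 B-spline with recursive prefiltering (near-exact
# for band-limited data); set prefiltered = TRUE when `a` already holds
# B-spline coefficients (lets one prefilter serve many resamples).
affine_resample <- function(a, M, off = c(0, 0, 0),
                            interp = c("linear", "cubic"), fill = 0,
                            prefiltered = FALSE) {
  interp <- match.arg(interp)
  d <- dim(a)
  if (!prefiltered && all(M == diag(3)) && all(off == 0))
    return(a)                    # identity transform: exact by definition
  if (interp == "linear")
    return(.affine_resample_cpp(as.numeric(a), as.integer(d), M,
                                as.numeric(off), 0L, fill))
  cf <- if (prefiltered) as.numeric(a) else
    .bspline_prefilter_cpp(as.numeric(a), as.integer(d))
  .affine_resample_cpp(cf, as.integer(d), M, as.numeric(off), 2L, fill)
}

#' Rotate a volume about the grid centre
#'
#' `rotate_volume(v, R)` returns the volume rotated *by* `R`: the output at
#' position `x` samples the input at `R^-1 x`. `R` may be a 3x3 matrix or
#' ZYZ Euler angles in degrees.
#'
#' @param v a [density_volume].
#' @param R 3x3 rotation matrix or length-3 Euler `(rot, tilt, psi)`.
#' @param interp `"linear"` or `"cubic"`.
#' @return the rotated [density_volume].
#' @export
rotate_volume <- function(v, R, interp = "cubic") {
  stopifnot_volume(v)
  if (!is.matrix(R)) R <- euler_matrix(R)
  density_volume(affine_resample(v$data, t(R), interp = interp),
                 voxel_size = v$voxel_size, origin = v$origin)
}

# forward transform: place a reference into a particle's frame.
# out(x) = in(R^-1 (x - t)), t in voxels.
pose_transform <- function(a, R, t = c(0, 0, 0), interp = "linear") {
  Rt <- t(R)
  affine_resample(a, Rt, off = -as.vector(Rt %*% t), interp = interp)
}

# inverse transform: bring a posed particle back to the reference frame.
# out(y) = in(R y + t).
pose_untransform <- function(a, R, t = c(0, 0, 0), interp = "cubic") {
  affine_resample(a, R, off = as.numeric(t), interp = interp)
}

# trilinear sampling of an array at arbitrary 1-based voxel coordinates
# (N x 3 matrix); outside the grid -> 0
sample_trilinear <- function(a, coords) {
  .sample_trilinear_cpp(as.numeric(a), as.integer(dim(a)),
                        as.matrix(coords))
}
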