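#' Mask specification
#'
#' Geometric real-space masks shared by the averaging, refinement and
#' resolution stages. Geometry parameters are in Angstrom, measured from the
#' grid centre; the soft edge is a cosine ramp of the given width in voxels
#' appended outside the hard region.
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{sphere}{`radius`}
#'   \item{soft_sphere}{`radius` (identical to sphere; kept as an explicit
#'     label for masks meant to be used with a non-zero soft edge)}
#'   \item{cylinder}{`radius`, `half_height` (z extent +/- about the centre)}
#'   \item{ring_shell}{`r_inner`, `r_outer`, `z_min`, `z_max` (an annulus in
#'     cylindrical coordinates about the z axis)}
#' }
#'
#' @param kind one of `"sphere"`, `"soft_sphere"`, `"cylinder"`, `"ring_shell"`.
#' @param ... named geometric parameters in Angstrom (see above).
#' @param soft_edge soft-edge width in voxels (>= 0).
#' @return an object of class `mask_spec`.
#' @export
mask_spec <- function(kind = c("sphere", "soft_sphere", "cylinder",
                               "ring_shell"), ..., soft_edge = 0) {
  kind <- match.arg(kind)
  params <- list(...)
  if (soft_edge < 0) stop("`soft_edge` must be >= 0", call. = FALSE)
  need <- switch(kind,
                 sphere = "radius", soft_sphere = "radius",
                 cylinder = c("radius", "half_height"),
                 ring_shell = c("r_inner", "r_outer", "z_min", "z_max"))
  missing_p <- setdiff(need, names(params))
  if (length(missing_p))
    stop("mask_spec(", kind, ") needs parameters: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  if (kind %in% c("sphere", "soft_sphere") && params$radius <= 0)
    stop("mask radius must be > 0", call. = FALSE)
  if (kind == "cylinder" && (params$radius <= 0 || params$half_height <= 0))
    stop("cylinder radius and half_height must be > 0", call. = FALSE)
  structure(list(kind = kind, params = params, soft_edge = soft_edge),
            class = "mask_spec")
}

cosine_ramp <- function(d_out, width) {
  # d_out: distance (Angstrom) outside the hard region; width in Angstrom
  if (width <= 0) return(as.numeric(d_out <= 0))
  v <- 0.5 * (1 + cos(pi * pmin(pmax(d_out, 0) / width, 1)))
  v[d_out <= 0] <- 1
  v
}

#' Build a mask volume from a specification
#'
#' @param spec a [mask_spec()].
#' @param shape integer grid dimensions (length 1 or 3).
#' @param voxel_size voxel size in Angstrom.
#' @return a [density_volume] with values in `[0, 1]`; the hard region is 1
#'   and a cosine ramp of `spec$soft_edge` voxels falls to 0 outside it.
#' @export
make_mask <- function(spec, shape, voxel_size) {
  if (!inherits(spec, "mask_spec")) stop("`spec` must be a mask_spec",
                                         call. = FALSE)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  xs <- axis_coords(shape[1], voxel_size)
  ys <- axis_coords(shape[2], voxel_size)
  zs <- axis_coords(shape[3], voxel_size)
  r2 <- outer(xs^2, ys^2, "+")
  r_cyl <- sqrt(array(rep(r2, times = shape[3]), shape))   # radius about z
  zz <- array(rep(zs, each = shape[1] * shape[2]), shape)
  w <- spec$soft_edge * voxel_size
  p <- spec$params
  d_out <- switch(spec$kind,
    sphere = ,
    soft_sphere = sqrt(r_cyl^2 + zz^2) - p$radius,
    cylinder = pmax(r_cyl - p$radius, abs(zz) - p$half_height),
    ring_shell = {
      if (p$r_inner >= p$r_outer)
        warning("ring_shell with r_inner >= r_outer is empty")
      pmax(p$r_inner - r_cyl, r_cyl - p$r_outer, p$z_min - zz, zz - p$z_max)
    })
  m <- cosine_ramp(d_out, w)
  if (spec$kind == "ring_shell" && p$r_inner >= p$r_outer)
    m[] <- 0
  density_volume(array(m, shape), voxel_size = voxel_size)
}
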