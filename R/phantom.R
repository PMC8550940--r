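#' Parametric NPC phantom description
#'
#' Full parametric description of the phantom geometry and rendering. All
#' lengths are nm (the reporting unit for NPC geometry); angles in degrees.
#' Defaults encode the wild-type in-situ architecture: 105 nm
#' membrane-to-membrane pore diameter, 57 nm central channel, CR/NR distal
#' offsets of 37/29 nm above/below the IR midplane, and
#' asymmetric membrane angles of 42 (cytoplasmic) and 28 (nucleoplasmic)
#' degrees against the IR midplane.
#'
#' Rendering conventions (see the methods vignette): each ring is an analytic
#' C-n shape -- a Gaussian annulus in (r, z) whose inner/outer radial
#' half-maximum crossings coincide with `channel_diameter/2` and
#' `ir_outer_diameter/2` for the IR, multiplied by an azimuthal lobing factor
#' `1 + lobe_contrast * cos(n_subunits * phi)`. The membrane is a pair of
#' straight cones rising from the waist at the stated angles until the
#' distal-offset heights, then flat, with Gaussian cross-section of FWHM
#' `membrane_thickness`.
#'
#' @param membrane_pore_diameter NE-to-NE diameter at the narrowest point (nm).
#' @param channel_diameter IR inner channel diameter (nm).
#' @param ir_outer_diameter IR outer diameter (nm). The default keeps the
#'   IR slightly detached from the envelope so the membrane and IR radial
#'   landmarks stay separable at ~14 A sampling (in vivo the IR runs out to
#'   the membrane itself; a fully touching render would merge the two
#'   half-maximum landmarks into one unmeasurable ridge).
#' @param cr_distal_offset distance IR midplane -> CR distal end (nm).
#' @param nr_distal_offset distance IR midplane -> NR distal end (nm).
#' @param angle_cyto,angle_nucleo membrane angles vs the IR midplane (deg).
#' @param membrane_thickness membrane density FWHM (nm).
#' @param ring_thickness ring density FWHM (nm).
#' @param n_subunits rotational symmetry order (8 for the NPC).
#' @param present_rings subset of `c("CR", "IR", "NR")`.
#' @param density_scale overall density amplitude.
#' @param lobe_contrast azimuthal lobing amplitude in `[0, 1)`.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(membrane_pore_diameter = 105,
                           channel_diameter = 57,
                           ir_outer_diameter = 93,
                           cr_distal_offset = 37,
                           nr_distal_offset = 29,
                           angle_cyto = 42,
                           angle_nucleo = 28,
                           membrane_thickness = 7,
                           ring_thickness = 12,
                           n_subunits = 8,
                           present_rings = c("CR", "IR", "NR"),
                           density_scale = 1,
                           lobe_contrast = 0.5) {
  if (channel_diameter >= membrane_pore_diameter)
    stop("channel_diameter must be smaller than membrane_pore_diameter",
         call. = FALSE)
  if (!(angle_cyto > 0 && angle_cyto < 90 &&
        angle_nucleo > 0 && angle_nucleo < 90))
    stop("membrane angles must lie in (0, 90) degrees", call. = FALSE)
  if (n_subunits < 1) stop("n_subunits must be >= 1", call. = FALSE)
  if (!all(present_rings %in% c("CR", "IR", "NR")))
    stop("present_rings must be a subset of CR, IR, NR", call. = FALSE)
  if (lobe_contrast < 0 || lobe_contrast >= 1)
    stop("lobe_contrast must be in [0, 1)", call. = FALSE)
  structure(list(membrane_pore_diameter = membrane_pore_diameter,
                 channel_diameter = channel_diameter,
                 ir_outer_diameter = ir_outer_diameter,
                 cr_distal_offset = cr_distal_offset,
                 nr_distal_offset = nr_distal_offset,
                 angle_cyto = angle_cyto, angle_nucleo = angle_nucleo,
                 membrane_thickness = membrane_thickness,
                 ring_thickness = ring_thickness,
                 n_subunits = as.integer(n_subunits),
                 present_rings = unique(present_rings),
                 density_scale = density_scale,
                 lobe_contrast = lobe_contrast),
            class = "phantom_params")
}

#' Phantom presets
#'
#' `"wildtype"` is the native three-ring architecture (105/57 nm diameters,
#' 37/29 nm offsets, 42/28 degree membrane angles). `"constricted"` encodes
#' the earlier purified-envelope geometry (43 nm channel, 89 nm IR outer
#' diameter). `"class1"`, `"class2"`, `"class3"` are the scaffold-depletion
#' classes retaining `{CR, IR, NR}`, `{IR, NR}` and `{IR}`.
#'
#' @param name preset name.
#' @param ... overrides passed to [phantom_params()].
#' @return a [phantom_params()] object.
#' @export
npc_preset <- function(name = c("wildtype", "constricted", "class1",
                                "class2", "class3"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    wildtype = list(),
    constricted = list(channel_diameter = 43, ir_outer_diameter = 79),
    class1 = list(present_rings = c("CR", "IR", "NR")),
    class2 = list(present_rings = c("IR", "NR")),
    class3 = list(present_rings = "IR"))
  do.call(phantom_params, utils::modifyList(args, list(...)))
}

# Derived geometry in Angstrom shared by build_phantom, phantom_point_model
# and ring_shell_specs. half_c = sqrt(2 log 2): half-maximum offset per sigma.
phantom_geometry <- function(params) {
  half_c <- sqrt(2 * log(2))
  sz <- params$ring_thickness * 10 / (2 * half_c)        # axial ring sigma, A
  r_in <- params$channel_diameter * 10 / 2
  r_out <- params$ir_outer_diameter * 10 / 2
  r_ring <- (r_in + r_out) / 2
  sr_ir <- max((r_out - r_in) / (2 * half_c), sz)
  rings <- list(
    IR = list(r = r_ring, z = 0, sr = sr_ir, sz = sz, amp = 1),
    CR = list(r = r_ring, z = params$cr_distal_offset * 10 - half_c * sz,
              sr = sz, sz = sz, amp = 1),
    NR = list(r = r_ring, z = -(params$nr_distal_offset * 10 - half_c * sz),
              sr = sz, sz = sz, amp = 1))
  list(rings = rings,
       r_waist = params$membrane_pore_diameter * 10 / 2,
       sigma_mem = params$membrane_thickness * 10 / (2 * half_c),
       z_flat_cyto = params$cr_distal_offset * 10,
       z_flat_nucleo = params$nr_distal_offset * 10,
       amp_mem = 0.8)
}

# distance (A) of cylindrical points (r, z) to the membrane midline of one
# side: a straight cone from the waist at `angle`, flattening at z_flat
membrane_distance_side <- function(r, z, r_waist, angle_deg, z_flat, side) {
  th <- angle_deg * pi / 180
  ux <- cos(th); uz <- side * sin(th)
  L <- z_flat / sin(th)                       # cone segment length
  px <- r - r_waist; pz <- z
  proj <- pmin(pmax(px * ux + pz * uz, 0), L)
  d_cone <- sqrt((px - proj * ux)^2 + (pz - proj * uz)^2)
  r1 <- r_waist + z_flat / tan(th)            # cone -> flat transition radius
  d_flat <- sqrt(pmax(r1 - r, 0)^2 + (z - side * z_flat)^2)
  pmin(d_cone, d_flat)
}

#' Build an NPC phantom volume
#'
#' Renders the parametric phantom on a grid. The result is exactly
#' Cn-symmetric about z by construction (all components are analytic in
#' cylindrical coordinates), non-negative, and omitted rings leave no density
#' in their shells.
#'
#' @param params a [phantom_params()].
#' @param shape grid dimensions (length 1 or 3), default 96.
#' @param voxel_size voxel size in Angstrom, default 13.6 (a 4x-binned
#'   3.4 A acquisition pixel).
#' @return a [density_volume].
#' @export
build_phantom <- function(params, shape = 96, voxel_size = 13.6) {
  if (!inherits(params, "phantom_params"))
    stop("`params` must be phantom_params", call. = FALSE)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  geo <- phantom_geometry(params)
  half_xy <- (min(shape[1:2]) / 2 - 1) * voxel_size
  half_z <- (shape[3] / 2 - 1) * voxel_size
  r_need <- max(geo$r_waist + 2 * geo$sigma_mem,
                vapply(geo$rings[params$present_rings],
                       function(g) g$r + 2 * g$sr, 0))
  z_need <- max(geo$z_flat_cyto, geo$z_flat_nucleo) + 2 * geo$sigma_mem
  if (r_need > half_xy - 2 * voxel_size || z_need > half_z - 2 * voxel_size)
    stop("phantom geometry does not fit in the grid with a 2-voxel margin",
         call. = FALSE)
  xs <- axis_coords(shape[1], voxel_size)
  ys <- axis_coords(shape[2], voxel_size)
  zs <- axis_coords(shape[3], voxel_size)
  x <- array(rep(xs, times = shape[2] * shape[3]), shape)
  y <- array(rep(rep(ys, each = shape[1]), times = shape[3]), shape)
  z <- array(rep(zs, each = shape[1] * shape[2]), shape)
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  dens <- array(0, shape)
  for (nm in params$present_rings) {
    g <- geo$rings[[nm]]
    lobe <- 1 + params$lobe_contrast * cos(params$n_subunits * phi)
    dens <- dens + g$amp * lobe *
      exp(-(r - g$r)^2 / (2 * g$sr^2) - (z - g$z)^2 / (2 * g$sz^2))
  }
  d_c <- membrane_distance_side(r, z, geo$r_waist, params$angle_cyto,
                                geo$z_flat_cyto, +1)
  d_n <- membrane_distance_side(r, z, geo$r_waist, params$angle_nucleo,
                                geo$z_flat_nucleo, -1)
  d_m <- pmin(d_c, d_n)
  dens <- dens + geo$amp_mem * exp(-d_m^2 / (2 * geo$sigma_mem^2))
  # cosine taper to zero inside the inscribed cylinder so the volume is
  # closed under rotations about z (the box truncates the flat NE anyway).
  # The ramp is spread over several voxels: a sharper edge cannot be
  # rotated on the grid without percent-level interpolation error.
  r_edge <- (min(shape[1:2]) / 2 - 1) * voxel_size
  taper <- cosine_ramp(r - r_edge + 8 * voxel_size, 7 * voxel_size)
  density_volume(dens * taper * params$density_scale,
                 voxel_size = voxel_size)
}

#' Point model
#'
#' Labeled 3D coordinates with weights, the currency of the rigid-body
#' fitting module (stands in for docked subcomplex coordinates).
#'
#' @param points N x 3 matrix of coordinates in Angstrom (physical frame,
#'   origin at the grid centre).
#' @param chain chain labels (recycled).
#' @param weight positive weights / masses (recycled).
#' @return a `data.frame` of class `point_model` with columns
#'   `x, y, z, chain, weight`.
#' @export
point_model <- function(points, chain = "A", weight = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 1L || ncol(points) != 3L)
    stop("`points` must be an N x 3 matrix with N >= 1", call. = FALSE)
  if (any(weight <= 0)) stop("weights must be > 0", call. = FALSE)
  df <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                   chain = rep_len(as.character(chain), nrow(points)),
                   weight = rep_len(as.numeric(weight), nrow(points)))
  class(df) <- c("point_model", "data.frame")
  df
}

model_coords <- function(model) as.matrix(model[, c("x", "y", "z")])

#' Point model matching a phantom
#'
#' Samples `points_per_subunit` points per subunit per present ring at and
#' around the ring lobe centres, consistent with [build_phantom()] (the
#' points lie inside the rendered density support and share its symmetry).
#'
#' @param params a [phantom_params()].
#' @param points_per_subunit integer >= 1.
#' @return a [point_model()] with
#'   `length(present_rings) * n_subunits * points_per_subunit` points.
#' @export
phantom_point_model <- function(params, points_per_subunit = 1) {
  if (points_per_subunit < 1) stop("points_per_subunit must be >= 1",
                                   call. = FALSE)
  if (length(params$present_rings) == 0L)
    stop("empty model: no rings present", call. = FALSE)
  geo <- phantom_geometry(params)
  n <- params$n_subunits
  m <- points_per_subunit
  pts <- NULL; chains <- character(0)
  for (nm in params$present_rings) {
    g <- geo$rings[[nm]]
    for (k in seq_len(n) - 1L) {
      phi0 <- 2 * pi * k / n
      j <- seq_len(m)
      dphi <- (j - (m + 1) / 2) * (0.5 / n) * (2 * pi) / max(m, 2)
      rr <- g$r + 0.3 * g$sr * cos(3 * j)
      zz <- g$z + 0.3 * g$sz * sin(3 * j)
      pts <- rbind(pts, cbind(rr * cos(phi0 + dphi), rr * sin(phi0 + dphi), zz))
      chains <- c(chains, rep(paste0(nm, k + 1L), m))
    }
  }
  point_model(pts, chain = chains, weight = 1)
}
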