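#' Simulation parameters
#'
#' Acquisition/noise parameters for subtomogram simulation. The defaults
#' encode the study conditions: a -52 to +68 degree tilt range and additive
#' white Gaussian noise at a stated signal-to-noise ratio. SNR is defined as
#' the variance of the wedge-filtered signal over the variance of the added
#' noise, with the signal variance evaluated inside a sphere of radius
#' `membrane_pore_diameter` (capped at the largest inscribed sphere of the
#' grid).
#'
#' @param n_particles number of particles to simulate.
#' @param tilt_min,tilt_max tilt range in degrees (default -52, +68).
#' @param snr signal power / noise power (> 0), default 0.5.
#' @param pose_jitter max random translation in voxels (uniform per axis).
#' @param wobble max tilt of the particle axis from z, degrees (emulates
#'   nuclear-envelope prealigned picking); set 90 with
#'   `random_azimuth = TRUE` for unconstrained poses.
#' @param random_azimuth draw random azimuth/orientation? `FALSE` gives
#'   identity poses (useful for noise-free closure tests).
#' @param seed integer seed; recorded in the output table's source id.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_particles = 16, tilt_min = -52, tilt_max = 68,
                       snr = 0.5, pose_jitter = 2, wobble = 15,
                       random_azimuth = TRUE, seed = 1) {
  if (!(tilt_min > -90 && tilt_max < 90 && tilt_min < tilt_max))
    stop("need -90 < tilt_min < tilt_max < 90", call. = FALSE)
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (n_particles < 1) stop("n_particles must be >= 1", call. = FALSE)
  structure(list(n_particles = as.integer(n_particles),
                 tilt_min = tilt_min, tilt_max = tilt_max, snr = snr,
                 pose_jitter = pose_jitter, wobble = wobble,
                 random_azimuth = isTRUE(random_azimuth),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate subtomogram particles from a phantom
#'
#' Each particle is the phantom rotated and shifted by a random pose
#' (uniform azimuth; particle-axis tilt limited by `wobble`, emulating
#' envelope-prealigned picking), multiplied in Fourier space by the binary
#' missing-wedge mask for the stated tilt range, plus white Gaussian noise
#' scaled to the stated SNR. True poses are recorded in the returned table;
#' half sets alternate A, B, A, B... by particle index. Fully reproducible
#' from `sim$seed`.
#'
#' @param phantom a [density_volume] (see [build_phantom()]).
#' @param sim a [sim_params()].
#' @param pore_diameter_nm sphere diameter used for the SNR normalisation
#'   region (default 105).
#' @return `list(particles = <list of density_volume>, table =
#'   <particle_table>, wedge = <wedge_mask>)`.
#' @export
simulate_particles <- function(phantom, sim, pore_diameter_nm = 105) {
  stopifnot_volume(phantom)
  if (!inherits(sim, "sim_params")) stop("`sim` must be sim_params",
                                         call. = FALSE)
  d <- dim(phantom$data)
  wm <- wedge_mask(sim$tilt_min, sim$tilt_max, d)
  set.seed(sim$seed)
  n <- sim$n_particles
  # draw all poses first so particle i does not depend on n
  psi <- if (sim$random_azimuth) runif(n, 0, 360) else rep(0, n)
  ct <- if (sim$random_azimuth)
    runif(n, cos(sim$wobble * pi / 180), 1) else rep(1, n)
  tilt <- acos(pmin(ct, 1)) * 180 / pi
  rot <- if (sim$random_azimuth) runif(n, 0, 360) else rep(0, n)
  shifts <- matrix(runif(3 * n, -sim$pose_jitter, sim$pose_jitter), ncol = 3)
  if (sim$pose_jitter == 0) shifts[] <- 0
  r_sph <- min(pore_diameter_nm * 10,
               (min(d) / 2 - 1) * phantom$voxel_size)
  sphere <- make_mask(mask_spec("sphere", radius = r_sph), d,
                      phantom$voxel_size)$data >= 0.5
  particles <- vector("list", n)
  for (i in seq_len(n)) {
    R <- euler_matrix(rot[i], tilt[i], psi[i])
    p <- pose_transform(phantom$data, R, shifts[i, ], interp = "cubic")
    p <- isfft(sfft(p) * wm$w)
    sig_var <- stats::var(p[sphere])
    noise_sd <- sqrt(sig_var / sim$snr)
    p <- p + rnorm(length(p), sd = noise_sd)
    particles[[i]] <- density_volume(array(p, d), phantom$voxel_size)
  }
  tab <- particle_table(
    particle_id = sprintf("P%04d", seq_len(n)),
    source_id = sprintf("sim_seed%d", sim$seed),
    x = shifts[, 1], y = shifts[, 2], z = shifts[, 3],
    rot = rot, tilt = tilt, psi = psi,
    half_set = rep(c("A", "B"), length.out = n))
  list(particles = particles, table = tab, wedge = wm)
}
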