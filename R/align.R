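#' Alignment configuration
#'
#' Controls the constrained cross-correlation alignment. `binnings` are
#' Fourier-crop factors relative to the input subvolumes (1 = as provided),
#' run in order with `n_iter` iterations each; the angular grid is scanned
#' exhaustively at the first binning's first iteration and refined locally
#' (step / `refine_factor` around the current pose) afterwards.
#'
#' @param angular_step coarse angular grid step in degrees.
#' @param refine_factor local refinement divides the step by this factor.
#' @param max_shift translation search half-window in voxels (at binning 1).
#' @param max_tilt particle-axis tilt search limit in degrees.
#' @param binnings ordered decreasing Fourier-crop factors, e.g. `c(2, 1)`.
#' @param n_iter iterations per binning (recycled to `length(binnings)`).
#' @param symmetry Cn point-group order applied to the reference (restricts
#'   the in-plane search to `360 / symmetry`).
#' @param tilt_min,tilt_max acquisition tilt range, degrees.
#' @param min_coverage absolute floor on the summed wedge weight below which
#'   Fourier voxels are zeroed instead of compensated.
#' @param soft_edge wedge mask soft edge in voxels.
#' @param score_period rotations are scored over Fourier components with
#'   period >= this many voxels (a band limit on the orientation search;
#'   translation updates and averaging remain full-band).
#' @return object of class `align_config`.
#' @export
align_config <- function(angular_step = 10, refine_factor = 4, max_shift = 4,
                         max_tilt = 20, binnings = c(2, 1), n_iter = c(2, 2),
                         symmetry = 8, tilt_min = -52, tilt_max = 68,
                         min_coverage = 0.5, soft_edge = 0,
                         score_period = 3) {
  if (angular_step <= 0) stop("angular_step must be > 0", call. = FALSE)
  if (any(diff(binnings) > 0)) stop("binnings must be decreasing",
                                    call. = FALSE)
  structure(list(angular_step = angular_step, refine_factor = refine_factor,
                 max_shift = max_shift, max_tilt = max_tilt,
                 binnings = as.integer(binnings),
                 n_iter = rep_len(as.integer(n_iter), length(binnings)),
                 symmetry = as.integer(symmetry),
                 tilt_min = tilt_min, tilt_max = tilt_max,
                 min_coverage = min_coverage, soft_edge = soft_edge,
                 score_period = score_period),
            class = "align_config")
}

# Global angular grid: psi over one asymmetric unit (360/sym), tilt up to
# max_tilt, azimuth of the tilt direction (rot) spaced ~geodesically.
angular_grid <- function(step, max_tilt, symmetry = 1) {
  psi <- seq(0, 360 / symmetry - 1e-9, by = step)
  grid <- NULL
  for (tl in seq(0, max_tilt, by = step)) {
    if (tl == 0) {
      grid <- rbind(grid, cbind(0, 0, psi))
    } else {
      n_rot <- max(1L, round(360 * sin(tl * pi / 180) / step))
      rots <- seq(0, 360, length.out = n_rot + 1)[seq_len(n_rot)]
      grid <- rbind(grid, as.matrix(expand.grid(rots, tl, psi)))
    }
  }
  colnames(grid) <- c("rot", "tilt", "psi")
  if (nrow(grid) == 0) stop("empty angular grid", call. = FALSE)
  grid
}

# small geodesic perturbations: rotations about the x/y/z axes composed
# onto a pose (well conditioned near tilt = 0, where ZYZ angles degenerate)
delta_rotations <- function(step) {
  rx <- function(a) { a <- a * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3) }
  ry <- function(a) { a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3) }
  rz <- function(a) { a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3) }
  g <- expand.grid(a = c(-step, 0, step), b = c(-step, 0, step),
                   c = c(-step, 0, step))
  lapply(seq_len(nrow(g)),
         function(i) rx(g$a[i]) %*% ry(g$b[i]) %*% rz(g$c[i]))
}

# --- spectral engine ---------------------------------------------------

# rotate a centred spectrum by pose R (spectrum of rotate_volume(., R)):
# out(k) = in(R^-1 k), trilinear on Re/Im
rotate_spectrum <- function(S, R) {
  Rt <- t(R)
  re <- affine_resample(Re(S), Rt, interp = "linear")
  im <- affine_resample(Im(S), Rt, interp = "linear")
  complex(real = re, imaginary = im)
}

# correlation of rotated-reference spectrum vs particle spectrum over the
# Fourier region W (centred layout), at a fixed relative shift already
# folded into Sb. Means are removed by zeroing DC through W.
masked_cc_score <- function(Sa, Sb, W) {
  num <- sum(W * (Re(Sa) * Re(Sb) + Im(Sa) * Im(Sb)))
  na <- sum(W * (Re(Sa)^2 + Im(Sa)^2))
  nb <- sum(W * (Re(Sb)^2 + Im(Sb)^2))
  if (na <= 0 || nb <= 0) return(NA_real_)
  num / sqrt(na * nb)
}

# subvoxel parabolic offset from three samples around a peak
parabolic_offset <- function(m1, c0, p1) {
  den <- m1 - 2 * c0 + p1
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (m1 - p1) / den
  max(-0.5, min(0.5, off))
}

# peak of a (wrapped) correlation map near zero shift; returns subvoxel
# shift and the interpolated peak value
cc_peak <- function(ccmap, max_shift) {
  d <- dim(ccmap)
  offs <- lapply(d, function(n) {
    s <- -max_shift:max_shift
    s[abs(s) <= n %/% 2 - 1]
  })
  idx <- lapply(seq_len(3), function(i) (offs[[i]] %% d[i]) + 1L)
  sub <- ccmap[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  best <- which(sub == max(sub), arr.ind = TRUE)[1, , drop = TRUE]
  shift <- c(offs[[1]][best[1]], offs[[2]][best[2]], offs[[3]][best[3]])
  at <- function(s) ccmap[(s[1] %% d[1]) + 1L, (s[2] %% d[2]) + 1L,
                          (s[3] %% d[3]) + 1L]
  peak <- at(shift)
  sub_off <- numeric(3)
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    sub_off[ax] <- parabolic_offset(at(shift - e), peak, at(shift + e))
  }
  list(shift = shift + sub_off, score = peak)
}

#' Missing-wedge constrained cross-correlation
#'
#' Normalized cross-correlation between two volumes computed only over the
#' Fourier region where both wedge masks are >= 0.5 (means removed by
#' excluding the DC term; unit-normalized within the region). Returns the
#' correlation peak over translations within `max_shift` voxels, refined to
#' subvoxel precision by parabolic interpolation, and the shift `s` such
#' that `b` is approximately `a` translated by `s`.
#'
#' @param a,b [density_volume]s of identical shape.
#' @param wedge_a,wedge_b [wedge_mask()]s in the frame of each volume;
#'   `NULL` means full coverage.
#' @param max_shift peak-search half window in voxels (0 = score at zero
#'   shift only).
#' @return `list(score, shift)`.
#' @export
constrained_cc <- function(a, b, wedge_a = NULL, wedge_b = NULL,
                           max_shift = 4) {
  stopifnot_volume(a); stopifnot_volume(b)
  d <- dim(a$data)
  if (!all(dim(b$data) == d)) stop("volumes must share a shape", call. = FALSE)
  W <- array(1, d)
  if (!is.null(wedge_a)) W <- W * (wedge_a$w >= 0.5)
  if (!is.null(wedge_b)) W <- W * (wedge_b$w >= 0.5)
  ctr <- vol_centre(d)
  W[ctr[1], ctr[2], ctr[3]] <- 0          # mean removal
  if (sum(W) < 1) stop("degenerate overlap: empty common wedge region",
                       call. = FALSE)
  Sa <- sfft(a$data); Sb <- sfft(b$data)
  na <- sum(W * (Re(Sa)^2 + Im(Sa)^2))
  nb <- sum(W * (Re(Sb)^2 + Im(Sb)^2))
  if (na <= .Machine$double.eps * prod(d) ||
      nb <= .Machine$double.eps * prod(d))
    stop("degenerate overlap: a volume has no power in the common region",
         call. = FALSE)
  if (max_shift <= 0) {
    return(list(score = masked_cc_score(Sa, Sb, W), shift = c(0, 0, 0)))
  }
  P <- W * Conj(Sa) * Sb
  ccmap <- Re(fft(ifftshift3(P), inverse = TRUE)) / sqrt(na * nb)
  pk <- cc_peak(ccmap, max_shift)
  list(score = pk$score, shift = pk$shift)
}

# Pin the axial translation gauge of reference-free alignment: a common
# z-offset of all particles (in the reference frame) is a free parameter
# that otherwise random-walks between iterations, rounding the membrane
# fold of the average outward. The z-component of R^T t is invariant to
# the C8 branch each particle latched onto, so it can be re-centred; the
# in-plane components are left alone (per-direction diameter landmarks are
# invariant to them).
recentre_z <- function(tab) {
  n <- nrow(tab)
  tz <- numeric(n)
  Rs <- vector("list", n)
  for (i in seq_len(n)) {
    Rs[[i]] <- euler_matrix(tab$rot[i], tab$tilt[i], tab$psi[i])
    tz[i] <- (t(Rs[[i]]) %*% c(tab$x[i], tab$y[i], tab$z[i]))[3]
  }
  mz <- mean(tz)
  for (i in seq_len(n)) {
    dl <- as.vector(Rs[[i]] %*% c(0, 0, mz))
    tab$x[i] <- tab$x[i] - dl[1]
    tab$y[i] <- tab$y[i] - dl[2]
    tab$z[i] <- tab$z[i] - dl[3]
  }
  tab
}

# internal single-particle alignment given precomputed spectra.
# Sref: centred spectrum of the reference; Sp: of the particle; W: particle
# wedge (>=0.5 binarised, DC zeroed). Rotations are scored on the
# band-limited wedge subset (period >= cfg$score_period voxels) by sampling
# the reference spectrum at the rotated frequencies; translations use the
# full-band correlation map. Returns pose + shift + cc.
align_spectra <- function(Sref, Sp, W, cfg, mode = c("global", "local"),
                          pose0 = c(0, 0, 0), shift0 = c(0, 0, 0),
                          max_shift = cfg$max_shift) {
  mode <- match.arg(mode)
  d <- dim(Sp)
  ctr <- vol_centre(d)
  k <- freq_grids(d)
  band <- min(d) / max(cfg$score_period, 2)
  sub <- which(W > 0 & (k$kx^2 + k$ky^2 + k$kz^2) <= band^2)
  kk <- cbind(k$kx[sub], k$ky[sub], k$kz[sub])
  ref_re <- Re(Sref); ref_im <- Im(Sref)
  nb_full <- sum(W * (Re(Sp)^2 + Im(Sp)^2))
  score_R <- function(Rlist, Sb_sub) {
    nb <- sum(Re(Sb_sub)^2 + Im(Sb_sub)^2)
    vapply(Rlist, function(R) {
      coords <- sweep(kk %*% R, 2, ctr, "+")   # (R^-1 k) + centre
      ar <- sample_trilinear(ref_re, coords)
      ai <- sample_trilinear(ref_im, coords)
      num <- sum(ar * Re(Sb_sub) + ai * Im(Sb_sub))
      na <- sum(ar^2 + ai^2)
      if (na <= 0 || nb <= 0) return(NA_real_)
      num / sqrt(na * nb)
    }, 0)
  }
  update_shift <- function(R) {
    Sa <- rotate_spectrum(Sref, R)
    P <- W * Conj(Sa) * Sp
    dim(P) <- d
    na <- sum(W * (Re(Sa)^2 + Im(Sa)^2))
    ccmap <- Re(fft(ifftshift3(P), inverse = TRUE)) / sqrt(na * nb_full)
    cc_peak(ccmap, max(1, ceiling(max_shift)))
  }
  # score rotations at the current translation (folded in as a phase ramp)
  shift <- shift0
  ramp_sub <- function(t) {
    ph <- 2 * pi * (kk[, 1] * (t[1] / d[1]) + kk[, 2] * (t[2] / d[2]) +
                    kk[, 3] * (t[3] / d[3]))
    complex(modulus = 1, argument = ph)
  }
  Sb_sub <- Sp[sub] * ramp_sub(shift)
  if (mode == "global") {
    cand <- angular_grid(cfg$angular_step, cfg$max_tilt, cfg$symmetry)
    Rlist <- lapply(seq_len(nrow(cand)),
                    function(i) euler_matrix(cand[i, ]))
    sc <- score_R(Rlist, Sb_sub)
    best_R <- Rlist[[which.max(sc)]]
  } else {
    best_R <- euler_matrix(pose0)
  }
  # local refinement by geodesic deltas, two shrinking passes
  for (f in cfg$angular_step / c(cfg$refine_factor / 2, cfg$refine_factor)) {
    deltas <- delta_rotations(f)
    Rlist <- lapply(deltas, function(Dl) best_R %*% Dl)
    sc <- score_R(Rlist, Sb_sub)
    best_R <- Rlist[[which.max(sc)]]
  }
  pk <- update_shift(best_R)
  list(pose = matrix_to_euler(best_R), shift = pk$shift, cc = pk$score)
}

prep_particle_spectrum <- function(p, wm, cfg) {
  d <- dim(p)
  W <- (wm$w >= 0.5) * 1
  ctr <- vol_centre(d)
  W[ctr[1], ctr[2], ctr[3]] <- 0
  list(S = sfft(p), W = W)
}

#' Align one particle to a reference
#'
#' Scans the angular grid (coarse scan over one asymmetric unit of the
#' configured symmetry, then local refinement at `angular_step /
#' refine_factor`), maximizing the missing-wedge constrained
#' cross-correlation; deterministic given its inputs.
#'
#' @param particle,reference [density_volume]s of identical shape.
#' @param wedge the particle's [wedge_mask()].
#' @param cfg an [align_config()].
#' @return `list(pose = c(rot, tilt, psi), shift, cc)` where the pose maps
#'   the reference onto the particle and `shift` is in voxels.
#' @export
align_particle <- function(particle, reference, wedge, cfg = align_config()) {
  stopifnot_volume(particle); stopifnot_volume(reference)
  ps <- prep_particle_spectrum(particle$data, wedge, cfg)
  res <- align_spectra(sfft(reference$data), ps$S, ps$W, cfg, mode = "global")
  # exact rescoring of the selected pose (the fast spectral search rotates
  # interpolated spectra; the reported score uses a real-space rotation)
  ex <- constrained_cc(rotate_volume(reference, res$pose), particle,
                       wedge_b = wedge,
                       max_shift = max(1, ceiling(cfg$max_shift)))
  res$cc <- ex$score
  res$shift <- ex$shift
  res
}

#' Wedge-compensated averaging of posed particles
#'
#' Brings every particle into the reference frame (cubic real-space
#' resampling of the inverse pose), sums the spectra weighted by each
#' particle's analytically pose-rotated wedge mask, and divides by the
#' summed wedge coverage (floored at `min_coverage`; never-covered regions
#' are zeroed) -- the missing-wedge compensation. Half maps are built
#' independently from the A and B half sets and the merged map applies the
#' compensation to the pooled sum.
#'
#' @param particles list of [density_volume]s.
#' @param table a [particle_table()] carrying poses (and half-set labels).
#' @param wedge the acquisition [wedge_mask()].
#' @param min_coverage absolute wedge-sum floor (default 0.5).
#' @param require_halves error (rather than warn) when a half set is empty.
#' @return `list(merged, half_A, half_B, table)`; empty half sets give NULL
#'   half maps with a warning.
#' @export
average_particles <- function(particles, table, wedge, min_coverage = 0.5,
                              require_halves = FALSE) {
  n <- length(particles)
  if (n < 1) stop("no particles to average", call. = FALSE)
  if (nrow(table) != n)
    stop("table must have one row per particle", call. = FALSE)
  d <- dim(particles[[1]]$data)
  vx <- particles[[1]]$voxel_size
  sums <- list(A = 0, B = 0); wsums <- list(A = 0, B = 0)
  labels <- ifelse(is.na(table$half_set), "A", table$half_set)
  for (i in seq_len(n)) {
    R <- euler_matrix(table$rot[i], table$tilt[i], table$psi[i])
    t_i <- c(table$x[i], table$y[i], table$z[i])
    est <- pose_untransform(particles[[i]]$data, R, t_i, interp = "cubic")
    Wr <- wedge_array_rotated(wedge, R)
    S <- sfft(est) * Wr
    h <- labels[i]
    sums[[h]] <- sums[[h]] + S
    wsums[[h]] <- wsums[[h]] + Wr
  }
  compensate <- function(S, Wsum) {
    out <- S
    ok <- Wsum >= min_coverage
    out[ok] <- out[ok] / Wsum[ok]
    out[!ok] <- 0
    density_volume(isfft(out), voxel_size = vx)
  }
  halves <- list(A = NULL, B = NULL)
  for (h in c("A", "B")) {
    if (!any(labels == h)) {
      msg <- paste0("half set ", h, " is empty; no half map produced")
      if (require_halves) stop(msg, call. = FALSE) else warning(msg)
    } else {
      halves[[h]] <- compensate(sums[[h]], wsums[[h]])
    }
  }
  merged <- compensate(sums$A + sums$B, wsums$A + wsums$B)
  list(merged = merged, half_A = halves$A, half_B = halves$B, table = table)
}

# Azimuth (degrees, mod 360/order) of a subunit lobe: the phase of the
# order-n circular harmonic on the equatorial slab, measured at the radius
# that maximizes its amplitude. The in-plane orientation of a
# reference-free Cn average is a free gauge; rotating the final maps by
# minus this angle gives them a deterministic orientation (the same
# convention the phantom is built in, with a subunit lobe on the +x axis).
harmonic_phase <- function(v, order) {
  d <- dim(v$data); ctr <- vol_centre(d); vx <- v$voxel_size
  n_ang <- 32 * order
  ang <- 2 * pi * (seq_len(n_ang) - 1) / n_ang
  best_F <- 0 + 0i
  for (rv in seq(6, min(d[1:2]) / 2 - 6, by = 1)) {
    acc <- 0
    for (dz in -1:1) {
      coords <- cbind(ctr[1] + rv * cos(ang), ctr[2] + rv * sin(ang),
                      ctr[3] + dz)
      acc <- acc + sample_trilinear(v$data, coords)
    }
    Fm <- sum(acc * exp(-1i * order * ang))
    if (Mod(Fm) > Mod(best_F)) best_F <- Fm
  }
  if (!is.finite(Mod(best_F)) || Mod(best_F) == 0) return(0)
  -Arg(best_F) / order * 180 / pi
}

#' Cn symmetrization about z
#'
#' Mean of the `order` copies rotated about the z axis; the result is
#' invariant under rotation by `360 / order` within interpolation tolerance,
#' and the operation is idempotent.
#'
#' @param v a [density_volume].
#' @param order Cn order (>= 1).
#' @param interp interpolation for the rotated copies.
#' @return the symmetrized [density_volume].
#' @export
apply_symmetry <- function(v, order, interp = "cubic") {
  stopifnot_volume(v)
  order <- as.integer(order)
  if (order < 1L) stop("symmetry order must be >= 1", call. = FALSE)
  if (order == 1L) return(v)
  acc <- v$data
  cf <- if (interp == "cubic")
    .bspline_prefilter_cpp(as.numeric(v$data), as.integer(dim(v$data)))
  else v$data
  dim(cf) <- dim(v$data)
  for (k in seq_len(order - 1L)) {
    Rk <- euler_matrix(360 * k / order, 0, 0)
    acc <- acc + affine_resample(cf, t(Rk), interp = interp,
                                 prefiltered = (interp == "cubic"))
  }
  density_volume(acc / order, voxel_size = v$voxel_size, origin = v$origin)
}

#' Iterative missing-wedge weighted alignment and averaging
#'
#' Runs the binning schedule of the configuration. Per iteration every
#' particle is aligned to the current template (the merged, symmetrized
#' average of the previous iteration -- half maps are merged after each
#' iteration and used as the next template), the average is rebuilt, the
#' point-group symmetry applied, and the mean correlation recorded. The
#' initial reference is the wedge-compensated average over the input poses,
#' symmetrized; alignment starts with an exhaustive angular scan at the
#' coarsest binning and refines locally afterwards.
#'
#' @param particles list of [density_volume]s (identical shapes).
#' @param table [particle_table()] with initial (prealignment) poses.
#' @param cfg an [align_config()].
#' @param verbose print per-iteration progress?
#' @return `list(merged, half_A, half_B, table, log, diverged)`; maps are at
#'   the native binning with the symmetry applied, `table` carries refined
#'   poses and cc scores, `log` is a data.frame (binning, iteration,
#'   mean_cc).
#' @export
iterative_align <- function(particles, table, cfg = align_config(),
                            verbose = FALSE) {
  n <- length(particles)
  if (n < 1) stop("no particles", call. = FALSE)
  d <- dim(particles[[1]]$data)
  poses <- table
  log <- NULL
  diverged <- FALSE
  total_iters <- sum(cfg$n_iter)
  for (bi in seq_along(cfg$binnings)) {
    f <- cfg$binnings[bi]
    if (cfg$n_iter[bi] < 1) next
    pb <- if (f > 1) lapply(particles, fourier_crop, f) else particles
    db <- dim(pb[[1]]$data)
    wm <- wedge_mask(cfg$tilt_min, cfg$tilt_max, db, cfg$soft_edge)
    max_shift_b <- max(1, cfg$max_shift / f)
    scale_tab <- function(tb, s) { tb$x <- tb$x * s; tb$y <- tb$y * s
                                   tb$z <- tb$z * s; tb }
    pose_b <- scale_tab(poses, 1 / f)
    avg <- average_particles(pb, pose_b, wm, cfg$min_coverage)
    ref <- apply_symmetry(avg$merged, cfg$symmetry)
    last_cc <- -Inf
    for (it in seq_len(cfg$n_iter[bi])) {
      mode <- if (bi == 1L) "global" else "local"
      Sref <- sfft(ref$data)
      for (i in seq_len(n)) {
        ps <- prep_particle_spectrum(pb[[i]]$data, wm, cfg)
        res <- align_spectra(Sref, ps$S, ps$W, cfg, mode = mode,
                             pose0 = c(pose_b$rot[i], pose_b$tilt[i],
                                       pose_b$psi[i]),
                             shift0 = c(pose_b$x[i], pose_b$y[i],
                                        pose_b$z[i]),
                             max_shift = max_shift_b)
        pose_b$rot[i] <- res$pose[1]; pose_b$tilt[i] <- res$pose[2]
        pose_b$psi[i] <- res$pose[3]
        pose_b$x[i] <- res$shift[1]; pose_b$y[i] <- res$shift[2]
        pose_b$z[i] <- res$shift[3]
        pose_b$cc[i] <- res$cc
      }
      pose_b <- recentre_z(pose_b)
      avg <- average_particles(pb, pose_b, wm, cfg$min_coverage)
      ref <- apply_symmetry(avg$merged, cfg$symmetry)
      mean_cc <- mean(pose_b$cc)
      log <- rbind(log, data.frame(binning = f, iteration = it,
                                   mean_cc = mean_cc))
      if (verbose)
        message(sprintf("binning %d iter %d: mean cc %.4f", f, it, mean_cc))
      if (mean_cc < last_cc - 0.05) {
        warning("alignment diverging (mean cc dropped > 0.05); stopping early")
        diverged <- TRUE
        break
      }
      last_cc <- mean_cc
    }
    poses <- scale_tab(pose_b, f)
    if (diverged) break
  }
  wm <- wedge_mask(cfg$tilt_min, cfg$tilt_max, d, cfg$soft_edge)
  rescore_exact <- function(ref, poses) {
    for (i in seq_len(n)) {
      rr <- rotate_volume(ref, c(poses$rot[i], poses$tilt[i], poses$psi[i]))
      poses$cc[i] <- tryCatch(
        constrained_cc(rr, particles[[i]], wedge_b = wm, max_shift = 1)$score,
        error = function(e) NA_real_)
    }
    poses
  }
  if (total_iters == 0) {
    avg <- average_particles(particles, poses, wm, cfg$min_coverage)
    ref <- apply_symmetry(avg$merged, cfg$symmetry)
    return(list(merged = ref, half_A = avg$half_A, half_B = avg$half_B,
                table = poses, log = NULL, diverged = FALSE))
  }
  avg <- average_particles(particles, poses, wm, cfg$min_coverage)
  merged <- apply_symmetry(avg$merged, cfg$symmetry)
  half_A <- if (!is.null(avg$half_A))
    apply_symmetry(avg$half_A, cfg$symmetry) else NULL
  half_B <- if (!is.null(avg$half_B))
    apply_symmetry(avg$half_B, cfg$symmetry) else NULL
  if (cfg$symmetry > 1L) {
    # standardize the free in-plane gauge of the final maps
    phi <- harmonic_phase(merged, cfg$symmetry)
    if (is.finite(phi) && abs(phi) > 1e-3) {
      merged <- rotate_volume(merged, c(-phi, 0, 0))
      if (!is.null(half_A)) half_A <- rotate_volume(half_A, c(-phi, 0, 0))
      if (!is.null(half_B)) half_B <- rotate_volume(half_B, c(-phi, 0, 0))
      for (i in seq_len(n)) {
        Rn <- euler_matrix(poses$rot[i], poses$tilt[i], poses$psi[i]) %*%
          euler_matrix(c(phi, 0, 0))
        e <- matrix_to_euler(Rn)
        poses$rot[i] <- e[1]; poses$tilt[i] <- e[2]; poses$psi[i] <- e[3]
      }
    }
  }
  poses <- rescore_exact(merged, poses)
  list(merged = merged, half_A = half_A, half_B = half_B,
       table = poses, log = log, diverged = diverged)
}
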