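#' Rigid transform
#'
#' ZYZ rotation (degrees) plus a translation in Angstrom, acting on point
#' models about the physical origin (the grid centre): `p' = R p + t`.
#'
#' @param euler length-3 `(rot, tilt, psi)` in degrees.
#' @param translation length-3 translation in Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(euler = c(0, 0, 0), translation = c(0, 0, 0)) {
  structure(list(euler = normalize_euler(euler),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

transform_points <- function(coords, tf) {
  sweep(coords %*% t(euler_matrix(tf$euler)), 2, tf$translation, "+")
}

# point coordinates (Angstrom, physical frame) -> 1-based voxel coordinates
points_to_voxels <- function(coords, d, voxel_size) {
  ctr <- vol_centre(d)
  sweep(coords / voxel_size, 2, ctr, "+")
}

#' Simulate a density map from a point model
#'
#' Renders each point as a 3D Gaussian with `sigma = 0.225 * resolution`
#' (the Fourier half-height convention of common map-simulation tools),
#' weighted by the point mass. The sum of grid values equals the total
#' weight up to boundary truncation.
#'
#' @param model a [point_model()].
#' @param resolution target resolution in Angstrom (>= 2 voxels).
#' @param shape grid dimensions (length 1 or 3).
#' @param voxel_size voxel size in Angstrom.
#' @return a [density_volume].
#' @export
simulate_map_from_model <- function(model, resolution, shape, voxel_size) {
  if (!inherits(model, "point_model") || nrow(model) < 1)
    stop("`model` must be a non-empty point_model", call. = FALSE)
  if (resolution < 2 * voxel_size)
    stop("resolution must be >= 2 x voxel size", call. = FALSE)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  sigma_vox <- 0.225 * resolution / voxel_size
  centres <- points_to_voxels(model_coords(model), shape, voxel_size)
  v <- .render_gaussians_cpp(shape, centres, model$weight, sigma_vox, 4.5)
  density_volume(v, voxel_size = voxel_size)
}

#' Correlation about the mean (CAM)
#'
#' Pearson correlation between the target and the model-simulated map,
#' restricted to the model map's support (voxels above `contour`, default
#' 1e-3 of its peak).
#'
#' @param target,model_map [density_volume]s on the same grid.
#' @param contour region threshold on `model_map`; `NULL` uses
#'   `1e-3 * max(model_map)`.
#' @return CAM score in `[-1, 1]`.
#' @export
cam_score <- function(target, model_map, contour = NULL) {
  stopifnot_volume(target); stopifnot_volume(model_map)
  if (is.null(contour)) contour <- 1e-3 * max(model_map$data)
  region <- model_map$data > contour
  if (sum(region) < 10)
    stop("degenerate region: fewer than 10 voxels above the contour",
         call. = FALSE)
  x <- target$data[region]; y <- model_map$data[region]
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0)
    stop("degenerate region: zero variance", call. = FALSE)
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy) *
    length(x) / (length(x) - 1)
}

#' Overlap score (OVR)
#'
#' Fraction of the model map's mass lying where the target exceeds its
#' contour.
#'
#' @param target,model_map [density_volume]s on the same grid.
#' @param target_contour density contour on the target; `NULL` uses
#'   `mean + 1 sd` of the target.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_score <- function(target, model_map, target_contour = NULL) {
  stopifnot_volume(target); stopifnot_volume(model_map)
  tot <- sum(model_map$data)
  if (tot <= 0) stop("model map has zero mass", call. = FALSE)
  if (is.null(target_contour))
    target_contour <- mean(target$data) + sd(target$data)
  sum(model_map$data[target$data > target_contour]) / tot
}

fit_metric <- function(target, model, tf, metric, resolution, target_contour) {
  d <- dim(target$data)
  coords <- transform_points(model_coords(model), tf)
  centres <- points_to_voxels(coords, d, target$voxel_size)
  sigma_vox <- 0.225 * resolution / target$voxel_size
  s <- .fit_score_cpp(as.numeric(target$data), as.integer(d), centres,
                      model$weight, sigma_vox, 4.5, target_contour)
  n <- s[1]
  if (n < 10 || s[7] <= 0) return(list(score = -Inf, cam = NA, ovr = NA))
  vx_ <- (s[4] - s[2]^2 / n) / (n - 1)
  vy_ <- (s[5] - s[3]^2 / n) / (n - 1)
  if (vx_ <= 0 || vy_ <= 0) return(list(score = -Inf, cam = NA, ovr = NA))
  cam <- ((s[6] - s[2] * s[3] / n) / (n - 1)) / sqrt(vx_ * vy_)
  ovr <- s[8] / s[7]
  score <- if (metric == "cam") cam else cam + ovr
  list(score = score, cam = cam, ovr = ovr)
}

#' Local optimization of a rigid fit
#'
#' Greedy coordinate ascent over the six pose parameters with shrinking
#' steps, stopping when the metric gain falls below `tol` or after
#' `max_steps` sweeps. The returned metric is never worse than at `init`.
#'
#' @param target a [density_volume].
#' @param model a [point_model()].
#' @param init a [rigid_transform()].
#' @param metric `"cam"` or `"cam_plus_ovr"`.
#' @param resolution map-simulation resolution in Angstrom (default 25).
#' @param tol convergence tolerance on the metric (default 1e-5).
#' @param max_steps maximum number of parameter updates (default 200).
#' @return `list(transform, cam, ovr, combined, score)`.
#' @export
local_optimize <- function(target, model, init = rigid_transform(),
                           metric = c("cam", "cam_plus_ovr"),
                           resolution = 25, tol = 1e-5, max_steps = 200) {
  metric <- match.arg(metric)
  target_contour <- mean(target$data) + sd(target$data)
  par <- c(init$euler, init$translation)
  ev <- function(p) fit_metric(target, model,
                               rigid_transform(p[1:3], p[4:6]),
                               metric, resolution, target_contour)
  cur <- ev(par)
  if (!is.finite(cur$score))
    stop("degenerate region: initial placement outside the map",
         call. = FALSE)
  # coarse-to-fine: early levels score against a blurred model rendering
  # (wider basins of attraction), later levels at the stated resolution
  ang_steps <- c(30, 15, 8, 4, 2, 1)
  trs_steps <- c(4, 2, 1, 0.5, 0.25, 0.25) * target$voxel_size
  res_scale <- c(2.5, 2, 1.5, 1, 1, 1)
  n_ev <- 0
  for (lev in seq_along(ang_steps)) {
    ev_l <- function(p) fit_metric(target, model,
                                   rigid_transform(p[1:3], p[4:6]), metric,
                                   resolution * res_scale[lev],
                                   target_contour)
    cur_l <- ev_l(par)
    if (!is.finite(cur_l$score)) next
    repeat {
      improved <- FALSE
      for (i in 1:6) {
        st <- if (i <= 3) ang_steps[lev] else trs_steps[lev]
        for (sg in c(1, -1)) {
          cand <- par; cand[i] <- cand[i] + sg * st
          res <- ev_l(cand); n_ev <- n_ev + 1
          if (is.finite(res$score) && res$score > cur_l$score + tol) {
            par <- cand; cur_l <- res; improved <- TRUE
          }
        }
      }
      if (!improved || n_ev > max_steps * 12) break
    }
    if (n_ev > max_steps * 12) break
  }
  cur2 <- ev(par)
  if (is.finite(cur2$score) && cur2$score >= cur$score) cur <- cur2
  list(transform = rigid_transform(par[1:3], par[4:6]),
       cam = cur$cam, ovr = cur$ovr, combined = cur$cam + cur$ovr,
       score = cur$score)
}

random_rotation <- function() {
  # uniform over SO(3) via random unit quaternion
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Global rigid-body fitting by random placements
#'
#' Draws `n_placements` uniformly random rotations and translations within
#' the target's support bounding box, locally optimizes each, clusters the
#' converged fits (same cluster when rotations differ by < 6 degrees and
#' translations by < 1 voxel), and returns one scored [rigid_transform] per
#' cluster sorted by descending metric. Reproducible from `seed`.
#'
#' @param target a [density_volume].
#' @param model a [point_model()].
#' @param n_placements number of random initial placements (>= 1).
#' @param seed integer seed.
#' @param metric `"cam"` or `"cam_plus_ovr"`.
#' @param resolution map-simulation resolution in Angstrom (default 25).
#' @param max_steps optimization budget per placement.
#' @return data.frame of class `fit_results`: one row per cluster with
#'   columns `cluster_id, rot, tilt, psi, tx, ty, tz, cam, ovr, combined,
#'   score, n_members` (see [fit_significance()] for z/p/q).
#' @export
global_fit <- function(target, model, n_placements = 1000, seed = 1,
                       metric = c("cam", "cam_plus_ovr"), resolution = 25,
                       max_steps = 60) {
  metric <- match.arg(metric)
  if (n_placements < 1) stop("n_placements must be >= 1", call. = FALSE)
  set.seed(seed)
  d <- dim(target$data)
  vx <- target$voxel_size
  thr <- mean(target$data) + sd(target$data)
  supp <- which(target$data > thr, arr.ind = TRUE)
  if (nrow(supp) == 0) supp <- cbind(vol_centre(d)[1], vol_centre(d)[2],
                                     vol_centre(d)[3])
  lo <- (apply(supp, 2, min) - vol_centre(d)) * vx
  hi <- (apply(supp, 2, max) - vol_centre(d)) * vx
  fits <- vector("list", n_placements)
  for (i in seq_len(n_placements)) {
    R0 <- random_rotation()
    t0 <- runif(3, lo, hi)
    init <- rigid_transform(matrix_to_euler(R0), t0)
    fits[[i]] <- tryCatch(
      local_optimize(target, model, init, metric, resolution,
                     max_steps = max_steps),
      error = function(e) NULL)
  }
  fits <- Filter(function(f) !is.null(f) && is.finite(f$score), fits)
  if (length(fits) == 0) stop("no placement converged", call. = FALSE)
  ord <- order(-vapply(fits, function(f) f$score, 0))
  fits <- fits[ord]
  reps <- list(); members <- integer(0)
  for (f in fits) {
    Rf <- euler_matrix(f$transform$euler)
    placed <- FALSE
    for (ci in seq_along(reps)) {
      g <- reps[[ci]]
      if (rotation_distance(Rf, euler_matrix(g$transform$euler)) < 6 &&
          sqrt(sum((f$transform$translation -
                    g$transform$translation)^2)) < vx) {
        members[ci] <- members[ci] + 1L
        placed <- TRUE; break
      }
    }
    if (!placed) { reps[[length(reps) + 1L]] <- f
                   members <- c(members, 1L) }
  }
  out <- do.call(rbind, lapply(seq_along(reps), function(ci) {
    f <- reps[[ci]]
    data.frame(cluster_id = ci,
               rot = f$transform$euler[1], tilt = f$transform$euler[2],
               psi = f$transform$euler[3],
               tx = f$transform$translation[1],
               ty = f$transform$translation[2],
               tz = f$transform$translation[3],
               cam = f$cam, ovr = f$ovr, combined = f$cam + f$ovr,
               score = f$score, n_members = members[ci])
  }))
  class(out) <- c("fit_results", "data.frame")
  out
}

#' Significance of fit clusters
#'
#' Transforms cluster scores into Z scores (population standard deviation
#' over clusters), derives two-sided normal P values and corrects them for
#' multiple testing with the Benjamini-Hochberg step-up procedure.
#'
#' @param results a [global_fit()] table (>= 2 clusters, non-constant
#'   scores).
#' @return the table with columns `z`, `p`, `q` added (`q >= p` always).
#' @export
fit_significance <- function(results) {
  if (nrow(results) < 2)
    stop("need >= 2 clusters for significance", call. = FALSE)
  sc <- results$score
  sigma <- sqrt(mean((sc - mean(sc))^2))
  if (sigma == 0)
    stop("degenerate score distribution (all scores equal)", call. = FALSE)
  results$z <- (sc - mean(sc)) / sigma
  results$p <- 2 * pnorm(-abs(results$z))
  results$q <- p.adjust(results$p, method = "BH")
  results
}

#' Subtract model density from a map
#'
#' Zeroes every voxel within `radius` Angstrom of any (transformed) model
#' point; all other voxels are unchanged.
#'
#' @param target a [density_volume].
#' @param model a [point_model()].
#' @param radius subtraction radius in Angstrom (>= 0).
#' @param transform optional [rigid_transform()] placing the model.
#' @return the subtracted [density_volume].
#' @export
subtract_density <- function(target, model, radius,
                             transform = rigid_transform()) {
  stopifnot_volume(target)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (radius == 0) return(target)
  d <- dim(target$data)
  coords <- transform_points(model_coords(model), transform)
  centres <- points_to_voxels(coords, d, target$voxel_size)
  out <- .zero_near_points_cpp(as.numeric(target$data), as.integer(d),
                               centres, radius / target$voxel_size)
  density_volume(array(out, d), voxel_size = target$voxel_size,
                 origin = target$origin)
}
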