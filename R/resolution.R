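#' Fourier shell correlation
#'
#' Per-shell correlation `FSC(s) = Re(sum F_a conj(F_b)) /
#' sqrt(sum |F_a|^2 sum |F_b|^2)` on spherical shells one voxel wide in
#' frequency. An optional real-space mask is applied to both volumes before
#' the transform.
#'
#' @param a,b [density_volume]s with identical shape and voxel size.
#' @param mask optional [mask_spec()] or [density_volume] mask.
#' @return object of class `fsc_curve`: data.frame with `shell` (index),
#'   `s` (spatial frequency, 1/Angstrom), `fsc`, `n_voxels`; attribute
#'   `voxel_size`.
#' @export
fsc <- function(a, b, mask = NULL) {
  stopifnot_volume(a); stopifnot_volume(b)
  d <- dim(a$data)
  if (!all(dim(b$data) == d)) stop("volumes must share a shape", call. = FALSE)
  if (!isTRUE(all.equal(a$voxel_size, b$voxel_size)))
    stop("volumes must share a voxel size", call. = FALSE)
  da <- a$data; db <- b$data
  if (!is.null(mask)) {
    m <- if (inherits(mask, "mask_spec"))
      make_mask(mask, d, a$voxel_size)$data else mask$data
    da <- da * m; db <- db * m
  }
  if (all(da == 0) || all(db == 0))
    stop("degenerate FSC: a masked volume is all zero", call. = FALSE)
  Fa <- sfft(da); Fb <- sfft(db)
  k <- freq_grids(d)
  # shell index in units of the smallest axis' frequency step
  n_ref <- min(d)
  rr <- sqrt((k$kx / d[1])^2 + (k$ky / d[2])^2 + (k$kz / d[3])^2) * n_ref
  shell <- as.integer(round(rr))
  nyq <- n_ref %/% 2L
  keep <- shell <= nyq
  sh <- shell[keep] + 1L
  num <- rowsum_vec(Re(Fa[keep]) * Re(Fb[keep]) +
                    Im(Fa[keep]) * Im(Fb[keep]), sh, nyq + 1L)
  pa <- rowsum_vec(Re(Fa[keep])^2 + Im(Fa[keep])^2, sh, nyq + 1L)
  pb <- rowsum_vec(Re(Fb[keep])^2 + Im(Fb[keep])^2, sh, nyq + 1L)
  nv <- rowsum_vec(rep(1, sum(keep)), sh, nyq + 1L)
  val <- ifelse(pa > 0 & pb > 0, num / sqrt(pa * pb), NA_real_)
  curve <- data.frame(shell = 0:nyq,
                      s = (0:nyq) / (n_ref * a$voxel_size),
                      fsc = val, n_voxels = nv)
  attr(curve, "voxel_size") <- a$voxel_size
  class(curve) <- c("fsc_curve", "data.frame")
  curve
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  acc <- rowsum(x, group)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Resolution at an FSC threshold
#'
#' Locates the first downward crossing of the threshold by linear
#' interpolation between adjacent shells and returns `1/s` in Angstrom.
#' A curve that never crosses returns the Nyquist resolution
#' (2 x voxel size) with attribute `at_nyquist = TRUE`; a curve already
#' below threshold at the first informative shell returns that shell's
#' resolution with a warning.
#'
#' @param curve an [fsc()] curve.
#' @param threshold FSC threshold in (-1, 1), default 0.5.
#' @return resolution in Angstrom (attributes `at_nyquist`, `s_cross`).
#' @export
resolution_at <- function(curve, threshold = 0.5) {
  if (!inherits(curve, "fsc_curve") || nrow(curve) == 0)
    stop("`curve` must be a non-empty fsc_curve", call. = FALSE)
  if (threshold <= -1 || threshold >= 1)
    stop("`threshold` must be inside (-1, 1)", call. = FALSE)
  vx <- attr(curve, "voxel_size")
  ok <- !is.na(curve$fsc) & curve$shell > 0
  s <- curve$s[ok]; f <- curve$fsc[ok]
  if (length(f) == 0) stop("empty FSC curve", call. = FALSE)
  if (f[1] < threshold) {
    warning("FSC below threshold at the lowest-resolution shell")
    return(structure(1 / s[1], at_nyquist = FALSE, s_cross = s[1]))
  }
  below <- which(f < threshold)
  if (length(below) == 0) {
    return(structure(2 * vx, at_nyquist = TRUE, s_cross = 1 / (2 * vx)))
  }
  i <- below[1]
  s_cross <- s[i - 1] + (s[i] - s[i - 1]) *
    (f[i - 1] - threshold) / (f[i - 1] - f[i])
  structure(1 / s_cross, at_nyquist = FALSE, s_cross = s_cross)
}

#' Windowed local resolution
#'
#' Slides a cubic window of `box` voxels over the two half maps on a regular
#' grid of `spacing` voxels, applies a spherical mask (radius box/2 with a
#' 10% cosine edge) to each pair of subvolumes, and records the FSC
#' threshold-crossing resolution at each grid position. Values are floored
#' at the Nyquist resolution.
#'
#' @param a,b half maps ([density_volume]s of equal shape).
#' @param box window size in voxels (default 40).
#' @param spacing grid spacing in voxels (default 4).
#' @param threshold FSC threshold (default 0.5).
#' @return object of class `local_resolution_field`: list with `values`
#'   (3D array of Angstrom resolutions), `centres` (list of the three axis
#'   index vectors, voxel units), `box`, `spacing`, `voxel_size`.
#' @export
local_resolution <- function(a, b, box = 40, spacing = 4, threshold = 0.5) {
  stopifnot_volume(a); stopifnot_volume(b)
  d <- dim(a$data)
  if (!all(dim(b$data) == d)) stop("half maps must share a shape",
                                   call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  if (box > min(d)) stop("`box` must fit inside the volume", call. = FALSE)
  vx <- a$voxel_size
  starts <- lapply(d, function(n) seq(1L, n - box + 1L, by = spacing))
  m <- make_mask(mask_spec("soft_sphere", radius = (box / 2) * vx,
                           soft_edge = 0.1 * box / 2),
                 rep(box, 3), vx)$data
  nv <- vapply(starts, length, 1L)
  vals <- array(NA_real_, nv)
  # precompute the shell partition of the box once (standard FFT layout)
  fi <- function(n) { v <- 0:(n - 1); ifelse(v > n %/% 2, v - n, v) }
  kx <- array(rep(fi(box), times = box * box), rep(box, 3))
  ky <- array(rep(rep(fi(box), each = box), times = box), rep(box, 3))
  kz <- array(rep(fi(box), each = box * box), rep(box, 3))
  shell <- as.integer(round(sqrt(kx^2 + ky^2 + kz^2)))
  nyq <- box %/% 2L
  keep <- which(shell <= nyq & shell > 0L)
  sh <- shell[keep] + 1L
  s_shells <- (1:nyq) / (box * vx)
  for (k3 in seq_len(nv[3])) for (k2 in seq_len(nv[2]))
    for (k1 in seq_len(nv[1])) {
      i <- starts[[1]][k1]; j <- starts[[2]][k2]; l <- starts[[3]][k3]
      sa <- a$data[i:(i + box - 1), j:(j + box - 1), l:(l + box - 1)] * m
      sb <- b$data[i:(i + box - 1), j:(j + box - 1), l:(l + box - 1)] * m
      if (all(sa == 0) || all(sb == 0)) next
      Fa <- fft(sa)[keep]; Fb <- fft(sb)[keep]   # shells are shift-invariant
      num <- rowsum_vec(Re(Fa) * Re(Fb) + Im(Fa) * Im(Fb), sh, nyq + 1L)
      pa <- rowsum_vec(Re(Fa)^2 + Im(Fa)^2, sh, nyq + 1L)
      pb <- rowsum_vec(Re(Fb)^2 + Im(Fb)^2, sh, nyq + 1L)
      f <- ifelse(pa > 0 & pb > 0, num / sqrt(pa * pb), NA_real_)[-1]
      vals[k1, k2, k3] <- max(crossing_resolution(s_shells, f, threshold, vx),
                              2 * vx)
    }
  structure(list(values = vals,
                 centres = lapply(starts, function(s) s + box / 2 - 0.5),
                 box = box, spacing = spacing, voxel_size = vx),
            class = "local_resolution_field")
}

# threshold crossing on a plain (s, fsc) sequence; returns Angstrom
crossing_resolution <- function(s, f, threshold, vx) {
  ok <- !is.na(f)
  s <- s[ok]; f <- f[ok]
  if (length(f) == 0) return(2 * vx)
  if (f[1] < threshold) return(1 / s[1])
  below <- which(f < threshold)
  if (length(below) == 0) return(2 * vx)
  i <- below[1]
  s_cross <- s[i - 1] + (s[i] - s[i - 1]) *
    (f[i - 1] - threshold) / (f[i - 1] - f[i])
  1 / s_cross
}

#' B-factor sharpening
#'
#' Multiplies Fourier amplitudes by `exp(-B s^2 / 4)` (s in 1/Angstrom; a
#' negative B sharpens), optionally followed by a cosine-edge low-pass at
#' the stated resolution. The DC term is unchanged.
#'
#' @param v a [density_volume].
#' @param b_factor B factor in Angstrom^2 (e.g. -2000 to sharpen).
#' @param lowpass optional low-pass resolution in Angstrom.
#' @param lowpass_width cosine edge width as a fraction of the cutoff
#'   frequency (default 0.1).
#' @return the filtered [density_volume].
#' @export
sharpen <- function(v, b_factor, lowpass = NULL, lowpass_width = 0.1) {
  stopifnot_volume(v)
  d <- dim(v$data)
  k <- freq_grids(d)
  s2 <- (k$kx / (d[1] * v$voxel_size))^2 + (k$ky / (d[2] * v$voxel_size))^2 +
        (k$kz / (d[3] * v$voxel_size))^2
  g <- exp(-b_factor * s2 / 4)
  if (!is.null(lowpass)) {
    s <- sqrt(s2)
    sc <- 1 / lowpass
    w <- sc * lowpass_width
    lp <- 0.5 * (1 + cos(pi * pmin(pmax(s - sc, 0) / max(w, 1e-12), 1)))
    lp[s <= sc] <- 1
    g <- g * lp
  }
  density_volume(isfft(sfft(v$data) * g), voxel_size = v$voxel_size,
                 origin = v$origin)
}
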