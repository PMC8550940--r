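# Geometric quantification of NPC architecture from density maps. All
# measurements operate on averages/phantoms with the NPC axis along z and
# the IR midplane near z = 0 (the package's alignment convention), report
# in nm, and use explicit landmark definitions (density maxima and
# half-maximum crossings on orthoslice profiles) in place of the manual
# measurements they emulate.

# mean density as a function of (cylindrical radius bin, z index);
# bin width = one voxel
cyl_profile <- function(v) {
  d <- dim(v$data)
  xs <- axis_coords(d[1], v$voxel_size)
  ys <- axis_coords(d[2], v$voxel_size)
  r <- sqrt(outer(xs^2, ys^2, "+"))
  rbin <- pmin(floor(r / v$voxel_size) + 1L, max(d[1:2]))
  nr <- max(rbin)
  counts <- tabulate(rbin, nr)
  prof <- matrix(0, nr, d[3])
  for (k in seq_len(d[3])) {
    sums <- tabulate_weighted(rbin, v$data[, , k], nr)
    prof[, k] <- sums / pmax(counts, 1)
  }
  list(profile = prof,
       r = (seq_len(nr) - 0.5) * v$voxel_size,   # bin-centre radius, A
       z = axis_coords(d[3], v$voxel_size))
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  acc <- rowsum(as.numeric(w), as.vector(bin))
  out[as.integer(rownames(acc))] <- acc
  out
}

# radial line profile along +/- an equatorial direction at `angle` degrees
# from +x, averaged over a perpendicular slab of +/- `hw` voxels and the
# given z slices. Returns profiles for the two opposite directions
# (sampled every voxel from the centre outward).
line_profiles <- function(v, angle = 0, z_idx, hw = 1) {
  d <- dim(v$data)
  ctr <- vol_centre(d)
  z_idx <- z_idx[z_idx >= 1 & z_idx <= d[3]]
  a <- angle * pi / 180
  dir <- c(cos(a), sin(a)); perp <- c(-sin(a), cos(a))
  rmax <- min(d[1:2]) %/% 2 - 1
  rr <- 0:rmax
  prof_for <- function(sgn) {
    acc <- 0; nacc <- 0
    for (off in -hw:hw) for (zi in z_idx) {
      coords <- cbind(ctr[1] + sgn * rr * dir[1] + off * perp[1],
                      ctr[2] + sgn * rr * dir[2] + off * perp[2],
                      rep(zi, length(rr)))
      acc <- acc + sample_trilinear(v$data, coords)
      nacc <- nacc + 1
    }
    acc / nacc
  }
  list(plus = prof_for(1), minus = prof_for(-1))
}

# azimuth of a subunit lobe (degrees): the diameter landmarks depend on
# whether a profile runs through a lobe or between lobes, so the two
# orthogonal measurement directions are taken through lobes. Falls back to
# 0 when no harmonic is detectable.
lobe_azimuth <- function(v, order = 8) {
  phi <- tryCatch(harmonic_phase(v, order), error = function(e) 0)
  if (!is.finite(phi)) 0 else phi
}

# outermost local maximum of a profile above the absolute level `lev`;
# subvoxel position by parabolic interpolation. r in sample units (0-based).
outermost_peak <- function(p, lev) {
  n <- length(p)
  if (n < 3) return(NA_real_)
  for (i in (n - 1):2) {
    if (p[i] >= lev && p[i] >= p[i - 1] && p[i] >= p[i + 1]) {
      return(i - 1 + parabolic_offset(p[i - 1], p[i], p[i + 1]))
    }
  }
  NA_real_
}

# innermost local maximum beyond r_min_samples
innermost_peak <- function(p, frac, r_min = 2) {
  n <- length(p)
  lev <- frac * max(p)
  for (i in (r_min + 1):(n - 1)) {
    if (p[i] >= lev && p[i] >= p[i - 1] && p[i] >= p[i + 1]) {
      return(i - 1 + parabolic_offset(p[i - 1], p[i], p[i + 1]))
    }
  }
  NA_real_
}

#' Membrane-to-membrane pore diameter
#'
#' Emulates the manual orthoslice measurement: on equatorial line profiles
#' (two orthogonal directions, each averaged over a thin slab), the membrane
#' is located as the outermost density maximum flanking the pore; the
#' NE-to-NE distance is taken at the narrowest z within the search band and
#' the two directions are averaged. Peak positions are refined to subvoxel
#' precision by parabolic interpolation. The band is restricted to the
#' membrane extent around the IR midplane (the measurement is made at the
#' level of the pore membrane) so ring densities outside it cannot be
#' mistaken for the envelope.
#'
#' @param v a [density_volume] (an NPC average or phantom).
#' @param z_band_nm half-extent of the z search band around the midplane
#'   (default 12 nm).
#' @param peak_frac minimum relative peak height (default 0.35).
#' @param angles the two measurement azimuths in degrees; `NULL` picks a
#'   lobe-aligned orthogonal pair (the landmark depends on whether the
#'   profile runs through a subunit lobe, so both directions are taken
#'   through lobes).
#' @return diameter in nm; attribute `per_direction` (nm per direction) and
#'   `z_narrowest_nm`.
#' @export
measure_pore_diameter <- function(v, z_band_nm = 12, peak_frac = 0.35,
                                  angles = NULL) {
  stopifnot_volume(v)
  d <- dim(v$data)
  vx <- v$voxel_size
  zc <- axis_coords(d[3], vx)
  z_cand <- which(abs(zc) <= z_band_nm * 10)
  lev <- peak_frac * max(v$data[, , z_cand])   # absolute membrane level
  if (!is.finite(lev) || lev <= 0)
    stop("no membrane detected: the volume is empty in the search band",
         call. = FALSE)
  if (is.null(angles)) {
    a0 <- lobe_azimuth(v)
    angles <- c(a0, a0 + 90)
  }
  res <- sapply(angles, function(ax) {
    n_z <- length(z_cand)
    rp <- rm <- hp <- rep(NA_real_, n_z)
    for (zi in seq_len(n_z)) {
      lp <- line_profiles(v, ax, z_cand[zi] + (-1:1))
      rp[zi] <- outermost_peak(lp$plus, lev)
      rm[zi] <- outermost_peak(lp$minus, lev)

      if (!is.na(rp[zi]) && !is.na(rm[zi]))
        hp[zi] <- min(lp$plus[round(rp[zi]) + 1], lp$minus[round(rm[zi]) + 1])
    }
    if (all(is.na(hp))) return(c(NA_real_, NA_real_))
    # group slices into connected ridge runs (adjacent z, radial jump
    # <= 4 voxels per side) and measure on the longest run: the envelope
    # is the long continuous ridge, while ring densities and streaks at
    # slices without membrane form short disconnected segments
    comp <- integer(n_z); cur <- 0L
    for (zi in seq_len(n_z)) {
      if (is.na(hp[zi])) { comp[zi] <- 0L; next }
      if (zi > 1 && !is.na(hp[zi - 1]) &&
          abs(rp[zi] - rp[zi - 1]) <= 4 && abs(rm[zi] - rm[zi - 1]) <= 4) {
        comp[zi] <- cur
      } else {
        cur <- cur + 1L
        comp[zi] <- cur
      }
    }
    sizes <- tabulate(comp)
    if (length(sizes) == 0) return(c(NA_real_, NA_real_))
    keep <- comp == which.max(sizes)
    if (sum(keep) < 2) return(c(NA_real_, NA_real_))
    diam_z <- ifelse(keep, (rp + rm) * vx, NA_real_)
    j <- which.min(diam_z)
    c(diam_z[j], zc[z_cand[j]])
  })
  per_dir <- setNames(res[1, ] / 10, paste0("a", round(angles)))
  if (all(is.na(per_dir)))
    stop("no membrane detected: no flanking density maxima found",
         call. = FALSE)
  if (any(is.na(per_dir)))
    warning("only a single direction measurable; single measurement used")
  structure(mean(per_dir, na.rm = TRUE), per_direction = per_dir,
            z_narrowest_nm = mean(res[2, ], na.rm = TRUE) / 10)
}

#' Central channel diameter
#'
#' Inner diameter of the IR density annulus at the IR midplane: on each of
#' two orthogonal equatorial line profiles, the IR is the innermost density
#' maximum; the channel edge is the first inward crossing of the
#' half-maximum level (relative to the local baseline), interpolated to
#' subvoxel precision. The two directions are averaged.
#'
#' @param v a [density_volume].
#' @param peak_frac minimum relative peak height (default 0.35).
#' @param r_min_nm smallest radius considered for the IR peak (default 8).
#' @param z_ir_nm IR midplane height in nm, if already measured
#'   (see [measure_axial_geometry()]); `NULL` measures it.
#' @param angles the two measurement azimuths in degrees; `NULL` picks a
#'   lobe-aligned orthogonal pair.
#' @return channel diameter in nm; attribute `per_direction`.
#' @export
measure_channel_diameter <- function(v, peak_frac = 0.35, r_min_nm = 8,
                                     z_ir_nm = NULL, angles = NULL) {
  stopifnot_volume(v)
  d <- dim(v$data)
  vx <- v$voxel_size
  if (is.null(z_ir_nm)) z_ir_nm <- measure_axial_geometry(v)$z_ir_nm
  z_ir <- z_ir_nm * 10
  z_idx <- which(abs(axis_coords(d[3], vx) - z_ir) <= 1.5 * vx)
  r_min <- max(2L, round(r_min_nm * 10 / vx))
  inner_half <- function(p) {
    pk <- innermost_peak(p, peak_frac, r_min)
    if (is.na(pk)) return(NA_real_)
    i <- round(pk)
    base <- min(p[seq_len(i + 1)])
    lev <- base + 0.5 * (p[i + 1] - base)
    for (j in (i + 1):2) {         # walk inward (1-based index j)
      if (p[j - 1] < lev) {
        f <- (p[j] - lev) / (p[j] - p[j - 1])
        return((j - 1) - f)        # 0-based subvoxel radius
      }
    }
    NA_real_
  }
  if (is.null(angles)) {
    a0 <- lobe_azimuth(v)
    angles <- c(a0, a0 + 90)
  }
  per_dir <- vapply(angles, function(ax) {
    lp <- line_profiles(v, ax, z_idx)
    rp <- inner_half(lp$plus); rm <- inner_half(lp$minus)
    if (is.na(rp) || is.na(rm)) NA_real_ else (rp + rm) * vx / 10
  }, 0)
  names(per_dir) <- paste0("a", round(angles))
  if (all(is.na(per_dir)))
    stop("no IR annulus detected", call. = FALSE)
  structure(mean(per_dir, na.rm = TRUE), per_direction = per_dir)
}

#' Ring axial geometry
#'
#' From the axial ring profile -- the maximum of the azimuthally averaged
#' density over the annulus radii inside the pore (maximum rather than mean,
#' so missing-wedge streaks through the channel cannot cancel the ring
#' signal) -- locates the IR as the peak nearest the midplane (centre of
#' mass of its peak region) and the CR/NR distal ends as the outermost
#' half-maximum crossings of their axial peaks. Distances are reported per
#' ring; the height is their sum by construction.
#'
#' @param v a [density_volume].
#' @param inner_radius_nm radial extent of the axial profile cylinder;
#'   `NULL` derives it from the measured pore diameter minus 6 nm.
#' @param peak_frac minimum relative peak height (default 0.25).
#' @param pore_diameter_nm pore diameter in nm, if already measured.
#' @return `list(ir_cr_nm, ir_nr_nm, height_nm, z_ir_nm)`; absent rings
#'   yield NA fields.
#' @export
measure_axial_geometry <- function(v, inner_radius_nm = NULL,
                                   peak_frac = 0.25,
                                   pore_diameter_nm = NULL) {
  stopifnot_volume(v)
  d <- dim(v$data)
  vx <- v$voxel_size
  if (is.null(inner_radius_nm)) {
    pd <- if (!is.null(pore_diameter_nm)) pore_diameter_nm else
      tryCatch(as.numeric(measure_pore_diameter(v)),
               error = function(e) NA_real_)
    inner_radius_nm <- if (is.na(pd)) (min(d[1:2]) / 2 - 2) * vx / 10 * 0.7
                       else pd / 2 - 6
  }
  cp <- cyl_profile(v)
  rkeep <- cp$r >= 120 & cp$r <= inner_radius_nm * 10
  a <- apply(cp$profile[rkeep, , drop = FALSE], 2, max)
  a_s <- smooth3(a)
  z <- cp$z
  lev <- peak_frac * max(a_s)
  peaks <- which(diff(sign(diff(a_s))) < 0) + 1L
  peaks <- peaks[a_s[peaks] >= lev]
  if (length(peaks) == 0) stop("no ring density found", call. = FALSE)
  ir_pk <- peaks[which.min(abs(z[peaks]))]
  if (abs(z[ir_pk]) > 120)
    stop("no IR density near the midplane", call. = FALSE)
  # IR centre: centre of mass over the IR peak's half-max region
  half <- 0.5 * a_s[ir_pk]
  lo <- ir_pk; while (lo > 1 && a_s[lo - 1] >= half &&
                      a_s[lo - 1] <= a_s[lo]) lo <- lo - 1
  hi <- ir_pk; while (hi < length(a_s) && a_s[hi + 1] >= half &&
                      a_s[hi + 1] <= a_s[hi]) hi <- hi + 1
  z_ir <- sum(z[lo:hi] * a_s[lo:hi]) / sum(a_s[lo:hi])
  distal_edge <- function(side) {
    cand <- peaks[side * (z[peaks] - z_ir) > 5 * vx]
    if (length(cand) == 0) return(NA_real_)
    pk <- cand[which.max(a_s[cand])]
    base <- unname(stats::quantile(a_s, 0.05))
    levh <- base + 0.5 * (a_s[pk] - base)
    idx <- if (side > 0) pk:length(a_s) else pk:1
    for (j in seq_along(idx)[-1]) {
      if (a_s[idx[j]] < levh) {
        f <- (a_s[idx[j - 1]] - levh) / (a_s[idx[j - 1]] - a_s[idx[j]])
        return(z[idx[j - 1]] + f * (z[idx[j]] - z[idx[j - 1]]))
      }
    }
    NA_real_
  }
  z_cr <- distal_edge(+1)
  z_nr <- distal_edge(-1)
  ir_cr <- if (is.na(z_cr)) NA_real_ else (z_cr - z_ir) / 10
  ir_nr <- if (is.na(z_nr)) NA_real_ else (z_ir - z_nr) / 10
  list(ir_cr_nm = ir_cr, ir_nr_nm = ir_nr, height_nm = ir_cr + ir_nr,
       z_ir_nm = z_ir / 10)
}

smooth3 <- function(x) {
  n <- length(x)
  c(x[1], (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3, x[n])
}

#' Membrane angles against the IR midplane
#'
#' Traces the nuclear envelope cone on each side of the midplane and
#' reports the absolute angle of the membrane midline to the IR midplane
#' (cytoplasmic = +z by the package's orientation convention). The primary
#' landmark is the radial position of the outermost membrane density
#' maximum per z slice (radial positions are well determined under a
#' missing wedge), traced as a connected run outward from the waist and fit
#' by weighted least squares; slices closer than 2 voxels to the waist are
#' excluded (the smeared waist rim biases them inward). When fewer than
#' three slices qualify (e.g. a flat membrane), the method falls back to
#' the axial ridge of the azimuthally averaged (r, z) density.
#'
#' @param v a [density_volume].
#' @param z_max_nm axial search limit per side (default 25 nm).
#' @param r_margin_nm radial offset from the waist where the fallback ridge
#'   trace starts (default 3 nm).
#' @param pore_diameter_nm pore diameter in nm, if already measured.
#' @param peak_frac minimum relative peak height (default 0.35).
#' @return `c(cyto = degrees, nucleo = degrees)`; a side without membrane
#'   gives NA.
#' @export
measure_membrane_angles <- function(v, z_max_nm = 25, r_margin_nm = 3,
                                    pore_diameter_nm = NULL,
                                    peak_frac = 0.35) {
  stopifnot_volume(v)
  vx <- v$voxel_size
  d <- dim(v$data)
  pd <- if (!is.null(pore_diameter_nm)) pore_diameter_nm else
    as.numeric(measure_pore_diameter(v))
  r_w <- as.numeric(pd) * 10 / 2
  cp <- cyl_profile(v)
  zb <- abs(cp$z) <= z_max_nm * 10
  lev <- peak_frac * max(cp$profile[, zb])
  r_lim <- (min(d[1:2]) / 2 - 9) * vx        # stay inside the edge taper
  radial_trace <- function(side) {
    zi <- which(side * cp$z >= 0 & abs(cp$z) <= z_max_nm * 10)
    zi <- zi[order(abs(cp$z[zi]))]           # waist outward
    rs <- c(); zs <- c(); ws <- c()
    prev_r <- r_w
    for (k in zi) {
      pk <- outermost_peak(cp$profile[, k], lev)
      if (is.na(pk)) break
      r_m <- (pk + 0.5) * vx
      if (abs(r_m - prev_r) > 2.5 * vx || r_m > r_lim) break
      if (abs(cp$z[k]) >= 1.5 * vx) {
        rs <- c(rs, r_m); zs <- c(zs, abs(cp$z[k]))
        ws <- c(ws, cp$profile[round(pk) + 1, k])
      }
      prev_r <- r_m
    }
    if (length(rs) < 3) return(NA_real_)
    fit <- stats::lm(zs ~ rs, weights = ws)
    abs(atan(unname(coef(fit)[2])) * 180 / pi)
  }
  mem_max <- max(cp$profile[cp$r >= r_w - 2 * vx, zb])
  r_use <- which(cp$r >= r_w + r_margin_nm * 10 & cp$r <= r_lim)
  ridge_fallback <- function(side) {
    zi <- which(side * cp$z >= 0 & abs(cp$z) <= z_max_nm * 10)
    if (side < 0) zi <- rev(zi)              # order: z = 0 outward
    if (length(zi) < 3) return(NA_real_)
    rs <- c(); zs <- c(); ws <- c()
    for (ri in r_use) {
      col <- cp$profile[ri, zi]
      j <- which.max(col)
      if (col[j] < 0.3 * mem_max) next
      if (j >= length(col)) next
      off <- if (j > 1) parabolic_offset(col[j - 1], col[j], col[j + 1])
             else 0                       # ridge on the midplane itself
      rs <- c(rs, cp$r[ri])
      zs <- c(zs, abs(cp$z[zi[j]]) + off * vx)
      ws <- c(ws, col[j])
    }
    if (length(rs) < 3) return(NA_real_)
    fit <- stats::lm(zs ~ rs, weights = ws)
    abs(atan(unname(coef(fit)[2])) * 180 / pi)
  }
  side_angle <- function(side) {
    a <- radial_trace(side)
    if (is.na(a)) a <- ridge_fallback(side)
    a
  }
  c(cyto = side_angle(+1), nucleo = side_angle(-1))
}

#' Channel cylinder volume
#'
#' The IR channel volume modelled as a cylinder: `pi (d/2)^2 h`.
#'
#' @param diameter channel diameter in nm (>= 0).
#' @param height cylinder height in nm (default 20).
#' @return volume in nm^3.
#' @export
channel_cylinder_volume <- function(diameter, height = 20) {
  if (diameter < 0 || height < 0) stop("inputs must be >= 0", call. = FALSE)
  pi * (diameter / 2)^2 * height
}

#' Percent increase
#'
#' `100 * (b / a - 1)`, the arithmetic behind "x% larger" comparisons.
#'
#' @param a reference value (> 0).
#' @param b comparison value.
#' @return percent increase of `b` over `a`.
#' @export
percent_increase <- function(a, b) {
  if (a <= 0) stop("reference must be > 0", call. = FALSE)
  100 * (b / a - 1)
}

#' Ring-shell mask specifications for a phantom geometry
#'
#' Cylindrical shells around the CR/IR/NR positions of a
#' [phantom_params()] geometry (all three rings, regardless of
#' `present_rings`), used for ring-presence calls.
#'
#' @param params a [phantom_params()].
#' @param width_sigma shell half-width in units of the ring sigma
#'   (default 1.5).
#' @return named list of [mask_spec()]s.
#' @export
ring_shell_specs <- function(params, width_sigma = 1.5) {
  geo <- phantom_geometry(params)
  out <- lapply(geo$rings, function(g) {
    mask_spec("ring_shell",
              r_inner = max(0, g$r - width_sigma * g$sr),
              r_outer = g$r + width_sigma * g$sr,
              z_min = g$z - width_sigma * g$sz,
              z_max = g$z + width_sigma * g$sz)
  })
  names(out) <- names(geo$rings)
  out
}

#' Ring presence call
#'
#' A ring is called present when the mean density inside its shell exceeds
#' the robust background level (median of the volume outside all shells) by
#' `threshold_sigma` robust standard deviations (MAD-based). Deterministic.
#'
#' @param v a [density_volume].
#' @param shells named list of non-overlapping ring [mask_spec()]s
#'   (see [ring_shell_specs()]).
#' @param threshold_sigma detection threshold (default 5).
#' @return character vector: the subset of `names(shells)` called present
#'   (attribute `zscores` carries the per-ring scores).
#' @export
ring_presence <- function(v, shells, threshold_sigma = 5) {
  stopifnot_volume(v)
  d <- dim(v$data)
  masks <- lapply(shells, function(s) make_mask(s, d, v$voxel_size)$data)
  hard <- lapply(masks, function(m) m >= 0.5)
  for (i in seq_along(hard)) for (j in seq_along(hard)) {
    if (i < j && any(hard[[i]] & hard[[j]]))
      stop("ring shells overlap: ", names(shells)[i], " / ",
           names(shells)[j], call. = FALSE)
  }
  bg_region <- !Reduce(`|`, hard)
  bg <- v$data[bg_region]
  # floor the robust scale so noise-free maps (background exactly zero)
  # do not declare every shell present
  sigma <- max(mad(bg), 1e-3 * max(abs(v$data)))
  zs <- vapply(hard, function(h) (mean(v$data[h]) - median(bg)) / sigma, 0)
  structure(names(shells)[zs > threshold_sigma], zscores = zs)
}

# largest-remainder (Hamilton) apportionment of percentages to integers
# summing to 100
largest_remainder_percent <- function(counts) {
  if (sum(counts) == 0) return(rep(0L, length(counts)))
  exact <- 100 * counts / sum(counts)
  fl <- floor(exact)
  rem <- 100L - sum(fl)
  add <- order(exact - fl, decreasing = TRUE)[seq_len(rem)]
  fl[add] <- fl[add] + 1
  as.integer(fl)
}

#' Summarize classes and measurements
#'
#' Per-class counts and integer percentages (largest-remainder
#' apportionment, so they total 100), plus summary statistics of any
#' numeric measurements supplied.
#'
#' @param class_labels integer class labels (one per particle); empty input
#'   yields an empty report, not an error.
#' @param measurements optional named list of numeric vectors (e.g.
#'   per-particle diameters in nm).
#' @return `list(classes = data.frame(class, n, percent),
#'   measurements = data.frame(name, n, mean, sd, min, max))`.
#' @export
summarize_measurements <- function(class_labels, measurements = NULL) {
  if (length(class_labels) == 0) {
    classes <- data.frame(class = integer(0), n = integer(0),
                          percent = integer(0))
  } else {
    tab <- table(class_labels)
    classes <- data.frame(class = as.integer(names(tab)),
                          n = as.integer(tab),
                          percent = largest_remainder_percent(as.integer(tab)))
  }
  meas <- NULL
  if (!is.null(measurements) && length(measurements)) {
    meas <- do.call(rbind, lapply(names(measurements), function(nm) {
      x <- measurements[[nm]]
      data.frame(name = nm, n = length(x), mean = mean(x),
                 sd = if (length(x) > 1) sd(x) else NA_real_,
                 min = suppressWarnings(min(x)),
                 max = suppressWarnings(max(x)))
    }))
  }
  list(classes = classes, measurements = meas)
}
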