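#' Expand aligned particles into asymmetric-unit protomers
#'
#' Emits `order` protomer records per particle. Protomer `k` (asu_index
#' `k = 0..order-1`) has pose `parent_pose %o% Rz(360 k / order)` and its
#' centre displaced from the parent centre by `radial_offset` along the
#' asu azimuth in the particle frame.
#'
#' @param table [particle_table()] with refined parent poses (no NAs).
#' @param order symmetry order (8 for the NPC).
#' @param radial_offset protomer centre radius in Angstrom.
#' @param voxel_size particle voxel size in Angstrom (to express protomer
#'   centres in voxels).
#' @return data.frame of class `protomer_records` with columns
#'   `parent_particle_id, asu_index, rot, tilt, psi, x, y, z, cc, included`.
#' @export
expand_protomers <- function(table, order, radial_offset, voxel_size = 13.6) {
  if (any(is.na(table$rot) | is.na(table$tilt) | is.na(table$psi)))
    stop("all particles must carry refined poses", call. = FALSE)
  order <- as.integer(order)
  n <- nrow(table)
  out <- vector("list", n)
  r_vox <- radial_offset / voxel_size
  for (i in seq_len(n)) {
    Rp <- euler_matrix(table$rot[i], table$tilt[i], table$psi[i])
    tp <- c(table$x[i], table$y[i], table$z[i])
    rows <- vector("list", order)
    for (k in seq_len(order) - 1L) {
      phi <- 360 * k / order
      Rk <- Rp %*% euler_matrix(phi, 0, 0)
      ck <- r_vox * c(cos(phi * pi / 180), sin(phi * pi / 180), 0)
      pos <- as.vector(Rp %*% ck) + tp
      e <- matrix_to_euler(Rk)
      rows[[k + 1L]] <- data.frame(
        parent_particle_id = table$particle_id[i], asu_index = k,
        rot = e[1], tilt = e[2], psi = e[3],
        x = pos[1], y = pos[2], z = pos[3],
        cc = table$cc[i], included = TRUE,
        stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  class(rec) <- c("protomer_records", "data.frame")
  rec
}

#' Extract protomer subvolumes
#'
#' Resamples each protomer's box out of its parent particle, bringing it to
#' the common protomer reference frame (protomer centre at the box centre,
#' axes of the asymmetric unit).
#'
#' @param particles list of parent [density_volume]s.
#' @param parent_ids character vector naming `particles` (matched against
#'   `records$parent_particle_id`).
#' @param records [expand_protomers()] output.
#' @param box protomer box size in voxels.
#' @return list of [density_volume]s, one per record (in record order).
#' @export
extract_protomers <- function(particles, parent_ids, records, box) {
  box <- as.integer(box)
  d_out <- rep(box, 3)
  c_out <- vol_centre(d_out)
  g <- as.matrix(expand.grid(seq_len(box), seq_len(box), seq_len(box)))
  y0 <- sweep(g, 2, c_out)
  lapply(seq_len(nrow(records)), function(j) {
    pi_ <- match(records$parent_particle_id[j], parent_ids)
    if (is.na(pi_)) stop("record parent not found among particles",
                         call. = FALSE)
    p <- particles[[pi_]]
    Rk <- euler_matrix(records$rot[j], records$tilt[j], records$psi[j])
    ctr <- vol_centre(dim(p$data))
    pos <- c(records$x[j], records$y[j], records$z[j])
    coords <- y0 %*% t(Rk)
    coords <- sweep(coords, 2, pos + ctr, "+")
    density_volume(array(sample_trilinear(p$data, coords), d_out),
                   voxel_size = p$voxel_size)
  })
}

#' Masked local refinement of protomer poses
#'
#' Refines each protomer against the (masked) average of the stack by a
#' small-range grid search of the masked constrained cross-correlation:
#' rotations within `max_angle` at step `step`, translations within
#' `max_shift` voxels. Pose updates are composed into the records.
#'
#' @param records [expand_protomers()] output.
#' @param stack list of protomer [density_volume]s (record order; see
#'   [extract_protomers()]).
#' @param ring_mask a [mask_spec()] for the ring of interest (applied to the
#'   reference in real space).
#' @param wedge the acquisition [wedge_mask()] at the protomer box size.
#' @param step angular step in degrees (default 4).
#' @param max_angle rotation search limit (default 10 degrees).
#' @param max_shift translation search limit in voxels (default 5).
#' @return updated records (refined poses and cc scores).
#' @export
masked_refine <- function(records, stack, ring_mask, wedge, step = 4,
                          max_angle = 10, max_shift = 5) {
  if (length(stack) != nrow(records))
    stop("stack must match records", call. = FALSE)
  d <- dim(stack[[1]]$data)
  vx <- stack[[1]]$voxel_size
  m <- make_mask(ring_mask, d, vx)$data
  if (sum(m >= 0.5) < 8) stop("ring mask is empty on this grid",
                              call. = FALSE)
  inc <- which(records$included)
  ref <- Reduce(`+`, lapply(stack[inc], function(v) v$data)) / length(inc)
  ref_m <- ref * m
  steps <- unique(pmin(seq(0, max_angle, by = step), max_angle))
  offs <- sort(unique(c(-steps, steps)))
  cand <- as.matrix(expand.grid(rot = offs, tilt = offs, psi = offs))
  cand <- cand[rowSums(abs(cand)) <= max_angle + 1e-9, , drop = FALSE]
  for (j in seq_len(nrow(records))) {
    Rk <- euler_matrix(records$rot[j], records$tilt[j], records$psi[j])
    Wp <- (wedge_array_rotated(wedge, Rk) >= 0.5) * 1
    ctr <- vol_centre(d); Wp[ctr[1], ctr[2], ctr[3]] <- 0
    Sp <- sfft(stack[[j]]$data)
    nb <- sum(Wp * (Re(Sp)^2 + Im(Sp)^2))
    best <- list(score = -Inf, delta = c(0, 0, 0), shift = c(0, 0, 0))
    for (ci in seq_len(nrow(cand))) {
      Rd <- euler_matrix(cand[ci, ])
      a <- affine_resample(ref_m, t(Rd), interp = "linear")
      Sa <- sfft(a)
      na <- sum(Wp * (Re(Sa)^2 + Im(Sa)^2))
      if (na <= 0 || nb <= 0)
        stop("degenerate overlap: masked reference has no power",
             call. = FALSE)
      P <- Wp * Conj(Sa) * Sp
      ccmap <- Re(fft(ifftshift3(P), inverse = TRUE)) / sqrt(na * nb)
      pk <- cc_peak(ccmap, max_shift)
      if (pk$score > best$score)
        best <- list(score = pk$score, delta = cand[ci, ], shift = pk$shift)
    }
    Rnew <- Rk %*% euler_matrix(best$delta)
    e <- matrix_to_euler(Rnew)
    records$rot[j] <- e[1]; records$tilt[j] <- e[2]; records$psi[j] <- e[3]
    pos_d <- as.vector(Rk %*% best$shift)
    records$x[j] <- records$x[j] + pos_d[1]
    records$y[j] <- records$y[j] + pos_d[2]
    records$z[j] <- records$z[j] + pos_d[3]
    records$cc[j] <- best$score
  }
  records
}

#' Exclude low-quality protomers
#'
#' Flags records failing the rule with `included = FALSE` (soft delete; the
#' record count is preserved so protomer accounting stays auditable). Ties
#' are broken deterministically by ascending `(cc, parent_particle_id,
#' asu_index)`.
#'
#' @param records [expand_protomers()] output with cc scores populated.
#' @param rule `"cc_threshold"` (exclude cc < value), `"worst_k"` (exclude
#'   the value lowest-scoring records), or `"percentile"` (exclude the
#'   lowest value fraction in (0, 1)).
#' @param value rule parameter.
#' @return records with the `included` flag updated.
#' @export
exclude_protomers <- function(records, rule = c("cc_threshold", "worst_k",
                                                "percentile"), value) {
  rule <- match.arg(rule)
  if (any(is.na(records$cc)))
    stop("cc scores must be populated before exclusion", call. = FALSE)
  ord <- order(records$cc, records$parent_particle_id, records$asu_index)
  n <- nrow(records)
  k <- switch(rule,
              cc_threshold = sum(records$cc < value),
              worst_k = as.integer(value),
              percentile = floor(n * value))
  if (k >= n) stop("exclusion rule removes every record", call. = FALSE)
  records$included <- TRUE
  if (k > 0) records$included[ord[seq_len(k)]] <- FALSE
  records
}

#' Split particles into ring-presence classes
#'
#' Class 1 = `{CR, IR, NR}`, class 2 = `{IR, NR}`, class 3 = `{IR}`.
#' A `{CR, IR}` call is flagged class 0 ("unexpected") with a warning --
#' the CR is lost before the NR under scaffold depletion, so CR+IR
#' assemblies are not expected. Any other combination is also class 0.
#'
#' @param table a [particle_table()].
#' @param presence named list: `particle_id -> character subset of
#'   c("CR", "IR", "NR")` (see [ring_presence()]).
#' @return the table with `class_label` filled in.
#' @export
split_classes <- function(table, presence) {
  missing_ids <- setdiff(table$particle_id, names(presence))
  if (length(missing_ids))
    stop("ring-presence call missing for: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  lab <- function(p) {
    if (setequal(p, c("CR", "IR", "NR"))) return(1L)
    if (setequal(p, c("IR", "NR"))) return(2L)
    if (setequal(p, "IR")) return(3L)
    if (setequal(p, c("CR", "IR")))
      warning("unexpected CR+IR assembly (class 0)")
    0L
  }
  table$class_label <- vapply(table$particle_id,
                              function(id) lab(presence[[id]]), 1L)
  table
}

#' Compose a full map from a subprotomer average
#'
#' Places the subprotomer volume into the canvas at the given pose and
#' blends the `order` symmetry copies (rotated about z). The composite is
#' Cn-symmetric by construction.
#'
#' @param subprotomer a [density_volume] (the subprotomer average).
#' @param order symmetry order.
#' @param placement `list(euler = c(rot, tilt, psi), shift = c(x, y, z))`
#'   mapping the subprotomer frame into the canvas frame (shift in canvas
#'   voxels from the canvas centre).
#' @param canvas canvas dimensions (length 1 or 3).
#' @param blend `"max"` (default) or `"mean"`.
#' @return the composite [density_volume].
#' @export
compose_full_map <- function(subprotomer, order, placement, canvas,
                             blend = c("max", "mean")) {
  blend <- match.arg(blend)
  stopifnot_volume(subprotomer)
  if (length(canvas) == 1L) canvas <- rep(canvas, 3L)
  canvas <- as.integer(canvas)
  d_sub <- dim(subprotomer$data)
  c_sub <- vol_centre(d_sub)
  c_cv <- vol_centre(canvas)
  if (any(abs(placement$shift) > canvas / 2))
    stop("placement falls outside the canvas", call. = FALSE)
  Rpl <- euler_matrix(placement$euler)
  g <- as.matrix(expand.grid(seq_len(canvas[1]), seq_len(canvas[2]),
                             seq_len(canvas[3])))
  xc <- sweep(g, 2, c_cv)
  acc <- NULL
  for (k in seq_len(order) - 1L) {
    Rzk <- euler_matrix(360 * k / order, 0, 0)
    Rk <- Rzk %*% Rpl
    tk <- as.vector(Rzk %*% placement$shift)
    coords <- sweep(xc, 2, tk) %*% Rk          # = t(R_k^-1 %*% t(xc - tk))
    coords <- sweep(coords, 2, c_sub, "+")
    vals <- sample_trilinear(subprotomer$data, coords)
    acc <- if (is.null(acc)) vals else
      if (blend == "max") pmax(acc, vals) else acc + vals
  }
  if (blend == "mean") acc <- acc / order
  density_volume(array(acc, canvas), voxel_size = subprotomer$voxel_size)
}
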