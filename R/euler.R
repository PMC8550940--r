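#' ZYZ Euler rotation matrix
#'
#' Package-wide Euler convention: ZYZ intrinsic, degrees. The returned matrix
#' maps reference-frame coordinates onto particle-frame coordinates,
#' `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)`.
#'
#' Worked example: `euler_matrix(90, 0, 0) %*% c(1, 0, 0)` sends the unit x
#' vector to (0, 1, 0) -- a +90 degree turn about z; `euler_matrix(0, 90, 0)`
#' sends (1, 0, 0) to (0, 0, -1) -- a +90 degree turn about y.
#'
#' @param rot,tilt,psi angles in degrees; alternatively `rot` may be a
#'   length-3 vector `(rot, tilt, psi)`.
#' @return 3x3 rotation matrix.
#' @export
euler_matrix <- function(rot, tilt = NULL, psi = NULL) {
  if (is.null(tilt) && length(rot) == 3L) {
    tilt <- rot[2]; psi <- rot[3]; rot <- rot[1]
  }
  rz <- function(a) {
    a <- a * pi / 180; c_ <- cos(a); s <- sin(a)
    matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180; c_ <- cos(a); s <- sin(a)
    matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
  }
  rz(rot) %*% ry(tilt) %*% rz(psi)
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_matrix()]; angles returned normalized with
#' `rot, psi` in `[-180, 180)` and `tilt` in `[0, 180]`.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector `(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  tilt <- acos(max(-1, min(1, R[3, 3]))) * 180 / pi
  if (abs(R[3, 3]) > 1 - 1e-10) {
    # degenerate: only rot + psi (or rot - psi) defined; put it all in psi
    rot <- 0
    psi <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    if (R[3, 3] < 0) psi <- -psi
  } else {
    rot <- atan2(R[2, 3], R[1, 3]) * 180 / pi
    psi <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  }
  normalize_euler(c(rot = rot, tilt = tilt, psi = psi))
}

#' Normalize Euler angles to the package ranges
#'
#' `rot`, `psi` are wrapped to `[-180, 180)`; `tilt` is folded into
#' `[0, 180]` (a negative tilt is equivalent to flipping rot and psi by 180).
#'
#' @param e numeric length-3 `(rot, tilt, psi)` in degrees.
#' @return normalized `(rot, tilt, psi)`.
#' @export
normalize_euler <- function(e) {
  wrap <- function(a) ((a + 180) %% 360) - 180
  rot <- e[[1]]; tilt <- e[[2]]; psi <- e[[3]]
  tilt <- wrap(tilt)
  if (tilt < 0) { tilt <- -tilt; rot <- rot + 180; psi <- psi + 180 }
  c(rot = wrap(rot), tilt = tilt, psi = wrap(psi))
}

# geodesic distance between two rotations, degrees
rotation_distance <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Particle pose table
#'
#' Builds the package's particle table: one row per particle with position
#' (voxels, translation of the particle relative to the reference frame),
#' ZYZ Euler angles (degrees, reference -> particle), a correlation score,
#' a half-set label in `{A, B}` and an optional integer class label.
#'
#' @param particle_id unique particle identifiers.
#' @param source_id tomogram / simulation batch identifier.
#' @param x,y,z translations in voxels.
#' @param rot,tilt,psi ZYZ Euler angles in degrees.
#' @param cc correlation score (NA before alignment).
#' @param half_set "A" or "B".
#' @param class_label optional integer class.
#' @return a `data.frame` with class `particle_table`.
#' @export
particle_table <- function(particle_id, source_id = "sim",
                           x = 0, y = 0, z = 0,
                           rot = 0, tilt = 0, psi = 0,
                           cc = NA_real_, half_set = NA_character_,
                           class_label = NA_integer_) {
  df <- data.frame(particle_id = as.character(particle_id),
                   source_id = as.character(source_id),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   rot = as.numeric(rot), tilt = as.numeric(tilt),
                   psi = as.numeric(psi), cc = as.numeric(cc),
                   half_set = as.character(half_set),
                   class_label = as.integer(class_label),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$particle_id))
    stop("particle_id values must be unique", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    e <- normalize_euler(c(df$rot[i], df$tilt[i], df$psi[i]))
    df$rot[i] <- e[1]; df$tilt[i] <- e[2]; df$psi[i] <- e[3]
  }
  class(df) <- c("particle_table", "data.frame")
  df
}

#' Write / read a particle table as tab-separated text
#'
#' Fixed, documented column order:
#' `particle_id source_id x y z rot tilt psi cc half_set class_label`.
#'
#' @param table a [particle_table()].
#' @param path file path.
#' @return `read_particle_table` returns a `particle_table`.
#' @export
write_particle_table <- function(table, path) {
  cols <- c("particle_id", "source_id", "x", "y", "z", "rot", "tilt", "psi",
            "cc", "half_set", "class_label")
  write.table(table[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_particle_table
#' @export
read_particle_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("particle_id", "source_id", "x", "y", "z", "rot", "tilt", "psi",
            "cc", "half_set", "class_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("particle table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$particle_id <- as.character(df$particle_id)
  df$half_set <- as.character(df$half_set)
  class(df) <- c("particle_table", "data.frame")
  df
}
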