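#' Construct a density volume
#'
#' A `density_volume` is the package's universal currency: a 3D scalar grid
#' with a physical voxel size. The physical origin (0, 0, 0) is at voxel index
#' `floor(dim/2) + 1` along each axis unless an explicit `origin` offset is
#' given.
#'
#' @param data numeric 3D array (nx x ny x nz), all values finite.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin physical coordinate (Angstrom) assigned to the grid centre,
#'   default `c(0, 0, 0)`.
#' @return An object of class `density_volume` with elements `data`,
#'   `voxel_size`, `origin`.
#' @examples
#' v <- density_volume(array(0, c(8, 8, 8)), voxel_size = 13.6)
#' dim(v$data)
#' @export
density_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("volume dimensions must be >= 2 in each axis", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (Angstrom)",
         call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_volume> %d x %d x %d voxels @ %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

is_density_volume <- function(x) inherits(x, "density_volume")

stopifnot_volume <- function(v, what = "volume") {
  if (!is_density_volume(v)) stop(what, " must be a density_volume",
                                  call. = FALSE)
  invisible(v)
}

# 1-based index of the physical centre along each axis
vol_centre <- function(dim) dim %/% 2L + 1L

# physical axis coordinates (Angstrom) for each voxel index along axis i
axis_coords <- function(n, voxel_size) (seq_len(n) - (n %/% 2L + 1L)) * voxel_size

#' Read an MRC2014 volume
#'
#' Reads modes 0 (int8), 1 (int16), 2 (float32) and 12 (float16 is not
#' supported; an error is raised for unknown modes). The voxel size is taken
#' from the cell dimensions in the header; a zero voxel size falls back to
#' 1.0 Angstrom with a warning.
#'
#' @param path path to an MRC file.
#' @return A [density_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  fsize <- file.info(path)$size
  if (is.na(fsize) || fsize < 1024)
    stop("corrupt MRC file (shorter than the 1024-byte header): ", path,
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5))
    stop("corrupt MRC header (bad dimensions)", call. = FALSE)
  if (any(c(nx, ny, nz) < 2))
    stop("MRC data is not 3D (all dimensions must be >= 2)", call. = FALSE)
  bytes <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L,
                  stop("unsupported MRC mode: ", mode, call. = FALSE))
  # header words 24 (nsymbt) .. skip to data
  seek(con, 23 * 4)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  ndata <- as.numeric(nx) * ny * nz
  if (fsize < 1024 + nsymbt + ndata * bytes)
    stop("truncated MRC file: ", path, call. = FALSE)
  seek(con, 1024 + nsymbt)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = ndata, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = ndata, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = ndata, size = 4, endian = "little"))
  if (length(data) < ndata) stop("truncated MRC data: ", path, call. = FALSE)
  vs <- if (mx > 0) cella[1] / mx else 0
  if (!is.finite(vs) || vs <= 0) {
    warning("MRC header has no voxel size; falling back to 1.0 A")
    vs <- 1.0
  }
  density_volume(array(data, c(nx, ny, nz)), voxel_size = vs)
}

#' Write an MRC2014 volume (mode 2, 32-bit float)
#'
#' Values are stored as 32-bit floats; writing is deterministic for identical
#' input. `write_volume()` then [read_volume()] round-trips bit-for-bit for
#' data already representable in float32.
#'
#' @param v a [density_volume].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_volume <- function(v, path) {
  stopifnot_volume(v)
  d <- dim(v$data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write: ", path, call. = FALSE))
  on.exit(close(con))
  wb_i <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wb_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wb_i(c(d, 2L))                       # nx ny nz mode
  wb_i(c(0L, 0L, 0L))                  # nxstart
  wb_i(d)                              # mx my mz
  wb_f(d * v$voxel_size)               # cella
  wb_f(c(90, 90, 90))                  # cellb
  wb_i(c(1L, 2L, 3L))                  # mapc mapr maps
  wb_f(c(min(v$data), max(v$data), mean(v$data)))  # dmin dmax dmean
  wb_i(c(1L, 0L))                      # ispg, nsymbt
  wb_i(rep(0L, 25))                    # extra
  wb_f(c(0, 0, 0))                     # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wb_f(stats::sd(v$data))              # rms
  wb_i(0L)                             # nlabl
  writeBin(raw(800), con)              # labels
  wb_f(v$data)
  invisible(path)
}
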