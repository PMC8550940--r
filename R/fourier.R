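# Fourier helpers shared by the wedge, alignment and resolution modules.
#
# Spectra are kept in *centred* layout: the DC component sits at voxel index
# floor(n/2) + 1 along each axis, the same index that holds the physical
# origin of a real-space volume. `sfft` computes the DFT of a volume whose
# object is centred there (so rotations of the spectrum about that index
# correspond to rotations of the object about the grid centre with no extra
# phase factor).

circshift3 <- function(x, s) {
  d <- dim(x)
  idx1 <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  idx2 <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  idx3 <- ((seq_len(d[3]) - 1 - s[3]) %% d[3]) + 1
  x[idx1, idx2, idx3, drop = FALSE]
}

fftshift3 <- function(x) circshift3(x, dim(x) %/% 2L)
ifftshift3 <- function(x) circshift3(x, -(dim(x) %/% 2L))

# centred integer frequency coordinates along an axis of length n
freq_index <- function(n) seq_len(n) - (n %/% 2L + 1L)

# centred DFT of a centre-origin volume (array in, complex array out)
sfft <- function(a) fftshift3(fft(ifftshift3(a)))

# inverse of sfft; returns the real part
isfft <- function(S) {
  n <- prod(dim(S))
  fftshift3(Re(fft(ifftshift3(S), inverse = TRUE))) / n
}

# 3D arrays of centred frequency indices
freq_grids <- function(d) {
  list(kx = array(rep(freq_index(d[1]), times = d[2] * d[3]), d),
       ky = array(rep(rep(freq_index(d[2]), each = d[1]), times = d[3]), d),
       kz = array(rep(freq_index(d[3]), each = d[1] * d[2]), d))
}

# phase ramp exp(+2*pi*i*(k . t)/n) in centred layout; t in voxels
phase_ramp <- function(d, t) {
  k <- freq_grids(d)
  ph <- 2 * pi * (k$kx * (t[1] / d[1]) + k$ky * (t[2] / d[2]) +
                  k$kz * (t[3] / d[3]))
  complex(modulus = 1, argument = ph)
}

#' Fourier-crop (bin) a volume
#'
#' Downsamples by an integer factor by cropping the centred spectrum (an
#' exact band limit, not real-space decimation). The voxel size grows by the
#' same factor; densities keep their scale (the mean value is preserved).
#'
#' @param v a [density_volume].
#' @param factor integer >= 1 dividing every dimension; the new grid must
#'   have even dimensions.
#' @return the binned [density_volume].
#' @export
fourier_crop <- function(v, factor) {
  stopifnot_volume(v)
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(v)
  d <- dim(v$data)
  if (any(d %% factor != 0L))
    stop("dimensions must be divisible by the binning factor", call. = FALSE)
  dn <- d %/% factor
  S <- sfft(v$data)
  ctr <- vol_centre(d)
  take <- function(n_old, n_new, c_old)
    (c_old - n_new %/% 2L):(c_old + (n_new - n_new %/% 2L) - 1L)
  Ss <- S[take(d[1], dn[1], ctr[1]),
          take(d[2], dn[2], ctr[2]),
          take(d[3], dn[3], ctr[3]), drop = FALSE]
  density_volume(isfft(Ss) / factor^3, voxel_size = v$voxel_size * factor,
                 origin = v$origin)
}
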