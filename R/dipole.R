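#' k-space dipole kernel
#'
#' Builds the unit dipole response on the discrete FFT frequency grid:
#' `D(k) = 1/3 - (k . b0)^2 / |k|^2`, with the `k = 0` (DC) term set to 0
#' by convention (the mean susceptibility does not perturb the field).
#' Values are dimensionless and bounded in `[-2/3, 1/3]`.
#'
#' @param grid_shape Integer length-3, volume dimensions in voxels.
#' @param voxel_size Numeric length-3, voxel size in mm.
#' @param b0_direction Unit vector of the main field direction. The default
#'   `c(0, 0, 1)` puts B0 along the third array axis.
#'
#' @return An object of class `dipole_kernel` with elements `values`
#'   (3-D array), `b0_direction`, `grid_shape`, `voxel_size`.
#' @export
#' @examples
#' k <- dipole_kernel(c(16, 16, 16), c(1, 1, 1))
#' k$values[1, 1, 1] # DC term, exactly 0
dipole_kernel <- function(grid_shape, voxel_size = c(1, 1, 1),
                          b0_direction = c(0, 0, 1)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("`grid_shape` must be 3 positive integers", call. = FALSE)
  }
  b0 <- as.numeric(b0_direction)
  nb <- sqrt(sum(b0^2))
  if (length(b0) != 3L || nb == 0) {
    stop("`b0_direction` must be a nonzero length-3 vector", call. = FALSE)
  }
  b0 <- b0 / nb
  voxel_size <- as.numeric(voxel_size)

  freqs <- lapply(1:3, function(i) fft_freq(grid_shape[i], voxel_size[i]))
  kx <- array(freqs[[1]], grid_shape)
  ky <- array(rep(freqs[[2]], each = grid_shape[1]), grid_shape)
  kz <- array(rep(freqs[[3]], each = grid_shape[1] * grid_shape[2]),
              grid_shape)

  k2 <- kx^2 + ky^2 + kz^2
  kb <- kx * b0[1] + ky * b0[2] + kz * b0[3]
  d <- 1 / 3 - kb^2 / k2
  d[k2 == 0] <- 0

  structure(
    list(values = d, b0_direction = b0, grid_shape = grid_shape,
         voxel_size = voxel_size),
    class = "dipole_kernel"
  )
}

# DFT sample frequencies for n points at spacing d (cycles per mm),
# in standard FFT order: 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1.
fft_freq <- function(n, d = 1) {
  pos <- 0:(floor((n - 1) / 2))
  neg <- if (n > 1) seq.int(-floor(n / 2), -1) else integer(0)
  c(pos, neg) / (n * d)
}

# 3-D FFT / inverse FFT wrappers; stats::fft is already N-dimensional.
fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

check_kernel_shape <- function(vol, kernel) {
  if (!inherits(kernel, "dipole_kernel")) {
    stop("`kernel` must be a dipole_kernel", call. = FALSE)
  }
  if (!identical(dim(vol), as.integer(kernel$grid_shape))) {
    stop("volume shape does not match kernel grid", call. = FALSE)
  }
}

#' Forward dipole field of a susceptibility distribution
#'
#' Computes the field perturbation (in ppm of B0) induced by a
#' susceptibility distribution via k-space multiplication with the dipole
#' kernel. Convolution is circular (periodic boundary); callers who need to
#' suppress wrap-around can zero-pad with `pad = TRUE`.
#'
#' @param chi A `qmap` or 3-D array of susceptibility in ppm.
#' @param kernel A [dipole_kernel()] on the same grid.
#' @param pad If `TRUE`, zero-pad to twice the grid before convolving and
#'   crop the result, suppressing periodic wrap-around at extra cost.
#'
#' @return 3-D numeric array: field perturbation in ppm. Its spatial mean is
#'   zero because the kernel's DC term is zero.
#' @export
forward_field <- function(chi, kernel, pad = FALSE) {
  vol <- as_volume(chi)
  if (pad) {
    d <- dim(vol)
    big <- array(0, 2L * d)
    big[1:d[1], 1:d[2], 1:d[3]] <- vol
    kbig <- dipole_kernel(2L * d, kernel$voxel_size, kernel$b0_direction)
    out <- Re(ifft3(fft3(big) * kbig$values))
    return(out[1:d[1], 1:d[2], 1:d[3]])
  }
  check_kernel_shape(vol, kernel)
  Re(ifft3(fft3(vol) * kernel$values))
}

#' Thresholded k-space division (TKD) dipole inversion
#'
#' Recovers susceptibility from a field map by dividing by the dipole
#' kernel, with kernel values of magnitude below `delta` replaced by
#' `sign(D) * delta` to stabilise the ill-posed division near the magic-angle
#' cone. The DC term (unrecoverable mean) is set to zero.
#'
#' @param field 3-D array, field perturbation in ppm.
#' @param kernel A [dipole_kernel()] on the same grid.
#' @param delta Truncation threshold, `0 < delta < 2/3`.
#'
#' @return A `qmap` with the estimated susceptibility in ppm.
#' @export
tkd_invert <- function(field, kernel, delta = 0.2) {
  vol <- as_volume(field)
  check_kernel_shape(vol, kernel)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 ||
      delta >= 2 / 3) {
    stop("`delta` must lie strictly between 0 and 2/3", call. = FALSE)
  }
  d <- kernel$values
  dthr <- d
  small <- abs(d) < delta
  dthr[small] <- sign(d[small]) * delta
  chik <- fft3(vol) / dthr
  chik[dthr == 0] <- 0 # DC (and any exactly-zero kernel value): mean lost
  vs <- if (inherits(field, "qmap")) field$voxel_size else kernel$voxel_size
  qmap(Re(ifft3(chik)), voxel_size = vs)
}

#' Tikhonov-regularised closed-form dipole inversion
#'
#' k-space analogue of quadratic (Tikhonov) regularisation:
#' `chi_hat = ifft( D / (D^2 + lambda) * fft(field) )`. Larger `lambda`
#' shrinks the solution norm monotonically towards zero.
#'
#' @param field 3-D array, field perturbation in ppm.
#' @param kernel A [dipole_kernel()] on the same grid.
#' @param lambda Regularisation weight, `lambda > 0`.
#'
#' @return A `qmap` with the estimated susceptibility in ppm.
#' @export
tikhonov_invert <- function(field, kernel, lambda = 0.05) {
  vol <- as_volume(field)
  check_kernel_shape(vol, kernel)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("`lambda` must be a single positive number", call. = FALSE)
  }
  d <- kernel$values
  chik <- fft3(vol) * d / (d^2 + lambda)
  vs <- if (inherits(field, "qmap")) field$voxel_size else kernel$voxel_size
  qmap(Re(ifft3(chik)), voxel_size = vs)
}
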