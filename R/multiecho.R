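# Proton gyromagnetic ratio, Hz per tesla.
GAMMA_HZ_PER_T <- 42.577478518e6

#' Specification of a multi-echo gradient-echo acquisition
#'
#' Holds the acquisition parameters used to turn a susceptibility map into
#' complex multi-echo GRE signal: echo times, repetition time, field
#' strength, main-field direction and signal-to-noise ratio. The defaults
#' are a 3 T four-echo protocol (TEs 4.61, 9.22, 13.83, 18.44 ms).
#'
#' @param echo_times Strictly increasing echo times in ms.
#' @param repetition_time Repetition time in ms.
#' @param field_strength Main field strength in tesla.
#' @param b0_direction Unit vector of the main field direction.
#' @param snr Magnitude signal-to-noise ratio (dimensionless).
#'
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(echo_times = c(4.61, 9.22, 13.83, 18.44),
                             repetition_time = 27, field_strength = 3,
                             b0_direction = c(0, 0, 1), snr = 100) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 1L || any(diff(echo_times) <= 0)) {
    stop("`echo_times` must be strictly increasing", call. = FALSE)
  }
  b0 <- as.numeric(b0_direction)
  nb <- sqrt(sum(b0^2))
  if (length(b0) != 3L || nb == 0) {
    stop("`b0_direction` must be a nonzero length-3 vector", call. = FALSE)
  }
  if (field_strength <= 0 || snr <= 0) {
    stop("`field_strength` and `snr` must be positive", call. = FALSE)
  }
  structure(
    list(echo_times = echo_times,
         repetition_time = as.numeric(repetition_time),
         field_strength = as.numeric(field_strength), b0_direction = b0 / nb,
         snr = as.numeric(snr)),
    class = "acquisition_spec"
  )
}

#' Simulate complex multi-echo GRE signal from a susceptibility map
#'
#' Computes the dipole field induced by `chi`, converts it to an
#' off-resonance frequency `f = gamma' * B0 * dB * 1e-6` (Hz), and builds
#' complex signal `m * exp(i * 2 * pi * f * TE)` per echo with additive
#' complex Gaussian noise of SD `1/snr` per channel. Magnitude is constant
#' per tissue label (1 everywhere by default). Susceptibility amplitudes
#' must keep inter-echo phase increments below half a cycle, otherwise the
#' temporal unwrapping in [fit_fieldmap()] becomes ambiguous; a violation
#' triggers a warning naming the maximum offending frequency.
#'
#' @param chi A [qmap()] of susceptibility in ppm.
#' @param acq An [acquisition_spec()].
#' @param seed Integer seed for the noise; `NULL` adds no noise.
#' @param labels Optional integer label volume for per-tissue magnitudes.
#' @param magnitudes Named numeric vector mapping label (as character) to
#'   magnitude; unlisted labels (and background) get 1.
#'
#' @return Complex 4-D array, dimensions `c(grid, n_echoes)`, with the echo
#'   times attached as attribute `echo_times` (ms) and the noiseless field
#'   map as attribute `field_hz`.
#' @export
simulate_multiecho <- function(chi, acq, seed = NULL, labels = NULL,
                               magnitudes = NULL) {
  stopifnot(inherits(chi, "qmap"), inherits(acq, "acquisition_spec"))
  kernel <- dipole_kernel(dim(chi$values), chi$voxel_size, acq$b0_direction)
  db_ppm <- forward_field(chi, kernel)
  f_hz <- GAMMA_HZ_PER_T * acq$field_strength * db_ppm * 1e-6

  te_s <- acq$echo_times / 1000
  max_dte <- max(diff(te_s), te_s[1])
  fmax <- max(abs(f_hz))
  if (fmax * max_dte > 0.5) {
    warning(sprintf(
      paste0("inter-echo phase increment exceeds half a cycle ",
             "(max |f| = %.1f Hz, max echo spacing %.2f ms): ",
             "temporal unwrapping may fail"),
      fmax, max_dte * 1000), call. = FALSE)
  }

  mag <- array(1, dim(chi$values))
  if (!is.null(labels) && !is.null(magnitudes)) {
    for (lab in names(magnitudes)) {
      mag[labels == as.integer(lab)] <- magnitudes[[lab]]
    }
  }

  ne <- length(te_s)
  out <- array(0i, c(dim(chi$values), ne))
  noise_sd <- 1 / acq$snr
  with_seed(seed, {
    for (e in seq_len(ne)) {
      sig <- mag * exp(2i * pi * f_hz * te_s[e])
      if (!is.null(seed)) {
        n <- length(sig)
        sig <- sig + complex(real = stats::rnorm(n, 0, noise_sd),
                             imaginary = stats::rnorm(n, 0, noise_sd))
      }
      out[, , , e] <- sig
    }
  })
  attr(out, "echo_times") <- acq$echo_times
  attr(out, "field_hz") <- f_hz
  out
}

#' Fit a field map from multi-echo complex data
#'
#' Estimates the per-voxel off-resonance frequency (Hz) as the slope of
#' phase versus echo time, by magnitude-squared-weighted linear least
#' squares with an intercept. Echo phases are first unwrapped temporally:
#' each echo's raw phase is shifted by the integer number of cycles that
#' brings it closest to the value extrapolated from the preceding echoes.
#'
#' @param stack Complex 4-D array from [simulate_multiecho()] (or any
#'   `c(grid, n_echoes)` stack with an `echo_times` attribute in ms, or
#'   supply `echo_times`).
#' @param acq Optional [acquisition_spec()] supplying the echo times.
#' @param echo_times Echo times in ms, overriding `stack`'s attribute.
#'
#' @return List with `field_hz` (3-D array of fitted frequencies) and
#'   `residual` (3-D array, RMS phase-fit residual in radians, a noise
#'   proxy).
#' @export
fit_fieldmap <- function(stack, acq = NULL, echo_times = NULL) {
  if (is.null(echo_times)) {
    echo_times <- if (!is.null(acq)) acq$echo_times else
      attr(stack, "echo_times")
  }
  if (is.null(echo_times)) {
    stop("echo times not supplied and not attached to `stack`",
         call. = FALSE)
  }
  d <- dim(stack)
  ne <- d[4]
  if (is.na(ne) || ne < 2L) {
    stop("at least 2 echoes are required to fit a field map", call. = FALSE)
  }
  if (length(echo_times) != ne) {
    stop("number of echo times does not match number of echoes",
         call. = FALSE)
  }
  te <- echo_times / 1000
  nv <- prod(d[1:3])
  sig <- matrix(stack, nv, ne)
  phase <- Arg(sig)
  w <- Mod(sig)^2

  # temporal unwrapping: predict echo e from the running slope estimate
  unwrapped <- phase
  for (e in 2:ne) {
    pred <- if (e == 2L) {
      unwrapped[, 1] * (te[2] / te[1])
    } else {
      slope <- (unwrapped[, e - 1] - unwrapped[, e - 2]) /
        (te[e - 1] - te[e - 2])
      unwrapped[, e - 1] + slope * (te[e] - te[e - 1])
    }
    unwrapped[, e] <- phase[, e] +
      2 * pi * round((pred - phase[, e]) / (2 * pi))
  }

  # weighted least squares, slope + intercept, vectorised over voxels
  sw <- rowSums(w)
  swt <- w %*% te
  swt2 <- w %*% te^2
  swy <- rowSums(w * unwrapped)
  swty <- rowSums(w * sweep(unwrapped, 2, te, `*`))
  denom <- sw * swt2 - swt^2
  slope <- (sw * swty - swt * swy) / denom
  intercept <- (swt2 * swy - swt * swty) / denom
  fitted <- outer(c(slope), te) + c(intercept)
  resid <- sqrt(rowMeans((unwrapped - fitted)^2))

  list(field_hz = array(slope / (2 * pi), d[1:3]),
       residual = array(resid, d[1:3]))
}
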