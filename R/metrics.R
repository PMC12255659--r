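#' Normalised root-mean-square error between two maps
#'
#' The l2 norm of the voxel-wise difference between the test and reference
#' maps over the mask, divided by the l2 norm of the reference. Lower is
#' better; 0 means identical. NRMSE is asymmetric in its arguments (the
#' first map is the normalising reference); by convention the
#' chronologically earlier scan is used as the reference.
#'
#' @param reference A [qmap()] or 3-D array; the normalising map.
#' @param test A [qmap()] or 3-D array on the same grid.
#' @param mask Logical array, or `NULL` to use the intersection of the two
#'   qmap masks (all voxels for bare arrays).
#'
#' @return Single non-negative number (dimensionless).
#' @export
#' @examples
#' a <- array(c(3, 4), c(2, 1, 1)); b <- array(0, c(2, 1, 1))
#' nrmse(a, b) # |(0,0)-(3,4)| / |(3,4)| = 1
nrmse <- function(reference, test, mask = NULL) {
  r <- as_volume(reference)
  t <- as_volume(test)
  if (!identical(dim(r), dim(t))) {
    stop("`reference` and `test` must share one grid", call. = FALSE)
  }
  mask <- resolve_mask(mask, reference, test)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  rv <- r[mask]
  tv <- t[mask]
  ref_norm <- sqrt(sum(rv^2))
  if (ref_norm == 0) {
    stop("reference is identically zero in the mask: NRMSE undefined",
         call. = FALSE)
  }
  sqrt(sum((tv - rv)^2)) / ref_norm
}

resolve_mask <- function(mask, a, b = NULL) {
  if (!is.null(mask)) {
    m <- array(as.logical(as_volume(mask)), dim(as_volume(a)))
    return(m)
  }
  m <- if (inherits(a, "qmap")) a$mask else array(TRUE, dim(as_volume(a)))
  if (inherits(b, "qmap")) m <- m & b$mask
  m
}

# Truncated Gaussian window weights for offsets -radius..radius (1-D).
gauss_weights_1d <- function(sigma, radius) {
  off <- -radius:radius
  w <- exp(-off^2 / (2 * sigma^2))
  w / sum(w)
}

# Circular 3-D convolution of `x` with the separable Gaussian kernel via
# FFT. `x` is assumed already zero-padded by `radius` so wrap-around only
# touches zeros.
gauss_conv3 <- function(x, sigma, radius) {
  d <- dim(x)
  w1 <- gauss_weights_1d(sigma, radius)
  kern <- array(0, d)
  idx <- function(n) ((-radius:radius) %% n) + 1L
  kern[idx(d[1]), idx(d[2]), idx(d[3])] <-
    outer(outer(w1, w1), w1)
  Re(ifft3(fft3(x) * fft3(kern)))
}

pad3 <- function(x, r) {
  d <- dim(x)
  out <- array(0, d + 2L * r)
  out[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- x
  out
}

#' Structural similarity for signed susceptibility maps (XSIM)
#'
#' A windowed structural-similarity index adapted to QSM: local means,
#' variances and covariance are computed under a Gaussian window and
#' combined with stabilisers `C1 = (k1 * L)^2`, `C2 = (k2 * L)^2`, using a
#' dynamic range `L` of 1 ppm and a small `k2` suited to signed data
#' centred near zero. At masked-region borders, windows are clipped to the
#' mask (weights renormalised over in-mask voxels), so voxels outside the
#' mask never contribute. Symmetric in its two arguments; 1 means
#' identical, values can be negative where the maps anti-correlate.
#'
#' @param reference,test [qmap()]s or 3-D arrays on the same grid.
#' @param mask Logical array, or `NULL` for the intersection of qmap masks.
#' @param dynamic_range Dynamic range `L` in ppm.
#' @param k1,k2 Stabiliser constants.
#' @param window_sigma Gaussian window SD in voxels.
#' @param window_radius Window truncation radius in voxels; the default
#'   covers +/- 3 SDs.
#'
#' @return Single number in `[-1, 1]`: the mean of the local similarity map
#'   over the mask.
#' @export
xsim <- function(reference, test, mask = NULL, dynamic_range = 1,
                 k1 = 0.01, k2 = 0.001, window_sigma = 1.5,
                 window_radius = ceiling(3 * window_sigma)) {
  r <- as_volume(reference)
  t <- as_volume(test)
  if (!identical(dim(r), dim(t))) {
    stop("`reference` and `test` must share one grid", call. = FALSE)
  }
  if (dynamic_range <= 0) stop("`dynamic_range` must be > 0", call. = FALSE)
  mask <- resolve_mask(mask, reference, test)
  if (!any(mask)) stop("mask is empty", call. = FALSE)

  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  m <- pad3(mask * 1, window_radius)
  x <- pad3(r * mask, window_radius)
  y <- pad3(t * mask, window_radius)

  wm <- gauss_conv3(m, window_sigma, window_radius)
  mu_x <- gauss_conv3(x, window_sigma, window_radius) / wm
  mu_y <- gauss_conv3(y, window_sigma, window_radius) / wm
  e_xx <- gauss_conv3(x * x, window_sigma, window_radius) / wm
  e_yy <- gauss_conv3(y * y, window_sigma, window_radius) / wm
  e_xy <- gauss_conv3(x * y, window_sigma, window_radius) / wm
  var_x <- pmax(e_xx - mu_x^2, 0)
  var_y <- pmax(e_yy - mu_y^2, 0)
  cov_xy <- e_xy - mu_x * mu_y

  ssim_map <- ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
  mean(ssim_map[pad3(mask, window_radius) > 0])
}

#' Pairwise voxel-wise similarity metrics across a cohort
#'
#' For every subject and every unordered pair of repetitions, computes
#' NRMSE (earlier repetition as reference) and XSIM within each ROI of the
#' cohort's label map. With `N_r` repetitions there are `choose(N_r, 2)`
#' pairs per subject.
#'
#' @param cohort A `qsm_cohort` from [sample_cohort()] or [read_cohort()].
#' @param rois Integer labels to evaluate; `NULL` for all ROIs in the label
#'   map.
#' @param metrics Character subset of `c("nrmse", "xsim")`.
#' @param whole_mask If `TRUE`, also evaluate over the union of all ROIs
#'   (reported as roi `"all"`).
#' @param pairs Optional 2-column matrix of repetition index pairs to
#'   restrict the comparison; `NULL` uses all unordered pairs.
#' @param ... Passed to [xsim()] (window and stabiliser settings).
#'
#' @return A tibble with columns `subject`, `rep_i`, `rep_j`, `roi`,
#'   `metric`, `value`.
#' @seealso [summarize_voxel_metrics()] for the across-subject mean +/- SD
#'   summary.
#' @export
pairwise_voxel_metrics <- function(cohort, rois = NULL,
                                   metrics = c("nrmse", "xsim"),
                                   whole_mask = FALSE, pairs = NULL, ...) {
  stopifnot(inherits(cohort, "qsm_cohort"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (cohort$n_repetitions < 2L) {
    stop("at least 2 repetitions are required for pairwise metrics",
         call. = FALSE)
  }
  if (is.null(rois)) {
    rois <- sort(unique(cohort$labels[cohort$labels > 0]))
  }
  roi_masks <- lapply(rois, function(l) cohort$labels == l)
  roi_tags <- as.character(cohort$roi_names[as.character(rois)])
  roi_tags[is.na(roi_tags)] <- as.character(rois)[is.na(roi_tags)]
  if (whole_mask) {
    roi_masks <- c(roi_masks, list(cohort$labels > 0))
    roi_tags <- c(roi_tags, "all")
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(cohort$n_repetitions, 2))
  }

  rows <- list()
  for (s in seq_len(cohort$n_subjects)) {
    for (p in seq_len(nrow(pairs))) {
      i <- min(pairs[p, ]) # earlier scan is the NRMSE reference
      j <- max(pairs[p, ])
      ref <- cohort$maps[[s]][[i]]
      tst <- cohort$maps[[s]][[j]]
      for (k in seq_along(roi_masks)) {
        vals <- c(
          if ("nrmse" %in% metrics)
            c(nrmse = nrmse(ref, tst, roi_masks[[k]])),
          if ("xsim" %in% metrics)
            c(xsim = xsim(ref, tst, roi_masks[[k]], ...))
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = s, rep_i = i, rep_j = j, roi = roi_tags[k],
          metric = names(vals), value = unname(vals)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarise voxel-wise metrics across subjects
#'
#' Averages each metric over repetition pairs within subject, then reports
#' the across-subject mean and SD per ROI and metric (the error bars of
#' inter-subject variability).
#'
#' @param metric_table Output of [pairwise_voxel_metrics()].
#'
#' @return A tibble with columns `roi`, `metric`, `mean`, `sd_between_subjects`,
#'   `n_subjects`.
#' @export
summarize_voxel_metrics <- function(metric_table) {
  metric_table |>
    dplyr::group_by(.data$subject, .data$roi, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$roi, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd_between_subjects = stats::sd(.data$value),
      n_subjects = dplyr::n(),
      .groups = "drop"
    )
}
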