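#' Specification of a repeated-measures cohort design
#'
#' Defines the hierarchical variance structure of a simulated test-retest
#' study: `n_subjects` subjects each scanned `scans_per_session` times in
#' each of `n_sessions` sessions (so `N_r = n_sessions * scans_per_session`
#' repetitions per subject). Per ROI, each subject receives one additive
#' offset drawn from `N(0, sigma_b^2)` and each repetition an offset from
#' `N(0, sigma_w^2)`; every voxel additionally receives iid measurement
#' noise of SD `voxel_noise_sd` redrawn per repetition. The defaults mirror
#' a 10-subject, two-session, three-scans-per-session design with
#' sigma_b = 10 ppb and sigma_w = 5 ppb, i.e. a true one-way ICC of 0.8.
#'
#' @param n_subjects Number of subjects (N_s).
#' @param n_sessions Number of sessions.
#' @param scans_per_session Scans per session.
#' @param sigma_b Between-subject SD in ppm; scalar or one value per ROI.
#' @param sigma_w Within-subject (between-repetition) SD in ppm; scalar or
#'   one value per ROI.
#' @param voxel_noise_sd Voxel-level measurement noise SD in ppm.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10L, n_sessions = 2L,
                        scans_per_session = 3L, sigma_b = 0.010,
                        sigma_w = 0.005, voxel_noise_sd = 0.005,
                        seed = 1L) {
  counts <- c(n_subjects = n_subjects, n_sessions = n_sessions,
              scans_per_session = scans_per_session)
  if (any(counts < 1)) {
    stop("all design counts must be >= 1", call. = FALSE)
  }
  if (any(c(sigma_b, sigma_w, voxel_noise_sd) < 0)) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         scans_per_session = as.integer(scans_per_session),
         n_repetitions = as.integer(n_sessions) *
           as.integer(scans_per_session),
         sigma_b = as.numeric(sigma_b), sigma_w = as.numeric(sigma_w),
         voxel_noise_sd = as.numeric(voxel_noise_sd),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Recycle a per-ROI parameter (scalar or length-n vector) to n ROIs.
roi_param <- function(x, n, what) {
  if (length(x) == 1L) return(rep(x, n))
  if (length(x) != n) {
    stop(sprintf("`%s` must have length 1 or one value per ROI (%d)",
                 what, n), call. = FALSE)
  }
  x
}

#' Simulate a repeated-measures cohort of susceptibility maps
#'
#' Generates `n_subjects * N_r` maps sharing one grid and one ROI label
#' map. Each subject gets its own anatomy: ROI texture is drawn once per
#' subject and reused across that subject's repetitions, so within-region
#' SD stays above within-subject SD. Subject offsets (`sigma_b`),
#' repetition offsets (`sigma_w`) and voxel noise (`voxel_noise_sd`) are
#' applied per ROI as additive shifts.
#'
#' @param phantom A `phantom_spec` (or the result of [build_phantom()],
#'   from which the spec is not recoverable — pass the spec).
#' @param cohort A [cohort_spec()].
#'
#' @return An object of class `qsm_cohort`: list with `maps` (list of
#'   subjects, each a list of `N_r` [qmap()]s), `labels` (integer array),
#'   `roi_names`, `session_of` (session index of each repetition),
#'   `n_subjects`, `n_repetitions`, and `truth` (the generating specs).
#' @export
#' @examples
#' co <- sample_cohort(default_phantom_spec(c(16, 16, 16)),
#'                     cohort_spec(n_subjects = 2, seed = 7))
#' length(co$maps) * length(co$maps[[1]]) # 2 x 6 maps
sample_cohort <- function(phantom, cohort) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(cohort, "cohort_spec"))
  labels <- phantom_labels(phantom)
  n_roi <- length(phantom$rois)
  sb <- roi_param(cohort$sigma_b, n_roi, "sigma_b")
  sw <- roi_param(cohort$sigma_w, n_roi, "sigma_w")
  ns <- cohort$n_subjects
  nr <- cohort$n_repetitions

  base <- array(phantom$background_chi, phantom$grid_shape)
  roi_idx <- lapply(phantom$rois, function(r) which(labels == r$label))

  maps <- vector("list", ns)
  with_seed(cohort$seed, {
    for (s in seq_len(ns)) {
      # subject anatomy: fixed texture, one offset per ROI
      subj <- base
      b_s <- stats::rnorm(n_roi, 0, sb)
      for (i in seq_len(n_roi)) {
        r <- phantom$rois[[i]]
        tex <- if (r$texture_sd > 0) {
          stats::rnorm(length(roi_idx[[i]]), 0, r$texture_sd)
        } else 0
        subj[roi_idx[[i]]] <- r$mean_chi + b_s[i] + tex
      }
      reps <- vector("list", nr)
      for (rep_i in seq_len(nr)) {
        vol <- subj
        w_sr <- stats::rnorm(n_roi, 0, sw)
        for (i in seq_len(n_roi)) {
          vol[roi_idx[[i]]] <- vol[roi_idx[[i]]] + w_sr[i]
        }
        if (cohort$voxel_noise_sd > 0) {
          vol <- vol + stats::rnorm(length(vol), 0, cohort$voxel_noise_sd)
        }
        reps[[rep_i]] <- qmap(vol, voxel_size = phantom$voxel_size)
      }
      maps[[s]] <- reps
    }
  })

  structure(
    list(maps = maps, labels = labels,
         roi_names = stats::setNames(
           vapply(phantom$rois, `[[`, character(1), "name"),
           vapply(phantom$rois, function(r) as.character(r$label),
                  character(1))),
         session_of = rep(seq_len(cohort$n_sessions),
                          each = cohort$scans_per_session),
         n_subjects = ns, n_repetitions = nr,
         truth = list(phantom = phantom, cohort = cohort)),
    class = "qsm_cohort"
  )
}

#' @export
print.qsm_cohort <- function(x, ...) {
  cat(sprintf(
    "<qsm_cohort> %d subjects x %d repetitions (%d maps), %d ROIs, grid %s\n",
    x$n_subjects, x$n_repetitions, x$n_subjects * x$n_repetitions,
    length(x$roi_names), paste(dim(x$labels), collapse = "x")
  ))
  invisible(x)
}

#' Simulate per-ROI mean susceptibilities directly at the table level
#'
#' Draws the long-format table of ROI mean susceptibilities
#' `chi_{s,r} = mean_chi + b_s + w_{s,r}` without rendering any volumes:
#' the exact hierarchical model the volumetric simulator induces on ROI
#' means, at a fraction of the cost. Useful for statistical calibration
#' studies that need hundreds of cohorts.
#'
#' @param cohort A [cohort_spec()]; `sigma_b`/`sigma_w` scalar or per ROI.
#' @param roi_means Named numeric vector of true ROI mean susceptibilities
#'   in ppm; names become the `roi` column.
#' @param method Method label for the `method` column.
#' @param seed Optional seed overriding `cohort$seed`.
#'
#' @return A tibble with columns `subject`, `session`, `repetition`,
#'   `method`, `roi`, `chi_ppm` — the same layout [roi_means()] produces
#'   from a volumetric cohort.
#' @export
simulate_roi_table <- function(cohort, roi_means, method = "simulated",
                               seed = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n_roi <- length(roi_means)
  if (is.null(names(roi_means))) {
    names(roi_means) <- paste0("roi", seq_len(n_roi))
  }
  sb <- roi_param(cohort$sigma_b, n_roi, "sigma_b")
  sw <- roi_param(cohort$sigma_w, n_roi, "sigma_w")
  ns <- cohort$n_subjects
  nr <- cohort$n_repetitions
  if (is.null(seed)) seed <- cohort$seed

  chi <- with_seed(seed, {
    # b: n_roi x ns, w: n_roi x (ns*nr); column-major order fixes the stream
    b <- matrix(stats::rnorm(n_roi * ns, 0, sb), n_roi, ns)
    w <- matrix(stats::rnorm(n_roi * ns * nr, 0, sw), n_roi, ns * nr)
    array(roi_means + c(b[, rep(seq_len(ns), each = nr)]) + c(w),
          c(n_roi, nr, ns))
  })

  tibble::tibble(
    subject = rep(seq_len(ns), each = n_roi * nr),
    repetition = rep(rep(seq_len(nr), each = n_roi), ns),
    session = rep(rep(seq_len(cohort$n_sessions),
                      each = n_roi * cohort$scans_per_session), ns),
    method = method,
    roi = rep(names(roi_means), ns * nr),
    chi_ppm = c(chi)
  )
}
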