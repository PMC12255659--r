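#' Within-region standard deviation of a susceptibility map
#'
#' Population standard deviation (divisor `N_v`, the voxel count) of the
#' susceptibility values inside an ROI mask: the voxel-scale heterogeneity
#' of the region, typically the largest of the three variance scales in
#' repeated QSM.
#'
#' @param qmap A [qmap()] or 3-D array.
#' @param roi_mask Logical array selecting the ROI voxels.
#'
#' @return Single non-negative number in the map's units (ppm).
#' @export
#' @examples
#' v <- array(c(0, 0, 3, 3), c(4, 1, 1))
#' sigma_r(v, array(TRUE, c(4, 1, 1))) # 1.5
sigma_r <- function(qmap, roi_mask) {
  v <- as_volume(qmap)
  roi_mask <- array(as.logical(as_volume(roi_mask)), dim(v))
  x <- v[roi_mask]
  if (length(x) == 0L) stop("ROI mask is empty", call. = FALSE)
  sqrt(mean((x - mean(x))^2))
}

# Population SD, divisor N.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-ROI mean susceptibilities of a repeated cohort
#'
#' Computes the mean susceptibility over each ROI for every subject and
#' repetition: the long-format table on which all ROI-level repeatability
#' statistics operate. The design is balanced by construction.
#'
#' @param cohort A `qsm_cohort`.
#' @param rois Integer labels to include; `NULL` for all.
#' @param method Method label recorded in the `method` column.
#'
#' @return A tibble with columns `subject`, `session`, `repetition`,
#'   `method`, `roi`, `chi_ppm`.
#' @export
roi_means <- function(cohort, rois = NULL, method = "simulated") {
  stopifnot(inherits(cohort, "qsm_cohort"))
  if (is.null(rois)) {
    rois <- sort(unique(cohort$labels[cohort$labels > 0]))
  }
  roi_idx <- lapply(rois, function(l) which(cohort$labels == l))
  roi_tags <- as.character(cohort$roi_names[as.character(rois)])
  roi_tags[is.na(roi_tags)] <- as.character(rois)[is.na(roi_tags)]

  rows <- vector("list", cohort$n_subjects * cohort$n_repetitions)
  n <- 0L
  for (s in seq_len(cohort$n_subjects)) {
    reps <- cohort$maps[[s]]
    if (length(reps) != cohort$n_repetitions ||
        any(vapply(reps, is.null, logical(1)))) {
      stop(sprintf("cohort incomplete: subject %d is missing repetitions", s),
           call. = FALSE)
    }
    for (r in seq_len(cohort$n_repetitions)) {
      vals <- vapply(roi_idx, function(ix) mean(reps[[r]]$values[ix]),
                     numeric(1))
      n <- n + 1L
      rows[[n]] <- tibble::tibble(
        subject = s, session = cohort$session_of[r], repetition = r,
        method = method, roi = roi_tags, chi_ppm = vals
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Reshape a long ROI-means table into a subjects-by-repetitions matrix
#'
#' Expects a table restricted to a single ROI and method. Errors, naming the
#' offending cell, if the design is unbalanced.
#'
#' @param table Long tibble with `subject`, `repetition`, `chi_ppm` columns.
#'
#' @return Numeric matrix, rows = subjects (named), columns = repetitions.
#' @export
roi_matrix <- function(table) {
  if (length(unique(table$roi %||% "x")) > 1L ||
      length(unique(table$method %||% "x")) > 1L) {
    stop("`table` must be restricted to a single ROI and method",
         call. = FALSE)
  }
  subjects <- sort(unique(table$subject))
  reps <- sort(unique(table$repetition))
  mat <- matrix(NA_real_, length(subjects), length(reps),
                dimnames = list(subjects, reps))
  mat[cbind(match(table$subject, subjects),
            match(table$repetition, reps))] <- table$chi_ppm
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("unbalanced design: subject %s is missing repetition %s",
                 subjects[miss[1]], reps[miss[2]]), call. = FALSE)
  }
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Within-subject standard deviation of ROI means
#'
#' Per subject: the population SD (divisor `N_r`) of that subject's `N_r`
#' repetition means. Pooled across subjects by root-mean-square (each
#' subject weighted equally), the summary used for repeatability plots and
#' the repeatability coefficient.
#'
#' @param x Subjects-by-repetitions matrix from [roi_matrix()] (or a long
#'   table coercible by it).
#'
#' @return `sigma_w_subjects()`: named vector of per-subject SDs (ppm).
#'   `pooled_sigma_w()`: single pooled SD (ppm).
#' @export
sigma_w_subjects <- function(x) {
  x <- as_roi_matrix(x)
  if (ncol(x) < 2L) {
    stop("at least 2 repetitions are required for sigma_w", call. = FALSE)
  }
  apply(x, 1, pop_sd)
}

#' @rdname sigma_w_subjects
#' @export
pooled_sigma_w <- function(x) {
  sqrt(mean(sigma_w_subjects(x)^2))
}

as_roi_matrix <- function(x) {
  if (is.matrix(x)) x else roi_matrix(x)
}

#' Between-subject standard deviation of ROI means
#'
#' Population SD (divisor `N_s`) of the subject-level means (each subject's
#' mean over its repetitions).
#'
#' @param x Subjects-by-repetitions matrix or long table.
#'
#' @return Single non-negative number (ppm).
#' @export
sigma_b <- function(x) {
  x <- as_roi_matrix(x)
  if (nrow(x) < 2L) {
    stop("at least 2 subjects are required for sigma_b", call. = FALSE)
  }
  pop_sd(rowMeans(x))
}

#' Within-subject coefficient of variation
#'
#' Per subject: `sigma_w / mean`, the within-subject SD divided by the
#' subject's mean over repetitions. Because susceptibility means are signed
#' and often near zero, CV can explode; a value is flagged unstable when
#' the mean is within two standard errors of zero
#' (`|mean| < 2 * sigma_w / sqrt(N_r)`), and reported as `NA` (flagged)
#' when the mean is exactly zero.
#'
#' @param x Subjects-by-repetitions matrix or long table.
#'
#' @return Tibble with columns `subject`, `mean_ppm`, `sigma_w`, `cv`,
#'   `unstable`.
#' @export
cv_within <- function(x) {
  x <- as_roi_matrix(x)
  sw <- sigma_w_subjects(x)
  m <- rowMeans(x)
  nr <- ncol(x)
  cv <- ifelse(m == 0, NA_real_, sw / m)
  tibble::tibble(
    subject = rownames(x) %||% as.character(seq_len(nrow(x))),
    mean_ppm = unname(m), sigma_w = unname(sw), cv = unname(cv),
    unstable = unname(m == 0 | abs(m) < 2 * sw / sqrt(nr))
  )
}

#' One-way random-effects intraclass correlation
#'
#' Estimates the ICC as the ratio of between-subject variance to total
#' variance, with variance components taken from a one-way random-effects
#' ANOVA: `MSB` over subjects, `MSW` within subjects,
#' `sigma_b^2 = (MSB - MSW) / N_r`, and
#' `ICC(1,1) = (MSB - MSW) / (MSB + (N_r - 1) * MSW)`. The raw estimate can
#' be negative in finite samples; it is reported alongside a `[0, 1]`
#' clamped value (the population quantity is a variance ratio, hence
#' non-negative).
#'
#' @param x Balanced subjects-by-repetitions matrix or long table.
#'
#' @return List of class `icc_result`: `icc` (clamped), `icc_raw`, `msb`,
#'   `msw`, `sigma2_b`, `sigma2_w`, `f`, `df`, `n_subjects`,
#'   `n_repetitions`.
#' @export
#' @examples
#' m <- rbind(c(1, 3), c(5, 7), c(9, 11))
#' icc_oneway(m)$icc_raw # 30/34
icc_oneway <- function(x) {
  x <- as_roi_matrix(x)
  ns <- nrow(x)
  nr <- ncol(x)
  if (ns < 2L || nr < 2L) {
    stop("icc_oneway needs at least 2 subjects and 2 repetitions",
         call. = FALSE)
  }
  grand <- mean(x)
  rm <- rowMeans(x)
  ssb <- nr * sum((rm - grand)^2)
  ssw <- sum((x - rm)^2)
  msb <- ssb / (ns - 1)
  msw <- ssw / (ns * (nr - 1))
  icc_raw <- if (msb + (nr - 1) * msw == 0) NA_real_ else
    (msb - msw) / (msb + (nr - 1) * msw)
  structure(
    list(icc = min(max(icc_raw, 0), 1), icc_raw = icc_raw,
         msb = msb, msw = msw,
         sigma2_b = (msb - msw) / nr, sigma2_w = msw,
         f = if (msw == 0) Inf else msb / msw,
         df = c(ns - 1, ns * (nr - 1)),
         n_subjects = ns, n_repetitions = nr),
    class = "icc_result"
  )
}

#' Bootstrap percentile confidence interval for the one-way ICC
#'
#' Resamples subjects with replacement (keeping each subject's full
#' repetition vector intact), recomputes the ICC per resample, and returns
#' the 2.5/97.5 percentile interval. Resamples containing a single unique
#' subject carry no between-subject information and are redrawn; the count
#' of redraws is returned.
#'
#' @param x Balanced subjects-by-repetitions matrix or long table.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for reproducibility.
#' @param conf Confidence level.
#'
#' @return List with `lower`, `upper`, `n_boot`, `n_redrawn`, and the
#'   vector of bootstrap ICCs (`boot_icc`, clamped to `[0, 1]`).
#' @export
bootstrap_icc_ci <- function(x, n_boot = 1000, seed = 1L, conf = 0.95) {
  x <- as_roi_matrix(x)
  ns <- nrow(x)
  nr <- ncol(x)
  if (ns < 2L) stop("at least 2 subjects are required", call. = FALSE)
  # sufficient statistics per subject: mean and within-subject SS
  rm_all <- rowMeans(x)
  ssw_all <- rowSums((x - rm_all)^2)
  dfw <- ns * (nr - 1)

  boot <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(ns, ns, replace = TRUE)
        if (length(unique(idx)) > 1L) break
        n_redrawn <- n_redrawn + 1L
      }
      m <- rm_all[idx]
      msb <- nr * sum((m - mean(m))^2) / (ns - 1)
      msw <- sum(ssw_all[idx]) / dfw
      denom <- msb + (nr - 1) * msw
      icc <- if (denom == 0) 1 else (msb - msw) / denom
      boot[b] <- min(max(icc, 0), 1)
    }
  })
  alpha <- (1 - conf) / 2
  qs <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  list(lower = qs[1], upper = qs[2], n_boot = n_boot,
       n_redrawn = n_redrawn, boot_icc = boot)
}

#' Confidence intervals for the repeatability standard deviations
#'
#' Interval estimates for the within-subject and between-subject SDs of a
#' balanced repeated-measures table. The default is the analytic
#' chi-square interval on the corresponding ANOVA variance estimate
#' (`MSW` with `N_s (N_r - 1)` degrees of freedom for `sigma_w`; the
#' sample variance of subject means with `N_s - 1` degrees of freedom for
#' `sigma_b`). A subject-resampling percentile bootstrap of the
#' population-divisor statistics is available as an alternative; the two
#' differ in small samples and the reporting convention varies between
#' studies.
#'
#' @param x Balanced subjects-by-repetitions matrix or long table.
#' @param which `"sigma_w"` or `"sigma_b"`.
#' @param type `"chisq"` (analytic, default) or `"bootstrap"`.
#' @param conf Confidence level.
#' @param n_boot,seed Bootstrap settings (ignored for `"chisq"`).
#'
#' @return List with `estimate`, `lower`, `upper`, `type`.
#' @export
sigma_ci <- function(x, which = c("sigma_w", "sigma_b"),
                     type = c("chisq", "bootstrap"), conf = 0.95,
                     n_boot = 1000, seed = 1L) {
  x <- as_roi_matrix(x)
  which <- match.arg(which)
  type <- match.arg(type)
  ns <- nrow(x)
  nr <- ncol(x)
  alpha <- (1 - conf) / 2

  if (type == "chisq") {
    if (which == "sigma_w") {
      df <- ns * (nr - 1)
      s2 <- icc_oneway(x)$sigma2_w
    } else {
      df <- ns - 1
      s2 <- stats::var(rowMeans(x))
    }
    est <- sqrt(s2)
    lo <- sqrt(df * s2 / stats::qchisq(1 - alpha, df))
    hi <- sqrt(df * s2 / stats::qchisq(alpha, df))
    return(list(estimate = est, lower = lo, upper = hi, type = "chisq"))
  }

  stat <- if (which == "sigma_w") pooled_sigma_w else sigma_b
  est <- stat(x)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(ns, ns, replace = TRUE)
        if (which == "sigma_w" || length(unique(idx)) > 1L) break
      }
      stat(x[idx, , drop = FALSE])
    }, numeric(1))
  })
  qs <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  list(estimate = est, lower = qs[1], upper = qs[2], type = "bootstrap")
}

#' Repeatability coefficient / minimum detectable effect size
#'
#' `RC = 1.96 * sqrt(2 * sigma_w^2)`: the smallest difference between two
#' repeated measurements detectable at 95% confidence, in the units of
#' `sigma_w`. Also interpretable as the minimum detectable effect size of a
#' single-timepoint group change.
#'
#' @param sigma_w Within-subject SD (any non-negative number; ppm or ppb).
#'
#' @return `1.96 * sqrt(2) * sigma_w`, same units as the input.
#' @export
#' @examples
#' rc_mde(10) # 27.72 for sigma_w = 10 ppb
rc_mde <- function(sigma_w) {
  if (any(sigma_w < 0)) stop("`sigma_w` must be >= 0", call. = FALSE)
  1.96 * sqrt(2 * sigma_w^2)
}

#' Classify an ICC value into repeatability categories
#'
#' Conventional reliability bands: below 0.5 poor, 0.5 to below 0.75
#' moderate, 0.75 to below 0.9 good, 0.9 and above excellent.
#'
#' @param icc ICC value(s) in `[0, 1]` (clamp negative raw estimates first).
#'
#' @return Character vector of categories.
#' @export
classify_icc <- function(icc) {
  if (any(icc < 0 | icc > 1, na.rm = TRUE)) {
    stop("`icc` must lie in [0, 1]; clamp raw estimates first",
         call. = FALSE)
  }
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE) |> as.character()
}

#' Full repeatability record per ROI and method
#'
#' Applies the whole ROI-level battery to a long table of per-ROI mean
#' susceptibilities: mean, pooled within-subject SD, between-subject SD,
#' pooled CV (with stability flag), one-way ICC with bootstrap CI,
#' repeatability coefficient and ICC classification, one row per
#' ROI-method combination.
#'
#' @param table Long tibble with columns `subject`, `repetition`, `method`,
#'   `roi`, `chi_ppm` (e.g. from [roi_means()] or [simulate_roi_table()]).
#' @param n_boot Bootstrap resamples for the ICC CI.
#' @param seed Seed for the bootstrap.
#' @param sigma_r_table Optional tibble with columns `roi`, `method`,
#'   `sigma_r` (ppm) to merge in (voxel-level SD is not computable from ROI
#'   means alone).
#'
#' @return Tibble with one row per ROI x method: `roi`, `method`,
#'   `mean_ppm`, `sigma_r`, `sigma_w`, `sigma_b`, `cv`, `cv_unstable`,
#'   `icc`, `icc_raw`, `icc_lower`, `icc_upper`, `rc_ppm`,
#'   `classification`.
#' @export
repeatability_summary <- function(table, n_boot = 1000, seed = 1L,
                                  sigma_r_table = NULL) {
  combos <- dplyr::distinct(table, .data$method, .data$roi)
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- dplyr::filter(table, .data$method == combos$method[i],
                         .data$roi == combos$roi[i])
    mat <- roi_matrix(sub)
    sw <- pooled_sigma_w(mat)
    grand <- mean(rowMeans(mat))
    fit <- icc_oneway(mat)
    ci <- bootstrap_icc_ci(mat, n_boot = n_boot, seed = seed)
    out[[i]] <- tibble::tibble(
      roi = combos$roi[i], method = combos$method[i],
      mean_ppm = grand,
      sigma_w = sw, sigma_b = sigma_b(mat),
      cv = if (grand == 0) NA_real_ else sw / grand,
      cv_unstable = grand == 0 | abs(grand) < 2 * sw / sqrt(ncol(mat)),
      icc = fit$icc, icc_raw = fit$icc_raw,
      icc_lower = ci$lower, icc_upper = ci$upper,
      rc_ppm = rc_mde(sw),
      classification = classify_icc(fit$icc)
    )
  }
  res <- dplyr::bind_rows(out)
  if (!is.null(sigma_r_table)) {
    res <- dplyr::left_join(res, sigma_r_table, by = c("roi", "method"))
  } else {
    res$sigma_r <- NA_real_
  }
  dplyr::relocate(res, "sigma_r", .before = "sigma_w")
}
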