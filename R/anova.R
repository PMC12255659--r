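#' One-factor repeated-measures ANOVA
#'
#' Tests for a condition (e.g. reconstruction method) effect across
#' within-subject conditions: `F = MS_condition / MS_(condition x subject)`
#' with degrees of freedom `(k - 1, (k - 1)(n - 1))`. Mauchly's sphericity
#' test runs alongside; when sphericity is rejected (or `correct =
#' "force"`), the conservative lower-bound correction `epsilon = 1/(k - 1)`
#' multiplies both degrees of freedom before the p-value is recomputed.
#'
#' @param data Numeric matrix, subjects in rows, conditions in columns; or
#'   a 3-D array subjects x conditions x replicates. Replicates are
#'   averaged per subject when `replicates = "means"` (default, avoiding
#'   pseudo-replication) or stacked as extra blocking rows when
#'   `replicates = "stack"`.
#' @param correct `"auto"` applies the lower-bound correction when Mauchly's
#'   p < `alpha`; `"none"` never; `"force"` always.
#' @param alpha Significance level for the sphericity decision.
#' @param replicates How to treat a replicate dimension, if present.
#'
#' @return Object of class `ranova_result`: `f`, `df`, `p`, `mauchly_w`,
#'   `mauchly_p`, `epsilon_lower_bound`, `p_corrected`,
#'   `sphericity_violated`, `degenerate` (true when the interaction mean
#'   square is zero and F is reported at its limit).
#' @export
rm_anova <- function(data, correct = c("auto", "none", "force"),
                     alpha = 0.05, replicates = c("means", "stack")) {
  correct <- match.arg(correct)
  replicates <- match.arg(replicates)
  if (length(dim(data)) == 3L) {
    data <- if (replicates == "means") {
      apply(data, c(1, 2), mean)
    } else {
      # stack subject x replicate as rows: each replicate series is a block
      do.call(rbind, lapply(seq_len(dim(data)[3]), function(r) data[, , r]))
    }
  }
  data <- as.matrix(data)
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2L || k < 2L) {
    stop("rm_anova needs at least 2 subjects and 2 conditions",
         call. = FALSE)
  }
  if (anyNA(data)) stop("missing cells are not supported", call. = FALSE)

  grand <- mean(data)
  row_m <- rowMeans(data)
  col_m <- colMeans(data)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_int <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_int <- ss_int / df2

  degenerate <- ms_int <= 0
  if (degenerate) {
    f <- if (ms_cond == 0) 0 else Inf
    p <- if (ms_cond == 0) 1 else 0
  } else {
    f <- ms_cond / ms_int
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }

  mauchly <- mauchly_test(data)
  res <- structure(
    list(f = f, df = c(df1, df2), p = p,
         mauchly_w = mauchly$w, mauchly_p = mauchly$p,
         epsilon_lower_bound = 1 / (k - 1),
         p_corrected = p, sphericity_violated = FALSE,
         degenerate = degenerate, n_subjects = n, n_conditions = k),
    class = "ranova_result"
  )
  if (correct == "force" ||
      (correct == "auto" && !is.na(mauchly$p) && mauchly$p < alpha)) {
    res <- lower_bound_correct(res)
  }
  res
}

#' @export
print.ranova_result <- function(x, ...) {
  cat(sprintf(
    "RM-ANOVA: F(%g, %g) = %.4g, p = %.4g\n", x$df[1], x$df[2], x$f, x$p))
  cat(sprintf("Mauchly W = %.4g (p = %.4g); %s\n", x$mauchly_w, x$mauchly_p,
              if (x$sphericity_violated)
                sprintf("lower-bound corrected p = %.4g", x$p_corrected)
              else "no sphericity correction applied"))
  if (x$degenerate) cat("note: zero interaction variance (degenerate)\n")
  invisible(x)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance matrix of orthonormal contrasts of the
#' conditions is proportional to the identity (equal variances of all
#' pairwise condition differences). `W` is the ratio of the geometric to
#' arithmetic mean of the contrast covariance eigenvalues; the p-value uses
#' the standard chi-square approximation. With two conditions sphericity
#' cannot be violated (`W = 1, p = 1`).
#'
#' @param data Numeric matrix, subjects in rows, conditions in columns.
#'
#' @return List with `w`, `p`, `df`, and `singular` (true when the contrast
#'   covariance is singular, in which case `W = 0, p = 0`).
#' @export
mauchly_test <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  k <- ncol(data)
  if (k < 2L) stop("at least 2 conditions are required", call. = FALSE)
  if (k == 2L) {
    return(list(w = 1, p = 1, df = 0L, singular = FALSE))
  }
  # orthonormal contrasts spanning the (k-1)-dim difference space
  ctr <- qr.Q(qr(stats::contr.helmert(k)))
  s <- stats::cov(data %*% ctr)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  # judge singularity against the scale of the data, not of the contrasts:
  # identical conditions give a numerically zero contrast covariance
  data_scale <- mean(diag(stats::cov(data)))
  if (data_scale <= 0 || any(ev <= 1e-12 * data_scale)) {
    return(list(w = 0, p = 0, df = as.integer(k * (k - 1) / 2 - 1),
                singular = TRUE))
  }
  p_dim <- k - 1
  w <- prod(ev) / (mean(ev))^p_dim
  dfc <- n - 1
  rho <- 1 - (2 * p_dim^2 + p_dim + 2) / (6 * p_dim * dfc)
  chi2 <- -rho * dfc * log(w)
  df <- as.integer(p_dim * (p_dim + 1) / 2 - 1) # = k(k-1)/2 - 1
  # chi-square approximation with the standard second-order series term
  w2 <- (p_dim + 2) * (p_dim - 1) * (p_dim - 2) *
    (2 * p_dim^3 + 6 * p_dim^2 + 3 * p_dim + 2) /
    (288 * (dfc * p_dim * rho)^2)
  pr1 <- stats::pchisq(chi2, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(chi2, df + 4, lower.tail = FALSE)
  list(w = w, p = min(max(pr1 + w2 * (pr2 - pr1), 0), 1), df = df,
       singular = FALSE)
}

#' Apply the lower-bound sphericity correction
#'
#' Multiplies both degrees of freedom of an RM-ANOVA by the lower bound
#' `epsilon = 1/(k - 1)` — the most conservative sphericity correction —
#' and recomputes the p-value. The corrected p is floored at the
#' uncorrected p (for F < 1 shrinking the degrees of freedom could
#' otherwise lower it), so the correction never strengthens the evidence.
#'
#' @param result A `ranova_result` from [rm_anova()].
#'
#' @return The result with `p_corrected` recomputed and
#'   `sphericity_violated` set.
#' @export
lower_bound_correct <- function(result) {
  stopifnot(inherits(result, "ranova_result"))
  eps <- result$epsilon_lower_bound
  result$p_corrected <- if (result$degenerate) {
    result$p
  } else {
    max(result$p,
        stats::pf(result$f, result$df[1] * eps, result$df[2] * eps,
                  lower.tail = FALSE))
  }
  result$sphericity_violated <- TRUE
  result
}

#' Test whether between-subject variance exceeds within-subject variance
#'
#' One-way random-effects F-test on the ROI means: `F = MSB / MSW` with
#' degrees of freedom `(N_s - 1, N_s (N_r - 1))`. A small p-value indicates
#' that subjects genuinely differ beyond repetition noise, i.e.
#' `sigma_b > sigma_w` in the variance-components sense.
#'
#' @param x Balanced subjects-by-repetitions matrix or long table (single
#'   ROI and method).
#'
#' @return List with `f`, `df`, `p`, `degenerate` (true when `MSW = 0`).
#' @export
between_vs_within_test <- function(x) {
  x <- as_roi_matrix(x)
  icc <- icc_oneway(x)
  degenerate <- icc$msw == 0
  p <- if (degenerate) {
    if (icc$msb == 0) 1 else 0
  } else {
    stats::pf(icc$f, icc$df[1], icc$df[2], lower.tail = FALSE)
  }
  list(f = icc$f, df = icc$df, p = p, degenerate = degenerate)
}

#' Pairwise method mean-difference matrices
#'
#' For each ROI, computes the k-by-k antisymmetric matrix of mean
#' differences between reconstruction methods (in ppb), evaluated on
#' subject-level means (repetitions averaged first, avoiding
#' pseudo-replication), together with paired two-sided t-tests across
#' subjects. The `not_significant` flag matrix marks pairs whose difference
#' is NOT significant at `alpha` (the highlight convention of
#' method-comparison tables); the diagonal is flagged by construction.
#'
#' @param table Long tibble with columns `subject`, `repetition`, `method`,
#'   `roi`, `chi_ppm` covering two or more methods on the same subjects and
#'   repetitions.
#' @param alpha Significance level.
#' @param bonferroni If `TRUE`, multiply p-values by the number of method
#'   pairs (capped at 1) before flagging.
#'
#' @return Named list, one entry per ROI, each with `diff_ppb`, `p` and
#'   `not_significant` (k x k matrices with method dimnames).
#' @export
pairwise_method_diffs <- function(table, alpha = 0.05, bonferroni = FALSE) {
  methods <- sort(unique(table$method))
  if (length(methods) < 2L) {
    stop("at least 2 methods are required", call. = FALSE)
  }
  rois <- sort(unique(table$roi))
  k <- length(methods)
  n_pairs <- k * (k - 1) / 2

  # subject-level means per method/roi
  sub_means <- table |>
    dplyr::group_by(.data$method, .data$roi, .data$subject) |>
    dplyr::summarise(chi_ppm = mean(.data$chi_ppm), .groups = "drop")

  out <- list()
  for (roi in rois) {
    wide <- sub_means |>
      dplyr::filter(.data$roi == !!roi) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "method",
                         values_from = "chi_ppm")
    if (anyNA(wide)) {
      stop(sprintf("ROI '%s': methods do not share the same subjects", roi),
           call. = FALSE)
    }
    mat <- as.matrix(wide[, methods, drop = FALSE])
    diff_ppb <- matrix(0, k, k, dimnames = list(methods, methods))
    pmat <- matrix(1, k, k, dimnames = list(methods, methods))
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j) next
        d <- mat[, i] - mat[, j]
        diff_ppb[i, j] <- mean(d) * 1000
        pmat[i, j] <- paired_p(d)
      }
    }
    if (bonferroni) pmat <- pmin(pmat * n_pairs, 1)
    out[[roi]] <- list(diff_ppb = diff_ppb, p = pmat,
                       not_significant = pmat >= alpha)
  }
  out
}

# Two-sided one-sample t-test p-value on paired differences, tolerating
# the (near-)zero-variance corner: identical columns give p = 1, a constant
# nonzero offset gives p = 0 (the test's limit).
paired_p <- function(d) {
  m <- mean(d)
  s <- stats::sd(d)
  if (length(d) < 2L || s == 0 || s <= 1e-10 * abs(m)) {
    return(if (abs(m) <= s) 1 else 0)
  }
  tryCatch(stats::t.test(d)$p.value,
           error = function(e) if (m == 0) 1 else 0)
}
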