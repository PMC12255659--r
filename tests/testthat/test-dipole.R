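test_that("dipole kernel takes its analytic values on and off axis", {
  k <- dipole_kernel(c(16, 16, 16), c(1, 1, 1), c(0, 0, 1))
  expect_identical(k$values[1, 1, 1], 0)         # DC convention
  expect_equal(k$values[1, 1, 2], -2 / 3)        # k parallel to B0
  expect_equal(k$values[2, 1, 1], 1 / 3)         # k perpendicular to B0
  expect_true(all(k$values >= -2 / 3 - 1e-12 & k$values <= 1 / 3 + 1e-12))
  expect_error(dipole_kernel(c(8, 8, 8), b0_direction = c(0, 0, 0)),
               "nonzero")
})

test_that("kernel respects an oblique field direction", {
  b0 <- c(1, 1, 1) / sqrt(3)
  k <- dipole_kernel(c(8, 8, 8), c(1, 1, 1), b0)
  # k-vector along (1,0,0): (k.b)^2/|k|^2 = 1/3 -> D = 0
  expect_equal(k$values[2, 1, 1], 0, tolerance = 1e-12)
})

test_that("uniform susceptibility induces zero field; field has zero mean", {
  k <- dipole_kernel(c(12, 12, 12), c(1, 1, 1))
  f <- forward_field(array(0.37, c(12, 12, 12)), k)
  expect_lt(max(abs(f)), 1e-12)
  set.seed(8)
  f2 <- forward_field(array(rnorm(12^3), c(12, 12, 12)), k)
  expect_lt(abs(mean(f2)), 1e-12)
})

test_that("forward field is linear and real for real input", {
  k <- dipole_kernel(c(12, 12, 12), c(1, 1, 1))
  set.seed(2)
  a <- array(rnorm(12^3), c(12, 12, 12))
  b <- array(rnorm(12^3), c(12, 12, 12))
  lhs <- forward_field(2 * a - 3 * b, k)
  rhs <- 2 * forward_field(a, k) - 3 * forward_field(b, k)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("sphere interior field is near zero (Lorentz closed form)", {
  # a uniformly magnetised sphere produces zero internal dipole field and a
  # dipolar external pattern; check the interior on a padded grid
  n <- 32
  g <- seq_len(n)
  sph <- array(0, c(n, n, n))
  r2 <- outer(outer((g - 16.5)^2, (g - 16.5)^2, `+`), (g - 16.5)^2, `+`)
  sph[r2 <= 6^2] <- 1
  k <- dipole_kernel(c(n, n, n), c(1, 1, 1))
  f <- forward_field(sph, k, pad = TRUE)
  interior <- f[r2 <= 3^2]
  # discretisation leaves small residuals; interior mean field ~ 0 vs the
  # chi = 1 source amplitude
  expect_lt(max(abs(interior)), 0.05)
  # exterior along B0 axis is positive (paramagnetic lobe), equatorial
  # exterior negative
  expect_gt(f[17, 17, 26], 0)
  expect_lt(f[17, 26, 17], 0)
})

test_that("TKD inverts its own forward field up to the truncated cone", {
  spec <- default_phantom_spec(c(32, 32, 32))
  spec$rois <- lapply(spec$rois, function(r) {
    r$texture_sd <- 0
    r
  })
  ph <- build_phantom(spec, seed = 2)
  k <- dipole_kernel(c(32, 32, 32), c(1.25, 1.25, 1.25))
  f <- forward_field(ph$qmap, k)
  ref <- ph$qmap$values - mean(ph$qmap$values) # DC is unrecoverable
  full <- array(TRUE, dim(ref))
  err <- vapply(c(0.3, 0.2, 0.1, 0.05),
                function(d) nrmse(ref, tkd_invert(f, k, d)$values, full),
                numeric(1))
  expect_true(all(diff(err) < 0))  # monotone improvement as delta shrinks
  expect_lt(err[3], 0.45)          # delta = 0.1 round-trip bound
  expect_error(tkd_invert(f, k, 0.7), "between 0 and 2/3")
  expect_error(tkd_invert(f, k, 0), "between 0 and 2/3")
})

test_that("zero field inverts to zero susceptibility", {
  k <- dipole_kernel(c(8, 8, 8), c(1, 1, 1))
  z <- array(0, c(8, 8, 8))
  expect_lt(max(abs(tkd_invert(z, k, 0.1)$values)), 1e-14)
  expect_lt(max(abs(tikhonov_invert(z, k, 0.05)$values)), 1e-14)
})

test_that("Tikhonov solution norm is non-increasing in lambda", {
  ph <- build_phantom(default_phantom_spec(c(16, 16, 16)), seed = 3)
  k <- dipole_kernel(c(16, 16, 16), c(1.25, 1.25, 1.25))
  f <- forward_field(ph$qmap, k)
  norms <- vapply(c(1e-4, 1e-3, 1e-2, 0.1, 1, 10), function(l) {
    sqrt(sum(tikhonov_invert(f, k, l)$values^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 0))
  # over-regularisation limit
  expect_lt(max(abs(tikhonov_invert(f, k, 1e6)$values)), 1e-6)
  expect_error(tikhonov_invert(f, k, 0), "positive")
})

test_that("two inversion methods disagree systematically on ROI means", {
  co <- tiny_cohort(n_subjects = 4, grid = c(16, 16, 16), seed = 21)
  k <- dipole_kernel(c(16, 16, 16), c(1.25, 1.25, 1.25))
  chi_tables <- lapply(
    list(tkd = function(f) tkd_invert(f, k, 0.2),
         tik = function(f) tikhonov_invert(f, k, 0.05)),
    function(inv) {
      rec <- co
      rec$maps <- lapply(co$maps, function(reps) {
        lapply(reps, function(q) {
          out <- inv(forward_field(q, k))
          out$mask <- q$mask
          out
        })
      })
      rec
    })
  ta <- roi_means(chi_tables$tkd, method = "tkd")
  tb <- roi_means(chi_tables$tik, method = "tik")
  both <- dplyr::bind_rows(ta, tb)
  one_roi <- dplyr::filter(both, roi == "vein")
  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(one_roi, subject, method),
                     chi_ppm = mean(chi_ppm), .groups = "drop"),
    names_from = "method", values_from = "chi_ppm")
  res <- rm_anova(as.matrix(wide[, c("tkd", "tik")]))
  expect_lt(res$p, 0.05) # regularisation bias differs between the methods
})

test_that("shape mismatches are rejected", {
  k <- dipole_kernel(c(8, 8, 8), c(1, 1, 1))
  expect_error(forward_field(array(0, c(8, 8, 9)), k), "shape")
})
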