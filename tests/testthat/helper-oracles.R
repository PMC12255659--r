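# Independent oracles used across tests. These re-derive expected values by
# brute force or through base-R model fits; they never call the code paths
# they check.

# Direct sliding-window SSIM evaluation with a Gaussian window clipped at
# the volume border and renormalised: the definition xsim() implements via
# FFT convolution on zero-padded volumes.
brute_force_xsim <- function(x, y, sigma = 1.5, radius = ceiling(3 * sigma),
                             L = 1, k1 = 0.01, k2 = 0.001) {
  d <- dim(x)
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  w1 <- exp(-(-radius:radius)^2 / (2 * sigma^2))
  out <- array(NA_real_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    ii <- (i - radius):(i + radius)
    jj <- (j - radius):(j + radius)
    kk <- (k - radius):(k + radius)
    vi <- ii >= 1 & ii <= d[1]
    vj <- jj >= 1 & jj <= d[2]
    vk <- kk >= 1 & kk <= d[3]
    w <- outer(outer(w1[vi], w1[vj]), w1[vk])
    w <- w / sum(w)
    xs <- x[ii[vi], jj[vj], kk[vk]]
    ys <- y[ii[vi], jj[vj], kk[vk]]
    mx <- sum(w * xs)
    my <- sum(w * ys)
    vx <- max(sum(w * xs^2) - mx^2, 0)
    vy <- max(sum(w * ys^2) - my^2, 0)
    cxy <- sum(w * xs * ys) - mx * my
    out[i, j, k] <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  mean(out)
}

# One-factor repeated-measures ANOVA through stats::aov with an
# Error(subject) stratum.
aov_rm_oracle <- function(mat) {
  df <- data.frame(
    y = c(mat),
    s = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    cond = factor(rep(seq_len(ncol(mat)), each = nrow(mat)))
  )
  tab <- summary(stats::aov(y ~ cond + Error(s / cond), data = df))
  row <- tab[["Error: s:cond"]][[1]]
  list(f = row["cond", "F value"], p = row["cond", "Pr(>F)"])
}

# One-way random-effects ANOVA mean squares through stats::aov.
aov_oneway_oracle <- function(mat) {
  df <- data.frame(
    y = c(mat),
    s = factor(rep(seq_len(nrow(mat)), ncol(mat)))
  )
  tab <- summary(stats::aov(y ~ s, data = df))[[1]]
  list(msb = tab["s", "Mean Sq"], msw = tab["Residuals", "Mean Sq"])
}

# Small cohort on a small grid for pipeline tests.
tiny_cohort <- function(n_subjects = 3, grid = c(12, 12, 12), seed = 1,
                        sigma_b = 0.010, sigma_w = 0.005,
                        voxel_noise_sd = 0.005) {
  sample_cohort(
    default_phantom_spec(grid),
    cohort_spec(n_subjects = n_subjects, sigma_b = sigma_b,
                sigma_w = sigma_w, voxel_noise_sd = voxel_noise_sd,
                seed = seed)
  )
}
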