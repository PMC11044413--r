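test_that("two-point ADC inversion is exact and clips negative estimates", {
  sig <- mono_signal(1e-3, sch9$values)
  expect_equal(fit_mono_adc(sig, sch9)$params[["ADC"]], 1e-3)

  flat <- rep(2, 9)
  expect_equal(fit_mono_adc(flat, sch9)$params[["ADC"]], 0)

  # round trip at the normal-tissue group mean
  sig <- mono_signal(1.362e-3, sch9$values, s0 = 3.7)
  expect_equal(fit_mono_adc(sig, sch9)$params[["ADC"]], 1.362e-3)

  # S(750) > S(0): valid call, clipped and flagged
  up <- rep(1, 9); up[6] <- 1.4
  res <- fit_mono_adc(up, sch9)
  expect_equal(res$params[["ADC"]], 0)
  expect_true("clipped_negative_adc" %in% res$flags)

  bad <- rep(1, 9); bad[6] <- 0
  expect_error(fit_mono_adc(bad, sch9), "unfittable")
})

test_that("IVIM joint fit recovers noiseless parameters and degenerate limits", {
  # benign group means, round trip
  truth <- c(0.940e-3, 0.019, 0.256)
  sig <- ivim_signal(truth[1], truth[2], truth[3], sch9$values, s0 = 2.534)
  p <- fit_ivim(sig, sch9)$params
  expect_true(all(abs(p - truth) / truth < 1e-4))

  # pure mono-exponential input: f pinned near 0, dt accurate, dp flagged
  sig0 <- mono_signal(1.1e-3, sch9$values)
  r0 <- fit_ivim(sig0, sch9)
  expect_lte(r0$params[["f"]], 0.01)
  expect_lt(abs(r0$params[["Dt"]] - 1.1e-3) / 1.1e-3, 0.01)
  expect_true("dp_unidentifiable" %in% r0$flags)

  # f = 1 truth: a parameter sits on a bound and the result is flagged
  sig1 <- ivim_signal(1e-3, 0.02, 1, sch9$values)
  r1 <- fit_ivim(sig1, sch9)
  expect_true("at_bound" %in% r1$flags)
  expect_lte(r1$residual_norm, 1e-6)

  expect_error(fit_ivim(c(0, rep(1, 8)), sch9), "positive")
})

test_that("IVIM optimum beats a dense grid search over the bounded box", {
  set.seed(4)
  for (i in 1:2) {
    truth <- c(runif(1, 2e-4, 2e-3), runif(1, 5e-3, 0.1), runif(1, 0.05, 0.5))
    sig <- ivim_signal(truth[1], truth[2], truth[3], sch9$values)
    if (i == 2) sig <- add_rician_noise(sig, snr = 20, seed = 40 + i)
    b <- sch9$ivim_subset
    y <- sig[seq_along(b)] / sig[1]
    fit <- fit_ivim(sig, sch9)
    expect_lte(fit$residual_norm^2, ivim_grid_rss(b, y) + 1e-12)
  }
})

test_that("RSI fit is exact, matches the NNLS oracle, and fractions sum to 1", {
  # noiseless round trip at the benign group means: 9 equations, 3 unknowns
  truth <- c(0.233, 1.972, 0.329)
  sig <- rsi_signal(truth[1], truth[2], truth[3], sch9$values)
  res <- fit_rsi(sig, sch9)
  expect_true(all(abs(res$params[c("C1", "C2", "C3")] - truth) / truth < 1e-6))

  # flat signal is entirely the zero-diffusivity compartment
  resk <- fit_rsi(rep(3.5, 9), sch9)
  expect_equal(resk$params[["C1"]], 3.5, tolerance = 1e-8)
  expect_lt(resk$params[["C2"]] + resk$params[["C3"]], 1e-8)

  # NNLS oracle agreement and fraction normalization on noisy voxels
  X <- cbind(1, exp(-sch9$values * RSI_ADCS[[2]]),
             exp(-sch9$values * RSI_ADCS[[3]]))
  set.seed(5)
  for (i in 1:25) {
    cc <- runif(3, 0, 2)
    sig <- add_rician_noise(rsi_signal(cc[1], cc[2], cc[3], sch9$values),
                            snr = 15, seed = 50 + i, s0 = sum(cc))
    res <- fit_rsi(sig, sch9)
    oracle <- pracma::lsqnonneg(X, sig)$x
    expect_lt(max(abs(res$params[c("C1", "C2", "C3")] - oracle)),
              1e-6 * max(1, sum(oracle)))
    expect_true(all(res$params[c("C1", "C2", "C3")] >= 0))
    expect_equal(sum(res$params[c("F1", "F2", "F3")]), 1, tolerance = 1e-9)
  }
  expect_error(fit_rsi(rep(0, 9), sch9), "all-zero")
})

test_that("round-trip recovery holds across the plausible parameter space", {
  # spans the class moments +/- 2 SD for each model family
  set.seed(6)
  for (dt in seq(0.45e-3, 1.5e-3, length.out = 3))
    for (f in c(0.15, 0.3)) {
      sig <- ivim_signal(dt, 0.02, f, sch9$values, s0 = 2)
      p <- fit_ivim(sig, sch9)$params
      expect_true(all(abs(p - c(dt, 0.02, f)) / c(dt, 0.02, f) < 1e-4))
    }
  for (i in 1:5) {
    cc <- runif(3, 0.05, 3)
    p <- fit_rsi(rsi_signal(cc[1], cc[2], cc[3], sch9$values), sch9)$params
    expect_true(all(abs(p[c("C1", "C2", "C3")] - cc) / cc < 1e-4))
  }
})

test_that("parameter error decreases with SNR under Rician noise", {
  truth <- c(Dt = 0.662e-3, Dp = 0.022, f = 0.235)
  cc <- c(0.540, 1.826, 0.161)
  s0 <- sum(cc)
  snrs <- c(10, 25, 50, 100)
  nvox <- 120
  med_err <- sapply(seq_along(snrs), function(k) {
    errs <- sapply(seq_len(nvox), function(v) {
      sig <- ivim_signal(truth[1], truth[2], truth[3], sch9$values, s0 = s0)
      sig <- add_rician_noise(sig, snrs[k], seed = 1000 * k + v)
      p <- fit_ivim(sig, sch9)$params
      adc <- fit_mono_adc(sig, sch9)$params[["ADC"]]
      c(abs(p - truth), ADC = abs(adc - fit_mono_adc(
        ivim_signal(truth[1], truth[2], truth[3], sch9$values, s0 = s0),
        sch9)$params[["ADC"]]))
    })
    apply(errs, 1, median)
  })
  for (param in rownames(med_err))
    expect_true(all(diff(med_err[param, ]) <= 1e-12),
                info = paste("median error not decreasing for", param))
})

test_that("fit_volume maps the grid, honors masks, and flags failures", {
  b <- sch9$values
  grid <- c(4, 4, 2)
  # two-region phantom at zero noise
  sig_a <- ivim_signal(0.662e-3, 0.022, 0.235, b, s0 = 2.527)
  sig_b <- ivim_signal(0.940e-3, 0.019, 0.256, b, s0 = 2.534)
  vol <- array(0, c(grid, 9))
  region <- array(rep(c(TRUE, FALSE), each = 16), grid)
  for (j in 1:9) {
    plane <- array(sig_b[j], grid)
    plane[region] <- sig_a[j]
    vol[, , , j] <- plane
  }
  maps <- fit_volume(vol, sch9, "ivim")
  expect_equal(mean(maps$Dt[region]), 0.662e-3, tolerance = 1e-6)
  expect_equal(mean(maps$Dt[!region]), 0.940e-3, tolerance = 1e-6)
  expect_equal(mean(maps$f[region]), 0.235, tolerance = 1e-6)

  # homogeneous phantom: constant maps
  volh <- array(rep(sig_a, each = prod(grid)), c(grid, 9))
  mh <- fit_volume(volh, sch9, "rsi")
  expect_lt(diff(range(mh$F1)), 1e-9)

  # masked fit leaves the sentinel outside
  mask <- array(FALSE, grid); mask[1:2, 1, 1] <- TRUE
  mm <- fit_volume(vol, sch9, "mono", mask = mask)
  expect_true(all(is.na(mm$ADC[!mask])))
  expect_true(all(!is.na(mm$ADC[mask])))
  log <- attr(mm, "fit_log")
  expect_equal(log$n_fitted, 2)

  expect_error(fit_volume(array(1, c(4, 4, 2, 5)), sch9, "mono"),
               "does not match")
})
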