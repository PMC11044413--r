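test_that("Kruskal-Wallis omnibus test behaves at the null and under separation", {
  # groups that are permutations of the same values: H exactly 0
  g <- list(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), c(3, 1, 5, 2, 4))
  kw <- kruskal_wallis(g)
  expect_lt(kw$chi2, 1e-12)
  expect_equal(kw$p, 1)

  # three non-overlapping groups: compare to a permutation-null oracle
  set.seed(11)
  g2 <- list(rnorm(10, 0), rnorm(10, 5), rnorm(10, 10))
  kw2 <- kruskal_wallis(g2)
  expect_lt(kw2$p, 0.001)
  pooled <- unlist(g2)
  lab <- rep(1:3, each = 10)
  h_obs <- kw2$chi2
  perm <- replicate(2000, {
    pl <- sample(lab)
    stats::kruskal.test(split(pooled, pl))$statistic
  })
  expect_lte(mean(perm >= h_obs), 0.001)  # observed H beyond the null

  # two identical groups plus a far-shifted third
  g3 <- list(rnorm(10), rnorm(10), rnorm(10, 50))
  expect_lt(kruskal_wallis(g3)$p, 0.001)

  expect_error(kruskal_wallis(list(1, c(1, 2), c(3, 4))), "at least 2")
})

test_that("Mann-Whitney exact p matches brute-force enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p, 0.1)
  expect_equal(mw$p, mw_exact_bruteforce(c(1, 2, 3), c(4, 5, 6)))

  # more enumeration cases with unbalanced sizes
  set.seed(12)
  for (i in 1:5) {
    a <- round(rnorm(4), 3); b <- round(rnorm(6) + runif(1, -1, 1), 3)
    mwi <- mann_whitney(a, b)
    expect_equal(mwi$p, mw_exact_bruteforce(a, b), info = paste("case", i))
  }

  # same multiset: |z| tiny, not significant
  x <- c(2, 4, 6, 8)
  mws <- mann_whitney(x, rev(x))
  expect_lt(abs(mws$z), 1e-12)
  expect_false(mws$significant)

  # exact and (continuity-corrected) normal-approximate p agree for
  # moderate n on continuous data
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(16, 0.4)
    mwa <- mann_whitney(a, b)        # n1*n2 = 240 <= 400: exact
    sigma <- sqrt(15 * 16 * (15 + 16 + 1) / 12)
    p_norm <- 2 * pnorm(-(max(abs(mwa$u - 120) - 0.5, 0)) / sigma)
    expect_lt(abs(mwa$p - p_norm), 0.01)
  }
  expect_error(mann_whitney(1, c(1, 2)), "at least 2")
})

test_that("single-parameter ROC: AUC, direction and Youden threshold", {
  # perfect separation
  r <- roc_single_parameter(c(1, 2, 3, 10, 11, 12),
                            c(0, 0, 0, 1, 1, 1), positive = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)

  # exhaustive-sweep example: threshold falls between 2 and 3
  r2 <- roc_single_parameter(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1)
  expect_equal(r2$auc, 1)
  expect_equal(r2$direction, ">")
  expect_gt(r2$threshold, 2); expect_lt(r2$threshold, 3)

  # chance level under independent labels
  set.seed(13)
  rc <- roc_single_parameter(rnorm(1000), rbinom(1000, 1, 0.5), positive = 1)
  expect_lt(abs(rc$auc - 0.5), 0.06)

  # sign flip: same AUC, flipped inequality convention
  v <- rnorm(60); l <- rbinom(60, 1, 0.5)
  l[1:2] <- c(0, 1)  # ensure both classes
  ra <- roc_single_parameter(v, l, positive = 1)
  rb <- roc_single_parameter(-v, l, positive = 1)
  expect_equal(ra$auc, rb$auc)
  expect_true(ra$direction != rb$direction)

  expect_error(roc_single_parameter(1:4, rep(1, 4)), "two classes")
})

test_that("ROC AUC equals the scaled Mann-Whitney U (rank identity)", {
  set.seed(14)
  for (i in 1:50) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    pos <- rnorm(n1, runif(1, 0, 2))
    neg <- rnorm(n2)
    mw <- mann_whitney(pos, neg)           # U of the positive sample
    auc_up <- mw$u / (n1 * n2)
    r <- roc_single_parameter(c(pos, neg), rep(c(1, 0), c(n1, n2)),
                              positive = 1)
    expect_equal(r$auc, max(auc_up, 1 - auc_up), tolerance = 1e-12)
  }
})

test_that("cross-validated logistic models: chance, separation, bookkeeping", {
  set.seed(15)
  n <- 200
  tab <- data.frame(lesion_id = 1:n,
                    class = rep(c("benign", "malignant"), each = n / 2),
                    ADC = rnorm(n), Dt = rnorm(n), Dp = rnorm(n),
                    f = rnorm(n))
  # no signal: shuffled labels give chance-level mean AUC
  tab_null <- tab
  tab_null$class <- sample(tab$class)
  m0 <- fit_diagnostic_model(tab_null, c("ADC", "Dt", "Dp", "f"), seed = 2)
  expect_lt(abs(m0$mean_auc - 0.5), 0.12)
  expect_equal(m0$mean_auc, mean(m0$fold_aucs))
  expect_equal(length(m0$fold_aucs), 5)

  # a perfectly separating feature drives AUC to 1
  tab_sep <- tab
  tab_sep$ADC <- ifelse(tab$class == "malignant", 5, -5) + rnorm(n, 0, 0.1)
  m1 <- suppressWarnings(fit_diagnostic_model(tab_sep, "ADC", seed = 2))
  expect_equal(m1$mean_auc, 1)

  # determinism and fold structure
  m2 <- fit_diagnostic_model(tab_null, "ADC", seed = 7)
  m3 <- fit_diagnostic_model(tab_null, "ADC", seed = 7)
  expect_identical(m2$fold_aucs, m3$fold_aucs)
  expect_equal(sort(unique(m2$scores$fold)), 1:5)

  small <- tab[c(1:4, 101:104), ]
  expect_error(fit_diagnostic_model(small, "ADC"), "stratification")
  expect_error(fit_diagnostic_model(tab, "nope"), "missing parameter")
})

test_that("the hybrid model is at least as discriminative as ADC alone", {
  co <- generate_cohort(60, 30, 0, voxels_per_lesion = 16, snr = 50,
                        seed = 41)
  fs <- feature_sets()
  auc_adc <- auc_hyb <- numeric(10)
  for (s in 1:10) {
    auc_adc[s] <- suppressWarnings(
      fit_diagnostic_model(co, fs$ADC, folds = 5, seed = s)$mean_auc)
    auc_hyb[s] <- suppressWarnings(
      fit_diagnostic_model(co, fs$`IVIM+RSI`, folds = 5, seed = s)$mean_auc)
  }
  expect_gte(mean(auc_hyb), mean(auc_adc))
})

test_that("DeLong comparison: degenerate, rank-invariant, and oracle-checked", {
  set.seed(16)
  lab <- rep(c(0, 1), each = 30)
  s <- rnorm(60) + lab
  d0 <- delong_compare(s, s, lab, positive = 1)
  expect_equal(d0$auc_a, d0$auc_b)
  expect_equal(d0$p, 1)

  # strictly increasing transform: identical AUCs, p = 1
  d1 <- delong_compare(s, exp(s), lab, positive = 1)
  expect_equal(d1$auc_a, d1$auc_b)
  expect_equal(d1$p, 1)

  # cross-check z and p against pROC's paired DeLong on non-degenerate scores
  for (i in 1:5) {
    sa <- rnorm(60) + 0.8 * lab
    sb <- 0.5 * sa + rnorm(60, 0, 0.7)
    mine <- delong_compare(sa, sb, lab, positive = 1)
    ra <- pROC::roc(lab, sa, levels = c(0, 1), direction = "<", quiet = TRUE)
    rb <- pROC::roc(lab, sb, levels = c(0, 1), direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(abs(mine$z), abs(unname(ref$statistic)), tolerance = 1e-10)
  }
  expect_error(delong_compare(1:5, 1:4, c(0, 1, 0, 1, 0)), "paired")
})

test_that("report tables carry the expected structure and scaling", {
  co <- generate_cohort(8, 6, 6, voxels_per_lesion = 6, snr = 50, seed = 51)
  g <- group_comparison_table(co)
  expect_equal(nrow(g), 12)
  expect_true(all(c("malignant_mean", "benign_mean", "normal_mean",
                    "chi2", "p_kw") %in% names(g)))
  # ADC display scaling: x 10^3 relative to the stored mm2/s values
  expect_equal(g$malignant_mean[g$parameter == "ADC"],
               1e3 * mean(co$ADC[co$class == "malignant"]))

  rt <- roc_table(co)
  expect_equal(nrow(rt), 36)  # 3 contrasts x 12 parameters
  expect_true(all(rt$auc >= 0.5 & rt$auc <= 1))
  expect_true(all(rt$direction %in% c(">", "<=")))

  ev <- suppressWarnings(evaluate_models(co, folds = 3, seed = 3))
  expect_equal(names(ev$models), c("ADC", "IVIM", "RSI", "IVIM+RSI"))
  expect_equal(nrow(ev$delong), 6)
  expect_true(all(ev$delong$p >= 0 & ev$delong$p <= 1))
})
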