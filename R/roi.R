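## ROI summarization and inter-observer agreement.

#' ROI mean of a parameter map
#'
#' Arithmetic mean over in-mask voxels, excluding missing-value sentinels
#' (unfittable voxels).
#'
#' @param map 3-D numeric parameter map.
#' @param mask 3-D logical/0-1 array on the same grid.
#' @return Scalar mean.
#' @export
summarize_roi <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) stop("map and mask grids differ")
  vals <- map[as.logical(mask)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("unfittable ROI: no non-missing voxels inside the mask")
  mean(vals)
}

#' Segmentation overlap metrics
#'
#' Dice similarity coefficient, recall and precision between two binary
#' masks on the same grid. `mask_a` is the reference reader: recall is the
#' fraction of the reference captured (|A ∩ B| / |A|) and precision the
#' fraction of the comparison mask that is correct (|A ∩ B| / |B|).
#'
#' @param mask_a Reference reader's mask (logical/0-1 array).
#' @param mask_b Second reader's mask, same grid.
#' @return Named list `dsc`, `recall`, `precision`, each in [0, 1].
#' @export
overlap_metrics <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask grids differ")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  na <- sum(a); nb <- sum(b); nab <- sum(a & b)
  if (na + nb == 0L) stop("undefined overlap: both masks are empty")
  list(dsc = 2 * nab / (na + nb),
       recall = if (na > 0) nab / na else NA_real_,
       precision = if (nb > 0) nab / nb else NA_real_)
}

#' Agreement band for an intraclass correlation coefficient
#'
#' Cut-points: 0.81-1.00 excellent, 0.61-0.80 good, 0.41-0.60 moderate,
#' 0.21-0.40 fair, 0.01-0.20 slight; at or below 0 "none".
#'
#' @param icc ICC value.
#' @return Character band label.
#' @export
icc_band <- function(icc) {
  if (icc > 0.80) "excellent"
  else if (icc > 0.60) "good"
  else if (icc > 0.40) "moderate"
  else if (icc > 0.20) "fair"
  else if (icc > 0) "slight"
  else "none"
}

#' Inter-observer agreement (intraclass correlation)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC — ICC(A,1)
#' in the McGraw & Wong taxonomy, the standard choice for two interchangeable
#' raters — with its 95% confidence interval and an F-test p-value against
#' ICC = 0. The agreement band uses [icc_band()].
#'
#' @param values_a,values_b Paired per-lesion measurements from the two
#'   readers, length >= 5.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return Named list `icc`, `ci_low`, `ci_high`, `p`, `band`, `n`.
#' @export
icc_agreement <- function(values_a, values_b, conf_level = 0.95) {
  if (length(values_a) != length(values_b)) stop("readers must be paired")
  ok <- stats::complete.cases(values_a, values_b)
  x <- cbind(values_a[ok], values_b[ok])
  n <- nrow(x); k <- 2
  if (n < 5) stop("at least 5 paired lesions required")
  if (stats::var(x[, 1]) == 0 && stats::var(x[, 2]) == 0)
    stop("undefined ICC: zero variance in both readers")

  # Two-way ANOVA mean squares (subjects x raters, one observation per cell)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  # McGraw & Wong (1996) interval for ICC(A,1)
  alpha <- 1 - conf_level
  Fj <- MSC / MSE
  vn <- (k - 1) * (n - 1) *
    (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * Fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)

  Fvalue <- MSR / MSE
  p <- stats::pf(Fvalue, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  list(icc = icc, ci_low = lower, ci_high = upper, p = p,
       band = icc_band(icc), n = n)
}

#' Inter-observer agreement report over a parameter table
#'
#' Runs [icc_agreement()] per parameter column shared by two readers'
#' lesion tables, producing a table of ICCs, confidence intervals, p-values
#' and agreement bands.
#'
#' @param table_a,table_b Lesion tables (data.frames) with identical
#'   parameter columns, rows paired by position.
#' @param params Parameter columns to assess; defaults to the 12 diffusion
#'   parameters present in both tables.
#' @return `data.frame` with one row per parameter.
#' @export
agreement_report <- function(table_a, table_b, params = NULL) {
  all_p <- c("ADC", "Dt", "Dp", "f", model_parameters("rsi"))
  if (is.null(params))
    params <- intersect(all_p, intersect(names(table_a), names(table_b)))
  if (length(params) == 0L) stop("no shared parameter columns")
  rows <- lapply(params, function(p) {
    a <- icc_agreement(table_a[[p]], table_b[[p]])
    data.frame(parameter = p, icc = a$icc, ci_low = a$ci_low,
               ci_high = a$ci_high, p_value = a$p, band = a$band)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
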