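## Voxel-wise inverse problems for the three diffusion models.
##
## Conventions: diffusivities in mm2/s throughout; IVIM is fitted on the
## normalized signal S(b)/S(0) over b <= 1000 (the b-list attached to the
## bi-exponential model), RSI on the raw signal over the full scheme.

# Box constraints of the IVIM fit, mm2/s for dt/dp, dimensionless for f.
IVIM_BOUNDS <- list(
  lower = c(dt = 1e-5, dp = 1e-3, f = 0),
  upper = c(dt = 3e-3, dp = 0.5, f = 1)
)

new_fit_result <- function(params, residual_norm, converged, n_iter,
                           flags = character()) {
  structure(
    list(params = params, residual_norm = residual_norm,
         converged = converged, n_iter = n_iter, flags = flags),
    class = "dwi_fit"
  )
}

#' @export
print.dwi_fit <- function(x, ...) {
  cat("DWI model fit\n  parameters:\n")
  print(signif(x$params, 6))
  cat("  residual norm:", format(x$residual_norm), "\n")
  cat("  converged:", x$converged, " iterations:", x$n_iter, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

signal_at_b <- function(signal, scheme, b) {
  i <- match(b, scheme$values)
  if (is.na(i)) stop("b = ", b, " s/mm2 not present in the scheme")
  signal[i]
}

#' Mono-exponential ADC fit (two-point inversion)
#'
#' The apparent diffusion coefficient is the exact solution of the
#' mono-exponential model on the two-point subset (b = 0, b = 750):
#' ADC = ln(S0 / S750) / 750. With two observations this coincides with the
#' linear least-squares fit of log signal on b. A negative estimate
#' (S750 > S0, possible under noise) is clipped to 0 and flagged.
#'
#' @param signal Numeric vector of signal intensities, one per scheme b-value.
#' @param scheme A [b_scheme()].
#' @return A `dwi_fit` with `params["ADC"]` in mm2/s.
#' @export
fit_mono_adc <- function(signal, scheme = b_scheme()) {
  if (length(signal) != length(scheme$values))
    stop("signal length does not match the b-value scheme")
  if (is.null(scheme$mono_subset))
    stop("scheme lacks b = 750; mono-exponential ADC undefined")
  s0 <- signal_at_b(signal, scheme, 0)
  sb <- signal_at_b(signal, scheme, 750)
  if (is.na(s0) || s0 <= 0) stop("unfittable voxel: S(0) must be positive")
  if (is.na(sb) || sb <= 0) stop("unfittable voxel: S(750) must be positive")
  adc <- log(s0 / sb) / 750
  flags <- character()
  if (adc < 0) {
    adc <- 0
    flags <- "clipped_negative_adc"
  }
  resid <- sb - mono_signal(adc, 750, s0)
  new_fit_result(c(ADC = adc), residual_norm = sqrt(sum(resid^2)),
                 converged = TRUE, n_iter = 1L, flags = flags)
}

ivim_start <- function(b, y) {
  # Segmented initialization: the perfusion term is negligible at b >= 250,
  # so a log-linear fit there gives dt and, by extrapolation to b = 0, the
  # tissue-only amplitude A; f0 = 1 - A.
  hi <- b >= 250 & y > 0
  if (sum(hi) >= 2) {
    co <- stats::coef(stats::lm(log(y[hi]) ~ b[hi]))
    dt0 <- min(max(-co[[2]], IVIM_BOUNDS$lower[["dt"]]), IVIM_BOUNDS$upper[["dt"]])
    f0 <- min(max(1 - exp(co[[1]]), 0.01), 0.6)
  } else {
    dt0 <- 1e-3
    f0 <- 0.1
  }
  c(dt = dt0, dp = 0.02, f = f0)
}

ivim_lm <- function(b, y, start, control) {
  fn <- function(p) ivim_signal(p[1], p[2], p[3], b) - y
  minpack.lm::nls.lm(par = start, lower = IVIM_BOUNDS$lower,
                     upper = IVIM_BOUNDS$upper, fn = fn, control = control)
}

#' IVIM bi-exponential fit
#'
#' Joint bounded Levenberg-Marquardt minimization of the squared residuals of
#' the bi-exponential model on the normalized signal S(b)/S(0), restricted to
#' the IVIM b-subset (b <= 1000). Bounds: dt in [1e-5, 3e-3] mm2/s, dp in
#' [1e-3, 0.5] mm2/s, f in [0, 1]. The fit is initialized by a segmented
#' scheme (log-linear fit over b >= 250) and refined jointly; a small set of
#' alternative pseudo-diffusion starts guards against the ill-conditioned
#' joint landscape, keeping the best (lowest residual) solution.
#'
#' @param signal Numeric vector of signal intensities, one per scheme b-value.
#' @param scheme A [b_scheme()].
#' @return A `dwi_fit` with `params` = (Dt, Dp, f). Flags: `at_bound` when a
#'   parameter sits on a box constraint, `dp_unidentifiable` when the fitted
#'   perfusion fraction is below 0.01 (the pseudo-diffusion term then carries
#'   essentially no signal), `not_converged` on iteration exhaustion.
#' @export
fit_ivim <- function(signal, scheme = b_scheme()) {
  if (length(signal) != length(scheme$values))
    stop("signal length does not match the b-value scheme")
  sub <- scheme$values %in% scheme$ivim_subset
  b <- scheme$values[sub]
  s <- signal[sub]
  s0 <- s[b == 0][1]
  if (is.na(s0) || s0 <= 0) stop("unfittable voxel: S(0) must be positive")
  ok <- !is.na(s) & s >= 0
  if (sum(ok) < 4) stop("unfittable voxel: fewer than 4 usable b-values")
  b <- b[ok]; y <- s[ok] / s0

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  starts <- list(ivim_start(b, y))
  for (dp0 in c(5e-3, 0.1)) {
    alt <- starts[[1]]; alt[["dp"]] <- dp0; starts <- c(starts, list(alt))
  }
  best <- NULL
  for (st in starts) {
    fit <- ivim_lm(b, y, st, ctrl)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  p <- stats::setNames(pmin(pmax(best$par, IVIM_BOUNDS$lower), IVIM_BOUNDS$upper),
                       c("Dt", "Dp", "f"))
  flags <- character()
  tol_b <- 1e-10
  at_low <- abs(p - c(IVIM_BOUNDS$lower)) < tol_b
  at_up <- abs(p - c(IVIM_BOUNDS$upper)) < tol_b
  if (any(at_low | at_up)) flags <- c(flags, "at_bound")
  if (p[["f"]] < 0.01) flags <- c(flags, "dp_unidentifiable")
  converged <- best$info %in% 1:4
  if (!converged) flags <- c(flags, "not_converged")
  new_fit_result(p, residual_norm = sqrt(best$deviance),
                 converged = converged, n_iter = best$niter, flags = flags)
}

#' RSI three-compartment fit
#'
#' Estimates the non-negative compartment contributions (C1, C2, C3) of the
#' fixed-diffusivity three-exponential model by bounded Levenberg-Marquardt
#' on the raw signal over the full b-value scheme. Because the three
#' diffusivities are fixed the problem is linear in the contributions, and
#' the bounded solution coincides with non-negative linear least squares;
#' fractions (F1, F2, F3, summing to 1) and the composite products C1*C2 and
#' F1*F2 are derived via [contributions_to_fractions()].
#'
#' @param signal Numeric vector of signal intensities, one per scheme b-value.
#' @param scheme A [b_scheme()].
#' @return A `dwi_fit` with `params` = (C1, C2, C3, C1C2, F1, F2, F3, F1F2).
#' @export
fit_rsi <- function(signal, scheme = b_scheme()) {
  if (length(signal) != length(scheme$values))
    stop("signal length does not match the b-value scheme")
  b <- scheme$rsi_subset
  s <- signal[match(b, scheme$values)]
  ok <- !is.na(s) & s >= 0
  if (sum(ok) < 3) stop("unfittable voxel: fewer than 3 usable b-values")
  b <- b[ok]; y <- s[ok]
  if (all(y == 0)) stop("unfittable voxel: all-zero signal")

  X <- cbind(1, exp(-b * RSI_ADCS[[2]]), exp(-b * RSI_ADCS[[3]]))
  start <- pmax(qr.solve(crossprod(X), crossprod(X, y))[, 1], 1e-8)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  fit <- minpack.lm::nls.lm(par = start, lower = rep(0, 3),
                            fn = function(p) X %*% p - y, control = ctrl)
  cc <- pmax(fit$par, 0)
  # Active-set refinement: the projected LM iterate can stall marginally
  # short of the constrained optimum when a contribution sits on the zero
  # bound. With 3 unknowns the exact non-negative optimum is the
  # best feasible unconstrained solution over the 7 possible supports.
  best_rss <- sum((X %*% cc - y)^2)
  for (support in list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), 1:3)) {
    Xs <- X[, support, drop = FALSE]
    cs <- tryCatch(qr.solve(crossprod(Xs), crossprod(Xs, y))[, 1],
                   error = function(e) NULL)
    if (is.null(cs) || any(cs < 0)) next
    cand <- numeric(3); cand[support] <- cs
    rss <- sum((X %*% cand - y)^2)
    if (rss < best_rss) { cc <- cand; best_rss <- rss }
  }
  fr <- contributions_to_fractions(cc[1], cc[2], cc[3])
  p <- c(C1 = cc[1], C2 = cc[2], C3 = cc[3], C1C2 = fr$c1c2,
         F1 = fr$f1, F2 = fr$f2, F3 = fr$f3, F1F2 = fr$f1f2)
  converged <- fit$info %in% 1:4
  new_fit_result(p, residual_norm = sqrt(best_rss), converged = converged,
                 n_iter = fit$niter,
                 flags = if (converged) character() else "not_converged")
}

#' Names of the parameter maps produced per model
#' @param model One of "mono", "ivim", "rsi".
#' @return Character vector of parameter names.
#' @export
model_parameters <- function(model = c("mono", "ivim", "rsi")) {
  switch(match.arg(model),
         mono = "ADC",
         ivim = c("Dt", "Dp", "f"),
         rsi = c("C1", "C2", "C3", "C1C2", "F1", "F2", "F3", "F1F2"))
}

#' Voxel-wise model fitting over a 4-D DWI volume
#'
#' Applies one of the three voxel fits to every (masked) voxel of a 4-D
#' volume whose fourth dimension indexes the b-values of `scheme`. Voxels
#' outside the mask, with non-positive baseline signal, or whose fit errors
#' carry the missing-value sentinel `NA` (NaN semantics: excluded from ROI
#' statistics downstream).
#'
#' @param volume 4-D numeric array (x, y, z, b).
#' @param scheme A [b_scheme()] matching the fourth dimension.
#' @param model One of "mono", "ivim", "rsi".
#' @param mask Optional 3-D logical/0-1 array on the same grid.
#' @return Named list of 3-D parameter maps (one per parameter of the model),
#'   plus an attribute `fit_log` counting fitted/flagged/failed voxels.
#' @export
fit_volume <- function(volume, scheme = b_scheme(),
                       model = c("mono", "ivim", "rsi"), mask = NULL) {
  model <- match.arg(model)
  dims <- dim(volume)
  if (length(dims) != 4L) stop("volume must be a 4-D array (x, y, z, b)")
  if (dims[4] != length(scheme$values))
    stop("4th dimension (", dims[4], ") does not match the scheme (",
         length(scheme$values), " b-values)")
  grid <- dims[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, grid)
  } else {
    if (!identical(dim(mask), grid)) stop("mask grid does not match the volume")
    mask <- array(as.logical(mask), grid)
  }
  pnames <- model_parameters(model)
  maps <- lapply(pnames, function(p) array(NA_real_, grid))
  names(maps) <- pnames
  fitfun <- switch(model, mono = fit_mono_adc, ivim = fit_ivim, rsi = fit_rsi)

  vox <- which(mask)
  n_fit <- 0L; n_flag <- 0L; n_fail <- 0L
  nvol <- prod(grid)
  for (i in vox) {
    sig <- volume[i + (seq_len(dims[4]) - 1L) * nvol]
    res <- tryCatch(fitfun(sig, scheme), error = function(e) NULL)
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      next
    }
    for (p in pnames) maps[[p]][i] <- res$params[[p]]
    n_fit <- n_fit + 1L
    if (length(res$flags)) n_flag <- n_flag + 1L
  }
  attr(maps, "fit_log") <- list(model = model, n_voxels = length(vox),
                                n_fitted = n_fit, n_flagged = n_flag,
                                n_failed = n_fail)
  maps
}
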