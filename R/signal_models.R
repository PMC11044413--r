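#' Fixed compartment diffusivities of the three-compartment RSI model
#'
#' The restricted (intracellular), hindered (extracellular/fibroglandular) and
#' free-water compartments have diffusivities fixed at 0, 1.4e-3 and
#' 10.2e-3 mm2/s respectively; only the compartment amplitudes are estimated.
#'
#' @format Numeric vector of length 3, mm2/s.
#' @export
RSI_ADCS <- c(restricted = 0, hindered = 1.4e-3, free = 10.2e-3)

#' Mono-exponential diffusion signal
#'
#' S(b) = s0 * exp(-b * adc). All diffusivities are in mm2/s (not the
#' x 10^-3 display convention); b in s/mm2.
#'
#' @param adc Apparent diffusion coefficient, mm2/s, >= 0.
#' @param b b-value(s), s/mm2, >= 0. Vectorized.
#' @param s0 Baseline (b = 0) signal, > 0.
#' @return Signal intensity at each `b`.
#' @examples
#' mono_signal(1e-3, b = 750)           # exp(-0.75)
#' @export
mono_signal <- function(adc, b, s0 = 1) {
  if (any(s0 <= 0)) stop("s0 must be positive")
  if (any(b < 0)) stop("b-values must be non-negative")
  if (any(adc < 0)) stop("adc must be non-negative")
  s0 * exp(-b * adc)
}

#' IVIM bi-exponential diffusion signal
#'
#' S(b) = s0 * ((1 - f) * exp(-b * dt) + f * exp(-b * (dt + dp))): slow
#' tissue diffusion `dt` plus capillary pseudo-diffusion `dt + dp` weighted by
#' the perfusion fraction `f`.
#'
#' @param dt True (tissue) diffusion coefficient, mm2/s, >= 0.
#' @param dp Pseudo-diffusion coefficient, mm2/s, >= 0.
#' @param f Perfusion fraction in [0, 1].
#' @param b b-value(s), s/mm2. Vectorized.
#' @param s0 Baseline signal, > 0.
#' @return Signal intensity at each `b`; equals `s0` exactly at b = 0.
#' @export
ivim_signal <- function(dt, dp, f, b, s0 = 1) {
  if (any(s0 <= 0)) stop("s0 must be positive")
  if (any(b < 0)) stop("b-values must be non-negative")
  if (any(dt < 0) || any(dp < 0)) stop("dt and dp must be non-negative")
  if (any(f < 0 | f > 1)) stop("perfusion fraction f must lie in [0, 1]")
  s0 * ((1 - f) * exp(-b * dt) + f * exp(-b * (dt + dp)))
}

#' RSI three-compartment diffusion signal
#'
#' S(b) = c1 + c2 * exp(-b * 1.4e-3) + c3 * exp(-b * 10.2e-3). The restricted
#' compartment has zero diffusivity, so its term is constant in b (exp(0) = 1
#' written explicitly; no 0 * Inf edge case). At b = 0 the signal equals
#' c1 + c2 + c3.
#'
#' @param c1,c2,c3 Non-negative compartment signal contributions
#'   (restricted, hindered, free), arbitrary signal units.
#' @param b b-value(s), s/mm2. Vectorized.
#' @return Signal intensity at each `b`.
#' @export
rsi_signal <- function(c1, c2, c3, b) {
  if (any(b < 0)) stop("b-values must be non-negative")
  if (any(c(c1, c2, c3) < 0)) stop("compartment contributions must be non-negative")
  c1 * 1 + c2 * exp(-b * RSI_ADCS[[2]]) + c3 * exp(-b * RSI_ADCS[[3]])
}

#' Signal fractions from compartment contributions
#'
#' Normalizes the three compartment contributions by the b = 0 signal and
#' renormalizes so that F1 + F2 + F3 = 1 exactly; also forms the composite
#' products C1*C2 and F1*F2 used as additional diagnostic markers.
#'
#' @param c1,c2,c3 Non-negative contributions.
#' @param s0 Baseline signal used for normalization, > 0. Defaults to
#'   c1 + c2 + c3 (the model value at b = 0), in which case renormalization
#'   is the identity.
#' @return Named list with `f1`, `f2`, `f3` (summing to 1), `c1c2` and `f1f2`.
#' @examples
#' contributions_to_fractions(1, 1, 2, s0 = 4)  # fractions 0.25, 0.25, 0.5
#' @export
contributions_to_fractions <- function(c1, c2, c3, s0 = c1 + c2 + c3) {
  if (any(c(c1, c2, c3) < 0)) stop("compartment contributions must be non-negative")
  if (s0 <= 0) stop("s0 must be positive")
  f <- c(c1, c2, c3) / s0
  tot <- sum(f)
  if (tot <= 0) stop("all contributions are zero; fractions undefined")
  f <- f / tot
  list(f1 = f[1], f2 = f[2], f3 = f[3], c1c2 = c1 * c2, f1f2 = f[1] * f[2])
}
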