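#' Diffusion-weighting (b-value) scheme
#'
#' Constructs the ordered set of b-values of a multi-b-value DWI acquisition
#' together with the per-model subsets used downstream: the mono-exponential
#' ADC uses only (0, 750), the IVIM bi-exponential uses b <= 1000, and the
#' RSI three-compartment decomposition uses all b-values.
#'
#' @param values Numeric vector of b-values in s/mm2, strictly increasing,
#'   starting at 0. Default is the nine-point breast protocol
#'   0, 50, 100, 250, 500, 750, 1000, 1500, 2000.
#' @return An object of class `b_scheme` with elements `values`,
#'   `mono_subset`, `ivim_subset` and `rsi_subset`.
#' @examples
#' sch <- b_scheme()
#' sch$ivim_subset
#' @export
b_scheme <- function(values = c(0, 50, 100, 250, 500, 750, 1000, 1500, 2000)) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("b-value scheme needs at least two b-values")
  if (values[1] != 0) stop("first b-value must be 0")
  if (any(diff(values) <= 0)) stop("b-values must be strictly increasing")
  mono <- c(0, 750)
  if (!all(mono %in% values)) mono <- NULL  # mono-ADC unavailable without b=750
  structure(
    list(
      values = values,
      mono_subset = mono,
      ivim_subset = values[values <= 1000],
      rsi_subset = values
    ),
    class = "b_scheme"
  )
}

#' @export
print.b_scheme <- function(x, ...) {
  cat("b-value scheme (s/mm2):", paste(x$values, collapse = ", "), "\n")
  cat("  mono subset:", paste(x$mono_subset, collapse = ", "), "\n")
  cat("  IVIM subset:", paste(x$ivim_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Read a b-value sidecar file
#'
#' Accepts FSL-style `.bval` files: either one whitespace-separated row or
#' one value per line.
#'
#' @param path Path to the text file.
#' @return Numeric vector of b-values.
#' @export
read_bvals <- function(path) {
  if (!file.exists(path)) stop("b-value file not found: ", path)
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) == 0L) stop("no b-values in ", path)
  vals
}
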