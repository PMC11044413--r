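## Synthetic phantoms and cohorts.
##
## The generative parameter set per tissue class is (Dt, Dp, f, C1, C2, C3):
## the IVIM triple shapes the decay and the RSI contributions set the b = 0
## amplitude (S0 = C1 + C2 + C3). A voxel's noiseless signal is the IVIM
## forward model scaled by that amplitude; ADC, the fitted RSI decomposition,
## fractions and products are emergent from fitting, never drawn directly.

# Truncation box for the generative draws: the IVIM triple uses the fitting
# bounds; contributions are positive with a small floor.
GEN_BOUNDS <- list(
  lower = c(Dt = 1e-5, Dp = 1e-3, f = 0, C1 = 1e-3, C2 = 1e-3, C3 = 1e-3),
  upper = c(Dt = 3e-3, Dp = 0.5, f = 1, C1 = Inf, C2 = Inf, C3 = Inf)
)

GEN_PARAMS <- names(GEN_BOUNDS$lower)

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }
  force(code)
}

#' Tissue class specification
#'
#' Per-class mean and SD of the generative parameters (Dt, Dp, f in model
#' units mm2/s; C1, C2, C3 in signal units). Lesion-level parameters are
#' drawn from Gaussians with these moments truncated to the fitting bounds.
#'
#' @param name Class label, one of "malignant", "benign", "normal".
#' @param means,sds Named numeric vectors over Dt, Dp, f, C1, C2, C3.
#' @return An object of class `tissue_class_spec`.
#' @export
tissue_class_spec <- function(name, means, sds) {
  name <- match.arg(name, c("malignant", "benign", "normal"))
  means <- means[GEN_PARAMS]; sds <- sds[GEN_PARAMS]
  if (anyNA(means) || anyNA(sds)) stop("means/sds must name all of: ",
                                       paste(GEN_PARAMS, collapse = ", "))
  if (any(sds <= 0)) stop("all SDs must be positive")
  if (any(means < GEN_BOUNDS$lower | means > GEN_BOUNDS$upper))
    stop("class means must lie inside the fitting bounds")
  structure(list(name = name, means = means, sds = sds),
            class = "tissue_class_spec")
}

#' Default tissue class specifications
#'
#' Published group-level moments (mean, SD) for malignant lesions, benign
#' lesions and normal fibroglandular tissue: IVIM Dt, Dp, f and the RSI
#' contributions C1 (restricted), C2 (hindered), C3 (free water). Dt is
#' stored in mm2/s (0.662e-3, not the 0.662 x 10^-3 display convention).
#' The benign C2 SD is taken as 1.000 (its printed source is ambiguous
#' between 1.000 and 1.0008).
#'
#' @return Named list of three [tissue_class_spec()] objects.
#' @export
default_tissue_specs <- function() {
  list(
    malignant = tissue_class_spec(
      "malignant",
      means = c(Dt = 0.662e-3, Dp = 0.022, f = 0.235,
                C1 = 0.540, C2 = 1.826, C3 = 0.161),
      sds = c(Dt = 0.106e-3, Dp = 0.006, f = 0.036,
              C1 = 0.250, C2 = 0.778, C3 = 0.159)),
    benign = tissue_class_spec(
      "benign",
      means = c(Dt = 0.940e-3, Dp = 0.019, f = 0.256,
                C1 = 0.233, C2 = 1.972, C3 = 0.329),
      sds = c(Dt = 0.304e-3, Dp = 0.007, f = 0.059,
              C1 = 0.195, C2 = 1.000, C3 = 0.345)),
    normal = tissue_class_spec(
      "normal",
      means = c(Dt = 0.868e-3, Dp = 0.025, f = 0.213,
                C1 = 0.119, C2 = 0.894, C3 = 0.215),
      sds = c(Dt = 0.420e-3, Dp = 0.007, f = 0.048,
              C1 = 0.102, C2 = 0.444, C3 = 0.110))
  )
}

# Truncated-Gaussian draw by rejection (the documented generative law).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out
}

draw_class_params <- function(spec, n = 1L) {
  draws <- vapply(GEN_PARAMS, function(p) {
    rtrunc_norm(n, spec$means[[p]], spec$sds[[p]],
                GEN_BOUNDS$lower[[p]], GEN_BOUNDS$upper[[p]])
  }, numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, GEN_PARAMS))
  draws
}

# Noiseless voxel signal of the generative law: IVIM decay scaled so the
# three-compartment decomposition holds at b = 0 (S0 = C1 + C2 + C3).
generative_signal <- function(params, b) {
  s0 <- params[["C1"]] + params[["C2"]] + params[["C3"]]
  ivim_signal(params[["Dt"]], params[["Dp"]], params[["f"]], b, s0 = s0)
}

#' Add Rician noise to a signal
#'
#' Magnitude-MRI noise: sqrt((S + n1)^2 + n2^2) with n1, n2 independent
#' zero-mean Gaussians of SD s0/snr. An infinite SNR returns the input
#' unchanged. A zero signal yields Rayleigh-distributed magnitudes with mean
#' sd * sqrt(pi/2).
#'
#' @param signal Numeric vector (or matrix) of noiseless signal values.
#' @param snr Ratio of the baseline (b = 0) signal to the noise SD, > 0.
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @param s0 Baseline signal defining the noise SD; defaults to the first
#'   element of `signal` (the b = 0 entry in scheme order).
#' @return Noisy signal, same shape as the input.
#' @export
add_rician_noise <- function(signal, snr, seed = NULL, s0 = signal[1]) {
  if (snr <= 0) stop("snr must be positive")
  if (is.infinite(snr)) return(signal)
  sd <- s0 / snr
  with_seed(seed, {
    n1 <- stats::rnorm(length(signal), 0, sd)
    n2 <- stats::rnorm(length(signal), 0, sd)
    out <- sqrt((signal + n1)^2 + n2^2)
    attributes(out) <- attributes(signal)
    out
  })
}

#' Phantom configuration
#'
#' @param grid Integer vector of 3 voxel counts.
#' @param lesions List of lesions, each `list(center = c(x, y, z),
#'   radius = r, class = "malignant")`; radius in voxels, >= 2.
#' @param background Background tissue class (default "normal").
#' @param snr Baseline-signal-to-noise ratio; `Inf` for a noiseless phantom.
#' @param seed Integer seed for the noise draw.
#' @param scheme A [b_scheme()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(24, 24, 12), lesions = list(),
                           background = "normal", snr = 50, seed = 1L,
                           scheme = b_scheme()) {
  if (length(grid) != 3L || any(grid < 1)) stop("grid must be 3 positive extents")
  if (snr <= 0) stop("snr must be positive")
  background <- match.arg(background, c("malignant", "benign", "normal"))
  for (les in lesions) {
    if (les$radius < 2) stop("lesion radius must be at least 2 voxels")
    if (any(les$center - les$radius < 1) || any(les$center + les$radius > grid))
      stop("lesion does not fit inside the grid")
    match.arg(les$class, c("malignant", "benign", "normal"))
  }
  if (length(lesions) > 1) {
    for (i in seq_along(lesions)[-1]) for (j in seq_len(i - 1)) {
      d <- sqrt(sum((lesions[[i]]$center - lesions[[j]]$center)^2))
      if (d <= lesions[[i]]$radius + lesions[[j]]$radius)
        stop("lesions ", j, " and ", i, " overlap")
    }
  }
  structure(list(grid = grid, lesions = lesions, background = background,
                 snr = snr, seed = as.integer(seed), scheme = scheme),
            class = "phantom_config")
}

sphere_mask <- function(grid, center, radius) {
  ix <- seq_len(grid[1]); iy <- seq_len(grid[2]); iz <- seq_len(grid[3])
  dx2 <- (ix - center[1])^2
  dy2 <- (iy - center[2])^2
  dz2 <- (iz - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

#' Generate a digital DWI phantom
#'
#' Builds a 4-D multi-b-value volume on a voxel grid: spherical lesions of
#' the configured classes on a uniform background, every voxel carrying its
#' class's mean generative parameters (so noiseless region means are exact
#' class values), corrupted by seeded Rician noise.
#'
#' @param config A [phantom_config()].
#' @param specs Tissue class specifications, default [default_tissue_specs()].
#' @return List with `volume` (4-D array), `truth` (3-D maps of Dt, Dp, f,
#'   S0), `masks` (one logical array per lesion), `class_map` (character
#'   array) and the `config`.
#' @export
generate_phantom <- function(config, specs = default_tissue_specs()) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  b <- config$scheme$values
  class_map <- array(config$background, grid)
  masks <- list()
  for (k in seq_along(config$lesions)) {
    les <- config$lesions[[k]]
    m <- sphere_mask(grid, les$center, les$radius)
    class_map[m] <- les$class
    masks[[k]] <- m
  }
  truth <- list(Dt = array(NA_real_, grid), Dp = array(NA_real_, grid),
                f = array(NA_real_, grid), S0 = array(NA_real_, grid))
  nvox <- prod(grid)
  volume <- array(NA_real_, c(grid, length(b)))
  for (cls in unique(as.vector(class_map))) {
    mu <- specs[[cls]]$means
    sig <- generative_signal(mu, b)
    sel <- class_map == cls
    truth$Dt[sel] <- mu[["Dt"]]; truth$Dp[sel] <- mu[["Dp"]]
    truth$f[sel] <- mu[["f"]]
    truth$S0[sel] <- mu[["C1"]] + mu[["C2"]] + mu[["C3"]]
    for (j in seq_along(b)) {
      plane <- volume[, , , j, drop = FALSE]
      plane[sel] <- sig[j]
      volume[, , , j] <- plane
    }
  }
  if (is.finite(config$snr)) {
    volume <- with_seed(config$seed, {
      sd <- truth$S0 / config$snr            # per-voxel noise scale
      noisy <- volume
      for (j in seq_along(b)) {
        n1 <- array(stats::rnorm(nvox, 0, sd), grid)
        n2 <- array(stats::rnorm(nvox, 0, sd), grid)
        noisy[, , , j] <- sqrt((volume[, , , j] + n1)^2 + n2^2)
      }
      noisy
    })
  }
  list(volume = volume, truth = truth, masks = masks,
       class_map = class_map, config = config)
}

# Fit all three models on a matrix of voxel signals (rows = voxels) and
# return the per-voxel 12-parameter matrix.
fit_voxel_matrix <- function(signals, scheme) {
  pn <- c("ADC", "Dt", "Dp", "f", model_parameters("rsi"))
  out <- matrix(NA_real_, nrow(signals), length(pn),
                dimnames = list(NULL, pn))
  for (v in seq_len(nrow(signals))) {
    sig <- signals[v, ]
    out[v, "ADC"] <- tryCatch(fit_mono_adc(sig, scheme)$params[["ADC"]],
                              error = function(e) NA_real_)
    iv <- tryCatch(fit_ivim(sig, scheme)$params, error = function(e) NULL)
    if (!is.null(iv)) out[v, c("Dt", "Dp", "f")] <- iv
    rs <- tryCatch(fit_rsi(sig, scheme)$params, error = function(e) NULL)
    if (!is.null(rs)) out[v, names(rs)] <- rs
  }
  out
}

#' Generate a synthetic lesion cohort
#'
#' For each lesion: draws its true generative parameters from the class's
#' truncated Gaussians, applies per-voxel multiplicative heterogeneity,
#' simulates the voxel signals under Rician noise, fits all three diffusion
#' models per voxel, and records the ROI means of the twelve fitted
#' parameters (composite products are averaged per voxel, not recomposed
#' from ROI means). Deterministic given `seed`.
#'
#' @param n_malignant,n_benign,n_normal Lesion counts per class (default the
#'   study composition 116 / 41 / 41); 0 excludes a class, otherwise >= 2.
#' @param specs Class specifications, default [default_tissue_specs()].
#' @param voxels_per_lesion Voxels simulated and fitted per lesion.
#' @param snr Baseline-signal-to-noise ratio (default 50, typical of breast
#'   DWI at b = 0); `Inf` for noiseless.
#' @param seed Integer seed.
#' @param scheme A [b_scheme()].
#' @param jitter SD of the per-voxel multiplicative parameter heterogeneity
#'   (default 0.05).
#' @return `data.frame` with columns `lesion_id`, `class` and the 12 fitted
#'   parameters; the drawn truth table is attached as attribute `truth`.
#' @export
generate_cohort <- function(n_malignant = 116, n_benign = 41, n_normal = 41,
                            specs = default_tissue_specs(),
                            voxels_per_lesion = 64, snr = 50, seed = 1L,
                            scheme = b_scheme(), jitter = 0.05) {
  counts <- c(malignant = n_malignant, benign = n_benign, normal = n_normal)
  if (any(counts < 0) || any(counts == 1))
    stop("class counts must be 0 (excluded) or at least 2")
  if (sum(counts > 0) < 1) stop("at least one class must be included")
  b <- scheme$values
  with_seed(seed, {
    rows <- list(); truths <- list(); id <- 0L
    for (cls in names(counts)) {
      if (counts[[cls]] == 0) next
      for (l in seq_len(counts[[cls]])) {
        id <- id + 1L
        tru <- draw_class_params(specs[[cls]])[1, ]
        vox <- matrix(rep(tru, each = voxels_per_lesion),
                      voxels_per_lesion, length(GEN_PARAMS),
                      dimnames = list(NULL, GEN_PARAMS))
        if (jitter > 0) {
          jit <- matrix(stats::rnorm(length(vox), 1, jitter), dim(vox)[1])
          vox <- vox * pmax(jit, 0.01)
          vox <- sweep(vox, 2, GEN_BOUNDS$lower[GEN_PARAMS], pmax)
          vox <- sweep(vox, 2, GEN_BOUNDS$upper[GEN_PARAMS], pmin)
        }
        signals <- t(apply(vox, 1, generative_signal, b = b))
        if (is.finite(snr)) {
          s0 <- signals[, 1]
          n1 <- matrix(stats::rnorm(length(signals), 0, s0 / snr), nrow(signals))
          n2 <- matrix(stats::rnorm(length(signals), 0, s0 / snr), nrow(signals))
          signals <- sqrt((signals + n1)^2 + n2^2)
        }
        fits <- fit_voxel_matrix(signals, scheme)
        rows[[id]] <- data.frame(lesion_id = id, class = cls,
                                 t(colMeans(fits, na.rm = TRUE)))
        truths[[id]] <- data.frame(lesion_id = id, class = cls, t(tru))
      }
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    truth <- do.call(rbind, truths)
    rownames(truth) <- NULL
    attr(cohort, "truth") <- truth
    attr(cohort, "seed") <- seed
    cohort
  })
}

#' Perturb an ROI mask at its boundary
#'
#' Emulates a second reader: every boundary voxel (an in-mask voxel
#' face-adjacent to background, or a background voxel face-adjacent to the
#' mask) is flipped independently with probability `prob`. Interior voxels
#' are never touched.
#'
#' @param mask 3-D logical array.
#' @param prob Flip probability in [0, 1].
#' @param seed Optional integer seed.
#' @return Perturbed logical mask of the same shape.
#' @export
perturb_mask <- function(mask, prob, seed = NULL) {
  if (prob < 0 || prob > 1) stop("prob must lie in [0, 1]")
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3-D array")
  m <- array(as.logical(mask), d)
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    rng <- seq_len(d[ax] - abs(by))
    if (by > 0) { idx_dst[[ax]] <- rng + by; idx_src[[ax]] <- rng }
    else { idx_dst[[ax]] <- rng; idx_src[[ax]] <- rng + abs(by) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  nb_any <- array(FALSE, d); nb_all <- array(TRUE, d)
  for (ax in 1:3) for (by in c(-1, 1)) {
    s <- shift(m, ax, by)
    nb_any <- nb_any | s
    # voxels at the array edge keep their own value for the "all" test
    edge <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    idx[[ax]] <- if (by > 0) 1L else d[ax]
    edge[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    s[edge] <- m[edge]
    nb_all <- nb_all & s
  }
  boundary <- (m & !nb_all) | (!m & nb_any)
  with_seed(seed, {
    flip <- boundary & array(stats::runif(length(m)) < prob, d)
    out <- xor(m, flip)
    array(out, d)
  })
}
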