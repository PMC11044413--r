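## Group comparison, ROC and diagnostic-model layer.
##
## Alpha conventions: 0.05 for the three-group omnibus test, 0.0167 for the
## pairwise two-group tests (Bonferroni-style guard over the three pairs).

PAIRWISE_ALPHA <- 0.0167

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction against a chi-square reference
#' with k - 1 degrees of freedom.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return Named list `chi2`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 observations")
  kt <- stats::kruskal.test(groups)
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The standardized statistic z is tie-corrected
#' and computed without continuity correction (the convention of printed
#' z-values); the p-value is obtained by exact enumeration of the U
#' distribution when n_a * n_b <= 400 and the data are tie-free, and from
#' the continuity-corrected normal approximation otherwise.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param alpha Significance level of the `significant` flag
#'   (default 0.0167, guarding the three pairwise comparisons).
#' @return Named list `u` (U of sample `a`), `z`, `p`, `significant`,
#'   `method` ("exact" or "normal").
#' @export
mann_whitney <- function(a, b, alpha = PAIRWISE_ALPHA) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 observations")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  if (!has_ties && n1 * n2 <= 400) {
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    zc <- if (sigma2 > 0) max(abs(u - mu) - 0.5, 0) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-zc))
    method <- "normal"
  }
  list(u = u, z = z, p = p, significant = p < alpha, method = method)
}

#' ROC analysis of a single parameter
#'
#' Empirical ROC over all observed thresholds; the AUC is the trapezoidal
#' area (equivalently the scaled Mann-Whitney U). The direction is chosen so
#' that AUC >= 0.5 and reported with its inequality convention: ">" when
#' larger values indicate the positive class, "<=" otherwise. The operating
#' threshold maximizes Youden's J = sensitivity + specificity - 1 (first
#' maximizer on ties).
#'
#' @param values Numeric marker values, one per lesion.
#' @param labels Class labels (any two-level vector).
#' @param positive The label of the positive class; defaults to the larger
#'   of the two sorted unique labels (e.g. 1 for 0/1, TRUE for logical).
#' @return Named list `auc`, `threshold`, `sensitivity`, `specificity`
#'   (percent), `direction`.
#' @export
roc_single_parameter <- function(values, labels, positive = NULL) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- lev[2]
  positive <- as.character(positive)
  if (!positive %in% lev) stop("positive class not present in labels")
  resp <- factor(ifelse(labels == positive, "pos", "neg"),
                 levels = c("neg", "pos"))
  roc_up <- pROC::roc(resp, values, levels = c("neg", "pos"),
                      direction = "<", quiet = TRUE)
  auc_up <- as.numeric(pROC::auc(roc_up))
  if (auc_up >= 0.5) {
    roc_use <- roc_up; auc <- auc_up; dir <- ">"
  } else {
    roc_use <- pROC::roc(resp, values, levels = c("neg", "pos"),
                         direction = ">", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc_use)); dir <- "<="
  }
  co <- pROC::coords(roc_use, x = "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[1, , drop = FALSE]
  list(auc = auc, threshold = co$threshold,
       sensitivity = 100 * co$sensitivity,
       specificity = 100 * co$specificity, direction = dir)
}

#' Standard diagnostic feature sets
#'
#' The four logistic diagnostic models: ADC alone, the IVIM triple
#' (Dt + Dp + f), the RSI set (C1 + C2 + C3 + C1C2 + F1 + F2 + F3 + F1F2)
#' and the hybrid IVIM + RSI union.
#'
#' @return Named list of character vectors of parameter names.
#' @export
feature_sets <- function() {
  ivim <- c("Dt", "Dp", "f")
  rsi <- model_parameters("rsi")
  list(ADC = "ADC", IVIM = ivim, RSI = rsi, `IVIM+RSI` = c(ivim, rsi))
}

stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validated logistic diagnostic model
#'
#' Fits a plain (unpenalized) maximum-likelihood logistic regression of the
#' lesion class on the selected parameters under stratified k-fold
#' cross-validation: per fold, features are standardized with training-split
#' statistics only, the model is fitted on the training split and scores the
#' held-out split. Reported are the per-fold AUCs, their arithmetic mean and
#' the pooled out-of-fold scores. Deterministic given `seed`.
#'
#' @param table Lesion table with a `class` column and parameter columns.
#' @param features Character vector of parameter columns to use.
#' @param contrast Length-2 character vector `(negative, positive)` class.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param name Optional model name for reports.
#' @return An object of class `model_eval`: `name`, `features`, `contrast`,
#'   `fold_aucs`, `mean_auc`, `scores` (lesion id, label, out-of-fold score,
#'   fold), `converged`, `seed`.
#' @export
fit_diagnostic_model <- function(table, features,
                                 contrast = c("benign", "malignant"),
                                 folds = 5, seed = 1L, name = NULL) {
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing parameter columns: ",
                         paste(miss, collapse = ", "))
  dat <- table[table$class %in% contrast, , drop = FALSE]
  y <- as.integer(dat$class == contrast[2])
  if (min(table(y)) < folds)
    stop("stratification error: each class needs at least ", folds,
         " lesions for ", folds, "-fold CV")
  fold <- stratified_folds(y, folds, seed)
  X <- as.matrix(dat[, features, drop = FALSE])
  scores <- numeric(nrow(dat))
  fold_aucs <- numeric(folds)
  converged <- TRUE
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    Ztr <- scale(X[tr, , drop = FALSE], mu, sd_)
    Zte <- scale(X[te, , drop = FALSE], mu, sd_)
    dtr <- data.frame(y = y[tr], Ztr)
    fit <- withCallingHandlers(
      stats::glm(y ~ ., family = stats::binomial(), data = dtr),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    scores[te] <- stats::predict(fit, newdata = data.frame(Zte),
                                 type = "link")
    r <- pROC::roc(y[te], scores[te], levels = c(0, 1), direction = "<",
                   quiet = TRUE)
    fold_aucs[k] <- as.numeric(pROC::auc(r))
  }
  if (!converged)
    warning("logistic fit did not fully converge in at least one fold ",
            "(possible separation); best-iterate scores reported")
  structure(
    list(name = if (is.null(name)) paste(features, collapse = "+") else name,
         features = features, contrast = contrast, fold_aucs = fold_aucs,
         mean_auc = mean(fold_aucs),
         scores = data.frame(lesion_id = dat$lesion_id, label = y,
                             score = scores, fold = fold),
         converged = converged, seed = seed),
    class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat("Diagnostic model:", x$name, " (", x$contrast[1], "vs",
      x$contrast[2], ")\n")
  cat("  fold AUCs:", paste(sprintf("%.3f", x$fold_aucs), collapse = ", "),
      "\n  mean AUC:", sprintf("%.3f", x$mean_auc), "\n")
  invisible(x)
}

#' DeLong comparison of two correlated AUCs
#'
#' Nonparametric comparison of two empirical AUCs computed from paired
#' scores on the same lesions, using the placement-value covariance
#' estimator and a two-sided normal test on the AUC difference. Higher
#' scores are taken to indicate the positive class for both score vectors.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels (0/1, logical, or two-level).
#' @param positive Positive-class label; default as in
#'   [roc_single_parameter()].
#' @return Named list `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores and labels must be paired (equal lengths)")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- lev[2]
  pos <- labels == as.character(positive)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present")
  placement <- function(s) {
    psi <- outer(s[pos], s[!pos],
                 function(x, y) (x > y) + 0.5 * (x == y))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  pa <- placement(scores_a); pb <- placement(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p)
}
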