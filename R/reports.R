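## Report tables mirroring the study's presentation conventions.

ALL_PARAMETERS <- c("ADC", "Dt", "Dp", "f",
                    "C1", "C2", "C3", "C1C2", "F1", "F2", "F3", "F1F2")

# ADC and Dt are stored in mm2/s but displayed in x 10^-3 mm2/s.
display_scale <- function(param) ifelse(param %in% c("ADC", "Dt"), 1e3, 1)

CLASS_ORDER <- c("malignant", "benign", "normal")

#' Group-comparison table of all diffusion parameters
#'
#' Per parameter: display-scaled mean and SD per class, the Kruskal-Wallis
#' omnibus statistic and p-value when three classes are present, and the
#' pairwise Mann-Whitney z / p / significance (alpha = 0.0167) for every
#' available class pair.
#'
#' @param cohort Lesion table with `class` and parameter columns.
#' @param params Parameter columns to include (default all 12).
#' @return `data.frame`, one row per parameter.
#' @export
group_comparison_table <- function(cohort, params = ALL_PARAMETERS) {
  params <- intersect(params, names(cohort))
  if (length(params) == 0L) stop("no parameter columns found")
  classes <- intersect(CLASS_ORDER, unique(cohort$class))
  if (length(classes) < 2) stop("need at least two classes")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rows <- lapply(params, function(p) {
    sc <- display_scale(p)
    row <- list(parameter = p)
    for (cl in classes) {
      v <- cohort[[p]][cohort$class == cl] * sc
      row[[paste0(cl, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(cl, "_sd")]] <- stats::sd(v, na.rm = TRUE)
    }
    if (length(classes) >= 3) {
      kw <- kruskal_wallis(split(cohort[[p]], cohort$class))
      row$chi2 <- kw$chi2; row$p_kw <- kw$p
    } else {
      row$chi2 <- NA_real_; row$p_kw <- NA_real_
    }
    for (pr in pairs) {
      mw <- mann_whitney(cohort[[p]][cohort$class == pr[1]],
                         cohort[[p]][cohort$class == pr[2]])
      tag <- paste(substr(pr[1], 1, 3), substr(pr[2], 1, 3), sep = "_vs_")
      row[[paste0("z_", tag)]] <- mw$z
      row[[paste0("p_", tag)]] <- mw$p
      row[[paste0("sig_", tag)]] <- mw$significant
    }
    as.data.frame(row, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-parameter ROC table
#'
#' ROC analysis of each individual diffusion parameter for each class
#' contrast: AUC, Youden-optimal threshold (display-scaled, with its
#' inequality direction), sensitivity and specificity in percent.
#'
#' @param cohort Lesion table with `class` and parameter columns.
#' @param contrasts List of length-2 vectors `(negative, positive)`;
#'   defaults to the three pairwise contrasts with the more aggressive
#'   tissue as the positive class.
#' @param params Parameter columns (default all 12).
#' @return `data.frame`, one row per contrast x parameter.
#' @export
roc_table <- function(cohort,
                      contrasts = list(c("benign", "malignant"),
                                       c("normal", "malignant"),
                                       c("normal", "benign")),
                      params = ALL_PARAMETERS) {
  params <- intersect(params, names(cohort))
  rows <- list()
  for (ct in contrasts) {
    if (!all(ct %in% cohort$class)) next
    sel <- cohort$class %in% ct
    for (p in params) {
      r <- roc_single_parameter(cohort[[p]][sel], cohort$class[sel],
                                positive = ct[2])
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste(ct[2], "vs", ct[1]), parameter = p,
        auc = r$auc, direction = r$direction,
        threshold = r$threshold * display_scale(p),
        sensitivity = r$sensitivity, specificity = r$specificity)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate and compare the four diagnostic models
#'
#' Fits the ADC, IVIM, RSI and hybrid IVIM + RSI logistic models under the
#' same seeded stratified CV folds and compares every model pair by the
#' DeLong test on the pooled out-of-fold scores (per-fold AUC lists are kept
#' in the result for inspection).
#'
#' @param cohort Lesion table.
#' @param contrast Length-2 vector `(negative, positive)`.
#' @param folds CV folds (default 5).
#' @param seed Integer seed shared by all models (identical fold
#'   assignments).
#' @return List with `models` (named list of `model_eval`), `auc`
#'   (named mean CV AUCs) and `delong` (data.frame of pairwise
#'   comparisons).
#' @export
evaluate_models <- function(cohort, contrast = c("benign", "malignant"),
                            folds = 5, seed = 1L) {
  fs <- feature_sets()
  models <- lapply(names(fs), function(nm)
    fit_diagnostic_model(cohort, fs[[nm]], contrast = contrast,
                         folds = folds, seed = seed, name = nm))
  names(models) <- names(fs)
  prs <- utils::combn(names(fs), 2, simplify = FALSE)
  cmp <- lapply(prs, function(pr) {
    a <- models[[pr[1]]]; b <- models[[pr[2]]]
    dl <- delong_compare(a$scores$score, b$scores$score, a$scores$label,
                         positive = 1)
    data.frame(model_a = pr[1], model_b = pr[2],
               pooled_auc_a = dl$auc_a, pooled_auc_b = dl$auc_b,
               z = dl$z, p = dl$p)
  })
  list(models = models,
       auc = vapply(models, function(m) m$mean_auc, 1),
       delong = do.call(rbind, cmp))
}
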