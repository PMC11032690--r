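#' Fit the scoring reference from control subjects
#'
#' Stores the control-group mean of each feature. Scores are then ratios
#' against these references, so an average control subject scores about 1
#' — which gives the screening threshold of 1 its meaning (below 1
#' normal, above 1 malignant).
#'
#' @param controls Subject-level feature table of the control group
#'   (n >= 2); all feature means must be strictly positive.
#' @return Named numeric vector of reference means, class
#'   `score_reference`.
#' @export
fit_reference <- function(controls) {
  feats <- texture_feature_names()
  stopifnot(all(feats %in% names(controls)))
  if (nrow(controls) < 2) {
    stop("at least 2 control subjects are required to fit a reference",
         call. = FALSE)
  }
  ref <- vapply(feats, function(f) mean(controls[[f]]), numeric(1))
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("reference means must be finite and strictly positive",
         call. = FALSE)
  }
  structure(ref, class = "score_reference")
}

#' Composite scoring index for one feature vector
#'
#' The index is a ratio of reference-normalised features,
#' \deqn{score = \frac{(E/E_0)(C/C_0)}{(G/G_0)(R/R_0)(H/H_0)}}
#' with E entropy, C contrast, G energy, R correlation, H homogeneity and
#' subscript 0 the control references: the numerator collects the
#' features elevated in dysplasia, the denominator those reduced, so the
#' score exceeds 1 exactly when the feature profile shifts in the
#' malignant direction. This mirrors the ratio construction of the
#' oxidative-stress-index style of composite markers. Labels use a strict
#' threshold: `label = 1` (malignant) iff `score > threshold`; a score
#' exactly at the threshold is labelled normal.
#'
#' @param features Named list or one-row data.frame with the five
#'   features; an undefined (`NA`) correlation yields an undefined score
#'   with `defined = FALSE`.
#' @param reference A [fit_reference()] result.
#' @param threshold Decision threshold, default 1.
#' @return A list with `score`, `threshold`, `label` (0 normal /
#'   1 malignant) and `defined`.
#' @export
#' @examples
#' ref <- structure(c(entropy = 1.84, contrast = 0.06, energy = 0.40,
#'                    correlation = 0.95, homogeneity = 0.95),
#'                  class = "score_reference")
#' scoring_index(list(entropy = 2.05, contrast = 0.11, energy = 0.38,
#'                    correlation = 0.94, homogeneity = 0.94), ref)$score
scoring_index <- function(features, reference, threshold = 1) {
  stopifnot(inherits(reference, "score_reference"))
  f <- vapply(texture_feature_names(), function(nm) {
    as.numeric(features[[nm]])
  }, numeric(1))
  if (anyNA(f)) {
    return(list(score = NA_real_, threshold = threshold,
                label = NA_integer_, defined = FALSE))
  }
  num <- (f[["entropy"]] / reference[["entropy"]]) *
    (f[["contrast"]] / reference[["contrast"]])
  den <- (f[["energy"]] / reference[["energy"]]) *
    (f[["correlation"]] / reference[["correlation"]]) *
    (f[["homogeneity"]] / reference[["homogeneity"]])
  if (!is.finite(den) || den == 0) {
    return(list(score = NA_real_, threshold = threshold,
                label = NA_integer_, defined = FALSE))
  }
  score <- num / den
  list(score = score, threshold = threshold,
       label = as.integer(score > threshold), defined = TRUE)
}

#' Score every subject in a feature table
#'
#' @param subjects Subject-level feature table.
#' @param reference A [fit_reference()] result.
#' @param threshold Decision threshold, default 1.
#' @return `subjects` with `score` and `label` columns appended.
#' @export
score_subjects <- function(subjects, reference, threshold = 1) {
  scored <- lapply(seq_len(nrow(subjects)), function(i) {
    scoring_index(subjects[i, ], reference, threshold = threshold)
  })
  subjects$score <- vapply(scored, `[[`, numeric(1), "score")
  subjects$label <- vapply(scored, `[[`, integer(1), "label")
  subjects
}

#' ROC analysis of subject scores
#'
#' Sweeps every distinct score as a strict-inequality threshold
#' (`positive iff score > threshold`), yielding a curve from (0, 0) to
#' (1, 1); the AUC is computed by the trapezoid rule. The operating point
#' at the stated decision threshold (default 1, the screening rule)
#' reports accuracy `(TP + TN) / all`, sensitivity `TP / (TP + FN)` and
#' specificity `TN / (TN + FP)`.
#'
#' @param scores Numeric subject scores.
#' @param truth Truth labels: logical, 0/1, or a factor/character where
#'   `positive` names the positive class.
#' @param threshold Operating threshold, default 1.
#' @param positive Positive-class label used when `truth` is not already
#'   0/1/logical.
#' @return An object of class `roc_result`: list with `fpr`, `tpr`,
#'   `thresholds`, `auc`, `operating_point` (threshold, accuracy,
#'   sensitivity, specificity), `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_analysis(c(0.2, 0.8, 1.5, 2.0), c(0, 0, 1, 1))$auc
roc_analysis <- function(scores, truth, threshold = 1, positive = "oscc") {
  y <- coerce_binary(truth, positive)
  stopifnot(length(scores) == length(y), !anyNA(scores))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(ths, function(t) sum(scores > t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores > t & y == 0) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(
    list(fpr = fpr, tpr = tpr, thresholds = ths, auc = auc,
         operating_point = list(
           threshold = threshold,
           accuracy = (tp + tn) / length(y),
           sensitivity = tp / (tp + fn),
           specificity = tn / (tn + fp)
         ),
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf(
    "<roc_result> AUC %.3f (%d pos / %d neg); at threshold %.3g: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$auc, x$n_pos, x$n_neg, op$threshold,
    100 * op$accuracy, 100 * op$sensitivity, 100 * op$specificity
  ))
  invisible(x)
}

coerce_binary <- function(truth, positive) {
  if (is.logical(truth)) return(as.integer(truth))
  if (is.numeric(truth)) {
    stopifnot(all(truth %in% c(0, 1)))
    return(as.integer(truth))
  }
  as.integer(as.character(truth) == positive)
}

#' Agreement between pipeline calls and reference reader labels
#'
#' Compares the pipeline's binary calls with an independent reference
#' labelling (in the clinical setting, the cytopathologists' consensus;
#' for the synthetic cohort, the generator's ground truth) via the
#' confusion matrix, percent agreement, and Cohen's kappa.
#'
#' @param predicted,reader Aligned label vectors (0/1, logical, or
#'   factor/character).
#' @param positive Positive-class label for non-numeric input.
#' @return A list with `confusion` (2 x 2 table), `agreement` (percent)
#'   and `kappa`.
#' @export
validate_against_reader <- function(predicted, reader, positive = "oscc") {
  if (length(predicted) != length(reader)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  p <- coerce_binary(predicted, positive)
  r <- coerce_binary(reader, positive)
  confusion <- table(predicted = factor(p, levels = c(0, 1)),
                     reader = factor(r, levels = c(0, 1)))
  po <- mean(p == r)
  pe <- mean(p == 1) * mean(r == 1) + mean(p == 0) * mean(r == 0)
  kappa <- if (pe >= 1) {
    if (po >= 1) 1 else 0
  } else {
    (po - pe) / (1 - pe)
  }
  list(confusion = confusion, agreement = 100 * po, kappa = kappa)
}

#' Published operating characteristics of the clinical study system
#'
#' Reference points from the clinical exfoliative-cytology screening
#' literature whose pipeline this package reimplements: the group feature
#' summaries (see [feature_gaussian_spec()] defaults) and the reported
#' operating characteristics (accuracy 88%, sensitivity 91%, specificity
#' 81%). These numbers were measured on a clinical smear cohort whose
#' images are not publicly deposited, so they cannot be recomputed here:
#' each entry is flagged `reproducible = FALSE` and serves as context
#' only. Likewise, of the five published t-values only the entropy row
#' (9.68) is recoverable from the published group means/SDs at n = 80
#' per group; the other four are not (the published summaries are rounded
#' to 2 decimals), which `t_recoverable` records.
#'
#' @return A list with elements `operating_point` (accuracy, sensitivity,
#'   specificity in percent, with `reproducible = FALSE`), and
#'   `t_values` (data.frame: feature, published t, `t_recoverable`).
#' @export
screening_benchmarks <- function() {
  list(
    operating_point = list(
      accuracy = 88, sensitivity = 91, specificity = 81,
      reproducible = FALSE,
      note = paste(
        "Measured on an undeposited clinical smear cohort;",
        "not recomputable from this package. The synthetic cohort's own",
        "operating point is reported by run_pipeline() instead."
      )
    ),
    t_values = data.frame(
      feature = texture_feature_names(),
      t_published = c(9.68, 11.17, 2.68, 4.36, 3.82),
      t_recoverable = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE
    )
  )
}
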