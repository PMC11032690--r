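#' Aggregate image-level features to subject level
#'
#' Each subject contributes several cropped images; the subject-level
#' value of each feature is the arithmetic mean over that subject's
#' images. With `level = "image"` rows pass through unchanged (useful for
#' sensitivity analysis at the image level).
#'
#' @param features A data.frame with columns `subject_id`, `group` and the
#'   five feature columns ([texture_feature_names()]).
#' @param level `"subject"` (default) or `"image"`.
#' @return A data.frame with one row per subject (or per image).
#' @export
aggregate_subjects <- function(features, level = c("subject", "image")) {
  level <- match.arg(level)
  feats <- texture_feature_names()
  stopifnot(all(c("subject_id", "group", feats) %in% names(features)))
  if (nrow(features) == 0) stop("empty feature table", call. = FALSE)
  if (level == "image") return(features)
  bad <- feats[vapply(feats, function(f) anyNA(features[[f]]), logical(1))]
  if (length(bad)) {
    stop(sprintf("missing feature values (%s); cannot aggregate",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  agg <- stats::aggregate(features[feats],
                          by = list(subject_id = features$subject_id),
                          FUN = mean)
  grp <- features$group[match(agg$subject_id, features$subject_id)]
  out <- data.frame(subject_id = agg$subject_id, group = grp,
                    agg[feats], stringsAsFactors = FALSE)
  out[order(out$subject_id), , drop = FALSE]
}

#' Per-group mean and standard deviation of each feature
#'
#' @param subjects A subject-level feature table (see
#'   [aggregate_subjects()]).
#' @return A data.frame with columns `feature`, `group`, `mean`, `sd`
#'   (sample SD, n-1 denominator), `n`.
#' @export
summarize_groups <- function(subjects) {
  feats <- texture_feature_names()
  stopifnot(all(c("group", feats) %in% names(subjects)))
  groups <- unique(subjects$group)
  if (length(groups) < 2) stop("both groups must be present", call. = FALSE)
  rows <- list()
  for (g in groups) {
    sub <- subjects[subjects$group == g, , drop = FALSE]
    if (nrow(sub) < 2) {
      stop(sprintf("group '%s' has n = %d < 2: SD undefined", g, nrow(sub)),
           call. = FALSE)
    }
    for (f in feats) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group = g, mean = mean(sub[[f]]),
        sd = stats::sd(sub[[f]]), n = nrow(sub), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Unpaired two-sample t-test from group summaries
#'
#' Computes the two-sided unpaired t-test directly from per-group means,
#' sample SDs and sizes. The pooled (Student) variant uses
#' \eqn{t = (\bar x_1 - \bar x_2) / (s_p \sqrt{1/n_1 + 1/n_2})} with the
#' pooled variance and `df = n1 + n2 - 2`; the Welch variant uses
#' per-group variances with Welch-Satterthwaite degrees of freedom. For
#' equal group sizes the two t statistics coincide.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list with `t`, `df`, `p`, `variant`.
#' @export
#' @examples
#' unpaired_t(2.05, 0.19, 80, 1.84, 0.04, 80)$t
unpaired_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                       variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative", call. = FALSE)
  if (sd1 == 0 && sd2 == 0) {
    stop("both SDs are zero: t statistic undefined", call. = FALSE)
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, variant = variant)
}

#' Two-group comparison table of the five texture features
#'
#' One row per feature: group means and SDs, the unpaired t-test between
#' the two groups (the dysplastic/OSCC-like group minus control, so
#' positive t means elevated in the dysplastic group), and a significance
#' flag at level `alpha`. No multiple-testing correction is applied by
#' default (five tests at alpha = 0.05); `bonferroni = TRUE` divides
#' `alpha` by the number of features.
#'
#' @param subjects Subject-level feature table with groups `"control"`
#'   and `"oscc"` (any two groups work; the non-control group is treated
#'   as group 1).
#' @param variant t-test variant, see [unpaired_t()].
#' @param alpha Significance level.
#' @param bonferroni Apply Bonferroni correction across the five tests.
#' @return A data.frame with columns `feature`, `mean_oscc`, `sd_oscc`,
#'   `mean_control`, `sd_control`, `n_oscc`, `n_control`, `t`, `df`, `p`,
#'   `significant`.
#' @export
summary_table <- function(subjects, variant = c("pooled", "welch"),
                          alpha = 0.05, bonferroni = FALSE) {
  variant <- match.arg(variant)
  sm <- summarize_groups(subjects)
  groups <- unique(sm$group)
  if (length(groups) != 2) stop("exactly two groups expected", call. = FALSE)
  ctrl <- if ("control" %in% groups) "control" else groups[2]
  case <- setdiff(groups, ctrl)[1]
  thr <- if (bonferroni) alpha / length(texture_feature_names()) else alpha
  rows <- lapply(texture_feature_names(), function(f) {
    s1 <- sm[sm$feature == f & sm$group == case, ]
    s2 <- sm[sm$feature == f & sm$group == ctrl, ]
    tt <- unpaired_t(s1$mean, s1$sd, s1$n, s2$mean, s2$sd, s2$n,
                     variant = variant)
    data.frame(feature = f,
               mean_oscc = s1$mean, sd_oscc = s1$sd,
               mean_control = s2$mean, sd_control = s2$sd,
               n_oscc = s1$n, n_control = s2$n,
               t = tt$t, df = tt$df, p = tt$p,
               significant = tt$p < thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a comparison table as Markdown
#'
#' @param tab A [summary_table()] result.
#' @param digits Digits for rounding.
#' @return A character vector of Markdown lines.
#' @export
format_summary_table <- function(tab, digits = 3) {
  hdr <- c(
    "| Feature | OSCC mean (SD) | Control mean (SD) | t | p | Significant |",
    "|---|---|---|---|---|---|"
  )
  body <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    sprintf("| %s | %s (%s) | %s (%s) | %s | %s | %s |",
            r$feature,
            signif(r$mean_oscc, digits), signif(r$sd_oscc, digits),
            signif(r$mean_control, digits), signif(r$sd_control, digits),
            signif(r$t, digits), format.pval(r$p, digits = 2),
            if (r$significant) "yes" else "no")
  }, character(1))
  c(hdr, body)
}
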