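#' Default pipeline configuration
#'
#' All tunable parameters of the full screening pipeline with their
#' defaults: synthetic cohort size (80 subjects per group, 10 images
#' each, 256 x 256 pixels), percentile contrast stretch (2, 98),
#' two-cluster fuzzy c-means selecting the darkest cluster, 8-level
#' asymmetric GLCM at offset (0, 1), pooled t-tests at subject level with
#' alpha 0.05, and the scoring threshold 1.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synth = list(
      n_per_group = 80L,
      images_per_subject = 10L,
      size = c(256L, 256L)
    ),
    enhance = list(method = "stretch", p_low = 2, p_high = 98),
    fcm = list(c = 2L, m = 2, tol = 1e-5, max_iter = 300L,
               select = "darkest"),
    glcm = list(n_levels = 8L, offsets = list(c(0L, 1L)),
                symmetric = FALSE),
    stats = list(variant = "pooled", alpha = 0.05, level = "subject",
                 bonferroni = FALSE),
    scoring = list(threshold = 1),
    version = as.character(utils::packageVersion("cytotexture"))
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Fills documented defaults for every omitted field, rejects unknown
#' keys, and range-checks every parameter, reporting all problems at once
#' (each message names the offending field, e.g. `glcm.n_levels`).
#'
#' @param config A (possibly partial) configuration list.
#' @return The fully defaulted, validated configuration.
#' @export
#' @examples
#' cfg <- validate_config(list(synth = list(n_per_group = 4)))
#' cfg$synth$n_per_group
validate_config <- function(config = list()) {
  defaults <- default_config()
  errors <- character(0)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top)) {
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown_top, collapse = ", ")))
  }
  cfg <- defaults
  for (blk in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[blk]]) && !is.null(names(defaults[[blk]]))) {
      sub <- config[[blk]]
      unknown <- setdiff(names(sub), names(defaults[[blk]]))
      if (length(unknown)) {
        errors <- c(errors, sprintf("unknown key(s) in `%s`: %s", blk,
                                    paste(unknown, collapse = ", ")))
      }
      for (k in intersect(names(sub), names(defaults[[blk]]))) {
        cfg[[blk]][[k]] <- sub[[k]]
      }
    } else {
      cfg[[blk]] <- config[[blk]]
    }
  }
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: single integer")
  chk(cfg$synth$n_per_group >= 1, "synth.n_per_group must be >= 1")
  chk(cfg$synth$images_per_subject >= 1,
      "synth.images_per_subject must be >= 1")
  chk(length(cfg$synth$size) == 2 && all(cfg$synth$size >= 32),
      "synth.size must be at least 32x32")
  chk(cfg$enhance$method %in% c("stretch", "equalize", "none"),
      "enhance.method must be one of stretch/equalize/none")
  chk(cfg$enhance$p_low < cfg$enhance$p_high,
      "enhance.p_low must be < enhance.p_high")
  chk(cfg$fcm$c >= 2, "fcm.c must be >= 2")
  chk(cfg$fcm$m > 1, "fcm.m must be > 1")
  chk(cfg$fcm$tol > 0, "fcm.tol must be > 0")
  chk(cfg$fcm$select %in% c("darkest", "brightest", "largest"),
      "fcm.select must be one of darkest/brightest/largest")
  chk(cfg$glcm$n_levels >= 2, "glcm.n_levels must be >= 2")
  chk(is.list(cfg$glcm$offsets) && length(cfg$glcm$offsets) >= 1 &&
        all(vapply(cfg$glcm$offsets,
                   function(o) length(o) == 2 && !all(o == 0), logical(1))),
      "glcm.offsets must be a list of nonzero (dr, dc) displacements")
  chk(cfg$stats$variant %in% c("pooled", "welch"),
      "stats.variant must be pooled or welch")
  chk(cfg$stats$alpha > 0 && cfg$stats$alpha < 1,
      "stats.alpha must lie in (0, 1)")
  chk(cfg$stats$level %in% c("subject", "image"),
      "stats.level must be subject or image")
  chk(cfg$scoring$threshold > 0, "scoring.threshold must be > 0")
  if (length(errors)) {
    stop(paste(c("invalid configuration:", errors), collapse = "\n  "),
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full screening pipeline
#'
#' Orchestrates every stage on a synthetic cohort: image generation,
#' contrast enhancement, fuzzy c-means segmentation, masked GLCM feature
#' extraction, subject-level aggregation, the two-group comparison table,
#' reference fitting on the control group, composite scoring, ROC
#' analysis, and agreement of the threshold-1 calls with the ground-truth
#' labels. Everything is driven by the single seed in `config`, and a
#' rerun with the same configuration is bit-identical (the run log
#' carries no timestamps for this reason).
#'
#' Output directory layout: `images/`, `manifest.csv`, `features.csv`,
#' `features-config.json`, `report.md`, `scores.csv`, `roc.csv`,
#' `summary.json`, `config-used.json`, `run.log`.
#'
#' @param config A (partial) configuration; see [validate_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `features`, `subjects`, `report`,
#'   `scores`, `roc`, `agreement`, `config`, `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("stage synth: %d subjects/group x %d images, %dx%d px, seed %d",
      cfg$synth$n_per_group, cfg$synth$images_per_subject,
      cfg$synth$size[1], cfg$synth$size[2], cfg$seed)
  manifest <- stage("synth", generate_cohort(
    out_dir, n_per_group = cfg$synth$n_per_group,
    images_per_subject = cfg$synth$images_per_subject,
    size = cfg$synth$size, seed = cfg$seed
  ))

  say("stage features: enhance=%s, fcm c=%d select=%s, glcm N=%d",
      cfg$enhance$method, cfg$fcm$c, cfg$fcm$select, cfg$glcm$n_levels)
  feat_rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$image_path[i]
    row <- stage(paste0("features [", path, "]"), {
      img <- load_image(file.path(out_dir, path))
      img <- enhance_contrast(img, cfg$enhance$method,
                              cfg$enhance$p_low, cfg$enhance$p_high)
      mask <- segment_image(img, c = cfg$fcm$c, select = cfg$fcm$select,
                            m = cfg$fcm$m, tol = cfg$fcm$tol,
                            max_iter = cfg$fcm$max_iter)
      f <- image_features(img, mask = mask, n_levels = cfg$glcm$n_levels,
                          offsets = cfg$glcm$offsets,
                          symmetric = cfg$glcm$symmetric)
      f$entropy_hist <- histogram_entropy(img, mask = mask,
                                          n_levels = cfg$glcm$n_levels)
      f
    })
    feat_rows[[i]] <- cbind(manifest[i, , drop = FALSE], row,
                            row.names = NULL)
  }
  features <- do.call(rbind, feat_rows)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_levels = cfg$glcm$n_levels, offsets = cfg$glcm$offsets,
         symmetric = cfg$glcm$symmetric, gray_limits = c(0, 255),
         mask = "fcm foreground"),
    file.path(out_dir, "features-config.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  say("stage stats: level=%s variant=%s", cfg$stats$level, cfg$stats$variant)
  subjects <- stage("stats", aggregate_subjects(features, cfg$stats$level))
  report <- stage("stats", summary_table(
    subjects, variant = cfg$stats$variant, alpha = cfg$stats$alpha,
    bonferroni = cfg$stats$bonferroni
  ))
  writeLines(format_summary_table(report), file.path(out_dir, "report.md"))

  say("stage score: threshold=%g", cfg$scoring$threshold)
  ref <- stage("score", fit_reference(
    subjects[subjects$group == "control", , drop = FALSE]
  ))
  scored <- stage("score", score_subjects(subjects, ref,
                                          threshold = cfg$scoring$threshold))
  utils::write.csv(scored, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)

  roc <- stage("evaluate", roc_analysis(
    scored$score, scored$group, threshold = cfg$scoring$threshold
  ))
  utils::write.csv(
    data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr),
    file.path(out_dir, "roc.csv"), row.names = FALSE
  )
  agreement <- stage("evaluate", validate_against_reader(
    scored$label, scored$group
  ))
  op <- roc$operating_point
  jsonlite::write_json(
    list(auc = roc$auc, accuracy = op$accuracy,
         sensitivity = op$sensitivity, specificity = op$specificity,
         threshold = op$threshold, agreement_percent = agreement$agreement,
         kappa = agreement$kappa,
         n_control = sum(scored$group == "control"),
         n_oscc = sum(scored$group == "oscc")),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  say("done: AUC %.4f, accuracy %.3f, sensitivity %.3f, specificity %.3f",
      roc$auc, op$accuracy, op$sensitivity, op$specificity)

  jsonlite::write_json(cfg, file.path(out_dir, "config-used.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(features = features, subjects = subjects, report = report,
                 scores = scored, roc = roc, agreement = agreement,
                 config = cfg, out_dir = out_dir))
}
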