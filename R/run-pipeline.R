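# End-to-end orchestration: simulate a demo study to disk, and run the full
# report (group summary, logistic associations, image-feature comparison,
# feature x marker correlations, ROC) from a config.

#' Simulate a study to disk
#'
#' Writes a cohort CSV, one PNG tongue image per subject with ground-truth
#' body/coating mask PNGs, and a ready-to-run YAML config. Case-group image
#' specs use brighter coating colours and a lower coating saturation, so the
#' downstream image comparison has a built-in effect; per-subject colour
#' jitter makes the feature distributions non-degenerate.
#'
#' @param dir output directory (created if needed).
#' @param n_glm,n_control subject counts.
#' @param image_size image side length in pixels.
#' @param seed master seed; every per-subject seed derives from it.
#' @return The path of the written config file, invisibly.
#' @export
simulate_study <- function(dir, n_glm = 40L, n_control = 40L,
                           image_size = 96L, seed = 1L) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  cs <- cohort_spec(n_glm = n_glm, n_control = n_control, seed = seed)
  records <- generate_cohort(cs)
  cohort_path <- file.path(dir, "cohort.csv")
  write_cohort_csv(records, cohort_path)

  base_colors <- list(
    GLM = list(body = c(185, 95, 100), coating = c(215, 205, 200),
               coating_fraction = 0.45),
    control = list(body = c(170, 100, 105), coating = c(185, 175, 165),
                   coating_fraction = 0.30))
  jitter <- with_seed(seed + 1L,
                      matrix(stats::rnorm(nrow(records) * 6, sd = 6), ncol = 6))
  for (i in seq_len(nrow(records))) {
    grp <- records$group[i]
    bc <- base_colors[[grp]]
    spec <- image_spec(
      width = image_size, height = image_size,
      body_color = clip(bc$body + jitter[i, 1:3], 0, 255),
      coating_color = clip(bc$coating + jitter[i, 4:6], 0, 255),
      coating_fraction = bc$coating_fraction,
      noise_sd = 5, texture_period = if (grp == "GLM") 32 else 16,
      texture_amp = 8, seed = seed + 100L + i)
    gen <- generate_tongue_image(spec)
    id <- records$subject_id[i]
    write_image_png(gen$image, file.path(dir, "images", paste0(id, ".png")))
    write_mask_png(gen$masks$body, file.path(dir, "images", paste0(id, "_body.png")))
    write_mask_png(gen$masks$coating, file.path(dir, "images", paste0(id, "_coating.png")))
  }
  config <- list(cohort_csv = cohort_path,
                 image_dir = file.path(dir, "images"),
                 out_dir = file.path(dir, "report"),
                 seed = seed,
                 use_ground_truth_masks = TRUE)
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  invisible(config_path)
}

.pipeline_block <- function(report, log, name, expr) {
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    report$errors[[name]] <- conditionMessage(res)
    log(sprintf("block %s FAILED: %s", name, conditionMessage(res)))
  } else {
    report[[name]] <- res
    log(sprintf("block %s produced", name))
  }
  report
}

#' Run the full analysis pipeline
#'
#' Reads the cohort CSV (and, when an image directory is configured, the
#' per-subject images and masks), extracts features, and assembles the five
#' report blocks: `table2` (group summary), `table3` (logistic
#' associations), `table4` (image-feature comparison), `table5`
#' (feature x marker Spearman grid) and `roc`. Each block is isolated: a
#' failure is recorded in `errors` and the remaining blocks still run.
#' Deterministic given the config; writes `report.json`, one CSV per table,
#' and a run log recording versions, seed and the analysis settings in
#' force.
#'
#' @param config a YAML file path or a list with at least `cohort_csv`;
#'   optional `image_dir`, `out_dir`, `seed`, `use_ground_truth_masks`,
#'   plus analysis settings `delta`, `m`, `mode`.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$cohort_csv)) stop("config must name `cohort_csv`", call. = FALSE)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  delta <- if (is.null(config$delta)) c(1L, 1L) else as.integer(config$delta)
  m <- if (is.null(config$m)) 256L else as.integer(config$m)
  mode <- if (is.null(config$mode)) "mean-rgb" else config$mode
  use_gt <- isTRUE(config$use_ground_truth_masks)

  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, sprintf("[%s] %s", Sys.time(), msg))
  log(sprintf("tonguemetrics %s on R %s; seed = %d; delta = (%s); m = %d; mode = %s",
              as.character(utils::packageVersion("tonguemetrics")),
              paste(R.version$major, R.version$minor, sep = "."),
              seed, paste(delta, collapse = ","), m, mode))

  records <- read_cohort_csv(config$cohort_csv)
  log(sprintf("cohort: %d subjects (%d GLM, %d control)", nrow(records),
              sum(records$group == "GLM"), sum(records$group == "control")))

  report <- list(errors = list())
  report <- .pipeline_block(report, log, "table2", summarize_cohort(records))
  report <- .pipeline_block(report, log, "table3", {
    fa <- feature_association(records)
    multi <- fa$multivariate
    list(univariate = fa$univariate,
         multivariate = if (is.null(multi)) NULL else data.frame(
           feature = names(multi$coefficients), OR = multi$odds_ratios,
           ci_low = multi$ci_low, ci_high = multi$ci_high,
           p_value = multi$p_values, converged = multi$converged,
           stringsAsFactors = FALSE))
  })
  report <- .pipeline_block(report, log, "roc", roc_report(records))

  feature_table <- NULL
  if (!is.null(config$image_dir)) {
    feature_table <- .extract_cohort_features(records, config$image_dir,
                                              use_gt, delta, m, mode, log)
    report <- .pipeline_block(report, log, "table4",
                              compare_image_features(feature_table,
                                                     records[, c("subject_id", "group")]))
    report <- .pipeline_block(report, log, "table5",
                              correlate_features_markers(records, feature_table))
  } else {
    log("no image_dir configured: table4/table5 skipped")
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, na = "null")
  write_tbl <- function(x, f) {
    if (!is.null(x)) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  }
  write_tbl(report$table2, "table2.csv")
  write_tbl(report$table3$univariate, "table3_univariate.csv")
  write_tbl(report$table3$multivariate, "table3_multivariate.csv")
  write_tbl(report$table4, "table4.csv")
  write_tbl(report$table5$grid, "table5.csv")
  write_tbl(report$roc, "roc.csv")
  if (!is.null(feature_table)) write_tbl(feature_table, "features.csv")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}

.extract_cohort_features <- function(records, image_dir, use_gt, delta, m, mode, log) {
  rows <- list()
  n_missing <- 0L
  for (i in seq_len(nrow(records))) {
    id <- records$subject_id[i]
    img_path <- file.path(image_dir, paste0(id, ".png"))
    if (!file.exists(img_path)) {
      n_missing <- n_missing + 1L
      next
    }
    img <- load_image(img_path)
    body_path <- file.path(image_dir, paste0(id, "_body.png"))
    coating_path <- file.path(image_dir, paste0(id, "_coating.png"))
    if (use_gt && file.exists(body_path) && file.exists(coating_path)) {
      body <- load_mask(body_path)
      coating <- load_mask(coating_path)
      masks <- region_masks(body | coating, body, coating)
    } else {
      tongue <- segment_tongue(img)$tongue
      masks <- split_body_coating(img, tongue)
    }
    feats <- extract_features(img, masks, delta = delta, m = m, mode = mode)
    feats <- cbind(subject_id = id, feats, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- feats
  }
  if (n_missing > 0) log(sprintf("%d subject(s) without image files excluded", n_missing))
  if (length(rows) == 0L) stop("no images found in image_dir", call. = FALSE)
  do.call(rbind, rows)
}
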