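# Cohort-level report builders: group summary (demographics + categorical
# features), logistic feature association, image-feature group comparison,
# feature x marker correlation, and binary-marker ROC.

.ordinal_codings <- list(
  tongue_shape = c(small_thin = 1, moderate = 2, fat = 3),
  body_color = c(light_red = 1, red = 2, dark_red = 3),
  coating_color = c(none = 1, white = 2, yellow = 3)
)

.fmt_median_range <- function(x) {
  sprintf("%.2f (%.2f-%.2f)", stats::median(x), min(x), max(x))
}

.fmt_n_pct <- function(k, n) sprintf("%d (%.2f%%)", k, 100 * k / n)

.check_groups <- function(records) {
  if (!all(c("GLM", "control") %in% records$group)) {
    stop("both groups (GLM and control) must be present", call. = FALSE)
  }
}

.counts_2x2 <- function(exposed, is_case) {
  matrix(c(sum(exposed & is_case), sum(!exposed & is_case),
           sum(exposed & !is_case), sum(!exposed & !is_case)),
         nrow = 2)
}

#' Group comparison table of a cohort
#'
#' Age is compared with the pooled two-tailed t test; blood markers with the
#' Mann-Whitney U test and summarised as median (min-max); binary categorical
#' features with the uncorrected Pearson chi-square; the three-level ordinal
#' features (tongue shape, body colour, coating colour) with the rank-sum
#' test on the documented ordinal scores (e.g. none < white < yellow).
#' Degenerate features (a zero margin, e.g. a category absent from both
#' groups) are reported with `p_value = NA` and a note.
#'
#' @param records cohort data.frame (see [generate_cohort()] /
#'   [read_cohort_csv()]).
#' @return A data.frame with one row per variable (or per category for the
#'   exclusive features): summaries per group, test label, statistic, p.
#' @export
summarize_cohort <- function(records) {
  .check_groups(records)
  required <- c("group", "age", .exclusive_features, .binary_features, .marker_names)
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop(sprintf("cohort schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  is_case <- records$group == "GLM"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  rows <- list()
  add <- function(variable, glm, control, test, statistic, p, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, glm = glm, control = control, test = test,
      statistic = statistic, p_value = p, note = note, stringsAsFactors = FALSE)
  }

  tt <- two_sample_t_raw(records$age[is_case], records$age[!is_case])
  add("age",
      sprintf("%.2f +/- %.2f", mean(records$age[is_case]), stats::sd(records$age[is_case])),
      sprintf("%.2f +/- %.2f", mean(records$age[!is_case]), stats::sd(records$age[!is_case])),
      "t", tt$statistic, tt$p_value)

  for (mk in .marker_names) {
    mw <- mann_whitney_u(records[[mk]][is_case], records[[mk]][!is_case])
    add(mk, .fmt_median_range(records[[mk]][is_case]),
        .fmt_median_range(records[[mk]][!is_case]),
        "mann-whitney", mw$statistic, mw$p_value)
  }

  for (feat in .exclusive_features) {
    coding <- .ordinal_codings[[feat]]
    x <- coding[records[[feat]][is_case]]
    y <- coding[records[[feat]][!is_case]]
    p <- NA_real_; stat <- NA_real_; note <- ""
    if (length(unique(c(x, y))) < 2L) {
      note <- "degenerate: single category observed"
    } else {
      mw <- mann_whitney_u(x, y)
      p <- mw$p_value; stat <- mw$statistic
    }
    add(feat, "", "", "rank-sum (ordinal)", stat, p, note)
    for (lev in names(coding)) {
      add(sprintf("%s: %s", feat, lev),
          .fmt_n_pct(sum(records[[feat]][is_case] == lev), n1),
          .fmt_n_pct(sum(records[[feat]][!is_case] == lev), n2),
          "", NA_real_, NA_real_)
    }
  }

  for (feat in .binary_features) {
    exposed <- records[[feat]] == .binary_positive[[feat]]
    glm_s <- .fmt_n_pct(sum(exposed & is_case), n1)
    ctl_s <- .fmt_n_pct(sum(exposed & !is_case), n2)
    res <- tryCatch(chi_square_2x2(.counts_2x2(exposed, is_case)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      add(feat, glm_s, ctl_s, "chi-square", NA_real_, NA_real_,
          note = conditionMessage(res))
    } else {
      add(feat, glm_s, ctl_s, "chi-square", res$statistic, res$p_value)
    }
  }
  do.call(rbind, rows)
}

.feature_encodings <- list(
  yellow_coating = function(r) r$coating_color == "yellow",
  white_coating = function(r) r$coating_color == "white",
  greasy_coating = function(r) r$coating_greasy == "greasy",
  thick_coating = function(r) r$coating_thick == "thick",
  fat_tongue = function(r) r$tongue_shape == "fat",
  tooth_marked = function(r) r$tooth_marked == "yes"
)

#' Logistic feature-association table
#'
#' Fits, per binary-encoded tongue feature (yellow/white coating colour,
#' greasy, thick, fat tongue, tooth-marked), the closed-form univariate
#' logistic regression of case status on the feature, then a joint
#' multivariate IRLS fit on the features whose univariate p < 0.05. A feature
#' with a zero cell (separation) is reported with a flag, never dropped
#' silently.
#'
#' @param records cohort data.frame.
#' @param alpha univariate inclusion threshold for the multivariate model.
#' @return A list with `univariate` (data.frame), `multivariate`
#'   (a [logistic_fit] or NULL) and `multivariate_features`.
#' @export
feature_association <- function(records, alpha = 0.05) {
  .check_groups(records)
  is_case <- records$group == "GLM"
  uni <- lapply(names(.feature_encodings), function(feat) {
    exposed <- .feature_encodings[[feat]](records)
    fit <- tryCatch(logistic_univariate_2x2(.counts_2x2(exposed, is_case)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(feature = feat, OR = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_,
                 flag = conditionMessage(fit), stringsAsFactors = FALSE)
    } else {
      data.frame(feature = feat, OR = fit$odds_ratios, ci_low = fit$ci_low,
                 ci_high = fit$ci_high, p_value = fit$p_values, flag = "",
                 stringsAsFactors = FALSE)
    }
  })
  uni <- do.call(rbind, uni)
  rownames(uni) <- NULL
  keep <- uni$feature[!is.na(uni$p_value) & uni$p_value < alpha]
  multi <- NULL
  if (length(keep) > 0) {
    X <- cbind(intercept = 1,
               vapply(keep, function(f) as.numeric(.feature_encodings[[f]](records)),
                      numeric(nrow(records))))
    colnames(X) <- c("intercept", keep)
    multi <- logistic_fit(as.numeric(is_case), X)
  }
  list(univariate = uni, multivariate = multi, multivariate_features = keep)
}

#' Group comparison of extracted image features
#'
#' For every region x index combination, reports the per-group median
#' (min-max) and the Mann-Whitney p-value. Subjects without features for a
#' region are excluded (their count is reported).
#'
#' @param feature_table data.frame with `subject_id`, `region` and numeric
#'   feature columns (as produced by [extract_features()] rows bound over
#'   subjects).
#' @param groups data.frame with `subject_id` and `group`.
#' @return A data.frame: region, index, group summaries, p-value, n per
#'   group.
#' @export
compare_image_features <- function(feature_table, groups) {
  idx_cols <- setdiff(names(feature_table),
                      c("subject_id", "region", "n_pixels"))
  merged <- merge(feature_table, groups[, c("subject_id", "group")],
                  by = "subject_id")
  dropped <- length(unique(feature_table$subject_id)) -
    length(unique(merged$subject_id))
  if (dropped > 0) {
    warning(sprintf("%d subject(s) with features but no group label excluded", dropped))
  }
  rows <- list()
  for (region in unique(merged$region)) {
    sub <- merged[merged$region == region, ]
    is_case <- sub$group == "GLM"
    if (sum(is_case) < 2 || sum(!is_case) < 2) {
      stop("need at least 2 subjects per group with image features", call. = FALSE)
    }
    for (ix in idx_cols) {
      x <- sub[[ix]][is_case]; y <- sub[[ix]][!is_case]
      mw <- mann_whitney_u(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, index = ix,
        glm = .fmt_median_range(x), control = .fmt_median_range(y),
        glm_median = stats::median(x), control_median = stats::median(y),
        p_value = mw$p_value, n_glm = sum(is_case), n_control = sum(!is_case),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate image features with blood markers
#'
#' Spearman rank correlation for every (feature, marker) pair, computed
#' within one group (the case group by default, matching how tongue-marker
#' correlations are reported). The full grid is always returned; the
#' `significant` subset filters at unadjusted p < `alpha`. Constant features
#' are skipped with a log entry.
#'
#' @param records cohort data.frame carrying the markers.
#' @param feature_table either NULL (numeric feature columns are taken from
#'   `records` itself, e.g. copula-induced columns) or a data.frame with
#'   `subject_id`, `region` and feature columns, which is widened to
#'   `region_index` columns.
#' @param markers marker column names.
#' @param group group to correlate within; NULL for all subjects.
#' @param alpha significance filter for the `significant` block.
#' @return A list with `grid`, `significant` and `skipped`.
#' @export
correlate_features_markers <- function(records, feature_table = NULL,
                                       markers = .marker_names,
                                       group = "GLM", alpha = 0.05) {
  if (!is.null(group)) records <- records[records$group %in% group, , drop = FALSE]
  if (is.null(feature_table)) {
    reserved <- c("age", markers)
    num <- vapply(records, is.numeric, TRUE)
    feat_cols <- setdiff(names(records)[num], reserved)
    wide <- records[, c("subject_id", feat_cols), drop = FALSE]
  } else {
    idx_cols <- setdiff(names(feature_table), c("subject_id", "region", "n_pixels"))
    pieces <- lapply(split(feature_table, feature_table$region), function(sub) {
      out <- sub[, c("subject_id", idx_cols)]
      names(out)[-1] <- paste(sub$region[1], idx_cols, sep = "_")
      out
    })
    wide <- Reduce(function(a, b) merge(a, b, by = "subject_id", all = TRUE), pieces)
    feat_cols <- setdiff(names(wide), "subject_id")
  }
  merged <- merge(wide, records[, c("subject_id", markers)], by = "subject_id")
  rows <- list(); skipped <- character(0)
  for (f in feat_cols) {
    for (mk in markers) {
      res <- tryCatch(spearman_cor(merged[[f]], merged[[mk]]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped, sprintf("%s x %s: %s", f, mk, conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, marker = mk, r = res$statistic, p_value = res$p_value,
        n = res$n, stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  if (!is.null(grid)) rownames(grid) <- NULL
  list(grid = grid,
       significant = if (is.null(grid)) NULL else grid[grid$p_value < alpha, , drop = FALSE],
       skipped = skipped)
}

#' Binary-marker ROC report
#'
#' AUC (with Hanley-McNeil CI and test against 0.5) for each binary tongue
#' feature and for the "greasy and thick" combination.
#'
#' @param records cohort data.frame.
#' @return A data.frame: feature, auc, ci_low, ci_high, p_value.
#' @export
roc_report <- function(records) {
  .check_groups(records)
  is_case <- records$group == "GLM"
  encs <- c(.feature_encodings,
            list(greasy_and_thick = function(r) {
              r$coating_greasy == "greasy" & r$coating_thick == "thick"
            }))
  rows <- lapply(names(encs), function(feat) {
    exposed <- encs[[feat]](records)
    rr <- roc_auc_binary(sum(exposed & is_case), sum(is_case),
                         sum(exposed & !is_case), sum(!is_case))
    data.frame(feature = feat, auc = rr$auc, ci_low = rr$ci_low,
               ci_high = rr$ci_high, p_value = rr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
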