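# Synthetic case-control cohorts: categorical tongue features with prescribed
# per-group marginals, right-skewed blood markers, and optional copula-induced
# rank correlations between a marker and an image-feature column.

.exclusive_features <- c("tongue_shape", "body_color", "coating_color")
.binary_features <- c("coating_thick", "coating_greasy", "tooth_marked",
                      "prick", "sublingual_vessel", "ecchymosis")
.binary_positive <- c(coating_thick = "thick", coating_greasy = "greasy",
                      tooth_marked = "yes", prick = "yes",
                      sublingual_vessel = "yes", ecchymosis = "yes")
.binary_negative <- c(coating_thick = "thin", coating_greasy = "normal",
                      tooth_marked = "no", prick = "no",
                      sublingual_vessel = "no", ecchymosis = "no")
.marker_names <- c("wbc", "plt", "crp", "il2", "il6", "tgfb")

#' Default per-group category probabilities
#'
#' The observed case/control proportions of a 40 + 40 granulomatous lobular
#' mastitis tongue-feature study: e.g. greasy coating 95% of cases vs 15% of
#' controls, thick coating 85% vs 12.5%, all tongue bodies light red in
#' cases. Exclusive features carry full probability vectors; binary features
#' carry the probability of the positive level.
#'
#' @return A named list, one element per feature, each with `GLM` and
#'   `control` entries.
#' @export
default_category_probs <- function() {
  list(
    tongue_shape = list(
      GLM = c(small_thin = 0, moderate = 0.675, fat = 0.325),
      control = c(small_thin = 0.225, moderate = 0.625, fat = 0.15)),
    body_color = list(
      GLM = c(light_red = 1, red = 0, dark_red = 0),
      control = c(light_red = 0.725, red = 0.275, dark_red = 0)),
    coating_color = list(
      GLM = c(none = 0.15, white = 0.80, yellow = 0.05),
      control = c(none = 0.70, white = 0.175, yellow = 0.125)),
    coating_thick = list(GLM = 0.85, control = 0.125),
    coating_greasy = list(GLM = 0.95, control = 0.15),
    tooth_marked = list(GLM = 0.375, control = 0.15),
    prick = list(GLM = 0, control = 0),
    sublingual_vessel = list(GLM = 0.375, control = 0),
    ecchymosis = list(GLM = 0, control = 0)
  )
}

#' Default blood-marker distribution parameters
#'
#' Each marker is log-normal with `sdlog` solved so that the printed min-max
#' range spans roughly a 98% envelope (`sdlog = log(max/min) / (2 * 2.326)`);
#' draws are confined to the printed range by inverse-CDF truncation (no
#' boundary point mass), and `meanlog` is solved numerically so that the
#' truncated distribution's median equals the printed group median.
#'
#' @return A named list per marker with `GLM` and `control` entries, each a
#'   list of `median` and `range`.
#' @export
default_marker_params <- function() {
  list(
    wbc  = list(GLM = list(median = 8.85, range = c(4.70, 21.14)),
                control = list(median = 7.42, range = c(6.19, 8.67))),
    plt  = list(GLM = list(median = 291.50, range = c(121.00, 552.00)),
                control = list(median = 205.00, range = c(108.00, 292.00))),
    crp  = list(GLM = list(median = 6.73, range = c(0.50, 85.63)),
                control = list(median = 2.69, range = c(1.73, 3.88))),
    il2  = list(GLM = list(median = 112.80, range = c(8.50, 262.70)),
                control = list(median = 60.64, range = c(46.07, 76.05))),
    il6  = list(GLM = list(median = 3.15, range = c(2.00, 26.40)),
                control = list(median = 2.98, range = c(1.61, 4.66))),
    tgfb = list(GLM = list(median = 430.00, range = c(51.70, 1169.90)),
                control = list(median = 186.08, range = c(148.10, 222.48)))
  )
}

#' Specification for a synthetic cohort
#'
#' @param n_glm,n_control subject counts per group.
#' @param category_probs per-feature, per-group probabilities; defaults to
#'   [default_category_probs()]. Partial lists override the defaults
#'   feature-wise.
#' @param marker_params per-marker, per-group log-normal parameters; defaults
#'   to [default_marker_params()].
#' @param age_params per-group normal mean/sd for age, truncated to 18-70.
#' @param correlation_targets optional list of targets, each
#'   `list(marker = "wbc", feature = "coating_CON", rho = -0.32)` with
#'   optional `feature_mean`/`feature_sd`: a Gaussian copula induces the
#'   requested population Spearman correlation between the marker and an
#'   added numeric feature column, within each group.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_glm = 40L, n_control = 40L,
                        category_probs = NULL, marker_params = NULL,
                        age_params = list(GLM = c(mean = 34.10, sd = 11.03),
                                          control = c(mean = 33.13, sd = 8.47)),
                        correlation_targets = NULL, seed = 1L) {
  assert_scalar_number(n_glm, "n_glm", lo = 1)
  assert_scalar_number(n_control, "n_control", lo = 1)
  assert_scalar_number(seed, "seed")
  probs <- default_category_probs()
  if (!is.null(category_probs)) probs[names(category_probs)] <- category_probs
  for (feat in names(probs)) {
    for (grp in c("GLM", "control")) {
      p <- probs[[feat]][[grp]]
      if (anyNA(p) || any(p < 0) || any(p > 1)) {
        stop_field(feat, sprintf("probabilities for group %s must lie in [0, 1]", grp))
      }
      if (feat %in% .exclusive_features && abs(sum(p) - 1) > 1e-8) {
        stop_field(feat, sprintf("probabilities for group %s must sum to 1", grp))
      }
    }
  }
  markers <- default_marker_params()
  if (!is.null(marker_params)) markers[names(marker_params)] <- marker_params
  for (mk in names(markers)) {
    for (grp in c("GLM", "control")) {
      mp <- markers[[mk]][[grp]]
      if (mp$median <= 0 || any(mp$range <= 0) || mp$range[1] >= mp$range[2]) {
        stop_field(mk, "marker medians and ranges must be positive with range[1] < range[2]")
      }
    }
  }
  if (!is.null(correlation_targets)) {
    for (ct in correlation_targets) {
      if (!ct$marker %in% .marker_names) stop_field("correlation_targets", "unknown marker")
      assert_scalar_number(ct$rho, "rho", lo = -1, hi = 1)
    }
  }
  structure(list(n_glm = as.integer(n_glm), n_control = as.integer(n_control),
                 category_probs = probs, marker_params = markers,
                 age_params = age_params,
                 correlation_targets = correlation_targets,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated log-normal quantile transform: u in (0,1) -> value in [lo, hi]
.qlnorm_trunc <- function(u, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + u * (phi - plo), meanlog, sdlog)
}

# sdlog is set from the printed range (~98% envelope); meanlog is then solved
# so the RANGE-TRUNCATED distribution's median equals the printed median —
# plain log(median) would drift when the median sits asymmetrically within
# the log-range (e.g. IL-2).
.marker_meansd <- function(mp) {
  sdlog <- log(mp$range[2] / mp$range[1]) / (2 * 2.326)
  trunc_median <- function(ml) {
    u <- (stats::plnorm(mp$range[1], ml, sdlog) +
            stats::plnorm(mp$range[2], ml, sdlog)) / 2
    stats::qlnorm(u, ml, sdlog)
  }
  meanlog <- stats::uniroot(function(ml) trunc_median(ml) - mp$median,
                            interval = log(mp$range), tol = 1e-10)$root
  c(meanlog = meanlog, sdlog = sdlog)
}

#' Generate a synthetic cohort
#'
#' Draws `n_glm + n_control` subject records: categorical tongue features
#' from the per-group probabilities, age from a truncated normal, and blood
#' markers from truncated log-normals. Correlation targets add numeric
#' feature columns rank-correlated with their marker through a Gaussian
#' copula (the bivariate-normal correlation is set to
#' \eqn{2 \sin(\pi \rho_S / 6)} so the population Spearman correlation equals
#' the target). Reproducible: the output is a pure function of the spec.
#'
#' @param spec a [cohort_spec].
#' @return A data.frame of subject records (one row per subject).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- c(GLM = spec$n_glm, control = spec$n_control)
  with_seed(spec$seed, {
    groups <- rep(c("GLM", "control"), times = n)
    total <- sum(n)
    rec <- data.frame(subject_id = sprintf("S%04d", seq_len(total)),
                      group = groups, stringsAsFactors = FALSE)
    # age
    rec$age <- NA_real_
    for (grp in c("GLM", "control")) {
      ap <- spec$age_params[[grp]]
      sel <- groups == grp
      u <- stats::runif(sum(sel))
      plo <- stats::pnorm(18, ap["mean"], ap["sd"])
      phi <- stats::pnorm(70, ap["mean"], ap["sd"])
      rec$age[sel] <- stats::qnorm(plo + u * (phi - plo), ap["mean"], ap["sd"])
    }
    # categorical features
    for (feat in names(spec$category_probs)) {
      vals <- character(total)
      for (grp in c("GLM", "control")) {
        sel <- groups == grp
        p <- spec$category_probs[[feat]][[grp]]
        if (feat %in% .exclusive_features) {
          vals[sel] <- sample(names(p), sum(sel), replace = TRUE, prob = p)
        } else {
          pos <- stats::runif(sum(sel)) < p
          vals[sel] <- ifelse(pos, .binary_positive[[feat]], .binary_negative[[feat]])
        }
      }
      rec[[feat]] <- vals
    }
    # markers (plain draws; copula targets overwrite their marker below)
    for (mk in .marker_names) {
      vals <- numeric(total)
      for (grp in c("GLM", "control")) {
        sel <- groups == grp
        mp <- spec$marker_params[[mk]][[grp]]
        ms <- .marker_meansd(mp)
        u <- stats::runif(sum(sel))
        vals[sel] <- .qlnorm_trunc(u, ms["meanlog"], ms["sdlog"],
                                   mp$range[1], mp$range[2])
      }
      rec[[mk]] <- vals
    }
    # copula-induced marker-feature rank correlations
    for (ct in spec$correlation_targets) {
      rp <- 2 * sin(pi * ct$rho / 6)
      f_mean <- if (is.null(ct$feature_mean)) 100 else ct$feature_mean
      f_sd <- if (is.null(ct$feature_sd)) 30 else ct$feature_sd
      fvals <- numeric(total)
      for (grp in c("GLM", "control")) {
        sel <- groups == grp
        m <- sum(sel)
        z1 <- stats::rnorm(m)
        z2 <- rp * z1 + sqrt(1 - rp^2) * stats::rnorm(m)
        mp <- spec$marker_params[[ct$marker]][[grp]]
        ms <- .marker_meansd(mp)
        rec[[ct$marker]][sel] <- .qlnorm_trunc(stats::pnorm(z1),
                                               ms["meanlog"], ms["sdlog"],
                                               mp$range[1], mp$range[2])
        fvals[sel] <- f_mean + f_sd * z2
      }
      rec[[ct$feature]] <- fvals
    }
    rec
  })
}

#' Write / read a cohort table as CSV
#'
#' One header row; columns `subject_id, group, age,` the nine categorical
#' features, and the six blood markers, plus any induced feature columns.
#'
#' @param records cohort data.frame from [generate_cohort()].
#' @param path file path.
#' @return `read_cohort_csv` returns the validated data.frame.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("group", "age", .exclusive_features, .binary_features, .marker_names)
  missing <- setdiff(required, names(rec))
  if (length(missing) > 0) {
    stop(sprintf("cohort schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rec
}
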