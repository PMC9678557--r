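# Logistic regression: the closed-form 2x2 (single binary predictor) fit and
# the general Newton-Raphson/IRLS maximum-likelihood fit, with Wald odds
# ratios and 95% confidence intervals.

.z975 <- 1.959964  # qnorm(0.975) to the precision printed CI bounds require

.logistic_fit_obj <- function(coefficients, standard_errors, converged, n_iter,
                              method, names = NULL) {
  if (!is.null(names)) {
    names(coefficients) <- names
    names(standard_errors) <- names
  }
  z <- coefficients / standard_errors
  structure(list(coefficients = coefficients,
                 standard_errors = standard_errors,
                 odds_ratios = exp(coefficients),
                 ci_low = exp(coefficients - .z975 * standard_errors),
                 ci_high = exp(coefficients + .z975 * standard_errors),
                 p_values = 2 * stats::pnorm(-abs(z)),
                 converged = converged, n_iter = n_iter, method = method),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s (%sconverged, %d iterations)\n",
              x$method, if (x$converged) "" else "NOT ", x$n_iter))
  print(data.frame(coef = x$coefficients, se = x$standard_errors,
                   OR = x$odds_ratios, ci_low = x$ci_low, ci_high = x$ci_high,
                   p = x$p_values))
  invisible(x)
}

#' Univariate logistic regression on a 2x2 table
#'
#' For a single binary predictor the logistic MLE is available in closed
#' form: the odds ratio is the cross-product ratio ad/(bc), and the standard
#' error of the log odds ratio is \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}
#' (Woolf). The 95% CI is the Wald interval \eqn{\exp(\log OR \pm 1.959964
#' \cdot SE)} and the p-value the two-sided Wald test.
#'
#' @param t 2x2 count matrix, rows = exposure yes/no, columns = case/control
#'   (a = exposed cases, b = exposed controls, c = unexposed cases, d =
#'   unexposed controls).
#' @param haldane apply the Haldane-Anscombe +0.5 correction to every cell.
#'   Off by default: a zero cell is an error (the MLE does not exist).
#' @return A `logistic_fit` for the exposure coefficient (no intercept row).
#' @examples
#' logistic_univariate_2x2(matrix(c(38, 6, 2, 34), 2))  # OR = 107.667
#' @export
logistic_univariate_2x2 <- function(t, haldane = FALSE) {
  t <- .as_2x2(t)
  if (any(t == 0)) {
    if (!haldane) {
      stop("separation: OR undefined (zero cell; set haldane = TRUE to apply the +0.5 correction)",
           call. = FALSE)
    }
    t <- t + 0.5
  }
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  .logistic_fit_obj(log_or, se, converged = TRUE, n_iter = 0L,
                    method = "univariate 2x2 (closed form)", names = "exposure")
}

#' Logistic regression by Newton-Raphson / IRLS
#'
#' Maximises the Bernoulli log-likelihood by iteratively reweighted least
#' squares. Convergence is declared when the maximum absolute score (gradient
#' component) falls below `tol`; the fit stops after `max_iter` iterations.
#' Wald standard errors come from the inverse observed information at the
#' optimum. Diverging coefficients (perfect separation) are flagged via
#' `converged = FALSE` rather than raising an error.
#'
#' @param y binary 0/1 outcome vector.
#' @param X design matrix including the intercept column.
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 50).
#' @return A `logistic_fit` with one row per design column.
#' @export
logistic_fit <- function(y, X, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!is_binary01(y)) stop_field("y", "must be a binary 0/1 vector")
  if (length(unique(y)) < 2L) stop_field("y", "must contain both classes")
  if (nrow(X) != length(y)) stop_field("X", "row count must match length(y)")
  if (nrow(X) <= ncol(X)) stop_field("X", "need more observations than predictors")
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      diverged <- TRUE
      break
    }
    beta <- beta + step
    if (max(abs(beta)) > 30) {  # log-odds beyond any data scale: separation
      diverged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- mu * (1 - mu)
  info <- crossprod(X * w, X)
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(cov))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p) - 1L)
  .logistic_fit_obj(beta, se, converged = converged && !diverged, n_iter = iter,
                    method = "Newton-Raphson IRLS", names = nm)
}
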