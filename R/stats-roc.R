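# ROC / AUC for binary and continuous markers, with Hanley-McNeil confidence
# intervals and a two-sided test against AUC = 0.5.

.hanley_mcneil_se <- function(auc, n1, n2) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n2 - 1) * (q2 - auc^2)) /
         (n1 * n2))
}

.roc_result <- function(auc, n1, n2) {
  se <- .hanley_mcneil_se(auc, n1, n2)
  se0 <- .hanley_mcneil_se(0.5, n1, n2)  # SE under the null AUC = 0.5
  z <- (auc - 0.5) / se0
  structure(list(auc = auc,
                 ci_low = max(0, auc - .z975 * se),
                 ci_high = min(1, auc + .z975 * se),
                 se = se,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n_cases = n1, n_controls = n2),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f, 95%% CI (%.4f, %.4f), p vs 0.5 = %.4g  [%d cases, %d controls]\n",
              x$auc, x$ci_low, x$ci_high, x$p_value, x$n_cases, x$n_controls))
  invisible(x)
}

#' ROC AUC of a binary marker from 2x2 counts
#'
#' For a yes/no marker the ROC curve has a single interior operating point,
#' and the area reduces to (sensitivity + specificity) / 2 — identical to the
#' midrank Mann-Whitney AUC of the 0/1 scores. The 95% CI uses the
#' Hanley-McNeil standard error at the estimated AUC; the two-sided p-value
#' tests AUC = 0.5 with the Hanley-McNeil standard error evaluated under the
#' null.
#'
#' @param exposed_cases,total_cases marker-positive and total case counts.
#' @param exposed_controls,total_controls same for controls.
#' @return A `roc_result`.
#' @examples
#' roc_auc_binary(38, 40, 6, 40)  # AUC = 0.900
#' @export
roc_auc_binary <- function(exposed_cases, total_cases, exposed_controls, total_controls) {
  assert_scalar_number(total_cases, "total_cases", lo = 1)
  assert_scalar_number(total_controls, "total_controls", lo = 1)
  assert_scalar_number(exposed_cases, "exposed_cases", lo = 0, hi = total_cases)
  assert_scalar_number(exposed_controls, "exposed_controls", lo = 0, hi = total_controls)
  sens <- exposed_cases / total_cases
  spec <- 1 - exposed_controls / total_controls
  .roc_result((sens + spec) / 2, total_cases, total_controls)
}

#' ROC AUC of a continuous marker
#'
#' Rank-based (trapezoidal) AUC with ties at midrank: the probability that a
#' random case outscores a random control, counting ties as 1/2. Reduces to
#' [roc_auc_binary()] on 0/1 scores. CI and p-value as there.
#'
#' @param scores numeric marker values (higher = more case-like).
#' @param labels binary labels (1/TRUE = case).
#' @return A `roc_result`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!is_binary01(labels)) stop_field("labels", "must be binary 0/1")
  if (length(scores) != length(labels)) stop_field("scores", "must pair with labels")
  n1 <- sum(labels == 1); n2 <- sum(labels == 0)
  if (n1 == 0 || n2 == 0) stop_field("labels", "both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  .roc_result(auc, n1, n2)
}
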