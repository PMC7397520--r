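#' Cross-tabulate predicted perfusion loss against observed outcome
#'
#' Builds the 2x2 table of predicted perfusion status versus the observed
#' outcome at follow-up. A true positive is a patient predicted to lose
#' perfusion (`predicted_onfh`) who develops osteonecrosis (`onfh`); a true
#' negative is a `predicted_viable` patient who achieves union.
#'
#' @param outcomes Character vector of observed outcomes, `"onfh"`/`"union"`.
#' @param predictions Character vector of the same length,
#'   `"predicted_onfh"`/`"predicted_viable"`.
#' @return An object of class `contingency_table` with integer fields `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
#' @examples
#' contingency(c("onfh", "union"), c("predicted_onfh", "predicted_viable"))
contingency <- function(outcomes, predictions) {
  if (length(outcomes) != length(predictions))
    stop("`outcomes` and `predictions` differ in length", call. = FALSE)
  if (length(outcomes) == 0L)
    stop("empty label sequences", call. = FALSE)
  bad_o <- setdiff(unique(outcomes), c("onfh", "union"))
  bad_p <- setdiff(unique(predictions), c("predicted_onfh", "predicted_viable"))
  if (length(bad_o) || length(bad_p))
    stop("unknown labels: ", paste(c(bad_o, bad_p), collapse = ", "),
         call. = FALSE)
  structure(
    list(
      tp = sum(predictions == "predicted_onfh" & outcomes == "onfh"),
      fp = sum(predictions == "predicted_onfh" & outcomes == "union"),
      fn = sum(predictions == "predicted_viable" & outcomes == "onfh"),
      tn = sum(predictions == "predicted_viable" & outcomes == "union")
    ),
    class = "contingency_table"
  )
}

#' Construct a contingency table from counts
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts.
#' @return An object of class `contingency_table`.
#' @export
#' @examples
#' contingency_table(tp = 5, fp = 6, fn = 1, tn = 18)
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  structure(lapply(as.list(cells), as.integer), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("predicted_onfh", "predicted_viable"),
                              c("onfh", "union")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a 2x2 table
#'
#' @param table A `contingency_table`.
#' @return A list with `sensitivity` (`tp / (tp + fn)`), `specificity`
#'   (`tn / (tn + fp)`) and `accuracy` (`(tp + tn) / total`), as
#'   proportions.
#' @export
#' @examples
#' m <- accuracy_metrics(contingency_table(5, 6, 1, 18))
#' round(100 * unlist(m), 1)  # 83.3, 75.0, 76.7
accuracy_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  npos <- table$tp + table$fn
  nneg <- table$tn + table$fp
  total <- npos + nneg
  if (npos == 0L)
    stop("sensitivity undefined: no observed-positive cases (tp + fn = 0)",
         call. = FALSE)
  if (nneg == 0L)
    stop("specificity undefined: no observed-negative cases (tn + fp = 0)",
         call. = FALSE)
  list(sensitivity = table$tp / npos,
       specificity = table$tn / nneg,
       accuracy = (table$tp + table$tn) / total)
}

#' Likelihood ratios with log-method confidence intervals
#'
#' Computes the positive and negative likelihood ratios
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec` and their
#' confidence intervals by the log method:
#' `exp(log(LR) +/- z * SE(log LR))` with
#' `SE(log LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` and
#' `SE(log LR-) = sqrt(1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn))`.
#' A perfect specificity yields an infinite LR+ (CI omitted); a perfect
#' sensitivity yields LR- = 0 (CI omitted).
#'
#' @param table A `contingency_table`.
#' @param alpha Significance level; the CIs are at level `1 - alpha`.
#' @param haldane If `TRUE`, add 0.5 to every cell *for the CI computation
#'   only* when any cell entering an SE term is zero (flagged in the
#'   result). Off by default.
#' @return An object of class `likelihood_ratios`: `lr_pos`, `ci_lr_pos`,
#'   `lr_neg`, `ci_lr_neg` (each CI a `c(lower, upper)` pair or `NULL` when
#'   the LR is degenerate), `alpha`, and `haldane_applied`.
#' @export
#' @examples
#' lr <- likelihood_ratios(contingency_table(5, 6, 1, 18))
#' round(c(lr$lr_pos, lr$ci_lr_pos), 2)  # 3.33, 1.52, 7.27
likelihood_ratios <- function(table, alpha = 0.05, haldane = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  met <- accuracy_metrics(table)
  sens <- met$sensitivity
  spec <- met$specificity
  z <- stats::qnorm(1 - alpha / 2)

  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (spec == 0) NaN else (1 - sens) / spec

  haldane_applied <- FALSE
  ci_cells <- table
  zero_cell <- with(table, tp == 0 || fp == 0 || fn == 0 || tn == 0)
  if (haldane && zero_cell) {
    ci_cells <- list(tp = table$tp + 0.5, fp = table$fp + 0.5,
                     fn = table$fn + 0.5, tn = table$tn + 0.5)
    haldane_applied <- TRUE
  }

  log_ci <- function(lr, se) {
    if (!is.finite(lr) || lr <= 0 || !is.finite(se)) return(NULL)
    lr * exp(c(-1, 1) * z * se)
  }
  ci_pos <- ci_neg <- NULL
  if (is.finite(lr_pos) && lr_pos > 0) {
    se_pos <- with(ci_cells,
                   suppressWarnings(sqrt(1 / tp - 1 / (tp + fn) +
                                           1 / fp - 1 / (fp + tn))))
    ci_pos <- log_ci(if (haldane_applied)
      (ci_cells$tp / (ci_cells$tp + ci_cells$fn)) /
        (ci_cells$fp / (ci_cells$fp + ci_cells$tn)) else lr_pos, se_pos)
  }
  if (is.finite(lr_neg) && lr_neg > 0) {
    se_neg <- with(ci_cells,
                   suppressWarnings(sqrt(1 / fn - 1 / (tp + fn) +
                                           1 / tn - 1 / (fp + tn))))
    ci_neg <- log_ci(if (haldane_applied)
      (ci_cells$fn / (ci_cells$tp + ci_cells$fn)) /
        (ci_cells$tn / (ci_cells$fp + ci_cells$tn)) else lr_neg, se_neg)
  }

  structure(
    list(lr_pos = lr_pos, ci_lr_pos = ci_pos,
         lr_neg = lr_neg, ci_lr_neg = ci_neg,
         alpha = alpha, haldane_applied = haldane_applied),
    class = "likelihood_ratios"
  )
}

#' @export
print.likelihood_ratios <- function(x, ...) {
  fmt_ci <- function(ci) if (is.null(ci)) "CI omitted"
    else sprintf("%d%% CI (%.2f, %.2f)", round(100 * (1 - x$alpha)), ci[1], ci[2])
  cat(sprintf("LR+ %.2f  %s\n", x$lr_pos, fmt_ci(x$ci_lr_pos)))
  cat(sprintf("LR- %.2f  %s\n", x$lr_neg, fmt_ci(x$ci_lr_neg)))
  if (x$haldane_applied) cat("(Haldane 0.5 correction applied to CIs)\n")
  invisible(x)
}
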