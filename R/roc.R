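# ROC construction, Youden cutoff derivation and DeLong AUC comparison.
#
# Perfusion ratios are negatively oriented (a LOW ratio indicates a
# perfusion deficit), so the default sweep calls a case test-positive when
# its score is <= the threshold.  Internally every sweep is reduced to the
# "higher is positive" convention by negating scores, which keeps the
# trapezoid / pair-count identity and the DeLong placements on one code
# path.

check_roc_input <- function(scores, outcomes) {
  if (length(scores) != length(outcomes))
    stop("`scores` and `outcomes` differ in length", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  bad <- setdiff(unique(outcomes), c("onfh", "union"))
  if (length(bad))
    stop("unknown outcome labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pos <- outcomes == "onfh"
  if (!any(pos) || all(pos))
    stop("ROC undefined: need at least one positive and one negative outcome",
         call. = FALSE)
  pos
}

#' Build an ROC curve by threshold sweep
#'
#' Sweeps the distinct score values as thresholds. With the default
#' `lower_is_positive` orientation a case is test-positive when its score
#' is at or below the threshold; tied scores enter at a single threshold.
#' The curve starts at (0, 0) (sentinel threshold classifying nothing
#' positive) and ends at (1, 1); its AUC is the trapezoidal area, which
#' equals the Mann-Whitney pair-count AUC exactly.
#'
#' @param scores Numeric scores (e.g. uptake ratios), one per case.
#' @param outcomes Observed outcome labels, `"onfh"` (positive) /
#'   `"union"` (negative).
#' @param orientation `"lower_is_positive"` (default: low ratio = deficit)
#'   or `"higher_is_positive"`.
#' @return An object of class `roc_curve`: `thresholds` (sentinel first),
#'   `fpr`, `tpr`, `sensitivity`, `specificity`, `auc`, `n_pos`, `n_neg`,
#'   `orientation`.
#' @export
#' @examples
#' rc <- roc_curve(c(0.3, 0.4, 1.0, 1.2), c("onfh", "onfh", "union", "union"))
#' rc$auc  # 1: perfect separation
roc_curve <- function(scores, outcomes,
                      orientation = c("lower_is_positive",
                                      "higher_is_positive")) {
  orientation <- match.arg(orientation)
  pos <- check_roc_input(scores, outcomes)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)

  # reduce to higher-is-positive risk scale
  risk <- if (orientation == "lower_is_positive") -scores else scores
  ord <- order(risk, decreasing = TRUE)
  risk_sorted <- risk[ord]
  pos_sorted <- pos[ord]
  grp <- cumsum(!duplicated(risk_sorted))        # tie groups, descending risk
  tp_cum <- cumsum(pos_sorted)
  fp_cum <- cumsum(!pos_sorted)
  last <- !duplicated(grp, fromLast = TRUE)      # last index of each group
  tpr <- c(0, tp_cum[last] / n_pos)
  fpr <- c(0, fp_cum[last] / n_neg)

  risk_thresholds <- risk_sorted[last]
  thresholds <- if (orientation == "lower_is_positive")
    c(-Inf, -risk_thresholds) else c(Inf, risk_thresholds)

  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(thresholds = thresholds, fpr = fpr, tpr = tpr,
         sensitivity = tpr, specificity = 1 - fpr,
         auc = auc, n_pos = n_pos, n_neg = n_neg,
         orientation = orientation),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d pos / %d neg, %s, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$orientation, x$auc))
  invisible(x)
}

#' Plot method for ROC curves
#'
#' @param x A `roc_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Mann-Whitney pair-count AUC
#'
#' The probability that a randomly chosen positive case is ranked as more
#' diseased than a randomly chosen negative case, counting tied pairs as
#' one half: `(concordant + tied / 2) / (n_pos * n_neg)`. Serves as the
#' pair-counting equivalent of the trapezoidal ROC area; the two are
#' identical on every input.
#'
#' @inheritParams roc_curve
#' @return The AUC, a value in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, outcomes,
                             orientation = c("lower_is_positive",
                                             "higher_is_positive")) {
  orientation <- match.arg(orientation)
  pos <- check_roc_input(scores, outcomes)
  risk <- if (orientation == "lower_is_positive") -scores else scores
  # midrank formulation of the pair count
  r <- rank(risk)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-index optimal cutoff
#'
#' Scans every threshold of an ROC curve and returns the one maximizing
#' Youden's J = sensitivity + specificity - 1. Ties are broken toward
#' higher specificity, then toward the lower threshold. The reported
#' cutoff is the midpoint between the optimal threshold's score and the
#' next distinct score (the decision boundary can sit anywhere between
#' two adjacent observed values; the midpoint is the natural
#' representative and yields round cutoffs for well-separated groups).
#'
#' @param curve A `roc_curve`.
#' @return A list: `cutoff` (midpoint form), `threshold` (observed-score
#'   form), `sensitivity`, `specificity`, `youden_j`.
#' @export
#' @examples
#' rc <- roc_curve(c(0.35, 0.45, 0.55, 1.3), c("onfh", "onfh", "union", "union"))
#' youden_cutoff(rc)$cutoff  # 0.5
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) {                      # higher specificity first
    best <- best[curve$specificity[best] == max(curve$specificity[best])]
    thr <- curve$thresholds[best]
    best <- best[which.min(thr)]                # then lower threshold
  }
  k <- best
  thr <- curve$thresholds[k]
  # midpoint with the adjacent distinct threshold on the positive side
  nxt <- if (k < length(curve$thresholds)) curve$thresholds[k + 1L] else NA_real_
  cutoff <- if (is.finite(thr) && !is.na(nxt) && is.finite(nxt))
    (thr + nxt) / 2 else thr
  list(cutoff = cutoff, threshold = thr,
       sensitivity = curve$sensitivity[k],
       specificity = curve$specificity[k],
       youden_j = j[k])
}

# Placement values of one score vector: V10 (per positive) and V01 (per
# negative), ties counting one half.  `risk` is on the higher-is-positive
# scale.
delong_placements <- function(risk, pos) {
  psi <- outer(risk[pos], risk[!pos],
               function(x, y) (x > y) + 0.5 * (x == y))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' Variance of a single AUC by DeLong's structural components
#'
#' @inheritParams roc_curve
#' @return A list with `auc` and `variance`.
#' @export
delong_variance <- function(scores, outcomes,
                            orientation = c("lower_is_positive",
                                            "higher_is_positive")) {
  orientation <- match.arg(orientation)
  pos <- check_roc_input(scores, outcomes)
  risk <- if (orientation == "lower_is_positive") -scores else scores
  pl <- delong_placements(risk, pos)
  m <- sum(pos); n <- sum(!pos)
  v <- (if (m > 1) stats::var(pl$v10) / m else 0) +
    (if (n > 1) stats::var(pl$v01) / n else 0)
  list(auc = pl$auc, variance = v)
}

#' DeLong test comparing two AUCs
#'
#' Nonparametric comparison of the areas under two ROC curves using
#' placement-value (structural-components) variance estimates. In the
#' paired form both score vectors belong to the same cases and the
#' covariance of the placements is carried into the variance of the AUC
#' difference; the unpaired form compares curves from independent cohorts
#' (covariance 0).
#'
#' @param scores_a,scores_b Score vectors for the two markers.
#' @param outcomes Outcome labels for `scores_a` (and for `scores_b` when
#'   paired).
#' @param outcomes_b Outcome labels for `scores_b` in the unpaired case;
#'   ignored when `paired = TRUE`.
#' @param orientation Score orientation, shared by both markers.
#' @param paired If `TRUE` (default) both scores are measured on the same
#'   cases.
#' @return An object of class `delong_result`: `auc_a`, `auc_b`,
#'   `variance_a`, `variance_b`, `covariance`, `z_statistic`, `p_value`,
#'   `paired`.
#' @export
#' @examples
#' s <- c(0.3, 0.4, 0.8, 1.1, 0.9, 1.3)
#' y <- c("onfh", "onfh", "onfh", "union", "union", "union")
#' delong_test(s, s, y)$p_value  # 1: self-comparison
delong_test <- function(scores_a, scores_b, outcomes, outcomes_b = NULL,
                        orientation = c("lower_is_positive",
                                        "higher_is_positive"),
                        paired = TRUE) {
  orientation <- match.arg(orientation)
  pos_a <- check_roc_input(scores_a, outcomes)
  if (paired) {
    if (length(scores_b) != length(scores_a))
      stop("paired comparison requires equal-length score vectors",
           call. = FALSE)
    pos_b <- pos_a
  } else {
    if (is.null(outcomes_b))
      stop("`outcomes_b` is required for an unpaired comparison",
           call. = FALSE)
    pos_b <- check_roc_input(scores_b, outcomes_b)
  }
  if (sum(pos_a) < 2L || sum(!pos_a) < 2L ||
      sum(pos_b) < 2L || sum(!pos_b) < 2L)
    stop("DeLong test needs at least 2 cases per class per curve",
         call. = FALSE)

  flip <- if (orientation == "lower_is_positive") -1 else 1
  pa <- delong_placements(flip * scores_a, pos_a)
  pb <- delong_placements(flip * scores_b, pos_b)
  m_a <- sum(pos_a); n_a <- sum(!pos_a)
  m_b <- sum(pos_b); n_b <- sum(!pos_b)

  var_a <- stats::var(pa$v10) / m_a + stats::var(pa$v01) / n_a
  var_b <- stats::var(pb$v10) / m_b + stats::var(pb$v01) / n_b
  cov_ab <- if (paired)
    stats::cov(pa$v10, pb$v10) / m_a + stats::cov(pa$v01, pb$v01) / n_a
  else 0

  diff <- pa$auc - pb$auc
  var_diff <- var_a + var_b - 2 * cov_ab
  if (var_diff <= .Machine$double.eps^0.5) {
    if (abs(diff) <= .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      stop("degenerate variance of the AUC difference with unequal AUCs",
           call. = FALSE)
    }
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = pa$auc, auc_b = pb$auc,
         variance_a = var_a, variance_b = var_b, covariance = cov_ab,
         z_statistic = z, p_value = p, paired = paired),
    class = "delong_result"
  )
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong %s comparison: AUC %.4f vs %.4f, z = %.3f, p = %.4f\n",
              if (x$paired) "paired" else "unpaired",
              x$auc_a, x$auc_b, x$z_statistic, x$p_value))
  invisible(x)
}
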