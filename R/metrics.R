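# Validity and reliability measures used to benchmark VA cause assignment
# against a reference standard: one-vs-rest sensitivity/specificity/PPV/NPV,
# Cohen's kappa, CSMF accuracy, chance-corrected concordance, Lin's
# concordance correlation of CSMFs, and a rank-based AUC. Degenerate inputs
# yield NA with an "undefined" attribute, never a silent 0.

undef <- function() structure(NA_real_, undefined = TRUE)

#' Cross-tabulate true vs assigned causes
#'
#' @param true,assigned Character vectors of va_codes, aligned by record.
#' @param cause_levels Cause universe (default: union of both vectors,
#'   sorted). The matrix is square and ordered by it.
#' @return Integer matrix, rows = true cause, columns = assigned cause,
#'   class \code{va_confusion}.
#' @export
confusion_matrix <- function(true, assigned, cause_levels = NULL) {
  if (length(true) != length(assigned)) {
    stop("true and assigned must align", call. = FALSE)
  }
  if (is.null(cause_levels)) cause_levels <- sort(union(true, assigned))
  m <- table(factor(true, levels = cause_levels),
             factor(assigned, levels = cause_levels))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("true", "assigned")
  structure(m, class = c("va_confusion", class(m)))
}

#' One-vs-rest binary metrics for a cause
#'
#' Collapses the confusion matrix to cause-vs-rest and reports sensitivity,
#' specificity, positive and negative predictive value. A zero denominator
#' (e.g. PPV for a never-assigned cause) is returned as \code{NA} with
#' attribute \code{undefined = TRUE}.
#'
#' @param confusion A [confusion_matrix()].
#' @param cause A cause present in the matrix.
#' @return Named list: \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv}.
#' @export
binary_metrics <- function(confusion, cause) {
  if (!cause %in% rownames(confusion)) {
    stop("cause not in confusion matrix: ", cause, call. = FALSE)
  }
  tp <- confusion[cause, cause]
  fn <- sum(confusion[cause, ]) - tp
  fp <- sum(confusion[, cause]) - tp
  tn <- sum(confusion) - tp - fn - fp
  ratio <- function(num, den) if (den == 0) undef() else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn))
}

#' Cohen's kappa for a confusion matrix
#'
#' Chance-corrected overall agreement \eqn{(p_o - p_e)/(1 - p_e)} with
#' expected agreement from the marginal products. \eqn{p_e = 1} (both
#' raters degenerate on one cause) is undefined.
#'
#' @param confusion A [confusion_matrix()].
#' @return Numeric kappa, or \code{NA} (attr \code{undefined}) when
#'   degenerate.
#' @export
cohens_kappa <- function(confusion) {
  n <- sum(confusion)
  if (n == 0) return(undef())
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) return(undef())
  (po - pe) / (1 - pe)
}

#' CSMF accuracy
#'
#' \deqn{1 - \frac{\sum_j |pred_j - true_j|}{2 (1 - \min_j true_j)}}
#' i.e. 1 minus total variation distance normalized by the worst error
#' achievable against the true distribution; 1 for identical CSMFs, 0 for
#' the worst possible prediction. The minimum runs over the declared cause
#' list as given — appending a cause with true = pred = 0 changes the
#' normalizer (it drives \eqn{\min_j true_j} to 0); callers choose the
#' universe deliberately. A degenerate truth (point mass, min = 1 with one
#' cause) is undefined.
#'
#' @param true_csmf,pred_csmf Nonnegative fraction vectors over the same
#'   ordered cause list, each summing to 1 (tolerance 1e-6).
#' @return Numeric in \code{[0, 1]}, or \code{NA} (attr \code{undefined}).
#' @examples
#' csmf_accuracy(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2))  # 0.75
#' @export
csmf_accuracy <- function(true_csmf, pred_csmf) {
  true_csmf <- as.numeric(true_csmf); pred_csmf <- as.numeric(pred_csmf)
  if (length(true_csmf) != length(pred_csmf)) {
    stop("CSMF vectors must align", call. = FALSE)
  }
  if (abs(sum(true_csmf) - 1) > 1e-6 || abs(sum(pred_csmf) - 1) > 1e-6) {
    stop("CSMF vectors must sum to 1", call. = FALSE)
  }
  worst <- 2 * (1 - min(true_csmf))
  if (worst == 0) return(undef())
  1 - sum(abs(pred_csmf - true_csmf)) / worst
}

#' Chance-corrected concordance
#'
#' Per-cause top-1 agreement rescaled so that random assignment among the N
#' declared causes scores 0 and perfect assignment 1:
#' \deqn{CCC_j = \frac{P(assigned = j | true = j) - 1/N}{1 - 1/N}}
#' The average runs over causes with at least one true death (the others
#' are \code{NA}).
#'
#' @param confusion A [confusion_matrix()] with N >= 2 causes.
#' @return List with \code{per_cause} (named vector, \code{NA} where no
#'   true deaths) and \code{average}.
#' @export
chance_corrected_concordance <- function(confusion) {
  n_causes <- nrow(confusion)
  if (n_causes < 2L) stop("need at least 2 causes", call. = FALSE)
  truth_n <- rowSums(confusion)
  frac <- ifelse(truth_n > 0, diag(confusion) / truth_n, NA_real_)
  per_cause <- (frac - 1 / n_causes) / (1 - 1 / n_causes)
  names(per_cause) <- rownames(confusion)
  list(per_cause = per_cause,
       average = mean(per_cause, na.rm = TRUE))
}

#' Lin's concordance correlation coefficient of CSMF series
#'
#' Agreement of paired fraction estimates around the identity line:
#' \deqn{\rho_c = \frac{2\,cov(x, y)}{var(x) + var(y) + (\bar x - \bar y)^2}}
#' (population moments). Penalizes location/scale shifts that Pearson
#' correlation ignores. Undefined when both series are constant.
#'
#' @param true_csmf,pred_csmf Numeric vectors of paired fractions (>= 2).
#' @return Numeric in \code{[-1, 1]}, or \code{NA} (attr \code{undefined}).
#' @export
csmf_concordance_correlation <- function(true_csmf, pred_csmf) {
  x <- as.numeric(true_csmf); y <- as.numeric(pred_csmf)
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need >= 2 paired observations", call. = FALSE)
  }
  n <- length(x)
  vx <- stats::var(x) * (n - 1) / n
  vy <- stats::var(y) * (n - 1) / n
  cxy <- stats::cov(x, y) * (n - 1) / n
  den <- vx + vy + (mean(x) - mean(y))^2
  if (den == 0) return(undef())
  2 * cxy / den
}

#' Rank-based AUC for a binary outcome
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midranks for ties: the probability a random positive scores above a
#' random negative (+ half the tie probability).
#'
#' @param truth Logical (or 0/1) vector, TRUE = positive.
#' @param score Numeric score vector.
#' @return Numeric in \code{[0, 1]}, or \code{NA} (attr \code{undefined})
#'   when either class is empty.
#' @export
rank_auc <- function(truth, score) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(undef())
  r <- rank(score)  # midranks for ties
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
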