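# Automated cause-of-death assignment: an InterVA-style Bayesian engine over
# a cause x indicator conditional-probability matrix, and a Tariff-style
# additive scorer. Both are matrix-parameterized; the package never claims
# any particular probability values as endorsed ones — matrices are user
# supplied or synthetic.

#' Construct a conditional-probability matrix
#'
#' P(indicator endorsed | cause) for a set of causes and indicators, plus a
#' baseline (prior) cause distribution.
#'
#' @param p Numeric matrix, rows = indicators, columns = causes, entries in
#'   \code{[0, 1]}; dimnames required (indicator ids, va_codes).
#' @param prior Numeric vector of baseline cause probabilities, one per
#'   column of \code{p}; normalized internally. Default uniform.
#' @return Object of class \code{va_prob_matrix}.
#' @export
va_prob_matrix <- function(p, prior = NULL) {
  p <- as.matrix(p)
  if (is.null(rownames(p)) || is.null(colnames(p))) {
    stop("matrix needs indicator row names and va_code column names",
         call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("conditional probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(prior)) prior <- rep(1, ncol(p))
  if (length(prior) != ncol(p) || any(prior < 0) || sum(prior) <= 0) {
    stop("prior must be a nonnegative vector over the causes", call. = FALSE)
  }
  out <- list(p = p, prior = stats::setNames(prior / sum(prior), colnames(p)))
  class(out) <- "va_prob_matrix"
  out
}

#' @export
print.va_prob_matrix <- function(x, ...) {
  cat("conditional-probability matrix:", nrow(x$p), "indicators x",
      ncol(x$p), "causes\n")
  invisible(x)
}

# likelihood floor: matrix entries are estimates, a literal 0 or 1 must not
# veto the whole posterior on one item
P_FLOOR <- 1e-6

#' Bayesian cause posterior for a record
#'
#' \code{posterior_j} is proportional to \code{prior_j} times the product
#' over endorsed ("yes") indicators of \code{P(i|j)} and, in
#' \code{full_bernoulli} mode, times the product over explicit "no" answers
#' of \code{1 - P(i|j)}. \code{dont_know} and \code{not_applicable}
#' contribute nothing. Probabilities are floored into
#' \code{[1e-6, 1 - 1e-6]} and the product runs in log space.
#'
#' The default \code{positive_only} mode ignores "no" answers, as the
#' InterVA family does; \code{full_bernoulli} also scores the negatives.
#'
#' @param record A [va_record()] (or a named response vector).
#' @param matrix A [va_prob_matrix()].
#' @param mode \code{"positive_only"} (default) or \code{"full_bernoulli"}.
#' @param strict Error if an answered indicator is absent from the matrix
#'   (default FALSE: such answers are ignored, e.g. personal/context items).
#' @return Named numeric posterior over the matrix's causes, summing to 1,
#'   with attribute \code{degenerate = TRUE} when every likelihood
#'   underflowed to zero and the prior was returned instead.
#' @examples
#' m <- va_prob_matrix(matrix(c(0.8, 0.2), 1, 2,
#'                     dimnames = list("i1", c("A", "B"))))
#' bayes_posterior(c(i1 = "yes"), m)  # 0.8, 0.2
#' @export
bayes_posterior <- function(record, matrix, mode = c("positive_only",
                                                     "full_bernoulli"),
                            strict = FALSE) {
  mode <- match.arg(mode)
  responses <- if (inherits(record, "va_record")) record$responses else record
  p <- pmin(pmax(matrix$p, P_FLOOR), 1 - P_FLOOR)
  answered <- names(responses)[responses %in% c("yes", "no")]
  outside <- setdiff(answered, rownames(p))
  if (strict && length(outside)) {
    stop("answered indicator(s) not in the matrix: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  yes <- intersect(names(responses)[responses == "yes"], rownames(p))
  loglik <- colSums(log(p[yes, , drop = FALSE]))
  if (mode == "full_bernoulli") {
    no <- intersect(names(responses)[responses == "no"], rownames(p))
    loglik <- loglik + colSums(log1p(-p[no, , drop = FALSE]))
  }
  logpost <- log(matrix$prior) + loglik
  w <- exp(logpost - max(logpost))
  degenerate <- !any(is.finite(w)) || sum(w) == 0
  post <- if (degenerate) matrix$prior else w / sum(w)
  attr(post, "degenerate") <- degenerate
  post
}

#' Fit a Tariff matrix from training data
#'
#' For each indicator i and cause j the endorsement rate \code{x(i, j)} is
#' the fraction of cause-j training deaths answering "yes". The tariff is
#' the robust-scaled deviation across causes:
#' \deqn{tariff(i, j) = (x(i, j) - median_j x(i, .)) / IQR_j x(i, .)}
#' with quantiles by linear interpolation (R type 7). An indicator whose
#' endorsement rate has zero IQR across causes falls back to scaling by
#' 1.4826 times the median absolute deviation; if that is also zero (a
#' cause-uninformative row) the whole row is 0.
#'
#' @param records List of [va_record()] training records.
#' @param causes Character vector of true va_codes, one per record.
#' @param cause_levels Cause universe for the matrix columns (default: the
#'   sorted unique training causes). Every level must have at least one
#'   training death.
#' @param indicators Indicator universe for the rows (default: all ids
#'   answered in training).
#' @return Object of class \code{va_tariff_matrix}: list with \code{tariff}
#'   (indicator x cause matrix) and \code{endorsement} (the rates).
#' @export
fit_tariff <- function(records, causes, cause_levels = sort(unique(causes)),
                       indicators = NULL) {
  if (length(records) != length(causes)) {
    stop("one true cause per training record required", call. = FALSE)
  }
  absent <- setdiff(cause_levels, causes)
  if (length(absent)) {
    stop("cause(s) absent from training data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (is.null(indicators)) {
    indicators <- sort(unique(unlist(lapply(records, function(r)
      names(r$responses)))))
  }
  x <- matrix(0, length(indicators), length(cause_levels),
              dimnames = list(indicators, cause_levels))
  for (j in seq_along(cause_levels)) {
    members <- records[causes == cause_levels[j]]
    yes <- vapply(members, function(r) {
      v <- r$responses[indicators]
      !is.na(v) & v == "yes"
    }, logical(length(indicators)))
    x[, j] <- rowMeans(matrix(yes, nrow = length(indicators)))
  }
  tariff <- t(apply(x, 1L, function(row) {
    center <- stats::median(row)
    q <- stats::quantile(row, c(0.25, 0.75), type = 7, names = FALSE)
    scale <- q[2L] - q[1L]
    if (scale == 0) scale <- stats::mad(row)  # 1.4826 * MAD
    if (scale == 0) return(rep(0, length(row)))
    (row - center) / scale
  }))
  dimnames(tariff) <- dimnames(x)
  out <- list(tariff = tariff, endorsement = x)
  class(out) <- "va_tariff_matrix"
  out
}

#' @export
print.va_tariff_matrix <- function(x, ...) {
  cat("tariff matrix:", nrow(x$tariff), "indicators x", ncol(x$tariff),
      "causes\n")
  invisible(x)
}

#' Tariff score vector for a record
#'
#' Additive scoring: \code{score_j} is the sum of \code{tariff(i, j)} over
#' indicators the record endorses ("yes"); no other response counts.
#'
#' @param record A [va_record()] (or named response vector).
#' @param tariff_matrix A [fit_tariff()] result (or a bare tariff matrix).
#' @return Named numeric score vector over causes.
#' @export
tariff_score <- function(record, tariff_matrix) {
  tm <- if (inherits(tariff_matrix, "va_tariff_matrix")) tariff_matrix$tariff
        else as.matrix(tariff_matrix)
  responses <- if (inherits(record, "va_record")) record$responses else record
  yes <- intersect(names(responses)[responses == "yes"], rownames(tm))
  colSums(tm[yes, , drop = FALSE])
}

#' Assign a cause of death to a record
#'
#' Runs the chosen engine and takes the maximum-scoring cause, breaking
#' exact ties by cause order (recorded in the result). With the Bayesian
#' engine, a top posterior below the indeterminacy threshold \code{tau}
#' yields \code{"VA-99"} (cause of death unknown) instead; the default
#' \code{tau = 0} always assigns.
#'
#' @param record A [va_record()].
#' @param engine \code{"bayes"} or \code{"tariff"}.
#' @param matrix A [va_prob_matrix()] (bayes) or [fit_tariff()] result
#'   (tariff).
#' @param tau Indeterminacy threshold in \code{[0, 1]} (bayes only).
#' @param mode Bayesian likelihood mode, see [bayes_posterior()].
#' @return Object of class \code{va_assignment}: list with
#'   \code{record_id}, \code{engine}, \code{scores} (posterior or score
#'   vector), \code{top_cause}, \code{top_value}, \code{tie} flag.
#' @export
assign_cause <- function(record, engine = c("bayes", "tariff"), matrix,
                         tau = 0, mode = "positive_only") {
  engine <- match.arg(engine)
  scores <- switch(engine,
    bayes = bayes_posterior(record, matrix, mode = mode),
    tariff = tariff_score(record, matrix))
  top <- which(scores == max(scores))
  top_cause <- names(scores)[top[1L]]
  top_value <- unname(scores[top[1L]])
  if (engine == "bayes" && top_value < tau) top_cause <- "VA-99"
  out <- list(record_id = if (inherits(record, "va_record")) record$record_id
              else NA_character_,
              engine = engine, scores = scores, top_cause = top_cause,
              top_value = top_value, tie = length(top) > 1L)
  class(out) <- "va_assignment"
  out
}

#' @export
print.va_assignment <- function(x, ...) {
  cat(x$record_id, "->", x$top_cause,
      sprintf("(%s, %.4g%s)\n", x$engine, x$top_value,
              if (x$tie) ", tie" else ""))
  invisible(x)
}

#' Cause-specific mortality fractions from assignments
#'
#' @param assignments List of [assign_cause()] results.
#' @param method \code{"top_cause"} tallies each record's top cause;
#'   \code{"posterior_average"} averages the full posterior vectors (bayes
#'   assignments only).
#' @param cause_levels Cause universe for the output; defaults to the score
#'   vector's causes (plus \code{"VA-99"} if any record fell below the
#'   threshold).
#' @return Named fraction vector summing to 1 (class \code{va_csmf}).
#' @export
csmf_from_assignments <- function(assignments,
                                  method = c("top_cause",
                                             "posterior_average"),
                                  cause_levels = NULL) {
  method <- match.arg(method)
  if (!length(assignments)) stop("no assignments supplied", call. = FALSE)
  if (is.null(cause_levels)) {
    cause_levels <- names(assignments[[1L]]$scores)
    tops <- vapply(assignments, `[[`, "", "top_cause")
    cause_levels <- union(cause_levels, tops)
  }
  if (method == "top_cause") {
    tops <- factor(vapply(assignments, `[[`, "", "top_cause"),
                   levels = cause_levels)
    frac <- as.vector(table(tops)) / length(assignments)
  } else {
    mat <- vapply(assignments, function(a) {
      s <- a$scores[cause_levels]
      s[is.na(s)] <- 0
      as.numeric(s)
    }, numeric(length(cause_levels)))
    frac <- rowMeans(matrix(mat, nrow = length(cause_levels)))
    frac <- frac / sum(frac)
  }
  structure(stats::setNames(frac, cause_levels), class = "va_csmf")
}

#' @export
print.va_csmf <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}
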