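# Synthetic VA cohorts with known cause structure. Records are generated
# skip-consistently (gate answers first, follow-ups only behind open gates)
# from a cause sampled off a known CSMF and cause-conditional Bernoulli
# endorsements, so every downstream module is testable without external
# data. Cohorts are statistical test instruments, not epidemiological
# emulations.

#' Build a synthetic indicator registry
#'
#' A minimal registry for simulation studies: \code{n_l1} level-1 items
#' plus optional level-2/3 items hung round-robin under the previous level.
#' All items are CoD-related and applicable to every age group; with
#' \code{n_l2 = n_l3 = 0} the topology is flat (no gates), which keeps the
#' endorsement model exactly the Bernoulli one the Bayesian engine assumes.
#'
#' @param n_l1,n_l2,n_l3 Item counts per skip level.
#' @param prefix Indicator id prefix.
#' @return A \code{va_registry} data.frame (see
#'   [load_indicator_registry()]).
#' @export
synthetic_registry <- function(n_l1, n_l2 = 0L, n_l3 = 0L, prefix = "sym") {
  mk <- function(level, n, parents) {
    if (!n) return(NULL)
    ids <- sprintf("%s_L%d_%03d", prefix, level, seq_len(n))
    data.frame(
      indicator_id = ids,
      label = sprintf("synthetic indicator L%d #%d", level, seq_len(n)),
      category = "cod_related", skip_level = level,
      parent_id = if (length(parents))
        parents[(seq_len(n) - 1L) %% length(parents) + 1L] else "",
      maternal = FALSE, adult = TRUE, child = TRUE, neonate = TRUE,
      stringsAsFactors = FALSE)
  }
  l1 <- mk(1L, n_l1, character())
  l2 <- mk(2L, n_l2, l1$indicator_id)
  l3 <- mk(3L, n_l3, l2$indicator_id)
  reg <- rbind(l1, l2, l3)
  reg$is_gate <- reg$indicator_id %in% reg$parent_id[nzchar(reg$parent_id)]
  class(reg) <- c("va_registry", "data.frame")
  reg
}

#' Generate a synthetic conditional-probability matrix
#'
#' Each indicator gets a shared baseline endorsement probability and one
#' randomly chosen signature cause. The \code{separability} exponent
#' controls how far columns are pulled from the shared baseline toward a
#' near-one-hot signature profile: with weight \eqn{w = 1 - 1/separability}
#' the entry is \eqn{(1-w)\,base_i + w\,s_{ij}} where \eqn{s_{ij}} is 0.95
#' on the signature cause and 0.02 elsewhere. \code{separability = 1}
#' therefore yields identical (cause-uninformative) columns, and
#' increasing it monotonically lowers the expected pairwise column overlap;
#' in the limit each indicator points almost deterministically at one
#' cause.
#'
#' @param causes Character vector of cause codes (>= 2).
#' @param indicators Character vector of indicator ids (>= 1).
#' @param separability Sharpening scalar >= 1.
#' @param seed Integer seed; fixed seed reproduces the matrix.
#' @param prior Prior over causes (default uniform).
#' @return A [va_prob_matrix()].
#' @export
generate_matrix <- function(causes, indicators, separability = 2, seed = 1L,
                            prior = NULL) {
  if (length(causes) < 2L || length(indicators) < 1L) {
    stop("need >= 2 causes and >= 1 indicator", call. = FALSE)
  }
  if (separability < 1) stop("separability must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  base <- stats::runif(length(indicators), 0.1, 0.9)
  sig <- sample(seq_along(causes), length(indicators), replace = TRUE)
  w <- 1 - 1 / separability
  s <- matrix(0.02, length(indicators), length(causes))
  s[cbind(seq_along(indicators), sig)] <- 0.95
  p <- (1 - w) * base + w * s
  dimnames(p) <- list(indicators, causes)
  va_prob_matrix(p, prior)
}

# mean pairwise Bhattacharyya coefficient between matrix columns, each
# normalized to a distribution over indicators; 1 = identical columns
column_overlap <- function(matrix) {
  p <- matrix$p
  q <- sweep(p, 2L, colSums(p), "/")
  nc <- ncol(q)
  pairs <- utils::combn(nc, 2L)
  mean(apply(pairs, 2L, function(ij)
    sum(sqrt(q[, ij[1L]] * q[, ij[2L]]))))
}

#' Generator configuration
#'
#' @param n_records Cohort size.
#' @param csmf_true Named fraction vector over causes (normalized
#'   internally).
#' @param matrix A [va_prob_matrix()] whose causes equal
#'   \code{names(csmf_true)}.
#' @param missing_rate Probability an answered non-gate item is recorded
#'   \code{dont_know}, in \code{[0, 1)}. Default 0.05.
#' @param seed Root integer seed; per-record substreams are derived from it
#'   so a cohort is reproducible record by record.
#' @param age_group_mix Named fractions over neonate/child/adult. Default
#'   all adult (cause-age independence keeps the endorsement model simple;
#'   override for age-structured studies).
#' @param gate_open_prob Cause-independent "yes" probability for gate items
#'   not covered by the matrix. Default 0.5.
#' @param background_rate "yes" probability for non-gate items not covered
#'   by the matrix (incl. personal/respondent/context blocks). Default 0.3.
#' @return List of class \code{va_generator_config}.
#' @export
generator_config <- function(n_records, csmf_true, matrix,
                             missing_rate = 0.05, seed = 1L,
                             age_group_mix = c(adult = 1),
                             gate_open_prob = 0.5, background_rate = 0.3) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(names(csmf_true)) ||
      !identical(sort(names(csmf_true)), sort(colnames(matrix$p)))) {
    stop("csmf_true must be named by the matrix's causes", call. = FALSE)
  }
  if (any(csmf_true < 0) || sum(csmf_true) <= 0) {
    stop("csmf_true must be a nonnegative vector with positive mass",
         call. = FALSE)
  }
  bad_ag <- setdiff(names(age_group_mix), AGE_GROUPS)
  if (length(bad_ag)) stop("unknown age group(s): ",
                           paste(bad_ag, collapse = ", "), call. = FALSE)
  structure(list(n_records = as.integer(n_records),
                 csmf_true = csmf_true / sum(csmf_true),
                 matrix = matrix, missing_rate = missing_rate,
                 seed = as.integer(seed),
                 age_group_mix = age_group_mix / sum(age_group_mix),
                 gate_open_prob = gate_open_prob,
                 background_rate = background_rate),
            class = "va_generator_config")
}

#' Generate a skip-consistent synthetic cohort
#'
#' For each record: a true cause is drawn from \code{csmf_true} and an age
#' group from \code{age_group_mix}; responses are then generated level by
#' level so skip logic holds by construction — items behind a closed gate
#' are recorded \code{not_applicable}. An answered item is "yes" with the
#' matrix probability \code{P(i | cause)} when the matrix covers it, the
#' cause-independent \code{gate_open_prob} when it is a gate outside the
#' matrix, and \code{background_rate} otherwise. \code{dont_know} is
#' injected at \code{missing_rate} on answered non-gate items. Every
#' generated record passes [validate_record()].
#'
#' @param config A [generator_config()].
#' @param registry A registry whose ids include the matrix's indicators.
#' @return Object of class \code{va_cohort}: list with \code{records}
#'   (list of [va_record()]), \code{true_causes} (named by record_id) and
#'   \code{config}.
#' @export
generate_cohort <- function(config, registry) {
  stopifnot(inherits(config, "va_generator_config"))
  mat_ind <- rownames(config$matrix$p)
  missing_ind <- setdiff(mat_ind, registry$indicator_id)
  if (length(missing_ind)) {
    stop("matrix indicator(s) absent from registry: ",
         paste(utils::head(missing_ind, 5L), collapse = ", "), call. = FALSE)
  }
  causes <- names(config$csmf_true)
  set.seed(config$seed)
  true_cause <- sample(causes, config$n_records, replace = TRUE,
                       prob = config$csmf_true)
  age_group <- sample(names(config$age_group_mix), config$n_records,
                      replace = TRUE, prob = config$age_group_mix)
  rec_seed <- sample.int(.Machine$integer.max - 1L, config$n_records)
  sex_pool <- c("male", "female")

  ord <- order(is.na(registry$skip_level), registry$skip_level)
  reg <- registry[ord, ]
  p_of <- function(id, cause, is_gate) {
    j <- match(id, mat_ind)
    if (!is.na(j)) return(config$matrix$p[j, cause])
    if (is_gate) config$gate_open_prob else config$background_rate
  }
  records <- vector("list", config$n_records)
  for (r in seq_len(config$n_records)) {
    set.seed(rec_seed[r])
    cause <- true_cause[r]
    ag <- age_group[r]
    sex <- if (ag == "adult") sample(sex_pool, 1L) else
      sample(c(sex_pool, "unknown"), 1L)
    in_group <- reg[[ag]]
    resp <- character(0)
    for (i in which(in_group)) {
      id <- reg$indicator_id[i]
      lev <- reg$skip_level[i]
      parent <- reg$parent_id[i]
      open <- is.na(lev) || lev == 1L ||
        (!is.na(resp[parent]) && resp[parent] == "yes")
      if (!open) { resp[id] <- "not_applicable"; next }
      # maternal block stays closed for male adults (screen answered "no")
      if (reg$maternal[i] && sex == "male") { resp[id] <- "no"; next }
      yes <- stats::runif(1) < p_of(id, cause, reg$is_gate[i])
      ans <- if (yes) "yes" else "no"
      if (!reg$is_gate[i] && config$missing_rate > 0 &&
          stats::runif(1) < config$missing_rate) ans <- "dont_know"
      resp[id] <- ans
    }
    records[[r]] <- va_record(sprintf("rec%05d", r), ag, sex, resp)
  }
  out <- list(records = records,
              true_causes = stats::setNames(
                true_cause, vapply(records, `[[`, "", "record_id")),
              config = config)
  class(out) <- "va_cohort"
  out
}

#' @export
print.va_cohort <- function(x, ...) {
  cat("synthetic VA cohort:", length(x$records), "records,",
      length(unique(x$true_causes)), "causes, seed", x$config$seed, "\n")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Generates a cohort, interprets every record with the true
#' conditional-probability matrix (or a tariff fit on a held-out training
#' cohort), and scores recovery with the evaluation metrics: CSMF accuracy
#' of the estimated against the cohort's empirical cause distribution,
#' average chance-corrected concordance, and top-1 accuracy.
#'
#' @param config A [generator_config()].
#' @param registry Registry to generate against; default a flat synthetic
#'   registry over exactly the matrix's indicators.
#' @param engine \code{"bayes"} (scored with the true matrix) or
#'   \code{"tariff"} (tariffs fit on a second cohort of the same size drawn
#'   with a shifted seed).
#' @param mode Bayesian likelihood mode.
#' @param tau Indeterminacy threshold (bayes).
#' @return List of class \code{va_recovery}: \code{csmf_accuracy},
#'   \code{ccc_average}, \code{top1_accuracy}, \code{confusion},
#'   \code{csmf_true_empirical}, \code{csmf_estimated}, \code{cohort}.
#' @export
recovery_experiment <- function(config, registry = NULL,
                                engine = c("bayes", "tariff"),
                                mode = "positive_only", tau = 0) {
  engine <- match.arg(engine)
  if (is.null(registry)) {
    registry <- synthetic_registry(nrow(config$matrix$p), prefix = "flat")
    registry$indicator_id <- rownames(config$matrix$p)
    registry$is_gate <- FALSE
  }
  cohort <- generate_cohort(config, registry)
  scorer <- config$matrix
  if (engine == "tariff") {
    train_cfg <- config
    train_cfg$seed <- config$seed + 1L
    train <- generate_cohort(train_cfg, registry)
    scorer <- fit_tariff(train$records, unname(train$true_causes),
                         cause_levels = names(config$csmf_true),
                         indicators = rownames(config$matrix$p))
  }
  assignments <- lapply(cohort$records, assign_cause, engine = engine,
                        matrix = scorer, tau = tau, mode = mode)
  causes <- names(config$csmf_true)
  assigned <- vapply(assignments, `[[`, "", "top_cause")
  truth <- unname(cohort$true_causes)
  conf <- confusion_matrix(truth, assigned,
                           cause_levels = union(causes, "VA-99"))
  emp <- as.vector(table(factor(truth, levels = causes))) / length(truth)
  est <- csmf_from_assignments(assignments, cause_levels = causes)
  est <- est / sum(est)  # renormalize if some mass fell to VA-99
  out <- list(
    csmf_accuracy = csmf_accuracy(emp, as.numeric(est)),
    ccc_average = chance_corrected_concordance(
      conf[causes, causes, drop = FALSE])$average,
    top1_accuracy = mean(assigned == truth),
    confusion = conf,
    csmf_true_empirical = stats::setNames(emp, causes),
    csmf_estimated = est,
    cohort = cohort)
  class(out) <- "va_recovery"
  out
}

#' @export
print.va_recovery <- function(x, ...) {
  cat(sprintf(
    "recovery: CSMF accuracy %.3f | avg chance-corrected concordance %.3f | top-1 %.3f\n",
    x$csmf_accuracy, x$ccc_average, x$top1_accuracy))
  invisible(x)
}
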