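# Skip-pattern questionnaire logic.
#
# CoD-related indicators sit in a forest of skip levels 1-4: level-1 items
# are always asked; a level-k item is asked only while its parent was asked
# and answered "yes". "dont_know" and missing answers close a gate (no
# follow-ups to an unconfirmed screen). personal/respondent/context items
# are gate-free.

RESPONSES <- c("yes", "no", "dont_know", "not_applicable")
AGE_GROUPS <- c("neonate", "child", "adult")

#' Construct a VA record
#'
#' One decedent's interview: age group, sex, and the indicator responses.
#'
#' @param record_id Identifier string.
#' @param age_group One of \code{"neonate"} (under 28 days), \code{"child"}
#'   (28 days to 14 years), \code{"adult"} (15+).
#' @param sex \code{"male"}, \code{"female"} or \code{"unknown"}.
#' @param responses Named character vector, indicator_id -> one of
#'   \code{"yes"}, \code{"no"}, \code{"dont_know"}, \code{"not_applicable"}.
#' @param free_text Optional narrative.
#' @return Object of class \code{va_record}.
#' @export
va_record <- function(record_id, age_group, sex = "unknown",
                      responses = character(), free_text = "") {
  if (!age_group %in% AGE_GROUPS) {
    stop("unknown age group: ", age_group, call. = FALSE)
  }
  if (!sex %in% c("male", "female", "unknown")) {
    stop("unknown sex: ", sex, call. = FALSE)
  }
  bad <- !responses %in% RESPONSES
  if (any(bad)) {
    stop("invalid response value(s): ",
         paste(unique(responses[bad]), collapse = ", "), call. = FALSE)
  }
  out <- list(record_id = as.character(record_id), age_group = age_group,
              sex = sex, responses = responses, free_text = free_text)
  class(out) <- "va_record"
  out
}

#' @export
print.va_record <- function(x, ...) {
  cat("VA record", x$record_id, "-", x$age_group, x$sex, "-",
      length(x$responses), "responses (",
      sum(x$responses == "yes"), "yes )\n")
  invisible(x)
}

#' Applicable indicators for a record
#'
#' Computes the fixpoint of the gating relation: all level-1 (and gate-free)
#' items of the age group, plus every deeper item whose parent is applicable
#' and answered \code{"yes"}. \code{"dont_know"}, \code{"no"} and missing
#' answers close a gate. The set is monotone in yes-answers: adding a "yes"
#' never removes applicability.
#'
#' @param age_group Age group label.
#' @param responses Named response vector (a \code{va_record$responses}).
#' @param registry A [load_indicator_registry()] result.
#' @param cod_only If TRUE (default FALSE) restrict to CoD-related items.
#' @return Character vector of applicable indicator ids, in registry order.
#' @export
applicable_indicators <- function(age_group, responses, registry,
                                  cod_only = FALSE) {
  if (!age_group %in% AGE_GROUPS) {
    stop("unknown age group: ", age_group, call. = FALSE)
  }
  in_group <- registry[[age_group]]
  open <- in_group & (is.na(registry$skip_level) | registry$skip_level == 1L)
  # levels are topologically ordered, one pass per level reaches the fixpoint
  for (lev in 2:4) {
    at <- in_group & !is.na(registry$skip_level) & registry$skip_level == lev
    parent_open <- registry$parent_id[at] %in% registry$indicator_id[open]
    parent_yes <- !is.na(responses[registry$parent_id[at]]) &
      responses[registry$parent_id[at]] == "yes"
    open[at] <- parent_open & parent_yes
  }
  if (cod_only) open <- open & registry$category == "cod_related"
  registry$indicator_id[open]
}

#' Validate a VA record against the skip topology
#'
#' Report-only consistency check. Flags: \code{substantive_on_closed} — a
#' yes/no/dont_know answer on an item the skip logic closed;
#' \code{missing_on_applicable} — an applicable item with no answer (or
#' marked not_applicable); \code{maternal_inconsistent} — a "yes" on a
#' maternal-block item for a male or non-adult decedent.
#'
#' @param record A [va_record()].
#' @param registry A [load_indicator_registry()] result.
#' @return Object of class \code{va_validation}: list with \code{is_valid}
#'   and a \code{violations} data.frame (\code{indicator_id}, \code{rule},
#'   \code{message}).
#' @export
validate_record <- function(record, registry) {
  applicable <- applicable_indicators(record$age_group, record$responses,
                                      registry)
  resp <- record$responses
  v <- list()
  flag <- function(ids, rule, msg) {
    if (length(ids)) {
      v[[length(v) + 1L]] <<- data.frame(indicator_id = ids, rule = rule,
                                         message = msg,
                                         stringsAsFactors = FALSE)
    }
  }
  answered <- names(resp)[resp %in% c("yes", "no", "dont_know")]
  in_group <- registry$indicator_id[registry[[record$age_group]]]
  flag(setdiff(answered, applicable), "substantive_on_closed",
       "substantive answer on an item the skip logic closed")
  missing <- setdiff(applicable,
                     names(resp)[resp %in% c("yes", "no", "dont_know")])
  flag(missing, "missing_on_applicable",
       "applicable item without a substantive answer")
  maternal_ids <- registry$indicator_id[registry$maternal]
  if (record$sex == "male" || record$age_group != "adult") {
    yes_maternal <- intersect(names(resp)[resp == "yes"], maternal_ids)
    flag(yes_maternal, "maternal_inconsistent",
         "maternal-block item endorsed on a male or non-adult record")
  }
  flag(setdiff(names(resp), c(in_group, registry$indicator_id)),
       "unknown_indicator", "response to an id absent from the registry")
  flag(setdiff(intersect(names(resp), registry$indicator_id),
               in_group), "outside_age_group",
       "response to an item not applicable to this age group")
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(indicator_id = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
  out <- list(record_id = record$record_id, is_valid = nrow(violations) == 0L,
              violations = violations)
  class(out) <- "va_validation"
  out
}

#' @export
print.va_validation <- function(x, ...) {
  cat("record", x$record_id, if (x$is_valid) "valid" else
    paste0("INVALID (", nrow(x$violations), " violations)"), "\n")
  invisible(x)
}

#' Maximum question count along the open-gate path
#'
#' Number of CoD-related items asked when every gate on the profile's path
#' opens. The \code{maternal} profile (adult female) opens every adult gate
#' including the maternal block; the \code{generic} profile opens everything
#' except the maternal block. The published maxima are 130 (adult maternal),
#' 101 (child) and 104 (neonate).
#'
#' @param age_group Age group label.
#' @param profile \code{"generic"} or \code{"maternal"}.
#' @param registry A [load_indicator_registry()] result.
#' @return Integer count of CoD-related indicators.
#' @examples
#' max_question_count("adult", "maternal", load_indicator_registry())  # 130
#' @export
max_question_count <- function(age_group, profile = "generic",
                               registry = load_indicator_registry()) {
  if (!age_group %in% AGE_GROUPS) {
    stop("unknown age group: ", age_group, call. = FALSE)
  }
  if (!profile %in% c("generic", "maternal")) {
    stop("unknown profile: ", profile, call. = FALSE)
  }
  if (profile == "maternal" && age_group != "adult") {
    stop("maternal profile applies to adult (female) deaths only",
         call. = FALSE)
  }
  cod <- registry$category == "cod_related" & registry[[age_group]]
  if (profile == "generic" && age_group == "adult") {
    # maternal gate is still asked (level 1) but its descendants are not
    cod <- cod & !(registry$maternal & registry$skip_level > 1L)
  }
  sum(cod)
}

## ------------------------------------------------------------- record CSV IO

RESP_CSV <- c(yes = "Y", no = "N", dont_know = "DK", not_applicable = "NA")

#' Write VA records to the record CSV dialect
#'
#' One row per decedent: \code{record_id}, \code{age_group}, \code{sex},
#' then one column per indicator with values \code{Y}/\code{N}/\code{DK}/
#' \code{NA} (empty = never reached). [read_va_records()] inverts it.
#'
#' @param records List of [va_record()] objects.
#' @param path Output file path.
#' @param registry Registry defining the indicator column order.
#' @return \code{path}, invisibly.
#' @export
write_va_records <- function(records, path, registry) {
  ids <- registry$indicator_id
  mat <- t(vapply(records, function(r) {
    row <- rep("", length(ids))
    hit <- match(names(r$responses), ids)
    row[hit[!is.na(hit)]] <- RESP_CSV[r$responses[!is.na(hit)]]
    row
  }, character(length(ids))))
  df <- data.frame(
    record_id = vapply(records, `[[`, "", "record_id"),
    age_group = vapply(records, `[[`, "", "age_group"),
    sex = vapply(records, `[[`, "", "sex"),
    stringsAsFactors = FALSE)
  df[ids] <- as.data.frame(mat, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read VA records from the record CSV dialect
#'
#' @param path CSV path written by [write_va_records()] or compatible.
#' @return List of [va_record()] objects.
#' @export
read_va_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = NULL)
  fixed <- c("record_id", "age_group", "sex")
  if (!all(fixed %in% names(df))) {
    stop("record CSV must have columns ", paste(fixed, collapse = ", "),
         call. = FALSE)
  }
  ind_cols <- setdiff(names(df), fixed)
  inv <- stats::setNames(names(RESP_CSV), RESP_CSV)
  lapply(seq_len(nrow(df)), function(i) {
    vals <- unlist(df[i, ind_cols, drop = FALSE])
    keep <- nzchar(vals)
    bad <- keep & !vals %in% names(inv)
    if (any(bad)) {
      stop("record ", df$record_id[i], ": invalid response code(s) ",
           paste(unique(vals[bad]), collapse = ", "), call. = FALSE)
    }
    va_record(df$record_id[i], df$age_group[i], df$sex[i],
              stats::setNames(inv[vals[keep]], ind_cols[keep]))
  })
}
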