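#' @importFrom jsonlite fromJSON read_json write_json
NULL

va_extdata <- function(file) {
  path <- system.file("extdata", file, package = "va2012")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  path
}

#' Load the VA cause list
#'
#' Reads the packaged 2012 WHO VA cause list: 62 cause categories (60 causes
#' plus fresh and macerated stillbirth) and the VA-99 "cause of death
#' unknown" pseudo-category, each with its certification (to-ICD) codes and
#' source (from-ICD) code ranges. All ICD fields are parsed and validated on
#' load; a malformed row aborts with a message naming it.
#'
#' @param path Path to a cause-list JSON file; defaults to the packaged
#'   standard.
#' @return An object of class \code{va_cause_list}: a list with
#'   \describe{
#'     \item{causes}{data.frame, one row per leaf category, in table order:
#'       \code{va_code}, \code{title}, \code{group_code}, \code{notes},
#'       \code{is_cause}, and list-columns \code{to_icd} (data.frame
#'       \code{code}/\code{context}) and \code{from_icd} (character ranges).}
#'     \item{rules}{data.frame of mapping rules, one per from-ICD entry (see
#'       [map_from_icd()]).}
#'   }
#' @examples
#' cl <- load_cause_list()
#' nrow(cl$causes)
#' subset(cl$causes, va_code == "VAs-01.05")$title
#' @export
load_cause_list <- function(path = va_extdata("causes.json")) {
  raw <- read_json(path)
  rows <- lapply(seq_along(raw), function(i) {
    x <- raw[[i]]
    req <- c("va_code", "title", "group_code", "to_icd", "from_icd")
    if (!all(req %in% names(x))) {
      stop("cause-list row ", i, ": missing field(s) ",
           paste(setdiff(req, names(x)), collapse = ", "), call. = FALSE)
    }
    to <- strsplit(unlist(x$to_icd), "|", fixed = TRUE)
    to_codes <- vapply(to, `[`, "", 1L)
    to_ctx <- vapply(to, function(p) if (length(p) > 1L) p[2L] else "default",
                     "")
    parsed_to <- tryCatch(parse_icd(to_codes), error = function(e) {
      stop("cause-list row ", i, " (", x$va_code, "): ", conditionMessage(e),
           call. = FALSE)
    })
    from <- unlist(x$from_icd)
    tryCatch(parse_icd_range(from), error = function(e) {
      stop("cause-list row ", i, " (", x$va_code, "): ", conditionMessage(e),
           call. = FALSE)
    })
    list(va_code = x$va_code, title = x$title, group_code = x$group_code,
         notes = if (is.null(x$notes)) "" else x$notes,
         is_cause = isTRUE(x$is_cause),
         to_icd = data.frame(code = parsed_to$code, context = to_ctx,
                             stringsAsFactors = FALSE),
         from_icd = from)
  })
  causes <- data.frame(
    va_code = vapply(rows, `[[`, "", "va_code"),
    title = vapply(rows, `[[`, "", "title"),
    group_code = vapply(rows, `[[`, "", "group_code"),
    notes = vapply(rows, `[[`, "", "notes"),
    is_cause = vapply(rows, `[[`, TRUE, "is_cause"),
    stringsAsFactors = FALSE)
  causes$to_icd <- lapply(rows, `[[`, "to_icd")
  causes$from_icd <- lapply(rows, `[[`, "from_icd")
  if (anyDuplicated(causes$va_code)) {
    stop("duplicate va_code in cause list: ",
         paste(unique(causes$va_code[duplicated(causes$va_code)]),
               collapse = ", "), call. = FALSE)
  }
  out <- list(causes = causes, rules = build_mapping_rules(causes))
  class(out) <- "va_cause_list"
  out
}

#' @export
print.va_cause_list <- function(x, ...) {
  cat("2012 WHO VA cause list:", sum(x$causes$is_cause),
      "cause categories (+", sum(!x$causes$is_cause),
      "unknown-cause pseudo-category),", nrow(x$rules), "mapping rules\n")
  invisible(x)
}

#' Load the VA indicator registry
#'
#' Reads the packaged indicator registry: CoD-related indicator stubs whose
#' per-age-group, per-skip-level and distinct counts reproduce the published
#' pattern of the 2012 instrument (221 distinct CoD-related items; levels
#' 93/87/31/10; per-group totals 130 adult, 101 child, 104 neonate), plus
#' the gate-free personal (26), respondent (3) and context (10) blocks. The
#' file is data: it can be replaced by the official WHO item list without
#' code change.
#'
#' Structural invariants (skip level > 1 implies a parent one level up whose
#' age groups cover the child's) are checked on load.
#'
#' @param path Path to a registry JSON file; defaults to the packaged one.
#' @return An object of class \code{va_registry}: a data.frame with columns
#'   \code{indicator_id}, \code{label}, \code{category}, \code{skip_level}
#'   (\code{NA} for non-CoD items), \code{parent_id}, \code{maternal},
#'   \code{is_gate}, and logical columns \code{adult}, \code{child},
#'   \code{neonate}.
#' @examples
#' reg <- load_indicator_registry()
#' sum(reg$category == "cod_related")
#' @export
load_indicator_registry <- function(path = va_extdata("indicators.json")) {
  raw <- read_json(path)
  reg <- data.frame(
    indicator_id = vapply(raw, `[[`, "", "indicator_id"),
    label = vapply(raw, `[[`, "", "label"),
    category = vapply(raw, `[[`, "", "category"),
    skip_level = vapply(raw, function(x)
      if (is.null(x$skip_level)) NA_integer_ else as.integer(x$skip_level), 0L),
    parent_id = vapply(raw, `[[`, "", "parent_id"),
    maternal = vapply(raw, function(x) isTRUE(x$maternal), TRUE),
    stringsAsFactors = FALSE)
  ag <- lapply(raw, function(x) unlist(x$age_groups))
  for (g in c("adult", "child", "neonate")) {
    reg[[g]] <- vapply(ag, function(a) g %in% a, TRUE)
  }
  if (anyDuplicated(reg$indicator_id)) {
    stop("duplicate indicator_id in registry", call. = FALSE)
  }
  bad_cat <- !reg$category %in% c("cod_related", "personal", "respondent",
                                  "context")
  if (any(bad_cat)) {
    stop("unknown indicator category: ",
         paste(unique(reg$category[bad_cat]), collapse = ", "), call. = FALSE)
  }
  # skip structure: level k>1 needs a parent at level k-1 covering its groups
  idx <- match(reg$parent_id, reg$indicator_id)
  deep <- which(!is.na(reg$skip_level) & reg$skip_level > 1L)
  orphan <- deep[is.na(idx[deep]) |
                   reg$skip_level[idx[deep]] != reg$skip_level[deep] - 1L]
  if (length(orphan)) {
    stop("indicator(s) with missing or wrong-level parent: ",
         paste(reg$indicator_id[orphan], collapse = ", "), call. = FALSE)
  }
  for (g in c("adult", "child", "neonate")) {
    bad <- deep[reg[[g]][deep] & !reg[[g]][idx[deep]]]
    if (length(bad)) {
      stop("indicator(s) applicable to ", g, " under a parent that is not: ",
           paste(reg$indicator_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  reg$is_gate <- reg$indicator_id %in% reg$parent_id[nzchar(reg$parent_id)]
  class(reg) <- c("va_registry", "data.frame")
  reg
}

#' Load the 2007-to-2012 cause subsumption map
#'
#' The 27 cause categories of the 2007 WHO VA standard that the 2012
#' revision folded into residual categories, with the absorbing 2012
#' va_code for each.
#'
#' @param path Path to a subsumption JSON file; defaults to the packaged one.
#' @param cause_list Optional [load_cause_list()] result; when supplied every
#'   target code is checked to resolve, and a dangling target is an error.
#' @return data.frame with columns \code{cause_2007}, \code{target_va_code}.
#' @export
load_subsumption_map <- function(path = va_extdata("subsumption.json"),
                                 cause_list = NULL) {
  raw <- read_json(path)
  map <- data.frame(
    cause_2007 = vapply(raw, `[[`, "", "cause_2007"),
    target_va_code = vapply(raw, `[[`, "", "target_va_code"),
    stringsAsFactors = FALSE)
  if (!is.null(cause_list)) {
    dangling <- setdiff(map$target_va_code, cause_list$causes$va_code)
    if (length(dangling)) {
      stop("subsumption target(s) not in cause list: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  map
}

#' Load the standard's structural constants
#'
#' The printed counts that the packaged data must reproduce: 106 causes and
#' 408 indicators in the 2007 standard, 62 causes and 221 CoD-related
#' indicators in the 2012 one, 164 retained / 57 new / 244 excluded
#' indicators, and the per-age-group skip-level pattern.
#'
#' @param path Path to a constants JSON file; defaults to the packaged one.
#' @return Nested list mirroring the file.
#' @export
load_standard_constants <- function(path = va_extdata("constants.json")) {
  read_json(path, simplifyVector = FALSE)
}

# distinct CoD-related indicator count per skip level
registry_level_counts <- function(registry) {
  cod <- registry[registry$category == "cod_related", ]
  vapply(1:4, function(l) sum(cod$skip_level == l), 0L)
}

# per-age-group count of CoD-related indicators at one level, or by category
registry_group_count <- function(registry, group, category = "cod_related",
                                 level = NULL) {
  sel <- registry$category == category & registry[[group]]
  if (!is.null(level)) sel <- sel & !is.na(registry$skip_level) &
      registry$skip_level == level
  sum(sel)
}

#' Audit the packaged standard against its printed constants
#'
#' Recomputes every structural count from the loaded artifacts and compares
#' it with the standard's constants; returns one row per violated constant
#' (empty when the data are consistent).
#'
#' @param registry A [load_indicator_registry()] result.
#' @param cause_list A [load_cause_list()] result.
#' @param constants A [load_standard_constants()] result.
#' @return data.frame with columns \code{constant}, \code{expected},
#'   \code{observed}; zero rows iff every invariant holds.
#' @examples
#' rep <- registry_consistency_report(load_indicator_registry(),
#'                                    load_cause_list(),
#'                                    load_standard_constants())
#' nrow(rep)  # 0
#' @export
registry_consistency_report <- function(registry, cause_list, constants) {
  checks <- list()
  add <- function(constant, expected, observed) {
    checks[[length(checks) + 1L]] <<- data.frame(
      constant = constant, expected = expected, observed = observed,
      stringsAsFactors = FALSE)
  }
  add("n_causes_2012", constants$n_causes_2012,
      sum(cause_list$causes$is_cause))
  add("n_cod_indicators", constants$n_indicators_2012,
      sum(registry$category == "cod_related"))
  lev <- registry_level_counts(registry)
  for (l in 1:4) {
    add(sprintf("distinct level-%d", l),
        constants$per_level_distinct[[as.character(l)]], lev[l])
  }
  for (g in c("adult", "child", "neonate")) {
    pg <- constants$per_group[[g]]
    for (l in 1:4) {
      add(sprintf("%s level-%d", g, l), pg$levels[[l]],
          registry_group_count(registry, g, level = l))
    }
    add(sprintf("%s cod total", g), pg$cod_total,
        registry_group_count(registry, g))
    add(sprintf("%s personal", g), pg$personal,
        registry_group_count(registry, g, category = "personal"))
    add(sprintf("%s respondent", g), pg$respondent,
        registry_group_count(registry, g, category = "respondent"))
    add(sprintf("%s context", g), pg$context,
        registry_group_count(registry, g, category = "context"))
    add(sprintf("%s total", g), pg$total,
        registry_group_count(registry, g) +
          registry_group_count(registry, g, category = "personal") +
          registry_group_count(registry, g, category = "respondent") +
          registry_group_count(registry, g, category = "context"))
  }
  # reduction arithmetic ties the constants to each other
  add("retained + new = 2012 indicators",
      constants$n_indicators_2012, constants$n_retained + constants$n_new)
  add("2007 indicators - excluded = retained",
      constants$n_retained,
      constants$n_indicators_2007 - constants$n_excluded)
  out <- do.call(rbind, checks)
  out[out$expected != out$observed, , drop = FALSE]
}
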