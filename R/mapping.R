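# Bidirectional ICD-10 <-> VA cause mapping.
#
# The published table overlaps broad residual ranges (e.g. C60-D48 under
# "other neoplasms", R00-R69 under "other NCD") with specific causes
# (C60-C63, R10, ...). The mapping therefore resolves by precedence:
# most specific rule first (exact subcode < single category < wider range),
# residual rules lose to non-residual ones of equal size, remaining ties
# break by table order. The two stillbirth rules both claim P95 at equal
# precedence; that code deliberately maps to both, flagged ambiguous,
# because fresh vs macerated stillbirth is an interview distinction, not an
# ICD one.

# one row per from-ICD entry; residual = VAs-98, VA-99 and *.99 categories.
# Exact-subcode rules get size 0.1 so they outrank a single category (size 1).
build_mapping_rules <- function(causes) {
  rows <- lapply(seq_len(nrow(causes)), function(i) {
    r <- parse_icd_range(causes$from_icd[[i]])
    data.frame(va_code = causes$va_code[i], range = r$text,
               lo_key = r$lo_key, hi_key = r$hi_key, sub = r$sub,
               size = ifelse(is.na(r$sub), r$n_categories, 0.1),
               residual = grepl("\\.99$|^VAs-98$|^VA-99$", causes$va_code[i]),
               stringsAsFactors = FALSE)
  })
  rules <- do.call(rbind, rows)
  rules$rule_order <- seq_len(nrow(rules))
  rules
}

#' Map an ICD-10 code to its VA cause category
#'
#' Finds every cause-list rule whose code set contains \code{code} and
#' resolves overlaps by precedence: smallest code set wins (an exact
#' subcoded rule such as O75.3 beats its enclosing categories), residual
#' categories (\code{VAs-98}, \code{VA-99}, \code{*.99}) lose to specific
#' ones of equal size, and remaining ties break by table order. P95 is the
#' one deliberate tie: it returns both stillbirth categories, flagged
#' ambiguous. A code no rule matches (e.g. the Z chapter) is reported
#' unmapped rather than coerced to VA-99, which is an explicit rule for R99
#' only.
#'
#' @param code ICD-10 code text (see [parse_icd()]).
#' @param cause_list A [load_cause_list()] result.
#' @return An object of class \code{va_mapping}: list with \code{code}
#'   (canonical), \code{va_codes} (character, empty if unmapped, ordered by
#'   precedence), \code{titles}, \code{rule} (winning range text),
#'   \code{ambiguous} and \code{unmapped} flags.
#' @examples
#' cl <- load_cause_list()
#' map_from_icd("B22", cl)$va_codes    # "VAs-01.03"
#' map_from_icd("P95", cl)$ambiguous   # TRUE
#' @export
map_from_icd <- function(code, cause_list) {
  pc <- parse_icd(code)
  if (nrow(pc) != 1L) stop("map_from_icd() maps one code at a time",
                           call. = FALSE)
  rules <- cause_list$rules
  hit <- (is.na(rules$sub) & rules$lo_key <= pc$key & pc$key <= rules$hi_key) |
    (!is.na(rules$sub) & rules$lo_key == pc$key & !is.na(pc$sub) &
       rules$sub == pc$sub)
  cand <- rules[hit, , drop = FALSE]
  if (!nrow(cand)) {
    out <- list(code = pc$code, va_codes = character(0), titles = character(0),
                rule = NA_character_, ambiguous = FALSE, unmapped = TRUE)
    class(out) <- "va_mapping"
    return(out)
  }
  cand <- cand[order(cand$size, cand$residual, cand$rule_order), ,
               drop = FALSE]
  top <- cand$size == cand$size[1L] & cand$residual == cand$residual[1L]
  winners <- cand[top, , drop = FALSE]
  out <- list(
    code = pc$code,
    va_codes = winners$va_code,
    titles = cause_list$causes$title[match(winners$va_code,
                                           cause_list$causes$va_code)],
    rule = winners$range[1L],
    ambiguous = nrow(winners) > 1L,
    unmapped = FALSE)
  class(out) <- "va_mapping"
  out
}

#' @export
print.va_mapping <- function(x, ...) {
  if (x$unmapped) {
    cat(x$code, "-> (unmapped)\n")
  } else {
    cat(x$code, "->", paste(x$va_codes, collapse = " | "),
        if (x$ambiguous) "[ambiguous]" else "", "\n")
  }
  invisible(x)
}

#' Certification ICD-10 code for a VA cause
#'
#' Returns the ICD-10 code to enter on a death certificate for a VA cause
#' category, honouring the context-dependent alternatives the standard
#' prints (e.g. obstetric haemorrhage certifies O46 antepartum but O72
#' postpartum; tetanus certifies A34 in an obstetric context). The
#' \code{default} context returns the first printed code.
#'
#' @param va_code A cause-list va_code.
#' @param context One of \code{"default"}, \code{"antepartum"},
#'   \code{"postpartum"}, \code{"obstetric"}, \code{"eclampsia"},
#'   \code{"acute_ischemic"}, \code{"status_asthmaticus"}.
#' @param cause_list A [load_cause_list()] result.
#' @return Canonical ICD-10 code text.
#' @examples
#' cl <- load_cause_list()
#' map_to_icd("VAs-09.04", "postpartum", cl)  # "O72"
#' @export
map_to_icd <- function(va_code, context = "default",
                       cause_list = load_cause_list()) {
  vocab <- c("default", "antepartum", "postpartum", "obstetric", "eclampsia",
             "acute_ischemic", "status_asthmaticus")
  if (!context %in% vocab) {
    stop("unknown context '", context, "'; valid contexts: ",
         paste(vocab, collapse = ", "), call. = FALSE)
  }
  i <- match(va_code, cause_list$causes$va_code)
  if (is.na(i)) stop("unknown va_code: ", va_code, call. = FALSE)
  to <- cause_list$causes$to_icd[[i]]
  if (context == "default") return(to$code[1L])
  j <- match(context, to$context)
  if (is.na(j)) {
    stop("context '", context, "' not defined for ", va_code,
         "; valid contexts: ",
         paste(unique(c("default", to$context[to$context != "default"])),
               collapse = ", "), call. = FALSE)
  }
  to$code[j]
}

#' Audit mapping coverage of an ICD-10 code universe
#'
#' Scans every category-level code in \code{universe}, reporting codes no
#' rule matches and codes claimed by more than one non-residual rule of
#' equal specificity (by construction only P95, the stillbirth pair).
#'
#' @param cause_list A [load_cause_list()] result.
#' @param universe Range expression for the codes to scan (default
#'   \code{"A00-Y98"}, the certifiable cause-of-death chapters).
#' @return List with \code{unmapped} (character codes) and \code{ambiguous}
#'   (data.frame \code{code}, \code{va_codes} collapsed with "|").
#' @export
coverage_audit <- function(cause_list, universe = "A00-Y98") {
  codes <- icd_universe(universe)
  res <- lapply(codes, map_from_icd, cause_list = cause_list)
  unmapped <- codes[vapply(res, `[[`, TRUE, "unmapped")]
  amb <- res[vapply(res, `[[`, TRUE, "ambiguous")]
  ambiguous <- data.frame(
    code = vapply(amb, `[[`, "", "code"),
    va_codes = vapply(amb, function(m) paste(m$va_codes, collapse = "|"), ""),
    stringsAsFactors = FALSE)
  list(unmapped = unmapped, ambiguous = ambiguous)
}
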