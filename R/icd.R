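#' Parse an ICD-10 code
#'
#' Parses ICD-10 code text of the form letter + two digits + optional single
#' decimal digit (e.g. \code{"B20"}, \code{"O75.3"}) into its components and
#' canonicalises case and zero padding. Only the code syntax used by the VA
#' cause list is supported: one letter, a two-digit category, at most one
#' sub-classification digit.
#'
#' @param text Character vector of ICD-10 codes.
#' @return A data.frame with columns \code{code} (canonical text),
#'   \code{letter}, \code{category} (integer 0--99), \code{sub} (integer
#'   0--9 or \code{NA}), and \code{key} (integer sort key over
#'   letter/category; the sub digit orders within a category, absent first).
#' @examples
#' parse_icd(c("B20", "o75.3"))
#' @export
parse_icd <- function(text) {
  text <- toupper(trimws(as.character(text)))
  m <- regmatches(text, regexec("^([A-Z])([0-9]{1,2})(?:\\.([0-9]))?$", text))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ", paste(text[bad], collapse = ", "),
         call. = FALSE)
  }
  letter <- vapply(m, `[`, "", 2L)
  category <- as.integer(vapply(m, `[`, "", 3L))
  sub <- suppressWarnings(as.integer(vapply(m, `[`, "", 4L)))
  code <- sprintf("%s%02d", letter, category)
  code[!is.na(sub)] <- paste0(code[!is.na(sub)], ".", sub[!is.na(sub)])
  data.frame(code = code, letter = letter, category = category, sub = sub,
             key = icd_key(letter, category), stringsAsFactors = FALSE)
}

# integer order key over (letter, category); sub codes sort inside their
# category and are handled separately where it matters
icd_key <- function(letter, category) {
  (match(letter, LETTERS) - 1L) * 100L + as.integer(category)
}

# inverse of icd_key, back to canonical category-level text
icd_from_key <- function(key) {
  sprintf("%s%02d", LETTERS[key %/% 100L + 1L], key %% 100L)
}

#' Parse an ICD-10 code range
#'
#' Parses range text such as \code{"A00-A09"} (en dash also accepted) into an
#' inclusive category-level interval; a single code is a degenerate range and
#' a subcoded single code (e.g. \code{"O75.3"}) is an exact-code rule. Ranges
#' may span letters (\code{"C60-D48"}); ordering is lexicographic on letter
#' then number.
#'
#' @param text Character vector of range expressions.
#' @return A data.frame with columns \code{text} (canonical), \code{lo_key},
#'   \code{hi_key} (inclusive category keys), \code{sub} (sub digit for
#'   exact-subcode rules, else \code{NA}), and \code{n_categories}.
#' @examples
#' parse_icd_range(c("A00-A09", "O75.3", "C60-D48"))
#' @export
parse_icd_range <- function(text) {
  text <- gsub("–", "-", trimws(as.character(text)))
  parts <- strsplit(text, "-", fixed = TRUE)
  n <- vapply(parts, length, 0L)
  if (any(n > 2L)) {
    stop("malformed ICD-10 range(s): ", paste(text[n > 2L], collapse = ", "),
         call. = FALSE)
  }
  lo <- parse_icd(vapply(parts, `[`, "", 1L))
  hi <- parse_icd(vapply(parts, function(p) p[length(p)], ""))
  if (any(n == 2L & (!is.na(lo$sub) | !is.na(hi$sub)))) {
    stop("range endpoints must be category-level codes: ",
         paste(text[n == 2L & (!is.na(lo$sub) | !is.na(hi$sub))],
               collapse = ", "), call. = FALSE)
  }
  if (any(lo$key > hi$key)) {
    stop("descending ICD-10 range(s): ",
         paste(text[lo$key > hi$key], collapse = ", "), call. = FALSE)
  }
  canon <- ifelse(n == 2L, paste0(lo$code, "-", hi$code), lo$code)
  data.frame(text = canon, lo_key = lo$key, hi_key = hi$key, sub = lo$sub,
             n_categories = hi$key - lo$key + 1L, stringsAsFactors = FALSE)
}

#' Test whether an ICD-10 range contains a code
#'
#' Containment follows the (letter, category) total order; a subcoded code
#' (e.g. \code{O75.3}) belongs to any category-level range containing its
#' three-character category. An exact-subcode "range" contains only that
#' exact code.
#'
#' @param range Range text or a row of [parse_icd_range()] output.
#' @param code Code text or a row of [parse_icd()] output.
#' @return Logical.
#' @examples
#' range_contains("A00-A09", "A09")   # TRUE
#' range_contains("A00-A09", "A10")   # FALSE
#' range_contains("C60-D48", "D10")   # TRUE
#' @export
range_contains <- function(range, code) {
  if (is.character(range)) range <- parse_icd_range(range)
  if (is.character(code)) code <- parse_icd(code)
  if (!is.na(range$sub)) {
    return(range$lo_key == code$key & !is.na(code$sub) &
             code$sub == range$sub)
  }
  range$lo_key <= code$key & code$key <= range$hi_key
}

# all category-level codes (canonical text) in a range expression like
# "A00-Y98"; used for coverage audits and oracle enumeration
icd_universe <- function(range = "A00-Y98") {
  r <- parse_icd_range(range)
  icd_from_key(seq.int(r$lo_key, r$hi_key))
}
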