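# CSV interchange for interpretation matrices.

#' Read a conditional-probability (or tariff) matrix from CSV
#'
#' Dialect: first column \code{indicator_id}, remaining columns va_codes,
#' cells = probabilities (or tariff scores).
#'
#' @param path Matrix CSV path.
#' @param prior_path Optional two-column CSV (\code{va_code},
#'   \code{probability}) with the baseline cause distribution.
#' @param type \code{"probability"} (returns a [va_prob_matrix()]) or
#'   \code{"tariff"} (returns a \code{va_tariff_matrix}).
#' @return A matrix object of the requested type.
#' @export
read_va_matrix <- function(path, prior_path = NULL,
                           type = c("probability", "tariff")) {
  type <- match.arg(type)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "indicator_id") {
    stop("matrix CSV must start with an indicator_id column", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$indicator_id
  if (type == "tariff") {
    out <- list(tariff = m, endorsement = NULL)
    class(out) <- "va_tariff_matrix"
    return(out)
  }
  prior <- NULL
  if (!is.null(prior_path)) {
    pr <- utils::read.csv(prior_path, stringsAsFactors = FALSE)
    prior <- pr[[2L]][match(colnames(m), pr[[1L]])]
    if (anyNA(prior)) {
      stop("prior CSV missing cause(s): ",
           paste(colnames(m)[is.na(prior)], collapse = ", "), call. = FALSE)
    }
  }
  va_prob_matrix(m, prior)
}

#' Write a matrix to the matrix CSV dialect
#'
#' @param matrix A [va_prob_matrix()] or [fit_tariff()] result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_va_matrix <- function(matrix, path) {
  m <- if (inherits(matrix, "va_tariff_matrix")) matrix$tariff else matrix$p
  df <- data.frame(indicator_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
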