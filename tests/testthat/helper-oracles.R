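# Independent oracles used across tests. They deliberately avoid the
# package's parsed-rule machinery: ranges are expanded into explicit code
# sets by letter/number arithmetic and precedence is applied by sorting the
# enumerated matches.

# expand "A00-A09" / "B05" / "O75.3" into an explicit vector of codes;
# subcode entries stay as-is, category ranges enumerate every member
oracle_expand <- function(text) {
  text <- gsub("–", "-", text)
  if (grepl(".", text, fixed = TRUE)) return(text)  # exact subcode
  ends <- strsplit(text, "-", fixed = TRUE)[[1]]
  lo <- ends[1]; hi <- ends[length(ends)]
  num <- function(x) (utf8ToInt(substr(x, 1, 1)) - utf8ToInt("A")) * 100 +
    as.integer(substr(x, 2, 3))
  ks <- seq(num(lo), num(hi))
  paste0(strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]][ks %/% 100 + 1],
         sprintf("%02d", ks %% 100))
}

# brute-force map: enumerate all rules matching `code`, order by
# (set size, residual, table order); returns list(va_codes, ambiguous)
oracle_map <- function(code, cause_list) {
  causes <- cause_list$causes
  hits <- list()
  for (i in seq_len(nrow(causes))) {
    for (rng in causes$from_icd[[i]]) {
      members <- oracle_expand(rng)
      sub_rule <- grepl(".", rng, fixed = TRUE)
      match_hit <- if (sub_rule) identical(code, members) else
        (code %in% members ||
           (grepl(".", code, fixed = TRUE) &&
              sub("\\..*$", "", code) %in% members))
      if (match_hit) {
        hits[[length(hits) + 1]] <- data.frame(
          va_code = causes$va_code[i],
          size = if (sub_rule) 0.1 else length(members),
          residual = grepl("\\.99$|^VAs-98$|^VA-99$", causes$va_code[i]),
          ord = length(hits) + i / 1000,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(list(va_codes = character(0), ambiguous = FALSE))
  h <- do.call(rbind, hits)
  h <- h[order(h$size, h$residual, h$ord), ]
  top <- h$size == h$size[1] & h$residual == h$residual[1]
  list(va_codes = h$va_code[top], ambiguous = sum(top) > 1)
}

# brute-force Bayesian posterior: plain product over endorsed indicators
# (and 1-p over "no" in full mode), with the same 1e-6 floor contract
oracle_posterior <- function(responses, p, prior, full = FALSE) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  w <- stats::setNames(prior / sum(prior), colnames(p))
  for (id in names(responses)) {
    if (!id %in% rownames(p)) next
    if (responses[[id]] == "yes") w <- w * p[id, ]
    if (full && responses[[id]] == "no") w <- w * (1 - p[id, ])
  }
  w / sum(w)
}

# small deterministic fixture: 3 causes x 2 indicators, both endorsed
fixture_bayes <- function() {
  p <- matrix(c(0.9, 0.2,
                0.4, 0.7,
                0.1, 0.5), nrow = 2,
              dimnames = list(c("i1", "i2"), c("A", "B", "C")))
  list(matrix = va_prob_matrix(p, prior = c(0.5, 0.3, 0.2)),
       responses = c(i1 = "yes", i2 = "yes"))
}

# shared loads (cheap, cached per test file)
std_cause_list <- local({
  cl <- NULL
  function() {
    if (is.null(cl)) cl <<- load_cause_list()
    cl
  }
})
std_registry <- local({
  r <- NULL
  function() {
    if (is.null(r)) r <<- load_indicator_registry()
    r
  }
})
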