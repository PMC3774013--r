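test_that("bayes posterior matches hand computation and oracle", {
  # one endorsed indicator, uniform prior: posterior is the normalized row
  m <- va_prob_matrix(matrix(c(0.8, 0.2), 1, 2,
                             dimnames = list("i1", c("A", "B"))))
  post <- bayes_posterior(c(i1 = "yes"), m)
  expect_equal(unname(post[c("A", "B")]), c(0.8, 0.2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # 3-cause x 2-indicator worked fixture vs brute-force oracle
  fx <- fixture_bayes()
  got <- bayes_posterior(fx$responses, fx$matrix)
  want <- oracle_posterior(as.list(fx$responses), fx$matrix$p,
                           fx$matrix$prior)
  expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # full_bernoulli also scores the "no"
  resp2 <- c(i1 = "yes", i2 = "no")
  got2 <- bayes_posterior(resp2, fx$matrix, mode = "full_bernoulli")
  want2 <- oracle_posterior(as.list(resp2), fx$matrix$p, fx$matrix$prior,
                            full = TRUE)
  expect_equal(unname(got2), unname(want2[names(got2)]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # positive_only ignores the "no" entirely
  expect_equal(unname(bayes_posterior(resp2, fx$matrix)),
               unname(bayes_posterior(resp2[1], fx$matrix)),
               ignore_attr = TRUE)
})

test_that("bayes invariances: identical columns, neutral rows, permutation", {
  # identical columns -> posterior = prior whatever the record says
  m <- va_prob_matrix(matrix(0.4, 3, 3,
                             dimnames = list(paste0("i", 1:3),
                                             c("A", "B", "C"))),
                      prior = c(0.5, 0.3, 0.2))
  post <- bayes_posterior(c(i1 = "yes", i2 = "yes", i3 = "no"), m,
                          mode = "full_bernoulli")
  expect_equal(unname(post), c(0.5, 0.3, 0.2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # adding an indicator with identical P across causes changes nothing
  fx <- fixture_bayes()
  p_ext <- rbind(fx$matrix$p, i3 = c(0.3, 0.3, 0.3))
  m_ext <- va_prob_matrix(p_ext, prior = fx$matrix$prior)
  expect_equal(
    unname(bayes_posterior(c(fx$responses, i3 = "yes"), m_ext)),
    unname(bayes_posterior(fx$responses, fx$matrix)),
    tolerance = 1e-12, ignore_attr = TRUE)
  # permuting cause order permutes the posterior identically
  perm <- c(3, 1, 2)
  m_perm <- va_prob_matrix(fx$matrix$p[, perm], fx$matrix$prior[perm])
  post0 <- bayes_posterior(fx$responses, fx$matrix)
  post1 <- bayes_posterior(fx$responses, m_perm)
  expect_equal(post1[names(post0)], post0, tolerance = 1e-12,
               ignore_attr = TRUE)
  # response-map order does not matter
  expect_equal(bayes_posterior(rev(fx$responses), fx$matrix),
               bayes_posterior(fx$responses, fx$matrix))
})

test_that("hard zeros are floored, not vetoes", {
  p <- matrix(c(0, 0.9, 0.9, 0.9), 2, 2,
              dimnames = list(c("i1", "i2"), c("A", "B")))
  m <- va_prob_matrix(p)
  post <- bayes_posterior(c(i1 = "yes", i2 = "yes"), m)
  expect_gt(post[["A"]], 0)  # floored at 1e-6, not annihilated
  expect_gt(post[["B"]], post[["A"]])
  expect_false(attr(post, "degenerate"))
})

test_that("tariff fit matches its robust-scaling definition", {
  mk <- function(id, yes) {
    va_record(id, "adult", "female",
              stats::setNames(ifelse(yes, "yes", "no"),
                              c("i1", "i2", "i3")))
  }
  # cause A deaths endorse i1 at 1.0, B and C at 0; i2 flat; i3 mixed
  records <- list(
    mk("a1", c(TRUE, TRUE, TRUE)), mk("a2", c(TRUE, TRUE, FALSE)),
    mk("b1", c(FALSE, TRUE, TRUE)), mk("b2", c(FALSE, TRUE, TRUE)),
    mk("c1", c(FALSE, TRUE, FALSE)), mk("c2", c(FALSE, TRUE, FALSE)))
  causes <- c("A", "A", "B", "B", "C", "C")
  tm <- fit_tariff(records, causes)
  x <- tm$endorsement
  expect_equal(unname(x["i1", ]), c(1, 0, 0))
  # independent recomputation of the i1 row
  q <- stats::quantile(x["i1", ], c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(unname(tm$tariff["i1", ]),
               unname((x["i1", ] - stats::median(x["i1", ])) /
                        (q[2] - q[1])))
  expect_gt(tm$tariff["i1", "A"], 0)
  expect_true(all(tm$tariff["i1", c("B", "C")] <= 0))
  # flat endorsement row carries zero tariffs
  expect_equal(unname(tm$tariff["i2", ]), c(0, 0, 0))
  # degenerate non-identical row: one endorsing cause among 5 makes both
  # the type-7 IQR and the MAD zero, so the declared fallback chain ends
  # at an all-zero tariff row (no spurious infinities)
  mk5 <- function(id, yes1) va_record(id, "adult", "female",
                                      c(i1 = ifelse(yes1, "yes", "no")))
  recs5 <- c(lapply(1:4, function(k) mk5(paste0("r", k), FALSE)),
             list(mk5("r5", TRUE)))
  tm5 <- fit_tariff(recs5, c("c1", "c2", "c3", "c4", "c5"))
  row <- tm5$endorsement["i1", ]
  expect_equal(stats::IQR(row, type = 7), 0)
  expect_equal(stats::mad(row), 0)
  expect_false(all(row == row[1]))
  expect_equal(unname(tm5$tariff["i1", ]), rep(0, 5))
  expect_error(fit_tariff(records, causes, cause_levels = c("A", "B", "D")),
               "D")
})

test_that("tariff is invariant to duplicating the training set", {
  mk <- function(id, yes) va_record(id, "adult", "female",
                                    stats::setNames(ifelse(yes, "yes", "no"),
                                                    c("i1", "i2")))
  records <- list(mk("a1", c(TRUE, FALSE)), mk("a2", c(TRUE, TRUE)),
                  mk("b1", c(FALSE, TRUE)), mk("b2", c(FALSE, FALSE)))
  causes <- c("A", "A", "B", "B")
  t1 <- fit_tariff(records, causes)
  t2 <- fit_tariff(c(records, records), c(causes, causes))
  expect_equal(t1$tariff, t2$tariff)
})

test_that("tariff scoring is the endorsed-row sum", {
  tm <- list(tariff = matrix(c(1, -1, 0.5, 2, 0, -0.5), 3, 2,
                             dimnames = list(c("i1", "i2", "i3"),
                                             c("A", "B"))))
  class(tm) <- "va_tariff_matrix"
  expect_equal(unname(tariff_score(character(0), tm)), c(0, 0))
  expect_equal(unname(tariff_score(c(i2 = "yes"), tm)),
               unname(tm$tariff["i2", ]))
  # multi-endorsement equals brute-force summation; no/dont_know ignored
  resp <- c(i1 = "yes", i2 = "no", i3 = "yes")
  expect_equal(unname(tariff_score(resp, tm)),
               unname(tm$tariff["i1", ] + tm$tariff["i3", ]))
})

test_that("assignment thresholds and tie-breaks behave as declared", {
  m <- va_prob_matrix(matrix(c(0.7, 0.3), 1, 2,
                             dimnames = list("i1", c("X", "Y"))))
  rec <- va_record("r", "adult", "female", c(i1 = "yes"))
  a <- assign_cause(rec, "bayes", m, tau = 0)
  expect_equal(a$top_cause, "X")
  expect_equal(a$top_value, 0.7, tolerance = 1e-9)
  # below threshold -> VA-99
  a99 <- assign_cause(rec, "bayes", m, tau = 0.75)
  expect_equal(a99$top_cause, "VA-99")
  # exact tie -> first cause in order, tie recorded
  m_tie <- va_prob_matrix(matrix(c(0.5, 0.5), 1, 2,
                                 dimnames = list("i1", c("X", "Y"))))
  at <- assign_cause(rec, "bayes", m_tie)
  expect_equal(at$top_cause, "X")
  expect_true(at$tie)
})

test_that("CSMF aggregation tallies and averages correctly", {
  mk_assign <- function(scores, top) {
    structure(list(record_id = "r", engine = "bayes", scores = scores,
                   top_cause = top, top_value = max(scores), tie = FALSE),
              class = "va_assignment")
  }
  s <- c(A = 1, B = 0)
  a1 <- mk_assign(c(A = 1, B = 0), "A")
  a2 <- mk_assign(c(A = 0, B = 1), "B")
  expect_equal(unname(csmf_from_assignments(rep(list(a1), 10))["A"]), 1)
  pa <- csmf_from_assignments(list(a1, a2), method = "posterior_average")
  expect_equal(unname(pa[c("A", "B")]), c(0.5, 0.5), ignore_attr = TRUE)
  mixed <- csmf_from_assignments(list(a1, a1, a2), method = "top_cause")
  expect_equal(unname(mixed[c("A", "B")]), c(2 / 3, 1 / 3),
               ignore_attr = TRUE)
  expect_equal(sum(mixed), 1, tolerance = 1e-9)
  expect_error(csmf_from_assignments(list()), "no assignments")
})
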