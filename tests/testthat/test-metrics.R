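test_that("binary metrics match hand computation, flag undefined ratios", {
  cm <- confusion_matrix(c(rep("pos", 50), rep("neg", 50)),
                         c(rep("pos", 40), rep("neg", 10),
                           rep("pos", 20), rep("neg", 30)))
  m <- binary_metrics(cm, "pos")
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$ppv, 40 / 60)
  expect_equal(m$npv, 0.75)
  # perfect diagonal: every metric 1 for every cause
  diag3 <- confusion_matrix(rep(c("a", "b", "c"), 5),
                            rep(c("a", "b", "c"), 5))
  for (cause in c("a", "b", "c")) {
    expect_equal(unlist(binary_metrics(diag3, cause)),
                 c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  }
  # never-assigned cause: PPV undefined, not zero
  cm2 <- confusion_matrix(c("a", "a", "b"), c("b", "b", "b"),
                          cause_levels = c("a", "b"))
  ppv <- binary_metrics(cm2, "a")$ppv
  expect_true(is.na(ppv))
  expect_true(attr(ppv, "undefined"))
  expect_error(binary_metrics(cm2, "zz"), "not in confusion")
})

test_that("kappa: hand fixture, identity, independence", {
  cm <- matrix(c(40, 20, 10, 30), 2, 2,
               dimnames = list(c("p", "n"), c("p", "n")))
  expect_equal(cohens_kappa(cm), 0.4)  # p_o = 0.7, p_e = 0.5
  expect_equal(cohens_kappa(diag(5) * 7), 1)
  # statistically independent margins -> exactly 0 (outer-product counts)
  ind <- outer(c(60, 40), c(30, 70)) / 100
  expect_equal(cohens_kappa(ind), 0, tolerance = 1e-12)
  # degenerate: all mass on one agreeing cell
  one <- matrix(c(10, 0, 0, 0), 2, 2)
  expect_true(is.na(cohens_kappa(one)))
})

test_that("CSMF accuracy: fixtures, worst case, declared min convention", {
  expect_equal(csmf_accuracy(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)), 1)
  expect_equal(csmf_accuracy(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2)), 0.75)
  # worst case: all predicted mass on the min-true cause -> exactly 0
  true <- c(0.5, 0.3, 0.2)
  expect_equal(csmf_accuracy(true, c(0, 0, 1)), 0, tolerance = 1e-12)
  # relabeling symmetry
  perm <- c(3, 1, 2)
  expect_equal(csmf_accuracy(true[perm], c(0.3, 0.5, 0.2)[perm]),
               csmf_accuracy(true, c(0.3, 0.5, 0.2)))
  # declared convention: appending a true = pred = 0 cause changes the
  # normalizer (min over the declared list as given)
  base <- csmf_accuracy(c(0.5, 0.5), c(0.3, 0.7))
  extended <- csmf_accuracy(c(0.5, 0.5, 0), c(0.3, 0.7, 0))
  expect_equal(base, 1 - 0.4 / (2 * 0.5))
  expect_equal(extended, 1 - 0.4 / 2)
  expect_gt(extended, base)
  # degenerate truth undefined; malformed input errors
  expect_true(is.na(csmf_accuracy(1, 1)))
  expect_error(csmf_accuracy(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("chance-corrected concordance: fixtures and chance level", {
  perfect <- confusion_matrix(rep(c("a", "b", "c"), 4),
                              rep(c("a", "b", "c"), 4))
  ccc <- chance_corrected_concordance(perfect)
  expect_equal(unname(ccc$per_cause), c(1, 1, 1))
  expect_equal(ccc$average, 1)
  # P(correct | true j) = 0.6 for all j, N = 3 -> (0.6 - 1/3)/(2/3) = 0.4
  cm <- matrix(c(6, 2, 2, 2, 6, 2, 2, 2, 6), 3, 3, byrow = TRUE,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(chance_corrected_concordance(cm)$average, 0.4,
               tolerance = 1e-12)
  # uniform random assignment at large n averages ~0 (3 sigma tolerance)
  set.seed(42)
  n <- 10000
  truth <- sample(letters[1:4], n, replace = TRUE)
  assigned <- sample(letters[1:4], n, replace = TRUE)
  avg <- chance_corrected_concordance(confusion_matrix(truth, assigned))$average
  # per-cause binomial SE rescaled by 1/(1 - 1/N); average over 4 causes
  se <- sqrt(0.25 * 0.75 / (n / 4)) / (1 - 0.25) / sqrt(4)
  expect_lt(abs(avg), 3 * se)
  # cause with zero true deaths excluded from the average
  cm0 <- matrix(c(5, 0, 0, 0, 0, 0, 0, 5, 0), 3, 3, byrow = TRUE,
                dimnames = list(letters[1:3], letters[1:3]))
  ccc0 <- chance_corrected_concordance(cm0)
  expect_true(is.na(ccc0$per_cause["b"]))
  expect_equal(ccc0$average, mean(ccc0$per_cause, na.rm = TRUE))
  expect_error(chance_corrected_concordance(matrix(1, 1, 1)), "2 causes")
})

test_that("Lin's CCC: identity, reversal, shift penalty", {
  expect_equal(csmf_concordance_correlation(c(0.7, 0.3, 0.5),
                                            c(0.7, 0.3, 0.5)), 1)
  # reversed pairs over 2 causes: brute-force formula evaluation
  x <- c(0.7, 0.3); y <- c(0.3, 0.7)
  n <- 2
  vx <- stats::var(x) * (n - 1) / n
  cxy <- stats::cov(x, y) * (n - 1) / n
  want <- 2 * cxy / (2 * vx + 0)
  got <- csmf_concordance_correlation(x, y)
  expect_equal(got, want)
  expect_lt(got, 0)
  # perfect correlation with a location shift scores below 1
  shifted <- csmf_concordance_correlation(c(0.1, 0.2, 0.3),
                                          c(0.2, 0.3, 0.4))
  expect_lt(shifted, 1)
  expect_gt(shifted, 0)
  expect_true(is.na(csmf_concordance_correlation(c(0.5, 0.5), c(0.5, 0.5))))
  expect_error(csmf_concordance_correlation(1, 1), "paired")
})

test_that("bounded metrics stay in range on random confusion matrices", {
  set.seed(7)
  for (k in 1:25) {
    n_causes <- sample(2:6, 1)
    cm <- matrix(rpois(n_causes^2, 3), n_causes, n_causes,
                 dimnames = list(letters[1:n_causes], letters[1:n_causes]))
    if (sum(cm) == 0) cm[1, 1] <- 1
    kap <- cohens_kappa(cm)
    if (!is.na(kap)) expect_true(kap >= -1 && kap <= 1)
    ccc <- chance_corrected_concordance(cm)
    expect_true(all(ccc$per_cause <= 1, na.rm = TRUE))
    truth <- rowSums(cm) / sum(cm)
    pred <- colSums(cm) / sum(cm)
    acc <- csmf_accuracy(truth, pred)
    if (!is.na(acc)) expect_true(acc >= 0 && acc <= 1)
    lin <- csmf_concordance_correlation(truth, pred)
    if (!is.na(lin)) expect_true(lin >= -1 && lin <= 1)
  }
})

test_that("collapsing two causes never decreases observed agreement", {
  set.seed(8)
  for (k in 1:10) {
    cm <- matrix(rpois(16, 4), 4, 4)
    po <- sum(diag(cm)) / sum(cm)
    # merge causes 1 and 2
    merged <- rbind(cm[1, ] + cm[2, ], cm[3, ], cm[4, ])
    merged <- cbind(merged[, 1] + merged[, 2], merged[, 3], merged[, 4])
    po2 <- sum(diag(merged)) / sum(merged)
    expect_gte(po2, po)
  }
})

test_that("rank AUC uses midranks and flags empty classes", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(rank_auc(truth, c(4, 3, 2, 1)), 1)
  expect_equal(rank_auc(truth, c(1, 2, 3, 4)), 0)
  expect_equal(rank_auc(truth, c(1, 1, 1, 1)), 0.5)
  # hand case: scores 3,1,2,1 -> pairs: (3>2),(3>1),(1<2),(1=1 tie)
  expect_equal(rank_auc(truth, c(3, 1, 2, 1)), (1 + 1 + 0 + 0.5) / 4)
  expect_true(is.na(rank_auc(c(TRUE, TRUE), c(1, 2))))
})
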