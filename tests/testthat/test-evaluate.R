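test_that("confusion counts enumerate the four cells", {
  cm <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cm)[c("TP", "FN", "TN", "FP")],
               list(TP = 1, FN = 1, TN = 1, FP = 1))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0)
  # inverting predictions swaps (TP, FN) with (FP, TN)
  y <- rep(c(0, 1), c(7, 5)); p <- c(rep(0, 4), rep(1, 8))
  a <- confusion_counts(y, p); b <- confusion_counts(y, 1 - p)
  expect_equal(c(a$TP, a$FN, a$FP, a$TN), c(b$FN, b$TP, b$TN, b$FP))
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "labels")
  expect_error(confusion_counts(c(0, 1), c(0, 1, 1)), "lengths")
})

test_that("metrics agree with an independent kappa implementation", {
  skip_if_not_installed("e1071")
  set.seed(31)
  y <- rbinom(500, 1, 0.45)
  p <- ifelse(runif(500) < 0.8, y, 1 - y)
  m <- classification_metrics(confusion_counts(y, p))
  tab <- table(factor(p, levels = 0:1), factor(y, levels = 0:1))
  ref <- e1071::classAgreement(tab)
  expect_equal(m$accuracy, ref$diag, tolerance = 1e-12)
  expect_equal(m$kappa, ref$kappa, tolerance = 1e-12)
})

test_that("metric edge cases are flagged, not fabricated", {
  all_neg <- classification_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.na(all_neg$precision))
  expect_true("precision" %in% attr(all_neg, "flagged"))
  perfect <- classification_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1",
                                "kappa")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, kappa = 1))
  # equal cells = chance agreement
  chance <- classification_metrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(chance$kappa, 0)
})

test_that("kappa equals 2 (accuracy - 1/2) under balanced marginals", {
  for (tp in c(30, 40, 45)) {
    cm <- list(TP = tp, TN = tp, FP = 50 - tp, FN = 50 - tp)
    m <- classification_metrics(cm)
    expect_equal(m$kappa, 2 * (m$accuracy - 0.5), tolerance = 1e-12)
  }
})

test_that("McNemar statistics match their closed forms and stats::mcnemar.test", {
  r <- mcnemar_from_counts(10, 2)
  expect_equal(r$chi2, 49 / 12, tolerance = 1e-12)
  expect_equal(r$p_value, 0.0433, tolerance = 1e-3)
  ref <- stats::mcnemar.test(matrix(c(5, 2, 10, 5), 2), correct = TRUE)
  expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  # without correction the statistic is the squared standardized difference
  set.seed(8)
  for (i in 1:20) {
    b <- rpois(1, 30); c_ <- rpois(1, 10)
    u <- mcnemar_from_counts(b, c_, continuity = FALSE)
    expect_equal(u$chi2, (b - c_)^2 / (b + c_), tolerance = 1e-12)
  }
})

test_that("paired comparison counts discordant predictions correctly", {
  y <- c(1, 1, 1, 0, 0, 0)
  pa <- c(1, 1, 0, 0, 0, 1)  # A correct on 1,2,4,5
  pb <- c(1, 0, 0, 0, 1, 1)  # B correct on 1,3? no: B correct on 1,4
  r <- mcnemar_compare(y, pa, pb)
  expect_equal(r$b, sum(pa == y & pb != y))
  expect_equal(r$c, sum(pa != y & pb == y))
  same <- mcnemar_compare(y, pa, pa)
  expect_equal(same$b + same$c, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$chi2, 0)
})

test_that("probability summaries quantify class separation", {
  sep <- probability_summary(c(rep(0.05, 50), rep(0.95, 50)),
                             rep(c(0, 1), each = 50))
  expect_equal(sep$overlap, 0)
  p <- rep(c(0.2, 0.8), 25)
  same <- probability_summary(c(p, p), rep(c(0, 1), each = 50))
  expect_equal(same$overlap, 1, tolerance = 1e-12)
})

test_that("overlap matches numeric integration for clipped Gaussians", {
  set.seed(12)
  n <- 200000
  p0 <- pmin(pmax(rnorm(n, 0.3, 0.1), 0), 1)
  p1 <- pmin(pmax(rnorm(n, 0.7, 0.1), 0), 1)
  got <- probability_summary(c(p0, p1), rep(0:1, each = n), bins = 40)$overlap
  # quadrature on the same bin grid
  br <- seq(0, 1, length.out = 41)
  d0 <- diff(pnorm(br, 0.3, 0.1)); d1 <- diff(pnorm(br, 0.7, 0.1))
  oracle <- sum(pmin(d0, d1))
  expect_lt(abs(got - oracle), 0.01)
})

test_that("metrics are invariant to sample order", {
  set.seed(13)
  y <- rbinom(100, 1, 0.5); p <- rbinom(100, 1, 0.5)
  o <- sample(100)
  expect_equal(classification_metrics(confusion_counts(y, p)),
               classification_metrics(confusion_counts(y[o], p[o])))
})

test_that("area agreement is symmetric percent agreement", {
  expect_equal(area_agreement(100, 100), 100)
  expect_equal(area_agreement(80, 100), 80)
  expect_equal(area_agreement(100, 80), 80)
  expect_error(area_agreement(-1, 5))
})
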