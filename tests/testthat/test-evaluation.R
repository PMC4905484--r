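test_that("logistic fit recovers the closed-form 2x2 log odds ratio", {
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  fit <- fitLogistic(x, y)
  expect_equal(unname(fit$coefficients), log(16), tolerance = 1e-6)
  expect_equal(fit$intercept, log(10 / 40), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("perfect separation raises an error instead of diverging", {
  x <- c(1:5, 6:10)
  y <- as.integer(x > 5)
  expect_error(fitLogistic(x, y), "separation")
  expect_error(fitLogistic(rnorm(10), rep(1, 10)), "label error")
})

test_that("a null predictor's coefficient shrinks to zero at large n", {
  set.seed(41)
  x <- rnorm(10000)
  y <- rbinom(10000, 1, 0.5)
  fit <- fitLogistic(x, y)
  expect_lt(abs(unname(fit$coefficients)), 0.1)
})

test_that("rank AUC equals pair counting, trapezoids, and pROC", {
  expect_equal(aucScore(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_equal(brutePairAUC(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)

  set.seed(43)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(c(1, 8), 1))  # sometimes heavy ties
    a <- aucScore(s, y)
    expect_equal(a, brutePairAUC(s, y), tolerance = 1e-12)
    expect_equal(a, trapezoidArea(rocPoints(s, y)), tolerance = 1e-10)
    expect_equal(aucScore(-s, y), 1 - a, tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:10) {
    y <- c(1, 0, rbinom(48, 1, 0.4))
    s <- rnorm(50) + y
    expect_equal(aucScore(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("Hanley-McNeil SE follows the plug-in formula at the boundaries", {
  expect_equal(unname(aucSeCi(0.5, 1, 1)["se"]), 0.5)
  expect_equal(unname(aucSeCi(1, 20, 30)["se"]), 0)
  out <- aucSeCi(0.74, 187, 47)
  expect_true(out["ci_low"] <= 0.74 && 0.74 <= out["ci_high"])
  expect_equal(unname(out["ci_high"] - 0.74), unname(0.74 - out["ci_low"]),
               tolerance = 1e-12)
})

test_that("DeLong SE matches the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(163)
  for (i in 1:5) {
    y <- c(1, 0, rbinom(58, 1, 0.4))
    s <- rnorm(60) + 0.8 * y
    expect_equal(aucSeDeLong(s, y),
                 sqrt(pROC::var(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<"))),
                 tolerance = 1e-10)
  }
  rs <- rocSummary(rnorm(60) + 0.8 * rep(0:1, 30), rep(0:1, 30),
                   seMethod = "delong")
  expect_true(rs$ci_low <= rs$auc && rs$auc <= rs$ci_high)
})

test_that("Youden cutoff maximizes J with the declared tie-breaks", {
  got <- youdenCutoff(c(0.9, 0.8, 0.25, 0.3, 0.2, 0.1),
                      c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(got["sensitivity"]), 1)
  expect_equal(unname(got["specificity"]), 2 / 3)
  expect_equal(unname(got["cutoff"]), 0.225)

  sep <- youdenCutoff(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(unname(sep["sensitivity"]), 1)
  expect_equal(unname(sep["specificity"]), 1)

  # alternative criterion: squared distance to the (0,1) ROC corner
  tl <- youdenCutoff(c(0.9, 0.8, 0.25, 0.3, 0.2, 0.1), c(1, 1, 1, 0, 0, 0),
                     criterion = "closest_topleft")
  expect_equal(unname(tl["sensitivity"]), 1)
  expect_equal(unname(tl["specificity"]), 2 / 3)

  # brute-force scan over every threshold on random score sets
  set.seed(53)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)
    got <- youdenCutoff(s, y)
    cands <- c(sort(unique(s)) - 1e-9, max(s) + 1)
    J <- vapply(cands, function(c)
      mean(s[y == 1] >= c) + mean(s[y == 0] < c) - 1, numeric(1))
    expect_equal(unname(got["sensitivity"] + got["specificity"] - 1),
                 max(J), tolerance = 1e-9)
  }
})

test_that("ROC summary is internally consistent", {
  set.seed(59)
  y <- rbinom(80, 1, 0.4)
  y[1:2] <- c(0, 1)
  s <- rnorm(80) + 1.2 * y
  rs <- rocSummary(s, y)
  expect_equal(rs$auc, trapezoidArea(rs$roc), tolerance = 1e-10)
  expect_equal(rs$roc$fpr[1], 0)
  expect_equal(rs$roc$tpr[nrow(rs$roc)], 1)
  expect_true(all(diff(rs$roc$fpr) >= 0) && all(diff(rs$roc$tpr) >= 0))
  expect_true(rs$ci_low <= rs$auc && rs$auc <= rs$ci_high)
})

test_that("single-marker search returns the discriminating marker", {
  expect_equal(bestSingleMarker(matrix(rnorm(20), 20, 1,
                                       dimnames = list(NULL, "only")),
                                rep(c(0, 1), 10))$marker, "only")
  set.seed(61)
  wins <- 0
  for (i in 1:20) {
    y <- rep(c(0, 1), each = 40)
    x <- cbind(noise = rnorm(80), marker = rnorm(80) + 2 * y)
    bw <- bestSingleMarker(x, y)
    wins <- wins + (bw$marker == "marker")
    # a dominating candidate wins under either criterion
    aic_win <- bestSingleMarker(x, y, criterion = "aic")
    lb <- bw$leaderboard
    if (lb$auc[1] > max(lb$auc[-1]) && lb$aic[1] < min(lb$aic[-1]))
      expect_equal(aic_win$marker, bw$marker)
  }
  expect_gte(wins, 19)
})

test_that("the fitted single-marker score preserves the raw marker's AUC", {
  set.seed(67)
  y <- rep(c(0, 1), each = 30)
  x <- rnorm(60) + 1.5 * y
  fit <- fitLogistic(x, y)
  expect_equal(aucScore(fit$fitted, y), aucScore(x, y), tolerance = 1e-12)
})

test_that("logistic parameter recovery at moderate n", {
  set.seed(71)
  ok <- 0
  for (i in 1:30) {
    x <- rnorm(2000)
    y <- rbinom(2000, 1, plogis(-1 + 1.5 * x))
    fit <- fitLogistic(x, y)
    ok <- ok + (abs(fit$intercept + 1) < 0.2 &&
                  abs(unname(fit$coefficients) - 1.5) < 0.2)
  }
  expect_gte(ok, 24)
})
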