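#' Fit a logistic marker model
#'
#' Maximum-likelihood logistic regression of a binary clinical contrast on
#' one or more marker relative levels, with explicit failure on complete
#' separation (rather than a silently diverging fit).
#'
#' @param x numeric vector or matrix of relative levels (samples x markers).
#' @param y binary outcome: 0/1, logical, or two-level factor (second level =
#'   positive class).
#' @param contrast optional `list(positive=, negative=)` group-label sets,
#'   recorded for provenance.
#' @return `LogisticModel`: list with `intercept`, `coefficients` (per unit
#'   relative level), `markers`, `fitted`, `converged`, `model` (the
#'   underlying [stats::glm] fit) and `contrast`.
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- rbinom(100, 1, plogis(-0.5 + x))
#' fitLogistic(x, y)$coefficients
#' @export
fitLogistic <- function(x, y, contrast = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("marker", seq_len(ncol(x)))
  y <- .binaryLabels(y)
  if (length(unique(y)) < 2)
    stop("label error: both classes must be present")
  if (any(apply(x, 2, function(col) length(unique(col)) == 1L)))
    stop("constant-column predictor(s) present")
  df <- data.frame(.y = y, x, check.names = FALSE)
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial()))
  p <- fitted(fit)
  eps <- 1e-7
  if (all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps))
    stop("separation error: classes are perfectly separated; ",
         "coefficients diverge")
  structure(list(intercept = unname(coef(fit)[1]),
                 coefficients = coef(fit)[-1],
                 markers = colnames(x),
                 fitted = as.numeric(p),
                 converged = fit$converged,
                 contrast = contrast,
                 model = fit),
            class = "LogisticModel")
}

.binaryLabels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("label error: y must be binary")
  as.integer(y)
}

#' @export
print.LogisticModel <- function(x, ...) {
  cat("LogisticModel: logit(p) =", signif(x$intercept, 5))
  for (i in seq_along(x$coefficients))
    cat(sprintf(" %+g*%s", signif(x$coefficients[i], 5), x$markers[i]))
  cat("\n  converged:", x$converged, "\n")
  invisible(x)
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half — computed from midranks,
#' and identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric marker scores (higher = more disease-like).
#' @param y binary labels (1 = positive class).
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, y) {
  y <- .binaryLabels(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("class error: both classes must be nonempty")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @inheritParams aucScore
#' @return data.frame of `(fpr, tpr)` points from (0,0) to (1,1), one step
#'   per distinct score, using the rule score >= cutoff => predicted
#'   positive.
#' @export
rocPoints <- function(scores, y) {
  y <- .binaryLabels(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("class error: both classes must be nonempty")
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) sum(scores >= c & y == 1) / n1, numeric(1))
  fpr <- vapply(cuts, function(c) sum(scores >= c & y == 0) / n0, numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under an ROC polygon
#' @param roc data.frame from [rocPoints()]
#' @return numeric area.
#' @export
trapezoidArea <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Hanley-McNeil standard error and Wald CI for an AUC
#'
#' Parametric-free SE of a rank AUC `A` with `Q1 = A/(2-A)` and
#' `Q2 = 2A^2/(1+A)`; the 95 percent confidence interval is
#' `A +/- z * se`, clipped to `[0, 1]`.
#'
#' @param auc the AUC estimate.
#' @param nPos,nNeg class sizes.
#' @param level confidence level (default 0.95).
#' @return named vector `c(se=, ci_low=, ci_high=)`.
#' @export
aucSeCi <- function(auc, nPos, nNeg, level = 0.95) {
  stopifnot(nPos >= 1, nNeg >= 1, auc >= 0, auc <= 1)
  A <- auc
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (nPos - 1) * (Q1 - A^2) +
                (nNeg - 1) * (Q2 - A^2)) / (nPos * nNeg))
  z <- qnorm(1 - (1 - level) / 2)
  c(se = se, ci_low = max(0, A - z * se), ci_high = min(1, A + z * se))
}

#' DeLong standard error of the empirical AUC
#'
#' Nonparametric SE from the per-observation placement components
#' (an alternative to the Hanley-McNeil plug-in that uses the observed
#' score distributions rather than the exponential model).
#'
#' @inheritParams aucScore
#' @return standard error of the rank AUC.
#' @export
aucSeDeLong <- function(scores, y) {
  y <- .binaryLabels(y)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  if (!length(pos) || !length(neg))
    stop("class error: both classes must be nonempty")
  psi <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  sqrt(stats::var(v10) / length(pos) + stats::var(v01) / length(neg))
}

#' Optimal operating cutoff by Youden's J
#'
#' Scans midpoints between adjacent distinct scores (plus sentinels below
#' and above the range) under the rule score >= cutoff => predicted
#' positive, and maximizes `J = sensitivity + specificity - 1` (or, with
#' `criterion = "closest_topleft"`, minimizes the squared ROC distance to
#' the ideal (0, 1) corner). Ties are broken toward higher sensitivity,
#' then toward the lower cutoff.
#'
#' @inheritParams aucScore
#' @param criterion `"youden"` (default) or `"closest_topleft"`.
#' @return named vector `c(cutoff=, sensitivity=, specificity=)`.
#' @export
youdenCutoff <- function(scores, y, criterion = c("youden",
                                                  "closest_topleft")) {
  criterion <- match.arg(criterion)
  y <- .binaryLabels(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("class error: both classes must be nonempty")
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  sens <- vapply(cand, function(c) sum(scores >= c & y == 1) / n1, numeric(1))
  spec <- vapply(cand, function(c) sum(scores < c & y == 0) / n0, numeric(1))
  J <- if (criterion == "youden") sens + spec - 1
  else -((1 - sens)^2 + (1 - spec)^2)
  best <- which(J == max(J))
  best <- best[sens[best] == max(sens[best])]
  best <- best[which.min(cand[best])]
  c(cutoff = cand[best], sensitivity = sens[best], specificity = spec[best])
}

#' ROC summary for one marker score
#'
#' Bundles the empirical ROC points, the rank AUC with its Hanley-McNeil SE
#' and confidence interval, and the Youden-optimal cutoff's sensitivity and
#' specificity.
#'
#' @inheritParams aucScore
#' @param level confidence level (default 0.95).
#' @param seMethod `"hanley_mcneil"` (default) or `"delong"`.
#' @param cutoffCriterion passed to [youdenCutoff()].
#' @return `RocSummary`: list with `roc`, `auc`, `se`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
rocSummary <- function(scores, y, level = 0.95,
                       seMethod = c("hanley_mcneil", "delong"),
                       cutoffCriterion = c("youden", "closest_topleft")) {
  seMethod <- match.arg(seMethod)
  y <- .binaryLabels(y)
  a <- aucScore(scores, y)
  seci <- aucSeCi(a, sum(y == 1), sum(y == 0), level = level)
  if (seMethod == "delong") {
    se <- aucSeDeLong(scores, y)
    z <- qnorm(1 - (1 - level) / 2)
    seci <- c(se = se, ci_low = max(0, a - z * se),
              ci_high = min(1, a + z * se))
  }
  yj <- youdenCutoff(scores, y, criterion = match.arg(cutoffCriterion))
  structure(list(roc = rocPoints(scores, y), auc = a,
                 se = unname(seci["se"]), ci_low = unname(seci["ci_low"]),
                 ci_high = unname(seci["ci_high"]),
                 cutoff = unname(yj["cutoff"]),
                 sensitivity = unname(yj["sensitivity"]),
                 specificity = unname(yj["specificity"]),
                 n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "RocSummary")
}

#' @export
print.RocSummary <- function(x, ...) {
  cat(sprintf("RocSummary: AUC %.3f [SE = %.3f, 95%% CI: %.3f-%.3f]\n",
              x$auc, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  cutoff %.4g: sensitivity %.1f%%, specificity %.1f%% (%d pos / %d neg)\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Best single-marker logistic model for a clinical contrast
#'
#' Fits each candidate marker alone against the outcome and returns the
#' model maximizing the criterion (rank AUC of the fitted score, or minimal
#' AIC), together with the full per-candidate leaderboard. Markers whose
#' fits fail (e.g. separation) stay on the leaderboard with `NA` scores.
#'
#' @param x matrix of relative levels, one column per candidate marker.
#' @param y binary outcome.
#' @param criterion `"auc"` (default) or `"aic"`.
#' @return list with `marker`, `model` ([fitLogistic()] fit), `summary`
#'   ([rocSummary()] of the winning score) and `leaderboard` (data.frame
#'   marker/auc/aic/converged sorted by the criterion).
#' @export
bestSingleMarker <- function(x, y, criterion = c("auc", "aic")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  if (!ncol(x)) stop("search error: no candidate markers")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("marker", seq_len(ncol(x)))
  y <- .binaryLabels(y)
  fits <- lapply(colnames(x), function(mk)
    tryCatch(fitLogistic(x[, mk, drop = FALSE], y), error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  lb <- data.frame(
    marker = colnames(x),
    auc = vapply(seq_along(fits), function(i)
      if (ok[i]) aucScore(fits[[i]]$fitted, y) else NA_real_, numeric(1)),
    aic = vapply(seq_along(fits), function(i)
      if (ok[i]) fits[[i]]$model$aic else NA_real_, numeric(1)),
    converged = vapply(seq_along(fits), function(i)
      ok[i] && fits[[i]]$converged, logical(1)),
    stringsAsFactors = FALSE)
  if (!any(ok)) stop("search error: every candidate fit failed")
  score <- if (criterion == "auc") lb$auc else -lb$aic
  lb <- lb[order(-score, lb$marker), , drop = FALSE]
  rownames(lb) <- NULL
  win <- lb$marker[1]
  wi <- match(win, colnames(x))
  list(marker = win, model = fits[[wi]],
       summary = rocSummary(fits[[wi]]$fitted, y),
       leaderboard = lb)
}
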