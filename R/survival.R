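#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Mean-dichotomization of marker levels
#'
#' Splits patients into "low" and "high" marker groups at the cohort mean of
#' the relative expression level: high means strictly above the mean, a value
#' exactly at the mean is "low". If every patient falls on one side a
#' degenerate-split warning is raised (downstream two-group analyses will
#' refuse such a split).
#'
#' @param levels numeric per-patient relative levels (finite).
#' @return factor with levels `c("low", "high")`; attribute `counts` holds
#'   the group sizes and attribute `mean` the split point.
#' @export
dichotomizeByMean <- function(levels) {
  if (length(levels) < 2) stop("need >= 2 patients to dichotomize")
  if (any(!is.finite(levels))) stop("levels must be finite")
  mu <- mean(levels)
  lab <- factor(ifelse(levels > mu, "high", "low"), levels = c("low", "high"))
  counts <- table(lab)
  if (any(counts == 0))
    warning("degenerate split: all patients on one side of the mean")
  attr(lab, "counts") <- c(counts)
  attr(lab, "mean") <- mu
  lab
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; censored observations
#' tied with events at the same time are handled after the events, per the
#' standard convention. Without censoring the estimate equals the empirical
#' survival function.
#'
#' @param times follow-up times in months (>= 0).
#' @param events event indicator (1 = dead, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, starting from the S(0) = 1 row.
#' @export
kmCurve <- function(times, events) {
  if (!length(times)) stop("data error: no observations")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  fit <- survfit(Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(times), fit$n.risk),
             n_event = c(0, fit$n.event),
             n_censor = c(0, fit$n.censor),
             surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' The standard log-rank statistic summing hypergeometric
#' expectation/variance contributions over the distinct event times, with a
#' p-value from the chi-square distribution on one degree of freedom. A
#' permutation p-value (random relabelings of the group vector) is available
#' for small samples.
#'
#' @param times,events as in [kmCurve()].
#' @param groups two-level grouping vector.
#' @param nPermutations if > 0, additionally compute a permutation p-value
#'   from this many shuffles.
#' @return list with `chisq`, `df`, `p`, per-group `observed`/`expected`,
#'   and `p_permutation` when requested.
#' @export
logrankTest <- function(times, events, groups, nPermutations = 0) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("group error: exactly two nonempty groups required")
  groups <- droplevels(groups)
  sd0 <- survdiff(Surv(times, events) ~ groups)
  chisq <- sd0$chisq
  out <- list(chisq = chisq, df = 1,
              p = pchisq(chisq, df = 1, lower.tail = FALSE),
              observed = setNames(sd0$obs, levels(groups)),
              expected = setNames(sd0$exp, levels(groups)))
  if (nPermutations > 0) {
    stat <- vapply(seq_len(nPermutations), function(i) {
      g <- sample(groups)
      survdiff(Surv(times, events) ~ g)$chisq
    }, numeric(1))
    out$p_permutation <- (1 + sum(stat >= chisq)) / (nPermutations + 1)
  }
  out
}

#' Build the multivariable survival design matrix
#'
#' Encodes the standard prognostic contrasts as 0/1 covariates, coded 1 for
#' the first-listed (risk) level: stage III-IV vs I-II, CEA > 5 ug/L vs
#' <= 5, age >= 55 vs < 55 years, female vs male, chemotherapy yes vs no,
#' and each marker high vs low. Controls are excluded; patients missing any
#' required field (or survival information) are dropped with a report.
#'
#' @param samples a [SampleTable-class] containing patients with `group`,
#'   `cea`, `age`, `sex`, `chemotherapy`, `os_time`, `os_event`.
#' @param markerLabels named list of per-patient low/high factors (as from
#'   [dichotomizeByMean()]) named by the patient `sample_id`s of `samples`'
#'   patient rows, or plain vectors aligned with those rows.
#' @return list with `design` (data.frame of 0/1 covariates), `times`,
#'   `events`, `sample_id` and `dropped` (ids removed for missing data).
#' @export
buildDesign <- function(samples, markerLabels = list()) {
  stopifnot(is(samples, "SampleTable"))
  pat <- samples[as.character(samples$group) != "control", , drop = FALSE]
  if (!nrow(pat)) stop("design error: no patients")
  req <- c("cea", "age", "sex", "chemotherapy", "os_time", "os_event")
  missing_cols <- setdiff(req, colnames(pat))
  if (length(missing_cols))
    stop("design error: missing clinical column(s): ",
         paste(missing_cols, collapse = ", "))
  design <- data.frame(
    stage_iii_iv = as.integer(as.character(pat$group) %in% c("III", "IV")),
    cea_high = as.integer(pat$cea > 5),
    age_55 = as.integer(pat$age >= 55),
    female = as.integer(tolower(as.character(pat$sex)) == "female"),
    chemotherapy = as.integer(pat$chemotherapy == 1))
  for (mk in names(markerLabels)) {
    lab <- markerLabels[[mk]]
    v <- if (!is.null(names(lab))) lab[pat$sample_id] else lab
    design[[paste0(mk, "_high")]] <- as.integer(as.character(v) == "high")
  }
  keep <- complete.cases(design) & !is.na(pat$os_time) & !is.na(pat$os_event)
  if (!any(keep)) stop("design error: every patient dropped for missing data")
  list(design = design[keep, , drop = FALSE],
       times = as.numeric(pat$os_time[keep]),
       events = as.integer(pat$os_event[keep]),
       sample_id = pat$sample_id[keep],
       dropped = pat$sample_id[!keep])
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Breslow tie handling by default, Efron available)
#' reporting, per covariate, the coefficient, the risk ratio `RR = exp(beta)`
#' with its Wald 95 percent confidence interval and the Wald p-value —
#' the usual multivariable prognostic-factor table.
#'
#' @param design data.frame of covariates (e.g. from [buildDesign()]).
#' @param times,events survival outcome.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return `CoxFit`: data.frame with columns factor, coef, se, p, risk_ratio,
#'   ci_low, ci_high; the underlying [survival::coxph] fit in attribute
#'   `fit`.
#' @export
coxFit <- function(design, times, events, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(events) < 1) stop("fit error: no events observed")
  if (any(vapply(design, function(col) length(unique(col)) == 1L, logical(1))))
    stop("fit error: constant covariate present")
  df <- cbind(data.frame(.t = times, .e = events), design)
  fit <- withCallingHandlers(
    coxph(Surv(.t, .e) ~ ., data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w)))
        stop("fit error: monotone likelihood or non-convergence: ",
             conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  out <- data.frame(factor = rownames(co),
                    coef = co[, "coef"],
                    se = co[, "se(coef)"],
                    p = co[, "Pr(>|z|)"],
                    risk_ratio = exp(co[, "coef"]),
                    ci_low = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("CoxFit", "data.frame")
  attr(out, "ties") <- ties
  attr(out, "fit") <- fit
  out
}
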