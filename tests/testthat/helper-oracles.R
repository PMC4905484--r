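# Independent oracles and small in-code fixtures shared across the suite.

# Exact two-sided Mann-Whitney p by full enumeration of group labelings:
# distance of the U statistic from its null center, tail-doubled by symmetry.
bruteMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); nb <- length(b)
  u_of <- function(bv, av) sum(outer(bv, av, ">")) + 0.5 * sum(outer(bv, av, "=="))
  center <- length(a) * nb / 2
  obs <- abs(u_of(b, a) - center)
  picks <- utils::combn(n, nb)
  stats <- apply(picks, 2, function(idx)
    abs(u_of(pooled[idx], pooled[-idx]) - center))
  mean(stats >= obs - 1e-12)
}

# AUC by exhaustive concordant-pair counting (ties count one half).
brutePairAUC <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# -ddCt by explicit loops, no matrix algebra.
bruteRelativeExpression <- function(ct, ref_assay, groups, baseline) {
  out <- ct * NA
  for (s in seq_len(ncol(ct))) for (a in seq_len(nrow(ct)))
    out[a, s] <- ct[a, s] - ct[ref_assay, s]
  base_cols <- which(groups == baseline)
  for (a in seq_len(nrow(ct))) {
    mu <- mean(out[a, base_cols])
    for (s in seq_len(ncol(ct))) out[a, s] <- -(out[a, s] - mu)
  }
  out
}

# Two-group log-rank by hand: hypergeometric mean/variance at each distinct
# event time.
handLogrank <- function(times, events, groups) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == gl[1])
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & groups == gl[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(O = O, E = E, V = V, chisq = chisq)
}

# Breslow partial log-likelihood for a single covariate (grid-search oracle).
breslowPLL <- function(beta, x, times, events) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    risk <- times >= t
    dead <- events == 1 & times == t
    ll <- ll + beta * sum(x[dead]) - sum(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Small CtSet fixture: deterministic values, optional planted structure.
makeCtSet <- function(values, ceiling = 40, ...) {
  CtSet(values, ceiling = ceiling, ...)
}

# A tiny five-group expression object with annotation, for screening tests.
makeExprSet <- function(m, groups) {
  ids <- colnames(m)
  cd <- data.frame(sample_id = ids, cohort = "discovery",
                   group = groups, row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relLevel = m), colData = S4Vectors::DataFrame(cd))
  S4Vectors::metadata(se)$reference_assay <- "ref"
  S4Vectors::metadata(se)$baseline_group <- "control"
  new("RelativeExpressionSet", se)
}
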