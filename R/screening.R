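#' A pairwise group comparison specification
#'
#' @param name comparison label.
#' @param sideA,sideB disjoint, nonempty sets of group labels.
#' @param category marker category this comparison screens for: one of
#'   `"detection"`, `"early_stage"`, `"late_stage"`, `"metastasis"`,
#'   `"stage2_vs_3"`.
#' @return a classed list (`ComparisonSpec`).
#' @export
comparisonSpec <- function(name, sideA, sideB, category) {
  sideA <- as.character(sideA); sideB <- as.character(sideB)
  stopifnot(length(sideA) > 0, length(sideB) > 0)
  if (length(intersect(sideA, sideB)))
    stop("comparison sides must be disjoint: ", name)
  if (!all(c(sideA, sideB) %in% GROUP_LEVELS))
    stop("unknown group label in comparison ", name)
  category <- match.arg(category, c("detection", "early_stage", "late_stage",
                                    "metastasis", "stage2_vs_3"))
  structure(list(name = name, sideA = sideA, sideB = sideB,
                 category = category), class = "ComparisonSpec")
}

#' The seven staged comparisons of the screening design
#'
#' Returns the standard comparison scheme: control vs all CRC, control vs
#' stage I-II, control vs stage III-IV, stage I-II vs III-IV, control vs
#' stage IV, stage I-III vs stage IV, and stage II vs stage III, each tagged
#' with the marker category it screens for (disease detection, early-stage,
#' late-stage, metastasis, and the stage II/III distinction that drives
#' adjuvant-chemotherapy decisions).
#'
#' @return list of seven [comparisonSpec()] objects.
#' @export
defaultScheme <- function() {
  list(
    comparisonSpec("control_vs_CRC", "control", CRC_GROUPS, "detection"),
    comparisonSpec("control_vs_I-II", "control", c("I", "II"), "early_stage"),
    comparisonSpec("control_vs_III-IV", "control", c("III", "IV"), "late_stage"),
    comparisonSpec("I-II_vs_III-IV", c("I", "II"), c("III", "IV"), "late_stage"),
    comparisonSpec("control_vs_IV", "control", "IV", "metastasis"),
    comparisonSpec("I-III_vs_IV", c("I", "II", "III"), "IV", "metastasis"),
    comparisonSpec("II_vs_III", "II", "III", "stage2_vs_3"))
}

#' Two-sided Mann-Whitney p-value
#'
#' Exact null enumeration when the combined sample size is at most
#' `exactMax` and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction.
#' @noRd
.mannWhitneyP <- function(a, b, exactMax = 20) {
  pooled <- c(a, b)
  if (all(pooled == pooled[1])) return(1)  # degenerate: no rank information
  exact <- length(pooled) <= exactMax && !anyDuplicated(pooled)
  p <- suppressWarnings(
    wilcox.test(b, a, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
  if (is.na(p)) 1 else min(p, 1)
}

#' Compare relative expression between two group sets
#'
#' Runs the configured two-sided test per assay for one comparison. The
#' effect measure is the difference of medians of the relative level
#' (side B minus side A); `direction` is `up_in_b`/`down_in_b` from the sign
#' of the effect (`tie` when the medians are equal). Mann-Whitney p-values
#' use exact enumeration when the combined n is at most 20 with no ties, and
#' the tie-corrected normal approximation otherwise; `t_test` uses Welch's
#' two-sample t-test.
#'
#' @param expr a [RelativeExpressionSet-class] (group annotation in
#'   `colData`).
#' @param samples optional [SampleTable-class] overriding the annotation.
#' @param spec a [comparisonSpec()].
#' @param test `"mann_whitney"` (default) or `"t_test"`.
#' @return data.frame with one row per assay: assay, comparison, category,
#'   test, p_value, effect, direction.
#' @export
compareGroups <- function(expr, samples = NULL, spec,
                          test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  stopifnot(is(expr, "RelativeExpressionSet"))
  grp <- if (!is.null(samples))
    as.character(samples$group[match(colnames(expr), samples$sample_id)])
  else as.character(colData(expr)$group)
  ia <- which(grp %in% spec$sideA)
  ib <- which(grp %in% spec$sideB)
  if (length(ia) < 2 || length(ib) < 2)
    stop("comparison error: fewer than 2 samples on one side of ", spec$name)
  m <- relLevels(expr)
  p <- vapply(seq_len(nrow(m)), function(i) {
    a <- m[i, ia]; b <- m[i, ib]
    if (test == "mann_whitney") .mannWhitneyP(a, b)
    else tryCatch(t.test(b, a)$p.value, error = function(e) 1)
  }, numeric(1))
  eff <- apply(m[, ib, drop = FALSE], 1L, median) -
    apply(m[, ia, drop = FALSE], 1L, median)
  data.frame(assay = rownames(m), comparison = spec$name,
             category = spec$category, test = test, p_value = p,
             effect = eff,
             direction = ifelse(eff > 0, "up_in_b",
                                ifelse(eff < 0, "down_in_b", "tie")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen for candidate marker miRNAs across a comparison scheme
#'
#' Runs every comparison of the scheme and keeps assays with `p < alpha`
#' (significant candidates) plus, flagged but not selected, assays in the
#' trend band `alpha <= p < alphaTrend` — the borderline behaviour a
#' reviewer may still want to see (default band up to 0.06). Optional
#' Benjamini-Hochberg correction is applied within each comparison across
#' assays before thresholding.
#'
#' @inheritParams compareGroups
#' @param scheme list of [comparisonSpec()]s (default [defaultScheme()]).
#' @param alpha significance threshold (default 0.05).
#' @param alphaTrend upper edge of the trend band (default 0.06).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param keepAll return all rows, with a `selected` column, instead of only
#'   candidate/trend rows.
#' @return data.frame candidate table: assay, comparison, category, test,
#'   p_value, effect, direction, selected (logical), trend (logical).
#' @export
runMarkerScreen <- function(expr, samples = NULL, scheme = defaultScheme(),
                            alpha = 0.05, alphaTrend = 0.06,
                            test = c("mann_whitney", "t_test"),
                            adjust = c("none", "BH"), keepAll = FALSE) {
  test <- match.arg(test); adjust <- match.arg(adjust)
  if (!length(scheme)) stop("empty comparison scheme")
  rows <- lapply(scheme, function(sp) {
    d <- compareGroups(expr, samples, sp, test = test)
    d$p_raw <- d$p_value
    if (adjust == "BH") d$p_value <- p.adjust(d$p_value, method = "BH")
    d$selected <- d$p_value < alpha
    d$trend <- !d$selected & d$p_value < alphaTrend
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!keepAll) out <- out[out$selected | out$trend, , drop = FALSE]
  attr(out, "parameters") <- list(alpha = alpha, alpha_trend = alphaTrend,
                                  test = test, adjust = adjust)
  out
}

#' Row z-scores for heat-map display
#'
#' Scales each selected assay's relative levels across samples to mean zero
#' and standard deviation one, using the population SD convention
#' (denominator n). This is the transform behind stage-ordered marker
#' heatmaps: values above the cohort mean shade one way, values below the
#' other.
#'
#' @param expr a [RelativeExpressionSet-class].
#' @param assays subset of assay names (default: all rows).
#' @return numeric z matrix with the same dimnames.
#' @export
zscoreForHeatmap <- function(expr, assays = NULL) {
  m <- relLevels(expr)
  if (!is.null(assays)) {
    missing <- setdiff(assays, rownames(m))
    if (length(missing)) stop("unknown assay(s): ",
                              paste(missing, collapse = ", "))
    m <- m[assays, , drop = FALSE]
  }
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  if (any(sdev == 0))
    stop("scaling error: zero-variance row(s): ",
         paste(rownames(m)[sdev == 0], collapse = ", "))
  (m - mu) / sdev
}
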