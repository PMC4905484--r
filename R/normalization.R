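#' Remove zero-variance assays
#'
#' Drops assays whose raw Ct is identical in every well — typically assays
#' never detected in any plasma sample, which sit at the detection ceiling
#' throughout and carry no information. The removed assay names are recorded
#' in `metadata(x)$removed_zero_variance`.
#'
#' @param ct a [CtSet-class] with at least 2 wells.
#' @return the filtered [CtSet-class].
#' @export
filterZeroVariance <- function(ct) {
  stopifnot(is(ct, "CtSet"))
  if (ncol(ct) < 2) stop("need >= 2 wells to assess variance")
  m <- ctValues(ct)
  flat <- apply(m, 1L, function(r) all(r == r[1]))
  if (all(flat))
    stop("all assays have zero variance; nothing left to analyse")
  out <- ct[!flat, ]
  metadata(out)$removed_zero_variance <- rownames(ct)[flat]
  out
}

#' Per-assay Ct summary used for reference ranking
#' @noRd
.assayStats <- function(ct) {
  m <- ctValues(ct)
  data.frame(assay = rownames(m),
             card = as.character(rowData(ct)$card),
             sd_ct = apply(m, 1L, sd),
             mean_ct = rowMeans(m),
             any_undetected = apply(undetectedWells(ct), 1L, any),
             stringsAsFactors = FALSE)
}

#' Shortlist candidate normalization references
#'
#' Applies the first two selection criteria: per card, the `k` assays with the
#' smallest Ct standard deviation (criterion 1, expression stability) among
#' assays with high enough RNA yield, i.e. mean raw Ct at most `maxMeanCt`
#' (criterion 2), and with no undetected well. Ties in SD are broken
#' lexicographically by assay name.
#'
#' @param ct a [CtSet-class], zero-variance assays already removed.
#' @param k shortlist size per card (default 6).
#' @param maxMeanCt yield threshold in cycles (default 35).
#' @return [ReferenceReport-class] with shortlists only (no neutrality
#'   p-values, no chosen assay yet).
#' @export
shortlistReferences <- function(ct, k = 6, maxMeanCt = 35) {
  stopifnot(is(ct, "CtSet"), k >= 1)
  st <- .assayStats(ct)
  st <- st[!st$any_undetected & st$mean_ct <= maxMeanCt, , drop = FALSE]
  if (!nrow(st)) {
    warning("no assays eligible for the reference shortlist")
    sl <- st
  } else {
    pieces <- lapply(split(st, st$card), function(d) {
      d <- d[order(d$sd_ct, d$assay), , drop = FALSE]
      if (nrow(d) < k)
        warning(sprintf("card %s: only %d eligible assay(s) for a shortlist of %d",
                        d$card[1], nrow(d), k))
      utils::head(d, k)
    })
    sl <- do.call(rbind, pieces)
    rownames(sl) <- NULL
  }
  sl$neutrality_p_cancer <- rep(NA_real_, nrow(sl))
  sl$neutrality_p_overall <- rep(NA_real_, nrow(sl))
  sl$passes <- rep(NA, nrow(sl))
  new("ReferenceReport", shortlist = sl[, c("assay", "card", "sd_ct",
                                            "mean_ct", "neutrality_p_cancer",
                                            "neutrality_p_overall", "passes")],
      chosen = character(),
      parameters = list(k = k, max_mean_ct = maxMeanCt))
}

#' Group-neutrality tests for a candidate reference
#'
#' Criterion 3 of reference selection: a usable normalizer must show no
#' statistically significant difference between clinical categories. Two
#' rank-based tests are run on the assay's Ct values: a two-sided
#' Mann-Whitney test of healthy controls versus all CRC patients
#' (`p_cancer`) and a Kruskal-Wallis test across the five groups
#' (control, stage I-IV; `p_overall`).
#'
#' @param ct a [CtSet-class]
#' @param samples a [SampleTable-class] aligned with `ct` (or `NULL` to use
#'   the group column already merged into `colData(ct)`).
#' @param assay assay name.
#' @return named numeric vector `c(p_cancer=, p_overall=)`.
#' @export
referenceNeutrality <- function(ct, samples = NULL, assay) {
  stopifnot(is(ct, "CtSet"))
  if (!(assay %in% rownames(ct))) stop("assay not present: ", assay)
  grp <- .groupsFor(ct, samples)
  vals <- ctValues(ct)[assay, ]
  for (g in GROUP_LEVELS)
    if (!any(grp == g)) stop("neutrality error: group '", g, "' is empty")
  is_crc <- grp %in% CRC_GROUPS
  if (sum(!is_crc) < 2 || sum(is_crc) < 2)
    stop("need >= 2 samples per side of the control vs CRC comparison")
  p_cancer <- suppressWarnings(
    wilcox.test(vals[!is_crc], vals[is_crc], exact = FALSE,
                correct = TRUE)$p.value)
  p_overall <- kruskal.test(vals, droplevels(factor(grp)))$p.value
  c(p_cancer = p_cancer, p_overall = p_overall)
}

.groupsFor <- function(ct, samples) {
  if (!is.null(samples)) {
    stopifnot(is(samples, "SampleTable"))
    grp <- samples$group[match(sampleIds(ct), samples$sample_id)]
  } else grp <- colData(ct)$group
  if (is.null(grp) || any(is.na(grp)))
    stop("group annotation missing for some samples; run alignSamples() first")
  as.character(grp)
}

#' Select the per-card normalization reference
#'
#' Full three-criterion selection: shortlist by stability and yield
#' ([shortlistReferences()]), then per card choose the shortlisted assay with
#' the smallest Ct standard deviation whose two neutrality p-values
#' ([referenceNeutrality()]) both exceed `alpha`. This mirrors the selection
#' that picks an endogenous miR-451-like control on card A and a
#' miR-877-like control on card B.
#'
#' @inheritParams shortlistReferences
#' @param samples a [SampleTable-class] aligned with `ct` (or `NULL` if the
#'   groups are already merged into `colData(ct)`).
#' @param alpha neutrality threshold; both p-values must *exceed* it
#'   (default 0.05).
#' @return a completed [ReferenceReport-class] with the chosen assay per card.
#' @export
selectReference <- function(ct, samples = NULL, k = 6, maxMeanCt = 35,
                            alpha = 0.05) {
  rep0 <- shortlistReferences(ct, k = k, maxMeanCt = maxMeanCt)
  sl <- rep0@shortlist
  if (!nrow(sl)) stop("selection error: empty reference shortlist")
  for (i in seq_len(nrow(sl))) {
    p <- referenceNeutrality(ct, samples, sl$assay[i])
    sl$neutrality_p_cancer[i] <- p[["p_cancer"]]
    sl$neutrality_p_overall[i] <- p[["p_overall"]]
  }
  sl$passes <- sl$neutrality_p_cancer > alpha & sl$neutrality_p_overall > alpha
  chosen <- character()
  for (cd in unique(sl$card)) {
    rows <- sl[sl$card == cd & sl$passes, , drop = FALSE]
    if (!nrow(rows)) {
      bad <- sl[sl$card == cd, , drop = FALSE]
      stop(sprintf(paste0("selection error: no shortlisted assay on card %s ",
                          "passes neutrality at alpha=%g (p_cancer: %s; ",
                          "p_overall: %s)"),
                   cd, alpha,
                   paste(signif(bad$neutrality_p_cancer, 3), collapse = ", "),
                   paste(signif(bad$neutrality_p_overall, 3), collapse = ", ")))
    }
    chosen[[cd]] <- rows$assay[which.min(rows$sd_ct)]
  }
  new("ReferenceReport", shortlist = sl, chosen = chosen,
      parameters = list(k = k, max_mean_ct = maxMeanCt, alpha = alpha))
}

#' Within-sample normalization: dCt
#'
#' Subtracts the reference assay's Ct from every assay's Ct within each
#' sample: `dCt(a, s) = Ct(a, s) - Ct(ref, s)`. With a per-card reference
#' (named vector `c(A=..., B=...)`), each assay is normalized by its own
#' card's reference; assays on card "none" require a single global reference
#' (the spike-in case). When `collapseDuplicates = TRUE`, technical replicate
#' wells sharing a `sample_id` are first averaged on the Ct scale (the mean
#' cycle threshold of the replicated measurements), and a collapsed well
#' counts as undetected only if all its replicates were.
#'
#' @param ct a [CtSet-class]
#' @param reference single assay id, or a named character vector keyed by
#'   card.
#' @param collapseDuplicates average technical replicates first (default
#'   FALSE).
#' @return numeric dCt matrix (assays x samples) with attributes `reference`
#'   and `colData` (the per-sample annotation carried over from `ct`).
#' @export
deltaCt <- function(ct, reference, collapseDuplicates = FALSE) {
  stopifnot(is(ct, "CtSet"))
  m <- ctValues(ct)
  und <- undetectedWells(ct)
  cd <- as.data.frame(colData(ct))
  if (collapseDuplicates) {
    sid <- sampleIds(ct)
    usid <- unique(sid)
    m <- vapply(usid, function(s) rowMeans(m[, sid == s, drop = FALSE]),
                numeric(nrow(m)))
    und <- vapply(usid, function(s) apply(und[, sid == s, drop = FALSE], 1, all),
                  logical(nrow(und)))
    dimnames(m) <- list(rownames(ct), usid)
    cd <- cd[match(usid, cd$sample_id), , drop = FALSE]
    rownames(cd) <- usid
    cd$replicate <- NULL
  }
  refs <- if (is.null(names(reference)) && length(reference) == 1L)
    setNames(rep(reference, 3), c("A", "B", "none")) else reference
  cards <- as.character(rowData(ct)$card)
  need <- unique(cards)
  if (!all(need %in% names(refs)))
    stop("no reference given for card(s): ",
         paste(setdiff(need, names(refs)), collapse = ", "))
  for (r in unique(refs[need])) {
    if (!(r %in% rownames(m))) stop("reference assay not present: ", r)
    if (any(und[r, ]))
      stop("normalization error: reference '", r,
           "' undetected in sample(s): ",
           paste(colnames(m)[und[r, ]], collapse = ", "))
  }
  refmat <- m[refs[cards], , drop = FALSE]
  dct <- m - refmat
  attr(dct, "reference") <- refs[need]
  attr(dct, "colData") <- cd
  dct
}

#' Relative expression: the -ddCt transform
#'
#' Subtracts from each sample's dCt the mean dCt of the baseline group
#' (`ddCt(a, s) = dCt(a, s) - mean dCt(a, baseline)`) and stores the relative
#' level as `-ddCt`: a log2-like quantity where +1 is roughly a two-fold
#' higher abundance than the baseline-group average. The linear fold-change
#' view `2^(-ddCt)` is available through [foldChanges()].
#'
#' @param dct dCt matrix from [deltaCt()].
#' @param samples a [SampleTable-class], or `NULL` to use the annotation
#'   carried on `dct`.
#' @param baselineGroup group label whose mean dCt is subtracted (default
#'   "control").
#' @return a [RelativeExpressionSet-class].
#' @export
relativeExpression <- function(dct, samples = NULL, baselineGroup = "control") {
  cd <- attr(dct, "colData")
  if (!is.null(samples)) {
    stopifnot(is(samples, "SampleTable"))
    cd <- as.data.frame(samples)[match(colnames(dct), samples$sample_id), ,
                                 drop = FALSE]
    rownames(cd) <- colnames(dct)
  }
  if (is.null(cd) || is.null(cd$group))
    stop("group annotation required to identify the baseline group")
  base <- which(as.character(cd$group) == baselineGroup)
  if (!length(base))
    stop("baseline error: no samples in baseline group '", baselineGroup, "'")
  ddct <- dct - rowMeans(dct[, base, drop = FALSE])
  rel <- -ddct
  attr(rel, "reference") <- NULL
  attr(rel, "colData") <- NULL
  se <- SummarizedExperiment(assays = list(relLevel = rel),
                             colData = as(cd, "DataFrame"))
  metadata(se)$reference_assay <- attr(dct, "reference")
  metadata(se)$baseline_group <- baselineGroup
  new("RelativeExpressionSet", se)
}
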