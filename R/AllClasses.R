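#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<-
#' @importFrom stats sd median rnorm runif rexp rbinom quantile pchisq pnorm
#'   qnorm rank wilcox.test kruskal.test t.test glm binomial coef fitted
#'   p.adjust setNames rlnorm complete.cases
#' @importFrom utils read.delim read.csv write.table packageVersion
NULL

GROUP_LEVELS <- c("control", "I", "II", "III", "IV")
CRC_GROUPS <- c("I", "II", "III", "IV")

#' Raw cycle-threshold container
#'
#' `CtSet` holds a matrix of raw qPCR cycle-threshold (Ct) values, one row per
#' miRNA assay and one column per well. Row metadata carries the TaqMan card
#' assignment (`card`: "A", "B" or "none") and an internal-control flag
#' (U6/RNU44/RNU48-type assays and spike-ins). A parallel logical matrix marks
#' undetected wells: any empty, "Undetermined" or above-ceiling reading is
#' stored *as* the detection ceiling (default 40 cycles) with its flag set.
#' Technical replicate wells are distinct columns sharing a `sample_id` in
#' `colData`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]; assays `ct`
#'   (numeric) and `undetected` (logical), `metadata(x)$ceiling` the ceiling.
#'
#' @seealso [CtSet()] for construction, [readCtMatrix()] for file input.
#' @export
setClass("CtSet", contains = "SummarizedExperiment")

setValidity("CtSet", function(object) {
  msg <- character()
  an <- names(assays(object))
  if (!all(c("ct", "undetected") %in% an))
    return("assays must contain 'ct' and 'undetected'")
  ct <- assay(object, "ct")
  und <- assay(object, "undetected")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "assay identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "well (column) identifiers must be present and unique")
  ceiling <- metadata(object)$ceiling
  if (!is.numeric(ceiling) || length(ceiling) != 1L || !is.finite(ceiling))
    msg <- c(msg, "metadata(x)$ceiling must be a single finite number")
  else {
    if (any(ct > ceiling + 1e-9, na.rm = TRUE) || any(ct <= 0, na.rm = TRUE))
      msg <- c(msg, "every Ct must satisfy 0 < Ct <= ceiling")
    if (any(und & abs(ct - ceiling) > 1e-9))
      msg <- c(msg, "undetected wells must be stored at the ceiling")
  }
  if (!is.logical(und)) msg <- c(msg, "'undetected' assay must be logical")
  rd <- rowData(object)
  if (!all(c("card", "is_control") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'card' and 'is_control'")
  else if (!all(as.character(rd$card) %in% c("A", "B", "none")))
    msg <- c(msg, "card must be one of 'A', 'B', 'none'")
  if (!("sample_id" %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'sample_id'")
  if (length(msg)) msg else TRUE
})

#' Construct a CtSet
#'
#' @param ct numeric matrix of raw Ct values (assays x wells) with row and
#'   column names. Values above `ceiling` or `NA` are stored at the ceiling
#'   and flagged undetected.
#' @param card per-assay card label in `c("A","B","none")`; recycled default
#'   `"none"`.
#' @param isControl per-assay logical internal-control flag (default `FALSE`).
#' @param ceiling detection ceiling in cycles (default 40): the Ct recorded
#'   for a well in which no amplification was observed.
#' @param sampleId per-column biological sample id; defaults to the column
#'   names. Technical replicates of one sample share a `sampleId` while
#'   keeping distinct column names.
#' @return a [CtSet-class] object.
#' @examples
#' m <- matrix(c(25, 31, NA, 26, 30.5, 39), nrow = 3,
#'             dimnames = list(c("miR-a", "miR-b", "miR-c"), c("s1", "s2")))
#' cs <- CtSet(m)
#' undetectedWells(cs)["miR-c", "s1"]
#' @export
CtSet <- function(ct, card = "none", isControl = FALSE, ceiling = 40,
                  sampleId = colnames(ct)) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix must have assay rownames and sample colnames")
  storage.mode(ct) <- "double"
  und <- is.na(ct) | ct > ceiling
  ct[und] <- ceiling
  rd <- DataFrame(card = rep(as.character(card), length.out = nrow(ct)),
                  is_control = rep(as.logical(isControl), length.out = nrow(ct)),
                  row.names = rownames(ct))
  cd <- DataFrame(sample_id = as.character(sampleId), row.names = colnames(ct))
  se <- SummarizedExperiment(assays = list(ct = ct, undetected = und),
                             rowData = rd, colData = cd)
  metadata(se)$ceiling <- ceiling
  new("CtSet", se)
}

#' Relative expression (-ddCt) container
#'
#' Holds relative miRNA levels on the -ddCt scale (log2-like; one unit is
#' approximately a two-fold change in abundance, positive values mean higher
#' than the baseline group). Provenance is kept in `metadata`: the reference
#' assay(s) used for within-sample normalization and the baseline group whose
#' mean dCt was subtracted.
#'
#' @seealso [relativeExpression()], [relLevels()], [foldChanges()].
#' @export
setClass("RelativeExpressionSet", contains = "SummarizedExperiment")

setValidity("RelativeExpressionSet", function(object) {
  msg <- character()
  if (!("relLevel" %in% names(assays(object))))
    msg <- c(msg, "assays must contain 'relLevel'")
  md <- metadata(object)
  if (is.null(md$reference_assay)) msg <- c(msg, "missing metadata reference_assay")
  if (is.null(md$baseline_group)) msg <- c(msg, "missing metadata baseline_group")
  if (length(msg)) msg else TRUE
})

#' Per-sample clinical annotation table
#'
#' A validated table with one row per biological sample: `sample_id`, `cohort`
#' ("discovery"/"validation"), `group` (control or TNM stage I-IV), and the
#' optional clinical fields `sex`, `age` (years), `cea` (carcinoembryonic
#' antigen, ug/L), `surgery`, `chemotherapy`, `os_time` (overall survival in
#' months) and `os_event` (1 = dead, 0 = censored at last follow-up).
#' Controls never carry survival fields.
#'
#' @seealso [SampleTable()], [readSampleTable()].
#' @export
setClass("SampleTable", contains = "DFrame")

setValidity("SampleTable", function(object) {
  msg <- character()
  req <- c("sample_id", "cohort", "group")
  if (!all(req %in% colnames(object)))
    return(paste("missing required columns:",
                 paste(setdiff(req, colnames(object)), collapse = ", ")))
  if (anyDuplicated(object$sample_id))
    msg <- c(msg, "duplicate sample_id")
  if (!all(as.character(object$group) %in% GROUP_LEVELS))
    msg <- c(msg, "group must be control or stage I-IV")
  if (!all(as.character(object$cohort) %in% c("discovery", "validation")))
    msg <- c(msg, "cohort must be 'discovery' or 'validation'")
  has_time <- "os_time" %in% colnames(object)
  has_event <- "os_event" %in% colnames(object)
  if (has_event && !has_time)
    msg <- c(msg, "os_event present without os_time")
  if (has_event && has_time) {
    ev <- object$os_event
    if (!all(ev %in% c(0, 1, NA)))
      msg <- c(msg, "os_event must be 0/1")
    if (any(!is.na(ev) & is.na(object$os_time)))
      msg <- c(msg, "os_event recorded without an os_time")
    if (any(!is.na(object$os_time) & object$os_time < 0))
      msg <- c(msg, "os_time must be >= 0")
    ctrl <- as.character(object$group) == "control"
    if (any(ctrl & (!is.na(object$os_time) | !is.na(ev))))
      msg <- c(msg, "controls must not carry survival fields")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SampleTable
#'
#' Group tokens are normalized case-insensitively ("Stage II", "ii" -> "II";
#' "healthy"/"ctrl" -> "control"). Missing optional fields stay absent and are
#' never imputed.
#'
#' @param df data.frame (or DataFrame) with at least `sample_id`, `cohort`,
#'   `group`.
#' @return a [SampleTable-class].
#' @export
SampleTable <- function(df) {
  df <- as(as.data.frame(df), "DataFrame")
  req <- c("sample_id", "cohort", "group")
  if (!all(req %in% colnames(df)))
    stop("sample table requires columns: ", paste(req, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$cohort <- tolower(as.character(df$cohort))
  df$group <- normalizeGroupToken(df$group)
  rownames(df) <- df$sample_id
  new("SampleTable", df)
}

normalizeGroupToken <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- sub("^stage[ _-]*", "", x)
  map <- c(control = "control", healthy = "control", ctrl = "control",
           normal = "control",
           i = "I", "1" = "I", ii = "II", "2" = "II",
           iii = "III", "3" = "III", iv = "IV", "4" = "IV")
  out <- map[x]
  if (any(is.na(out)))
    stop("unknown group token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  factor(unname(out), levels = GROUP_LEVELS)
}

#' Normalization reference report
#'
#' Per-card shortlist of candidate endogenous controls (standard deviation and
#' mean of raw Ct, neutrality p-values) and the chosen reference per card.
#'
#' @slot shortlist data.frame with columns assay, card, sd_ct, mean_ct,
#'   neutrality_p_cancer, neutrality_p_overall, passes.
#' @slot chosen named character vector, one chosen assay per card.
#' @slot parameters list of the selection parameters used.
#' @export
setClass("ReferenceReport",
         representation(shortlist = "data.frame", chosen = "character",
                        parameters = "list"))

setValidity("ReferenceReport", function(object) {
  sl <- object@shortlist
  msg <- character()
  for (cd in names(object@chosen)) {
    ch <- object@chosen[[cd]]
    rows <- sl[sl$card == cd, , drop = FALSE]
    if (!(ch %in% rows$assay))
      msg <- c(msg, sprintf("chosen assay '%s' not in card %s shortlist", ch, cd))
  }
  if (nrow(sl) && is.unsorted(order(sl$card, sl$sd_ct)) &&
      any(tapply(sl$sd_ct, sl$card, is.unsorted)))
    msg <- c(msg, "shortlist must be sorted ascending by sd_ct within card")
  if (length(msg)) msg else TRUE
})

#' @describeIn CtSet-class compact display
#' @param object a `CtSet`
#' @export
setMethod("show", "CtSet", function(object) {
  cat(sprintf("CtSet: %d assays x %d wells (%d samples), ceiling %g cycles\n",
              nrow(object), ncol(object),
              length(unique(colData(object)$sample_id)),
              metadata(object)$ceiling))
  cat(sprintf("  cards: %s | undetected wells: %d (%.1f%%)\n",
              paste(names(table(rowData(object)$card)), collapse = "/"),
              sum(assay(object, "undetected")),
              100 * mean(assay(object, "undetected"))))
})

#' @describeIn ReferenceReport-class compact display
#' @param object a `ReferenceReport`
#' @export
setMethod("show", "ReferenceReport", function(object) {
  cat("ReferenceReport\n")
  for (cd in names(object@chosen))
    cat(sprintf("  card %s: chosen %s\n", cd, object@chosen[[cd]]))
  cat(sprintf("  shortlist: %d candidate(s)\n", nrow(object@shortlist)))
})
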