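#' Accessors for CtSet and RelativeExpressionSet
#'
#' `ctValues` returns the raw Ct matrix; `undetectedWells` the logical
#' undetected-flag matrix; `ctCeiling` the detection ceiling in cycles;
#' `assayCards` the per-assay card labels; `controlAssays` the names of
#' internal-control assays; `sampleIds` the per-column biological sample ids;
#' `relLevels` the -ddCt relative-level matrix; `foldChanges` its linear-scale
#' view `2^(-ddCt)`; `referenceAssay` and `baselineGroup` the normalization
#' provenance.
#'
#' @param x a [CtSet-class] or [RelativeExpressionSet-class]
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
ctValues <- function(x) assay(x, "ct")

#' @rdname accessors
#' @export
undetectedWells <- function(x) assay(x, "undetected")

#' @rdname accessors
#' @export
ctCeiling <- function(x) metadata(x)$ceiling

#' @rdname accessors
#' @export
assayCards <- function(x) setNames(as.character(rowData(x)$card), rownames(x))

#' @rdname accessors
#' @export
controlAssays <- function(x) rownames(x)[rowData(x)$is_control]

#' @rdname accessors
#' @export
sampleIds <- function(x) as.character(colData(x)$sample_id)

#' @rdname accessors
#' @export
relLevels <- function(x) assay(x, "relLevel")

#' @rdname accessors
#' @export
foldChanges <- function(x) 2^assay(x, "relLevel")

#' @rdname accessors
#' @export
referenceAssay <- function(x) metadata(x)$reference_assay

#' @rdname accessors
#' @export
baselineGroup <- function(x) metadata(x)$baseline_group

#' @rdname accessors
#' @export
referenceShortlist <- function(x) {
  stopifnot(is(x, "ReferenceReport"))
  x@shortlist
}

#' @rdname accessors
#' @export
chosenReference <- function(x) {
  stopifnot(is(x, "ReferenceReport"))
  x@chosen
}
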