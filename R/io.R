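#' Read a Ct table
#'
#' Reads a cycle-threshold table in one of three dialects. Wide tables carry
#' one row per assay (first column `assay_id`, optional `card` and `control`
#' metadata columns, remaining columns one per sample/well). Long tables carry
#' columns `assay_id`, `sample_id`, `ct` and optionally `well` (distinct well
#' id for technical replicates; defaults to the sample id). Cells may be
#' numeric, empty, `NA` or the token "Undetermined" (case-insensitive); the
#' latter three are stored at the detection ceiling with the undetected flag
#' set, as are numeric readings above the ceiling.
#'
#' @param path file path (TSV or CSV).
#' @param dialect one of `"auto"`, `"wide_tsv"`, `"wide_csv"`, `"long_tsv"`.
#'   `"auto"` picks the separator from the extension and wide vs. long from
#'   the header.
#' @param ceiling detection ceiling in cycles (default 40).
#' @return a [CtSet-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("assay_id\ts1\ts2", "miR-a\t25\t26", "miR-b\tUndetermined\t31"), tf)
#' readCtMatrix(tf)
#' @export
readCtMatrix <- function(path, dialect = c("auto", "wide_tsv", "wide_csv",
                                           "long_tsv"), ceiling = 40) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "wide_csv" ||
             (dialect == "auto" && grepl("\\.csv$", path, ignore.case = TRUE)))
    "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  long <- all(c("assay_id", "sample_id", "ct") %in% names(raw))
  if (dialect == "long_tsv" && !long)
    stop("long table requires columns assay_id, sample_id, ct")
  if (long) .readCtLong(raw, ceiling, path) else .readCtWide(raw, ceiling, path)
}

.parseCt <- function(x, ceiling, where) {
  x <- trimws(x)
  und <- is.na(x) | x == "" | tolower(x) %in% c("undetermined", "na")
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!und & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric Ct cell '%s' at %s", x[bad[1]], where[bad[1]]))
  out[und] <- NA_real_
  list(ct = out, undetected = und)
}

.readCtWide <- function(raw, ceiling, path) {
  if (names(raw)[1] != "assay_id")
    stop("wide Ct table must start with an 'assay_id' column")
  meta_cols <- intersect(c("card", "control"), names(raw))
  sample_cols <- names(raw)[!(names(raw) %in% c("assay_id", meta_cols))]
  if (!length(sample_cols)) stop("no sample columns found in ", path)
  if (anyDuplicated(sample_cols))
    stop("duplicate sample column: ",
         sample_cols[duplicated(sample_cols)][1])
  if (anyDuplicated(raw$assay_id))
    stop("duplicate assay_id: ", raw$assay_id[duplicated(raw$assay_id)][1])
  vals <- as.matrix(raw[, sample_cols, drop = FALSE])
  where <- outer(raw$assay_id, sample_cols,
                 function(a, s) sprintf("row '%s', column '%s'", a, s))
  p <- .parseCt(as.vector(vals), ceiling, as.vector(where))
  m <- matrix(p$ct, nrow = nrow(raw),
              dimnames = list(raw$assay_id, sample_cols))
  card <- if ("card" %in% meta_cols) {
    cc <- trimws(raw$card)
    cc[cc == "" | is.na(cc)] <- "none"
    cc
  } else "none"
  ctrl <- if ("control" %in% meta_cols)
    as.integer(raw$control) == 1L else FALSE
  CtSet(m, card = card, isControl = ctrl, ceiling = ceiling)
}

.readCtLong <- function(raw, ceiling, path) {
  well <- if ("well" %in% names(raw)) raw$well else raw$sample_id
  key <- paste(raw$assay_id, well, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop(sprintf("duplicate (assay, well) pair: ('%s', '%s')", d[1], d[2]))
  }
  p <- .parseCt(raw$ct, ceiling,
                sprintf("assay '%s', sample '%s'", raw$assay_id, raw$sample_id))
  assays <- unique(raw$assay_id)
  wells <- unique(well)
  m <- matrix(NA_real_, length(assays), length(wells),
              dimnames = list(assays, wells))
  m[cbind(match(raw$assay_id, assays), match(well, wells))] <- p$ct
  sid <- raw$sample_id[match(wells, well)]
  CtSet(m, ceiling = ceiling, sampleId = sid)
}

#' Write a Ct table
#'
#' Writes the wide dialect (with `card` and `control` metadata columns) or the
#' long dialect (with `well` and `sample_id` columns, preserving technical
#' replicate structure). Undetected wells are written as "Undetermined".
#' Writing then reading reproduces the stored values and flags exactly.
#'
#' @param x a [CtSet-class]
#' @param path output file path
#' @param dialect `"wide_tsv"`, `"wide_csv"` or `"long_tsv"`
#' @return `path`, invisibly.
#' @export
writeCtMatrix <- function(x, path, dialect = c("wide_tsv", "wide_csv",
                                               "long_tsv")) {
  dialect <- match.arg(dialect)
  ct <- ctValues(x)
  und <- undetectedWells(x)
  chr <- matrix(formatC(ct, format = "g", digits = 17), nrow = nrow(ct),
                dimnames = dimnames(ct))
  chr[und] <- "Undetermined"
  if (dialect == "long_tsv") {
    df <- data.frame(assay_id = rep(rownames(ct), times = ncol(ct)),
                     sample_id = rep(sampleIds(x), each = nrow(ct)),
                     well = rep(colnames(ct), each = nrow(ct)),
                     ct = as.vector(chr))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(assay_id = rownames(ct),
                     card = as.character(rowData(x)$card),
                     control = as.integer(rowData(x)$is_control),
                     chr, check.names = FALSE)
    write.table(df, path, sep = if (dialect == "wide_csv") "," else "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV/CSV with required columns `sample_id`, `cohort`, `group` and any of the
#' optional clinical columns (`sex`, `age`, `cea`, `surgery`, `chemotherapy`,
#' `os_time`, `os_event`). Group tokens are normalized ("Stage II" -> "II").
#' Missing optional values stay `NA`; nothing is imputed.
#'
#' @param path file path; separator chosen from the extension.
#' @return a [SampleTable-class].
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   na.strings = c("", "NA"))
  for (col in c("age", "cea", "os_time"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  for (col in c("surgery", "chemotherapy", "os_event"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  SampleTable(df)
}

#' Write a sample annotation table
#'
#' @param x a [SampleTable-class]
#' @param path output file path (TSV unless it ends in .csv)
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Align a Ct matrix with a sample table
#'
#' Restricts both objects to the intersection of their sample ids, keeping
#' the Ct matrix's column order as canonical (the annotation table is
#' reordered to match) and reporting dropped ids on both sides. Clinical
#' fields are merged into the `colData` of the returned `CtSet` so downstream
#' stages can work from one object.
#'
#' @param ct a [CtSet-class]
#' @param samples a [SampleTable-class]
#' @return list with elements `ct` (annotated, restricted [CtSet-class]),
#'   `samples` (restricted, reordered [SampleTable-class]) and `dropped`
#'   (list of ids present on only one side).
#' @export
alignSamples <- function(ct, samples) {
  stopifnot(is(ct, "CtSet"), is(samples, "SampleTable"))
  ids_ct <- unique(sampleIds(ct))
  ids_tab <- samples$sample_id
  keep <- ids_ct[ids_ct %in% ids_tab]
  if (!length(keep))
    stop("alignment error: no sample ids shared between Ct matrix and table")
  dropped <- list(ct_only = setdiff(ids_ct, ids_tab),
                  table_only = setdiff(ids_tab, ids_ct))
  ct2 <- ct[, sampleIds(ct) %in% keep]
  tab <- samples[match(keep, ids_tab), , drop = FALSE]
  cd <- colData(ct2)
  idx <- match(cd$sample_id, tab$sample_id)
  for (col in setdiff(colnames(tab), "sample_id"))
    cd[[col]] <- tab[[col]][idx]
  colData(ct2) <- cd
  list(ct = ct2, samples = tab, dropped = dropped)
}
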