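test_that("wide Ct tables parse, with Undetermined mapped to the ceiling", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay_id\tcard\tcontrol\ts1\ts2",
               "miR-a\tA\t0\t25.5\t26",
               "miR-b\tA\t0\tUndetermined\t31",
               "U6\tB\t1\t22\t22.5"), tf)
  cs <- readCtMatrix(tf)
  expect_s4_class(cs, "CtSet")
  expect_equal(dim(cs), c(3L, 2L))
  expect_equal(ctValues(cs)["miR-b", "s1"], 40)
  expect_true(undetectedWells(cs)["miR-b", "s1"])
  expect_false(any(undetectedWells(cs)[c("miR-a", "U6"), ]))
  expect_equal(unname(assayCards(cs)), c("A", "A", "B"))
  expect_equal(controlAssays(cs), "U6")
})

test_that("long and wide dialects parse to the same matrix", {
  wide <- withr::local_tempfile(fileext = ".tsv")
  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay_id\ts1\ts2",
               "miR-a\t25.5\t26",
               "miR-b\tUndetermined\t31",
               "miR-c\t30\t29.25"), wide)
  writeLines(c("assay_id\tsample_id\tct",
               "miR-a\ts1\t25.5", "miR-a\ts2\t26",
               "miR-b\ts1\tUndetermined", "miR-b\ts2\t31",
               "miR-c\ts1\t30", "miR-c\ts2\t29.25"), long)
  w <- readCtMatrix(wide)
  l <- readCtMatrix(long, dialect = "long_tsv")
  expect_identical(ctValues(w), ctValues(l))
  expect_identical(undetectedWells(w), undetectedWells(l))
})

test_that("malformed Ct tables raise named format errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay_id\ts1\ts1", "miR-a\t25\t26"), tf)
  expect_error(readCtMatrix(tf), "duplicate sample")
  writeLines(c("assay_id\ts1", "miR-a\t25", "miR-a\t26"), tf)
  expect_error(readCtMatrix(tf), "duplicate assay_id: miR-a")
  writeLines(c("assay_id\ts1\ts2", "miR-a\t25\tabc"), tf)
  expect_error(readCtMatrix(tf), "non-numeric.*abc.*s2")
})

test_that("Ct round-trip through both dialects preserves values and flags", {
  set.seed(42)
  m <- matrix(round(runif(12, 20, 39), 7), 3, 4,
              dimnames = list(paste0("m", 1:3), paste0("s", 1:4)))
  m[2, 3] <- NA
  cs <- CtSet(m, card = c("A", "A", "B"))
  for (d in c("wide_tsv", "wide_csv", "long_tsv")) {
    tf <- withr::local_tempfile(fileext = sub("^.*_", ".", d))
    writeCtMatrix(cs, tf, dialect = d)
    back <- readCtMatrix(tf, dialect = if (d == "wide_csv") "auto" else d)
    expect_identical(ctValues(back), ctValues(cs), label = d)
    expect_identical(undetectedWells(back), undetectedWells(cs), label = d)
  }
})

test_that("parsing is invariant to row order up to the declared ordering", {
  tf1 <- withr::local_tempfile(fileext = ".tsv")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay_id\ts1\ts2", "miR-a\t25\t26", "miR-b\t30\t31"), tf1)
  writeLines(c("assay_id\ts1\ts2", "miR-b\t30\t31", "miR-a\t25\t26"), tf2)
  a <- ctValues(readCtMatrix(tf1))
  b <- ctValues(readCtMatrix(tf2))
  expect_identical(a, b[rownames(a), ])
})

test_that("sample tables validate and normalize group tokens", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcohort\tgroup",
               "s1\tdiscovery\tcontrol", "s2\tdiscovery\tStage I",
               "s3\tdiscovery\tii", "s4\tdiscovery\tIII",
               "s5\tdiscovery\tstage IV"), tf)
  st <- readSampleTable(tf)
  expect_s4_class(st, "SampleTable")
  expect_equal(as.character(st$group), c("control", "I", "II", "III", "IV"))

  expect_error(SampleTable(data.frame(sample_id = "s1", cohort = "discovery",
                                      group = "stage V")),
               "unknown group token")
  expect_error(SampleTable(data.frame(sample_id = "s1", cohort = "validation",
                                      group = "II", os_event = 1)),
               "os_event present without os_time")
})

test_that("sample tables round-trip through write/read", {
  df <- data.frame(sample_id = c("p1", "p2", "c1"),
                   cohort = "validation", group = c("II", "IV", "control"),
                   sex = c("male", "female", "male"), age = c(61.2, 48, 55),
                   cea = c(3.1, 8.7, NA), surgery = c(1L, 0L, NA),
                   chemotherapy = c(1L, 1L, NA),
                   os_time = c(12.5, 3, NA), os_event = c(0L, 1L, NA))
  st <- SampleTable(df)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeSampleTable(st, tf)
  back <- readSampleTable(tf)
  expect_equal(as.data.frame(back), as.data.frame(st))
})

test_that("alignSamples intersects ids, keeps Ct order, reports drops", {
  m <- matrix(25, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  cs <- CtSet(m)
  st <- SampleTable(data.frame(sample_id = c("s4", "s3", "s2"),
                               cohort = "discovery",
                               group = c("I", "II", "control")))
  al <- alignSamples(cs, st)
  expect_equal(sampleIds(al$ct), c("s2", "s3"))
  expect_equal(al$samples$sample_id, c("s2", "s3"))
  expect_equal(al$dropped, list(ct_only = "s1", table_only = "s4"))
  expect_equal(as.character(SummarizedExperiment::colData(al$ct)$group),
               c("control", "II"))

  same <- SampleTable(data.frame(sample_id = c("s1", "s2", "s3"),
                                 cohort = "discovery", group = "I"))
  al2 <- alignSamples(cs, same)
  expect_equal(sampleIds(al2$ct), c("s1", "s2", "s3"))
  expect_length(unlist(al2$dropped), 0)

  disj <- SampleTable(data.frame(sample_id = "x1", cohort = "discovery",
                                 group = "I"))
  expect_error(alignSamples(cs, disj), "no sample ids shared")
})

test_that("CtSet validity enforces the Ct range and flag consistency", {
  m <- matrix(c(25, 41), 1, 2, dimnames = list("a", c("s1", "s2")))
  cs <- CtSet(m)                       # above-ceiling clipped on construction
  expect_equal(ctValues(cs)["a", "s2"], 40)
  expect_true(undetectedWells(cs)["a", "s2"])
  bad <- cs
  SummarizedExperiment::assay(bad, "ct")[1, 1] <- -1
  expect_error(validObject(bad), "0 < Ct")
})
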