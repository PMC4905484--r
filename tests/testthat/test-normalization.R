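groups5 <- function(n_per = 2) rep(c("control", "I", "II", "III", "IV"),
                                   each = n_per)

tinyCohort <- function(n_per = 10, n_assays = 10, seed = 7, sd = 1) {
  set.seed(seed)
  grp <- groups5(n_per)
  m <- matrix(rnorm(n_assays * length(grp), 28, sd), n_assays,
              dimnames = list(sprintf("m%02d", seq_len(n_assays)),
                              sprintf("s%02d", seq_along(grp))))
  st <- SampleTable(data.frame(sample_id = colnames(m), cohort = "discovery",
                               group = grp))
  list(ct = CtSet(m), samples = st, groups = grp)
}

test_that("zero-variance assays are filtered with a report", {
  m <- rbind(flat40 = c(40, 40, 40), near = c(30, 30, 30.01),
             ok = c(25, 26, 27))
  colnames(m) <- paste0("s", 1:3)
  out <- filterZeroVariance(CtSet(m))
  expect_equal(rownames(out), c("near", "ok"))
  expect_equal(S4Vectors::metadata(out)$removed_zero_variance, "flat40")
  allflat <- CtSet(matrix(40, 2, 3, dimnames = list(c("a", "b"),
                                                    paste0("s", 1:3))))
  expect_error(filterZeroVariance(allflat), "zero variance")
})

test_that("shortlisting ranks by SD under the yield and detection gates", {
  set.seed(11)
  n <- 12
  m <- matrix(rnorm(10 * n, 28, 1), 10, n,
              dimnames = list(sprintf("m%02d", 1:10), sprintf("s%02d", 1:n)))
  m["m05", ] <- 28 + rnorm(n, 0, 0.1)   # the planted low-SD assay
  cs <- CtSet(m)
  # direct SD oracle
  sds <- apply(ctValues(cs), 1, sd)
  expect_equal(names(which.min(sds)), "m05")
  rep <- shortlistReferences(cs, k = 3)
  sl <- referenceShortlist(rep)
  expect_equal(sl$assay[1], "m05")
  expect_equal(sl$sd_ct, sort(sl$sd_ct))
  expect_equal(sl$sd_ct, unname(sds[sl$assay]))

  # assays with any undetected well are never shortlisted
  m2 <- m; m2["m05", 1] <- NA
  sl2 <- referenceShortlist(shortlistReferences(CtSet(m2), k = 3))
  expect_false("m05" %in% sl2$assay)

  # yield gate: everything too dim -> empty shortlist plus warning
  dim_cs <- CtSet(m + 10)
  expect_warning(rep3 <- shortlistReferences(dim_cs, k = 3),
                 "eligible")
  expect_equal(nrow(referenceShortlist(rep3)), 0)
})

test_that("neutrality tests pass identical groups and flag shifted ones", {
  coh <- tinyCohort(n_per = 4, n_assays = 3, seed = 3)
  m <- ctValues(coh$ct)
  m["m01", ] <- rep(c(27, 28, 29, 30), times = 5)  # same multiset per group
  cs <- CtSet(m)
  p <- referenceNeutrality(cs, coh$samples, "m01")
  expect_gte(p[["p_cancer"]], 0.99)
  expect_gte(p[["p_overall"]], 0.99)

  set.seed(5)
  grp <- groups5(10)
  v <- rnorm(50, 28, 0.1) + ifelse(grp == "IV", 3, 0)
  m2 <- rbind(shifted = v, other = rnorm(50, 30, 1))
  colnames(m2) <- sprintf("s%02d", 1:50)
  st <- SampleTable(data.frame(sample_id = colnames(m2), cohort = "discovery",
                               group = grp))
  p2 <- referenceNeutrality(CtSet(m2), st, "shifted")
  expect_lt(p2[["p_overall"]], 0.01)

  no_ctrl <- SampleTable(data.frame(sample_id = colnames(m2),
                                    cohort = "discovery",
                                    group = rep(c("I", "II", "III", "IV",
                                                  "IV"), each = 10)))
  expect_error(referenceNeutrality(CtSet(m2), no_ctrl, "shifted"),
               "group 'control' is empty")
})

test_that("reference selection needs a neutral shortlisted assay", {
  coh <- tinyCohort(n_per = 10, n_assays = 8, seed = 9)
  expect_error(selectReference(coh$ct, coh$samples, k = 3, alpha = 1),
               "selection error")
  rep <- selectReference(coh$ct, coh$samples, k = 3, alpha = 0.05)
  expect_true(all(chosenReference(rep) %in% referenceShortlist(rep)$assay))
  sl <- referenceShortlist(rep)
  expect_true(all(sl$passes[sl$assay %in% chosenReference(rep)]))
})

test_that("dCt subtracts the reference within sample; replicates average first", {
  m <- rbind(target = c(30, 32), ref = c(25, 26))
  colnames(m) <- c("s1", "s2")
  d <- deltaCt(CtSet(m), "ref")
  expect_equal(unname(d["target", ]), c(5, 6))
  expect_equal(unname(d["ref", ]), c(0, 0))

  # duplicate wells collapse on the Ct scale before subtraction
  m2 <- rbind(target = c(29.8, 30.2, 31, 31), ref = c(25, 25, 25, 25))
  colnames(m2) <- c("s1_r1", "s1_r2", "s2_r1", "s2_r2")
  cs2 <- CtSet(m2, sampleId = c("s1", "s1", "s2", "s2"))
  d2 <- deltaCt(cs2, "ref", collapseDuplicates = TRUE)
  expect_equal(unname(d2["target", ]), c(5, 6))
  expect_equal(colnames(d2), c("s1", "s2"))

  # an undetected reference well is an error naming the sample
  m3 <- rbind(target = c(30, 31), ref = c(25, NA))
  colnames(m3) <- c("s1", "s2")
  expect_error(deltaCt(CtSet(m3), "ref"), "undetected in sample.*s2")
})

test_that("per-card references normalize each card's assays", {
  m <- rbind(a1 = c(30, 31), refA = c(25, 25), b1 = c(33, 34),
             refB = c(28, 29))
  colnames(m) <- c("s1", "s2")
  cs <- CtSet(m, card = c("A", "A", "B", "B"))
  d <- deltaCt(cs, c(A = "refA", B = "refB"))
  expect_equal(unname(d["a1", ]), c(5, 6))
  expect_equal(unname(d["b1", ]), c(5, 5))
})

test_that("-ddCt matches the definition and the brute-force oracle", {
  m <- rbind(t = c(30, 31, 29, 30), ref = c(25, 25, 25, 25))
  colnames(m) <- paste0("s", 1:4)
  st <- SampleTable(data.frame(sample_id = colnames(m), cohort = "discovery",
                               group = c("control", "control", "II", "IV")))
  d <- deltaCt(CtSet(m), "ref")
  rel <- relativeExpression(d, st)
  # dCt 5, baseline mean 4.5 -> ddCt 0.5, level -0.5 ... by hand:
  expect_equal(unname(relLevels(rel)["t", ]), c(0.5, -0.5, 1.5, 0.5))
  expect_equal(mean(relLevels(rel)["t", 1:2]), 0)
  expect_equal(unname(relLevels(rel)["ref", ]), rep(0, 4))
  expect_equal(foldChanges(rel)["t", "s3"], 2^1.5)
  expect_equal(baselineGroup(rel), "control")

  # randomized oracle comparison
  set.seed(21)
  for (rep_i in 1:25) {
    mm <- matrix(runif(20 * 12, 20, 38), 20, 12,
                 dimnames = list(sprintf("a%02d", 1:20),
                                 sprintf("s%02d", 1:12)))
    grp <- sample(rep(c("control", "I", "III"), each = 4))
    st2 <- SampleTable(data.frame(sample_id = colnames(mm),
                                  cohort = "discovery", group = grp))
    d2 <- deltaCt(CtSet(mm), "a01")
    got <- relLevels(relativeExpression(d2, st2))
    want <- bruteRelativeExpression(mm, "a01", grp, "control")
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("relative levels are location-invariant and monotone in target Ct", {
  set.seed(31)
  m <- matrix(runif(5 * 6, 22, 32), 5, 6,
              dimnames = list(paste0("a", 1:5), paste0("s", 1:6)))
  st <- SampleTable(data.frame(sample_id = colnames(m), cohort = "discovery",
                               group = rep(c("control", "IV"), each = 3)))
  base <- relLevels(relativeExpression(deltaCt(CtSet(m), "a1"), st))
  # add a per-sample constant (global efficiency shift): levels unchanged
  m2 <- sweep(m, 2, runif(6, -2, 2), "+")
  shifted <- relLevels(relativeExpression(deltaCt(CtSet(m2), "a1"), st))
  expect_equal(shifted, base, tolerance = 1e-12)
  # one extra cycle on a target in one sample -> exactly -1 on its level
  m3 <- m; m3["a3", "s5"] <- m3["a3", "s5"] + 1
  one <- relLevels(relativeExpression(deltaCt(CtSet(m3), "a1"), st))
  expect_equal(one["a3", "s5"] - base["a3", "s5"], -1)
})
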