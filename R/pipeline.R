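#' Pipeline run configuration
#'
#' Bundles every tunable of the two-phase pipeline. Inputs come either from
#' files (`discoveryCt`/`discoverySamples`/`validationCt`/`validationSamples`)
#' or, when those are `NULL`, from the synthetic generator under `simulation`.
#' A YAML file with any of these fields can be supplied as `configFile`;
#' explicit arguments win over the file.
#'
#' @param outputDir directory for artifacts (created if needed); `NULL`
#'   disables file output.
#' @param seed integer seed recorded in every manifest and governing all
#'   randomness.
#' @param alpha,alphaTrend screening thresholds (defaults 0.05 / 0.06).
#' @param test screening test, `"mann_whitney"` or `"t_test"`.
#' @param adjust multiple-testing handling for the screen (`"none"`/"BH").
#' @param k,maxMeanCt,refAlpha reference-selection parameters.
#' @param baselineGroup baseline for the -ddCt transform (default "control").
#' @param criterion marker-search criterion (`"auc"`/`"aic"`).
#' @param ties Cox tie handling (`"breslow"`/`"efron"`).
#' @param simulation a [simulationConfig()].
#' @param discoveryCt,discoverySamples,validationCt,validationSamples optional
#'   input file paths.
#' @param configFile optional YAML file of the same fields.
#' @return classed list `RunConfig`.
#' @export
runConfig <- function(outputDir = NULL, seed = 1, alpha = 0.05,
                      alphaTrend = 0.06,
                      test = c("mann_whitney", "t_test"),
                      adjust = c("none", "BH"),
                      k = 6, maxMeanCt = 35, refAlpha = 0.05,
                      baselineGroup = "control",
                      criterion = c("auc", "aic"),
                      ties = c("breslow", "efron"),
                      simulation = simulationConfig(),
                      discoveryCt = NULL, discoverySamples = NULL,
                      validationCt = NULL, validationSamples = NULL,
                      configFile = NULL) {
  cfg <- list(outputDir = outputDir, seed = as.integer(seed), alpha = alpha,
              alphaTrend = alphaTrend, test = match.arg(test),
              adjust = match.arg(adjust), k = k, maxMeanCt = maxMeanCt,
              refAlpha = refAlpha, baselineGroup = baselineGroup,
              criterion = match.arg(criterion), ties = match.arg(ties),
              simulation = simulation, discoveryCt = discoveryCt,
              discoverySamples = discoverySamples, validationCt = validationCt,
              validationSamples = validationSamples)
  if (!is.null(configFile)) {
    if (!file.exists(configFile)) stop("config file not found: ", configFile)
    over <- yaml::read_yaml(configFile)
    known <- intersect(names(over), names(cfg))
    supplied <- names(match.call())[-1]
    for (nm in setdiff(known, supplied)) cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "RunConfig")
}

#' FNV-1a hash of a configuration (hex string)
#' @noRd
.configHash <- function(cfg) {
  cfg$outputDir <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

.writeTsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writeManifest <- function(cfg, files, stage, dir, extra = list()) {
  if (is.null(dir)) return(invisible(NULL))
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     config_hash = .configHash(unclass(cfg)),
                     package_version = as.character(packageVersion("plasmaMiR")),
                     r_version = R.version.string,
                     parameters = list(alpha = cfg$alpha,
                                       alpha_trend = cfg$alphaTrend,
                                       test = cfg$test, adjust = cfg$adjust,
                                       k = cfg$k, max_mean_ct = cfg$maxMeanCt,
                                       ref_alpha = cfg$refAlpha,
                                       criterion = cfg$criterion,
                                       ties = cfg$ties),
                     files = files),
                extra)
  path <- file.path(dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.phaseInputs <- function(cfg, phase) {
  if (phase == "discovery") {
    if (!is.null(cfg$discoveryCt)) {
      ct <- readCtMatrix(cfg$discoveryCt)
      samples <- readSampleTable(cfg$discoverySamples)
      list(ct = ct, samples = samples, truth = NULL)
    } else simulateDiscovery(cfg$simulation, seed = cfg$seed)
  } else {
    if (!is.null(cfg$validationCt)) {
      ct <- readCtMatrix(cfg$validationCt)
      samples <- readSampleTable(cfg$validationSamples)
      list(ct = ct, samples = samples, truth = NULL)
    } else simulateValidation(cfg$simulation, seed = cfg$seed)
  }
}

#' Run the discovery phase
#'
#' Executes the screening arm end to end: zero-variance filtering, reference
#' selection by the three stability criteria, per-card dCt normalization,
#' -ddCt relative expression against the control baseline, and the
#' seven-comparison marker screen. When an output directory is configured,
#' writes `reference_report.tsv`, `relative_expression.tsv`,
#' `candidates.tsv`, `heatmap_z.tsv` and a JSON manifest recording the seed,
#' config hash and package version.
#'
#' @param cfg a [runConfig()].
#' @return list with `reference` ([ReferenceReport-class]), `expr`
#'   ([RelativeExpressionSet-class]), `candidates` (screen table), `truth`
#'   (generator ground truth or `NULL`), `files`.
#' @export
runDiscoveryPhase <- function(cfg = runConfig()) {
  inp <- .phaseInputs(cfg, "discovery")
  al <- alignSamples(inp$ct, inp$samples)
  ct <- filterZeroVariance(al$ct)
  ref <- selectReference(ct, k = cfg$k, maxMeanCt = cfg$maxMeanCt,
                         alpha = cfg$refAlpha)
  dct <- deltaCt(ct, chosenReference(ref))
  expr <- relativeExpression(dct, baselineGroup = cfg$baselineGroup)
  cand <- runMarkerScreen(expr, alpha = cfg$alpha,
                          alphaTrend = cfg$alphaTrend, test = cfg$test,
                          adjust = cfg$adjust)
  dir <- cfg$outputDir
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  files$reference <- .writeTsv(referenceShortlist(ref), dir,
                               "reference_report.tsv")
  files$expression <- .writeTsv(
    data.frame(assay_id = rownames(relLevels(expr)), relLevels(expr),
               check.names = FALSE), dir, "relative_expression.tsv")
  files$candidates <- .writeTsv(cand, dir, "candidates.tsv")
  sel <- unique(cand$assay[cand$selected])
  if (length(sel)) {
    z <- zscoreForHeatmap(expr, sel)
    files$heatmap <- .writeTsv(
      data.frame(assay_id = rownames(z), z, check.names = FALSE), dir,
      "heatmap_z.tsv")
  }
  files$manifest <- .writeManifest(
    cfg, files, "discovery", dir,
    list(chosen_reference = as.list(chosenReference(ref))))
  list(reference = ref, expr = expr, candidates = cand, truth = inp$truth,
       files = files)
}

#' The three clinical contrasts evaluated in the validation phase
#' @noRd
.clinicalContrasts <- function() {
  list(
    CRC_vs_control = list(positive = CRC_GROUPS, negative = "control",
                          categories = c("detection", "early_stage")),
    `III-IV_vs_I-II` = list(positive = c("III", "IV"), negative = c("I", "II"),
                            categories = "late_stage"),
    `IV_vs_I-III` = list(positive = "IV", negative = c("I", "II", "III"),
                         categories = "metastasis"))
}

#' Run the validation phase
#'
#' Quantifies the candidate markers against the spike-in (duplicate wells
#' averaged on the Ct scale), forms -ddCt relative levels against the control
#' baseline, and then for each clinical contrast (CRC vs control, stage
#' III-IV vs I-II, stage IV vs I-III) runs per-marker group comparisons,
#' selects the best single-marker logistic model and summarizes its ROC.
#' Survival follow-up: per-candidate mean-dichotomized Kaplan-Meier/log-rank
#' in patients, and a multivariable Cox model over stage, CEA, age, sex,
#' chemotherapy and the markers with univariate log-rank p < 0.05.
#'
#' @param cfg a [runConfig()].
#' @param candidates character vector of marker assay names to evaluate;
#'   defaults to every non-control assay present in the validation data.
#' @return list with `expr`, `comparisons`, `winners` (per contrast:
#'   marker, model, RocSummary, leaderboard), `km` (per-candidate log-rank
#'   table), `kmCurves`, `cox` ([coxFit()] table or `NULL`), `truth`,
#'   `files`.
#' @export
runValidationPhase <- function(cfg = runConfig(), candidates = NULL) {
  inp <- .phaseInputs(cfg, "validation")
  al <- alignSamples(inp$ct, inp$samples)
  spike <- cfg$simulation$spikeIn$assay
  ref <- if (spike %in% rownames(al$ct)) spike else
    stop("spike-in assay '", spike, "' absent from validation data")
  dct <- deltaCt(al$ct, ref, collapseDuplicates = TRUE)
  expr <- relativeExpression(dct, baselineGroup = cfg$baselineGroup)
  avail <- setdiff(rownames(relLevels(expr)), c(ref, controlAssays(al$ct)))
  if (is.null(candidates)) candidates <- avail
  candidates <- intersect(candidates, avail)
  if (!length(candidates)) stop("no candidate markers to validate")
  m <- relLevels(expr)
  grp <- as.character(colData(expr)$group)
  contrasts <- .clinicalContrasts()
  comparisons <- list(); winners <- list()
  for (nm in names(contrasts)) {
    ctr <- contrasts[[nm]]
    keep <- grp %in% c(ctr$positive, ctr$negative)
    y <- as.integer(grp[keep] %in% ctr$positive)
    x <- t(m[candidates, keep, drop = FALSE])
    comparisons[[nm]] <- data.frame(
      assay = candidates,
      p_value = vapply(candidates, function(a)
        .mannWhitneyP(m[a, keep][y == 0], m[a, keep][y == 1]), numeric(1)),
      effect = vapply(candidates, function(a)
        median(m[a, keep][y == 1]) - median(m[a, keep][y == 0]), numeric(1)),
      row.names = NULL)
    bw <- bestSingleMarker(x, y, criterion = cfg$criterion)
    winners[[nm]] <- c(bw, list(contrast = ctr))
  }
  # survival arm: patients with survival information
  pat <- grp %in% CRC_GROUPS
  has_os <- pat & !is.na(colData(expr)$os_time) & !is.na(colData(expr)$os_event)
  times <- as.numeric(colData(expr)$os_time[has_os])
  events <- as.integer(colData(expr)$os_event[has_os])
  kmtab <- NULL; curves <- list(); labels <- list(); coxtab <- NULL
  if (sum(events) >= 1) {
    rows <- lapply(candidates, function(a) {
      lab <- dichotomizeByMean(m[a, has_os])
      if (any(table(lab) == 0))
        return(data.frame(assay = a, chisq = NA_real_, p = NA_real_,
                          n_low = sum(lab == "low"), n_high = sum(lab == "high")))
      lr <- logrankTest(times, events, lab)
      labels[[a]] <<- setNames(lab, colnames(m)[has_os])
      curves[[a]] <<- list(low = kmCurve(times[lab == "low"],
                                         events[lab == "low"]),
                           high = kmCurve(times[lab == "high"],
                                          events[lab == "high"]))
      data.frame(assay = a, chisq = lr$chisq, p = lr$p,
                 n_low = sum(lab == "low"), n_high = sum(lab == "high"))
    })
    kmtab <- do.call(rbind, rows)
    prognostic <- kmtab$assay[!is.na(kmtab$p) & kmtab$p < cfg$alpha]
    cox_ok <- all(c("cea", "age", "sex", "chemotherapy") %in%
                    colnames(colData(expr)))
    if (cox_ok && length(prognostic)) {
      des <- buildDesign(al$samples, markerLabels = labels[prognostic])
      coxtab <- tryCatch(coxFit(des$design, des$times, des$events,
                                ties = cfg$ties),
                         error = function(e) {
                           warning("Cox stage skipped: ", conditionMessage(e))
                           NULL
                         })
    }
  }
  dir <- cfg$outputDir
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(comparisons))
    files[[paste0("comparison_", nm)]] <-
      .writeTsv(comparisons[[nm]], dir, sprintf("comparison_%s.tsv", nm))
  wtab <- data.frame(
    contrast = names(winners),
    marker = vapply(winners, `[[`, character(1), "marker"),
    auc = vapply(winners, function(w) w$summary$auc, numeric(1)),
    se = vapply(winners, function(w) w$summary$se, numeric(1)),
    ci_low = vapply(winners, function(w) w$summary$ci_low, numeric(1)),
    ci_high = vapply(winners, function(w) w$summary$ci_high, numeric(1)),
    sensitivity = vapply(winners, function(w) w$summary$sensitivity, numeric(1)),
    specificity = vapply(winners, function(w) w$summary$specificity, numeric(1)),
    row.names = NULL)
  files$winners <- .writeTsv(wtab, dir, "contrast_winners.tsv")
  if (!is.null(kmtab)) files$logrank <- .writeTsv(kmtab, dir, "logrank.tsv")
  if (!is.null(coxtab)) files$cox <- .writeTsv(as.data.frame(coxtab), dir,
                                               "cox_fit.tsv")
  files$manifest <- .writeManifest(cfg, files, "validation", dir)
  list(expr = expr, comparisons = comparisons, winners = winners,
       winnerTable = wtab, km = kmtab, kmCurves = curves, cox = coxtab,
       truth = inp$truth, files = files)
}

#' Run the full two-phase pipeline
#'
#' Chains discovery and validation: the validation candidate list is the set
#' of discovery-selected assays that the validation assay panel measures
#' (markers taken forward to singleplex qPCR).
#'
#' @param cfg a [runConfig()].
#' @return list with `discovery`, `validation`, `candidates`.
#' @export
runAll <- function(cfg = runConfig()) {
  disc <- runDiscoveryPhase(cfg)
  sel <- unique(disc$candidates$assay[disc$candidates$selected])
  val <- runValidationPhase(cfg, candidates = sel)
  list(discovery = disc, validation = val,
       candidates = val$comparisons[[1]]$assay)
}
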