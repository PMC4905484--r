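#' Default planted marker panel
#'
#' Eleven marker miRNAs mirroring a staged plasma-biomarker panel: five
#' general detection markers, two early-stage markers (one of which also
#' separates stage II from III), three late-stage markers and one metastasis
#' marker. Shifts are on the Ct scale in cycles, per stage, negative = fewer
#' cycles = higher abundance in that stage (one cycle is roughly two-fold).
#' `prog_coef` is the log-hazard coefficient per standard deviation of the
#' marker's latent level in the survival model.
#'
#' @return data.frame with columns assay, card, category, mean_ct, sd,
#'   shift_I..shift_IV, prog_coef.
#' @export
defaultMarkerPanel <- function() {
  p <- rbind(
    c("let-7f-2*",  "A", "detection",   28, -1.2, -1.2, -1.2, -1.8, 0),
    c("miR-15b*",   "A", "detection",   27, -0.8, -0.8, -0.8, -1.5, 0),
    c("miR-526b",   "B", "detection",   29, -0.8, -0.8, -0.8, -1.4, 0),
    c("miR-628-5p", "B", "detection",   28, -1.0, -1.0, -1.4, -1.8, 0),
    c("miR-486-3p", "A", "detection",   26, -1.0, -1.0, -1.0, -1.0, 0),
    c("miR-96",     "A", "early_stage", 30, -1.5, -1.7, -0.7, -2.2, 0.6),
    c("miR-148a",   "A", "early_stage", 27, -1.2, -1.4, -1.0, -1.8, 0),
    c("miR-203",    "B", "late_stage",  29,  0.0,  0.0, -1.8, -2.0, 0),
    c("miR-200b",   "A", "late_stage",  28,  0.0,  0.0, -1.6, -2.2, 0.9),
    c("miR-22",     "A", "late_stage",  26,  0.0,  0.0, -1.2, -1.4, 0),
    c("miR-141",    "A", "metastasis",  30,  0.0,  0.0,  0.0, -2.5, 0.4))
  out <- data.frame(assay = p[, 1], card = p[, 2], category = p[, 3],
                    mean_ct = as.numeric(p[, 4]), sd = 1,
                    shift_I = as.numeric(p[, 5]), shift_II = as.numeric(p[, 6]),
                    shift_III = as.numeric(p[, 7]), shift_IV = as.numeric(p[, 8]),
                    prog_coef = as.numeric(p[, 9]),
                    stringsAsFactors = FALSE)
  out
}

#' Default stable (endogenous-control candidate) assays
#'
#' Six low-variation assays per card, mirroring the six-per-card shortlist a
#' stability screen produces: three are truly neutral across groups (the
#' designated reference analogues, miR-451-like on card A and miR-877-like on
#' card B, having the smallest SD) and three are low-variation but carry a
#' modest disease-associated shift (a miR-16-like hemolysis-sensitive
#' pattern), so the neutrality criterion has real work to do.
#'
#' @return data.frame with columns assay, card, mean_ct, sd, neutral, shift
#'   (cycles applied to every CRC stage).
#' @export
defaultStableAssays <- function() {
  p <- rbind(
    c("miR-451",     "A", 24, 0.12, TRUE,  0.0),
    c("miR-103",     "A", 25, 0.17, TRUE,  0.0),
    c("miR-192",     "A", 26, 0.19, TRUE,  0.0),
    c("miR-16",      "A", 23, 0.22, FALSE, -0.6),
    c("miR-17",      "A", 25, 0.24, FALSE, -0.4),
    c("miR-93",      "A", 26, 0.26, FALSE, -0.3),
    c("miR-877",     "B", 25, 0.13, TRUE,  0.0),
    c("miR-188",     "B", 26, 0.17, TRUE,  0.0),
    c("miR-520c-3p", "B", 27, 0.19, TRUE,  0.0),
    c("U6",          "B", 24, 0.23, FALSE, 0.5),
    c("miR-138-1",   "B", 27, 0.25, FALSE, -0.4),
    c("miR-610",     "B", 28, 0.27, FALSE, 0.3))
  data.frame(assay = p[, 1], card = p[, 2], mean_ct = as.numeric(p[, 3]),
             sd = as.numeric(p[, 4]), neutral = as.logical(p[, 5]),
             shift = as.numeric(p[, 6]), stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a discovery cohort
#' of 10 healthy controls plus 10 CRC patients per stage I-IV profiled on a
#' 754-assay two-card panel, and a validation cohort of 47 controls and 187
#' patients (stages 38/50/50/49) with duplicate-well qPCR of the marker
#' panel, a cel-miR-39 spike-in, CEA values, and overall survival from an
#' exponential hazard with stage and marker effects censored around a
#' 28-month median follow-up.
#'
#' @param nAssays total assays across both cards (default 754).
#' @param discoverySizes named group sizes for the discovery cohort.
#' @param validationSizes named group sizes for the validation cohort.
#' @param baselineCtRange range of per-assay baseline mean Ct (cycles).
#' @param bioSdRange range of per-assay biological SD (cycles).
#' @param techSd technical duplicate SD in cycles (default 0.15).
#' @param ceiling detection ceiling (default 40 cycles).
#' @param markers planted marker table ([defaultMarkerPanel()]).
#' @param stable stable-assay table ([defaultStableAssays()]).
#' @param spikeIn list(assay, mean_ct, sd) for the synthetic spike-in.
#' @param nAbsent number of never-detected assays (flat at the ceiling).
#' @param survival list: `base_rate` (exponential baseline hazard per month),
#'   `stage_coef` (log-hazard for stage III-IV vs I-II), `censor_range`
#'   (months, uniform administrative censoring, median ~28), `no_info`
#'   (patients with no survival information).
#' @param cea list: `meanlog_I` and `stage_step` on the log scale, `sdlog`.
#' @return classed list `SimulationConfig`.
#' @export
simulationConfig <- function(
    nAssays = 754,
    discoverySizes = c(control = 10, I = 10, II = 10, III = 10, IV = 10),
    validationSizes = c(control = 47, I = 38, II = 50, III = 50, IV = 49),
    baselineCtRange = c(22, 38),
    bioSdRange = c(0.3, 1.5),
    techSd = 0.15,
    ceiling = 40,
    markers = defaultMarkerPanel(),
    stable = defaultStableAssays(),
    spikeIn = list(assay = "cel-miR-39", mean_ct = 20, sd = 0.08),
    nAbsent = 30,
    survival = list(base_rate = 0.006, stage_coef = 1.1,
                    censor_range = c(6, 50), no_info = 13),
    cea = list(meanlog_I = 0.7, stage_step = 0.35, sdlog = 0.7)) {
  cfg <- list(nAssays = nAssays, discoverySizes = discoverySizes,
              validationSizes = validationSizes,
              baselineCtRange = baselineCtRange, bioSdRange = bioSdRange,
              techSd = techSd, ceiling = ceiling, markers = markers,
              stable = stable, spikeIn = spikeIn, nAbsent = nAbsent,
              survival = survival, cea = cea)
  .validateSimConfig(cfg)
  structure(cfg, class = "SimulationConfig")
}

.validateSimConfig <- function(cfg) {
  if (any(cfg$discoverySizes < 2) || any(cfg$validationSizes < 2))
    stop("config error: every group needs >= 2 samples")
  if (!setequal(names(cfg$discoverySizes), GROUP_LEVELS) ||
      !setequal(names(cfg$validationSizes), GROUP_LEVELS))
    stop("config error: group sizes must be named control, I, II, III, IV")
  mk <- cfg$markers
  if (nrow(mk)) {
    shifts <- as.matrix(mk[, c("shift_I", "shift_II", "shift_III", "shift_IV")])
    if (any(!is.finite(shifts))) stop("config error: marker shifts must be finite")
    if (!all(mk$category %in% c("detection", "early_stage", "late_stage",
                                "metastasis", "stage2_vs_3")))
      stop("config error: unknown marker category")
  }
  planted <- c(mk$assay, cfg$stable$assay)
  if (anyDuplicated(planted))
    stop("config error: duplicate planted assay names")
  if (cfg$nAssays < length(planted) + cfg$nAbsent + 2)
    stop("config error: nAssays too small for the planted assays")
  invisible(TRUE)
}

#' Ground-truth table of planted effects
#'
#' @param config a [simulationConfig()].
#' @return data.frame with one row per planted marker: assay, category,
#'   per-stage Ct shifts and the prognostic log-hazard coefficient. Empty if
#'   no markers are planted.
#' @export
plantedTruth <- function(config) {
  mk <- config$markers
  if (!nrow(mk))
    return(data.frame(assay = character(), category = character(),
                      shift_I = numeric(), shift_II = numeric(),
                      shift_III = numeric(), shift_IV = numeric(),
                      prog_coef = numeric()))
  mk[, c("assay", "category", "shift_I", "shift_II", "shift_III", "shift_IV",
         "prog_coef")]
}

.subSeed <- function(seed, k) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + k * 7919) %%
               2147483629) + 1L
}

.groupVector <- function(sizes) {
  factor(rep(names(sizes), times = sizes), levels = GROUP_LEVELS)
}

.shiftFor <- function(markers, stable, assay_order, groups) {
  # matrix of planted Ct shifts (assay x sample); zero for filler assays
  sh <- matrix(0, length(assay_order), length(groups),
               dimnames = list(assay_order, NULL))
  gidx <- match(as.character(groups), CRC_GROUPS)  # NA for controls
  for (i in seq_len(nrow(markers))) {
    v <- as.numeric(markers[i, c("shift_I", "shift_II", "shift_III",
                                 "shift_IV")])
    sh[markers$assay[i], ] <- ifelse(is.na(gidx), 0, v[gidx])
  }
  for (i in seq_len(nrow(stable)))
    sh[stable$assay[i], ] <- ifelse(is.na(gidx), 0, stable$shift[i])
  sh
}

#' Assay layout for the discovery card set
#' @noRd
.assayLayout <- function(cfg) {
  planted <- data.frame(
    assay = c(cfg$stable$assay, cfg$markers$assay, "RNU44", "RNU48"),
    card = c(cfg$stable$card, cfg$markers$card, "A", "B"),
    mean_ct = c(cfg$stable$mean_ct, cfg$markers$mean_ct, 37.5, 38.2),
    sd = c(cfg$stable$sd, cfg$markers$sd, 0.8, 0.8),
    is_control = c(cfg$stable$assay %in% c("U6", "RNU44", "RNU48"),
                   rep(FALSE, nrow(cfg$markers)), TRUE, TRUE),
    stringsAsFactors = FALSE)
  n_fill <- cfg$nAssays - nrow(planted) - cfg$nAbsent
  fill <- data.frame(
    assay = sprintf("miR-sim-%04d", seq_len(n_fill)),
    card = rep(NA_character_, n_fill), mean_ct = rep(NA_real_, n_fill),
    sd = rep(NA_real_, n_fill), is_control = rep(FALSE, n_fill),
    stringsAsFactors = FALSE)
  absent <- data.frame(
    assay = sprintf("miR-abs-%03d", seq_len(cfg$nAbsent)),
    card = rep(NA_character_, cfg$nAbsent),
    mean_ct = rep(cfg$ceiling + 5, cfg$nAbsent),
    sd = rep(0, cfg$nAbsent),
    is_control = rep(FALSE, cfg$nAbsent), stringsAsFactors = FALSE)
  out <- rbind(planted, fill, absent)
  # balance cards A/B to an even split of nAssays
  target_a <- ceiling(cfg$nAssays / 2)
  open <- which(is.na(out$card))
  n_a <- sum(out$card == "A", na.rm = TRUE)
  out$card[open] <- rep(c("A", "B"),
                        c(max(0, target_a - n_a),
                          length(open) - max(0, target_a - n_a)))
  out
}

#' Simulate the discovery cohort
#'
#' Generates the full two-card Ct matrix (default 754 assays x 50 samples:
#' 10 controls and 10 patients per stage I-IV). Each assay's Ct is its
#' baseline mean plus the planted per-stage shift plus biological noise;
#' readings above the ceiling are stored at the ceiling and flagged. Filler
#' assays draw baseline mean Ct from `baselineCtRange` and SD from
#' `bioSdRange`; absent assays sit flat at the ceiling (and are the material
#' for the zero-variance filter). Output is deterministic given
#' `(config, seed)`.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @return list with `ct` ([CtSet-class]), `samples` ([SampleTable-class]),
#'   `truth` ([plantedTruth()] table).
#' @export
simulateDiscovery <- function(config = simulationConfig(), seed = 1) {
  .validateSimConfig(config)
  set.seed(.subSeed(seed, 1))
  grp <- .groupVector(config$discoverySizes)
  n <- length(grp)
  ids <- sprintf("D%03d", seq_len(n))
  lay <- .assayLayout(config)
  open <- is.na(lay$mean_ct)
  lay$mean_ct[open] <- runif(sum(open), config$baselineCtRange[1],
                             config$baselineCtRange[2])
  lay$sd[open] <- runif(sum(open), config$bioSdRange[1], config$bioSdRange[2])
  sh <- .shiftFor(config$markers, config$stable, lay$assay, grp)
  noise <- matrix(rnorm(nrow(lay) * n, 0, rep(lay$sd, n)), nrow(lay), n)
  ct <- lay$mean_ct + sh + noise
  dimnames(ct) <- list(lay$assay, ids)
  cs <- CtSet(ct, card = lay$card, isControl = lay$is_control,
              ceiling = config$ceiling)
  n_ctrl <- config$discoverySizes[["control"]]
  n_pat <- n - n_ctrl
  sex <- character(n)
  sex[grp == "control"] <- .fixedLabels(n_ctrl, c(male = 5, female = 5))
  sex[grp != "control"] <- .fixedLabels(n_pat, c(male = n_pat / 2,
                                                 female = n_pat / 2))
  age <- ifelse(grp == "control", rnorm(n, 54, 6.4), rnorm(n, 55, 6.3))
  samples <- SampleTable(data.frame(
    sample_id = ids, cohort = "discovery", group = as.character(grp),
    sex = sex, age = round(age, 1), stringsAsFactors = FALSE))
  list(ct = cs, samples = samples, truth = plantedTruth(config))
}

.fixedLabels <- function(n, counts) {
  # exact composition: a permuted vector with the given label counts
  counts <- round(counts)
  counts[1] <- n - sum(counts[-1])
  sample(rep(names(counts), times = counts))
}

#' Simulate the validation cohort
#'
#' Generates duplicate-well qPCR data for the planted marker panel plus the
#' spike-in and a miR-451-like endogenous control, over 47 controls and 187
#' patients (stages 38/50/50/49 by default). Every sample yields two
#' technical replicate wells per assay (shared `sample_id`, distinct well
#' ids). Patients carry CEA (log-normal, stage-shifted), fixed-composition
#' sex/surgery/chemotherapy flags matching the study population table (one
#' patient with unknown chemotherapy), and overall survival drawn from an
#' exponential hazard `base_rate * exp(stage_coef * [stage III-IV] + sum
#' prog_coef_m * z_m)` where `z_m` is the marker's standardized latent level;
#' follow-up is administratively censored (uniform on `censor_range`, median
#' about 28 months) and a fixed number of patients carry no survival
#' information. Controls carry no survival fields.
#'
#' @inheritParams simulateDiscovery
#' @return list with `ct` (replicated [CtSet-class] incl. spike-in),
#'   `samples` ([SampleTable-class]) and `truth`.
#' @export
simulateValidation <- function(config = simulationConfig(), seed = 1) {
  .validateSimConfig(config)
  set.seed(.subSeed(seed, 2))
  grp <- .groupVector(config$validationSizes)
  n <- length(grp)
  ids <- sprintf("V%03d", seq_len(n))
  mk <- config$markers
  ref <- config$stable[config$stable$assay == "miR-451", , drop = FALSE]
  lay <- data.frame(assay = c(mk$assay, ref$assay, config$spikeIn$assay),
                    mean_ct = c(mk$mean_ct, ref$mean_ct, config$spikeIn$mean_ct),
                    sd = c(mk$sd, ref$sd, config$spikeIn$sd),
                    is_control = c(rep(FALSE, nrow(mk)),
                                   rep(TRUE, nrow(ref)), TRUE),
                    stringsAsFactors = FALSE)
  sh <- .shiftFor(mk, ref, lay$assay, grp)
  bio <- matrix(rnorm(nrow(lay) * n, 0, rep(lay$sd, n)), nrow(lay), n,
                dimnames = list(lay$assay, ids))
  level <- lay$mean_ct + sh + bio            # per-sample latent Ct
  tech1 <- level + rnorm(length(level), 0, config$techSd)
  tech2 <- level + rnorm(length(level), 0, config$techSd)
  wells <- matrix(NA_real_, nrow(lay), 2 * n,
                  dimnames = list(lay$assay,
                                  paste0(rep(ids, each = 2), c("_r1", "_r2"))))
  wells[, seq(1, 2 * n, by = 2)] <- tech1
  wells[, seq(2, 2 * n, by = 2)] <- tech2
  cs <- CtSet(wells, card = "none", isControl = lay$is_control,
              ceiling = config$ceiling, sampleId = rep(ids, each = 2))
  # clinical annotation with fixed composition
  is_pat <- grp != "control"
  n_pat <- sum(is_pat)
  sex <- character(n)
  sex[!is_pat] <- .fixedLabels(n - n_pat, c(male = 22, female = 25))
  sex[is_pat] <- .fixedLabels(n_pat, c(male = 99, female = 88))
  age <- ifelse(is_pat, rnorm(n, 55, 7.8), rnorm(n, 54, 6.3))
  surgery <- rep(NA_integer_, n)
  surgery[is_pat] <- as.integer(.fixedLabels(n_pat, c("1" = 156, "0" = 31)))
  chemo <- rep(NA_integer_, n)
  chemo[is_pat] <- suppressWarnings(
    as.integer(.fixedLabels(n_pat, c("1" = 144, "0" = 42, "NA" = 1))))
  stage_idx <- match(as.character(grp), CRC_GROUPS)
  cea <- rep(NA_real_, n)
  cea[is_pat] <- rlnorm(n_pat,
                        meanlog = config$cea$meanlog_I +
                          config$cea$stage_step * (stage_idx[is_pat] - 1),
                        sdlog = config$cea$sdlog)
  # survival: exponential hazard with stage + marker effects
  sv <- config$survival
  z <- (-(sh + bio)) / lay$sd               # standardized latent marker level
  lp <- sv$stage_coef * as.numeric(stage_idx >= 3)
  for (i in which(mk$prog_coef != 0))
    lp <- lp + mk$prog_coef[i] * z[mk$assay[i], ]
  os_time <- rep(NA_real_, n)
  os_event <- rep(NA_integer_, n)
  if (any(is_pat)) {
    rate <- sv$base_rate * exp(lp[is_pat])
    tt <- if (all(rate > 0)) rexp(n_pat, rate) else {
      out <- rep(Inf, n_pat)
      pos <- rate > 0
      out[pos] <- rexp(sum(pos), rate[pos])
      out
    }
    cc <- runif(n_pat, sv$censor_range[1], sv$censor_range[2])
    os_time[is_pat] <- round(pmin(tt, cc), 2)
    os_event[is_pat] <- as.integer(tt <= cc)
    if (sv$no_info > 0) {
      drop <- sample(which(is_pat), min(sv$no_info, n_pat))
      os_time[drop] <- NA_real_
      os_event[drop] <- NA_integer_
    }
  }
  samples <- SampleTable(data.frame(
    sample_id = ids, cohort = "validation", group = as.character(grp),
    sex = sex, age = round(age, 1), cea = round(cea, 2), surgery = surgery,
    chemotherapy = chemo, os_time = os_time, os_event = os_event,
    stringsAsFactors = FALSE))
  list(ct = cs, samples = samples, truth = plantedTruth(config))
}
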