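#' Configuration for the synthetic multi-site longitudinal cohort
#'
#' The generator emulates the structure the training stages assume: a latent
#' per-subject disease severity that drives regional atrophy on MRI and tracer
#' uptake on PET, per-site affine intensity effects, monotone longitudinal
#' progression, per-visit PET missingness, diagnosis labels thresholded from
#' severity, and conversion times drawn from an exponential
#' proportional-hazards model with log-hazard linear in baseline severity
#' (censored administratively at `censoringTime`).
#'
#' Severity is unitless; one unit roughly spans one diagnostic stage. Class
#' means place CN/MCI/AD at 0.5/1.25/2.25 with `severitySd` spread, and
#' `diagnosisThresholds` cut the latent scale at the midpoints, so labels are
#' monotone in severity by construction. Per-subject progression slopes are
#' positive (truncated normal), making severity non-decreasing across visits.
#'
#' @param nSubjects number of subjects.
#' @param nSites number of acquisition sites (>= 2).
#' @param visitsRange integer range `c(min, max)` of visits per subject.
#' @param visitSpacing months between consecutive visits.
#' @param gridSize voxels per axis (>= 8); volumes are isotropic cubes.
#' @param classProbs mixture weights over CN/MCI/AD latent classes.
#' @param classMeans latent severity means per class.
#' @param severitySd within-class severity standard deviation.
#' @param progressionRate mean severity units gained per month.
#' @param progressionSd between-subject sd of the progression slope.
#' @param diagnosisThresholds two cut points mapping severity to CN/MCI/AD.
#' @param siteShift additive intensity offset per site (recycled to `nSites`).
#' @param siteScale multiplicative intensity factor per site (recycled).
#' @param siteGradient per-site bias-field strength: a linear intensity
#'   gradient across the x axis (intensity units from centre to edge),
#'   emulating scanner inhomogeneity that survives per-volume
#'   standardization. Default 0 for all sites.
#' @param anatomySd standard deviation (intensity units) of the per-subject
#'   smooth anatomy field — a random low-order polynomial pattern, fixed per
#'   subject across visits and shared between co-registered modalities
#'   (scaled by `anatomyScale`), giving each subject an identity beyond
#'   severity.
#' @param anatomyScale per-modality multiplier of the anatomy field.
#' @param petMissingProb probability a visit lacks PET.
#' @param hazardBaseline baseline conversion hazard, events/month.
#' @param hazardLogRatio log hazard ratio per severity unit.
#' @param censoringTime administrative censoring horizon, months.
#' @param noiseSd i.i.d. Gaussian intensity noise inside the mask.
#' @param mriHealthy,mriSlope target-region MRI mean at severity 0 and its
#'   (negative) change per severity unit — the atrophy surrogate.
#' @param petHealthy,petSlope target-region PET mean at severity 0 and its
#'   (positive) change per severity unit — the tracer-uptake surrogate.
#' @param background intensity of brain tissue outside the target region.
#' @param seed integer seed; all stochastic draws flow from it.
#' @return A validated list of class `"cohortConfig"`.
#' @export
cohortConfig <- function(nSubjects = 100L, nSites = 2L,
                         visitsRange = c(2L, 3L), visitSpacing = 6,
                         gridSize = 16L,
                         classProbs = c(CN = 0.4, MCI = 0.35, AD = 0.25),
                         classMeans = c(CN = 0.5, MCI = 1.25, AD = 2.25),
                         severitySd = 0.25,
                         progressionRate = 0.02, progressionSd = 0.01,
                         diagnosisThresholds = c(0.875, 1.75),
                         siteShift = NULL, siteScale = NULL,
                         siteGradient = NULL,
                         anatomySd = 3, anatomyScale = c(MRI = 1, PET = 0.7),
                         petMissingProb = 0.3,
                         hazardBaseline = 0.004, hazardLogRatio = 0.9,
                         censoringTime = 36, noiseSd = 2,
                         mriHealthy = 80, mriSlope = -10,
                         petHealthy = 40, petSlope = 25,
                         background = c(MRI = 60, PET = 30),
                         seed = 1L) {
  if (is.null(siteShift)) siteShift <- seq(0, by = 5, length.out = nSites)
  if (is.null(siteScale)) siteScale <- rep(1, nSites)
  if (is.null(siteGradient)) siteGradient <- rep(0, nSites)
  cfg <- list(
    nSubjects = as.integer(nSubjects), nSites = as.integer(nSites),
    visitsRange = as.integer(visitsRange), visitSpacing = visitSpacing,
    gridSize = as.integer(gridSize), classProbs = classProbs,
    classMeans = classMeans, severitySd = severitySd,
    progressionRate = progressionRate, progressionSd = progressionSd,
    diagnosisThresholds = diagnosisThresholds,
    siteShift = rep_len(siteShift, nSites),
    siteScale = rep_len(siteScale, nSites),
    siteGradient = rep_len(siteGradient, nSites),
    anatomySd = anatomySd, anatomyScale = anatomyScale,
    petMissingProb = petMissingProb, hazardBaseline = hazardBaseline,
    hazardLogRatio = hazardLogRatio, censoringTime = censoringTime,
    noiseSd = noiseSd, mriHealthy = mriHealthy, mriSlope = mriSlope,
    petHealthy = petHealthy, petSlope = petSlope, background = background,
    seed = as.integer(seed)
  )
  checkCohortConfig(cfg)
  class(cfg) <- "cohortConfig"
  cfg
}

checkCohortConfig <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid cohort configuration: '%s' %s", field, why),
         call. = FALSE)
  if (cfg$nSubjects < 1L) bad("nSubjects", "must be >= 1")
  if (cfg$nSites < 2L) bad("nSites", "must be >= 2")
  if (cfg$gridSize < 8L) bad("gridSize", "must be >= 8")
  if (length(cfg$visitsRange) != 2L || any(cfg$visitsRange < 1L) ||
      cfg$visitsRange[1] > cfg$visitsRange[2])
    bad("visitsRange", "must be an increasing pair of positive counts")
  if (cfg$petMissingProb < 0 || cfg$petMissingProb > 1)
    bad("petMissingProb", "must lie in [0, 1]")
  if (any(cfg$classProbs < 0) || abs(sum(cfg$classProbs) - 1) > 1e-8)
    bad("classProbs", "must be nonnegative and sum to 1")
  if (cfg$hazardBaseline <= 0) bad("hazardBaseline", "must be positive")
  if (cfg$hazardLogRatio < 0) bad("hazardLogRatio", "must be nonnegative")
  if (cfg$censoringTime <= 0) bad("censoringTime", "must be positive")
  if (cfg$noiseSd < 0) bad("noiseSd", "must be nonnegative")
  if (cfg$anatomySd < 0) bad("anatomySd", "must be nonnegative")
  if (cfg$severitySd < 0) bad("severitySd", "must be nonnegative")
  if (cfg$progressionRate <= 0) bad("progressionRate", "must be positive")
  if (length(cfg$diagnosisThresholds) != 2L ||
      diff(cfg$diagnosisThresholds) <= 0)
    bad("diagnosisThresholds", "must be two increasing cut points")
  invisible(TRUE)
}

severityToDiagnosis <- function(severity, thresholds) {
  c("CN", "MCI", "AD")[findInterval(severity, thresholds) + 1L]
}

#' Generate a synthetic multi-site longitudinal cohort
#'
#' Draws subjects, sites, severity trajectories, diagnosis labels, PET
#' availability, and conversion outcomes, and (optionally) renders the MRI/PET
#' volumes. Conversion times use inverse-transform sampling from an
#' exponential proportional-hazards model: hazard
#' `h = hazardBaseline * exp(hazardLogRatio * severity0)`, `T = -log(U)/h`,
#' censored at `censoringTime`. Deterministic given `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @param renderVolumes if `TRUE` (default) volumes are rendered for every
#'   available subject-visit-modality.
#' @return An [ImagingCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nSubjects = 5, seed = 7))
#' visitTable(coh)[, 1:6]
#' @export
generateCohort <- function(config, renderVolumes = TRUE) {
  checkCohortConfig(config)
  set.seed(config$seed)
  n <- config$nSubjects
  ids <- sprintf("S%04d", seq_len(n))
  site <- sprintf("site%02d", sample.int(config$nSites, n, replace = TRUE))
  cls <- sample(names(config$classProbs), n, replace = TRUE,
                prob = config$classProbs)
  sev0 <- pmax(0, config$classMeans[cls] + rnorm(n, 0, config$severitySd))
  slope <- pmax(1e-4, rnorm(n, config$progressionRate, config$progressionSd))
  age <- round(runif(n, 60, 85), 1)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  anat <- matrix(rnorm(n * 9L), n, 9L,
                 dimnames = list(NULL, paste0("anat", 1:9)))
  nv <- sample(seq(config$visitsRange[1], config$visitsRange[2]),
               n, replace = TRUE)
  hazard <- config$hazardBaseline * exp(config$hazardLogRatio * sev0)
  tConv <- rexp(n, rate = hazard)
  event <- as.integer(tConv <= config$censoringTime)
  tObs <- pmin(tConv, config$censoringTime)

  subjects <- data.frame(
    subject_id = ids, site_id = site, age = age, sex = sex,
    latent_class = cls, severity_baseline = as.numeric(sev0),
    progression_slope = slope, T_months = tObs, event = event,
    stringsAsFactors = FALSE
  )
  subjects <- cbind(subjects, as.data.frame(anat))

  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- (seq_len(nv[i]) - 1) * config$visitSpacing
    sev <- sev0[i] + slope[i] * tt
    data.frame(
      subject_id = ids[i], visit_time_months = tt, site_id = site[i],
      age = age[i] + tt / 12, sex = sex[i],
      diagnosis = severityToDiagnosis(sev, config$diagnosisThresholds),
      has_mri = TRUE,
      has_pet = runif(nv[i]) >= config$petMissingProb,
      severity = as.numeric(sev), stringsAsFactors = FALSE
    )
  }))
  rownames(visits) <- NULL

  volumes <- list()
  if (renderVolumes) {
    for (r in seq_len(nrow(visits))) {
      vr <- visits[r, ]
      mods <- c(if (vr$has_mri) "MRI", if (vr$has_pet) "PET")
      si <- match(vr$subject_id, ids)
      for (m in mods) {
        vol <- renderVolume(vr$severity, m, config, siteId = vr$site_id,
                            subjectId = vr$subject_id,
                            visitTime = vr$visit_time_months,
                            anatomy = anat[si, ])
        volumes[[volumeKey(vr$subject_id, vr$visit_time_months, m)]] <- vol
      }
    }
  }
  new("ImagingCohort", visits = visits, subjects = subjects,
      volumes = volumes, config = unclass(config))
}

# Cached geometry: ellipsoidal brain mask plus concentric target region.
cohortGeometry <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ctr <- (n + 1) / 2
    ax <- seq_len(n) - ctr
    r2 <- outer(outer(ax^2 / (0.45 * n)^2, ax^2 / (0.40 * n)^2, "+"),
                ax^2 / (0.40 * n)^2, "+")
    mask <- r2 <= 1
    t2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
    target <- array(t2 <= (0.16 * n)^2, dim(mask)) & mask
    # smooth low-order spatial basis for the per-subject anatomy field and
    # the per-site bias-field gradient; standardized within the mask
    u <- ax / max(abs(ax))
    one <- rep(1, n)
    X <- outer(outer(u, one), one)
    Y <- outer(outer(one, u), one)
    Z <- outer(outer(one, one), u)
    raw <- list(X, Y, Z, X * Y, X * Z, Y * Z, X^2, Y^2, Z^2)
    basis <- lapply(raw, function(b) {
      v <- b[mask]
      b[] <- 0
      b[mask] <- (v - mean(v)) / sd(v)
      b
    })
    xgrad <- basis[[1]]
    g <- list(mask = mask, target = target, basis = basis, xgrad = xgrad)
    cache[[key]] <<- g
    g
  }
})

#' Render one synthetic brain volume
#'
#' An ellipsoidal "brain" on an isotropic grid with an interior target region
#' whose mean intensity decreases linearly in severity for MRI (atrophy
#' surrogate) and increases for PET (tracer uptake). The per-site affine
#' intensity transform (`siteScale`, `siteShift`) and i.i.d. Gaussian noise are
#' applied inside the mask; voxels outside are zero. MRI and PET share the
#' grid and mask, so paired volumes are co-registered by construction. Draws
#' come from the current RNG state (seed it for determinism).
#'
#' @param severity latent severity at the visit.
#' @param modality `"MRI"` or `"PET"`.
#' @param config a [cohortConfig()].
#' @param siteId site label (must be one of the configured sites).
#' @param subjectId,visitTime annotations stored on the volume.
#' @param anatomy optional length-9 coefficient vector of the subject's
#'   anatomy field (drawn once per subject by [generateCohort()]); `NULL`
#'   renders the anatomy-free average brain.
#' @return A [BrainVolume-class].
#' @export
renderVolume <- function(severity, modality = c("MRI", "PET"), config,
                         siteId = "site01", subjectId = NA_character_,
                         visitTime = 0, anatomy = NULL) {
  modality <- match.arg(modality)
  checkCohortConfig(config)
  siteIdx <- match(siteId, sprintf("site%02d", seq_len(config$nSites)))
  if (is.na(siteIdx))
    stop(sprintf("unknown site '%s' for this configuration", siteId),
         call. = FALSE)
  g <- cohortGeometry(config$gridSize)
  targetMean <- if (modality == "MRI") {
    config$mriHealthy + config$mriSlope * severity
  } else {
    config$petHealthy + config$petSlope * severity
  }
  dat <- array(0, dim(g$mask))
  dat[g$mask] <- config$background[[modality]]
  dat[g$target] <- targetMean
  if (!is.null(anatomy) && config$anatomySd > 0) {
    stopifnot(length(anatomy) == 9L)
    field <- Reduce(`+`, Map(function(b, cf) b * cf, g$basis,
                             as.numeric(anatomy)))
    dat[g$mask] <- dat[g$mask] +
      config$anatomySd * config$anatomyScale[[modality]] *
      field[g$mask] / sqrt(9)
  }
  dat[g$mask] <- dat[g$mask] * config$siteScale[siteIdx] +
    config$siteShift[siteIdx]
  if (config$siteGradient[siteIdx] != 0)
    dat[g$mask] <- dat[g$mask] + config$siteGradient[siteIdx] *
      g$xgrad[g$mask]
  if (config$noiseSd > 0)
    dat[g$mask] <- dat[g$mask] + rnorm(sum(g$mask), 0, config$noiseSd)
  brainVolume(dat, mask = g$mask, spacing = rep(160 / config$gridSize, 3),
              modality = modality, subjectId = subjectId,
              visitTime = visitTime, siteId = siteId)
}

#' Mean intensity of the generative target region
#'
#' Convenience accessor used by validity checks: the mean intensity within the
#' interior target region of a rendered volume.
#'
#' @param v a [BrainVolume-class] on the generator's grid.
#' @return scalar mean.
#' @export
targetRegionMean <- function(v) {
  g <- cohortGeometry(dim(v@data)[1])
  mean(v@data[g$target])
}

#' Write a cohort to disk (NIfTI volumes + CSV tables + JSON manifest)
#'
#' One gzipped NIfTI file per subject-visit-modality (RAS orientation, float32
#' storage), `visits.csv`, `subjects.csv`, and `manifest.json` listing the
#' files with a configuration echo. Volumes containing non-finite voxels are
#' rejected before serialization.
#'
#' @param cohort an [ImagingCohort-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "ImagingCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort@volumes)) {
    v <- cohort@volumes[[key]]
    if (!all(is.finite(v@data)))
      stop(sprintf("volume '%s' contains non-finite voxels; refusing to serialize", key),
           call. = FALSE)
  }
  files <- character(0)
  for (key in names(cohort@volumes)) {
    v <- cohort@volumes[[key]]
    fn <- paste0(gsub("[|]", "_", key), ".nii.gz")
    img <- RNifti::asNifti(v@data, pixdim = v@spacing, datatype = "float")
    RNifti::writeNifti(img, file.path(dir, fn))
    files[key] <- fn
  }
  # one shared mask per grid (co-registration by construction)
  if (length(cohort@volumes)) {
    m <- cohort@volumes[[1]]@mask
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(m), dim(m))),
                       file.path(dir, "brain_mask.nii.gz"))
  }
  write.csv(cohort@visits, file.path(dir, "visits.csv"), row.names = FALSE)
  write.csv(cohort@subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  manifest <- list(
    format = "neurossl-cohort-v1",
    files = as.list(files),
    mask = if (length(cohort@volumes)) "brain_mask.nii.gz" else NULL,
    config = cohort@config
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return An [ImagingCohort-class]; read-then-write is the identity on data,
#'   mask and table fields up to float32 storage precision.
#' @export
readCohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp))
    stop(sprintf("no manifest.json in '%s'", dir), call. = FALSE)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  visits <- read.csv(file.path(dir, "visits.csv"), stringsAsFactors = FALSE)
  subjects <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  mask <- NULL
  if (!is.null(manifest$mask)) {
    mask <- as.array(RNifti::readNifti(file.path(dir, manifest$mask))) > 0.5
  }
  volumes <- list()
  for (key in names(manifest$files)) {
    fn <- file.path(dir, manifest$files[[key]])
    if (!file.exists(fn))
      stop(sprintf("missing volume file for '%s' (%s)", key,
                   manifest$files[[key]]), call. = FALSE)
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    img <- RNifti::readNifti(fn)
    dat <- array(as.numeric(img), dim(img))
    if (!is.null(mask) && !identical(dim(dat), dim(mask)))
      stop(sprintf("volume '%s' shape disagrees with the manifest mask", key),
           call. = FALSE)
    volumes[[key]] <- brainVolume(
      dat, mask = mask %||% array(dat != 0, dim(dat)),
      spacing = RNifti::pixdim(img)[1:3],
      modality = parts[3], subjectId = parts[1],
      visitTime = as.numeric(parts[2]), siteId = NA_character_
    )
    volumes[[key]]@siteId <-
      visits$site_id[match(parts[1], visits$subject_id)]
  }
  cfg <- manifest$config
  new("ImagingCohort", visits = visits, subjects = subjects,
      volumes = volumes, config = as.list(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
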