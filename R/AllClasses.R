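#' @import methods
#' @importFrom stats approx coef cor cov glm lm median optimize plogis pnorm
#'   qnorm quantile rbinom rexp rnorm runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

#' BrainVolume: one 3D intensity grid for one subject-visit-modality
#'
#' A minimal volumetric container: a 3D numeric array, a boolean brain mask of
#' the same shape, voxel spacing in millimetres, a modality tag
#' (`"MRI"` or `"PET"`), and the subject/visit/site annotations that the
#' training and harmonization stages key on. Paired MRI/PET volumes of a visit
#' are co-registered by construction: they share grid shape, spacing, and mask.
#'
#' @slot data 3D numeric array of intensities; finite everywhere.
#' @slot mask 3D logical array, same shape as `data`; nonempty.
#' @slot spacing numeric length-3, voxel edge length in mm per axis.
#' @slot modality `"MRI"` or `"PET"`.
#' @slot subjectId,visitTime,siteId annotations (visit time in months).
#' @exportClass BrainVolume
setClass("BrainVolume",
  representation(
    data = "array", mask = "array", spacing = "numeric",
    modality = "character", subjectId = "character",
    visitTime = "numeric", siteId = "character"
  )
)

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "'data' must be a 3D array")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "'data' must be finite everywhere")
  if (!identical(dim(object@data), dim(object@mask)))
    msg <- c(msg, "'mask' must have the same shape as 'data'")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (!any(object@mask))
    msg <- c(msg, "'mask' must be nonempty")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive numbers")
  if (!object@modality %in% c("MRI", "PET"))
    msg <- c(msg, "'modality' must be 'MRI' or 'PET'")
  if (length(msg)) msg else TRUE
})

#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param mask 3D logical array, same shape; defaults to `data != 0`.
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @param modality `"MRI"` or `"PET"`.
#' @param subjectId,visitTime,siteId annotations.
#' @return A [BrainVolume-class] object.
#' @export
brainVolume <- function(data, mask = NULL, spacing = c(1, 1, 1),
                        modality = "MRI", subjectId = NA_character_,
                        visitTime = NA_real_, siteId = NA_character_) {
  if (is.null(mask)) mask <- array(data != 0, dim(data))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("BrainVolume",
    data = data, mask = mask, spacing = as.numeric(spacing),
    modality = modality, subjectId = as.character(subjectId),
    visitTime = as.numeric(visitTime), siteId = as.character(siteId)
  )
}

#' @describeIn BrainVolume-class voxel intensity array
#' @param object,x a `BrainVolume`
#' @export
voxelData <- function(x) x@data

#' @describeIn BrainVolume-class brain mask array
#' @export
brainMask <- function(x) x@mask

#' @describeIn BrainVolume-class voxel spacing (mm)
#' @export
voxelSpacing <- function(x) x@spacing

#' @describeIn BrainVolume-class modality tag
#' @export
modality <- function(x) x@modality

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "BrainVolume [%s] %dx%dx%d voxels, %d in mask\n  subject %s, visit %s mo, site %s\n",
    object@modality, d[1], d[2], d[3], sum(object@mask),
    object@subjectId, format(object@visitTime), object@siteId
  ))
})

#' ImagingCohort: a multi-site, longitudinal, two-modality cohort
#'
#' Holds the per-visit table (subject, visit time, site, covariates, diagnosis,
#' modality availability), the per-subject survival outcomes (time to
#' conversion in months and the event indicator), and the rendered volumes
#' keyed `"<subject>|<visit>|<modality>"`. Synthetic cohorts additionally carry
#' the latent ground truth (severity, slopes) that downstream validity checks
#' rely on.
#'
#' @slot visits data.frame with columns `subject_id, visit_time_months,
#'   site_id, age, sex, diagnosis, has_mri, has_pet` (plus `severity` for
#'   synthetic cohorts).
#' @slot subjects data.frame with one row per subject: `subject_id, site_id,
#'   age, sex, T_months, event` (plus latent truth for synthetic cohorts).
#' @slot volumes named list of [BrainVolume-class] objects.
#' @slot config list; the generating configuration (echoed for provenance).
#' @exportClass ImagingCohort
setClass("ImagingCohort",
  representation(
    visits = "data.frame", subjects = "data.frame",
    volumes = "list", config = "list"
  )
)

setValidity("ImagingCohort", function(object) {
  msg <- character()
  need <- c("subject_id", "visit_time_months", "site_id", "age", "sex",
            "diagnosis", "has_mri", "has_pet")
  miss <- setdiff(need, names(object@visits))
  if (length(miss))
    msg <- c(msg, paste("visits table missing columns:",
                        paste(miss, collapse = ", ")))
  needS <- c("subject_id", "site_id", "T_months", "event")
  missS <- setdiff(needS, names(object@subjects))
  if (length(missS))
    msg <- c(msg, paste("subjects table missing columns:",
                        paste(missS, collapse = ", ")))
  if (!all(object@visits$subject_id %in% object@subjects$subject_id))
    msg <- c(msg, "every visit must belong to a known subject")
  if (length(object@volumes) &&
      !all(vapply(object@volumes, is, TRUE, "BrainVolume")))
    msg <- c(msg, "all volumes must be BrainVolume objects")
  if (length(msg)) msg else TRUE
})

#' @describeIn ImagingCohort-class per-visit table
#' @param x an `ImagingCohort`
#' @export
visitTable <- function(x) x@visits

#' @describeIn ImagingCohort-class per-subject table with survival outcomes
#' @export
subjectTable <- function(x) x@subjects

#' @describeIn ImagingCohort-class named list of volumes
#' @export
cohortVolumes <- function(x) x@volumes

#' @describeIn ImagingCohort-class fetch one volume (NULL if absent)
#' @param subjectId,visitTime,modality volume key
#' @export
getVolume <- function(x, subjectId, visitTime, modality) {
  x@volumes[[volumeKey(subjectId, visitTime, modality)]]
}

volumeKey <- function(subjectId, visitTime, modality) {
  sprintf("%s|%g|%s", subjectId, visitTime, modality)
}

setMethod("show", "ImagingCohort", function(object) {
  v <- object@visits
  cat(sprintf(
    "ImagingCohort: %d subjects, %d visits, %d sites, %d volumes\n",
    nrow(object@subjects), nrow(v), length(unique(v$site_id)),
    length(object@volumes)
  ))
  cat(sprintf("  PET available at %d/%d visits; %d/%d subjects converted\n",
              sum(v$has_pet), nrow(v), sum(object@subjects$event),
              nrow(object@subjects)))
})

#' ReferenceTemplate: quantile template for histogram matching
#'
#' Sorted within-mask intensity quantiles from a designated reference set of
#' volumes of one modality. [histogramMatch()] maps any volume onto these
#' quantiles by a monotone piecewise-linear transfer.
#'
#' @slot probs strictly increasing probabilities in `[0, 1]`.
#' @slot values non-decreasing intensity values at those probabilities.
#' @slot modality modality tag the template was built from.
#' @slot fitSubjects subject ids the template was fitted on (leakage audit).
#' @exportClass ReferenceTemplate
setClass("ReferenceTemplate",
  representation(probs = "numeric", values = "numeric",
                 modality = "character", fitSubjects = "character")
)

setValidity("ReferenceTemplate", function(object) {
  msg <- character()
  p <- object@probs
  if (length(p) < 2L || any(diff(p) <= 0) || min(p) < 0 || max(p) > 1)
    msg <- c(msg, "'probs' must be strictly increasing within [0, 1]")
  if (length(object@values) != length(p))
    msg <- c(msg, "'values' must align with 'probs'")
  if (any(diff(object@values) < 0))
    msg <- c(msg, "'values' must be non-decreasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceTemplate", function(object) {
  cat(sprintf(
    "ReferenceTemplate [%s]: %d quantile knots on [%.3g, %.3g], %d fitting subjects\n",
    object@modality, length(object@probs), min(object@values),
    max(object@values), length(object@fitSubjects)
  ))
})

#' CombatModel: empirical-Bayes location/scale site-effect model
#'
#' The standard ComBat formulation: feature-wise grand mean and covariate
#' coefficients, per-site additive effects gamma and multiplicative effects
#' delta^2 after empirical-Bayes shrinkage, and the feature-wise pooled
#' variance. Fitted once on training samples and applied identically to any
#' sample from a fitted site, so all timepoints of a subject receive the same
#' transform.
#'
#' @slot grandMean numeric, per-feature grand mean (site-size weighted).
#' @slot beta covariate coefficient matrix (q x p), possibly 0-row.
#' @slot gammaStar,delta2Star site x feature matrices of shrunken effects.
#' @slot pooledVar per-feature pooled variance.
#' @slot sites fitted site labels (row order of the effect matrices).
#' @slot covariateNames names of fitted covariate columns.
#' @slot covariateCenter centering applied to covariates at fit time.
#' @slot fitSubjects subject ids used at fit time (leakage audit).
#' @exportClass CombatModel
setClass("CombatModel",
  representation(
    grandMean = "numeric", beta = "matrix", gammaStar = "matrix",
    delta2Star = "matrix", pooledVar = "numeric", sites = "character",
    covariateNames = "character", covariateCenter = "numeric",
    fitSubjects = "character"
  )
)

setValidity("CombatModel", function(object) {
  msg <- character()
  if (any(object@delta2Star <= 0))
    msg <- c(msg, "'delta2Star' must be positive everywhere")
  if (nrow(object@gammaStar) != length(object@sites) ||
      nrow(object@delta2Star) != length(object@sites))
    msg <- c(msg, "site-effect matrices must have one row per fitted site")
  if (any(object@pooledVar <= 0))
    msg <- c(msg, "'pooledVar' must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CombatModel", function(object) {
  cat(sprintf(
    "CombatModel: %d sites x %d features, covariates [%s], %d fitting subjects\n",
    length(object@sites), length(object@grandMean),
    paste(object@covariateNames, collapse = ", "), length(object@fitSubjects)
  ))
})

#' EmbeddingSet: a batch of unit-norm embeddings with annotations
#'
#' Rows of `z` are l2-normalized d-vectors produced by an encoder and
#' projection head; `info` carries the subject/visit/modality/site annotation
#' each loss groups on.
#'
#' @slot z numeric matrix (n x d), rows unit-norm within 1e-5.
#' @slot info data.frame with columns `subject_id, visit_time, modality,
#'   site_id` aligned with the rows of `z`.
#' @exportClass EmbeddingSet
setClass("EmbeddingSet",
  representation(z = "matrix", info = "data.frame")
)

setValidity("EmbeddingSet", function(object) {
  msg <- character()
  if (nrow(object@z) != nrow(object@info))
    msg <- c(msg, "'info' must align with rows of 'z'")
  need <- c("subject_id", "visit_time", "modality", "site_id")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("'info' must contain", paste(need, collapse = ", ")))
  if (nrow(object@z)) {
    nrm <- sqrt(rowSums(object@z^2))
    if (any(abs(nrm - 1) > 1e-5))
      msg <- c(msg, "rows of 'z' must be unit-norm within 1e-5")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn EmbeddingSet-class the embedding matrix
#' @param x an `EmbeddingSet`
#' @export
embeddingMatrix <- function(x) x@z

#' @describeIn EmbeddingSet-class the annotation table
#' @export
embeddingInfo <- function(x) x@info

setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet: %d embeddings of dimension %d (%s)\n",
              nrow(object@z), ncol(object@z),
              paste(unique(object@info$modality), collapse = "+")))
})

#' SSLModel: modality-specific encoders plus SSL auxiliaries
#'
#' Bundles the two disjoint encoder parameter sets (MRI and PET), the shared
#' architecture spec, the BYOL predictor, the site discriminator, the momentum
#' (key) encoders, and the per-modality MoCo queues. Produced by
#' [newSSLModel()] or [pretrainSSL()].
#'
#' @slot spec encoder architecture description (see [encoderSpec()]).
#' @slot params list with elements `mri`, `pet`, `predictor`, `discriminator`.
#' @slot keyParams momentum copies of `mri`/`pet` encoder parameters.
#' @slot queues per-modality MoCo queues.
#' @slot sites site labels the discriminator was built over.
#' @slot config training configuration echo.
#' @exportClass SSLModel
setClass("SSLModel",
  representation(spec = "list", params = "list", keyParams = "list",
                 queues = "list", sites = "character", config = "list")
)

setMethod("show", "SSLModel", function(object) {
  cat(sprintf(
    "SSLModel: grid %d^3, widths [%s], d=%d, norm=%s; %d sites; queue %d/%d\n",
    object@spec$gridSize, paste(object@spec$widths, collapse = "/"),
    object@spec$dim, object@spec$norm, length(object@sites),
    if (length(object@queues)) object@queues[[1]]$size else 0L,
    if (length(object@queues)) object@queues[[1]]$capacity else 0L
  ))
})

#' FinetunedModel: encoders plus fusion gate, task heads and calibration
#'
#' The stage-2 artifact: fine-tuned encoders, the availability-conditioned
#' fusion gate, diagnosis and Cox risk heads, the post-hoc temperature, the
#' covariate standardization fitted on the training fold, and the subject
#' fingerprints of every training-stage input (for the no-leakage audit).
#'
#' @slot spec encoder spec; @slot params full parameter list (encoders, gate,
#'   heads); @slot temperature fitted softmax temperature; @slot classes
#'   diagnosis class labels; @slot covariateStats centering/scaling of
#'   clinical covariates; @slot trainSubjects,validSubjects subject ids seen
#'   during fine-tuning / temperature fitting; @slot config echo.
#' @exportClass FinetunedModel
setClass("FinetunedModel",
  representation(
    spec = "list", params = "list", temperature = "numeric",
    classes = "character", covariateStats = "list",
    trainSubjects = "character", validSubjects = "character", config = "list"
  )
)

setMethod("show", "FinetunedModel", function(object) {
  cat(sprintf(
    "FinetunedModel: %d classes [%s], T=%.3f, %d train / %d validation subjects\n",
    length(object@classes), paste(object@classes, collapse = ", "),
    object@temperature, length(object@trainSubjects),
    length(object@validSubjects)
  ))
})
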