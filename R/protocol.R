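# Reproducible procedure: leakage-free subject-level splits, the stage-1
# pretraining loop, linear-probe checkpoint selection, the stage-2
# fine-tuning loop with early stopping and post-hoc calibration, evaluation
# with bootstrap CIs, cross-cohort transfer, cross-validation with a
# programmatic no-leakage audit, and the ablation runner.

#' Subject-level stratified k-fold split plan
#'
#' Every subject lands in exactly one test fold, all visits of a subject
#' share its fold (no subject or visit leakage), and folds balance the
#' stratification keys (site and baseline diagnosis by default) by greedy
#' round-robin within strata. Deterministic given `seed`.
#'
#' @param cohort an [ImagingCohort-class] (or a visits data.frame).
#' @param k number of folds (default 5).
#' @param stratifyKeys visit-table columns to stratify on.
#' @param seed integer seed.
#' @return list of class `"splitPlan"` with `assignment` (subject_id, fold),
#'   `k`, `seed`.
#' @export
makeSplits <- function(cohort, k = 5L, stratifyKeys = c("site_id", "diagnosis"),
                       seed = 1L) {
  visits <- if (is(cohort, "ImagingCohort")) cohort@visits else cohort
  base <- visits[!duplicated(visits$subject_id), , drop = FALSE]
  if (k > nrow(base))
    stop("more folds than subjects", call. = FALSE)
  set.seed(seed)
  strat <- do.call(paste, c(base[, intersect(stratifyKeys, names(base)),
                                 drop = FALSE], sep = "|"))
  fold <- integer(nrow(base))
  nxt <- sample.int(k, 1L)  # rotate the starting fold between strata
  for (s in unique(strat)) {
    ix <- which(strat == s)
    ix <- ix[sample.int(length(ix))]
    for (i in seq_along(ix)) {
      fold[ix[i]] <- ((nxt - 1L) %% k) + 1L
      nxt <- nxt + 1L
    }
  }
  plan <- list(assignment = data.frame(subject_id = base$subject_id,
                                       fold = fold,
                                       stringsAsFactors = FALSE),
               k = as.integer(k), seed = as.integer(seed),
               stratifyKeys = stratifyKeys)
  class(plan) <- "splitPlan"
  plan
}

#' @export
print.splitPlan <- function(x, ...) {
  cat(sprintf("splitPlan: %d subjects in %d folds (seed %d)\n",
              nrow(x$assignment), x$k, x$seed))
  print(table(x$assignment$fold))
  invisible(x)
}

#' Linear probe on frozen embeddings
#'
#' Trains a ridge-regularized logistic separator (fixed small penalty) on the
#' probe-train rows and scores balanced accuracy on the probe-validation
#' rows. The encoder is untouched: the probe sees only the embedding matrix.
#' Used to rank SSL checkpoints and to measure residual site information.
#'
#' @param z embedding matrix (n x d).
#' @param labels factor/character labels.
#' @param trainIdx,validIdx row indices.
#' @param lambda fixed ridge penalty (default 0.01).
#' @return list with `bac`, `accuracy`, `predicted`.
#' @export
linearProbe <- function(z, labels, trainIdx, validIdx, lambda = 0.01) {
  labels <- factor(labels)
  ytr <- droplevels(labels[trainIdx])
  if (nlevels(ytr) < 2L)
    stop("probe training set contains a single class", call. = FALSE)
  fam <- if (nlevels(ytr) == 2L) "binomial" else "multinomial"
  # desk-scale probe sets can have small classes; glmnet warns but fits
  fit <- suppressWarnings(
    glmnet::glmnet(z[trainIdx, , drop = FALSE], ytr, family = fam,
                   alpha = 0, lambda = lambda, standardize = FALSE))
  pred <- predict(fit, z[validIdx, , drop = FALSE], type = "class")
  pred <- as.character(pred[, 1])
  truth <- as.character(labels[validIdx])
  list(bac = balancedAccuracy(truth, pred),
       accuracy = mean(truth == pred), predicted = pred)
}

#' @importFrom stats predict
NULL

#' Stage-1 SSL pretraining configuration
#'
#' @param epochs training epochs.
#' @param stepsPerEpoch optimizer steps per epoch (default: enough to visit
#'   each subject about once).
#' @param batchSubjects subjects per batch; up to two visits per subject are
#'   drawn so longitudinal pairs appear inside batches.
#' @param weights an [sslWeights()].
#' @param policy an [augmentationPolicy()].
#' @param spec an [encoderSpec()].
#' @param queueSize MoCo queue capacity per modality.
#' @param momentum key-encoder EMA coefficient (0.9 at desk scale: with few
#'   optimizer steps a slower EMA would leave the key encoder at its
#'   initialization).
#' @param lr,weightDecay AdamW settings (cosine-decayed learning rate).
#' @param discSteps extra discriminator-only gradient steps per batch, so the
#'   site discriminator stays near-optimal and the reversed gradient points
#'   at real site information (the usual alternating schedule in
#'   domain-adversarial training).
#' @param checkpointEvery snapshot cadence in epochs (0 = final only).
#' @param seed integer seed.
#' @return list of class `"sslConfig"`.
#' @export
sslConfig <- function(epochs = 10L, stepsPerEpoch = NULL, batchSubjects = 16L,
                      weights = sslWeights(), policy = augmentationPolicy(),
                      spec = encoderSpec(), queueSize = 256L,
                      momentum = 0.9, lr = 1e-3, weightDecay = 1e-4,
                      discSteps = 5L, checkpointEvery = 0L, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), stepsPerEpoch = stepsPerEpoch,
              batchSubjects = as.integer(batchSubjects), weights = weights,
              policy = policy, spec = spec, queueSize = as.integer(queueSize),
              momentum = momentum, lr = lr, weightDecay = weightDecay,
              discSteps = as.integer(discSteps),
              checkpointEvery = as.integer(checkpointEvery),
              seed = as.integer(seed))
  class(cfg) <- "sslConfig"
  cfg
}

# site-aware subject sampling: cycle sites so every batch sees >= 2 sites
# whenever the pool does
sampleBatchSubjects <- function(subjects, sites, nPick) {
  bySite <- split(subjects, sites)
  bySite <- lapply(bySite, function(s) s[sample.int(length(s))])
  out <- character(0)
  i <- 1L
  while (length(out) < nPick && any(lengths(bySite) > 0)) {
    for (s in seq_along(bySite)) {
      if (length(out) >= nPick) break
      if (length(bySite[[s]])) {
        out <- c(out, bySite[[s]][1])
        bySite[[s]] <- bySite[[s]][-1]
      }
    }
    i <- i + 1L
  }
  out
}

#' Stage-1 self-supervised pretraining
#'
#' Runs the full SSL objective on a cohort: per step, a site-aware batch of
#' subjects (up to two visits each) is augmented into two views per modality;
#' the online encoders process view 1, the momentum (key) encoders view 2;
#' intra-modal InfoNCE (keys + MoCo queue as candidates), symmetric
#' cross-modal InfoNCE over paired MRI-PET visits, BYOL regression onto the
#' key targets, longitudinal and cross-time cross-modal consistency within
#' the batch, and the gradient-reversed site-adversarial term are combined by
#' the configured weights into one AdamW update (cosine-decayed learning
#' rate); key encoders then take an EMA step and the keys enter the queues.
#' The longitudinal terms auto-disable (reported as exactly 0 and flagged)
#' when no subject has two visits.
#'
#' @param cohort a harmonized [ImagingCohort-class] with volumes.
#' @param config an [sslConfig()].
#' @param subjects subject ids to train on (default: all) — the SSL stage
#'   records them for the leakage audit.
#' @return list with `model` ([SSLModel-class]), `history` (per-epoch mean
#'   component losses), `checkpoints` (list of SSLModel snapshots),
#'   `longitudinalEnabled`, and `subjects`.
#' @export
pretrainSSL <- function(cohort, config = sslConfig(), subjects = NULL) {
  stopifnot(is(cohort, "ImagingCohort"), inherits(config, "sslConfig"))
  visits <- cohort@visits
  subjects <- subjects %||% unique(visits$subject_id)
  visits <- visits[visits$subject_id %in% subjects, , drop = FALSE]
  sites <- sort(unique(cohort@visits$site_id))
  w <- config$weights
  set.seed(config$seed)
  model <- newSSLModel(structure(config$spec, class = "encoderSpec"),
                       sites, config$queueSize,
                       seed = config$seed)
  params <- model@params
  keyParams <- model@keyParams
  queues <- model@queues
  opt <- adamwInit(params)
  vpc <- table(visits$subject_id)
  longEnabled <- any(vpc >= 2L)
  subjSite <- visits$site_id[match(unique(visits$subject_id),
                                   visits$subject_id)]
  subjPool <- unique(visits$subject_id)
  steps <- config$stepsPerEpoch %||%
    max(1L, ceiling(length(subjPool) / config$batchSubjects))
  totalSteps <- config$epochs * steps
  history <- NULL
  checkpoints <- list()
  stepNo <- 0L

  for (epoch in seq_len(config$epochs)) {
    acc <- c(intra = 0, cross = 0, byol = 0, long = 0, longx = 0,
             site = 0, total = 0)
    for (st in seq_len(steps)) {
      stepNo <- stepNo + 1L
      batchSub <- sampleBatchSubjects(subjPool, subjSite,
                                      min(config$batchSubjects,
                                          length(subjPool)))
      items <- do.call(rbind, lapply(batchSub, function(s) {
        vs <- visits[visits$subject_id == s, , drop = FALSE]
        vs[sample.int(nrow(vs), min(2L, nrow(vs))), , drop = FALSE]
      }))
      n <- nrow(items)
      mriV1 <- vector("list", n); mriV2 <- vector("list", n)
      petV1 <- list(); petV2 <- list(); petRow <- integer(0)
      for (r in seq_len(n)) {
        vm <- getVolume(cohort, items$subject_id[r],
                        items$visit_time_months[r], "MRI")
        mriV1[[r]] <- augmentVolume(vm, config$policy)
        mriV2[[r]] <- augmentVolume(vm, config$policy)
        if (items$has_pet[r]) {
          vp <- getVolume(cohort, items$subject_id[r],
                          items$visit_time_months[r], "PET")
          if (!is.null(vp)) {
            petV1 <- c(petV1, list(augmentVolume(vp, config$policy)))
            petV2 <- c(petV2, list(augmentVolume(vp, config$policy)))
            petRow <- c(petRow, r)
          }
        }
      }
      spec <- structure(config$spec, class = "encoderSpec")
      siteIdxM <- match(items$site_id, sites)
      fwM <- encoderForward(volumesToMatrix(mriV1), params$mri, spec, n,
                            siteIdx = siteIdxM, train = TRUE)
      params$mri <- fwM$params
      kM <- encoderForward(volumesToMatrix(mriV2), keyParams$mri, spec, n,
                           siteIdx = siteIdxM, train = FALSE)$z
      nP <- length(petRow)
      if (nP > 0) {
        siteIdxP <- siteIdxM[petRow]
        fwP <- encoderForward(volumesToMatrix(petV1), params$pet, spec, nP,
                              siteIdx = siteIdxP, train = TRUE)
        params$pet <- fwP$params
        kP <- encoderForward(volumesToMatrix(petV2), keyParams$pet, spec, nP,
                             siteIdx = siteIdxP, train = FALSE)$z
      }
      zM <- fwM$z
      zP <- if (nP > 0) fwP$z else NULL
      dzM <- zM * 0
      dzP <- if (nP > 0) zP * 0 else NULL
      comp <- c(intra = 0, cross = 0, byol = 0, long = 0, longx = 0,
                site = 0)
      gPred <- NULL; gDisc <- NULL

      # intra-modal InfoNCE (keys are stop-gradient targets)
      li <- intraModalInfoNCE(zM, kM, queues$MRI, w$tau)
      comp["intra"] <- li$value
      dzM <- dzM + w$intra * li$gradAnchors
      if (nP >= 2) {
        lp <- intraModalInfoNCE(zP, kP, queues$PET, w$tau)
        comp["intra"] <- comp["intra"] + lp$value
        dzP <- dzP + w$intra * lp$gradAnchors
      }
      # cross-modal InfoNCE on paired visits
      if (nP >= 2) {
        lc <- crossModalInfoNCE(zM[petRow, , drop = FALSE], zP,
                                queues$MRI, queues$PET, w$tau)
        comp["cross"] <- lc$value
        dzM[petRow, ] <- dzM[petRow, ] + w$cross * lc$gradMri
        dzP <- dzP + w$cross * lc$gradPet
      }
      # BYOL regression onto key targets
      lb <- byolLoss(zM, kM, params$predictor)
      comp["byol"] <- lb$value
      dzM <- dzM + w$byol * lb$gradOnline
      gPred <- mapParams(function(g) w$byol * g, lb$gradPredictor)
      if (nP > 0) {
        lbp <- byolLoss(zP, kP, params$predictor)
        comp["byol"] <- comp["byol"] + lbp$value
        dzP <- dzP + w$byol * lbp$gradOnline
        gPred <- mapParams(`+`, gPred,
                           mapParams(function(g) w$byol * g,
                                     lbp$gradPredictor))
      }
      # longitudinal terms (within-batch)
      if (longEnabled) {
        allZ <- rbind(zM, if (nP > 0) zP)
        sub <- c(items$subject_id, items$subject_id[petRow])
        tim <- c(items$visit_time_months, items$visit_time_months[petRow])
        mod <- c(rep("MRI", n), rep("PET", nP))
        ll <- longitudinalConsistency(allZ, sub, tim, mod)
        lx <- crossTimeCrossModal(allZ, sub, tim, mod)
        comp["long"] <- ll$value; comp["longx"] <- lx$value
        dAll <- w$long * ll$grad + w$longx * lx$grad
        dzM <- dzM + dAll[seq_len(n), , drop = FALSE]
        if (nP > 0) dzP <- dzP + dAll[n + seq_len(nP), , drop = FALSE]
      }
      # site-adversarial with gradient reversal; the discriminator always
      # trains (it is the monitor), the reversed gradient reaches the
      # encoder only when the site weight is on
      allZ <- rbind(zM, if (nP > 0) zP)
      siteAll <- c(siteIdxM, if (nP > 0) siteIdxM[petRow])
      ls <- siteAdversarialLoss(allZ, siteAll, params$discriminator,
                                w$grlStrength)
      comp["site"] <- ls$value
      gDisc <- ls$gradDiscriminator
      if (w$site > 0) {
        dzM <- dzM + w$site * ls$gradEncoder[seq_len(n), , drop = FALSE]
        if (nP > 0)
          dzP <- dzP + w$site * ls$gradEncoder[n + seq_len(nP), ,
                                               drop = FALSE]
      }

      grads <- list(
        mri = encoderBackward(dzM, params$mri, spec, fwM$cache),
        pet = if (nP > 0) encoderBackward(dzP, params$pet, spec, fwP$cache)
              else zeroLike(params$pet),
        predictor = gPred %||% zeroLike(params$predictor),
        discriminator = gDisc %||% zeroLike(params$discriminator)
      )
      lrNow <- cosineLR(config$lr, stepNo, totalSteps)
      upd <- adamwStep(params, grads, opt, lr = lrNow,
                       weightDecay = config$weightDecay)
      params <- upd$params; opt <- upd$state
      keyParams$mri <- momentumUpdate(keyParams$mri, params$mri,
                                      config$momentum)
      keyParams$pet <- momentumUpdate(keyParams$pet, params$pet,
                                      config$momentum)
      # keep the discriminator near-optimal on the current embeddings
      if (config$discSteps > 0L) {
        for (j in seq_len(config$discSteps)) {
          lsd <- siteAdversarialLoss(allZ, siteAll, params$discriminator, 0)
          params$discriminator$W <- params$discriminator$W -
            0.5 * lsd$gradDiscriminator$W
          params$discriminator$b <- params$discriminator$b -
            0.5 * lsd$gradDiscriminator$b
        }
      }
      queues$MRI <- queuePush(queues$MRI, kM)
      if (nP > 0) queues$PET <- queuePush(queues$PET, kP)

      rep <- totalSslLoss(comp, w)
      acc <- acc + c(comp, total = rep$total) / steps
    }
    history <- rbind(history, data.frame(epoch = epoch, t(acc)))
    if (config$checkpointEvery > 0 && epoch %% config$checkpointEvery == 0) {
      checkpoints[[length(checkpoints) + 1L]] <-
        buildSSLModel(model, params, keyParams, queues, config, subjects)
    }
  }
  final <- buildSSLModel(model, params, keyParams, queues, config, subjects)
  checkpoints[[length(checkpoints) + 1L]] <- final
  list(model = final, history = history, checkpoints = checkpoints,
       longitudinalEnabled = longEnabled, subjects = sort(unique(subjects)))
}

buildSSLModel <- function(model, params, keyParams, queues, config,
                          subjects) {
  initialize(model, params = params, keyParams = keyParams, queues = queues,
             config = list(seed = config$seed,
                           trainSubjects = sort(unique(subjects))))
}

#' Stage-2 fine-tuning configuration
#'
#' @param epochs maximum epochs.
#' @param batchSize visits per minibatch (Cox risk sets form within batch
#'   over its baseline visits).
#' @param lr,weightDecay AdamW settings.
#' @param coefficients `(alpha, beta, gamma)` of the joint objective.
#' @param patience early-stopping patience (epochs) on the monitored
#'   validation metrics (balanced accuracy and C-index).
#' @param freezeEncoders if `TRUE` only the gate and heads train.
#' @param seed integer seed.
#' @return list of class `"ftConfig"`.
#' @export
ftConfig <- function(epochs = 20L, batchSize = 24L, lr = 3e-4,
                     weightDecay = 1e-4, coefficients = c(1, 1, 0.5),
                     patience = 10L, freezeEncoders = FALSE, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              lr = lr, weightDecay = weightDecay,
              coefficients = coefficients, patience = as.integer(patience),
              freezeEncoders = isTRUE(freezeEncoders), seed = as.integer(seed))
  class(cfg) <- "ftConfig"
  cfg
}

buildCovariates <- function(visits, stats = NULL) {
  age <- visits$age
  sex <- as.numeric(visits$sex == "M")
  if (is.null(stats))
    stats <- list(ageMean = mean(age), ageSd = max(sd(age), 1e-8))
  cbindOut <- cbind(age = (age - stats$ageMean) / stats$ageSd, sex = sex)
  list(mat = cbindOut, stats = stats)
}

ftForwardBatch <- function(items, cohort, params, spec, sites, covStats,
                           classes, train = TRUE) {
  n <- nrow(items)
  volsM <- lapply(seq_len(n), function(r)
    getVolume(cohort, items$subject_id[r], items$visit_time_months[r], "MRI"))
  siteIdx <- match(items$site_id, sites)
  fwM <- encoderForward(volumesToMatrix(volsM), params$mri, spec, n,
                        siteIdx = siteIdx, train = train)
  petRow <- which(items$has_pet &
                  vapply(seq_len(n), function(r)
                    !is.null(getVolume(cohort, items$subject_id[r],
                                       items$visit_time_months[r], "PET")),
                    TRUE))
  zP <- matrix(0, n, ncol(fwM$z))
  fwP <- NULL
  if (length(petRow)) {
    volsP <- lapply(petRow, function(r)
      getVolume(cohort, items$subject_id[r], items$visit_time_months[r],
                "PET"))
    fwP <- encoderForward(volumesToMatrix(volsP), params$pet, spec,
                          length(petRow), siteIdx = siteIdx[petRow],
                          train = train)
    zP[petRow, ] <- fwP$z
  }
  ind <- cbind(mri = rep(1, n), pet = as.numeric(seq_len(n) %in% petRow))
  cov <- buildCovariates(items, covStats)
  fusion <- gatedFusion(fwM$z, zP, ind, cov$mat, params$gate)
  logits <- sweep(fusion$e %*% params$diagHead$W, 2, params$diagHead$b, "+")
  risks <- as.numeric(fusion$e %*% params$coxHead$W + params$coxHead$b)
  list(fwM = fwM, fwP = fwP, petRow = petRow, fusion = fusion,
       logits = logits, risks = risks, ind = ind, n = n)
}

#' Stage-2 multi-task fine-tuning
#'
#' Initializes encoders from an SSL checkpoint and jointly optimizes the
#' class-weighted diagnosis cross-entropy, the Cox partial log-likelihood on
#' baseline visits (risk sets within the minibatch), and PET-to-MRI
#' distillation, through the missing-aware gated fusion. Early stopping
#' monitors validation balanced accuracy and C-index (patience per config);
#' the softmax temperature is then fitted post hoc on the validation logits
#' without touching encoder weights.
#'
#' @param sslModel an [SSLModel-class] checkpoint.
#' @param cohort a harmonized [ImagingCohort-class].
#' @param trainSubjects,validSubjects disjoint subject id sets.
#' @param config an [ftConfig()].
#' @return a [FinetunedModel-class].
#' @export
finetuneModel <- function(sslModel, cohort, trainSubjects, validSubjects,
                          config = ftConfig()) {
  stopifnot(is(sslModel, "SSLModel"))
  if (length(intersect(trainSubjects, validSubjects)))
    stop("train and validation subjects overlap", call. = FALSE)
  set.seed(config$seed)
  spec <- structure(sslModel@spec, class = "encoderSpec")
  sites <- sslModel@sites
  visits <- cohort@visits
  vTrain <- visits[visits$subject_id %in% trainSubjects, , drop = FALSE]
  vValid <- visits[visits$subject_id %in% validSubjects, , drop = FALSE]
  subj <- cohort@subjects
  classes <- sort(unique(vTrain$diagnosis))
  K <- length(classes)
  d <- sslModel@spec$dim
  cv0 <- buildCovariates(vTrain)
  covStats <- cv0$stats
  q <- ncol(cv0$mat)
  eDim <- 2L * d + q
  params <- list(
    mri = sslModel@params$mri, pet = sslModel@params$pet,
    gate = list(w = c(0, 0), b = 0),
    diagHead = list(W = matrix(rnorm(eDim * K, 0, 0.05), eDim, K),
                    b = rep(0, K)),
    coxHead = list(W = matrix(rnorm(eDim, 0, 0.05), eDim, 1), b = 0)
  )
  opt <- adamwInit(params)
  cw <- inverseFrequencyWeights(factor(vTrain$diagnosis, levels = classes))
  svT <- subj[match(vTrain$subject_id, subj$subject_id), ]
  coefs <- config$coefficients

  bestScore <- -Inf; bestParams <- params; wait <- 0L
  evalValid <- function(p) {
    fb <- ftForwardBatch(vValid, cohort, p, spec, sites, covStats, classes,
                         train = FALSE)
    pred <- classes[max.col(fb$logits, ties.method = "first")]
    bac <- tryCatch(balancedAccuracy(vValid$diagnosis, pred),
                    error = function(e) 0.5)
    base <- vValid$visit_time_months == 0
    sv <- subj[match(vValid$subject_id[base], subj$subject_id), ]
    ci <- tryCatch(cIndex(fb$risks[base], sv$T_months, sv$event),
                   error = function(e) 0.5)
    list(score = bac + ci, bac = bac, ci = ci, logits = fb$logits)
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(nrow(vTrain))
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    for (bix in batches) {
      items <- vTrain[bix, , drop = FALSE]
      fb <- ftForwardBatch(items, cohort, params, spec, sites, covStats,
                           classes, train = TRUE)
      y <- match(items$diagnosis, classes) - 1L
      ld <- diagnosisLoss(fb$logits, y, cw)
      base <- which(items$visit_time_months == 0)
      sv <- subj[match(items$subject_id[base], subj$subject_id), ]
      dRisk <- rep(0, fb$n)
      lcVal <- 0
      if (length(base) >= 2 && any(sv$event == 1)) {
        lc <- coxPartialLoglik(fb$risks[base], sv$T_months, sv$event)
        lcVal <- lc$value / length(base)
        dRisk[base] <- lc$grad / length(base)
      }
      zPetFull <- matrix(0, fb$n, d)
      if (length(fb$petRow)) zPetFull[fb$petRow, ] <- fb$fwP$z
      ldist <- distillationLoss(fb$fwM$z, zPetFull, fb$ind[, 2])
      # backward
      dLogits <- coefs[1] * ld$gradLogits
      dE <- dLogits %*% t(params$diagHead$W) +
        coefs[2] * dRisk %*% t(params$coxHead$W)
      gDiag <- list(W = crossprod(fb$fusion$e, dLogits),
                    b = colSums(dLogits))
      gCox <- list(W = crossprod(fb$fusion$e,
                                 matrix(coefs[2] * dRisk, ncol = 1)),
                   b = sum(coefs[2] * dRisk))
      gb <- gatedFusionBackward(dE, fb$fusion)
      dzM <- gb$dzMri + coefs[3] * ldist$gradMri
      dzP <- gb$dzPet
      grads <- list(
        mri = if (config$freezeEncoders) zeroLike(params$mri)
              else encoderBackward(dzM, params$mri, spec, fb$fwM$cache),
        pet = if (config$freezeEncoders || !length(fb$petRow))
                zeroLike(params$pet)
              else encoderBackward(dzP[fb$petRow, , drop = FALSE],
                                   params$pet, spec, fb$fwP$cache),
        gate = gb$gradGate,
        diagHead = gDiag,
        coxHead = gCox
      )
      upd <- adamwStep(params, grads, opt, lr = config$lr,
                       weightDecay = config$weightDecay)
      params <- upd$params; opt <- upd$state
    }
    ev <- evalValid(params)
    if (ev$score > bestScore + 1e-6) {
      bestScore <- ev$score; bestParams <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  params <- bestParams
  ev <- evalValid(params)
  yv <- match(vValid$diagnosis, classes) - 1L
  temp <- tryCatch(fitTemperature(ev$logits, yv), error = function(e) 1)
  new("FinetunedModel",
      spec = sslModel@spec, params = params, temperature = temp,
      classes = classes,
      covariateStats = covStats,
      trainSubjects = sort(unique(trainSubjects)),
      validSubjects = sort(unique(validSubjects)),
      config = list(sites = sites, coefficients = coefs,
                    classWeights = cw, seed = config$seed,
                    sslTrainSubjects = sslModel@config$trainSubjects))
}

#' Predictions from a fine-tuned model
#'
#' MRI-only visits are valid inputs: the PET block of the fused
#' representation is zero and the gate handles the availability change.
#'
#' @param model a [FinetunedModel-class].
#' @param cohort an [ImagingCohort-class].
#' @param subjects subject ids to predict for (default: all).
#' @param mriOnly if `TRUE`, ignore PET even where available.
#' @return data.frame with subject_id, visit_time_months, diagnosis, one
#'   calibrated probability column per class, `predicted`, and `risk`.
#' @export
predictModel <- function(model, cohort, subjects = NULL, mriOnly = FALSE) {
  stopifnot(is(model, "FinetunedModel"))
  visits <- cohort@visits
  subjects <- subjects %||% unique(visits$subject_id)
  items <- visits[visits$subject_id %in% subjects, , drop = FALSE]
  if (mriOnly) items$has_pet <- FALSE
  spec <- structure(model@spec, class = "encoderSpec")
  fb <- ftForwardBatch(items, cohort, model@params, spec,
                       model@config$sites, model@covariateStats,
                       model@classes, train = FALSE)
  probs <- applyTemperature(fb$logits, model@temperature)
  colnames(probs) <- paste0("p_", model@classes)
  out <- data.frame(subject_id = items$subject_id,
                    visit_time_months = items$visit_time_months,
                    diagnosis = items$diagnosis,
                    stringsAsFactors = FALSE)
  out <- cbind(out, probs)
  out$predicted <- model@classes[max.col(fb$logits, ties.method = "first")]
  out$risk <- fb$risks
  out
}

breslowBaseline <- function(risks, times, events) {
  er <- exp(risks)
  et <- sort(unique(times[events == 1]))
  H0 <- vapply(et, function(t)
    sum(events == 1 & times == t) / sum(er[times >= t]), 0)
  list(time = et, cumhaz = cumsum(H0))
}

survivalFromRisk <- function(baseline, risks, grid) {
  H <- stats::stepfun(baseline$time, c(0, baseline$cumhaz))(grid)
  outer(exp(risks), H, function(er, h) exp(-er * h))
}

#' Evaluate a fine-tuned model on a subject set
#'
#' Emits the full battery: multi-class balanced accuracy, macro F1, AD-vs-CN
#' AUC and sensitivity at 0.80 specificity, ECE of the calibrated confidence,
#' C-index, time-dependent AUC at the median follow-up, and IPCW integrated
#' Brier score (survival curves from the Breslow baseline fitted on the
#' training fold's risks), with subject-level percentile bootstrap CIs. The
#' test subjects must be disjoint from every training-stage input; this is
#' asserted.
#'
#' @param model a [FinetunedModel-class].
#' @param cohort an [ImagingCohort-class].
#' @param subjects test subject ids.
#' @param B bootstrap samples (0 disables CIs).
#' @param checkLeakage assert disjointness from training subjects.
#' @return data.frame of class `"metricReport"`: metric, value, low, high.
#' @export
evaluateModel <- function(model, cohort, subjects, B = 200L,
                          checkLeakage = TRUE) {
  trainSeen <- unique(c(model@trainSubjects, model@validSubjects,
                        model@config$sslTrainSubjects))
  if (checkLeakage && length(intersect(subjects, trainSeen)))
    stop("evaluation subjects overlap a training-stage input", call. = FALSE)
  preds <- predictModel(model, cohort, subjects)
  subj <- cohort@subjects
  base <- preds[preds$visit_time_months == 0, , drop = FALSE]
  sv <- subj[match(base$subject_id, subj$subject_id), ]
  probCols <- paste0("p_", model@classes)
  conf <- apply(as.matrix(preds[probCols]), 1, max)
  correct <- as.numeric(preds$predicted == preds$diagnosis)

  rows <- list()
  addMetric <- function(name, fn, data) {
    v <- tryCatch(fn(data), error = function(e) NA_real_)
    cir <- c(NA_real_, NA_real_)
    if (B > 0 && is.finite(v))
      cir <- tryCatch(bootstrapCi(fn, data, B = B, seed = 7L),
                      error = function(e) c(NA_real_, NA_real_))
    rows[[length(rows) + 1L]] <<-
      data.frame(metric = name, value = v, low = cir[1], high = cir[2])
  }
  dDiag <- data.frame(truth = preds$diagnosis, pred = preds$predicted,
                      conf = conf, correct = correct,
                      stringsAsFactors = FALSE)
  addMetric("bac", function(d) balancedAccuracy(d$truth, d$pred), dDiag)
  addMetric("f1", function(d) f1Score(d$truth, d$pred), dDiag)
  addMetric("ece", function(d) ece(d$conf, d$correct,
                                   bins = min(10L, nrow(d))), dDiag)
  if (all(c("CN", "AD") %in% preds$diagnosis) && "p_AD" %in% probCols) {
    bin <- preds[preds$diagnosis %in% c("CN", "AD"), , drop = FALSE]
    dBin <- data.frame(y = as.integer(bin$diagnosis == "AD"),
                       s = bin$p_AD)
    addMetric("auc_ad_cn", function(d) aucScore(d$y, d$s), dBin)
    addMetric("sens_at_spec80",
              function(d) sensitivityAtSpecificity(d$y, d$s), dBin)
  }
  dSurv <- data.frame(risk = base$risk, T = sv$T_months, event = sv$event)
  addMetric("c_index", function(d) cIndex(d$risk, d$T, d$event), dSurv)
  tHor <- median(sv$T_months)
  addMetric("td_auc", function(d) tdAuc(d$risk, d$T, d$event, tHor), dSurv)
  ibsFn <- function(d) {
    grid <- seq(1e-6, max(d$T), length.out = 20)
    bl <- breslowBaseline(d$risk, d$T, d$event)
    S <- survivalFromRisk(bl, d$risk, grid)
    integratedBrierScore(brierCurve(S, d$T, d$event, grid))
  }
  addMetric("ibs", ibsFn, dSurv)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metricReport", class(out))
  out
}

#' Cross-cohort (out-of-distribution) evaluation
#'
#' Trains the full pipeline on one cohort and evaluates both in-distribution
#' (held-out subjects of the training cohort) and out-of-distribution (the
#' whole test cohort). Harmonization templates are fitted on the training
#' subjects only and applied to the test cohort; overlapping subject ids are
#' an error.
#'
#' @param trainCohort,testCohort two [ImagingCohort-class] objects with
#'   disjoint subject ids.
#' @param sslCfg,ftCfg stage configs.
#' @param holdoutFrac fraction of training subjects held out for the ID
#'   report.
#' @param B bootstrap samples for the reports.
#' @return list with `idReport`, `oodReport`, `model`.
#' @export
crossCohortEval <- function(trainCohort, testCohort, sslCfg = sslConfig(),
                            ftCfg = ftConfig(), holdoutFrac = 0.25,
                            B = 100L) {
  overlap <- intersect(trainCohort@subjects$subject_id,
                       testCohort@subjects$subject_id)
  if (length(overlap))
    stop(sprintf("subject id collision across cohorts: %s",
                 paste(head(overlap, 3), collapse = ", ")), call. = FALSE)
  set.seed(sslCfg$seed)
  subs <- trainCohort@subjects$subject_id
  nHold <- max(2L, round(length(subs) * holdoutFrac))
  hold <- sample(subs, nHold)
  rest <- setdiff(subs, hold)
  nVal <- max(2L, round(length(rest) * 0.25))
  valid <- sample(rest, nVal)
  train <- setdiff(rest, valid)

  hTrain <- harmonizeCohort(trainCohort, fitSubjects = train)
  testH <- applyTemplates(testCohort, hTrain$templates)
  pre <- pretrainSSL(hTrain$cohort, sslCfg, subjects = c(train, valid))
  mdl <- finetuneModel(pre$model, hTrain$cohort, train, valid, ftCfg)
  idReport <- evaluateModel(mdl, hTrain$cohort, hold, B = B)
  oodReport <- evaluateModel(mdl, testH, testCohort@subjects$subject_id,
                             B = B)
  list(idReport = idReport, oodReport = oodReport, model = mdl)
}

applyTemplates <- function(cohort, templates) {
  out <- cohort
  out@volumes <- lapply(cohort@volumes, function(v) {
    v2 <- if (v@modality == "MRI") zscoreVolume(v) else
      suvrNormalize(v, v@mask)
    tpl <- templates[[v@modality]]
    if (is.null(tpl)) v2 else histogramMatch(v2, tpl)
  })
  out
}

#' Subject-level cross-validated pipeline run
#'
#' For each fold: harmonization templates, SSL pretraining, fine-tuning
#' (with an inner validation split for early stopping and temperature), and
#' evaluation on the untouched test fold. Every stage records the subject
#' ids it consumed so [auditLeakage()] can verify the no-leakage contract
#' programmatically.
#'
#' @param cohort an [ImagingCohort-class].
#' @param k folds.
#' @param sslCfg,ftCfg stage configs.
#' @param B bootstrap samples per report.
#' @return list of class `"cvRun"` with `plan`, `folds` (reports plus the
#'   per-stage subject sets).
#' @export
runCrossValidation <- function(cohort, k = 5L, sslCfg = sslConfig(),
                               ftCfg = ftConfig(), B = 0L) {
  plan <- makeSplits(cohort, k = k, seed = sslCfg$seed)
  folds <- list()
  for (f in seq_len(k)) {
    test <- plan$assignment$subject_id[plan$assignment$fold == f]
    pool <- setdiff(plan$assignment$subject_id, test)
    set.seed(sslCfg$seed + f)
    valid <- sample(pool, max(2L, round(length(pool) * 0.25)))
    train <- setdiff(pool, valid)
    h <- harmonizeCohort(cohort, fitSubjects = train)
    pre <- pretrainSSL(h$cohort, sslCfg, subjects = pool)
    mdl <- finetuneModel(pre$model, h$cohort, train, valid, ftCfg)
    report <- evaluateModel(mdl, h$cohort, test, B = B)
    folds[[f]] <- list(
      report = report,
      testSubjects = sort(test),
      stageSubjects = list(
        template = sort(unique(unlist(lapply(h$templates,
                                             function(t) t@fitSubjects)))),
        ssl = pre$subjects,
        finetune = mdl@trainSubjects,
        temperature = mdl@validSubjects
      )
    )
  }
  out <- list(plan = plan, folds = folds)
  class(out) <- "cvRun"
  out
}

#' Audit a cross-validated run for subject leakage
#'
#' Verifies that for every fold, the test subjects are absent from every
#' training-stage input (template fitting, SSL pretraining, fine-tuning,
#' temperature fitting), and that test folds partition the cohort.
#'
#' @param cvRun result of [runCrossValidation()].
#' @return `TRUE` if clean, otherwise a character vector describing the
#'   violations.
#' @export
auditLeakage <- function(cvRun) {
  stopifnot(inherits(cvRun, "cvRun"))
  bad <- character(0)
  allTest <- unlist(lapply(cvRun$folds, `[[`, "testSubjects"))
  if (anyDuplicated(allTest))
    bad <- c(bad, "a subject appears in more than one test fold")
  if (!setequal(allTest, cvRun$plan$assignment$subject_id))
    bad <- c(bad, "test folds do not cover the cohort")
  for (f in seq_along(cvRun$folds)) {
    fd <- cvRun$folds[[f]]
    for (stage in names(fd$stageSubjects)) {
      ov <- intersect(fd$testSubjects, fd$stageSubjects[[stage]])
      if (length(ov))
        bad <- c(bad, sprintf("fold %d: %d test subject(s) leaked into %s",
                              f, length(ov), stage))
    }
  }
  if (length(bad)) bad else TRUE
}

#' Run an ablation battery
#'
#' Each arm overrides parts of the base SSL/fine-tune configuration (loss
#' switches, harmonization toggles, normalization mode) while sharing the
#' seed and the split, then reports the evaluation metrics plus a post-hoc
#' linear site-probe accuracy on frozen embeddings — the controlled
#' comparison the site-invariance claim rests on.
#'
#' @param arms named list; each element a list of overrides with optional
#'   entries `weights` (replacement [sslWeights()]), `histogram` (logical),
#'   `spec` (replacement [encoderSpec()]).
#' @param cohort an [ImagingCohort-class].
#' @param sslCfg,ftCfg base configs.
#' @param probeSplit fraction of visits for probe training.
#' @return data.frame with one row per arm (baseline row included).
#' @export
runAblation <- function(arms, cohort, sslCfg = sslConfig(),
                        ftCfg = ftConfig(), probeSplit = 0.5) {
  if (is.null(arms)) arms <- list()
  arms <- c(list(baseline = list()), arms)
  rows <- list()
  for (nm in names(arms)) {
    ov <- arms[[nm]]
    cfg <- sslCfg
    if (!is.null(ov$weights)) cfg$weights <- ov$weights
    if (!is.null(ov$spec)) cfg$spec <- ov$spec
    hist <- ov$histogram %||% TRUE
    h <- harmonizeCohort(cohort, histogram = hist)
    pre <- pretrainSSL(h$cohort, cfg)
    probe <- siteProbeAccuracy(pre$model, h$cohort, probeSplit,
                               seed = cfg$seed)
    rows[[nm]] <- data.frame(
      arm = nm, finalLoss = tail(pre$history$total, 1),
      siteProbeAcc = probe, configDiff = paste(names(ov), collapse = "+"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear site-probe accuracy on frozen MRI embeddings
#'
#' Encodes every MRI visit with the (frozen) online encoder, splits visits
#' at the subject level, and reports the validation accuracy of a linear
#' site classifier — near-chance accuracy means the representation carries
#' little site information.
#'
#' @param model an [SSLModel-class].
#' @param cohort an [ImagingCohort-class].
#' @param probeSplit train fraction.
#' @param seed split seed.
#' @return validation accuracy of the site probe.
#' @export
siteProbeAccuracy <- function(model, cohort, probeSplit = 0.5, seed = 1L) {
  visits <- cohort@visits
  vols <- lapply(seq_len(nrow(visits)), function(r)
    getVolume(cohort, visits$subject_id[r], visits$visit_time_months[r],
              "MRI"))
  keep <- !vapply(vols, is.null, TRUE)
  vols <- vols[keep]; visits <- visits[keep, , drop = FALSE]
  emb <- encodeVolumes(vols, model)
  set.seed(seed)
  subs <- unique(visits$subject_id)
  trS <- sample(subs, round(length(subs) * probeSplit))
  trIdx <- which(visits$subject_id %in% trS)
  vaIdx <- setdiff(seq_len(nrow(visits)), trIdx)
  pr <- linearProbe(embeddingMatrix(emb), visits$site_id, trIdx, vaIdx)
  pr$accuracy
}
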