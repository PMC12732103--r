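#' Per-volume z-score intensity normalization
#'
#' Standardizes within-mask intensities to mean 0 and standard deviation 1;
#' voxels outside the mask are set to 0. The usual first normalization step
#' for structural MRI before histogram matching and ComBat.
#'
#' @param v a [BrainVolume-class] with nonempty mask and nonzero within-mask
#'   standard deviation.
#' @return a [BrainVolume-class].
#' @export
zscoreVolume <- function(v) {
  stopifnot(is(v, "BrainVolume"))
  x <- v@data[v@mask]
  s <- sd(x)
  if (!is.finite(s) || s <= 0)
    stop("degenerate input: constant intensity within the mask", call. = FALSE)
  out <- array(0, dim(v@data))
  out[v@mask] <- (x - mean(x)) / s
  initialize(v, data = out)
}

#' SUVR normalization of a PET volume
#'
#' Divides every voxel by the mean intensity within a reference region
#' (cerebellum/pons analogue), the standardized uptake value ratio.
#'
#' @param pet a PET [BrainVolume-class].
#' @param referenceMask logical array, a nonempty subset of the brain mask.
#' @return a [BrainVolume-class] in SUVR units.
#' @export
suvrNormalize <- function(pet, referenceMask) {
  stopifnot(is(pet, "BrainVolume"))
  if (!identical(dim(referenceMask), dim(pet@data)))
    stop("reference mask shape must match the volume", call. = FALSE)
  if (!any(referenceMask & pet@mask))
    stop("reference mask must be a nonempty subset of the brain mask",
         call. = FALSE)
  if (any(referenceMask & !pet@mask))
    stop("reference mask must lie inside the brain mask", call. = FALSE)
  ref <- mean(pet@data[referenceMask])
  if (!is.finite(ref) || ref <= 0)
    stop("degenerate input: nonpositive mean reference intensity",
         call. = FALSE)
  initialize(pet, data = pet@data / ref)
}

#' Build a quantile reference template for histogram matching
#'
#' Pools within-mask intensities of the reference volumes (all of one
#' modality) and records their empirical quantiles at `nKnots` evenly spaced
#' probabilities. Duplicate quantile values (flat histogram stretches) are
#' kept; the transfer function in [histogramMatch()] remains monotone.
#'
#' @param volumes list of [BrainVolume-class] of a single modality.
#' @param nKnots number of quantile knots (default 101).
#' @return a [ReferenceTemplate-class].
#' @export
buildReferenceTemplate <- function(volumes, nKnots = 101L) {
  stopifnot(length(volumes) >= 1L)
  mods <- unique(vapply(volumes, function(v) v@modality, ""))
  if (length(mods) != 1L)
    stop("all reference volumes must share one modality", call. = FALSE)
  pooled <- unlist(lapply(volumes, function(v) v@data[v@mask]),
                   use.names = FALSE)
  probs <- seq(0, 1, length.out = nKnots)
  new("ReferenceTemplate",
      probs = probs,
      values = as.numeric(quantile(pooled, probs, names = FALSE, type = 7)),
      modality = mods,
      fitSubjects = sort(unique(vapply(volumes, function(v) v@subjectId, ""))))
}

#' Histogram matching to a reference template
#'
#' Maps within-mask intensities so that the volume's quantile function matches
#' the template's, by the monotone piecewise-linear transfer between the
#' volume's own quantiles and the template values at the same probabilities.
#' Rank order within the volume is preserved (the transform is monotone, so
#' subject-level anatomical structure survives); tails beyond the knot range
#' are clamped to the template extremes.
#'
#' @param v a [BrainVolume-class]; same modality as the template.
#' @param template a [ReferenceTemplate-class].
#' @return a [BrainVolume-class].
#' @export
histogramMatch <- function(v, template) {
  stopifnot(is(v, "BrainVolume"), is(template, "ReferenceTemplate"))
  if (!identical(v@modality, template@modality))
    stop(sprintf("modality mismatch: volume is %s, template is %s",
                 v@modality, template@modality), call. = FALSE)
  x <- v@data[v@mask]
  if (!length(x))
    stop("degenerate input: empty mask", call. = FALSE)
  srcQ <- as.numeric(quantile(x, template@probs, names = FALSE, type = 7))
  # collapse duplicate source knots so approx() sees a function
  keep <- !duplicated(srcQ)
  xk <- srcQ[keep]
  yk <- template@values[keep]
  mapped <- if (length(xk) == 1L) {
    rep(yk, length(x))
  } else {
    approx(xk, yk, xout = x, rule = 2, ties = "ordered")$y
  }
  out <- array(0, dim(v@data))
  out[v@mask] <- mapped
  initialize(v, data = out)
}

#' Fit the ComBat empirical-Bayes site-effect model
#'
#' The standard location/scale ComBat formulation with site/scanner as the
#' batch variable: feature-wise OLS of the data on site indicators plus
#' biological covariates (age, sex), standardization by the pooled variance,
#' and empirical-Bayes shrinkage of the per-site additive (gamma) and
#' multiplicative (delta^2) effects under parametric priors (normal for
#' gamma, inverse-gamma for delta^2) with method-of-moments hyperparameters,
#' solved by the usual fixed-point iteration. Non-biological site effects are
#' removed at [combatApply()] time while covariate effects are restored.
#'
#' @param features numeric matrix, samples x features.
#' @param site character/factor site label per sample (>= 2 samples per site).
#' @param covariates optional data.frame/matrix of biological covariates
#'   (e.g. age, sex); factors/characters are expanded to dummies; must be full
#'   rank after centering.
#' @param subjectIds optional subject ids recorded for the leakage audit.
#' @param eb if `FALSE`, skip shrinkage and use the raw site estimates.
#' @return a [CombatModel-class].
#' @export
combatFit <- function(features, site, covariates = NULL, subjectIds = NULL,
                      eb = TRUE) {
  X <- as.matrix(features)
  site <- as.character(site)
  stopifnot(nrow(X) == length(site))
  tab <- table(site)
  if (any(tab < 2L))
    stop(sprintf("site(s) with fewer than 2 samples: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")), call. = FALSE)
  sites <- sort(names(tab))
  nI <- as.numeric(tab[sites])
  n <- nrow(X); p <- ncol(X)
  B <- outer(site, sites, "==") * 1  # n x S site indicators

  C <- buildCovariateMatrix(covariates, n)
  ctr <- if (ncol(C$mat)) colMeans(C$mat) else numeric(0)
  Cc <- sweep(C$mat, 2, ctr)
  design <- cbind(B, Cc)
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient design: covariates are confounded with site or each other",
         call. = FALSE)
  # OLS feature-wise
  bh <- solve(crossprod(design), crossprod(design, X))  # (S+q) x p
  siteMeans <- bh[seq_along(sites), , drop = FALSE]
  beta <- bh[-seq_along(sites), , drop = FALSE]
  if (!nrow(beta)) beta <- matrix(0, 0, p)
  grand <- as.numeric(crossprod(nI / n, siteMeans))      # weighted grand mean
  fitted <- B %*% siteMeans + Cc %*% beta
  pooledVar <- colSums((X - fitted)^2) / n
  pooledVar <- pmax(pooledVar, 1e-12)

  stand <- sweep(X - matrix(grand, n, p, byrow = TRUE) - Cc %*% beta,
                 2, sqrt(pooledVar), "/")
  gammaHat <- t(vapply(sites, function(s)
    colMeans(stand[site == s, , drop = FALSE]), numeric(p)))
  # maximum-likelihood (1/n_i) site variances, consistent with pooledVar so
  # that a single-site model standardizes to exactly unit scale
  delta2Hat <- t(vapply(sites, function(s) {
    Zi <- stand[site == s, , drop = FALSE]
    colMeans(Zi^2) - colMeans(Zi)^2
  }, numeric(p)))
  delta2Hat[!is.finite(delta2Hat) | delta2Hat <= 0] <- 1
  dim(gammaHat) <- c(length(sites), p)
  dim(delta2Hat) <- c(length(sites), p)

  if (eb && p >= 2L && length(sites) >= 2L) {
    gammaStar <- gammaHat; delta2Star <- delta2Hat
    for (i in seq_along(sites)) {
      gbar <- mean(gammaHat[i, ]); t2 <- var(gammaHat[i, ])
      # inverse-gamma method-of-moments hyperparameters
      m <- mean(delta2Hat[i, ]); s2 <- var(delta2Hat[i, ])
      aprior <- (2 * s2 + m^2) / s2
      bprior <- (m * s2 + m^3) / s2
      if (!is.finite(aprior) || !is.finite(bprior) || s2 <= 0) {
        aprior <- 2 + 1e-3; bprior <- m
      }
      idx <- site == sites[i]
      Zi <- stand[idx, , drop = FALSE]
      ni <- sum(idx)
      g <- gammaHat[i, ]; d <- delta2Hat[i, ]
      if (!is.finite(t2) || t2 <= 0) t2 <- 1e-8
      for (iter in seq_len(100L)) {
        gNew <- (t2 * ni * gammaHat[i, ] + d * gbar) / (t2 * ni + d)
        sse <- colSums(sweep(Zi, 2, gNew)^2)
        dNew <- (0.5 * sse + bprior) / (ni / 2 + aprior - 1)
        if (max(abs(gNew - g), abs(dNew - d)) < 1e-8) {
          g <- gNew; d <- dNew; break
        }
        g <- gNew; d <- dNew
      }
      gammaStar[i, ] <- g
      delta2Star[i, ] <- pmax(d, 1e-12)
    }
  } else {
    gammaStar <- gammaHat
    delta2Star <- pmax(delta2Hat, 1e-12)
  }
  new("CombatModel",
      grandMean = grand, beta = beta, gammaStar = gammaStar,
      delta2Star = delta2Star, pooledVar = pooledVar, sites = sites,
      covariateNames = colnames(C$mat) %||% character(0),
      covariateCenter = ctr,
      fitSubjects = sort(unique(as.character(subjectIds %||% character(0)))))
}

buildCovariateMatrix <- function(covariates, n) {
  if (is.null(covariates)) return(list(mat = matrix(0, n, 0)))
  cv <- as.data.frame(covariates)
  stopifnot(nrow(cv) == n)
  cols <- lapply(names(cv), function(nm) {
    col <- cv[[nm]]
    if (is.numeric(col)) {
      m <- matrix(col, ncol = 1); colnames(m) <- nm; m
    } else {
      f <- factor(col)
      if (nlevels(f) < 2L) return(NULL)
      m <- outer(f, levels(f)[-1], "==") * 1
      colnames(m) <- paste0(nm, levels(f)[-1]); m
    }
  })
  cols <- Filter(Negate(is.null), cols)
  mat <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  list(mat = mat)
}

#' Apply a fitted ComBat model
#'
#' Standardizes with the fitted grand mean, covariate coefficients, and pooled
#' variance, removes the shrunken site location/scale effects, and restores
#' the covariate effects. Because the transform depends only on the sample's
#' site and covariates (not on the visit), all timepoints of a subject receive
#' the identical harmonization. A model fitted on a single site returns the
#' input within numerical tolerance.
#'
#' @param model a [CombatModel-class].
#' @param features samples x features matrix; columns as at fit time.
#' @param site site label per sample; must all be fitted sites.
#' @param covariates covariates as at fit time (same columns).
#' @return harmonized matrix, same shape as `features`.
#' @export
combatApply <- function(model, features, site, covariates = NULL) {
  stopifnot(is(model, "CombatModel"))
  X <- as.matrix(features)
  site <- as.character(site)
  unseen <- setdiff(unique(site), model@sites)
  if (length(unseen))
    stop(sprintf("site(s) not seen at fit time: %s",
                 paste(unseen, collapse = ", ")), call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (p != length(model@grandMean))
    stop("feature count disagrees with the fitted model", call. = FALSE)
  C <- buildCovariateMatrix(covariates, n)
  if (!identical(colnames(C$mat) %||% character(0), model@covariateNames))
    stop("covariate columns disagree with the fitted model", call. = FALSE)
  Cc <- if (ncol(C$mat)) sweep(C$mat, 2, model@covariateCenter) else C$mat
  covEff <- if (ncol(Cc)) Cc %*% model@beta else matrix(0, n, p)
  sdp <- sqrt(model@pooledVar)
  Z <- sweep(X - matrix(model@grandMean, n, p, byrow = TRUE) - covEff,
             2, sdp, "/")
  si <- match(site, model@sites)
  Zadj <- (Z - model@gammaStar[si, , drop = FALSE]) /
    sqrt(model@delta2Star[si, , drop = FALSE])
  out <- sweep(Zadj, 2, sdp, "*") +
    matrix(model@grandMean, n, p, byrow = TRUE) + covEff
  dimnames(out) <- dimnames(X)
  out
}

#' Site drift before and after harmonization
#'
#' Summarizes per-site within-mask intensity distributions before and after a
#' harmonization stage and reports a scalar drift statistic per stage: the
#' between-site variance of volume means. The `ratio` (post/pre) quantifies
#' how much site drift the stage removed (1 means none).
#'
#' @param volumesPre,volumesPost matching lists of [BrainVolume-class].
#' @param site site label per volume.
#' @param breaks histogram breaks count (shared across sites and stages).
#' @return list with `perSite` (data.frame of per-site mean/sd at both
#'   stages), `histograms`, `driftPre`, `driftPost`, `ratio`.
#' @export
siteDriftReport <- function(volumesPre, volumesPost, site, breaks = 30L) {
  if (length(volumesPre) != length(volumesPost) ||
      length(volumesPre) != length(site))
    stop("volumesPre, volumesPost and site must have matching lengths",
         call. = FALSE)
  site <- as.character(site)
  vmeans <- function(vols) vapply(vols, function(v) mean(v@data[v@mask]), 0)
  stageStats <- function(vols, stage) {
    mns <- vmeans(vols)
    agg <- do.call(rbind, lapply(split(seq_along(vols), site), function(ix) {
      x <- unlist(lapply(vols[ix], function(v) v@data[v@mask]))
      data.frame(mean = mean(x), sd = sd(x))
    }))
    data.frame(stage = stage, site_id = rownames(agg),
               mean = agg$mean, sd = agg$sd, row.names = NULL)
  }
  drift <- function(vols) {
    mns <- vmeans(vols)
    siteMeans <- tapply(mns, site, mean)
    if (length(siteMeans) < 2L) 0 else var(as.numeric(siteMeans))
  }
  histStage <- function(vols) {
    allx <- unlist(lapply(vols, function(v) v@data[v@mask]))
    br <- seq(min(allx), max(allx), length.out = breaks + 1L)
    lapply(split(seq_along(vols), site), function(ix) {
      x <- unlist(lapply(vols[ix], function(v) v@data[v@mask]))
      h <- hist(x, breaks = br, plot = FALSE)
      data.frame(mid = h$mids, density = h$density)
    })
  }
  dPre <- drift(volumesPre); dPost <- drift(volumesPost)
  list(
    perSite = rbind(stageStats(volumesPre, "pre"),
                    stageStats(volumesPost, "post")),
    histograms = list(pre = histStage(volumesPre),
                      post = histStage(volumesPost)),
    driftPre = dPre, driftPost = dPost,
    ratio = if (dPre > 0) dPost / dPre else 1
  )
}

#' @importFrom graphics hist
NULL

#' Run the offline harmonization pipeline on a cohort
#'
#' Applies the fixed pipeline order z-score (MRI) / SUVR (PET) -> histogram
#' matching -> (optional feature-level ComBat happens downstream on
#' embeddings/features, not voxel grids here). Templates are fitted on the
#' supplied `fitSubjects` only (train fold), then applied to every volume, so
#' held-out subjects never influence the transform.
#'
#' @param cohort an [ImagingCohort-class].
#' @param fitSubjects subject ids used to fit the templates (default: all).
#' @param referenceMask optional logical array for SUVR; default: the
#'   generator's target-free brain shell is approximated by the full mask.
#' @param histogram if `TRUE` apply histogram matching after z-score/SUVR.
#' @return list with the harmonized `cohort` and the fitted `templates`.
#' @export
harmonizeCohort <- function(cohort, fitSubjects = NULL, referenceMask = NULL,
                            histogram = TRUE) {
  stopifnot(is(cohort, "ImagingCohort"))
  fitSubjects <- fitSubjects %||% cohort@subjects$subject_id
  vols <- cohort@volumes
  norm1 <- lapply(vols, function(v) {
    if (v@modality == "MRI") {
      zscoreVolume(v)
    } else {
      suvrNormalize(v, referenceMask %||% v@mask)
    }
  })
  templates <- list()
  if (histogram) {
    for (m in c("MRI", "PET")) {
      ref <- Filter(function(v) v@modality == m &&
                      v@subjectId %in% fitSubjects, norm1)
      if (!length(ref)) next
      templates[[m]] <- buildReferenceTemplate(ref)
    }
    norm1 <- lapply(norm1, function(v) {
      tpl <- templates[[v@modality]]
      if (is.null(tpl)) v else histogramMatch(v, tpl)
    })
  }
  out <- cohort
  out@volumes <- norm1
  list(cohort = out, templates = templates)
}
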