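## dominant Gaussian component of a structure (by mixture weight)
.structureComponent <- function(params, structure) {
  rows <- which(params@mixture$structure == structure)
  if (!length(rows)) return(NA_integer_)
  params@mixture$component[rows[which.max(params@mixture$weight[rows])]]
}

#' Lesion intensity candidate mask
#'
#' Prior knowledge about the appearance of white-matter lesions: a voxel is
#' a candidate lesion only if its bias-corrected log intensity is strictly
#' higher than the gray-matter Gaussian mean in every available FLAIR- or
#' T2-role channel.  If the image has no such channel, or no gray-matter
#' component is declared, all brain-mask voxels are candidates.
#'
#' @param image log-transformed [MultiContrastImage-class].
#' @param params fitted [AppearanceParams-class].
#' @param basis the [BiasBasis-class] used during fitting.
#' @return logical vector (I); `FALSE` outside the brain mask.
#' @export
candidateMask <- function(image, params, basis) {
  if (!image@logTransformed) stop("candidateMask expects log intensities")
  cand <- image@mask
  ch <- which(image@roles %in% c("flair", "t2w"))
  if (!length(ch)) return(cand)
  gmStruct <- params@gmComponent
  gmComp <- if (is.na(gmStruct)) NA_integer_
            else .structureComponent(params, gmStruct)
  if (is.na(gmComp)) {
    warning("no gray-matter component declared; all voxels are candidates")
    return(cand)
  }
  Dc <- image@intensities - basis@values %*% params@biasCoeffs
  for (n in ch) cand <- cand & (Dc[, n] > params@means[n, gmComp])
  cand
}

## per-voxel Bernoulli lesion posterior for one configuration (f, theta_les)
.lesionBernoulli <- function(Dc, A, rho, f, params, lesMean, lesCov, mask) {
  host <- params@hostStructures
  hostMass <- rowSums(A[, host, drop = FALSE])
  pLes <- pmin(pmax(f * rho, 0), 1)
  mix <- params@mixture
  I <- nrow(A)
  logNon <- matrix(-Inf, I, nrow(mix))
  for (r in seq_len(nrow(mix))) {
    k <- mix$structure[r]
    mass <- mix$weight[r] * A[, k]
    if (k %in% host) mass <- mass * (1 - pLes)
    logNon[, r] <- log(mass) +
      .mvnLogDensity(Dc, params@means[, mix$component[r]],
                     params@covs[[mix$component[r]]])
  }
  logNon[!is.finite(logNon)] <- -Inf
  lseNon <- logSumExpRows(logNon)
  logLes <- log(pLes * hostMass) + .mvnLogDensity(Dc, lesMean, lesCov)
  p <- 1 / (1 + exp(lseNon - logLes))
  p[pLes * hostMass <= 0] <- 0
  p[!mask] <- 0
  p
}

#' Monte-Carlo estimate of the voxelwise lesion posterior
#'
#' Approximates p(z_i = 1 | d_i) by averaging per-voxel Bernoulli
#' posteriors over retained samples of a blocked Gibbs-style chain that
#' alternates (1) sampling the latent shape code h from the encoder
#' posterior given the current lesion map and decoding it into voxelwise
#' shape factors f(h); (2) sampling the lesion Gaussian from its
#' normal-inverse-Wishart conditional posterior given the current lesion
#' map (conjugacy); (3) resampling the lesion map from independent
#' voxelwise Bernoulli posteriors.  Without a shape model, f is clamped
#' to 1.  With `fixed`, both h and the lesion Gaussian are held at the
#' supplied values and the estimator is exact (the per-voxel closed form).
#'
#' @param image log-transformed [MultiContrastImage-class].
#' @param atlas the [MeshAtlas-class] used in fitting.
#' @param fit a [FitResult-class].
#' @param shapeModel a [LesionShapeModel-class] or `NULL` (shape factors
#'   clamped to 1).
#' @param S retained Monte-Carlo samples (>= 1).
#' @param burnin discarded initial sweeps.
#' @param seed integer seed; the chain is reproducible.
#' @param fixed optional list with elements `h` (latent code) and/or
#'   `lesionMean`/`lesionCov` to hold fixed (degenerate chain).
#' @param basis the [BiasBasis-class] used during fitting; rebuilt from the
#'   coefficient count if omitted.
#' @return numeric vector (I) of posterior probabilities in [0,1].
#' @export
sampleLesionPosterior <- function(image, atlas, fit, shapeModel = NULL,
                                  S = 50L, burnin = 20L, seed = 1L,
                                  fixed = NULL, basis = NULL) {
  if (S < 1L) stop("S must be >= 1")
  params <- fit@params
  if (is.null(basis)) {
    d <- length(image@geometry@dim)
    ord <- as.integer(round(nrow(params@biasCoeffs)^(1 / d)))
    basis <- makeBiasBasis(image@geometry, ord)
    stopifnot(ncol(basis@values) == nrow(params@biasCoeffs))
  }
  Dc <- image@intensities - basis@values %*% params@biasCoeffs
  pr <- .deformedPriors(fit@deformation@positions, atlas)
  mask <- image@mask
  nuL <- params@nu
  N <- ncol(Dc)
  wmMean <- params@means[, params@wmComponent]
  wmCov <- params@covs[[params@wmComponent]]
  fixedH <- !is.null(fixed$h)
  fixedLes <- !is.null(fixed$lesionMean)
  lesMean <- if (fixedLes) fixed$lesionMean else params@lesionMean
  lesCov <- if (fixedLes) as.matrix(fixed$lesionCov) else params@lesionCov
  f <- if (fixedH && !is.null(shapeModel))
    decodeShape(shapeModel, fixed$h) else 1
  canSampleLes <- !fixedLes && nuL - N - 2 > N - 1
  ## initialize z from the simplified-model posterior (f = 1)
  p0 <- .lesionBernoulli(Dc, pr$A, pr$rho, 1, params, params@lesionMean,
                         params@lesionCov, mask)
  z <- p0 > 0.5
  acc <- numeric(nrow(Dc))
  withSeed(deriveSeed(seed, 11L), {
    for (sweep in seq_len(burnin + S)) {
      if (!is.null(shapeModel) && !fixedH) {
        q <- encodeShape(shapeModel, as.numeric(z))
        h <- q$mean + sqrt(q$var) * stats::rnorm(shapeModel@latentDim)
        f <- decodeShape(shapeModel, h)
      }
      if (canSampleLes) {
        resp <- as.numeric(z)
        R <- sum(resp)
        m <- if (R > 0) colSums(resp * Dc) / R else wmMean
        Sm <- if (R > 0) {
          Xc <- sweep(Dc, 2L, m) * sqrt(resp)
          crossprod(Xc)
        } else matrix(0, N, N)
        dd <- m - wmMean
        lamN <- nuL + R
        muN <- (nuL * wmMean + R * m) / lamN
        PsiN <- params@kappa * nuL * wmCov + Sm +
          (nuL * R / lamN) * tcrossprod(dd)
        dofN <- nuL - N - 2 + R
        if (params@diagonalCov) {
          s2 <- diag(PsiN) / (2 * stats::rgamma(N, dofN / 2))
          lesCov <- diag(s2, N)
        } else {
          Prec <- stats::rWishart(1L, dofN, solve(PsiN))[, , 1L]
          lesCov <- solve(Prec)
        }
        ch <- chol(lesCov / lamN)
        lesMean <- muN + drop(t(ch) %*% stats::rnorm(N))
      }
      p <- .lesionBernoulli(Dc, pr$A, pr$rho, f, params, lesMean, lesCov,
                            mask)
      z <- stats::runif(length(p)) < p
      if (sweep > burnin) acc <- acc + p
    }
  })
  acc / S
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold the lesion posterior
#'
#' Binary lesion mask: voxels whose posterior strictly exceeds the
#' user-specified threshold `gamma` and that belong to the intensity
#' candidate mask.
#'
#' @param posterior numeric voxelwise lesion posterior in [0,1].
#' @param gamma threshold in [0,1] (default 0.5).
#' @param candidate optional logical candidate mask (see
#'   [candidateMask()]).
#' @return logical vector.
#' @export
thresholdLesions <- function(posterior, gamma = 0.5, candidate = NULL) {
  if (!isScalarNumber(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must be a number in [0,1]")
  z <- posterior > gamma
  if (!is.null(candidate)) z <- z & candidate
  z
}

#' Final structure labeling
#'
#' Voxels in the lesion mask receive the dedicated lesion label
#' (`K + 1`); every other brain-mask voxel is assigned to the anatomical
#' structure with the highest posterior weight (mixture components
#' re-aggregated to structures; argmax ties broken by the lowest structure
#' index).  Voxels outside the brain mask are 0.
#'
#' @param weights I x (C+1) component posterior weights (lesion last), or
#'   an I x K structure-level matrix when `params` is `NULL`.
#' @param lesionMask logical vector.
#' @param mask logical brain mask.
#' @param params the [AppearanceParams-class] used to aggregate components
#'   to structures (`NULL` if `weights` is already structure-level).
#' @param K number of anatomical structures.
#' @return integer label map (I).
#' @export
finalLabeling <- function(weights, lesionMask, mask = NULL, params = NULL,
                          K = ncol(weights)) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(weights))
  u <- if (is.null(params)) weights[, seq_len(K), drop = FALSE]
       else aggregateToStructures(weights, params, K)[, seq_len(K),
                                                      drop = FALSE]
  lab <- max.col(u, ties.method = "first")
  lab[lesionMask] <- K + 1L
  lab[!mask] <- 0L
  as.integer(lab)
}

#' Segment a multi-contrast image
#'
#' Full pipeline: generalized-EM parameter estimation in the simplified
#' model, intensity candidate masking, Monte-Carlo lesion-posterior
#' estimation under the shape and location priors, thresholding at
#' `gamma`, and final structure labeling.  End-to-end reproducible given
#' the configuration seed.
#'
#' @param image a [MultiContrastImage-class].
#' @param atlas a [MeshAtlas-class].
#' @param shapeModel optional [LesionShapeModel-class].
#' @param config a [FitConfig-class].
#' @return a [SegmentationResult-class].
#' @export
segmentBrain <- function(image, atlas, shapeModel = NULL,
                         config = fitConfig()) {
  if (!image@logTransformed) image <- logTransform(image)
  fit <- fitParameters(image, atlas, config)
  basis <- makeBiasBasis(image@geometry, config@biasOrder)
  cand <- candidateMask(image, fit@params, basis)
  post <- sampleLesionPosterior(image, atlas, fit, shapeModel,
                                S = config@mcSamples,
                                burnin = config@mcBurnin,
                                seed = config@seed, basis = basis)
  post[!cand] <- 0               # hard intensity constraint
  z <- thresholdLesions(post, config@gamma, cand)
  pr <- .deformedPriors(fit@deformation@positions, atlas)
  W <- posteriorLabelWeights(image, pr$A, fit@params, basis, rho = pr$rho)
  K <- length(fit@structures)
  soft <- aggregateToStructures(W, fit@params, K)
  lab <- finalLabeling(W, z, mask = image@mask, params = fit@params, K = K)
  new("SegmentationResult", softWeights = soft[, seq_len(K), drop = FALSE],
      lesionPosterior = post, lesionMask = z, labelMap = lab,
      structures = c(fit@structures, "lesion"), fit = fit,
      provenance = list(gamma = config@gamma, S = config@mcSamples,
                        burnin = config@mcBurnin, seed = config@seed,
                        nu = config@nu, kappa = config@kappa,
                        shapeModel = !is.null(shapeModel)))
}

setMethod("show", "SegmentationResult", function(object) {
  K <- length(object@structures)
  cat("SegmentationResult:",
      sum(object@labelMap > 0L), "labeled voxels;",
      sum(object@lesionMask), "lesion voxels\n")
  tab <- table(factor(object@labelMap[object@labelMap > 0L],
                      levels = seq_len(K), labels = object@structures))
  print(tab)
})
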