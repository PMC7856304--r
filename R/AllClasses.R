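#' Image-grid geometry
#'
#' Voxel grid metadata shared by all volumes in an analysis: grid dimensions,
#' voxel size in mm, and a world affine carried as metadata only.  All
#' computations use 0-based continuous voxel coordinates with voxel centers
#' at integers.
#'
#' @slot dim integer vector of grid dimensions (2-D or 3-D).
#' @slot voxelSize numeric vector, voxel edge lengths in mm (one per axis).
#' @slot affine numeric (d+1)x(d+1) voxel-to-world matrix (metadata only).
#' @export
setClass("GridGeometry",
  representation(dim = "integer", voxelSize = "numeric", affine = "matrix"))

setValidity("GridGeometry", function(object) {
  d <- length(object@dim)
  if (!(d %in% c(2L, 3L))) return("grid must be 2-D or 3-D")
  if (any(object@dim < 1L)) return("each grid dimension must be >= 1")
  if (length(object@voxelSize) != d) return("voxelSize length must match dim")
  if (any(object@voxelSize <= 0)) return("voxel sizes must be positive")
  TRUE
})

#' @describeIn GridGeometry constructor.
#' @param dim,voxelSize,affine see slots.
#' @export
gridGeometry <- function(dim, voxelSize = rep(1, length(dim)), affine = NULL) {
  dim <- as.integer(dim)
  d <- length(dim)
  if (is.null(affine)) {
    affine <- diag(d + 1)
    diag(affine)[seq_len(d)] <- voxelSize
  }
  new("GridGeometry", dim = dim, voxelSize = as.numeric(voxelSize),
      affine = affine)
}

#' Multi-contrast image
#'
#' A stack of co-registered volumes (e.g. T1w/T2w/FLAIR) on a single grid,
#' stored as an I x N matrix of voxel intensities (I = number of grid voxels
#' in column-major order, N = number of contrasts), together with the grid
#' geometry, a brain mask restricting analysis, and per-contrast channel
#' roles.  Intensities may be raw or log-transformed (see
#' [logTransform()]); the \code{logFloor} slot records the clamping floor
#' applied per contrast before taking logs.
#'
#' @slot intensities numeric I x N matrix.
#' @slot geometry a [GridGeometry-class].
#' @slot mask logical vector of length I; voxels entering the analysis.
#' @slot roles character vector of length N; one of "t1w", "t2w", "flair",
#'   "other".
#' @slot logTransformed logical scalar.
#' @slot logFloor numeric vector (length N) of clamping floors, NA when raw.
#' @export
setClass("MultiContrastImage",
  representation(intensities = "matrix", geometry = "GridGeometry",
                 mask = "logical", roles = "character",
                 logTransformed = "logical", logFloor = "numeric"))

setValidity("MultiContrastImage", function(object) {
  I <- prod(object@geometry@dim)
  if (nrow(object@intensities) != I)
    return("intensity rows must equal number of grid voxels")
  if (length(object@mask) != I) return("mask length must equal voxel count")
  if (sum(object@mask) == 0L) return("brain mask is empty")
  n <- ncol(object@intensities)
  if (length(object@roles) != n) return("one role per contrast required")
  bad <- setdiff(object@roles, c("t1w", "t2w", "flair", "other"))
  if (length(bad)) return(paste("unknown channel role:", bad[1]))
  TRUE
})

#' @describeIn MultiContrastImage constructor.
#' @param intensities,geometry,mask,roles see slots.
#' @export
multiContrastImage <- function(intensities, geometry, mask = NULL,
                               roles = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(mask)) mask <- rep(TRUE, nrow(intensities))
  if (is.null(roles)) roles <- rep("other", ncol(intensities))
  new("MultiContrastImage", intensities = intensities, geometry = geometry,
      mask = as.logical(mask), roles = roles, logTransformed = FALSE,
      logFloor = rep(NA_real_, ncol(intensities)))
}

#' Deformable probabilistic mesh atlas
#'
#' A simplex mesh (triangles in 2-D, tetrahedra in 3-D) over the image
#' domain carrying, at each of its J vertices, a probability vector over the
#' K anatomical labels and a lesion occurrence probability.  Per-voxel label
#' priors arise by barycentric (piecewise-linear) interpolation of the
#' vertex tables at the current mesh deformation; the lesion probability map
#' deforms in conjunction with the anatomy.
#'
#' @slot vertices numeric J x d matrix of reference vertex positions
#'   (0-based voxel coordinates).
#' @slot simplices integer S x (d+1) matrix of vertex indices; every simplex
#'   has positive signed volume in the reference configuration.
#' @slot labelProbs numeric J x K matrix; each row sums to 1.
#' @slot lesionProbs numeric vector (J) of per-vertex lesion probabilities.
#' @slot labels character vector of K label names.
#' @slot stiffness nonnegative scalar weight of the deformation prior.
#' @slot geometry the [GridGeometry-class] the atlas was built for.
#' @export
setClass("MeshAtlas",
  representation(vertices = "matrix", simplices = "matrix",
                 labelProbs = "matrix", lesionProbs = "numeric",
                 labels = "character", stiffness = "numeric",
                 geometry = "GridGeometry"))

setValidity("MeshAtlas", function(object) {
  J <- nrow(object@vertices)
  d <- ncol(object@vertices)
  if (ncol(object@simplices) != d + 1L)
    return("simplices must have d+1 vertices each")
  if (max(object@simplices) > J || min(object@simplices) < 1L)
    return("simplex vertex index out of range")
  if (nrow(object@labelProbs) != J) return("one labelProbs row per vertex")
  rs <- rowSums(object@labelProbs)
  if (any(abs(rs - 1) > 1e-9)) return("labelProbs rows must sum to 1")
  if (any(object@labelProbs < -1e-12)) return("labelProbs must be >= 0")
  if (length(object@lesionProbs) != J) return("one lesionProb per vertex")
  if (any(object@lesionProbs < -1e-12 | object@lesionProbs > 1 + 1e-12))
    return("lesionProbs must lie in [0,1]")
  if (length(object@labels) != ncol(object@labelProbs))
    return("one label name per labelProbs column")
  if (object@stiffness < 0) return("stiffness must be nonnegative")
  v <- simplexVolumes(object@vertices, object@simplices)
  if (any(v <= 0)) return("reference mesh contains non-positive volumes")
  TRUE
})

#' Mesh deformation state
#'
#' Current positions of a mesh atlas's vertices.  A deformation is valid iff
#' every simplex retains positive signed volume (no tearing or folding).
#'
#' @slot positions numeric J x d matrix of deformed vertex positions.
#' @export
setClass("DeformationState", representation(positions = "matrix"))

#' @describeIn DeformationState constructor; defaults to the atlas's
#'   reference (identity) configuration.
#' @param atlas a [MeshAtlas-class].
#' @param positions optional J x d matrix of vertex positions.
#' @export
deformationState <- function(atlas, positions = NULL) {
  if (is.null(positions)) positions <- atlas@vertices
  if (!all(dim(positions) == dim(atlas@vertices)))
    stop("deformation must have the same vertex count as its atlas")
  new("DeformationState", positions = as.matrix(positions))
}

#' Smooth bias-field basis
#'
#' Evaluation table of P separable smooth (cosine) basis functions over the
#' grid; the first function is constant.  The multiplicative bias field is
#' modeled, after log transformation, as a per-contrast linear combination
#' of these functions added to the class means.
#'
#' @slot values numeric I x P matrix of basis function values per voxel.
#' @slot order integer per-axis orders; P = prod(order).
#' @export
setClass("BiasBasis", representation(values = "matrix", order = "integer"))

setValidity("BiasBasis", function(object) {
  if (prod(object@order) != ncol(object@values))
    return("number of basis functions must equal prod(order)")
  if (any(object@order < 1L)) return("orders must be >= 1")
  if (max(abs(object@values[, 1] - object@values[1, 1])) > 1e-12)
    return("first basis function must be constant")
  TRUE
})

#' Appearance-model parameters
#'
#' Gaussian intensity model for each mixture component, bias-field
#' coefficients, the structure-to-component sharing map (several anatomical
#' structures may share one Gaussian; a structure may also be a mixture of
#' several Gaussians), and the lesion Gaussian with its normal-inverse-
#' Wishart hyperparameters (nu pseudo-voxels, variance scale kappa) tying it
#' to the white-matter Gaussian.
#'
#' @slot means numeric N x C matrix; column c is the mean of Gaussian
#'   component c in log-intensity space (N contrasts).
#' @slot covs list of C symmetric positive-definite N x N matrices.
#' @slot biasCoeffs numeric P x N matrix of bias coefficients per contrast.
#' @slot mixture data.frame with columns \code{component}, \code{structure},
#'   \code{weight}; weights sum to 1 within each structure.
#' @slot lesionMean numeric vector (N).
#' @slot lesionCov numeric N x N matrix.
#' @slot nu nonnegative scalar; pseudo-voxel count of the lesion prior
#'   (already scaled by voxel volume).
#' @slot kappa scalar > 1; lesion variance inflation relative to white
#'   matter.
#' @slot wmComponent integer index of the white-matter Gaussian component.
#' @slot gmComponent integer index of the gray-matter Gaussian component
#'   (used by the lesion intensity candidate rule); NA disables the rule.
#' @slot hostStructures integer indices of structures whose prior mass hosts
#'   lesions (default: white matter).
#' @slot diagonalCov logical; restrict covariances to diagonals.
#' @export
setClass("AppearanceParams",
  representation(means = "matrix", covs = "list", biasCoeffs = "matrix",
                 mixture = "data.frame", lesionMean = "numeric",
                 lesionCov = "matrix", nu = "numeric", kappa = "numeric",
                 wmComponent = "integer", gmComponent = "integer",
                 hostStructures = "integer", diagonalCov = "logical"))

setValidity("AppearanceParams", function(object) {
  C <- ncol(object@means)
  if (length(object@covs) != C) return("one covariance per component")
  N <- nrow(object@means)
  for (S in object@covs) {
    if (!all(dim(S) == N)) return("covariance dimension mismatch")
    if (max(abs(S - t(S))) > 1e-8) return("covariance must be symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return("covariance must be positive definite")
  }
  mw <- tapply(object@mixture$weight, object@mixture$structure, sum)
  if (any(abs(mw - 1) > 1e-9))
    return("mixture weights must sum to 1 within each structure")
  if (object@nu < 0) return("nu must be >= 0")
  if (object@kappa <= 1) return("kappa must be > 1")
  TRUE
})

#' Variational-autoencoder lesion shape model
#'
#' Weights of a variational autoencoder over binary lesion masks: a decoder
#' mapping a latent code h (standard-normal prior) to a voxelwise lesion
#' probability field through a sigmoid output, and an encoder producing the
#' approximate-posterior mean and (softplus) variance of h given a mask.
#'
#' @slot decoder list of weight matrices/bias vectors of the decoder.
#' @slot encoder list of weight matrices/bias vectors of the encoder.
#' @slot latentDim integer latent dimension.
#' @slot inputShape integer grid dimensions of the masks.
#' @slot training list of training metadata (epochs, lr, seed, elboTrace).
#' @export
setClass("LesionShapeModel",
  representation(decoder = "list", encoder = "list", latentDim = "integer",
                 inputShape = "integer", training = "list"))

#' Fitting configuration
#'
#' Tuning knobs of the generalized-EM parameter estimation and the
#' Monte-Carlo lesion-posterior step.  See the methods vignette for the
#' rationale behind the defaults.
#'
#' @slot maxOuterIters integer maximum outer GEM iterations.
#' @slot emTolerance relative objective-change convergence threshold.
#' @slot innerEmIters integer E/M sweeps per outer iteration.
#' @slot biasOrder integer per-axis bias basis orders.
#' @slot diagonalCov logical covariance mode (diagonal is the default).
#' @slot nu,kappa lesion-prior hyperparameters; nu is specified per mm^d and
#'   rescaled by the voxel volume of the image being fitted.
#' @slot gamma lesion posterior threshold.
#' @slot mcSamples,mcBurnin Monte-Carlo sample counts for lesion inference.
#' @slot deformIters gradient-ascent steps on the mesh per outer iteration.
#' @slot deformStepSize initial step size (voxels) of the mesh optimizer.
#' @slot seed integer seed from which all stochastic stages derive streams.
#' @export
setClass("FitConfig",
  representation(maxOuterIters = "integer", emTolerance = "numeric",
                 innerEmIters = "integer", biasOrder = "integer",
                 diagonalCov = "logical", nu = "numeric", kappa = "numeric",
                 gamma = "numeric", mcSamples = "integer",
                 mcBurnin = "integer", deformIters = "integer",
                 deformStepSize = "numeric", seed = "integer"))

setValidity("FitConfig", function(object) {
  if (object@emTolerance <= 0) return("emTolerance must be > 0")
  if (object@gamma < 0 || object@gamma > 1) return("gamma must be in [0,1]")
  if (object@nu < 0) return("nu must be >= 0")
  if (object@kappa <= 1) return("kappa must be > 1")
  TRUE
})

#' @describeIn FitConfig constructor with package defaults.
#' @param maxOuterIters,emTolerance,innerEmIters,biasOrder,diagonalCov
#'   see slots.
#' @param nu,kappa,gamma,mcSamples,mcBurnin,deformIters,deformStepSize,seed
#'   see slots.
#' @export
fitConfig <- function(maxOuterIters = 100L, emTolerance = 1e-5,
                      innerEmIters = 2L, biasOrder = 3L,
                      diagonalCov = TRUE, nu = 500, kappa = 50,
                      gamma = 0.5, mcSamples = 50L, mcBurnin = 20L,
                      deformIters = 2L, deformStepSize = 0.5, seed = 1L) {
  new("FitConfig", maxOuterIters = as.integer(maxOuterIters),
      emTolerance = emTolerance, innerEmIters = as.integer(innerEmIters),
      biasOrder = as.integer(biasOrder), diagonalCov = diagonalCov,
      nu = nu, kappa = kappa, gamma = gamma,
      mcSamples = as.integer(mcSamples), mcBurnin = as.integer(mcBurnin),
      deformIters = as.integer(deformIters),
      deformStepSize = deformStepSize, seed = as.integer(seed))
}

#' Result of model fitting
#'
#' Point estimates of the appearance parameters and mesh deformation
#' obtained by generalized-EM coordinate ascent on the simplified model
#' (lesion shape factors clamped to 1), with the log-posterior trace.
#'
#' @slot params an [AppearanceParams-class].
#' @slot deformation a [DeformationState-class].
#' @slot objectiveTrace numeric log-posterior per outer iteration
#'   (non-decreasing up to 1e-6 relative slack).
#' @slot converged logical.
#' @slot structures character vector of structure names.
#' @export
setClass("FitResult",
  representation(params = "AppearanceParams",
                 deformation = "DeformationState",
                 objectiveTrace = "numeric", converged = "logical",
                 structures = "character"))

#' Segmentation result
#'
#' Soft structure assignments, the Monte-Carlo voxelwise lesion posterior,
#' the thresholded binary lesion mask, and the final anatomical label map
#' (lesion voxels carry the dedicated lesion label).
#'
#' @slot softWeights numeric I x K matrix of per-structure posteriors
#'   (masked voxels; rows of unmasked voxels are zero).
#' @slot lesionPosterior numeric vector (I) in [0,1].
#' @slot lesionMask logical vector (I).
#' @slot labelMap integer vector (I); 0 outside the brain mask; the value
#'   \code{length(structures)+1} denotes lesion.
#' @slot structures character structure names.
#' @slot fit the underlying [FitResult-class].
#' @slot provenance list (gamma, S, seed, configuration echo).
#' @export
setClass("SegmentationResult",
  representation(softWeights = "matrix", lesionPosterior = "numeric",
                 lesionMask = "logical", labelMap = "integer",
                 structures = "character", fit = "FitResult",
                 provenance = "list"))

#' Synthetic brain-phantom specification
#'
#' Parameters of the synthetic multi-contrast phantom generator: grid and
#' voxel size, concentric-ellipse anatomy (background, CSF, gray matter,
#' white matter, deep gray matter), per-structure per-contrast intensity
#' means/SDs, smooth multiplicative bias-field amplitude, and blob-like
#' white-matter lesions hyperintense in the FLAIR-role channel.
#'
#' @slot dim integer grid dimensions.
#' @slot voxelSize numeric voxel size (mm).
#' @slot roles character contrast roles.
#' @slot means numeric N x 5 matrix of structure means (columns: background,
#'   CSF, GM, WM, deep GM) per contrast (raw intensity units).
#' @slot sds numeric N x 5 matrix of structure standard deviations.
#' @slot lesionOffsets numeric vector (N) added to the WM mean inside
#'   lesions (positive in the FLAIR-role channel).
#' @slot lesionSd numeric lesion intensity SD per contrast (vector N).
#' @slot lesionRate expected number of lesions (Poisson).
#' @slot lesionRadius numeric length-2 range of lesion radii (voxels).
#' @slot biasAmplitude numeric SD of log-domain bias coefficients (0 = no
#'   bias field).
#' @slot biasOrder integer per-axis order of the generated bias field.
#' @slot jitter numeric geometric jitter SD (voxels) of structure boundaries.
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", voxelSize = "numeric", roles = "character",
                 means = "matrix", sds = "matrix",
                 lesionOffsets = "numeric", lesionSd = "numeric",
                 lesionRate = "numeric", lesionRadius = "numeric",
                 biasAmplitude = "numeric", biasOrder = "integer",
                 jitter = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (any(object@means <= 0)) return("phantom means must be positive")
  if (!all(dim(object@sds) == dim(object@means)))
    return("sds must match means in shape")
  if (length(object@lesionOffsets) != nrow(object@means))
    return("one lesion offset per contrast")
  if (object@lesionRate < 0) return("lesionRate must be >= 0")
  TRUE
})
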