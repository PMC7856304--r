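#' Log-transform image intensities
#'
#' The bias field is multiplicative and spatially smooth, so the model
#' works with natural-log intensities, where it becomes additive.
#' Intensities are clamped below at a small positive floor before taking
#' logs; by default the floor is `floorFrac` times a per-contrast robust
#' maximum (99th percentile over the brain mask).
#'
#' @param image a raw-intensity [MultiContrastImage-class].
#' @param floor optional explicit floor (scalar or one per contrast).
#' @param floorFrac fraction of the robust maximum used when `floor` is
#'   `NULL`.
#' @return the image with log intensities; the floors used are recorded in
#'   the `logFloor` slot.
#' @export
logTransform <- function(image, floor = NULL, floorFrac = 1e-4) {
  if (image@logTransformed) stop("image is already log-transformed")
  D <- image@intensities
  n <- ncol(D)
  if (is.null(floor)) {
    robustMax <- apply(D[image@mask, , drop = FALSE], 2L, stats::quantile,
                       probs = 0.99, names = FALSE)
    if (any(robustMax <= 0))
      stop("contrast with all non-positive intensities cannot be ",
           "log-transformed")
    floor <- floorFrac * robustMax
  } else {
    floor <- rep_len(floor, n)
    if (any(floor <= 0)) stop("log floor must be positive")
  }
  for (j in seq_len(n)) D[, j] <- log(pmax(D[, j], floor[j]))
  image@intensities <- D
  image@logTransformed <- TRUE
  image@logFloor <- floor
  image
}

#' Build a smooth bias-field basis
#'
#' Separable cosine (DCT-like) basis evaluated over the grid:
#' along each axis of length L the functions are
#' cos(pi m (x + 1/2) / L), m = 0, ..., order-1, and the full basis is the
#' tensor product across axes.  The first function is constant, so a
#' constant log-offset (global multiplicative scaling) is always in span.
#'
#' @param geometry a [GridGeometry-class].
#' @param order integer per-axis orders (recycled); P = prod(order)
#'   functions.
#' @return a [BiasBasis-class] with an I x P evaluation table.
#' @export
makeBiasBasis <- function(geometry, order = 3L) {
  d <- length(geometry@dim)
  order <- as.integer(rep_len(order, d))
  if (any(order < 1L)) stop("bias basis order must be >= 1 per axis")
  coords <- gridCoords(geometry@dim)
  axisBasis <- lapply(seq_len(d), function(a) {
    L <- geometry@dim[a]
    outer(coords[, a], seq_len(order[a]) - 1L,
          function(x, m) cos(pi * m * (x + 0.5) / L))
  })
  combos <- as.matrix(expand.grid(lapply(order, seq_len)))
  P <- nrow(combos)
  values <- matrix(1, prod(geometry@dim), P)
  for (p in seq_len(P))
    for (a in seq_len(d))
      values[, p] <- values[, p] * axisBasis[[a]][, combos[p, a]]
  new("BiasBasis", values = values, order = order)
}

## multivariate normal log density rows of X against (mean, cov)
.mvnLogDensity <- function(X, mean, cov) {
  N <- ncol(X)
  ch <- tryCatch(chol(cov), error = function(e)
    stop("covariance matrix is not positive definite"))
  R <- sweep(X, 2L, mean)
  z <- backsolve(ch, t(R), transpose = TRUE)
  -0.5 * N * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Per-voxel Gaussian class log-likelihoods
#'
#' Evaluates log N(d_i | mu_c + C phi_i, Sigma_c) for every voxel and every
#' Gaussian component, with the bias field (basis functions times the
#' per-contrast coefficients) added to the component means.  The last
#' column is the lesion Gaussian.
#'
#' @param image a log-transformed [MultiContrastImage-class].
#' @param params an [AppearanceParams-class].
#' @param basis a [BiasBasis-class] on the same grid.
#' @return numeric I x (C+1) matrix; column C+1 is the lesion component.
#' @export
classLogLikelihoods <- function(image, params, basis) {
  if (!image@logTransformed)
    stop("classLogLikelihoods expects a log-transformed image")
  D <- image@intensities
  if (ncol(D) != nrow(params@means))
    stop("contrast count mismatch between image and parameters")
  bias <- basis@values %*% params@biasCoeffs
  Dc <- D - bias
  C <- ncol(params@means)
  ll <- matrix(-Inf, nrow(D), C + 1L)
  for (c in seq_len(C))
    ll[, c] <- .mvnLogDensity(Dc, params@means[, c], params@covs[[c]])
  ll[, C + 1L] <- .mvnLogDensity(Dc, params@lesionMean, params@lesionCov)
  ll
}

## expand a per-voxel structure prior (I x K) into per-component prior
## masses (I x (C+1), lesion last), carving the lesion prior rho out of the
## host structures' mass: p(lesion) = f * rho * sum_host prior, host
## structures scaled by (1 - f * rho).  `f` is the (clamped or decoded)
## shape factor, 1 in the simplified model.
expandPriorMasses <- function(structPrior, params, rho = NULL, f = 1) {
  I <- nrow(structPrior)
  C <- ncol(params@means)
  if (is.null(rho)) rho <- rep(0, I)
  rho <- pmin(pmax(rho * f, 0), 1)
  host <- params@hostStructures
  hostMass <- rowSums(structPrior[, host, drop = FALSE])
  masses <- matrix(0, I, C + 1L)
  for (r in seq_len(nrow(params@mixture))) {
    k <- params@mixture$structure[r]
    c <- params@mixture$component[r]
    w <- params@mixture$weight[r]
    scale <- if (k %in% host) (1 - rho) else 1
    masses[, c] <- masses[, c] + w * scale * structPrior[, k]
  }
  masses[, C + 1L] <- rho * hostMass
  masses
}

#' Posterior label weights
#'
#' Soft voxel assignments: the per-component Gaussian likelihood times the
#' (component-expanded) atlas prior, normalized over components.  Computed
#' in the log domain for numerical stability.  With a lesion location prior
#' `rho`, the lesion component receives prior mass rho times the host
#' structures' mass and host structures are scaled by (1 - rho), so each
#' voxel's prior remains a probability vector.
#'
#' @inheritParams classLogLikelihoods
#' @param structPrior numeric I x K per-voxel structure prior (from
#'   [rasterizeLabelPrior()]).
#' @param rho optional lesion location prior (from
#'   [rasterizeLesionPrior()]); `NULL` disables the lesion component.
#' @param f lesion shape factor(s) in [0,1] multiplying `rho` (scalar or
#'   per-voxel); 1 in the simplified model.
#' @return numeric I x (C+1) matrix of posterior weights; masked rows sum
#'   to 1, rows outside the brain mask are 0.
#' @export
posteriorLabelWeights <- function(image, structPrior, params, basis,
                                  rho = NULL, f = 1) {
  ll <- classLogLikelihoods(image, params, basis)
  masses <- expandPriorMasses(structPrior, params, rho = rho, f = f)
  logPost <- log(masses) + ll        # -Inf where mass is 0
  logPost[masses == 0] <- -Inf
  W <- matrix(0, nrow(ll), ncol(ll))
  idx <- which(image@mask)
  lse <- logSumExpRows(logPost[idx, , drop = FALSE])
  bad <- !is.finite(lse)
  if (any(bad))
    stop("voxel ", idx[which(bad)[1L]],
         " has zero total posterior mass")
  W[idx, ] <- exp(logPost[idx, , drop = FALSE] - lse)
  W
}

## aggregate component-level weights (incl. lesion last col) to structure
## level: I x (K+1) with lesion last
aggregateToStructures <- function(weights, params, K) {
  out <- matrix(0, nrow(weights), K + 1L)
  for (r in seq_len(nrow(params@mixture)))
    out[, params@mixture$structure[r]] <-
      out[, params@mixture$structure[r]] +
      weights[, params@mixture$component[r]]
  out[, K + 1L] <- weights[, ncol(weights)]
  out
}

## log multivariate gamma function
.lmvgamma <- function(p, a) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

#' Normal-inverse-Wishart log prior on the lesion Gaussian
#'
#' Log density of the conjugate prior tying the lesion intensity Gaussian
#' to the white-matter Gaussian:
#' N(mu_les | mu_WM, Sigma_les / nu) x IW(Sigma_les | kappa nu Sigma_WM,
#' nu - N - 2).  It acts as nu pseudo-voxels with mean mu_WM and variance
#' kappa Sigma_WM.  With nu = 0 the prior is flat and the function returns
#' 0 for any arguments.
#'
#' @param lesionMean,lesionCov lesion Gaussian parameters (length-N mean,
#'   N x N covariance).
#' @param wmMean,wmCov white-matter Gaussian parameters.
#' @param nu pseudo-voxel count (>= 0), already scaled by voxel volume.
#' @param kappa variance inflation factor (> 1).
#' @return scalar log density (0 when `nu == 0`).
#' @export
niwLogPrior <- function(lesionMean, lesionCov, wmMean, wmCov, nu, kappa) {
  if (nu < 0) stop("nu must be >= 0")
  if (kappa <= 1) stop("kappa must be > 1")
  if (nu == 0) return(0)
  N <- length(lesionMean)
  m <- nu - N - 2
  if (m <= N - 1)
    stop("inverse-Wishart degrees of freedom nu - N - 2 must exceed N - 1")
  lesionCov <- as.matrix(lesionCov)
  wmCov <- as.matrix(wmCov)
  Psi <- kappa * nu * wmCov
  cInv <- solve(lesionCov)
  dmu <- lesionMean - wmMean
  logDetLes <- determinant(lesionCov, logarithm = TRUE)$modulus[1L]
  logDetPsi <- determinant(Psi, logarithm = TRUE)$modulus[1L]
  normPart <- -N / 2 * log(2 * pi) + N / 2 * log(nu) - 0.5 * logDetLes -
    nu / 2 * drop(t(dmu) %*% cInv %*% dmu)
  iwPart <- m / 2 * logDetPsi - m * N / 2 * log(2) - .lmvgamma(N, m / 2) -
    (m + N + 1) / 2 * logDetLes - 0.5 * sum(diag(Psi %*% cInv))
  normPart + iwPart
}
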