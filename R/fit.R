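#' Construct appearance parameters
#'
#' @param means N x C matrix of component means (log-intensity domain).
#' @param covs list of C covariance matrices.
#' @param biasCoeffs P x N bias coefficient matrix (default all zero needs
#'   `P`).
#' @param mixture data.frame (component, structure, weight); default one
#'   exclusive component per structure with weight 1.
#' @param lesionMean,lesionCov lesion Gaussian (defaults: prior mode given
#'   the white-matter component).
#' @param nu,kappa lesion-prior hyperparameters (effective, i.e. already
#'   voxel-volume scaled).
#' @param wmComponent,gmComponent,hostStructures model roles (see
#'   [AppearanceParams-class]).
#' @param diagonalCov logical covariance mode.
#' @param P number of bias basis functions when `biasCoeffs` is `NULL`.
#' @return an [AppearanceParams-class].
#' @export
appearanceParams <- function(means, covs, biasCoeffs = NULL, mixture = NULL,
                             lesionMean = NULL, lesionCov = NULL,
                             nu = 500, kappa = 50, wmComponent = NA,
                             gmComponent = NA, hostStructures = NULL,
                             diagonalCov = TRUE, P = 1L) {
  means <- as.matrix(means)
  C <- ncol(means)
  if (is.null(biasCoeffs)) biasCoeffs <- matrix(0, P, nrow(means))
  if (is.null(mixture))
    mixture <- data.frame(component = seq_len(C), structure = seq_len(C),
                          weight = 1)
  wmComponent <- as.integer(wmComponent)
  if (is.null(lesionMean)) {
    if (is.na(wmComponent)) stop("need lesionMean or wmComponent")
    lesionMean <- means[, wmComponent]
  }
  if (is.null(lesionCov)) lesionCov <- kappa * covs[[wmComponent]]
  if (is.null(hostStructures)) {
    hostStructures <- if (!is.na(wmComponent))
      unique(mixture$structure[mixture$component == wmComponent])
    else integer(0)
  }
  new("AppearanceParams", means = means, covs = covs,
      biasCoeffs = as.matrix(biasCoeffs), mixture = mixture,
      lesionMean = as.numeric(lesionMean), lesionCov = as.matrix(lesionCov),
      nu = nu, kappa = kappa, wmComponent = wmComponent,
      gmComponent = as.integer(gmComponent),
      hostStructures = as.integer(hostStructures),
      diagonalCov = diagonalCov)
}

#' MAP update of the lesion Gaussian under the normal-inverse-Wishart prior
#'
#' Closed-form maximizer of the responsibility-weighted lesion
#' log-likelihood plus [niwLogPrior()], obtained from conjugacy: the prior
#' acts as `nu` pseudo-voxels with mean `wmMean` and variance
#' `kappa * wmCov`.  With `nu = 0` this is the unregularized weighted
#' maximum-likelihood update; with zero total responsibility it returns the
#' prior mode (`wmMean`, `kappa * wmCov`).
#'
#' @param resp numeric vector of per-voxel lesion responsibilities (>= 0).
#' @param data numeric I x N matrix of bias-corrected log intensities.
#' @param wmMean,wmCov white-matter Gaussian parameters.
#' @param nu,kappa prior hyperparameters.
#' @param diagonal logical; return a diagonal covariance.
#' @return list with elements `mean` and `cov`.
#' @export
niwMapUpdate <- function(resp, data, wmMean, wmCov, nu, kappa,
                         diagonal = FALSE) {
  data <- as.matrix(data)
  wmCov <- as.matrix(wmCov)
  if (any(resp < 0)) stop("responsibilities must be nonnegative")
  R <- sum(resp)
  if (R > 0) {
    m <- colSums(resp * data) / R
    Xc <- sweep(data, 2L, m)
    S <- crossprod(Xc * resp, Xc)
  } else {
    m <- wmMean
    S <- matrix(0, ncol(data), ncol(data))
  }
  if (nu == 0 && R == 0) return(list(mean = wmMean, cov = kappa * wmCov))
  mu <- (nu * wmMean + R * m) / (nu + R)
  dd <- m - wmMean
  Psi <- kappa * nu * wmCov + S + (nu * R / max(nu + R, 1e-300)) *
    tcrossprod(dd)
  cov <- Psi / (nu + R)
  if (diagonal) cov <- diag(diag(cov), ncol(data))
  list(mean = mu, cov = cov)
}

#' Weighted least-squares update of the bias-field coefficients
#'
#' Exact maximizer of the expected complete-data log-likelihood over the
#' bias coefficients given the current responsibilities, means and
#' covariances: solves the (N P) x (N P) normal equations coupling all
#' contrasts through the component precisions.  Falls back to a ridge
#' solution with a warning if the system is singular.
#'
#' @param image log-transformed [MultiContrastImage-class].
#' @param weights I x (C+1) responsibility matrix (lesion last column).
#' @param params an [AppearanceParams-class].
#' @param basis a [BiasBasis-class].
#' @return P x N coefficient matrix.
#' @export
updateBias <- function(image, weights, params, basis) {
  idx <- which(image@mask)
  D <- image@intensities[idx, , drop = FALSE]
  Phi <- basis@values[idx, , drop = FALSE]
  W <- weights[idx, , drop = FALSE]
  N <- ncol(D)
  P <- ncol(Phi)
  C <- ncol(params@means)
  allMeans <- cbind(params@means, params@lesionMean)
  allCovs <- c(params@covs, list(params@lesionCov))
  Lbar <- matrix(0, length(idx), N * N)     # row i holds vec(Lambda-bar_i)
  Tm <- matrix(0, length(idx), N)           # row i holds t_i
  for (c in seq_len(C + 1L)) {
    Lam <- solve(allCovs[[c]])
    Lbar <- Lbar + W[, c] %o% as.numeric(Lam)
    Rc <- sweep(D, 2L, allMeans[, c])
    Tm <- Tm + (W[, c] * Rc) %*% Lam
  }
  A <- matrix(0, N * P, N * P)
  b <- numeric(N * P)
  for (p in seq_len(P)) {
    for (q in seq_len(p)) {
      blk <- matrix(colSums(Phi[, p] * Phi[, q] * Lbar), N, N)
      rp <- (p - 1L) * N + seq_len(N)
      rq <- (q - 1L) * N + seq_len(N)
      A[rp, rq] <- blk
      A[rq, rp] <- t(blk)
    }
    b[(p - 1L) * N + seq_len(N)] <- colSums(Phi[, p] * Tm)
  }
  sol <- tryCatch(solve(A, b), error = function(e) {
    warning("singular bias normal equations; using ridge fallback")
    solve(A + diag(1e-8 * mean(diag(A)), nrow(A)), b)
  })
  Cmat <- matrix(sol, N, P)                 # row n = coefficients c_n
  t(Cmat)                                   # P x N
}

## ---- deformation optimization -------------------------------------------

## per-voxel prior fields at given vertex positions; returns structure
## prior A (I x K), lesion prior rho (I), and the rasterization
.deformedPriors <- function(positions, atlas) {
  raster <- rasterizeMesh(positions, atlas@simplices, atlas@geometry@dim)
  K <- ncol(atlas@labelProbs)
  both <- interpolateVertexValues(raster, atlas@simplices,
                                  cbind(atlas@labelProbs,
                                        atlas@lesionProbs))
  A <- both[, seq_len(K), drop = FALSE]
  if (any(!raster$inside))
    A[!raster$inside, match("background", atlas@labels, nomatch = 1L)] <- 1
  A[A < 0] <- 0
  A <- A / rowSums(A)
  rho <- pmin(pmax(both[, K + 1L], 0), 1)
  list(A = A, rho = rho, raster = raster)
}

## marginal data term sum_i log sum_c mass_ic exp(ll_ic) over masked voxels
.deformDataTerm <- function(A, rho, ll, params, mask) {
  masses <- expandPriorMasses(A, params, rho = rho)
  lp <- log(masses) + ll
  lp[masses == 0] <- -Inf
  sum(logSumExpRows(lp[mask, , drop = FALSE]))
}

#' Update the mesh deformation
#'
#' Gradient ascent with backtracking line search on the exact marginal
#' objective (per-voxel log mixture likelihood under the deformed atlas
#' prior) plus the topology-preserving deformation log prior.  Steps
#' producing a folded mesh are rejected by the line search; on line-search
#' failure the input state is returned unchanged.
#'
#' @param image log-transformed [MultiContrastImage-class].
#' @param atlas a [MeshAtlas-class].
#' @param deformation current [DeformationState-class].
#' @param params an [AppearanceParams-class].
#' @param basis a [BiasBasis-class].
#' @param nSteps number of ascent steps.
#' @param stepSize initial maximum vertex displacement per step (voxels).
#' @param rigidSearch also run an axis-aligned whole-mesh translation line
#'   search after the gradient steps (recovers bulk misalignment; the
#'   deformation prior is translation-invariant).
#' @return the updated (never folded) [DeformationState-class].
#' @export
updateDeformation <- function(image, atlas, deformation, params, basis,
                              nSteps = 2L, stepSize = 0.5,
                              rigidSearch = TRUE) {
  ll <- classLogLikelihoods(image, params, basis)
  mask <- image@mask
  K <- ncol(atlas@labelProbs)
  host <- params@hostStructures
  objective <- function(pos) {
    if (any(simplexVolumes(pos, atlas@simplices) <= 0)) return(-Inf)
    pr <- .deformedPriors(pos, atlas)
    .deformDataTerm(pr$A, pr$rho, ll, params, mask) -
      atlas@stiffness * sum(.simplexPenalties(pos, atlas))
  }
  pos <- deformation@positions
  for (step in seq_len(nSteps)) {
    pr <- .deformedPriors(pos, atlas)
    W <- posteriorLabelWeights(image, pr$A, params, basis, rho = pr$rho)
    u <- aggregateToStructures(W, params, K)       # I x (K+1)
    v <- u[, K + 1L]
    uStruct <- u[, seq_len(K), drop = FALSE]
    hostMassA <- rowSums(pr$A[, host, drop = FALSE])
    ## dQ/dA_ik and dQ/drho_i (safe divisions: 0 numerator -> 0)
    dA <- matrix(0, nrow(uStruct), K)
    for (k in seq_len(K)) {
      num <- uStruct[, k]
      dA[, k] <- ifelse(num > 0, num / pmax(pr$A[, k], 1e-300), 0)
      if (k %in% host)
        dA[, k] <- dA[, k] + ifelse(v > 0, v / pmax(hostMassA, 1e-300), 0)
    }
    uHost <- rowSums(uStruct[, host, drop = FALSE])
    dRho <- ifelse(v > 0, v / pmax(pr$rho, 1e-300), 0) -
      ifelse(uHost > 0, uHost / pmax(1 - pr$rho, 1e-300), 0)
    dA[!mask, ] <- 0
    dRho[!mask] <- 0
    ## chain rule through barycentric weights to vertex positions
    d <- ncol(pos)
    grad <- matrix(0, nrow(pos), d)
    raster <- pr$raster
    for (s in unique(raster$simplex[raster$inside])) {
      idx <- which(raster$simplex == s)
      verts <- atlas@simplices[s, ]
      g <- dA[idx, , drop = FALSE] %*% t(atlas@labelProbs[verts, ,
                                                          drop = FALSE]) +
        dRho[idx] %o% atlas@lesionProbs[verts]
      U <- g %*% raster$G[, seq_len(d), s]
      lam <- raster$lambda[idx, , drop = FALSE]
      for (a in seq_len(d + 1L))
        grad[verts[a], ] <- grad[verts[a], ] - colSums(lam[, a] * U)
    }
    grad <- grad + deformationLogPriorGrad(
      new("DeformationState", positions = pos), atlas)
    gmax <- max(abs(grad))
    if (!is.finite(gmax) || gmax == 0) break
    dir <- grad / gmax                      # max displacement = t voxels
    f0 <- objective(pos)
    t <- stepSize
    accepted <- FALSE
    for (ls in 1:12) {
      cand <- pos + t * dir
      f1 <- objective(cand)
      if (is.finite(f1) && f1 > f0) {
        pos <- cand
        accepted <- f1 - f0 > 1e-3   # stop once gains are negligible
        break
      }
      t <- t / 2
    }
    if (!accepted) break
  }
  ## rigid refinement: axis-aligned translation line search (the
  ## deformation prior is translation-invariant, so this recovers bulk
  ## misalignment that local gradient ascent approaches only slowly)
  if (!rigidSearch) return(new("DeformationState", positions = pos))
  f0 <- objective(pos)
  for (a in seq_len(ncol(pos))) {
    for (sgn in c(1, -1)) {
      t <- stepSize
      repeat {
        cand <- pos
        cand[, a] <- cand[, a] + sgn * t
        f1 <- objective(cand)
        if (is.finite(f1) && f1 > f0 + 1e-9) {
          pos <- cand
          f0 <- f1
        } else {
          t <- t / 2
          if (t < stepSize / 8) break
        }
      }
    }
  }
  new("DeformationState", positions = pos)
}

## ---- the generalized-EM fit ---------------------------------------------

## mixture-row-level E step: responsibilities over mixture rows + lesion.
## Returns row weights (I x (R+1)), per-voxel log evidence, and the
## component log likelihood matrix.
.rowPosterior <- function(image, A, params, basis, rho) {
  ll <- classLogLikelihoods(image, params, basis)
  mix <- params@mixture
  nR <- nrow(mix)
  host <- params@hostStructures
  I <- nrow(A)
  logMass <- matrix(-Inf, I, nR + 1L)
  for (r in seq_len(nR)) {
    k <- mix$structure[r]
    mass <- mix$weight[r] * A[, k]
    if (k %in% host) mass <- mass * (1 - rho)
    logMass[, r] <- log(mass) + ll[, mix$component[r]]
  }
  hostMass <- rowSums(A[, host, drop = FALSE])
  lesMass <- rho * hostMass
  logMass[, nR + 1L] <- log(lesMass) + ll[, ncol(ll)]
  logMass[!is.finite(logMass)] <- -Inf
  idx <- which(image@mask)
  lse <- logSumExpRows(logMass[idx, , drop = FALSE])
  if (any(!is.finite(lse)))
    stop("voxel ", idx[which(!is.finite(lse))[1L]],
         " has zero total posterior mass")
  W <- matrix(0, I, nR + 1L)
  W[idx, ] <- exp(logMass[idx, , drop = FALSE] - lse)
  list(W = W, evidence = sum(lse), ll = ll)
}

## collapse row-level weights to component-level (lesion last)
.rowToComponent <- function(Wrows, params) {
  C <- ncol(params@means)
  out <- matrix(0, nrow(Wrows), C + 1L)
  for (r in seq_len(nrow(params@mixture)))
    out[, params@mixture$component[r]] <-
      out[, params@mixture$component[r]] + Wrows[, r]
  out[, C + 1L] <- Wrows[, ncol(Wrows)]
  out
}

## WM-block objective used by the monotonicity safeguard: weighted WM
## log likelihood + NIW prior term (which depends on the WM parameters)
.wmBlockObjective <- function(mu, cov, respWM, Dc, params) {
  sum(respWM * .mvnLogDensity(Dc, mu, cov)) +
    niwLogPrior(params@lesionMean, params@lesionCov, mu, cov,
                params@nu, params@kappa)
}

#' Fit the generative model to an image
#'
#' Point estimation of the appearance parameters, lesion Gaussian, bias
#' field and mesh deformation by generalized-EM coordinate ascent on the
#' simplified model (lesion shape factors clamped to 1):
#' E-step responsibilities over all Gaussian components including the
#' lesion (whose spatial prior is the interpolated lesion map carved out of
#' the host structures' prior mass); closed-form M-step for means and
#' covariances with the lesion update MAP-regularized by the
#' normal-inverse-Wishart prior; weighted-least-squares bias update; and
#' gradient ascent with fold rejection for the mesh deformation.  The
#' recorded log-posterior trace is non-decreasing.
#'
#' @param image a [MultiContrastImage-class] (raw images are
#'   log-transformed automatically).
#' @param atlas a [MeshAtlas-class] on the same grid.
#' @param config a [FitConfig-class].
#' @return a [FitResult-class].
#' @export
fitParameters <- function(image, atlas, config = fitConfig()) {
  if (!all(atlas@geometry@dim == image@geometry@dim))
    stop("image and atlas grids are incompatible")
  if (!image@logTransformed) image <- logTransform(image)
  geom <- image@geometry
  basis <- makeBiasBasis(geom, config@biasOrder)
  nuEff <- config@nu / prod(geom@voxelSize)
  K <- ncol(atlas@labelProbs)
  labels <- atlas@labels
  idx <- which(image@mask)
  D <- image@intensities
  N <- ncol(D)

  ## initialization: identity deformation, prior-weighted means, global
  ## covariance, zero bias, lesion at its prior mode
  deformation <- deformationState(atlas)
  pr <- .deformedPriors(deformation@positions, atlas)
  globalCov <- stats::cov(D[idx, , drop = FALSE])
  if (config@diagonalCov) globalCov <- diag(diag(globalCov), N)
  means <- matrix(0, N, K)
  for (k in seq_len(K)) {
    wk <- pr$A[idx, k]
    means[, k] <- if (sum(wk) > 0) colSums(wk * D[idx, , drop = FALSE]) /
      sum(wk) else colMeans(D[idx, , drop = FALSE])
  }
  covs <- rep(list(globalCov), K)
  wmComp <- grep("wm|white", labels, ignore.case = TRUE)[1L]
  if (is.na(wmComp)) wmComp <- K
  gmComp <- grep("^gm$|gray|grey|cortex", labels, ignore.case = TRUE)[1L]
  params <- appearanceParams(means, covs, P = ncol(basis@values),
                             nu = nuEff, kappa = config@kappa,
                             wmComponent = wmComp, gmComponent = gmComp,
                             diagonalCov = config@diagonalCov)
  varFloor <- 1e-8 * diag(globalCov)

  objective <- function(params, deformation, pr) {
    dataTerm <- .rowPosterior(image, pr$A, params, basis, pr$rho)$evidence
    dataTerm + deformationLogPrior(deformation, atlas) +
      niwLogPrior(params@lesionMean, params@lesionCov,
                  params@means[, params@wmComponent],
                  params@covs[[params@wmComponent]],
                  params@nu, params@kappa)
  }

  trace <- numeric(0)
  converged <- FALSE
  deformStalls <- 0L
  for (outer in seq_len(config@maxOuterIters)) {
    for (inner in seq_len(config@innerEmIters)) {
      ep <- .rowPosterior(image, pr$A, params, basis, pr$rho)
      Wc <- .rowToComponent(ep$W, params)
      bias <- basis@values %*% params@biasCoeffs
      Dc <- D - bias
      C <- ncol(params@means)
      ## mixture weight update (row-level responsibilities)
      mix <- params@mixture
      rowR <- colSums(ep$W[idx, seq_len(nrow(mix)), drop = FALSE])
      for (k in unique(mix$structure)) {
        rows <- which(mix$structure == k)
        tot <- sum(rowR[rows])
        if (tot > 0) mix$weight[rows] <- rowR[rows] / tot
      }
      params@mixture <- mix
      ## Gaussian updates (WM safeguarded for the NIW coupling)
      for (c in seq_len(C)) {
        resp <- Wc[idx, c]
        R <- sum(resp)
        if (R < 1e-8) next
        muNew <- colSums(resp * Dc[idx, , drop = FALSE]) / R
        Xc <- sweep(Dc[idx, , drop = FALSE], 2L, muNew)
        covNew <- crossprod(Xc * resp, Xc) / R
        if (config@diagonalCov) covNew <- diag(diag(covNew), N)
        dg <- diag(covNew)
        if (any(dg < varFloor))
          diag(covNew) <- pmax(dg, varFloor)
        if (c == params@wmComponent && params@nu > 0) {
          muOld <- params@means[, c]
          covOld <- params@covs[[c]]
          f0 <- .wmBlockObjective(muOld, covOld, resp,
                                  Dc[idx, , drop = FALSE], params)
          t <- 1
          for (bt in 1:20) {
            muT <- muOld + t * (muNew - muOld)
            covT <- covOld + t * (covNew - covOld)
            f1 <- .wmBlockObjective(muT, covT, resp,
                                    Dc[idx, , drop = FALSE], params)
            if (is.finite(f1) && f1 >= f0) break
            t <- t / 2
            if (bt == 20L) t <- 0
          }
          muNew <- muOld + t * (muNew - muOld)
          covNew <- covOld + t * (covNew - covOld)
        }
        params@means[, c] <- muNew
        params@covs[[c]] <- covNew
      }
      ## lesion MAP update under the NIW prior
      les <- niwMapUpdate(Wc[idx, C + 1L], Dc[idx, , drop = FALSE],
                          params@means[, params@wmComponent],
                          params@covs[[params@wmComponent]],
                          params@nu, params@kappa,
                          diagonal = config@diagonalCov)
      params@lesionMean <- les$mean
      params@lesionCov <- les$cov
      ## bias update (exact weighted least squares)
      ep2 <- .rowPosterior(image, pr$A, params, basis, pr$rho)
      params@biasCoeffs <- updateBias(image, .rowToComponent(ep2$W, params),
                                      params, basis)
      ## gauge fix: the constant basis function and the class means span
      ## the same global log offset; fold it into the means so both are
      ## identifiable (pure reparameterization, objective unchanged)
      shift <- params@biasCoeffs[1L, ]
      params@means <- sweep(params@means, 1L, shift, "+")
      params@lesionMean <- params@lesionMean + shift
      params@biasCoeffs[1L, ] <- 0
    }
    ## deformation update (frozen once it stops moving the mesh)
    if (config@deformIters > 0L && deformStalls < 2L) {
      newDef <- updateDeformation(image, atlas, deformation, params,
                                  basis, nSteps = config@deformIters,
                                  stepSize = config@deformStepSize,
                                  rigidSearch = outer <= 2L)
      if (max(abs(newDef@positions - deformation@positions)) < 1e-8)
        deformStalls <- deformStalls + 1L
      else deformStalls <- 0L
      deformation <- newDef
      pr <- .deformedPriors(deformation@positions, atlas)
    }
    obj <- objective(params, deformation, pr)
    trace <- c(trace, obj)
    if (outer > 1L) {
      rel <- abs(obj - trace[outer - 1L]) /
        max(abs(trace[outer - 1L]), 1e-12)
      if (rel < config@emTolerance) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("generalized EM did not converge within maxOuterIters")
  new("FitResult", params = params, deformation = deformation,
      objectiveTrace = trace, converged = converged, structures = labels)
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d structures, %d outer iterations (%s)\n",
              length(object@structures), length(object@objectiveTrace),
              if (object@converged) "converged" else "not converged"))
  cat(sprintf("  final log posterior: %.3f\n",
              utils::tail(object@objectiveTrace, 1L)))
})
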