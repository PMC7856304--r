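#' Construct a mesh atlas
#'
#' Low-level constructor; most users build atlases with
#' [buildRegularAtlas()] or [makeAtlasFromPhantoms()].
#'
#' @param vertices,simplices,labelProbs,lesionProbs,labels,stiffness,geometry
#'   see [MeshAtlas-class].
#' @return a [MeshAtlas-class].
#' @export
meshAtlas <- function(vertices, simplices, labelProbs, lesionProbs, labels,
                      geometry, stiffness = 1) {
  new("MeshAtlas", vertices = as.matrix(vertices),
      simplices = as.matrix(simplices), labelProbs = as.matrix(labelProbs),
      lesionProbs = as.numeric(lesionProbs), labels = labels,
      stiffness = stiffness, geometry = geometry)
}

setMethod("show", "MeshAtlas", function(object) {
  cat(sprintf("MeshAtlas: %d vertices, %d simplices (%d-D), %d labels\n",
              nrow(object@vertices), nrow(object@simplices),
              ncol(object@vertices), length(object@labels)))
  cat("  labels:", paste(object@labels, collapse = ", "), "\n")
  cat(sprintf("  lesion prior mass: %.3f, stiffness: %g\n",
              mean(object@lesionProbs), object@stiffness))
})

#' Is a deformation topologically valid?
#'
#' A deformation is valid iff every simplex of its atlas retains a positive
#' signed volume (the mesh has not torn or folded).
#'
#' @param atlas a [MeshAtlas-class].
#' @param deformation a [DeformationState-class].
#' @return logical scalar.
#' @export
validDeformation <- function(atlas, deformation) {
  if (nrow(deformation@positions) != nrow(atlas@vertices))
    stop("deformation vertex count does not match atlas")
  all(simplexVolumes(deformation@positions, atlas@simplices) > 0)
}

#' Rasterize the atlas label prior
#'
#' Evaluates the per-voxel prior probability of each anatomical label by
#' piecewise-linear (barycentric) interpolation of the per-vertex label
#' probabilities at the current mesh deformation.  Each voxel's K-vector
#' sums to 1.
#'
#' @param atlas a [MeshAtlas-class].
#' @param deformation a [DeformationState-class]; `NULL` means the
#'   reference (identity) configuration.
#' @param outside what to do with voxels falling outside the deformed mesh:
#'   `"background"` assigns them the first (background) label, `"error"`
#'   fails.
#' @return numeric I x K matrix of per-voxel label priors.
#' @export
rasterizeLabelPrior <- function(atlas, deformation = NULL,
                                outside = c("background", "error")) {
  outside <- match.arg(outside)
  if (is.null(deformation)) deformation <- deformationState(atlas)
  if (!validDeformation(atlas, deformation))
    stop("rejected: folded (invalid) mesh deformation")
  raster <- rasterizeMesh(deformation@positions, atlas@simplices,
                          atlas@geometry@dim)
  if (outside == "error" && !all(raster$inside))
    stop("voxels outside the deformed mesh support")
  prior <- interpolateVertexValues(raster, atlas@simplices,
                                   atlas@labelProbs)
  if (any(!raster$inside)) {
    bg <- match("background", atlas@labels, nomatch = 1L)
    prior[!raster$inside, bg] <- 1
  }
  ## clip tiny negative interpolation round-off and renormalize
  prior[prior < 0] <- 0
  prior / rowSums(prior)
}

#' Rasterize the lesion location prior
#'
#' Interpolates the per-vertex lesion probabilities at the current mesh
#' deformation, yielding the voxelwise prior probability of lesion
#' occurrence based on spatial location alone.  The map deforms in
#' conjunction with the anatomical atlas.
#'
#' @inheritParams rasterizeLabelPrior
#' @return numeric vector (I) with values in [0,1]; 0 outside the mesh.
#' @export
rasterizeLesionPrior <- function(atlas, deformation = NULL,
                                 outside = c("background", "error")) {
  outside <- match.arg(outside)
  if (is.null(deformation)) deformation <- deformationState(atlas)
  if (!validDeformation(atlas, deformation))
    stop("rejected: folded (invalid) mesh deformation")
  raster <- rasterizeMesh(deformation@positions, atlas@simplices,
                          atlas@geometry@dim)
  if (outside == "error" && !all(raster$inside))
    stop("voxels outside the deformed mesh support")
  rho <- interpolateVertexValues(raster, atlas@simplices,
                                 cbind(atlas@lesionProbs))[, 1L]
  pmin(pmax(rho, 0), 1)
}

## per-simplex deformation penalty terms (shared by value and oracle tests):
## squared log volume ratio plus squared relative edge-length distortion
.simplexPenalties <- function(positions, atlas) {
  ref <- atlas@vertices
  simp <- atlas@simplices
  vRef <- simplexVolumes(ref, simp)
  vDef <- simplexVolumes(positions, simp)
  if (any(vDef <= 0)) return(NULL)
  d <- ncol(ref)
  pairs <- utils::combn(d + 1L, 2L)
  pen <- (log(vDef / vRef))^2
  for (p in seq_len(ncol(pairs))) {
    a <- simp[, pairs[1L, p]]
    b <- simp[, pairs[2L, p]]
    eRef <- sqrt(rowSums((ref[a, , drop = FALSE] -
                          ref[b, , drop = FALSE])^2))
    eDef <- sqrt(rowSums((positions[a, , drop = FALSE] -
                          positions[b, , drop = FALSE])^2))
    pen <- pen + (eDef / eRef - 1)^2
  }
  pen
}

#' Log prior of a mesh deformation
#'
#' Topology-preserving deformation prior: the log density (up to a
#' constant) is minus the stiffness-weighted sum over simplices of a
#' squared log volume-ratio term and a squared relative edge-length
#' distortion term.  It is 0 at the reference configuration, decreases with
#' deviation from it, and returns `-Inf` whenever any simplex volume is
#' non-positive (a torn or folded mesh).
#'
#' @inheritParams rasterizeLabelPrior
#' @return scalar log prior (`-Inf` for invalid deformations).
#' @export
deformationLogPrior <- function(deformation, atlas) {
  if (nrow(deformation@positions) != nrow(atlas@vertices))
    stop("deformation vertex count does not match atlas")
  pen <- .simplexPenalties(deformation@positions, atlas)
  if (is.null(pen)) return(-Inf)
  -atlas@stiffness * sum(pen)
}

## gradient of deformationLogPrior wrt vertex positions (finite differences
## over the cheap per-simplex functional); returns J x d matrix
deformationLogPriorGrad <- function(deformation, atlas, h = 1e-5) {
  pos <- deformation@positions
  f <- function(v) {
    p <- .simplexPenalties(matrix(v, nrow(pos)), atlas)
    if (is.null(p)) return(-Inf)
    -atlas@stiffness * sum(p)
  }
  matrix(numGrad(f, as.numeric(pos), h = h), nrow(pos))
}

## EM for per-vertex categorical probabilities under linear interpolation:
## p(class k at voxel i) = sum_j theta_jk psi_ji.  `rasters` is a list of
## rasterizations (one per training map), `Y` a list of I x K soft class
## indicator matrices.  Vertices with no voxel support stay uniform.
vertexProbEM <- function(rasters, Y, simplices, J, maxIter = 50,
                         tol = 1e-7) {
  K <- ncol(Y[[1L]])
  theta <- matrix(1 / K, J, K)
  for (it in seq_len(maxIter)) {
    num <- matrix(0, J, K)
    for (m in seq_along(rasters)) {
      r <- rasters[[m]]
      for (s in unique(r$simplex[r$inside])) {
        idx <- which(r$simplex == s)
        verts <- simplices[s, ]
        P <- r$lambda[idx, , drop = FALSE]
        Th <- theta[verts, , drop = FALSE]
        Ys <- Y[[m]][idx, , drop = FALSE]
        denom <- rowSums((P %*% Th) * Ys)
        denom[denom <= 0] <- 1
        num[verts, ] <- num[verts, ] + Th * (t(P / denom) %*% Ys)
      }
    }
    tot <- rowSums(num)
    thetaNew <- theta
    supp <- tot > 0
    thetaNew[supp, ] <- num[supp, , drop = FALSE] / tot[supp]
    delta <- max(abs(thetaNew - theta))
    theta <- thetaNew
    if (delta < tol) break
  }
  theta
}

#' Estimate the per-vertex lesion probabilities
#'
#' Given binary lesion masks with their fitted mesh deformations, estimates
#' the vertex lesion probabilities that maximize the interpolated-Bernoulli
#' likelihood of the masks via expectation-maximization over the
#' interpolation weights (the same technique used for the anatomical label
#' probabilities).
#'
#' @param atlas a [MeshAtlas-class].
#' @param deformations list of [DeformationState-class], one per mask.
#' @param lesionMasks list of logical/0-1 vectors or arrays on the atlas
#'   grid.
#' @param maxIter,tol EM controls.
#' @return the atlas with its `lesionProbs` slot replaced by the estimates.
#' @export
estimateLesionProbMap <- function(atlas, deformations, lesionMasks,
                                  maxIter = 50, tol = 1e-7) {
  if (length(lesionMasks) == 0L) stop("empty training set")
  if (length(deformations) != length(lesionMasks))
    stop("one deformation per lesion mask required")
  rasters <- lapply(deformations, function(dd) {
    rasterizeMesh(dd@positions, atlas@simplices, atlas@geometry@dim)
  })
  Y <- lapply(lesionMasks, function(z) {
    z <- as.numeric(z)
    cbind(z, 1 - z)
  })
  theta <- vertexProbEM(rasters, Y, atlas@simplices, nrow(atlas@vertices),
                        maxIter = maxIter, tol = tol)
  atlas@lesionProbs <- pmin(pmax(theta[, 1L], 0), 1)
  atlas
}

#' Build a regular mesh atlas from training label maps
#'
#' Lays a regular simplex mesh (triangles in 2-D, tetrahedra in 3-D) at the
#' requested spacing over the grid and estimates the per-vertex label
#' probabilities from aligned training label maps by interpolated-
#' likelihood EM.  Label 1 is the background label.
#'
#' @param labelMaps list of integer vectors/arrays (values 1..K) on a
#'   common grid.
#' @param geometry a [GridGeometry-class] describing that grid.
#' @param spacing mesh vertex spacing in voxels.
#' @param labels optional character label names (length K).
#' @param stiffness deformation-prior weight.
#' @param maxIter,tol EM controls.
#' @return a [MeshAtlas-class] with zero lesion probabilities (see
#'   [estimateLesionProbMap()]).
#' @export
buildRegularAtlas <- function(labelMaps, geometry, spacing, labels = NULL,
                              stiffness = 1, maxIter = 50, tol = 1e-7) {
  if (length(labelMaps) == 0L) stop("no training label maps")
  if (any(spacing >= geometry@dim)) stop("mesh spacing exceeds grid extent")
  K <- max(vapply(labelMaps, function(m) max(as.integer(m)), 1L))
  if (is.null(labels)) labels <- c("background",
                                   paste0("structure", seq_len(K - 1L)))
  mesh <- buildRegularMesh(geometry@dim, spacing)
  raster <- rasterizeMesh(mesh$vertices, mesh$simplices, geometry@dim)
  rasters <- rep(list(raster), length(labelMaps))
  Y <- lapply(labelMaps, function(m) {
    m <- as.integer(m)
    Ym <- matrix(0, length(m), K)
    Ym[cbind(seq_along(m), m)] <- 1
    Ym
  })
  alpha <- vertexProbEM(rasters, Y, mesh$simplices, nrow(mesh$vertices),
                        maxIter = maxIter, tol = tol)
  alpha <- pmax(alpha, 0)
  alpha <- alpha / rowSums(alpha)
  meshAtlas(mesh$vertices, mesh$simplices, alpha,
            rep(0, nrow(mesh$vertices)), labels, geometry,
            stiffness = stiffness)
}
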