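## Mesh atlas: interpolation semantics, deformation prior, vertex EM.

smallAtlas <- function(K = 3, spacing = 4, dim = c(9L, 9L), beta = NULL,
                       stiffness = 1) {
  mesh <- wmlseg:::buildRegularMesh(dim, spacing)
  J <- nrow(mesh$vertices)
  set.seed(42)
  alpha <- matrix(rexp(J * K), J, K)
  alpha <- alpha / rowSums(alpha)
  if (is.null(beta)) beta <- rep(0, J)
  meshAtlas(mesh$vertices, mesh$simplices, alpha, beta,
            paste0("s", seq_len(K)), gridGeometry(dim), stiffness)
}

test_that("regular meshes cover the grid with positively oriented simplices", {
  for (dim in list(c(9L, 9L), c(7L, 5L, 6L))) {
    mesh <- wmlseg:::buildRegularMesh(dim, 3)
    vols <- wmlseg:::simplexVolumes(mesh$vertices, mesh$simplices)
    expect_true(all(vols > 0))
    raster <- wmlseg:::rasterizeMesh(mesh$vertices, mesh$simplices, dim)
    expect_true(all(raster$inside))
    ## total simplex volume equals the grid extent
    expect_equal(sum(vols), prod(dim - 1))
  }
})

test_that("label prior interpolation is exact at vertices and normalized", {
  at <- smallAtlas()
  prior <- rasterizeLabelPrior(at)
  expect_equal(rowSums(prior), rep(1, nrow(prior)), tolerance = 1e-9)
  ## voxels at vertex locations reproduce the vertex rows exactly
  vidx <- at@vertices[, 1] + at@vertices[, 2] * at@geometry@dim[1] + 1
  expect_equal(prior[vidx, ], unname(at@labelProbs), tolerance = 1e-12)
})

test_that("uniform label probabilities give a uniform prior under any deformation", {
  at <- smallAtlas()
  at@labelProbs[] <- 1 / 3
  def <- deformationState(at)
  set.seed(7)
  def@positions <- def@positions +
    matrix(rnorm(length(def@positions), 0, 0.2), nrow(def@positions))
  stopifnot(validDeformation(at, def))
  prior <- rasterizeLabelPrior(at, def)
  inside <- wmlseg:::rasterizeMesh(def@positions, at@simplices,
                                   at@geometry@dim)$inside
  expect_equal(prior[inside, ], matrix(1 / 3, sum(inside), 3),
               tolerance = 1e-9)
})

test_that("barycenter of a triangle with one-hot vertex rows gives 1/3 each", {
  ## single triangle mesh with rows e1, e2, e3
  verts <- rbind(c(0, 0), c(3, 0), c(0, 3))
  at <- meshAtlas(verts, matrix(1:3, 1), diag(3), rep(0, 3),
                  c("a", "b", "c"), gridGeometry(c(4L, 4L)), 1)
  bary <- colMeans(verts)
  w <- bruteForceInterp(verts, matrix(1:3, 1), diag(3), rbind(bary))
  expect_equal(drop(w), rep(1 / 3, 3), tolerance = 1e-12)
  raster <- wmlseg:::rasterizeMesh(verts, matrix(1:3, 1), c(4L, 4L))
  vals <- wmlseg:::interpolateVertexValues(raster, matrix(1:3, 1), diag(3))
  i11 <- 1 + 1 * 4 + 1  # voxel (1,1), inside the triangle
  expect_equal(vals[i11, ], drop(bruteForceInterp(verts, matrix(1:3, 1),
                                                  diag(3), rbind(c(1, 1)))),
               tolerance = 1e-12)
})

test_that("rasterization agrees with the brute-force barycentric oracle", {
  at <- smallAtlas(K = 4, spacing = 4, dim = c(9L, 9L))
  def <- deformationState(at)
  set.seed(3)
  def@positions <- def@positions +
    matrix(rnorm(length(def@positions), 0, 0.3), nrow(def@positions))
  stopifnot(validDeformation(at, def))
  prior <- rasterizeLabelPrior(at, def)
  pts <- gridCoords <- wmlseg:::gridCoords(at@geometry@dim)
  oracle <- bruteForceInterp(def@positions, at@simplices, at@labelProbs,
                             pts)
  inside <- !is.na(oracle[, 1])
  expect_gt(sum(inside), 50)
  expect_equal(prior[inside, ], oracle[inside, ], tolerance = 1e-9)
})

test_that("lesion prior interpolates beta fields correctly", {
  at <- smallAtlas()
  expect_equal(rasterizeLesionPrior(at), rep(0, 81))
  at2 <- at; at2@lesionProbs <- rep(0.2, nrow(at@vertices))
  expect_equal(rasterizeLesionPrior(at2), rep(0.2, 81), tolerance = 1e-12)
  ## one-hot beta equals that vertex's barycentric weight field
  at3 <- at; at3@lesionProbs <- rep(0, nrow(at@vertices))
  at3@lesionProbs[5] <- 1
  rho <- rasterizeLesionPrior(at3)
  J <- nrow(at@vertices)
  oracle <- bruteForceInterp(at@vertices, at@simplices,
                             diag(J)[, 5, drop = FALSE],
                             wmlseg:::gridCoords(at@geometry@dim))
  expect_equal(rho, drop(oracle), tolerance = 1e-9)
})

test_that("folded deformations are rejected by rasterization", {
  at <- smallAtlas()
  def <- deformationState(at)
  def@positions[1, ] <- c(20, 20)   # flips the corner simplices
  expect_false(validDeformation(at, def))
  expect_error(rasterizeLabelPrior(at, def), "folded")
})

test_that("deformation log prior: identity optimum, fold barrier, oracle sum", {
  at <- smallAtlas(stiffness = 2)
  def <- deformationState(at)
  expect_identical(deformationLogPrior(def, at), 0)
  ## fold one simplex
  defF <- def; defF@positions[1, ] <- c(30, 30)
  expect_identical(deformationLogPrior(defF, at), -Inf)
  ## small random deformation: equals an independently coded per-simplex sum
  set.seed(9)
  defR <- def
  defR@positions <- defR@positions +
    matrix(rnorm(length(def@positions), 0, 0.15), nrow(def@positions))
  val <- deformationLogPrior(defR, at)
  oracle <- 0
  for (s in seq_len(nrow(at@simplices))) {
    iv <- at@simplices[s, ]
    ref <- at@vertices[iv, ]; cur <- defR@positions[iv, ]
    aRef <- ((ref[2, 1] - ref[1, 1]) * (ref[3, 2] - ref[1, 2]) -
             (ref[3, 1] - ref[1, 1]) * (ref[2, 2] - ref[1, 2])) / 2
    aCur <- ((cur[2, 1] - cur[1, 1]) * (cur[3, 2] - cur[1, 2]) -
             (cur[3, 1] - cur[1, 1]) * (cur[2, 2] - cur[1, 2])) / 2
    pen <- log(aCur / aRef)^2
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      eR <- sqrt(sum((ref[p[1], ] - ref[p[2], ])^2))
      eC <- sqrt(sum((cur[p[1], ] - cur[p[2], ])^2))
      pen <- pen + (eC / eR - 1)^2
    }
    oracle <- oracle - at@stiffness * pen
  }
  expect_equal(val, oracle, tolerance = 1e-10)
  ## invariant under simplex relabeling
  perm <- sample(nrow(at@simplices))
  atP <- at; atP@simplices <- at@simplices[perm, ]
  expect_equal(deformationLogPrior(defR, atP), val, tolerance = 1e-12)
})

test_that("penalty strictly decreases when a simplex shrinks toward zero volume", {
  at <- smallAtlas()
  def <- deformationState(at)
  v <- at@simplices[1, 1]
  others <- at@simplices[1, -1]
  target <- colMeans(at@vertices[others, ])   # collapses simplex 1
  prev <- 0
  vals <- vapply(seq(0.1, 0.999, length.out = 12), function(t) {
    d <- def
    d@positions[v, ] <- (1 - t) * at@vertices[v, ] + t * target
    deformationLogPrior(d, at)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("lesion probability estimation matches direct frequency oracles", {
  dim <- c(9L, 9L)
  at <- smallAtlas(spacing = 2, dim = dim)
  defs <- list(deformationState(at))
  I <- prod(dim)
  ## degenerate cases
  expect_equal(estimateLesionProbMap(at, defs,
                                     list(rep(0, I)))@lesionProbs,
               rep(0, nrow(at@vertices)), tolerance = 1e-9)
  expect_equal(estimateLesionProbMap(at, defs,
                                     list(rep(1, I)))@lesionProbs,
               rep(1, nrow(at@vertices)), tolerance = 1e-9)
  expect_error(estimateLesionProbMap(at, list(), list()), "empty")
  ## single mask, fine mesh: vertex estimate tracks the local frequency
  atF <- smallAtlas(spacing = 1, dim = dim)
  z <- as.numeric(wmlseg:::gridCoords(dim)[, 1] >= 5)
  est <- estimateLesionProbMap(atF, list(deformationState(atF)),
                               list(z))@lesionProbs
  ## spacing-1 vertices sit on voxels: estimate equals the voxel value
  vidx <- atF@vertices[, 1] + atF@vertices[, 2] * dim[1] + 1
  expect_equal(est, z[vidx], tolerance = 1e-6)
})

test_that("regular atlas estimation reproduces training label statistics", {
  dim <- c(9L, 9L)
  geom <- gridGeometry(dim)
  lab <- matrix(1L, dim[1], dim[2])
  lab[3:7, 3:7] <- 2L
  ## spacing 1: one-hot reproduction at vertices
  at1 <- buildRegularAtlas(list(lab), geom, 1)
  vidx <- at1@vertices[, 1] + at1@vertices[, 2] * dim[1] + 1
  onehot <- cbind(as.numeric(lab)[vidx] == 1, as.numeric(lab)[vidx] == 2)
  expect_equal(unname(at1@labelProbs), unname(onehot) * 1, tolerance = 1e-6)
  ## duplicated maps give the same atlas as a single map
  at2 <- buildRegularAtlas(list(lab, lab), geom, 2)
  at3 <- buildRegularAtlas(list(lab), geom, 2)
  expect_equal(at2@labelProbs, at3@labelProbs, tolerance = 1e-9)
  ## two maps disagreeing in a region -> about 50/50 there
  labB <- lab; labB[3:7, 3:7] <- 1L
  atD <- buildRegularAtlas(list(lab, labB), geom, 1)
  centerVertex <- which(atD@vertices[, 1] == 4 & atD@vertices[, 2] == 4)
  expect_equal(unname(atD@labelProbs[centerVertex, ]), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_error(buildRegularAtlas(list(lab), geom, 20), "spacing")
})
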