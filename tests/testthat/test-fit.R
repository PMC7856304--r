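## Generalized-EM fitting: NIW MAP update, bias update, deformation
## optimization, reductions and symmetries.

test_that("NIW MAP update covers its limiting regimes", {
  set.seed(31)
  N <- 2
  D <- matrix(rnorm(20), 10, N)
  resp <- runif(10)
  wmMean <- c(0.2, -0.1)
  wmCov <- diag(c(0.3, 0.5))
  ## nu = 0: unregularized weighted maximum likelihood
  up <- niwMapUpdate(resp, D, wmMean, wmCov, nu = 0, kappa = 50)
  R <- sum(resp)
  m <- colSums(resp * D) / R
  Xc <- sweep(D, 2, m)
  expect_equal(up$mean, m, tolerance = 1e-12)
  expect_equal(up$cov, crossprod(Xc * resp, Xc) / R, tolerance = 1e-12)
  ## zero responsibilities: prior mode
  up0 <- niwMapUpdate(rep(0, 10), D, wmMean, wmCov, nu = 20, kappa = 50)
  expect_equal(up0$mean, wmMean)
  expect_equal(up0$cov, 50 * wmCov, tolerance = 1e-12)
  ## huge nu pins the lesion Gaussian to the white-matter prior
  upBig <- niwMapUpdate(resp, D, wmMean, wmCov, nu = 1e8, kappa = 50)
  expect_lt(sqrt(sum((upBig$mean - wmMean)^2)) / sqrt(sum(wmMean^2)), 1e-3)
  expect_equal(upBig$cov, 50 * wmCov, tolerance = 1e-4)
  expect_error(niwMapUpdate(c(-1, resp[-1]), D, wmMean, wmCov, 0, 50),
               "nonnegative")
})

test_that("NIW MAP update maximizes weighted log-likelihood plus log prior", {
  ## 1-D: compare against grid-search maximization of the exact objective
  set.seed(32)
  for (case in 1:10) {
    n <- 5
    d <- rnorm(n, 1, 0.8)
    resp <- runif(n)
    wmMean <- rnorm(1)
    wmCov <- matrix(runif(1, 0.2, 1), 1, 1)
    nu <- 10
    kappa <- 5
    up <- niwMapUpdate(resp, cbind(d), wmMean, wmCov, nu, kappa)
    obj <- function(mu, s2) {
      sum(resp * dnorm(d, mu, sqrt(s2), log = TRUE)) +
        niwLogPrior(mu, matrix(s2, 1, 1), wmMean, wmCov, nu, kappa)
    }
    muGrid <- seq(up$mean - 0.5, up$mean + 0.5, length.out = 101)
    s2Grid <- seq(max(1e-3, up$cov[1] * 0.5), up$cov[1] * 1.5,
                  length.out = 101)
    vals <- outer(muGrid, s2Grid, Vectorize(obj))
    best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    expect_equal(muGrid[best[1]], unname(drop(up$mean)), tolerance = 2e-2)
    expect_equal(s2Grid[best[2]], up$cov[1, 1], tolerance = 2e-2)
    ## closed form is at least as good as every grid point
    expect_gte(obj(drop(up$mean), up$cov[1, 1]) + 1e-10, max(vals))
  }
})

test_that("bias update recovers in-span fields and absorbs constants", {
  set.seed(33)
  geom <- gridGeometry(c(12L, 10L))
  basis <- makeBiasBasis(geom, 2L)
  I <- prod(geom@dim)
  N <- 2
  mu <- c(1, -0.5)
  Ctrue <- matrix(c(0, 0.4, -0.2, 0.15, 0, 0.3, 0.1, -0.25), 4, 2)
  D <- matrix(mu, I, N, byrow = TRUE) + basis@values %*% Ctrue  # noiseless
  img <- multiContrastImage(D, geom)
  img@logTransformed <- TRUE
  par <- appearanceParams(cbind(mu), list(diag(2) * 0.1), P = 4L,
                          wmComponent = 1)
  W <- cbind(rep(1, I), 0)       # single class plus (empty) lesion column
  C <- updateBias(img, W, par, basis)
  expect_equal(C, Ctrue, tolerance = 1e-6)
  ## zero-bias data: no spurious non-constant coefficients
  D0 <- matrix(mu, I, N, byrow = TRUE)
  img0 <- img; img0@intensities <- D0
  C0 <- updateBias(img0, W, par, basis)
  expect_lt(max(abs(C0[-1, ])), 1e-6)
  ## a constant multiplicative factor b appears as log b in the constant
  imgB <- img0
  imgB@intensities <- D0 + log(2)
  CB <- updateBias(imgB, W, par, basis)
  expect_equal(CB[1, ], c(log(2), log(2)), tolerance = 1e-9)
  expect_lt(max(abs(CB[-1, ])), 1e-6)
})

test_that("deformation update recovers a known translation differentially", {
  spec <- phantomSpec(lesionRate = 0)
  ph <- generatePhantom(spec, seed = 12L)
  arr <- array(ph$image@intensities, c(spec@dim, 3))
  arr2 <- arr
  arr2[3:64, , ] <- arr[1:62, , ]
  arr2[1:2, , ] <- arr[1, 1, 1]
  imgT <- logTransform(multiContrastImage(matrix(arr2, ncol = 3),
                                          ph$image@geometry,
                                          roles = spec@roles))
  img0 <- logTransform(ph$image)
  atlas <- makeAtlasFromPhantoms(spec, nTrain = 8L, nLesionMasks = 10L,
                                 spacing = 8, jitter = 1, stiffness = 500,
                                 seed = 3L)
  lm <- log(spec@means)
  lsd <- spec@sds / spec@means
  covs <- lapply(1:5, function(k) diag(lsd[, k]^2, 3))
  basis <- makeBiasBasis(img0@geometry, 3L)
  par <- appearanceParams(lm, covs, P = ncol(basis@values),
                          wmComponent = 4, gmComponent = 3)
  fitDef <- function(img) {
    def <- deformationState(atlas)
    for (it in 1:6)
      def <- updateDeformation(img, atlas, def, par, basis, nSteps = 5L,
                               stepSize = 1)
    def
  }
  defT <- fitDef(imgT)
  def0 <- fitDef(img0)
  expect_true(validDeformation(atlas, defT))
  expect_true(validDeformation(atlas, def0))
  shift <- colMeans(defT@positions - atlas@vertices) -
    colMeans(def0@positions - atlas@vertices)
  expect_lt(abs(shift[1] - 2), 0.5)
  expect_lt(abs(shift[2]), 0.5)
  ## aligned atlas: displacement stays near zero
  disp0 <- def0@positions - atlas@vertices
  expect_lt(sqrt(mean(disp0^2)), 0.5)
})

test_that("deformation proposals that would fold the mesh are rejected", {
  spec <- phantomSpec(lesionRate = 0, dim = c(24L, 24L))
  ph <- generatePhantom(spec, seed = 5L)
  img <- logTransform(ph$image)
  lab <- ph$labelMap
  atlas <- buildRegularAtlas(list(lab), img@geometry, 6,
                             labels = c("background", "csf", "gm", "wm",
                                        "dgm"), stiffness = 0.01)
  basis <- makeBiasBasis(img@geometry, 2L)
  lm <- log(spec@means)
  covs <- lapply(1:5, function(k) diag((spec@sds[, k] / spec@means[, k])^2,
                                       3))
  par <- appearanceParams(lm, covs, P = ncol(basis@values),
                          wmComponent = 4, gmComponent = 3)
  def <- deformationState(atlas)
  ## absurdly large steps: every accepted configuration must stay valid
  out <- updateDeformation(img, atlas, def, par, basis, nSteps = 5L,
                           stepSize = 12)
  expect_true(validDeformation(atlas, out))
})

test_that("with a zero lesion prior the fit reduces to the lesion-free model", {
  spec <- phantomSpec(lesionRate = 0, dim = c(32L, 32L))
  ph <- generatePhantom(spec, seed = 6L)
  atlas <- makeAtlasFromPhantoms(spec, nTrain = 4L, nLesionMasks = 5L,
                                 spacing = 8, jitter = 0.5, seed = 7L)
  atlas@lesionProbs[] <- 0
  img <- logTransform(ph$image)
  cfg <- fitConfig(maxOuterIters = 15L, deformIters = 0L, seed = 1L)
  fit <- suppressWarnings(fitParameters(img, atlas, cfg))
  basis <- makeBiasBasis(img@geometry, cfg@biasOrder)
  pr <- rasterizeLabelPrior(atlas, fit@deformation)
  W <- posteriorLabelWeights(img, pr, fit@params, basis,
                             rho = rep(0, nrow(pr)))
  expect_equal(max(W[, ncol(W)]), 0)
})

test_that("objective trace is non-decreasing and label permutation symmetric", {
  spec <- phantomSpec(lesionRate = 0, dim = c(32L, 32L))
  ph <- generatePhantom(spec, seed = 9L)
  atlas <- makeAtlasFromPhantoms(spec, nTrain = 4L, nLesionMasks = 5L,
                                 spacing = 8, jitter = 0.5, seed = 7L)
  img <- logTransform(ph$image)
  cfg <- fitConfig(maxOuterIters = 12L, seed = 1L)
  fit <- suppressWarnings(fitParameters(img, atlas, cfg))
  tr <- fit@objectiveTrace
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  ## permute structure labels in the atlas: fitted means permute along
  ## (short run so float-level path divergence cannot amplify)
  cfgS <- fitConfig(maxOuterIters = 5L, seed = 1L)
  fitS <- suppressWarnings(fitParameters(img, atlas, cfgS))
  perm <- c(2L, 1L, 4L, 3L, 5L)
  atlasP <- atlas
  atlasP@labelProbs <- atlas@labelProbs[, perm]
  atlasP@labels <- atlas@labels[perm]
  fitP <- suppressWarnings(fitParameters(img, atlasP, cfgS))
  expect_equal(fitP@params@means, fitS@params@means[, perm],
               tolerance = 1e-4)
  expect_equal(fitP@objectiveTrace, fitS@objectiveTrace, tolerance = 1e-6)
})
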