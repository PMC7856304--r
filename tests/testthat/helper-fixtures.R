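## Shared fixtures, built once per test run and cached.  Everything is
## generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), .fixtures)
  get(name, envir = .fixtures)
}

## default study conditions: 64x64 slice phantoms, 3 contrasts
fixtureSpec <- function() phantomSpec()

## self-consistent test atlas (8 jittered training phantoms, lesion-prior
## corpus of 20 masks, 8-voxel mesh)
fixtureAtlas <- function() {
  fixture("atlas", function()
    makeAtlasFromPhantoms(fixtureSpec(), nTrain = 8L, nLesionMasks = 20L,
                          spacing = 8, jitter = 1, stiffness = 5,
                          seed = 3L))
}

## lesion shape model trained on the synthetic corpus
fixtureShapeModel <- function() {
  fixture("shapeModel", function() {
    masks <- generateLesionMaskCorpus(100L, fixtureSpec(), seed = 11L)
    trainShapeModel(masks, fixtureSpec()@dim, epochs = 50L, seed = 4L)
  })
}

## a lesion phantom plus its converged fit (used by several infer tests)
fixtureLesionFit <- function() {
  fixture("lesionFit", function() {
    ph <- generatePhantom(phantomSpec(lesionRate = 3), seed = 8L)
    img <- logTransform(ph$image)
    cfg <- fitConfig(seed = 5L)
    fit <- fitParameters(img, fixtureAtlas(), cfg)
    list(ph = ph, img = img, cfg = cfg, fit = fit,
         basis = makeBiasBasis(img@geometry, cfg@biasOrder))
  })
}

## suite of 20 seeded lesion-free, bias-free control phantoms with their
## converged fits (shared by the monotonicity, parameter-recovery and
## control-specificity checks)
fixtureFitSuite <- function() {
  fixture("fitSuite", function() {
    lapply(1:20, function(i) {
      ph <- generatePhantom(phantomSpec(lesionRate = 0), seed = 100L + i)
      img <- logTransform(ph$image)
      cfg <- fitConfig(seed = 1L)
      fit <- suppressWarnings(fitParameters(img, fixtureAtlas(), cfg))
      list(ph = ph, img = img, fit = fit, cfg = cfg)
    })
  })
}

## suite of 15 seeded low-lesion-load phantoms with fits and Monte-Carlo
## lesion posteriors for both arms (with / without the shape prior)
fixtureAblationSuite <- function() {
  fixture("ablationSuite", function() {
    shape <- fixtureShapeModel()
    lapply(1:15, function(i) {
      ph <- generatePhantom(phantomSpec(lesionRate = 2), seed = 200L + i)
      img <- logTransform(ph$image)
      cfg <- fitConfig(seed = 1L)
      fit <- suppressWarnings(fitParameters(img, fixtureAtlas(), cfg))
      basis <- makeBiasBasis(img@geometry, cfg@biasOrder)
      cand <- candidateMask(img, fit@params, basis)
      postShape <- sampleLesionPosterior(img, fixtureAtlas(), fit, shape,
                                         S = 30L, burnin = 10L,
                                         seed = 300L + i, basis = basis)
      postNone <- sampleLesionPosterior(img, fixtureAtlas(), fit, NULL,
                                        S = 30L, burnin = 10L,
                                        seed = 300L + i, basis = basis)
      postShape[!cand] <- 0
      postNone[!cand] <- 0
      list(truth = ph$lesionMask, postShape = postShape,
           postNone = postNone)
    })
  })
}

## tiny 2-voxel / 1-latent shape model with hand-set weights, small enough
## for exhaustive quadrature over the latent space
fixtureToyShapeModel <- function() {
  enc <- list(W1 = matrix(c(0.5, -0.3, 0.2, 0.7), 2, 2),
              b1 = c(0.1, -0.1),
              W2 = matrix(c(0.3, -0.2, 0.5, 0.4), 2, 2),
              b2 = c(0, 0.2),
              Wm = matrix(c(0.4, -0.6), 2, 1), bm = 0.05,
              Ws = matrix(c(0.2, 0.3), 2, 1), bs = -0.5)
  dec <- list(V1 = matrix(c(0.8, -0.5), 1, 2), c1 = c(0.1, 0),
              V2 = matrix(c(0.3, 0.2, -0.4, 0.6), 2, 2), c2 = c(0, -0.1),
              V3 = matrix(c(1.2, -0.7, 0.4, 0.9), 2, 2), c3 = c(-0.2, 0.3))
  new("LesionShapeModel", decoder = dec, encoder = enc, latentDim = 1L,
      inputShape = c(2L, 1L), training = list(epochs = 0L))
}

## brute-force barycentric interpolation oracle: locate each point in the
## first containing simplex (independent re-implementation of the
## rasterizer used by the atlas module)
bruteForceInterp <- function(positions, simplices, values, points) {
  values <- as.matrix(values)
  out <- matrix(NA_real_, nrow(points), ncol(values))
  for (i in seq_len(nrow(points))) {
    for (s in seq_len(nrow(simplices))) {
      verts <- positions[simplices[s, ], , drop = FALSE]
      M <- rbind(t(verts), 1)
      lam <- tryCatch(solve(M, c(points[i, ], 1)), error = function(e) NULL)
      if (is.null(lam) || any(lam < -1e-9)) next
      out[i, ] <- drop(t(lam) %*% values[simplices[s, ], , drop = FALSE])
      break
    }
  }
  out
}
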