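#' Synthetic phantom specification with package defaults
#'
#' Defaults describe a 64 x 64 two-dimensional slice phantom at 1 mm
#' isotropic resolution with three contrasts (T1w-, T2w- and FLAIR-like),
#' concentric-ellipse anatomy, a smooth multiplicative bias field and
#' blob-like white-matter lesions that are hyperintense in the FLAIR- and
#' T2w-role channels and hypointense in T1w.  See the methods vignette for
#' how the default intensities were chosen.
#'
#' @param dim,voxelSize,roles grid and contrast layout.
#' @param means,sds N x 5 matrices (columns background, CSF, GM, WM, deep
#'   GM).
#' @param lesionOffsets,lesionSd lesion intensity shift (added to the WM
#'   mean) and SD per contrast.
#' @param lesionRate expected lesion count (Poisson); 0 disables lesions.
#' @param lesionRadius length-2 radius range in voxels.
#' @param biasAmplitude SD of the random log-domain bias coefficients
#'   (0 = no bias field).
#' @param biasOrder per-axis order of the generated bias field.
#' @param jitter SD (voxels) of the random anatomy jitter.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(64L, 64L), voxelSize = c(1, 1),
                        roles = c("t1w", "t2w", "flair"),
                        means = NULL, sds = NULL, lesionOffsets = NULL,
                        lesionSd = NULL, lesionRate = 3,
                        lesionRadius = c(2, 4), biasAmplitude = 0,
                        biasOrder = 2L, jitter = 0) {
  if (is.null(means))
    means <- rbind(t1w = c(12, 35, 80, 110, 92),
                   t2w = c(12, 120, 85, 65, 78),
                   flair = c(12, 30, 90, 72, 84))[seq_along(roles), ,
                                                  drop = FALSE]
  if (is.null(sds)) sds <- matrix(3, nrow(means), 5)
  if (is.null(lesionOffsets))
    lesionOffsets <- c(t1w = -25, t2w = 30, flair = 45)[seq_along(roles)]
  if (is.null(lesionSd)) lesionSd <- rep(4, nrow(means))
  colnames(means) <- colnames(sds) <-
    c("background", "csf", "gm", "wm", "dgm")
  new("PhantomSpec", dim = as.integer(dim), voxelSize = voxelSize,
      roles = roles, means = means, sds = sds,
      lesionOffsets = as.numeric(lesionOffsets),
      lesionSd = rep_len(lesionSd, nrow(means)),
      lesionRate = lesionRate, lesionRadius = lesionRadius,
      biasAmplitude = biasAmplitude, biasOrder = as.integer(biasOrder),
      jitter = jitter)
}

## ellipse/ellipsoid membership
.inEllipse <- function(coords, ctr, radii) {
  acc <- 0
  for (a in seq_along(ctr))
    acc <- acc + ((coords[, a] - ctr[a]) / radii[a])^2
  acc <= 1
}

## concentric-ellipse anatomy; draws jitter from the current RNG stream.
## Labels: 1 background, 2 CSF, 3 GM, 4 WM, 5 deep GM.
.phantomLabelMap <- function(spec) {
  dim <- spec@dim
  d <- length(dim)
  coords <- gridCoords(dim)
  ctr <- (dim - 1) / 2
  j <- function() if (spec@jitter > 0) stats::rnorm(d, 0, spec@jitter)
                  else numeric(d)
  ext <- min(dim)
  lab <- rep(1L, nrow(coords))
  lab[.inEllipse(coords, ctr + j(), 0.44 * ext * rep(1, d))] <- 2L  # CSF rim
  lab[.inEllipse(coords, ctr + j(), 0.40 * ext * rep(1, d))] <- 3L  # GM
  lab[.inEllipse(coords, ctr + j(), 0.30 * ext * rep(1, d))] <- 4L  # WM
  off <- numeric(d); off[1] <- 0.14 * ext
  lab[.inEllipse(coords, ctr + off + j(), 0.05 * ext * rep(1, d))] <- 5L
  lab[.inEllipse(coords, ctr - off + j(), 0.05 * ext * rep(1, d))] <- 5L
  lab[.inEllipse(coords, ctr + j(), 0.07 * ext * rep(1, d))] <- 2L  # ventricle
  lab
}

## place blob lesions fully inside white matter, with centers drawn from
## the same periventricular placement density the lesion-prior corpus
## uses (lesion location statistics of the phantom population are
## consistent with the location prior trained from that population);
## bounded retries, then a warning with fewer lesions than requested
.placeLesions <- function(labelMap, spec, nLesions) {
  coords <- gridCoords(spec@dim)
  d <- length(spec@dim)
  wmIdx <- which(labelMap == 4L)
  dens <- lesionPlacementDensity(spec)[wmIdx]
  if (sum(dens) == 0) dens <- rep(1, length(wmIdx))
  lesion <- rep(FALSE, length(labelMap))
  placed <- 0L
  if (!length(wmIdx)) nLesions <- 0L
  for (l in seq_len(nLesions)) {
    ok <- FALSE
    for (try in 1:50) {
      ctr <- coords[wmIdx[sample.int(length(wmIdx), 1L, prob = dens)], ]
      r <- stats::runif(1, spec@lesionRadius[1], spec@lesionRadius[2])
      radii <- r * stats::runif(d, 0.7, 1.3)
      blob <- .inEllipse(coords, ctr, radii)
      if (all(labelMap[blob] == 4L)) {
        lesion <- lesion | blob
        ok <- TRUE
        break
      }
    }
    if (ok) placed <- placed + 1L
  }
  if (placed < nLesions)
    warning("placed only ", placed, " of ", nLesions,
            " lesions inside white matter")
  lesion
}

#' Generate a synthetic multi-contrast brain phantom
#'
#' Draws anatomy (with optional geometric jitter), embeds blob-like
#' lesions in white matter, samples per-voxel intensities from the
#' per-structure Gaussians, and applies a smooth multiplicative bias field
#' (exponentiated low-order cosine expansion).  All ground truths are
#' returned for recovery experiments.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed; the phantom is a deterministic function of
#'   (spec, seed).
#' @return list with elements `image` (raw-intensity
#'   [MultiContrastImage-class]), `labelMap` (integer vector, lesion voxels
#'   keep their anatomical label), `lesionMask` (logical), `biasLog`
#'   (I x N log-domain bias field), `truth` (list of the generating means,
#'   SDs and lesion parameters) and `spec`.
#' @export
generatePhantom <- function(spec = phantomSpec(), seed = 1L) {
  withSeed(seed, {
    dim <- spec@dim
    I <- prod(dim)
    N <- nrow(spec@means)
    labelMap <- .phantomLabelMap(spec)
    nLesions <- if (spec@lesionRate > 0) stats::rpois(1L, spec@lesionRate)
                else 0L
    lesionMask <- .placeLesions(labelMap, spec, nLesions)
    D <- matrix(0, I, N)
    lesionMeans <- spec@means[, "wm"] + spec@lesionOffsets
    for (n in seq_len(N)) {
      D[, n] <- stats::rnorm(I, spec@means[n, labelMap],
                             spec@sds[n, labelMap])
      nl <- sum(lesionMask)
      if (nl > 0)
        D[lesionMask, n] <- stats::rnorm(nl, lesionMeans[n],
                                         spec@lesionSd[n])
    }
    D[D <= 0] <- 0.5              # guard: intensities stay positive
    geom <- gridGeometry(dim, spec@voxelSize)
    biasLog <- matrix(0, I, N)
    if (spec@biasAmplitude > 0) {
      basis <- makeBiasBasis(geom, spec@biasOrder)
      for (n in seq_len(N)) {
        cf <- stats::rnorm(ncol(basis@values), 0, spec@biasAmplitude)
        cf[1L] <- 0               # no global scaling component
        biasLog[, n] <- basis@values %*% cf
      }
      D <- D * exp(biasLog)
    }
    image <- multiContrastImage(D, geom, roles = spec@roles)
    list(image = image, labelMap = labelMap, lesionMask = lesionMask,
         biasLog = biasLog,
         truth = list(means = spec@means, sds = spec@sds,
                      lesionMeans = lesionMeans, lesionSd = spec@lesionSd,
                      nLesions = sum(lesionMask > 0)),
         spec = spec)
  })
}

## spatial placement density for the lesion corpus: two periventricular
## bumps (anterior/posterior along the second axis), restricted to WM
lesionPlacementDensity <- function(spec) {
  dim <- spec@dim
  coords <- gridCoords(dim)
  ctr <- (dim - 1) / 2
  ext <- min(dim)
  dens <- rep(0, nrow(coords))
  for (sgn in c(-1, 1)) {
    bump <- ctr
    bump[2] <- ctr[2] + sgn * 0.16 * ext
    dens <- dens + exp(-rowSums(sweep(coords, 2L, bump)^2) /
                         (2 * (0.07 * ext)^2))
  }
  noJitter <- spec
  noJitter@jitter <- 0
  base <- withSeed(0L, .phantomLabelMap(noJitter))
  dens[base != 4L] <- 0
  if (sum(dens) > 0) dens <- dens / sum(dens)
  dens
}

#' Generate a corpus of binary lesion masks
#'
#' Training data for the lesion shape model: blob-like masks whose
#' placement follows a spatially structured frequency map (anterior and
#' posterior periventricular bumps inside white matter), so the corpus has
#' learnable shape and location statistics.
#'
#' @param n number of masks.
#' @param spec a [PhantomSpec-class] (geometry source).
#' @param seed integer seed.
#' @return list of `n` logical masks; the placement density is attached as
#'   attribute `"density"`.
#' @export
generateLesionMaskCorpus <- function(n, spec = phantomSpec(), seed = 1L) {
  dens <- lesionPlacementDensity(spec)
  coords <- gridCoords(spec@dim)
  d <- length(spec@dim)
  masks <- withSeed(seed, {
    lapply(seq_len(n), function(i) {
      k <- 1L + stats::rpois(1L, 1.5)
      m <- rep(FALSE, nrow(coords))
      if (sum(dens) == 0) return(m)
      for (l in seq_len(k)) {
        ctr <- coords[sample.int(length(dens), 1L, prob = dens), ]
        r <- stats::runif(1, spec@lesionRadius[1], spec@lesionRadius[2])
        m <- m | .inEllipse(coords, ctr, r * stats::runif(d, 0.7, 1.3))
      }
      m
    })
  })
  attr(masks, "density") <- dens
  masks
}

#' Build a self-consistent test atlas from jittered phantoms
#'
#' Generates geometrically jittered phantom label maps, estimates the
#' per-vertex label probabilities on a regular mesh, and estimates the
#' per-vertex lesion probabilities from a lesion-mask corpus (identity
#' deformations, since phantoms are generated in atlas space).
#'
#' @param spec a [PhantomSpec-class].
#' @param nTrain number of jittered training phantoms.
#' @param nLesionMasks number of corpus masks for the lesion prior.
#' @param spacing mesh spacing in voxels.
#' @param jitter anatomy jitter SD (voxels) of the training phantoms.
#' @param stiffness deformation-prior weight of the returned atlas.
#' @param seed integer seed.
#' @return a [MeshAtlas-class].
#' @export
makeAtlasFromPhantoms <- function(spec = phantomSpec(), nTrain = 8L,
                                  nLesionMasks = 20L, spacing = 12,
                                  jitter = 1, stiffness = 5, seed = 1L) {
  trainSpec <- spec
  trainSpec@jitter <- jitter
  trainSpec@lesionRate <- 0
  labelMaps <- lapply(seq_len(nTrain), function(i)
    withSeed(deriveSeed(seed, 100L + i), .phantomLabelMap(trainSpec)))
  geom <- gridGeometry(spec@dim, spec@voxelSize)
  atlas <- buildRegularAtlas(labelMaps, geom, spacing,
                             labels = c("background", "csf", "gm", "wm",
                                        "dgm"),
                             stiffness = stiffness)
  masks <- generateLesionMaskCorpus(nLesionMasks, spec,
                                    seed = deriveSeed(seed, 999L))
  defs <- rep(list(deformationState(atlas)), length(masks))
  estimateLesionProbMap(atlas, defs, masks)
}
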