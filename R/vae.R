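## Variational autoencoder over binary lesion masks.  Desk-scale dense
## architecture: two ReLU hidden layers on each side, a linear mean head
## and a softplus variance head in the encoder, and a sigmoid output layer
## in the decoder; trained by maximizing the evidence lower bound (closed
## form KL + single-sample reparameterized Monte-Carlo reconstruction term)
## with Adam.

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

.vaeInit <- function(V, latentDim, hidden = c(256L, 64L), seed = 1L) {
  withSeed(seed, {
    rw <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / a)), a, b)
    list(
      encoder = list(W1 = rw(V, hidden[1]), b1 = numeric(hidden[1]),
                     W2 = rw(hidden[1], hidden[2]),
                     b2 = numeric(hidden[2]),
                     Wm = rw(hidden[2], latentDim),
                     bm = numeric(latentDim),
                     Ws = rw(hidden[2], latentDim),
                     bs = numeric(latentDim)),
      decoder = list(V1 = rw(latentDim, hidden[2]),
                     c1 = numeric(hidden[2]),
                     V2 = rw(hidden[2], hidden[1]),
                     c2 = numeric(hidden[1]),
                     V3 = rw(hidden[1], V), c3 = numeric(V)))
  })
}

.encoderForward <- function(enc, X) {
  a1 <- pmax(X %*% enc$W1 + rep(enc$b1, each = nrow(X)), 0)
  a2 <- pmax(a1 %*% enc$W2 + rep(enc$b2, each = nrow(X)), 0)
  mu <- a2 %*% enc$Wm + rep(enc$bm, each = nrow(X))
  sRaw <- a2 %*% enc$Ws + rep(enc$bs, each = nrow(X))
  var <- .softplus(sRaw) + 1e-6
  list(a1 = a1, a2 = a2, mu = mu, sRaw = sRaw, var = var)
}

.decoderForward <- function(dec, H) {
  d1 <- pmax(H %*% dec$V1 + rep(dec$c1, each = nrow(H)), 0)
  d2 <- pmax(d1 %*% dec$V2 + rep(dec$c2, each = nrow(H)), 0)
  logits <- d2 %*% dec$V3 + rep(dec$c3, each = nrow(H))
  list(d1 = d1, d2 = d2, logits = logits, f = .sigmoid(logits))
}

## stable Bernoulli log likelihood from logits: z*logit - softplus(logit)
.bernoulliLLFromLogits <- function(Z, logits) {
  rowSums(Z * logits - .softplus(logits))
}

## one minibatch: returns mean ELBO and parameter gradients (for ascent)
.vaeBatchGrad <- function(model, Z) {
  enc <- model$encoder
  dec <- model$decoder
  B <- nrow(Z)
  ef <- .encoderForward(enc, Z)
  sd <- sqrt(ef$var)
  eps <- matrix(stats::rnorm(length(ef$mu)), nrow(ef$mu))
  H <- ef$mu + sd * eps
  df <- .decoderForward(dec, H)
  recon <- .bernoulliLLFromLogits(Z, df$logits)
  kl <- 0.5 * rowSums(ef$mu^2 + ef$var - log(ef$var) - 1)
  elbo <- mean(recon - kl)
  ## backward pass (gradient of mean ELBO)
  gLogits <- (Z - df$f) / B
  gV3 <- crossprod(df$d2, gLogits); gc3 <- colSums(gLogits)
  gd2 <- (gLogits %*% t(dec$V3)) * (df$d2 > 0)
  gV2 <- crossprod(df$d1, gd2); gc2 <- colSums(gd2)
  gd1 <- (gd2 %*% t(dec$V2)) * (df$d1 > 0)
  gV1 <- crossprod(H, gd1); gc1 <- colSums(gd1)
  gH <- gd1 %*% t(dec$V1)
  gMu <- gH - ef$mu / B
  gVar <- gH * eps / (2 * sd) - 0.5 * (1 - 1 / ef$var) / B
  gSRaw <- gVar * .sigmoid(ef$sRaw)
  gWm <- crossprod(ef$a2, gMu); gbm <- colSums(gMu)
  gWs <- crossprod(ef$a2, gSRaw); gbs <- colSums(gSRaw)
  ga2 <- (gMu %*% t(enc$Wm) + gSRaw %*% t(enc$Ws)) * (ef$a2 > 0)
  gW2 <- crossprod(ef$a1, ga2); gb2 <- colSums(ga2)
  ga1 <- (ga2 %*% t(enc$W2)) * (ef$a1 > 0)
  gW1 <- crossprod(Z, ga1); gb1 <- colSums(ga1)
  list(elbo = elbo,
       grads = list(encoder = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                                   Wm = gWm, bm = gbm, Ws = gWs, bs = gbs),
                    decoder = list(V1 = gV1, c1 = gc1, V2 = gV2, c2 = gc2,
                                   V3 = gV3, c3 = gc3)))
}

## nearest-neighbour rotation of a 2-D/3-D binary mask about the grid
## center; used for training-set augmentation
rotateMask <- function(mask, dim, degrees, axis = 3L) {
  arr <- array(as.numeric(mask), dim)
  d <- length(dim)
  theta <- degrees * pi / 180
  ctr <- (dim - 1) / 2
  coords <- gridCoords(dim)
  rel <- sweep(coords, 2L, ctr)
  if (d == 2L) ax <- c(1L, 2L)
  else ax <- setdiff(1:3, axis)
  x <- rel[, ax[1]]; y <- rel[, ax[2]]
  src <- rel
  src[, ax[1]] <- cos(theta) * x + sin(theta) * y
  src[, ax[2]] <- -sin(theta) * x + cos(theta) * y
  src <- round(sweep(src, 2L, ctr, "+")) + 1
  ok <- rep(TRUE, nrow(src))
  for (a in seq_len(d)) ok <- ok & src[, a] >= 1 & src[, a] <= dim[a]
  out <- numeric(prod(dim))
  lin <- src[ok, 1]
  mult <- 1
  for (a in seq_len(d)[-1]) {
    mult <- mult * dim[a - 1]
    lin <- lin + (src[ok, a] - 1) * mult
  }
  out[ok] <- arr[lin]
  out
}

#' Train the lesion shape model
#'
#' Fits a variational autoencoder to a corpus of binary lesion masks by
#' stochastic gradient ascent (Adam) on the evidence lower bound, using the
#' closed-form Gaussian KL term and a single reparameterized Monte-Carlo
#' sample for the reconstruction term per step.  Optionally augments the
#' corpus with +/- `augmentDegrees` rotations about each axis.
#'
#' @param masks list of binary masks (vectors or arrays on `inputShape`).
#' @param inputShape integer grid dimensions of the masks.
#' @param latentDim latent code dimension.
#' @param hidden integer sizes of the two hidden layers.
#' @param epochs,batchSize,lr training schedule (Adam).
#' @param augmentDegrees nonzero: augment with rotations of this many
#'   degrees about each axis.
#' @param seed integer seed; the run is fully reproducible.
#' @return a [LesionShapeModel-class] whose `training` metadata records the
#'   per-epoch mean ELBO trace.
#' @export
trainShapeModel <- function(masks, inputShape, latentDim = 16L,
                            hidden = c(256L, 64L), epochs = 50L,
                            batchSize = 10L, lr = 1e-3,
                            augmentDegrees = 0, seed = 1L) {
  if (length(masks) < 10L) stop("at least 10 training masks required")
  inputShape <- as.integer(inputShape)
  V <- prod(inputShape)
  Z <- do.call(rbind, lapply(masks, function(m) as.numeric(m)))
  if (ncol(Z) != V) stop("mask size does not match inputShape")
  if (augmentDegrees != 0) {
    axes <- if (length(inputShape) == 2L) 1L else 1:3
    aug <- list(Z)
    for (ax in axes) for (sgn in c(1, -1))
      aug <- c(aug, list(t(apply(Z, 1L, rotateMask, dim = inputShape,
                                 degrees = sgn * augmentDegrees,
                                 axis = ax))))
    Z <- do.call(rbind, aug)
  }
  model <- .vaeInit(V, latentDim, hidden, seed = deriveSeed(seed, 1L))
  adam <- list(m = rapply(model, function(x) x * 0, how = "replace"),
               v = rapply(model, function(x) x * 0, how = "replace"))
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  t <- 0
  elboTrace <- numeric(epochs)
  withSeed(deriveSeed(seed, 2L), {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(nrow(Z))
      batches <- split(ord, ceiling(seq_along(ord) / batchSize))
      acc <- 0
      for (bidx in batches) {
        bg <- .vaeBatchGrad(model, Z[bidx, , drop = FALSE])
        if (!is.finite(bg$elbo))
          stop("divergent (non-finite) ELBO during VAE training at epoch ",
               epoch)
        acc <- acc + bg$elbo * length(bidx)
        t <- t + 1
        for (part in c("encoder", "decoder")) {
          for (nm in names(model[[part]])) {
            g <- bg$grads[[part]][[nm]]
            adam$m[[part]][[nm]] <- b1 * adam$m[[part]][[nm]] + (1 - b1) * g
            adam$v[[part]][[nm]] <- b2 * adam$v[[part]][[nm]] +
              (1 - b2) * g^2
            mh <- adam$m[[part]][[nm]] / (1 - b1^t)
            vh <- adam$v[[part]][[nm]] / (1 - b2^t)
            model[[part]][[nm]] <- model[[part]][[nm]] +
              lr * mh / (sqrt(vh) + epsA)
          }
        }
      }
      elboTrace[epoch] <- acc / nrow(Z)
    }
  })
  new("LesionShapeModel", decoder = model$decoder, encoder = model$encoder,
      latentDim = as.integer(latentDim), inputShape = inputShape,
      training = list(epochs = epochs, batchSize = batchSize, lr = lr,
                      seed = seed, nMasks = length(masks),
                      elboTrace = elboTrace))
}

#' Decode a latent code into a lesion probability field
#'
#' Deterministic decoder output f(h): the voxelwise probability of lesion
#' presence implied by latent code `h`, squashed into (0,1) by the sigmoid
#' output layer.
#'
#' @param model a [LesionShapeModel-class].
#' @param h numeric latent vector (length `latentDim`) or matrix (rows =
#'   codes).
#' @return numeric vector (or matrix) of per-voxel probabilities in (0,1).
#' @export
decodeShape <- function(model, h) {
  H <- if (is.matrix(h)) h else matrix(h, 1L)
  if (ncol(H) != model@latentDim) stop("latent code dimension mismatch")
  f <- .decoderForward(model@decoder, H)$f
  if (is.matrix(h)) f else f[1L, ]
}

#' Encode a lesion mask into the approximate posterior
#'
#' Returns the mean and (strictly positive, softplus-activated) variance of
#' the Gaussian approximate posterior over the latent code given a binary
#' mask.
#'
#' @param model a [LesionShapeModel-class].
#' @param mask binary vector or array matching the model's `inputShape`.
#' @return list with numeric vectors `mean` and `var`.
#' @export
encodeShape <- function(model, mask) {
  z <- as.numeric(mask)
  if (length(z) != prod(model@inputShape)) stop("mask shape mismatch")
  ef <- .encoderForward(model@encoder, matrix(z, 1L))
  list(mean = ef$mu[1L, ], var = ef$var[1L, ])
}

#' Evidence lower bound of a mask under the shape model
#'
#' Closed-form negative KL divergence between the encoder posterior and the
#' standard-normal prior, plus a Monte-Carlo estimate (reparameterization
#' trick) of the expected Bernoulli reconstruction log-likelihood.
#' Probabilities are clamped to [1e-6, 1-1e-6] inside the Bernoulli term.
#'
#' @param model a [LesionShapeModel-class].
#' @param mask binary mask.
#' @param nSamples number of Monte-Carlo samples (>= 1).
#' @param seed optional seed for the samples.
#' @return scalar ELBO value.
#' @export
shapeElbo <- function(model, mask, nSamples = 1L, seed = NULL) {
  if (nSamples < 1L) stop("nSamples must be >= 1")
  z <- as.numeric(mask)
  ef <- .encoderForward(model@encoder, matrix(z, 1L))
  kl <- 0.5 * sum(ef$mu^2 + ef$var - log(ef$var) - 1)
  sd <- sqrt(ef$var)
  recon <- withSeed(seed, {
    vals <- numeric(nSamples)
    for (s in seq_len(nSamples)) {
      h <- ef$mu + sd * stats::rnorm(model@latentDim)
      f <- .decoderForward(model@decoder, matrix(h, 1L))$f[1L, ]
      f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
      vals[s] <- sum(z * log(f) + (1 - z) * log(1 - f))
    }
    mean(vals)
  })
  -kl + recon
}

setMethod("show", "LesionShapeModel", function(object) {
  cat(sprintf(
    "LesionShapeModel: %s grid, latent dim %d, trained %d epochs\n",
    paste(object@inputShape, collapse = "x"), object@latentDim,
    object@training$epochs))
  tr <- object@training$elboTrace
  if (length(tr))
    cat(sprintf("  mean ELBO: %.2f (first) -> %.2f (last)\n",
                tr[1L], tr[length(tr)]))
})
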