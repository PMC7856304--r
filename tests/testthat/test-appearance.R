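## Intensity model: log transform, bias basis, Gaussian likelihoods,
## posterior weights, normal-inverse-Wishart prior.

tinyImage <- function(D, dim = NULL, roles = NULL) {
  if (is.null(dim)) dim <- c(nrow(D), 1L)
  img <- multiContrastImage(D, gridGeometry(dim), roles = roles)
  img@logTransformed <- TRUE
  img
}

test_that("log transform applies the clamping floor rule", {
  D <- cbind(c(1, exp(1), 0, 100))
  img <- multiContrastImage(D, gridGeometry(c(4L, 1L)))
  lt <- logTransform(img, floor = 1e-4)
  expect_equal(lt@intensities[1, 1], 0)
  expect_equal(lt@intensities[2, 1], 1)
  expect_equal(lt@intensities[3, 1], log(1e-4))
  expect_identical(lt@logFloor, 1e-4)
  expect_error(logTransform(lt), "already")
  neg <- multiContrastImage(cbind(c(-1, -2, 0, -3)), gridGeometry(c(4L, 1L)))
  expect_error(logTransform(neg), "non-positive")
})

test_that("bias basis is a well-conditioned cosine family with constant first", {
  geom <- gridGeometry(c(8L, 6L))
  b1 <- makeBiasBasis(geom, 1L)
  expect_equal(ncol(b1@values), 1L)
  expect_equal(b1@values[, 1], rep(1, 48))
  b <- makeBiasBasis(geom, c(2L, 1L))
  expect_equal(ncol(b@values), 2L)
  ## second function monotone along axis 1
  byX <- b@values[1:8, 2]
  expect_true(all(diff(byX) < 0))
  ## Gram matrix over the mask is full rank
  b3 <- makeBiasBasis(geom, 3L)
  G <- crossprod(b3@values)
  expect_equal(qr(G)$rank, 9L)
})

test_that("class log likelihoods match the quadratic-form oracle", {
  set.seed(21)
  N <- 3; I <- 10
  D <- matrix(rnorm(I * N), I, N)
  geom <- gridGeometry(c(I, 1L))
  basis <- makeBiasBasis(geom, c(2L, 1L))
  mu <- rnorm(N)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  par <- appearanceParams(cbind(mu), list(A), P = 2L, wmComponent = 1,
                          nu = 0.0, kappa = 50)
  par@nu <- 0
  par@biasCoeffs <- matrix(rnorm(2 * N, 0, 0.1), 2, N)
  img <- tinyImage(D, c(I, 1L))
  ll <- classLogLikelihoods(img, par, basis)
  bias <- basis@values %*% par@biasCoeffs
  for (i in c(1, 5, 10)) {
    r <- D[i, ] - bias[i, ] - mu
    oracle <- -N / 2 * log(2 * pi) - 0.5 * determinant(A)$modulus[1] -
      0.5 * drop(t(r) %*% solve(A) %*% r)
    expect_equal(ll[i, 1], oracle, tolerance = 1e-12)
  }
  ## at d = mu (zero bias), identity covariance: -(N/2) log(2 pi)
  par0 <- appearanceParams(cbind(mu), list(diag(3)), P = 1L,
                           wmComponent = 1)
  img0 <- tinyImage(matrix(mu, 1, 3, byrow = TRUE), c(1L, 1L))
  basis0 <- makeBiasBasis(gridGeometry(c(1L, 2L)), 1L)
  basis0@values <- basis0@values[1, , drop = FALSE]
  expect_equal(classLogLikelihoods(img0, par0, basis0)[1, 1],
               -1.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("likelihood is invariant to shifting data and bias together", {
  set.seed(22)
  I <- 20; N <- 2
  D <- matrix(rnorm(I * N), I, N)
  geom <- gridGeometry(c(5L, 4L))
  basis <- makeBiasBasis(geom, 2L)
  par <- appearanceParams(cbind(rnorm(N)), list(diag(N) * 0.5), P = 4L,
                          wmComponent = 1)
  ll0 <- classLogLikelihoods(tinyImage(D, c(5L, 4L)), par, basis)
  C <- matrix(rnorm(4 * N, 0, 0.3), 4, N)
  par2 <- par; par2@biasCoeffs <- C
  D2 <- D + basis@values %*% C
  ll1 <- classLogLikelihoods(tinyImage(D2, c(5L, 4L)), par2, basis)
  expect_equal(ll0, ll1, tolerance = 1e-9)
})

test_that("diagonal covariance mode equals full mode for diagonal matrices", {
  set.seed(23)
  D <- matrix(rnorm(30), 10, 3)
  basis <- makeBiasBasis(gridGeometry(c(10L, 1L)), 1L)
  S <- diag(c(0.5, 1.2, 2))
  parF <- appearanceParams(cbind(rnorm(3)), list(S), P = 1L,
                           wmComponent = 1, diagonalCov = FALSE)
  parD <- parF; parD@diagonalCov <- TRUE
  img <- tinyImage(D, c(10L, 1L))
  expect_equal(classLogLikelihoods(img, parF, basis),
               classLogLikelihoods(img, parD, basis))
})

test_that("posterior weights implement the normalized likelihood-times-prior rule", {
  set.seed(24)
  ## K = 1: weights identically 1
  D <- matrix(rnorm(6), 3, 2)
  img <- tinyImage(D, c(3L, 1L))
  basis <- makeBiasBasis(gridGeometry(c(3L, 1L)), 1L)
  par1 <- appearanceParams(cbind(c(0, 0)), list(diag(2)), P = 1L,
                           wmComponent = 1)
  W1 <- posteriorLabelWeights(img, cbind(rep(1, 3)), par1, basis)
  expect_equal(W1[, 1], rep(1, 3))
  ## equal likelihoods: weights equal the prior field
  prior <- cbind(c(0.2, 0.5, 0.9), c(0.8, 0.5, 0.1))
  par2 <- appearanceParams(cbind(c(0, 0), c(0, 0)),
                           list(diag(2), diag(2)), P = 1L, wmComponent = 2)
  W2 <- posteriorLabelWeights(img, prior, par2, basis)
  expect_equal(W2[, 1:2], unname(prior), tolerance = 1e-12)
  ## 2-class hand oracle on random instances
  for (rep in 1:5) {
    D <- matrix(rnorm(6), 3, 2)
    img <- tinyImage(D, c(3L, 1L))
    mus <- matrix(rnorm(4), 2, 2)
    s1 <- crossprod(matrix(rnorm(4), 2)) + diag(2)
    s2 <- crossprod(matrix(rnorm(4), 2)) + diag(2)
    pr <- matrix(runif(6), 3, 2); pr <- pr / rowSums(pr)
    par <- appearanceParams(mus, list(s1, s2), P = 1L, wmComponent = 2,
                            diagonalCov = FALSE)
    W <- posteriorLabelWeights(img, pr, par, basis)
    dens <- function(d, m, S)
      exp(-0.5 * drop(t(d - m) %*% solve(S) %*% (d - m))) /
        sqrt((2 * pi)^2 * det(S))
    for (i in 1:3) {
      n1 <- dens(D[i, ], mus[, 1], s1) * pr[i, 1]
      n2 <- dens(D[i, ], mus[, 2], s2) * pr[i, 2]
      expect_equal(W[i, 1], n1 / (n1 + n2), tolerance = 1e-10)
    }
    expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("mixture sharing splits structure mass across components", {
  ## one structure modeled as a 2-component mixture, plus a host structure
  mix <- data.frame(component = c(1L, 2L, 3L), structure = c(1L, 1L, 2L),
                    weight = c(0.3, 0.7, 1))
  par <- appearanceParams(cbind(0, 1, 2),
                          list(diag(1), diag(1), diag(1)),
                          mixture = mix, P = 1L, wmComponent = 3)
  prior <- cbind(c(0.4, 0.8), c(0.6, 0.2))
  rho <- c(0.5, 0)
  masses <- wmlseg:::expandPriorMasses(prior, par, rho = rho)
  ## rows still sum to 1; components split the structure mass by weight
  expect_equal(rowSums(masses), c(1, 1), tolerance = 1e-12)
  expect_equal(masses[1, 1:2], 0.4 * c(0.3, 0.7))
  ## host structure (2) is carved by rho, the lesion picks it up
  expect_equal(masses[1, 3], 0.6 * 0.5)
  expect_equal(masses[1, 4], 0.5 * 0.6)
  expect_equal(masses[2, 4], 0)
})

test_that("NIW prior: flat at nu = 0, concave in the mean, textbook oracle", {
  expect_identical(niwLogPrior(c(1, 2), diag(2), c(0, 0), diag(2), 0, 50), 0)
  ## term-by-term oracle, N = 2
  set.seed(25)
  nu <- 20; kappa <- 5
  wmMean <- c(1, -0.5)
  wmCov <- crossprod(matrix(rnorm(4), 2)) + diag(2)
  lesMean <- c(1.4, 0)
  lesCov <- crossprod(matrix(rnorm(4), 2)) + diag(2)
  N <- 2; m <- nu - N - 2
  Psi <- kappa * nu * wmCov
  normOracle <- -N / 2 * log(2 * pi) - 0.5 * log(det(lesCov / nu)) -
    0.5 * nu * drop(t(lesMean - wmMean) %*% solve(lesCov) %*%
                    (lesMean - wmMean))
  lmv <- N * (N - 1) / 4 * log(pi) + lgamma(m / 2) + lgamma(m / 2 - 0.5)
  iwOracle <- m / 2 * log(det(Psi)) - m * N / 2 * log(2) - lmv -
    (m + N + 1) / 2 * log(det(lesCov)) -
    0.5 * sum(diag(Psi %*% solve(lesCov)))
  expect_equal(niwLogPrior(lesMean, lesCov, wmMean, wmCov, nu, kappa),
               normOracle + iwOracle, tolerance = 1e-10)
  ## concave quadratic in the mean, maximized at the WM mean
  f <- function(mu) niwLogPrior(mu, lesCov, wmMean, wmCov, nu, kappa)
  base <- f(wmMean)
  for (d in list(c(0.1, 0), c(0, 0.2), c(-0.3, 0.3)))
    expect_lt(f(wmMean + d), base)
  expect_equal(f(wmMean + c(0.1, 0)), f(wmMean - c(0.1, 0)),
               tolerance = 1e-10)
  ## invalid degrees of freedom
  expect_error(niwLogPrior(lesMean, lesCov, wmMean, wmCov, 3, 50),
               "degrees of freedom")
})

test_that("for large nu the NIW mode approaches (wmMean, kappa * wmCov)", {
  wmMean <- c(0.5, -1)
  wmCov <- diag(c(0.2, 0.4))
  kappa <- 50
  nu <- 1e6
  ## numerically maximize over diagonal lesion parameters
  f <- function(p) -niwLogPrior(p[1:2], diag(exp(p[3:4])), wmMean, wmCov,
                                nu, kappa)
  opt <- optim(c(wmMean + 0.3, log(kappa * diag(wmCov)) + 0.5), f,
               method = "L-BFGS-B",
               lower = c(-5, -5, -10, -10), upper = c(5, 5, 10, 10))
  expect_equal(opt$par[1:2], wmMean, tolerance = 1e-3)
  expect_equal(exp(opt$par[3:4]), kappa * diag(wmCov), tolerance = 0.01)
})
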