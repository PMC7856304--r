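## Simplex-mesh engine: regular (Freudenthal) meshes over a voxel grid,
## signed volumes, point location and barycentric interpolation.  All in
## 0-based continuous voxel coordinates, generic over 2-D and 3-D.

## signed volume of each simplex (area in 2-D) -- positive means the simplex
## keeps its reference orientation
simplexVolumes <- function(positions, simplices) {
  d <- ncol(positions)
  v0 <- positions[simplices[, 1L], , drop = FALSE]
  if (d == 2L) {
    e1 <- positions[simplices[, 2L], , drop = FALSE] - v0
    e2 <- positions[simplices[, 3L], , drop = FALSE] - v0
    (e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]) / 2
  } else {
    e1 <- positions[simplices[, 2L], , drop = FALSE] - v0
    e2 <- positions[simplices[, 3L], , drop = FALSE] - v0
    e3 <- positions[simplices[, 4L], , drop = FALSE] - v0
    cx <- e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]
    cy <- e2[, 3L] * e3[, 1L] - e2[, 1L] * e3[, 3L]
    cz <- e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L]
    (e1[, 1L] * cx + e1[, 2L] * cy + e1[, 3L] * cz) / 6
  }
}

## permutations of 1..n (tiny n), used for the Freudenthal cube split
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

## regular simplex mesh over a grid: vertices on a lattice with (roughly)
## the requested spacing, each lattice cell split into d! simplices
buildRegularMesh <- function(dim, spacing) {
  d <- length(dim)
  if (any(spacing >= dim)) stop("mesh spacing exceeds grid extent")
  breaks <- lapply(seq_len(d), function(a) {
    b <- seq(0, dim[a] - 1, by = spacing)
    if (b[length(b)] < dim[a] - 1) b <- c(b, dim[a] - 1)
    b
  })
  nb <- vapply(breaks, length, 1L)
  vertGrid <- unname(as.matrix(expand.grid(breaks)))  # column-major lattice
  dimnames(vertGrid) <- NULL
  vidx <- function(ijk) {                     # 1-based lattice index -> row
    idx <- ijk[, 1]
    mult <- 1
    for (a in seq_len(d)[-1]) {
      mult <- mult * nb[a - 1]
      idx <- idx + (ijk[, a] - 1) * mult
    }
    idx
  }
  cells <- as.matrix(expand.grid(lapply(nb - 1L, seq_len)))
  perms <- .permutations(d)
  simplices <- matrix(0L, nrow(cells) * nrow(perms), d + 1L)
  row <- 1L
  for (ci in seq_len(nrow(cells))) {
    base <- cells[ci, ]
    for (pi in seq_len(nrow(perms))) {
      corners <- matrix(base, d + 1L, d, byrow = TRUE)
      for (m in seq_len(d))
        corners[(m + 1L):(d + 1L), perms[pi, m]] <-
          corners[(m + 1L):(d + 1L), perms[pi, m]] + 1L
      simplices[row, ] <- vidx(corners)
      row <- row + 1L
    }
  }
  storage.mode(simplices) <- "integer"
  ## enforce positive orientation in the reference configuration
  vols <- simplexVolumes(vertGrid, simplices)
  flip <- vols < 0
  if (any(flip)) simplices[flip, c(1L, 2L)] <- simplices[flip, c(2L, 1L)]
  list(vertices = vertGrid, simplices = simplices)
}

## inverse barycentric matrices: G[, , s] maps (x, 1) to barycentric weights
simplexG <- function(positions, simplices) {
  d <- ncol(positions)
  S <- nrow(simplices)
  G <- array(NA_real_, c(d + 1L, d + 1L, S))
  ok <- rep(TRUE, S)
  if (d == 2L) {
    ## closed-form inverse of [[x0 x1 x2], [y0 y1 y2], [1 1 1]]
    x <- matrix(positions[simplices, 1L], S)
    y <- matrix(positions[simplices, 2L], S)
    det <- x[, 1L] * (y[, 2L] - y[, 3L]) + x[, 2L] * (y[, 3L] - y[, 1L]) +
      x[, 3L] * (y[, 1L] - y[, 2L])
    ok <- abs(det) > 1e-300
    idx <- rbind(c(2L, 3L), c(3L, 1L), c(1L, 2L))
    for (r in 1:3) {
      j <- idx[r, 1L]; k <- idx[r, 2L]
      G[r, 1L, ] <- (y[, j] - y[, k]) / det
      G[r, 2L, ] <- (x[, k] - x[, j]) / det
      G[r, 3L, ] <- (x[, j] * y[, k] - x[, k] * y[, j]) / det
    }
    G[, , !ok] <- NA_real_
  } else {
    for (s in seq_len(S)) {
      M <- rbind(t(positions[simplices[s, ], , drop = FALSE]), 1)
      Gs <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(Gs)) ok[s] <- FALSE else G[, , s] <- Gs
    }
  }
  list(G = G, ok = ok)
}

## locate every voxel of a grid in the deformed mesh and compute its
## barycentric weights; ties on shared faces go to the first containing
## simplex in the fixed simplex iteration order
rasterizeMesh <- function(positions, simplices, dim, tol = 1e-9) {
  d <- length(dim)
  I <- prod(dim)
  coords <- gridCoords(dim)
  gi <- simplexG(positions, simplices)
  simplex <- integer(I)            # 0 = outside
  lambda <- matrix(0, I, d + 1L)
  remaining <- seq_len(I)          # voxels not yet located
  ## per-simplex bounding boxes, vectorized over simplices
  lo <- hi <- positions[simplices[, 1L], , drop = FALSE]
  for (a in 2L:(d + 1L)) {
    va <- positions[simplices[, a], , drop = FALSE]
    lo <- pmin(lo, va)
    hi <- pmax(hi, va)
  }
  lo <- lo - tol
  hi <- hi + tol
  for (s in seq_len(nrow(simplices))) {
    if (!gi$ok[s]) next
    if (!length(remaining)) break
    inBox <- coords[remaining, 1L] >= lo[s, 1L] &
      coords[remaining, 1L] <= hi[s, 1L]
    for (a in 2:d)
      inBox <- inBox & coords[remaining, a] >= lo[s, a] &
        coords[remaining, a] <= hi[s, a]
    cand <- remaining[inBox]
    if (!length(cand)) next
    lam <- cbind(coords[cand, , drop = FALSE], 1) %*% t(gi$G[, , s])
    inside <- lam[, 1L] >= -tol
    for (a in 2:(d + 1L)) inside <- inside & lam[, a] >= -tol
    hit <- cand[inside]
    if (length(hit)) {
      simplex[hit] <- s
      lambda[hit, ] <- lam[inside, , drop = FALSE]
      remaining <- c(remaining[!inBox], cand[!inside])
    }
  }
  list(simplex = simplex, lambda = lambda, inside = simplex > 0L,
       G = gi$G, ok = gi$ok)
}

## interpolate per-vertex values (J x m) at every voxel given a
## rasterization; rows of voxels outside the mesh are left at `fill`
interpolateVertexValues <- function(raster, simplices, values, fill = 0) {
  values <- as.matrix(values)
  I <- length(raster$simplex)
  out <- matrix(fill, I, ncol(values))
  for (s in unique(raster$simplex[raster$inside])) {
    idx <- which(raster$simplex == s)
    out[idx, ] <- raster$lambda[idx, , drop = FALSE] %*%
      values[simplices[s, ], , drop = FALSE]
  }
  out
}
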