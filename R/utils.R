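#' @keywords internal
"_PACKAGE"

## numerically stable log(sum(exp(x))) along rows of a matrix
logSumExpRows <- function(x) {
  m <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, j])
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

## run expr with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic sub-stream seeds derived from a master seed; kept < 2^31
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483647)
}

## central finite-difference gradient (used only for small, cheap functionals)
numGrad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

## 0-based voxel-center coordinates of every voxel of a grid, column-major
gridCoords <- function(dim) {
  arrayInd(seq_len(prod(dim)), .dim = dim) - 1
}

## full-precision text serialization of numeric matrices (round-trips doubles)
writeNumericCsv <- function(x, path) {
  x <- as.matrix(x)
  lines <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
}

readNumericCsv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
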