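# Internal helpers: array shifts, coordinate grids, interpolation, RNG scoping.

# Shift a 3D array by `by` (+1/-1) along `axis`; result[i] = a[i + by],
# positions shifted in from outside get `fill`.
.shift3 <- function(a, axis, by, fill = NA) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (n < 2L) return(out)
  dst <- src <- lapply(d, seq_len)
  if (by == 1L) {
    dst[[axis]] <- seq_len(n - 1L); src[[axis]] <- 2L:n
  } else if (by == -1L) {
    dst[[axis]] <- 2L:n; src[[axis]] <- seq_len(n - 1L)
  } else stop("by must be +1 or -1")
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# World-mm coordinate grids for a voxel lattice under a 0-based-index affine.
# Returns list(X, Y, Z) of arrays with dim d.
.coordGrids <- function(d, affine) {
  i <- seq_len(d[1L]) - 1
  j <- seq_len(d[2L]) - 1
  k <- seq_len(d[3L]) - 1
  I <- array(rep(i, times = d[2L] * d[3L]), d)
  J <- array(rep(rep(j, each = d[1L]), times = d[3L]), d)
  K <- array(rep(k, each = d[1L] * d[2L]), d)
  list(
    X = affine[1L, 1L] * I + affine[1L, 2L] * J + affine[1L, 3L] * K + affine[1L, 4L],
    Y = affine[2L, 1L] * I + affine[2L, 2L] * J + affine[2L, 3L] * K + affine[2L, 4L],
    Z = affine[3L, 1L] * I + affine[3L, 2L] * J + affine[3L, 3L] * K + affine[3L, 4L]
  )
}

# Default affine: axis-aligned voxel grid centred on the world origin.
.centeredAffine <- function(d, spacing) {
  aff <- diag(4)
  aff[1L, 1L] <- spacing[1L]; aff[2L, 2L] <- spacing[2L]; aff[3L, 3L] <- spacing[3L]
  aff[1L:3L, 4L] <- -(d[1L:3L] - 1) / 2 * spacing
  aff
}

# world mm -> continuous 0-based voxel index
.worldToVoxel <- function(point, affine) {
  as.numeric(solve(affine, c(point, 1))[1L:3L])
}

# Trilinear interpolation of one 3D volume at a continuous 0-based index.
.trilinear3 <- function(vol, idx) {
  d <- dim(vol)
  if (any(idx < 0) || any(idx > d - 1))
    stop("probe point lies outside the imaged volume", call. = FALSE)
  i0 <- pmin(floor(idx), d - 2); i0 <- pmax(i0, 0)
  f <- idx - i0
  i0 <- as.integer(i0) + 1L              # to 1-based corner
  c000 <- vol[i0[1L], i0[2L], i0[3L]]
  c100 <- vol[i0[1L] + 1L, i0[2L], i0[3L]]
  c010 <- vol[i0[1L], i0[2L] + 1L, i0[3L]]
  c110 <- vol[i0[1L] + 1L, i0[2L] + 1L, i0[3L]]
  c001 <- vol[i0[1L], i0[2L], i0[3L] + 1L]
  c101 <- vol[i0[1L] + 1L, i0[2L], i0[3L] + 1L]
  c011 <- vol[i0[1L], i0[2L] + 1L, i0[3L] + 1L]
  c111 <- vol[i0[1L] + 1L, i0[2L] + 1L, i0[3L] + 1L]
  c00 <- c000 * (1 - f[1L]) + c100 * f[1L]
  c10 <- c010 * (1 - f[1L]) + c110 * f[1L]
  c01 <- c001 * (1 - f[1L]) + c101 * f[1L]
  c11 <- c011 * (1 - f[1L]) + c111 * f[1L]
  c0 <- c00 * (1 - f[2L]) + c10 * f[2L]
  c1 <- c01 * (1 - f[2L]) + c11 * f[2L]
  c0 * (1 - f[3L]) + c1 * f[3L]
}

# Evaluate code with a private RNG stream; the global .Random.seed is
# restored afterwards so callers' simulations are undisturbed.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Monomial design matrix of total degree <= order in 3 scaled coordinates.
.polyBasis <- function(x, y, z, order) {
  pows <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  pows <- pows[rowSums(pows) <= order, , drop = FALSE]
  n <- length(x)
  M <- matrix(NA_real_, n, nrow(pows))
  for (c in seq_len(nrow(pows)))
    M[, c] <- x^pows$i[c] * y^pows$j[c] * z^pows$k[c]
  M
}

.unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5)
    stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}
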