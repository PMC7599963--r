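#' @useDynLib microtract, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif setNames
NULL

# eigenvalue floor (mm^2/s) applied wherever an inverse eigenvalue appears
EPS_LAMBDA <- 1e-6

stop_validation <- function(...) {
  stop(structure(class = c("microtract_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("microtract_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Define a volume grid
#'
#' A grid couples an array shape with voxel dimensions (mm) and a 4x4
#' voxel-to-world affine. When no affine is given, a diagonal scaling
#' affine with the origin at voxel (1,1,1) is constructed.
#'
#' @param shape integer vector of length 3, array dimensions.
#' @param voxel_size numeric length 3, voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world transform (0-based voxel
#'   indices map to world mm).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_validation("shape must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop_validation("voxel_size must be 3 positive numbers (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(matrix(as.numeric(affine), 4, 4))) < .Machine$double.eps)
    stop_validation("affine must be an invertible 4x4 matrix")
  affine <- matrix(as.numeric(affine), 4L, 4L)
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-4) {
  all(a$shape == b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$affine - b$affine) < tol)
}

voxel_volume <- function(grid) prod(grid$voxel_size)

# voxel (1-based ijk, rows) -> world mm using the 0-based affine convention
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  xyz1 <- cbind(ijk - 1, 1) %*% t(grid$affine)
  xyz1[, 1:3, drop = FALSE]
}

# ---- small numerical helpers -------------------------------------------

# separable gaussian smoothing of a 3-D array, sigma in voxels (per axis),
# replicate padding at the edges
gauss_smooth3 <- function(arr, sigma = 1) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, d)
    idx <- seq_len(d[ax])
    for (o in seq(-r, r)) {
      src <- pmin(pmax(idx + o, 1L), d[ax])   # replicate edges
      sl <- switch(ax,
                   arr[src, , , drop = FALSE],
                   arr[, src, , drop = FALSE],
                   arr[, , src, drop = FALSE])
      acc <- acc + k[o + r + 1] * sl
    }
    arr <- acc
  }
  out <- arr
  out
}

# trilinear interpolation at continuous 1-based voxel coordinates (n x 3);
# outside the array -> `outside`
trilinear <- function(arr, pts, outside = 0) {
  d <- dim(arr)
  pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  val <- rep(outside, n)
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
        pts[, 2] >= 1 & pts[, 2] <= d[2] &
        pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (!any(ok)) return(val)
  p <- pts[ok, , drop = FALSE]
  f0 <- pmin(floor(p), matrix(rep(d - 1L, each = nrow(p)), ncol = 3))
  fr <- p - f0
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
         (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
         (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    ii <- cbind(f0[, 1] + cx, f0[, 2] + cy, f0[, 3] + cz)
    acc <- acc + w * arr[ii]
  }
  val[ok] <- acc
  val
}

# mean of a Normal(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# truncated-normal draws whose *truncated* mean equals `mean`: the parent
# location is shifted so that clipping at physical bounds does not bias
# the configured marginal mean
rtruncnorm_meanmatch <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  if (!is.finite(lo) && !is.finite(hi)) return(rnorm(n, mean, sd))
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - mean
  mu <- tryCatch(stats::uniroot(f, c(mean - 4 * sd, mean + 4 * sd))$root,
                 error = function(e) mean)
  rtruncnorm(n, mu, sd, lo, hi)
}

# normal draws truncated to [lo, hi] by rejection (falls back to clamping
# when the window mass is tiny)
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lo), hi)
  x
}

# 26-neighbourhood adjacency (CSR, 0-based) between the TRUE voxels of a
# 3-D logical mask; used by TFCE and cluster reporting
mask_adjacency <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  rank <- integer(prod(d))
  rank[idx] <- seq_len(n)
  ijk <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbr <- vector("list", nrow(offs))
  src <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    p <- sweep(ijk, 2, offs[k, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] &
          p[, 2] >= 1 & p[, 2] <= d[2] &
          p[, 3] >= 1 & p[, 3] <= d[3]
    if (!any(ok)) next
    lin <- p[ok, 1] + (p[ok, 2] - 1L) * d[1] + (p[ok, 3] - 1L) * d[1] * d[2]
    r <- rank[lin]
    keep <- r > 0L
    nbr[[k]] <- r[keep]
    src[[k]] <- which(ok)[keep]
  }
  from <- unlist(src)
  to <- unlist(nbr)
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  counts <- tabulate(from, nbins = n)
  list(indptr = c(0L, cumsum(counts)), indices = as.integer(to - 1L),
       idx = idx, n = n)
}
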