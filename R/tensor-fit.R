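# Diffusion-tensor estimation and DTI scalar maps

#' Fit the diffusion tensor per voxel
#'
#' Weighted linear least squares on the log signal: the design is
#' \[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz\]
#' (so the intercept is log S0), with one reweighting pass using weights
#' equal to the squared predicted signal. Signal ratios relative to the
#' mean baseline are clipped to \[1e-6, 1\] before the log, which keeps
#' the Rician noise floor from producing S > S0. Voxels whose signal is
#' all zero are dropped from the mask.
#'
#' @param dwi a [dwi_stack()].
#' @param mask 3-D logical array (default: all voxels).
#' @param method "wls" (default) or "ols".
#' @return a `tensor_field`: list with `grid`, `D` (n_vox x 6 matrix,
#'   lower-triangular order Dxx, Dxy, Dyy, Dxz, Dyz, Dzz; NA outside
#'   mask), `S0` (3-D array) and `mask`.
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("wls", "ols")) {
  method <- match.arg(method)
  scheme <- dwi$scheme
  n_vol <- length(scheme$bvals)
  if (n_vol < 7L)
    stop_validation("tensor fit needs >= 7 volumes (6 directions + baseline); got ",
                    n_vol)
  if (sum(!scheme$is_b0) < 6L)
    stop_validation("tensor fit needs >= 6 diffusion-weighted directions")
  grid <- dwi$grid
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  if (!all(dim(mask) == grid$shape))
    stop_validation("mask shape does not match grid")
  nv <- prod(grid$shape)
  Y <- matrix(dwi$data, nv, n_vol)            # voxels x volumes
  midx <- which(as.vector(mask))
  allzero <- midx[rowSums(Y[midx, , drop = FALSE]) == 0]
  if (length(allzero)) {
    mask[allzero] <- FALSE
    midx <- setdiff(midx, allzero)
  }
  if (!length(midx)) stop_validation("empty mask after excluding zero voxels")
  Ym <- Y[midx, , drop = FALSE]
  s0hat <- rowMeans(Ym[, scheme$is_b0, drop = FALSE])
  s0hat[s0hat <= 0] <- 1
  ratio <- pmin(pmax(Ym / s0hat, 1e-6), 1)
  logS <- log(ratio) + log(s0hat)             # log of the clipped signal
  g <- scheme$bvecs; b <- scheme$bvals
  X <- cbind(1,
             -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  beta <- cpp_wls_fit(t(logS), X, reweight = if (method == "wls") 1L else 0L)
  D <- matrix(NA_real_, nv, 6)
  # design columns: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz -> reorder to
  # (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
  D[midx, ] <- t(beta[c(2, 5, 3, 6, 7, 4), , drop = FALSE])
  S0 <- array(NA_real_, grid$shape)
  S0[midx] <- exp(beta[1, ])
  structure(list(grid = grid, D = D, S0 = S0, mask = mask),
            class = "tensor_field")
}

#' Eigendecompose a tensor field
#'
#' Per-voxel symmetric eigendecomposition, eigenvalues sorted descending
#' (lambda1 >= lambda2 >= lambda3) with orthonormal eigenvectors.
#' Eigenvalues below the floor `eps` are clamped to it (when
#' `clamp = TRUE`) and the number of affected voxels is recorded in
#' `n_clamped` — inverse-eigenvalue measures explode otherwise.
#'
#' @param tensors a `tensor_field`.
#' @param clamp clamp small/negative eigenvalues to `eps`?
#' @param eps eigenvalue floor in mm^2/s.
#' @return an `eigen_system`: `lambda` (n_vox x 3), `vectors`
#'   (n_vox x 9; e1, e2, e3 concatenated), `mask`, `grid`, `n_clamped`.
#' @export
eigendecompose <- function(tensors, clamp = TRUE, eps = EPS_LAMBDA) {
  midx <- which(as.vector(tensors$mask))
  Dm <- tensors$D[midx, , drop = FALSE]
  if (any(!is.finite(Dm))) {
    bad <- midx[which(rowSums(!is.finite(Dm)) > 0)[1]]
    stop_validation("non-finite tensor at voxel index ", bad)
  }
  ed <- cpp_eig3(t(Dm))
  lam <- t(ed$lambda)
  vec <- t(ed$vectors)
  n_clamped <- 0L
  if (clamp) {
    low <- lam < eps
    n_clamped <- sum(rowSums(low) > 0)
    lam[low] <- eps
  }
  nv <- prod(tensors$grid$shape)
  lambda <- matrix(NA_real_, nv, 3)
  vectors <- matrix(NA_real_, nv, 9)
  lambda[midx, ] <- lam
  vectors[midx, ] <- vec
  structure(list(grid = tensors$grid, lambda = lambda, vectors = vectors,
                 mask = tensors$mask, n_clamped = n_clamped),
            class = "eigen_system")
}

#' DTI scalar maps from an eigensystem
#'
#' MD = (l1+l2+l3)/3, AD = l1, RD = (l2+l3)/2 and
#' FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2)), with FA = 0
#' where all eigenvalues vanish.
#'
#' @param eigen an `eigen_system`.
#' @return named list of [scalar_map()]s: FA, MD, AD, RD.
#' @export
dti_scalars <- function(eigen) {
  lam <- eigen$lambda
  md <- rowMeans(lam)
  ss <- rowSums(lam^2)
  dev <- rowSums((lam - md)^2)
  fa <- sqrt(1.5) * sqrt(dev) / sqrt(ss)
  fa[which(ss == 0)] <- 0
  fa <- pmin(pmax(fa, 0), 1)
  shp <- eigen$grid$shape
  list(FA = scalar_map(eigen$grid, "FA", array(fa, shp)),
       MD = scalar_map(eigen$grid, "MD", array(md, shp)),
       AD = scalar_map(eigen$grid, "AD", array(lam[, 1], shp)),
       RD = scalar_map(eigen$grid, "RD", array((lam[, 2] + lam[, 3]) / 2, shp)))
}
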