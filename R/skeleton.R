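# TBSS-style mean-FA skeleton and projection of subject maps onto it.
#
# The skeleton rule is self-contained rather than a re-implementation of
# the original tool: a voxel is on the skeleton when the (slightly
# smoothed) mean FA exceeds the threshold and is a local maximum along
# the across-tract direction, taken as the dominant negative-curvature
# eigenvector of the local Hessian. Exact voxel-level agreement with the
# original TBSS binaries is a non-goal.

#' Inference / skeleton configuration
#'
#' @param fa_threshold mean-FA threshold separating white from gray
#'   matter (default 0.2).
#' @param n_permutations permutations per contrast (default 5000).
#' @param alpha significance level for corrected p (default 0.05).
#' @param tfce_h,tfce_e TFCE height and extent exponents (2, 0.5).
#' @param tfce_nsteps number of TFCE integration steps (dh = max/nsteps).
#' @param min_region_volume_mm3 smallest reportable significant volume
#'   within one atlas region (default 30 mm^3; regions at or below it are
#'   dropped).
#' @param search_radius_mm projection search distance perpendicular to
#'   the skeleton (default 4 mm).
#' @param smooth_sigma_vox Gaussian smoothing (voxels) applied to the
#'   mean FA before ridge detection.
#' @param seed integer seed for the permutation stream.
#' @return object of class `inference_config`.
#' @export
inference_config <- function(fa_threshold = 0.2, n_permutations = 5000,
                             alpha = 0.05, tfce_h = 2, tfce_e = 0.5,
                             tfce_nsteps = 100, min_region_volume_mm3 = 30,
                             search_radius_mm = 4, smooth_sigma_vox = 1,
                             seed = 1) {
  if (n_permutations < 100) stop_validation("n_permutations must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  if (tfce_h <= 0 || tfce_e <= 0) stop_validation("TFCE exponents must be > 0")
  if (min_region_volume_mm3 < 0) stop_validation("min_region_volume_mm3 must be >= 0")
  structure(list(fa_threshold = fa_threshold,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 tfce_h = tfce_h, tfce_e = tfce_e,
                 tfce_nsteps = as.integer(tfce_nsteps),
                 min_region_volume_mm3 = min_region_volume_mm3,
                 search_radius_mm = search_radius_mm,
                 smooth_sigma_vox = smooth_sigma_vox, seed = seed),
            class = "inference_config")
}

# central-difference gradient of a 3-D array (mm units); n_vox x 3
fa_gradient <- function(f, voxel_size) {
  d <- dim(f)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  sh <- function(dx, dy, dz)
    f[pad(seq_len(d[1]) + dx, d[1]),
      pad(seq_len(d[2]) + dy, d[2]),
      pad(seq_len(d[3]) + dz, d[3])]
  cbind(as.vector(sh(1,0,0) - sh(-1,0,0)) / (2 * voxel_size[1]),
        as.vector(sh(0,1,0) - sh(0,-1,0)) / (2 * voxel_size[2]),
        as.vector(sh(0,0,1) - sh(0,0,-1)) / (2 * voxel_size[3]))
}

# dominant negative-curvature direction of the Hessian of `f` (mm units)
# at every voxel; returns n_vox x 3 unit vectors
hessian_ridge_dirs <- function(f, voxel_size) {
  d <- dim(f)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  sh <- function(dx, dy, dz)
    f[pad(seq_len(d[1]) + dx, d[1]),
      pad(seq_len(d[2]) + dy, d[2]),
      pad(seq_len(d[3]) + dz, d[3])]
  h <- voxel_size
  H <- array(0, c(prod(d), 3, 3))
  H[, 1, 1] <- as.vector(sh(1,0,0) - 2*f + sh(-1,0,0)) / h[1]^2
  H[, 2, 2] <- as.vector(sh(0,1,0) - 2*f + sh(0,-1,0)) / h[2]^2
  H[, 3, 3] <- as.vector(sh(0,0,1) - 2*f + sh(0,0,-1)) / h[3]^2
  H[, 1, 2] <- H[, 2, 1] <-
    as.vector(sh(1,1,0) - sh(1,-1,0) - sh(-1,1,0) + sh(-1,-1,0)) /
    (4 * h[1] * h[2])
  H[, 1, 3] <- H[, 3, 1] <-
    as.vector(sh(1,0,1) - sh(1,0,-1) - sh(-1,0,1) + sh(-1,0,-1)) /
    (4 * h[1] * h[3])
  H[, 2, 3] <- H[, 3, 2] <-
    as.vector(sh(0,1,1) - sh(0,1,-1) - sh(0,-1,1) + sh(0,-1,-1)) /
    (4 * h[2] * h[3])
  Dm <- rbind(H[, 1, 1], H[, 1, 2], H[, 2, 2], H[, 1, 3], H[, 2, 3], H[, 3, 3])
  ed <- cpp_eig3(Dm)
  # eigenvalues descending; the most negative curvature direction is e3
  list(e3 = t(ed$vectors[7:9, , drop = FALSE]),
       e2 = t(ed$vectors[4:6, , drop = FALSE]),
       lam = t(ed$lambda))
}

#' Build a mean-FA skeleton
#'
#' @param fa_maps list of subject FA [scalar_map()]s on one grid.
#' @param config an [inference_config()].
#' @return a `skeleton_model`: `grid`, `mean_fa` (3-D), `mask` (3-D
#'   logical), `idx` (skeleton voxel indices), `perp` (n_skel x 3
#'   across-tract unit directions), `adjacency` (26-neighbourhood CSR on
#'   the skeleton).
#' @export
build_skeleton <- function(fa_maps, config = inference_config()) {
  if (length(fa_maps) < 2) stop_validation("need >= 2 subjects")
  grid <- fa_maps[[1]]$grid
  for (m in fa_maps)
    if (!grids_identical(grid, m$grid))
      stop_validation("FA maps are not on a common grid")
  mean_fa <- Reduce(`+`, lapply(fa_maps, function(m) {
    v <- m$values; v[is.na(v)] <- 0; v
  })) / length(fa_maps)
  fs <- gauss_smooth3(mean_fa, config$smooth_sigma_vox)
  hr <- hessian_ridge_dirs(fs, grid$voxel_size)
  cand <- which(mean_fa > config$fa_threshold)
  # grid faces have one-sided derivative support only; exclude them
  bjk <- arrayInd(cand, grid$shape)
  interior <- bjk[, 1] > 1 & bjk[, 1] < grid$shape[1] &
              bjk[, 2] > 1 & bjk[, 2] < grid$shape[2] &
              bjk[, 3] > 1 & bjk[, 3] < grid$shape[3]
  cand <- cand[interior]
  mask <- array(FALSE, grid$shape)
  ridge_max <- function(vals, ijk, u) {
    # local max of the smoothed FA along the direction u (~1 voxel steps)
    step <- sweep(u, 2, grid$voxel_size, "/")
    step <- step / pmax(apply(abs(step), 1, max), 1e-12)
    keep <- rep(TRUE, nrow(ijk))
    for (s in c(1, 2)) {
      fwd <- trilinear(fs, ijk + s * step, outside = 0)
      bwd <- trilinear(fs, ijk - s * step, outside = 0)
      keep <- keep & vals >= fwd - 1e-12 & vals >= bwd - 1e-12
    }
    keep
  }
  if (length(cand)) {
    ijk <- arrayInd(cand, grid$shape)
    ctr <- fs[cand]
    keep <- ridge_max(ctr, ijk, hr$e3[cand, , drop = FALSE])
    # where the second curvature is comparably negative (tube-like rather
    # than sheet-like cross-section) require a ridge along it as well
    lam <- hr$lam[cand, , drop = FALSE]
    tube <- lam[, 2] < 0 & lam[, 2] <= 0.25 * lam[, 3]
    k2 <- ridge_max(ctr, ijk, hr$e2[cand, , drop = FALSE])
    keep <- keep & (!tube | k2)
    # off-ridge voxels have a substantial FA gradient; they must not be
    # kept just because some curvature direction is tangential, so also
    # require a local maximum along the gradient where it is non-trivial
    gr <- fa_gradient(fs, grid$voxel_size)[cand, , drop = FALSE]
    gn <- sqrt(rowSums(gr^2))
    strong <- gn > 0.1 * max(gn)
    if (any(strong)) {
      kg <- ridge_max(ctr[strong], ijk[strong, , drop = FALSE],
                      gr[strong, , drop = FALSE] / gn[strong])
      keep[strong] <- keep[strong] & kg
    }
    mask[cand[keep]] <- TRUE
  }
  idx <- which(mask)
  structure(list(grid = grid, mean_fa = mean_fa, mask = mask, idx = idx,
                 perp = hr$e3[idx, , drop = FALSE],
                 adjacency = if (length(idx)) mask_adjacency(mask) else NULL),
            class = "skeleton_model")
}

#' Projection indices for one subject
#'
#' For each skeleton voxel, searches along the across-tract direction
#' (both ways, up to `search_radius_mm`) for the subject's maximum-FA
#' voxel. The returned source indices are computed once per subject from
#' FA and reused to project every measure.
#'
#' @param skeleton a `skeleton_model`.
#' @param subject_fa the subject's FA [scalar_map()].
#' @param config an [inference_config()].
#' @return integer vector of source voxel indices, one per skeleton
#'   voxel.
#' @export
projection_indices <- function(skeleton, subject_fa,
                               config = inference_config()) {
  grid <- skeleton$grid
  if (!grids_identical(grid, subject_fa$grid))
    stop_validation("subject map is not on the skeleton grid")
  fa <- subject_fa$values
  fa[is.na(fa)] <- 0
  d <- grid$shape
  idx <- skeleton$idx
  n <- length(idx)
  if (!n) return(integer(0))
  ijk <- arrayInd(idx, d)
  step_mm <- min(grid$voxel_size)
  offs <- seq(-config$search_radius_mm, config$search_radius_mm, by = step_mm)
  best <- rep(-Inf, n)
  src <- idx
  for (o in offs) {
    p <- ijk + sweep(skeleton$perp, 2, grid$voxel_size, "/") * o
    pr <- round(p)
    ok <- pr[, 1] >= 1 & pr[, 1] <= d[1] & pr[, 2] >= 1 & pr[, 2] <= d[2] &
          pr[, 3] >= 1 & pr[, 3] <= d[3]
    lin <- rep(NA_integer_, n)
    lin[ok] <- pr[ok, 1] + (pr[ok, 2] - 1L) * d[1] +
      (pr[ok, 3] - 1L) * d[1] * d[2]
    val <- rep(-Inf, n)
    val[ok] <- fa[lin[ok]]
    upd <- which(val > best + 1e-15)
    best[upd] <- val[upd]
    src[upd] <- lin[upd]
  }
  as.integer(src)
}

#' Project a subject map onto the skeleton
#'
#' @param skeleton a `skeleton_model`.
#' @param subject_map the measure to project (any [scalar_map()]).
#' @param subject_fa the same subject's FA map, or precomputed indices
#'   from [projection_indices()].
#' @param config an [inference_config()].
#' @return numeric vector of projected values, one per skeleton voxel.
#' @export
project_to_skeleton <- function(skeleton, subject_map, subject_fa,
                                config = inference_config()) {
  src <- if (is.numeric(subject_fa)) as.integer(subject_fa)
         else projection_indices(skeleton, subject_fa, config)
  if (length(src) != length(skeleton$idx))
    stop_validation("projection index length does not match the skeleton")
  if (!grids_identical(skeleton$grid, subject_map$grid))
    stop_validation("subject map is not on the skeleton grid")
  subject_map$values[src]
}

#' Project a whole cohort
#'
#' Computes each subject's projection indices from FA once, then applies
#' them to every requested measure.
#'
#' @param skeleton a `skeleton_model`.
#' @param maps list over subjects of named lists of [scalar_map()]s
#'   (must include FA).
#' @param measures measure names to project.
#' @param config an [inference_config()].
#' @return named list of subjects x skeleton-voxel matrices.
#' @export
project_cohort <- function(skeleton, maps, measures = "FA",
                           config = inference_config()) {
  n <- length(maps)
  out <- lapply(measures, function(m)
    matrix(NA_real_, n, length(skeleton$idx)))
  names(out) <- measures
  for (s in seq_len(n)) {
    src <- projection_indices(skeleton, maps[[s]]$FA, config)
    for (m in measures)
      out[[m]][s, ] <- project_to_skeleton(skeleton, maps[[s]][[m]], src,
                                           config)
  }
  out
}
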