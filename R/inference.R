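# TFCE, permutation-based family-wise-error inference (Freedman-Lane),
# and atlas-region reporting.

#' Threshold-free cluster enhancement on the skeleton
#'
#' TFCE(v) = sum over thresholds h of e(h, v)^E * h^H * dh, where
#' e(h, v) is the extent (voxel count) of the cluster supporting v at
#' height h, clusters use 26-connectivity restricted to the skeleton,
#' and dh = max(stat)/nsteps. One-sided: non-positive input yields zero.
#'
#' @param stat numeric statistic per skeleton voxel.
#' @param adjacency CSR adjacency from a `skeleton_model`
#'   (`skeleton$adjacency`) or [mask_adjacency()].
#' @param config an [inference_config()] (uses tfce_h, tfce_e,
#'   tfce_nsteps).
#' @return numeric vector of enhanced values.
#' @export
tfce_enhance <- function(stat, adjacency, config = inference_config()) {
  if (any(!is.finite(stat))) stop_validation("non-finite statistic map")
  if (length(stat) != adjacency$n)
    stop_validation("statistic length does not match the adjacency")
  cpp_tfce(as.numeric(stat), adjacency$indptr, adjacency$indices,
           config$tfce_e, config$tfce_h, config$tfce_nsteps)
}

# distinct two-group relabelings (columns = indicator of group A),
# enumerated exactly when feasible
enumerate_relabelings <- function(ga, n_max) {
  n <- length(ga)
  na <- sum(ga)
  total <- choose(n, na)
  if (total <= n_max) {
    cmb <- utils::combn(n, na)
    lapply(seq_len(ncol(cmb)), function(j) {
      z <- logical(n); z[cmb[, j]] <- TRUE; z
    })
  } else NULL
}

#' Permutation inference with TFCE and FWE correction
#'
#' Two-sample comparison on skeleton-projected data with optional
#' nuisance covariates, following the Freedman-Lane scheme: covariates
#' are regressed out, residuals are relabeled at each permutation, the
#' group t-statistic map is recomputed, TFCE-enhanced, and its maximum
#' recorded. Corrected p(v) = (1 + #\{perm max >= observed TFCE(v)\}) /
#' (1 + n_permutations), so the smallest attainable p is
#' 1/(1 + n_permutations). When fewer distinct relabelings exist than
#' requested permutations, all of them are enumerated exactly.
#'
#' @param data subjects x skeleton-voxels matrix of projected values.
#' @param group factor/character with exactly two levels (contrast
#'   `levels[1] - levels[2]`).
#' @param covariates optional data.frame / matrix of nuisance variables.
#' @param adjacency skeleton adjacency (e.g. `skeleton$adjacency`).
#' @param config an [inference_config()] (n_permutations, seed, TFCE
#'   parameters, alpha).
#' @param contrasts which one-sided contrasts to compute: "both"
#'   (default), "greater" (A > B) or "less" (A < B).
#' @return object of class `stat_maps`: per contrast a list with `tstat`,
#'   `tfce`, `p_corr`, `contrast`; plus `n_permutations_used`, `exact`.
#' @export
permutation_fwe <- function(data, group, covariates = NULL, adjacency,
                            config = inference_config(),
                            contrasts = c("both", "greater", "less")) {
  contrasts <- match.arg(contrasts)
  data <- as.matrix(data)
  n <- nrow(data)
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L)
    stop_validation("exactly two groups are required per contrast")
  if (any(table(group) < 2L))
    stop_validation("each group needs >= 2 subjects")
  ga <- group == levels(group)[1]
  Z <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    if (nrow(C) != n) stop_validation("covariate rows do not match subjects")
    for (j in seq_len(ncol(C)))
      if (stats::sd(C[, j]) < 1e-12)
        stop_validation("covariate ", j, " is constant (collinear with the intercept)")
    Z <- cbind(Z, scale(C, scale = FALSE))
    if (qr(cbind(Z, as.numeric(ga)))$rank < ncol(Z) + 1L)
      stop_validation("covariates are collinear with the group contrast")
  }
  # Freedman-Lane: residualize against nuisance only
  Ql <- qr(Z)
  E <- data - Z %*% qr.coef(Ql, data)
  tmap_fun <- function(Yp, gvec) {
    X <- cbind(Z, as.numeric(gvec))
    p <- ncol(X)
    XtXi <- solve(crossprod(X))
    XtY <- crossprod(X, Yp)
    beta <- XtXi %*% XtY
    rss <- colSums(Yp^2) - colSums(XtY * beta)
    rss[rss < 0] <- 0
    se2 <- XtXi[p, p] * rss / (n - p)
    tt <- beta[p, ] / sqrt(pmax(se2, .Machine$double.xmin))
    tt[se2 == 0] <- 0
    tt
  }
  obs_t <- tmap_fun(E, ga)
  want <- switch(contrasts, both = c("greater", "less"),
                 greater = "greater", less = "less")
  obs_tfce <- list()
  if ("greater" %in% want)
    obs_tfce$greater <- tfce_enhance(obs_t, adjacency, config)
  if ("less" %in% want)
    obs_tfce$less <- tfce_enhance(-obs_t, adjacency, config)
  exact <- enumerate_relabelings(ga, config$n_permutations)
  run_perm <- function() {
    if (!is.null(exact)) {
      nperm <- length(exact)
      tmats <- lapply(exact, function(z) tmap_fun(E, z))
    } else {
      nperm <- config$n_permutations
      tmats <- lapply(seq_len(nperm), function(i) tmap_fun(E[sample(n), ], ga))
    }
    maxes <- list(greater = numeric(0), less = numeric(0))
    for (tt in tmats) {
      if ("greater" %in% want)
        maxes$greater <- c(maxes$greater,
                           max(tfce_enhance(tt, adjacency, config)))
      if ("less" %in% want)
        maxes$less <- c(maxes$less,
                        max(tfce_enhance(-tt, adjacency, config)))
    }
    list(nperm = nperm, maxes = maxes)
  }
  pr <- if (!is.null(config$seed)) withr::with_seed(config$seed, run_perm())
        else run_perm()
  res <- list()
  for (side in want) {
    mx <- pr$maxes[[side]]
    ot <- obs_tfce[[side]]
    pc <- (1 + vapply(ot, function(v) sum(mx >= v), 0L)) / (1 + pr$nperm)
    res[[side]] <- list(
      tstat = if (side == "greater") obs_t else -obs_t,
      tfce = ot, p_corr = pmin(pc, 1),
      contrast = paste(levels(group)[1],
                       if (side == "greater") ">" else "<",
                       levels(group)[2]))
  }
  structure(list(contrast_maps = res, n_permutations_used = pr$nperm,
                 exact = !is.null(exact), alpha = config$alpha),
            class = "stat_maps")
}

#' Atlas-region report of significant skeleton voxels
#'
#' Per atlas region: the significant volume (count of region-and-skeleton
#' voxels with corrected p < alpha times the voxel volume), the minimum
#' corrected p, and the world-coordinate peak (smallest corrected p; ties
#' broken by larger TFCE, then lower voxel index). Regions whose
#' significant volume does not exceed `min_region_volume_mm3` are
#' dropped. Sorted by region name.
#'
#' @param stat a `stat_maps` object from [permutation_fwe()].
#' @param side "greater" or "less" — which one-sided contrast to report.
#' @param atlas a [label_map()] on the skeleton grid.
#' @param skeleton the `skeleton_model` the statistics live on.
#' @param config an [inference_config()].
#' @return data.frame: region, volume_mm3, min_p_corr, peak_x/y/z (mm).
#' @export
roi_report <- function(stat, side, atlas, skeleton,
                       config = inference_config()) {
  if (!side %in% names(stat$contrast_maps))
    stop_validation("contrast side '", side, "' was not computed")
  if (!grids_identical(atlas$grid, skeleton$grid))
    stop_validation("atlas grid does not match the skeleton grid")
  cm <- stat$contrast_maps[[side]]
  idx <- skeleton$idx
  lab <- atlas$labels[idx]
  sig <- cm$p_corr < config$alpha
  vv <- voxel_volume(skeleton$grid)
  out <- list()
  for (lb in sort(unique(lab[lab > 0 & sig]))) {
    in_reg <- lab == lb & sig
    vol <- sum(in_reg) * vv
    if (vol <= config$min_region_volume_mm3) next
    cand <- which(in_reg)
    o <- order(cm$p_corr[cand], -cm$tfce[cand], cand)
    peak <- cand[o[1]]
    w <- voxel_to_world(skeleton$grid,
                        arrayInd(idx[peak], skeleton$grid$shape))
    out[[length(out) + 1L]] <- data.frame(
      region = unname(atlas$lookup[[as.character(lb)]]),
      volume_mm3 = vol,
      min_p_corr = min(cm$p_corr[cand]),
      peak_x = w[1], peak_y = w[2], peak_z = w[3],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(region = character(0), volume_mm3 = numeric(0),
                      min_p_corr = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$region), , drop = FALSE]
}
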