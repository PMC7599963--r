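# Self-contained simulation studies: null calibration of the skeleton
# permutation test and recovery of a seeded group effect through the full
# pipeline. These encode the package's reference validation conditions
# and are reused by the test suite and the acceptance script.

#' Family-wise error calibration under the null
#'
#' Simulates datasets of two groups drawn from one normal distribution on
#' a block "skeleton", runs the TFCE permutation test (one-sided A > B)
#' and reports how often the family-wise minimum corrected p falls below
#' alpha. For a calibrated test the rate is ~alpha.
#'
#' @param n_datasets number of simulated null cohorts.
#' @param n_per_group subjects per group.
#' @param skeleton_shape 3-D dimensions of the block skeleton (512 voxels
#'   by default).
#' @param n_permutations permutations per dataset.
#' @param alpha nominal level.
#' @param seed integer seed for the whole study.
#' @return list: `rejection_rate`, `n_datasets`, `rejected` (logical).
#' @export
simulate_null_calibration <- function(n_datasets = 200, n_per_group = 12,
                                      skeleton_shape = c(8, 8, 8),
                                      n_permutations = 500, alpha = 0.05,
                                      seed = 1) {
  adj <- mask_adjacency(array(TRUE, skeleton_shape))
  nv <- adj$n
  n <- 2 * n_per_group
  grp <- rep(c("A", "B"), each = n_per_group)
  rej <- withr::with_seed(seed, {
    dataset_seeds <- sample.int(.Machine$integer.max - 1, n_datasets)
    vapply(seq_len(n_datasets), function(i) {
      dat <- matrix(rnorm(n * nv), n, nv)
      cfg <- inference_config(n_permutations = n_permutations,
                              seed = dataset_seeds[i])
      r <- permutation_fwe(dat, grp, NULL, adj, cfg, contrasts = "greater")
      min(r$contrast_maps$greater$p_corr) < alpha
    }, NA)
  })
  list(rejection_rate = mean(rej), n_datasets = n_datasets, rejected = rej)
}

#' Recovery of a seeded axial-diffusivity effect
#'
#' One full-pipeline run: a two-tract phantom cohort with a
#' `factor_l1`-scaled lambda1 in tract A for the CM group (default -10%),
#' Rician noise at the given baseline SNR, tensor fitting, apparent
#' return-to-plane maps, skeleton construction, projection, and TFCE
#' permutation inference on both the AD (expected EM > CM) and RTPP
#' (expected EM < CM) contrasts, plus the region report for the AD
#' contrast.
#'
#' @param seed integer seed for this run.
#' @param n_per_group subjects per group (EM and CM).
#' @param snr baseline signal-to-noise ratio S0/sigma.
#' @param factor_l1 multiplicative effect on lambda1 in tract A for CM.
#' @param n_permutations permutations per contrast.
#' @return list with logical flags `ad_detected` (significant AD voxel
#'   inside tract A), `ad_specific` (no significant voxel beyond one
#'   voxel from tract A), `roi_listed` (tract A in the region report),
#'   `rtpp_detected` (significant opposite-direction RTPP voxel in tract
#'   A), plus the counts behind them.
#' @export
simulate_effect_recovery <- function(seed, n_per_group = 25, snr = 20,
                                     factor_l1 = 0.9,
                                     n_permutations = 1000) {
  grid <- volume_grid(c(30, 22, 10), c(2, 2, 2))
  trA <- tract_tube(c(2, 8, 8), c(58, 8, 8), radius = 5,
                    evals = c(1.7e-3, 0.3e-3, 0.3e-3), name = "tractA")
  trB <- tract_tube(c(2, 34, 8), c(58, 34, 8), radius = 5,
                    evals = c(1.7e-3, 0.3e-3, 0.3e-3), name = "tractB")
  ph <- phantom_spec(grid, list(trA, trB), background_eval = 0.7e-3,
                     S0 = 1000)
  scheme <- gradient_scheme(
    c(0, rep(1000, 61)),
    cbind(0, t(fibonacci_directions(61))))
  eff <- group_effect("CM", labels = 1L, factor_l1 = factor_l1)
  co <- generate_cohort(ph, list(eff),
                        list(EM = n_per_group, CM = n_per_group),
                        scheme, sigma = 1000 / snr, seed = seed)
  cfg <- eap_config()
  maps <- lapply(co$dwis, function(dwi) {
    es <- eigendecompose(fit_tensor(dwi))
    sc <- dti_scalars(es)
    adc <- directional_adc(dwi, config = cfg)
    ap <- apparent_eap_scalars(adc, es$vectors[, 1:3], cfg,
                               measures = "RTPP")
    c(sc, ap)
  })
  icfg <- inference_config(n_permutations = n_permutations, seed = seed + 1)
  sk <- build_skeleton(lapply(maps, `[[`, "FA"), icfg)
  proj <- project_cohort(sk, maps, c("AD", "RTPP"), icfg)
  grp <- co$table$group
  rAD <- permutation_fwe(proj$AD, grp, NULL, sk$adjacency, icfg)
  rRT <- permutation_fwe(proj$RTPP, grp, NULL, sk$adjacency, icfg)
  lab <- co$labels$labels[sk$idx]
  inA_wide <- near_region(co$labels, sk$idx, region = 1L, dilate = 1L)
  sigAD <- rAD$contrast_maps$greater$p_corr < icfg$alpha  # EM > CM
  sigRT <- rRT$contrast_maps$less$p_corr < icfg$alpha     # EM < CM
  rep <- roi_report(rAD, "greater", co$labels, sk, icfg)
  list(ad_detected = any(sigAD & lab == 1L),
       ad_specific = !any(sigAD & !inA_wide),
       roi_listed = "tractA" %in% rep$region,
       rtpp_detected = any(sigRT & lab == 1L),
       n_skeleton = length(sk$idx),
       n_sig_ad = sum(sigAD), n_sig_rtpp = sum(sigRT),
       report = rep)
}

# TRUE for skeleton voxels within `dilate` voxels (Chebyshev) of `region`
near_region <- function(labels, idx, region, dilate = 1L) {
  d <- labels$grid$shape
  reg <- array(labels$labels == region, d)
  if (dilate > 0) {
    for (k in seq_len(dilate)) {
      grown <- reg
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        sh <- array(FALSE, d)
        src <- seq_len(d[ax] - 1L)
        if (ax == 1) { if (s > 0) sh[src + 1L, , ] <- reg[src, , ]
                       else sh[src, , ] <- reg[src + 1L, , ] }
        if (ax == 2) { if (s > 0) sh[, src + 1L, ] <- reg[, src, ]
                       else sh[, src, ] <- reg[, src + 1L, ] }
        if (ax == 3) { if (s > 0) sh[, , src + 1L] <- reg[, , src]
                       else sh[, , src] <- reg[, , src + 1L] }
        grown <- grown | sh
      }
      reg <- grown
    }
  }
  reg[idx]
}

#' Deterministic well-spread unit directions (Fibonacci lattice)
#'
#' The reference 61-direction single-shell scheme used by the validation
#' studies is built from these.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}
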