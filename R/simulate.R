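# Forward simulation: Gaussian tensor signal + Rician noise, and the
# three-group synthetic cohort generator.

#' Rician noise specification
#' @param sigma noise standard deviation of each Gaussian channel, in
#'   intensity units (>= 0; 0 means noise-free).
#' @param seed integer seed (NULL leaves the RNG stream untouched).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0)
    stop_validation("sigma must be >= 0")
  structure(list(model = "rician", sigma = sigma, seed = seed),
            class = "noise_spec")
}

#' Simulate a diffusion-weighted stack from a tensor field
#'
#' Noise-free signal follows the Gaussian (tensor) forward model
#' S(g, b) = S0 exp(-b g' D g). Rician noise is applied as
#' |(S + N(0, sigma^2)) + i N(0, sigma^2)|, the magnitude-image noise
#' model of MRI.
#'
#' @param tensors a `tensor_field` (e.g. from [build_tensor_phantom()]).
#' @param scheme a [gradient_scheme()].
#' @param S0 baseline intensity: scalar or 3-D array (defaults to the
#'   field's own S0).
#' @param noise a [noise_spec()].
#' @return a [dwi_stack()].
#' @export
simulate_dwi <- function(tensors, scheme, S0 = NULL, noise = noise_spec(0)) {
  grid <- tensors$grid
  if (is.null(S0)) S0 <- tensors$S0
  if (length(S0) == 1L) S0 <- array(S0, grid$shape)
  g <- scheme$bvecs; b <- scheme$bvals
  # quadratic-form coefficients per volume, matching D's component order
  A <- cbind(g[1, ]^2, 2 * g[1, ] * g[2, ], g[2, ]^2,
             2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ], g[3, ]^2) * b
  Q <- tensors$D %*% t(A)                      # n_vox x n_vol
  S <- as.vector(S0) * exp(-Q)
  sim <- function() {
    if (noise$sigma > 0) {
      n <- length(S)
      re <- S + rnorm(n, 0, noise$sigma)
      im <- rnorm(n, 0, noise$sigma)
      S <- sqrt(re^2 + im^2)
    }
    dwi_stack(grid, array(S, c(grid$shape, length(b))), scheme)
  }
  if (!is.null(noise$seed)) withr::with_seed(noise$seed, sim()) else sim()
}

#' Default demographics configuration
#'
#' Per-group marginal distributions for the demographic and clinical
#' fields: normal means/SDs (truncated at physical bounds) for the
#' continuous fields, Bernoulli probabilities for the binary ones.
#' Defaults reproduce the marginal structure of a three-group
#' migraine case-control cohort (ages ~36-38 y; duration of migraine
#' history 14.1 +/- 11.1 y in EM vs 19.6 +/- 10.4 y in CM; headache
#' frequency 3.6 +/- 1.9 vs 23.3 +/- 6.3 days/month; migraine frequency
#' 3.6 +/- 1.9 vs 13.9 +/- 6.9 days/month; time from onset of
#' chronification 24.5 +/- 32.9 months; male fraction 0.22/0.17/0.11;
#' aura 0.167/0.018; medication overuse 0/0.75).
#'
#' @return nested list, one entry per group.
#' @export
default_demographics <- function() {
  list(
    HC = list(age = c(36.1, 13.2), p_male = 11 / 50),
    EM = list(age = c(37.1, 8.2), p_male = 9 / 54,
              duration = c(14.1, 11.1),
              headache_freq = c(3.6, 1.9), migraine_freq = c(3.6, 1.9),
              p_aura = 9 / 54, p_overuse = 0 / 54),
    CM = list(age = c(38.1, 8.7), p_male = 6 / 56,
              duration = c(19.6, 10.4), cm_onset_months = c(24.5, 32.9),
              headache_freq = c(23.3, 6.3), migraine_freq = c(13.9, 6.9),
              p_aura = 1 / 56, p_overuse = 42 / 56)
  )
}

sample_demographics <- function(n_per_group, config = default_demographics()) {
  rows <- list()
  for (grp in names(n_per_group)) {
    n <- n_per_group[[grp]]
    cf <- config[[grp]]
    r <- data.frame(
      id = sprintf("%s%03d", grp, seq_len(n)),
      group = grp,
      sex = ifelse(rbinom(n, 1, cf$p_male) == 1, "male", "female"),
      age = rtruncnorm_meanmatch(n, cf$age[1], cf$age[2], 18, 80),
      duration = NA_real_, cm_onset_months = NA_real_,
      headache_freq = NA_real_, migraine_freq = NA_real_,
      aura = NA, overuse = NA,
      stringsAsFactors = FALSE)
    if (grp %in% c("EM", "CM")) {
      r$duration <- rtruncnorm_meanmatch(n, cf$duration[1], cf$duration[2], 0.5, 60)
      r$headache_freq <- rtruncnorm_meanmatch(n, cf$headache_freq[1],
                                    cf$headache_freq[2], 0, 31)
      r$migraine_freq <- pmin(
        rtruncnorm_meanmatch(n, cf$migraine_freq[1], cf$migraine_freq[2], 0, 31),
        r$headache_freq)
      r$aura <- rbinom(n, 1, cf$p_aura) == 1
      r$overuse <- rbinom(n, 1, cf$p_overuse) == 1
    }
    if (grp == "CM")
      r$cm_onset_months <- rtruncnorm_meanmatch(n, cf$cm_onset_months[1],
                                      cf$cm_onset_months[2], 1, 240)
    rows[[grp]] <- r
  }
  cohort_table(do.call(rbind, rows))
}

#' Seeded group effect on tract microstructure
#'
#' A multiplicative change of the generating eigenvalues inside given
#' phantom regions, applied to every subject of the target group. E.g.
#' `factor_l1 = 0.9` lowers lambda1 (hence axial diffusivity) by 10%,
#' which raises the return-to-plane probability.
#'
#' @param group "EM" or "CM".
#' @param labels integer label ids of the affected phantom regions.
#' @param factor_l1 multiplicative factor on lambda1.
#' @param factor_l23 multiplicative factor on lambda2 and lambda3.
#' @return object of class `group_effect`.
#' @export
group_effect <- function(group, labels, factor_l1 = 1, factor_l23 = 1) {
  group <- match.arg(group, c("EM", "CM"))
  if (factor_l1 <= 0 || factor_l23 <= 0)
    stop_validation("effect factors must be positive")
  structure(list(group = group, labels = as.integer(labels),
                 factor_l1 = factor_l1, factor_l23 = factor_l23),
            class = "group_effect")
}

#' Generate a synthetic three-group cohort
#'
#' Every subject shares the phantom geometry; subjects of a targeted
#' group get the seeded eigenvalue effects inside the affected regions;
#' all subjects get an independent global eigenvalue scaling
#' ~ Normal(1, jitter_sd^2) truncated to \[0.9, 1.1\] (between-subject
#' variability), and Rician noise on the simulated signal. The whole
#' cohort is a pure function of (specs, seed).
#'
#' @param phantom a [phantom_spec()].
#' @param effects list of [group_effect()]s.
#' @param n_per_group named vector/list, subjects per group (each > 1).
#' @param scheme a [gradient_scheme()].
#' @param sigma Rician noise sd (intensity units); the baseline
#'   signal-to-noise ratio is S0/sigma.
#' @param demographics per-group distribution config
#'   ([default_demographics()]).
#' @param jitter_sd sd of the per-subject global eigenvalue scaling.
#' @param seed integer seed; same seed, same cohort.
#' @return list: `dwis` (list of [dwi_stack()] per subject, named by id),
#'   `table` ([cohort_table()]), `labels` (the phantom [label_map()]),
#'   `truth` (per-voxel generating eigenvalues per group).
#' @export
generate_cohort <- function(phantom, effects, n_per_group, scheme,
                            sigma = 0, demographics = default_demographics(),
                            jitter_sd = 0.02, seed = 1) {
  n_per_group <- as.list(n_per_group)
  if (any(unlist(n_per_group) <= 1))
    stop_validation("need n > 1 per group (group statistics undefined)")
  base <- build_tensor_phantom(phantom)
  labvec <- as.vector(base$labels$labels)
  for (ef in effects)
    if (!all(ef$labels %in% labvec))
      stop_validation("effect targets label(s) absent from the phantom")
  withr::with_seed(seed, {
    tab <- sample_demographics(n_per_group, demographics)
    lambda_by_group <- list()
    dwis <- vector("list", nrow(tab))
    names(dwis) <- tab$id
    for (grp in names(n_per_group)) {
      lam <- base$lambda
      for (ef in effects) {
        if (ef$group != grp) next
        hit <- labvec %in% ef$labels
        lam[hit, 1] <- lam[hit, 1] * ef$factor_l1
        lam[hit, 2:3] <- lam[hit, 2:3] * ef$factor_l23
      }
      if (any(lam[, 1] < lam[, 2] | lam[, 2] < lam[, 3]))
        stop_validation("effect factors break the eigenvalue ordering")
      lambda_by_group[[grp]] <- lam
    }
    for (s in seq_len(nrow(tab))) {
      grp <- as.character(tab$group[s])
      scale <- rtruncnorm(1, 1, jitter_sd, 0.9, 1.1)
      lam <- lambda_by_group[[grp]] * scale
      D <- rebuild_tensors(base, lam)
      tf <- structure(list(grid = phantom$grid, D = D,
                           S0 = array(phantom$S0, phantom$grid$shape),
                           mask = array(TRUE, phantom$grid$shape)),
                      class = "tensor_field")
      dwis[[s]] <- simulate_dwi(tf, scheme, noise = noise_spec(sigma))
    }
    list(dwis = dwis, table = tab, labels = base$labels,
         truth = lambda_by_group)
  })
}

# rebuild the 6-component tensors from per-voxel eigenvalues, reusing the
# phantom's principal-axis field (background voxels are isotropic)
rebuild_tensors <- function(base, lam) {
  nv <- nrow(lam)
  D <- matrix(0, nv, 6)
  iso <- !is.finite(base$tangent[, 1])
  D[iso, c(1, 3, 6)] <- lam[iso, 1]
  ins <- which(!iso)
  if (length(ins)) {
    # eigenvalues are constant within each tract, but the jitter scaling
    # keeps them proportional, so build per unique triple
    key <- paste(lam[ins, 1], lam[ins, 2], lam[ins, 3])
    for (k in unique(key)) {
      sel <- ins[key == k]
      D[sel, ] <- tensor_from_axis(base$tangent[sel, , drop = FALSE],
                                   lam[sel[1], ])
    }
  }
  D
}
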