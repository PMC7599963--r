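# Return-probability scalars (RTOP, RTAP, RTPP), two routes:
#  (a) Gaussian closed forms in the tensor eigenvalues;
#  (b) the single-shell "apparent" construction: fit the directional ADC
#      on the shell with even spherical harmonics, extend the signal
#      mono-exponentially along each radial ray (the radial-independence
#      assumption), and evaluate the q-space integrals analytically per
#      direction, leaving spherical / equatorial averages to quadrature.

#' EAP configuration
#'
#' @param tau effective diffusion time in s. RTOP scales as tau^(-3/2),
#'   RTAP as tau^(-1), RTPP as tau^(-1/2); group contrasts and ratios are
#'   tau-free.
#' @param sh_order even spherical-harmonic order of the directional-ADC
#'   expansion; (sh_order+1)(sh_order+2)/2 coefficients must not exceed
#'   the number of gradient directions.
#' @param equator_samples points on the great circle for the RTAP
#'   average.
#' @param n_theta,n_phi polar (Gauss-Legendre) and azimuthal (trapezoid)
#'   resolution of the fixed spherical quadrature for RTOP.
#' @return object of class `eap_config`.
#' @export
eap_config <- function(tau = 0.025, sh_order = 6, equator_samples = 48,
                       n_theta = 24, n_phi = 48) {
  if (tau <= 0) stop_validation("tau must be > 0")
  if (sh_order < 0 || sh_order %% 2 != 0)
    stop_validation("sh_order must be even and >= 0")
  if (equator_samples < 16) stop_validation("equator_samples must be >= 16")
  structure(list(tau = tau, sh_order = sh_order,
                 equator_samples = equator_samples,
                 n_theta = n_theta, n_phi = n_phi),
            class = "eap_config")
}

n_sh_coef <- function(lmax) (lmax + 1) * (lmax + 2) / 2

# real, even-order, orthonormal spherical-harmonic design matrix
# dirs: n x 3 unit vectors -> n x n_sh_coef(lmax)
sh_basis <- function(dirs, lmax) {
  dirs <- matrix(dirs, ncol = 3)
  z <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  B <- matrix(0, n, n_sh_coef(lmax))
  col <- 1L
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, z)            # (l+1) x n, rows m = 0..l
    if (l == 0) P <- matrix(P, 1, n)
    for (m in -l:l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      B[, col] <- if (m == 0) nrm * P[1, ]
      else if (m > 0) sqrt(2) * nrm * P[am + 1, ] * cos(am * phi)
      else sqrt(2) * nrm * P[am + 1, ] * sin(am * phi)
      col <- col + 1L
    }
  }
  B
}

# fixed product quadrature on the sphere: Gauss-Legendre in cos(theta) x
# uniform azimuth; exact for band-limited integrands up to high order.
# Returns nodes (n x 3) and weights summing to 4*pi.
sphere_quadrature <- function(n_theta = 24, n_phi = 48) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(1 - ct^2, 0))
  ph <- rep(phi, n_theta)
  nodes <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  list(nodes = nodes, w = w)
}

#' Directional apparent diffusion coefficient profile
#'
#' Per masked voxel, E(u) = S(u)/S0 on the (single) shell, clipped to
#' \[1e-6, 1\], D(u) = -log(E(u))/b, then a least-squares fit with real
#' even spherical harmonics.
#'
#' @param dwi a single-shell [dwi_stack()].
#' @param S0 3-D baseline map (defaults to the mean of the b=0 volumes).
#' @param mask 3-D logical array.
#' @param config an [eap_config()].
#' @return an `adc_profile`: `coef` (n_coef x n_vox_masked SH
#'   coefficients), `midx` (masked voxel indices), `b`, `grid`,
#'   `sh_order`, `n_clipped`.
#' @export
directional_adc <- function(dwi, S0 = NULL, mask = NULL,
                            config = eap_config()) {
  scheme <- dwi$scheme
  if (!scheme$single_shell)
    stop_validation("single-shell scheme required")
  ndir <- sum(!scheme$is_b0)
  if (n_sh_coef(config$sh_order) > ndir)
    stop_validation("sh_order ", config$sh_order, " needs ",
                    n_sh_coef(config$sh_order),
                    " coefficients but only ", ndir, " directions are available")
  grid <- dwi$grid
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  nv <- prod(grid$shape)
  Y <- matrix(dwi$data, nv, length(scheme$bvals))
  if (is.null(S0))
    S0 <- array(rowMeans(Y[, scheme$is_b0, drop = FALSE]), grid$shape)
  midx <- which(as.vector(mask) & as.vector(S0) > 0)
  b <- scheme$b_shell[1]
  Edir <- Y[midx, !scheme$is_b0, drop = FALSE] / as.vector(S0)[midx]
  n_clipped <- sum(Edir < 1e-6 | Edir > 1)
  Edir <- pmin(pmax(Edir, 1e-6), 1)
  Ddir <- -log(Edir) / b                       # n_vox x n_dir
  B <- sh_basis(t(scheme$bvecs[, !scheme$is_b0, drop = FALSE]),
                config$sh_order)
  coef <- qr.solve(qr(B), t(Ddir))             # n_coef x n_vox
  structure(list(coef = coef, midx = midx, b = b, grid = grid,
                 sh_order = config$sh_order, n_clipped = n_clipped),
            class = "adc_profile")
}

#' Gaussian closed-form return probabilities from eigenvalues
#'
#' Under a Gaussian propagator with diffusion time tau:
#' RTOP = (4 pi tau)^(-3/2) (l1 l2 l3)^(-1/2),
#' RTPP = (4 pi tau l1)^(-1/2),
#' RTAP = (4 pi tau)^(-1) (l2 l3)^(-1/2).
#' RTOP and RTAP carry inverse square roots of the *small* eigenvalues,
#' which is why this route is fragile on noisy fits (hence the clamping
#' in [eigendecompose()]).
#'
#' @param eigen an `eigen_system`.
#' @param config an [eap_config()].
#' @param enforce_floor error if eigenvalues fall below the floor
#'   (expected to be pre-clamped); set FALSE to study the unclamped
#'   behaviour.
#' @return named list of [scalar_map()]s: RTOP, RTAP, RTPP.
#' @export
gaussian_eap_from_eigenvalues <- function(eigen, config = eap_config(),
                                          enforce_floor = TRUE) {
  lam <- eigen$lambda
  ok <- !is.na(lam[, 1])
  if (enforce_floor && any(lam[ok, ] < EPS_LAMBDA))
    stop_validation("eigenvalues below the floor; run eigendecompose(clamp = TRUE)")
  tau <- config$tau
  rtop <- (4 * pi * tau)^(-1.5) / sqrt(lam[, 1] * lam[, 2] * lam[, 3])
  rtpp <- (4 * pi * tau)^(-0.5) / sqrt(lam[, 1])
  rtap <- (4 * pi * tau)^(-1) / sqrt(lam[, 2] * lam[, 3])
  shp <- eigen$grid$shape
  mk <- function(name, v) {
    if (enforce_floor) v[which(v < 0)] <- NA
    scalar_map(eigen$grid, name, array(v, shp))
  }
  if (!enforce_floor) {
    # leave raw values (possibly Inf/NaN) untouched for stability studies
    return(list(RTOP = structure(list(grid = eigen$grid, name = "RTOP",
                                      values = array(rtop, shp),
                                      units = SCALAR_UNITS[["RTOP"]]),
                                 class = "scalar_map"),
                RTAP = structure(list(grid = eigen$grid, name = "RTAP",
                                      values = array(rtap, shp),
                                      units = SCALAR_UNITS[["RTAP"]]),
                                 class = "scalar_map"),
                RTPP = structure(list(grid = eigen$grid, name = "RTPP",
                                      values = array(rtpp, shp),
                                      units = SCALAR_UNITS[["RTPP"]]),
                                 class = "scalar_map")))
  }
  list(RTOP = mk("RTOP", rtop), RTAP = mk("RTAP", rtap),
       RTPP = mk("RTPP", rtpp))
}

#' Apparent return probabilities from a single shell
#'
#' Extends the shell signal mono-exponentially along each ray,
#' E(q u) = exp(-4 pi^2 tau q^2 D(u)), so the q-space integrals reduce to
#' directional averages of powers of the ADC profile:
#' RTOP = (4 pi tau)^(-3/2) <D(u)^(-3/2)> over the sphere,
#' RTPP = (4 pi tau D(e1))^(-1/2) on the principal axis,
#' RTAP = (4 pi tau)^(-1) <D(u)^(-1)> over the equator perpendicular to
#' e1. On a noise-free tensor signal all three agree with the eigenvalue
#' closed forms (the Gaussian signal is exactly mono-exponential along
#' every ray).
#'
#' @param adc an `adc_profile` from [directional_adc()].
#' @param e1 principal directions: n_vox x 3 matrix (rows for `adc$midx`
#'   voxels may be a superset), typically `eigen$vectors[, 1:3]`.
#' @param config an [eap_config()].
#' @param measures subset of c("RTOP", "RTAP", "RTPP") to compute (the
#'   equatorial RTAP average is the expensive one).
#' @return named list of [scalar_map()]s for the requested measures.
#' @export
apparent_eap_scalars <- function(adc, e1, config = eap_config(),
                                 measures = c("RTOP", "RTAP", "RTPP")) {
  measures <- match.arg(measures, several.ok = TRUE)
  tau <- config$tau
  midx <- adc$midx
  nvm <- length(midx)
  e1m <- matrix(e1, ncol = 3)[midx, , drop = FALSE]
  if (any(!is.finite(e1m)))
    stop_validation("missing principal direction at a masked voxel")
  n_floored <- 0L
  floorD <- function(x) {
    n_floored <<- n_floored + sum(x < EPS_LAMBDA)
    pmax(x, EPS_LAMBDA)
  }
  out <- list()
  shp <- adc$grid$shape
  mk <- function(name, vm) {
    v <- rep(NA_real_, prod(shp))
    v[midx] <- vm
    scalar_map(adc$grid, name, array(v, shp))
  }
  if ("RTOP" %in% measures) {
    # spherical average of D^(-3/2)
    q <- sphere_quadrature(config$n_theta, config$n_phi)
    Bq <- sh_basis(q$nodes, adc$sh_order)
    Dq <- floorD(Bq %*% adc$coef)            # n_nodes x n_vox
    out$RTOP <- mk("RTOP", (4 * pi * tau)^(-1.5) *
                     as.vector(crossprod(q$w, Dq^(-1.5))) / (4 * pi))
  }
  if ("RTAP" %in% measures) {
    # average of 1/D over the great circle perpendicular to e1
    M <- config$equator_samples
    ref <- matrix(rep(c(0, 0, 1), each = nvm), nvm, 3)
    swap <- abs(e1m[, 3]) > 0.9
    ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    v1 <- ref - e1m * rowSums(ref * e1m)
    v1 <- v1 / sqrt(rowSums(v1^2))
    v2 <- cbind(e1m[, 2] * v1[, 3] - e1m[, 3] * v1[, 2],
                e1m[, 3] * v1[, 1] - e1m[, 1] * v1[, 3],
                e1m[, 1] * v1[, 2] - e1m[, 2] * v1[, 1])
    ang <- 2 * pi * (seq_len(M) - 1) / M
    idxrep <- rep(seq_len(nvm), each = M)
    U <- v1[idxrep, ] * rep(cos(ang), nvm) + v2[idxrep, ] * rep(sin(ang), nvm)
    Du <- floorD(rowSums(sh_basis(U, adc$sh_order) * t(adc$coef)[idxrep, ]))
    inv_mean <- rowMeans(matrix(1 / Du, nvm, M, byrow = TRUE))
    out$RTAP <- mk("RTAP", (4 * pi * tau)^(-1) * inv_mean)
  }
  if ("RTPP" %in% measures) {
    # D along the principal axis
    Be <- sh_basis(e1m, adc$sh_order)
    De1 <- floorD(rowSums(Be * t(adc$coef)))
    out$RTPP <- mk("RTPP", (4 * pi * tau * De1)^(-0.5))
  }
  for (m in names(out)) attr(out[[m]], "n_floored") <- n_floored
  out[measures]
}
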