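# Return-probability scalars: closed forms, the single-shell apparent
# construction, and their equivalence on Gaussian signals

iso_field <- function(d0, n = 4, S0 = 1000) {
  grid <- volume_grid(c(n, 1, 1))
  D <- matrix(0, n, 6); D[, c(1, 3, 6)] <- d0
  structure(list(grid = grid, D = D, S0 = array(S0, c(n, 1, 1)),
                 mask = array(TRUE, c(n, 1, 1))), class = "tensor_field")
}

eigsys_from_lambda <- function(lam) {
  n <- nrow(lam)
  structure(list(grid = volume_grid(c(n, 1, 1)), lambda = lam,
                 vectors = matrix(rep(diag(3), each = n), n, 9),
                 mask = array(TRUE, c(n, 1, 1)), n_clamped = 0L),
            class = "eigen_system")
}

test_that("closed forms obey RTOP = RTPP x RTAP and power-law scaling", {
  lam <- random_tensor_set(300, seed = 2)$lambda
  cfg <- eap_config()
  g <- gaussian_eap_from_eigenvalues(eigsys_from_lambda(lam), cfg)
  rel <- abs(g$RTOP$values - g$RTPP$values * g$RTAP$values) / g$RTOP$values
  expect_lt(max(rel), 1e-12)
  g4 <- gaussian_eap_from_eigenvalues(eigsys_from_lambda(lam * 4), cfg)
  expect_equal(g4$RTPP$values, g$RTPP$values / 2, tolerance = 1e-12)
  expect_equal(g4$RTAP$values, g$RTAP$values / 4, tolerance = 1e-12)
  expect_equal(g4$RTOP$values, g$RTOP$values / 8, tolerance = 1e-12)
})

test_that("isotropic RTOP equals the numerical q-space integral of the signal", {
  d0 <- 0.7e-3
  tau <- 0.025
  # RTOP = integral over 3-D q-space of exp(-4 pi^2 tau q^2 D0)
  oracle <- stats::integrate(function(q)
    4 * pi * q^2 * exp(-4 * pi^2 * tau * q^2 * d0), 0, Inf,
    rel.tol = 1e-10)$value
  g <- gaussian_eap_from_eigenvalues(
    eigsys_from_lambda(matrix(d0, 1, 3)), eap_config(tau = tau))
  expect_equal(g$RTOP$values[1, 1, 1], oracle, tolerance = 1e-3)
})

test_that("an isotropic signal gives a pure order-0 ADC profile and analytic scalars", {
  d0 <- 0.9e-3
  cfg <- eap_config(tau = 0.02)
  dwi <- simulate_dwi(iso_field(d0), scheme_b1000())
  adc <- directional_adc(dwi, config = cfg)
  co <- adc$coef[, 1]
  expect_gt(abs(co[1]), 1e-6)
  expect_lt(max(abs(co[-1])), abs(co[1]) * 1e-8)
  e1 <- matrix(rep(c(1, 0, 0), each = 4), 4, 3)
  ap <- apparent_eap_scalars(adc, e1, cfg)
  tau <- cfg$tau
  expect_equal(ap$RTOP$values[1, 1, 1], (4 * pi * tau * d0)^(-1.5),
               tolerance = 1e-6)
  expect_equal(ap$RTAP$values[1, 1, 1], (4 * pi * tau * d0)^(-1),
               tolerance = 1e-6)
  expect_equal(ap$RTPP$values[1, 1, 1], (4 * pi * tau * d0)^(-0.5),
               tolerance = 1e-6)
})

test_that("the fitted ADC profile reproduces the quadratic form of the tensor", {
  ts <- random_tensor_set(5, seed = 19, lam_min = 0.2e-3, lam_max = 2e-3)
  dwi <- simulate_dwi(tensors_as_field(ts$D), scheme_b1000())
  adc <- directional_adc(dwi, config = eap_config())
  B <- microtract:::sh_basis
  set.seed(7)
  u <- matrix(rnorm(600), 200, 3)
  u <- u / sqrt(rowSums(u^2))
  Bu <- B(u, 6)
  for (i in 1:5) {
    fit <- as.vector(Bu %*% adc$coef[, i])
    d <- ts$D[i, ]
    M <- matrix(c(d[1], d[2], d[4], d[2], d[3], d[5], d[4], d[5], d[6]), 3, 3)
    truth <- rowSums((u %*% M) * u)
    expect_lt(max(abs(fit - truth) / truth), 0.005)
  }
})

test_that("signal below the clip floor caps the ADC and is counted", {
  sc <- gradient_scheme(c(0, rep(1000, 28)),
                        cbind(0, t(fib_directions(28))))
  grid <- volume_grid(c(1, 1, 1))
  dat <- array(1000, c(1, 1, 1, 29))
  dat[, , , 2] <- 1e-9                      # E ~ 1e-12, below the 1e-6 floor
  dwi <- dwi_stack(grid, dat, sc)
  adc <- directional_adc(dwi, config = eap_config(sh_order = 2))
  expect_gte(adc$n_clipped, 1L)
  # the capped ADC never exceeds -log(1e-6)/b
  B <- microtract:::sh_basis(t(sc$bvecs[, !sc$is_b0]), 2)
  fit <- as.vector(B %*% adc$coef[, 1])
  expect_lte(max(fit), -log(1e-6) / 1000 + 1e-9)
})

test_that("multi-shell input and oversized sh_order are rejected", {
  sc2 <- gradient_scheme(c(0, rep(1000, 30), rep(2000, 31)),
                         cbind(0, t(fib_directions(61))))
  grid <- volume_grid(c(2, 1, 1))
  dwi <- dwi_stack(grid, array(1, c(2, 1, 1, 62)), sc2)
  expect_error(directional_adc(dwi), "single-shell")
  dwi1 <- simulate_dwi(iso_field(1e-3, n = 2),
                       gradient_scheme(c(0, rep(1000, 10)),
                                       cbind(0, t(fib_directions(10)))))
  expect_error(directional_adc(dwi1, config = eap_config(sh_order = 6)),
               "sh_order")
})

test_that("apparent scalars match the Gaussian closed forms on noise-free tensors", {
  ts <- random_tensor_set(250, seed = 29)
  dwi <- simulate_dwi(tensors_as_field(ts$D), scheme_b1000())
  cfg <- eap_config()
  es <- eigendecompose(fit_tensor(dwi))
  ge <- gaussian_eap_from_eigenvalues(es, cfg)
  ap <- apparent_eap_scalars(directional_adc(dwi, config = cfg),
                             es$vectors[, 1:3], cfg)
  for (m in c("RTOP", "RTAP", "RTPP")) {
    rel <- abs(ap[[m]]$values - ge[[m]]$values) / ge[[m]]$values
    expect_lt(stats::median(rel), 0.01)
    expect_lt(max(rel), 0.03)
  }
})

test_that("a tensor ADC profile is order-2 band-limited, so order 2 is already exact", {
  # D(u) = u' D u lives entirely in spherical-harmonic orders {0, 2}:
  # raising the fit order cannot change the profile on noise-free
  # single-tensor signals
  ts <- random_tensor_set(20, seed = 37)
  dwi <- simulate_dwi(tensors_as_field(ts$D), scheme_b1000())
  es <- eigendecompose(fit_tensor(dwi))
  res <- lapply(c(2, 6), function(L) {
    cfg <- eap_config(sh_order = L)
    ap <- apparent_eap_scalars(directional_adc(dwi, config = cfg),
                               es$vectors[, 1:3], cfg, measures = "RTOP")
    as.vector(ap$RTOP$values)
  })
  expect_equal(res[[1]], res[[2]], tolerance = 1e-8)
})

test_that("SH convergence: crossing-fiber profiles improve from order 2 to 4 to 6", {
  # a 50/50 bi-tensor signal has a non-band-limited ADC profile; the
  # reference is the exact profile evaluated at the quadrature nodes
  sc <- scheme_b1000()
  tau <- 0.025
  set.seed(71)
  n <- 20
  qd <- microtract:::sphere_quadrature(24, 48)
  quad_rtop <- function(Dq) (4 * pi * tau)^(-1.5) *
    sum(qd$w * pmax(Dq, 1e-6)^(-1.5)) / (4 * pi)
  errs <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    t1 <- random_tensor_set(1, seed = 100 + i)$D[1, ]
    t2 <- random_tensor_set(1, seed = 200 + i)$D[1, ]
    qf <- function(d, U) {
      M <- matrix(c(d[1], d[2], d[4], d[2], d[3], d[5], d[4], d[5], d[6]), 3, 3)
      rowSums((U %*% M) * U)
    }
    dirs <- t(sc$bvecs[, !sc$is_b0])
    E <- 0.5 * exp(-1000 * qf(t1, dirs)) + 0.5 * exp(-1000 * qf(t2, dirs))
    dat <- array(1000 * c(1, E), c(1, 1, 1, 62))
    dwi <- dwi_stack(volume_grid(c(1, 1, 1)), dat, sc)
    Dtrue <- -log(0.5 * exp(-1000 * qf(t1, qd$nodes)) +
                    0.5 * exp(-1000 * qf(t2, qd$nodes))) / 1000
    truth <- quad_rtop(Dtrue)
    for (k in 1:3) {
      L <- c(2, 4, 6)[k]
      adc <- directional_adc(dwi, config = eap_config(sh_order = L, tau = tau))
      ap <- apparent_eap_scalars(adc, matrix(c(1, 0, 0), 1, 3),
                                 eap_config(sh_order = L, tau = tau),
                                 measures = "RTOP")
      errs[i, k] <- abs(ap$RTOP$values[1, 1, 1] - truth) / truth
    }
  }
  me <- colMeans(errs)
  expect_true(all(diff(me) < 0))
})

test_that("apparent scalars are invariant under joint rotation", {
  ts <- random_tensor_set(40, seed = 43)
  sc <- scheme_b1000()
  ang <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
  rotD <- t(apply(ts$D, 1, function(d) {
    M <- matrix(c(d[1], d[2], d[4], d[2], d[3], d[5], d[4], d[5], d[6]), 3, 3)
    M2 <- R %*% M %*% t(R)
    c(M2[1, 1], M2[1, 2], M2[2, 2], M2[1, 3], M2[2, 3], M2[3, 3])
  }))
  cfg <- eap_config()
  run <- function(D, scheme) {
    dwi <- simulate_dwi(tensors_as_field(D), scheme)
    es <- eigendecompose(fit_tensor(dwi))
    apparent_eap_scalars(directional_adc(dwi, config = cfg),
                         es$vectors[, 1:3], cfg)
  }
  a <- run(ts$D, sc)
  b <- run(rotD, gradient_scheme(sc$bvals, R %*% sc$bvecs))
  for (m in c("RTOP", "RTAP", "RTPP")) {
    rel <- abs(b[[m]]$values - a[[m]]$values) / a[[m]]$values
    expect_lt(max(rel), 0.005)
  }
})

test_that("Jensen ordering and monotonicity of the apparent scalars hold", {
  ts <- random_tensor_set(50, seed = 53)
  cfg <- eap_config()
  dwi <- simulate_dwi(tensors_as_field(ts$D), scheme_b1000())
  es <- eigendecompose(fit_tensor(dwi))
  adc <- directional_adc(dwi, config = cfg)
  ap <- apparent_eap_scalars(adc, es$vectors[, 1:3], cfg)
  # apparent RTOP >= closed form evaluated at the spherical-mean ADC
  # (convexity of x^(-3/2)); order-0 SH coefficient / Y00 = mean ADC
  dbar <- adc$coef[1, ] / sqrt(4 * pi) * sqrt(4 * pi) # c0 * Y00 = c0/sqrt(4pi)
  dbar <- adc$coef[1, ] / (2 * sqrt(pi))
  rtop_mean_adc <- (4 * pi * cfg$tau)^(-1.5) * dbar^(-1.5)
  expect_true(all(as.vector(ap$RTOP$values) >= rtop_mean_adc * (1 - 1e-9)))
  # uniformly larger ADC strictly lowers every scalar
  dwi_hot <- simulate_dwi(tensors_as_field(ts$D * 1.3), scheme_b1000())
  es2 <- eigendecompose(fit_tensor(dwi_hot))
  ap2 <- apparent_eap_scalars(directional_adc(dwi_hot, config = cfg),
                              es2$vectors[, 1:3], cfg)
  for (m in c("RTOP", "RTAP", "RTPP"))
    expect_true(all(ap2[[m]]$values < ap[[m]]$values))
})

test_that("tensor-route RTOP explodes under noise while the apparent route stays bounded", {
  # high anisotropy, SNR 20: the inverse square root of the smallest
  # eigenvalue makes the unclamped tensor route blow up in a small but
  # non-negligible fraction of voxels; the apparent route stays bounded
  n <- 4000
  lam <- c(1.9e-3, 0.12e-3, 0.12e-3)
  ts <- random_tensor_set(n, seed = 61)
  D <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    d <- ts$D[i, ]
    M <- matrix(c(d[1], d[2], d[4], d[2], d[3], d[5], d[4], d[5], d[6]), 3, 3)
    V <- eigen(M, symmetric = TRUE)$vectors
    M2 <- V %*% diag(lam) %*% t(V)
    D[i, ] <- c(M2[1, 1], M2[1, 2], M2[2, 2], M2[1, 3], M2[2, 3], M2[3, 3])
  }
  sc <- scheme_b1000()
  cfg <- eap_config()
  noisefree <- simulate_dwi(tensors_as_field(D, S0 = 1000), sc)
  es0 <- eigendecompose(fit_tensor(noisefree))
  ref <- stats::median(
    gaussian_eap_from_eigenvalues(es0, cfg)$RTOP$values)
  noisy <- simulate_dwi(tensors_as_field(D, S0 = 1000), sc,
                        noise = noise_spec(50, seed = 67))
  es <- eigendecompose(fit_tensor(noisy), clamp = FALSE)
  raw <- suppressWarnings(
    gaussian_eap_from_eigenvalues(es, cfg, enforce_floor = FALSE))
  bad <- !is.finite(raw$RTOP$values) | raw$RTOP$values > 1e3 * ref
  expect_gt(mean(bad), 0.001)
  ap <- apparent_eap_scalars(directional_adc(noisy, config = cfg),
                             es$vectors[, 1:3], cfg, measures = "RTOP")
  q999 <- stats::quantile(ap$RTOP$values, 0.999)
  expect_true(is.finite(q999))
  expect_lt(q999, 1e3 * ref)
})
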