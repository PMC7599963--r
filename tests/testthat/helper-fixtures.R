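# Shared fixtures: deterministic gradient schemes, random tensors,
# phantoms, and independent oracles.

# Fibonacci-lattice unit directions: deterministic, well spread
fib_directions <- function(n) fibonacci_directions(n)

# the study-style acquisition: 1 baseline + 61 directions at b = 1000
scheme_b1000 <- function(n_dir = 61, b = 1000) {
  g <- t(fib_directions(n_dir))
  gradient_scheme(c(0, rep(b, n_dir)), cbind(0, g))
}

# n random positive-definite tensors with eigenvalues drawn in
# [lam_min, lam_max] mm^2/s; returns lambda (n x 3, descending),
# D (n x 6, lower-tri order) and the principal axes (n x 3)
random_tensor_set <- function(n, seed = 1, lam_min = 0.1e-3,
                              lam_max = 2.1e-3) {
  withr::with_seed(seed, {
    lam <- t(apply(matrix(runif(3 * n, lam_min, lam_max), n), 1,
                   sort, decreasing = TRUE))
    D <- matrix(0, n, 6)
    e1 <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      A <- matrix(rnorm(9), 3)
      R <- qr.Q(qr(A))
      M <- R %*% diag(lam[i, ]) %*% t(R)
      o <- order(diag(t(R) %*% M %*% R), decreasing = TRUE)
      e1[i, ] <- R[, o[1]]
      D[i, ] <- c(M[1, 1], M[1, 2], M[2, 2], M[1, 3], M[2, 3], M[3, 3])
    }
    list(lambda = lam, D = D, e1 = e1)
  })
}

# wrap a voxel-list tensor set as a tensor_field on an n x 1 x 1 grid
tensors_as_field <- function(D, S0 = 1000) {
  n <- nrow(D)
  grid <- volume_grid(c(n, 1, 1), c(2, 2, 2))
  structure(list(grid = grid, D = D, S0 = array(S0, c(n, 1, 1)),
                 mask = array(TRUE, c(n, 1, 1))),
            class = "tensor_field")
}

# straight two-tract phantom used by the inference tests; tract 1 is the
# effect target, tract 2 the control
two_tract_phantom <- function() {
  grid <- volume_grid(c(30, 22, 10), c(2, 2, 2))
  trA <- tract_tube(c(2, 8, 8), c(58, 8, 8), radius = 5,
                    evals = c(1.7e-3, 0.3e-3, 0.3e-3), name = "tractA")
  trB <- tract_tube(c(2, 34, 8), c(58, 34, 8), radius = 5,
                    evals = c(1.7e-3, 0.3e-3, 0.3e-3), name = "tractB")
  phantom_spec(grid, list(trA, trB), background_eval = 0.7e-3, S0 = 1000)
}

# ---- independent oracles ------------------------------------------------

# brute-force TFCE by explicit threshold sweep, with clusters found by
# igraph connected components (independent of the union-find C++ path)
brute_tfce <- function(values, adjacency, E, H, nsteps) {
  V <- length(values)
  out <- numeric(V)
  vmax <- max(values, 0)
  if (vmax <= 0) return(out)
  dh <- vmax / nsteps
  from <- rep(seq_len(V),
              times = diff(adjacency$indptr))
  to <- adjacency$indices + 1L
  keep <- from < to
  from <- from[keep]; to <- to[keep]
  for (s in seq_len(nsteps)) {
    h <- s * dh
    act <- values >= h
    if (!any(act)) break
    sel <- act[from] & act[to]
    g <- igraph::graph_from_edgelist(cbind(from[sel], to[sel]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, V - igraph::vcount(g)))
    cm <- igraph::components(g)
    sizes <- cm$csize[cm$membership]
    out[act] <- out[act] + sizes[act]^E * h^H * dh
  }
  out
}

# nonlinear least-squares tensor fit of one voxel's signal (oracle for
# the weighted linear fit); direct minimization of the sum of squared
# signal residuals over (log S0, 6 tensor components)
nls_tensor_oracle <- function(signal, scheme) {
  g <- scheme$bvecs; b <- scheme$bvals
  A <- cbind(g[1, ]^2, 2 * g[1, ] * g[2, ], g[2, ]^2,
             2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ], g[3, ]^2) * b
  obj <- function(p) {
    pred <- exp(p[1] - as.vector(A %*% p[2:7]))
    sum((signal - pred)^2)
  }
  md0 <- mean(-log(pmax(signal[!scheme$is_b0], 1e-6) /
                     mean(signal[scheme$is_b0])) / b[!scheme$is_b0])
  p0 <- c(log(mean(signal[scheme$is_b0])), md0, 0, md0, 0, 0, md0)
  fit <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14,
                                     parscale = c(1, rep(1e-3, 6))))
  fit$par[2:7]
}

# eigenvalues of a lower-tri 6-vector tensor
eig_of_D6 <- function(d) {
  M <- matrix(c(d[1], d[2], d[4],
                d[2], d[3], d[5],
                d[4], d[5], d[6]), 3, 3)
  sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# Benjamini-Hochberg step-up from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- min(prev, 1)
  }
  adj
}
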