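# TFCE enhancement and permutation-based FWE inference

line_adjacency <- function(n) {
  mask <- array(FALSE, c(n, 3, 3)); mask[, 2, 2] <- TRUE
  microtract:::mask_adjacency(mask)
}

test_that("TFCE of a null or all-negative map is zero", {
  adj <- line_adjacency(10)
  cfg <- inference_config()
  expect_equal(tfce_enhance(rep(0, 10), adj, cfg), rep(0, 10))
  expect_equal(tfce_enhance(rep(-2, 10), adj, cfg), rep(0, 10))
  expect_error(tfce_enhance(c(NA, rep(0, 9)), adj, cfg), "non-finite")
})

test_that("a constant 1-D segment matches the brute-force threshold sum within 2%", {
  adj <- line_adjacency(12)
  v <- numeric(12); v[4:9] <- 2.5
  cfg <- inference_config()
  got <- tfce_enhance(v, adj, cfg)
  oracle <- brute_tfce(v, adj, cfg$tfce_e, cfg$tfce_h, 1000)
  expect_lt(max(abs(got[4:9] - oracle[4:9]) / oracle[4:9]), 0.02)
  expect_true(all(got[-(4:9)] == 0))
  # closed form for a constant segment: extent^E * sum of h^H dh
  # (midpoint thresholds h = (k - 1/2) dh)
  h <- 2.5 / 100 * (1:100 - 0.5)
  closed <- 6^0.5 * sum(h^2 * 2.5 / 100)
  expect_equal(got[4], closed, tolerance = 1e-12)
})

test_that("TFCE matches the igraph brute force on random smooth 3-D maps", {
  withr::with_seed(5, {
    mask <- array(TRUE, c(8, 8, 6))
    adj <- microtract:::mask_adjacency(mask)
    cfg <- inference_config()
    for (r in 1:5) {
      v <- as.vector(microtract:::gauss_smooth3(
        array(rnorm(prod(dim(mask))), dim(mask)), 1.2))
      v <- pmax(v, 0) * 3
      got <- tfce_enhance(v, adj, cfg)
      oracle <- brute_tfce(v, adj, cfg$tfce_e, cfg$tfce_h, 1000)
      # cluster-extent jumps make isolated voxels sensitive to the
      # threshold grid; the map-normalized deviation and the per-voxel
      # median both stay within 2%
      expect_lt(max(abs(got - oracle)) / max(oracle), 0.02)
      keep <- oracle > max(oracle) * 0.05
      expect_lt(stats::median(abs(got[keep] - oracle[keep]) / oracle[keep]),
                0.02)
    }
  })
})

test_that("raising one voxel's statistic never lowers any TFCE value", {
  withr::with_seed(9, {
    adj <- line_adjacency(20)
    cfg <- inference_config()
    for (r in 1:25) {
      v <- pmax(rnorm(20, 0.5), 0)
      base <- tfce_enhance(v, adj, cfg)
      i <- sample(which(v < max(v) - 0.1), 1)
      # raise a non-maximal voxel below the map maximum: the threshold
      # grid is unchanged, so monotonicity must hold exactly
      v2 <- v; v2[i] <- v2[i] + runif(1, 0.05, max(v) - v[i] - 1e-6)
      up <- tfce_enhance(v2, adj, cfg)
      expect_true(all(up >= base - 1e-12))
      # raising the maximum itself re-grids the thresholds; away from
      # the low-valued tail the property still holds approximately
      v3 <- v; v3[which.max(v)] <- max(v) + 0.5
      up3 <- tfce_enhance(v3, adj, cfg)
      hi <- base > 0.2 * max(base)
      expect_true(all(up3[hi] >= base[hi] * 0.85))
    }
  })
})

test_that("with E -> 0, H = 1 a single-voxel cluster integrates its height", {
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  adj <- microtract:::mask_adjacency(mask)
  cfg <- inference_config(tfce_h = 1, tfce_e = 1e-9)
  got <- tfce_enhance(3, adj, cfg)
  dh <- 3 / 100
  expect_equal(got, sum((1:100 - 0.5) * dh * dh), tolerance = 1e-9)
  # the midpoint sum of h dh is exactly the height integral max^2/2
  expect_equal(got, 3^2 / 2, tolerance = 1e-9)
})

test_that("permutation p-values respect the 1/(1+n) floor and rank invariance", {
  withr::with_seed(33, {
    adj <- line_adjacency(30)
    n <- 12
    dat <- matrix(rnorm(n * 30), n, 30)
    dat[1:6, 10:20] <- dat[1:6, 10:20] + 3      # strong group-A effect
    grp <- rep(c("A", "B"), each = 6)
    cfg <- inference_config(n_permutations = 200, seed = 3)
    r <- permutation_fwe(dat, grp, NULL, adj, cfg, contrasts = "greater")
    p <- r$contrast_maps$greater$p_corr
    expect_true(all(p >= 1 / (1 + r$n_permutations_used)))
    expect_lt(min(p), 0.05)
    # affine rescaling of the data leaves the p map unchanged up to
    # floating-point ties at the permutation maxima
    r2 <- permutation_fwe(dat * 3 + 5, grp, NULL, adj, cfg,
                          contrasts = "greater")
    expect_lt(max(abs(r2$contrast_maps$greater$p_corr - p)),
              2.5 / (1 + r$n_permutations_used))
  })
})

test_that("tiny groups switch to exact enumeration of relabelings", {
  adj <- line_adjacency(8)
  dat <- matrix(rnorm(6 * 8), 6, 8)
  grp <- rep(c("A", "B"), each = 3)
  cfg <- inference_config(n_permutations = 5000, seed = 1)
  r <- permutation_fwe(dat, grp, NULL, adj, cfg, contrasts = "greater")
  expect_true(r$exact)
  expect_equal(r$n_permutations_used, choose(6, 3))
})

test_that("degenerate designs are rejected", {
  adj <- line_adjacency(5)
  dat <- matrix(rnorm(40), 8, 5)
  expect_error(permutation_fwe(dat, rep(c("A", "B", "C"), c(3, 3, 2)),
                               NULL, adj, inference_config()), "two groups")
  expect_error(permutation_fwe(dat[1:4, ], rep(c("A", "B"), c(1, 3)),
                               NULL, adj, inference_config()), ">= 2")
  expect_error(permutation_fwe(dat, rep(c("A", "B"), each = 4),
                               data.frame(z = rep(1, 8)), adj,
                               inference_config()), "constant")
})

test_that("Freedman-Lane removes a strong nuisance covariate", {
  withr::with_seed(44, {
    adj <- line_adjacency(40)
    n <- 30
    grp <- rep(c("A", "B"), each = 15)
    age <- c(rnorm(15, 30, 5), rnorm(15, 50, 5))  # confounded with group
    dat <- matrix(rnorm(n * 40), n, 40) + outer(age, rep(0.2, 40))
    cfg <- inference_config(n_permutations = 300, seed = 7)
    # without the covariate the age gradient masquerades as a group effect
    raw <- permutation_fwe(dat, grp, NULL, adj, cfg, contrasts = "less")
    expect_lt(min(raw$contrast_maps$less$p_corr), 0.05)
    # with it, nothing survives
    adj_r <- permutation_fwe(dat, grp, data.frame(age = age), adj, cfg,
                             contrasts = "less")
    expect_gt(min(adj_r$contrast_maps$less$p_corr), 0.05)
  })
})

test_that("ROI reports apply the minimum-volume rule and find the peak", {
  grid <- volume_grid(c(10, 10, 2), c(1, 1, 1))   # 1-mm voxels
  mask <- array(TRUE, grid$shape)
  skeleton <- structure(list(grid = grid, mask = mask, idx = which(mask),
                             adjacency = microtract:::mask_adjacency(mask)),
                        class = "skeleton_model")
  labels <- array(0L, grid$shape)
  labels[1:5, , 1] <- 1L       # region A: 50 voxels
  labels[6:10, , 1] <- 2L      # region B: 50 voxels
  atlas <- label_map(grid, labels, c(`1` = "regA", `2` = "regB"))
  nv <- length(skeleton$idx)
  p <- rep(1, nv); tf <- rep(0, nv); tstat <- rep(0, nv)
  regA <- which(as.vector(labels)[skeleton$idx] == 1L)
  regB <- which(as.vector(labels)[skeleton$idx] == 2L)
  p[regA[1:40]] <- 0.01                       # 40 mm^3 significant
  p[regA[5]] <- 0.001                         # the peak
  tf[regA] <- 2
  p[regB[1:20]] <- 0.01                       # only 20 mm^3 -> dropped
  stat <- structure(list(contrast_maps = list(greater = list(
    tstat = tstat, tfce = tf, p_corr = p, contrast = "A > B")),
    n_permutations_used = 1000, exact = FALSE, alpha = 0.05),
    class = "stat_maps")
  rep <- roi_report(stat, "greater", atlas, skeleton, inference_config())
  expect_equal(rep$region, "regA")
  expect_equal(rep$volume_mm3, 40)
  expect_equal(rep$min_p_corr, 0.001)
  peak_idx <- skeleton$idx[regA[5]]
  w <- (arrayInd(peak_idx, grid$shape) - 1)   # 1-mm voxels, identity affine
  expect_equal(c(rep$peak_x, rep$peak_y, rep$peak_z), as.vector(w))
  # all-null map produces an empty report
  stat$contrast_maps$greater$p_corr <- rep(1, nv)
  expect_equal(nrow(roi_report(stat, "greater", atlas, skeleton,
                               inference_config())), 0L)
})
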