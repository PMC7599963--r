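# Tensor-field phantoms: geometric "tracts" (tubes / arcs) embedded in an
# isotropic background, with a label map naming each tract.

#' Describe a straight tube tract
#'
#' @param start,end endpoints in world mm (length-3).
#' @param radius tube radius in mm.
#' @param evals tract eigenvalues (lambda1 >= lambda2 >= lambda3 > 0, mm^2/s);
#'   lambda1 is aligned with the tube axis.
#' @param name region name for the label map.
#' @return tract descriptor list.
#' @export
tract_tube <- function(start, end, radius, evals, name) {
  check_evals(evals)
  list(type = "tube", start = as.numeric(start), end = as.numeric(end),
       radius = radius, evals = as.numeric(evals), name = name)
}

#' Describe a curved arc tract
#'
#' A circular arc of radius `arc_radius` around `center`, lying in the
#' plane spanned by `u` and `v` (orthonormalized), swept over
#' `theta` (radians), thickened into a tube of radius `radius`.
#' The principal eigenvector follows the arc tangent.
#'
#' @param center arc center, world mm.
#' @param arc_radius radius of the arc center-line, mm.
#' @param u,v two non-collinear vectors spanning the arc plane.
#' @param theta length-2 angular range in radians.
#' @param radius tube radius, mm.
#' @param evals tract eigenvalues (mm^2/s), descending.
#' @param name region name.
#' @return tract descriptor list.
#' @export
tract_arc <- function(center, arc_radius, u, v, theta, radius, evals, name) {
  check_evals(evals)
  u <- u / sqrt(sum(u^2))
  v <- v - sum(v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) stop_validation("arc plane vectors are collinear")
  v <- v / nv
  list(type = "arc", center = as.numeric(center), arc_radius = arc_radius,
       u = u, v = v, theta = as.numeric(theta), radius = radius,
       evals = as.numeric(evals), name = name)
}

check_evals <- function(evals) {
  if (length(evals) != 3L || any(!is.finite(evals)) || any(evals <= 0) ||
      is.unsorted(rev(evals)))
    stop_validation("eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 > 0")
  invisible(evals)
}

#' Phantom specification
#'
#' @param grid a [volume_grid()].
#' @param tracts list of [tract_tube()] / [tract_arc()] descriptors.
#' @param background_eval isotropic background diffusivity (mm^2/s).
#' @param S0 baseline (b=0) intensity.
#' @param blend overlap rule: "error" (default) or "overwrite"
#'   (later tracts win).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, tracts, background_eval = 0.7e-3, S0 = 1000,
                         blend = c("error", "overwrite")) {
  if (background_eval <= 0) stop_validation("background diffusivity must be > 0")
  structure(list(grid = grid, tracts = tracts,
                 background_eval = background_eval, S0 = S0,
                 blend = match.arg(blend)),
            class = "phantom_spec")
}

# per-voxel geometry of one tract: inside mask + unit tangent at the
# nearest center-line point (world coordinates, rows = voxels)
tract_geometry <- function(tract, xyz) {
  if (tract$type == "tube") {
    a <- tract$start; b <- tract$end
    ab <- b - a
    len2 <- sum(ab^2)
    t <- pmin(pmax((sweep(xyz, 2, a) %*% ab) / len2, 0), 1)
    closest <- sweep(outer(as.vector(t), ab), 2, a, "+")
    d <- sqrt(rowSums((xyz - closest)^2))
    tang <- ab / sqrt(len2)
    list(inside = d <= tract$radius,
         tangent = matrix(tang, nrow(xyz), 3, byrow = TRUE))
  } else {
    rel <- sweep(xyz, 2, tract$center)
    pu <- rel %*% tract$u
    pv <- rel %*% tract$v
    ang <- atan2(pv, pu)
    # wrap into the arc's angular range
    lo <- tract$theta[1]
    ang <- lo + (ang - lo) %% (2 * pi)
    onarc <- ang <= tract$theta[2]
    angc <- pmin(pmax(ang, tract$theta[1]), tract$theta[2])
    cl <- tract$center +
      tract$arc_radius * (outer(cos(angc)[, 1], tract$u) +
                          outer(sin(angc)[, 1], tract$v))
    d <- sqrt(rowSums((xyz - cl)^2))
    tang <- -outer(sin(angc)[, 1], tract$u) + outer(cos(angc)[, 1], tract$v)
    tang <- tang / sqrt(rowSums(tang^2))
    list(inside = as.vector(onarc) & d <= tract$radius, tangent = tang)
  }
}

# rotation taking (1,0,0) to unit vector t, applied to diag(evals):
# D = l3 I + (l1 - l3) t t' + (l2 - l3) s s'   with s any unit vector
# orthogonal to t (the l2/l3 plane orientation is arbitrary; we fix s
# deterministically from t)
tensor_from_axis <- function(tangent, evals) {
  n <- nrow(tangent)
  ref <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  swap <- abs(tangent[, 3]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  s <- ref - tangent * rowSums(ref * tangent)
  s <- s / sqrt(rowSums(s^2))
  l1 <- evals[1]; l2 <- evals[2]; l3 <- evals[3]
  D <- matrix(0, n, 6)   # Dxx, Dxy, Dyy, Dxz, Dyz, Dzz
  tt <- tangent; ss <- s
  D[, 1] <- l3 + (l1 - l3) * tt[, 1]^2 + (l2 - l3) * ss[, 1]^2
  D[, 3] <- l3 + (l1 - l3) * tt[, 2]^2 + (l2 - l3) * ss[, 2]^2
  D[, 6] <- l3 + (l1 - l3) * tt[, 3]^2 + (l2 - l3) * ss[, 3]^2
  D[, 2] <- (l1 - l3) * tt[, 1] * tt[, 2] + (l2 - l3) * ss[, 1] * ss[, 2]
  D[, 4] <- (l1 - l3) * tt[, 1] * tt[, 3] + (l2 - l3) * ss[, 1] * ss[, 3]
  D[, 5] <- (l1 - l3) * tt[, 2] * tt[, 3] + (l2 - l3) * ss[, 2] * ss[, 3]
  D
}

#' Build a tensor-field phantom
#'
#' Each voxel inside a tract receives a tensor whose principal axis
#' follows the tract geometry (tube axis or arc tangent) with the tract's
#' eigenvalues; background voxels are isotropic. Deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return list with `tensors` (a `tensor_field`), `labels` (a
#'   [label_map()]; tract i gets label i), `lambda` (n_vox x 3 generating
#'   eigenvalues) and `tangent` (n_vox x 3 principal axis, NA for
#'   background).
#' @export
build_tensor_phantom <- function(spec) {
  grid <- spec$grid
  nv <- prod(grid$shape)
  ijk <- arrayInd(seq_len(nv), grid$shape)
  xyz <- voxel_to_world(grid, ijk)
  d0 <- spec$background_eval
  D <- matrix(0, nv, 6)
  D[, c(1, 3, 6)] <- d0
  lambda <- matrix(d0, nv, 3)
  tangent <- matrix(NA_real_, nv, 3)
  labels <- integer(nv)
  for (i in seq_along(spec$tracts)) {
    tr <- spec$tracts[[i]]
    g <- tract_geometry(tr, xyz)
    ins <- which(g$inside)
    if (!length(ins))
      stop_validation("tract '", tr$name, "' lies outside the grid")
    clash <- ins[labels[ins] != 0L]
    if (length(clash) && spec$blend == "error")
      stop_validation("tracts overlap at ", length(clash),
                      " voxel(s); set blend = 'overwrite' to allow")
    D[ins, ] <- tensor_from_axis(g$tangent[ins, , drop = FALSE], tr$evals)
    lambda[ins, ] <- matrix(tr$evals, length(ins), 3, byrow = TRUE)
    tangent[ins, ] <- g$tangent[ins, , drop = FALSE]
    labels[ins] <- i
  }
  lookup <- setNames(vapply(spec$tracts, `[[`, "", "name"),
                     seq_along(spec$tracts))
  tf <- structure(list(grid = grid,
                       D = D,
                       S0 = array(spec$S0, grid$shape),
                       mask = array(TRUE, grid$shape)),
                  class = "tensor_field")
  list(tensors = tf,
       labels = label_map(grid, array(labels, grid$shape), lookup),
       lambda = lambda, tangent = tangent)
}
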