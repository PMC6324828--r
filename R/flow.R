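# Time-varying velocity fields and the diffeomorphic flow
# phi_dot_t = v_t o phi_t, t in [0, 1], phi_0 = identity.
#
# Discretization: a field with n_T >= 2 time nodes at t_k = (k-1)/(n_T - 1)
# is integrated in n_T - 1 Euler substeps, substep k using the average of the
# two adjacent node fields; n_T = 1 means a steady field integrated in one
# unit step. The time quadrature of the path energy is trapezoidal on the
# same nodes, so metric and flow share one discretization.

#' Time-varying velocity field
#'
#' @param fields list of 4D arrays `[nx, ny, nz, 3]` (physical-unit
#'   velocity), one per time node.
#' @return an object of class `tv_velocity`.
#' @export
tv_velocity <- function(fields) {
  if (!is.list(fields) || length(fields) < 1L)
    stop("tv_velocity: need at least one field")
  dm <- dim(fields[[1]])
  if (length(dm) != 4L || dm[4] != 3L)
    stop("tv_velocity: fields must be [nx, ny, nz, 3] arrays")
  for (f in fields) {
    if (!identical(dim(f), dm)) stop("tv_velocity: inconsistent field shapes")
    if (any(!is.finite(f))) stop("tv_velocity: non-finite velocity")
  }
  structure(list(fields = fields, n_t = length(fields)), class = "tv_velocity")
}

#' @rdname tv_velocity
#' @param dm grid dimensions `(nx, ny, nz)`.
#' @param n_t number of time nodes.
#' @export
zero_velocity <- function(dm, n_t = 10L) {
  tv_velocity(replicate(n_t, array(0, c(dm, 3L)), simplify = FALSE))
}

# Trapezoidal quadrature weights over the time nodes (sum to 1).
time_weights <- function(n_t) {
  if (n_t == 1L) return(1)
  dt <- 1 / (n_t - 1)
  c(dt / 2, rep(dt, max(n_t - 2L, 0L)), dt / 2)
}

# Per-substep fields (averages of adjacent nodes) and substep size.
substep_fields <- function(v) {
  if (v$n_t == 1L) return(list(fields = v$fields, dt = 1))
  n_s <- v$n_t - 1L
  f <- lapply(seq_len(n_s),
              function(k) (v$fields[[k]] + v$fields[[k + 1L]]) / 2)
  list(fields = f, dt = 1 / n_s)
}

#' Path energy of a velocity field
#'
#' `int_0^1 ||v_t||_V^2 dt` by trapezoidal quadrature over the time nodes;
#' this is the squared diffeomorphometry path length of the current
#' (relaxation) path.
#'
#' @param v a [tv_velocity()].
#' @param spacing voxel spacing.
#' @param kp a [kernel_params()].
#' @return scalar.
#' @export
path_energy <- function(v, spacing, kp = kernel_params()) {
  w <- time_weights(v$n_t)
  s <- 0
  for (k in seq_len(v$n_t))
    s <- s + w[k] * v_norm_sq(v$fields[[k]], spacing, kp)
  s
}

# Grid of world coordinates as a 4D array [dims, 3].
world_grid <- function(dm, spacing, origin) {
  g <- array(0, c(dm, 3L))
  g[, , , 1] <- origin[1] + (seq_len(dm[1]) - 1) * spacing[1]
  g[, , , 2] <- rep(origin[2] + (seq_len(dm[2]) - 1) * spacing[2],
                    each = dm[1])
  g[, , , 3] <- rep(origin[3] + (seq_len(dm[3]) - 1) * spacing[3],
                    each = dm[1] * dm[2])
  g
}

#' Integrate a velocity field into a pair of diffeomorphisms
#'
#' Builds the inverse map semi-Lagrangianly,
#' `phi_inv_{t+dt}(x) = phi_inv_t(x - dt v_t(x))`, and the forward map by the
#' pointwise characteristic recursion `phi_{t+dt}(x) = phi_t(x) + dt v_t(phi_t(x))`,
#' both with trilinear interpolation (edge-extended for displacement
#' fields). Also returns the Jacobian determinant of the inverse map by
#' central differences; strict positivity at every interior voxel is the
#' working check that the map is diffeomorphic.
#'
#' A CFL-like sanity check warns (but does not fail) when a single substep
#' displaces by more than one voxel pitch.
#'
#' @param v a [tv_velocity()].
#' @param spacing voxel spacing.
#' @param origin world origin of the grid.
#' @return an object of class `diffeo_pair` with elements `phi`, `phi_inv`
#'   (4D position arrays in world coordinates), `jacobian_det`, `spacing`,
#'   `origin`.
#' @export
integrate_flow <- function(v, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(inherits(v, "tv_velocity"))
  dm <- dim(v$fields[[1]])[1:3]
  ss <- substep_fields(v)
  vmax <- max(vapply(ss$fields, function(f) max(abs(f)), 0))
  if (vmax * ss$dt > min(spacing))
    warning("integrate_flow: substep displacement exceeds one voxel pitch")
  grid <- world_grid(dm, spacing, origin)
  uinv <- array(0, c(dm, 3L))   # displacement of phi_inv
  ufwd <- array(0, c(dm, 3L))   # displacement of phi
  gx <- grid[, , , 1]; gy <- grid[, , , 2]; gz <- grid[, , , 3]
  for (k in seq_along(ss$fields)) {
    w <- ss$fields[[k]]
    # inverse map: pull back along -dt * v evaluated at the grid
    yx <- gx - ss$dt * w[, , , 1]
    yy <- gy - ss$dt * w[, , , 2]
    yz <- gz - ss$dt * w[, , , 3]
    xi <- (yx - origin[1]) / spacing[1] + 1
    yi <- (yy - origin[2]) / spacing[2] + 1
    zi <- (yz - origin[3]) / spacing[3] + 1
    plan <- trilinear_plan(dm, xi, yi, zi)
    new_uinv <- uinv
    for (d in 1:3) {
      ud <- trilinear_value_clamped(uinv[, , , d], plan)
      new_uinv[, , , d] <- array(ud, dm)
    }
    new_uinv[, , , 1] <- new_uinv[, , , 1] + (yx - gx)
    new_uinv[, , , 2] <- new_uinv[, , , 2] + (yy - gy)
    new_uinv[, , , 3] <- new_uinv[, , , 3] + (yz - gz)
    uinv <- new_uinv
    # forward map: follow characteristics from the grid
    px <- gx + ufwd[, , , 1]
    py <- gy + ufwd[, , , 2]
    pz <- gz + ufwd[, , , 3]
    xi <- (px - origin[1]) / spacing[1] + 1
    yi <- (py - origin[2]) / spacing[2] + 1
    zi <- (pz - origin[3]) / spacing[3] + 1
    planf <- trilinear_plan(dm, xi, yi, zi)
    for (d in 1:3) {
      wd <- trilinear_value_clamped(w[, , , d], planf)
      ufwd[, , , d] <- ufwd[, , , d] + ss$dt * array(wd, dm)
    }
  }
  phi <- grid + ufwd
  phi_inv <- grid + uinv
  structure(list(phi = phi, phi_inv = phi_inv,
                 jacobian_det = map_jacobian_det(phi_inv, spacing),
                 spacing = spacing, origin = origin),
            class = "diffeo_pair")
}

# Edge-extended trilinear value (no zero fill): out-of-domain points take
# the value at the clamped coordinate, appropriate for displacement fields.
trilinear_value_clamped <- function(vol, plan) {
  i0 <- plan$idx0; ox <- plan$ox; oy <- plan$oy; oz <- plan$oz
  fx <- plan$fx; fy <- plan$fy; fz <- plan$fz
  c000 <- vol[i0];           c100 <- vol[i0 + ox]
  c010 <- vol[i0 + oy];      c110 <- vol[i0 + ox + oy]
  c001 <- vol[i0 + oz];      c101 <- vol[i0 + ox + oz]
  c011 <- vol[i0 + oy + oz]; c111 <- vol[i0 + ox + oy + oz]
  w00 <- c000 * (1 - fx) + c100 * fx
  w10 <- c010 * (1 - fx) + c110 * fx
  w01 <- c001 * (1 - fx) + c101 * fx
  w11 <- c011 * (1 - fx) + c111 * fx
  v0 <- w00 * (1 - fy) + w10 * fy
  v1 <- w01 * (1 - fy) + w11 * fy
  v0 * (1 - fz) + v1 * fz
}

# Jacobian determinant of a position map (4D [dims, 3], world coords) by
# central differences, one-sided at the boundary.
map_jacobian_det <- function(map, spacing) {
  dm <- dim(map)[1:3]
  J <- vector("list", 9)
  idx <- 1
  for (comp in 1:3) {
    m <- map[, , , comp]
    for (ax in 1:3) {
      J[[idx]] <- axis_diff(m, ax) / spacing[ax]
      idx <- idx + 1
    }
  }
  # rows: components, cols: axes; J[[ (comp-1)*3 + ax ]]
  a <- J[[1]]; b <- J[[2]]; c_ <- J[[3]]
  d <- J[[4]]; e <- J[[5]]; f <- J[[6]]
  g <- J[[7]]; h <- J[[8]]; i <- J[[9]]
  a * (e * i - f * h) - b * (d * i - f * g) + c_ * (d * h - e * g)
}

# Central difference along one axis with one-sided boundary.
axis_diff <- function(x, axis) {
  dm <- dim(x)
  n <- dm[axis]
  ip <- c(2:n, n); im <- c(1, 1:(n - 1))
  denom <- array(2, dm)
  if (axis == 1) {
    out <- x[ip, , , drop = FALSE] - x[im, , , drop = FALSE]
    denom[c(1, n), , ] <- 1
  } else if (axis == 2) {
    out <- x[, ip, , drop = FALSE] - x[, im, , drop = FALSE]
    denom[, c(1, n), ] <- 1
  } else {
    out <- x[, , ip, drop = FALSE] - x[, , im, drop = FALSE]
    denom[, , c(1, n)] <- 1
  }
  out / denom
}

#' Warp a volume through a position map
#'
#' Samples `vol` at the positions of `map` (for example `phi_inv`, giving
#' the deformed volume `vol o phi_inv`). Trilinear for intensities,
#' nearest-neighbour for label volumes.
#'
#' @param vol a [volume3d()].
#' @param map 4D position array in world coordinates (e.g. `dp$phi_inv`).
#' @param method `"trilinear"` or `"nearest"`.
#' @return a [volume3d()] on the map's grid.
#' @export
warp_volume <- function(vol, map, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  dm_out <- dim(map)[1:3]
  xi <- (map[, , , 1] - vol$origin[1]) / vol$spacing[1] + 1
  yi <- (map[, , , 2] - vol$origin[2]) / vol$spacing[2] + 1
  zi <- (map[, , , 3] - vol$origin[3]) / vol$spacing[3] + 1
  vals <- if (method == "trilinear")
    trilinear_sample(vol$values, xi, yi, zi)$values
  else
    nearest_sample3(vol$values, xi, yi, zi)$values
  volume3d(array(vals, dm_out), spacing = vol$spacing, origin = vol$origin)
}

# Iterated warping of scalar volumes by the inverse-flow recursion
# J_k(x) = J_{k-1}(x - dt w_k(x)); this is the discrete realization of
# I o phi_inv used inside the matching energy, and the object the exact
# backpropagated gradient differentiates. Returns the warped channels and,
# if keep = TRUE, the per-step plans and intermediate images needed by the
# adjoint pass.
flow_warp_channels <- function(channels, v, spacing, keep = FALSE) {
  dm <- dim(channels[[1]])
  ss <- substep_fields(v)
  n_s <- length(ss$fields)
  ix <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm)
  iy <- array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm)
  iz <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  imgs <- channels
  plans <- if (keep) vector("list", n_s) else NULL
  hist <- if (keep) vector("list", n_s) else NULL
  for (k in seq_len(n_s)) {
    w <- ss$fields[[k]]
    xi <- ix - ss$dt * w[, , , 1] / spacing[1]
    yi <- iy - ss$dt * w[, , , 2] / spacing[2]
    zi <- iz - ss$dt * w[, , , 3] / spacing[3]
    plan <- trilinear_plan(dm, xi, yi, zi)
    if (keep) { plans[[k]] <- plan; hist[[k]] <- imgs }
    imgs <- lapply(imgs, function(im) array(trilinear_value(im, plan), dm))
  }
  list(images = imgs, plans = plans, history = hist, dt = ss$dt, n_s = n_s)
}
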