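# Synthetic phantoms and the sectioning observation model used by the
# simulation studies: curved binary phantoms (the classic curvature
# non-identifiability fixture), cylinders, blobs, brain-like grayscale
# objects; random sectioning with rigid jitter, cumulative shear and
# Gaussian noise; and random ground-truth diffeomorphisms.

# Run code under a temporary RNG state so generators are deterministic
# given their seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic phantom
#'
#' @param shape grid dimensions `(nx, ny, nz)` in voxels.
#' @param kind `"curved_cylinder"`, `"straight_cylinder"`,
#'   `"gaussian_blob"` or `"brainlike"`.
#' @param curvature peak centreline deflection (voxels) of the curved
#'   cylinder: the in-plane offset follows a parabola along z, zero at the
#'   ends and `curvature` at the apex.
#' @param radius cross-section radius in voxels (>= 2); length-2 for an
#'   elliptical cross-section, which breaks in-plane rotational symmetry
#'   and makes the rotation estimator identifiable.
#' @param anti_alias soften the binary edge with a smoothstep profile over
#'   `edge_width` voxels (keeps resampling error small on the edge).
#' @param edge_width anti-aliasing width in voxels.
#' @param seed RNG seed for the brain-like phantom's random structure.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 32),
                         kind = c("curved_cylinder", "straight_cylinder",
                                  "gaussian_blob", "brainlike"),
                         curvature = 8, radius = 10, anti_alias = TRUE,
                         edge_width = 3, seed = 1L) {
  kind <- match.arg(kind)
  if (min(radius) < 2) stop("phantom_spec: radius must be >= 2 voxels")
  if (kind == "straight_cylinder") curvature <- 0
  structure(list(shape = as.integer(shape), kind = kind,
                 curvature = curvature, radius = radius,
                 anti_alias = anti_alias, edge_width = edge_width,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume
#'
#' Cylinders are unions of (possibly elliptical) disks centred on a
#' parabolic centreline along z with apex deflection `curvature`; the
#' brain-like phantom is a smooth ellipsoidal body with seeded internal
#' intensity structure, emulating the contour richness of a grayscale
#' anatomy without any real data.
#'
#' @param spec a [phantom_spec()].
#' @param spacing voxel spacing of the returned volume.
#' @return a [volume3d()] with intensities in `[0, 1]`.
#' @export
make_phantom <- function(spec, spacing = c(1, 1, 1)) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape
  cx <- (dm[1] + 1) / 2; cy <- (dm[2] + 1) / 2
  rad <- rep_len(spec$radius, 2L)
  if (spec$kind %in% c("curved_cylinder", "straight_cylinder")) {
    if (cx + spec$curvature + rad[1] > dm[1] + 0.5 || cy + rad[2] > dm[2] + 0.5)
      stop("make_phantom: geometry exceeds grid")
    vals <- array(0, dm)
    xg <- matrix(rep(seq_len(dm[1]), dm[2]), dm[1], dm[2])
    yg <- matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1], dm[2])
    for (k in seq_len(dm[3])) {
      u <- 2 * (k - 1) / (dm[3] - 1) - 1
      off <- spec$curvature * (1 - u^2)
      # approximate signed distance to the ellipse boundary
      rho <- sqrt(((xg - cx - off) / rad[1])^2 + ((yg - cy) / rad[2])^2)
      d <- (rho - 1) * min(rad)
      vals[, , k] <- if (spec$anti_alias) {
        u <- pmin(pmax(0.5 - d / spec$edge_width, 0), 1)
        u * u * (3 - 2 * u)   # smoothstep edge
      } else (d <= 0) + 0
    }
  } else if (spec$kind == "gaussian_blob") {
    cz <- (dm[3] + 1) / 2
    s2 <- 2 * mean(rad)^2
    a <- outer(exp(-(seq_len(dm[1]) - cx)^2 / s2),
               exp(-(seq_len(dm[2]) - cy)^2 / s2))
    vals <- outer(a, exp(-(seq_len(dm[3]) - cz)^2 / s2))
  } else {   # brainlike
    vals <- with_seed(spec$seed, brainlike_values(dm, rad))
  }
  volume3d(vals, spacing = spacing)
}

# Smooth ellipsoidal body plus a handful of interior intensity lobes and a
# gentle gradient: enough internal level lines for matching to grip.
brainlike_values <- function(dm, rad) {
  ctr <- (dm + 1) / 2
  semi <- pmax(dm * 0.33, 3)
  xg <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm)
  yg <- array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm)
  zg <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  rho <- sqrt(((xg - ctr[1]) / semi[1])^2 + ((yg - ctr[2]) / semi[2])^2 +
              ((zg - ctr[3]) / semi[3])^2)
  # smoothstep body edge over ~3 voxels: keeps resampling smooth
  u <- pmin(pmax(((1 - rho) * min(semi) + 1.5) / 3, 0), 1)
  body <- u * u * (3 - 2 * u)
  tex <- 0.55 + 0.1 * (xg - ctr[1]) / dm[1]
  n_lobes <- sample(3:5, 1)
  for (b in seq_len(n_lobes)) {
    c_b <- ctr + (stats::runif(3) - 0.5) * semi
    s_b <- (0.15 + 0.2 * stats::runif(1)) * min(semi)
    amp <- stats::runif(1, -0.35, 0.45)
    tex <- tex + amp * exp(-((xg - c_b[1])^2 + (yg - c_b[2])^2 +
                             (zg - c_b[3])^2) / (2 * s_b^2))
  }
  pmin(pmax(body * tex, 0), 1)
}

#' Specification of the sectioning observation model
#'
#' Random per-section rigid jitter (circular-Gaussian rotation, Gaussian
#' translation), optional cumulative per-section shear offset, and i.i.d.
#' Gaussian intensity noise. The default jitter matches the simulation
#' protocol for the binary phantoms: translation components with variance
#' 36 (standard deviation 6 pixels) and rotation with standard deviation
#' 10 degrees.
#'
#' @param t_sigma translation jitter standard deviation, physical units.
#' @param theta_sigma_deg rotation jitter standard deviation, degrees.
#' @param noise_sigma intensity noise standard deviation.
#' @param shear_per_section per-section cumulative offset `(dx, dy)`; the
#'   classic shear protocol uses `c(0.25, 0.25)` pixels.
#' @param seed RNG seed; the whole observation draw is reproducible.
#' @return an object of class `sectioning_spec`.
#' @export
sectioning_spec <- function(t_sigma = 6, theta_sigma_deg = 10,
                            noise_sigma = 0, shear_per_section = c(0, 0),
                            seed = 1L) {
  if (t_sigma < 0 || theta_sigma_deg < 0 || noise_sigma < 0)
    stop("sectioning_spec: standard deviations must be nonnegative")
  structure(list(t_sigma = t_sigma, theta_sigma_deg = theta_sigma_deg,
                 noise_sigma = noise_sigma,
                 shear_per_section = rep_len(shear_per_section, 2L),
                 seed = as.integer(seed)),
            class = "sectioning_spec")
}

#' Section a phantom with jitter, shear and noise
#'
#' Extracts the z-slabs of the volume and applies the *inverse* of each
#' sampled ground-truth motion to each section, so that restacking the
#' observed sections with the returned ground-truth motions restores
#' alignment (`I^R(., z_i) = J_i o R_i`), with no sign gymnastics when
#' comparing estimates to truth. Cumulative shear (if any) is composed into
#' the applied offset but excluded from the returned truth — it is a
#' deformation of the object, not jitter, and is what the diffeomorphic
#' channel must absorb. Gaussian noise is added last. The transported
#' in-domain masks become the stack's data masks.
#'
#' @param vol a [volume3d()] phantom.
#' @param spec a [sectioning_spec()].
#' @return list with `stack` (a [section_stack()]) and `truth` (list of
#'   [rigid_motion()]).
#' @export
section_phantom <- function(vol, spec) {
  stopifnot(inherits(vol, "volume3d"), inherits(spec, "sectioning_spec"))
  dm <- dim(vol$values)
  n <- dm[3]
  sp2 <- vol$spacing[1:2]
  with_seed(spec$seed, {
    theta <- stats::rnorm(n, 0, spec$theta_sigma_deg * pi / 180)
    tx <- stats::rnorm(n, 0, spec$t_sigma)
    ty <- stats::rnorm(n, 0, spec$t_sigma)
    truth <- lapply(seq_len(n), function(i) rigid_motion(theta[i], tx[i], ty[i]))
    sections <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      shear <- (i - 1) * spec$shear_per_section * sp2
      gen <- rigid_motion(theta[i], tx[i] + shear[1], ty[i] + shear[2])
      obs <- apply_rigid(vol$values[, , i], rigid_invert(gen), sp2)
      s <- obs$values
      if (spec$noise_sigma > 0)
        s <- s + stats::rnorm(length(s), 0, spec$noise_sigma)
      sections[[i]] <- matrix(s, dm[1], dm[2])
      masks[[i]] <- obs$mask
    }
    list(stack = section_stack(sections,
                               z_positions = vol$origin[3] +
                                 (seq_len(n) - 1) * vol$spacing[3],
                               in_plane_spacing = sp2,
                               data_masks = masks),
         truth = truth)
  })
}

#' Draw a random diffeomorphism
#'
#' White-noise momentum smoothed by the Green's kernel, scaled so the
#' maximum displacement of the integrated flow matches the requested
#' amplitude, then integrated into a map pair. Used to pose ground-truth
#' deformations for simulated atlases.
#'
#' @param dm grid dimensions `(nx, ny, nz)`.
#' @param kp a [kernel_params()].
#' @param amplitude requested maximum displacement, physical units.
#' @param n_t time nodes for the flow.
#' @param spacing,origin grid geometry.
#' @param seed RNG seed.
#' @return list with `diffeo` (a `diffeo_pair`) and `v` (the generating
#'   [tv_velocity()]).
#' @export
random_diffeomorphism <- function(dm, kp = kernel_params(), amplitude = 1,
                                  n_t = 10L, spacing = c(1, 1, 1),
                                  origin = c(0, 0, 0), seed = 1L) {
  if (amplitude == 0) {
    v <- zero_velocity(dm, n_t)
    return(list(diffeo = integrate_flow(v, spacing, origin), v = v))
  }
  with_seed(seed, {
    mom <- array(stats::rnorm(prod(dm) * 3), c(dm, 3L))
    sm <- apply_kernel(mom, spacing, kp)
    sm <- sm / max(abs(sm))
    v <- tv_velocity(replicate(n_t, sm, simplify = FALSE))
    dp <- integrate_flow(v, spacing, origin)
    disp <- dp$phi - world_grid(dm, spacing, origin)
    d0 <- max(abs(disp))
    sm <- sm * amplitude / d0
    v <- tv_velocity(replicate(n_t, sm, simplify = FALSE))
    dp <- integrate_flow(v, spacing, origin)
    if (min(dp$jacobian_det) <= 0)
      stop("random_diffeomorphism: amplitude too large")
    list(diffeo = dp, v = v)
  })
}
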