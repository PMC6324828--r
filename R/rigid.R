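# In-plane rigid motions per section: group operations, image action by
# bilinear resampling about the section centre, and the Gaussian priors used
# by the MAP restacking objective.

#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return wrapped angles; useful when differencing estimated and true
#'   rotations.
#' @export
wrap_angle <- function(theta) {
  th <- (theta + pi) %% (2 * pi) - pi
  # map the boundary -pi to +pi so the representative interval is (-pi, pi]
  th[th == -pi] <- pi
  th
}

#' In-plane rigid motion of a section
#'
#' A rotation by `theta` (radians, wrapped to `(-pi, pi]`) about the
#' geometric centre of the section's physical extent followed by a
#' translation `(tx, ty)` in physical units. Acting on a point
#' `p = (x, y)` in centred coordinates:
#' `R(p) = (cos(theta) x + sin(theta) y + tx, -sin(theta) x + cos(theta) y + ty)`.
#'
#' @param theta rotation angle in radians.
#' @param tx,ty translation in physical units.
#' @return an object of class `rigid_motion`.
#' @export
rigid_motion <- function(theta = 0, tx = 0, ty = 0) {
  if (!all(is.finite(c(theta, tx, ty))))
    stop("rigid_motion: non-finite parameters")
  structure(list(theta = wrap_angle(theta), tx = tx, ty = ty),
            class = "rigid_motion")
}

#' @export
print.rigid_motion <- function(x, ...) {
  cat(sprintf("<rigid_motion> theta = %.6g rad (%.4g deg), t = (%.6g, %.6g)\n",
              x$theta, x$theta * 180 / pi, x$tx, x$ty))
  invisible(x)
}

rigid_matrix <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
}

#' Group operations on rigid motions
#'
#' `rigid_compose(a, b)` is the motion `a o b` (apply `b` to the point, then
#' `a`), so that resampling a section with the composite equals resampling
#' twice: `apply_rigid(J, rigid_compose(a, b)) = apply_rigid(apply_rigid(J, a), b)`
#' up to interpolation. `rigid_invert(r)` is the group inverse.
#'
#' @param a,b,r [rigid_motion()] objects.
#' @return a [rigid_motion()].
#' @export
rigid_compose <- function(a, b) {
  M <- rigid_matrix(a$theta)
  t_new <- M %*% c(b$tx, b$ty) + c(a$tx, a$ty)
  rigid_motion(a$theta + b$theta, t_new[1], t_new[2])
}

#' @rdname rigid_compose
#' @export
rigid_invert <- function(r) {
  Mi <- rigid_matrix(-r$theta)
  t_new <- -Mi %*% c(r$tx, r$ty)
  rigid_motion(-r$theta, t_new[1], t_new[2])
}

rigid_is_identity <- function(r, tol = 0)
  abs(r$theta) <= tol && abs(r$tx) <= tol && abs(r$ty) <= tol

#' Resample a section under a rigid motion
#'
#' Computes `J o R`: each output pixel centre `p` (in physical coordinates
#' centred on the section extent) takes the bilinear interpolation of the
#' section at `R(p)`. Pixels mapping outside the section domain are zero in
#' the output and zero in the output mask. The data mask is transported with
#' nearest-neighbour interpolation and intersected with the in-domain
#' indicator, so resampled missing data stays excluded from cost terms.
#'
#' @param section numeric matrix.
#' @param R a [rigid_motion()].
#' @param spacing pixel pitch `(dx, dy)` in the units of the translation.
#' @param mask optional binary matrix of observed pixels.
#' @param with_gradient also return the spatial intensity gradient of the
#'   output (physical units), used by the analytic parameter gradients.
#' @return list with `values`, `mask`, and if requested `gx`, `gy` and the
#'   centred coordinates `px`, `py` of the output pixels.
#' @export
apply_rigid <- function(section, R, spacing = c(1, 1), mask = NULL,
                        with_gradient = FALSE) {
  stopifnot(inherits(R, "rigid_motion"))
  if (any(!is.finite(section))) stop("apply_rigid: non-finite section")
  if (rigid_is_identity(R) && !with_gradient) {
    m <- if (is.null(mask)) matrix(1, nrow(section), ncol(section)) else (mask != 0) + 0
    return(list(values = section * m, mask = m))
  }
  if (!is.null(mask) && !any(mask == 0)) mask <- NULL  # fully observed
  dm <- dim(section)
  cc <- section_centered_coords(dm, spacing)
  px <- rep(cc$x, times = dm[2])
  py <- rep(cc$y, each = dm[1])
  ct <- cos(R$theta); st <- sin(R$theta)
  qx <- ct * px + st * py + R$tx
  qy <- -st * px + ct * py + R$ty
  # physical -> index coordinates
  xi <- qx / spacing[1] + (dm[1] + 1) / 2
  yi <- qy / spacing[2] + (dm[2] + 1) / 2
  smp <- if (with_gradient) bilinear_sample_grad(section, xi, yi)
         else bilinear_sample(section, xi, yi)
  mvals <- if (is.null(mask)) smp$inside + 0 else {
    mm <- nearest_sample(mask, xi, yi)
    ((mm$values != 0) & smp$inside) + 0
  }
  out <- list(values = matrix(smp$values * mvals, dm[1], dm[2]),
              mask = matrix(mvals, dm[1], dm[2]))
  if (with_gradient) {
    out$gx <- matrix(smp$gx / spacing[1], dm[1], dm[2])
    out$gy <- matrix(smp$gy / spacing[2], dm[1], dm[2])
    out$px <- matrix(px, dm[1], dm[2])
    out$py <- matrix(py, dm[1], dm[2])
  }
  out
}

#' Gaussian priors on section motions
#'
#' Independent Gaussians on the rotation angle (circular Gaussian with
#' standard deviation `sigma_theta`, mean zero) and on the two translation
#' components (standard deviation `sigma_c`, means `mu_c` at the section
#' centre). Defaults follow the restacking hyper-parameters used for
#' 20-micrometre mouse histology: standard deviations of `pi/9` radians on
#' rotation (about 5% of the angular range) and 7 pixel pitches on
#' translation -- `sigma_c` is in the physical units of the translations,
#' so scale it by the pixel pitch of the working grid.
#'
#' @param sigma_theta prior standard deviation of the rotation, radians.
#' @param sigma_c prior standard deviation of each translation component.
#' @param mu_c_x,mu_c_y translation prior means.
#' @return an object of class `rigid_prior`.
#' @export
rigid_prior <- function(sigma_theta = pi / 9, sigma_c = 7,
                        mu_c_x = 0, mu_c_y = 0) {
  if (sigma_theta <= 0 || sigma_c <= 0)
    stop("rigid_prior: standard deviations must be strictly positive")
  structure(list(sigma_theta = sigma_theta, sigma_c = sigma_c,
                 mu_c_x = mu_c_x, mu_c_y = mu_c_y),
            class = "rigid_prior")
}

#' Log-density of the rigid-motion prior
#'
#' `-theta^2/(2 sigma_theta^2) - (tx - mu_x)^2/(2 sigma_c^2)
#'  - (ty - mu_y)^2/(2 sigma_c^2)` plus the standard Gaussian
#' log-normalizers. `rigid_log_prior_grad` returns the analytic gradient
#' with respect to `(theta, tx, ty)`.
#'
#' @param R a [rigid_motion()].
#' @param prior a [rigid_prior()].
#' @return scalar log-density (gradient: numeric length 3).
#' @export
rigid_log_prior <- function(R, prior) {
  stats::dnorm(R$theta, 0, prior$sigma_theta, log = TRUE) +
    stats::dnorm(R$tx, prior$mu_c_x, prior$sigma_c, log = TRUE) +
    stats::dnorm(R$ty, prior$mu_c_y, prior$sigma_c, log = TRUE)
}

#' @rdname rigid_log_prior
#' @export
rigid_log_prior_grad <- function(R, prior) {
  c(theta = -R$theta / prior$sigma_theta^2,
    tx = -(R$tx - prior$mu_c_x) / prior$sigma_c^2,
    ty = -(R$ty - prior$mu_c_y) / prior$sigma_c^2)
}

#' Sample rigid motions from the prior
#'
#' Used by the sectioning simulator to draw jitter. With `seed` the draw is
#' reproducible and the caller's RNG stream is left untouched; otherwise
#' the session RNG stream is used.
#'
#' @param prior a [rigid_prior()].
#' @param n number of motions to draw.
#' @param seed optional integer seed.
#' @return a list of `n` [rigid_motion()] objects.
#' @export
sample_rigid_prior <- function(prior, n = 1, seed = NULL) {
  draw <- function() {
    th <- stats::rnorm(n, 0, prior$sigma_theta)
    tx <- stats::rnorm(n, prior$mu_c_x, prior$sigma_c)
    ty <- stats::rnorm(n, prior$mu_c_y, prior$sigma_c)
    lapply(seq_len(n), function(i) rigid_motion(th[i], tx[i], ty[i]))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
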