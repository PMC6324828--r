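# First-order Sobolev smoothness prior along the cutting axis: the mixed
# differential-difference operator realized as staggered-grid forward
# differences between adjacent sections, and the stack-smoothness energy it
# induces. Only the z-term enters the optimized objective: the in-plane
# first-derivative terms are invariant to in-plane rigid motion of each
# section (up to boundary/interpolation effects), so they would add cost
# without moving the argmax; they remain available as a diagnostic.

#' Configuration of the stack-smoothness prior
#'
#' @param order_k derivative order; the estimator exercises `k = 1`.
#' @param weight nonnegative multiplier on the energy.
#' @return an object of class `sobolev_config`.
#' @export
sobolev_config <- function(order_k = 1L, weight = 1.0) {
  if (order_k < 1L) stop("sobolev_config: order_k must be >= 1")
  if (weight < 0) stop("sobolev_config: weight must be nonnegative")
  structure(list(order_k = as.integer(order_k), weight = weight),
            class = "sobolev_config")
}

#' Staggered z-difference of a stack volume
#'
#' Slab `k` of the output is `(slab[k+1] - slab[k]) / dz`: the centred
#' difference evaluated at the half-grid midpoints between sections. The
#' forced-zero gradient at the stack boundary is realized by there being no
#' difference term beyond the first and last sections, so a volume with `n`
#' slabs yields `n - 1` difference slabs.
#'
#' @param vol a [volume3d()] with at least 2 slabs.
#' @return a [volume3d()] with `n - 1` slabs, origin shifted by `dz / 2`.
#' @export
z_difference <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  n <- dim(vol$values)[3]
  if (n < 2L) stop("z_difference: need at least 2 slabs")
  dz <- vol$spacing[3]
  d <- (vol$values[, , -1L, drop = FALSE] -
        vol$values[, , -n, drop = FALSE]) / dz
  volume3d(d, spacing = vol$spacing,
           origin = vol$origin + c(0, 0, dz / 2))
}

# Pairwise observation masks for the staggered differences: a difference
# term exists only where both adjacent sections observe the pixel.
pair_masks <- function(masks) {
  n <- length(masks)
  lapply(seq_len(n - 1L), function(k) masks[[k]] * masks[[k + 1L]])
}

#' Stack-smoothness energy
#'
#' One half times `weight` times the sum over staggered difference slabs of
#' the pixel-area-weighted masked squared norm: the discrete realization of
#' the per-section L2 norms of the z-derivative. Constant stacks score zero;
#' rough restackings score high, which is what drives the atlas-free
#' alignment.
#'
#' @param vol a [volume3d()] (a restacked section volume).
#' @param masks optional list of per-section binary matrices.
#' @param cfg a [sobolev_config()].
#' @return nonnegative scalar.
#' @export
stack_smoothness_energy <- function(vol, masks = NULL, cfg = sobolev_config()) {
  d <- z_difference(vol)
  area <- vol$spacing[1] * vol$spacing[2]
  if (is.null(masks)) {
    s <- sum(d$values^2)
  } else {
    pm <- pair_masks(masks)
    s <- 0
    for (k in seq_along(pm)) s <- s + sum(pm[[k]] * d$values[, , k]^2)
  }
  0.5 * cfg$weight * area * s
}

#' Gradient of the stack-smoothness energy with respect to one section
#'
#' The derivative of [stack_smoothness_energy()] with respect to the pixel
#' values of section `i`: `weight * area * (2 I_i - I_{i-1} - I_{i+1}) / dz^2`
#' on the interior (one-sided at the first and last sections), restricted to
#' pixels whose staggered difference terms are observed. This is the term
#' that couples the rigid registration across sections.
#'
#' @param vol a [volume3d()].
#' @param i section index in `1..n`.
#' @param masks optional list of per-section binary matrices.
#' @param cfg a [sobolev_config()].
#' @return numeric matrix, the per-pixel gradient.
#' @export
sobolev_gradient_section <- function(vol, i, masks = NULL,
                                     cfg = sobolev_config()) {
  stopifnot(inherits(vol, "volume3d"))
  n <- dim(vol$values)[3]
  if (i < 1L || i > n) stop("sobolev_gradient_section: index out of range")
  dz <- vol$spacing[3]
  area <- vol$spacing[1] * vol$spacing[2]
  g <- matrix(0, dim(vol$values)[1], dim(vol$values)[2])
  Ii <- vol$values[, , i]
  if (i > 1L) {
    m <- if (is.null(masks)) 1 else masks[[i - 1L]] * masks[[i]]
    g <- g + m * (Ii - vol$values[, , i - 1L]) / dz^2
  }
  if (i < n) {
    m <- if (is.null(masks)) 1 else masks[[i]] * masks[[i + 1L]]
    g <- g + m * (Ii - vol$values[, , i + 1L]) / dz^2
  }
  cfg$weight * area * g
}

#' Full first-order Sobolev energy (diagnostic)
#'
#' The complete first-order norm including the in-plane derivative terms,
#' reported for diagnostics. In-plane terms use central differences with
#' replicated boundary (zero-gradient); the z-term is the staggered
#' difference of [z_difference()].
#'
#' @param vol a [volume3d()].
#' @param cfg a [sobolev_config()].
#' @return list with `z`, `x`, `y` energy components and `total`.
#' @export
h1_energy <- function(vol, cfg = sobolev_config()) {
  v <- vol$values
  area <- vol$spacing[1] * vol$spacing[2]
  dm <- dim(v)
  dx <- (v[c(2:dm[1], dm[1]), , ] - v[c(1, 1:(dm[1] - 1)), , ]) /
    (2 * vol$spacing[1])
  dy <- (v[, c(2:dm[2], dm[2]), ] - v[, c(1, 1:(dm[2] - 1)), ]) /
    (2 * vol$spacing[2])
  ez <- stack_smoothness_energy(vol, cfg = cfg)
  ex <- 0.5 * cfg$weight * area * sum(dx^2)
  ey <- 0.5 * cfg$weight * area * sum(dy^2)
  list(z = ez, x = ex, y = ey, total = ez + ex + ey)
}
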