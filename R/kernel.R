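# The RKHS of velocity fields: differential operator L = (1 - a^2 lap)^s
# realized as an FFT multiplier with the *discrete* Laplacian symbol, so that
# the forward operator |Lhat|^2 and the Green's kernel K = (L'L)^-1 are exact
# mutual inverses on the grid.

#' Kernel / operator parameters for the velocity-field norm
#'
#' The velocity norm is `||v||_V^2 = sum_i int ((1 - a^2 lap)^s v_i)^2 dx`,
#' with `a` the kernel length scale in normalized image-width units (so
#' `a = 0.05` means 5% of the physical x-extent of the grid) and `s` the
#' operator power. The coarse-to-fine continuation used in registration is a
#' non-increasing cascade of length scales, by default `0.05, 0.02, 0.01`.
#'
#' @param length_scale scale `a` in normalized image-width units.
#' @param power_s integer operator power `s` (default 2).
#' @param cascade non-increasing vector of length scales for continuation.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(length_scale = 0.05, power_s = 2L,
                          cascade = c(0.05, 0.02, 0.01)) {
  if (length_scale < 0) stop("kernel_params: length scale must be nonnegative")
  if (power_s < 1L) stop("kernel_params: power_s must be >= 1")
  if (is.unsorted(rev(cascade))) stop("kernel_params: cascade must be non-increasing")
  structure(list(length_scale = length_scale, power_s = as.integer(power_s),
                 cascade = cascade),
            class = "kernel_params")
}

# Fourier multiplier Lhat(omega) = (1 + a_phys^2 * lambda(omega))^s with
# lambda the symbol of the (negative) discrete Laplacian,
# lambda = sum_d 2 (1 - cos(2 pi k_d / N_d)) / dx_d^2.
kernel_lhat <- function(dm, spacing, kp) {
  a_phys <- kp$length_scale * dm[1] * spacing[1]
  lam_axis <- function(n, dx) 2 * (1 - cos(2 * pi * (0:(n - 1)) / n)) / dx^2
  lx <- lam_axis(dm[1], spacing[1])
  ly <- lam_axis(dm[2], spacing[2])
  lz <- lam_axis(dm[3], spacing[3])
  lam <- outer(outer(lx, ly, `+`), lz, `+`)
  (1 + a_phys^2 * lam)^kp$power_s
}

fft3 <- function(x) stats::fft(x)
ifft3_re <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# Apply a real Fourier multiplier to each spatial component of a vector
# field stored as a 4D array [nx, ny, nz, 3].
apply_multiplier <- function(field, mult) {
  out <- field
  for (d in 1:3) out[, , , d] <- ifft3_re(fft3(field[, , , d]) * mult)
  out
}

#' Squared V-norm of a velocity field
#'
#' Computed in the Fourier domain as
#' `sum_i sum_omega |Lhat|^2 |vhat_i|^2 * voxel_volume / N`, which by
#' Parseval equals the spatial-domain sum of `(L v_i)^2` times the voxel
#' volume. Nonnegative, and zero iff the field is identically zero.
#'
#' @param field 4D array `[nx, ny, nz, 3]`, physical-unit velocity.
#' @param spacing voxel spacing.
#' @param kp a [kernel_params()].
#' @return scalar.
#' @export
v_norm_sq <- function(field, spacing, kp = kernel_params()) {
  dm <- dim(field)[1:3]
  lhat <- kernel_lhat(dm, spacing, kp)
  voxvol <- prod(spacing)
  n <- prod(dm)
  s <- 0
  for (d in 1:3)
    s <- s + sum(lhat^2 * Mod(fft3(field[, , , d]))^2)
  s * voxvol / n
}

#' Apply the forward operator or the Green's kernel to a vector field
#'
#' `apply_operator` multiplies by the forward multiplier `|Lhat|^2` (that is,
#' applies `L'L`); `apply_kernel` applies the Green's kernel
#' `K = (L'L)^{-1}`, the smoothing used to precondition LDDMM gradients.
#' The two are exact mutual inverses on the grid. The kernel is self-adjoint
#' and positive definite.
#'
#' @param field 4D array `[nx, ny, nz, 3]`.
#' @param spacing voxel spacing.
#' @param kp a [kernel_params()].
#' @return a field of the same shape.
#' @export
apply_kernel <- function(field, spacing, kp = kernel_params()) {
  if (any(!is.finite(field))) stop("apply_kernel: non-finite field")
  lhat <- kernel_lhat(dim(field)[1:3], spacing, kp)
  apply_multiplier(field, 1 / lhat^2)
}

#' @rdname apply_kernel
#' @export
apply_operator <- function(field, spacing, kp = kernel_params()) {
  if (any(!is.finite(field))) stop("apply_operator: non-finite field")
  lhat <- kernel_lhat(dim(field)[1:3], spacing, kp)
  apply_multiplier(field, lhat^2)
}
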