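# Shared fixtures, all generated in code at test time.

# Smooth compactly supported 2D bump (zero near the frame so resampling
# boundaries do not contaminate gradients).
bump2d <- function(nx = 20, ny = 18, cx = (nx + 1) / 2, cy = (ny + 1) / 2,
                   s = nx / 3) {
  r2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`)
  w <- pmax(1 - r2 / s^2, 0)
  w^2
}

# Disk with a smoothstep edge of width w (soft anti-aliasing keeps the
# resampling error of a rotation small).
disk2d <- function(nx, r, w = 5, cx = (nx + 1) / 2, cy = (nx + 1) / 2) {
  d <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(nx) - cy)^2, `+`))
  u <- pmin(pmax((r + w / 2 - d) / w, 0), 1)
  u * u * (3 - 2 * u)
}

# Separable 3D Gaussian blob volume.
blob3d <- function(dm, ctr = (dm + 1) / 2, s = 14, spacing = c(1, 1, 1)) {
  a <- outer(exp(-(seq_len(dm[1]) - ctr[1])^2 / s),
             exp(-(seq_len(dm[2]) - ctr[2])^2 / s))
  volume3d(outer(a, exp(-(seq_len(dm[3]) - ctr[3])^2 / s)), spacing = spacing)
}

# A z-smooth stack of drifting bumps: intensity varies smoothly along z.
smooth_stack <- function(nx = 24, ny = 22, n = 8, spacing = c(1, 1), dz = 1) {
  sections <- lapply(seq_len(n), function(k)
    bump2d(nx, ny, s = nx / 3) * (0.3 + 0.6 * k / n))
  section_stack(sections, z_positions = (seq_len(n) - 1) * dz,
                in_plane_spacing = spacing)
}

# Smooth random velocity field: kernel-smoothed white noise, unit max norm.
smooth_velocity <- function(dm, n_t, spacing = c(1, 1, 1), scale = 0.2,
                            seed = 1) {
  set.seed(seed)
  kp <- kernel_params(0.2)
  fields <- lapply(seq_len(n_t), function(k) {
    f <- apply_kernel(array(rnorm(prod(dm) * 3), c(dm, 3L)), spacing, kp)
    f / max(abs(f)) * scale
  })
  tv_velocity(fields)
}

# Joint-estimation fixture at the 40 micrometre working scale.
scale40 <- 40
cfg40 <- function(...) {
  joint_config(prior = rigid_prior(sigma_c = 7 * scale40), ...)
}
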