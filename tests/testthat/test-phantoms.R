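test_that("cylinder phantoms follow their specified geometry", {
  # zero curvature: every slab identical
  st <- make_phantom(phantom_spec(shape = c(24, 24, 8),
                                  kind = "straight_cylinder", radius = 6))
  for (k in 2:8) expect_identical(st$values[, , k], st$values[, , 1])
  # curved phantom: slab centroids on the specified parabola within 0.5 vox
  spec <- phantom_spec(shape = c(48, 40, 20), kind = "curved_cylinder",
                       curvature = 6, radius = 7)
  ph <- make_phantom(spec)
  cen <- centroid_axis(ph)$centroids
  cx <- (48 + 1) / 2
  for (r in seq_len(nrow(cen))) {
    k <- cen$slab[r]
    u <- 2 * (k - 1) / 19 - 1
    expect_lt(abs(cen$x[r] - (cx + 6 * (1 - u^2))), 0.5)
  }
  # voxel count of the binary cylinder within 5% of n pi r^2
  bin <- make_phantom(phantom_spec(shape = c(32, 32, 10),
                                   kind = "straight_cylinder", radius = 8,
                                   anti_alias = FALSE))
  expect_lt(abs(sum(bin$values) - 10 * pi * 64) / (10 * pi * 64), 0.05)
  expect_error(make_phantom(phantom_spec(shape = c(20, 20, 6),
                                         kind = "curved_cylinder",
                                         curvature = 8, radius = 6)),
               "exceeds")
  # brain-like phantom is deterministic given its seed
  b1 <- make_phantom(phantom_spec(shape = c(20, 18, 8), kind = "brainlike",
                                  radius = 5, seed = 11))
  b2 <- make_phantom(phantom_spec(shape = c(20, 18, 8), kind = "brainlike",
                                  radius = 5, seed = 11))
  expect_identical(b1$values, b2$values)
})

test_that("sectioning: clean limit, inverse consistency, noise level", {
  # a wide smoothstep edge keeps the double-resampling (jitter + restore)
  # interpolation error within the stated bound
  ph <- make_phantom(phantom_spec(shape = c(40, 36, 10),
                                  kind = "curved_cylinder", curvature = 4,
                                  radius = 7, edge_width = 6))
  # zero jitter, zero noise: sections equal slabs, truth is the identity
  sim0 <- section_phantom(ph, sectioning_spec(0, 0, 0, seed = 1))
  for (k in c(1, 5, 10)) {
    expect_equal(sim0$stack$sections[[k]], ph$values[, , k])
    expect_equal(sim0$truth[[k]], rigid_motion(0, 0, 0))
  }
  # restacking with the returned truth restores the slabs on the interior
  sim <- section_phantom(ph, sectioning_spec(t_sigma = 2, theta_sigma_deg = 5,
                                             seed = 2))
  interior <- 10:30
  for (k in c(2, 7)) {
    rec <- apply_rigid(sim$stack$sections[[k]], sim$truth[[k]],
                       sim$stack$in_plane_spacing,
                       mask = sim$stack$data_masks[[k]])
    err <- abs(rec$values - ph$values[, , k])[interior, 10:27]
    expect_lt(max(err), 0.05)
  }
  # the draw is bit-reproducible given the seed, and seeds differ
  sim2 <- section_phantom(ph, sectioning_spec(t_sigma = 2, theta_sigma_deg = 5,
                                              seed = 2))
  expect_identical(sim$stack$sections, sim2$stack$sections)
  expect_identical(sim$truth, sim2$truth)
  sim3 <- section_phantom(ph, sectioning_spec(t_sigma = 2, theta_sigma_deg = 5,
                                              seed = 3))
  expect_false(identical(sim$truth, sim3$truth))
  # additive noise has the requested standard deviation (within 2%)
  simn <- section_phantom(ph, sectioning_spec(0, 0, noise_sigma = 0.5,
                                              seed = 4))
  resid <- unlist(lapply(1:10, function(k)
    simn$stack$sections[[k]] - ph$values[, , k]))
  expect_lt(abs(sd(resid) - 0.5) / 0.5, 0.02)
})

test_that("cumulative shear offsets sections while truth keeps jitter only", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 8),
                                  kind = "straight_cylinder", radius = 8))
  sim <- section_phantom(ph, sectioning_spec(0, 0, 0,
                                             shear_per_section = c(0.25, 0.25),
                                             seed = 1))
  expect_equal(sim$truth[[8]], rigid_motion(0, 0, 0))
  # section k is offset by (k-1) * 0.25 px: centroid drifts linearly
  cen <- centroid_axis(stack_to_volume(sim$stack))$centroids
  drift <- cen$x[8] - cen$x[1]
  expect_equal(drift, 7 * 0.25, tolerance = 0.1)
})

test_that("the straightened curved stack has lower z-energy than the truth", {
  # the quantitative heart of the curvature non-identifiability: aligning
  # the disks into a straight cylinder scores better smoothness than the
  # true curved stacking
  spec <- phantom_spec(shape = c(48, 40, 20), kind = "curved_cylinder",
                       curvature = 6, radius = 7)
  ph <- make_phantom(spec)
  straight <- make_phantom(phantom_spec(shape = c(48, 40, 20),
                                        kind = "straight_cylinder",
                                        radius = 7))
  expect_lt(stack_smoothness_energy(straight), stack_smoothness_energy(ph))
})

test_that("random diffeomorphisms: determinism, amplitude, invertibility", {
  dm <- c(16, 16, 12)
  kp <- kernel_params(0.15)
  # amplitude zero: identity
  d0 <- random_diffeomorphism(dm, kp, amplitude = 0, seed = 1)
  g <- stackmorph:::world_grid(dm, c(1, 1, 1), c(0, 0, 0))
  expect_equal(d0$diffeo$phi, g)
  # same seed: identical; different seeds: different
  d1 <- random_diffeomorphism(dm, kp, amplitude = 1.2, seed = 5)
  d1b <- random_diffeomorphism(dm, kp, amplitude = 1.2, seed = 5)
  expect_identical(d1$diffeo$phi, d1b$diffeo$phi)
  d2 <- random_diffeomorphism(dm, kp, amplitude = 1.2, seed = 6)
  expect_gt(max(abs(d1$diffeo$phi - d2$diffeo$phi)), 0.1)
  # maximum displacement within 10% of the request
  disp <- max(abs(d1$diffeo$phi - g))
  expect_lt(abs(disp - 1.2) / 1.2, 0.1)
  expect_true(all(d1$diffeo$jacobian_det > 0))
})
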