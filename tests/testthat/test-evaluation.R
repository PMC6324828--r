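test_that("replicate statistics: algebraic identity and null baselines", {
  ph <- make_phantom(phantom_spec(shape = c(32, 30, 6),
                                  kind = "straight_cylinder",
                                  radius = c(9, 6)), spacing = rep(40, 3))
  ss <- sectioning_spec(t_sigma = 3 * 40, theta_sigma_deg = 6,
                        noise_sigma = 0)
  # the identity "estimator" returns the prior means: its RMSE equals the
  # jitter distribution's RMS within sampling error
  ident <- function(stack, atlas, cfg)
    lapply(stack$sections, function(s) rigid_motion(0, 0, 0))
  st <- run_replicates(ph, ss, ident, n_reps = 40, base_seed = 7)
  n <- st$stats$n[1]
  for (p in c("tx", "ty")) {
    r <- st$stats$rmse[st$stats$param == p]
    expect_lt(abs(r - 3), 3 * 3 / sqrt(2 * n))
  }
  r_th <- st$stats$rmse[st$stats$param == "theta"]
  expect_lt(abs(r_th - 6 * pi / 180), 3 * (6 * pi / 180) / sqrt(2 * n))
  # rmse^2 = bias^2 + sd^2 to within 1e-10 (pooled population moments)
  for (k in seq_len(nrow(st$stats)))
    expect_lt(abs(st$stats$rmse[k]^2 - st$stats$bias[k]^2 - st$stats$sd[k]^2),
              1e-10)
  # bit-reproducible given the base seed
  st2 <- run_replicates(ph, ss, ident, n_reps = 40, base_seed = 7)
  expect_identical(st$stats, st2$stats)
  expect_identical(st$errors, st2$errors)
})

test_that("no-op recovery: zero jitter and noise gives near-zero errors", {
  ph <- make_phantom(phantom_spec(shape = c(32, 30, 6),
                                  kind = "straight_cylinder",
                                  radius = c(9, 6)), spacing = rep(40, 3))
  ss <- sectioning_spec(t_sigma = 0, theta_sigma_deg = 0, noise_sigma = 0)
  cfg <- cfg40(lddmm_iters = 0, rigid_sweeps = 5, outer_iters = 1)
  st <- run_replicates(ph, ss, "atlas_informed", n_reps = 2, base_seed = 1,
                       cfg = cfg)
  expect_lt(max(abs(st$stats$bias)), 1e-6)
  expect_lt(max(st$stats$rmse[st$stats$param %in% c("tx", "ty")]), 0.1)
})

test_that("failed replicates are counted and bounded", {
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 4),
                                  kind = "straight_cylinder", radius = 6),
                     spacing = rep(40, 3))
  ss <- sectioning_spec(0, 0, 0)
  boom <- function(stack, atlas, cfg) stop("nope")
  expect_error(run_replicates(ph, ss, boom, n_reps = 4, base_seed = 1),
               "failed")
})

test_that("centroid axis summarises straight and curved stacks", {
  straight <- make_phantom(phantom_spec(shape = c(32, 30, 12),
                                        kind = "straight_cylinder",
                                        radius = 7))
  ca <- centroid_axis(straight)
  expect_lt(ca$max_deflection, 0.1)
  curved <- make_phantom(phantom_spec(shape = c(48, 40, 20),
                                      kind = "curved_cylinder",
                                      curvature = 6, radius = 7))
  cc_ <- centroid_axis(curved)
  expect_lt(abs(cc_$max_deflection - 6) / 6, 0.1)
  # polyline inequality
  expect_gte(cc_$curve_length, cc_$chord_length)
  expect_gte(ca$curve_length, ca$chord_length)
  # empty slabs are skipped and flagged
  v <- curved
  v$values[, , 3] <- 0
  expect_equal(centroid_axis(v)$skipped, 3L)
  expect_error(centroid_axis(volume3d(array(0, c(4, 4, 4)))), "empty")
})

test_that("warped-grid rendering: identity, translation, line survival", {
  dm <- c(24, 24, 8)
  # identity: lines at exactly the requested spacing
  d0 <- random_diffeomorphism(dm, amplitude = 0, seed = 1)
  img <- export_warped_grid(d0$diffeo, axis = 3, index = 4, line_spacing = 4)
  expect_equal(img[2, ], ((0:23) %% 4 == 0) + 0)
  expect_equal(img[, 1], rep(1, 24))
  # pure translation: the same grid shifted by the offset
  v <- zero_velocity(dm, 3)
  for (k in 1:3) v$fields[[k]][, , , 1] <- -2   # phi_inv shifts +2 along x
  dp <- integrate_flow(v)
  img2 <- export_warped_grid(dp, axis = 3, index = 4, line_spacing = 4)
  expect_equal(img2[1:22, 2], img[3:24, 2], tolerance = 1e-6)
  # a Jacobian-bounded warp preserves the number of grid lines crossed
  dr <- random_diffeomorphism(dm, kernel_params(0.25), amplitude = 0.5,
                              seed = 3)
  img3 <- export_warped_grid(dr$diffeo, axis = 3, index = 4, line_spacing = 6)
  crossings <- function(row) sum(diff(row > 0.5) == 1) + (row[1] > 0.5)
  expect_equal(crossings(img3[, 12]), crossings(((0:23) %% 6 == 0) + 0))
})

test_that("estimator statistics export to the CSV layout", {
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 4),
                                  kind = "straight_cylinder", radius = 6),
                     spacing = rep(40, 3))
  ss <- sectioning_spec(t_sigma = 40, theta_sigma_deg = 2, noise_sigma = 0.1)
  ident <- function(stack, atlas, cfg)
    lapply(stack$sections, function(s) rigid_motion(0, 0, 0))
  st <- run_replicates(ph, ss, ident, n_reps = 3, base_seed = 2)
  f <- tempfile(fileext = ".csv")
  write_stats_csv(st, f)
  df <- read.csv(f)
  expect_named(df, c("noise_level", "param", "bias", "std", "rmse", "n"))
  expect_equal(nrow(df), 3)
})
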