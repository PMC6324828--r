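# Small, fast fixtures; the full-scale simulation studies live in
# test-acceptance.R.

joint_fixture <- function(n = 6, noise = 0, jitter_t = 0, jitter_th = 0,
                          seed = 1) {
  ps <- phantom_spec(shape = c(28, 26, n), kind = "brainlike", radius = 6,
                     seed = 2)
  ph <- make_phantom(ps, spacing = c(scale40, scale40, scale40))
  ss <- sectioning_spec(t_sigma = jitter_t * scale40,
                        theta_sigma_deg = jitter_th,
                        noise_sigma = noise, seed = seed)
  c(section_phantom(ph, ss), list(phantom = ph))
}

test_that("joint objective: compositional oracle and weight linearity", {
  fx <- joint_fixture(jitter_t = 1, jitter_th = 3)
  cfg <- cfg40()
  motions <- fx$truth
  obj <- joint_objective(fx$stack, motions, fx$phantom, cfg)
  # independent recomputation from the public module operations
  sp2 <- fx$stack$in_plane_spacing
  rsvol <- stack_to_volume(section_stack(
    lapply(seq_along(motions), function(i)
      apply_rigid(fx$stack$sections[[i]], motions[[i]], sp2,
                  fx$stack$data_masks[[i]])$values),
    z_positions = fx$stack$z_positions, in_plane_spacing = sp2))
  masks <- lapply(seq_along(motions), function(i)
    apply_rigid(fx$stack$sections[[i]], motions[[i]], sp2,
                fx$stack$data_masks[[i]])$mask)
  sob <- stack_smoothness_energy(rsvol, masks,
                                 sobolev_config(weight = cfg$w_sobolev))
  pri <- -cfg$w_prior * sum(vapply(motions, rigid_log_prior, 0,
                                   prior = cfg$prior))
  mat <- cfg$w_match * sum(vapply(seq_along(motions), function(i) {
    ad <- apply_rigid(fx$phantom$values[, , i], rigid_invert(motions[[i]]),
                      sp2)
    prod(sp2) * sum(fx$stack$data_masks[[i]] *
                    (fx$stack$sections[[i]] - ad$values)^2)
  }, 0))
  expect_equal(obj$total, sob + pri + mat, tolerance = 1e-10)
  # doubling w_match doubles the matching term and nothing else
  cfg2 <- cfg40(w_match = 2)
  obj2 <- joint_objective(fx$stack, motions, fx$phantom, cfg2)
  expect_equal(obj2$match, 2 * obj$match, tolerance = 1e-12)
  expect_equal(obj2$sobolev, obj$sobolev)
  expect_equal(obj2$prior, obj$prior)
  expect_error(joint_objective(fx$stack, motions,
                               blob3d(c(8, 8, 8)), cfg), "grid")
})

test_that("rigid gradients match central finite differences", {
  # zero generation jitter keeps the data masks full, so the objective is
  # smooth in the motions over the FD step
  fx <- joint_fixture(seed = 3)
  cfg <- cfg40(w_prior = 0.01)
  motions <- lapply(1:6, function(i)
    rigid_motion(0.04 * (-1)^i, 12 * sin(i), -9 * cos(i)))
  h <- 1e-3
  for (i in c(1, 4, 6)) {
    g <- rigid_gradient(fx$stack, motions, fx$phantom, cfg, i)
    pars <- c(motions[[i]]$theta, motions[[i]]$tx, motions[[i]]$ty)
    for (p2 in 1:3) {
      hp <- if (p2 == 1) 1e-6 else h
      pp <- pars; pp[p2] <- pp[p2] + hp
      pm <- pars; pm[p2] <- pm[p2] - hp
      mp <- motions; mp[[i]] <- rigid_motion(pp[1], pp[2], pp[3])
      mm <- motions; mm[[i]] <- rigid_motion(pm[1], pm[2], pm[3])
      fd <- (joint_objective(fx$stack, mp, fx$phantom, cfg)$total -
             joint_objective(fx$stack, mm, fx$phantom, cfg)$total) / (2 * hp)
      expect_lt(abs(fd - g[p2]) / max(abs(fd), 1e-8), 1e-3)
    }
  }
})

test_that("with coupling off, the gradient reduces to one isolated section", {
  fx <- joint_fixture(seed = 4)
  i <- 3
  w <- rep(0, 6); w[i] <- 1
  st <- section_stack(fx$stack$sections, z_positions = fx$stack$z_positions,
                      in_plane_spacing = fx$stack$in_plane_spacing,
                      weights = w, data_masks = fx$stack$data_masks)
  cfg <- cfg40(w_sobolev = 0, w_prior = 0)
  motions <- lapply(1:6, function(j) rigid_motion(0.02, 5, -4))
  g <- rigid_gradient(st, motions, fx$phantom, cfg, i)
  # isolated oracle: finite differences of the single-section match term
  sp2 <- st$in_plane_spacing
  match_i <- function(m) {
    ad <- apply_rigid(fx$phantom$values[, , i], rigid_invert(m), sp2)
    prod(sp2) * sum(st$data_masks[[i]] * (st$sections[[i]] - ad$values)^2)
  }
  pars <- c(0.02, 5, -4)
  for (p2 in 1:3) {
    hp <- if (p2 == 1) 1e-6 else 1e-3
    pp <- pars; pp[p2] <- pp[p2] + hp
    pm <- pars; pm[p2] <- pm[p2] - hp
    fd <- (match_i(rigid_motion(pp[1], pp[2], pp[3])) -
           match_i(rigid_motion(pm[1], pm[2], pm[3]))) / (2 * hp)
    expect_lt(abs(fd - g[p2]) / max(abs(fd), 1e-8), 1e-3)
  }
  # and perturbing another section's parameters changes nothing
  motions2 <- motions; motions2[[5]] <- rigid_motion(-0.3, 30, 2)
  g2 <- rigid_gradient(st, motions2, fx$phantom, cfg, i)
  expect_equal(g, g2)
})

test_that("a z-constant stack at the prior means is a stationary point", {
  sections <- lapply(1:5, function(k) bump2d(24, 24, s = 8))
  st <- section_stack(sections, in_plane_spacing = c(scale40, scale40),
                      z_positions = (0:4) * scale40)
  atl <- stack_to_volume(st)
  cfg <- cfg40()
  motions <- lapply(1:5, function(i) rigid_motion(0, 0, 0))
  for (i in c(1, 3)) {
    g <- rigid_gradient(st, motions, atl, cfg, i)
    expect_lt(max(abs(g[2:3])) / scale40, 1e-6)   # translations, in pixels
    expect_lt(abs(g[1]), 1e-6)
  }
})

test_that("atlas-free restacking starts clean and reduces jitter roughness", {
  # already-smooth stack at the prior means: motions stay at the identity
  sections <- lapply(1:5, function(k) bump2d(24, 24, s = 8) * (0.5 + 0.05 * k))
  st <- section_stack(sections, in_plane_spacing = c(scale40, scale40),
                      z_positions = (0:4) * scale40)
  cfg <- cfg40()
  af0 <- restack_atlas_free(st, cfg, max_sweeps = 20)
  expect_lt(max(vapply(af0$rigid_motions,
                       function(r) max(abs(c(r$tx, r$ty))), 0)) / scale40, 0.1)
  expect_lt(max(vapply(af0$rigid_motions,
                       function(r) abs(r$theta), 0)) * 180 / pi, 0.1)
  # jittered smooth cylinder: recovered motions cut the roughness to < 10%
  ps <- phantom_spec(shape = c(32, 30, 10), kind = "straight_cylinder",
                     radius = 8)
  ph <- make_phantom(ps, spacing = rep(scale40, 3))
  sim <- section_phantom(ph, sectioning_spec(t_sigma = 2 * scale40,
                                             theta_sigma_deg = 4, seed = 5))
  e_jit <- stack_smoothness_energy(stack_to_volume(sim$stack))
  af <- restack_atlas_free(sim$stack, cfg, max_sweeps = 120)
  e_rec <- stack_smoothness_energy(af$reconstructed,
                                   af$masks)
  expect_lt(e_rec, 0.1 * e_jit)
  expect_true(all(diff(af$objective_trace$total) <= 1e-10))
})

test_that("the matching-weight limit reproduces atlas-free updates exactly", {
  fx <- joint_fixture(jitter_t = 1.5, jitter_th = 4, seed = 6)
  cfg <- cfg40(w_match = 0, lddmm_iters = 0, rigid_sweeps = 25,
               outer_iters = 1, tol = 1e-9)
  joint <- estimate_joint(fx$stack, fx$phantom, cfg)
  free <- restack_atlas_free(fx$stack, cfg, max_sweeps = 25)
  expect_equal(joint$rigid_motions, free$rigid_motions, tolerance = 1e-14)
})

test_that("the joint estimator fixes the perfect-data fixed point", {
  fx <- joint_fixture()
  cfg <- cfg40(n_t = 3, lddmm_iters = 5, rigid_sweeps = 8, outer_iters = 2)
  est <- estimate_joint(fx$stack, fx$phantom, cfg)
  expect_lt(max(vapply(est$rigid_motions,
                       function(r) max(abs(c(r$tx, r$ty))), 0)) / scale40, 0.1)
  expect_lt(max(vapply(est$rigid_motions,
                       function(r) abs(r$theta), 0)) * 180 / pi, 0.1)
  expect_lt(path_energy(est$velocity, rep(scale40, 3), cfg$kernel), 1e-8)
  expect_true(all(diff(est$objective_trace$total) <= 1e-8))
  expect_true(all(est$diffeo$jacobian_det > 0))
})

test_that("label transfer: identity passthrough, translation, set inclusion", {
  fx <- joint_fixture()
  labels <- volume3d(array(sample(0:4, 28 * 26 * 6, TRUE), c(28, 26, 6)),
                     spacing = rep(scale40, 3))
  cfg <- cfg40(lddmm_iters = 0, rigid_sweeps = 0, outer_iters = 1)
  est <- estimate_joint(fx$stack, fx$phantom, cfg)
  est$diffeo <- NULL   # atlas-free style estimate: identity transfer
  out <- transfer_labels(labels, est)
  expect_equal(stack_to_volume(out)$values, labels$values)
  # pure-translation diffeomorphism moves labels by the same offset
  v <- zero_velocity(c(28, 26, 6), 3)
  for (k in 1:3) v$fields[[k]][, , , 1] <- scale40  # one voxel along x
  est$diffeo <- integrate_flow(v, rep(scale40, 3))
  out2 <- stack_to_volume(transfer_labels(labels, est))
  expect_equal(out2$values[5:28, , ], labels$values[4:27, , ])
  expect_true(all(out2$values %in% labels$values))
  expect_error(transfer_labels(volume3d(labels$values + 0.5,
                                        spacing = rep(scale40, 3)), est),
               "integer")
})

test_that("the two-channel (tissue-mask) variant runs and stays valid", {
  set.seed(9)
  ps <- phantom_spec(shape = c(24, 22, 6), kind = "straight_cylinder",
                     radius = 7)
  ph <- make_phantom(ps, spacing = rep(scale40, 3))
  sim <- section_phantom(ph, sectioning_spec(t_sigma = scale40,
                                             theta_sigma_deg = 3, seed = 9))
  cfg <- cfg40(n_t = 3, lddmm_iters = 3, rigid_sweeps = 5, outer_iters = 2,
               use_mask_channel = TRUE)
  est <- estimate_joint(sim$stack, ph, cfg)
  expect_s3_class(est, "joint_estimate")
  expect_true(all(est$diffeo$jacobian_det > 0))
  expect_lt(max(vapply(est$rigid_motions,
                       function(r) max(abs(c(r$tx, r$ty))), 0)) / scale40, 3)
})
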