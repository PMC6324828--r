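# The joint MAP / penalized-likelihood estimator: one objective
#   E(R, v) = metric(v) + w_sobolev * SobolevEnergy(I^R)
#           + w_prior * sum_i -log pi(R_i)
#           + w_match * sum_i alpha_i || masked (I^R - I_0 o phi_inv)(. , z_i) ||_2^2
# minimized by alternating LDDMM updates of v (rigid motions fixed) with
# simultaneous gradient sweeps over the per-section rigid motions (flow
# fixed). Dropping the atlas (w_match = 0) leaves the atlas-free MAP
# restacking driven by the smoothness prior alone. Both sub-steps accept
# only decreases of the same objective, so the outer trace is monotone.

#' Configuration of the joint estimator
#'
#' Defaults are the hyper-parameters used for 20-micrometre mouse histology:
#' matching 1.0, rigid prior 0.001 and Sobolev 1.0 weights on the rigid
#' objective; prior variances pi/9 (rotation) and 7.0 (translation); LDDMM
#' matching 0.4 against regularization 1.0; kernel-scale cascade
#' 0.05, 0.02, 0.01 in normalized image-width units. Iteration budgets and
#' the convergence tolerance are desk-scale choices, all overridable.
#'
#' @param w_match,w_prior,w_sobolev weights of the matching term, the rigid
#'   prior and the stack-smoothness energy in the rigid objective.
#' @param prior a [rigid_prior()].
#' @param lddmm_match,lddmm_reg relative weights of matching and
#'   regularization inside the LDDMM update; the joint objective's metric
#'   term carries `w_match * lddmm_reg / lddmm_match` so that both
#'   sub-problems descend one consistent objective.
#' @param kernel a [kernel_params()].
#' @param use_cascade continue the LDDMM update over the whole kernel
#'   cascade (default: single scale `kernel$length_scale`).
#' @param n_t time nodes of the velocity field.
#' @param lddmm_iters LDDMM gradient iterations per outer iteration.
#' @param rigid_sweeps rigid gradient sweeps per outer iteration.
#' @param outer_iters maximum outer alternations.
#' @param tol relative objective-change convergence criterion.
#' @param censored_in_prior do sections with weight 0 still participate in
#'   the smoothness term (the smoothness is a prior on the reconstruction,
#'   not part of the likelihood)?
#' @param sweep_mode `"jacobi"` (simultaneous update of all sections with a
#'   shared backtracking step) or `"gauss_seidel"` (in-order updates).
#' @param use_mask_channel add an estimated tissue-mask channel to the
#'   LDDMM matching (the two-channel variant used on real histology). The
#'   monitored joint objective then tracks the intensity channel only.
#' @param snapshot_every if positive, store the reconstructed volume every
#'   this many outer iterations (debug/figures).
#' @return an object of class `joint_config`.
#' @export
joint_config <- function(w_match = 1.0, w_prior = 0.001, w_sobolev = 1.0,
                         prior = rigid_prior(),
                         lddmm_match = 0.4, lddmm_reg = 1.0,
                         kernel = kernel_params(), use_cascade = FALSE,
                         n_t = 10L, lddmm_iters = 50L, rigid_sweeps = 20L,
                         outer_iters = 20L, tol = 1e-4,
                         censored_in_prior = TRUE,
                         sweep_mode = c("jacobi", "gauss_seidel"),
                         use_mask_channel = FALSE, snapshot_every = 0L) {
  if (any(c(w_match, w_prior, w_sobolev, lddmm_match, lddmm_reg) < 0))
    stop("joint_config: weights must be nonnegative")
  if (tol <= 0) stop("joint_config: tol must be positive")
  structure(list(w_match = w_match, w_prior = w_prior, w_sobolev = w_sobolev,
                 prior = prior, lddmm_match = lddmm_match,
                 lddmm_reg = lddmm_reg, kernel = kernel,
                 use_cascade = use_cascade, n_t = as.integer(n_t),
                 lddmm_iters = as.integer(lddmm_iters),
                 rigid_sweeps = as.integer(rigid_sweeps),
                 outer_iters = as.integer(outer_iters), tol = tol,
                 censored_in_prior = censored_in_prior,
                 sweep_mode = match.arg(sweep_mode),
                 use_mask_channel = use_mask_channel,
                 snapshot_every = as.integer(snapshot_every)),
            class = "joint_config")
}

# Restack: apply each motion to its section, returning the reconstructed
# volume, transported masks, and optionally per-section gradients.
restack <- function(stack, motions, with_gradient = FALSE) {
  n <- length(stack$sections)
  stopifnot(length(motions) == n)
  out <- lapply(seq_len(n), function(i)
    apply_rigid(stack$sections[[i]], motions[[i]], stack$in_plane_spacing,
                mask = stack$data_masks[[i]], with_gradient = with_gradient))
  dm <- dim(stack$sections[[1]])
  vol <- volume3d(array(unlist(lapply(out, `[[`, "values"), use.names = FALSE),
                        c(dm, n)),
                  spacing = c(stack$in_plane_spacing,
                              diff(stack$z_positions[1:2])),
                  origin = c(0, 0, stack$z_positions[1]))
  list(volume = vol, masks = lapply(out, `[[`, "mask"), resampled = out)
}

# Sobolev masks honouring the censoring switch: with censored_in_prior the
# smoothness term sees every section's data mask; without it, censored
# sections are removed from the prior by zeroing their mask.
sobolev_masks <- function(masks, weights, cfg) {
  if (cfg$censored_in_prior) return(masks)
  lapply(seq_along(masks),
         function(i) if (weights[i] > 0) masks[[i]] else masks[[i]] * 0)
}

#' The joint restacking objective
#'
#' Evaluates the minimization form of the joint MAP / penalized-likelihood
#' objective at given motions: `metric` (supplied by the caller, constant
#' in `R`) plus the weighted Sobolev stack-smoothness energy, the negated
#' log-priors of the motions, and the per-section masked matching term
#' against the deformed atlas. Each term is reported separately.
#'
#' @param stack a [section_stack()].
#' @param motions list of [rigid_motion()], one per section.
#' @param atlas_deformed a [volume3d()] on the stack grid (the deformed
#'   atlas `I_0 o phi_inv`), or `NULL` for the atlas-free objective.
#' @param cfg a [joint_config()].
#' @param metric value of the metric term to carry into the total.
#' @return list with `total`, `metric`, `sobolev`, `prior`, `match`.
#' @export
joint_objective <- function(stack, motions, atlas_deformed = NULL,
                            cfg = joint_config(), metric = 0) {
  rs <- restack(stack, motions)
  joint_objective_terms(stack, rs, motions, atlas_deformed, cfg, metric)
}

# The matching term is evaluated in each observed section's own frame:
# || J_i - (deformed atlas)(R_i^-1 . , z_i) ||^2 (a rigid change of
# variables with unit Jacobian from the restacked form). Only the smooth
# atlas is interpolated, never the noisy data, so the interpolated-noise
# energy is constant in R and cannot carve spurious fractional-offset
# minima into the objective. The atlas is taken as zero outside its frame.
joint_objective_terms <- function(stack, rs, motions, atlas_deformed, cfg,
                                  metric = 0) {
  if (!is.null(atlas_deformed) &&
      !identical(dim(atlas_deformed$values), dim(rs$volume$values)))
    stop("joint_objective: atlas grid does not match the stack grid")
  sob <- stack_smoothness_energy(
    rs$volume, sobolev_masks(rs$masks, stack$weights, cfg),
    sobolev_config(weight = cfg$w_sobolev))
  pri <- -sum(vapply(motions, rigid_log_prior, 0, prior = cfg$prior)) *
    cfg$w_prior
  mat <- 0
  if (!is.null(atlas_deformed) && cfg$w_match > 0) {
    area <- prod(stack$in_plane_spacing)
    for (i in seq_along(motions)) {
      a <- stack$weights[i]
      if (a == 0) next
      ad <- apply_rigid(atlas_deformed$values[, , i],
                        rigid_invert(motions[[i]]),
                        stack$in_plane_spacing)
      r <- stack$sections[[i]] - ad$values
      mat <- mat + a * area * sum(stack$data_masks[[i]] * r^2)
    }
    mat <- cfg$w_match * mat
  }
  list(total = metric + sob + pri + mat, metric = metric,
       sobolev = sob, prior = pri, match = mat)
}

#' Analytic gradient of the joint objective for one section
#'
#' Chain rule through the resampling `J_i o R_i`: the image-space gradient
#' of the Sobolev and matching terms is pulled back through the spatial
#' intensity gradient of the resampled section and the motion's parameter
#' Jacobian (rotation acts on the centred coordinates, translations act as
#' unit shifts), and the prior gradient is added. The Sobolev term couples
#' the gradient to sections `i - 1` and `i + 1`, so registration is not
#' independent across sections. Matches central finite differences of
#' [joint_objective()] on smooth instances.
#'
#' @inheritParams joint_objective
#' @param i section index.
#' @return named numeric `(theta, tx, ty)`.
#' @export
rigid_gradient <- function(stack, motions, atlas_deformed = NULL,
                           cfg = joint_config(), i = 1L) {
  n <- length(stack$sections)
  if (i < 1L || i > n) stop("rigid_gradient: index out of range")
  rs <- restack(stack, motions, with_gradient = TRUE)
  rigid_gradient_from_state(stack, rs, motions, atlas_deformed, cfg, i)
}

rigid_gradient_from_state <- function(stack, rs, motions, atlas_deformed,
                                      cfg, i) {
  res <- rs$resampled[[i]]
  th <- motions[[i]]$theta
  ct <- cos(th); st <- sin(th)
  # Sobolev part: image-space gradient w.r.t. section i's resampled pixels,
  # pulled back through J_i o R_i
  G <- sobolev_gradient_section(
    rs$volume, i, sobolev_masks(rs$masks, stack$weights, cfg),
    sobolev_config(weight = cfg$w_sobolev))
  dq_dtheta_x <- -st * res$px + ct * res$py
  dq_dtheta_y <- -ct * res$px - st * res$py
  g_theta <- sum(G * (res$gx * dq_dtheta_x + res$gy * dq_dtheta_y))
  g_tx <- sum(G * res$gx)
  g_ty <- sum(G * res$gy)
  # matching part in the section frame: residual against the deformed atlas
  # pulled back through A_i o R_i^-1
  if (!is.null(atlas_deformed) && cfg$w_match > 0 && stack$weights[i] > 0) {
    sp2 <- stack$in_plane_spacing
    area <- prod(sp2)
    ad <- apply_rigid(atlas_deformed$values[, , i], rigid_invert(motions[[i]]),
                      sp2, with_gradient = TRUE)
    Gm <- 2 * cfg$w_match * stack$weights[i] * area *
      stack$data_masks[[i]] * (ad$values - stack$sections[[i]])
    # p = M(-theta) (y - t): sample position in atlas-slab coordinates
    ux <- ad$px - motions[[i]]$tx
    uy <- ad$py - motions[[i]]$ty
    p_x <- ct * ux - st * uy
    p_y <- st * ux + ct * uy
    g_theta <- g_theta + sum(Gm * (ad$gx * (-p_y) + ad$gy * p_x))
    g_tx <- g_tx + sum(Gm * (ad$gx * (-ct) + ad$gy * (-st)))
    g_ty <- g_ty + sum(Gm * (ad$gx * st + ad$gy * (-ct)))
  }
  g <- c(theta = g_theta, tx = g_tx, ty = g_ty)
  g - cfg$w_prior * rigid_log_prior_grad(motions[[i]], cfg$prior)
}

# One simultaneous (Jacobi) or in-order (Gauss-Seidel) sweep over all
# sections with a shared backtracking step. Rotation gradients are
# preconditioned by the mean squared radius of the section extent so the
# angular and translational steps move comparable distances. Returns the
# new state; only accepts decreases of the objective.
rigid_sweep <- function(stack, motions, atlas_deformed, cfg, obj, step) {
  n <- length(stack$sections)
  dm <- dim(stack$sections[[1]])
  cc <- section_centered_coords(dm, stack$in_plane_spacing)
  r2bar <- mean(cc$x^2) + mean(cc$y^2)
  rs <- restack(stack, motions, with_gradient = TRUE)
  grads <- vapply(seq_len(n), function(i)
    rigid_gradient_from_state(stack, rs, motions, atlas_deformed, cfg, i),
    numeric(3))
  grads[1, ] <- grads[1, ] / r2bar
  gmax <- max(abs(grads))
  if (gmax == 0)
    return(list(motions = motions, obj = obj, step = step, moved = FALSE))
  if (is.null(step)) step <- 0.5 * min(stack$in_plane_spacing) / gmax
  for (bt in seq_len(40L)) {
    prop <- lapply(seq_len(n), function(i)
      rigid_motion(motions[[i]]$theta - step * grads[1, i],
                   motions[[i]]$tx - step * grads[2, i],
                   motions[[i]]$ty - step * grads[3, i]))
    obj_try <- joint_objective(stack, prop, atlas_deformed, cfg, obj$metric)
    if (obj_try$total < obj$total)
      return(list(motions = prop, obj = obj_try, step = step * 1.5,
                  moved = TRUE))
    step <- step / 2
  }
  list(motions = motions, obj = obj, step = step, moved = FALSE)
}

rigid_sweep_gs <- function(stack, motions, atlas_deformed, cfg, obj, step) {
  n <- length(stack$sections)
  dm <- dim(stack$sections[[1]])
  cc <- section_centered_coords(dm, stack$in_plane_spacing)
  r2bar <- mean(cc$x^2) + mean(cc$y^2)
  if (is.null(step)) step <- 0.25 * min(stack$in_plane_spacing)
  moved <- FALSE
  for (i in seq_len(n)) {
    rs <- restack(stack, motions, with_gradient = TRUE)
    g <- rigid_gradient_from_state(stack, rs, motions, atlas_deformed, cfg, i)
    g[1] <- g[1] / r2bar
    gmax <- max(abs(g))
    if (gmax == 0) next
    st_i <- step / gmax
    for (bt in seq_len(20L)) {
      prop <- motions
      prop[[i]] <- rigid_motion(motions[[i]]$theta - st_i * g[1],
                                motions[[i]]$tx - st_i * g[2],
                                motions[[i]]$ty - st_i * g[3])
      obj_try <- joint_objective(stack, prop, atlas_deformed, cfg, obj$metric)
      if (obj_try$total < obj$total) {
        motions <- prop; obj <- obj_try; moved <- TRUE; break
      }
      st_i <- st_i / 2
    }
  }
  list(motions = motions, obj = obj, step = step, moved = moved)
}

run_rigid_sweeps <- function(stack, motions, atlas_deformed, cfg, obj,
                             n_sweeps, tol) {
  step <- NULL
  sweep_fn <- if (cfg$sweep_mode == "jacobi") rigid_sweep else rigid_sweep_gs
  trace <- numeric(0)
  for (s in seq_len(n_sweeps)) {
    prev <- obj$total
    res <- sweep_fn(stack, motions, atlas_deformed, cfg, obj, step)
    motions <- res$motions; obj <- res$obj; step <- res$step
    trace <- c(trace, obj$total)
    if (!res$moved) break
    if ((prev - obj$total) < tol * max(abs(prev), 1e-12)) break
  }
  list(motions = motions, obj = obj, trace = trace)
}

new_joint_estimate <- function(motions, v, diffeo, rs, trace, cfg) {
  structure(list(rigid_motions = motions, velocity = v, diffeo = diffeo,
                 reconstructed = rs$volume, masks = rs$masks,
                 objective_trace = trace, config = cfg),
            class = "joint_estimate")
}

#' @export
print.joint_estimate <- function(x, ...) {
  n <- length(x$rigid_motions)
  tmax <- max(vapply(x$rigid_motions, function(r) max(abs(c(r$tx, r$ty))), 0))
  thmax <- max(vapply(x$rigid_motions, function(r) abs(r$theta), 0))
  cat(sprintf("<joint_estimate> %d sections; max |t| = %.3g, max |theta| = %.3g rad; %s\n",
              n, tmax, thmax,
              if (is.null(x$velocity)) "atlas-free (no deformation)"
              else sprintf("velocity with %d time nodes", x$velocity$n_t)))
  if (nrow(x$objective_trace))
    cat(sprintf("  objective: %.6g -> %.6g in %d recorded steps\n",
                x$objective_trace$total[1],
                x$objective_trace$total[nrow(x$objective_trace)],
                nrow(x$objective_trace)))
  invisible(x)
}

#' Atlas-free MAP restacking
#'
#' Maximizes `sum_i (log pi(R_i) - 1/2 ||D_h I^R(. , z_i)||^2)`: rigid
#' restacking driven by the smoothness prior and the motion priors alone,
#' with no atlas. This is the limit of the joint estimator as the matching
#' weight vanishes. Simultaneous gradient sweeps with a shared backtracking
#' step; the returned objective trace is non-increasing.
#'
#' @param stack a [section_stack()].
#' @param cfg a [joint_config()]; `w_match` is ignored.
#' @param init optional initial motions (default: prior means).
#' @param max_sweeps sweep budget.
#' @return a `joint_estimate` with `velocity = NULL`.
#' @export
restack_atlas_free <- function(stack, cfg = joint_config(), init = NULL,
                               max_sweeps = 200L) {
  motions <- if (is.null(init)) init_motions(stack, cfg) else init
  obj <- joint_objective(stack, motions, NULL, cfg)
  res <- run_rigid_sweeps(stack, motions, NULL, cfg, obj, max_sweeps, cfg$tol)
  rs <- restack(stack, res$motions)
  trace <- data.frame(outer = seq_along(c(obj$total, res$trace)) - 1L,
                      total = c(obj$total, res$trace))
  new_joint_estimate(res$motions, NULL, NULL, rs, trace, cfg)
}

init_motions <- function(stack, cfg) {
  replicate(length(stack$sections),
            rigid_motion(0, cfg$prior$mu_c_x, cfg$prior$mu_c_y),
            simplify = FALSE)
}

# Resample the atlas once onto the stack grid (world-coordinate lookup);
# later deformed atlases compose the flow with this resampled volume so the
# original is interpolated only once more.
resample_atlas <- function(atlas, vol) {
  if (identical(dim(atlas$values), dim(vol$values)) &&
      isTRUE(all.equal(atlas$spacing, vol$spacing)) &&
      isTRUE(all.equal(atlas$origin, vol$origin))) return(atlas)
  warp_volume(atlas, world_grid(dim(vol$values), vol$spacing, vol$origin))
}

#' Joint MAP / penalized-likelihood estimation
#'
#' The alternating estimator: (a) an LDDMM update of the velocity field
#' with the rigid motions fixed, then (b) rigid-motion sweeps with the flow
#' fixed, repeated until the relative change of the joint objective falls
#' below `cfg$tol` or `cfg$outer_iters` is reached. Both sub-steps accept
#' only decreases of one consistent objective, so the outer trace is
#' non-increasing; a (numerically impossible) increase raises an error
#' carrying the trace.
#'
#' @param stack a [section_stack()].
#' @param atlas a [volume3d()]; resampled once onto the stack grid.
#' @param cfg a [joint_config()].
#' @param init optional initial motions (default prior means); pass the
#'   motions of an atlas-free estimate for a warm start.
#' @return a `joint_estimate`.
#' @export
estimate_joint <- function(stack, atlas, cfg = joint_config(), init = NULL) {
  stopifnot(inherits(stack, "section_stack"), inherits(atlas, "volume3d"))
  motions <- if (is.null(init)) init_motions(stack, cfg) else init
  rs <- restack(stack, motions)
  atlas0 <- resample_atlas(atlas, rs$volume)
  dm <- dim(rs$volume$values)
  sp <- rs$volume$spacing
  v <- zero_velocity(dm, cfg$n_t)
  reg_eff <- if (cfg$lddmm_match > 0)
    cfg$w_match * cfg$lddmm_reg / cfg$lddmm_match else 1.0
  atlas_channels <- function() {
    if (!cfg$use_mask_channel) return(list(atlas0))
    list(atlas0, estimate_tissue_mask(atlas0))
  }
  a_ch <- atlas_channels()
  deformed <- function(v) {
    w <- flow_warp_channels(lapply(a_ch, `[[`, "values"), v, sp)$images
    volume3d(w[[1]], spacing = sp, origin = rs$volume$origin)
  }
  metric_of <- function(v)
    0.5 * reg_eff * path_energy(v, sp, cfg$kernel) / (prod(dm) * prod(sp))
  atl_def <- deformed(v)
  obj <- joint_objective(stack, motions, atl_def, cfg, metric_of(v))
  trace <- list(data.frame(outer = 0L, metric = obj$metric,
                           sobolev = obj$sobolev, prior = obj$prior,
                           match = obj$match, total = obj$total))
  snapshots <- list()
  for (outer in seq_len(cfg$outer_iters)) {
    total_prev <- obj$total
    # (a) LDDMM with R fixed
    if (cfg$w_match > 0 && cfg$lddmm_iters > 0L) {
      tgt_ch <- if (cfg$use_mask_channel)
        list(rs$volume, volume3d((stack_masks_3d(rs) != 0) + 0,
                                 spacing = sp, origin = rs$volume$origin))
      else rs$volume
      fit <- lddmm_descent(
        a_ch, tgt_ch,
        v_init = v, kp = cfg$kernel,
        alpha = stack$weights, mask = stack_masks_3d(rs),
        reg_weight = reg_eff, match_weight = cfg$w_match,
        max_iters = cfg$lddmm_iters, use_cascade = cfg$use_cascade)
      # the inner step descends the stack-frame surrogate; accept its
      # velocity only if the canonical (section-frame) objective decreased
      atl_try <- deformed(fit$v)
      obj_try <- joint_objective(stack, motions, atl_try, cfg,
                                 metric_of(fit$v))
      if (obj_try$total < obj$total) {
        v <- fit$v; atl_def <- atl_try; obj <- obj_try
      }
    }
    # (b) rigid sweeps with phi fixed
    if (cfg$rigid_sweeps > 0L) {
      res <- run_rigid_sweeps(stack, motions, atl_def, cfg, obj,
                              cfg$rigid_sweeps, cfg$tol)
      motions <- res$motions; obj <- res$obj
      rs <- restack(stack, motions)
    }
    trace[[outer + 1L]] <- data.frame(outer = outer, metric = obj$metric,
                                      sobolev = obj$sobolev,
                                      prior = obj$prior, match = obj$match,
                                      total = obj$total)
    if (obj$total > total_prev + 1e-8 * max(abs(total_prev), 1)) {
      stop(paste0("estimate_joint: objective increased at outer iteration ",
                  outer, " (", total_prev, " -> ", obj$total, ")"))
    }
    if (cfg$snapshot_every > 0L && outer %% cfg$snapshot_every == 0L)
      snapshots[[length(snapshots) + 1L]] <- rs$volume
    if ((total_prev - obj$total) < cfg$tol * max(abs(total_prev), 1e-12))
      break
  }
  dp <- integrate_flow(v, sp, rs$volume$origin)
  est <- new_joint_estimate(motions, v, dp, rs, do.call(rbind, trace), cfg)
  if (length(snapshots)) est$snapshots <- snapshots
  est
}

stack_masks_3d <- function(rs) {
  dm <- dim(rs$volume$values)
  array(unlist(rs$masks, use.names = FALSE), dm)
}

#' Cast atlas labels onto the reconstructed sections
#'
#' Transfers an integer label volume from atlas coordinates through the
#' estimated diffeomorphism (`labels o phi_inv`, nearest-neighbour, so no
#' new label values can appear) and slices the result into a section stack
#' aligned with the reconstruction.
#'
#' @param labels a [volume3d()] of integer labels on the atlas grid.
#' @param estimate a `joint_estimate`.
#' @return a [section_stack()] of integer label sections.
#' @export
transfer_labels <- function(labels, estimate) {
  stopifnot(inherits(labels, "volume3d"), inherits(estimate, "joint_estimate"))
  if (max(abs(labels$values - round(labels$values))) > 0)
    stop("transfer_labels: labels must be an integer volume")
  vol <- if (is.null(estimate$diffeo)) {
    labels
  } else {
    warp_volume(labels, estimate$diffeo$phi_inv, method = "nearest")
  }
  volume_to_stack(vol)
}

#' Moment-based initial motions
#'
#' A robust starting point for heavily jittered stacks: each section is
#' lightly box-smoothed (suppressing intensity noise), thresholded, and its
#' intensity centroid and principal axis are matched to those of the
#' corresponding atlas section. The rotation is resolved modulo pi by
#' taking the representative nearest zero (jitter rotations are far from
#' 90 degrees), and the translation solves the centroid correspondence
#' under that rotation. Errors of a pixel or two remain for the gradient
#' sweeps to remove.
#'
#' @param stack a [section_stack()].
#' @param atlas a [volume3d()] on the stack grid.
#' @param threshold intensity threshold after smoothing (default half the
#'   atlas maximum).
#' @return list of [rigid_motion()], one per section.
#' @export
init_motions_moments <- function(stack, atlas, threshold = NULL) {
  dm <- dim(stack$sections[[1]])
  sp2 <- stack$in_plane_spacing
  if (is.null(threshold)) threshold <- 0.5 * max(atlas$values)
  cc <- section_centered_coords(dm, sp2)
  px <- matrix(rep(cc$x, times = dm[2]), dm[1], dm[2])
  py <- matrix(rep(cc$y, each = dm[1]), dm[1], dm[2])
  moments <- function(img) {
    w <- (box_smooth(img) >= threshold) + 0
    tot <- sum(w)
    if (tot < 9) return(NULL)
    cx <- sum(w * px) / tot; cy <- sum(w * py) / tot
    mxx <- sum(w * (px - cx)^2) / tot
    myy <- sum(w * (py - cy)^2) / tot
    mxy <- sum(w * (px - cx) * (py - cy)) / tot
    list(c = c(cx, cy), alpha = 0.5 * atan2(2 * mxy, mxx - myy),
         aniso = sqrt((mxx - myy)^2 + 4 * mxy^2) / (mxx + myy))
  }
  lapply(seq_along(stack$sections), function(i) {
    mj <- moments(stack$sections[[i]] * stack$data_masks[[i]])
    ma <- moments(atlas$values[, , i])
    if (is.null(mj) || is.null(ma)) return(rigid_motion(0, 0, 0))
    # J ~ A o R^-1: the section's axis is the atlas axis rotated by the
    # motion, and R maps section coordinates onto atlas coordinates
    th <- if (ma$aniso > 0.05 && mj$aniso > 0.05) {
      d <- (ma$alpha - mj$alpha) %% pi
      if (d > pi / 2) d - pi else d
    } else 0
    M <- rigid_matrix(th)
    t_ <- mj$c - as.vector(M %*% ma$c)
    rigid_motion(th, t_[1], t_[2])
  })
}

# 3x3 box smoothing with replicated edges.
box_smooth <- function(img) {
  n <- nrow(img); m <- ncol(img)
  xm <- img[c(1, 1:(n - 1)), ]; xp <- img[c(2:n, n), ]
  s <- xm + img + xp
  (s[, c(1, 1:(m - 1))] + s + s[, c(2:m, m)]) / 9
}
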