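# Estimator-statistics harness (bias / standard deviation / RMSE of the
# rigid-motion estimators over simulation replicates) and geometric
# diagnostics: centroid-axis curvature and warped-grid rendering.

#' Replicate study of the rigid-motion estimators
#'
#' For each replicate: section the phantom with a fresh jitter/noise draw
#' (replicate `r` uses seed `base_seed + r`), run the chosen estimator, and
#' record the per-section parameter errors (estimate minus truth, angles
#' wrapped). Translation errors are reported in pixels (physical error
#' divided by the in-plane pixel pitch); rotation errors in radians.
#' Errors are pooled over sections and replicates: bias is the
#' mean error, the standard deviation is the population standard deviation
#' of the errors, and RMSE the root mean squared error, so that
#' `rmse^2 = bias^2 + sd^2` exactly. Per-section summaries are also
#' returned. Failed replicates are recorded and excluded; more than 10%
#' failures aborts the run.
#'
#' @param phantom a [volume3d()] (sectioned afresh in every replicate).
#' @param sect_spec a [sectioning_spec()]; its seed field is overridden per
#'   replicate.
#' @param estimator `"atlas_free"`, `"atlas_informed"`, or a function
#'   `(stack, atlas, cfg)` returning a `joint_estimate` or a list of
#'   [rigid_motion()].
#' @param n_reps number of replicates (>= 2).
#' @param base_seed integer; replicate `r` uses `base_seed + r`.
#' @param cfg a [joint_config()].
#' @param atlas atlas for the informed estimator (default: the phantom
#'   itself, the usual simulation protocol).
#' @return an object of class `estimator_stats`: a list with `stats` (a
#'   data.frame `param, bias, sd, rmse, n`), `per_section`, `errors` (the
#'   raw per-replicate table), `n_failed`, `noise_level`, and `seeds`.
#' @export
run_replicates <- function(phantom, sect_spec, estimator = "atlas_free",
                           n_reps = 50L, base_seed = 1L,
                           cfg = joint_config(), atlas = NULL) {
  stopifnot(n_reps >= 2L)
  est_fun <- resolve_estimator(estimator)
  if (is.null(atlas)) atlas <- phantom
  rows <- list()
  n_failed <- 0L
  seeds <- base_seed + seq_len(n_reps)
  for (r in seq_len(n_reps)) {
    ss <- sect_spec; ss$seed <- seeds[r]
    sim <- section_phantom(phantom, ss)
    est <- tryCatch(est_fun(sim$stack, atlas, cfg), error = function(e) e)
    if (inherits(est, "error")) { n_failed <- n_failed + 1L; next }
    motions <- if (inherits(est, "joint_estimate")) est$rigid_motions else est
    sp2 <- sim$stack$in_plane_spacing
    for (i in seq_along(motions)) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, section = i,
        theta = wrap_angle(motions[[i]]$theta - sim$truth[[i]]$theta),
        tx = (motions[[i]]$tx - sim$truth[[i]]$tx) / sp2[1],
        ty = (motions[[i]]$ty - sim$truth[[i]]$ty) / sp2[2])
    }
  }
  if (n_failed > 0.1 * n_reps)
    stop(sprintf("run_replicates: %d of %d replicates failed", n_failed, n_reps))
  err <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(c("theta", "tx", "ty"), function(p) {
    e <- err[[p]]
    data.frame(param = p, bias = mean(e),
               sd = sqrt(mean((e - mean(e))^2)),
               rmse = sqrt(mean(e^2)), n = length(e))
  }))
  per_section <- do.call(rbind, lapply(sort(unique(err$section)), function(s) {
    do.call(rbind, lapply(c("theta", "tx", "ty"), function(p) {
      e <- err[[p]][err$section == s]
      data.frame(section = s, param = p, bias = mean(e),
                 sd = sqrt(mean((e - mean(e))^2)),
                 rmse = sqrt(mean(e^2)), n = length(e))
    }))
  }))
  structure(list(stats = pooled, per_section = per_section, errors = err,
                 n_failed = n_failed, noise_level = sect_spec$noise_sigma,
                 seeds = seeds),
            class = "estimator_stats")
}

resolve_estimator <- function(estimator) {
  if (is.function(estimator)) return(estimator)
  switch(estimator,
    atlas_free = function(stack, atlas, cfg) restack_atlas_free(stack, cfg),
    atlas_informed = function(stack, atlas, cfg)
      estimate_joint(stack, atlas, cfg),
    stop("run_replicates: unknown estimator"))
}

#' @export
print.estimator_stats <- function(x, ...) {
  cat(sprintf("<estimator_stats> noise sigma = %g, %d error records, %d failed\n",
              x$noise_level, nrow(x$errors), x$n_failed))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Write estimator statistics as CSV
#'
#' Columns `noise_level, param, bias, std, rmse, n`.
#'
#' @param x an `estimator_stats`.
#' @param path CSV path.
#' @export
write_stats_csv <- function(x, path) {
  df <- data.frame(noise_level = x$noise_level, param = x$stats$param,
                   bias = x$stats$bias, std = x$stats$sd,
                   rmse = x$stats$rmse, n = x$stats$n)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Centroid axis of a stacked object
#'
#' The intensity-weighted in-plane centroid of every slab with
#' suprathreshold content (slabs without any are skipped and flagged),
#' plus scalar summaries: the maximum in-plane deflection of the centroid
#' polyline from its chord (the line joining the first and last centroid),
#' the mean discrete curvature (second-difference magnitude), and the
#' polyline and chord lengths. Coordinates are voxel indices.
#'
#' @param vol a [volume3d()].
#' @param threshold intensities at or above this count as content; default
#'   half the maximum.
#' @return list with `centroids` (data.frame `slab, x, y`),
#'   `max_deflection`, `mean_curvature`, `curve_length`, `chord_length`,
#'   `skipped`.
#' @export
centroid_axis <- function(vol, threshold = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  if (max(vol$values) <= 0) stop("centroid_axis: empty volume")
  if (is.null(threshold)) threshold <- 0.5 * max(vol$values)
  dm <- dim(vol$values)
  xs <- seq_len(dm[1]); ys <- seq_len(dm[2])
  rows <- list(); skipped <- integer(0)
  for (k in seq_len(dm[3])) {
    w <- vol$values[, , k] * (vol$values[, , k] >= threshold)
    tot <- sum(w)
    if (tot == 0) { skipped <- c(skipped, k); next }
    rows[[length(rows) + 1L]] <- data.frame(
      slab = k, x = sum(rowSums(w) * xs) / tot, y = sum(colSums(w) * ys) / tot)
  }
  cen <- do.call(rbind, rows)
  if (is.null(cen) || nrow(cen) < 2L) stop("centroid_axis: fewer than 2 slabs with content")
  p0 <- c(cen$x[1], cen$y[1]); p1 <- c(cen$x[nrow(cen)], cen$y[nrow(cen)])
  u <- (cen$slab - cen$slab[1]) / max(cen$slab[nrow(cen)] - cen$slab[1], 1)
  chord_x <- p0[1] + u * (p1[1] - p0[1])
  chord_y <- p0[2] + u * (p1[2] - p0[2])
  defl <- sqrt((cen$x - chord_x)^2 + (cen$y - chord_y)^2)
  dx <- diff(cen$x); dy <- diff(cen$y); dz <- diff(cen$slab)
  seglen <- sqrt(dx^2 + dy^2 + dz^2)
  curv <- if (nrow(cen) >= 3L)
    mean(sqrt(diff(dx)^2 + diff(dy)^2)) else 0
  list(centroids = cen, max_deflection = max(defl), mean_curvature = curv,
       curve_length = sum(seglen),
       chord_length = sqrt(sum((p1 - p0)^2) +
                           (cen$slab[nrow(cen)] - cen$slab[1])^2),
       skipped = skipped)
}

#' In-plane RMSE between the centroid axes of two volumes
#'
#' @param vol,ref [volume3d()] objects on matching grids.
#' @param threshold as in [centroid_axis()], applied to each volume.
#' @return scalar RMSE over the slabs present in both axes.
#' @export
centroid_axis_rmse <- function(vol, ref, threshold = NULL) {
  a <- centroid_axis(vol, threshold)$centroids
  b <- centroid_axis(ref, threshold)$centroids
  m <- merge(a, b, by = "slab", suffixes = c("", "_ref"))
  sqrt(mean((m$x - m$x_ref)^2 + (m$y - m$y_ref)^2))
}

#' Render a deformed coordinate grid
#'
#' Draws a regular grid-line image on the chosen plane and pulls it back
#' through the inverse map, the standard visualization of a deformation.
#' The identity map reproduces straight lines at exactly `line_spacing`
#' intervals.
#'
#' @param diffeo a `diffeo_pair`.
#' @param axis plane normal axis (1, 2 or 3).
#' @param index slab index along that axis.
#' @param line_spacing grid period in voxels.
#' @return numeric matrix, the rendered plane.
#' @export
export_warped_grid <- function(diffeo, axis = 3L, index = 1L,
                               line_spacing = 4L) {
  stopifnot(inherits(diffeo, "diffeo_pair"))
  dm <- dim(diffeo$phi_inv)[1:3]
  if (axis < 1L || axis > 3L) stop("export_warped_grid: bad axis")
  if (index < 1L || index > dm[axis]) stop("export_warped_grid: bad index")
  ax_in <- setdiff(1:3, axis)
  # grid-line image over the in-plane axes
  n1 <- dm[ax_in[1]]; n2 <- dm[ax_in[2]]
  line1 <- ((seq_len(n1) - 1) %% line_spacing) == 0
  line2 <- ((seq_len(n2) - 1) %% line_spacing) == 0
  G <- outer(line1, line2, `|`) + 0
  # in-plane components of phi_inv on the plane, world -> index
  sl <- switch(axis,
               diffeo$phi_inv[index, , , ],
               diffeo$phi_inv[, index, , ],
               diffeo$phi_inv[, , index, ])   # [n1, n2, 3]
  sl <- matrix(sl, n1 * n2, 3)
  u <- (sl[, ax_in[1]] - diffeo$origin[ax_in[1]]) / diffeo$spacing[ax_in[1]] + 1
  w <- (sl[, ax_in[2]] - diffeo$origin[ax_in[2]]) / diffeo$spacing[ax_in[2]] + 1
  out <- bilinear_sample(G, u, w)$values
  matrix(out, n1, n2)
}
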