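#' Dense 3D scalar volume on a regular grid
#'
#' The basic container for atlases, phantoms and restacked histology volumes:
#' a dense scalar field sampled on a regular grid with physical voxel spacing
#' and a world origin. The convention used throughout the package is that
#' voxel `(i, j, k)` (1-based in R, corresponding to 0-based voxel
#' `(i-1, j-1, k-1)`) sits at world coordinate
#' `origin + (i-1, j-1, k-1) * spacing`, and the third axis is always the
#' sectioning (cutting) axis.
#'
#' @param values numeric 3D array of intensities.
#' @param spacing numeric length-3, strictly positive voxel spacing
#'   `(dx, dy, dz)` in physical units (micrometres by convention).
#' @param origin numeric length-3 world coordinate of the first voxel.
#' @return an object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 3)), spacing = c(40, 40, 20))
#' dim(v$values)
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("volume3d: `values` must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: spacing must be three strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume3d: origin must be three finite numbers")
  if (any(!is.finite(values)))
    stop("volume3d: values contain NaN or Inf")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing (%g, %g, %g), origin (%g, %g, %g)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Ordered stack of 2D sections
#'
#' Container for a serially sectioned target: an ordered list of 2D sections
#' at uniformly spaced positions along the cutting axis, with per-section
#' likelihood weights and binary observation masks. A weight of zero marks a
#' censored (damaged) section which contributes nothing to any matching term;
#' a mask pixel of zero marks missing data excluded from all cost terms.
#'
#' @param sections list of equal-shaped numeric matrices.
#' @param z_positions numeric vector of section positions along the cutting
#'   axis, strictly increasing and uniformly spaced.
#' @param in_plane_spacing numeric length-2 pixel pitch `(dx, dy)`.
#' @param weights per-section nonnegative weights, recycled from length 1.
#' @param data_masks list of binary matrices matching the sections, or `NULL`
#'   for fully observed sections.
#' @return an object of class `section_stack`.
#' @export
section_stack <- function(sections, z_positions = NULL,
                          in_plane_spacing = c(1, 1),
                          weights = 1, data_masks = NULL) {
  if (!is.list(sections) || length(sections) < 2L)
    stop("section_stack: need a list of at least 2 sections")
  n <- length(sections)
  dm <- dim(sections[[1]])
  for (s in sections)
    if (!identical(dim(s), dm)) stop("section_stack: inconsistent section shapes")
  if (is.null(z_positions)) z_positions <- seq_len(n) - 1
  z_positions <- as.numeric(z_positions)
  if (length(z_positions) != n) stop("section_stack: z_positions length mismatch")
  dz <- diff(z_positions)
  if (any(dz <= 0)) stop("section_stack: z_positions must be strictly increasing")
  if (max(abs(dz - dz[1])) > 1e-6 * abs(dz[1]))
    stop("section_stack: z_positions must be uniformly spaced")
  in_plane_spacing <- as.numeric(in_plane_spacing)
  if (length(in_plane_spacing) != 2L || any(in_plane_spacing <= 0))
    stop("section_stack: in_plane_spacing must be two positive numbers")
  weights <- rep_len(as.numeric(weights), n)
  if (any(weights < 0)) stop("section_stack: weights must be nonnegative")
  if (is.null(data_masks)) {
    data_masks <- lapply(seq_len(n), function(i) matrix(1, dm[1], dm[2]))
  } else {
    if (length(data_masks) != n) stop("section_stack: data_masks length mismatch")
    data_masks <- lapply(data_masks, function(m) {
      if (!identical(dim(m), dm)) stop("section_stack: mask shape mismatch")
      (m != 0) + 0
    })
  }
  structure(list(sections = sections, z_positions = z_positions,
                 in_plane_spacing = in_plane_spacing,
                 weights = weights, data_masks = data_masks),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  dm <- dim(x$sections[[1]])
  cat(sprintf("<section_stack> %d sections of %d x %d pixels, dz = %g, pixel pitch (%g, %g)\n",
              length(x$sections), dm[1], dm[2], diff(x$z_positions[1:2]),
              x$in_plane_spacing[1], x$in_plane_spacing[2]))
  if (any(x$weights == 0))
    cat(sprintf("  %d censored section(s)\n", sum(x$weights == 0)))
  invisible(x)
}

#' Assemble a section stack into a 3D volume
#'
#' Slab `k` of the returned volume is section `k`; the volume spacing is
#' `(dx, dy, dz)` with `dz` the section spacing. Inverse of
#' [volume_to_stack()].
#'
#' @param stack a [section_stack()].
#' @return a [volume3d()].
#' @export
stack_to_volume <- function(stack) {
  stopifnot(inherits(stack, "section_stack"))
  dm <- dim(stack$sections[[1]])
  n <- length(stack$sections)
  vals <- array(unlist(stack$sections, use.names = FALSE), c(dm[1], dm[2], n))
  volume3d(vals,
           spacing = c(stack$in_plane_spacing, diff(stack$z_positions[1:2])),
           origin = c(0, 0, stack$z_positions[1]))
}

#' Slice a 3D volume into a section stack
#'
#' @param vol a [volume3d()].
#' @param weights,data_masks optional per-section weights and masks, as in
#'   [section_stack()].
#' @return a [section_stack()].
#' @export
volume_to_stack <- function(vol, weights = 1, data_masks = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  n <- dim(vol$values)[3]
  sections <- lapply(seq_len(n), function(k) vol$values[, , k])
  section_stack(sections,
                z_positions = vol$origin[3] + (seq_len(n) - 1) * vol$spacing[3],
                in_plane_spacing = vol$spacing[1:2],
                weights = weights, data_masks = data_masks)
}

# Pixel-centred physical coordinates of a section grid, origin at the centre
# of the physical extent. Rotations act about this centre.
section_centered_coords <- function(dm, spacing) {
  list(x = (seq_len(dm[1]) - (dm[1] + 1) / 2) * spacing[1],
       y = (seq_len(dm[2]) - (dm[2] + 1) / 2) * spacing[2])
}

#' Rescale volume intensities to [0, 1] by a percentile window
#'
#' Maps the `lo` percentile to 0 and the `hi` percentile to 1, clamping the
#' tails. Matching and smoothness weights in the package presume order-1
#' intensities, so loaders apply this by default.
#'
#' @param vol a [volume3d()].
#' @param lo,hi percentile window bounds in `[0, 100]`.
#' @return a rescaled [volume3d()].
#' @export
normalize_intensity <- function(vol, lo = 1, hi = 99) {
  stopifnot(inherits(vol, "volume3d"))
  q <- stats::quantile(vol$values, c(lo, hi) / 100, names = FALSE)
  if (q[2] <= q[1]) stop("normalize_intensity: degenerate intensity window")
  v <- (vol$values - q[1]) / (q[2] - q[1])
  vol$values <- pmin(pmax(v, 0), 1)
  vol
}
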