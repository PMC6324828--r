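# Tissue-mask estimation: robust foreground thresholding driven by repeated
# normal fits to sampled foreground candidates (a RANSAC-like consensus over
# the intensity histogram), followed by binary opening and closing.

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

shift3 <- function(m, dx, dy, dz, fill) {
  dm <- dim(m)
  out <- array(fill, dm)
  sx <- max(1, 1 + dx):min(dm[1], dm[1] + dx)
  sy <- max(1, 1 + dy):min(dm[2], dm[2] + dy)
  sz <- max(1, 1 + dz):min(dm[3], dm[3] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

binary_dilate <- function(m, radius) {
  off <- ball_offsets(radius)
  out <- array(FALSE, dim(m))
  for (k in seq_len(nrow(off)))
    out <- out | shift3(m, off$dx[k], off$dy[k], off$dz[k], FALSE)
  out
}

binary_erode <- function(m, radius) {
  off <- ball_offsets(radius)
  out <- array(TRUE, dim(m))
  for (k in seq_len(nrow(off)))
    out <- out & shift3(m, off$dx[k], off$dy[k], off$dz[k], FALSE)
  out
}

binary_open <- function(m, radius) binary_dilate(binary_erode(m, radius), radius)
binary_close <- function(m, radius) binary_erode(binary_dilate(m, radius), radius)

#' Estimate a binary tissue mask
#'
#' Assumes the image foreground (tissue) is brighter than the background
#' and approximately normally distributed in intensity. Candidate
#' foreground subsets are repeatedly sampled from the bright part of the
#' histogram; each gets a normal fit, the fit with the largest consensus
#' (voxels within two standard deviations) wins, and the volume is
#' thresholded at its mean minus two standard deviations. Binary opening
#' followed by closing (ball structuring element) removes speckle and fills
#' pinholes.
#'
#' @param vol a [volume3d()].
#' @param n_trials number of sampled candidate fits.
#' @param sample_fraction fraction of the bright-half voxels sampled per
#'   trial (at least 10 voxels).
#' @param morph_radius structuring-element radius in voxels; 0 disables
#'   morphology.
#' @param invert set when tissue is darker than background.
#' @return a binary [volume3d()] (values 0/1).
#' @export
estimate_tissue_mask <- function(vol, n_trials = 100L, sample_fraction = 0.1,
                                 morph_radius = 2, invert = FALSE) {
  stopifnot(inherits(vol, "volume3d"))
  x <- as.vector(vol$values)
  if (max(x) == min(x)) stop("estimate_tissue_mask: degenerate histogram")
  if (invert) x <- max(x) + min(x) - x
  pool <- x[x > mean(x)]
  if (length(pool) < 10L) stop("estimate_tissue_mask: degenerate histogram")
  sd_all <- stats::sd(x)
  m <- max(10L, round(sample_fraction * length(pool)))
  best <- NULL; best_inl <- -1
  for (t in seq_len(n_trials)) {
    s <- pool[sample.int(length(pool), min(m, length(pool)))]
    mu <- mean(s); sg <- stats::sd(s)
    if (!is.finite(sg) || sg > sd_all) next
    if (sg == 0) sg <- 1e-12   # binary foreground: threshold at its value
    inl <- sum(x >= mu - 2 * sg & x <= mu + 2 * sg)
    if (inl > best_inl) { best_inl <- inl; best <- c(mu, sg) }
  }
  if (is.null(best)) stop("estimate_tissue_mask: no admissible normal fit")
  thr <- best[1] - 2 * best[2]
  mask <- array(x >= thr, dim(vol$values))
  if (morph_radius > 0) {
    mask <- binary_open(mask, morph_radius)
    mask <- binary_close(mask, morph_radius)
  }
  volume3d(mask + 0, spacing = vol$spacing, origin = vol$origin)
}
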