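# Readers and writers: NIfTI-1 volumes, PNG/TIFF section series, rigid CSVs.

#' Read a 3D volume
#'
#' Accepts a NIfTI file (spacing and origin taken from the header), a
#' multi-page TIFF, or a directory of equal-shaped single-channel PNG/TIFF
#' sections ordered lexicographically by filename. Raster stacks carry no
#' spacing metadata, so `spacing` must be supplied for them; supplying it for
#' NIfTI overrides the header.
#'
#' @param path file or directory path.
#' @param spacing numeric length-3 voxel spacing; required for raster stacks.
#' @param normalize rescale intensities to `[0, 1]` by the 1st/99th
#'   percentile window (see [normalize_intensity()]); default `FALSE` so that
#'   round trips are exact, loaders of real histology should enable it.
#' @return a [volume3d()].
#' @export
read_volume <- function(path, spacing = NULL, normalize = FALSE) {
  if (!file.exists(path))
    stop(sprintf("read_volume: '%s' does not exist", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 1L)
      stop(sprintf("read_volume: no PNG/TIFF sections found in '%s'", path))
    if (is.null(spacing))
      stop(sprintf("read_volume: '%s' is a raster series; spacing must be given", path))
    sections <- lapply(files, read_section_image)
    dm <- dim(sections[[1]])
    for (f in seq_along(sections))
      if (!identical(dim(sections[[f]]), dm))
        stop(sprintf("read_volume: inconsistent section shape in '%s'", files[f]))
    vals <- array(unlist(sections, use.names = FALSE),
                  c(dm[1], dm[2], length(sections)))
    vol <- volume3d(vals, spacing = spacing)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim(img))
    if (length(dim(vals)) == 2L) vals <- array(vals, c(dim(vals), 1L))
    if (length(dim(vals)) != 3L)
      stop(sprintf("read_volume: '%s' is not a 3D image", path))
    sp <- if (is.null(spacing)) RNifti::pixdim(img)[1:3] else spacing
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop(sprintf("read_volume: non-positive spacing in '%s'", path))
    vol <- volume3d(vals, spacing = sp)
  } else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (is.null(spacing))
      stop(sprintf("read_volume: '%s' is a raster stack; spacing must be given", path))
    sections <- lapply(pages, normalize_raster_page)
    dm <- dim(sections[[1]])
    vals <- array(unlist(sections, use.names = FALSE),
                  c(dm[1], dm[2], length(sections)))
    vol <- volume3d(vals, spacing = spacing)
  } else {
    stop(sprintf("read_volume: unsupported format for '%s'", path))
  }
  if (normalize) vol <- normalize_intensity(vol) else vol
}

# Raster pages come in row-major (row = y); transpose to the package's
# [x, y] convention and collapse any colour channels to grayscale.
normalize_raster_page <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1]
  t(p)
}

read_section_image <- function(path) {
  p <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  normalize_raster_page(p)
}

#' Write a 3D volume
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) with spacing in the header, or a multi-page
#' TIFF (32-bit float, spacing not stored).
#'
#' @param vol a [volume3d()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(dim(vol$values)[3]),
                    function(k) t(vol$values[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    stop(sprintf("write_volume: unsupported format for '%s'", path))
  }
  invisible(path)
}

#' Write a section stack as a PNG series
#'
#' One 8-bit grayscale PNG per section, named `section_0001.png`, ... so that
#' lexicographic order is stack order. Intensities are clamped to `[0, 1]`
#' and quantized to the PNG bit depth; binary masks survive exactly.
#'
#' @param stack a [section_stack()].
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_stack_png <- function(stack, dir) {
  stopifnot(inherits(stack, "section_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$sections)) {
    img <- pmin(pmax(stack$sections[[i]], 0), 1)
    png::writePNG(t(img), file.path(dir, sprintf("section_%04d.png", i)))
  }
  invisible(dir)
}

#' Read/write per-section rigid motions as CSV
#'
#' The interchange format has columns
#' `section_index, theta_rad, tx, ty` with translations in physical units.
#'
#' @param motions list of [rigid_motion()].
#' @param path CSV path.
#' @return `read_rigid_csv` returns a list of [rigid_motion()];
#'   `write_rigid_csv` returns `path` invisibly.
#' @export
write_rigid_csv <- function(motions, path) {
  df <- data.frame(
    section_index = seq_along(motions) - 1L,
    theta_rad = vapply(motions, function(r) r$theta, 0),
    tx = vapply(motions, function(r) r$tx, 0),
    ty = vapply(motions, function(r) r$ty, 0)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rigid_csv
#' @export
read_rigid_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("section_index", "theta_rad", "tx", "ty")
  if (!all(need %in% names(df)))
    stop("read_rigid_csv: missing required columns")
  df <- df[order(df$section_index), ]
  lapply(seq_len(nrow(df)),
         function(i) rigid_motion(df$theta_rad[i], df$tx[i], df$ty[i]))
}
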