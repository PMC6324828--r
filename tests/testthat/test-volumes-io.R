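test_that("volume3d and section_stack enforce their invariants", {
  expect_error(volume3d(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(volume3d(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
  expect_error(volume3d(array(c(NA, rep(0, 7)), c(2, 2, 2))), "NaN|finite")
  s <- list(matrix(1, 3, 3), matrix(2, 3, 3))
  expect_error(section_stack(s, z_positions = c(0, 1, 2)), "length")
  expect_error(section_stack(s, z_positions = c(1, 0)), "increasing")
  expect_error(section_stack(list(matrix(1, 3, 3), matrix(1, 4, 3))),
               "shapes")
  expect_error(section_stack(list(matrix(1, 2, 2), matrix(1, 2, 2),
                                  matrix(1, 2, 2)),
                             z_positions = c(0, 1, 2.5)), "uniform")
})

test_that("stack_to_volume and volume_to_stack are mutually inverse", {
  set.seed(1)
  sections <- lapply(1:4, function(k) matrix(rnorm(12), 3, 4))
  st <- section_stack(sections, z_positions = c(0, 20, 40, 60),
                      in_plane_spacing = c(40, 40))
  vol <- stack_to_volume(st)
  expect_equal(vol$spacing, c(40, 40, 20))
  expect_equal(vol$values[, , 3], sections[[3]])
  back <- volume_to_stack(vol)
  expect_equal(back$sections, st$sections)
  expect_equal(back$z_positions, st$z_positions)
  # constant sections give a constant volume
  cst <- section_stack(lapply(1:3, function(k) matrix(7, 2, 2)))
  expect_true(all(stack_to_volume(cst)$values == 7))
})

test_that("NIfTI volumes round-trip through write_volume/read_volume", {
  set.seed(2)
  vol <- volume3d(array(rnorm(5 * 4 * 3), c(5, 4, 3)), spacing = c(40, 40, 20))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$values, vol$values, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing)
  expect_error(read_volume(tempfile(fileext = ".nii")), "exist")
})

test_that("a header written by an independent NIfTI writer reads back", {
  skip_if_not_installed("oro.nifti")
  arr <- array(seq_len(4 * 4 * 2) / 10, c(4, 4, 2))
  nim <- oro.nifti::nifti(arr, datatype = 16)
  oro.nifti::pixdim(nim)[2:4] <- c(40, 40, 40)
  path <- tempfile()
  suppressMessages(oro.nifti::writeNIfTI(nim, path, gzipped = TRUE))
  vol <- read_volume(paste0(path, ".nii.gz"))
  expect_equal(vol$spacing, c(40, 40, 40))
  expect_equal(vol$values, arr, tolerance = 1e-6)
})

test_that("PNG section series and multi-page TIFF round-trip", {
  set.seed(3)
  sections <- lapply(1:5, function(k) matrix(runif(6 * 7), 6, 7))
  st <- section_stack(sections, in_plane_spacing = c(40, 40))
  d <- tempfile()
  write_stack_png(st, d)
  expect_error(read_volume(d), "spacing")
  vol <- read_volume(d, spacing = c(40, 40, 20))
  expect_equal(dim(vol$values), c(6L, 7L, 5L))
  expect_equal(vol$spacing, c(40, 40, 20))
  expect_lt(max(abs(vol$values - stack_to_volume(st)$values)), 1 / 255)
  # 32-bit float TIFF keeps values to single precision
  v2 <- volume3d(array(runif(4 * 4 * 3), c(4, 4, 3)))
  tf <- tempfile(fileext = ".tif")
  write_volume(v2, tf)
  back <- read_volume(tf, spacing = c(1, 1, 1))
  expect_lt(max(abs(back$values - v2$values)), 1e-6)
})

test_that("rigid CSVs round-trip motions", {
  motions <- list(rigid_motion(0.1, -3, 2), rigid_motion(-0.2, 0.5, 1))
  path <- tempfile(fileext = ".csv")
  write_rigid_csv(motions, path)
  back <- read_rigid_csv(path)
  expect_equal(back, motions, tolerance = 1e-12)
})

test_that("tissue mask separates two intensity populations", {
  set.seed(4)
  dm <- c(24, 24, 24)
  ctr <- (dm + 1) / 2
  d2 <- array(0, dm)
  for (k in 1:dm[3])
    d2[, , k] <- outer((seq_len(dm[1]) - ctr[1])^2,
                       (seq_len(dm[2]) - ctr[2])^2, `+`) + (k - ctr[3])^2
  ball <- d2 <= 8^2
  vals <- array(rnorm(prod(dm), 0.05, 0.05), dm)
  vals[ball] <- rnorm(sum(ball), 0.8, 0.05)
  vol <- volume3d(vals)
  m <- estimate_tissue_mask(vol)
  expect_gte(mean(m$values[ball] == 1), 0.99)
  expect_lte(mean(m$values[!ball] == 1), 0.01)
  # inverting intensities with the invert flag gives the same mask
  vinv <- volume3d(max(vals) + min(vals) - vals)
  minv <- estimate_tissue_mask(vinv, invert = TRUE)
  expect_gte(mean(minv$values == m$values), 0.99)
  # idempotence: re-estimating on the masked image reproduces the mask
  m2 <- estimate_tissue_mask(volume3d(vals * m$values))
  expect_gte(mean(m2$values == m$values), 0.98)
  expect_error(estimate_tissue_mask(volume3d(array(1, c(4, 4, 4)))),
               "degenerate")
})

test_that("binary phantom support is recovered by the mask up to morphology", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 10), kind = "straight_cylinder",
                                  radius = 8, anti_alias = FALSE))
  set.seed(5)
  m <- estimate_tissue_mask(ph, morph_radius = 0)
  expect_gte(mean((m$values == 1) == (ph$values == 1)), 0.999)
})

test_that("intensity normalization maps the percentile window to [0, 1]", {
  set.seed(6)
  vol <- volume3d(array(rnorm(4000, 100, 25), c(20, 20, 10)))
  nv <- normalize_intensity(vol)
  expect_gte(min(nv$values), 0)
  expect_lte(max(nv$values), 1)
  expect_error(normalize_intensity(volume3d(array(3, c(2, 2, 2)))),
               "degenerate")
})
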