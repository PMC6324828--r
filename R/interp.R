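# Low-level interpolation kernels shared by the rigid, flow and warping code.
# All samplers work in continuous 1-based voxel-index coordinates; points
# outside the grid return the fill value and are flagged so callers can
# exclude them from cost terms instead of matching against the fill.

#' Bilinear sampling of a 2D image
#'
#' @param img numeric matrix.
#' @param xi,yi numeric vectors of continuous 1-based index coordinates.
#' @param fill value used outside the image domain.
#' @return list with `values` and logical `inside`.
#' @keywords internal
#' @noRd
bilinear_sample <- function(img, xi, yi, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  stopifnot(nx >= 2L, ny >= 2L)
  inside <- is.finite(xi) & is.finite(yi) & xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  x <- pmin(pmax(xi, 1), nx)
  y <- pmin(pmax(yi, 1), ny)
  x0 <- pmin(floor(x), nx - 1)
  y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- x0 + (y0 - 1) * nx
  v00 <- img[i00]; v10 <- img[i00 + 1]
  v01 <- img[i00 + nx]; v11 <- img[i00 + nx + 1]
  val <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  val[!inside] <- fill
  list(values = val, inside = inside)
}

# Exact derivative of the bilinear interpolant with respect to the sample
# position (index units). Zero outside the domain.
bilinear_gradient <- function(img, xi, yi) {
  nx <- nrow(img); ny <- ncol(img)
  inside <- is.finite(xi) & is.finite(yi) & xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  x <- pmin(pmax(xi, 1), nx)
  y <- pmin(pmax(yi, 1), ny)
  x0 <- pmin(floor(x), nx - 1)
  y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- x0 + (y0 - 1) * nx
  v00 <- img[i00]; v10 <- img[i00 + 1]
  v01 <- img[i00 + nx]; v11 <- img[i00 + nx + 1]
  gx <- (1 - fy) * (v10 - v00) + fy * (v11 - v01)
  gy <- (1 - fx) * (v01 - v00) + fx * (v11 - v10)
  gx[!inside] <- 0; gy[!inside] <- 0
  list(gx = gx, gy = gy, inside = inside)
}

# Fused value + position-derivative bilinear sampling (one corner fetch).
bilinear_sample_grad <- function(img, xi, yi, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  inside <- is.finite(xi) & is.finite(yi) & xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  x <- pmin(pmax(xi, 1), nx)
  y <- pmin(pmax(yi, 1), ny)
  x0 <- pmin(floor(x), nx - 1)
  y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- x0 + (y0 - 1) * nx
  v00 <- img[i00]; v10 <- img[i00 + 1]
  v01 <- img[i00 + nx]; v11 <- img[i00 + nx + 1]
  a <- v10 - v00; b <- v01 - v00; c_ <- v11 - v01 - a
  val <- v00 + fx * a + fy * b + fx * fy * c_
  gx <- a + fy * c_
  gy <- b + fx * c_
  val[!inside] <- fill
  gx[!inside] <- 0; gy[!inside] <- 0
  list(values = val, gx = gx, gy = gy, inside = inside)
}

# Nearest-neighbour sampling (masks, label maps).
nearest_sample <- function(img, xi, yi, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  inside <- is.finite(xi) & is.finite(yi) & xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  x <- pmin(pmax(round(xi), 1), nx)
  y <- pmin(pmax(round(yi), 1), ny)
  val <- img[x + (y - 1) * nx]
  val[!inside] <- fill
  list(values = val, inside = inside)
}

# --- 3D -----------------------------------------------------------------

# A sampling "plan" factors trilinear interpolation into (corner index,
# fractional offsets, inside flag) so the same geometry can drive the value,
# the position-derivative, and the adjoint scatter used in backpropagation
# through the flow.
trilinear_plan <- function(dm, xi, yi, zi) {
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  stopifnot(nx >= 2L, ny >= 2L, nz >= 2L)
  inside <- is.finite(xi) & is.finite(yi) & is.finite(zi) &
    xi >= 1 & xi <= nx & yi >= 1 & yi <= ny & zi >= 1 & zi <= nz
  x <- pmin(pmax(xi, 1), nx)
  y <- pmin(pmax(yi, 1), ny)
  z <- pmin(pmax(zi, 1), nz)
  x0 <- pmin(floor(x), nx - 1)
  y0 <- pmin(floor(y), ny - 1)
  z0 <- pmin(floor(z), nz - 1)
  list(
    idx0 = x0 + (y0 - 1) * nx + (z0 - 1) * nx * ny,
    fx = x - x0, fy = y - y0, fz = z - z0,
    inside = inside, ox = 1, oy = nx, oz = nx * ny, n = nx * ny * nz
  )
}

trilinear_value <- function(vol, plan, fill = 0) {
  i0 <- plan$idx0; ox <- plan$ox; oy <- plan$oy; oz <- plan$oz
  fx <- plan$fx; fy <- plan$fy; fz <- plan$fz
  c000 <- vol[i0];           c100 <- vol[i0 + ox]
  c010 <- vol[i0 + oy];      c110 <- vol[i0 + ox + oy]
  c001 <- vol[i0 + oz];      c101 <- vol[i0 + ox + oz]
  c011 <- vol[i0 + oy + oz]; c111 <- vol[i0 + ox + oy + oz]
  w00 <- c000 * (1 - fx) + c100 * fx
  w10 <- c010 * (1 - fx) + c110 * fx
  w01 <- c001 * (1 - fx) + c101 * fx
  w11 <- c011 * (1 - fx) + c111 * fx
  v0 <- w00 * (1 - fy) + w10 * fy
  v1 <- w01 * (1 - fy) + w11 * fy
  val <- v0 * (1 - fz) + v1 * fz
  val[!plan$inside] <- fill
  val
}

# d(interp)/d(position), index units; zero outside.
trilinear_grad_pos <- function(vol, plan) {
  i0 <- plan$idx0; ox <- plan$ox; oy <- plan$oy; oz <- plan$oz
  fx <- plan$fx; fy <- plan$fy; fz <- plan$fz
  c000 <- vol[i0];           c100 <- vol[i0 + ox]
  c010 <- vol[i0 + oy];      c110 <- vol[i0 + ox + oy]
  c001 <- vol[i0 + oz];      c101 <- vol[i0 + ox + oz]
  c011 <- vol[i0 + oy + oz]; c111 <- vol[i0 + ox + oy + oz]
  gx <- ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz) +
        ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz
  gy <- ((c010 - c000) * (1 - fx) + (c110 - c100) * fx) * (1 - fz) +
        ((c011 - c001) * (1 - fx) + (c111 - c101) * fx) * fz
  gz <- ((c001 - c000) * (1 - fx) + (c101 - c100) * fx) * (1 - fy) +
        ((c011 - c010) * (1 - fx) + (c111 - c110) * fx) * fy
  gx[!plan$inside] <- 0; gy[!plan$inside] <- 0; gz[!plan$inside] <- 0
  list(gx = gx, gy = gy, gz = gz)
}

# Accumulate weights into a dense vector: out[idx] += w with duplicate idx.
accum_add <- function(idx, w, n) {
  keep <- w != 0
  if (!any(keep)) return(numeric(n))
  r <- rowsum(w[keep], idx[keep])
  out <- numeric(n)
  out[as.numeric(rownames(r))] <- r
  out
}

# Adjoint of trilinear_value: scatter per-point cotangents g back onto the
# source grid. Points outside the domain contribute nothing (matching the
# zero-fill in the forward pass).
trilinear_scatter <- function(g, plan) {
  i0 <- plan$idx0; ox <- plan$ox; oy <- plan$oy; oz <- plan$oz
  fx <- plan$fx; fy <- plan$fy; fz <- plan$fz
  g <- g * plan$inside
  wx0 <- 1 - fx; wy0 <- 1 - fy; wz0 <- 1 - fz
  idx <- c(i0,            i0 + ox,           i0 + oy,           i0 + ox + oy,
           i0 + oz,       i0 + ox + oz,      i0 + oy + oz,      i0 + ox + oy + oz)
  w <- c(g * wx0 * wy0 * wz0, g * fx * wy0 * wz0, g * wx0 * fy * wz0, g * fx * fy * wz0,
         g * wx0 * wy0 * fz,  g * fx * wy0 * fz,  g * wx0 * fy * fz,  g * fx * fy * fz)
  accum_add(idx, w, plan$n)
}

trilinear_sample <- function(vol, xi, yi, zi, fill = 0) {
  plan <- trilinear_plan(dim(vol), xi, yi, zi)
  list(values = trilinear_value(vol, plan, fill = fill), inside = plan$inside)
}

nearest_sample3 <- function(vol, xi, yi, zi, fill = 0) {
  dm <- dim(vol)
  inside <- is.finite(xi) & is.finite(yi) & is.finite(zi) &
    xi >= 1 & xi <= dm[1] & yi >= 1 & yi <= dm[2] & zi >= 1 & zi <= dm[3]
  x <- pmin(pmax(round(xi), 1), dm[1])
  y <- pmin(pmax(round(yi), 1), dm[2])
  z <- pmin(pmax(round(zi), 1), dm[3])
  val <- vol[x + (y - 1) * dm[1] + (z - 1) * dm[1] * dm[2]]
  val[!inside] <- fill
  list(values = val, inside = inside)
}
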