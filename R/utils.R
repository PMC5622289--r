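# Shared numeric helpers. Conventions used throughout the package:
# pixel coordinates are 0-based, x right / y down, origin at the top-left
# pixel of each field of view; a matrix `m` stores intensity m[y + 1, x + 1].

#' Integral image (summed-area table)
#'
#' @param img numeric matrix (h x w).
#' @return (h+1) x (w+1) matrix `ii` with `ii[i+1, j+1] = sum(img[1:i, 1:j])`
#'   and a zero first row/column, so rectangle sums need no bounds special
#'   cases.
#' @keywords internal
integral_image <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1L, -1L] <- apply(apply(img, 2L, cumsum), 1L, cumsum) |> t()
  ii
}

# Sum of img over the inclusive 0-based pixel rectangle [x0,x1] x [y0,y1],
# vectorized over equally long coordinate vectors. Coordinates must be
# integer-valued and inside the image.
rect_sum <- function(ii, x0, y0, x1, y1) {
  nr <- nrow(ii)
  i00 <- (x0) * nr + y0 + 1L          # ii[y0+1, x0+1] in 0-based corners
  ii[i00 + nr + 1L + (x1 - x0) * nr + (y1 - y0)] -  # ii[y1+2, x1+2]
    ii[i00 + nr + (x1 - x0) * nr] -                 # ii[y0+1, x1+2]
    ii[i00 + 1L + (y1 - y0)] +                      # ii[y1+2, x0+1]
    ii[i00]                                         # ii[y0+1, x0+1]
}

#' Bilinear sampling of an image at fractional 0-based coordinates
#'
#' Out-of-bounds samples return `fill`.
#' @keywords internal
bilinear_sample <- function(img, x, y, fill = NA_real_) {
  h <- nrow(img)
  w <- ncol(img)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  ok <- x >= 0 & y >= 0 & x <= w - 1 & y <= h - 1
  # clamp the upper corner so points exactly on the last row/col still sample
  x0c <- pmin(pmax(x0, 0), w - 2)
  y0c <- pmin(pmax(y0, 0), h - 2)
  fxc <- ifelse(ok, x - x0c, 0)
  fyc <- ifelse(ok, y - y0c, 0)
  idx <- function(xx, yy) yy + 1L + xx * h
  v <- (1 - fxc) * (1 - fyc) * img[idx(x0c, y0c)] +
    fxc * (1 - fyc) * img[idx(x0c + 1, y0c)] +
    (1 - fxc) * fyc * img[idx(x0c, y0c + 1)] +
    fxc * fyc * img[idx(x0c + 1, y0c + 1)]
  v[!ok] <- fill
  v
}

# Two-pass 3-4 chamfer distance transform (units: ~pixels, scaled by 1/3).
# `mask` is logical: TRUE = inside/valid. Distance of a valid pixel to the
# nearest invalid or outside pixel; invalid pixels get 0.
chamfer_distance <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  big <- 3 * (h + w)
  d <- matrix(0, h + 2L, w + 2L)           # pad with zeros = outside
  d[2:(h + 1L), 2:(w + 1L)] <- ifelse(mask, big, 0)
  for (i in 2:(h + 1L)) {                   # forward pass (row-vectorized in x)
    row <- d[i, ]
    up <- d[i - 1L, ]
    cand <- pmin(up + 3, c(big, up[-(w + 2L)]) + 4, c(up[-1L], big) + 4)
    row <- pmin(row, cand)
    for (j in 2:(w + 1L)) row[j] <- min(row[j], row[j - 1L] + 3)
    d[i, ] <- row
  }
  for (i in (h + 1L):2) {                   # backward pass
    dn <- d[i + 1L, ]
    row <- d[i, ]
    cand <- pmin(dn + 3, c(big, dn[-(w + 2L)]) + 4, c(dn[-1L], big) + 4)
    row <- pmin(row, cand)
    for (j in (w + 1L):2) row[j] <- min(row[j], row[j + 1L] + 3)
    d[i, ] <- row
  }
  d[2:(h + 1L), 2:(w + 1L)] / 3
}

#' Round half away from zero to `digits` decimals
#'
#' Display rounding used by the agreement tables; base `round()` rounds half
#' to even which does not reproduce the printed ratios.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Rec. 601 luma of an h x w x 3 array in [0,1].
rgb_to_gray <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Quantize [0,1] intensities to the 8-bit grid (values k/255) so that PNG
# round-trips are bit-exact.
quantize8 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  round(x * 255) / 255
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
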