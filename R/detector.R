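# SURF-style scale-space keypoint detector with per-layer adaptive
# thresholding.
#
# The detector approximates the Hessian determinant with integral-image box
# filters of increasing size (one "layer" per filter size), keeps 3x3x3
# scale-space local maxima, and instead of one global response threshold
# chooses one threshold per layer so that each layer contributes a bounded
# number of keypoints (a count band). This keeps descriptor matching cost
# bounded without starving feature-poor layers.

#' Detector configuration
#'
#' @param layer_filter_sizes strictly increasing odd box-filter sizes in
#'   pixels; each size is one pyramid layer (default `c(9,15,21,27,39,51)`).
#' @param per_layer_count_band integer pair `c(n_lo, n_hi)`: the target
#'   keypoint count band per layer. Layers with more than `n_hi` candidates
#'   are capped at `n_hi` by raising that layer's threshold; layers with
#'   fewer than `n_lo` keep everything above the floor (scarcity accepted).
#' @param min_absolute_response floor threshold on the scale-normalized
#'   Hessian-determinant response, for intensities in `[0,1]` (default 1e-4,
#'   i.e. 1e-4 of the maximal attainable response of the normalized filters).
#' @param upright if `TRUE` (default) descriptors are not oriented;
#'   microscope stages translate but do not rotate. Set `FALSE` to assign a
#'   dominant orientation per keypoint.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(layer_filter_sizes = c(9L, 15L, 21L, 27L, 39L, 51L),
                            per_layer_count_band = c(50L, 400L),
                            min_absolute_response = 1e-4,
                            upright = TRUE) {
  sz <- as.integer(layer_filter_sizes)
  if (any(sz %% 2L == 0L) || any(sz %% 3L != 0L))
    stopf("layer_filter_sizes must be odd multiples of 3")
  if (is.unsorted(sz, strictly = TRUE))
    stopf("layer_filter_sizes must be strictly increasing")
  band <- as.integer(per_layer_count_band)
  if (band[1] >= band[2]) stopf("count band requires n_lo < n_hi")
  structure(list(layer_filter_sizes = sz, per_layer_count_band = band,
                 min_absolute_response = min_absolute_response,
                 upright = isTRUE(upright)),
            class = "detector_config")
}

# Scale (in pixels) associated with a box-filter size; 9 px box ~ sigma 1.2.
filter_scale <- function(L) 1.2 * L / 9

# Scale-normalized determinant-of-Hessian response map for one filter size.
# Returns a h x w matrix, -Inf outside the valid border.
doh_response <- function(ii, w, h, L) {
  l <- L %/% 3L
  half <- (L - 1L) %/% 2L
  if (w < 2L * half + 1L || h < 2L * half + 1L)
    return(matrix(-Inf, h, w))
  xs <- half:(w - 1L - half)
  ys <- half:(h - 1L - half)
  X <- rep(xs, each = length(ys))
  Y <- rep(ys, times = length(xs))
  wl <- l - 1L                         # half-width of the 2l-1 lobe
  mid <- (l - 1L) %/% 2L
  # Dyy: three stacked (l x 2l-1) boxes, weights 1,-2,1
  dyy <- rect_sum(ii, X - wl, Y - half, X + wl, Y + half) -
    3 * rect_sum(ii, X - wl, Y - mid, X + wl, Y + mid)
  dxx <- rect_sum(ii, X - half, Y - wl, X + half, Y + wl) -
    3 * rect_sum(ii, X - mid, Y - wl, X + mid, Y + wl)
  dxy <- rect_sum(ii, X - l, Y - l, X - 1L, Y - 1L) +
    rect_sum(ii, X + 1L, Y + 1L, X + l, Y + l) -
    rect_sum(ii, X + 1L, Y - l, X + l, Y - 1L) -
    rect_sum(ii, X - l, Y + 1L, X - 1L, Y + l)
  n2 <- as.numeric(L)^2
  det <- (dxx / n2) * (dyy / n2) - 0.81 * (dxy / n2)^2
  out <- matrix(-Inf, h, w)
  out[cbind(Y + 1L, X + 1L)] <- det
  out
}

# Max over the 8 in-layer neighbors (dx,dy != 0,0) or the 9 neighbors of an
# adjacent layer, via shifted copies.
shift_mat <- function(m, dx, dy, fill = -Inf) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  ys <- max(1L, 1L - dy):min(h, h - dy)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

neighborhood_max <- function(m, include_center) {
  acc <- if (include_center) m else matrix(-Inf, nrow(m), ncol(m))
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    acc <- pmax(acc, shift_mat(m, dx, dy))
  }
  acc
}

#' Adaptive per-layer response threshold
#'
#' Returns the smallest threshold `>= floor` such that the number of
#' responses strictly above it is at most `n_hi`. When fewer than `n_lo`
#' responses exceed the floor, scarcity is accepted and the floor itself is
#' returned. Deterministic given its input.
#'
#' @param responses non-negative response scores of one layer's candidates.
#' @param band integer pair `c(n_lo, n_hi)`.
#' @param floor minimum admissible threshold.
#' @return A single threshold value.
#' @export
adaptive_layer_threshold <- function(responses, band, floor) {
  if (length(responses) == 0L) return(floor)
  if (any(responses < 0)) stopf("responses must be non-negative")
  n_hi <- band[2]
  above <- sum(responses > floor)
  if (above <= n_hi) return(floor)
  sorted <- sort(responses, decreasing = TRUE)
  max(floor, sorted[n_hi + 1L])
}

# Quadratic sub-pixel refinement along one axis from three samples; clamped
# to +/- 0.5 sample.
quad_refine <- function(rm, r0, rp) {
  den <- rm - 2 * r0 + rp
  d <- ifelse(is.finite(rm) & is.finite(rp) & den < 0,
              0.5 * (rm - rp) / den, 0)
  pmin(pmax(d, -0.5), 0.5)
}

#' Detect keypoints in a field of view
#'
#' Keypoints are local maxima of the box-filter-approximated Hessian
#' determinant over 3x3x3 scale-space neighborhoods that survive their
#' layer's adaptive threshold (see [adaptive_layer_threshold()]). Positions
#' are refined to sub-pixel accuracy by quadratic interpolation (clamped to
#' half a sample). Descriptors are computed for every returned keypoint;
#' keypoints whose descriptor support window exits the image are dropped.
#'
#' @param f a [fov()].
#' @param cfg a [detector_config()].
#' @return A list of class `keypoint_set` with elements `fov_index`,
#'   `keypoints` (data.frame `x, y, scale, response, layer`), `descriptors`
#'   (n x 64 matrix, unit rows), `per_layer_thresholds` and
#'   `per_layer_counts` (post-threshold survivor tallies per layer).
#' @export
detect <- function(f, cfg = detector_config()) {
  img <- f$pixels
  h <- nrow(img); w <- ncol(img)
  Lmax <- max(cfg$layer_filter_sizes)
  if (w < 2L * Lmax || h < 2L * Lmax)
    stopf("image %dx%d too small: need at least twice the largest filter size (%d)",
          w, h, Lmax)
  ii <- integral_image(img)
  sizes <- cfg$layer_filter_sizes
  nl <- length(sizes)
  resp <- lapply(sizes, function(L) doh_response(ii, w, h, L))
  floor_t <- cfg$min_absolute_response
  thresholds <- rep(NA_real_, nl)
  counts <- integer(nl)
  kp <- list()
  for (li in seq(2L, nl - 1L)) {
    R <- resp[[li]]
    m8 <- neighborhood_max(R, include_center = FALSE)
    m_up <- neighborhood_max(resp[[li + 1L]], include_center = TRUE)
    m_dn <- neighborhood_max(resp[[li - 1L]], include_center = TRUE)
    is_max <- is.finite(R) & R > floor_t & R > m8 & R > m_up & R > m_dn
    idx <- which(is_max)
    thr <- adaptive_layer_threshold(R[idx], cfg$per_layer_count_band, floor_t)
    thresholds[li] <- thr
    idx <- idx[R[idx] > thr]
    counts[li] <- length(idx)
    if (!length(idx)) next
    yy <- (idx - 1L) %% h        # 0-based row
    xx <- (idx - 1L) %/% h       # 0-based col
    i1 <- cbind(yy + 1L, xx + 1L)
    dx <- quad_refine(R[cbind(yy + 1L, xx)], R[i1], R[cbind(yy + 1L, xx + 2L)])
    dy <- quad_refine(R[cbind(yy, xx + 1L)], R[i1], R[cbind(yy + 2L, xx + 1L)])
    s_lo <- filter_scale(sizes[li - 1L])
    s_hi <- filter_scale(sizes[li + 1L])
    ds <- quad_refine(resp[[li - 1L]][i1], R[i1], resp[[li + 1L]][i1])
    kp[[length(kp) + 1L]] <- data.frame(
      x = xx + dx, y = yy + dy,
      scale = filter_scale(sizes[li]) + ds * (s_hi - s_lo) / 2,
      response = R[i1], layer = li - 1L)   # 0-based layer index
  }
  kps <- if (length(kp)) do.call(rbind, kp)
         else data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
                         response = numeric(0), layer = integer(0))
  ord <- order(kps$layer, kps$y, kps$x)
  kps <- kps[ord, , drop = FALSE]
  rownames(kps) <- NULL
  desc <- describe(f, kps, cfg, ii = ii)
  keep <- attr(desc, "kept")
  structure(list(fov_index = f$index,
                 keypoints = kps[keep, , drop = FALSE],
                 descriptors = desc,
                 per_layer_thresholds = thresholds,
                 per_layer_counts = counts),
            class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set: fov #%s, %d keypoints>\n",
              x$fov_index, nrow(x$keypoints)))
  invisible(x)
}

# Haar wavelet responses (dx, dy) of half-size hs at integer 0-based centers.
haar_xy <- function(ii, px, py, hs) {
  dx <- rect_sum(ii, px, py - hs, px + hs - 1L, py + hs - 1L) -
    rect_sum(ii, px - hs, py - hs, px - 1L, py + hs - 1L)
  dy <- rect_sum(ii, px - hs, py, px + hs - 1L, py + hs - 1L) -
    rect_sum(ii, px - hs, py - hs, px + hs - 1L, py - 1L)
  list(dx = dx, dy = dy)
}

# Dominant orientation (radians): Gaussian-weighted Haar responses in a
# radius-6s disc, summed over a sliding pi/3 window (standard SURF scheme).
assign_orientation <- function(ii, w, h, x, y, s) {
  hs <- max(1L, as.integer(round(2 * s)))
  grid <- expand.grid(i = -6:6, j = -6:6)
  grid <- grid[grid$i^2 + grid$j^2 <= 36, ]
  px <- as.integer(round(x + grid$i * s))
  py <- as.integer(round(y + grid$j * s))
  ok <- px - hs >= 0L & py - hs >= 0L & px + hs <= w - 1L & py + hs <= h - 1L
  if (sum(ok) < 5L) return(0)
  g <- exp(-(grid$i[ok]^2 + grid$j[ok]^2) / (2 * 2.5^2))
  r <- haar_xy(ii, px[ok], py[ok], hs)
  rx <- r$dx * g; ry <- r$dy * g
  ang <- atan2(ry, rx)
  cand <- seq(-pi, pi, length.out = 43L)[-43L]
  best <- 0; best_len <- -1
  for (a in cand) {
    d <- abs(((ang - a + pi) %% (2 * pi)) - pi)
    inwin <- d < pi / 6
    sx <- sum(rx[inwin]); sy <- sum(ry[inwin])
    len <- sx * sx + sy * sy
    if (len > best_len) { best_len <- len; best <- atan2(sy, sx) }
  }
  best
}

#' Compute SURF-style descriptors
#'
#' 64-dimensional descriptors: a 20s x 20s grid of Haar wavelet responses
#' (wavelet size 2s), Gaussian-weighted (sigma 3.3s), accumulated as
#' `(sum dx, sum dy, sum |dx|, sum |dy|)` over 4x4 subregions, then
#' unit-normalized. In upright mode (the default) no orientation is
#' assigned. Keypoints whose support window exits the image are dropped;
#' the returned matrix carries a logical attribute `kept` aligned with the
#' input keypoints.
#'
#' @param f a [fov()].
#' @param keypoints data.frame with columns `x, y, scale`.
#' @param cfg a [detector_config()].
#' @param ii precomputed integral image (optional).
#' @return n_kept x 64 numeric matrix with attribute `kept`.
#' @export
describe <- function(f, keypoints, cfg = detector_config(), ii = NULL) {
  img <- f$pixels
  h <- nrow(img); w <- ncol(img)
  if (is.null(ii)) ii <- integral_image(img)
  n <- nrow(keypoints)
  off <- seq(-9.5, 9.5, by = 1)
  G <- expand.grid(i = off, j = off)           # i varies fastest (x)
  block <- (findInterval(G$j, c(-4.5, 0.5, 5.5)) ) * 4 +
    findInterval(G$i, c(-4.5, 0.5, 5.5)) + 1   # 1..16, row-major in (j,i)
  gw <- exp(-(G$i^2 + G$j^2) / (2 * 3.3^2))
  out <- matrix(0, n, 64L)
  kept <- rep(TRUE, n)
  for (k in seq_len(n)) {
    x <- keypoints$x[k]; y <- keypoints$y[k]; s <- keypoints$scale[k]
    hs <- max(1L, as.integer(round(s)))
    theta <- if (cfg$upright) 0 else assign_orientation(ii, w, h, x, y, s)
    ct <- cos(theta); st <- sin(theta)
    gx <- G$i * s * ct - G$j * s * st
    gy <- G$i * s * st + G$j * s * ct
    px <- as.integer(round(x + gx))
    py <- as.integer(round(y + gy))
    if (min(px) - hs < 0L || min(py) - hs < 0L ||
        max(px) + hs > w - 1L || max(py) + hs > h - 1L) {
      kept[k] <- FALSE
      next
    }
    r <- haar_xy(ii, px, py, hs)
    # rotate responses into the keypoint frame
    dx <- gw * (r$dx * ct + r$dy * st)
    dy <- gw * (-r$dx * st + r$dy * ct)
    v <- numeric(64L)
    for (b in 1:16) {
      sel <- block == b
      v[(b - 1L) * 4L + 1:4] <- c(sum(dx[sel]), sum(dy[sel]),
                                  sum(abs(dx[sel])), sum(abs(dy[sel])))
    }
    nv <- sqrt(sum(v * v))
    out[k, ] <- v / max(nv, 1e-12)
  }
  res <- out[kept, , drop = FALSE]
  attr(res, "kept") <- kept
  res
}
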