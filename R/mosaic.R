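# Global placement, blending and tiled export of the virtual slide.

#' Solve global FoV placement from pairwise translations
#'
#' Positions minimize `sum_links || p_b - p_a - t_ab ||^2` with the anchor
#' FoV (lowest index) fixed at the origin — an ordinary linear least squares
#' on the translation graph, solved independently per axis via the QR
#' decomposition of the (reduced) incidence matrix. On consistent inputs
#' (translations derived from one true position assignment) the recovery is
#' exact up to the anchor.
#'
#' @param links list of [pair_link()]s with `t_server` set (or any list of
#'   `list(fov_a, fov_b, t_server)`).
#' @param fov_indices integer vector of accepted FoV indices to place; if
#'   missing, the union of link endpoints.
#' @return list of class `mosaic_layout`: `positions` (data.frame
#'   `fov, x, y`), `residuals` (per-link Euclidean residual), `bbox`.
#' @export
solve_layout <- function(links, fov_indices = NULL) {
  la <- vapply(links, function(l) as.integer(l$fov_a), integer(1))
  lb <- vapply(links, function(l) as.integer(l$fov_b), integer(1))
  nodes <- sort(unique(c(fov_indices, la, lb)))
  n <- length(nodes)
  if (n == 1L)
    return(structure(list(positions = data.frame(fov = nodes, x = 0, y = 0),
                          residuals = numeric(0),
                          bbox = c(0, 0, 0, 0)),
                     class = "mosaic_layout"))
  if (!length(links)) stopf("no links given for %d FoVs", n)
  g <- igraph::graph_from_edgelist(
    cbind(match(la, nodes), match(lb, nodes)), directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    parts <- split(nodes, comp$membership)
    stopf("link graph is disconnected: components {%s}",
          paste(vapply(parts, function(p) paste(p, collapse = ","),
                       character(1)), collapse = "} {"))
  }
  nl <- length(links)
  A <- matrix(0, nl, n)
  A[cbind(seq_len(nl), match(la, nodes))] <- -1
  A[cbind(seq_len(nl), match(lb, nodes))] <- 1
  tmat <- t(vapply(links, function(l) as.numeric(l$t_server), numeric(2)))
  Ared <- A[, -1L, drop = FALSE]          # anchor = first node, fixed at 0
  qrA <- qr(Ared)
  px <- c(0, qr.coef(qrA, tmat[, 1]))
  py <- c(0, qr.coef(qrA, tmat[, 2]))
  res <- sqrt((A %*% px - tmat[, 1])^2 + (A %*% py - tmat[, 2])^2)[, 1]
  structure(list(positions = data.frame(fov = nodes, x = px, y = py),
                 residuals = res,
                 bbox = c(min(px), min(py), max(px), max(py))),
            class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf("<mosaic_layout: %d FoVs, max link residual %.3f px>\n",
              nrow(x$positions),
              if (length(x$residuals)) max(x$residuals) else 0))
  invisible(x)
}

# Feathering weight of one FoV: distance (px) to the nearest invalid pixel
# or image border, zero on invalid pixels.
feather_weight <- function(f) {
  mask <- f$valid %||% matrix(TRUE, nrow(f$pixels), ncol(f$pixels))
  chamfer_distance(mask)
}

#' Render the virtual slide canvas
#'
#' Places every FoV at its (rounded) layout position and blends overlaps
#' with validity-aware feathering: each FoV contributes with weight equal to
#' the distance from its nearest invalid pixel or edge, so seams fade
#' linearly instead of cutting. Pixels covered by no valid FoV are masked
#' out. The canvas is quantized to the 8-bit grid so that tiled export
#' round-trips bit-exactly.
#'
#' @param layout a `mosaic_layout` covering the FoVs.
#' @param fovs list of (corrected) [fov()]s, indices matching the layout.
#' @return list of class `virtual_slide`: `canvas` (h x w in `[0,1]`),
#'   `mask` (logical), `origin` (canvas (0,0) in layout coords),
#'   `tile_size`.
#' @export
render <- function(layout, fovs, tile_size = 256L) {
  idx <- vapply(fovs, function(f) f$index, integer(1))
  pos <- layout$positions
  if (!all(pos$fov %in% idx)) stopf("layout references FoVs not supplied")
  d <- fov_dim(fovs[[1]])
  w <- d[["w"]]; h <- d[["h"]]
  ox <- floor(min(pos$x)); oy <- floor(min(pos$y))
  cw <- ceiling(max(pos$x) + w) - ox
  ch <- ceiling(max(pos$y) + h) - oy
  if (cw <= 0 || ch <= 0) stopf("zero-area bounding box")
  num <- matrix(0, ch, cw); den <- matrix(0, ch, cw)
  for (i in seq_len(nrow(pos))) {
    f <- fovs[[match(pos$fov[i], idx)]]
    wgt <- feather_weight(f)
    x0 <- round(pos$x[i]) - ox          # integer placement at render time
    y0 <- round(pos$y[i]) - oy
    rows <- (y0 + 1L):(y0 + h)
    cols <- (x0 + 1L):(x0 + w)
    num[rows, cols] <- num[rows, cols] + wgt * f$pixels
    den[rows, cols] <- den[rows, cols] + wgt
  }
  mask <- den > 0
  canvas <- matrix(0, ch, cw)
  canvas[mask] <- num[mask] / den[mask]
  structure(list(canvas = quantize8(canvas), mask = mask,
                 origin = c(ox, oy), tile_size = as.integer(tile_size)),
            class = "virtual_slide")
}

#' @export
print.virtual_slide <- function(x, ...) {
  cat(sprintf("<virtual_slide: %dx%d canvas, %.0f%% covered, tile %d>\n",
              ncol(x$canvas), nrow(x$canvas), 100 * mean(x$mask),
              x$tile_size))
  invisible(x)
}

# Ceil-half box downsampling of canvas + mask; averages the valid children
# of each 2x2 (or ragged edge) block.
pyramid_down <- function(canvas, mask) {
  h <- nrow(canvas); w <- ncol(canvas)
  gr <- (seq_len(h) - 1L) %/% 2L + 1L
  gc <- (seq_len(w) - 1L) %/% 2L + 1L
  sum_v <- t(rowsum(t(rowsum(canvas * mask, gr)), gc))
  cnt <- t(rowsum(t(rowsum(mask * 1, gr)), gc))
  m2 <- cnt > 0
  v <- matrix(0, nrow(sum_v), ncol(sum_v))
  v[m2] <- sum_v[m2] / cnt[m2]
  list(canvas = quantize8(v), mask = m2)
}

#' Export a virtual slide as a tiled image pyramid
#'
#' DeepZoom-style layout: an XML descriptor (`slide.dzi`) plus one
#' directory of PNG tiles per level under `slide_files/`. Level 0 is the
#' full-resolution canvas; level L is its factor-2^L box-downsample; the
#' top level's largest dimension is at most the tile size. Tiles are
#' written as gray+alpha PNGs (alpha = coverage mask) so that reassembling
#' the level-0 tiles reproduces the canvas bit-exactly.
#'
#' @param vs a `virtual_slide`.
#' @param out_dir output directory (created).
#' @return path to the descriptor file.
#' @export
export_pyramid <- function(vs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create directory: %s", out_dir)
  ts <- vs$tile_size
  levels <- list(list(canvas = vs$canvas, mask = vs$mask))
  while (max(dim(levels[[length(levels)]]$canvas)) > ts) {
    lv <- levels[[length(levels)]]
    levels[[length(levels) + 1L]] <- pyramid_down(lv$canvas, lv$mask)
  }
  files_dir <- file.path(out_dir, "slide_files")
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    ld <- file.path(files_dir, li - 1L)
    dir.create(ld, recursive = TRUE, showWarnings = FALSE)
    h <- nrow(lv$canvas); w <- ncol(lv$canvas)
    for (ty in seq_len(ceiling(h / ts)) - 1L) {
      for (tx in seq_len(ceiling(w / ts)) - 1L) {
        rows <- (ty * ts + 1L):min((ty + 1L) * ts, h)
        cols <- (tx * ts + 1L):min((tx + 1L) * ts, w)
        tile <- array(0, dim = c(length(rows), length(cols), 2L))
        tile[, , 1] <- lv$canvas[rows, cols]
        tile[, , 2] <- lv$mask[rows, cols] * 1
        png::writePNG(tile, file.path(ld, sprintf("%d_%d.png", tx, ty)))
      }
    }
  }
  doc <- xml2::xml_new_root("Image",
                            xmlns = "http://schemas.microsoft.com/deepzoom/2008",
                            TileSize = as.character(ts), Overlap = "0",
                            Format = "png",
                            Levels = as.character(length(levels)))
  xml2::xml_add_child(doc, "Size", Width = as.character(ncol(vs$canvas)),
                      Height = as.character(nrow(vs$canvas)))
  desc <- file.path(out_dir, "slide.dzi")
  xml2::write_xml(doc, desc)
  desc
}

#' Reassemble one pyramid level from exported tiles
#'
#' Inverse of [export_pyramid()] for verification: pastes the tiles of a
#' level back into a canvas + mask.
#'
#' @param out_dir directory passed to [export_pyramid()].
#' @param level level index (0 = full resolution).
#' @return list `canvas`, `mask`.
#' @export
reassemble_level <- function(out_dir, level = 0L) {
  ld <- file.path(out_dir, "slide_files", level)
  tiles <- list.files(ld, pattern = "^\\d+_\\d+\\.png$")
  if (!length(tiles)) stopf("no tiles found in %s", ld)
  coords <- do.call(rbind, lapply(strsplit(sub("\\.png$", "", tiles), "_"),
                                  as.integer))
  arrs <- lapply(seq_along(tiles),
                 function(i) png::readPNG(file.path(ld, tiles[i])))
  # any non-edge tile has the full tile size; a lone tile needs none
  ts <- max(vapply(arrs, function(a) max(dim(a)[1:2]), numeric(1)))
  w <- 0L; h <- 0L
  for (i in seq_along(arrs)) {
    w <- max(w, coords[i, 1] * ts + dim(arrs[[i]])[2])
    h <- max(h, coords[i, 2] * ts + dim(arrs[[i]])[1])
  }
  canvas <- matrix(0, h, w); mask <- matrix(FALSE, h, w)
  for (i in seq_along(arrs)) {
    a <- arrs[[i]]
    rows <- (coords[i, 2] * ts + 1L):(coords[i, 2] * ts + dim(a)[1])
    cols <- (coords[i, 1] * ts + 1L):(coords[i, 1] * ts + dim(a)[2])
    canvas[rows, cols] <- a[, , 1]
    mask[rows, cols] <- a[, , 2] > 0.5
  }
  list(canvas = canvas, mask = mask)
}

#' Normalized cross-correlation of a rendered mosaic against ground truth
#'
#' Samples the true slide image at every covered canvas pixel (using the
#' known true position of the anchor FoV to place the canvas in slide
#' coordinates) and returns the Pearson correlation over covered pixels.
#' Evaluation-only: consumes ground truth, so pipelines must not call it.
#'
#' @param vs a `virtual_slide` from [render()].
#' @param layout the `mosaic_layout` used to render.
#' @param slide_img true slide image matrix.
#' @param anchor_true true `c(x, y)` slide position of the anchor (first)
#'   FoV in the layout.
#' @return correlation in `[-1, 1]`.
#' @export
mosaic_fidelity <- function(vs, layout, slide_img, anchor_true) {
  ch <- nrow(vs$canvas); cw <- ncol(vs$canvas)
  gx <- rep(0:(cw - 1L), each = ch) + vs$origin[1] + anchor_true[1]
  gy <- rep(0:(ch - 1L), times = cw) + vs$origin[2] + anchor_true[2]
  truth <- matrix(bilinear_sample(slide_img, gx, gy), ch, cw)
  sel <- vs$mask & !is.na(truth)
  stats::cor(vs$canvas[sel], truth[sel])
}
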