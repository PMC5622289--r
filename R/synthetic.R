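# Deterministic ground-truthed synthetic scans.
#
# The generator emulates what the stitching pipeline actually consumes: a
# histology-like slide (smooth illumination + dark elliptical "nuclei" +
# fine speckle), an unknown radial lens distortion applied to every captured
# frame, a serpentine field-of-view path with seeded jitter, and injected
# operator faults (blank / defocused / jumped frames) that exercise each
# tracker guidance code. Every byte is reproducible from (config, seed).

#' Synthetic scan configuration
#'
#' @param slide_dim slide size `c(width, height)` in px.
#' @param seed integer seed; all randomness in the generator derives from it.
#' @param nucleus_density nuclei per pixel (default 6e-4, ~100 nuclei per
#'   480x360 FoV).
#' @param nucleus_radius radius range `c(min, max)` in px.
#' @param texture_sd amplitude of the fine per-pixel speckle (default 0.02).
#' @param stromal_sd,stromal_scale amplitude (default 0.05) and grain size
#'   in px (default 6) of the band-limited "stromal" background texture —
#'   the cytoplasm/stroma granularity that, like real tissue, gives the
#'   detector stable structure between nuclei at both resolution tiers.
#' @param distortion radial distortion coefficients `c(k1, k2)` of the
#'   inverse-distortion map `P(u) = u * (1 + k1 |u|^2 + k2 |u|^4)` in
#'   normalized coordinates, or `NULL` for no distortion.
#' @param fov_dim FoV size `c(width, height)` in full-resolution px.
#' @param overlap nominal overlap fraction between adjacent FoVs, in (0, 0.9).
#' @param jitter_sd standard deviation of the per-step stage jitter in px.
#' @param faults list of `list(frame = stream index (0-based), type =
#'   "blank"|"blur"|"jump")`; fault frames are inserted into the capture
#'   stream at those indices and do not advance the serpentine path.
#' @param downsample_ratio integer client downsampling ratio (FoV dims must
#'   be divisible by it).
#' @param grid optional `c(ncols, nrows)` FoV grid; `NULL` fits the largest
#'   grid inside the slide.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(slide_dim = c(1664L, 1280L), seed = 1L,
                             nucleus_density = 6e-4,
                             nucleus_radius = c(5, 10), texture_sd = 0.02,
                             stromal_sd = 0.05, stromal_scale = 6,
                             distortion = NULL, fov_dim = c(480L, 360L),
                             overlap = 0.3, jitter_sd = 1,
                             faults = list(), downsample_ratio = 2L,
                             grid = NULL) {
  if (overlap <= 0 || overlap >= 0.9) stopf("overlap must be in (0, 0.9)")
  if (any(fov_dim >= slide_dim)) stopf("fov_dim must be smaller than slide_dim")
  if (any(fov_dim %% downsample_ratio != 0))
    stopf("fov_dim must be divisible by downsample_ratio")
  structure(list(slide_dim = as.integer(slide_dim), seed = as.integer(seed),
                 nucleus_density = nucleus_density,
                 nucleus_radius = nucleus_radius, texture_sd = texture_sd,
                 stromal_sd = stromal_sd, stromal_scale = stromal_scale,
                 distortion = distortion, fov_dim = as.integer(fov_dim),
                 overlap = overlap, jitter_sd = jitter_sd, faults = faults,
                 downsample_ratio = as.integer(downsample_ratio),
                 grid = grid),
            class = "synthetic_config")
}

#' Generate a procedural histology-like slide image
#'
#' @param cfg a [synthetic_config()].
#' @return list with `image` (h x w matrix in `[0,1]`, quantized to the
#'   8-bit grid) and `blobs` (data.frame `x, y, r` of nucleus centers and
#'   radii, 0-based px).
#' @export
generate_slide <- function(cfg) {
  w <- cfg$slide_dim[1]; h <- cfg$slide_dim[2]
  withr::with_seed(cfg$seed, {
    xs <- 0:(w - 1L); ys <- 0:(h - 1L)
    img <- matrix(0.88, h, w)
    for (i in 1:3) {  # smooth illumination field
      fx <- stats::runif(1, 0.5, 2) * 2 * pi / w
      fy <- stats::runif(1, 0.5, 2) * 2 * pi / h
      ph <- stats::runif(2, 0, 2 * pi)
      amp <- stats::runif(1, 0.01, 0.03)
      img <- img + amp * outer(cos(fy * ys + ph[2]), cos(fx * xs + ph[1]))
    }
    n <- round(cfg$nucleus_density * w * h)
    blobs <- data.frame(
      x = stats::runif(n, 2, w - 3), y = stats::runif(n, 2, h - 3),
      r = stats::runif(n, cfg$nucleus_radius[1], cfg$nucleus_radius[2]))
    depth <- stats::runif(n, 0.3, 0.5)
    aspect <- stats::runif(n, 0.65, 1)
    ang <- stats::runif(n, 0, pi)
    for (i in seq_len(n)) {
      r <- blobs$r[i]
      m <- ceiling(r + 4)
      x0 <- max(0, floor(blobs$x[i] - m)); x1 <- min(w - 1, ceiling(blobs$x[i] + m))
      y0 <- max(0, floor(blobs$y[i] - m)); y1 <- min(h - 1, ceiling(blobs$y[i] + m))
      gx <- x0:x1; gy <- y0:y1
      dx <- outer(rep(1, length(gy)), gx - blobs$x[i])
      dy <- outer(gy - blobs$y[i], rep(1, length(gx)))
      ct <- cos(ang[i]); st <- sin(ang[i])
      u <- dx * ct + dy * st
      v <- (-dx * st + dy * ct) / aspect[i]
      q <- sqrt(u * u + v * v)
      prof <- depth[i] / (1 + exp((q - r) / 0.8))  # soft-edged disc
      img[gy + 1L, gx + 1L] <- img[gy + 1L, gx + 1L] - prof
    }
    # band-limited stromal texture: white noise on a coarse grid,
    # bilinearly upsampled to bumps of ~stromal_scale px
    cs <- cfg$stromal_scale
    cw <- ceiling(w / cs) + 2L; chh <- ceiling(h / cs) + 2L
    coarse <- matrix(stats::rnorm(cw * chh), chh, cw)
    gx <- rep(xs / cs, each = h); gy <- rep(ys / cs, times = w)
    img <- img + cfg$stromal_sd *
      matrix(bilinear_sample(coarse, gx, gy, fill = 0), h, w)
    img <- img + matrix(stats::runif(w * h, -1, 1) * cfg$texture_sd, h, w)
    list(image = quantize8(img), blobs = blobs)
  })
}

# Inverse-distortion map P (normalized coords): u * (1 + k1 r^2 + k2 r^4).
# This is what a captured (raw) frame position must be mapped through to
# land in the corrected space; it is a degree-5 polynomial.
radial_correct <- function(u, k) {
  r2 <- rowSums(u * u)
  u * (1 + k[1] * r2 + k[2] * r2 * r2)
}

# Forward lens distortion g = P^{-1} (corrected -> raw), solved per point by
# Newton iteration on the radius.
radial_distort <- function(v, k) {
  rv <- sqrt(rowSums(v * v))
  r <- rv
  for (i in 1:30) {
    fr <- r * (1 + k[1] * r^2 + k[2] * r^4) - rv
    dfr <- 1 + 3 * k[1] * r^2 + 5 * k[2] * r^4
    r <- r - fr / dfr
  }
  scale <- ifelse(rv > 0, r / rv, 1)
  v * scale
}

#' Generate a serpentine scan of a synthetic slide
#'
#' The path visits a row-major serpentine grid with step
#' `(1 - overlap) * fov_dim` plus seeded Gaussian jitter. Each captured
#' frame is the slide content seen through the lens: the pixel at raw
#' position `u` records the slide at `pos + center + R * P(u_n)` where `P`
#' is the radial inverse-distortion polynomial — so the configured
#' `distortion` coefficients are exactly what a perfect correction would
#' recover. Fault frames are inserted at the configured
#' stream indices: `blank` (constant intensity), `blur` (defocused: content
#' destroyed, noise remains) and `jump` (captured 75% of a FoV width away,
#' exceeding the tracker's overlap floor).
#'
#' @param slide output of [generate_slide()] (or any list with `image`).
#' @param cfg a [synthetic_config()].
#' @return A list of class `synthetic_scan`: `session` (a [scan_session()]
#'   of full-resolution frames), `client_fovs` (downsampled client-tier
#'   [fov()]s, same stream indices), `truth` (data.frame per stream frame:
#'   `frame, path_index, x, y, fault, expected_status`), `slide`, `cfg`.
#' @export
generate_scan <- function(slide, cfg) {
  w <- cfg$fov_dim[1]; h <- cfg$fov_dim[2]
  sw <- ncol(slide$image); sh <- nrow(slide$image)
  geom <- norm_geometry(w, h)
  k <- cfg$distortion
  max_disp <- if (is.null(k)) 0 else geom$scale * (abs(k[1]) + abs(k[2])) + 1
  margin <- ceiling(max_disp + 3 * cfg$jitter_sd + 2)
  step <- (1 - cfg$overlap) * c(w, h)
  avail <- c(sw, sh) - c(w, h) - 2 * margin
  if (any(avail < 0)) stopf("slide too small for FoV plus margins")
  grid <- cfg$grid %||% (floor(avail / step) + 1L)
  nx <- grid[1]; ny <- grid[2]
  if ((nx - 1) * step[1] > avail[1] || (ny - 1) * step[2] > avail[2])
    stopf("scan path would exit the slide: grid %dx%d does not fit", nx, ny)

  withr::with_seed(cfg$seed + 1L, {
    path <- list()
    for (r in 0:(ny - 1L)) {
      cols <- if (r %% 2L == 0L) 0:(nx - 1L) else (nx - 1L):0
      for (cc in cols) path[[length(path) + 1L]] <- c(cc, r)
    }
    npath <- length(path)
    jit <- matrix(stats::rnorm(2L * npath, 0, cfg$jitter_sd), ncol = 2L)
    jit[1, ] <- 0
    pos <- t(vapply(seq_len(npath), function(i)
      margin + c(path[[i]][1] * step[1], path[[i]][2] * step[2]) + jit[i, ],
      numeric(2)))

    # assemble the capture stream: path frames plus inserted faults
    fault_at <- vapply(cfg$faults, function(f) as.integer(f$frame), integer(1))
    fault_ty <- vapply(cfg$faults, function(f) f$type, character(1))
    n_stream <- npath + length(fault_at)
    truth <- data.frame(frame = 0:(n_stream - 1L), path_index = NA_integer_,
                        x = NA_real_, y = NA_real_, fault = "none",
                        expected_status = "no_error",
                        stringsAsFactors = FALSE)
    fovs_full <- vector("list", n_stream)
    client <- vector("list", n_stream)
    pi_next <- 1L
    bg <- mean(slide$image)
    for (s in 0:(n_stream - 1L)) {
      fi <- match(s, fault_at)
      if (!is.na(fi)) {
        ty <- fault_ty[fi]
        base_pos <- pos[max(pi_next - 1L, 1L), ]
        if (ty == "blank") {
          frame <- matrix(quantize8(bg), h, w)
          truth$expected_status[s + 1L] <- "touching_boundary"
        } else if (ty == "blur") {
          # defocus: smooth blob mush uncorrelated with the slide — plenty
          # of keypoints, none of which match the reference frame
          cw <- ceiling(w / 8) + 2L; chh <- ceiling(h / 8) + 2L
          coarse <- matrix(stats::rnorm(cw * chh), chh, cw)
          bx <- rep((0:(w - 1L)) / 8, each = h)
          by <- rep((0:(h - 1L)) / 8, times = w)
          frame <- quantize8(bg +
            0.12 * matrix(bilinear_sample(coarse, bx, by, fill = 0), h, w))
          truth$expected_status[s + 1L] <- "lost"
        } else if (ty == "jump") {
          dirx <- if (base_pos[1] + 0.75 * w + w + margin <= sw) 1 else -1
          jpos <- base_pos + c(dirx * 0.75 * w, 0)
          frame <- capture_frame(slide$image, jpos, w, h, geom, k)
          truth$x[s + 1L] <- jpos[1]; truth$y[s + 1L] <- jpos[2]
          truth$expected_status[s + 1L] <- "moving_too_fast"
        } else stopf("unknown fault type '%s'", ty)
        truth$fault[s + 1L] <- ty
      } else {
        p <- pos[pi_next, ]
        frame <- capture_frame(slide$image, p, w, h, geom, k)
        truth$path_index[s + 1L] <- pi_next - 1L
        truth$x[s + 1L] <- p[1]; truth$y[s + 1L] <- p[2]
        pi_next <- pi_next + 1L
      }
      fovs_full[[s + 1L]] <- fov(s, frame, tier = "server_full")
      client[[s + 1L]] <- fov(s, downsample_block(frame, cfg$downsample_ratio),
                              tier = "client_downsampled",
                              downsample_ratio = cfg$downsample_ratio)
    }
    structure(list(session = scan_session(fovs_full, w, h,
                                          downsample_ratio = cfg$downsample_ratio),
                   client_fovs = client, truth = truth, slide = slide,
                   cfg = cfg),
              class = "synthetic_scan")
  })
}

# One captured frame: bilinear sample of the slide through the forward
# distortion. `p` is the true (corrected-space) top-left position.
capture_frame <- function(slide_img, p, w, h, geom, k) {
  gx <- rep(0:(w - 1L), each = h)
  gy <- rep(0:(h - 1L), times = w)
  if (is.null(k)) {
    sx <- p[1] + gx
    sy <- p[2] + gy
  } else {
    # the lens maps slide point s to sensor position u = P^-1(s - pos), so
    # the raw pixel at u sees the slide at pos + P(u): capture samples
    # through the inverse-distortion polynomial itself
    un <- cbind((gx - geom$center[1]) / geom$scale,
                (gy - geom$center[2]) / geom$scale)
    d <- radial_correct(un, k)
    sx <- p[1] + geom$center[1] + geom$scale * d[, 1]
    sy <- p[2] + geom$center[2] + geom$scale * d[, 2]
  }
  v <- bilinear_sample(slide_img, sx, sy, fill = mean(slide_img))
  quantize8(matrix(v, h, w))
}

# Integer block-average downsampling (client tier), re-quantized.
downsample_block <- function(img, d) {
  if (d == 1L) return(img)
  h <- nrow(img); w <- ncol(img)
  a <- rowsum(img, rep(seq_len(h %/% d), each = d))        # (h/d) x w
  b <- t(rowsum(t(a), rep(seq_len(w %/% d), each = d)))    # (h/d) x (w/d)
  quantize8(b / (d * d))
}

#' Save the ground truth of a synthetic scan
#'
#' Written as a sibling `truth.json` that pipeline commands refuse to read;
#' only evaluation code should consume it.
#'
#' @param scan a `synthetic_scan`.
#' @param dir session directory.
#' @return The path to `truth.json`.
#' @export
save_ground_truth <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(distortion = scan$cfg$distortion, truth = scan$truth,
         seed = scan$cfg$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  path
}

# Synthesized keypoint-match links for distortion-fit tests and benchmarks:
# random overlapping pair geometries, matched points sampled in the overlap,
# observed at their distorted (raw) coordinates, with optional localization
# noise. Returns links in the form fit_hop() consumes.
#' Synthesize distorted pairwise matches with known geometry
#'
#' Builds `n_pairs` overlapping FoV-pair geometries and, for each, a set of
#' matched point observations at their raw (distorted) coordinates — the
#' exact situation [fit_hop()] faces, with the truth known in closed form.
#'
#' @param fov_dim FoV size `c(w, h)`.
#' @param k radial coefficients `c(k1, k2)` of the true inverse-distortion
#'   polynomial (see [synthetic_config()]), or `NULL` for identity.
#' @param n_pairs number of FoV pairs (default 12).
#' @param n_matches matched points per pair (default 60).
#' @param noise_sd localization noise added to raw coordinates, px.
#' @param seed RNG seed.
#' @param overlap nominal overlap fraction of each pair.
#' @return list with `links` (each `list(fov_a, fov_b, uA, uB)`, raw px
#'   coordinates) and `t_true` (n_pairs x 2 true translations).
#' @export
synth_hop_links <- function(fov_dim, k, n_pairs = 12L, n_matches = 60L,
                            noise_sd = 0, seed = 1L, overlap = 0.4) {
  w <- fov_dim[1]; h <- fov_dim[2]
  geom <- norm_geometry(w, h)
  to_raw <- function(u_px) {
    un <- sweep(u_px, 2L, geom$center) / geom$scale
    d <- if (is.null(k)) un else radial_distort(un, k)
    sweep(d * geom$scale, 2L, geom$center, "+")
  }
  withr::with_seed(seed, {
    links <- vector("list", n_pairs)
    t_true <- matrix(0, n_pairs, 2L)
    for (i in seq_len(n_pairs)) {
      horiz <- i %% 2L == 0L
      tmag <- stats::runif(1, 1 - overlap - 0.1, 1 - overlap + 0.1)
      t <- if (horiz) c(tmag * w, stats::rnorm(1, 0, 3))
           else c(stats::rnorm(1, 0, 3), tmag * h)
      if (i %% 4L < 2L) t <- -t
      lo <- pmax(c(0, 0), t)       # overlap box in A's ideal coords
      hi <- pmin(c(w - 1, h - 1), c(w - 1, h - 1) + t)
      uA <- cbind(stats::runif(n_matches, lo[1] + 2, hi[1] - 2),
                  stats::runif(n_matches, lo[2] + 2, hi[2] - 2))
      uB <- sweep(uA, 2L, t)       # ideal coords in B
      rawA <- to_raw(uA) + stats::rnorm(2L * n_matches, 0, noise_sd)
      rawB <- to_raw(uB) + stats::rnorm(2L * n_matches, 0, noise_sd)
      links[[i]] <- list(fov_a = 2L * i - 2L, fov_b = 2L * i - 1L,
                         uA = rawA, uB = rawB)
      t_true[i, ] <- t
    }
    list(links = links, t_true = t_true)
  })
}
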