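# Session containers and on-disk formats.
#
# Coordinate conventions (used by every module):
#   * pixel coordinates are 0-based, (x right, y down), origin at the
#     top-left pixel of each field of view (FoV);
#   * normalized FoV-local coordinates place the origin at the image center
#     ((w-1)/2, (h-1)/2) and divide by half the image diagonal, so the image
#     fits in the unit disk;
#   * the translation t_AB between FoVs A and B is the global position of B
#     minus the global position of A: a slide point at local position u in A
#     appears at u - t_AB in B.

TIERS <- c("client_downsampled", "server_full")
LINK_STATUSES <- c("no_error", "moving_too_fast", "lost", "touching_boundary",
                   "lost_with_prior")

#' Construct a field of view
#'
#' A FoV is one captured camera frame. The grayscale working copy (`pixels`)
#' is what detection and matching operate on; an optional RGB array is kept
#' for rendering. Intensities are stored in `[0, 1]`.
#'
#' @param index 0-based capture order integer, unique within a session.
#' @param pixels numeric h x w matrix in `[0, 1]` (grayscale working copy).
#' @param tier `"client_downsampled"` or `"server_full"`.
#' @param downsample_ratio full-resolution pixels per downsampled pixel
#'   (>= 1); must be exactly 1 for the `server_full` tier.
#' @param rgb optional h x w x 3 array in `[0, 1]`.
#' @param valid optional logical h x w validity mask (e.g. after distortion
#'   correction); `NULL` means all pixels valid.
#' @return An object of class `fov`.
#' @export
fov <- function(index, pixels, tier = "server_full", downsample_ratio = 1,
                rgb = NULL, valid = NULL) {
  tier <- match.arg(tier, TIERS)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stopf("FoV %d: pixels must be a non-empty matrix", index)
  if (tier == "server_full" && downsample_ratio != 1)
    stopf("FoV %d: downsample_ratio must be 1 for server_full tier", index)
  if (downsample_ratio < 1)
    stopf("FoV %d: downsample_ratio must be >= 1", index)
  structure(list(index = as.integer(index), pixels = pixels, tier = tier,
                 downsample_ratio = downsample_ratio, rgb = rgb,
                 valid = valid),
            class = "fov")
}

fov_dim <- function(f) c(w = ncol(f$pixels), h = nrow(f$pixels))

#' @export
print.fov <- function(x, ...) {
  cat(sprintf("<fov #%d %dx%d %s ratio=%g>\n", x$index, ncol(x$pixels),
              nrow(x$pixels), x$tier, x$downsample_ratio))
  invisible(x)
}

#' Construct a pair link
#'
#' Records the estimated relationship between two FoVs: the client-side
#' translation in downsampled pixels, the server-side translation in
#' full-resolution corrected pixels (the pair's "phase difference"), the
#' match set it came from, and the tracker status code.
#'
#' @param fov_a,fov_b FoV indices (`fov_a != fov_b`).
#' @param t_client optional length-2 numeric, downsampled px.
#' @param t_server optional length-2 numeric, full-resolution corrected px;
#'   only allowed when `status == "no_error"`.
#' @param matches optional `match_set` (see [match_brute_force()]).
#' @param status one of `no_error`, `moving_too_fast`, `lost`,
#'   `touching_boundary`, `lost_with_prior`.
#' @return An object of class `pair_link`.
#' @export
pair_link <- function(fov_a, fov_b, t_client = NULL, t_server = NULL,
                      matches = NULL, status = "no_error") {
  status <- match.arg(status, LINK_STATUSES)
  if (fov_a == fov_b) stopf("pair_link: fov_a must differ from fov_b")
  if (!is.null(t_server) && status != "no_error")
    stopf("pair_link: t_server only allowed when status is no_error")
  structure(list(fov_a = as.integer(fov_a), fov_b = as.integer(fov_b),
                 t_client = t_client, t_server = t_server,
                 matches = matches, status = status),
            class = "pair_link")
}

#' Construct a scan session
#'
#' @param fovs list of [fov()] objects in strictly increasing capture order.
#' @param fov_width,fov_height full-resolution FoV pixel dimensions.
#' @param downsample_ratio client-tier downsampling ratio.
#' @param pair_links list of [pair_link()] objects (filled during processing).
#' @param magnification_label free-text metadata, e.g. `"20X"`.
#' @return An object of class `scan_session`.
#' @export
scan_session <- function(fovs, fov_width, fov_height, downsample_ratio = 1,
                         pair_links = list(), magnification_label = "") {
  idx <- vapply(fovs, function(f) f$index, integer(1))
  if (anyDuplicated(idx)) stopf("scan_session: duplicate FoV indices")
  if (is.unsorted(idx, strictly = TRUE))
    stopf("scan_session: capture order must be strictly increasing")
  for (f in fovs) {
    d <- fov_dim(f)
    exp_d <- if (f$tier == "server_full") c(fov_width, fov_height)
             else c(round(fov_width / downsample_ratio),
                    round(fov_height / downsample_ratio))
    if (d[["w"]] != exp_d[1] || d[["h"]] != exp_d[2])
      stopf("scan_session: FoV %d has dimensions %dx%d, expected %dx%d",
            f$index, d[["w"]], d[["h"]], exp_d[1], exp_d[2])
  }
  structure(list(fovs = fovs, fov_width = as.integer(fov_width),
                 fov_height = as.integer(fov_height),
                 downsample_ratio = downsample_ratio,
                 pair_links = pair_links,
                 magnification_label = magnification_label),
            class = "scan_session")
}

#' @export
print.scan_session <- function(x, ...) {
  cat(sprintf("<scan_session: %d FoVs %dx%d, ratio=%g, %d links>\n",
              length(x$fovs), x$fov_width, x$fov_height,
              x$downsample_ratio, length(x$pair_links)))
  invisible(x)
}

# ---- image file I/O (PNG) --------------------------------------------------

read_fov_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) list(gray = a, rgb = NULL)
  else if (dim(a)[3] >= 3L)
    list(gray = rgb_to_gray(a[, , 1:3, drop = FALSE]), rgb = a[, , 1:3])
  else list(gray = a[, , 1], rgb = NULL)
}

write_fov_image <- function(f, path) {
  img <- if (!is.null(f$rgb)) f$rgb else f$pixels
  png::writePNG(img, path)
  path
}

# ---- manifest I/O ----------------------------------------------------------

#' Save a scan session to a directory
#'
#' Writes one PNG per FoV plus a JSON manifest with keys
#' `{fov_width, fov_height, downsample_ratio, fovs:[{index, path, tier}]}`.
#' Pair links, when present, are serialized alongside under `pair_links`
#' (match sets are dropped; translations and statuses survive the round
#' trip). Image paths are relative to the manifest location.
#'
#' @param session a [scan_session()].
#' @param dir output directory (created if needed).
#' @return Path to the written `manifest.json`, invisibly usable by
#'   [load_session()].
#' @export
save_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create directory: %s", dir)
  entries <- lapply(session$fovs, function(f) {
    rel <- sprintf("fov_%04d_%s.png", f$index,
                   if (f$tier == "server_full") "full" else "client")
    write_fov_image(f, file.path(dir, rel))
    list(index = f$index, path = rel, tier = f$tier,
         downsample_ratio = f$downsample_ratio)
  })
  links <- lapply(session$pair_links, function(l) {
    out <- list(fov_a = l$fov_a, fov_b = l$fov_b, status = l$status)
    if (!is.null(l$t_client)) out$t_client <- as.numeric(l$t_client)
    if (!is.null(l$t_server)) out$t_server <- as.numeric(l$t_server)
    out
  })
  manifest <- list(fov_width = session$fov_width,
                   fov_height = session$fov_height,
                   downsample_ratio = session$downsample_ratio,
                   magnification_label = session$magnification_label,
                   fovs = entries, pair_links = links)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Load a scan session from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [save_session()] (or assembled by hand with the same keys).
#' @return A [scan_session()] with pixel data loaded.
#' @export
load_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stopf("manifest not found: %s", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  fovs <- lapply(m$fovs, function(e) {
    img <- read_fov_image(file.path(base, e$path))
    fov(index = e$index, pixels = img$gray, tier = e$tier,
        downsample_ratio = e$downsample_ratio %||% 1, rgb = img$rgb)
  })
  links <- lapply(m$pair_links %||% list(), function(l) {
    pair_link(l$fov_a, l$fov_b,
              t_client = if (!is.null(l$t_client)) as.numeric(l$t_client),
              t_server = if (!is.null(l$t_server)) as.numeric(l$t_server),
              status = l$status)
  })
  scan_session(fovs, fov_width = m$fov_width, fov_height = m$fov_height,
               downsample_ratio = m$downsample_ratio %||% 1,
               pair_links = links,
               magnification_label = m$magnification_label %||% "")
}

# ---- diagnosis records -----------------------------------------------------

DIAG_CATEGORIES <- c("breast", "uterine_corpus", "thyroid", "lung", "ovary")
DIAG_MODALITIES <- c("optical", "swsi_vs", "scanner_vs")
DIAG_CLASSES <- c("accurate", "lsen", "lspe")

#' Load slide-level diagnosis records
#'
#' Reads a CSV with header columns `sample_id, category, modality, rater_id,
#' classification`, one diagnosed slide per row. `classification` is the
#' three-way slide-level call: `accurate`, `lsen` (a critical region of
#' interest was missed) or `lspe` (all regions found but a pattern misread).
#'
#' @param csv_path path to the CSV file.
#' @return A data.frame with the five columns above, one row per record.
#' @export
load_diagnosis_records <- function(csv_path) {
  if (!file.exists(csv_path)) stopf("records file not found: %s", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        comment.char = "#")
  need <- c("sample_id", "category", "modality", "rater_id", "classification")
  if (!all(need %in% names(df)))
    stopf("records CSV must have columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  bad <- which(!(df$category %in% DIAG_CATEGORIES))
  if (length(bad))
    stopf("row %d: unknown category '%s'", bad[1], df$category[bad[1]])
  bad <- which(!(df$modality %in% DIAG_MODALITIES))
  if (length(bad))
    stopf("row %d: unknown modality '%s'", bad[1], df$modality[bad[1]])
  bad <- which(!(df$classification %in% DIAG_CLASSES))
  if (length(bad))
    stopf("row %d: unknown classification '%s'", bad[1],
          df$classification[bad[1]])
  df
}

# Normalized FoV-local coordinates: origin at the image center, scaled by
# half the image diagonal so the image fits in the unit disk.
norm_geometry <- function(w, h) {
  list(center = c((w - 1) / 2, (h - 1) / 2),
       scale = sqrt((w - 1)^2 + (h - 1)^2) / 2)
}
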