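# Client-side real-time scan tracking.
#
# Each incoming downsampled frame is matched against the last *accepted*
# frame and classified by a finite-state machine into one of four guidance
# codes shown to the operator:
#   touching_boundary - too few keypoints (FoV likely near the slide edge),
#   lost              - no reliable translation (defocus or no overlap),
#   moving_too_fast   - translation exceeds the overlap floor,
#   no_error          - translation reliable; frame accepted.
# Decision precedence is boundary > lost > too-fast: matching is meaningless
# without keypoints, and a translation must exist before its magnitude can
# be judged. Rejected frames never advance the reference frame, so the
# operator can recover by moving back.

#' Tracker configuration
#'
#' @param kp_min minimum keypoint count before the boundary warning fires
#'   (default 20).
#' @param max_translation_frac translations larger than this fraction of the
#'   smaller FoV dimension trigger `moving_too_fast` (default 0.7, i.e. a
#'   30% minimum overlap floor).
#' @param detector a [detector_config()] for client frames; the default uses
#'   the four finest filter sizes so that small downsampled frames remain
#'   admissible.
#' @param matcher a [match_config()]; the default keeps the client inlier
#'   radius of 3 px.
#' @param minimap_cell_px mini-map rasterization cell size in downsampled px.
#' @return list of class `tracker_config`.
#' @export
tracker_config <- function(kp_min = 20L, max_translation_frac = 0.7,
                           detector = detector_config(
                             layer_filter_sizes = c(9L, 15L, 21L, 27L),
                             per_layer_count_band = c(30L, 200L)),
                           matcher = match_config(ransac_inlier_px = 3),
                           minimap_cell_px = 4L) {
  if (max_translation_frac <= 0 || max_translation_frac >= 1)
    stopf("max_translation_frac must be in (0, 1)")
  structure(list(kp_min = as.integer(kp_min),
                 max_translation_frac = max_translation_frac,
                 detector = detector, matcher = matcher,
                 minimap_cell_px = as.integer(minimap_cell_px)),
            class = "tracker_config")
}

#' Initial tracker state
#' @return list of class `tracker_state`.
#' @export
tracker_init <- function() {
  structure(list(status = NA_character_, position = NULL,
                 accepted_fovs = integer(0), pair_links = list(),
                 positions = list(), last_kps = NULL, fov_dim = NULL),
            class = "tracker_state")
}

#' Advance the tracker by one client frame
#'
#' The first viable frame of a session (enough keypoints to track from) is
#' accepted at position `(0, 0)` with status `no_error` — there is nothing
#' to match it against. Later frames are classified in the order
#' boundary > lost > too-fast; accepted frames update the cumulative
#' position and append a [pair_link()] (with `t_client` set) to the state.
#'
#' @param state a `tracker_state`.
#' @param new_fov a client-tier [fov()].
#' @param cfg a [tracker_config()].
#' @return list `(state, status)`.
#' @export
step <- function(state, new_fov, cfg = tracker_config()) {
  if (new_fov$tier != "client_downsampled")
    stopf("tracker frames must be client_downsampled tier")
  kps <- detect(new_fov, cfg$detector)
  d <- fov_dim(new_fov)
  if (is.null(state$last_kps)) {
    # the session starts on the first viable frame: there is nothing to
    # match against, so it is accepted unconditionally — unless it has too
    # few keypoints to ever track from (e.g. a blank or off-slide frame)
    if (nrow(kps$keypoints) < cfg$kp_min) {
      state$status <- "touching_boundary"
      return(list(state = state, status = "touching_boundary"))
    }
    state$position <- c(0, 0)
    state$accepted_fovs <- new_fov$index
    state$positions[[as.character(new_fov$index)]] <- c(0, 0)
    state$last_kps <- kps
    state$fov_dim <- d
    state$status <- "no_error"
    return(list(state = state, status = "no_error"))
  }
  status <- if (nrow(kps$keypoints) < cfg$kp_min) "touching_boundary" else {
    ms <- match_brute_force(state$last_kps, kps, cfg$matcher)
    # the overlap floor is per axis: |tx| vs width, |ty| vs height, so a
    # legitimate along-row step of a rectangular FoV is not flagged
    if (is.null(ms$translation)) "lost"
    else if (any(abs(ms$translation) > cfg$max_translation_frac * d))
      "moving_too_fast"
    else "no_error"
  }
  if (status == "no_error") {
    t <- ms$translation                     # t_AB: last accepted -> new
    link <- pair_link(state$last_kps$fov_index, new_fov$index,
                      t_client = t, status = "no_error")
    state$pair_links[[length(state$pair_links) + 1L]] <- link
    state$position <- state$position + t
    state$accepted_fovs <- c(state$accepted_fovs, new_fov$index)
    state$positions[[as.character(new_fov$index)]] <- state$position
    state$last_kps <- kps
  }
  state$status <- status
  list(state = state, status = status)
}

#' Mini-map occupancy grid
#'
#' Binary raster of the slide area visited so far: one cell per
#' `minimap_cell_px` downsampled pixels, a cell marked when its center lies
#' inside any accepted FoV rectangle. The current position is returned as a
#' cell coordinate attribute.
#'
#' @param state a `tracker_state` with at least one accepted FoV.
#' @param cfg a [tracker_config()].
#' @return logical matrix with attributes `origin` (downsampled px of cell
#'   (1,1) corner), `cell_px` and `current` (current FoV position, cell
#'   units).
#' @export
minimap <- function(state, cfg = tracker_config()) {
  if (!length(state$accepted_fovs)) stopf("no accepted FoVs yet")
  pos <- do.call(rbind, state$positions)
  w <- state$fov_dim[["w"]]; h <- state$fov_dim[["h"]]
  c_px <- cfg$minimap_cell_px
  x0 <- floor(min(pos[, 1])); y0 <- floor(min(pos[, 2]))
  x1 <- ceiling(max(pos[, 1]) + w); y1 <- ceiling(max(pos[, 2]) + h)
  ncx <- ceiling((x1 - x0) / c_px); ncy <- ceiling((y1 - y0) / c_px)
  gx <- x0 + (seq_len(ncx) - 0.5) * c_px    # cell centers
  gy <- y0 + (seq_len(ncy) - 0.5) * c_px
  grid <- matrix(FALSE, ncy, ncx)
  for (i in seq_len(nrow(pos))) {
    cx <- gx >= pos[i, 1] & gx < pos[i, 1] + w
    cy <- gy >= pos[i, 2] & gy < pos[i, 2] + h
    grid[cy, cx] <- TRUE
  }
  structure(grid, origin = c(x0, y0), cell_px = c_px,
            current = (state$position - c(x0, y0)) / c_px)
}

#' Run the tracker over a stream of client frames
#'
#' @param fov_stream list of client-tier [fov()]s in capture order.
#' @param cfg a [tracker_config()].
#' @param full_fovs optional list of matching full-resolution [fov()]s; when
#'   given, the returned session contains the accepted full-resolution
#'   frames (the server's input), otherwise the accepted client frames.
#' @return list with `session` (a [scan_session()] of accepted FoVs and
#'   their pair links), `events` (data.frame `frame_index, status`),
#'   `state` (final `tracker_state`).
#' @export
run_session <- function(fov_stream, cfg = tracker_config(), full_fovs = NULL) {
  if (!length(fov_stream)) stopf("empty FoV stream")
  state <- tracker_init()
  events <- data.frame(frame_index = integer(0), status = character(0))
  for (f in fov_stream) {
    res <- step(state, f, cfg)
    state <- res$state
    events <- rbind(events, data.frame(frame_index = f$index,
                                       status = res$status))
  }
  if (!length(state$accepted_fovs))
    stopf("session empty: no FoV was accepted")
  keep <- state$accepted_fovs
  src <- full_fovs %||% fov_stream
  fovs <- Filter(function(f) f$index %in% keep, src)
  d0 <- fov_dim(src[[1]])
  ratio <- fov_stream[[1]]$downsample_ratio
  sess <- scan_session(fovs, fov_width = d0[["w"]], fov_height = d0[["h"]],
                       downsample_ratio = if (is.null(full_fovs)) 1 else ratio,
                       pair_links = state$pair_links)
  list(session = sess, events = events, state = state)
}
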