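# End-to-end pipeline: simulate -> track -> selective stitch -> distortion
# fit -> correct -> layout -> render -> export. Each stage is a thin call
# into the module functions; the pipeline adds only sequencing, config
# handling and the run report.

#' Default pipeline configuration
#'
#' Nested named list with one entry per stage; every field has a default.
#' Unknown keys are rejected by [run_pipeline()]. `seed` drives every
#' source of randomness.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("vs_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = list(slide_dim = c(1664L, 1280L), fov_dim = c(480L, 360L),
                     overlap = 0.3, jitter_sd = 1, distortion = c(0.05, -0.01),
                     nucleus_density = 6e-4, downsample_ratio = 2L,
                     grid = NULL, faults = list()),
    detector = list(count_band = c(50L, 400L)),
    matcher = list(ratio_test = 0.8, min_inliers = 8L,
                   selective_radius = 64, server_inlier_px = 5),
    tracker = list(kp_min = 20L, max_translation_frac = 0.7),
    hop = list(order = 3L, enabled = TRUE),
    mosaic = list(tile_size = 256L, export = TRUE),
    log_level = "info"), class = "pipeline_config")
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stopf("unknown configuration key: %s", full)
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], override[[k]], full)
    else base[[k]] <- override[[k]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Strict schema: keys not present in [pipeline_config()] are rejected
#' before any work is done.
#'
#' @param path YAML file; `NULL` gives the defaults.
#' @param seed overrides the file's seed when not `NULL`.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path = NULL, seed = NULL) {
  cfg <- pipeline_config()
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, y)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

plog <- function(cfg, level, fmt, ...) {
  lv <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (lv[[level]] >= lv[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full pipeline on a synthetic scan
#'
#' Stages: (1) simulate a ground-truthed scan, (2) client tracking over the
#' downsampled stream, (3) full-resolution detection and prior-guided
#' selective matching along the accepted chain, (4) distortion
#' self-calibration (optional), (5) correction of every FoV, (6) global
#' layout, (7) rendering, (8) tiled export. A machine-readable run report
#' (JSON) with per-stage timings, counts and residuals is written to the
#' output directory; any stage failure aborts with a stage-named error.
#'
#' @param cfg a `pipeline_config`.
#' @return invisibly, a list with `report`, `session`, `model`, `layout`,
#'   `virtual_slide`, `scan` and the report path.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) stopf("invalid configuration object")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, stages = list())
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    report$stages[[name]] <<- c(report$stages[[name]],
                                list(seconds = round(tic() - t0, 3)))
    plog(cfg, "info", "stage %-12s %6.2fs", name, tic() - t0)
    res
  }

  scan <- stage("simulate", {
    sc <- cfg$synthetic
    scfg <- synthetic_config(slide_dim = sc$slide_dim, seed = cfg$seed,
                             nucleus_density = sc$nucleus_density,
                             distortion = sc$distortion,
                             fov_dim = sc$fov_dim, overlap = sc$overlap,
                             jitter_sd = sc$jitter_sd, faults = sc$faults,
                             downsample_ratio = sc$downsample_ratio,
                             grid = sc$grid)
    generate_scan(generate_slide(scfg), scfg)
  })
  report$stages$simulate$frames <- length(scan$client_fovs)

  trk_cfg <- tracker_config(kp_min = cfg$tracker$kp_min,
                            max_translation_frac = cfg$tracker$max_translation_frac)
  tracked <- stage("track",
                   run_session(scan$client_fovs, trk_cfg,
                               full_fovs = scan$session$fovs))
  report$stages$track$accepted <- length(tracked$state$accepted_fovs)
  report$stages$track$events <- table(tracked$events$status)

  sess <- tracked$session
  ratio <- scan$cfg$downsample_ratio
  srv_match <- match_config(ratio_test = cfg$matcher$ratio_test,
                            min_inliers = cfg$matcher$min_inliers,
                            ransac_inlier_px = cfg$matcher$server_inlier_px,
                            selective_radius = cfg$matcher$selective_radius)
  det_cfg <- detector_config(per_layer_count_band = cfg$detector$count_band)

  kps <- stage("detect", lapply(sess$fovs, detect, cfg = det_cfg))
  report$stages$detect$keypoints <- sum(vapply(kps, function(k)
    nrow(k$keypoints), integer(1)))

  links <- stage("stitch", {
    out <- list()
    for (l in sess$pair_links) {
      ia <- match(l$fov_a, vapply(sess$fovs, `[[`, integer(1), "index"))
      ib <- match(l$fov_b, vapply(sess$fovs, `[[`, integer(1), "index"))
      ms <- match_selective(kps[[ia]], kps[[ib]], l$t_client * ratio,
                            srv_match)
      if (ms$status != "no_error")
        stopf("pair %d-%d unmatched at full resolution (%s)",
              l$fov_a, l$fov_b, ms$status)
      inl <- ms$inliers
      out[[length(out) + 1L]] <- list(
        fov_a = l$fov_a, fov_b = l$fov_b,
        uA = cbind(kps[[ia]]$keypoints$x[ms$pairs$idx_a],
                   kps[[ia]]$keypoints$y[ms$pairs$idx_a])[inl, , drop = FALSE],
        uB = cbind(kps[[ib]]$keypoints$x[ms$pairs$idx_b],
                   kps[[ib]]$keypoints$y[ms$pairs$idx_b])[inl, , drop = FALSE],
        t_match = ms$translation)
    }
    out
  })
  report$stages$stitch$links <- length(links)

  fdim <- c(sess$fov_width, sess$fov_height)
  if (isTRUE(cfg$hop$enabled)) {
    fit <- stage("fit_distortion",
                 fit_hop(links, fdim, order = cfg$hop$order))
    model <- fit$model
    t_pairs <- fit$t_pairs
    report$stages$fit_distortion$rms <- fit$report$rms
    report$stages$fit_distortion$iterations <- fit$report$iterations
    save_hop(model, file.path(cfg$out_dir, "hop.json"))
  } else {
    model <- NULL
    t_pairs <- t(vapply(links, function(l) l$t_match, numeric(2)))
  }

  corrected <- stage("correct", {
    if (is.null(model)) sess$fovs
    else lapply(sess$fovs, function(f) apply_hop(model, f))
  })

  layout <- stage("layout", {
    ln <- lapply(seq_along(links), function(i)
      list(fov_a = links[[i]]$fov_a, fov_b = links[[i]]$fov_b,
           t_server = t_pairs[i, ]))
    solve_layout(ln)
  })
  report$stages$layout$max_residual <-
    if (length(layout$residuals)) max(layout$residuals) else 0

  vs <- stage("render", render(layout, corrected,
                               tile_size = cfg$mosaic$tile_size))
  report$stages$render$canvas <- dim(vs$canvas)

  if (isTRUE(cfg$mosaic$export)) {
    desc <- stage("export", export_pyramid(vs, file.path(cfg$out_dir,
                                                         "pyramid")))
    report$stages$export$descriptor <- desc
  }

  report_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(list(report = report, report_path = report_path, scan = scan,
                 session = sess, model = model, layout = layout,
                 virtual_slide = vs, tracked = tracked))
}
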