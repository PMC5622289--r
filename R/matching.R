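# Pairwise FoV translation estimation from keypoint correspondences.
#
# Two strategies share one verification backend:
#   * brute-force matching evaluates descriptor distances for all cross
#     pairs (used on small downsampled client frames);
#   * selective matching evaluates, for a keypoint at x in A, only the
#     B-keypoints within a constant radius of the location x - prior_t
#     predicted by the (up-sampled) client translation; all other pairs are
#     treated as infinitely distant, i.e. never materialized.
# Candidate evaluation counts are reported so the cost saving of selective
# matching is measurable independently of hardware.

#' Matching configuration
#'
#' @param ratio_test Lowe nearest/second-nearest distance ratio (default 0.8).
#' @param min_inliers minimum consensus size for a translation (default 8).
#' @param ransac_inlier_px inlier radius in px for the translation consensus
#'   (default 3 for client frames; use ~5 on uncorrected full-resolution
#'   frames where lens distortion inflates residuals).
#' @param selective_radius candidate search radius around the prior-predicted
#'   location, in full-resolution px (default 64).
#' @param max_translation_frac reject translations larger than this fraction
#'   of the smaller FoV dimension (default 0.7, i.e. at least 30% overlap).
#' @param max_iter cap on consensus hypotheses evaluated (default 200).
#' @param seed RNG seed used only when subsampling hypotheses (determinism).
#' @return A list of class `match_config`.
#' @export
match_config <- function(ratio_test = 0.8, min_inliers = 8L,
                         ransac_inlier_px = 3, selective_radius = 64,
                         max_translation_frac = 0.7, max_iter = 200L,
                         seed = 7L) {
  if (ratio_test <= 0 || ratio_test >= 1) stopf("ratio_test must be in (0,1)")
  if (selective_radius <= 0 || ransac_inlier_px <= 0)
    stopf("radii must be positive")
  structure(list(ratio_test = ratio_test, min_inliers = as.integer(min_inliers),
                 ransac_inlier_px = ransac_inlier_px,
                 selective_radius = selective_radius,
                 max_translation_frac = max_translation_frac,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "match_config")
}

new_match_set <- function(pairs, inliers, translation, rms, evals, status) {
  structure(list(pairs = pairs, inliers = inliers, translation = translation,
                 rms_residual = rms, candidate_evaluations = evals,
                 status = status),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  t <- if (is.null(x$translation)) "none"
       else sprintf("(%.2f, %.2f)", x$translation[1], x$translation[2])
  cat(sprintf("<match_set: %d pairs, %d inliers, t=%s, status=%s, evals=%d>\n",
              nrow(x$pairs), sum(x$inliers), t, x$status,
              x$candidate_evaluations))
  invisible(x)
}

empty_pairs <- function() {
  data.frame(idx_a = integer(0), idx_b = integer(0), dist = numeric(0))
}

# Ratio-test filter given, for each A keypoint, its nearest and second
# nearest candidate in B. `nn` is a data.frame idx_a, idx_b, d1, d2.
ratio_filter <- function(nn, ratio) {
  keep <- nn$d1 < ratio * nn$d2
  data.frame(idx_a = nn$idx_a[keep], idx_b = nn$idx_b[keep],
             dist = nn$d1[keep])
}

#' Brute-force descriptor matching between two keypoint sets
#'
#' Nearest + second-nearest descriptor search over all cross pairs, Lowe
#' ratio-test filtering, then geometric verification with
#' [estimate_translation()]. `candidate_evaluations` equals `|A| * |B|`.
#'
#' @param kpsA,kpsB `keypoint_set` objects (see [detect()]).
#' @param cfg a [match_config()].
#' @return A `match_set`; `status` is `"lost"` when no reliable translation
#'   was found (never an exception).
#' @export
match_brute_force <- function(kpsA, kpsB, cfg = match_config()) {
  nA <- nrow(kpsA$keypoints); nB <- nrow(kpsB$keypoints)
  evals <- as.numeric(nA) * nB
  if (nA == 0L || nB == 0L)
    return(new_match_set(empty_pairs(), logical(0), NULL, NA_real_, evals,
                         "lost"))
  # unit descriptors: d^2 = 2 - 2 A.B
  cp <- kpsA$descriptors %*% t(kpsB$descriptors)
  d2 <- pmax(2 - 2 * cp, 0)
  nn <- nearest_two(d2)
  pairs <- ratio_filter(nn, cfg$ratio_test)
  finish_match(pairs, kpsA, kpsB, cfg, evals, prior = NULL)
}

# Per-row nearest and second nearest of a distance-squared matrix.
nearest_two <- function(d2) {
  nA <- nrow(d2); nB <- ncol(d2)
  j1 <- max.col(-d2, ties.method = "first")
  d1 <- sqrt(d2[cbind(seq_len(nA), j1)])
  if (nB >= 2L) {
    d2m <- d2
    d2m[cbind(seq_len(nA), j1)] <- Inf
    j2 <- max.col(-d2m, ties.method = "first")
    d2nd <- sqrt(d2m[cbind(seq_len(nA), j2)])
  } else d2nd <- rep(Inf, nA)
  data.frame(idx_a = seq_len(nA), idx_b = j1, d1 = d1, d2 = d2nd)
}

#' Prior-guided selective matching
#'
#' For a keypoint at position `x` in A, descriptor distances are evaluated
#' only against B-keypoints within `cfg$selective_radius` of the predicted
#' location `x - prior_t` (sign convention: a slide point at `u` in A
#' appears at `u - t_AB` in B). All other pairs are treated as infinitely
#' distant. When more than 90% of A's keypoints have no candidate at all,
#' the prior is considered bad and status `"lost_with_prior"` is returned.
#'
#' @param kpsA,kpsB `keypoint_set` objects.
#' @param prior_t length-2 prior translation in the pixel units of these
#'   keypoint sets (client translation times the downsample ratio for
#'   full-resolution frames).
#' @param cfg a [match_config()].
#' @return A `match_set` with `candidate_evaluations` equal to the number of
#'   descriptor distances actually computed.
#' @export
match_selective <- function(kpsA, kpsB, prior_t, cfg = match_config()) {
  if (is.null(prior_t) || length(prior_t) != 2L)
    stopf("match_selective requires a length-2 prior translation")
  nA <- nrow(kpsA$keypoints); nB <- nrow(kpsB$keypoints)
  if (nA == 0L || nB == 0L)
    return(new_match_set(empty_pairs(), logical(0), NULL, NA_real_, 0,
                         "lost"))
  predx <- kpsA$keypoints$x - prior_t[1]
  predy <- kpsA$keypoints$y - prior_t[2]
  dx <- outer(predx, kpsB$keypoints$x, "-")
  dy <- outer(predy, kpsB$keypoints$y, "-")
  near <- dx * dx + dy * dy <= cfg$selective_radius^2
  cand_per_a <- rowSums(near)
  evals <- sum(cand_per_a)
  if (mean(cand_per_a == 0) > 0.9)
    return(new_match_set(empty_pairs(), logical(0), NULL, NA_real_, evals,
                         "lost_with_prior"))
  rows <- which(cand_per_a > 0L)
  nn <- do.call(rbind, lapply(rows, function(i) {
    js <- which(near[i, ])
    diff <- kpsB$descriptors[js, , drop = FALSE] -
      matrix(kpsA$descriptors[i, ], length(js), 64L, byrow = TRUE)
    d <- sqrt(rowSums(diff * diff))
    o <- order(d)
    data.frame(idx_a = i, idx_b = js[o[1]], d1 = d[o[1]],
               d2 = if (length(d) >= 2L) d[o[2]] else Inf)
  }))
  pairs <- ratio_filter(nn, cfg$ratio_test)
  finish_match(pairs, kpsA, kpsB, cfg, evals, prior = prior_t)
}

finish_match <- function(pairs, kpsA, kpsB, cfg, evals, prior) {
  if (nrow(pairs) == 0L)
    return(new_match_set(pairs, logical(0), NULL, NA_real_, evals, "lost"))
  est <- estimate_translation(pairs, kpsA, kpsB, cfg)
  status <- if (is.null(est$translation)) "lost" else "no_error"
  new_match_set(pairs, est$inliers, est$translation, est$rms, evals, status)
}

#' Robust single-translation fit from tentative matches
#'
#' Each tentative pair proposes the translation `pos_A - pos_B` (so that a
#' point at `u` in A appears at `u - t` in B). Hypotheses are scored by the
#' number of pairs within `ransac_inlier_px`; the best consensus is refined
#' as the inlier mean (re-collecting inliers once). All hypotheses are
#' evaluated when there are at most `cfg$max_iter` pairs, otherwise a seeded
#' subsample, so the result is deterministic. Ties are broken by lower rms,
#' then lexicographically smaller translation.
#'
#' @param pairs data.frame `idx_a, idx_b, dist` of tentative matches.
#' @param kpsA,kpsB `keypoint_set` objects the indices refer to.
#' @param cfg a [match_config()].
#' @return list with `translation` (or `NULL` if consensus `<
#'   cfg$min_inliers`), logical `inliers`, and `rms`.
#' @export
estimate_translation <- function(pairs, kpsA, kpsB, cfg = match_config()) {
  n <- nrow(pairs)
  if (n == 0L) return(list(translation = NULL, inliers = logical(0),
                           rms = NA_real_))
  tx <- kpsA$keypoints$x[pairs$idx_a] - kpsB$keypoints$x[pairs$idx_b]
  ty <- kpsA$keypoints$y[pairs$idx_a] - kpsB$keypoints$y[pairs$idx_b]
  hyp <- if (n <= cfg$max_iter) seq_len(n)
         else withr::with_seed(cfg$seed, sample.int(n, cfg$max_iter))
  r2 <- cfg$ransac_inlier_px^2
  best <- NULL
  for (i in hyp) {
    d2 <- (tx - tx[i])^2 + (ty - ty[i])^2
    inl <- d2 <= r2
    cnt <- sum(inl)
    if (cnt == 0L) next
    t_ref <- c(mean(tx[inl]), mean(ty[inl]))
    d2r <- (tx - t_ref[1])^2 + (ty - t_ref[2])^2
    inl <- d2r <= r2
    if (!any(inl)) next
    t_ref <- c(mean(tx[inl]), mean(ty[inl]))
    rms <- sqrt(mean((tx[inl] - t_ref[1])^2 + (ty[inl] - t_ref[2])^2))
    cand <- list(count = sum(inl), rms = rms, t = t_ref, inliers = inl)
    if (is.null(best) ||
        cand$count > best$count ||
        (cand$count == best$count && cand$rms < best$rms - 1e-12) ||
        (cand$count == best$count && abs(cand$rms - best$rms) <= 1e-12 &&
         (cand$t[1] < best$t[1] ||
          (cand$t[1] == best$t[1] && cand$t[2] < best$t[2]))))
      best <- cand
  }
  if (is.null(best) || best$count < cfg$min_inliers)
    return(list(translation = NULL, inliers = rep(FALSE, n), rms = NA_real_))
  list(translation = best$t, inliers = best$inliers, rms = best$rms)
}
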