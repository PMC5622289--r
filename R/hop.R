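# Self-calibration of lens distortion with a high-order polynomial (HOP)
# inverse-distortion model.
#
# Model: in normalized FoV coordinates z (origin at the image center, unit =
# half the image diagonal), the corrected position is
#     P(z) = z + sum_{2 <= p+q <= D} a_pq * z_x^p * z_y^q     (per axis),
# i.e. the constant term is zero and the linear part is fixed to the
# identity (gauge fixing: any affine component of the map is absorbed into
# the per-pair translations, so only this normalization makes the joint
# problem well-posed). One model is fitted per scan session.
#
# Fitting uses the phase-difference constraint: all matched pixel pairs of
# one overlapping FoV pair share one translation. Eliminating each pair's
# translation in closed form (weighted centering of the pair's residuals)
# leaves a single linear least-squares problem in the coefficients, which is
# iterated with Huber reweighting to resist mismatches.

hop_monomials <- function(order) {
  p <- integer(0); q <- integer(0)
  for (d in 2:order) {
    p <- c(p, d:0)
    q <- c(q, 0:d)
  }
  data.frame(p = p, q = q)
}

#' Construct a HOP inverse-distortion model
#'
#' @param order polynomial degree D (2-5; default 3).
#' @param coeffs_x,coeffs_y numeric vectors of coefficients over the
#'   monomials `z_x^p z_y^q`, `2 <= p+q <= D`, in the order given by the
#'   internal monomial table (degree-major, x-power descending). Length must
#'   be `(D+1)(D+2)/2 - 3`.
#' @param domain_scale half image diagonal in px used for normalization.
#' @param fov_dim FoV dimensions `c(w, h)` the model applies to.
#' @return list of class `hop_model`.
#' @export
hop_model <- function(order = 3L, coeffs_x = NULL, coeffs_y = NULL,
                      domain_scale, fov_dim) {
  order <- as.integer(order)
  if (order < 2L || order > 5L) stopf("order must be between 2 and 5")
  mono <- hop_monomials(order)
  m <- nrow(mono)
  stopifnot(m == (order + 1L) * (order + 2L) / 2L - 3L)
  coeffs_x <- coeffs_x %||% numeric(m)
  coeffs_y <- coeffs_y %||% numeric(m)
  if (length(coeffs_x) != m || length(coeffs_y) != m)
    stopf("expected %d coefficients per axis for order %d", m, order)
  structure(list(order = order, monomials = mono,
                 coeffs_x = as.numeric(coeffs_x),
                 coeffs_y = as.numeric(coeffs_y),
                 domain_scale = domain_scale, fov_dim = as.integer(fov_dim)),
            class = "hop_model")
}

#' @export
print.hop_model <- function(x, ...) {
  cat(sprintf("<hop_model: order %d, %d coeffs/axis, |a|_max=%.3g, scale=%.1f px>\n",
              x$order, length(x$coeffs_x),
              max(abs(c(x$coeffs_x, x$coeffs_y)), 0), x$domain_scale))
  invisible(x)
}

# Monomial design matrix Phi(z): n x m, and its partial derivatives.
hop_design <- function(z, mono) {
  n <- nrow(z)
  vapply(seq_len(nrow(mono)),
         function(j) z[, 1]^mono$p[j] * z[, 2]^mono$q[j], numeric(n))
}

hop_design_grad <- function(z, mono) {
  n <- nrow(z)
  dx <- vapply(seq_len(nrow(mono)), function(j) {
    if (mono$p[j] == 0L) rep(0, n)
    else mono$p[j] * z[, 1]^(mono$p[j] - 1L) * z[, 2]^mono$q[j]
  }, numeric(n))
  dy <- vapply(seq_len(nrow(mono)), function(j) {
    if (mono$q[j] == 0L) rep(0, n)
    else mono$q[j] * z[, 1]^mono$p[j] * z[, 2]^(mono$q[j] - 1L)
  }, numeric(n))
  list(dx = dx, dy = dy)
}

# Evaluate P in normalized coordinates: n x 2 in, n x 2 out.
hop_eval_norm <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, ncol = 2L)
  Phi <- hop_design(z, model$monomials)
  cbind(z[, 1] + Phi %*% model$coeffs_x,
        z[, 2] + Phi %*% model$coeffs_y)
}

#' Apply a HOP model to points in FoV pixel coordinates
#'
#' Normalize, evaluate the polynomial, de-normalize. Exact arithmetic
#' contract: `correct_point(model, center)` returns the center for any
#' model (gauge constraint P(0) = 0).
#'
#' @param model a [hop_model()].
#' @param pts n x 2 matrix (or length-2 vector) of 0-based pixel coords.
#' @return n x 2 matrix of corrected pixel coordinates.
#' @export
correct_point <- function(model, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2L)
  geom <- norm_geometry(model$fov_dim[1], model$fov_dim[2])
  z <- sweep(pts, 2L, geom$center) / geom$scale
  sweep(hop_eval_norm(model, z) * geom$scale, 2L, geom$center, "+")
}

#' Fit the HOP model from pooled pairwise matches
#'
#' Minimizes `sum_pairs sum_matches || P(u) - P(v) - t_pair ||^2` jointly
#' over the polynomial coefficients and the per-pair translations. The
#' translations are eliminated in closed form (each pair's residuals are
#' centered with the current robust weights), leaving one linear
#' least-squares problem per axis; this is iterated with Huber reweighting
#' until the coefficient change is below `tol` or `max_iter` iterations.
#' A ridge term `lambda` stabilizes the normal matrix.
#'
#' @param links list of pairwise match records, each
#'   `list(fov_a, fov_b, uA, uB)` with `uA`, `uB` n x 2 matrices of matched
#'   raw pixel coordinates (A's point and its correspondent in B).
#' @param fov_dim `c(w, h)` in px.
#' @param order polynomial degree D (default 3).
#' @param max_iter,tol IRLS stopping rule (default 25 iterations, 1e-8
#'   coefficient change).
#' @param lambda ridge weight on the normal matrix (default 1e-6).
#' @param huber_k Huber tuning constant in robust-scale units (default
#'   1.345).
#' @return list with `model` (a [hop_model()]), `report` (class
#'   `hop_fit_report`: `iterations`, `rms` in px, `inlier_fraction`,
#'   `condition_number`) and `t_pairs` (per-link fitted translations, px,
#'   convention `t_AB = P(uA) - P(uB)`).
#' @export
fit_hop <- function(links, fov_dim, order = 3L, max_iter = 25L, tol = 1e-8,
                    lambda = 1e-6, huber_k = 1.345) {
  if (length(links) < 2L) stopf("need at least 2 distinct FoV pairs")
  mono <- hop_monomials(order)
  m <- nrow(mono)
  n_per <- vapply(links, function(l) nrow(l$uA), integer(1))
  n_tot <- sum(n_per)
  if (n_tot < 3L * 2L * m)
    stopf("underdetermined: %d matches for %d unknowns (coefficients %d + translations %d); need at least %d matches",
          n_tot, 2L * m + 2L * length(links), 2L * m, 2L * length(links),
          3L * 2L * m)
  geom <- norm_geometry(fov_dim[1], fov_dim[2])
  pair_id <- rep(seq_along(links), n_per)
  uA <- do.call(rbind, lapply(links, function(l) l$uA))
  uB <- do.call(rbind, lapply(links, function(l) l$uB))
  zA <- sweep(uA, 2L, geom$center) / geom$scale
  zB <- sweep(uB, 2L, geom$center) / geom$scale
  d <- uA - uB                                    # px
  M <- (hop_design(zA, mono) - hop_design(zB, mono)) * geom$scale  # px units
  ax <- numeric(m); ay <- numeric(m)
  wts <- rep(1, n_tot)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    # weighted per-pair centering eliminates translations in closed form
    wsum <- rowsum(wts, pair_id)[pair_id]
    cen <- function(v) v - (rowsum(wts * v, pair_id) / rowsum(wts, pair_id))[pair_id]
    Mt <- apply(M, 2L, cen)
    dxt <- cen(d[, 1]); dyt <- cen(d[, 2])
    N <- crossprod(Mt, wts * Mt)
    N <- N + lambda * mean(diag(N)) * diag(m)   # scale-aware ridge
    new_ax <- solve(N, -crossprod(Mt, wts * dxt))[, 1]
    new_ay <- solve(N, -crossprod(Mt, wts * dyt))[, 1]
    delta <- max(abs(new_ax - ax), abs(new_ay - ay))
    ax <- new_ax; ay <- new_ay
    # residuals with current coefficients (translations re-eliminated)
    rx <- dxt + as.vector(Mt %*% ax)
    ry <- dyt + as.vector(Mt %*% ay)
    r <- sqrt(rx^2 + ry^2)
    sc <- max(1.4826 * stats::median(r), 0.25)
    dlt <- huber_k * sc
    wts <- ifelse(r <= dlt, 1, dlt / r)
    if (delta < tol) break
  }
  model <- hop_model(order, ax, ay, geom$scale, fov_dim)
  # final residuals and per-pair translations under the fitted model
  PA <- correct_point(model, uA)
  PB <- correct_point(model, uB)
  diffp <- PA - PB
  t_pairs <- rowsum(wts * diffp, pair_id) / as.vector(rowsum(wts, pair_id))
  res <- diffp - t_pairs[pair_id, , drop = FALSE]
  rms <- sqrt(mean(rowSums(res^2)))
  N <- crossprod(apply(M, 2L, function(v) v - (rowsum(wts * v, pair_id) /
                                                 rowsum(wts, pair_id))[pair_id]),
                 wts * apply(M, 2L, function(v) v - (rowsum(wts * v, pair_id) /
                                                       rowsum(wts, pair_id))[pair_id]))
  cond <- kappa(N + lambda * mean(diag(N)) * diag(m), exact = TRUE)
  report <- structure(list(iterations = iters, rms = rms,
                           inlier_fraction = mean(wts >= 1 - 1e-12),
                           condition_number = cond,
                           warning = if (cond > 1e10)
                             "normal system ill-conditioned (condition number > 1e10)"
                           else NULL),
                      class = "hop_fit_report")
  list(model = model, report = report, t_pairs = t_pairs)
}

#' @export
print.hop_fit_report <- function(x, ...) {
  cat(sprintf("<hop_fit_report: %d iterations, rms %.4f px, %.0f%% inliers, cond %.3g>\n",
              x$iterations, x$rms, 100 * x$inlier_fraction,
              x$condition_number))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Pairwise stitch rms of match links under a model
#'
#' Root-mean-square of the per-pair centered residuals `P(uA) - P(uB) -
#' t_pair` with each pair's translation at its optimum (the plain mean).
#' With `model = NULL` the identity map is used, giving the uncorrected
#' baseline.
#'
#' @param links as in [fit_hop()].
#' @param model a [hop_model()] or `NULL`.
#' @return rms in px.
#' @export
link_rms <- function(links, model = NULL) {
  res2 <- unlist(lapply(links, function(l) {
    pa <- if (is.null(model)) l$uA else correct_point(model, l$uA)
    pb <- if (is.null(model)) l$uB else correct_point(model, l$uB)
    df <- pa - pb
    df <- sweep(df, 2L, colMeans(df))
    rowSums(df^2)
  }))
  sqrt(mean(res2))
}

#' Apply a HOP model to a field of view
#'
#' Resamples the image so that the output pixel at location `P(u)` carries
#' the input intensity at `u`: each output pixel position is inverse-mapped
#' through the model by damped Newton iteration on the polynomial, then the
#' input is sampled bilinearly. Output pixels whose pre-image falls outside
#' the input (or fails to converge) are marked invalid in the validity mask.
#'
#' @param model a [hop_model()]; its `domain_scale` must match the FoV.
#' @param f a [fov()].
#' @return A corrected [fov()] of the same dimensions with a `valid` mask.
#' @export
apply_hop <- function(model, f) {
  w <- ncol(f$pixels); h <- nrow(f$pixels)
  geom <- norm_geometry(w, h)
  if (abs(geom$scale - model$domain_scale) > 1e-6)
    stopf("model domain_scale %.3f does not match FoV half-diagonal %.3f",
          model$domain_scale, geom$scale)
  mono <- model$monomials
  # reject non-physical models: Jacobian must stay invertible over the image
  zs <- cbind(rep(seq(0, w - 1L, by = 2L), each = length(seq(0, h - 1L, by = 2L))),
              rep(seq(0, h - 1L, by = 2L), times = length(seq(0, w - 1L, by = 2L))))
  zn <- sweep(zs, 2L, geom$center) / geom$scale
  g <- hop_design_grad(zn, mono)
  j11 <- 1 + g$dx %*% model$coeffs_x
  j12 <- g$dy %*% model$coeffs_x
  j21 <- g$dx %*% model$coeffs_y
  j22 <- 1 + g$dy %*% model$coeffs_y
  detj <- j11 * j22 - j12 * j21
  if (any(detj <= 1e-8)) {
    i <- which.min(detj)
    stopf("non-invertible local Jacobian at pixel (%.0f, %.0f): model rejected as non-physical",
          zs[i, 1], zs[i, 2])
  }
  gx <- rep(0:(w - 1L), each = h)
  gy <- rep(0:(h - 1L), times = w)
  yn <- cbind((gx - geom$center[1]) / geom$scale,
              (gy - geom$center[2]) / geom$scale)
  u <- yn
  for (it in 1:25) {
    Phi <- hop_design(u, mono)
    ex <- u[, 1] + Phi %*% model$coeffs_x - yn[, 1]
    ey <- u[, 2] + Phi %*% model$coeffs_y - yn[, 2]
    gr <- hop_design_grad(u, mono)
    j11 <- 1 + gr$dx %*% model$coeffs_x
    j12 <- gr$dy %*% model$coeffs_x
    j21 <- gr$dx %*% model$coeffs_y
    j22 <- 1 + gr$dy %*% model$coeffs_y
    det <- j11 * j22 - j12 * j21
    du <- cbind((j22 * ex - j12 * ey) / det, (-j21 * ex + j11 * ey) / det)
    u <- u - du
    if (max(abs(du)) < 1e-12) break
  }
  Phi <- hop_design(u, mono)
  ex <- u[, 1] + Phi %*% model$coeffs_x - yn[, 1]
  ey <- u[, 2] + Phi %*% model$coeffs_y - yn[, 2]
  converged <- abs(ex) + abs(ey) < 1e-8
  sx <- geom$center[1] + u[, 1] * geom$scale
  sy <- geom$center[2] + u[, 2] * geom$scale
  inb <- sx >= 0 & sy >= 0 & sx <= w - 1 & sy <= h - 1
  val <- converged & inb
  pix <- bilinear_sample(f$pixels, sx, sy, fill = 0)
  pix[!val] <- 0
  if (!is.null(f$valid)) {
    src_ok <- bilinear_sample(f$valid * 1, sx, sy, fill = 0) > 0.999
    val <- val & src_ok
  }
  fov(f$index, matrix(pix, h, w), tier = f$tier,
      downsample_ratio = f$downsample_ratio,
      valid = matrix(val, h, w))
}

#' Serialize / deserialize a HOP model as JSON
#'
#' Layout: `{order, domain_scale, fov_dim, coeffs_x: {"pq": value}, coeffs_y:
#' {...}}` with monomial keys `"pq"` = x-power, y-power.
#'
#' @param model a [hop_model()].
#' @param path file path.
#' @return `save_hop` the path; `load_hop` the model.
#' @export
save_hop <- function(model, path) {
  key <- sprintf("%d%d", model$monomials$p, model$monomials$q)
  jsonlite::write_json(
    list(order = model$order, domain_scale = model$domain_scale,
         fov_dim = model$fov_dim,
         coeffs_x = stats::setNames(as.list(model$coeffs_x), key),
         coeffs_y = stats::setNames(as.list(model$coeffs_y), key)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' @rdname save_hop
#' @export
load_hop <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mono <- hop_monomials(j$order)
  key <- sprintf("%d%d", mono$p, mono$q)
  hop_model(j$order, as.numeric(j$coeffs_x[key]), as.numeric(j$coeffs_y[key]),
            j$domain_scale, j$fov_dim)
}
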