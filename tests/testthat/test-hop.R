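# Distortion self-calibration: gauge, identity recovery, inversion of a
# known map, image resampling, point arithmetic and serialization.

FD <- c(480L, 360L)

test_that("correct_point honors the gauge and hand arithmetic", {
  geom <- slidestitch:::norm_geometry(FD[1], FD[2])
  # center maps to itself for any model
  m <- hop_model(3L, runif(7, -0.02, 0.02), runif(7, -0.02, 0.02),
                 geom$scale, FD)
  expect_equal(correct_point(m, geom$center)[1, ], geom$center)
  # D=2, a_20 = 0.01 on x^2, point at normalized (0.5, 0):
  # offset is 0.01 * 0.25 = 0.0025 in normalized x
  m2 <- hop_model(2L, c(0.01, 0, 0), c(0, 0, 0), geom$scale, FD)
  pt <- c(geom$center[1] + 0.5 * geom$scale, geom$center[2])
  out <- correct_point(m2, pt)
  expect_equal(out[1, 1] - pt[1], 0.0025 * geom$scale)
  expect_equal(out[1, 2], pt[2])
})

test_that("polynomial evaluation matches a naive monomial-sum oracle", {
  withr::with_seed(12, {
    m <- hop_model(4L, rnorm(12, 0, 0.01), rnorm(12, 0, 0.01),
                   slidestitch:::norm_geometry(FD[1], FD[2])$scale, FD)
    pts <- cbind(runif(50, 0, FD[1] - 1), runif(50, 0, FD[2] - 1))
  })
  geom <- slidestitch:::norm_geometry(FD[1], FD[2])
  z <- sweep(pts, 2, geom$center) / geom$scale
  mono <- m$monomials
  naive <- z
  for (j in seq_len(nrow(mono))) {
    naive[, 1] <- naive[, 1] + m$coeffs_x[j] * z[, 1]^mono$p[j] * z[, 2]^mono$q[j]
    naive[, 2] <- naive[, 2] + m$coeffs_y[j] * z[, 1]^mono$p[j] * z[, 2]^mono$q[j]
  }
  expected <- sweep(naive * geom$scale, 2, geom$center, "+")
  expect_equal(correct_point(m, pts), expected, tolerance = 1e-12)
})

test_that("identity matches are recovered as the identity model", {
  sy <- synth_hop_links(FD, NULL, n_pairs = 6L, n_matches = 40L, seed = 2L)
  fit <- fit_hop(sy$links, FD)
  expect_lt(max(abs(c(fit$model$coeffs_x, fit$model$coeffs_y))), 1e-6)
  expect_lt(fit$report$rms, 1e-6)
  # gauge holds to machine precision
  geom <- slidestitch:::norm_geometry(FD[1], FD[2])
  expect_equal(correct_point(fit$model, geom$center)[1, ], geom$center,
               tolerance = 1e-12)
})

test_that("a known radial map is inverted up to the translation gauge", {
  # cubic truth (k2 = 0) lies inside the D=3 family, so inversion must be
  # sharp; quintic truths are only approximated (see order-sanity test)
  k <- c(0.06, 0)
  sy <- synth_hop_links(FD, k, n_pairs = 12L, n_matches = 60L, seed = 5L)
  fit <- fit_hop(sy$links, FD, order = 3L)
  geom <- slidestitch:::norm_geometry(FD[1], FD[2])
  g <- as.matrix(expand.grid(x = seq(15, FD[1] - 16, length.out = 20),
                             y = seq(15, FD[2] - 16, length.out = 20)))
  un <- sweep(g, 2, geom$center) / geom$scale
  raw <- sweep(slidestitch:::radial_distort(un, k) * geom$scale, 2,
               geom$center, "+")
  d <- correct_point(fit$model, raw) - g
  d <- sweep(d, 2, colMeans(d))      # best uniform shift
  expect_lt(max(sqrt(rowSums(d^2))), 0.5)
  # fitted translations match the construction
  expect_lt(max(abs(fit$t_pairs - sy$t_true)), 0.5)
})

test_that("underdetermined systems and bad pair counts are rejected", {
  sy <- synth_hop_links(FD, NULL, n_pairs = 2L, n_matches = 5L, seed = 3L)
  expect_error(fit_hop(sy$links, FD, order = 3L), "underdetermined")
  expect_error(fit_hop(sy$links[1], FD), "2 distinct FoV pairs")
})

test_that("residual never degrades relative to the identity baseline and with order", {
  withr::with_seed(9, ks <- cbind(runif(5, -0.08, 0.08), runif(5, -0.02, 0.02)))
  for (i in seq_len(nrow(ks))) {
    sy <- synth_hop_links(FD, ks[i, ], n_pairs = 10L, n_matches = 50L,
                          noise_sd = 0.2, seed = 100L + i)
    f2 <- fit_hop(sy$links, FD, order = 2L)
    f3 <- fit_hop(sy$links, FD, order = 3L)
    base <- link_rms(sy$links)
    expect_lte(f3$report$rms, base + 1e-9)
    expect_lte(f3$report$rms, f2$report$rms + 1e-9)
  }
})

test_that("apply_hop resamples correctly", {
  scan <- small_scan()
  f <- scan$session$fovs[[1]]
  geom <- slidestitch:::norm_geometry(FD[1], FD[2])
  # identity model: output equals input up to resampling quantization
  id <- hop_model(3L, domain_scale = geom$scale, fov_dim = FD)
  out <- apply_hop(id, f)
  expect_lte(max(abs(out$pixels - f$pixels)), 1 / 255)
  expect_true(all(out$valid))
  # center pixel carries the center intensity under any model
  m <- hop_model(3L, rep(0.01, 7), rep(-0.01, 7), geom$scale, FD)
  outm <- apply_hop(m, f)
  cpx <- round(geom$center)
  expect_lt(abs(outm$pixels[cpx[2] + 1, cpx[1] + 1] -
                slidestitch:::bilinear_sample(f$pixels,
                                              geom$center[1],
                                              geom$center[2])), 0.06)
  # correcting the known distortion reproduces the undistorted crop
  truth_model <- true_radial_hop(c(scan$cfg$distortion, 0)[1:2], FD)
  cf <- apply_hop(truth_model, f)
  pos <- as.numeric(scan$truth[1, c("x", "y")])
  gx <- rep(0:(FD[1] - 1), each = FD[2])
  gy <- rep(0:(FD[2] - 1), times = FD[1])
  ref <- matrix(slidestitch:::bilinear_sample(scan$slide$image,
                                              pos[1] + gx, pos[2] + gy),
                FD[2], FD[1])
  sel <- cf$valid
  expect_gt(cor(cf$pixels[sel], ref[sel]), 0.98)
})

test_that("a non-invertible model is rejected with a located error", {
  geom <- slidestitch:::norm_geometry(FD[1], FD[2])
  bad <- hop_model(2L, c(-3, 0, 0), c(0, 0, 0), geom$scale, FD)
  f <- fov(0, matrix(0.5, FD[2], FD[1]))
  expect_error(apply_hop(bad, f), "non-invertible")
})

test_that("models serialize to JSON and back", {
  withr::with_seed(6, {
    m <- hop_model(3L, rnorm(7, 0, 0.01), rnorm(7, 0, 0.01),
                   slidestitch:::norm_geometry(FD[1], FD[2])$scale, FD)
  })
  p <- withr::local_tempfile(fileext = ".json")
  save_hop(m, p)
  m2 <- load_hop(p)
  expect_equal(m2$coeffs_x, m$coeffs_x)
  expect_equal(m2$coeffs_y, m$coeffs_y)
  expect_equal(m2$order, m$order)
  expect_equal(m2$domain_scale, m$domain_scale)
})
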