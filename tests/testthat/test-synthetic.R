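# Ground-truthed generator: determinism, geometry, distortion closed form,
# fault injection and the representability bound for the distortion family.

test_that("slide generation is deterministic and respects its knobs", {
  cfg <- synthetic_config(slide_dim = c(512L, 384L), seed = 9L)
  a <- generate_slide(cfg)
  b <- generate_slide(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$blobs, b$blobs)
  expect_equal(nrow(a$blobs),
               round(cfg$nucleus_density * 512 * 384))
  expect_true(all(a$blobs$x >= 0 & a$blobs$x < 512))
  expect_true(all(a$blobs$y >= 0 & a$blobs$y < 384))
  # zero density: texture only, no strong blob responses at nucleus scales
  cfg0 <- synthetic_config(slide_dim = c(512L, 384L), seed = 9L,
                           nucleus_density = 0, stromal_sd = 0,
                           texture_sd = 0.005)
  s0 <- generate_slide(cfg0)
  kp <- detect(fov(0, s0$image[1:256, 1:256]),
               detector_config(min_absolute_response = 1e-3))
  expect_lt(nrow(kp$keypoints), 5L)
})

test_that("serpentine geometry matches the overlap arithmetic", {
  cfg <- synthetic_config(slide_dim = c(1344L, 760L), seed = 3L,
                          grid = c(3L, 2L), overlap = 0.3, jitter_sd = 0)
  scan <- generate_scan(generate_slide(cfg), cfg)
  tt <- scan$truth
  expect_equal(nrow(tt), 6L)
  # same-row consecutive offsets are exactly (0.7 W, 0)
  expect_equal(as.numeric(tt[2, c("x", "y")]) - as.numeric(tt[1, c("x", "y")]),
               c(0.7 * 480, 0))
  expect_equal(as.numeric(tt[3, c("x", "y")]) - as.numeric(tt[2, c("x", "y")]),
               c(0.7 * 480, 0))
  # row transition moves down, serpentine reverses direction
  expect_equal(as.numeric(tt[4, c("x", "y")]) - as.numeric(tt[3, c("x", "y")]),
               c(0, 0.7 * 360))
  expect_equal(as.numeric(tt[5, c("x", "y")]) - as.numeric(tt[4, c("x", "y")]),
               c(-0.7 * 480, 0))
  # determinism of the whole scan
  scan2 <- generate_scan(generate_slide(cfg), cfg)
  expect_identical(scan$session$fovs[[4]]$pixels, scan2$session$fovs[[4]]$pixels)
  expect_identical(scan$client_fovs[[2]]$pixels, scan2$client_fovs[[2]]$pixels)
  # an oversized grid errors
  cfg_bad <- synthetic_config(slide_dim = c(1344L, 760L), grid = c(9L, 9L))
  expect_error(generate_scan(generate_slide(cfg), cfg_bad), "exit the slide")
})

test_that("distortion displaces corners by the closed-form radial amount", {
  k <- c(0.05, -0.01)
  cfg <- synthetic_config(slide_dim = c(1344L, 760L), seed = 5L,
                          grid = c(2L, 1L), distortion = k, jitter_sd = 0)
  sl <- generate_slide(cfg)
  scan <- generate_scan(sl, cfg)
  f <- scan$session$fovs[[1]]
  pos <- as.numeric(scan$truth[1, c("x", "y")])
  geom <- slidestitch:::norm_geometry(480, 360)
  # the exact frame center is undisplaced: P(0) = 0
  expect_equal(slidestitch:::radial_correct(matrix(c(0, 0), 1), k)[1, ],
               c(0, 0))
  # a probe pixel sees slide content displaced by R*(P(u_n) - u_n): verify
  # by sampling the slide at the predicted source to 0.1 px equivalence
  probe <- c(30, 40)
  un <- (probe - geom$center) / geom$scale
  src <- pos + geom$center + geom$scale *
    slidestitch:::radial_correct(matrix(un, 1), k)[1, ]
  expect_lt(abs(f$pixels[probe[2] + 1, probe[1] + 1] -
                slidestitch:::bilinear_sample(sl$image, src[1], src[2])),
            1.5 / 255)
})

test_that("fault frames are generated as designed", {
  cfg <- synthetic_config(slide_dim = c(1344L, 760L), seed = 7L,
                          grid = c(3L, 2L), overlap = 0.35,
                          faults = list(list(frame = 4L, type = "blank"),
                                        list(frame = 6L, type = "jump")))
  scan <- generate_scan(generate_slide(cfg), cfg)
  tt <- scan$truth
  expect_equal(nrow(tt), 8L)
  blank <- scan$session$fovs[[5]]$pixels
  expect_equal(max(blank) - min(blank), 0)
  expect_equal(tt$fault, c("none", "none", "none", "none", "blank", "none",
                           "jump", "none"))
  # the jump frame is offset by 0.75 FoV width from the previous path frame
  jrow <- tt[tt$fault == "jump", ]
  prev <- tt[6, ]
  expect_equal(abs(jrow$x - prev$x), 0.75 * 480)
  # path frames are unaffected by the insertions
  expect_equal(sum(tt$fault == "none"), 6L)
})

test_that("the radial family is representable by HOP at the stated orders", {
  # direct polynomial fit to the closed form on the unit disk bounds what
  # fit_hop can achieve. The quintic family is exact at order 5 (< 0.1 px
  # at any scale); the order-3 truncation residual is a fixed fraction of
  # the half-diagonal R, so the absolute < 0.5 px bound applies at
  # R ~ 120 px (a 192x144 FoV) and scales linearly for larger FoVs.
  gr <- as.matrix(expand.grid(x = seq(-1, 1, length.out = 41),
                              y = seq(-1, 1, length.out = 41)))
  gr <- gr[rowSums(gr^2) <= 1, ]
  fit_err <- function(k, D) {
    target <- slidestitch:::radial_correct(gr, k) - gr
    mono <- slidestitch:::hop_monomials(D)
    Phi <- slidestitch:::hop_design(gr, mono)
    res <- target - cbind(Phi %*% qr.coef(qr(Phi), target[, 1]),
                          Phi %*% qr.coef(qr(Phi), target[, 2]))
    max(sqrt(rowSums(res^2)))           # normalized units (fraction of R)
  }
  R_ref <- slidestitch:::norm_geometry(192, 144)$scale
  worst3 <- 0; worst5 <- 0
  for (k in list(c(0.08, 0.02), c(-0.08, -0.02), c(0.08, -0.02),
                 c(0.05, 0.015))) {
    worst3 <- max(worst3, fit_err(k, 3L))
    worst5 <- max(worst5, fit_err(k, 5L))
  }
  expect_lt(worst5 * R_ref, 0.1)
  expect_lt(worst3 * R_ref, 0.5)
  # cubic-only truths (the distortion-recovery world) are exact at order 3
  expect_lt(fit_err(c(0.08, 0), 3L) * 300, 1e-6)
})

test_that("ground truth round trips through truth.json", {
  scan <- small_scan()
  dir <- withr::local_tempdir()
  p <- save_ground_truth(scan, dir)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$distortion, scan$cfg$distortion)
  expect_equal(nrow(j$truth), nrow(scan$truth))
  expect_equal(j$truth$x, scan$truth$x)
})
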