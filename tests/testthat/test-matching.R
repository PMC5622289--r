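# Pairwise matching: translation recovery, selective pruning semantics,
# robust consensus, and the selective/brute equivalence + antisymmetry
# properties on a batch of seeded synthetic pairs.

test_that("brute-force matching recovers crop offsets", {
  sl <- small_slide()
  a <- detect(crop_fov(sl$image, 0L, 100, 50))
  # self-match of a disjoint copy at offset (0, 0)
  b0 <- detect(crop_fov(sl$image, 1L, 100, 50))
  m0 <- match_brute_force(a, b0)
  expect_equal(m0$status, "no_error")
  expect_lt(max(abs(m0$translation)), 0.5)
  expect_equal(m0$candidate_evaluations,
               nrow(a$keypoints) * nrow(b0$keypoints))
  # generator crop offset (37, -12) is the oracle
  b <- detect(crop_fov(sl$image, 2L, 137, 38))
  m <- match_brute_force(a, b)
  expect_lt(max(abs(m$translation - c(37, -12))), 1)
})

test_that("featureless pairs are lost, not an error", {
  withr::with_seed(8, {
    na <- fov(0, matrix(runif(256 * 192, 0.49, 0.51), 192, 256))
    nb <- fov(1, matrix(runif(256 * 192, 0.49, 0.51), 192, 256))
  })
  m <- match_brute_force(detect(na), detect(nb))
  expect_true(m$status %in% c("lost"))
  expect_lt(sum(m$inliers), match_config()$min_inliers)
  expect_null(m$translation)
})

test_that("selective matching equals brute force at lower cost", {
  sl <- small_slide()
  a <- detect(crop_fov(sl$image, 0L, 60, 120))
  b <- detect(crop_fov(sl$image, 1L, 123, 101))   # t = (63, -19)
  mb <- match_brute_force(a, b)
  ms <- match_selective(a, b, c(63, -19) + c(10, -8))
  expect_equal(ms$status, "no_error")
  expect_lt(max(abs(ms$translation - mb$translation)), 1)
  expect_lt(ms$candidate_evaluations, mb$candidate_evaluations)
})

test_that("a prior wrong by more than the radius reports lost_with_prior", {
  sl <- small_slide()
  a <- detect(crop_fov(sl$image, 0L, 60, 120))
  b <- detect(crop_fov(sl$image, 1L, 123, 101))
  ms <- match_selective(a, b, c(63, -19) + c(400, 0))
  expect_equal(ms$status, "lost_with_prior")
  expect_null(ms$translation)
})

test_that("selective candidate fraction matches the geometric expectation", {
  # uniform keypoints in a 512x512 FoV, radius 64: expected fraction of
  # candidate evaluations ~ pi * 64^2 / 512^2 ~ 0.049
  withr::with_seed(21, {
    fake_kps <- function(idx, n) {
      structure(list(fov_index = idx,
                     keypoints = data.frame(x = runif(n, 0, 511),
                                            y = runif(n, 0, 511),
                                            scale = 2, response = 1,
                                            layer = 1),
                     descriptors = matrix(rnorm(n * 64), n, 64)),
                class = "keypoint_set")
    }
    fr <- replicate(10, {
      a <- fake_kps(0L, 150L)
      b <- fake_kps(1L, 150L)
      m <- match_selective(a, b, c(0, 0), match_config(selective_radius = 64))
      m$candidate_evaluations / (150 * 150)
    })
  })
  expect_lt(abs(mean(fr) - pi * 64^2 / 512^2), 0.02)
})

test_that("translation consensus is robust and thresholded", {
  mk <- function(pos) {
    structure(list(fov_index = 0L,
                   keypoints = data.frame(x = pos[, 1], y = pos[, 2],
                                          scale = 2, response = 1, layer = 1),
                   descriptors = matrix(0, nrow(pos), 64)),
              class = "keypoint_set")
  }
  withr::with_seed(3, {
    base <- cbind(runif(20, 50, 200), runif(20, 50, 200))
  })
  pairs <- data.frame(idx_a = 1:20, idx_b = 1:20, dist = 0.1)
  # all pairs displaced exactly (5, 7)
  est <- estimate_translation(pairs, mk(base + matrix(c(5, 7), 20, 2,
                                                      byrow = TRUE)),
                              mk(base))
  expect_equal(est$translation, c(5, 7))
  expect_equal(sum(est$inliers), 20L)
  expect_equal(est$rms, 0)
  # 15 consistent + 5 outliers offset by >= 50 px
  shifted <- base + matrix(c(5, 7), 20, 2, byrow = TRUE)
  withr::with_seed(4, {
    shifted[16:20, ] <- shifted[16:20, ] +
      cbind(runif(5, 50, 120), runif(5, 50, 120))
  })
  est2 <- estimate_translation(pairs, mk(shifted), mk(base))
  expect_lt(max(abs(est2$translation - c(5, 7))), 0.5)
  expect_equal(sum(est2$inliers), 15L)
  # below min_inliers -> failure
  est3 <- estimate_translation(pairs[1:4, ], mk(shifted), mk(base))
  expect_null(est3$translation)
})

test_that("selective/brute agreement, cost reduction and antisymmetry hold over seeded pairs", {
  sl <- small_slide()
  reduction <- numeric(0)
  withr::with_seed(31, {
    for (i in 1:8) {
      x <- sample(60:300, 1); y <- sample(50:230, 1)
      dx <- sample(-60:80, 1); dy <- sample(-45:45, 1)
      a <- detect(crop_fov(sl$image, 0L, x, y))
      b <- detect(crop_fov(sl$image, 1L, x + dx, y + dy))
      mb <- match_brute_force(a, b)
      prior <- c(dx, dy) + round(runif(2, -20, 20))
      ms <- match_selective(a, b, prior)
      expect_equal(ms$status, "no_error")
      expect_lt(max(abs(ms$translation - mb$translation)), 1)
      expect_lt(max(abs(ms$translation - c(dx, dy))), 1)
      reduction <- c(reduction,
                     1 - ms$candidate_evaluations / mb$candidate_evaluations)
      # antisymmetry
      mrev <- match_selective(b, a, -prior)
      expect_lt(max(abs(mrev$translation + ms$translation)), 1)
    }
  })
  expect_true(all(reduction > 0))
  expect_gt(mean(reduction), 0.5)
})
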