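# Global layout, rendering and pyramid export.

mklink <- function(a, b, t) list(fov_a = a, fov_b = b, t_server = t)

test_that("chain and cycle layouts are solved exactly", {
  chain <- list(mklink(0L, 1L, c(100, 0)), mklink(1L, 2L, c(100, 0)))
  lay <- solve_layout(chain)
  expect_equal(lay$positions$x, c(0, 100, 200))
  expect_equal(lay$positions$y, c(0, 0, 0))
  # consistent 2x2 cycle: truth (0,0) (120,0) (120,90) (0,90)
  cyc <- list(mklink(0L, 1L, c(120, 0)), mklink(1L, 2L, c(0, 90)),
              mklink(2L, 3L, c(-120, 0)), mklink(3L, 0L, c(0, -90)))
  lay2 <- solve_layout(cyc)
  expect_equal(lay2$positions$x, c(0, 120, 120, 0), tolerance = 1e-12)
  expect_equal(lay2$positions$y, c(0, 0, 90, 90), tolerance = 1e-12)
  expect_lt(max(lay2$residuals), 1e-12)
  # single FoV
  expect_equal(solve_layout(list(), fov_indices = 5L)$positions$x, 0)
})

test_that("a perturbed cycle distributes residuals and matches the dense oracle", {
  cyc <- list(mklink(0L, 1L, c(124, 0)), mklink(1L, 2L, c(0, 90)),
              mklink(2L, 3L, c(-120, 0)), mklink(3L, 0L, c(0, -90)))
  lay <- solve_layout(cyc)
  expect_lt(max(lay$residuals), 4)
  expect_gt(max(lay$residuals), 0)
  # dense normal-equations oracle
  A <- matrix(0, 4, 4)
  A[cbind(1:4, c(1, 2, 3, 4))] <- -1
  A[cbind(1:4, c(2, 3, 4, 1))] <- 1
  tm <- rbind(c(124, 0), c(0, 90), c(-120, 0), c(0, -90))
  Ar <- A[, -1]
  px <- solve(t(Ar) %*% Ar, t(Ar) %*% tm[, 1])
  py <- solve(t(Ar) %*% Ar, t(Ar) %*% tm[, 2])
  expect_equal(lay$positions$x[-1], as.numeric(px), tolerance = 1e-9)
  expect_equal(lay$positions$y[-1], as.numeric(py), tolerance = 1e-9)
})

test_that("random connected graphs match the dense least-squares oracle", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(5:30, 1)
      truth <- cbind(runif(n, 0, 2000), runif(n, 0, 1500))
      # spanning chain plus random extra edges, translations = truth + noise
      ed <- cbind(1:(n - 1), 2:n)
      extra <- max(1L, n %/% 2L)
      ed <- rbind(ed, t(replicate(extra, sample.int(n, 2))))
      ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
      tm <- truth[ed[, 2], ] - truth[ed[, 1], ] +
        matrix(rnorm(2 * nrow(ed), 0, 2), ncol = 2)
      links <- lapply(seq_len(nrow(ed)), function(i)
        mklink(ed[i, 1] - 1L, ed[i, 2] - 1L, tm[i, ]))
      lay <- solve_layout(links)
      A <- matrix(0, nrow(ed), n)
      A[cbind(seq_len(nrow(ed)), ed[, 1])] <- -1
      A[cbind(seq_len(nrow(ed)), ed[, 2])] <- 1
      Ar <- A[, -1]
      px <- solve(t(Ar) %*% Ar, t(Ar) %*% tm[, 1])
      py <- solve(t(Ar) %*% Ar, t(Ar) %*% tm[, 2])
      expect_equal(lay$positions$x[-1], as.numeric(px), tolerance = 1e-9)
      expect_equal(lay$positions$y[-1], as.numeric(py), tolerance = 1e-9)
    }
  })
})

test_that("exact translations from a true assignment are recovered exactly", {
  withr::with_seed(23, {
    truth <- cbind(runif(12, 0, 900), runif(12, 0, 700))
    ed <- rbind(cbind(1:11, 2:12), c(1, 12), c(3, 9))
    links <- lapply(seq_len(nrow(ed)), function(i)
      mklink(ed[i, 1] - 1L, ed[i, 2] - 1L,
             truth[ed[i, 2], ] - truth[ed[i, 1], ]))
  })
  lay <- solve_layout(links)
  rec <- cbind(lay$positions$x, lay$positions$y)
  shift <- sweep(truth, 2, truth[1, ])
  expect_equal(rec, unname(shift), tolerance = 1e-9)
  expect_lt(max(lay$residuals), 1e-9)
})

test_that("disconnected graphs raise an error listing components", {
  links <- list(mklink(0L, 1L, c(1, 0)), mklink(5L, 6L, c(1, 0)))
  expect_error(solve_layout(links), "disconnected")
})

test_that("rendering a single FoV reproduces it exactly", {
  sl <- small_slide()
  f <- crop_fov(sl$image, 0L, 30, 40, w = 120L, h = 100L)
  lay <- solve_layout(list(), fov_indices = 0L)
  vs <- render(lay, list(f))
  expect_equal(dim(vs$canvas), c(100L, 120L))
  expect_equal(vs$canvas, f$pixels)
  expect_true(all(vs$mask))
})

test_that("overlapping identical content blends seamlessly", {
  sl <- small_slide()
  a <- crop_fov(sl$image, 0L, 50, 60, w = 160L, h = 120L)
  b <- crop_fov(sl$image, 1L, 130, 60, w = 160L, h = 120L)
  lay <- solve_layout(list(mklink(0L, 1L, c(80, 0))))
  vs <- render(lay, list(a, b))
  ref <- sl$image[61:180, 51:290]
  expect_lte(max(abs(vs$canvas - ref)), 1 / 255 + 1e-12)
})

test_that("pyramid export tiles, reassembles bit-exactly and conserves intensity", {
  sl <- small_slide()
  canvas <- sl$image[1:400, 1:600]
  vs <- structure(list(canvas = canvas,
                       mask = matrix(TRUE, 400, 600),
                       origin = c(0, 0), tile_size = 256L),
                  class = "virtual_slide")
  dir <- withr::local_tempdir()
  desc <- export_pyramid(vs, dir)
  expect_true(file.exists(desc))
  x <- xml2::read_xml(desc)
  expect_equal(xml2::xml_attr(x, "TileSize"), "256")
  # level 0: 3x2 tiles with ragged last row/column
  t0 <- list.files(file.path(dir, "slide_files", "0"))
  expect_length(t0, 6L)
  re0 <- reassemble_level(dir, 0L)
  expect_identical(re0$canvas, canvas)
  # all levels reassemble to the successive box-downsample
  lv <- list(canvas = canvas, mask = vs$mask)
  li <- 0L
  while (max(dim(lv$canvas)) > 256L) {
    lv <- slidestitch:::pyramid_down(lv$canvas, lv$mask)
    li <- li + 1L
    re <- reassemble_level(dir, li)
    expect_identical(re$canvas, lv$canvas)
    expect_lt(abs(mean(re$canvas) - mean(canvas)), 0.5 / 255 * (li + 1))
  }
  expect_lte(max(dim(lv$canvas)), 256L)
  # a small canvas yields a single level
  vs2 <- structure(list(canvas = canvas[1:200, 1:200],
                        mask = matrix(TRUE, 200, 200),
                        origin = c(0, 0), tile_size = 256L),
                   class = "virtual_slide")
  d2 <- withr::local_tempdir()
  export_pyramid(vs2, d2)
  expect_equal(list.files(file.path(d2, "slide_files")), "0")
})
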