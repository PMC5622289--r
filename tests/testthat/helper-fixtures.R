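# Shared fixtures, built once per test run. Small worlds keep the suite
# fast; the acceptance tests use the full-size defaults where a criterion
# demands it.

# A compact slide reused by detector/matching tests (no scan path needed,
# so margins do not apply).
small_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_slide(synthetic_config(slide_dim = c(640L, 480L),
                                                seed = 101L))
    cache
  }
})

# Crop a server-tier FoV out of a slide image at 0-based position (x, y).
crop_fov <- function(slide_img, index, x, y, w = 256L, h = 192L) {
  fov(index, slide_img[(y + 1L):(y + h), (x + 1L):(x + w)])
}

# A small clean scan with distortion, shared by tracker/pipeline tests.
small_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(slide_dim = c(1344L, 760L), seed = 42L,
                              distortion = c(0.05, 0), grid = c(3L, 2L),
                              overlap = 0.35)
      cache <<- generate_scan(generate_slide(cfg), cfg)
    }
    cache
  }
})

records_fixture_path <- function() {
  system.file("extdata", "diagnosis_records.csv", package = "slidestitch",
              mustWork = TRUE)
}

# True radial inverse-distortion expressed exactly as a hop_model (degree 5).
true_radial_hop <- function(k, fov_dim) {
  mono <- slidestitch:::hop_monomials(5L)
  cx <- numeric(nrow(mono)); cy <- numeric(nrow(mono))
  setc <- function(v, p, q, val) {
    v[mono$p == p & mono$q == q] <- val
    v
  }
  cx <- setc(cx, 3, 0, k[1]); cx <- setc(cx, 1, 2, k[1])
  cx <- setc(cx, 5, 0, k[2]); cx <- setc(cx, 3, 2, 2 * k[2])
  cx <- setc(cx, 1, 4, k[2])
  cy <- setc(cy, 0, 3, k[1]); cy <- setc(cy, 2, 1, k[1])
  cy <- setc(cy, 0, 5, k[2]); cy <- setc(cy, 2, 3, 2 * k[2])
  cy <- setc(cy, 4, 1, k[2])
  geom <- slidestitch:::norm_geometry(fov_dim[1], fov_dim[2])
  hop_model(5L, cx, cy, geom$scale, fov_dim)
}
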