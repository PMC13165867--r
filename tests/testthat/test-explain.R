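test_that("occlusion importance validates the grid and is deterministic", {
  m <- tiny_model()
  s <- tiny_dataset(1)[[1]]
  expect_error(occlusion_importance(m, s, grid = c(300L, 4L)), "invalid")
  a <- occlusion_importance(m, s, grid = c(2L, 2L))
  b <- occlusion_importance(m, s, grid = c(2L, 2L))
  expect_identical(a$importance, b$importance)
  expect_equal(dim(a$importance), c(2, 2))
  expect_s3_class(a, "occlusion_map")
})

test_that("cell foreground fractions partition the mask", {
  m <- tiny_model()
  s <- tiny_dataset(1)[[1]]
  omap <- occlusion_importance(m, s, grid = c(2L, 2L))
  frac <- cell_foreground_fraction(s$mask, omap)
  expect_equal(dim(frac), c(2, 2))
  # cell areas are equal (256 divides evenly), so the mean of the per-cell
  # fractions is the global foreground fraction
  expect_equal(mean(frac), mean(s$mask), tolerance = 1e-12)
})
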