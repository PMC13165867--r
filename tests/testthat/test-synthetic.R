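test_that("scene generation is deterministic and index-varied", {
  cfg <- scene_config(image_size = c(64L, 64L))
  a <- generate_scene(cfg, 1)
  b <- generate_scene(cfg, 1)
  c <- generate_scene(cfg, 2)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$image, c$image))
})

test_that("samples satisfy the contract", {
  cfg <- scene_config(image_size = c(64L, 64L))
  s <- generate_scene(cfg, 3)
  expect_equal(dim(s$image), c(64, 64, 3))
  expect_true(min(s$image) >= 0 && max(s$image) <= 1)
  expect_true(all(s$mask %in% c(0, 1)))
  af <- s$meta$area_fraction_pre_occlusion
  expect_true(af >= cfg$organ_area_range[1] && af <= cfg$organ_area_range[2])
})

test_that("occluders carve pixels out of the mask unless asked not to", {
  cfg <- scene_config(image_size = c(64L, 64L), n_occluders = 2L)
  carved <- generate_scene(cfg, 5, mask_includes_occluded = FALSE)
  full <- generate_scene(cfg, 5, mask_includes_occluded = TRUE)
  expect_true(all(full$mask - carved$mask >= 0))
  expect_gte(sum(full$mask), sum(carved$mask))
})

test_that("configuration validation names the offending field", {
  expect_error(scene_config(organ_area_range = c(0.5, 0.1)),
               "organ_area_range")
  expect_error(scene_config(noise_sigma = -1), "noise_sigma")
  expect_error(scene_config(specular_prob = 2), "specular_prob")
})

test_that("datasets have unique ids and respect n", {
  ds <- generate_dataset(3, scene_config(image_size = c(64L, 64L)))
  expect_length(ds, 3)
  ids <- vapply(ds, function(s) s$sample_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_error(generate_dataset(0), "n must be")
})
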