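test_that("presets toggle the expected stages", {
  p <- preprocess_presets()
  expect_named(p, c("none", "clahe", "clahe_denoise", "full"))
  expect_false(p$none$enable_clahe)
  expect_true(p$clahe$enable_clahe && !p$clahe$enable_denoise)
  expect_true(p$clahe_denoise$enable_denoise &&
                !p$clahe_denoise$enable_mask_refine)
  expect_true(p$full$enable_clahe && p$full$enable_denoise &&
                p$full$enable_mask_refine)
})

test_that("disabled stages are exact no-ops", {
  s <- generate_scene(scene_config(image_size = c(64L, 64L)), 1)
  off <- preprocess_config(enable_clahe = FALSE, enable_denoise = FALSE,
                           enable_mask_refine = FALSE)
  expect_identical(apply_clahe(s$image, off), s$image)
  expect_identical(denoise_nlm(s$image, off), s$image)
  expect_identical(refine_mask(s$mask, off), s$mask)
})

test_that("CLAHE changes the image but stays in range", {
  s <- generate_scene(scene_config(image_size = c(64L, 64L)), 2)
  cfg <- preprocess_config()
  out <- apply_clahe(s$image, cfg)
  expect_equal(dim(out), dim(s$image))
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_false(identical(out, s$image))
})

test_that("denoising reduces noise on a noisy flat image", {
  set.seed(9)
  img <- array(0.5 + stats::rnorm(48 * 48 * 3, sd = 0.05), c(48, 48, 3))
  img[img < 0] <- 0; img[img > 1] <- 1
  cfg <- preprocess_config(nlm_strength = 0.1)
  out <- denoise_nlm(img, cfg)
  expect_lt(stats::sd(out), stats::sd(img))
})

test_that("mask refinement removes specks and fills pinholes", {
  m <- matrix(0, 32, 32)
  m[10:22, 10:22] <- 1
  m[16, 16] <- 0        # pinhole
  m[2, 2] <- 1          # speck
  out <- refine_mask(m, preprocess_config(morph_kernel_size = 3L))
  expect_equal(out[2, 2], 0)
  expect_equal(out[16, 16], 1)
  expect_true(all(out %in% c(0, 1)))
})

test_that("standardization resizes and binarizes to the contract", {
  s <- generate_scene(scene_config(image_size = c(100L, 80L)), 3)
  cfg <- preprocess_config(target_size = c(64L, 64L))
  out <- standardize_sample(s, cfg)
  expect_equal(dim(out$image), c(64, 64, 3))
  expect_equal(dim(out$mask), c(64, 64))
  expect_true(all(out$mask %in% c(0, 1)))
  expect_true(min(out$image) >= 0 && max(out$image) <= 1)
})

test_that("full pipeline is deterministic", {
  s <- generate_scene(scene_config(image_size = c(64L, 64L)), 4)
  cfg <- preprocess_config(target_size = c(64L, 64L),
                           nlm_search_window = 9L)
  a <- preprocess_sample(s, cfg)
  b <- preprocess_sample(s, cfg)
  expect_identical(a, b)
})

test_that("preprocess configuration validates its inputs", {
  expect_error(preprocess_config(binarize_threshold = 0), "binarize_threshold")
  expect_error(preprocess_config(clahe_clip_limit = -1), "clahe_clip_limit")
  expect_error(preprocess_config(nlm_template_window = 4L), "odd")
})
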