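test_that("architecture specification validates its inputs", {
  expect_error(architecture_spec("nonsense"))
  expect_error(architecture_spec(aspp_dilations = c(4, 2)), "increasing")
  expect_error(architecture_spec(width_multiplier = 0), "width_multiplier")
  expect_error(architecture_spec(input_size = c(100L, 100L, 3L)),
               "divisible by 32")
})

test_that("all four variants build and expose the right endpoints", {
  for (v in c("imau_net", "inceptionv3_unet", "mcp_unet", "aspp_unet")) {
    m <- build_model(architecture_spec(v, width_multiplier = 0.0625),
                     seed = 1)
    expect_s3_class(m, "segmentation_model")
    expect_gt(m$parameter_count, 0)
    expect_true("head" %in% names(m$graph$nodes))
    if (v %in% c("imau_net", "mcp_unet"))
      expect_true(!is.null(m$endpoints$mcp))
    if (v %in% c("imau_net", "aspp_unet"))
      expect_true(!is.null(m$endpoints$aspp_concat))
  }
})

test_that("bottleneck fan-in widths are 768 (MCP) and 1280 (ASPP) at full width", {
  spec <- architecture_spec("imau_net")
  mcp <- build_mcp_block(512L, spec, input_size = c(8L, 8L), seed = 1)
  expect_identical(mcp$out_channels, 768L)
  aspp <- build_aspp_block(512L, spec, input_size = c(8L, 8L), seed = 1)
  expect_identical(aspp$concat_channels, 1280L)
  expect_identical(aspp$out_channels, 512L)
  set.seed(1)
  x <- array(stats::runif(8 * 8 * 512), c(8, 8, 512, 1))
  expect_equal(dim(mcp$forward(x))[3], 768)
  y <- aspp$forward(x)
  expect_equal(dim(y$concat)[3], 1280)
  expect_equal(dim(y$out)[3], 512)
})

test_that("width scaling follows max(1, round(f * wm))", {
  spec <- architecture_spec("imau_net", width_multiplier = 0.125)
  mcp <- build_mcp_block(64L, spec, input_size = c(8L, 8L), seed = 1)
  expect_identical(mcp$out_channels, 3L * 32L)
  tinyspec <- architecture_spec("imau_net", width_multiplier = 0.001)
  mcp1 <- build_mcp_block(4L, tinyspec, input_size = c(8L, 8L), seed = 1)
  expect_identical(mcp1$out_channels, 3L)  # every branch floors at 1 filter
})

test_that("initialization is seed-deterministic", {
  spec <- architecture_spec("imau_net", width_multiplier = 0.0625)
  a <- build_model(spec, seed = 7)
  b <- build_model(spec, seed = 7)
  c <- build_model(spec, seed = 8)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("forward pass and predict respect the output contract", {
  m <- tiny_model()
  ds <- tiny_dataset(2)
  p <- predict(m, ds[[1]], type = "prob")
  expect_equal(dim(p), c(256, 256))
  expect_true(all(p > 0 & p < 1))
  msk <- predict(m, ds[[1]], type = "mask")
  expect_true(all(msk %in% c(0, 1)))
  expect_identical(p, predict(m, ds[[1]], type = "prob"))  # deterministic
})

test_that("print and summary methods run and mention the key facts", {
  m <- tiny_model()
  expect_output(print(m), "imau_net")
  expect_output(print(m), "parameters")
  expect_output(print(summary(m)), "head")
})

test_that("pretrained backbone weights are not available offline", {
  expect_error(build_encoder_taps(pretrained = TRUE), "pretrained|weights")
})
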