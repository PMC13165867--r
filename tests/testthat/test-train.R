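test_that("train configuration validates its inputs", {
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(loss = "bce"))
})

test_that("a few optimizer steps reduce the training loss", {
  m <- tiny_model()
  ds <- tiny_dataset(2)
  cfg <- train_config(batch_size = 2, epochs = 6, seed = 1,
                      convergence_patience = 100L)
  tr <- train_segmenter(m, ds, ds, cfg)
  expect_true(tr$trained)
  h <- tr$history
  expect_length(h$train_loss, 6)
  expect_length(h$val_dice, 6)
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_equal(h$steps, 6L)
})

test_that("training is seed-deterministic", {
  ds <- tiny_dataset(2)
  cfg <- train_config(batch_size = 2, epochs = 2, seed = 5,
                      convergence_patience = 100L)
  a <- train_segmenter(tiny_model(), ds, ds, cfg)
  b <- train_segmenter(tiny_model(), ds, ds, cfg)
  expect_identical(a$history$train_loss, b$history$train_loss)
  expect_identical(a$params, b$params)
})

test_that("max_steps_override caps the number of updates", {
  ds <- tiny_dataset(2)
  cfg <- train_config(batch_size = 1, epochs = 10, seed = 1,
                      max_steps_override = 3L,
                      convergence_patience = 100L)
  tr <- train_segmenter(tiny_model(), ds, ds, cfg)
  expect_identical(tr$history$steps, 3L)
})

test_that("fold assignment is disjoint, covering and balanced", {
  ds <- tiny_dataset(11)
  folds <- make_folds(ds, k = 3, seed = 2)
  expect_s3_class(folds, "fold_assignment")
  all_ids <- sort(unlist(folds))
  expect_identical(all_ids,
                   sort(vapply(ds, function(s) s$sample_id, character(1))))
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  for (i in 1:2) for (j in (i + 1):3)
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  expect_error(make_folds(ds, k = 20), "smaller than k")
})

test_that("fold assignment stratifies by foreground area", {
  ds <- tiny_dataset(12)
  folds <- make_folds(ds, k = 2, seed = 1)
  ids <- vapply(ds, function(s) s$sample_id, character(1))
  areas <- vapply(ds, function(s) mean(s$mask), numeric(1))
  m1 <- mean(areas[ids %in% folds[[1]]])
  m2 <- mean(areas[ids %in% folds[[2]]])
  # stratified halves should have closer means than the worst-case split
  expect_lt(abs(m1 - m2), diff(range(areas)) / 2)
})

test_that("dataset splitting floors val/test and gives the rest to train", {
  ds <- as.list(seq_len(307))
  sp <- split_dataset(ds, seed = 1)
  expect_length(sp$train, 215)
  expect_length(sp$val, 46)
  expect_length(sp$test, 46)
  expect_length(unique(c(unlist(sp$train), unlist(sp$val),
                         unlist(sp$test))), 307)
  expect_error(split_dataset(ds, fractions = c(0.5, 0.5, 0.5)), "summing")
})
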