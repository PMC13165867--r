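# Shared fixtures, memoized so the expensive overfitting run happens once
# per test session and is reused by the training and explainability checks.

.fixture_env <- new.env(parent = emptyenv())

# Width-0.125 IMAU-Net, randomly initialized, overfit on 8 synthetic
# 256x256 scenes with Adam on the Dice loss; at most 200 optimizer steps.
overfit_fixture <- function() {
  if (!is.null(.fixture_env$overfit)) return(.fixture_env$overfit)
  spec <- architecture_spec("imau_net", width_multiplier = 0.125)
  model <- build_model(spec, seed = 1)
  dataset <- generate_dataset(8, scene_config(seed = 42))
  cfg <- train_config(batch_size = 8, epochs = 200, seed = 1,
                      max_steps_override = 200,
                      convergence_patience = 10000L,
                      target_train_dice = 0.93)
  t0 <- Sys.time()
  model <- train_segmenter(model, dataset, dataset, cfg)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  .fixture_env$overfit <- list(model = model, dataset = dataset,
                               elapsed = elapsed,
                               steps = model$history$steps)
  .fixture_env$overfit
}

# Small model for cheap structural tests: full 256x256 input (smaller
# inputs leave the deepest tap below the kernel-5 MCP pool) at the
# narrowest useful width.
tiny_model <- function() {
  if (!is.null(.fixture_env$tiny)) return(.fixture_env$tiny)
  spec <- architecture_spec("imau_net", width_multiplier = 0.0625)
  .fixture_env$tiny <- build_model(spec, seed = 3)
  .fixture_env$tiny
}

tiny_dataset <- function(n = 4) {
  if (is.null(.fixture_env$tinyds) || length(.fixture_env$tinyds) < n)
    .fixture_env$tinyds <- generate_dataset(n, scene_config(seed = 11))
  .fixture_env$tinyds[seq_len(n)]
}

random_mask <- function(h, w, p = 0.4) {
  matrix(as.numeric(stats::runif(h * w) < p), h, w)
}
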