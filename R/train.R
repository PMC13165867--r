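#' Training configuration
#'
#' Defaults follow the study protocol for the full model: Adam at learning
#' rate 1e-3 minimizing the soft Dice loss, batch size 32, up to 50 epochs,
#' with convergence defined as a validation-loss plateau.
#'
#' @param batch_size samples per gradient update (>= 1).
#' @param epochs maximum full passes over the training set (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param loss loss function; only \code{"dice"} is provided.
#' @param seed seed controlling initialization-independent randomness
#'   (shuffling).
#' @param max_steps_override optional cap on total optimizer steps
#'   (desk-scale runs).
#' @param convergence_patience epochs of validation-loss plateau (min-delta
#'   1e-4) before early stopping.
#' @param dice_smooth smoothing constant of the Dice loss.
#' @param target_train_dice optional early-stop target: training halts as
#'   soon as the batch-mean training Dice reaches it (overfitting probes).
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(batch_size = 32L, epochs = 50L,
                         learning_rate = 1e-3, loss = "dice", seed = 1L,
                         max_steps_override = NULL,
                         convergence_patience = 10L, dice_smooth = 1,
                         target_train_dice = NULL) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  loss <- match.arg(loss, "dice")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed),
                 max_steps_override = max_steps_override,
                 convergence_patience = as.integer(convergence_patience),
                 dice_smooth = dice_smooth,
                 target_train_dice = target_train_dice),
            class = "train_config")
}

samples_to_batch <- function(dataset) {
  n <- length(dataset)
  d <- dim(dataset[[1]]$image)
  x <- array(0, dim = c(d[1], d[2], 3L, n))
  y <- array(0, dim = c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- dataset[[i]]$image
    y[, , 1, i] <- dataset[[i]]$mask
  }
  list(x = x, y = y)
}

batch_dice_stats <- function(prob, y, smooth = 1) {
  n <- dim(prob)[4]
  losses <- numeric(n); dices <- numeric(n)
  for (i in seq_len(n)) {
    p <- prob[, , 1, i]; t <- y[, , 1, i]
    losses[i] <- dice_loss(p, t, smooth)
    cc <- confusion_counts((p > 0.5) + 0, t)
    dices[i] <- dice_coefficient(cc)
  }
  c(loss = mean(losses), dice = mean(dices))
}

#' Train a segmentation model
#'
#' Seeded Adam training on the soft Dice loss. Runs for at most
#' \code{cfg$epochs} epochs (or \code{cfg$max_steps_override} optimizer
#' steps) and stops early when the validation loss fails to improve by more
#' than 1e-4 for \code{cfg$convergence_patience} consecutive epochs.
#'
#' @param model a \code{\link{build_model}} object.
#' @param train_set,val_set non-empty lists of preprocessed samples whose
#'   size matches the model input.
#' @param cfg a \code{\link{train_config}}.
#' @param verbose print one line per epoch.
#' @return the trained model, with \code{history} holding per-epoch train
#'   loss/Dice, validation loss/Dice, the stopping epoch and total steps.
#' @export
train_segmenter <- function(model, train_set, val_set = train_set,
                            cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "segmentation_model"),
            inherits(cfg, "train_config"))
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("train_set and val_set must be non-empty")
  tr <- samples_to_batch(train_set)
  va <- samples_to_batch(val_set)
  n <- length(train_set)
  opt <- adam_init(model$params)
  hist <- list(train_loss = numeric(), train_dice = numeric(),
               val_loss = numeric(), val_dice = numeric())
  set.seed(cfg$seed)
  steps <- 0L
  best_val <- Inf; stall <- 0L; converged_epoch <- NA_integer_
  max_steps <- cfg$max_steps_override %||% Inf
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- c(); ep_dice <- c()
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- tr$y[, , , idx, drop = FALSE]
      fwd <- ng_forward(model$graph, model$params, xb, training = TRUE,
                        state = model$state)
      model$state <- fwd$state
      prob <- fwd$outs[["head"]]
      nb <- length(idx)
      ghead <- array(0, dim = dim(prob))
      bl <- 0
      for (i in seq_len(nb)) {
        p <- prob[, , 1, i]; t <- yb[, , 1, i]
        bl <- bl + dice_loss(p, t, cfg$dice_smooth) / nb
        ghead[, , 1, i] <- dice_loss_grad(p, t, cfg$dice_smooth) / nb
      }
      if (!is.finite(bl))
        stop("NaN/Inf loss at epoch ", epoch, ", step ", steps + 1L,
             "; aborting training")
      grads <- ng_backward(model$graph, model$params, fwd,
                           list(head = ghead))
      upd <- adam_step(model$params, grads, opt, lr = cfg$learning_rate)
      model$params <- upd$params; opt <- upd$opt
      steps <- steps + 1L
      st <- batch_dice_stats(prob, yb, cfg$dice_smooth)
      ep_loss <- c(ep_loss, bl); ep_dice <- c(ep_dice, st["dice"])
      if (steps >= max_steps) break
      if (!is.null(cfg$target_train_dice) &&
          st["dice"] >= cfg$target_train_dice) break
    }
    vfwd <- ng_forward(model$graph, model$params, va$x, training = FALSE,
                       state = model$state)
    vst <- batch_dice_stats(vfwd$outs[["head"]], va$y, cfg$dice_smooth)
    hist$train_loss <- c(hist$train_loss, mean(ep_loss))
    hist$train_dice <- c(hist$train_dice, mean(ep_dice))
    hist$val_loss <- c(hist$val_loss, vst["loss"])
    hist$val_dice <- c(hist$val_dice, vst["dice"])
    if (verbose)
      message(sprintf("epoch %d  loss %.4f dice %.4f | val %.4f / %.4f",
                      epoch, mean(ep_loss), mean(ep_dice), vst["loss"],
                      vst["dice"]))
    if (vst["loss"] < best_val - 1e-4) {
      best_val <- vst["loss"]; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$convergence_patience) {
        converged_epoch <- epoch
        break
      }
    }
    if (steps >= max_steps) break
    if (!is.null(cfg$target_train_dice) && length(ep_dice) &&
        ep_dice[length(ep_dice)] >= cfg$target_train_dice) break
  }
  hist$converged_epoch <- converged_epoch
  hist$steps <- steps
  model$state <- recalibrate_bn_stats(model, tr$x, cfg$batch_size)
  model$history <- hist
  model$trained <- TRUE
  model
}

# Replace the exponentially averaged batch-norm running statistics with the
# actual training-set statistics (one momentum-0 pass, averaged over
# batches). After short runs the 0.99-momentum averages are still dominated
# by their initialization, which would make inference-mode normalization
# inconsistent with the trained weights.
recalibrate_bn_stats <- function(model, x, batch_size) {
  n <- dim(x)[4]
  acc <- NULL; nb <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fwd <- ng_forward(model$graph, model$params,
                      x[, , , idx, drop = FALSE], training = TRUE,
                      state = model$state, momentum = 0)
    nb <- nb + 1
    if (is.null(acc)) acc <- fwd$state
    else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + fwd$state[[nm]]
  }
  lapply(acc, function(v) v / nb)
}

#' Plot training history
#'
#' @param x a trained \code{segmentation_model}.
#' @param ... passed to \code{matplot}.
#' @export
plot.segmentation_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
                    col = c("black", "red"), xlab = "epoch",
                    ylab = "Dice loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Stratifies by foreground-area quartile (the scalar available from the
#' masks alone), then deals samples to folds so fold sizes differ by at most
#' one and each fold's quartile composition tracks the global one.
#'
#' @param dataset list of image samples.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return object of class \code{fold_assignment}: list of \code{k}
#'   pairwise-disjoint sample-id vectors covering the dataset.
#' @export
make_folds <- function(dataset, k = 5L, seed = 1L) {
  n <- length(dataset)
  if (n < k) stop("dataset (", n, ") smaller than k (", k, ")")
  ids <- vapply(dataset, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  areas <- vapply(dataset, function(s) mean(s$mask), numeric(1))
  qs <- stats::quantile(areas, c(0.25, 0.5, 0.75))
  strat <- findInterval(areas, unique(qs))
  set.seed(as.integer(seed))
  ord <- order(strat, stats::runif(n))
  fold_of <- integer(n)
  fold_of[ord] <- rep_len(seq_len(k), n)
  folds <- lapply(seq_len(k), function(f) ids[fold_of == f])
  structure(folds, class = "fold_assignment")
}

#' k-fold cross-validation of one architecture
#'
#' Trains one model per fold on the remaining folds, evaluates on the
#' held-out fold (leakage asserted impossible), and aggregates the per-fold
#' mean metrics (mean and population standard deviation).
#'
#' @param spec an \code{\link{architecture_spec}}.
#' @param dataset list of preprocessed samples.
#' @param cfg a \code{\link{train_config}}.
#' @param k number of folds.
#' @return object of class \code{cv_summary}: per-fold metric table,
#'   aggregate mean/std, and per-image rows.
#' @export
run_cv <- function(spec, dataset, cfg = train_config(), k = 5L) {
  folds <- make_folds(dataset, k, cfg$seed)
  ids <- vapply(dataset, function(s) s$sample_id, character(1))
  fold_rows <- list(); image_rows <- list()
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(ids, test_ids)
    stopifnot(length(intersect(train_ids, test_ids)) == 0)  # no leakage
    tr <- dataset[match(train_ids, ids)]
    te <- dataset[match(test_ids, ids)]
    model <- build_model(spec, seed = cfg$seed + f)
    model <- train_segmenter(model, tr, te, cfg)
    ev <- evaluate_model(model, te)
    ev$fold <- f
    image_rows[[f]] <- ev
    fold_rows[[f]] <- data.frame(
      fold = f, dice = mean(ev$dice), iou = mean(ev$iou),
      precision = mean(ev$precision, na.rm = TRUE),
      recall = mean(ev$recall, na.rm = TRUE), mae = mean(ev$mae),
      hd95 = mean(ev$hd95, na.rm = TRUE), auc = mean(ev$auc, na.rm = TRUE))
  }
  fold_metrics <- do.call(rbind, fold_rows)
  out <- aggregate_folds(fold_metrics[, setdiff(names(fold_metrics), "fold")])
  out$fold_metrics <- fold_metrics
  out$image_metrics <- do.call(rbind, image_rows)
  out$folds <- folds
  out
}

variant_labels <- c(inceptionv3_unet = "Baseline (IncV3)",
                    mcp_unet = "+ MCP", aspp_unet = "+ ASPP",
                    imau_net = "Full IMAU-Net")

#' Architectural ablation experiment
#'
#' Trains the four variants under identical settings (cross-validated) and
#' tabulates mean metrics with Dice/IoU deltas against the baseline.
#'
#' @param dataset list of preprocessed samples.
#' @param cfg shared \code{\link{train_config}}.
#' @param k folds per variant.
#' @param width_multiplier,input_size forwarded to every
#'   \code{\link{architecture_spec}}.
#' @return data frame with one row per variant (baseline first) and
#'   \code{delta_dice}/\code{delta_iou} columns.
#' @export
run_architectural_ablation <- function(dataset, cfg = train_config(), k = 2L,
                                       width_multiplier = 0.125,
                                       input_size = c(256L, 256L, 3L)) {
  variants <- c("inceptionv3_unet", "mcp_unet", "aspp_unet", "imau_net")
  rows <- lapply(variants, function(v) {
    spec <- architecture_spec(v, input_size = input_size,
                              width_multiplier = width_multiplier)
    cv <- run_cv(spec, dataset, cfg, k)
    data.frame(variant = variant_labels[[v]],
               dice = cv$mean["dice"], dice_std = cv$std["dice"],
               iou = cv$mean["iou"], iou_std = cv$std["iou"],
               precision = cv$mean["precision"], recall = cv$mean["recall"],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ablation_deltas(tab, c("dice", "iou"))
}

#' Add baseline deltas to an ablation table
#'
#' For each value column, appends \code{delta_<col>} = value - value of the
#' baseline (first) row; the baseline delta is 0 by construction.
#'
#' @param tab data frame of per-variant results, baseline in row 1.
#' @param cols value columns to difference.
#' @return the table with delta columns appended.
#' @export
ablation_deltas <- function(tab, cols = "dice") {
  for (cl in cols) tab[[paste0("delta_", cl)]] <- tab[[cl]] - tab[[cl]][1]
  tab
}

#' Controlled training comparison
#'
#' Re-trains all four variants under one shared configuration (same batch
#' size, epochs, learning rate, loss and seed) on a fixed train/validation/
#' test split, recording the shared settings as provenance columns and all
#' pairwise Dice differences.
#'
#' @inheritParams run_architectural_ablation
#' @param split_seed seed of the 70/15/15 split.
#' @return list with \code{table} (per-variant metrics + provenance) and
#'   \code{pairwise} (Dice differences between every variant pair).
#' @export
run_controlled_comparison <- function(dataset, cfg = train_config(),
                                      width_multiplier = 0.125,
                                      input_size = c(256L, 256L, 3L),
                                      split_seed = 1L) {
  variants <- c("inceptionv3_unet", "mcp_unet", "aspp_unet", "imau_net")
  sp <- split_dataset(dataset, seed = split_seed)
  rows <- lapply(variants, function(v) {
    spec <- architecture_spec(v, input_size = input_size,
                              width_multiplier = width_multiplier)
    model <- build_model(spec, seed = cfg$seed)
    model <- train_segmenter(model, sp$train, sp$val, cfg)
    ev <- evaluate_model(model, sp$test)
    data.frame(variant = variant_labels[[v]], dice = mean(ev$dice),
               iou = mean(ev$iou),
               precision = mean(ev$precision, na.rm = TRUE),
               recall = mean(ev$recall, na.rm = TRUE),
               batch_size = cfg$batch_size, epochs = cfg$epochs,
               learning_rate = cfg$learning_rate, loss = cfg$loss,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, pairwise = pairwise_differences(tab, "dice", "variant"))
}

#' All pairwise differences of one column
#'
#' @param tab data frame.
#' @param col value column.
#' @param label label column.
#' @return data frame (a, b, difference = value_a - value_b) over all pairs.
#' @export
pairwise_differences <- function(tab, col = "dice", label = "variant") {
  n <- nrow(tab)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out[[length(out) + 1]] <- data.frame(
      a = tab[[label]][i], b = tab[[label]][j],
      difference = tab[[col]][i] - tab[[col]][j],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Preprocessing ablation experiment
#'
#' Trains one model under each of the four preprocessing configurations
#' (none / CLAHE only / CLAHE + denoising / full) applied to one raw
#' dataset, and tabulates Dice/IoU with deltas against the unpreprocessed
#' configuration.
#'
#' @param dataset list of RAW (unpreprocessed) image samples.
#' @param spec architecture to train.
#' @param cfg a \code{\link{train_config}}.
#' @param target_size standardization size for every configuration.
#' @param split_seed seed of the 70/15/15 split.
#' @return data frame with rows "No Preprocessing", "CLAHE Only",
#'   "CLAHE + Denoising", "Full Preprocessing" and their stage toggles.
#' @export
run_preprocessing_ablation <- function(dataset, spec, cfg = train_config(),
                                       target_size = c(256L, 256L),
                                       split_seed = 1L) {
  presets <- preprocess_presets(target_size = target_size)
  labels <- c(none = "No Preprocessing", clahe = "CLAHE Only",
              clahe_denoise = "CLAHE + Denoising",
              full = "Full Preprocessing")
  rows <- list()
  for (nm in names(presets)) {
    pc <- presets[[nm]]
    pp <- preprocess_dataset(dataset, pc)
    sp <- split_dataset(pp, seed = split_seed)
    model <- build_model(spec, seed = cfg$seed)
    model <- train_segmenter(model, sp$train, sp$val, cfg)
    ev <- evaluate_model(model, sp$test)
    rows[[nm]] <- data.frame(configuration = labels[[nm]],
                             dice = mean(ev$dice), iou = mean(ev$iou),
                             clahe = pc$enable_clahe,
                             denoise = pc$enable_denoise,
                             mask_refine = pc$enable_mask_refine,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ablation_deltas(tab, c("dice", "iou"))
}
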