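#' Architecture specification for the segmentation model family
#'
#' Declarative description of one of the four encoder--decoder variants:
#' \describe{
#'   \item{\code{inceptionv3_unet}}{InceptionV3-style backbone taps + U-Net
#'     decoder (the baseline).}
#'   \item{\code{mcp_unet}}{plain convolutional encoder + Multi-Core Pooling
#'     (MCP) bottleneck.}
#'   \item{\code{aspp_unet}}{plain encoder + improved Atrous Spatial Pyramid
#'     Pooling (ASPP) bottleneck.}
#'   \item{\code{imau_net}}{backbone taps + fused MCP||ASPP bottleneck
#'     (IMAU-Net).}
#' }
#'
#' The MCP block applies parallel stride-1 same-padding max-pools (kernels
#' 2/3/5), each followed by a learnable 1x1 convolution with
#' \code{branch_filters} outputs, then concatenates (3 x 256 = 768 channels at
#' defaults). The improved ASPP block applies four 3x3 dilated convolutions
#' (rates 2/4/6/8) plus a global-average-pooling branch, concatenates all five
#' (1280 channels at defaults) and reduces to \code{aspp_reduced_filters} with
#' a 1x1 convolution. Batch normalization follows every convolution in both
#' blocks.
#'
#' @param variant one of \code{"imau_net"}, \code{"inceptionv3_unet"},
#'   \code{"mcp_unet"}, \code{"aspp_unet"}.
#' @param input_size integer (height, width, channels); height/width must be
#'   divisible by 32.
#' @param mcp_kernels max-pool kernel sizes of the MCP branches.
#' @param aspp_dilations strictly increasing dilation rates of the ASPP
#'   branches.
#' @param branch_filters filters of every MCP/ASPP branch convolution.
#' @param aspp_reduced_filters output channels of the ASPP 1x1 reduction.
#' @param decoder_filters six integers: (transposed-conv filters, conv filters)
#'   for the three decoder stages of the backbone variants.
#' @param encoder_filters stage widths of the plain convolutional encoder used
#'   by \code{mcp_unet}/\code{aspp_unet}.
#' @param width_multiplier scales every filter count (rounded, minimum 1);
#'   1.0 reproduces the full-width architecture, small values give a
#'   CPU-trainable model of identical topology.
#' @param pretrained_backbone if \code{TRUE}, request ImageNet-pretrained
#'   backbone weights (requires a weights file; random initialization is the
#'   offline default).
#' @return an object of class \code{architecture_spec}.
#' @export
architecture_spec <- function(variant = c("imau_net", "inceptionv3_unet",
                                          "mcp_unet", "aspp_unet"),
                              input_size = c(256L, 256L, 3L),
                              mcp_kernels = c(2L, 3L, 5L),
                              aspp_dilations = c(2L, 4L, 6L, 8L),
                              branch_filters = 256L,
                              aspp_reduced_filters = 512L,
                              decoder_filters = c(768L, 384L, 288L, 144L,
                                                  256L, 64L),
                              encoder_filters = c(64L, 128L, 256L, 512L),
                              width_multiplier = 1,
                              pretrained_backbone = FALSE) {
  variant <- match.arg(variant)
  if (any(mcp_kernels < 1)) stop("mcp_kernels must be positive")
  if (any(diff(aspp_dilations) <= 0))
    stop("aspp_dilations must be strictly increasing")
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("width_multiplier must be in (0, 1]")
  if (length(input_size) != 3 || any(input_size[1:2] %% 32 != 0))
    stop("input_size height/width must be divisible by 32")
  if (length(decoder_filters) != 6) stop("decoder_filters must have length 6")
  structure(list(variant = variant,
                 input_size = as.integer(input_size),
                 mcp_kernels = as.integer(mcp_kernels),
                 aspp_dilations = as.integer(aspp_dilations),
                 branch_filters = as.integer(branch_filters),
                 aspp_reduced_filters = as.integer(aspp_reduced_filters),
                 decoder_filters = as.integer(decoder_filters),
                 encoder_filters = as.integer(encoder_filters),
                 width_multiplier = width_multiplier,
                 pretrained_backbone = isTRUE(pretrained_backbone)),
            class = "architecture_spec")
}

spec_f <- function(spec, filters) bb_f(filters, spec$width_multiplier)

# Append the MCP bottleneck to graph `g` on node `input`; returns the graph
# and the names of the branch/concat endpoints.
add_mcp_block <- function(g, input, spec, prefix = "mcp") {
  sh <- ng_shape(g, input)
  if (any(spec$mcp_kernels > min(sh[1:2])))
    stop("configuration error: MCP pool kernel (",
         max(spec$mcp_kernels), ") larger than input spatial size (",
         min(sh[1:2]), ")")
  bf <- spec_f(spec, spec$branch_filters)
  branches <- character()
  for (k in spec$mcp_kernels) {
    pn <- paste0(prefix, "_pool", k)
    g <- ng_add(g, pn, "maxpool", input, k = as.integer(k), stride = 1L,
                padding = "same")
    g <- ng_conv_bn_relu(g, paste0(prefix, "_c", k), pn, bf, 1L)
    branches <- c(branches, paste0(prefix, "_c", k))
  }
  g <- ng_add(g, paste0(prefix, "_out"), "concat", branches)
  list(graph = g, out = paste0(prefix, "_out"), pools = branches)
}

# Append the improved ASPP bottleneck: four dilated 3x3 branches, a pooled
# global-context branch, five-way concat, then 1x1 reduction.
add_aspp_block <- function(g, input, spec, prefix = "aspp") {
  sh <- ng_shape(g, input)
  bf <- spec_f(spec, spec$branch_filters)
  branches <- character()
  for (r in spec$aspp_dilations) {
    nm <- paste0(prefix, "_d", r)
    g <- ng_conv_bn_relu(g, nm, input, bf, 3L, dilation = as.integer(r))
    branches <- c(branches, nm)
  }
  g <- ng_add(g, paste0(prefix, "_gap"), "gap", input)
  g <- ng_conv_bn_relu(g, paste0(prefix, "_gapc"), paste0(prefix, "_gap"),
                       bf, 1L)
  g <- ng_add(g, paste0(prefix, "_gapup"), "resize", paste0(prefix, "_gapc"),
              size = sh[1:2])
  g <- ng_add(g, paste0(prefix, "_concat"), "concat",
              c(branches, paste0(prefix, "_gapup")))
  g <- ng_conv_bn_relu(g, paste0(prefix, "_out"), paste0(prefix, "_concat"),
                       spec_f(spec, spec$aspp_reduced_filters), 1L)
  list(graph = g, out = paste0(prefix, "_out"),
       concat = paste0(prefix, "_concat"))
}

# U-Net decoder over backbone taps: three (transposed conv -> resized-skip
# concat -> two 3x3 convs) stages, then resize to the input resolution and a
# 1x1 sigmoid head.
add_tap_decoder <- function(g, bottleneck, skips, spec,
                            extra_upsample = FALSE) {
  df <- vapply(spec$decoder_filters, function(x) spec_f(spec, x), integer(1))
  x <- bottleneck
  for (i in 1:3) {
    a <- df[2 * i - 1]; b <- df[2 * i]
    dn <- paste0("dec", i)
    g <- ng_add(g, paste0(dn, "_up"), "convt", x, filters = a, k = 3L,
                stride = 2L)
    g <- ng_add(g, paste0(dn, "_upr"), "relu", paste0(dn, "_up"))
    cur <- ng_shape(g, paste0(dn, "_upr"))
    g <- ng_add(g, paste0(dn, "_skip"), "resize", skips[i], size = cur[1:2])
    g <- ng_add(g, paste0(dn, "_cat"), "concat",
                c(paste0(dn, "_upr"), paste0(dn, "_skip")))
    g <- ng_add(g, paste0(dn, "_c1"), "conv", paste0(dn, "_cat"), filters = b,
                k = 3L, bias = TRUE)
    g <- ng_add(g, paste0(dn, "_c1r"), "relu", paste0(dn, "_c1"))
    g <- ng_add(g, paste0(dn, "_c2"), "conv", paste0(dn, "_c1r"), filters = b,
                k = 3L, bias = TRUE)
    g <- ng_add(g, dn, "relu", paste0(dn, "_c2"))
    x <- dn
  }
  if (extra_upsample) {
    # baseline head: two additional stride-2 transposed convolutions before
    # the final resize
    g <- ng_add(g, "up4", "convt", x, filters = spec_f(spec, 64L), k = 3L,
                stride = 2L)
    g <- ng_add(g, "up4_r", "relu", "up4")
    g <- ng_add(g, "up5", "convt", "up4_r", filters = spec_f(spec, 32L),
                k = 3L, stride = 2L)
    g <- ng_add(g, "up5_r", "relu", "up5")
    x <- "up5_r"
  }
  g <- ng_add(g, "head_resize", "resize", x, size = spec$input_size[1:2])
  g <- ng_add(g, "head_conv", "conv", "head_resize", filters = 1L, k = 1L,
              bias = TRUE)
  g <- ng_add(g, "head", "sigmoid", "head_conv")
  g
}

# Plain U-Net encoder (two 3x3 convs + 2x2 max-pool per stage) used by the
# single-bottleneck variants.
add_plain_encoder <- function(g, input, spec) {
  x <- input
  skips <- character()
  for (i in seq_along(spec$encoder_filters)) {
    fl <- spec_f(spec, spec$encoder_filters[i])
    en <- paste0("enc", i)
    g <- ng_add(g, paste0(en, "_c1"), "conv", x, filters = fl, k = 3L,
                bias = TRUE)
    g <- ng_add(g, paste0(en, "_c1r"), "relu", paste0(en, "_c1"))
    g <- ng_add(g, paste0(en, "_c2"), "conv", paste0(en, "_c1r"),
                filters = fl, k = 3L, bias = TRUE)
    g <- ng_add(g, en, "relu", paste0(en, "_c2"))
    skips <- c(skips, en)
    g <- ng_add(g, paste0(en, "_pool"), "maxpool", en, k = 2L, stride = 2L,
                padding = "valid")
    x <- paste0(en, "_pool")
  }
  list(graph = g, out = x, skips = skips)
}

add_plain_decoder <- function(g, bottleneck, skips, spec) {
  x <- bottleneck
  for (i in rev(seq_along(skips))) {
    fl <- spec_f(spec, spec$encoder_filters[i])
    dn <- paste0("dec", i)
    g <- ng_add(g, paste0(dn, "_up"), "convt", x, filters = fl, k = 3L,
                stride = 2L)
    g <- ng_add(g, paste0(dn, "_upr"), "relu", paste0(dn, "_up"))
    cur <- ng_shape(g, paste0(dn, "_upr"))
    g <- ng_add(g, paste0(dn, "_skip"), "resize", skips[i], size = cur[1:2])
    g <- ng_add(g, paste0(dn, "_cat"), "concat",
                c(paste0(dn, "_upr"), paste0(dn, "_skip")))
    g <- ng_add(g, paste0(dn, "_c1"), "conv", paste0(dn, "_cat"),
                filters = fl, k = 3L, bias = TRUE)
    g <- ng_add(g, paste0(dn, "_c1r"), "relu", paste0(dn, "_c1"))
    g <- ng_add(g, paste0(dn, "_c2"), "conv", paste0(dn, "_c1r"),
                filters = fl, k = 3L, bias = TRUE)
    g <- ng_add(g, dn, "relu", paste0(dn, "_c2"))
    x <- dn
  }
  g <- ng_add(g, "head_conv", "conv", x, filters = 1L, k = 1L, bias = TRUE)
  g <- ng_add(g, "head", "sigmoid", "head_conv")
  g
}

#' Build a segmentation model
#'
#' Constructs the computation graph for the requested variant and initializes
#' its parameters (seeded, He-normal). The returned object is ready for
#' \code{\link{train_segmenter}} or \code{\link[=predict.segmentation_model]{predict}}.
#'
#' @param spec an \code{\link{architecture_spec}}.
#' @param seed integer seed for parameter initialization.
#' @return an object of class \code{segmentation_model} with elements
#'   \code{spec}, \code{graph}, \code{params}, \code{state} (batch-norm
#'   running statistics), \code{endpoints} (named internal nodes: taps,
#'   bottleneck, decoder stages, head) and \code{parameter_count}.
#' @examples
#' spec <- architecture_spec("mcp_unet", input_size = c(64, 64, 3),
#'                           width_multiplier = 0.0625)
#' m <- build_model(spec, seed = 1)
#' print(m)
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (spec$pretrained_backbone)
    stop("pretrained backbone weights are not bundled; run in offline mode ",
         "with pretrained_backbone = FALSE (seeded random initialization)")
  g <- nn_graph()
  g <- ng_add(g, "image", "input", shape = spec$input_size)
  endpoints <- list(head = "head")
  if (spec$variant %in% c("imau_net", "inceptionv3_unet")) {
    bb <- add_inception_v3(g, "image", spec$width_multiplier)
    g <- bb$graph
    taps <- bb$taps
    endpoints$taps <- taps
    if (spec$variant == "imau_net") {
      mcp <- add_mcp_block(g, taps["c4"], spec)
      g <- mcp$graph
      aspp <- add_aspp_block(g, taps["c4"], spec)
      g <- aspp$graph
      g <- ng_add(g, "bottleneck", "concat", c(mcp$out, aspp$out))
      endpoints$mcp <- mcp$out
      endpoints$aspp_concat <- aspp$concat
      endpoints$aspp <- aspp$out
    } else {
      g <- ng_add(g, "bottleneck", "concat", taps["c4"])
    }
    endpoints$bottleneck <- "bottleneck"
    g <- add_tap_decoder(g, "bottleneck",
                         rev(unname(taps[c("c1", "c2", "c3")])), spec,
                         extra_upsample = spec$variant == "inceptionv3_unet")
  } else {
    enc <- add_plain_encoder(g, "image", spec)
    g <- enc$graph
    if (spec$variant == "mcp_unet") {
      blk <- add_mcp_block(g, enc$out, spec)
      endpoints$mcp <- blk$out
    } else {
      blk <- add_aspp_block(g, enc$out, spec)
      endpoints$aspp_concat <- blk$concat
      endpoints$aspp <- blk$out
    }
    g <- blk$graph
    g <- ng_add(g, "bottleneck", "concat", blk$out)
    endpoints$bottleneck <- "bottleneck"
    g <- add_plain_decoder(g, "bottleneck", enc$skips, spec)
  }
  endpoints$decoder <- grep("^dec[0-9]+$", names(g$nodes), value = TRUE)
  params <- ng_init_params(g, seed)
  structure(list(spec = spec, graph = g, params = params,
                 state = ng_init_state(g), endpoints = endpoints,
                 parameter_count = ng_n_params(g, params),
                 init_seed = as.integer(seed), trained = FALSE,
                 history = NULL),
            class = "segmentation_model")
}

# Forward pass on a (H, W, 3, N) batch; returns the full activation set.
model_forward <- function(model, x, training = FALSE) {
  ng_forward(model$graph, model$params, x, training = training,
             state = model$state)
}

#' @export
print.segmentation_model <- function(x, ...) {
  sh <- x$spec$input_size
  cat("Segmentation model [", x$spec$variant, "]\n", sep = "")
  cat("  input: ", paste(sh, collapse = "x"),
      "   output: ", paste(c(sh[1:2], 1L), collapse = "x"), "\n", sep = "")
  cat("  width multiplier: ", x$spec$width_multiplier,
      "   parameters: ", format(x$parameter_count, big.mark = ","),
      "\n", sep = "")
  cat("  bottleneck channels: ",
      ng_shape(x$graph, x$endpoints$bottleneck)[3], "\n", sep = "")
  if (x$trained) cat("  trained: yes (", length(x$history$train_loss),
                     " epochs recorded)\n", sep = "")
  invisible(x)
}

#' Layer summary of a segmentation model
#'
#' @param object a \code{segmentation_model}.
#' @param ... unused.
#' @return data frame with one row per graph node: name, operation, output
#'   shape and trainable parameter count.
#' @export
summary.segmentation_model <- function(object, ...) {
  g <- object$graph
  rows <- lapply(g$nodes, function(nd) {
    np <- sum(vapply(nd$param_names,
                     function(p) length(object$params[[p]]), numeric(1)))
    data.frame(name = nd$name, op = nd$op,
               output_shape = paste(nd$out_shape, collapse = "x"),
               parameters = np, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.segmentation_model", "data.frame")
  out
}

#' Predict segmentation masks
#'
#' @param object a (typically trained) \code{segmentation_model}.
#' @param newdata one image sample (list with \code{image}), a list of
#'   samples, or a (H, W, 3, N) array.
#' @param type \code{"prob"} for probability maps, \code{"mask"} for binary
#'   masks thresholded at \code{threshold}.
#' @param threshold binarization cut for \code{type = "mask"}.
#' @param ... unused.
#' @return (H, W, N) array of probabilities or \{0,1\} masks (drops to a
#'   matrix for a single sample).
#' @export
predict.segmentation_model <- function(object, newdata, type = c("prob", "mask"),
                                       threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- as_image_batch(newdata, object$spec$input_size)
  fwd <- model_forward(object, x, training = FALSE)
  p <- fwd$outs[["head"]]
  d <- dim(p)
  out <- array(p, dim = c(d[1], d[2], d[4]))
  if (type == "mask") out <- (out > threshold) + 0
  if (dim(out)[3] == 1L) out <- out[, , 1]
  out
}

# Coerce samples into the (H, W, 3, N) batch layout.
as_image_batch <- function(newdata, input_size) {
  if (is.array(newdata) && length(dim(newdata)) == 4) return(newdata)
  if (is.list(newdata) && !is.null(newdata$image)) newdata <- list(newdata)
  if (is.list(newdata)) {
    n <- length(newdata)
    x <- array(0, dim = c(input_size[1], input_size[2], 3L, n))
    for (i in seq_len(n)) x[, , , i] <- newdata[[i]]$image
    return(x)
  }
  stop("newdata must be an image batch array, a sample, or a list of samples")
}

#' Construct backbone encoder taps
#'
#' Builds the InceptionV3-style backbone for a given input size and reports
#' the four tap endpoints (mixed0 / mixed3 / mixed6 / mixed10) with their
#' actual shapes. Tap spatial sizes are strictly non-increasing; the decoder
#' absorbs any mismatch through resize-based skip fusion.
#'
#' @param pretrained request pretrained weights (errors: offline builds use
#'   seeded random initialization).
#' @param input_size (height, width, channels) of the model input.
#' @param width_multiplier filter scaling, as in
#'   \code{\link{architecture_spec}}.
#' @param seed seed for parameter initialization.
#' @return list with the graph, tap node names and a data frame of tap shapes.
#' @export
build_encoder_taps <- function(pretrained = FALSE,
                               input_size = c(256L, 256L, 3L),
                               width_multiplier = 1, seed = 1L) {
  if (isTRUE(pretrained))
    stop("pretrained backbone weights are not bundled; run in offline mode ",
         "(pretrained = FALSE) for seeded random initialization")
  g <- nn_graph()
  g <- ng_add(g, "image", "input", shape = as.integer(input_size))
  bb <- add_inception_v3(g, "image", width_multiplier)
  shp <- t(vapply(bb$taps, function(nm) ng_shape(bb$graph, nm), integer(3)))
  taps <- data.frame(tap = names(bb$taps), node = unname(bb$taps),
                     height = shp[, 1], width = shp[, 2],
                     channels = shp[, 3], stringsAsFactors = FALSE)
  params <- ng_init_params(bb$graph, seed)
  list(graph = bb$graph, taps = bb$taps, shapes = taps, params = params)
}

#' Build a standalone Multi-Core Pooling block
#'
#' Parallel stride-1 same-padding max-pools (one per kernel in
#' \code{spec$mcp_kernels}), each followed by a 1x1 convolution with
#' \code{branch_filters} outputs (batch norm + ReLU), concatenated along
#' channels. Output spatial size equals input spatial size; output channels =
#' \code{length(mcp_kernels) * branch_filters}.
#'
#' @param in_channels channels of the input feature map.
#' @param spec an \code{\link{architecture_spec}}.
#' @param input_size spatial size (height, width) of the block input.
#' @param seed seed for the 1x1 convolution weights.
#' @return list with \code{forward(x)} (x is a (H, W, C, N) array; returns
#'   the concatenated output) and \code{out_channels}.
#' @export
build_mcp_block <- function(in_channels, spec = architecture_spec(),
                            input_size = c(8L, 8L), seed = 1L) {
  stopifnot(in_channels >= 1)
  g <- nn_graph()
  g <- ng_add(g, "x", "input",
              shape = c(as.integer(input_size), as.integer(in_channels)))
  blk <- add_mcp_block(g, "x", spec)
  params <- ng_init_params(blk$graph, seed)
  state <- ng_init_state(blk$graph)
  list(forward = function(x, training = FALSE) {
         fwd <- ng_forward(blk$graph, params, x, training, state)
         fwd$outs[[blk$out]]
       },
       graph = blk$graph, out = blk$out,
       out_channels = ng_shape(blk$graph, blk$out)[3])
}

#' Build a standalone improved ASPP block
#'
#' Four parallel 3x3 dilated convolutions plus an upsampled global-average-
#' pool branch, concatenated (5 x \code{branch_filters} channels) and reduced
#' to \code{aspp_reduced_filters} by a 1x1 convolution; batch norm after every
#' convolution.
#'
#' @inheritParams build_mcp_block
#' @return list with \code{forward(x)} returning both the concatenation
#'   endpoint and the reduced output, plus their channel counts.
#' @export
build_aspp_block <- function(in_channels, spec = architecture_spec(),
                             input_size = c(8L, 8L), seed = 1L) {
  stopifnot(in_channels >= 1)
  g <- nn_graph()
  g <- ng_add(g, "x", "input",
              shape = c(as.integer(input_size), as.integer(in_channels)))
  blk <- add_aspp_block(g, "x", spec)
  params <- ng_init_params(blk$graph, seed)
  state <- ng_init_state(blk$graph)
  list(forward = function(x, training = FALSE) {
         fwd <- ng_forward(blk$graph, params, x, training, state)
         list(concat = fwd$outs[[blk$concat]], out = fwd$outs[[blk$out]])
       },
       graph = blk$graph, out = blk$out, concat = blk$concat,
       concat_channels = ng_shape(blk$graph, blk$concat)[3],
       out_channels = ng_shape(blk$graph, blk$out)[3])
}
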