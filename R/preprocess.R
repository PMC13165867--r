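#' Preprocessing configuration
#'
#' Parameters of the four-stage pipeline applied before training:
#' CLAHE contrast enhancement, non-local-means denoising, morphological mask
#' refinement, then standardization (resize to \code{target_size}, [0, 1]
#' normalization and mask binarization at \code{binarize_threshold}). Each
#' stage has an enable flag so ablation configurations (none / CLAHE only /
#' CLAHE + denoise / full) are expressible.
#'
#' @param enable_clahe,enable_denoise,enable_mask_refine stage toggles.
#' @param clahe_clip_limit CLAHE clip limit (> 0).
#' @param clahe_tile_grid (rows, cols) of the CLAHE tile grid.
#' @param nlm_strength non-local-means filtering strength on the [0, 1]
#'   intensity scale.
#' @param nlm_template_window odd patch size in pixels.
#' @param nlm_search_window odd search-window size in pixels.
#' @param morph_kernel_size odd size of the elliptical structuring element.
#' @param target_size output (height, width).
#' @param binarize_threshold mask cut in (0, 1); a pixel becomes foreground
#'   iff its interpolated value exceeds the threshold.
#' @param mask_interp \code{"nearest"} (default; avoids phantom intermediate
#'   labels) or \code{"bilinear"} followed by thresholding.
#' @return an object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(enable_clahe = TRUE,
                              clahe_clip_limit = 2,
                              clahe_tile_grid = c(8L, 8L),
                              enable_denoise = TRUE,
                              nlm_strength = 10 / 255,
                              nlm_template_window = 7L,
                              nlm_search_window = 21L,
                              enable_mask_refine = TRUE,
                              morph_kernel_size = 3L,
                              target_size = c(256L, 256L),
                              binarize_threshold = 0.5,
                              mask_interp = c("nearest", "bilinear")) {
  mask_interp <- match.arg(mask_interp)
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    stop("binarize_threshold must be strictly inside (0, 1)")
  if (clahe_clip_limit <= 0) stop("clahe_clip_limit must be > 0")
  for (v in c(nlm_template_window, nlm_search_window, morph_kernel_size))
    if (v < 3 || v %% 2 == 0)
      stop("window/kernel sizes must be odd and >= 3")
  structure(list(enable_clahe = isTRUE(enable_clahe),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 enable_denoise = isTRUE(enable_denoise),
                 nlm_strength = nlm_strength,
                 nlm_template_window = as.integer(nlm_template_window),
                 nlm_search_window = as.integer(nlm_search_window),
                 enable_mask_refine = isTRUE(enable_mask_refine),
                 morph_kernel_size = as.integer(morph_kernel_size),
                 target_size = as.integer(target_size),
                 binarize_threshold = binarize_threshold,
                 mask_interp = mask_interp),
            class = "preprocess_config")
}

#' The four standard preprocessing ablation configurations
#'
#' @param ... overrides passed to every \code{\link{preprocess_config}}.
#' @return named list of configs: \code{none}, \code{clahe},
#'   \code{clahe_denoise}, \code{full}.
#' @export
preprocess_presets <- function(...) {
  list(
    none = preprocess_config(enable_clahe = FALSE, enable_denoise = FALSE,
                             enable_mask_refine = FALSE, ...),
    clahe = preprocess_config(enable_clahe = TRUE, enable_denoise = FALSE,
                              enable_mask_refine = FALSE, ...),
    clahe_denoise = preprocess_config(enable_clahe = TRUE,
                                      enable_denoise = TRUE,
                                      enable_mask_refine = FALSE, ...),
    full = preprocess_config(...)
  )
}

check_rgb <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("expected a height x width x 3 image, got dim ",
         paste(d, collapse = "x"))
  invisible(d)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Applied to the L channel of CIE Lab only, so local contrast is boosted
#' without hue shifts; output clipped to [0, 1].
#'
#' @param image HxWx3 array in [0, 1].
#' @param cfg a \code{\link{preprocess_config}}.
#' @return enhanced image, same shape, values in [0, 1].
#' @export
apply_clahe <- function(image, cfg = preprocess_config()) {
  d <- check_rgb(image)
  if (!cfg$enable_clahe) return(image)
  px <- matrix(image, ncol = 3)
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1] / 100, d[1], d[2])
  L[L < 0] <- 0; L[L > 1] <- 1
  Leq <- EBImage::clahe(EBImage::Image(L),
                        nx = cfg$clahe_tile_grid[2],
                        ny = cfg$clahe_tile_grid[1],
                        limit = cfg$clahe_clip_limit)
  lab[, 1] <- pmin(pmax(as.numeric(EBImage::imageData(Leq)), 0), 1) * 100
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  out[out < 0] <- 0; out[out > 1] <- 1
  array(out, dim = d)
}

#' Non-local-means denoising
#'
#' Patch-based averaging with weights from patch similarity; preserves edges
#' while removing sensor noise. No-op when \code{cfg$enable_denoise} is off.
#'
#' @inheritParams apply_clahe
#' @return denoised image, same shape and range.
#' @export
denoise_nlm <- function(image, cfg = preprocess_config()) {
  d <- check_rgb(image)
  if (!cfg$enable_denoise) return(image)
  out <- nlm_denoise_rgb(image, (cfg$nlm_template_window - 1L) %/% 2L,
                         (cfg$nlm_search_window - 1L) %/% 2L,
                         cfg$nlm_strength)
  out[out < 0] <- 0; out[out > 1] <- 1
  array(out, dim = d)
}

#' Morphological mask refinement
#'
#' Opening then closing with an elliptical (disc) structuring element of
#' \code{morph_kernel_size}, removing isolated foreground specks and filling
#' pinholes while leaving large structures intact.
#'
#' @param mask binary HxW matrix.
#' @param cfg a \code{\link{preprocess_config}}.
#' @return refined binary mask, same shape.
#' @export
refine_mask <- function(mask, cfg = preprocess_config()) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  if (!cfg$enable_mask_refine) return(mask)
  kern <- EBImage::makeBrush(cfg$morph_kernel_size, shape = "disc")
  m <- EBImage::Image(mask)
  m <- EBImage::closing(EBImage::opening(m, kern), kern)
  out <- EBImage::imageData(m)
  dim(out) <- dim(mask)
  (out > 0.5) + 0
}

#' Standardize a sample to the model input contract
#'
#' Resizes the image bilinearly to \code{target_size} (intensities stay in
#' [0, 1]) and the mask by nearest neighbor (or bilinear, per config), then
#' binarizes the mask: foreground iff value > \code{binarize_threshold}.
#'
#' @param sample an image sample (list with \code{image}, \code{mask}).
#' @param cfg a \code{\link{preprocess_config}}.
#' @return standardized image sample.
#' @export
standardize_sample <- function(sample, cfg = preprocess_config()) {
  validate_sample(sample)
  d <- dim(sample$image)
  if (any(d[1:2] < 1)) stop("empty image")
  th <- cfg$target_size[1]; tw <- cfg$target_size[2]
  img <- sample$image
  if (!identical(as.integer(d[1:2]), cfg$target_size)) {
    img <- EBImage::imageData(EBImage::resize(EBImage::Image(sample$image,
                                                             colormode = "Color"),
                                              w = th, h = tw))
    dim(img) <- c(th, tw, 3L)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  msk <- sample$mask
  if (!identical(as.integer(dim(msk)), cfg$target_size)) {
    filt <- if (cfg$mask_interp == "nearest") "none" else "bilinear"
    msk <- EBImage::imageData(EBImage::resize(EBImage::Image(sample$mask),
                                              w = th, h = tw, filter = filt))
    dim(msk) <- c(th, tw)
  }
  msk <- (msk > cfg$binarize_threshold) + 0
  out <- sample
  out$image <- img
  out$mask <- msk
  validate_sample(out)
  out
}

#' Run the full preprocessing pipeline
#'
#' Stage order: CLAHE -> denoise -> mask refinement -> standardize. Each
#' stage is skipped when its enable flag is off; the pipeline is fully
#' deterministic.
#'
#' @inheritParams standardize_sample
#' @return preprocessed image sample satisfying the model input contract.
#' @export
preprocess_sample <- function(sample, cfg = preprocess_config()) {
  validate_sample(sample)
  out <- sample
  out$image <- apply_clahe(out$image, cfg)
  out$image <- denoise_nlm(out$image, cfg)
  out$mask <- refine_mask(out$mask, cfg)
  standardize_sample(out, cfg)
}

#' Preprocess a whole dataset
#'
#' @param dataset list of image samples.
#' @param cfg a \code{\link{preprocess_config}}.
#' @return list of preprocessed samples.
#' @export
preprocess_dataset <- function(dataset, cfg = preprocess_config()) {
  lapply(dataset, preprocess_sample, cfg = cfg)
}
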