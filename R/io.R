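#' Load an image/mask dataset from disk
#'
#' Expects \code{dir/images/*.png} and \code{dir/masks/*.png} with matching
#' base names. Images are decoded to HxWx3 arrays in [0, 1] (grayscale is
#' replicated, alpha dropped). Masks are binarized: foreground iff the pixel
#' equals \code{mask_rgb_value} exactly (on the 0-255 scale) in all
#' channels. An image without a mask, a mask without an image, or an empty
#' directory is an error naming the offending file.
#'
#' @param dir dataset root.
#' @param mask_rgb_value per-channel 0-255 value marking foreground in the
#'   mask files (length 1 or 3).
#' @return list of image samples (\code{image}, \code{mask},
#'   \code{sample_id}).
#' @export
load_dataset <- function(dir, mask_rgb_value = c(21L, 21L, 21L)) {
  img_dir <- file.path(dir, "images"); msk_dir <- file.path(dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("expected ", dir, " to contain images/ and masks/ subdirectories")
  imgs <- sort(list.files(img_dir, pattern = "\\.png$"))
  msks <- sort(list.files(msk_dir, pattern = "\\.png$"))
  if (length(imgs) == 0) stop("no PNG images found in ", img_dir)
  orphan_img <- setdiff(imgs, msks); orphan_msk <- setdiff(msks, imgs)
  if (length(orphan_img))
    stop("image without mask: ", paste(orphan_img, collapse = ", "))
  if (length(orphan_msk))
    stop("mask without image: ", paste(orphan_msk, collapse = ", "))
  if (length(mask_rgb_value) == 1) mask_rgb_value <- rep(mask_rgb_value, 3)
  lapply(imgs, function(fn) {
    img <- read_png_rgb(file.path(img_dir, fn))
    msk <- read_png_rgb(file.path(msk_dir, fn))
    m255 <- round(msk * 255)
    mask <- (m255[, , 1] == mask_rgb_value[1] &
             m255[, , 2] == mask_rgb_value[2] &
             m255[, , 3] == mask_rgb_value[3]) + 0
    s <- list(image = img, mask = mask,
              sample_id = sub("\\.png$", "", fn))
    validate_sample(s)
    s
  })
}

read_png_rgb <- function(path) {
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  if (dim(a)[3] == 2) a <- array(rep(a[, , 1], 3), dim = c(dim(a)[1:2], 3L))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Save a dataset to disk
#'
#' Writes \code{dir/images/<id>.png} (RGB), \code{dir/masks/<id>.png}
#' (8-bit grayscale, foreground 255 / background 0) and a
#' \code{manifest.csv} with sample id and foreground area fraction.
#'
#' @param dataset list of image samples.
#' @param dir output root (created if absent).
#' @return \code{dir}, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(s) {
    validate_sample(s)
    png::writePNG(s$image, file.path(dir, "images",
                                     paste0(s$sample_id, ".png")))
    png::writePNG(s$mask, file.path(dir, "masks",
                                    paste0(s$sample_id, ".png")))
    data.frame(sample_id = s$sample_id, area_fraction = mean(s$mask),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Deterministic train/validation/test split
#'
#' Shuffles with the seed and splits by the given fractions; sizes are
#' floored and every remainder sample goes to the training set, so 307
#' samples at 0.70/0.15/0.15 give 215/46/46.
#'
#' @param dataset list of image samples.
#' @param fractions length-3 vector (train, val, test) summing to 1.
#' @param seed shuffle seed.
#' @return list with \code{train}, \code{val}, \code{test}.
#' @export
split_dataset <- function(dataset, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 3 values summing to 1")
  n <- length(dataset)
  n_val <- floor(n * fractions[2]); n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1 && n >= 3)
    stop("split leaves an empty partition for n = ", n)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  list(train = dataset[ord[seq_len(n_train)]],
       val = dataset[ord[n_train + seq_len(n_val)]],
       test = dataset[ord[n_train + n_val + seq_len(n_test)]])
}
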