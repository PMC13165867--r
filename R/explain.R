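#' Occlusion-based importance map
#'
#' Slides an occluder over a grid of image cells: each cell in turn is
#' replaced by \code{baseline_value}, the model is re-run, and the cell's
#' importance is the drop in Dice (against the ground-truth mask) relative
#' to the unoccluded prediction. Regions the model relies on score high;
#' irrelevant background scores near zero. Fully deterministic given the
#' model and sample.
#'
#' @param model a trained \code{segmentation_model}.
#' @param sample an image sample matching the model input size.
#' @param grid (rows, cols) of the occlusion grid; each entry must not
#'   exceed the corresponding image dimension.
#' @param baseline_value intensity written into the occluded cell.
#' @param threshold binarization cut for the Dice computation.
#' @return object of class \code{occlusion_map}: matrix \code{importance}
#'   (grid-shaped Dice drops), \code{base_dice}, \code{grid}, and the cell
#'   pixel boundaries.
#' @export
occlusion_importance <- function(model, sample, grid = c(8L, 8L),
                                 baseline_value = 0, threshold = 0.5) {
  stopifnot(inherits(model, "segmentation_model"))
  validate_sample(sample)
  d <- dim(sample$image)
  grid <- as.integer(grid)
  if (any(grid < 1) || grid[1] > d[1] || grid[2] > d[2])
    stop("grid ", paste(grid, collapse = "x"),
         " invalid for a ", d[1], "x", d[2], " image")
  base_prob <- predict(model, sample, type = "prob")
  base_dice <- dice_coefficient(
    confusion_counts((base_prob > threshold) + 0, sample$mask))
  # cell c spans pixels (breaks[c]+1):breaks[c+1] -- equal split, remainder
  # spread over the leading cells
  row_breaks <- round(seq(0, d[1], length.out = grid[1] + 1))
  col_breaks <- round(seq(0, d[2], length.out = grid[2] + 1))
  imp <- matrix(0, grid[1], grid[2])
  for (gi in seq_len(grid[1])) for (gj in seq_len(grid[2])) {
    occluded <- sample$image
    occluded[(row_breaks[gi] + 1):row_breaks[gi + 1],
             (col_breaks[gj] + 1):col_breaks[gj + 1], ] <- baseline_value
    s2 <- sample; s2$image <- occluded
    p <- predict(model, s2, type = "prob")
    dc <- dice_coefficient(
      confusion_counts((p > threshold) + 0, sample$mask))
    imp[gi, gj] <- base_dice - dc
  }
  structure(list(importance = imp, base_dice = base_dice, grid = grid,
                 row_breaks = row_breaks, col_breaks = col_breaks),
            class = "occlusion_map")
}

#' @export
print.occlusion_map <- function(x, ...) {
  cat("Occlusion importance map (", x$grid[1], "x", x$grid[2],
      " grid), unoccluded Dice ", format_fixed(x$base_dice), "\n", sep = "")
  cat("  importance (Dice drop) range: [",
      format_fixed(min(x$importance)), ", ",
      format_fixed(max(x$importance)), "]\n", sep = "")
  invisible(x)
}

#' Fraction of ground-truth foreground covered by each occlusion cell
#'
#' Companion to \code{\link{occlusion_importance}}: grid-shaped matrix of
#' per-cell mean mask values, letting cells be classified as
#' organ-overlapping (> 0) or pure background (= 0).
#'
#' @param mask binary HxW mask.
#' @param omap an \code{occlusion_map} (supplies the cell boundaries).
#' @return matrix shaped like \code{omap$importance}.
#' @export
cell_foreground_fraction <- function(mask, omap) {
  stopifnot(inherits(omap, "occlusion_map"))
  out <- matrix(0, omap$grid[1], omap$grid[2])
  for (gi in seq_len(omap$grid[1])) for (gj in seq_len(omap$grid[2])) {
    out[gi, gj] <- mean(mask[(omap$row_breaks[gi] + 1):omap$row_breaks[gi + 1],
                             (omap$col_breaks[gj] + 1):omap$col_breaks[gj + 1]])
  }
  out
}
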