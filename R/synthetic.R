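#' Configuration for the synthetic laparoscopic scene generator
#'
#' The generator emulates the structure of intraoperative laparoscopic frames:
#' one irregular bright organ region on darker tissue background, straight
#' instrument-like occluders, a non-uniform illumination ramp, occasional
#' specular highlights and additive sensor noise, with a pixel-wise binary
#' mask of the VISIBLE organ.
#'
#' @param image_size integer (height, width) in pixels.
#' @param organ_area_range (min, max) organ area as a fraction of the image,
#'   both strictly inside (0, 1); enforced before occlusion.
#' @param boundary_irregularity non-negative amplitude of the radial boundary
#'   perturbation, as a fraction of the local ellipse radius (0 = exact
#'   ellipse).
#' @param n_occluders number of instrument-like bars drawn over the scene.
#' @param occluder_width_range (min, max) bar width in pixels.
#' @param illumination_gradient strength in [0, 1] of the multiplicative
#'   illumination ramp across the frame.
#' @param specular_prob probability in [0, 1] that a frame receives specular
#'   highlight blobs.
#' @param noise_sigma standard deviation of the additive Gaussian sensor
#'   noise (intensity units).
#' @param seed integer; one global stream per dataset, substreamed by sample
#'   index, so generation is order-independent.
#' @return an object of class \code{scene_config}.
#' @export
scene_config <- function(image_size = c(256L, 256L),
                         organ_area_range = c(0.1, 0.5),
                         boundary_irregularity = 0.15,
                         n_occluders = 2L,
                         occluder_width_range = c(8, 24),
                         illumination_gradient = 0.4,
                         specular_prob = 0.5,
                         noise_sigma = 0.02,
                         seed = 42L) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid scene_config field '", field, "': ", why,
                  call. = FALSE)
  }
  chk(length(image_size) == 2 && all(image_size >= 16), "image_size",
      "need (height, width) >= 16")
  chk(length(organ_area_range) == 2 &&
        organ_area_range[1] < organ_area_range[2], "organ_area_range",
      "need min < max")
  chk(all(organ_area_range > 0) && all(organ_area_range < 1),
      "organ_area_range", "fractions must be strictly inside (0, 1)")
  chk(boundary_irregularity >= 0, "boundary_irregularity",
      "must be non-negative")
  chk(n_occluders >= 0, "n_occluders", "must be non-negative")
  chk(length(occluder_width_range) == 2 &&
        occluder_width_range[1] < occluder_width_range[2] &&
        occluder_width_range[1] > 0, "occluder_width_range",
      "need 0 < min < max")
  chk(illumination_gradient >= 0 && illumination_gradient <= 1,
      "illumination_gradient", "must be in [0, 1]")
  chk(specular_prob >= 0 && specular_prob <= 1, "specular_prob",
      "must be in [0, 1]")
  chk(noise_sigma >= 0, "noise_sigma", "must be non-negative")
  structure(list(image_size = as.integer(image_size),
                 organ_area_range = as.numeric(organ_area_range),
                 boundary_irregularity = boundary_irregularity,
                 n_occluders = as.integer(n_occluders),
                 occluder_width_range = as.numeric(occluder_width_range),
                 illumination_gradient = illumination_gradient,
                 specular_prob = specular_prob,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Deterministic per-sample substream of the dataset-level seed.
scene_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(index) * 7919) %%
               2147483587)
}

# Smooth periodic radial perturbation, normalized to max |.| = 1.
radial_profile <- function(phi) {
  p <- numeric(length(phi))
  for (k in 2:6) {
    p <- p + stats::rnorm(1, sd = 1 / k) * cos(k * phi) +
      stats::rnorm(1, sd = 1 / k) * sin(k * phi)
  }
  m <- max(abs(p))
  if (m < 1e-12) p else p / m
}

# Rasterize the organ: ellipse with perturbed radial boundary, rescaled until
# its area fraction lands inside the configured range.
draw_organ <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  target <- stats::runif(1, cfg$organ_area_range[1], cfg$organ_area_range[2])
  q <- stats::runif(1, 0.55, 0.95)          # axis ratio
  theta <- stats::runif(1, 0, 2 * pi)
  cy <- H * stats::runif(1, 0.4, 0.6)
  cx <- W * stats::runif(1, 0.4, 0.6)
  A <- sqrt(target * H * W / (pi * q))
  coefs_phi <- stats::runif(1, 0, 2 * pi)   # phase shared by the profile
  # freeze one radial profile for this organ
  harm <- matrix(stats::rnorm(10), 5, 2) / (2:6)
  profile <- function(phi) {
    p <- numeric(length(phi))
    for (i in 1:5)
      p <- p + harm[i, 1] * cos((i + 1) * phi + coefs_phi) +
        harm[i, 2] * sin((i + 1) * phi)
    m <- max(abs(p), 1e-12)
    p / m
  }
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  rasterize <- function(A) {
    B <- q * A
    u <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
    v <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
    re <- sqrt((u / A)^2 + (v / B)^2)
    phi <- atan2(v / B, u / A)
    rho <- 1 + cfg$boundary_irregularity * profile(phi)
    (re <= rho) + 0
  }
  mask <- rasterize(A)
  for (it in 1:8) {
    frac <- mean(mask)
    if (frac >= cfg$organ_area_range[1] && frac <= cfg$organ_area_range[2])
      break
    A <- A * sqrt(target / max(frac, 1e-6))
    mask <- rasterize(A)
  }
  frac <- mean(mask)
  if (frac < cfg$organ_area_range[1] || frac > cfg$organ_area_range[2])
    stop("organ rasterization failed to meet organ_area_range")
  mask
}

# Straight instrument-like bar through a random interior point.
draw_occluder <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  width <- stats::runif(1, cfg$occluder_width_range[1],
                        cfg$occluder_width_range[2])
  ang <- stats::runif(1, 0, pi)
  py <- stats::runif(1, 0.2 * H, 0.8 * H)
  px <- stats::runif(1, 0.2 * W, 0.8 * W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  # signed distance to the bar's center line
  d <- abs(-(xx - px) * sin(ang) + (yy - py) * cos(ang))
  list(mask = d <= width / 2, edge = abs(d - width / 2) <= 1.2)
}

smooth_field <- function(H, W, n_waves = 3) {
  yy <- matrix(seq_len(H) / H, H, W)
  xx <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
  f <- matrix(0, H, W)
  for (i in seq_len(n_waves)) {
    fx <- stats::runif(1, 1, 4); fy <- stats::runif(1, 1, 4)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + stats::rnorm(1, sd = 1 / i) *
      cos(2 * pi * (fx * xx + ph[1])) * cos(2 * pi * (fy * yy + ph[2]))
  }
  f / max(abs(f), 1e-12)
}

#' Generate one synthetic laparoscopic scene
#'
#' Deterministic for a fixed (\code{cfg$seed}, \code{index}) pair. The
#' returned mask covers the VISIBLE organ only: occluder pixels are removed
#' (set \code{mask_includes_occluded = TRUE} to keep the full organ extent).
#' If occluders leave less than 0.5\% of the frame as foreground, the
#' occluders are redrawn (up to 10 times) before an error is raised.
#'
#' @param cfg a \code{\link{scene_config}}.
#' @param index sample index within the dataset (drives the substream).
#' @param mask_includes_occluded keep occluded organ pixels in the mask.
#' @return an image sample: list with \code{image} (HxWx3 array in [0, 1]),
#'   \code{mask} (HxW \{0,1\} matrix), \code{sample_id} and \code{meta}
#'   (pre-occlusion area fraction, occluder count).
#' @export
generate_scene <- function(cfg, index = 1L, mask_includes_occluded = FALSE) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(scene_seed(cfg$seed, index))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  organ <- draw_organ(cfg)
  area_pre <- mean(organ)

  organ_col <- c(0.62, 0.34, 0.26)
  bg_col <- c(0.32, 0.14, 0.12)
  tex_o <- smooth_field(H, W, 4) * 0.06
  tex_b <- smooth_field(H, W, 3) * 0.05
  img <- array(0, dim = c(H, W, 3))
  for (c in 1:3) {
    img[, , c] <- bg_col[c] + tex_b +
      organ * (organ_col[c] - bg_col[c] + tex_o)
  }

  # occluders: dark-gray bars with a bright specular edge, removed from mask
  occ_all <- matrix(FALSE, H, W)
  for (attempt in 0:10) {
    if (attempt == 10)
      stop("occluders cover the organ entirely after 10 redraws")
    occ_all <- matrix(FALSE, H, W)
    edges <- matrix(FALSE, H, W)
    if (cfg$n_occluders > 0) {
      for (i in seq_len(cfg$n_occluders)) {
        oc <- draw_occluder(cfg)
        occ_all <- occ_all | oc$mask
        edges <- edges | (oc$edge & oc$mask)
      }
    }
    visible <- organ * !occ_all
    if (mean(visible) >= 0.005 || area_pre < 1e-9) break
  }
  for (c in 1:3) {
    plane <- img[, , c]
    plane[occ_all] <- 0.25 + 0.02 * (c == 1)
    plane[edges] <- 0.62
    img[, , c] <- plane
  }

  # multiplicative illumination ramp in a random direction
  if (cfg$illumination_gradient > 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    yy <- matrix(seq_len(H) / H, H, W)
    xx <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
    ramp <- (cos(ang) * xx + sin(ang) * yy -
               min(cos(ang) * xx + sin(ang) * yy))
    ramp <- ramp / max(ramp, 1e-12)
    gain <- 1 - cfg$illumination_gradient / 2 +
      cfg$illumination_gradient * ramp
    for (c in 1:3) img[, , c] <- img[, , c] * gain
  }

  # specular highlight blobs
  if (stats::runif(1) < cfg$specular_prob) {
    n_spec <- sample(1:3, 1)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(n_spec)) {
      sy <- stats::runif(1, 1, H); sx <- stats::runif(1, 1, W)
      rad <- stats::runif(1, 2, 6)
      blob <- exp(-((yy - sy)^2 + (xx - sx)^2) / (2 * rad^2))
      for (c in 1:3) img[, , c] <- img[, , c] + 0.9 * blob
    }
  }

  if (cfg$noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img), sd = cfg$noise_sigma),
                       dim = dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1

  mask <- if (mask_includes_occluded) organ else organ * !occ_all
  sample <- list(image = img, mask = mask,
                 sample_id = sprintf("scene_%05d", as.integer(index)),
                 meta = list(area_fraction_pre_occlusion = area_pre,
                             n_occluders = cfg$n_occluders))
  validate_sample(sample)
  sample
}

#' Generate a synthetic dataset
#'
#' @param n number of samples (>= 1).
#' @param cfg a \code{\link{scene_config}}.
#' @param ... passed to \code{\link{generate_scene}}.
#' @return list of \code{n} image samples with unique ids; reproducible for a
#'   fixed \code{cfg$seed} and independent of generation order.
#' @export
generate_dataset <- function(n, cfg = scene_config(), ...) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  lapply(seq_len(as.integer(n)), function(i) generate_scene(cfg, i, ...))
}

# Contract check shared by the generator, preprocessing and the loaders.
validate_sample <- function(sample) {
  if (is.null(sample$image) || is.null(sample$mask))
    stop("image sample needs both image and mask")
  di <- dim(sample$image); dm <- dim(sample$mask)
  if (length(di) != 3 || di[3] != 3)
    stop("image must be height x width x 3, got ",
         paste(di, collapse = "x"))
  if (!identical(di[1:2], dm[1:2]))
    stop("image (", paste(di[1:2], collapse = "x"), ") and mask (",
         paste(dm, collapse = "x"), ") spatial shapes differ")
  if (min(sample$image) < 0 || max(sample$image) > 1)
    stop("image values must lie in [0, 1]")
  if (!all(sample$mask %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  invisible(TRUE)
}
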