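# Numerical-kernel properties: every primitive is checked against a naive
# oracle or a finite-difference / adjoint identity.

conv_oracle <- function(x, w, b, s, dil, pt, pl, Ho, Wo) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; Co <- wd[4]
  y <- array(0, c(Ho, Wo, Co, N))
  for (n in 1:N) for (co in 1:Co) for (wo in 1:Wo) for (ho in 1:Ho) {
    acc <- if (length(b)) b[co] else 0
    for (ci in 1:C) for (dw in 1:kw) for (dh in 1:kh) {
      ih <- (ho - 1) * s - pt + (dh - 1) * dil + 1
      iw <- (wo - 1) * s - pl + (dw - 1) * dil + 1
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
        acc <- acc + x[ih, iw, ci, n] * w[dh, dw, ci, co]
    }
    y[ho, wo, co, n] <- acc
  }
  y
}

test_that("convolution matches a naive oracle (same, strided, dilated)", {
  set.seed(42)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  y <- imauseg:::nn_conv_fwd(x, w, b, 1, 1, 1, 1, 1, 7, 6)
  expect_lt(max(abs(y - conv_oracle(x, w, b, 1, 1, 1, 1, 7, 6))), 1e-12)
  Ho <- (7 - 3) %/% 2 + 1; Wo <- (6 - 3) %/% 2 + 1
  y2 <- imauseg:::nn_conv_fwd(x, w, b, 2, 2, 1, 0, 0, Ho, Wo)
  expect_lt(max(abs(y2 - conv_oracle(x, w, b, 2, 1, 0, 0, Ho, Wo))), 1e-12)
  y3 <- imauseg:::nn_conv_fwd(x, w, b, 1, 1, 2, 2, 2, 7, 6)
  expect_lt(max(abs(y3 - conv_oracle(x, w, b, 1, 2, 2, 2, 7, 6))), 1e-12)
})

test_that("convolution gradients pass finite-difference checks", {
  set.seed(43)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  y <- imauseg:::nn_conv_fwd(x, w, b, 1, 1, 1, 1, 1, 5, 5)
  g <- imauseg:::nn_conv_bwd(x, w, y, 1, 1, 1, 1, 1, TRUE)
  eps <- 1e-6
  loss <- function(xx, ww)
    sum(imauseg:::nn_conv_fwd(xx, ww, b, 1, 1, 1, 1, 1, 5, 5)^2) / 2
  dx <- array(0, dim(x)); dx[2, 3, 1, 1] <- eps
  expect_lt(abs((loss(x + dx, w) - loss(x - dx, w)) / (2 * eps) -
                  g$gx[2, 3, 1, 1]), 1e-5)
  dw <- array(0, dim(w)); dw[1, 2, 2, 3] <- eps
  expect_lt(abs((loss(x, w + dw) - loss(x, w - dw)) / (2 * eps) -
                  g$gw[1, 2, 2, 3]), 1e-5)
})

test_that("transposed convolution satisfies the adjoint identity", {
  set.seed(44)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  w <- array(rnorm(3 * 3 * 5 * 3), c(3, 3, 5, 3))
  b0 <- rep(0, 5)
  y <- imauseg:::nn_convt_fwd(x, w, b0, 2, 0, 0, 8, 8)
  expect_equal(dim(y), c(8, 8, 5, 2))
  u <- array(rnorm(length(y)), dim(y))
  g <- imauseg:::nn_convt_bwd(x, w, u, 2, 0, 0)
  expect_lt(abs(sum(y * u) - sum(x * g$gx)), 1e-9)
  eps <- 1e-6
  dw <- array(0, dim(w)); dw[2, 1, 3, 2] <- eps
  f <- function(ww) sum(imauseg:::nn_convt_fwd(x, ww, b0, 2, 0, 0, 8, 8) * u)
  expect_lt(abs((f(w + dw) - f(w - dw)) / (2 * eps) - g$gw[2, 1, 3, 2]),
            1e-5)
})

test_that("max pooling with asymmetric same padding matches an oracle", {
  set.seed(45)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  mp <- imauseg:::nn_maxpool_fwd(x, 2, 2, 1, 1, 0, 0, 7, 6)
  ref <- array(0, c(7, 6, 3, 2))
  for (n in 1:2) for (c in 1:3) for (wo in 1:6) for (ho in 1:7) {
    vals <- c()
    for (dw in 0:1) for (dh in 0:1) {
      ih <- ho + dh; iw <- wo + dw
      if (ih <= 7 && iw <= 6) vals <- c(vals, x[ih, iw, c, n])
    }
    ref[ho, wo, c, n] <- max(vals)
  }
  expect_equal(mp$y, ref)
})

test_that("batch norm backward passes a finite-difference check", {
  set.seed(46)
  x <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  gmm <- rnorm(3); bet <- rnorm(3)
  r <- imauseg:::nn_bn_fwd(x, gmm, bet, rep(0, 3), rep(1, 3), TRUE, 1e-3)
  u <- array(rnorm(length(x)), dim(x))
  bw <- imauseg:::nn_bn_bwd(x, gmm, r$mean, r$var, u, 1e-3, TRUE)
  eps <- 1e-6
  f <- function(xx) {
    rr <- imauseg:::nn_bn_fwd(xx, gmm, bet, rep(0, 3), rep(1, 3), TRUE, 1e-3)
    sum(rr$y * u)
  }
  dx <- array(0, dim(x)); dx[3, 2, 2, 1] <- eps
  expect_lt(abs((f(x + dx) - f(x - dx)) / (2 * eps) - bw$gx[3, 2, 2, 1]),
            1e-4)
})

test_that("bilinear resize is adjoint-consistent and preserves constants", {
  set.seed(47)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  y <- imauseg:::nn_resize_bilinear_fwd(x, 13, 9)
  u <- array(rnorm(length(y)), dim(y))
  gx <- imauseg:::nn_resize_bilinear_bwd(u, dim(x))
  expect_lt(abs(sum(y * u) - sum(x * gx)), 1e-9)
  cst <- array(0.7, c(5, 5, 1, 1))
  expect_lt(max(abs(imauseg:::nn_resize_bilinear_fwd(cst, 11, 3) - 0.7)),
            1e-12)
})

test_that("non-local-means leaves a constant image unchanged", {
  ci <- array(0.5, c(16, 16, 3))
  expect_lt(max(abs(imauseg:::nlm_denoise_rgb(ci, 2, 4, 0.1) - 0.5)), 1e-12)
})
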