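# InceptionV3-style encoder backbone, built as graph nodes with the standard
# stem and mixed0..mixed10 modules (factorized 7x7 in the middle blocks,
# expanded filter banks at the end). Every convolution is conv -> batch norm
# -> ReLU without bias. `wm` scales every filter count (minimum 1) so the same
# topology runs desk-scale on a CPU.

bb_f <- function(filters, wm) max(1L, as.integer(round(filters * wm)))

add_inception_v3 <- function(g, input, wm = 1) {
  f <- function(x) bb_f(x, wm)
  cbr <- function(g, name, inp, filters, k, stride = 1L, padding = "same")
    ng_conv_bn_relu(g, name, inp, f(filters), k, stride, padding)

  # stem
  g <- cbr(g, "stem1", input, 32, 3L, 2L, "valid")
  g <- cbr(g, "stem2", "stem1", 32, 3L, 1L, "valid")
  g <- cbr(g, "stem3", "stem2", 64, 3L, 1L, "same")
  g <- ng_add(g, "stem_pool1", "maxpool", "stem3", k = 3L, stride = 2L,
              padding = "valid")
  g <- cbr(g, "stem4", "stem_pool1", 80, 1L, 1L, "valid")
  g <- cbr(g, "stem5", "stem4", 192, 3L, 1L, "valid")
  g <- ng_add(g, "stem_pool2", "maxpool", "stem5", k = 3L, stride = 2L,
              padding = "valid")
  x <- "stem_pool2"

  # mixed0..mixed2: 5x5 filter-bank modules
  pool_filters <- c(32L, 64L, 64L)
  for (i in 0:2) {
    p <- paste0("m", i, "_")
    g <- cbr(g, paste0(p, "b0"), x, 64, 1L)
    g <- cbr(g, paste0(p, "b1a"), x, 48, 1L)
    g <- cbr(g, paste0(p, "b1"), paste0(p, "b1a"), 64, 5L)
    g <- cbr(g, paste0(p, "b2a"), x, 64, 1L)
    g <- cbr(g, paste0(p, "b2b"), paste0(p, "b2a"), 96, 3L)
    g <- cbr(g, paste0(p, "b2"), paste0(p, "b2b"), 96, 3L)
    g <- ng_add(g, paste0(p, "pool"), "avgpool", x, k = 3L, stride = 1L,
                padding = "same")
    g <- cbr(g, paste0(p, "b3"), paste0(p, "pool"), pool_filters[i + 1], 1L)
    g <- ng_add(g, paste0("mixed", i), "concat",
                paste0(p, c("b0", "b1", "b2", "b3")))
    x <- paste0("mixed", i)
  }

  # mixed3: grid-size reduction
  g <- cbr(g, "m3_b0", x, 384, 3L, 2L, "valid")
  g <- cbr(g, "m3_b1a", x, 64, 1L)
  g <- cbr(g, "m3_b1b", "m3_b1a", 96, 3L)
  g <- cbr(g, "m3_b1", "m3_b1b", 96, 3L, 2L, "valid")
  g <- ng_add(g, "m3_pool", "maxpool", x, k = 3L, stride = 2L,
              padding = "valid")
  g <- ng_add(g, "mixed3", "concat", c("m3_b0", "m3_b1", "m3_pool"))
  x <- "mixed3"

  # mixed4..mixed7: factorized 7x7 modules
  c7s <- c(128L, 160L, 160L, 192L)
  for (i in 4:7) {
    c7 <- c7s[i - 3]
    p <- paste0("m", i, "_")
    g <- cbr(g, paste0(p, "b0"), x, 192, 1L)
    g <- cbr(g, paste0(p, "b1a"), x, c7, 1L)
    g <- cbr(g, paste0(p, "b1b"), paste0(p, "b1a"), c7, c(1L, 7L))
    g <- cbr(g, paste0(p, "b1"), paste0(p, "b1b"), 192, c(7L, 1L))
    g <- cbr(g, paste0(p, "b2a"), x, c7, 1L)
    g <- cbr(g, paste0(p, "b2b"), paste0(p, "b2a"), c7, c(7L, 1L))
    g <- cbr(g, paste0(p, "b2c"), paste0(p, "b2b"), c7, c(1L, 7L))
    g <- cbr(g, paste0(p, "b2d"), paste0(p, "b2c"), c7, c(7L, 1L))
    g <- cbr(g, paste0(p, "b2"), paste0(p, "b2d"), 192, c(1L, 7L))
    g <- ng_add(g, paste0(p, "pool"), "avgpool", x, k = 3L, stride = 1L,
                padding = "same")
    g <- cbr(g, paste0(p, "b3"), paste0(p, "pool"), 192, 1L)
    g <- ng_add(g, paste0("mixed", i), "concat",
                paste0(p, c("b0", "b1", "b2", "b3")))
    x <- paste0("mixed", i)
  }

  # mixed8: grid-size reduction
  g <- cbr(g, "m8_b0a", x, 192, 1L)
  g <- cbr(g, "m8_b0", "m8_b0a", 320, 3L, 2L, "valid")
  g <- cbr(g, "m8_b1a", x, 192, 1L)
  g <- cbr(g, "m8_b1b", "m8_b1a", 192, c(1L, 7L))
  g <- cbr(g, "m8_b1c", "m8_b1b", 192, c(7L, 1L))
  g <- cbr(g, "m8_b1", "m8_b1c", 192, 3L, 2L, "valid")
  g <- ng_add(g, "m8_pool", "maxpool", x, k = 3L, stride = 2L,
              padding = "valid")
  g <- ng_add(g, "mixed8", "concat", c("m8_b0", "m8_b1", "m8_pool"))
  x <- "mixed8"

  # mixed9, mixed10: expanded filter-bank modules
  for (i in 9:10) {
    p <- paste0("m", i, "_")
    g <- cbr(g, paste0(p, "b0"), x, 320, 1L)
    g <- cbr(g, paste0(p, "b1a"), x, 384, 1L)
    g <- cbr(g, paste0(p, "b1x"), paste0(p, "b1a"), 384, c(1L, 3L))
    g <- cbr(g, paste0(p, "b1y"), paste0(p, "b1a"), 384, c(3L, 1L))
    g <- ng_add(g, paste0(p, "b1"), "concat", paste0(p, c("b1x", "b1y")))
    g <- cbr(g, paste0(p, "b2a"), x, 448, 1L)
    g <- cbr(g, paste0(p, "b2b"), paste0(p, "b2a"), 384, 3L)
    g <- cbr(g, paste0(p, "b2x"), paste0(p, "b2b"), 384, c(1L, 3L))
    g <- cbr(g, paste0(p, "b2y"), paste0(p, "b2b"), 384, c(3L, 1L))
    g <- ng_add(g, paste0(p, "b2"), "concat", paste0(p, c("b2x", "b2y")))
    g <- ng_add(g, paste0(p, "pool"), "avgpool", x, k = 3L, stride = 1L,
                padding = "same")
    g <- cbr(g, paste0(p, "b3"), paste0(p, "pool"), 192, 1L)
    g <- ng_add(g, paste0("mixed", i), "concat",
                paste0(p, c("b0", "b1", "b2", "b3")))
    x <- paste0("mixed", i)
  }

  list(graph = g,
       taps = c(c1 = "mixed0", c2 = "mixed3", c3 = "mixed6", c4 = "mixed10"))
}
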