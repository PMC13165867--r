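# Brute-force reference implementations used by the metric tests.

counts_oracle <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; t <- truth[i, j]
    if (p == 1 && t == 1) tp <- tp + 1
    else if (p == 1 && t == 0) fp <- fp + 1
    else if (p == 0 && t == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Pooled directed boundary distances, 95th percentile, by exhaustive
# pairwise search (boundary = foreground pixel with a background 4-neighbor,
# image border counting as background).
hd95_oracle <- function(pred, truth) {
  bnd <- function(m) {
    H <- nrow(m); W <- ncol(m)
    out <- NULL
    for (i in 1:H) for (j in 1:W) {
      if (m[i, j] != 1) next
      nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < H) m[i + 1, j] else 0,
              if (j > 1) m[i, j - 1] else 0, if (j < W) m[i, j + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(i, j))
    }
    out
  }
  bp <- bnd(pred); bt <- bnd(truth)
  mind <- function(a, b) apply(a, 1, function(p)
    min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)))
  unname(stats::quantile(c(mind(bp, bt), mind(bt, bp)), 0.95, type = 7))
}
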