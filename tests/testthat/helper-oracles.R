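# Independent scalar oracles used across tests. These deliberately avoid the
# package's vectorized implementations.

# per-pixel evaluation of the windowing transform
oracle_window_scalar <- function(x, center = 50, width = 400, y_min = 0, y_max = 65535) {
  lo <- center - 0.5 - (width - 1) / 2
  hi <- center - 0.5 + (width - 1) / 2
  if (x <= lo) return(y_min)
  if (x >= hi) return(y_max)
  y <- ((x - (center - 0.5)) / (width - 1) + 0.5) * (y_max - y_min) + y_min
  sign(y) * floor(abs(y) + 0.5)
}

# brute-force pixel confusion counts via an explicit double loop
oracle_confusion_loop <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- isTRUE(pred[i, j]); g <- isTRUE(gt[i, j])
      if (p && g) tp <- tp + 1L
      else if (p && !g) fp <- fp + 1L
      else if (!p && g) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

random_mask <- function(h = 16, w = 16, p = 0.3) matrix(stats::runif(h * w) < p, h, w)

# a small converted phantom dataset shared by tests that need files on disk
phantom_store <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$man)) {
      dir <- file.path(tempdir(), "ctseg-test-store")
      unlink(dir, recursive = TRUE)
      cache$man <- generate_dataset(
        3, phantom_config(n_slices = 6, size = 64, distractor_count = 2),
        seed = 404, out_dir = dir)
    }
    cache$man
  }
})
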