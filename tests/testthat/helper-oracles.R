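# Shared fixtures and independent brute-force oracles.

rand_gray <- function(h, w, seed = 1) {
  withr::with_seed(seed,
    matrix(as.numeric(sample(0:255, h * w, replace = TRUE)), h, w))
}

# per-pixel loop oracle for the weighted-average grayscale conversion
gray_oracle <- function(arr) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  out <- matrix(0, h, w)
  for (i in seq_len(h))
    for (j in seq_len(w)) {
      y <- 0.299 * arr[i, j, 1] + 0.587 * arr[i, j, 2] + 0.114 * arr[i, j, 3]
      out[i, j] <- min(max(floor(y + 0.5), 0), 255)
    }
  out
}

# sort-based median filter oracle with edge replication
median_oracle <- function(img, window = 3) {
  h <- nrow(img); w <- ncol(img); k <- window %/% 2
  out <- matrix(0, h, w)
  for (i in seq_len(h))
    for (j in seq_len(w)) {
      ii <- pmin(pmax(i + (-k:k), 1), h)
      jj <- pmin(pmax(j + (-k:k), 1), w)
      v <- sort(as.vector(img[ii, jj]))
      out[i, j] <- v[(window * window + 1) / 2]
    }
  out
}

# exhaustive zero-mean NCC over all placements (no rotation/scale),
# zero-variance windows score 0, clipped at 0
ncc_oracle <- function(img, tpl) {
  th <- nrow(tpl); tw <- ncol(tpl)
  tc <- tpl - mean(tpl)
  sst <- sum(tc^2)
  best <- 0
  if (sst <= 1e-9) return(0)
  for (i in seq_len(nrow(img) - th + 1))
    for (j in seq_len(ncol(img) - tw + 1)) {
      win <- img[i:(i + th - 1), j:(j + tw - 1)]
      ssw <- sum((win - mean(win))^2)
      if (ssw <= 1e-9) next
      best <- max(best, sum(tc * win) / sqrt(sst * ssw))
    }
  best
}

# per-pixel enumeration oracle for the mean gray inside a circle
shell_gray_oracle <- function(img, cx, cy, r) {
  acc <- 0; n <- 0
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img)))
      if ((i - cy)^2 + (j - cx)^2 < r^2) { acc <- acc + img[i, j]; n <- n + 1 }
  acc / n
}

# one protocol-sized labelled feature table, reused across training tests
crab_table <- function(seed = 1, n = 80) {
  make_dataset(n, seed = seed, with_images = FALSE)$features
}
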