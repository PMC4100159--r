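# Shared helpers: seeded toy data and independent brute-force oracles.
# Oracles deliberately use plain loops, not the package's matrix code.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Random cysteine-centered windows (no padding).
randWindows <- function(n, L = 11L, seed = 1L) {
  set.seed(seed)
  center <- (L + 1L) / 2L
  vapply(seq_len(n), function(i) {
    res <- sample(AA, L, replace = TRUE)
    res[center] <- "C"
    paste(res, collapse = "")
  }, character(1))
}

# Brute-force per-window, per-position tally.
bruteTally <- function(windows) {
  L <- nchar(windows[1])
  m <- matrix(0L, nrow = 20L, ncol = L, dimnames = list(AA, NULL))
  for (w in windows) {
    for (j in seq_len(L)) {
      ch <- substr(w, j, j)
      if (ch != "X") m[ch, j] <- m[ch, j] + 1L
    }
  }
  m
}

# Brute-force confusion tally + metric formulas from per-sample labels.
bruteMetrics <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (truth[i] == -1 && pred[i] == 1) fp <- fp + 1L
    if (truth[i] == -1 && pred[i] == -1) tn <- tn + 1L
    if (truth[i] == 1 && pred[i] == -1) fn <- fn + 1L
  }
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sn = 100 * tp / (tp + fn), sp = 100 * tn / (tn + fp),
       acc = 100 * (tp + tn) / (tp + fp + tn + fn),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# A linearly separable toy feature set: positives near the 1-vector,
# negatives near the 0-vector.
separableToy <- function(nPos = 15L, nNeg = 15L, d = 10L, seed = 3L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(nPos * d, 1, 0.05), nPos),
             matrix(rnorm(nNeg * d, 0, 0.05), nNeg))
  list(x = x, y = rep(c(1L, -1L), c(nPos, nNeg)))
}
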