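# Shared fixtures and independent oracles.

# Paint a filled disk of the given value into a matrix (row/col center).
draw_disk <- function(m, center, radius, value) {
  for (r in seq_len(nrow(m)))
    for (c in seq_len(ncol(m)))
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) m[r, c] <- value
  m
}

# Linear pixel indices of a disk, for set-arithmetic IoU oracles.
disk_pixels <- function(dim, center, radius) {
  idx <- which(outer((seq_len(dim[1]) - center[1])^2,
                     (seq_len(dim[2]) - center[2])^2, "+") <= radius^2)
  idx
}

# Brute-force oracle for the trimmed-fraction statistic: full sort, slice,
# arithmetic means. Independent of the package implementation.
oracle_rnonr <- function(signals, f) {
  n <- length(signals)
  n_top <- max(1, floor((f - 0.1) * n + 0.5))
  n_bottom <- max(1, floor((0.9 - f) * n + 0.5))
  s <- sort(signals, decreasing = TRUE)
  r_mean <- mean(s[1:n_top])
  nonr_mean <- mean(s[(n - n_bottom + 1):n])
  list(n_top = n_top, n_bottom = n_bottom, r_mean = r_mean,
       nonr_mean = nonr_mean, ratio = r_mean / nonr_mean)
}
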