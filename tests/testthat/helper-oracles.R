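# Independent brute-force oracles used to cross-check the package's
# population detection and scoring. These re-derive every quantity with
# plain loops from the stated definitions and share no code with the
# package internals.

# textbook Pearson correlation from the covariance / standard deviation
# definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force population finder: triangular smoothing, exhaustive local
# maxima, O(n^2) prominence scans, watershed boundaries at the between-peak
# minima (valley excluded from both basins), raw within-basin argmax as the
# population position, raw basin mass, mass floor
populations_oracle <- function(x, samples, smooth_width = 3,
                               prominence_frac = 0.10, mass_min = 0.15) {
  n <- length(x)
  if (all(x == 0)) return(data.frame(peak_sample = integer(), mass = numeric()))
  half <- (smooth_width - 1) / 2
  s <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      if (abs(j - i) <= half) {
        w <- half + 1 - abs(j - i)
        num <- num + w * x[j]
        den <- den + w
      }
    }
    s[i] <- num / den
  }
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- if (i == 1) TRUE else s[i] > s[i - 1]
    right_ok <- if (i == n) TRUE else s[i] >= s[i + 1]
    is_max[i] <- left_ok && right_ok
  }
  peaks <- which(is_max)
  proms <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    left_base <- s[i]
    if (i > 1) {
      m <- s[i]
      for (j in (i - 1):1) {
        if (s[j] > s[i]) break
        m <- min(m, s[j])
      }
      left_base <- m
    }
    right_base <- s[i]
    if (i < n) {
      m <- s[i]
      for (j in (i + 1):n) {
        if (s[j] > s[i]) break
        m <- min(m, s[j])
      }
      right_base <- m
    }
    proms[k] <- s[i] - max(left_base, right_base)
  }
  peaks <- peaks[proms >= prominence_frac * max(s)]
  if (length(peaks) == 0) {
    return(data.frame(peak_sample = integer(), mass = numeric()))
  }
  bounds <- integer(0)
  if (length(peaks) > 1) {
    for (k in seq_len(length(peaks) - 1)) {
      idx <- (peaks[k] + 1):(peaks[k + 1] - 1)
      bounds <- c(bounds, idx[which.min(s[idx])])
    }
  }
  lo <- c(1, bounds + 1)
  hi <- c(bounds - 1, n)
  out <- data.frame(peak_sample = integer(0), mass = numeric(0))
  for (k in seq_along(peaks)) {
    idx <- lo[k]:hi[k]
    mass <- sum(x[idx])
    if (mass >= mass_min) {
      out <- rbind(out, data.frame(peak_sample = samples[idx[which.max(x[idx])]],
                                   mass = mass))
    }
  }
  out[order(out$peak_sample), , drop = FALSE]
}
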