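# Brute-force oracles kept deliberately independent of the package
# implementations: nested loops and direct moment formulas only.

oracle_glcm <- function(patch, levels = 8, distance = 1,
                        angles = c(0, 45, 90, 135)) {
  lo <- min(patch); hi <- max(patch)
  q <- if (hi == lo) matrix(1L, nrow(patch), ncol(patch))
  else if (all(patch == round(patch)) && (hi - lo) < levels)
    matrix(as.integer(patch - lo + 1), nrow(patch), ncol(patch))
  else {
    qq <- floor((patch - lo) / (hi - lo) * levels) + 1
    qq[qq > levels] <- levels
    matrix(as.integer(qq), nrow(patch), ncol(patch))
  }
  off <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
              `135` = c(-1, -1))
  pavg <- matrix(0, levels, levels)
  used <- 0
  for (ang in as.character(angles)) {
    dr <- off[[ang]][1] * distance; dc <- off[[ang]][2] * distance
    cm <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        cm[q[r, cc], q[r2, c2]] <- cm[q[r, cc], q[r2, c2]] + 1
        cm[q[r2, c2], q[r, cc]] <- cm[q[r2, c2], q[r, cc]] + 1
      }
    }
    if (sum(cm) > 0) {
      pavg <- pavg + cm / sum(cm)
      used <- used + 1
    }
  }
  p <- pavg / used
  ent <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels))
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
  hom <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels))
    hom <- hom + p[i, j] / (1 + abs(i - j))
  c(entropy = ent, energy = sum(p^2), homogeneity = hom)
}

oracle_histogram <- function(patch, bins = 256) {
  x <- as.numeric(patch)
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  qs <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  contrast <- if (qs[1] + qs[2] == 0) 0 else (qs[2] - qs[1]) / (qs[2] + qs[1])
  lo <- min(x); hi <- max(x)
  energy <- if (hi == lo) 1 else {
    counts <- numeric(bins)
    for (xi in x) {
      b <- floor((xi - lo) / (hi - lo) * bins) + 1
      if (b > bins) b <- bins
      counts[b] <- counts[b] + 1
    }
    sum((counts / n)^2)
  }
  c(mean = mu, energy_hist = energy, std = s, rms = sqrt(sum(x^2) / n),
    contrast = contrast, variance = v,
    skewness = if (s > 0) m3 / s^3 else 0,
    kurtosis = if (s > 0) m4 / s^4 else 0)
}

# two well-separated Gaussian blobs as a linearly separable feature table
separable_table <- function(n_per_class = 30, p = 4, shift = 8, seed = 42,
                            labels = c("A", "B")) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = shift), ncol = p))
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(p))
  df$label <- rep(labels, each = n_per_class)
  df$group <- paste0(df$label, rep(seq_len(n_per_class), 2))
  df$patch <- 1L
  class(df) <- c("feature_table", "data.frame")
  df
}

# small noise-free class params for fast phantom tests
quiet_params <- function(class_label = "MCT") {
  p <- phantom_class_table()[[class_label]]
  p$noise_sigma <- 0
  p$image_noise_rel <- 0
  p
}
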