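# Small fixtures and independent oracles shared across tests.

tiny_config <- function(shape = c(32, 32, 16), n_subjects = 4, ...) {
  phantom_config(shape = shape, n_subjects = n_subjects, seed = 42L, ...)
}

# a small healthy 2D label with a one-hot region layout (C x H x W)
onehot_label_2d <- function(h = 8, w = 8, channel = "WM") {
  probs <- array(0, c(length(ALL_CHANNELS), h, w))
  probs[match(channel, ALL_CHANNELS), , ] <- 1
  prob_label_map(probs)
}

# 2D label with a given number of WMH voxels on a WM background
wmh_label_2d <- function(n_wmh, h = 8, w = 8) {
  probs <- array(0, c(length(ALL_CHANNELS), h, w))
  probs[3, , ] <- 1                      # WM
  if (n_wmh > 0) {
    idx <- arrayInd(seq_len(n_wmh), c(h, w))
    for (k in seq_len(n_wmh)) {
      probs[3, idx[k, 1], idx[k, 2]] <- 0
      probs[6, idx[k, 1], idx[k, 2]] <- 1   # WMH
    }
  }
  prob_label_map(probs)
}

# brute-force focal loss oracle: explicit per-pixel loop, independent of the
# package's vectorised implementation
focal_oracle <- function(l, p, gamma) {
  eps <- 1e-6
  tot <- 0
  for (i in seq_along(l)) {
    li <- min(max(l[i], eps), 1 - eps)
    pi <- min(max(p[i], eps), 1 - eps)
    ce <- -(l[i] * log(pi) + (1 - l[i]) * log(1 - pi))
    ce0 <- -(li * log(li) + (1 - li) * log(1 - li))
    pt <- l[i] * pi + (1 - l[i]) * (1 - pi)
    w <- if (gamma == 0) 1 else max(1 - pt, eps)^gamma
    tot <- tot + w * (ce - ce0)
  }
  tot / length(l)
}

# numeric gradient of a scalar-valued function of an array
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
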