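# Statistics-derived image simulator: weighted moments, bias fields, and
# the per-voxel Gaussian model.

test_that("estimate_region_stats reproduces brute-force weighted moments", {
  set.seed(4)
  lab <- onehot_label_2d(6, 6, "WM")
  # constant image over a one-hot region: mu = v, sigma = 0
  st <- estimate_region_stats(list(array(2.5, c(6, 6))), list(lab),
                              "T1", "d")
  expect_equal(st$mu[st$region == "WM"], 2.5)
  expect_equal(st$sigma[st$region == "WM"], 0)
  # two images with values 0 and 2 and equal mass: mu = 1
  st2 <- estimate_region_stats(list(array(0, c(6, 6)), array(2, c(6, 6))),
                               list(lab, lab), "T1", "d")
  expect_equal(st2$mu[st2$region == "WM"], 1)
  # random soft labels vs a direct weighted-moment computation
  probs <- array(runif(9 * 5 * 5), c(9, 5, 5))
  probs <- sweep(probs, c(2, 3), apply(probs, c(2, 3), sum), "/")
  probs[6:9, , ] <- 0   # keep lesion channels binary (zero)
  soft <- prob_label_map(probs)
  img <- array(rnorm(25), c(5, 5))
  st3 <- estimate_region_stats(list(img), list(soft), "T1", "d")
  for (r in 1:5) {
    w <- as.numeric(probs[r, , ])
    mu <- sum(w * img) / sum(w)
    va <- sum(w * img^2) / sum(w) - mu^2
    expect_equal(st3$mu[r], mu, tolerance = 1e-9)
    expect_equal(st3$sigma[r], sqrt(max(va, 0)), tolerance = 1e-9)
  }
  # a requested region without probability mass fails with its name
  expect_error(estimate_region_stats(list(img), list(soft), "T1", "d",
                                     regions = c("WM", "oedema")),
               "zero probability mass: oedema")
})

test_that("bias fields are smooth, positive, near-unit mean", {
  bf <- sample_bias_field(c(24, 24), bias_field_params(), 3L)
  expect_true(all(bf > 0))
  expect_equal(mean(bf), 1, tolerance = 0.1)
  dev <- max(abs(log(bf)))
  expect_gte(dev, 0.05 - 1e-9)
  expect_lte(dev, 0.15 + 1e-9)
  # degenerate coefficient range gives the identity field
  bf0 <- sample_bias_field(c(8, 8), bias_field_params(coeff_range = c(0, 0)),
                           1L)
  expect_equal(bf0, array(1, c(8, 8)))
  # strong spatial autocorrelation at lag 1
  ac <- sapply(1:20, function(s) {
    f <- log(sample_bias_field(c(24, 24), bias_field_params(), s))
    cor(as.numeric(f[-1, ]), as.numeric(f[-24, ]))
  })
  expect_gt(mean(ac), 0.9)
})

test_that("sd_image follows the per-region Gaussian model", {
  lab <- onehot_label_2d(8, 8, "GM")
  stats <- region_intensity_stats(
    data.frame(modality = "T1", dataset = "d", region = "GM",
               mu = 0.6, sigma = 0),
    K = c(T1 = 6))
  img <- sd_image(lab, stats, "T1", "d", bias_field_params(probability = 0),
                  1L)
  expect_equal(img, array(0.6, c(8, 8)))
  # missing stats entry fails
  expect_error(sd_image(onehot_label_2d(8, 8, "WM"), stats, "T1", "d",
                        bias_field_params(probability = 0), 1L), "missing")
  # K -> Inf collapses the noise onto the mixture of means
  stats2 <- region_intensity_stats(
    data.frame(modality = "T1", dataset = "d", region = "GM",
               mu = 0.6, sigma = 0.3),
    K = c(T1 = 1e9))
  img2 <- sd_image(lab, stats2, "T1", "d",
                   bias_field_params(probability = 0), 2L)
  expect_equal(img2, array(0.6, c(8, 8)), tolerance = 1e-6)
})

test_that("per-voxel noise std matches sigma / K over 1000 seeds", {
  lab <- onehot_label_2d(4, 4, "WM")
  sigma <- 0.3; K <- 6
  stats <- region_intensity_stats(
    data.frame(modality = "T1", dataset = "d", region = "WM",
               mu = 0.7, sigma = sigma),
    K = c(T1 = K))
  draws <- vapply(1:1000, function(s)
    sd_image(lab, stats, "T1", "d", bias_field_params(probability = 0),
             s)[2, 2], numeric(1))
  expect_lt(abs(sd(draws) - sigma / K), 0.05 * sigma / K)
})

test_that("bias-field application rate matches its probability", {
  lab <- onehot_label_2d(6, 6, "WM")
  stats <- region_intensity_stats(
    data.frame(modality = "T1", dataset = "d", region = "WM",
               mu = 0.7, sigma = 0),
    K = c(T1 = 6))
  p <- 0.4; n <- 500
  hits <- vapply(1:n, function(s) {
    img <- sd_image(lab, stats, "T1", "d",
                    bias_field_params(probability = p), s)
    # sigma = 0: any deviation from the constant mean signals a bias field
    max(abs(img - 0.7)) > 1e-9
  }, logical(1))
  ci <- p + c(-1, 1) * stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_gte(mean(hits), ci[1])
  expect_lte(mean(hits), ci[2])
})

test_that("regions separated by more than 3 sigma/K are detectable", {
  probs <- array(0, c(9, 64, 64))
  probs[2, , 1:32] <- 1   # GM left
  probs[3, , 33:64] <- 1  # WM right
  lab <- prob_label_map(probs)
  stats <- default_phantom_stats()
  img <- sd_image(lab, stats, "T1", "phantom",
                  bias_field_params(probability = 0), 5L)
  tt <- t.test(img[, 1:32], img[, 33:64])
  expect_lt(tt$p.value, 1e-6)
})
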