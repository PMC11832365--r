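# Loss implementations vs brute-force oracles on tiny fixtures.

test_that("focal reconstruction loss matches a per-pixel oracle", {
  set.seed(5)
  l <- array(runif(9), c(3, 3))
  p <- array(runif(9), c(3, 3))
  expect_equal(focal_recon_loss(l, p, gamma = 0.3),
               focal_oracle(l, p, 0.3), tolerance = 1e-9)
  expect_equal(focal_recon_loss(l, p, gamma = 0),
               focal_oracle(l, p, 0), tolerance = 1e-9)
  # binary fixture
  lb <- array(round(runif(16)), c(4, 4))
  pb <- array(runif(16), c(4, 4))
  expect_equal(focal_recon_loss(lb, pb, 0.3), focal_oracle(lb, pb, 0.3),
               tolerance = 1e-9)
})

test_that("focal loss is zero iff reconstruction equals the target", {
  l <- array(c(0, 1, 0.3, 0.8, 0.5, 0, 1, 0.2, 0.6), c(3, 3))
  expect_lt(focal_recon_loss(l, l), 1e-6)
  expect_gt(focal_recon_loss(l, pmin(l + 0.1, 1)), 1e-4)
  expect_error(focal_recon_loss(l * NA, l), "non-finite")
})

test_that("Gaussian KLD matches the closed form", {
  set.seed(6)
  mu <- rnorm(7); lv <- rnorm(7, 0, 0.5)
  expect_equal(kld_gaussian(mu, lv),
               0.5 * sum(mu^2 + exp(lv) - lv - 1), tolerance = 1e-9)
  expect_equal(kld_gaussian(rep(0, 5), rep(0, 5)), 0)
})

test_that("hinge GAN loss matches hand computation on both sides", {
  r <- array(c(2, 1.5, 1, 3), c(2, 2))   # all beyond the margin
  f <- array(c(-2, -1, -1.5, -3), c(2, 2))
  expect_equal(hinge_gan_loss(r, f, "discriminator"), 0)
  expect_equal(hinge_gan_loss(NULL, array(0, c(2, 2)), "generator"), 0)
  # generic fixture vs explicit formula
  set.seed(7)
  r2 <- array(rnorm(8), c(2, 2, 1, 2)); f2 <- array(rnorm(8), c(2, 2, 1, 2))
  expect_equal(hinge_gan_loss(r2, f2, "discriminator"),
               mean(pmax(1 - r2, 0)) + mean(pmax(1 + f2, 0)),
               tolerance = 1e-12)
  expect_equal(hinge_gan_loss(NULL, f2, "generator"), -mean(f2),
               tolerance = 1e-12)
  # multi-scale: sums over scales
  expect_equal(hinge_gan_loss(list(r2, r2), list(f2, f2), "discriminator"),
               2 * (mean(pmax(1 - r2, 0)) + mean(pmax(1 + f2, 0))),
               tolerance = 1e-12)
})

test_that("feature matching equals the L1 double sum", {
  set.seed(8)
  fr <- list(list(array(rnorm(8), c(2, 2, 2, 1)), array(rnorm(4), c(2, 2, 1, 1))),
             list(array(rnorm(8), c(2, 2, 2, 1)), array(rnorm(4), c(2, 2, 1, 1))))
  ff <- lapply(fr, function(sc) lapply(sc, function(a) a + rnorm(length(a))))
  manual <- sum(mapply(function(s1, s2)
    sum(mapply(function(a, b) mean(abs(a - b)), s1, s2)), fr, ff))
  expect_equal(feature_matching_loss(fr, ff), manual, tolerance = 1e-12)
  expect_equal(feature_matching_loss(fr, fr), 0)
  # single scale, single feature reduces to plain L1
  a <- array(rnorm(9), c(3, 3, 1, 1)); b <- array(rnorm(9), c(3, 3, 1, 1))
  expect_equal(feature_matching_loss(list(a), list(b)), mean(abs(a - b)),
               tolerance = 1e-12)
  expect_error(feature_matching_loss(fr, ff[1]), "mismatched")
})

test_that("perceptual loss through an identity extractor is plain L1", {
  identity_extractor <- function(x) list(mrisynth:::.ensure_hwcn(x))
  a <- array(runif(16), c(4, 4)); b <- array(runif(16), c(4, 4))
  expect_equal(perceptual_loss(a, b, identity_extractor), mean(abs(a - b)),
               tolerance = 1e-12)
  fx <- make_feature_extractor(1, seed = 11)
  expect_equal(perceptual_loss(a, a, fx), 0)
  # layerwise oracle with the real extractor
  fa <- fx(array(a, c(4, 4, 1, 1))); fb <- fx(array(b, c(4, 4, 1, 1)))
  manual <- sum(mapply(function(u, v) mean(abs(u$value - v$value)), fa, fb))
  expect_equal(perceptual_loss(a, b, fx), manual, tolerance = 1e-12)
})

test_that("contrastive style loss follows cosine geometry", {
  enc_id <- function(img) as.numeric(img)[1:4]
  img <- array(runif(16) + 0.1, c(4, 4))
  expect_equal(contrastive_style_loss(enc_id, img,
                                      augmenter = function(i, s) i), 0,
               tolerance = 1e-12)
  # antiparallel codes give loss 2
  flip <- local({i <- 0; function(img) {i <<- i + 1
    if (i %% 2 == 1) c(1, 0) else c(-1, 0)}})
  expect_equal(contrastive_style_loss(flip, img,
                                      augmenter = function(i, s) i), 2)
  # matches a direct dot-product computation under the affine augmenter
  enc_mean <- function(img) c(mean(img), stats::sd(img))
  a <- enc_mean(img); b <- enc_mean(affine_augment(img, 3L))
  expect_equal(contrastive_style_loss(enc_mean, img, rng_seed = 3L),
               1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
               tolerance = 1e-12)
  zero_enc <- function(img) c(0, 0)
  expect_error(contrastive_style_loss(zero_enc, img), "zero-norm")
})

test_that("modality/dataset discrimination loss reduces to weighted BCEs", {
  clf <- function(img) list(modality = c(0.9, 0.1), dataset = c(0.2, 0.8))
  img <- array(0.5, c(4, 4))
  manual <- bce_loss(c(1, 0), c(0.9, 0.1)) + 2 * bce_loss(c(0, 1), c(0.2, 0.8))
  expect_equal(modality_dataset_disc_loss(clf, img, c(1, 0), c(0, 1),
                                          1, 2), manual, tolerance = 1e-12)
  expect_equal(modality_dataset_disc_loss(clf, img, c(1, 0), c(0, 1), 0, 0), 0)
  perfect <- function(img) list(modality = c(1 - 1e-7, 1e-7),
                                dataset = c(1e-7, 1 - 1e-7))
  expect_lt(modality_dataset_disc_loss(perfect, img, c(1, 0), c(0, 1)), 1e-5)
  expect_error(modality_dataset_disc_loss(NULL, img, c(1, 0), c(0, 1)),
               "classifier")
})
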