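# Evaluation metrics: proportions, FP_tum, SSIM/MSE, Frechet distance,
# Dice retrieval, style clustering.

test_that("tissue proportion profiles match brute-force counting", {
  lab <- onehot_label_2d(8, 8, "WM")
  lab$slice_index <- 0L
  prof <- tissue_proportion_profile(list(lab), "per_slice")
  expect_equal(prof$mean[prof$region == "WM"], 1)
  expect_equal(sum(prof$mean), 1)
  # mixed fixture vs manual counting
  set.seed(15)
  labs <- lapply(1:4, function(s) {
    l <- generate_phantom_label(tiny_config(shape = c(16, 16)), s)
    l$slice_index <- 0L
    l
  })
  prof2 <- tissue_proportion_profile(labs, "per_slice")
  manual <- rowMeans(sapply(labs, function(l) {
    pm <- matrix(l$probs, 9)
    sapply(1:5, function(i) sum(pm[i, ]) / sum(pm))
  }))
  expect_equal(prof2$mean[match(HEALTHY_CHANNELS, prof2$region)],
               unname(manual), tolerance = 1e-12)
  # healthy maps: proportions over healthy channels sum to 1
  expect_equal(sum(prof2$mean), 1, tolerance = 1e-9)
  expect_error(tissue_proportion_profile(list()), "empty")
})

test_that("profile coverage compares sampled and reference bins", {
  lab <- onehot_label_2d(8, 8, "WM"); lab$slice_index <- 0L
  ref <- tissue_proportion_profile(list(lab, lab), "per_slice")
  cov <- profile_coverage(ref, ref)
  expect_equal(cov$fraction, 1)
})

test_that("fp_tum is the mislabelled fraction of tumour voxels", {
  tum <- array(0, c(5, 5)); tum[1:2, 1:5] <- 1          # 10 voxels
  pred <- array(0, c(5, 5)); pred[1, 1:4] <- 1           # 4 overlap
  expect_equal(fp_tum(pred, tum), 0.4)
  expect_equal(fp_tum(array(0, c(5, 5)), tum), 0)        # disjoint
  expect_equal(fp_tum(array(1, c(5, 5)), tum), 1)        # superset
  expect_error(fp_tum(pred, array(0, c(5, 5))), "empty tumour")
  expect_error(fp_tum(pred, tum[1:4, 1:4]), "differ")
})

test_that("SSIM and MSE behave at their fixed points", {
  set.seed(16)
  img <- array(runif(1024), c(32, 32))
  fid <- image_fidelity(img, img)
  expect_equal(fid$ssim, 1, tolerance = 1e-9)
  expect_equal(fid$mse, 0)
  inv <- image_fidelity(img, 1 - img)
  expect_lt(inv$ssim, 1)
  other <- array(runif(1024), c(32, 32))
  expect_equal(image_fidelity(img, other)$mse, mean((img - other)^2),
               tolerance = 1e-12)
})

test_that("Frechet distance matches closed forms", {
  set.seed(17)
  X <- matrix(rnorm(600), 200, 3)
  expect_lt(fid_score(X, X), 1e-6)
  # two 1-D unit-variance Gaussians with mean offset delta: FID -> delta^2
  delta <- 1.7
  a <- matrix(rnorm(5000), ncol = 1)
  b <- matrix(rnorm(5000) + delta, ncol = 1)
  expect_equal(fid_score(a, b), delta^2, tolerance = 0.15)
  # independent implementation of the closed form on Gaussian fits
  A <- matrix(rnorm(900), 300, 3)
  B <- matrix(rnorm(900, 0.3, 1.2), 300, 3)
  mua <- colMeans(A); mub <- colMeans(B)
  Sa <- cov(A) + diag(1e-6, 3); Sb <- cov(B) + diag(1e-6, 3)
  # sqrt(Sa Sb) via similarity transform with Sa^(1/2)
  es <- eigen(Sa); sa_half <- es$vectors %*% diag(sqrt(es$values)) %*% t(es$vectors)
  ev <- eigen(sa_half %*% Sb %*% sa_half, only.values = TRUE)$values
  manual <- sum((mua - mub)^2) + sum(diag(Sa)) + sum(diag(Sb)) -
    2 * sum(sqrt(pmax(ev, 0)))
  expect_equal(fid_score(A, B), manual, tolerance = 1e-8)
  expect_gte(fid_score(A, B), 0)
  expect_error(fid_score(A, matrix(0, 1, 3)), "at least 2")
  expect_error(fid_score(A, matrix(0, 10, 2)), "dims differ")
})

test_that("nearest-neighbour Dice retrieval finds planted queries exactly", {
  set.seed(18)
  cfg <- tiny_config(shape = c(16, 16))
  train <- lapply(1:6, function(s) generate_phantom_label(cfg, s))
  res <- nn_dice_retrieval(train[[4]], train, k = 4)
  expect_equal(res$index[1], 4)
  expect_equal(res$dice[1], 1.0)
  # ranking matches brute-force all-pairs Dice
  manual <- vapply(train, function(l) label_dice(train[[4]], l), numeric(1))
  expect_equal(res$index, order(manual, decreasing = TRUE)[1:4])
  expect_equal(res$dice, sort(manual, decreasing = TRUE)[1:4])
  expect_message(nn_dice_retrieval(train[[1]], train, k = 10), "exceeds")
})

test_that("Dice is symmetric", {
  cfg <- tiny_config(shape = c(16, 16))
  a <- generate_phantom_label(cfg, 1)
  b <- generate_phantom_label(cfg, 2)
  expect_equal(label_dice(a, b), label_dice(b, a))
})

test_that("style-code clustering recovers separable groups", {
  set.seed(19)
  blob1 <- matrix(rnorm(100, 0), 50, 2)
  blob2 <- matrix(rnorm(100, 6), 50, 2)
  codes <- rbind(blob1, blob2)
  truth <- rep(c("a", "b"), each = 50)
  res <- style_code_clustering(codes, truth, k = 2)
  expect_equal(res$ari, 1)
  expect_equal(style_code_clustering(codes, truth, k = 1)$ari, 0)
  expect_error(style_code_clustering(codes[1:1, , drop = FALSE], "a", k = 2),
               "fewer")
  # k-means objective does not increase with more iterations
  wss <- vapply(c(1, 2, 5, 20), function(it)
    with_seed(7, suppressWarnings(
      stats::kmeans(codes, 2, iter.max = it)))$tot.withinss, numeric(1))
  expect_true(all(diff(wss) <= 1e-9))
  # pluggable embedding is honoured
  res_pca <- style_code_clustering(codes, truth, k = 2,
                                   embed = function(X) prcomp(X)$x[, 1:2])
  expect_equal(res_pca$ari, 1)
})
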