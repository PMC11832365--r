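# Phantom generator: label-map invariants, lesion placement, fusion rule.

test_that("phantom labels satisfy all probabilistic label-map invariants", {
  cfg <- tiny_config()
  lab <- generate_phantom_label(cfg, 7L)
  expect_true(validate_label(lab))
  pm <- matrix(lab$probs, dim(lab$probs)[1])
  expect_lte(max(colSums(pm)), 1 + 1e-5)
  # fractional border probabilities exist (smoothed boundaries)
  frac <- pm > 0.05 & pm < 0.95
  expect_gt(sum(frac), 100)
})

test_that("phantom generation is deterministic in the seed and varies across seeds", {
  cfg <- tiny_config()
  a <- generate_phantom_label(cfg, 9L)
  b <- generate_phantom_label(cfg, 9L)
  expect_identical(a$probs, b$probs)
  c2 <- generate_phantom_label(cfg, 10L)
  wm_a <- a$probs[3, , , ] > 0.5
  wm_c <- c2$probs[3, , , ] > 0.5
  expect_lt(mrisynth:::dice_binary(wm_a, wm_c), 1.0)
})

test_that("too-small shapes are rejected", {
  expect_error(phantom_config(shape = c(8, 8, 4)), "too small")
})

test_that("lesion masks respect layering, monotonicity and placement", {
  cfg <- tiny_config()
  lab <- generate_phantom_label(cfg, 3L)
  mt <- generate_lesion_mask(lab, "tumour", 0.7, 5L, cfg)
  expect_gt(sum(mt$layers$NE_tumour), 0)
  expect_equal(sum(mt$layers$NE_tumour * mt$layers$oedema), 0)
  expect_equal(sum(mt$layers$NE_tumour * mt$layers$GD_tumour), 0)
  expect_equal(sum(mt$layers$GD_tumour * mt$layers$oedema), 0)
  # size_param = 0 yields a minimal lesion under the default flag,
  # and errors when the flag is off
  m0 <- generate_lesion_mask(lab, "wmh", 0, 11L, cfg)
  expect_gte(sum(m0$mask), 1)
  cfg_strict <- tiny_config(min_one_voxel = FALSE)
  expect_error(generate_lesion_mask(lab, "wmh", 0, 11L, cfg_strict))
  expect_error(generate_lesion_mask(lab, "cyst", 0.5, 1L, cfg), "unknown")
})

test_that("expected lesion volume increases with size_param (Monte Carlo)", {
  cfg <- tiny_config()
  lab <- generate_phantom_label(cfg, 3L)
  sizes <- c(0.1, 0.4, 0.7, 1.0)
  seeds <- 1:25
  counts <- sapply(sizes, function(sp)
    sapply(seeds, function(s)
      sum(generate_lesion_mask(lab, "wmh", sp, s, cfg)$mask)))
  means <- colMeans(counts)
  expect_true(all(diff(means) > -1e-9))
  ct <- suppressWarnings(
    cor.test(rep(sizes, each = length(seeds)), as.numeric(counts),
             method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("fuse_lesion zeroes healthy tissue exactly under the mask", {
  cfg <- tiny_config()
  lab <- generate_phantom_label(cfg, 3L)
  msk <- generate_lesion_mask(lab, "wmh", 0.5, 2L, cfg)
  fused <- fuse_lesion(lab, msk)
  expect_true(validate_label(fused))
  sel <- msk$mask == 1
  for (i in 1:5) expect_true(all(fused$probs[i, , , ][sel] == 0))
  # untouched voxels unchanged
  for (i in 1:9) expect_equal(fused$probs[i, , , ][!sel],
                              lab$probs[i, , , ][!sel])
  # empty mask is the identity
  empty <- msk
  empty$mask <- msk$mask * 0
  empty$layers <- lapply(msk$layers, function(x) x * 0)
  expect_equal(fuse_lesion(lab, empty)$probs, lab$probs)
  # channel mismatch fails
  bad <- msk
  names(bad$layers) <- "not_a_channel"
  expect_error(fuse_lesion(lab, bad), "channel-name mismatch")
})

test_that("channel sums never increase under fusion", {
  cfg <- tiny_config()
  lab <- generate_phantom_label(cfg, 4L)
  msk <- generate_lesion_mask(lab, "tumour", 0.8, 6L, cfg)
  fused <- fuse_lesion(lab, msk)
  cs_before <- colSums(matrix(lab$probs, 9))
  cs_after <- colSums(matrix(fused$probs, 9))
  expect_true(all(cs_after <= pmax(cs_before, 1) + 1e-9))
})

test_that("tumour superimposition augments healthy maps without replacement", {
  cfg <- tiny_config()
  healthy <- lapply(1:4, function(s) generate_phantom_label(cfg, s))
  tum <- lapply(5:8, function(s) {
    l <- generate_phantom_label(cfg, s)
    fuse_lesion(l, generate_lesion_mask(l, "tumour", 0.6, s, cfg))
  })
  expect_identical(superimpose_tumour_augmentation(healthy, tum, 0), list())
  aug <- superimpose_tumour_augmentation(healthy, tum, 3, 1L)
  expect_length(aug, 3)
  for (a in aug) {
    expect_true(validate_label(a))
    expect_gt(sum(lesion_voxel_counts(a)[c("NE_tumour", "oedema",
                                           "GD_tumour")]), 0)
  }
  expect_error(superimpose_tumour_augmentation(healthy, tum, 9),
               "exceeds")
})

test_that("dataset assembly produces matched labels, images and metadata", {
  cfg <- phantom_config(n_subjects = 3, seed = 2,
                        lesion_frequency = c(wmh = 0, tumour = 0))
  ds <- make_phantom_dataset(cfg, default_phantom_stats(), c("T1", "FLAIR"))
  expect_length(ds$subjects, 3)
  expect_length(ds$subjects[[1]]$images, 2)
  for (s in ds$subjects) {
    expect_true(all(is.finite(s$images$T1)))
    expect_gte(min(s$images$T1), 0)
    expect_equal(sum(lesion_voxel_counts(s$label)), 0)  # frequency 0
  }
  # slices drop background-only planes and record indices
  sl <- ds$slices
  expect_gt(length(sl), 0)
  expect_true(all(vapply(sl, function(x) !is.null(x$label$slice_index),
                         logical(1))))
})
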