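# Image generator building blocks: scheduler, discriminator input,
# triplets, augmentation, style encoding.

test_that("adversarial scheduler follows the strict-threshold truth table", {
  decide <- function(m) {
    st <- scheduler_state()
    out <- scheduler_step(st, m)    # single entry: mean equals the value
    c(G = out$train_G, D = out$train_D)
  }
  expect_equal(decide(0.5),  c(G = FALSE, D = TRUE))   # below T_down
  expect_equal(decide(0.6),  c(G = TRUE, D = TRUE))    # boundary: both
  expect_equal(decide(0.7),  c(G = TRUE, D = TRUE))
  expect_equal(decide(0.75), c(G = TRUE, D = TRUE))    # boundary: both
  expect_equal(decide(0.8),  c(G = TRUE, D = FALSE))   # above T_up
  expect_error(scheduler_step(scheduler_state(), 1.2), "\\[0, 1\\]")
  expect_error(scheduler_state(t_up = 0.5, t_down = 0.6))
})

test_that("scheduler window rolls at length 20 and averages available entries", {
  st <- scheduler_state()
  # 5 entries of 0.9: shorter-than-capacity window uses what it has
  for (i in 1:5) { out <- scheduler_step(st, 0.9); st <- out$state }
  expect_equal(out$mean_acc, 0.9)
  expect_true(out$train_G); expect_false(out$train_D)
  # flood with 25 zeros: only the last 20 remain
  for (i in 1:25) { out <- scheduler_step(st, 0); st <- out$state }
  expect_length(st$acc, 20)
  expect_equal(out$mean_acc, 0)
  # pure function of window contents: same window, same decision
  st2 <- scheduler_state(); st2$acc <- st$acc[-20]
  expect_equal(scheduler_step(st2, 0)$train_D, out$train_D)
})

test_that("discriminator input stacks image, labels and modality planes", {
  img <- array(runif(64), c(8, 8))
  m <- onehot_label_2d(8, 8, "GM")
  x <- discriminator_input(img, m, c(0, 1, 0))
  expect_equal(dim(x), c(8L, 8L, 13L, 1L))   # 1 + 9 + 3
  expect_equal(x[, , 1, 1], img)                      # image first
  expect_equal(x[, , 1 + 2, 1], m$probs[2, , ])       # then label channels
  expect_true(all(x[, , 11, 1] == 0))                 # one-hot planes are
  expect_true(all(x[, , 12, 1] == 1))                 # constant-valued
  expect_true(all(x[, , 13, 1] == 0))
})

test_that("training triplets pair a slice with an unpaired same-volume style", {
  cfg <- tiny_config()
  lab <- generate_phantom_label(cfg, 2L)
  vol <- sd_image(lab, default_phantom_stats(), "T1", "phantom",
                  bias_field_params(probability = 0), 3L)
  styles_differ <- vapply(1:100, function(s) {
    tri <- make_training_triplet(vol, lab, s)
    tri$style_index != tri$slice_index
  }, logical(1))
  expect_true(all(styles_differ))
  tri <- make_training_triplet(vol, lab, 1L)
  expect_equal(tri$i, vol[, , tri$slice_index + 1])
  expect_equal(tri$i_s, vol[, , tri$style_index + 1])
  # single usable slice falls back with a warning
  expect_warning(make_training_triplet(vol, lab, 1L, usable_idx = 5L),
                 "single-slice")
})

test_that("affine augmentation preserves shape and is seeded", {
  img <- array(runif(1024), c(32, 32))
  a1 <- affine_augment(img, 5L)
  a2 <- affine_augment(img, 5L)
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(img))
  expect_gt(mean(abs(a1 - img)), 0)       # geometry actually perturbed
  expect_lte(max(a1), max(img) + 1e-9)    # bilinear stays in the value hull
  expect_gte(min(a1), min(img) - 1e-9)
})

test_that("style codes are 16-dimensional and deterministic in eval mode", {
  gans <- trained_image_gans()
  img <- normalize_image(gans$holdout[[1]]$images$T1)[, , 8]
  s1 <- encode_style(gans$full, img)
  s2 <- encode_style(gans$full, img)
  expect_identical(s1$mu, s2$mu)
  expect_length(s1$s, 16)
  expect_true(all(is.finite(c(s1$mu, s1$logvar))))
  expect_true(is.finite(kld_gaussian(s1$mu, s1$logvar)))
  expect_error(encode_style(gans$full, img[1:16, 1:16]), "spatial size")
})

test_that("image generation is deterministic, bounded, and style-sensitive", {
  gans <- trained_image_gans()
  sub <- gans$holdout[[1]]
  us <- slice_label(sub$label)
  m <- us[[6]]
  sty_t1 <- encode_style(gans$full, normalize_image(sub$images$T1)[, , 8])
  sty_t2 <- encode_style(gans$full, normalize_image(sub$images$T2)[, , 8])
  g1 <- generate_image(gans$full, m, sty_t1)
  g2 <- generate_image(gans$full, m, sty_t1)
  expect_identical(g1, g2)
  expect_true(all(g1 >= 0 & g1 <= 1))
  # different styles, same semantic map: images differ after training
  g3 <- generate_image(gans$full, m, sty_t2)
  expect_gt(mean(abs(g1 - g3)), 0)
  # 3D maps are rejected at this interface
  expect_error(generate_image(gans$full, sub$label, sty_t1), "2D")
})

test_that("image generator training is reproducible under a fixed seed", {
  ds <- make_phantom_dataset(
    phantom_config(n_subjects = 3, seed = 21,
                   lesion_frequency = c(wmh = 0, tumour = 0)),
    default_phantom_stats(), c("T1", "T2"))
  cfg <- image_gan_config(iters = 6, batch_size = 4, seed = 3)
  g1 <- train_image_generator(ds, cfg)
  g2 <- train_image_generator(ds, cfg)
  expect_identical(g1$history, g2$history)
  expect_identical(g1$params$enc$w1$value, g2$params$enc$w1$value)
})
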