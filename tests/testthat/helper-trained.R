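# Heavy toy-scale trainings are run once per test session and shared across
# test files (test_dir runs everything in one process).

.trained <- new.env(parent = emptyenv())

acceptance_dataset <- function() {
  if (is.null(.trained$ds)) {
    .trained$ds <- make_phantom_dataset(
      phantom_config(n_subjects = 44, seed = 11,
                     lesion_frequency = c(wmh = 0.45, tumour = 0.35)),
      default_phantom_stats(), c("T1", "FLAIR", "T2"))
  }
  .trained$ds
}

# S-VAE + conditioned LDM trained on ~500 32x32 phantom slices
trained_label_stack <- function() {
  if (is.null(.trained$stack)) {
    ds <- acceptance_dataset()
    labs <- lapply(ds$slices, `[[`, "label")
    ho <- labs[1:40]
    tr <- labs[41:length(labs)]
    vae <- train_label_vae(tr, label_vae_config(widths = c(16, 32),
                                                epochs = 24, seed = 5))
    ldm <- train_label_diffusion(vae, tr,
                                 label_ldm_config(epochs = 140, seed = 7))
    .trained$stack <- list(vae = vae, ldm = ldm, train = tr, holdout = ho)
  }
  .trained$stack
}

# image generator trained on two SD modalities, plus its ablation
trained_image_gans <- function() {
  if (is.null(.trained$gans)) {
    ds <- acceptance_dataset()
    pick <- function(s) { s$images <- s$images[c("T1", "T2")]; s }
    tr <- lapply(ds$subjects[1:36], pick)
    ho <- lapply(ds$subjects[37:44], pick)
    cfg <- image_gan_config(iters = 800, lambda_perc = 3, lambda_cont = 2,
                            lambda_kld = 0.05, seed = 9)
    cfg_ab <- image_gan_config(iters = 800, lambda_perc = 3,
                               lambda_cont = 0, unpaired_style = FALSE,
                               lambda_kld = 0.05, seed = 9)
    .trained$gans <- list(full = train_image_generator(tr, cfg),
                          ablated = train_image_generator(tr, cfg_ab),
                          train = tr, holdout = ho)
  }
  .trained$gans
}

# held-out style codes (slices with enough brain area to carry a style)
holdout_style_codes <- function(gan, holdout, min_area = 0.3) {
  codes <- list(); grp <- character(0)
  for (s in holdout) for (m in names(s$images)) {
    vol <- normalize_image(s$images[[m]])
    for (u in slice_label(s$label)) {
      area <- mean(apply(u$probs, c(2, 3), sum) > 0.5)
      if (area < min_area) next
      codes[[length(codes) + 1]] <-
        encode_style(gan, vol[, , u$slice_index + 1])$mu
      grp <- c(grp, m)
    }
  }
  list(codes = do.call(rbind, codes), groups = grp)
}
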