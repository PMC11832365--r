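# Spatial VAE over probabilistic label maps: compresses (H, W, C) labels
# into a latent grid at 1/4 resolution (two downsamplings) and reconstructs
# them, trained with a five-term loss (KLD + perceptual + adversarial +
# focal reconstruction + noise-robustness).

#' Loss weights for the label VAE
#'
#' Defaults are set so that all terms are within one order of magnitude on
#' phantom batches at initialisation.
#'
#' @param kld,perc,adv,fl,nr non-negative term weights.
#' @param gamma focal focusing parameter (default 0.3).
#' @param nr_mu,nr_sigma mean and sd of the latent perturbation in the
#'   noise-robustness term (defaults 0 and 0.05).
#' @return a `vae_loss_weights` list.
#' @export
vae_loss_weights <- function(kld = 1e-4, perc = 0.02, adv = 0.02, fl = 1,
                             nr = 0.5, gamma = 0.3, nr_mu = 0,
                             nr_sigma = 0.05) {
  w <- list(kld = kld, perc = perc, adv = adv, fl = fl, nr = nr,
            gamma = gamma, nr_mu = nr_mu, nr_sigma = nr_sigma)
  if (any(unlist(w[1:5]) < 0)) stop("loss weights must be non-negative")
  if (gamma < 0) stop("gamma must be positive")
  structure(w, class = "vae_loss_weights")
}

#' Label VAE configuration
#'
#' @param channels label channel count.
#' @param latent_channels latent grid channels (default 3, mirroring a
#'   latent at 1/16 the voxel count of the input after two downsamplings).
#' @param widths encoder widths per downsampling stage.
#' @param weights a [vae_loss_weights()].
#' @param epochs,batch_size,lr training budget.
#' @param seed master training seed.
#' @return a `label_vae_config` list.
#' @export
label_vae_config <- function(channels = 9, latent_channels = 3,
                             widths = c(32, 64), weights = vae_loss_weights(),
                             epochs = 20, batch_size = 16, lr = 2e-3,
                             seed = 1L) {
  structure(list(channels = channels, latent_channels = latent_channels,
                 widths = widths, weights = weights, epochs = epochs,
                 batch_size = batch_size, lr = lr, seed = as.integer(seed)),
            class = "label_vae_config")
}

# parameter construction -----------------------------------------------------

.vae_new_params <- function(cfg) {
  C <- cfg$channels; w1 <- cfg$widths[1]; w2 <- cfg$widths[2]
  cz <- cfg$latent_channels
  list(
    # encoder
    e1w = init_conv_param(3, 3, C, w1),  e1b = init_bias_param(w1),
    e2w = init_conv_param(3, 3, w1, w2), e2b = init_bias_param(w2),
    e3w = init_conv_param(3, 3, w2, w2), e3b = init_bias_param(w2),
    e4w = init_conv_param(3, 3, w2, 2 * cz), e4b = init_bias_param(2 * cz),
    # decoder
    d1w = init_conv_param(3, 3, cz, w2), d1b = init_bias_param(w2),
    d2w = init_conv_param(3, 3, w2, w2), d2b = init_bias_param(w2),
    d3w = init_conv_param(3, 3, w2, w1), d3b = init_bias_param(w1),
    d4w = init_conv_param(3, 3, w1, w1), d4b = init_bias_param(w1),
    d5w = init_conv_param(3, 3, w1, C),  d5b = init_bias_param(C))
}

.vae_encode_node <- function(pp, x) {
  h <- nn_lrelu(nn_conv(x, pp$e1w, pp$e1b, 2L, 1L))
  h <- nn_lrelu(nn_conv(h, pp$e2w, pp$e2b, 2L, 1L))
  h <- nn_lrelu(nn_conv(h, pp$e3w, pp$e3b, 1L, 1L))
  ml <- nn_conv(h, pp$e4w, pp$e4b, 1L, 1L)
  cz <- dim(ml$value)[3] / 2
  list(mu = nn_slice_c(ml, seq_len(cz)),
       logvar = nn_clamp(nn_slice_c(ml, cz + seq_len(cz)), -10, 10))
}

.vae_decode_node <- function(pp, z) {
  h <- nn_lrelu(nn_conv(z, pp$d1w, pp$d1b, 1L, 1L))
  h <- nn_lrelu(nn_conv(h, pp$d2w, pp$d2b, 1L, 1L))
  h <- nn_upsample2(h)
  h <- nn_lrelu(nn_conv(h, pp$d3w, pp$d3b, 1L, 1L))
  h <- nn_upsample2(h)
  h <- nn_lrelu(nn_conv(h, pp$d4w, pp$d4b, 1L, 1L))
  nn_sigmoid(nn_conv(h, pp$d5w, pp$d5b, 1L, 1L))
}

# patch discriminator over label maps (8x8 patch scores on 32x32 input)
.patchdisc_new <- function(C, w = c(32, 64)) {
  list(w1 = init_conv_param(4, 4, C, w[1]),   b1 = init_bias_param(w[1]),
       w2 = init_conv_param(4, 4, w[1], w[2]), b2 = init_bias_param(w[2]),
       w3 = init_conv_param(3, 3, w[2], 1),    b3 = init_bias_param(1))
}

.patchdisc_fwd <- function(pp, x) {
  h1 <- nn_lrelu(nn_conv(x, pp$w1, pp$b1, 2L, 1L))
  h2 <- nn_lrelu(nn_conv(h1, pp$w2, pp$b2, 2L, 1L))
  s <- nn_conv(h2, pp$w3, pp$b3, 1L, 1L)
  list(scores = s, features = list(h1, h2))
}

# batching helpers ------------------------------------------------------------

# list of 2D prob_label_map -> (H, W, C, N) array
labels_to_batch <- function(labels) {
  d <- dim(labels[[1]]$probs)            # (C, H, W)
  out <- array(0, c(d[2], d[3], d[1], length(labels)))
  for (i in seq_along(labels)) out[, , , i] <- aperm(labels[[i]]$probs,
                                                     c(2, 3, 1))
  out
}

batch_to_labels <- function(batch, template = NULL) {
  N <- dim(batch)[4]
  lapply(seq_len(N), function(i) {
    probs <- aperm(array(batch[, , , i], dim(batch)[1:3]), c(3, 1, 2))
    prob_label_map(restore_label_invariants(probs))
  })
}

#' Restore probabilistic label-map invariants on decoded probabilities
#'
#' Voxels whose channel sum exceeds 1 are renormalised; lesion channels are
#' binarised at 0.5 and healthy channels zeroed under lesions.
#'
#' @param probs `(C, ...)` array of decoded probabilities in `[0, 1]`.
#' @return array satisfying the `prob_label_map` invariants.
#' @export
restore_label_invariants <- function(probs) {
  C <- dim(probs)[1]
  pm <- matrix(probs, C)
  li <- match(intersect(LESION_CHANNELS, ALL_CHANNELS[seq_len(C)]),
              ALL_CHANNELS[seq_len(C)])
  hi <- setdiff(seq_len(C), li)
  if (length(li)) {
    les <- pm[li, , drop = FALSE]
    # voxels claimed by several lesion channels keep only the strongest
    # (lesion layers are disjoint by construction)
    win <- max.col(t(les), ties.method = "first")
    bin <- matrix(0, nrow(les), ncol(les))
    bin[cbind(win, seq_len(ncol(les)))] <- (les[cbind(win, seq_len(ncol(les)))] > 0.5) * 1
    pm[li, ] <- bin
    lesany <- colSums(bin) > 0
    pm[hi, lesany] <- 0
  }
  cs <- colSums(pm)
  over <- cs > 1
  if (any(over)) pm[, over] <- sweep(pm[, over, drop = FALSE], 2, cs[over], "/")
  array(pmin(pmax(pm, 0), 1), dim(probs))
}

# encode / decode user surface ------------------------------------------------

#' Encode label maps into the VAE latent grid
#'
#' @param vae a trained [train_label_vae()] model.
#' @param labels a 2D `prob_label_map`, a list of them, or an
#'   `(H, W, C, N)` array.
#' @param sample if `TRUE`, return a reparameterised sample
#'   `z = mu + exp(logvar / 2) * eps`; otherwise `z = mu` (eval mode).
#' @param rng_seed seed for the reparameterisation noise.
#' @return a `latent_grid`: list with `mu`, `logvar`, `z` (all
#'   `(h, w, c_z, N)` arrays) and the downsampling `factor`.
#' @export
encode_labels <- function(vae, labels, sample = FALSE, rng_seed = 1L) {
  x <- if (inherits(labels, "prob_label_map")) labels_to_batch(list(labels))
  else if (is.list(labels)) labels_to_batch(labels)
  else labels
  d <- dim(x)
  if (any(d[1:2] %% 4 != 0))
    stop("spatial dims must be divisible by ", 4,
         " (two downsamplings); pad the input to a multiple of 4")
  enc <- .vae_encode_node(vae$params, nn_const(x))
  mu <- enc$mu$value; logvar <- enc$logvar$value
  z <- if (sample)
    with_seed(rng_seed, mu + exp(logvar / 2) *
                array(stats::rnorm(length(mu)), dim(mu)))
  else mu
  structure(list(mu = mu, logvar = logvar, z = z, factor = 4L),
            class = "latent_grid")
}

#' Decode a latent grid back into probabilistic label maps
#'
#' Decoder outputs pass through a per-channel sigmoid and
#' [restore_label_invariants()], so results always satisfy the
#' `prob_label_map` bounds regardless of the latent.
#'
#' @param vae a trained [train_label_vae()] model.
#' @param z a `latent_grid`, or an `(h, w, c_z, N)` array of latents.
#' @return list of 2D [prob_label_map()] (length N).
#' @export
decode_labels <- function(vae, z) {
  if (inherits(z, "latent_grid")) z <- z$z
  dz <- dim(z)
  if (length(dz) == 3) { dim(z) <- c(dz, 1); dz <- dim(z) }
  want <- vae$config$latent_channels
  if (dz[3] != want)
    stop("latent has ", dz[3], " channels; model expects ", want)
  y <- .vae_decode_node(vae$params, nn_const(z))$value
  batch_to_labels(y)
}

#' Noise-robustness loss
#'
#' Focal loss between a label and the decoding of its latent after additive
#' Gaussian perturbation `N(nr_mu, nr_sigma^2)` (defaults 0 and 0.05);
#' encourages a latent space whose neighbourhoods decode consistently.
#'
#' @param vae trained or in-training model (list with `params`).
#' @param l target `(H, W, C, N)` array or `prob_label_map`.
#' @param z latent array matching the model.
#' @param sigma perturbation sd.
#' @param rng_seed seed.
#' @param mu perturbation mean.
#' @param gamma focal parameter.
#' @return scalar loss.
#' @export
noise_robust_loss <- function(vae, l, z, sigma = 0.05, rng_seed = 1L,
                              mu = 0, gamma = 0.3) {
  stopifnot(sigma >= 0)
  if (inherits(l, "prob_label_map")) l <- labels_to_batch(list(l))
  if (inherits(z, "latent_grid")) z <- z$z
  eps <- with_seed(rng_seed, array(stats::rnorm(length(z), mu, sigma), dim(z)))
  lhat <- .vae_decode_node(vae$params, nn_const(z + eps))
  focal_node(l, lhat, gamma)$value
}

#' Five-term VAE loss with per-term breakdown
#'
#' `kld * KLD + perc * L_perc + adv * L_adv + fl * L_fl + nr * L_nr`; the
#' breakdown always sums to the total.
#'
#' @param vae model list (params + config).
#' @param l `(H, W, C, N)` target batch.
#' @param weights a [vae_loss_weights()].
#' @param feature_extractor perceptual extractor
#'   ([make_feature_extractor()]).
#' @param discriminator patch discriminator params (or `NULL` to skip the
#'   adversarial term).
#' @param rng_seed seed for reparameterisation / noise-robustness draws.
#' @return list with `total` and `breakdown` (named numeric).
#' @export
vae_total_loss <- function(vae, l, weights = vae_loss_weights(),
                           feature_extractor = NULL, discriminator = NULL,
                           rng_seed = 1L) {
  if (inherits(l, "prob_label_map")) l <- labels_to_batch(list(l))
  ln <- nn_const(l)
  enc <- .vae_encode_node(vae$params, ln)
  eps <- with_seed(rng_seed,
                   array(stats::rnorm(length(enc$mu$value)), dim(enc$mu$value)))
  z <- nn_add(enc$mu, nn_mul(nn_exp(nn_mulc(enc$logvar, 0.5)), nn_const(eps)))
  lhat <- .vae_decode_node(vae$params, z)
  br <- c(kld = weights$kld * kld_node(enc$mu, enc$logvar,
                                       batch_dim = 4)$value,
          perc = if (weights$perc > 0 && !is.null(feature_extractor))
            weights$perc * l1_features_node(feature_extractor(ln),
                                            feature_extractor(lhat))$value
          else 0,
          adv = if (weights$adv > 0 && !is.null(discriminator))
            weights$adv * hinge_node(NULL,
                                     .patchdisc_fwd(discriminator, lhat)$scores,
                                     "generator")$value
          else 0,
          fl = weights$fl * focal_node(l, lhat, weights$gamma)$value,
          nr = weights$nr * noise_robust_loss(vae, l, z$value,
                                              weights$nr_sigma,
                                              derive_seed(rng_seed, 17),
                                              weights$nr_mu, weights$gamma))
  list(total = sum(br), breakdown = br)
}

# ----------------------------------------------------------------------------

#' Train the label S-VAE
#'
#' Seeded alternating VAE/patch-discriminator training with the five-term
#' loss. Runs are bit-reproducible under a fixed seed.
#'
#' @param dataset list of 2D [prob_label_map()], or a `phantom_dataset`
#'   (its 2D slices are used).
#' @param config a [label_vae_config()].
#' @param verbose print per-epoch losses.
#' @return an object of class `label_vae`: parameters, config, loss
#'   `history`, and the latent scale (`latent_sd`) estimated on the training
#'   set for downstream diffusion.
#' @export
train_label_vae <- function(dataset, config = label_vae_config(),
                            verbose = FALSE) {
  labels <- if (inherits(dataset, "phantom_dataset"))
    lapply(dataset$slices, `[[`, "label") else dataset
  if (length(labels) == 0) stop("empty dataset")
  x_all <- labels_to_batch(labels)
  N <- dim(x_all)[4]
  w <- config$weights
  model <- with_seed(config$seed, {
    list(params = .vae_new_params(config), config = config)
  })
  disc <- with_seed(derive_seed(config$seed, 1),
                    .patchdisc_new(config$channels))
  fext <- make_feature_extractor(config$channels,
                                 seed = derive_seed(config$seed, 2))
  g_params <- model$params
  opt_g <- adam_new(g_params, lr = config$lr)
  opt_d <- adam_new(disc, lr = config$lr)
  hist_rows <- list()
  set.seed(derive_seed(config$seed, 3))
  nb <- ceiling(N / config$batch_size)
  for (ep in seq_len(config$epochs)) {
    # step-decay: late epochs fine-tune channel calibration at low rate
    fac <- if (ep > 0.85 * config$epochs) 0.25
           else if (ep > 0.6 * config$epochs) 0.5 else 1
    opt_g$lr <- config$lr * fac
    opt_d$lr <- config$lr * fac
    ord <- sample.int(N)
    ep_loss <- c(total = 0, kld = 0, perc = 0, adv = 0, fl = 0, nr = 0,
                 d = 0)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, N)]
      x <- array(x_all[, , , idx, drop = FALSE],
                 c(dim(x_all)[1:3], length(idx)))
      ln <- nn_const(x)
      enc <- .vae_encode_node(g_params, ln)
      epsz <- array(stats::rnorm(length(enc$mu$value)), dim(enc$mu$value))
      z <- nn_add(enc$mu, nn_mul(nn_exp(nn_mulc(enc$logvar, 0.5)),
                                 nn_const(epsz)))
      lhat <- .vae_decode_node(g_params, z)
      terms <- list(
        kld = nn_mulc(kld_node(enc$mu, enc$logvar, batch_dim = 4), w$kld),
        fl = nn_mulc(focal_node(x, lhat, w$gamma), w$fl))
      if (w$perc > 0)
        terms$perc <- nn_mulc(l1_features_node(fext(ln), fext(lhat)), w$perc)
      if (w$adv > 0)
        terms$adv <- nn_mulc(hinge_node(NULL, .patchdisc_fwd(disc, lhat)$scores,
                                        "generator"), w$adv)
      if (w$nr > 0 && b %% 2 == 1) {
        # evaluated on alternate batches at doubled weight: an unbiased
        # stochastic estimate of the term at half its decoder cost
        noise <- array(stats::rnorm(length(z$value), w$nr_mu, w$nr_sigma),
                       dim(z$value))
        lhat_nr <- .vae_decode_node(g_params, nn_add(z, nn_const(noise)))
        terms$nr <- nn_mulc(focal_node(x, lhat_nr, w$gamma), 2 * w$nr)
      }
      loss <- Reduce(nn_add, terms)
      if (!is.finite(loss$value))
        stop("label VAE training diverged (non-finite loss) at epoch ", ep)
      adam_zero_grad(opt_g)
      nn_backward(loss)
      adam_step(opt_g)
      # discriminator update on detached reconstruction
      if (w$adv > 0) {
        dl <- hinge_node(.patchdisc_fwd(disc, ln)$scores,
                         .patchdisc_fwd(disc, nn_detach(lhat))$scores,
                         "discriminator")
        adam_zero_grad(opt_d)
        nn_backward(dl)
        adam_step(opt_d)
        ep_loss["d"] <- ep_loss["d"] + dl$value
      }
      for (nm in names(terms))
        ep_loss[nm] <- ep_loss[nm] + terms[[nm]]$value
      ep_loss["total"] <- ep_loss["total"] + loss$value
    }
    hist_rows[[ep]] <- as.data.frame(as.list(c(epoch = ep, ep_loss / nb)))
    if (verbose)
      message(sprintf("epoch %d: total=%.4f fl=%.4f", ep,
                      ep_loss["total"] / nb, ep_loss["fl"] / nb))
  }
  history <- do.call(rbind, hist_rows)
  out <- list(params = g_params, discriminator = disc, config = config,
              history = history, channels = config$channels,
              frozen = TRUE)
  class(out) <- "label_vae"
  # latent scale for downstream diffusion (global sd of mu over training set)
  mus <- encode_labels(out, x_all)$mu
  out$latent_sd <- stats::sd(as.numeric(mus))
  out
}

#' @export
print.label_vae <- function(x, ...) {
  cat("label_vae:", x$config$channels, "channels, latent",
      x$config$latent_channels, "ch @ 1/4 resolution;",
      nrow(x$history), "epochs trained\n")
  if (nrow(x$history))
    cat(sprintf("  final loss %.4f (focal %.4f)\n",
                utils::tail(x$history$total, 1),
                utils::tail(x$history$fl, 1)))
  invisible(x)
}

#' Reconstruct label maps through the trained VAE
#'
#' @param object a `label_vae`.
#' @param newdata list of 2D `prob_label_map` or an `(H, W, C, N)` array.
#' @param type `"reconstruct"` for decoded label maps, `"latent"` for the
#'   latent grid.
#' @param ... unused.
#' @return list of reconstructed [prob_label_map()] or a `latent_grid`.
#' @export
predict.label_vae <- function(object, newdata, type = c("reconstruct",
                                                        "latent"), ...) {
  type <- match.arg(type)
  lg <- encode_labels(object, newdata)
  if (type == "latent") lg else decode_labels(object, lg)
}

#' Mean per-channel absolute reconstruction error
#'
#' @param vae a `label_vae`.
#' @param labels held-out list of 2D `prob_label_map`.
#' @return scalar mean absolute error across voxels and channels.
#' @export
reconstruction_mae <- function(vae, labels) {
  x <- labels_to_batch(labels)
  rec <- predict(vae, labels)
  y <- labels_to_batch(rec)
  mean(abs(x - y))
}
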