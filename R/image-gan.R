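# Semantic image synthesis VAE-GAN: a style encoder compresses an intensity
# image into a 16-dimensional style code; a decoder driven by the semantic
# label map through spatially-adaptive (SPADE) normalisation renders an
# image in that style. Trained adversarially with hinge loss, feature
# matching, perceptual and contrastive style losses, gated by an
# accuracy-window adversarial scheduler.

#' Image generator configuration
#'
#' @param style_dim style code length (default 16).
#' @param n_scales number of discriminator scales (default 2).
#' @param base_width decoder width at the coarsest resolution.
#' @param lambda_kld,lambda_perc,lambda_feat,lambda_cont loss weights.
#' @param lambda_mod,lambda_dat modality/dataset discrimination weights;
#'   disabled (0) by default — inter-slice consistency gains come from the
#'   contrastive loss and unpaired styles, so these auxiliary terms are off
#'   unless a classifier is supplied.
#' @param unpaired_style draw the style image from a different slice of the
#'   same volume (`TRUE`; set `FALSE` only for ablation).
#' @param t_up,t_down,window adversarial scheduler thresholds and window.
#' @param iters,batch_size,lr training budget (iterations of G/D updates);
#'   `lr` is the generator rate.
#' @param lr_d discriminator learning rate; a faster discriminator keeps the
#'   scheduler in the band where both networks train.
#' @param seed master seed.
#' @return an `image_gan_config` list.
#' @export
image_gan_config <- function(style_dim = 16, n_scales = 2, base_width = 48,
                             lambda_kld = 0.005, lambda_perc = 2,
                             lambda_feat = 2, lambda_cont = 1,
                             lambda_mod = 0, lambda_dat = 0,
                             unpaired_style = TRUE,
                             t_up = 0.75, t_down = 0.6, window = 20,
                             iters = 600, batch_size = 8, lr = 5e-4,
                             lr_d = 2e-3, seed = 1L) {
  structure(list(style_dim = style_dim, n_scales = n_scales,
                 base_width = base_width, lambda_kld = lambda_kld,
                 lambda_perc = lambda_perc, lambda_feat = lambda_feat,
                 lambda_cont = lambda_cont, lambda_mod = lambda_mod,
                 lambda_dat = lambda_dat, unpaired_style = unpaired_style,
                 t_up = t_up, t_down = t_down, window = window,
                 iters = iters, batch_size = batch_size, lr = lr,
                 lr_d = lr_d, seed = as.integer(seed)),
            class = "image_gan_config")
}

# ---- parameters -------------------------------------------------------------

.stylenc_new <- function(style_dim) {
  list(w1 = init_conv_param(3, 3, 1, 12),  b1 = init_bias_param(12),
       w2 = init_conv_param(3, 3, 12, 24), b2 = init_bias_param(24),
       w3 = init_conv_param(3, 3, 24, 32), b3 = init_bias_param(32),
       f1 = init_dense_param(4 * 4 * 32, 64), f1b = init_bias_param(64),
       f2 = init_dense_param(64, 2 * style_dim),
       f2b = init_bias_param(2 * style_dim))
}

.stylenc_fwd <- function(pp, x) {
  h <- nn_lrelu(nn_conv(x, pp$w1, pp$b1, 2L, 1L))
  h <- nn_lrelu(nn_conv(h, pp$w2, pp$b2, 2L, 1L))
  h <- nn_lrelu(nn_conv(h, pp$w3, pp$b3, 2L, 1L))
  h <- nn_lrelu(nn_dense(nn_flatten(h), pp$f1, pp$f1b))
  ml <- nn_dense(h, pp$f2, pp$f2b)
  sd2 <- ncol(ml$value) / 2
  list(mu = nn_node(ml$value[, seq_len(sd2), drop = FALSE], list(ml),
                    function(g) {
                      gg <- ml$value * 0; gg[, seq_len(sd2)] <- g; list(gg)
                    }),
       logvar = nn_node(pmin(pmax(ml$value[, sd2 + seq_len(sd2), drop = FALSE],
                                  -10), 10), list(ml),
                        function(g) {
                          v <- ml$value[, sd2 + seq_len(sd2), drop = FALSE]
                          gg <- ml$value * 0
                          gg[, sd2 + seq_len(sd2)] <- g * (v >= -10 & v <= 10)
                          list(gg)
                        }))
}

.spade_new <- function(c_lab, c_in, c_out, style_dim, hid = 16) {
  list(sh = init_conv_param(3, 3, c_lab, hid), shb = init_bias_param(hid),
       sg = init_conv_param(3, 3, hid, c_in), sgb = init_bias_param(c_in),
       sb = init_conv_param(3, 3, hid, c_in), sbb = init_bias_param(c_in),
       fg = init_dense_param(style_dim, c_in), fgb = init_bias_param(c_in),
       fb = init_dense_param(style_dim, c_in), fbb = init_bias_param(c_in),
       cw = init_conv_param(3, 3, c_in, c_out), cb = init_bias_param(c_out))
}

# h: (r,r,c_in,N); m: label map at matching resolution; s: (N, style_dim).
# The semantic map supplies the per-pixel scale/shift (SPADE); the style
# code additionally modulates each channel globally, so contrast
# information survives the normalisation at every resolution.
.spade_fwd <- function(pp, h, m, s) {
  hid <- nn_lrelu(nn_conv(m, pp$sh, pp$shb, 1L, 1L))
  gam <- nn_conv(hid, pp$sg, pp$sgb, 1L, 1L)
  bet <- nn_conv(hid, pp$sb, pp$sbb, 1L, 1L)
  hn <- nn_instnorm(h)
  out <- nn_add(nn_mul(hn, nn_addc(gam, 1)), bet)
  sg <- nn_dense(s, pp$fg, pp$fgb)
  sb <- nn_dense(s, pp$fb, pp$fbb)
  out <- nn_add_nc(nn_mul_nc(out, nn_addc(sg, 1)), sb)
  nn_lrelu(nn_conv(nn_lrelu(out), pp$cw, pp$cb, 1L, 1L))
}

.decoder_new <- function(style_dim, c_lab, w0) {
  ws <- c(w0, round(w0 * 2 / 3), round(w0 / 2), round(w0 / 3))
  list(fc = init_dense_param(style_dim, 4 * 4 * w0),
       fcb = init_bias_param(4 * 4 * w0),
       s1 = .spade_new(c_lab, ws[1], ws[1], style_dim),
       s2 = .spade_new(c_lab, ws[1], ws[2], style_dim),
       s3 = .spade_new(c_lab, ws[2], ws[3], style_dim),
       s4 = .spade_new(c_lab, ws[3], ws[4], style_dim),
       ow = init_conv_param(3, 3, ws[4], 1), ob = init_bias_param(1),
       widths = ws)
}

.decoder_fwd <- function(pp, m, s) {
  # m: (32,32,C,N) label node; s: (N, style_dim) node
  m16 <- nn_avgpool2(m); m8 <- nn_avgpool2(m16); m4 <- nn_avgpool2(m8)
  h <- nn_unflatten(nn_dense(s, pp$fc, pp$fcb), c(4, 4, pp$widths[1]))
  h <- .spade_fwd(pp$s1, h, m4, s)
  h <- nn_upsample2(h)
  h <- .spade_fwd(pp$s2, h, m8, s)
  h <- nn_upsample2(h)
  h <- .spade_fwd(pp$s3, h, m16, s)
  h <- nn_upsample2(h)
  h <- .spade_fwd(pp$s4, h, m, s)
  nn_sigmoid(nn_conv(h, pp$ow, pp$ob, 1L, 1L))
}

.disc_scale_new <- function(c_in) {
  list(w1 = init_conv_param(4, 4, c_in, 24), b1 = init_bias_param(24),
       w2 = init_conv_param(4, 4, 24, 48),   b2 = init_bias_param(48),
       w3 = init_conv_param(3, 3, 48, 1),    b3 = init_bias_param(1))
}

.disc_scale_fwd <- function(pp, x) {
  h1 <- nn_lrelu(nn_conv(x, pp$w1, pp$b1, 2L, 1L))
  h2 <- nn_lrelu(nn_conv(h1, pp$w2, pp$b2, 2L, 1L))
  list(scores = nn_conv(h2, pp$w3, pp$b3, 1L, 1L), features = list(h1, h2))
}

# multi-scale: x full resolution input node; returns per-scale lists
.msdisc_fwd <- function(disc, x) {
  out <- list()
  for (j in seq_along(disc)) {
    out[[j]] <- .disc_scale_fwd(disc[[j]], x)
    if (j < length(disc)) x <- nn_avgpool2(x)
  }
  list(scores = lapply(out, `[[`, "scores"),
       features = lapply(out, `[[`, "features"))
}

# ---- user-facing building blocks -------------------------------------------

#' Assemble the discriminator input stack
#'
#' Channel concatenation `[image | label channels | broadcast one-hot
#' modality]`, in that fixed order; the modality encoding is broadcast as
#' constant spatial planes.
#'
#' @param image `(H, W)` or `(H, W, 1, N)` intensity array.
#' @param m 2D [prob_label_map()] or `(H, W, C, N)` label array.
#' @param modality_onehot numeric vector (length = number of modalities) or
#'   `(N, n_mod)` matrix.
#' @return `(H, W, 1 + C + n_mod, N)` array.
#' @export
discriminator_input <- function(image, m, modality_onehot) {
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1, 1))
  if (inherits(m, "prob_label_map")) m <- labels_to_batch(list(m))
  if (is.null(dim(modality_onehot)))
    modality_onehot <- matrix(modality_onehot, nrow = dim(image)[4],
                              ncol = length(modality_onehot), byrow = TRUE)
  d <- dim(image)
  nmod <- ncol(modality_onehot)
  out <- array(0, c(d[1], d[2], 1 + dim(m)[3] + nmod, d[4]))
  out[, , 1, ] <- image
  out[, , 1 + seq_len(dim(m)[3]), ] <- m
  for (k in seq_len(nmod))
    for (n in seq_len(d[4]))
      out[, , 1 + dim(m)[3] + k, n] <- modality_onehot[n, k]
  out
}

#' Random affine augmentation of a 2D image
#'
#' Contrast-preserving, geometry-perturbing transform used for the
#' contrastive style pair: rotation up to 10 degrees, translation up to 5%
#' of the image size, isotropic scaling in `[0.95, 1.05]`; bilinear
#' resampling with edge clamping.
#'
#' @param img 2D array.
#' @param rng_seed integer seed.
#' @param max_rot_deg,max_trans_frac,scale_range transform ranges.
#' @return transformed array of the same shape.
#' @export
affine_augment <- function(img, rng_seed = 1L, max_rot_deg = 10,
                           max_trans_frac = 0.05,
                           scale_range = c(0.95, 1.05)) {
  d <- dim(img)
  with_seed(rng_seed, {
    th <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
    sc <- stats::runif(1, scale_range[1], scale_range[2])
    tx <- stats::runif(1, -max_trans_frac, max_trans_frac) * d[1]
    ty <- stats::runif(1, -max_trans_frac, max_trans_frac) * d[2]
    ctr <- (d + 1) / 2
    gr <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
    # inverse map: output pixel -> source coordinates
    xr <- (gr$r - ctr[1]); yc <- (gr$c - ctr[2])
    sx <- (cos(th) * xr + sin(th) * yc) / sc + ctr[1] - tx
    sy <- (-sin(th) * xr + cos(th) * yc) / sc + ctr[2] - ty
    sx <- pmin(pmax(sx, 1), d[1]); sy <- pmin(pmax(sy, 1), d[2])
    x0 <- floor(sx); y0 <- floor(sy)
    x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2])
    fx <- sx - x0; fy <- sy - y0
    v <- img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
      img[cbind(x1, y0)] * fx * (1 - fy) +
      img[cbind(x0, y1)] * (1 - fx) * fy +
      img[cbind(x1, y1)] * fx * fy
    array(v, d)
  })
}

#' Contrastive style loss
#'
#' `1 - cosine_similarity(E(i), E(augment(i)))`: the style codes of an image
#' and a random affine-augmented version of it should agree (the
#' augmentation changes geometry, not contrast).
#'
#' @param encoder function mapping a 2D image to a style-code vector (e.g.
#'   built from a trained generator), or an `image_gan` object.
#' @param i 2D intensity image.
#' @param augmenter augmentation function `(img, rng_seed) -> img`
#'   (default [affine_augment()]).
#' @param rng_seed seed passed to the augmenter.
#' @return scalar loss in `[0, 2]`.
#' @export
contrastive_style_loss <- function(encoder, i, augmenter = affine_augment,
                                   rng_seed = 1L) {
  enc <- if (inherits(encoder, "image_gan"))
    function(img) encode_style(encoder, img)$mu else encoder
  a <- as.numeric(enc(i))
  b <- as.numeric(enc(augmenter(i, rng_seed)))
  if (sum(a^2) == 0 || sum(b^2) == 0) stop("zero-norm style code")
  1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Modality and dataset discrimination loss
#'
#' `lambda_mod * BCE(m, m_hat) + lambda_dat * BCE(d, d_hat)` where the hats
#' are an auxiliary classifier's predictions on a generated image. Disabled
#' by default in training (weights 0): in ablation the contrastive loss and
#' unpaired styles carried the consistency gains, so these terms are kept
#' available but off.
#'
#' @param classifier function mapping a 2D image to
#'   `list(modality = probs, dataset = probs)`.
#' @param i_tilde generated 2D image.
#' @param true_modality,true_dataset one-hot (or probability) vectors.
#' @param lambda_mod,lambda_dat weights.
#' @return scalar loss.
#' @export
modality_dataset_disc_loss <- function(classifier, i_tilde, true_modality,
                                       true_dataset, lambda_mod = 1,
                                       lambda_dat = 1) {
  if (lambda_mod == 0 && lambda_dat == 0) return(0)
  if (is.null(classifier))
    stop("modality/dataset loss enabled but no classifier supplied")
  pr <- classifier(i_tilde)
  lambda_mod * bce_loss(true_modality, pr$modality) +
    lambda_dat * bce_loss(true_dataset, pr$dataset)
}

#' Adversarial scheduler state
#'
#' Rolling window (length 20) of discriminator accuracies with thresholds
#' `T_up = 0.75` and `T_down = 0.6`.
#'
#' @param window window length.
#' @param t_up,t_down thresholds (must satisfy `t_down < t_up`).
#' @return a `scheduler_state` list.
#' @export
scheduler_state <- function(window = 20, t_up = 0.75, t_down = 0.6) {
  stopifnot(t_down < t_up, window >= 1)
  structure(list(acc = numeric(0), window = window, t_up = t_up,
                 t_down = t_down), class = "scheduler_state")
}

#' Adversarial scheduler step
#'
#' Appends the new discriminator accuracy to the rolling window and decides
#' which networks train: mean accuracy strictly above `t_up` trains only the
#' generator, strictly below `t_down` only the discriminator, otherwise
#' both (boundary values train both). A window shorter than its capacity
#' uses the available entries.
#'
#' @param state a [scheduler_state()].
#' @param new_d_accuracy discriminator accuracy in `[0, 1]`.
#' @return list with `train_G`, `train_D`, updated `state`, and the window
#'   `mean_acc`.
#' @export
scheduler_step <- function(state, new_d_accuracy) {
  if (new_d_accuracy < 0 || new_d_accuracy > 1)
    stop("accuracy must lie in [0, 1]")
  acc <- c(state$acc, new_d_accuracy)
  if (length(acc) > state$window)
    acc <- acc[(length(acc) - state$window + 1):length(acc)]
  state$acc <- acc
  m <- mean(acc)
  list(train_G = !(m < state$t_down), train_D = !(m > state$t_up),
       state = state, mean_acc = m)
}

#' Build a training triplet from a volume
#'
#' Draws a (label slice, paired image slice) and a style image from a
#' *different* slice of the same volume and modality, enforcing the
#' separation of content and style pathways. Single-slice volumes reuse the
#' same slice with a warning.
#'
#' @param volume_images `(H, W, D)` intensity array.
#' @param volume_label 3D [prob_label_map()].
#' @param rng_seed integer seed.
#' @param usable_idx optional integer axial indices (1-based) to draw from.
#' @return a `training_triplet`: list `m` (2D label), `i`, `i_s`,
#'   `slice_index`, `style_index`.
#' @export
make_training_triplet <- function(volume_images, volume_label, rng_seed = 1L,
                                  usable_idx = NULL) {
  if (is.null(usable_idx)) {
    sl <- slice_label(volume_label)
    usable_idx <- vapply(sl, function(s) s$slice_index + 1L, 0L)
  }
  with_seed(rng_seed, {
    zi <- usable_idx[sample.int(length(usable_idx), 1)]
    if (length(usable_idx) > 1) {
      zs <- sample(setdiff(usable_idx, zi), 1)
    } else {
      warning("single-slice volume: style image equals content image")
      zs <- zi
    }
    p3 <- volume_label$probs
    m <- prob_label_map(array(p3[, , , zi], dim(p3)[1:3]),
                        volume_label$channel_names,
                        volume_label$voxel_size_mm, volume_label$subject_id,
                        volume_label$dataset_tag, slice_index = zi - 1L)
    structure(list(m = m, i = volume_images[, , zi],
                   i_s = volume_images[, , zs],
                   slice_index = zi - 1L, style_index = zs - 1L),
              class = "training_triplet")
  })
}

#' Percentile-normalise an intensity image
#'
#' Clips to the 1st/99th percentile range and rescales to `[0, 1]`.
#'
#' @param img intensity array.
#' @param probs lower/upper clipping percentiles.
#' @return normalised array.
#' @export
normalize_image <- function(img, probs = c(0.01, 0.99)) {
  q <- stats::quantile(img, probs, names = FALSE)
  if (q[2] <= q[1]) return(img * 0)
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

# discriminator accuracy under the hinge convention: fraction of patches on
# the correct side of 0, averaged over patches and scales
.disc_accuracy <- function(scores_real, scores_fake) {
  accs <- mapply(function(r, f) {
    (mean(r$value > 0) + mean(f$value < 0)) / 2
  }, scores_real, scores_fake)
  mean(accs)
}

# ---- training ---------------------------------------------------------------

#' Train the semantic image generator
#'
#' Alternating VAE-GAN training on (label slice, image, unpaired style
#' image) triplets drawn from the dataset volumes. Generator loss: hinge GAN
#' + KLD on the style posterior + perceptual + discriminator feature
#' matching + contrastive style loss (+ optional modality/dataset
#' discrimination). Generator/discriminator updates are gated by the
#' accuracy-window scheduler.
#'
#' @param dataset a `phantom_dataset` with 3D subjects, or a list of
#'   subjects shaped like its `$subjects` entries.
#' @param config an [image_gan_config()].
#' @param classifier optional auxiliary modality/dataset classifier
#'   (required if `lambda_mod` or `lambda_dat` is nonzero).
#' @param verbose print progress.
#' @return an object of class `image_gan` with encoder/decoder/discriminator
#'   parameters, config, modality table and training history.
#' @export
train_image_generator <- function(dataset, config = image_gan_config(),
                                  classifier = NULL, verbose = FALSE) {
  subjects <- if (inherits(dataset, "phantom_dataset")) dataset$subjects
              else dataset
  if (length(subjects) == 0) stop("empty dataset")
  modalities <- names(subjects[[1]]$images)
  nmod <- length(modalities)
  c_lab <- dim(subjects[[1]]$label$probs)[1]
  if ((config$lambda_mod > 0 || config$lambda_dat > 0) && is.null(classifier))
    stop("modality/dataset loss enabled but no classifier supplied")
  # per-volume percentile normalisation (per modality); per-slice
  # normalisation would rescale contrast by slice content and blur the
  # modality signal the style code must carry
  subjects <- lapply(subjects, function(s) {
    s$images <- lapply(s$images, normalize_image)
    s
  })
  # usable slices per subject
  usable <- lapply(subjects, function(s) {
    sl <- slice_label(s$label)
    vapply(sl, function(x) x$slice_index + 1L, 0L)
  })
  pars <- with_seed(config$seed, list(
    enc = .stylenc_new(config$style_dim),
    dec = .decoder_new(config$style_dim, c_lab, config$base_width),
    disc = lapply(seq_len(config$n_scales), function(j)
      .disc_scale_new(1 + c_lab + nmod))))
  gp <- c(.flatten_params(pars$enc), .flatten_params(pars$dec))
  dp <- unlist(lapply(pars$disc, .flatten_params), recursive = FALSE)
  opt_g <- adam_new(gp, lr = config$lr)
  opt_d <- adam_new(dp, lr = config$lr_d %||% config$lr)
  fext <- make_feature_extractor(1, widths = c(12, 24),
                                 seed = derive_seed(config$seed, 2),
                                 include_input = TRUE)
  sched <- scheduler_state(config$window, config$t_up, config$t_down)
  set.seed(derive_seed(config$seed, 3))
  hist <- list(g = numeric(0), d = numeric(0), acc = numeric(0),
               g_on = logical(0), d_on = logical(0))
  for (it in seq_len(config$iters)) {
    if (it == ceiling(0.7 * config$iters)) {
      opt_g$lr <- opt_g$lr * 0.5
      opt_d$lr <- opt_d$lr * 0.5
    }
    bs <- config$batch_size
    si <- sample.int(length(subjects), bs, replace = TRUE)
    mi <- sample.int(nmod, bs, replace = TRUE)
    ms <- array(0, c(dim(subjects[[1]]$label$probs)[2:3], c_lab, bs))
    ii <- array(0, c(dim(ms)[1:2], 1, bs))
    is_ <- array(0, c(dim(ms)[1:2], 1, bs))
    onehot <- matrix(0, bs, nmod)
    for (k in seq_len(bs)) {
      sub <- subjects[[si[k]]]
      tri <- make_training_triplet(sub$images[[mi[k]]], sub$label,
                                   rng_seed = sample.int(1e7, 1),
                                   usable_idx = usable[[si[k]]])
      if (!config$unpaired_style) tri$i_s <- tri$i
      ms[, , , k] <- aperm(tri$m$probs, c(2, 3, 1))
      ii[, , 1, k] <- tri$i
      is_[, , 1, k] <- tri$i_s
      onehot[k, mi[k]] <- 1
    }
    mnode <- nn_const(ms)
    # ---- forward G
    st <- .stylenc_fwd(pars$enc, nn_const(is_))
    epss <- matrix(stats::rnorm(length(st$mu$value)), nrow(st$mu$value))
    s <- nn_add(st$mu, nn_mul(nn_exp(nn_mulc(st$logvar, 0.5)),
                              nn_const(epss)))
    fake <- .decoder_fwd(pars$dec, mnode, s)
    din_real <- nn_const(discriminator_input(ii, ms, onehot))
    din_fake_g <- .disc_cat(fake, ms, onehot)
    dr <- .msdisc_fwd(pars$disc, din_real)
    df <- .msdisc_fwd(pars$disc, din_fake_g)
    acc <- .disc_accuracy(dr$scores, df$scores)
    dec <- scheduler_step(sched, acc)
    sched <- dec$state
    g_loss_val <- NA_real_
    if (dec$train_G) {
      terms <- list(hinge_node(NULL, df$scores, "generator"),
                    nn_mulc(kld_node(st$mu, st$logvar, batch_dim = 1),
                            config$lambda_kld))
      if (config$lambda_perc > 0)
        terms <- c(terms, list(nn_mulc(l1_features_node(
          fext(nn_const(ii)), fext(fake)), config$lambda_perc)))
      if (config$lambda_feat > 0) {
        fr <- lapply(dr$features, function(fs) lapply(fs, nn_detach))
        terms <- c(terms, list(nn_mulc(l1_features_node(
          unlist(fr, recursive = FALSE),
          unlist(df$features, recursive = FALSE)), config$lambda_feat)))
      }
      if (config$lambda_cont > 0) {
        aug <- array(0, dim(is_))
        for (k in seq_len(bs))
          aug[, , 1, k] <- affine_augment(array(is_[, , 1, k], dim(is_)[1:2]),
                                          sample.int(1e7, 1))
        sa <- .stylenc_fwd(pars$enc, nn_const(aug))
        cs <- .batch_cosine_node(st$mu, sa$mu)
        terms <- c(terms, list(nn_mulc(nn_addc(nn_neg(cs), 1),
                                       config$lambda_cont)))
        if (config$unpaired_style) {
          # same contrast, different slice: codes of the style image and the
          # paired ground-truth slice must also agree
          si_ <- .stylenc_fwd(pars$enc, nn_const(ii))
          cs2 <- .batch_cosine_node(st$mu, si_$mu)
          terms <- c(terms, list(nn_mulc(nn_addc(nn_neg(cs2), 1),
                                         config$lambda_cont)))
        }
      }
      if (config$lambda_mod > 0 || config$lambda_dat > 0) {
        md <- mean(vapply(seq_len(bs), function(k)
          modality_dataset_disc_loss(classifier,
                                     array(fake$value[, , 1, k],
                                           dim(fake$value)[1:2]),
                                     onehot[k, ], 1,
                                     config$lambda_mod, config$lambda_dat),
          numeric(1)))
        # the pluggable classifier is a black-box function, so this term
        # enters the reported total without a gradient path
        terms <- c(terms, list(nn_const(md)))
      }
      g_loss <- Reduce(nn_add, terms)
      if (!is.finite(g_loss$value))
        stop("image generator training diverged at iteration ", it)
      adam_zero_grad(opt_g)
      nn_backward(g_loss)
      adam_step(opt_g)
      g_loss_val <- g_loss$value
    }
    d_loss_val <- NA_real_
    if (dec$train_D) {
      din_fake_d <- nn_const(discriminator_input(fake$value, ms, onehot))
      dr2 <- .msdisc_fwd(pars$disc, din_real)
      df2 <- .msdisc_fwd(pars$disc, din_fake_d)
      d_loss <- hinge_node(dr2$scores, df2$scores, "discriminator")
      adam_zero_grad(opt_d)
      nn_backward(d_loss)
      adam_step(opt_d)
      d_loss_val <- d_loss$value
    }
    hist$g <- c(hist$g, g_loss_val); hist$d <- c(hist$d, d_loss_val)
    hist$acc <- c(hist$acc, acc)
    hist$g_on <- c(hist$g_on, dec$train_G)
    hist$d_on <- c(hist$d_on, dec$train_D)
    if (verbose && it %% 50 == 0)
      message(sprintf("iter %d: G %.3f D %.3f acc %.2f", it,
                      g_loss_val, d_loss_val, mean(dec$mean_acc)))
  }
  out <- list(params = pars, config = config, modalities = modalities,
              history = hist, image_shape = dim(subjects[[1]]$label$probs)[2:3])
  class(out) <- "image_gan"
  out
}

.flatten_params <- function(x) {
  out <- list()
  for (nm in names(x)) {
    if (inherits(x[[nm]], "nn_node")) out[[length(out) + 1]] <- x[[nm]]
    else if (is.list(x[[nm]])) out <- c(out, .flatten_params(x[[nm]]))
  }
  out
}

# concat fake image node with const label/modality planes, keeping gradients
.disc_cat <- function(fake, ms, onehot) {
  d <- dim(ms)
  nmod <- ncol(onehot)
  planes <- array(0, c(d[1], d[2], nmod, d[4]))
  for (k in seq_len(nmod))
    for (n in seq_len(d[4])) planes[, , k, n] <- onehot[n, k]
  nn_concat_c(list(fake, nn_const(ms), nn_const(planes)))
}

# mean cosine similarity over batch rows of two (N,F) nodes
.batch_cosine_node <- function(a, b) {
  eps <- 1e-8
  num <- nn_matmul_rowsum(a, b)
  na <- nn_sqrt(nn_addc(nn_rowsum_sq(a), eps))
  nb <- nn_sqrt(nn_addc(nn_rowsum_sq(b), eps))
  nn_mean(nn_mul(num, nn_pow(nn_mul(na, nb), -1)))
}

# rowwise dot product of (N,F) nodes -> (N) vector node
nn_matmul_rowsum <- function(a, b) {
  av <- a$value; bv <- b$value
  nn_node(rowSums(av * bv), list(a, b),
          function(g) list(av * 0 + g * bv, bv * 0 + g * av))
}

nn_rowsum_sq <- function(a) {
  av <- a$value
  nn_node(rowSums(av^2), list(a), function(g) list(2 * av * g))
}

#' @export
print.image_gan <- function(x, ...) {
  cat("image_gan:", paste(x$image_shape, collapse = "x"), "images,",
      x$config$style_dim, "dim style,", x$config$n_scales,
      "discriminator scales;", length(x$history$acc), "iterations\n")
  if (length(x$history$acc))
    cat(sprintf("  final D accuracy %.2f; G-only %.0f%%, D-only %.0f%% of iters\n",
                mean(utils::tail(x$history$acc, 20)),
                100 * mean(x$history$g_on & !x$history$d_on),
                100 * mean(x$history$d_on & !x$history$g_on)))
  invisible(x)
}

#' Encode an image into a style code
#'
#' @param gan a trained [train_image_generator()] model.
#' @param image 2D intensity array (model resolution). Supply slices on the
#'   same intensity convention the model was trained with (per-volume
#'   percentile normalisation); set `normalize = TRUE` to apply a per-image
#'   normalisation instead.
#' @param sample reparameterised sample (`TRUE`) or posterior mean (eval
#'   mode, default).
#' @param rng_seed seed when sampling.
#' @param normalize apply per-image percentile normalisation first.
#' @param modality,dataset_tag optional source tags carried on the code.
#' @return a `style_code`: list with `s`, `mu`, `logvar`, tags.
#' @export
encode_style <- function(gan, image, sample = FALSE, rng_seed = 1L,
                         normalize = FALSE, modality = NA_character_,
                         dataset_tag = NA_character_) {
  if (!identical(dim(image), as.integer(gan$image_shape)) &&
      !identical(dim(image), gan$image_shape))
    stop("wrong spatial size: expected ",
         paste(gan$image_shape, collapse = "x"))
  if (normalize) image <- normalize_image(image)
  x <- array(image, c(dim(image), 1, 1))
  st <- .stylenc_fwd(gan$params$enc, nn_const(x))
  mu <- as.numeric(st$mu$value); lv <- as.numeric(st$logvar$value)
  s <- if (sample) with_seed(rng_seed, mu + exp(lv / 2) * stats::rnorm(length(mu)))
       else mu
  structure(list(s = s, mu = mu, logvar = lv, modality = modality,
                 dataset_tag = dataset_tag), class = "style_code")
}

#' Generate an image from a semantic map and a style code
#'
#' The label map drives content through the spatially-adaptive normalisation
#' blocks; the style code drives contrast. Deterministic for fixed inputs.
#'
#' @param gan a trained [train_image_generator()] model.
#' @param m 2D [prob_label_map()] (3D maps must be assembled slice by slice
#'   by the pipeline).
#' @param s a `style_code` (its `s` vector is used) or numeric vector.
#' @return 2D intensity array in `[0, 1]`.
#' @export
generate_image <- function(gan, m, s) {
  if (inherits(m, "prob_label_map") && length(dim(m$probs)) != 3)
    stop("generate_image takes 2D maps; assemble 3D volumes slice by slice")
  mb <- if (inherits(m, "prob_label_map")) labels_to_batch(list(m)) else m
  sv <- if (inherits(s, "style_code")) s$s else as.numeric(s)
  out <- .decoder_fwd(gan$params$dec, nn_const(mb),
                      nn_const(matrix(sv, 1)))$value
  array(out[, , 1, 1], dim(out)[1:2])
}

#' Generate an image from a fitted image generator
#'
#' @param object an `image_gan`.
#' @param newdata a 2D [prob_label_map()].
#' @param style a `style_code` or numeric vector.
#' @param ... unused.
#' @return 2D intensity array.
#' @export
predict.image_gan <- function(object, newdata, style, ...) {
  generate_image(object, newdata, style)
}
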