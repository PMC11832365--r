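# Training losses. Each loss has an internal node form (suffix `_node`)
# used inside the autodiff graphs, and an exported numeric form operating on
# plain arrays, so every term can be checked against brute-force oracles.

.as_node <- function(x) if (nn_is_node(x)) x else nn_const(x)

.EPS_CLAMP <- 1e-6

# focal reconstruction loss (see focal_recon_loss below), node form
focal_node <- function(l, lhat, gamma = 0.3) {
  l <- .as_node(l)
  p <- nn_clamp(.as_node(lhat), .EPS_CLAMP, 1 - .EPS_CLAMP)
  lv <- pmin(pmax(l$value, .EPS_CLAMP), 1 - .EPS_CLAMP)
  ce_min <- -(lv * log(lv) + (1 - lv) * log(1 - lv))      # entropy floor
  ce <- nn_neg(nn_add(nn_mul(l, nn_log(p)),
                      nn_mul(nn_addc(nn_neg(l), 1), nn_log(nn_addc(nn_neg(p), 1)))))
  excess <- nn_sub(ce, nn_const(ce_min))
  # soft "true-class probability": pt = l*p + (1-l)*(1-p)
  pt <- nn_add(nn_mul(l, p),
               nn_mul(nn_addc(nn_neg(l), 1), nn_addc(nn_neg(p), 1)))
  w <- nn_pow(nn_clamp(nn_addc(nn_neg(pt), 1), .EPS_CLAMP, 1), gamma)
  if (gamma == 0) nn_mean(excess) else nn_mean(nn_mul(w, excess))
}

#' Focal reconstruction loss between probabilistic label maps
#'
#' Focal-weighted excess binary cross-entropy, applied per channel and
#' averaged over all elements: each element contributes
#' `(1 - pt)^gamma * (CE(l, p) - CE(l, l))`, where `pt = l*p + (1-l)*(1-p)`
#' is the probability assigned to the correct side. Subtracting the entropy
#' floor `CE(l, l)` makes the loss exactly zero when the reconstruction
#' equals the target (also for fractional border probabilities), and
#' `gamma = 0` reduces it to the unweighted excess cross-entropy.
#'
#' @param l target array (values in `[0, 1]`) or `prob_label_map`.
#' @param l_hat reconstruction of matching shape.
#' @param gamma focusing parameter (default 0.3).
#' @return scalar loss.
#' @export
focal_recon_loss <- function(l, l_hat, gamma = 0.3) {
  if (inherits(l, "prob_label_map")) l <- l$probs
  if (inherits(l_hat, "prob_label_map")) l_hat <- l_hat$probs
  if (any(!is.finite(l)) || any(!is.finite(l_hat)))
    stop("focal_recon_loss: non-finite input")
  stopifnot(identical(dim(l), dim(l_hat)))
  focal_node(l, l_hat, gamma)$value
}

# KLD of diagonal Gaussian posterior vs N(0,1); sum over dims, mean over batch
kld_node <- function(mu, logvar, batch_dim = NULL) {
  mu <- .as_node(mu); logvar <- .as_node(logvar)
  n_batch <- if (is.null(batch_dim)) 1 else dim(mu$value)[batch_dim]
  s <- nn_sum(nn_mulc(nn_sub(nn_add(nn_pow(mu, 2), nn_exp(logvar)),
                             nn_addc(logvar, 1)), 0.5))
  nn_mulc(s, 1 / n_batch)
}

#' Kullback-Leibler divergence of a diagonal Gaussian against N(0, 1)
#'
#' Closed form `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)`.
#'
#' @param mu,logvar arrays of posterior means and log-variances.
#' @return scalar divergence (summed over dimensions).
#' @export
kld_gaussian <- function(mu, logvar) {
  kld_node(mu, logvar)$value
}

# multi-layer L1 between feature lists (nodes)
l1_features_node <- function(fa, fb) {
  stopifnot(length(fa) == length(fb))
  terms <- mapply(function(a, b) nn_mean(nn_abs(nn_sub(.as_node(a), .as_node(b)))),
                  fa, fb, SIMPLIFY = FALSE)
  Reduce(nn_add, terms)
}

#' Perceptual loss through a pluggable feature extractor
#'
#' Sum of L1 distances between the extractor's intermediate representations
#' of the two images. The default extractor in this package is a fixed-seed
#' convolutional feature stack (see [make_feature_extractor()]); an
#' extractor with pretrained weights can be plugged in via the same
#' interface (a function mapping an `(H, W, C, N)` array to a list of
#' feature arrays).
#'
#' @param i,i_tilde image arrays of identical shape, `(H, W)` or
#'   `(H, W, C, N)`.
#' @param feature_extractor extractor object from
#'   [make_feature_extractor()], or any function with the same contract.
#' @return scalar loss.
#' @export
perceptual_loss <- function(i, i_tilde, feature_extractor) {
  fa <- feature_extractor(.ensure_hwcn(i))
  fb <- feature_extractor(.ensure_hwcn(i_tilde))
  l1_features_node(fa, fb)$value
}

.ensure_hwcn <- function(x) {
  if (nn_is_node(x)) return(x)
  d <- dim(x)
  if (is.null(d) || length(d) == 2) x <- array(x, c(dim(as.matrix(x)), 1, 1))
  nn_const(x)
}

#' Create a convolutional feature extractor
#'
#' A small fixed-seed convolutional stack (two strided layers with leaky
#' ReLU) whose intermediate activations serve as perceptual features.
#' Untrained random convolutional features preserve local structure
#' differences and give a usable perceptual metric at desk scale; the
#' returned object is a closure, so a stack with externally supplied weights
#' can be substituted anywhere an extractor is accepted.
#'
#' @param in_channels input channel count.
#' @param widths channel widths of the two layers.
#' @param seed RNG seed fixing the weights.
#' @param include_input prepend the raw input as an identity "layer", so the
#'   loss also carries a direct pixel-level L1 term.
#' @return function mapping an `(H, W, C, N)` array or node to a list of
#'   feature nodes.
#' @export
make_feature_extractor <- function(in_channels, widths = c(16, 32),
                                   seed = 77L, include_input = FALSE) {
  params <- with_seed(seed, list(
    w1 = init_conv_param(3, 3, in_channels, widths[1]),
    b1 = init_bias_param(widths[1]),
    w2 = init_conv_param(3, 3, widths[1], widths[2]),
    b2 = init_bias_param(widths[2])))
  for (p in params) p$req <- FALSE   # frozen
  function(x) {
    x <- .ensure_hwcn(x)
    h1 <- nn_lrelu(nn_conv(x, params$w1, params$b1, 2L, 1L))
    h2 <- nn_lrelu(nn_conv(h1, params$w2, params$b2, 2L, 1L))
    if (include_input) list(x, h1, h2) else list(h1, h2)
  }
}

# hinge GAN loss, node form; scores are lists over scales or single nodes
hinge_node <- function(scores_real, scores_fake, side = c("discriminator",
                                                          "generator")) {
  side <- match.arg(side)
  if (!is.list(scores_real) && !is.null(scores_real))
    scores_real <- list(scores_real)
  if (!is.list(scores_fake)) scores_fake <- list(scores_fake)
  if (side == "discriminator") {
    terms <- mapply(function(r, f) {
      nn_add(nn_mean(nn_relu(nn_addc(nn_neg(.as_node(r)), 1))),
             nn_mean(nn_relu(nn_addc(.as_node(f), 1))))
    }, scores_real, scores_fake, SIMPLIFY = FALSE)
  } else {
    terms <- lapply(scores_fake, function(f) nn_neg(nn_mean(.as_node(f))))
  }
  Reduce(nn_add, terms)
}

#' Hinge GAN loss over multi-scale patch scores
#'
#' Discriminator side: `mean(relu(1 - real)) + mean(relu(1 + fake))` summed
#' over scales; generator side: `-mean(fake)` summed over scales.
#'
#' @param scores_real,scores_fake patch-score arrays, or lists of arrays
#'   (one per discriminator scale). `scores_real` may be `NULL` on the
#'   generator side.
#' @param side `"discriminator"` or `"generator"`.
#' @return scalar loss.
#' @export
hinge_gan_loss <- function(scores_real, scores_fake,
                           side = c("discriminator", "generator")) {
  hinge_node(scores_real, scores_fake, side)$value
}

#' Discriminator feature-matching loss
#'
#' Sum over discriminator scales and intermediate layers of L1 distances
#' between features of the real and generated image.
#'
#' @param features_real,features_fake lists (per scale) of lists (per layer)
#'   of feature arrays, or flat lists of arrays for a single scale.
#' @return scalar loss.
#' @export
feature_matching_loss <- function(features_real, features_fake) {
  if (length(features_real) != length(features_fake))
    stop("mismatched feature lists")
  flat <- function(x) if (is.list(x[[1]])) unlist(x, recursive = FALSE) else x
  fr <- flat(features_real); ff <- flat(features_fake)
  if (length(fr) != length(ff)) stop("mismatched feature lists")
  l1_features_node(fr, ff)$value
}

# cosine similarity of two code nodes (vectors as 1xF matrices)
cosine_node <- function(a, b) {
  num <- nn_sum(nn_mul(a, b))
  na <- nn_sqrt(nn_sum(nn_pow(a, 2)))
  nb <- nn_sqrt(nn_sum(nn_pow(b, 2)))
  if (na$value == 0 || nb$value == 0) stop("zero-norm style code")
  nn_mul(num, nn_pow(nn_mul(na, nb), -1))
}

#' Binary cross-entropy
#'
#' @param target,pred arrays in `[0, 1]` of matching shape.
#' @return scalar mean BCE.
#' @export
bce_loss <- function(target, pred) {
  p <- pmin(pmax(pred, .EPS_CLAMP), 1 - .EPS_CLAMP)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}
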