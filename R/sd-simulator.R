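# Statistics-derived (SD) MRI simulator: per-region Gaussian intensities
# scaled by a modality contrast factor K and modulated by a random
# multiplicative bias field.

#' Region intensity statistics for the SD simulator
#'
#' A table keyed by (modality, dataset, region) holding the mean and standard
#' deviation of region intensities, plus a per-modality contrast factor K
#' (dimensionless, > 0) that divides the noise standard deviation to control
#' tissue contrast-to-noise.
#'
#' @param table data.frame with columns `modality`, `dataset`, `region`,
#'   `mu`, `sigma`.
#' @param K named numeric, contrast factor per modality.
#' @return a `region_intensity_stats` object.
#' @export
region_intensity_stats <- function(table, K) {
  stopifnot(all(c("modality", "dataset", "region", "mu", "sigma") %in%
                  names(table)),
            all(table$sigma >= 0), all(K > 0))
  structure(list(table = table, K = K), class = "region_intensity_stats")
}

#' Default phantom intensity statistics
#'
#' Emulates T1/FLAIR/T2 contrast: tissue means ordered as in real MRI
#' (e.g. WM bright and CSF dark on T1; WMH and oedema bright on FLAIR). K
#' defaults keep GM/WM contrast-to-noise at 3 or more.
#'
#' @param dataset_tag dataset key the entries are filed under.
#' @param modalities subset of `c("T1", "FLAIR", "T2")`.
#' @return a [region_intensity_stats()].
#' @export
default_phantom_stats <- function(dataset_tag = "phantom",
                                  modalities = c("T1", "FLAIR", "T2")) {
  mu <- list(
    T1    = c(CSF = 0.12, GM = 0.55, WM = 0.82, DGM = 0.62, brainstem = 0.70,
              WMH = 0.60, NE_tumour = 0.35, oedema = 0.50, GD_tumour = 0.90),
    FLAIR = c(CSF = 0.08, GM = 0.55, WM = 0.45, DGM = 0.50, brainstem = 0.48,
              WMH = 0.95, NE_tumour = 0.40, oedema = 0.85, GD_tumour = 0.65),
    T2    = c(CSF = 0.95, GM = 0.60, WM = 0.42, DGM = 0.55, brainstem = 0.50,
              WMH = 0.85, NE_tumour = 0.70, oedema = 0.88, GD_tumour = 0.60))
  sg <- 0.25
  rows <- do.call(rbind, lapply(modalities, function(m)
    data.frame(modality = m, dataset = dataset_tag, region = names(mu[[m]]),
               mu = unname(mu[[m]]), sigma = sg)))
  region_intensity_stats(rows, K = stats::setNames(rep(6, length(modalities)),
                                                   modalities))
}

.stats_lookup <- function(stats, modality, dataset_tag, region) {
  t <- stats$table
  r <- t[t$modality == modality & t$dataset == dataset_tag &
           t$region == region, ]
  if (nrow(r) == 0)
    stop("missing intensity stats for (", modality, ", ", dataset_tag, ", ",
         region, ")")
  r[1, ]
}

#' Estimate region intensity statistics from paired images and labels
#'
#' Probability-weighted mean and standard deviation of intensities per region
#' channel across a set of (image, label) pairs. Images should be bias-free.
#'
#' @param images list of intensity arrays.
#' @param labels list of matching [prob_label_map()].
#' @param modality,dataset_tag keys for the resulting entries.
#' @param regions regions the result must cover; defaults to the channels
#'   carrying any probability mass. A requested region with zero total mass
#'   is an error naming the region.
#' @return a data.frame of `region_intensity_stats` rows.
#' @export
estimate_region_stats <- function(images, labels, modality, dataset_tag,
                                  regions = NULL) {
  stopifnot(length(images) == length(labels))
  chans <- labels[[1]]$channel_names
  acc_w <- acc_wx <- acc_wx2 <- stats::setNames(numeric(length(chans)), chans)
  for (k in seq_along(images)) {
    img <- as.numeric(images[[k]])
    pm <- matrix(labels[[k]]$probs, length(chans))
    for (i in seq_along(chans)) {
      w <- pm[i, ]
      acc_w[i] <- acc_w[i] + sum(w)
      acc_wx[i] <- acc_wx[i] + sum(w * img)
      acc_wx2[i] <- acc_wx2[i] + sum(w * img^2)
    }
  }
  if (is.null(regions)) regions <- chans[acc_w > 0]
  if (length(regions) == 0) stop("region(s) with zero probability mass: all")
  missing_mass <- regions[acc_w[regions] <= 0]
  if (length(missing_mass))
    stop("region(s) with zero probability mass: ",
         paste(missing_mass, collapse = ", "))
  mu <- acc_wx[regions] / acc_w[regions]
  va <- pmax(acc_wx2[regions] / acc_w[regions] - mu^2, 0)
  data.frame(modality = modality, dataset = dataset_tag, region = regions,
             mu = unname(mu), sigma = unname(sqrt(va)),
             row.names = NULL)
}

#' Bias field parameters
#'
#' @param coeff_range multiplicative deviation range (default
#'   `c(0.05, 0.15)`).
#' @param probability chance a sampled field is non-identity (default 0.4).
#' @param smoothness Gaussian smoothing sigma (voxels) of the underlying
#'   random field; larger is smoother.
#' @return a `bias_field_params` list.
#' @export
bias_field_params <- function(coeff_range = c(0.05, 0.15), probability = 0.4,
                              smoothness = 8) {
  stopifnot(coeff_range[1] >= 0, coeff_range[2] < 1,
            probability >= 0, probability <= 1)
  structure(list(coeff_range = coeff_range, probability = probability,
                 smoothness = smoothness), class = "bias_field_params")
}

#' Sample a random multiplicative bias field
#'
#' The field is the exponential of a heavily smoothed white-noise field
#' rescaled so that its maximum absolute log-deviation is drawn uniformly
#' from `coeff_range`; it is smooth, strictly positive and has mean close
#' to 1. The application probability is handled by [sd_image()]; this
#' function always returns a non-identity field unless `coeff_range` is
#' degenerate at zero.
#'
#' @param shape integer spatial shape (2D or 3D).
#' @param params a [bias_field_params()].
#' @param rng_seed integer seed.
#' @return array of `shape`, strictly positive.
#' @export
sample_bias_field <- function(shape, params = bias_field_params(),
                              rng_seed = 1L) {
  with_seed(rng_seed, {
    z <- array(stats::rnorm(prod(shape)), shape)
    z <- gaussian_smooth(z, params$smoothness)
    z <- z - mean(z)
    mx <- max(abs(z))
    amp <- stats::runif(1, params$coeff_range[1], params$coeff_range[2])
    if (mx > 0 && amp > 0) z <- z / mx * amp else z <- z * 0
    exp(z)
  })
}

#' Simulate a statistics-derived intensity image from a label map
#'
#' Per-voxel intensity is `BF * sum_i L_i * N(mu_i, sigma_i / K)`: each
#' region channel contributes its probability times an independent Gaussian
#' draw per voxel (the minimal-assumption reading; set
#' `per_region = TRUE` for a single draw per region), the whole image is
#' multiplied by a random bias field with the configured probability, and
#' negative intensities are clipped to zero (MRI magnitude images are
#' non-negative).
#'
#' @param label a [prob_label_map()].
#' @param stats a [region_intensity_stats()] covering all regions present.
#' @param modality,dataset_tag lookup keys.
#' @param params a [bias_field_params()].
#' @param rng_seed integer seed.
#' @param per_region draw one Gaussian sample per region instead of per
#'   voxel.
#' @return intensity array of the label's spatial shape, all values >= 0.
#' @export
sd_image <- function(label, stats, modality, dataset_tag = label$dataset_tag,
                     params = bias_field_params(), rng_seed = 1L,
                     per_region = FALSE) {
  shape <- dim(label$probs)[-1]
  nvox <- prod(shape)
  K <- stats$K[[modality]]
  if (is.null(K)) stop("missing contrast factor K for modality ", modality)
  pm <- matrix(label$probs, dim(label$probs)[1])
  with_seed(rng_seed, {
    img <- numeric(nvox)
    for (i in seq_along(label$channel_names)) {
      ch <- label$channel_names[i]
      if (all(pm[i, ] == 0)) next
      st <- .stats_lookup(stats, modality, dataset_tag, ch)
      draw <- if (per_region) rep(stats::rnorm(1, st$mu, st$sigma / K), nvox)
              else stats::rnorm(nvox, st$mu, st$sigma / K)
      img <- img + pm[i, ] * draw
    }
    if (stats::runif(1) < params$probability) {
      bf <- sample_bias_field(shape, params,
                              derive_seed(rng_seed, 99))
      img <- img * as.numeric(bf)
    }
    array(pmax(img, 0), shape)
  })
}
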