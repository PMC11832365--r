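# Quality, conditioning, fidelity and privacy diagnostics.

#' Tissue-proportion profile of a label set
#'
#' For each label, the mass of every region channel divided by the total
#' brain mass, aggregated per axial slice index (`per_slice`) or per volume
#' (`per_volume`) with mean and standard deviation.
#'
#' @param labels non-empty list of [prob_label_map()].
#' @param mode `"per_slice"` (2D labels carrying `slice_index`) or
#'   `"per_volume"`.
#' @param channels channels to profile (default: the five healthy tissues).
#' @return a `proportion_profile`: data.frame with `slice` (NA for
#'   per-volume), `region`, `mean`, `sd`, `n`.
#' @export
tissue_proportion_profile <- function(labels,
                                      mode = c("per_slice", "per_volume"),
                                      channels = HEALTHY_CHANNELS) {
  mode <- match.arg(mode)
  if (length(labels) == 0) stop("empty label list")
  one <- function(l) {
    pm <- matrix(l$probs, dim(l$probs)[1])
    idx <- match(channels, l$channel_names)
    tot <- sum(pm[match(HEALTHY_CHANNELS, l$channel_names), ]) +
      sum(pm[match(intersect(LESION_CHANNELS, l$channel_names),
                   l$channel_names), ])
    vapply(idx, function(i) sum(pm[i, ]) / max(tot, 1e-12), numeric(1))
  }
  props <- t(vapply(labels, one, numeric(length(channels))))
  colnames(props) <- channels
  key <- if (mode == "per_slice")
    vapply(labels, function(l) as.integer(l$slice_index %||% NA_integer_),
           integer(1))
  else rep(NA_integer_, length(labels))
  out <- do.call(rbind, lapply(split(seq_along(labels), key), function(ix) {
    data.frame(slice = key[ix[1]], region = channels,
               mean = colMeans(props[ix, , drop = FALSE]),
               sd = apply(props[ix, , drop = FALSE], 2, stats::sd),
               n = length(ix), row.names = NULL)
  }))
  out$sd[is.na(out$sd)] <- 0
  class(out) <- c("proportion_profile", "data.frame")
  out
}

#' Compare a sampled profile against a reference profile
#'
#' Fraction of (region, slice) bins whose sampled mean lies within
#' `k * sd` of the reference mean (a floor is applied to near-zero
#' reference sds).
#'
#' @param reference,sampled `proportion_profile` objects on matching bins.
#' @param k sd multiplier (default 3).
#' @param sd_floor minimum sd used in the band.
#' @return list with `fraction`, and the merged per-bin table.
#' @export
profile_coverage <- function(reference, sampled, k = 3, sd_floor = 1e-3) {
  m <- merge(as.data.frame(reference), as.data.frame(sampled),
             by = c("slice", "region"), suffixes = c("_ref", "_sam"))
  if (nrow(m) == 0) stop("profiles share no bins")
  m$within <- abs(m$mean_sam - m$mean_ref) <= k * pmax(m$sd_ref, sd_floor)
  list(fraction = mean(m$within), bins = m)
}

#' Lesion-size response to conditioning
#'
#' Samples labels at each conditioning value (other lesions at 0) and
#' records thresholded lesion voxel counts.
#'
#' @param vae,ldm trained label generator stages.
#' @param cond_values ascending conditioning grid.
#' @param n_per_value samples per value.
#' @param lesion_type conditioned lesion channel.
#' @param rng_seed seed.
#' @param n_steps DDIM steps.
#' @param slice_position slice conditioning for 2D models.
#' @return a `conditioning_curve` data.frame: `value`, `median`, `q1`,
#'   `q3`, `n`, plus a `counts` attribute (list of per-value counts).
#' @export
lesion_size_curve <- function(vae, ldm, cond_values = c(0, 0.33, 0.66, 1),
                              n_per_value = 50, lesion_type = "WMH",
                              rng_seed = 1L, n_steps = 200,
                              slice_position = 0.5) {
  stopifnot(!is.unsorted(cond_values))
  ci <- match(lesion_type, COND_LESIONS)
  if (is.na(ci)) stop("unknown lesion type: ", lesion_type)
  counts <- list()
  rows <- list()
  for (i in seq_along(cond_values)) {
    v <- cond_values[i]
    cond <- matrix(0, n_per_value, length(ldm$cond_names))
    cond[, ci] <- v
    if ("slice" %in% ldm$cond_names)
      cond[, match("slice", ldm$cond_names)] <- slice_position
    labs <- sample_labels(vae, ldm, cond, n_steps,
                          derive_seed(rng_seed, i))
    cnt <- vapply(labs, function(l) lesion_voxel_counts(l)[[lesion_type]],
                  numeric(1))
    counts[[i]] <- cnt
    q <- stats::quantile(cnt, c(0.25, 0.5, 0.75), names = FALSE)
    rows[[i]] <- data.frame(value = v, median = q[2], q1 = q[1], q3 = q[3],
                            n = n_per_value)
  }
  out <- do.call(rbind, rows)
  attr(out, "counts") <- counts
  class(out) <- c("conditioning_curve", "data.frame")
  out
}

#' Tumour voxels mislabelled as WMH
#'
#' `|WMH-prediction intersect tumour| / |tumour|`: the fraction of tumour
#' voxels that a WMH segmentation wrongly claims.
#'
#' @param wmh_prediction binary mask (array or logical).
#' @param tumour_truth binary mask of the same shape; must be non-empty.
#' @return scalar in `[0, 1]`.
#' @export
fp_tum <- function(wmh_prediction, tumour_truth) {
  if (!identical(dim(wmh_prediction), dim(tumour_truth)))
    stop("mask shapes differ")
  nt <- sum(tumour_truth == 1)
  if (nt == 0) stop("empty tumour mask (division by zero)")
  sum(wmh_prediction == 1 & tumour_truth == 1) / nt
}

#' SSIM and MSE between two images
#'
#' Standard single-scale structural similarity (Gaussian window sd 1.5,
#' 11x11 support, K1 = 0.01, K2 = 0.03, dynamic range 1) and mean squared
#' error.
#'
#' @param i,i_tilde 2D intensity arrays on `[0, 1]`.
#' @param L dynamic range.
#' @return list with `ssim` and `mse`.
#' @export
image_fidelity <- function(i, i_tilde, L = 1) {
  stopifnot(identical(dim(i), dim(i_tilde)))
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  blur <- function(x) gaussian_smooth(x, 1.5)
  mu1 <- blur(i); mu2 <- blur(i_tilde)
  s11 <- blur(i * i) - mu1^2
  s22 <- blur(i_tilde * i_tilde) - mu2^2
  s12 <- blur(i * i_tilde) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  list(ssim = mean(ssim_map), mse = mean((i - i_tilde)^2))
}

#' Frechet distance between two feature distributions
#'
#' Gaussian fits to each feature set, then
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`. The covariance
#' square root uses an eigendecomposition with 1e-6 jitter on the diagonal;
#' near-singular fits are regularised (and noted via a message).
#'
#' @param features_a,features_b numeric matrices (samples x features) with
#'   at least 2 rows each and equal column count.
#' @return non-negative scalar.
#' @export
fid_score <- function(features_a, features_b) {
  features_a <- as.matrix(features_a); features_b <- as.matrix(features_b)
  if (ncol(features_a) != ncol(features_b)) stop("feature dims differ")
  if (nrow(features_a) < 2 || nrow(features_b) < 2)
    stop("need at least 2 samples per set")
  eps <- 1e-6
  mua <- colMeans(features_a); mub <- colMeans(features_b)
  Sa <- stats::cov(features_a); Sb <- stats::cov(features_b)
  d <- ncol(Sa)
  Sa <- Sa + diag(eps, d); Sb <- Sb + diag(eps, d)
  sqrtm <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), d) %*% t(e$vectors)
  }
  sa_half <- sqrtm(Sa)
  inner <- sa_half %*% Sb %*% sa_half
  ev <- eigen(inner, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) message("fid_score: covariance product regularised")
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  max(sum((mua - mub)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * tr_sqrt, 0)
}

#' Mean per-channel Dice between two label maps
#'
#' Channels are thresholded at 0.5; Dice is averaged (unweighted) over
#' channels present (nonzero) in either map. Two empty maps score 1.
#'
#' @param a,b [prob_label_map()] with matching channels.
#' @return scalar Dice in `[0, 1]`.
#' @export
label_dice <- function(a, b) {
  pa <- matrix(a$probs, dim(a$probs)[1]) > 0.5
  pb <- matrix(b$probs, dim(b$probs)[1]) > 0.5
  keep <- rowSums(pa) + rowSums(pb) > 0
  if (!any(keep)) return(1)
  mean(vapply(which(keep), function(i) dice_binary(pa[i, ], pb[i, ]),
              numeric(1)))
}

#' Nearest-neighbour retrieval by Dice (memorisation check)
#'
#' Ranks training labels by mean per-channel Dice against the query and
#' returns the top k. A query present in the training set is retrieved at
#' rank 1 with Dice 1.
#'
#' @param query a [prob_label_map()].
#' @param training_labels list of [prob_label_map()].
#' @param k neighbours to return (values beyond the set size are truncated
#'   with a message).
#' @return data.frame `rank`, `index`, `dice`, in descending Dice order.
#' @export
nn_dice_retrieval <- function(query, training_labels, k = 4) {
  if (k > length(training_labels)) {
    message("k exceeds training set size; returning all ",
            length(training_labels))
    k <- length(training_labels)
  }
  d <- vapply(training_labels, function(l) label_dice(query, l), numeric(1))
  ord <- order(d, decreasing = TRUE)[seq_len(k)]
  data.frame(rank = seq_len(k), index = ord, dice = d[ord])
}

#' Cluster style codes and score agreement with known groups
#'
#' Optional 2-D embedding (pluggable; default none, clustering happens in
#' code space) followed by seeded k-means (random initialisation, 300
#' iterations); agreement is the adjusted Rand index against the true
#' groups.
#'
#' @param codes matrix (n x code_dim) or list of `style_code`.
#' @param true_groups vector of group labels (length n).
#' @param k number of clusters.
#' @param embed optional function mapping the code matrix to an embedding
#'   used for clustering.
#' @param rng_seed seed for k-means initialisation.
#' @param nstart k-means restarts.
#' @return list with `cluster`, `ari`, `centers`.
#' @export
style_code_clustering <- function(codes, true_groups, k, embed = NULL,
                                  rng_seed = 1L, nstart = 10) {
  X <- if (is.list(codes)) do.call(rbind, lapply(codes, function(s)
    if (inherits(s, "style_code")) s$mu else as.numeric(s))) else as.matrix(codes)
  if (nrow(X) < k) stop("fewer codes than clusters")
  if (!is.null(embed)) X <- embed(X)
  km <- with_seed(rng_seed,
                  stats::kmeans(X, k, iter.max = 300, nstart = nstart))
  ari <- if (k == 1) 0 else mclust::adjustedRandIndex(km$cluster, true_groups)
  list(cluster = km$cluster, ari = ari, centers = km$centers,
       tot_withinss = km$tot.withinss)
}
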