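# Brain phantom generator: probabilistic tissue label maps with optional
# lesions, standing in for GIF-style parcellations of real MRI.

HEALTHY_CHANNELS <- c("CSF", "GM", "WM", "DGM", "brainstem")
LESION_CHANNELS  <- c("WMH", "NE_tumour", "oedema", "GD_tumour")
ALL_CHANNELS     <- c(HEALTHY_CHANNELS, LESION_CHANNELS)

#' Construct a probabilistic label map
#'
#' A `prob_label_map` stores per-voxel tissue probabilities across ordered
#' channels: five healthy tissues (CSF, GM, WM, DGM, brainstem) followed by
#' four binary lesion channels (WMH, NE tumour core, oedema, GD-enhancing
#' tumour). Per-voxel probabilities sum to at most 1; wherever a lesion
#' channel is 1 every healthy channel is 0.
#'
#' @param probs array of shape (C, H, W) or (C, H, W, D) with values in
#'   `[0, 1]`.
#' @param channel_names ordered channel names; defaults to the standard nine.
#' @param voxel_size_mm numeric length-3 voxel size.
#' @param subject_id,dataset_tag identifying strings.
#' @param slice_index integer axial index for 2D slices (optional).
#' @return an object of class `prob_label_map`.
#' @export
prob_label_map <- function(probs, channel_names = ALL_CHANNELS,
                           voxel_size_mm = c(1, 1, 1),
                           subject_id = "phantom", dataset_tag = "phantom",
                           slice_index = NULL) {
  stopifnot(length(dim(probs)) %in% c(3, 4),
            dim(probs)[1] == length(channel_names))
  x <- list(probs = probs, channel_names = channel_names,
            voxel_size_mm = voxel_size_mm, subject_id = subject_id,
            dataset_tag = dataset_tag, slice_index = slice_index)
  class(x) <- "prob_label_map"
  x
}

#' @export
print.prob_label_map <- function(x, ...) {
  d <- dim(x$probs)
  cat("prob_label_map:", paste(d[-1], collapse = "x"),
      sprintf("(%dD), %d channels, subject %s [%s]\n",
              length(d) - 1, d[1], x$subject_id, x$dataset_tag))
  les <- lesion_voxel_counts(x)
  if (any(les > 0))
    cat("  lesion voxels:",
        paste(names(les)[les > 0], les[les > 0], sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Validate the probabilistic label map invariants
#'
#' Checks finiteness, `[0,1]` bounds, per-voxel channel sums not exceeding 1,
#' binarity of lesion channels, and the fusion rule (healthy channels are
#' exactly zero under lesions).
#'
#' @param x a `prob_label_map`.
#' @param tol tolerance on the channel-sum bound.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_label <- function(x, tol = 1e-5) {
  p <- x$probs
  if (!all(is.finite(p))) stop("label contains non-finite values")
  if (min(p) < 0 || max(p) > 1) stop("label values outside [0,1]")
  cs <- colSums(matrix(p, dim(p)[1]))
  if (max(cs) > 1 + tol) stop("per-voxel channel sum exceeds 1")
  li <- match(intersect(LESION_CHANNELS, x$channel_names), x$channel_names)
  hi <- match(intersect(HEALTHY_CHANNELS, x$channel_names), x$channel_names)
  pm <- matrix(p, dim(p)[1])               # channels x voxels
  for (i in li) {
    if (!all(pm[i, ] %in% c(0, 1))) stop("lesion channel not binary")
  }
  if (length(li)) {
    lesany <- apply(pm[li, , drop = FALSE], 2, max) == 1
    hsum <- colSums(pm[hi, , drop = FALSE])
    if (any(hsum[lesany] > 0)) stop("healthy probability under a lesion voxel")
  }
  invisible(TRUE)
}

#' Phantom generator configuration
#'
#' @param shape integer vector (H, W) or (H, W, D); in-plane dims must be at
#'   least 16 to accommodate all five tissue regions.
#' @param n_subjects number of phantoms.
#' @param jitter fractional perturbation of ellipsoid axes/centres in
#'   `[0, 0.5]`.
#' @param lesion_frequency named numeric, fraction of subjects receiving each
#'   lesion type (`wmh`, `tumour`).
#' @param lesion_size_range voxel radius range for lesion blobs.
#' @param softness Gaussian boundary smoothing sigma in voxels.
#' @param min_one_voxel if `TRUE`, a `size_param` of 0 still yields a
#'   one-voxel lesion; otherwise it is an error.
#' @param seed integer RNG seed; a fixed seed makes output bit-identical.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(32, 32, 16), n_subjects = 40,
                           jitter = 0.08,
                           lesion_frequency = c(wmh = 0.4, tumour = 0.4),
                           lesion_size_range = c(1, 4), softness = 1.5,
                           min_one_voxel = TRUE, seed = 1L) {
  if (length(shape) < 2 || any(shape[1:2] < 16))
    stop("shape too small: in-plane dims must be >= 16")
  if (jitter < 0 || jitter > 0.5) stop("jitter must lie in [0, 0.5]")
  structure(list(shape = shape, n_subjects = n_subjects, jitter = jitter,
                 lesion_frequency = lesion_frequency,
                 lesion_size_range = lesion_size_range, softness = softness,
                 min_one_voxel = min_one_voxel, seed = as.integer(seed)),
            class = "phantom_config")
}

# normalised coordinate grids in [-1, 1] per axis
.coord_grids <- function(shape) {
  lapply(seq_along(shape), function(ax) {
    g <- seq(-1, 1, length.out = shape[ax])
    if (length(shape) == 2) {
      if (ax == 1) matrix(g, shape[1], shape[2])
      else matrix(g, shape[1], shape[2], byrow = TRUE)
    } else {
      a <- array(0, shape)
      if (ax == 1) a[] <- g
      else if (ax == 2) a[] <- rep(g, each = shape[1])
      else a[] <- rep(g, each = shape[1] * shape[2])
      a
    }
  })
}

# super-ellipsoid "radius" field; p controls squareness
.se_radius <- function(grids, centre, axes, p = 2.5) {
  r <- 0
  for (i in seq_along(grids))
    r <- r + abs((grids[[i]] - centre[i]) / axes[i])^p
  r^(1 / p)
}

#' Generate a probabilistic brain phantom
#'
#' Builds nested smoothed super-ellipsoid anatomy: an outer CSF shell, a GM
#' ribbon, a WM interior, two central DGM blobs and an inferior brainstem
#' stalk (3D; in 2D a posterior-central stalk surrogate). Gaussian boundary
#' smoothing produces genuinely fractional probabilities at region borders,
#' emulating probabilistic parcellation output. Lesion channels are zero.
#'
#' @param config a [phantom_config()].
#' @param rng_seed integer seed; the phantom is a pure function of
#'   `(config, rng_seed)`.
#' @return a [prob_label_map()] with healthy channels only.
#' @export
generate_phantom_label <- function(config, rng_seed = config$seed) {
  shape <- config$shape
  nd <- length(shape)
  with_seed(rng_seed, {
    jit <- function(n) stats::runif(n, -config$jitter, config$jitter)
    axes0 <- if (nd == 2) c(0.82, 0.74) else c(0.82, 0.74, 0.80)
    axes <- axes0 * (1 + jit(nd))
    centre <- jit(nd) * 0.3
    grids <- .coord_grids(shape)
    r <- .se_radius(grids, centre, axes)
    brain <- r <= 1
    gm_in <- r <= 0.85 * (1 + jit(1) * 0.5)
    wm_in <- r <= 0.66 * (1 + jit(1) * 0.5)
    csf <- brain & !gm_in
    gm <- gm_in & !wm_in
    wm <- wm_in
    # two deep grey blobs near the centre
    dgm <- array(FALSE, shape)
    for (s in c(-1, 1)) {
      cdg <- centre + jit(nd) * 0.2
      cdg[2] <- cdg[2] + s * 0.18
      rd <- .se_radius(grids, cdg, rep(0.16, nd) * (1 + jit(1)))
      dgm <- dgm | (rd <= 1)
    }
    dgm <- dgm & wm
    # brainstem: inferior central stalk (3D) / posterior-central stalk (2D)
    bs <- array(FALSE, shape)
    if (nd == 3) {
      rs <- .se_radius(grids[1:2], centre[1:2] + c(0.25, 0) + jit(2) * 0.1,
                       c(0.16, 0.14))        # constant along z
      zlow <- grids[[3]] < -0.45
      bs <- (rs <= 1) & zlow & brain
    } else {
      rs <- .se_radius(grids, centre + c(0.45, 0) + jit(2) * 0.1,
                       c(0.18, 0.13))
      bs <- (rs <= 1) & brain
    }
    wm <- wm & !dgm & !bs
    gm <- gm & !bs
    csf <- csf & !bs
    dgm <- dgm & !bs
    regions <- list(CSF = csf, GM = gm, WM = wm, DGM = dgm, brainstem = bs)
    sm <- lapply(regions, function(m) gaussian_smooth(m * 1, config$softness))
    tot <- Reduce(`+`, sm)
    scl <- 1 / pmax(tot, 1)
    probs <- array(0, c(length(ALL_CHANNELS), shape))
    for (i in seq_along(sm)) {
      v <- pmin(pmax(sm[[i]] * scl, 0), 1)
      if (nd == 2) probs[i, , ] <- v else probs[i, , , ] <- v
    }
    prob_label_map(probs, subject_id = sprintf("phantom-%06d", rng_seed))
  })
}

#' Construct a lesion mask for a healthy label map
#'
#' WMH lesions are one or more small spherical blobs placed in a dilated
#' periventricular band around the deep grey matter; tumours are three
#' concentric disjoint layers (NE core, GD-enhancing ring, oedema shell)
#' centred in white matter. Expected lesion volume is non-decreasing in
#' `size_param`.
#'
#' @param label a healthy-only [prob_label_map()].
#' @param lesion_type `"wmh"` or `"tumour"`.
#' @param size_param lesion size scale in `[0, 1]`.
#' @param rng_seed integer seed.
#' @param config a [phantom_config()] supplying size range and the
#'   zero-size policy.
#' @return a `lesion_mask`: list with `lesion_type`, binary `layers` (named
#'   by lesion channel) and their union `mask`.
#' @export
generate_lesion_mask <- function(label, lesion_type, size_param, rng_seed,
                                 config = phantom_config(shape = dim(label$probs)[-1])) {
  stopifnot(size_param >= 0, size_param <= 1)
  if (!lesion_type %in% c("wmh", "tumour"))
    stop("unknown lesion type: ", lesion_type)
  p <- label$probs
  shape <- dim(p)[-1]
  nd <- length(shape)
  idx <- function(ch) match(ch, label$channel_names)
  getch <- function(ch) {
    if (nd == 2) p[idx(ch), , ] else p[idx(ch), , , ]
  }
  wm <- getch("WM"); dgm <- getch("DGM")
  hsum <- getch("CSF") + getch("GM") + wm + dgm + getch("brainstem")
  with_seed(rng_seed, {
    sphere <- function(centre, radius) {
      grids <- lapply(seq_len(nd), function(ax) {
        a <- array(0, shape)
        g <- seq_len(shape[ax])
        if (ax == 1) a[] <- g
        else if (ax == 2) a[] <- rep(g, each = shape[1])
        else a[] <- rep(g, each = shape[1] * shape[2])
        a
      })
      d2 <- 0
      for (i in seq_len(nd)) d2 <- d2 + (grids[[i]] - centre[i])^2
      sqrt(d2) <= radius
    }
    pick <- function(cand) {
      w <- which(cand)
      if (!length(w)) stop("no eligible placement region for ", lesion_type)
      arrayInd(w[sample.int(length(w), 1)], shape)
    }
    rng <- config$lesion_size_range
    radius <- rng[1] + size_param * (rng[2] - rng[1])
    if (size_param == 0 && !config$min_one_voxel)
      stop("size_param = 0 with min_one_voxel = FALSE")
    if (lesion_type == "wmh") {
      band <- gaussian_smooth(dgm, 2.5) > 0.02 & wm > 0.5
      if (!any(band)) band <- wm > 0.5
      nblob <- if (length(shape) == 3) 2L + stats::rbinom(1, 4, 0.3 + 0.4 * size_param)
               else 1L + stats::rbinom(1, 2, size_param * 0.6)
      m <- array(FALSE, shape)
      for (b in seq_len(nblob)) {
        ctr <- pick(band)
        m <- m | (sphere(ctr, radius) & hsum > 0.5)
      }
      if (!any(m)) m[matrix(pick(band), 1)] <- TRUE
      layers <- list(WMH = m * 1)
      mask <- m * 1
    } else {
      core_ok <- wm > 0.6
      ctr <- pick(core_ok)
      r1 <- 0.5 + 2.5 * size_param
      r2 <- r1 + 1
      r3 <- r2 + 0.8 + 2.2 * size_param
      inside <- hsum > 0.3
      core <- sphere(ctr, r1) & inside
      ring <- sphere(ctr, r2) & inside & !core
      oed  <- sphere(ctr, r3) & inside & !core & !ring
      if (!any(core)) core[matrix(ctr, 1)] <- TRUE
      layers <- list(NE_tumour = core * 1, GD_tumour = ring * 1,
                     oedema = oed * 1)
      mask <- (core | ring | oed) * 1
    }
    structure(list(lesion_type = lesion_type, layers = layers, mask = mask),
              class = "lesion_mask")
  })
}

#' Fuse a lesion mask into a probabilistic label map
#'
#' Lesion channels are set from the mask layers and every healthy channel is
#' set to exactly zero wherever any lesion layer equals 1; all other voxels
#' are unchanged. Channel sums never increase.
#'
#' @param label a [prob_label_map()].
#' @param mask a `lesion_mask` from [generate_lesion_mask()] with matching
#'   spatial shape.
#' @return the fused [prob_label_map()].
#' @export
fuse_lesion <- function(label, mask) {
  p <- label$probs
  shape <- dim(p)[-1]
  for (ch in names(mask$layers)) {
    if (!ch %in% label$channel_names)
      stop("channel-name mismatch: ", ch, " not present in label")
    if (!identical(dim(mask$layers[[ch]]), as.integer(shape)) &&
        !identical(dim(mask$layers[[ch]]), shape))
      stop("lesion mask shape does not match label")
  }
  union <- mask$mask == 1
  hidx <- match(HEALTHY_CHANNELS, label$channel_names)
  nd <- length(shape)
  for (i in hidx) {
    if (nd == 2) { v <- p[i, , ]; v[union] <- 0; p[i, , ] <- v }
    else { v <- p[i, , , ]; v[union] <- 0; p[i, , , ] <- v }
  }
  for (ch in names(mask$layers)) {
    i <- match(ch, label$channel_names)
    lay <- mask$layers[[ch]]
    if (nd == 2) { v <- p[i, , ]; v[lay == 1] <- 1; p[i, , ] <- v }
    else { v <- p[i, , , ]; v[lay == 1] <- 1; p[i, , , ] <- v }
  }
  out <- label
  out$probs <- p
  out
}

#' Tumour-mask superimposition augmentation
#'
#' Transplants tumour masks from tumour-bearing label maps onto randomly
#' paired healthy (or WMH-bearing) label maps, producing new multi-pathology
#' labels. Pairing is drawn without replacement under the seed.
#'
#' @param healthy_labels,tumour_labels lists of [prob_label_map()].
#' @param n number of new maps; must not exceed either list length.
#' @param rng_seed integer seed.
#' @return list of `n` fused [prob_label_map()].
#' @export
superimpose_tumour_augmentation <- function(healthy_labels, tumour_labels, n,
                                            rng_seed = 1L) {
  if (n > min(length(healthy_labels), length(tumour_labels)))
    stop("n exceeds available subjects")
  if (n == 0) return(list())
  with_seed(rng_seed, {
    hi <- sample.int(length(healthy_labels), n)
    ti <- sample.int(length(tumour_labels), n)
    lapply(seq_len(n), function(k) {
      h <- healthy_labels[[hi[k]]]
      tl <- tumour_labels[[ti[k]]]
      layers <- lapply(c("NE_tumour", "GD_tumour", "oedema"), function(ch) {
        i <- match(ch, tl$channel_names)
        if (length(dim(tl$probs)) == 3) (tl$probs[i, , ] > 0.5) * 1
        else (tl$probs[i, , , ] > 0.5) * 1
      })
      names(layers) <- c("NE_tumour", "GD_tumour", "oedema")
      msk <- structure(list(lesion_type = "tumour", layers = layers,
                            mask = (Reduce(`+`, layers) > 0) * 1),
                       class = "lesion_mask")
      out <- fuse_lesion(h, msk)
      out$subject_id <- paste0(h$subject_id, "+tum")
      out
    })
  })
}

#' Lesion voxel counts of a label map
#'
#' Counts voxels above the 0.5 threshold per lesion channel.
#'
#' @param label a [prob_label_map()].
#' @return named numeric vector over `WMH`, `NE_tumour`, `oedema`,
#'   `GD_tumour`.
#' @export
lesion_voxel_counts <- function(label) {
  pm <- matrix(label$probs, dim(label$probs)[1])
  sapply(LESION_CHANNELS, function(ch) {
    i <- match(ch, label$channel_names)
    if (is.na(i)) 0L else sum(pm[i, ] > 0.5)
  })
}

#' Slice a 3D label map into axial 2D label maps
#'
#' Background-dominated slices (brain area below `min_brain_frac` of pixels)
#' are dropped. Each slice records its integer axial index.
#'
#' @param label a 3D [prob_label_map()].
#' @param min_brain_frac minimum brain-pixel fraction to keep a slice.
#' @return list of 2D [prob_label_map()] with `slice_index` set.
#' @export
slice_label <- function(label, min_brain_frac = 0.01) {
  p <- label$probs
  stopifnot(length(dim(p)) == 4)
  D <- dim(p)[4]
  out <- list()
  for (z in seq_len(D)) {
    sl <- array(p[, , , z], dim(p)[1:3])
    brain <- apply(sl, c(2, 3), sum) > 0.5
    if (mean(brain) < min_brain_frac) next
    out[[length(out) + 1L]] <-
      prob_label_map(sl, label$channel_names, label$voxel_size_mm,
                     label$subject_id, label$dataset_tag,
                     slice_index = z - 1L)
  }
  out
}

#' Generate a full phantom dataset of labels and simulated images
#'
#' For each subject: a (possibly lesioned, per the configured frequencies)
#' label map plus one statistics-derived image per modality, with metadata.
#' With `slices = TRUE`, 3D subjects are additionally sliced into 2D
#' label/image pairs with recorded axial indices.
#'
#' @param config a [phantom_config()].
#' @param stats a [region_intensity_stats()] covering all regions and
#'   modalities.
#' @param modalities character vector, e.g. `c("T1", "FLAIR")`.
#' @param slices return 2D slices of 3D subjects as well.
#' @param bias a [bias_field_params()] for the simulator.
#' @return a `phantom_dataset`: list with `subjects` (each holding `label`,
#'   `images`, `meta`) and, if requested, `slices`.
#' @export
make_phantom_dataset <- function(config, stats, modalities = c("T1", "FLAIR"),
                                 slices = length(config$shape) == 3,
                                 bias = bias_field_params()) {
  subjects <- vector("list", config$n_subjects)
  freq <- config$lesion_frequency
  for (s in seq_len(config$n_subjects)) {
    seed_s <- derive_seed(config$seed, s)
    lab <- generate_phantom_label(config, seed_s)
    ltype <- with_seed(derive_seed(seed_s, 1), {
      u <- stats::runif(1)
      if (u < (freq["wmh"] %||% 0)) "wmh"
      else if (u < (freq["wmh"] %||% 0) + (freq["tumour"] %||% 0)) "tumour"
      else "none"
    })
    if (ltype != "none") {
      sz <- with_seed(derive_seed(seed_s, 2), stats::runif(1))
      msk <- generate_lesion_mask(lab, ltype, sz, derive_seed(seed_s, 3),
                                  config)
      lab <- fuse_lesion(lab, msk)
    }
    imgs <- lapply(modalities, function(m)
      sd_image(lab, stats, m, lab$dataset_tag, bias,
               derive_seed(seed_s, 10 + match(m, modalities))))
    names(imgs) <- modalities
    subjects[[s]] <- list(label = lab, images = imgs,
                          meta = list(subject_id = lab$subject_id,
                                      dataset_tag = lab$dataset_tag,
                                      lesion = ltype))
  }
  out <- list(subjects = subjects, config = config, modalities = modalities)
  if (slices) {
    sl <- list()
    for (s in seq_along(subjects)) {
      labs2d <- slice_label(subjects[[s]]$label)
      for (l2 in labs2d) {
        z <- l2$slice_index + 1L
        im2 <- lapply(subjects[[s]]$images, function(im) im[, , z])
        sl[[length(sl) + 1L]] <- list(label = l2, images = im2,
                                      meta = c(subjects[[s]]$meta,
                                               slice_index = l2$slice_index))
      }
    }
    out$slices <- sl
  }
  class(out) <- "phantom_dataset"
  out
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("phantom_dataset:", length(x$subjects), "subjects,",
      paste(x$modalities, collapse = "/"),
      if (!is.null(x$slices)) sprintf("(%d usable 2D slices)", length(x$slices)),
      "\n")
  invisible(x)
}
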