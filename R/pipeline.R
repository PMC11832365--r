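# End-to-end orchestration: conditioned dataset sampling, 3D assembly with
# a constant style, real/synthetic mixing, and NIfTI I/O.

#' Sampling specification
#'
#' Per-lesion conditioning mode: a lesion absent from `lesions` is
#' conditioned at 0; a named `NA` entry draws the value uniformly between
#' the 1st and 3rd quartiles of the training proportions (stored on the
#' trained diffusion model); a named numeric entry is used as-is.
#'
#' @param lesions named numeric vector, e.g. `c(WMH = NA, oedema = 0.3)`;
#'   explicit values must lie in `[0, 1]`.
#' @param modality style modality tag.
#' @param n number of samples.
#' @param n_steps DDIM steps (default 200).
#' @param seed master seed.
#' @return a `sampling_spec` list.
#' @export
sampling_spec <- function(lesions = c(), modality = "T1", n = 10,
                          n_steps = 200, seed = 1L) {
  if (length(lesions)) {
    bad <- !is.na(lesions) & (lesions < 0 | lesions > 1)
    if (any(bad)) stop("explicit conditioning values must lie in [0, 1]")
    if (!all(names(lesions) %in% COND_LESIONS))
      stop("unknown lesion name in spec")
  }
  if (n_steps < 1) stop("n_steps must be >= 1")
  structure(list(lesions = lesions, modality = modality, n = n,
                 n_steps = n_steps, seed = as.integer(seed)),
            class = "sampling_spec")
}

# conditioning matrix for a spec: quartile draws for NA entries
.spec_conditioning <- function(ldm, spec, slice_positions = NULL) {
  n <- spec$n
  cond <- matrix(0, n, length(ldm$cond_names),
                 dimnames = list(NULL, ldm$cond_names))
  with_seed(derive_seed(spec$seed, 101), {
    for (nm in names(spec$lesions)) {
      v <- spec$lesions[[nm]]
      if (is.na(v)) {
        q <- ldm$cond_quartiles[, nm]
        cond[, nm] <- stats::runif(n, q[1], q[2])
      } else cond[, nm] <- v
    }
    if ("slice" %in% ldm$cond_names) {
      cond[, "slice"] <- if (is.null(slice_positions))
        stats::runif(n, min(ldm$cond_quartiles[, "slice"]),
                     max(ldm$cond_quartiles[, "slice"]))
      else slice_positions
    }
  })
  cond
}

#' Sample a paired 2D label/image dataset
#'
#' Samples conditioned label slices from the two-stage label generator and
#' renders each through the image generator with the requested style.
#'
#' @param vae,ldm trained label generator stages.
#' @param gan trained [train_image_generator()] model.
#' @param spec a [sampling_spec()].
#' @param style_image 2D intensity array used as the style reference
#'   (required).
#' @return list of pairs: each has `label` (2D [prob_label_map()]), `image`,
#'   and `meta` (conditioning row, style modality, seed).
#' @export
sample_paired_dataset_2d <- function(vae, ldm, gan, spec, style_image) {
  if (missing(style_image) || is.null(style_image))
    stop("a style image is required")
  if (spec$n == 0) return(list())
  cond <- .spec_conditioning(ldm, spec)
  labs <- sample_labels(vae, ldm, cond, spec$n_steps,
                        derive_seed(spec$seed, 1))
  sty <- encode_style(gan, style_image)
  lapply(seq_along(labs), function(i) {
    list(label = labs[[i]], image = generate_image(gan, labs[[i]], sty),
         meta = list(cond = cond[i, ], modality = spec$modality,
                     seed = spec$seed))
  })
}

#' Sample a paired 3D label/image volume
#'
#' Generates an axial stack of conditioned label slices (slice-position
#' conditioning swept over the volume, lesion conditioning constant) and
#' forwards every slice through the 2D image generator with the same style
#' code, concatenating the results along the axial axis for a consistent
#' intensity transition between neighbouring slices.
#'
#' @param vae,ldm,gan trained models.
#' @param spec a [sampling_spec()]; `spec$n` is ignored (one volume).
#' @param style_image 2D style reference.
#' @param n_slices axial slices to generate.
#' @return list with 3D `label` ([prob_label_map()]), 3D `image` array,
#'   `style_code`, and `slice_codes` (the per-slice style codes actually
#'   used; all identical).
#' @export
sample_paired_volume_3d <- function(vae, ldm, gan, spec, style_image,
                                    n_slices = 12) {
  spec2 <- spec; spec2$n <- n_slices
  slpos <- seq(0.1, 0.85, length.out = n_slices)
  cond <- .spec_conditioning(ldm, spec2, slice_positions = slpos)
  # constant lesion conditioning across the volume: one draw reused
  for (nm in names(spec$lesions)) cond[, nm] <- cond[1, nm]
  labs <- sample_labels(vae, ldm, cond, spec$n_steps,
                        derive_seed(spec$seed, 2))
  sty <- encode_style(gan, style_image)
  imgs <- lapply(labs, function(l) generate_image(gan, l, sty))
  d2 <- dim(labs[[1]]$probs)
  probs3 <- array(0, c(d2[1], d2[2], d2[3], n_slices))
  img3 <- array(0, c(d2[2], d2[3], n_slices))
  for (z in seq_len(n_slices)) {
    probs3[, , , z] <- labs[[z]]$probs
    img3[, , z] <- imgs[[z]]
  }
  list(label = prob_label_map(probs3, labs[[1]]$channel_names),
       image = img3, style_code = sty,
       slice_codes = replicate(n_slices, sty, simplify = FALSE))
}

#' Mix real and synthetic datasets into a manifest
#'
#' Selects `real_pct`% of the real set and `syn_pct`% of the synthetic set
#' (rounded half-up) by seeded subsampling without replacement.
#'
#' @param real,synthetic lists (datasets of any element type).
#' @param real_pct,syn_pct percentages in `[0, 100]`; their sum must be
#'   positive.
#' @param rng_seed seed.
#' @return list with `entries` (the mixed list), `source` (factor
#'   real/synthetic), and the counts.
#' @export
mix_real_synthetic <- function(real, synthetic, real_pct, syn_pct,
                               rng_seed = 1L) {
  if (real_pct < 0 || syn_pct < 0 || real_pct + syn_pct <= 0)
    stop("percentages must be non-negative with a positive sum")
  round_half_up <- function(x) floor(x + 0.5)
  nr <- round_half_up(length(real) * real_pct / 100)
  ns <- round_half_up(length(synthetic) * syn_pct / 100)
  if (nr + ns == 0) stop("empty mixed dataset")
  with_seed(rng_seed, {
    ri <- if (nr > 0) sort(sample.int(length(real), nr)) else integer(0)
    si <- if (ns > 0) sort(sample.int(length(synthetic), ns)) else integer(0)
    list(entries = c(real[ri], synthetic[si]),
         source = factor(c(rep("real", nr), rep("synthetic", ns))),
         n_real = nr, n_synthetic = ns)
  })
}

# ---- NIfTI I/O --------------------------------------------------------------

#' Write a probabilistic label map as multi-channel NIfTI with sidecar
#'
#' Channels are stored on the 4th dimension (2D slices gain a singleton
#' depth); a JSON sidecar records channel names, dataset tag, voxel size and
#' slice index (the sidecar is the authoritative carrier of the voxel
#' size).
#'
#' @param label a [prob_label_map()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path` invisibly.
#' @export
write_label_nifti <- function(label, path) {
  p <- label$probs
  arr <- if (length(dim(p)) == 3)
    aperm(array(p, c(dim(p), 1)), c(2, 3, 4, 1))   # (H, W, 1, C)
  else aperm(p, c(2, 3, 4, 1))                      # (H, W, D, C)
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(channel_names = label$channel_names,
                            dataset_tag = label$dataset_tag,
                            subject_id = label$subject_id,
                            voxel_size_mm = label$voxel_size_mm,
                            slice_index = label$slice_index),
                       sidecar, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a probabilistic label map written by [write_label_nifti()]
#'
#' @param path NIfTI path; the JSON sidecar is looked up next to it. A
#'   missing sidecar falls back to the default channel order with a
#'   warning.
#' @return a [prob_label_map()].
#' @export
read_label_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("malformed label NIfTI (need 4D): ", path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warning("missing sidecar for ", path, "; assuming default channel order")
    meta <- list(channel_names = ALL_CHANNELS, dataset_tag = "unknown",
                 subject_id = "unknown", voxel_size_mm = c(1, 1, 1),
                 slice_index = NULL)
  }
  arr <- array(as.numeric(arr), dim(arr))
  p <- aperm(arr, c(4, 1, 2, 3))                    # (C, H, W, D)
  if (dim(p)[4] == 1) p <- array(p, dim(p)[1:3])
  prob_label_map(p, meta$channel_names, as.numeric(meta$voxel_size_mm),
                 meta$subject_id %||% "unknown",
                 meta$dataset_tag %||% "unknown",
                 slice_index = meta$slice_index)
}

#' Write / read intensity images as single-channel NIfTI
#'
#' @param image 2D or 3D intensity array.
#' @param path NIfTI path.
#' @param voxel_size_mm voxel size triple.
#' @return the path (write) or the array (read).
#' @export
write_image_nifti <- function(image, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(image, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  out <- as.array(img)
  array(as.numeric(out), dim(out))
}
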