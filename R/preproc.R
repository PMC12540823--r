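# NIfTI input and the preprocessing pipeline: per-volume [0,1] intensity
# normalisation, channel stacking of modalities, axial slicing with an
# optional lesion-slice filter, resizing (bilinear image / nearest-neighbour
# mask) and training-time augmentation.

#' Load a 3D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param modality Optional modality label attached to the volume.
#' @return A `seg_volume` with `data` (3D array) and `spacing` (mm).
#' @export
load_nifti_volume <- function(path, modality = NA_character_) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- try(RNifti::readNifti(path), silent = TRUE)
  if (inherits(img, "try-error"))
    stop("not a readable NIfTI file: ", path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume but '%s' has %d dimensions; split 4D files into one volume per modality",
                 path, length(d)))
  new_volume(array(as.numeric(img), d), RNifti::pixdim(img), modality)
}

#' Normalise a volume to [0, 1]
#'
#' Whole-volume min-max scaling: `(x - min) / (max - min)`. A constant volume
#' (range below the `1e-8` guard) maps to all zeros.
#'
#' @param v A `seg_volume` or numeric array.
#' @return Same type as the input, values in `[0, 1]`.
#' @export
normalize_volume <- function(v) {
  d <- if (inherits(v, "seg_volume")) v$data else v
  if (any(!is.finite(d))) stop("volume contains non-finite values")
  lo <- min(d); hi <- max(d)
  out <- if (hi - lo < 1e-8) array(0, dim(d)) else (d - lo) / (hi - lo)
  if (inherits(v, "seg_volume")) new_volume(out, v$spacing, v$modality) else out
}

#' Stack modality volumes along the channel axis
#'
#' @param volumes List of `seg_volume`s sharing shape and spacing; channel
#'   order follows the list order.
#' @return A `seg_mm_volume`: list with 4D `data` `(H, W, D, C)`, `spacing`,
#'   `modalities`.
#' @export
stack_modalities <- function(volumes) {
  stopifnot(length(volumes) >= 1)
  if (inherits(volumes, "seg_volume")) volumes <- list(volumes)
  d0 <- dim(volumes[[1]]$data); sp0 <- volumes[[1]]$spacing
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!all(dim(v$data) == d0))
      stop(sprintf("modality %d ('%s') has shape %s, expected %s",
                   i, v$modality %||% "?", paste(dim(v$data), collapse = "x"),
                   paste(d0, collapse = "x")))
    if (!isTRUE(all.equal(v$spacing, sp0)))
      stop(sprintf("modality %d ('%s') has mismatched spacing", i, v$modality %||% "?"))
  }
  arr <- array(0, c(d0, length(volumes)))
  for (i in seq_along(volumes)) arr[, , , i] <- volumes[[i]]$data
  structure(list(data = arr, spacing = sp0,
                 modalities = vapply(volumes, function(v) v$modality %||% NA_character_, "")),
            class = "seg_mm_volume")
}

#' Extract axial 2D slices from a multi-modal volume
#'
#' @param mmv A `seg_mm_volume` from [stack_modalities()] (or a single
#'   `seg_volume`, treated as one channel).
#' @param mask Binary mask `seg_volume` or 3D array matching the volume grid.
#' @param lesion_only If `TRUE`, keep only slices whose mask contains at
#'   least one foreground pixel (ascending slice order); an all-background
#'   volume then yields an empty list.
#' @param volume_id Identifier recorded in each slice's `source`.
#' @return List of `mm_slice` objects: `image` `(H, W, C)`, `mask` `(H, W)`,
#'   `source = (volume_id, slice_index)`.
#' @export
extract_axial_slices <- function(mmv, mask, lesion_only = FALSE, volume_id = "vol") {
  if (inherits(mmv, "seg_volume")) mmv <- stack_modalities(list(mmv))
  md <- if (inherits(mask, "seg_volume")) mask$data else mask
  d <- dim(mmv$data)
  if (!all(dim(md) == d[1:3])) stop("mask shape does not match volume")
  out <- list()
  for (z in seq_len(d[3])) {
    msk <- md[, , z]
    if (lesion_only && sum(msk) == 0) next
    img <- array(mmv$data[, , z, ], c(d[1], d[2], d[4]))
    out[[length(out) + 1L]] <- structure(
      list(image = img, mask = array(as.numeric(msk != 0), d[1:2]),
           source = list(volume_id = volume_id, slice = z)),
      class = "mm_slice")
  }
  out
}

#' Resize a slice
#'
#' Bilinear interpolation for the image channels, nearest neighbour for the
#' mask (which therefore stays binary).
#'
#' @param s An `mm_slice`.
#' @param size Target `(H, W)`, both at least 8.
#' @return The resized `mm_slice`.
#' @export
resize_slice <- function(s, size = c(224L, 224L)) {
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 8L)) stop("target size must be at least 8 pixels")
  if (all(dim(s$mask) == size)) return(s)
  img <- EBImage::resize(s$image, w = size[1], h = size[2], filter = "bilinear")
  img <- pmin(pmax(array(img, c(size, dim(s$image)[3])), 0), 1)
  msk <- EBImage::resize(s$mask, w = size[1], h = size[2], filter = "none")
  structure(list(image = img, mask = array(as.numeric(msk != 0), size),
                 source = s$source), class = "mm_slice")
}

#' Augmentation configuration
#'
#' @param rotation Maximum absolute rotation, degrees (drawn uniformly).
#' @param flip_prob Probability of each of horizontal and vertical flip.
#' @param contrast Range of the multiplicative contrast gain.
#' @return Named list.
#' @export
augment_config <- function(rotation = 15, flip_prob = 0.5, contrast = c(0.9, 1.1)) {
  list(rotation = rotation, flip_prob = flip_prob, contrast = contrast)
}

#' Randomly augment a slice
#'
#' Applies one random rotation and horizontal/vertical flips jointly to image
#' and mask (so their overlap is preserved), then a multiplicative contrast
#' gain to the image only, clipped back to `[0, 1]`. Draws come from the
#' caller's RNG stream (seed with [set.seed()]), or can be forced via
#' `draws` for deterministic use.
#'
#' @param s An `mm_slice` with image values in `[0, 1]`.
#' @param config An [augment_config()].
#' @param draws Optional list `angle`, `flip_h`, `flip_v`, `gain` overriding
#'   the random draws.
#' @return The augmented `mm_slice`.
#' @export
augment_slice <- function(s, config = augment_config(), draws = NULL) {
  if (is.null(draws))
    draws <- list(angle = runif(1, -config$rotation, config$rotation),
                  flip_h = runif(1) < config$flip_prob,
                  flip_v = runif(1) < config$flip_prob,
                  gain = runif(1, config$contrast[1], config$contrast[2]))
  img <- s$image; msk <- s$mask
  dm <- dim(msk)
  if (abs(draws$angle) > 1e-12) {
    img <- array(EBImage::rotate(img, draws$angle, filter = "bilinear",
                                 output.dim = dm, bg.col = 0), dim(s$image))
    msk <- array(EBImage::rotate(msk, draws$angle, filter = "none",
                                 output.dim = dm, bg.col = 0), dm)
  }
  if (isTRUE(draws$flip_h)) {  # mirror columns (left-right)
    img <- img[, rev(seq_len(dm[2])), , drop = FALSE]
    msk <- msk[, rev(seq_len(dm[2])), drop = FALSE]
  }
  if (isTRUE(draws$flip_v)) {  # mirror rows (top-bottom)
    img <- img[rev(seq_len(dm[1])), , , drop = FALSE]
    msk <- msk[rev(seq_len(dm[1])), , drop = FALSE]
  }
  img <- pmin(pmax(img * draws$gain, 0), 1)
  structure(list(image = array(img, dim(s$image)),
                 mask = array(as.numeric(msk != 0), dm), source = s$source),
            class = "mm_slice")
}
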