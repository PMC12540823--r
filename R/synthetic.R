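# Seeded synthetic multi-modal brain-like volumes with ellipsoidal lesions.
#
# Each modality is a smooth low-frequency background field plus i.i.d.
# Gaussian noise; lesions are axis-aligned ellipsoids added with a
# modality-dependent contrast and a quadratic intensity falloff towards the
# boundary. Raw intensities are mapped to modality-specific ranges well
# outside [0, 1], so per-volume min-max normalisation is a real operation.
# The ground-truth mask is the union of the lesion ellipsoids.

#' Specification of a synthetic multi-modal volume
#'
#' @param volume_shape Integer `(H, W, D)` voxel grid.
#' @param n_modalities 3 (T1/T2/DWI-like) or 4 (T1/T1c/T2/FLAIR-like).
#' @param voxel_spacing mm per axis.
#' @param lesion_count_range Integer interval for the number of lesions.
#' @param lesion_radius_range In-plane lesion radius interval, voxels.
#' @param lesion_contrast Per-modality intensity offset of lesion tissue, in
#'   internal units where the background field has amplitude ~0.5.
#' @param background_level Mean background intensity, internal units.
#' @param smooth_field_scale Correlation length of the background field,
#'   voxels.
#' @param field_amplitude Amplitude of the smooth background field.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param intensity_range `n_modalities x 2` matrix of raw intensity ranges;
#'   internal values are mapped linearly onto them.
#' @param seed Default seed used when none is passed to the generators.
#' @return Validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(volume_shape = c(64L, 64L, 12L),
                           n_modalities = 3L,
                           voxel_spacing = c(1, 1, 2),
                           lesion_count_range = c(1L, 3L),
                           lesion_radius_range = c(4, 9),
                           lesion_contrast = NULL,
                           background_level = 0.35,
                           smooth_field_scale = 8,
                           field_amplitude = 0.15,
                           noise_sigma = 0.03,
                           intensity_range = NULL,
                           seed = 1L) {
  if (!n_modalities %in% c(3L, 4L)) stop("n_modalities must be 3 or 4")
  if (is.null(lesion_contrast))
    lesion_contrast <- c(0.10, 0.25, 0.45, 0.35)[seq_len(n_modalities)]
  if (is.null(intensity_range))
    intensity_range <- matrix(c(0, 180, 0, 320, 0, 90, 0, 255),
                              ncol = 2L, byrow = TRUE)[seq_len(n_modalities), , drop = FALSE]
  spec <- list(volume_shape = as.integer(volume_shape),
               n_modalities = as.integer(n_modalities),
               voxel_spacing = voxel_spacing,
               lesion_count_range = as.integer(lesion_count_range),
               lesion_radius_range = lesion_radius_range,
               lesion_contrast = lesion_contrast,
               background_level = background_level,
               smooth_field_scale = smooth_field_scale,
               field_amplitude = field_amplitude,
               noise_sigma = noise_sigma,
               intensity_range = intensity_range,
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  s <- spec$volume_shape
  if (length(s) != 3L || any(s < 8L)) stop("volume_shape must be three sizes >= 8")
  if (!spec$n_modalities %in% c(3L, 4L)) stop("n_modalities must be 3 or 4")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(spec$voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (2 * max(spec$lesion_radius_range) + 4 > min(s[1:2]))
    stop("lesion_radius_range does not fit inside volume_shape")
  if (length(spec$lesion_contrast) != spec$n_modalities)
    stop("lesion_contrast needs one value per modality")
  if (diff(spec$lesion_count_range) < 0 || spec$lesion_count_range[1] < 0)
    stop("bad lesion_count_range")
  invisible(spec)
}

new_volume <- function(data, spacing, modality = NA_character_) {
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "seg_volume")
}

#' @export
print.seg_volume <- function(x, ...) {
  cat(sprintf("<seg_volume %s: %s voxels, spacing %s mm>\n",
              x$modality %||% "?", paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

# low-frequency random field: coarse uniform noise linearly upsampled
smooth_field <- function(shape, scale) {
  coarse_dim <- pmax(2L, ceiling(shape / scale) + 1L)
  coarse <- array(runif(prod(coarse_dim), -1, 1), coarse_dim)
  up_axis <- function(a, axis, n_out) {
    d <- dim(a)
    xin <- seq(0, 1, length.out = d[axis])
    xout <- seq(0, 1, length.out = n_out)
    m <- apply(a, setdiff(1:3, axis), function(v) stats::approx(xin, v, xout)$y)
    # apply returns n_out x (prod other dims); restore axis order
    dm <- d; dm[axis] <- n_out
    arr <- array(m, c(n_out, d[setdiff(1:3, axis)]))
    aperm(arr, order(c(axis, setdiff(1:3, axis))))
  }
  f <- coarse
  for (ax in 1:3) f <- up_axis(f, ax, shape[ax])
  f
}

# ellipsoid membership and falloff on the full grid (evaluated on a bounding
# box for speed); returns list(inside logical array, falloff numeric array)
ellipsoid_field <- function(shape, center, radii) {
  lo <- pmax(1L, floor(center - radii)); hi <- pmin(shape, ceiling(center + radii))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  qx <- ((xs - center[1]) / radii[1])^2
  qy <- ((ys - center[2]) / radii[2])^2
  qz <- ((zs - center[3]) / radii[3])^2
  rho2 <- outer(outer(qx, qy, `+`), qz, `+`)
  inside <- array(FALSE, shape); fall <- array(0, shape)
  inside[xs, ys, zs] <- rho2 <= 1
  fall[xs, ys, zs] <- pmax(0, 1 - rho2)
  list(inside = inside, falloff = fall)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic multi-modal volume with its lesion mask
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; identical spec + seed give identical output.
#' @return List with `images` (one `seg_volume` of raw intensities per
#'   modality), `mask` (binary `seg_volume`), and `lesions` (data.frame of
#'   centers and radii).
#' @export
generate_volume <- function(spec, seed = spec$seed) {
  validate_synthetic_spec(spec)
  shape <- spec$volume_shape
  with_seed(seed, {
    n_les <- if (diff(spec$lesion_count_range) == 0) spec$lesion_count_range[1]
             else sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1L)
    mask <- array(0L, shape)
    fall_total <- array(0, shape)
    lesions <- NULL
    rr <- spec$lesion_radius_range
    zmax <- max(1, (shape[3] - 4) / 2)
    for (i in seq_len(n_les)) {
      radii <- c(runif(2, rr[1], rr[2]), min(zmax, runif(1, rr[1], rr[2]) / 2))
      # margins keep the first and last axial slice lesion-free
      cx <- runif(1, radii[1] + 2, shape[1] - radii[1] - 1)
      cy <- runif(1, radii[2] + 2, shape[2] - radii[2] - 1)
      cz <- runif(1, radii[3] + 2, shape[3] - radii[3] - 1)
      ef <- ellipsoid_field(shape, c(cx, cy, cz), radii)
      mask[ef$inside] <- 1L
      fall_total <- pmax(fall_total, ef$falloff)
      lesions <- rbind(lesions, data.frame(cx = cx, cy = cy, cz = cz,
                                           rx = radii[1], ry = radii[2], rz = radii[3]))
    }
    anatomy <- smooth_field(shape, spec$smooth_field_scale)
    images <- vector("list", spec$n_modalities)
    for (m in seq_len(spec$n_modalities)) {
      u <- spec$background_level + spec$field_amplitude * anatomy +
        spec$lesion_contrast[m] * fall_total +
        array(rnorm(prod(shape), sd = spec$noise_sigma), shape)
      rng <- spec$intensity_range[m, ]
      raw <- rng[1] + u * (rng[2] - rng[1])
      images[[m]] <- new_volume(raw, spec$voxel_spacing, paste0("mod", m))
    }
    list(images = images, mask = new_volume(mask, spec$voxel_spacing, "mask"),
         lesions = lesions)
  })
}

#' Write a volume as NIfTI-1
#'
#' Images are stored as float64 and integer 0/1 masks as uint8, so a
#' read-back returns voxelwise identical data; the voxel spacing is stored in
#' the pixdim header fields.
#'
#' @param volume A `seg_volume` (or a bare 3D array, 1 mm spacing assumed).
#' @param path Output path; `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  if (!inherits(volume, "seg_volume"))
    volume <- new_volume(volume, rep(1, length(dim(volume))))
  d <- volume$data
  is_mask <- all(d %in% c(0L, 1L))
  img <- RNifti::asNifti(d + 0)  # force numeric storage
  RNifti::pixdim(img) <- volume$spacing
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- try(RNifti::writeNifti(img, path,
                               datatype = if (is_mask) "uint8" else "double"),
            silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path))
    stop("failed to write NIfTI file: ", path)
  invisible(path)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_volumes` image/mask NIfTI pairs plus a tab-separated manifest
#' recording per-volume seeds and train/val/test split assignments.
#'
#' @param spec A [synthetic_spec()].
#' @param n_volumes Number of volumes.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; drives per-volume seeds and split assignment.
#' @param split Fractions for train/val/test (must sum to 1).
#' @return The manifest data.frame (columns `volume_id`, `file`, `role`,
#'   `modality`, `split`, `seed`), invisibly; also written to
#'   `<out_dir>/manifest.tsv`.
#' @export
generate_dataset <- function(spec, n_volumes, out_dir, seed = spec$seed,
                             split = c(0.6, 0.2, 0.2)) {
  validate_synthetic_spec(spec)
  stopifnot(n_volumes >= 1, abs(sum(split) - 1) < 1e-8)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  vol_seeds <- with_seed(seed, sample.int(1e8L, n_volumes))
  n_train <- floor(n_volumes * split[1])
  n_val <- floor(n_volumes * split[2])
  splits <- rep(c("train", "val", "test"),
                c(n_train, n_val, n_volumes - n_train - n_val))
  rows <- list()
  for (i in seq_len(n_volumes)) {
    vol <- generate_volume(spec, vol_seeds[i])
    vid <- sprintf("vol%03d", i)
    for (m in seq_len(spec$n_modalities)) {
      f <- sprintf("%s_mod%d.nii.gz", vid, m)
      write_nifti(vol$images[[m]], file.path(out_dir, f))
      rows[[length(rows) + 1L]] <- data.frame(
        volume_id = vid, file = f, role = "image", modality = m,
        split = splits[i], seed = vol_seeds[i], stringsAsFactors = FALSE)
    }
    f <- sprintf("%s_mask.nii.gz", vid)
    write_nifti(vol$mask, file.path(out_dir, f))
    rows[[length(rows) + 1L]] <- data.frame(
      volume_id = vid, file = f, role = "mask", modality = NA_integer_,
      split = splits[i], seed = vol_seeds[i], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path Either the manifest file itself or the dataset directory.
#' @return The manifest data.frame with attribute `dir` set to the dataset
#'   directory.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.tsv")
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}
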