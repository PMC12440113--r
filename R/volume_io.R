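# NIfTI volume handling, isotropic resampling, stride-controlled slice
# extraction, slice preprocessing (percentile clamp + min-max + resize) and
# joint geometric augmentation.
#
# Conventions: volume axes are indexed 1..3 in stored order (no anatomical
# reorientation); slice indices in plans are 0-based with half-open ranges;
# the stride offset defaults to 0.

#' Construct an in-memory MRI volume
#'
#' @param grid 3D numeric array
#' @param spacing mm per axis, all > 0
#' @param source_path provenance string
#' @return an object of class `mri_volume`
#' @export
mri_volume <- function(grid, spacing = c(1, 1, 1), source_path = "") {
  if (length(dim(grid)) != 3L) stop("grid must have 3 axes")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(grid = grid, spacing = spacing, source_path = source_path),
            class = "mri_volume")
}

#' Read / write NIfTI volumes
#'
#' Grids and voxel spacing round-trip exactly through `write_volume()` then
#' `read_volume()` (intensities are stored as float64, labels/masks may be
#' written with `datatype = "int32"`).
#'
#' @param path a `.nii` or `.nii.gz` file
#' @param vol an [mri_volume()] or bare 3D array
#' @param datatype NIfTI storage type passed to RNifti
#' @return `read_volume` returns an [mri_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot parse '", path, "' as NIfTI: ",
                                           conditionMessage(e)))
  grid <- array(as.numeric(img), dim = dim(img)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  mri_volume(grid, spacing = sp, source_path = path)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, datatype = "double") {
  if (!inherits(vol, "mri_volume")) vol <- mri_volume(vol)
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Stride-based slice sampling plan
#'
#' Taking every k-th slice simulates a few-shot annotation budget: halving the
#' stride exactly doubles the slice count on even-length axes.
#'
#' @param k positive integer stride
#' @param axes subset of 1:3 to slice along
#' @param offset 0-based start index, `0 <= offset < k`
#' @return an object of class `stride_plan`
#' @export
stride_plan <- function(k, axes = 3L, offset = 0L) {
  k <- as.integer(k); offset <- as.integer(offset)
  if (k < 1L) stop("stride k must be >= 1")
  if (offset < 0L || offset >= k) stop("offset must satisfy 0 <= offset < k")
  if (!all(axes %in% 1:3)) stop("axes must be a subset of 1:3")
  structure(list(k = k, axes = as.integer(axes), offset = offset),
            class = "stride_plan")
}

#' Number of slices selected on an axis of given length
#' @param len axis length; @param k stride; @param offset 0-based start
#' @return `ceiling((len - offset) / k)`
#' @export
slice_count <- function(len, k, offset = 0L) as.integer(ceiling((len - offset) / k))

interp_axis <- function(grid, axis, new_len, pos, method) {
  # apply 1D interpolation along one axis at positions `pos` (1-based)
  idx_lo <- pmin(pmax(floor(pos), 1L), dim(grid)[axis])
  idx_hi <- pmin(idx_lo + 1L, dim(grid)[axis])
  w <- pmin(pmax(pos - idx_lo, 0), 1)
  take <- function(i) {
    switch(axis,
           grid[i, , , drop = FALSE],
           grid[, i, , drop = FALSE],
           grid[, , i, drop = FALSE])
  }
  if (method == "nearest") {
    out <- take(ifelse(w < 0.5, idx_lo, idx_hi))
  } else {
    lo <- take(idx_lo); hi <- take(idx_hi)
    # weight array broadcast along `axis`
    dm <- dim(lo)
    wv <- switch(axis,
                 array(rep(w, times = dm[2] * dm[3]), dim = dm),
                 aperm(array(rep(w, times = dm[1] * dm[3]), dim = dm[c(2, 1, 3)]), c(2, 1, 3)),
                 aperm(array(rep(w, times = dm[1] * dm[2]), dim = dm[c(3, 1, 2)]), c(2, 3, 1)))
    out <- lo * (1 - wv) + hi * wv
  }
  out
}

#' Resample a volume to isotropic voxels
#'
#' Target spacing is the minimum input spacing; each axis length is scaled by
#' its spacing ratio and rounded to the nearest integer. Intensities use
#' linear interpolation; masks and label volumes must use
#' `method = "nearest"`, which never invents new label values.
#'
#' @param vol an [mri_volume()]
#' @param method `"linear"` or `"nearest"`
#' @return an [mri_volume()] with isotropic spacing
#' @export
resample_isotropic <- function(vol, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(vol, "mri_volume"))
  sp <- vol$spacing
  target <- min(sp)
  if (all(sp == target)) return(vol)
  grid <- vol$grid
  for (axis in 1:3) {
    len <- dim(grid)[axis]
    new_len <- as.integer(round(len * sp[axis] / target))
    if (new_len == len) next
    # voxel-centre alignment: output voxel j sits at input position
    pos <- (seq_len(new_len) - 0.5) * len / new_len + 0.5
    grid <- interp_axis(grid, axis, new_len, pos, method)
  }
  mri_volume(grid, spacing = rep(target, 3L), source_path = vol$source_path)
}

#' Extract 2D slices according to a stride plan
#'
#' Per requested axis `a`, slice indices are `offset, offset + k, ...`
#' (0-based), giving `ceiling((len_a - offset) / k)` slices. Each returned
#' `slice_sample` carries provenance (volume id, axis, 0-based index).
#'
#' @param vol an [mri_volume()]
#' @param plan a [stride_plan()]
#' @param mask,labels optional companion volumes (same geometry) sliced jointly
#' @return list of `slice_sample` objects (raw, not yet preprocessed)
#' @export
extract_slices <- function(vol, plan, mask = NULL, labels = NULL) {
  stopifnot(inherits(vol, "mri_volume"), inherits(plan, "stride_plan"))
  d <- dim(vol$grid)
  out <- list(); n <- 0L
  grab <- function(arr, axis, i1) {
    switch(axis, arr[i1, , ], arr[, i1, ], arr[, , i1])
  }
  for (axis in plan$axes) {
    if (axis > length(d)) stop("axis ", axis, " out of range")
    idx0 <- seq.int(plan$offset, d[axis] - 1L, by = plan$k)
    for (i0 in idx0) {
      n <- n + 1L
      s <- list(image = grab(vol$grid, axis, i0 + 1L),
                brain_mask = if (!is.null(mask)) grab(mask, axis, i0 + 1L),
                label_grid = if (!is.null(labels)) grab(labels, axis, i0 + 1L),
                class_label = NULL,
                provenance = list(volume = vol$source_path, axis = axis, index = i0))
      class(s) <- "slice_sample"
      out[[n]] <- s
    }
  }
  out
}

#' Preprocessing configuration
#'
#' @param clamp_low,clamp_high intensity percentiles (defaults 0.1 and 99.9)
#' @param target_size output (H, W), default 224 x 224
#' @return an object of class `preprocess_config`
#' @export
preprocess_config <- function(clamp_low = 0.1, clamp_high = 99.9,
                              target_size = c(224L, 224L)) {
  if (!(clamp_low >= 0 && clamp_low < clamp_high && clamp_high <= 100))
    stop("need 0 <= clamp_low < clamp_high <= 100")
  target_size <- as.integer(rep(target_size, length.out = 2L))
  structure(list(clamp_low = clamp_low, clamp_high = clamp_high,
                 target_size = target_size),
            class = "preprocess_config")
}

resize2d <- function(m, target, nearest = FALSE) {
  if (all(dim(m) == target)) return(m)
  r <- EBImage::resize(m, w = target[1L], h = target[2L],
                       filter = if (nearest) "none" else "bilinear")
  matrix(EBImage::imageData(r), target[1L], target[2L])
}

#' Preprocess a raw slice
#'
#' Clamps intensities to the [clamp_low, clamp_high] percentile interval
#' (computed on this slice), min-max rescales to [0, 1], and resizes to
#' `target_size` (bilinear; any mask/label grid is resized nearest-neighbour).
#' A constant slice maps to all zeros and is flagged in provenance rather than
#' raising a division error, since aggregated cohorts contain empty slices.
#'
#' @param raw numeric matrix (a raw 2D slice) or a `slice_sample`
#' @param cfg a [preprocess_config()]
#' @param mask,labels optional companion grids, same shape as `raw`
#' @return a `slice_sample` with image values in [0, 1]
#' @export
preprocess_slice <- function(raw, cfg = preprocess_config(), mask = NULL,
                             labels = NULL) {
  if (inherits(raw, "slice_sample")) {
    mask <- mask %||% raw$brain_mask
    labels <- labels %||% raw$label_grid
    prov <- raw$provenance
    raw <- raw$image
  } else prov <- list(volume = "", axis = NA_integer_, index = NA_integer_)
  if (length(raw) == 0L) stop("slice is empty")
  q <- stats::quantile(raw, c(cfg$clamp_low, cfg$clamp_high) / 100,
                       names = FALSE, na.rm = FALSE)
  x <- pmin(pmax(raw, q[1L]), q[2L])
  rng <- q[2L] - q[1L]
  constant <- rng <= 0
  x <- if (constant) matrix(0, nrow(raw), ncol(raw)) else (x - q[1L]) / rng
  s <- list(image = resize2d(x, cfg$target_size),
            brain_mask = if (!is.null(mask))
              resize2d(matrix(as.numeric(mask), nrow(mask)), cfg$target_size, nearest = TRUE),
            label_grid = if (!is.null(labels))
              resize2d(matrix(as.numeric(labels), nrow(labels)), cfg$target_size, nearest = TRUE),
            class_label = NULL,
            provenance = c(prov, list(constant = constant)))
  class(s) <- "slice_sample"
  s
}

#' Augmentation configuration
#'
#' @param max_rotation_deg rotation drawn uniformly in +/- this many degrees
#' @param flip_probability probability of a horizontal flip
#' @param crop_fraction_range random crop side fraction (resized back)
#' @param rotation,flip,crop enable flags
#' @return an object of class `augment_config`
#' @export
augment_config <- function(max_rotation_deg = 10, flip_probability = 0.5,
                           crop_fraction_range = c(0.85, 1),
                           rotation = TRUE, flip = TRUE, crop = TRUE) {
  if (flip_probability < 0 || flip_probability > 1)
    stop("flip_probability must be in [0, 1]")
  structure(list(max_rotation_deg = max_rotation_deg,
                 flip_probability = flip_probability,
                 crop_fraction_range = crop_fraction_range,
                 rotation = rotation, flip = flip, crop = crop),
            class = "augment_config")
}

#' Random geometric augmentation of a slice
#'
#' The identical transform (rotation, flip, crop) is applied jointly to the
#' image, its brain mask and its label grid; masks and labels use
#' nearest-neighbour interpolation. Deterministic under a fixed seed. With all
#' flags disabled the input is returned unchanged.
#'
#' @param s a `slice_sample`
#' @param cfg an [augment_config()]
#' @param seed integer seed
#' @return an augmented `slice_sample`
#' @export
augment_slice <- function(s, cfg, seed = 0L) {
  stopifnot(inherits(s, "slice_sample"))
  if (!cfg$rotation && !cfg$flip && !cfg$crop) return(s)
  prm <- with_seed(substream_seed(seed, "augment"), list(
    angle = stats::runif(1L, -cfg$max_rotation_deg, cfg$max_rotation_deg),
    do_flip = stats::runif(1L) < cfg$flip_probability,
    frac = stats::runif(1L, cfg$crop_fraction_range[1L], cfg$crop_fraction_range[2L]),
    cx = stats::runif(1L), cy = stats::runif(1L)))
  tf <- function(m, nearest) {
    if (is.null(m)) return(NULL)
    d0 <- dim(m)
    if (cfg$rotation) {
      m <- EBImage::imageData(EBImage::rotate(m, prm$angle,
                                              filter = if (nearest) "none" else "bilinear",
                                              output.dim = d0, bg.col = 0))
      m <- matrix(m, d0[1L], d0[2L])
    }
    if (cfg$flip && prm$do_flip) m <- m[rev(seq_len(d0[1L])), , drop = FALSE]
    if (cfg$crop && prm$frac < 1) {
      side <- pmax(round(d0 * prm$frac), 2L)
      off <- c(floor(prm$cx * (d0[1L] - side[1L])), floor(prm$cy * (d0[2L] - side[2L])))
      m <- m[off[1L] + seq_len(side[1L]), off[2L] + seq_len(side[2L]), drop = FALSE]
      m <- resize2d(m, d0, nearest = nearest)
    }
    m
  }
  s$image <- pmin(pmax(tf(s$image, FALSE), 0), 1)
  s$brain_mask <- tf(s$brain_mask, TRUE)
  s$label_grid <- tf(s$label_grid, TRUE)
  s
}

#' Write / read a plain-text slice manifest
#'
#' One row per sample: path, axis, 0-based index, label. Tab-separated.
#' @param manifest a data.frame
#' @param path file path
#' @export
write_slice_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_slice_manifest
#' @export
read_slice_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
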