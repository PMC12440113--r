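# Synthetic head phantoms: nested-ellipsoid multi-tissue geometry with
# per-subject affine jitter, pseudo-sequence contrast rendering (bias field +
# noise), and balanced labelled slice sets for sequence classification.
#
# Phantoms stand in for real cohorts at desk scale: they provide exactly the
# supervision the models need (intensity volumes, binary brain masks, integer
# tissue labels) with known ground truth and full determinism per seed.

TISSUE_BASE <- c("background", "skull", "csf", "gray_matter", "white_matter",
                 "ventricle")

#' Tissue class names for a phantom specification
#' @param n_deep number of small deep structures
#' @return character vector; class label of tissue `i` is `i - 1` (background = 0)
#' @export
tissue_classes <- function(n_deep = 3L) {
  c(TISSUE_BASE, if (n_deep > 0L) paste0("deep_", seq_len(n_deep)))
}

#' Default tissue-contrast table
#'
#' One column per pseudo-sequence, one row per tissue, entries are mean
#' intensities in [0, 1]. Orderings mimic the standard MRI contrasts: pT1 has
#' white > gray > CSF, pT2 has CSF > gray > white, pFLAIR suppresses CSF, pPD
#' compresses the gray/white contrast. Distinct orderings make sequence
#' identity learnable from a slice.
#'
#' @param n_deep number of deep structures (each gets its own row)
#' @return numeric matrix with tissue rownames and sequence colnames
#' @export
default_contrast_table <- function(n_deep = 3L) {
  base <- rbind(
    background   = c(pT1 = 0.02, pT2 = 0.02, pFLAIR = 0.02, pPD = 0.02),
    skull        = c(0.10, 0.08, 0.09, 0.12),
    csf          = c(0.20, 0.90, 0.12, 0.50),
    gray_matter  = c(0.60, 0.55, 0.65, 0.75),
    white_matter = c(0.85, 0.35, 0.45, 0.60),
    ventricle    = c(0.15, 0.92, 0.08, 0.48)
  )
  if (n_deep > 0L) {
    deep <- t(vapply(seq_len(n_deep), function(i)
      c(0.50, 0.60, 0.55, 0.65) + 0.03 * i, numeric(4L)))
    rownames(deep) <- paste0("deep_", seq_len(n_deep))
    base <- rbind(base, deep)
  }
  colnames(base) <- c("pT1", "pT2", "pFLAIR", "pPD")
  base
}

#' Specification of a synthetic head phantom
#'
#' @param grid_size voxels per axis (scalar or length 3); minimum 32
#' @param n_deep number of small deep structures inside white matter
#' @param skull_thickness skull rim thickness in voxels
#' @param geometry_jitter per-subject affine perturbation scale (fraction)
#' @param noise_sd additive Gaussian noise SD in intensity units
#' @param bias_field_order polynomial order of the multiplicative bias field;
#'   0 disables it exactly
#' @param spacing voxel spacing in mm per axis
#' @param contrast_table tissue x sequence mean-intensity matrix
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_size = 96L, n_deep = 3L, skull_thickness = 3L,
                         geometry_jitter = 0.04, noise_sd = 0.02,
                         bias_field_order = 2L, spacing = c(1, 1, 1),
                         contrast_table = default_contrast_table(n_deep)) {
  grid_size <- as.integer(rep(grid_size, length.out = 3L))
  if (any(grid_size < 32L)) stop("grid_size must be at least 32 voxels per axis")
  if (n_deep < 0L) stop("n_deep must be >= 0")
  stopifnot(all(spacing > 0), length(spacing) == 3L)
  tc <- tissue_classes(n_deep)
  if (!all(tc %in% rownames(contrast_table)))
    stop("contrast_table must have a row for every tissue class")
  structure(list(grid_size = grid_size, n_deep = as.integer(n_deep),
                 skull_thickness = skull_thickness,
                 geometry_jitter = geometry_jitter, noise_sd = noise_sd,
                 bias_field_order = as.integer(bias_field_order),
                 spacing = as.numeric(spacing),
                 contrast_table = contrast_table,
                 tissues = tc),
            class = "phantom_spec")
}

# normalized, jittered, rotated coordinates for every voxel: N x 3 matrix
phantom_coords <- function(d, jitter, seed) {
  with_seed(seed, {
    sc <- 1 + stats::runif(3L, -jitter, jitter)
    tr <- stats::runif(3L, -jitter, jitter) * d / 8
    th <- stats::runif(1L, -pi, pi) * jitter * 4
    ctr <- (d + 1) / 2 + tr
    x <- (rep(seq_len(d[1L]), times = d[2L] * d[3L]) - ctr[1L]) / (d[1L] / 2)
    y <- (rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]) - ctr[2L]) / (d[2L] / 2)
    z <- (rep(seq_len(d[3L]), each = d[1L] * d[2L]) - ctr[3L]) / (d[3L] / 2)
    xr <- (cos(th) * x - sin(th) * y) / sc[1L]
    yr <- (sin(th) * x + cos(th) * y) / sc[2L]
    cbind(xr, yr, z / sc[3L])
  })
}

in_ellipsoid <- function(co, center, radii) {
  ((co[, 1L] - center[1L]) / radii[1L])^2 +
    ((co[, 2L] - center[2L]) / radii[2L])^2 +
    ((co[, 3L] - center[3L]) / radii[3L])^2 <= 1
}

#' Generate one phantom subject
#'
#' Builds a nested-ellipsoid head: skull rim, CSF layer, gray-matter shell,
#' white-matter core, two elongated ventricles and `n_deep` small spherical
#' deep structures strictly inside white matter. The same `(spec, subject_seed)`
#' pair reproduces the identical volume bit-for-bit.
#'
#' @param spec a [phantom_spec()]
#' @param subject_seed integer seed controlling the per-subject geometry jitter
#' @return an object of class `phantom_volume`: list with integer array
#'   `labels` (0 = background), binary array `brain_mask` (union of all
#'   intracranial classes), `spacing`, and `subject_seed`
#' @export
make_phantom_volume <- function(spec, subject_seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_size
  co <- phantom_coords(d, spec$geometry_jitter,
                       substream_seed(subject_seed, "geometry"))
  lab <- integer(prod(d))

  skull_out <- c(0.92, 0.88, 0.90)
  thick <- spec$skull_thickness / (d / 2)
  skull_in <- skull_out - thick
  if (any(skull_in <= 0)) stop("grid too small to host the skull rim")
  csf_out <- skull_in
  gray_out <- csf_out - 2 / (d / 2)
  if (any(gray_out <= 0)) stop("grid too small to host the intracranial tissues")
  white_out <- gray_out * 0.72

  ctr0 <- c(0, 0, 0)
  lab[in_ellipsoid(co, ctr0, skull_out)] <- 1L
  lab[in_ellipsoid(co, ctr0, skull_in)] <- 2L
  lab[in_ellipsoid(co, ctr0, gray_out)] <- 3L
  lab[in_ellipsoid(co, ctr0, white_out)] <- 4L

  vent_r <- c(0.05, 0.22, 0.07)
  for (s in c(-1, 1)) {
    sel <- in_ellipsoid(co, c(s * 0.14, 0.03, 0.05), vent_r) & lab == 4L
    lab[sel] <- 5L
  }
  if (!any(lab == 5L)) stop("grid too small to host the ventricles")

  if (spec$n_deep > 0L) {
    for (i in seq_len(spec$n_deep)) {
      phi <- 2 * pi * i / spec$n_deep + 0.4
      ctr <- c(0.30 * cos(phi), 0.30 * sin(phi), -0.18)
      sel <- in_ellipsoid(co, ctr, rep(0.055, 3L)) & lab == 4L
      if (!any(sel)) stop("grid too small to host deep structure ", i)
      lab[sel] <- 5L + i
    }
  }

  labels <- array(lab, dim = d)
  structure(list(labels = labels,
                 brain_mask = array(as.integer(lab >= 2L), dim = d),
                 spacing = spec$spacing,
                 subject_seed = subject_seed),
            class = "phantom_volume")
}

# smooth multiplicative bias field, mean-normalized to 1; order 0 is exactly 1
bias_field <- function(d, order, seed) {
  if (order <= 0L) return(1)
  with_seed(seed, {
    x <- (rep(seq_len(d[1L]), times = d[2L] * d[3L]) - (d[1L] + 1) / 2) / (d[1L] / 2)
    y <- (rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]) - (d[2L] + 1) / 2) / (d[2L] / 2)
    z <- (rep(seq_len(d[3L]), each = d[1L] * d[2L]) - (d[3L] + 1) / 2) / (d[3L] / 2)
    f <- rep(1, length(x))
    for (a in 0:order) for (b in 0:(order - a)) for (cc in 0:(order - a - b)) {
      deg <- a + b + cc
      if (deg == 0L) next
      f <- f + stats::rnorm(1L, 0, 0.12 / deg) * x^a * y^b * z^cc
    }
    f <- pmax(f, 0.05)
    f / mean(f)
  })
}

#' Render an intensity volume for one pseudo-sequence
#'
#' Intensity = contrast_table[tissue, sequence] x smooth multiplicative bias
#' field + additive Gaussian noise. With `noise_sd = 0` and
#' `bias_field_order = 0` the output is exactly piecewise constant at the
#' contrast-table values.
#'
#' @param phantom a `phantom_volume` (or a raw integer label array)
#' @param sequence a column name of `spec$contrast_table`
#' @param spec the [phantom_spec()] used to generate the phantom
#' @param noise_seed integer seed for bias-field coefficients and noise
#' @return an [mri_volume()] with the same grid and spacing
#' @export
render_sequence <- function(phantom, sequence, spec, noise_seed = 0L) {
  labels <- if (inherits(phantom, "phantom_volume")) phantom$labels else phantom
  ct <- spec$contrast_table
  if (!sequence %in% colnames(ct))
    stop("unknown sequence '", sequence, "'; contrast table has: ",
         paste(colnames(ct), collapse = ", "))
  d <- dim(labels)
  lev <- ct[spec$tissues, sequence]
  inten <- lev[as.vector(labels) + 1L]
  f <- bias_field(d, spec$bias_field_order, substream_seed(noise_seed, "bias"))
  inten <- pmax(inten * f, 0)
  if (spec$noise_sd > 0) {
    inten <- inten + with_seed(substream_seed(noise_seed, "noise"),
                               stats::rnorm(length(inten), 0, spec$noise_sd))
  }
  mri_volume(array(inten, dim = d), spacing = spec$spacing,
             source_path = paste0("phantom:", sequence))
}

#' Balanced labelled slice set for sequence classification
#'
#' Draws `n_per_class` axial slices per pseudo-sequence, each from a distinct
#' phantom subject and a random brain-covering position, preprocessed to
#' `target_size`. The class label of a sample is the 1-based index of its
#' sequence in `sequences`.
#'
#' @param n_per_class slices per sequence (>= 1)
#' @param sequences character vector of contrast-table column names
#' @param seed master seed; fixed seed reproduces the identical manifest
#' @param spec a [phantom_spec()]
#' @param target_size slice side length after preprocessing
#' @return list with `samples` (list of `slice_sample`s) and `manifest`
#'   (data.frame: sample, sequence, class, subject_seed, axis, index)
#' @export
make_classification_set <- function(n_per_class, sequences, seed,
                                    spec = phantom_spec(grid_size = 64L),
                                    target_size = 64L) {
  if (length(sequences) == 0L) stop("sequences must be non-empty")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  cfg <- preprocess_config(target_size = c(target_size, target_size))
  samples <- list(); rows <- list(); k <- 0L
  for (ci in seq_along(sequences)) {
    for (r in seq_len(n_per_class)) {
      k <- k + 1L
      subj <- substream_seed(seed, sprintf("subject_%d_%d", ci, r))
      ph <- make_phantom_volume(spec, subj)
      vol <- render_sequence(ph, sequences[ci], spec,
                             noise_seed = substream_seed(seed, sprintf("noise_%d_%d", ci, r)))
      cov <- apply(ph$brain_mask, 3L, mean)
      ok <- which(cov > 0.05)
      idx <- with_seed(substream_seed(seed, sprintf("pos_%d_%d", ci, r)),
                       ok[sample.int(length(ok), 1L)])
      s <- preprocess_slice(vol$grid[, , idx], cfg,
                            mask = ph$brain_mask[, , idx])
      s$class_label <- ci
      s$provenance$volume <- paste0("phantom_subject_", subj)
      s$provenance$axis <- 3L
      s$provenance$index <- idx
      samples[[k]] <- s
      rows[[k]] <- data.frame(sample = k, sequence = sequences[ci], class = ci,
                              subject_seed = subj, axis = 3L, index = idx)
    }
  }
  list(samples = samples, manifest = do.call(rbind, rows))
}
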