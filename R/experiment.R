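# Few-shot experiment plumbing: labelled phantom slice sets for segmentation,
# the paired-method few-shot benchmark, and pretraining corpus construction.

#' Build a pretraining slice corpus from phantoms
#'
#' Draws axial slices (all coverages, including empty and near-empty slices so
#' the coverage weighting is exercised) from multiple phantom subjects across
#' pseudo-sequences.
#'
#' @param n_slices number of (image, brain mask) pairs
#' @param seed master seed
#' @param spec a [phantom_spec()]
#' @param target_size slice side length after preprocessing
#' @param sequences pseudo-sequences to draw from
#' @param slices_per_subject slices taken per generated subject
#' @return list of `slice_sample`s with `image` and binary `brain_mask`
#' @export
make_pretrain_set <- function(n_slices, seed = 0L,
                              spec = phantom_spec(grid_size = 64L),
                              target_size = 64L,
                              sequences = c("pT1", "pT2"),
                              slices_per_subject = 10L) {
  cfg <- preprocess_config(target_size = c(target_size, target_size))
  n_subj <- ceiling(n_slices / slices_per_subject)
  out <- vector("list", n_slices); k <- 0L
  for (si in seq_len(n_subj)) {
    subj <- substream_seed(seed, paste0("pretrain_subject_", si))
    ph <- make_phantom_volume(spec, subj)
    sq <- sequences[(si - 1L) %% length(sequences) + 1L]
    vol <- render_sequence(ph, sq, spec,
                           noise_seed = substream_seed(seed, paste0("pretrain_noise_", si)))
    nz <- dim(ph$labels)[3L]
    idx <- with_seed(substream_seed(seed, paste0("pretrain_pos_", si)),
                     sample.int(nz, min(slices_per_subject, nz)))
    for (i in idx) {
      if (k >= n_slices) break
      k <- k + 1L
      s <- preprocess_slice(vol$grid[, , i], cfg, mask = ph$brain_mask[, , i])
      s$provenance$volume <- paste0("phantom_subject_", subj)
      s$provenance$axis <- 3L; s$provenance$index <- i
      out[[k]] <- s
    }
  }
  out[seq_len(k)]
}

#' Build a labelled phantom slice set for segmentation
#'
#' Axial slices with at least 10% brain coverage, labelled either with the
#' binary brain mask (`task = "skullstrip"`) or the full tissue label map
#' (`task = "multiclass"`). Subjects are derived from `subject_tag`, so two
#' sets built with different tags share no subjects (the few-shot benchmark
#' enforces this).
#'
#' @param n_slices number of labelled slices
#' @param seed master seed
#' @param spec a [phantom_spec()]
#' @param target_size slice side after preprocessing
#' @param sequence pseudo-sequence rendered
#' @param task `"skullstrip"` or `"multiclass"`
#' @param slices_per_subject slices per generated subject
#' @param subject_tag string namespacing the subject seeds
#' @return list with `samples` (slice_samples carrying `label_grid`),
#'   `subjects` (per-sample subject id), `num_classes`
#' @export
make_segmentation_set <- function(n_slices, seed = 0L,
                                  spec = phantom_spec(grid_size = 64L),
                                  target_size = 64L, sequence = "pT1",
                                  task = c("skullstrip", "multiclass"),
                                  slices_per_subject = 5L,
                                  subject_tag = "train") {
  task <- match.arg(task)
  cfg <- preprocess_config(target_size = c(target_size, target_size))
  n_subj <- ceiling(n_slices / slices_per_subject)
  samples <- vector("list", n_slices); subjects <- character(n_slices); k <- 0L
  for (si in seq_len(n_subj)) {
    subj <- substream_seed(seed, paste0("seg_", subject_tag, "_subject_", si))
    ph <- make_phantom_volume(spec, subj)
    vol <- render_sequence(ph, sequence, spec,
                           noise_seed = substream_seed(seed, paste0("seg_", subject_tag, "_noise_", si)))
    cov <- apply(ph$brain_mask, 3L, mean)
    ok <- which(cov >= 0.10)
    idx <- with_seed(substream_seed(seed, paste0("seg_", subject_tag, "_pos_", si)),
                     sample(ok, min(slices_per_subject, length(ok))))
    for (i in idx) {
      if (k >= n_slices) break
      k <- k + 1L
      lab <- if (task == "skullstrip") ph$brain_mask[, , i] else {
        l <- ph$labels[, , i]
        l[l == 1L] <- 0L            # skull is outside the segmentation target
        l[l > 1L] <- l[l > 1L] - 1L # csf..deep become 1..
        l
      }
      s <- preprocess_slice(vol$grid[, , i], cfg, mask = ph$brain_mask[, , i],
                            labels = lab)
      s$label_grid <- matrix(as.integer(round(s$label_grid)),
                             nrow(s$label_grid), ncol(s$label_grid))
      s$provenance$volume <- paste0("phantom_subject_", subj)
      s$provenance$axis <- 3L; s$provenance$index <- i
      samples[[k]] <- s
      subjects[k] <- paste0(subject_tag, "_", subj)
    }
  }
  nc <- if (task == "skullstrip") 2L else max(2L, 1L + max(vapply(samples[seq_len(k)],
        function(s) max(s$label_grid), integer(1L))))
  list(samples = samples[seq_len(k)], subjects = subjects[seq_len(k)],
       num_classes = nc, task = task)
}

#' Paired few-shot segmentation benchmark
#'
#' Trains every requested method on the identical labelled subset with the
#' same seed and budget, then evaluates all of them on a fixed held-out set.
#' Train and test sets must come from disjoint subjects; any overlap is a
#' hard error (leakage guard).
#'
#' @param encoder a pretrained, frozen `mae_model`
#' @param train_set,test_set sets from [make_segmentation_set()]
#' @param methods subset of `"mae_funet"`, `"unet"`, `"mae_direct"`
#' @param fusion_strategy fusion used by the MAE-FUnet entry
#' @param depth,base_dim,fusion_layers backbone sizing shared by FUnet/U-Net
#' @param steps,batch_size,lr shared training budget
#' @param loss_cfg a [hybrid_loss_config()]
#' @param seed shared seed
#' @return list: `reports` (named `metric_report`s), `summary` data.frame
#'   with mean foreground Dice/IoU per method, `models` (trained models)
#' @export
fewshot_benchmark <- function(encoder, train_set, test_set,
                              methods = c("mae_funet", "unet", "mae_direct"),
                              fusion_strategy = "concat", depth = 2L,
                              base_dim = 8L, fusion_layers = c(1L, 2L, 4L),
                              steps = 300L, batch_size = 4L, lr = 1e-3,
                              loss_cfg = hybrid_loss_config(), seed = 0L) {
  if (length(methods) < 1L) stop("configure at least one method")
  overlap <- intersect(unique(train_set$subjects), unique(test_set$subjects))
  if (length(overlap))
    stop("train/test subject overlap detected: ", paste(overlap, collapse = ", "))
  if (train_set$num_classes != test_set$num_classes)
    stop("train and test sets disagree on num_classes")
  nc <- train_set$num_classes
  S <- nrow(train_set$samples[[1L]]$image)
  build <- function(method) {
    switch(method,
           mae_funet = funet_init(funet_config(num_classes = nc, image_size = S,
                                               depth = depth, base_dim = base_dim,
                                               fusion_strategy = fusion_strategy,
                                               fusion_layers = fusion_layers),
                                  encoder, seed = seed),
           unet = funet_init(funet_config(num_classes = nc, image_size = S,
                                          depth = depth, base_dim = base_dim,
                                          fusion_strategy = "none"),
                             encoder, seed = seed),
           mae_direct = mae_direct_init(nc, encoder, seed = seed),
           stop("unknown method '", method, "'"))
  }
  truths <- lapply(test_set$samples, function(s) s$label_grid)
  reports <- list(); models <- list(); rows <- list()
  for (m in methods) {
    model <- train_segmenter(build(m), train_set$samples, loss_cfg,
                             steps = steps, batch_size = batch_size,
                             lr = lr, seed = seed)
    preds <- lapply(test_set$samples, function(s)
      forward_segment(model, s$image)$label_map)
    rep <- evaluate_dataset(preds, truths, classes = 0:(nc - 1L))
    reports[[m]] <- rep
    models[[m]] <- model
    rows[[m]] <- data.frame(method = m, mean_dice = rep$mean_dice,
                            mean_iou = rep$mean_iou,
                            trainable_params = count_trainable(model))
  }
  list(reports = reports, summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       models = models)
}
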