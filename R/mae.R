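# Vision-transformer masked autoencoder with a brain-coverage-weighted
# reconstruction loss.
#
# The batch loss is L = (1/N) * sum_i w_i * l~_i where l~_i is the mean
# squared error over the masked patches of sample i and w_i in [0, 1] is the
# fraction of slice pixels inside the brain mask (with a configurable floor).
# The divisor is N, not sum(w): slices with little brain content genuinely
# contribute less, they are not renormalized away.

#' Vision-transformer MAE configuration
#'
#' Defaults mirror the ViT-Base sizing (16x16 patches, 12 encoder layers,
#' 768-dim embeddings) with the customary lightweight decoder. `mask_ratio`
#' defaults to 0.75. Use [vit_tiny_config()] for desk-scale runs.
#'
#' @param image_size input side length (square slices)
#' @param patch_size patch side; must divide `image_size`
#' @param channels input channels (1 for MRI slices)
#' @param encoder_dim,encoder_depth,encoder_heads transformer encoder sizing
#' @param decoder_dim,decoder_depth,decoder_heads decoder sizing
#' @param mask_ratio fraction of patches masked during pretraining, in (0, 1)
#' @param norm_pix_targets normalize each target patch to zero mean / unit SD
#'   before the reconstruction loss (off by default: plain MSE on pixels)
#' @param mlp_ratio feed-forward expansion factor
#' @return an object of class `vit_config`
#' @export
vit_config <- function(image_size = 224L, patch_size = 16L, channels = 1L,
                       encoder_dim = 768L, encoder_depth = 12L, encoder_heads = 12L,
                       decoder_dim = 512L, decoder_depth = 8L, decoder_heads = 16L,
                       mask_ratio = 0.75, norm_pix_targets = FALSE, mlp_ratio = 4L) {
  if (image_size %% patch_size != 0L) stop("image_size must be divisible by patch_size")
  if (mask_ratio <= 0 || mask_ratio >= 1) stop("mask_ratio must be in (0, 1)")
  if (encoder_depth < 1L || decoder_depth < 1L) stop("depths must be >= 1")
  if (encoder_dim %% encoder_heads != 0L || decoder_dim %% decoder_heads != 0L)
    stop("embedding dims must be divisible by head counts")
  structure(list(image_size = as.integer(image_size), patch_size = as.integer(patch_size),
                 channels = as.integer(channels), encoder_dim = as.integer(encoder_dim),
                 encoder_depth = as.integer(encoder_depth), encoder_heads = as.integer(encoder_heads),
                 decoder_dim = as.integer(decoder_dim), decoder_depth = as.integer(decoder_depth),
                 decoder_heads = as.integer(decoder_heads), mask_ratio = mask_ratio,
                 norm_pix_targets = norm_pix_targets, mlp_ratio = as.integer(mlp_ratio)),
            class = "vit_config")
}

#' Reduced ViT preset for desk-scale experiments
#' @param image_size,patch_size,... overrides passed to [vit_config()]
#' @inheritParams vit_config
#' @return a `vit_config`
#' @export
vit_tiny_config <- function(image_size = 64L, patch_size = 8L,
                            encoder_dim = 32L, encoder_depth = 4L, encoder_heads = 2L,
                            decoder_dim = 32L, decoder_depth = 1L, decoder_heads = 2L,
                            ...) {
  vit_config(image_size = image_size, patch_size = patch_size,
             encoder_dim = encoder_dim, encoder_depth = encoder_depth,
             encoder_heads = encoder_heads, decoder_dim = decoder_dim,
             decoder_depth = decoder_depth, decoder_heads = decoder_heads, ...)
}

n_tokens_of <- function(cfg) (cfg$image_size %/% cfg$patch_size)^2L

# ---- patch rearrangement ----------------------------------------------------

patch_index <- function(H, p) {
  cache_get(sprintf("pat_%d_%d", H, p), function() {
    g <- H %/% p
    M <- matrix(0L, g * g, p * p)
    for (r in seq_len(g)) for (cc in seq_len(g)) {
      t <- (r - 1L) * g + cc                      # raster (row-major) patch order
      for (pi in seq_len(p)) for (pj in seq_len(p)) {
        o <- (pi - 1L) * p + pj                   # row-major within the patch
        i <- (r - 1L) * p + pi; j <- (cc - 1L) * p + pj
        M[t, o] <- i + (j - 1L) * H
      }
    }
    M
  })
}

#' Rearrange an image into a patch matrix and back
#'
#' Patches are enumerated in row-major raster order over the patch grid, and
#' pixels row-major within each patch. `unpatchify(patchify(x))` is exact.
#'
#' @param image square numeric matrix with side divisible by `patch_size`
#' @param patch_size patch side length
#' @return `patchify`: an (n_patches x patch_size^2) matrix.
#' @export
patchify <- function(image, patch_size) {
  H <- nrow(image)
  if (H != ncol(image)) stop("image must be square")
  if (H %% patch_size != 0L) stop("image side must be divisible by patch_size")
  M <- patch_index(H, patch_size)
  matrix(image[as.vector(M)], nrow(M), ncol(M))
}

#' @rdname patchify
#' @param patches a patch matrix as produced by `patchify`
#' @param image_size side length of the reconstructed image
#' @export
unpatchify <- function(patches, image_size, patch_size) {
  M <- patch_index(image_size, patch_size)
  if (!all(dim(patches) == dim(M))) stop("patch matrix shape does not match")
  out <- matrix(0, image_size, image_size)
  out[as.vector(M)] <- as.vector(patches)
  out
}

# ---- masking ----------------------------------------------------------------

#' Sample a random masking plan
#'
#' Uniform sampling without replacement of `round(ratio * n_tokens)` token
#' indices (round half away from zero). Degenerate plans (0 or all tokens
#' masked) are refused.
#'
#' @param n_tokens number of patch tokens
#' @param ratio masking ratio in (0, 1)
#' @param seed integer seed; the same seed reproduces the identical plan
#' @return an object of class `masking_plan` with sorted `masked` and
#'   `visible` 1-based index vectors
#' @export
sample_masking <- function(n_tokens, ratio, seed = 0L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n_mask <- as.integer(round_half_up(ratio * n_tokens))
  if (n_mask == 0L || n_mask == n_tokens)
    stop("degenerate masking plan: ", n_mask, " of ", n_tokens, " tokens masked")
  masked <- with_seed(seed, sort(sample.int(n_tokens, n_mask)))
  structure(list(masked = masked, visible = setdiff(seq_len(n_tokens), masked),
                 ratio = ratio, seed = seed, n_tokens = as.integer(n_tokens)),
            class = "masking_plan")
}

# ---- positional embeddings --------------------------------------------------

# fixed 2D sine-cosine embeddings on a g x g grid, row-major token order;
# row 1 of the returned (T+1) x dim matrix is the all-zero [CLS] position
posemb_sincos_2d <- function(g, dim) {
  q <- dim %/% 4L
  pe <- matrix(0, g * g + 1L, dim)
  if (q > 0L) {
    omega <- 1 / 10000^((seq_len(q) - 1) / q)
    r <- rep(seq_len(g), each = g); cc <- rep(seq_len(g), times = g)
    t <- (r - 1L) * g + cc   # row-major order
    for (k in seq_len(q)) {
      pe[t + 1L, k] <- sin(r * omega[k])
      pe[t + 1L, q + k] <- cos(r * omega[k])
      pe[t + 1L, 2L * q + k] <- sin(cc * omega[k])
      pe[t + 1L, 3L * q + k] <- cos(cc * omega[k])
    }
  }
  pe
}

# ---- initialization ---------------------------------------------------------

tn <- function(n, sd = 0.02) pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)

init_block <- function(prefix, dim, mlp_ratio) {
  h <- dim * mlp_ratio
  p <- list(
    matrix(1, 1, dim), matrix(0, 1, dim),                 # ln1 g, b
    matrix(tn(dim * dim), dim, dim), matrix(0, 1, dim),   # wq, bq
    matrix(tn(dim * dim), dim, dim), matrix(0, 1, dim),   # wk, bk
    matrix(tn(dim * dim), dim, dim), matrix(0, 1, dim),   # wv, bv
    matrix(tn(dim * dim), dim, dim), matrix(0, 1, dim),   # wo, bo
    matrix(1, 1, dim), matrix(0, 1, dim),                 # ln2 g, b
    matrix(tn(dim * h), dim, h), matrix(0, 1, h),         # mlp w1, b1
    matrix(tn(dim * h), h, dim), matrix(0, 1, dim))       # mlp w2, b2
  names(p) <- paste0(prefix, "_", c("ln1_g", "ln1_b", "wq", "bq", "wk", "bk",
                                    "wv", "bv", "wo", "bo", "ln2_g", "ln2_b",
                                    "w1", "b1", "w2", "b2"))
  p
}

#' Initialize an MAE model
#'
#' @param cfg a [vit_config()]
#' @param seed integer seed for weight initialization
#' @return an object of class `mae_model` (also the checkpoint content):
#'   config, flat named weight list, optimizer state, seed and training history
#' @export
mae_init <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "vit_config"))
  with_seed(substream_seed(seed, "init"), {
    D <- cfg$encoder_dim; Dd <- cfg$decoder_dim
    pp <- cfg$patch_size^2L * cfg$channels
    params <- c(
      list(pe_w = matrix(tn(pp * D), pp, D), pe_b = matrix(0, 1, D),
           cls = matrix(tn(D), 1, D)),
      do.call(c, lapply(seq_len(cfg$encoder_depth), function(i)
        init_block(paste0("e", i), D, cfg$mlp_ratio))),
      list(enc_ln_g = matrix(1, 1, D), enc_ln_b = matrix(0, 1, D),
           dec_w = matrix(tn(D * Dd), D, Dd), dec_b = matrix(0, 1, Dd),
           mask_tok = matrix(tn(Dd), 1, Dd)),
      do.call(c, lapply(seq_len(cfg$decoder_depth), function(i)
        init_block(paste0("d", i), Dd, cfg$mlp_ratio))),
      list(dec_ln_g = matrix(1, 1, Dd), dec_ln_b = matrix(0, 1, Dd),
           pred_w = matrix(tn(Dd * pp), Dd, pp), pred_b = matrix(0, 1, pp)))
    g <- cfg$image_size %/% cfg$patch_size
    structure(list(cfg = cfg, params = params,
                   pos_enc = posemb_sincos_2d(g, D),
                   pos_dec = posemb_sincos_2d(g, Dd),
                   opt_state = NULL, seed = seed, history = numeric(0)),
              class = "mae_model")
  })
}

# ---- forward graphs ---------------------------------------------------------

attn_block_nodes <- function(x, p, prefix, heads) {
  g1 <- p[[paste0(prefix, "_ln1_g")]]; b1 <- p[[paste0(prefix, "_ln1_b")]]
  h <- ag_layernorm(x, g1, b1)
  D <- ncol(h$value); dh <- D %/% heads
  q <- ag_add_vec(ag_matmul(h, p[[paste0(prefix, "_wq")]]), p[[paste0(prefix, "_bq")]])
  k <- ag_add_vec(ag_matmul(h, p[[paste0(prefix, "_wk")]]), p[[paste0(prefix, "_bk")]])
  v <- ag_add_vec(ag_matmul(h, p[[paste0(prefix, "_wv")]]), p[[paste0(prefix, "_bv")]])
  heads_out <- NULL
  for (hd in seq_len(heads)) {
    cols <- (hd - 1L) * dh + seq_len(dh)
    at <- ag_softmax_rows(ag_scale(ag_matmul_tb(ag_cols(q, cols), ag_cols(k, cols)),
                                   1 / sqrt(dh)))
    o <- ag_matmul(at, ag_cols(v, cols))
    heads_out <- if (is.null(heads_out)) o else ag_cbind2(heads_out, o)
  }
  o <- ag_add_vec(ag_matmul(heads_out, p[[paste0(prefix, "_wo")]]),
                  p[[paste0(prefix, "_bo")]])
  x <- ag_add(x, o)
  h2 <- ag_layernorm(x, p[[paste0(prefix, "_ln2_g")]], p[[paste0(prefix, "_ln2_b")]])
  m <- ag_add_vec(ag_matmul(ag_gelu(ag_add_vec(ag_matmul(h2, p[[paste0(prefix, "_w1")]]),
                                               p[[paste0(prefix, "_b1")]])),
                            p[[paste0(prefix, "_w2")]]), p[[paste0(prefix, "_b2")]])
  ag_add(x, m)
}

# encoder graph; returns per-layer patch-token nodes, final normalized node
# (row 1 = [CLS]) and the kept token indices
mae_encoder_nodes <- function(model, pnodes, image, plan = NULL) {
  cfg <- model$cfg
  if (!all(dim(image) == cfg$image_size))
    stop("image shape ", paste(dim(image), collapse = "x"),
         " does not match config image_size ", cfg$image_size)
  patches <- patchify(image, cfg$patch_size)
  keep <- if (is.null(plan)) seq_len(nrow(patches)) else plan$visible
  emb <- ag_add_vec(ag_matmul(ag_const(patches), pnodes$pe_w), pnodes$pe_b)
  emb <- ag_add(emb, ag_const(model$pos_enc[-1L, , drop = FALSE]))
  if (!is.null(plan)) emb <- ag_rows(emb, keep)
  x <- ag_rbind2(pnodes$cls, emb)
  layers <- vector("list", cfg$encoder_depth)
  for (i in seq_len(cfg$encoder_depth)) {
    x <- attn_block_nodes(x, pnodes, paste0("e", i), cfg$encoder_heads)
    layers[[i]] <- ag_rows(x, 1L + seq_along(keep))
  }
  final <- ag_layernorm(x, pnodes$enc_ln_g, pnodes$enc_ln_b)
  list(layers = layers, final = final, keep = keep)
}

mae_decoder_nodes <- function(model, pnodes, enc_final, plan) {
  cfg <- model$cfg
  Tn <- n_tokens_of(cfg)
  emb <- ag_add_vec(ag_matmul(enc_final, pnodes$dec_w), pnodes$dec_b)
  nvis <- length(plan$visible)
  nmask <- length(plan$masked)
  comb <- ag_rbind2(emb, ag_tile_rows(pnodes$mask_tok, nmask))
  # reorder [cls, visible..., mask tokens...] into [cls, token 1..T]
  rowsel <- integer(Tn + 1L); rowsel[1L] <- 1L
  rowsel[plan$visible + 1L] <- 1L + seq_len(nvis)
  rowsel[plan$masked + 1L] <- 1L + nvis + seq_len(nmask)
  x <- ag_add(ag_rows(comb, rowsel), ag_const(model$pos_dec))
  for (i in seq_len(cfg$decoder_depth))
    x <- attn_block_nodes(x, pnodes, paste0("d", i), cfg$decoder_heads)
  x <- ag_layernorm(x, pnodes$dec_ln_g, pnodes$dec_ln_b)
  pred <- ag_add_vec(ag_matmul(x, pnodes$pred_w), pnodes$pred_b)
  ag_rows(pred, 1L + seq_len(Tn))
}

#' Encode an image with the MAE encoder (inference)
#'
#' In pretraining mode (a [sample_masking()] plan is given) only the visible
#' tokens pass through the encoder; without a plan all tokens pass and the
#' per-layer token embeddings are exposed for feature fusion.
#'
#' @param model an `mae_model`
#' @param image preprocessed square matrix matching the model's `image_size`
#' @param plan optional `masking_plan`
#' @return list: `per_layer_tokens` (one token matrix per encoder layer, in
#'   row-major token order), `cls_embedding` (final-layer, post-normalization),
#'   `grid` (tokens per side), `keep` (token indices that were encoded)
#' @export
mae_encode <- function(model, image, plan = NULL) {
  stopifnot(inherits(model, "mae_model"))
  pnodes <- wrap_params(model$params, trainable = FALSE)
  out <- mae_encoder_nodes(model, pnodes, image, plan)
  list(per_layer_tokens = lapply(out$layers, function(n) n$value),
       cls_embedding = as.vector(out$final$value[1L, ]),
       grid = model$cfg$image_size %/% model$cfg$patch_size,
       keep = out$keep)
}

#' Reconstruct patches from a masked image (inference)
#'
#' Predictions are produced for every token position; only masked positions
#' participate in the loss.
#'
#' @inheritParams mae_encode
#' @param plan the `masking_plan` used for encoding (required)
#' @return an (n_tokens x patch_size^2) predicted patch matrix
#' @export
mae_reconstruct <- function(model, image, plan) {
  stopifnot(inherits(plan, "masking_plan"))
  if (plan$n_tokens != n_tokens_of(model$cfg))
    stop("masking plan token count does not match model config")
  pnodes <- wrap_params(model$params, trainable = FALSE)
  enc <- mae_encoder_nodes(model, pnodes, image, plan)
  mae_decoder_nodes(model, pnodes, enc$final, plan)$value
}

# ---- loss pieces ------------------------------------------------------------

norm_pix <- function(target) {
  mu <- rowMeans(target)
  sd <- sqrt(rowMeans((target - mu)^2))
  (target - mu) / (sd + 1e-6)
}

#' Per-sample reconstruction loss over masked patches
#'
#' Mean squared error restricted to the masked patch rows. With
#' `norm_pix_targets` each target patch is standardized first.
#'
#' @param pred,target (n_tokens x patch_size^2) matrices
#' @param plan the `masking_plan`
#' @param norm_pix_targets logical
#' @return a non-negative scalar
#' @export
per_sample_masked_mse <- function(pred, target, plan, norm_pix_targets = FALSE) {
  stopifnot(all(dim(pred) == dim(target)))
  if (norm_pix_targets) target <- norm_pix(target)
  d <- pred[plan$masked, , drop = FALSE] - target[plan$masked, , drop = FALSE]
  mean(d * d)
}

#' Brain-coverage weight of a slice
#'
#' The fraction of pixels inside the binary brain mask, floored at `floor`.
#' Slices with little or no brain content are down-weighted in the pretraining
#' loss.
#'
#' @param brain_mask binary matrix (values 0/1) at image resolution
#' @param floor lower bound for the weight (default 0)
#' @return a weight in [floor, 1]
#' @export
coverage_weight <- function(brain_mask, floor = 0) {
  if (!is_binary(brain_mask)) stop("brain mask must be binary (0/1)")
  max(mean(brain_mask), floor)
}

#' Coverage-weighted batch reconstruction loss
#'
#' `(1/N) * sum_i w_i * l_i` -- the divisor is the batch size N, not the sum
#' of the weights, so uniformly down-weighted batches yield a smaller loss.
#'
#' @param per_sample_loss vector of per-sample masked MSE values
#' @param weights vector of coverage weights in [0, 1]
#' @return scalar loss
#' @export
weighted_batch_loss <- function(per_sample_loss, weights) {
  stopifnot(length(per_sample_loss) == length(weights),
            length(per_sample_loss) >= 1L)
  if (any(per_sample_loss < 0)) stop("per-sample losses must be >= 0")
  if (any(weights < 0 | weights > 1)) stop("weights must be in [0, 1]")
  mean(weights * per_sample_loss)
}

# ---- pretraining ------------------------------------------------------------

#' Pretrain an MAE on (image, brain mask) slice pairs
#'
#' AdamW on the coverage-weighted masked reconstruction loss. Deterministic:
#' the same seed and data yield bit-identical checkpoints. `steps = 0` returns
#' the model unchanged.
#'
#' @param model an `mae_model` from [mae_init()]
#' @param samples list of `slice_sample`s with `image` and `brain_mask`
#' @param steps optimizer steps
#' @param batch_size samples per step
#' @param lr learning rate (default 1e-4, the standard recipe)
#' @param weight_decay decoupled weight decay on weight matrices
#' @param coverage_floor floor for [coverage_weight()]
#' @param seed master seed for batch order and masking
#' @param log_file optional append-only plain-text log (step, loss, seconds)
#' @return the trained `mae_model`; `$history` holds the per-step loss
#' @export
mae_pretrain <- function(model, samples, steps = 300L, batch_size = 8L,
                         lr = 1e-4, weight_decay = 0.01, coverage_floor = 0,
                         seed = 0L, log_file = NULL) {
  stopifnot(inherits(model, "mae_model"))
  n <- length(samples)
  if (n == 0L) stop("empty data source")
  cfg <- model$cfg
  Tn <- n_tokens_of(cfg)
  if (is.null(model$opt_state)) model$opt_state <- adamw_init(model$params)
  set.seed(substream_seed(seed, "pretrain"))
  t0 <- proc.time()[3L]
  hist <- numeric(steps)
  for (st in seq_len(steps)) {
    idx <- sample.int(n, batch_size, replace = batch_size > n)
    mask_seeds <- sample.int(.Machine$integer.max, batch_size)
    pnodes <- wrap_params(model$params, trainable = TRUE)
    total <- NULL
    for (b in seq_len(batch_size)) {
      s <- samples[[idx[b]]]
      plan <- sample_masking(Tn, cfg$mask_ratio, mask_seeds[b])
      enc <- mae_encoder_nodes(model, pnodes, s$image, plan)
      pred <- mae_decoder_nodes(model, pnodes, enc$final, plan)
      target <- patchify(s$image, cfg$patch_size)
      if (cfg$norm_pix_targets) target <- norm_pix(target)
      w <- coverage_weight(s$brain_mask, coverage_floor)
      li <- ag_scale(ag_masked_mse(pred, target, plan$masked), w / batch_size)
      total <- if (is.null(total)) li else ag_add(total, li)
    }
    ag_backward(total)
    upd <- adamw_step(model$params, grads_of(pnodes), model$opt_state,
                      lr = lr, weight_decay = weight_decay)
    model$params <- upd$params
    model$opt_state <- upd$state
    hist[st] <- as.numeric(total$value)
    log_line(log_file, st, sprintf("%.6f", hist[st]),
             sprintf("%.2f", proc.time()[3L] - t0))
  }
  model$history <- c(model$history, hist)
  model$seed <- seed
  model
}
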