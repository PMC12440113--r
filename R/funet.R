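# MAE-FUnet: a U-Net backbone whose decoder fuses frozen per-layer MAE
# transformer embeddings by concatenation, addition, or cross-attention; the
# MAE-direct baseline (frozen encoder + convolutional upsampling head); and
# the hybrid Dice + Focal + cross-entropy segmentation loss.
#
# Feature maps are (H*W) x C matrices with pixels in column-major order.
# Fusion placement: the deepest selected encoder layer fuses at the
# bottleneck, successively shallower layers at successively higher-resolution
# decoder stages. All fusion strategies return the CNN feature shape, so the
# rest of the decoder is strategy-agnostic. The MAE weights stay frozen.

#' MAE-FUnet configuration
#'
#' @param num_classes segmentation classes including background (>= 2)
#' @param image_size input side length; must be divisible by 2^depth
#' @param depth number of down/upsampling levels (plus a bottleneck)
#' @param base_dim initial feature channels (32, 64 or 96 at full scale)
#' @param fusion_strategy one of `"concat"`, `"add"`, `"attention"`, or
#'   `"none"` for the backbone-only U-Net baseline
#' @param fusion_layers increasing encoder layer indices, one per fusion
#'   point (`depth + 1` of them); ignored when `fusion_strategy = "none"`
#' @param channels input image channels
#' @return an object of class `funet_config`
#' @export
funet_config <- function(num_classes, image_size = 224L, depth = 4L,
                         base_dim = 64L,
                         fusion_strategy = c("concat", "add", "attention", "none"),
                         fusion_layers = c(1L, 3L, 6L, 9L, 12L), channels = 1L) {
  fusion_strategy <- match.arg(fusion_strategy)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (base_dim < 1L) stop("base_dim must be positive")
  if (image_size %% 2L^depth != 0L)
    stop("image_size must be divisible by 2^depth")
  if (fusion_strategy != "none") {
    fusion_layers <- as.integer(fusion_layers)
    if (length(fusion_layers) != depth + 1L)
      stop("need exactly depth + 1 = ", depth + 1L, " fusion layers")
    if (is.unsorted(fusion_layers, strictly = TRUE))
      stop("fusion_layers must be strictly increasing")
  }
  structure(list(num_classes = as.integer(num_classes),
                 image_size = as.integer(image_size), depth = as.integer(depth),
                 base_dim = as.integer(base_dim),
                 fusion_strategy = fusion_strategy,
                 fusion_layers = fusion_layers, channels = as.integer(channels)),
            class = "funet_config")
}

#' Desk-scale MAE-FUnet preset
#' @inheritParams funet_config
#' @param ... further overrides passed to [funet_config()]
#' @return a `funet_config`
#' @export
funet_tiny_config <- function(num_classes = 2L, image_size = 64L, depth = 2L,
                              base_dim = 8L, fusion_strategy = "concat",
                              fusion_layers = c(1L, 2L, 4L), ...) {
  funet_config(num_classes = num_classes, image_size = image_size,
               depth = depth, base_dim = base_dim,
               fusion_strategy = fusion_strategy,
               fusion_layers = fusion_layers, ...)
}

# channel width at encoder level i (1-based; level depth+1 is the bottleneck)
funet_level_dim <- function(cfg, i) cfg$base_dim * 2L^(i - 1L)

# named parameter shapes; the single source of truth for init and counting
funet_shapes <- function(cfg, encoder_dim) {
  L <- cfg$depth
  sh <- list()
  conv_block_shapes <- function(prefix, cin, cout) {
    s <- list(c(9L * cin, cout), c(1L, cout), c(1L, cout), c(1L, cout),
              c(9L * cout, cout), c(1L, cout), c(1L, cout), c(1L, cout))
    names(s) <- paste0(prefix, "_", c("c1_w", "c1_b", "n1_g", "n1_b",
                                      "c2_w", "c2_b", "n2_g", "n2_b"))
    s
  }
  fusion_shapes <- function(prefix, C) {
    if (cfg$fusion_strategy == "none") return(list())
    s <- list(c(encoder_dim, C), c(1L, C))
    names(s) <- paste0(prefix, c("_proj_w", "_proj_b"))
    if (cfg$fusion_strategy == "concat") {
      s2 <- list(c(2L * C, C), c(1L, C))
      names(s2) <- paste0(prefix, c("_mix_w", "_mix_b"))
      s <- c(s, s2)
    } else if (cfg$fusion_strategy == "attention") {
      s2 <- list(c(C, C), c(1L, C), c(C, C), c(1L, C),
                 c(C, C), c(1L, C), c(C, C), c(1L, C))
      names(s2) <- paste0(prefix, "_", c("wq", "bq", "wk", "bk",
                                         "wv", "bv", "wo", "bo"))
      s <- c(s, s2)
    }
    s
  }
  for (i in seq_len(L)) {
    cin <- if (i == 1L) cfg$channels else funet_level_dim(cfg, i - 1L)
    sh <- c(sh, conv_block_shapes(paste0("enc", i), cin, funet_level_dim(cfg, i)))
  }
  sh <- c(sh, conv_block_shapes("bot", funet_level_dim(cfg, L),
                                funet_level_dim(cfg, L + 1L)))
  sh <- c(sh, fusion_shapes("fus_bot", funet_level_dim(cfg, L + 1L)))
  for (i in rev(seq_len(L))) {
    C <- funet_level_dim(cfg, i)
    up <- list(c(9L * 2L * C, C), c(1L, C), c(1L, C), c(1L, C))
    names(up) <- paste0("up", i, "_", c("w", "b", "n_g", "n_b"))
    sh <- c(sh, up, conv_block_shapes(paste0("dec", i), 2L * C, C),
            fusion_shapes(paste0("fus_d", i), C))
  }
  head <- list(c(cfg$base_dim, cfg$num_classes), c(1L, cfg$num_classes))
  names(head) <- c("head_w", "head_b")
  c(sh, head)
}

init_from_shapes <- function(shapes) {
  params <- lapply(names(shapes), function(nm) {
    d <- shapes[[nm]]
    if (grepl("(_g$)", nm)) return(matrix(1, d[1L], d[2L]))
    if (grepl("(_b$|_n_b$)", nm) || d[1L] == 1L) return(matrix(0, d[1L], d[2L]))
    matrix(stats::rnorm(prod(d), 0, sqrt(2 / d[1L])), d[1L], d[2L])
  })
  names(params) <- names(shapes)
  params
}

#' Initialize an MAE-FUnet model
#'
#' The encoder checkpoint is stored alongside the trainable CNN/fusion/head
#' weights and remains frozen throughout segmenter training.
#'
#' @param cfg a [funet_config()]
#' @param encoder a pretrained (frozen) `mae_model`
#' @param seed weight-initialization seed
#' @return an object of class `funet_model`
#' @export
funet_init <- function(cfg, encoder, seed = 0L) {
  stopifnot(inherits(cfg, "funet_config"), inherits(encoder, "mae_model"))
  if (cfg$image_size != encoder$cfg$image_size)
    stop("funet image_size must match the encoder's image_size")
  if (cfg$fusion_strategy != "none" &&
      max(cfg$fusion_layers) > encoder$cfg$encoder_depth)
    stop("fusion layer index exceeds encoder depth ", encoder$cfg$encoder_depth)
  params <- with_seed(substream_seed(seed, "funet-init"),
                      init_from_shapes(funet_shapes(cfg, encoder$cfg$encoder_dim)))
  structure(list(cfg = cfg, params = params, encoder = encoder,
                 opt_state = NULL, seed = seed),
            class = "funet_model")
}

# ---- fusion -----------------------------------------------------------------

# permutation taking row-major token order to column-major pixel order
token_pixel_perm <- function(g) {
  cache_get(sprintf("tp_%d", g), function() {
    p <- seq_len(g * g)
    r <- ((p - 1L) %% g) + 1L
    cc <- ((p - 1L) %/% g) + 1L
    (r - 1L) * g + cc
  })
}

#' Project transformer tokens onto a spatial feature map
#'
#' Reshapes per-layer tokens ([CLS] excluded) onto their native patch grid,
#' applies a learned channel projection, and bilinearly interpolates to the
#' target resolution.
#'
#' @param tokens (n_tokens x encoder_dim) token matrix in row-major order
#' @param proj_w,proj_b learned projection (encoder_dim x C, length C)
#' @param target_res output side length
#' @return an (target_res^2 x C) feature-map matrix, pixels column-major
#' @export
project_tokens <- function(tokens, proj_w, proj_b, target_res) {
  g <- as.integer(sqrt(nrow(tokens)))
  if (g * g != nrow(tokens)) stop("token count is not a square grid")
  px <- tokens[token_pixel_perm(g), , drop = FALSE]
  m <- sweep(px %*% proj_w, 2L, as.vector(proj_b), "+")
  as.matrix(resize_operator(g, g, target_res, target_res) %*% m)
}

#' Fuse a CNN feature map with projected MAE features
#'
#' All strategies return the CNN feature shape. `add` is the element-wise sum;
#' `concat` concatenates channel-wise and projects back to the CNN channel
#' count; `attention` treats CNN pixels as queries against the MAE features
#' as keys/values (single head) and adds the attended values residually.
#' `none` returns the CNN features untouched.
#'
#' @param cnn_feat (n_pixels x C) CNN feature matrix
#' @param mae_feat projected MAE feature matrix; same shape for add/concat,
#'   any row count for attention
#' @param strategy fusion strategy name
#' @param params named list of fusion weights (`mix_w`/`mix_b` for concat;
#'   `wq`,`bq`,`wk`,`bk`,`wv`,`bv`,`wo`,`bo` for attention)
#' @return fused feature matrix, same shape as `cnn_feat`
#' @export
fuse <- function(cnn_feat, mae_feat, strategy, params = NULL) {
  switch(strategy,
         none = cnn_feat,
         add = {
           stopifnot(all(dim(cnn_feat) == dim(mae_feat)))
           cnn_feat + mae_feat
         },
         concat = {
           stopifnot(all(dim(cnn_feat) == dim(mae_feat)))
           sweep(cbind(cnn_feat, mae_feat) %*% params$mix_w, 2L,
                 as.vector(params$mix_b), "+")
         },
         attention = {
           C <- ncol(cnn_feat)
           Q <- sweep(cnn_feat %*% params$wq, 2L, as.vector(params$bq), "+")
           K <- sweep(mae_feat %*% params$wk, 2L, as.vector(params$bk), "+")
           V <- sweep(mae_feat %*% params$wv, 2L, as.vector(params$bv), "+")
           A <- exp(tcrossprod(Q, K) / sqrt(C))
           A <- A / rowSums(A)
           cnn_feat + sweep((A %*% V) %*% params$wo, 2L, as.vector(params$bo), "+")
         },
         stop("unknown fusion strategy '", strategy, "'"))
}

#' Random fusion weights for a given channel width
#' @param C channel count; @param strategy fusion strategy; @param seed seed
#' @return named list of weight matrices (empty for add/none)
#' @export
fuse_params <- function(C, strategy, seed = 0L) {
  with_seed(substream_seed(seed, "fuse"), switch(
    strategy,
    none = , add = list(),
    concat = list(mix_w = matrix(stats::rnorm(2 * C * C, 0, sqrt(1 / C)), 2L * C, C),
                  mix_b = matrix(0, 1, C)),
    attention = {
      w <- function() matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C)
      list(wq = w(), bq = matrix(0, 1, C), wk = w(), bk = matrix(0, 1, C),
           wv = w(), bv = matrix(0, 1, C), wo = w(), bo = matrix(0, 1, C))
    },
    stop("unknown fusion strategy '", strategy, "'")))
}

# graph-level fusion; mae_px is a constant (g^2 x D) matrix in pixel order
fuse_nodes <- function(cnn, mae_px, pn, prefix, strategy, target_res) {
  if (strategy == "none") return(cnn)
  p <- function(suffix) pn[[paste0(prefix, "_", suffix)]]
  proj <- ag_add_vec(ag_matmul(ag_const(mae_px), p("proj_w")), p("proj_b"))
  if (strategy == "attention") {
    C <- ncol(cnn$value)
    Q <- ag_add_vec(ag_matmul(cnn, p("wq")), p("bq"))
    K <- ag_add_vec(ag_matmul(proj, p("wk")), p("bk"))
    V <- ag_add_vec(ag_matmul(proj, p("wv")), p("bv"))
    A <- ag_softmax_rows(ag_scale(ag_matmul_tb(Q, K), 1 / sqrt(C)))
    return(ag_add(cnn, ag_add_vec(ag_matmul(ag_matmul(A, V), p("wo")), p("bo"))))
  }
  g <- as.integer(sqrt(nrow(mae_px)))
  m <- ag_sparse_lmul(resize_operator(g, g, target_res, target_res), proj)
  if (strategy == "add") return(ag_add(cnn, m))
  ag_add_vec(ag_matmul(ag_cbind2(cnn, m), p("mix_w")), p("mix_b"))  # concat
}

# ---- forward ----------------------------------------------------------------

conv_block_nodes <- function(x, pn, prefix, H, W) {
  x <- ag_conv3(x, pn[[paste0(prefix, "_c1_w")]], pn[[paste0(prefix, "_c1_b")]], H, W)
  x <- ag_relu(ag_instnorm(x, pn[[paste0(prefix, "_n1_g")]], pn[[paste0(prefix, "_n1_b")]]))
  x <- ag_conv3(x, pn[[paste0(prefix, "_c2_w")]], pn[[paste0(prefix, "_c2_b")]], H, W)
  ag_relu(ag_instnorm(x, pn[[paste0(prefix, "_n2_g")]], pn[[paste0(prefix, "_n2_b")]]))
}

# frozen encoder features needed by a funet config: one pixel-ordered token
# matrix per fusion point (index i = decoder level i, index depth+1 = bottleneck)
funet_encoder_features <- function(model, image) {
  if (model$cfg$fusion_strategy == "none") return(NULL)
  enc <- mae_encode(model$encoder, image)
  g <- enc$grid
  perm <- token_pixel_perm(g)
  lapply(model$cfg$fusion_layers, function(l)
    enc$per_layer_tokens[[l]][perm, , drop = FALSE])
}

funet_logits_nodes <- function(model, pn, image, mae_feats) {
  cfg <- model$cfg
  S <- cfg$image_size; L <- cfg$depth
  strat <- cfg$fusion_strategy
  x <- ag_const(matrix(as.vector(image), S * S, cfg$channels))
  skips <- vector("list", L)
  for (i in seq_len(L)) {
    R <- S %/% 2L^(i - 1L)
    x <- conv_block_nodes(x, pn, paste0("enc", i), R, R)
    skips[[i]] <- x
    x <- ag_maxpool2(x, R, R)
  }
  Rb <- S %/% 2L^L
  x <- conv_block_nodes(x, pn, "bot", Rb, Rb)
  if (strat != "none")
    x <- fuse_nodes(x, mae_feats[[L + 1L]], pn, "fus_bot", strat, Rb)
  for (i in rev(seq_len(L))) {
    R <- S %/% 2L^(i - 1L)
    x <- ag_upsample2(x, R %/% 2L, R %/% 2L)
    x <- ag_conv3(x, pn[[paste0("up", i, "_w")]], pn[[paste0("up", i, "_b")]], R, R)
    x <- ag_relu(ag_instnorm(x, pn[[paste0("up", i, "_n_g")]], pn[[paste0("up", i, "_n_b")]]))
    x <- ag_cbind2(skips[[i]], x)
    x <- conv_block_nodes(x, pn, paste0("dec", i), R, R)
    if (strat != "none")
      x <- fuse_nodes(x, mae_feats[[i]], pn, paste0("fus_d", i), strat, R)
  }
  ag_add_vec(ag_matmul(x, pn$head_w), pn$head_b)
}

seg_prediction_from_logits <- function(logits_mat, S) {
  C <- ncol(logits_mat)
  p <- exp(logits_mat - apply(logits_mat, 1L, max))
  p <- p / rowSums(p)
  lab <- max.col(logits_mat, ties.method = "first") - 1L
  structure(list(logits = array(logits_mat, c(S, S, C)),
                 probabilities = array(p, c(S, S, C)),
                 label_map = matrix(lab, S, S)),
            class = "seg_prediction")
}

#' Dense segmentation forward pass
#'
#' Returns per-pixel logits at full input resolution, their softmax
#' probabilities and the argmax label map (ties resolve to the lowest class
#' index; background is class 0).
#'
#' @param model a `funet_model` or `mae_direct_model`
#' @param image preprocessed square slice
#' @param ... unused
#' @return an object of class `seg_prediction`
#' @export
forward_segment <- function(model, image, ...) UseMethod("forward_segment")

#' @export
forward_segment.funet_model <- function(model, image, ...) {
  pn <- wrap_params(model$params, trainable = FALSE)
  feats <- funet_encoder_features(model, image)
  logits <- funet_logits_nodes(model, pn, image, feats)
  seg_prediction_from_logits(logits$value, model$cfg$image_size)
}

# ---- MAE-direct baseline ----------------------------------------------------

mae_direct_shapes <- function(num_classes, encoder_dim, head_dim, n_up) {
  sh <- list(proj_w = c(encoder_dim, head_dim), proj_b = c(1L, head_dim))
  for (j in seq_len(n_up)) {
    s <- list(c(9L * head_dim, head_dim), c(1L, head_dim),
              c(1L, head_dim), c(1L, head_dim))
    names(s) <- paste0("u", j, "_", c("w", "b", "n_g", "n_b"))
    sh <- c(sh, s)
  }
  c(sh, list(head_w = c(head_dim, num_classes), head_b = c(1L, num_classes)))
}

#' Initialize the MAE-direct segmentation baseline
#'
#' A multi-layer convolutional upsampling head on the frozen encoder's
#' final-layer tokens: tokens are reshaped to their patch grid, channel
#' projected, then repeatedly upsampled (2x) with conv/norm/ReLU stages up to
#' full resolution, followed by a 1x1 classification conv.
#'
#' @param num_classes segmentation classes including background
#' @param encoder a frozen `mae_model`; image side / patch grid must be a
#'   power-of-two multiple
#' @param head_dim head channel width
#' @param seed initialization seed
#' @return an object of class `mae_direct_model`
#' @export
mae_direct_init <- function(num_classes, encoder, head_dim = 32L, seed = 0L) {
  stopifnot(inherits(encoder, "mae_model"))
  if (num_classes < 2L) stop("num_classes must be >= 2")
  S <- encoder$cfg$image_size
  g <- S %/% encoder$cfg$patch_size
  n_up <- log2(S / g)
  if (n_up != round(n_up)) stop("image size / patch grid ratio must be a power of 2")
  params <- with_seed(substream_seed(seed, "direct-init"),
                      init_from_shapes(mae_direct_shapes(num_classes,
                                                         encoder$cfg$encoder_dim,
                                                         head_dim, as.integer(n_up))))
  structure(list(cfg = list(num_classes = as.integer(num_classes),
                            image_size = S, head_dim = as.integer(head_dim),
                            n_up = as.integer(n_up), grid = g),
                 params = params, encoder = encoder, opt_state = NULL,
                 seed = seed),
            class = "mae_direct_model")
}

mae_direct_features <- function(model, image) {
  enc <- mae_encode(model$encoder, image)
  enc$per_layer_tokens[[length(enc$per_layer_tokens)]][token_pixel_perm(enc$grid), ,
                                                       drop = FALSE]
}

mae_direct_logits_nodes <- function(model, pn, tokens_px) {
  g <- model$cfg$grid
  x <- ag_add_vec(ag_matmul(ag_const(tokens_px), pn$proj_w), pn$proj_b)
  R <- g
  for (j in seq_len(model$cfg$n_up)) {
    x <- ag_upsample2(x, R, R)
    R <- 2L * R
    x <- ag_conv3(x, pn[[paste0("u", j, "_w")]], pn[[paste0("u", j, "_b")]], R, R)
    x <- ag_relu(ag_instnorm(x, pn[[paste0("u", j, "_n_g")]], pn[[paste0("u", j, "_n_b")]]))
  }
  ag_add_vec(ag_matmul(x, pn$head_w), pn$head_b)
}

#' @export
forward_segment.mae_direct_model <- function(model, image, ...) {
  pn <- wrap_params(model$params, trainable = FALSE)
  logits <- mae_direct_logits_nodes(model, pn, mae_direct_features(model, image))
  seg_prediction_from_logits(logits$value, model$cfg$image_size)
}

# ---- losses (numeric; one sample) ------------------------------------------

#' Hybrid segmentation loss configuration
#'
#' @param lambda_dice,lambda_focal,lambda_ce component weights (defaults 1.0)
#' @param gamma focal exponent (default 2.0)
#' @param alpha focal scale (default 0.25)
#' @param epsilon Dice smoothing constant (default 1e-5)
#' @return an object of class `hybrid_loss_config`
#' @export
hybrid_loss_config <- function(lambda_dice = 1, lambda_focal = 1, lambda_ce = 1,
                               gamma = 2, alpha = 0.25, epsilon = 1e-5) {
  if (any(c(lambda_dice, lambda_focal, lambda_ce) < 0)) stop("lambdas must be >= 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(lambda_dice = lambda_dice, lambda_focal = lambda_focal,
                 lambda_ce = lambda_ce, gamma = gamma, alpha = alpha,
                 epsilon = epsilon),
            class = "hybrid_loss_config")
}

as_prob_matrix <- function(p) {
  if (is.matrix(p)) p else matrix(p, prod(dim(p)[1:2]), dim(p)[3L])
}

#' Soft Dice loss (single sample, background included)
#'
#' Per class c: `1 - (2 sum(p*g) + eps) / (sum(p^2) + sum(g^2) + eps)`,
#' averaged over all classes including background. A class absent from both
#' prediction and truth contributes `1 - eps/eps = 0`.
#'
#' @param prob softmax probabilities: (n_pixels x C) matrix or H x W x C array
#' @param labels 0-based integer class map (matrix or vector)
#' @param epsilon smoothing constant
#' @return scalar in [0, 1] (up to epsilon effects)
#' @export
dice_loss <- function(prob, labels, epsilon = 1e-5) {
  p <- as_prob_matrix(prob)
  y <- as.integer(labels) + 1L
  stopifnot(nrow(p) == length(y), all(y >= 1L), all(y <= ncol(p)))
  g <- matrix(0, nrow(p), ncol(p)); g[cbind(seq_along(y), y)] <- 1
  num <- 2 * colSums(p * g) + epsilon
  den <- colSums(p * p) + colSums(g) + epsilon
  mean(1 - num / den)
}

#' Focal loss (single sample)
#'
#' Mean over pixels of `-alpha * (1 - p_t)^gamma * log(p_t)` where p_t is the
#' predicted probability of the true class, clipped to [1e-8, 1] before the
#' logarithm (the clipping is part of the contract). With `gamma = 0`,
#' `alpha = 1` this is the pixel-mean cross-entropy.
#'
#' @inheritParams dice_loss
#' @param gamma focusing exponent; @param alpha scale
#' @return non-negative scalar
#' @export
focal_loss <- function(prob, labels, gamma = 2, alpha = 0.25) {
  p <- as_prob_matrix(prob)
  y <- as.integer(labels) + 1L
  stopifnot(nrow(p) == length(y))
  pt <- pmin(pmax(p[cbind(seq_along(y), y)], 1e-8), 1)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Pixel-wise multi-class cross-entropy (single sample)
#'
#' Mean over pixels of `-log p_y`, computed from raw logits via log-sum-exp
#' for numerical stability.
#'
#' @param logits (n_pixels x C) matrix or H x W x C array of raw scores
#' @param labels 0-based integer class map
#' @return non-negative scalar
#' @export
ce_pixel_loss <- function(logits, labels) {
  z <- as_prob_matrix(logits)
  y <- as.integer(labels) + 1L
  stopifnot(nrow(z) == length(y))
  mx <- apply(z, 1L, max)
  lse <- mx + log(rowSums(exp(z - mx)))
  mean(lse - z[cbind(seq_along(y), y)])
}

#' Hybrid Dice + Focal + cross-entropy loss (single sample)
#'
#' `lambda_dice * L_dice + lambda_focal * L_focal + lambda_ce * L_ce`,
#' exactly the weighted sum of the three components.
#'
#' @param logits raw score grid; softmax is taken internally for the Dice and
#'   focal terms
#' @param labels 0-based integer class map
#' @param cfg a [hybrid_loss_config()]
#' @return non-negative scalar
#' @export
hybrid_loss <- function(logits, labels, cfg = hybrid_loss_config()) {
  z <- as_prob_matrix(logits)
  p <- exp(z - apply(z, 1L, max))
  p <- p / rowSums(p)
  cfg$lambda_dice * dice_loss(p, labels, cfg$epsilon) +
    cfg$lambda_focal * focal_loss(p, labels, cfg$gamma, cfg$alpha) +
    cfg$lambda_ce * ce_pixel_loss(z, labels)
}

# ---- training ---------------------------------------------------------------

#' Train a segmenter (MAE-FUnet or MAE-direct) with the hybrid loss
#'
#' Only CNN/fusion/head parameters are updated; the MAE encoder weights are
#' frozen (its features are computed once per slice and cached). Training is
#' deterministic per seed. `steps = 0` returns the initialized model.
#'
#' @param model a `funet_model` or `mae_direct_model`
#' @param samples list of `slice_sample`s with `image` and `label_grid`
#'   holding 0-based integer class maps
#' @param loss_cfg a [hybrid_loss_config()]
#' @param steps,batch_size optimizer schedule
#' @param lr learning rate; @param weight_decay AdamW decoupled decay
#' @param seed master seed; @param log_file optional plain-text log
#' @return the trained model; `$history` holds per-step hybrid loss values
#' @export
train_segmenter <- function(model, samples, loss_cfg = hybrid_loss_config(),
                            steps = 200L, batch_size = 4L, lr = 1e-3,
                            weight_decay = 0.01, seed = 0L, log_file = NULL) {
  stopifnot(inherits(model, "funet_model") || inherits(model, "mae_direct_model"))
  n <- length(samples)
  if (n == 0L) stop("at least one labelled slice is required")
  C <- model$cfg$num_classes
  for (s in samples) {
    if (is.null(s$label_grid)) stop("every sample needs a label_grid")
    if (max(s$label_grid) >= C)
      stop("label values must be < num_classes = ", C)
  }
  is_funet <- inherits(model, "funet_model")
  feats <- lapply(samples, function(s)
    if (is_funet) funet_encoder_features(model, s$image)
    else mae_direct_features(model, s$image))
  if (is.null(model$opt_state)) model$opt_state <- adamw_init(model$params)
  set.seed(substream_seed(seed, "seg-train"))
  t0 <- proc.time()[3L]
  hist <- numeric(steps)
  for (st in seq_len(steps)) {
    idx <- sample.int(n, min(batch_size, n))
    pn <- wrap_params(model$params, trainable = TRUE)
    total <- NULL
    for (b in idx) {
      s <- samples[[b]]
      logits <- if (is_funet)
        funet_logits_nodes(model, pn, s$image, feats[[b]])
      else mae_direct_logits_nodes(model, pn, feats[[b]])
      y <- as.integer(s$label_grid) + 1L
      p <- ag_softmax_rows(logits)
      li <- ag_scale(ag_dice_p(p, y, loss_cfg$epsilon), loss_cfg$lambda_dice)
      li <- ag_add(li, ag_scale(ag_focal_p(p, y, loss_cfg$gamma, loss_cfg$alpha),
                                loss_cfg$lambda_focal))
      li <- ag_add(li, ag_scale(ag_ce_rows(logits, y), loss_cfg$lambda_ce))
      li <- ag_scale(li, 1 / length(idx))
      total <- if (is.null(total)) li else ag_add(total, li)
    }
    ag_backward(total)
    upd <- adamw_step(model$params, grads_of(pn), model$opt_state,
                      lr = lr, weight_decay = weight_decay)
    model$params <- upd$params
    model$opt_state <- upd$state
    hist[st] <- as.numeric(total$value)
    log_line(log_file, st, sprintf("%.6f", hist[st]),
             sprintf("%.2f", proc.time()[3L] - t0))
  }
  model$history <- c(model$history, hist)
  model
}
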