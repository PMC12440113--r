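# Frozen-encoder linear probing for MRI sequence classification.
#
# The encoder stays frozen; a single affine head z = W e + b on the final
# [CLS] embedding is trained with the cross-entropy loss
# L_ce = -z_y + log sum_j exp(z_j). Trainable parameters: C * (d + 1).

#' Linear-probe configuration
#'
#' @param num_classes number of classes C (>= 2)
#' @param embedding_dim encoder embedding dimension d
#' @param freeze_encoder must be TRUE for the probing protocol
#' @param learning_rate AdamW learning rate
#' @return an object of class `probe_config`
#' @export
probe_config <- function(num_classes, embedding_dim, freeze_encoder = TRUE,
                         learning_rate = 1e-4) {
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (!freeze_encoder) stop("the probing protocol requires a frozen encoder")
  structure(list(num_classes = as.integer(num_classes),
                 embedding_dim = as.integer(embedding_dim),
                 freeze_encoder = freeze_encoder,
                 learning_rate = learning_rate),
            class = "probe_config")
}

#' Final [CLS] embedding of an image under a frozen encoder
#'
#' @param model a frozen `mae_model`
#' @param image preprocessed slice matching the encoder's `image_size`
#' @return numeric vector of length `encoder_dim`
#' @export
cls_embedding <- function(model, image) {
  mae_encode(model, image)$cls_embedding
}

#' Initialize a linear probe head
#'
#' @param cfg a [probe_config()]
#' @param seed initialization seed
#' @return an object of class `probe_head` with weight matrix `W` (C x d),
#'   bias `b` (length C) and the config
#' @export
probe_init <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "probe_config"))
  with_seed(substream_seed(seed, "probe-init"), {
    structure(list(cfg = cfg,
                   params = list(W = matrix(tn(cfg$num_classes * cfg$embedding_dim),
                                            cfg$num_classes, cfg$embedding_dim),
                                 b = matrix(0, cfg$num_classes, 1)),
                   opt_state = NULL, seed = seed),
              class = "probe_head")
  })
}

#' Raw class logits of an embedding under a probe head
#'
#' @param head a `probe_head`
#' @param embedding numeric vector of length `embedding_dim`
#' @return numeric vector of length `num_classes`
#' @export
probe_logits <- function(head, embedding) {
  if (length(embedding) != head$cfg$embedding_dim)
    stop("embedding length ", length(embedding), " != configured dim ",
         head$cfg$embedding_dim)
  as.vector(head$params$W %*% embedding + head$params$b)
}

#' Cross-entropy loss of a logit vector
#'
#' `-z_y + log sum_j exp(z_j)`, evaluated with an overflow-safe
#' log-sum-exp. Invariant under adding a constant to every logit.
#'
#' @param z raw logits
#' @param y 1-based true class index
#' @return scalar loss
#' @export
ce_loss <- function(z, y) {
  stopifnot(y >= 1L, y <= length(z), all(is.finite(z)))
  -z[y] + logsumexp(z)
}

#' Train a linear probe on a frozen encoder
#'
#' Embeddings are computed once (the encoder is never touched); only the head
#' parameters are updated, with AdamW. Following the customary linear-probing
#' protocol, features are standardized with statistics of the training set (a
#' fixed, non-trainable normalization applied identically at prediction time)
#' before the affine head. Classes missing from the training set produce a
#' warning, not an error.
#'
#' @param encoder a frozen `mae_model`
#' @param samples list of `slice_sample`s (or precomputed embedding matrix,
#'   one row per sample)
#' @param labels 1-based integer class labels
#' @param cfg a [probe_config()]
#' @param steps,batch_size optimizer schedule
#' @param standardize standardize features with training-set statistics
#' @param seed master seed
#' @return a trained `probe_head`
#' @export
train_probe <- function(encoder, samples, labels, cfg, steps = 200L,
                        batch_size = 16L, standardize = TRUE, seed = 0L) {
  stopifnot(inherits(cfg, "probe_config"))
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > cfg$num_classes)) stop("labels out of range")
  missing_cls <- setdiff(seq_len(cfg$num_classes), unique(labels))
  if (length(missing_cls))
    warning("classes absent from training set: ", paste(missing_cls, collapse = ", "))
  E <- if (is.matrix(samples)) samples else
    t(vapply(samples, function(s) cls_embedding(encoder, s$image),
             numeric(cfg$embedding_dim)))
  stopifnot(nrow(E) == length(labels))
  head <- probe_init(cfg, seed)
  if (standardize) {
    mu <- colMeans(E)
    sdv <- apply(E, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    head$feature_mean <- mu
    head$feature_sd <- sdv
    E <- scale(E, mu, sdv)
  }
  if (steps == 0L) return(head)
  head$opt_state <- adamw_init(head$params)
  n <- nrow(E)
  set.seed(substream_seed(seed, "probe-train"))
  for (st in seq_len(steps)) {
    idx <- sample.int(n, min(batch_size, n))
    Eb <- E[idx, , drop = FALSE]
    yb <- labels[idx]
    Z <- Eb %*% t(head$params$W) + matrix(head$params$b, length(idx),
                                          cfg$num_classes, byrow = TRUE)
    # closed-form CE gradient: softmax minus one-hot
    S <- exp(Z - apply(Z, 1L, max)); S <- S / rowSums(S)
    S[cbind(seq_along(idx), yb)] <- S[cbind(seq_along(idx), yb)] - 1
    S <- S / length(idx)
    grads <- list(W = t(S) %*% Eb, b = matrix(colSums(S), cfg$num_classes, 1))
    upd <- adamw_step(head$params, grads, head$opt_state,
                      lr = cfg$learning_rate)
    head$params <- upd$params
    head$opt_state <- upd$state
  }
  head
}

#' Predict class labels with a frozen encoder and probe head
#'
#' Argmax over logits; ties resolve to the lowest class index.
#' @inheritParams train_probe
#' @param head a `probe_head`
#' @return integer vector of 1-based predicted labels
#' @export
probe_predict <- function(encoder, head, samples) {
  E <- if (is.matrix(samples)) samples else
    t(vapply(samples, function(s) cls_embedding(encoder, s$image),
             numeric(head$cfg$embedding_dim)))
  if (!is.null(head$feature_mean))
    E <- scale(E, head$feature_mean, head$feature_sd)
  apply(E %*% t(head$params$W) + matrix(head$params$b, nrow(E),
                                        head$cfg$num_classes, byrow = TRUE),
        1L, which.max)
}

#' Per-class and overall classification accuracy
#'
#' Per-class accuracy is correct/total within each class (macro view);
#' overall accuracy pools all samples (micro). Classes with no test samples
#' are reported as NA and excluded from the per-class table semantics.
#'
#' @param truth,pred 1-based integer label vectors of equal length
#' @param num_classes C
#' @return list with `per_class` (named numeric, NA for empty classes) and
#'   `overall`
#' @export
eval_accuracy <- function(truth, pred, num_classes) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1L)
  per <- vapply(seq_len(num_classes), function(c) {
    sel <- truth == c
    if (!any(sel)) NA_real_ else mean(pred[sel] == c)
  }, numeric(1L))
  names(per) <- paste0("class_", seq_len(num_classes))
  list(per_class = per, overall = mean(pred == truth))
}
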