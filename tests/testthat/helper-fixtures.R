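# Shared fixtures, built in code at test time.

# finite-difference gradient check for a scalar-valued graph builder;
# build_fn(params) must return list(node = <scalar ag node>, pn = <wrapped params>)
check_grad <- function(build_fn, params, param_names, eps = 1e-7, tol = 1e-4) {
  out <- build_fn(params)
  maefunet:::ag_backward(out$node)
  worst <- 0
  for (nm in param_names) {
    g <- out$pn[[nm]]$grad
    if (is.null(g)) stop("no gradient reached parameter ", nm)
    i <- which.max(abs(g))
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (as.numeric(build_fn(p1)$node$value) -
              as.numeric(build_fn(p2)$node$value)) / (2 * eps)
    worst <- max(worst, abs(g[i] - num) / max(abs(num), 1e-8))
  }
  worst < tol
}

# small ViT config for fast graph tests (16 x 16 images, 4 x 4 patches)
tiny16_cfg <- function(encoder_depth = 3L) {
  vit_tiny_config(image_size = 16L, patch_size = 4L, encoder_dim = 8L,
                  encoder_depth = encoder_depth, encoder_heads = 2L,
                  decoder_dim = 8L, decoder_depth = 1L, decoder_heads = 2L)
}

# a slice_sample with a synthetic disc brain mask (no phantom machinery)
disc_sample <- function(S = 16L, r = 0.35, noise_seed = 1L) {
  set.seed(noise_seed)
  i <- rep(seq_len(S), S); j <- rep(seq_len(S), each = S)
  mask <- matrix(as.numeric(((i - S / 2)^2 + (j - S / 2)^2) <= (r * S)^2), S, S)
  img <- 0.2 + 0.6 * mask + matrix(rnorm(S * S, 0, 0.02), S, S)
  s <- list(image = pmin(pmax(img, 0), 1), brain_mask = mask,
            label_grid = matrix(as.integer(mask), S, S), class_label = NULL,
            provenance = list(volume = "disc", axis = 3L, index = 0L))
  class(s) <- "slice_sample"
  s
}

# memoized desk-scale pretrained encoder (500 phantom slices, 300 steps)
# shared by the few-shot acceptance checks and the probe learnability test
.fixture_env <- new.env()
pretrained_tiny64 <- function() {
  if (is.null(.fixture_env$enc64)) {
    slices <- make_pretrain_set(500L, seed = 11L)
    enc <- mae_init(vit_tiny_config(), seed = 11L)
    .fixture_env$enc64 <- mae_pretrain(enc, slices, steps = 300L,
                                       batch_size = 8L, seed = 11L)
  }
  .fixture_env$enc64
}
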