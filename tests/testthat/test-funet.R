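# MAE-FUnet: backbone shape arithmetic, fusion strategies, the hybrid
# Dice/Focal/CE loss against brute-force oracles, freeze contract, training.

make_enc16 <- function(seed = 1L) mae_init(tiny16_cfg(), seed = seed)

test_that("backbone levels halve resolution and double channels", {
  cfg <- funet_config(num_classes = 9L, image_size = 224L, depth = 4L,
                      base_dim = 64L, fusion_strategy = "concat",
                      fusion_layers = c(1L, 3L, 6L, 9L, 12L))
  sh <- maefunet:::funet_shapes(cfg, encoder_dim = 768L)
  # encoder conv output channels at resolutions 224,112,56,28 then bottleneck 14
  expect_equal(unname(vapply(1:4, function(i) sh[[paste0("enc", i, "_c1_w")]][2L],
                             numeric(1L))), c(64, 128, 256, 512))
  expect_equal(sh$bot_c1_w[2L], 1024)
  # resolutions implied by the pooling chain
  expect_equal(224 / 2^(0:4), c(224, 112, 56, 28, 14))
})

test_that("parameter counts grow strictly with base_dim at full scale", {
  counts <- vapply(c(32L, 64L, 96L), function(b)
    funet_param_count(funet_config(num_classes = 9L, image_size = 224L,
                                   depth = 4L, base_dim = b), 768L),
    numeric(1L))
  expect_true(all(diff(counts) > 0))
  # analytic count equals enumeration of an initialized model at test scale
  enc <- make_enc16()
  cfg <- funet_config(3L, image_size = 16L, depth = 2L, base_dim = 4L,
                      fusion_layers = c(1L, 2L, 3L))
  model <- funet_init(cfg, enc, seed = 1L)
  expect_identical(count_trainable(model),
                   as.integer(funet_param_count(cfg, enc$cfg$encoder_dim)))
})

test_that("all fusion strategies are drop-in interchangeable in shape", {
  enc <- make_enc16()
  img <- disc_sample(16L)$image
  shapes <- lapply(c("concat", "add", "attention", "none"), function(strat) {
    cfg <- funet_config(3L, image_size = 16L, depth = 2L, base_dim = 4L,
                        fusion_strategy = strat, fusion_layers = c(1L, 2L, 3L))
    pred <- forward_segment(funet_init(cfg, enc, seed = 2L), img)
    dim(pred$logits)
  })
  for (s in shapes) expect_equal(s, c(16L, 16L, 3L))
  # config grid: depths and base dims all yield full-resolution output
  for (depth in c(1L, 2L)) for (base in c(4L, 8L)) {
    cfg <- funet_config(2L, image_size = 16L, depth = depth, base_dim = base,
                        fusion_strategy = "add",
                        fusion_layers = seq_len(depth + 1L))
    pred <- forward_segment(funet_init(cfg, enc, seed = 3L), img)
    expect_equal(dim(pred$label_map), c(16L, 16L))
  }
})

test_that("fuse() honours its algebraic contracts", {
  set.seed(50)
  cnn <- matrix(rnorm(64 * 6), 64, 6)
  mae <- matrix(rnorm(64 * 6), 64, 6)
  expect_identical(fuse(cnn, matrix(0, 64, 6), "add"), cnn)
  expect_identical(fuse(cnn, mae, "none"), cnn)
  pc <- fuse_params(6L, "concat", seed = 1L)
  expect_equal(dim(fuse(cnn, mae, "concat", pc)), dim(cnn))
  pa <- fuse_params(6L, "attention", seed = 1L)
  expect_equal(dim(fuse(cnn, mae, "attention", pa)), dim(cnn))
  # uniform keys/values: attention adds a query-independent vector field
  uni <- matrix(1, 16, 6)
  out <- fuse(cnn, uni, "attention", pa)
  delta <- out - cnn
  expect_lt(max(abs(sweep(delta, 2L, delta[1L, ]))), 1e-10)
  expect_error(fuse(cnn, mae, "meld"), "unknown fusion")
})

test_that("token projection reshapes to the patch grid and interpolates", {
  set.seed(51)
  tok <- matrix(rnorm(196 * 8), 196, 8)
  pw <- matrix(rnorm(8 * 5), 8, 5); pb <- rep(0, 5)
  out14 <- project_tokens(tok, pw, pb, 14L)
  expect_equal(dim(out14), c(196L, 5L))       # identity interpolation at 14x14
  expect_equal(out14, (tok %*% pw)[maefunet:::token_pixel_perm(14L), ],
               tolerance = 1e-12)
  out28 <- project_tokens(tok, pw, pb, 28L)
  expect_equal(dim(out28), c(784L, 5L))       # channels preserved
  expect_error(project_tokens(matrix(0, 10, 8), pw, pb, 14L), "square")
})

test_that("dice loss matches a brute-force evaluator and guards empty classes", {
  # 4-pixel, 2-class example with uniform predictions
  p <- matrix(0.5, 4, 2)
  y <- c(0L, 0L, 0L, 1L)
  eps <- 1e-5
  brute <- mean(vapply(1:2, function(cl) {
    g <- as.numeric(y == (cl - 1L))
    1 - (2 * sum(p[, cl] * g) + eps) / (sum(p[, cl]^2) + sum(g^2) + eps)
  }, numeric(1L)))
  expect_equal(dice_loss(p, y, eps), brute, tolerance = 1e-12)
  # perfect one-hot prediction: epsilon-close to zero
  ph <- matrix(0, 4, 2); ph[cbind(1:4, y + 1L)] <- 1
  expect_lt(dice_loss(ph, y), 1e-6)
  # class 3 absent from both prediction and truth contributes exactly 0
  p3 <- cbind(ph, 0)
  expect_equal(dice_loss(p3, y), dice_loss(ph, y) * 2 / 3, tolerance = 1e-12)
})

test_that("focal loss matches its closed form and reduces to cross-entropy", {
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1, 2), 0L, gamma = 2, alpha = 0.25),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  expect_equal(focal_loss(matrix(c(1, 0), 1, 2), 0L), 0)
  set.seed(52)
  z <- matrix(rnorm(64 * 3), 64, 3)
  y <- sample(0:2, 64, replace = TRUE)
  p <- exp(z) / rowSums(exp(z))
  expect_equal(focal_loss(p, y, gamma = 0, alpha = 1), ce_pixel_loss(z, y),
               tolerance = 1e-10)
})

test_that("pixel cross-entropy equals the -log softmax oracle", {
  set.seed(53)
  for (i in 1:5) {
    z <- matrix(rnorm(64 * 4, sd = 3), 64, 4)
    y <- sample(0:3, 64, replace = TRUE)
    oracle <- -mean(log((exp(z) / rowSums(exp(z)))[cbind(1:64, y + 1L)]))
    expect_equal(ce_pixel_loss(z, y), oracle, tolerance = 1e-9)
  }
  zh <- matrix(-50, 4, 3); zh[cbind(1:4, c(1L, 2L, 3L, 1L))] <- 50
  expect_lt(ce_pixel_loss(zh, c(0L, 1L, 2L, 0L)), 1e-12)
  expect_equal(ce_pixel_loss(matrix(0, 10, 5), rep(0L, 10)), log(5))
})

test_that("the hybrid loss is the exact weighted sum of its components", {
  set.seed(54)
  z <- matrix(rnorm(4 * 2), 4, 2)
  y <- c(0L, 1L, 0L, 1L)
  p <- exp(z) / rowSums(exp(z))
  cfg <- hybrid_loss_config()
  expect_equal(hybrid_loss(z, y, cfg),
               dice_loss(p, y, cfg$epsilon) +
                 focal_loss(p, y, cfg$gamma, cfg$alpha) +
                 ce_pixel_loss(z, y), tolerance = 1e-12)
  expect_equal(hybrid_loss(z, y, hybrid_loss_config(0, 0, 0)), 0)
  expect_equal(hybrid_loss(z, y, hybrid_loss_config(1, 0, 0)),
               dice_loss(p, y, 1e-5), tolerance = 1e-12)
  expect_gte(hybrid_loss(z, y, cfg), 0)
})

test_that("segmenter training freezes the encoder and is deterministic", {
  enc <- make_enc16()
  digest0 <- weight_digest(enc)
  slices <- lapply(1:4, function(i) disc_sample(16L, noise_seed = i))
  for (strat in c("concat", "add", "attention")) {
    cfg <- funet_config(2L, image_size = 16L, depth = 2L, base_dim = 4L,
                        fusion_strategy = strat, fusion_layers = c(1L, 2L, 3L))
    m0 <- funet_init(cfg, enc, seed = 4L)
    expect_identical(train_segmenter(m0, slices, steps = 0L)$params, m0$params)
    m1 <- train_segmenter(m0, slices, steps = 4L, batch_size = 2L, seed = 6L)
    m2 <- train_segmenter(m0, slices, steps = 4L, batch_size = 2L, seed = 6L)
    expect_identical(m1$params, m2$params)
    expect_identical(weight_digest(m1$encoder), digest0)
  }
  bad <- lapply(slices, function(s) { s$label_grid[1L] <- 5L; s })
  m0 <- funet_init(funet_config(2L, image_size = 16L, depth = 2L, base_dim = 4L,
                                fusion_strategy = "none"), enc)
  expect_error(train_segmenter(m0, bad, steps = 1L), "num_classes")
  expect_error(funet_config(1L, image_size = 16L, depth = 2L), "num_classes")
})

test_that("MAE-direct predicts at full resolution with a frozen encoder", {
  enc <- make_enc16()
  digest0 <- weight_digest(enc)
  md <- mae_direct_init(2L, enc, head_dim = 6L, seed = 1L)
  img <- disc_sample(16L)$image
  pred <- forward_segment(md, img)
  expect_equal(dim(pred$label_map), c(16L, 16L))
  expect_equal(apply(pred$probabilities, c(1, 2), sum),
               matrix(1, 16, 16), tolerance = 1e-12)
  md <- train_segmenter(md, lapply(1:3, function(i) disc_sample(16L, noise_seed = i)),
                        steps = 3L, seed = 1L)
  expect_identical(weight_digest(md$encoder), digest0)
})

test_that("a tiny segmenter overfits one labelled slice to high Dice", {
  enc <- mae_init(vit_tiny_config(image_size = 32L, patch_size = 8L,
                                  encoder_dim = 16L, encoder_depth = 3L,
                                  encoder_heads = 2L, decoder_dim = 16L,
                                  decoder_depth = 1L, decoder_heads = 2L),
                  seed = 1L)
  s <- disc_sample(32L)
  cfg <- funet_config(2L, image_size = 32L, depth = 2L, base_dim = 6L,
                      fusion_strategy = "concat", fusion_layers = c(1L, 2L, 3L))
  m <- funet_init(cfg, enc, seed = 2L)
  m <- train_segmenter(m, list(s), steps = 120L, batch_size = 1L, lr = 3e-3,
                       seed = 2L)
  pred <- forward_segment(m, s$image)
  expect_gte(dice_score(pred$label_map == 1L, s$label_grid == 1L), 0.99)
})
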