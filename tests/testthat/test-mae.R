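# Masked autoencoder: patch rearrangement, masking plans, encoder/decoder
# contracts, the coverage-weighted loss, and the pretraining loop.

test_that("patchify produces raster-ordered patches and inverts exactly", {
  img <- matrix(runif(224 * 224), 224, 224)
  p <- patchify(img, 16L)
  expect_equal(dim(p), c(196L, 256L))   # (224/16)^2 patches of 16^2 pixels
  expect_identical(unpatchify(p, 224L, 16L), img)
  # raster convention on a 32x32 image with 16x16 patches
  m <- matrix(0, 32, 32)
  m[1:16, 1:16] <- 1; m[1:16, 17:32] <- 2; m[17:32, 1:16] <- 3; m[17:32, 17:32] <- 4
  pm <- patchify(m, 16L)
  expect_equal(dim(pm), c(4L, 256L))
  expect_equal(rowMeans(pm), c(1, 2, 3, 4))  # row0col0, row0col1, row1col0, row1col1
  expect_error(patchify(matrix(0, 30, 30), 16L), "divisible")
})

test_that("patchify round-trips exactly for all divisible sizes up to 64", {
  set.seed(30)
  for (S in c(8L, 16L, 24L, 32L, 48L, 64L)) for (p in c(2L, 4L, 8L)) {
    if (S %% p != 0L) next
    img <- matrix(rnorm(S * S), S, S)
    expect_identical(unpatchify(patchify(img, p), S, p), img)
  }
})

test_that("masking plans have exact counts, determinism and partition", {
  plan <- sample_masking(196L, 0.75, seed = 4L)
  expect_length(plan$masked, 147L)
  expect_identical(sample_masking(196L, 0.75, seed = 4L)$masked, plan$masked)
  expect_setequal(c(plan$masked, plan$visible), seq_len(196L))
  expect_length(intersect(plan$masked, plan$visible), 0L)
  expect_error(sample_masking(4L, 0.01, 1L), "degenerate")
  for (n in c(7L, 49L, 196L, 400L)) for (r in c(0.25, 0.5, 0.75))
    expect_length(sample_masking(n, r, 1L)$masked, floor(r * n + 0.5))
})

test_that("encoder output shapes honour the masking plan", {
  cfg <- vit_config(image_size = 224L, patch_size = 16L, encoder_dim = 8L,
                    encoder_depth = 2L, encoder_heads = 2L, decoder_dim = 8L,
                    decoder_depth = 1L, decoder_heads = 2L)
  m <- mae_init(cfg, seed = 1L)
  img <- matrix(runif(224 * 224), 224, 224)
  full <- mae_encode(m, img)
  expect_length(full$per_layer_tokens, 2L)
  expect_equal(nrow(full$per_layer_tokens[[1L]]), 196L)
  expect_length(full$cls_embedding, 8L)
  plan <- sample_masking(196L, 0.75, 2L)
  vis <- mae_encode(m, img, plan)
  expect_equal(nrow(vis$per_layer_tokens[[1L]]), 49L)  # 196 - 147 visible
  expect_error(mae_encode(m, matrix(0, 64, 64)), "does not match")
})

test_that("frozen encoding and reconstruction are deterministic", {
  cfg <- tiny16_cfg()
  m <- mae_init(cfg, seed = 2L)
  img <- matrix(runif(256), 16, 16)
  expect_identical(mae_encode(m, img)$cls_embedding,
                   mae_encode(m, img)$cls_embedding)
  plan <- sample_masking(16L, 0.75, 3L)
  r1 <- mae_reconstruct(m, img, plan)
  expect_equal(dim(r1), c(16L, 16L))   # predictions for every token position
  expect_identical(r1, mae_reconstruct(m, img, plan))
})

test_that("masked MSE has the stated closed forms and masked-only dependence", {
  set.seed(31)
  plan <- sample_masking(16L, 0.5, 5L)
  target <- matrix(rnorm(16 * 4), 16, 4)
  expect_equal(per_sample_masked_mse(target, target, plan), 0)
  pred <- target; pred[plan$masked, ] <- pred[plan$masked, ] + 0.3
  expect_equal(per_sample_masked_mse(pred, target, plan), 0.09, tolerance = 1e-12)
  # perturbing targets at visible positions changes nothing
  t2 <- target; t2[plan$visible, ] <- rnorm(length(plan$visible) * 4)
  expect_identical(per_sample_masked_mse(pred, target, plan),
                   per_sample_masked_mse(pred, t2, plan))
})

test_that("coverage weights are mask fractions with a floor", {
  expect_equal(coverage_weight(matrix(1, 8, 8)), 1)
  expect_equal(coverage_weight(matrix(0, 8, 8)), 0)
  q <- matrix(0, 8, 8); q[1:4, 1:4] <- 1
  expect_equal(coverage_weight(q), 0.25)
  expect_equal(coverage_weight(matrix(0, 8, 8), floor = 0.1), 0.1)
  expect_error(coverage_weight(matrix(0.5, 2, 2)), "binary")
})

test_that("the weighted batch loss follows its definition exactly", {
  expect_equal(weighted_batch_loss(c(0.2, 0.4), c(1, 0.5)), 0.2)
  l <- runif(5)
  expect_equal(weighted_batch_loss(l, rep(1, 5)), mean(l))
  expect_equal(weighted_batch_loss(l, rep(0, 5)), 0)
  # linear in the weights
  w <- runif(5)
  expect_equal(weighted_batch_loss(l, 0.5 * w), 0.5 * weighted_batch_loss(l, w))
  expect_error(weighted_batch_loss(l, rep(2, 5)), "\\[0, 1\\]")
})

test_that("pretraining is a no-op at zero steps and bit-reproducible", {
  cfg <- tiny16_cfg(encoder_depth = 2L)
  m0 <- mae_init(cfg, seed = 7L)
  slices <- lapply(1:6, function(i) disc_sample(16L, noise_seed = i))
  expect_identical(mae_pretrain(m0, slices, steps = 0L)$params, m0$params)
  m1 <- mae_pretrain(m0, slices, steps = 5L, batch_size = 4L, seed = 3L)
  m2 <- mae_pretrain(m0, slices, steps = 5L, batch_size = 4L, seed = 3L)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m0$params))
  expect_error(mae_pretrain(m0, list(), steps = 1L), "empty")
})

test_that("a tiny model overfits one image to near-zero masked MSE", {
  cfg <- tiny16_cfg(encoder_depth = 2L)
  m <- mae_init(cfg, seed = 9L)
  s <- disc_sample(16L)
  m <- mae_pretrain(m, list(s), steps = 400L, batch_size = 1L, lr = 3e-3,
                    weight_decay = 0, seed = 9L)
  first <- mean(m$history[1:20])
  last <- mean(tail(m$history, 20))
  expect_lt(last, 0.1 * first)
  expect_lt(last, 0.01)
})

test_that("checkpoints round-trip models through disk", {
  m <- mae_init(tiny16_cfg(encoder_depth = 2L), seed = 1L)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_identical(weight_digest(m2), weight_digest(m))
  expect_error(load_checkpoint(tempfile()), "not found")
})
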