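# Dice/IoU scoring against set-arithmetic oracles, dataset aggregation,
# error maps, parameter accounting and sweep summaries.

test_that("dice and iou match direct set arithmetic on the worked pair", {
  # |P| = 4, |G| = 6, overlap 3
  P <- matrix(FALSE, 5, 5); P[1:4] <- TRUE
  G <- matrix(FALSE, 5, 5); G[2:7] <- TRUE
  expect_equal(dice_score(P, G), 0.6)
  expect_equal(iou_score(P, G), 3 / 7)
  expect_equal(dice_score(G, G), 1)
  expect_equal(iou_score(G, G), 1)
  D <- matrix(FALSE, 5, 5); D[20:22] <- TRUE
  expect_equal(dice_score(P, D), 0)
  expect_equal(iou_score(P, D), 0)
  # both empty: perfect agreement on absence
  E <- matrix(FALSE, 3, 3)
  expect_equal(dice_score(E, E), 1)
  expect_equal(iou_score(E, E), 1)
})

test_that("scores agree with a random-mask oracle and the Dice/IoU identity", {
  set.seed(60)
  for (i in 1:1000) {
    n <- sample(4:64, 1L)
    P <- runif(n) < runif(1L)
    G <- runif(n) < runif(1L)
    inter <- sum(P & G); uni <- sum(P | G)
    d_oracle <- if (sum(P) + sum(G) == 0) 1 else 2 * inter / (sum(P) + sum(G))
    j_oracle <- if (uni == 0) 1 else inter / uni
    d <- dice_score(P, G); j <- iou_score(P, G)
    expect_identical(d, d_oracle)
    expect_identical(j, j_oracle)
    expect_equal(j, d / (2 - d), tolerance = 1e-14)
    # symmetry
    expect_identical(dice_score(G, P), d)
    expect_identical(iou_score(G, P), j)
  }
})

test_that("both scores are monotone in the overlap at fixed set sizes", {
  n <- 40L
  base <- c(rep(TRUE, 10L), rep(FALSE, 30L))
  d <- j <- numeric(0)
  for (shift in 0:10) {
    G <- c(rep(FALSE, shift), rep(TRUE, 10L), rep(FALSE, 30L - shift))
    d <- c(d, dice_score(base, G)); j <- c(j, iou_score(base, G))
  }
  expect_true(all(diff(d) <= 0))  # overlap shrinks as the shift grows
  expect_true(all(diff(j) <= 0))
})

test_that("dataset evaluation pools counts per class before scoring", {
  # slice 1 perfect, slice 2 empty-vs-empty for the foreground
  p1 <- matrix(c(1L, 1L, 0L, 0L), 2, 2); t1 <- p1
  p2 <- matrix(0L, 2, 2); t2 <- p2
  rep_pool <- evaluate_dataset(list(p1, p2), list(t1, t2), classes = 0:1)
  # pooled: foreground counts come only from slice 1 -> exactly 1
  expect_equal(rep_pool$per_class$dice[rep_pool$per_class$class == 1L], 1)
  rep_slice <- evaluate_dataset(list(p1, p2), list(t1, t2), classes = 0:1,
                                aggregate = "per_slice")
  # per-slice oracle: mean of 1 (perfect) and 1 (empty-vs-empty)
  expect_equal(rep_slice$per_class$dice[2L], 1)
  # an imperfect slice separates the two modes
  p1b <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  pool2 <- evaluate_dataset(list(p1b, p2), list(t1, t2), classes = 0:1)
  slice2 <- evaluate_dataset(list(p1b, p2), list(t1, t2), classes = 0:1,
                             aggregate = "per_slice")
  expect_equal(pool2$per_class$dice[2L], 2 * 1 / (1 + 2))       # pooled counts
  expect_equal(slice2$per_class$dice[2L], mean(c(2 / 3, 1)))    # slice mean
  expect_true(all(rep_pool$per_class$iou <= rep_pool$per_class$dice + 1e-14))
})

test_that("single-slice evaluation equals the single-pair scores", {
  set.seed(61)
  p <- matrix(sample(0:2, 64, TRUE), 8, 8)
  t <- matrix(sample(0:2, 64, TRUE), 8, 8)
  rep <- evaluate_dataset(list(p), list(t), classes = 0:2)
  for (cl in 0:2) {
    expect_equal(rep$per_class$dice[rep$per_class$class == cl],
                 dice_score(p == cl, t == cl))
  }
  expect_equal(rep$mean_dice, mean(rep$per_class$dice[-1L]))  # background excluded
  expect_error(evaluate_dataset(list(p), list(matrix(0L, 4, 4))), "mismatch")
})

test_that("error maps flag exactly the mislabelled pixels", {
  a <- matrix(0L, 6, 6)
  expect_false(any(error_map(a, a)))
  b <- a; b[3, 4] <- 2L
  em <- error_map(b, a)
  expect_identical(sum(em), 1L)
  set.seed(62)
  p <- matrix(sample(0:3, 100, TRUE), 10, 10)
  t <- matrix(sample(0:3, 100, TRUE), 10, 10)
  expect_equal(sum(error_map(p, t)), round(100 * (1 - mean(p == t))))
})

test_that("trainable-parameter accounting is exact and additive", {
  expect_identical(count_trainable(list()), 0L)       # fully frozen: nothing
  expect_identical(count_trainable(list(a = matrix(0, 3, 4), b = rep(0, 5))), 17L)
  # the frozen-encoder linear head at full scale: 8 x (768 + 1)
  head <- probe_init(probe_config(8L, 768L), seed = 1L)
  expect_identical(count_trainable(head), 6152L)
  expect_identical(probe_param_count(8L, 768L), 6152L)
  # unfreezing one d-vector adds exactly d
  d <- 768L
  expect_identical(count_trainable(c(head$params, list(extra = rep(0, d)))),
                   6152L + d)
})

test_that("sweep reports compute closed-form two-point statistics", {
  res <- data.frame(method = "m", grid = c(1, 2),
                    dice = c(0.9, 0.8), iou = c(0.8, 0.7))
  rep <- sweep_report(res)
  expect_equal(rep$mean_dice, 0.85)
  expect_equal(rep$sd_dice, abs(0.9 - 0.8) / sqrt(2), tolerance = 1e-12)
  const <- data.frame(method = "m", grid = 1:4, dice = 0.5, iou = 0.4)
  expect_equal(sweep_report(const)$sd_dice, 0)
  single <- data.frame(method = "m", grid = 1, dice = 0.5, iou = 0.4)
  expect_true(is.na(sweep_report(single)$sd_dice))
  # order invariance
  shuf <- res[c(2, 1), ]
  expect_identical(sweep_report(shuf), sweep_report(res))
})
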