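# Reverse-mode automatic differentiation on a dynamic tape.
#
# Every model in this package (ViT masked autoencoder, U-Net backbone, fusion
# blocks, segmentation heads) is built from the operators below. A node wraps a
# numeric matrix/array value plus a closure that maps the incoming gradient to
# gradients for its parents. `ag_backward()` runs reverse-topological
# accumulation from a scalar loss. Nodes whose `requires` flag is FALSE (pure
# constants, e.g. frozen encoder activations) are never traversed, which is
# what makes the frozen-encoder contract cheap to honour.

new_node <- function(value, parents = list(), backfn = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$requires <- requires
  class(e) <- "ag_node"
  e
}

#' @keywords internal
ag_const <- function(value) new_node(value)

#' @keywords internal
ag_param <- function(value) new_node(value, requires = TRUE)

node_requires <- function(...) {
  for (n in list(...)) if (n$requires) return(TRUE)
  FALSE
}

#' Run reverse-mode accumulation from a scalar loss node
#'
#' Gradients are left on the `grad` field of every node on a path from a
#' parameter to the loss; read them off parameter nodes after the call.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_node"), length(loss$value) == 1L)
  # iterative post-order DFS over requires-parents
  topo <- vector("list", 256L); k <- 0L
  stack_nodes <- vector("list", 64L)
  stack_child <- integer(64L)
  sp <- 1L
  stack_nodes[[1L]] <- loss; stack_child[1L] <- 0L
  loss$.seen <- TRUE
  while (sp > 0L) {
    node <- stack_nodes[[sp]]
    ci <- stack_child[sp]
    ps <- node$parents
    if (ci < length(ps)) {
      stack_child[sp] <- ci + 1L
      p <- ps[[ci + 1L]]
      if (p$requires && is.null(p$.seen)) {
        p$.seen <- TRUE
        sp <- sp + 1L
        stack_nodes[[sp]] <- p
        stack_child[sp] <- 0L
      }
    } else {
      k <- k + 1L
      if (k > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[k]] <- node
      sp <- sp - 1L
    }
  }
  topo <- topo[seq_len(k)]
  for (n in topo) { n$.seen <- NULL; n$grad <- NULL }
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (i in rev(seq_len(k))) {
    node <- topo[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$requires || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- basic algebra ----------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ra <- a$requires; rb <- b$requires
  new_node(av %*% bv, list(a, b),
           function(g) list(if (ra) tcrossprod(g, bv) else NULL,
                            if (rb) crossprod(av, g) else NULL),
           ra || rb)
}

# a %*% t(b)
ag_matmul_tb <- function(a, b) {
  av <- a$value; bv <- b$value
  ra <- a$requires; rb <- b$requires
  new_node(tcrossprod(av, bv), list(a, b),
           function(g) list(if (ra) g %*% bv else NULL,
                            if (rb) crossprod(g, av) else NULL),
           ra || rb)
}

ag_add <- function(a, b) {
  ra <- a$requires; rb <- b$requires
  new_node(a$value + b$value, list(a, b),
           function(g) list(if (ra) g else NULL, if (rb) g else NULL),
           ra || rb)
}

# add a length-ncol vector to every row (bias)
ag_add_vec <- function(a, v) {
  ra <- a$requires; rv <- v$requires
  new_node(sweep(a$value, 2L, as.vector(v$value), "+"), list(a, v),
           function(g) list(if (ra) g else NULL,
                            if (rv) colSums(g) else NULL),
           ra || rv)
}

ag_scale <- function(a, s) {
  ra <- a$requires
  new_node(a$value * s, list(a),
           function(g) list(if (ra) g * s else NULL), ra)
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ra <- a$requires; rb <- b$requires
  new_node(av * bv, list(a, b),
           function(g) list(if (ra) g * bv else NULL,
                            if (rb) g * av else NULL),
           ra || rb)
}

ag_relu <- function(a) {
  av <- a$value; ra <- a$requires
  new_node(pmax(av, 0), list(a),
           function(g) list(if (ra) g * (av > 0) else NULL), ra)
}

ag_gelu <- function(a) {
  av <- a$value; ra <- a$requires
  new_node(av * stats::pnorm(av), list(a),
           function(g) list(if (ra) g * (stats::pnorm(av) + av * stats::dnorm(av)) else NULL),
           ra)
}

ag_mean_all <- function(a) {
  n <- length(a$value); ra <- a$requires
  dm <- dim(a$value)
  new_node(matrix(mean(a$value), 1L, 1L), list(a),
           function(g) list(if (ra) array(as.numeric(g) / n, dim = dm) else NULL), ra)
}

# ---- row/column selection and joins ----------------------------------------

# select rows (idx must be unique); also serves as a row permutation
ag_rows <- function(a, idx) {
  av <- a$value; ra <- a$requires
  nr <- nrow(av); nc <- ncol(av)
  new_node(av[idx, , drop = FALSE], list(a),
           function(g) {
             if (!ra) return(list(NULL))
             z <- matrix(0, nr, nc); z[idx, ] <- g; list(z)
           }, ra)
}

ag_cols <- function(a, idx) {
  av <- a$value; ra <- a$requires
  nr <- nrow(av); nc <- ncol(av)
  new_node(av[, idx, drop = FALSE], list(a),
           function(g) {
             if (!ra) return(list(NULL))
             z <- matrix(0, nr, nc); z[, idx] <- g; list(z)
           }, ra)
}

ag_rbind2 <- function(a, b) {
  na <- nrow(a$value); nb <- nrow(b$value)
  ra <- a$requires; rb <- b$requires
  new_node(rbind(a$value, b$value), list(a, b),
           function(g) list(if (ra) g[seq_len(na), , drop = FALSE] else NULL,
                            if (rb) g[na + seq_len(nb), , drop = FALSE] else NULL),
           ra || rb)
}

ag_cbind2 <- function(a, b) {
  na <- ncol(a$value); nb <- ncol(b$value)
  ra <- a$requires; rb <- b$requires
  new_node(cbind(a$value, b$value), list(a, b),
           function(g) list(if (ra) g[, seq_len(na), drop = FALSE] else NULL,
                            if (rb) g[, na + seq_len(nb), drop = FALSE] else NULL),
           ra || rb)
}

# replicate a 1 x d row n times
ag_tile_rows <- function(a, n) {
  ra <- a$requires
  new_node(matrix(a$value, n, length(a$value), byrow = TRUE), list(a),
           function(g) list(if (ra) matrix(colSums(g), 1L) else NULL), ra)
}

# ---- normalization and softmax ---------------------------------------------

# layer norm over each row, learned per-column gain/bias
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  y <- sweep(sweep(xh, 2L, gv, "*"), 2L, bv, "+")
  rx <- x$requires; rg <- gamma$requires; rb <- beta$requires
  new_node(y, list(x, gamma, beta),
           function(g) {
             gxh <- sweep(g, 2L, gv, "*")
             dx <- if (rx) inv * (gxh - rowMeans(gxh) - xh * rowMeans(gxh * xh)) else NULL
             list(dx,
                  if (rg) colSums(g * xh) else NULL,
                  if (rb) colSums(g) else NULL)
           }, rx || rg || rb)
}

# instance norm over each column (channel), learned per-channel gain/bias;
# used inside U-Net conv blocks where feature maps are (H*W) x C matrices
ag_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xh, 2L, gv, "*"), 2L, bv, "+")
  rx <- x$requires; rg <- gamma$requires; rb <- beta$requires
  new_node(y, list(x, gamma, beta),
           function(g) {
             gxh <- sweep(g, 2L, gv, "*")
             dx <- NULL
             if (rx) {
               # dx = inv * (gxh - mean(gxh) - xh * mean(gxh * xh)), per column
               dx <- sweep(gxh, 2L, colMeans(gxh)) -
                 sweep(xh, 2L, colMeans(gxh * xh), "*")
               dx <- sweep(dx, 2L, inv, "*")
             }
             list(dx,
                  if (rg) colSums(g * xh) else NULL,
                  if (rb) colSums(g) else NULL)
           }, rx || rg || rb)
}

ag_softmax_rows <- function(x) {
  xv <- x$value
  s <- exp(xv - apply(xv, 1L, max))
  s <- s / rowSums(s)
  rx <- x$requires
  new_node(s, list(x),
           function(g) list(if (rx) s * (g - rowSums(g * s)) else NULL), rx)
}

# ---- spatial operators (feature maps are (H*W) x C, pixels column-major) ----

.op_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.op_cache[[key]])) .op_cache[[key]] <- make()
  .op_cache[[key]]
}

# 3x3 same-padding neighbour indices: (H*W) x 9 matrix, 0 marks out-of-grid
conv3_index <- function(H, W) {
  cache_get(sprintf("c3_%d_%d", H, W), function() {
    i <- rep(seq_len(H), times = W)
    j <- rep(seq_len(W), each = H)
    idx <- matrix(0L, H * W, 9L)
    k <- 0L
    for (dj in -1:1) for (di in -1:1) {
      k <- k + 1L
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
      v <- integer(H * W)
      v[ok] <- ii[ok] + (jj[ok] - 1L) * H
      idx[, k] <- v
    }
    idx
  })
}

# 3x3 convolution, stride 1, zero padding. w: (9*Cin) x Cout, b: Cout
ag_conv3 <- function(x, w, b, H, W) {
  xv <- x$value
  cin <- ncol(xv)
  idx <- conv3_index(H, W)
  col <- matrix(0, H * W, 9L * cin)
  for (k in 1:9) {
    v <- idx[, k]; ok <- v > 0L
    col[ok, ((k - 1L) * cin + 1L):(k * cin)] <- xv[v[ok], , drop = FALSE]
  }
  wv <- w$value
  out <- sweep(col %*% wv, 2L, as.vector(b$value), "+")
  rx <- x$requires; rw <- w$requires; rb <- b$requires
  new_node(out, list(x, w, b),
           function(g) {
             dx <- NULL
             if (rx) {
               dcol <- tcrossprod(g, wv)
               dx <- matrix(0, H * W, cin)
               for (k in 1:9) {
                 v <- idx[, k]; ok <- v > 0L
                 rows <- v[ok]
                 dx[rows, ] <- dx[rows, , drop = FALSE] +
                   dcol[ok, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
               }
             }
             list(dx,
                  if (rw) crossprod(col, g) else NULL,
                  if (rb) colSums(g) else NULL)
           }, rx || rw || rb)
}

maxpool2_index <- function(H, W) {
  cache_get(sprintf("mp_%d_%d", H, W), function() {
    Ho <- H %/% 2L; Wo <- W %/% 2L
    io <- rep(seq_len(Ho), times = Wo)
    jo <- rep(seq_len(Wo), each = Ho)
    lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d) {
      (2L * io - 1L + d[1L]) + (2L * jo - 2L + d[2L]) * H
    })
  })
}

# 2x2 max pooling, stride 2
ag_maxpool2 <- function(x, H, W) {
  xv <- x$value
  idx <- maxpool2_index(H, W)
  cand <- lapply(idx, function(v) xv[v, , drop = FALSE])
  m <- cand[[1L]]; arg <- matrix(1L, nrow(m), ncol(m))
  for (k in 2:4) {
    better <- cand[[k]] > m
    m[better] <- cand[[k]][better]
    arg[better] <- k
  }
  rx <- x$requires
  new_node(m, list(x),
           function(g) {
             if (!rx) return(list(NULL))
             dx <- matrix(0, H * W, ncol(xv))
             for (k in 1:4) {
               sel <- (arg == k)
               if (!any(sel)) next
               gk <- g * sel
               rows <- idx[[k]]
               dx[rows, ] <- dx[rows, , drop = FALSE] + gk
             }
             list(dx)
           }, rx)
}

upsample2_index <- function(H, W) {
  cache_get(sprintf("up_%d_%d", H, W), function() {
    H2 <- 2L * H; W2 <- 2L * W
    i2 <- rep(seq_len(H2), times = W2)
    j2 <- rep(seq_len(W2), each = H2)
    fwd <- ((i2 + 1L) %/% 2L) + (((j2 + 1L) %/% 2L) - 1L) * H  # out pixel -> in pixel
    inv <- matrix(0L, H * W, 4L)                                # in pixel -> 4 out pixels
    i <- rep(seq_len(H), times = W)
    j <- rep(seq_len(W), each = H)
    k <- 0L
    for (dj in 0:1) for (di in 0:1) {
      k <- k + 1L
      inv[, k] <- (2L * i - 1L + di) + (2L * j - 2L + dj) * H2
    }
    list(fwd = fwd, inv = inv)
  })
}

# nearest-neighbour 2x upsampling
ag_upsample2 <- function(x, H, W) {
  xv <- x$value
  ix <- upsample2_index(H, W)
  rx <- x$requires
  new_node(xv[ix$fwd, , drop = FALSE], list(x),
           function(g) {
             if (!rx) return(list(NULL))
             list(g[ix$inv[, 1L], , drop = FALSE] + g[ix$inv[, 2L], , drop = FALSE] +
                    g[ix$inv[, 3L], , drop = FALSE] + g[ix$inv[, 4L], , drop = FALSE])
           }, rx)
}

#' Sparse bilinear-resize operator between two grid sizes
#'
#' Returns the (h2*w2) x (h1*w1) sparse matrix A such that `A %*% vec(X)` is
#' the bilinearly resized image, pixels in column-major order. Identity when
#' sizes match. Cached per size pair.
#' @keywords internal
resize_operator <- function(h1, w1, h2, w2) {
  cache_get(sprintf("rz_%d_%d_%d_%d", h1, w1, h2, w2), function() {
    axis_op <- function(n1, n2) {
      o <- seq_len(n2)
      s <- (o - 0.5) * n1 / n2 + 0.5
      i0 <- floor(s); t <- s - i0
      i0c <- pmin(pmax(i0, 1L), n1)
      i1c <- pmin(pmax(i0 + 1L, 1L), n1)
      Matrix::sparseMatrix(i = c(o, o), j = c(i0c, i1c), x = c(1 - t, t),
                           dims = c(n2, n1))
    }
    Matrix::kronecker(axis_op(w1, w2), axis_op(h1, h2))
  })
}

# multiply by a constant sparse matrix (used for bilinear resize)
ag_sparse_lmul <- function(A, x) {
  rx <- x$requires
  new_node(as.matrix(A %*% x$value), list(x),
           function(g) list(if (rx) as.matrix(Matrix::crossprod(A, g)) else NULL), rx)
}

# ---- fused losses -----------------------------------------------------------

# mean squared error restricted to a set of patch rows
ag_masked_mse <- function(pred, target, masked_rows) {
  pv <- pred$value
  d <- pv[masked_rows, , drop = FALSE] - target[masked_rows, , drop = FALSE]
  n <- length(d)
  rx <- pred$requires
  new_node(matrix(mean(d * d), 1L, 1L), list(pred),
           function(g) {
             if (!rx) return(list(NULL))
             z <- matrix(0, nrow(pv), ncol(pv))
             z[masked_rows, ] <- 2 * d / n
             list(z * as.numeric(g))
           }, rx)
}

# mean over rows of -z_y + log sum_j exp(z_j); y is a 1-based class index vector
ag_ce_rows <- function(logits, y) {
  zv <- logits$value
  n <- nrow(zv)
  mx <- apply(zv, 1L, max)
  lse <- mx + log(rowSums(exp(zv - mx)))
  zy <- zv[cbind(seq_len(n), y)]
  rx <- logits$requires
  sm <- exp(zv - lse)  # row softmax
  new_node(matrix(mean(lse - zy), 1L, 1L), list(logits),
           function(g) {
             if (!rx) return(list(NULL))
             gz <- sm
             gz[cbind(seq_len(n), y)] <- gz[cbind(seq_len(n), y)] - 1
             list(gz * (as.numeric(g) / n))
           }, rx)
}

# soft Dice loss over all classes (background included) for a single sample;
# p: (n_pixels x C) softmax probabilities, y: 1-based class index per pixel
ag_dice_p <- function(p, y, eps = 1e-5) {
  pv <- p$value
  C <- ncol(pv); n <- nrow(pv)
  g1 <- matrix(0, n, C); g1[cbind(seq_len(n), y)] <- 1
  num <- 2 * colSums(pv * g1) + eps
  den <- colSums(pv * pv) + colSums(g1) + eps
  terms <- 1 - num / den
  rx <- p$requires
  new_node(matrix(mean(terms), 1L, 1L), list(p),
           function(g) {
             if (!rx) return(list(NULL))
             # d term_c / d p_ic = -(2 g_ic * den_c - num_c * 2 p_ic) / den_c^2
             dnum <- sweep(2 * g1, 2L, den, "/")
             dden <- sweep(2 * pv, 2L, num / (den * den), "*")
             list((dden - dnum) * (as.numeric(g) / C))
           }, rx)
}

# focal loss: mean over pixels of -alpha (1-p_t)^gamma log p_t, p clipped at 1e-8
ag_focal_p <- function(p, y, gamma = 2, alpha = 0.25) {
  pv <- p$value
  n <- nrow(pv)
  sel <- cbind(seq_len(n), y)
  pt_raw <- pv[sel]
  pt <- pmin(pmax(pt_raw, 1e-8), 1)
  one_m <- 1 - pt
  val <- mean(-alpha * one_m^gamma * log(pt))
  rx <- p$requires
  new_node(matrix(val, 1L, 1L), list(p),
           function(g) {
             if (!rx) return(list(NULL))
             d <- -alpha * (-gamma * one_m^pmax(gamma - 1, 0) * log(pt) * (gamma > 0) +
                              one_m^gamma / pt)
             d[pt_raw < 1e-8 | pt_raw > 1] <- 0  # clipped region: flat
             z <- matrix(0, n, ncol(pv))
             z[sel] <- d / n
             list(z * as.numeric(g))
           }, rx)
}

# ---- parameter plumbing -----------------------------------------------------

wrap_params <- function(params, trainable = TRUE) {
  lapply(params, if (trainable) ag_param else ag_const)
}

grads_of <- function(nodes) lapply(nodes, function(n) n$grad)

# ---- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

# decoupled weight decay applied to matrices only (not biases or norm gains)
adamw_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- as.numeric(g)
    p <- params[[nm]]
    m <- state$m[[nm]] * beta1 + (1 - beta1) * g
    v <- state$v[[nm]] * beta2 + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    wd <- if (!is.null(dim(p)) && length(dim(p)) >= 2L) weight_decay else 0
    params[[nm]] <- p - lr * (array(upd, dim = dim(p) %||% length(p)) + wd * p)
  }
  list(params = params, state = state)
}
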