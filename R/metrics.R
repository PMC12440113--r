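# Dice/IoU scoring, dataset-level aggregation, error maps, trainable-parameter
# accounting and sweep summaries.
#
# Conventions: Dice = 2|P \cap G| / (|P| + |G|), IoU = |P \cap G| / |P \cup G|,
# both defined as 1 when prediction and truth are both empty (perfect
# agreement on absence). The identity IoU = Dice / (2 - Dice) links them.

#' Dice score of a predicted/true mask pair
#'
#' @param pred,truth logical (or 0/1) arrays of the same shape
#' @return scalar in [0, 1]; 1 when both masks are empty
#' @export
dice_score <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  p <- as.logical(pred); g <- as.logical(truth)
  denom <- sum(p) + sum(g)
  if (denom == 0L) return(1)
  2 * sum(p & g) / denom
}

#' Intersection-over-union (Jaccard index) of a mask pair
#'
#' @inheritParams dice_score
#' @return scalar in [0, 1]; 1 when both masks are empty
#' @export
iou_score <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  p <- as.logical(pred); g <- as.logical(truth)
  uni <- sum(p | g)
  if (uni == 0L) return(1)
  sum(p & g) / uni
}

#' Evaluate predicted label maps against ground truth
#'
#' Per class, pixel counts are pooled over the whole test set before scoring
#' (micro aggregation; the per-slice mean is available via
#' `aggregate = "per_slice"`). The mean row excludes the background class
#' (class 0). Binary tasks therefore report the foreground class.
#'
#' @param predictions,truths lists of integer label maps (0-based classes),
#'   pairwise identical shapes
#' @param classes integer vector of class ids present in the task (default:
#'   union of observed values)
#' @param aggregate `"pooled"` (default) or `"per_slice"`
#' @return an object of class `metric_report`: data.frame `per_class` with
#'   dice and iou columns, `mean_dice`, `mean_iou` over foreground classes,
#'   and `n_items`
#' @export
evaluate_dataset <- function(predictions, truths, classes = NULL,
                             aggregate = c("pooled", "per_slice")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(predictions) == length(truths), length(predictions) >= 1L)
  for (i in seq_along(predictions))
    if (!all(dim(predictions[[i]]) == dim(truths[[i]])))
      stop("prediction/truth shape mismatch at item ", i)
  if (is.null(classes))
    classes <- sort(unique(c(unlist(lapply(truths, unique)),
                             unlist(lapply(predictions, unique)))))
  score_class <- function(cl) {
    if (aggregate == "pooled") {
      inter <- 0; np <- 0; ng <- 0
      for (i in seq_along(predictions)) {
        p <- predictions[[i]] == cl; g <- truths[[i]] == cl
        inter <- inter + sum(p & g); np <- np + sum(p); ng <- ng + sum(g)
      }
      d <- if (np + ng == 0) 1 else 2 * inter / (np + ng)
      j <- if (np + ng - inter == 0) 1 else inter / (np + ng - inter)
      c(dice = d, iou = j)
    } else {
      sc <- vapply(seq_along(predictions), function(i)
        c(dice_score(predictions[[i]] == cl, truths[[i]] == cl),
          iou_score(predictions[[i]] == cl, truths[[i]] == cl)), numeric(2L))
      c(dice = mean(sc[1L, ]), iou = mean(sc[2L, ]))
    }
  }
  sc <- t(vapply(classes, score_class, numeric(2L)))
  per_class <- data.frame(class = classes, dice = sc[, 1L], iou = sc[, 2L])
  fg <- per_class$class != 0L
  structure(list(per_class = per_class,
                 mean_dice = mean(per_class$dice[fg]),
                 mean_iou = mean(per_class$iou[fg]),
                 n_items = length(predictions), aggregate = aggregate),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics (", x$aggregate, " aggregation, ",
      x$n_items, " items)\n", sep = "")
  print(transform(x$per_class, dice = round(dice, 4), iou = round(iou, 4)),
        row.names = FALSE)
  cat(sprintf("mean (foreground): Dice %.4f / IoU %.4f\n", x$mean_dice, x$mean_iou))
  invisible(x)
}

#' Binary error map between two label maps
#'
#' @param pred,truth integer label maps of identical shape
#' @return logical grid, TRUE where the predicted class differs from truth
#' @export
error_map <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("label maps must share a shape")
  pred != truth
}

#' Count trainable parameters of a model
#'
#' Frozen components (the MAE encoder inside probes and segmenters) are
#' excluded; only parameters the optimizer updates are counted.
#'
#' @param model a model object or a plain named list of arrays
#' @param ... unused
#' @return integer count
#' @export
count_trainable <- function(model, ...) UseMethod("count_trainable")

#' @export
count_trainable.default <- function(model, ...) {
  stopifnot(is.list(model))
  sum(vapply(model, length, integer(1L)))
}

#' @export
count_trainable.mae_model <- function(model, ...) count_trainable(model$params)

#' @export
count_trainable.probe_head <- function(model, ...) count_trainable(model$params)

#' @export
count_trainable.funet_model <- function(model, ...) count_trainable(model$params)

#' @export
count_trainable.mae_direct_model <- function(model, ...) count_trainable(model$params)

#' Closed-form trainable-parameter counts
#'
#' `probe_param_count` is the linear head's `C * (d + 1)`;
#' `funet_param_count` enumerates the parameter shapes of a [funet_config()]
#' without allocating any weights (identical to counting an initialized
#' model).
#'
#' @param num_classes classes C; @param embedding_dim encoder dim d
#' @return integer count
#' @export
probe_param_count <- function(num_classes, embedding_dim) {
  as.integer(num_classes) * (as.integer(embedding_dim) + 1L)
}

#' @rdname probe_param_count
#' @param cfg a [funet_config()]; @param encoder_dim MAE embedding width
#' @export
funet_param_count <- function(cfg, encoder_dim) {
  sum(vapply(funet_shapes(cfg, encoder_dim), prod, numeric(1L)))
}

#' Mean/STD summary of a metric sweep
#'
#' Aggregates Dice and IoU across a sweep grid (strides or sample sizes) per
#' method: the mean and the sample (n-1) standard deviation. A single grid
#' point yields the mean with an undefined (NA) STD.
#'
#' @param results data.frame with columns `method`, `grid`, `dice`, `iou`
#' @return data.frame with one row per method: mean/STD of both scores and
#'   the number of grid points; row order is independent of input order
#' @export
sweep_report <- function(results) {
  stopifnot(all(c("method", "grid", "dice", "iou") %in% names(results)))
  methods <- sort(unique(results$method))
  out <- do.call(rbind, lapply(methods, function(m) {
    r <- results[results$method == m, ]
    r <- r[order(r$grid), ]
    data.frame(method = m, n_points = nrow(r),
               mean_dice = mean(r$dice),
               sd_dice = if (nrow(r) > 1L) stats::sd(r$dice) else NA_real_,
               mean_iou = mean(r$iou),
               sd_iou = if (nrow(r) > 1L) stats::sd(r$iou) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
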