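# Shared plumbing: deterministic seed substreams, weight digests, checkpoints,
# append-only training logs.

CHECKPOINT_FORMAT <- "maefunet-ckpt-1"

#' Derive a named deterministic sub-seed from a master seed
#'
#' A single experiment seed fans out to independent, reproducible streams for
#' data sampling, masking, initialization and augmentation. The derivation is
#' a small integer hash of the stream name folded into the master seed; all
#' results stay below 2^31.
#'
#' @param seed master integer seed
#' @param name character stream name
#' @return an integer seed
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147480017)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' MD5 digest of a model's weights
#'
#' Used to assert the freeze contract: the digest of a frozen encoder must be
#' identical before and after any probe or segmenter training.
#'
#' @param x a model object or a plain list of numeric arrays
#' @return a length-one character MD5 string
#' @export
weight_digest <- function(x) {
  params <- if (is.list(x) && !is.null(x$params)) x$params else x
  stopifnot(is.list(params))
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f))
  con <- file(f, "wb")
  # serialize values only, in name order, so attribute churn cannot alter it
  ord <- order(names(params))
  for (i in ord) {
    writeChar(names(params)[i], con, eos = NULL)
    writeBin(as.numeric(params[[i]]), con)
  }
  close(con)
  unname(tools::md5sum(f))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive holding the model configuration, all
#' weights, optimizer state, the training seed and a format-version string.
#'
#' @param model a model object (`mae_model`, `probe_head`, `funet_model`, ...)
#' @param path file path
#' @return `load_checkpoint` returns the model object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(is.list(model))
  model$format <- CHECKPOINT_FORMAT
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!identical(model$format, CHECKPOINT_FORMAT))
    stop("unrecognized checkpoint format in ", path)
  model
}

log_line <- function(log_file, ...) {
  if (is.null(log_file)) return(invisible())
  cat(paste0(paste(..., sep = "\t"), "\n"), file = log_file, append = TRUE)
}

round_half_up <- function(x) floor(x + 0.5)

logsumexp <- function(z) {
  m <- max(z)
  m + log(sum(exp(z - m)))
}

is_binary <- function(x) all(x %in% c(0, 1))
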