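#' @title Dropout patch classifier
#' @description A small convolutional network with a 2-unit softmax head
#'   and multiplicative dropout after every conv block. Dropout masks are
#'   drawn in R and passed to the compiled forward pass, so any stochastic
#'   forward pass can be replayed exactly (and checked against an
#'   independent pure-R oracle). One model is trained per resolution level.
#' @name dropout-classifier
NULL

#' Model configuration
#'
#' The backbone is a configurable stack of `length(conv_channels)` blocks,
#' each a 3x3 convolution with stride 2 and zero padding 1 followed by ReLU
#' and dropout, then global average pooling and a dense 2-unit softmax
#' head. The architecture is deliberately small so that training fits on
#' one CPU in minutes; fidelity is to the weak-label + Monte-Carlo-dropout
#' framework, not to any particular large backbone.
#'
#' @param conv_channels integer vector of output channels per block.
#' @param stem_pool number of 2x average-pool applications in front of the
#'   conv stack (default 1). The stem reduces compute roughly fourfold per
#'   application while keeping the 299x299 patch contract; it contains no
#'   parameters and no dropout.
#' @param dropout_rate shared dropout probability in `[0, 1)`; every block
#'   and the pooled feature vector in front of the dense head are
#'   active-at-inference dropout sites.
#' @param input_size training tile side in pixels (default 299).
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_iterations number of SGD steps.
#' @param eval_every validation-accuracy checkpoint interval (iterations).
#' @param augment_flips random horizontal/vertical flips during training.
#' @param seed seed controlling initialisation and the training stream.
#' @return a `model_config` object.
#' @export
model_config <- function(conv_channels = c(8L, 16L, 32L, 32L),
                         stem_pool = 1L, dropout_rate = 0.3, input_size = 299L,
                         learning_rate = 0.003,
                         batch_size = 8L, max_iterations = 300L,
                         eval_every = 25L, augment_flips = TRUE, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  stopifnot(length(conv_channels) >= 1, all(conv_channels >= 1),
            input_size >= 2^length(conv_channels))
  structure(list(conv_channels = as.integer(conv_channels),
                 stem_pool = as.integer(stem_pool),
                 dropout_rate = dropout_rate,
                 input_size = as.integer(input_size),
                 output_units = 2L,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 eval_every = as.integer(eval_every),
                 augment_flips = isTRUE(augment_flips),
                 seed = as.integer(seed)),
            class = "model_config")
}

# Spatial output size of each block for a given input side.
block_out_dims <- function(config, input_dims = rep(config$input_size, 2)) {
  dims <- vector("list", length(config$conv_channels))
  h <- input_dims[1]; w <- input_dims[2]
  for (s in seq_len(config$stem_pool)) {
    h <- (h + 1L) %/% 2L
    w <- (w + 1L) %/% 2L
  }
  for (b in seq_along(config$conv_channels)) {
    h <- (h - 1L) %/% 2L + 1L
    w <- (w - 1L) %/% 2L + 1L
    dims[[b]] <- c(h, w, config$conv_channels[b])
  }
  dims
}

zero_params <- function(config) {
  cin <- c(3L, head(config$conv_channels, -1))
  list(Wc = lapply(seq_along(config$conv_channels), function(b)
         matrix(0, config$conv_channels[b], 9L * cin[b])),
       bc = lapply(config$conv_channels, function(co) numeric(co)),
       Wd = matrix(0, 2, tail(config$conv_channels, 1)),
       bd = numeric(2))
}

#' Build an (untrained) dropout classifier
#'
#' He-style Gaussian initialisation, fully determined by `config$seed`.
#'
#' @param config a [model_config()].
#' @param level resolution level this model is intended for (provenance).
#' @return a `slide_model` with fields `params`, `config`, `level`,
#'   `learning_curve`, `trained`.
#' @export
build_model <- function(config = model_config(), level = NA_integer_) {
  stopifnot(inherits(config, "model_config"))
  cin <- c(3L, head(config$conv_channels, -1))
  params <- local_seed(mix_seed(config$seed, "init"), {
    Wc <- lapply(seq_along(config$conv_channels), function(b) {
      co <- config$conv_channels[b]
      matrix(rnorm(co * 9 * cin[b], sd = sqrt(2 / (9 * cin[b]))), co, 9L * cin[b])
    })
    Wd <- matrix(rnorm(2 * tail(config$conv_channels, 1),
                       sd = sqrt(2 / tail(config$conv_channels, 1))),
                 2, tail(config$conv_channels, 1))
    list(Wc = Wc, bc = lapply(config$conv_channels, function(co) numeric(co)),
         Wd = Wd, bd = numeric(2))
  })
  structure(list(params = params, config = config, level = level,
                 learning_curve = NULL, trained = FALSE),
            class = "slide_model")
}

#' @export
print.slide_model <- function(x, ...) {
  npar <- sum(vapply(x$params$Wc, length, 0)) +
    sum(vapply(x$params$bc, length, 0)) + length(x$params$Wd) + 2
  cat(sprintf("slide_model (%s): %d conv block(s) %s, dropout %.2f, %d parameters\n",
              if (x$trained) "trained" else "untrained",
              length(x$config$conv_channels),
              paste(x$config$conv_channels, collapse = "-"),
              x$config$dropout_rate, npar))
  if (!is.na(x$level)) cat(sprintf("  resolution level %d\n", x$level))
  if (!is.null(x$learning_curve))
    cat(sprintf("  final validation accuracy %.3f\n",
                tail(x$learning_curve$val_accuracy, 1)))
  invisible(x)
}

#' Number of dropout sites active at inference
#' @param model a `slide_model`.
#' @return integer count (one per conv block, plus the head site).
#' @export
dropout_sites <- function(model) length(model$config$conv_channels) + 1L

# Draw one set of inverted-scale dropout masks from the current RNG stream.
# Order contract (shared with the test oracle): conv blocks in order, each
# mask filled column-major from a single runif vector, then the head mask
# (one value per pooled feature channel).
draw_dropout_masks <- function(config, input_dims = rep(config$input_size, 2)) {
  p <- config$dropout_rate
  masks <- lapply(block_out_dims(config, input_dims), function(d) {
    array((runif(prod(d)) >= p) / (1 - p), d)
  })
  c(masks, list((runif(tail(config$conv_channels, 1)) >= p) / (1 - p)))
}

# normalise input: patches are in [0, 1]; the network sees x - 0.5
prep_patch <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3 || dim(x)[3] != 3)
    stop("patch must be an H x W x 3 array")
  x - 0.5
}

as_patch_list <- function(patches) {
  if (inherits(patches, "patch_set")) return(patches$patches)
  if (is.list(patches) && all(vapply(patches, inherits, TRUE, "patch_set")))
    return(unlist(lapply(patches, `[[`, "patches"), recursive = FALSE))
  if (is.array(patches)) return(list(patches))
  stopifnot(is.list(patches))
  patches
}

patch_labels <- function(patch_sets) {
  if (inherits(patch_sets, "patch_set")) patch_sets <- list(patch_sets)
  unlist(lapply(patch_sets, function(ps) {
    if (is.na(ps$weak_label)) stop("patch set '", ps$slide_id, "' is unlabelled")
    rep(ps$weak_label, length(ps$patches))
  }))
}

flip_patch <- function(x, fh, fv) {
  if (fh) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  if (fv) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  x
}

#' Deterministic forward pass (dropout disabled)
#'
#' @param model a `slide_model`.
#' @param patches a `patch_set`, list of patch sets, a single `H x W x 3`
#'   array, or a list of such arrays.
#' @return numeric matrix `n x 2` of class probabilities (columns A, B);
#'   each row sums to 1. Repeated calls are bit-identical.
#' @export
predict_deterministic <- function(model, patches) {
  stopifnot(inherits(model, "slide_model"))
  xs <- lapply(as_patch_list(patches), prep_patch)
  probs <- .cpp_forward_batch(model$params, xs, NULL, model$config$stem_pool)
  colnames(probs) <- c("A", "B")
  probs
}

#' Train the patch classifier on weakly labelled patches
#'
#' Mini-batch Adam on the softmax cross-entropy, with optional
#' horizontal/vertical flip augmentation. The validation accuracy
#' (deterministic forward pass, argmax labelling) is recorded every
#' `eval_every` iterations and the parameters with the best validation
#' accuracy are retained. The whole run is a pure function of the data and
#' `config$seed`.
#'
#' @param model a `slide_model` from [build_model()].
#' @param train_patches,val_patches labelled `patch_set`s (or lists of
#'   them); both must contain both classes.
#' @param config optional [model_config()] override (defaults to the
#'   model's own).
#' @return the trained `slide_model`, with `learning_curve` set
#'   (`data.frame(iteration, train_loss, val_accuracy)`).
#' @export
train_model <- function(model, train_patches, val_patches, config = NULL) {
  stopifnot(inherits(model, "slide_model"))
  if (is.null(config)) config <- model$config
  xs <- lapply(as_patch_list(train_patches), prep_patch)
  ytr <- patch_labels(train_patches)
  xv <- lapply(as_patch_list(val_patches), prep_patch)
  yv <- patch_labels(val_patches)
  if (length(unique(ytr)) < 2 || length(unique(yv)) < 2)
    stop("training and validation splits must both contain classes A and B")
  bad <- !vapply(xs, function(x) all(dim(x)[1:2] == config$input_size), TRUE)
  if (any(bad))
    stop(sum(bad), " training tile(s) are not ", config$input_size, "x",
         config$input_size)
  y0 <- as.integer(ytr == "B") # class index: A = 0, B = 1

  params <- model$params
  state <- list(m = zero_params(config), v = zero_params(config))
  n <- length(xs)
  curve <- list()
  best <- list(acc = -Inf, params = params)
  val_acc <- function(p) {
    pr <- .cpp_forward_batch(p, xv, NULL, config$stem_pool)
    mean(ifelse(pr[, 1] >= pr[, 2], "A", "B") == yv)
  }
  local_seed(mix_seed(config$seed, "train"), {
    for (it in seq_len(config$max_iterations)) {
      idx <- sample.int(n, min(config$batch_size, n))
      batch <- lapply(idx, function(i) {
        if (config$augment_flips) {
          flip_patch(xs[[i]], runif(1) < 0.5, runif(1) < 0.5)
        } else xs[[i]]
      })
      pdrop <- if (config$dropout_rate > 0) config$dropout_rate else -1
      step <- .cpp_train_batch(params, batch, y0[idx], pdrop,
                               config$learning_rate, state, it,
                               config$stem_pool)
      params <- step$params
      state <- step$state
      if (it %% config$eval_every == 0 ||
          (it == config$max_iterations && it %% config$eval_every != 0)) {
        acc <- val_acc(params)
        curve[[length(curve) + 1]] <-
          data.frame(iteration = it, train_loss = step$loss, val_accuracy = acc)
        if (acc > best$acc) best <- list(acc = acc, params = params)
      }
    }
  })
  model$params <- best$params
  model$config <- config
  model$learning_curve <- do.call(rbind, curve)
  model$trained <- TRUE
  model
}
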