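## CNN calculus (public, oracle-checked) and the seeded training harness.
##
## The public ops expose the layer arithmetic directly: a convolution layer
## computes Y_i = f(B_i + sum_j K_ij * Y_j) over input maps (valid
## cross-correlation, stride 1); a pooling layer maps an
## (m1, m2, m3) volume to (m1, (m2 - F)/S + 1, (m3 - F)/S + 1).

#' Convolution layer specification
#'
#' @param kernels kh x kw x m_in x m_out array of filters `K_ij`.
#' @param biases length-m_out vector `B_i`, one per output map.
#' @param activation `"linear"` or `"relu"` (or any function of one array).
#' @return a `conv_layer_spec`.
#' @export
conv_layer_spec <- function(kernels, biases, activation = "linear") {
  fm_assert(is.array(kernels) && length(dim(kernels)) == 4, "conv",
            "kernels must be a kh x kw x m_in x m_out array")
  fm_assert(all(dim(kernels)[1:2] >= 1), "conv", "kernel spatial dims must be >= 1")
  fm_assert(length(biases) == dim(kernels)[4], "conv",
            "need one bias per output map (%d), got %d", dim(kernels)[4], length(biases))
  f <- if (is.function(activation)) activation
       else switch(activation, linear = identity, relu = relu,
                   fm_stop("conv", "unknown activation '%s'", activation))
  structure(list(kernels = kernels, biases = biases, activation = f),
            class = "conv_layer_spec")
}

#' Forward pass of a convolution layer
#'
#' `Y_i = f(B_i + sum_j K_ij * Y_j)` with `*` the valid cross-correlation at
#' stride 1: output spatial dims are `input - kernel + 1`.
#'
#' @param input_maps H x W x m_in array (a single map may be passed as a
#'   matrix).
#' @param spec a [conv_layer_spec()].
#' @return (H - kh + 1) x (W - kw + 1) x m_out array.
#' @export
#' @examples
#' x <- array(1, dim = c(3, 3, 1))
#' k <- array(1, dim = c(2, 2, 1, 1))
#' conv_forward(x, conv_layer_spec(k, 0))  # all entries 4
conv_forward <- function(input_maps, spec) {
  if (is.matrix(input_maps)) input_maps <- array(input_maps, dim = c(dim(input_maps), 1L))
  fm_assert(inherits(spec, "conv_layer_spec"), "conv", "spec must be a conv_layer_spec")
  d <- dim(input_maps); kd <- dim(spec$kernels)
  fm_assert(d[3] == kd[3], "conv",
            "input has %d maps but kernels expect %d", d[3], kd[3])
  fm_assert(kd[1] <= d[1] && kd[2] <= d[2], "conv",
            "kernel (%d x %d) larger than input (%d x %d)", kd[1], kd[2], d[1], d[2])
  idx <- im2col_index(d[1], d[2], d[3], kd[1], kd[2])
  wmat <- matrix(spec$kernels, ncol = kd[4])
  spec$activation(conv_fwd(input_maps, wmat, spec$biases, idx)$out)
}

#' Output shape of a pooling layer
#'
#' `m1` (the map count) is unchanged; each spatial dim m becomes
#' `floor((m - F) / S) + 1`.
#'
#' @param in_dims integer vector `(m1, m2, m3)`.
#' @param F pooling filter size, >= 1.
#' @param S stride, >= 1.
#' @return integer vector `(m1, m2', m3')`.
#' @export
#' @examples
#' pool_output_shape(c(3, 224, 224), 2, 2)  # 3 112 112
pool_output_shape <- function(in_dims, F, S) {
  fm_assert(length(in_dims) == 3, "pool", "in_dims must be (m1, m2, m3)")
  fm_assert(F >= 1 && S >= 1, "pool", "F and S must be >= 1")
  fm_assert(in_dims[2] >= F && in_dims[3] >= F, "pool",
            "pool filter F = %d exceeds spatial dims (%d, %d)", F, in_dims[2], in_dims[3])
  as.integer(c(in_dims[1],
               (in_dims[2] - F) %/% S + 1,
               (in_dims[3] - F) %/% S + 1))
}

#' Max pooling
#'
#' Each output cell is the maximum over its F x F window at stride S; the
#' output shape agrees with [pool_output_shape()].
#'
#' @param feature_map H x W matrix or H x W x m array.
#' @param F window size.
#' @param S stride.
#' @return pooled matrix or array.
#' @export
#' @examples
#' max_pool(matrix(1:4, 2, 2, byrow = TRUE), 2, 2)  # 4
max_pool <- function(feature_map, F, S) {
  was_mat <- is.matrix(feature_map)
  if (was_mat) feature_map <- array(feature_map, dim = c(dim(feature_map), 1L))
  d <- dim(feature_map)
  pool_output_shape(c(d[3], d[1], d[2]), F, S)  # validates F against dims
  out <- pool_fwd(feature_map, as.integer(F), as.integer(S))$out
  if (was_mat) matrix(out[, , 1], dim(out)[1], dim(out)[2]) else out
}

#' Training configuration
#'
#' Defaults follow the tuned protocol: 100 epochs, learning rate 0.001,
#' numerical-stability epsilon 1e-10, batch size 64. The `tiny` backbone (two
#' conv blocks + max pooling + one fully connected layer, input side 64) is
#' buildable offline; the named transfer-learning backbones require a local
#' weight file and are configuration options only.
#'
#' @param epochs training epochs, >= 1.
#' @param lr learning rate in (0, 1).
#' @param epsilon adaptive-moment stability constant.
#' @param batch mini-batch size, >= 1.
#' @param backbone one of `"tiny"`, `"vgg16"`, `"vgg19"`, `"resnet101"`.
#' @param seed integer seed for initialisation, splits and batch order.
#' @param split train/validation/test fractions summing to 1.
#' @param input_side model input side in pixels (tiny backbone default 64).
#' @param weights_path optional path to pretrained weights for named
#'   backbones.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 0.001, epsilon = 1e-10, batch = 64L,
                         backbone = "tiny", seed = 0L,
                         split = c(0.8, 0.1, 0.1), input_side = 64L,
                         weights_path = NULL) {
  fm_assert(epochs >= 1, "config", "train.epochs must be >= 1")
  fm_assert(lr > 0 && lr < 1, "config", "train.lr must lie in (0, 1)")
  fm_assert(batch >= 1, "config", "train.batch must be >= 1")
  fm_assert(length(split) == 3 && abs(sum(split) - 1) < 1e-8, "config",
            "train.split fractions must sum to 1")
  structure(list(epochs = as.integer(epochs), lr = lr, epsilon = epsilon,
                 batch = as.integer(batch), backbone = backbone,
                 seed = as.integer(seed), split = split,
                 input_side = as.integer(input_side), weights_path = weights_path),
            class = "train_config")
}

known_backbones <- function() c("tiny", "vgg16", "vgg19", "resnet101")

#' Build an untrained classification model
#'
#' The `tiny` backbone is a two-block CNN (3x3 conv, ReLU, 2x2 max pool,
#' twice) feeding one fully connected layer with a two-class softmax head;
#' initial parameters are seeded He-normal draws, so identical configurations
#' give identical models. Named backbones (VGG16/VGG19/ResNet-101) are
#' accepted only with a local `weights_path`; offline without weights they
#' raise a labelled "weights unavailable" error.
#'
#' @param config a [train_config()].
#' @return a `fang_model`.
#' @export
build_model <- function(config = train_config()) {
  fm_assert(inherits(config, "train_config"), "config", "config must be a train_config")
  if (!config$backbone %in% known_backbones()) {
    fm_stop("backbone", "unknown backbone '%s' (options: %s)",
            config$backbone, paste(known_backbones(), collapse = ", "))
  }
  if (config$backbone != "tiny") {
    if (is.null(config$weights_path) || !file.exists(config$weights_path %||% "")) {
      fm_stop("weights", "weights unavailable for backbone '%s': supply weights_path",
              config$backbone)
    }
    fm_stop("weights", "loading pretrained '%s' weights is not supported offline",
            config$backbone)
  }
  side <- config$input_side
  f1 <- 8L; f2 <- 16L
  s1 <- side - 2L; p1 <- s1 %/% 2L          # conv 3x3 then pool 2/2
  s2 <- p1 - 2L;  p2 <- s2 %/% 2L
  flat <- p2 * p2 * f2
  params <- with_seed(config$seed, list(
    w1 = array(stats::rnorm(3 * 3 * 3 * f1, 0, sqrt(2 / (3 * 3 * 3))), c(3, 3, 3, f1)),
    b1 = numeric(f1),
    w2 = array(stats::rnorm(3 * 3 * f1 * f2, 0, sqrt(2 / (3 * 3 * f1))), c(3, 3, f1, f2)),
    b2 = numeric(f2),
    wf = matrix(stats::rnorm(flat * 2, 0, sqrt(2 / flat)), flat, 2),
    bf = numeric(2)
  ))
  structure(list(backbone = "tiny", input_side = side, params = params,
                 classes = bite_labels(), trained = FALSE, config = config),
            class = "fang_model")
}

## per-shape im2col index cache (the index matrices depend only on layer
## shapes, which are fixed for a model; rebuilding them per image dominates
## small-batch cost otherwise)
.idx_cache <- new.env(parent = emptyenv())

cached_idx <- function(h, w, ch, kh, kw) {
  key <- paste(h, w, ch, kh, kw, sep = "x")
  got <- .idx_cache[[key]]
  if (is.null(got)) {
    got <- im2col_index(h, w, ch, kh, kw)
    .idx_cache[[key]] <- got
  }
  got
}

## forward pass; with cache = TRUE returns intermediates for backprop
model_forward <- function(model, x, cache = FALSE) {
  p <- model$params
  d1 <- dim(x)
  idx1 <- cached_idx(d1[1], d1[2], 3L, 3L, 3L)
  c1 <- conv_fwd(x, matrix(p$w1, ncol = dim(p$w1)[4]), p$b1, idx1)
  a1 <- relu(c1$out)
  pl1 <- pool_fwd(a1, 2L, 2L)
  d2 <- dim(pl1$out)
  idx2 <- cached_idx(d2[1], d2[2], d2[3], 3L, 3L)
  c2 <- conv_fwd(pl1$out, matrix(p$w2, ncol = dim(p$w2)[4]), p$b2, idx2)
  a2 <- relu(c2$out)
  pl2 <- pool_fwd(a2, 2L, 2L)
  flat <- as.vector(pl2$out)
  z <- drop(flat %*% p$wf) + p$bf
  if (!cache) return(z)
  list(z = z, x = x, c1 = c1, a1 = a1, pl1 = pl1, c2 = c2, a2 = a2, pl2 = pl2,
       flat = flat, idx1 = idx1, idx2 = idx2)
}

## backprop from dz (length 2) to parameter gradients
model_backward <- function(model, cache, dz) {
  p <- model$params
  dwf <- cache$flat %o% dz
  dbf <- dz
  dflat <- p$wf %*% dz
  dpl2 <- array(dflat, dim = dim(cache$pl2$out))
  da2 <- pool_bwd(dpl2, cache$pl2$arg, dim(cache$a2))
  dc2 <- da2 * (cache$c2$out > 0)
  b2 <- conv_bwd(dc2, cache$c2$cols, matrix(p$w2, ncol = dim(p$w2)[4]),
                 cache$idx2, dim(cache$pl1$out))
  dpl1 <- b2$dx
  da1 <- pool_bwd(dpl1, cache$pl1$arg, dim(cache$a1))
  dc1 <- da1 * (cache$c1$out > 0)
  b1 <- conv_bwd(dc1, cache$c1$cols, matrix(p$w1, ncol = dim(p$w1)[4]),
                 cache$idx1, dim(cache$x))
  list(w1 = array(b1$dw, dim = dim(p$w1)), b1 = b1$db,
       w2 = array(b2$dw, dim = dim(p$w2)), b2 = b2$db,
       wf = dwf, bf = dbf)
}

prepare_pixels <- function(img, side) {
  px <- if (inherits(img, "labeled_image")) img$pixels else as_image(img)
  if (!identical(dim(px)[1:2], c(side, side))) px <- resize_to_canonical(px, side)
  px
}

## stratified index split, seeded
split_dataset <- function(labels, split, seed) {
  parts <- list(train = integer(), val = integer(), test = integer())
  with_seed(seed, {
    for (lb in unique(labels)) {
      idx <- sample(which(labels == lb))
      n <- length(idx)
      n_tr <- round(split[1] * n)
      n_va <- round(split[2] * n)
      n_tr <- min(n_tr, n); n_va <- min(n_va, n - n_tr)
      parts$train <- c(parts$train, idx[seq_len(n_tr)])
      parts$val <- c(parts$val, idx[n_tr + seq_len(n_va)])
      parts$test <- c(parts$test, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
  })
  parts
}

eval_on <- function(model, xs, y) {
  if (length(xs) == 0) return(list(loss = NA_real_, acc = NA_real_, scores = numeric()))
  loss <- 0; correct <- 0; scores <- numeric(length(xs))
  for (i in seq_along(xs)) {
    z <- model_forward(model, xs[[i]])
    pr <- softmax_rows(matrix(z, 1))
    loss <- loss - log(max(pr[y[i]], 1e-12))
    correct <- correct + (which.max(pr) == y[i])
    scores[i] <- pr[1]
  }
  list(loss = loss / length(xs), acc = correct / length(xs), scores = scores)
}

#' Train a classifier on a labelled dataset
#'
#' Mini-batch gradient training with softmax cross-entropy loss and
#' adaptive-moment updates (stability constant `config$epsilon`). The dataset
#' is split train/validation/test by the config fractions (stratified,
#' seeded); one `(train_loss, train_acc, val_acc)` record is logged per epoch,
#' both computed by a full evaluation pass at epoch end. Calling on an already
#' trained model warm-starts from its parameters.
#'
#' @param model a `fang_model` from [build_model()].
#' @param dataset list of `labeled_image`.
#' @param config a [train_config()].
#' @return the trained model, with `$history` (data.frame), `$splits`
#'   (index lists) and `$trained = TRUE`.
#' @export
train_classifier <- function(model, dataset, config = model$config) {
  fm_assert(inherits(model, "fang_model"), "train", "model must be a fang_model")
  fm_assert(length(dataset) > 0, "train", "dataset is empty")
  labels <- vapply(dataset, function(d) d$label, character(1))
  splits <- split_dataset(labels, config$split, config$seed)
  tr_labels <- labels[splits$train]
  fm_assert(length(splits$train) > 0 && length(unique(tr_labels)) == 2, "train",
            "training split must contain both classes")
  side <- model$input_side
  xs <- lapply(dataset, prepare_pixels, side = side)
  y <- match(labels, model$classes)             # 1 = cobra, 2 = other
  tr <- splits$train; va <- splits$val
  params <- model$params
  state <- adam_init(params)
  history <- vector("list", config$epochs)
  t_step <- 0L
  ## per-batch RNG order seeded once; forward index caches shared across calls
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      order_idx <- sample(tr)
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch))
      for (b in batches) {
        grads <- NULL
        for (i in b) {
          m_tmp <- model; m_tmp$params <- params
          cache <- model_forward(m_tmp, xs[[i]], cache = TRUE)
          pr <- softmax_rows(matrix(cache$z, 1))
          dz <- as.vector(pr); dz[y[i]] <- dz[y[i]] - 1
          g <- model_backward(m_tmp, cache, dz / length(b))
          grads <- if (is.null(grads)) g
                   else Map(`+`, grads, g)
        }
        t_step <- t_step + 1L
        upd <- adam_update(params, grads, state, config$lr, t_step,
                           eps = config$epsilon)
        params <- upd$params; state <- upd$state
      }
      m_tmp <- model; m_tmp$params <- params
      tr_eval <- eval_on(m_tmp, xs[tr], y[tr])
      va_eval <- eval_on(m_tmp, xs[va], y[va])
      history[[ep]] <- data.frame(epoch = ep, train_loss = tr_eval$loss,
                                  train_acc = tr_eval$acc, val_acc = va_eval$acc)
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$config <- config
  model$history <- do.call(rbind, history)
  model$splits <- splits
  model
}

#' Predict labels and cobra probabilities
#'
#' @param object a trained `fang_model`.
#' @param images list of H x W x 3 arrays (or `labeled_image`s) at the model
#'   input size.
#' @param ... unused.
#' @return data.frame with one row per image: `label` and `score` (the cobra
#'   probability; `score` and its complement sum to 1).
#' @export
predict.fang_model <- function(object, images, ...) {
  if (length(images) == 0) {
    return(data.frame(label = character(), score = numeric()))
  }
  side <- object$input_side
  labels <- character(length(images)); scores <- numeric(length(images))
  for (i in seq_along(images)) {
    px <- if (inherits(images[[i]], "labeled_image")) images[[i]]$pixels
          else as_image(images[[i]])
    fm_assert(identical(dim(px), c(side, side, 3L)), "predict",
              "image %d has shape [%s], model expects [%d, %d, 3]",
              i, paste(dim(px), collapse = ", "), side, side)
    z <- model_forward(object, px)
    pr <- softmax_rows(matrix(z, 1))
    labels[i] <- object$classes[which.max(pr)]
    scores[i] <- pr[1]
  }
  data.frame(label = labels, score = scores)
}
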