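# Vision module: a small CNN classifier over the 64 object classes.
# Architecture: conv(32, 3x3) -> ReLU -> 2x2 max-pool -> conv(32, 3x3) -> ReLU
# -> fc(16) -> ReLU -> fc(16) -> ReLU -> linear softmax head over 64 classes.
# The 16-dim activations of the second fully connected layer (the layer before
# the softmax head) are the agent's visual object representation.

#' Construct an untrained vision module
#'
#' @param image_size Input side length in pixels (must be even; default 64).
#' @param channels Channels in both convolutional layers (default 32).
#' @param rep_dim Width of the two fully connected layers; the dimensionality
#'   of the visual representation (default 16).
#' @param n_classes Number of object classes (default 64).
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `vision_module`.
#' @export
vision_module <- function(image_size = 64L, channels = 32L, rep_dim = 16L,
                          n_classes = 64L, seed = NULL) {
  image_size <- as.integer(image_size)
  assert_that(image_size %% 2L == 0L && image_size >= 8L,
              "image_size must be an even integer >= 8")
  H2 <- image_size %/% 2L
  flat_dim <- H2 * H2 * channels
  params <- with_local_seed(seed, list(
    conv1 = list(W = init_mat(9L * 3L, channels), b = numeric(channels)),
    conv2 = list(W = init_mat(9L * channels, channels), b = numeric(channels)),
    fc1 = list(W = init_mat(flat_dim, rep_dim), b = rep(0.1, rep_dim)),
    fc2 = list(W = init_mat(rep_dim, rep_dim), b = rep(0.1, rep_dim)),
    head = list(W = init_mat(rep_dim, n_classes), b = numeric(n_classes))))
  structure(list(params = params,
                 image_size = image_size, channels = channels,
                 rep_dim = rep_dim, n_classes = n_classes,
                 geom1 = conv_geom(image_size, image_size, 3L),
                 geom2 = conv_geom(H2, H2, channels)),
            class = "vision_module")
}

# Coerce an image batch (H x W x 3 x n array, or already-flat matrix) to the
# (H*W*3) x n layout used by the conv engine.
as_image_matrix <- function(images, image_size) {
  if (is.matrix(images)) {
    assert_that(nrow(images) == image_size * image_size * 3L,
                "flat image matrix has wrong row count for this module")
    return(images)
  }
  d <- dim(images)
  assert_that(length(d) %in% c(3L, 4L) && d[1] == image_size && d[2] == image_size,
              "images must be H x W x 3 (x n) with H = W = image_size")
  n <- if (length(d) == 4L) d[4] else 1L
  dim(images) <- c(image_size * image_size * 3L, n)
  images
}

# Full forward pass. Returns embeddings (n x rep_dim), logits (n x n_classes)
# and, when keep_cache, the intermediates needed by vision_backward().
vision_forward <- function(vm, images, keep_cache = FALSE) {
  x <- as_image_matrix(images, vm$image_size) - 0.5   # center pixel values
  n <- ncol(x)
  H <- vm$image_size; H2 <- H %/% 2L; F <- vm$channels
  c1 <- conv_forward(stack_images(x, H * H), vm$geom1,
                     vm$params$conv1$W, vm$params$conv1$b)
  r1 <- pmax(c1$out, 0)
  pl <- pool_forward(r1, H, H, n, F)
  c2 <- conv_forward(pl$out, vm$geom2, vm$params$conv2$W, vm$params$conv2$b)
  r2 <- pmax(c2$out, 0)
  feat <- convout_to_rows(r2, H2 * H2, n, F)
  a1 <- feat %*% vm$params$fc1$W + rep(vm$params$fc1$b, each = n)
  f1 <- pmax(a1, 0)
  a2 <- f1 %*% vm$params$fc2$W + rep(vm$params$fc2$b, each = n)
  f2 <- pmax(a2, 0)
  logits <- f2 %*% vm$params$head$W + rep(vm$params$head$b, each = n)
  out <- list(embedding = f2, logits = logits)
  if (keep_cache) {
    out$cache <- list(n = n, c1 = c1, r1mask = c1$out > 0, pool = pl,
                      c2 = c2, r2mask = c2$out > 0, feat = feat,
                      f1 = f1, f2 = f2)
  }
  out
}

# Backward pass from d loss / d logits and (optionally) d loss / d embedding.
# Returns gradients shaped like vm$params.
vision_backward <- function(vm, cache, dlogits = NULL, dembed = NULL) {
  n <- cache$n
  H <- vm$image_size; H2 <- H %/% 2L; F <- vm$channels
  grads <- zeros_like(vm$params)
  if (is.null(dlogits)) {
    df2 <- matrix(0, n, vm$rep_dim)
  } else {
    grads$head$W <- crossprod(cache$f2, dlogits)
    grads$head$b <- colSums(dlogits)
    df2 <- dlogits %*% t(vm$params$head$W)
  }
  if (!is.null(dembed)) df2 <- df2 + dembed
  df2 <- df2 * (cache$f2 > 0)
  grads$fc2$W <- crossprod(cache$f1, df2)
  grads$fc2$b <- colSums(df2)
  df1 <- (df2 %*% t(vm$params$fc2$W)) * (cache$f1 > 0)
  grads$fc1$W <- crossprod(cache$feat, df1)
  grads$fc1$b <- colSums(df1)
  dfeat <- df1 %*% t(vm$params$fc1$W)
  dr2 <- rows_to_convout(dfeat, H2 * H2, n, F) * cache$r2mask
  bk2 <- conv_backward(dr2, cache$c2, vm$geom2, vm$params$conv2$W)
  grads$conv2$W <- bk2$dW
  grads$conv2$b <- bk2$db
  dr1 <- pool_backward(bk2$dx, cache$pool) * cache$r1mask
  bk1 <- conv_backward(dr1, cache$c1, vm$geom1, vm$params$conv1$W,
                       need_dx = FALSE)   # input layer: no upstream gradient
  grads$conv1$W <- bk1$dW
  grads$conv1$b <- bk1$db
  grads
}

#' Visual representations of images
#'
#' @param vm A [vision_module()].
#' @param images Image array (`H x W x 3 x n`) or flat matrix.
#' @param batch_size Evaluation chunk size.
#' @return An `n x rep_dim` matrix of representations (activations of the
#'   fully connected layer before the softmax head).
#' @export
embed_images <- function(vm, images, batch_size = 512L) {
  x <- as_image_matrix(images, vm$image_size)
  n <- ncol(x)
  out <- matrix(0, n, vm$rep_dim)
  for (i0 in seq(1L, n, by = batch_size)) {
    i1 <- min(i0 + batch_size - 1L, n)
    out[i0:i1, ] <- vision_forward(vm, x[, i0:i1, drop = FALSE])$embedding
  }
  out
}

#' Hard-label classification accuracy
#'
#' @param vm A [vision_module()].
#' @param images Image array or flat matrix.
#' @param class_index True classes (0-based).
#' @param batch_size Evaluation chunk size.
#' @return Fraction of images whose argmax class matches the true class.
#' @export
vision_accuracy <- function(vm, images, class_index, batch_size = 512L) {
  x <- as_image_matrix(images, vm$image_size)
  n <- ncol(x)
  correct <- 0L
  for (i0 in seq(1L, n, by = batch_size)) {
    i1 <- min(i0 + batch_size - 1L, n)
    lg <- vision_forward(vm, x[, i0:i1, drop = FALSE])$logits
    correct <- correct + sum(max.col(lg, ties.method = "first") - 1L == class_index[i0:i1])
  }
  correct / n
}

#' Pretraining hyperparameters
#'
#' Defaults follow the full-scale protocol (SGD, learning rate 0.001, batch
#' size 128, 200 epochs, 64-pixel images); all values can be scaled down for
#' quick experiments.
#'
#' @param lr SGD learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param image_size Rendered image side length in pixels.
#' @param momentum SGD momentum (default 0: plain SGD, the full-scale
#'   protocol; small-budget runs converge in far fewer steps with 0.9).
#' @param seed Optional integer seed controlling initialization and batching.
#' @param verbose Print per-epoch losses.
#' @return A list of hyperparameters.
#' @export
pretrain_hp <- function(lr = 0.001, batch_size = 128L, epochs = 200L,
                        image_size = 64L, momentum = 0, seed = NULL,
                        verbose = FALSE) {
  list(lr = lr, batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       image_size = as.integer(image_size), momentum = momentum, seed = seed,
       verbose = verbose)
}

#' Pretrain a vision module with relational label smoothing
#'
#' Trains the CNN classifier by SGD on the cross-entropy between its softmax
#' output and the smoothed targets of [relational_target()], then reports the
#' hard-label accuracy on the held-out test items.
#'
#' @param split A train/test split from [make_split()].
#' @param spec A [smoothing_spec()] (or [bias_condition()]) defining the bias.
#' @param hp Hyperparameters from [pretrain_hp()].
#' @return A `vision_module` with extra fields `test_accuracy`, `spec`,
#'   `hp` and `loss_trace`.
#' @export
pretrain_vision <- function(split, spec = bias_condition("default"), hp = pretrain_hp()) {
  assert_that(is.list(split) && nrow(split$train) > 0, "split$train must be nonempty")
  assert_that(inherits(spec, "smoothing_spec"), "spec must be a smoothing_spec")
  x <- as_image_matrix(render_batch(split$train, hp$image_size), hp$image_size)
  cls <- class_of(split$train)$class_index
  targets <- relational_target(cls, spec)
  n <- ncol(x)
  vm <- vision_module(image_size = hp$image_size, seed = derive_seed(hp$seed, 1L))
  losses <- numeric(hp$epochs)
  mom <- hp$momentum %||% 0
  vel <- if (mom > 0) zeros_like(vm$params) else NULL
  with_local_seed(derive_seed(hp$seed, 2L), {
    for (ep in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (i0 in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[i0:min(i0 + hp$batch_size - 1L, n)]
        fw <- vision_forward(vm, x[, idx, drop = FALSE], keep_cache = TRUE)
        ce <- softmax_xent(fw$logits, targets[idx, , drop = FALSE])
        if (!is.finite(ce$loss)) {
          stop_refgame(sprintf("pretraining diverged (non-finite loss at epoch %d)", ep))
        }
        grads <- vision_backward(vm, fw$cache, dlogits = ce$dlogits)
        if (mom > 0) {
          vel <- map2_params(vel, grads, function(v, g) mom * v + g)
          vm$params <- map2_params(vm$params, vel, function(p, v) p - hp$lr * v)
        } else {
          vm$params <- sgd_update(vm$params, grads, hp$lr)
        }
        ep_loss <- ep_loss + ce$loss
        nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
      if (isTRUE(hp$verbose)) message(sprintf("epoch %3d  loss %.4f", ep, losses[ep]))
    }
  })
  if (nrow(split$test) > 0) {
    xt <- as_image_matrix(render_batch(split$test, hp$image_size), hp$image_size)
    vm$test_accuracy <- vision_accuracy(vm, xt, class_of(split$test)$class_index)
  } else {
    vm$test_accuracy <- NA_real_
  }
  vm$spec <- spec
  vm$hp <- hp
  vm$loss_trace <- losses
  vm
}

#' @export
print.vision_module <- function(x, ...) {
  cat(sprintf("<vision_module> %dpx, %d channels, rep dim %d",
              x$image_size, x$channels, x$rep_dim))
  if (!is.null(x$spec)) cat(" |", format(x$spec$attributes %||% "default"))
  if (!is.null(x$test_accuracy)) cat(sprintf(" | test acc %.3f", x$test_accuracy))
  cat("\n")
  invisible(x)
}

#' Save / load vision module checkpoints as plain text
#'
#' Parameters are written as a JSON file (requires 'jsonlite').
#'
#' @param vm A `vision_module`.
#' @param file Path to write to / read from.
#' @return `save_vision_module` returns the path invisibly;
#'   `load_vision_module` returns the module.
#' @export
save_vision_module <- function(vm, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_refgame("checkpoint export requires the 'jsonlite' package")
  }
  meta <- list(image_size = vm$image_size, channels = vm$channels,
               rep_dim = vm$rep_dim, n_classes = vm$n_classes,
               flat = flatten_params(vm$params))
  jsonlite::write_json(meta, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname save_vision_module
#' @export
load_vision_module <- function(file) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_refgame("checkpoint import requires the 'jsonlite' package")
  }
  meta <- jsonlite::read_json(file, simplifyVector = TRUE)
  vm <- vision_module(meta$image_size, meta$channels, meta$rep_dim, meta$n_classes)
  vm$params <- unflatten_params(vm$params, meta$flat)
  vm
}
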