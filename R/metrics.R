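# Quantifying perceptual bias (representational similarity analysis against
# attribute templates) and linguistic bias (plug-in information-theoretic
# scores over objects, messages and selections).

l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop_refgame("zero-norm representation encountered")
  x / nrm
}

#' Representational similarity matrix over the 64 object classes
#'
#' Entry (i, j) is the mean pairwise cosine similarity between representations
#' of class i-1 and class j-1 (0-based classes). Diagonal entries average only
#' over pairs of *distinct* examples of the same class, so self-similarity
#' does not inflate them.
#'
#' @param representations `n x d` matrix of representations.
#' @param class_index Length-`n` vector of 0-based classes; all 64 classes
#'   must be present with at least 2 examples each.
#' @param N Examples subsampled per class (default 50; fewer are used if a
#'   class has fewer examples).
#' @param seed Optional integer seed for the subsampling.
#' @return A symmetric 64 x 64 matrix.
#' @export
build_rsm <- function(representations, class_index, N = 50L, seed = NULL) {
  assert_that(is.matrix(representations) && nrow(representations) == length(class_index),
              "representations must be a matrix with one row per class label")
  keep <- with_local_seed(seed, {
    unlist(lapply(0:63, function(k) {
      idx <- which(class_index == k)
      assert_that(length(idx) >= 2L,
                  sprintf("class %d needs at least 2 examples for an RSM", k))
      if (length(idx) > N) sample(idx, N) else idx
    }), use.names = FALSE)
  })
  R <- l2_normalize_rows(representations[keep, , drop = FALSE])
  cls <- class_index[keep]
  C <- tcrossprod(R)
  counts <- as.numeric(table(factor(cls, levels = 0:63)))
  A <- matrix(0, 64, nrow(R))
  A[cbind(cls + 1L, seq_len(nrow(R)))] <- 1 / counts[cls + 1L]
  S <- A %*% C %*% t(A)
  # replace diagonal means (which include unit self-pairs) by distinct-pair means
  d_incl <- diag(S)
  diag(S) <- (d_incl * counts^2 - counts) / (counts * (counts - 1))
  (S + t(S)) / 2
}

#' Template similarity matrices from attribute encodings
#'
#' The `overall` template is the pairwise cosine similarity of 3-hot
#' (color, scale, shape) encodings: the fraction of shared attributes.
#' The per-attribute templates come from one-hot encodings of a single
#' attribute's value: unit blocks for classes sharing the value, 0 elsewhere.
#'
#' @return A named list of 64 x 64 matrices: `overall`, `color`, `scale`,
#'   `shape`.
#' @export
attribute_templates <- function() {
  v <- class_values(0:63)
  same <- function(x) outer(x, x, "==") * 1
  list(overall = (same(v$color_value) + same(v$scale_value) + same(v$shape_value)) / 3,
       color = same(v$color_value),
       scale = same(v$scale_value),
       shape = same(v$shape_value))
}

#' RSA score between two similarity matrices
#'
#' Spearman rank correlation (average-rank ties) over the upper off-diagonal
#' triangle of the two matrices.
#'
#' @param rsm_a,rsm_b Equally sized square matrices.
#' @return A correlation in \[-1, 1\]; `NA` (with a warning) when either
#'   triangle is constant, where rank correlation is undefined.
#' @export
rsa <- function(rsm_a, rsm_b) {
  assert_that(is.matrix(rsm_a) && all(dim(rsm_a) == dim(rsm_b)),
              "RSMs must be matrices of equal shape")
  ut <- upper.tri(rsm_a)
  a <- rsm_a[ut]; b <- rsm_b[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant similarity matrix: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Per-attribute RSA bias profile of a vision module
#'
#' Samples `N` instances of each class, embeds them, builds the empirical RSM
#' and correlates it with the overall and per-attribute templates.
#'
#' @param vm A [vision_module()].
#' @param N Example images per class.
#' @param seed Optional integer seed (controls the instance draw).
#' @return Named numeric vector with elements `overall`, `color`, `scale`,
#'   `shape`.
#' @export
rsa_bias_profile <- function(vm, N = 50L, seed = NULL) {
  latents <- sample_instance(rep(0:63, each = N), seed = derive_seed(seed, 1L))
  reps <- embed_images(vm, render_batch(latents, vm$image_size))
  rsm <- build_rsm(reps, class_of(latents)$class_index, N = N,
                   seed = derive_seed(seed, 2L))
  tpl <- attribute_templates()
  vapply(tpl, function(t) rsa(rsm, t), numeric(1))
}

#' RSA alignment between two vision modules
#'
#' Correlates the empirical RSMs of two agents' representations of the same
#' sampled instances (a measure of perceptual alignment).
#'
#' @param vm_a,vm_b Two [vision_module()]s with equal image size.
#' @param N Example images per class.
#' @param seed Optional integer seed.
#' @return A Spearman correlation.
#' @export
rsa_alignment <- function(vm_a, vm_b, N = 50L, seed = NULL) {
  latents <- sample_instance(rep(0:63, each = N), seed = derive_seed(seed, 1L))
  cls <- class_of(latents)$class_index
  imgs <- render_batch(latents, vm_a$image_size)
  ra <- build_rsm(embed_images(vm_a, imgs), cls, N = N, seed = derive_seed(seed, 2L))
  rb <- build_rsm(embed_images(vm_b, imgs), cls, N = N, seed = derive_seed(seed, 2L))
  rsa(ra, rb)
}

# Plug-in entropies (nats) from observation vectors.
plugin_entropy <- function(x) {
  p <- table(x)
  p <- p / sum(p)
  -sum(p * log(p))
}

plugin_joint_entropy <- function(x, y) {
  plugin_entropy(paste(as.character(x), as.character(y), sep = "\r"))
}

as_message_key <- function(messages) {
  if (is.matrix(messages)) apply(messages, 1, paste, collapse = "-") else as.character(messages)
}

#' Information diagram of objects, messages and selections
#'
#' Plug-in (empirical) entropies, conditional entropies and mutual
#' information from paired observations. With selections supplied, the
#' symmetry diagnostics comparing the sender side (objects-messages) and the
#' receiver side (messages-selections) are included.
#'
#' @param objects Vector of target-object labels (one per round).
#' @param messages Messages: a character vector or an `n x L` symbol matrix.
#' @param selections Optional vector of selected-object labels.
#' @param base Logarithm base (default 2: bits).
#' @return A list with `H_O`, `H_M`, `H_O_given_M`, `H_M_given_O`, `I_OM`,
#'   and, when selections are given, `H_S`, `H_S_given_M`, `H_M_given_S`,
#'   `I_MS`.
#' @export
info_diagram <- function(objects, messages, selections = NULL, base = 2) {
  assert_that(length(objects) > 0, "empty input")
  m <- as_message_key(messages)
  assert_that(length(m) == length(objects), "objects and messages must be paired")
  lb <- log(base)
  H_O <- plugin_entropy(objects) / lb
  H_M <- plugin_entropy(m) / lb
  H_OM <- plugin_joint_entropy(objects, m) / lb
  out <- list(H_O = H_O, H_M = H_M,
              H_O_given_M = H_OM - H_M,
              H_M_given_O = H_OM - H_O,
              I_OM = H_O + H_M - H_OM,
              base = base)
  if (!is.null(selections)) {
    assert_that(length(selections) == length(objects), "selections must be paired")
    H_S <- plugin_entropy(selections) / lb
    H_SM <- plugin_joint_entropy(selections, m) / lb
    out$H_S <- H_S
    out$H_S_given_M <- H_SM - H_M
    out$H_M_given_S <- H_SM - H_S
    out$I_MS <- H_M + H_S - H_SM
  }
  out
}

#' Effectiveness of messages about objects
#'
#' `E(O, M) = 1 - H(O|M) / H(O)`: the fraction of object uncertainty removed
#' by knowing the messages. When `objects` are class indices (0..63), the
#' per-attribute scores `E(O_a, M)` for color, scale and shape and their
#' average are also returned.
#'
#' @param objects Object labels per round; 0-based class indices enable the
#'   per-attribute scores.
#' @param messages Character vector or `n x L` symbol matrix.
#' @param per_attribute Compute per-attribute scores (requires class indices).
#' @return A list with `overall`, and when available `per_attribute` (named
#'   vector over color/scale/shape) and `average`.
#' @export
effectiveness <- function(objects, messages, per_attribute = TRUE) {
  m <- as_message_key(messages)
  score <- function(o) {
    H_O <- plugin_entropy(o)
    if (H_O == 0) {
      warning("H(O) = 0: effectiveness undefined")
      return(NA_real_)
    }
    1 - (plugin_joint_entropy(o, m) - plugin_entropy(m)) / H_O
  }
  out <- list(overall = score(objects))
  if (per_attribute && is.numeric(objects) && all(objects == floor(objects)) &&
      all(objects >= 0 & objects <= 63)) {
    v <- class_values(objects)
    out$per_attribute <- c(color = score(v$color_value),
                           scale = score(v$scale_value),
                           shape = score(v$shape_value))
    out$average <- mean(out$per_attribute)
  }
  out
}

#' Greedy message production over an item set
#'
#' Renders each item, embeds it with the sender's vision module and decodes a
#' greedy message — the evaluation regime for linguistic-bias scores.
#'
#' @param sender A [sender_agent()].
#' @param items A latent-factor data.frame.
#' @param pool Optional precomputed [embedding_pool()] for the sender vision.
#' @return A list with `class_index`, `messages` (symbol matrix) and `keys`
#'   (collapsed message strings).
#' @export
evaluate_language <- function(sender, items, pool = NULL) {
  emb <- pool %||% embedding_pool(sender$vision, items)
  fw <- sender_forward(sender, embeddings = emb, mode = "greedy")
  list(class_index = class_of(items)$class_index,
       messages = fw$message,
       keys = as_message_key(fw$message))
}

#' Percentile bootstrap confidence interval
#'
#' @param samples Numeric vector of observations (>= 2).
#' @param statistic Function of a numeric vector (default [mean()]).
#' @param level Coverage level (default 0.95).
#' @param reps Bootstrap resamples (default 10000).
#' @param seed Optional integer seed.
#' @return Numeric vector `c(lower, upper)` with attribute `estimate`.
#' @export
bootstrap_ci <- function(samples, statistic = mean, level = 0.95,
                         reps = 10000L, seed = NULL) {
  assert_that(length(samples) >= 2L, "need at least 2 samples")
  n <- length(samples)
  stats_boot <- with_local_seed(seed, {
    vapply(seq_len(reps),
           function(i) statistic(samples[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats_boot, c(alpha, 1 - alpha), type = 7))
  attr(ci, "estimate") <- statistic(samples)
  ci
}

#' Mean absolute difference between per-condition mean scores
#'
#' With matrices/data.frames (runs x conditions), column means are compared;
#' with plain vectors of condition means, the values are compared directly.
#'
#' @param scores_a,scores_b Two sets of scores over the same conditions.
#' @return Mean over conditions of the absolute difference in means.
#' @export
mean_abs_diff <- function(scores_a, scores_b) {
  ma <- if (is.null(dim(scores_a))) as.numeric(scores_a) else colMeans(as.matrix(scores_a))
  mb <- if (is.null(dim(scores_b))) as.numeric(scores_b) else colMeans(as.matrix(scores_b))
  assert_that(length(ma) == length(mb), "score sets must cover the same conditions")
  mean(abs(ma - mb))
}
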