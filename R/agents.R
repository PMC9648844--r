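# Sender and receiver agents. Each couples a vision module with a recurrent
# language module: the sender initializes a GRU from its visual representation
# of the target and emits a fixed-length symbol sequence; the receiver encodes
# the message with a GRU and scores candidate images by the dot product
# between their adapted visual representations and its final hidden state.
#
# Conventions: symbols and object classes are 0-based; candidate slots are
# 1-based R indices.

#' Construct a sender agent
#'
#' @param vision A [vision_module()] (pretrained or fresh).
#' @param vocab_size Vocabulary size `|V|` (default 4).
#' @param message_length Message length `L` (default 3).
#' @param embed_dim Symbol embedding dimensionality (default 128).
#' @param hidden_dim GRU hidden state dimensionality (default 128).
#' @param seed Optional integer seed for the language-module weights.
#' @return An object of class `sender_agent`.
#' @export
sender_agent <- function(vision, vocab_size = 4L, message_length = 3L,
                         embed_dim = 128L, hidden_dim = 128L, seed = NULL) {
  assert_that(inherits(vision, "vision_module"), "vision must be a vision_module")
  params <- with_local_seed(seed, list(
    adapter = list(W = init_mat(vision$rep_dim, hidden_dim), b = numeric(hidden_dim)),
    embed = list(E = init_mat(vocab_size, embed_dim)),
    gru = gru_params(embed_dim, hidden_dim),
    out = list(W = init_mat(hidden_dim, vocab_size), b = numeric(vocab_size))))
  structure(list(vision = vision, params = params,
                 vocab_size = as.integer(vocab_size),
                 message_length = as.integer(message_length),
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim)),
            class = "sender_agent")
}

#' Construct a receiver agent
#'
#' @inheritParams sender_agent
#' @return An object of class `receiver_agent`.
#' @export
receiver_agent <- function(vision, vocab_size = 4L, message_length = 3L,
                           embed_dim = 128L, hidden_dim = 128L, seed = NULL) {
  assert_that(inherits(vision, "vision_module"), "vision must be a vision_module")
  params <- with_local_seed(seed, list(
    adapter = list(W = init_mat(vision$rep_dim, hidden_dim), b = numeric(hidden_dim)),
    embed = list(E = init_mat(vocab_size, embed_dim)),
    gru = gru_params(embed_dim, hidden_dim)))
  structure(list(vision = vision, params = params,
                 vocab_size = as.integer(vocab_size),
                 message_length = as.integer(message_length),
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim)),
            class = "receiver_agent")
}

# Sample one symbol per row from softmax probabilities (0-based).
sample_symbols <- function(p) {
  V <- ncol(p)
  cs <- p
  for (j in seq_len(V - 1L) + 1L) cs[, j] <- cs[, j - 1L] + cs[, j]
  u <- stats::runif(nrow(p))
  # clamp guards against u exceeding a cumulative sum of 1 - eps
  pmin(as.integer(rowSums(u > cs)), V - 1L)
}

#' Sender forward pass: generate messages
#'
#' Implements the factorized policy
#' `pi_S(m | i) = prod_t pi_S(s_t | s_{<t}, i)`. The GRU hidden state is
#' initialized from the adapted visual representation of the target image;
#' the first input is a zero vector.
#'
#' @param agent A [sender_agent()].
#' @param images Target images (`H x W x 3 x n` array or flat matrix); ignored
#'   when `embeddings` is supplied.
#' @param embeddings Optional precomputed `n x rep_dim` visual representations.
#' @param mode `"sample"` draws each symbol from the policy; `"greedy"` takes
#'   per-step argmax (used at test time).
#' @param seed Optional integer seed for sampling.
#' @param keep_cache Keep intermediates for the REINFORCE backward pass.
#' @return A list with `message` (`n x L`, 0-based symbols), `logp` (`n x L`
#'   per-step log-probabilities of the emitted symbols), `entropy` (`n x L`
#'   per-step policy entropies, nats) and optionally `cache`.
#' @export
sender_forward <- function(agent, images = NULL, embeddings = NULL,
                           mode = c("sample", "greedy"), seed = NULL,
                           keep_cache = FALSE) {
  mode <- match.arg(mode)
  emb <- embeddings %||% embed_images(agent$vision, images)
  n <- nrow(emb)
  L <- agent$message_length
  h <- emb %*% agent$params$adapter$W + rep(agent$params$adapter$b, each = n)
  x <- matrix(0, n, agent$embed_dim)
  msg <- matrix(0L, n, L)
  logp <- matrix(0, n, L)
  ent <- matrix(0, n, L)
  steps <- if (keep_cache) vector("list", L) else NULL
  with_local_seed(seed, {
    for (t in seq_len(L)) {
      g <- gru_cell_forward(x, h, agent$params$gru)
      h <- g$h
      logits <- h %*% agent$params$out$W + rep(agent$params$out$b, each = n)
      p <- softmax_rows(logits)
      s <- if (mode == "greedy") {
        max.col(p, ties.method = "first") - 1L
      } else {
        sample_symbols(p)
      }
      msg[, t] <- s
      logp[, t] <- log(pmax(p[cbind(seq_len(n), s + 1L)], 1e-12))
      ent[, t] <- softmax_entropy(p)$H
      if (keep_cache) steps[[t]] <- list(gru = g$cache, h = h, p = p, s = s)
      x <- agent$params$embed$E[s + 1L, , drop = FALSE]
    }
  })
  out <- list(message = msg, logp = logp, entropy = ent, mode = mode)
  if (keep_cache) out$cache <- list(emb = emb, steps = steps, n = n)
  out
}

#' Receiver forward pass: score candidates given a message
#'
#' Selection policy `pi_R(i | m) ~ exp(f1_R(v_R(i)) . l_R(m))`: a softmax over
#' the dot products between each candidate's adapted representation and the
#' final GRU state after reading the message.
#'
#' @param agent A [receiver_agent()].
#' @param messages `n x L` matrix of 0-based symbols.
#' @param candidate_images Optional `H x W x 3 x (n*(k+1))` array ordered
#'   candidate-within-round; ignored when `candidate_embeddings` is supplied.
#' @param candidate_embeddings `n x (k+1) x rep_dim` array of visual
#'   representations of the candidates.
#' @param mode `"sample"` or `"greedy"`.
#' @param seed Optional integer seed for sampling.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return A list with `selection` (1-based candidate slots), `probs`
#'   (`n x (k+1)` selection distribution), `logp`, `entropy` and optionally
#'   `cache`.
#' @export
receiver_forward <- function(agent, messages, candidate_images = NULL,
                             candidate_embeddings = NULL,
                             mode = c("sample", "greedy"), seed = NULL,
                             keep_cache = FALSE) {
  mode <- match.arg(mode)
  if (is.null(candidate_embeddings)) {
    assert_that(!is.null(candidate_images), "supply candidate images or embeddings")
    n <- nrow(messages)
    flat <- as_image_matrix(candidate_images, agent$vision$image_size)
    k1 <- as.integer(ncol(flat) / n)
    e <- embed_images(agent$vision, flat)
    candidate_embeddings <- array(0, c(n, k1, agent$vision$rep_dim))
    for (j in seq_len(k1)) {
      candidate_embeddings[, j, ] <- e[seq(j, by = k1, length.out = n), ]
    }
  }
  dims <- dim(candidate_embeddings)
  n <- dims[1]; k1 <- dims[2]
  assert_that(k1 >= 2L, "need at least two candidates")
  assert_that(nrow(messages) == n, "messages and candidates disagree in batch size")
  L <- agent$message_length
  h <- matrix(0, n, agent$hidden_dim)
  steps <- if (keep_cache) vector("list", L) else NULL
  for (t in seq_len(L)) {
    x <- agent$params$embed$E[messages[, t] + 1L, , drop = FALSE]
    g <- gru_cell_forward(x, h, agent$params$gru)
    h <- g$h
    if (keep_cache) steps[[t]] <- list(gru = g$cache)
  }
  scores <- matrix(0, n, k1)
  U <- if (keep_cache) vector("list", k1) else NULL
  for (j in seq_len(k1)) {
    ej <- matrix(candidate_embeddings[, j, ], n, dims[3])
    uj <- ej %*% agent$params$adapter$W + rep(agent$params$adapter$b, each = n)
    scores[, j] <- rowSums(uj * h)
    if (keep_cache) U[[j]] <- uj
  }
  p <- softmax_rows(scores)
  sel <- with_local_seed(seed, {
    if (mode == "greedy") max.col(p, ties.method = "first") else sample_symbols(p) + 1L
  })
  out <- list(selection = sel, probs = p,
              logp = log(pmax(p[cbind(seq_len(n), sel)], 1e-12)),
              entropy = softmax_entropy(p)$H, mode = mode)
  if (keep_cache) {
    out$cache <- list(steps = steps, h = h, U = U, messages = messages,
                      cand = candidate_embeddings, n = n, k1 = k1)
  }
  out
}

# REINFORCE backward pass for the sender. The per-agent loss is
#   -(1/n) sum_b adv_b * sum_t log pi(s_t)  -  coef * mean_{b,t} H_bt.
# Returns gradients for the language parameters, the gradient w.r.t. the
# visual embedding of the target (for trainable vision), and the loss value.
sender_backward <- function(agent, fw, advantage, entropy_coef = 0.02) {
  cache <- fw$cache
  assert_that(!is.null(cache), "sender_forward must be called with keep_cache = TRUE")
  n <- cache$n
  L <- agent$message_length
  grads <- zeros_like(agent$params)
  dh_next <- matrix(0, n, agent$hidden_dim)
  for (t in rev(seq_len(L))) {
    st <- cache$steps[[t]]
    onehot <- matrix(0, n, agent$vocab_size)
    onehot[cbind(seq_len(n), st$s + 1L)] <- 1
    dlogits <- (-advantage / n) * (onehot - st$p)
    if (entropy_coef != 0) {
      dlogits <- dlogits - (entropy_coef / (n * L)) * softmax_entropy(st$p)$dlogits
    }
    grads$out$W <- grads$out$W + crossprod(st$h, dlogits)
    grads$out$b <- grads$out$b + colSums(dlogits)
    dh <- dlogits %*% t(agent$params$out$W) + dh_next
    bk <- gru_cell_backward(dh, st$gru, agent$params$gru)
    grads$gru <- add_grads(grads$gru, bk$grads)
    dh_next <- bk$dh
    if (t > 1L) {
      prev_s <- cache$steps[[t - 1L]]$s
      acc <- rowsum(bk$dx, group = prev_s)
      rows <- as.integer(rownames(acc)) + 1L
      grads$embed$E[rows, ] <- grads$embed$E[rows, ] + acc
    }
  }
  grads$adapter$W <- crossprod(cache$emb, dh_next)
  grads$adapter$b <- colSums(dh_next)
  loss <- -mean(advantage * rowSums(fw$logp)) - entropy_coef * mean(fw$entropy)
  list(grads = grads, demb = dh_next %*% t(agent$params$adapter$W), loss = loss)
}

# REINFORCE backward pass for the receiver (loss analogous to the sender's,
# with the log-probability of the sampled selection). Returns gradients, the
# gradient w.r.t. each candidate embedding (n x (k+1) x rep_dim), and the loss.
receiver_backward <- function(agent, fw, advantage, entropy_coef = 0.02) {
  cache <- fw$cache
  assert_that(!is.null(cache), "receiver_forward must be called with keep_cache = TRUE")
  n <- cache$n
  k1 <- cache$k1
  L <- agent$message_length
  grads <- zeros_like(agent$params)
  onehot <- matrix(0, n, k1)
  onehot[cbind(seq_len(n), fw$selection)] <- 1
  dscore <- (-advantage / n) * (onehot - fw$probs)
  if (entropy_coef != 0) {
    dscore <- dscore - (entropy_coef / n) * softmax_entropy(fw$probs)$dlogits
  }
  dh <- matrix(0, n, agent$hidden_dim)
  dcand <- array(0, dim(cache$cand))
  for (j in seq_len(k1)) {
    dh <- dh + dscore[, j] * cache$U[[j]]
    duj <- dscore[, j] * cache$h
    ej <- matrix(cache$cand[, j, ], n, dim(cache$cand)[3])
    grads$adapter$W <- grads$adapter$W + crossprod(ej, duj)
    grads$adapter$b <- grads$adapter$b + colSums(duj)
    dcand[, j, ] <- duj %*% t(agent$params$adapter$W)
  }
  for (t in rev(seq_len(L))) {
    bk <- gru_cell_backward(dh, cache$steps[[t]]$gru, agent$params$gru)
    grads$gru <- add_grads(grads$gru, bk$grads)
    dh <- bk$dh
    acc <- rowsum(bk$dx, group = cache$messages[, t])
    rows <- as.integer(rownames(acc)) + 1L
    grads$embed$E[rows, ] <- grads$embed$E[rows, ] + acc
  }
  loss <- -mean(advantage * fw$logp) - entropy_coef * mean(fw$entropy)
  list(grads = grads, dcand = dcand, loss = loss)
}

#' @export
print.sender_agent <- function(x, ...) {
  cat(sprintf("<sender_agent> |V| = %d, L = %d, embed/hidden = %d/%d\n",
              x$vocab_size, x$message_length, x$embed_dim, x$hidden_dim))
  invisible(x)
}

#' @export
print.receiver_agent <- function(x, ...) {
  cat(sprintf("<receiver_agent> |V| = %d, L = %d, embed/hidden = %d/%d\n",
              x$vocab_size, x$message_length, x$embed_dim, x$hidden_dim))
  invisible(x)
}
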