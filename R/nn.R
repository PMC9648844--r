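# Minimal neural-network engine: dense / convolution (im2col) / 2x2 max-pool
# layers, a GRU cell, softmax losses and SGD / Adam optimizers, all with
# hand-derived backward passes. Gradients are verified against
# finite-difference oracles in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Fan-based uniform initialization.
init_mat <- function(fin, fout) {
  l <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -l, l), fin, fout)
}

softmax_rows <- function(a) {
  p <- exp(a - apply(a, 1, max))
  p / rowSums(p)
}

# ---- convolution (3x3, stride 1, zero 'same' padding) ----------------------
#
# Activation layout on the vision path: a batch of n feature maps with C
# channels is a (n*H*W) x C matrix, row index = p + (i-1)*H*W with spatial
# position p = h + (w-1)*H (h fastest) and image i. Convolution is computed
# as nine offset-shifted GEMMs against C x F weight blocks, which keeps the
# hot path inside BLAS with no large array transposes.

# Precomputed geometry for one spatial size / channel count. The per-batch
# padded-row index vectors are memoized by batch size in `cache`.
conv_geom <- function(H, W, C, k = 3L) {
  stopifnot(k == 3L)
  Hp <- H + 2L; Wp <- W + 2L
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  orig <- w * Hp + h + 1L                 # padded flat position of (h, w)
  offsets <- vector("list", 9L)
  j <- 0L
  for (dw in -1:1) {
    for (dh in -1:1) {
      j <- j + 1L
      offsets[[j]] <- list(
        # rows of the stacked weight matrix (9C x F) for this spatial offset
        wrows = (0:(C - 1L)) * 9L + (dw + 1L) * 3L + (dh + 1L) + 1L,
        pos = orig + dh + dw * Hp)
    }
  }
  list(H = H, W = W, C = C, K = 9L * C, HpWp = Hp * Wp, orig = orig,
       offsets = offsets, cache = new.env(parent = emptyenv()))
}

# Padded-row index vectors for a batch of n images (memoized).
conv_rows <- function(geom, n) {
  key <- as.character(n)
  got <- geom$cache[[key]]
  if (!is.null(got)) return(got)
  img_off <- (0:(n - 1L)) * geom$HpWp
  got <- list(orig = as.vector(outer(geom$orig, img_off, `+`)),
              shift = lapply(geom$offsets,
                             function(o) as.vector(outer(o$pos, img_off, `+`))))
  geom$cache[[key]] <- got
  got
}

# x: (n*H*W) x C stacked activations. W: (9C) x F stacked kernel, b: F.
conv_forward <- function(x, geom, W, b) {
  HW <- geom$H * geom$W
  n <- nrow(x) %/% HW
  rows <- conv_rows(geom, n)
  P <- matrix(0, n * geom$HpWp, geom$C)
  P[rows$orig, ] <- x
  out <- matrix(rep(b, each = n * HW), n * HW, length(b))
  for (j in 1:9) {
    out <- out + P[rows$shift[[j]], , drop = FALSE] %*%
      W[geom$offsets[[j]]$wrows, , drop = FALSE]
  }
  list(out = out, P = P, n = n)
}

conv_backward <- function(dout, cache, geom, W, need_dx = TRUE) {
  n <- cache$n
  rows <- conv_rows(geom, n)
  dW <- matrix(0, nrow(W), ncol(W))
  dP <- if (need_dx) matrix(0, n * geom$HpWp, geom$C) else NULL
  for (j in 1:9) {
    sr <- rows$shift[[j]]
    wr <- geom$offsets[[j]]$wrows
    dW[wr, ] <- crossprod(cache$P[sr, , drop = FALSE], dout)
    if (need_dx) {
      dP[sr, ] <- dP[sr, , drop = FALSE] + dout %*% t(W[wr, , drop = FALSE])
    }
  }
  list(dW = dW, db = colSums(dout),
       dx = if (need_dx) dP[rows$orig, , drop = FALSE] else NULL)
}

# ---- 2x2 max pooling (stride 2) --------------------------------------------

# Memoized row indices of the four 2x2-window positions in the stacked
# (n*H*W) x F layout, keyed by (H, W, n).
pool_rows_cache <- new.env(parent = emptyenv())

pool_rows <- function(H, W, n) {
  key <- paste(H, W, n, sep = "_")
  got <- pool_rows_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  ho <- rep(seq_len(H2), times = W2)
  wo <- rep(seq_len(W2), each = H2)
  img <- rep((0:(n - 1L)) * H * W, each = H2 * W2)
  base_h <- rep(2L * ho - 1L, n)
  base_w <- rep(wo, n)
  got <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(o) {
    (base_h + o[1]) + (2L * base_w - 2L + o[2]) * H + img
  })
  pool_rows_cache[[key]] <- got
  got
}

# x: (n*H*W) x F as produced by conv_forward. Returns pooled maps as a
# (n*H2*W2) x F stacked matrix plus what the backward pass needs.
pool_forward <- function(x, H, W, n, F) {
  idx <- pool_rows(H, W, n)
  M <- x[idx[[1]], , drop = FALSE]
  I <- matrix(1L, nrow(M), ncol(M))
  for (t in 2:4) {
    A <- x[idx[[t]], , drop = FALSE]
    upd <- A > M
    M[upd] <- A[upd]
    I[upd] <- t
  }
  list(out = M, I = I, H = H, W = W, n = n, F = F)
}

# dM: (n*H2*W2) x F stacked pooled gradients; pf: the pool_forward() result.
# Returns stacked (n*H*W) x F gradients routed to the argmax positions.
pool_backward <- function(dM, pf) {
  idx <- pool_rows(pf$H, pf$W, pf$n)
  dA <- matrix(0, pf$n * pf$H * pf$W, pf$F)
  for (t in 1:4) {
    sel <- pf$I == t
    tmp <- matrix(0, nrow(dM), ncol(dM))
    tmp[sel] <- dM[sel]
    dA[idx[[t]], ] <- tmp
  }
  dA
}

# Convert a batch of images stored as (H*W*3) x n per-image columns (the
# render_batch layout) into the stacked (n*H*W) x 3 activation layout.
stack_images <- function(x, HW) {
  n <- ncol(x)
  dim(x) <- c(HW, 3L, n)
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(HW * n, 3L)
  x
}

# Stacked conv output (n*HW) x F -> n x (HW*F) per-image feature rows.
convout_to_rows <- function(x, HW, n, F) {
  dim(x) <- c(HW, n, F)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(n, HW * F)
  x
}

rows_to_convout <- function(x, HW, n, F) {
  dim(x) <- c(n, HW, F)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(HW * n, F)
  x
}

# ---- GRU cell ---------------------------------------------------------------

# Gate order in the stacked weight matrices: reset (r), update (z), new (n).
# h' = (1 - z) * n + z * h,  n = tanh(Wn x + bn_i + r * (Un h + bn_h)).
gru_params <- function(din, H) {
  list(Wi = init_mat(din, 3L * H), Wh = init_mat(H, 3L * H),
       bi = numeric(3L * H), bh = numeric(3L * H))
}

gru_cell_forward <- function(x, h, p) {
  H <- ncol(h)
  gi <- x %*% p$Wi + rep(p$bi, each = nrow(x))
  gh <- h %*% p$Wh + rep(p$bh, each = nrow(h))
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1
  r <- sigmoid(gi[, i1, drop = FALSE] + gh[, i1, drop = FALSE])
  z <- sigmoid(gi[, i2, drop = FALSE] + gh[, i2, drop = FALSE])
  q <- gh[, i3, drop = FALSE]
  nn <- tanh(gi[, i3, drop = FALSE] + r * q)
  hnew <- (1 - z) * nn + z * h
  list(h = hnew, cache = list(x = x, h0 = h, r = r, z = z, nn = nn, q = q))
}

gru_cell_backward <- function(dh2, cache, p) {
  r <- cache$r; z <- cache$z; nn <- cache$nn; q <- cache$q
  dz <- dh2 * (cache$h0 - nn)
  dn <- dh2 * (1 - z)
  dh <- dh2 * z
  dan <- dn * (1 - nn^2)
  dq <- dan * r
  dr <- dan * q
  dar <- dr * r * (1 - r)
  daz <- dz * z * (1 - z)
  dgi <- cbind(dar, daz, dan)
  dgh <- cbind(dar, daz, dq)
  list(dx = dgi %*% t(p$Wi),
       dh = dh + dgh %*% t(p$Wh),
       grads = list(Wi = crossprod(cache$x, dgi), Wh = crossprod(cache$h0, dgh),
                    bi = colSums(dgi), bh = colSums(dgh)))
}

# ---- losses -----------------------------------------------------------------

# Cross-entropy of softmax(logits) against (possibly soft) target rows.
# Returns mean loss and d loss / d logits.
softmax_xent <- function(logits, targets) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -sum(targets * log(pmax(p, 1e-12))) / n
  list(loss = loss, dlogits = (p - targets) / n, p = p)
}

# Entropy of each softmax row (nats) and d entropy / d logits.
softmax_entropy <- function(p) {
  lp <- log(pmax(p, 1e-12))
  Hrow <- -rowSums(p * lp)
  list(H = Hrow, dlogits = -p * (lp + Hrow))
}

# ---- parameter-list utilities ----------------------------------------------

zeros_like <- function(params) lapply(params, function(x) {
  if (is.list(x)) zeros_like(x) else array(0, dim(x) %||% length(x))
})

map2_params <- function(a, b, f) {
  stopifnot(identical(names(a), names(b)))
  out <- a
  for (nm in names(a)) {
    out[[nm]] <- if (is.list(a[[nm]])) map2_params(a[[nm]], b[[nm]], f) else f(a[[nm]], b[[nm]])
  }
  out
}

add_grads <- function(a, b) map2_params(a, b, `+`)

sgd_update <- function(params, grads, lr) {
  map2_params(params, grads, function(p, g) p - lr * g)
}

adam_init <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- state$m
  params <- map2_params(params, map2_params(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  }), function(p, step) p - lr * step)
  list(params = params, state = state)
}

# Flatten a nested parameter list into a single numeric vector (and back);
# used by finite-difference tests and checkpoint export.
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(template, vec) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    k <- length(x)
    out <- vec[(i + 1L):(i + k)]
    i <<- i + k
    dim(out) <- dim(x)
    out
  }
  rec(template)
}
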