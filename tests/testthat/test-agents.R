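test_that("sender messages have fixed length, valid symbols, consistent log-probs", {
  vm <- tiny_vision()
  sa <- sender_agent(vm, vocab_size = 4, message_length = 3, embed_dim = 16,
                     hidden_dim = 24, seed = 1)
  emb <- matrix(rnorm(6 * 16), 6, 16)
  fw <- sender_forward(sa, embeddings = emb, mode = "sample", seed = 9,
                       keep_cache = TRUE)
  expect_equal(dim(fw$message), c(6L, 3L))
  expect_true(all(fw$message >= 0 & fw$message < 4))
  # per-step distributions are probability vectors
  for (st in fw$cache$steps) {
    expect_equal(rowSums(st$p), rep(1, 6), tolerance = 1e-9)
  }
  # factorization: per-step log-probs recover the cached distributions
  for (t in 1:3) {
    st <- fw$cache$steps[[t]]
    expect_equal(fw$logp[, t],
                 log(st$p[cbind(1:6, fw$message[, t] + 1)]), tolerance = 1e-6)
  }
  # total message log-prob equals the sum of per-step log-probs by construction;
  # check additivity against an independent recomputation
  expect_equal(rowSums(fw$logp),
               vapply(1:6, function(i) {
                 sum(log(vapply(1:3, function(t) {
                   fw$cache$steps[[t]]$p[i, fw$message[i, t] + 1]
                 }, numeric(1))))
               }, numeric(1)), tolerance = 1e-6)
})

test_that("greedy decoding is deterministic; sampling is seed-reproducible", {
  vm <- tiny_vision()
  sa <- sender_agent(vm, seed = 2)
  emb <- matrix(rnorm(4 * 16), 4, 16)
  g1 <- sender_forward(sa, embeddings = emb, mode = "greedy")
  g2 <- sender_forward(sa, embeddings = emb, mode = "greedy")
  expect_identical(g1$message, g2$message)
  s1 <- sender_forward(sa, embeddings = emb, mode = "sample", seed = 5)
  s2 <- sender_forward(sa, embeddings = emb, mode = "sample", seed = 5)
  expect_identical(s1$message, s2$message)
})

test_that("receiver distribution is a softmax over candidates", {
  vm <- tiny_vision()
  ra <- receiver_agent(vm, seed = 3)
  msgs <- matrix(c(0L, 1L, 2L), 5, 3, byrow = TRUE)
  cand <- array(rnorm(5 * 3 * 16), c(5, 3, 16))
  fw <- receiver_forward(ra, msgs, candidate_embeddings = cand, mode = "greedy")
  expect_equal(rowSums(fw$probs), rep(1, 5), tolerance = 1e-9)
  expect_true(all(fw$selection %in% 1:3))
  expect_error(receiver_forward(ra, msgs,
                                candidate_embeddings = cand[, 1, , drop = FALSE]),
               "at least two")
})

test_that("duplicated candidates get equal probability; permutation equivariance", {
  vm <- tiny_vision()
  ra <- receiver_agent(vm, seed = 4)
  msgs <- matrix(c(1L, 0L, 3L), 4, 3, byrow = TRUE)
  cand <- array(rnorm(4 * 3 * 16), c(4, 3, 16))
  cand[, 3, ] <- cand[, 1, ]   # slot 3 duplicates slot 1
  fw <- receiver_forward(ra, msgs, candidate_embeddings = cand, mode = "greedy")
  expect_equal(fw$probs[, 1], fw$probs[, 3], tolerance = 1e-12)

  cand2 <- array(rnorm(4 * 3 * 16), c(4, 3, 16))
  perm <- c(3L, 1L, 2L)
  fw_a <- receiver_forward(ra, msgs, candidate_embeddings = cand2, mode = "greedy")
  fw_b <- receiver_forward(ra, msgs, candidate_embeddings = cand2[, perm, ],
                           mode = "greedy")
  expect_equal(fw_b$probs, fw_a$probs[, perm], tolerance = 1e-12)
})

test_that("randomly initialized agents select at chance level", {
  # Monte-Carlo: with random heads, expected accuracy over random rounds is
  # ~ 1/(k+1); 3 candidates, 3000 rounds -> SE ~ 0.0086, allow 4 SE
  vm <- tiny_vision()
  sa <- sender_agent(vm, seed = 11)
  ra <- receiver_agent(vm, seed = 12)
  set.seed(13)
  n <- 3000
  emb <- matrix(rnorm(n * 16, sd = 0.5), n, 16)
  cand <- array(rnorm(n * 3 * 16, sd = 0.5), c(n, 3, 16))
  target_pos <- sample.int(3, n, replace = TRUE)
  msg <- sender_forward(sa, embeddings = emb, mode = "sample", seed = 14)$message
  sel <- receiver_forward(ra, msg, candidate_embeddings = cand,
                          mode = "sample", seed = 15)$selection
  acc <- mean(sel == target_pos)
  expect_lt(abs(acc - 1 / 3), 4 * sqrt(1 / 3 * 2 / 3 / n))
})

test_that("agents reject mismatched vision input", {
  vm <- tiny_vision()
  expect_error(sender_agent(list()), "vision_module")
  sa <- sender_agent(vm, seed = 1)
  expect_error(sender_forward(sa, images = array(0, c(9, 9, 3, 1))), "image_size|H = W")
})
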