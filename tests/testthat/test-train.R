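test_that("joint loss adds classification only when enabled", {
  sc_on <- scenario_config("full_emergence", classification_loss = "on")
  sc_off <- scenario_config("fixed_vision_emergence", classification_loss = "off")
  expect_equal(joint_loss(1.5, 2.25, sc_on), 3.75)
  expect_equal(joint_loss(1.5, 2.25, sc_off), 1.5)
  expect_equal(joint_loss(1.5, 0, sc_on), 1.5)
  # auto: on exactly when some vision module is trainable
  expect_equal(joint_loss(1, 1, scenario_config("language_learning")), 2)
  expect_equal(joint_loss(1, 1, scenario_config("fixed_vision_emergence")), 1)
})

test_that("zero reward and no entropy bonus give a zero policy gradient", {
  ns <- asNamespace("refgame")
  vm <- tiny_vision()
  sa <- sender_agent(vm, seed = 1)
  ra <- receiver_agent(vm, seed = 2)
  emb <- matrix(rnorm(8 * 16), 8, 16)
  cand <- array(rnorm(8 * 3 * 16), c(8, 3, 16))
  fs <- sender_forward(sa, embeddings = emb, mode = "sample", seed = 3,
                       keep_cache = TRUE)
  fr <- receiver_forward(ra, fs$message, candidate_embeddings = cand,
                         mode = "sample", seed = 4, keep_cache = TRUE)
  sb <- ns$sender_backward(sa, fs, advantage = rep(0, 8), entropy_coef = 0)
  rb <- ns$receiver_backward(ra, fr, advantage = rep(0, 8), entropy_coef = 0)
  expect_equal(max(abs(ns$flatten_params(sb$grads))), 0)
  expect_equal(max(abs(ns$flatten_params(rb$grads))), 0)
})

test_that("REINFORCE expected gradient matches finite differences of -E[r]", {
  # Oracle: for a one-step policy with enumerable actions, the expectation of
  # the score-function gradient over actions equals the gradient of -E[r].
  ns <- asNamespace("refgame")
  vm <- tiny_vision()
  sa <- sender_agent(vm, vocab_size = 3, message_length = 1, embed_dim = 4,
                     hidden_dim = 5, seed = 6)
  emb <- matrix(rnorm(16), 1, 16)
  r_of_action <- c(1, 0.25, 0.6)
  action_probs <- function(params) {
    sa2 <- sa
    sa2$params <- params
    fw <- sender_forward(sa2, embeddings = emb, mode = "greedy", keep_cache = TRUE)
    fw$cache$steps[[1]]$p[1, ]
  }
  neg_expected_reward <- function(vec) {
    -sum(action_probs(ns$unflatten_params(sa$params, vec)) * r_of_action)
  }
  # analytic expected REINFORCE gradient: sum_a pi(a) * grad[-r_a log pi(a)]
  fw <- sender_forward(sa, embeddings = emb, mode = "greedy", keep_cache = TRUE)
  p <- fw$cache$steps[[1]]$p[1, ]
  expected_grad <- NULL
  for (a in 0:2) {
    fw_a <- fw
    fw_a$message[1, 1] <- a
    fw_a$cache$steps[[1]]$s <- a
    fw_a$logp[1, 1] <- log(p[a + 1])
    g_a <- ns$flatten_params(
      ns$sender_backward(sa, fw_a, advantage = r_of_action[a + 1],
                         entropy_coef = 0)$grads)
    expected_grad <- if (is.null(expected_grad)) p[a + 1] * g_a else
      expected_grad + p[a + 1] * g_a
  }
  v0 <- ns$flatten_params(sa$params)
  idx <- seq_along(v0)
  eps <- 1e-5
  fd <- vapply(idx, function(i) {
    vp <- v0; vp[i] <- vp[i] + eps
    vm_ <- v0; vm_[i] <- vm_[i] - eps
    (neg_expected_reward(vp) - neg_expected_reward(vm_)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - expected_grad)), 1e-4)
})

test_that("frozen modules stay bit-identical through training", {
  ns <- asNamespace("refgame")
  vm <- desk_vision("default")
  items <- sample_latents(2, seed = 41)
  sp <- make_split(items, 0.75, seed = 42)
  gc_ <- game_config()
  # fixed-vision scenario: both vision modules frozen
  sc1 <- scenario_config("fixed_vision_emergence", epochs = 2, batch_size = 16,
                         batches_per_epoch = 2, eval_rounds = 30, seed = 43)
  snd <- sender_agent(vm, seed = 44)
  rcv <- receiver_agent(vm, seed = 45)
  fit <- train_agents(snd, rcv, sp, gc_, sc1)
  expect_identical(ns$flatten_params(fit$sender$vision$params),
                   ns$flatten_params(vm$params))
  expect_identical(ns$flatten_params(fit$receiver$vision$params),
                   ns$flatten_params(vm$params))
  # language modules did change
  expect_false(identical(ns$flatten_params(fit$sender$params),
                         ns$flatten_params(snd$params)))
  # language learning: the whole sender is frozen
  sc2 <- scenario_config("language_learning", epochs = 1, batch_size = 16,
                         batches_per_epoch = 2, eval_rounds = 30, seed = 46)
  fit2 <- train_agents(fit$sender, receiver_agent(vm, seed = 47), sp, gc_, sc2)
  expect_identical(ns$flatten_params(fit2$sender$params),
                   ns$flatten_params(fit$sender$params))
  expect_identical(ns$flatten_params(fit2$sender$vision$params),
                   ns$flatten_params(fit$sender$vision$params))
  # receiver vision trained
  expect_false(identical(ns$flatten_params(fit2$receiver$vision$params),
                         ns$flatten_params(vm$params)))
})

test_that("training traces are reproducible and bounded", {
  vm <- tiny_vision()
  items <- sample_latents(2, seed = 51)
  sp <- make_split(items, 0.75, seed = 52)
  gc_ <- game_config()
  sc <- scenario_config("fixed_vision_emergence", epochs = 2, batch_size = 16,
                        batches_per_epoch = 2, eval_rounds = 40, seed = 53)
  run <- function() {
    train_agents(sender_agent(vm, seed = 54), receiver_agent(vm, seed = 55),
                 sp, gc_, sc)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$test_reward, f2$test_reward)
  expect_true(all(f1$trace$reward >= 0 & f1$trace$reward <= 1))
  expect_gte(f1$test_reward, 0)
  expect_lte(f1$test_reward, 1)
})

test_that("classification keeps trainable vision above the untrained baseline", {
  vm <- desk_vision("default")
  items <- desk_items()
  sp <- desk_split()
  gc_ <- game_config()
  sc <- scenario_config("language_learning", epochs = 2, batch_size = 32,
                        batches_per_epoch = 4, eval_rounds = 30, seed = 61)
  snd <- sender_agent(vm, seed = 62)
  rcv <- receiver_agent(vm, seed = 63)
  fit <- train_agents(snd, rcv, sp, gc_, sc)
  xt <- refgame:::as_image_matrix(render_batch(sp$test, 16), 16)
  acc <- vision_accuracy(fit$receiver$vision, xt, class_of(sp$test)$class_index)
  untrained <- vision_accuracy(vision_module(16, seed = 64), xt,
                               class_of(sp$test)$class_index)
  expect_gt(acc, untrained)
})

test_that("reinforce_step applies updates only to trainable modules", {
  ns <- asNamespace("refgame")
  vm <- tiny_vision()
  items <- sample_latents(2, seed = 71)
  rb <- sample_round(items, game_config(), n = 12, seed = 72)
  sc <- scenario_config("fixed_vision_emergence", batch_size = 12)
  snd <- sender_agent(vm, seed = 73)
  rcv <- receiver_agent(vm, seed = 74)
  out <- reinforce_step(snd, rcv, rb, sc, lr = 0.01, seed = 75)
  expect_identical(ns$flatten_params(out$sender$vision$params),
                   ns$flatten_params(vm$params))
  expect_false(identical(ns$flatten_params(out$receiver$params),
                         ns$flatten_params(rcv$params)))
  expect_true(all(out$reward %in% c(0, 1)))
})
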