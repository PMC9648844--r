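# REINFORCE training of sender-receiver pairs under three scenarios:
#   fixed_vision_emergence - both language modules train, both visions frozen
#   language_learning      - the whole sender is frozen (its language defines
#                            the protocol); receiver language + vision train
#   full_emergence         - everything trains
# When a vision module is trainable, classification training (with the same
# smoothed targets as pretraining) can continue alongside the game; the two
# losses are added unweighted.

#' Scenario configuration for communication training
#'
#' Defaults follow the full-scale protocol: Adam with learning rate 0.0005 and
#' batch size 128, entropy regularization 0.02, 150 epochs when both agents
#' train and 25 for language learning.
#'
#' @param scenario One of `"fixed_vision_emergence"`, `"language_learning"`,
#'   `"full_emergence"`.
#' @param classification_loss `"auto"` (on exactly when some vision module is
#'   trainable), `"on"` or `"off"` (the no-classification control).
#' @param lr Adam learning rate.
#' @param batch_size Rounds per REINFORCE batch.
#' @param entropy_coef Entropy regularization weight.
#' @param epochs Training epochs (default 150, or 25 for language learning).
#' @param batches_per_epoch Batches per epoch (default: training pool size /
#'   batch size, at least 1).
#' @param baseline Subtract the batch-mean reward from the per-round reward in
#'   the policy gradient (off by default; a stabilizer for small batches).
#' @param eval_rounds Number of greedy test rounds played after training.
#' @param seed Optional integer master seed for the whole run.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("fixed_vision_emergence",
                                         "language_learning", "full_emergence"),
                            classification_loss = c("auto", "on", "off"),
                            lr = 0.0005, batch_size = 128L, entropy_coef = 0.02,
                            epochs = NULL, batches_per_epoch = NULL,
                            baseline = FALSE, eval_rounds = 512L, seed = NULL) {
  scenario <- match.arg(scenario)
  classification_loss <- match.arg(classification_loss)
  if (is.null(epochs)) {
    epochs <- if (scenario == "language_learning") 25L else 150L
  }
  structure(list(scenario = scenario, classification_loss = classification_loss,
                 lr = lr, batch_size = as.integer(batch_size),
                 entropy_coef = entropy_coef, epochs = as.integer(epochs),
                 batches_per_epoch = batches_per_epoch,
                 baseline = isTRUE(baseline),
                 eval_rounds = as.integer(eval_rounds), seed = seed),
            class = "scenario_config")
}

# Which modules train under a scenario.
trainable_modules <- function(sc) {
  switch(sc$scenario,
         fixed_vision_emergence = list(sender_lang = TRUE, sender_vis = FALSE,
                                       receiver_lang = TRUE, receiver_vis = FALSE),
         language_learning = list(sender_lang = FALSE, sender_vis = FALSE,
                                  receiver_lang = TRUE, receiver_vis = TRUE),
         full_emergence = list(sender_lang = TRUE, sender_vis = TRUE,
                               receiver_lang = TRUE, receiver_vis = TRUE))
}

classification_on <- function(sc) {
  tr <- trainable_modules(sc)
  switch(sc$classification_loss,
         on = TRUE, off = FALSE,
         auto = tr$sender_vis || tr$receiver_vis)
}

#' Combine game and classification losses
#'
#' The joint objective is the unweighted sum of the communication-game loss
#' and the classification loss when classification training is on; the game
#' loss alone otherwise.
#'
#' @param game_loss Communication-game loss (scalar).
#' @param classification_loss Classification cross-entropy (scalar).
#' @param config A [scenario_config()].
#' @return The joint scalar loss.
#' @export
joint_loss <- function(game_loss, classification_loss, config) {
  if (classification_on(config)) game_loss + classification_loss else game_loss
}

# One REINFORCE gradient computation on a sampled round batch. Uses the
# ambient RNG stream (wrap in with_local_seed for reproducibility). Returns
# rewards, per-agent losses and gradients for every trainable module.
reinforce_grads <- function(sender, receiver, rounds, sc,
                            item_images = NULL, sender_pool = NULL,
                            receiver_pool = NULL) {
  tr <- trainable_modules(sc)
  n <- rounds$n
  spec_of <- function(vm) vm$spec %||% bias_condition("default")

  # Sender forward (vision with cache only when trainable)
  if (tr$sender_vis) {
    xs <- item_images[, rounds$sender_row, drop = FALSE]
    vs <- vision_forward(sender$vision, xs, keep_cache = TRUE)
    s_emb <- vs$embedding
  } else {
    if (is.null(sender_pool)) sender_pool <- embedding_pool(sender$vision, rounds$items)
    s_emb <- sender_pool[rounds$sender_row, , drop = FALSE]
  }
  fs <- sender_forward(sender, embeddings = s_emb, mode = "sample",
                       keep_cache = TRUE)

  # Receiver forward
  k1 <- ncol(rounds$cand_rows)
  if (tr$receiver_vis) {
    cols <- as.vector(t(rounds$cand_rows))          # candidate-within-round order
    xc <- item_images[, cols, drop = FALSE]
    vr <- vision_forward(receiver$vision, xc, keep_cache = TRUE)
    cand <- array(0, c(n, k1, receiver$vision$rep_dim))
    for (j in seq_len(k1)) cand[, j, ] <- vr$embedding[seq(j, by = k1, length.out = n), ]
  } else {
    if (is.null(receiver_pool)) receiver_pool <- embedding_pool(receiver$vision, rounds$items)
    cand <- gather_candidates(receiver_pool, rounds$cand_rows)
  }
  fr <- receiver_forward(receiver, fs$message, candidate_embeddings = cand,
                         mode = "sample", keep_cache = TRUE)

  reward <- as.numeric(fr$selection == rounds$target_position)
  adv <- if (sc$baseline) reward - mean(reward) else reward

  out <- list(reward = reward,
              message = fs$message, selection = fr$selection,
              sender = list(), receiver = list(),
              class_loss = 0)

  if (tr$sender_lang || tr$sender_vis) {
    sb <- sender_backward(sender, fs, adv, sc$entropy_coef)
    if (!is.finite(sb$loss)) stop_refgame("non-finite sender loss; aborting")
    out$sender$lang_grads <- sb$grads
    out$sender$loss <- sb$loss
    if (tr$sender_vis) {
      vg <- vision_backward(sender$vision, vs$cache, dembed = sb$demb)
      if (classification_on(sc)) {
        cb <- sample.int(nrow(rounds$items), min(sc$batch_size, nrow(rounds$items)))
        cls <- class_of(rounds$items[cb, , drop = FALSE])$class_index
        fwc <- vision_forward(sender$vision, item_images[, cb, drop = FALSE],
                              keep_cache = TRUE)
        ce <- softmax_xent(fwc$logits, relational_target(cls, spec_of(sender$vision)))
        vg <- add_grads(vg, vision_backward(sender$vision, fwc$cache,
                                            dlogits = ce$dlogits))
        out$class_loss <- out$class_loss + ce$loss
      }
      out$sender$vis_grads <- vg
    }
  } else {
    out$sender$loss <- -mean(adv * rowSums(fs$logp)) - sc$entropy_coef * mean(fs$entropy)
  }

  rb <- receiver_backward(receiver, fr, adv, sc$entropy_coef)
  if (!is.finite(rb$loss)) stop_refgame("non-finite receiver loss; aborting")
  if (tr$receiver_lang || tr$receiver_vis) {
    out$receiver$lang_grads <- rb$grads
  }
  out$receiver$loss <- rb$loss
  if (tr$receiver_vis) {
    demb <- matrix(0, n * k1, receiver$vision$rep_dim)
    for (j in seq_len(k1)) demb[seq(j, by = k1, length.out = n), ] <- rb$dcand[, j, ]
    vg <- vision_backward(receiver$vision, vr$cache, dembed = demb)
    if (classification_on(sc)) {
      cb <- sample.int(nrow(rounds$items), min(sc$batch_size, nrow(rounds$items)))
      cls <- class_of(rounds$items[cb, , drop = FALSE])$class_index
      fwc <- vision_forward(receiver$vision, item_images[, cb, drop = FALSE],
                            keep_cache = TRUE)
      ce <- softmax_xent(fwc$logits, relational_target(cls, spec_of(receiver$vision)))
      vg <- add_grads(vg, vision_backward(receiver$vision, fwc$cache,
                                          dlogits = ce$dlogits))
      out$class_loss <- out$class_loss + ce$loss
    }
    out$receiver$vis_grads <- vg
  }
  out$entropy_sender <- mean(fs$entropy)
  out$entropy_receiver <- mean(fr$entropy)
  out
}

#' One REINFORCE update step
#'
#' Computes policy gradients for a sampled round batch and applies a single
#' SGD update with step size `lr` to the trainable modules only. Mostly a
#' building block for inspection and testing; [train_agents()] runs the full
#' Adam-based loop.
#'
#' @param sender,receiver The agents.
#' @param rounds A `round_batch` from [sample_round()].
#' @param sc A [scenario_config()].
#' @param lr Step size for this single update (default `sc$lr`).
#' @param seed Optional integer seed for action sampling.
#' @return A list with updated `sender`, `receiver`, the batch `reward`
#'   vector and per-agent losses.
#' @export
reinforce_step <- function(sender, receiver, rounds, sc, lr = sc$lr, seed = NULL) {
  tr <- trainable_modules(sc)
  need_imgs <- tr$sender_vis || tr$receiver_vis
  item_images <- if (need_imgs) {
    as_image_matrix(render_batch(rounds$items, sender$vision$image_size),
                    sender$vision$image_size)
  } else {
    NULL
  }
  g <- with_local_seed(seed, reinforce_grads(sender, receiver, rounds, sc,
                                             item_images = item_images))
  if (tr$sender_lang) sender$params <- sgd_update(sender$params, g$sender$lang_grads, lr)
  if (tr$sender_vis) {
    sender$vision$params <- sgd_update(sender$vision$params, g$sender$vis_grads, lr)
  }
  if (tr$receiver_lang) {
    receiver$params <- sgd_update(receiver$params, g$receiver$lang_grads, lr)
  }
  if (tr$receiver_vis) {
    receiver$vision$params <- sgd_update(receiver$vision$params, g$receiver$vis_grads, lr)
  }
  list(sender = sender, receiver = receiver, reward = g$reward,
       sender_loss = g$sender$loss, receiver_loss = g$receiver$loss,
       class_loss = g$class_loss)
}

#' Train a sender-receiver pair on the reference game
#'
#' Runs REINFORCE (Adam) over seeded batches of rounds sampled from the
#' training split, under the module-freezing rules of the scenario, then
#' evaluates the greedy (argmax) pair on rounds sampled from the test split.
#'
#' @param sender A [sender_agent()].
#' @param receiver A [receiver_agent()].
#' @param split A train/test split of latent items from [make_split()].
#' @param gc A [game_config()].
#' @param sc A [scenario_config()].
#' @return A list with the trained `sender` and `receiver`, a `trace`
#'   data.frame of per-epoch training metrics, the scalar greedy
#'   `test_reward`, and the completed evaluation `eval_rounds`.
#' @export
train_agents <- function(sender, receiver, split, gc = game_config(),
                         sc = scenario_config()) {
  assert_that(inherits(gc, "game_config"), "gc must be a game_config")
  assert_that(inherits(sc, "scenario_config"), "sc must be a scenario_config")
  assert_that(sender$vocab_size == gc$vocab_size &&
                sender$message_length == gc$message_length &&
                receiver$vocab_size == gc$vocab_size,
              "agents and game config disagree on |V| or L")
  tr <- trainable_modules(sc)
  items <- split$train
  nb <- sc$batches_per_epoch %||% max(1L, nrow(items) %/% sc$batch_size)
  need_imgs <- tr$sender_vis || tr$receiver_vis
  item_images <- if (need_imgs) {
    as_image_matrix(render_batch(items, sender$vision$image_size),
                    sender$vision$image_size)
  } else {
    NULL
  }
  sender_pool <- if (!tr$sender_vis) embedding_pool(sender$vision, items) else NULL
  receiver_pool <- if (!tr$receiver_vis) embedding_pool(receiver$vision, items) else NULL

  opt <- list()
  if (tr$sender_lang) opt$sl <- adam_init(sender$params)
  if (tr$sender_vis) opt$sv <- adam_init(sender$vision$params)
  if (tr$receiver_lang) opt$rl <- adam_init(receiver$params)
  if (tr$receiver_vis) opt$rv <- adam_init(receiver$vision$params)

  trace <- data.frame(epoch = seq_len(sc$epochs), reward = NA_real_,
                      sender_loss = NA_real_, receiver_loss = NA_real_,
                      class_loss = NA_real_, entropy_sender = NA_real_,
                      entropy_receiver = NA_real_)
  run <- function() {
    for (ep in seq_len(sc$epochs)) {
      ep_r <- ep_sl <- ep_rl <- ep_cl <- ep_es <- ep_er <- 0
      for (b in seq_len(nb)) {
        rounds <- sample_round(items, gc, n = sc$batch_size)
        g <- reinforce_grads(sender, receiver, rounds, sc,
                             item_images = item_images,
                             sender_pool = sender_pool,
                             receiver_pool = receiver_pool)
        if (tr$sender_lang) {
          up <- adam_update(sender$params, g$sender$lang_grads, opt$sl, sc$lr)
          sender$params <<- up$params; opt$sl <<- up$state
        }
        if (tr$sender_vis) {
          up <- adam_update(sender$vision$params, g$sender$vis_grads, opt$sv, sc$lr)
          sender$vision$params <<- up$params; opt$sv <<- up$state
        }
        if (tr$receiver_lang) {
          up <- adam_update(receiver$params, g$receiver$lang_grads, opt$rl, sc$lr)
          receiver$params <<- up$params; opt$rl <<- up$state
        }
        if (tr$receiver_vis) {
          up <- adam_update(receiver$vision$params, g$receiver$vis_grads, opt$rv, sc$lr)
          receiver$vision$params <<- up$params; opt$rv <<- up$state
        }
        ep_r <- ep_r + mean(g$reward); ep_sl <- ep_sl + g$sender$loss
        ep_rl <- ep_rl + g$receiver$loss; ep_cl <- ep_cl + g$class_loss
        ep_es <- ep_es + g$entropy_sender; ep_er <- ep_er + g$entropy_receiver
      }
      trace[ep, -1] <<- c(ep_r, ep_sl, ep_rl, ep_cl, ep_es, ep_er) / nb
    }
  }
  if (is.null(sc$seed)) run() else with_local_seed(sc$seed, run())

  # Refresh pools if visions changed, then evaluate greedily on the test split.
  if (tr$sender_vis) sender_pool <- NULL
  if (tr$receiver_vis) receiver_pool <- NULL
  eval_items <- if (nrow(split$test) > 0) split$test else items
  eval_rounds <- sample_round(eval_items, gc, n = sc$eval_rounds,
                              seed = derive_seed(sc$seed, 999983L))
  sp <- embedding_pool(sender$vision, eval_items)
  rp <- embedding_pool(receiver$vision, eval_items)
  eval_rounds <- play_round(sender, receiver, eval_rounds, mode = "greedy",
                            sender_pool = sp, receiver_pool = rp)
  list(sender = sender, receiver = receiver, trace = trace,
       test_reward = mean(eval_rounds$reward), eval_rounds = eval_rounds)
}
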