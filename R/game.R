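# Reference game: the sender sees a target image and emits a message; the
# receiver sees a (possibly different) image of the target plus k distractor
# images and must pick the target. Both get reward 1 on success, 0 otherwise.
# Game variants can restrict which object attributes are relevant: sender and
# receiver targets then only need to agree on the relevant attributes, and
# distractors must differ from the target in at least one relevant attribute.

#' Reference-game configuration
#'
#' @param vocab_size Vocabulary size `|V|` (default 4).
#' @param message_length Message length `L` (default 3).
#' @param n_distractors Number of distractors `k` (default 2).
#' @param relevant_attributes Nonempty subset of `c("color", "scale", "shape")`
#'   that matters for the game (default all three).
#' @return An object of class `game_config`.
#' @export
game_config <- function(vocab_size = 4L, message_length = 3L, n_distractors = 2L,
                        relevant_attributes = class_attributes()) {
  assert_that(vocab_size >= 2L, "|V| must be at least 2")
  assert_that(message_length >= 1L, "L must be at least 1")
  assert_that(n_distractors >= 1L, "k must be at least 1")
  relevant_attributes <- as.character(relevant_attributes)
  assert_that(length(relevant_attributes) > 0 &&
                all(relevant_attributes %in% class_attributes()),
              "relevant_attributes must be a nonempty subset of color/scale/shape")
  structure(list(vocab_size = as.integer(vocab_size),
                 message_length = as.integer(message_length),
                 n_distractors = as.integer(n_distractors),
                 relevant_attributes = sort(unique(relevant_attributes))),
            class = "game_config")
}

# Integer id of the relevant-attribute projection of each class (0-based).
relevant_projection <- function(class_index, relevant) {
  v <- class_values(class_index)
  id <- integer(length(class_index))
  mult <- 1L
  for (a in relevant) {
    val <- switch(a, color = v$color_value, scale = v$scale_value, shape = v$shape_value)
    id <- id + val * mult
    mult <- mult * 4L
  }
  id
}

#' Sample reference-game rounds
#'
#' For each round: a target class is drawn uniformly among the classes present
#' in the item pool; the sender's image and the receiver's target image are
#' independent instances agreeing on the relevant attributes (class attributes
#' not relevant to the game are re-drawn freely for the receiver target);
#' distractor classes are drawn uniformly, mutually distinct, among classes
#' differing from the target in at least one relevant attribute; the target's
#' slot among the `k + 1` candidates is uniform.
#'
#' @param items A latent-factor data.frame to draw instances from, or a split
#'   from [make_split()] (its `train` part is used).
#' @param config A [game_config()].
#' @param n Number of rounds.
#' @param seed Optional integer seed.
#' @return A `round_batch` list with per-round item-row indices, classes and
#'   target positions (fields `sender_row`, `cand_rows`, `target_class`,
#'   `receiver_target_class`, `target_position`).
#' @export
sample_round <- function(items, config = game_config(), n = 1L, seed = NULL) {
  if (is.list(items) && !is.data.frame(items) && !is.null(items$train)) {
    items <- items$train
  }
  validate_latents(items)
  assert_that(nrow(items) > 0, "item pool is empty")
  cls <- class_of(items)$class_index
  classes <- sort(unique(cls))
  rows_by_class <- split(seq_len(nrow(items)), cls)
  rel <- config$relevant_attributes
  proj <- relevant_projection(classes, rel)
  n_proj <- length(unique(proj))
  assert_that(n_proj >= config$n_distractors + 1L,
              paste0("the game needs at least k + 1 distinct relevant-attribute ",
                     "combinations among the available classes"))
  k <- config$n_distractors
  sender_row <- integer(n)
  target_class <- integer(n)
  recv_class <- integer(n)
  target_pos <- integer(n)
  cand_rows <- matrix(0L, n, k + 1L)
  cand_class <- matrix(0L, n, k + 1L)
  pick_row <- function(cl) {
    rr <- rows_by_class[[as.character(cl)]]
    if (is.null(rr)) stop_refgame("no instance of class ", cl, " in the item pool")
    if (length(rr) == 1L) rr else rr[sample.int(length(rr), 1L)]
  }
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      tc <- classes[sample.int(length(classes), 1L)]
      pt <- proj[match(tc, classes)]
      same <- classes[proj == pt]
      rc <- same[sample.int(length(same), 1L)]
      other <- classes[proj != pt]
      dc <- other[sample.int(length(other), k)]
      pos <- sample.int(k + 1L, 1L)
      cc <- integer(k + 1L)
      cc[pos] <- rc
      cc[-pos] <- dc
      sender_row[i] <- pick_row(tc)
      target_class[i] <- tc
      recv_class[i] <- rc
      target_pos[i] <- pos
      cand_class[i, ] <- cc
      cand_rows[i, ] <- vapply(cc, pick_row, integer(1))
    }
  })
  structure(list(config = config, n = n, items = items,
                 sender_row = sender_row, target_class = target_class,
                 receiver_target_class = recv_class,
                 target_position = target_pos,
                 cand_rows = cand_rows, cand_class = cand_class),
            class = "round_batch")
}

#' Precompute visual representations for an item pool
#'
#' Renders every item once at the vision module's resolution and embeds it,
#' so that repeated games over the same pool avoid re-running the CNN.
#'
#' @param vm A [vision_module()].
#' @param items A latent-factor data.frame.
#' @return An `nrow(items) x rep_dim` matrix aligned with the item rows.
#' @export
embedding_pool <- function(vm, items) {
  embed_images(vm, render_batch(items, vm$image_size))
}

# Gather candidate embeddings for a round batch into an n x (k+1) x rep_dim
# array from a pool matrix aligned with the batch's item rows.
gather_candidates <- function(pool, cand_rows) {
  n <- nrow(cand_rows); k1 <- ncol(cand_rows)
  out <- array(0, c(n, k1, ncol(pool)))
  for (j in seq_len(k1)) out[, j, ] <- pool[cand_rows[, j], , drop = FALSE]
  out
}

#' Play completed rounds
#'
#' Runs the sender and receiver on a sampled round batch and scores the
#' outcome: reward 1 when the receiver selects the target slot, else 0.
#'
#' @param sender A [sender_agent()].
#' @param receiver A [receiver_agent()].
#' @param rounds A `round_batch` from [sample_round()].
#' @param mode `"greedy"` (test-time argmax, default) or `"sample"`.
#' @param seed Optional integer seed (used in sample mode).
#' @param sender_pool,receiver_pool Optional precomputed [embedding_pool()]
#'   matrices for the two agents' vision modules (aligned with the round
#'   batch's item pool).
#' @return The round batch completed with `message`, `selection` and `reward`.
#' @export
play_round <- function(sender, receiver, rounds, mode = c("greedy", "sample"),
                       seed = NULL,
                       sender_pool = NULL, receiver_pool = NULL) {
  mode <- match.arg(mode)
  assert_that(inherits(rounds, "round_batch"), "rounds must come from sample_round()")
  if (is.null(sender_pool)) {
    s_emb <- embed_images(sender$vision,
                          render_batch(rounds$items[rounds$sender_row, , drop = FALSE],
                                       sender$vision$image_size))
  } else {
    s_emb <- sender_pool[rounds$sender_row, , drop = FALSE]
  }
  if (is.null(receiver_pool)) {
    receiver_pool <- embedding_pool(receiver$vision, rounds$items)
  }
  cand <- gather_candidates(receiver_pool, rounds$cand_rows)
  fs <- sender_forward(sender, embeddings = s_emb, mode = mode,
                       seed = derive_seed(seed, 1L))
  fr <- receiver_forward(receiver, fs$message, candidate_embeddings = cand,
                         mode = mode, seed = derive_seed(seed, 2L))
  rounds$message <- fs$message
  rounds$selection <- fr$selection
  rounds$reward <- as.integer(fr$selection == rounds$target_position)
  rounds
}

#' Tabulate completed rounds
#'
#' @param rounds A completed `round_batch` from [play_round()].
#' @return A data.frame with one row per round: target class, message symbols
#'   (collapsed to a string), selection, target position, reward.
#' @export
round_log <- function(rounds) {
  assert_that(!is.null(rounds$reward), "rounds have not been played yet")
  data.frame(round = seq_len(rounds$n),
             target_class = rounds$target_class,
             receiver_target_class = rounds$receiver_target_class,
             message = apply(rounds$message, 1, paste, collapse = "-"),
             target_position = rounds$target_position,
             selection = rounds$selection,
             reward = rounds$reward)
}
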