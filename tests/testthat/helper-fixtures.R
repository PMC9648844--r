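# Shared, cheap fixtures built in code. Heavier trained objects are memoized
# per test run in `fixture_env` so several test files can reuse them.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# Small balanced item pool and split used throughout the desk-scale tests.
desk_items <- function() memo("items", refgame::sample_latents(8, seed = 42))
desk_split <- function() memo("split", refgame::make_split(desk_items(), 0.75, seed = 43))

# Desk-scale pretraining settings: 16 px images, 8 instances per class,
# momentum SGD for fast convergence.
desk_hp <- function(seed) {
  refgame::pretrain_hp(lr = 0.1, momentum = 0.9, batch_size = 128L, epochs = 60L,
                       image_size = 16L, seed = seed)
}

# Memoized pretrained vision module per (condition, seed).
desk_vision <- function(condition, seed = 101L) {
  memo(paste0("vm_", condition, "_", seed),
       refgame::pretrain_vision(desk_split(), refgame::bias_condition(condition),
                                desk_hp(seed)))
}

# Desk-scale communication-game settings: short REINFORCE runs with a batch
# baseline for stability at small batch sizes.
desk_game_sc <- function(seed) {
  refgame::scenario_config("fixed_vision_emergence", epochs = 15L,
                           batch_size = 64L, batches_per_epoch = 6L,
                           baseline = TRUE, eval_rounds = 400L, seed = seed)
}

# A tiny untrained vision module for structural agent tests.
tiny_vision <- function(seed = 7L) {
  memo(paste0("tiny_vm_", seed),
       refgame::vision_module(image_size = 8L, channels = 4L, rep_dim = 16L,
                              seed = seed))
}
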