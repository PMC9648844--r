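# Example experiment configuration for inst/scripts/refgame-cli.R.
# Unset fields fall back to the package defaults (full-scale protocol).
# The values below are the desk scale used by the test suite.

condition: color        # default | color | scale | shape | all | color-scale | ...
images_per_class: 8
image_size: 16
train_fraction: 0.75
data_seed: 42
split_seed: 43
seed: 101

# pretraining
pretrain_lr: 0.1
momentum: 0.9
pretrain_epochs: 60
batch_size: 128

# communication game
scenario: fixed_vision_emergence   # | language_learning | full_emergence
vocab_size: 4
message_length: 3
n_distractors: 2
game_lr: 0.0005
entropy_coef: 0.02
game_epochs: 15
batches_per_epoch: 6
baseline: true
eval_rounds: 400
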