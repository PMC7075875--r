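# Desk-scale adversarial-training fixtures, computed once per test run
# and shared between the improvement and transfer checks.
#
# Study conditions for the smoke task: 128 training pairs and 32 held-out
# pairs of 32 x 32 phantoms, 5 degrees of inter-shot rotation, S = 4
# shots, random trajectory, 8 coils.  Corrector: 2-block residual U-Net
# with 16 base features; Adam pretraining (600 steps, lr 2e-3) followed
# by 500 adversarial steps (RMSProp, lr 1e-4, lambda 0.6, batch 4, two
# discriminator updates per generator update).

smoke_cache <- new.env(parent = emptyenv())

smoke_unet <- function() unet_config(n_blocks = 2, base_features = 16,
                                     input_size = 32)

smoke_train_config <- function(seed, steps = 500L, pretrain = TRUE) {
  train_config(learning_rate = 1e-4, batch_size = 4L, lambda = 0.6,
               d_updates_per_g = 2L, pretrain = pretrain,
               pretrain_steps = 600L, pretrain_learning_rate = 2e-3,
               steps = steps, seed = seed, eval_every = 25L)
}

smoke_seeds <- c(11L, 12L, 13L)

memo <- function(key, expr) {
  if (!exists(key, envir = smoke_cache)) {
    assign(key, force(expr), envir = smoke_cache)
  }
  get(key, envir = smoke_cache)
}

smoke_dataset <- function(n_shots = 4L) {
  memo(sprintf("data_S%d", n_shots),
       make_paired_dataset(128, 32, 5, n_shots, "random", n_coils = 8,
                           seed = 101))
}

smoke_holdout <- function(n_shots = 4L) {
  memo(sprintf("hold_S%d", n_shots),
       make_paired_dataset(32, 32, 5, n_shots, "random", n_coils = 8,
                           seed = 202))
}

# From-scratch smoke models, one per seed, with validation logging.
smoke_scratch_models <- function() {
  memo("scratch", lapply(smoke_seeds, function(s)
    train(smoke_dataset(), smoke_train_config(s), smoke_unet(),
          val_dataset = smoke_holdout())))
}

# Model trained on the S = 16 variant of the smoke task (transfer source).
smoke_s16_model <- function() {
  memo("s16", train(smoke_dataset(16L), smoke_train_config(21L),
                    smoke_unet()))
}

batch_as_list <- function(x) {
  lapply(seq_len(dim(x)[4]), function(i) matrix(x[, , 1, i],
                                                dim(x)[1], dim(x)[2]))
}
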