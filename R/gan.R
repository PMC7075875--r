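# Conditional adversarial training of the motion corrector.
#
# The generator G maps CG-SENSE motion-artifact images x_m to corrected
# images; the discriminator D scores images as real (clean) vs generated.
# G minimizes  ||x_c - G(x_m)||_2 + lambda * log(1 - D(G(x_m)))  (batch
# averaged); D minimizes the standard cross-entropy objective
# -[log D(x_c) + log(1 - D(G(x_m)))].  Following common practice the
# generator's adversarial gradient uses the non-saturating form
# (maximize log D(G(x_m))) while the reported generator loss is the
# weighted-sum definition above.  D is updated twice per G update; both
# use RMSProp; optional generator pretraining on the data term alone uses
# Adam at the same learning rate.

PROB_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# Per-image L2 norms of (clean - generated), batch averaged.
data_mismatch <- function(clean, generated) {
  d <- dim(clean)
  diff <- matrix(clean - generated, prod(d[1:3]), d[4])
  norms <- sqrt(colSums(diff * diff))
  list(loss = mean(norms), norms = norms, diff = diff)
}

#' Generator loss: data mismatch plus weighted adversarial term
#'
#' `mean_i ||x_c_i - G(x_m)_i||_2 + lambda * mean_i log(1 - D(G(x_m))_i)`.
#' With `lambda = 0` this is the batch-mean L2 norm of the residual.
#'
#' @param clean Batch of reference images (matrix, list, or 4D array).
#' @param generated Matching batch of generator outputs `G(x_m)`.
#' @param d_fake Discriminator probabilities on `generated` (required when
#'   `lambda > 0`).
#' @param lambda Non-negative adversarial weight.
#' @return Scalar loss.
#' @export
generator_loss <- function(clean, generated, d_fake = NULL, lambda = 0) {
  abort_if(!is.numeric(lambda) || lambda < 0, "`lambda` must be >= 0")
  clean <- as_image_batch(clean)
  generated <- as_image_batch(generated)
  abort_if(!all(dim(clean) == dim(generated)),
           "`clean` and `generated` shapes disagree")
  loss <- data_mismatch(clean, generated)$loss
  if (lambda > 0) {
    abort_if(is.null(d_fake), "`d_fake` is required when lambda > 0")
    loss <- loss + lambda * mean(log(1 - clamp_prob(d_fake)))
  }
  loss
}

#' Discriminator loss: binary cross-entropy on real vs generated
#'
#' `-[mean log D(x_c) + mean log(1 - D(G(x_m)))]`, probabilities clamped
#' to `[1e-7, 1 - 1e-7]`.  A discriminator outputting 0.5 everywhere
#' scores `2 log 2`.
#'
#' @param d_real Probabilities on clean images.
#' @param d_fake Probabilities on generated images.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  -(mean(log(clamp_prob(d_real))) + mean(log(1 - clamp_prob(d_fake))))
}

#' Training settings for the adversarial corrector
#'
#' Defaults mirror the full-scale recipe: RMSProp at learning rate
#' `1e-4`, batch size 16, two discriminator updates per generator update,
#' adversarial weight `lambda = 0.6` (the winning region of the
#' validation grid is `> 0.5`), and Adam generator pretraining at the
#' same learning rate.
#'
#' @param learning_rate RMSProp learning rate for G and D.
#' @param batch_size Minibatch size (>= 1).
#' @param lambda Adversarial weight in `[0, 1]`.
#' @param d_updates_per_g Discriminator updates per generator update.
#' @param pretrain Run Adam pretraining of G on the data term first.
#' @param pretrain_steps Number of pretraining steps.
#' @param pretrain_learning_rate Adam learning rate (defaults to
#'   `learning_rate`).
#' @param steps Number of adversarial steps.
#' @param seed Master seed for initialization and batch sampling.
#' @param eval_every Validation-loss logging period (steps).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         lambda = 0.6, d_updates_per_g = 2L,
                         pretrain = TRUE, pretrain_steps = 200L,
                         pretrain_learning_rate = learning_rate,
                         steps = 500L, seed = 0L, eval_every = 25L) {
  abort_if(lambda < 0, "`lambda` must be >= 0")
  abort_if(batch_size < 1, "`batch_size` must be >= 1")
  abort_if(d_updates_per_g < 1, "`d_updates_per_g` must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), lambda = lambda,
                 d_updates_per_g = as.integer(d_updates_per_g),
                 pretrain = isTRUE(pretrain),
                 pretrain_steps = as.integer(pretrain_steps),
                 pretrain_learning_rate = pretrain_learning_rate,
                 steps = as.integer(steps), seed = as.integer(seed),
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

dataset_arrays <- function(dataset) {
  abort_if(is.null(dataset$clean) || is.null(dataset$corrupted),
           "dataset must contain `clean` and `corrupted` images")
  clean <- as_image_batch(dataset$clean)
  corrupted <- as_image_batch(dataset$corrupted)
  abort_if(dim(clean)[4] == 0, "dataset is empty")
  abort_if(!all(dim(clean) == dim(corrupted)),
           "clean and corrupted sets disagree in shape")
  list(clean = clean, corrupted = corrupted, n = dim(clean)[4])
}

sample_batch <- function(arrays, batch_size) {
  idx <- sample.int(arrays$n, min(batch_size, arrays$n))
  list(clean = arrays$clean[, , , idx, drop = FALSE],
       corrupted = arrays$corrupted[, , , idx, drop = FALSE])
}

# Gradient of the batch-mean per-image L2 norm w.r.t. the generated batch.
data_mismatch_grad <- function(dm, d) {
  B <- d[4]
  scale <- 1 / (B * pmax(dm$norms, 1e-12))
  array(-dm$diff * rep(scale, each = prod(d[1:3])), d)
}

new_corrector <- function(params, unet_cfg, train_cfg, log,
                          disc_params = NULL) {
  structure(list(params = params, config = unet_cfg,
                 train_config = train_cfg, log = log,
                 disc_params = disc_params),
            class = "trained_corrector")
}

#' Pretrain the generator on the data-mismatch term
#'
#' Adam optimization of the batch-mean L2 residual norm alone (no
#' discriminator), used to warm-start adversarial training.
#'
#' @param dataset Paired dataset: list with `clean` and `corrupted`
#'   image batches (see [make_paired_dataset()]).
#' @param config A [train_config()]; uses `pretrain_steps`,
#'   `pretrain_learning_rate`, `batch_size`, `seed`.
#' @param unet A [unet_config()] describing the generator.
#' @return A `trained_corrector` with the pretraining log.
#' @export
pretrain_generator <- function(dataset, config, unet) {
  arrays <- dataset_arrays(dataset)
  abort_if(dim(arrays$clean)[1] != unet$input_size,
           "dataset image size does not match the network config")
  with_seed(derive_seed(config$seed, "pretrain"), {
    params <- init_generator_params(unet, derive_seed(config$seed, "g_init"))
    state <- adam_init(params)
    log <- data.frame(step = integer(0), data_loss = numeric(0))
    for (step in seq_len(config$pretrain_steps)) {
      batch <- sample_batch(arrays, config$batch_size)
      fw <- gen_forward(params, unet, batch$corrupted, keep = TRUE)
      dm <- data_mismatch(batch$clean, fw$y)
      dG <- data_mismatch_grad(dm, dim(fw$y))
      bk <- gen_backward(params, unet, fw$cache, dG)
      upd <- adam_step(params, bk$grads, state,
                       config$pretrain_learning_rate)
      params <- upd$params; state <- upd$state
      log <- rbind(log, data.frame(step = step, data_loss = dm$loss))
    }
    new_corrector(params, unet, config, list(pretrain = log))
  })
}

#' Train the adversarial motion corrector
#'
#' Alternating optimization: per generator update the discriminator is
#' updated `d_updates_per_g` times on fresh minibatches; both networks
#' use RMSProp.  With `config$pretrain = TRUE` (and no `init` model) the
#' generator is first pretrained with Adam on the data term.
#'
#' @inheritParams pretrain_generator
#' @param init Optional `trained_corrector` whose generator parameters
#'   warm-start training (used by [finetune()]).
#' @param val_dataset Optional held-out paired dataset; its data loss is
#'   logged before the first step and every `config$eval_every` steps.
#' @param stop_at_val_loss Optional target: stop as soon as a logged
#'   validation data loss is at or below it (requires `val_dataset`).
#' @return A `trained_corrector`; `$log$train` holds per-step generator /
#'   discriminator losses, `$log$validation` the validation-loss trace.
#' @export
train <- function(dataset, config, unet, init = NULL, val_dataset = NULL,
                  stop_at_val_loss = NULL) {
  arrays <- dataset_arrays(dataset)
  abort_if(dim(arrays$clean)[1] != unet$input_size,
           "dataset image size does not match the network config")
  val <- if (!is.null(val_dataset)) dataset_arrays(val_dataset) else NULL

  pre_log <- NULL
  if (!is.null(init)) {
    abort_if(!inherits(init, "trained_corrector"),
             "`init` must be a trained_corrector")
    abort_if(init$config$input_size != unet$input_size,
             "`init` model size does not match the network config")
    g_params <- init$params
  } else if (config$pretrain && config$pretrain_steps > 0) {
    pre <- pretrain_generator(dataset, config, unet)
    g_params <- pre$params
    pre_log <- pre$log$pretrain
  } else {
    g_params <- init_generator_params(unet, derive_seed(config$seed, "g_init"))
  }

  with_seed(derive_seed(config$seed, "train"), {
    d_params <- init_discriminator_params(unet,
                                          derive_seed(config$seed, "d_init"))
    g_state <- rmsprop_init(g_params)
    d_state <- rmsprop_init(d_params)
    lam <- config$lambda
    log <- vector("list", config$steps)
    val_log <- list()

    val_loss <- function(params) {
      fw <- gen_forward(params, unet, val$corrupted)
      data_mismatch(val$clean, fw$y)$loss
    }
    if (!is.null(val)) {
      v0 <- val_loss(g_params)
      val_log[[1]] <- data.frame(step = 0L, val_data_loss = v0)
    }
    hit_target <- function() {
      !is.null(stop_at_val_loss) && length(val_log) > 0 &&
        val_log[[length(val_log)]]$val_data_loss <= stop_at_val_loss
    }

    for (step in seq_len(config$steps)) {
      if (hit_target()) break
      # -- discriminator updates ------------------------------------------
      d_loss <- NA_real_
      for (du in seq_len(config$d_updates_per_g)) {
        batch <- sample_batch(arrays, config$batch_size)
        fake <- gen_forward(g_params, unet, batch$corrupted)$y
        B <- dim(fake)[4]
        fr <- disc_forward(d_params, unet, batch$clean, keep = TRUE)
        ff <- disc_forward(d_params, unet, fake, keep = TRUE)
        d_loss <- discriminator_loss(fr$p, ff$p)
        dp_real <- -1 / (B * clamp_prob(fr$p))
        dp_fake <- 1 / (B * (1 - clamp_prob(ff$p)))
        bk_r <- disc_backward(d_params, unet, fr$cache, dp_real)
        bk_f <- disc_backward(d_params, unet, ff$cache, dp_fake)
        grads <- mapply(`+`, bk_r$grads[names(d_params)],
                        bk_f$grads[names(d_params)], SIMPLIFY = FALSE)
        upd <- rmsprop_step(d_params, grads, d_state, config$learning_rate)
        d_params <- upd$params; d_state <- upd$state
      }

      # -- generator update -----------------------------------------------
      batch <- sample_batch(arrays, config$batch_size)
      fw <- gen_forward(g_params, unet, batch$corrupted, keep = TRUE)
      B <- dim(fw$y)[4]
      dm <- data_mismatch(batch$clean, fw$y)
      dG <- data_mismatch_grad(dm, dim(fw$y))
      adv_loss <- 0
      if (lam > 0) {
        ff <- disc_forward(d_params, unet, fw$y, keep = TRUE)
        pf <- clamp_prob(ff$p)
        adv_loss <- mean(log(1 - pf))
        # non-saturating gradient: ascend log D(G(x_m))
        dp <- -lam / (B * pf)
        bk_d <- disc_backward(d_params, unet, ff$cache, dp)
        dG <- dG + bk_d$dx
      }
      bk <- gen_backward(g_params, unet, fw$cache, dG)
      upd <- rmsprop_step(g_params, bk$grads, g_state, config$learning_rate)
      g_params <- upd$params; g_state <- upd$state

      log[[step]] <- data.frame(step = step, d_loss = d_loss,
                                g_loss = dm$loss + lam * adv_loss,
                                data_loss = dm$loss, adv_loss = adv_loss)
      if (!is.null(val) &&
          (step %% config$eval_every == 0 || step == config$steps)) {
        val_log[[length(val_log) + 1]] <-
          data.frame(step = step, val_data_loss = val_loss(g_params))
      }
    }

    logs <- list(pretrain = pre_log, train = do.call(rbind, log),
                 validation = if (length(val_log)) do.call(rbind, val_log)
                              else NULL)
    new_corrector(g_params, unet, config, logs, disc_params = d_params)
  })
}

#' Apply a trained corrector to motion-artifact images
#'
#' Single deterministic forward pass of the generator; outputs are
#' clipped to `[0, 1]`.
#'
#' @param model A `trained_corrector`.
#' @param x Image matrix, list of matrices, or `[H, W, 1, B]` array whose
#'   size matches the training input size.
#' @return Corrected image(s), same container shape as a matrix (single
#'   image) or array.
#' @export
correct <- function(model, x) {
  abort_if(!inherits(model, "trained_corrector"),
           "`model` must be a trained_corrector")
  single <- is.matrix(x)
  xb <- as_image_batch(x, model$config$input_size)
  y <- gen_forward(model$params, model$config, xb)$y
  y <- pmin(pmax(y, 0), 1)
  if (single) matrix(y, dim(y)[1], dim(y)[2]) else y
}

#' Continue training an existing corrector on a (new) dataset
#'
#' @param model A `trained_corrector` to start from.
#' @param dataset Paired dataset to fine-tune on.
#' @param config A [train_config()]; `config$steps = 0` returns the model
#'   unchanged (aside from the logged fine-tuning record).
#' @param val_dataset Optional held-out set for validation logging.
#' @param stop_at_val_loss Optional early-stopping target passed to
#'   [train()].
#' @return A `trained_corrector` with updated parameters and a log entry
#'   marking the run as fine-tuning.
#' @export
finetune <- function(model, dataset, config, val_dataset = NULL,
                     stop_at_val_loss = NULL) {
  abort_if(!inherits(model, "trained_corrector"),
           "`model` must be a trained_corrector")
  arrays <- dataset_arrays(dataset)
  abort_if(dim(arrays$clean)[1] != model$config$input_size,
           "dataset image size does not match the model")
  if (config$steps == 0) {
    model$log$finetune <- data.frame(step = integer(0))
    return(model)
  }
  out <- train(dataset, config, model$config, init = model,
               val_dataset = val_dataset, stop_at_val_loss = stop_at_val_loss)
  out$log$finetuned_from <- TRUE
  out
}

#' Save / load a trained corrector
#'
#' The checkpoint is a single RDS file holding the generator (and, when
#' present, discriminator) parameters together with the architecture and
#' training configuration and the training log.  Reloading reproduces
#' forward outputs bit-identically.
#'
#' @param model A `trained_corrector`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `trained_corrector` (load).
#' @export
save_corrector <- function(model, path) {
  abort_if(!inherits(model, "trained_corrector"),
           "`model` must be a trained_corrector")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_corrector
#' @export
load_corrector <- function(path) {
  abort_if(!file.exists(path),
           sprintf("checkpoint '%s' does not exist", path))
  model <- readRDS(path)
  abort_if(!inherits(model, "trained_corrector"),
           "file does not contain a trained_corrector")
  model
}

#' Write a training log as CSV
#'
#' @param model A `trained_corrector`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  abort_if(is.null(model$log$train), "model has no adversarial training log")
  utils::write.csv(model$log$train, path, row.names = FALSE)
  invisible(path)
}
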