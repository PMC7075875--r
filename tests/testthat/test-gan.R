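test_that("generator loss reduces to the batch L2 data term at lambda 0", {
  # hand case: residual (0.5, 0, 0, 0) -> L2 norm 0.5
  clean <- matrix(c(1, 0, 0, 1), 2, 2)
  gen <- matrix(c(0.5, 0, 0, 1), 2, 2)
  expect_equal(generator_loss(clean, gen, lambda = 0), 0.5)
  expect_equal(generator_loss(clean, clean, lambda = 0), 0)

  # batch of two: mean of the per-image norms
  cl <- list(clean, clean)
  gn <- list(gen, clean)
  expect_equal(generator_loss(cl, gn, lambda = 0), 0.25)

  # adversarial term adds lambda * mean log(1 - D)
  expect_equal(generator_loss(clean, gen, d_fake = 0.5, lambda = 0.6),
               0.5 + 0.6 * log(0.5))
  expect_error(generator_loss(clean, gen, lambda = -1), "lambda")
})

test_that("discriminator loss matches its closed forms", {
  expect_equal(discriminator_loss(c(0.5, 0.5), c(0.5, 0.5)), 2 * log(2),
               tolerance = 1e-12)
  # perfect discriminator, clamped at eps = 1e-7
  expect_equal(discriminator_loss(1, 0), -2 * log(1 - 1e-7),
               tolerance = 1e-12)
  # inverted discriminator: large but finite
  expect_equal(discriminator_loss(0, 1), 2 * log(1e7), tolerance = 1e-6)
})

small_unet <- unet_config(n_blocks = 2, base_features = 8, input_size = 32)

small_gan_data <- function(n, seed) {
  make_paired_dataset(n, 32, 5, 4, "random", n_coils = 4, seed = seed)
}

test_that("generator pretraining descends on the data term", {
  ds <- small_gan_data(64, seed = 51)
  tc <- train_config(batch_size = 4, pretrain_steps = 200,
                     pretrain_learning_rate = 2e-3, seed = 1)
  model <- pretrain_generator(ds, tc, small_unet)
  log <- model$log$pretrain
  first <- mean(log$data_loss[1:10])
  last <- mean(log$data_loss[191:200])
  expect_lt(last, first)
})

test_that("identity pairs are learned towards zero loss", {
  ds <- small_gan_data(32, seed = 52)
  ds$corrupted <- ds$clean  # x_m == x_c
  tc <- train_config(batch_size = 4, pretrain_steps = 200,
                     pretrain_learning_rate = 2e-3, seed = 2)
  model <- pretrain_generator(ds, tc, small_unet)
  log <- model$log$pretrain
  expect_lt(mean(log$data_loss[191:200]), 0.35 * mean(log$data_loss[1:10]))
})

test_that("training is deterministic for a fixed seed", {
  ds <- small_gan_data(16, seed = 53)
  tc <- train_config(learning_rate = 1e-4, batch_size = 4, steps = 8,
                     pretrain = TRUE, pretrain_steps = 10,
                     pretrain_learning_rate = 1e-3, seed = 5)
  m1 <- train(ds, tc, small_unet)
  m2 <- train(ds, tc, small_unet)
  expect_identical(m1$log$train, m2$log$train)
  expect_identical(m1$params, m2$params)
  m3 <- train(ds, train_config(learning_rate = 1e-4, batch_size = 4,
                               steps = 8, pretrain = FALSE, seed = 6),
              small_unet)
  expect_false(identical(m1$params, m3$params))
})

test_that("the training loop logs both losses and honours d_updates", {
  ds <- small_gan_data(16, seed = 54)
  tc <- train_config(learning_rate = 1e-4, batch_size = 4, steps = 5,
                     pretrain = FALSE, lambda = 0.6, seed = 7)
  m <- train(ds, tc, small_unet)
  expect_equal(nrow(m$log$train), 5)
  expect_true(all(is.finite(m$log$train$d_loss)))
  expect_true(all(is.finite(m$log$train$g_loss)))
  expect_equal(m$log$train$g_loss,
               m$log$train$data_loss + 0.6 * m$log$train$adv_loss)
})

test_that("correct() is a deterministic shape-preserving forward pass", {
  ds <- small_gan_data(8, seed = 55)
  tc <- train_config(batch_size = 4, pretrain_steps = 20,
                     pretrain_learning_rate = 1e-3, seed = 3)
  model <- pretrain_generator(ds, tc, small_unet)
  x <- matrix(ds$corrupted[, , 1, 1], 32, 32)
  y1 <- correct(model, x)
  expect_equal(dim(y1), c(32L, 32L))
  expect_true(all(y1 >= 0 & y1 <= 1))
  expect_identical(y1, correct(model, x))
  expect_error(correct(model, matrix(0.5, 16, 16)), "does not match")
})

test_that("checkpoints round-trip bit-identically", {
  ds <- small_gan_data(8, seed = 56)
  tc <- train_config(batch_size = 4, pretrain_steps = 15,
                     pretrain_learning_rate = 1e-3, seed = 4)
  model <- pretrain_generator(ds, tc, small_unet)
  path <- tempfile(fileext = ".rds")
  save_corrector(model, path)
  back <- load_corrector(path)
  x <- matrix(ds$corrupted[, , 1, 2], 32, 32)
  expect_identical(correct(model, x), correct(back, x))
  expect_identical(model$params, back$params)
  unlink(path)
  expect_error(load_corrector(path), "does not exist")
})

test_that("finetuning with zero steps leaves parameters unchanged", {
  ds <- small_gan_data(8, seed = 57)
  tc <- train_config(batch_size = 4, pretrain_steps = 15,
                     pretrain_learning_rate = 1e-3, seed = 8)
  model <- pretrain_generator(ds, tc, small_unet)
  same <- finetune(model, ds, train_config(steps = 0, seed = 9))
  expect_identical(same$params, model$params)
  moved <- finetune(model, ds,
                    train_config(learning_rate = 1e-4, batch_size = 4,
                                 steps = 5, pretrain = FALSE, seed = 9))
  expect_false(identical(moved$params, model$params))
})

test_that("training logs can be exported as CSV", {
  ds <- small_gan_data(8, seed = 58)
  tc <- train_config(learning_rate = 1e-4, batch_size = 4, steps = 3,
                     pretrain = FALSE, seed = 10)
  m <- train(ds, tc, small_unet)
  path <- tempfile(fileext = ".csv")
  write_training_log(m, path)
  log <- read.csv(path)
  expect_equal(nrow(log), 3)
  expect_true(all(c("step", "g_loss", "d_loss", "data_loss",
                    "adv_loss") %in% names(log)))
  unlink(path)
})
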