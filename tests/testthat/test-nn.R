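tiny_cfg <- unet_config(n_blocks = 2, base_features = 4, input_size = 16)

test_that("generator forward preserves shape and stays finite", {
  net <- build_generator(tiny_cfg, seed = 1)
  x <- array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3))
  y <- network_forward(net, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_true(all(y > 0 & y < 1))  # sigmoid output

  big <- build_generator(unet_config(4, 64, 128), seed = 1)
  yb <- network_forward(big, matrix(runif(128 * 128), 128, 128))
  expect_equal(dim(yb), c(128L, 128L, 1L, 1L))
  expect_true(all(is.finite(yb)))
})

test_that("capacity grows monotonically with base features", {
  n8 <- count_parameters(build_generator(unet_config(2, 8, 16), 1))
  n4 <- count_parameters(build_generator(unet_config(2, 4, 16), 1))
  expect_gt(n8, n4)
  expect_error(unet_config(3, 16, 20), "divisible")
  expect_error(unet_config(2, 7, 16), "even")
})

test_that("discriminator yields per-image probabilities deterministically", {
  net <- build_discriminator(tiny_cfg, seed = 2)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  p1 <- network_forward(net, x)
  expect_length(p1, 2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, network_forward(net, x))
})

test_that("discriminator responds to its input", {
  net <- build_discriminator(tiny_cfg, seed = 3)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  h <- 1e-4
  probes <- list(c(3, 5), c(9, 2), c(14, 14))
  sens <- vapply(probes, function(ij) {
    x1 <- x; x2 <- x
    x1[ij[1], ij[2], 1, 1] <- x1[ij[1], ij[2], 1, 1] + h
    x2[ij[1], ij[2], 1, 1] <- x2[ij[1], ij[2], 1, 1] - h
    (network_forward(net, x1) - network_forward(net, x2)) / (2 * h)
  }, numeric(1))
  expect_true(all(is.finite(sens)))
  expect_gt(max(abs(sens)), 0)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_cfg
  set.seed(31)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  proj <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  params <- mrimoco:::init_generator_params(cfg, seed = 7)
  loss <- function(p) sum(mrimoco:::gen_forward(p, cfg, x)$y * proj)
  fw <- mrimoco:::gen_forward(params, cfg, x, keep = TRUE)
  bk <- mrimoco:::gen_backward(params, cfg, fw$cache, proj)
  h <- 1e-5
  for (nm in c("enc1.c1.W", "enc2.c3.W", "dec1.t5.W", "dec2.c4.b",
               "out.W", "out.b")) {
    k <- 1 + (13 %% length(params[[nm]]))
    p1 <- params; p2 <- params
    p1[[nm]][k] <- p1[[nm]][k] + h
    p2[[nm]][k] <- p2[[nm]][k] - h
    num <- (loss(p1) - loss(p2)) / (2 * h)
    ana <- bk$grads[[nm]][k]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-10), 1e-4,
              label = sprintf("gradient of %s", nm))
  }

  dparams <- mrimoco:::init_discriminator_params(cfg, seed = 8)
  wts <- c(1.3, -0.7)
  dl <- function(p) sum(mrimoco:::disc_forward(p, cfg, x)$p * wts)
  fd <- mrimoco:::disc_forward(dparams, cfg, x, keep = TRUE)
  bd <- mrimoco:::disc_backward(dparams, cfg, fd$cache, wts)
  for (nm in c("enc1.c2.W", "head.w", "head.b")) {
    k <- 1 + (5 %% length(dparams[[nm]]))
    p1 <- dparams; p2 <- dparams
    p1[[nm]][k] <- p1[[nm]][k] + h
    p2[[nm]][k] <- p2[[nm]][k] - h
    num <- (dl(p1) - dl(p2)) / (2 * h)
    ana <- bd$grads[[nm]][k]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-10), 1e-4,
              label = sprintf("gradient of %s", nm))
  }
  # input gradient used by the adversarial generator update
  x1 <- x; x2 <- x
  x1[5, 7, 1, 1] <- x1[5, 7, 1, 1] + h
  x2[5, 7, 1, 1] <- x2[5, 7, 1, 1] - h
  num <- (dl2 <- (sum(mrimoco:::disc_forward(dparams, cfg, x1)$p * wts) -
                    sum(mrimoco:::disc_forward(dparams, cfg, x2)$p * wts)) /
            (2 * h))
  expect_lt(abs(num - bd$dx[5, 7, 1, 1]) / max(abs(num), 1e-10), 1e-4)
})

test_that("compiled conv kernels match a plain R reference", {
  set.seed(41)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  W <- array(rnorm(3 * 3 * 3 * 5), c(3, 3, 3, 5))
  b <- rnorm(5)
  out <- mrimoco:::conv_forward(x, W, b, stride = 1L)$y
  # reference: direct loop convolution with zero padding
  ref <- array(0, c(8, 8, 5, 2))
  xp <- array(0, c(10, 10, 3, 2))
  xp[2:9, 2:9, , ] <- x
  for (bb in 1:2) for (co in 1:5) for (i in 1:8) for (j in 1:8) {
    acc <- b[co]
    for (ci in 1:3)
      acc <- acc + sum(xp[i:(i + 2), j:(j + 2), ci, bb] * W[, , ci, co])
    ref[i, j, co, bb] <- acc
  }
  expect_equal(out, ref, tolerance = 1e-12)

  # strided convolution and its transpose are mutually adjoint
  Wt <- array(rnorm(3 * 3 * 4 * 3), c(3, 3, 4, 3))
  u <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  v <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  Tu <- mrimoco:::tconv_forward(u, Wt, numeric(4), stride = 2L)$y
  # the matching conv reinterprets the same flat weights as [k,k,Cin=4,Cout=3]
  Wc <- array(as.vector(Wt), c(3, 3, 4, 3))
  Cv <- mrimoco:::conv_forward(v, Wc, numeric(3), stride = 2L)$y
  expect_equal(sum(Tu * v), sum(u * Cv), tolerance = 1e-8)
})

test_that("optimizers descend on a quadratic bowl", {
  target <- list(w = matrix(c(1, -2, 3, 0.5), 2, 2))
  params <- list(w = matrix(0, 2, 2))
  st_a <- mrimoco:::adam_init(params)
  for (i in 1:400) {
    g <- list(w = params$w - target$w)
    up <- mrimoco:::adam_step(params, g, st_a, lr = 0.05)
    params <- up$params; st_a <- up$state
  }
  expect_lt(max(abs(params$w - target$w)), 1e-2)

  params <- list(w = matrix(0, 2, 2))
  st_r <- mrimoco:::rmsprop_init(params)
  for (i in 1:400) {
    g <- list(w = params$w - target$w)
    up <- mrimoco:::rmsprop_step(params, g, st_r, lr = 0.05)
    params <- up$params; st_r <- up$state
  }
  expect_lt(max(abs(params$w - target$w)), 1e-2)
})
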