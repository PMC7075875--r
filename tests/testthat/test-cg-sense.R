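test_that("noiseless fully sampled data is recovered to machine precision", {
  p <- generate_phantom(64, seed = 1)
  coils <- simulate_coil_maps(8, 64)
  sc <- make_scheme("cartesian_parallel_1d", 4, 64)
  mo <- make_motion("constant_increment", 4, 0)
  y <- forward_corrupt(p, mo, sc, coils)
  rec <- cg_sense_reconstruct(y, coils, cg_config(tolerance = 1e-8))
  nrmse <- sqrt(mean((rec$image - p)^2)) / sqrt(mean(p^2))
  expect_lt(nrmse, 1e-5)
})

test_that("a single uniform coil reduces CG-SENSE to the inverse DFT", {
  p <- generate_phantom(32, seed = 4)
  coils <- simulate_coil_maps(1, 32)
  y <- encode(p, coils)
  rec <- cg_sense_reconstruct(y, coils, cg_config(tolerance = 1e-8))
  direct <- abs(ifft2c(y[, , 1]))
  expect_equal(rec$image, direct / max(direct), tolerance = 1e-8)
  expect_lte(rec$iterations_used, 1)
})

test_that("CG matches a dense solve of the normal equations", {
  # undersampled rows + 4 coils make E^H E well-conditioned but nontrivial
  N <- 16
  coils <- simulate_coil_maps(4, N)
  mask <- make_scheme("cartesian_parallel_1d", 2, N)$masks[[1]]
  p <- generate_phantom(N, seed = 6)
  y <- encode(p, coils, mask)

  E <- dense_encoding_matrix(coils, mask)
  A_dense <- Conj(t(E)) %*% E
  b_dense <- Conj(t(E)) %*% as.vector(y)
  x_direct <- solve(A_dense, b_dense)

  rec <- cg_sense_reconstruct(y, coils,
                              cg_config(max_iterations = 200,
                                        tolerance = 1e-12), mask = mask)
  rel <- sqrt(sum(abs(as.vector(rec$complex_solution) - x_direct)^2)) /
    sqrt(sum(abs(x_direct)^2))
  expect_lt(rel, 1e-6)

  hist <- rec$residual_history
  expect_true(all(diff(hist) <= 1e-12))
})

test_that("the normal operator is Hermitian and positive semi-definite", {
  N <- 16
  coils <- simulate_coil_maps(4, N)
  set.seed(2)
  mask <- matrix(rbinom(N * N, 1, 0.5), N, N)
  for (i in 1:5) {
    x <- matrix(rand_complex_array(c(N, N, 1), 20 + i)[, , 1], N, N)
    z <- matrix(rand_complex_array(c(N, N, 1), 40 + i)[, , 1], N, N)
    Ax <- apply_normal_operator(x, coils, mask)
    Az <- apply_normal_operator(z, coils, mask)
    lhs <- sum(Conj(Ax) * z)
    rhs <- sum(Conj(x) * Az)
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-12), 1e-10)
    quad <- Re(sum(Conj(x) * Ax))
    expect_gte(quad, -1e-12)
  }
  # identity limit: full mask, one uniform coil
  one <- simulate_coil_maps(1, N)
  x <- matrix(rand_complex_array(c(N, N, 1), 99)[, , 1], N, N)
  expect_lt(max(abs(apply_normal_operator(x, one, matrix(1, N, N)) - x)),
            1e-10)
})

test_that("zero-motion reconstruction is independent of scheme and shots", {
  p <- generate_phantom(32, seed = 9)
  coils <- simulate_coil_maps(4, 32)
  recs <- lapply(c(2, 8), function(S) {
    sc <- make_scheme("random", S, 32, seed = S)
    mo <- make_motion("constant_increment", S, 0)
    cg_sense_reconstruct(forward_corrupt(p, mo, sc, coils), coils)$image
  })
  expect_equal(recs[[1]], recs[[2]], tolerance = 1e-10)
})

test_that("motion corruption raises artifact power over the clean branch", {
  p <- generate_phantom(64, seed = 10)
  coils <- simulate_coil_maps(4, 64)
  sc <- make_scheme("random", 16, 64, seed = 3)
  clean_rec <- cg_sense_reconstruct(
    forward_corrupt(p, make_motion("constant_increment", 16, 0), sc, coils),
    coils)
  motion_rec <- cg_sense_reconstruct(
    forward_corrupt(p, make_motion("constant_increment", 16, 5), sc, coils),
    coils)
  expect_gt(artifact_power(p, motion_rec$image),
            artifact_power(p, clean_rec$image))
})

test_that("degenerate inputs are rejected", {
  coils <- simulate_coil_maps(2, 16)
  y <- array(0i, c(16, 16, 2))
  expect_error(cg_sense_reconstruct(y, coils, mask = matrix(0, 16, 16)),
               "all zero")
  y[1, 1, 1] <- NaN + 0i
  expect_error(cg_sense_reconstruct(y, coils), "non-finite")
  expect_error(cg_config(max_iterations = 0), "max_iterations")
  expect_error(cg_config(tolerance = 0), "tolerance")
})
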