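test_that("motion schedules honour the reference shot and bounds", {
  ramp <- make_motion("constant_increment", n_shots = 2, max_rotation = 5)
  expect_equal(ramp$angles, c(0, 5))

  zero <- make_motion("constant_increment", n_shots = 8, max_rotation = 0)
  expect_true(all(zero$angles == 0) && all(zero$tx == 0) && all(zero$ty == 0))

  rnd <- make_motion("random_uniform", n_shots = 8, max_rotation = 10,
                     seed = 3)
  expect_length(rnd$angles, 8)
  expect_true(all(abs(rnd$angles) <= 10))
  expect_equal(rnd$angles[1], 0)
  expect_identical(rnd$angles,
                   make_motion("random_uniform", 8, 10, seed = 3)$angles)

  cust <- make_motion("custom", n_shots = 3, max_rotation = 5,
                      angles = c(0, 2, 4))
  expect_equal(cust$angles, c(0, 2, 4))

  expect_error(make_motion("constant_increment", 4, -1), "max_rotation")
  expect_error(make_motion("spline", 4, 1), "unknown schedule")
})

test_that("rigid transform: identity is exact, 90 degrees is a permutation", {
  p <- generate_phantom(33, seed = 2, n_ellipses = 4)
  expect_identical(apply_rigid_transform(p, 0, 0, 0), p)
  expect_equal(apply_rigid_transform(p, 90, 0, 0), rot90_oracle(p),
               tolerance = 1e-12)
})

test_that("rotate-unrotate error stays within the interpolation budget", {
  p <- generate_phantom(64, seed = 5)
  back <- apply_rigid_transform(apply_rigid_transform(p, 17, 0, 0), -17, 0, 0)
  interior <- 10:55
  expect_lte(mean(abs(back[interior, interior] - p[interior, interior])),
             0.02)
})

test_that("integer translations shift pixels exactly", {
  p <- generate_phantom(32, seed = 6)
  sh <- apply_rigid_transform(p, 0, 3, 0)  # +3 columns
  expect_equal(sh[, 4:32], p[, 1:29], tolerance = 1e-12)
  expect_true(all(abs(sh[, 1:3]) < 1e-12))  # zero fill behind the shift
})

test_that("simulated coil maps are SOS-normalized and smooth", {
  one <- simulate_coil_maps(1, 64)
  expect_equal(as.complex(one[, , 1]), rep(1 + 0i, 64 * 64))

  maps <- simulate_coil_maps(8, 128)
  sos <- apply(abs(unclass(maps))^2, c(1, 2), sum)
  expect_lt(max(abs(sos - 1)), 1e-9)

  maps4 <- simulate_coil_maps(4, 32)
  for (c in 1:4) {
    m <- maps4[, , c]
    grad <- max(abs(diff(m)), abs(t(diff(t(m)))))
    expect_lt(grad, 0.5)
  }
  expect_error(simulate_coil_maps(0, 32), "n_coils")
})

test_that("encoding reduces to the plain DFT for one uniform coil", {
  p <- generate_phantom(32, seed = 8)
  coils <- simulate_coil_maps(1, 32)
  y <- encode(p, coils)
  expect_equal(y[, , 1], fft2c(p), tolerance = 1e-12)
  expect_equal(encode(matrix(0, 32, 32), coils),
               array(0i, c(32, 32, 1)))
  # orthonormal round trip through the adjoint
  expect_lt(max(abs(encode_adjoint(y, coils) - p)), 1e-10)
})

test_that("encode and encode_adjoint are exact adjoints", {
  coils <- simulate_coil_maps(4, 16)
  set.seed(10)
  for (i in 1:5) {
    mask <- matrix(rbinom(256, 1, 0.6), 16, 16)
    x <- matrix(rnorm(256), 16, 16)
    y <- rand_complex_array(c(16, 16, 4), seed = 100 + i) * rep(mask, 4)
    lhs <- sum(Conj(encode(x, coils, mask)) * y)
    rhs <- sum(Conj(x) * encode_adjoint(y, coils))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
  expect_error(encode(matrix(0, 16, 16), simulate_coil_maps(2, 32)),
               "coil maps")
})

test_that("zero motion reproduces the clean encoding for every scheme", {
  p <- generate_phantom(32, seed = 3)
  coils <- simulate_coil_maps(4, 32)
  clean <- encode(p, coils)
  for (nm in c("cartesian_sequential", "cartesian_parallel_1d",
               "cartesian_parallel_2d", "random")) {
    sc <- make_scheme(nm, 4, 32, seed = 2)
    mo <- make_motion("constant_increment", 4, 0)
    y <- forward_corrupt(p, mo, sc, coils)
    expect_identical(y$samples, clean)
  }
})

test_that("forward corruption is linear in the image at zero motion", {
  p <- generate_phantom(32, seed = 12)
  coils <- simulate_coil_maps(4, 32)
  sc <- make_scheme("random", 4, 32, seed = 1)
  mo <- make_motion("constant_increment", 4, 0)
  y1 <- forward_corrupt(p, mo, sc, coils)$samples
  y3 <- forward_corrupt(3 * p, mo, sc, coils)$samples
  expect_lt(max(abs(y3 - 3 * y1)), 1e-10)
})

test_that("inter-shot motion produces measurable k-space corruption", {
  p <- generate_phantom(64, seed = 1)
  coils <- simulate_coil_maps(4, 64)
  sc <- make_scheme("cartesian_sequential", 2, 64)
  mo <- make_motion("custom", 2, 5, angles = c(0, 5))
  y <- forward_corrupt(p, mo, sc, coils)
  recon <- abs(encode_adjoint(y, coils))
  recon <- recon / max(recon)
  expect_gt(artifact_power(p, recon), 0)
  bad <- make_motion("constant_increment", 8, 5)
  expect_error(forward_corrupt(p, bad, sc, coils), "number of shots")
})
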