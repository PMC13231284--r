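test_that("build_phantom validates its specification", {
  expect_error(build_phantom(c(16, 32, 32)), ">= 32")
  expect_error(build_phantom(c(32, 32, 32), classes = default_tissue_classes()[1:2]),
               "at least 3")
  dup <- default_tissue_classes()
  dup[[2]]$label_id <- 1L
  expect_error(build_phantom(c(32, 32, 32), classes = dup), "overlapping label")
})

test_that("phantom labels, tensors and mask honor the class specs", {
  ph <- get_small_phantom()
  ids <- vapply(ph$classes, function(cl) cl$label_id, 1L)
  expect_setequal(unique(as.vector(ph$labels)), c(0L, ids))
  # mask contains every labeled voxel
  expect_true(all(ph$mask[ph$labels != 0L]))
  # CSF is exactly isotropic: FA 0
  csf <- which(ph$labels == 4L)
  fa <- fractional_anisotropy(matrix(ph$tensors, ncol = 6)[csf, ])
  expect_lt(max(fa), 1e-10)
  # white matter (radial rule): principal eigenvector parallel to the radial
  # direction, recomputed by direct eigendecomposition
  t6 <- matrix(ph$tensors, ncol = 6)
  wm <- which(ph$labels == 1L)
  set.seed(1)
  ctr_est <- colMeans(which(ph$labels > 0L, arr.ind = TRUE))
  for (i in sample(wm, 25)) {
    v <- t6[i, ]
    D <- matrix(c(v[1], v[2], v[3], v[2], v[4], v[5], v[3], v[5], v[6]), 3, 3)
    e1 <- eigen(D, symmetric = TRUE)$vectors[, 1]
    pos <- arrayInd(i, dim(ph$labels))
    r <- pos - ctr_est
    # the phantom centre is jittered; allow the small offset via 0.99 cosine
    expect_gt(abs(sum(e1 * r / sqrt(sum(r^2)))), 0.95)
  }
  # class FA matches the closed form from the spec eigenvalues
  lam <- ph$classes[[1]]$eigenvalues
  fa_expect <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  fa_wm <- fractional_anisotropy(t6[wm, ])
  expect_equal(max(abs(fa_wm - fa_expect)), 0, tolerance = 1e-10)
  # determinism
  ph2 <- build_phantom(c(32L, 32L, 32L), seed = 42L)
  expect_identical(ph2$labels, ph$labels)
  expect_identical(ph2$tensors, ph$tensors)
})

test_that("tensor_signal matches the closed form and its symmetries", {
  D <- diag(3) * 1e-3
  expect_equal(tensor_signal(D, 1000, c(0, 0, 1), S0 = 1), exp(-1),
               tolerance = 1e-12)
  expect_equal(tensor_signal(D, 0, c(1, 0, 0), S0 = 3.5), 3.5)
  expect_error(tensor_signal(D, -1, c(0, 0, 1)), "negative")
  # rotational symmetry of the quadratic form
  Dan <- diag(c(1.7e-3, 3e-4, 3e-4))
  g <- c(1, 2, 2) / 3
  R <- sample_rotation(5)
  expect_equal(tensor_signal(R %*% Dan %*% t(R), 1000, drop(R %*% g)),
               tensor_signal(Dan, 1000, g), tolerance = 1e-12)
  # decay monotone in b for fixed g
  b <- seq(0, 3000, by = 250)
  s <- vapply(b, function(bb) tensor_signal(Dan, bb, c(1, 0, 0)), 1)
  expect_true(all(diff(s) <= 0))
})

test_that("simulate_acquisition is exact without noise and Rician with", {
  ph <- get_small_phantom()
  sch <- get_small_scheme()
  expect_error(simulate_acquisition(ph, acquisition_scheme(
    generate_directions(4, seed = 1), rep(1000, 4))), "no b0")
  dwi0 <- simulate_acquisition(ph, sch, noise_sigma = 0, seed = 3)
  m <- which(!sch$is_b0)[1]
  ref <- dwiseg:::tensor_signal_field(ph$tensors, sch$bvals[m],
                                      sch$bvecs[m, ], ph$s0)
  expect_identical(dwi0$data[, , , m], ref)
  # noiseless mean b0 equals s0 exactly
  expect_equal(dwi0$mean_b0, ph$s0, tolerance = 1e-15)
  # determinism
  dwi1 <- simulate_acquisition(ph, sch, snr = 25, seed = 9)
  dwi2 <- simulate_acquisition(ph, sch, snr = 25, seed = 9)
  expect_identical(dwi1$data, dwi2$data)
  # Rician mean: constant signal A >> sigma over many voxels
  A <- 1; sigma <- 0.05
  set.seed(11)
  mag <- sqrt((A + rnorm(10000, sd = sigma))^2 + rnorm(10000, sd = sigma)^2)
  expect_lt(abs(mean(mag) - (A + sigma^2 / (2 * A))),
            3 * sigma / sqrt(10000) + sigma^2 / 100)
})
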