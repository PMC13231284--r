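test_that("normalize_signals divides, clips and rejects degenerate voxels", {
  expect_equal(normalize_signals(c(2, 0, 5), mean_b0 = 2), c(1, 0, 2))
  expect_equal(normalize_signals(1.2, 1.2), 1)
  expect_error(normalize_signals(1, 0), "degenerate")
  expect_error(normalize_signals(1, 1e-9, eps = 1e-6), "degenerate")
})

test_that("featurization is an even function of the b-vector", {
  g <- c(0.3, -0.5, sqrt(1 - 0.34))
  f1 <- featurize_measurement(g, 1000, 0.5)
  f2 <- featurize_measurement(-g, 1000, 0.5)
  expect_identical(f1, f2)
  # fixed (xx, xy, xz, yy, yz, zz) order
  expect_equal(drop(featurize_measurement(c(0, 0, 1), 0, 0.7)),
               c(0, 0, 0, 0, 0, 1, 0, 0.7))
  # b = 0 passes the signal through with a zero b-value feature
  expect_equal(featurize_measurement(c(1, 0, 0), 0, 0.9)[, 7], 0)
})

test_that("encode is permutation- and sign-invariant with constant length L", {
  cfg <- encoder_config(L = 8L, hidden_width = 16L)
  params <- discus_init(cfg, seed = 1)
  obs <- random_obs(30, seed = 3)
  e0 <- discus_encode(obs, params)
  expect_length(e0, 8L)
  set.seed(4)
  for (i in 1:5) {
    p <- sample(obs$N)
    ep <- discus_encode(observation_set(obs$bvecs[p, ], obs$bvals[p],
                                        obs$signals[p]), params)
    expect_equal(ep, e0, tolerance = 1e-5)
  }
  # antipodal flips of arbitrary subsets: bit-identical
  flip <- sample(c(-1, 1), obs$N, replace = TRUE)
  ef <- discus_encode(observation_set(obs$bvecs * flip, obs$bvals,
                                      obs$signals), params)
  expect_identical(ef, e0)
  # embedding length constant across N
  for (n in c(1L, 5L, 10L, 30L, 90L))
    expect_length(discus_encode(random_obs(n, seed = n), params), 8L)
  expect_error(discus_encode(observation_set(matrix(0, 0, 3), numeric(0),
                                             numeric(0)), params),
               "at least one")
})

test_that("decode is sign-invariant and checks the embedding length", {
  cfg <- encoder_config(L = 8L, hidden_width = 16L)
  params <- discus_init(cfg, seed = 2)
  emb <- discus_encode(random_obs(12, seed = 5), params)
  g <- c(0.6, 0.8, 0) / 1
  y1 <- discus_decode(list(bvec = g, bval = 1000), emb, params)
  y2 <- discus_decode(list(bvec = -g, bval = 1000), emb, params)
  expect_identical(y1, y2)
  expect_error(discus_decode(list(bvec = g, bval = 1000), emb[1:5], params),
               "does not match")
  # zeroed output layer forces the prediction to equal the output bias
  params$dec[[length(params$dec)]]$W[] <- 0
  params$dec[[length(params$dec)]]$b <- 0.123
  for (gg in list(c(1, 0, 0), c(0, 1, 0), g))
    expect_equal(discus_decode(list(bvec = gg, bval = 1000), emb, params),
                 0.123)
})

test_that("pretraining learns a constant dataset and beats the mean baseline", {
  sch <- acquisition_scheme(generate_directions(10, seed = 1), rep(1000, 10))
  sig <- matrix(0.37, 400, 10)
  fit <- pretrain_reconstruction(sig, sch, encoder_config(L = 4L, hidden_width = 8L),
                                 seed = 1, epochs = 60, batch_size = 32,
                                 lr = 0.005)
  expect_lt(utils::tail(fit$history$val, 1), 1e-4)
  pred <- reconstruct_signals(sig[1:5, ], sch, fit$params)
  expect_equal(as.vector(pred), rep(0.37, 50), tolerance = 0.05)
  # error path: M below n_min
  sch3 <- acquisition_scheme(generate_directions(3, seed = 2), rep(1000, 3))
  expect_error(pretrain_reconstruction(matrix(0.5, 10, 3), sch3,
                                       encoder_config(L = 4, hidden_width = 8)),
               "n_min")
  # reproducibility: same seed, same loss history
  fit2 <- pretrain_reconstruction(sig[1:100, ], sch,
                                  encoder_config(L = 4, hidden_width = 8),
                                  seed = 7, epochs = 3, batch_size = 32)
  fit3 <- pretrain_reconstruction(sig[1:100, ], sch,
                                  encoder_config(L = 4, hidden_width = 8),
                                  seed = 7, epochs = 3, batch_size = 32)
  expect_identical(fit2$history, fit3$history)
})

test_that("rotated tensor data with rotated queries has identical signals", {
  # joint-rotation consistency as a closed-form data property
  ph <- get_small_phantom()
  t6 <- matrix(ph$tensors, ncol = 6)
  rows <- which(ph$labels == 1L)[1:50]
  G <- generate_directions(15, seed = 8)
  R <- sample_rotation(21)
  s_orig <- oracle_signals(t6[rows, ], G)
  # rotate each tensor: D' = R D R', queries G' = G R'
  t6r <- t(apply(t6[rows, ], 1, function(v) {
    D <- matrix(c(v[1], v[2], v[3], v[2], v[4], v[5], v[3], v[5], v[6]), 3, 3)
    Dr <- R %*% D %*% t(R)
    c(Dr[1, 1], Dr[1, 2], Dr[1, 3], Dr[2, 2], Dr[2, 3], Dr[3, 3])
  }))
  s_rot <- oracle_signals(t6r, G %*% t(R))
  expect_equal(s_rot, s_orig, tolerance = 1e-12)
})

test_that("encoder config enforces its invariants", {
  expect_error(encoder_config(L = 0), "L must be")
  expect_error(encoder_config(L = 32, hidden_width = 16), "hidden_width")
})
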