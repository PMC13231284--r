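# small shared fixture: phantom + noisy acquisition + prepared case
local_case <- function() {
  if (is.null(fixture_env$case)) {
    ph <- get_small_phantom()
    dwi <- simulate_acquisition(ph, get_small_scheme(), snr = 25, seed = 5)
    fixture_env$enc_cfg <- encoder_config(L = 4L, hidden_width = 8L)
    fixture_env$case <- prepare_case(ph, dwi, fixture_env$enc_cfg)
  }
  fixture_env$case
}

test_that("embed_volume gathers in-mask voxels and equals dense evaluation", {
  ph <- get_small_phantom()
  sch <- get_small_scheme()
  dwi <- simulate_acquisition(ph, sch, snr = 25, seed = 5)
  cfg <- encoder_config(L = 4L, hidden_width = 8L)
  params <- discus_init(cfg, seed = 1)
  emb <- embed_volume(dwi, ph$mask, params)
  expect_identical(dim(emb), c(dim(ph$mask), 4L))
  # out-of-mask voxels are all-zero
  out_idx <- which(!ph$mask)[1:100]
  for (l in 1:4) expect_true(all(emb[out_idx + (l - 1) * length(ph$mask)] == 0))
  # dense per-voxel oracle on a handful of in-mask voxels
  set.seed(3)
  norm <- dwiseg:::normalize_case_signals(dwi, ph$mask, cfg)
  idx <- which(ph$mask)
  pick <- sample(length(idx), 10)
  for (i in pick) {
    obs <- observation_set(sch$bvecs, sch$bvals, norm[i, ])
    e_dense <- discus_encode(obs, params)
    pos <- arrayInd(idx[i], dim(ph$mask))
    expect_equal(emb[pos[1], pos[2], pos[3], ], e_dense, tolerance = 1e-6)
  }
  # empty mask: all zeros, no evaluation
  emb0 <- embed_volume(dwi, array(FALSE, dim(ph$mask)), params)
  expect_true(all(emb0 == 0))
  expect_error(embed_volume(dwi, array(TRUE, c(2, 2, 2)), params), "shape")
})

test_that("assemble_slice_input builds C = L + 3 channels with edge rule", {
  cs <- local_case()
  L <- 4L
  emb <- array(rnorm(prod(cs$shape) * L), c(cs$shape, L))
  x <- assemble_slice_input(emb, cs$b0z, 5L, "axial")
  expect_identical(dim(x), c(cs$shape[1:2], L + 3L))
  expect_equal(x[, , 1:L], emb[, , 5, ])
  expect_equal(x[, , L + 1], cs$b0z[, , 4])
  expect_equal(x[, , L + 3], cs$b0z[, , 6])
  # edge replication at index 1
  x1 <- assemble_slice_input(emb, cs$b0z, 1L, "axial")
  expect_equal(x1[, , L + 1], cs$b0z[, , 1])
  expect_equal(x1[, , L + 2], cs$b0z[, , 1])
  # neighboring embedding slices are NOT included: only the central slice
  emb2 <- emb
  emb2[, , 4, ] <- 99; emb2[, , 6, ] <- -99   # perturb neighbors only
  expect_identical(assemble_slice_input(emb2, cs$b0z, 5L, "axial")[, , 1:L],
                   x[, , 1:L])
  expect_error(assemble_slice_input(emb, cs$b0z, 5L, "oblique"),
               "invalid view")
  expect_error(assemble_slice_input(emb, cs$b0z, 999L, "axial"),
               "out of range")
})

test_that("compute_class_weights implements median-frequency weighting", {
  lab <- c(rep(0L, 5), rep(1L, 5))
  expect_equal(unname(compute_class_weights(lab, 2)), c(1, 1))
  # frequencies (0.5, 0.3, 0.2) -> weights (0.6, 1.0, 1.5)
  lab <- rep(c(0L, 1L, 2L), times = c(50, 30, 20))
  expect_equal(unname(compute_class_weights(lab, 3)), c(0.6, 1.0, 1.5))
  # rarest class always has the largest weight
  set.seed(9)
  lab <- sample(0:3, 500, replace = TRUE, prob = c(.5, .3, .15, .05))
  w <- compute_class_weights(lab, 4)
  expect_equal(unname(which.max(w)), which.min(tabulate(lab + 1L, 4)))
  expect_error(compute_class_weights(rep(0L, 10), 3), "absent.*1, 2")
})

test_that("segmentation_loss follows the composite contract", {
  S <- 3L
  target <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  onehot <- array(0, c(2, 2, S))
  for (i in 1:2) for (j in 1:2) onehot[i, j, target[i, j] + 1] <- 1
  w <- rep(1, S)
  expect_lt(segmentation_loss(onehot, target, w, dice_weight = 1), 1e-5)
  # uniform prediction, uniform labels, no edges -> CE = log(S)
  unif <- array(1 / S, c(4, 4, S))
  lab0 <- matrix(0L, 4, 4)
  l <- segmentation_loss(unif, lab0, w, dice_weight = 0)
  expect_equal(l, log(S), tolerance = 1e-12)
  # unnormalized rows are a contract violation
  bad <- unif; bad[1, 1, ] <- c(0.5, 0.2, 0.2)
  expect_error(segmentation_loss(bad, lab0, w), "contract violation")
  # doubling edge_boost strictly increases the loss when a boundary voxel is
  # misclassified
  edge <- matrix(FALSE, 4, 4); edge[2, 2] <- TRUE
  l1 <- segmentation_loss(unif, lab0, w, edge_mask = edge, edge_boost = 2,
                          dice_weight = 0)
  l2 <- segmentation_loss(unif, lab0, w, edge_mask = edge, edge_boost = 4,
                          dice_weight = 0)
  expect_gt(l2, l1)
})

test_that("scale augmentation is exactly neutral at scale 1", {
  cfg <- vinn_config(L = 4L, S = 6L, filters = 4L)
  vp <- vinn_init(cfg, seed = 2)
  x <- array(rnorm(24 * 20 * 7), c(24, 20, 7))
  f1 <- vinn_forward(vp, x, scale = 1)
  # pinning the interpolation to the identity must be bit-wise equal to an
  # explicitly resized pass at the same size
  f2 <- vinn_forward(vp, dwiseg:::bilin_fw(x, 24L, 20L), scale = 1)
  expect_identical(f1$logits, f2$logits)
})

test_that("train_view schemes freeze or update the encoder as specified", {
  cs <- local_case()
  enc_cfg <- fixture_env$enc_cfg
  vcfg <- vinn_config(L = 4L, S = 6L, filters = 4L, lr = 1e-3)
  enc0 <- discus_init(enc_cfg, seed = 3)
  expect_error(train_view("axial", list(cs), NULL, "pretrain_frozen",
                          config = vcfg), "configuration error")
  h0 <- dwiseg:::params_checksum(enc0[c("pre", "post", "dec")])
  fr <- train_view("axial", list(cs), enc0, "pretrain_frozen", vcfg,
                   seed = 1, steps = 3)
  expect_identical(dwiseg:::params_checksum(fr$encoder[c("pre", "post", "dec")]),
                   h0)
  sc <- train_view("axial", list(cs), enc0, "scratch_seg_only", vcfg,
                   seed = 1, steps = 3)
  expect_false(identical(
    dwiseg:::params_checksum(sc$encoder[c("pre", "post")]),
    dwiseg:::params_checksum(enc0[c("pre", "post")])))
  mt <- train_view("axial", list(cs), enc0, "multitask_seg_recon", vcfg,
                   seed = 1, steps = 3, recon_batch = 64L)
  expect_true(all(is.finite(mt$history$seg_loss)))
  expect_true(all(is.finite(mt$history$recon_loss)))
  # frozen-scheme reproducibility: same seed, identical loss history
  fr2 <- train_view("axial", list(cs), enc0, "pretrain_frozen", vcfg,
                    seed = 1, steps = 3)
  expect_identical(fr$history, fr2$history)
})

test_that("predict_segmentation aggregates views and masks the background", {
  cs <- local_case()
  enc0 <- discus_init(fixture_env$enc_cfg, seed = 3)
  vcfg <- vinn_config(L = 4L, S = 6L, filters = 4L)
  vm <- train_view("axial", list(cs), enc0, "pretrain_frozen", vcfg,
                   seed = 1, steps = 2)
  expect_error(predict_segmentation(cs, list()), "no view")
  pred <- predict_segmentation(cs, list(axial = vm))
  expect_identical(dim(pred$labels), cs$shape)
  expect_true(all(pred$labels[!cs$mask] == 0L))
  expect_true(all(pred$labels %in% 0:5))
  # probability volumes sum to 1 in-mask
  psum <- apply(pred$prob, 1:3, sum)
  expect_equal(range(psum[cs$mask]), c(1, 1), tolerance = 1e-6)
  # end-to-end permutation robustness: shuffling the DWIs and their
  # gradient-table columns leaves the labeling unchanged (float-tolerance
  # budget: <= 0.1% of voxels)
  set.seed(31)
  perm <- sample(cs$scheme$M)
  cs2 <- cs
  cs2$norm <- cs$norm[, perm]
  cs2$scheme <- acquisition_scheme(cs$scheme$bvecs[perm, ],
                                   cs$scheme$bvals[perm])
  pred2 <- predict_segmentation(cs2, list(axial = vm))
  expect_lte(mean(pred2$labels != pred$labels), 0.001)
})

test_that("view aggregation is a mean with lowest-index tie-break", {
  # toy 2-voxel, 2-class case: (0.6,0.4)/(0.4,0.6)/(0.4,0.6) -> class 1
  p <- (c(0.6, 0.4) + c(0.4, 0.6) + c(0.4, 0.6)) / 3
  expect_equal(p, c(0.4666667, 0.5333333), tolerance = 1e-6)
  expect_equal(which.max(p) - 1L, 1L)
  # max.col with ties.method "first" breaks ties toward the lowest class
  m <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(max.col(m, ties.method = "first") - 1L, 0L)
})
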