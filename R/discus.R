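#' Encoder configuration
#'
#' Architecture and normalization knobs of the per-voxel set encoder/decoder.
#' The contract is fixed (variable-length observation set in, length-`L`
#' embedding out, permutation- and sign-invariant); the layer inventory is a
#' configurable stand-in: a per-measurement stage of `n_pre` ReLU layers of
#' width `hidden_width`, symmetric mean pooling, a post-pooling stage of
#' `n_post` layers ending in the embedding, and a decoder of `n_dec` layers
#' mapping `[featurized query, embedding]` to one predicted signal.
#'
#' @param L embedding length (>= 1).
#' @param hidden_width feature width of the hidden stages (>= L).
#' @param n_pre,n_post,n_dec layer counts of the three stages.
#' @param bval_scale normalization constant for b-values (s/mm^2); default
#'   1000, the single-shell regime the package targets.
#' @param n_min smallest observation-set size drawn during augmentation.
#' @param clip_max upper clip for normalized signals (Rician noise can push
#'   DWI/b0 above 1).
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(L = 32L, hidden_width = 64L, n_pre = 3L, n_post = 2L,
                           n_dec = 3L, bval_scale = 1000, n_min = 5L,
                           clip_max = 2) {
  L <- as.integer(L); hidden_width <- as.integer(hidden_width)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (hidden_width < L) stop("hidden_width must be >= L", call. = FALSE)
  structure(list(L = L, hidden_width = hidden_width, n_pre = as.integer(n_pre),
                 n_post = as.integer(n_post), n_dec = as.integer(n_dec),
                 bval_scale = bval_scale, n_min = as.integer(n_min),
                 clip_max = clip_max),
            class = "encoder_config")
}

#' Initialize encoder/decoder parameters
#'
#' @param config an [encoder_config()].
#' @param seed integer seed (deterministic initialization).
#' @return list with elements `pre`, `post`, `dec` (each an MLP parameter
#'   list) plus the `config`.
#' @export
discus_init <- function(config = encoder_config(), seed = 1L) {
  h <- config$hidden_width
  with_seed(seed, {
    list(pre = mlp_init(c(8L, rep(h, config$n_pre))),
         post = mlp_init(c(rep(h, config$n_post), config$L)),
         dec = mlp_init(c(7L + config$L, rep(h, config$n_dec - 1L), 1L)),
         config = config)
  })
}

#' Construct an observation set
#'
#' The per-voxel unstructured input: three parallel sequences of equal length
#' `N >= 1` holding b-vectors, b-values, and normalized signals.
#'
#' @param bvecs `N x 3` matrix of directions (unit norm where `bval > 0`).
#' @param bvals length-`N` vector (s/mm^2).
#' @param signals length-`N` vector of normalized signals.
#' @return an `observation_set` list.
#' @export
observation_set <- function(bvecs, bvals, signals) {
  bvecs <- matrix(as.numeric(bvecs), ncol = 3L)
  N <- nrow(bvecs)
  if (N < 1L) stop("observation set must contain at least one measurement",
                   call. = FALSE)
  if (length(bvals) != N || length(signals) != N)
    stop("bvecs, bvals, signals must have equal length", call. = FALSE)
  structure(list(bvecs = bvecs, bvals = as.numeric(bvals),
                 signals = as.numeric(signals), N = N),
            class = "observation_set")
}

#' Normalize per-voxel signals by the mean b0
#'
#' Divides each raw signal by the voxel's mean b0 intensity and clips to
#' `[0, clip_max]`. A mean b0 at or below the floor `eps` marks a degenerate
#' voxel and raises an error; in-mask callers must handle it explicitly
#' rather than silently skipping the voxel.
#'
#' @param signals raw signal intensities.
#' @param mean_b0 the voxel's mean b0 intensity.
#' @param clip_max upper clip (default 2).
#' @param eps degeneracy floor; callers typically pass
#'   `1e-6 * median(in-mask mean b0)`.
#' @return normalized signals in `[0, clip_max]`.
#' @export
normalize_signals <- function(signals, mean_b0, clip_max = 2, eps = 1e-6) {
  if (!is.finite(mean_b0) || mean_b0 <= eps)
    stop(sprintf("degenerate voxel: mean b0 (%g) at or below floor %g",
                 mean_b0, eps), call. = FALSE)
  pmin(pmax(signals / mean_b0, 0), clip_max)
}

#' Featurize measurements with antipodal symmetry built in
#'
#' Maps each (b-vector, b-value, signal) triplet to an 8-vector that is an
#' even function of the b-vector: the six unique entries of the symmetric
#' outer product `g g'` in the fixed order (xx, xy, xz, yy, yz, zz), followed
#' by `bval / bval_scale` and the normalized signal. Because `(-g)(-g)' =
#' g g'`, features for `g` and `-g` are bit-identical, which gives the
#' encoder its sign invariance by construction rather than by augmentation.
#'
#' @param bvecs `N x 3` matrix (or length-3 vector).
#' @param bvals length-`N` vector.
#' @param signals length-`N` vector.
#' @param bval_scale b-value normalization constant.
#' @return `N x 8` feature matrix.
#' @export
featurize_measurement <- function(bvecs, bvals, signals, bval_scale = 1000) {
  bvecs <- matrix(as.numeric(bvecs), ncol = 3L)
  cbind(outer_product_features(bvecs), as.numeric(bvals) / bval_scale,
        as.numeric(signals), deparse.level = 0)
}

# query featurization: same even construction, no signal column
featurize_query <- function(bvecs, bvals, bval_scale = 1000) {
  bvecs <- matrix(as.numeric(bvecs), ncol = 3L)
  cbind(outer_product_features(bvecs), as.numeric(bvals) / bval_scale,
        deparse.level = 0)
}

outer_product_features <- function(g) {
  cbind(g[, 1]^2, g[, 1] * g[, 2], g[, 1] * g[, 3],
        g[, 2]^2, g[, 2] * g[, 3], g[, 3]^2, deparse.level = 0)
}

#' Encode an observation set into a diffusion embedding
#'
#' Shared per-measurement network, symmetric mean pooling over the `N`
#' measurements, post-pooling network, length-`L` embedding. The output is
#' invariant to any permutation of the measurements (up to floating-point
#' summation order) and exactly invariant to sign flips of any subset of
#' b-vectors.
#'
#' @param obs an [observation_set()].
#' @param params a [discus_init()] parameter set.
#' @return numeric vector of length `L`.
#' @export
discus_encode <- function(obs, params) {
  stopifnot(inherits(obs, "observation_set"))
  config <- params$config
  feats <- featurize_measurement(obs$bvecs, obs$bvals, obs$signals,
                                 config$bval_scale)
  H <- mlp_forward(params$pre, feats)$out
  pooled <- matrix(colMeans(H), 1L)
  drop(mlp_forward(params$post, pooled)$out)
}

#' Predict the signal for a query vector from an embedding
#'
#' @param query list with `bvec` (unit 3-vector) and `bval`, or a
#'   1-row matrix/vector pair via `bvec`/`bval` arguments.
#' @param emb length-`L` embedding from [discus_encode()].
#' @param params a [discus_init()] parameter set.
#' @return predicted normalized signal (scalar).
#' @export
discus_decode <- function(query, emb, params) {
  config <- params$config
  if (length(emb) != config$L)
    stop(sprintf("embedding length %d does not match configured L = %d",
                 length(emb), config$L), call. = FALSE)
  qf <- featurize_query(query$bvec, query$bval, config$bval_scale)
  drop(mlp_forward(params$dec, cbind(qf, matrix(emb, 1L)))$out)
}

# ---- batched internals ------------------------------------------------------

# rotate directions per voxel: Q (B x 4 unit quaternions), G (M x 3).
# returns (B*M) x 3 voxel-major rotated directions
rotate_dirs_batch <- function(Q, G) {
  B <- nrow(Q); M <- nrow(G)
  U <- Q[rep(seq_len(B), each = M), 2:4, drop = FALSE]
  w <- Q[rep(seq_len(B), each = M), 1]
  V <- G[rep(seq_len(M), times = B), , drop = FALSE]
  # v' = v + w*t + u x t,  t = 2 (u x v)
  tx <- 2 * (U[, 2] * V[, 3] - U[, 3] * V[, 2])
  ty <- 2 * (U[, 3] * V[, 1] - U[, 1] * V[, 3])
  tz <- 2 * (U[, 1] * V[, 2] - U[, 2] * V[, 1])
  cbind(V[, 1] + w * tx + U[, 2] * tz - U[, 3] * ty,
        V[, 2] + w * ty + U[, 3] * tx - U[, 1] * tz,
        V[, 3] + w * tz + U[, 1] * ty - U[, 2] * tx, deparse.level = 0)
}

# encode B voxels sharing one direction set (no augmentation).
# signals: B x M, bvecs: M x 3, bvals: length M. Returns B x L.
encode_voxels_dense <- function(signals, bvecs, bvals, params) {
  config <- params$config
  B <- nrow(signals); M <- nrow(bvecs)
  gfeat <- cbind(outer_product_features(bvecs), bvals / config$bval_scale,
                 deparse.level = 0)
  feats <- cbind(gfeat[rep(seq_len(M), times = B), , drop = FALSE],
                 as.vector(t(signals)), deparse.level = 0)
  H <- mlp_infer(params$pre, feats)
  pooled <- rowsum(H, group = rep(seq_len(B), each = M), reorder = FALSE) / M
  mlp_infer(params$post, pooled)
}

# full forward for training: masked subsets + optional per-voxel rotation.
# signals: B x M (normalized), mask: B x M logical, Q: B x 4 quaternions or NULL.
# Returns everything needed for the backward pass.
discus_forward_train <- function(signals, bvecs, bvals, mask, Q, params,
                                 run_decoder = TRUE) {
  config <- params$config
  B <- nrow(signals); M <- nrow(bvecs)
  g_rows <- if (is.null(Q)) {
    bvecs[rep(seq_len(M), times = B), , drop = FALSE]
  } else {
    rotate_dirs_batch(Q, bvecs)
  }
  b_rows <- rep(bvals, times = B) / config$bval_scale
  gf <- cbind(outer_product_features(g_rows), b_rows, deparse.level = 0)
  inc <- which(as.vector(t(mask)))               # voxel-major row index
  vox_of_row <- rep(seq_len(B), each = M)
  n_per_vox <- rowSums(mask)
  feats_in <- cbind(gf[inc, , drop = FALSE], as.vector(t(signals))[inc],
                    deparse.level = 0)
  fw_pre <- mlp_forward(params$pre, feats_in)
  w_row <- 1 / n_per_vox[vox_of_row[inc]]
  pooled <- rowsum(fw_pre$out * w_row, group = vox_of_row[inc], reorder = FALSE)
  fw_post <- mlp_forward(params$post, pooled)
  E <- fw_post$out                               # B x L
  fw_dec <- NULL; pred <- NULL
  if (run_decoder) {
    dec_in <- cbind(gf, E[vox_of_row, , drop = FALSE], deparse.level = 0)
    fw_dec <- mlp_forward(params$dec, dec_in)
    pred <- drop(fw_dec$out)
  }
  list(pred = pred, E = E, fw_pre = fw_pre, fw_post = fw_post,
       fw_dec = fw_dec, inc = inc, w_row = w_row, vox_of_row = vox_of_row,
       B = B, M = M)
}

# backward for discus_forward_train given d(loss)/d(pred) as a vector.
# returns grads for pre/post/dec
discus_backward_train <- function(fw, g_pred, params) {
  L <- params$config$L
  bw_dec <- mlp_backward_full(params$dec, fw$fw_dec$cache, matrix(g_pred, ncol = 1L))
  gE_rows <- bw_dec$gX[, 8:(7 + L), drop = FALSE]
  gE <- rowsum(gE_rows, group = fw$vox_of_row, reorder = FALSE)
  bw_post <- mlp_backward_full(params$post, fw$fw_post$cache, gE)
  gH <- bw_post$gX[fw$vox_of_row[fw$inc], , drop = FALSE] * fw$w_row
  bw_pre <- mlp_backward_full(params$pre, fw$fw_pre$cache, gH)
  list(pre = bw_pre$grads, post = bw_post$grads, dec = bw_dec$grads)
}

# encoder-only backward: gradient of loss wrt embeddings gE (B x L), from a
# dense (unmasked or masked) encode; fw from discus_forward_train with any Q
discus_backward_encoder <- function(fw, gE, params) {
  bw_post <- mlp_backward_full(params$post, fw$fw_post$cache, gE)
  gH <- bw_post$gX[fw$vox_of_row[fw$inc], , drop = FALSE] * fw$w_row
  bw_pre <- mlp_backward_full(params$pre, fw$fw_pre$cache, gH)
  list(pre = bw_pre$grads, post = bw_post$grads)
}

#' Pre-train the encoder/decoder with the reconstruction objective
#'
#' Per training step and voxel, the number of observed measurements `N` is
#' drawn uniformly in `[n_min, M]`, a random size-`N` subset is selected, a
#' Haar-uniform rotation is applied jointly to observation and query
#' directions, and the decoder predicts all `M` reference signals from the
#' embedding; the loss is the mean squared error. The learning rate starts at
#' `lr` and is divided by 10 at the halfway epoch. Validation loss is
#' computed on a held-out voxel split with the full observation set and no
#' rotation.
#'
#' @param signals `B x M` matrix of normalized per-voxel signals (rows are
#'   voxels of the training tissue).
#' @param scheme the `dwi_scheme` the signals were acquired with (length `M`
#'   along measurements; may include b0 entries).
#' @param config an [encoder_config()].
#' @param seed integer seed; training is deterministic given seed.
#' @param epochs number of passes over the data (learning-rate drop at
#'   `floor(epochs/2)`).
#' @param batch_size voxels per gradient step.
#' @param lr initial learning rate.
#' @param val_frac fraction of voxels held out for validation.
#' @param rotate apply per-voxel q-space rotation augmentation.
#' @param verbose print per-epoch losses.
#' @return list with `params` (trained, includes `config`), `history`
#'   (data.frame epoch/train/val), and `baseline_val_mse` (predict-the-mean
#'   reference on the validation split).
#' @export
pretrain_reconstruction <- function(signals, scheme, config = encoder_config(),
                                    seed = 1L, epochs = 100L,
                                    batch_size = 4096L, lr = 0.005,
                                    val_frac = 0.1, rotate = TRUE,
                                    verbose = FALSE) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  signals <- as.matrix(signals)
  M <- scheme$M
  if (ncol(signals) != M)
    stop("signals must have one column per scheme measurement", call. = FALSE)
  if (M < config$n_min)
    stop(sprintf("scheme has M = %d measurements but n_min = %d", M,
                 config$n_min), call. = FALSE)
  B_total <- nrow(signals)
  params <- discus_init(config, seed = seed)
  with_seed(seed + 1L, {
    n_val <- max(1L, round(val_frac * B_total))
    val_idx <- sample.int(B_total, n_val)
    train_idx <- setdiff(seq_len(B_total), val_idx)
    val_sig <- signals[val_idx, , drop = FALSE]
    train_sig <- signals[train_idx, , drop = FALSE]
    baseline_val <- mean((val_sig - rowMeans(val_sig))^2)
    opt <- adam_init(params[c("pre", "post", "dec")])
    half <- max(1L, epochs %/% 2L)
    history <- data.frame(epoch = integer(), train = numeric(), val = numeric())
    n_train <- nrow(train_sig)
    for (ep in seq_len(epochs)) {
      cur_lr <- if (ep > half) lr * 0.1 else lr
      ord <- sample.int(n_train)
      starts <- seq(1L, n_train, by = batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (s in starts) {
        rows <- ord[s:min(s + batch_size - 1L, n_train)]
        sig <- train_sig[rows, , drop = FALSE]
        B <- nrow(sig)
        Nv <- sample(config$n_min:M, B, replace = TRUE)
        # exact size-N subset per voxel: keep the Nv smallest i.i.d. uniforms
        mask <- subset_masks(matrix(stats::runif(B * M), B, M), Nv)
        Q <- NULL
        if (rotate) {
          Q <- matrix(stats::rnorm(B * 4), B, 4)
          Q <- Q / sqrt(rowSums(Q^2))
        }
        fw <- discus_forward_train(sig, scheme$bvecs, scheme$bvals, mask, Q,
                                   params)
        resid <- fw$pred - as.vector(t(sig))
        loss <- mean(resid^2)
        grads <- discus_backward_train(fw, 2 * resid / length(resid), params)
        upd <- adam_step(params[c("pre", "post", "dec")], grads, opt, cur_lr)
        params[c("pre", "post", "dec")] <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
      }
      val_pred <- reconstruct_signals(val_sig, scheme, params)
      val_loss <- mean((val_pred - val_sig)^2)
      history <- rbind(history, data.frame(epoch = ep, train = ep_loss / ep_n,
                                           val = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  lr %.4g  train %.6f  val %.6f",
                        ep, cur_lr, ep_loss / ep_n, val_loss))
    }
    list(params = params, history = history, baseline_val_mse = baseline_val)
  })
}

#' Reconstruct all scheme signals from full observation sets
#'
#' Deterministic forward pass (no sub-sampling, no rotation): encodes each
#' voxel's complete observation set and decodes every measurement of the
#' scheme. Used for validation and for held-out-direction evaluation via
#' `query_scheme`.
#'
#' @param signals `B x M` observed normalized signals.
#' @param scheme acquisition scheme of the observations.
#' @param params trained [discus_init()] parameters.
#' @param query_scheme optional scheme to decode (defaults to `scheme`).
#' @return `B x M_query` matrix of predicted signals.
#' @export
reconstruct_signals <- function(signals, scheme, params, query_scheme = scheme) {
  signals <- as.matrix(signals)
  config <- params$config
  E <- encode_voxels_dense(signals, scheme$bvecs, scheme$bvals, params)
  B <- nrow(E); Mq <- query_scheme$M
  qf <- featurize_query(query_scheme$bvecs, query_scheme$bvals, config$bval_scale)
  dec_in <- cbind(qf[rep(seq_len(Mq), times = B), , drop = FALSE],
                  E[rep(seq_len(B), each = Mq), , drop = FALSE],
                  deparse.level = 0)
  matrix(mlp_infer(params$dec, dec_in), nrow = B, byrow = TRUE)
}
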