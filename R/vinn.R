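#' Segmenter configuration
#'
#' Knobs of the 2.5D segmentation stage. The backbone is a two-level 2D
#' encoder--decoder with skip connection and input/output interpolation
#' layers; the interpolation scale factor is the target of the scale
#' augmentation (drawn from a truncated normal during training, pinned to 1
#' at inference).
#'
#' @param L embedding length of the encoder feeding this segmenter.
#' @param S number of segmentation classes (including background 0).
#' @param filters base feature width of the backbone.
#' @param scale_sd standard deviation of the scale-augmentation normal
#'   (mean 1).
#' @param scale_range truncation interval for the scale factor.
#' @param edge_boost multiplicative loss weight at label boundaries.
#' @param dice_weight mixing coefficient of the soft Dice loss.
#' @param lr constant segmentation learning rate (default 1e-4).
#' @param batch_size slices per gradient step (default 2).
#' @param views the views to train/aggregate.
#' @return a `vinn_config` list.
#' @export
vinn_config <- function(L, S, filters = 24L, scale_sd = 0.1,
                        scale_range = c(0.8, 1.2), edge_boost = 2,
                        dice_weight = 1, lr = 1e-4, batch_size = 2L,
                        views = c("axial", "coronal", "sagittal")) {
  views <- match.arg(views, c("axial", "coronal", "sagittal"),
                     several.ok = TRUE)
  structure(list(L = as.integer(L), S = as.integer(S),
                 filters = as.integer(filters), scale_sd = scale_sd,
                 scale_range = scale_range, edge_boost = edge_boost,
                 dice_weight = dice_weight, lr = lr,
                 batch_size = as.integer(batch_size), views = views),
            class = "vinn_config")
}

conv_init <- function(k, c_in, c_out) {
  list(W = matrix(stats::rnorm(k * k * c_in * c_out,
                               sd = sqrt(2 / (k * k * c_in))),
                  k * k * c_in, c_out),
       b = numeric(c_out), k = k)
}

#' Initialize per-view segmenter parameters
#'
#' @param config a [vinn_config()].
#' @param seed integer seed.
#' @return named list of conv-layer parameter lists.
#' @export
vinn_init <- function(config, seed = 1L) {
  C <- config$L + 3L
  f <- config$filters
  with_seed(seed, list(
    c1a = conv_init(3L, C, f),
    c1b = conv_init(3L, f, f),
    c2a = conv_init(3L, f, 2L * f),
    c2b = conv_init(3L, 2L * f, 2L * f),
    c3  = conv_init(3L, 3L * f, f),
    out = conv_init(1L, f, config$S)
  ))
}

relu_cube <- function(x) { x[x < 0] <- 0; x }

# forward pass on one (d1, d2, C) slice input; scale is the interpolation
# factor of the input/output interpolation layers
vinn_forward <- function(vp, x, scale = 1) {
  d1 <- dim(x)[1]; d2 <- dim(x)[2]
  h <- max(8L, as.integer(round(d1 * scale)))
  w <- max(8L, as.integer(round(d2 * scale)))
  x1 <- if (h == d1 && w == d2) x else bilin_fw(x, h, w)
  a1 <- relu_cube(conv2d_fw(x1, vp$c1a$W, vp$c1a$b, 3L))
  a2 <- relu_cube(conv2d_fw(a1, vp$c1b$W, vp$c1b$b, 3L))
  mp <- maxpool2_fw(a2)
  b1 <- relu_cube(conv2d_fw(mp$y, vp$c2a$W, vp$c2a$b, 3L))
  b2 <- relu_cube(conv2d_fw(b1, vp$c2b$W, vp$c2b$b, 3L))
  up <- bilin_fw(b2, dim(a2)[1], dim(a2)[2])
  cat32 <- array(c(a2, up), c(dim(a2)[1], dim(a2)[2], dim(a2)[3] + dim(up)[3]))
  c3a <- relu_cube(conv2d_fw(cat32, vp$c3$W, vp$c3$b, 3L))
  back <- if (h == d1 && w == d2) c3a else bilin_fw(c3a, d1, d2)
  logits <- conv2d_fw(back, vp$out$W, vp$out$b, 1L)
  list(logits = logits,
       cache = list(x = x, x1 = x1, a1 = a1, a2 = a2, mp = mp, b1 = b1,
                    b2 = b2, up = up, cat32 = cat32, c3a = c3a, back = back,
                    scale_dims = c(h, w), in_dims = c(d1, d2)))
}

# backward pass; returns parameter grads and the gradient wrt the input slice
vinn_backward <- function(vp, cache, glogits) {
  d1 <- cache$in_dims[1]; d2 <- cache$in_dims[2]
  h <- cache$scale_dims[1]; w <- cache$scale_dims[2]
  bw_out <- conv2d_bw(cache$back, vp$out$W, glogits, 1L)
  g_c3a <- if (h == d1 && w == d2) bw_out$gx else bilin_bw(bw_out$gx, h, w)
  g_c3a <- g_c3a * (cache$c3a > 0)
  bw_c3 <- conv2d_bw(cache$cat32, vp$c3$W, g_c3a, 3L)
  f <- dim(cache$a2)[3]
  g_a2_skip <- bw_c3$gx[, , seq_len(f), drop = FALSE]
  g_up <- bw_c3$gx[, , f + seq_len(dim(cache$up)[3]), drop = FALSE]
  g_b2 <- bilin_bw(g_up, dim(cache$b2)[1], dim(cache$b2)[2])
  g_b2 <- g_b2 * (cache$b2 > 0)
  bw_c2b <- conv2d_bw(cache$b1, vp$c2b$W, g_b2, 3L)
  g_b1 <- bw_c2b$gx * (cache$b1 > 0)
  bw_c2a <- conv2d_bw(cache$mp$y, vp$c2a$W, g_b1, 3L)
  g_a2 <- maxpool2_bw(cache$mp$idx, bw_c2a$gx, dim(cache$a2)[1],
                      dim(cache$a2)[2]) + g_a2_skip
  g_a2 <- g_a2 * (cache$a2 > 0)
  bw_c1b <- conv2d_bw(cache$a1, vp$c1b$W, g_a2, 3L)
  g_a1 <- bw_c1b$gx * (cache$a1 > 0)
  bw_c1a <- conv2d_bw(cache$x1, vp$c1a$W, g_a1, 3L)
  gx <- if (h == d1 && w == d2) bw_c1a$gx else bilin_bw(bw_c1a$gx, d1, d2)
  grads <- list(c1a = list(W = bw_c1a$gw, b = bw_c1a$gb),
                c1b = list(W = bw_c1b$gw, b = bw_c1b$gb),
                c2a = list(W = bw_c2a$gw, b = bw_c2a$gb),
                c2b = list(W = bw_c2b$gw, b = bw_c2b$gb),
                c3  = list(W = bw_c3$gw, b = bw_c3$gb),
                out = list(W = bw_out$gw, b = bw_out$gb))
  list(grads = grads, gx = gx)
}

# ---- views and slice assembly ----------------------------------------------

.view_axis <- c(axial = 3L, coronal = 2L, sagittal = 1L)

check_view <- function(view) {
  if (!view %in% names(.view_axis))
    stop("invalid view '", view, "' (use axial, coronal or sagittal)",
         call. = FALSE)
  view
}

n_slices_view <- function(shape, view) shape[.view_axis[[check_view(view)]]]

slice3 <- function(vol, view, k) {
  switch(check_view(view),
         axial = vol[, , k], coronal = vol[, k, ], sagittal = vol[k, , ])
}

slice4 <- function(vol4, view, k) {
  switch(check_view(view),
         axial = vol4[, , k, , drop = FALSE][, , 1, ],
         coronal = vol4[, k, , , drop = FALSE][, 1, , ],
         sagittal = vol4[k, , , , drop = FALSE][1, , , ])
}

#' Assemble a slice input for the segmenter
#'
#' Channel layout (fixed): the `L` embedding channels of the central slice,
#' then the mean-b0 slice at `index - 1`, `index`, `index + 1`. Only the
#' central embedding slice is included (no embedding neighbors); missing b0
#' neighbors at the volume edge are edge-replicated. The channel count is
#' therefore always `C = L + 3`.
#'
#' @param emb_volume 4D embedding volume (W, H, D, L).
#' @param mean_b0 3D mean b0 volume (typically z-scored within the mask).
#' @param index slice index along the view axis.
#' @param view `"axial"`, `"coronal"` or `"sagittal"`.
#' @return array (d1, d2, L + 3).
#' @export
assemble_slice_input <- function(emb_volume, mean_b0, index, view) {
  check_view(view)
  shape <- dim(mean_b0)
  n <- n_slices_view(shape, view)
  if (index < 1L || index > n)
    stop(sprintf("slice index %d out of range [1, %d] for view %s",
                 index, n, view), call. = FALSE)
  es <- slice4(emb_volume, view, index)
  L <- dim(emb_volume)[4]
  d1 <- dim(es)[1]; d2 <- dim(es)[2]
  x <- array(0, c(d1, d2, L + 3L))
  x[, , seq_len(L)] <- es
  nb <- pmin(pmax(index + (-1L:1L), 1L), n)   # edge replication
  for (i in 1:3) x[, , L + i] <- slice3(mean_b0, view, nb[i])
  x
}

#' Compute an embedding volume from a diffusion series
#'
#' Evaluates the encoder only for voxels inside the brain mask (gather),
#' scatters the embeddings back into place and fills out-of-mask voxels with
#' zeros. Signals are normalized per voxel by the mean b0.
#'
#' @param dwi a `dwi_volume` from [simulate_acquisition()] (or an equivalent
#'   list with `data`, `scheme`, `mean_b0`).
#' @param mask logical 3D brain mask with the volume's shape.
#' @param params trained encoder parameters ([discus_init()] structure).
#' @param subset_indices optional measurement indices to restrict the
#'   observation set to (e.g. a [subsample_max_coverage()] result).
#' @param batch voxels per encoder evaluation.
#' @return array (W, H, D, L).
#' @export
embed_volume <- function(dwi, mask, params, subset_indices = NULL,
                         batch = 16384L) {
  shape <- dim(dwi$mean_b0)
  if (!identical(dim(mask), shape))
    stop("mask shape does not match the volume shape", call. = FALSE)
  check_dwi_scheme(dwi$data, dwi$scheme)
  L <- params$config$L
  emb <- array(0, c(shape, L))
  idx <- which(mask)
  if (length(idx) == 0L) return(emb)
  norm <- normalize_case_signals(dwi, mask, params$config)
  cols <- if (is.null(subset_indices)) seq_len(dwi$scheme$M) else subset_indices
  bvecs <- dwi$scheme$bvecs[cols, , drop = FALSE]
  bvals <- dwi$scheme$bvals[cols]
  sig <- norm[, cols, drop = FALSE]
  n <- nrow(sig)
  batch <- max(1L, as.integer(min(batch, ceiling(4e5 / length(cols)))))
  embm <- matrix(0, n, L)
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    embm[s:e, ] <- encode_voxels_dense(sig[s:e, , drop = FALSE], bvecs, bvals,
                                       params)
  }
  step <- prod(shape)
  for (l in seq_len(L)) emb[idx + (l - 1L) * step] <- embm[, l]
  emb
}

# normalized in-mask signals (n_mask x M), rows in which(mask) order
normalize_case_signals <- function(dwi, mask, config) {
  idx <- which(mask)
  b0v <- dwi$mean_b0[idx]
  eps <- 1e-6 * stats::median(b0v)
  if (any(b0v <= eps))
    stop(sprintf("degenerate voxel(s) inside mask: %d voxels with mean b0 <= %g",
                 sum(b0v <= eps), eps), call. = FALSE)
  M <- dwi$scheme$M
  dmat <- matrix(dwi$data, ncol = M)[idx, , drop = FALSE]
  pmin(pmax(dmat / b0v, 0), config$clip_max)
}

#' Prepare a training/evaluation case
#'
#' Precomputes everything the segmentation stage needs from a phantom and its
#' simulated acquisition: normalized in-mask voxel signals, a z-scored mean
#' b0 volume, the label volume, the boundary (edge) mask and per-view voxel
#' lookup tables.
#'
#' @param phantom a [build_phantom()] result (provides mask + labels).
#' @param dwi the matching [simulate_acquisition()] result.
#' @param config an [encoder_config()] (for the signal clip).
#' @return a `seg_case` list.
#' @export
prepare_case <- function(phantom, dwi, config = encoder_config()) {
  mask <- phantom$mask
  shape <- dim(mask)
  norm <- normalize_case_signals(dwi, mask, config)
  b0 <- dwi$mean_b0
  mu <- mean(b0[mask]); sdv <- stats::sd(b0[mask])
  b0z <- (b0 - mu) / max(sdv, 1e-12)
  rowmap <- array(0L, shape)
  rowmap[which(mask)] <- seq_len(sum(mask))
  structure(list(norm = norm, mask = mask, rowmap = rowmap, b0z = b0z,
                 labels = phantom$labels, edge = compute_edge_mask(phantom$labels),
                 scheme = dwi$scheme, spacing = phantom$spacing, shape = shape),
            class = "seg_case")
}

# voxels within one face-neighbor of a label boundary
compute_edge_mask <- function(labels) {
  d <- dim(labels)
  e <- array(FALSE, d)
  ne <- function(a, b) a != b
  e[-1, , ] <- e[-1, , ] | ne(labels[-1, , ], labels[-d[1], , ])
  e[-d[1], , ] <- e[-d[1], , ] | ne(labels[-d[1], , ], labels[-1, , ])
  e[, -1, ] <- e[, -1, ] | ne(labels[, -1, ], labels[, -d[2], ])
  e[, -d[2], ] <- e[, -d[2], ] | ne(labels[, -d[2], ], labels[, -1, ])
  e[, , -1] <- e[, , -1] | ne(labels[, , -1], labels[, , -d[3]])
  e[, , -d[3]] <- e[, , -d[3]] | ne(labels[, , -d[3]], labels[, , -1])
  e
}

#' Median-frequency class weights
#'
#' `weight_c = median(class frequencies) / frequency_c`, so the class whose
#' frequency equals the median gets weight 1 and rare classes are boosted.
#'
#' @param labels integer label array with classes `0 .. S-1`.
#' @param S number of classes; every class must be present.
#' @return numeric vector of `S` weights (named by class).
#' @export
compute_class_weights <- function(labels, S) {
  counts <- tabulate(as.vector(labels) + 1L, nbins = S)
  if (any(counts == 0L))
    stop("class(es) absent from training labels: ",
         paste(which(counts == 0L) - 1L, collapse = ", "), call. = FALSE)
  freq <- counts / sum(counts)
  stats::setNames(stats::median(freq) / freq, paste0("class", 0:(S - 1L)))
}

#' Composite segmentation loss
#'
#' Median-frequency-weighted cross-entropy with edge boost plus a soft
#' multi-class Dice loss. The per-pixel cross-entropy weight is
#' `class_weight[target] * edge_boost` at label boundaries and
#' `class_weight[target]` elsewhere; the Dice term is
#' `1 - mean_c (2 I_c + eps) / (U_c + eps)` over all classes.
#'
#' @param pred_probs array (d1, d2, S) of per-pixel class probabilities;
#'   rows must sum to 1 within 1e-5.
#' @param target_labels (d1, d2) integer labels in `0 .. S-1`.
#' @param class_weights `S` positive weights (see [compute_class_weights()]).
#' @param edge_mask logical (d1, d2); `NULL` for no edge boost.
#' @param edge_boost boundary weight multiplier.
#' @param dice_weight Dice mixing coefficient.
#' @return scalar loss.
#' @export
segmentation_loss <- function(pred_probs, target_labels, class_weights,
                              edge_mask = NULL, edge_boost = 2,
                              dice_weight = 1) {
  S <- dim(pred_probs)[3]
  pm <- matrix(pred_probs, ncol = S)
  if (max(abs(rowSums(pm) - 1)) > 1e-5)
    stop("contract violation: probability rows do not sum to 1", call. = FALSE)
  t_vec <- as.vector(target_labels)
  n <- length(t_vec)
  w <- class_weights[t_vec + 1L]
  if (!is.null(edge_mask)) w <- w * ifelse(as.vector(edge_mask), edge_boost, 1)
  p_t <- pm[cbind(seq_len(n), t_vec + 1L)]
  ce <- sum(w * -log(pmax(p_t, 1e-12))) / n
  ce + dice_weight * soft_dice_loss(pm, t_vec, S)
}

soft_dice_loss <- function(pm, t_vec, S, eps = 1e-6) {
  d <- 0
  for (c in seq_len(S)) {
    tc <- as.numeric(t_vec == c - 1L)
    d <- d + (2 * sum(pm[, c] * tc) + eps) / (sum(pm[, c]) + sum(tc) + eps)
  }
  1 - d / S
}

# loss + gradient wrt logits for training. logits (d1,d2,S); target (d1,d2);
# wmap per-pixel CE weights (class weight x edge boost)
seg_loss_grad <- function(logits, target, wmap, dice_weight, S) {
  d1 <- dim(logits)[1]; d2 <- dim(logits)[2]
  lm <- matrix(logits, ncol = S)
  lm <- lm - apply(lm, 1L, max)
  pm <- exp(lm)
  pm <- pm / rowSums(pm)
  t_vec <- as.vector(target)
  n <- length(t_vec)
  w <- as.vector(wmap)
  onehot_idx <- cbind(seq_len(n), t_vec + 1L)
  ce <- sum(w * -log(pmax(pm[onehot_idx], 1e-12))) / n
  g_ce <- pm * (w / n)
  g_ce[onehot_idx] <- g_ce[onehot_idx] - w / n
  # soft dice and its gradient wrt probabilities, then through softmax
  eps <- 1e-6
  dice <- 0
  g_p <- matrix(0, n, S)
  for (c in seq_len(S)) {
    tc <- as.numeric(t_vec == c - 1L)
    Ic <- sum(pm[, c] * tc); Uc <- sum(pm[, c]) + sum(tc)
    dice <- dice + (2 * Ic + eps) / (Uc + eps)
    g_p[, c] <- -(2 * tc * (Uc + eps) - (2 * Ic + eps)) / (S * (Uc + eps)^2)
  }
  dice_loss <- 1 - dice / S
  # softmax jacobian: g_logit = p * (g - sum_j g_j p_j)
  g_dice <- pm * (g_p - rowSums(g_p * pm))
  glogits <- array(g_ce + dice_weight * g_dice, c(d1, d2, S))
  list(loss = ce + dice_weight * dice_loss, ce = ce, dice = dice_loss,
       glogits = glogits)
}

# ---- training ---------------------------------------------------------------

# encoder forward on a set of voxels sharing one direction set, with caches
# for the encoder-only backward (used by scratch/multitask schemes)
encode_voxels_cache <- function(signals, bvecs, bvals, params) {
  B <- nrow(signals); M <- nrow(bvecs)
  mask <- matrix(TRUE, B, M)
  discus_forward_train(signals, bvecs, bvals, mask, NULL, params,
                       run_decoder = FALSE)
}

#' Train one view of the segmenter
#'
#' Per training slice, the number of observed measurements `N` is drawn
#' uniformly in `[n_min, M]` and a random subset of that size is applied
#' identically to every voxel of the slice (no q-space rotation in the
#' segmentation pass); the interpolation scale factor is drawn from a
#' truncated normal. Training schemes: `"pretrain_frozen"` keeps the encoder
#' bit-identical and updates only the segmenter; `"scratch_seg_only"` updates
#' encoder and segmenter from the segmentation objective;
#' `"multitask_seg_recon"` additionally runs a per-voxel reconstruction pass
#' (with rotation and sub-sampling) whose MSE updates encoder and decoder,
#' with both updates applied jointly.
#'
#' @param view `"axial"`, `"coronal"` or `"sagittal"`.
#' @param cases list of [prepare_case()] results.
#' @param encoder encoder parameters; required (pre-trained) for
#'   `pretrain_frozen`, a fresh [discus_init()] otherwise.
#' @param scheme training scheme (see above).
#' @param config a [vinn_config()].
#' @param seed integer seed; training is deterministic given seed.
#' @param steps gradient steps (default: one pass over all usable slices).
#' @param lr learning rate (default `config$lr`).
#' @param recon_batch voxels per reconstruction pass (multitask only).
#' @param verbose print progress every 25 steps.
#' @return list with `view`, `params` (segmenter), `encoder` (updated or
#'   identical), `history` (per-step losses), `scheme`, `config`.
#' @export
train_view <- function(view, cases, encoder,
                       scheme = c("pretrain_frozen", "scratch_seg_only",
                                  "multitask_seg_recon"),
                       config, seed = 1L, steps = NULL, lr = config$lr,
                       recon_batch = 256L, verbose = FALSE) {
  check_view(view)
  scheme <- match.arg(scheme)
  if (is.null(encoder))
    stop(sprintf("configuration error: scheme '%s' requires encoder parameters%s",
                 scheme, if (scheme == "pretrain_frozen")
                   " from reconstruction pre-training" else ""), call. = FALSE)
  enc_cfg <- encoder$config
  S <- config$S
  all_labels <- unlist(lapply(cases, function(cs) as.vector(cs$labels)))
  cw <- compute_class_weights(all_labels, S)
  dwi_cols <- which(!cases[[1]]$scheme$is_b0)
  Md <- length(dwi_cols)
  # usable slices: at least a handful of in-mask voxels
  pool <- do.call(rbind, lapply(seq_along(cases), function(ci) {
    ns <- n_slices_view(cases[[ci]]$shape, view)
    cnt <- vapply(seq_len(ns), function(k)
      sum(slice3(cases[[ci]]$mask, view, k)), 1L)
    data.frame(case = ci, k = which(cnt >= 10L))
  }))
  if (is.null(steps)) steps <- ceiling(nrow(pool) / config$batch_size)
  update_enc <- scheme != "pretrain_frozen"
  vp <- vinn_init(config, seed = seed)
  opt_v <- adam_init(list(vp))
  opt_e <- if (update_enc) {
    groups <- if (scheme == "multitask_seg_recon") c("pre", "post", "dec")
              else c("pre", "post")
    adam_init(encoder[groups])
  }
  history <- data.frame(step = integer(), seg_loss = numeric(),
                        recon_loss = numeric())
  L <- enc_cfg$L
  with_seed(seed, {
    for (st in seq_len(steps)) {
      picks <- pool[sample.int(nrow(pool), config$batch_size, replace = TRUE), ]
      acc_v <- NULL; acc_e <- NULL
      seg_loss <- 0; recon_loss <- NA_real_
      for (bi in seq_len(nrow(picks))) {
        cs <- cases[[picks$case[bi]]]
        k <- picks$k[bi]
        # slice-level q-space sampling augmentation
        N <- sample(enc_cfg$n_min:Md, 1L)
        cols <- sort(sample(dwi_cols, N))
        sl_map <- slice3(cs$rowmap, view, k)
        sel <- which(sl_map > 0L)
        rows <- sl_map[sel]
        sig <- cs$norm[rows, cols, drop = FALSE]
        bvecs <- cs$scheme$bvecs[cols, , drop = FALSE]
        bvals <- cs$scheme$bvals[cols]
        fw_enc <- if (update_enc) {
          encode_voxels_cache(sig, bvecs, bvals, encoder)
        } else NULL
        E <- if (update_enc) fw_enc$E
             else encode_voxels_dense(sig, bvecs, bvals, encoder)
        d12 <- dim(sl_map)
        x <- array(0, c(d12, L + 3L))
        step2 <- prod(d12)
        for (l in seq_len(L)) x[sel + (l - 1L) * step2] <- E[, l]
        ns <- n_slices_view(cs$shape, view)
        nb <- pmin(pmax(k + (-1L:1L), 1L), ns)
        for (i in 1:3) x[, , L + i] <- slice3(cs$b0z, view, nb[i])
        # scale augmentation
        s <- stats::rnorm(1, 1, config$scale_sd)
        s <- min(max(s, config$scale_range[1]), config$scale_range[2])
        fw <- vinn_forward(vp, x, scale = s)
        target <- slice3(cs$labels, view, k)
        wmap <- matrix(cw[as.vector(target) + 1L], d12[1], d12[2]) *
          ifelse(slice3(cs$edge, view, k), config$edge_boost, 1)
        lg <- seg_loss_grad(fw$logits, target, wmap, config$dice_weight, S)
        seg_loss <- seg_loss + lg$loss
        bw <- vinn_backward(vp, fw$cache, lg$glogits)
        acc_v <- accumulate_grads(acc_v, list(bw$grads))
        if (update_enc) {
          gE <- matrix(0, length(rows), L)
          for (l in seq_len(L)) gE[, l] <- bw$gx[sel + (l - 1L) * step2]
          ge <- discus_backward_encoder(fw_enc, gE, encoder)
          if (scheme == "multitask_seg_recon") {
            # joint per-voxel reconstruction pass with rotation + sub-sampling
            vb <- sample.int(nrow(cs$norm), min(recon_batch, nrow(cs$norm)))
            rsig <- cs$norm[vb, dwi_cols, drop = FALSE]
            B <- nrow(rsig)
            Nv <- sample(enc_cfg$n_min:Md, B, replace = TRUE)
            rmask <- subset_masks(matrix(stats::runif(B * Md), B, Md), Nv)
            Q <- matrix(stats::rnorm(B * 4), B, 4)
            Q <- Q / sqrt(rowSums(Q^2))
            rfw <- discus_forward_train(rsig, cs$scheme$bvecs[dwi_cols, , drop = FALSE],
                                        cs$scheme$bvals[dwi_cols], rmask, Q,
                                        encoder)
            resid <- rfw$pred - as.vector(t(rsig))
            recon_loss <- if (is.na(recon_loss)) mean(resid^2)
                          else recon_loss + mean(resid^2)
            gr <- discus_backward_train(rfw, 2 * resid / length(resid), encoder)
            ge <- list(pre = add_grads(ge$pre, gr$pre),
                       post = add_grads(ge$post, gr$post),
                       dec = gr$dec)
          }
          acc_e <- accumulate_grads(acc_e, list(ge))
        }
      }
      nb <- nrow(picks)
      acc_v <- scale_grads(acc_v, 1 / nb)
      upd <- adam_step(list(vp), acc_v, opt_v, lr)
      vp <- upd$params[[1]]; opt_v <- upd$state
      if (update_enc) {
        acc_e2 <- scale_grads(acc_e, 1 / nb)[[1]]
        groups <- names(opt_e$m)
        upd_e <- adam_step(encoder[groups], acc_e2[groups], opt_e, lr)
        encoder[groups] <- upd_e$params
        opt_e <- upd_e$state
      }
      history <- rbind(history, data.frame(
        step = st, seg_loss = seg_loss / nb,
        recon_loss = if (scheme == "multitask_seg_recon") recon_loss / nb
                     else NA_real_))
      if (verbose && st %% 25L == 0L)
        message(sprintf("[%s] step %d/%d  seg %.4f", view, st, steps,
                        seg_loss / nb))
    }
  })
  list(view = view, params = vp, encoder = encoder, history = history,
       scheme = scheme, config = config, class_weights = cw)
}

# grads is a (possibly nested) list of numeric leaves; acc sums elementwise
accumulate_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  add_grads(acc, grads)
}

add_grads <- function(a, b) {
  if (is.numeric(b)) return(a + b)
  for (i in seq_along(b)) a[[i]] <- add_grads(a[[i]], b[[i]])
  a
}

scale_grads <- function(acc, f) {
  rapply(acc, function(x) x * f, how = "replace")
}

#' Segment a volume with trained per-view models
#'
#' Per view, slice-wise class probabilities are assembled into a 3D
#' probability volume; views are aggregated by the voxel-wise mean of their
#' probability volumes; the final label is the argmax with ties broken toward
#' the lowest class index, and out-of-mask voxels are forced to background.
#'
#' @param case a [prepare_case()] result (or the output of
#'   [case_from_files()]).
#' @param view_models named list of [train_view()] results (at least one
#'   view; the encoder of the first model is used for the embedding).
#' @param subset_indices optional measurement subset (original scheme
#'   indices, e.g. from [subsample_max_coverage()]); b0 entries are used for
#'   the mean b0 regardless.
#' @return list with `labels` (integer 3D volume) and `prob` (4D mean
#'   probability volume).
#' @export
predict_segmentation <- function(case, view_models, subset_indices = NULL) {
  if (length(view_models) == 0L)
    stop("no view models supplied", call. = FALSE)
  encoder <- view_models[[1]]$encoder
  config <- view_models[[1]]$config
  S <- config$S
  L <- encoder$config$L
  dwi_cols <- which(!case$scheme$is_b0)
  cols <- if (is.null(subset_indices)) dwi_cols
          else intersect(subset_indices, dwi_cols)
  shape <- case$shape
  # embed in-mask voxels once for the chosen subset
  emb <- array(0, c(shape, L))
  idx <- which(case$mask)
  sig <- case$norm[, cols, drop = FALSE]
  bvecs <- case$scheme$bvecs[cols, , drop = FALSE]
  bvals <- case$scheme$bvals[cols]
  n <- nrow(sig)
  step <- prod(shape)
  batch <- max(1L, as.integer(ceiling(4e5 / length(cols))))
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    E <- encode_voxels_dense(sig[s:e, , drop = FALSE], bvecs, bvals, encoder)
    for (l in seq_len(L)) emb[idx[s:e] + (l - 1L) * step] <- E[, l]
  }
  prob <- array(0, c(shape, S))
  for (vm in view_models) {
    vw <- vm$view
    ns <- n_slices_view(shape, vw)
    for (k in seq_len(ns)) {
      x <- assemble_slice_input(emb, case$b0z, k, vw)
      logits <- vinn_forward(vm$params, x, scale = 1)$logits
      lm <- matrix(logits, ncol = S)
      lm <- exp(lm - apply(lm, 1L, max))
      pm <- lm / rowSums(lm)
      pa <- array(pm, c(dim(x)[1], dim(x)[2], S))
      if (vw == "axial") prob[, , k, ] <- prob[, , k, ] + pa
      else if (vw == "coronal") prob[, k, , ] <- prob[, k, , ] + pa
      else prob[k, , , ] <- prob[k, , , ] + pa
    }
  }
  prob <- prob / length(view_models)
  pm <- matrix(prob, ncol = S)
  lab <- max.col(pm, ties.method = "first") - 1L
  lab[!as.vector(case$mask)] <- 0L
  list(labels = array(as.integer(lab), shape), prob = prob)
}
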