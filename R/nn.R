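# Minimal dense-network machinery: He-initialized MLPs with ReLU hidden
# units, hand-written backprop, and an Adam optimizer. Parameters are plain
# lists of (W, b) so they serialize and checksum trivially. All heavy lifting
# is delegated to BLAS through %*% / crossprod.

# sizes: vector of layer widths, e.g. c(8, 64, 64, 16)
mlp_init <- function(sizes) {
  n <- length(sizes) - 1L
  lapply(seq_len(n), function(i) {
    fan_in <- sizes[i]
    list(W = matrix(stats::rnorm(fan_in * sizes[i + 1], sd = sqrt(2 / fan_in)),
                    fan_in, sizes[i + 1]),
         b = numeric(sizes[i + 1]))
  })
}

# inference-only forward pass (no cache): hidden ReLU, last layer linear
mlp_infer <- function(params, X) {
  n <- length(params)
  for (i in seq_len(n)) X <- dense_fw(X, params[[i]]$W, params[[i]]$b, i < n)
  X
}

# forward pass; hidden layers ReLU, last layer linear.
# returns list(out, cache) where cache holds the layer inputs (post-activation)
mlp_forward <- function(params, X) {
  n <- length(params)
  cache <- vector("list", n)
  A <- X
  for (i in seq_len(n)) {
    cache[[i]] <- A
    A <- dense_fw(A, params[[i]]$W, params[[i]]$b, i < n)
  }
  list(out = A, cache = cache)
}

# backward pass; also returns the gradient wrt the input X
mlp_backward_full <- function(params, cache, gOut) {
  n <- length(params)
  grads <- vector("list", n)
  G <- gOut
  for (i in rev(seq_len(n))) {
    A <- cache[[i]]
    grads[[i]] <- list(W = crossprod(A, G), b = colSums(G))
    G <- dense_bw_input(G, params[[i]]$W, cache[[i]], i > 1L)
  }
  list(grads = grads, gX = G)
}

# ---- Adam -------------------------------------------------------------------

# state mirrors a nested parameter list (lists of list(W, b) groups)
adam_init <- function(param_groups) {
  zero_like <- function(p) lapply(p, function(l) list(W = l$W * 0, b = l$b * 0))
  list(m = lapply(param_groups, zero_like),
       v = lapply(param_groups, zero_like),
       t = 0L)
}

adam_step <- function(param_groups, grad_groups, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (g in seq_along(param_groups)) {
    for (l in seq_along(param_groups[[g]])) {
      for (nm in c("W", "b")) {
        gr <- grad_groups[[g]][[l]][[nm]]
        state$m[[g]][[l]][[nm]] <- beta1 * state$m[[g]][[l]][[nm]] + (1 - beta1) * gr
        state$v[[g]][[l]][[nm]] <- beta2 * state$v[[g]][[l]][[nm]] + (1 - beta2) * gr^2
        mhat <- state$m[[g]][[l]][[nm]] / bc1
        vhat <- state$v[[g]][[l]][[nm]] / bc2
        param_groups[[g]][[l]][[nm]] <-
          param_groups[[g]][[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(params = param_groups, state = state)
}

# stable fingerprint of a nested parameter list (frozen-encoder assertions)
params_checksum <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  rapply(params, function(x) writeBin(as.numeric(x), con, size = 8,
                                      endian = "little"), how = "unlist")
  close(con)
  unname(tools::md5sum(f))
}
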