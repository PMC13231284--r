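# Shared lightweight fixtures (built in code, cached per test run)

fixture_env <- new.env(parent = emptyenv())

# small phantom + noiseless/noisy acquisitions, built once
get_small_phantom <- function() {
  if (is.null(fixture_env$ph))
    fixture_env$ph <- build_phantom(c(32L, 32L, 32L), seed = 42L)
  fixture_env$ph
}

get_small_scheme <- function() {
  if (is.null(fixture_env$sch))
    fixture_env$sch <- single_shell_scheme(12L, 1000, 2L, seed = 7L)
  fixture_env$sch
}

# closed-form noiseless signals for a tensor row-matrix (n x 6) and
# direction set (independent oracle used across tests)
oracle_signals <- function(t6, G, b = 1000) {
  vapply(seq_len(nrow(G)), function(m) {
    g <- G[m, ]
    q <- t6[, 1] * g[1]^2 + t6[, 4] * g[2]^2 + t6[, 6] * g[3]^2 +
      2 * (t6[, 2] * g[1] * g[2] + t6[, 3] * g[1] * g[3] +
             t6[, 5] * g[2] * g[3])
    exp(-b * q)
  }, numeric(nrow(t6)))
}

# brute-force pooled boundary-distance multiset (independent of hd99's path)
hd_pool_oracle <- function(a, b, sp) {
  pts <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    d <- dim(m)
    keep <- vapply(seq_len(nrow(idx)), function(r) {
      v <- idx[r, ]
      nb <- rbind(v + c(1, 0, 0), v - c(1, 0, 0), v + c(0, 1, 0),
                  v - c(0, 1, 0), v + c(0, 0, 1), v - c(0, 0, 1))
      any(apply(nb, 1, function(u)
        any(u < 1 | u > d) || !m[u[1], u[2], u[3]]))
    }, TRUE)
    idx[keep, , drop = FALSE] * sp
  }
  pa <- pts(a); pb <- pts(b)
  dists <- function(x, y) apply(x, 1, function(v)
    sqrt(min(colSums((t(y) - v)^2))))
  c(dists(pa, pb), dists(pb, pa))
}

random_obs <- function(n, seed = 1L) {
  set.seed(seed)
  observation_set(bvecs = generate_directions(n, seed = seed),
                  bvals = rep(1000, n),
                  signals = runif(n, 0.1, 0.9))
}
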