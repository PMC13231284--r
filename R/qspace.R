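#' Construct an acquisition scheme (gradient table)
#'
#' An acquisition scheme is the q-space sampling identity of a diffusion MRI
#' dataset: `M` diffusion-encoding directions (unit b-vectors) with their
#' diffusion weightings (b-values, s/mm^2). Entries with `bval == 0` are b0
#' measurements; their b-vector is irrelevant and they are excluded from all
#' direction-coverage computations.
#'
#' @param bvecs numeric matrix, `M x 3` (rows are directions) or `3 x M`
#'   (FSL layout; auto-detected when unambiguous). Vectors paired with a
#'   positive b-value are renormalized to unit norm.
#' @param bvals numeric vector of length `M`, non-negative, in s/mm^2.
#' @return An object of class `dwi_scheme`: list with `bvecs` (`M x 3`),
#'   `bvals`, `M`, and logical `is_b0`.
#' @export
acquisition_scheme <- function(bvecs, bvals) {
  bvecs <- as.matrix(bvecs)
  bvals <- as.numeric(bvals)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("`bvecs` must be an M x 3 (or 3 x M) matrix", call. = FALSE)
  M <- nrow(bvecs)
  if (M < 1L) stop("scheme must contain at least one measurement", call. = FALSE)
  if (length(bvals) != M)
    stop(sprintf("bvecs (%d) and bvals (%d) lengths differ", M, length(bvals)),
         call. = FALSE)
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative", call. = FALSE)
  is_b0 <- bvals == 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(!is_b0 & nrm < 1e-12))
    stop("zero b-vector paired with a positive b-value", call. = FALSE)
  bvecs[!is_b0, ] <- bvecs[!is_b0, , drop = FALSE] / nrm[!is_b0]
  structure(
    list(bvecs = bvecs, bvals = bvals, M = M, is_b0 = is_b0),
    class = "dwi_scheme"
  )
}

#' @export
print.dwi_scheme <- function(x, ...) {
  cat(sprintf("<dwi_scheme> %d measurements (%d b0, %d diffusion-weighted)\n",
              x$M, sum(x$is_b0), sum(!x$is_b0)))
  shells <- sort(unique(x$bvals[!x$is_b0]))
  if (length(shells)) cat("  shells (s/mm^2):", paste(shells, collapse = ", "), "\n")
  invisible(x)
}

#' Antipodal electrostatic repulsion energy of a direction set
#'
#' Sum over pairs of `1/|g_i - g_j| + 1/|g_i + g_j|`. The second term makes
#' the energy invariant under sign flips of any subset of directions
#' (antipodal symmetry of diffusion encoding): parallel and anti-parallel
#' pairs are penalized equally, so minimizers spread directions over the
#' projective sphere, the standard notion of angular coverage.
#'
#' @param bvecs `n x 3` matrix of unit vectors.
#' @return scalar energy (`0` for a single direction).
#' @export
coverage_energy <- function(bvecs) {
  bvecs <- as.matrix(bvecs)
  n <- nrow(bvecs)
  if (n < 2L) return(0)
  G <- tcrossprod(bvecs)                  # g_i . g_j
  nn <- diag(G)
  d2m <- outer(nn, nn, "+") - 2 * G       # |gi - gj|^2
  d2p <- outer(nn, nn, "+") + 2 * G       # |gi + gj|^2
  ut <- upper.tri(d2m)
  sum(1 / sqrt(pmax(d2m[ut], 1e-300))) + sum(1 / sqrt(pmax(d2p[ut], 1e-300)))
}

#' Generate approximately uniformly spread gradient directions
#'
#' Minimizes the antipodal repulsion energy ([coverage_energy]) by projected
#' gradient descent from a seeded random start on the sphere. Deterministic
#' given `seed`.
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed.
#' @param n_iter descent iterations.
#' @return `n x 3` matrix of unit vectors.
#' @export
generate_directions <- function(n, seed = 1L, n_iter = 400L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  g <- with_seed(seed, {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  })
  if (n == 1L) return(g)
  step <- 0.1 / n
  e_old <- coverage_energy(g)
  for (it in seq_len(n_iter)) {
    gr <- .coverage_energy_grad(g)
    # project gradient onto sphere tangent space, step, renormalize
    cand <- g - step * (gr - g * rowSums(gr * g))
    cand <- cand / sqrt(rowSums(cand^2))
    e_new <- coverage_energy(cand)
    if (e_new < e_old) {
      g <- cand; e_old <- e_new
      step <- step * 1.1
    } else {
      step <- step * 0.5
      if (step < 1e-12) break
    }
  }
  g
}

# gradient of coverage_energy wrt each row
.coverage_energy_grad <- function(g) {
  n <- nrow(g)
  G <- tcrossprod(g)
  nn <- diag(G)
  d2m <- outer(nn, nn, "+") - 2 * G
  d2p <- outer(nn, nn, "+") + 2 * G
  diag(d2m) <- Inf
  wm <- d2m^(-1.5)               # d/dx 1/|d| = -(d)/|d|^3
  wp <- d2p^(-1.5)
  diag(wp) <- 0
  # grad_i = sum_j -wm_ij (g_i - g_j) - wp_ij (g_i + g_j)
  sm <- rowSums(wm); sp <- rowSums(wp)
  -(sm * g - wm %*% g) - (sp * g + wp %*% g)
}

#' Sub-sample a scheme for maximum angular coverage
#'
#' Selects `k` of the diffusion-weighted (bval > 0) measurements so that the
#' retained directions keep maximal angular coverage, i.e. minimal antipodal
#' repulsion energy over the subset. Uses a deterministic greedy seed followed
#' by pairwise exchange passes (ties broken toward the lowest index), the
#' desk-scale equivalent of selecting 10/30/90-direction sub-acquisitions
#' from a 90-direction shell.
#'
#' @param scheme a [acquisition_scheme()].
#' @param k subset size, `1 <= k <=` number of bval>0 entries.
#' @param max_sweeps maximum exchange sweeps (energy is non-increasing in
#'   sweeps; stops early at a local optimum).
#' @return sorted integer vector of `k` original measurement indices.
#' @export
subsample_max_coverage <- function(scheme, k, max_sweeps = 200L) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  dwi_idx <- which(!scheme$is_b0)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(dwi_idx))
    stop(sprintf("`k` must be in [1, %d] (diffusion-weighted measurements)",
                 length(dwi_idx)), call. = FALSE)
  if (k == length(dwi_idx)) return(dwi_idx)
  g <- scheme$bvecs[dwi_idx, , drop = FALSE]
  n <- nrow(g)
  # pairwise antipodal energies
  G <- tcrossprod(g)
  nn <- diag(G)
  pe <- 1 / sqrt(pmax(outer(nn, nn, "+") - 2 * G, 1e-300)) +
        1 / sqrt(pmax(outer(nn, nn, "+") + 2 * G, 1e-300))
  diag(pe) <- 0
  # greedy: start from index 1, repeatedly add point with least added energy
  sel <- 1L
  while (length(sel) < k) {
    add_cost <- colSums(pe[sel, , drop = FALSE])
    add_cost[sel] <- Inf
    sel <- c(sel, which.min(add_cost))   # which.min takes lowest index on tie
  }
  # exchange passes: swap any selected for any unselected if energy drops
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (si in seq_along(sel)) {
      i <- sel[si]
      rest <- sel[-si]
      cost_i <- sum(pe[i, rest])
      out <- setdiff(seq_len(n), sel)
      cost_out <- colSums(pe[rest, out, drop = FALSE])
      j <- out[which.min(cost_out)]
      if (min(cost_out) < cost_i - 1e-12) {
        sel[si] <- j
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  sort(dwi_idx[sel])
}

#' Draw a uniformly distributed 3D rotation
#'
#' Haar-uniform over SO(3) via the normalized-quaternion construction: a
#' 4-vector of i.i.d. standard normals, normalized, is uniform on S^3, and
#' the induced rotation is uniform on the rotation group.
#'
#' @param seed integer seed; deterministic given seed.
#' @return 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @export
sample_rotation <- function(seed = 1L) {
  q <- with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  quat_to_rotmat(q)
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# draw a rotation from the current RNG stream (no reseeding)
rotmat_from_rng <- function() {
  q <- stats::rnorm(4)
  quat_to_rotmat(q / sqrt(sum(q^2)))
}

#' Read / write FSL-dialect gradient tables
#'
#' The FSL dialect stores the b-vectors as 3 whitespace-separated rows of M
#' columns and the b-values as a single row of M entries. On read, b-vectors
#' paired with a positive b-value are renormalized to unit norm; an all-zero
#' b-vector is accepted (and flagged b0) only when its b-value is 0.
#'
#' @param bvec_path,bval_path file paths.
#' @return [read_gradient_table()]: a `dwi_scheme`.
#' @export
read_gradient_table <- function(bvec_path, bval_path) {
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path, call. = FALSE)
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path, call. = FALSE)
  parse_rows <- function(path, what) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
    for (r in seq_along(rows)) {
      bad <- which(is.na(suppressWarnings(as.numeric(rows[[r]]))))
      if (length(bad))
        stop(sprintf("%s: non-numeric token in row %d, column %d ('%s')",
                     what, r, bad[1], rows[[r]][bad[1]]), call. = FALSE)
    }
    lapply(rows, as.numeric)
  }
  vec_rows <- parse_rows(bvec_path, "bvec")
  val_rows <- parse_rows(bval_path, "bval")
  if (length(vec_rows) != 3L)
    stop(sprintf("bvec: expected 3 rows, found %d", length(vec_rows)), call. = FALSE)
  if (length(val_rows) != 1L)
    stop(sprintf("bval: expected 1 row, found %d", length(val_rows)), call. = FALSE)
  ncols <- vapply(vec_rows, length, 1L)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("bvec: rows have unequal column counts (%s)",
                 paste(ncols, collapse = ", ")), call. = FALSE)
  M <- ncols[1]
  if (length(val_rows[[1]]) != M)
    stop(sprintf("bval has %d entries but bvec has %d columns",
                 length(val_rows[[1]]), M), call. = FALSE)
  acquisition_scheme(do.call(rbind, vec_rows), val_rows[[1]])
}

#' @param scheme a `dwi_scheme`.
#' @rdname read_gradient_table
#' @export
write_gradient_table <- function(scheme, bvec_path, bval_path) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  fmt <- function(x) paste(sprintf("%.10g", x), collapse = " ")
  writeLines(c(fmt(scheme$bvecs[, 1]), fmt(scheme$bvecs[, 2]), fmt(scheme$bvecs[, 3])),
             bvec_path)
  writeLines(fmt(scheme$bvals), bval_path)
  invisible(c(bvec = bvec_path, bval = bval_path))
}

#' Build a single-shell scheme with interleaved b0 images
#'
#' Convenience constructor mirroring a typical single-shell protocol:
#' `n_dirs` diffusion-weighted directions at `bval` with `n_b0` b0 images
#' interleaved evenly among them.
#'
#' @param n_dirs number of diffusion directions.
#' @param bval shell b-value (s/mm^2).
#' @param n_b0 number of interleaved b0 measurements.
#' @param seed seed for direction generation.
#' @return a `dwi_scheme` of `n_dirs + n_b0` measurements.
#' @export
single_shell_scheme <- function(n_dirs = 90L, bval = 1000, n_b0 = 3L, seed = 1L) {
  g <- generate_directions(n_dirs, seed = seed)
  M <- n_dirs + n_b0
  b0_pos <- unique(round(seq(1, M, length.out = n_b0)))
  bvecs <- matrix(0, M, 3)
  bvals <- rep(bval, M)
  bvals[b0_pos] <- 0
  bvecs[setdiff(seq_len(M), b0_pos), ] <- g
  acquisition_scheme(bvecs, bvals)
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
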