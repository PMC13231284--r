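#' Tissue class specification for the digital phantom
#'
#' Each tissue class carries a label id, the diffusion-tensor eigenvalues
#' (mm^2/s, descending), a rule assigning the principal eigenvector per voxel,
#' and the non-diffusion-weighted intensity statistics. The default inventory
#' emulates the contrast of the brain tissue groups relevant for segmentation:
#' anisotropic white matter, two gray-matter classes, free-water CSF in the
#' ventricles, and a cerebellar class.
#'
#' @param label_id positive integer label (0 is background).
#' @param name human-readable class name.
#' @param eigenvalues three positive diffusivities, descending (mm^2/s).
#' @param orientation `"constant"`, `"radial"` (principal eigenvector along
#'   the outward direction from the region centre) or `"tangential"`
#'   (perpendicular to it).
#' @param s0_mean mean b0 intensity (arbitrary units).
#' @param s0_cv coefficient of variation of the per-voxel b0 intensity.
#' @param axis unit 3-vector used when `orientation = "constant"`.
#' @return a `tissue_class_spec` list.
#' @export
tissue_class_spec <- function(label_id, name, eigenvalues,
                              orientation = c("constant", "radial", "tangential"),
                              s0_mean = 1, s0_cv = 0.05, axis = c(0, 0, 1)) {
  orientation <- match.arg(orientation)
  eigenvalues <- as.numeric(eigenvalues)
  if (length(eigenvalues) != 3L || any(eigenvalues <= 0))
    stop("eigenvalues must be 3 strictly positive diffusivities", call. = FALSE)
  if (is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be in descending order", call. = FALSE)
  structure(list(label_id = as.integer(label_id), name = name,
                 eigenvalues = eigenvalues, orientation = orientation,
                 s0_mean = s0_mean, s0_cv = s0_cv,
                 axis = axis / sqrt(sum(axis^2))),
            class = "tissue_class_spec")
}

#' @rdname tissue_class_spec
#' @export
default_tissue_classes <- function() {
  list(
    tissue_class_spec(1L, "white matter", c(1.7e-3, 0.3e-3, 0.3e-3),
                      "radial", s0_mean = 1.0, s0_cv = 0.05),
    tissue_class_spec(2L, "cortical gray matter", c(0.9e-3, 0.75e-3, 0.75e-3),
                      "tangential", s0_mean = 1.3, s0_cv = 0.05),
    tissue_class_spec(3L, "deep gray matter", c(0.75e-3, 0.7e-3, 0.7e-3),
                      "constant", s0_mean = 1.15, s0_cv = 0.05),
    tissue_class_spec(4L, "ventricle CSF", c(3.0e-3, 3.0e-3, 3.0e-3),
                      "constant", s0_mean = 2.2, s0_cv = 0.03),
    tissue_class_spec(5L, "cerebellum", c(0.9e-3, 0.7e-3, 0.7e-3),
                      "tangential", s0_mean = 1.2, s0_cv = 0.05)
  )
}

#' Build a digital anatomical phantom
#'
#' Generates a nested-ellipsoid "brain": an outer cortical ribbon (gray
#' matter) around a white-matter interior, a central ventricle cavity (CSF),
#' two deep-nuclei blobs, and an inferior-posterior cerebellar lobule. The
#' geometry is jittered per seed so that phantoms play the role of distinct
#' participants. Per-voxel diffusion tensors are assembled from the class
#' eigenvalues and orientation rule; the brain mask is the union of
#' non-background labels, dilated twice and hole-filled.
#'
#' @param shape integer 3-vector, each entry >= 32.
#' @param classes list of [tissue_class_spec()]; at least three classes with
#'   unique label ids.
#' @param seed integer seed (deterministic output).
#' @param spacing isotropic voxel size (mm).
#' @return a `dwi_phantom`: list with `labels` (W x H x D integer),
#'   `tensors` (W x H x D x 6, order xx,xy,xz,yy,yz,zz, mm^2/s), `s0`,
#'   `mask` (logical), `spacing`, `classes`.
#' @export
build_phantom <- function(shape = c(64L, 64L, 64L),
                          classes = default_tissue_classes(),
                          seed = 1L, spacing = 1.0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("`shape` must be a 3-vector with every axis >= 32", call. = FALSE)
  if (length(classes) < 3L)
    stop("at least 3 tissue classes are required", call. = FALSE)
  ids <- vapply(classes, function(cl) cl$label_id, 1L)
  if (anyDuplicated(ids))
    stop("overlapping label specification: duplicate label ids ",
         paste(ids[duplicated(ids)], collapse = ", "), call. = FALSE)
  if (any(ids <= 0L)) stop("label ids must be positive (0 is background)", call. = FALSE)
  cls <- stats::setNames(classes, as.character(ids))
  need <- c("1", "2", "3", "4", "5")
  if (!all(need %in% names(cls)))
    stop("default geometry requires classes with label ids 1..5", call. = FALSE)

  with_seed(seed, {
    jit <- function(x, frac = 0.05) x * (1 + stats::runif(length(x), -frac, frac))
    W <- shape[1]; H <- shape[2]; D <- shape[3]
    ctr <- jit(shape / 2, 0.03)
    ax <- jit(0.40 * shape, 0.05)            # brain semi-axes
    xs <- seq_len(W); ys <- seq_len(H); zs <- seq_len(D)
    X <- array(rep(xs, times = H * D), shape)
    Y <- array(rep(rep(ys, each = W), times = D), shape)
    Z <- array(rep(zs, each = W * H), shape)
    # normalized ellipsoidal radius of the brain
    rho <- sqrt(((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
                ((Z - ctr[3]) / ax[3])^2)
    ribbon <- jit(0.18, 0.1)
    labels <- array(0L, shape)
    labels[rho <= 1] <- 2L                   # cortical ribbon (outer shell)
    labels[rho <= 1 - ribbon] <- 1L          # white-matter interior
    # cerebellum: inferior-posterior lobule
    cctr <- ctr + c(0, jit(0.28, 0.1), -jit(0.30, 0.1)) * shape
    cax <- jit(c(0.20, 0.14, 0.12) * shape, 0.05)
    rho_c <- sqrt(((X - cctr[1]) / cax[1])^2 + ((Y - cctr[2]) / cax[2])^2 +
                  ((Z - cctr[3]) / cax[3])^2)
    labels[rho_c <= 1] <- 5L
    # ventricles: central cavity
    vctr <- ctr + jit(c(0, -0.02, 0.05), 0.3) * shape
    vax <- jit(c(0.10, 0.16, 0.10) * shape, 0.08)
    rho_v <- sqrt(((X - vctr[1]) / vax[1])^2 + ((Y - vctr[2]) / vax[2])^2 +
                  ((Z - vctr[3]) / vax[3])^2)
    labels[rho_v <= 1] <- 4L
    # deep nuclei: lateral blobs beside the ventricles
    for (sgn in c(-1, 1)) {
      nctr <- ctr + jit(c(sgn * 0.20, 0.02, 0.02), 0.15) * shape
      nax <- jit(c(0.085, 0.11, 0.085) * shape, 0.08)
      rho_n <- sqrt(((X - nctr[1]) / nax[1])^2 + ((Y - nctr[2]) / nax[2])^2 +
                    ((Z - nctr[3]) / nax[3])^2)
      labels[rho_n <= 1 & labels == 1L] <- 3L
    }

    mask <- fill_holes(dilate6(dilate6(labels != 0L)))

    # per-voxel principal direction by class orientation rule
    idx <- which(labels != 0L)
    lab_v <- labels[idx]
    rx <- X[idx] - ctr[1]; ry <- Y[idx] - ctr[2]; rz <- Z[idx] - ctr[3]
    rn <- pmax(sqrt(rx^2 + ry^2 + rz^2), 1e-9)
    rx <- rx / rn; ry <- ry / rn; rz <- rz / rn
    e1 <- matrix(0, length(idx), 3)
    for (id in ids) {
      sel <- lab_v == id
      if (!any(sel)) next
      cl <- cls[[as.character(id)]]
      if (cl$orientation == "constant") {
        e1[sel, ] <- matrix(cl$axis, sum(sel), 3, byrow = TRUE)
      } else if (cl$orientation == "radial") {
        e1[sel, ] <- cbind(rx[sel], ry[sel], rz[sel])
      } else {                                # tangential: radial x z (fallback x)
        tx <- ry[sel]; ty <- -rx[sel]; tz <- rep(0, sum(sel))
        deg <- tx^2 + ty^2 < 1e-12
        tx[deg] <- 1; ty[deg] <- 0
        tn <- sqrt(tx^2 + ty^2 + tz^2)
        e1[sel, ] <- cbind(tx / tn, ty / tn, tz / tn)
      }
    }
    lam <- t(vapply(cls[as.character(lab_v)], function(cl) cl$eigenvalues,
                    numeric(3)))
    # lambda2 == lambda3 for all shipped classes: D = l3 I + (l1 - l3) e1 e1'
    if (any(abs(lam[, 2] - lam[, 3]) > 1e-15))
      stop("phantom tensors require lambda2 == lambda3 (axially symmetric classes)",
           call. = FALSE)
    tensors <- array(0, c(shape, 6L))
    dl <- lam[, 1] - lam[, 3]
    put <- function(k, vals) {
      sl <- array(0, shape); sl[idx] <- vals
      tensors[, , , k] <<- sl
    }
    put(1L, lam[, 3] + dl * e1[, 1]^2)        # xx
    put(2L, dl * e1[, 1] * e1[, 2])           # xy
    put(3L, dl * e1[, 1] * e1[, 3])           # xz
    put(4L, lam[, 3] + dl * e1[, 2]^2)        # yy
    put(5L, dl * e1[, 2] * e1[, 3])           # yz
    put(6L, lam[, 3] + dl * e1[, 3]^2)        # zz

    s0 <- array(0, shape)
    mu <- vapply(cls[as.character(lab_v)], function(cl) cl$s0_mean, 1)
    cv <- vapply(cls[as.character(lab_v)], function(cl) cl$s0_cv, 1)
    s0[idx] <- pmax(mu * (1 + cv * stats::rnorm(length(idx))), 0.05)

    structure(list(labels = labels, tensors = tensors, s0 = s0, mask = mask,
                   spacing = spacing, classes = classes, seed = seed),
              class = "dwi_phantom")
  })
}

#' @export
print.dwi_phantom <- function(x, ...) {
  cat(sprintf("<dwi_phantom> %s voxels, %d tissue classes, %d in mask\n",
              paste(dim(x$labels), collapse = "x"), length(x$classes),
              sum(x$mask)))
  invisible(x)
}

# 6-connected binary dilation
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# fill interior cavities: background connected to the volume border stays
# background, everything else becomes foreground
fill_holes <- function(m) {
  d <- dim(m)
  outside <- array(FALSE, d)
  border <- !m
  outside[1, , ] <- border[1, , ]; outside[d[1], , ] <- border[d[1], , ]
  outside[, 1, ] <- outside[, 1, ] | border[, 1, ]
  outside[, d[2], ] <- outside[, d[2], ] | border[, d[2], ]
  outside[, , 1] <- outside[, , 1] | border[, , 1]
  outside[, , d[3]] <- outside[, , d[3]] | border[, , d[3]]
  repeat {
    grown <- dilate6(outside) & border
    if (sum(grown) == sum(outside)) break
    outside <- grown
  }
  !outside
}

#' Diffusion tensor signal
#'
#' Closed-form single-tensor forward model `S = S0 * exp(-b * g' D g)`.
#'
#' @param D symmetric 3 x 3 tensor (mm^2/s), or a length-6 vector in the
#'   package order (xx, xy, xz, yy, yz, zz).
#' @param b b-value (s/mm^2), non-negative.
#' @param g direction 3-vector; must have unit norm when `b > 0`.
#' @param S0 non-diffusion-weighted intensity.
#' @return signal intensity.
#' @export
tensor_signal <- function(D, b, g, S0 = 1) {
  if (b < 0) stop("negative b-value", call. = FALSE)
  if (length(D) == 6L) {
    D <- matrix(c(D[1], D[2], D[3], D[2], D[4], D[5], D[3], D[5], D[6]), 3, 3)
  }
  if (b > 0 && abs(sum(g^2) - 1) > 1e-6)
    stop("`g` must be a unit vector when b > 0", call. = FALSE)
  S0 * exp(-b * drop(crossprod(g, D %*% g)))
}

# vectorized over a (... x 6) tensor field; returns array of signals
tensor_signal_field <- function(tensors6, b, g, s0) {
  if (b == 0) return(s0 + 0)
  dd <- dim(tensors6)
  k <- length(dd)
  tf <- matrix(tensors6, ncol = 6L)
  q <- tf[, 1] * g[1]^2 + tf[, 4] * g[2]^2 + tf[, 6] * g[3]^2 +
       2 * (tf[, 2] * g[1] * g[2] + tf[, 3] * g[1] * g[3] + tf[, 5] * g[2] * g[3])
  array(as.vector(s0) * exp(-b * q), dd[-k])
}

#' Fractional anisotropy of a tensor field
#'
#' Computed from rotational invariants (no eigendecomposition):
#' `FA = sqrt(3/2 * (tr(D^2) - tr(D)^2 / 3) / tr(D^2))`.
#'
#' @param tensors6 array with trailing dimension 6 (xx, xy, xz, yy, yz, zz),
#'   or a length-6 vector.
#' @return array of FA values (0 where the tensor is zero).
#' @export
fractional_anisotropy <- function(tensors6) {
  if (is.null(dim(tensors6))) dim(tensors6) <- c(1L, 6L)
  dd <- dim(tensors6)
  tf <- matrix(tensors6, ncol = 6L)
  tr <- tf[, 1] + tf[, 4] + tf[, 6]
  tr2 <- tf[, 1]^2 + tf[, 4]^2 + tf[, 6]^2 +
         2 * (tf[, 2]^2 + tf[, 3]^2 + tf[, 5]^2)
  num <- pmax(tr2 - tr^2 / 3, 0)
  fa <- sqrt(1.5 * num / pmax(tr2, 1e-300))
  fa[tr2 == 0] <- 0
  if (length(dd) > 2L) array(fa, dd[-length(dd)]) else as.vector(fa)
}

#' Simulate a diffusion-weighted acquisition of a phantom
#'
#' Evaluates the tensor forward model for every voxel and measurement of the
#' scheme, then corrupts each signal with Rician noise of scale
#' `noise_sigma` (magnitude of two independent Gaussian channels). Outside
#' the head (`s0 = 0`) this produces pure Rayleigh noise. The mean b0 volume
#' is the voxel-wise mean over the scheme's (noisy) b0 measurements.
#'
#' @param phantom a [build_phantom()] result.
#' @param scheme a `dwi_scheme`; must contain at least one b0 entry (the
#'   mean b0 image is required downstream).
#' @param noise_sigma Rician scale in signal units; default
#'   `mean(in-mask s0) / snr`.
#' @param snr signal-to-noise ratio used when `noise_sigma` is `NULL`.
#' @param seed integer seed; the simulation is bit-reproducible given seed.
#' @return a `dwi_volume`: list with `data` (W x H x D x M), `scheme`,
#'   `mean_b0`, `noise_sigma`, `spacing`.
#' @export
simulate_acquisition <- function(phantom, scheme, noise_sigma = NULL,
                                 snr = 25, seed = 1L) {
  stopifnot(inherits(phantom, "dwi_phantom"), inherits(scheme, "dwi_scheme"))
  if (!any(scheme$is_b0))
    stop("scheme has no b0 entry; a mean b0 image is required downstream",
         call. = FALSE)
  if (is.null(noise_sigma))
    noise_sigma <- mean(phantom$s0[phantom$mask & phantom$s0 > 0]) / snr
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  shape <- dim(phantom$labels)
  M <- scheme$M
  data <- array(0, c(shape, M))
  with_seed(seed, {
    n_vox <- prod(shape)
    for (m in seq_len(M)) {
      s <- tensor_signal_field(phantom$tensors, scheme$bvals[m],
                               scheme$bvecs[m, ], phantom$s0)
      if (noise_sigma > 0) {
        s <- sqrt((s + stats::rnorm(n_vox, sd = noise_sigma))^2 +
                  stats::rnorm(n_vox, sd = noise_sigma)^2)
      }
      data[, , , m] <- s
    }
  })
  b0_idx <- which(scheme$is_b0)
  mean_b0 <- array(0, shape)
  for (m in b0_idx) mean_b0 <- mean_b0 + data[, , , m]
  mean_b0 <- mean_b0 / length(b0_idx)
  structure(list(data = data, scheme = scheme, mean_b0 = mean_b0,
                 noise_sigma = noise_sigma, spacing = phantom$spacing),
            class = "dwi_volume")
}
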