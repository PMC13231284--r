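#' Merge labels before metric computation
#'
#' Voxel-wise relabeling with a total map from source label ids to merged
#' ids. The map must cover every label present; it is applied identically to
#' prediction and reference (callers do both). Applying the result of a merge
#' a second time is a no-op as long as the map is idempotent over its own
#' range (e.g. a map sending 8 -> 7 and 7 -> 7).
#'
#' @param seg integer label array.
#' @param merge_map named integer vector or two-column data.frame: source
#'   label id -> merged label id.
#' @return relabeled array, same shape.
#' @export
merge_labels <- function(seg, merge_map) {
  if (is.data.frame(merge_map))
    merge_map <- stats::setNames(merge_map[[2]], merge_map[[1]])
  src <- as.integer(names(merge_map))
  dst <- as.integer(merge_map)
  present <- sort(unique(as.vector(seg)))
  missing <- setdiff(present, src)
  if (length(missing))
    stop("mapping error: label(s) not covered by the merge map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lut <- integer(max(src) + 1L)
  lut[src + 1L] <- dst
  array(lut[as.vector(seg) + 1L], dim(seg))
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)`. Two empty masks agree perfectly on absence and
#' score 1 (the `both_empty` attribute flags this case).
#'
#' @param pred_mask,ref_mask logical arrays of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask), dim(ref_mask)))
    stop("shape mismatch between prediction and reference masks", call. = FALSE)
  a <- sum(pred_mask); b <- sum(ref_mask)
  if (a + b == 0) return(structure(1.0, both_empty = TRUE))
  2 * sum(pred_mask & ref_mask) / (a + b)
}

# face-connectivity boundary voxels of a mask: in-mask voxels with at least
# one of the 6 neighbors outside (volume border counts as outside)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  # neighbor-in-mask indicators with FALSE padding
  all6 <- array(TRUE, d)
  shift_and <- function(acc, dimi, dir) {
    m <- array(FALSE, d)
    if (dimi == 1L) {
      if (dir > 0) m[-d[1], , ] <- mask[-1, , ] else m[-1, , ] <- mask[-d[1], , ]
    } else if (dimi == 2L) {
      if (dir > 0) m[, -d[2], ] <- mask[, -1, ] else m[, -1, ] <- mask[, -d[2], ]
    } else {
      if (dir > 0) m[, , -d[3]] <- mask[, , -1] else m[, , -1] <- mask[, , -d[3]]
    }
    acc & m
  }
  for (dimi in 1:3) for (dir in c(-1, 1)) all6 <- shift_and(all6, dimi, dir)
  mask & !all6
}

#' 99th percentile Hausdorff distance
#'
#' Boundary surfaces of both masks are extracted as face-connectivity
#' boundary voxel centers; for every boundary point of A the distance (mm) to
#' the nearest boundary point of B is computed and vice versa; the two
#' directed distance multisets are pooled and the requested percentile
#' (linear-interpolation convention, `quantile` type 7) is returned.
#'
#' @param pred_mask,ref_mask logical arrays of equal shape; both non-empty
#'   (an empty mask yields an undefined metric: `NA` with attribute
#'   `undefined`, the missing-region case excluded from group means).
#' @param spacing_mm voxel spacing (scalar or per-axis).
#' @param percentile percentile of the pooled distances (default 99).
#' @return distance in mm, or flagged `NA` when undefined.
#' @export
hd99 <- function(pred_mask, ref_mask, spacing_mm = 1, percentile = 99) {
  if (!identical(dim(pred_mask), dim(ref_mask)))
    stop("shape mismatch between prediction and reference masks", call. = FALSE)
  if (sum(pred_mask) == 0L || sum(ref_mask) == 0L)
    return(structure(NA_real_, undefined = TRUE))
  sp <- rep_len(as.numeric(spacing_mm), 3L)
  pts <- function(mask) {
    idx <- which(boundary_voxels(mask), arr.ind = TRUE)
    cbind(idx[, 1] * sp[1], idx[, 2] * sp[2], idx[, 3] * sp[3])
  }
  a <- pts(pred_mask); b <- pts(ref_mask)
  d <- c(nearest_distances(a, b), nearest_distances(b, a))
  unname(stats::quantile(d, percentile / 100, type = 7))
}

#' Aggregate metric records into per-group averages
#'
#' Arithmetic mean over a group's regions, per participant and metric.
#' Undefined entries (`NA` values, e.g. HD99 for empty regions) are excluded
#' from that participant's group mean and counted in `n_excluded`.
#'
#' @param records data.frame with columns `participant`, `region`, `metric`,
#'   `value`.
#' @param group_map named character vector: region id -> group name; every
#'   evaluated region must belong to exactly one group.
#' @return data.frame with `participant`, `group`, `metric`, `value`,
#'   `n_regions`, `n_excluded`.
#' @export
group_metrics <- function(records, group_map) {
  if (length(group_map) == 0L) stop("empty group map", call. = FALSE)
  regs <- unique(records$region)
  missing <- setdiff(as.character(regs), names(group_map))
  if (length(missing))
    stop("configuration error: region(s) without group: ",
         paste(missing, collapse = ", "), call. = FALSE)
  records$group <- unname(group_map[as.character(records$region)])
  sp <- split(records, list(records$participant, records$group,
                            records$metric), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(df) {
    ok <- !is.na(df$value)
    data.frame(participant = df$participant[1], group = df$group[1],
               metric = df$metric[1],
               value = if (any(ok)) mean(df$value[ok]) else NA_real_,
               n_regions = nrow(df), n_excluded = sum(!ok))
  }))
  rownames(out) <- NULL
  out
}

#' One-sided Wilcoxon signed-rank test
#'
#' Paired test on `x - y` differences (or on pre-computed differences):
#' zero differences are dropped, ties receive midranks, and the one-sided
#' p-value for the alternative "differences are positive" (`"greater"`) or
#' negative (`"less"`) is computed by exact enumeration of the signed-rank
#' null for `n <= 25` (dynamic program over the 2^n sign assignments) and by
#' the normal approximation with continuity and tie correction above.
#'
#' @param diffs numeric vector of paired differences.
#' @param alternative `"greater"` (e.g. Dice of method A exceeds B) or
#'   `"less"` (e.g. HD99 of A below B).
#' @param exact_max largest n for which the exact null is enumerated.
#' @return list with `p.value`, `statistic` (W+, the positive-rank sum),
#'   `n` (nonzero pairs), `exact`.
#' @export
wilcoxon_one_sided <- function(diffs, alternative = c("greater", "less"),
                               exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L)
    stop("undefined test: all differences are zero", call. = FALSE)
  if (alternative == "less") d <- -d
  r <- rank(abs(d))                      # midranks for ties
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: each rank contributes to W+ with prob 1/2 independently.
    # work in doubled-rank integers so midranks (k + 0.5) stay integral.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- numeric(total + 1L)           # counts of achievable 2*W+ values
    cnt[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), cnt[seq_len(total + 1L - rr)])
      cnt <- cnt + shifted
    }
    w2 <- round(2 * w_pos)
    p <- sum(cnt[(w2 + 1L):(total + 1L)]) / 2^n
    list(p.value = p, statistic = w_pos, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu - 0.5) / sqrt(sigma2)
    list(p.value = stats::pnorm(z, lower.tail = FALSE), statistic = w_pos,
         n = n, exact = FALSE)
  }
}

#' Render a p-value as a significance marker
#'
#' `***` if p < 0.001, `**` if 0.001 <= p < 0.01, `*` if 0.01 <= p < 0.05,
#' `"n.s."` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of markers.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "n.s."), right = FALSE) |> as.character()
}

#' Evaluate a predicted segmentation against a reference
#'
#' Computes DSC and HD99 per region (after optional label merging) and
#' returns tidy metric records.
#'
#' @param pred,ref integer label volumes.
#' @param spacing_mm voxel spacing.
#' @param participant participant identifier for the records.
#' @param merge_map optional label merge map applied to both volumes.
#' @param regions region ids to evaluate (default: all non-zero reference
#'   labels after merging).
#' @return data.frame with `participant`, `region`, `metric`, `value`.
#' @export
evaluate_segmentation <- function(pred, ref, spacing_mm = 1,
                                  participant = "p1", merge_map = NULL,
                                  regions = NULL) {
  if (!is.null(merge_map)) {
    pred <- merge_labels(pred, merge_map)
    ref <- merge_labels(ref, merge_map)
  }
  if (is.null(regions)) regions <- setdiff(sort(unique(as.vector(ref))), 0L)
  recs <- lapply(regions, function(rg) {
    pm <- pred == rg; rm <- ref == rg
    dsc <- as.numeric(dice(pm, rm))
    hd <- as.numeric(hd99(pm, rm, spacing_mm))
    data.frame(participant = participant, region = rg,
               metric = c("DSC", "HD99"), value = c(dsc, hd))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
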