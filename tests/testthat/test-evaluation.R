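test_that("merge_labels relabels, conserves counts, and is idempotent", {
  set.seed(1)
  seg <- array(sample(c(0L, 7L, 8L), 60, replace = TRUE, prob = c(.6, .3, .1)),
               c(5, 4, 3))
  idm <- stats::setNames(c(0L, 7L, 8L), c(0, 7, 8))
  expect_identical(merge_labels(seg, idm), seg)
  mm <- stats::setNames(c(0L, 7L, 7L), c(0, 7, 8))
  merged <- merge_labels(seg, mm)
  expect_equal(sum(merged == 7L), sum(seg %in% c(7L, 8L)))
  expect_identical(merge_labels(merged, mm), merged)
  expect_error(merge_labels(seg, stats::setNames(0L, 0)), "not covered.*7")
})

test_that("dice matches brute-force enumeration", {
  a <- array(FALSE, c(4, 4, 1)); b <- a
  a[1:2, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1.0)
  b[3:4, 4, 1] <- TRUE
  expect_equal(dice(a, b), 0.0)
  # |A| = 4, |B| = 6, |A n B| = 3
  a <- array(FALSE, c(4, 4, 1)); b <- a
  a[1:4, 1, 1] <- TRUE
  b[2:4, 1, 1] <- TRUE; b[1:3, 2, 1] <- TRUE
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))
  expect_error(dice(a, array(FALSE, c(3, 4, 1))), "shape")
  both <- dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2)))
  expect_equal(as.numeric(both), 1.0)
  expect_true(attr(both, "both_empty"))
})

test_that("hd99 matches the brute-force oracle on random masks", {
  # two single-voxel masks 3 voxels apart
  a <- array(FALSE, c(8, 8, 8)); b <- a
  a[2, 2, 2] <- TRUE; b[5, 2, 2] <- TRUE
  expect_equal(hd99(a, b, 1), 3.0)
  expect_equal(hd99(a, b, 2), 6.0)          # spacing scales distances
  expect_equal(hd99(a, a, 1), 0.0)
  expect_true(attr(hd99(a, array(FALSE, c(8, 8, 8))), "undefined"))

  # percentile convention pinned to sort-and-interpolate (quantile type 7):
  # with 199 zeros and a single 10, the 99th percentile index (1 + 199*0.99 =
  # 198.01) falls among the zeros, so the pooled HD99 is 0 by construction
  d <- c(rep(0, 199), 10)
  expect_equal(unname(stats::quantile(d, 0.99, type = 7)), 0)
  a <- array(FALSE, c(8, 8, 8)); a[2:7, 2:7, 2:7] <- TRUE
  b <- a; b[7, 7, 7] <- FALSE
  expect_equal(hd99(a, b, 1, percentile = 99),
               unname(stats::quantile(hd_pool_oracle(a, b, 1), 0.99, type = 7)),
               tolerance = 1e-12)

  # brute-force oracle on random masks (subset of the acceptance sweep)
  brute_hd <- function(a, b, sp, p = 99) {
    pts <- function(m) {
      idx <- which(m, arr.ind = TRUE)
      keep <- logical(nrow(idx))
      d <- dim(m)
      for (r in seq_len(nrow(idx))) {
        v <- idx[r, ]
        nb <- rbind(v + c(1, 0, 0), v - c(1, 0, 0), v + c(0, 1, 0),
                    v - c(0, 1, 0), v + c(0, 0, 1), v - c(0, 0, 1))
        out <- apply(nb, 1, function(u)
          any(u < 1 | u > d) || !m[u[1], u[2], u[3]])
        keep[r] <- any(out)
      }
      idx[keep, , drop = FALSE] * sp
    }
    pa <- pts(a); pb <- pts(b)
    dists <- function(x, y) apply(x, 1, function(v)
      sqrt(min(colSums((t(y) - v)^2))))
    unname(stats::quantile(c(dists(pa, pb), dists(pb, pa)), p / 100, type = 7))
  }
  set.seed(5)
  for (i in 1:5) {
    a <- array(FALSE, c(10, 10, 10)); b <- a
    a[sample(1000, 60)] <- TRUE; b[sample(1000, 60)] <- TRUE
    expect_equal(hd99(a, b, 1.5), brute_hd(a, b, 1.5), tolerance = 1e-9)
    expect_equal(hd99(a, b, 1.5), hd99(b, a, 1.5), tolerance = 1e-12)
  }
})

test_that("group_metrics averages regions and excludes undefined entries", {
  gm <- c(`1` = "wm", `2` = "gm", `3` = "gm")
  recs <- data.frame(participant = "p1", region = c(1, 2, 3),
                     metric = "DSC", value = c(0.9, 0.8, 0.7))
  out <- group_metrics(recs, gm)
  expect_equal(out$value[out$group == "gm"], 0.75)
  expect_equal(out$value[out$group == "wm"], 0.9)
  # single-region group equals the region value
  expect_equal(out$n_regions[out$group == "wm"], 1)
  # undefined exclusion
  recs2 <- data.frame(participant = "p1", region = c(1, 2, 3), metric = "HD99",
                      value = c(2, NA, 4))
  gm2 <- c(`1` = "g", `2` = "g", `3` = "g")
  out2 <- group_metrics(recs2, gm2)
  expect_equal(out2$value, 3)
  expect_equal(out2$n_excluded, 1)
  expect_error(group_metrics(recs, c(`1` = "wm")), "without group")
})

test_that("wilcoxon_one_sided matches exact enumeration", {
  # all-positive n = 6: p = 1/64
  expect_equal(wilcoxon_one_sided(c(1, 2, 3, 4, 5, 6))$p.value, 1 / 64)
  # symmetric pair: W+ takes values {0, 1.5, 1.5, 3} over the 4 sign
  # assignments, so P(W+ >= 1.5) = 3/4 under the standard >= convention
  expect_equal(wilcoxon_one_sided(c(1, -1))$p.value, 0.75)
  expect_error(wilcoxon_one_sided(c(0, 0)), "all differences")
  # direction convention
  expect_equal(wilcoxon_one_sided(-(1:6), alternative = "less")$p.value, 1 / 64)
  # full enumeration oracle for random patterns (incl. ties), n <= 10
  enum_p <- function(d) {
    d <- d[d != 0]; n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    mean(w_all >= w_obs - 1e-9)
  }
  set.seed(42)
  for (i in 1:8) {
    n <- sample(3:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)
    expect_equal(wilcoxon_one_sided(d)$p.value, enum_p(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
})

test_that("significance markers follow the star convention", {
  expect_equal(significance_stars(c(0.0005, 0.03, 0.2, 0.005)),
               c("***", "*", "n.s.", "**"))
})

test_that("evaluate_segmentation produces tidy records", {
  set.seed(2)
  ref <- array(0L, c(12, 12, 12))
  ref[3:9, 3:9, 3:9] <- 1L
  ref[5:7, 5:7, 5:7] <- 2L
  pred <- ref
  pred[3, 3, 3] <- 0L                        # small perturbation
  recs <- evaluate_segmentation(pred, ref, spacing_mm = 1, participant = "x")
  expect_setequal(recs$metric, c("DSC", "HD99"))
  expect_true(all(recs$value[recs$metric == "DSC"] > 0.9))
  expect_equal(recs$value[recs$region == 2 & recs$metric == "HD99"], 0)
})
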