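test_that("acquisition_scheme validates and normalizes", {
  g <- matrix(c(2, 0, 0, 0, 3, 0), 2, 3, byrow = TRUE)
  sch <- acquisition_scheme(g, c(1000, 1000))
  expect_equal(sqrt(rowSums(sch$bvecs^2)), c(1, 1), tolerance = 1e-12)
  expect_error(acquisition_scheme(g, c(1000, 1000, 1000)), "lengths differ")
  expect_error(acquisition_scheme(matrix(0, 1, 3), 1000), "zero b-vector")
  # b0 with zero vector is fine and flagged
  sch0 <- acquisition_scheme(rbind(c(0, 0, 0), c(0, 0, 1)), c(0, 1000))
  expect_identical(sch0$is_b0, c(TRUE, FALSE))
})

test_that("generate_directions minimizes the antipodal energy", {
  expect_error(generate_directions(0), "positive")
  g1 <- generate_directions(1, seed = 3)
  expect_equal(sum(g1^2), 1, tolerance = 1e-12)
  # n = 2: perpendicular pairs minimize the energy (checked against a fine
  # angular grid oracle: energy(theta) = 1/(2 sin(t/2)) + 1/(2 cos(t/2)))
  thetas <- seq(0.01, pi / 2, length.out = 2000)
  e_grid <- 1 / (2 * sin(thetas / 2)) + 1 / (2 * cos(thetas / 2))
  expect_equal(thetas[which.min(e_grid)], pi / 2, tolerance = 1e-2)
  g2 <- generate_directions(2, seed = 5)
  expect_lt(abs(sum(g2[1, ] * g2[2, ])), 0.05)
  # n = 6: two seeds give energies within 1%
  e <- vapply(c(1, 99), function(s)
    coverage_energy(generate_directions(6, seed = s)), 1)
  expect_lt(abs(e[1] - e[2]) / e[1], 0.01)
})

test_that("coverage energy is antipodally symmetric", {
  g <- generate_directions(8, seed = 2)
  e0 <- coverage_energy(g)
  set.seed(1)
  for (i in 1:5) {
    flip <- sample(c(-1, 1), 8, replace = TRUE)
    expect_equal(coverage_energy(g * flip), e0, tolerance = 1e-9)
  }
})

test_that("subsample_max_coverage selects well-spread subsets", {
  sch <- single_shell_scheme(90, 1000, 3, seed = 1)
  dwi_idx <- which(!sch$is_b0)
  expect_identical(subsample_max_coverage(sch, 90), dwi_idx)
  expect_error(subsample_max_coverage(sch, 91), "must be in")
  for (k in c(10L, 30L)) {
    sub <- subsample_max_coverage(sch, k)
    expect_length(sub, k)
    expect_true(all(sub %in% dwi_idx))
    expect_identical(sub, sort(sub))
  }
  # random-subset oracle: selected 10-subset beats 1000 random 10-subsets
  sub10 <- subsample_max_coverage(sch, 10)
  e_sel <- coverage_energy(sch$bvecs[sub10, ])
  set.seed(123)
  e_rand <- replicate(1000, coverage_energy(
    sch$bvecs[sample(dwi_idx, 10), ]))
  expect_lte(e_sel, min(e_rand))
  # deterministic
  expect_identical(sub10, subsample_max_coverage(sch, 10))
})

test_that("sample_rotation is a Haar-uniform rotation", {
  for (s in c(1L, 17L, 123L)) {
    R <- sample_rotation(s)
    expect_equal(R %*% t(R), diag(3), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    # closure under composition
    R2 <- R %*% sample_rotation(s + 1L)
    expect_equal(R2 %*% t(R2), diag(3), tolerance = 1e-9)
  }
  # isometry on a gradient table
  sch <- single_shell_scheme(20, 1000, 1, seed = 2)
  R <- sample_rotation(9)
  G <- sch$bvecs %*% t(R)
  expect_equal(tcrossprod(G), tcrossprod(sch$bvecs), tolerance = 1e-10)
  # Monte-Carlo mean of R e1 is near zero (uniformity over SO(3))
  m <- rowMeans(vapply(1:10000, function(s) sample_rotation(s)[, 1],
                       numeric(3)))
  expect_true(all(abs(m) < 0.05))
})

test_that("gradient table round-trips in the FSL dialect", {
  sch <- single_shell_scheme(90, 1000, 3, seed = 4)
  bvec <- withr::local_tempfile()
  bval <- withr::local_tempfile()
  write_gradient_table(sch, bvec, bval)
  back <- read_gradient_table(bvec, bval)
  expect_equal(back$bvecs, sch$bvecs, tolerance = 1e-6)
  expect_equal(back$bvals, sch$bvals, tolerance = 1e-6)
  # mismatched column counts
  writeLines(c("1 0", "0 1", "0 0"), bvec)
  writeLines("1000 1000 1000", bval)
  expect_error(read_gradient_table(bvec, bval), "3 columns|2 columns")
  # non-numeric token is named
  writeLines(c("1 x", "0 1", "0 0"), bvec)
  writeLines("1000 1000", bval)
  expect_error(read_gradient_table(bvec, bval), "row 1, column 2")
})

test_that("subset coverage energy is non-increasing in exchange sweeps", {
  sch <- single_shell_scheme(40, 1000, 1, seed = 6)
  e_prev <- Inf
  for (sw in c(0L, 1L, 5L, 200L)) {
    sub <- subsample_max_coverage(sch, 12, max_sweeps = sw)
    e <- coverage_energy(sch$bvecs[sub, ])
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
})
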