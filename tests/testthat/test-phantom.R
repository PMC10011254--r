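small_spec <- function(...) {
  phantom_spec(shape = c(24, 48, 48), volume_cm3 = 8, seed = 7, ...)
}

test_that("phantom generation is reproducible and partitions levels", {
  spec <- small_spec()
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(unclass(a$activity), unclass(b$activity))
  expect_identical(a$gt_static, b$gt_static)

  n <- sum(a$gt_static)
  counts <- vapply(a$level_masks, sum, 0L)
  expect_equal(sum(counts), n)
  expect_true(all(abs(counts - n / 3) <= 1))
  # level masks partition the ground truth
  expect_false(any(a$level_masks[[1]] & a$level_masks[[2]]))
  expect_false(any(a$level_masks[[2]] & a$level_masks[[3]]))
  expect_true(all(a$gt_static == (a$level_masks[[1]] | a$level_masks[[2]] |
                                    a$level_masks[[3]])))
  # lesion activities are the three kinetic ratios, background is 1
  vals <- sort(unique(as.numeric(a$activity)))
  expect_equal(length(vals), 4L)
  expect_equal(vals[1], 1)
})

test_that("degenerate level fractions give a homogeneous lesion", {
  spec <- small_spec(level_fractions = c(1, 0, 0))
  a <- build_phantom(spec)
  lesion_vals <- unique(a$activity[a$gt_static])
  expect_equal(length(lesion_vals), 1L)
  p <- fdg_tissue_params()
  expect_equal(lesion_vals,
               uptake_ratios(p["level1"], p$lung), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a lesion larger than the grid is rejected", {
  expect_error(phantom_spec(shape = c(16, 24, 24), volume_cm3 = 500),
               "does not fit")
})

test_that("motion averaging conserves activity and grows the GT union", {
  spec <- small_spec()
  a <- build_phantom(spec)
  b <- apply_motion(a, spec)
  # bin-3 reference: static mask is contained in the union, which is larger
  expect_true(all(b$gt_motion[a$gt_static]))
  expect_gt(sum(b$gt_motion), sum(a$gt_static))
  # rigid whole-voxel shifts conserve total activity to well under 0.1%
  expect_equal(sum(b$activity), sum(a$activity), tolerance = 1e-3)

  # zero amplitudes: no-op
  spec0 <- small_spec(diaphragm_cm = 0, ap_cm = 0)
  a0 <- build_phantom(spec0)
  b0 <- apply_motion(a0, spec0)
  expect_identical(unclass(a0$activity), unclass(b0$activity))
  expect_identical(b0$gt_motion, a0$gt_static)
})

test_that("degradation is seeded, non-negative, and mean-preserving", {
  spec <- small_spec()
  a <- build_phantom(spec)
  d1 <- degrade(a$activity, spec, seed = 11)
  d2 <- degrade(a$activity, spec, seed = 11)
  d3 <- degrade(a$activity, spec, seed = 12)
  expect_identical(unclass(d1), unclass(d2))
  expect_false(identical(unclass(d1), unclass(d3)))
  expect_true(all(d1 >= 0))
  expect_error(degrade(voxel_volume(array(-1, c(4, 4, 4))), spec),
               "non-negative")

  # Monte-Carlo unbiasedness on a uniform region: the mean over noise
  # realizations recovers the noise-free value within 3 standard errors
  u <- voxel_volume(array(5, c(10, 10, 10)), spacing = c(0.5, 0.41, 0.41))
  nrep <- 200
  ms <- vapply(seq_len(nrep), function(i)
    mean(degrade(u, spec, seed = 1000 + i)), numeric(1))
  se <- stats::sd(ms) / sqrt(nrep)
  expect_lt(abs(mean(ms) - 5), 3 * se + 1e-9)
})

test_that("initial-mask generation contains GT and behaves as documented", {
  # single voxel, margin 3: a 7x7x7 box away from borders
  gt <- array(FALSE, c(15, 15, 15))
  gt[8, 8, 8] <- TRUE
  m <- gen_masks(gt, seed = 1, margin = 3L)
  expect_equal(sum(m$rectangle), 7^3)
  expect_true(m$rectangle[8, 8, 8])

  # containment scan over random cases; different seeds change only the
  # irregular mask
  for (s in 1:50) {
    gt <- random_mask(n = 14, seed = s)
    m1 <- gen_masks(gt, seed = s)
    m2 <- gen_masks(gt, seed = s + 1000)
    expect_true(all(m1$rectangle[gt]) && all(m1$irregular[gt]))
    expect_gt(sum(m1$irregular), sum(gt))   # strict containment
    expect_identical(m1$rectangle, m2$rectangle)
  }
  s_diff <- vapply(1:10, function(s) {
    gt <- random_mask(n = 14, seed = s)
    !identical(gen_masks(gt, seed = 1)$irregular,
               gen_masks(gt, seed = 2)$irregular)
  }, logical(1))
  expect_true(any(s_diff))
  expect_error(gen_masks(array(FALSE, c(4, 4, 4))), "empty")
})
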