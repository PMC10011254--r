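test_that("41%-of-maximum threshold selects exactly the expected voxels", {
  m <- sphere_mask(20, 5)
  img <- two_level_volume(m, hot = 10, cold = 1)
  init <- array(TRUE, dim(img))
  s <- seg_41max(img, init)
  expect_identical(s$mask, array(m, dim(m)))

  # scale invariance: threshold scales with the maximum
  s2 <- seg_41max(voxel_volume(unclass(img) * 37.5, vox_spacing(img)), init)
  expect_identical(s2$mask, s$mask)

  # 1-D profile: threshold 4.1 keeps the {5, 10, 9} run
  prof <- voxel_volume(array(c(1, 2, 5, 10, 9, 4, 1), c(7, 1, 1)))
  sp <- seg_41max(prof, array(TRUE, c(7, 1, 1)))
  expect_identical(which(sp$mask), 3:5)

  # an all-zero image cannot be segmented
  z <- seg_41max(voxel_volume(array(0, c(4, 4, 4))), array(TRUE, c(4, 4, 4)))
  expect_true(z$failed)
})

test_that("contrast-oriented threshold follows its defining formula", {
  # homogeneous object 10 on flat background 2 inside a known bg mask:
  # mSUV70 = 10, BG = 2, T = 0.5*10 + 0.5*2 = 6 -> exactly the object
  m <- sphere_mask(20, 5)
  img <- two_level_volume(m, hot = 10, cold = 2)
  init <- array(petconseg:::dilate1(petconseg:::dilate1(m)), dim(m))
  bg <- array(TRUE, dim(m)) & !init
  s <- seg_st(img, init, bg = bg)
  expect_identical(s$mask, array(m, dim(m)))

  # flat background 1: T = 5.5, still exactly the object, auto bg shell
  img1 <- two_level_volume(m, hot = 10, cold = 1)
  s1 <- seg_st(img1, init)
  expect_identical(s1$mask, array(m, dim(m)))

  expect_error(seg_st(img, init, bg = init), "overlaps")
})

test_that("ST with a = 0.41 max / mSUV70, b = 0 reduces to 41MAX", {
  for (seed in 1:5) {
    img <- withr::with_seed(seed, {
      base <- array(stats::runif(16^3, 1, 2), c(16, 16, 16))
      base[sphere_mask(16, 4)] <- stats::runif(sum(sphere_mask(16, 4)), 6, 12)
      voxel_volume(base)
    })
    init <- array(sphere_mask(16, 6), c(16, 16, 16))
    mx <- max(img[init])
    m70 <- mean(img[init & unclass(img) >= 0.7 * mx])
    s_st <- seg_st(img, init, cfg = seg_config(st_a = 0.41 * mx / m70,
                                               st_b = 0))
    s_41 <- seg_41max(img, init)
    expect_identical(s_st$mask, s_41$mask)
  }
})

test_that("affinity propagation separates two intensity populations", {
  # balanced populations: the median-similarity preference then falls on
  # the cross-population block and message passing returns two clusters
  m <- array(FALSE, c(10, 10, 10))
  m[6:10, , ] <- TRUE
  img <- withr::with_seed(1, {
    arr <- array(stats::rnorm(1000, 1, 0.01), c(10, 10, 10))
    arr[m] <- stats::rnorm(sum(m), 10, 0.01)
    voxel_volume(arr)
  })
  init <- array(TRUE, dim(m))
  s <- seg_ap(img, init)
  expect_identical(s$mask, m)

  # constant image: a single cluster covering the whole initial mask
  cimg <- voxel_volume(array(4, c(8, 8, 8)))
  cinit <- array(sphere_mask(8, 3), c(8, 8, 8))
  sc <- seg_ap(cimg, cinit)
  expect_identical(sc$mask, cinit)
})

test_that("AP matches the exhaustive exemplar-search oracle on tiny inputs", {
  # three clear intensity groups in <= 12 voxels
  vals_sets <- list(c(1.0, 1.1, 0.9, 5.0, 5.2, 4.9, 9.8, 10.0, 10.3),
                    c(2.0, 2.2, 1.9, 2.1, 8.0, 8.3, 7.9, 8.1),
                    c(1, 1.2, 6, 6.3, 6.1, 11, 11.4, 10.8, 11.2, 1.1))
  for (vals in vals_sets) {
    n <- length(vals)
    img <- voxel_volume(array(vals, c(n, 1, 1)))
    init <- array(TRUE, c(n, 1, 1))
    s <- seg_ap(img, init)
    # the package's preference rule on all-unique values: weighted median
    # of distinct-pair similarities
    S <- -outer(vals, vals, `-`)^2
    pref <- stats::median(S[upper.tri(S)])
    oracle <- ap_brute_force(vals, pref)
    # the hottest oracle cluster must equal the AP segmentation
    hottest_ex <- oracle$assign[which.max(vals)]
    want <- oracle$assign == hottest_ex
    expect_identical(as.vector(s$mask), want)
  }
})

test_that("MASAC recovers sharp objects and is deterministic", {
  m <- sphere_mask(20, 5)
  img <- two_level_volume(m, hot = 10, cold = 1)
  init <- array(petconseg:::dilate1(petconseg:::dilate1(m)), dim(m))
  s <- seg_masac(img, init)
  expect_gte(dsc(s, m), 0.99)
  s2 <- seg_masac(img, init)
  expect_identical(s$mask, s2$mask)
})

test_that("large lambda reduces MASAC to the two-region data partition", {
  img <- withr::with_seed(3, {
    arr <- array(stats::rnorm(14^3, 2, 0.5), c(14, 14, 14))
    arr[sphere_mask(14, 4)] <- stats::rnorm(sum(sphere_mask(14, 4)), 9, 0.5)
    voxel_volume(abs(arr))
  })
  init <- array(TRUE, c(14, 14, 14))
  s <- seg_masac(img, init, seg_config(lambda = 1e6))
  # independent two-means partition iterated to a fixed point
  u <- unclass(img) >= 0.41 * max(img)
  for (i in 1:200) {
    c1 <- mean(img[u]); c2 <- mean(img[!u])
    u_new <- (unclass(img) - c1)^2 < (unclass(img) - c2)^2
    if (identical(u_new, u)) break
    u <- u_new
  }
  lab <- petconseg:::label_components(array(u, dim(u)))
  tab <- tabulate(lab[lab > 0])
  want <- array(lab == which.max(tab), dim(u))
  expect_identical(s$mask, want)
})

test_that("every method's result is contained in its initial mask", {
  spec <- phantom_spec(shape = c(24, 48, 48), volume_cm3 = 8, seed = 3)
  case <- build_phantom(spec)
  img <- degrade(case$activity, spec, seed = 5)
  masks <- gen_masks(case$gt_static, seed = 9)
  for (cond in names(masks)) {
    for (meth in c("41max", "st", "ap", "masac")) {
      s <- segment_pet(img, masks[[cond]], meth)
      expect_true(all(masks[[cond]][s$mask]),
                  label = paste(meth, cond, "containment"))
    }
  }
})
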