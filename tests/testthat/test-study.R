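test_that("an easy noise-free case is segmented well by every method", {
  cfg <- study_config(n_cases = 1, seed = 3, motion = FALSE, noise = FALSE,
                      shape = c(24, 48, 48), volume_range_cm3 = c(8, 8),
                      level_fractions = c(1, 0, 0))
  st <- run_study(cfg)
  ind <- st$records[st$records$method %in% cfg$methods, ]
  expect_true(all(ind$DSC >= 0.95))
  tm <- st$trt[st$trt$metric == "MATV_cm3" & st$trt$method %in% cfg$methods, ]
  expect_true(all(abs(tm$TRT) < 1e-9))
})

test_that("a study is byte-identical when rerun from the same config", {
  cfg <- study_config(n_cases = 1, seed = 11, shape = c(24, 48, 48),
                      volume_range_cm3 = c(5, 9))
  a <- run_study(cfg)
  b <- run_study(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$trt, b$trt)
  expect_identical(a$summary, b$summary)
})

test_that("summaries agree with an independent median/quartile recompute", {
  # synthetic 13 x 6 x 2 metrics fixture
  methods <- c("MASAC", "AP", "ST", "41MAX", "AveSeg", "ConSeg")
  grid <- expand.grid(case = 1:13, method = methods,
                      mask_condition = c("rectangle", "irregular"),
                      stringsAsFactors = FALSE)
  records <- withr::with_seed(21, cbind(grid,
    MATV_cm3 = stats::rlnorm(nrow(grid), 2.5, 0.5),
    RE_pct = stats::rnorm(nrow(grid), -30, 15),
    DSC = stats::runif(nrow(grid), 0.4, 0.95)))
  s <- summarize_metrics(records)
  # spot-check every cell against a direct sort-based quantile
  for (j in sample(seq_len(nrow(s)), 6)) {
    g <- records[records$method == s$method[j] &
                   records$mask_condition == s$mask_condition[j], ]
    v <- sort(g$MATV_cm3)
    n <- length(v)
    qi <- function(p) { h <- 1 + (n - 1) * p
      v[floor(h)] + (h - floor(h)) * (v[ceiling(h)] - v[floor(h)]) }
    expect_equal(s$MATV_cm3_median[j], qi(0.5))
    expect_equal(s$MATV_cm3_q1[j], qi(0.25))
    expect_equal(s$MATV_cm3_q3[j], qi(0.75))
  }
  # single case: degenerate IQR
  one <- records[records$case == 1 & records$method == "ST" &
                   records$mask_condition == "rectangle", ]
  s1 <- summarize_metrics(one)
  expect_equal(s1$MATV_cm3_median, one$MATV_cm3)
  expect_equal(s1$MATV_cm3_q1, s1$MATV_cm3_q3)
})

test_that("study artifacts round-trip through the report writer", {
  cfg <- study_config(n_cases = 1, seed = 2, shape = c(24, 48, 48),
                      volume_range_cm3 = c(5, 9))
  st <- run_study(cfg)
  dir <- file.path(tempdir(), "petconseg-report")
  write_report(st, dir)
  back <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_equal(nrow(back), nrow(st$records))
  expect_equal(back$MATV_cm3, st$records$MATV_cm3, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "report.json")))
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_true(!is.null(rep$summary))
  unlink(dir, recursive = TRUE)
})

test_that("volumes round-trip through NIfTI with spacing preserved", {
  v <- voxel_volume(array(stats::runif(4 * 5 * 6), c(4, 5, 6)),
                    spacing = c(0.50, 0.41, 0.41))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  w <- read_volume(path)
  expect_equal(unclass(w), unclass(v), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(vox_spacing(w), vox_spacing(v), tolerance = 1e-6)
  unlink(path)
})
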