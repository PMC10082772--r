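test_that("center count follows the configured fraction", {
  plan <- blindspot:::with_seed(1, build_mask_plan(c(200, 200), mask_config()))
  expect_equal(nrow(plan$centers), 40)  # 0.001 * 200 * 200
  expect_equal(sum(plan$loss_mask), 40)
  expect_true(all(plan$loss_mask[plan$centers]))
  expect_false(any(duplicated(plan$centers)))
})

test_that("zero center fraction yields an empty plan and identity masking", {
  plan <- build_mask_plan(c(64, 64), mask_config(center_fraction = 0))
  expect_equal(nrow(plan$centers), 0)
  expect_false(any(plan$loss_mask))
  p <- matrix(runif(64 * 64), 64, 64)
  expect_identical(apply_mask(p, plan), p)
})

test_that("strip geometry: every masked coordinate is within the 7x1 extent", {
  plan <- blindspot:::with_seed(2, build_mask_plan(c(128, 128), mask_config()))
  total <- 0
  for (i in seq_len(nrow(plan$centers))) {
    sc <- blindspot:::strip_coords(plan$centers[i, ], plan$config$mask_shape)
    total <- total + nrow(sc)
    expect_true(all(abs(sc[, "row"] - plan$centers[i, 1]) <= 3))
    expect_true(all(sc[, "col"] == plan$centers[i, 2]))
    expect_true(all(sc >= 1) && all(sc[, "row"] <= 128) && all(sc[, "col"] <= 128))
  }
  expect_lte(total, 7 * nrow(plan$centers))
})

test_that("replacement copies a continuous strip from the offset source", {
  p <- blindspot:::with_seed(3, matrix(runif(200 * 200), 200, 200))
  plan <- build_mask_plan(c(200, 200), mask_config(center_fraction = 0))
  plan$centers <- matrix(c(50L, 80L), 1)
  plan$offsets <- matrix(c(2L, 1L), 1)
  plan$loss_mask[50, 80] <- TRUE
  out <- apply_mask(p, plan)
  expect_identical(out[47:53, 80], p[49:55, 81])
  untouched <- out
  untouched[47:53, 80] <- p[47:53, 80]
  expect_identical(untouched, p)
})

test_that("zero offsets make masking the identity", {
  p <- matrix(runif(64 * 64), 64, 64)
  plan <- blindspot:::with_seed(4, build_mask_plan(c(64, 64), mask_config()))
  plan$offsets[] <- 0L
  expect_identical(apply_mask(p, plan), p)
})

test_that("offsets respect the Chebyshev radius and keep sources in bounds", {
  cfg <- mask_config()
  blindspot:::with_seed(5, {
    for (k in 1:200) {
      plan <- build_mask_plan(c(32, 32), cfg)
      expect_true(all(abs(plan$offsets) <= 5))
      src_r <- plan$centers[, 1] + plan$offsets[, 1]
      src_c <- plan$centers[, 2] + plan$offsets[, 2]
      expect_true(all(src_r >= 4 & src_r <= 29 & src_c >= 1 & src_c <= 32))
    }
  })
})

test_that("offsets from interior centers are uniform on the 11x11 grid", {
  offs <- blindspot:::with_seed(6, {
    acc <- NULL
    for (k in 1:80) {
      plan <- build_mask_plan(c(200, 200), mask_config())
      interior <- plan$centers[, 1] >= 12 & plan$centers[, 1] <= 189 &
        plan$centers[, 2] >= 6 & plan$centers[, 2] <= 195
      acc <- rbind(acc, plan$offsets[interior, , drop = FALSE])
    }
    acc
  })
  counts <- table(factor(offs[, 1], levels = -5:5),
                  factor(offs[, 2], levels = -5:5))
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  # also marginal uniformity
  p1 <- stats::chisq.test(table(factor(offs[, 1], levels = -5:5)))$p.value
  expect_gt(p, 1e-4)
  expect_gt(p1, 1e-4)
})

test_that("disjoint strips commute: joint application equals the union of singles", {
  p <- blindspot:::with_seed(7, matrix(runif(96 * 96), 96, 96))
  plan <- blindspot:::with_seed(7, build_mask_plan(c(96, 96), mask_config()))
  # keep a subset with pairwise-disjoint strips (distinct columns suffice)
  keep <- !duplicated(plan$centers[, 2])
  plan$centers <- plan$centers[keep, , drop = FALSE]
  plan$offsets <- plan$offsets[keep, , drop = FALSE]
  joint <- apply_mask(p, plan)
  acc <- p
  for (i in sample(seq_len(nrow(plan$centers)))) {
    single <- plan
    single$centers <- plan$centers[i, , drop = FALSE]
    single$offsets <- plan$offsets[i, , drop = FALSE]
    one <- apply_mask(p, single)
    changed <- one != p
    acc[changed] <- one[changed]
  }
  expect_identical(joint, acc)
})

test_that("plans that cannot fit are refused; CSV round-trip preserves the plan", {
  expect_error(build_mask_plan(c(10, 10), mask_config()), "too small")
  plan <- blindspot:::with_seed(8, build_mask_plan(c(64, 64), mask_config()))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_mask_plan(plan, tmp)
  back <- read_mask_plan(tmp, c(64, 64), mask_config())
  expect_equal(back$centers[, 1], plan$centers[, 1])
  expect_equal(back$offsets[, 2], plan$offsets[, 2])
  expect_identical(back$loss_mask, plan$loss_mask)
})
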