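test_that("confusion counts match a brute-force voxel loop", {
  gt <- rand_mask(c(8, 8, 8), p = 0.35, seed = 3)
  pred <- rand_mask(c(8, 8, 8), p = 0.35, seed = 4)
  cc <- confusion_counts(gt, pred)
  tp <- fp <- fn <- tn <- 0L
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    g <- gt$data[i, j, k]; p <- pred$data[i, j, k]
    if (g == 1 && p == 1) tp <- tp + 1L
    else if (g == 0 && p == 1) fp <- fp + 1L
    else if (g == 1 && p == 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(tp, fp, fn, tn))
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 512L)

  empty <- as_mask(array(0L, c(8, 8, 8)))
  cc2 <- confusion_counts(gt, empty)
  expect_identical(cc2$tp, 0L)
  expect_identical(cc2$fp, 0L)
  expect_identical(cc2$fn, sum(gt$data))

  expect_error(confusion_counts(gt, rand_mask(c(4, 4, 4))), "shapes")
})

test_that("overlap metrics match hand arithmetic and their identities", {
  cc <- structure(list(tp = 6L, fp = 2L, fn = 2L, tn = 54L),
                  class = "confusion_counts")
  expect_equal(dice(cc), 0.75)
  expect_equal(jaccard(cc), 0.6)
  expect_equal(over_seg(cc), 0.25)
  expect_equal(under_seg(cc), 0.25)
  expect_equal(over_seg(cc) + under_seg(cc), 2 * (1 - dice(cc)))

  perfect <- structure(list(tp = 10L, fp = 0L, fn = 0L, tn = 54L),
                       class = "confusion_counts")
  expect_equal(c(dice(perfect), jaccard(perfect), over_seg(perfect),
                 under_seg(perfect)), c(1, 1, 0, 0))

  # empty prediction, nonempty ground truth: US reaches its maximum of 2
  miss <- structure(list(tp = 0L, fp = 0L, fn = 7L, tn = 57L),
                    class = "confusion_counts")
  expect_equal(dice(miss), 0)
  expect_equal(under_seg(miss), 2)
  expect_equal(over_seg(miss), 0)

  # both empty: defined as a perfect degenerate match
  none <- structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 64L),
                    class = "confusion_counts")
  expect_equal(c(dice(none), jaccard(none), over_seg(none), under_seg(none)),
               c(1, 1, 0, 0))
})

test_that("metric identities hold over random mask pairs", {
  for (i in 1:50) {
    gt <- rand_mask(c(8, 8, 8), p = runif(1, 0.1, 0.6), seed = 100 + i)
    pred <- rand_mask(c(8, 8, 8), p = runif(1, 0.1, 0.6), seed = 200 + i)
    cc <- confusion_counts(gt, pred)
    d <- dice(cc)
    expect_equal(over_seg(cc) + under_seg(cc), 2 * (1 - d), tolerance = 1e-9)
    expect_equal(jaccard(cc), d / (2 - d), tolerance = 1e-9)
  }
})

test_that("hd95 matches closed forms and the brute-force oracle", {
  d <- c(12, 12, 12)
  a <- array(0L, d); a[4, 6, 6] <- 1L
  b <- array(0L, d); b[7, 6, 6] <- 1L
  # single voxels 3 apart along an axis with 2 mm spacing -> 6 mm
  expect_equal(hd95(as_mask(a, c(2, 1, 1)), as_mask(b, c(2, 1, 1))), 6)

  m <- rand_mask(c(10, 10, 10), p = 0.3, seed = 5)
  expect_equal(hd95(m, m), 0)

  gt <- rand_mask(c(16, 16, 16), p = 0.3, seed = 6, spacing = c(1, 1.2, 2))
  pred <- rand_mask(c(16, 16, 16), p = 0.3, seed = 7, spacing = c(1, 1.2, 2))
  expect_equal(hd95(gt, pred), brute_hd95(gt, pred, c(1, 1.2, 2)),
               tolerance = 1e-9)

  # symmetry, dominance by the exact Hausdorff distance, linear spacing scaling
  expect_equal(hd95(gt, pred), hd95(pred, gt), tolerance = 1e-12)
  expect_lte(hd95(gt, pred), hd95(gt, pred, percentile = 100))
  expect_equal(hd95(gt, pred, spacing = 2 * c(1, 1.2, 2)),
               2 * hd95(gt, pred), tolerance = 1e-9)

  empty <- as_mask(array(0L, c(16, 16, 16)))
  expect_error(hd95(gt, empty), "empty")
})

test_that("border stripping erodes by the expected cube shell", {
  d <- c(13, 13, 13)
  cube <- array(0L, d); cube[3:11, 3:11, 3:11] <- 1L
  m <- as_mask(cube)
  s3 <- border_strip(m, 3)
  expected <- array(0L, d); expected[4:10, 4:10, 4:10] <- 1L
  expect_identical(s3$data, expected)
  expect_identical(sum(s3$data), 343L)  # 7^3

  # identity at edge 1; thin masks vanish
  expect_identical(border_strip(m, 1)$data, m$data)
  slab <- array(0L, d); slab[5, , ] <- 1L
  expect_identical(sum(border_strip(as_mask(slab), 3)$data), 0L)

  expect_error(border_strip(m, 4), "odd")

  # anti-monotone in cube edge
  for (i in 1:10) {
    rm <- rand_mask(c(10, 10, 10), p = 0.7, seed = 300 + i)
    s3 <- border_strip(rm, 3)$data
    s5 <- border_strip(rm, 5)$data
    expect_true(all(s5 <= s3))
    expect_true(all(s3 <= rm$data))
  }
})

test_that("mask combination implements logical-or and Hadamard product", {
  a <- rand_mask(c(6, 6, 6), p = 0.4, seed = 8)
  b <- rand_mask(c(6, 6, 6), p = 0.4, seed = 9)
  u <- combine_masks(a, b, "union")
  x <- combine_masks(a, b, "intersection")
  expect_identical(u$data, array(as.integer(a$data | b$data), dim(a$data)))
  expect_identical(x$data, a$data * b$data)
  expect_identical(combine_masks(a, a, "union")$data, a$data)
  expect_identical(combine_masks(a, a, "intersection")$data, a$data)

  da <- array(0L, c(4, 4, 4)); da[1, 1, 1] <- 1L
  db <- array(0L, c(4, 4, 4)); db[4, 4, 4] <- 1L
  expect_identical(sum(combine_masks(as_mask(da), as_mask(db), "union")$data), 2L)
  expect_identical(sum(combine_masks(as_mask(da), as_mask(db), "intersection")$data), 0L)
})

test_that("evaluate_pair attributes disagreement to the right direction", {
  ph <- small_phantom()
  same <- evaluate_pair(ph$gt, ph$gt, volume_id = "self")
  expect_equal(same$dice, 1)
  expect_equal(same$jaccard, 1)
  expect_equal(same$os, 0)
  expect_equal(same$us, 0)
  expect_equal(same$hd95_mm, 0)

  eroded <- perturb_mask(ph$gt, "erode_boundary", magnitude = 1)
  r1 <- evaluate_pair(ph$gt, eroded)
  expect_equal(r1$os, 0)
  expect_gt(r1$us, 0)

  leaked <- perturb_mask(ph$gt, "dilate_leak", magnitude = 2, seed = 1)
  r2 <- evaluate_pair(ph$gt, leaked)
  expect_equal(r2$us, 0)
  expect_gt(r2$os, 0)

  # dice translation invariance under simultaneous shifts
  g <- ph$gt$data
  shift <- function(a) {
    out <- array(0L, dim(a)); d <- dim(a)
    out[2:d[1], 2:d[2], ] <- a[1:(d[1] - 1), 1:(d[2] - 1), ]
    out
  }
  p <- perturb_mask(ph$gt, "erode_boundary", 1)$data
  d_orig <- evaluate_pair(as_mask(g), as_mask(p))$dice
  d_shift <- evaluate_pair(as_mask(shift(g)), as_mask(shift(p)))$dice
  expect_equal(d_orig, d_shift, tolerance = 1e-12)
})

test_that("metric summaries aggregate as mean/SD/median/IQR", {
  r1 <- evaluate_pair(rand_mask(c(6, 6, 6), 0.4, 1), rand_mask(c(6, 6, 6), 0.4, 2))
  expect_warning(s1 <- summarize_metrics(r1), "single report")
  expect_equal(s1$mean[s1$metric == "dice"], r1$dice)
  expect_equal(s1$sd[s1$metric == "dice"], 0)

  two <- tibble::tibble(dice = c(0.9, 0.7))
  s2 <- summarize_metrics(two)
  expect_equal(s2$mean, 0.8)
  expect_equal(s2$median, 0.8)
  expect_equal(s2$sd, stats::sd(c(0.9, 0.7)))

  # permutation invariance
  many <- tibble::tibble(dice = runif(9), os = runif(9))
  expect_equal(summarize_metrics(many), summarize_metrics(many[sample(9), ]))

  expect_error(summarize_metrics(tibble::tibble()), "no reports")
})
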