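test_that("Dice handles identity, disjoint and hand-counted overlaps", {
  m <- grid_meta(c(1, 1, 1))
  a <- array(0L, c(4, 4, 2)); a[1:2, 1:2, 1] <- 7L
  expect_equal(dice_score(label_mask(a, m), label_mask(a, m), "aorta"), 1)
  b <- array(0L, c(4, 4, 2)); b[3:4, 3:4, 2] <- 7L
  expect_equal(dice_score(label_mask(a, m), label_mask(b, m), "aorta"), 0)
  # |A| = 4, |B| = 5, |A intersect B| = 3 -> 2*3/9
  p <- array(0L, c(4, 4, 1)); p[1:4, 1, 1] <- 7L
  q <- array(0L, c(4, 4, 1)); q[2:4, 1, 1] <- 7L; q[1:2, 2, 1] <- 7L
  expect_equal(dice_score(label_mask(p, m), label_mask(q, m), 7L), 2 * 3 / 9)
  # both empty -> perfect agreement by convention
  e <- array(0L, c(4, 4, 1))
  expect_equal(dice_score(label_mask(e, m), label_mask(e, m), "aorta"), 1)
})

test_that("Dice equals the brute-force set computation on random masks", {
  for (seed in 1:20) {
    mk <- random_masks(seed, p = stats::runif(1, 0.05, 0.6))
    expect_equal(dice_score(mk$pred, mk$truth, 7L),
                 dice_bruteforce(mk$pred, mk$truth, 7L))
    # symmetry
    expect_equal(dice_score(mk$pred, mk$truth, 7L),
                 dice_score(mk$truth, mk$pred, 7L))
  }
})

test_that("eroding a correct mask strictly decreases Dice", {
  m <- grid_meta(c(1, 1, 1))
  a <- array(0L, c(12, 12, 12)); a[3:10, 3:10, 3:10] <- 7L
  # one-voxel erosion: keep voxels whose 6-neighbourhood is fully labelled
  er <- a
  inside <- array(FALSE, dim(a))
  inside[2:11, 2:11, 2:11] <-
    (a[1:10, 2:11, 2:11] == 7L) & (a[3:12, 2:11, 2:11] == 7L) &
    (a[2:11, 1:10, 2:11] == 7L) & (a[2:11, 3:12, 2:11] == 7L) &
    (a[2:11, 2:11, 1:10] == 7L) & (a[2:11, 2:11, 3:12] == 7L)
  er[!inside] <- 0L
  d1 <- dice_score(label_mask(a, m), label_mask(a, m), 7L)
  d2 <- dice_score(label_mask(er, m), label_mask(a, m), 7L)
  expect_lt(d2, d1)
  expect_gt(d2, 0)
})

test_that("Dice rejects shape mismatches", {
  m <- grid_meta(c(1, 1, 1))
  a <- label_mask(array(0L, c(4, 4, 4)), m)
  b <- label_mask(array(0L, c(4, 4, 5)), m)
  expect_error(dice_score(a, b, 7L), "shape mismatch")
})

test_that("cross-sectional areas convert voxel counts to cm^2", {
  m <- grid_meta(c(1, 1, 1))
  a <- array(0L, c(20, 20, 3)); a[1:10, 1:10, 2] <- 7L  # 100 voxels of 1 mm^2
  expect_equal(cross_section_area(label_mask(a, m), "aorta", 2), 1.00)
  expect_warning(z <- cross_section_area(label_mask(a, m), "aorta", 1),
                 "absent")
  expect_equal(z, 0)
  expect_error(cross_section_area(label_mask(a, m), "aorta", 9), "axial_index")
})

test_that("a rasterised disc recovers the analytic circle area", {
  m <- grid_meta(c(1, 1, 1))
  g <- expand.grid(x = 1:40, y = 1:40)
  disc <- array(0L, c(40, 40, 1))
  disc[cbind(g$x, g$y, 1)] <-
    ifelse((g$x - 20.5)^2 + (g$y - 20.5)^2 <= 16^2, 7L, 0L)
  expect_equal(cross_section_area(label_mask(disc, m), "aorta", 1),
               pi * 1.6^2, tolerance = 0.05)
})

test_that("score aggregation uses the sample (n-1) standard deviation", {
  s <- summarize_scores(c(0.86, 0.75, 0.84))
  expect_equal(round(s$mean, 2), 0.82)
  expect_equal(round(s$sd, 2), 0.06)
  expect_equal(round(summarize_scores(c(0.82, 0.81, 0.60))$sd, 2), 0.12)
  expect_equal(summarize_scores(c(0.5, 0.5, 0.5))$sd, 0)
  expect_error(summarize_scores(numeric(0)), "non-empty")
})

test_that("segmentation report evaluates on the mid-LV slice", {
  m <- grid_meta(c(1, 1, 1))
  truth <- array(0L, c(16, 16, 10))
  truth[2:7, 2:7, 3:8] <- 1L          # LV spans z 3..8, midpoint slice 5
  truth[10:14, 10:14, ] <- 7L
  pred <- truth
  pred[2, , ] <- 0L                   # clip one LV face
  lm_t <- label_mask(truth, m); lm_p <- label_mask(pred, m)
  expect_equal(lv_mid_slice(lm_t), 5L)
  rep <- segmentation_report(list(case1 = list(pred = lm_p, truth = lm_t)))
  expect_setequal(rep$structure, c("aorta", "LV"))
  aorta_row <- rep[rep$case == "case1" & rep$structure == "aorta", ]
  expect_equal(aorta_row$dice, 1)
  lv_row <- rep[rep$case == "case1" & rep$structure == "LV", ]
  expect_lt(lv_row$dice, 1)
  expect_equal(lv_row$area_truth_cm2, 36 / 100)
})
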