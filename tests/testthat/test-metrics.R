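test_that("confusion counts match direct tallies", {
  g <- array(0L, c(8, 8, 4)); g[2:4, 2:5, 2] <- 1L  # 12 voxels
  cc <- confusion_counts(g, g)
  expect_equal(cc$tp, 12); expect_equal(cc$fp, 0); expect_equal(cc$fn, 0)
  p <- array(0L, c(8, 8, 4)); p[6:7, 6:7, 3] <- 1L  # disjoint, 4 voxels
  g2 <- array(0L, c(8, 8, 4)); g2[1:7, 1, 1] <- 1L  # 7 voxels
  cc2 <- confusion_counts(p, g2)
  expect_equal(cc2$tp, 0); expect_equal(cc2$fp, 4); expect_equal(cc2$fn, 7)
  expect_equal(cc2$tp + cc2$fp + cc2$fn + cc2$tn, 8 * 8 * 4)
  expect_error(confusion_counts(p, array(0L, c(4, 4, 4))), "shapes")
})

test_that("overlap metrics follow their defining ratios and the Dice-IoU identity", {
  m <- overlap_metrics(list(tp = 40, fp = 10, fn = 10, tn = 1000))
  expect_equal(m$dice, 0.8)
  expect_equal(m$iou, 2 / 3, tolerance = 1e-12)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$ppv, 0.8)
  # both-empty convention
  e <- overlap_metrics(list(tp = 0, fp = 0, fn = 0, tn = 100))
  expect_true(all(unlist(e[, 1:4]) == 1))
  expect_true(e$degenerate)
  # identity dice = 2 iou / (1 + iou) on random counts
  set.seed(8)
  for (i in 1:50) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               fn = sample(0:50, 1), tn = 100)
    om <- overlap_metrics(cc)
    if (!is.na(om$dice) && !is.na(om$iou)) {
      expect_equal(om$dice, 2 * om$iou / (1 + om$iou), tolerance = 1e-12)
    }
  }
})

test_that("surface extraction matches a brute-force neighbour scan", {
  # single voxel is its own surface
  lab <- array(0L, c(5, 5, 5)); lab[3, 3, 3] <- 1L
  expect_equal(nrow(surface_points(lab, c(1, 1, 1))), 1)
  # solid 5x5x5 cube inside a larger grid: 5^3 - 3^3 = 98 surface voxels
  cube <- array(0L, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- 1L
  expect_equal(nrow(surface_points(cube, c(1, 1, 1))), 98)
  # random blobs equal the exhaustive oracle
  set.seed(11)
  for (i in 1:5) {
    lab <- random_blob_mask(c(16, 16, 6))
    sp <- c(0.7, 0.9, 2.5)
    got <- surface_points(lab, sp)
    want <- oracle_surface(lab, sp)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE],
                 tolerance = 1e-12)
  }
})

test_that("hd95 reproduces hand-computable distances and is symmetric", {
  a <- array(0L, c(8, 8, 8)); a[1, 1, 1] <- 1L
  b <- array(0L, c(8, 8, 8)); b[1, 4, 5] <- 1L  # offset (0, 3, 4) -> 5 mm
  expect_equal(hd95(a, b, c(1, 1, 1)), 5)
  expect_equal(hd95(a, b, c(1, 1, 1), mode = "scaled95"), 4.75)
  expect_equal(hd95(b, a, c(1, 1, 1)), hd95(a, b, c(1, 1, 1)))
  # identity
  expect_equal(hd95(a, a, c(1, 1, 1)), 0)
  # empty mask is undefined
  expect_true(is.na(hd95(a, array(0L, c(8, 8, 8)), c(1, 1, 1))))
})

test_that("hd95 equals the all-pairs brute-force oracle on random blobs", {
  set.seed(12)
  for (i in 1:10) {
    g <- random_blob_mask(c(24, 24, 8))
    p <- random_blob_mask(c(24, 24, 8))
    if (sum(g) == 0 || sum(p) == 0) next
    sp <- c(0.8, 1.1, 3)
    expect_equal(hd95(g, p, sp), oracle_hd95(g, p, sp), tolerance = 1e-9)
    expect_equal(hd95(g, p, sp, mode = "scaled95"),
                 oracle_hd95(g, p, sp, mode = "scaled95"), tolerance = 1e-9)
    # the robust percentile never exceeds the exact Hausdorff distance
    expect_lte(hd95(g, p, sp),
               oracle_hd95(g, p, sp, mode = "scaled95") / 0.95 + 1e-12)
  }
})

test_that("dilating the prediction never decreases sensitivity", {
  dilate6 <- function(lab) {
    d <- dim(lab)
    out <- lab
    out[-1, , ] <- pmax(out[-1, , ], lab[-d[1], , ])
    out[-d[1], , ] <- pmax(out[-d[1], , ], lab[-1, , ])
    out[, -1, ] <- pmax(out[, -1, ], lab[, -d[2], ])
    out[, -d[2], ] <- pmax(out[, -d[2], ], lab[, -1, ])
    out
  }
  set.seed(13)
  for (i in 1:5) {
    g <- random_blob_mask(c(16, 16, 6))
    p <- random_blob_mask(c(16, 16, 6))
    s0 <- overlap_metrics(confusion_counts(p, g))$sensitivity
    s1 <- overlap_metrics(confusion_counts(dilate6(p), g))$sensitivity
    if (!is.na(s0) && !is.na(s1)) expect_gte(s1, s0)
  }
})

test_that("per-case evaluation pools the full stack and aggregates with exclusions", {
  g <- array(0L, c(8, 8, 4)); g[2:4, 2:4, 2:3] <- 1L
  perfect <- evaluate_case(g, g, spacing_mm = c(1, 1, 4))
  expect_equal(perfect$dice, 1)
  expect_equal(perfect$hd95_mm, 0)
  reports <- dplyr::bind_rows(
    evaluate_case(g, g, spacing_mm = c(1, 1, 4), case_id = "a"),
    {
      p <- array(0L, c(8, 8, 4))
      evaluate_case(p, g, spacing_mm = c(1, 1, 4), case_id = "b")
    }
  )
  # one case has dice 1, the empty prediction has dice 0 and undefined hd95
  expect_equal(reports$dice, c(1, 0))
  agg <- aggregate_metrics(reports)
  expect_equal(agg$mean[agg$metric == "dice"], 0.5)
  expect_equal(agg$n_excluded[agg$metric == "hd95_mm"], 1)
  expect_equal(agg$mean[agg$metric == "hd95_mm"], 0)
})

test_that("cohort evaluation demands matching case sets", {
  g <- list(a = array(0L, c(4, 4, 2)))
  g$a[2, 2, 1] <- 1L
  expect_error(evaluate_cohort(list(b = g$a), g), "Missing predictions")
  out <- evaluate_cohort(list(a = g$a), g, spacing_mm = c(1, 1, 1))
  expect_equal(out$dice, 1)
})
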