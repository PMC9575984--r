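test_that("voxel-count volume follows the spacing arithmetic exactly", {
  lab <- array(0L, c(20, 20, 5))
  lab[sample(20 * 20 * 5, 100)] <- 1L
  expect_equal(mask_volume_ml(lab, c(0.45, 0.45, 4.0)), 0.081,
               tolerance = 1e-12)
  expect_equal(mask_volume_ml(array(0L, c(4, 4, 2)), c(1, 1, 1)), 0)
  expect_error(mask_volume_ml(array(2L, c(2, 2, 1)), c(1, 1, 1)), "binary")
  # additive over disjoint components and invariant to slice order
  a <- array(0L, c(10, 10, 4)); a[2:3, 2:3, 1] <- 1L
  b <- array(0L, c(10, 10, 4)); b[7:8, 7:8, 3] <- 1L
  expect_equal(mask_volume_ml(a + b, c(1, 2, 3)),
               mask_volume_ml(a, c(1, 2, 3)) + mask_volume_ml(b, c(1, 2, 3)))
  expect_equal(mask_volume_ml((a + b)[, , c(3, 1, 2, 4)], c(1, 2, 3)),
               mask_volume_ml(a + b, c(1, 2, 3)))
})

test_that("Coniglobus A/B/C reproduce the rectangle corner-point oracle", {
  lab <- array(0L, c(32, 32, 5))
  lab[6:15, 6:25, 2:4] <- 1L  # 10 x 20 pixels, 3 lesion slices
  m <- coniglobus_abc(lab, spacing_mm = c(1, 1, 4))
  diag_ref <- sqrt(10^2 + 20^2)
  expect_equal(m$A_mm, diag_ref, tolerance = 1e-9)
  expect_equal(m$B_mm, 2 * 10 * 20 / diag_ref, tolerance = 1e-9)
  expect_equal(m$C_mm, 12)
  expect_equal(coniglobus_volume(m), 22.3607 * 17.8885 * 12 / 2 / 1000,
               tolerance = 1e-4)
  expect_equal(coniglobus_volume(m), 2.4, tolerance = 1e-9)
})

test_that("a single-pixel lesion is measured over its four corner points", {
  lab <- array(0L, c(9, 9, 3)); lab[5, 5, 2] <- 1L
  m <- coniglobus_abc(lab, spacing_mm = c(1, 1, 4))
  # brute force over the 4 corners of the unit pixel
  corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  dm <- as.matrix(dist(corners))
  A_ref <- max(dm)
  pair <- which(dm == A_ref, arr.ind = TRUE)[1, ]
  u <- (corners[pair[2], ] - corners[pair[1], ]) / A_ref
  proj <- corners %*% c(-u[2], u[1])
  expect_equal(m$A_mm, A_ref)          # sqrt(2)
  expect_equal(m$B_mm, max(proj) - min(proj))
  expect_equal(m$C_mm, 4)
})

test_that("a rasterized disk has A and B close to its diameter at any rotation", {
  r_mm <- 10
  lab <- array(0L, c(128, 128, 3))
  ctr <- 64.5
  for (i in 1:128) for (j in 1:128) {
    if ((i - ctr)^2 + (j - ctr)^2 <= (r_mm / 0.25)^2) lab[i, j, 2] <- 1L
  }
  m <- coniglobus_abc(lab, spacing_mm = c(0.25, 0.25, 4))
  expect_equal(m$A_mm, 2 * r_mm, tolerance = 2 * 0.25 / (2 * r_mm))
  expect_equal(m$B_mm, 2 * r_mm, tolerance = 2 * 0.25 / (2 * r_mm))
})

test_that("Coniglobus A is stable under in-plane rotation of the lesion", {
  vols <- sapply(c(0, 30, 60, 115), function(rot) {
    spec <- phantom_spec("ellipsoid", semi_axes_mm = c(16, 9, 8),
                        matrix = 128, n_slices = 12,
                        spacing_mm = c(0.75, 0.75, 4), noise_sd_hu = 0,
                        rotation_deg = rot, seed = 1)
    m <- coniglobus_abc(generate_phantom(spec)$mask)
    m$A_mm
  })
  # the caliper diameter of the same shape, rotated, varies by at most
  # about a pixel diagonal
  expect_lt(max(vols) - min(vols), 2 * 0.75 * sqrt(2))
})

test_that("Coniglobus reads an axis-aligned ellipsoid at about 3/pi of the voxel-count volume", {
  spec <- phantom_spec("ellipsoid", semi_axes_mm = c(18, 13, 10),
                       matrix = 256, n_slices = 40,
                       spacing_mm = c(0.35, 0.35, 0.7), noise_sd_hu = 0,
                       seed = 4)
  ph <- generate_phantom(spec)
  ratio <- coniglobus_volume(ph$mask) / mask_volume_ml(ph$mask)
  expect_gt(ratio, 0.93)
  expect_lt(ratio, 0.98)
})

test_that("multifocal lesions use the largest component and are flagged", {
  lab <- array(0L, c(24, 24, 4))
  lab[3:10, 3:10, 2] <- 1L   # 64-pixel focus
  lab[18:20, 18:20, 3] <- 1L # smaller, disjoint focus
  m <- coniglobus_abc(lab, spacing_mm = c(1, 1, 4))
  expect_true(m$multifocal)
  expect_equal(m$n_components, 2)
  expect_equal(m$slice_index, 2)
  expect_equal(m$C_mm, 4)  # only the largest component's slices count
  expect_error(coniglobus_abc(array(0L, c(4, 4, 2)), c(1, 1, 1)), "empty")
})

test_that("ICC is 1 on identical methods, penalizes shifts, and matches an ANOVA oracle", {
  x <- c(12, 25, 31, 47, 58, 63)
  expect_equal(icc_agreement(x, x)$icc, 1)
  expect_lt(icc_agreement(x, x + 10)$icc, 1)
  # independent oracle: variance components via stats::aov mean squares
  oracle_icc <- function(x, y) {
    n <- length(x)
    df <- data.frame(v = c(x, y),
                     subj = factor(rep(seq_len(n), 2)),
                     meth = factor(rep(1:2, each = n)))
    ms <- anova(stats::aov(v ~ subj + meth, data = df))$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + 2 / n * (msc - mse))
  }
  set.seed(51)
  for (i in 1:20) {
    a <- runif(10, 5, 80)
    b <- a * runif(1, 0.8, 1.2) + rnorm(10, sd = 3)
    expect_equal(icc_agreement(a, b)$icc, oracle_icc(a, b), tolerance = 1e-9)
  }
})

test_that("regression agreement matches the normal-equations oracle", {
  x <- c(10, 20, 30, 40, 55)
  r <- regression_consistency(x, x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  r2 <- regression_consistency(x, 2 * x + 1)
  expect_equal(c(r2$slope, r2$intercept), c(2, 1), tolerance = 1e-9)
  set.seed(52)
  for (i in 1:10) {
    a <- runif(12, 1, 90)
    b <- 0.9 * a + rnorm(12, sd = 5)
    fit <- regression_consistency(a, b)
    # closed-form least squares
    slope_ref <- sum((a - mean(a)) * (b - mean(b))) / sum((a - mean(a))^2)
    int_ref <- mean(b) - slope_ref * mean(a)
    ss_res <- sum((b - int_ref - slope_ref * a)^2)
    r2_ref <- 1 - ss_res / sum((b - mean(b))^2)
    expect_equal(fit$slope, slope_ref, tolerance = 1e-9)
    expect_equal(fit$intercept, int_ref, tolerance = 1e-9)
    expect_equal(fit$r_squared, r2_ref, tolerance = 1e-9)
  }
  expect_error(regression_consistency(rep(1, 5), 1:5), "zero variance")
})

test_that("consistency report compares methods per case and in aggregate", {
  set.seed(53)
  gt <- list(); pred <- list()
  for (i in 1:4) {
    lab <- random_blob_mask(c(24, 24, 6), n_blobs = 1)
    gt[[sprintf("c%d", i)]] <- ich_mask(lab, c(1, 1, 4))
    pred[[sprintf("c%d", i)]] <- ich_mask(lab, c(1, 1, 4))
  }
  rep <- consistency_report(gt, pred)
  expect_equal(nrow(rep$cases), 4)
  expect_equal(rep$agreement$icc[rep$agreement$method == "model"], 1)
  expect_equal(rep$agreement$slope[rep$agreement$method == "model"], 1,
               tolerance = 1e-9)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_error(consistency_report(gt, pred[1:2]), "Missing predictions")
})
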