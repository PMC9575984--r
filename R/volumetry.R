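#' Hemorrhage volume by voxel counting, in mL
#'
#' The lesion volume is the voxel volume times the lesion voxel count,
#' accumulated slice by slice: `V = sum_i X * Y * T * W_i` over the `L`
#' slices, where `W_i` is the number of lesion voxels in slice `i`, and
#' `X`, `Y`, `T` are the in-plane spacings and the slice thickness in mm.
#' The mm^3 result is reported in mL (divided by 1000).
#'
#' @param mask An [ich_mask] or binary 3-D array.
#' @param spacing_mm Voxel spacing `(X, Y, T)`; taken from the mask when
#'   omitted.
#' @return Volume in mL (0 for an empty mask).
#' @export
mask_volume_ml <- function(mask, spacing_mm = NULL) {
  lab <- mask_labels(mask)
  if (!all(lab %in% c(0, 1))) stop("Mask must be binary.")
  sp <- mask_spacing(mask, spacing_mm)
  sum(lab) * prod(sp) / 1000
}

# Largest 6-connected lesion component; returns list(component array,
# n_components).
largest_component <- function(lab) {
  d <- dim(lab)
  cl <- label_components_cpp(as.integer(lab != 0), d[1], d[2], d[3])
  ncomp <- max(cl)
  if (ncomp == 0) stop("Mask is empty.")
  if (ncomp == 1) return(list(comp = array(cl != 0, d) * 1L, n = 1L))
  sizes <- tabulate(cl[cl > 0], nbins = ncomp)
  keep <- which.max(sizes)
  list(comp = array(as.integer(cl == keep), d), n = ncomp)
}

#' Automated Coniglobus measurement of a hemorrhage mask
#'
#' Mimics the clinical caliper procedure on the largest connected lesion
#' component: on the axial slice of maximal lesion area (ties broken by
#' the lowest slice index), `A` is the largest distance between any two
#' lesion-pixel corner points (edge-to-edge, caliper style), `B` is the
#' extent of the corner points projected onto the direction perpendicular
#' to the `A` chord, and `C` is the number of slices containing lesion
#' voxels times the slice thickness. All lengths are in mm.
#'
#' @param mask A non-empty [ich_mask] or binary 3-D array.
#' @param spacing_mm Voxel spacing; taken from the mask when omitted.
#' @return A list of class `coniglobus`: `A_mm`, `B_mm`, `C_mm`,
#'   `slice_index`, `n_components`, `multifocal`.
#' @export
coniglobus_abc <- function(mask, spacing_mm = NULL) {
  lab <- mask_labels(mask)
  sp <- mask_spacing(mask, spacing_mm)
  lc <- largest_component(lab)
  comp <- lc$comp
  areas <- apply(comp, 3, sum)
  k <- which.max(areas)  # ties -> lowest slice index
  sl <- comp[, , k]
  px <- which(sl != 0, arr.ind = TRUE)
  # corner points of lesion pixels, caliper-style edge-to-edge, in mm
  ctr_x <- (px[, 1] - 0.5) * sp[1]
  ctr_y <- (px[, 2] - 0.5) * sp[2]
  corners <- rbind(
    cbind(ctr_x - sp[1] / 2, ctr_y - sp[2] / 2),
    cbind(ctr_x + sp[1] / 2, ctr_y - sp[2] / 2),
    cbind(ctr_x - sp[1] / 2, ctr_y + sp[2] / 2),
    cbind(ctr_x + sp[1] / 2, ctr_y + sp[2] / 2)
  )
  corners <- unique(round(corners, 9))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  dm <- as.matrix(stats::dist(hull))
  far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  A <- dm[far[1], far[2]]
  if (A == 0) {
    # degenerate single-point slice cannot happen (pixels have 4 corners)
    u <- c(1, 0)
  } else {
    u <- (hull[far[2], ] - hull[far[1], ]) / A
  }
  perp <- c(-u[2], u[1])
  proj <- hull %*% perp
  B <- max(proj) - min(proj)
  C <- sum(areas > 0) * sp[3]
  structure(
    list(A_mm = A, B_mm = B, C_mm = C, slice_index = k,
         n_components = lc$n, multifocal = lc$n > 1),
    class = "coniglobus"
  )
}

#' @export
print.coniglobus <- function(x, ...) {
  cat(sprintf("<coniglobus> A %.2f mm, B %.2f mm, C %.2f mm (slice %d)%s\n",
              x$A_mm, x$B_mm, x$C_mm, x$slice_index,
              ifelse(x$multifocal,
                     sprintf(" [multifocal: %d components, largest used]",
                             x$n_components), "")))
  invisible(x)
}

#' Coniglobus A x B x C / 2 volume, in mL
#'
#' @param m A `coniglobus` measurement, or a mask (then measured first).
#' @param spacing_mm Spacing, when `m` is a mask.
#' @return Volume in mL.
#' @export
coniglobus_volume <- function(m, spacing_mm = NULL) {
  if (!inherits(m, "coniglobus")) m <- coniglobus_abc(m, spacing_mm)
  m$A_mm * m$B_mm * m$C_mm / 2 / 1000
}

#' Intraclass correlation between two measurement methods
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(2,1)) computed from the ANOVA mean squares of the n x 2
#' subject-by-method table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2`.
#'
#' @param x,y Paired per-case measurements (n >= 3).
#' @return A list of class `hemseg_icc`: `icc`, `variant`, mean squares,
#'   `n`, `k`.
#' @export
icc_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired.")
  n <- length(x)
  if (n < 3) stop("ICC needs at least 3 paired cases.")
  m <- cbind(x, y)
  k <- 2L
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (den == 0) NA_real_ else (msr - mse) / den
  structure(
    list(icc = icc, variant = "ICC(2,1) two-way random, absolute agreement",
         msr = msr, msc = msc, mse = mse, n = n, k = k,
         degenerate = den == 0),
    class = "hemseg_icc"
  )
}

#' @export
print.hemseg_icc <- function(x, ...) {
  cat(sprintf("<hemseg_icc> %s: %.4f (n = %d)\n", x$variant, x$icc, x$n))
  invisible(x)
}

#' @export
tidy.hemseg_icc <- function(x, ...) {
  tibble::tibble(term = c("subjects", "methods", "residual"),
                 mean_square = c(x$msr, x$msc, x$mse))
}

#' @export
glance.hemseg_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, variant = x$variant, n = x$n, k = x$k,
                 degenerate = x$degenerate)
}

#' Ordinary least squares agreement of a method against reference volumes
#'
#' Fits `y ~ x` (method volume against reference volume) by OLS and
#' reports slope, intercept and the coefficient of determination.
#'
#' @param x Reference (ground-truth) volumes, n >= 3.
#' @param y Method volumes.
#' @return A list of class `hemseg_regression` wrapping the `lm` fit with
#'   `slope`, `intercept`, `r_squared`.
#' @export
regression_consistency <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired.")
  if (length(x) < 3) stop("Regression needs at least 3 paired cases.")
  if (sd(x) == 0) stop("Reference volumes have zero variance.")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  # direct R^2 (summary.lm warns on exact fits, which are routine here)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(fit = fit,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r2),
    class = "hemseg_regression"
  )
}

#' @export
print.hemseg_regression <- function(x, ...) {
  cat(sprintf("<hemseg_regression> slope %.4f, intercept %.4f, r^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
tidy.hemseg_regression <- function(x, ...) generics::tidy(x$fit, ...)

#' @export
glance.hemseg_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared)
}

#' Per-case volume report and method-agreement summary
#'
#' For each case computes the reference voxel-count volume (V-GT, from the
#' ground-truth mask), the model voxel-count volume (from the predicted
#' mask), and the automated Coniglobus volume (from the ground-truth mask,
#' emulating the clinical measurement), then summarises the agreement of
#' each method against V-GT by ICC and OLS regression.
#'
#' @param gt_masks,pred_masks Named lists of aligned masks over the same
#'   case set.
#' @param spacing_mm Shared spacing override; per-mask spacing otherwise.
#' @return A list of class `consistency_report`: `cases` (tibble:
#'   case_id, v_gt_ml, v_model_ml, v_coniglobus_ml, and per-method
#'   differences) and `agreement` (tibble: method, icc, slope, intercept,
#'   r_squared).
#' @export
consistency_report <- function(gt_masks, pred_masks, spacing_mm = NULL) {
  ids <- names(gt_masks)
  missing <- setdiff(ids, names(pred_masks))
  if (length(missing)) {
    stop("Missing predictions for cases: ", paste(missing, collapse = ", "))
  }
  cases <- purrr::map_dfr(ids, function(id) {
    g <- gt_masks[[id]]; p <- pred_masks[[id]]
    vg <- mask_volume_ml(g, spacing_mm)
    vm <- mask_volume_ml(p, spacing_mm)
    vc <- coniglobus_volume(g, spacing_mm)
    tibble::tibble(case_id = id, v_gt_ml = vg, v_model_ml = vm,
                   v_coniglobus_ml = vc,
                   model_diff_ml = vm - vg, coniglobus_diff_ml = vc - vg)
  })
  agree <- purrr::map_dfr(
    list(model = cases$v_model_ml, coniglobus = cases$v_coniglobus_ml),
    function(v) {
      ic <- icc_agreement(cases$v_gt_ml, v)
      rg <- regression_consistency(cases$v_gt_ml, v)
      tibble::tibble(icc = ic$icc, slope = rg$slope,
                     intercept = rg$intercept, r_squared = rg$r_squared)
    }, .id = "method")
  structure(list(cases = cases, agreement = agree),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %d cases\n", nrow(x$cases)))
  print(x$agreement)
  invisible(x)
}

#' @export
tidy.consistency_report <- function(x, ...) x$cases

#' @export
glance.consistency_report <- function(x, ...) x$agreement

#' @export
autoplot.consistency_report <- function(object, ...) {
  long <- object$cases |>
    tidyr::pivot_longer(c("v_model_ml", "v_coniglobus_ml"),
                        names_to = "method", values_to = "volume_ml") |>
    dplyr::mutate(method = dplyr::recode(.data$method,
                                         v_model_ml = "model",
                                         v_coniglobus_ml = "Coniglobus"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$v_gt_ml,
                                     y = .data$volume_ml,
                                     colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "reference volume V-GT (mL)",
                  y = "measured volume (mL)",
                  title = "Volume agreement against V-GT") +
    ggplot2::theme_minimal()
}
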