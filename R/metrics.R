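#' Voxelwise confusion counts between predicted and reference masks
#'
#' @param pred,gt Binary masks ([ich_mask] or 3-D 0/1 arrays) of identical
#'   shape.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt) {
  p <- mask_labels(pred)
  g <- mask_labels(gt)
  if (!identical(dim(p), dim(g))) {
    stop("Prediction and reference masks have different shapes.")
  }
  p <- p != 0
  g <- g != 0
  structure(
    list(tp = sum(p & g), fp = sum(p & !g),
         fn = sum(!p & g), tn = sum(!p & !g)),
    class = "confusion_counts"
  )
}

#' Overlap metrics from confusion counts
#'
#' Dice `= 2TP / (FP + 2TP + FN)`, IoU `= TP / (FP + TP + FN)`,
#' sensitivity `= TP / (TP + FN)`, and PPV `= TP / (TP + FP)`. When both
#' masks are empty every metric is defined as 1 and flagged degenerate;
#' a 0/0 with a non-empty counterpart is returned as `NA` with the flag.
#'
#' @param cc A `confusion_counts` object (or list with tp/fp/fn/tn).
#' @return One-row tibble: `dice`, `iou`, `sensitivity`, `ppv`,
#'   `degenerate`.
#' @export
overlap_metrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn
  both_empty <- (tp + fp + fn) == 0
  ratio <- function(num, den) {
    if (both_empty) 1 else if (den == 0) NA_real_ else num / den
  }
  tibble::tibble(
    dice = ratio(2 * tp, fp + 2 * tp + fn),
    iou = ratio(tp, fp + tp + fn),
    sensitivity = ratio(tp, tp + fn),
    ppv = ratio(tp, tp + fp),
    degenerate = both_empty || (tp + fn) == 0 || (tp + fp) == 0
  )
}

#' Surface points of a binary mask, in millimetres
#'
#' A lesion voxel belongs to the surface when at least one of its six
#' face-adjacent neighbours is background, or when it lies on the array
#' boundary. Voxel centres are scaled by the voxel spacing into mm.
#'
#' @param mask An [ich_mask] or binary 3-D array.
#' @param spacing_mm Voxel spacing `(X, Y, T)`; taken from the mask when
#'   omitted.
#' @return Numeric matrix (n x 3) of surface-voxel centres in mm; zero
#'   rows for an empty mask.
#' @export
surface_points <- function(mask, spacing_mm = NULL) {
  lab <- mask_labels(mask)
  sp <- mask_spacing(mask, spacing_mm)
  d <- dim(lab)
  idx <- surface_voxels_cpp(as.integer(lab != 0), d[1], d[2], d[3])
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 3))
  cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2], (idx[, 3] - 1) * sp[3])
}

#' 95% Hausdorff surface distance in millimetres
#'
#' Directed distances are nearest-neighbour distances between the two
#' surface point sets. In `percentile95` mode (the default) the statistic
#' is the larger of the two directed 95th percentiles
#' (linear-interpolation percentile), which suppresses the influence of a
#' small subset of outlier surface points. `scaled95` instead takes the
#' literal reading 0.95 x the exact Hausdorff distance. Both modes are
#' symmetric in their arguments.
#'
#' @param gt,pred Non-empty binary masks of identical shape.
#' @param spacing_mm Voxel spacing `(X, Y, T)`; taken from `gt` when
#'   omitted.
#' @param mode `"percentile95"` or `"scaled95"`.
#' @return Distance in mm, or `NA` with a warning-free degenerate flag via
#'   [evaluate_case()] when either mask is empty.
#' @export
hd95 <- function(gt, pred, spacing_mm = NULL,
                 mode = c("percentile95", "scaled95")) {
  mode <- match.arg(mode)
  sp <- mask_spacing(gt, spacing_mm)
  G <- surface_points(gt, sp)
  P <- surface_points(pred, sp)
  if (nrow(G) == 0 || nrow(P) == 0) return(NA_real_)
  d_gp <- nn_dists_cpp(G, P)
  d_pg <- nn_dists_cpp(P, G)
  if (mode == "percentile95") {
    max(quantile(d_gp, 0.95, names = FALSE, type = 7),
        quantile(d_pg, 0.95, names = FALSE, type = 7))
  } else {
    0.95 * max(max(d_gp), max(d_pg))
  }
}

#' Evaluate one segmented case against its reference
#'
#' Confusion counts are pooled over the full 3-D stack and HD95 is
#' computed on 3-D surface points in mm, giving one row of metrics per
#' case.
#'
#' @param pred,gt Aligned binary masks.
#' @param spacing_mm Voxel spacing; taken from `gt` when omitted.
#' @param case_id Case identifier for the report row.
#' @param hd_mode HD95 mode passed to [hd95()].
#' @return One-row tibble: `case_id`, `dice`, `iou`, `sensitivity`, `ppv`,
#'   `hd95_mm`, `degenerate`.
#' @export
evaluate_case <- function(pred, gt, spacing_mm = NULL, case_id = NULL,
                          hd_mode = "percentile95") {
  if (is.null(case_id)) {
    case_id <- if (inherits(gt, "ich_mask")) gt$case_id else NA_character_
  }
  cc <- confusion_counts(pred, gt)
  om <- overlap_metrics(cc)
  h <- hd95(gt, pred, spacing_mm, mode = hd_mode)
  tibble::tibble(case_id = case_id, om[, c("dice", "iou", "sensitivity",
                                           "ppv")],
                 hd95_mm = h,
                 degenerate = om$degenerate || is.na(h))
}

#' Evaluate a cohort of predictions
#'
#' @param pred_masks,gt_masks Named lists of aligned masks (identical case
#'   sets).
#' @param spacing_mm Shared spacing override; per-mask spacing otherwise.
#' @param hd_mode HD95 mode passed to [hd95()].
#' @return A tibble with one row per case (as [evaluate_case()]).
#' @export
evaluate_cohort <- function(pred_masks, gt_masks, spacing_mm = NULL,
                            hd_mode = "percentile95") {
  ids <- names(gt_masks)
  missing <- setdiff(ids, names(pred_masks))
  extra <- setdiff(names(pred_masks), ids)
  if (length(missing) || length(extra)) {
    stop("Case sets differ. Missing predictions: ",
         paste(missing, collapse = ", "), "; unmatched predictions: ",
         paste(extra, collapse = ", "))
  }
  purrr::map_dfr(ids, function(id) {
    evaluate_case(pred_masks[[id]], gt_masks[[id]], spacing_mm,
                  case_id = id, hd_mode = hd_mode)
  })
}

#' Cohort summary of per-case metrics
#'
#' Unweighted means per metric; undefined (NA) values are excluded from
#' the mean with the number of exclusions reported.
#'
#' @param reports Tibble of per-case rows from [evaluate_case()] /
#'   [evaluate_cohort()].
#' @return Tibble with one row per metric: `metric`, `mean`, `sd`, `n`,
#'   `n_excluded`.
#' @export
aggregate_metrics <- function(reports) {
  reports |>
    dplyr::select(dplyr::any_of(c("dice", "iou", "sensitivity", "ppv",
                                  "hd95_mm"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      n_excluded = sum(is.na(.data$value)),
      .groups = "drop"
    )
}

#' Violin plot of per-case segmentation metrics
#'
#' @param object Tibble of per-case rows from [evaluate_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_metric_distribution <- function(object, ...) {
  long <- object |>
    dplyr::select(dplyr::any_of(c("dice", "iou", "sensitivity", "ppv"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "per-case value",
                  title = "Segmentation metric distribution") +
    ggplot2::theme_minimal()
}
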