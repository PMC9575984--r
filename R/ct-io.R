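#' Read a CT case or hemorrhage mask from NIfTI
#'
#' Reads a NIfTI volume (optionally gzipped) into a [ct_volume] with the
#' voxel spacing taken from the file header (`pixdim`). DICOM series are
#' not supported: pass a NIfTI file converted upstream.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param case_id Case identifier; defaults to the file name stem.
#' @return A [ct_volume] (for `read_case`) or [ich_mask] (for `read_mask`).
#' @export
read_case <- function(path, case_id = NULL) {
  if (dir.exists(path)) {
    stop("`", path, "` is a directory. DICOM series input is not supported; ",
         "convert the series to NIfTI and pass the file path.")
  }
  if (!file.exists(path)) stop("No such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop("NIfTI header of ", path, " has missing or non-positive voxel spacing.")
  }
  if (is.null(case_id)) case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  arr <- array(as.numeric(img), dim(img))
  ct_volume(arr, spacing_mm = sp[1:3], case_id = case_id)
}

#' @rdname read_case
#' @export
read_mask <- function(path, case_id = NULL) {
  vol <- read_case(path, case_id = case_id)
  ich_mask(round(vol$voxels), spacing_mm = vol$spacing_mm, case_id = vol$case_id)
}

#' Write a CT volume or mask to NIfTI
#'
#' @param x A [ct_volume] or [ich_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    arr <- x$voxels
  } else if (inherits(x, "ich_mask")) {
    arr <- x$labels
  } else {
    stop("`x` must be a ct_volume or ich_mask.")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample slices in-plane to a target matrix size
#'
#' Each axial slice is resampled to `target` x `target`. The in-plane
#' spacing is rescaled so the physical field of view is preserved. Images
#' use bilinear interpolation; masks use nearest-neighbour so labels stay
#' binary.
#'
#' @param x A [ct_volume] or [ich_mask].
#' @param target In-plane matrix size (default 512).
#' @return The resampled object with updated spacing.
#' @export
resample_inplane <- function(x, target = 512L) {
  target <- as.integer(target)
  if (is.na(target) || target < 16L) stop("`target` must be at least 16.")
  is_mask <- inherits(x, "ich_mask")
  arr <- if (is_mask) x$labels else x$voxels
  d <- dim(arr)
  if (d[1] == target && d[2] == target) return(x)
  filt <- if (is_mask) "none" else "bilinear"
  out <- EBImage::resize(arr, w = target, h = target, filter = filt)
  out <- array(out, c(target, target, d[3]))
  sp <- x$spacing_mm
  sp_new <- c(sp[1] * d[1] / target, sp[2] * d[2] / target, sp[3])
  if (is_mask) {
    ich_mask(round(out), spacing_mm = sp_new, case_id = x$case_id)
  } else {
    y <- ct_volume(out, spacing_mm = sp_new, case_id = x$case_id, units = x$units)
    y$padding <- x$padding
    y
  }
}

#' Hounsfield windowing and normalization
#'
#' Clips voxel values to the hemorrhage window `[lo, hi]` HU and maps the
#' window linearly onto `[0, 1]`. The default window of -60 to 140 HU covers
#' the CT value range in which acute intracerebral hemorrhage concentrates.
#' The map is monotone non-decreasing and idempotent once data are expressed
#' in window units.
#'
#' @param vol A [ct_volume] in HU.
#' @param lo,hi Window bounds in HU (`lo < hi`).
#' @return A normalized [ct_volume] (`units = "normalized"`).
#' @export
window_normalize <- function(vol, lo = -60, hi = 140) {
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume.")
  if (!(lo < hi)) stop("Window bounds must satisfy lo < hi.")
  v <- pmin(pmax(vol$voxels, lo), hi)
  v <- (v - lo) / (hi - lo)
  out <- ct_volume(array(v, dim(vol$voxels)), spacing_mm = vol$spacing_mm,
                   case_id = vol$case_id, units = "normalized")
  out$padding <- vol$padding
  out$window_hu <- c(lo, hi)
  out
}

slice_head_scores <- function(arr, air_hu) {
  # per-slice head content: mean intensity excess above the air threshold
  apply(pmax(arr - air_hu, 0), 3, mean)
}

#' Select a fixed number of axial slices
#'
#' Reduces (or pads) a stack to exactly `n` slices. When the stack is
#' longer than `n`, the contiguous window of `n` slices with the largest
#' total head score is kept, where a slice's score is its mean intensity
#' excess above an air threshold; this localizes the head and discards
#' chest/abdomen slices. When the stack is shorter, air slices
#' (-1000 HU) are padded at both stack ends (extra slice at the top) and
#' recorded in the `padding` field.
#'
#' @param vol A [ct_volume] in HU.
#' @param n Number of slices to keep (default 40).
#' @param air_hu Air threshold in HU (default -500).
#' @return A [ct_volume] with exactly `n` slices.
#' @export
select_slices <- function(vol, n = 40L, air_hu = -500) {
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume.")
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1.")
  arr <- vol$voxels
  L <- dim(arr)[3]
  if (L == n) return(vol)
  if (L > n) {
    sc <- slice_head_scores(arr, air_hu)
    win <- vapply(seq_len(L - n + 1L), function(s) sum(sc[s:(s + n - 1L)]),
                  numeric(1))
    s <- which.max(win)  # ties -> lowest start index
    out <- ct_volume(arr[, , s:(s + n - 1L), drop = FALSE],
                     spacing_mm = vol$spacing_mm, case_id = vol$case_id,
                     units = vol$units)
    out$slice_window <- c(s, s + n - 1L)
    return(out)
  }
  d <- n - L
  lo <- d %/% 2L
  hi <- d - lo
  air <- if (vol$units == "HU") -1000 else 0
  pad_lo <- array(air, c(dim(arr)[1:2], lo))
  pad_hi <- array(air, c(dim(arr)[1:2], hi))
  stacked <- array(c(pad_lo, arr, pad_hi), c(dim(arr)[1:2], n))
  out <- ct_volume(stacked, spacing_mm = vol$spacing_mm,
                   case_id = vol$case_id, units = vol$units)
  out$padding <- c(lo, hi)
  out
}

#' Full preprocessing pipeline for one case
#'
#' Applies the standard pipeline: in-plane resampling to a square matrix,
#' head-window slice selection, then Hounsfield windowing and
#' normalization.
#'
#' @inheritParams window_normalize
#' @inheritParams resample_inplane
#' @inheritParams select_slices
#' @return A normalized [ct_volume] of shape `target x target x n`.
#' @export
preprocess_case <- function(vol, target = 512L, n = 40L, lo = -60, hi = 140) {
  vol |>
    resample_inplane(target = target) |>
    select_slices(n = n) |>
    window_normalize(lo = lo, hi = hi)
}
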