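#' CT volume and hemorrhage mask containers
#'
#' A `ct_volume` wraps a 3-D voxel array together with its physical voxel
#' spacing. Arrays follow the R neuroimaging convention: dimensions are
#' `(rows, cols, slices)` with the axial slice along the third axis, and
#' `spacing_mm = c(X, Y, T)` gives the in-plane voxel spacing `X`, `Y` and
#' the slice thickness `T` in millimetres. Voxel values are either
#' Hounsfield units (`units = "HU"`) or window-normalized to `[0, 1]`
#' (`units = "normalized"`).
#'
#' @param voxels 3-D numeric array, dim `(rows, cols, slices)`.
#' @param spacing_mm Length-3 positive numeric `(X, Y, T)` in mm.
#' @param case_id Optional case identifier.
#' @param units `"HU"` or `"normalized"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, case_id = NA_character_,
                      units = c("HU", "normalized")) {
  units <- match.arg(units)
  voxels <- as_vox_array(voxels)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three positive values (X, Y, T) in mm.")
  }
  if (dim(voxels)[3] < 1) stop("A CT volume needs at least one slice.")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         case_id = case_id, units = units, padding = c(0L, 0L)),
    class = "ct_volume"
  )
}

#' @param labels 3-D array of 0/1 labels aligned to a companion `ct_volume`.
#' @rdname ct_volume
#' @export
ich_mask <- function(labels, spacing_mm, case_id = NA_character_) {
  labels <- as_vox_array(labels)
  vals <- unique(as.vector(labels))
  if (!all(vals %in% c(0, 1))) {
    stop("Mask labels must be binary (0/1); found other values.")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three positive values (X, Y, T) in mm.")
  }
  structure(
    list(labels = array(as.integer(labels), dim(labels)),
         spacing_mm = spacing_mm, case_id = case_id),
    class = "ich_mask"
  )
}

as_vox_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3) {
    stop("Voxel data must be a 3-D array (rows, cols, slices).")
  }
  x
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %s: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, %s\n",
              ifelse(is.na(x$case_id), "(unnamed)", x$case_id),
              d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3], x$units))
  invisible(x)
}

#' @export
print.ich_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<ich_mask> %s: %d x %d x %d voxels, %d foreground, spacing (%.3g, %.3g, %.3g) mm\n",
              ifelse(is.na(x$case_id), "(unnamed)", x$case_id),
              d[1], d[2], d[3], sum(x$labels),
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
dim.ich_mask <- function(x) dim(x$labels)

mask_labels <- function(mask) {
  if (inherits(mask, "ich_mask")) mask$labels else as_vox_array(mask)
}

mask_spacing <- function(mask, spacing_mm = NULL) {
  if (!is.null(spacing_mm)) return(as.numeric(spacing_mm))
  if (inherits(mask, "ich_mask")) return(mask$spacing_mm)
  stop("Supply `spacing_mm` when the mask is a bare array.")
}
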