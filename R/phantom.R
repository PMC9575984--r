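#' Specification of a synthetic head-CT phantom
#'
#' Describes one synthetic case: a head model (air background, elliptical
#' brain inside a skull shell) containing a hyperdense hemorrhage lesion
#' with analytically known geometry. Three shape families are supported:
#' `ellipsoid` (a single, possibly rotated ellipsoid), `lobulated` (a union
#' of 2-4 overlapping rotated ellipsoid lobes - a markedly non-ellipsoid
#' shape), and `multifocal` (two disjoint ellipsoids).
#'
#' Defaults mirror the acquisition regime the package targets: a 512 x 512
#' matrix, 40 axial slices, 4.0 mm slice thickness, and a hematoma
#' attenuation inside the -60 to 140 HU hemorrhage window.
#'
#' @param shape_family `"ellipsoid"`, `"lobulated"`, or `"multifocal"`.
#' @param semi_axes_mm Positive semi-axis lengths in mm. A length-3 vector,
#'   or a list of length-3 vectors (one per lobe) for lobulated/multifocal
#'   shapes.
#' @param lobe_offsets_mm List of 3-vectors: each lobe's centre offset from
#'   `center_mm` (empty for a single ellipsoid).
#' @param center_mm Lesion centre in mm relative to the volume centre.
#' @param rotation_deg In-plane rotation of each lobe in degrees (recycled).
#' @param hu_levels Named list with `background`, `brain`, `hematoma`,
#'   `skull` attenuation levels (HU). Brain must lie in \[20, 40\] and the
#'   hematoma level inside the \[-60, 140\] hemorrhage window.
#' @param noise_sd_hu Additive Gaussian HU noise standard deviation (>= 0).
#' @param matrix In-plane matrix size (default 512).
#' @param n_slices Number of axial slices (default 40).
#' @param spacing_mm Voxel spacing `(X, Y, T)` mm; default `c(0.45, 0.45, 4)`.
#' @param seed Integer seed governing all randomness for this case.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_family = c("ellipsoid", "lobulated", "multifocal"),
                         semi_axes_mm = c(15, 12, 10),
                         lobe_offsets_mm = NULL,
                         center_mm = c(0, 0, 0),
                         rotation_deg = 0,
                         hu_levels = list(background = -1000, brain = 30,
                                          hematoma = 70, skull = 1000),
                         noise_sd_hu = 5,
                         matrix = 512L,
                         n_slices = 40L,
                         spacing_mm = c(0.45, 0.45, 4.0),
                         seed = 1L) {
  shape_family <- match.arg(shape_family)
  if (!is.list(semi_axes_mm)) semi_axes_mm <- list(as.numeric(semi_axes_mm))
  semi_axes_mm <- lapply(semi_axes_mm, as.numeric)
  if (any(vapply(semi_axes_mm, length, 1L) != 3) ||
      any(unlist(semi_axes_mm) <= 0)) {
    stop("Each lobe needs three positive semi-axes (mm).")
  }
  if (is.null(lobe_offsets_mm)) {
    lobe_offsets_mm <- if (shape_family == "ellipsoid") {
      list(c(0, 0, 0))
    } else {
      stop("lobulated/multifocal shapes require `lobe_offsets_mm`.")
    }
  }
  if (!is.list(lobe_offsets_mm)) lobe_offsets_mm <- list(lobe_offsets_mm)
  n_lobes <- length(lobe_offsets_mm)
  if (shape_family == "ellipsoid" && n_lobes != 1) {
    stop("An ellipsoid phantom has exactly one lobe.")
  }
  if (shape_family == "lobulated" && (n_lobes < 2 || n_lobes > 4)) {
    stop("A lobulated phantom has 2-4 lobes.")
  }
  if (shape_family == "multifocal" && n_lobes != 2) {
    stop("A multifocal phantom has exactly 2 foci.")
  }
  semi_axes_mm <- rep_len(semi_axes_mm, n_lobes)
  rotation_deg <- rep_len(as.numeric(rotation_deg), n_lobes)
  if (hu_levels$hematoma < -60 || hu_levels$hematoma > 140) {
    stop("Hematoma HU level must lie inside the [-60, 140] hemorrhage window.")
  }
  if (hu_levels$brain < 20 || hu_levels$brain > 40) {
    stop("Brain HU level must lie in [20, 40].")
  }
  if (noise_sd_hu < 0) stop("`noise_sd_hu` must be >= 0.")
  matrix <- as.integer(matrix); n_slices <- as.integer(n_slices)
  if (matrix < 16L || n_slices < 1L) stop("Invalid matrix / n_slices.")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three positive values (X, Y, T).")
  }
  spec <- structure(
    list(shape_family = shape_family, semi_axes_mm = semi_axes_mm,
         lobe_offsets_mm = lapply(lobe_offsets_mm, as.numeric),
         center_mm = as.numeric(center_mm), rotation_deg = rotation_deg,
         hu_levels = hu_levels, noise_sd_hu = noise_sd_hu,
         matrix = matrix, n_slices = n_slices, spacing_mm = spacing_mm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  check_lesion_fits(spec)
  spec
}

# Brain semi-axes of the head model, in mm, from the field of view.
brain_semi_axes <- function(spec) {
  ext <- c(spec$matrix, spec$matrix, spec$n_slices) * spec$spacing_mm
  c(0.40 * ext[1], 0.40 * ext[2], 0.45 * ext[3])
}

# Sufficient containment check. In the coordinates where the brain
# ellipsoid is the unit ball (scaling D = diag(1/b)), a lobe point is
# c + R diag(a) u with |u| <= 1, so the lobe lies inside whenever
# |D c| + sigma_max(D R diag(a)) <= 1 (triangle inequality + operator
# norm).
check_lesion_fits <- function(spec) {
  b <- brain_semi_axes(spec)
  for (i in seq_along(spec$lobe_offsets_mm)) {
    ctr <- spec$center_mm + spec$lobe_offsets_mm[[i]]
    ax <- spec$semi_axes_mm[[i]]
    th <- spec$rotation_deg[i] * pi / 180
    R3 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    M <- diag(1 / b) %*% R3 %*% diag(ax)
    if (sqrt(sum((ctr / b)^2)) + max(svd(M, nu = 0, nv = 0)$d) > 1) {
      stop("Lesion lobe ", i, " extends outside the brain region of the ",
           "field of view; shrink the lesion or enlarge the volume.")
    }
  }
  invisible(TRUE)
}

# Membership of points (n x 3 matrix, mm) in any lesion lobe.
lesion_membership <- function(pts, spec) {
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_along(spec$lobe_offsets_mm)) {
    ctr <- spec$center_mm + spec$lobe_offsets_mm[[i]]
    ax <- spec$semi_axes_mm[[i]]
    th <- spec$rotation_deg[i] * pi / 180
    dx <- pts[, 1] - ctr[1]; dy <- pts[, 2] - ctr[2]; dz <- pts[, 3] - ctr[3]
    # rotate into the lobe frame (in-plane rotation about the lobe centre)
    rx <- cos(th) * dx + sin(th) * dy
    ry <- -sin(th) * dx + cos(th) * dy
    inside <- inside | ((rx / ax[1])^2 + (ry / ax[2])^2 + (dz / ax[3])^2 <= 1)
  }
  inside
}

# mm coordinates of voxel centres relative to the volume centre.
voxel_centres <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

#' Generate one synthetic head-CT case
#'
#' Builds the HU image and binary lesion mask for a [phantom_spec]. A voxel
#' belongs to the mask exactly when its centre lies inside the lesion
#' geometry (the way expert delineations rasterize). The ground-truth
#' volume is the closed-form ellipsoid volume for single ellipsoids and a
#' 4x-per-axis supersampled voxelization for lobulated and multifocal
#' shapes.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `volume` ([ct_volume], HU), `mask`
#'   ([ich_mask]), `analytic_volume_ml`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$matrix; L <- spec$n_slices; sp <- spec$spacing_mm
  xs <- voxel_centres(n, sp[1])
  ys <- voxel_centres(n, sp[2])
  zs <- voxel_centres(L, sp[3])
  b <- brain_semi_axes(spec)
  hu <- spec$hu_levels

  vox <- array(hu$background, c(n, n, L))
  lab <- array(0L, c(n, n, L))
  inplane <- cbind(rep(xs, times = n), rep(ys, each = n))
  for (k in seq_len(L)) {
    pts <- cbind(inplane, zs[k])
    e <- (pts[, 1] / b[1])^2 + (pts[, 2] / b[2])^2 + (pts[, 3] / b[3])^2
    sl <- rep(hu$background, n * n)
    sl[e <= 1.17] <- hu$skull          # skull shell: 1 < norm^2 <= ~1.08^2
    sl[e <= 1] <- hu$brain
    les <- lesion_membership(pts, spec)
    sl[les] <- hu$hematoma
    vox[, , k] <- sl
    lab[, , k] <- as.integer(les)
  }

  if (spec$noise_sd_hu > 0) {
    vox <- with_seed(spec$seed, {
      v <- vox + rnorm(length(vox), sd = spec$noise_sd_hu)
      pmin(pmax(v, -1024), 3071)
    })
    vox <- array(vox, c(n, n, L))
  }

  case_id <- sprintf("phantom_%s_%06d", spec$shape_family, spec$seed)
  list(
    volume = ct_volume(vox, spacing_mm = sp, case_id = case_id),
    mask = ich_mask(lab, spacing_mm = sp, case_id = case_id),
    analytic_volume_ml = analytic_volume_ml(spec),
    spec = spec
  )
}

#' Analytic lesion volume of a phantom spec, in mL
#'
#' Closed form `4/3 * pi * a * b * c / 1000` for a single ellipsoid;
#' supersampled voxelization (4 subdivisions per axis over the lesion
#' bounding box) for lobulated and multifocal shapes.
#'
#' @param spec A [phantom_spec].
#' @return Volume in mL.
#' @export
analytic_volume_ml <- function(spec) {
  if (spec$shape_family == "ellipsoid") {
    ax <- spec$semi_axes_mm[[1]]
    return(4 / 3 * pi * prod(ax) / 1000)
  }
  # bounding box of all lobes, in mm
  lims <- sapply(1:3, function(k) {
    los <- vapply(seq_along(spec$lobe_offsets_mm), function(i) {
      spec$center_mm[k] + spec$lobe_offsets_mm[[i]][k] - max(spec$semi_axes_mm[[i]])
    }, 1)
    his <- vapply(seq_along(spec$lobe_offsets_mm), function(i) {
      spec$center_mm[k] + spec$lobe_offsets_mm[[i]][k] + max(spec$semi_axes_mm[[i]])
    }, 1)
    c(min(los), max(his))
  })
  sub <- spec$spacing_mm / 4
  grids <- lapply(1:3, function(k) {
    seq(lims[1, k] + sub[k] / 2, lims[2, k] - sub[k] / 2, by = sub[k])
  })
  nvox <- 0
  inplane <- cbind(rep(grids[[1]], times = length(grids[[2]])),
                   rep(grids[[2]], each = length(grids[[1]])))
  for (z in grids[[3]]) {
    nvox <- nvox + sum(lesion_membership(cbind(inplane, z), spec))
  }
  nvox * prod(sub) / 1000
}

#' Generate a reproducible cohort of phantom cases
#'
#' Draws case specs from seeded parameter ranges, writes each image and
#' mask as NIfTI, and returns (and writes) a manifest tibble.
#'
#' @param n_cases Number of cases (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-case seeds are derived from it.
#' @param shape `"ellipsoid"`, `"lobulated"`, `"multifocal"`, or `"mixed"`.
#' @param matrix,n_slices,spacing_mm Acquisition geometry for every case.
#' @param semi_axes_range Range (mm) the per-axis lesion semi-axes are drawn
#'   from, uniformly.
#' @param noise_sd_hu HU noise level applied to every case.
#' @return A tibble manifest with one row per case: `case_id`,
#'   `shape_family`, `seed`, `analytic_volume_ml`, `image_path`, `mask_path`.
#' @export
generate_cohort <- function(n_cases, out_dir, seed = 1L,
                            shape = c("mixed", "ellipsoid", "lobulated",
                                      "multifocal"),
                            matrix = 512L, n_slices = 40L,
                            spacing_mm = c(0.45, 0.45, 4.0),
                            semi_axes_range = c(10, 22),
                            noise_sd_hu = 5) {
  shape <- match.arg(shape)
  if (n_cases < 1) stop("`n_cases` must be at least 1.")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("Cannot create output directory: ", out_dir)
  }
  specs <- draw_cohort_specs(n_cases, seed, shape, matrix, n_slices,
                             spacing_mm, semi_axes_range, noise_sd_hu)
  rows <- purrr::imap(specs, function(spec, i) {
    case <- generate_phantom(spec)
    cid <- sprintf("case_%03d", i)
    ipath <- file.path(out_dir, paste0(cid, "_image.nii.gz"))
    mpath <- file.path(out_dir, paste0(cid, "_mask.nii.gz"))
    write_nifti(case$volume, ipath)
    write_nifti(case$mask, mpath)
    tibble::tibble(
      case_id = cid, shape_family = spec$shape_family, seed = spec$seed,
      semi_a_mm = spec$semi_axes_mm[[1]][1],
      semi_b_mm = spec$semi_axes_mm[[1]][2],
      semi_c_mm = spec$semi_axes_mm[[1]][3],
      n_lobes = length(spec$lobe_offsets_mm),
      analytic_volume_ml = case$analytic_volume_ml,
      image_path = ipath, mask_path = mpath
    )
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

# Seeded draw of cohort specs; deterministic for a given seed.
draw_cohort_specs <- function(n_cases, seed, shape, matrix, n_slices,
                              spacing_mm, semi_axes_range, noise_sd_hu) {
  b <- brain_semi_axes(list(matrix = matrix, n_slices = n_slices,
                            spacing_mm = spacing_mm))
  with_seed(seed, {
    lapply(seq_len(n_cases), function(i) {
      # redraw (deterministically, consuming the RNG stream) until the
      # lesion fits inside the brain region
      for (attempt in 1:100) {
        spec <- try(draw_one_spec(shape, matrix, n_slices, spacing_mm,
                                  semi_axes_range, noise_sd_hu, b),
                    silent = TRUE)
        if (!inherits(spec, "try-error")) return(spec)
      }
      stop("Could not draw a lesion that fits the field of view; ",
           "shrink `semi_axes_range` or enlarge the volume.")
    })
  })
}

draw_one_spec <- function(shape, matrix, n_slices, spacing_mm,
                          semi_axes_range, noise_sd_hu, b) {
  fam <- if (shape == "mixed") {
    sample(c("ellipsoid", "lobulated", "multifocal"), 1)
  } else shape
  ax <- sort(runif(3, semi_axes_range[1], semi_axes_range[2]),
             decreasing = TRUE)
  rot <- runif(1, 0, 180)
  # keep the lesion well inside the brain ellipsoid
  ctr <- runif(3, -1, 1) * pmax(b * 0.35 - max(ax), 0)
  case_seed <- sample.int(.Machine$integer.max - 1L, 1)
  if (fam == "ellipsoid") {
        phantom_spec("ellipsoid", semi_axes_mm = ax, center_mm = ctr,
                     rotation_deg = rot, noise_sd_hu = noise_sd_hu,
                     matrix = matrix, n_slices = n_slices,
                     spacing_mm = spacing_mm, seed = case_seed)
      } else if (fam == "lobulated") {
        n_lobes <- sample(2:4, 1)
        offs <- lapply(seq_len(n_lobes), function(j) {
          if (j == 1) c(0, 0, 0) else runif(3, -0.8, 0.8) * ax
        })
        axs <- lapply(seq_len(n_lobes), function(j) {
          if (j == 1) ax else ax * runif(1, 0.5, 0.9)
        })
        rots <- runif(n_lobes, 0, 180)
        phantom_spec("lobulated", semi_axes_mm = axs, lobe_offsets_mm = offs,
                     center_mm = ctr, rotation_deg = rots,
                     noise_sd_hu = noise_sd_hu, matrix = matrix,
                     n_slices = n_slices, spacing_mm = spacing_mm,
                     seed = case_seed)
      } else {
        gap <- max(ax) * 2.4
        dir3 <- c(1, 0.3, 0) / sqrt(1 + 0.09)
        offs <- list(-dir3 * gap / 2, dir3 * gap / 2)
        axs <- list(ax, ax * 0.6)
        phantom_spec("multifocal", semi_axes_mm = axs, lobe_offsets_mm = offs,
                     center_mm = ctr, rotation_deg = runif(2, 0, 180),
                     noise_sd_hu = noise_sd_hu, matrix = matrix,
                     n_slices = n_slices, spacing_mm = spacing_mm,
                     seed = case_seed)
      }
}
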