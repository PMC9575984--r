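# Shared fixtures, all generated in code.

# A small, fast phantom spec for unit tests.
tiny_sphere_spec <- function(r = 10, spacing = c(0.5, 0.5, 0.5),
                             matrix = 96, n_slices = 64, noise = 0,
                             seed = 7) {
  phantom_spec("ellipsoid", semi_axes_mm = c(r, r, r),
               matrix = matrix, n_slices = n_slices,
               spacing_mm = spacing, noise_sd_hu = noise, seed = seed)
}

# Random blob mask: union of 1-2 random ellipsoids rasterized on a grid.
# Compact surfaces keep brute-force oracles cheap.
random_blob_mask <- function(dims = c(32, 32, 8), n_blobs = NULL) {
  lab <- array(0L, dims)
  if (is.null(n_blobs)) n_blobs <- sample(1:2, 1)
  for (b in seq_len(n_blobs)) {
    ctr <- sapply(dims, function(n) runif(1, 0.25 * n, 0.75 * n))
    ax <- c(runif(2, 2, dims[1] / 3), runif(1, 1, dims[3] / 2))
    g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
    inside <- ((g$i - ctr[1]) / ax[1])^2 + ((g$j - ctr[2]) / ax[2])^2 +
      ((g$k - ctr[3]) / ax[3])^2 <= 1
    lab[as.matrix(g[inside, ])] <- 1L
  }
  lab
}

# Brute-force per-voxel confusion counts (independent of the package path).
oracle_confusion <- function(pred, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else if (gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force surface extraction by explicit neighbour scan.
oracle_surface <- function(lab, spacing) {
  d <- dim(lab)
  pts <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (lab[i, j, k] == 0) next
    nb <- c(
      if (i > 1) lab[i - 1, j, k] else 0L,
      if (i < d[1]) lab[i + 1, j, k] else 0L,
      if (j > 1) lab[i, j - 1, k] else 0L,
      if (j < d[2]) lab[i, j + 1, k] else 0L,
      if (k > 1) lab[i, j, k - 1] else 0L,
      if (k < d[3]) lab[i, j, k + 1] else 0L
    )
    on_boundary <- i == 1 || i == d[1] || j == 1 || j == d[2] ||
      k == 1 || k == d[3]
    if (on_boundary || any(nb == 0)) {
      pts <- rbind(pts, c((i - 1) * spacing[1], (j - 1) * spacing[2],
                          (k - 1) * spacing[3]))
    }
  }
  if (is.null(pts)) matrix(numeric(0), 0, 3) else pts
}

# All-pairs directed-distance HD95 oracle (linear-interpolation percentile).
oracle_hd95 <- function(gt, pred, spacing, mode = "percentile95") {
  G <- oracle_surface(gt, spacing)
  P <- oracle_surface(pred, spacing)
  dm <- sqrt(pmax(outer(rowSums(G^2), rowSums(P^2), "+") - 2 * G %*% t(P), 0))
  d_gp <- apply(dm, 1, min)
  d_pg <- apply(dm, 2, min)
  if (mode == "percentile95") {
    max(quantile(d_gp, 0.95, names = FALSE, type = 7),
        quantile(d_pg, 0.95, names = FALSE, type = 7))
  } else {
    0.95 * max(max(d_gp), max(d_pg))
  }
}
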