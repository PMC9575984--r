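# Low-level differentiable layers. Feature maps are arrays dim (H, W, C).
# Conv weights are matrices (fan_in x C_out); for 3x3 kernels fan_in rows
# follow the im2col column layout r = c*9 + (kw+1)*3 + (kh+1). Biases are
# length C_out. The (HW x fan_in) im2col matrix keeps every GEMM operand
# contiguous.

he_init <- function(fan_in, c_out) {
  matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out)
}

conv3_init <- function(c_in, c_out) {
  list(W = he_init(9 * c_in, c_out), b = numeric(c_out))
}

conv1_init <- function(c_in, c_out) {
  list(W = he_init(c_in, c_out), b = numeric(c_out))
}

conv3_fwd <- function(x, p) {
  d <- dim(x)
  cols <- im2col3_cpp(x, d[1], d[2], d[3])
  outm <- cols %*% p$W
  outm <- outm + rep(p$b, each = d[1] * d[2])
  list(out = array(outm, c(d[1], d[2], ncol(p$W))),
       cache = list(cols = cols, d = d))
}

conv3_bwd <- function(dout, p, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  doutm <- matrix(dout, hw, length(dout) / hw)
  dW <- crossprod(cache$cols, doutm)
  db <- colSums(doutm)
  dcols <- tcrossprod(doutm, p$W)
  dx <- col2im3_cpp(dcols, d[1], d[2], d[3])
  list(dx = dx, dW = dW, db = db)
}

conv1_fwd <- function(x, p) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  outm <- xm %*% p$W
  outm <- outm + rep(p$b, each = d[1] * d[2])
  list(out = array(outm, c(d[1], d[2], ncol(p$W))),
       cache = list(xm = xm, d = d))
}

conv1_bwd <- function(dout, p, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  doutm <- matrix(dout, hw, length(dout) / hw)
  dW <- crossprod(cache$xm, doutm)
  db <- colSums(doutm)
  dx <- array(tcrossprod(doutm, p$W), d)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, cache = m)
}
relu_bwd <- function(dout, cache) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

maxpool_fwd <- function(x) {
  d <- dim(x)
  r <- maxpool2_fwd_cpp(x, d[1], d[2], d[3])
  list(out = r$out, cache = list(idx = r$idx, d = d))
}

maxpool_bwd <- function(dout, cache) {
  maxpool2_bwd_cpp(dout, cache$idx, cache$d[1], cache$d[2], cache$d[3])
}

upsample_fwd <- function(x) {
  d <- dim(x)
  list(out = upsample2_fwd_cpp(x, d[1], d[2], d[3]), cache = d)
}

upsample_bwd <- function(dout, d) upsample2_bwd_cpp(dout, d[1], d[2], d[3])

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

split_c <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), drop = FALSE],
       x[, , (c1 + 1):d[3], drop = FALSE])
}

#' Space-to-depth focus transform
#'
#' Losslessly rearranges a feature map of shape `(H, W, C)` into
#' `(H/2, W/2, 4C)` by sampling with stride 2: the four output channel
#' blocks are the (even, even), (even, odd), (odd, even) and (odd, odd)
#' row/column phase sub-grids, in that fixed order. The transform is a
#' bijection; [focus_inverse()] reconstructs the input exactly.
#'
#' @param x 3-D array `(H, W, C)` with `H` and `W` even.
#' @return Array of shape `(H/2, W/2, 4C)`.
#' @export
focus_transform <- function(x) {
  x <- as_vox_array(x)
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop("focus_transform needs even height and width.")
  }
  H <- d[1]; W <- d[2]; C <- d[3]
  ev_r <- seq(1, H, by = 2); od_r <- seq(2, H, by = 2)
  ev_c <- seq(1, W, by = 2); od_c <- seq(2, W, by = 2)
  out <- array(0, c(H / 2, W / 2, 4 * C))
  out[, , seq_len(C)] <- x[ev_r, ev_c, , drop = FALSE]
  out[, , C + seq_len(C)] <- x[ev_r, od_c, , drop = FALSE]
  out[, , 2 * C + seq_len(C)] <- x[od_r, ev_c, , drop = FALSE]
  out[, , 3 * C + seq_len(C)] <- x[od_r, od_c, , drop = FALSE]
  out
}

#' @rdname focus_transform
#' @param y Array of shape `(H/2, W/2, 4C)` as produced by
#'   `focus_transform`.
#' @export
focus_inverse <- function(y) {
  y <- as_vox_array(y)
  d <- dim(y)
  if (d[3] %% 4 != 0) stop("Channel count must be a multiple of 4.")
  C <- d[3] / 4
  H <- 2 * d[1]; W <- 2 * d[2]
  ev_r <- seq(1, H, by = 2); od_r <- seq(2, H, by = 2)
  ev_c <- seq(1, W, by = 2); od_c <- seq(2, W, by = 2)
  x <- array(0, c(H, W, C))
  x[ev_r, ev_c, ] <- y[, , seq_len(C), drop = FALSE]
  x[ev_r, od_c, ] <- y[, , C + seq_len(C), drop = FALSE]
  x[od_r, ev_c, ] <- y[, , 2 * C + seq_len(C), drop = FALSE]
  x[od_r, od_c, ] <- y[, , 3 * C + seq_len(C), drop = FALSE]
  x
}

# gradient of focus_transform is its inverse permutation applied to dout
focus_bwd <- function(dout) focus_inverse(dout)
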