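#' Network configuration for the attention-gated focus U-Net
#'
#' Describes the 2-D segmentation network: a U-Net whose encoder fuses, at
#' every downsampling, a lossless space-to-depth "focus" branch of the
#' incoming features with the max-pooled path, and whose decoder gates each
#' skip connection with a learned attention map before concatenation.
#' Disabling the focus branch yields the attention U-Net ablation
#' (AttUNet); disabling both gives a plain U-Net.
#'
#' @param depth Number of encoder levels including the bottleneck
#'   (default 5).
#' @param base_channels Channels at the first level; doubled per level
#'   (default 64). Must be even under the `half_C` focus rule.
#' @param focus_enabled Include the focus encoder branch?
#' @param ag_enabled Gate skip connections with attention?
#' @param ag_mode How the gate combines its two projected inputs:
#'   `"additive"` (sum) or `"concat"` (channel concatenation).
#' @param focus_out_rule `"half_C"`: the focus branch outputs
#'   `max(1, C/2)` channels for a C-channel input; `"configured"`: use
#'   `focus_channels`.
#' @param focus_channels Focus output channels under the `configured` rule.
#' @param focus_entry `"per_level"` fuses a focus branch at every encoder
#'   downsampling; `"stem"` applies it only at the first.
#' @param in_channels,out_channels Image and prediction channels (both 1).
#' @param head_bias_init Initial bias of the sigmoid head. The default
#'   `qlogis(0.05)` starts predictions near a 5% foreground prior, the
#'   standard initialization for heavily imbalanced lesion detection.
#' @return An object of class `net_config`.
#' @export
net_config <- function(depth = 5L, base_channels = 64L,
                       focus_enabled = TRUE, ag_enabled = TRUE,
                       ag_mode = c("additive", "concat"),
                       focus_out_rule = c("half_C", "configured"),
                       focus_channels = NULL,
                       focus_entry = c("per_level", "stem"),
                       in_channels = 1L, out_channels = 1L,
                       head_bias_init = stats::qlogis(0.05)) {
  ag_mode <- match.arg(ag_mode)
  focus_out_rule <- match.arg(focus_out_rule)
  focus_entry <- match.arg(focus_entry)
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  if (depth < 2L) stop("`depth` must be at least 2.")
  if (base_channels < 1L) stop("`base_channels` must be positive.")
  if (focus_out_rule == "half_C" && base_channels %% 2L != 0L) {
    stop("`base_channels` must be even under the half_C focus rule.")
  }
  if (focus_out_rule == "configured" &&
      (is.null(focus_channels) || focus_channels < 1)) {
    stop("`focus_channels` must be set under the configured rule.")
  }
  structure(
    list(depth = depth, base_channels = base_channels,
         focus_enabled = isTRUE(focus_enabled),
         ag_enabled = isTRUE(ag_enabled),
         ag_mode = ag_mode, focus_out_rule = focus_out_rule,
         focus_channels = focus_channels, focus_entry = focus_entry,
         in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         head_bias_init = head_bias_init),
    class = "net_config"
  )
}

level_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

focus_out_channels <- function(cfg, c_in) {
  if (cfg$focus_out_rule == "half_C") max(1L, c_in %/% 2L)
  else as.integer(cfg$focus_channels)
}

focus_at_level <- function(cfg, l) {
  cfg$focus_enabled && (cfg$focus_entry == "per_level" || l == 1L)
}

#' Build an attention-gated focus U-Net
#'
#' Instantiates seeded He-initialized weights for a [net_config]. With
#' `focus_enabled = FALSE, ag_enabled = TRUE` the model is the attention
#' U-Net ablation; with both disabled it is a plain U-Net.
#'
#' @param cfg A [net_config].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `attfocusnet_model`.
#' @export
build_network <- function(cfg = net_config(), seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  ch <- level_channels(cfg)
  params <- with_seed(seed, {
    p <- list(enc = vector("list", cfg$depth),
              focus = vector("list", cfg$depth - 1L),
              dec = vector("list", cfg$depth - 1L))
    for (l in seq_len(cfg$depth)) {
      if (l == 1L) {
        c_in <- cfg$in_channels
      } else {
        c_in <- ch[l - 1L] +
          if (focus_at_level(cfg, l - 1L)) focus_out_channels(cfg, ch[l - 1L]) else 0L
      }
      p$enc[[l]] <- list(c1 = conv3_init(c_in, ch[l]),
                         c2 = conv3_init(ch[l], ch[l]))
    }
    for (l in seq_len(cfg$depth - 1L)) {
      if (focus_at_level(cfg, l)) {
        p$focus[[l]] <- conv3_init(4L * ch[l], focus_out_channels(cfg, ch[l]))
      }
      fi <- max(1L, ch[l] %/% 2L)
      ag <- if (cfg$ag_enabled) {
        psi_in <- if (cfg$ag_mode == "concat") 2L * fi else fi
        list(Ws = conv1_init(ch[l], fi), Wg = conv1_init(ch[l], fi),
             psi = conv1_init(psi_in, 1L))
      }
      p$dec[[l]] <- list(up = conv3_init(ch[l + 1L], ch[l]), ag = ag,
                         c1 = conv3_init(2L * ch[l], ch[l]),
                         c2 = conv3_init(ch[l], ch[l]))
    }
    p$head <- conv1_init(ch[1L], cfg$out_channels)
    # start the sigmoid head at the foreground prior so training on the
    # heavily imbalanced lesion/background task does not first have to
    # drive every logit down through a saturating collapse
    p$head$b[] <- cfg$head_bias_init
    p
  })
  structure(list(params = params, cfg = cfg, seed = as.integer(seed)),
            class = "attfocusnet_model")
}

#' @export
print.attfocusnet_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "<attfocusnet_model> depth %d, base %d, focus %s, attention gates %s (%s), %s parameters\n",
    cfg$depth, cfg$base_channels,
    ifelse(cfg$focus_enabled, "on", "off"),
    ifelse(cfg$ag_enabled, "on", "off"), cfg$ag_mode,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `attfocusnet_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$W)) n <<- n + length(x$W) + length(x$b)
      else for (el in x) if (!is.null(el)) walk(el)
    }
  }
  walk(model$params)
  n
}

# ---- double conv -----------------------------------------------------------

dc_fwd <- function(x, p) {
  a1 <- conv3_fwd(x, p$c1); r1 <- relu_fwd(a1$out)
  a2 <- conv3_fwd(r1$out, p$c2); r2 <- relu_fwd(a2$out)
  list(out = r2$out,
       cache = list(a1 = a1$cache, r1 = r1$cache,
                    a2 = a2$cache, r2 = r2$cache))
}

dc_bwd <- function(dout, p, cache) {
  d2 <- relu_bwd(dout, cache$r2)
  b2 <- conv3_bwd(d2, p$c2, cache$a2)
  d1 <- relu_bwd(b2$dx, cache$r1)
  b1 <- conv3_bwd(d1, p$c1, cache$a1)
  list(dx = b1$dx,
       grads = list(c1 = list(W = b1$dW, b = b1$db),
                    c2 = list(W = b2$dW, b = b2$db)))
}

# ---- attention gate --------------------------------------------------------

ag_fwd <- function(skip, gate, p, mode) {
  ts <- conv1_fwd(skip, p$Ws)
  tg <- conv1_fwd(gate, p$Wg)
  pre <- if (mode == "concat") concat_c(ts$out, tg$out) else ts$out + tg$out
  r <- relu_fwd(pre)
  pa <- conv1_fwd(r$out, p$psi)
  alpha <- sigmoid(pa$out)
  out <- skip * as.vector(alpha)
  list(out = out, alpha = alpha,
       cache = list(ts = ts$cache, tg = tg$cache, r = r$cache,
                    pa = pa$cache, alpha = alpha, skip = skip,
                    fi = dim(ts$out)[3]))
}

ag_bwd <- function(dout, p, cache, mode) {
  skip <- cache$skip
  d <- dim(skip)
  hw <- d[1] * d[2]
  alpha <- cache$alpha
  dalpha <- array(rowSums(matrix(dout * skip, hw, d[3])), c(d[1], d[2], 1L))
  dskip <- dout * as.vector(alpha)
  dpa <- dalpha * alpha * (1 - alpha)
  bpsi <- conv1_bwd(dpa, p$psi, cache$pa)
  dpre <- relu_bwd(bpsi$dx, cache$r)
  if (mode == "concat") {
    parts <- split_c(dpre, cache$fi)
    dts <- parts[[1]]; dtg <- parts[[2]]
  } else {
    dts <- dpre; dtg <- dpre
  }
  bs <- conv1_bwd(dts, p$Ws, cache$ts)
  bg <- conv1_bwd(dtg, p$Wg, cache$tg)
  list(dskip = dskip + bs$dx, dgate = bg$dx,
       grads = list(Ws = list(W = bs$dW, b = bs$db),
                    Wg = list(W = bg$dW, b = bg$db),
                    psi = list(W = bpsi$dW, b = bpsi$db)))
}

#' Apply a 2-D attention gate to a skip connection
#'
#' Projects the skip and gating feature maps through 1x1 convolutions,
#' combines them (additively or by channel concatenation), applies ReLU,
#' reduces to a single channel, and squashes through a sigmoid to obtain an
#' attention map `alpha` in (0, 1), which multiplicatively reweights the
#' skip features.
#'
#' @param skip,gate Arrays `(H, W, C)` with identical spatial size.
#' @param params Gate parameters from [init_attention_gate()]; created with
#'   `seed` if `NULL`.
#' @param mode `"additive"` or `"concat"`.
#' @param seed Seed for default parameter creation.
#' @return List with `out` (gated skip, same shape as `skip`) and `alpha`
#'   (`(H, W, 1)` attention map).
#' @export
attention_gate <- function(skip, gate, params = NULL,
                           mode = c("additive", "concat"), seed = 1L) {
  mode <- match.arg(mode)
  skip <- as_vox_array(skip); gate <- as_vox_array(gate)
  if (!all(dim(skip)[1:2] == dim(gate)[1:2])) {
    stop("`skip` and `gate` must have the same spatial size.")
  }
  if (is.null(params)) {
    params <- init_attention_gate(dim(skip)[3], dim(gate)[3],
                                  mode = mode, seed = seed)
  }
  r <- ag_fwd(skip, gate, params, mode)
  list(out = r$out, alpha = r$alpha)
}

#' @rdname attention_gate
#' @param c_skip,c_gate Channel counts of the two inputs.
#' @param f_int Intermediate channels (default `max(1, c_skip/2)`).
#' @export
init_attention_gate <- function(c_skip, c_gate, f_int = NULL,
                                mode = c("additive", "concat"), seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(f_int)) f_int <- max(1L, c_skip %/% 2L)
  psi_in <- if (mode == "concat") 2L * f_int else f_int
  with_seed(seed, list(Ws = conv1_init(c_skip, f_int),
                       Wg = conv1_init(c_gate, f_int),
                       psi = conv1_init(psi_in, 1L)))
}

#' Focus block: space-to-depth plus learned convolution
#'
#' [focus_transform()] followed by a 3x3 convolution and ReLU. Under the
#' `half_C` rule a C-channel input yields `max(1, C/2)` output channels
#' (the clamp covers the single-channel raw image).
#'
#' @param x Array `(H, W, C)`, `H` and `W` even.
#' @param cfg A [net_config] supplying the output-channel rule.
#' @param params Optional conv parameters; seeded He init if `NULL`.
#' @param seed Seed for default parameter creation.
#' @return Array `(H/2, W/2, C_out)`.
#' @export
focus_block <- function(x, cfg = net_config(), params = NULL, seed = 1L) {
  x <- as_vox_array(x)
  c_in <- dim(x)[3]
  c_out <- focus_out_channels(cfg, c_in)
  if (is.null(params)) {
    params <- with_seed(seed, conv3_init(4L * c_in, c_out))
  }
  s <- focus_transform(x)
  relu_fwd(conv3_fwd(s, params)$out)$out
}

# ---- full network forward / backward --------------------------------------

check_input_size <- function(cfg, d) {
  f <- 2L^(cfg$depth - 1L)
  if (d[1] %% f != 0L || d[2] %% f != 0L) {
    stop("Input spatial size (", d[1], " x ", d[2],
         ") must be divisible by 2^(depth-1) = ", f, ".")
  }
}

net_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  x <- as_vox_array(x)
  check_input_size(cfg, dim(x))
  depth <- cfg$depth
  f <- vector("list", depth)
  cache <- list(enc = vector("list", depth),
                down = vector("list", depth - 1L),
                dec = vector("list", depth - 1L))
  for (l in seq_len(depth)) {
    if (l == 1L) {
      xin <- x
    } else {
      mp <- maxpool_fwd(f[[l - 1L]])
      if (focus_at_level(cfg, l - 1L)) {
        s2 <- focus_transform(f[[l - 1L]])
        fc <- conv3_fwd(s2, p$focus[[l - 1L]])
        fr <- relu_fwd(fc$out)
        xin <- concat_c(fr$out, mp$out)
        cache$down[[l - 1L]] <- list(mp = mp$cache, fc = fc$cache,
                                     fr = fr$cache, fb_c = dim(fr$out)[3])
      } else {
        xin <- mp$out
        cache$down[[l - 1L]] <- list(mp = mp$cache)
      }
    }
    dc <- dc_fwd(xin, p$enc[[l]])
    f[[l]] <- dc$out
    cache$enc[[l]] <- dc$cache
  }
  d <- f[[depth]]
  for (l in rev(seq_len(depth - 1L))) {
    up <- upsample_fwd(d)
    uc <- conv3_fwd(up$out, p$dec[[l]]$up)
    ur <- relu_fwd(uc$out)
    u <- ur$out
    if (cfg$ag_enabled) {
      ag <- ag_fwd(f[[l]], u, p$dec[[l]]$ag, cfg$ag_mode)
      s <- ag$out
      agc <- ag$cache
    } else {
      s <- f[[l]]
      agc <- NULL
    }
    dc <- dc_fwd(concat_c(u, s), p$dec[[l]])
    cache$dec[[l]] <- list(up_d = up$cache, uc = uc$cache, ur = ur$cache,
                           ag = agc, dc = dc$cache, c_l = dim(u)[3])
    d <- dc$out
  }
  hc <- conv1_fwd(d, p$head)
  logits <- hc$out
  out <- list(prob = sigmoid(logits), logits = logits)
  if (keep_cache) {
    cache$head <- hc$cache
    out$cache <- cache
  }
  out
}

net_backward <- function(model, dlogits, cache) {
  cfg <- model$cfg; p <- model$params
  depth <- cfg$depth
  g <- list(enc = vector("list", depth),
            focus = vector("list", depth - 1L),
            dec = vector("list", depth - 1L))
  hb <- conv1_bwd(dlogits, p$head, cache$head)
  g$head <- list(W = hb$dW, b = hb$db)
  dd <- hb$dx
  df <- vector("list", depth)
  add_df <- function(l, v) {
    df[[l]] <<- if (is.null(df[[l]])) v else df[[l]] + v
  }
  for (l in seq_len(depth - 1L)) {
    cc <- cache$dec[[l]]
    dcb <- dc_bwd(dd, p$dec[[l]], cc$dc)
    parts <- split_c(dcb$dx, cc$c_l)
    du <- parts[[1]]; ds <- parts[[2]]
    if (cfg$ag_enabled) {
      agb <- ag_bwd(ds, p$dec[[l]]$ag, cc$ag, cfg$ag_mode)
      add_df(l, agb$dskip)
      du <- du + agb$dgate
      ag_g <- agb$grads
    } else {
      add_df(l, ds)
      ag_g <- NULL
    }
    dur <- relu_bwd(du, cc$ur)
    ub <- conv3_bwd(dur, p$dec[[l]]$up, cc$uc)
    dd <- upsample_bwd(ub$dx, cc$up_d)
    g$dec[[l]] <- c(list(up = list(W = ub$dW, b = ub$db), ag = ag_g),
                    dcb$grads)
    if (l == depth - 1L) add_df(depth, dd)
  }
  for (l in rev(seq_len(depth))) {
    dcb <- dc_bwd(df[[l]], p$enc[[l]], cache$enc[[l]])
    g$enc[[l]] <- dcb$grads
    if (l > 1L) {
      cc <- cache$down[[l - 1L]]
      if (focus_at_level(cfg, l - 1L)) {
        parts <- split_c(dcb$dx, cc$fb_c)
        dfb <- parts[[1]]; dmp <- parts[[2]]
        dfr <- relu_bwd(dfb, cc$fr)
        fb <- conv3_bwd(dfr, p$focus[[l - 1L]], cc$fc)
        g$focus[[l - 1L]] <- list(W = fb$dW, b = fb$db)
        add_df(l - 1L, focus_bwd(fb$dx))
        add_df(l - 1L, maxpool_bwd(dmp, cc$mp))
      } else {
        add_df(l - 1L, maxpool_bwd(dcb$dx, cc$mp))
      }
    }
  }
  g
}

#' Forward one image slice through the network
#'
#' @param model An `attfocusnet_model`.
#' @param slice Matrix or `(H, W, 1)` array of normalized intensities.
#' @return Matrix of foreground probabilities in (0, 1), same spatial size.
#' @export
predict_slice <- function(model, slice) {
  x <- as_vox_array(slice)
  pr <- net_forward(model, x)$prob
  matrix(pr, dim(x)[1], dim(x)[2])
}

#' Segment a full CT case slice by slice
#'
#' Forwards each axial slice independently through the network and
#' thresholds the probability map (`>= threshold` is foreground, so a
#' probability exactly at the threshold is positive).
#'
#' @param model An `attfocusnet_model`.
#' @param vol A normalized [ct_volume].
#' @param threshold Probability threshold in `[0, 1]` (default 0.5).
#' @return An [ich_mask] aligned with `vol`.
#' @export
predict_case <- function(model, vol, threshold = 0.5) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$units != "normalized") {
    stop("`vol` must be window-normalized; call window_normalize() first.")
  }
  d <- dim(vol$voxels)
  check_input_size(model$cfg, d)
  lab <- array(0L, d)
  for (k in seq_len(d[3])) {
    pr <- predict_slice(model, vol$voxels[, , k, drop = FALSE])
    lab[, , k] <- as.integer(pr >= threshold)
  }
  ich_mask(lab, spacing_mm = vol$spacing_mm, case_id = vol$case_id)
}
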