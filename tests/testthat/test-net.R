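test_that("focus transform rearranges (H, W, C) into (H/2, W/2, 4C) losslessly", {
  set.seed(1)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  y <- focus_transform(x)
  expect_equal(dim(y), c(32L, 32L, 12L))
  expect_identical(focus_inverse(y), x)
  # fixed phase order: block 1 is the (even, even) sub-grid
  expect_equal(y[, , 1:3], x[seq(1, 63, 2), seq(1, 63, 2), ])
  expect_equal(y[, , 4:6], x[seq(1, 63, 2), seq(2, 64, 2), ])
  # a permutation preserves values
  cst <- array(3.5, c(8, 8, 2))
  expect_true(all(focus_transform(cst) == 3.5))
  expect_error(focus_transform(array(0, c(7, 8, 1))), "even")
})

test_that("focus block halves spatial size and applies the C/2 channel rule", {
  set.seed(2)
  x <- array(rnorm(32 * 32 * 64), c(32, 32, 64))
  out <- focus_block(x, net_config(depth = 2, base_channels = 64))
  expect_equal(dim(out), c(16L, 16L, 32L))
  # single-channel input clamps to one output channel
  x1 <- array(rnorm(32 * 32), c(32, 32, 1))
  expect_equal(dim(focus_block(x1, net_config(depth = 2, base_channels = 2))),
               c(16L, 16L, 1L))
})

test_that("attention gate gates multiplicatively with alpha strictly in (0, 1)", {
  set.seed(3)
  skip <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  gate <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  for (mode in c("additive", "concat")) {
    r <- attention_gate(skip, gate, mode = mode, seed = 4)
    expect_equal(dim(r$out), dim(skip))
    expect_true(all(r$alpha > 0 & r$alpha < 1))
    # |gated| never exceeds |skip|
    expect_true(all(abs(r$out) <= abs(skip)))
    # zero skip -> zero output
    z <- attention_gate(skip * 0, gate, mode = mode, seed = 4)
    expect_true(all(z$out == 0))
  }
  # saturating the psi bias forces alpha to 1, making the gate an identity
  p <- init_attention_gate(8, 8, seed = 4)
  p$psi$W[] <- 0
  p$psi$b[] <- 100
  r1 <- attention_gate(skip, gate, params = p)
  expect_equal(r1$out, skip)
  expect_error(attention_gate(skip, array(0, c(8, 8, 8))), "spatial size")
})

test_that("network forward pass honours shape and probability contracts", {
  m <- build_network(net_config(depth = 3, base_channels = 4), seed = 5)
  pr <- predict_slice(m, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(pr), c(64L, 64L))
  expect_true(all(pr > 0 & pr < 1))
  expect_error(predict_slice(m, matrix(0, 30, 30)), "divisible")
})

test_that("the focus branch adds parameters over the plain attention U-Net", {
  cfg_f <- net_config(depth = 3, base_channels = 16)
  cfg_a <- net_config(depth = 3, base_channels = 16, focus_enabled = FALSE)
  cfg_u <- net_config(depth = 3, base_channels = 16, focus_enabled = FALSE,
                      ag_enabled = FALSE)
  n_f <- count_parameters(build_network(cfg_f, seed = 1))
  n_a <- count_parameters(build_network(cfg_a, seed = 1))
  n_u <- count_parameters(build_network(cfg_u, seed = 1))
  expect_gt(n_f, n_a)
  expect_gt(n_a, n_u)
})

test_that("inference is deterministic and weight init is seed-reproducible", {
  m1 <- build_network(net_config(depth = 2, base_channels = 4), seed = 9)
  m2 <- build_network(net_config(depth = 2, base_channels = 4), seed = 9)
  expect_identical(m1$params, m2$params)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict_slice(m1, x), predict_slice(m1, x))
})

test_that("analytic gradients match central finite differences", {
  getp <- function(tree, path) {
    cur <- tree
    for (s in path) cur <- cur[[s]]
    cur
  }
  setp <- function(tree, path, value) {
    if (length(path) == 0) return(value)
    tree[[path[[1]]]] <- setp(tree[[path[[1]]]], path[-1], value)
    tree
  }
  check_cfg <- function(cfg, seed) {
    m <- build_network(cfg, seed = seed)
    set.seed(seed + 50)
    x <- array(runif(64), c(8, 8, 1))
    t <- array(rbinom(64, 1, 0.3), c(8, 8, 1))
    fw <- hemseg:::net_forward(m, x, keep_cache = TRUE)
    lg <- hemseg:::loss_grad_logits(fw$prob, t, "dice_bce")
    g <- hemseg:::net_backward(m, lg$dlogits, fw$cache)
    lossfun <- function(params) {
      mm <- m; mm$params <- params
      hemseg:::loss_grad_logits(hemseg:::net_forward(mm, x)$prob, t,
                                "dice_bce")$loss
    }
    paths <- list(list("enc", 1L, "c1"), list("enc", 2L, "c2"),
                  list("dec", 1L, "up"), list("head"))
    if (cfg$focus_enabled) paths <- c(paths, list(list("focus", 1L)))
    if (cfg$ag_enabled) {
      paths <- c(paths, list(list("dec", 1L, "ag", "psi"),
                             list("dec", 1L, "ag", "Ws"),
                             list("dec", 1L, "ag", "Wg")))
    }
    errs <- c()
    for (path in paths) {
      gl <- getp(g, path)
      for (field in c("W", "b")) {
        idx <- sample(length(gl[[field]]), min(2, length(gl[[field]])))
        for (i in idx) {
          eps <- 1e-6
          lp <- getp(m$params, path); lp[[field]][i] <- lp[[field]][i] + eps
          lm <- getp(m$params, path); lm[[field]][i] <- lm[[field]][i] - eps
          num <- (lossfun(setp(m$params, path, lp)) -
                    lossfun(setp(m$params, path, lm))) / (2 * eps)
          errs <- c(errs, abs(num - gl[[field]][i]) /
                      max(1e-6, abs(num) + abs(gl[[field]][i])))
        }
      }
    }
    errs
  }
  e1 <- check_cfg(net_config(depth = 3, base_channels = 2), 31)
  e2 <- check_cfg(net_config(depth = 2, base_channels = 2,
                             ag_mode = "concat", focus_enabled = FALSE), 32)
  e3 <- check_cfg(net_config(depth = 3, base_channels = 2,
                             ag_enabled = FALSE, focus_entry = "stem"), 33)
  # a ReLU kink can make an isolated finite difference inexact; the bulk
  # of coordinates must agree tightly
  all_err <- c(e1, e2, e3)
  expect_lt(median(all_err), 1e-5)
  expect_gt(mean(all_err < 1e-4), 0.9)
})

test_that("predicted masks follow the threshold contract slice by slice", {
  ph <- generate_phantom(phantom_spec("ellipsoid", semi_axes_mm = c(20, 18, 7),
                                      matrix = 32, n_slices = 6,
                                      spacing_mm = c(5, 5, 4), seed = 2))
  vol <- window_normalize(ph$volume)
  m <- build_network(net_config(depth = 2, base_channels = 4), seed = 6)
  pm <- predict_case(m, vol)
  expect_s3_class(pm, "ich_mask")
  expect_equal(dim(pm$labels), dim(vol$voxels))
  # threshold above 1 gives an empty mask
  expect_equal(sum(predict_case(m, vol, threshold = 1.01)$labels), 0)
  # an untrained head with zero weights outputs probability 0.5, which the
  # >= rule maps to foreground
  m0 <- m
  m0$params$head$W[] <- 0
  m0$params$head$b[] <- 0
  pm0 <- predict_case(m0, vol, threshold = 0.5)
  expect_true(all(pm0$labels == 1L))
  # HU input is rejected
  expect_error(predict_case(m, ph$volume), "normalized")
})
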