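# The layer engine is validated by central-difference gradient checks: a graph
# exercising every op type must have analytic gradients matching numerical
# ones for both parameters and the training loss.

grad_check_graph <- function(build, H = 8, W = 8, N = 2, seed = 61, n_probe = 4) {
  set.seed(seed)
  g <- ctseg:::nn_graph()
  inp <- ctseg:::ng_add(g, "input")
  out <- build(g, inp)
  x <- ctseg:::act(matrix(runif(H * W * N), ncol = 1), H, W, N)
  t <- round(runif(H * W * N))
  cfg <- loss_config()
  run <- function() {
    fwd <- ctseg:::nn_forward(g, x, train = TRUE, keep_cache = TRUE)
    p <- fwd$acts[[out]]$x[, 1]
    lg <- ctseg:::.focal_tversky_grad(p, t, cfg)
    list(fwd = fwd, loss = lg$loss, grad = matrix(lg$grad, ncol = 1))
  }
  r <- run()
  grads <- ctseg:::nn_backward(g, r$fwd, r$grad, out_id = out)
  eps <- 1e-5
  for (h in ctseg:::nn_param_handles(g)) {
    p <- g$nodes[[h$id]]$params[[h$name]]
    for (i in sample(length(p), min(n_probe, length(p)))) {
      orig <- p[i]
      g$nodes[[h$id]]$params[[h$name]][i] <- orig + eps
      lp <- run()$loss
      g$nodes[[h$id]]$params[[h$name]][i] <- orig - eps
      lm <- run()$loss
      g$nodes[[h$id]]$params[[h$name]][i] <- orig
      num <- (lp - lm) / (2 * eps)
      ana <- grads[[h$id]][[h$name]][i]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = sprintf("analytic grad (node %d %s[%d])", h$id, h$name, i))
    }
  }
}

test_that("conv/bn/relu/maxpool/upsample gradients match central differences", {
  grad_check_graph(function(g, inp) {
    c1 <- ctseg:::ng_conv(g, inp, 1, 3, k = 3)
    b1 <- ctseg:::ng_bn(g, c1, 3)
    r1 <- ctseg:::ng_relu(g, b1)
    mp <- ctseg:::ng_maxpool(g, r1)
    up <- ctseg:::ng_upsample(g, mp)
    c2 <- ctseg:::ng_conv(g, up, 3, 1, k = 3, bias = TRUE)
    ctseg:::ng_sigmoid(g, c2)
  })
})

test_that("residual add, concat and strided conv gradients are exact", {
  grad_check_graph(function(g, inp) {
    a1 <- ctseg:::ng_conv(g, inp, 1, 2, k = 3, stride = 2)
    a2 <- ctseg:::ng_conv(g, inp, 1, 2, k = 1, stride = 2, pad = 0)
    ad <- ctseg:::ng_add_op(g, a1, a2)
    up <- ctseg:::ng_upsample(g, ad)
    cc <- ctseg:::ng_concat(g, up, inp)
    hd <- ctseg:::ng_conv(g, cc, 3, 1, k = 3, bias = TRUE)
    ctseg:::ng_sigmoid(g, hd)
  })
})

test_that("7x7 stride-2 stem convolution gradients are exact", {
  grad_check_graph(function(g, inp) {
    c1 <- ctseg:::ng_conv(g, inp, 1, 2, k = 7, stride = 2, pad = 3)
    r1 <- ctseg:::ng_relu(g, c1)
    u1 <- ctseg:::ng_upsample(g, r1)
    hd <- ctseg:::ng_conv(g, u1, 2, 1, k = 3, bias = TRUE)
    ctseg:::ng_sigmoid(g, hd)
  }, H = 8, W = 8)
})

test_that("convolution forward agrees with a direct per-pixel oracle", {
  set.seed(62)
  H <- 6; W <- 5
  x <- matrix(runif(H * W), ncol = 1)
  a <- ctseg:::act(x, H, W, 1L)
  k <- 3
  p <- list(W = matrix(runif(k * k), ncol = 1), b = NULL, kh = k, kw = k,
            stride = 1L, pad = 1L, cin = 1L, cout = 1L)
  got <- matrix(ctseg:::.conv_fwd(a, p)$out$x, H, W)
  img <- matrix(x, H, W)
  kern <- matrix(p$W, k, k) # rows = dh (fast), cols = dw
  want <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    acc <- 0
    for (dh in 0:(k - 1)) for (dw in 0:(k - 1)) {
      rr <- r + dh - 1; cc <- c + dw - 1
      v <- if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) img[rr, cc] else 0
      acc <- acc + v * kern[dh + 1, dw + 1]
    }
    want[r, c] <- acc
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("batch norm eval mode uses running statistics", {
  set.seed(63)
  g <- ctseg:::nn_graph()
  inp <- ctseg:::ng_add(g, "input")
  bn <- ctseg:::ng_bn(g, inp, 1L)
  x <- ctseg:::act(matrix(rnorm(64, mean = 3, sd = 2), ncol = 1), 8, 8, 1L)
  for (i in 1:200) ctseg:::nn_forward(g, x, train = TRUE) # converge running stats
  node <- g$nodes[[bn]]
  expect_equal(node$state$running_mean, mean(x$x), tolerance = 1e-3)
  y <- ctseg:::nn_forward(g, x, train = FALSE)$acts[[bn]]$x
  expect_equal(mean(y), 0, tolerance = 1e-2)
})
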