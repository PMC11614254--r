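# Minimal CNN engine: a static layer graph with explicit forward/backward
# passes. Activations are stored as (H*W*N) x C matrices (rows ordered h, then
# w, then image), so convolutions reduce to gather + matrix multiply (im2col)
# and BLAS does the heavy lifting. This is sized for desk-scale 2-D
# segmentation networks; there is no GPU path.

.idx_cache <- new.env(parent = emptyenv())

# gather indices for a kh x kw window sweep: a (Ho*Wo*N) x (kh*kw) integer
# matrix of row indices into the activation matrix, with S*N+1 marking
# out-of-bounds (padding) taps.
.conv_idx <- function(H, W, N, kh, kw, stride, pad) {
  key <- paste(H, W, N, kh, kw, stride, pad, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  ho <- rep(seq_len(Ho), times = Wo * N)
  wo <- rep(rep(seq_len(Wo), each = Ho), times = N)
  nn <- rep(seq_len(N), each = Ho * Wo)
  base_h <- (ho - 1L) * stride - pad
  base_w <- (wo - 1L) * stride - pad
  off_n <- (nn - 1L) * H * W
  pad_row <- H * W * N + 1L
  idx <- matrix(0L, nrow = Ho * Wo * N, ncol = kh * kw)
  k <- 0L
  for (dw in seq_len(kw) - 1L) {
    for (dh in seq_len(kh) - 1L) {
      k <- k + 1L
      h_in <- base_h + dh + 1L
      w_in <- base_w + dw + 1L
      ok <- h_in >= 1L & h_in <= H & w_in >= 1L & w_in <= W
      idx[, k] <- ifelse(ok, h_in + H * (w_in - 1L) + off_n, pad_row)
    }
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .idx_cache[[key]] <- out
  out
}

.upsample_idx <- function(H, W, N) {
  key <- paste("up", H, W, N, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- 2L * H; Wo <- 2L * W
  ho <- rep(seq_len(Ho), times = Wo * N)
  wo <- rep(rep(seq_len(Wo), each = Ho), times = N)
  nn <- rep(seq_len(N), each = Ho * Wo)
  src <- ((ho - 1L) %/% 2L + 1L) + H * ((wo - 1L) %/% 2L) + H * W * (nn - 1L)
  .idx_cache[[key]] <- src
  src
}

act <- function(x, H, W, N) list(x = x, H = H, W = W, N = N)

.with_pad_row <- function(m, fill = 0) rbind(m, matrix(fill, 1L, ncol(m)))

# ---- per-op forward/backward -------------------------------------------------

.conv_fwd <- function(a, p) {
  ci <- .conv_idx(a$H, a$W, a$N, p$kh, p$kw, p$stride, p$pad)
  xz <- .with_pad_row(a$x)
  C <- ncol(a$x); kk <- p$kh * p$kw
  cols <- matrix(0, nrow(ci$idx), kk * C)
  for (k in seq_len(kk)) cols[, ((k - 1L) * C + 1L):(k * C)] <- xz[ci$idx[, k], , drop = FALSE]
  y <- cols %*% p$W
  if (!is.null(p$b)) y <- y + rep(p$b, each = nrow(y))
  list(out = act(y, ci$Ho, ci$Wo, a$N), cache = list(cols = cols, a = a, ci = ci))
}

.conv_bwd <- function(dy, cache, p) {
  dW <- crossprod(cache$cols, dy)
  db <- if (!is.null(p$b)) colSums(dy) else NULL
  dcols <- tcrossprod(dy, p$W) # (SoutN) x (kk*C)
  a <- cache$a; ci <- cache$ci
  C <- ncol(a$x); kk <- p$kh * p$kw
  dxz <- matrix(0, nrow(a$x) + 1L, C)
  for (k in seq_len(kk)) {
    rows <- ci$idx[, k]
    dxz[rows, ] <- dxz[rows, , drop = FALSE] + dcols[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
  }
  list(dx = list(act(dxz[-nrow(dxz), , drop = FALSE], a$H, a$W, a$N)),
       grads = list(W = dW, b = db))
}

.bn_fwd <- function(a, p, train, node_env) {
  eps <- 1e-5
  if (train) {
    mu <- colMeans(a$x)
    xc <- sweep(a$x, 2L, mu)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, istd, "*")
    m <- nrow(a$x)
    unbias <- if (m > 1L) m / (m - 1L) else 1
    node_env$running_mean <- (1 - p$momentum) * node_env$running_mean + p$momentum * mu
    node_env$running_var <- (1 - p$momentum) * node_env$running_var + p$momentum * v * unbias
    y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
    list(out = act(y, a$H, a$W, a$N), cache = list(xhat = xhat, istd = istd, a = a))
  } else {
    istd <- 1 / sqrt(node_env$running_var + eps)
    y <- sweep(sweep(sweep(sweep(a$x, 2L, node_env$running_mean), 2L, istd, "*"),
                     2L, p$gamma, "*"), 2L, p$beta, "+")
    list(out = act(y, a$H, a$W, a$N), cache = NULL)
  }
}

.bn_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, p$gamma, "*")
  mdxhat <- colMeans(dxhat)
  mdxx <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2L, mdxhat) - sweep(xhat, 2L, mdxx, "*"),
              2L, cache$istd, "*")
  a <- cache$a
  list(dx = list(act(dx, a$H, a$W, a$N)), grads = list(gamma = dgamma, beta = dbeta))
}

.maxpool_fwd <- function(a, p) {
  ci <- .conv_idx(a$H, a$W, a$N, p$kh, p$kw, p$stride, p$pad)
  xz <- .with_pad_row(a$x, fill = -Inf)
  C <- ncol(a$x); kk <- p$kh * p$kw
  best <- matrix(-Inf, nrow(ci$idx), C)
  bestk <- matrix(0L, nrow(ci$idx), C)
  for (k in seq_len(kk)) {
    v <- xz[ci$idx[, k], , drop = FALSE]
    upd <- v > best
    best[upd] <- v[upd]
    bestk[upd] <- k
  }
  list(out = act(best, ci$Ho, ci$Wo, a$N), cache = list(bestk = bestk, a = a, ci = ci))
}

.maxpool_bwd <- function(dy, cache, p) {
  a <- cache$a; ci <- cache$ci
  kk <- p$kh * p$kw
  dxz <- matrix(0, nrow(a$x) + 1L, ncol(a$x))
  for (k in seq_len(kk)) {
    sel <- cache$bestk == k
    if (!any(sel)) next
    chunk <- dy * sel
    rows <- ci$idx[, k]
    dxz[rows, ] <- dxz[rows, , drop = FALSE] + chunk
  }
  list(dx = list(act(dxz[-nrow(dxz), , drop = FALSE], a$H, a$W, a$N)), grads = NULL)
}

.upsample_fwd <- function(a) {
  src <- .upsample_idx(a$H, a$W, a$N)
  list(out = act(a$x[src, , drop = FALSE], 2L * a$H, 2L * a$W, a$N),
       cache = list(a = a, src = src))
}

.upsample_bwd <- function(dy, cache) {
  a <- cache$a
  dx <- rowsum(dy, cache$src, reorder = TRUE)
  list(dx = list(act(dx, a$H, a$W, a$N)), grads = NULL)
}

# ---- graph construction ------------------------------------------------------

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

ng_add <- function(g, op, inputs = integer(0), params = NULL, state = NULL) {
  inputs <- as.integer(inputs) # force now: nested builder calls append nodes
  force(params); force(state)
  id <- length(g$nodes) + 1L
  node <- list(id = id, op = op, inputs = inputs, params = params)
  if (!is.null(state)) {
    env <- new.env(parent = emptyenv())
    for (nm in names(state)) assign(nm, state[[nm]], envir = env)
    node$state <- env
  }
  g$nodes[[id]] <- node
  id
}

.he_conv <- function(kh, kw, cin, cout, zero = FALSE, bias = FALSE) {
  fan_in <- kh * kw * cin
  W <- if (zero) matrix(0, fan_in, cout)
       else matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  p <- list(W = W, kh = kh, kw = kw, stride = 1L, pad = (kh - 1L) %/% 2L,
            cin = cin, cout = cout)
  p$b <- if (bias) numeric(cout) else NULL
  p
}

ng_conv <- function(g, input, cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                    bias = FALSE, zero = FALSE) {
  p <- .he_conv(k, k, cin, cout, zero = zero, bias = bias)
  p$stride <- as.integer(stride); p$pad <- as.integer(pad)
  ng_add(g, "conv", input, p)
}

ng_bn <- function(g, input, c) {
  ng_add(g, "bn", input,
         params = list(gamma = rep(1, c), beta = rep(0, c), momentum = 0.1),
         state = list(running_mean = rep(0, c), running_var = rep(1, c)))
}

ng_bn_zero <- function(g, input, c) {
  id <- ng_bn(g, input, c)
  g$nodes[[id]]$params$gamma <- rep(0, c) # zero-init residual-branch gain
  id
}

ng_relu <- function(g, input) ng_add(g, "relu", input)
ng_sigmoid <- function(g, input) ng_add(g, "sigmoid", input)
ng_add_op <- function(g, a, b) ng_add(g, "add", c(a, b))
ng_concat <- function(g, a, b) ng_add(g, "concat", c(a, b))
ng_maxpool <- function(g, input, k = 3L, stride = 2L, pad = 1L)
  ng_add(g, "maxpool", input, params = list(kh = as.integer(k), kw = as.integer(k),
                                            stride = as.integer(stride), pad = as.integer(pad)))
ng_upsample <- function(g, input) ng_add(g, "upsample", input)

# conv-bn-relu convenience
ng_cbr <- function(g, input, cin, cout, k = 3L, stride = 1L) {
  ng_relu(g, ng_bn(g, ng_conv(g, input, cin, cout, k = k, stride = stride), cout))
}

# ---- execution ---------------------------------------------------------------

nn_forward <- function(g, input_act, train = FALSE, keep_cache = FALSE) {
  n <- length(g$nodes)
  acts <- vector("list", n)
  caches <- if (keep_cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    node <- g$nodes[[i]]
    res <- switch(node$op,
      input = list(out = input_act, cache = NULL),
      conv = .conv_fwd(acts[[node$inputs[1]]], node$params),
      bn = .bn_fwd(acts[[node$inputs[1]]], node$params, train, node$state),
      relu = {
        a <- acts[[node$inputs[1]]]
        list(out = act(pmax(a$x, 0), a$H, a$W, a$N), cache = list(mask = a$x > 0))
      },
      sigmoid = {
        a <- acts[[node$inputs[1]]]
        y <- 1 / (1 + exp(-a$x))
        list(out = act(y, a$H, a$W, a$N), cache = list(y = y))
      },
      add = {
        a <- acts[[node$inputs[1]]]; b <- acts[[node$inputs[2]]]
        list(out = act(a$x + b$x, a$H, a$W, a$N), cache = NULL)
      },
      concat = {
        a <- acts[[node$inputs[1]]]; b <- acts[[node$inputs[2]]]
        list(out = act(cbind(a$x, b$x), a$H, a$W, a$N),
             cache = list(ca = ncol(a$x)))
      },
      maxpool = .maxpool_fwd(acts[[node$inputs[1]]], node$params),
      upsample = .upsample_fwd(acts[[node$inputs[1]]]),
      stop("unknown op ", node$op)
    )
    acts[[i]] <- res$out
    if (keep_cache) caches[[i]] <- res$cache
  }
  list(acts = acts, caches = caches)
}

# dy_out: gradient matrix w.r.t. the output node's activation
nn_backward <- function(g, fwd, dy_out, out_id = length(g$nodes)) {
  n <- length(g$nodes)
  dacts <- vector("list", n)
  grads <- vector("list", n)
  dacts[[out_id]] <- dy_out
  for (i in seq(n, 1L)) {
    dy <- dacts[[i]]
    if (is.null(dy)) next
    node <- g$nodes[[i]]
    a_in <- if (length(node$inputs)) fwd$acts[[node$inputs[1]]] else NULL
    res <- switch(node$op,
      input = NULL,
      conv = .conv_bwd(dy, fwd$caches[[i]], node$params),
      bn = .bn_bwd(dy, fwd$caches[[i]], node$params),
      relu = list(dx = list(act(dy * fwd$caches[[i]]$mask, a_in$H, a_in$W, a_in$N)), grads = NULL),
      sigmoid = {
        y <- fwd$caches[[i]]$y
        list(dx = list(act(dy * y * (1 - y), a_in$H, a_in$W, a_in$N)), grads = NULL)
      },
      add = list(dx = list(act(dy, a_in$H, a_in$W, a_in$N), act(dy, a_in$H, a_in$W, a_in$N)),
                 grads = NULL),
      concat = {
        ca <- fwd$caches[[i]]$ca
        b_in <- fwd$acts[[node$inputs[2]]]
        list(dx = list(act(dy[, seq_len(ca), drop = FALSE], a_in$H, a_in$W, a_in$N),
                       act(dy[, -seq_len(ca), drop = FALSE], b_in$H, b_in$W, b_in$N)),
             grads = NULL)
      },
      maxpool = .maxpool_bwd(dy, fwd$caches[[i]], node$params),
      upsample = .upsample_bwd(dy, fwd$caches[[i]]),
      stop("unknown op ", node$op)
    )
    if (is.null(res)) next
    grads[i] <- list(res$grads)
    for (j in seq_along(node$inputs)) {
      tgt <- node$inputs[j]
      dacts[[tgt]] <- if (is.null(dacts[[tgt]])) res$dx[[j]]$x else dacts[[tgt]] + res$dx[[j]]$x
    }
    dacts[i] <- list(NULL) # free
  }
  grads
}

# flatten trainable parameters for the optimizer: list of (node, name) handles
nn_param_handles <- function(g) {
  out <- list()
  for (node in g$nodes) {
    if (is.null(node$params)) next
    for (nm in intersect(names(node$params), c("W", "b", "gamma", "beta"))) {
      if (!is.null(node$params[[nm]]))
        out[[length(out) + 1L]] <- list(id = node$id, name = nm)
    }
  }
  out
}
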