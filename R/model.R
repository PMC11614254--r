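#' Segmentation model specification
#'
#' Describes the 2-D encoder-decoder network: a residual (ResNet-style basic
#' block) encoder feeding either a U-Net decoder (skip connections at every
#' encoder resolution) or a Feature Pyramid Network decoder, with a per-pixel
#' sigmoid output. `width_multiplier` scales every channel count so that
#' desk-scale variants can be trained quickly on a CPU; 1.0 is the full
#' architecture (ResNet34 encoder: 64/64/128/256/512 channels, basic-block
#' layout 3-4-6-3).
#'
#' @param encoder_depth 18 or 34 (basic-block residual encoders).
#' @param decoder `"unet"` or `"fpn"`.
#' @param in_channels Input channels (CT slices are single-channel).
#' @param out_channels Output probability channels (binary segmentation: 1).
#' @param pretrained Load pretrained encoder weights. Off by default; when
#'   `TRUE` a local weights file must be supplied to [build_model()] — there is
#'   no download hook.
#' @param width_multiplier Channel scale factor in (0, 1].
#' @return Object of class `ctseg_model_spec`.
#' @export
model_spec <- function(encoder_depth = 34, decoder = c("unet", "fpn"),
                       in_channels = 1L, out_channels = 1L,
                       pretrained = FALSE, width_multiplier = 1) {
  decoder <- match.arg(decoder)
  if (!encoder_depth %in% c(18, 34))
    stop("`encoder_depth` must be 18 or 34 (basic-block variants)", call. = FALSE)
  stopifnot(width_multiplier > 0, in_channels >= 1, out_channels >= 1)
  structure(
    list(encoder_depth = as.integer(encoder_depth), decoder = decoder,
         in_channels = as.integer(in_channels), out_channels = as.integer(out_channels),
         pretrained = isTRUE(pretrained), width_multiplier = width_multiplier),
    class = "ctseg_model_spec"
  )
}

.enc_channels <- function(spec) pmax(1L, round(c(64, 64, 128, 256, 512) * spec$width_multiplier))
.enc_blocks <- function(spec) if (spec$encoder_depth == 34L) c(3L, 4L, 6L, 3L) else c(2L, 2L, 2L, 2L)

# one basic residual block: conv-bn-relu-conv-bn (+ projection) -> add -> relu
.res_block <- function(g, input, cin, cout, stride) {
  c1 <- ng_conv(g, input, cin, cout, k = 3L, stride = stride)
  b1 <- ng_relu(g, ng_bn(g, c1, cout))
  c2 <- ng_conv(g, b1, cout, cout, k = 3L)
  b2 <- ng_bn_zero(g, c2, cout) # identity-at-init residual branch
  shortcut <- if (stride != 1L || cin != cout) {
    ng_bn(g, ng_conv(g, input, cin, cout, k = 1L, stride = stride, pad = 0L), cout)
  } else input
  ng_relu(g, ng_add_op(g, b2, shortcut))
}

.build_encoder <- function(g, input, spec) {
  ch <- .enc_channels(spec)
  blocks <- .enc_blocks(spec)
  stem_c <- ng_conv(g, input, spec$in_channels, ch[1], k = 7L, stride = 2L, pad = 3L)
  f1 <- ng_relu(g, ng_bn(g, stem_c, ch[1]))            # 1/2
  x <- ng_maxpool(g, f1)                                # 1/4
  feats <- c(f1)
  cin <- ch[1]
  for (s in 1:4) {
    cout <- ch[s + 1]
    stride <- if (s == 1L) 1L else 2L
    x <- .res_block(g, x, cin, cout, stride)
    for (b in seq_len(blocks[s] - 1L)) x <- .res_block(g, x, cout, cout, 1L)
    cin <- cout
    feats <- c(feats, x)
  }
  feats # f1 (1/2), f2 (1/4), f3 (1/8), f4 (1/16), f5 (1/32)
}

.build_unet_decoder <- function(g, feats, spec) {
  ch <- .enc_channels(spec)
  dch <- pmax(1L, round(c(256, 128, 64, 32, 16) * spec$width_multiplier))
  skips <- c(feats[4], feats[3], feats[2], feats[1]) # 1/16, 1/8, 1/4, 1/2
  skip_ch <- c(ch[4], ch[3], ch[2], ch[1])
  x <- feats[5]; cin <- ch[5]
  for (i in 1:5) {
    x <- ng_upsample(g, x)
    if (i <= 4L) {
      x <- ng_concat(g, x, skips[i])
      cin <- cin + skip_ch[i]
    }
    x <- ng_cbr(g, x, cin, dch[i])
    x <- ng_cbr(g, x, dch[i], dch[i])
    cin <- dch[i]
  }
  head <- ng_conv(g, x, cin, spec$out_channels, k = 3L, bias = TRUE)
  ng_sigmoid(g, head)
}

.build_fpn_decoder <- function(g, feats, spec) {
  ch <- .enc_channels(spec)
  pch <- max(1L, round(128 * spec$width_multiplier)) # pyramid width
  sch <- max(1L, round(64 * spec$width_multiplier))  # segmentation width
  # lateral 1x1 projections of f5..f2, top-down nearest-upsample + add
  lat <- function(f, c_in) ng_conv(g, f, c_in, pch, k = 1L, pad = 0L, bias = TRUE)
  p5 <- lat(feats[5], ch[5])
  p4 <- ng_add_op(g, lat(feats[4], ch[4]), ng_upsample(g, p5))
  p3 <- ng_add_op(g, lat(feats[3], ch[3]), ng_upsample(g, p4))
  p2 <- ng_add_op(g, lat(feats[2], ch[2]), ng_upsample(g, p3))
  # segmentation blocks: conv to sch, then upsample everything to the 1/4 scale
  seg <- function(p, ups) {
    x <- ng_cbr(g, p, pch, sch)
    for (i in seq_len(ups)) x <- ng_upsample(g, x)
    x
  }
  merged <- ng_add_op(g, ng_add_op(g, seg(p5, 3L), seg(p4, 2L)),
                      ng_add_op(g, seg(p3, 1L), seg(p2, 0L)))
  x <- ng_cbr(g, merged, sch, sch)
  x <- ng_upsample(g, ng_upsample(g, x)) # 1/4 -> full resolution
  head <- ng_conv(g, x, sch, spec$out_channels, k = 3L, bias = TRUE)
  ng_sigmoid(g, head)
}

#' Build a segmentation model
#'
#' Constructs the network graph described by a [model_spec()] with seeded
#' random (He) initialization of all encoder and decoder weights. Residual
#' branches use zero-initialized batch-norm gains so deep random-init networks
#' start near the identity.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization; two builds with the same
#'   seed have identical weights.
#' @param encoder_weights Optional path to a weights file for a pretrained
#'   encoder (required when `spec$pretrained` is `TRUE`).
#' @return An object of class `ctseg_model` (an environment holding the layer
#'   graph); use [predict_mask()] or [predict_proba()] for inference and
#'   [train_model()] to fit.
#' @export
build_model <- function(spec = model_spec(), seed = 42L, encoder_weights = NULL) {
  stopifnot(inherits(spec, "ctseg_model_spec"))
  if (spec$pretrained && is.null(encoder_weights))
    stop("pretrained = TRUE requires a local `encoder_weights` file; ",
         "no download hook is provided", call. = FALSE)
  model <- local_seed(seed, {
    g <- nn_graph()
    input <- ng_add(g, "input")
    feats <- .build_encoder(g, input, spec)
    out <- switch(spec$decoder,
                  unet = .build_unet_decoder(g, feats, spec),
                  fpn = .build_fpn_decoder(g, feats, spec))
    g$spec <- spec
    g$out_id <- out
    g$adam <- NULL
    class(g) <- c("ctseg_model", class(g))
    g
  })
  if (!is.null(encoder_weights)) load_weights(model, encoder_weights)
  model
}

#' @export
print.ctseg_model <- function(x, ...) {
  np <- sum(vapply(nn_param_handles(x), function(h)
    length(x$nodes[[h$id]]$params[[h$name]]), numeric(1)))
  cat(sprintf("<ctseg_model> ResNet%d encoder + %s decoder, width x%g, %s parameters\n",
              x$spec$encoder_depth, toupper(x$spec$decoder), x$spec$width_multiplier,
              format(np, big.mark = ",")))
  invisible(x)
}

.check_div32 <- function(H, W) {
  if (H %% 32L != 0L || W %% 32L != 0L)
    stop("input spatial dimensions must be divisible by 32 (got ", H, "x", W, ")",
         call. = FALSE)
}

.pack_batch <- function(images) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]]); N <- length(images)
  x <- matrix(unlist(images, use.names = FALSE), nrow = H * W * N, ncol = 1L)
  act(x, H, W, N)
}

#' Per-pixel probability maps
#'
#' Runs the model in inference mode (batch-norm running statistics) on
#' normalized `[0, 1]` slice images. Results are independent of how slices are
#' grouped into batches.
#'
#' @param model A [build_model()] model.
#' @param images A single matrix or list of matrices with values in `[0, 1]`,
#'   spatial dimensions divisible by 32.
#' @param batch_size Slices per forward pass (plumbing only).
#' @return List of probability matrices in `[0, 1]`, same shapes as the input.
#' @export
predict_proba <- function(model, images, batch_size = 8L) {
  stopifnot(inherits(model, "ctseg_model"))
  single <- is.matrix(images)
  if (single) images <- list(images)
  if (length(images) == 0L) stop("no input slices", call. = FALSE)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  .check_div32(H, W)
  out <- vector("list", length(images))
  idx <- split(seq_along(images), ceiling(seq_along(images) / batch_size))
  for (b in idx) {
    a <- .pack_batch(images[b])
    fwd <- nn_forward(model, a, train = FALSE, keep_cache = FALSE)
    y <- fwd$acts[[model$out_id]]
    for (j in seq_along(b)) {
      out[[b[j]]] <- matrix(y$x[(j - 1L) * H * W + seq_len(H * W), 1L], H, W)
    }
  }
  if (single) out[[1]] else out
}

#' Predict binary masks for a sequence of slices
#'
#' Thresholds the model's probability maps at `threshold`; a pixel with
#' probability exactly equal to the threshold is included (`>=` convention).
#' Slice order is preserved.
#'
#' @inheritParams predict_proba
#' @param threshold Probability cut-off in `[0, 1]` (default 0.5).
#' @return List of logical mask matrices (or a single matrix for matrix input).
#' @export
predict_mask <- function(model, images, threshold = 0.5, batch_size = 8L) {
  probs <- predict_proba(model, images, batch_size = batch_size)
  if (is.matrix(probs)) probs >= threshold else lapply(probs, function(p) p >= threshold)
}

# ---- weight serialization ----------------------------------------------------

.weight_state <- function(model) {
  handles <- nn_param_handles(model)
  params <- lapply(handles, function(h) model$nodes[[h$id]]$params[[h$name]])
  names(params) <- vapply(handles, function(h) paste0("n", h$id, ".", h$name), character(1))
  bn_state <- list()
  for (node in model$nodes) {
    if (node$op == "bn")
      bn_state[[paste0("n", node$id)]] <- list(running_mean = node$state$running_mean,
                                               running_var = node$state$running_var)
  }
  list(spec = unclass(model$spec), params = params, bn_state = bn_state)
}

#' Save / load model weights
#'
#' Weights are stored with the generating [model_spec()]; loading audits the
#' spec and every parameter shape and fails on any mismatch (e.g. U-Net weights
#' into an FPN model, or a different width multiplier). After a save/load round
#' trip, predictions on a fixed input are bit-identical.
#'
#' @param model A `ctseg_model`.
#' @param path File path (RDS).
#' @return `save_weights()`: `path` invisibly; `load_weights()`: the model,
#'   invisibly, modified in place.
#' @export
save_weights <- function(model, path) {
  stopifnot(inherits(model, "ctseg_model"))
  saveRDS(.weight_state(model), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  stopifnot(inherits(model, "ctseg_model"))
  st <- readRDS(path)
  cur <- .weight_state(model)
  if (!identical(st$spec[c("encoder_depth", "decoder", "in_channels", "out_channels",
                           "width_multiplier")],
                 cur$spec[c("encoder_depth", "decoder", "in_channels", "out_channels",
                            "width_multiplier")]))
    stop("incompatible weights: model spec differs from the saved spec", call. = FALSE)
  if (!identical(names(st$params), names(cur$params)))
    stop("incompatible weights: parameter sets differ", call. = FALSE)
  for (nm in names(st$params)) {
    if (!identical(dim(st$params[[nm]]), dim(cur$params[[nm]])) ||
        length(st$params[[nm]]) != length(cur$params[[nm]]))
      stop("incompatible weights: shape mismatch at ", nm, call. = FALSE)
  }
  handles <- nn_param_handles(model)
  for (h in handles) {
    model$nodes[[h$id]]$params[[h$name]] <- st$params[[paste0("n", h$id, ".", h$name)]]
  }
  for (node in model$nodes) {
    if (node$op == "bn") {
      s <- st$bn_state[[paste0("n", node$id)]]
      node$state$running_mean <- s$running_mean
      node$state$running_var <- s$running_var
    }
  }
  invisible(model)
}
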