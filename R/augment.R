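#' Training-time augmentation configuration
#'
#' Each transform fires independently with probability `prob` (default 0.5) per
#' sample. Geometric transforms (rotation, scale, translation, flips) are
#' applied identically to the image and its mask — bilinear interpolation for
#' the image, nearest-neighbour for the mask — and the random crop fixes the
#' output size (a center crop is taken when the crop transform does not fire).
#' Intensity transforms act on the image only, on its `[0, 1]` scale. Set any
#' parameter to `NULL` to disable that transform.
#'
#' @param rotation Degree range, default `c(-5, 5)`.
#' @param scale Isotropic zoom range, default `c(0.6, 1.4)`.
#' @param translation Maximum shift in px (both axes), default 80.
#' @param crop Output crop size in px (square), default 448.
#' @param hflip,vflip Enable horizontal / vertical flips.
#' @param gamma Gamma-correction exponent range, default `c(0.5, 1.8)`.
#' @param brightness_contrast Intensity-unit range (8-bit convention, i.e.
#'   divided by 255 on the normalized scale), default `c(30, 100)`; the shift
#'   and the contrast change each get a random sign.
#' @param salt_pepper Fraction of pixels replaced by 0 or 1, default 0.1.
#' @param gaussian_noise Noise level as percent of the dynamic range (default
#'   0.5, i.e. sd 0.005 on the `[0, 1]` scale).
#' @param blur_kernels,blur_sigma Gaussian blur kernel sizes and sigma range,
#'   defaults `c(3, 7, 11)` and `c(1, 10)`.
#' @param median_kernels Median blur kernel sizes, default `c(3, 7, 11)`.
#' @param cutout Fraction of the image area occluded by a zeroed square,
#'   default 0.2.
#' @param prob Per-transform firing probability in `[0, 1]`.
#' @return Object of class `ctseg_aug_config`.
#' @export
augmentation_config <- function(rotation = c(-5, 5), scale = c(0.6, 1.4),
                                translation = 80, crop = 448,
                                hflip = TRUE, vflip = TRUE,
                                gamma = c(0.5, 1.8),
                                brightness_contrast = c(30, 100),
                                salt_pepper = 0.1, gaussian_noise = 0.5,
                                blur_kernels = c(3, 7, 11), blur_sigma = c(1, 10),
                                median_kernels = c(3, 7, 11), cutout = 0.2,
                                prob = 0.5) {
  if (prob < 0 || prob > 1) stop("`prob` must be in [0, 1]", call. = FALSE)
  structure(list(rotation = rotation, scale = scale, translation = translation,
                 crop = crop, hflip = isTRUE(hflip), vflip = isTRUE(vflip),
                 gamma = gamma, brightness_contrast = brightness_contrast,
                 salt_pepper = salt_pepper, gaussian_noise = gaussian_noise,
                 blur_kernels = blur_kernels, blur_sigma = blur_sigma,
                 median_kernels = median_kernels, cutout = cutout, prob = prob),
            class = "ctseg_aug_config")
}

# inverse-mapped affine resampling about the image center.
# theta in radians, scale isotropic, shift = c(rows, cols) in px.
.affine_sample <- function(img, theta, scale, shift, interp = c("bilinear", "nearest"),
                           fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r <- rep(seq_len(H), times = W) - cr - shift[1]
  c <- rep(seq_len(W), each = H) - cc - shift[2]
  # inverse of (rotate theta, scale s): rotate -theta, scale 1/s
  sr <- (cos(theta) * r + sin(theta) * c) / scale + cr
  sc <- (-sin(theta) * r + cos(theta) * c) / scale + cc
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- rep(fill, H * W)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    out <- rep(as.numeric(fill), H * W)
    val <- function(ri, ci) {
      ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
      v <- numeric(length(ri)); v[ok] <- img[cbind(ri[ok], ci[ok])]
      v
    }
    out <- val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
      val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
  }
  matrix(out, H, W)
}

.gauss_kernel <- function(k, sigma) {
  r <- (k - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

# same-padding 2-D convolution of a single-channel image (reuses the engine)
.filter2d <- function(img, kern) {
  k <- nrow(kern)
  a <- act(matrix(as.numeric(img), ncol = 1L), nrow(img), ncol(img), 1L)
  p <- list(W = matrix(as.numeric(kern), ncol = 1L), b = NULL, kh = k, kw = k,
            stride = 1L, pad = (k - 1L) %/% 2L, cin = 1L, cout = 1L)
  matrix(.conv_fwd(a, p)$out$x, nrow(img), ncol(img))
}

.median2d <- function(img, k) {
  ci <- .conv_idx(nrow(img), ncol(img), 1L, k, k, 1L, (k - 1L) %/% 2L)
  xz <- c(as.numeric(img), NA_real_)
  cols <- matrix(xz[ci$idx], nrow = nrow(ci$idx))
  matrix(apply(cols, 1L, stats::median, na.rm = TRUE), nrow(img), ncol(img))
}

#' Augment an image/mask pair
#'
#' Applies the configured transforms, each firing with probability
#' `cfg$prob` using the current RNG state (seed the RNG for reproducibility).
#' The output spatial size always equals `cfg$crop` (or the input size when
#' `crop` is disabled).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Logical matrix of the same shape.
#' @param cfg An [augmentation_config()].
#' @return List with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, cfg = augmentation_config()) {
  stopifnot(inherits(cfg, "ctseg_aug_config"))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  if (!is.null(cfg$crop) && (cfg$crop > nrow(image) || cfg$crop > ncol(image)))
    stop("crop size ", cfg$crop, " exceeds image size ",
         nrow(image), "x", ncol(image), call. = FALSE)
  fire <- function() stats::runif(1) < cfg$prob
  mask <- mask * 1 # numeric for resampling; re-binarized at the end

  # -- geometric (shared between image and mask) --
  theta <- 0; sc <- 1; shift <- c(0, 0); any_geom <- FALSE
  if (!is.null(cfg$rotation) && fire()) {
    theta <- stats::runif(1, cfg$rotation[1], cfg$rotation[2]) * pi / 180
    any_geom <- TRUE
  }
  if (!is.null(cfg$scale) && fire()) {
    sc <- stats::runif(1, cfg$scale[1], cfg$scale[2]); any_geom <- TRUE
  }
  if (!is.null(cfg$translation) && fire()) {
    shift <- stats::runif(2, -cfg$translation, cfg$translation); any_geom <- TRUE
  }
  if (any_geom) {
    image <- .affine_sample(image, theta, sc, shift, "bilinear")
    mask <- .affine_sample(mask, theta, sc, shift, "nearest")
  }

  # -- crop (output size contract) --
  if (!is.null(cfg$crop)) {
    H <- nrow(image); W <- ncol(image); cs <- cfg$crop
    if (fire()) {
      r0 <- if (H > cs) sample.int(H - cs + 1L, 1L) else 1L
      c0 <- if (W > cs) sample.int(W - cs + 1L, 1L) else 1L
    } else {
      r0 <- (H - cs) %/% 2L + 1L; c0 <- (W - cs) %/% 2L + 1L
    }
    image <- image[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)]
    mask <- mask[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)]
  }

  # -- flips --
  if (cfg$hflip && fire()) {
    image <- image[, rev(seq_len(ncol(image)))]
    mask <- mask[, rev(seq_len(ncol(mask)))]
  }
  if (cfg$vflip && fire()) {
    image <- image[rev(seq_len(nrow(image))), ]
    mask <- mask[rev(seq_len(nrow(mask))), ]
  }

  # -- intensity (image only) --
  if (!is.null(cfg$gamma) && fire())
    image <- pmax(image, 0)^stats::runif(1, cfg$gamma[1], cfg$gamma[2])
  if (!is.null(cfg$brightness_contrast) && fire()) {
    bc <- cfg$brightness_contrast
    delta <- sample(c(-1, 1), 1) * stats::runif(1, bc[1], bc[2]) / 255
    factor <- 1 + sample(c(-1, 1), 1) * stats::runif(1, bc[1], bc[2]) / 255
    image <- (image - 0.5) * factor + 0.5 + delta
  }
  if (!is.null(cfg$salt_pepper) && fire()) {
    n <- length(image)
    hit <- which(stats::runif(n) < cfg$salt_pepper)
    image[hit] <- stats::rbinom(length(hit), 1L, 0.5)
  }
  if (!is.null(cfg$gaussian_noise) && fire())
    image <- image + stats::rnorm(length(image), 0, cfg$gaussian_noise / 100)
  if (!is.null(cfg$blur_kernels) && fire()) {
    k <- sample(cfg$blur_kernels, 1L)
    sigma <- stats::runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2])
    image <- .filter2d(image, .gauss_kernel(k, sigma))
  }
  if (!is.null(cfg$median_kernels) && fire())
    image <- .median2d(image, sample(cfg$median_kernels, 1L))
  if (!is.null(cfg$cutout) && fire()) {
    side <- max(1L, round(sqrt(cfg$cutout) * min(dim(image))))
    r0 <- sample.int(nrow(image) - side + 1L, 1L)
    c0 <- sample.int(ncol(image) - side + 1L, 1L)
    image[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 0
  }

  list(image = pmin(pmax(image, 0), 1), mask = mask > 0.5)
}
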