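#' Focal Tversky loss configuration
#'
#' The Tversky index generalizes Dice overlap by weighting false positives by
#' `alpha` and false negatives by `beta`; the focal exponent `gamma` sharpens
#' the loss on hard examples. Defaults are the published small-organ
#' segmentation setting: alpha 0.7, beta 0.3, gamma 0.75, additive smoothing 1.
#'
#' @param alpha Weight on false positives (>= 0).
#' @param beta Weight on false negatives (>= 0); `alpha + beta` must not
#'   exceed 2.
#' @param gamma Focal exponent (> 0).
#' @param smooth Additive smoothing constant (> 0) keeping the index defined
#'   for empty masks.
#' @param form `"standard"` gives the loss `(1 - TI)^gamma` (zero for a perfect
#'   prediction); `"printed"` gives `TI^gamma`, the literal form some reports
#'   print, which is maximal - not minimal - at a perfect prediction and is
#'   provided for fidelity only.
#' @return Object of class `ctseg_loss_config`.
#' @export
loss_config <- function(alpha = 0.7, beta = 0.3, gamma = 0.75, smooth = 1,
                        form = c("standard", "printed")) {
  form <- match.arg(form)
  if (alpha < 0 || beta < 0 || alpha + beta > 2)
    stop("`alpha` and `beta` must be >= 0 with alpha + beta <= 2", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (smooth <= 0) stop("`smooth` must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, smooth = smooth,
                 form = form),
            class = "ctseg_loss_config")
}

#' Confusion counts
#'
#' Container for (possibly soft) true-positive / false-positive /
#' false-negative / true-negative counts.
#'
#' @param tp,fp,fn,tn Non-negative counts; soft (fractional) counts are allowed
#'   for loss computation, integer counts arise in evaluation.
#' @return Object of class `ctseg_counts`.
#' @export
confusion <- function(tp, fp, fn, tn = 0) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "ctseg_counts")
}

#' Tversky index
#'
#' `(TP + s) / (TP + alpha * FP + beta * FN + s)` with smoothing `s`; equals
#' the Dice coefficient when `alpha = beta = 0.5` (up to smoothing). Always in
#' `(0, 1]`; equals 1 when `FP = FN = 0`.
#'
#' @param counts A [confusion()] object (soft counts allowed).
#' @param cfg A [loss_config()].
#' @return Numeric scalar in `(0, 1]`.
#' @examples
#' tversky_index(confusion(10, 5, 5))  # 11/16 = 0.6875 at the default weights
#' @export
tversky_index <- function(counts, cfg = loss_config()) {
  stopifnot(inherits(counts, "ctseg_counts"), inherits(cfg, "ctseg_loss_config"))
  (counts$tp + cfg$smooth) /
    (counts$tp + cfg$alpha * counts$fp + cfg$beta * counts$fn + cfg$smooth)
}

.soft_counts <- function(pred, target) {
  p <- as.numeric(pred); t <- as.numeric(target)
  confusion(tp = sum(p * t), fp = sum(p * (1 - t)), fn = sum((1 - p) * t))
}

#' Focal Tversky loss
#'
#' Computes soft confusion counts pooled over the whole batch
#' (`TP = sum(p * t)` etc.) and returns `(1 - TI)^gamma` (or `TI^gamma` under
#' `form = "printed"`). Zero exactly when the prediction equals a hard target.
#'
#' @param pred Numeric matrix/array (or list of matrices) of probabilities in
#'   `[0, 1]`.
#' @param target Same shape, hard `{0,1}` or logical target masks.
#' @param cfg A [loss_config()].
#' @return Scalar loss (>= 0 for the standard form).
#' @examples
#' t <- matrix(0, 4, 4); t[2:3, 2:3] <- 1
#' focal_tversky_loss(t, t)  # perfect prediction -> 0
#' @export
focal_tversky_loss <- function(pred, target, cfg = loss_config()) {
  if (is.list(pred)) pred <- unlist(pred, use.names = FALSE)
  if (is.list(target)) target <- unlist(target, use.names = FALSE)
  if (length(pred) != length(target))
    stop("shape mismatch between `pred` and `target`", call. = FALSE)
  ti <- tversky_index(.soft_counts(pred, target), cfg)
  if (cfg$form == "printed") ti^cfg$gamma else (1 - ti)^cfg$gamma
}

# loss and d(loss)/d(pred) in one pass, for training
.focal_tversky_grad <- function(p, t, cfg) {
  tp <- sum(p * t); fp <- sum(p * (1 - t)); fn <- sum((1 - p) * t)
  den <- tp + cfg$alpha * fp + cfg$beta * fn + cfg$smooth
  num <- tp + cfg$smooth
  ti <- num / den
  # d ti / d p_i = (t_i * den - num * (t_i + alpha (1 - t_i) - beta t_i)) / den^2
  dden <- t + cfg$alpha * (1 - t) - cfg$beta * t
  dti <- (t * den - num * dden) / den^2
  if (cfg$form == "printed") {
    loss <- ti^cfg$gamma
    dl_dti <- cfg$gamma * ti^(cfg$gamma - 1)
  } else {
    base <- max(1 - ti, 1e-8) # gamma < 1 makes the derivative singular at ti = 1
    loss <- base^cfg$gamma
    dl_dti <- -cfg$gamma * base^(cfg$gamma - 1)
  }
  list(loss = loss, grad = dl_dti * dti)
}
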