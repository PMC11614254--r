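#' Training configuration
#'
#' The published protocol: 50 epochs, batch size 16, Adam with initial learning
#' rate and weight decay 1e-4, and a multi-step schedule dropping the rate by a
#' factor of 0.1 after epochs 20, 30 and 40, under 5-fold patient-grouped
#' cross-validation. Every field may be overridden for desk-scale runs.
#'
#' @param epochs Number of epochs.
#' @param batch_size Slices per optimizer step.
#' @param lr0 Initial learning rate.
#' @param weight_decay L2 penalty added to gradients (Adam convention).
#' @param milestones Strictly increasing epoch indices (< `epochs`) at which
#'   the learning rate is multiplied by `lr_factor`.
#' @param lr_factor Multiplicative decay at each milestone.
#' @param folds Cross-validation folds (>= 2).
#' @param seed Master seed for shuffling and augmentation.
#' @return Object of class `ctseg_train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 16L, lr0 = 1e-4,
                         weight_decay = 1e-4, milestones = c(20L, 30L, 40L),
                         lr_factor = 0.1, folds = 5L, seed = 1L) {
  milestones <- as.integer(milestones)
  if (length(milestones) && (is.unsorted(milestones, strictly = TRUE) ||
                             any(milestones >= epochs)))
    stop("`milestones` must be strictly increasing and < epochs", call. = FALSE)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, weight_decay = weight_decay, milestones = milestones,
                 lr_factor = lr_factor, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "ctseg_train_config")
}

#' Learning rate at a given epoch
#'
#' Multi-step schedule: `lr0 * lr_factor^(number of milestones <= epoch)`.
#' Epochs are 0-based, matching the convention that the rate is "reduced after"
#' the milestone epoch has been reached.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param cfg A [train_config()].
#' @return Learning rate.
#' @examples
#' lr_at_epoch(10, train_config())  # 1e-4
#' lr_at_epoch(45, train_config())  # 1e-7
#' @export
lr_at_epoch <- function(epoch, cfg = train_config()) {
  stopifnot(epoch >= 0, epoch < cfg$epochs)
  cfg$lr0 * cfg$lr_factor^sum(cfg$milestones <= epoch)
}

#' Desk-scale training configuration
#'
#' A small-budget protocol for CPU-only runs on phantom data: 30 epochs, batch
#' size 8, initial learning rate 3e-3 with one decay step after epoch 25.
#' The hotter initial rate (vs. the full protocol's 1e-4) is what a
#' randomly-initialized narrow model needs to converge within a few dozen
#' optimizer steps; the full-scale protocol assumes a pretrained encoder and
#' tens of thousands of slices.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
desk_train_config <- function(seed = 7L, ...) {
  defaults <- list(epochs = 30L, batch_size = 8L, lr0 = 3e-3,
                   weight_decay = 1e-4, milestones = 25L, lr_factor = 0.1,
                   seed = seed)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(train_config, defaults)
}

# one Adam step over all trainable parameters (weight decay in the gradient)
.adam_step <- function(model, grads, lr, wd, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(model$adam)) model$adam <- list(t = 0L, m = list(), v = list())
  st <- model$adam
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (h in nn_param_handles(model)) {
    key <- paste0("n", h$id, ".", h$name)
    p <- model$nodes[[h$id]]$params[[h$name]]
    g <- grads[[h$id]][[h$name]]
    if (is.null(g)) next
    g <- g + wd * p
    m <- if (is.null(st$m[[key]])) g * 0 else st$m[[key]]
    v <- if (is.null(st$v[[key]])) g * 0 else st$v[[key]]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    st$m[[key]] <- m; st$v[[key]] <- v
    model$nodes[[h$id]]$params[[h$name]] <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  model$adam <- st
  invisible(model)
}

.pooled_dsc <- function(preds, masks) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(preds)) {
    p <- preds[[i]]; t <- masks[[i]]
    tp <- tp + sum(p & t); fp <- fp + sum(p & !t); fn <- fn + sum(!p & t)
  }
  if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

#' Train a segmentation model
#'
#' Fits the model on the slices of `manifest` (each must carry a ground-truth
#' mask) by minimizing the Focal Tversky loss with Adam under the multi-step
#' learning-rate schedule of `cfg`. Augmentations, shuffling and
#' initialization all draw from RNG streams seeded by `cfg$seed`, so a run is
#' reproducible. The per-epoch history records the learning rate, mean batch
#' loss, and the pooled training Dice coefficient measured in inference mode.
#'
#' @param model A [build_model()] model (modified in place).
#' @param manifest Manifest tibble with masks for every slice.
#' @param cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param aug_cfg Optional [augmentation_config()]; `NULL` disables
#'   augmentation.
#' @param dsc_every Measure training DSC every this many epochs (1 = every
#'   epoch; 0 disables, recording `NA`).
#' @param verbose Print a line per epoch.
#' @return Object of class `ctseg_fit`: `model`, `history` tibble
#'   (epoch, lr, loss, dsc), and the configurations used.
#' @export
train_model <- function(model, manifest, cfg = train_config(),
                        loss_cfg = loss_config(), aug_cfg = NULL,
                        dsc_every = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "ctseg_model"), inherits(cfg, "ctseg_train_config"))
  if (nrow(manifest) == 0L) stop("no training data: manifest is empty", call. = FALSE)
  data <- load_manifest_data(manifest, normalize = TRUE)
  if (any(vapply(data$masks, is.null, logical(1))))
    stop("every training slice needs a ground-truth mask", call. = FALSE)
  n <- length(data$images)
  history <- vector("list", cfg$epochs)
  local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- lr_at_epoch(epoch, cfg)
      ord <- sample.int(n)
      losses <- c()
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (b in batches) {
        imgs <- data$images[b]; msks <- data$masks[b]
        if (!is.null(aug_cfg)) {
          for (j in seq_along(b)) {
            a <- augment(imgs[[j]], msks[[j]], aug_cfg)
            imgs[[j]] <- a$image; msks[[j]] <- a$mask
          }
        }
        x <- .pack_batch(imgs)
        t <- as.numeric(unlist(msks, use.names = FALSE))
        fwd <- nn_forward(model, x, train = TRUE, keep_cache = TRUE)
        p <- fwd$acts[[model$out_id]]$x[, 1L]
        lg <- .focal_tversky_grad(p, t, loss_cfg)
        grads <- nn_backward(model, fwd, matrix(lg$grad, ncol = 1L),
                             out_id = model$out_id)
        .adam_step(model, grads, lr, cfg$weight_decay)
        losses <- c(losses, lg$loss)
      }
      dsc <- NA_real_
      if (dsc_every > 0L && ((epoch + 1L) %% dsc_every == 0L || epoch == cfg$epochs - 1L)) {
        preds <- predict_mask(model, data$images, batch_size = cfg$batch_size)
        dsc <- .pooled_dsc(preds, data$masks)
      }
      history[[epoch + 1L]] <- tibble::tibble(epoch = epoch + 1L, lr = lr,
                                              loss = mean(losses), dsc = dsc)
      if (verbose)
        message(sprintf("epoch %3d  lr %.1e  loss %.4f  dsc %s", epoch + 1L, lr,
                        mean(losses), ifelse(is.na(dsc), "-", sprintf("%.3f", dsc))))
    }
  })
  structure(list(model = model, history = dplyr::bind_rows(history),
                 train_config = cfg, loss_config = loss_cfg, aug_config = aug_cfg,
                 n_slices = n),
            class = "ctseg_fit")
}

#' @export
print.ctseg_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<ctseg_fit> %d epochs on %d slices; final loss %.4f, training DSC %s\n",
              nrow(x$history), x$n_slices, last$loss,
              ifelse(is.na(last$dsc), "-", sprintf("%.3f", last$dsc))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history
#'
#' @param x A `ctseg_fit`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `lr`, `loss`, `dsc`.
#' @method tidy ctseg_fit
#' @export
tidy.ctseg_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x A `ctseg_fit`.
#' @param ... Unused.
#' @return One-row tibble: epochs, slices, final loss, final training DSC.
#' @method glance ctseg_fit
#' @export
glance.ctseg_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), n_slices = x$n_slices,
                 final_loss = last$loss, final_dsc = last$dsc)
}

#' Plot a training history
#'
#' @param object A `ctseg_fit`.
#' @param ... Unused.
#' @return A ggplot: loss and training DSC per epoch.
#' @method autoplot ctseg_fit
#' @export
autoplot.ctseg_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "dsc"),
                            names_to = "metric", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Patient-grouped cross-validated training
#'
#' Splits the manifest's patients into `cfg$folds` grouped folds, trains one
#' model per fold on the training patients, and evaluates pooled segmentation
#' metrics on the fold's validation patients. Folds are trained independently
#' and reported separately.
#'
#' @param spec A [model_spec()] used to build each fold's model.
#' @param manifest Manifest tibble with masks.
#' @inheritParams train_model
#' @return List with `folds` (per-fold `ctseg_fit`), `metrics` (tibble of
#'   per-fold validation dsc/recall/precision) and the fold assignment tibble.
#' @export
train_cv <- function(spec, manifest, cfg = train_config(),
                     loss_cfg = loss_config(), aug_cfg = NULL, verbose = FALSE) {
  assign_tbl <- group_kfold_split(manifest$patient_id, k = cfg$folds, seed = cfg$seed)
  fits <- vector("list", cfg$folds)
  rows <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    val_pat <- assign_tbl$patient_id[assign_tbl$fold == f]
    tr_man <- manifest[!manifest$patient_id %in% val_pat, , drop = FALSE]
    va_man <- manifest[manifest$patient_id %in% val_pat, , drop = FALSE]
    attr(tr_man, "root") <- attr(va_man, "root") <- manifest_root(manifest)
    model <- build_model(spec, seed = cfg$seed + f)
    fit <- train_model(model, tr_man, cfg, loss_cfg, aug_cfg,
                       dsc_every = 0L, verbose = verbose)
    fits[[f]] <- fit
    va <- load_manifest_data(va_man)
    preds <- predict_mask(model, va$images, batch_size = cfg$batch_size)
    m <- seg_metrics(preds, va$masks)
    rows[[f]] <- dplyr::mutate(m, fold = f, .before = 1L)
  }
  list(folds = fits, metrics = dplyr::bind_rows(rows), assignment = assign_tbl)
}

#' Read a YAML training configuration
#'
#' The file mirrors the configuration objects field-for-field under the keys
#' `train`, `loss` and `augment` (an absent `augment` key disables
#' augmentation; `augment: default` uses the published defaults).
#'
#' @param path YAML file path.
#' @return List with `train` ([train_config()]), `loss` ([loss_config()]) and
#'   `augment` ([augmentation_config()] or `NULL`).
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  train <- do.call(train_config, y$train %||% list())
  loss <- do.call(loss_config, y$loss %||% list())
  aug <- if (is.null(y$augment)) NULL
         else if (identical(y$augment, "default")) augmentation_config()
         else do.call(augmentation_config, y$augment)
  list(train = train, loss = loss, augment = aug)
}
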