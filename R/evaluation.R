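#' Pixel confusion counts between two masks
#'
#' @param pred,gt Logical matrices of equal shape (prediction and ground
#'   truth).
#' @return A [confusion()] with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("shape mismatch between prediction and ground truth", call. = FALSE)
  pred <- pred > 0; gt <- gt > 0
  tp <- sum(pred & gt)
  confusion(tp = tp, fp = sum(pred) - tp, fn = sum(gt) - tp,
            tn = length(pred) - sum(pred | gt))
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`, defined as 1 when both masks are empty
#' (`TP = FP = FN = 0`).
#'
#' @param counts A [confusion()].
#' @return Value in `[0, 1]`.
#' @export
dsc <- function(counts) {
  stopifnot(inherits(counts, "ctseg_counts"))
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) 1 else 2 * counts$tp / den
}

.seg_from_counts <- function(tp, fp, fn) {
  tibble::tibble(
    dsc = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),       # nothing to find
    precision = if (tp + fp == 0) 1 else tp / (tp + fp)     # no false alarms made
  )
}

#' Per-scan segmentation metrics
#'
#' Pools pixel confusion counts over all slices of a scan and computes DSC,
#' recall and precision once per scan (per-volume convention); `per = "slice"`
#' instead returns one row per slice. An empty prediction against a non-empty
#' ground truth scores recall 0, DSC 0 and precision 1 (no false positives
#' were made); two empty masks score 1 throughout.
#'
#' @param pred,gt Lists of logical mask matrices, equal length and shapes.
#' @param per `"volume"` (default) or `"slice"`.
#' @return Tibble of `dsc`, `recall`, `precision` (one row per scan, or per
#'   slice).
#' @export
seg_metrics <- function(pred, gt, per = c("volume", "slice")) {
  per <- match.arg(per)
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(gt)) gt <- list(gt)
  if (length(pred) != length(gt))
    stop("prediction and ground truth have different slice counts", call. = FALSE)
  counts <- purrr::map(seq_along(pred), ~confusion_counts(pred[[.x]], gt[[.x]]))
  if (per == "slice") {
    return(dplyr::bind_rows(purrr::map(counts, ~.seg_from_counts(.x$tp, .x$fp, .x$fn))))
  }
  tp <- sum(purrr::map_dbl(counts, "tp"))
  fp <- sum(purrr::map_dbl(counts, "fp"))
  fn <- sum(purrr::map_dbl(counts, "fn"))
  .seg_from_counts(tp, fp, fn)
}

#' Classify one slice for organ detection
#'
#' A slice counts as a true positive when the ground truth is non-empty and
#' the prediction overlaps it by at least one pixel; non-empty ground truth
#' with no overlap is a false negative (even if the prediction is non-empty
#' elsewhere — the miss dominates); empty ground truth with a non-empty
#' prediction is a false positive; two empty masks are a true negative.
#'
#' @param pred,gt Logical matrices of equal shape.
#' @return One of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
detect_slice <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("shape mismatch between prediction and ground truth", call. = FALSE)
  gt_any <- any(gt); pr_any <- any(pred)
  if (gt_any) {
    if (any(pred & gt)) "TP" else "FN"
  } else {
    if (pr_any) "FP" else "TN"
  }
}

#' Tally slice-level detections over a scan or dataset
#'
#' @param pred,gt Lists of logical mask matrices.
#' @return A [confusion()] of slice counts.
#' @export
detection_tally <- function(pred, gt) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(gt)) gt <- list(gt)
  stopifnot(length(pred) == length(gt))
  cls <- vapply(seq_along(pred), function(i) detect_slice(pred[[i]], gt[[i]]), character(1))
  confusion(tp = sum(cls == "TP"), fp = sum(cls == "FP"),
            fn = sum(cls == "FN"), tn = sum(cls == "TN"))
}

#' Slice-level detection metrics
#'
#' Accuracy, specificity, sensitivity, positive and negative predictive value
#' from a slice-level tally, as percentages. Ratios with a zero denominator
#' are reported as `NA` (missing), never as 0.
#'
#' @param tally A [confusion()] of slice counts with at least one slice.
#' @return One-row tibble of percentages: `accuracy`, `specificity`,
#'   `sensitivity`, `ppv`, `npv`.
#' @export
detection_metrics <- function(tally) {
  stopifnot(inherits(tally, "ctseg_counts"))
  n <- tally$tp + tally$fp + tally$fn + tally$tn
  if (n == 0) stop("no slices in tally", call. = FALSE)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    accuracy = pct(tally$tp + tally$tn, n),
    specificity = pct(tally$tn, tally$tn + tally$fp),
    sensitivity = pct(tally$tp, tally$tp + tally$fn),
    ppv = pct(tally$tp, tally$tp + tally$fp),
    npv = pct(tally$tn, tally$tn + tally$fn)
  )
}

#' Mean and standard deviation over per-scan metrics
#'
#' @param metrics Tibble of per-scan metric rows (e.g. repeated
#'   [seg_metrics()] results), all columns numeric.
#' @return Tibble with one row per metric: `metric`, `mean`, `sd` (sample SD,
#'   0 for a single scan).
#' @export
dataset_summary <- function(metrics) {
  if (nrow(metrics) == 0L) stop("no scans to summarize", call. = FALSE)
  tidyr::pivot_longer(metrics, dplyr::where(is.numeric),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1L) stats::sd(.data$value, na.rm = TRUE) else 0,
      .groups = "drop"
    )
}

#' Evaluate predicted masks against a ground-truth manifest
#'
#' Runs a model over every scan in the manifest and reports per-scan pooled
#' segmentation metrics plus the dataset-level slice-detection tally.
#'
#' @param model A `ctseg_model`.
#' @param manifest Manifest tibble with ground-truth masks.
#' @param threshold Probability threshold for [predict_mask()].
#' @return List with `per_scan` (tibble: patient_id, dsc, recall, precision),
#'   `summary` (mean/SD tibble), `detection` (percent metrics tibble) and
#'   `tally` (slice counts).
#' @export
evaluate_dataset <- function(model, manifest, threshold = 0.5) {
  data <- load_manifest_data(manifest)
  preds <- predict_mask(model, data$images, threshold = threshold)
  idx <- split(seq_len(nrow(manifest)), manifest$patient_id)
  per_scan <- dplyr::bind_rows(purrr::imap(idx, function(i, pid) {
    dplyr::mutate(seg_metrics(preds[i], data$masks[i]), patient_id = pid, .before = 1L)
  }))
  tally <- detection_tally(preds, data$masks)
  list(per_scan = per_scan,
       summary = dataset_summary(per_scan[, c("dsc", "recall", "precision")]),
       detection = detection_metrics(tally),
       tally = tally)
}

#' Plot per-scan segmentation metrics
#'
#' @param object Tibble as returned in `evaluate_dataset()$per_scan`.
#' @param ... Unused.
#' @return A ggplot of the per-scan metric distributions.
#' @export
plot_seg_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("dsc", "recall", "precision"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-scan segmentation metrics")
}
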