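#' Patient-grouped k-fold split
#'
#' Assigns every patient to exactly one validation fold so that no patient's
#' slices ever straddle the train/validation boundary. Patients are shuffled
#' with `seed` and then greedily assigned (largest slice count first) to the
#' currently lightest fold, which balances fold sizes: 13 single-scan patients
#' over 5 folds give validation sizes 3/3/3/2/2.
#'
#' @param patient_ids Character vector of patient identifiers, one entry per
#'   slice (or per scan); repeated ids are weighted by their multiplicity.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return A tibble with one row per distinct patient: `patient_id` and `fold`
#'   (the validation fold, `1..k`).
#' @export
group_kfold_split <- function(patient_ids, k = 5L, seed = 1L) {
  counts <- table(patient_ids)
  if (length(counts) < k)
    stop("fewer distinct patients (", length(counts), ") than folds (", k, ")",
         call. = FALSE)
  ids <- names(counts)
  w <- as.integer(counts)
  ord <- local_seed(seed, sample.int(length(ids)))
  ids <- ids[ord]; w <- w[ord]
  ord2 <- order(-w) # largest groups placed first (stable: keeps shuffle order in ties)
  fold <- integer(length(ids))
  load <- numeric(k)
  for (i in ord2) {
    f <- which.min(load)
    fold[i] <- f
    load[f] <- load[f] + w[i]
  }
  tibble::tibble(patient_id = ids, fold = fold) |> dplyr::arrange(.data$patient_id)
}

#' Patient-level train/test hold-out
#'
#' Randomly assigns a fraction of patients to a held-out test set with no
#' stratification (80 scans at the default 20% give a 64/16 split).
#'
#' @param patient_ids Character vector of patient identifiers.
#' @param test_fraction Fraction of distinct patients held out (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` character vectors of patient ids.
#' @export
holdout_split <- function(patient_ids, test_fraction = 0.2, seed = 1L) {
  ids <- unique(patient_ids)
  n_test <- round(test_fraction * length(ids))
  test <- local_seed(seed, sample(ids, n_test))
  list(train = setdiff(ids, test), test = test)
}

#' Drop slices whose mask is empty
#'
#' Retains only manifest rows whose ground-truth mask contains at least one
#' foreground pixel, preserving order. Uses the manifest's `mask_area` column
#' when available, otherwise reads the mask files.
#'
#' @param manifest Manifest tibble (see [convert_volume()]).
#' @return Filtered manifest (possibly empty).
#' @export
filter_empty_slices <- function(manifest) {
  area <- manifest$mask_area
  if (is.null(area) || anyNA(area)) {
    root <- manifest_root(manifest)
    area <- vapply(seq_len(nrow(manifest)), function(i) {
      if (is.na(manifest$mask[i])) 0L
      else sum(read_mask_png(file.path(root, manifest$mask[i])))
    }, integer(1))
  }
  out <- manifest[area > 0L, , drop = FALSE]
  attr(out, "root") <- attr(manifest, "root", exact = TRUE)
  out
}

#' Merge slice-store manifests from multiple sources
#'
#' Concatenates manifests, resolving image/mask paths against each manifest's
#' own root so the merged manifest is self-contained, and keeps patient-id
#' namespaces separate through the `source` column. Duplicate
#' (source, patient, slice) keys are an error.
#'
#' @param ... Manifest tibbles.
#' @return Combined manifest tibble with root `"."`.
#' @export
merge_datasets <- function(...) {
  mans <- list(...)
  stopifnot(length(mans) >= 1L)
  resolved <- purrr::map(mans, function(m) {
    root <- manifest_root(m)
    m$image <- file.path(root, m$image)
    m$mask <- ifelse(is.na(m$mask), NA_character_, file.path(root, m$mask))
    m
  })
  out <- dplyr::bind_rows(resolved)
  key <- paste(out$source, out$patient_id, out$slice_index)
  if (anyDuplicated(key))
    stop("collision: duplicate (source, patient, slice) keys in merged manifests",
         call. = FALSE)
  attr(out, "root") <- "."
  out
}
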