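#' Convert an HU volume to a windowed PNG slice store
#'
#' Applies a window/level transform to every axial slice and writes one
#' grayscale PNG per slice (plus one binary mask PNG per slice when masks are
#' supplied), with deterministic zero-padded names
#' `<patientID>_<sliceIndex>.png` (0-based, 4 digits). A JSON manifest listing
#' the files in slice order is written alongside.
#'
#' @param volume A [hu_volume()].
#' @param spec A [window_spec()]; its `bit_depth` decides the PNG depth.
#' @param out_dir Output directory (created if needed).
#' @param masks Optional logical array with the same dimensions as
#'   `volume$slices`, the per-slice ground-truth masks.
#' @param source Provenance tag recorded per slice (dataset name).
#' @param force Overwrite an existing manifest in `out_dir` (default refuse).
#' @return The manifest as a tibble (one row per slice) with columns `source`,
#'   `patient_id`, `slice_index`, `image`, `mask`, `mask_area`, `phase`,
#'   `height`, `width`, `bit_depth`. Paths are relative to `out_dir`; the
#'   tibble carries `out_dir` as attribute `root`.
#' @export
convert_volume <- function(volume, spec = window_spec(), out_dir,
                           masks = NULL, source = "local", force = FALSE) {
  stopifnot(inherits(volume, "ctseg_volume"), inherits(spec, "ctseg_window"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("manifest already exists in ", out_dir, " (use force = TRUE to overwrite)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$slices)
  if (!is.null(masks)) stopifnot(identical(dim(masks), d))
  n <- d[1]
  rows <- purrr::map(seq_len(n) - 1L, function(i) {
    img_name <- sprintf("%s_%04d.png", volume$patient_id, i)
    px <- apply_window(volume$slices[i + 1L, , ], spec)
    write_slice_png(px, file.path(out_dir, img_name), spec$bit_depth)
    mask_name <- NA_character_; area <- NA_integer_
    if (!is.null(masks)) {
      mask_name <- sprintf("%s_%04d_mask.png", volume$patient_id, i)
      m <- masks[i + 1L, , ]
      write_mask_png(m, file.path(out_dir, mask_name))
      area <- sum(m)
    }
    tibble::tibble(source = source, patient_id = volume$patient_id,
                   slice_index = i, image = img_name, mask = mask_name,
                   mask_area = area, phase = volume$phase,
                   height = d[2], width = d[3], bit_depth = spec$bit_depth)
  })
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, manifest_path)
  attr(manifest, "root") <- out_dir
  manifest
}

#' Write / read a slice-store manifest
#'
#' Manifests are JSON arrays of per-slice records; paths are stored relative to
#' the manifest's directory, which becomes the tibble's `root` attribute on
#' read.
#'
#' @param manifest Manifest tibble (see [convert_volume()]).
#' @param path JSON file path.
#' @return `write_manifest()`: `path` invisibly. `read_manifest()`: the
#'   manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(as.data.frame(manifest), path, auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- jsonlite::fromJSON(path)
  out <- tibble::as_tibble(df)
  out$slice_index <- as.integer(out$slice_index)
  attr(out, "root") <- dirname(path)
  out
}

manifest_root <- function(manifest) {
  r <- attr(manifest, "root", exact = TRUE)
  if (is.null(r)) "." else r
}

#' Load image and mask pixel data referenced by a manifest
#'
#' @param manifest Manifest tibble.
#' @param normalize Divide image intensities by the bit-depth maximum into
#'   `[0, 1]` (the network input convention).
#' @return List with `images` (list of matrices in slice order) and `masks`
#'   (list of logical matrices, `NULL` where the manifest has no mask).
#' @export
load_manifest_data <- function(manifest, normalize = TRUE) {
  root <- manifest_root(manifest)
  images <- purrr::map(seq_len(nrow(manifest)), function(i) {
    img <- read_slice_png(file.path(root, manifest$image[i]))
    if (normalize) img$pixels / (2^img$bit_depth - 1) else img$pixels
  })
  masks <- purrr::map(seq_len(nrow(manifest)), function(i) {
    if (is.na(manifest$mask[i])) NULL
    else read_mask_png(file.path(root, manifest$mask[i]))
  })
  list(images = images, masks = masks)
}
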