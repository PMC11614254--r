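# Deterministic CT phantom: a soft-tissue body ellipse in air, an elongated
# tapered target blob (pancreas-like head-to-tail profile) on a contiguous
# central run of slices, and distractor blobs of similar HU. Every module is
# testable against it with no data download.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom generator configuration
#'
#' @param n_slices Number of axial slices.
#' @param size Pixels per side (must be divisible by 32 so generated slices can
#'   feed the segmentation network directly).
#' @param seed Integer seed; identical configs give bit-identical phantoms.
#' @param organ_hu Mean HU of the target blob (default 90, an enhancing
#'   pancreas in the portal venous phase).
#' @param background_hu Mean HU of surrounding soft tissue (default 40); the
#'   modest 50 HU contrast emulates the low organ/background separation that
#'   makes abdominal segmentation hard.
#' @param noise_sd Gaussian HU noise standard deviation (default 10).
#' @param organ_present If `FALSE`, the volume contains no target and all masks
#'   are empty (a scan without the organ in the field of view).
#' @param distractor_count Number of similar-HU (within 15 HU) blobs that are
#'   not part of the ground truth (default 3).
#' @return An object of class `ctseg_phantom_config`.
#' @export
phantom_config <- function(n_slices = 16, size = 128, seed = 1L,
                           organ_hu = 90, background_hu = 40, noise_sd = 10,
                           organ_present = TRUE, distractor_count = 3L) {
  if (size %% 32 != 0) stop("`size` must be divisible by 32", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  stopifnot(n_slices >= 1, distractor_count >= 0)
  structure(
    list(n_slices = as.integer(n_slices), size = as.integer(size),
         seed = as.integer(seed), organ_hu = organ_hu,
         background_hu = background_hu, noise_sd = noise_sd,
         organ_present = isTRUE(organ_present),
         distractor_count = as.integer(distractor_count)),
    class = "ctseg_phantom_config"
  )
}

# rotated, tapered super-ellipse on an integer grid; returns logical matrix
.blob_mask <- function(size, center, semi_major, semi_minor, theta, power = 2.5,
                       taper = 0.35) {
  g <- seq_len(size)
  dx <- outer(g - center[1], rep(1, size))    # row offsets
  dy <- outer(rep(1, size), g - center[2])    # col offsets
  xr <- (cos(theta) * dx + sin(theta) * dy) / semi_major
  yr <- (-sin(theta) * dx + cos(theta) * dy) / semi_minor
  w <- 1 - taper * (pmin(pmax(xr, -1), 1) + 1) / 2  # thinner toward the tail
  abs(xr)^power + abs(yr / w)^power <= 1
}

.body_mask <- function(size) {
  g <- seq_len(size)
  c0 <- (size + 1) / 2
  dx <- outer(g - c0, rep(1, size)) / (0.45 * size)
  dy <- outer(rep(1, size), g - c0) / (0.38 * size)
  dx^2 + dy^2 <= 1
}

#' Generate a CT-like phantom volume with ground-truth masks
#'
#' Builds a body ellipse of soft tissue (`background_hu` plus Gaussian noise)
#' surrounded by air (-1000 HU). If `organ_present`, an elongated rotated
#' super-ellipse blob at `organ_hu` — its in-plane width tapering from head to
#' tail and its per-slice area tapering over a contiguous central run of
#' slices — defines the ground truth. Distractor blobs with HU within 15 of
#' `organ_hu` are placed inside the body but never overlap the target mask.
#' Output is identical for identical configs.
#'
#' @param config A [phantom_config()].
#' @return List with `volume` (a [hu_volume()]) and `masks` (logical array of
#'   the same dimensions, `TRUE` exactly on target-blob pixels).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "ctseg_phantom_config"))
  local_seed(config$seed, {
    S <- config$size; n <- config$n_slices
    body <- .body_mask(S)
    c0 <- (S + 1) / 2
    slices <- array(-1000, dim = c(n, S, S))
    masks <- array(FALSE, dim = c(n, S, S))

    # target placement (drawn even when absent, to keep RNG streams aligned)
    theta <- stats::runif(1, -pi / 6, pi / 6)
    off <- stats::runif(2, -0.12 * S, 0.12 * S)
    center <- c(c0 + off[1], c0 + off[2])
    z0 <- max(1L, round(0.25 * n)); z1 <- min(n, max(z0, round(0.75 * n)))
    a_max <- 0.16 * S; b_max <- 0.06 * S

    # distractor geometry
    ndis <- config$distractor_count
    dis <- vector("list", ndis)
    target_zone <- .blob_mask(S, center, a_max + 3, b_max + 3, theta)
    for (j in seq_len(ndis)) {
      for (try in 1:50) {
        dc <- c0 + stats::runif(2, -0.3 * S, 0.3 * S)
        r <- stats::runif(1, 0.02 * S, 0.05 * S)
        m <- .blob_mask(S, dc, r * stats::runif(1, 1.2, 2), r, stats::runif(1, -pi, pi))
        if (!any(m & !body) && !any(m & target_zone)) break
        m <- NULL
      }
      dis[[j]] <- list(mask = m, hu = config$organ_hu + stats::runif(1, -15, 15),
                       zr = sort(sample.int(n, 2L, replace = TRUE)))
    }

    for (z in seq_len(n)) {
      hu <- matrix(-1000, S, S)
      hu[body] <- config$background_hu
      for (j in seq_len(ndis)) {
        d <- dis[[j]]
        if (!is.null(d$mask) && z >= d$zr[1] && z <= d$zr[2]) hu[d$mask] <- d$hu
      }
      if (config$organ_present && z >= z0 && z <= z1) {
        frac <- if (z1 > z0) (z - z0) / (z1 - z0) else 0.5
        scale <- 0.55 + 0.45 * sin(pi * (0.1 + 0.8 * frac)) # per-slice area taper
        m <- .blob_mask(S, center, a_max * scale, b_max * scale, theta) & body
        hu[m] <- config$organ_hu
        masks[z, , ] <- m
      }
      if (config$noise_sd > 0) hu <- hu + matrix(stats::rnorm(S * S, 0, config$noise_sd), S, S)
      slices[z, , ] <- hu
    }

    vol <- hu_volume(slices, pixel_spacing = c(0.8, 0.8), slice_thickness = 2.5,
                     patient_id = sprintf("phantom%04d", config$seed %% 10000L),
                     phase = "portal venous")
    list(volume = vol, masks = masks)
  })
}

#' Generate a multi-scan phantom dataset as a PNG slice store
#'
#' Generates `n_scans` phantoms with per-scan seeds derived deterministically
#' from `seed`, converts each to windowed PNGs with masks under
#' `out_dir/<patient>/`, and returns the combined manifest. Scan slice counts
#' vary around the template's `n_slices` (emulating variable scan lengths), and
#' a deterministic fraction of scans is organ-absent: the last
#' `round(absent_fraction * n_scans)` scans.
#'
#' @param n_scans Number of scans (>= 1).
#' @param config Template [phantom_config()]; per-scan seed and presence
#'   override its `seed`/`organ_present`.
#' @param seed Master seed for the dataset.
#' @param out_dir Output directory.
#' @param absent_fraction Fraction of scans generated without the target organ.
#' @param spec [window_spec()] used for conversion.
#' @param vary_length Vary per-scan slice count by up to ±25% (default TRUE).
#' @return Combined manifest tibble (root attribute = `out_dir`) with one row
#'   per slice.
#' @export
generate_dataset <- function(n_scans, config = phantom_config(), seed = 1L,
                             out_dir, absent_fraction = 0,
                             spec = window_spec(), vary_length = TRUE) {
  stopifnot(n_scans >= 1)
  n_absent <- round(absent_fraction * n_scans)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_len(n_scans), function(i) {
    scan_seed <- (as.integer(seed) * 131L + i * 7919L) %% 2147483647L
    cfg <- config
    cfg$seed <- scan_seed
    cfg$organ_present <- config$organ_present && (i <= n_scans - n_absent)
    if (vary_length)
      cfg$n_slices <- max(4L, as.integer(round(config$n_slices *
        local_seed(scan_seed + 1L, stats::runif(1, 0.75, 1.25)))))
    ph <- generate_phantom(cfg)
    pid <- sprintf("phantom%03d", i)
    ph$volume$patient_id <- pid
    man <- convert_volume(ph$volume, spec, file.path(out_dir, pid),
                          masks = ph$masks, source = "phantom", force = TRUE)
    man$image <- file.path(pid, man$image)
    man$mask <- ifelse(is.na(man$mask), NA_character_, file.path(pid, man$mask))
    man
  })
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  attr(manifest, "root") <- out_dir
  manifest
}
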