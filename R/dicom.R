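# Minimal single-series DICOM support: enough of Part 10 (little-endian,
# explicit or implicit VR, single-frame grayscale) to read CT series into
# calibrated HU volumes and to write synthetic fixtures for tests. No R DICOM
# package is available, so the subset used here is implemented directly.

#' Calibrated Hounsfield-unit CT volume
#'
#' An ordered stack of axial CT slices in calibrated HU, with voxel geometry
#' and minimal patient metadata. Slices are ordered by ascending position along
#' the slice axis.
#'
#' @param slices 3-D numeric array, `slice x row x col`, in HU.
#' @param pixel_spacing Length-2 numeric, mm per pixel (row, col).
#' @param slice_thickness Slice thickness in mm.
#' @param patient_id Opaque patient/scan identifier.
#' @param phase Free-text acquisition-phase tag (e.g. "portal venous").
#' @return An object of class `ctseg_volume`.
#' @export
hu_volume <- function(slices, pixel_spacing = c(1, 1), slice_thickness = 1,
                      patient_id = "anon", phase = "") {
  if (length(dim(slices)) != 3L || dim(slices)[1] < 1L)
    stop("`slices` must be a 3-D array with at least one slice", call. = FALSE)
  structure(
    list(slices = slices, pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness),
         patient_id = as.character(patient_id), phase = as.character(phase)),
    class = "ctseg_volume"
  )
}

#' @export
print.ctseg_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<ctseg_volume> patient %s: %d slices of %dx%d px, %.3gx%.3g mm spacing, %.3g mm thick%s\n",
              x$patient_id, d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_thickness, if (nzchar(x$phase)) paste0(" [", x$phase, "]") else ""))
  invisible(x)
}

#' @export
dim.ctseg_volume <- function(x) dim(x$slices)

# ---- low-level element I/O ---------------------------------------------------

.dcm_vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# implicit-VR dictionary for the tags the reader interprets
.dcm_dict <- c(
  "0008,0018" = "UI", "0008,0016" = "UI", "0008,103E" = "LO",
  "0010,0020" = "LO", "0018,0050" = "DS",
  "0020,000D" = "UI", "0020,000E" = "UI", "0020,0013" = "IS",
  "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US", "0028,0011" = "US",
  "0028,0030" = "DS", "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US",
  "0028,0103" = "US", "0028,1052" = "DS", "0028,1053" = "DS",
  "7FE0,0010" = "OW"
)

.u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

.tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

.parse_elements <- function(bytes, pos, explicit, stop_at = NULL) {
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n + 1L && pos <= n) {
    if (pos + 7L > n) break
    group <- .u16(bytes[pos:(pos + 1L)]); elem <- .u16(bytes[(pos + 2L):(pos + 3L)])
    key <- .tag_key(group, elem)
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% .dcm_vr_long) {
        len <- .u32(bytes[(pos + 4L):(pos + 7L)]); pos <- pos + 8L
      } else {
        len <- .u16(bytes[(pos + 2L):(pos + 3L)]); pos <- pos + 4L
      }
    } else {
      vr <- if (key %in% names(.dcm_dict)) .dcm_dict[[key]] else "UN"
      len <- .u32(bytes[pos:(pos + 3L)]); pos <- pos + 4L
    }
    if (len == 4294967295) # undefined length (sequences) is out of scope
      stop("unsupported DICOM element with undefined length at tag ", key, call. = FALSE)
    value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    out[[key]] <- list(vr = vr, value = value)
    if (!is.null(stop_at) && group >= stop_at) break
  }
  out
}

.el_str <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NA_character_)
  v <- e$value
  while (length(v) > 0 && v[length(v)] %in% as.raw(c(0L, 32L))) v <- v[-length(v)]
  rawToChar(v)
}
.el_num <- function(els, key) {
  s <- .el_str(els, key)
  if (is.na(s)) return(NA_real_)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.el_us <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NA_integer_)
  .u16(e$value[1:2])
}

.read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  # file meta group (always explicit VR little endian)
  pos <- 133L
  meta <- list()
  repeat {
    group <- .u16(bytes[pos:(pos + 1L)])
    if (group != 2L) break
    elem <- .u16(bytes[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .dcm_vr_long) {
      len <- .u32(bytes[(pos + 8L):(pos + 11L)]); hdr <- 12L
    } else {
      len <- .u16(bytes[(pos + 6L):(pos + 7L)]); hdr <- 8L
    }
    meta[[.tag_key(group, elem)]] <- list(vr = vr,
      value = if (len > 0) bytes[(pos + hdr):(pos + hdr + len - 1L)] else raw(0))
    pos <- pos + hdr + len
  }
  ts <- .el_str(meta, "0002,0010")
  explicit <- !identical(ts, "1.2.840.10008.1.2") # implicit VR LE is the only non-explicit we accept
  if (!is.na(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported transfer syntax ", ts, " in ", path, call. = FALSE)
  els <- .parse_elements(bytes, pos, explicit)

  rows <- .el_us(els, "0028,0010"); cols <- .el_us(els, "0028,0011")
  bits <- .el_us(els, "0028,0100")
  if (is.na(rows) || is.na(cols) || is.na(bits))
    stop("missing image geometry tags in ", path, call. = FALSE)
  if (bits != 16L) stop("only 16-bit stored pixel data is supported (", path, ")", call. = FALSE)
  signed <- isTRUE(.el_us(els, "0028,0103") == 1L)
  px <- els[["7FE0,0010"]]
  if (is.null(px)) stop("missing pixel data in ", path, call. = FALSE)
  stored <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  slope <- .el_num(els, "0028,1053"); intercept <- .el_num(els, "0028,1052")
  if (is.na(slope)) slope <- 1
  if (is.na(intercept)) intercept <- 0
  hu <- matrix(stored * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)

  ipp <- .el_num(els, "0020,0032")
  iop <- .el_num(els, "0020,0037")
  zpos <- if (length(ipp) == 3L && length(iop) == 6L) {
    normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
                iop[3] * iop[4] - iop[1] * iop[6],
                iop[1] * iop[5] - iop[2] * iop[4])
    sum(ipp * normal)
  } else if (length(ipp) == 3L) ipp[3] else NA_real_

  list(
    hu = hu,
    series_uid = .el_str(els, "0020,000E"),
    patient_id = .el_str(els, "0010,0020"),
    phase = .el_str(els, "0008,103E"),
    instance = suppressWarnings(as.integer(.el_num(els, "0020,0013"))),
    zpos = zpos,
    pixel_spacing = .el_num(els, "0028,0030"),
    slice_thickness = .el_num(els, "0018,0050")
  )
}

# ---- public API --------------------------------------------------------------

#' Read a DICOM CT series into a calibrated HU volume
#'
#' Reads every DICOM file in `directory` (one series), converts stored values
#' to HU via the rescale slope/intercept, and orders slices by ascending
#' position along the slice normal (projection of ImagePositionPatient onto the
#' plane normal; ties and missing positions fall back to InstanceNumber).
#'
#' @param directory Directory containing the files of a single DICOM series.
#' @return A [hu_volume()].
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no DICOM files found in ", directory, call. = FALSE)
  parsed <- lapply(files, .read_dicom_file)

  uids <- vapply(parsed, function(p) p$series_uid %||% NA_character_, character(1))
  if (length(unique(stats::na.omit(uids))) > 1L)
    stop("mixed series: directory contains more than one SeriesInstanceUID", call. = FALSE)
  shapes <- vapply(parsed, function(p) paste(dim(p$hu), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1L)
    stop("geometry error: slices have inconsistent shapes (", paste(unique(shapes), collapse = ", "), ")",
         call. = FALSE)

  zpos <- vapply(parsed, function(p) p$zpos %||% NA_real_, numeric(1))
  inst <- vapply(parsed, function(p) if (is.null(p$instance) || length(p$instance) == 0) NA_integer_ else p$instance, integer(1))
  ord <- if (all(is.finite(zpos))) order(zpos, inst) else order(inst)
  parsed <- parsed[ord]

  d <- dim(parsed[[1]]$hu)
  slices <- array(0, dim = c(length(parsed), d[1], d[2]))
  for (i in seq_along(parsed)) slices[i, , ] <- parsed[[i]]$hu

  hu_volume(
    slices,
    pixel_spacing = parsed[[1]]$pixel_spacing %||% c(1, 1),
    slice_thickness = parsed[[1]]$slice_thickness %||% 1,
    patient_id = parsed[[1]]$patient_id %||% "anon",
    phase = parsed[[1]]$phase %||% ""
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# ---- fixture writer ----------------------------------------------------------

.dcm_el_explicit <- function(group, elem, vr, value_raw) {
  head <- c(writeBin(as.integer(group), raw(), size = 2L, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2L, endian = "little"),
            charToRaw(vr))
  if (vr %in% .dcm_vr_long) {
    c(head, as.raw(c(0, 0)), writeBin(length(value_raw), raw(), size = 4L, endian = "little"), value_raw)
  } else {
    c(head, writeBin(length(value_raw), raw(), size = 2L, endian = "little"), value_raw)
  }
}

.dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, charToRaw(" "))
  r
}
.dcm_ui <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, as.raw(0L))
  r
}
.dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

#' Write a synthetic single-series DICOM fixture
#'
#' Writes one explicit-VR little-endian DICOM file per slice of `volume`,
#' storing `(HU - intercept)/slope` as signed 16-bit integers. Intended for
#' generating test fixtures for [read_dicom_series()]; it is not a clinical
#' DICOM exporter.
#'
#' @param volume A [hu_volume()].
#' @param directory Output directory (created if needed).
#' @param slope,intercept Rescale calibration to encode (defaults 1 and -1024).
#' @param instance_numbers Integer vector of InstanceNumbers, one per slice
#'   (default `1:n`); file order on disk is independent of slice order.
#' @param series_uid Series identifier string.
#' @return Character vector of file paths written, invisibly.
#' @export
write_dicom_series <- function(volume, directory, slope = 1, intercept = -1024,
                               instance_numbers = NULL,
                               series_uid = "1.2.826.0.1.3680043.9999.1") {
  stopifnot(inherits(volume, "ctseg_volume"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- dim(volume$slices)[1]
  if (is.null(instance_numbers)) instance_numbers <- seq_len(n)
  stopifnot(length(instance_numbers) == n)
  rows <- dim(volume$slices)[2]; cols <- dim(volume$slices)[3]
  sop_class <- "1.2.840.10008.5.1.4.1.1.2"
  paths <- character(n)
  for (i in seq_len(n)) {
    stored <- round((volume$slices[i, , ] - intercept) / slope)
    if (any(stored < -32768 | stored > 32767))
      stop("HU values out of range for signed 16-bit storage", call. = FALSE)
    px <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
    sop_uid <- paste0(series_uid, ".", instance_numbers[i])
    zpos <- (i - 1) * volume$slice_thickness
    body <- c(
      .dcm_el_explicit(0x0008, 0x0016, "UI", .dcm_ui(sop_class)),
      .dcm_el_explicit(0x0008, 0x0018, "UI", .dcm_ui(sop_uid)),
      .dcm_el_explicit(0x0008, 0x103E, "LO", .dcm_str(volume$phase)),
      .dcm_el_explicit(0x0010, 0x0020, "LO", .dcm_str(volume$patient_id)),
      .dcm_el_explicit(0x0018, 0x0050, "DS", .dcm_str(format(volume$slice_thickness))),
      .dcm_el_explicit(0x0020, 0x000E, "UI", .dcm_ui(series_uid)),
      .dcm_el_explicit(0x0020, 0x0013, "IS", .dcm_str(as.character(instance_numbers[i]))),
      .dcm_el_explicit(0x0020, 0x0032, "DS", .dcm_str(sprintf("0\\0\\%g", zpos))),
      .dcm_el_explicit(0x0020, 0x0037, "DS", .dcm_str("1\\0\\0\\0\\1\\0")),
      .dcm_el_explicit(0x0028, 0x0002, "US", .dcm_us(1L)),
      .dcm_el_explicit(0x0028, 0x0004, "CS", .dcm_str("MONOCHROME2")),
      .dcm_el_explicit(0x0028, 0x0010, "US", .dcm_us(rows)),
      .dcm_el_explicit(0x0028, 0x0011, "US", .dcm_us(cols)),
      .dcm_el_explicit(0x0028, 0x0030, "DS",
                       .dcm_str(sprintf("%g\\%g", volume$pixel_spacing[1], volume$pixel_spacing[2]))),
      .dcm_el_explicit(0x0028, 0x0100, "US", .dcm_us(16L)),
      .dcm_el_explicit(0x0028, 0x0101, "US", .dcm_us(16L)),
      .dcm_el_explicit(0x0028, 0x0102, "US", .dcm_us(15L)),
      .dcm_el_explicit(0x0028, 0x0103, "US", .dcm_us(1L)),
      .dcm_el_explicit(0x0028, 0x1052, "DS", .dcm_str(format(intercept))),
      .dcm_el_explicit(0x0028, 0x1053, "DS", .dcm_str(format(slope))),
      .dcm_el_explicit(0x7FE0, 0x0010, "OW", px)
    )
    meta_body <- c(
      .dcm_el_explicit(0x0002, 0x0002, "UI", .dcm_ui(sop_class)),
      .dcm_el_explicit(0x0002, 0x0003, "UI", .dcm_ui(sop_uid)),
      .dcm_el_explicit(0x0002, 0x0010, "UI", .dcm_ui("1.2.840.10008.1.2.1"))
    )
    meta <- c(
      .dcm_el_explicit(0x0002, 0x0000, "UL",
                       writeBin(length(meta_body), raw(), size = 4L, endian = "little")),
      meta_body
    )
    path <- file.path(directory, sprintf("slice_%04d.dcm", instance_numbers[i]))
    con <- file(path, "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[i] <- path
  }
  invisible(paths)
}
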