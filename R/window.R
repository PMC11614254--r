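#' Windowing specification
#'
#' Parameters of the linear window/level transform that maps a Hounsfield-unit
#' (HU) interval onto an integer intensity range. The window is described by
#' its center and width in HU; values outside the window are clamped to the
#' output extremes. Defaults are the soft-tissue window used for
#' portal-venous-phase abdominal CT (center 50 HU, width 400 HU) mapped onto
#' the full 16-bit range.
#'
#' @param center Window center in HU.
#' @param width Window width in HU; must exceed 1.
#' @param y_min,y_max Output integer range (defaults 0 and 65535 for 16-bit
#'   storage; use 0 and 255 for 8-bit).
#' @return An object of class `ctseg_window` with fields `center`, `width`,
#'   `y_min`, `y_max` and `bit_depth` (8 or 16, inferred from `y_max`).
#' @examples
#' window_spec()                      # abdominal soft-tissue default
#' window_spec(center = 40, width = 80, y_max = 255)  # 8-bit brain window
#' @export
window_spec <- function(center = 50, width = 400, y_min = 0, y_max = 65535) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 1)
    stop("window `width` must be a finite number > 1", call. = FALSE)
  if (!is.numeric(y_min) || !is.numeric(y_max) || y_max <= y_min)
    stop("`y_max` must exceed `y_min`", call. = FALSE)
  bit_depth <- if (y_max <= 255) 8L else 16L
  structure(
    list(center = as.numeric(center), width = as.numeric(width),
         y_min = as.numeric(y_min), y_max = as.numeric(y_max),
         bit_depth = bit_depth),
    class = "ctseg_window"
  )
}

#' @export
print.ctseg_window <- function(x, ...) {
  cat(sprintf("<ctseg_window> center %g HU, width %g HU -> [%g, %g] (%d-bit)\n",
              x$center, x$width, x$y_min, x$y_max, x$bit_depth))
  invisible(x)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Apply a window/level transform to HU values
#'
#' Maps calibrated HU values to stored integer intensities by the linear VOI
#' transform
#' \deqn{y = \left(\frac{x - (w_c - 0.5)}{w_l - 1} + 0.5\right)(y_{max} - y_{min}) + y_{min}}
#' with values at or beyond the window edges clamped to `y_min` / `y_max`, and
#' the result rounded to the nearest integer (ties away from zero). The map is
#' monotonically non-decreasing in `x`.
#'
#' @param hu Numeric vector, matrix or array of HU values; all values must be
#'   finite.
#' @param spec A [window_spec()].
#' @return Integer-valued numeric object of the same shape as `hu`, within
#'   `[spec$y_min, spec$y_max]`.
#' @examples
#' w <- window_spec()
#' apply_window(c(-150, 49.5, 249), w)  # 0, 32768, 65535
#' @export
apply_window <- function(hu, spec = window_spec()) {
  stopifnot(inherits(spec, "ctseg_window"))
  if (!is.numeric(hu)) stop("`hu` must be numeric", call. = FALSE)
  if (any(!is.finite(hu))) stop("non-finite HU values in input", call. = FALSE)
  y <- ((hu - (spec$center - 0.5)) / (spec$width - 1) + 0.5) *
    (spec$y_max - spec$y_min) + spec$y_min
  y <- pmin(pmax(y, spec$y_min), spec$y_max)
  out <- round_half_away(y)
  # clamping before rounding keeps the edges exact: the linear map hits
  # y_min/y_max exactly at x = center - 0.5 -/+ (width - 1)/2
  if (is.array(hu)) dim(out) <- dim(hu)
  out
}
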