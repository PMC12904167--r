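#' Construct a fiber_image
#'
#' The in-memory container for a two-channel fluorescence micrograph of a
#' single muscle fiber: channel `"zline"` (alpha-actinin / Z-lines) and
#' channel `"nsp"` (click-labelled newly synthesized protein), plus the
#' physical pixel pitch and an optional fiber mask.
#'
#' @param ch0,ch1 Numeric matrices (rows = lateral, cols = axial).
#' @param pixel_pitch um per pixel.
#' @param mask Logical matrix marking fiber pixels; `NULL` if unknown.
#' @param meta Free-form provenance list.
#' @return A `fiber_image`.
#' @export
new_fiber_image <- function(ch0, ch1, pixel_pitch, mask = NULL, meta = list()) {
  stopifnot(is.matrix(ch0), is.matrix(ch1), all(dim(ch0) == dim(ch1)))
  if (!is.null(mask)) stopifnot(all(dim(mask) == dim(ch0)))
  structure(list(ch = array(c(ch0, ch1), dim = c(dim(ch0), 2L)),
                 pixel_pitch = pixel_pitch, mask = mask, meta = meta),
            class = "fiber_image")
}

#' Extract one channel of a fiber_image as a matrix
#' @param image A `fiber_image`.
#' @param channel `"zline"` (channel 0) or `"nsp"` (channel 1), or an
#'   integer 0/1.
#' @return Numeric matrix.
#' @export
fiber_channel <- function(image, channel = c("zline", "nsp")) {
  stopifnot(inherits(image, "fiber_image"))
  k <- if (is.numeric(channel)) as.integer(channel) + 1L
       else match(match.arg(channel), c("zline", "nsp"))
  image$ch[, , k]
}

#' @export
print.fiber_image <- function(x, ...) {
  d <- dim(x$ch)
  cat(sprintf("<fiber_image> %d x %d px (2 channels), %.4g um/px (%.3g x %.3g um)\n",
              d[1], d[2], x$pixel_pitch, d[1] * x$pixel_pitch, d[2] * x$pixel_pitch))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d Z-lines, %d split(s), %d hotspot(s), fiber rows %d..%d\n",
              x$n_zlines,
              if (is.null(x$splits)) 0L else nrow(x$splits),
              if (is.null(x$hotspots)) 0L else nrow(x$hotspots),
              x$fiber_row0, x$fiber_row1))
  invisible(x)
}

#' Fiber mask of an image (rows belonging to the fiber)
#' @param image A `fiber_image`.
#' @return Logical matrix; if no mask was recorded, one is estimated from
#'   channel-0 row means (rows brighter than the midpoint between the
#'   dimmest and brightest row mean).
#' @export
fiber_mask <- function(image) {
  if (!is.null(image$mask)) return(image$mask)
  rm <- rowMeans(fiber_channel(image, "zline"))
  thr <- (min(rm) + max(rm)) / 2
  mask <- matrix(FALSE, nrow(image$ch), ncol(image$ch))
  mask[rm > thr, ] <- TRUE
  mask
}
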