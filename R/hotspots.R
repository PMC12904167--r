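# NSP hotspot detection: local-background estimation, fold thresholding
# with sarcomere-scale size gates, hotspot-positive fiber calls, and the
# normal-vs-disarrayed ROI comparison.

#' Estimate the local background of the NSP channel
#'
#' Per-pixel local background as the median of window pixels restricted
#' to the fiber mask after discarding the brightest `trim` fraction of
#' the window (so hotspots do not inflate their own background).  The
#' trimmed median is evaluated on a grid every `grid_step_px` pixels and
#' bilinearly interpolated; the background varies on the fiber scale, far
#' above the grid step.
#'
#' @param nsp NSP-channel matrix.
#' @param mask Logical fiber mask (non-empty).
#' @param pixel_pitch um/px.
#' @param window_um Window side, um (default 5, about two sarcomeres).
#' @param trim Fraction of brightest window pixels excluded (default
#'   0.10).
#' @param grid_step_px Evaluation grid step.
#' @return Numeric matrix of background estimates (class
#'   `background_map` attributes record the parameters); strictly
#'   positive wherever `mask` is true.
#' @export
estimate_local_background <- function(nsp, mask, pixel_pitch = 0.103,
                                      window_um = 5, trim = 0.10,
                                      grid_step_px = 8L) {
  stopifnot(is.matrix(nsp), is.logical(mask), all(dim(mask) == dim(nsp)))
  if (!any(mask)) abort("fiber mask is empty; no background to estimate")
  w <- round(window_um / pixel_pitch)
  if (w < 3) abort("background window of %d px is smaller than 3 px", w)
  h <- w %/% 2L
  nr <- nrow(nsp); nc <- ncol(nsp)
  gr <- unique(c(seq(1L, nr, by = grid_step_px), nr))
  gc <- unique(c(seq(1L, nc, by = grid_step_px), nc))
  G <- matrix(NA_real_, length(gr), length(gc))
  for (i in seq_along(gr)) {
    rr <- max(1L, gr[i] - h):min(nr, gr[i] + h)
    for (j in seq_along(gc)) {
      cc <- max(1L, gc[j] - h):min(nc, gc[j] + h)
      v <- nsp[rr, cc][mask[rr, cc]]
      if (length(v) == 0L) next
      if (trim > 0) v <- v[v <= stats::quantile(v, 1 - trim, names = FALSE)]
      G[i, j] <- stats::median(v)
    }
  }
  if (all(is.na(G))) abort("background grid is entirely empty")
  # fill grid nodes with no fiber pixels from their nearest valid node
  if (anyNA(G)) {
    valid <- which(!is.na(G), arr.ind = TRUE)
    nas <- which(is.na(G), arr.ind = TRUE)
    for (k in seq_len(nrow(nas))) {
      d2 <- (valid[, 1] - nas[k, 1])^2 + (valid[, 2] - nas[k, 2])^2
      G[nas[k, 1], nas[k, 2]] <- G[valid[which.min(d2), 1], valid[which.min(d2), 2]]
    }
  }
  # separable bilinear interpolation to full resolution
  tmp <- matrix(0, length(gr), nc)
  for (i in seq_along(gr))
    tmp[i, ] <- stats::approx(gc, G[i, ], xout = seq_len(nc), rule = 2)$y
  bg <- matrix(0, nr, nc)
  for (j in seq_len(nc))
    bg[, j] <- stats::approx(gr, tmp[, j], xout = seq_len(nr), rule = 2)$y
  if (any(bg[mask] <= 0))
    abort("background estimate is non-positive inside the fiber mask")
  attr(bg, "params") <- list(window_um = window_um, trim = trim,
                             grid_step_px = grid_step_px)
  class(bg) <- c("background_map", class(bg))
  bg
}

#' Feret diameters of a pixel set
#'
#' Minimum and maximum caliper widths of the convex hull of the pixel
#' centers, plus one pixel of footprint, over a 1-degree angle grid.
#'
#' @param px n x 2 matrix of (row, col) pixel coordinates.
#' @return `c(min_feret, max_feret)` in px.
#' @export
feret_diameters <- function(px) {
  if (nrow(px) == 1L) return(c(1, 1))
  pts <- unique(px[, c(2, 1), drop = FALSE])  # (x, y)
  hull <- if (nrow(pts) > 2L) pts[grDevices::chull(pts), , drop = FALSE] else pts
  th <- seq(0, pi, length.out = 181L)[-181L]
  P <- hull %*% rbind(cos(th), sin(th))     # nh x 180 projections
  widths <- do.call(pmax, asplit(P, 1)) - do.call(pmin, asplit(P, 1)) + 1
  c(min(widths), max(widths))
}

#' Detect NSP hotspots by local-background fold thresholding
#'
#' Candidate loci are 8-connected components of fiber pixels whose
#' intensity exceeds `detect_fold` times the local background; each is
#' then measured on its qualifying mask (pixels at or above
#' `fold_threshold` x background, falling back to the whole component)
#' and gated: a hotspot qualifies iff its fold enrichment is at least
#' `fold_threshold` (default 2.0, inclusive) and its size lies inside
#' `size_range_nm` (default 400-1900 nm, inclusive, sarcomere-scale).
#' The gated size measure is the minimum Feret (transverse) diameter by
#' default -- sarcomere diameters are bounded transversely, while
#' multi-sarcomere morphologies legitimately extend axially --
#' with the mask-equivalent diameter available via
#' `size_measure = "equiv"`.  Non-qualifying candidates are retained
#' with reason codes.
#'
#' @param nsp NSP-channel matrix.
#' @param background A `background_map` from
#'   [estimate_local_background()].
#' @param mask Logical fiber mask.
#' @param pixel_pitch um/px.
#' @param fold_threshold Qualification fold (default 2.0).
#' @param detect_fold Detection fold for candidate pixels (default 1.5;
#'   must be <= `fold_threshold` so near-threshold candidates are
#'   reported rather than silently missed).
#' @param size_range_nm Inclusive `c(lo, hi)` gate, nm.
#' @param size_measure `"min_feret"` (default) or `"equiv"`.
#' @param min_area_px Components smaller than this are dropped outright
#'   (noise specks well below the size gate).
#' @return A `hotspot_set`: list with `table` (one row per candidate:
#'   centroid, area, equiv/min/max diameters in nm, axial extent in um,
#'   fold, `qualifies`, `reason`) and `masks` (0-based (row, col)
#'   qualifying masks).
#' @export
detect_hotspots <- function(nsp, background, mask, pixel_pitch = 0.103,
                            fold_threshold = 2.0, detect_fold = 1.5,
                            size_range_nm = c(400, 1900),
                            size_measure = c("min_feret", "equiv"),
                            min_area_px = 4L) {
  size_measure <- match.arg(size_measure)
  stopifnot(all(dim(background) == dim(nsp)))
  bg <- unclass(background)
  cand <- mask & (nsp >= detect_fold * bg)
  lab <- label_components8(cand)
  n <- max(lab)
  # a convex-ish mask of minimum caliper width w covers at least ~0.7 w^2
  # pixels, so components below that area can never reach the lower size
  # gate: skip the (costly) Feret measurement for them
  gate_lo_px <- size_range_nm[1] / 1000 / pixel_pitch
  min_area_gate <- 0.7 * gate_lo_px^2
  acc <- list(centroid_row = numeric(0), centroid_col = numeric(0),
              area_px = integer(0), equiv_diameter_nm = numeric(0),
              min_feret_nm = numeric(0), max_feret_nm = numeric(0),
              axial_extent_um = numeric(0), fold = numeric(0),
              qualifies = logical(0), reason = character(0))
  masks <- list()
  if (n > 0) {
    idx_all <- which(lab > 0)
    comp <- split(idx_all, lab[idx_all])
    nr <- nrow(nsp)
    eps_nm <- 1e-6; eps_fold <- 1e-9  # inclusive gates, float-robust
    for (ci in seq_along(comp)) {
      idx <- comp[[ci]]
      if (length(idx) < min_area_px) next
      rr <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      strong <- nsp[idx] >= fold_threshold * bg[idx]
      use <- if (any(strong)) which(strong) else seq_along(idx)
      urr <- rr[use]; ucc <- cc[use]
      cen_r <- round(mean(urr)); cen_c <- round(mean(ucc))
      fold <- mean(nsp[idx[use]]) / bg[cen_r, cen_c]
      area <- length(use)
      eq_nm <- 2 * sqrt(area / pi) * pixel_pitch * 1000
      if (area >= min_area_gate) {
        fer <- feret_diameters(cbind(urr, ucc)) * pixel_pitch * 1000
        size_nm <- if (size_measure == "min_feret") fer[1] else eq_nm
      } else {
        fer <- c(NA_real_, NA_real_)   # provably below the lower gate
        size_nm <- 0
      }
      reason <- character(0)
      if (fold < fold_threshold - eps_fold) reason <- c(reason, "fold")
      if (size_nm < size_range_nm[1] - eps_nm) reason <- c(reason, "size_small")
      if (size_nm > size_range_nm[2] + eps_nm) reason <- c(reason, "size_large")
      k <- length(acc$fold) + 1L
      acc$centroid_row[k] <- mean(urr) - 1
      acc$centroid_col[k] <- mean(ucc) - 1
      acc$area_px[k] <- area
      acc$equiv_diameter_nm[k] <- eq_nm
      acc$min_feret_nm[k] <- fer[1]; acc$max_feret_nm[k] <- fer[2]
      acc$axial_extent_um[k] <- (max(ucc) - min(ucc)) * pixel_pitch
      acc$fold[k] <- fold
      acc$qualifies[k] <- length(reason) == 0L
      acc$reason[k] <- paste(reason, collapse = ",")
      masks[[k]] <- cbind(row = urr - 1L, col = ucc - 1L)
    }
  }
  tab <- data.frame(id = seq_along(acc$fold), acc, stringsAsFactors = FALSE)
  structure(list(table = tab, masks = masks, pixel_pitch = pixel_pitch,
                 params = list(fold_threshold = fold_threshold,
                               detect_fold = detect_fold,
                               size_range_nm = size_range_nm,
                               size_measure = size_measure)),
            class = "hotspot_set")
}

#' Full hotspot detection for one fiber image
#'
#' Convenience wrapper: background estimation then [detect_hotspots()].
#'
#' @param image A `fiber_image`.
#' @param ... Passed to [detect_hotspots()].
#' @inheritParams estimate_local_background
#' @return A `hotspot_set`.
#' @export
find_hotspots <- function(image, window_um = 5, ...) {
  stopifnot(inherits(image, "fiber_image"))
  mask <- fiber_mask(image)
  nsp <- fiber_channel(image, "nsp")
  bg <- estimate_local_background(nsp, mask, image$pixel_pitch, window_um)
  detect_hotspots(nsp, bg, mask, image$pixel_pitch, ...)
}

#' Call a fiber hotspot-positive
#'
#' A fiber is positive when it contains multiple qualifying hotspots --
#' operationalized as at least `min_count` (default 2).
#'
#' @param hotspots A `hotspot_set` or a logical vector of `qualifies`
#'   flags.
#' @param min_count Minimum number of qualifying hotspots.
#' @return Logical.
#' @export
call_positive_fiber <- function(hotspots, min_count = 2L) {
  q <- if (inherits(hotspots, "hotspot_set")) hotspots$table$qualifies else hotspots
  sum(q) >= min_count
}

#' Classify an ROI as normal or disarrayed
#'
#' Disarray is quantified through the continuous Z-line length: an ROI is
#' disarrayed when its mean continuous Z-line length falls below
#' `f` times the reference length (default f = 0.6; the reference is
#' typically the fiber-level median of ROI means).
#'
#' @param mean_length_um ROI mean continuous Z-line length, um.
#' @param reference_um Reference length, um.
#' @param f Fraction defining disarray (default 0.6).
#' @return `"normal"` or `"disarrayed"`.
#' @export
classify_roi <- function(mean_length_um, reference_um, f = 0.6) {
  if (mean_length_um < f * reference_um) "disarrayed" else "normal"
}

#' Tile a fiber into square ROIs and classify each by Z-line disarray
#'
#' The fiber is tiled with axis-aligned `roi_um` x `roi_um` squares
#' (default 10 um, i.e. 100 um^2); each tile's mean continuous Z-line
#' length is computed and compared to the fiber-level median of the tile
#' means.  Tiles whose segmentation finds no Z-lines are excluded as
#' unclassifiable.
#'
#' @param image A `fiber_image`.
#' @param roi_um ROI side, um.
#' @param f Disarray fraction, see [classify_roi()].
#' @param sarcomere_length_um,theta_max Passed to [zline_analysis()].
#' @return Data frame: `roi_id`, `row0`, `col0`, `size_px` (0-based
#'   origin), `mean_czl_um`, `label`; attribute `"reference_um"`.
#' @export
classify_fiber_rois <- function(image, roi_um = 10, f = 0.6,
                                sarcomere_length_um = 2.4, theta_max = 20) {
  stopifnot(inherits(image, "fiber_image"))
  p <- image$pixel_pitch
  s <- max(8L, round(roi_um / p))
  mask <- fiber_mask(image)
  frows <- which(rowSums(mask) > 0)
  nrb <- length(frows) %/% s; ncb <- ncol(image$ch) %/% s
  if (nrb < 1L || ncb < 1L) abort("fiber smaller than one %g um ROI", roi_um)
  out <- list()
  for (i in seq_len(nrb)) for (j in seq_len(ncb)) {
    r0 <- frows[1] + (i - 1L) * s; c0 <- 1L + (j - 1L) * s
    raster <- fiber_channel(image, "zline")[r0:(r0 + s - 1L), c0:(c0 + s - 1L)]
    mz <- try(zline_analysis(raster, pixel_pitch = p,
                             sarcomere_length_um = sarcomere_length_um,
                             theta_max = theta_max), silent = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      roi_id = length(out) + 1L, row0 = r0 - 1L, col0 = c0 - 1L, size_px = s,
      mean_czl_um = if (inherits(mz, "try-error")) NA_real_ else mz$mean_length_um)
  }
  tab <- do.call(rbind, out)
  n_bad <- sum(is.na(tab$mean_czl_um))
  if (n_bad > 0)
    message(sprintf("%d ROI(s) had no detectable Z-lines and were excluded", n_bad))
  tab <- tab[!is.na(tab$mean_czl_um), , drop = FALSE]
  if (nrow(tab) == 0L) abort("no classifiable ROIs in this fiber")
  ref <- stats::median(tab$mean_czl_um)
  tab$label <- vapply(tab$mean_czl_um, classify_roi, "", reference_um = ref, f = f)
  attr(tab, "reference_um") <- ref
  tab
}

#' Paired normal/disarrayed hotspot counts within one fiber
#'
#' Counts qualifying hotspots per classified ROI, samples an equal
#' number of normal and disarrayed ROIs (seeded), and returns the
#' per-class mean counts as a pair -- the within-fiber unit that is then
#' aggregated per muscle and compared with a paired test.
#'
#' @param rois Output of [classify_fiber_rois()].
#' @param hotspots A `hotspot_set` for the same image.
#' @param seed Integer seed for the ROI subsampling.
#' @param n_pairs Number of ROIs per class (default: the size of the
#'   smaller class).
#' @return List `normal_mean`, `disarrayed_mean`, `n_each`; or `NULL`
#'   (with a message) when the fiber lacks one of the two classes.
#' @export
hotspots_per_roi_paired <- function(rois, hotspots, seed = 1L, n_pairs = NULL) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  ht <- hotspots$table[hotspots$table$qualifies, , drop = FALSE]
  counts <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    sum(ht$centroid_row >= r$row0 & ht$centroid_row < r$row0 + r$size_px &
        ht$centroid_col >= r$col0 & ht$centroid_col < r$col0 + r$size_px)
  }, numeric(1))
  i_n <- which(rois$label == "normal"); i_d <- which(rois$label == "disarrayed")
  if (length(i_n) == 0L || length(i_d) == 0L) {
    message("fiber lacks one ROI class; excluded from pairing")
    return(NULL)
  }
  k <- min(length(i_n), length(i_d))
  if (!is.null(n_pairs)) k <- min(k, n_pairs)
  with_seed(seed, {
    s_n <- sample(i_n, k); s_d <- sample(i_d, k)
    list(normal_mean = mean(counts[s_n]), disarrayed_mean = mean(counts[s_d]),
         n_each = k)
  })
}
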