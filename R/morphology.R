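# Hotspot morphology: axial span in local sarcomere units, registration
# of the blob boundaries to the flanking Z-lines, and classification
# against the candidate sarcomerogenesis models.
#
# Classes: "yu" (one sarcomere, Z-to-Z), "rodier" (two in-series
# sarcomeres, Z-to-Z), "hzone" (one sarcomere length centered on a
# Z-line, i.e. the adjacent inner halves of two in-series sarcomeres),
# plus "short_atypical" (< 2 sarcomeres, unregistered) and
# "long_atypical" (> 2 sarcomeres).

#' Register the Z-line grid around one hotspot
#'
#' Averages the Z-line channel over the hotspot's lateral rows within an
#' axial window of +/- `search_sarcomeres` sarcomeres, detects intensity
#' peaks (with sub-pixel parabolic refinement), and reports the Z-line
#' axial positions plus the local sarcomere length (median inter-peak
#' spacing).
#'
#' @param zch Z-line channel matrix.
#' @param rows,cols 1-based row and column ranges of the hotspot mask.
#' @param pixel_pitch um/px.
#' @param sarcomere_length_um Expected sarcomere length (window sizing
#'   only).
#' @param search_sarcomeres Half-window, sarcomeres.
#' @return List `zlines_um` (axial positions, um), `local_sl_um`; or
#'   `NULL` when fewer than 2 Z-lines are resolvable.
#' @export
sarcomere_registration <- function(zch, rows, cols, pixel_pitch = 0.103,
                                   sarcomere_length_um = 2.4,
                                   search_sarcomeres = 3) {
  sl_px <- sarcomere_length_um / pixel_pitch
  pad <- round(search_sarcomeres * sl_px + sl_px / 2)
  c0 <- max(1L, min(cols) - pad); c1 <- min(ncol(zch), max(cols) + pad)
  rr <- rows[rows >= 1 & rows <= nrow(zch)]
  prof <- colMeans(zch[rr, c0:c1, drop = FALSE])
  n <- length(prof)
  if (n < 5L) return(NULL)
  rng <- range(prof)
  if (diff(rng) <= 0) return(NULL)
  thr <- rng[1] + 0.45 * diff(rng)
  pk <- which(prof > thr &
              prof >= c(-Inf, prof[-n]) & prof > c(prof[-1], -Inf))
  pk <- pk[pk > 1 & pk < n]
  if (length(pk) < 2L) return(NULL)
  # enforce a minimum peak separation well above the noise scale: maxima
  # riding between or on ridges must not masquerade as extra Z-lines
  min_sep <- 0.6 * sl_px
  keep <- integer(0)
  for (k in pk[order(prof[pk], decreasing = TRUE)])
    if (!length(keep) || all(abs(k - keep) >= min_sep)) keep <- c(keep, k)
  pk <- sort(keep)
  if (length(pk) < 2L) return(NULL)
  # sub-pixel parabolic refinement of each peak
  sub <- vapply(pk, function(k) {
    a <- prof[k - 1]; b <- prof[k]; cc <- prof[k + 1]
    den <- a - 2 * b + cc
    if (den >= 0) return(as.numeric(k))
    k + 0.5 * (a - cc) / den
  }, numeric(1))
  z_um <- (c0 - 1 + sub - 1) * pixel_pitch
  list(zlines_um = z_um, local_sl_um = stats::median(diff(z_um)))
}

#' Measure a hotspot's axial span and Z-line registration
#'
#' Projects the hotspot's qualifying mask onto the fiber axis: the span
#' is its axial extent in units of the local sarcomere length, and each
#' boundary's phase is its distance to the nearest registered Z-line in
#' sarcomere units (0 = on a Z-line, 0.5 = mid-sarcomere).
#'
#' @param mask 0-based (row, col) matrix of the hotspot mask (as stored
#'   in a `hotspot_set`).
#' @param registration Output of [sarcomere_registration()].
#' @param pixel_pitch um/px.
#' @return List `span`, `start_phase`, `end_phase`, `axial_extent_um`,
#'   `local_sl_um`; or `NULL` when the blob cannot be registered (a
#'   boundary falls outside the resolved Z-line grid).
#' @export
measure_axial_span <- function(mask, registration, pixel_pitch = 0.103) {
  if (is.null(registration) || length(registration$zlines_um) < 2L) return(NULL)
  z <- registration$zlines_um; sl <- registration$local_sl_um
  if (!is.finite(sl) || sl <= 0) return(NULL)
  # robust axial footprint: columns covered by at least half of the
  # blob's peak lateral thickness, so single-row noise dilations of the
  # mask do not stretch the measured span
  cnt <- table(mask[, "col"])
  covered <- as.integer(names(cnt))[cnt >= max(cnt) / 2]
  x0 <- min(covered) * pixel_pitch
  x1 <- max(covered) * pixel_pitch
  # boundaries must lie within (or just beyond) the registered grid
  if (x0 < min(z) - 0.6 * sl || x1 > max(z) + 0.6 * sl) return(NULL)
  phase <- function(x) min(abs(x - z)) / sl
  list(span = (x1 - x0) / sl,
       start_phase = min(phase(x0), 0.5),
       end_phase = min(phase(x1), 0.5),
       axial_extent_um = x1 - x0, local_sl_um = sl)
}

#' Classify a measured hotspot morphology
#'
#' Rules, applied in order with span tolerance `tau_span` and
#' registration tolerance `tau_reg` (both in sarcomere units):
#' \enumerate{
#'   \item span within `tau_span` of 1 and both boundaries Z-registered
#'     (phases <= `tau_reg`): `"yu"`;
#'   \item span within `tau_span` of 2, boundaries Z-registered:
#'     `"rodier"`;
#'   \item span within `tau_span` of 1 and both boundaries mid-sarcomere
#'     (phases >= 0.5 - `tau_reg`, blob centered on a Z-line):
#'     `"hzone"`;
#'   \item otherwise `"short_atypical"` when span < 2, else
#'     `"long_atypical"`.
#' }
#' With `tau_span` < 0.5 the three model acceptance regions are pairwise
#' disjoint; the precedence nonetheless fixes the stated ambiguity that
#' two adjacent single-sarcomere events merged into one blob present as,
#' and are deliberately labelled, the two-sarcomere class.
#'
#' @param span Axial span, sarcomere units.
#' @param start_phase,end_phase Boundary phases in [0, 0.5].
#' @param tau_span,tau_reg Tolerances (default 0.25 each).
#' @return One of [HOTSPOT_CLASSES].
#' @export
classify_hotspot_morphology <- function(span, start_phase, end_phase,
                                        tau_span = 0.25, tau_reg = 0.25) {
  registered <- start_phase <= tau_reg && end_phase <= tau_reg
  central <- start_phase >= 0.5 - tau_reg && end_phase >= 0.5 - tau_reg
  if (abs(span - 1) <= tau_span && registered) return("yu")
  if (abs(span - 2) <= tau_span && registered) return("rodier")
  if (abs(span - 1) <= tau_span && central) return("hzone")
  if (span < 2) "short_atypical" else "long_atypical"
}

#' Measure and classify all qualifying hotspots of one image
#'
#' @param image A `fiber_image`.
#' @param hotspots A `hotspot_set` from [find_hotspots()].
#' @param tau_span,tau_reg Classification tolerances.
#' @param sarcomere_length_um Expected sarcomere length for the
#'   registration window.
#' @return Data frame: `id`, `span`, `start_phase`, `end_phase`,
#'   `local_sl_um`, `label` (`NA` rows are hotspots excluded as
#'   unmeasurable, with `exclude_reason`).
#' @export
hotspot_morphology <- function(image, hotspots, tau_span = 0.25, tau_reg = 0.25,
                               sarcomere_length_um = 2.4) {
  stopifnot(inherits(image, "fiber_image"), inherits(hotspots, "hotspot_set"))
  zch <- fiber_channel(image, "zline")
  p <- image$pixel_pitch
  qual <- which(hotspots$table$qualifies)
  out <- lapply(qual, function(i) {
    m <- hotspots$masks[[i]]
    reg <- sarcomere_registration(zch, rows = range(m[, "row"]) + 1L,
                                  cols = range(m[, "col"]) + 1L,
                                  pixel_pitch = p,
                                  sarcomere_length_um = sarcomere_length_um)
    ms <- measure_axial_span(m, reg, p)
    if (is.null(ms))
      return(data.frame(id = hotspots$table$id[i], span = NA_real_,
                        start_phase = NA_real_, end_phase = NA_real_,
                        local_sl_um = NA_real_, label = NA_character_,
                        exclude_reason = "unresolvable Z-lines",
                        stringsAsFactors = FALSE))
    data.frame(id = hotspots$table$id[i], span = ms$span,
               start_phase = ms$start_phase, end_phase = ms$end_phase,
               local_sl_um = ms$local_sl_um,
               label = classify_hotspot_morphology(ms$span, ms$start_phase,
                                                   ms$end_phase, tau_span, tau_reg),
               exclude_reason = "", stringsAsFactors = FALSE)
  })
  if (length(out) == 0L)
    return(data.frame(id = integer(0), span = numeric(0), start_phase = numeric(0),
                      end_phase = numeric(0), local_sl_um = numeric(0),
                      label = character(0), exclude_reason = character(0)))
  do.call(rbind, out)
}

#' Per-fiber and per-sample morphology class proportions
#'
#' For each fiber the proportion of its classified hotspots in each
#' class (proportions sum to 1); fibers with fewer than `min_hotspots`
#' classified hotspots are excluded.  Sample-level summary is the mean
#' +/- SEM over fibers.
#'
#' @param labels Data frame with columns `fiber` and `label`
#'   (unclassifiable hotspots, `NA` label, never enter the denominator).
#' @param min_hotspots Minimum classified hotspots per fiber (default 5).
#' @return List with `per_fiber` (fiber x class proportion matrix),
#'   `mean`, `sem` (named by class), `n_fibers`, `n_excluded_fibers`.
#' @export
summarize_mix <- function(labels, min_hotspots = 5L) {
  stopifnot(all(c("fiber", "label") %in% names(labels)))
  labels <- labels[!is.na(labels$label), , drop = FALSE]
  counts <- table(factor(labels$fiber),
                  factor(labels$label, levels = HOTSPOT_CLASSES))
  tot <- rowSums(counts)
  keep <- tot >= min_hotspots
  if (!all(keep))
    message(sprintf("%d fiber(s) below %d classified hotspots excluded",
                    sum(!keep), min_hotspots))
  if (!any(keep)) abort("no fiber reaches the minimum hotspot count")
  prop <- sweep(counts[keep, , drop = FALSE], 1, tot[keep], "/")
  list(per_fiber = prop,
       mean = colMeans(prop),
       sem = apply(prop, 2, sem),
       n_fibers = sum(keep), n_excluded_fibers = sum(!keep))
}
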