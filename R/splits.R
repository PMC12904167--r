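# Net transverse-split counting: trace an A-band (inter-Z-line gap) across
# the fiber width, record every bifurcation/merge of its bounding Z-lines,
# and report the net count normalized to the fiber width.

#' Per-row Z-line crossing positions
#'
#' For each image row, the (sorted) columns at which the traced Z-line
#' skeleton crosses it.  This is the substrate on which A-band traces run.
#'
#' @param x A `fiber_image`, a `zline_skeleton`, or a logical skeleton
#'   matrix.
#' @param min_separation_px Crossings closer than this within a row are
#'   collapsed to their mean (same physical Z-line segmented as two runs
#'   under noise); 0 disables.  Keep below half the daughter-line spacing
#'   (a quarter sarcomere) so genuine fork daughters survive.
#' @param ... For a `fiber_image`: passed to [segment_zlines()].
#' @return List of length `nrow`, each element a sorted numeric vector of
#'   1-based crossing columns.
#' @export
zline_crossings <- function(x, min_separation_px = 0, ...) {
  px <- if (inherits(x, "fiber_image")) {
    sk <- zline_skeleton(segment_zlines(fiber_channel(x, "zline"),
                                        pixel_pitch = x$pixel_pitch, ...))
    sk$px
  } else if (inherits(x, "zline_skeleton")) {
    x$px
  } else {
    which(x, arr.ind = TRUE)
  }
  nr <- if (inherits(x, "fiber_image")) nrow(x$ch)
        else if (inherits(x, "zline_skeleton")) x$dim[1]
        else nrow(x)
  out <- vector("list", nr)
  for (r in seq_len(nr)) out[[r]] <- numeric(0)
  if (nrow(px)) {
    sp <- split(px[, 2], px[, 1])
    for (nm in names(sp)) out[[as.integer(nm)]] <- sort(as.numeric(sp[[nm]]))
  }
  if (min_separation_px > 0) {
    out <- lapply(out, function(v) {
      if (length(v) < 2L) return(v)
      grp <- cumsum(c(1, diff(v) >= min_separation_px))
      as.numeric(tapply(v, grp, mean))
    })
  }
  out
}

# one boundary update for a directional trace step.
# state: list(pos, hist, refractory); inner_sign +1 if the gap lies to the
# right of this boundary.  Fork detection compares candidate crossings
# against the oldest recent boundary position (3 rows back) so that the
# gradual emergence of blurred fork daughters is not absorbed by
# row-to-row boundary drift; after any event the history is reset and
# detection pauses for 3 rows.
.step_boundary <- function(state, cross_next, cross_cur, inner_sign,
                           tol, tol_fork, tol_merge, dir_up) {
  ev <- 0L
  pos <- state$pos
  if (state$refractory == 0L) {
    ref <- state$hist[1]
    Cf <- cross_next[abs(cross_next - ref) <= tol_fork]
    if (length(Cf) >= 2L) {
      # boundary forks along the trace direction
      new <- if (inner_sign > 0) max(Cf) else min(Cf)
      return(list(pos = new, hist = new, refractory = 3L,
                  event = if (dir_up) 1L else -1L))
    }
  }
  C <- cross_next[abs(cross_next - pos) <= tol]
  if (length(C) >= 1L) {
    new <- C[which.min(abs(C - pos))]
    if (state$refractory == 0L) {
      back <- cross_cur[abs(cross_cur - new) <= tol]
      if (length(back) >= 2L) {
        # two current lines close onto one: fork seen against direction
        return(list(pos = new, hist = new, refractory = 3L,
                    event = if (dir_up) -1L else 1L))
      }
    }
    hist <- c(state$hist, new); if (length(hist) > 3L) hist <- hist[-1]
    return(list(pos = new, hist = hist,
                refractory = max(0L, state$refractory - 1L), event = 0L))
  }
  # no match within tol: boundary merged into a line displaced by ~SL/2
  C2 <- cross_next[abs(cross_next - pos) <= tol_merge]
  if (length(C2) >= 1L) {
    new <- if (length(C2) == 1L) C2 else if (inner_sign > 0) max(C2) else min(C2)
    return(list(pos = new, hist = new, refractory = 3L,
                event = if (dir_up) -1L else 1L))
  }
  list(pos = NA_real_, hist = state$hist, refractory = 0L, event = 0L)
}

#' Trace one A-band across the fiber width, recording split events
#'
#' Starting from a point inside an inter-Z-line gap, the trace follows the
#' gap laterally row by row toward both fiber edges.  Whenever one of its
#' two bounding Z-lines bifurcates (or two bounding lines merge), the
#' event is recorded and the trace continues between the descendants of
#' its current boundaries (taking the daughter nearer the gap interior).
#' Events are signed by their effect on the in-series sarcomere count with
#' increasing lateral position: a fork opening toward the far edge is +1,
#' a merge is -1; the signing is invariant to the direction in which the
#' band is traversed.
#'
#' @param crossings Output of [zline_crossings()].
#' @param start Numeric `c(row, col)` (0-based) inside a gap.
#' @param fiber_rows `c(first, last)` 0-based fiber rows.
#' @param sarcomere_length_px Local sarcomere length in px (sets the
#'   matching tolerances: 0.3 and 0.7 sarcomere lengths).
#' @param pixel_pitch um/px.
#' @return An `aband_trace`: list with `events` (data.frame row,
#'   sense), `n_bifurcations`, `n_merges`, `partial`, `width_traversed_um`.
#' @export
trace_aband <- function(crossings, start, fiber_rows, sarcomere_length_px,
                        pixel_pitch = 0.103) {
  r_start <- as.integer(start[1]) + 1L
  x_start <- as.numeric(start[2]) + 1
  r0 <- as.integer(fiber_rows[1]) + 1L; r1 <- as.integer(fiber_rows[2]) + 1L
  if (r_start < r0 || r_start > r1)
    abort("A-band trace start row %d lies outside the fiber mask (rows %d..%d)",
          r_start - 1L, r0 - 1L, r1 - 1L)
  cr <- crossings[[r_start]]
  if (length(cr) < 2L) abort("no Z-line gap at the start row")
  if (any(abs(cr - x_start) <= 1)) abort("A-band trace must start between Z-lines, not on one")
  iL <- findInterval(x_start, cr)
  if (iL < 1L || iL >= length(cr))
    abort("start column %g is not inside an inter-Z-line gap", x_start - 1)
  tol <- 0.3 * sarcomere_length_px
  tol_fork <- 0.35 * sarcomere_length_px
  tol_merge <- 0.7 * sarcomere_length_px

  run <- function(dir) {
    sL <- list(pos = cr[iL], hist = cr[iL], refractory = 0L)
    sR <- list(pos = cr[iL + 1L], hist = cr[iL + 1L], refractory = 0L)
    rows_seq <- if (dir > 0) seq(r_start + 1L, r1, by = 1L) else seq(r_start - 1L, r0, by = -1L)
    if (r_start == (if (dir > 0) r1 else r0)) rows_seq <- integer(0)
    ev_rows <- integer(0); ev_sense <- integer(0); partial <- FALSE
    prev <- r_start
    for (r in rows_seq) {
      nL <- .step_boundary(sL, crossings[[r]], crossings[[prev]], +1,
                           tol, tol_fork, tol_merge, dir > 0)
      nR <- .step_boundary(sR, crossings[[r]], crossings[[prev]], -1,
                           tol, tol_fork, tol_merge, dir > 0)
      if (is.na(nL$pos) || is.na(nR$pos)) { partial <- TRUE; break }
      if (nL$pos == nR$pos) {
        # the traced gap itself collapsed: both boundaries merged into one
        # line; count a single merge and reopen the gap around it
        M <- nL$pos
        cn <- crossings[[r]]
        Lf <- cn[cn < M]; Rf <- cn[cn > M]
        if (length(Lf) == 0L || length(Rf) == 0L) { partial <- TRUE; break }
        ev_rows <- c(ev_rows, r - 1L)
        ev_sense <- c(ev_sense, if (dir > 0) -1L else 1L)
        sL <- list(pos = max(Lf), hist = max(Lf), refractory = 3L)
        sR <- list(pos = min(Rf), hist = min(Rf), refractory = 3L)
        prev <- r
        next
      }
      if (nL$pos >= nR$pos) { partial <- TRUE; break }
      for (e in c(nL$event, nR$event)) if (e != 0L) {
        ev_rows <- c(ev_rows, r - 1L); ev_sense <- c(ev_sense, e)
      }
      sL <- nL[c("pos", "hist", "refractory")]
      sR <- nR[c("pos", "hist", "refractory")]
      prev <- r
    }
    list(rows = ev_rows, sense = ev_sense, partial = partial, last = prev)
  }
  up <- run(+1L); down <- run(-1L)
  events <- data.frame(row = c(rev(down$rows), up$rows),
                       sense = c(rev(down$sense), up$sense))
  nb <- sum(events$sense == 1L); nm <- sum(events$sense == -1L)
  structure(list(events = events, n_bifurcations = nb, n_merges = nm,
                 start = c(r_start - 1L, x_start - 1),
                 partial = up$partial || down$partial,
                 width_traversed_um = (up$last - down$last) * pixel_pitch),
            class = "aband_trace")
}

#' Net split count of one traced A-band
#'
#' The net number of transverse splits across the fiber width is
#' `|n_bifurcations - n_merges|` -- equivalently, the absolute change in
#' the in-series sarcomere count between the two fiber edges along the
#' traced band.  A partial trace is flagged: its count is a lower bound.
#'
#' @param trace An `aband_trace`.
#' @param fiber_width_um Fiber width for the per-10-um normalization.
#' @return A `split_count` list: `net`, `n_bifurcations`, `n_merges`,
#'   `fiber_width_um`, `per_10um`, `partial`.
#' @export
count_net_splits <- function(trace, fiber_width_um = NA_real_) {
  stopifnot(inherits(trace, "aband_trace"))
  net <- abs(trace$n_bifurcations - trace$n_merges)
  if (trace$partial)
    warn("partial A-band trace: net count %d is a lower bound", net)
  structure(list(net = net,
                 n_bifurcations = trace$n_bifurcations,
                 n_merges = trace$n_merges,
                 fiber_width_um = fiber_width_um,
                 per_10um = if (is.na(fiber_width_um)) NA_real_ else net / fiber_width_um * 10,
                 partial = trace$partial),
            class = "split_count")
}

#' Mean net split count over randomly selected A-bands of one fiber
#'
#' Segments and skeletonizes the Z-line channel, enumerates the
#' inter-Z-line gaps at the near fiber edge, randomly selects `n_abands`
#' of them (seeded, without duplicates), traces each across the full
#' fiber width and averages the net counts, normalized to splits per
#' 10 um of fiber width.
#'
#' @param image A `fiber_image`.
#' @param n_abands Number of A-bands to sample (default 40); if fewer are
#'   available, all are used with a warning.
#' @param seed Integer seed for the A-band selection.
#' @param sarcomere_length_um Expected sarcomere length (tolerances and
#'   ridge scale).
#' @param edge_margin Rows inside the fiber edge at which traces start.
#' @return List with `per_aband` (data.frame), `mean_net`,
#'   `mean_per_10um`, `fiber_width_um`, `n_traced`.
#' @export
splits_per_fiber <- function(image, n_abands = 40L, seed = 1L,
                             sarcomere_length_um = 2.4, edge_margin = 1L) {
  stopifnot(inherits(image, "fiber_image"))
  p <- image$pixel_pitch
  mask <- fiber_mask(image)
  frows <- which(rowSums(mask) > 0)
  r0 <- frows[1]; r1 <- frows[length(frows)]
  width_um <- length(frows) * p
  sk <- zline_skeleton(segment_zlines(fiber_channel(image, "zline"),
                                      pixel_pitch = p,
                                      sarcomere_length_um = sarcomere_length_um))
  sl_px_seg <- sarcomere_length_um / p
  crossings <- zline_crossings(sk, min_separation_px = 0.25 * sl_px_seg)
  start_row <- r0 + edge_margin
  cr <- crossings[[start_row]]
  if (length(cr) < 2L) abort("no Z-line gaps detected at the near fiber edge")
  n_gaps <- length(cr) - 1L
  take <- n_abands
  if (n_gaps < n_abands) {
    warn("only %d A-bands available (requested %d); using all", n_gaps, n_abands)
    take <- n_gaps
  }
  gaps <- with_seed(seed, sort(sample.int(n_gaps, take)))
  sl_px <- sarcomere_length_um / p
  rows <- lapply(gaps, function(g) {
    x0 <- (cr[g] + cr[g + 1L]) / 2
    tr <- trace_aband(crossings, start = c(start_row - 1L, x0 - 1),
                      fiber_rows = c(r0 - 1L, r1 - 1L),
                      sarcomere_length_px = sl_px, pixel_pitch = p)
    sc <- suppressWarnings(count_net_splits(tr, width_um))
    data.frame(aband = g, net = sc$net, n_bifurcations = sc$n_bifurcations,
               n_merges = sc$n_merges, per_10um = sc$per_10um,
               partial = sc$partial)
  })
  per <- do.call(rbind, rows)
  list(per_aband = per, mean_net = mean(per$net),
       mean_per_10um = mean(per$per_10um),
       fiber_width_um = width_um, n_traced = nrow(per))
}
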