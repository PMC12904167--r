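# Synthetic two-channel striated-fiber rendering with exact planted ground
# truth.  Conventions: images are [row, col] matrices; rows run across the
# fiber width (lateral), cols along the fiber axis (axial).  Pixel centers
# sit at integer coordinates; the axial position of column c (1-based) is
# (c - 1) * pixel_pitch um, and all coordinates in ground-truth output are
# 0-based (row, col) pixel indices.

#' Realized fiber geometry shared by rendering and ground truth
#' @keywords internal
fiber_geometry <- function(spec, fiber) {
  nr <- spec$shape[1]; nc <- spec$shape[2]; p <- spec$pixel_pitch
  half_w <- fiber$width_um / (2 * p)
  rc <- (nr + 1) / 2
  r0 <- max(1L, as.integer(ceiling(rc - half_w)))
  r1 <- min(nr, as.integer(floor(rc + half_w)))
  if (r1 - r0 + 1L < 8L) abort("fiber occupies fewer than 8 rows; widen the fiber or the image")
  sl <- fiber$sarcomere_length_um
  x_max <- (nc - 1) * p
  z_base <- seq(sl / 2, x_max - sl / 4, by = sl)
  if (length(z_base) < 3L) abort("image too short along the fiber axis for 3 Z-lines")
  list(r0 = r0, r1 = r1, width_px = r1 - r0 + 1L, width_um = (r1 - r0 + 1L) * p,
       z_base = z_base, n_z = length(z_base), sl = sl, pitch = p, nr = nr, nc = nc)
}

# first 1-based row at which a split with lateral_fraction f is active
# (rows are at lateral fractions (r - r0 + 0.5) / width_px)
split_row_threshold <- function(f, geom) {
  r <- geom$r0 + as.integer(ceiling(f * geom$width_px - 0.5))
  min(max(r, geom$r0 + 1L), geom$r1)  # strictly inside the fiber
}

#' Z-line axial positions (um) for one lateral row, given active splits
#'
#' A bifurcation (sense +1) at Z-line k replaces it with two daughters at
#' k -/+ sarcomere_length/4; a merge (sense -1) replaces Z-lines k and
#' k+1 with their midpoint.  The perturbation is confined within one
#' sarcomere length axially of the parent line.
#' @keywords internal
zline_positions_for <- function(geom, splits, active) {
  pos <- geom$z_base
  drop <- rep(FALSE, length(pos))
  extra <- numeric(0)
  for (i in seq_along(splits)) {
    if (!active[i]) next
    s <- splits[[i]]
    k <- s$aband_index + 1L   # bifurcating Z-line (far boundary of gap aband_index)
    if (s$sense == 1L) {
      drop[k] <- TRUE
      extra <- c(extra, geom$z_base[k] - geom$sl / 4, geom$z_base[k] + geom$sl / 4)
    } else {
      drop[k] <- TRUE; drop[k + 1L] <- TRUE
      extra <- c(extra, (geom$z_base[k] + geom$z_base[k + 1L]) / 2)
    }
  }
  sort(c(pos[!drop], extra))
}

validate_splits <- function(splits, geom) {
  if (length(splits) == 0L) return(invisible(TRUE))
  touched <- integer(0)
  for (s in splits) {
    if (!inherits(s, "split_event")) abort("splits must be a list of split_event objects")
    k <- s$aband_index + 1L
    kk <- if (s$sense == 1L) k else c(k, k + 1L)
    if (any(kk < 2L) || any(kk > geom$n_z - 1L))
      abort("split at A-band %d touches a Z-line outside the fiber interior (valid abands: 1..%d)",
            s$aband_index, geom$n_z - 3L)
    if (any(kk %in% touched))
      abort("two planted splits touch the same Z-line (Z-line %d); plant at most one per Z-line", k)
    touched <- c(touched, kk)
  }
  invisible(TRUE)
}

# axial extent [x0, x1] in um of a hotspot, from the base Z-line grid
hotspot_axial_extent <- function(h, geom) {
  i <- h$anchor_sarcomere
  sl <- geom$sl; z <- geom$z_base
  need <- switch(h$model_class,
    yu = i + 1L, rodier = i + 2L, hzone = i + 1L,
    short_atypical = i + 1L, long_atypical = i + ceiling(h$span_sarcomeres))
  if (i < 1L || need > geom$n_z)
    abort("hotspot anchored at sarcomere %d (%s) does not fit within the %d planted Z-lines",
          i, h$model_class, geom$n_z)
  switch(h$model_class,
    yu             = c(z[i], z[i + 1L]),
    rodier         = c(z[i], z[i + 2L]),
    hzone          = c(z[i] + sl / 2, z[i + 1L] + sl / 2),
    short_atypical = c(z[i] + 0.2 * sl, z[i] + (0.2 + h$span_sarcomeres) * sl),
    long_atypical  = c(z[i], z[i] + h$span_sarcomeres * sl))
}

# pixel-footprint of one hotspot: integer rows/cols (1-based) of its
# rectangular mask
hotspot_footprint <- function(h, geom) {
  ext <- hotspot_axial_extent(h, geom)
  p <- geom$pitch
  c0 <- round(ext[1] / p) + 1L; c1 <- round(ext[2] / p) + 1L
  if (c0 < 1L || c1 > geom$nc) abort("hotspot extends beyond the image axially")
  d_px <- max(1L, round(h$diameter / 1000 / p))
  rc <- geom$r0 - 1L + round(h$lateral_fraction * geom$width_px)
  rr0 <- rc - (d_px - 1L) %/% 2L; rr1 <- rr0 + d_px - 1L
  if (rr0 < geom$r0 || rr1 > geom$r1)
    abort("hotspot (diameter %g nm at lateral fraction %g) extends outside the fiber mask",
          h$diameter, h$lateral_fraction)
  list(rows = rr0:rr1, cols = c0:c1, x0_um = ext[1], x1_um = ext[2])
}

#' Render a synthetic two-channel striated fiber with exact ground truth
#'
#' Channel 0 (`"zline"`) carries periodic alpha-actinin-like Z-line
#' striations; each planted [split_event()] forks one Z-line so that the
#' lateral side beyond `lateral_fraction` carries one extra (sense +1) or
#' one fewer (sense -1) in-series sarcomere, producing locally misaligned
#' Z-lines.  Channel 1 (`"nsp"`) carries a uniform NSP background on which
#' each [hotspot_spec()] is painted as a flat-topped rectangular blob at
#' `fold` times the background, with the axial extent and Z-line
#' registration dictated by its model class.  The returned ground truth
#' records realized pixel geometry before any blur or noise.
#'
#' @param spec An [image_spec()].
#' @param fiber A [fiber_model()].
#' @param splits List of [split_event()] (at most one per Z-line).
#' @param hotspots List of [hotspot_spec()].
#' @param allow_contiguous If `FALSE` (default), planted hotspots whose
#'   masks would 8-connect into a single component are rejected with a
#'   diagnostic, keeping the ground truth unambiguous.  Set `TRUE` only
#'   for deliberate merged-morphology experiments.
#' @return A list with elements `image` (a `fiber_image`) and
#'   `ground_truth` (a `ground_truth`).
#' @export
render_fiber <- function(spec, fiber, splits = list(), hotspots = list(),
                         allow_contiguous = FALSE) {
  stopifnot(inherits(spec, "image_spec"), inherits(fiber, "fiber_model"))
  geom <- fiber_geometry(spec, fiber)
  validate_splits(splits, geom)

  nr <- geom$nr; nc <- geom$nc; p <- geom$pitch
  x <- (seq_len(nc) - 1) * p

  ch0 <- matrix(fiber$background_intensity, nr, nc)
  ch1 <- matrix(fiber$nsp_outside, nr, nc)

  # partition fiber rows into lateral bands with a constant set of active
  # splits, and render each band's Z-line profile once
  thresholds <- vapply(splits, function(s) split_row_threshold(s$lateral_fraction, geom), 1L)
  cuts <- sort(unique(c(geom$r0, thresholds, geom$r1 + 1L)))
  bands <- list()
  two_s2 <- 2 * fiber$zline_sigma_um^2
  for (b in seq_len(length(cuts) - 1L)) {
    rows <- cuts[b]:(cuts[b + 1L] - 1L)
    active <- vapply(splits, function(s) rows[1] >= split_row_threshold(s$lateral_fraction, geom), TRUE)
    pos <- zline_positions_for(geom, splits, active)
    ridge <- rowSums(exp(-outer(x, pos, "-")^2 / two_s2))
    prof <- fiber$aband_intensity +
      (fiber$zline_intensity - fiber$aband_intensity) * pmin(ridge, 1)
    ch0[rows, ] <- matrix(prof, length(rows), nc, byrow = TRUE)
    ch1[rows, ] <- fiber$nsp_background
    bands[[b]] <- list(row0 = rows[1] - 1L, row1 = rows[length(rows)] - 1L,
                       positions_um = pos)
  }

  # hotspots
  hs_df <- NULL; hs_masks <- list()
  if (length(hotspots) > 0L) {
    foot <- lapply(hotspots, function(h) {
      stopifnot(inherits(h, "hotspot_spec")); hotspot_footprint(h, geom)
    })
    union_mask <- matrix(0, nr, nc)
    for (f in foot) union_mask[f$rows, f$cols] <- 1
    ncomp <- max(label_components8(union_mask))
    if (ncomp < length(hotspots) && !allow_contiguous)
      abort(paste0("planted hotspots would merge into %d connected component(s); ",
                   "separate them or set allow_contiguous = TRUE"), ncomp)
    hs_df <- do.call(rbind, lapply(seq_along(hotspots), function(i) {
      h <- hotspots[[i]]; f <- foot[[i]]
      data.frame(id = i, model_class = h$model_class,
                 anchor_sarcomere = h$anchor_sarcomere,
                 lateral_fraction = h$lateral_fraction,
                 diameter_nm = h$diameter, fold = h$fold,
                 span_sarcomeres = if (is.null(h$span_sarcomeres)) NA_real_ else h$span_sarcomeres,
                 x0_um = f$x0_um, x1_um = f$x1_um,
                 row0 = f$rows[1] - 1L, row1 = f$rows[length(f$rows)] - 1L,
                 col0 = f$cols[1] - 1L, col1 = f$cols[length(f$cols)] - 1L,
                 centroid_row = mean(f$rows) - 1, centroid_col = mean(f$cols) - 1,
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_along(hotspots)) {
      f <- foot[[i]]
      ch1[f$rows, f$cols] <- hotspots[[i]]$fold * fiber$nsp_background
      px <- expand.grid(row = f$rows - 1L, col = f$cols - 1L)
      hs_masks[[i]] <- as.matrix(px)
    }
  }

  splits_df <- if (length(splits) > 0L) {
    do.call(rbind, lapply(seq_along(splits), function(i) {
      s <- splits[[i]]; k <- s$aband_index + 1L
      data.frame(id = i, aband_index = s$aband_index, zline_index = k,
                 lateral_fraction = s$lateral_fraction, sense = s$sense,
                 row_threshold = split_row_threshold(s$lateral_fraction, geom) - 1L,
                 zline_x_um = geom$z_base[k], stringsAsFactors = FALSE)
    }))
  } else NULL

  mask <- matrix(FALSE, nr, nc); mask[geom$r0:geom$r1, ] <- TRUE
  img <- new_fiber_image(ch0, ch1, spec$pixel_pitch, mask,
                         meta = list(spec = unclass(spec), fiber = unclass(fiber)))
  gt <- structure(list(
    splits = splits_df, hotspots = hs_df, hotspot_masks = hs_masks,
    zline_bands = bands, z_base_um = geom$z_base, n_zlines = geom$n_z,
    sarcomere_length_um = geom$sl,
    fiber_row0 = geom$r0 - 1L, fiber_row1 = geom$r1 - 1L,
    fiber_width_um = geom$width_um, pixel_pitch = p,
    spec = unclass(spec), fiber = unclass(fiber)), class = "ground_truth")
  list(image = img, ground_truth = gt)
}

#' Z-line axial positions (um) at a given 0-based row, from ground truth
#' @param gt A `ground_truth` object.
#' @param row 0-based lateral row index.
#' @return Numeric vector of axial positions in um.
#' @export
gt_zline_positions <- function(gt, row) {
  for (b in gt$zline_bands)
    if (row >= b$row0 && row <= b$row1) return(b$positions_um)
  abort("row %d lies outside the fiber (rows %d..%d)", row, gt$fiber_row0, gt$fiber_row1)
}

#' Planted signed net split count for one A-band gap
#'
#' The oracle for split-count recovery: a trace of gap `g` (between base
#' Z-lines g and g+1) encounters exactly the planted events whose
#' bifurcating Z-line is one of its two bounding lines.
#'
#' @param gt A `ground_truth`.
#' @param gap 1-based base-grid gap index.
#' @return List with `net`, `n_bifurcations`, `n_merges`.
#' @export
gt_net_splits_for_gap <- function(gt, gap) {
  if (is.null(gt$splits)) return(list(net = 0L, n_bifurcations = 0L, n_merges = 0L))
  # a bifurcation involves one Z-line; a merge involves two (k and k+1)
  hit <- mapply(function(k, sense) {
    any(c(gap, gap + 1L) %in% if (sense == 1L) k else c(k, k + 1L))
  }, gt$splits$zline_index, gt$splits$sense)
  nb <- sum(gt$splits$sense[hit] == 1L); nm <- sum(gt$splits$sense[hit] == -1L)
  list(net = abs(nb - nm), n_bifurcations = nb, n_merges = nm)
}

#' Apply PSF blur and Poisson-Gaussian noise to a fiber image
#'
#' Gaussian blur of `psf_sigma` is applied first, then Poisson shot noise
#' (at `poisson_gain` photons per intensity unit) and additive Gaussian
#' read noise of SD `gaussian_sd`.  Seeded and reproducible: the same
#' `spec$seed` always produces identical arrays.  With all three
#' parameters zero the image is returned unchanged.
#'
#' @param image A `fiber_image`.
#' @param spec The [image_spec()] carrying `psf_sigma`, `noise`, `seed`.
#' @return A degraded `fiber_image`.
#' @export
add_noise <- function(image, spec) {
  stopifnot(inherits(image, "fiber_image"))
  sig_px <- spec$psf_sigma / image$pixel_pitch
  g <- spec$noise$poisson_gain; sd <- spec$noise$gaussian_sd
  ch <- image$ch
  if (sig_px > 0)
    for (k in 1:2) ch[, , k] <- EBImage::gblur(ch[, , k], sigma = sig_px)
  if (g > 0 || sd > 0) {
    ch <- with_seed(spec$seed, {
      out <- ch
      if (g > 0)
        for (k in 1:2) out[, , k] <- stats::rpois(length(out[, , k]), pmax(out[, , k], 0) * g) / g
      if (sd > 0) out <- out + stats::rnorm(length(out), sd = sd)
      out
    })
  }
  image$ch <- ch
  image
}
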