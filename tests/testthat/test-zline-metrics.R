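# Continuous Z-line segmentation, tracing and the disarray statistic.

test_that("ROI selection is physical, seeded, and validated", {
  r <- render_fiber(spec_clean(), fiber_model())
  roi <- select_roi(r$image, seed = 4)
  expect_equal(roi$extent * 0.103, c(20.6, 41.2))
  roi2 <- select_roi(r$image, seed = 4)
  expect_identical(roi, roi2)
  narrow <- render_fiber(spec_clean(), fiber_model(width_um = 10.3))
  expect_error(select_roi(narrow$image),
               "fiber rows available, 200 required")
})

test_that("segmentation covers every planted Z-line center within 1 px", {
  r <- render_fiber(spec_clean(), fiber_model())
  roi <- select_roi(r$image, seed = 7)
  mask <- segment_zlines(roi_raster(r$image, roi))
  sk <- zline_skeleton(mask)
  skm <- matrix(FALSE, roi$extent[1], roi$extent[2])
  skm[sk$px] <- TRUE
  gt <- r$ground_truth
  centers <- round(gt$z_base_um / 0.103) + 1 - roi$col0
  centers <- centers[centers >= 2 & centers <= roi$extent[2] - 1]
  for (row in seq(5, roi$extent[1] - 5, by = 13))
    for (cc in centers)
      expect_true(any(skm[row, (cc - 1):(cc + 1)]))
})

test_that("degenerate rasters are flagged or symmetric", {
  u <- segment_zlines(matrix(7, 100, 100))
  expect_true(attr(u, "empty"))
  expect_false(any(u))
  expect_error(zline_analysis(matrix(7, 100, 100), pixel_pitch = 0.103),
               "empty mask")
  r <- render_fiber(spec_clean(), fiber_model())
  raster <- roi_raster(r$image, select_roi(r$image, seed = 1))
  m1 <- segment_zlines(raster)
  m2 <- segment_zlines(max(raster) - raster, invert = TRUE)
  expect_identical(which(m1), which(m2))
})

test_that("ideal striations trace to full-width lines of 20.6 um", {
  r <- render_fiber(spec_clean(), fiber_model())
  za <- zline_analysis(r$image, select_roi(r$image, seed = 7))
  expect_true(all(abs(za$lines$lines$length_um - 20.6) <= 2 * 0.103))
  expect_equal(za$mean_length_um, 20.6, tolerance = 2 * 0.103 / 20.6)
})

test_that("bisecting every Z-line mid-width halves the mean length", {
  r0 <- render_fiber(spec_clean(), fiber_model())
  nz <- r0$ground_truth$n_zlines
  splits <- lapply(seq_len(nz - 2L), function(k) split_event(k, 0.5))
  r <- render_fiber(spec_clean(), fiber_model(), splits = splits)
  za <- zline_analysis(r$image, select_roi(r$image, seed = 7))
  expect_equal(za$mean_length_um, 10.3, tolerance = 0.05)
})

test_that("isolated pixels and weighting arithmetic behave as specified", {
  skm <- matrix(FALSE, 64, 64); skm[10, 10] <- TRUE
  sk <- zline_skeleton(skm)
  cz <- trace_continuous_zlines(sk, pixel_pitch = 0.103)
  expect_equal(nrow(cz$lines), 1L)
  expect_equal(cz$lines$length_um, 0)
  expect_equal(mean_continuous_zline_length(c(10, 20)), 15)
  expect_equal(mean_continuous_zline_length(c(10, 20), "length"), 50 / 3)
  expect_error(mean_continuous_zline_length(numeric(0)), "no continuous")
})

test_that("tracing partitions the skeleton: every pixel in exactly one line", {
  r <- render_fiber(spec_clean(), fiber_model(),
                    splits = list(split_event(4, 0.3), split_event(10, 0.7)))
  mask <- segment_zlines(fiber_channel(r$image, "zline"))
  sk <- zline_skeleton(mask)
  cz <- trace_continuous_zlines(sk, pixel_pitch = 0.103)
  expect_equal(sum(cz$lines$n_px), nrow(sk$px))
  all_px <- do.call(rbind, cz$paths)
  expect_equal(nrow(unique(all_px)), nrow(sk$px))
})

test_that("with theta_max = 180 and no branches, lines are the components", {
  r <- render_fiber(spec_clean(), fiber_model())
  mask <- segment_zlines(fiber_channel(r$image, "zline"))
  sk <- zline_skeleton(mask)
  expect_false(any(sk$branch))
  cz <- trace_continuous_zlines(sk, theta_max = 180, pixel_pitch = 0.103)
  # independent 8-connected component count: plain BFS flood fill
  skm <- matrix(FALSE, sk$dim[1], sk$dim[2]); skm[sk$px] <- TRUE
  seen <- matrix(FALSE, nrow(skm), ncol(skm))
  ncomp <- 0L
  for (p in seq_len(nrow(sk$px))) {
    r <- sk$px[p, 1]; cc <- sk$px[p, 2]
    if (seen[r, cc]) next
    ncomp <- ncomp + 1L
    queue <- list(c(r, cc)); seen[r, cc] <- TRUE
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- q[1] + dr; c2 <- q[2] + dc
        if (rr >= 1 && rr <= nrow(skm) && c2 >= 1 && c2 <= ncol(skm) &&
            skm[rr, c2] && !seen[rr, c2]) {
          seen[rr, c2] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, c2)
        }
      }
    }
  }
  expect_equal(nrow(cz$lines), ncomp)
})

test_that("a 90-degree rotation changes no line length beyond 2 px", {
  r <- render_fiber(spec_clean(), fiber_model())
  raster <- roi_raster(r$image, select_roi(r$image, seed = 3))
  za <- zline_analysis(raster, pixel_pitch = 0.103)
  rot <- t(raster[nrow(raster):1, ])  # 90 degrees clockwise
  za_rot <- zline_analysis(rot, pixel_pitch = 0.103)
  l1 <- sort(za$lines$lines$length_um)
  l2 <- sort(za_rot$lines$lines$length_um)
  expect_equal(length(l1), length(l2))
  expect_true(all(abs(l1 - l2) <= 2 * 0.103))
})

test_that("mean length decreases strictly with planted split density", {
  densities <- c(0, 0.1, 0.3)
  means <- vapply(seq_along(densities), function(di) {
    d <- densities[di]
    vals <- vapply(1:4, function(i) {
      sp <- spec_clean(seed = 100 * di + i)
      geom_nz <- render_fiber(sp, fiber_model())$ground_truth$n_zlines
      set.seed(100 * di + i)
      ks <- which(stats::runif(geom_nz - 2L) < d)
      splits <- lapply(ks, function(k) split_event(k, stats::runif(1, 0.2, 0.8)))
      r <- render_fiber(sp, fiber_model(), splits = splits)
      zline_analysis(r$image, select_roi(r$image, seed = i))$mean_length_um
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(means[1] > means[2] && means[2] > means[3])
})
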