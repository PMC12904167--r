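# Local background estimation, hotspot gates, positive-fiber calls, ROI
# disarray classification and the paired normal/disarrayed comparison.

test_that("background of a uniform field is exact; blobs barely perturb it", {
  nsp <- matrix(100, 120, 120)
  mask <- matrix(TRUE, 120, 120)
  bg <- estimate_local_background(nsp, mask, pixel_pitch = 0.103)
  expect_true(all(bg == 100))
  # one bright blob: background under it stays within 5% of the field
  nsp2 <- nsp; nsp2[55:65, 55:65] <- 500
  bg2 <- estimate_local_background(nsp2, mask, pixel_pitch = 0.103)
  expect_lt(abs(bg2[60, 60] - 100) / 100, 0.05)
})

test_that("background estimation rejects degenerate inputs", {
  nsp <- matrix(100, 100, 100)
  expect_error(estimate_local_background(nsp, matrix(FALSE, 100, 100)),
               "mask is empty")
  expect_error(estimate_local_background(nsp, matrix(TRUE, 100, 100),
                                         pixel_pitch = 1, window_um = 2),
               "smaller than 3 px")
})

# a flat-topped rectangular blob on a uniform background, pitch chosen so
# nm gates land on integer pixels (0.1 um/px: 4 px = 400 nm)
blob_image <- function(fold, w_px, h_px = w_px, bgv = 100, size = 120L) {
  nsp <- matrix(bgv, size, size)
  r0 <- (size - h_px) %/% 2L; c0 <- (size - w_px) %/% 2L
  nsp[r0:(r0 + h_px - 1L), c0:(c0 + w_px - 1L)] <- fold * bgv
  nsp
}

test_that("fold and size gates are exact and inclusive at their boundaries", {
  mask <- matrix(TRUE, 120, 120)
  detect <- function(nsp) {
    bg <- estimate_local_background(nsp, mask, pixel_pitch = 0.1)
    detect_hotspots(nsp, bg, mask, pixel_pitch = 0.1)
  }
  # fold 1.99: detected (above detect_fold 1.5) but does not qualify
  h <- detect(blob_image(1.99, 8))
  expect_equal(nrow(h$table), 1L)
  expect_false(h$table$qualifies)
  expect_equal(h$table$reason, "fold")
  expect_equal(h$table$fold, 1.99, tolerance = 1e-10)
  # fold exactly 2.0 at 400 nm (4 px at 0.1 um/px): qualifies, inclusive
  h <- detect(blob_image(2.0, 4, 20))
  expect_true(h$table$qualifies)
  expect_equal(h$table$min_feret_nm, 400)
  # 1900 nm (19 px): inclusive upper bound
  h <- detect(blob_image(3, 19, 19))
  expect_true(h$table$qualifies)
  expect_equal(h$table$min_feret_nm, 1900)
  # 2000 nm: rejected as too large
  h <- detect(blob_image(3, 20, 20))
  expect_false(h$table$qualifies)
  expect_equal(h$table$reason, "size_large")
  # 300 nm (3 px): too small
  h <- detect(blob_image(3, 3, 20))
  expect_false(h$table$qualifies)
  expect_equal(h$table$reason, "size_small")
})

test_that("equivalent-diameter gating is available and exact on disk areas", {
  mask <- matrix(TRUE, 120, 120)
  nsp <- blob_image(3, 10, 10)   # area 100 px -> eq diam 2*sqrt(100/pi) px
  bg <- estimate_local_background(nsp, mask, pixel_pitch = 0.1)
  h <- detect_hotspots(nsp, bg, mask, pixel_pitch = 0.1,
                       size_measure = "equiv")
  expect_equal(h$table$equiv_diameter_nm, 2 * sqrt(100 / pi) * 100)
  expect_true(h$table$qualifies)
})

test_that("raising the fold threshold never adds qualifying hotspots", {
  r <- render_five_classes(spec_noisy(21, shape = c(260L, 700L)))
  img <- r$image
  mask <- fiber_mask(img)
  nsp <- fiber_channel(img, "nsp")
  bg <- estimate_local_background(nsp, mask, img$pixel_pitch)
  n_qual <- vapply(c(1.6, 2.0, 2.5, 3.5), function(thr)
    sum(detect_hotspots(nsp, bg, mask, img$pixel_pitch,
                        fold_threshold = thr)$table$qualifies), numeric(1))
  expect_true(all(diff(n_qual) <= 0))
})

test_that("noise-free planted hotspots are recovered exactly, none spurious", {
  sp <- spec_clean(6, shape = c(260L, 700L))
  hs <- list(hotspot_spec("yu", 4), hotspot_spec("yu", 10, 0.35),
             hotspot_spec("rodier", 16, 0.65))
  r <- render_fiber(sp, fiber_model(), hotspots = hs)
  h <- find_hotspots(r$image)
  expect_equal(sum(h$table$qualifies), 3L)
  m <- match_hotspots(h, r$ground_truth)
  expect_true(all(m$recalled))
  expect_equal(m$spurious, 0L)
  # the detected qualifying masks are the planted pixel sets exactly
  qual_ids <- which(h$table$qualifies)
  det <- do.call(rbind, h$masks[qual_ids])
  planted <- do.call(rbind, r$ground_truth$hotspot_masks)
  expect_setequal(paste(det[, 1], det[, 2]),
                  paste(planted[, "row"], planted[, "col"]))
})

test_that("positive-fiber calls follow the multiple-loci rule", {
  expect_false(call_positive_fiber(logical(0)))
  expect_false(call_positive_fiber(c(TRUE, FALSE)))
  expect_true(call_positive_fiber(c(TRUE, TRUE)))
  expect_true(call_positive_fiber(rep(TRUE, 5), min_count = 3))
  # 18 of 30 positive fibers -> 60%
  pos <- c(rep(TRUE, 18), rep(FALSE, 12))
  expect_equal(mean(pos) * 100, 60)
})

test_that("ROI disarray classification matches the fractional rule", {
  expect_equal(classify_roi(10, 10, f = 0.6), "normal")
  expect_equal(classify_roi(5.9, 10, f = 0.6), "disarrayed")
  expect_equal(classify_roi(6.0, 10, f = 0.6), "normal")  # boundary: not below
  expect_equal(classify_roi(0.01, 10, f = 0), "normal")   # f = 0 limit
})

test_that("split-halved ROIs are called disarrayed against pristine ones", {
  sp <- spec_clean(12, shape = c(260L, 800L))
  nz <- render_fiber(sp, fiber_model())$ground_truth$n_zlines
  # splits confined to the left half of the fiber
  ks <- seq(2L, as.integer(nz / 2) - 2L)
  splits <- lapply(ks, function(k) split_event(k, 0.5))
  r <- render_fiber(sp, fiber_model(), splits = splits)
  rois <- classify_fiber_rois(r$image)
  split_cols_px <- range(r$ground_truth$splits$zline_x_um) / 0.103
  in_split <- rois$col0 + rois$size_px / 2 < split_cols_px[2]
  expect_true(any(rois$label[in_split] == "disarrayed"))
  expect_true(all(rois$label[!in_split] == "normal"))
})

test_that("paired ROI counts isolate hotspots planted in disarrayed regions", {
  rois <- data.frame(roi_id = 1:4, row0 = c(0, 0, 100, 100),
                     col0 = c(0, 100, 0, 100), size_px = 100,
                     mean_czl_um = c(20, 20, 8, 8),
                     label = c("normal", "normal", "disarrayed", "disarrayed"))
  fake_hs <- structure(list(table = data.frame(
    id = 1:3, centroid_row = c(150, 160, 120), centroid_col = c(50, 60, 150),
    qualifies = TRUE)), class = "hotspot_set")
  pr <- hotspots_per_roi_paired(rois, fake_hs, seed = 1)
  expect_equal(pr$normal_mean, 0)
  expect_gt(pr$disarrayed_mean, 0)
  expect_equal(pr$n_each, 2L)
  # a fiber lacking one class is excluded
  rois_norm <- rois; rois_norm$label <- "normal"
  expect_message(out <- hotspots_per_roi_paired(rois_norm, fake_hs), "excluded")
  expect_null(out)
})
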