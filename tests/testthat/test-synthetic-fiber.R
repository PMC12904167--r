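# Synthetic fiber generator: planted geometry, determinism, noise model.

test_that("constructors validate their invariants", {
  expect_error(image_spec(pixel_pitch = 0), "pixel_pitch")
  expect_error(image_spec(shape = c(32, 440)), ">= 64")
  expect_error(image_spec(psf_sigma = -1), "psf_sigma")
  expect_error(fiber_model(zline_intensity = 50, aband_intensity = 60),
               "intensities")
  expect_error(split_event(3, 0), "strictly inside")
  expect_error(split_event(3, 1), "strictly inside")
  expect_error(split_event(3, 0.5, sense = 2), "sense")
  expect_error(hotspot_spec("yu", 3, diameter = -5), "diameter")
  expect_error(hotspot_spec("short_atypical", 3, span_sarcomeres = 2.5), "< 2")
  expect_error(hotspot_spec("long_atypical", 3, span_sarcomeres = 1.5), "> 2")
  expect_error(hotspot_spec("yu", 3, span_sarcomeres = 1), "atypical")
})

test_that("clean render has the planted striation period (FFT oracle)", {
  r <- render_fiber(spec_clean(), fiber_model())
  prof <- fiber_channel(r$image, "zline")[130, ]
  expect_equal(fft_period_px(prof), 2.4 / 0.103, tolerance = 0.05)
})

test_that("ground truth bookkeeping is one-to-one with planted items", {
  hs <- list(hotspot_spec("yu", 3), hotspot_spec("rodier", 8, 0.3),
             hotspot_spec("hzone", 14, 0.7))
  r <- render_fiber(spec_clean(), fiber_model(), hotspots = hs)
  expect_equal(nrow(r$ground_truth$hotspots), 3L)
  expect_equal(length(r$ground_truth$hotspot_masks), 3L)
  expect_equal(r$ground_truth$hotspots$model_class,
               c("yu", "rodier", "hzone"))
})

test_that("an h-zone hotspot is centered on its Z-line within 1 px", {
  r <- render_fiber(spec_clean(), fiber_model(),
                    hotspots = list(hotspot_spec("hzone", 10)))
  gt <- r$ground_truth
  # the blob straddles the Z-line between sarcomeres 10 and 11
  z_px <- gt$z_base_um[11] / gt$pixel_pitch
  centroid <- gt$hotspots$centroid_col[1]
  expect_lt(abs(centroid - z_px), 1)
  # and its intensity profile in the render is centered there too
  nsp <- fiber_channel(r$image, "nsp")
  rows <- (gt$hotspots$row0[1]:gt$hotspots$row1[1]) + 1L
  prof <- colMeans(nsp[rows, ])
  com <- sum(seq_along(prof) * (prof - min(prof))) / sum(prof - min(prof)) - 1
  expect_lt(abs(com - z_px), 1)
})

test_that("in-series sarcomere count is conserved across planted splits", {
  splits <- list(split_event(4, 0.3), split_event(9, 0.6),
                 split_event(14, 0.45, sense = -1L))
  r <- render_fiber(spec_clean(), fiber_model(), splits = splits)
  gt <- r$ground_truth
  for (row in c(gt$fiber_row0, 80, 130, 180, gt$fiber_row1)) {
    crossed <- sum(vapply(splits, function(s) {
      thr <- gt$splits$row_threshold[gt$splits$aband_index == s$aband_index]
      if (row >= thr) s$sense else 0L
    }, 0L))
    expect_equal(length(gt_zline_positions(gt, row)), gt$n_zlines + crossed)
  }
})

test_that("planted hotspot masks are recovered exactly from the clean render", {
  hs <- list(hotspot_spec("yu", 4), hotspot_spec("rodier", 12, 0.35))
  r <- render_fiber(spec_clean(), fiber_model(), hotspots = hs)
  nsp <- fiber_channel(r$image, "nsp")
  fm <- fiber_model()
  hot <- which(nsp >= 2 * fm$nsp_background & r$image$mask, arr.ind = TRUE) - 1L
  planted <- do.call(rbind, r$ground_truth$hotspot_masks)
  expect_setequal(paste(hot[, 1], hot[, 2]),
                  paste(planted[, "row"], planted[, "col"]))
})

test_that("contiguous planted hotspots are rejected unless allowed", {
  hs <- list(hotspot_spec("yu", 10), hotspot_spec("yu", 11))
  expect_error(render_fiber(spec_clean(), fiber_model(), hotspots = hs),
               "merge")
  r <- render_fiber(spec_clean(), fiber_model(), hotspots = hs,
                    allow_contiguous = TRUE)
  expect_equal(nrow(r$ground_truth$hotspots), 2L)
})

test_that("splits are validated against the fiber geometry", {
  expect_error(render_fiber(spec_clean(), fiber_model(),
                            splits = list(split_event(500, 0.5))),
               "outside the fiber interior")
  expect_error(render_fiber(spec_clean(), fiber_model(),
                            splits = list(split_event(5, 0.4),
                                          split_event(5, 0.6))),
               "same Z-line")
})

test_that("degradation is seeded and reproducible; zero noise is identity", {
  r <- render_fiber(spec_clean(), fiber_model())
  id <- add_noise(r$image, spec_clean())
  expect_identical(id$ch, r$image$ch)
  sp <- image_spec(psf_sigma = 0.2, noise = list(gaussian_sd = 10,
                                                 poisson_gain = 0.5), seed = 42)
  n1 <- add_noise(r$image, sp)
  n2 <- add_noise(r$image, sp)
  expect_identical(n1$ch, n2$ch)
  expect_false(identical(n1$ch, r$image$ch))
})

test_that("additive noise has the requested SD on a flat region", {
  r <- render_fiber(spec_clean(), fiber_model())
  sp <- image_spec(psf_sigma = 0, noise = list(gaussian_sd = 5,
                                               poisson_gain = 0), seed = 9)
  noisy <- add_noise(r$image, sp)
  flat <- (noisy$ch[1:30, , 1] - r$image$ch[1:30, , 1])  # outside the fiber
  expect_equal(sd(flat), 5, tolerance = 0.1)
})

test_that("identical seed and spec give bit-identical renders", {
  r1 <- render_fiber(spec_clean(7), fiber_model(),
                     splits = list(split_event(5, 0.5)),
                     hotspots = list(hotspot_spec("yu", 10)))
  r2 <- render_fiber(spec_clean(7), fiber_model(),
                     splits = list(split_event(5, 0.5)),
                     hotspots = list(hotspot_spec("yu", 10)))
  expect_identical(r1$image$ch, r2$image$ch)
  expect_identical(r1$ground_truth, r2$ground_truth)
})

test_that("cohort simulation honours densities, mixture and bookkeeping", {
  cfg <- cohort_config(groups = data.frame(group = c("sham", "mov"),
                                           rapamycin = "veh",
                                           split_density = c(0, 0.2),
                                           hotspot_rate = c(0, 3)),
                       muscles_per_group = 3L, fibers_per_muscle = 4L,
                       class_mixture = c(yu = 1),
                       shape = c(260L, 440L), psf_sigma = 0, gaussian_sd = 0)
  co <- simulate_cohort(cfg, seed = 3)
  man <- co$manifest
  expect_equal(sum(man$group == "sham"), 12L)  # muscles x fibers per group
  expect_equal(sum(man$group == "mov"), 12L)
  sham <- man$group == "sham"
  expect_true(all(man$n_splits[sham] == 0))
  expect_true(all(man$n_hotspots[sham] == 0))
  for (rec in co$records) {
    if (is.null(rec$ground_truth$hotspots)) next
    expect_true(all(rec$ground_truth$hotspots$model_class == "yu"))
  }
  # reproducibility of the whole cohort
  co2 <- simulate_cohort(cfg, seed = 3)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$records[[5]]$image$ch, co2$records[[5]]$image$ch)
})

test_that("single-fiber tables honour CV = 0 and planted effects exactly", {
  p <- single_fiber_params(mov_effect = 1.075, n = 6L)
  p$fiber_length_cv <- 0; p$sarcomere_length_cv <- 0
  tab <- simulate_single_fiber_table(p, seed = 1)
  sham <- tab$fiber_length_um[tab$group == "sham" & tab$rapamycin == "veh"]
  mov <- tab$fiber_length_um[tab$group == "mov" & tab$rapamycin == "veh"]
  expect_true(all(sham == 2500))
  expect_equal(mean(mov) / mean(sham), 1.075)
  nsham <- serial_sarcomere_number(sham, tab$sarcomere_length_um[tab$group == "sham"][1])
  nmov <- serial_sarcomere_number(mov, 2.4)
  expect_equal(mean(nmov) / mean(nsham), 1.075)
  p_bad <- p; p_bad$fiber_length_cv <- -0.1
  expect_error(simulate_single_fiber_table(p_bad), "variation")
  # lognormal draws reproduce the requested mean and CV
  p2 <- single_fiber_params(n = 4000L)[1, ]
  tab2 <- simulate_single_fiber_table(p2, seed = 2)
  expect_equal(mean(tab2$fiber_length_um), 2500, tolerance = 0.01)
  expect_equal(sd(tab2$fiber_length_um) / mean(tab2$fiber_length_um), 0.10,
               tolerance = 0.05)
})
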