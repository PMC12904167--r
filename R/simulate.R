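# Cohort-level simulation: sham/overload contrasts with planted split and
# hotspot densities, and single-fiber morphometry tables.

#' Default cohort configuration
#'
#' The generator's defaults are the study conditions the package emulates:
#' a sham group with sparse transverse splits and rare NSP hotspots, and a
#' mechanically overloaded (MOV) group with a 4.9-fold higher split
#' density and a hotspot rate tuned so that roughly 60% of MOV fibers
#' (vs ~5% of sham fibers) carry two or more qualifying hotspots.  The
#' hotspot class mixture plants 87% model-conforming morphologies
#' (dominated by single-sarcomere Z-line splitting) and 13% atypical ones.
#' Densities and rates are configuration, not measurements.
#'
#' @param groups Data frame with one row per experimental arm: columns
#'   `group`, `rapamycin`, `split_density` (expected bifurcations per
#'   interior Z-line), `hotspot_rate` (expected hotspots per fiber,
#'   Poisson).
#' @param muscles_per_group,fibers_per_muscle Cohort sizes.
#' @param class_mixture Named probabilities over [HOTSPOT_CLASSES].
#' @param shape,pixel_pitch,psf_sigma,gaussian_sd,poisson_gain Imaging
#'   conditions handed to [image_spec()].
#' @param fiber,hotspot_fold,hotspot_diameter_nm Fiber model and hotspot
#'   rendering parameters.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(groups = data.frame(
                            group = c("sham", "mov"),
                            rapamycin = c("veh", "veh"),
                            split_density = c(0.05, 0.245),
                            hotspot_rate = c(0.35, 2.0)),
                          muscles_per_group = 3L,
                          fibers_per_muscle = 30L,
                          class_mixture = c(yu = 0.696, rodier = 0.17,
                                            hzone = 0.003,
                                            short_atypical = 0.043,
                                            long_atypical = 0.088),
                          shape = c(260L, 1024L),
                          pixel_pitch = 0.103,
                          psf_sigma = 0.2,
                          gaussian_sd = 8,
                          poisson_gain = 0,
                          fiber = fiber_model(),
                          hotspot_fold = 3,
                          hotspot_diameter_nm = 1000) {
  req <- c("group", "rapamycin", "split_density", "hotspot_rate")
  if (!all(req %in% names(groups)))
    abort("groups must have columns %s", paste(req, collapse = ", "))
  if (any(groups$split_density < 0) || any(groups$hotspot_rate < 0))
    abort("densities must be >= 0")
  cm <- class_mixture / sum(class_mixture)
  if (!all(names(cm) %in% HOTSPOT_CLASSES)) abort("unknown hotspot class in mixture")
  structure(list(groups = groups, muscles_per_group = as.integer(muscles_per_group),
                 fibers_per_muscle = as.integer(fibers_per_muscle),
                 class_mixture = cm, shape = as.integer(shape),
                 pixel_pitch = pixel_pitch, psf_sigma = psf_sigma,
                 gaussian_sd = gaussian_sd, poisson_gain = poisson_gain,
                 fiber = fiber, hotspot_fold = hotspot_fold,
                 hotspot_diameter_nm = hotspot_diameter_nm),
            class = "cohort_config")
}

# draw planted hotspots and splits for one fiber.  Hotspots are the
# scarce resource (anchors must be spaced and Z-registrable), so they are
# planted first; splits then go on Z-lines clear of any hotspot's
# registration neighbourhood, keeping every planted morphology
# measurable against an unforked local grid.
.plant_fiber <- function(config, group_row, geom_nz, seed) {
  with_seed(seed, {
    n_h <- stats::rpois(1, group_row$hotspot_rate)
    hotspots <- list()
    blocked <- integer(0)
    if (n_h > 0) {
      classes <- sample(names(config$class_mixture), n_h, replace = TRUE,
                        prob = config$class_mixture)
      cand <- seq(2L, geom_nz - 5L, by = 5L)  # masks can never touch
      n_h <- min(n_h, length(cand))
      anchors <- sample(cand, n_h)
      hotspots <- lapply(seq_len(n_h), function(i)
        hotspot_spec(classes[i], anchors[i],
                     lateral_fraction = stats::runif(1, 0.25, 0.75),
                     diameter = config$hotspot_diameter_nm,
                     fold = config$hotspot_fold))
      need <- vapply(hotspots, function(h)
        switch(h$model_class, yu = 2L, rodier = 3L, hzone = 2L,
               short_atypical = 2L,
               long_atypical = as.integer(ceiling(h$span_sarcomeres)) + 1L),
        1L)
      blocked <- unique(unlist(Map(function(a, nd) (a - 1L):(a + nd), anchors,
                                   need)))
    }
    eligible <- setdiff(2:(geom_nz - 1L), blocked)   # Z-lines free to fork
    hit <- eligible[stats::runif(length(eligible)) < group_row$split_density]
    splits <- lapply(hit, function(k)
      split_event(k - 1L, stats::runif(1, 0.15, 0.85)))
    list(splits = splits, hotspots = hotspots)
  })
}

#' Simulate a sham/overload cohort of fiber images with ground truth
#'
#' Reproducible: all randomness flows from `seed` via per-fiber derived
#' seeds.  Each record carries the rendered (degraded) image, its exact
#' pre-noise ground truth, and its cohort labels; the manifest has one
#' row per fiber.
#'
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @return A `fiber_cohort`: list with `records`, `manifest` (data.frame
#'   `muscle_id`, `fiber_id`, `group`, `rapamycin`, `n_splits`,
#'   `n_hotspots`), and `config`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  base_spec <- image_spec(pixel_pitch = config$pixel_pitch, shape = config$shape,
                          psf_sigma = config$psf_sigma,
                          noise = list(gaussian_sd = config$gaussian_sd,
                                       poisson_gain = config$poisson_gain),
                          seed = 1L)
  geom <- fiber_geometry(base_spec, config$fiber)
  max_splits <- geom$n_z - 2L
  if (any(config$groups$split_density > 1))
    abort("split_density > 1 per Z-line: more planted splits than geometric slots")

  n_per_group <- config$muscles_per_group * config$fibers_per_muscle
  total <- nrow(config$groups) * n_per_group
  seeds <- derive_seeds(seed, total)
  records <- vector("list", total)
  man <- vector("list", total)
  i <- 0L
  for (g in seq_len(nrow(config$groups))) {
    grow <- config$groups[g, ]
    for (m in seq_len(config$muscles_per_group)) {
      muscle_id <- sprintf("%s_%s_m%02d", grow$group, grow$rapamycin, m)
      for (f in seq_len(config$fibers_per_muscle)) {
        i <- i + 1L
        si <- seeds[i]
        planted <- .plant_fiber(config, grow, geom$n_z, si)
        spec_i <- image_spec(pixel_pitch = config$pixel_pitch,
                             shape = config$shape, psf_sigma = config$psf_sigma,
                             noise = list(gaussian_sd = config$gaussian_sd,
                                          poisson_gain = config$poisson_gain),
                             seed = si)
        r <- render_fiber(spec_i, config$fiber, planted$splits, planted$hotspots)
        img <- add_noise(r$image, spec_i)
        records[[i]] <- list(image = img, ground_truth = r$ground_truth,
                             muscle_id = muscle_id, fiber_id = f,
                             group = grow$group, rapamycin = grow$rapamycin)
        man[[i]] <- data.frame(muscle_id = muscle_id, fiber_id = f,
                               group = grow$group, rapamycin = grow$rapamycin,
                               n_splits = length(planted$splits),
                               n_hotspots = length(planted$hotspots),
                               seed = si, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(records = records, manifest = do.call(rbind, man),
                 config = config), class = "fiber_cohort")
}

#' Default single-fiber morphometry design
#'
#' Emulates a 16-day sham/overload contrast under vehicle and rapamycin:
#' overload lengthens fibers by 7.5% with unchanged sarcomere length, and
#' the lengthening is rapamycin-insensitive (the rapamycin arms share the
#' overload effect).  Absolute levels (2500 um fiber length, 2.4 um
#' sarcomere length, CVs 0.10 and 0.02, 30 fibers per arm) are stated
#' modelling assumptions.
#'
#' @param mov_effect Multiplicative overload effect on fiber length.
#' @param n Fibers per arm.
#' @return Data frame usable as `params` in
#'   [simulate_single_fiber_table()].
#' @export
single_fiber_params <- function(mov_effect = 1.075, n = 30L) {
  data.frame(group = rep(c("sham", "mov"), 2),
             rapamycin = rep(c("veh", "rap"), each = 2),
             timepoint_days = 16L,
             n = as.integer(n),
             fiber_length_mean_um = rep(c(2500, 2500 * mov_effect), 2),
             fiber_length_cv = 0.10,
             sarcomere_length_mean_um = 2.4,
             sarcomere_length_cv = 0.02,
             stringsAsFactors = FALSE)
}

#' Simulate a single-fiber morphometry table
#'
#' Fiber and sarcomere lengths are drawn lognormally (guaranteeing
#' positivity) with the requested group means and coefficients of
#' variation; sarcomere length is drawn independently of group when the
#' design says it is unchanged (the structural assumption that overload
#' adds sarcomeres in series rather than stretching them).  `cv = 0`
#' degenerates to every fiber equalling the group mean.
#'
#' @param params Data frame as from [single_fiber_params()].
#' @param seed Integer seed.
#' @return Data frame with columns `group`, `rapamycin`,
#'   `timepoint_days`, `fiber_id`, `fiber_length_um`,
#'   `sarcomere_length_um`.
#' @export
simulate_single_fiber_table <- function(params = single_fiber_params(), seed = 1L) {
  req <- c("group", "rapamycin", "timepoint_days", "n", "fiber_length_mean_um",
           "fiber_length_cv", "sarcomere_length_mean_um", "sarcomere_length_cv")
  if (!all(req %in% names(params)))
    abort("params must have columns %s", paste(req, collapse = ", "))
  if (any(params$fiber_length_cv < 0) || any(params$sarcomere_length_cv < 0))
    abort("coefficients of variation must be >= 0")
  if (any(params$fiber_length_mean_um <= 0) || any(params$sarcomere_length_mean_um <= 0))
    abort("mean lengths must be > 0")
  rln <- function(n, m, cv) {
    if (cv == 0) return(rep(m, n))
    s2 <- log(1 + cv^2)
    stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      data.frame(group = p$group, rapamycin = p$rapamycin,
                 timepoint_days = p$timepoint_days,
                 fiber_id = seq_len(p$n),
                 fiber_length_um = rln(p$n, p$fiber_length_mean_um, p$fiber_length_cv),
                 sarcomere_length_um = rln(p$n, p$sarcomere_length_mean_um,
                                           p$sarcomere_length_cv),
                 stringsAsFactors = FALSE)
    }))
  })
}
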