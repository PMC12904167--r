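# File formats: 16-bit multi-channel TIFF images, schema-versioned
# ground-truth JSON, flat key-value pipeline configuration, manifests.
# All CSV output is UTF-8, comma-separated, '.' decimal, with a header
# row; units are encoded in column names (length_um, diameter_nm);
# coordinates are 0-based (row, col) pixel indices.

GT_SCHEMA_VERSION <- "1.0"
TIFF_SCALE <- 65535

#' Write a fiber image as a 16-bit two-page TIFF
#'
#' Channel 0 (Z-lines) and channel 1 (NSP) are stored as two pages,
#' scaled by `max_intensity` into the 16-bit range (values are clamped
#' to it; pick `max_intensity` above the data range to make the write
#' lossless to 16-bit precision).
#'
#' @param image A `fiber_image`.
#' @param path Output path.
#' @param max_intensity Intensity mapped to the top of the 16-bit range.
#' @return `path`, invisibly.
#' @export
write_fiber_tiff <- function(image, path, max_intensity = 1000) {
  stopifnot(inherits(image, "fiber_image"))
  pages <- lapply(1:2, function(k) {
    m <- image$ch[, , k] / max_intensity
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a two-channel fiber TIFF
#'
#' The file must carry at least 2 pages/channels.  The pixel pitch comes
#' from the configuration (`pixel_pitch`), which wins over any file
#' metadata by the package's stated precedence.
#'
#' @param path TIFF path.
#' @param pixel_pitch um/px.
#' @param max_intensity Intensity scale used at write time.
#' @param channel_map Integer pages for (zline, nsp); default `c(1, 2)`.
#' @return A `fiber_image`.
#' @export
read_fiber_image <- function(path, pixel_pitch = 0.103, max_intensity = 1000,
                             channel_map = c(zline = 1L, nsp = 2L)) {
  if (!file.exists(path)) abort("no such image file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    abort("image %s has %d channel(s); 2 are required (zline, nsp)",
          path, length(pages))
  ch0 <- pages[[channel_map[["zline"]]]] * max_intensity
  ch1 <- pages[[channel_map[["nsp"]]]] * max_intensity
  new_fiber_image(ch0, ch1, pixel_pitch,
                  meta = list(path = path, channel_map = channel_map))
}

#' Serialize ground truth to JSON
#'
#' Schema-versioned; numeric precision is preserved (no rounding) so
#' that a read-back compares identical.
#'
#' @param gt A `ground_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  obj <- unclass(gt)
  obj$schema_version <- GT_SCHEMA_VERSION
  obj$hotspot_masks <- lapply(obj$hotspot_masks, function(m)
    list(row = as.integer(m[, "row"]), col = as.integer(m[, "col"])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read ground truth back from JSON
#' @param path JSON path.
#' @return A `ground_truth`.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, GT_SCHEMA_VERSION))
    abort("ground-truth schema %s not supported (expected %s)",
          as.character(obj$schema_version), GT_SCHEMA_VERSION)
  obj$schema_version <- NULL
  hm <- obj$hotspot_masks
  obj$hotspot_masks <- if (is.data.frame(hm)) {
    lapply(seq_len(nrow(hm)), function(i)
      cbind(row = as.integer(hm$row[[i]]), col = as.integer(hm$col[[i]])))
  } else {
    lapply(hm, function(m)
      cbind(row = as.integer(m$row), col = as.integer(m$col)))
  }
  obj$zline_bands <- lapply(seq_len(nrow(obj$zline_bands)), function(i)
    list(row0 = obj$zline_bands$row0[i], row1 = obj$zline_bands$row1[i],
         positions_um = obj$zline_bands$positions_um[[i]]))
  for (f in c("fiber_row0", "fiber_row1", "n_zlines"))
    obj[[f]] <- as.integer(obj[[f]])
  structure(obj, class = "ground_truth")
}

#' Default pipeline configuration
#'
#' The flat key-value document of every tunable parameter; embedded into
#' analysis outputs together with the package version.  Units are part
#' of the key names.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    config_version = "1.0",
    pixel_pitch_um = 0.103,
    sarcomere_length_um = 2.4,
    muscles_per_group = 3L,
    fibers_per_muscle = 30L,
    image_rows = 260L, image_cols = 1024L,
    roi_rows_px = 200L, roi_cols_px = 400L,
    theta_max_deg = 20,
    zline_min_length_um = 0,
    zline_weighting = "line",
    n_abands = 40L,
    hotspot_fold_threshold = 2.0,
    hotspot_detect_fold = 1.5,
    hotspot_size_min_nm = 400,
    hotspot_size_max_nm = 1900,
    hotspot_size_measure = "min_feret",
    background_window_um = 5,
    positive_fiber_min_hotspots = 2L,
    disarray_fraction = 0.6,
    roi_square_um = 10,
    tau_span = 0.25, tau_reg = 0.25,
    min_hotspots_per_fiber = 5L,
    seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML/flat key-value; unknown keys are a hard error so that misspelled
#' parameters can never fall back to silent defaults.
#'
#' @param path Config file path (YAML).
#' @return Named list merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    abort("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(def, user)
}

#' Write a pipeline configuration file
#' @param config Named list (validated against [default_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  unknown <- setdiff(names(config), names(default_config()))
  if (length(unknown))
    abort("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a cohort to disk (images, ground truth, manifest)
#'
#' One TIFF and one ground-truth JSON per fiber plus `manifest.csv`
#' with per-file MD5 checksums.
#'
#' @param cohort A `fiber_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fiber_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$records, function(rec) {
    stem <- sprintf("%s_f%02d", rec$muscle_id, rec$fiber_id)
    ip <- file.path(dir, paste0(stem, ".tif"))
    gp <- file.path(dir, paste0(stem, "_truth.json"))
    write_fiber_tiff(rec$image, ip)
    write_ground_truth(rec$ground_truth, gp)
    data.frame(muscle_id = rec$muscle_id, fiber_id = rec$fiber_id,
               group = rec$group, rapamycin = rec$rapamycin,
               path = basename(ip), truth_path = basename(gp),
               md5 = unname(tools::md5sum(ip)), stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort manifest and verify checksums
#' @param dir Cohort directory containing `manifest.csv`.
#' @return Manifest data frame with absolute paths.
#' @export
read_manifest <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) abort("no manifest.csv in %s", dir)
  man <- utils::read.csv(mp, stringsAsFactors = FALSE)
  if (nrow(man) == 0L) abort("manifest in %s is empty", dir)
  man$path <- file.path(dir, man$path)
  man$truth_path <- file.path(dir, man$truth_path)
  sums <- unname(tools::md5sum(man$path))
  bad <- which(sums != man$md5)
  if (length(bad))
    abort("checksum mismatch for %s", paste(basename(man$path[bad]), collapse = ", "))
  man
}
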