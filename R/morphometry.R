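# Single-fiber morphometry (sarcomere length from striation periodicity,
# serial sarcomere number) and the accompanying statistical procedures:
# outlier exclusion, relative-to-control normalization, t tests and one-
# and two-way ANOVA with Tukey / Fisher LSD post hocs.

#' Estimate the sarcomere period of an intensity profile
#'
#' Dominant striation period from the first local maximum of the
#' autocorrelation function, refined to sub-pixel precision by parabolic
#' interpolation (sarcomere-length differences of interest are well below
#' one pixel at 0.103 um/px).  Scale-invariant in the profile intensity.
#'
#' @param profile Numeric vector of intensities along the fiber axis.
#' @param pixel_pitch um/px.
#' @param min_period_px Smallest admissible period (default 6 px).
#' @param min_acf Noise floor: the autocorrelation peak must reach this
#'   value (default 0.2) or an error is raised.
#' @return Period, um.
#' @export
estimate_period <- function(profile, pixel_pitch = 0.103, min_period_px = 6L,
                            min_acf = 0.2) {
  n <- length(profile)
  if (n < 4L * min_period_px) abort("profile too short for period estimation")
  if (stats::sd(profile) == 0)
    abort("no periodicity: the intensity profile is flat")
  a <- stats::acf(profile, lag.max = n %/% 2L, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(a) - 1L
  prev <- c(Inf, a[-length(a)]); nxt <- c(a[-1], -Inf)
  loc <- which(a > prev & a >= nxt)  # local maxima
  loc <- loc[lags[loc] >= min_period_px & loc < length(a)]
  loc <- loc[a[loc] >= min_acf]
  if (length(loc) == 0L)
    abort("no periodicity peak above the noise floor (acf >= %g)", min_acf)
  k <- loc[1]
  # parabolic sub-pixel refinement around the peak
  if (k > 1L && k < length(a)) {
    y0 <- a[k - 1]; y1 <- a[k]; y2 <- a[k + 1]
    den <- y0 - 2 * y1 + y2
    d <- if (den < 0) 0.5 * (y0 - y2) / den else 0
  } else d <- 0
  period_px <- lags[k] + d
  if (n < 10 * period_px)
    abort("profile covers fewer than 10 periods (%.1f px each)", period_px)
  period_px * pixel_pitch
}

#' Mean sarcomere length of a fiber from linear segments
#'
#' The per-fiber sarcomere length is the mean of the period estimates
#' from `n_segments` linear intensity profiles (rows of the Z-line
#' channel spread across the fiber width).
#'
#' @param image A `fiber_image` (or a matrix, with `pixel_pitch` given).
#' @param n_segments Number of linear segments (default 3).
#' @param pixel_pitch um/px.
#' @param seed Seed for the segment placement.
#' @return Mean sarcomere length, um.
#' @export
mean_sarcomere_length <- function(image, n_segments = 3L, pixel_pitch = NULL,
                                  seed = 1L) {
  if (inherits(image, "fiber_image")) {
    if (is.null(pixel_pitch)) pixel_pitch <- image$pixel_pitch
    zch <- fiber_channel(image, "zline")
    frows <- which(rowSums(fiber_mask(image)) > 0)
  } else {
    if (is.null(pixel_pitch)) abort("pixel_pitch is required for a plain matrix")
    zch <- image; frows <- seq_len(nrow(zch))
  }
  rows <- with_seed(seed, sample(frows, min(n_segments, length(frows))))
  mean(vapply(rows, function(r) estimate_period(zch[r, ], pixel_pitch),
              numeric(1)))
}

#' Serial sarcomere number
#'
#' The number of in-series sarcomeres per fiber: fiber length divided by
#' mean sarcomere length, kept as an exact (continuous) quotient.
#'
#' @param fiber_length_um Fiber length, um (> 0).
#' @param sarcomere_length_um Mean sarcomere length, um (> 0).
#' @return Unitless quotient.
#' @export
serial_sarcomere_number <- function(fiber_length_um, sarcomere_length_um) {
  if (any(fiber_length_um <= 0) || any(sarcomere_length_um <= 0))
    abort("lengths must be > 0")
  fiber_length_um / sarcomere_length_um
}

#' Exclude outliers beyond three standard deviations
#'
#' Single pass, per group: values strictly more than 3 sample SDs from
#' their group mean are excluded; a value at exactly 3.0 SD is retained.
#' The rule is deliberately not iterated (re-application to the retained
#' values could exclude more).
#'
#' @param values Numeric vector.
#' @param group Optional grouping factor (default: one group).
#' @param n_sd Threshold (default 3).
#' @return List with `values`, `group` (retained) and `excluded`
#'   (data.frame of excluded values with z-scores).
#' @export
exclude_outliers <- function(values, group = NULL, n_sd = 3) {
  if (is.null(group)) group <- rep("all", length(values))
  group <- as.character(group)
  keep <- rep(TRUE, length(values))
  z <- rep(NA_real_, length(values))
  for (g in unique(group)) {
    i <- which(group == g)
    if (length(i) < 3L) next
    s <- stats::sd(values[i])
    if (s == 0) next
    z[i] <- (values[i] - mean(values[i])) / s
    keep[i] <- abs(z[i]) <= n_sd
  }
  list(values = values[keep], group = group[keep],
       excluded = data.frame(value = values[!keep], group = group[!keep],
                             z = z[!keep]))
}

#' Normalize values to the mean of a control group
#'
#' @param values Numeric vector.
#' @param group Grouping vector.
#' @param control Name of the control group.
#' @return `values / mean(values[group == control])`.
#' @export
normalize_to_control <- function(values, group, control) {
  i <- group == control
  if (!any(i)) abort("control group '%s' not found", control)
  m <- mean(values[i])
  if (m == 0) abort("control-group mean is zero; cannot normalize")
  values / m
}

# Fisher LSD pairwise comparisons of factor `fac` within each level of
# `within`, using the residual MSE and df of the fitted full model
.fisher_lsd <- function(data, value, fac, within, mse, df_err) {
  out <- list()
  for (w in unique(data[[within]])) {
    d <- data[data[[within]] == w, ]
    levs <- unique(as.character(d[[fac]]))
    if (length(levs) < 2L) next
    cmb <- utils::combn(levs, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- d[[value]][d[[fac]] == cmb[1, k]]
      b <- d[[value]][d[[fac]] == cmb[2, k]]
      t <- (mean(a) - mean(b)) / sqrt(mse * (1 / length(a) + 1 / length(b)))
      out[[length(out) + 1L]] <- data.frame(
        within = w, contrast = paste(cmb[1, k], "-", cmb[2, k]),
        estimate = mean(a) - mean(b), t = t, df = df_err,
        p = 2 * stats::pt(-abs(t), df_err), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Group comparison with the study's statistical designs
#'
#' Dispatches to Student's t test (`"t"`), paired t test (`"paired_t"`),
#' one-way ANOVA with Tukey HSD post hocs (`"anova1"`), two-way ANOVA
#' with Type-II sums of squares and Fisher-LSD post hocs within each
#' factor (`"anova2"`), or two-way repeated-measures ANOVA with a
#' within-subject factor (`"anova2_rm"`).
#'
#' @param data Data frame.  For `"t"`/`"anova1"`: columns `value`,
#'   `group`.  For `"paired_t"`: columns `value`, `group` (2 levels),
#'   `id` (pair identifier).  For `"anova2"`: `value`, `A`, `B`.  For
#'   `"anova2_rm"`: `value`, `A` (between), `B` (within), `subject`.
#' @param design One of `"t"`, `"paired_t"`, `"anova1"`, `"anova2"`,
#'   `"anova2_rm"`.
#' @return A `test_result`: list with `test`, `statistic`, `df`,
#'   `p_value`, `direction`, and `posthoc`/`table` where applicable.
#' @export
compare_groups <- function(data, design = c("t", "paired_t", "anova1",
                                            "anova2", "anova2_rm")) {
  design <- match.arg(design)
  res <- switch(design,
    t = {
      g <- unique(as.character(data$group))
      if (length(g) != 2L) abort("t test needs exactly 2 groups, got %d", length(g))
      a <- data$value[data$group == g[1]]; b <- data$value[data$group == g[2]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        abort("zero within-group variance; t test undefined")
      tt <- stats::t.test(a, b, var.equal = TRUE)
      list(test = "Student t", statistic = unname(tt$statistic),
           df = unname(tt$parameter), p_value = tt$p.value,
           direction = sign(mean(a) - mean(b)))
    },
    paired_t = {
      g <- unique(as.character(data$group))
      if (length(g) != 2L) abort("paired t test needs exactly 2 groups")
      wide <- merge(data[data$group == g[1], c("id", "value")],
                    data[data$group == g[2], c("id", "value")], by = "id")
      d <- wide$value.x - wide$value.y
      if (stats::sd(d) == 0 && all(d == 0)) {
        list(test = "paired t", statistic = 0, df = length(d) - 1L,
             p_value = 1, direction = 0)
      } else {
        if (stats::sd(d) == 0) abort("zero variance of paired differences")
        tt <- stats::t.test(d)
        list(test = "paired t", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             direction = sign(mean(d)))
      }
    },
    anova1 = {
      data$group <- factor(data$group)
      fit <- stats::aov(value ~ group, data = data)
      s <- summary(fit)[[1]]
      list(test = "one-way ANOVA", statistic = s$`F value`[1],
           df = c(s$Df[1], s$Df[2]), p_value = s$`Pr(>F)`[1],
           direction = NA,
           posthoc = as.data.frame(stats::TukeyHSD(fit)$group))
    },
    anova2 = {
      data$A <- factor(data$A); data$B <- factor(data$B)
      fit <- stats::lm(value ~ A * B, data = data)
      an <- car::Anova(fit, type = 2)
      tab <- data.frame(term = rownames(an), sum_sq = an$`Sum Sq`,
                        df = an$Df, F = an$`F value`, p = an$`Pr(>F)`,
                        stringsAsFactors = FALSE)
      mse <- an$`Sum Sq`[nrow(an)] / an$Df[nrow(an)]
      ph <- rbind(.fisher_lsd(data, "value", "A", "B", mse, an$Df[nrow(an)]),
                  .fisher_lsd(data, "value", "B", "A", mse, an$Df[nrow(an)]))
      list(test = "two-way ANOVA (Type II)",
           statistic = stats::setNames(tab$F[1:3], tab$term[1:3]),
           df = stats::setNames(tab$df, tab$term),
           p_value = stats::setNames(tab$p[1:3], tab$term[1:3]),
           direction = NA, table = tab, posthoc = ph)
    },
    anova2_rm = {
      data$A <- factor(data$A); data$B <- factor(data$B)
      data$subject <- factor(data$subject)
      fit <- stats::aov(value ~ A * B + Error(subject / B), data = data)
      s <- summary(fit)
      flat <- do.call(rbind, lapply(s, function(x) {
        d <- as.data.frame(x[[1]]); d$term <- trimws(rownames(d)); d
      }))
      flat <- flat[!grepl("Residuals", flat$term), ]
      list(test = "two-way RM ANOVA",
           statistic = stats::setNames(flat$`F value`, flat$term),
           df = stats::setNames(flat$Df, flat$term),
           p_value = stats::setNames(flat$`Pr(>F)`, flat$term),
           direction = NA, table = flat)
    })
  structure(res, class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n", x$test))
  st <- x$statistic
  if (length(st) == 1L && is.null(names(st))) {
    cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
                st, paste(x$df, collapse = ", "), x$p_value))
  } else {
    for (nm in names(st))
      cat(sprintf("  %s: F = %.4g, p = %.4g\n", nm, st[[nm]], x$p_value[[nm]]))
  }
  invisible(x)
}
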