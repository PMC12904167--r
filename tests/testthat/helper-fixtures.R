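# Shared fixtures and independent oracles.  Everything is generated in
# code; no stored binary data.

# small, fast imaging spec used across unit tests (noise-free, no blur)
spec_clean <- function(seed = 1L, shape = c(260L, 440L)) {
  image_spec(shape = shape, psf_sigma = 0, noise = list(gaussian_sd = 0,
                                                        poisson_gain = 0),
             seed = seed)
}

# blurred + noisy spec at a chosen SNR (peak-above-background / noise SD)
# for the default hotspot fold of 3 over background 100: peak excess 200
spec_noisy <- function(seed = 1L, shape = c(260L, 440L), snr = 5,
                       psf_sigma = 0.2) {
  image_spec(shape = shape, psf_sigma = psf_sigma,
             noise = list(gaussian_sd = 200 / snr, poisson_gain = 0),
             seed = seed)
}

# independent period oracle: dominant non-DC frequency of the FFT
fft_period_px <- function(profile) {
  n <- length(profile)
  sp <- Mod(stats::fft(profile - mean(profile)))[2:(n %/% 2)]
  n / which.max(sp)
}

# independent two-way ANOVA oracle: explicit projection-matrix sums of
# squares (Type II for the main effects, interaction from the full fit),
# written against model matrices built by hand -- no lm/aov/car anywhere.
anova2_oracle <- function(value, A, B) {
  A <- factor(A); B <- factor(B)
  one <- matrix(1, length(value), 1)
  XA <- stats::model.matrix(~ A)[, -1, drop = FALSE]
  XB <- stats::model.matrix(~ B)[, -1, drop = FALSE]
  XAB <- stats::model.matrix(~ A:B)[, -1, drop = FALSE]
  rss <- function(X) {
    # residual sum of squares after projecting onto col space of X
    # (keep only the rank-many Q columns: X may be rank-deficient)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    r <- value - Q %*% crossprod(Q, value)
    sum(r^2)
  }
  r_full <- rss(cbind(one, XA, XB, XAB))
  r_ab <- rss(cbind(one, XA, XB))
  r_a <- rss(cbind(one, XA))
  r_b <- rss(cbind(one, XB))
  ss_A <- r_b - r_ab    # A after B (Type II)
  ss_B <- r_a - r_ab    # B after A
  ss_AB <- r_ab - r_full
  df_A <- nlevels(A) - 1L; df_B <- nlevels(B) - 1L
  df_AB <- df_A * df_B
  df_err <- length(value) - nlevels(A) * nlevels(B)
  mse <- r_full / df_err
  c(F_A = (ss_A / df_A) / mse,
    F_B = (ss_B / df_B) / mse,
    F_AB = (ss_AB / df_AB) / mse)
}

# render a fiber with one planted hotspot per class, anchors spaced to
# avoid contact; returns list(image, ground_truth) after degradation
render_five_classes <- function(spec, fiber = fiber_model()) {
  hs <- list(hotspot_spec("yu", 3),
             hotspot_spec("rodier", 8, 0.35),
             hotspot_spec("hzone", 13, 0.6),
             hotspot_spec("short_atypical", 18, 0.4),
             hotspot_spec("long_atypical", 23, 0.55))
  r <- render_fiber(spec, fiber, hotspots = hs)
  list(image = add_noise(r$image, spec), ground_truth = r$ground_truth,
       classes = vapply(hs, function(h) h$model_class, ""))
}

# match detected qualifying hotspots to planted ones by centroid distance
match_hotspots <- function(hotspot_set, gt, max_dist_px = 8) {
  ht <- hotspot_set$table[hotspot_set$table$qualifies, , drop = FALSE]
  planted <- gt$hotspots
  if (is.null(planted) || nrow(planted) == 0L)
    return(list(recalled = logical(0), spurious = nrow(ht)))
  hit <- rep(FALSE, nrow(planted))
  spurious <- 0L
  for (i in seq_len(nrow(ht))) {
    d <- sqrt((ht$centroid_row[i] - planted$centroid_row)^2 +
              (ht$centroid_col[i] - planted$centroid_col)^2)
    j <- which.min(d)
    if (d[j] <= max_dist_px) hit[j] <- TRUE else spurious <- spurious + 1L
  }
  list(recalled = hit, spurious = spurious)
}
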