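# Sarcomere-period estimation, serial sarcomere number, outlier rule,
# control normalization and the statistical designs.

test_that("the striation period is recovered to 0.02 um and is scale-free", {
  r <- render_fiber(spec_clean(5, shape = c(260L, 600L)), fiber_model())
  prof <- fiber_channel(r$image, "zline")[130, ]
  expect_equal(estimate_period(prof), 2.4, tolerance = 0.02 / 2.4)
  expect_equal(estimate_period(prof * 37 + 11), estimate_period(prof))
  expect_equal(estimate_period(prof), 0.103 * fft_period_px(prof),
               tolerance = 0.01)
  expect_error(estimate_period(rep(3, 600)), "flat")
  expect_error(estimate_period(rnorm(600)), "noise floor|periods")
  # mean over segments on a degraded image
  sp <- spec_noisy(5, shape = c(260L, 600L), snr = 10)
  img <- add_noise(r$image, sp)
  expect_equal(mean_sarcomere_length(img, seed = 2), 2.4,
               tolerance = 0.02 / 2.4)
})

test_that("serial sarcomere number is an exact, homogeneous quotient", {
  expect_identical(serial_sarcomere_number(2500, 2.5), 1000)
  expect_equal(serial_sarcomere_number(7 * 2500, 7 * 2.5), 1000)
  expect_error(serial_sarcomere_number(-1, 2.5), "> 0")
  expect_error(serial_sarcomere_number(2500, 0), "> 0")
})

test_that("the 3-SD outlier rule is single-pass, strict, and exact at its boundary", {
  o <- exclude_outliers(rep(5, 10))
  expect_equal(length(o$values), 10L)
  # z of the extreme value is 2.846 < 3: retained
  o <- exclude_outliers(c(rep(0, 9), 100))
  expect_equal(length(o$values), 10L)
  expect_equal(nrow(o$excluded), 0L)
  # c(rep(0, 17), 1, -1) puts the extremes at exactly 3.0 SD: retained
  v3 <- c(rep(0, 17), 1, -1)
  expect_equal(max(abs(scale(v3))), 3)
  expect_equal(length(exclude_outliers(v3)$values), 19L)
  # one more zero pushes them past 3 SD: both excluded, z-scores logged
  v4 <- c(rep(0, 18), 1, -1)
  o4 <- exclude_outliers(v4)
  expect_equal(length(o4$values), 18L)
  expect_equal(sort(o4$excluded$value), c(-1, 1))
  expect_true(all(abs(o4$excluded$z) > 3))
  # per-group application
  og <- exclude_outliers(c(v4, rep(5, 4)), c(rep("a", 20), rep("b", 4)))
  expect_equal(sum(og$group == "b"), 4L)
})

test_that("control normalization is exact and unit-invariant", {
  v <- c(2, 2, 3); g <- c("ctl", "ctl", "trt")
  expect_equal(normalize_to_control(v, g, "ctl"), c(1, 1, 1.5))
  expect_equal(mean(normalize_to_control(v, g, "ctl")[g == "ctl"]), 1)
  expect_equal(normalize_to_control(v * 1000, g, "ctl"),
               normalize_to_control(v, g, "ctl"))
  expect_error(normalize_to_control(c(0, 0, 1), g, "ctl"), "zero")
  expect_error(normalize_to_control(v, g, "nope"), "not found")
})

test_that("degenerate t-test inputs behave as documented", {
  d <- data.frame(value = c(1, 2, 3, 1, 2, 3), group = rep(c("a", "b"), each = 3))
  tt <- compare_groups(d, "t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  dz <- data.frame(value = rep(1, 6), group = rep(c("a", "b"), each = 3))
  expect_error(compare_groups(dz, "t"), "zero within-group variance")
  dp <- data.frame(value = c(2, 0, 1, 1), group = rep(c("x", "y"), each = 2),
                   id = c(1, 2, 1, 2))  # paired differences {1, -1}
  pt <- compare_groups(dp, "paired_t")
  expect_equal(pt$statistic, 0)
  expect_equal(pt$p_value, 1)
})

test_that("two-way ANOVA F statistics match the projection-matrix oracle", {
  set.seed(42)
  for (rep in 1:8) {
    balanced <- rep %% 2 == 0
    nA <- sample(2:3, 1); nB <- sample(2:3, 1)
    n_cell <- if (balanced) sample(3:6, 1) else NA
    rows <- do.call(rbind, lapply(seq_len(nA), function(a)
      do.call(rbind, lapply(seq_len(nB), function(b) {
        n <- if (balanced) n_cell else sample(3:7, 1)
        data.frame(value = rnorm(n, mean = a + 0.5 * b + 0.2 * a * b),
                   A = letters[a], B = LETTERS[b])
      }))))
    res <- compare_groups(rows, "anova2")
    oracle <- anova2_oracle(rows$value, rows$A, rows$B)
    expect_equal(unname(res$statistic[c("A", "B", "A:B")]),
                 unname(oracle), tolerance = 1e-8)
  }
})

test_that("balanced two-way sums of squares decompose the total exactly", {
  set.seed(7)
  d <- data.frame(value = rnorm(36), A = rep(c("a", "b"), each = 18),
                  B = rep(rep(c("x", "y", "z"), each = 6), 2))
  res <- compare_groups(d, "anova2")
  ss <- res$table$sum_sq
  expect_equal(sum(ss), sum((d$value - mean(d$value))^2), tolerance = 1e-10)
})

test_that("one-way ANOVA carries Tukey post hocs; two-way carries Fisher LSD", {
  set.seed(3)
  d1 <- data.frame(value = rnorm(30, rep(c(0, 0, 2), each = 10)),
                   group = rep(letters[1:3], each = 10))
  r1 <- compare_groups(d1, "anova1")
  expect_equal(nrow(r1$posthoc), 3L)
  expect_true(all(c("diff", "p adj") %in% colnames(r1$posthoc)))
  d2 <- data.frame(value = rnorm(24), A = rep(c("s", "m"), each = 12),
                   B = rep(rep(c("v", "r"), each = 6), 2))
  r2 <- compare_groups(d2, "anova2")
  expect_equal(nrow(r2$posthoc), 4L)  # A within each B, B within each A
  expect_true(all(r2$posthoc$df == 20))
  d3 <- data.frame(value = rnorm(24), A = rep(c("s", "m"), each = 12),
                   B = rep(c("v", "r"), 12), subject = rep(1:12, each = 2))
  r3 <- compare_groups(d3, "anova2_rm")
  expect_equal(sort(names(r3$statistic)), sort(c("A", "B", "A:B")))
})

test_that("the full generator-to-t-test pipeline keeps nominal type-I error", {
  p <- single_fiber_params(mov_effect = 1, n = 10L)[1:2, ]  # null: no effect
  set.seed(11)
  seeds <- sample.int(1e6, 400)
  rej <- vapply(seeds, function(s) {
    tab <- simulate_single_fiber_table(p, seed = s)
    tab$n_sarc <- serial_sarcomere_number(tab$fiber_length_um,
                                          tab$sarcomere_length_um)
    kept <- exclude_outliers(tab$n_sarc, tab$group)
    tt <- compare_groups(data.frame(value = kept$values, group = kept$group), "t")
    tt$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
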