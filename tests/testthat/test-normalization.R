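test_that("well aggregation is the arithmetic per-channel field mean", {
  f <- data.frame(plate_id = "p", well_id = "A01", field = 1:6,
                  neurite_length = c(0, 0, 0, 0, 0, 60),
                  cell_body_area = 10, marker_intensity = 2,
                  reporter_intensity = 5)
  w <- aggregate_wells(f)
  expect_equal(w$neurite_length, 10)
  expect_equal(w$n_fields, 6)

  set.seed(5)
  f2 <- data.frame(plate_id = "p", well_id = rep(c("A01", "B02"), each = 4),
                   neurite_length = runif(8), cell_body_area = runif(8),
                   marker_intensity = runif(8), reporter_intensity = runif(8))
  w2 <- aggregate_wells(f2)
  # independent summation oracle
  expect_equal(w2$cell_body_area[1], sum(f2$cell_body_area[1:4]) / 4, tolerance = 1e-12)
  expect_equal(w2$reporter_intensity[2], sum(f2$reporter_intensity[5:8]) / 4,
               tolerance = 1e-12)
  expect_error(aggregate_wells(f[0, ]), "at least one")
})

test_that("percent transformation anchors controls at 100 and 0", {
  expect_equal(to_percent(80, 80, 20), 100)
  expect_equal(to_percent(20, 80, 20), 0)
  expect_equal(to_percent(50, 80, 20), 50)
  expect_equal(to_percent(110, 80, 20), 150)  # not clipped
  expect_error(to_percent(1, 5, 5), "degenerate")
})

test_that("control regression matches the closed-form OLS oracle", {
  x <- c(0, 1, 2, 3)
  expect_equal(fit_control_regression(x, 2 * x + 1), c(m = 2, b = 1))
  expect_equal(fit_control_regression(c(0, 1, 0.5), c(0, 1, 0.5)), c(m = 1, b = 0))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(20, 100, 15); y <- 0.7 * x + rnorm(20, 30, 3)
    fit <- fit_control_regression(x, y)
    m_or <- cov(x, y) / var(x)          # closed-form covariance/variance oracle
    expect_equal(unname(fit["m"]), m_or, tolerance = 1e-9)
    expect_equal(unname(fit["b"]), mean(y) - m_or * mean(x), tolerance = 1e-9)
  }
  expect_error(fit_control_regression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_control_regression(1:2, 1:2), ">= 3")
})

test_that("regression deviation equals the stated formula and the distance oracle", {
  expect_equal(regression_deviation(3, 2 * 3 + 1, 2, 1), 0)
  expect_equal(regression_deviation(50, 10, 0, 0), -10)
  expect_equal(regression_deviation(0, 1, 1, 0), -0.70710678, tolerance = 1e-8)

  # |d| is the minimal Euclidean distance to the line (brute-force oracle),
  # and d > 0 exactly when the point lies below the line
  brute_dist <- function(x, y, m, b) {
    xs <- seq(x - 50, x + 50, length.out = 200001)
    min(sqrt((xs - x)^2 + (m * xs + b - y)^2))
  }
  set.seed(7)
  for (i in 1:25) {
    m <- rnorm(1); b <- rnorm(1, 0, 10); x <- rnorm(1, 0, 10); y <- rnorm(1, 0, 10)
    d <- regression_deviation(x, y, m, b)
    expect_equal(abs(d), brute_dist(x, y, m, b), tolerance = 1e-6)
    expect_equal(d > 0, y < m * x + b)
  }
  expect_error(regression_deviation(Inf, 0, 1, 0), "non-finite")
})

test_that("positive-control standardized deviations have mean 0 and SD 1 per plate", {
  scr <- generate_screen(full_config(null_targets(30), noise_cv = 0.05, seed = 2))
  w <- aggregate_wells(scr$fields)
  sw <- score_wells(w)
  for (p in unique(sw$plate_id)) {
    for (m in c("differentiation", "outgrowth")) {
      s <- sw$score[sw$plate_id == p & sw$measure == m &
                      sw$role == "positive_control"]
      expect_equal(mean(s), 0, tolerance = 1e-9)
      expect_equal(sd(s), 1, tolerance = 1e-9)
    }
    g <- sw$score[sw$plate_id == p & sw$measure == "growth" &
                    sw$role == "positive_control"]
    expect_equal(mean(g), 0, tolerance = 1e-9)
    expect_equal(sd(g), 1, tolerance = 1e-9)
  }
})

test_that("growth score is the percent-scale z-score against positive controls", {
  st <- data.frame(pos_mean_reporter = 1000, neg_mean_reporter = 300,
                   mean_reporter_pct = 100, sd_reporter_pct = 10)
  expect_equal(growth_score(1000, st), 0)
  # control mean 100%, SD 10%, well at 70% -> -3
  expect_equal(growth_score(300 + 0.70 * 700, st), -3)
  scr <- generate_screen(full_config(null_targets(10), noise_cv = 0.04, seed = 6))
  w <- aggregate_wells(scr$fields)
  stats <- plate_control_stats(w)
  p1 <- stats[1, ]
  wp <- w[w$plate_id == p1$plate_id & w$role == "treatment", ]
  pct <- 100 * (wp$reporter_intensity - p1$neg_mean_reporter) /
    (p1$pos_mean_reporter - p1$neg_mean_reporter)
  expect_equal(growth_score(wp$reporter_intensity, p1),
               (pct - p1$mean_reporter_pct) / p1$sd_reporter_pct, tolerance = 1e-9)
  st0 <- st; st0$sd_reporter_pct <- 0
  expect_error(growth_score(1000, st0), "degenerate")
})

test_that("zero-noise injected effects are recovered exactly through the chain", {
  tg <- screen_targets(c("og", "pr", "df"),
                       class = c("outgrowth", "proliferation", "differentiation"),
                       size = c(-5, -4, 2))
  scr <- generate_screen(full_config(tg, noise_cv = 0))
  ps <- phenotype_scores(aggregate_wells(scr$fields))
  at_max <- ps[ps$dose == 4, ]
  get <- function(g, m) at_max$mean[at_max$gene == g & at_max$measure == m]
  expect_equal(get("og", "outgrowth"), -5, tolerance = 1e-6)
  expect_equal(get("pr", "growth"), -4, tolerance = 1e-6)
  expect_equal(get("df", "differentiation"), 2, tolerance = 1e-6)
  expect_lt(max(abs(at_max$sem)), 1e-9)
})

test_that("a pure proliferation effect leaves differentiation and outgrowth at zero", {
  tg <- screen_targets("prolif", class = "proliferation", size = -5)
  scr <- generate_screen(full_config(tg, noise_cv = 0))
  ps <- phenotype_scores(aggregate_wells(scr$fields))
  dec <- ps[ps$gene == "prolif" & ps$measure != "growth", ]
  expect_lt(max(abs(dec$mean)), 1e-9)
  gro <- ps[ps$gene == "prolif" & ps$measure == "growth" & ps$dose == 4, ]
  expect_equal(gro$mean, -5, tolerance = 1e-6)
})

test_that("replicate combination reports mean and SEM = SD/sqrt(n)", {
  scr <- generate_screen(full_config(null_targets(6), noise_cv = 0.05, seed = 8))
  ps <- phenotype_scores(aggregate_wells(scr$fields), audit = TRUE)
  reps <- lapply(strsplit(ps$replicate_scores, ","), as.numeric)
  expect_equal(ps$n, lengths(reps))
  expect_equal(ps$mean, vapply(reps, mean, numeric(1)), tolerance = 1e-6)
  expect_equal(ps$sem, vapply(reps, function(r) sd(r) / sqrt(length(r)), numeric(1)),
               tolerance = 1e-6)
  # the worked arithmetic: replicates {-4, -3.5, -4.5}
  expect_equal(sd(c(-4, -3.5, -4.5)) / sqrt(3), 0.28867513, tolerance = 1e-7)
})

test_that("per-field scoring mode agrees with per-well scoring on average", {
  tg <- screen_targets("og", class = "outgrowth", size = -5)
  cfg <- full_config(tg, noise_cv = 0.02, seed = 4)
  scr <- generate_screen(cfg)
  w <- aggregate_wells(scr$fields)
  pw <- phenotype_scores(w, measures = "outgrowth")
  pf <- phenotype_scores(w, measures = "outgrowth", per_field = TRUE,
                         fields = scr$fields)
  expect_equal(pf$mean[pf$dose == 4], pw$mean[pw$dose == 4], tolerance = 0.2)
})
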