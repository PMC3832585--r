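test_that("identical config and seed reproduce the screen bit-identically", {
  tg <- screen_targets(c("a", "b"), class = c("outgrowth", "null"), size = c(-4, 0))
  cfg <- full_config(tg, noise_cv = 0.05, seed = 42)
  s1 <- generate_screen(cfg)
  s2 <- generate_screen(cfg)
  expect_identical(s1$fields, s2$fields)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_screen(full_config(tg, noise_cv = 0.05, seed = 43))
  expect_false(identical(s1$fields, s3$fields))
})

test_that("all-null, zero-noise treatment wells sit exactly at the positive-control mean", {
  scr <- generate_screen(tiny_config(null_targets(5)))
  w <- aggregate_wells(scr$fields)
  chans <- c("neurite_length", "cell_body_area", "marker_intensity",
             "reporter_intensity")
  for (p in unique(w$plate_id)) {
    wp <- w[w$plate_id == p, ]
    pos_mean <- colMeans(wp[wp$role == "positive_control", chans])
    tr <- wp[wp$role == "treatment", chans]
    for (ch in chans)
      expect_equal(tr[[ch]], rep(unname(pos_mean[ch]), nrow(tr)), tolerance = 1e-12)
  }
})

test_that("ground truth carries injected shifts and zeros for null genes", {
  tg <- screen_targets(c("up", "dn", "nil"),
                       class = c("outgrowth", "proliferation", "null"),
                       size = c(3, -2, 0))
  scr <- generate_screen(full_config(tg, noise_cv = 0))
  tru <- scr$truth
  nil <- tru[tru$gene == "nil", ]
  expect_true(all(nil$true_growth == 0 & nil$true_differentiation == 0 &
                    nil$true_outgrowth == 0))
  # linear dose response relative to the maximal dose
  up <- tru[tru$gene == "up", ]
  expect_equal(up$true_outgrowth, 3 * up$dose / 4)
  dn <- tru[tru$gene == "dn", ]
  expect_equal(dn$true_growth, -2 * dn$dose / 4)
})

test_that("every plate carries the configured control wells", {
  scr <- generate_screen(full_config(null_targets(400), noise_cv = 0, doses = 4))
  w <- aggregate_wells(scr$fields)
  tab <- table(w$plate_id, w$role)
  expect_true(all(tab[, "positive_control"] == 20))
  expect_true(all(tab[, "negative_control"] == 20))
  # 400 series at one dose spill over into a second plate block per replicate
  expect_equal(length(unique(w$plate_id)), 6)
})

test_that("invalid configurations fail naming the offending field", {
  tg <- null_targets(3)
  expect_error(screen_config(tg, doses = c(2, 1)), "doses")
  expect_error(screen_config(tg, doses = c(-1, 2)), "doses")
  expect_error(screen_config(tg, n_replicate_plates = 0), "n_replicate_plates")
  expect_error(screen_config(tg, noise_cv = 2), "noise_cv")
  expect_error(screen_config(tg, n_pos_controls = 10), "n_pos_controls")
  expect_error(screen_config(tg, control_scatter = list(growth = 0.1)),
               "control_scatter")
  expect_error(screen_targets("a", class = "mitosis"), "class")
  expect_error(screen_targets("a", size = Inf), "size")
  expect_error(screen_targets(c("a", "a")), "duplicated")
})

test_that("config YAML round-trips through read/write", {
  tg <- screen_targets(c("g1", "g2"), class = c("outgrowth", "null"), size = c(-5, 0))
  cfg <- full_config(tg, noise_cv = 0.03, seed = 9)
  path <- withr::local_tempfile(fileext = ".yml")
  write_screen_config(cfg, path)
  cfg2 <- read_screen_config(path)
  expect_true(isTRUE(all.equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)))
  expect_identical(generate_screen(cfg2)$fields, generate_screen(cfg)$fields)
})

test_that("field image generator: empty field is pure background", {
  fi <- generate_field_images(list(), dim = c(64, 64), background = 80)
  for (ch in fi$images) expect_true(all(ch == 80))
  expect_equal(unname(fi$truth$total_intensity["marker"]), 0)
})

test_that("field image truth records drawn geometry by construction", {
  fi <- disc_and_line_field(radius = 10, line_len = 100)
  # soma area is reported by the rasterizer itself
  expect_equal(fi$truth$soma_area, sum((outer((1:256 - 60)^2, (1:256 - 60)^2, "+")) <= 100))
  expect_equal(fi$truth$neurite_length, 100)
  # straight diagonal polyline has exact Euclidean truth
  expect_equal(polyline_length(rbind(c(10, 50), c(110, 50))), 100)
  expect_equal(polyline_length(rbind(c(0, 0), c(3, 4))), 5)
})

test_that("out-of-bounds geometry is rejected with the offending cell", {
  cells <- list(field_cell(c(32, 32), 5),
                field_cell(c(60, 60), 10, list(cbind(60, 55:70))))
  expect_error(generate_field_images(cells, dim = c(64, 64)), "cell\\(s\\) 2")
  expect_error(generate_field_images(list(field_cell(c(3, 3), 5)), dim = c(64, 64)),
               "out of image bounds")
})

test_that("TIFF round-trip preserves counts and the truth sidecar", {
  fi <- generate_field_images(
    list(field_cell(c(40, 20), 6, list(cbind(20, 30:70)))), dim = c(96, 96))
  dir <- withr::local_tempdir()
  paths <- write_field_images(fi, dir, prefix = "f1")
  img <- read_field_image(file.path(dir, "f1_marker.tif"))
  expect_equal(img, round(fi$images$marker), ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "f1_truth.json"), simplifyVector = TRUE)
  expect_equal(truth$neurite_length, fi$truth$neurite_length)
})
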