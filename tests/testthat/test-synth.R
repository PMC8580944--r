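test_that("dataset generation is byte-reproducible and complete", {
  d1 <- file.path(tempdir(), "synth1"); d2 <- file.path(tempdir(), "synth2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- phantomConfigDesk(seed = 21L)
  m1 <- generateDataset(10, cfg, d1)
  m2 <- generateDataset(10, cfg, d2)
  expect_equal(m1, m2)
  expect_length(list.files(d1, pattern = "^\\d+_HC\\.png$"), 10)
  expect_length(list.files(d1, pattern = "_Annotation\\.png$"), 10)
  expect_identical(readBin(file.path(d1, "004_HC.png"), "raw", 1e6),
                   readBin(file.path(d2, "004_HC.png"), "raw", 1e6))
  csv <- read.csv(file.path(d1, "training_set_pixel_size_and_HC.csv"),
                  check.names = FALSE)
  expect_equal(nrow(csv), 10)
  coco <- jsonlite::read_json(file.path(d1, "annotations_coco.json"))
  expect_length(coco$annotations, 10)
  expect_length(coco$images, 10)
  # manifest invariant: HC = Ramanujan perimeter x pixel size
  for (i in 1:10) {
    e <- ellipse(m1$cx[i], m1$cy[i], m1$a[i], m1$b[i], m1$theta[i])
    expect_equal(m1$hcMm[i], ellipsePerimeter(e) * m1$mmPerPx[i],
                 tolerance = 1e-9)
  }
})

test_that("reading a generated dataset reproduces the manifest", {
  d <- file.path(tempdir(), "synth_rt"); unlink(d, recursive = TRUE)
  cfg <- phantomConfigDesk(seed = 33L)
  man <- generateDataset(6, cfg, d)
  samples <- readHC18Dataset(d, fieldConfig(cfg@fieldR))
  expect_length(samples, 6)
  for (s in samples) {
    i <- match(s$filename, man$filename)
    expect_equal(s$mmPerPx, man$mmPerPx[i], tolerance = 1e-6)
    expect_equal(s$hcMm, man$hcMm[i], tolerance = 1e-4)
    # annotation round trip: skeleton fit within 2 px / 2 deg of the manifest
    expect_lt(max(abs(c(s$gtEllipse@cx - man$cx[i], s$gtEllipse@cy - man$cy[i],
                        s$gtEllipse@a - man$a[i], s$gtEllipse@b - man$b[i]))), 2)
    dth <- abs(s$gtEllipse@theta - man$theta[i]); dth <- min(dth, pi - dth)
    expect_lt(dth * 180 / pi, 2)
    expect_gt(min(s$field[s$skeleton == 1L]), 0.999)
  }
})

test_that("orphan images are skipped with a warning", {
  d <- file.path(tempdir(), "synth_orphan"); unlink(d, recursive = TRUE)
  generateDataset(2, phantomConfigDesk(seed = 5L), d)
  file.remove(file.path(d, "002_HC_Annotation.png"))
  expect_warning(s <- readHC18Dataset(d, fieldConfig(24)), "skipping")
  expect_length(s, 1)
})

test_that("drawn phantom parameters follow their configured distributions", {
  cfg <- phantomConfigDesk(seed = 77L)
  set.seed(cfg@seed)
  draws <- replicate(200, samplePhantomParams(cfg), simplify = FALSE)
  a <- sapply(draws, function(p) p$ellipse@a)
  ratio <- sapply(draws, function(p) p$ellipse@b) / a
  th <- sapply(draws, function(p) p$ellipse@theta)
  mm <- sapply(draws, function(p) p$mmPerPx)
  expect_gt(ks.test(a, "punif", cfg@aRange[1], cfg@aRange[2])$p.value, 0.01)
  expect_gt(ks.test(ratio, "punif", cfg@axisRatioRange[1],
                    cfg@axisRatioRange[2])$p.value, 0.01)
  expect_gt(ks.test(th, "punif", 0, pi)$p.value, 0.01)
  expect_gt(ks.test(mm, "punif", cfg@mmPerPxRange[1],
                    cfg@mmPerPxRange[2])$p.value, 0.01)
  expect_true(all(mm >= 0.052 & mm <= 0.326))
  # pixel size anticorrelates with head size (sonographer emulation)
  expect_lt(cor(a, mm), -0.4)
  # containment margin: head plus field support fits inside the canvas
  for (p in draws) {
    e <- p$ellipse
    m <- p$acoustic$thickness + cfg@fieldR / 2
    ex <- sqrt(e@a^2 * cos(e@theta)^2 + e@b^2 * sin(e@theta)^2)
    ey <- sqrt(e@a^2 * sin(e@theta)^2 + e@b^2 * cos(e@theta)^2)
    expect_true(e@cx - ex - m >= 0 && e@cx + ex + m <= cfg@imageSize - 1)
    expect_true(e@cy - ey - m >= 0 && e@cy + ey + m <= cfg@imageSize - 1)
  }
})

test_that("rendering honours the drawn contrast and unit-mean speckle", {
  cfg <- phantomConfigDesk(seed = 3L, speckleShape = 0, shadowProbability = 0)
  set.seed(3); p <- samplePhantomParams(cfg)
  img <- renderPhantom(p, cfg)
  pts <- ellipsePoints(p$ellipse, 300)
  onContour <- img[cbind(round(pts[, "y"]) + 1, round(pts[, "x"]) + 1)]
  # background sampled away from the band
  far <- ellipsePoints(p$ellipse, 300)
  allp <- ellipsePoints(p$ellipse, 2000)
  g <- expand.grid(r = 1:128, c = 1:128)
  dmin <- fetalHC:::cpp_min_dist_points(g$c - 1, g$r - 1,
                                        allp[, "x"], allp[, "y"])
  bg <- img[as.matrix(g[dmin > 4 * p$acoustic$thickness, c("r", "c")])]
  expect_equal(mean(onContour) - mean(bg), p$acoustic$contrast,
               tolerance = 0.02 * p$acoustic$contrast / p$acoustic$contrast)
  # unit-mean speckle preserves the image mean within 2% at 512^2
  cfgBig <- phantomConfig(seed = 9L, shadowProbability = 0)
  set.seed(9); pb <- samplePhantomParams(cfgBig)
  set.seed(101); withSpeckle <- renderPhantom(pb, cfgBig)
  cfgNo <- phantomConfig(seed = 9L, shadowProbability = 0, speckleShape = 0)
  set.seed(101); noSpeckle <- renderPhantom(pb, cfgNo)
  expect_lt(abs(mean(withSpeckle) - mean(noSpeckle)) / mean(noSpeckle), 0.02)
  # determinism
  set.seed(55); i1 <- renderPhantom(p, cfg)
  set.seed(55); i2 <- renderPhantom(p, cfg)
  expect_identical(i1, i2)
})

test_that("submission CSV carries mm-scaled canonical parameters", {
  ms <- list(
    "001_HC.png" = hcMeasurement(ellipse(60, 50, 30, 20, 0.7), 0.1),
    "002_HC.png" = hcMeasurement(ellipse(70, 55, 25, 24, 2.1), 0.2),
    "003_HC.png" = fetalHC:::noMeasurement("no-head", 0.1))
  path <- tempfile(fileext = ".csv")
  writeSubmissionCsv(ms, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 3)
  expect_equal(names(df), c("filename", "center_x_mm", "center_y_mm",
                            "semi_axes_a_mm", "semi_axes_b_mm", "angle_rad",
                            "status"))
  ok <- df$status == "ok"
  expect_true(all(df$semi_axes_a_mm[ok] >= df$semi_axes_b_mm[ok]))
  expect_true(all(df$angle_rad[ok] >= 0 & df$angle_rad[ok] < pi))
  expect_equal(df$center_x_mm[1], 6)
  expect_true(is.na(df$center_x_mm[3]))
  expect_error(writeSubmissionCsv(ms[c(1, 1)], tempfile()),
               class = "fhcBadInput")
})
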