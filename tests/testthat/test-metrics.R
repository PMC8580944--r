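test_that("DF is signed prediction minus reference, ADF its magnitude", {
  expect_equal(unname(metricDfAdf(99, 100)), c(-1, 1))
  expect_equal(unname(metricDfAdf(100, 100)), c(0, 0))
  d1 <- metricDfAdf(97, 103); d2 <- metricDfAdf(103, 97)
  expect_equal(d1[["df"]], -d2[["df"]])
  expect_equal(d1[["adf"]], d2[["adf"]])
})

test_that("Dice coefficient matches analytic overlaps", {
  e <- ellipse(60, 50, 30, 20, 0.7)
  expect_equal(metricDsc(e, e, c(128, 128)), 1.0)
  expect_equal(metricDsc(ellipse(30, 30, 10, 8, 0), ellipse(90, 90, 10, 8, 0),
                         c(128, 128)), 0.0)
  # half-overlapping 10x10 squares via the mask variant: 2*50/200 = 0.5
  a <- matrix(FALSE, 40, 40); a[11:20, 11:20] <- TRUE
  b <- matrix(FALSE, 40, 40); b[11:20, 16:25] <- TRUE
  expect_equal(metricDscMasks(a, b), 0.5)
  expect_error(metricDscMasks(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)),
               class = "fhcEmptyMask")
})

test_that("Hausdorff distance matches concentric-circle geometry and is symmetric", {
  c10 <- ellipse(50, 50, 10, 10, 0)
  c12 <- ellipse(50, 50, 12, 12, 0)
  expect_equal(metricHd(c10, c10, 0.1), 0)
  hd <- metricHd(c10, c12, 0.1)
  expect_equal(hd, 0.2, tolerance = 0.01)   # sampling tolerance
  expect_equal(metricHd(c12, c10, 0.1), hd)
  # sampling density stability: 10x denser changes the value by < 1%
  e1 <- ellipse(100, 90, 60, 40, 0.3); e2 <- ellipse(104, 92, 57, 42, 0.5)
  h1 <- metricHd(e1, e2, 1, n = 3600L)
  h2 <- metricHd(e1, e2, 1, n = 36000L)
  expect_lt(abs(h1 - h2) / h2, 0.01)
})

test_that("metrics are invariant to a joint rigid transform of both ellipses", {
  e1 <- ellipse(100, 90, 60, 40, 0.3); e2 <- ellipse(104, 92, 57, 42, 0.5)
  move <- function(e, dx, dy, phi)
    ellipse(e@cx * cos(phi) - e@cy * sin(phi) + dx,
            e@cx * sin(phi) + e@cy * cos(phi) + dy, e@a, e@b, e@theta + phi)
  h0 <- metricHd(e1, e2, 1)
  h1 <- metricHd(move(e1, 30, -20, 0.8), move(e2, 30, -20, 0.8), 1)
  expect_equal(h0, h1, tolerance = 1e-3)
  d0 <- metricDsc(e1, e2, c(256, 256))
  d1 <- metricDsc(move(e1, 20, 15, 0.4), move(e2, 20, 15, 0.4), c(256, 256))
  expect_equal(d0, d1, tolerance = 0.01)  # rasterization tolerance
})

test_that("dataset evaluation aggregates per-image metrics and counts failures", {
  mk <- function(e, mm) hcMeasurement(e, mm)
  gt <- list(
    a = list(measurement = mk(ellipse(60, 50, 30, 20, 0), 0.1), shape = c(128, 128)),
    b = list(measurement = mk(ellipse(70, 60, 25, 22, 1), 0.1), shape = c(128, 128)),
    c = list(measurement = mk(ellipse(50, 70, 28, 18, 2), 0.1), shape = c(128, 128)))
  # perfect predictions
  perfect <- lapply(gt, function(g) g$measurement)
  ev <- evaluateDataset(perfect, gt)
  expect_equal(unname(ev$summary[, "mean"]), c(0, 0, 0, 1))
  expect_equal(unname(ev$summary[, "sd"]), c(0, 0, 0, 0))
  expect_equal(ev$nFailed, 0)
  # hand-computed mean ADF on perturbed predictions
  pred <- list(a = mk(ellipse(60, 50, 31, 20, 0), 0.1),
               b = mk(ellipse(70, 60, 25, 23, 1), 0.1),
               c = gt$c$measurement)
  ev2 <- evaluateDataset(pred, gt)
  adfs <- sapply(c("a", "b", "c"), function(k)
    metricDfAdf(pred[[k]], gt[[k]]$measurement)[["adf"]])
  expect_equal(ev2$summary["adf", "mean"], mean(adfs))
  # failure records are excluded from aggregates but counted
  pred$b <- fetalHC:::noMeasurement("no-head", 0.1)
  ev3 <- evaluateDataset(pred, gt)
  expect_equal(ev3$nFailed, 1)
  expect_equal(ev3$summary["adf", "mean"], mean(adfs[c("a", "c")]))
  expect_error(evaluateDataset(pred[c("a", "b")], gt), class = "fhcBadInput")
})

test_that("single-image aggregate has zero sd", {
  g <- list(x = list(measurement = hcMeasurement(ellipse(60, 50, 30, 20, 0), 0.1),
                     shape = c(128, 128)))
  ev <- evaluateDataset(list(x = g$x$measurement), g)
  expect_equal(unname(ev$summary[, "sd"]), c(0, 0, 0, 0))
})
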