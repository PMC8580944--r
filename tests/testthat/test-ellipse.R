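test_that("thresholding keeps exactly the superlevel pixels in image coordinates", {
  s <- circleSkeleton(256, 256, 100, 512)
  f <- buildDistanceField(s, fieldConfig(100))
  pts <- thresholdField(f, 0.9)
  # all surviving pixels lie within sigma * sqrt(2 ln(1/0.9)) of the contour
  dmax <- 50 * sqrt(2 * log(1 / 0.9))
  d <- abs(sqrt((pts[, 1] - 256)^2 + (pts[, 2] - 256)^2) - 100)
  expect_lte(max(d), dmax + 0.75)  # half-pixel slack for the discrete skeleton
  expect_gt(nrow(pts), 1000)
  expect_error(thresholdField(matrix(0, 32, 32), 0.9), class = "fhcNoDetection")
  f2 <- matrix(0.5, 32, 32)
  expect_error(thresholdField(f2, 0.999999), class = "fhcNoDetection")
})

test_that("ellipse fit is exact on noise-free samples", {
  # circle
  e0 <- ellipse(0, 0, 10, 10, 0)
  fit0 <- fitEllipse(ellipsePoints(e0, 360))
  expect_equal(c(fit0@cx, fit0@cy, fit0@a, fit0@b, fit0@theta),
               c(0, 0, 10, 10, 0), tolerance = 1e-9)
  # the reference eccentric case
  e1 <- ellipse(250, 300, 120, 80, pi / 6)
  fit1 <- fitEllipse(ellipsePoints(e1, 200))
  expect_lt(max(abs(c(fit1@cx - 250, fit1@cy - 300, fit1@a - 120,
                      fit1@b - 80, fit1@theta - pi / 6)) /
                c(250, 300, 120, 80, pi / 6)), 1e-6)
  # random ellipses up to a/b = 10
  set.seed(11)
  for (i in 1:10) {
    a <- runif(1, 20, 200); b <- a / runif(1, 1, 10)
    e <- ellipse(runif(1, -100, 400), runif(1, -100, 400), a, b, runif(1, 0, pi))
    fit <- fitEllipse(ellipsePoints(e, 120))
    expect_lt(max(abs(c(fit@cx - e@cx, fit@cy - e@cy, fit@a - e@a,
                        fit@b - e@b))) / a, 1e-6)
    expect_lt(abs(fit@theta - e@theta), 1e-6)
  }
})

test_that("degenerate inputs raise fit-failure errors", {
  expect_error(fitEllipse(cbind(1:10, 1:10)), class = "fhcFitFailure")
  expect_error(fitEllipse(cbind(1:5, (1:5)^2)), class = "fhcFitFailure")
  # points on a hyperbola-like conic must not be reported as an ellipse
  t <- seq(-1.2, 1.2, length.out = 50)
  expect_error(fitEllipse(cbind(cosh(t), sinh(t))), class = "fhcFitFailure")
})

test_that("fit is rotationally equivariant on noise-free samples", {
  set.seed(5)
  e <- ellipse(120, 140, 90, 60, 0.4)
  pts <- ellipsePoints(e, 150)
  for (phi in c(0.3, 1.1, 2.5)) {
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    ctr <- cbind(pts[, 1] - e@cx, pts[, 2] - e@cy) %*% t(R)
    fit <- fitEllipse(cbind(ctr[, 1] + e@cx, ctr[, 2] + e@cy))
    dth <- abs(fit@theta - ((e@theta + phi) %% pi))
    expect_lt(min(dth, pi - dth), 1e-6)
  }
})

test_that("Ramanujan II perimeter matches adaptive quadrature", {
  expect_equal(ellipsePerimeter(10, 10), 20 * pi, tolerance = 1e-12)
  expect_equal(ellipsePerimeter(2, 1), 9.68845, tolerance = 1e-5)
  expect_equal(ellipsePerimeter(2, 1), perimeterQuadrature(2, 1),
               tolerance = 1e-5)
  # invariant to pose
  e <- ellipse(50, 60, 30, 20, 1.1)
  expect_equal(ellipsePerimeter(e), ellipsePerimeter(30, 20))
  # grid of aspect ratios up to 5
  for (ab in seq(1, 5, length.out = 25)) {
    p1 <- ellipsePerimeter(ab, 1)
    p2 <- perimeterQuadrature(ab, 1)
    expect_lt(abs(p1 - p2) / p2, 1e-4)
  }
})

test_that("HC length is perimeter times pixel size", {
  expect_equal(hcLengthMm(1000, 0.1), 100)
  expect_equal(hcLengthMm(628.3185, 0.052), 32.672562, tolerance = 1e-6)
  expect_error(hcLengthMm(100, 0), class = "fhcBadInput")
  expect_error(hcLengthMm(-3, 0.1), class = "fhcBadInput")
})

test_that("geometry round trip recovers the generating ellipse", {
  set.seed(99)
  for (i in 1:5) {
    e <- randomEllipse(512, aRange = c(60, 160), ratio = c(0.6, 0.9))
    tg <- buildTargets(e, 512, 512, fieldConfig(100))
    fit <- fitFromField(tg$field, 0.9)
    expect_lt(max(abs(c(fit@cx - e@cx, fit@cy - e@cy))), 2)
    expect_lt(max(abs(c(fit@a - e@a, fit@b - e@b))), 2)
    dth <- abs(fit@theta - e@theta); dth <- min(dth, pi - dth)
    expect_lt(dth * 180 / pi, 2)
  }
})

test_that("canonical form orders axes and wraps theta", {
  e <- ellipse(0, 0, 5, 9, 0.2)   # swapped axes on input
  expect_gte(e@a, e@b)
  expect_equal(e@a, 9)
  expect_equal(e@theta, 0.2 + pi / 2)
  e2 <- ellipse(0, 0, 4, 4, 2.5)  # circle: theta canonicalized to 0
  expect_equal(e2@theta, 0)
  expect_error(new("Ellipse", cx = 0, cy = 0, a = 1, b = 2, theta = 0))
})
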