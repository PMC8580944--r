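test_that("rasterized circle ring is closed, 2px wide, near the analytic contour", {
  e <- ellipse(256, 256, 50, 50, 0)
  m <- rasterizeEllipse(e, 512, 512, 2)
  idx <- which(m == 1L, arr.ind = TRUE)
  d <- abs(sqrt((idx[, 1] - 257)^2 + (idx[, 2] - 257)^2) - 50)
  expect_lte(max(d), 1.5)
  expect_lt(abs(sum(m) - 2 * 2 * pi * 50) / (2 * 2 * pi * 50), 0.15)
  # closed: every angular bin around the center is populated
  ang <- atan2(idx[, 1] - 257, idx[, 2] - 257)
  expect_equal(length(unique(cut(ang, seq(-pi, pi, length.out = 73)))), 72)
})

test_that("fully off-canvas ellipse raises an empty-annotation error", {
  expect_error(rasterizeEllipse(ellipse(-500, -500, 50, 50, 0), 512, 512, 2),
               class = "fhcEmptyAnnotation")
})

test_that("skeletonization thins a 2px ring to a closed 1px ring and is idempotent", {
  ring2 <- rasterizeEllipse(ellipse(100, 100, 50, 50, 0), 200, 200, 2)
  s <- skeletonizeContour(ring2)
  idx <- which(s == 1L, arr.ind = TRUE)
  expect_lte(max(abs(sqrt((idx[, 1] - 101)^2 + (idx[, 2] - 101)^2) - 50)), 1.5)
  # one-pixel wide: no 2x2 all-ones block
  blk <- s[-nrow(s), -ncol(s)] & s[-1, -ncol(s)] & s[-nrow(s), -1] & s[-1, -1]
  expect_equal(sum(blk), 0)
  # closed curve: every skeleton pixel has at least 2 neighbours
  nb <- matrix(0L, nrow(s), ncol(s))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(0L, nrow(s), ncol(s))
    rs <- max(1, 1 + dr):min(nrow(s), nrow(s) + dr)
    cs <- max(1, 1 + dc):min(ncol(s), ncol(s) + dc)
    sh[rs, cs] <- s[rs - dr, cs - dc]
    nb <- nb + sh
  }
  expect_true(all(nb[s == 1L] >= 2))
  expect_identical(skeletonizeContour(s), s)
  expect_error(skeletonizeContour(matrix(0L, 8, 8)), class = "fhcEmptyMask")
})

test_that("distance field follows the Gaussian of the exact distance with r/2 support", {
  # single-pixel skeleton: every distance is analytic
  s <- matrix(0L, 121, 121); s[61, 61] <- 1L
  f <- buildDistanceField(s, fieldConfig(100))
  expect_equal(f[61, 61], 1.0)
  expect_equal(f[61, 86], exp(-25^2 / (2 * 50^2)), tolerance = 1e-12) # d = 25
  expect_equal(f[61, 121], 0)                                        # d = 60 > r/2
  expect_equal(f[61, 111], exp(-0.5), tolerance = 1e-12)             # d = 50 edge
  # support switch
  ffull <- buildDistanceField(s, fieldConfig(100, support = "full"))
  expect_gt(ffull[61, 121], 0)
  expect_error(buildDistanceField(matrix(0L, 8, 8)), class = "fhcEmptyMask")
})

test_that("distance field equals the brute-force nearest-skeleton computation", {
  set.seed(42)
  for (i in 1:6) {
    s <- matrix(0L, 64, 64)
    s[cbind(sample(64, 12), sample(64, 12))] <- 1L
    r <- sample(c(10, 24, 60), 1)
    f <- buildDistanceField(s, fieldConfig(r))
    expect_lt(max(abs(f - bruteForceField(s, r))), 1e-6)
  }
})

test_that("field is 1 exactly on the skeleton and decreases along a normal", {
  s <- circleSkeleton(100, 100, 60, 201)
  f <- buildDistanceField(s, fieldConfig(40))
  expect_true(all(f[s == 1L] == 1))
  expect_true(all(f[s == 0L] < 1))
  # sample outward along +x from a contour point: strictly decreasing in d
  vals <- f[101, 161:180]  # x = 160..179, d = 0..19 < r/2
  expect_true(all(diff(vals) < 0))
})

test_that("field bbox is minimal and matches the analytic support box", {
  s <- circleSkeleton(256, 256, 100, 512)
  f <- buildDistanceField(s, fieldConfig(100))
  bb <- fieldBBox(f)
  expect_equal(unname(bb), c(106, 106, 407, 407))
  # minimality: every side touches a nonzero pixel
  expect_true(any(f[, bb[["x1"]] + 1] > 0) && any(f[, bb[["x2"]]] > 0))
  expect_true(any(f[bb[["y1"]] + 1, ] > 0) && any(f[bb[["y2"]], ] > 0))
  # tiny field: single pixel at (10, 10), r = 2 -> support radius 1
  s2 <- matrix(0L, 32, 32); s2[11, 11] <- 1L
  expect_equal(unname(fieldBBox(buildDistanceField(s2, fieldConfig(2)))),
               c(9, 9, 12, 12))
  expect_error(fieldBBox(matrix(0, 4, 4)), class = "fhcEmptyMask")
})

test_that("shifting the skeleton shifts field and box identically", {
  s <- matrix(0L, 64, 64)
  s[cbind(c(20, 21, 22, 23), c(30, 31, 31, 32))] <- 1L
  f1 <- buildDistanceField(s, fieldConfig(10))
  s2 <- matrix(0L, 64, 64)
  s2[cbind(c(20, 21, 22, 23) + 7, c(30, 31, 31, 32) + 4)] <- 1L
  f2 <- buildDistanceField(s2, fieldConfig(10))
  expect_equal(f2[(1 + 7):64, (1 + 4):64], f1[1:(64 - 7), 1:(64 - 4)])
  expect_equal(unname(fieldBBox(f2) - fieldBBox(f1)), c(4, 7, 4, 7))
})

test_that("padded resize preserves aspect ratio and inverts to within a pixel", {
  img <- matrix(runif(540 * 800), 540, 800)
  rs <- resizeWithPadding(img, 512)
  tf <- rs$transform
  expect_equal(dim(rs$image), c(512, 512))
  expect_equal(tf@scale, 0.64)
  expect_equal(tf@padBottom, 166L)   # 540 * 0.64 = 345.6 -> 346
  expect_equal(tf@padRight, 0L)
  expect_true(all(rs$image[347:512, ] == 0))
  p <- matrix(c(400, 300), 1)
  back <- transformPoints(tf, transformPoints(tf, p), inverse = TRUE)
  expect_lt(max(abs(back - p)), 1)
  # identity case
  rs2 <- resizeWithPadding(matrix(runif(512^2), 512, 512), 512)
  expect_equal(rs2$transform@scale, 1)
  expect_equal(rs2$transform@padRight + rs2$transform@padBottom, 0L)
  expect_error(resizeWithPadding(matrix(numeric(0), 0, 0), 512),
               class = "fhcEmptyMask")
})

test_that("16-bit field PNG round-trips at 1/65535 resolution", {
  f <- buildDistanceField(circleSkeleton(40, 40, 20, 81), fieldConfig(24))
  path <- tempfile(fileext = ".png")
  writeFieldPNG(f, path)
  back <- readFieldPNG(path)
  expect_lt(max(abs(back - f)), 1 / 65535)
})
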