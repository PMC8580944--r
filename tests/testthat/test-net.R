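# tiny configurations keep these structural checks fast on one CPU
tinyCfg <- function(...) {
  netConfig(backboneDepth = 18L, baseWidth = 8L, fpnChannels = 8L,
            headChannels = 4L, fcWidth = 16L, imageSize = 128L, ...)
}

test_that("anchor set follows the scale/ratio parametrization and count formula", {
  cfg <- netConfig()   # 512 px, scales [32,64,128,256,512] x ratios [.5,1,2]
  an <- generateAnchors(cfg)
  expect_equal(nrow(an$boxes), 3 * (128^2 + 64^2 + 32^2 + 16^2 + 8^2)) # 65472
  expect_equal(nrow(an$boxes), 65472)
  w <- an$boxes[, 3] - an$boxes[, 1]; h <- an$boxes[, 4] - an$boxes[, 2]
  # ratio-1 anchors are square at the level scale
  r1 <- abs(w - h) < 1e-9
  expect_true(any(r1))
  expect_equal(sort(unique(w[r1])), c(32, 64, 128, 256, 512))
  # scale 64 (level P3), ratio 0.5: w = 64*sqrt(.5), h = 64/sqrt(.5)
  lvl3 <- an$level == 3
  expect_true(any(abs(w[lvl3] - 64 * sqrt(0.5)) < 1e-9 &
                  abs(h[lvl3] - 64 / sqrt(0.5)) < 1e-9))
  # count formula holds for other input sizes too
  an2 <- generateAnchors(cfg, lapply(c(4, 8, 16, 32, 64), function(s)
    c(256 %/% s, 256 %/% s)))
  expect_equal(nrow(an2$boxes), 3 * sum((256 %/% c(4, 8, 16, 32, 64))^2))
})

test_that("box delta encoding and decoding are mutual inverses", {
  set.seed(8)
  ref <- cbind(runif(50, 0, 200), runif(50, 0, 200), 0, 0)
  ref[, 3] <- ref[, 1] + runif(50, 5, 100)
  ref[, 4] <- ref[, 2] + runif(50, 5, 100)
  tgt <- ref + cbind(runif(50, -10, 10), runif(50, -10, 10),
                     runif(50, -10, 10), runif(50, -10, 10))
  tgt[, 3] <- pmax(tgt[, 3], tgt[, 1] + 2)
  tgt[, 4] <- pmax(tgt[, 4], tgt[, 2] + 2)
  dec <- decodeBoxes(ref, encodeBoxes(ref, tgt))
  expect_lt(max(abs(dec - tgt)), 1e-6)
  # worked delta: (0, 0, log 2, log 2) on a 32x32 anchor doubles the box
  out <- decodeBoxes(c(0, 0, 32, 32), c(0, 0, log(2), log(2)))
  expect_equal(as.numeric(out), c(-16, -16, 48, 48))
})

test_that("proposal filtering decodes, clips and suppresses duplicates", {
  anchors <- list(boxes = rbind(c(10, 10, 42, 42), c(10, 10, 42, 42),
                                c(60, 60, 100, 100), c(-10, -10, 22, 22)))
  obj <- c(3, 2.9, 1, 0.5)
  # zero deltas: proposals equal the (clipped) anchors; identical pair collapses
  prop <- proposeRois(anchors, obj, matrix(0, 4, 4), 128, nmsThresh = 0.7,
                      preNmsK = 10L, postNmsK = 10L)
  expect_equal(nrow(prop$boxes), 3)
  expect_equal(prop$boxes[1, ], c(10, 10, 42, 42))
  expect_true(all(prop$boxes >= 0 & prop$boxes <= 128))
  expect_equal(unname(prop$boxes[3, 1:2]), c(0, 0))   # clipped anchor
})

test_that("feature pyramid levels follow the stride and channel contract", {
  set.seed(2)
  cfg <- tinyCfg()
  params <- initNetParams(cfg)
  tape <- fetalHC:::newTape()
  img <- matrix(runif(128 * 128), 128, 128)
  t0 <- Sys.time()
  pyr <- fetalHC:::buildFeaturePyramid(tape, img, params, cfg)
  expect_lt(as.numeric(Sys.time()) - as.numeric(t0), 2)  # one CPU, < 2 s
  sizes <- sapply(pyr, function(p) dim(p$value)[1])
  expect_equal(unname(sizes), c(32, 16, 8, 4, 2))
  expect_true(all(sapply(pyr, function(p) dim(p$value)[3]) == cfg@fpnChannels))
  expect_error(
    fetalHC:::buildFeaturePyramid(fetalHC:::newTape(),
                                  matrix(0, 100, 100), params, cfg),
    class = "fhcBadInput")
})

test_that("RPN outputs align one-to-one with the anchor ordering", {
  set.seed(3)
  cfg <- tinyCfg()
  params <- initNetParams(cfg)
  tape <- fetalHC:::newTape()
  img <- matrix(runif(128 * 128), 128, 128)
  pyr <- fetalHC:::buildFeaturePyramid(tape, img, params, cfg)
  an <- generateAnchors(cfg, lapply(pyr, function(p) dim(p$value)[1:2]))
  flat <- fetalHC:::rpnFlatten(fetalHC:::rpnForwardNodes(tape, pyr, params))
  expect_equal(length(flat$objectness), nrow(an$boxes))
  expect_equal(nrow(flat$deltas), nrow(an$boxes))
  p <- 1 / (1 + exp(-flat$objectness))
  expect_true(all(p >= 0 & p <= 1))
  # deterministic given fixed weights and input
  flat2 <- fetalHC:::rpnFlatten(fetalHC:::rpnForwardNodes(
    fetalHC:::newTape(), fetalHC:::buildFeaturePyramid(
      fetalHC:::newTape(), img, params, cfg), params))
  expect_identical(flat$objectness, flat2$objectness)
})

test_that("ROI align equals a brute-force bilinear sampler on a toy map", {
  set.seed(4)
  feat <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  boxes <- rbind(c(2.3, 3.1, 9.7, 12.2), c(0.0, 0.0, 16.0, 16.0),
                 c(5.5, 5.5, 6.5, 6.5))
  d <- 4L
  tape <- fetalHC:::newTape()
  out <- fetalHC:::agRoiAlign(tape, fetalHC:::constNode(tape, feat),
                              boxes, d)$value
  # independent sampler: mean of 2x2 bilinear samples per bin, clamped
  bil <- function(m, y, x) {
    y <- min(max(y, 0), nrow(m) - 1); x <- min(max(x, 0), ncol(m) - 1)
    y0 <- floor(y); x0 <- floor(x)
    y1 <- min(y0 + 1, nrow(m) - 1); x1 <- min(x0 + 1, ncol(m) - 1)
    fy <- y - y0; fx <- x - x0
    m[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) + m[y1 + 1, x0 + 1] * fy * (1 - fx) +
      m[y0 + 1, x1 + 1] * (1 - fy) * fx + m[y1 + 1, x1 + 1] * fy * fx
  }
  for (b in 1:3) for (c in 1:2) {
    bw <- (boxes[b, 3] - boxes[b, 1]) / d; bh <- (boxes[b, 4] - boxes[b, 2]) / d
    for (pw in 0:(d - 1)) for (ph in 0:(d - 1)) {
      acc <- 0
      for (sj in 0:1) for (si in 0:1) {
        x <- boxes[b, 1] + (pw + (sj + 0.5) / 2) * bw
        y <- boxes[b, 2] + (ph + (si + 0.5) / 2) * bh
        acc <- acc + bil(feat[, , c], y - 0.5, x - 0.5)
      }
      expect_lt(abs(out[ph + 1, pw + 1, c, b] - acc / 4), 1e-5)
    }
  }
  # constant feature map -> constant patches
  cf <- array(3.7, c(16, 16, 1))
  o2 <- fetalHC:::agRoiAlign(fetalHC:::newTape(),
                             fetalHC:::constNode(fetalHC:::newTape(), cf),
                             boxes, d)$value
  expect_lt(max(abs(o2 - 3.7)), 1e-12)
  expect_error(fetalHC:::roiAlignPatches(tape, list(), rbind(c(5, 5, 5, 9)), d),
               class = "fhcBadInput")
})

test_that("distance-field head output is (2^u d) squared for every variant", {
  set.seed(5)
  for (case in list(list(d = 14L, u = 3L, v = "upconv", out = 112L),
                    list(d = 14L, u = 1L, v = "transposed", out = 28L),
                    list(d = 14L, u = 2L, v = "upconv", out = 56L),
                    list(d = 10L, u = 2L, v = "transposed", out = 40L),
                    list(d = 10L, u = 3L, v = "upconv", out = 80L),
                    list(d = 10L, u = 1L, v = "upconv", out = 20L))) {
    cfg <- tinyCfg(roiSize = case$d, nUpsamplings = case$u,
                   upsamplingVariant = case$v)
    params <- initNetParams(cfg)
    tape <- fetalHC:::newTape()
    patches <- fetalHC:::constNode(tape, array(rnorm(case$d^2 * 8 * 2),
                                               c(case$d, case$d, 8L, 2L)))
    y <- fetalHC:::distanceFieldHead(tape, patches, params, cfg)
    expect_equal(dim(y$value), c(case$out, case$out, 1L, 2L))
  }
})

test_that("classification head normalizes two scores and can be omitted", {
  set.seed(6)
  cfg <- tinyCfg()
  params <- initNetParams(cfg)
  tape <- fetalHC:::newTape()
  patches <- fetalHC:::constNode(
    tape, array(rnorm(cfg@roiSize^2 * cfg@fpnChannels * 5),
                c(cfg@roiSize, cfg@roiSize, cfg@fpnChannels, 5L)))
  heads <- fetalHC:::classBoxHead(tape, patches, params, cfg)
  expect_equal(ncol(heads$cls$value), 2)
  z <- heads$cls$value
  p <- exp(z) / rowSums(exp(z))
  expect_equal(rowSums(p), rep(1, 5))
  expect_equal(ncol(heads$box$value), 4)
  # MaskNoClass: no classification parameters, head omitted
  cfgN <- tinyCfg(includeClassHead = FALSE)
  paramsN <- initNetParams(cfgN)
  expect_null(paramsN[["head.cls.W"]])
  headsN <- fetalHC:::classBoxHead(fetalHC:::newTape(), patches, paramsN, cfgN)
  expect_null(headsN$cls)
})

test_that("full forward returns contract-satisfying detections", {
  set.seed(7)
  cfg <- tinyCfg(includeClassHead = FALSE, scoreThresh = 0.3)
  params <- initNetParams(cfg)
  img <- matrix(runif(128 * 128), 128, 128)
  dets <- fullForward(img, params, cfg)
  expect_gt(length(dets), 0)   # objectness scoring finds something at init
  P <- 2^cfg@nUpsamplings * cfg@roiSize
  for (d in dets) {
    expect_true(d$score >= 0 && d$score <= 1)
    expect_true(all(d$box[c(1, 3)] >= 0 & d$box[c(1, 3)] <= 128))
    expect_true(d$box[3] > d$box[1] && d$box[4] > d$box[2])
    expect_equal(dim(d$patch), c(P, P))
  }
})
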