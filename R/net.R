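# The detector-regressor: ResNet/FPN backbone, region-proposal network,
# ROI align, and three heads (classification, box refinement, distance-field
# regression), with the upsampling-path ablation variants as configuration.

#' Network configuration
#'
#' Defaults follow the reference configuration: ResNet-101 backbone, FPN with
#' 256 channels, anchor scales [32, 64, 128, 256, 512] (one per pyramid
#' level) x ratios [0.5, 1, 2], ROI-align output d = 14, a distance-field
#' head with four 3x3 convolutions and three up-convolutions (output 8d x
#' 8d), 150 training ROIs per image. Widths (\code{baseWidth},
#' \code{fpnChannels}, \code{headChannels}, \code{fcWidth}) are configurable
#' so the same architecture runs at desk scale on one CPU.
#'
#' @slot backboneDepth integer, one of 18, 34, 50, 101.
#' @slot baseWidth integer stem width of the ResNet (64 standard).
#' @slot fpnChannels,headChannels,fcWidth integer widths.
#' @slot roiSize integer ROI-align output side d (even).
#' @slot nUpsamplings integer u in 1..3; head output side is 2^u * d.
#' @slot upsamplingVariant \code{"upconv"} (2x upsample + convs, UNet style)
#'   or \code{"transposed"} (stride-2 transposed convolutions).
#' @slot includeClassHead logical; FALSE gives the variant without the
#'   classification head, scored by RPN objectness.
#' @slot anchorScales numeric length 5 (one scale per level P2..P6).
#' @slot anchorRatios numeric length 3 (width/height).
#' @slot trainRoisPerImage,maxFieldRois integer ROI sampling budget.
#' @slot imageSize integer network input side (divisible by 64).
#' @slot scoreThresh,detNms,proposalNms numeric detection-time thresholds.
#' @slot preNmsTrain,postNmsTrain,preNmsTest,postNmsTest,rpnBatch integer
#'   proposal/sampling counts.
#' @slot rpnPosIou,rpnNegIou,headPosIou numeric IoU thresholds.
#' @export
setClass("NetConfig",
  representation(backboneDepth = "integer", baseWidth = "integer",
                 fpnChannels = "integer", headChannels = "integer",
                 fcWidth = "integer", roiSize = "integer",
                 nUpsamplings = "integer", upsamplingVariant = "character",
                 includeClassHead = "logical", anchorScales = "numeric",
                 anchorRatios = "numeric", trainRoisPerImage = "integer",
                 maxFieldRois = "integer", imageSize = "integer",
                 scoreThresh = "numeric", detNms = "numeric",
                 proposalNms = "numeric", preNmsTrain = "integer",
                 postNmsTrain = "integer", preNmsTest = "integer",
                 postNmsTest = "integer", rpnBatch = "integer",
                 rpnPosIou = "numeric", rpnNegIou = "numeric",
                 headPosIou = "numeric"),
  validity = function(object) {
    if (!object@backboneDepth %in% c(18L, 34L, 50L, 101L))
      return("backboneDepth must be 18, 34, 50 or 101")
    if (length(object@anchorScales) != 5)
      return("one anchor scale per pyramid level (5) is required")
    if (object@roiSize %% 2 != 0 && object@roiSize != 7)
      return("roiSize should be even (or the desk-scale 7)")
    if (object@nUpsamplings < 1 || object@nUpsamplings > 3)
      return("nUpsamplings must be 1, 2 or 3")
    if (!object@upsamplingVariant %in% c("upconv", "transposed"))
      return("upsamplingVariant must be 'upconv' or 'transposed'")
    if (object@imageSize %% 64 != 0)
      return("imageSize must be divisible by 64")
    TRUE
  })

#' @param ... slot overrides.
#' @rdname NetConfig-class
#' @export
netConfig <- function(...) {
  args <- list(backboneDepth = 101L, baseWidth = 64L, fpnChannels = 256L,
               headChannels = 256L, fcWidth = 1024L, roiSize = 14L,
               nUpsamplings = 3L, upsamplingVariant = "upconv",
               includeClassHead = TRUE,
               anchorScales = c(32, 64, 128, 256, 512),
               anchorRatios = c(0.5, 1, 2), trainRoisPerImage = 150L,
               maxFieldRois = 150L, imageSize = 512L, scoreThresh = 0.7,
               detNms = 0.3, proposalNms = 0.7, preNmsTrain = 6000L,
               postNmsTrain = 1000L, preNmsTest = 1000L, postNmsTest = 100L,
               rpnBatch = 256L, rpnPosIou = 0.7, rpnNegIou = 0.3,
               headPosIou = 0.5)
  ov <- list(...)
  args[names(ov)] <- ov
  ints <- c("backboneDepth", "baseWidth", "fpnChannels", "headChannels",
            "fcWidth", "roiSize", "nUpsamplings", "trainRoisPerImage",
            "maxFieldRois", "imageSize", "preNmsTrain", "postNmsTrain",
            "preNmsTest", "postNmsTest", "rpnBatch")
  for (k in ints) args[[k]] <- as.integer(args[[k]])
  do.call(new, c("NetConfig", args))
}

#' Desk-scale configuration
#'
#' A width-reduced configuration that trains end-to-end on one CPU within
#' minutes on 128 px phantoms: ResNet-18 at stem width 16, 32 FPN channels,
#' 8-channel field head, d = 7, anchor scales matched to the 128 px heads,
#' 32 training ROIs per image (field loss on up to 4 positives), detection
#' score threshold 0.5 (scores are less saturated after a short schedule).
#'
#' @param ... overrides.
#' @rdname NetConfig-class
#' @export
netConfigDesk <- function(...) {
  netConfig(backboneDepth = 18L, baseWidth = 12L, fpnChannels = 24L,
            headChannels = 8L, fcWidth = 96L, roiSize = 7L,
            nUpsamplings = 3L, imageSize = 128L,
            anchorScales = c(16, 32, 64, 96, 128),
            trainRoisPerImage = 32L, maxFieldRois = 4L, rpnBatch = 64L,
            preNmsTrain = 600L, postNmsTrain = 100L, preNmsTest = 300L,
            postNmsTest = 25L, scoreThresh = 0.5, ...)
}

setMethod("show", "NetConfig", function(object) {
  cat(sprintf(
    "NetConfig: ResNet-%d/FPN(%d ch), d=%d, %s x%d -> %dx%d field patch, input %d px\n",
    object@backboneDepth, object@fpnChannels, object@roiSize,
    object@upsamplingVariant, object@nUpsamplings,
    2^object@nUpsamplings * object@roiSize,
    2^object@nUpsamplings * object@roiSize, object@imageSize))
})

# ---- parameter initialization --------------------------------------------

heConv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

addConv <- function(p, name, kh, kw, cin, cout, bn = TRUE, sd = NULL) {
  p[[paste0(name, ".W")]] <- if (is.null(sd)) heConv(kh, kw, cin, cout)
    else array(rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
  p[[paste0(name, ".b")]] <- numeric(cout)
  if (bn) {
    p[[paste0(name, ".bn.gamma")]] <- rep(1, cout)
    p[[paste0(name, ".bn.beta")]] <- numeric(cout)
  }
  p
}

addDense <- function(p, name, din, dout, sd = NULL) {
  p[[paste0(name, ".W")]] <- matrix(
    rnorm(din * dout, sd = if (is.null(sd)) sqrt(2 / din) else sd), din, dout)
  p[[paste0(name, ".b")]] <- numeric(dout)
  p
}

resnetBlocks <- function(depth) {
  switch(as.character(depth),
         "18" = list(n = c(2, 2, 2, 2), bottleneck = FALSE),
         "34" = list(n = c(3, 4, 6, 3), bottleneck = FALSE),
         "50" = list(n = c(3, 4, 6, 3), bottleneck = TRUE),
         "101" = list(n = c(3, 4, 23, 3), bottleneck = TRUE))
}

#' Initialize network parameters
#'
#' He-normal convolution weights, zero biases, unit batch-norm scale. Uses
#' the current R RNG state (seed upstream for reproducibility). Optionally
#' pretrained backbone weights of the same shapes may be supplied to
#' override the random initialization.
#'
#' @param cfg a \code{\linkS4class{NetConfig}}.
#' @param pretrained optional named list of parameter overrides.
#' @return named list of parameter arrays.
#' @export
initNetParams <- function(cfg, pretrained = NULL) {
  p <- list()
  bw <- cfg@baseWidth
  blocks <- resnetBlocks(cfg@backboneDepth)
  exp <- if (blocks$bottleneck) 4L else 1L
  p <- addConv(p, "stem.conv", 7, 7, 1, bw)
  cin <- bw
  widths <- bw * c(1, 2, 4, 8)
  for (st in 1:4) {
    w <- widths[st]
    for (bl in seq_len(blocks$n[st])) {
      nm <- sprintf("layer%d.block%d", st, bl)
      stride <- if (st > 1 && bl == 1) 2L else 1L
      cout <- w * exp
      if (blocks$bottleneck) {
        p <- addConv(p, paste0(nm, ".conv1"), 1, 1, cin, w)
        p <- addConv(p, paste0(nm, ".conv2"), 3, 3, w, w)
        p <- addConv(p, paste0(nm, ".conv3"), 1, 1, w, cout)
      } else {
        p <- addConv(p, paste0(nm, ".conv1"), 3, 3, cin, w)
        p <- addConv(p, paste0(nm, ".conv2"), 3, 3, w, w)
      }
      if (stride != 1L || cin != cout)
        p <- addConv(p, paste0(nm, ".down"), 1, 1, cin, cout)
      cin <- cout
    }
  }
  fc <- cfg@fpnChannels
  cs <- widths * exp
  for (k in 2:5)
    p <- addConv(p, sprintf("fpn.lateral%d", k), 1, 1, cs[k - 1], fc, bn = FALSE)
  for (k in 2:5)
    p <- addConv(p, sprintf("fpn.smooth%d", k), 3, 3, fc, fc, bn = FALSE)
  p <- addConv(p, "rpn.conv", 3, 3, fc, fc, bn = FALSE)
  p <- addConv(p, "rpn.cls", 1, 1, fc, 3, bn = FALSE, sd = 0.01)
  p <- addConv(p, "rpn.box", 1, 1, fc, 12, bn = FALSE, sd = 0.01)
  d <- cfg@roiSize
  p <- addDense(p, "head.fc1", d * d * fc, cfg@fcWidth)
  p <- addDense(p, "head.fc2", cfg@fcWidth, cfg@fcWidth)
  if (cfg@includeClassHead)
    p <- addDense(p, "head.cls", cfg@fcWidth, 2, sd = 0.01)
  p <- addDense(p, "head.box", cfg@fcWidth, 4, sd = 0.01)
  hc <- cfg@headChannels
  p <- addConv(p, "df.conv1", 3, 3, fc, hc)
  for (i in 2:4) p <- addConv(p, sprintf("df.conv%d", i), 3, 3, hc, hc)
  for (j in seq_len(cfg@nUpsamplings)) {
    if (cfg@upsamplingVariant == "upconv") {
      p <- addConv(p, sprintf("df.up%d.convA", j), 2, 2, hc, hc)
      p <- addConv(p, sprintf("df.up%d.convB", j), 3, 3, hc, hc)
      p <- addConv(p, sprintf("df.up%d.convC", j), 3, 3, hc, hc)
    } else {
      p <- addConv(p, sprintf("df.tconv%d", j), 2, 2, hc, hc)
    }
  }
  p <- addConv(p, "df.out", 1, 1, hc, 1, bn = FALSE, sd = 0.01)
  if (!is.null(pretrained)) {
    for (nm in names(pretrained)) {
      if (!is.null(p[[nm]]) &&
          identical(dim(p[[nm]]), dim(pretrained[[nm]])))
        p[[nm]] <- pretrained[[nm]]
    }
  }
  p
}

# drop the first row/column (for 'same' 2x2 convolutions: pad 1 then crop)
agCropTL <- function(tape, x) {
  d <- dim4(x$value)
  xv <- array(x$value, d)
  y <- xv[-1, -1, , , drop = FALSE]
  if (length(dim(x$value)) == 3) dim(y) <- dim(y)[1:3]
  addNode(tape, y, parents = list(x), vjp = function(gy) {
    gx <- array(0, d)
    gx[-1, -1, , ] <- gy
    if (length(dim(x$value)) == 3) dim(gx) <- d[1:3]
    list(gx)
  })
}

# 2x2 'same' convolution + BN + ReLU
cbr2 <- function(tape, x, params, name) {
  y <- agCropTL(tape, agConv(tape, x, params, name, stride = 1L, pad = 1L))
  agRelu(tape, agBN(tape, y, params, paste0(name, ".bn")))
}

# conv + BN + ReLU
cbr <- function(tape, x, params, name, stride = 1L, pad = NULL) {
  agRelu(tape, agBN(tape, agConv(tape, x, params, name, stride, pad),
                    params, paste0(name, ".bn")))
}

basicBlock <- function(tape, x, params, nm, stride) {
  y <- cbr(tape, x, params, paste0(nm, ".conv1"), stride)
  y <- agBN(tape, agConv(tape, y, params, paste0(nm, ".conv2")),
            params, paste0(nm, ".conv2.bn"))
  sc <- if (!is.null(params[[paste0(nm, ".down.W")]]))
    agBN(tape, agConv(tape, x, params, paste0(nm, ".down"), stride, pad = 0L),
         params, paste0(nm, ".down.bn"))
  else x
  agRelu(tape, agAdd(tape, y, sc))
}

bottleneckBlock <- function(tape, x, params, nm, stride) {
  y <- cbr(tape, x, params, paste0(nm, ".conv1"), pad = 0L)
  y <- cbr(tape, y, params, paste0(nm, ".conv2"), stride)
  y <- agBN(tape, agConv(tape, y, params, paste0(nm, ".conv3"), pad = 0L),
            params, paste0(nm, ".conv3.bn"))
  sc <- if (!is.null(params[[paste0(nm, ".down.W")]]))
    agBN(tape, agConv(tape, x, params, paste0(nm, ".down"), stride, pad = 0L),
         params, paste0(nm, ".down.bn"))
  else x
  agRelu(tape, agAdd(tape, y, sc))
}

#' Feature pyramid forward pass
#'
#' ResNet stages C2..C5 followed by the top-down pathway with 1x1 lateral
#' connections and 3x3 smoothing; P6 is a stride-2 subsampling of P5.
#' Returns P2..P6 at strides 4, 8, 16, 32, 64, each with
#' \code{fpnChannels} channels.
#'
#' @param tape autograd tape (internal); use \code{newTape()}.
#' @param image (H, W, 1) array node or plain array, H = W divisible by 64.
#' @param params parameter list from [initNetParams()].
#' @param cfg a \code{\linkS4class{NetConfig}}.
#' @return list of nodes P2..P6.
#' @keywords internal
buildFeaturePyramid <- function(tape, image, params, cfg) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  x <- if (is.environment(image)) image else constNode(tape, image)
  d <- dim(x$value)
  if (d[1] %% 64 != 0 || d[2] %% 64 != 0)
    fhcStop("fhcBadInput", "input size must be divisible by 64")
  blocks <- resnetBlocks(cfg@backboneDepth)
  y <- cbr(tape, x, params, "stem.conv", stride = 2L, pad = 3L)
  y <- agMaxpool(tape, y, 3L, 2L, 1L)
  cs <- list()
  for (st in 1:4) {
    for (bl in seq_len(blocks$n[st])) {
      nm <- sprintf("layer%d.block%d", st, bl)
      stride <- if (st > 1 && bl == 1) 2L else 1L
      y <- if (blocks$bottleneck) bottleneckBlock(tape, y, params, nm, stride)
           else basicBlock(tape, y, params, nm, stride)
    }
    cs[[st]] <- y
  }
  p5 <- agConv(tape, cs[[4]], params, "fpn.lateral5", pad = 0L)
  p4 <- agAdd(tape, agConv(tape, cs[[3]], params, "fpn.lateral4", pad = 0L),
              agUpsample2(tape, p5))
  p3 <- agAdd(tape, agConv(tape, cs[[2]], params, "fpn.lateral3", pad = 0L),
              agUpsample2(tape, p4))
  p2 <- agAdd(tape, agConv(tape, cs[[1]], params, "fpn.lateral2", pad = 0L),
              agUpsample2(tape, p3))
  p2 <- agConv(tape, p2, params, "fpn.smooth2")
  p3 <- agConv(tape, p3, params, "fpn.smooth3")
  p4 <- agConv(tape, p4, params, "fpn.smooth4")
  p5 <- agConv(tape, p5, params, "fpn.smooth5")
  p6 <- agSubsample2(tape, p5)
  list(P2 = p2, P3 = p3, P4 = p4, P5 = p5, P6 = p6)
}

#' Generate the anchor set for a pyramid
#'
#' Three anchors per cell per level: one scale per level, ratios
#' width/height; \code{w = s * sqrt(ratio)}, \code{h = s / sqrt(ratio)},
#' centered on cell centers in input coordinates. Anchor ordering matches
#' the column-major flattening of the RPN output maps (rows fastest, then
#' columns, then ratio).
#'
#' @param cfg a \code{\linkS4class{NetConfig}}.
#' @param pyramidShapes list of c(H, W) per level (P2..P6); defaults to the
#'   shapes implied by \code{cfg@imageSize}.
#' @return list: \code{boxes} (n x 4), \code{level} (per anchor, 2..6),
#'   \code{cell} (n x 3: row, col, ratio index).
#' @export
generateAnchors <- function(cfg, pyramidShapes = NULL) {
  key <- paste(c(cfg@imageSize, cfg@anchorScales, cfg@anchorRatios,
                 unlist(pyramidShapes)), collapse = ",")
  hit <- .anchorCache[[key]]
  if (!is.null(hit)) return(hit)
  out <- generateAnchorsImpl(cfg, pyramidShapes)
  .anchorCache[[key]] <- out
  out
}

.anchorCache <- new.env(parent = emptyenv())

generateAnchorsImpl <- function(cfg, pyramidShapes = NULL) {
  strides <- c(4, 8, 16, 32, 64)
  if (is.null(pyramidShapes))
    pyramidShapes <- lapply(strides, function(s)
      c(cfg@imageSize %/% s, cfg@imageSize %/% s))
  boxes <- list(); lev <- list(); cell <- list()
  for (k in 1:5) {
    H <- pyramidShapes[[k]][1]; W <- pyramidShapes[[k]][2]
    s <- strides[k]; scale <- cfg@anchorScales[k]
    per <- list()
    for (j in seq_along(cfg@anchorRatios)) {
      r <- cfg@anchorRatios[j]
      w <- scale * sqrt(r); h <- scale / sqrt(r)
      g <- expand.grid(row = seq_len(H), col = seq_len(W))
      cx <- (g$col - 0.5) * s; cy <- (g$row - 0.5) * s
      per[[j]] <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
      cell[[length(cell) + 1]] <- cbind(g$row, g$col, j)
    }
    boxes[[k]] <- do.call(rbind, per)
    lev[[k]] <- rep(k + 1L, 3 * H * W)
  }
  list(boxes = do.call(rbind, boxes), level = unlist(lev),
       cell = do.call(rbind, cell),
       shapes = pyramidShapes)
}

# RPN head on every level; returns per-level nodes plus detached flat values
rpnForwardNodes <- function(tape, pyramid, params) {
  out <- list()
  for (nm in names(pyramid)) {
    h <- agRelu(tape, agConv(tape, pyramid[[nm]], params, "rpn.conv"))
    out[[nm]] <- list(obj = agConv(tape, h, params, "rpn.cls", pad = 0L),
                      box = agConv(tape, h, params, "rpn.box", pad = 0L))
  }
  out
}

# flatten detached RPN outputs into anchor-aligned vectors
rpnFlatten <- function(rpnOut) {
  objs <- list(); dels <- list()
  for (nm in names(rpnOut)) {
    ov <- rpnOut[[nm]]$obj$value       # (H, W, 3)
    dv <- rpnOut[[nm]]$box$value       # (H, W, 12)
    d <- dim(ov)
    objs[[nm]] <- as.vector(ov)
    arr <- array(dv, c(d[1], d[2], 4, 3))      # coord fastest in channel
    dels[[nm]] <- matrix(aperm(arr, c(1, 2, 4, 3)), ncol = 4)
  }
  list(objectness = unlist(objs), deltas = do.call(rbind, dels))
}

#' Propose regions from anchors and RPN outputs
#'
#' Applies the delta decoding, clips to the image, filters degenerate boxes,
#' keeps the top-k by objectness before and after greedy NMS.
#'
#' @param anchors anchor set from [generateAnchors()].
#' @param objectness logit vector aligned with the anchors.
#' @param deltas n x 4 matrix aligned with the anchors.
#' @param size image side for clipping.
#' @param nmsThresh IoU threshold.
#' @param preNmsK,postNmsK proposal budgets.
#' @return list: \code{boxes}, \code{scores} (sigmoid objectness).
#' @export
proposeRois <- function(anchors, objectness, deltas, size, nmsThresh = 0.7,
                        preNmsK = 1000L, postNmsK = 100L) {
  scores <- 1 / (1 + exp(-objectness))
  top <- head(order(scores, decreasing = TRUE), preNmsK)
  boxes <- decodeBoxes(anchors$boxes[top, , drop = FALSE],
                       deltas[top, , drop = FALSE])
  boxes <- clipBoxes(boxes, size)
  ok <- (boxes[, 3] - boxes[, 1]) >= 1 & (boxes[, 4] - boxes[, 2]) >= 1
  boxes <- boxes[ok, , drop = FALSE]; sc <- scores[top][ok]
  if (nrow(boxes) == 0) return(list(boxes = boxes, scores = sc))
  keep <- nmsBoxes(boxes, sc, nmsThresh, postNmsK)
  list(boxes = boxes[keep, , drop = FALSE], scores = sc[keep])
}

# FPN level assignment for ROI align (k0 = 4, 224 reference, clamp to P2..P5)
roiLevels <- function(boxes) {
  area <- pmax(boxes[, 3] - boxes[, 1], 1e-6) *
          pmax(boxes[, 4] - boxes[, 2], 1e-6)
  pmin(pmax(floor(4 + log2(sqrt(area) / 224)), 2), 5)
}

#' ROI align over the pyramid
#'
#' Boxes are assigned to levels with the standard FPN heuristic
#' (k = floor(4 + log2(sqrt(wh)/224)), clamped to P2..P5) and sampled with
#' quantization-free bilinear interpolation to d x d.
#'
#' @param tape tape.
#' @param pyramid list P2..P6 of map nodes.
#' @param boxes n x 4 matrix in input coordinates.
#' @param d output side.
#' @return node of (d, d, C, n) patches.
#' @keywords internal
roiAlignPatches <- function(tape, pyramid, boxes, d) {
  if (any((boxes[, 3] - boxes[, 1]) <= 0 | (boxes[, 4] - boxes[, 2]) <= 0))
    fhcStop("fhcBadInput", "zero-area ROI")
  lv <- roiLevels(boxes)
  strides <- c(P2 = 4, P3 = 8, P4 = 16, P5 = 32)
  parts <- list(); ord <- list()
  for (k in 2:5) {
    idx <- which(lv == k)
    if (length(idx) == 0) next
    nm <- paste0("P", k)
    fb <- boxes[idx, , drop = FALSE] / strides[[nm]]
    feat <- pyramid[[nm]]
    f3 <- if (length(dim(feat$value)) == 4) {
      fv <- feat$value; dim(fv) <- dim(fv)[1:3]
      n2 <- addNode(tape, fv, parents = list(feat), vjp = function(gy) {
        dim(gy) <- c(dim(gy), 1L); list(gy)
      })
      n2
    } else feat
    parts[[length(parts) + 1]] <- agRoiAlign(tape, f3, fb, d)
    ord[[length(ord) + 1]] <- idx
  }
  order_all <- unlist(ord)
  agConcatN(tape, parts, order = order(order_all))
}

# classification + box heads on shared FCs
classBoxHead <- function(tape, patches, params, cfg) {
  flat <- agFlattenN(tape, patches)
  h <- agRelu(tape, agDense(tape, flat, params, "head.fc1"))
  h <- agRelu(tape, agDense(tape, h, params, "head.fc2"))
  cls <- if (cfg@includeClassHead) agDense(tape, h, params, "head.cls")
         else NULL
  box <- agDense(tape, h, params, "head.box")
  list(cls = cls, box = box)
}

# distance-field regression head; output (2^u d, 2^u d, 1, N)
distanceFieldHead <- function(tape, patches, params, cfg) {
  y <- patches
  for (i in 1:4) y <- cbr(tape, y, params, sprintf("df.conv%d", i))
  for (j in seq_len(cfg@nUpsamplings)) {
    if (cfg@upsamplingVariant == "upconv") {
      y <- agUpsample2(tape, y)
      y <- cbr2(tape, y, params, sprintf("df.up%d.convA", j))
      y <- cbr(tape, y, params, sprintf("df.up%d.convB", j))
      y <- cbr(tape, y, params, sprintf("df.up%d.convC", j))
    } else {
      y <- agRelu(tape, agBN(tape, agConvT2(tape, y, params,
                                            sprintf("df.tconv%d", j)),
                             params, sprintf("df.tconv%d.bn", j)))
    }
  }
  agConv(tape, y, params, "df.out", pad = 0L)   # linear 1x1
}

#' Full forward pass: detections with field patches
#'
#' Pyramid, RPN proposals, heads, per-class score threshold and NMS, field
#' patches computed on the final refined boxes. With
#' \code{includeClassHead = FALSE} detections are scored by RPN objectness.
#'
#' @param image (H, W) matrix in [0, 1] at network resolution.
#' @param params parameter list.
#' @param cfg a \code{\linkS4class{NetConfig}}.
#' @param maxDetections cap on returned detections.
#' @return list of detections: each \code{list(box, score, patch)} with
#'   \code{patch} a (2^u d) square matrix (values unclipped).
#' @export
fullForward <- function(image, params, cfg, maxDetections = 5L) {
  tape <- newTape()
  pyr <- buildFeaturePyramid(tape, image, params, cfg)
  shapes <- lapply(pyr, function(p) dim(p$value)[1:2])
  anchors <- generateAnchors(cfg, shapes)
  rpnOut <- rpnForwardNodes(tape, pyr, params)
  flat <- rpnFlatten(rpnOut)
  size <- nrow(image)
  prop <- proposeRois(anchors, flat$objectness, flat$deltas, size,
                      cfg@proposalNms, cfg@preNmsTest, cfg@postNmsTest)
  if (nrow(prop$boxes) == 0) return(list())
  patches <- roiAlignPatches(tape, pyr, prop$boxes, cfg@roiSize)
  heads <- classBoxHead(tape, patches, params, cfg)
  scores <- if (cfg@includeClassHead) {
    z <- heads$cls$value
    ez <- exp(z - apply(z, 1, max))
    (ez / rowSums(ez))[, 1]      # class 1 = head
  } else prop$scores
  refined <- clipBoxes(decodeBoxes(prop$boxes, heads$box$value), size)
  ok <- which(scores >= cfg@scoreThresh &
              (refined[, 3] - refined[, 1]) >= 1 &
              (refined[, 4] - refined[, 2]) >= 1)
  if (length(ok) == 0) return(list())
  keep <- ok[nmsBoxes(refined[ok, , drop = FALSE], scores[ok], cfg@detNms)]
  keep <- head(keep, maxDetections)
  fp <- distanceFieldHead(
    tape, roiAlignPatches(tape, pyr, refined[keep, , drop = FALSE],
                          cfg@roiSize), params, cfg)
  out <- vector("list", length(keep))
  P <- dim(fp$value)[1]
  for (i in seq_along(keep)) {
    out[[i]] <- list(box = refined[keep[i], ], score = scores[keep[i]],
                     patch = matrix(fp$value[, , 1, i], P, P))
  }
  out
}
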