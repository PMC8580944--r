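# Training: multi-task loss L = alpha*L_cls + beta*L_box + gamma*L_df,
# ROI target assignment, on-the-fly affine augmentation, and the three-stage
# freezing schedule (heads -> distance-field head -> full network) with SGD
# and momentum. The classification and box terms collect both the RPN and
# the head contributions so the L identity covers the jointly trained RPN.

#' Training configuration
#'
#' @slot lr numeric learning rate (0.001).
#' @slot momentum numeric (0.9).
#' @slot alpha,beta,gamma numeric loss weights (all 1).
#' @slot stageEpochs integer length 3: epochs for (heads, field head, full).
#' @slot seed integer; every source of randomness (initialization, ROI and
#'   anchor sampling, augmentation, epoch shuffling) flows from it.
#' @slot augScale,augTranslate,augRotate,augShear numeric augmentation
#'   ranges: scale factor bounds, translation as a fraction of the image
#'   side, rotation and shear in degrees.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", momentum = "numeric", alpha = "numeric",
                 beta = "numeric", gamma = "numeric", stageEpochs = "integer",
                 seed = "integer", augScale = "numeric",
                 augTranslate = "numeric", augRotate = "numeric",
                 augShear = "numeric"),
  validity = function(object) {
    if (any(c(object@alpha, object@beta, object@gamma) < 0))
      return("loss weights must be non-negative")
    if (length(object@stageEpochs) != 3 || any(object@stageEpochs < 0))
      return("stageEpochs must be 3 non-negative integers")
    TRUE
  })

#' @param lr,momentum optimizer settings.
#' @param alpha,beta,gamma loss weights.
#' @param stageEpochs epochs per stage (heads, field head, full).
#' @param seed RNG seed.
#' @param augScale,augTranslate,augRotate,augShear augmentation ranges
#'   (scale bounds; translation fraction; degrees).
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(lr = 0.001, momentum = 0.9, alpha = 1, beta = 1,
                        gamma = 1, stageEpochs = c(50L, 50L, 50L), seed = 1L,
                        augScale = c(0.9, 1.1), augTranslate = 0.05,
                        augRotate = 15, augShear = 8) {
  new("TrainConfig", lr = lr, momentum = momentum, alpha = alpha, beta = beta,
      gamma = gamma, stageEpochs = as.integer(stageEpochs),
      seed = as.integer(seed), augScale = augScale,
      augTranslate = augTranslate, augRotate = augRotate, augShear = augShear)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: lr=%g momentum=%g, weights (%g, %g, %g), stages %s, seed %d\n",
    object@lr, object@momentum, object@alpha, object@beta, object@gamma,
    paste(object@stageEpochs, collapse = "+"), object@seed))
})

#' Field-patch RMSE
#'
#' Root mean square error between predicted and target field patches,
#' averaged over ROIs. Zero iff identical.
#'
#' @param pred,target arrays of equal shape ((h, w) or (h, w, 1, N)).
#' @return scalar.
#' @export
fieldRmse <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    fhcStop("fhcBadInput", "field patch shapes differ")
  if (length(dim(pred)) == 2) return(sqrt(mean((pred - target)^2)))
  d <- dim(pred)
  n <- if (length(d) == 4) d[4] else 1
  diffs <- matrix(pred - target, ncol = n)
  mean(sqrt(colMeans(diffs^2)))
}

#' Combine component losses into the multi-task loss
#'
#' \code{L = alpha L_cls + beta L_box + gamma L_df}; the classification term
#' is dropped for configurations without the classification head.
#'
#' @param parts named list/vector with \code{cls}, \code{box}, \code{df}.
#' @param cfg a \code{\linkS4class{TrainConfig}}.
#' @param includeClassHead logical.
#' @return named numeric \code{c(L, cls, box, df)}.
#' @export
totalLoss <- function(parts, cfg, includeClassHead = TRUE) {
  cls <- if (includeClassHead) parts[["cls"]] else 0
  L <- cfg@alpha * cls + cfg@beta * parts[["box"]] + cfg@gamma * parts[["df"]]
  c(L = L, cls = cls, box = parts[["box"]], df = parts[["df"]])
}

# ---- target assignment ----------------------------------------------------

# RPN anchor labels for a single ground-truth box
rpnTargets <- function(anchors, gtBox, cfg) {
  ious <- boxIou(anchors$boxes, gtBox)[, 1]
  labels <- rep(NA_integer_, length(ious))          # NA = ignore
  labels[ious <= cfg@rpnNegIou] <- 0L
  labels[ious >= cfg@rpnPosIou] <- 1L
  labels[which.max(ious)] <- 1L                     # best anchor always positive
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  nPos <- min(length(pos), cfg@rpnBatch %/% 2)
  pos <- if (length(pos) > nPos) sample(pos, nPos) else pos
  nNeg <- min(length(neg), cfg@rpnBatch - length(pos))
  neg <- if (length(neg) > nNeg) sample(neg, nNeg) else neg
  list(pos = pos, neg = neg,
       posDeltas = encodeBoxes(anchors$boxes[pos, , drop = FALSE],
                               matrix(gtBox, length(pos), 4, byrow = TRUE)))
}

#' Assign head training targets to proposals
#'
#' Proposals with IoU >= 0.5 against the ground-truth box are positive;
#' sampling keeps at most \code{trainRoisPerImage} ROIs with a <= 1:3
#' positive:negative ratio. Each positive ROI gets a box-delta target and
#' (for up to \code{maxFieldRois}) a field-patch target: the ground-truth
#' field cropped to the ROI and bilinearly resized to the head output size.
#'
#' @param proposals n x 4 box matrix.
#' @param gtBox ground-truth box c(x1, y1, x2, y2).
#' @param gtField ground-truth field at network resolution.
#' @param cfg a \code{\linkS4class{NetConfig}}.
#' @return list: \code{rois}, \code{labels} (1 head / 0 background),
#'   \code{boxTargets} (positives), \code{posIdx}, \code{fieldIdx} (indices
#'   into rois), \code{fieldTargets} ((P, P, 1, nf) array).
#' @export
assignTargets <- function(proposals, gtBox, gtField, cfg) {
  if (is.null(gtBox) || is.null(gtField))
    fhcStop("fhcBadInput", "ground truth is required for target assignment")
  ious <- boxIou(proposals, gtBox)[, 1]
  pos <- which(ious >= cfg@headPosIou)
  neg <- which(ious < cfg@headPosIou)
  nPos <- min(length(pos), max(1L, cfg@trainRoisPerImage %/% 4))
  if (length(pos) > nPos) pos <- sample(pos, nPos)
  nNeg <- min(length(neg), cfg@trainRoisPerImage - length(pos))
  if (length(neg) > nNeg) neg <- sample(neg, nNeg)
  keep <- c(pos, neg)
  rois <- proposals[keep, , drop = FALSE]
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  boxTargets <- if (length(pos) > 0)
    encodeBoxes(rois[seq_along(pos), , drop = FALSE],
                matrix(gtBox, length(pos), 4, byrow = TRUE))
  else matrix(0, 0, 4)
  P <- as.integer(2^cfg@nUpsamplings * cfg@roiSize)
  fieldIdx <- head(seq_along(pos), cfg@maxFieldRois)
  ft <- if (length(fieldIdx) > 0) {
    arr <- array(0, c(P, P, 1, length(fieldIdx)))
    for (i in seq_along(fieldIdx)) {
      arr[, , 1, i] <- cropResizeField(gtField, rois[fieldIdx[i], ], P)
    }
    arr
  } else NULL
  list(rois = rois, labels = labels, boxTargets = boxTargets,
       posIdx = seq_along(pos), fieldIdx = fieldIdx, fieldTargets = ft)
}

# crop a field to a (continuous) box and resize to P x P, bilinear
cropResizeField <- function(field, box, P) {
  H <- nrow(field); W <- ncol(field)
  x1 <- max(0, floor(box[1])); y1 <- max(0, floor(box[2]))
  x2 <- min(W, ceiling(box[3])); y2 <- min(H, ceiling(box[4]))
  if (x2 - x1 < 1 || y2 - y1 < 1) return(matrix(0, P, P))
  sub <- field[(y1 + 1):y2, (x1 + 1):x2, drop = FALSE]
  cpp_resize_bilinear(sub, P, P)
}

# ---- augmentation ---------------------------------------------------------

#' Affine on-the-fly augmentation
#'
#' Applies one random affine transform (scale, translation, rotation, shear
#' about the image center) consistently to image and field; the box is
#' recomputed from the transformed field. If the head leaves the canvas the
#' transform is resampled (up to 10 tries), after which the sample is
#' returned unaugmented. Draws from the current R RNG state.
#'
#' @param sample list with \code{image}, \code{field} (matrices), \code{bbox}.
#' @param cfg a \code{\linkS4class{TrainConfig}}.
#' @return the augmented sample.
#' @export
augmentSample <- function(sample, cfg) {
  if (cfg@augScale[1] == 1 && cfg@augScale[2] == 1 &&
      cfg@augTranslate == 0 && cfg@augRotate == 0 && cfg@augShear == 0)
    return(sample)
  H <- nrow(sample$image); W <- ncol(sample$image)
  for (try in 1:10) {
    s <- runif(1, cfg@augScale[1], cfg@augScale[2])
    tx <- runif(1, -1, 1) * cfg@augTranslate * W
    ty <- runif(1, -1, 1) * cfg@augTranslate * H
    rot <- runif(1, -1, 1) * cfg@augRotate * pi / 180
    sh <- tan(runif(1, -1, 1) * cfg@augShear * pi / 180)
    # forward map about the image center: scale, shear, rotate, then shift
    A <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2) %*%
         matrix(c(1, 0, sh, 1), 2, 2) * s
    out <- applyAffineSample(sample, A, tx, ty)
    if (!is.null(out)) return(out)
  }
  sample
}

# apply one affine (2x2 matrix about the center + translation) to a sample;
# NULL when the transformed field leaves the canvas
applyAffineSample <- function(sample, A, tx, ty) {
  H <- nrow(sample$image); W <- ncol(sample$image)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  Ainv <- solve(A)
  M <- cbind(Ainv, c(cx, cy) - Ainv %*% c(cx + tx, cy + ty))
  fld <- cpp_warp_affine(sample$field, M, H, W)
  if (!any(fld > 0)) return(NULL)
  sample$image <- cpp_warp_affine(sample$image, M, H, W)
  sample$field <- fld
  sample$bbox <- fieldBBox(fld)
  sample
}

# ---- one optimization step ------------------------------------------------

# forward + all losses on one sample; returns loss nodes and the tape
lossForward <- function(sample, params, netCfg, trainCfg,
                        detachBackbone = FALSE) {
  tape <- newTape()
  pyr <- buildFeaturePyramid(tape, sample$image, params, netCfg)
  # while the backbone is frozen no gradient needs to flow below the pyramid
  if (detachBackbone)
    pyr <- lapply(pyr, function(p) constNode(tape, p$value))
  shapes <- lapply(pyr, function(p) dim(p$value)[1:2])
  anchors <- generateAnchors(netCfg, shapes)
  rpnOut <- rpnForwardNodes(tape, pyr, params)
  flat <- rpnFlatten(rpnOut)
  gtBox <- as.numeric(sample$bbox)
  rt <- rpnTargets(anchors, gtBox, netCfg)
  # gather sampled anchor logits/deltas from the per-level maps
  gatherRpn <- function(kind) {
    idx <- c(rt$pos, rt$neg)
    if (kind == "box") idx <- rt$pos
    lvl <- anchors$level[idx]
    nodes <- list(); vals <- list()
    offs <- c(0, cumsum(sapply(anchors$shapes, function(s) 3 * s[1] * s[2])))
    for (k in sort(unique(lvl))) {
      sel <- idx[lvl == k]
      local_i <- sel - offs[k - 1]
      nm <- paste0("P", k)
      node <- rpnOut[[nm]][[if (kind == "box") "box" else "obj"]]
      d <- dim(node$value)[1:2]
      cellh <- (local_i - 1) %% d[1]
      rest <- (local_i - 1) %/% d[1]
      cellw <- rest %% d[2]
      j <- rest %/% d[2]
      if (kind == "obj") {
        fidx <- cellh + d[1] * cellw + d[1] * d[2] * j + 1
        nodes[[length(nodes) + 1]] <- agGatherFlat(tape, node, fidx)
      } else {
        fidx <- as.vector(sapply(0:3, function(cc)
          cellh + d[1] * cellw + d[1] * d[2] * (4 * j + cc) + 1))
        g <- agGatherFlat(tape, node, fidx)
        g2 <- addNode(tape, matrix(g$value, ncol = 4), parents = list(g),
                      vjp = function(gy) list(as.vector(gy)))
        nodes[[length(nodes) + 1]] <- g2
      }
    }
    nodes
  }
  objNodes <- gatherRpn("obj")
  objCat <- if (length(objNodes) == 1) objNodes[[1]] else {
    vals <- unlist(lapply(objNodes, function(n) n$value))
    ls <- sapply(objNodes, function(n) length(n$value))
    at <- cumsum(c(0, ls))
    addNode(tape, vals, parents = objNodes, vjp = function(gy)
      lapply(seq_along(ls), function(i) gy[(at[i] + 1):at[i + 1]]))
  }
  # labels aligned with the per-level gather order (sorted by level)
  idxAll <- c(rt$pos, rt$neg)
  labAll <- c(rep(1, length(rt$pos)), rep(0, length(rt$neg)))
  ordLvl <- order(anchors$level[idxAll])
  # within-level order must match the gather (which keeps idx order)
  perLevelOrder <- unlist(lapply(sort(unique(anchors$level[idxAll])),
                                 function(k) which(anchors$level[idxAll] == k)))
  rpnClsLoss <- agSigmoidCE(tape, objCat, labAll[perLevelOrder])
  rpnBoxLoss <- if (length(rt$pos) > 0) {
    boxNodes <- gatherRpn("box")
    boxCat <- if (length(boxNodes) == 1) boxNodes[[1]] else {
      vals <- do.call(rbind, lapply(boxNodes, function(n) n$value))
      ls <- sapply(boxNodes, function(n) nrow(n$value))
      at <- cumsum(c(0, ls))
      addNode(tape, vals, parents = boxNodes, vjp = function(gy)
        lapply(seq_along(ls), function(i) gy[(at[i] + 1):at[i + 1], , drop = FALSE]))
    }
    lvlPos <- anchors$level[rt$pos]
    orderPos <- unlist(lapply(sort(unique(lvlPos)),
                              function(k) which(lvlPos == k)))
    agSmoothL1(tape, boxCat, rt$posDeltas[orderPos, , drop = FALSE])
  } else constNode(tape, 0)
  # proposals (detached) + the ground-truth box, then head targets
  prop <- proposeRois(anchors, flat$objectness, flat$deltas,
                      nrow(sample$image), netCfg@proposalNms,
                      netCfg@preNmsTrain, netCfg@postNmsTrain)
  proposals <- rbind(prop$boxes, gtBox)
  tg <- assignTargets(proposals, gtBox, sample$field, netCfg)
  patches <- roiAlignPatches(tape, pyr, tg$rois, netCfg@roiSize)
  heads <- classBoxHead(tape, patches, params, netCfg)
  headClsLoss <- if (netCfg@includeClassHead)
    agSoftmaxCE(tape, heads$cls, ifelse(tg$labels == 1L, 1L, 2L))
  else constNode(tape, 0)
  headBoxLoss <- if (length(tg$posIdx) > 0) {
    sel <- addNode(tape, heads$box$value[tg$posIdx, , drop = FALSE],
                   parents = list(heads$box), vjp = function(gy) {
                     g <- matrix(0, nrow(heads$box$value), 4)
                     g[tg$posIdx, ] <- gy
                     list(g)
                   })
    agSmoothL1(tape, sel, tg$boxTargets)
  } else constNode(tape, 0)
  dfLoss <- if (!is.null(tg$fieldTargets)) {
    fpatch <- agSelectN(tape, patches, tg$fieldIdx)
    fout <- distanceFieldHead(tape, fpatch, params, netCfg)
    agRMSE(tape, fout, tg$fieldTargets)
  } else constNode(tape, 0)
  clsNode <- agWeightedSum(tape, list(rpnClsLoss, headClsLoss), c(1, 1))
  boxNode <- agWeightedSum(tape, list(rpnBoxLoss, headBoxLoss), c(1, 1))
  L <- agWeightedSum(tape, list(clsNode, boxNode, dfLoss),
                     c(trainCfg@alpha, trainCfg@beta, trainCfg@gamma))
  list(tape = tape, L = L,
       parts = c(L = L$value, cls = clsNode$value, box = boxNode$value,
                 df = dfLoss$value))
}

sgdUpdate <- function(params, grads, vel, trainable, lr, momentum) {
  for (nm in names(grads)) {
    base <- sub("\\.(W|b|gamma|beta)$", "", nm)
    if (!any(startsWith(nm, trainable))) next
    v <- vel[[nm]]
    if (is.null(v)) v <- 0
    v <- momentum * v - lr * grads[[nm]]
    vel[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, vel = vel)
}

stagePrefixes <- function(stage) {
  switch(stage,
         c("rpn.", "head.", "df."),   # stage 1: heads, frozen backbone
         c("df."),                    # stage 2: distance-field head alone
         c(""))                       # stage 3: everything
}

#' Staged training loop
#'
#' Stage 1 trains the RPN and the three heads with a frozen backbone; stage
#' 2 trains the distance-field head alone (its loss decays more slowly than
#' the detection terms); stage 3 trains the whole network. SGD with
#' momentum, batch size 1. One checkpoint per epoch with the validation L.
#'
#' @param samples list of training samples (image, field, bbox).
#' @param valSamples validation samples for model selection.
#' @param netCfg a \code{\linkS4class{NetConfig}}.
#' @param trainCfg a \code{\linkS4class{TrainConfig}}.
#' @param verbose print per-epoch losses.
#' @return list with \code{checkpoints} (list of \code{list(params, stage,
#'   epoch, valL)}), \code{history} (data.frame epoch, stage, L, cls, box,
#'   df, valL), \code{params} (final), \code{netCfg}.
#' @export
stagedTraining <- function(samples, valSamples, netCfg, trainCfg,
                           verbose = FALSE) {
  if (length(samples) == 0) fhcStop("fhcBadInput", "empty training set")
  set.seed(trainCfg@seed)
  params <- initNetParams(netCfg)
  vel <- list()
  checkpoints <- list(list(params = params, stage = 0L, epoch = 0L,
                           valL = NA_real_))
  hist <- list()
  epochGlobal <- 0L
  for (stage in 1:3) {
    trainable <- stagePrefixes(stage)
    for (ep in seq_len(trainCfg@stageEpochs[stage])) {
      epochGlobal <- epochGlobal + 1L
      ord <- sample(length(samples))
      acc <- c(L = 0, cls = 0, box = 0, df = 0)
      for (i in ord) {
        s <- augmentSample(samples[[i]], trainCfg)
        fw <- lossForward(s, params, netCfg, trainCfg,
                          detachBackbone = stage < 3)
        grads <- backward(fw$tape, fw$L)
        upd <- sgdUpdate(params, grads, vel, trainable,
                         trainCfg@lr, trainCfg@momentum)
        params <- upd$params; vel <- upd$vel
        acc <- acc + fw$parts
      }
      acc <- acc / length(samples)
      valL <- validationLoss(valSamples, params, netCfg, trainCfg)
      checkpoints[[length(checkpoints) + 1]] <-
        list(params = params, stage = stage, epoch = epochGlobal, valL = valL)
      hist[[length(hist) + 1]] <-
        data.frame(epoch = epochGlobal, stage = stage, L = acc[["L"]],
                   cls = acc[["cls"]], box = acc[["box"]], df = acc[["df"]],
                   valL = valL)
      if (verbose)
        message(sprintf(
          "stage %d epoch %d: L=%.4f cls=%.4f box=%.4f df=%.4f val=%.4f",
          stage, epochGlobal, acc[["L"]], acc[["cls"]], acc[["box"]],
          acc[["df"]], valL))
    }
  }
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(0), stage = integer(0), L = numeric(0),
               cls = numeric(0), box = numeric(0), df = numeric(0),
               valL = numeric(0))
  list(checkpoints = checkpoints, history = history, params = params,
       netCfg = netCfg)
}

# validation L (no augmentation, no update)
validationLoss <- function(valSamples, params, netCfg, trainCfg) {
  if (length(valSamples) == 0) return(NA_real_)
  tot <- 0
  for (s in valSamples) {
    fw <- lossForward(s, params, netCfg, trainCfg)
    tot <- tot + fw$parts[["L"]]
  }
  tot / length(valSamples)
}

#' Select the best checkpoint by validation loss
#'
#' Argmin of validation L; ties break to the earliest epoch; checkpoints
#' without a validation loss (the initialization) are skipped unless nothing
#' else exists.
#'
#' @param checkpoints list from [stagedTraining()].
#' @param valLosses optional explicit validation losses (defaults to the
#'   \code{valL} recorded on each checkpoint).
#' @return the selected checkpoint.
#' @export
selectBest <- function(checkpoints, valLosses = NULL) {
  if (length(checkpoints) == 0) fhcStop("fhcBadInput", "no checkpoints")
  if (is.null(valLosses))
    valLosses <- sapply(checkpoints, function(c) c$valL)
  if (all(is.na(valLosses))) return(checkpoints[[1]])
  checkpoints[[which.min(valLosses)]]   # which.min takes the first minimum
}

#' Save / load a training log as CSV
#' @param history data.frame from [stagedTraining()].
#' @param path CSV path.
#' @export
writeTrainingLog <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}
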