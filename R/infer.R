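# End-to-end inference: predicted field pasted to image coordinates,
# thresholding, ellipse fit, HC in millimetres.

#' Predict the distance field for one image
#'
#' Runs the detector, keeps the top-scoring detection, resizes its field
#' patch to the detection box, pastes it into a zero canvas at network
#' resolution, clips to [0, 1], and maps the canvas back to source-image
#' coordinates through the inverse resize transform.
#'
#' @param image source grayscale matrix in [0, 1] (any size).
#' @param model list with \code{params} and \code{netCfg} (a trained
#'   checkpoint, or \code{list(params=, netCfg=)}).
#' @param transform optional precomputed \code{\linkS4class{ResizeTransform}}
#'   (with the already-resized image as \code{resized}).
#' @return list: \code{field} (source-size matrix), \code{detection}
#'   (box/score at network resolution).
#' @export
predictField <- function(image, model, transform = NULL) {
  cfg <- model$netCfg
  if (is.null(transform)) {
    rs <- resizeWithPadding(image, cfg@imageSize)
    net_img <- rs$image; tf <- rs$transform
  } else {
    net_img <- transform$resized; tf <- transform$transform
  }
  dets <- fullForward(net_img, model$params, cfg)
  if (length(dets) == 0)
    fhcStop("fhcNoDetection", "no detection above the score threshold")
  best <- dets[[which.max(sapply(dets, function(d) d$score))]]
  canvas <- matrix(0, cfg@imageSize, cfg@imageSize)
  bx <- best$box
  x1 <- max(0L, as.integer(round(bx[1]))); y1 <- max(0L, as.integer(round(bx[2])))
  x2 <- min(cfg@imageSize, as.integer(round(bx[3])))
  y2 <- min(cfg@imageSize, as.integer(round(bx[4])))
  if (x2 - x1 >= 1 && y2 - y1 >= 1) {
    patch <- cpp_resize_bilinear(best$patch, y2 - y1, x2 - x1)
    canvas[(y1 + 1):y2, (x1 + 1):x2] <- patch
  }
  canvas <- pmin(pmax(canvas, 0), 1)
  field <- if (tf@scale == 1 && tf@padRight == 0 && tf@padBottom == 0) canvas
           else fieldToSource(tf, canvas)
  field <- pmin(pmax(field, 0), 1)
  list(field = field, detection = best)
}

#' Delineate the head circumference in one image
#'
#' \code{predictField} -> threshold (0.9) -> field crest -> ellipse fit ->
#' perimeter -> HC in mm. Detection or fit failures propagate as
#' no-measurement records rather than errors.
#'
#' @param image source grayscale matrix in [0, 1].
#' @param mmPerPx pixel size in mm.
#' @param model trained model (list with \code{params}, \code{netCfg}).
#' @param threshold superlevel threshold (default 0.9).
#' @param ridge fit the one-pixel crest of the field (gradient non-maximum
#'   suppression inside the superlevel set)
#'   before fitting (default TRUE; see the methods vignette).
#' @param weighted weight fitted pixels by their field value.
#' @return an \code{\linkS4class{HCMeasurement}} (status \code{"ok"},
#'   \code{"no-head"} or \code{"fit-failure"}).
#' @export
delineate <- function(image, mmPerPx, model, threshold = 0.9, ridge = TRUE,
                      weighted = FALSE) {
  pf <- tryCatch(predictField(image, model), fhcNoDetection = function(e) NULL)
  if (is.null(pf)) return(noMeasurement("no-head", mmPerPx))
  measureField(pf$field, mmPerPx, threshold = threshold, ridge = ridge,
               weighted = weighted)
}

#' Measure HC from a (predicted or ground-truth) distance field
#'
#' The geometry half of [delineate()], usable with an oracle field.
#'
#' @inheritParams delineate
#' @param field distance field in source-image coordinates.
#' @return an \code{\linkS4class{HCMeasurement}}.
#' @export
measureField <- function(field, mmPerPx, threshold = 0.9, ridge = TRUE,
                         weighted = FALSE) {
  res <- tryCatch({
    pts <- thresholdField(field, threshold, weights = weighted)
    if (ridge) {
      # crest of the field inside the superlevel set (gradient non-maximum
      # suppression), thinned to one pixel; see the methods vignette
      crest <- cpp_field_ridge(field, threshold)
      rid <- skeletonizeContour(crest)
      idx <- which(rid == 1L, arr.ind = TRUE)
      if (nrow(idx) < 6)
        fhcStop("fhcNoDetection", "ridge too small to fit")
      w <- if (weighted) field[idx] else NULL
      pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)
      if (!is.null(w)) attr(pts, "weights") <- w
    }
    fitEllipse(pts)
  },
  fhcNoDetection = function(e) "no-head",
  fhcFitFailure = function(e) "fit-failure")
  if (is.character(res)) return(noMeasurement(res, mmPerPx))
  hcMeasurement(res, mmPerPx)
}

#' Delineate a list of samples and evaluate against their ground truth
#'
#' Convenience wrapper used by the desk-scale experiments: runs
#' [delineate()] on every sample and pairs it with the sample's
#' ground-truth measurement.
#'
#' @param samples list of samples (image, mmPerPx, gtEllipse).
#' @param model trained model.
#' @param ... passed to [delineate()].
#' @return the [evaluateDataset()] report.
#' @export
evaluateModel <- function(samples, model, ...) {
  pred <- list(); gt <- list()
  for (s in samples) {
    pred[[s$filename]] <- delineate(s$image, s$mmPerPx, model, ...)
    gt[[s$filename]] <- list(measurement = hcMeasurement(s$gtEllipse, s$mmPerPx),
                             shape = dim(s$image))
  }
  evaluateDataset(pred, gt)
}
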