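# Evaluation metrics: signed/absolute HC difference (mm), Hausdorff distance
# (mm), Dice similarity coefficient on filled-head masks.

#' Signed and absolute HC difference
#'
#' \code{DF = hc_pred - hc_gt} (a negative mean DF therefore reads as
#' under-estimation); \code{ADF = |DF|}. Both in mm.
#'
#' @param pred,gt \code{\linkS4class{HCMeasurement}} objects (or numeric HC
#'   lengths in mm).
#' @return named numeric \code{c(df, adf)}.
#' @export
metricDfAdf <- function(pred, gt) {
  hp <- if (is(pred, "HCMeasurement")) pred@hcMm else pred
  hg <- if (is(gt, "HCMeasurement")) gt@hcMm else gt
  df <- hp - hg
  c(df = df, adf = abs(df))
}

#' Filled-ellipse mask
#'
#' @param e an \code{\linkS4class{Ellipse}}.
#' @param shape integer \code{c(rows, cols)}.
#' @return logical matrix, TRUE inside the ellipse.
#' @export
fillEllipseMask <- function(e, shape) {
  H <- shape[1]; W <- shape[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  ct <- cos(e@theta); st <- sin(e@theta)
  dx <- xs - e@cx; dy <- ys - e@cy
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  (u / e@a)^2 + (v / e@b)^2 <= 1
}

#' Dice similarity coefficient of two binary masks
#'
#' \code{2 |A intersect B| / (|A| + |B|)}.
#'
#' @param a,b logical/0-1 matrices of equal dim.
#' @return fraction in \code{[0, 1]}.
#' @export
metricDscMasks <- function(a, b) {
  a <- a != 0; b <- b != 0
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) fhcStop("fhcEmptyMask", "both masks are empty")
  2 * sum(a & b) / (sa + sb)
}

#' Dice similarity coefficient of two ellipses (full-head masks)
#'
#' Rasterizes both ellipses as filled masks on \code{shape} and computes the
#' Dice coefficient.
#'
#' @param pred,gt \code{\linkS4class{Ellipse}} objects.
#' @param shape integer \code{c(rows, cols)}.
#' @return fraction in \code{[0, 1]}.
#' @export
metricDsc <- function(pred, gt, shape) {
  metricDscMasks(fillEllipseMask(pred, shape), fillEllipseMask(gt, shape))
}

#' Hausdorff distance between two ellipse contours, in mm
#'
#' Classic symmetric (max-min) Hausdorff distance between densely sampled
#' contours.
#'
#' @param pred,gt \code{\linkS4class{Ellipse}} objects.
#' @param mmPerPx pixel size, mm.
#' @param n contour samples per ellipse (default 3600).
#' @return distance in mm.
#' @export
metricHd <- function(pred, gt, mmPerPx = 1, n = 3600L) {
  cpp_hausdorff(ellipsePoints(pred, n), ellipsePoints(gt, n)) * mmPerPx
}

#' Evaluate a set of predictions against ground truth
#'
#' Inputs are named lists keyed by filename; each ground-truth element is a
#' list with \code{measurement} (\code{\linkS4class{HCMeasurement}}) and
#' \code{shape}; predictions are \code{HCMeasurement}s (possibly
#' no-measurement records, which are counted separately and excluded from the
#' aggregate statistics).
#'
#' @param pred named list of predicted \code{HCMeasurement}s.
#' @param gt named list of ground-truth entries.
#' @return list with \code{perImage} (data.frame: filename, df, adf, hd, dsc),
#'   \code{summary} (mean and sd of each metric), and \code{nFailed}.
#' @export
evaluateDataset <- function(pred, gt) {
  if (!setequal(names(pred), names(gt)))
    fhcStop("fhcBadInput", "prediction and ground-truth filename keys differ")
  keys <- sort(names(gt))
  rows <- lapply(keys, function(k) {
    g <- gt[[k]]; p <- pred[[k]]
    if (measurementStatus(p) != "ok")
      return(data.frame(filename = k, df = NA_real_, adf = NA_real_,
                        hd = NA_real_, dsc = NA_real_,
                        status = measurementStatus(p)))
    da <- metricDfAdf(p, g$measurement)
    data.frame(filename = k, df = da[["df"]], adf = da[["adf"]],
               hd = metricHd(fittedEllipse(p), fittedEllipse(g$measurement),
                             p@mmPerPx),
               dsc = metricDsc(fittedEllipse(p), fittedEllipse(g$measurement),
                               g$shape),
               status = "ok")
  })
  perImage <- do.call(rbind, rows)
  ok <- perImage$status == "ok"
  agg <- function(v) c(mean = mean(v[ok]), sd = if (sum(ok) > 1) sd(v[ok]) else 0)
  summary <- rbind(df = agg(perImage$df), adf = agg(perImage$adf),
                   hd = agg(perImage$hd), dsc = agg(perImage$dsc))
  list(perImage = perImage, summary = summary, nFailed = sum(!ok))
}
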