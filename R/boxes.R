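# Box utilities: IoU, the standard (dx, dy, dw, dh) log-space delta encoding,
# greedy non-maximum suppression, clipping. Boxes are rows (x1, y1, x2, y2),
# half-open, 0-based.

#' Intersection-over-union between two sets of boxes
#' @param a,b matrices with columns x1, y1, x2, y2.
#' @return \code{nrow(a) x nrow(b)} IoU matrix.
#' @export
boxIou <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  ix1 <- outer(a[, 1], b[, 1], pmax); iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin); iy2 <- outer(a[, 4], b[, 4], pmin)
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  areaA <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(areaA, areaB, "+") - inter)
}

#' Encode target boxes relative to reference boxes
#'
#' \code{dx = (cx_t - cx_r)/w_r}, \code{dy = (cy_t - cy_r)/h_r},
#' \code{dw = log(w_t/w_r)}, \code{dh = log(h_t/h_r)}.
#' @param ref,target box matrices (rows aligned).
#' @return matrix of deltas.
#' @export
encodeBoxes <- function(ref, target) {
  ref <- rbind(ref); target <- rbind(target)
  wr <- ref[, 3] - ref[, 1]; hr <- ref[, 4] - ref[, 2]
  wt <- target[, 3] - target[, 1]; ht <- target[, 4] - target[, 2]
  cbind((target[, 1] + wt / 2 - ref[, 1] - wr / 2) / wr,
        (target[, 2] + ht / 2 - ref[, 2] - hr / 2) / hr,
        log(wt / wr), log(ht / hr))
}

#' Apply deltas to reference boxes (inverse of [encodeBoxes()])
#' @param ref box matrix.
#' @param deltas delta matrix (rows aligned with \code{ref}).
#' @export
decodeBoxes <- function(ref, deltas) {
  ref <- rbind(ref); deltas <- rbind(deltas)
  wr <- ref[, 3] - ref[, 1]; hr <- ref[, 4] - ref[, 2]
  cx <- ref[, 1] + wr / 2 + deltas[, 1] * wr
  cy <- ref[, 2] + hr / 2 + deltas[, 2] * hr
  w <- wr * exp(pmin(deltas[, 3], 8)); h <- hr * exp(pmin(deltas[, 4], 8))
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

clipBoxes <- function(boxes, size) {
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), size)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), size)
  boxes
}

#' Greedy IoU-based non-maximum suppression
#' @param boxes box matrix.
#' @param scores vector of scores.
#' @param thresh IoU threshold above which lower-scored boxes are removed.
#' @return indices of the kept boxes, in decreasing score order.
#' @export
nmsBoxes <- function(boxes, scores, thresh, maxKeep = nrow(rbind(boxes))) {
  cpp_nms(rbind(boxes), scores, thresh, as.integer(maxKeep))
}
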