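# Ground-truth construction: contour rasterization, skeletonization,
# Gaussian-of-distance regression fields, bounding boxes, canonical resize.
#
# Raster conventions used throughout the package: a raster is an H x W R
# matrix indexed [row, col]; exported point/box coordinates are 0-based with
# x along columns and y along rows; boxes are half-open [x1, x2) x [y1, y2).

#' Sample points along an ellipse contour
#'
#' @param e an \code{\linkS4class{Ellipse}}.
#' @param n number of parametric samples.
#' @return n x 2 matrix of (x, y) coordinates.
#' @export
ellipsePoints <- function(e, n = 720) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ct <- cos(e@theta); st <- sin(e@theta)
  px <- e@a * cos(t); py <- e@b * sin(t)
  cbind(x = e@cx + px * ct - py * st, y = e@cy + px * st + py * ct)
}

#' Rasterize an ellipse contour
#'
#' Draws the contour with the given line width on an \code{height x width}
#' canvas, matching the annotation convention of 2-px-wide ellipse outlines.
#' A pixel is on when its center lies within \code{lineWidth / 2} of the
#' (densely sampled) analytic contour.
#'
#' @param e an \code{\linkS4class{Ellipse}}.
#' @param height,width canvas size, pixels.
#' @param lineWidth contour width, pixels (default 2).
#' @return integer 0/1 matrix of dim \code{c(height, width)}.
#' @export
rasterizeEllipse <- function(e, height, width, lineWidth = 2) {
  stopifnot(height >= 1, width >= 1, lineWidth >= 1)
  validObject(e)
  n <- max(720L, ceiling(ellipsePerimeter(e) / 0.2))
  pts <- ellipsePoints(e, n)
  hw <- lineWidth / 2
  # window of interest around the contour (1-based row/col on the canvas)
  r0 <- max(1, floor(min(pts[, "y"]) - hw) + 1)
  r1 <- min(height, ceiling(max(pts[, "y"]) + hw) + 1)
  c0 <- max(1, floor(min(pts[, "x"]) - hw) + 1)
  c1 <- min(width, ceiling(max(pts[, "x"]) + hw) + 1)
  if (r0 > r1 || c0 > c1)
    fhcStop("fhcEmptyAnnotation", "ellipse contour lies entirely outside the canvas")
  # candidate prefilter: mark nearest pixels of the dense samples, take an
  # EDT band one pixel wider than the line, then measure the exact distance
  # from candidate pixel centers to the continuous contour samples
  wh <- r1 - r0 + 1; ww <- c1 - c0 + 1
  rows <- round(pts[, "y"]) + 1 - (r0 - 1)
  cols <- round(pts[, "x"]) + 1 - (c0 - 1)
  keep <- rows >= 1 & rows <= wh & cols >= 1 & cols <= ww
  if (!any(keep))
    fhcStop("fhcEmptyAnnotation", "ellipse contour lies entirely outside the canvas")
  marked <- matrix(0L, wh, ww)
  marked[cbind(rows[keep], cols[keep])] <- 1L
  dd <- EBImage::distmap(1 - marked)
  cand <- which(dd <= hw + 1.5, arr.ind = TRUE)
  qx <- cand[, 2] - 1 + (c0 - 1)   # back to 0-based canvas coords
  qy <- cand[, 1] - 1 + (r0 - 1)
  dexact <- cpp_min_dist_points(qx, qy, pts[, "x"], pts[, "y"])
  on <- dexact <= hw
  if (!any(on))
    fhcStop("fhcEmptyAnnotation", "ellipse contour lies entirely outside the canvas")
  mask <- matrix(0L, height, width)
  mask[cbind(qy[on] + 1, qx[on] + 1)] <- 1L
  mask
}

#' Skeletonize a binary contour mask
#'
#' Morphological thinning (Zhang-Suen, with a post-pass that removes
#' redundant pixels of residual 2x2 blocks when deletion preserves local
#' connectivity). A closed input ring thins to a closed one-pixel-wide ring;
#' an already one-pixel-wide curve is a fixed point.
#'
#' @param mask integer/logical 0/1 matrix, non-empty.
#' @return integer 0/1 matrix of the same dim.
#' @export
skeletonizeContour <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) fhcStop("fhcEmptyMask", "cannot skeletonize an empty mask")
  # thin on the cropped foreground window (1px margin), then re-embed
  r0 <- max(1, min(idx[, 1]) - 1); r1 <- min(nrow(m), max(idx[, 1]) + 1)
  c0 <- max(1, min(idx[, 2]) - 1); c1 <- min(ncol(m), max(idx[, 2]) + 1)
  thin <- cpp_thin(m[r0:r1, c0:c1, drop = FALSE])
  out <- matrix(0L, nrow(m), ncol(m))
  out[r0:r1, c0:c1] <- thin
  out
}

#' Build the Gaussian distance-field regression target
#'
#' \code{F(p) = exp(-d(p)^2 / (2 sigma^2))} with \code{sigma = r/2} and
#' \code{d(p)} the Euclidean distance from pixel p to the nearest skeleton
#' pixel; outside the support band (\code{d > r/2} by default, \code{d > r}
#' for \code{support = "full"}) the field is exactly 0. The peak value is
#' exactly 1 on skeleton pixels.
#'
#' @param skel 0/1 skeleton matrix, non-empty.
#' @param cfg a \code{\linkS4class{FieldConfig}}.
#' @return numeric matrix in \code{[0, 1]} of the same dim.
#' @export
buildDistanceField <- function(skel, cfg = fieldConfig()) {
  s <- (skel != 0) * 1L
  if (!any(s == 1L))
    fhcStop("fhcEmptyMask", "cannot build a distance field from an empty skeleton")
  validObject(cfg)
  d <- EBImage::distmap(1 - s)
  d <- matrix(as.numeric(d), nrow(s), ncol(s))
  sigma <- cfg@r / 2
  supp <- if (cfg@support == "half") cfg@r / 2 else cfg@r
  f <- exp(-d^2 / (2 * sigma^2))
  f[d > supp] <- 0
  f
}

#' Minimal bounding box of a field's support
#'
#' Smallest axis-aligned half-open box \code{c(x1, y1, x2, y2)} (0-based)
#' containing every pixel with \code{F > 0}; each side touches at least one
#' such pixel.
#'
#' @param field numeric matrix.
#' @return numeric length-4 vector \code{c(x1, y1, x2, y2)}.
#' @export
fieldBBox <- function(field) {
  idx <- which(field > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) fhcStop("fhcEmptyMask", "field has no non-zero pixel")
  c(x1 = min(idx[, 2]) - 1, y1 = min(idx[, 1]) - 1,
    x2 = max(idx[, 2]), y2 = max(idx[, 1]))
}

#' Resize a grayscale image to a square canvas with zero padding
#'
#' The longer side is scaled to \code{target}; the shorter side scales by the
#' same factor (rounded to the nearest pixel) and zeros pad the right/bottom,
#' so the aspect ratio is preserved. Interpolation is bilinear for images and
#' fields, nearest for masks.
#'
#' @param image numeric matrix (rows x cols).
#' @param target side of the square output (default 512).
#' @param kind \code{"image"}/\code{"field"} (bilinear) or \code{"mask"}
#'   (nearest).
#' @return list with elements \code{image} (target x target matrix) and
#'   \code{transform} (a \code{\linkS4class{ResizeTransform}}).
#' @export
resizeWithPadding <- function(image, target = 512L, kind = c("image", "field", "mask")) {
  kind <- match.arg(kind)
  if (!is.matrix(image) || nrow(image) == 0 || ncol(image) == 0)
    fhcStop("fhcEmptyMask", "empty image")
  H <- nrow(image); W <- ncol(image)
  scale <- target / max(H, W)
  newH <- if (H >= W) as.integer(target) else as.integer(round(H * scale))
  newW <- if (W >= H) as.integer(target) else as.integer(round(W * scale))
  resized <- if (newH == H && newW == W) image
             else if (kind == "mask") cpp_resize_nearest(image, newH, newW)
             else cpp_resize_bilinear(image, newH, newW)
  out <- matrix(0, target, target)
  out[1:newH, 1:newW] <- resized
  tf <- new("ResizeTransform", scale = scale,
            padRight = as.integer(target - newW),
            padBottom = as.integer(target - newH),
            srcShape = c(H, W), dstShape = c(as.integer(target), as.integer(target)))
  list(image = out, transform = tf)
}

#' Map point coordinates through a ResizeTransform
#'
#' Points use the half-pixel-center convention so that a round trip through
#' the forward and inverse maps returns to within one pixel.
#'
#' @param tf a \code{\linkS4class{ResizeTransform}}.
#' @param pts n x 2 matrix of (x, y), 0-based.
#' @param inverse map from the resized canvas back to source coordinates.
#' @return n x 2 matrix.
#' @export
transformPoints <- function(tf, pts, inverse = FALSE) {
  pts <- rbind(pts)
  s <- if (inverse) 1 / tf@scale else tf@scale
  cbind((pts[, 1] + 0.5) * s - 0.5, (pts[, 2] + 0.5) * s - 0.5)
}

#' Map a box through a ResizeTransform
#' @inheritParams transformPoints
#' @param box numeric \code{c(x1, y1, x2, y2)}.
#' @export
transformBox <- function(tf, box, inverse = FALSE) {
  s <- if (inverse) 1 / tf@scale else tf@scale
  unname(box * s)
}

#' Map a field on the resized canvas back to source-image coordinates
#'
#' Crops the zero-padded strip and resizes the content region back to the
#' source shape (bilinear).
#'
#' @param tf a \code{\linkS4class{ResizeTransform}}.
#' @param field matrix of dim \code{dstShape}.
#' @return matrix of dim \code{srcShape}.
#' @export
fieldToSource <- function(tf, field) {
  ch <- tf@dstShape[1] - tf@padBottom
  cw <- tf@dstShape[2] - tf@padRight
  content <- field[1:ch, 1:cw, drop = FALSE]
  cpp_resize_bilinear(content, tf@srcShape[1], tf@srcShape[2])
}

#' Full ground-truth targets for one annotation
#'
#' Convenience wrapper: rasterized contour -> skeleton -> distance field ->
#' bounding box.
#'
#' @param e ground-truth \code{\linkS4class{Ellipse}}.
#' @param height,width canvas size.
#' @param cfg a \code{\linkS4class{FieldConfig}}.
#' @return list with \code{contour}, \code{skeleton}, \code{field},
#'   \code{bbox}.
#' @export
buildTargets <- function(e, height, width, cfg = fieldConfig()) {
  contour <- rasterizeEllipse(e, height, width)
  skel <- skeletonizeContour(contour)
  field <- buildDistanceField(skel, cfg)
  list(contour = contour, skeleton = skel, field = field,
       bbox = fieldBBox(field))
}
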