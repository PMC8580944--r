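#' @useDynLib fetalHC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rgamma quantile median sd integrate qnorm pnorm
#' @importFrom utils write.csv read.csv
NULL

# internal: typed conditions so callers can distinguish failure modes
fhcStop <- function(class, msg, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "fhcError", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

#' Ellipse parameters in pixel coordinates
#'
#' Canonical parametrization of the head-circumference ellipse: center
#' (\code{cx}, \code{cy}), semi-major axis \code{a}, semi-minor axis \code{b}
#' (pixels) and orientation \code{theta} (radians, counter-clockwise from the
#' +x axis). The canonical form has \code{a >= b > 0} and
#' \code{theta} in \code{[0, pi)}; a circle (\code{a == b}) is reported with
#' \code{theta == 0}. Coordinates are 0-based with x along image columns and
#' y along image rows.
#'
#' @slot cx,cy numeric center, pixels (0-based image coordinates).
#' @slot a,b numeric semi-major / semi-minor axis lengths, pixels.
#' @slot theta numeric orientation, radians in \code{[0, pi)}.
#' @export
setClass("Ellipse",
  representation(cx = "numeric", cy = "numeric", a = "numeric",
                 b = "numeric", theta = "numeric"),
  validity = function(object) {
    if (length(object@cx) != 1 || length(object@cy) != 1 ||
        length(object@a) != 1 || length(object@b) != 1 ||
        length(object@theta) != 1)
      return("all slots must be scalar")
    if (!all(is.finite(c(object@cx, object@cy, object@a, object@b,
                         object@theta))))
      return("all slots must be finite")
    if (object@b <= 0) return("axes must be positive")
    if (object@a < object@b) return("canonical form requires a >= b")
    if (object@theta < 0 || object@theta >= pi)
      return("theta must lie in [0, pi)")
    TRUE
  })

#' Construct an Ellipse, canonicalizing the parametrization
#'
#' Accepts any (a, b, theta); if \code{a < b} the axes are swapped and the
#' orientation rotated by pi/2, theta is wrapped to \code{[0, pi)}, and a
#' circle gets \code{theta = 0}.
#'
#' @param cx,cy center, pixels (0-based).
#' @param a,b axis lengths, pixels.
#' @param theta orientation, radians.
#' @return An \code{\linkS4class{Ellipse}}.
#' @examples
#' ellipse(250, 300, 120, 80, pi / 6)
#' @export
ellipse <- function(cx, cy, a, b, theta = 0) {
  if (a < b) { tmp <- a; a <- b; b <- tmp; theta <- theta + pi / 2 }
  theta <- theta %% pi
  if (isTRUE(all.equal(a, b, tolerance = 1e-12))) theta <- 0
  new("Ellipse", cx = cx, cy = cy, a = a, b = b, theta = theta)
}

setMethod("show", "Ellipse", function(object) {
  cat(sprintf(
    "Ellipse: center (%.2f, %.2f) px, semi-axes a=%.2f b=%.2f px, theta=%.4f rad\n",
    object@cx, object@cy, object@a, object@b, object@theta))
})

#' Distance-field construction parameters
#'
#' The regression ground truth is a Gaussian of the Euclidean distance to the
#' skeletonized contour: F(p) = exp(-d(p)^2 / (2 sigma^2)) with
#' sigma = r/2. \code{support} fixes the truncation rule: \code{"half"}
#' truncates at d <= r/2 (a band of total thickness r, edge value
#' exp(-1/2) ~ 0.607), \code{"full"} at d <= r.
#'
#' @slot r numeric band thickness in pixels (default 100).
#' @slot support character, \code{"half"} or \code{"full"}.
#' @export
setClass("FieldConfig",
  representation(r = "numeric", support = "character"),
  validity = function(object) {
    if (length(object@r) != 1 || !is.finite(object@r) || object@r < 2)
      return("r must be a finite scalar >= 2")
    if (!object@support %in% c("half", "full"))
      return("support must be 'half' or 'full'")
    TRUE
  })

#' @param r band thickness, pixels.
#' @param support truncation rule, \code{"half"} (d <= r/2) or \code{"full"}.
#' @rdname FieldConfig-class
#' @export
fieldConfig <- function(r = 100, support = c("half", "full")) {
  new("FieldConfig", r = r, support = match.arg(support))
}

setMethod("show", "FieldConfig", function(object) {
  cat(sprintf("FieldConfig: r=%g px (sigma=%g), support d <= %s\n",
              object@r, object@r / 2,
              if (object@support == "half") "r/2" else "r"))
})

#' Record of a padded aspect-preserving resize
#'
#' Maps a source image of shape \code{srcShape} (rows, cols) to a square
#' canvas of shape \code{dstShape}: the longer side is scaled to the target,
#' the shorter side by the same factor, and zeros pad the right/bottom.
#' Invertible on the unpadded region.
#'
#' @slot scale numeric scale factor applied to both axes.
#' @slot padRight,padBottom integer pixels of zero padding.
#' @slot srcShape,dstShape integer (rows, cols).
#' @export
setClass("ResizeTransform",
  representation(scale = "numeric", padRight = "integer",
                 padBottom = "integer", srcShape = "integer",
                 dstShape = "integer"),
  validity = function(object) {
    if (object@scale <= 0) return("scale must be positive")
    if (any(object@padRight < 0, object@padBottom < 0))
      return("padding must be non-negative")
    TRUE
  })

setMethod("show", "ResizeTransform", function(object) {
  cat(sprintf(
    "ResizeTransform: %dx%d -> %dx%d, scale %.4f, pad right %d bottom %d\n",
    object@srcShape[1], object@srcShape[2], object@dstShape[1],
    object@dstShape[2], object@scale, object@padRight, object@padBottom))
})

#' A head-circumference measurement
#'
#' Couples the fitted ellipse with its perimeter in pixels and physical HC
#' length in mm (\code{hcMm = perimeterPx * mmPerPx}). \code{status} is
#' \code{"ok"} for a successful measurement; failed inferences propagate as
#' no-measurement records with status \code{"no-head"} or
#' \code{"fit-failure"} and NA numeric slots.
#'
#' @slot perimeterPx,hcMm,mmPerPx numeric.
#' @slot params an \code{\linkS4class{Ellipse}} (a zero-area placeholder for
#'   failed records).
#' @slot status character.
#' @export
setClass("HCMeasurement",
  representation(perimeterPx = "numeric", hcMm = "numeric",
                 params = "Ellipse", mmPerPx = "numeric",
                 status = "character"),
  validity = function(object) {
    if (!object@status %in% c("ok", "no-head", "fit-failure"))
      return("status must be ok / no-head / fit-failure")
    if (object@status == "ok") {
      if (!is.finite(object@hcMm) || object@hcMm <= 0)
        return("hcMm must be positive for an ok measurement")
      if (abs(object@hcMm - object@perimeterPx * object@mmPerPx) >
          1e-6 * max(1, object@hcMm))
        return("hcMm must equal perimeterPx * mmPerPx")
    }
    TRUE
  })

#' @param params fitted \code{\linkS4class{Ellipse}}.
#' @param mmPerPx pixel size, mm.
#' @rdname HCMeasurement-class
#' @export
hcMeasurement <- function(params, mmPerPx) {
  p <- ellipsePerimeter(params)
  new("HCMeasurement", perimeterPx = p, hcMm = p * mmPerPx, params = params,
      mmPerPx = mmPerPx, status = "ok")
}

noMeasurement <- function(status, mmPerPx = NA_real_) {
  new("HCMeasurement", perimeterPx = NA_real_, hcMm = NA_real_,
      params = new("Ellipse", cx = 0, cy = 0, a = 1, b = 1, theta = 0),
      mmPerPx = mmPerPx, status = status)
}

setMethod("show", "HCMeasurement", function(object) {
  if (object@status == "ok") {
    cat(sprintf("HCMeasurement: HC = %.2f mm (%.1f px at %.4f mm/px)\n",
                object@hcMm, object@perimeterPx, object@mmPerPx))
  } else {
    cat(sprintf("HCMeasurement: no measurement (%s)\n", object@status))
  }
})

#' Accessors
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ellipseCenter", function(x) standardGeneric("ellipseCenter"))
#' @rdname accessors
#' @export
setMethod("ellipseCenter", "Ellipse", function(x) c(x = x@cx, y = x@cy))
#' @rdname accessors
#' @export
setGeneric("semiAxes", function(x) standardGeneric("semiAxes"))
#' @rdname accessors
#' @export
setMethod("semiAxes", "Ellipse", function(x) c(a = x@a, b = x@b))
#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname accessors
#' @export
setMethod("orientation", "Ellipse", function(x) x@theta)
#' @rdname accessors
#' @export
setGeneric("hcMm", function(x) standardGeneric("hcMm"))
#' @rdname accessors
#' @export
setMethod("hcMm", "HCMeasurement", function(x) x@hcMm)
#' @rdname accessors
#' @export
setGeneric("measurementStatus", function(x) standardGeneric("measurementStatus"))
#' @rdname accessors
#' @export
setMethod("measurementStatus", "HCMeasurement", function(x) x@status)
#' @rdname accessors
#' @export
setGeneric("fittedEllipse", function(x) standardGeneric("fittedEllipse"))
#' @rdname accessors
#' @export
setMethod("fittedEllipse", "HCMeasurement", function(x) x@params)
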