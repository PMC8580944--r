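# Ellipse fitting on thresholded distance-field pixels and HC length.

#' Threshold a distance field into a point set
#'
#' Returns the (x, y) coordinates (0-based, full-image frame) of all pixels
#' with \code{F >= t}.
#'
#' @param field numeric matrix in \code{[0, 1]}.
#' @param t threshold in (0, 1); the delineation pipeline uses 0.9.
#' @param weights if TRUE, attach the field values as a \code{"weights"}
#'   attribute for weighted fitting.
#' @return n x 2 matrix of (x, y); error of class \code{fhcNoDetection} when
#'   fewer than 6 pixels survive.
#' @export
thresholdField <- function(field, t = 0.9, weights = FALSE) {
  stopifnot(t > 0, t < 1)
  idx <- which(field >= t, arr.ind = TRUE)
  if (nrow(idx) < 6)
    fhcStop("fhcNoDetection",
            sprintf("only %d pixels at or above threshold %g", nrow(idx), t))
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  if (weights) attr(pts, "weights") <- field[idx]
  pts
}

#' Least-squares ellipse fit (non-iterative)
#'
#' Unconstrained, non-iterative least squares on the conic
#' \code{x^2 + B xy + C y^2 + D x + E y + F = 0} (the coefficient of
#' \code{x^2} is normalized to 1), solved in one linear system -- no
#' iteration, no constraint matrix. The solution is exact for noise-free
#' samples of an ellipse. Degenerate input (collinear points, rank-deficient
#' system) or a fitted conic that is not an ellipse raise an error of class
#' \code{fhcFitFailure}.
#'
#' @param points n x 2 matrix of (x, y), n >= 6.
#' @param weights optional per-point non-negative weights (default: the
#'   \code{"weights"} attribute of \code{points}, if any, else unweighted).
#' @return an \code{\linkS4class{Ellipse}} in canonical form.
#' @examples
#' e <- ellipse(250, 300, 120, 80, pi / 6)
#' fitEllipse(ellipsePoints(e, 200))
#' @export
fitEllipse <- function(points, weights = NULL) {
  pts <- rbind(points)
  if (is.null(weights)) weights <- attr(points, "weights")
  if (nrow(unique(pts)) < 6)
    fhcStop("fhcFitFailure", "at least 6 distinct points are required")
  if (!all(is.finite(pts)))
    fhcStop("fhcFitFailure", "non-finite coordinates")
  x <- pts[, 1]; y <- pts[, 2]
  # centre/scale for conditioning; the conic transforms back exactly
  mx <- mean(x); my <- mean(y)
  s <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (s < .Machine$double.eps)
    fhcStop("fhcFitFailure", "degenerate point set")
  xs <- (x - mx) / s; ys <- (y - my) / s
  M <- cbind(xs * ys, ys^2, xs, ys, 1)
  rhs <- -xs^2
  if (!is.null(weights)) {
    w <- sqrt(pmax(weights, 0))
    M <- M * w; rhs <- rhs * w
  }
  qrm <- qr(M)
  if (qrm$rank < 5)
    fhcStop("fhcFitFailure", "degenerate (collinear or rank-deficient) input")
  beta <- unname(qr.coef(qrm, rhs))
  # conic in scaled frame: xs^2 + B xs ys + C ys^2 + D xs + E ys + F = 0
  A <- 1; B <- beta[1]; C <- beta[2]; D <- beta[3]; E <- beta[4]; F <- beta[5]
  # undo scaling: xs = (x - mx)/s
  A2 <- A / s^2; B2 <- B / s^2; C2 <- C / s^2
  D2 <- D / s - 2 * A * mx / s^2 - B * my / s^2
  E2 <- E / s - 2 * C * my / s^2 - B * mx / s^2
  F2 <- F + A * mx^2 / s^2 + B * mx * my / s^2 + C * my^2 / s^2 -
        D * mx / s - E * my / s
  conicToEllipse(c(A2, B2, C2, D2, E2, F2))
}

# convert general conic coefficients (A, B, C, D, E, F) for
# A x^2 + B xy + C y^2 + D x + E y + F = 0 into canonical ellipse parameters
conicToEllipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0)
    fhcStop("fhcFitFailure", "fitted conic is not an ellipse")
  cx <- (2 * C * D - B * E) / disc
  cy <- (2 * A * E - B * D) / disc
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(Q, symmetric = TRUE)
  lam <- ev$values              # decreasing
  ax2 <- -Fc / lam
  if (any(!is.finite(ax2)) || any(ax2 <= 0))
    fhcStop("fhcFitFailure", "fitted conic is not a real ellipse")
  # smaller eigenvalue -> larger axis; its eigenvector gives the major axis
  a <- sqrt(ax2[2]); b <- sqrt(ax2[1])
  vmaj <- ev$vectors[, 2]
  theta <- atan2(vmaj[2], vmaj[1])
  ellipse(cx, cy, a, b, theta)
}

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' \code{h = ((a - b) / (a + b))^2};
#' \code{P = pi (a + b) (1 + 3h / (10 + sqrt(4 - 3h)))}. Relative error is
#' below 1e-4 for axis ratios up to 5 (and far better for the mild
#' eccentricities of fetal heads).
#'
#' @param e an \code{\linkS4class{Ellipse}}, or the semi-major axis if
#'   \code{b} is given.
#' @param b optional semi-minor axis (numeric interface).
#' @return perimeter in pixels.
#' @export
ellipsePerimeter <- function(e, b = NULL) {
  if (is(e, "Ellipse")) { a <- e@a; bb <- e@b } else { a <- e; bb <- b }
  stopifnot(a > 0, bb > 0)
  h <- ((a - bb) / (a + bb))^2
  pi * (a + bb) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Head circumference in millimetres
#'
#' @param perimeterPx contour length in pixels.
#' @param mmPerPx pixel physical size in mm.
#' @return HC length in mm.
#' @export
hcLengthMm <- function(perimeterPx, mmPerPx) {
  if (!is.finite(perimeterPx) || perimeterPx <= 0)
    fhcStop("fhcBadInput", "perimeter must be positive")
  if (!is.finite(mmPerPx) || mmPerPx <= 0)
    fhcStop("fhcBadInput", "mm_per_px must be positive")
  perimeterPx * mmPerPx
}
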