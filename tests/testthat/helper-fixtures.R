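# shared fixtures built in code

# analytic circle skeleton: nearest-pixel marks of a radius-r circle
circleSkeleton <- function(cx, cy, r, size) {
  t <- seq(0, 2 * pi, length.out = 4 * ceiling(2 * pi * r))[-1]
  m <- matrix(0L, size, size)
  m[unique(cbind(round(cy + r * sin(t)) + 1, round(cx + r * cos(t)) + 1))] <- 1L
  m
}

# brute-force nearest-skeleton-pixel distance field (independent oracle)
bruteForceField <- function(skel, r, support = c("half", "full")) {
  support <- match.arg(support)
  idx <- which(skel != 0, arr.ind = TRUE)
  H <- nrow(skel); W <- ncol(skel)
  g <- expand.grid(row = 1:H, col = 1:W)
  d2 <- outer(g$row, idx[, 1], "-")^2 + outer(g$col, idx[, 2], "-")^2
  d <- sqrt(apply(d2, 1, min))
  sigma <- r / 2
  supp <- if (support == "half") r / 2 else r
  f <- exp(-d^2 / (2 * sigma^2))
  f[d > supp] <- 0
  matrix(f, H, W)
}

# threshold -> crest ridge -> fit, the delineation geometry chain
fitFromField <- function(field, t = 0.9) {
  fittedEllipse(measureField(field, 1, threshold = t))
}

# random canonical ellipse matching the phantom statistics
randomEllipse <- function(size = 512, aRange = c(40, 220), ratio = c(0.6, 0.95),
                          margin = 60) {
  repeat {
    a <- runif(1, aRange[1], aRange[2])
    b <- a * runif(1, ratio[1], ratio[2])
    th <- runif(1, 0, pi)
    ex <- sqrt(a^2 * cos(th)^2 + b^2 * sin(th)^2)
    ey <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
    if (size - 1 - 2 * (margin + ex) <= 0 || size - 1 - 2 * (margin + ey) <= 0)
      next
    cx <- runif(1, margin + ex, size - 1 - margin - ex)
    cy <- runif(1, margin + ey, size - 1 - margin - ey)
    return(ellipse(cx, cy, a, b, th))
  }
}

# arc length of an ellipse by adaptive quadrature (independent oracle)
perimeterQuadrature <- function(a, b) {
  4 * integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                0, pi / 2, rel.tol = 1e-10)$value
}
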