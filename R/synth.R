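# Synthetic fetal-ultrasound phantoms emulating the HC18 dataset structure:
# one bright elliptical skull band per image over a low-frequency soft-tissue
# background, optional angular shadow sectors, multiplicative gamma speckle,
# and per-image pixel calibration negatively correlated with head size (big
# heads are imaged at coarser pixel sizes, emulating sonographers' depth
# adjustments). The renderer is a structural phantom, not a wave-propagation
# simulator.

#' Phantom generator configuration
#'
#' @slot imageSize integer canvas side, px (512 default; 128 for desk scale).
#' @slot aRange numeric semi-major axis range, px.
#' @slot axisRatioRange numeric b/a range.
#' @slot skullThicknessRange numeric skull band thickness range, px.
#' @slot contrastRange numeric band contrast over background.
#' @slot speckleShape numeric gamma shape of the unit-mean multiplicative
#'   speckle; larger = milder speckle; 0 disables speckle.
#' @slot shadowProbability numeric probability that an image carries shadow
#'   sectors.
#' @slot mmPerPxRange numeric pixel physical size range, mm.
#' @slot fieldR numeric distance-field band thickness used for targets and
#'   containment margins, px.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomConfig",
  representation(imageSize = "integer", aRange = "numeric",
                 axisRatioRange = "numeric", skullThicknessRange = "numeric",
                 contrastRange = "numeric", speckleShape = "numeric",
                 shadowProbability = "numeric", mmPerPxRange = "numeric",
                 fieldR = "numeric", seed = "integer"),
  validity = function(object) {
    rngOk <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] <= r[2]
    if (object@imageSize < 32) return("imageSize too small")
    if (!rngOk(object@aRange) || object@aRange[1] <= 0)
      return("invalid aRange")
    if (!rngOk(object@axisRatioRange) || object@axisRatioRange[1] <= 0 ||
        object@axisRatioRange[2] > 1)
      return("axisRatioRange must lie in (0, 1]")
    if (!rngOk(object@skullThicknessRange)) return("invalid skullThicknessRange")
    if (!rngOk(object@mmPerPxRange) || object@mmPerPxRange[1] <= 0)
      return("invalid mmPerPxRange")
    if (object@shadowProbability < 0 || object@shadowProbability > 1)
      return("shadowProbability must be in [0, 1]")
    m <- object@skullThicknessRange[2] + object@fieldR / 2
    if (object@aRange[2] + m >= object@imageSize / 2)
      return("head cannot fit inside the image with the containment margin")
    TRUE
  })

#' Construct a PhantomConfig
#'
#' Defaults emulate the HC18 statistics at 512 px: pixel sizes in
#' [0.052, 0.326] mm, one head per image at varying position, size,
#' orientation and ellipticity. \code{phantomConfigDesk()} gives the
#' scaled-down 128 px configuration used for CPU-scale end-to-end runs.
#'
#' @param imageSize canvas side in px.
#' @param aRange,axisRatioRange,skullThicknessRange,contrastRange,mmPerPxRange
#'   sampling ranges (uniform).
#' @param speckleShape gamma shape of unit-mean speckle (0 = disabled).
#' @param shadowProbability probability of shadow sectors.
#' @param fieldR distance-field thickness r used for targets/margins.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{PhantomConfig}}.
#' @export
phantomConfig <- function(imageSize = 512L, aRange = c(60, 140),
                          axisRatioRange = c(0.6, 0.95),
                          skullThicknessRange = c(5, 15),
                          contrastRange = c(0.35, 0.6),
                          speckleShape = 4, shadowProbability = 0.5,
                          mmPerPxRange = c(0.052, 0.326),
                          fieldR = 100, seed = 1L) {
  new("PhantomConfig", imageSize = as.integer(imageSize), aRange = aRange,
      axisRatioRange = axisRatioRange,
      skullThicknessRange = skullThicknessRange,
      contrastRange = contrastRange, speckleShape = speckleShape,
      shadowProbability = shadowProbability, mmPerPxRange = mmPerPxRange,
      fieldR = fieldR, seed = as.integer(seed))
}

#' @rdname phantomConfig
#' @param ... overrides passed to \code{phantomConfig}.
#' @export
phantomConfigDesk <- function(seed = 1L, ...) {
  args <- list(imageSize = 128L, aRange = c(18, 42),
               axisRatioRange = c(0.6, 0.95), skullThicknessRange = c(3, 6),
               contrastRange = c(0.35, 0.6), speckleShape = 4,
               shadowProbability = 0.5, mmPerPxRange = c(0.052, 0.326),
               fieldR = 24, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantomConfig, args)
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %dpx, a in [%g, %g] px, b/a in [%g, %g], mm/px in [%g, %g], field r=%g\n",
    object@imageSize, object@aRange[1], object@aRange[2],
    object@axisRatioRange[1], object@axisRatioRange[2],
    object@mmPerPxRange[1], object@mmPerPxRange[2], object@fieldR))
})

#' Draw one phantom's geometric and acoustic parameters
#'
#' The ellipse is uniformly positioned subject to full containment with a
#' margin of (skull thickness + r/2); b = a * U(ratio range); theta ~
#' U[0, pi). The pixel size has a uniform marginal on \code{mmPerPxRange} but
#' is negatively correlated with the head size through a Gaussian copula
#' (correlation 0.7), emulating coarser imaging of bigger heads.
#'
#' Uses the current R RNG state; seed it upstream for determinism.
#'
#' @param cfg a \code{\linkS4class{PhantomConfig}}.
#' @return list with \code{ellipse}, \code{acoustic} (thickness, contrast,
#'   shadow sectors, speckle shape), \code{mmPerPx}.
#' @export
samplePhantomParams <- function(cfg) {
  size <- cfg@imageSize
  for (try in 1:100) {
    a <- runif(1, cfg@aRange[1], cfg@aRange[2])
    b <- a * runif(1, cfg@axisRatioRange[1], cfg@axisRatioRange[2])
    theta <- runif(1, 0, pi)
    thick <- runif(1, cfg@skullThicknessRange[1], cfg@skullThicknessRange[2])
    margin <- thick + cfg@fieldR / 2
    ex <- sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2)
    ey <- sqrt(a^2 * sin(theta)^2 + b^2 * cos(theta)^2)
    lox <- margin + ex; hix <- size - 1 - margin - ex
    loy <- margin + ey; hiy <- size - 1 - margin - ey
    if (lox > hix || loy > hiy) next
    cx <- runif(1, lox, hix); cy <- runif(1, loy, hiy)
    # uniform-marginal mm/px negatively correlated with head size
    ua <- (a - cfg@aRange[1]) / diff(cfg@aRange)
    rho <- 0.7
    z <- rho * qnorm(1 - pmin(pmax(ua, 1e-9), 1 - 1e-9)) +
         sqrt(1 - rho^2) * rnorm(1)
    mmPerPx <- cfg@mmPerPxRange[1] + diff(cfg@mmPerPxRange) * pnorm(z)
    nShadow <- if (runif(1) < cfg@shadowProbability) sample(1:2, 1) else 0L
    shadows <- if (nShadow > 0)
      data.frame(angle = runif(nShadow, 0, 2 * pi),
                 width = runif(nShadow, 0.2, 0.7),
                 strength = runif(nShadow, 0.2, 0.6))
    else NULL
    return(list(ellipse = ellipse(cx, cy, a, b, theta),
                acoustic = list(thickness = thick,
                                contrast = runif(1, cfg@contrastRange[1],
                                                 cfg@contrastRange[2]),
                                shadows = shadows,
                                speckleShape = cfg@speckleShape),
                mmPerPx = mmPerPx))
  }
  fhcStop("fhcConfigError",
          "could not place a head inside the image after 100 tries")
}

# exact distance from every pixel near the band to the contour, as in
# rasterizeEllipse but returning the distances on a window
bandProfile <- function(e, size, sigma, cut) {
  n <- max(720L, ceiling(ellipsePerimeter(e) / 0.25))
  pts <- ellipsePoints(e, n)
  r0 <- max(1, floor(min(pts[, "y"]) - cut) + 1)
  r1 <- min(size, ceiling(max(pts[, "y"]) + cut) + 1)
  c0 <- max(1, floor(min(pts[, "x"]) - cut) + 1)
  c1 <- min(size, ceiling(max(pts[, "x"]) + cut) + 1)
  wh <- r1 - r0 + 1; ww <- c1 - c0 + 1
  marked <- matrix(0L, wh, ww)
  rows <- round(pts[, "y"]) + 1 - (r0 - 1)
  cols <- round(pts[, "x"]) + 1 - (c0 - 1)
  keep <- rows >= 1 & rows <= wh & cols >= 1 & cols <= ww
  marked[cbind(rows[keep], cols[keep])] <- 1L
  dd <- EBImage::distmap(1 - marked)
  cand <- which(dd <= cut + 1.5, arr.ind = TRUE)
  qx <- cand[, 2] - 1 + (c0 - 1); qy <- cand[, 1] - 1 + (r0 - 1)
  dex <- cpp_min_dist_points(qx, qy, pts[, "x"], pts[, "y"])
  on <- dex <= cut
  prof <- matrix(0, size, size)
  prof[cbind(qy[on] + 1, qx[on] + 1)] <- exp(-dex[on]^2 / (2 * sigma^2))
  prof
}

#' Render one phantom image
#'
#' Low-frequency background texture, a bright skull band with a Gaussian
#' cross-profile (sigma = thickness/2) whose amplitude is pre-compensated so
#' the stated contrast is the post-smoothing contrast on the contour,
#' optional angular shadow sectors attenuating the band, unit-mean gamma
#' speckle, light Gaussian smoothing, 8-bit quantization.
#'
#' Uses the current R RNG state; seed it upstream for determinism.
#'
#' @param params output of [samplePhantomParams()].
#' @param cfg a \code{\linkS4class{PhantomConfig}}.
#' @return numeric matrix in \code{[0, 1]} (8-bit quantized).
#' @export
renderPhantom <- function(params, cfg) {
  size <- cfg@imageSize
  e <- params$ellipse; ac <- params$acoustic
  # soft-tissue background: bilinearly upsampled random coarse grid
  coarse <- matrix(runif(64, 0.08, 0.30), 8, 8)
  bg <- cpp_resize_bilinear(coarse, size, size)
  sigma <- ac$thickness / 2
  blurSigma <- 0.7
  amp <- ac$contrast * sqrt(sigma^2 + blurSigma^2) / sigma
  band <- amp * bandProfile(e, size, sigma, cut = 3 * sigma)
  if (!is.null(ac$shadows)) {
    ys <- matrix(rep(0:(size - 1), times = size), size, size)
    xs <- matrix(rep(0:(size - 1), each = size), size, size)
    ang <- atan2(ys - e@cy, xs - e@cx)
    att <- matrix(1, size, size)
    for (k in seq_len(nrow(ac$shadows))) {
      d <- abs(((ang - ac$shadows$angle[k] + pi) %% (2 * pi)) - pi)
      att[d < ac$shadows$width[k] / 2] <-
        pmin(att[d < ac$shadows$width[k] / 2], 1 - ac$shadows$strength[k])
    }
    band <- band * att
  }
  img <- pmin(pmax(bg + band, 0), 1)
  if (ac$speckleShape > 0) {
    sp <- matrix(rgamma(size * size, shape = ac$speckleShape,
                        rate = ac$speckleShape), size, size)
    img <- img * sp
  }
  img <- as.matrix(EBImage::gblur(img, sigma = blurSigma))
  img <- pmin(pmax(img, 0), 1)
  round(img * 255) / 255
}

#' Generate a synthetic HC18-layout dataset
#'
#' Writes, under \code{outDir}: \code{NNN_HC.png} phantom images,
#' \code{NNN_HC_Annotation.png} 2-px-wide ellipse contour rasters,
#' \code{training_set_pixel_size_and_HC.csv} (filename, pixel size, HC in
#' mm), and \code{annotations_coco.json} with the distance-field-derived
#' bounding boxes. Fully deterministic given \code{cfg@seed}.
#'
#' @param n number of images.
#' @param cfg a \code{\linkS4class{PhantomConfig}}.
#' @param outDir output directory (created if missing).
#' @param writeImages set FALSE to skip disk output and return the in-memory
#'   samples only (used for training at desk scale).
#' @return invisibly, the manifest data.frame: filename, mmPerPx, hcMm,
#'   ellipse parameters, trimester tercile label; with attribute
#'   \code{"samples"} holding the in-memory sample list.
#' @export
generateDataset <- function(n, cfg, outDir = NULL, writeImages = !is.null(outDir)) {
  stopifnot(n >= 1)
  if (writeImages && !dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    fhcStop("fhcBadInput", sprintf("cannot create directory '%s'", outDir))
  set.seed(cfg@seed)
  fcfg <- fieldConfig(cfg@fieldR)
  samples <- vector("list", n)
  rows <- vector("list", n)
  coco_images <- vector("list", n)
  coco_ann <- vector("list", n)
  for (i in seq_len(n)) {
    p <- samplePhantomParams(cfg)
    img <- renderPhantom(p, cfg)
    tg <- buildTargets(p$ellipse, cfg@imageSize, cfg@imageSize, fcfg)
    fname <- sprintf("%03d_HC.png", i)
    hc <- ellipsePerimeter(p$ellipse) * p$mmPerPx
    samples[[i]] <- list(filename = fname, image = img,
                         mmPerPx = p$mmPerPx, gtEllipse = p$ellipse,
                         hcMm = hc, contour = tg$contour,
                         skeleton = tg$skeleton, field = tg$field,
                         bbox = tg$bbox)
    rows[[i]] <- data.frame(filename = fname, mmPerPx = p$mmPerPx, hcMm = hc,
                            cx = p$ellipse@cx, cy = p$ellipse@cy,
                            a = p$ellipse@a, b = p$ellipse@b,
                            theta = p$ellipse@theta)
    bb <- tg$bbox
    coco_images[[i]] <- list(id = i, file_name = fname,
                             height = cfg@imageSize, width = cfg@imageSize)
    coco_ann[[i]] <- list(id = i, image_id = i, category_id = 1,
                          bbox = c(bb[["x1"]], bb[["y1"]],
                                   bb[["x2"]] - bb[["x1"]],
                                   bb[["y2"]] - bb[["y1"]]),
                          area = (bb[["x2"]] - bb[["x1"]]) *
                                 (bb[["y2"]] - bb[["y1"]]),
                          iscrowd = 0)
    if (writeImages) {
      png::writePNG(img, file.path(outDir, fname))
      png::writePNG(samples[[i]]$contour * 1.0,
                    file.path(outDir, sprintf("%03d_HC_Annotation.png", i)))
    }
  }
  manifest <- do.call(rbind, rows)
  terc <- quantile(manifest$hcMm, c(1 / 3, 2 / 3))
  manifest$trimester <- cut(manifest$hcMm, c(-Inf, terc, Inf),
                            labels = c("T1", "T2", "T3"))
  if (writeImages) {
    csv <- data.frame(filename = manifest$filename,
                      `pixel size(mm)` = manifest$mmPerPx,
                      `head circumference (mm)` = manifest$hcMm,
                      check.names = FALSE)
    write.csv(csv, file.path(outDir, "training_set_pixel_size_and_HC.csv"),
              row.names = FALSE, quote = FALSE)
    coco <- list(images = coco_images, annotations = coco_ann,
                 categories = list(list(id = 1, name = "head")))
    jsonlite::write_json(coco, file.path(outDir, "annotations_coco.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(manifest, "samples") <- samples
  invisible(manifest)
}

#' Read an HC18-layout dataset directory
#'
#' Pairs \code{*.png} images with their \code{*_Annotation.png} contours and
#' the pixel-size CSV, and derives the field/box targets. Files with a
#' missing annotation or CSV row are skipped with a warning.
#'
#' @param dir dataset directory.
#' @param fieldCfg a \code{\linkS4class{FieldConfig}} for target
#'   construction.
#' @return list of samples (filename, image, mmPerPx, contour, skeleton,
#'   field, bbox, gtEllipse fitted from the skeleton, hcMm from the CSV).
#' @export
readHC18Dataset <- function(dir, fieldCfg = fieldConfig()) {
  csvPath <- file.path(dir, "training_set_pixel_size_and_HC.csv")
  if (!file.exists(csvPath))
    fhcStop("fhcBadInput", "missing training_set_pixel_size_and_HC.csv")
  cal <- read.csv(csvPath, check.names = FALSE)
  imgs <- setdiff(list.files(dir, pattern = "\\.png$"),
                  list.files(dir, pattern = "_Annotation\\.png$"))
  out <- list()
  for (f in imgs) {
    annPath <- file.path(dir, sub("\\.png$", "_Annotation.png", f))
    row <- cal[cal$filename == f, , drop = FALSE]
    if (!file.exists(annPath) || nrow(row) == 0) {
      warning(sprintf("skipping '%s': missing annotation or calibration", f))
      next
    }
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3) img <- img[, , 1]
    ann <- png::readPNG(annPath)
    if (length(dim(ann)) == 3) ann <- ann[, , 1]
    contour <- (ann > 0.5) * 1L
    skel <- skeletonizeContour(contour)
    field <- buildDistanceField(skel, fieldCfg)
    idx <- which(skel == 1L, arr.ind = TRUE)
    gtE <- fitEllipse(cbind(idx[, 2] - 1, idx[, 1] - 1))
    out[[length(out) + 1]] <- list(
      filename = f, image = img, mmPerPx = row[[2]][1],
      contour = contour, skeleton = skel, field = field,
      bbox = fieldBBox(field), gtEllipse = gtE, hcMm = row[[3]][1])
  }
  if (length(out) == 0)
    fhcStop("fhcBadInput", "no usable image/annotation pairs found")
  out
}

#' Write an HC18-style submission CSV
#'
#' One row per image with the ellipse parameters converted to mm:
#' filename, center_x_mm, center_y_mm, semi_axes_a_mm, semi_axes_b_mm,
#' angle_rad. No-measurement records are flagged in a \code{status} column
#' with NA parameters.
#'
#' @param measurements named list (by filename) of
#'   \code{\linkS4class{HCMeasurement}}.
#' @param path output CSV path.
#' @export
writeSubmissionCsv <- function(measurements, path) {
  if (anyDuplicated(names(measurements)))
    fhcStop("fhcBadInput", "duplicate filenames in submission")
  rows <- lapply(names(measurements), function(f) {
    m <- measurements[[f]]
    if (measurementStatus(m) == "ok") {
      e <- fittedEllipse(m)
      data.frame(filename = f, center_x_mm = e@cx * m@mmPerPx,
                 center_y_mm = e@cy * m@mmPerPx,
                 semi_axes_a_mm = e@a * m@mmPerPx,
                 semi_axes_b_mm = e@b * m@mmPerPx,
                 angle_rad = e@theta, status = "ok")
    } else {
      data.frame(filename = f, center_x_mm = NA_real_, center_y_mm = NA_real_,
                 semi_axes_a_mm = NA_real_, semi_axes_b_mm = NA_real_,
                 angle_rad = NA_real_, status = measurementStatus(m))
    }
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
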