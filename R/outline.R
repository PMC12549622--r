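#' Segment the lens outline from a silhouette image
#'
#' Thresholds the image midway between its extreme intensities, keeps the
#' largest connected foreground component (an error is raised when there
#' is none, or when a second comparably sized component exists), and
#' extracts its ordered sub-pixel boundary as the 0.5-level contour. The
#' outline is centred on the optical centre: the symmetry axis is found by
#' minimising the top/bottom mismatch of the silhouette and the axial
#' origin is placed at the equator (maximal transverse extent).
#'
#' @param image numeric matrix (grayscale in [0,1] or 8/16-bit values) or
#'   path to a PNG file.
#' @param pixelScale mm per pixel.
#' @return A [LensOutline-class] ordered counter-clockwise.
#' @export
segmentOutline <- function(image, pixelScale) {
  if (pixelScale <= 0) stop("pixelScale must be positive")
  if (is.character(image)) {
    image <- png::readPNG(image)
    if (length(dim(image)) == 3L) image <- apply(image[, , 1:3], c(1, 2), mean)
  }
  image <- unclass(as.matrix(image))
  rng <- range(image)
  if (diff(rng) == 0) stop("segmentation error: no foreground component")
  bw <- image > mean(rng)
  if (!any(bw)) stop("segmentation error: no foreground component")
  lab <- EBImage::bwlabel(bw * 1)
  sizes <- sort(table(lab[lab > 0]), decreasing = TRUE)
  if (length(sizes) > 1L &&
      as.integer(sizes[2]) > max(50, 0.05 * as.integer(sizes[1])))
    stop("segmentation error: multiple large foreground components")
  mask <- (lab == as.integer(names(sizes)[1])) * 1
  cl <- grDevices::contourLines(x = seq_len(ncol(mask)),
                                y = seq_len(nrow(mask)),
                                z = t(mask), levels = 0.5)
  if (!length(cl)) stop("segmentation error: no boundary contour")
  cl <- cl[[which.max(lengths(lapply(cl, `[[`, "x")))]]
  cy <- (nrow(mask) + 1) / 2
  pts <- cbind(cl$x * pixelScale, (cy - cl$y) * pixelScale)
  # vertical centring on the symmetry axis: midline between the top and
  # bottom envelope, averaged over the axial extent
  mid <- outlineMidline(pts)
  pts[, 2] <- pts[, 2] - mid$y0
  # axial origin at the equator (maximal transverse extent)
  pts[, 1] <- pts[, 1] - equatorPosition(pts)$x0
  # orient counter-clockwise
  n <- nrow(pts)
  area2 <- sum(pts[, 1] * pts[c(2:n, 1), 2] - pts[c(2:n, 1), 1] * pts[, 2])
  if (area2 < 0) pts <- pts[n:1, , drop = FALSE]
  new("LensOutline", points = pts, pixelScale = pixelScale,
      excluded = rep(FALSE, n))
}

# midline offset between top and bottom envelopes over a common axial grid
outlineMidline <- function(pts, nBins = 100) {
  top <- pts[pts[, 2] > 0, , drop = FALSE]
  bot <- pts[pts[, 2] < 0, , drop = FALSE]
  lo <- max(min(top[, 1]), min(bot[, 1]))
  hi <- min(max(top[, 1]), max(bot[, 1]))
  xg <- seq(lo + 0.02 * (hi - lo), hi - 0.02 * (hi - lo),
            length.out = nBins)
  tg <- stats::approx(top[, 1], top[, 2], xout = xg, ties = max)$y
  bg <- stats::approx(bot[, 1], bot[, 2], xout = xg, ties = min)$y
  ctr <- (tg + bg) / 2
  list(y0 = mean(ctr, na.rm = TRUE), centreline = cbind(xg, ctr))
}

# sub-pixel equator position and radius. A rasterised silhouette has a
# flat plateau at its transverse extreme: the envelope is a staircase
# whose treads carry no sub-pixel information and bias any least-squares
# fit that includes them, while a symmetric flank-midpoint estimator is
# biased when the two sides of the envelope have different curvatures
# (asymmetric lenses). The estimator therefore collects flank crossings
# of the envelope at a dense ladder of thresholds within 4% of the
# maximum (deep enough to span several quantisation levels, shallow
# enough to stay inside the equatorial blend region where the half-width
# really is a cubic) and fits the two-sided apex model
# y = y0 - c (x - x0)^2 + d (x - x0)^3 with independent (c, d) per side
# and zero gradient at the shared apex; given x0 the model is linear, so
# x0 comes from a grid scan refined by a 1-D search.
equatorPosition <- function(pts) {
  one <- function(side) {
    s <- pts[sign(pts[, 2]) == side, , drop = FALSE]
    y <- abs(s[, 2])
    xg <- seq(min(s[, 1]), max(s[, 1]), length.out = 1600)
    yg <- stats::approx(s[, 1], y, xout = xg, ties = max)$y
    ok <- !is.na(yg)
    xg <- xg[ok]; yg <- yg[ok]
    ymax <- max(yg)
    iMax <- which.max(yg)
    nG <- length(xg)
    thrs <- ymax - seq(0.002, 0.04, by = 0.002) * ymax
    cx <- numeric(0); cy <- numeric(0)
    for (thr in thrs) {
      above <- yg >= thr
      L <- iMax; while (L > 1L && above[L - 1L]) L <- L - 1L
      R <- iMax; while (R < nG && above[R + 1L]) R <- R + 1L
      if (L > 1L) {
        cx <- c(cx, stats::approx(yg[c(L - 1L, L)], xg[c(L - 1L, L)],
                                  xout = thr)$y)
        cy <- c(cy, thr)
      }
      if (R < nG) {
        cx <- c(cx, stats::approx(yg[c(R + 1L, R)], xg[c(R + 1L, R)],
                                  xout = thr)$y)
        cy <- c(cy, thr)
      }
    }
    if (length(cx) < 6L) return(c(xg[iMax], ymax))
    rssAt <- function(x0) {
      u <- cx - x0
      left <- u < 0
      Xm <- cbind(1, -u^2 * left, u^3 * left, -u^2 * !left, u^3 * !left)
      sum(stats::lm.fit(Xm, cy)$residuals^2)
    }
    g <- seq(min(cx), max(cx), length.out = 161)
    v <- vapply(g, rssAt, numeric(1))
    i0 <- which.min(v)
    op <- stats::optimize(rssAt, c(g[max(1L, i0 - 2L)],
                                   g[min(length(g), i0 + 2L)]), tol = 1e-8)
    c(op$minimum, ymax)
  }
  t1 <- one(1); t2 <- one(-1)
  list(x0 = mean(c(t1[1], t2[1])), radius = mean(c(t1[2], t2[2])))
}

#' Flag holder-contact regions of an outline
#'
#' Marks outline points within one or more angular intervals (about the
#' optical centre) as excluded so they never enter any subsequent fit,
#' emulating the removal of the support-ring contact regions.
#'
#' @param outline a [LensOutline-class].
#' @param interval numeric length-2 angular interval in radians
#'   (atan2(y, x) convention, interval may wrap across +/-pi), a list of
#'   such intervals, or `NULL` for no change.
#' @return The outline with its `excluded` flags updated.
#' @export
removeHolderRegion <- function(outline, interval) {
  if (is.null(interval) || (is.numeric(interval) && !length(interval)))
    return(outline)
  if (is.numeric(interval)) interval <- list(interval)
  ang <- atan2(outline@points[, 2], outline@points[, 1])
  excl <- outline@excluded
  for (iv in interval) {
    if (length(iv) != 2L || any(!is.finite(iv)))
      stop("holder interval must be two finite angles")
    if (iv[1] == iv[2]) next
    inIv <- if (iv[1] < iv[2]) ang >= iv[1] & ang <= iv[2]
            else ang >= iv[1] | ang <= iv[2]      # wraps across +/- pi
    excl <- excl | inIv
  }
  if (mean(excl) > 0.5)
    stop("holder region would exclude more than 50% of the outline")
  outline@excluded <- excl
  outline
}

#' Align an outline and split it at the equator
#'
#' Finds the small rotation (at most 0.1 rad) that best symmetrises the
#' silhouette about the horizontal axis, applies it together with a
#' recentring, and splits the points at the equator (maximal transverse
#' extent) into anterior (x > 0) and posterior (x < 0) groups. Excluded
#' points are dropped from the returned groups.
#'
#' @param outline a [LensOutline-class].
#' @param maxTilt tilt threshold in radians; a required rotation beyond it
#'   raises a tilt error mirroring the manual alignment check.
#' @return A list with `anterior` and `posterior` point matrices, the
#'   applied `rotation` (radians), the aligned `outline` and the estimated
#'   `equatorialRadius` (mm).
#' @export
alignAndSplit <- function(outline, maxTilt = 0.1) {
  pts <- outline@points
  ctr <- colMeans(pts)
  asym <- function(phi) {
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    p <- sweep(pts, 2, ctr) %*% R
    m <- outlineMidline(p)
    mean((m$centreline[, 2] - m$y0)^2, na.rm = TRUE)
  }
  win <- maxTilt * 1.2
  op <- stats::optimize(asym, c(-win, win), tol = 1e-6)
  phi <- op$minimum
  if (abs(phi) > maxTilt)
    stop("tilt error: required rotation ", signif(abs(phi), 3),
         " rad exceeds the ", maxTilt, " rad alignment threshold")
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  p <- sweep(pts, 2, ctr) %*% R
  p[, 2] <- p[, 2] - outlineMidline(p)$y0
  eq <- equatorPosition(p)
  p[, 1] <- p[, 1] - eq$x0
  out <- outline
  out@points <- p
  keep <- !out@excluded
  ant <- p[keep & p[, 1] > 0, , drop = FALSE]
  post <- p[keep & p[, 1] < 0, , drop = FALSE]
  if (!nrow(ant) || !nrow(post))
    stop("equator split produced an empty point group")
  list(anterior = ant, posterior = post, rotation = phi, outline = out,
       equatorialRadius = eq$radius)
}

#' Fit a composite lens shape to a segmented outline
#'
#' Full geometry-extraction pipeline: align and split the outline, fit an
#' aspheric cap to each side using the points inside the cap span
#' (|y| <= `junctionFraction` times the equatorial radius), and compose
#' the shape with constrained cubic equatorial blends anchored at the
#' measured equator.
#'
#' @param outline a [LensOutline-class].
#' @param junctionFraction cap/blend junction radius as a fraction of the
#'   equatorial radius.
#' @param maxTilt passed to [alignAndSplit()].
#' @return A [LensShape-class].
#' @export
fitLensShape <- function(outline, junctionFraction = 0.95, maxTilt = 0.1) {
  al <- alignAndSplit(outline, maxTilt = maxTilt)
  a <- al$equatorialRadius
  rJ <- junctionFraction * a
  antPts <- al$anterior[abs(al$anterior[, 2]) <= rJ, , drop = FALSE]
  postPts <- al$posterior[abs(al$posterior[, 2]) <= rJ, , drop = FALSE]
  ant <- fitAspheric(antPts, side = "anterior")
  post <- fitAspheric(postPts, side = "posterior")
  composeShape(ant, post, equatorialRadius = a,
               junctionFraction = junctionFraction)
}
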