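#' Render a binary silhouette of a lens
#'
#' Rasterises the solid meridional profile of a lens shape (or of a
#' deformed outline) onto a pixel grid: a pixel is foreground when its
#' centre lies within the half-width envelope |y| <= h(x). Optional edge
#' jitter perturbs the top and bottom envelope independently per column by
#' Gaussian noise, emulating segmentation-level edge uncertainty.
#'
#' @param lens a [LensShape-class], [GroundTruthLens-class], or a matrix
#'   outline with columns `x`, `r` (mm).
#' @param pixelScale mm per pixel.
#' @param noise edge-jitter SD in pixels.
#' @param pad background margin in pixels.
#' @param width,height optional canvas size in pixels; an error is raised
#'   when the shape does not fit.
#' @param seed seed for the jitter.
#' @return Numeric 0/1 matrix (rows = vertical, columns = horizontal/axial)
#'   with attributes `pixelScale` and `origin` (mm of the centre of pixel
#'   [1, 1] as c(x, y)).
#' @export
renderSilhouette <- function(lens, pixelScale = 0.05, noise = 0, pad = 10,
                             width = NULL, height = NULL, seed = 0) {
  if (pixelScale <= 0) stop("pixelScale must be positive")
  if (is(lens, "GroundTruthLens")) lens <- lens@shape
  if (is(lens, "LensShape")) {
    xr <- c(-lens@TP, lens@TA)
    rmax <- lens@ED / 2
    hfun <- function(x) lensHalfWidth(lens, x)
  } else {
    m <- as.matrix(lens)
    if (nrow(m) < 2L || all(m[, 2] <= 0)) stop("empty shape cannot be rendered")
    m <- m[order(m[, 1]), , drop = FALSE]
    xr <- range(m[, 1])
    rmax <- max(m[, 2])
    hfun <- function(x) {
      h <- stats::approx(m[, 1], m[, 2], xout = x, yleft = 0, yright = 0,
                         ties = mean)$y
      pmax(h, 0)
    }
  }
  if (rmax <= 0) stop("empty shape cannot be rendered")
  ncolN <- ceiling(diff(xr) / pixelScale) + 2L * pad
  nrowN <- 2L * (ceiling(rmax / pixelScale) + pad) + 1L
  if (!is.null(width)) {
    if (width < ncolN) stop("shape exceeds the requested canvas width")
    ncolN <- width
  }
  if (!is.null(height)) {
    if (height < nrowN) stop("shape exceeds the requested canvas height")
    nrowN <- height
  }
  x0 <- mean(xr) - (ncolN / 2 - 0.5) * pixelScale   # mm at pixel [.,1] centre
  cy <- (nrowN + 1) / 2
  xs <- x0 + (seq_len(ncolN) - 1) * pixelScale
  ys <- (cy - seq_len(nrowN)) * pixelScale
  h <- hfun(xs)
  if (noise > 0) {
    jit <- withSeed(seed, matrix(stats::rnorm(2 * ncolN, 0,
                                              noise * pixelScale), 2))
    hTop <- ifelse(h > 0, pmax(h + jit[1, ], 0), 0)
    hBot <- ifelse(h > 0, pmax(h + jit[2, ], 0), 0)
  } else {
    hTop <- h; hBot <- h
  }
  img <- matrix(0, nrowN, ncolN)
  for (j in seq_len(ncolN)) {
    if (h[j] > 0)
      img[ys <= hTop[j] & ys >= -hBot[j], j] <- 1
  }
  attr(img, "pixelScale") <- pixelScale
  attr(img, "origin") <- c(x0, ys[1])
  img
}

#' Write a silhouette (or any [0,1] image matrix) as PNG
#'
#' @param img numeric matrix in [0, 1].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeSilhouettePng <- function(img, path) {
  png::writePNG(pmin(pmax(unclass(img), 0), 1), target = path)
  invisible(path)
}
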