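#' Write a lens shape as JSON
#'
#' Serialises the full analytic description (both aspheric caps, blend
#' coefficients, junction layout) plus the derived LT, ED and volume as a
#' human-readable sidecar file.
#'
#' @param shape a [LensShape-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeShapeJson <- function(shape, path) {
  surf <- function(s) list(R = s@R, kappa = s@kappa, a4 = s@a4, a6 = s@a6,
                           a8 = s@a8, side = s@side,
                           vertexOffset = s@vertexOffset)
  blend <- function(b) list(a = b@a, b = b@b, c = b@c, d = b@d,
                            fittedSpan = b@fittedSpan)
  obj <- list(anterior = surf(shape@anterior),
              posterior = surf(shape@posterior),
              blendTop = blend(shape@blendTop),
              blendBottom = blend(shape@blendBottom),
              TA = shape@TA, TP = shape@TP, LT = shape@LT, ED = shape@ED,
              equatorialRadius = shape@equatorialRadius,
              junctionFraction = shape@rJunction / shape@equatorialRadius,
              volume = lensVolume(shape))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lens shape from JSON
#'
#' Rebuilds the [LensShape-class] written by [writeShapeJson()] by
#' recomposing the caps and re-deriving the blends from the stored junction
#' layout (the blend is fully determined by its equality constraints, so
#' the recomposition is exact).
#'
#' @param path JSON file written by [writeShapeJson()].
#' @return A [LensShape-class].
#' @export
readShapeJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(s) asphericSurface(R = s$R, kappa = s$kappa, a4 = s$a4,
                                    a6 = s$a6, a8 = s$a8, side = s$side,
                                    vertexOffset = s$vertexOffset)
  composeShape(mk(obj$anterior), mk(obj$posterior),
               equatorialRadius = obj$equatorialRadius,
               junctionFraction = obj$junctionFraction)
}

#' Write an outline as CSV
#'
#' Columns `x_mm`, `y_mm`, `excluded` — the serialisation used for
#' segmented and deformed outlines.
#'
#' @param outline a [LensOutline-class] or a two-column matrix.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeOutlineCsv <- function(outline, path) {
  if (is(outline, "LensOutline")) {
    df <- data.frame(x_mm = outline@points[, 1], y_mm = outline@points[, 2],
                     excluded = outline@excluded)
  } else {
    m <- as.matrix(outline)
    df <- data.frame(x_mm = m[, 1], y_mm = m[, 2],
                     excluded = rep(FALSE, nrow(m)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an outline CSV
#'
#' @param path CSV written by [writeOutlineCsv()].
#' @param pixelScale mm per pixel recorded on the returned object.
#' @return A [LensOutline-class].
#' @export
readOutlineCsv <- function(path, pixelScale = 0.05) {
  df <- utils::read.csv(path)
  new("LensOutline", points = cbind(df$x_mm, df$y_mm),
      pixelScale = pixelScale, excluded = as.logical(df$excluded))
}

#' Write a voxel map as NIfTI
#'
#' @param map numeric matrix or array.
#' @param path output `.nii`/`.nii.gz` file.
#' @param spacing voxel spacing (mm), recycled over dimensions.
#' @return The path, invisibly.
#' @export
writeMapNifti <- function(map, path, spacing = 1) {
  img <- RNifti::asNifti(unclass(map),
                         pixdim = rep(spacing, length.out = length(dim(map))))
  RNifti::writeNifti(img, path)
  invisible(path)
}
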