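#' @name accessors
#' @title Accessor generics for lens objects
#' @description Small accessor layer over the S4 classes: lens thickness
#'   and equatorial diameter of shapes, SVF parameters, and profile
#'   coordinates.
#' @param object an object of the documented classes.
#' @return The accessed value.
NULL

#' @rdname accessors
#' @export
setGeneric("lensThickness", function(object) standardGeneric("lensThickness"))
#' @rdname accessors
#' @export
setMethod("lensThickness", "LensShape", function(object) object@LT)
#' @rdname accessors
#' @export
setMethod("lensThickness", "GroundTruthLens",
          function(object) object@shape@LT)

#' @rdname accessors
#' @export
setGeneric("equatorialDiameter",
           function(object) standardGeneric("equatorialDiameter"))
#' @rdname accessors
#' @export
setMethod("equatorialDiameter", "LensShape", function(object) object@ED)
#' @rdname accessors
#' @export
setMethod("equatorialDiameter", "GroundTruthLens",
          function(object) object@shape@ED)

#' @rdname accessors
#' @export
setGeneric("svfAlpha", function(object) standardGeneric("svfAlpha"))
#' @rdname accessors
#' @export
setMethod("svfAlpha", "SVF", function(object) object@alpha)
#' @rdname accessors
#' @export
setMethod("svfAlpha", "SVFFit", function(object) object@svf@alpha)

#' @rdname accessors
#' @export
setGeneric("svfBeta", function(object) standardGeneric("svfBeta"))
#' @rdname accessors
#' @export
setMethod("svfBeta", "SVF", function(object) object@beta)
#' @rdname accessors
#' @export
setMethod("svfBeta", "SVFFit", function(object) object@svf@beta)

#' @rdname accessors
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setMethod("profileValues", "LineProfile", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("profilePositions",
           function(object) standardGeneric("profilePositions"))
#' @rdname accessors
#' @export
setMethod("profilePositions", "LineProfile",
          function(object) object@positions)

setMethod("show", "AsphericSurface", function(object) {
  cat(sprintf("AsphericSurface (%s): R = %.4g mm, kappa = %.4g\n",
              object@side, object@R, object@kappa))
  cat(sprintf("  a4 = %.4g, a6 = %.4g, a8 = %.4g; vertex at x = %.4g mm\n",
              object@a4, object@a6, object@a8, object@vertexOffset))
  if (is.finite(object@rmsResidual))
    cat(sprintf("  fit RMS residual: %.3g mm\n", object@rmsResidual))
  invisible(NULL)
})

setMethod("show", "LensShape", function(object) {
  cat(sprintf("LensShape: LT = %.4f mm (TA %.4f + TP %.4f), ED = %.4f mm\n",
              object@LT, object@TA, object@TP, object@ED))
  cat(sprintf("  cap/blend junction at radius %.4f mm (x in [%.4f, %.4f])\n",
              object@rJunction, object@xV2, object@xV1))
  invisible(NULL)
})

setMethod("show", "GroundTruthLens", function(object) {
  cat(sprintf("GroundTruthLens preset '%s'\n", object@preset))
  show(object@shape)
  show(object@material)
  invisible(NULL)
})

setMethod("show", "SVF", function(object) {
  cat(sprintf("SVF: G(xi/xi0) = %.4g Pa * exp(%.4g * xi/xi0)\n",
              object@alpha, object@beta))
  invisible(NULL)
})

setMethod("show", "MaterialModel", function(object) {
  cat(sprintf("MaterialModel: nu = %.3g, density = %.4g kg/m^3\n",
              object@nu, object@density))
  show(object@svf)
  invisible(NULL)
})

setMethod("show", "SpinCondition", function(object) {
  cat(sprintf("SpinCondition: %.4g RPM (omega = %.4f rad/s)\n",
              object@rpm, object@omega))
  invisible(NULL)
})

setMethod("show", "AxisymMesh", function(object) {
  cat(sprintf("AxisymMesh: %d nodes, %d triangles, %d boundary nodes\n",
              nrow(object@nodes), nrow(object@elements),
              length(object@boundary)))
  invisible(NULL)
})

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf(
    "DisplacementField at omega = %.4f rad/s: |u| <= %.4g mm, w in [%.4g, %.4g] mm\n",
    object@omega, max(abs(object@u)), min(object@w), max(object@w)))
  invisible(NULL)
})

setMethod("show", "SVFFit", function(object) {
  cat(sprintf("SVFFit: alpha = %.4g Pa, beta = %.4g\n",
              object@svf@alpha, object@svf@beta))
  cat(sprintf("  misfit %.4g mm^2 after %d objective evaluations (%s%s)\n",
              object@misfit, object@iterations,
              if (object@converged) "converged" else "iteration cap hit",
              if (object@boundActive) ", bound active" else ""))
  invisible(NULL)
})

setMethod("show", "LensOutline", function(object) {
  cat(sprintf("LensOutline: %d points at %.4g mm/px (%d excluded)\n",
              nrow(object@points), object@pixelScale, sum(object@excluded)))
  invisible(NULL)
})

setMethod("show", "T1PDMaps", function(object) {
  cat(sprintf("T1PDMaps: %d x %d voxels, %.1f%% valid, TR = %.3g ms\n",
              nrow(object@t1), ncol(object@t1),
              100 * mean(object@valid), object@tr))
  if (is.finite(object@pdWater))
    cat(sprintf("  water reference PD = %.4g\n", object@pdWater))
  invisible(NULL)
})

setMethod("show", "LineProfile", function(object) {
  cat(sprintf("LineProfile (%s): %d stations, r/a in [%.2f, %.2f]\n",
              object@kind, length(object@positions),
              min(object@positions), max(object@positions)))
  invisible(NULL)
})

setMethod("show", "ComparisonBand", function(object) {
  cat(sprintf("ComparisonBand (%s): %d stations, mean in [%.4g, %.4g]\n",
              object@mode, length(object@positions),
              min(object@mean, na.rm = TRUE),
              max(object@mean, na.rm = TRUE)))
  invisible(NULL)
})
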