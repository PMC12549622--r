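#' @import methods
NULL

#' Aspheric lens surface
#'
#' Analytic description of one lens face as a conic-plus-polynomial sag
#' profile \eqn{Z(r) = r^2 / [R (1 + \sqrt{1 - (1+\kappa) r^2/R^2})] +
#' a_4 r^4 + a_6 r^6 + a_8 r^8}, where \eqn{r} is the radial distance from
#' the optical axis, \eqn{R} the apical radius of curvature (mm) and
#' \eqn{\kappa} the conic constant. The vertex is at \code{vertexOffset} on
#' the optical axis of the composed lens (positive for the anterior face).
#'
#' @slot R apical radius of curvature (mm), non-zero.
#' @slot kappa conic constant (dimensionless).
#' @slot a4,a6,a8 aspheric deviation coefficients (mm^-3, mm^-5, mm^-7).
#' @slot side `"anterior"` or `"posterior"`.
#' @slot vertexOffset axial position of the vertex in the lens frame (mm).
#' @slot rmsResidual RMS residual of the fit that produced the surface (mm),
#'   `NA` for analytically constructed surfaces.
#' @exportClass AsphericSurface
setClass("AsphericSurface",
  representation(R = "numeric", kappa = "numeric", a4 = "numeric",
                 a6 = "numeric", a8 = "numeric", side = "character",
                 vertexOffset = "numeric", rmsResidual = "numeric"),
  prototype(kappa = 0, a4 = 0, a6 = 0, a8 = 0, side = "anterior",
            vertexOffset = 0, rmsResidual = NA_real_),
  validity = function(object) {
    if (length(object@R) != 1L || !is.finite(object@R) || object@R == 0)
      return("R must be a single non-zero finite radius of curvature")
    if (!object@side %in% c("anterior", "posterior"))
      return("side must be 'anterior' or 'posterior'")
    TRUE
  })

#' Cubic equatorial blend
#'
#' Cubic polynomial \eqn{z(t) = a t^3 + b t^2 + c t + d} joining an aspheric
#' cap to the equator with matched value and first derivative at both
#' junction vertices. The abscissa \eqn{t} is the axial position so that the
#' equatorial bulge is single-valued; the ordinate is the radial half-width.
#'
#' @slot a,b,c,d cubic coefficients (mixed mm units).
#' @slot fittedSpan abscissa interval (mm) over which the blend is valid.
#' @exportClass EquatorialBlend
setClass("EquatorialBlend",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                 fittedSpan = "numeric"),
  validity = function(object) {
    if (length(object@fittedSpan) != 2L)
      return("fittedSpan must be an interval of length 2")
    TRUE
  })

#' Equality constraints for the equatorial blend
#'
#' Positions, values and first derivatives prescribed at the two junction
#' vertices of a cubic blend. `rv1`/`rv2` are the abscissa positions of the
#' vertices (ordered; for the axial parameterisation these are axial
#' positions), `zv1`/`zv2` the ordinate values and `dzv1`/`dzv2` the
#' gradients there.
#'
#' @exportClass BlendConstraints
setClass("BlendConstraints",
  representation(rv1 = "numeric", rv2 = "numeric", zv1 = "numeric",
                 zv2 = "numeric", dzv1 = "numeric", dzv2 = "numeric"),
  validity = function(object) {
    v <- c(object@rv1, object@rv2, object@zv1, object@zv2,
           object@dzv1, object@dzv2)
    if (length(v) != 6L || any(!is.finite(v)))
      return("all vertex positions, values and gradients must be finite")
    TRUE
  })

#' Composite axisymmetric lens shape
#'
#' Piecewise-analytic meridional profile of an axisymmetric lens: two
#' aspheric caps joined to the equator by two C1 cubic blends. The lens
#' frame has the optical axis along x with the equatorial plane at x = 0;
#' the anterior pole is at x = TA and the posterior pole at x = -TP.
#' The surface half-width h(x) is evaluated with [lensHalfWidth()].
#'
#' @slot anterior,posterior the two [AsphericSurface-class] caps.
#' @slot blendTop,blendBottom anterior-side and posterior-side
#'   [EquatorialBlend-class] cubics.
#' @slot TA,TP anterior and posterior thickness (mm).
#' @slot LT lens thickness TA + TP (mm).
#' @slot ED equatorial diameter 2 * max h(x) (mm).
#' @slot equatorialRadius radius at the equator vertex (mm).
#' @slot rJunction radial position of the cap/blend junctions (mm).
#' @slot xV1,xV2 axial positions of the anterior and posterior junctions (mm).
#' @exportClass LensShape
setClass("LensShape",
  representation(anterior = "AsphericSurface", posterior = "AsphericSurface",
                 blendTop = "EquatorialBlend", blendBottom = "EquatorialBlend",
                 TA = "numeric", TP = "numeric", LT = "numeric",
                 ED = "numeric", equatorialRadius = "numeric",
                 rJunction = "numeric", xV1 = "numeric", xV2 = "numeric"),
  validity = function(object) {
    if (object@TA <= 0 || object@TP <= 0)
      return("anterior and posterior thickness must be positive")
    if (abs(object@LT - (object@TA + object@TP)) > 1e-9)
      return("LT must equal TA + TP")
    if (object@ED <= 0) return("ED must be positive")
    TRUE
  })

#' Segmented lens outline
#'
#' Ordered sub-pixel boundary of a lens silhouette in mm, centred on the
#' optical centre (intersection of the optical axis and the equatorial
#' plane). Column 1 is the axial (horizontal) coordinate, column 2 the
#' transverse (vertical) coordinate. Points flagged in `excluded` (e.g.
#' holder contact regions) never enter any fit.
#'
#' @exportClass LensOutline
setClass("LensOutline",
  representation(points = "matrix", pixelScale = "numeric",
                 excluded = "logical"),
  validity = function(object) {
    if (ncol(object@points) != 2L) return("points must be an n x 2 matrix")
    if (nrow(object@points) < 100L)
      return("an outline needs at least 100 points")
    if (length(object@excluded) != nrow(object@points))
      return("excluded flag must match the number of points")
    if (object@pixelScale <= 0) return("pixelScale must be positive")
    TRUE
  })

#' Exponential shear-modulus spatial variation function
#'
#' Two-parameter model \eqn{G(\xi/\xi_0) = \alpha e^{\beta \xi/\xi_0}} for
#' the spatial variation of the shear modulus along the dimensionless
#' radius: `alpha` (Pa) is the modulus at the lens midpoint, `beta` the
#' exponential rate towards the surface. The inverse problem constrains
#' (alpha, beta) to the box [1000, 50000] x [-3, 3]; forward evaluation
#' permits any finite values.
#'
#' @exportClass SVF
setClass("SVF",
  representation(alpha = "numeric", beta = "numeric"),
  validity = function(object) {
    if (!is.finite(object@alpha) || object@alpha <= 0)
      return("alpha must be a positive finite modulus in Pa")
    if (!is.finite(object@beta)) return("beta must be finite")
    TRUE
  })

#' Linear elastic material model of the lens
#'
#' @slot nu Poisson's ratio, strictly inside (0, 0.5).
#' @slot density mass density (kg m^-3).
#' @slot svf the [SVF-class] shear-modulus field.
#' @exportClass MaterialModel
setClass("MaterialModel",
  representation(nu = "numeric", density = "numeric", svf = "SVF"),
  validity = function(object) {
    if (object@nu <= 0 || object@nu >= 0.5)
      return("nu must lie strictly between 0 and 0.5 (use the near-incompressible setting for nu -> 0.5)")
    if (object@density <= 0) return("density must be positive")
    TRUE
  })

#' Spin condition
#'
#' @slot rpm rotational speed in revolutions per minute.
#' @slot omega angular velocity in rad/s, always rpm * 2 pi / 60.
#' @exportClass SpinCondition
setClass("SpinCondition",
  representation(rpm = "numeric", omega = "numeric"),
  validity = function(object) {
    if (object@rpm < 0) return("rpm must be non-negative")
    if (abs(object@omega - object@rpm * 2 * pi / 60) > 1e-9 * max(1, object@omega))
      return("omega must equal rpm * 2*pi/60")
    TRUE
  })

#' Axisymmetric triangular mesh of the lens half-section
#'
#' Mesh of the meridional half-section \{(r, z): 0 <= r <= h(z)\} with
#' linear triangles. `nodes` are (r, z) coordinates in mm; `boundary`
#' indexes the outer-surface nodes ordered from the posterior to the
#' anterior pole; `xi` holds the per-node dimensionless radius xi/xi0.
#'
#' @exportClass AxisymMesh
setClass("AxisymMesh",
  representation(nodes = "matrix", elements = "matrix", boundary = "integer",
                 xi = "numeric"),
  validity = function(object) {
    if (ncol(object@nodes) != 2L) return("nodes must be n x 2 (r, z)")
    if (ncol(object@elements) != 3L) return("elements must be m x 3")
    if (any(object@nodes[, 1] < -1e-9)) return("all node radii must be >= 0")
    if (length(object@xi) && length(object@xi) != nrow(object@nodes))
      return("xi must have one value per node")
    TRUE
  })

#' Dimensionless radius field
#'
#' Per-node decomposition of position along meridional rays from the lens
#' midpoint: `xi` is the distance from the midpoint (mm), `xi0` the
#' midpoint-to-surface distance along the same ray, `ratio = xi/xi0` the
#' dimensionless radius (0 at the midpoint, 1 on the surface), `theta` the
#' ray angle atan2(z, r) and `delta = xi0 - xi` the node-to-surface
#' distance.
#'
#' @exportClass DimlessRadiusField
setClass("DimlessRadiusField",
  representation(xi = "numeric", xi0 = "numeric", ratio = "numeric",
                 theta = "numeric", delta = "numeric"),
  validity = function(object) {
    n <- length(object@xi)
    if (any(lengths(list(object@xi0, object@ratio, object@theta,
                         object@delta)) != n))
      return("all field components must have equal length")
    if (any(object@ratio < -1e-9 | object@ratio > 1 + 1e-9))
      return("ratio must lie in [0, 1] for interior nodes")
    if (any(abs(object@xi + object@delta - object@xi0) > 1e-6))
      return("xi + delta must equal xi0 along each ray")
    TRUE
  })

#' Nodal displacement field on an axisymmetric mesh
#'
#' @slot mesh the [AxisymMesh-class] the solution lives on.
#' @slot u,w radial and axial nodal displacements (mm).
#' @slot omega angular velocity of the load case (rad/s).
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(mesh = "AxisymMesh", u = "numeric", w = "numeric",
                 omega = "numeric"),
  validity = function(object) {
    n <- nrow(object@mesh@nodes)
    if (length(object@u) != n || length(object@w) != n)
      return("u and w must have one value per node")
    axis <- abs(object@mesh@nodes[, 1]) < 1e-9
    if (any(abs(object@u[axis]) > 1e-8))
      return("radial displacement must vanish on the symmetry axis")
    TRUE
  })

#' Result of the inverse shear-modulus fit
#'
#' @slot svf the recovered [SVF-class].
#' @slot misfit final value of the deformation objective (mm^2).
#' @slot iterations objective evaluations used over all starts.
#' @slot converged logical; FALSE when the iteration cap was hit.
#' @slot boundActive logical; TRUE when a box bound is active at the optimum.
#' @slot starts per-start summary data frame.
#' @exportClass SVFFit
setClass("SVFFit",
  representation(svf = "SVF", misfit = "numeric", iterations = "numeric",
                 converged = "logical", boundActive = "logical",
                 starts = "data.frame"))

#' Single flip-angle spoiled gradient-echo image
#'
#' @slot signal magnitude image (arbitrary units, >= 0).
#' @slot flip nominal flip angle in degrees, in (0, 90).
#' @slot tr repetition time (ms).
#' @slot te echo time (ms); identical across angles so it cancels in the fit.
#' @exportClass FlipAngleImage
setClass("FlipAngleImage",
  representation(signal = "matrix", flip = "numeric", tr = "numeric",
                 te = "numeric"),
  prototype(te = 2.49),
  validity = function(object) {
    if (any(object@signal < 0)) return("signal must be non-negative")
    if (object@flip <= 0 || object@flip >= 90)
      return("nominal flip angle must lie in (0, 90) degrees")
    if (object@tr <= 0) return("tr must be positive")
    TRUE
  })

#' Radiofrequency field (B1) multiplier map
#'
#' Dimensionless multiplier between the actual and the nominal flip angle.
#' `spacing` and `origin` (mm) place voxel centres in a common frame so a
#' low-resolution map can be resampled onto an image grid.
#'
#' @exportClass B1Map
setClass("B1Map",
  representation(b1 = "matrix", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1), origin = c(0, 0)),
  validity = function(object) {
    if (any(object@b1 <= 0)) return("b1 must be strictly positive")
    if (length(object@spacing) != 2L || any(object@spacing <= 0))
      return("spacing must be two positive voxel sizes")
    if (length(object@origin) != 2L) return("origin must have length 2")
    TRUE
  })

#' Voxelwise T1, proton density and water-content maps
#'
#' `t1` (ms) is the free-water surrogate, `pd` (arbitrary units) the
#' total-water surrogate; `rho` = pd / pdWater is the normalised water
#' content once [waterContent()] has filled the pure-water reference.
#' `valid` flags voxels where the two-point fit was admissible; invalid
#' voxels hold NA so downstream averaging excludes rather than propagates.
#'
#' @exportClass T1PDMaps
setClass("T1PDMaps",
  representation(t1 = "matrix", pd = "matrix", valid = "matrix",
                 pdWater = "numeric", rho = "matrix", tr = "numeric"),
  prototype(pdWater = NA_real_),
  validity = function(object) {
    if (!all(dim(object@t1) == dim(object@pd)) ||
        !all(dim(object@t1) == dim(object@valid)))
      return("t1, pd and valid must share dimensions")
    if (any(object@t1[object@valid] <= 0, na.rm = TRUE))
      return("T1 must be positive where the fit is valid")
    TRUE
  })

#' One-dimensional profile against normalised lens distance
#'
#' Values of some voxel or model quantity sampled along the equatorial
#' axis, plotted against r/a in [-1, 1] where 0 is the lens centre and
#' +/-1 the boundary. `n` counts the voxels averaged per station.
#'
#' @exportClass LineProfile
setClass("LineProfile",
  representation(positions = "numeric", values = "numeric", n = "integer",
                 bandHalfwidth = "numeric", kind = "character"),
  prototype(bandHalfwidth = 2, kind = "generic"),
  validity = function(object) {
    if (length(object@positions) != length(object@values))
      return("positions and values must have equal length")
    if (is.unsorted(object@positions)) return("positions must be sorted")
    if (min(object@positions) < -1 - 1e-9 || max(object@positions) > 1 + 1e-9)
      return("positions must lie in [-1, 1]")
    TRUE
  })

#' Pointwise comparison band between conditions
#'
#' Per-station mean post/baseline ratio (or difference) with a two-sided
#' 95% confidence interval from the t distribution on n - 1 degrees of
#' freedom. The no-change reference is 1 for ratios and 0 for differences.
#'
#' @exportClass ComparisonBand
setClass("ComparisonBand",
  representation(positions = "numeric", mean = "numeric", lower = "numeric",
                 upper = "numeric", n = "integer", mode = "character"),
  validity = function(object) {
    k <- length(object@positions)
    if (any(lengths(list(object@mean, object@lower, object@upper,
                         object@n)) != k))
      return("all band components must have equal length")
    ok <- is.finite(object@lower) & is.finite(object@upper)
    if (any(object@lower[ok] > object@mean[ok] + 1e-9) ||
        any(object@upper[ok] < object@mean[ok] - 1e-9))
      return("band must satisfy lower <= mean <= upper")
    TRUE
  })

#' Ground-truth synthetic lens
#'
#' A lens with fully known geometry and material used to close the loop on
#' every downstream stage: silhouette rendering, segmentation, shape
#' fitting, spin simulation and inverse modulus recovery.
#'
#' @exportClass GroundTruthLens
setClass("GroundTruthLens",
  representation(shape = "LensShape", material = "MaterialModel",
                 preset = "character"),
  validity = function(object) {
    if (object@shape@ED <= 0 || object@shape@LT <= 0)
      return("equatorial diameter and thickness must be positive")
    # spheres have ED == LT; lenses are otherwise oblate
    if (object@shape@ED < object@shape@LT - 1e-9)
      return("equatorial diameter must be at least the lens thickness")
    TRUE
  })
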