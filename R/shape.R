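# Radius r solving sag(r) = s on [0, rMax]; vectorised Newton with clamping.
# The sag is monotone increasing on a cap, so Newton from a scaled initial
# guess converges; targets of 0 map to the pole exactly.
invertCapRadius <- function(surface, s, rMax) {
  sJ <- asphericSag(surface, rMax)
  r <- rMax * sqrt(pmax(s, 0) / sJ)
  r <- pmin(pmax(r, 0), rMax)
  for (i in 1:60) {
    f <- asphericSag(surface, r) - s
    fp <- asphericSagDeriv(surface, r)
    fp[!is.finite(fp) | fp < 1e-12] <- 1e-12
    step <- f / fp
    step[r == 0 & s <= 0] <- 0
    r <- pmin(pmax(r - step, 0), rMax * (1 + 1e-9))
    if (max(abs(f), na.rm = TRUE) < 1e-13) break
  }
  r[s <= 0] <- 0
  r
}

#' Compose a lens shape from caps and equatorial blends
#'
#' Joins two aspheric caps to the equator with two cubic blends so the
#' composite half-width h(x) is continuous with a continuous first
#' derivative at all four junctions. The lens frame puts the equatorial
#' plane at x = 0; caps cover |radius| <= `junctionFraction * a` and the
#' blends the outermost annulus up to the equator vertex at radius
#' `equatorialRadius`, where the gradient dh/dx is zero by symmetry of the
#' bulge. When `blendTop`/`blendBottom` are `NULL` they are constructed by
#' constrained least squares from the cap junction and equator vertex
#' constraints.
#'
#' @param anterior,posterior [AsphericSurface-class] caps with
#'   `vertexOffset` at +TA and -TP respectively.
#' @param equatorialRadius radius a at the equator vertex (mm).
#' @param blendTop,blendBottom optional precomputed
#'   [EquatorialBlend-class]s; must share the junction vertices with the
#'   caps to within 1e-6 mm.
#' @param junctionFraction cap/blend junction radius as a fraction of a.
#' @return A [LensShape-class].
#' @export
composeShape <- function(anterior, posterior, equatorialRadius,
                         blendTop = NULL, blendBottom = NULL,
                         junctionFraction = 0.95) {
  TA <- anterior@vertexOffset
  TP <- -posterior@vertexOffset
  if (TA <= 0 || TP <= 0)
    stop("cap vertices must lie on opposite sides of the equatorial plane")
  a <- equatorialRadius
  rJ <- junctionFraction * a
  sagA <- asphericSag(anterior, rJ)
  sagP <- asphericSag(posterior, rJ)
  if (!is.finite(sagA) || !is.finite(sagP))
    stop("cap surface is not real-valued at the junction radius")
  xV1 <- TA - sagA
  xV2 <- -TP + sagP
  if (xV1 <= 0 || xV2 >= 0)
    stop("cap junctions must bracket the equatorial plane; ",
         "surfaces never intersect a common equator")
  gradTop <- -1 / asphericSagDeriv(anterior, rJ)   # dh/dx at anterior junction
  gradBot <- 1 / asphericSagDeriv(posterior, rJ)
  mkBlend <- function(xv, grad) {
    cns <- blendConstraints(rv1 = 0, rv2 = xv, zv1 = a, zv2 = rJ,
                            dzv1 = 0, dzv2 = grad)
    ts <- seq(0, xv, length.out = 8)
    scatter <- cbind(ts, a + (rJ - a) * abs(ts / xv))  # consistency scatter
    fitEquatorialBlend(scatter, cns)
  }
  if (is.null(blendTop)) blendTop <- mkBlend(xV1, gradTop)
  if (is.null(blendBottom)) blendBottom <- mkBlend(xV2, gradBot)
  chk <- c(evalBlend(blendTop, xV1) - rJ, evalBlend(blendTop, 0) - a,
           evalBlend(blendBottom, xV2) - rJ, evalBlend(blendBottom, 0) - a)
  if (max(abs(chk)) > 1e-6)
    stop("junction mismatch between blends and caps exceeds 1e-6 mm")
  ED <- 2 * max(blendMax(blendTop)[["value"]],
                blendMax(blendBottom)[["value"]], rJ)
  new("LensShape", anterior = anterior, posterior = posterior,
      blendTop = blendTop, blendBottom = blendBottom,
      TA = TA, TP = TP, LT = TA + TP, ED = ED, equatorialRadius = a,
      rJunction = rJ, xV1 = xV1, xV2 = xV2)
}

#' Surface half-width h(x) of a composed lens
#'
#' Piecewise evaluation of the meridional half-width at axial positions x:
#' aspheric caps towards the poles, cubic blends around the equator, zero
#' outside [-TP, TA].
#'
#' @param shape a [LensShape-class].
#' @param x axial positions (mm).
#' @return Half-widths (mm), >= 0 with equality only at (and beyond) the poles.
#' @export
lensHalfWidth <- function(shape, x) {
  h <- numeric(length(x))
  iA <- which(x >= shape@xV1 & x <= shape@TA)
  if (length(iA))
    h[iA] <- invertCapRadius(shape@anterior, shape@TA - x[iA], shape@rJunction)
  iT <- which(x >= 0 & x < shape@xV1)
  if (length(iT)) h[iT] <- evalBlend(shape@blendTop, x[iT])
  iB <- which(x < 0 & x > shape@xV2)
  if (length(iB)) h[iB] <- evalBlend(shape@blendBottom, x[iB])
  iP <- which(x <= shape@xV2 & x >= -shape@TP)
  if (length(iP))
    h[iP] <- invertCapRadius(shape@posterior, x[iP] + shape@TP,
                             shape@rJunction)
  pmax(h, 0)
}

# Solve the apical radius so the cap's extrapolated profile passes through
# the equator control point (radius a, sag thickness T).
solveCapRadius <- function(a, T, kappa, a4, a6, a8) {
  f <- function(R) {
    s <- asphericSurface(R = R, kappa = kappa, a4 = a4, a6 = a6, a8 = a8)
    asphericSag(s, a) - T
  }
  Rlo <- if (kappa > -1) a * sqrt(1 + kappa) * (1 + 1e-10) else 1e-3 * a
  fLo <- f(Rlo)
  # hemispheric boundary case: the requested sag equals the maximum
  # achievable at the equator, reached exactly at the bracket end
  if (is.finite(fLo) && fLo < 0 && fLo > -1e-4 * a) return(Rlo)
  if (!is.finite(fLo) || fLo < 0)
    stop("invalid shape: no cap of the requested curvature family reaches ",
         "the common equator")
  Rhi <- Rlo * 2
  while (f(Rhi) > 0 && Rhi < 1e6 * a) Rhi <- Rhi * 2
  if (f(Rhi) > 0)
    stop("invalid shape: surfaces never intersect a common equator")
  stats::uniroot(f, c(Rlo, Rhi), tol = 1e-13)$root
}

#' Construct an analytic lens shape of requested size
#'
#' Builds a blended axisymmetric lens whose measured equatorial diameter and
#' thickness equal the request: the equator vertex is placed at ED/2 and the
#' poles at +`fracTA * LT` / -(1 - `fracTA`) * LT, and each cap's apical
#' radius is solved so its extrapolated profile passes through the equator
#' control point.
#'
#' @param ED equatorial diameter (mm).
#' @param LT lens thickness (mm).
#' @param fracTA anterior fraction of the thickness (the anterior bovine
#'   face is the flatter one).
#' @param kappaAnterior,kappaPosterior conic constants.
#' @param aAnterior,aPosterior length-3 vectors (a4, a6, a8) per face.
#' @param junctionFraction cap/blend junction radius as a fraction of ED/2.
#' @return A [LensShape-class].
#' @examples
#' sh <- makeLensShape(ED = 17.466, LT = 12.489)
#' c(sh@ED, sh@LT)
#' @export
makeLensShape <- function(ED, LT, fracTA = 0.45,
                          kappaAnterior = 0, kappaPosterior = 0,
                          aAnterior = c(0, 0, 0), aPosterior = c(0, 0, 0),
                          junctionFraction = 0.95) {
  if (ED <= 0 || LT <= 0) stop("requested ED and LT must be positive")
  a <- ED / 2
  TA <- fracTA * LT
  TP <- LT - TA
  RA <- solveCapRadius(a, TA, kappaAnterior,
                       aAnterior[1], aAnterior[2], aAnterior[3])
  RP <- solveCapRadius(a, TP, kappaPosterior,
                       aPosterior[1], aPosterior[2], aPosterior[3])
  ant <- asphericSurface(R = RA, kappa = kappaAnterior, a4 = aAnterior[1],
                         a6 = aAnterior[2], a8 = aAnterior[3],
                         side = "anterior", vertexOffset = TA)
  post <- asphericSurface(R = RP, kappa = kappaPosterior, a4 = aPosterior[1],
                          a6 = aPosterior[2], a8 = aPosterior[3],
                          side = "posterior", vertexOffset = -TP)
  composeShape(ant, post, equatorialRadius = a,
               junctionFraction = junctionFraction)
}

#' Ground-truth lens presets
#'
#' Bovine lens presets at the physical scale of the isotonic-AAH cohort
#' (ED 17.466 mm, LT 12.489 mm) combined with the literature-derived
#' material constants used for spin-test modelling: Poisson's ratio 0.4,
#' density 1104 kg m^-3, and exponential shear-modulus fields
#' (alpha = 17000 Pa, beta = -0.79) for the young-bovine and
#' (alpha = 10080 Pa, beta = -2.02) for the old-bovine preset. The
#' `"sphere"` preset is a homogeneous sphere used for closed-form checks.
#'
#' @param preset `"young-bovine"`, `"old-bovine"` or `"sphere"`.
#' @param r0 sphere radius (mm), used by the `"sphere"` preset only.
#' @return A [GroundTruthLens-class].
#' @export
lensPreset <- function(preset = c("young-bovine", "old-bovine", "sphere"),
                       r0 = 5) {
  preset <- match.arg(preset)
  if (preset == "sphere") {
    shape <- makeLensShape(ED = 2 * r0, LT = 2 * r0, fracTA = 0.5)
    mat <- materialModel(nu = 0.4, density = 1104,
                         svf = svf(alpha = 17000, beta = 0))
  } else {
    sv <- if (preset == "young-bovine") svf(17000, -0.79) else svf(10080, -2.02)
    shape <- makeLensShape(ED = 17.466, LT = 12.489)
    mat <- materialModel(nu = 0.4, density = 1104, svf = sv)
  }
  new("GroundTruthLens", shape = shape, material = mat, preset = preset)
}

# composite Simpson over [lo, hi] with an even number of intervals
simpsonInt <- function(f, lo, hi, step) {
  len <- hi - lo
  if (len <= 0) return(0)
  n <- max(4L, 2L * ceiling(len / step / 2))
  x <- seq(lo, hi, length.out = n + 1L)
  y <- f(x)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * y) * len / n / 3
}

#' Lens volume by solid of revolution
#'
#' \eqn{V = \pi \int_{-T_P}^{T_A} h(x)^2 dx} by composite Simpson
#' quadrature, integrated piecewise over the four analytic segments so the
#' integrand is smooth within every panel.
#'
#' @param shape a [LensShape-class].
#' @param step quadrature step (mm); default LT/2000.
#' @return Volume (mm^3).
#' @examples
#' lensVolume(lensPreset("sphere", r0 = 5)@shape)  # ~ 4/3 pi 125
#' @export
lensVolume <- function(shape, step = shape@LT / 2000) {
  if (step <= 0) stop("quadrature step must be positive")
  f <- function(x) lensHalfWidth(shape, x)^2
  brk <- c(-shape@TP, shape@xV2, 0, shape@xV1, shape@TA)
  pi * sum(vapply(seq_len(4), function(i)
    simpsonInt(f, brk[i], brk[i + 1], step), numeric(1)))
}

#' Percent change between paired measurements
#'
#' Per-lens percent change 100 (after - before)/before; for vectors the
#' mean and sample SD over lenses are reported and, with n >= 3, a plain
#' paired two-sided t-test p-value is attached.
#'
#' @param before,after matched scalars or per-lens vectors; `before` must
#'   be non-zero.
#' @return A list with `perLens`, `mean`, `sd`, `n` and `p` (NA when n < 3).
#' @examples
#' percentChange(1755.31, 1652.65)$mean  # -5.85 (2 dp)
#' @export
percentChange <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must have matched lengths")
  if (any(before == 0)) stop("before values must be non-zero")
  pct <- 100 * (after - before) / before
  p <- if (length(pct) >= 3L)
    stats::t.test(after, before, paired = TRUE)$p.value else NA_real_
  list(perLens = pct, mean = mean(pct),
       sd = if (length(pct) > 1L) stats::sd(pct) else NA_real_,
       n = length(pct), p = p)
}
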