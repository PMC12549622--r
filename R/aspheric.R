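#' Construct an aspheric surface
#'
#' @param R apical radius of curvature (mm), non-zero.
#' @param kappa conic constant.
#' @param a4,a6,a8 aspheric deviation coefficients.
#' @param side `"anterior"` or `"posterior"`.
#' @param vertexOffset axial position of the vertex in the lens frame (mm).
#' @return An [AsphericSurface-class].
#' @examples
#' s <- asphericSurface(R = 8)
#' asphericSag(s, c(0, 1, 2))
#' @export
asphericSurface <- function(R, kappa = 0, a4 = 0, a6 = 0, a8 = 0,
                            side = c("anterior", "posterior"),
                            vertexOffset = 0) {
  side <- match.arg(side)
  new("AsphericSurface", R = R, kappa = kappa, a4 = a4, a6 = a6, a8 = a8,
      side = side, vertexOffset = vertexOffset)
}

#' Evaluate the sag of an aspheric surface
#'
#' Vertex-local sag \eqn{Z(r)}; positive towards the equatorial plane.
#' Returns `NA` where the conic term is not real-valued.
#'
#' @param surface an [AsphericSurface-class].
#' @param r radial distances from the optical axis (mm).
#' @return Sag values (mm).
#' @export
asphericSag <- function(surface, r) {
  R <- surface@R; k <- surface@kappa
  disc <- 1 - (1 + k) * r^2 / R^2
  z <- ifelse(disc >= 0,
              r^2 / (R * (1 + sqrt(pmax(disc, 0)))),
              NA_real_)
  z + surface@a4 * r^4 + surface@a6 * r^6 + surface@a8 * r^8
}

#' First derivative dZ/dr of the aspheric sag
#'
#' @inheritParams asphericSag
#' @return Derivative values (dimensionless).
#' @export
asphericSagDeriv <- function(surface, r) {
  R <- surface@R; k <- surface@kappa
  disc <- 1 - (1 + k) * r^2 / R^2
  dz <- ifelse(disc > 0, r / (R * sqrt(pmax(disc, 1e-300))), NA_real_)
  dz + 4 * surface@a4 * r^3 + 6 * surface@a6 * r^5 + 8 * surface@a8 * r^7
}

#' Backward-difference gradient at a vertex point
#'
#' Numerical gradient \eqn{(z(r_v) - z(r_{v-1})) / (r_v - r_{v-1})} between a
#' vertex point and its predecessor in an ordered point sequence. The
#' backward difference (rather than a centred one) is used deliberately so
#' the gradient at a sequence-terminal junction vertex is well defined.
#'
#' @param points n x 2 matrix of ordered (r, z) points.
#' @param vertexIndex index of the vertex point (must have a predecessor).
#' @return The gradient (dimensionless).
#' @examples
#' r <- seq(0, 1, by = 0.01)
#' vertexGradient(cbind(r, r^2), length(r))  # 1.99, not 2
#' @export
vertexGradient <- function(points, vertexIndex) {
  points <- as.matrix(points)
  if (vertexIndex <= 1L || vertexIndex > nrow(points))
    stop("vertex must have a neighbouring point before it")
  dr <- points[vertexIndex, 1] - points[vertexIndex - 1L, 1]
  if (dr == 0) stop("coincident abscissae at the vertex")
  unname((points[vertexIndex, 2] - points[vertexIndex - 1L, 2]) / dr)
}

#' Fit an aspheric surface to cap points
#'
#' Least-squares fit of the conic-plus-polynomial sag model with three
#' aspheric terms (a4, a6, a8) to points from one lens cap. Points are
#' given in the lens frame (axial x, transverse y); the radial coordinate
#' is |y| and the sag is measured from the fitted vertex, whose axial
#' position is estimated jointly with the surface parameters.
#'
#' @param points n x 2 matrix of (x, y) points in mm, n >= 10, spanning at
#'   least 60% of the cap's radial extent.
#' @param side `"anterior"` (vertex at max x) or `"posterior"` (min x).
#' @return An [AsphericSurface-class] with `rmsResidual` filled.
#' @export
fitAspheric <- function(points, side = c("anterior", "posterior")) {
  side <- match.arg(side)
  points <- as.matrix(points)
  if (nrow(points) < 10L)
    stop("at least 10 points are required to fit an aspheric surface")
  r <- abs(points[, 2])
  if ((max(r) - min(r)) < 0.6 * max(r))
    stop("points must span at least 60% of the cap's radial extent")
  sgn <- if (side == "anterior") 1 else -1
  x <- sgn * points[, 1]               # vertex now at max x for both sides
  xv0 <- max(x)
  sag <- xv0 - x
  # parabolic start for the apical radius: sag ~ r^2 / (2R)
  R0 <- 1 / (2 * max(stats::coef(stats::lm(sag ~ I(r^2) + 0))[1], 1e-6))
  # variable projection: for a candidate (R, kappa) the remaining
  # parameters (xv, a4, a6, a8) enter linearly and are solved exactly,
  # leaving a smooth 2-D profile objective for the nonlinear pair
  X <- cbind(1, -r^4, -r^6, -r^8)
  conicSag <- function(R, kappa) {
    disc <- 1 - (1 + kappa) * r^2 / R^2
    if (any(disc <= 1e-12)) return(NULL)   # complex over the span
    r^2 / (R * (1 + sqrt(disc)))
  }
  rssOf <- function(p) {                   # p = (log R, kappa)
    cz <- conicSag(exp(p[1]), p[2])
    if (is.null(cz)) return(1e12 * (1 + abs(p[2])))
    sum(stats::lm.fit(X, x + cz)$residuals^2)
  }
  o <- stats::optim(c(log(R0), 0), rssOf, method = "Nelder-Mead",
                    control = list(maxit = 4000, reltol = 1e-15))
  o <- stats::optim(o$par, rssOf, method = "Nelder-Mead",
                    control = list(maxit = 4000, reltol = 1e-15))
  if (o$value >= 1e11)
    stop("aspheric fit did not converge to a real-valued surface")
  # the profile objective is a shallow valley in kappa (the conic term is
  # only weakly separated from the polynomial terms over a finite span),
  # so refine with a nested 1-D search: outer golden-section on kappa,
  # inner on log R
  profR <- function(k)
    stats::optimize(function(lr) rssOf(c(lr, k)),
                    o$par[1] + c(-log(2), log(2)), tol = 1e-12)
  ok <- stats::optimize(function(k) profR(k)$objective,
                        o$par[2] + c(-0.6, 0.6), tol = 1e-9)
  kappa <- ok$minimum
  R <- exp(profR(kappa)$minimum)
  rssFinal <- rssOf(c(log(R), kappa))
  lin <- unname(stats::lm.fit(X, x + conicSag(R, kappa))$coefficients)
  # Levenberg-Marquardt polish of all six parameters from the profile
  # solution (harmless when already at the optimum)
  safeSag <- function(r, R, kappa, a4, a6, a8) {
    disc <- pmax(1 - (1 + kappa) * r^2 / R^2, 1e-12)
    r^2 / (R * (1 + sqrt(disc))) + a4 * r^4 + a6 * r^6 + a8 * r^8
  }
  fit <- try(minpack.lm::nlsLM(
    x ~ xv - safeSag(r, R, kappa, a4, a6, a8),
    data = data.frame(r = r, x = x),
    start = list(xv = lin[1], R = R, kappa = kappa, a4 = lin[2],
                 a6 = lin[3], a8 = lin[4]),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)), silent = TRUE)
  pProfile <- c(xv = lin[1], R = R, kappa = kappa, a4 = lin[2],
                a6 = lin[3], a8 = lin[4])
  if (inherits(fit, "try-error") ||
      mean(stats::resid(fit)^2) > rssFinal / length(r)) {
    p <- pProfile
    rms <- sqrt(rssFinal / length(r))
  } else {
    p <- stats::coef(fit)
    rms <- sqrt(mean(stats::resid(fit)^2))
  }
  # surface must be real over the fitted span
  if ((1 + p[["kappa"]]) * max(r)^2 / p[["R"]]^2 > 1 + 1e-9)
    stop("fitted surface is complex-valued over the data span")
  s <- asphericSurface(R = p[["R"]], kappa = p[["kappa"]], a4 = p[["a4"]],
                       a6 = p[["a6"]], a8 = p[["a8"]], side = side,
                       vertexOffset = sgn * p[["xv"]])
  s@rmsResidual <- rms
  s
}
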