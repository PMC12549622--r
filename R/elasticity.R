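#' Construct a shear-modulus spatial variation function
#'
#' @param alpha shear modulus at the lens midpoint (Pa).
#' @param beta exponential rate along the dimensionless radius.
#' @return An [SVF-class].
#' @export
svf <- function(alpha, beta) new("SVF", alpha = alpha, beta = beta)

#' Construct a material model
#'
#' @param nu Poisson's ratio, strictly in (0, 0.5).
#' @param density mass density (kg m^-3).
#' @param svf an [SVF-class]; defaults to a uniform 17 kPa field.
#' @return A [MaterialModel-class].
#' @export
materialModel <- function(nu = 0.4, density = 1104,
                          svf = lensmech::svf(17000, 0)) {
  new("MaterialModel", nu = nu, density = density, svf = svf)
}

#' Construct a spin condition
#'
#' @param rpm rotational speed (rev/min); or give `omega` instead.
#' @param omega angular velocity (rad/s).
#' @return A [SpinCondition-class] with both fields consistent.
#' @export
spinCondition <- function(rpm = NULL, omega = NULL) {
  if (is.null(rpm) && is.null(omega)) stop("give rpm or omega")
  if (is.null(omega)) omega <- rpm * 2 * pi / 60
  if (is.null(rpm)) rpm <- omega * 60 / (2 * pi)
  new("SpinCondition", rpm = rpm, omega = omega)
}

#' Convert rotational speed to angular velocity
#'
#' @param rpm revolutions per minute, >= 0.
#' @return Angular velocity in rad/s (rpm * 2 pi / 60).
#' @examples
#' rpmToAngularVelocity(1000)  # 104.72 rad/s
#' @export
rpmToAngularVelocity <- function(rpm) {
  if (any(rpm < 0)) stop("rpm must be non-negative")
  rpm * 2 * pi / 60
}

#' Strobe positions per rotation
#'
#' Number of distinct angular positions captured when a strobe fires every
#' `interval` radians during a full rotation.
#'
#' @param interval strobe interval in radians.
#' @return Positions per rotation, 2 pi / interval.
#' @examples
#' strobePositionsPerRotation(0.5236)  # ~12
#' @export
strobePositionsPerRotation <- function(interval) {
  if (any(interval <= 0)) stop("interval must be positive")
  2 * pi / interval
}

#' Shear modulus from Young's modulus
#'
#' Isotropic conversion G = E / (2 (1 + nu)).
#'
#' @param E Young's modulus (Pa), positive.
#' @param nu Poisson's ratio in (-1, 0.5]; incompressible nu = 0.5 is
#'   admitted here because the conversion (unlike the displacement
#'   formulation) stays well defined.
#' @return Shear modulus (Pa).
#' @examples
#' shearFromYoung(3.70e3, 0.5)  # 1.23e3 Pa at 3 s.f.
#' @export
shearFromYoung <- function(E, nu) {
  if (any(E <= 0)) stop("E must be positive")
  if (any(nu <= -1 | nu > 0.5)) stop("nu must lie in (-1, 0.5]")
  E / (2 * (1 + nu))
}

#' Evaluate the shear-modulus field
#'
#' \eqn{G_i = \alpha e^{\beta \, \xi_i/\xi_{0,i}}} per node of a
#' dimensionless radius field (or directly on given ratios).
#'
#' @param svf an [SVF-class].
#' @param field a [DimlessRadiusField-class] or a numeric vector of ratios.
#' @return Shear moduli (Pa).
#' @export
svfModulus <- function(svf, field) {
  ratio <- if (is(field, "DimlessRadiusField")) field@ratio else field
  svf@alpha * exp(svf@beta * ratio)
}

# Precompute the geometry-dependent part of the axisymmetric FEM system:
# per-element unit stiffness triplets (stiffness = sum_e G_e * Khat_e),
# centrifugal load per unit rho*omega^2, the free-dof reduction and the
# per-element dimensionless radius. Linear (constant-strain) triangles,
# one-point quadrature at the centroid; dofs are (u_1..u_n, w_1..w_n).
femSystem <- function(mesh, nu) {
  nd <- mesh@nodes / 1000                      # mm -> m
  el <- mesh@elements
  m <- nrow(el); n <- nrow(nd)
  r1 <- nd[el[, 1], 1]; z1 <- nd[el[, 1], 2]
  r2 <- nd[el[, 2], 1]; z2 <- nd[el[, 2], 2]
  r3 <- nd[el[, 3], 1]; z3 <- nd[el[, 3], 2]
  twoA <- (r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1)
  if (any(twoA <= 0)) stop("mesh contains non-positively oriented elements")
  A <- twoA / 2
  rbar <- (r1 + r2 + r3) / 3
  b <- cbind(z2 - z3, z3 - z1, z1 - z2) / twoA      # dN_i/dr
  cc <- cbind(r3 - r2, r1 - r3, r2 - r1) / twoA     # dN_i/dz
  # B rows: e_rr, e_zz, e_tt, g_rz ; local cols (u1,w1,u2,w2,u3,w3)
  B <- vector("list", 4)
  for (p in 1:4) B[[p]] <- matrix(0, m, 6)
  for (i in 1:3) {
    B[[1]][, 2 * i - 1] <- b[, i]
    B[[2]][, 2 * i] <- cc[, i]
    B[[3]][, 2 * i - 1] <- (1 / 3) / rbar
    B[[4]][, 2 * i - 1] <- cc[, i]
    B[[4]][, 2 * i] <- b[, i]
  }
  # D = G * D1 with E = 2 G (1 + nu)
  M <- matrix(c(1 - nu, nu, nu, 0,
                nu, 1 - nu, nu, 0,
                nu, nu, 1 - nu, 0,
                0, 0, 0, (1 - 2 * nu) / 2), 4, 4)
  D1 <- 2 / (1 - 2 * nu) * M
  fac <- 2 * pi * rbar * A
  vals <- matrix(0, m, 36)
  iLoc <- integer(36); jLoc <- integer(36)
  k <- 0L
  for (i in 1:6) for (j in 1:6) {
    k <- k + 1L
    iLoc[k] <- i; jLoc[k] <- j
    acc <- 0
    for (p in 1:4) for (q in 1:4) if (D1[p, q] != 0)
      acc <- acc + D1[p, q] * B[[p]][, i] * B[[q]][, j]
    vals[, k] <- fac * acc
  }
  locDof <- function(loc) {                    # local col -> global dof
    node <- el[, ceiling(loc / 2)]
    if (loc %% 2 == 1) node else n + node
  }
  iIdx <- integer(36 * m); jIdx <- integer(36 * m)
  for (k in 1:36) {
    sl <- ((k - 1) * m + 1):(k * m)
    iIdx[sl] <- locDof(iLoc[k])
    jIdx[sl] <- locDof(jLoc[k])
  }
  valsUnit <- as.vector(vals)                  # column-major: block per (i,j)
  elemOf <- rep(seq_len(m), times = 36)
  # centrifugal load per unit rho*omega^2: radial, lumped via shape fns
  fUnit <- numeric(2 * n)
  contrib <- fac * rbar / 3
  for (i in 1:3) {
    t <- tapply(contrib, el[, i], sum)
    idx <- as.integer(names(t))
    fUnit[idx] <- fUnit[idx] + t
  }
  # boundary conditions: u = 0 on the symmetry axis, w pinned at the node
  # nearest the midpoint (removes the axial rigid-body translation)
  axis <- which(abs(mesh@nodes[, 1]) < 1e-9)
  pin <- which.min(mesh@nodes[, 1]^2 + mesh@nodes[, 2]^2)
  fixed <- c(axis, n + pin)
  free <- setdiff(seq_len(2 * n), fixed)
  dofMap <- integer(2 * n); dofMap[free] <- seq_along(free)
  keep <- dofMap[iIdx] > 0 & dofMap[jIdx] > 0
  xiElem <- (mesh@xi[el[, 1]] + mesh@xi[el[, 2]] + mesh@xi[el[, 3]]) / 3
  list(n = n, free = free,
       iRed = dofMap[iIdx[keep]], jRed = dofMap[jIdx[keep]],
       valsUnit = valsUnit[keep], elemOf = elemOf[keep],
       fUnit = fUnit[free], xiElem = xiElem)
}

# Solve the reduced system for given per-element shear moduli (Pa) and
# load multiplier rho*omega^2; returns full-length (u, w) in metres.
femSolve <- function(sys, Gelem, rhoOmega2) {
  x <- sys$valsUnit * Gelem[sys$elemOf]
  K <- Matrix::sparseMatrix(i = sys$iRed, j = sys$jRed, x = x,
                            dims = c(length(sys$free), length(sys$free)))
  sol <- tryCatch(as.numeric(Matrix::solve(K, sys$fUnit * rhoOmega2)),
                  error = function(e)
                    stop("singular stiffness system; for nearly ",
                         "incompressible materials use nu <= 0.49 ",
                         "(near-incompressible setting): ", e$message))
  full <- numeric(2 * sys$n)
  full[sys$free] <- sol
  list(u = full[seq_len(sys$n)], w = full[sys$n + seq_len(sys$n)])
}

#' Forward spin simulation
#'
#' Solves axisymmetric linear isotropic elastostatics for a lens spun about
#' its optical axis: centrifugal body force \eqn{\rho \omega^2 r} directed
#' radially outward, traction-free outer surface, zero radial displacement
#' on the symmetry axis, and the axial rigid-body translation removed by
#' pinning the node nearest the lens midpoint. The shear modulus varies
#' per element as the material's SVF evaluated at the mean nodal
#' dimensionless radius.
#'
#' @param mesh an [AxisymMesh-class] with its `xi` field filled (as
#'   produced by [lensMesh()]).
#' @param material a [MaterialModel-class].
#' @param spin a [SpinCondition-class].
#' @return A [DisplacementField-class] with nodal displacements in mm.
#' @export
forwardSpin <- function(mesh, material, spin) {
  sys <- femSystem(mesh, material@nu)
  G <- svfModulus(material@svf, sys$xiElem)
  sol <- femSolve(sys, G, material@density * spin@omega^2)
  new("DisplacementField", mesh = mesh, u = sol$u * 1000, w = sol$w * 1000,
      omega = spin@omega)
}

#' Deformed outer outline of a displacement field
#'
#' @param field a [DisplacementField-class].
#' @return Matrix with columns `x` (axial, mm) and `r` (radial, mm), the
#'   displaced boundary nodes ordered from the posterior to the anterior
#'   pole.
#' @export
deformedOutline <- function(field) {
  b <- field@mesh@boundary
  out <- cbind(x = field@mesh@nodes[b, 2] + field@w[b],
               r = field@mesh@nodes[b, 1] + field@u[b])
  out
}

#' Spin-deform a lens shape
#'
#' Convenience wrapper: meshes the shape, runs [forwardSpin()] and returns
#' the deformed outer outline. At omega = 0 the undeformed boundary is
#' returned unchanged.
#'
#' @param lens a [GroundTruthLens-class], or a [LensShape-class] when
#'   `material` is given.
#' @param omega angular velocity (rad/s), >= 0.
#' @param material a [MaterialModel-class] (ignored when `lens` is a
#'   ground-truth lens).
#' @param nS,nTheta mesh resolution.
#' @return Matrix with columns `x`, `r` (mm); attribute `"field"` carries
#'   the full [DisplacementField-class].
#' @export
spinDeformShape <- function(lens, omega, material = NULL,
                            nS = 40, nTheta = 80) {
  if (omega < 0) stop("omega must be non-negative")
  if (is(lens, "GroundTruthLens")) {
    shape <- lens@shape; material <- lens@material
  } else {
    shape <- lens
    if (is.null(material)) stop("material required for a bare shape")
  }
  mesh <- lensMesh(shape, nS = nS, nTheta = nTheta)
  if (omega == 0) {
    fld <- new("DisplacementField", mesh = mesh,
               u = numeric(nrow(mesh@nodes)), w = numeric(nrow(mesh@nodes)),
               omega = 0)
  } else {
    fld <- forwardSpin(mesh, material, spinCondition(omega = omega))
  }
  out <- deformedOutline(fld)
  attr(out, "field") <- fld
  out
}

#' Shear-modulus line profile along the equatorial axis
#'
#' Samples G(r/a) of an SVF on the equatorial radius, mirrored to
#' r/a in [-1, 1] (along the equatorial axis the dimensionless radius
#' equals |r|/a), and divides by a normalising modulus.
#'
#' @param svf an [SVF-class].
#' @param positions stations r/a in [-1, 1].
#' @param normaliseTo positive reference modulus (Pa); e.g. the nuclear
#'   maximum of the baseline profile.
#' @return A [LineProfile-class] of kind `"shear"`.
#' @export
shearProfile <- function(svf, positions = seq(-1, 1, length.out = 101),
                         normaliseTo = 1) {
  if (normaliseTo <= 0) stop("normaliseTo must be positive")
  vals <- svfModulus(svf, abs(positions)) / normaliseTo
  new("LineProfile", positions = positions, values = vals,
      n = rep(1L, length(positions)), bandHalfwidth = 0, kind = "shear")
}
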