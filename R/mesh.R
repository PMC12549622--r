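#' Distance from the lens midpoint to the surface along a meridional ray
#'
#' The midpoint is the intersection of the optical and equatorial axes
#' (the origin of the lens frame). For a ray at angle
#' \eqn{\theta = atan2(z, r)} the surface distance \eqn{\xi_0} solves
#' \eqn{t \cos\theta = h(t \sin\theta)} by exact root bracketing against
#' the analytic composite surface.
#'
#' @param shape a [LensShape-class].
#' @param theta ray angles in radians, in [-pi/2, pi/2].
#' @return Distances (mm).
#' @export
boundaryDistance <- function(shape, theta) {
  a <- shape@equatorialRadius
  tmax <- 1.5 * (a + shape@LT)
  vapply(theta, function(th) {
    ct <- cos(th); st <- sin(th)
    if (abs(ct) < 1e-12) return(if (st > 0) shape@TA else shape@TP)
    g <- function(t) t * ct - lensHalfWidth(shape, t * st)
    stats::uniroot(g, c(1e-9, tmax), tol = 1e-12)$root
  }, numeric(1))
}

#' Dimensionless radius field over mesh nodes
#'
#' For every node, the distance \eqn{\xi} to the lens midpoint, the
#' midpoint-to-surface distance \eqn{\xi_0} along the same meridional ray
#' (by exact ray-boundary intersection against the analytic surface), and
#' their ratio: 0 at the midpoint, 1 on the surface.
#'
#' @param mesh an [AxisymMesh-class] (or an n x 2 matrix of (r, z) nodes).
#' @param shape the [LensShape-class] the nodes lie in.
#' @return A [DimlessRadiusField-class].
#' @export
dimensionlessRadius <- function(mesh, shape) {
  nodes <- if (is(mesh, "AxisymMesh")) mesh@nodes else as.matrix(mesh)
  r <- nodes[, 1]; z <- nodes[, 2]
  t <- sqrt(r^2 + z^2)
  theta <- atan2(z, r)
  theta[t < 1e-12] <- 0
  key <- round(theta, 12)
  uk <- unique(key)
  xi0u <- boundaryDistance(shape, uk)
  xi0 <- xi0u[match(key, uk)]
  ratio <- t / xi0
  if (any(ratio > 1 + 1e-9))
    stop("node(s) outside the lens surface")
  ratio <- pmin(ratio, 1)
  new("DimlessRadiusField", xi = t, xi0 = xi0, ratio = ratio,
      theta = theta, delta = xi0 - t)
}

#' Structured axisymmetric mesh of the lens half-section
#'
#' Triangulates the meridional half-section on a polar grid of rays from
#' the lens midpoint: `nTheta + 1` rays spanning [-pi/2, pi/2] and `nS`
#' radial layers at equal fractions of the ray's surface distance, giving
#' `nTheta * (2 nS - 1)` positively oriented triangles. Node layout makes
#' the stored dimensionless radius exact by construction.
#'
#' @param shape a [LensShape-class].
#' @param nS radial layers.
#' @param nTheta angular intervals.
#' @return An [AxisymMesh-class].
#' @export
lensMesh <- function(shape, nS = 32, nTheta = 64) {
  thetas <- seq(-pi / 2, pi / 2, length.out = nTheta + 1L)
  xi0 <- boundaryDistance(shape, thetas)
  nn <- 1L + nS * (nTheta + 1L)
  nodes <- matrix(0, nn, 2)
  xi <- numeric(nn)
  id <- function(i, j) 1L + (i - 1L) * (nTheta + 1L) + j + 1L  # i>=1, j 0-based
  for (i in seq_len(nS)) {
    s <- i / nS
    jj <- 0:nTheta
    nodes[id(i, jj), 1] <- s * xi0 * cos(thetas)
    nodes[id(i, jj), 2] <- s * xi0 * sin(thetas)
    xi[id(i, jj)] <- s
  }
  nodes[abs(nodes[, 1]) < 1e-12, 1] <- 0
  elems <- matrix(0L, nTheta * (2L * nS - 1L), 3L)
  k <- 0L
  for (j in seq_len(nTheta) - 1L) {            # fan around the midpoint
    k <- k + 1L
    elems[k, ] <- c(1L, id(1L, j), id(1L, j + 1L))
  }
  for (i in seq_len(nS - 1L)) {
    for (j in seq_len(nTheta) - 1L) {
      A <- id(i, j); B <- id(i, j + 1L)
      C <- id(i + 1L, j); D <- id(i + 1L, j + 1L)
      elems[k + 1L, ] <- c(A, C, D)
      elems[k + 2L, ] <- c(A, D, B)
      k <- k + 2L
    }
  }
  bnd <- as.integer(id(nS, 0:nTheta))
  new("AxisymMesh", nodes = nodes, elements = elems, boundary = bnd, xi = xi)
}
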