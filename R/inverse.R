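# run expr with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Squared-difference misfit between two deformed outlines
#'
#' Resamples both outlines onto a common grid of axial stations spanning
#' their overlap and sums the squared differences of the radial positions:
#' \eqn{\sum_k (r_{sim}(z_k) - r_{obs}(z_k))^2}. Zero iff the outlines
#' coincide on the grid; invariant to the point ordering of the inputs.
#'
#' @param simulated,observed matrices with columns `x` (axial, mm) and `r`
#'   (radial, mm).
#' @param nGrid number of axial stations.
#' @return Scalar misfit (mm^2).
#' @export
deformationObjective <- function(simulated, observed, nGrid = 200) {
  s <- as.matrix(simulated); o <- as.matrix(observed)
  s <- s[order(s[, 1]), , drop = FALSE]
  o <- o[order(o[, 1]), , drop = FALSE]
  lo <- max(min(s[, 1]), min(o[, 1]))
  hi <- min(max(s[, 1]), max(o[, 1]))
  if (hi <= lo) stop("outlines have non-overlapping axial ranges")
  zg <- seq(lo, hi, length.out = nGrid)
  rs <- stats::approx(s[, 1], s[, 2], xout = zg, ties = mean)$y
  ro <- stats::approx(o[, 1], o[, 2], xout = zg, ties = mean)$y
  sum((rs - ro)^2)
}

#' Inverse estimation of the shear-modulus spatial variation
#'
#' Recovers the (alpha, beta) of the exponential shear-modulus field from a
#' stationary lens shape and an observed spun outline, by minimising
#' [deformationObjective()] between the simulated and observed deformed
#' outlines over the box `bounds`. The optimizer is bounded L-BFGS-B on
#' box-scaled parameters, started from the centre of the box plus
#' `nRestarts` Latin-hypercube restarts; forward solves are cached in beta
#' (for fixed beta the displacement scales as 1/alpha, so alpha moves are
#' free).
#'
#' @param stationary the stationary [LensShape-class].
#' @param spunOutline observed deformed outline, matrix with columns
#'   `x`, `r` (mm).
#' @param material a [MaterialModel-class]; its `svf` slot is ignored.
#' @param spin a [SpinCondition-class].
#' @param bounds list with `alpha` and `beta` length-2 ranges; defaults to
#'   the standard box alpha in [1000, 50000] Pa, beta in [-3, 3].
#' @param tol optimality tolerance (projected gradient on the scaled
#'   problem).
#' @param maxit iteration cap; hitting it sets `converged = FALSE` (a
#'   warning flag, not an error).
#' @param nRestarts additional seeded Latin-hypercube starts.
#' @param nS,nTheta mesh resolution for the forward model
#'   (default ~4k elements).
#' @param maxMisfit sanity threshold: a final misfit above it raises a
#'   quality error.
#' @param seed seed for the restart design.
#' @param nGrid axial stations for the objective.
#' @return An [SVFFit-class].
#' @export
invertSVF <- function(stationary, spunOutline, material, spin,
                      bounds = list(alpha = c(1000, 50000), beta = c(-3, 3)),
                      tol = 1e-3, maxit = 1000, nRestarts = 4,
                      nS = 32, nTheta = 64, maxMisfit = 10, seed = 0,
                      nGrid = 200) {
  mesh <- lensMesh(stationary, nS = nS, nTheta = nTheta)
  sys <- femSystem(mesh, material@nu)
  rhoW2 <- material@density * spin@omega^2
  bnd <- mesh@boundary
  bx <- mesh@nodes[bnd, 2]; br <- mesh@nodes[bnd, 1]
  cache <- new.env(parent = emptyenv())
  nEval <- 0L
  unitDisp <- function(beta) {                 # displacement at alpha = 1
    key <- sprintf("%.15g", beta)
    if (!is.null(cache[[key]])) return(cache[[key]])
    sol <- femSolve(sys, exp(beta * sys$xiElem), rhoW2)
    cache[[key]] <- sol
    sol
  }
  obj <- function(p) {                         # p scaled to [0,1]^2
    nEval <<- nEval + 1L
    alpha <- bounds$alpha[1] + p[1] * diff(bounds$alpha)
    beta <- bounds$beta[1] + p[2] * diff(bounds$beta)
    sol <- unitDisp(beta)
    sim <- cbind(x = bx + sol$w[bnd] * 1000 / alpha,
                 r = br + sol$u[bnd] * 1000 / alpha)
    deformationObjective(sim, spunOutline, nGrid = nGrid)
  }
  starts <- rbind(c(0.5, 0.5),
                  if (nRestarts > 0)
                    withSeed(seed, lhs::randomLHS(nRestarts, 2)))
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                 lower = rep(1e-9, 2), upper = rep(1 - 1e-9, 2),
                 control = list(maxit = maxit, pgtol = tol * 1e-3,
                                factr = 1e4))
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(vals)]]
  p <- best$par
  alpha <- bounds$alpha[1] + p[1] * diff(bounds$alpha)
  beta <- bounds$beta[1] + p[2] * diff(bounds$beta)
  boundActive <- any(p < 1e-4 | p > 1 - 1e-4)
  converged <- best$convergence != 1
  if (!converged)
    warning("optimizer hit the iteration cap before reaching tolerance")
  if (best$value > maxMisfit)
    stop("inverse fit quality error: final misfit ", signif(best$value, 3),
         " mm^2 exceeds the sanity threshold ", maxMisfit)
  startDf <- data.frame(
    alpha0 = bounds$alpha[1] + starts[, 1] * diff(bounds$alpha),
    beta0 = bounds$beta[1] + starts[, 2] * diff(bounds$beta),
    misfit = vals)
  new("SVFFit", svf = svf(alpha, beta), misfit = best$value,
      iterations = nEval, converged = converged,
      boundActive = boundActive, starts = startDf)
}

#' Forward-inverse validation of the modulus recovery
#'
#' Simulates the forward spin problem for a known shear-modulus field,
#' optionally jitters the deformed outline, feeds the synthetic pair to
#' the inverse problem, and reports the recovery. Passes when the alpha
#' error is below 5% and the absolute beta error below 0.05 (the
#' zero-noise contract). By default the data-generating solve uses the
#' same mesh resolution as the inverse model (the standard closed-loop
#' validation of an inverse solver); set `forwardNS`/`forwardNTheta`
#' higher to study the discretisation bias instead — at ~4k linear
#' elements that bias alone moves alpha by several percent, so the
#' mismatched variant is a mesh study, not a pass/fail validation.
#'
#' @param truth the true [SVF-class].
#' @param shape the stationary [LensShape-class].
#' @param spin a [SpinCondition-class].
#' @param noise outline jitter SD in pixels (radial), applied at
#'   `pixelScale`.
#' @param pixelScale mm per pixel used to express the jitter.
#' @param material a [MaterialModel-class] providing nu and density.
#' @param seed seed for the jitter and the optimizer restarts.
#' @param forwardNS,forwardNTheta mesh resolution of the data-generating
#'   forward solve; defaults match the inverse mesh (see Description).
#' @param ... passed to [invertSVF()].
#' @return A list with `truth`, `estimate` ([SVFFit-class]), relative
#'   `alphaError`, absolute `betaError` and logical `pass`.
#' @export
validateForwardInverse <- function(truth, shape, spin, noise = 0,
                                   pixelScale = 0.05,
                                   material = materialModel(),
                                   seed = 0, forwardNS = 32,
                                   forwardNTheta = 64, ...) {
  mat <- material
  mat@svf <- truth
  out <- spinDeformShape(shape, spin@omega, material = mat,
                         nS = forwardNS, nTheta = forwardNTheta)
  if (noise > 0)
    out[, "r"] <- withSeed(seed, out[, "r"] +
                             stats::rnorm(nrow(out), 0, noise * pixelScale))
  fit <- invertSVF(shape, out, material, spin, seed = seed, ...)
  aErr <- abs(fit@svf@alpha - truth@alpha) / truth@alpha
  bErr <- fit@svf@beta - truth@beta
  list(truth = truth, estimate = fit, alphaError = aErr, betaError = bErr,
       pass = aErr < 0.05 && abs(bErr) < 0.05)
}
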