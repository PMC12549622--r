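test_that("unit conversions are exact", {
  expect_equal(round(rpmToAngularVelocity(1000), 2), 104.72)
  expect_identical(rpmToAngularVelocity(0), 0)
  expect_equal(round(rpmToAngularVelocity(60), 4), 6.2832)
  expect_error(rpmToAngularVelocity(-1), "non-negative")
  expect_equal(round(strobePositionsPerRotation(0.5236)), 12)
})

test_that("shear from Young's modulus round trips", {
  expect_equal(signif(shearFromYoung(3.70e3, 0.5), 3), 1.23e3)
  expect_equal(signif(shearFromYoung(14.00e3, 0.5), 3), 4.67e3)
  G <- 1234; nu <- 0.37
  expect_equal(shearFromYoung(2 * G * (1 + nu), nu), G)
  expect_error(shearFromYoung(-1, 0.4), "positive")
  expect_error(shearFromYoung(1, 0.6), "nu")
})

test_that("dimensionless radius on a sphere is the normalised distance", {
  sph <- lensPreset("sphere", r0 = 5)@shape
  set.seed(3)
  th <- stats::runif(40, -pi / 2, pi / 2)
  d <- stats::runif(40, 0, 4.9)
  nodes <- cbind(d * cos(th), d * sin(th))
  fld <- dimensionlessRadius(nodes, sph)
  expect_lt(max(abs(fld@ratio - d / 5)), 2e-3)  # sphere: xi0 = r0 every ray
  expect_lt(max(abs(fld@xi + fld@delta - fld@xi0)), 1e-9)
})

test_that("dimensionless radius is 0 at the midpoint and 1 on the surface", {
  sh <- lensPreset("young-bovine")@shape
  mid <- dimensionlessRadius(cbind(0, 0), sh)
  expect_equal(mid@ratio, 0)
  th <- seq(-1.4, 1.4, length.out = 9)
  d <- boundaryDistance(sh, th)
  fld <- dimensionlessRadius(cbind(d * cos(th), d * sin(th)), sh)
  expect_lt(max(abs(fld@ratio - 1)), 1e-6)
  expect_error(dimensionlessRadius(cbind(20, 0), sh), "outside")
})

test_that("mesh nodes carry an exact dimensionless radius", {
  sh <- lensPreset("young-bovine")@shape
  mesh <- lensMesh(sh, nS = 8, nTheta = 16)
  fld <- dimensionlessRadius(mesh, sh)
  expect_lt(max(abs(fld@ratio - mesh@xi)), 1e-9)
  expect_true(all(mesh@xi[mesh@boundary] == 1))
})

test_that("shear-modulus field evaluates the exponential model", {
  sv <- svf(10080, -2.02)
  expect_equal(svfModulus(sv, 0), 10080)
  expect_equal(svfModulus(sv, 1), 10080 * exp(-2.02))
  expect_equal(svfModulus(svf(5000, 0), c(0, 0.5, 1)), rep(5000, 3))
})

test_that("forward spin displacement vanishes at omega = 0 and scales with omega^2", {
  lens <- lensPreset("young-bovine")
  mesh <- lensMesh(lens@shape, nS = 10, nTheta = 20)
  f0 <- forwardSpin(mesh, lens@material, spinCondition(omega = 0))
  expect_identical(max(abs(c(f0@u, f0@w))), 0)
  f1 <- forwardSpin(mesh, lens@material, spinCondition(omega = 50))
  f2 <- forwardSpin(mesh, lens@material, spinCondition(omega = 100))
  expect_lt(max(abs(f2@u - 4 * f1@u)) / max(abs(f2@u)), 1e-10)
  expect_lt(max(abs(f2@w - 4 * f1@w)) / max(abs(f2@w)), 1e-10)
})

test_that("forward solution converges under mesh refinement", {
  lens <- lensPreset("young-bovine")
  m1 <- lensMesh(lens@shape, nS = 16, nTheta = 32)   # ~1k elements
  m2 <- lensMesh(lens@shape, nS = 32, nTheta = 64)   # ~4k elements
  sp <- spinCondition(rpm = 1000)
  d1 <- max(abs(forwardSpin(m1, lens@material, sp)@u))
  d2 <- max(abs(forwardSpin(m2, lens@material, sp)@u))
  expect_lt(abs(d2 - d1) / d2, 0.01)
})

test_that("deformation objective is a faithful squared misfit", {
  x <- cbind(x = seq(-5, 5, length.out = 50),
             r = 3 + cos(seq(-5, 5, length.out = 50)))
  expect_identical(deformationObjective(x, x), 0)
  y <- x; y[, "r"] <- y[, "r"] + 0.1
  expect_equal(deformationObjective(x, y, nGrid = 100), 100 * 0.01,
               tolerance = 1e-9)
  shuffle <- x[sample(nrow(x)), ]
  expect_equal(deformationObjective(shuffle, y, nGrid = 100),
               deformationObjective(x, y, nGrid = 100))
  z <- cbind(x = seq(50, 60, length.out = 10), r = 1:10)
  expect_error(deformationObjective(x, z), "non-overlapping")
})

test_that("shear profiles follow the exponential and its normalisation", {
  sv <- svf(10080, -2.02)
  pr <- shearProfile(sv, normaliseTo = 10080)
  expect_equal(pr@values[pr@positions == 0], 1)
  half <- pr@values[pr@positions >= 0]
  expect_true(all(diff(half) < 0))       # beta < 0: decreasing outward
  expect_equal(pr@values[pr@positions == 1], exp(-2.02))
  expect_equal(pr@values, rev(pr@values))  # mirror symmetry
  expect_error(shearProfile(sv, normaliseTo = 0), "positive")
})

test_that("an undeformed observation drives the inverse fit to the stiff bound", {
  lens <- lensPreset("young-bovine")
  spin <- spinCondition(rpm = 1000)
  undeformed <- spinDeformShape(lens, 0, nS = 16, nTheta = 32)
  fit <- invertSVF(lens@shape, undeformed, lens@material, spin,
                   nS = 16, nTheta = 32, nRestarts = 1)
  expect_true(fit@boundActive)
  expect_gt(fit@svf@alpha, 49000)        # stiffest allowed alpha
})

test_that("recovery error grows with outline noise", {
  lens <- lensPreset("old-bovine")
  spin <- spinCondition(rpm = 1000)
  err <- function(noise) {
    es <- vapply(1:3, function(s) {
      v <- validateForwardInverse(lens@material@svf, lens@shape, spin,
                                  noise = noise, seed = s,
                                  forwardNS = 16, forwardNTheta = 32,
                                  nS = 16, nTheta = 32, nRestarts = 1)
      abs(v$alphaError) + abs(v$betaError)
    }, numeric(1))
    mean(es)
  }
  expect_lt(err(0), err(0.5))
})

test_that("displacement fields report mm-scale deformation at 1000 RPM", {
  out <- spinDeformShape(lensPreset("old-bovine"), 104.72,
                         nS = 16, nTheta = 32)
  fld <- attr(out, "field")
  # order of magnitude of the reported spin-test deformations (~0.1-0.3 mm)
  expect_gt(max(fld@u), 0.03)
  expect_lt(max(fld@u), 1)
})
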