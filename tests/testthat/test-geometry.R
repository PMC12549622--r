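test_that("segmenting a rendered circle recovers the radius sub-pixel", {
  img <- renderSilhouette(lensPreset("sphere", r0 = 5), pixelScale = 0.05)
  out <- segmentOutline(img, 0.05)
  rad <- sqrt(rowSums(out@points^2))
  expect_lt(mean(abs(rad - 5)), 0.025)   # 0.5 px
})

test_that("segmentation errors on empty or multi-component images", {
  expect_error(segmentOutline(matrix(0, 50, 50), 0.05), "no foreground")
  two <- matrix(0, 80, 80)
  two[10:30, 10:30] <- 1
  two[50:75, 50:75] <- 1
  expect_error(segmentOutline(two, 0.05), "multiple large")
})

test_that("segmentation of a rendered preset recovers ED within 1%", {
  lens <- lensPreset("young-bovine")
  img <- renderSilhouette(lens, pixelScale = 0.05)
  out <- segmentOutline(img, 0.05)
  ed <- 2 * max(abs(out@points[, 2]))
  expect_lt(abs(ed - lens@shape@ED) / lens@shape@ED, 0.01)
})

test_that("holder-region removal flags points without moving them", {
  img <- renderSilhouette(lensPreset("young-bovine"), pixelScale = 0.05)
  out <- segmentOutline(img, 0.05)
  same <- removeHolderRegion(out, NULL)
  expect_identical(same@excluded, out@excluded)
  cut <- removeHolderRegion(out, c(-0.3, 0.3))
  ang <- atan2(cut@points[, 2], cut@points[, 1])
  expect_true(all(cut@excluded[ang >= -0.3 & ang <= 0.3]))
  expect_false(any(cut@excluded[ang > 0.4 | ang < -0.4]))
  expect_identical(cut@points, out@points)
  expect_error(removeHolderRegion(out, c(-2, 2)), "50%")
})

test_that("excluded points never enter the shape fit", {
  lens <- lensPreset("young-bovine")
  img <- renderSilhouette(lens, pixelScale = 0.05)
  out <- segmentOutline(img, 0.05)
  # cut a wedge around the posterior pole; the fit must still succeed and
  # the split groups must shrink by exactly the flagged count
  cut <- removeHolderRegion(out, c(-pi, -pi + 0.4))
  al0 <- alignAndSplit(out)
  al1 <- alignAndSplit(cut)
  expect_equal(nrow(al1$anterior) + nrow(al1$posterior),
               nrow(al0$anterior) + nrow(al0$posterior) - sum(cut@excluded))
})

test_that("alignAndSplit finds no rotation for a symmetric outline", {
  img <- renderSilhouette(lensPreset("young-bovine"), pixelScale = 0.05)
  out <- segmentOutline(img, 0.05)
  al <- alignAndSplit(out)
  expect_lt(abs(al$rotation), 1e-3)
  expect_gt(nrow(al$anterior), 0)
  expect_gt(nrow(al$posterior), 0)
})

test_that("alignAndSplit recovers a known pre-rotation", {
  img <- renderSilhouette(lensPreset("young-bovine"), pixelScale = 0.05)
  out <- segmentOutline(img, 0.05)
  phi <- 0.05
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  rot <- out
  rot@points <- out@points %*% R
  al <- alignAndSplit(rot)
  expect_lt(abs(al$rotation - (-phi)), 0.005)
})

test_that("a strongly tilted outline raises a tilt error", {
  img <- renderSilhouette(lensPreset("young-bovine"), pixelScale = 0.05)
  out <- segmentOutline(img, 0.05)
  phi <- 0.2
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  rot <- out
  rot@points <- out@points %*% R
  expect_error(alignAndSplit(rot, maxTilt = 0.1), "tilt")
})

test_that("aspheric fit recovers a sphere", {
  r <- seq(0, 5.5, length.out = 60)
  truth <- asphericSurface(R = 8)
  pts <- cbind(-asphericSag(truth, r), r)   # anterior cap, vertex at x = 0
  fit <- fitAspheric(pts, side = "anterior")
  expect_lt(abs(fit@R - 8), 0.001)
  expect_lt(abs(fit@kappa), 0.01)
  expect_lt(max(abs(c(fit@a4, fit@a6, fit@a8))), 1e-6)
  expect_lt(fit@rmsResidual, 1e-4)
})

test_that("aspheric fit recovers conic and polynomial terms within 0.5%", {
  truth <- asphericSurface(R = 9, kappa = -1.2, a4 = 2e-5)
  r <- seq(0, 7, length.out = 80)
  pts <- cbind(3 - asphericSag(truth, r), r)
  fit <- fitAspheric(pts, side = "anterior")
  expect_lt(abs(fit@R - 9) / 9, 0.005)
  expect_lt(abs(fit@kappa - (-1.2)) / 1.2, 0.005)
  expect_lt(abs(fit@a4 - 2e-5) / 2e-5, 0.005)
  expect_lt(abs(fit@vertexOffset - 3), 1e-4)
})

test_that("aspheric fit preconditions are enforced", {
  truth <- asphericSurface(R = 8)
  r <- seq(0, 5, length.out = 5)
  expect_error(fitAspheric(cbind(-asphericSag(truth, r), r), "anterior"),
               "at least 10 points")
  r <- seq(4.5, 5, length.out = 20)   # only the outer 10% of the span
  expect_error(fitAspheric(cbind(-asphericSag(truth, r), r), "anterior"),
               "60%")
})

test_that("vertex gradient is the exact backward difference", {
  r <- seq(0, 1, by = 0.01)
  expect_equal(vertexGradient(cbind(r, 2 * r), length(r)), 2)
  expect_equal(vertexGradient(cbind(r, r^2), length(r)), 1.99)
  expect_equal(vertexGradient(cbind(r, rep(3, length(r))), length(r)), 0)
  expect_error(vertexGradient(cbind(r, r), 1), "neighbouring")
})

test_that("blend fit reproduces a cubic consistent with its constraints", {
  co <- c(0.3, -1.1, 0.5, 2)
  cubic <- function(t) co[1] * t^3 + co[2] * t^2 + co[3] * t + co[4]
  dcubic <- function(t) 3 * co[1] * t^2 + 2 * co[2] * t + co[3]
  cns <- blendConstraints(rv1 = 0.2, rv2 = 1.5, zv1 = cubic(0.2),
                          zv2 = cubic(1.5), dzv1 = dcubic(0.2),
                          dzv2 = dcubic(1.5))
  tt <- seq(0.2, 1.5, length.out = 12)
  fit <- fitEquatorialBlend(cbind(tt, cubic(tt)), cns)
  expect_equal(c(fit@a, fit@b, fit@c, fit@d), co, tolerance = 1e-9)
})

test_that("blend fit equals the closed-form constraint solution (100 seeds)", {
  for (s in 1:100) {
    set.seed(s)
    rv <- sort(stats::rnorm(2, 0, 2))
    if (abs(diff(rv)) < 0.5) rv[2] <- rv[1] + 1
    beq <- stats::rnorm(4)
    cns <- blendConstraints(rv1 = rv[1], rv2 = rv[2], zv1 = beq[3],
                            zv2 = beq[4], dzv1 = beq[1], dzv2 = beq[2])
    tt <- stats::runif(8, rv[1], rv[2])
    scatter <- cbind(tt, stats::rnorm(8))
    fit <- fitEquatorialBlend(scatter, cns)
    # with 4 equality constraints on 4 coefficients the solution is the
    # unique constraint solve, independent of the scatter
    Aeq <- rbind(c(3 * rv[1]^2, 2 * rv[1], 1, 0),
                 c(3 * rv[2]^2, 2 * rv[2], 1, 0),
                 c(rv[1]^3, rv[1]^2, rv[1], 1),
                 c(rv[2]^3, rv[2]^2, rv[2], 1))
    ref <- solve(Aeq, beq)
    expect_lt(max(abs(c(fit@a, fit@b, fit@c, fit@d) - ref)), 1e-9)
  }
})

test_that("coincident junction vertices raise a rank error", {
  cns <- blendConstraints(rv1 = 1, rv2 = 1, zv1 = 0, zv2 = 0,
                          dzv1 = 1, dzv2 = 1)
  expect_error(fitEquatorialBlend(cbind(1:4, 1:4), cns), "rank-deficient")
})

test_that("composed shapes are C1 at all four junctions", {
  sh <- makeLensShape(ED = 17.466, LT = 12.489, kappaAnterior = -0.5,
                      aAnterior = c(1e-5, 0, 0))
  eps <- 1e-6
  for (xj in c(sh@xV1, sh@xV2, 0)) {
    hl <- lensHalfWidth(sh, xj - eps)
    hr <- lensHalfWidth(sh, xj + eps)
    expect_lt(abs(hr - hl), 1e-4)                       # continuity
    dl <- (lensHalfWidth(sh, xj) - lensHalfWidth(sh, xj - eps)) / eps
    dr <- (lensHalfWidth(sh, xj + eps) - lensHalfWidth(sh, xj)) / eps
    expect_lt(abs(dr - dl), 1e-2)                       # C1
  }
})

test_that("full image-to-shape pipeline recovers geometry within 1%", {
  lens <- lensPreset("young-bovine")
  img <- renderSilhouette(lens, pixelScale = 0.05)
  sh <- fitLensShape(segmentOutline(img, 0.05))
  expect_lt(abs(sh@ED - lens@shape@ED) / lens@shape@ED, 0.01)
  expect_lt(abs(sh@LT - lens@shape@LT) / lens@shape@LT, 0.01)
  expect_lt(abs(lensVolume(sh) - lensVolume(lens@shape)) /
              lensVolume(lens@shape), 0.01)
})

test_that("image-to-shape pipeline tolerates 0.5 px edge noise within 2%", {
  lens <- lensPreset("young-bovine")
  img <- renderSilhouette(lens, pixelScale = 0.05, noise = 0.5, seed = 1)
  sh <- fitLensShape(segmentOutline(img, 0.05))
  expect_lt(abs(sh@ED - lens@shape@ED) / lens@shape@ED, 0.02)
  expect_lt(abs(sh@LT - lens@shape@LT) / lens@shape@LT, 0.02)
  expect_lt(abs(lensVolume(sh) - lensVolume(lens@shape)) /
              lensVolume(lens@shape), 0.02)
})

test_that("volume quadrature matches closed forms", {
  sph <- lensPreset("sphere", r0 = 5)@shape
  expect_lt(abs(lensVolume(sph) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            5e-4)
  sc <- lensPreset("sphere", r0 = 2)@shape
  expect_lt(abs(lensVolume(sc) - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 5e-4)
})

test_that("volume scales with the cube of a length rescale", {
  v1 <- lensVolume(lensPreset("sphere", r0 = 3)@shape)
  v2 <- lensVolume(lensPreset("sphere", r0 = 6)@shape)
  expect_equal(v2 / v1, 8, tolerance = 1e-6)
})

test_that("volume quadrature converges under step halving", {
  sh <- makeLensShape(ED = 17.466, LT = 12.489)
  v1 <- lensVolume(sh, step = sh@LT / 500)
  v2 <- lensVolume(sh, step = sh@LT / 1000)
  expect_lt(abs(v2 - v1) / v1, 1e-4)    # halving changes V by < 0.01%
  expect_error(lensVolume(sh, step = 0), "positive")
})

test_that("percent change matches hand arithmetic", {
  expect_equal(round(percentChange(1755.31, 1652.65)$mean, 2), -5.85)
  expect_equal(percentChange(5, 5)$mean, 0)
  pc <- percentChange(c(10, 20), c(11, 22))
  expect_equal(pc$mean, 10)
  expect_equal(pc$sd, 0)
  expect_true(is.na(pc$p))
  pc3 <- percentChange(c(10, 20, 30), c(11, 21, 29))
  expect_false(is.na(pc3$p))
  expect_error(percentChange(1:3, 1:2), "matched lengths")
  expect_error(percentChange(0, 1), "non-zero")
})
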