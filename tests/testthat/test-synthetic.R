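test_that("makeLensShape meets the requested ED and LT within 0.5%", {
  sh <- makeLensShape(ED = 17.466, LT = 12.489)
  expect_lt(abs(sh@ED - 17.466) / 17.466, 0.005)
  expect_lt(abs(sh@LT - 12.489) / 12.489, 0.005)
})

test_that("sphere preset gives a hemispheric profile with ED = 2 r0 exactly", {
  sph <- lensPreset("sphere", r0 = 5)
  expect_equal(sph@shape@ED, 10, tolerance = 1e-9)
  expect_equal(sph@shape@LT, 10, tolerance = 1e-9)
  # half-width equals the circle equation
  x <- seq(-4.9, 4.9, length.out = 101)
  expect_lt(max(abs(lensHalfWidth(sph@shape, x) - sqrt(25 - x^2))), 5e-3)
})

test_that("composed caps match direct evaluation of the sag formula", {
  sh <- makeLensShape(ED = 17, LT = 12.5, kappaAnterior = -1,
                      aAnterior = c(1e-5, 0, 0))
  r <- seq(0, sh@rJunction, length.out = 1000)
  sag <- asphericSag(sh@anterior, r)
  # the cap region of h(x) inverts exactly that sag
  x <- sh@TA - sag
  expect_lt(max(abs(lensHalfWidth(sh, x) - r)), 1e-9)
})

test_that("invalid shape requests error out", {
  # a thickness far beyond the hemispheric maximum has no spherical cap
  expect_error(makeLensShape(ED = 10, LT = 30, fracTA = 0.5),
               "equator")
  expect_error(makeLensShape(ED = -1, LT = 5), "positive")
})

test_that("rendered sphere silhouette has the right foreground area", {
  img <- renderSilhouette(lensPreset("sphere", r0 = 5), pixelScale = 0.05)
  expect_lt(abs(sum(img) - pi * 100^2) / (pi * 100^2), 0.01)
})

test_that("render + segment round trip stays within one pixel (Hausdorff)", {
  lens <- lensPreset("young-bovine")
  img <- renderSilhouette(lens, pixelScale = 0.05, noise = 0)
  out <- segmentOutline(img, pixelScale = 0.05)
  # dense reference boundary by ray casting from the midpoint
  th <- seq(-pi / 2, pi / 2, length.out = 2000)
  d <- boundaryDistance(lens@shape, th)
  bx <- d * sin(th); by <- d * cos(th)   # outline frame: col1 axial, col2 transverse
  ref <- rbind(cbind(bx, by), cbind(bx, -by))
  pts <- out@points
  mind <- vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((ref[, 1] - pts[i, 1])^2 + (ref[, 2] - pts[i, 2])^2)),
    numeric(1))
  expect_lt(max(mind), 0.05)   # 1 px at 0.05 mm/px
})

test_that("rendering an empty shape errors", {
  expect_error(renderSilhouette(cbind(c(0, 1), c(0, 0))), "empty shape")
  expect_error(renderSilhouette(lensPreset("sphere"), width = 5),
               "canvas")
})

test_that("spin deformation at omega = 0 is the identity on outlines", {
  lens <- lensPreset("young-bovine")
  out <- spinDeformShape(lens, 0, nS = 8, nTheta = 16)
  fld <- attr(out, "field")
  expect_identical(max(abs(fld@u)), 0)
  expect_identical(max(abs(fld@w)), 0)
  mesh <- fld@mesh
  expect_equal(out[, "r"], unname(mesh@nodes[mesh@boundary, 1]))
})

test_that("spun lens bulges at the equator and flattens at the poles", {
  lens <- lensPreset("old-bovine")
  out <- spinDeformShape(lens, 104.72, nS = 16, nTheta = 32)
  fld <- attr(out, "field")
  # signs and order of magnitude (0.01 - 1 mm)
  expect_gt(max(fld@u), 0.01)
  expect_lt(max(fld@u), 1)
  nodes <- fld@mesh@nodes
  topPole <- which.max(nodes[, 2] - 100 * nodes[, 1])
  botPole <- which.min(nodes[, 2] + 100 * nodes[, 1])
  expect_lt(fld@w[topPole], 0)   # anterior pole moves toward the equator
  expect_gt(fld@w[botPole], 0)
})

test_that("doubling omega quadruples the displacement", {
  lens <- lensPreset("young-bovine")
  f1 <- attr(spinDeformShape(lens, 50, nS = 10, nTheta = 20), "field")
  f2 <- attr(spinDeformShape(lens, 100, nS = 10, nTheta = 20), "field")
  expect_lt(max(abs(f2@u - 4 * f1@u)) / max(abs(f2@u)), 0.05)
})

test_that("noiseless MRI phantoms are generated exactly from the model", {
  t1 <- matrix(1000, 8, 8); pd <- matrix(1, 8, 8)
  ph <- makeMriPhantom(t1, pd)
  expect_equal(ph$images[[1]]@signal,
               spgrSignal(4, 1, 1000, 1, 15) + 0 * t1)
  maps <- fitT1PD(ph$images, ph$b1)
  expect_lt(max(abs(maps@t1 - 1000)) / 1000, 1e-6)
  expect_lt(max(abs(maps@pd - 1)), 1e-6)
})

test_that("zero proton density gives zero signal at all flip angles", {
  pd <- matrix(c(0, 1), 2, 2)
  ph <- makeMriPhantom(matrix(800, 2, 2), pd)
  for (im in ph$images) expect_identical(im@signal[pd == 0], c(0, 0))
})

test_that("phantom generation validates its inputs", {
  expect_error(makeMriPhantom(matrix(-1, 2, 2), matrix(1, 2, 2)),
               "T1 must be positive")
  expect_error(makeMriPhantom(matrix(1, 2, 2), matrix(1, 3, 3)),
               "share dimensions")
  expect_error(makeMriPhantom(matrix(1, 2, 2), matrix(1, 2, 2),
                              flipAngles = c(5, 5)), "distinct")
})

test_that("phantom noise is seed-deterministic", {
  a <- makeMriPhantom(matrix(900, 6, 6), matrix(0.7, 6, 6), noiseSd = 0.01,
                      seed = 7)
  b <- makeMriPhantom(matrix(900, 6, 6), matrix(0.7, 6, 6), noiseSd = 0.01,
                      seed = 7)
  expect_identical(a$images[[2]]@signal, b$images[[2]]@signal)
})
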