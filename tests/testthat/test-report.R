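mkProfile <- function(values, positions = seq(-1, 1, length.out = 101)) {
  new("LineProfile", positions = positions,
      values = rep(values, length.out = length(positions)),
      n = rep(1L, length(positions)), bandHalfwidth = 0, kind = "test")
}

test_that("averaging identical profiles gives zero SD", {
  p <- mkProfile(2.5)
  av <- averageProfiles(list(p, p))
  expect_true(all(av$mean == 2.5))
  expect_true(all(av$sd == 0))
})

test_that("average of constant profiles 0.8 and 1.2 has SD 0.2828", {
  av <- averageProfiles(list(mkProfile(0.8), mkProfile(1.2)))
  expect_true(all(abs(av$mean - 1) < 1e-12))
  expect_equal(av$sd[1], sqrt(0.08), tolerance = 1e-4)  # 0.2828
  expect_error(averageProfiles(list(mkProfile(1))), "at least two")
})

test_that("profile averaging matches a brute-force per-station mean", {
  set.seed(5)
  grid <- seq(-1, 1, length.out = 101)
  vals <- matrix(stats::rnorm(505), 101, 5)
  profs <- lapply(1:5, function(j) mkProfile(vals[, j], grid))
  av <- averageProfiles(profs, grid = grid)
  expect_equal(av$mean, rowMeans(vals))
  expect_equal(av$sd, apply(vals, 1, sd))
})

test_that("shear normalisation pins the baseline nuclear maximum at 1", {
  base <- shearProfile(svf(17000, -0.79))
  post <- shearProfile(svf(34000, -0.79))
  nm <- normaliseShear(base, post)
  nuc <- abs(nm$baseline@positions) < 0.2
  expect_equal(max(nm$baseline@values[nuc]), 1)
  expect_equal(max(nm$post@values[nuc]), 2, tolerance = 1e-9)
  zero <- base; zero@values <- 0 * zero@values
  expect_error(normaliseShear(zero, post), "positive")
})

test_that("a sign-flipped beta inverts the nucleus/cortex ordering", {
  base <- shearProfile(svf(17000, -0.79))
  post <- shearProfile(svf(17000, 0.79))
  nm <- normaliseShear(base, post)
  nuc <- mean(nm$post@values[abs(nm$post@positions) < 0.2])
  cortex <- mean(nm$post@values[abs(nm$post@positions) > 0.6])
  expect_lt(nuc, cortex)
})

test_that("comparing a condition with itself gives a unit ratio band", {
  profs <- lapply(c(1, 1.1, 0.9), function(s)
    shearProfile(svf(17000 * s, -0.79)))
  band <- compareConditions(profs, profs)
  expect_true(all(abs(band@mean - 1) < 1e-12))
  expect_true(all(band@lower <= 1 + 1e-9 & band@upper >= 1 - 1e-9))
})

test_that("the ratio confidence interval matches the hand t-interval", {
  base <- lapply(1:3, function(i) mkProfile(1))
  post <- lapply(c(1.1, 1.2, 1.3), mkProfile)
  band <- compareConditions(base, post)
  expect_true(all(abs(band@mean - 1.2) < 1e-12))
  half <- stats::qt(0.975, 2) * 0.1 / sqrt(3)        # 4.303 * 0.1/sqrt(3)
  expect_equal(band@lower[1], 1.2 - half, tolerance = 1e-6)
  expect_equal(band@upper[1], 1.2 + half, tolerance = 1e-6)
  expect_equal(round(c(1.2 - half, 1.2 + half), 3), c(0.952, 1.448))
  expect_error(compareConditions(base, post[1:2]), "paired")
})

test_that("difference mode reports post minus baseline", {
  base <- lapply(1:2, function(i) mkProfile(2))
  post <- lapply(1:2, function(i) mkProfile(2.5))
  band <- compareConditions(base, post, mode = "difference")
  expect_true(all(abs(band@mean - 0.5) < 1e-12))
})

test_that("a strong synthetic effect excludes the no-change line", {
  set.seed(2)
  n <- 4
  base <- lapply(seq_len(n), function(i) mkProfile(1))
  post <- lapply(stats::rnorm(n, 0.7, 0.03), mkProfile)  # ~10 SD effect
  band <- compareConditions(base, post)
  nuc <- abs(band@positions) < 0.2
  expect_true(all(band@upper[nuc] < 1))
})

test_that("identical before/after geometry reports zero change, ns", {
  lenses <- lapply(1:4, function(i)
    list(before = list(LT = 12.5, ED = 17.5), after = list(LT = 12.5, ED = 17.5)))
  tab <- geometryChangeTable(list(isotonic = lenses))
  expect_true(all(tab$pct_change_mean == 0))
  expect_true(all(tab$stars == "ns", na.rm = TRUE))
})

test_that("a synthetic cohort recovers its generating percent change", {
  coh <- synthGeometryCohort("hypertonic", n = 6, seed = 0)
  tab <- geometryChangeTable(list(hypertonic = coh))
  vol <- tab[tab$parameter == "Vol", ]
  se <- 1.48 / sqrt(6)
  expect_lt(abs(vol$pct_change_mean - (-5.85)), 2 * se)
  lt <- tab[tab$parameter == "LT", ]
  expect_lt(abs(lt$pct_change_mean - (-1.86)), 2 * 0.47 / sqrt(6))
  expect_true(vol$p_value < 0.05)
})

test_that("the geometry table serialises to CSV one row per pair", {
  conds <- list(hypertonic = synthGeometryCohort("hypertonic", 3, seed = 1),
                hypotonic = synthGeometryCohort("hypotonic", 3, seed = 2))
  tab <- geometryChangeTable(conds)
  expect_equal(nrow(tab), 2 * 3)      # 2 conditions x {LT, ED, Vol}
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$pct_change_mean, tab$pct_change_mean, tolerance = 1e-9)
  unlink(f)
})

test_that("single-lens cohorts suppress the statistics", {
  coh <- synthGeometryCohort("isotonic", n = 1, seed = 3)
  tab <- geometryChangeTable(list(isotonic = coh))
  expect_true(all(is.na(tab$before_sd)))
  expect_true(all(is.na(tab$p_value)))
  expect_true(all(is.na(tab$stars)))
})

test_that("cohort generation is seed-deterministic", {
  a <- synthGeometryCohort("ouabain", 4, seed = 9)
  b <- synthGeometryCohort("ouabain", 4, seed = 9)
  expect_identical(a, b)
  expect_error(synthGeometryCohort("nonsense"), "unknown condition")
})

test_that("the pipeline validates its config before computing", {
  d <- tempfile()
  expect_error(runPipeline(list(stages = list(geometry = "yes")), d),
               "config error")
  expect_error(runPipeline(list(geometry = list(conditions = "salty")), d),
               "unknown condition")
  expect_error(runPipeline(list(spin = list(preset = "granite")), d),
               "unknown spin preset")
  expect_false(dir.exists(d))    # nothing was written
})

test_that("the pipeline is deterministic and respects stage toggles", {
  cfg <- list(seed = 1,
              stages = list(geometry = TRUE, spin = FALSE, mri = FALSE,
                            comparison = TRUE),
              geometry = list(conditions = "hypertonic", nLenses = 3),
              comparison = list(nLenses = 3))
  d1 <- tempfile(); d2 <- tempfile()
  runPipeline(cfg, d1)
  runPipeline(cfg, d2)
  expect_true(file.exists(file.path(d1, "geometry_changes.csv")))
  expect_false(file.exists(file.path(d1, "spun_outline.csv")))
  expect_false(file.exists(file.path(d1, "rho_map.nii.gz")))
  for (f in c("geometry_changes.csv", "shear_comparison.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("shape and outline files round trip through disk", {
  sh <- makeLensShape(ED = 16, LT = 11, kappaAnterior = -0.3)
  f <- tempfile(fileext = ".json")
  writeShapeJson(sh, f)
  back <- readShapeJson(f)
  expect_equal(back@ED, sh@ED, tolerance = 1e-9)
  expect_equal(back@LT, sh@LT, tolerance = 1e-9)
  x <- seq(-sh@TP, sh@TA, length.out = 50)
  expect_equal(lensHalfWidth(back, x), lensHalfWidth(sh, x),
               tolerance = 1e-9)
  unlink(f)
  img <- renderSilhouette(lensPreset("sphere", 3), pixelScale = 0.05)
  o <- segmentOutline(img, 0.05)
  fc <- tempfile(fileext = ".csv")
  writeOutlineCsv(o, fc)
  ob <- readOutlineCsv(fc, 0.05)
  expect_equal(ob@points, unname(o@points), tolerance = 1e-9)
  unlink(fc)
})
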