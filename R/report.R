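# resample a LineProfile onto a common r/a grid
resampleProfile <- function(profile, grid) {
  stats::approx(profile@positions, profile@values, xout = grid,
                rule = 2, ties = mean)$y
}

#' Average a set of line profiles
#'
#' Resamples each profile onto a common r/a grid by linear interpolation
#' and reports the pointwise mean and sample SD over lenses.
#'
#' @param profiles list of at least two [LineProfile-class] objects.
#' @param grid common r/a stations (default 101 points in [-1, 1]).
#' @return Data frame with `position`, `mean`, `sd`, `n`.
#' @export
averageProfiles <- function(profiles,
                            grid = seq(-1, 1, length.out = 101)) {
  if (length(profiles) < 2L)
    stop("at least two profiles are required (SD undefined for one)")
  vals <- vapply(profiles, resampleProfile, numeric(length(grid)),
                 grid = grid)
  data.frame(position = grid,
             mean = rowMeans(vals, na.rm = TRUE),
             sd = apply(vals, 1, stats::sd, na.rm = TRUE),
             n = apply(vals, 1, function(v) sum(!is.na(v))))
}

#' Normalise a baseline/post shear-profile pair
#'
#' Divides both profiles by the baseline's nuclear maximum (the maximum
#' over |r/a| < 0.2), the convention that removes lens size as a variable:
#' the baseline nuclear peak maps to 1.
#'
#' @param baseline,post [LineProfile-class] shear profiles of one lens.
#' @param nuclearWidth half-width of the nuclear window in r/a units.
#' @return List with normalised `baseline` and `post` profiles and the
#'   `factor` used (Pa).
#' @export
normaliseShear <- function(baseline, post, nuclearWidth = 0.2) {
  nuc <- abs(baseline@positions) < nuclearWidth
  if (!any(nuc)) stop("no stations inside the nuclear window")
  f <- max(baseline@values[nuc], na.rm = TRUE)
  if (!is.finite(f) || f <= 0)
    stop("baseline nuclear maximum must be positive")
  baseline@values <- baseline@values / f
  post@values <- post@values / f
  list(baseline = baseline, post = post, factor = f)
}

#' Pointwise comparison band between baseline and post profiles
#'
#' For paired per-lens profiles, computes the per-station post/baseline
#' ratio (or difference) per lens, its mean across lenses, and a
#' two-sided 95% confidence interval from the t distribution with n - 1
#' degrees of freedom. The no-change reference is 1 for ratios.
#'
#' @param baseline,post lists of paired [LineProfile-class] objects, same
#'   length and order.
#' @param mode `"ratio"` or `"difference"`.
#' @param grid common r/a stations.
#' @param level confidence level.
#' @return A [ComparisonBand-class].
#' @export
compareConditions <- function(baseline, post, mode = c("ratio", "difference"),
                              grid = seq(-1, 1, length.out = 101),
                              level = 0.95) {
  mode <- match.arg(mode)
  if (length(baseline) != length(post) || !length(baseline))
    stop("baseline and post must be paired per-lens profile lists")
  per <- vapply(seq_along(baseline), function(i) {
    b <- resampleProfile(baseline[[i]], grid)
    p <- resampleProfile(post[[i]], grid)
    if (mode == "ratio") p / b else p - b
  }, numeric(length(grid)))
  per <- matrix(per, nrow = length(grid))
  n <- apply(per, 1, function(v) sum(is.finite(v)))
  mu <- rowMeans(per, na.rm = TRUE)
  sdv <- apply(per, 1, stats::sd, na.rm = TRUE)
  half <- ifelse(n >= 2,
                 stats::qt(1 - (1 - level) / 2, pmax(n - 1, 1)) *
                   sdv / sqrt(n), NA_real_)
  new("ComparisonBand", positions = grid, mean = mu,
      lower = mu - half, upper = mu + half, n = as.integer(n), mode = mode)
}

# the paper-style significance star convention
significanceStars <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Geometry-change report table
#'
#' Summarises before/after lens geometry per condition: group means and
#' SDs, the per-lens percent change (mean and SD), and a paired two-sided
#' t-test p-value mapped to the star convention (* 0.01 <= p < 0.05,
#' ** 0.001 <= p < 0.01, *** p < 0.001). With fewer than two lenses the
#' statistics are suppressed and only means are reported.
#'
#' @param conditions named list; each element is a list of per-lens
#'   records `list(before = c(LT=, ED=, Vol=), after = c(...))` (any
#'   consistent set of named parameters).
#' @return Data frame with one row per (condition, parameter); serialises
#'   directly to CSV.
#' @export
geometryChangeTable <- function(conditions) {
  rows <- list()
  for (cond in names(conditions)) {
    lenses <- conditions[[cond]]
    pars <- names(lenses[[1]]$before)
    for (par in pars) {
      bef <- vapply(lenses, function(l) l$before[[par]], numeric(1))
      aft <- vapply(lenses, function(l) l$after[[par]], numeric(1))
      n <- length(bef)
      pc <- percentChange(bef, aft)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, parameter = par, n = n,
        before_mean = mean(bef),
        before_sd = if (n >= 2) stats::sd(bef) else NA_real_,
        after_mean = mean(aft),
        after_sd = if (n >= 2) stats::sd(aft) else NA_real_,
        pct_change_mean = pc$mean,
        pct_change_sd = pc$sd,
        p_value = pc$p,
        stars = if (n >= 2 && is.finite(pc$p)) significanceStars(pc$p)
                else NA_character_)
    }
  }
  do.call(rbind, rows)
}

# Study-condition presets for the synthetic geometry cohorts: baseline
# group means/SDs and per-lens percent changes (mean, SD) for LT, ED and
# volume under each culture condition.
geometryConditionPresets <- function() {
  list(
    isotonic   = list(before = list(LT = c(12.489, 0.247), ED = c(17.466, 0.311), Vol = c(1962.36, 84.25)),
                      change = list(LT = c(0.89, 1.19), ED = c(-0.56, 1.15), Vol = c(-0.47, 1.01))),
    hypertonic = list(before = list(LT = c(11.965, 0.291), ED = c(16.966, 0.410), Vol = c(1755.31, 82.90)),
                      change = list(LT = c(-1.86, 0.47), ED = c(-3.00, 0.98), Vol = c(-5.85, 1.48))),
    hypotonic  = list(before = list(LT = c(12.275, 0.360), ED = c(17.321, 0.488), Vol = c(1862.72, 153.43)),
                      change = list(LT = c(4.95, 0.77), ED = c(-1.54, 0.60), Vol = c(3.83, 1.19))),
    `high-K`   = list(before = list(LT = c(12.404, 0.363), ED = c(17.118, 0.303), Vol = c(1842.05, 112.14)),
                      change = list(LT = c(2.38, 1.07), ED = c(-0.49, 0.18), Vol = c(2.53, 0.51))),
    ouabain    = list(before = list(LT = c(12.384, 0.289), ED = c(17.126, 0.269), Vol = c(1831.48, 87.06)),
                      change = list(LT = c(0.580, 0.397), ED = c(-0.870, 0.292), Vol = c(-1.325, 0.910))))
}

#' Draw a synthetic before/after geometry cohort
#'
#' Per-lens baseline values are drawn from the condition's group
#' distribution and per-lens percent changes from the treatment-effect
#' distribution; the after value is baseline * (1 + change/100).
#'
#' @param condition one of `"isotonic"`, `"hypertonic"`, `"hypotonic"`,
#'   `"high-K"`, `"ouabain"`.
#' @param n lenses.
#' @param seed RNG seed.
#' @return List of per-lens records suitable for [geometryChangeTable()].
#' @export
synthGeometryCohort <- function(condition = "hypertonic", n = 6, seed = 0) {
  pre <- geometryConditionPresets()[[condition]]
  if (is.null(pre)) stop("unknown condition preset: ", condition)
  withSeed(seed, lapply(seq_len(n), function(i) {
    bef <- vapply(pre$before, function(ms)
      stats::rnorm(1, ms[1], ms[2]), numeric(1))
    chg <- vapply(pre$change, function(ms)
      stats::rnorm(1, ms[1], ms[2]), numeric(1))
    list(before = as.list(bef), after = as.list(bef * (1 + chg / 100)))
  }))
}
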