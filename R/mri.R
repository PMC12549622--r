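#' Spoiled gradient-echo signal model
#'
#' Steady-state magnitude signal
#' \eqn{S = PD \sin(\theta) (1 - E) / (1 - E \cos\theta)} with
#' \eqn{\theta = b_1 \alpha} the effective flip angle and
#' \eqn{E = e^{-TR/T_1}}.
#'
#' @param flip nominal flip angle (degrees).
#' @param b1 flip-angle multiplier.
#' @param t1 longitudinal relaxation time (ms).
#' @param pd proton density (arbitrary units).
#' @param tr repetition time (ms).
#' @return Signal in the units of `pd`.
#' @export
spgrSignal <- function(flip, b1, t1, pd, tr) {
  th <- b1 * flip * pi / 180
  E <- exp(-tr / t1)
  out <- pd * sin(th) * (1 - E) / (1 - E * cos(th))
  out[pd == 0] <- 0
  out
}

#' Construct a flip-angle image
#'
#' @param signal magnitude image matrix (>= 0).
#' @param flip nominal flip angle (degrees), in (0, 90).
#' @param tr repetition time (ms).
#' @param te echo time (ms).
#' @return A [FlipAngleImage-class].
#' @export
flipAngleImage <- function(signal, flip, tr = 15, te = 2.49)
  new("FlipAngleImage", signal = as.matrix(signal), flip = flip,
      tr = tr, te = te)

#' Construct a B1 multiplier map
#'
#' @param b1 multiplier matrix (> 0).
#' @param spacing voxel size c(row, col) in mm.
#' @param origin mm position of the centre of voxel [1, 1].
#' @return A [B1Map-class].
#' @export
b1Map <- function(b1, spacing = c(1, 1), origin = c(0, 0))
  new("B1Map", b1 = as.matrix(b1), spacing = spacing, origin = origin)

#' Generate a multi-flip-angle MRI phantom
#'
#' Forward-simulates spoiled gradient-echo magnitude images from ground
#' truth T1, proton-density and B1 fields at the requested flip angles,
#' with additive Gaussian noise on the magnitude signals. With
#' `noiseSd = 0` the signals follow the model exactly.
#'
#' @param t1Field matrix of T1 (ms), > 0.
#' @param pdField matrix of proton density (>= 0), same size.
#' @param b1Field matrix of B1 multipliers (> 0), same size (resample a
#'   low-resolution map with [resampleB1()] first).
#' @param flipAngles at least two distinct nominal flip angles (degrees).
#' @param tr repetition time (ms).
#' @param noiseSd Gaussian noise SD in signal units.
#' @param seed noise seed.
#' @return List with `images` (list of [FlipAngleImage-class]), `b1`
#'   ([B1Map-class]) and `truth` (the input fields).
#' @export
makeMriPhantom <- function(t1Field, pdField, b1Field = NULL,
                           flipAngles = c(4, 23), tr = 15, noiseSd = 0,
                           seed = 0) {
  t1Field <- as.matrix(t1Field); pdField <- as.matrix(pdField)
  if (is.null(b1Field)) b1Field <- matrix(1, nrow(t1Field), ncol(t1Field))
  b1Field <- as.matrix(b1Field)
  if (!all(dim(t1Field) == dim(pdField)) ||
      !all(dim(t1Field) == dim(b1Field)))
    stop("t1, pd and b1 fields must share dimensions")
  if (any(t1Field <= 0)) stop("all T1 must be positive")
  if (any(pdField < 0)) stop("proton density must be non-negative")
  if (any(b1Field <= 0)) stop("b1 must be strictly positive")
  if (length(unique(flipAngles)) < 2L)
    stop("at least two distinct flip angles are required")
  imgs <- withSeed(seed, lapply(flipAngles, function(fa) {
    s <- spgrSignal(fa, b1Field, t1Field, pdField, tr)
    if (noiseSd > 0)
      s <- pmax(s + matrix(stats::rnorm(length(s), 0, noiseSd),
                           nrow(s)), 0)
    flipAngleImage(s, flip = fa, tr = tr)
  }))
  list(images = imgs, b1 = b1Map(b1Field),
       truth = list(t1 = t1Field, pd = pdField, b1 = b1Field))
}

#' Resample a low-resolution B1 map onto an image grid
#'
#' Bilinear interpolation of the multiplier map onto the target voxel
#' centres; positions outside the source extent take the nearest-edge
#' value. Linear interpolation reproduces linear fields exactly at
#' interior voxels.
#'
#' @param b1 a [B1Map-class].
#' @param targetDim c(rows, cols) of the target grid.
#' @param targetSpacing voxel size c(row, col) in mm.
#' @param targetOrigin mm position of the centre of target voxel [1, 1].
#' @return A [B1Map-class] on the target grid.
#' @export
resampleB1 <- function(b1, targetDim, targetSpacing = c(1, 1),
                       targetOrigin = c(0, 0)) {
  src <- b1@b1
  sr <- b1@origin[1] + (seq_len(nrow(src)) - 1) * b1@spacing[1]
  sc <- b1@origin[2] + (seq_len(ncol(src)) - 1) * b1@spacing[2]
  tr <- targetOrigin[1] + (seq_len(targetDim[1]) - 1) * targetSpacing[1]
  tc <- targetOrigin[2] + (seq_len(targetDim[2]) - 1) * targetSpacing[2]
  if (max(tr) < min(sr) || min(tr) > max(sr) ||
      max(tc) < min(sc) || min(tc) > max(sc))
    stop("disjoint fields of view between the B1 map and the target grid")
  clampIdx <- function(pos, grid) {
    # fractional index into grid, clamped to the edges
    f <- stats::approx(grid, seq_along(grid), xout = pos, rule = 2)$y
    f
  }
  fr <- clampIdx(tr, sr); fc <- clampIdx(tc, sc)
  i0 <- pmin(pmax(floor(fr), 1), length(sr) - 1L); wi <- fr - i0
  j0 <- pmin(pmax(floor(fc), 1), length(sc) - 1L); wj <- fc - j0
  out <- matrix(0, targetDim[1], targetDim[2])
  for (jj in seq_along(fc)) {
    a <- src[cbind(i0, j0[jj])] * (1 - wi) + src[cbind(i0 + 1L, j0[jj])] * wi
    b <- src[cbind(i0, j0[jj] + 1L)] * (1 - wi) +
         src[cbind(i0 + 1L, j0[jj] + 1L)] * wi
    out[, jj] <- a * (1 - wj[jj]) + b * wj[jj]
  }
  b1Map(out, spacing = targetSpacing, origin = targetOrigin)
}

#' Voxelwise T1 and proton density from dual flip angles
#'
#' Standard linearised two-point fit of the spoiled gradient-echo signal
#' with B1-corrected effective flip angles: per voxel the points
#' (S/tan(b1 a), S/sin(b1 a)) for the two angles define a line of slope
#' \eqn{m = e^{-TR/T_1}} and intercept \eqn{c = PD (1 - m)}, so
#' \eqn{T_1 = -TR/\ln m} and \eqn{PD = c/(1 - m)}. Voxels whose slope
#' falls outside (0, 1) (e.g. zero signal) are flagged invalid and hold
#' NA rather than propagating.
#'
#' @param images list of two [FlipAngleImage-class] with common TR and
#'   distinct flip angles.
#' @param b1 a [B1Map-class] on the image grid, or `NULL` to disable the
#'   correction (b1 = 1).
#' @param mask optional logical foreground matrix; outside voxels are
#'   invalid.
#' @return A [T1PDMaps-class] (rho unfilled until [waterContent()]).
#' @export
fitT1PD <- function(images, b1 = NULL, mask = NULL) {
  if (length(images) != 2L)
    stop("exactly two flip-angle images are required")
  A <- images[[1]]; B <- images[[2]]
  if (!all(dim(A@signal) == dim(B@signal)))
    stop("flip-angle images must share dimensions")
  if (abs(A@tr - B@tr) > 1e-9) stop("images must share TR")
  if (abs(A@flip - B@flip) < 1e-9) stop("flip angles must be distinct")
  b1m <- if (is.null(b1)) matrix(1, nrow(A@signal), ncol(A@signal))
         else b1@b1
  if (!all(dim(b1m) == dim(A@signal)))
    stop("B1 map must be resampled onto the image grid first")
  th1 <- b1m * A@flip * pi / 180
  th2 <- b1m * B@flip * pi / 180
  x1 <- A@signal / tan(th1); y1 <- A@signal / sin(th1)
  x2 <- B@signal / tan(th2); y2 <- B@signal / sin(th2)
  dx <- x2 - x1
  m <- (y2 - y1) / dx
  valid <- is.finite(m) & m > 0 & m < 1 & abs(dx) > 0
  if (!is.null(mask)) valid <- valid & mask
  t1 <- matrix(NA_real_, nrow(m), ncol(m))
  pd <- t1
  t1[valid] <- -A@tr / log(m[valid])
  pd[valid] <- (y1[valid] - m[valid] * x1[valid]) / (1 - m[valid])
  new("T1PDMaps", t1 = t1, pd = pd, valid = valid, tr = A@tr,
      rho = matrix(NA_real_, nrow(m), ncol(m)))
}

#' Normalised water content from a pure-water reference
#'
#' Sets the pure-water proton density to the mean PD over the reference
#' region and fills \eqn{\rho_{lens} = PD / PD_{water}}; a pure-water
#' voxel maps to 1 and the ratio is invariant to global signal scaling.
#'
#' @param maps a [T1PDMaps-class].
#' @param waterRoi logical matrix marking pure-water voxels.
#' @return The maps with `pdWater` and `rho` filled.
#' @export
waterContent <- function(maps, waterRoi) {
  roi <- waterRoi & maps@valid
  if (!any(roi)) stop("water reference region is empty or entirely invalid")
  maps@pdWater <- mean(maps@pd[roi])
  maps@rho <- maps@pd / maps@pdWater
  maps
}

#' Equatorial band line profile of a voxel map
#'
#' Averages a voxel map over a band of `2 * bandHalfwidth + 1` rows
#' centred on the lens equatorial axis (the longest horizontal chord of
#' the mask through its centroid) and reports it against normalised lens
#' distance: the chord end points map to r/a = -1 and +1, the chord
#' centre to 0.
#'
#' @param map numeric voxel matrix (NAs excluded from averaging).
#' @param mask logical lens mask.
#' @param bandHalfwidth band half-width in pixels (default 2, i.e. a
#'   5-pixel band).
#' @return A [LineProfile-class].
#' @export
equatorialLineProfile <- function(map, mask, bandHalfwidth = 2) {
  if (!any(mask)) stop("empty lens mask")
  runLen <- function(v) {
    if (!any(v)) return(0L)
    r <- rle(v); max(r$lengths[r$values])
  }
  chords <- apply(mask, 1, runLen)
  cen <- mean(which(rowSums(mask) > 0))
  best <- which(chords == max(chords))
  row0 <- best[which.min(abs(best - cen))]
  rows <- (row0 - bandHalfwidth):(row0 + bandHalfwidth)
  if (min(rows) < 1 || max(rows) > nrow(mask) ||
      any(rowSums(mask[rows, , drop = FALSE]) == 0))
    stop("lens mask is thinner than the requested band")
  cols <- which(mask[row0, ])
  lo <- min(cols); hi <- max(cols)
  cols <- lo:hi
  mid <- (lo + hi) / 2; half <- (hi - lo) / 2
  vals <- numeric(length(cols)); nn <- integer(length(cols))
  sub <- map[rows, , drop = FALSE]
  msub <- mask[rows, , drop = FALSE]
  for (k in seq_along(cols)) {
    v <- sub[, cols[k]]
    use <- msub[, cols[k]] & !is.na(v)
    vals[k] <- if (any(use)) mean(v[use]) else NA_real_
    nn[k] <- sum(use)
  }
  new("LineProfile", positions = (cols - mid) / half, values = vals,
      n = nn, bandHalfwidth = bandHalfwidth, kind = "map")
}

#' Lens MRI phantom at the study geometry
#'
#' Builds a mid-sagittal 2-D phantom of a lens in its imaging chamber:
#' a lens cross-section (from a lens shape, oriented with the equatorial
#' axis horizontal) with radially parabolic T1 and PD fields, surrounded
#' by a pure-water bath, with a smooth B1 inhomogeneity. Defaults follow
#' the dual-flip-angle protocol (4 and 23 degrees, TR 15 ms, 0.2 mm
#' in-plane).
#'
#' @param shape a [LensShape-class]; default the young-bovine preset.
#' @param spacing in-plane voxel size (mm).
#' @param margin water margin around the lens (mm).
#' @param t1Centre,t1Edge lens T1 at centre and boundary (ms).
#' @param pdCentre,pdEdge lens water content at centre and boundary
#'   (fraction of pure water).
#' @param t1Water water T1 (ms).
#' @param b1Amplitude amplitude of the smooth B1 deviation from 1.
#' @param flipAngles,tr acquisition parameters.
#' @param noiseSd magnitude noise SD (pure water PD = 1 unit).
#' @param seed noise seed.
#' @return As [makeMriPhantom()], plus `lensMask` and `waterRoi` logical
#'   matrices and `spacing`.
#' @export
lensMriPhantom <- function(shape = lensPreset("young-bovine")@shape,
                           spacing = 0.2, margin = 3,
                           t1Centre = 600, t1Edge = 1100,
                           pdCentre = 0.68, pdEdge = 0.85,
                           t1Water = 3000, b1Amplitude = 0.1,
                           flipAngles = c(4, 23), tr = 15,
                           noiseSd = 0, seed = 0) {
  a <- shape@ED / 2
  nx <- ceiling((shape@ED + 2 * margin) / spacing)
  ny <- ceiling((shape@LT + 2 * margin) / spacing)
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing    # radial (columns)
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing    # axial (rows)
  lensMask <- outer(ys, xs, function(y, x) abs(x) <= lensHalfWidth(shape, y))
  # dimensionless radius on the grid (Euclidean approximation on the
  # normalised semi-axes; adequate for a smooth hydration gradient)
  rr <- outer(ys / (shape@LT / 2), xs / a, function(y, x) sqrt(x^2 + y^2))
  rr <- pmin(rr, 1)
  t1 <- matrix(t1Water, ny, nx)
  pd <- matrix(1, ny, nx)
  t1[lensMask] <- (t1Centre + (t1Edge - t1Centre) * rr^2)[lensMask]
  pd[lensMask] <- (pdCentre + (pdEdge - pdCentre) * rr^2)[lensMask]
  b1 <- 1 + b1Amplitude * outer(sin(pi * seq(0, 1, length.out = ny)),
                                cos(pi * seq(0, 1, length.out = nx)))
  waterRoi <- !lensMask
  # keep the reference away from the lens boundary
  dil <- outer(ys, xs, function(y, x)
    abs(x) <= lensHalfWidth(shape, y) + 2 * spacing &
      y >= -shape@TP - 2 * spacing & y <= shape@TA + 2 * spacing)
  waterRoi <- waterRoi & !dil
  ph <- makeMriPhantom(t1, pd, b1, flipAngles = flipAngles, tr = tr,
                       noiseSd = noiseSd, seed = seed)
  ph$lensMask <- lensMask
  ph$waterRoi <- waterRoi
  ph$spacing <- spacing
  ph
}
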