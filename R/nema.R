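# ---- sensitivity ------------------------------------------------------------

#' Absolute coincidence sensitivity
#'
#' Prompt true coincidences per positron emission, in percent, for each
#' requested energy window.  The positron emission rate is the simulated
#' decay count (branching is applied at decay sampling), following the NU4
#' convention of dividing by the branching-corrected source activity.
#'
#' @param stream a \code{SinglesStream} from \code{\link{simulateAcquisition}}.
#' @param geom the \code{ScannerGeometry}.
#' @param acq base \code{\link{acquisitionConfig}}; its energy window is
#'   replaced by each entry of \code{windows}.
#' @param windows named list of keV windows (\code{NULL} = threshold only).
#' @return data.frame: \code{window}, \code{sensitivity_pct}.
#' @export
sensitivityAnalysis <- function(stream, geom, acq = acquisitionConfig(),
                                windows = list(none = NULL,
                                               `250-750` = c(250, 750),
                                               `350-650` = c(350, 650))) {
  if (numDecays(stream) <= 0) stop("no decays simulated")
  surv <- applyDeadTime(stream, acq)
  out <- lapply(names(windows), function(w) {
    acq$energyWindow <- windows[[w]]
    cc <- classifyCoincidences(sortCoincidences(surv, geom, acq))
    nt <- sum(cc$stream == "prompt" & cc$truth == "true")
    data.frame(window = w, sensitivity_pct = 100 * nt / numDecays(stream))
  })
  do.call(rbind, out)
}

#' Axial sensitivity profile
#'
#' Repeats the point-source sensitivity measurement at a series of axial
#' positions; for a full uniform ring the profile is approximately
#' triangular, peaked at the axial center.
#'
#' @param geom a \code{ScannerGeometry}.
#' @param zPositions source positions, mm.
#' @param duration per-position acquisition, s.
#' @param physics a \code{\link{physicsConfig}}.
#' @param acq an \code{\link{acquisitionConfig}}.
#' @param activity_kbq source activity, kBq.
#' @param seed base seed (one sub-seed per position).
#' @return data.frame: \code{z}, \code{sensitivity_pct}.
#' @export
axialSensitivityProfile <- function(geom, zPositions = seq(-80, 80, by = 20),
                                    duration = 0.05,
                                    physics = physicsConfig(),
                                    acq = acquisitionConfig(),
                                    activity_kbq = 500, seed = 1L) {
  out <- lapply(seq_along(zPositions), function(i) {
    ph <- makeSensitivitySource(z = zPositions[i], activity_kbq = activity_kbq)
    sim <- simulateAcquisition(ph, geom, physics, duration,
                               seed = seed + 1000L * i)
    s <- sensitivityAnalysis(sim, geom, acq,
                             windows = list(w = acq$energyWindow))
    data.frame(z = zPositions[i], sensitivity_pct = s$sensitivity_pct)
  })
  do.call(rbind, out)
}

# ---- spatial resolution -----------------------------------------------------

# 1D FWHM with NEMA conventions: parabolic fit of the 3 samples around the
# peak for the maximum, linear interpolation of the half-maximum crossings.
profileFWHM <- function(pos, val) {
  i <- which.max(val)
  if (i <= 1 || i >= length(val)) stop("peak at the profile border")
  # parabolic peak estimate
  y1 <- val[i - 1]; y2 <- val[i]; y3 <- val[i + 1]
  den <- y1 - 2 * y2 + y3
  pk <- if (den < 0) y2 - (y1 - y3)^2 / (8 * den) else y2
  half <- pk / 2
  left <- NA_real_
  for (j in seq(i, 2)) {
    if (val[j - 1] <= half && val[j] > half) {
      left <- pos[j - 1] + (half - val[j - 1]) / (val[j] - val[j - 1]) *
        (pos[j] - pos[j - 1])
      break
    }
  }
  right <- NA_real_
  for (j in seq(i, length(val) - 1)) {
    if (val[j + 1] <= half && val[j] > half) {
      right <- pos[j] + (val[j] - half) / (val[j] - val[j + 1]) *
        (pos[j + 1] - pos[j])
      break
    }
  }
  if (is.na(left) || is.na(right)) stop("half maximum not crossed in profile")
  right - left
}

#' Point-source FWHM from a reconstructed volume
#'
#' Extracts 1D profiles through the source maximum along the transverse (x,
#' y) and axial (z) axes, subtracts the local background estimated from an
#' annulus around the source, and measures the FWHM by linear interpolation
#' of the half-maximum crossings with a parabolic 3-point peak estimate.
#'
#' @param vol reconstructed \code{ImageVolume}.
#' @param location nominal source position, mm.
#' @param searchRadius radius around the nominal position searched for the
#'   peak voxel, mm.
#' @param annulus inner/outer radius of the background annulus, mm.
#' @return named vector: \code{transverse} (mean of x and y), \code{axial},
#'   plus \code{fwhm_x}, \code{fwhm_y} (mm).
#' @export
pointSourceFWHM <- function(vol, location = c(0, 0, 0), searchRadius = 5,
                            annulus = c(8, 12)) {
  a <- vol@data
  d <- dim(a)
  ctr <- voxelIndex(vol, location)
  rv <- ceiling(searchRadius / vol@voxelSize)
  xs <- max(1, ctr[1] - rv):min(d[1], ctr[1] + rv)
  ys <- max(1, ctr[2] - rv):min(d[2], ctr[2] + rv)
  zs <- max(1, ctr[3] - rv):min(d[3], ctr[3] + rv)
  sub <- a[xs, ys, zs, drop = FALSE]
  w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  pk <- c(xs[w[1]], ys[w[2]], zs[w[3]])
  if (any(pk <= 2) || any(pk >= d - 1)) stop("peak at volume border")
  # background: annulus in the transverse plane of the peak
  ix <- seq_len(d[1]); iy <- seq_len(d[2])
  cx <- vol@origin[1] + (pk[1] - 0.5) * vol@voxelSize
  cy <- vol@origin[2] + (pk[2] - 0.5) * vol@voxelSize
  X <- outer(vol@origin[1] + (ix - 0.5) * vol@voxelSize - cx, rep(1, d[2]))
  Y <- outer(rep(1, d[1]), vol@origin[2] + (iy - 0.5) * vol@voxelSize - cy)
  rr <- sqrt(X^2 + Y^2)
  ann <- rr >= annulus[1] & rr <= annulus[2]
  bkg <- mean(a[, , pk[3]][ann])
  if (!is.finite(bkg)) bkg <- 0
  if (bkg >= a[pk[1], pk[2], pk[3]]) stop("background at or above the peak")
  coords <- function(k, n) vol@origin[k] + (seq_len(n) - 0.5) * vol@voxelSize
  px <- pmax(a[, pk[2], pk[3]] - bkg, 0)
  py <- pmax(a[pk[1], , pk[3]] - bkg, 0)
  pz <- pmax(a[pk[1], pk[2], ] - bkg, 0)
  fx <- profileFWHM(coords(1, d[1]), px)
  fy <- profileFWHM(coords(2, d[2]), py)
  fz <- profileFWHM(coords(3, d[3]), pz)
  c(transverse = (fx + fy) / 2, axial = fz, fwhm_x = fx, fwhm_y = fy)
}

voxelIndex <- function(vol, p) {
  pmin(pmax(1L, as.integer(floor((p - vol@origin) / vol@voxelSize)) + 1L),
       dim(vol@data))
}

# logical mask of a z-aligned cylindrical VOI on the volume grid
cylinderMask <- function(vol, center, diameter, height) {
  d <- dim(vol@data)
  xs <- vol@origin[1] + (seq_len(d[1]) - 0.5) * vol@voxelSize
  ys <- vol@origin[2] + (seq_len(d[2]) - 0.5) * vol@voxelSize
  zs <- vol@origin[3] + (seq_len(d[3]) - 0.5) * vol@voxelSize
  inxy <- outer((xs - center[1])^2, (ys - center[2])^2, "+") <=
    (diameter / 2)^2
  inz <- abs(zs - center[3]) <= height / 2
  array(inxy, d) & rep(inz, each = d[1] * d[2])
}

# ---- uniformity, recovery, spill-over --------------------------------------

#' Uniformity (%STD) over a volume of interest
#'
#' 100 x sd/mean over the voxels of a cylindrical VOI in the uniform region
#' (default: 101 mm diameter x 10 mm height, 75\% of the image-quality
#' phantom diameter).
#'
#' @param vol reconstructed \code{ImageVolume}.
#' @param center VOI center, mm.
#' @param diameter,height VOI size, mm.
#' @return percent standard deviation.
#' @export
uniformity <- function(vol, center = c(0, 0, -30), diameter = 101,
                       height = 10) {
  m <- cylinderMask(vol, center, diameter, height)
  if (!any(m)) stop("empty VOI")
  v <- vol@data[m]
  100 * stats::sd(v) / mean(v)
}

#' Hot-rod recovery coefficients
#'
#' NU4-style: transverse slices covering the central 10 mm of the rod length
#' are averaged; the maximum pixel of each rod region in the averaged slice
#' fixes the profile position; the RC is the mean of the axial profile at
#' that position divided by (uniform-region mean x nominal activity ratio).
#' The quoted sd propagates the axial-profile and background variabilities.
#'
#' @param vol reconstructed \code{ImageVolume}.
#' @param rods data.frame with \code{x}, \code{y}, \code{diameter} (mm).
#' @param uniformMean mean of the uniform-region VOI.
#' @param uniformSd sd of the uniform-region VOI (for the error propagation).
#' @param ratio nominal rod-to-background activity ratio.
#' @param zRange axial extent of the rods, mm.
#' @return data.frame: \code{diameter}, \code{rc}, \code{rc_sd}.
#' @export
recoveryCoefficients <- function(vol, rods, uniformMean, uniformSd = 0,
                                 ratio = 4, zRange = c(1.5, 51.5)) {
  d <- dim(vol@data)
  zc <- mean(zRange)
  zs <- vol@origin[3] + (seq_len(d[3]) - 0.5) * vol@voxelSize
  zSel <- which(abs(zs - zc) <= 5)  # central 10 mm
  zProf <- which(zs >= zRange[1] + 2 & zs <= zRange[2] - 2)
  if (!length(zSel) || !length(zProf)) stop("rod outside the volume grid")
  avg <- apply(vol@data[, , zSel, drop = FALSE], c(1, 2), mean)
  xs <- vol@origin[1] + (seq_len(d[1]) - 0.5) * vol@voxelSize
  ys <- vol@origin[2] + (seq_len(d[2]) - 0.5) * vol@voxelSize
  out <- lapply(seq_len(nrow(rods)), function(i) {
    r <- rods[i, ]
    m <- outer((xs - r$x)^2, (ys - r$y)^2, "+") <= (r$diameter / 2)^2
    if (!any(m)) stop("rod outside the volume grid")
    w <- which(avg == max(avg[m]) & m, arr.ind = TRUE)[1, ]
    prof <- vol@data[w[1], w[2], zProf]
    rc <- mean(prof) / (uniformMean * ratio)
    rc_sd <- rc * sqrt((stats::sd(prof) / mean(prof))^2 +
                         (uniformSd / uniformMean)^2)
    data.frame(diameter = r$diameter, rc = rc, rc_sd = rc_sd)
  })
  do.call(rbind, out)
}

#' Cold-rod spill-over ratios
#'
#' Mean of an eroded cylindrical VOI inside each cold rod divided by the
#' uniform-region mean; the VOI radius is the nominal rod radius minus
#' \code{erosionVoxels} voxels to avoid edge partial-volume effects.
#'
#' @param vol reconstructed \code{ImageVolume}.
#' @param rods data.frame with \code{x}, \code{y}, \code{diameter} (mm).
#' @param uniformMean,uniformSd uniform-region statistics.
#' @param erosionVoxels voxels eroded from the nominal radius.
#' @param zRange axial extent of the rods, mm.
#' @return data.frame: \code{diameter}, \code{sor}, \code{sor_sd}.
#' @export
spillOverRatios <- function(vol, rods, uniformMean, uniformSd = 0,
                            erosionVoxels = 2, zRange = c(1.5, 51.5)) {
  out <- lapply(seq_len(nrow(rods)), function(i) {
    r <- rods[i, ]
    rad <- r$diameter / 2 - erosionVoxels * vol@voxelSize
    if (rad <= 0) stop("rod too small for the requested erosion")
    m <- cylinderMask(vol, c(r$x, r$y, mean(zRange)), 2 * rad,
                      diff(zRange) - 4)
    if (!any(m)) stop("rod outside the volume grid")
    v <- vol@data[m]
    sor <- mean(v) / uniformMean
    sor_sd <- sor * sqrt((stats::sd(v) / max(mean(v), 1e-12))^2 +
                           (uniformSd / uniformMean)^2)
    data.frame(diameter = r$diameter, sor = sor, sor_sd = sor_sd)
  })
  do.call(rbind, out)
}

# ---- count rates ------------------------------------------------------------

#' NECR curve over an activity sweep
#'
#' Simulates the scatter phantom at each activity (frame durations shortened
#' at high activity so the simulated decay count stays constant), applies
#' dead time and coincidence sorting, and summarizes T/S/R/NECR per point.
#' The peak is located by a 3-point quadratic fit around the maximum sample;
#' the scatter fraction is reported from the randoms-negligible low-activity
#' regime.
#'
#' @param kind "rat" or "head".
#' @param activities MBq sweep.
#' @param geom a \code{ScannerGeometry}.
#' @param physics,acq configurations.
#' @param decaysPerPoint target simulated decays per activity.
#' @param seed base seed.
#' @return list: \code{curve} (data.frame per activity), \code{peak_necr_cps},
#'   \code{peak_activity_mbq}, \code{scatter_fraction_pct},
#'   \code{peak_warning}.
#' @export
necrCurve <- function(kind = c("rat", "head"),
                      activities = exp(seq(log(0.5), log(40), length.out = 12)),
                      geom, physics = physicsConfig(),
                      acq = acquisitionConfig(), decaysPerPoint = 3e5,
                      seed = 1L) {
  kind <- match.arg(kind)
  rows <- lapply(seq_along(activities), function(i) {
    A <- activities[i]
    ph <- makeScatterPhantom(kind, activity_mbq = A)
    dur <- decaysPerPoint / (A * 1e6 * positronBranching(ph@isotope))
    sim <- simulateAcquisition(ph, geom, physics, dur, seed = seed + 37L * i)
    cc <- classifyCoincidences(
      sortCoincidences(applyDeadTime(sim, acq), geom, acq))
    countRates(cc, dur, activity_mbq = A)
  })
  curve <- do.call(rbind, rows)
  i <- which.max(curve$necr)
  warn <- i == 1 || i == nrow(curve)
  if (warn) {
    pk <- curve$necr[i]
    pa <- curve$activity_mbq[i]
  } else {
    # 3-point quadratic through the maximum and neighbors (log-activity axis)
    xs <- log(curve$activity_mbq[(i - 1):(i + 1)])
    ysv <- curve$necr[(i - 1):(i + 1)]
    cf <- solve(cbind(1, xs, xs^2), ysv)
    xpk <- -cf[2] / (2 * cf[3])
    if (cf[3] >= 0 || xpk < xs[1] || xpk > xs[3]) {
      pk <- ysv[2]
      pa <- exp(xs[2])
    } else {
      pk <- cf[1] + cf[2] * xpk + cf[3] * xpk^2
      pa <- exp(xpk)
    }
  }
  lowA <- curve$randoms <= 0.05 * pmax(curve$prompts, 1e-12)
  sfsel <- if (any(lowA)) lowA else seq_len(nrow(curve)) == 1
  sf <- stats::weighted.mean(curve$sf[sfsel],
                             curve$trues[sfsel] + curve$scattered[sfsel])
  list(curve = curve, peak_necr_cps = pk, peak_activity_mbq = pa,
       scatter_fraction_pct = sf, peak_warning = warn)
}

# ---- report container -------------------------------------------------------

#' Assemble a figure-of-merit report
#'
#' @param ... named report fields (data.frames or scalars).
#' @return a \code{\link{NemaReport-class}}.
#' @export
nemaReport <- function(...) new("NemaReport", report = list(...))

#' Serialize / read a NemaReport as YAML
#'
#' @param report a \code{NemaReport}.
#' @param path file path.
#' @export
writeNemaReport <- function(report, path) {
  ser <- lapply(report@report, function(x)
    if (is.data.frame(x)) as.list(x) else x)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname writeNemaReport
#' @export
readNemaReport <- function(path) {
  raw <- yaml::read_yaml(path)
  fields <- lapply(raw, function(x) {
    if (is.list(x) && length(x) && !is.null(names(x)) &&
        all(vapply(x, is.atomic, TRUE)) &&
        length(unique(lengths(x))) == 1)
      as.data.frame(x, stringsAsFactors = FALSE)
    else x
  })
  new("NemaReport", report = fields)
}
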