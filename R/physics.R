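#' Linear attenuation coefficients at 511 keV
#'
#' Default photon attenuation table (mm^-1) used for phantom voxelization and
#' transport.  Values follow standard photon cross-section tables; all are
#' overridable through \code{\link{physicsConfig}}.
#' @return named numeric vector, mm^-1.
#' @export
attenuationCoefficients <- function() {
  c(water = 0.0096, polyethylene = 0.0090, acrylic = 0.0109, air = 0,
    LYSO = 0.083)
}

#' Photon-transport and detector physics configuration
#'
#' Bundles the physical parameters of the simplified Monte Carlo: energy
#' resolution (fractional FWHM at 511 keV, scaling as 1/sqrt(E)), annihilation
#' photon acollinearity, isotope positron ranges, the LYSO attenuation split
#' into photoelectric and Compton components, the singles low-energy
#' threshold, and the detector interaction model.
#'
#' \code{detectorModel = "tracking"} (default) follows the photon through the
#' crystal ring: photoelectric absorption deposits the full energy, Compton
#' interactions deposit the recoil-electron energy and the scattered photon is
#' tracked further; deposits are summed per crystal and each crystal above
#' threshold produces one single.  \code{"simple"} stops at the first
#' interaction and deposits the full photon energy there.
#'
#' @param energyResolution fractional FWHM at 511 keV (0.178).
#' @param noncollinearityFwhmDeg acollinearity FWHM of the deviation angle,
#'   degrees.
#' @param positronRangeFwhm named per-axis Gaussian FWHM, mm, by isotope.
#' @param muLyso total LYSO attenuation at 511 keV, mm^-1.
#' @param lysoPhotofraction photoelectric fraction of \code{muLyso} at 511 keV.
#' @param singlesThreshold low-energy singles threshold, keV (post blur).
#' @param detectorModel "tracking" or "simple".
#' @param energyCut photon termination energy, keV.
#' @param attenuation material table, mm^-1 at 511 keV.
#' @return a list of class \code{petPhysicsConfig}.
#' @export
physicsConfig <- function(energyResolution = 0.178,
                          noncollinearityFwhmDeg = 0.25,
                          positronRangeFwhm = c(F18 = 1.02, Na22 = 1.1),
                          muLyso = 0.083, lysoPhotofraction = 0.33,
                          singlesThreshold = 100,
                          detectorModel = c("tracking", "simple"),
                          energyCut = 20,
                          attenuation = attenuationCoefficients()) {
  detectorModel <- match.arg(detectorModel)
  stopifnot(energyResolution >= 0, noncollinearityFwhmDeg >= 0,
            all(positronRangeFwhm >= 0), muLyso > 0,
            lysoPhotofraction > 0, lysoPhotofraction < 1,
            singlesThreshold >= 0, energyCut > 0)
  structure(list(energyResolution = energyResolution,
                 noncollinearityFwhmDeg = noncollinearityFwhmDeg,
                 positronRangeFwhm = positronRangeFwhm,
                 muLyso = muLyso, lysoPhotofraction = lysoPhotofraction,
                 singlesThreshold = singlesThreshold,
                 detectorModel = detectorModel,
                 energyCut = energyCut, maxChain = 30L,
                 attenuation = attenuation),
            class = "petPhysicsConfig")
}

# positron branching ratios (fraction of decays emitting a positron)
positronBranching <- function(isotope) {
  switch(isotope, F18 = 0.967, Na22 = 0.906,
         stop("unknown isotope: ", isotope))
}

# physics parameter vector consumed by C++
physParamVector <- function(cfg, isotope = "F18",
                            positronRange = TRUE, noncollinearity = TRUE) {
  pr <- if (positronRange) unname(cfg$positronRangeFwhm[isotope]) else 0
  c(cfg$energyResolution,
    if (noncollinearity) cfg$noncollinearityFwhmDeg else 0,
    pr,
    cfg$muLyso * cfg$lysoPhotofraction,
    cfg$muLyso * (1 - cfg$lysoPhotofraction),
    cfg$singlesThreshold,
    if (cfg$detectorModel == "simple") 1 else 0,
    cfg$energyCut,
    cfg$maxChain)
}

#' Acquisition (DAQ) configuration
#'
#' Coincidence window, delayed-window offset for randoms estimation, the
#' detector dead time with its model and scope, the coincidence energy window
#' and the geometric pair criterion.
#'
#' @param coincidenceWindow coincidence time window, ns.
#' @param delayedWindowOffset delayed window offset, ns (must exceed 10x the
#'   coincidence window).
#' @param deadTime detector dead time, microseconds.
#' @param deadTimeModel "paralyzable" or "nonparalyzable".
#' @param deadTimeScope "per_tile", "per_module" or "global".
#' @param energyWindow keV interval \code{c(lo, hi)} applied to singles before
#'   pairing, or \code{NULL} for no window (threshold-only).
#' @param minSectorDifference minimal circular sector separation for a valid
#'   coincidence pair.
#' @return a list of class \code{petAcquisitionConfig}.
#' @export
acquisitionConfig <- function(coincidenceWindow = 5,
                              delayedWindowOffset = 500,
                              deadTime = 17.2,
                              deadTimeModel = c("paralyzable", "nonparalyzable"),
                              deadTimeScope = c("per_tile", "per_module", "global"),
                              energyWindow = c(350, 650),
                              minSectorDifference = 1L) {
  deadTimeModel <- match.arg(deadTimeModel)
  deadTimeScope <- match.arg(deadTimeScope)
  stopifnot(coincidenceWindow > 0, deadTime >= 0)
  if (delayedWindowOffset <= 10 * coincidenceWindow)
    stop("delayedWindowOffset must exceed 10x the coincidence window")
  if (!is.null(energyWindow) && (length(energyWindow) != 2 ||
                                 energyWindow[1] >= energyWindow[2]))
    stop("energyWindow must be c(lo, hi) in keV")
  structure(list(coincidenceWindow = coincidenceWindow,
                 delayedWindowOffset = delayedWindowOffset,
                 deadTime = deadTime, deadTimeModel = deadTimeModel,
                 deadTimeScope = deadTimeScope, energyWindow = energyWindow,
                 minSectorDifference = as.integer(minSectorDifference)),
            class = "petAcquisitionConfig")
}

#' Reconstruction configuration
#'
#' @param iterations MLEM iterations (results are conventionally read at
#'   iteration 100).
#' @param psfFwhm space-invariant 3D Gaussian PSF modelled in image space,
#'   FWHM mm.
#' @param voxelSize reconstruction voxel size, mm.
#' @param beta quadratic-penalty strength (0 = plain MLEM).
#' @param snapshots iterations at which intermediate volumes are kept.
#' @param sensitivitySamples LOR samples for the sensitivity image (0 =
#'   compute from the measured LORs only; toy/complete-sampling use).
#' @return a list of class \code{petReconConfig}.
#' @export
reconConfig <- function(iterations = 100L, psfFwhm = 2.3, voxelSize = 1.0,
                        beta = 0, snapshots = integer(0),
                        sensitivitySamples = 2e6) {
  stopifnot(iterations >= 1, psfFwhm >= 0, voxelSize > 0, beta >= 0)
  structure(list(iterations = as.integer(iterations), psfFwhm = psfFwhm,
                 voxelSize = voxelSize, beta = beta,
                 snapshots = as.integer(snapshots),
                 sensitivitySamples = sensitivitySamples),
            class = "petReconConfig")
}
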