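# Orchestration of the four characterization experiments at configurable
# scale.  Every parameter of a generated spec is tagged with its provenance:
# "reported" (a published instrument/protocol value) or "decision" (a
# documented package default).

prov <- function(parameter, value, source)
  data.frame(parameter = parameter, value = as.character(value),
             source = source)

#' Reference experiment specifications
#'
#' Builds a fully populated \code{\link{ExperimentSpec-class}} for one of the
#' four characterization experiments, at a given count scale.  Scale 1
#' corresponds to the full published protocol (e.g. 1200 s for the
#' image-quality acquisition); smaller scales shorten the acquisition
#' proportionally, leaving rates and figure-of-merit point estimates
#' unbiased.
#'
#' @param name "sensitivity", "resolution", "image_quality" or "necr".
#' @param scale fraction of full-scale counts, in (0, 1].
#' @param seed integer seed.
#' @return an \code{ExperimentSpec}.
#' @export
referenceExperiment <- function(name = c("sensitivity", "resolution",
                                         "image_quality", "necr"),
                                scale = 0.05, seed = 1L) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  physics <- physicsConfig()
  acq <- acquisitionConfig()
  rc <- reconConfig()
  base <- rbind(
    prov("coincidence_window_ns", acq$coincidenceWindow, "reported"),
    prov("dead_time_us", acq$deadTime, "reported"),
    prov("energy_resolution_fwhm", physics$energyResolution, "reported"),
    prov("psf_fwhm_mm", rc$psfFwhm, "reported"),
    prov("mlem_iterations", rc$iterations, "reported"),
    prov("delayed_window_offset_ns", acq$delayedWindowOffset, "decision"),
    prov("noncollinearity_fwhm_deg", physics$noncollinearityFwhmDeg, "decision"),
    prov("positron_range_fwhm_mm", physics$positronRangeFwhm["F18"], "decision"),
    prov("singles_threshold_kev", physics$singlesThreshold, "decision"),
    prov("dead_time_scope", acq$deadTimeScope, "decision"))
  spec <- switch(
    name,
    sensitivity = {
      ph <- makeSensitivitySource()
      new("ExperimentSpec", name = name, phantom = ph, physics = physics,
          acquisition = acq, recon = rc, duration = 10 * scale,
          activities = numeric(0), seed = as.numeric(seed), scale = scale,
          provenance = rbind(base,
            prov("source_activity_kbq", 500, "reported"),
            prov("source_radius_mm", 0.1, "reported"),
            prov("acrylic_cube_side_mm", 10, "reported"),
            prov("energy_windows_kev", "250-750, 350-650", "reported"),
            prov("base_duration_s", 10, "decision")))
    },
    resolution = {
      ph <- makeWarmPointSources(radialPositions = c(0, 25, 50),
                                 backgroundDiameter = 120,
                                 pointActivity_kbq = 40)
      new("ExperimentSpec", name = name, phantom = ph, physics = physics,
          acquisition = acq, recon = rc, duration = 300 * scale,
          activities = numeric(0), seed = as.numeric(seed), scale = scale,
          provenance = rbind(base,
            prov("acquisition_s", 300, "reported"),
            prov("background_conc_kbq_ml", 5.3, "reported"),
            prov("radial_positions_mm", "0, 25, 50 (of 0..100)", "reported"),
            prov("warm_cylinder_mm", "d120 x h40", "decision"),
            prov("point_activity_kbq", 40, "decision"),
            prov("recon_voxel_mm", 1, "decision")))
    },
    image_quality = {
      ph <- makeIQPhantom()
      new("ExperimentSpec", name = name, phantom = ph, physics = physics,
          acquisition = acq, recon = rc, duration = 1200 * scale,
          activities = numeric(0), seed = as.numeric(seed), scale = scale,
          provenance = rbind(base,
            prov("acquisition_s", 1200, "reported"),
            prov("background_conc_kbq_ml", 5.3, "reported"),
            prov("rod_background_ratio", 4, "reported"),
            prov("phantom_mm", "d135 x h103, rods d20..4.5 x 50", "reported"),
            prov("uniform_voi_mm", "d101 x h10", "reported"),
            prov("rod_circle_radius_mm", 36, "decision"),
            prov("recon_voxel_mm", 2, "decision")))
    },
    necr = {
      acts <- exp(seq(log(0.5), log(40), length.out = 12))
      new("ExperimentSpec", name = name,
          phantom = list(rat = makeScatterPhantom("rat"),
                         head = makeScatterPhantom("head")),
          physics = physics, acquisition = acq, recon = rc,
          duration = NA_real_, activities = acts, seed = as.numeric(seed),
          scale = scale,
          provenance = rbind(base,
            prov("rat_phantom_mm", "d50 x h150 PE, line at r17.5", "reported"),
            prov("head_phantom_mm", "d200 x h150 PE, line at r45", "reported"),
            prov("activity_grid_mbq", "0.5-40 log, 12 points", "decision"),
            prov("decays_per_point", round(1.5e7 * scale), "decision")))
    })
  spec
}

#' Run an experiment end to end
#'
#' simulate -> DAQ -> (reconstruct) -> figures of merit.  Deterministic for a
#' fixed spec (every random draw derives from the spec seed); the report
#' carries the configuration hash, seed and package version.
#'
#' @param spec an \code{ExperimentSpec} from \code{\link{referenceExperiment}}.
#' @param geom a \code{ScannerGeometry} (default ring).
#' @return a \code{\link{NemaReport-class}}.
#' @export
runExperiment <- function(spec, geom = buildGeometry()) {
  res <- switch(spec@name,
                sensitivity = runSensitivityExperiment(spec, geom),
                resolution = runResolutionExperiment(spec, geom),
                image_quality = runImageQualityExperiment(spec, geom),
                necr = runNecrExperiment(spec, geom),
                stop("unknown experiment: ", spec@name))
  res@report$provenance <- spec@provenance
  res@report$meta <- list(
    experiment = spec@name, seed = spec@seed, scale = spec@scale,
    config_hash = specHash(spec),
    version = as.character(utils::packageVersion("brainpetsim")))
  res
}

specHash <- function(spec) {
  s <- paste(spec@name, spec@duration, spec@scale, spec@seed,
             paste(spec@activities, collapse = ","),
             paste(unlist(spec@physics[1:8]), collapse = ","),
             paste(unlist(spec@acquisition), collapse = ","), sep = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Acquire a LOR histogram in bounded memory
#'
#' Splits a long acquisition into time chunks: each chunk is simulated,
#' passed through dead time and coincidence sorting, histogrammed onto LORs
#' and discarded, so arbitrarily long acquisitions aggregate into a fixed-size
#' sparse histogram.
#'
#' @param phantom,geom,physics,acq simulation and DAQ configuration.
#' @param duration total acquisition, s.
#' @param seed integer seed (one sub-seed per chunk).
#' @param chunks number of time chunks.
#' @return list: \code{lorCounts} (as \code{\link{binListmode}}),
#'   \code{rates} (summed count-rate summary), \code{nDecays}.
#' @export
acquireLORHistogram <- function(phantom, geom, physics = physicsConfig(),
                                acq = acquisitionConfig(), duration, seed = 1L,
                                chunks = 1L) {
  agg <- NULL
  nDecays <- 0
  counts <- c(true = 0, scattered = 0, random = 0, delayed = 0)
  for (k in seq_len(chunks)) {
    sim <- simulateAcquisition(phantom, geom, physics, duration / chunks,
                               seed = seed + 7919L * (k - 1L))
    nDecays <- nDecays + numDecays(sim)
    cc <- classifyCoincidences(
      sortCoincidences(applyDeadTime(sim, acq), geom, acq))
    pr <- cc$stream == "prompt"
    counts["true"] <- counts["true"] + sum(pr & cc$truth == "true")
    counts["scattered"] <- counts["scattered"] + sum(pr & cc$truth == "scattered")
    counts["random"] <- counts["random"] + sum(pr & cc$truth == "random")
    counts["delayed"] <- counts["delayed"] + sum(!pr)
    lc <- binListmode(cc, geom)[, c("id_a", "id_b", "prompts", "delayed")]
    agg <- if (is.null(agg)) lc else {
      both <- data.table::rbindlist(list(agg, lc))
      as.data.frame(both[, list(prompts = sum(prompts),
                                delayed = sum(delayed)),
                         by = c("id_a", "id_b")])
    }
  }
  agg$net <- pmax(agg$prompts - agg$delayed, 0)
  T <- counts[["true"]] / duration
  S <- counts[["scattered"]] / duration
  R <- counts[["random"]] / duration
  rates <- data.frame(trues = T, scattered = S, randoms = R,
                      randoms_delayed = counts[["delayed"]] / duration,
                      prompts = T + S + R,
                      necr = if (T + S + R > 0) T^2 / (T + S + R) else 0,
                      sf = if (S + T > 0) 100 * S / (S + T) else NA_real_)
  list(lorCounts = structure(agg, randoms_policy = "delayed_subtraction"),
       rates = rates, nDecays = nDecays)
}

runSensitivityExperiment <- function(spec, geom) {
  sim <- simulateAcquisition(spec@phantom, geom, spec@physics, spec@duration,
                             seed = spec@seed)
  sens <- sensitivityAnalysis(sim, geom, spec@acquisition)
  nemaReport(sensitivity_by_window = sens,
             n_decays = numDecays(sim))
}

runResolutionExperiment <- function(spec, geom) {
  acqr <- acquireLORHistogram(spec@phantom, geom, spec@physics,
                              spec@acquisition, spec@duration, spec@seed,
                              chunks = max(1L, ceiling(spec@duration / 4)))
  lc <- acqr$lorCounts
  pr <- spec@phantom@primitives
  bg <- pr[1, ]
  vox <- voxelize(spec@phantom, voxelSize = 2,
                  attenuation = spec@physics$attenuation)
  grid <- reconGrid(c(2 * bg$d1 + 4, 2 * bg$d1 + 4, bg$d2 + 4),
                    voxelSize = spec@recon$voxelSize,
                    center = c(bg$cx, bg$cy, bg$cz))
  rec <- reconstructMLEM(lc, geom, grid, muVol = vox$mu,
                         config = spec@recon, seed = spec@seed)
  pts <- pr[pr$kind == "sphere", , drop = FALSE]
  fw <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    f <- pointSourceFWHM(rec$image, c(pts$cx[i], pts$cy[i], pts$cz[i]))
    data.frame(radius = sqrt(pts$cx[i]^2 + pts$cy[i]^2),
               transverse = f[["transverse"]], axial = f[["axial"]])
  }))
  nemaReport(fwhm_table = fw, n_prompts = sum(lc$prompts))
}

runImageQualityExperiment <- function(spec, geom) {
  acqr <- acquireLORHistogram(spec@phantom, geom, spec@physics,
                              spec@acquisition, spec@duration, spec@seed,
                              chunks = max(1L, ceiling(spec@duration / 2)))
  lc <- acqr$lorCounts
  vox <- voxelize(spec@phantom, voxelSize = 2,
                  attenuation = spec@physics$attenuation)
  rcfg <- spec@recon
  rcfg$voxelSize <- 2
  rcfg$snapshots <- seq(10L, rcfg$iterations, by = 10L)
  grid <- reconGrid(c(140, 140, 108), voxelSize = rcfg$voxelSize)
  rec <- reconstructMLEM(lc, geom, grid, muVol = vox$mu, config = rcfg,
                         seed = spec@seed)
  layout <- iqRodLayout()
  uz <- layout$uniformZ
  uCtr <- c(0, 0, mean(uz))
  uMask <- cylinderMask(rec$image, uCtr, 101, diff(uz))
  uMean <- mean(rec$image@data[uMask])
  uSd <- stats::sd(rec$image@data[uMask])
  unif <- data.frame(
    iteration = rcfg$snapshots,
    uniformity_pct = vapply(rec$snapshots, function(v)
      uniformity(v, center = uCtr, diameter = 101, height = diff(uz)), 0))
  hot <- layout$role == "hot"
  rods <- data.frame(x = layout$center[, 1], y = layout$center[, 2],
                     diameter = layout$diameter)
  rc <- recoveryCoefficients(rec$image, rods[hot, ], uMean, uSd,
                             ratio = 4, zRange = layout$zRange)
  sor <- spillOverRatios(rec$image, rods[!hot, ], uMean, uSd,
                         erosionVoxels = 2, zRange = layout$zRange)
  sor$material <- c("water", "air")[match(sor$diameter, c(20, 15))]
  nemaReport(uniformity_by_iteration = unif, rc_by_rod = rc,
             sor_by_rod = sor, n_prompts = sum(lc$prompts))
}

runNecrExperiment <- function(spec, geom) {
  dpp <- round(1.5e7 * spec@scale)
  rat <- necrCurve("rat", spec@activities, geom, spec@physics,
                   spec@acquisition, decaysPerPoint = dpp, seed = spec@seed)
  head <- necrCurve("head", spec@activities, geom, spec@physics,
                    spec@acquisition, decaysPerPoint = dpp,
                    seed = spec@seed + 5000L)
  nemaReport(necr_rat = rat$curve, necr_head = head$curve,
             peaks = data.frame(
               phantom = c("rat", "head"),
               peak_necr_kcps = c(rat$peak_necr_cps, head$peak_necr_cps) / 1000,
               peak_activity_mbq = c(rat$peak_activity_mbq,
                                     head$peak_activity_mbq),
               scatter_fraction_pct = c(rat$scatter_fraction_pct,
                                        head$scatter_fraction_pct)))
}
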