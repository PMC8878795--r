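#' Sample decay events from a phantom
#'
#' Positron-emission positions are drawn analytically from the shape
#' primitives in proportion to their activity, with primitive precedence
#' enforced by thinning (a candidate inside a later, overriding primitive is
#' discarded), so the accepted count is Poisson at the phantom's effective
#' positron emission rate.  Decay times are uniform over the acquisition.
#'
#' This R implementation mirrors the C++ path used by
#' \code{\link{simulateAcquisition}} and is intended for inspection and
#' testing.
#'
#' @param phantom a \code{PhantomModel}.
#' @param duration acquisition time, s.
#' @param seed integer seed.
#' @param n optional fixed number of candidate decays (overrides the Poisson
#'   draw).
#' @return data.frame: \code{event_id}, \code{x}, \code{y}, \code{z} (mm),
#'   \code{t_ns}.
#' @export
sampleDecays <- function(phantom, duration, seed = 1L, n = NULL) {
  stopifnot(duration > 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  pr <- phantom@primitives
  rates <- primActivityBq(pr) * positronBranching(phantom@isotope)
  tot <- sum(rates)
  if (tot <= 0 || (!is.null(n) && n == 0))
    return(data.frame(event_id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), t_ns = numeric(0)))
  nc <- if (is.null(n)) rpois(1, tot * duration) else n
  if (nc == 0)
    return(data.frame(event_id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), t_ns = numeric(0)))
  pi_idx <- sample.int(nrow(pr), nc, replace = TRUE, prob = rates)
  pts <- matrix(0, nc, 3)
  for (k in unique(pi_idx)) {
    sel <- pi_idx == k
    pts[sel, ] <- samplePrimitive(pr[k, ], sum(sel))
  }
  keep <- rep(TRUE, nc)
  for (j in seq_len(nrow(pr))) {
    earlier <- pi_idx < j
    if (any(earlier))
      keep[earlier] <- keep[earlier] & !containsPoint(pr[j, ], pts[earlier, , drop = FALSE])
  }
  pts <- pts[keep, , drop = FALSE]
  m <- nrow(pts)
  data.frame(event_id = seq_len(m) - 1L, x = pts[, 1], y = pts[, 2],
             z = pts[, 3], t_ns = sort(runif(m, 0, duration * 1e9)))
}

#' Emit an annihilation photon pair
#'
#' The first photon is isotropic; the second is back-to-back up to an
#' acollinearity deviation sampled from a Gaussian of the configured FWHM
#' (random azimuth).  The annihilation point is displaced from the decay
#' position by the positron range (per-axis Gaussian).
#'
#' @param n number of pairs.
#' @param physics a \code{\link{physicsConfig}}.
#' @param isotope "F18" or "Na22" (selects the positron range).
#' @param seed integer seed.
#' @param positronRange,noncollinearity logical toggles.
#' @return list of matrices \code{d1}, \code{d2} (unit directions) and
#'   \code{displacement} (mm).
#' @export
emitAnnihilationPairs <- function(n, physics = physicsConfig(),
                                  isotope = "F18", seed = 1L,
                                  positronRange = TRUE,
                                  noncollinearity = TRUE) {
  cpp_emit_pairs(as.integer(n),
                 if (noncollinearity) physics$noncollinearityFwhmDeg else 0,
                 if (positronRange) unname(physics$positronRangeFwhm[isotope]) else 0,
                 seed)
}

#' Simulate an acquisition
#'
#' Full decay-to-singles Monte Carlo: decays are sampled from the phantom,
#' annihilation pairs emitted (positron range, acollinearity), photons tracked
#' through the voxelized attenuation map (Woodcock tracking, Klein-Nishina
#' Compton scattering with ground-truth scatter counting) and then through
#' the crystal ring, where per-crystal energy deposits are blurred by the
#' energy resolution and thresholded into a time-ordered singles stream.
#'
#' @param phantom a \code{PhantomModel}.
#' @param geom a \code{ScannerGeometry}.
#' @param physics a \code{\link{physicsConfig}}.
#' @param duration acquisition time, s.
#' @param seed integer seed (all randomness derives from it).
#' @param attenuationVoxel voxel size of the internal attenuation map, mm.
#' @param attenuate simulate photon interactions in the phantom (set
#'   \code{FALSE} for a vacuum phantom: every coincidence is then true).
#' @param positronRange,noncollinearity physics toggles.
#' @return a \code{\link{SinglesStream-class}}; the singles data.frame has
#'   columns \code{t_ns}, \code{flat_id}, \code{tile}, \code{energy} (keV),
#'   \code{event_id}, \code{scattered}, \code{photon}.
#' @export
simulateAcquisition <- function(phantom, geom, physics = physicsConfig(),
                                duration = 1, seed = 1L,
                                attenuationVoxel = 2, attenuate = TRUE,
                                positronRange = TRUE, noncollinearity = TRUE) {
  stopifnot(is(phantom, "PhantomModel"), is(geom, "ScannerGeometry"),
            duration > 0)
  pr <- phantom@primitives
  branch <- positronBranching(phantom@isotope)
  prim <- cbind(kind = vapply(pr$kind, function(k)
                  switch(k, cylinder = 1, sphere = 2, box = 3, point = 5), 0),
                cx = pr$cx, cy = pr$cy, cz = pr$cz,
                d1 = pr$d1, d2 = pr$d2, d3 = pr$d3,
                rate = primActivityBq(pr) * branch)
  if (attenuate) {
    vox <- voxelize(phantom, voxelSize = attenuationVoxel,
                    attenuation = physics$attenuation)
    muvec <- as.vector(vox$mu@data)
    mudim <- dim(vox$mu@data)
    muorg <- vox$mu@origin
    muvox <- vox$mu@voxelSize
  } else {
    muvec <- numeric(0)
    mudim <- c(0L, 0L, 0L)
    muorg <- c(0, 0, 0)
    muvox <- 1
  }
  res <- cpp_simulate(prim, duration, geomParamVector(geom),
                      physParamVector(physics, phantom@isotope,
                                      positronRange, noncollinearity),
                      seed, muvec, as.integer(mudim), muorg, muvox)
  df <- data.frame(t_ns = res$t_ns, flat_id = res$flat_id,
                   tile = res$flat_id %/% (geom@params$topGrid^2 +
                                             geom@params$bottomGrid^2),
                   energy = res$energy, event_id = res$event_id,
                   scattered = res$scattered, photon = res$photon)
  new("SinglesStream", singles = df, nDecays = res$n_decays,
      duration = duration, seed = as.numeric(seed))
}
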