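#' Exact ray-grid intersection (Siddon path)
#'
#' @param p0,p1 segment endpoints, mm.
#' @param dim grid dimensions (voxels).
#' @param origin low corner of the grid, mm.
#' @param voxelSize isotropic voxel size, mm.
#' @return list with 1-based linear voxel \code{index} and intersection
#'   \code{length} (mm); lengths sum to the in-grid chord length.
#' @export
siddonPath <- function(p0, p1, dim, origin, voxelSize) {
  if (sum((p1 - p0)^2) == 0) stop("degenerate zero-length ray")
  cpp_siddon_path(as.numeric(p0), as.numeric(p1), as.integer(dim),
                  as.numeric(origin), voxelSize)
}

#' Forward / back projection through the factorized system matrix
#'
#' \code{forwardProject} computes \code{y_i = N_i A_i <G_i, R x>}: the image
#' is blurred by the image-space PSF, ray-projected, and scaled by the
#' per-LOR normalization and attenuation factors.  \code{backProject} applies
#' the adjoint.
#'
#' @param vol an \code{ImageVolume} (nonnegative).
#' @param endpoints n x 6 LOR endpoint matrix (see \code{\link{lorEndpoints}}).
#' @param normalization,attenuation per-LOR factors (scalar 1 recycled).
#' @param psfFwhm image-space Gaussian PSF FWHM, mm (0 = none).
#' @return \code{forwardProject}: numeric vector of expected counts per LOR.
#' @export
forwardProject <- function(vol, endpoints, normalization = 1,
                           attenuation = 1, psfFwhm = 0) {
  x <- as.vector(vol@data)
  if (any(x < 0)) stop("negative voxel values in the image")
  if (psfFwhm > 0)
    x <- cpp_blur3(x, dim(vol@data), psfFwhm, vol@voxelSize)
  y <- cpp_forward_project(endpoints, x, dim(vol@data), vol@origin,
                           vol@voxelSize)
  y * normalization * attenuation
}

#' @rdname forwardProject
#' @param y per-LOR values to backproject.
#' @param grid an \code{ImageVolume} defining the target grid (data ignored).
#' @return \code{backProject}: an \code{ImageVolume}.
#' @export
backProject <- function(y, endpoints, grid, normalization = 1,
                        attenuation = 1, psfFwhm = 0) {
  x <- cpp_back_project(endpoints, y * normalization * attenuation,
                        dim(grid@data), grid@origin, grid@voxelSize)
  if (psfFwhm > 0)
    x <- cpp_blur3(x, dim(grid@data), psfFwhm, grid@voxelSize)
  new("ImageVolume", data = array(x, dim(grid@data)),
      voxelSize = grid@voxelSize, origin = grid@origin)
}

#' Per-LOR attenuation factors
#'
#' \code{A_i = exp(-integral of mu along the LOR)} through a voxelized
#' attenuation map.
#'
#' @param muVol attenuation \code{ImageVolume}, mm^-1.
#' @param endpoints n x 6 LOR endpoint matrix.
#' @return numeric vector of factors in (0, 1].
#' @export
computeAttenuationFactors <- function(muVol, endpoints) {
  if (any(muVol@data < 0)) stop("negative attenuation coefficients")
  exp(-cpp_ray_integral(endpoints, as.vector(muVol@data), dim(muVol@data),
                        muVol@origin, muVol@voxelSize))
}

#' Per-LOR normalization factors from a normalization scan
#'
#' Estimates crystal efficiencies by iterated fan-sums of the
#' measured-to-predicted count ratio, then a residual geometric factor per
#' sector-difference class; \code{N_i = eff_a * eff_b * g_class}, normalized
#' to unit mean.  LORs with zero expected counts get their class-average
#' value.
#'
#' @param geom a \code{ScannerGeometry}.
#' @param lorData data.frame with \code{id_a}, \code{id_b}, \code{measured},
#'   \code{expected}.
#' @param iterations fan-sum iterations.
#' @return numeric vector of per-LOR normalization factors (unit mean).
#' @export
computeNormalization <- function(geom, lorData, iterations = 8L) {
  n <- numCrystals(geom)
  ratio <- ifelse(lorData$expected > 0, lorData$measured / lorData$expected,
                  NA_real_)
  a <- lorData$id_a + 1L
  b <- lorData$id_b + 1L
  eff <- rep(1, n)
  ok <- !is.na(ratio)
  for (it in seq_len(iterations)) {
    # fan-sum: average ratio over all LORs touching a crystal, partner
    # efficiency divided out
    r_a <- ratio[ok] / eff[b[ok]]
    r_b <- ratio[ok] / eff[a[ok]]
    sums <- rep(0, n)
    cnts <- rep(0, n)
    sa <- rowsum(r_a, a[ok])
    sb <- rowsum(r_b, b[ok])
    ca <- rowsum(rep(1, sum(ok)), a[ok])
    cb <- rowsum(rep(1, sum(ok)), b[ok])
    ia <- as.integer(rownames(sa))
    ib <- as.integer(rownames(sb))
    sums[ia] <- sums[ia] + sa[, 1]
    sums[ib] <- sums[ib] + sb[, 1]
    cnts[ia] <- cnts[ia] + ca[, 1]
    cnts[ib] <- cnts[ib] + cb[, 1]
    upd <- cnts > 0
    eff[upd] <- sums[upd] / cnts[upd]
  }
  cls <- sectorDifference(geom, lorData$id_a, lorData$id_b)
  resid <- ratio / (eff[a] * eff[b])
  g <- tapply(resid[ok], cls[ok], mean)
  gAll <- g[as.character(cls)]
  gAll[is.na(gAll)] <- mean(resid[ok])
  N <- eff[a] * eff[b] * as.numeric(gAll)
  N[!ok] <- (eff[a] * eff[b] * as.numeric(gAll))[!ok]  # class-average fill-in
  N / mean(N)
}

#' Histogram coincidences onto lines of response
#'
#' Aggregates a coincidence stream (or list-mode file) into per-LOR prompt
#' and delayed counts plus the randoms-subtracted net counts
#' (\code{max(prompts - delayed, 0)}).
#'
#' @param coinc coincidence data.frame, or a list-mode file path.
#' @param geom the \code{ScannerGeometry} (hash-checked for files).
#' @return data.frame: \code{id_a}, \code{id_b}, \code{prompts},
#'   \code{delayed}, \code{net}; attribute \code{randoms_policy}.
#' @export
binListmode <- function(coinc, geom) {
  if (is.character(coinc)) coinc <- readListmode(coinc, geom)
  if (nrow(coinc) == 0)
    return(structure(data.frame(id_a = integer(0), id_b = integer(0),
                                prompts = numeric(0), delayed = numeric(0),
                                net = numeric(0)),
                     randoms_policy = "delayed_subtraction"))
  dt <- data.table::as.data.table(coinc[, c("id_a", "id_b", "stream")])
  agg <- dt[, list(prompts = sum(stream == "prompt"),
                   delayed = sum(stream == "delayed")),
            by = c("id_a", "id_b")]
  out <- as.data.frame(agg)
  out$net <- pmax(out$prompts - out$delayed, 0)
  structure(out, randoms_policy = "delayed_subtraction")
}

#' Sensitivity image over the full LOR set
#'
#' Backprojects the normalization-attenuation factor over a uniform random
#' sample of all allowed crystal pairs, then applies the PSF adjoint; this is
#' the denominator image of the MLEM update.
#'
#' @param geom a \code{ScannerGeometry}.
#' @param grid target \code{ImageVolume} (data ignored).
#' @param muVol optional attenuation map.
#' @param nSamples number of sampled LORs.
#' @param minSectorDifference pair criterion (match the acquisition).
#' @param psfFwhm PSF FWHM, mm.
#' @param seed RNG seed.
#' @return an \code{ImageVolume}.
#' @export
sensitivityImage <- function(geom, grid, muVol = NULL, nSamples = 2e6,
                             minSectorDifference = 1L, psfFwhm = 2.3,
                             seed = 1L) {
  ct <- geom@crystals
  centers <- as.matrix(ct[, c("x", "y", "z")])
  s <- cpp_sensitivity_image(centers, as.integer(ct$sector),
                             as.integer(nSamples),
                             as.integer(minSectorDifference),
                             geom@params$nSectors,
                             if (is.null(muVol)) numeric(0) else as.vector(muVol@data),
                             if (is.null(muVol)) c(0L, 0L, 0L) else as.integer(dim(muVol@data)),
                             if (is.null(muVol)) c(0, 0, 0) else muVol@origin,
                             if (is.null(muVol)) 1 else muVol@voxelSize,
                             dim(grid@data), grid@origin, grid@voxelSize, seed)
  if (psfFwhm > 0)
    s <- cpp_blur3(s, dim(grid@data), psfFwhm, grid@voxelSize)
  # scale to the full pair count so sensitivities are comparable across runs
  nc <- nrow(ct)
  s <- s * (nc * (nc - 1) / 2) / nSamples
  new("ImageVolume", data = array(s, dim(grid@data)),
      voxelSize = grid@voxelSize, origin = grid@origin)
}

#' Define a reconstruction grid
#'
#' @param extent grid extent, mm (scalar or length 3), centered at
#'   \code{center}.
#' @param voxelSize isotropic voxel size, mm.
#' @param center grid center, mm.
#' @return an empty \code{ImageVolume}.
#' @export
reconGrid <- function(extent, voxelSize = 1, center = c(0, 0, 0)) {
  extent <- rep(extent, length.out = 3)
  n <- pmax(1L, as.integer(round(extent / voxelSize)))
  new("ImageVolume", data = array(0, n), voxelSize = voxelSize,
      origin = center - n * voxelSize / 2)
}

#' MLEM / penalized-MLEM reconstruction
#'
#' Maximum-likelihood EM with the factorized system matrix
#' \code{N A G R}: per-LOR normalization and attenuation factors, a
#' ray-driven geometric projector and a space-invariant image-space Gaussian
#' PSF applied on both sides of the projector.  With \code{beta > 0} a
#' quadratic neighborhood penalty (6-neighborhood, unit weights) is applied
#' through a De Pierro separable surrogate, so every iteration keeps the
#' closed-form multiplicative structure; \code{beta = 0} is exactly plain
#' MLEM.  Nonnegativity is preserved at every iteration.
#'
#' @param lorCounts LOR histogram from \code{\link{binListmode}} (or any
#'   data.frame with \code{id_a}, \code{id_b} and the count column).
#' @param geom a \code{ScannerGeometry}.
#' @param grid target grid (\code{\link{reconGrid}}).
#' @param muVol optional attenuation map for attenuation correction.
#' @param normalization per-LOR normalization factors (scalar 1 recycled).
#' @param config a \code{\link{reconConfig}}.
#' @param data which count column to reconstruct ("net" or "prompts").
#' @param sensitivity optional precomputed sensitivity \code{ImageVolume};
#'   \code{NULL} with \code{sensitivitySamples > 0} samples it over the full
#'   LOR set; with \code{sensitivitySamples = 0} it is computed from the
#'   measured LORs only (complete-sampling / toy problems).
#' @param seed RNG seed for the sensitivity sampling.
#' @return list: \code{image} (ImageVolume at the final iteration),
#'   \code{snapshots} (named list of ImageVolumes), \code{loglik} (Poisson
#'   log-likelihood per iteration), \code{sensitivity}.
#' @export
reconstructMLEM <- function(lorCounts, geom, grid, muVol = NULL,
                            normalization = 1, config = reconConfig(),
                            data = c("net", "prompts"), sensitivity = NULL,
                            seed = 1L) {
  data <- match.arg(data)
  y <- lorCounts[[data]]
  ep <- lorEndpoints(geom, lorCounts$id_a, lorCounts$id_b)
  A <- if (is.null(muVol)) rep(1, nrow(ep)) else
    computeAttenuationFactors(muVol, ep)
  q <- A * rep(normalization, length.out = nrow(ep))
  sensVec <- numeric(0)
  if (!is.null(sensitivity)) {
    sensVec <- as.vector(sensitivity@data)
  } else if (config$sensitivitySamples > 0) {
    sv <- sensitivityImage(geom, grid, muVol = muVol,
                           nSamples = config$sensitivitySamples,
                           psfFwhm = config$psfFwhm, seed = seed)
    sensVec <- as.vector(sv@data)
  }
  res <- cpp_mlem(ep, as.numeric(y), q, dim(grid@data), grid@origin,
                  grid@voxelSize, sensVec, config$psfFwhm,
                  config$iterations, config$beta,
                  as.integer(config$snapshots), 1.0)
  mkVol <- function(v) new("ImageVolume", data = array(v, dim(grid@data)),
                           voxelSize = grid@voxelSize, origin = grid@origin)
  snaps <- lapply(res$snapshots, mkVol)
  list(image = mkVol(res$x), snapshots = snaps, loglik = res$loglik,
       sensitivity = mkVol(res$sens))
}
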