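# small ring used for enumeration/normalization/recon toy problems
toyGeometry <- function(nSectors = 6) {
  buildGeometry(nSectors = nSectors, modulesPerSector = 1L, topGrid = 2L,
                bottomGrid = 3L, pitch = 3.4, topThickness = 8,
                bottomThickness = 12, afov = 21, tfov = 40)
}

# synthetic Poisson singles stream on one or more scopes (tiles)
poissonSingles <- function(rate_hz, duration_s, tile = 0L, flat_id = tile * 113L,
                           energy = 511, seed = 1) {
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_s)
  t <- sort(runif(n, 0, duration_s * 1e9))
  data.frame(t_ns = t, flat_id = flat_id, tile = tile, energy = energy,
             event_id = seq_len(n), scattered = 0L, photon = 0L)
}

mergeSingles <- function(...) {
  df <- do.call(rbind, list(...))
  df <- df[order(df$t_ns), ]
  rownames(df) <- NULL
  df
}

# analytic Gaussian blob volume for FWHM oracles
gaussianBlobVolume <- function(sigma = 1, n = 41L, vox = 0.5, amplitude = 1,
                               background = 0) {
  g <- reconGrid(rep(n * vox, 3), vox)
  d <- dim(g)
  cs <- gridOrigin(g)[1] + (seq_len(d[1]) - 0.5) * vox
  a <- amplitude * exp(-0.5 * outer(outer(cs^2, cs^2, "+"), cs^2, "+") / sigma^2)
  new("ImageVolume", data = a + background, voxelSize = vox,
      origin = gridOrigin(g))
}

# run every acceptance block even after earlier failures
if (!nzchar(Sys.getenv("TESTTHAT_MAX_FAILS"))) Sys.setenv(TESTTHAT_MAX_FAILS = "1000")
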