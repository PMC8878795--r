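test_that("Siddon path is exact on aligned and oblique rays", {
  dims <- c(10L, 10L, 10L)
  org <- c(0, 0, 0)
  # axis-aligned ray through 10 voxels of 1 mm
  sp <- siddonPath(c(-5, 4.5, 4.5), c(15, 4.5, 4.5), dims, org, 1)
  expect_equal(length(sp$length), 10L)
  expect_true(all(abs(sp$length - 1) < 1e-12))
  # chord-length conservation on random oblique rays
  set.seed(7)
  for (i in 1:50) {
    p0 <- runif(3, -15, -1)
    p1 <- runif(3, 11, 25)
    sp <- siddonPath(p0, p1, dims, org, 1)
    d <- p1 - p0
    tmin <- 0; tmax <- 1
    for (k in 1:3) {
      ta <- (0 - p0[k]) / d[k]; tb <- (10 - p0[k]) / d[k]
      if (ta > tb) { tt <- ta; ta <- tb; tb <- tt }
      tmin <- max(tmin, ta); tmax <- min(tmax, tb)
    }
    chord <- max(0, tmax - tmin) * sqrt(sum(d^2))
    expect_lt(abs(sum(sp$length) - chord), 1e-9)
  }
  # ray missing the grid
  sp <- siddonPath(c(-5, 50, 0), c(15, 50, 0), dims, org, 1)
  expect_equal(length(sp$length), 0L)
  expect_error(siddonPath(c(1, 1, 1), c(1, 1, 1), dims, org, 1), "degenerate")
})

test_that("forward and back projection are exact adjoints", {
  set.seed(8)
  grid <- reconGrid(c(24, 24, 24), 1)
  ep <- cbind(matrix(runif(90, -30, 30), 30, 3),
              matrix(runif(90, -30, 30), 30, 3))
  x <- new("ImageVolume", data = array(runif(24^3), c(24, 24, 24)),
           voxelSize = 1, origin = gridOrigin(grid))
  y <- runif(30)
  fx <- forwardProject(x, ep)
  bty <- backProject(y, ep, grid)
  lhs <- sum(fx * y)
  rhs <- sum(as.array(x) * as.array(bty))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  # x = 0 -> all zeros; single unit voxel -> intersection length
  x0 <- new("ImageVolume", data = array(0, c(24, 24, 24)), voxelSize = 1,
            origin = gridOrigin(grid))
  expect_true(all(forwardProject(x0, ep) == 0))
  xv <- as.array(x0)
  xv[12, 12, 12] <- 1
  x1 <- new("ImageVolume", data = xv, voxelSize = 1, origin = gridOrigin(grid))
  y1 <- forwardProject(x1, ep)
  oracle <- vapply(seq_len(nrow(ep)), function(i) {
    sp <- siddonPath(ep[i, 1:3], ep[i, 4:6], c(24L, 24L, 24L),
                     gridOrigin(grid), 1)
    j <- which(sp$index == 12 + 11 * 24 + 11 * 576)
    if (length(j)) sp$length[j] else 0
  }, 0)
  expect_equal(y1, oracle, tolerance = 1e-12)
  expect_error(forwardProject(new("ImageVolume",
                                  data = array(-1, c(2, 2, 2)),
                                  voxelSize = 1, origin = c(0, 0, 0)), ep),
               "negative")
})

test_that("attenuation factors follow Beer-Lambert through the mu map", {
  # vacuum: A = 1 everywhere
  grid <- reconGrid(c(40, 40, 20), 2)
  muV <- new("ImageVolume", data = array(0, dim(grid)), voxelSize = 2,
             origin = gridOrigin(grid))
  ep <- matrix(c(-100, 0, 0, 100, 0, 0), 1)
  expect_equal(computeAttenuationFactors(muV, ep), 1)
  # 135 mm water cylinder crossed diametrically
  ph <- brainpetsim:::newPhantom(
    "w", primCylinder(c(0, 0, 0), 67.5, 40, "water", conc = 1))
  vox <- voxelize(ph, voxelSize = 1)
  A <- computeAttenuationFactors(vox$mu, ep)
  expect_equal(A, exp(-0.0096 * 135), tolerance = 0.02)
  # monotone in the attenuation scale
  mu2 <- vox$mu
  mu2@data <- mu2@data * 2
  expect_lt(computeAttenuationFactors(mu2, ep), A)
})

test_that("normalization recovers uniform and planted-defect efficiencies", {
  g <- toyGeometry()
  lors <- enumerateLORs(g, 2)
  set.seed(9)
  expected <- rep(400, nrow(lors))
  measured <- rpois(nrow(lors), expected)
  N <- computeNormalization(g, cbind(lors, measured = measured,
                                     expected = expected))
  expect_equal(mean(N), 1, tolerance = 1e-9)
  expect_lt(sd(N), 0.12)
  # halve the efficiency of one sector: its LORs recover N ~ 0.5 relative
  sec <- crystalTable(g)$sector
  eff <- ifelse(sec[lors$id_a + 1] == 0 | sec[lors$id_b + 1] == 0, 0.5, 1)
  measured2 <- rpois(nrow(lors), expected * eff)
  N2 <- computeNormalization(g, cbind(lors, measured = measured2,
                                      expected = expected))
  bad <- eff == 0.5
  expect_equal(mean(N2[bad]) / mean(N2[!bad]), 0.5, tolerance = 0.1)
})

test_that("MLEM has the EM fixed point and monotone likelihood", {
  g <- toyGeometry()
  lors <- enumerateLORs(g, 2)
  ep <- lorEndpoints(g, lors$id_a, lors$id_b)
  grid <- reconGrid(c(24, 24, 24), 2)
  # noiseless data from a known digital phantom
  truth <- array(0, dim(grid))
  truth[3:8, 4:9, 5:8] <- 2
  tv <- new("ImageVolume", data = truth, voxelSize = 2,
            origin = gridOrigin(grid))
  y <- forwardProject(tv, ep, psfFwhm = 2.3)
  lc <- cbind(lors, net = y, prompts = y)
  cfg <- reconConfig(iterations = 60, psfFwhm = 2.3, voxelSize = 2,
                     snapshots = c(10L, 60L), sensitivitySamples = 0)
  rec <- reconstructMLEM(lc, g, grid, config = cfg)
  # log-likelihood non-decreasing at every iteration
  expect_true(all(diff(rec$loglik) >= -1e-7 * abs(rec$loglik[1])))
  # nonnegativity
  expect_true(all(as.array(rec$image) >= 0))
  # recovery: normalized RMSE decreases from iteration 10 to 60
  nrmse <- function(v) sqrt(mean((as.array(v) - truth)^2)) / mean(truth)
  expect_lt(nrmse(rec$snapshots$iter60), nrmse(rec$snapshots$iter10))
  # count conservation at beta = 0 with complete sampling
  sens <- as.array(rec$sensitivity)
  est <- sum(as.array(rec$image) * sens)
  expect_equal(est, sum(y), tolerance = 1e-3)
})

test_that("penalized reconstruction reduces to MLEM as beta -> 0", {
  g <- toyGeometry()
  lors <- enumerateLORs(g, 2)
  ep <- lorEndpoints(g, lors$id_a, lors$id_b)
  grid <- reconGrid(c(24, 24, 24), 2)
  flat <- new("ImageVolume", data = array(1, dim(grid)), voxelSize = 2,
              origin = gridOrigin(grid))
  set.seed(10)
  y <- rpois(nrow(ep), forwardProject(flat, ep, psfFwhm = 2.3) * 0.5)
  lc <- cbind(lors, net = y)
  run <- function(beta, iters = 40)
    reconstructMLEM(lc, g, grid,
                    config = reconConfig(iterations = iters, psfFwhm = 2.3,
                                         voxelSize = 2, beta = beta,
                                         sensitivitySamples = 0))
  r0 <- run(0)
  rEps <- run(1e-12)
  expect_lt(max(abs(as.array(r0$image) - as.array(rEps$image))) /
              max(as.array(r0$image)), 1e-10)
  # increasing beta monotonically smooths the noisy uniform reconstruction
  voi <- function(r) {
    v <- as.array(r$image)[4:9, 4:9, 4:9]
    100 * sd(v) / mean(v)
  }
  stds <- vapply(c(0, 5, 50), function(b) voi(run(b)), 0)
  expect_true(all(diff(stds) < 0))
  # flat data keep a flat image under the penalty
  yfl <- forwardProject(flat, ep, psfFwhm = 2.3)
  rf <- reconstructMLEM(cbind(lors, net = yfl), g, grid,
                        config = reconConfig(iterations = 20, psfFwhm = 2.3,
                                             voxelSize = 2, beta = 10,
                                             sensitivitySamples = 0))
  inner <- as.array(rf$image)[3:10, 3:10, 3:10]
  expect_lt(sd(inner) / mean(inner), 0.02)
})
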