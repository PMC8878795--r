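test_that("decay sampling matches rate x time with positron branching", {
  ph <- makeSensitivitySource(activity_kbq = 500)  # Na22, branching 0.906
  counts <- vapply(1:8, function(s) nrow(sampleDecays(ph, 0.1, seed = s)), 0)
  mean_expected <- 500e3 * 0.906 * 0.1
  expect_lt(abs(mean(counts) - mean_expected),
            4 * sqrt(mean_expected / length(counts)))
  # zero activity: empty stream, not an error
  cold <- brainpetsim:::newPhantom(
    "cold", primCylinder(c(0, 0, 0), 10, 10, "water", conc = 0))
  expect_equal(nrow(sampleDecays(cold, 1)), 0L)
})

test_that("two-compartment phantom splits decays by activity x volume", {
  pr <- rbind(primCylinder(c(-30, 0, 0), 10, 20, "water", conc = 4),
              primCylinder(c(30, 0, 0), 10, 20, "water", conc = 1))
  ph <- brainpetsim:::newPhantom("two", pr)
  d <- sampleDecays(ph, 1, seed = 2, n = 100000L)
  left <- d$x < 0
  expect_gt(stats::chisq.test(table(left), p = c(0.2, 0.8))$p.value, 0.01)
})

test_that("same seed reproduces the identical singles stream", {
  g <- buildGeometry()
  ph <- makeSensitivitySource(activity_kbq = 100)
  s1 <- simulateAcquisition(ph, g, duration = 0.02, seed = 9)
  s2 <- simulateAcquisition(ph, g, duration = 0.02, seed = 9)
  expect_identical(singles(s1), singles(s2))
  expect_identical(numDecays(s1), numDecays(s2))
})

test_that("annihilation pair emission reproduces the configured blur", {
  # limit case: no acollinearity, no range -> exactly antiparallel
  p0 <- emitAnnihilationPairs(1000, seed = 4, positronRange = FALSE,
                              noncollinearity = FALSE)
  expect_lt(max(abs(p0$d1 + p0$d2)), 1e-12)
  expect_true(all(p0$displacement == 0))
  expect_equal(max(abs(rowSums(p0$d1^2) - 1)), 0, tolerance = 1e-12)
  # acollinearity: folded-normal deviation angle with the configured FWHM
  cfg <- physicsConfig(noncollinearityFwhmDeg = 0.5)
  p <- emitAnnihilationPairs(3e5, physics = cfg, seed = 5,
                             positronRange = FALSE)
  dev <- acos(pmin(1, -rowSums(p$d1 * p$d2)))
  sigma_hat <- mean(dev) * sqrt(pi / 2)
  fwhm_hat <- sigma_hat * 2.35482 * 180 / pi
  expect_equal(fwhm_hat, 0.5, tolerance = 0.02)
  # positron range: mean 3D displacement of a per-axis Gaussian
  cfg2 <- physicsConfig(positronRangeFwhm = c(F18 = 1.02, Na22 = 1.1))
  p2 <- emitAnnihilationPairs(2e5, physics = cfg2, isotope = "F18", seed = 6,
                              noncollinearity = FALSE)
  r <- sqrt(rowSums(p2$displacement^2))
  sg <- 1.02 / 2.35482
  expect_equal(mean(r), sg * 2 * sqrt(2 / pi), tolerance = 0.01)
})

test_that("photon survival through water follows Beer-Lambert", {
  mu <- array(0.0096, c(60, 60, 60))  # 2 mm voxels: 120 mm cube
  r <- brainpetsim:::cpp_phantom_escape(
    as.vector(mu), dim(mu), c(-60, -60, -60), 2, c(-50, 0, 0), c(1, 0, 0),
    511, 200000L, 5, 20)
  # path from x=-50 to +60 boundary: 110 mm of water
  expect_equal(r$unscattered / 200000, exp(-0.0096 * 110), tolerance = 0.02)
})

test_that("Klein-Nishina sampler matches the analytic cross-section", {
  for (E in c(511, 250)) {
    s <- brainpetsim:::cpp_sample_kn(200000L, E, 11)
    breaks <- seq(-1, 1, length.out = 41)
    obs <- table(cut(s, breaks))
    mids <- (breaks[-1] + breaks[-41]) / 2
    a <- E / 511
    P <- 1 / (1 + a * (1 - mids))
    f <- P^2 * (P + 1 / P - (1 - mids^2))
    expect_gt(stats::chisq.test(as.vector(obs), p = f / sum(f))$p.value, 0.01)
  }
})

test_that("Compton energy transfer is conserved and bounded", {
  # backscatter limit: E' = E / (1 + 2E/511); at 511 keV -> 511/3
  s <- brainpetsim:::cpp_sample_kn(50000L, 511, 13)
  ep <- 511 / (1 + (511 / 511) * (1 - s))
  expect_gte(min(ep), 511 / 3 - 1e-9)
  expect_lte(max(ep), 511 + 1e-9)
})

test_that("detector response matches the attenuation closed form", {
  g <- buildGeometry()
  gp <- brainpetsim:::geomParamVector(g)
  # aim at a crystal-footprint center: 20 mm of LYSO at normal incidence
  simple <- brainpetsim:::physParamVector(physicsConfig(detectorModel = "simple"))
  r <- brainpetsim:::cpp_aimed_photons(gp, simple, c(0, 13.6, 13.6),
                                       c(1, 0, 0), 511, 30000L, 2)
  expect_equal(mean(r$n_singles > 0), 1 - exp(-0.083 * 20), tolerance = 0.02)
  # blurred photopeak: almost all full-absorption deposits stay in 350-650
  det <- r$e_max[r$n_singles > 0]
  expect_gt(mean(det >= 350 & det <= 650), 0.998)
  # tracking model can only reduce the photopeak fraction
  track <- brainpetsim:::physParamVector(physicsConfig())
  r2 <- brainpetsim:::cpp_aimed_photons(gp, track, c(0, 13.6, 13.6),
                                        c(1, 0, 0), 511, 30000L, 2)
  det2 <- r2$e_max[r2$n_singles > 0]
  expect_lt(mean(det2 >= 350 & det2 <= 650), mean(det >= 350 & det <= 650))
})

test_that("vacuum phantom yields only true coincidences and bounded acceptance", {
  g <- buildGeometry()
  ph <- makeSensitivitySource(activity_kbq = 200)
  sim <- simulateAcquisition(ph, g, duration = 0.05, seed = 21,
                             attenuate = FALSE)
  cc <- classifyCoincidences(sortCoincidences(sim, g))
  pr <- cc[cc$stream == "prompt", ]
  expect_gt(nrow(pr), 100)
  expect_true(all(pr$truth %in% c("true", "random")))
  expect_equal(sum(pr$truth == "scattered"), 0L)
  # per-decay coincidence probability bounded by the geometric acceptance
  expect_lt(nrow(pr) / numDecays(sim), 0.467)
})

test_that("singles rate is linear in duration before dead time", {
  g <- buildGeometry()
  ph <- makeSensitivitySource(activity_kbq = 300)
  n1 <- nrow(singles(simulateAcquisition(ph, g, duration = 0.02, seed = 31)))
  n2 <- nrow(singles(simulateAcquisition(ph, g, duration = 0.04, seed = 32)))
  expect_lt(abs(n2 - 2 * n1), 6 * sqrt(n2 + 4 * n1))
})

test_that("coincidence LORs pass near the source when blur is disabled", {
  g <- buildGeometry()
  ph <- makeSensitivitySource(activity_kbq = 200)
  # first-interaction detector model: the assigned crystal is the crystal of
  # interaction, so every true LOR must pass close to the source
  sim <- simulateAcquisition(ph, g, physics = physicsConfig(detectorModel = "simple"),
                             duration = 0.03, seed = 41,
                             attenuate = FALSE, positronRange = FALSE,
                             noncollinearity = FALSE)
  cc <- classifyCoincidences(sortCoincidences(sim, g))
  pr <- cc[cc$stream == "prompt" & cc$truth == "true", ]
  ep <- lorEndpoints(g, pr$id_a, pr$id_b)
  d <- ep[, 4:6] - ep[, 1:3]
  # distance of each LOR line from the origin (source at CFOV)
  cr <- cbind(ep[, 2] * d[, 3] - ep[, 3] * d[, 2],
              ep[, 3] * d[, 1] - ep[, 1] * d[, 3],
              ep[, 1] * d[, 2] - ep[, 2] * d[, 1])
  dist <- sqrt(rowSums(cr^2)) / sqrt(rowSums(d^2))
  expect_gt(mean(dist <= 3.4), 0.95)
})
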