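test_that("FWHM estimator recovers a Gaussian blob within 0.05 mm", {
  vol <- gaussianBlobVolume(sigma = 1, n = 61L, vox = 0.5)
  f <- pointSourceFWHM(vol, c(0, 0, 0))
  expect_equal(unname(f["transverse"]), 2.35482, tolerance = 0.05 / 2.35)
  expect_equal(unname(f["axial"]), 2.35482, tolerance = 0.05 / 2.35)
  # constant background is removed by the annulus subtraction
  volB <- gaussianBlobVolume(sigma = 1, n = 61L, vox = 0.5, background = 0.1)
  fB <- pointSourceFWHM(volB, c(0, 0, 0))
  expect_lt(abs(fB[["transverse"]] - f[["transverse"]]), 0.05)
  expect_lt(abs(fB[["axial"]] - f[["axial"]]), 0.05)
  # sampling floor: a sub-voxel blob cannot report below the voxel size
  tiny <- gaussianBlobVolume(sigma = 0.2, n = 41L, vox = 1)
  ft <- pointSourceFWHM(tiny, c(0, 0, 0))
  expect_gte(ft[["axial"]], 1)
  # degenerate inputs are rejected
  flat <- gaussianBlobVolume(sigma = 1, n = 21L, vox = 1, amplitude = 0,
                             background = 1)
  expect_error(pointSourceFWHM(flat, c(0, 0, 0)))
})

test_that("uniformity is the percent sd/mean of the VOI", {
  g <- reconGrid(c(120, 120, 40), 2)
  const <- new("ImageVolume", data = array(3, dim(g)), voxelSize = 2,
               origin = gridOrigin(g))
  expect_equal(uniformity(const, center = c(0, 0, 0)), 0)
  # two-value volume {1, 3} in equal proportions: sd/mean = 50%
  a <- array(1, dim(g))
  a[seq(1, length(a), by = 2)] <- 3
  two <- new("ImageVolume", data = a, voxelSize = 2, origin = gridOrigin(g))
  u <- uniformity(two, center = c(0, 0, 0))
  expect_equal(u, 50, tolerance = 0.001)
  expect_error(uniformity(const, center = c(500, 0, 0)), "empty VOI")
})

# analytic image-quality volume: uniform 1, hot rods at `ratio`, cold rods at
# `coldLevel`, on the package rod layout
analyticIQVolume <- function(ratio = 4, coldLevel = 0, vox = 1) {
  lay <- brainpetsim:::iqRodLayout()
  g <- reconGrid(c(140, 140, 108), vox)
  a <- array(0, dim(g))
  d <- dim(g)
  xs <- gridOrigin(g)[1] + (seq_len(d[1]) - 0.5) * vox
  zs <- gridOrigin(g)[3] + (seq_len(d[3]) - 0.5) * vox
  inPh <- outer(xs^2, xs^2, "+") <= 67.5^2
  inZ <- abs(zs) <= 51.5
  a[] <- outer(as.vector(inPh), inZ) * 1.0
  for (i in 1:6) {
    m <- outer((xs - lay$center[i, 1])^2, (xs - lay$center[i, 2])^2, "+") <=
      (lay$diameter[i] / 2)^2
    zr <- zs >= lay$zRange[1] & zs <= lay$zRange[2]
    lvl <- if (lay$role[i] == "hot") ratio else coldLevel
    a[outer(as.vector(m), zr, "&")] <- lvl
  }
  new("ImageVolume", data = a, voxelSize = vox, origin = gridOrigin(g))
}

test_that("recovery coefficients are exact on ideal volumes", {
  lay <- brainpetsim:::iqRodLayout()
  vol <- analyticIQVolume(ratio = 4)
  hot <- lay$role == "hot"
  rods <- data.frame(x = lay$center[, 1], y = lay$center[, 2],
                     diameter = lay$diameter)
  rc <- recoveryCoefficients(vol, rods[hot, ], uniformMean = 1, ratio = 4)
  expect_equal(rc$rc, rep(1, 4), tolerance = 1e-9)
  # rods filled at background level: ratio-normalized RC = 1/4
  volBg <- analyticIQVolume(ratio = 1)
  rcBg <- recoveryCoefficients(volBg, rods[hot, ], uniformMean = 1, ratio = 4)
  expect_equal(rcBg$rc, rep(0.25, 4), tolerance = 1e-9)
  # wide blur: RC decreases with rod diameter (partial volume)
  volBlur <- vol
  volBlur@data <- array(
    brainpetsim:::cpp_blur3(as.vector(vol@data), dim(vol@data), 8, 1),
    dim(vol@data))
  rcB <- recoveryCoefficients(volBlur, rods[hot, ], uniformMean = 1,
                              ratio = 4)
  expect_true(all(diff(rcB$rc[order(rcB$diameter)]) >= 0))
  expect_true(all(rcB$rc <= 1 + 1e-6))
})

test_that("spill-over ratios hit their definitional anchors", {
  lay <- brainpetsim:::iqRodLayout()
  rods <- data.frame(x = lay$center[, 1], y = lay$center[, 2],
                     diameter = lay$diameter)
  cold <- rods[!lay$role == "hot", ][1:2, ]
  vol0 <- analyticIQVolume(coldLevel = 0)
  s0 <- spillOverRatios(vol0, cold, uniformMean = 1)
  expect_equal(s0$sor, c(0, 0))
  vol1 <- analyticIQVolume(coldLevel = 1)
  s1 <- spillOverRatios(vol1, cold, uniformMean = 1)
  expect_equal(s1$sor, c(1, 1), tolerance = 1e-9)
})

test_that("figures of merit are invariant under global image rescaling", {
  lay <- brainpetsim:::iqRodLayout()
  rods <- data.frame(x = lay$center[, 1], y = lay$center[, 2],
                     diameter = lay$diameter)
  set.seed(12)
  vol <- analyticIQVolume(ratio = 4)
  vol@data <- vol@data * (1 + 0.05 * array(runif(length(vol@data)),
                                           dim(vol@data)))
  um <- mean(vol@data[brainpetsim:::cylinderMask(vol, c(0, 0, -30), 101, 10)])
  scale <- 7.3
  vol2 <- vol
  vol2@data <- vol2@data * scale
  hot <- lay$role == "hot"
  expect_equal(recoveryCoefficients(vol2, rods[hot, ], um * scale)$rc,
               recoveryCoefficients(vol, rods[hot, ], um)$rc,
               tolerance = 1e-12)
  expect_equal(spillOverRatios(vol2, rods[!hot, ], um * scale)$sor,
               spillOverRatios(vol, rods[!hot, ], um)$sor, tolerance = 1e-12)
  expect_equal(uniformity(vol2, c(0, 0, -30)), uniformity(vol, c(0, 0, -30)),
               tolerance = 1e-12)
})

test_that("sensitivity is monotone in the energy window", {
  g <- buildGeometry()
  sim <- simulateAcquisition(makeSensitivitySource(), g, duration = 0.05,
                             seed = 17)
  s <- sensitivityAnalysis(sim, g,
                           windows = list(narrow = c(450, 572),
                                          standard = c(350, 650),
                                          wide = c(250, 750), none = NULL))
  v <- s$sensitivity_pct
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 100))
})

test_that("NEMA report round-trips through YAML", {
  rep <- nemaReport(
    sensitivity_by_window = data.frame(window = c("none", "350-650"),
                                       sensitivity_pct = c(14.2, 7.6)),
    scatter_fraction = list(rat = 17.2, head = 54.1),
    note = "desk-scale run")
  f <- tempfile(fileext = ".yaml")
  writeNemaReport(rep, f)
  back <- readNemaReport(f)
  expect_equal(reportFields(back)$sensitivity_by_window,
               reportFields(rep)$sensitivity_by_window)
  expect_equal(reportFields(back)$scatter_fraction$head, 54.1)
  expect_equal(reportFields(back)$note, "desk-scale run")
})
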