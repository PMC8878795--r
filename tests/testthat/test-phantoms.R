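test_that("image-quality phantom encodes the hot/cold rod scheme", {
  ph <- makeIQPhantom(4, 5.3)
  pr <- primitives(ph)
  expect_equal(pr$d1[1], 135 / 2)
  expect_equal(pr$d2[1], 103)
  rods <- pr[-1, ]
  expect_equal(sort(rods$d1 * 2, decreasing = TRUE), c(20, 15, 12, 9, 6, 4.5))
  hot <- rods[rods$conc_kbq_ml > 0, ]
  expect_true(all(abs(hot$conc_kbq_ml - 21.2) < 1e-12))  # 4 x 5.3
  expect_equal(nrow(hot), 4L)
  expect_equal(rods$material[rods$d1 == 7.5], "air")
  # ratio 1: hot rods indistinguishable from background
  ph1 <- makeIQPhantom(1, 5.3)
  pr1 <- primitives(ph1)
  expect_true(all(pr1$conc_kbq_ml[pr1$conc_kbq_ml > 0] == 5.3))
  expect_error(makeIQPhantom(placementRadius = 10), "overlap")
})

test_that("voxelized activity converges to the analytic total", {
  ph <- newPhantom <- brainpetsim:::newPhantom(
    "cyl", primCylinder(c(0, 0, 0), 30, 40, "water", conc = 5.3))
  analytic <- totalActivity(ph)
  v1 <- voxelize(ph, voxelSize = 1)
  expect_equal(sum(as.array(v1$activity)), analytic, tolerance = 0.02)
  v2 <- voxelize(ph, voxelSize = 2)
  # refinement: halving the voxel changes the total by < 1%
  expect_lt(abs(sum(as.array(v1$activity)) - sum(as.array(v2$activity))) /
              sum(as.array(v1$activity)), 0.01)
})

test_that("material precedence: later primitives override earlier ones", {
  pr <- rbind(primCylinder(c(0, 0, 0), 20, 20, "water", conc = 10),
              primCylinder(c(0, 0, 0), 10, 20, "air", conc = 0))
  ph <- brainpetsim:::newPhantom("nested", pr)
  v <- voxelize(ph, voxelSize = 1)
  mu <- as.array(v$mu)
  act <- as.array(v$activity)
  ctr <- dim(mu) %/% 2 + 1L  # voxel at the center: inner air cylinder
  expect_equal(mu[ctr[1], ctr[2], ctr[3]], 0)
  expect_equal(act[ctr[1], ctr[2], ctr[3]], 0)
  # water shell voxel
  ix <- ctr + c(15L, 0L, 0L)
  expect_equal(mu[ix[1], ix[2], ix[3]], 0.0096)
  expect_equal(act[ix[1], ix[2], ix[3]], 10)  # 1 mm^3 voxel at 10 Bq/mm^3
  # analytic total respects the override
  expect_equal(totalActivity(ph), 10 * pi * (20^2 - 10^2) * 20,
               tolerance = 0.02)
})

test_that("sensitivity source preserves its total activity at any voxel size", {
  ph <- makeSensitivitySource()
  expect_equal(ph@isotope, "Na22")
  expect_equal(totalActivity(ph), 500e3)
  for (vs in c(0.5, 1, 2)) {
    v <- voxelize(ph, voxelSize = vs)
    expect_equal(sum(as.array(v$activity)), 500e3, tolerance = 1e-9)
  }
  # axial parameterization for the profile
  ph2 <- makeSensitivitySource(z = 82)
  expect_equal(primitives(ph2)$cz[2], 82)
})

test_that("scatter phantoms follow the NU4 and head-adapted dimensions", {
  rat <- makeScatterPhantom("rat")
  pr <- primitives(rat)
  expect_equal(pr$d1[1], 25)
  expect_equal(pr$d2[1], 150)
  expect_equal(pr$cx[2], 17.5)
  expect_equal(pr$material[1], "polyethylene")
  head <- makeScatterPhantom("head")
  prh <- primitives(head)
  expect_equal(prh$d1[1], 100)  # bounding radius, 20 cm diameter
  expect_equal(prh$cx[2], 45)
  # zero-activity line source -> nothing decays
  z <- makeScatterPhantom("rat", activity_mbq = 0)
  expect_equal(nrow(sampleDecays(z, 1, seed = 1)), 0L)
})

test_that("warm point-source phantom places the source plane correctly", {
  ph <- makeWarmPointSources()
  pr <- primitives(ph)
  expect_equal(pr$cx[-1], c(0, 5, 10, 15, 25, 50, 75, 100))
  q <- makeWarmPointSources(radialPositions = c(0, 25), axialPlane = "quarter")
  expect_equal(unique(primitives(q)$cz), 164 / 4)
  empty <- makeWarmPointSources(radialPositions = numeric(0))
  expect_equal(nrow(primitives(empty)), 1L)
  expect_error(makeWarmPointSources(radialPositions = 140), "130 mm")
})

test_that("derenzo phantom has six non-overlapping rod groups", {
  ph <- makeDerenzo()
  pr <- primitives(ph)
  rods <- pr[-1, ]
  expect_setequal(unique(rods$d1), c(1.8, 2.3, 2.8, 3.3, 3.8, 4.3))
  # brute-force pairwise overlap check
  n <- nrow(rods)
  xy <- cbind(rods$cx, rods$cy)
  dm <- as.matrix(dist(xy))
  rr <- outer(rods$d1, rods$d1, "+")
  diag(dm) <- Inf
  expect_true(all(dm >= rr - 1e-9))
  # all rods inside the phantom
  expect_true(all(sqrt(rods$cx^2 + rods$cy^2) + rods$d1 <= pr$d1[1]))
})

test_that("phantom YAML round trip is lossless", {
  ph <- makeIQPhantom()
  f <- tempfile(fileext = ".yaml")
  writePhantom(ph, f)
  ph2 <- readPhantom(f)
  expect_equal(primitives(ph2), primitives(ph), tolerance = 1e-12)
  expect_equal(ph2@isotope, ph@isotope)
})

test_that("clipping grids warn and report", {
  ph <- makeIQPhantom()
  expect_warning(voxelize(ph, voxelSize = 2, gridExtent = 50), "clip")
})
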