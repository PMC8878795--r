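# ---- primitive constructors -------------------------------------------------

primRow <- function(kind, center, d1, d2 = 0, d3 = 0, material = "water",
                    conc = 0, total = 0) {
  data.frame(kind = kind, cx = center[1], cy = center[2], cz = center[3],
             d1 = d1, d2 = d2, d3 = d3, material = material,
             conc_kbq_ml = conc, total_kbq = total)
}

#' Shape primitives for phantom construction
#'
#' Cylinders are axis-aligned with z.  Activity is given either as a
#' concentration (\code{conc}, kBq/ml) or as a total (\code{total}, kBq) for
#' point-like sources.
#'
#' @param center center, mm.
#' @param radius,height,side,widths dimensions, mm.
#' @param material one of \code{names(attenuationCoefficients())}.
#' @param conc activity concentration, kBq/ml.
#' @param total total activity, kBq (point-like sources).
#' @name primitives-constructors
NULL

#' @rdname primitives-constructors
#' @export
primCylinder <- function(center, radius, height, material = "water", conc = 0,
                         total = 0)
  primRow("cylinder", center, radius, height, 0, material, conc, total)

#' @rdname primitives-constructors
#' @export
primSphere <- function(center, radius, material = "water", conc = 0, total = 0)
  primRow("sphere", center, radius, 0, 0, material, conc, total)

#' @rdname primitives-constructors
#' @export
primBox <- function(center, widths, material = "water", conc = 0, total = 0)
  primRow("box", center, widths[1], widths[2], widths[3], material, conc, total)

#' @rdname primitives-constructors
#' @export
primPoint <- function(center, material = "water", total = 0)
  primRow("point", center, 0, 0, 0, material, 0, total)

primVolume <- function(pr) {
  switch(pr$kind,
         cylinder = pi * pr$d1^2 * pr$d2,
         sphere = 4 / 3 * pi * pr$d1^3,
         box = pr$d1 * pr$d2 * pr$d3,
         point = 0)
}

# raw activity (Bq) per primitive: 1 kBq/ml == 1 Bq/mm^3
primActivityBq <- function(pr) {
  vol <- vapply(seq_len(nrow(pr)), function(i) primVolume(pr[i, ]), 0)
  pr$conc_kbq_ml * vol + pr$total_kbq * 1000
}

newPhantom <- function(name, primitives, isotope = "F18") {
  rownames(primitives) <- NULL
  new("PhantomModel", name = name, primitives = primitives, isotope = isotope)
}

#' Total phantom activity
#'
#' Analytic total activity in Bq, accounting for primitive precedence (later
#' primitives override earlier ones where they overlap; only full containment
#' of the common phantom layouts is corrected analytically).
#' @param phantom a \code{PhantomModel}.
#' @return activity, Bq.
#' @export
totalActivity <- function(phantom) {
  pr <- phantom@primitives
  raw <- primActivityBq(pr)
  # subtract the overridden share of earlier volumetric primitives: Monte
  # Carlo estimate of the override fraction, exact for nested layouts
  if (nrow(pr) > 1) {
    for (i in seq_len(nrow(pr) - 1)) {
      if (raw[i] <= 0) next
      pts <- samplePrimitive(pr[i, ], 4000L, rng_seed = 7L)
      inside <- rep(FALSE, nrow(pts))
      for (j in seq((i + 1), nrow(pr)))
        inside <- inside | containsPoint(pr[j, ], pts)
      raw[i] <- raw[i] * (1 - mean(inside))
    }
  }
  sum(raw)
}

containsPoint <- function(pr, pts) {
  dx <- pts[, 1] - pr$cx
  dy <- pts[, 2] - pr$cy
  dz <- pts[, 3] - pr$cz
  switch(pr$kind,
         cylinder = dx^2 + dy^2 <= pr$d1^2 & abs(dz) <= pr$d2 / 2,
         sphere = dx^2 + dy^2 + dz^2 <= pr$d1^2,
         box = abs(dx) <= pr$d1 / 2 & abs(dy) <= pr$d2 / 2 & abs(dz) <= pr$d3 / 2,
         point = rep(FALSE, nrow(pts)))
}

samplePrimitive <- function(pr, n, rng_seed = NULL) {
  if (!is.null(rng_seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(rng_seed)
  }
  switch(pr$kind,
         cylinder = {
           r <- pr$d1 * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
           cbind(pr$cx + r * cos(a), pr$cy + r * sin(a),
                 pr$cz + runif(n, -0.5, 0.5) * pr$d2)
         },
         sphere = {
           z <- runif(n, -1, 1); a <- runif(n, 0, 2 * pi)
           rr <- sqrt(pmax(0, 1 - z^2)); r <- pr$d1 * runif(n)^(1 / 3)
           cbind(pr$cx + r * rr * cos(a), pr$cy + r * rr * sin(a), pr$cz + r * z)
         },
         box = cbind(pr$cx + runif(n, -0.5, 0.5) * pr$d1,
                     pr$cy + runif(n, -0.5, 0.5) * pr$d2,
                     pr$cz + runif(n, -0.5, 0.5) * pr$d3),
         point = matrix(rep(c(pr$cx, pr$cy, pr$cz), each = n), n, 3))
}

# ---- phantom factories ------------------------------------------------------

#' Image-quality rod phantom
#'
#' Head-sized adaptation of the NU4 image-quality phantom: a water cylinder
#' 135 mm in diameter and 103 mm high.  Its upper half carries six 50 mm long
#' rods of diameter 20, 15, 12, 9, 6 and 4.5 mm placed on a circle; the lower
#' half is the uniform region.  The two largest rods are cold (20 mm:
#' non-radioactive water, 15 mm: air); the remaining four are hot at
#' \code{rodBackgroundRatio} times the background concentration.
#'
#' @param rodBackgroundRatio rod-to-background activity concentration ratio.
#' @param backgroundConc background concentration, kBq/ml.
#' @param placementRadius radius of the rod placement circle, mm.
#' @return a \code{PhantomModel}.
#' @examples
#' iq <- makeIQPhantom(4, 5.3)
#' @export
makeIQPhantom <- function(rodBackgroundRatio = 4, backgroundConc = 5.3,
                          placementRadius = 36) {
  stopifnot(rodBackgroundRatio > 0, backgroundConc >= 0)
  geomIQ <- iqRodLayout(placementRadius)
  # adjacent rods must not touch
  for (i in 1:5) {
    d <- sqrt(sum((geomIQ$center[i, 1:2] - geomIQ$center[i + 1, 1:2])^2))
    if (d < (geomIQ$diameter[i] + geomIQ$diameter[i + 1]) / 2)
      stop("rod placement radius too small: rods overlap")
  }
  pr <- primCylinder(c(0, 0, 0), 135 / 2, 103, "water", conc = backgroundConc)
  for (i in seq_len(6)) {
    conc <- if (geomIQ$role[i] == "hot") rodBackgroundRatio * backgroundConc else 0
    mat <- if (geomIQ$role[i] == "cold_air") "air" else "water"
    pr <- rbind(pr, primCylinder(geomIQ$center[i, ], geomIQ$diameter[i] / 2, 50,
                                 mat, conc = conc))
  }
  newPhantom("image_quality", pr, "F18")
}

# rod layout shared with the analysis side: diameters, roles, centers
iqRodLayout <- function(placementRadius = 36) {
  diameter <- c(20, 15, 12, 9, 6, 4.5)
  role <- c("cold_water", "cold_air", "hot", "hot", "hot", "hot")
  ang <- (0:5) * pi / 3
  center <- cbind(placementRadius * cos(ang), placementRadius * sin(ang),
                  rep(26.5, 6))  # rods span z in [1.5, 51.5] (upper half)
  list(diameter = diameter, role = role, center = center,
       zRange = c(1.5, 51.5), uniformZ = c(-35, -25))
}

#' Derenzo hot-rod phantom
#'
#' Six 60-degree wedges of rods on a triangular lattice; within a wedge the
#' center-to-center spacing is twice the rod diameter.  Default rod radii run
#' from 1.8 to 4.3 mm in 0.5 mm steps.
#'
#' @param rodRadii rod radii per group, mm.
#' @param activity rod activity concentration, kBq/ml.
#' @param diameter phantom diameter, mm.
#' @param height rod/phantom height, mm.
#' @return a \code{PhantomModel}.
#' @export
makeDerenzo <- function(rodRadii = c(1.8, 2.3, 2.8, 3.3, 3.8, 4.3),
                        activity = 5.3, diameter = 120, height = 40) {
  stopifnot(all(rodRadii > 0))
  pr <- primCylinder(c(0, 0, 0), diameter / 2, height, "water", conc = 0)
  rmax <- diameter / 2
  for (g in seq_along(rodRadii)) {
    r <- rodRadii[g]
    s <- 4 * r  # center-to-center = 2 x rod diameter
    phi <- (g - 1) * pi / 3 + pi / 6
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    r0 <- 10
    nrow_max <- floor((rmax - r0 - 2 * r) / (s * sqrt(3) / 2))
    for (i in 0:nrow_max) {
      yv <- r0 + i * s * sqrt(3) / 2
      xs <- (seq_len(i + 1) - 1 - i / 2) * s
      for (x in xs) {
        # keep the rod fully inside the wedge and the phantom
        if (sqrt(x^2 + yv^2) + r > rmax - 1) next
        if (abs(atan2(x, yv)) > pi / 6 - asin(min(1, r / max(yv, 1)))) next
        p <- rot %*% c(x, yv)
        pr <- rbind(pr, primCylinder(c(p[1], p[2], 0), r, height, "water",
                                     conc = activity))
      }
    }
  }
  if (nrow(pr) < 2) stop("no rods fit inside the phantom")
  newPhantom("derenzo", pr, "F18")
}

#' Point source for sensitivity measurements
#'
#' A 0.1 mm radius Na-22 sphere embedded in a 10 mm acrylic cube, 500 kBq by
#' default (low enough that dead-time losses are negligible).  The source can
#' be stepped along z for the axial sensitivity profile.
#'
#' @param z axial source position, mm.
#' @param activity_kbq total source activity, kBq.
#' @return a \code{PhantomModel} (isotope Na22).
#' @export
makeSensitivitySource <- function(z = 0, activity_kbq = 500) {
  pr <- rbind(primBox(c(0, 0, z), c(10, 10, 10), "acrylic"),
              primSphere(c(0, 0, z), 0.1, "water", total = activity_kbq))
  newPhantom("sensitivity_source", pr, "Na22")
}

#' Scatter phantoms for NECR and scatter-fraction measurements
#'
#' \code{"rat"}: the NU4-2008 rat-like phantom, a polyethylene cylinder 50 mm
#' in diameter and 150 mm long with a line source threaded parallel to the
#' axis at a 17.5 mm radial offset.  \code{"head"}: a polyethylene cylinder
#' 200 mm in diameter and 150 mm high with the line source at a 45 mm radial
#' offset.  The line source is a thin water-filled cylinder (1.6 mm radius)
#' spanning the phantom length.
#'
#' @param kind "rat" or "head".
#' @param activity_mbq total line-source activity, MBq.
#' @return a \code{PhantomModel} (isotope F18).
#' @export
makeScatterPhantom <- function(kind = c("rat", "head"), activity_mbq = 1) {
  kind <- match.arg(kind)
  if (kind == "rat") {
    body <- primCylinder(c(0, 0, 0), 25, 150, "polyethylene")
    line <- primCylinder(c(17.5, 0, 0), 1.6, 150, "water",
                         total = activity_mbq * 1000)
  } else {
    body <- primCylinder(c(0, 0, 0), 100, 150, "polyethylene")
    line <- primCylinder(c(45, 0, 0), 1.6, 150, "water",
                         total = activity_mbq * 1000)
  }
  newPhantom(paste0("scatter_", kind), rbind(body, line), "F18")
}

#' Point sources in a warm background
#'
#' Point-like spheres at the requested radial positions embedded in a uniform
#' warm water cylinder, for spatial-resolution measurements with a nonneg
#' iterative reconstruction (a cold background would underestimate the FWHM).
#' The source plane is either the axial center or the plane at 1/4 of the
#' axial FOV.
#'
#' @param radialPositions radii along +x, mm (default the standard series).
#' @param axialPlane "center" (z = 0) or "quarter" (z = AFOV/4).
#' @param backgroundConc warm background concentration, kBq/ml.
#' @param pointActivity_kbq activity per point source, kBq.
#' @param backgroundDiameter,backgroundHeight warm cylinder size, mm.
#' @param afov axial field of view used to place the quarter plane, mm.
#' @return a \code{PhantomModel}.
#' @export
makeWarmPointSources <- function(radialPositions = c(0, 5, 10, 15, 25, 50, 75, 100),
                                 axialPlane = c("center", "quarter"),
                                 backgroundConc = 5.3,
                                 pointActivity_kbq = 20,
                                 backgroundDiameter = 212,
                                 backgroundHeight = 40, afov = 164) {
  axialPlane <- match.arg(axialPlane)
  if (any(radialPositions > 130))
    stop("source position beyond 130 mm radius")
  if (any(radialPositions > backgroundDiameter / 2 - 4))
    stop("source outside the warm background cylinder")
  z <- if (axialPlane == "quarter") afov / 4 else 0
  pr <- primCylinder(c(0, 0, z), backgroundDiameter / 2, backgroundHeight,
                     "water", conc = backgroundConc)
  for (r in radialPositions)
    pr <- rbind(pr, primSphere(c(r, 0, z), 0.25, "water",
                               total = pointActivity_kbq))
  newPhantom("warm_points", pr, "F18")
}

# ---- voxelization -----------------------------------------------------------

#' Voxelize a phantom
#'
#' Paints the primitives (in order, later overriding earlier) onto co-registered
#' activity and attenuation grids.  Volumetric activity is converted to Bq per
#' voxel by center sampling; point-like primitives (points, spheres smaller
#' than a voxel) deposit their total activity into the containing voxel so the
#' integral is preserved at any resolution.
#'
#' @param phantom a \code{PhantomModel}.
#' @param voxelSize isotropic voxel size, mm.
#' @param gridExtent extent (mm, scalar or length 3) of the grid, centered on
#'   the phantom bounding box; default covers the phantom with a margin.
#' @param attenuation material table, mm^-1 at 511 keV.
#' @return list with \code{activity} (Bq/voxel) and \code{mu} (mm^-1)
#'   \code{ImageVolume}s, plus a \code{clipped} report.
#' @export
voxelize <- function(phantom, voxelSize = 1, gridExtent = NULL,
                     attenuation = attenuationCoefficients()) {
  stopifnot(voxelSize > 0)
  pr <- phantom@primitives
  bb <- phantomBoundingBox(pr)
  ctr <- (bb$lo + bb$hi) / 2
  fullExtent <- bb$hi - bb$lo + 2 * voxelSize
  if (is.null(gridExtent)) gridExtent <- fullExtent
  gridExtent <- rep(gridExtent, length.out = 3)
  clipped <- any(gridExtent < fullExtent - 2 * voxelSize + 1e-9)
  if (clipped)
    warning("grid does not cover the phantom; activity outside is clipped")
  n <- pmax(1L, as.integer(ceiling(gridExtent / voxelSize)))
  origin <- ctr - n * voxelSize / 2
  xs <- origin[1] + (seq_len(n[1]) - 0.5) * voxelSize
  ys <- origin[2] + (seq_len(n[2]) - 0.5) * voxelSize
  zs <- origin[3] + (seq_len(n[3]) - 0.5) * voxelSize
  act <- array(0, n)
  mu <- array(attenuation["air"], n)
  vvol <- voxelSize^3
  X <- array(rep(xs, times = n[2] * n[3]), n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
  Z <- array(rep(zs, each = n[1] * n[2]), n)
  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    pointLike <- p$kind == "point" || (p$kind == "sphere" && p$d1 < voxelSize)
    if (pointLike) {
      ix <- pmin(pmax(1L, as.integer(floor((c(p$cx, p$cy, p$cz) - origin) /
                                             voxelSize)) + 1L), n)
      act[ix[1], ix[2], ix[3]] <- act[ix[1], ix[2], ix[3]] + p$total_kbq * 1000
      next
    }
    # fractional occupancy from a 2x2x2 subsample: partial-volume blending at
    # primitive boundaries keeps the voxelized total activity first-order
    # accurate in the voxel size
    occ <- array(0, n)
    q <- voxelSize / 4
    for (dx in c(-q, q)) for (dy in c(-q, q)) for (dz in c(-q, q))
      occ <- occ + containsPoint(p, cbind(as.vector(X) + dx,
                                          as.vector(Y) + dy,
                                          as.vector(Z) + dz))
    occ <- occ / 8
    m <- occ > 0
    mu[m] <- attenuation[[p$material]] * occ[m] + mu[m] * (1 - occ[m])
    a <- p$conc_kbq_ml * vvol
    if (p$total_kbq > 0) a <- a + p$total_kbq * 1000 / max(1, sum(occ))
    act[m] <- a * occ[m] + act[m] * (1 - occ[m])
  }
  list(activity = new("ImageVolume", data = act, voxelSize = voxelSize,
                      origin = origin),
       mu = new("ImageVolume", data = mu, voxelSize = voxelSize,
                origin = origin),
       clipped = clipped)
}

phantomBoundingBox <- function(pr) {
  lo <- c(Inf, Inf, Inf)
  hi <- -lo
  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    half <- switch(p$kind,
                   cylinder = c(p$d1, p$d1, p$d2 / 2),
                   sphere = rep(p$d1, 3),
                   box = c(p$d1, p$d2, p$d3) / 2,
                   point = rep(0.5, 3))
    lo <- pmin(lo, c(p$cx, p$cy, p$cz) - half)
    hi <- pmax(hi, c(p$cx, p$cy, p$cz) + half)
  }
  list(lo = lo, hi = hi)
}
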