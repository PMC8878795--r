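#' Build the crystal-level scanner geometry
#'
#' Constructs the full-ring detector model: \code{nSectors} flat sectors on a
#' regular polygon around the z axis, each carrying \code{modulesPerSector}
#' square modules of 2x2 tiles.  Every tile holds two stacked crystal layers
#' sharing one pitch: a thin "top" layer (facing the field of view) whose grid
#' is one crystal smaller per side and staggered by half a pitch against the
#' thick "bottom" layer behind it.  The two discrete layers encode depth of
#' interaction.
#'
#' The default configuration is the TRIMAGE-type brain ring: 18 sectors, 3
#' modules, 7x7 top crystals of 3.3x3.3x8 mm and 8x8 bottom crystals of
#' 3.3x3.3x12 mm at 3.4 mm pitch, AFOV 164 mm and TFOV 260 mm, giving
#' 216 tiles x 113 crystals = 24,408 crystals.
#'
#' The inner radius (apothem of the sector polygon) is derived so the sector
#' faces close tightly: \code{(sectorWidth + sectorGap) / 2 / tan(pi/nSectors)};
#' it can be overridden.
#'
#' @param nSectors sectors around the ring.
#' @param modulesPerSector square modules along z per sector.
#' @param topGrid,bottomGrid crystals per tile side in each layer.
#' @param topThickness,bottomThickness layer thicknesses, mm.
#' @param pitch crystal pitch, mm (both layers).
#' @param afov,tfov axial / transaxial field of view, mm.
#' @param innerRadius optional override of the derived apothem, mm.
#' @param sectorGap physical gap between adjacent sector faces, mm.
#' @return a \code{\link{ScannerGeometry-class}} object.
#' @examples
#' g <- buildGeometry()
#' numCrystals(g)  # 24408
#' @export
buildGeometry <- function(nSectors = 18L, modulesPerSector = 3L,
                          topGrid = 7L, bottomGrid = 8L,
                          topThickness = 8, bottomThickness = 12,
                          pitch = 3.4, afov = 164, tfov = 260,
                          innerRadius = NULL, sectorGap = 0) {
  if (nSectors < 3 || modulesPerSector < 1 || topGrid < 1 || bottomGrid < 1)
    stop("geometry counts must be positive (nSectors >= 3)")
  if (pitch <= 0 || topThickness <= 0 || bottomThickness <= 0)
    stop("geometry lengths must be positive")
  tileWidth <- bottomGrid * pitch
  topMargin <- (tileWidth - topGrid * pitch) / 2
  if (topMargin < -1e-9)
    stop("inconsistent tiling: top grid does not fit the tile width")
  sectorWidth <- 2 * tileWidth
  if (is.null(innerRadius))
    innerRadius <- (sectorWidth + sectorGap) / 2 / tan(pi / nSectors)
  params <- list(nSectors = as.integer(nSectors),
                 modulesPerSector = as.integer(modulesPerSector),
                 topGrid = as.integer(topGrid),
                 bottomGrid = as.integer(bottomGrid),
                 topThickness = topThickness,
                 bottomThickness = bottomThickness,
                 pitch = pitch, tileWidth = tileWidth, topMargin = topMargin,
                 staggerOffset = topMargin,  # half-pitch when topGrid = bottomGrid - 1
                 afov = afov, tfov = tfov, innerRadius = innerRadius,
                 sectorGap = sectorGap)

  perTile <- topGrid^2 + bottomGrid^2
  nTiles <- nSectors * modulesPerSector * 4L
  n <- nTiles * perTile
  id <- 0:(n - 1)
  off <- id %% perTile
  t1 <- id %/% perTile
  tile <- t1 %% 4L
  t2 <- t1 %/% 4L
  module <- t2 %% modulesPerSector
  sector <- t2 %/% modulesPerSector
  top <- off < topGrid^2
  row <- ifelse(top, off %/% topGrid, (off - topGrid^2) %/% bottomGrid)
  col <- ifelse(top, off %% topGrid, (off - topGrid^2) %% bottomGrid)

  centers <- cpp_crystal_centers(geomParamVector(params))
  crystals <- data.frame(flat_id = id, sector = sector, module = module,
                         tile = tile,
                         layer = ifelse(top, "top", "bottom"),
                         row = row, col = col,
                         x = centers[, 1], y = centers[, 2], z = centers[, 3])
  new("ScannerGeometry", params = params, crystals = crystals)
}

# parameter vector consumed by the C++ Scanner struct
geomParamVector <- function(p) {
  if (is(p, "ScannerGeometry")) p <- p@params
  c(nsec = p$nSectors,
    R = p$innerRadius,
    halfW = p$tileWidth,                       # 2 tiles transaxial / 2
    halfH = p$modulesPerSector * 2 * p$tileWidth / 2,
    tTop = p$topThickness,
    tBot = p$bottomThickness,
    pitch = p$pitch,
    tileW = p$tileWidth,
    topMargin = p$topMargin,
    topN = p$topGrid,
    botN = p$bottomGrid,
    modAx = p$modulesPerSector,
    tilesAxPerMod = 2,
    tilesTrans = 2)
}

#' Crystal center coordinates
#'
#' @param geom a \code{ScannerGeometry}.
#' @param ids 0-based flat crystal ids.
#' @return matrix with columns x, y, z (mm).
#' @export
crystalCenter <- function(geom, ids) {
  ct <- geom@crystals
  if (any(ids < 0 | ids >= nrow(ct))) stop("crystal id out of range")
  as.matrix(ct[ids + 1L, c("x", "y", "z")])
}

#' Minimal circular sector difference between two crystals
#' @param geom a \code{ScannerGeometry}.
#' @param a,b 0-based flat crystal ids.
#' @export
sectorDifference <- function(geom, a, b) {
  ns <- geom@params$nSectors
  sa <- geom@crystals$sector[a + 1L]
  sb <- geom@crystals$sector[b + 1L]
  d <- abs(sa - sb)
  pmin(d, ns - d)
}

#' Enumerate lines of response
#'
#' Emits every unordered crystal pair with at least \code{minSectorDifference}
#' sectors between the two crystals, in canonical order
#' (\code{id_a < id_b}).  Intended for toy geometries and normalization
#' studies; the full default ring has ~3e8 pairs and is refused.
#'
#' @param geom a \code{ScannerGeometry}.
#' @param minSectorDifference minimal circular sector separation (0..nSectors/2).
#' @param maxPairs safety limit on the number of emitted pairs.
#' @return data.frame with \code{id_a}, \code{id_b}.
#' @export
enumerateLORs <- function(geom, minSectorDifference = 0L, maxPairs = 5e6) {
  ns <- geom@params$nSectors
  if (minSectorDifference < 0 || minSectorDifference > ns %/% 2)
    stop("minSectorDifference out of range")
  n <- numCrystals(geom)
  if (n * (n - 1) / 2 > maxPairs)
    stop("too many crystal pairs to enumerate; use a toy geometry or sampling")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- idx[, 1] - 1L
  b <- idx[, 2] - 1L
  keep <- sectorDifference(geom, a, b) >= minSectorDifference
  data.frame(id_a = a[keep], id_b = b[keep])
}

#' LOR endpoint matrix
#'
#' Endpoints are the geometric centers of the two crystals (depth of
#' interaction enters through the layer identity of each crystal).
#'
#' @param geom a \code{ScannerGeometry}.
#' @param idA,idB 0-based flat crystal ids (canonical order not required).
#' @return n x 6 matrix (xa, ya, za, xb, yb, zb), mm.
#' @export
lorEndpoints <- function(geom, idA, idB) {
  cbind(crystalCenter(geom, idA), crystalCenter(geom, idB))
}

#' Deterministic hash of a geometry configuration
#'
#' Used to stamp list-mode files so events are never rebinned against the
#' wrong crystal map.
#' @param geom a \code{ScannerGeometry}.
#' @return a numeric scalar hash.
#' @export
geometryHash <- function(geom) {
  v <- as.numeric(geomParamVector(geom))
  h <- 0
  for (x in v) h <- (h * 31 + sum(as.integer(charToRaw(format(x, digits = 12))))) %% 2147483647
  h
}
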