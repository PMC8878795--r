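#' @import methods
NULL

#' Crystal-level scanner model
#'
#' An S4 container for the full detector ring: the configuration parameters
#' (sector count, layer grids, pitches, fields of view) plus the derived
#' per-crystal table with 3D positions and layer identity.  Built by
#' \code{\link{buildGeometry}}.
#'
#' @slot params named list of configuration parameters (all lengths in mm).
#' @slot crystals data.frame with one row per crystal: \code{flat_id} (0-based
#'   unique id), \code{sector}, \code{module}, \code{tile}, \code{layer}
#'   ("top"/"bottom"), \code{row}, \code{col}, and the center coordinates
#'   \code{x}, \code{y}, \code{z}.
#' @export
setClass("ScannerGeometry",
         representation(params = "list", crystals = "data.frame"))

setValidity("ScannerGeometry", function(object) {
  p <- object@params
  msgs <- character(0)
  need <- c("nSectors", "modulesPerSector", "topGrid", "bottomGrid", "pitch",
            "topThickness", "bottomThickness", "afov", "tfov", "innerRadius")
  miss <- setdiff(need, names(p))
  if (length(miss)) msgs <- c(msgs, paste("missing params:", paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    nExpect <- p$nSectors * p$modulesPerSector * 4L *
      (p$topGrid^2 + p$bottomGrid^2)
    if (nrow(object@crystals) != nExpect)
      msgs <- c(msgs, sprintf("crystal table has %d rows, expected %d",
                              nrow(object@crystals), nExpect))
    ax <- p$modulesPerSector * 2 * p$bottomGrid * p$pitch
    if (ax > p$afov + 1e-6)
      msgs <- c(msgs, "axial crystal stack exceeds the AFOV")
    r <- sqrt(object@crystals$x^2 + object@crystals$y^2)
    if (any(r < p$innerRadius - 1e-9))
      msgs <- c(msgs, "crystal centers inside the inner radius")
  }
  if (length(msgs)) msgs else TRUE
})

#' Analytic phantom model
#'
#' An ordered list of shape primitives (later primitives override earlier ones
#' where they overlap) together with the positron-emitting isotope.  Activity
#' is carried either as a concentration (kBq/ml) for volumetric primitives or
#' as a total (kBq) for point-like sources.
#'
#' @slot name label of the phantom.
#' @slot primitives data.frame: \code{kind} ("cylinder", "sphere", "box",
#'   "point"), center \code{cx,cy,cz} (mm), dimensions \code{d1,d2,d3} (mm;
#'   radius/height for cylinders, radius for spheres, full widths for boxes),
#'   \code{material}, \code{conc_kbq_ml}, \code{total_kbq}.
#' @slot isotope "F18" or "Na22".
#' @export
setClass("PhantomModel",
         representation(name = "character", primitives = "data.frame",
                        isotope = "character"))

setValidity("PhantomModel", function(object) {
  pr <- object@primitives
  msgs <- character(0)
  if (!all(pr$kind %in% c("cylinder", "sphere", "box", "point")))
    msgs <- c(msgs, "unknown primitive kind")
  if (!all(pr$material %in% names(attenuationCoefficients())))
    msgs <- c(msgs, "unknown material")
  if (any(pr$d1 < 0, na.rm = TRUE)) msgs <- c(msgs, "negative dimension")
  if (any(pr$conc_kbq_ml < 0, na.rm = TRUE) || any(pr$total_kbq < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative activity")
  if (!object@isotope %in% c("F18", "Na22"))
    msgs <- c(msgs, "isotope must be F18 or Na22")
  if (length(msgs)) msgs else TRUE
})

#' Voxelized 3D volume
#'
#' A dense 3D grid with isotropic voxels on a millimetre world frame;
#' \code{origin} is the low corner of voxel \code{[1,1,1]}.
#'
#' @slot data 3D numeric array.
#' @slot voxelSize voxel edge length, mm.
#' @slot origin low corner of the grid, mm.
#' @export
setClass("ImageVolume",
         representation(data = "array", voxelSize = "numeric",
                        origin = "numeric"))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@data)) != 3) return("data must be a 3D array")
  if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
    return("voxelSize must be a positive scalar")
  if (length(object@origin) != 3) return("origin must have length 3")
  TRUE
})

#' Singles stream from a simulated acquisition
#'
#' Time-ordered detector singles with ground-truth labels: crystal id, blurred
#' deposited energy, timestamp, originating decay id and a phantom-scatter
#' flag.
#'
#' @slot singles data.frame of singles (see \code{\link{simulateAcquisition}}).
#' @slot nDecays number of positron emissions simulated.
#' @slot duration acquisition time, s.
#' @slot seed RNG seed used.
#' @export
setClass("SinglesStream",
         representation(singles = "data.frame", nDecays = "numeric",
                        duration = "numeric", seed = "numeric"))

#' Figure-of-merit report
#'
#' Structured container for the NEMA-adapted figures of merit (sensitivity,
#' resolution, uniformity, recovery, spill-over, count rates) with the VOI
#' definitions used.  Serializable to YAML via \code{\link{writeNemaReport}}.
#'
#' @slot report named list of result tables/values.
#' @export
setClass("NemaReport", representation(report = "list"))

#' End-to-end experiment specification
#'
#' @slot name one of "sensitivity", "resolution", "image_quality", "necr".
#' @slot phantom the PhantomModel (or list of them).
#' @slot physics,acquisition,recon configuration lists.
#' @slot duration acquisition time, s (already scaled).
#' @slot activities activity schedule, MBq (count-rate experiments).
#' @slot seed integer seed.
#' @slot scale fraction of full-scale counts.
#' @slot provenance data.frame tracing every parameter to a reported value or
#'   a documented package default.
#' @export
setClass("ExperimentSpec",
         representation(name = "character", phantom = "ANY", physics = "ANY",
                        acquisition = "ANY", recon = "ANY",
                        duration = "numeric", activities = "numeric",
                        seed = "numeric", scale = "numeric",
                        provenance = "data.frame"))

# ---- accessors --------------------------------------------------------------

#' @rdname ScannerGeometry-class
#' @param object,x a \code{ScannerGeometry}
#' @export
setGeneric("crystalTable", function(object) standardGeneric("crystalTable"))
#' @rdname ScannerGeometry-class
#' @export
setMethod("crystalTable", "ScannerGeometry", function(object) object@crystals)

#' @rdname ScannerGeometry-class
#' @export
setGeneric("numCrystals", function(object) standardGeneric("numCrystals"))
#' @rdname ScannerGeometry-class
#' @export
setMethod("numCrystals", "ScannerGeometry",
          function(object) nrow(object@crystals))

#' @rdname ScannerGeometry-class
#' @export
setGeneric("innerRadius", function(object) standardGeneric("innerRadius"))
#' @rdname ScannerGeometry-class
#' @export
setMethod("innerRadius", "ScannerGeometry",
          function(object) object@params$innerRadius)

#' @rdname PhantomModel-class
#' @param object a \code{PhantomModel}
#' @export
setGeneric("primitives", function(object) standardGeneric("primitives"))
#' @rdname PhantomModel-class
#' @export
setMethod("primitives", "PhantomModel", function(object) object@primitives)

#' @rdname ImageVolume-class
#' @param object an \code{ImageVolume}
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname ImageVolume-class
#' @export
setMethod("voxelSize", "ImageVolume", function(object) object@voxelSize)

#' @rdname ImageVolume-class
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))
#' @rdname ImageVolume-class
#' @export
setMethod("gridOrigin", "ImageVolume", function(object) object@origin)

#' @rdname SinglesStream-class
#' @param object a \code{SinglesStream}
#' @export
setGeneric("singles", function(object) standardGeneric("singles"))
#' @rdname SinglesStream-class
#' @export
setMethod("singles", "SinglesStream", function(object) object@singles)

#' @rdname SinglesStream-class
#' @export
setGeneric("numDecays", function(object) standardGeneric("numDecays"))
#' @rdname SinglesStream-class
#' @export
setMethod("numDecays", "SinglesStream", function(object) object@nDecays)

#' @rdname NemaReport-class
#' @param object a \code{NemaReport}
#' @export
setGeneric("reportFields", function(object) standardGeneric("reportFields"))
#' @rdname NemaReport-class
#' @export
setMethod("reportFields", "NemaReport", function(object) object@report)

#' Extract the data array of an ImageVolume
#' @param x an \code{ImageVolume}
#' @param ... ignored
#' @export
setMethod("as.array", "ImageVolume", function(x, ...) x@data)

#' @rdname ImageVolume-class
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

# ---- show methods -----------------------------------------------------------

setMethod("show", "ScannerGeometry", function(object) {
  p <- object@params
  cat(sprintf("ScannerGeometry: %d sectors x %d modules x 4 tiles = %d crystals\n",
              p$nSectors, p$modulesPerSector, numCrystals(object)))
  cat(sprintf("  layers: top %dx%d (%.1f mm), bottom %dx%d (%.1f mm), pitch %.1f mm\n",
              p$topGrid, p$topGrid, p$topThickness, p$bottomGrid, p$bottomGrid,
              p$bottomThickness, p$pitch))
  cat(sprintf("  inner radius %.1f mm, AFOV %.0f mm, TFOV %.0f mm\n",
              p$innerRadius, p$afov, p$tfov))
})

setMethod("show", "PhantomModel", function(object) {
  cat(sprintf("PhantomModel '%s' (%s): %d primitives, total activity %.1f kBq\n",
              object@name, object@isotope, nrow(object@primitives),
              totalActivity(object) / 1000))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %dx%dx%d, voxel %.2f mm, origin (%.1f, %.1f, %.1f) mm\n",
              d[1], d[2], d[3], object@voxelSize, object@origin[1],
              object@origin[2], object@origin[3]))
})

setMethod("show", "SinglesStream", function(object) {
  cat(sprintf("SinglesStream: %d singles from %.0f decays over %.3g s\n",
              nrow(object@singles), object@nDecays, object@duration))
})

setMethod("show", "NemaReport", function(object) {
  cat("NemaReport with fields:", paste(names(object@report), collapse = ", "), "\n")
})

setMethod("show", "ExperimentSpec", function(object) {
  cat(sprintf("ExperimentSpec '%s': duration %.3g s, scale %.3g, seed %d\n",
              object@name, object@duration, object@scale, object@seed))
})
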