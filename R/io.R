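# Structured-text interchange: YAML for configurations and phantoms, NIfTI
# for volumes, CSV for tables.

#' Write / read a phantom definition as YAML
#' @param phantom a \code{PhantomModel}.
#' @param path file path.
#' @export
writePhantom <- function(phantom, path) {
  yaml::write_yaml(list(name = phantom@name, isotope = phantom@isotope,
                        units = list(length = "mm", concentration = "kBq/ml",
                                     total = "kBq"),
                        primitives = as.list(phantom@primitives)),
                   path, precision = 15)
  invisible(path)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(path) {
  y <- yaml::read_yaml(path)
  newPhantom(y$name, as.data.frame(y$primitives, stringsAsFactors = FALSE),
             y$isotope)
}

#' Write / read a scanner geometry configuration as YAML
#' @param geom a \code{ScannerGeometry}.
#' @param path file path.
#' @export
writeGeometryConfig <- function(geom, path) {
  yaml::write_yaml(c(list(units = "mm"), geom@params), path, precision = 15)
  invisible(path)
}

#' @rdname writeGeometryConfig
#' @export
readGeometryConfig <- function(path) {
  p <- yaml::read_yaml(path)
  buildGeometry(nSectors = p$nSectors, modulesPerSector = p$modulesPerSector,
                topGrid = p$topGrid, bottomGrid = p$bottomGrid,
                topThickness = p$topThickness,
                bottomThickness = p$bottomThickness, pitch = p$pitch,
                afov = p$afov, tfov = p$tfov, innerRadius = p$innerRadius,
                sectorGap = p$sectorGap)
}

#' Export the crystal table as CSV
#' @param geom a \code{ScannerGeometry}.
#' @param path file path.
#' @export
exportCrystalTable <- function(geom, path) {
  data.table::fwrite(geom@crystals, path)
  invisible(path)
}

#' Write an ImageVolume as NIfTI
#'
#' The affine encodes the mm grid (origin at the center of voxel [1,1,1]).
#' @param vol an \code{ImageVolume}.
#' @param path output path (".nii" or ".nii.gz").
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  vs <- vol@voxelSize
  org <- vol@origin + vs / 2
  aff <- rbind(cbind(diag(vs, 3), org), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vs <- aff[1, 1]
  org <- aff[1:3, 4] - vs / 2
  new("ImageVolume", data = array(as.numeric(img), dim(img)),
      voxelSize = vs, origin = as.numeric(org))
}

#' Export a count-rate table as CSV
#' @param rates data.frame from \code{\link{countRates}} rows.
#' @param path file path.
#' @export
writeCountRates <- function(rates, path) {
  data.table::fwrite(rates, path)
  invisible(path)
}

#' Export a singles stream as CSV
#' @param stream a \code{SinglesStream}.
#' @param path file path.
#' @export
writeSingles <- function(stream, path) {
  data.table::fwrite(singles(stream), path)
  invisible(path)
}
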