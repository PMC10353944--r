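#' @describeIn CalibrationCurve-class Construct a calibration curve from node
#'   vectors.
#' @param force,efficiency numeric vectors of calibration nodes.
#' @param id character identifier recorded in downstream force maps.
#' @return A \code{CalibrationCurve}.
#' @examples
#' cal <- CalibrationCurve(c(0, 5, 10), c(0.9, 0.5, 0.15))
#' calEfficiency(cal, 2.5)
#' @export
CalibrationCurve <- function(force, efficiency, id = "custom") {
  new("CalibrationCurve", force = as.numeric(force),
      efficiency = as.numeric(efficiency), id = as.character(id)[1L])
}

#' @rdname CalibrationCurve-class
#' @param object,x a \code{CalibrationCurve}.
#' @export
setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve '%s': %d nodes, force %.3g..%.3g pN, E %.3g..%.3g\n",
              object@id, length(object@force), min(object@force),
              max(object@force), max(object@efficiency),
              min(object@efficiency)))
})

#' @rdname CalibrationCurve-class
#' @export
calForces <- function(x) x@force

#' @rdname CalibrationCurve-class
#' @export
calEfficiencies <- function(x) x@efficiency

#' Evaluate a calibration curve at given forces
#'
#' Piecewise-linear interpolation of efficiency at force \code{f}; forces
#' outside the calibrated range clamp to the terminal node efficiencies.
#'
#' @param cal a [CalibrationCurve-class].
#' @param f numeric forces in pN.
#' @return numeric efficiencies.
#' @export
calEfficiency <- function(cal, f) {
  stopifnot(is(cal, "CalibrationCurve"))
  approx(cal@force, cal@efficiency, xout = f, rule = 2)$y
}

#' Synthetic default calibration used in examples and tests
#'
#' A six-node curve from 0 pN (E = 0.90) to 10 pN (E = 0.15).  It is a
#' synthetic stand-in with the qualitative shape of published sensor
#' calibrations (monotone decreasing), not a measured curve; quantitative
#' work must supply the calibration of the actual sensor construct via
#' [readCalibration()] or [CalibrationCurve()].
#'
#' @return A [CalibrationCurve-class].
#' @export
defaultCalibration <- function() {
  CalibrationCurve(force = c(0, 1, 2.5, 5, 7.5, 10),
                   efficiency = c(0.90, 0.82, 0.68, 0.47, 0.30, 0.15),
                   id = "synthetic-default")
}

## ---- PixelMap accessors -------------------------------------------------

#' @describeIn PixelMap-class matrix of per-pixel values.
#' @param x,object a \code{PixelMap}.
#' @export
mapData <- function(x) x@data

#' @describeIn PixelMap-class logical matrix of valid pixels.
#' @export
validMask <- function(x) x@valid

#' @describeIn PixelMap-class pixel edge length in micrometres.
#' @export
pixelSize <- function(x) x@pixelSize

#' @rdname PixelMap-class
#' @export
setMethod("show", "PixelMap", function(object) {
  v <- object@data[object@valid]
  cat(sprintf("%s: %d x %d px (%.3g um/px), %d valid (%.1f%%)",
              class(object), nrow(object@data), ncol(object@data),
              object@pixelSize, sum(object@valid),
              100 * mean(object@valid)))
  if (length(v))
    cat(sprintf(", range %.3g..%.3g", min(v), max(v)))
  cat("\n")
})

#' @rdname PixelMap-class
#' @export
setMethod("dim", "PixelMap", function(x) dim(x@data))

## ---- AdhesionSet accessors ----------------------------------------------

#' @describeIn AdhesionSet-class per-adhesion statistics table.
#' @param x,object an \code{AdhesionSet}.
#' @export
adhesionStats <- function(x) x@stats

#' @describeIn AdhesionSet-class integer label image (0 = background).
#' @export
labelMatrix <- function(x) x@labels

#' @rdname AdhesionSet-class
#' @export
setMethod("length", "AdhesionSet", function(x) nrow(x@stats))

#' @rdname AdhesionSet-class
#' @export
setMethod("show", "AdhesionSet", function(object) {
  cat(sprintf("AdhesionSet: %d adhesions over %d cell(s)\n",
              nrow(object@stats),
              length(unique(object@stats$cell_id))))
  if (nrow(object@stats))
    cat(sprintf("  area %.3g..%.3g um2, mean force %.3g..%.3g pN\n",
                min(object@stats$area_um2), max(object@stats$area_um2),
                min(object@stats$mean_force_pN),
                max(object@stats$mean_force_pN)))
})

## ---- SectionGeometry accessors ------------------------------------------

#' @describeIn SectionGeometry-class cell centroid/marker table.
#' @param x,object a \code{SectionGeometry}.
#' @export
sectionCells <- function(x) x@cells

#' @describeIn SectionGeometry-class ventricle-border polyline vertices.
#' @export
sectionBorder <- function(x) x@border

#' @describeIn SectionGeometry-class named list of region polygons.
#' @export
sectionRegions <- function(x) x@regions

#' @rdname SectionGeometry-class
#' @export
setMethod("show", "SectionGeometry", function(object) {
  cat(sprintf("SectionGeometry: %d cells, border with %d vertices, %d region(s)%s\n",
              nrow(object@cells), nrow(object@border),
              length(object@regions),
              if (length(object@regions))
                paste0(" (", paste(names(object@regions), collapse = ", "), ")")
              else ""))
})
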