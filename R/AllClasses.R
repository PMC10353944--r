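#' @import methods
#' @importFrom stats aggregate approx cor dhyper median na.omit pnorm
#'   quantile rbinom rnbinom rnorm rpois runif sd setNames
#' @importFrom utils head tail
NULL

#' Force-to-efficiency calibration curve of a molecular tension sensor
#'
#' Ordered \code{(force, efficiency)} node pairs describing how the FRET
#' efficiency of a tension sensor falls as the force across it rises.  Forces
#' must be strictly increasing from 0 and efficiencies strictly decreasing:
#' higher force always means lower FRET efficiency.  Between nodes the curve
#' is evaluated by piecewise-linear interpolation.
#'
#' @slot force numeric, strictly increasing forces in pN, starting at 0.
#' @slot efficiency numeric, strictly decreasing FRET efficiencies in (0, 1].
#' @slot id character scalar identifying the calibration (e.g. file name).
#'
#' @seealso [CalibrationCurve()], [calEfficiency()], [forceFromEfficiency()]
#' @export
setClass("CalibrationCurve",
  representation(force = "numeric", efficiency = "numeric", id = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@force) < 2L)
      msg <- c(msg, "calibration needs at least 2 nodes")
    if (length(object@force) != length(object@efficiency))
      msg <- c(msg, "force and efficiency must have equal length")
    if (anyNA(object@force) || anyNA(object@efficiency))
      msg <- c(msg, "calibration nodes must be finite")
    if (length(object@force) >= 2L) {
      if (any(diff(object@force) <= 0))
        msg <- c(msg, "forces must be strictly increasing")
      if (any(diff(object@efficiency) >= 0))
        msg <- c(msg, "efficiencies must be strictly decreasing")
    }
    if (length(object@force) && object@force[1L] < 0)
      msg <- c(msg, "forces must be non-negative")
    if (length(object@efficiency) &&
        (any(object@efficiency <= 0) || any(object@efficiency > 1)))
      msg <- c(msg, "efficiencies must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Per-pixel map with a validity mask
#'
#' Virtual parent of [EfficiencyMap-class] and [ForceMap-class]: a numeric
#' pixel grid, a logical mask of valid pixels, and the physical pixel size.
#'
#' @slot data numeric matrix of per-pixel values.
#' @slot valid logical matrix, same shape; TRUE where the value is trusted.
#' @slot pixelSize physical pixel edge length in micrometres.
#' @export
setClass("PixelMap",
  representation("VIRTUAL", data = "matrix", valid = "matrix",
                 pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@data), dim(object@valid)))
      msg <- c(msg, "data and valid mask must have identical dimensions")
    if (!is.logical(object@valid))
      msg <- c(msg, "valid mask must be logical")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Per-pixel FRET efficiency map
#'
#' Grid of FRET efficiencies in \[0, 1\] computed from a donor/acceptor image
#' pair; pixels whose summed background-corrected intensity fell below the
#' intensity floor are marked invalid.
#'
#' @seealso [computeEfficiency()]
#' @export
setClass("EfficiencyMap", contains = "PixelMap",
  validity = function(object) {
    v <- object@data[object@valid]
    if (length(v) && (any(v < 0) || any(v > 1)))
      "valid efficiencies must lie in [0, 1]" else TRUE
  })

#' Per-pixel force map
#'
#' Grid of forces in pN obtained by inverting a [CalibrationCurve-class]
#' on an [EfficiencyMap-class]; shares the efficiency map's validity mask.
#'
#' @slot calibrationId id of the calibration used for the inversion.
#' @seealso [forceFromEfficiency()]
#' @export
setClass("ForceMap", contains = "PixelMap",
  representation(calibrationId = "character"),
  validity = function(object) {
    v <- object@data[object@valid]
    if (length(v) && any(v < 0)) "valid forces must be non-negative" else TRUE
  })

#' Labeled set of force-producing adhesions
#'
#' Result of watershed segmentation of a force map: an integer label image
#' (0 = background) plus a per-adhesion statistics table with area,
#' pixel-mean force and efficiency, centroid and parent cell.
#'
#' @slot labels integer matrix of disjoint adhesion labels, 0 = background.
#' @slot stats data.frame, one row per adhesion: \code{label}, \code{cell_id},
#'   \code{n_pixels}, \code{area_um2}, \code{mean_force_pN},
#'   \code{mean_efficiency}, \code{centroid_row}, \code{centroid_col}.
#' @slot pixelSize micrometres per pixel.
#' @seealso [segmentAdhesions()], [profileCell()]
#' @export
setClass("AdhesionSet",
  representation(labels = "matrix", stats = "data.frame",
                 pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("label", "cell_id", "n_pixels", "area_um2", "mean_force_pN",
              "mean_efficiency", "centroid_row", "centroid_col")
    if (!all(need %in% names(object@stats)))
      msg <- c(msg, paste("stats must have columns:",
                          paste(need, collapse = ", ")))
    lab <- object@labels[object@labels > 0]
    if (nrow(object@stats) && !setequal(unique(lab), object@stats$label))
      msg <- c(msg, "stats labels must match the label image")
    if (length(msg)) msg else TRUE
  })

#' Geometry of a brain-section quantification
#'
#' Holds a ventricle-border polyline, optional named region polygons
#' (e.g. SVZ, RMS, OB) and a table of marker-annotated cell centroids, all in
#' micrometres in the section plane.
#'
#' @slot cells data.frame with at least \code{x}, \code{y} (um) plus logical
#'   marker flag columns, \code{animal} and optionally \code{group} and
#'   \code{true_distance_um}.
#' @slot border numeric matrix (n >= 2) x 2 of polyline vertices (x, y) in um.
#' @slot regions named list of polygon vertex matrices, each (n >= 3) x 2.
#' @seealso [simulateSection()], [distanceToBorder()], [countInRegions()]
#' @export
setClass("SectionGeometry",
  representation(cells = "data.frame", border = "matrix", regions = "list"),
  validity = function(object) {
    msg <- character()
    if (!all(c("x", "y") %in% names(object@cells)))
      msg <- c(msg, "cells must have x and y columns")
    if (ncol(object@border) != 2L || nrow(object@border) < 2L)
      msg <- c(msg, "border must be an (n >= 2) x 2 vertex matrix")
    else if (any(rowSums(abs(diff(object@border))) == 0))
      msg <- c(msg, "consecutive border vertices must be distinct")
    if (length(object@regions) &&
        (is.null(names(object@regions)) || any(names(object@regions) == "")))
      msg <- c(msg, "regions must be a named list")
    if (length(msg)) msg else TRUE
  })
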