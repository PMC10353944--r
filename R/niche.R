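## Niche spatial geometry: distance of marker-classified cells to the
## ventricle border, the 200-um analysis band, region counts along the
## SVZ -> RMS -> OB path, and EdU labeling efficiency.

#' Minimum Euclidean distance from points to a polyline
#'
#' Exact point-to-segment distance minimized over all segments of the
#' border polyline — the distance from the center of each nucleus to the
#' ventricle border.
#'
#' @param points data.frame or matrix with columns/ x, y in um (one row per
#'   point), or a length-2 numeric vector.
#' @param polyline vertex matrix (x, y), at least 2 rows.
#' @return numeric vector of distances in um.
#' @export
distanceToBorder <- function(points, polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 vertices")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  if (anyNA(points) || any(!is.finite(points)))
    stop("points must be finite")
  p1 <- polyline[-nrow(polyline), , drop = FALSE]
  p2 <- polyline[-1L, , drop = FALSE]
  dvec <- p2 - p1
  len2 <- rowSums(dvec^2)
  if (any(len2 == 0)) stop("consecutive polyline vertices must be distinct")
  vapply(seq_len(nrow(points)), function(i) {
    w <- cbind(points[i, 1L] - p1[, 1L], points[i, 2L] - p1[, 2L])
    tt <- pmin(1, pmax(0, (w[, 1L] * dvec[, 1L] + w[, 2L] * dvec[, 2L]) / len2))
    proj <- p1 + tt * dvec
    sqrt(min((points[i, 1L] - proj[, 1L])^2 + (points[i, 2L] - proj[, 2L])^2))
  }, numeric(1))
}

## Marker panels: decision tables mapping flag combinations to cell types.
.panels <- list(
  "GFAP/Ki67" = function(df)
    ifelse(df$GFAP & !df$Ki67, "qNSC/astrocyte",
    ifelse(df$GFAP & df$Ki67, "aNSC", "unclassified")),
  "S100a6/Ki67" = function(df)
    ifelse(df$S100a6 & !df$Ki67, "qNSC",
    ifelse(df$S100a6 & df$Ki67, "aNSC", "unclassified")),
  "EdU/Ki67/DCX" = function(df)
    ifelse(!df$EdU, "unclassified",
    ifelse(df$DCX, "neuroblast",
    ifelse(df$Ki67, "aNSC/NPC", "unclassified"))))

#' Classify cells from marker flags
#'
#' Applies one of the staining-panel decision tables:
#' \describe{
#'   \item{GFAP/Ki67}{GFAP+/Ki67- -> qNSC/astrocyte; GFAP+/Ki67+ -> aNSC.}
#'   \item{S100a6/Ki67}{S100a6+/Ki67- -> qNSC; S100a6+/Ki67+ -> aNSC.}
#'   \item{EdU/Ki67/DCX}{EdU+ cells only: DCX+ -> neuroblast (regardless of
#'     Ki67); DCX-/Ki67+ -> aNSC/NPC.}
#' }
#' Anything else is \code{"unclassified"}.  Cells flagged
#' \code{vessel_adjacent} are censored (label \code{NA}): NSCs lining a
#' blood vessel are attributed to the vessel, not the ventricle niche.
#'
#' @param cells data.frame with the logical marker columns the panel needs
#'   and optionally \code{vessel_adjacent}.
#' @param panel one of \code{"GFAP/Ki67"}, \code{"S100a6/Ki67"},
#'   \code{"EdU/Ki67/DCX"}.
#' @return character vector of cell-type labels (NA for censored cells).
#' @export
classifyCells <- function(cells, panel = c("GFAP/Ki67", "S100a6/Ki67",
                                           "EdU/Ki67/DCX")) {
  panel <- match.arg(panel)
  need <- strsplit(panel, "/")[[1]]
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop(sprintf("panel '%s' requires missing marker column(s): %s",
                 panel, paste(miss, collapse = ", ")))
  lab <- .panels[[panel]](cells)
  if ("vessel_adjacent" %in% names(cells))
    lab[cells$vessel_adjacent] <- NA_character_
  lab
}

#' Restrict cells to a band near the border
#'
#' Retains exactly the cells whose distance to the border polyline is at
#' most \code{maxDistance} (boundary inclusive) — the 200-um band used to
#' exclude striatal astrocytes from niche quantifications.  Idempotent.
#'
#' @param cells data.frame with \code{x}, \code{y} in um.
#' @param polyline border vertex matrix.
#' @param maxDistance band width in um (default 200).
#' @return the retained subset of \code{cells}, with a
#'   \code{distance_um} column added.
#' @export
filterBand <- function(cells, polyline, maxDistance = 200) {
  d <- distanceToBorder(cells[, c("x", "y")], polyline)
  cells$distance_um <- d
  cells[d <= maxDistance, , drop = FALSE]
}

#' Per-animal mean distance to the border, by cell type, with group tests
#'
#' Computes each animal's mean cell-to-border distance per cell type
#' ("each dot is the mean distance per mouse") and compares the two groups'
#' animal means with a two-tailed Mann-Whitney test, per cell type.
#'
#' @param cells data.frame with \code{x}, \code{y}, \code{animal},
#'   \code{group} and \code{cell_type} (censored NA types are dropped).
#' @param polyline border vertex matrix.
#' @return list with \code{animal_means} (group, animal, cell_type, mean
#'   distance) and \code{tests} (named list of Mann-Whitney results per
#'   cell type present in both groups).
#' @export
perAnimalDistanceSummary <- function(cells, polyline) {
  cells <- cells[!is.na(cells$cell_type), , drop = FALSE]
  cells$distance_um <- distanceToBorder(cells[, c("x", "y")], polyline)
  am <- aggregate(distance_um ~ group + animal + cell_type, data = cells,
                  FUN = mean)
  gs <- unique(am$group)
  tests <- list()
  if (length(gs) == 2L) {
    for (ct in unique(am$cell_type)) {
      a <- am$distance_um[am$group == gs[1L] & am$cell_type == ct]
      b <- am$distance_um[am$group == gs[2L] & am$cell_type == ct]
      if (length(a) && length(b))
        tests[[ct]] <- mannWhitneyTwoTailed(a, b)
    }
  }
  list(animal_means = am, tests = tests)
}

#' Even-odd point-in-polygon test (boundary counts as inside)
#'
#' @param points matrix/data.frame of (x, y) rows.
#' @param polygon vertex matrix of a simple polygon (closed implicitly).
#' @return logical vector.
#' @export
pointInPolygon <- function(points, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  ring <- rbind(polygon, polygon[1L, ])
  on_edge <- distanceToBorder(points, ring) <= 1e-9
  px <- points[, 1L]; py <- points[, 2L]
  inside <- rep(FALSE, nrow(points))
  n <- nrow(polygon)
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1L]; yi <- polygon[i, 2L]
    xj <- polygon[j, 1L]; yj <- polygon[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Count marker-positive cells in named regions
#'
#' Even-odd point-in-polygon counting (boundary inclusive) of the cells
#' passing the marker filter, per region — e.g. EdU+ nuclei along the
#' SVZ, RMS and OB.  Overlapping regions trigger a warning and a cell is
#' counted in each region containing it.
#'
#' @param cells data.frame with \code{x}, \code{y} and marker columns.
#' @param regions named list of polygon vertex matrices.
#' @param markerFilter optional name of a logical column; only TRUE cells
#'   are counted.
#' @return named integer vector of counts.
#' @export
countInRegions <- function(cells, regions, markerFilter = NULL) {
  if (!length(regions)) stop("regions must be a non-empty named list")
  if (!is.null(markerFilter)) {
    if (!markerFilter %in% names(cells))
      stop(sprintf("marker column '%s' missing", markerFilter))
    cells <- cells[isTRUE_vec(cells[[markerFilter]]), , drop = FALSE]
  }
  inside <- vapply(regions, function(poly)
    if (nrow(cells)) pointInPolygon(cells[, c("x", "y")], poly)
    else logical(0), logical(nrow(cells)))
  if (nrow(cells) == 0L)
    return(setNames(integer(length(regions)), names(regions)))
  inside <- matrix(inside, nrow = nrow(cells))
  if (any(rowSums(inside) > 1))
    warning("regions overlap; overlapping cells counted in each region")
  setNames(as.integer(colSums(inside)), names(regions))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' EdU labeling efficiency
#'
#' The number of EdU+ cells divided by the number of Ki67+ cells among the
#' supplied cells (restrict to the SVZ with [countInRegions()] /
#' [pointInPolygon()] beforehand, or pass \code{region} here).
#'
#' @param cells data.frame with logical \code{EdU} and \code{Ki67} columns.
#' @param region optional polygon; only cells inside are considered.
#' @return fraction in \[0, Inf) (normally \[0, 1\]).
#' @export
labelingEfficiency <- function(cells, region = NULL) {
  if (!all(c("EdU", "Ki67") %in% names(cells)))
    stop("cells must have EdU and Ki67 columns")
  if (!is.null(region))
    cells <- cells[pointInPolygon(cells[, c("x", "y")], region), , drop = FALSE]
  k <- sum(isTRUE_vec(cells$Ki67))
  if (k == 0) stop("no Ki67+ cells; labeling efficiency undefined")
  sum(isTRUE_vec(cells$EdU)) / k
}
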