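## FRET tension-sensor force mapping: donor/acceptor images -> per-pixel
## efficiency -> force via calibration inversion -> watershed adhesion
## segmentation -> per-cell force profiles and group comparisons.

#' Per-pixel FRET efficiency from a donor/acceptor image pair
#'
#' Sensitized-emission proximity ratio.  After background subtraction
#' (\code{D' = donor - bgDonor}) and bleed-through correction
#' (\code{A' = acceptor - bgAcceptor - beta * D'}), the efficiency is
#' \deqn{E = A' / (A' + \gamma D')}
#' clamped to \[0, 1\].  Pixels with total corrected signal
#' \code{D' + A'} below \code{intensityFloor} carry no usable sensor signal
#' and are marked invalid.
#'
#' @param donor,acceptor numeric matrices of equal shape (photon counts).
#' @param bgDonor,bgAcceptor scalar background levels subtracted per channel.
#' @param beta donor-to-acceptor spectral bleed-through fraction (>= 0).
#' @param gamma detection-efficiency ratio between channels (> 0).
#' @param intensityFloor minimum corrected total intensity for a pixel to be
#'   considered valid.
#' @param pixelSize micrometres per pixel, propagated to the map.
#' @return An [EfficiencyMap-class].
#' @export
computeEfficiency <- function(donor, acceptor, bgDonor = 0, bgAcceptor = 0,
                              beta = 0, gamma = 1, intensityFloor = 0,
                              pixelSize = 0.16) {
  if (!identical(dim(donor), dim(acceptor)))
    stop("donor and acceptor images must have identical dimensions")
  if (beta < 0) stop("beta must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  Dp <- donor - bgDonor
  Ap <- acceptor - bgAcceptor - beta * Dp
  total <- Dp + Ap
  valid <- is.finite(total) & (total >= intensityFloor) & (total > 0)
  E <- matrix(NA_real_, nrow(donor), ncol(donor))
  E[valid] <- pmin(1, pmax(0, Ap[valid] / (Ap[valid] + gamma * Dp[valid])))
  E[!valid] <- 0
  if (!any(valid))
    warning("no pixel exceeds the intensity floor; efficiency map is empty")
  new("EfficiencyMap", data = E, valid = valid, pixelSize = pixelSize)
}

#' Invert a calibration curve to map efficiency to force
#'
#' Monotone piecewise-linear inversion of the sensor calibration:
#' efficiencies at or above the zero-force node clamp to force 0 and
#' efficiencies at or below the maximal-force node clamp to the maximal
#' calibrated force.  Invalid pixels stay invalid.
#'
#' @param E an [EfficiencyMap-class].
#' @param cal a [CalibrationCurve-class] (validity enforces monotonicity).
#' @return A [ForceMap-class] in pN.
#' @export
forceFromEfficiency <- function(E, cal) {
  stopifnot(is(E, "EfficiencyMap"), is(cal, "CalibrationCurve"))
  ## approx needs increasing x: reverse the decreasing efficiency nodes
  eff <- rev(cal@efficiency)
  frc <- rev(cal@force)
  F <- matrix(0, nrow(E@data), ncol(E@data))
  v <- E@valid
  F[v] <- approx(eff, frc, xout = E@data[v], rule = 2)$y
  new("ForceMap", data = F, valid = v, pixelSize = E@pixelSize,
      calibrationId = cal@id)
}

## Merge 4-connected labels that touch diagonally, giving 8-connectivity.
.relabel8 <- function(lab) {
  mx <- max(lab)
  if (mx < 2L) return(lab)
  parent <- seq_len(mx)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dr in c(-1L, 1L)) {
    a <- lab[seq_len(nr - 1L) + (dr == -1L), seq_len(nc - 1L), drop = FALSE]
    b <- lab[seq_len(nr - 1L) + (dr == 1L),  seq_len(nc - 1L) + 1L, drop = FALSE]
    hit <- which(a > 0 & b > 0 & a != b)
    for (k in hit) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(mx), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment force-producing adhesions from a force map
#'
#' Candidate pixels are valid, inside the cell mask and above
#' \code{forceThreshold}.  Candidates are grouped into 8-connected
#' components; components smaller than \code{minArea} are discarded.  With
#' \code{split = TRUE}, touching adhesions are divided by a watershed of the
#' force landscape seeded at local force maxima (EBImage watershed on the
#' masked force image; \code{seedTolerance} is the minimum force drop, in pN,
#' between two maxima for them to seed separate adhesions).
#'
#' @param F a [ForceMap-class].
#' @param cellMask integer (or numeric) matrix of cell ids, 0 = background,
#'   same shape as \code{F}.
#' @param forceThreshold pN; pixels must exceed this to be candidates.
#' @param minArea minimum adhesion area in um^2 (> 0).
#' @param split logical; divide touching adhesions by watershed.
#' @param seedTolerance watershed tolerance in pN (default 10% of the
#'   calibrated force range above threshold, via the map's maximum).
#' @return An [AdhesionSet-class]; its stats table also records the mean
#'   efficiency implied by force through no transform (NA) unless
#'   \code{efficiencyMap} is supplied.
#' @param efficiencyMap optional [EfficiencyMap-class] used to report each
#'   adhesion's mean efficiency.
#' @export
segmentAdhesions <- function(F, cellMask, forceThreshold, minArea = 0.5,
                             split = TRUE, seedTolerance = NULL,
                             efficiencyMap = NULL) {
  stopifnot(is(F, "ForceMap"))
  if (!identical(dim(cellMask), dim(F@data)))
    stop("cellMask must match the force map's dimensions")
  if (minArea <= 0) stop("minArea must be > 0")
  px_area <- F@pixelSize^2
  min_px <- ceiling(minArea / px_area - 1e-9)

  cand <- F@valid & (cellMask > 0) & (F@data > forceThreshold)
  empty <- function() new("AdhesionSet",
                          labels = matrix(0L, nrow(F@data), ncol(F@data)),
                          stats = data.frame(label = integer(), cell_id = integer(),
                                             n_pixels = integer(), area_um2 = numeric(),
                                             mean_force_pN = numeric(),
                                             mean_efficiency = numeric(),
                                             centroid_row = numeric(),
                                             centroid_col = numeric()),
                          pixelSize = F@pixelSize)
  if (!any(cand)) return(empty())

  if (split) {
    if (is.null(seedTolerance)) {
      rng <- max(F@data[cand]) - forceThreshold
      seedTolerance <- 0.1 * max(rng, .Machine$double.eps)
    }
    elev <- matrix(0, nrow(F@data), ncol(F@data))
    elev[cand] <- F@data[cand] - forceThreshold
    lab <- EBImage::watershed(EBImage::Image(elev), tolerance = seedTolerance,
                              ext = 1)
    lab <- matrix(as.integer(lab), nrow(elev), ncol(elev))
  } else {
    lab <- matrix(as.integer(EBImage::bwlabel(cand * 1)), nrow(F@data))
    lab <- .relabel8(lab)
  }

  ## enforce the cell mask and drop small components
  lab[!cand] <- 0L
  sz <- tabulate(lab)
  keep <- which(sz >= min_px)
  if (!length(keep)) return(empty())
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0] <- match(lab[lab > 0], keep)

  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  npx <- tabulate(l)
  meanF <- as.numeric(tapply(F@data[idx], l, mean))
  meanE <- if (!is.null(efficiencyMap))
    as.numeric(tapply(efficiencyMap@data[idx], l, mean)) else rep(NA_real_, length(npx))
  ## parent cell: majority cell id over the adhesion's pixels
  cellid <- as.integer(tapply(cellMask[idx], l, function(v)
    as.integer(names(which.max(table(v))))))
  stats <- data.frame(
    label = seq_along(npx),
    cell_id = cellid,
    n_pixels = npx,
    area_um2 = npx * px_area,
    mean_force_pN = meanF,
    mean_efficiency = meanE,
    centroid_row = as.numeric(tapply(rows, l, mean)),
    centroid_col = as.numeric(tapply(cols, l, mean)))
  new("AdhesionSet", labels = lab, stats = stats, pixelSize = F@pixelSize)
}

#' Per-cell adhesion force profile
#'
#' Summarizes one cell's adhesions: number of adhesions, whether the cell is
#' force-producing (at least one adhesion), average adhesion force and total
#' adhesion area.  The average is pixel-weighted by default (mean force over
#' all the cell's adhesion pixels); \code{weighting = "adhesion"} instead
#' averages the per-adhesion mean forces unweighted.
#'
#' @param adhesions an [AdhesionSet-class].
#' @param cellId cell identifier present in the segmentation's cell mask.
#' @param weighting \code{"pixel"} (default) or \code{"adhesion"}.
#' @param knownCells optional vector of all cell ids in the image; a cell
#'   with no adhesions is then a valid query (otherwise an unknown id errors).
#' @return A one-row data.frame: \code{cell_id}, \code{n_adhesions},
#'   \code{force_producing}, \code{avg_force_pN} (NA when no adhesions),
#'   \code{total_area_um2}.
#' @export
profileCell <- function(adhesions, cellId, weighting = c("pixel", "adhesion"),
                        knownCells = NULL) {
  stopifnot(is(adhesions, "AdhesionSet"))
  weighting <- match.arg(weighting)
  st <- adhesions@stats
  known <- union(unique(st$cell_id), knownCells)
  if (!cellId %in% known)
    stop(sprintf("unknown cell_id '%s'", cellId))
  mine <- st[st$cell_id == cellId, , drop = FALSE]
  n <- nrow(mine)
  avg <- if (n == 0L) NA_real_
  else if (weighting == "pixel")
    sum(mine$mean_force_pN * mine$n_pixels) / sum(mine$n_pixels)
  else mean(mine$mean_force_pN)
  data.frame(cell_id = cellId, n_adhesions = n, force_producing = n >= 1L,
             avg_force_pN = avg, total_area_um2 = sum(mine$area_um2))
}

#' Profile every cell of a segmentation
#'
#' @inheritParams profileCell
#' @param cellIds vector of all cell ids to profile (include cells without
#'   adhesions so that force-producing proportions are correct).
#' @return data.frame with one row per cell (see [profileCell()]).
#' @export
profileCells <- function(adhesions, cellIds, weighting = c("pixel", "adhesion")) {
  weighting <- match.arg(weighting)
  do.call(rbind, lapply(cellIds, function(id)
    profileCell(adhesions, id, weighting, knownCells = cellIds)))
}

#' Compare adhesion force profiles between groups
#'
#' Per-animal means of per-cell average adhesion force are compared by a
#' two-tailed Mann-Whitney test; the proportions of force-producing cells
#' are compared by a two-sided Fisher exact test on the pooled 2x2 table of
#' cells (force-producing vs not, by group).
#'
#' @param profiles data.frame from [profileCells()] with added \code{group}
#'   and \code{animal} columns.
#' @return list with \code{animal_means} (data.frame: group, animal, mean
#'   avg force), \code{force_test} (Mann-Whitney on animal means),
#'   \code{prevalence_table} (2x2), \code{prevalence_test} (Fisher exact).
#' @export
compareGroupsForce <- function(profiles) {
  need <- c("group", "animal", "avg_force_pN", "force_producing")
  if (!all(need %in% names(profiles)))
    stop("profiles must have columns group, animal, avg_force_pN, force_producing")
  groups <- unique(profiles$group)
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (any(tapply(profiles$force_producing, profiles$group, length) == 0))
    stop("each group must contain at least one cell")

  am <- aggregate(avg_force_pN ~ group + animal, data = profiles,
                  FUN = mean, na.action = stats::na.omit)
  g1 <- am$avg_force_pN[am$group == groups[1L]]
  g2 <- am$avg_force_pN[am$group == groups[2L]]
  force_test <- if (length(g1) && length(g2))
    mannWhitneyTwoTailed(g1, g2) else NULL

  fp <- table(factor(profiles$group, levels = groups),
              factor(profiles$force_producing, levels = c(TRUE, FALSE)))
  prevalence_test <- fisherExactTwoSided(fp[1, 1], fp[1, 2], fp[2, 1], fp[2, 2])
  list(animal_means = am, force_test = force_test,
       prevalence_table = fp, prevalence_test = prevalence_test)
}
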