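## Generic image quantification operators (particle counting, masked
## intensity, ROI construction) and the detachment / centrifugation /
## Matrigel-dispersion assay measures built on them.

#' Otsu threshold of an image
#'
#' Convenience wrapper around EBImage's Otsu method.  Automatic thresholds
#' are never applied silently: every operator below takes the threshold as
#' an explicit argument, mirroring the practice of keeping one manual
#' threshold per experiment.
#'
#' @param image numeric matrix scaled to \[0, 1\] or raw counts (rescaled
#'   internally).
#' @return threshold on the original intensity scale.
#' @export
otsuThreshold <- function(image) {
  rng <- range(image, finite = TRUE)
  if (diff(rng) == 0) return(rng[1L])
  scaled <- (image - rng[1L]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1L] + t01 * diff(rng)
}

#' Count particles in an image
#'
#' Binarizes the image at \code{threshold} (inclusive), optionally splits
#' touching objects by a watershed of the distance map, discards objects
#' smaller than \code{minArea}, and counts within the ROI mask if given —
#' the "analyze particles" style operator with an explicit size floor.
#'
#' @param image numeric matrix.
#' @param threshold intensity threshold; pixels >= threshold are foreground.
#' @param minArea minimum object area (same units as \code{pixelSize^2};
#'   with the default \code{pixelSize = 1}, in pixels).
#' @param watershedSplit logical; split touching objects via distance-map
#'   watershed.
#' @param roiMask optional logical matrix restricting the analysis.
#' @param pixelSize micrometres per pixel (areas reported in um^2).
#' @return list of class \code{"LabeledParticles"}: \code{labels} (integer
#'   matrix), \code{count}, \code{table} (label, n_pixels, area, centroid
#'   rows/cols).
#' @export
countParticles <- function(image, threshold, minArea = 0.5,
                           watershedSplit = TRUE, roiMask = NULL,
                           pixelSize = 1) {
  if (minArea <= 0) stop("minArea must be > 0")
  fg <- image >= threshold
  if (!is.null(roiMask)) {
    if (!identical(dim(roiMask), dim(image)))
      stop("roiMask must match the image dimensions")
    if (!any(roiMask)) warning("ROI mask is empty; count is 0")
    fg <- fg & roiMask
  }
  px_area <- pixelSize^2
  min_px <- ceiling(minArea / px_area - 1e-9)
  empty <- function() structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                                     count = 0L,
                                     table = data.frame(label = integer(),
                                                        n_pixels = integer(),
                                                        area = numeric(),
                                                        centroid_row = numeric(),
                                                        centroid_col = numeric())),
                                class = "LabeledParticles")
  if (!any(fg)) return(empty())
  if (watershedSplit) {
    dm <- EBImage::distmap(EBImage::Image(fg * 1))
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    lab <- matrix(as.integer(lab), nrow(image))
  } else {
    lab <- .relabel8(matrix(as.integer(EBImage::bwlabel(fg * 1)), nrow(image)))
  }
  lab[!fg] <- 0L
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
  structure(list(labels = lab, count = length(npx),
                 table = data.frame(label = seq_along(npx), n_pixels = npx,
                                    area = npx * px_area,
                                    centroid_row = as.numeric(tapply(rows, l, mean)),
                                    centroid_col = as.numeric(tapply(cols, l, mean)))),
            class = "LabeledParticles")
}

#' @export
print.LabeledParticles <- function(x, ...) {
  cat(sprintf("LabeledParticles: %d object(s)\n", x$count))
  invisible(x)
}

#' Percentage of cells remaining after enzymatic detachment
#'
#' \code{100 * countAfter / countBefore} — the enzyme-based detachment
#' assay readout.
#'
#' @param countBefore,countAfter cell counts before/after treatment.
#' @return percentage (may exceed 100 if cells were gained).
#' @export
percentRemaining <- function(countBefore, countAfter) {
  if (countBefore <= 0) stop("countBefore must be > 0")
  if (countAfter < 0) stop("countAfter must be >= 0")
  100 * countAfter / countBefore
}

#' ROI mask excluding a border band
#'
#' Restricts a well image by \code{marginPx} pixels on every side, the
#' standard guard against debris accumulating at well edges.
#'
#' @param image matrix (only its shape is used).
#' @param marginPx border width in pixels to exclude.
#' @return logical matrix, TRUE inside the retained interior.
#' @export
restrictMargin <- function(image, marginPx) {
  d <- dim(image)
  if (marginPx < 0) stop("marginPx must be >= 0")
  if (2 * marginPx >= min(d)) stop("margin leaves no interior pixels")
  m <- matrix(FALSE, d[1L], d[2L])
  m[(marginPx + 1L):(d[1L] - marginPx), (marginPx + 1L):(d[2L] - marginPx)] <- TRUE
  m
}

#' Centered circular ROI mask
#'
#' Crops a well image to a centered disk of \code{radiusPx} pixels
#' (pixel-center sampling), the pre-processing used before area-fraction
#' measurements in the centrifugation assay.
#'
#' @param image matrix (only its shape is used).
#' @param radiusPx disk radius in pixels.
#' @return logical matrix, TRUE inside the disk.
#' @export
cropCircle <- function(image, radiusPx) {
  d <- dim(image)
  if (radiusPx <= 0) stop("radiusPx must be > 0")
  if (2 * radiusPx > min(d)) stop("circle does not fit inside the image")
  cr <- (d[1L] + 1) / 2; cc <- (d[2L] + 1) / 2
  rr <- outer((seq_len(d[1L]) - cr)^2, (seq_len(d[2L]) - cc)^2, "+")
  rr <= radiusPx^2
}

#' Percentage of ROI area covered by signal
#'
#' @param image numeric matrix.
#' @param threshold pixels >= threshold count as covered.
#' @param roiMask logical matrix; analysis restricted to TRUE pixels.
#' @return percentage in \[0, 100\].
#' @export
areaFraction <- function(image, threshold, roiMask = NULL) {
  if (is.null(roiMask)) roiMask <- matrix(TRUE, nrow(image), ncol(image))
  if (!identical(dim(roiMask), dim(image)))
    stop("roiMask must match the image dimensions")
  n <- sum(roiMask)
  if (n == 0) stop("ROI is empty")
  100 * sum(image[roiMask] >= threshold) / n
}

#' Percentage of adherent area remaining after centrifugation
#'
#' Computed as \code{100 * after / before}, consistent with the
#' enzyme-detachment convention (a value of 100 means nothing was lost).
#' Note the assay's ratio has also been printed in the literature with the
#' operands in the opposite order; this implementation fixes after/before.
#'
#' @param coverageBefore,coverageAfter percent area covered before/after
#'   spinning (from [areaFraction()]).
#' @return percentage remaining.
#' @export
percentAreaRemaining <- function(coverageBefore, coverageAfter) {
  if (coverageBefore <= 0) stop("coverage before spinning must be > 0")
  if (coverageAfter < 0) stop("coverage after spinning must be >= 0")
  100 * coverageAfter / coverageBefore
}

#' Size-normalized masked intensity per cell
#'
#' Sums pixel intensities inside each labeled cell mask (the "RawIntDen"
#' readout) and divides by the cell's pixel area, yielding a mean intensity
#' per cell that is invariant to cell size.  Normalization to a reference
#' group's mean is done downstream with [normalizeToReferenceMean()].
#'
#' @param image numeric intensity matrix.
#' @param cellMask integer matrix of cell labels (0 = background).
#' @return data.frame \code{cell_id, raw_integrated_density, n_pixels,
#'   mean_intensity}.
#' @export
maskedIntensity <- function(image, cellMask) {
  if (!identical(dim(image), dim(cellMask)))
    stop("image and cellMask must have identical dimensions")
  ids <- sort(unique(cellMask[cellMask > 0]))
  if (!length(ids)) stop("cellMask contains no cells")
  idx <- which(cellMask > 0)
  l <- cellMask[idx]
  npx <- as.numeric(tapply(rep(1, length(idx)), l, sum))
  if (any(npx == 0)) stop("zero-area cell in mask")
  raw <- as.numeric(tapply(image[idx], l, sum))
  data.frame(cell_id = ids, raw_integrated_density = raw, n_pixels = npx,
             mean_intensity = raw / npx)
}

#' Maximum dispersion distance beyond an initial spot perimeter
#'
#' The Matrigel dispersion readout: the maximum, over cell pixels at time t
#' lying outside the initial spot, of the Euclidean distance to the
#' boundary of the initial spot mask.  The boundary is the set of t0
#' foreground pixels 4-adjacent to background; distances are between pixel
#' centers.  Returns 0 when all time-t pixels lie inside the initial spot.
#'
#' @param maskT0 logical matrix, initial spot (must be non-empty).
#' @param maskT logical matrix at time t, same shape (must be non-empty).
#' @param pixelSize micrometres per pixel.
#' @return distance in um.
#' @export
dispersionDistance <- function(maskT0, maskT, pixelSize = 1) {
  if (!identical(dim(maskT0), dim(maskT)))
    stop("masks must have identical dimensions")
  if (!any(maskT0)) stop("initial mask is empty")
  if (!any(maskT)) stop("mask at time t is empty")
  outside <- maskT & !maskT0
  if (!any(outside)) return(0)
  ## boundary: t0 foreground 4-adjacent to background
  pad <- function(m) rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  p <- pad(maskT0)
  nr <- nrow(p); nc <- ncol(p)
  core <- p[2:(nr - 1), 2:(nc - 1)]
  nb_bg <- !p[1:(nr - 2), 2:(nc - 1)] | !p[3:nr, 2:(nc - 1)] |
           !p[2:(nr - 1), 1:(nc - 2)] | !p[2:(nr - 1), 3:nc]
  boundary <- core & nb_bg
  ## Euclidean distance of every pixel to the nearest boundary pixel
  dm <- EBImage::distmap(EBImage::Image(1 - boundary))
  max(as.matrix(dm)[outside]) * pixelSize
}
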