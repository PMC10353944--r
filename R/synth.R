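## Synthetic ground-truth generators for every analysis stage: tension-sensor
## image pairs, persistent-random-walk migration tracks, Bernoulli detachment,
## niche section geometries, and negative-binomial count matrices.
## All generators take an explicit integer seed and use the Mersenne-Twister
## generator, so a fixed seed reproduces outputs exactly.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(expr)
}

#' Simulation configuration for tension-sensor images
#'
#' @param seed integer PRNG seed (Mersenne-Twister; recorded in outputs).
#' @param imageShape integer (rows, cols) in pixels.
#' @param pixelSize micrometres per pixel; default 0.16 (typical x100 TIRF).
#' @param backgroundPhotons mean background counts per pixel per channel.
#' @param sensorPhotons mean total sensor signal counts per pixel.
#' @param restingEfficiency FRET efficiency of the unloaded sensor; must lie
#'   within the calibration's efficiency range.
#' @param calibration a [CalibrationCurve-class].
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, imageShape = c(256L, 256L), pixelSize = 0.16,
                      backgroundPhotons = 100, sensorPhotons = 2000,
                      restingEfficiency = 0.90,
                      calibration = defaultCalibration()) {
  stopifnot(is(calibration, "CalibrationCurve"))
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  if (length(imageShape) != 2L || any(imageShape < 8))
    stop("imageShape must be two values >= 8")
  er <- range(calibration@efficiency)
  if (restingEfficiency < er[1L] || restingEfficiency > er[2L])
    stop("restingEfficiency must lie within the calibration efficiency range")
  if (backgroundPhotons < 0 || sensorPhotons <= 0)
    stop("photon budgets must be non-negative (sensor > 0)")
  structure(list(seed = as.integer(seed),
                 imageShape = as.integer(imageShape), pixelSize = pixelSize,
                 backgroundPhotons = backgroundPhotons,
                 sensorPhotons = sensorPhotons,
                 restingEfficiency = restingEfficiency,
                 calibration = calibration),
            class = "SimConfig")
}

## Rasterize an ellipse at pixel centers (no anti-aliasing): physical coords
## x = (col-1)*px, y = (row-1)*px.
.ellipse_mask <- function(shape, px, cx, cy, a, b, theta) {
  cols <- ((seq_len(shape[2L]) - 1L) * px)
  rows <- ((seq_len(shape[1L]) - 1L) * px)
  dx <- outer(rep(1, shape[1L]), cols - cx)
  dy <- outer(rows - cy, rep(1, shape[2L]))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u^2 + v^2 <= 1
}

#' Simulate a donor/acceptor tension-sensor image pair with ground truth
#'
#' Cells are disk footprints; each carries elliptical adhesions bearing a
#' drawn force.  The true per-pixel efficiency is the resting efficiency
#' everywhere except inside adhesions, where it is the calibration curve
#' evaluated at the adhesion's force.  Expected intensities are
#' \code{donor = S(1 - E) + B} and \code{acceptor = S E + B} with S the
#' sensor photon budget and B the background; observed counts are Poisson
#' (shot noise only) unless \code{noise = FALSE}.
#'
#' An adhesion whose ellipse leaves its cell's footprint is rejected and
#' resampled (up to 200 tries, then an error).
#'
#' @param config a [simConfig()].
#' @param nCells number of cells.
#' @param adhesionsPerCell integer count, or a function \code{(n)} drawing
#'   counts.
#' @param forceDistribution function \code{(n)} drawing adhesion forces in
#'   pN (default uniform on 2..8 pN within the default calibration range).
#' @param cellRadius cell footprint radius in um.
#' @param adhesionAxes function \code{(n)} drawing semi-axis pairs in um;
#'   default semi-major 0.6-1.2 um, semi-minor 0.3-0.5 um, giving areas of
#'   about 0.57-1.9 um^2, typical of focal adhesions.
#' @param noise logical; Poisson shot noise on both channels.
#' @return list with \code{donor}, \code{acceptor} (integer count matrices
#'   if \code{noise}, else expected-value matrices), \code{cellMask}
#'   (integer matrix of cell ids), \code{truth} (data.frame: adhesion_id,
#'   cell_id, centroid, semi-axes, orientation, force_pN, n_pixels),
#'   \code{truthMasks} (list of logical matrices per adhesion),
#'   \code{trueEfficiency} matrix and the \code{config}.
#' @export
simulateTensionImages <- function(config, nCells = 3L, adhesionsPerCell = 2L,
                                  forceDistribution = function(n) runif(n, 2, 8),
                                  cellRadius = 6,
                                  adhesionAxes = function(n)
                                    cbind(runif(n, 0.6, 1.2), runif(n, 0.3, 0.5)),
                                  noise = TRUE) {
  stopifnot(inherits(config, "SimConfig"))
  shape <- config$imageShape; px <- config$pixelSize
  draw_k <- if (is.function(adhesionsPerCell)) adhesionsPerCell
            else function(n) rep(as.integer(adhesionsPerCell), n)
  .with_seed(config$seed, {
    W <- (shape[2L] - 1L) * px; H <- (shape[1L] - 1L) * px
    r_px <- cellRadius
    cellMask <- matrix(0L, shape[1L], shape[2L])
    centers <- matrix(NA_real_, nCells, 2L)
    ## place cells on a jittered grid so footprints do not overlap
    ng <- ceiling(sqrt(nCells))
    gx <- (seq_len(ng) - 0.5) / ng * W
    gy <- (seq_len(ng) - 0.5) / ng * H
    slots <- expand.grid(x = gx, y = gy)[seq_len(nCells), ]
    for (i in seq_len(nCells)) {
      cx <- slots$x[i]; cy <- slots$y[i]
      m <- .ellipse_mask(shape, px, cx, cy, r_px, r_px, 0)
      cellMask[m] <- i
      centers[i, ] <- c(cx, cy)
    }
    E <- matrix(config$restingEfficiency, shape[1L], shape[2L])
    k <- draw_k(nCells)
    total <- sum(k)
    truth <- data.frame(adhesion_id = integer(), cell_id = integer(),
                        cx_um = numeric(), cy_um = numeric(),
                        a_um = numeric(), b_um = numeric(),
                        theta_rad = numeric(), force_pN = numeric(),
                        n_pixels = integer())
    masks <- list()
    aid <- 0L
    for (i in seq_len(nCells)) {
      if (k[i] == 0L) next
      ax <- adhesionAxes(k[i])
      frc <- forceDistribution(k[i])
      if (any(frc < 0)) stop("forces must be non-negative")
      for (j in seq_len(k[i])) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          rr <- runif(1, 0, 0.7 * r_px)
          an <- runif(1, 0, 2 * pi)
          cx <- centers[i, 1L] + rr * cos(an)
          cy <- centers[i, 2L] + rr * sin(an)
          th <- runif(1, 0, pi)
          m <- .ellipse_mask(shape, px, cx, cy, ax[j, 1L], ax[j, 2L], th)
          ## a 2-px margin keeps adhesions spatially distinct, as focal
          ## adhesions are; tested with the ellipse grown by the margin
          grown <- .ellipse_mask(shape, px, cx, cy, ax[j, 1L] + 2 * px,
                                 ax[j, 2L] + 2 * px, th)
          if (any(m) && all(cellMask[m] == i) &&
              !any(grown & (E != config$restingEfficiency))) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place an adhesion inside its cell after 200 tries")
        aid <- aid + 1L
        E[m] <- calEfficiency(config$calibration, frc[j])
        truth[aid, ] <- list(aid, i, cx, cy, ax[j, 1L], ax[j, 2L], th,
                             frc[j], sum(m))
        masks[[aid]] <- m
      }
    }
    S <- config$sensorPhotons; B <- config$backgroundPhotons
    donor_mu <- S * (1 - E) + B
    acceptor_mu <- S * E + B
    if (noise) {
      donor <- matrix(rpois(length(donor_mu), donor_mu), shape[1L])
      acceptor <- matrix(rpois(length(acceptor_mu), acceptor_mu), shape[1L])
    } else {
      donor <- donor_mu; acceptor <- acceptor_mu
    }
    list(donor = donor, acceptor = acceptor, cellMask = cellMask,
         truth = truth, truthMasks = masks, trueEfficiency = E,
         config = config)
  })
}

#' Simulate migration tracks with a persistent random walk
#'
#' Cell velocities follow a discrete mean-reverting (Ornstein-Uhlenbeck)
#' process in 2-D with persistence time \code{persistenceTime}; the
#' stationary speed distribution is Rayleigh with mean \code{meanSpeed}.
#' Positions integrate velocity; optional Gaussian positional noise is added
#' to the reported detections only.
#'
#' @param nCells number of cells.
#' @param meanSpeed stationary mean speed in um/h.
#' @param persistenceTime velocity correlation time in h.
#' @param dt frame interval in h.
#' @param duration total imaging time in h (frames = duration/dt + 1).
#' @param positionalNoise s.d. of detection noise in um.
#' @param seed integer PRNG seed.
#' @param fieldSize side of the square field in um (initial placement).
#' @return data.frame \code{cell_id, frame, t, x, y} sorted by frame then
#'   cell; frames start at 0.
#' @export
simulateTracks <- function(nCells, meanSpeed, persistenceTime = 1, dt = 0.5,
                           duration = 20, positionalNoise = 0, seed = 1L,
                           fieldSize = 1000) {
  if (dt <= 0 || duration < dt || persistenceTime <= 0 || nCells < 1)
    stop("nCells, dt, duration and persistenceTime must be positive (duration >= dt)")
  if (meanSpeed < 0 || positionalNoise < 0)
    stop("meanSpeed and positionalNoise must be >= 0")
  nframes <- as.integer(floor(duration / dt)) + 1L
  sigma <- meanSpeed / sqrt(pi / 2)     # E|v| = sigma*sqrt(pi/2) for 2-D
  a <- exp(-dt / persistenceTime)
  s <- sigma * sqrt(1 - a^2)
  .with_seed(seed, {
    x <- runif(nCells, 0, fieldSize); y <- runif(nCells, 0, fieldSize)
    vx <- rnorm(nCells, 0, sigma); vy <- rnorm(nCells, 0, sigma)
    out <- vector("list", nframes)
    for (f in seq_len(nframes) - 1L) {
      ex <- x + rnorm(nCells, 0, positionalNoise)
      ey <- y + rnorm(nCells, 0, positionalNoise)
      out[[f + 1L]] <- data.frame(cell_id = seq_len(nCells), frame = f,
                                  t = f * dt, x = ex, y = ey)
      x <- x + vx * dt; y <- y + vy * dt
      vx <- a * vx + s * rnorm(nCells)
      vy <- a * vy + s * rnorm(nCells)
    }
    do.call(rbind, out)
  })
}

#' Simulate a detachment assay by Bernoulli retention
#'
#' Each plated cell is retained after enzyme treatment independently with
#' probability \code{pRetain}; the after set is a subset of the before set.
#'
#' @param nBefore number of cells before treatment.
#' @param pRetain retention probability in \[0, 1\].
#' @param seed integer PRNG seed.
#' @param fieldSize side of the square field in um.
#' @return list with \code{before} and \code{after} coordinate data.frames
#'   (\code{cell_id, x, y}); \code{after} rows are a subset of \code{before}.
#' @export
simulateDetachment <- function(nBefore, pRetain, seed = 1L, fieldSize = 1000) {
  if (pRetain < 0 || pRetain > 1) stop("pRetain must lie in [0, 1]")
  if (nBefore < 1) stop("nBefore must be >= 1")
  .with_seed(seed, {
    before <- data.frame(cell_id = seq_len(nBefore),
                         x = runif(nBefore, 0, fieldSize),
                         y = runif(nBefore, 0, fieldSize))
    keep <- runif(nBefore) < pRetain
    list(before = before, after = before[keep, , drop = FALSE])
  })
}

#' Simulate a brain-section geometry with known distances to the border
#'
#' For each group, cell distances to the ventricle border are drawn from the
#' group's distance distribution; each cell is placed by perpendicular
#' offset from a uniformly chosen point along the border polyline, on the
#' tissue side.  The recorded \code{true_distance_um} is recomputed against
#' the full polyline with [distanceToBorder()], so it is exact even for
#' curved borders.  Marker flags are assigned per the scheme.
#'
#' @param nPerGroup named integer vector: cells per group.
#' @param distanceDistributions named list of functions \code{(n)} drawing
#'   non-negative distances in um, one per group.
#' @param border polyline vertex matrix (x, y) in um; default a straight
#'   vertical border at x = 0 spanning 0..500 um.
#' @param regions optional named list of polygon vertex matrices.
#' @param markerScheme named list mapping group -> named logical vector of
#'   marker flags (e.g. \code{list(qNSC = c(GFAP = TRUE, Ki67 = FALSE))}).
#' @param nAnimals animals per group; cells are assigned round-robin.
#' @param seed integer PRNG seed.
#' @return A [SectionGeometry-class]; \code{sectionCells()} carries
#'   \code{group}, \code{animal}, marker flags, \code{vessel_adjacent}
#'   (all FALSE) and \code{true_distance_um}.
#' @export
simulateSection <- function(nPerGroup, distanceDistributions,
                            border = cbind(x = c(0, 0), y = c(0, 500)),
                            regions = list(), markerScheme = list(),
                            nAnimals = 4L, seed = 1L) {
  border <- as.matrix(border)
  if (nrow(border) < 2L) stop("border polyline needs at least 2 vertices")
  if (is.null(names(nPerGroup))) stop("nPerGroup must be named by group")
  .with_seed(seed, {
    seglen <- sqrt(rowSums(diff(border)^2))
    cum <- c(0, cumsum(seglen))
    total_len <- sum(seglen)
    rows <- list()
    for (g in names(nPerGroup)) {
      n <- nPerGroup[[g]]
      d <- distanceDistributions[[g]](n)
      if (any(d < 0)) stop("distances must be non-negative")
      s <- runif(n, 0, total_len)
      seg <- findInterval(s, cum, rightmost.closed = TRUE)
      seg[seg > length(seglen)] <- length(seglen)
      frac <- (s - cum[seg]) / seglen[seg]
      p0 <- border[seg, , drop = FALSE]
      dvec <- border[seg + 1L, , drop = FALSE] - p0
      dn <- dvec / seglen[seg]
      ## left normal; tissue assumed on that side of the oriented polyline
      normal <- cbind(-dn[, 2L], dn[, 1L])
      pts <- p0 + frac * dvec + d * normal
      flags <- markerScheme[[g]]
      df <- data.frame(x = pts[, 1L], y = pts[, 2L], group = g,
                       animal = paste0(g, "_a", (seq_len(n) - 1L) %% nAnimals + 1L),
                       vessel_adjacent = FALSE)
      if (!is.null(flags))
        for (mk in names(flags)) df[[mk]] <- flags[[mk]]
      rows[[g]] <- df
    }
    cells <- do.call(rbind, lapply(rows, function(d) {
      miss <- setdiff(unique(unlist(lapply(rows, names))), names(d))
      for (m in miss) d[[m]] <- FALSE
      d
    }))
    rownames(cells) <- NULL
    cells$true_distance_um <- distanceToBorder(cells[, c("x", "y")], border)
    new("SectionGeometry", cells = cells, border = border,
        regions = lapply(regions, as.matrix))
  })
}

#' Simulate a single-cell count matrix with a gene-set effect
#'
#' Counts are negative-binomial with log-normal baseline gene means; in the
#' second (\code{"old"}) group, genes belonging to \code{geneSet} have their
#' means multiplied by \code{exp(logFoldEffect)}.
#'
#' @param nPerGroup named integer vector of cells per group (first group is
#'   the reference; the effect applies to all later groups).
#' @param nGenes number of genes (named gene1..geneN).
#' @param geneSet character vector of affected gene names (subset of genes).
#' @param logFoldEffect natural-log fold change applied to gene-set genes in
#'   non-reference groups.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param meanRange log-uniform range of baseline gene means.
#' @param seed integer PRNG seed.
#' @return list with \code{counts} (genes x cells integer matrix),
#'   \code{groups} (per-cell labels), \code{animal} (per-cell ids) and
#'   \code{geneMeans} (baseline means).
#' @export
simulateCounts <- function(nPerGroup, nGenes = 200L, geneSet = character(),
                           logFoldEffect = 0, dispersion = 0.3,
                           meanRange = c(0.1, 20), seed = 1L) {
  if (is.null(names(nPerGroup))) stop("nPerGroup must be named by group")
  .with_seed(seed, {
    genes <- paste0("gene", seq_len(nGenes))
    mu0 <- exp(runif(nGenes, log(meanRange[1L]), log(meanRange[2L])))
    names(mu0) <- genes
    in_set <- genes %in% geneSet
    counts <- NULL; groups <- character(); animal <- character()
    for (gi in seq_along(nPerGroup)) {
      g <- names(nPerGroup)[gi]
      n <- nPerGroup[[gi]]
      mu <- mu0
      if (gi > 1L) mu[in_set] <- mu[in_set] * exp(logFoldEffect)
      block <- matrix(rnbinom(nGenes * n, mu = mu, size = 1 / dispersion),
                      nrow = nGenes)
      counts <- cbind(counts, block)
      groups <- c(groups, rep(g, n))
      animal <- c(animal, paste0(g, "_a", (seq_len(n) - 1L) %% 4L + 1L))
    }
    rownames(counts) <- genes
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
    list(counts = counts, groups = groups, animal = animal, geneMeans = mu0)
  })
}
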