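make_map <- function(values, valid = NULL, px = 0.16,
                     class = "EfficiencyMap") {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  new(class, data = values, valid = valid, pixelSize = px)
}

test_that("efficiency formula handles the canonical corner cases", {
  D <- matrix(10, 2, 2); A <- matrix(0, 2, 2)
  expect_equal(unique(as.vector(mapData(computeEfficiency(D, A)))), 0)
  expect_equal(unique(as.vector(mapData(computeEfficiency(A, D)))), 1)
  expect_equal(unique(as.vector(mapData(computeEfficiency(D, D)))), 0.5)
  ## bleed-through correction: A' = A - beta*D
  Em <- computeEfficiency(matrix(10, 1, 1), matrix(15, 1, 1), beta = 0.5)
  expect_equal(as.vector(mapData(Em)), 10 / 20)   # A' = 10, D' = 10
  ## detection-ratio gamma weights the donor term
  Eg <- computeEfficiency(matrix(10, 1, 1), matrix(10, 1, 1), gamma = 2)
  expect_equal(as.vector(mapData(Eg)), 10 / 30)
  expect_error(computeEfficiency(matrix(0, 2, 2), matrix(0, 3, 3)),
               "dimensions")
  ## pixels below the intensity floor are invalid, and exactly those
  D <- matrix(c(100, 2), 1, 2); A <- matrix(c(100, 2), 1, 2)
  Ef <- computeEfficiency(D, A, intensityFloor = 50)
  expect_identical(as.vector(validMask(Ef)), c(TRUE, FALSE))
})

test_that("calibration inversion round-trips nodes and interpolates midpoints", {
  cal <- defaultCalibration()
  E <- make_map(matrix(calEfficiencies(cal), 2, 3))
  Fm <- forceFromEfficiency(E, cal)
  expect_equal(as.vector(mapData(Fm)), calForces(cal), tolerance = 1e-9)
  ## midpoint of two node efficiencies -> midpoint of node forces
  eff <- calEfficiencies(cal); frc <- calForces(cal)
  mid_e <- (eff[-1] + eff[-length(eff)]) / 2
  mid_f <- (frc[-1] + frc[-length(frc)]) / 2
  Fm2 <- forceFromEfficiency(make_map(matrix(mid_e, 1)), cal)
  expect_equal(as.vector(mapData(Fm2)), mid_f, tolerance = 1e-12)
  ## efficiencies above resting clamp to zero force
  F0 <- forceFromEfficiency(make_map(matrix(1, 3, 3)), cal)
  expect_true(all(mapData(F0) == 0))
  ## monotonicity: pointwise lower efficiency -> higher force
  set.seed(2)
  e1 <- matrix(runif(36, 0.15, 0.9), 6)
  e2 <- pmin(e1 + runif(36, 0, 0.1), 0.9)
  f1 <- mapData(forceFromEfficiency(make_map(e1), cal))
  f2 <- mapData(forceFromEfficiency(make_map(e2), cal))
  expect_true(all(f1 >= f2 - 1e-12))
  expect_error(CalibrationCurve(c(0, 5), c(0.5, 0.9)), "decreasing")
})

test_that("thresholding force equals thresholding efficiency at cal(F_t)", {
  cal <- defaultCalibration()
  set.seed(3)
  E <- make_map(matrix(runif(400, 0.15, 0.9), 20))
  Fm <- forceFromEfficiency(E, cal)
  Ft <- 4
  expect_identical(mapData(Fm) > Ft,
                   mapData(E) < calEfficiency(cal, Ft))
})

test_that("segmentation finds synthetic adhesions and respects the mask", {
  cal <- defaultCalibration()
  cfg <- simConfig(seed = 5, imageShape = c(192, 192))
  sim <- simulateTensionImages(cfg, nCells = 2, adhesionsPerCell = 2,
                               noise = FALSE)
  E <- computeEfficiency(sim$donor, sim$acceptor, 100, 100, pixelSize = 0.16)
  Fm <- forceFromEfficiency(E, cal)
  ## uniform sub-threshold map -> empty set
  expect_equal(length(segmentAdhesions(make_map(matrix(0.5, 20, 20),
                                                class = "ForceMap",
                                                px = 0.16),
                                       matrix(1L, 20, 20),
                                       forceThreshold = 1)), 0L)
  ad <- segmentAdhesions(Fm, sim$cellMask, forceThreshold = 1, minArea = 0.5,
                         efficiencyMap = E)
  expect_equal(length(ad), nrow(sim$truth))
  ## each detected mask covers >= 90% of its ground-truth pixels
  lab <- labelMatrix(ad)
  for (i in seq_len(nrow(sim$truth))) {
    m <- sim$truthMasks[[i]]
    covering <- table(lab[m])
    best <- max(covering[names(covering) != "0"]) / sum(m)
    expect_gte(best, 0.9)
  }
  ## labels disjoint and inside the cell mask
  expect_true(all(sim$cellMask[lab > 0] > 0))
  st <- adhesionStats(ad)
  expect_equal(sum(st$n_pixels), sum(lab > 0))
  ## recovered per-adhesion mean force within 1% of ground truth, matching
  ## detections to truth by mask overlap
  for (i in seq_len(nrow(sim$truth))) {
    m <- sim$truthMasks[[i]]
    hit <- table(lab[m & lab > 0])
    l <- as.integer(names(which.max(hit)))
    expect_equal(st$mean_force_pN[st$label == l], sim$truth$force_pN[i],
                 tolerance = 0.01)
  }
})

test_that("watershed splitting separates bridged adhesions", {
  ## two square adhesions joined by a 1-px bridge
  f <- matrix(0, 30, 30)
  f[10:14, 5:9] <- 5
  f[10:14, 15:19] <- 5
  f[12, 10:14] <- 4.2           # bridge, slightly lower force
  Fm <- new("ForceMap", data = f, valid = matrix(TRUE, 30, 30),
            pixelSize = 1, calibrationId = "fixture")
  cells <- matrix(1L, 30, 30)
  merged <- segmentAdhesions(Fm, cells, forceThreshold = 1, minArea = 2,
                             split = FALSE)
  expect_equal(length(merged), 1L)
  split <- segmentAdhesions(Fm, cells, forceThreshold = 1, minArea = 2,
                            split = TRUE, seedTolerance = 0.5)
  expect_equal(length(split), 2L)
})

test_that("per-cell profiles weight forces as documented", {
  ## two adhesions: 10 px at 4 pN, 30 px at 8 pN
  lab <- matrix(0L, 20, 20)
  lab[1:2, 1:5] <- 1L; lab[5:10, 1:5] <- 2L
  st <- data.frame(label = 1:2, cell_id = 1L, n_pixels = c(10L, 30L),
                   area_um2 = c(10, 30), mean_force_pN = c(4, 8),
                   mean_efficiency = NA_real_, centroid_row = c(1, 7),
                   centroid_col = 3)
  ad <- new("AdhesionSet", labels = lab, stats = st, pixelSize = 1)
  expect_equal(profileCell(ad, 1)$avg_force_pN, 7)                  # pixel-weighted
  expect_equal(profileCell(ad, 1, weighting = "adhesion")$avg_force_pN, 6)
  ## a cell with no adhesions: force_producing FALSE, average force absent
  p0 <- profileCell(ad, 2, knownCells = 1:2)
  expect_false(p0$force_producing)
  expect_true(is.na(p0$avg_force_pN))
  expect_equal(p0$total_area_um2, 0)
  expect_error(profileCell(ad, 99), "unknown cell_id")
})

test_that("group comparison combines animal-level force and pooled prevalence", {
  prof <- data.frame(
    cell_id = 1:40,
    group = rep(c("young", "old"), each = 20),
    animal = rep(paste0("m", 1:8), each = 5),
    avg_force_pN = c(rnorm(20, 4), rnorm(20, 4)),
    force_producing = rep(c(TRUE, FALSE), 20))
  out <- compareGroupsForce(prof)
  ## identical prevalence 10/20 vs 10/20 -> Fisher p = 1
  expect_equal(out$prevalence_test$p.value, 1)
  expect_equal(dim(out$prevalence_table), c(2L, 2L))
  ## identical per-animal values -> MWU p = 1
  prof$avg_force_pN <- rep(5, 40)
  expect_equal(compareGroupsForce(prof)$force_test$p.value, 1)
  expect_error(compareGroupsForce(prof[prof$group == "young", ]), "two groups")
})
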