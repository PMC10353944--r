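test_that("tension-sensor simulation honours its forward model", {
  cfg <- simConfig(seed = 3, imageShape = c(160, 160))
  ## no adhesions, noise off: efficiency uniform at resting level everywhere
  sim0 <- simulateTensionImages(cfg, nCells = 2, adhesionsPerCell = 0,
                                noise = FALSE)
  expect_true(all(sim0$trueEfficiency == cfg$restingEfficiency))
  expect_equal(nrow(sim0$truth), 0L)

  ## count conservation: 3 cells x 2 adhesions -> 6 ground-truth rows
  sim <- simulateTensionImages(simConfig(seed = 1, imageShape = c(192, 192)),
                               nCells = 3, adhesionsPerCell = 2, noise = FALSE)
  expect_equal(nrow(sim$truth), 6L)
  expect_equal(length(sim$truthMasks), 6L)

  ## noise off: recomputed mean efficiency inside each ground-truth mask
  ## equals the calibration at the drawn force, to 1e-9
  E <- computeEfficiency(sim$donor, sim$acceptor, bgDonor = 100,
                         bgAcceptor = 100, pixelSize = 0.16)
  for (i in seq_len(nrow(sim$truth))) {
    m <- sim$truthMasks[[i]]
    expect_equal(mean(mapData(E)[m]),
                 calEfficiency(cfg$calibration, sim$truth$force_pN[i]),
                 tolerance = 1e-9)
  }

  ## determinism: same config, identical outputs
  sim2 <- simulateTensionImages(simConfig(seed = 1, imageShape = c(192, 192)),
                                nCells = 3, adhesionsPerCell = 2, noise = FALSE)
  expect_identical(sim$donor, sim2$donor)
  expect_identical(sim$truth, sim2$truth)

  ## noisy images are non-negative integer counts
  simn <- simulateTensionImages(simConfig(seed = 4, imageShape = c(96, 96)),
                                nCells = 1, adhesionsPerCell = 1)
  expect_true(all(simn$donor >= 0) && all(simn$donor == round(simn$donor)))
  expect_true(all(simn$acceptor >= 0))
})

test_that("adhesions always lie inside their cell's footprint", {
  for (seed in 1:4) {
    sim <- simulateTensionImages(simConfig(seed = seed, imageShape = c(192, 192)),
                                 nCells = 3, adhesionsPerCell = 3, noise = FALSE)
    for (i in seq_len(nrow(sim$truth))) {
      m <- sim$truthMasks[[i]]
      expect_true(all(sim$cellMask[m] == sim$truth$cell_id[i]))
    }
  }
})

test_that("track simulation has the stated stationary speed and shape", {
  ## stationary cells
  still <- simulateTracks(5, meanSpeed = 0, dt = 0.5, duration = 5, seed = 2)
  expect_equal(nrow(still), 5 * 11)
  for (id in 1:5) {
    tr <- still[still$cell_id == id, ]
    expect_equal(diff(tr$x), rep(0, 10))
    expect_equal(diff(tr$y), rep(0, 10))
  }
  ## 50 cells, 41 frames
  det <- simulateTracks(50, meanSpeed = 20, dt = 0.5, duration = 20, seed = 3)
  expect_equal(nrow(det), 50 * 41)
  ## law of large numbers: 500 cells recover the mean speed within 5%
  det <- simulateTracks(500, meanSpeed = 20, dt = 0.5, duration = 20, seed = 4)
  sp <- with(det, {
    spl <- split(det, cell_id)
    mean(vapply(spl, function(d)
      sum(sqrt(diff(d$x)^2 + diff(d$y)^2)) / (max(d$t) - min(d$t)),
      numeric(1)))
  })
  expect_lt(abs(sp - 20) / 20, 0.05)
  expect_error(simulateTracks(5, 10, dt = 0), "positive")
})

test_that("detachment simulation is Bernoulli retention with after within before", {
  all_kept <- simulateDetachment(50, 1, seed = 1)
  expect_identical(all_kept$after, all_kept$before)
  none <- simulateDetachment(50, 0, seed = 1)
  expect_equal(nrow(none$after), 0L)
  sim <- simulateDetachment(300, 0.6, seed = 9)
  expect_true(all(sim$after$cell_id %in% sim$before$cell_id))
  ## retention fraction within binomial 99% CI over 200 seeds
  fr <- vapply(1:200, function(s)
    nrow(simulateDetachment(500, 0.6, seed = s)$after) / 500, numeric(1))
  ci <- 0.6 + c(-1, 1) * 2.576 * sqrt(0.6 * 0.4 / (500 * 200))
  expect_gt(mean(fr), ci[1])
  expect_lt(mean(fr), ci[2])
  expect_error(simulateDetachment(10, 1.2), "pRetain")
})

test_that("section simulation records exact distances and conserves counts", {
  ## zero-width distance distribution at d = 0: all cells on the border
  on_border <- simulateSection(c(g = 20), list(g = function(n) rep(0, n)),
                               seed = 1)
  expect_equal(max(sectionCells(on_border)$true_distance_um), 0, tolerance = 1e-9)

  gsec <- simulateSection(
    c(young_q = 150, old_q = 150),
    list(young_q = function(n) rgamma(n, shape = 4, scale = 5),
         old_q = function(n) rgamma(n, shape = 4, scale = 10)),
    markerScheme = list(young_q = c(GFAP = TRUE, Ki67 = FALSE),
                        old_q = c(GFAP = TRUE, Ki67 = FALSE)),
    seed = 8)
  cells <- sectionCells(gsec)
  expect_equal(nrow(cells), 300)
  ## recorded distance is the exact distance to the border polyline
  expect_equal(cells$true_distance_um,
               distanceToBorder(cells[, c("x", "y")], sectionBorder(gsec)))
  ## group means track the distribution means (20 vs 40 um) within MC error
  m <- tapply(cells$true_distance_um, cells$group, mean)
  expect_lt(abs(m[["young_q"]] - 20), 3 * 10 / sqrt(150))
  expect_lt(abs(m[["old_q"]] - 40), 3 * 20 / sqrt(150))
  expect_true(all(cells$GFAP) && !any(cells$Ki67))
  expect_error(simulateSection(c(g = 5), list(g = function(n) rep(1, n)),
                               border = matrix(c(0, 0), 1, 2)),
               "2 vertices")
})

test_that("count simulation yields NB counts with the requested gene-set effect", {
  set <- paste0("gene", 1:20)
  null_sim <- simulateCounts(c(young = 200, old = 200), nGenes = 100,
                             geneSet = set, logFoldEffect = 0, seed = 2)
  expect_equal(dim(null_sim$counts), c(100L, 400L))
  expect_true(all(null_sim$counts >= 0))
  ## null case: signature-score means agree across groups within MC error
  expr <- logNormalizeCP10K(null_sim$counts)
  sc <- signatureScore(expr, set)
  m <- tapply(sc, null_sim$groups, mean)
  s <- tapply(sc, null_sim$groups, sd)
  expect_lt(abs(m[["young"]] - m[["old"]]),
            3 * sqrt(s[["young"]]^2 / 200 + s[["old"]]^2 / 200))

  ## realized per-gene mean ratio within 10% of exp(effect) at n = 2000
  eff <- simulateCounts(c(young = 2000, old = 2000), nGenes = 50,
                        geneSet = paste0("gene", 1:10), logFoldEffect = log(2),
                        seed = 3)
  young <- rowMeans(eff$counts[1:10, eff$groups == "young"])
  old <- rowMeans(eff$counts[1:10, eff$groups == "old"])
  expect_lt(max(abs(old / young - 2) / 2), 0.10)
})

test_that("generators are deterministic and do not disturb the global RNG", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(simulateTracks(5, 10, seed = 6))
  expect_identical(runif(1), before)
  expect_identical(simulateCounts(c(a = 5, b = 5), nGenes = 10, seed = 4),
                   simulateCounts(c(a = 5, b = 5), nGenes = 10, seed = 4))
})
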