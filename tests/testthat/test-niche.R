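test_that("point-to-polyline distance is exact on closed-form cases", {
  seg <- cbind(c(0, 10), c(0, 0))
  expect_equal(distanceToBorder(c(5, 3), seg), 3)
  expect_equal(distanceToBorder(c(5, 0), seg), 0)      # on the segment
  expect_equal(distanceToBorder(c(-3, 4), seg), 5)     # beyond an endpoint
  poly <- cbind(c(0, 5, 10), c(0, 5, 0))
  expect_equal(distanceToBorder(c(5, 6), poly), 1, tolerance = 1e-12)  # apex
  expect_equal(distanceToBorder(c(2, 3), poly), 1 / sqrt(2),
               tolerance = 1e-12)                 # perpendicular to y = x
  expect_error(distanceToBorder(c(NA, 1), seg), "finite")
  expect_error(distanceToBorder(c(1, 1), cbind(0, 0)), "2 vertices")
})

test_that("distance agrees with the dense-sampling oracle on random geometry", {
  set.seed(17)
  for (i in 1:25) {
    poly <- random_polyline(sample(3:8, 1))
    extent <- max(dist(poly))
    pt <- c(runif(1, -20, 120), runif(1, -20, 80))
    expect_lt(abs(distanceToBorder(pt, poly) -
                    oracle_polyline_distance(pt, poly)),
              0.001 * extent)
  }
})

test_that("distance is invariant under joint rigid transforms", {
  set.seed(23)
  poly <- random_polyline(6)
  pt <- c(30, 10)
  d0 <- distanceToBorder(pt, poly)
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(-40, 25)
  expect_equal(distanceToBorder(as.vector(R %*% pt + shift),
                                t(R %*% t(poly) + shift)),
               d0, tolerance = 1e-9)
})

test_that("marker panels classify exactly as their decision tables state", {
  cells <- data.frame(GFAP = c(TRUE, TRUE, FALSE, FALSE),
                      Ki67 = c(FALSE, TRUE, TRUE, FALSE),
                      vessel_adjacent = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(classifyCells(cells, "GFAP/Ki67"),
               c("qNSC/astrocyte", "aNSC", "unclassified", NA))
  s1 <- data.frame(S100a6 = TRUE, Ki67 = FALSE)
  expect_equal(classifyCells(s1, "S100a6/Ki67"), "qNSC")
  edu <- data.frame(EdU = c(TRUE, TRUE, TRUE, FALSE),
                    Ki67 = c(TRUE, FALSE, TRUE, TRUE),
                    DCX = c(FALSE, TRUE, TRUE, FALSE))
  ## EdU+/DCX+ is a neuroblast regardless of Ki67; EdU- is never classified
  expect_equal(classifyCells(edu, "EdU/Ki67/DCX"),
               c("aNSC/NPC", "neuroblast", "neuroblast", "unclassified"))
  expect_error(classifyCells(data.frame(GFAP = TRUE), "GFAP/Ki67"), "Ki67")
})

test_that("the 200-um band filter is exact on boundaries and idempotent", {
  border <- cbind(c(0, 0), c(0, 100))
  cells <- data.frame(x = c(50, 199.999, 200, 200.1), y = 50)
  kept <- filterBand(cells, border, 200)
  expect_equal(kept$x, c(50, 199.999, 200))   # 200.1 um excluded, 200 kept
  again <- filterBand(kept[, c("x", "y")], border, 200)
  expect_equal(again$x, kept$x)
  ## equals the brute-force filter by recomputed distance
  set.seed(3)
  rnd <- data.frame(x = runif(200, -50, 400), y = runif(200, -50, 150))
  poly <- random_polyline(5)
  d <- distanceToBorder(rnd, poly)
  expect_equal(nrow(filterBand(rnd, poly, 60)), sum(d <= 60))
})

test_that("per-animal distance summaries recover opposing simulated shifts", {
  sec <- simulateSection(
    c(young = 240, old = 240),
    list(young = function(n) rgamma(n, 4, scale = 5),    # mean 20 um
         old = function(n) rgamma(n, 4, scale = 12)),    # mean 48 um
    markerScheme = list(young = c(GFAP = TRUE, Ki67 = FALSE),
                        old = c(GFAP = TRUE, Ki67 = FALSE)),
    nAnimals = 6, seed = 12)
  cells <- sectionCells(sec)
  cells$cell_type <- classifyCells(cells, "GFAP/Ki67")
  out <- perAnimalDistanceSummary(cells, sectionBorder(sec))
  am <- out$animal_means
  expect_gt(mean(am$distance_um[am$group == "old"]),
            mean(am$distance_um[am$group == "young"]))
  expect_lt(out$tests[["qNSC/astrocyte"]]$p.value, 0.05)
  ## one animal with distances {10, 20} averages to 15
  single <- data.frame(x = c(10, 20), y = 0, animal = "m1", group = "g",
                       cell_type = "t")
  expect_equal(perAnimalDistanceSummary(single,
                                        cbind(c(0, 0), c(-5, 5)))$animal_means$distance_um,
               15)
})

test_that("region counts follow the even-odd rule with inclusive boundaries", {
  ob <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  svz <- cbind(c(20, 30, 30, 20), c(0, 0, 10, 10))
  cells <- data.frame(x = c(rep(5, 10), 10, 15), y = c(seq(1, 9.1, 0.9), 5, 5),
                      EdU = TRUE)
  counts <- countInRegions(cells, list(OB = ob, SVZ = svz), "EdU")
  expect_equal(counts, c(OB = 11L, SVZ = 0L))   # boundary x=10 counts inside
  expect_equal(countInRegions(cells[0, ], list(OB = ob, SVZ = svz)),
               c(OB = 0L, SVZ = 0L))
  ## counts on a convex polygon match the half-plane oracle
  set.seed(9)
  tri <- cbind(c(0, 40, 20), c(0, 0, 30))
  pts <- data.frame(x = runif(300, -5, 45), y = runif(300, -5, 35))
  inside_oracle <- apply(pts, 1, function(p) {
    sgn <- sapply(1:3, function(i) {
      a <- tri[i, ]; b <- tri[i %% 3 + 1, ]
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    })
    all(sgn >= 0) || all(sgn <= 0)
  })
  expect_equal(unname(countInRegions(pts, list(tri = tri))[["tri"]]),
               sum(inside_oracle))
  ## overlapping regions warn and double-count
  expect_warning(both <- countInRegions(data.frame(x = 5, y = 5),
                                        list(a = ob, b = ob)), "overlap")
  expect_equal(sum(both), 2L)
})

test_that("labeling efficiency divides EdU+ by Ki67+ cells", {
  cells <- data.frame(EdU = rep(c(TRUE, FALSE), c(30, 90)),
                      Ki67 = rep(TRUE, 120))
  expect_equal(labelingEfficiency(cells), 0.25)
  all_pos <- data.frame(EdU = TRUE, Ki67 = TRUE)
  expect_equal(labelingEfficiency(all_pos), 1)
  none <- data.frame(EdU = FALSE, Ki67 = TRUE)
  expect_equal(labelingEfficiency(none), 0)
  expect_error(labelingEfficiency(data.frame(EdU = TRUE, Ki67 = FALSE)),
               "Ki67")
  ## region restriction is applied before the ratio
  spatial <- data.frame(x = c(1, 1, 100), y = 1, EdU = c(TRUE, FALSE, TRUE),
                        Ki67 = TRUE)
  svz <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(labelingEfficiency(spatial, svz), 0.5)
})
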