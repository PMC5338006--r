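test_that("thickness measurement recovers the known layer heights of a slab fixture", {
  fix <- makeSlab(list(
    list(type = "SS", thickness = 40, cellSize = c(6.5, 6.5, 3.5)),
    list(type = "SC", thickness = 20, cellSize = c(15, 15, 0.5))
  ))
  th <- measureThickness(fix$tissue, fix$membrane, mode = "both")
  expect_true(all(!th$empty))
  expect_true(all(th$scPresent))
  # Tolerance covers the half-cell discretization of the packing.
  expect_equal(mean(th$ve), 40, tolerance = 0.1)
  expect_equal(mean(th$sc), 20, tolerance = 0.1)
  # Flat membrane: deepest and shallowest sample points agree.
  deep <- th[th$mode == "deepest", ]
  shal <- th[th$mode == "shallowest", ]
  expect_equal(deep$ve, shal$ve, tolerance = 1e-9)
  expect_equal(deep$sc, shal$sc, tolerance = 1e-9)
})

test_that("thickness handles empty tissues and tissues without corneocytes", {
  mem <- membraneGeometry("flat")
  thE <- measureThickness(newTissue(), mem)
  expect_true(all(thE$empty))
  expect_true(all(thE$ve == 0 & thE$sc == 0))
  fix <- makeSlab(list(list(type = "SS", thickness = 30, cellSize = c(6.5, 6.5, 3.5))))
  th <- measureThickness(fix$tissue, fix$membrane)
  expect_true(all(!th$scPresent))
  expect_equal(mean(th$ve), 30, tolerance = 0.1)
  expect_true(all(th$sc == 0))
})

test_that("depth profiles recover constant and depth-linear content", {
  # Uniform content: every occupied bin has that mean and zero spread.
  fix <- makeColumn(10, water = 73.5)
  pr <- depthProfile(fix$tissue, fix$membrane, "water", binHeight = 5)
  occ <- pr[pr$n > 0, ]
  expect_true(all(abs(occ$mean - 73.5) < 1e-9))
  expect_true(all(occ$sd == 0))
  # Content linear in depth: bin means recover the line within bin width.
  n <- 20
  fix2 <- makeColumn(n, water = 100)
  # Depth of cell k below the top cell's surface, by construction.
  gt <- fix2$groundTruth
  depth <- (gt$heights[n] + 3.5) - gt$heights
  cl <- cells(fix2$tissue)
  cl$caMobile <- 2 * depth
  fix2$tissue@cells <- cl
  pr2 <- depthProfile(fix2$tissue, fix2$membrane, "caMobile", binHeight = 6)
  occ2 <- pr2[pr2$n > 0, ]
  expect_gt(nrow(occ2), 5)
  expect_true(all(abs(occ2$mean - 2 * occ2$depthMid) < 2 * 6))
  # All cells in one giant bin: a single-row profile.
  pr3 <- depthProfile(fix$tissue, fix$membrane, "water", binHeight = 500)
  expect_equal(sum(pr3$n), 10)
  expect_equal(nrow(pr3), 1L)
})

test_that("calcium histograms over time have row sums equal to layer counts and track binding decay", {
  cfg <- defaultConfig("reduced", steps = 150L, seed = 8L, outputEvery = 10L)
  res <- runSimulation(cfg)
  m <- trajectoryMetrics(res)
  for (layer in c("SS", "SC")) {
    hist <- calciumHistogramOverTime(m, layer, breaks = seq(0, 3, by = 0.25))
    rec <- m@cellRecords
    counts <- table(factor(rec$step[rec$type == layer],
      levels = sort(unique(rec$step))
    ))
    expect_equal(unname(rowSums(hist)), as.integer(counts))
  }
  # A single corneocyte under pure binding drifts monotonically to lower bins.
  tis <- makeColumn(1, types = "SC", caMobile = 1.9)$tissue
  tr <- defaultTransportParameters()
  traj <- numeric(30)
  for (k in 1:30) {
    tis <- bindCalcium(tis, tr)$tissue
    traj[k] <- cells(tis)$caMobile
  }
  bins <- findInterval(traj, seq(0, 2, by = 0.2))
  expect_true(all(diff(bins) <= 0))
  expect_lt(bins[30], bins[1])
})

test_that("cross sections return exactly the bodies intersecting the plane, filtered by type", {
  fix <- makeSlab(list(
    list(type = "SS", thickness = 20, cellSize = c(6.5, 6.5, 3.5)),
    list(type = "SG", thickness = 10, cellSize = c(8, 8, 2.2))
  ))
  # Plane inside the SS band.
  cs <- extractCrossSection(fix$tissue, height = 10)
  expect_true(all(cs$type == "SS"))
  expect_gt(nrow(cs), 0)
  csSG <- extractCrossSection(fix$tissue, height = 25, types = "SG")
  expect_true(all(csSG$type == "SG"))
  # Plane above all cells, or outside a single body: empty.
  expect_equal(nrow(extractCrossSection(fix$tissue, height = 100)), 0L)
  one <- newTissue(data.frame(
    type = "SS", x = 10, y = 10, z = 10, a = 5, b = 5, c = 5
  ))
  expect_equal(nrow(extractCrossSection(one, height = 16)), 0L)
  hit <- extractCrossSection(one, height = 12)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$x, hit$y), c(10, 10))
})

test_that("Delaunay degrees match an exhaustive empty-circumcircle oracle on random points", {
  set.seed(14)
  pts <- cbind(runif(25), runif(25))
  topo <- delaunayNeighbourDistribution(pts)
  expect_equal(neighbourCounts(topo), as.integer(bruteForceDelaunayDegrees(pts)))
  expect_equal(sum(neighbourDistribution(topo)), 1)
})

test_that("Delaunay topology of lattices: triangle, hexagonal interior degree 6", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.4, 1))
  topo <- delaunayNeighbourDistribution(tri)
  expect_equal(neighbourCounts(topo), c(2L, 2L, 2L))
  pts <- makeLatticePoints("hexagonal", nx = 8L, ny = 8L)
  topo6 <- delaunayNeighbourDistribution(pts)
  interior <- attr(pts, "interior")
  expect_true(all(neighbourCounts(topo6)[interior] == 6L))
  # Boundary exclusion drops hull points from the distribution.
  topoB <- delaunayNeighbourDistribution(pts, excludeBoundary = TRUE)
  hull <- grDevices::chull(pts)
  expect_true(all(is.na(neighbourCounts(topoB)[hull])))
  expect_equal(sum(neighbourDistribution(topoB)), 1)
  # Degenerate inputs are rejected.
  expect_error(delaunayNeighbourDistribution(rbind(c(0, 0), c(1, 1))), "3 points")
  col <- cbind(1:5, 2 * (1:5))
  expect_error(delaunayNeighbourDistribution(col), "collinear")
})

test_that("cross-sections of a grown tissue have a unimodal neighbour distribution with mode 5-7", {
  res <- cachedGrowthRun(100)
  cl <- cells(res)
  # Pick the plane through the densest spinous band.
  ssz <- cl$z[cl$type == "SS"]
  plane <- stats::median(ssz)
  cs <- extractCrossSection(res@tissue, height = plane, types = "SS")
  expect_gt(nrow(cs), 10)
  # Hull points of the periodic section carry artificially low degrees;
  # exclude them as the ROI boundary.
  topo <- delaunayNeighbourDistribution(cs[, c("x", "y")],
    excludeBoundary = TRUE, layer = "SS", plane = plane
  )
  dist <- neighbourDistribution(topo)
  mode <- as.integer(names(dist)[which.max(dist)])
  expect_true(mode %in% 5:7)
})

test_that("homeostasis detection finds plateaus and rejects ramps", {
  expect_equal(detectHomeostasis(rep(5, 300), window = 100), 1L)
  ramp <- c(seq(1, 60, length.out = 100), rep(60, 400))
  got <- detectHomeostasis(ramp, window = 200, tolerance = 0.01)
  expect_true(got >= 90 && got <= 110)
  expect_true(is.na(detectHomeostasis(seq_len(400), window = 100, tolerance = 0.01)))
  expect_error(detectHomeostasis(1:10, window = 50), "shorter")
  expect_error(detectHomeostasis(1:100, window = 1L), "2 samples")
})
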