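baseCell <- function(type = "SS", ...) {
  over <- list(...)
  cl <- emptyCellTable(1L)
  cl$id <- 1L
  cl$type <- type
  cl$x <- 30; cl$y <- 30; cl$z <- 10
  cl$a <- 5; cl$b <- 5; cl$c <- 5
  cl$water <- 100
  cl$adhesion <- 1
  cl$cycleLen <- 10L
  for (nm in names(over)) cl[[nm]] <- over[[nm]]
  new("Tissue", cells = cl, nextId = 2L)
}

test_that("stem division is asymmetric and conserves water and calcium", {
  set.seed(1)
  tis <- baseCell("STEM",
    ageInType = 50L, cycleLen = 10L, membraneContact = TRUE,
    water = 80, caMobile = 1.2
  )
  out <- attemptDivisions(tis)
  expect_equal(out$nDivisions, 1L)
  cl <- cells(out$tissue)
  expect_setequal(cl$type, c("STEM", "TA"))
  expect_equal(cl$taLeft[cl$type == "TA"], 3L)
  expect_equal(sum(cl$water), 80)
  expect_equal(sum(cl$caMobile), 1.2)
  expect_equal(cl$ageInType[cl$type == "STEM"], 0L)
})

test_that("TA cells divide into SB daughters and convert to SB when exhausted", {
  set.seed(2)
  tis <- baseCell("TA",
    taLeft = 2L, ageInType = 60L, cycleLen = 10L, membraneContact = TRUE
  )
  out <- attemptDivisions(tis)
  cl <- cells(out$tissue)
  expect_setequal(cl$type, c("TA", "SB"))
  expect_equal(cl$taLeft[cl$type == "TA"], 1L)
  # Exhausted TA converts in place, no daughter.
  tis0 <- baseCell("TA",
    taLeft = 0L, ageInType = 60L, cycleLen = 10L, membraneContact = TRUE
  )
  out0 <- attemptDivisions(tis0)
  expect_equal(out0$nDivisions, 0L)
  expect_equal(out0$nExhausted, 1L)
  expect_equal(cells(out0$tissue)$type, "SB")
  # Non-proliferative and detached cells never divide.
  for (tis in list(
    baseCell("SS", ageInType = 99L, membraneContact = TRUE),
    baseCell("STEM", ageInType = 99L, membraneContact = FALSE)
  )) {
    expect_equal(attemptDivisions(tis)$nDivisions, 0L)
  }
})

test_that("lineage TA generations never exceed three in a seeded run", {
  cfg <- defaultConfig("reduced", steps = 260L, seed = 5L, humidity = 100)
  res <- runSimulation(cfg)
  expect_true(all(cells(res)$taLeft <= 3L))
  expect_true(all(cells(res)$taLeft[cells(res)$type == "TA"] >= 0L))
})

test_that("differentiation follows the lineage triggers and sets flags", {
  # Detached SB-lineage cells become SS.
  for (ty in c("TA", "SB")) {
    tis <- baseCell(ty, membraneContact = FALSE)
    out <- updateDifferentiation(tis)
    expect_equal(cells(out$tissue)$type, "SS")
    expect_equal(cells(out$tissue)$ageInType, 0L)
  }
  b <- defaultBehaviourParameters()
  # SS over the calcium threshold: homeostatic SG.
  tis <- baseCell("SS", caMobile = b$caThreshold + 0.1)
  out <- updateDifferentiation(tis)
  expect_equal(cells(out$tissue)$type, "SG")
  expect_false(cells(out$tissue)$premature)
  # SS with low water: premature SG.
  tis <- baseCell("SS", water = b$lowWaterThreshold - 1)
  out <- updateDifferentiation(tis)
  expect_equal(cells(out$tissue)$type, "SG")
  expect_true(cells(out$tissue)$premature)
  # Mature SG cornifies.
  tis <- baseCell("SG", ageInType = b$sgMaturation)
  out <- updateDifferentiation(tis)
  expect_equal(cells(out$tissue)$type, "SC")
  expect_false(cells(out$tissue)$desiccated)
  expect_equal(cells(out$tissue)$adhesion, b$adhesionInit)
  # Sustained low water desiccates SS and SG to dead corneocytes.
  for (ty in c("SS", "SG")) {
    tis <- baseCell(ty,
      water = b$lowWaterThreshold - 1,
      lowWaterClock = b$lowWaterPersist - 1L
    )
    out <- updateDifferentiation(tis)
    expect_equal(cells(out$tissue)$type, "SC")
    expect_true(cells(out$tissue)$desiccated)
  }
  # The low-water clock resets when water recovers.
  tis <- baseCell("SS", water = 90, lowWaterClock = 5L)
  out <- updateDifferentiation(tis)
  expect_equal(cells(out$tissue)$lowWaterClock, 0L)
})

test_that("shape relaxation is a monotone contraction onto the type target", {
  b <- defaultBehaviourParameters()
  tis <- baseCell("SC", a = 5, b = 5, c = 5)
  dist <- Inf
  for (k in 1:60) {
    tis <- updateShape(tis, b)
    cl <- cells(tis)
    d <- sqrt(sum((c(cl$a, cl$b, cl$c) - b$shapeTargets$SC)^2))
    expect_lte(d, dist + 1e-12)
    dist <- d
  }
  cl <- cells(tis)
  expect_equal(c(cl$a, cl$b, cl$c), b$shapeTargets$SC, tolerance = 1e-4)
  # Corneocyte target: 30 um wide, under 1 um high.
  expect_lt(2 * b$shapeTargets$SC[3], 1)
  expect_equal(2 * b$shapeTargets$SC[1], 30)
  # A cell at its target is a fixed point.
  at <- baseCell("SS",
    a = b$shapeTargets$SS[1], b = b$shapeTargets$SS[2],
    c = b$shapeTargets$SS[3]
  )
  expect_equal(cells(updateShape(at, b)), cells(at))
})

test_that("barrier components follow the homeostatic and premature pathways", {
  b <- defaultBehaviourParameters()
  # Homeostatic SG: tight junctions rise, bounded by 1; no lipids.
  tis <- baseCell("SG", caMobile = 1)
  tj <- 0
  for (k in 1:80) {
    tis <- updateBarrierComponents(tis, b)
    expect_gte(cells(tis)$tj, tj)
    tj <- cells(tis)$tj
    expect_lte(tj, 1)
  }
  expect_equal(cells(tis)$lipid, 0)
  # Live corneocyte produces both components.
  sc <- updateBarrierComponents(baseCell("SC", caMobile = 1), b)
  expect_gt(cells(sc)$tj, 0)
  expect_gt(cells(sc)$lipid, 0)
  # Calcium-starved SS activates the premature pathway at the multiplier.
  starved <- updateBarrierComponents(
    baseCell("SS", caMobile = b$lowCaThreshold / 2), b
  )
  expect_equal(cells(starved)$tj, b$prematureMult * b$tjRate, tolerance = 1e-12)
  expect_gt(cells(starved)$lipid, 0)
  # The alternative reading keeps premature lipids off.
  b2 <- b
  b2$prematureLipidProduction <- FALSE
  starved2 <- updateBarrierComponents(
    baseCell("SS", caMobile = b$lowCaThreshold / 2), b2
  )
  expect_equal(cells(starved2)$lipid, 0)
  # Healthy SS produces nothing.
  idle <- updateBarrierComponents(baseCell("SS", caMobile = 1), b)
  expect_equal(cells(idle)$tj, 0)
  # Desiccated corneocytes are dead: no production ever.
  dead <- baseCell("SC", desiccated = TRUE, lipid = 0.3, tj = 0.3)
  out <- updateBarrierComponents(dead, b)
  expect_equal(cells(out)$lipid, 0.3)
  expect_equal(cells(out)$tj, 0.3)
})

test_that("corneocyte adhesion rises to its peak then decays and never goes negative", {
  b <- defaultBehaviourParameters()
  tis <- baseCell("SC", adhesion = b$adhesionInit, ageInType = 0L)
  prev <- b$adhesionInit
  for (age in 1:(3 * b$adhesionPeak)) {
    cl <- cells(tis)
    cl$ageInType <- age - 1L
    tis@cells <- cl
    tis <- updateCorneocyteAdhesion(tis, b)
    now <- cells(tis)$adhesion
    if (age <= b$adhesionPeak) expect_gt(now, prev) else expect_lt(now, prev + 1e-12)
    expect_gte(now, 0)
    prev <- now
  }
  # Not a corneocyte: untouched.
  ss <- baseCell("SS", adhesion = 0.7)
  expect_equal(cells(updateCorneocyteAdhesion(ss, b))$adhesion, 0.7)
})

test_that("desquamation removes weakly adherent surface corneocytes only", {
  mem <- membraneGeometry("flat", Lx = 120, Ly = 120)
  b <- defaultBehaviourParameters()
  f <- defaultForceParameters()
  mkStack <- function(adh) {
    newTissue(data.frame(
      type = "SC", x = 60, y = 60, z = c(10, 10.8, 11.6),
      a = 15, b = 15, c = 0.5, adhesion = adh
    ))
  }
  # Top cell decayed below threshold -> removed; buried weak cell retained.
  tis <- mkStack(c(1, 1, 0.01))
  g <- buildContactGraph(tis, mem)
  rm1 <- checkDesquamation(tis, g, f, b)
  expect_equal(rm1, c(FALSE, FALSE, TRUE))
  tis2 <- mkStack(c(0.01, 1, 1))
  g2 <- buildContactGraph(tis2, mem)
  expect_equal(checkDesquamation(tis2, g2, f, b), rep(FALSE, 3))
  # Isolated surface corneocyte (no neighbours): mean strength 0 -> removed.
  solo <- newTissue(data.frame(
    type = "SC", x = 60, y = 60, z = 40, a = 15, b = 15, c = 0.5, adhesion = 1
  ))
  gS <- buildContactGraph(solo, mem)
  expect_true(checkDesquamation(solo, gS, f, b))
  # Viable surface cells never desquamate.
  ss <- newTissue(data.frame(
    type = "SS", x = 60, y = 60, z = 40, a = 5, b = 5, c = 5, adhesion = 1
  ))
  expect_false(any(checkDesquamation(ss, buildContactGraph(ss, mem), f, b)))
})
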