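test_that("pair damping is 1 with no barrier, monotone, bounded and knockout-aware", {
  tr <- defaultTransportParameters()
  expect_equal(pairDamping(0, 0, 0, 0, tr, "water"), 1)
  expect_equal(pairDamping(0, 0, 0, 0, tr, "calcium"), 1)
  # Strictly decreasing in the tight-junction level, bounded away from 0.
  lv <- seq(0, 1, by = 0.1)
  fc <- pairDamping(lv, 0, 0, 0, tr, "calcium")
  expect_true(all(diff(fc) < 0))
  expect_true(all(fc > 0))
  # The maximum of the two sides governs the interface.
  expect_equal(
    pairDamping(0.8, 0.2, 0, 0, tr, "water"),
    pairDamping(0.2, 0.8, 0, 0, tr, "water")
  )
  # Species asymmetry: tight junctions damp calcium more than water,
  # lipids damp water more than calcium.
  expect_lt(pairDamping(1, 0, 0, 0, tr, "calcium"), pairDamping(1, 0, 0, 0, tr, "water"))
  expect_lt(pairDamping(0, 0, 1, 0, tr, "water"), pairDamping(0, 0, 1, 0, tr, "calcium"))
  # Knockouts remove the component's effect entirely.
  trTj <- tr
  trTj$tjDisabled <- TRUE
  expect_equal(pairDamping(1, 1, 0, 0, trTj, "calcium"), 1)
  trLip <- tr
  trLip$lipidDisabled <- TRUE
  expect_equal(pairDamping(0, 0, 1, 1, trLip, "water"), 1)
})

test_that("closed-system water diffusion conserves, equilibrates, and is linear in damping", {
  fix <- makeColumn(2, water = c(90, 30))
  g <- buildContactGraph(fix$tissue, fix$membrane)
  tr <- defaultTransportParameters()
  tis <- fix$tissue
  for (k in 1:50) {
    out <- waterStep(tis, g, tr)
    tis <- out$tissue
    expect_equal(sum(cells(tis)$water), 120, tolerance = 1e-10)
  }
  expect_lt(abs(diff(cells(tis)$water)), abs(90 - 30))
  # Equal contents: zero flux.
  eq <- makeColumn(2, water = 50)
  expect_equal(waterStep(eq$tissue, buildContactGraph(eq$tissue, eq$membrane), tr)$fluxes, 0)
  # Halving the damping (via tj) halves the flux while in the linear regime.
  hi <- makeColumn(2, water = c(60, 50), tj = 0)
  lo <- makeColumn(2, water = c(60, 50), tj = 1)
  gH <- buildContactGraph(hi$tissue, hi$membrane)
  qH <- waterStep(hi$tissue, gH, tr)$fluxes
  qL <- waterStep(lo$tissue, gH, tr)$fluxes
  expect_equal(qL / qH, pairDamping(1, 1, 0, 0, tr, "water"), tolerance = 1e-9)
  # Bounds hold under extreme gradients.
  ext <- makeColumn(3, water = c(100, 0, 100))
  gE <- buildContactGraph(ext$tissue, ext$membrane)
  tis <- ext$tissue
  for (k in 1:30) tis <- waterStep(tis, gE, tr)$tissue
  expect_true(all(cells(tis)$water >= 0 & cells(tis)$water <= 100))
})

test_that("calcium transport conserves, reduces to diffusion at zero coupling, and advects with the water flux", {
  tr <- defaultTransportParameters()
  # Pure diffusion: alpha = 0 with zero water flux conserves the total.
  fix <- makeColumn(3, water = 50, caMobile = c(2, 0.5, 0.1))
  g <- buildContactGraph(fix$tissue, fix$membrane)
  tr0 <- tr
  tr0$alpha <- 0
  tis <- fix$tissue
  for (k in 1:40) {
    ws <- waterStep(tis, g, tr0)
    tis <- calciumStep(ws$tissue, g, ws$fluxes, tr0)$tissue
    expect_equal(sum(cells(tis)$caMobile), 2.6, tolerance = 1e-10)
  }
  expect_true(all(cells(tis)$caMobile >= 0))
  # Two-cell hand computation: equal calcium, upward water flux -> the
  # diffusive part vanishes and the advective part moves
  # alpha * ca_donor * q * damp upward.
  two <- makeColumn(2, water = c(55, 45), caMobile = 1)
  g2 <- buildContactGraph(two$tissue, two$membrane)
  ws <- waterStep(two$tissue, g2, tr)
  q <- ws$fluxes
  expect_gt(q, 0) # water moves from the wet bottom cell up
  cs <- calciumStep(ws$tissue, g2, q, tr)
  expect_equal(cs$fluxes, tr$alpha * 1 * q, tolerance = 1e-12)
  caAfter <- cells(cs$tissue)$caMobile
  expect_equal(caAfter[2] - 1, 1 - caAfter[1], tolerance = 1e-12)
  expect_gt(caAfter[2], caAfter[1])
})

test_that("corneocyte binding moves mobile calcium to the inert bound pool", {
  tis <- makeColumn(2, types = c("SS", "SC"), caMobile = 1)$tissue
  tr <- defaultTransportParameters()
  prevMobile <- 1
  for (k in 1:10) {
    out <- bindCalcium(tis, tr)
    tis <- out$tissue
    cl <- cells(tis)
    expect_equal(cl$caMobile[1], 1) # non-corneocyte untouched
    expect_equal(cl$caMobile[2] + cl$caBound[2], 1, tolerance = 1e-12)
    expect_lt(cl$caMobile[2], prevMobile)
    prevMobile <- cl$caMobile[2]
  }
})

test_that("boundary exchange feeds basal cells, evaporates at the surface, and scales with humidity", {
  tr <- defaultTransportParameters()
  fix <- makeColumn(4, water = c(40, 95, 95, 95), caMobile = 0.2)
  g <- buildContactGraph(fix$tissue, fix$membrane)
  out <- boundaryExchange(fix$tissue, g, fix$membrane, tr, H = 50)
  cl <- cells(out$tissue)
  expect_gt(cl$water[1], 40) # dermal refill of the basal cell
  expect_gt(out$ledger[["dermisWaterIn"]], 0)
  expect_lt(cl$water[4], 95) # evaporative loss at the surface
  expect_gt(out$ledger[["tewlOut"]], 0)
  expect_gt(out$ledger[["depositionOut"]], 0)
  expect_equal(cl$water[2:3], c(95, 95)) # interior untouched
  # TEWL decreases with humidity and is maximal at H = 0.
  loss <- vapply(c(0, 50, 100), function(H) {
    boundaryExchange(fix$tissue, g, fix$membrane, tr, H)$ledger[["tewlOut"]]
  }, numeric(1))
  expect_gt(loss[1], loss[2])
  expect_gt(loss[2], loss[3])
  # Under the strict linear law (no evaporation floor) H = 100 gives zero
  # TEWL for every cell.
  trLin <- tr
  trLin$tewlFloor <- 0
  expect_equal(
    boundaryExchange(fix$tissue, g, fix$membrane, trLin, 100)$ledger[["tewlOut"]], 0
  )
})

test_that("a dermis-fed, surface-evaporating column develops a monotone water gradient and a calcium peak below a barrier band", {
  tr <- defaultTransportParameters()
  # 20-cell column, barrier band (high tj + lipid) in the top 5 cells.
  n <- 20
  fix <- makeColumn(n,
    water = 100, caMobile = 1, types = c(rep("SS", n - 5), rep("SC", 5)),
    tj = c(rep(0, n - 5), rep(1, 5)), lipid = c(rep(0, n - 5), rep(1, 5))
  )
  res <- equilibrateTransport(fix$tissue, fix$membrane, tr, H = 50, steps = 600)
  cl <- cells(res$tissue)
  # Water decreases monotonically with height (few-unit wiggles tolerated).
  w <- cl$water
  expect_true(all(diff(w) < 1))
  expect_lt(w[n], w[1])
  # Calcium peaks just below the corneocyte barrier band -- above the
  # dermis-fed base level -- and crashes inside the band where corneocytes
  # bind it (the Fig-4 shape).
  ca <- cl$caMobile
  peak <- which.max(ca)
  expect_true(peak %in% c(n - 6, n - 5))
  expect_gt(ca[peak], ca[1])
  expect_gt(ca[peak], 2 * mean(ca[(n - 3):n]))
})

test_that("the column calcium gradient steepens as humidity decreases", {
  tr <- defaultTransportParameters()
  n <- 20
  mk <- function() {
    makeColumn(n,
      water = 100, caMobile = 1, types = c(rep("SS", n - 5), rep("SC", 5)),
      tj = c(rep(0, n - 5), rep(1, 5)), lipid = c(rep(0, n - 5), rep(1, 5))
    )
  }
  spread <- vapply(c(100, 50, 0), function(H) {
    fix <- mk()
    res <- equilibrateTransport(fix$tissue, fix$membrane, tr, H, steps = 600)
    ca <- cells(res$tissue)$caMobile
    max(ca) - min(ca)
  }, numeric(1))
  expect_gt(spread[2], spread[1])
  expect_gt(spread[3], spread[2])
})
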