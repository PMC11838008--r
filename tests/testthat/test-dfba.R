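test_that("exchange bounds convert kinetic derivatives to specific fluxes", {
  fx <- cachedFixture()
  t <- 30
  bs <- exchangeBoundsAt(t, fx$traj, fx$cmap, fx$network)
  st <- stateAt(fx$traj, t); dv <- derivativeAt(fx$traj, t)
  # unit-conversion oracle: g/(L h) over MW (g/mol) and X (gDW/L), x1000
  for (nm in c("Glx", "F", "Eth")) {
    row <- bs[bs$reaction == fx$cmap$reaction[fx$cmap$state == nm], ]
    vkin <- dv[[nm]] / (fx$cmap$mw[fx$cmap$state == nm] * st[["X"]]) * 1000
    expect_equal(row$lower, vkin, tolerance = 1e-12)
    expect_equal(row$upper, vkin, tolerance = 1e-12)
    expect_identical(row$provenance, "equality-constrained")
  }
  # worked conversion: -1.802 g/(L h), MW 180.2, X = 10 -> -1 mmol/(gDW h)
  expect_equal(-1.802 / (180.2 * 10) * 1000, -0.001 * 1000 / 1, tolerance = 1e-12)
  # inequality secretion gets a floor of zero, uptake a ceiling of zero
  glyc <- bs[bs$reaction == "EX_glyc", ]
  expect_equal(glyc$lower, 0)
  expect_gt(glyc$upper, 0)
  nh4 <- bs[bs$reaction == "EX_nh4", ]
  expect_lt(nh4$lower, 0)
  expect_equal(nh4$upper, 0)
  # biomass bound equals the specific growth rate
  bio <- bs[bs$reaction == "EX_biomass", ]
  expect_equal(bio$lower, dv[["X"]] / st[["X"]], tolerance = 1e-12)
  expect_equal(bio$lower, bio$upper)
})

test_that("exchange bounds reject degenerate biomass and unmapped names", {
  fx <- cachedFixture()
  zeroX <- fx$traj
  zeroX@states[, "X"] <- 0
  expect_error(exchangeBoundsAt(10, zeroX, fx$cmap, fx$network), "X\\(t\\)")
  badMap <- fx$cmap
  badMap$reaction[1] <- "EX_nope"
  expect_error(exchangeBoundsAt(10, fx$traj, badMap, fx$network), "missing")
})

test_that("objective weights follow the nitrogen regulator", {
  fx <- cachedFixture()
  # early: nitrogen abundant, ATP-dominated objective
  w0 <- objectiveAt(1, fx$traj)
  expect_gt(w0$atp, 0.9)
  expect_equal(w0$atp + w0$protein, 1)
  # late: nitrogen exhausted, pure protein objective
  wL <- objectiveAt(180, fx$traj)
  expect_gt(wL$protein, 0.99)
  # continuity in t
  tt <- seq(20, 60, 0.5)
  wp <- vapply(tt, function(t) objectiveAt(t, fx$traj)$protein, numeric(1))
  expect_lt(max(abs(diff(wp))), 0.12)
  # half-saturation: YAN == ksC gives equal weights (synthetic check)
  v <- parameterValues(fx$params)
  expect_equal(phiNS(v[["ksC"]], v[["ksC"]]), 0.5)
})

test_that("pFBA matches the vertex-enumeration oracle on seeded instances", {
  fx <- cachedFixture()
  net <- applyGam(fx$network, fx$gam)
  set.seed(2024)
  tPool <- seq(5, 185, length.out = 40)
  times <- sample(tPool, 8)
  for (t in times) {
    bs <- exchangeBoundsAt(t, fx$traj, fx$cmap, net)
    w <- objectiveAt(t, fx$traj)
    v <- pfba(net, bs, w)
    b <- fermflux:::.applyBoundSet(net, bs)
    obj <- fermflux:::.objectiveVector(net, w)
    oracle <- enumerateLPVertices(stoichMatrix(net), b$lb, b$ub, obj)
    expect_false(is.null(oracle))
    # relative agreement, with an absolute floor: late in fermentation the
    # objective is a near-vanishing convex combination of O(1) fluxes, so
    # agreement below ~1e-8 absolute is beyond the formulation's precision
    expect_lt(abs(attr(v, "objective") - oracle$opt),
              1e-8 * max(1, abs(oracle$opt)) + 1e-8)
    expect_lte(attr(v, "sumAbs"), oracle$minSumAbs +
                 1e-4 * (1 + oracle$minSumAbs))
  }
})

test_that("a futile cycle is suppressed by the parsimony stage", {
  # two alternate optima that differ by an internal cycle: pFBA must return
  # the cycle-free one
  S <- matrix(c(
    # A imported, converted to B by two parallel routes, B exported;
    # ATPM is an isolated dummy carrying the objective role
    -1, -1, -1,  0,  0,
     0,  1,  1, -1,  0),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("A", "B"),
                    c("EX_A", "R1", "R2", "EX_B", "ATPM")))
  # R2 reversible: R1 forward + R2 backward form a futile cycle
  net <- metabolicNetwork(
    S = S,
    lowerBounds = c(-5, 0, -5, 0, 0),
    upperBounds = c(0, 5, 5, 5, 5),
    reactions = c("EX_A", "R1", "R2", "EX_B", "ATPM"),
    metabolites = c("A", "B"),
    roles = list(biomass = "EX_B", atpMaintenance = "ATPM",
                 proteinSynthesis = "R1",
                 exchanges = c("EX_A", "EX_B")))
  bs <- data.frame(reaction = c("EX_A", "EX_B"), lower = c(-1, 1),
                   upper = c(-1, 1), provenance = "equality-constrained")
  v <- pfba(net, bs, weights = list(atp = 1, protein = 0))
  # total conversion must be 1; the cycle would inflate |R1| + |R2|
  expect_equal(v[["R1"]] + v[["R2"]], 1, tolerance = 1e-9)
  expect_lte(abs(v[["R1"]]) + abs(v[["R2"]]), 1 + 1e-6)
})

test_that("FVA ranges collapse under equality bounds and contain pFBA", {
  fx <- cachedFixture()
  net <- applyGam(fx$network, fx$gam)
  bs <- exchangeBoundsAt(60, fx$traj, fx$cmap, net)
  w <- objectiveAt(60, fx$traj)
  v <- pfba(net, bs, w)
  rng <- fva(net, bs, w)
  for (k in seq_len(nrow(rng))) {
    r <- rng$reaction[k]
    expect_gte(v[[r]], rng$min[k] - 1e-6)
    expect_lte(v[[r]], rng$max[k] + 1e-6)
  }
  # equality-bounded exchanges have no variability
  eqRxns <- bs$reaction[bs$provenance == "equality-constrained"]
  sel <- rng$reaction %in% eqRxns
  expect_lt(max(rng$max[sel] - rng$min[sel]), 1e-9)
})

test_that("FVA isolates a free internal cycle", {
  # parallel routes R1/R2 with R2 reversible form the only free direction
  # once the exchanges are fixed: their ranges are wide, everything else
  # is pinned
  S <- matrix(c(-1, -1, -1, 0, 0,
                 0,  1,  1, -1, 0),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"),
                              c("EX_A", "R1", "R2", "EX_B", "ATPM")))
  net <- metabolicNetwork(S, c(-5, 0, -5, 0, 0), c(0, 5, 5, 5, 5),
                          colnames(S), rownames(S),
                          roles = list(biomass = "EX_B",
                                       atpMaintenance = "ATPM",
                                       proteinSynthesis = "R1",
                                       exchanges = c("EX_A", "EX_B")))
  bs <- data.frame(reaction = c("EX_A", "EX_B"), lower = c(-1, 1),
                   upper = c(-1, 1), provenance = "equality-constrained")
  rng <- fva(net, bs, weights = list(atp = 0, protein = 0))
  rownames(rng) <- rng$reaction
  expect_gt(rng["R1", "max"] - rng["R1", "min"], 1)
  expect_gt(rng["R2", "max"] - rng["R2", "min"], 1)
  expect_lt(rng["EX_A", "max"] - rng["EX_A", "min"], 1e-9)
  expect_lt(rng["EX_B", "max"] - rng["EX_B", "min"], 1e-9)
})

test_that("a constant-state trajectory yields identical flux vectors", {
  fx <- cachedFixture()
  frozen <- fx$traj
  i0 <- which(sampleTimes(frozen) == 60)
  frozen@states <- frozen@states[rep(i0, 5), ]
  frozen@derivatives <- frozen@derivatives[rep(i0, 5), ]
  frozen@times <- seq(0, 40, 10)
  ft <- runDFBA(frozen, fx$network, fx$cmap, fx$gam, times = c(10, 20, 30))
  fl <- fluxMatrix(ft)
  expect_lt(max(abs(sweep(fl, 2, fl[1, ]))), 1e-6)
  expect_true(all(lpStatus(ft) == "optimal"))
  expect_equal(nrow(fl), 3)
})

test_that("the dFBA run is consistent with the kinetic derivatives", {
  fx <- cachedFixture()
  ft <- cachedFixtureDFBA()
  expect_equal(length(sampleTimes(ft)), 100)
  expect_true(all(lpStatus(ft) == "optimal"))
  fl <- fluxMatrix(ft)
  S <- as.matrix(stoichMatrix(applyGam(fx$network, fx$gam)))
  worst <- 0
  for (i in seq_along(sampleTimes(ft))) {
    t <- sampleTimes(ft)[i]
    # steady state at every step
    expect_lt(max(abs(S %*% fl[i, ])), 1e-6)
    st <- stateAt(fx$traj, t); dv <- derivativeAt(fx$traj, t)
    for (nm in c("Glx", "F", "Eth")) {
      r <- fx$cmap$reaction[fx$cmap$state == nm]
      vkin <- dv[[nm]] / (fx$cmap$mw[fx$cmap$state == nm] * st[["X"]]) * 1000
      worst <- max(worst, abs(fl[i, r] - vkin))
    }
  }
  expect_lt(worst, 1e-7)
  # no relaxations were needed on the co-designed fixture
  expect_equal(nrow(ft@relaxLog), 0)
})

test_that("smooth bounds produce smooth flux responses", {
  fx <- cachedFixture()
  ft <- cachedFixtureDFBA()
  fl <- fluxMatrix(ft)
  tt <- sampleTimes(ft)
  # equality-driven exchange fluxes change exactly as much as their kinetic
  # bounds do, never more (no spurious jumps)
  for (nm in c("Glx", "F", "Eth")) {
    r <- fx$cmap$reaction[fx$cmap$state == nm]
    mw <- fx$cmap$mw[fx$cmap$state == nm]
    bound <- vapply(tt, function(t)
      derivativeAt(fx$traj, t)[[nm]] /
        (mw * stateAt(fx$traj, t)[["X"]]) * 1000, numeric(1))
    expect_lt(max(abs(diff(fl[, r]) - diff(bound))), 1e-7)
  }
  # no spurious vertex jumps: each step's largest flux change is bounded by
  # the total bound-set change times an order-one stability constant (the
  # largest stoichiometric amplification in the network is ~6)
  boundVec <- function(t) {
    bs <- exchangeBoundsAt(t, fx$traj, fx$cmap, fx$network)
    c(bs$lower, bs$upper)
  }
  ratios <- vapply(seq_len(length(tt) - 1), function(i) {
    bd <- sum(abs(boundVec(tt[i + 1]) - boundVec(tt[i])))
    max(abs(fl[i + 1, ] - fl[i, ])) / max(bd, 1e-12)
  }, numeric(1))
  expect_lt(max(ratios), 10)
})
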