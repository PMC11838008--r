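test_that("lag factor matches the closed form and its limits", {
  # t = 0 returns a0; a0 = 1 is the no-lag identity
  expect_equal(lagFactor(0, 0.3, 0.2), 0.3)
  expect_equal(lagFactor(37, 1, 0.2), 1)
  # direct evaluation of the analytic solution
  expect_equal(lagFactor(20, 0.1, 0.2), 0.1 / (0.1 + 0.9 * exp(-4)),
               tolerance = 1e-12)
  # bounded in (0,1], non-decreasing, saturates at 1
  tt <- seq(0, 200, length.out = 50)
  lv <- lagFactor(tt, 0.05, 0.25)
  expect_true(all(lv > 0 & lv <= 1))
  expect_true(all(diff(lv) >= 0))
  expect_equal(lagFactor(1e4, 0.05, 0.25), 1, tolerance = 1e-12)
  expect_error(lagFactor(1, 0, 0.2), "a0")
  expect_error(lagFactor(1, 1.2, 0.2), "a0")
})

test_that("nitrogen and sugar regulators follow their half-saturation forms", {
  expect_equal(phiNS(0, 0.5), 1)
  expect_equal(phiNS(0.5, 0.5), 0.5)
  expect_equal(phiNS(99 * 0.02, 0.02), 0.01, tolerance = 1e-12)
  yan <- seq(0, 2, length.out = 40)
  pv <- phiNS(yan, 0.3)
  expect_true(all(pv >= 0 & pv <= 1))
  expect_true(all(diff(pv) <= 0))
  expect_error(phiNS(0.1, 0), "ksC")

  expect_equal(phiSugar(0, 0, 2), 1)
  expect_equal(phiSugar(1, 1, 2), 0.5)
  expect_equal(phiSugar(100, 100, 2), 2 / 202, tolerance = 1e-12)
  expect_error(phiSugar(1, 1, -1), "ksS")
})

test_that("primary growth converts nitrogen uptake with the element table", {
  expect_equal(primaryGrowthRate(c(Ala = 0, Arg = 0, NH4Cl = 0), 5), 0)
  tab <- aminoAcidTable()
  arg <- tab[tab$name == "Arg", ]
  expect_equal(arg$NN, 4L)
  expect_equal(arg$MW, 174.2)
  # hand evaluation: 14.0067 * (4 / 174.2) * 0.1
  expect_equal(primaryGrowthRate(c(Arg = -0.1), YxN = 1),
               14.0067 * 4 / 174.2 * 0.1, tolerance = 1e-12)
  # linear in YxN
  expect_equal(primaryGrowthRate(c(Arg = -0.1), YxN = 7),
               7 * primaryGrowthRate(c(Arg = -0.1), YxN = 1))
  expect_error(primaryGrowthRate(c(Pro = -0.1), 1), "unknown")
})

test_that("secondary growth behaves as a proportional controller", {
  expect_equal(secondaryGrowthRate(2, 0.8, phiNS = 1, ThetaC = 0.4,
                                   PhiC = 0.5), 0)
  expect_equal(secondaryGrowthRate(2, 0.4, phiNS = 0, ThetaC = 0.4,
                                   PhiC = 0.5), 0)
  expect_equal(secondaryGrowthRate(2, 0.4, phiNS = 1, ThetaC = 0.4,
                                   PhiC = 0.5), 0.2)
  # sign follows the distance to the set point
  expect_lt(secondaryGrowthRate(2, 1.2, 1, 0.4, 0.5), 0)
  expect_error(secondaryGrowthRate(0, 0, 1, 0.4, 0.5), "X")
})

test_that("the RHS matches an independent term-by-term evaluation", {
  p <- kineticParameters(
    delta = 1, YxN = 6, kNH4Cl = 0.2, vmaxGlx = 1.2, vmaxF = 0.9,
    ksGlx = 2, ksF = 3, alpha = 4, kSucrose = 0.1, tauGNS = 0.15,
    a0 = 0.2, muMaxN = 0.3, ThetaC = 0.5, PhiC = 0.2, ksC = 0.05,
    ksS = 8, YEth = 0.4, YGlycerol = 0.06, YAce = 0.02, YSucc = 0.01,
    YLac = 0.005, YBDO = 0.003, kcSucc = 0.02)
  s <- initialState(biomass = 1.5, Glx = 50, F = 40, Sucrose = 10,
                    NH4Cl = 0.2, aminoAcids = c(Arg = 0.5, Glu = 0.3),
                    params = p)
  s["GNS"] <- 0.25
  s["Succ"] <- 0.6
  t <- 12
  d <- kineticRHS(t, s, p)

  # independent evaluation of each constitutive piece
  lag <- 0.2 / (0.2 + 0.8 * exp(-0.3 * 12))
  XP <- 0.59 * 1.5
  dArg <- -lag * 0.4 * 0.5 * XP      # preset kAA.Arg = 0.4
  dGlu <- -lag * 0.15 * 0.3 * XP
  dNH4 <- -lag * 0.2 * 0.2 * XP
  muN <- -14.0067 * (4 / 174.2 * dArg + 1 / 147.13 * dGlu +
                       1 / 53.49 * dNH4) * 6
  expect_equal(d[["Arg"]], dArg, tolerance = 1e-12)
  expect_equal(d[["NH4Cl"]], dNH4, tolerance = 1e-12)
  expect_equal(d[["YAN"]], -muN / 6, tolerance = 1e-12)

  pN <- 0.05 / (s[["YAN"]] + 0.05)
  muC <- pN * 1.5 * 0.2 * (0.5 - 0.29)
  expect_equal(d[["XC"]], 0.29 * muN + muC, tolerance = 1e-12)
  expect_equal(d[["XP"]], 0.59 * muN, tolerance = 1e-12)
  expect_equal(d[["XmRNA"]], 0.12 * muN, tolerance = 1e-12)
  expect_equal(d[["X"]], muN + muC, tolerance = 1e-12)

  dSuc <- -0.1 * 10
  upGlx <- 1.2 * XP * 50 / 52 * (1 + 4 * muN)
  upF <- 0.9 * XP * 40 / 43 * (1 + 4 * muN)
  dGlx <- -upGlx - 0.5 * dSuc
  dF <- -upF - 0.5 * dSuc
  expect_equal(d[["Sucrose"]], dSuc, tolerance = 1e-12)
  expect_equal(d[["Glx"]], dGlx, tolerance = 1e-12)
  expect_equal(d[["F"]], dF, tolerance = 1e-12)

  # production terms are driven by hexose uptake, excluding sucrose release
  sugarUp <- -(upGlx + upF)
  pS <- 8 / (90 + 8)
  expect_equal(d[["GNS"]], (pN * pS - 0.25) * 0.15, tolerance = 1e-12)
  expect_equal(d[["Eth"]], -0.4 * sugarUp, tolerance = 1e-12)
  expect_equal(d[["Glycerol"]], -0.06 * sugarUp * 0.75, tolerance = 1e-12)
  expect_equal(d[["Lac"]], -0.005 * sugarUp * 0.75, tolerance = 1e-12)
  expect_equal(d[["Ace"]], -0.02 * sugarUp * 0.75, tolerance = 1e-12)
  expect_equal(d[["Succ"]], -0.01 * pN * sugarUp - 0.02 * (1 - pN) * 0.6 * XP,
               tolerance = 1e-12)
  # BDO: nitrogen-delayed + repressed variant by default
  expect_equal(d[["BDO"]], -0.003 * pN * sugarUp * 0.75, tolerance = 1e-12)
  # nitrogen-delayed variant without repression
  expect_equal(d[["Iamo"]],
               -parameterValues(p)[["YIamo"]] * pN * sugarUp,
               tolerance = 1e-12)
})

test_that("the acetate equation switches with the must type", {
  s <- initialState(biomass = 1, Glx = 50, F = 50, NH4Cl = 0.3,
                    aminoAcids = c(Glu = 0.5))
  s["Ace"] <- 0.4; s["GNS"] <- 0.1
  pNat <- kineticParameters(delta = 0, YAce = 0.02, kcAce = 0.05)
  pSyn <- kineticParameters(delta = 1, YAce = 0.02, kcAce = 0.05)
  dN <- kineticRHS(5, s, pNat)
  dS <- kineticRHS(5, s, pSyn)
  v <- parameterValues(pNat)
  pN <- v[["ksC"]] / (s[["YAN"]] + v[["ksC"]])
  sugarUp <- dN[["Glx"]] + dN[["F"]]
  XP <- s[["XP"]]
  expect_equal(dS[["Ace"]], -0.02 * sugarUp * 0.9, tolerance = 1e-12)
  expect_equal(dN[["Ace"]],
               -0.02 * sugarUp * (1 - pN) - 0.05 * pN * XP * 0.4 * 0.9,
               tolerance = 1e-12)
})

test_that("production stops when no sugar is present", {
  p <- presetParameters("fast")
  s <- initialState(biomass = 1, Glx = 0, F = 0, Sucrose = 0, NH4Cl = 0.2,
                    aminoAcids = c(Glu = 0.3), params = p)
  d <- kineticRHS(10, s, p)
  expect_equal(d[["Eth"]], 0)
  for (prod in secondaryProductNames()) expect_equal(d[[prod]], 0)
})

test_that("the RHS rejects pathological states", {
  p <- presetParameters("fast")
  s <- initialState(params = p)
  sBad <- s; sBad["Glx"] <- -5
  expect_error(kineticRHS(1, sBad, p), "negative")
  sNA <- s; sNA["Eth"] <- NaN
  expect_error(kineticRHS(1, sNA, p), "NA")
})
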