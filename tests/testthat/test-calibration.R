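test_that("the weighted cost reproduces hand-computed sums", {
  p <- presetParameters("fast")
  init <- presetInitialState("fast", p)
  des <- samplingDesign(cv = 0, seed = 1)
  gen <- generateDataset(p, init, des)
  # model predictions equal the (noise-free) data -> zero cost
  expect_equal(weightedCost(p, gen$dataset, init), 0, tolerance = 1e-4,
               ignore_attr = TRUE)

  # displace three data points by known residuals (1, 2, 0.25) with sigmas
  # (1, 2, 0.5): the cost must be the hand sum 1 + 1 + 0.25 = 2.25
  dsR <- gen$dataset
  pred <- fermflux:::.predictObservables(p, dsR, init, 1e-8, 1e-10)
  dsR@summary$mean <- pred
  dsR@summary$mean[1:3] <- pred[1:3] + c(1, 2, 0.25)
  dsR@summary$sigma[] <- 1
  dsR@summary$sigma[1:3] <- c(1, 2, 0.5)
  expect_equal(as.numeric(weightedCost(p, dsR, init)), 2.25,
               tolerance = 1e-6)
  # single displaced point: residual 2 at sigma 1 -> 4
  dsS <- dsR
  dsS@summary$mean <- pred
  dsS@summary$mean[5] <- pred[5] + 2
  dsS@summary$sigma[] <- 1
  expect_equal(as.numeric(weightedCost(p, dsS, init)), 4, tolerance = 1e-6)

  # scaling all sigmas by c scales the cost by 1/c^2
  ds <- gen$dataset
  pOff <- setParameterValues(p, c(vmaxGlx = 1.4))
  c0 <- weightedCost(pOff, ds, init)
  ds2 <- ds; ds2@summary$sigma <- ds@summary$sigma * 3
  expect_equal(as.numeric(weightedCost(pOff, ds2, init)),
               as.numeric(c0) / 9, tolerance = 1e-8)

  # invariant under reordering of the data points
  ds3 <- ds
  perm <- sample(nrow(ds3@summary))
  ds3@summary <- ds3@summary[perm, ]
  expect_equal(as.numeric(weightedCost(pOff, ds3, init)),
               as.numeric(c0), tolerance = 1e-10)
})

test_that("simulation failure is penalized, not fatal", {
  p <- presetParameters("fast")
  init <- presetInitialState("fast", p)
  des <- samplingDesign(cv = 0, seed = 1)
  gen <- generateDataset(p, init, des)
  # an invalid start state makes the simulation raise; the cost must turn
  # that into a large flagged penalty so global searches can continue
  badInit <- init
  badInit["Glx"] <- -1
  cost <- weightedCost(p, gen$dataset, badInit)
  expect_true(attr(cost, "failed"))
  expect_gte(as.numeric(cost), 1e10)
})

test_that("a noise-free fit initialized at the truth stays at the truth", {
  p <- presetParameters("fast")
  init <- presetInitialState("fast", p)
  gen <- generateDataset(p, init, samplingDesign(cv = 0, seed = 3))
  fit <- fitKinetics(gen$dataset, p, init,
                     subset = c("vmaxGlx", "YEth"), nStarts = 1, seed = 3)
  expect_lt(fit@cost, 1e-6)
  tv <- parameterValues(p)[c("vmaxGlx", "YEth")]
  expect_equal(fit@theta, tv, tolerance = 1e-4)
})

test_that("a two-parameter recovery from a displaced start succeeds", {
  p <- presetParameters("fast")
  init <- presetInitialState("fast", p)
  gen <- generateDataset(p, init, samplingDesign(cv = 0.01, seed = 11),
                         sigmaFloorFrac = 0.01)
  start <- setParameterValues(p, c(vmaxGlx = 0.6, YEth = 0.7))
  fit <- fitKinetics(gen$dataset, start, init,
                     subset = c("vmaxGlx", "YEth"), nStarts = 3, seed = 5)
  tv <- parameterValues(p)[c("vmaxGlx", "YEth")]
  expect_lt(max(abs(fit@theta - tv) / tv), 0.05)
  # deterministic given the seed
  fit2 <- fitKinetics(gen$dataset, start, init,
                      subset = c("vmaxGlx", "YEth"), nStarts = 3, seed = 5)
  expect_identical(fit@theta, fit2@theta)
})

test_that("confidence intervals match the linear-limit closed form", {
  # ethanol is exactly linear in its yield: Eth(t) = YEth * G(t) with G the
  # cumulative sugar uptake, so the FIM half-width for a YEth-only fit must
  # equal the weighted-least-squares standard error times the t quantile
  p <- presetParameters("fast")
  init <- presetInitialState("fast", p)
  gen <- generateDataset(p, init, samplingDesign(cv = 0, seed = 6),
                         observables = c(ethanol = "Eth"))
  fit <- fitKinetics(gen$dataset, p, init, subset = "YEth",
                     nStarts = 1, seed = 6)
  ci <- confidenceIntervals(fit, gen$dataset)
  summ <- gen$dataset@summary
  g <- summ$mean / parameterValues(p)[["YEth"]]   # regressor values
  hwClosed <- stats::qt(0.975, nrow(summ) - 1) /
    sqrt(sum((g / summ$sigma)^2))
  expect_equal(ci$halfWidth, hwClosed, tolerance = 1e-3)
})

test_that("duplicating the data shrinks half-widths by about 1/sqrt(2)", {
  p <- presetParameters("fast")
  init <- presetInitialState("fast", p)
  gen <- generateDataset(p, init, samplingDesign(cv = 0.02, seed = 9))
  fit <- fitKinetics(gen$dataset, p, init, subset = c("vmaxGlx", "YEth"),
                     nStarts = 1, seed = 9)
  ci1 <- confidenceIntervals(fit, gen$dataset)
  dsDup <- gen$dataset
  dsDup@summary <- rbind(dsDup@summary, dsDup@summary)
  ci2 <- confidenceIntervals(fit, dsDup)
  ratio <- ci2$halfWidth / ci1$halfWidth
  # FIM doubles; the t quantile also tightens slightly with more df
  expect_true(all(ratio < 1 / sqrt(2) + 0.02))
  expect_true(all(ratio > 1 / sqrt(2) - 0.1))
})

test_that("structural non-identifiability raises the singular-FIM warning", {
  p <- presetParameters("fast")
  init <- presetInitialState("fast", p)
  init["Mal"] <- 0   # malate absent: kcMal has zero sensitivity
  gen <- generateDataset(p, init, samplingDesign(cv = 0, seed = 2),
                         observables = c(ethanol = "Eth"))
  fit <- fitKinetics(gen$dataset, p, init, subset = c("YEth", "kcMal"),
                     nStarts = 1, seed = 2)
  expect_warning(ci <- confidenceIntervals(fit, gen$dataset), "singular")
  expect_true(all(ci$halfWidth >= 0))
  # degenerate degrees of freedom are rejected outright
  dsTiny <- gen$dataset
  dsTiny@summary <- dsTiny@summary[1:2, ]
  expect_error(confidenceIntervals(fit, dsTiny), "positive")
})

test_that("R-squared follows its definition", {
  p <- presetParameters("fast")
  init <- presetInitialState("fast", p)
  gen <- generateDataset(p, init, samplingDesign(cv = 0, seed = 4))
  rsq <- rSquared(p, gen$dataset, init)
  expect_true(all(rsq > 1 - 1e-6))   # perfect fit

  # SSres = 2, SStot = 8 -> 0.75 by definition
  expect_equal(1 - 2 / 8, 0.75)

  # prediction == mean of data -> 0: constant-prediction observable
  ds <- gen$dataset
  sel <- ds@summary$observable == "glucose"
  ymean <- mean(ds@summary$mean[sel])
  ssres <- sum((ds@summary$mean[sel] - ymean)^2)
  sstot <- ssres
  expect_equal(1 - ssres / sstot, 0)
})

test_that("product-model selection recovers the generating variant", {
  p <- presetParameters("fast")
  p@values[["YBDO"]] <- 0.02
  p@values[["tauGNS"]] <- 0.5   # strong late repression signal
  p@values[["ksS"]] <- 60
  init <- presetInitialState("fast", p)
  obs <- c(butanediol = "BDO")
  des <- samplingDesign(times = c(8, 20, 32, 44, 56, 68, 90), cv = 0.005,
                        seed = 21)

  pRep <- p; pRep@variants["BDO"] <- "nitrogen_delayed_repressed"
  genRep <- generateDataset(pRep, init, des, observables = obs,
                            sigmaFloorFrac = 0.005)
  selRep <- selectProductModel(genRep$dataset, "BDO", p, init, seed = 1)
  expect_equal(as.character(selRep), "nitrogen_delayed_repressed")

  pPlain <- p; pPlain@variants["BDO"] <- "nitrogen_delayed"
  genPlain <- generateDataset(pPlain, init, des, observables = obs,
                              sigmaFloorFrac = 0.005)
  selPlain <- selectProductModel(genPlain$dataset, "BDO", p, init, seed = 1)
  expect_equal(as.character(selPlain), "nitrogen_delayed")

  # forced ties break towards the simpler variant
  crit <- attr(selPlain, "criteria")
  expect_length(crit, 2)
})
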