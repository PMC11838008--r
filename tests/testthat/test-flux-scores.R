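# Hand-built flux trajectory with analytically integrable series.
makeFluxTraj <- function(times, fluxes, dw = rep(1, length(times)),
                         hexose = c("EX_glc", "EX_frc")) {
  new("FluxTrajectory", times = times, fluxes = fluxes,
      objective = rep(0, length(times)),
      status = rep("optimal", length(times)),
      dw = dw, phiNS = rep(0, length(times)),
      hexoseReactions = hexose,
      relaxLog = data.frame(time = numeric(), action = character()))
}

test_that("flux scores self-normalize on the hexose reactions", {
  tt <- seq(0, 10, 0.5)
  fl <- cbind(EX_glc = rep(-2, length(tt)), EX_frc = rep(0, length(tt)),
              EX_eth = rep(3.5, length(tt)))
  ft <- makeFluxTraj(tt, fl)
  # the glucose reaction against itself: |FS| = 100, uptake-signed
  expect_equal(fluxScore(ft, "EX_glc", 0, 10), -100)
  expect_equal(fluxScore(ft, "EX_frc", 0, 10), 0)
  expect_equal(fluxScore(ft, "EX_eth", 0, 10), 100 * 3.5 / 2)
})

test_that("trapezoidal scores are exact for linear flux with constant DW", {
  tt <- seq(2, 8, 0.5)
  vr <- 0.5 + 0.3 * tt                       # linear in time
  fl <- cbind(EX_glc = rep(-1, length(tt)), EX_frc = rep(-1, length(tt)),
              R = vr)
  ft <- makeFluxTraj(tt, fl)
  # closed form: int_2^8 (0.5 + 0.3 t) dt = 0.5*6 + 0.15*(64 - 4) = 12
  expect_equal(fluxScore(ft, "R", 2, 8), 100 * 12 / (6 + 6),
               tolerance = 1e-12)
  # interval endpoints between grid points interpolate linearly, still exact
  expect_equal(fluxScore(ft, "R", 2.25, 7.75),
               100 * (0.5 * 5.5 + 0.15 * (7.75^2 - 2.25^2)) / (5.5 + 5.5),
               tolerance = 1e-12)
})

test_that("normalized scores divide by duration and stay additive", {
  tt <- seq(0, 10, 1)
  fl <- cbind(EX_glc = rep(-1, length(tt)), EX_frc = rep(-1, length(tt)),
              R = rep(0.4, length(tt)))
  ft <- makeFluxTraj(tt, fl)
  fs5 <- fluxScore(ft, "R", 0, 5)
  expect_equal(normalizedFluxScore(ft, "R", tA = 0, tB = 5), fs5 / 5)
  # with constant fluxes FS is duration-invariant (numerator and hexose
  # denominator both scale with the interval), so NFS scales as 1/duration
  expect_equal(fluxScore(ft, "R", 0, 10), fs5, tolerance = 1e-12)
  expect_equal(normalizedFluxScore(ft, "R", tA = 0, tB = 10),
               normalizedFluxScore(ft, "R", tA = 0, tB = 5) / 2,
               tolerance = 1e-12)
  # the flux integrals underlying FS recombine additively over contiguous
  # intervals, so FS over a union equals the integral-weighted combination
  num <- function(a, b)
    fermflux:::.integrateSeries(tt, fl[, "R"] * 1, a, b)
  den <- function(a, b)
    fermflux:::.integrateSeries(tt, abs(fl[, "EX_glc"]), a, b) +
    fermflux:::.integrateSeries(tt, abs(fl[, "EX_frc"]), a, b)
  expect_equal(num(0, 4) + num(4, 10), num(0, 10), tolerance = 1e-12)
  expect_equal(fluxScore(ft, "R", 0, 10),
               100 * (num(0, 4) + num(4, 10)) / (den(0, 4) + den(4, 10)),
               tolerance = 1e-10)
  expect_error(normalizedFluxScore(ft, "R", tA = 3, tB = 3), "duration")
})

test_that("phase additivity holds on the integral scale for dFBA output", {
  ft <- cachedFixtureDFBA()
  fx <- cachedFixture()
  ph <- phaseTable(detectPhases(fx$traj))
  a <- max(ph$start[2], min(sampleTimes(ft)))
  m <- ph$end[2]; b <- ph$end[3]
  tt <- sampleTimes(ft)
  intOf <- function(tA, tB, r)
    fermflux:::.integrateSeries(tt, fluxMatrix(ft)[, r] * biomassSeries(ft),
                                tA, tB)
  # numerator and denominator integrals are both additive, hence FS over the
  # union interval is their ratio
  expect_equal(intOf(a, m, "EX_eth") + intOf(m, b, "EX_eth"),
               intOf(a, b, "EX_eth"), tolerance = 1e-8)
  denOf <- function(tA, tB)
    fermflux:::.integrateSeries(tt, abs(fluxMatrix(ft)[, "EX_glc"] *
                                          biomassSeries(ft)), tA, tB) +
    fermflux:::.integrateSeries(tt, abs(fluxMatrix(ft)[, "EX_frc"] *
                                          biomassSeries(ft)), tA, tB)
  expect_equal(fluxScore(ft, "EX_eth", a, b),
               100 * (intOf(a, m, "EX_eth") + intOf(m, b, "EX_eth")) /
                 (denOf(a, m) + denOf(m, b)), tolerance = 1e-10)
})

test_that("zero hexose denominators are an error", {
  tt <- 0:5
  fl <- cbind(EX_glc = rep(0, 6), EX_frc = rep(0, 6), R = rep(1, 6))
  ft <- makeFluxTraj(tt, fl)
  expect_error(fluxScore(ft, "R", 0, 5), "hexose")
  expect_error(fluxScore(ft, "R", 5, 0), "tA")
})

test_that("score tables carry FS = NFS x duration per phase", {
  ft <- cachedFixtureDFBA()
  fx <- cachedFixture()
  ph <- detectPhases(fx$traj)
  tab <- fluxScoreTable(ft, ph)
  dur <- tab@phases$end - tab@phases$start
  expect_equal(fsMatrix(tab),
               sweep(nfsMatrix(tab), 2, dur, "*"), tolerance = 1e-10)
  # ethanol secretion scores positive in every phase
  expect_true(all(fsMatrix(tab)["EX_eth", ] > 0))
  # hexose self-normalization within each phase
  hex <- colSums(abs(fsMatrix(tab)[c("EX_glc", "EX_frc"), ]))
  expect_equal(unname(hex), rep(100, ncol(fsMatrix(tab))),
               tolerance = 1e-9)
})

test_that("differential reactions follow the log-ratio filter", {
  phases <- data.frame(phase = "stationary", start = 0, end = 1)
  mk <- function(x) new("FluxScoreTable",
                        FS = matrix(x, ncol = 1,
                                    dimnames = list(names(x), "stationary")),
                        NFS = matrix(x, ncol = 1,
                                     dimnames = list(names(x), "stationary")),
                        phases = phases)
  s1 <- c(r1 = 1, r2 = 2, r3 = 0, r4 = 0, r5 = 1.001)
  s2 <- c(r1 = 1, r2 = 1, r3 = 1, r4 = 0, r5 = 1)
  a <- mk(s1); b <- mk(s2)
  hits <- differentialReactions(a, b, threshold = 1e-3)
  # r1 identical -> out; r2 ratio 2 -> in; r3 one-sided zero -> in;
  # r4 both zero -> out; r5 ratio 1.001 -> log10 ~ 4.3e-4 < 1e-3 -> out
  expect_setequal(hits, c("r2", "r3"))
  # threshold below log10(1.001) admits r5
  expect_true("r5" %in% differentialReactions(a, b, threshold = 4e-4))
  # s1 = 2 s2 is included for any threshold below log10(2)
  expect_true("r2" %in% differentialReactions(a, b, threshold = 0.3))
  bBad <- mk(s2); bBad@phases$phase <- "growth"
  expect_error(differentialReactions(a, bBad), "phases")
})
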