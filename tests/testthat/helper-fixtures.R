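# Shared fixtures, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function() {
  if (is.null(.fixtureCache$fx))
    .fixtureCache$fx <- fermentationFixture()
  .fixtureCache$fx
}

cachedFixtureDFBA <- function() {
  if (is.null(.fixtureCache$ft)) {
    fx <- cachedFixture()
    .fixtureCache$ft <- runDFBA(fx$traj, fx$network, fx$cmap, fx$gam,
                                times = seq(2, 190, length.out = 100))
  }
  .fixtureCache$ft
}

# A short synthetic trajectory used where full fermentations are overkill.
shortTrajectory <- function(profile = "fast", tmax = 60, by = 1) {
  p <- presetParameters(profile)
  simulateKinetics(p, presetInitialState(profile, p), seq(0, tmax, by = by))
}
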