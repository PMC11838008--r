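#' Detect fermentation phases from a kinetic trajectory
#'
#' Four phases are delimited from the solution itself: the lag phase ends
#' when the Baranyi-Roberts adaptation factor first reaches `lagThreshold`;
#' the exponential growth phase ends when assimilable nitrogen first falls
#' to `yanEpsilon`; the growth-no-growth transition ends when the total
#' growth rate dX/dt first falls to `growthEpsilon` after nitrogen
#' depletion; the stationary phase runs to the end of the horizon.
#'
#' If nitrogen never depletes (or growth never becomes numerically null)
#' within the horizon, the corresponding boundary is set to the final time
#' and a flag is recorded.
#'
#' @param traj A [KineticTrajectory].
#' @param lagThreshold Lag factor level ending the lag phase (default 0.99).
#' @param yanEpsilon Nitrogen depletion threshold, gN/L (default 1e-4).
#' @param growthEpsilon Growth-rate nullity threshold, gDW/(L h)
#'   (default 1e-6).
#' @return A [PhaseSchedule].
#' @export
detectPhases <- function(traj, lagThreshold = 0.99, yanEpsilon = 1e-4,
                         growthEpsilon = 1e-6) {
  stopifnot(is(traj, "KineticTrajectory"))
  times <- traj@times
  tFinal <- times[length(times)]
  v <- parameterValues(kineticParams(traj))
  flags <- character()

  lagv <- lagFactor(times, v[["a0"]], v[["muMaxN"]])
  iLag <- which(lagv >= lagThreshold)[1]
  tLag <- if (is.na(iLag)) {
    flags <- c(flags, "lagNeverEnds")
    tFinal
  } else times[iLag]

  yan <- traj@states[, "YAN"]
  iYan <- which(yan <= yanEpsilon)[1]
  tGrowth <- if (is.na(iYan)) {
    flags <- c(flags, "yanNeverDepleted")
    tFinal
  } else times[iYan]
  tGrowth <- max(tGrowth, tLag)

  dX <- traj@derivatives[, "X"]
  iGng <- which(times >= tGrowth & dX <= growthEpsilon)[1]
  tGng <- if (is.na(iGng)) {
    flags <- c(flags, "growthNeverNull")
    tFinal
  } else times[iGng]
  tGng <- max(tGng, tGrowth)

  new("PhaseSchedule", tLagEnd = tLag, tGrowthEnd = tGrowth,
      tGngEnd = tGng, tFinal = tFinal, flags = flags)
}

#' @rdname PhaseSchedule-class
#' @export
setMethod("phaseTable", "PhaseSchedule", function(x) {
  data.frame(
    phase = c("lag", "growth", "gng", "stationary"),
    start = c(0, x@tLagEnd, x@tGrowthEnd, x@tGngEnd),
    end = c(x@tLagEnd, x@tGrowthEnd, x@tGngEnd, x@tFinal),
    stringsAsFactors = FALSE
  )
})

setMethod("show", "PhaseSchedule", function(object) {
  tab <- phaseTable(object)
  cat("PhaseSchedule (h):\n")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-10s %8.2f -> %8.2f  (%.2f h)\n", tab$phase[i],
                tab$start[i], tab$end[i], tab$end[i] - tab$start[i]))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
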