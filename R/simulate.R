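#' Integrate the kinetic model
#'
#' Solves the 41-state ODE system with a stiffness-capable adaptive
#' integrator (`deSolve::lsoda`) and returns a [KineticTrajectory] holding
#' states and right-hand-side evaluations on the requested grid.
#'
#' @param params A [KineticParameters] object.
#' @param init Named initial state (see [initialState()]); concentrations
#'   must be non-negative.
#' @param times Strictly increasing output grid (h).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return A [KineticTrajectory].
#' @export
#' @examples
#' p <- presetParameters("fast")
#' traj <- simulateKinetics(p, initialState(params = p), seq(0, 50, 1))
simulateKinetics <- function(params, init, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(params, "KineticParameters"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  init <- init[kineticStateNames()]
  if (anyNA(init)) stop("init must cover all kinetic states")
  conc <- setdiff(kineticStateNames(), "GNS")
  if (any(init[conc] < 0)) stop("initial concentrations must be >= 0")

  cp <- .compileParams(params)
  rhs <- function(t, y, parms) list(.rhsCore(t, y, parms))
  sol <- deSolve::lsoda(y = unname(init), times = times, func = rhs,
                        parms = cp, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    tFail <- if (nrow(sol) >= 1) sol[nrow(sol), 1] else times[1]
    stop("integration failed at t = ", signif(tFail, 6), " h")
  }
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- kineticStateNames()
  derivs <- t(vapply(seq_along(times), function(i)
    .rhsCore(times[i], states[i, ], cp), numeric(ncol(states))))
  colnames(derivs) <- kineticStateNames()
  new("KineticTrajectory", times = as.numeric(times), states = states,
      derivatives = derivs, params = params)
}

#' @rdname KineticTrajectory-class
#' @export
setMethod("sampleTimes", "KineticTrajectory", function(x) x@times)

#' @rdname KineticTrajectory-class
#' @export
setMethod("stateMatrix", "KineticTrajectory", function(x) x@states)

#' @rdname KineticTrajectory-class
#' @export
setMethod("derivativeMatrix", "KineticTrajectory", function(x) x@derivatives)

#' @rdname KineticTrajectory-class
#' @export
setMethod("kineticParams", "KineticTrajectory", function(x) x@params)

setMethod("show", "KineticTrajectory", function(object) {
  n <- length(object@times)
  cat("KineticTrajectory:", n, "time points over [",
      object@times[1], ",", object@times[n], "] h,",
      ncol(object@states), "states\n")
  fin <- object@states[n, ]
  cat(sprintf("  final: X = %.3f gDW/L, Glx+F = %.2f g/L, YAN = %.4f gN/L, Eth = %.2f g/L\n",
              fin[["X"]], fin[["Glx"]] + fin[["F"]], fin[["YAN"]],
              fin[["Eth"]]))
})

# Piecewise-linear interpolation of a trajectory column at time t.
.interpCol <- function(times, values, t) {
  stats::approx(times, values, xout = t, rule = 2)$y
}

#' Interpolate trajectory states or derivatives
#'
#' Piecewise-linear interpolation between stored grid points.
#'
#' @param traj A [KineticTrajectory].
#' @param t Time (h) within the trajectory span.
#' @return Named numeric state (or derivative) vector at `t`.
#' @export
stateAt <- function(traj, t) {
  stopifnot(is(traj, "KineticTrajectory"))
  if (t < traj@times[1] - 1e-9 || t > traj@times[length(traj@times)] + 1e-9)
    stop("t outside trajectory span")
  vapply(kineticStateNames(),
         function(s) .interpCol(traj@times, traj@states[, s], t), numeric(1))
}

#' @rdname stateAt
#' @export
derivativeAt <- function(traj, t) {
  stopifnot(is(traj, "KineticTrajectory"))
  if (t < traj@times[1] - 1e-9 || t > traj@times[length(traj@times)] + 1e-9)
    stop("t outside trajectory span")
  vapply(kineticStateNames(),
         function(s) .interpCol(traj@times, traj@derivatives[, s], t),
         numeric(1))
}

#' Export a trajectory as tidy data
#'
#' @param traj A [KineticTrajectory].
#' @return data.frame with columns `time`, `variable`, `value`.
#' @export
trajectoryToTidy <- function(traj) {
  stopifnot(is(traj, "KineticTrajectory"))
  sn <- colnames(traj@states)
  data.frame(
    time = rep(traj@times, times = length(sn)),
    variable = rep(sn, each = length(traj@times)),
    value = as.vector(traj@states),
    stringsAsFactors = FALSE
  )
}

#' Rebuild a trajectory from tidy data
#'
#' Inverse of [trajectoryToTidy()]: assembles the state matrix from a tidy
#' (time, variable, value) table and recomputes the derivatives with
#' [kineticRHS()] under the supplied parameters, so that exported
#' trajectories can re-enter the dynamic-FBA pipeline.
#'
#' @param data data.frame with columns `time`, `variable`, `value` covering
#'   every kinetic state.
#' @param params The [KineticParameters] the trajectory was produced with.
#' @return A [KineticTrajectory].
#' @export
trajectoryFromTidy <- function(data, params) {
  need <- c("time", "variable", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns time, variable, value")
  times <- sort(unique(data$time))
  sn <- kineticStateNames()
  miss <- setdiff(sn, unique(data$variable))
  if (length(miss))
    stop("missing state variables: ", paste(miss, collapse = ", "))
  states <- matrix(NA_real_, length(times), length(sn),
                   dimnames = list(NULL, sn))
  for (nm in sn) {
    d <- data[data$variable == nm, ]
    states[, nm] <- d$value[match(times, d$time)]
  }
  if (anyNA(states)) stop("incomplete state grid in tidy data")
  cp <- .compileParams(params)
  derivs <- t(vapply(seq_along(times), function(i)
    .rhsCore(times[i], states[i, ], cp), numeric(ncol(states))))
  colnames(derivs) <- sn
  new("KineticTrajectory", times = as.numeric(times), states = states,
      derivatives = derivs, params = params)
}
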