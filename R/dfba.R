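#' Exchange-reaction bounds from kinetic derivatives
#'
#' Converts kinetic derivatives into specific exchange fluxes at time `t`:
#' `v = (d[compound]/dt) / (MW * X(t)) * 1000` in mmol/(gDW h), with uptake
#' negative and secretion positive (COBRA convention). Equality-class
#' compounds fix both bounds at `v`; inequality-class compounds (noisier
#' measurements) keep the direction but relax the magnitude floor: secretion
#' gets bounds (0, v), uptake gets (v, 0). The biomass drain is bounded by
#' the specific growth rate `(dX/dt) / X`.
#'
#' @param t Time (h) within the trajectory.
#' @param traj A [KineticTrajectory].
#' @param cmap A [compoundMap()].
#' @param network Optional [MetabolicNetwork] for reaction validation.
#' @return data.frame (`reaction`, `lower`, `upper`, `provenance`) — the
#'   bound set at `t`; unmapped reactions keep model-default bounds.
#' @export
exchangeBoundsAt <- function(t, traj, cmap, network = NULL) {
  stopifnot(inherits(cmap, "compoundMap"))
  st <- stateAt(traj, t)
  dv <- derivativeAt(traj, t)
  X <- st[["X"]]
  if (X <= 0) stop("biomass X(t) must be > 0 at t = ", t)
  if (!is.null(network)) {
    bad <- setdiff(cmap$reaction, networkRoles(network)$exchanges)
    if (length(bad))
      stop("mapped reactions missing from network: ",
           paste(bad, collapse = ", "))
  }
  v <- dv[cmap$state] / (cmap$mw * X) * 1000
  lower <- upper <- v
  prov <- rep("equality-constrained", length(v))
  ineq <- cmap$class == "inequality"
  lower[ineq & v >= 0] <- 0              # secretion floor relaxed to 0
  upper[ineq & v < 0] <- 0               # uptake ceiling relaxed to 0
  prov[ineq] <- "inequality-relaxed"
  out <- data.frame(reaction = cmap$reaction, lower = lower, upper = upper,
                    provenance = prov, stringsAsFactors = FALSE)
  if (!is.null(network)) {
    mu <- dv[["X"]] / X
    out <- rbind(out, data.frame(reaction = networkRoles(network)$biomass,
                                 lower = mu, upper = mu,
                                 provenance = "equality-constrained"))
  }
  rownames(out) <- NULL
  out
}

#' Time-varying cellular objective weights
#'
#' The dFBA objective trades ATP maintenance against protein synthesis as
#' nitrogen depletes: weight `1 - phiNS` on the ATP-hydrolysis flux and
#' `phiNS` on the protein-synthesis flux, continuous along the trajectory.
#'
#' @param t Time (h).
#' @param traj A [KineticTrajectory].
#' @return list with elements `atp` and `protein` (summing to 1).
#' @export
objectiveAt <- function(t, traj) {
  v <- parameterValues(kineticParams(traj))
  yan <- max(stateAt(traj, t)[["YAN"]], 0)
  phi <- phiNS(yan, v[["ksC"]])
  list(atp = 1 - phi, protein = phi)
}

# Merge a bound-set data.frame into the network's bound vectors.
.applyBoundSet <- function(network, bounds) {
  lb <- network@lowerBounds; ub <- network@upperBounds
  names(lb) <- names(ub) <- network@reactions
  if (!is.null(bounds) && nrow(bounds)) {
    idx <- match(bounds$reaction, network@reactions)
    if (anyNA(idx))
      stop("unknown reactions in bound set: ",
           paste(bounds$reaction[is.na(idx)], collapse = ", "))
    lb[idx] <- bounds$lower
    ub[idx] <- bounds$upper
  }
  list(lb = unname(lb), ub = unname(ub))
}

# Substitute out variables fixed by lb == ub and drop vacuous rows.
# Returns NULL status "infeasible" when a fully-fixed row is violated.
.presolve <- function(S, lb, ub, tol = 1e-9) {
  fixed <- which(ub - lb <= tol)
  free <- setdiff(seq_along(lb), fixed)
  vfix <- (lb[fixed] + ub[fixed]) / 2
  beq <- if (length(fixed)) -as.vector(S[, fixed, drop = FALSE] %*% vfix)
  else rep(0, nrow(S))
  Sred <- as.matrix(S[, free, drop = FALSE])
  vac <- apply(abs(Sred), 1, max) < 1e-12
  if (any(vac & abs(beq) > 1e-6))
    return(list(infeasible = TRUE))
  list(infeasible = FALSE, free = free, fixed = fixed, vfix = vfix,
       S = Sred[!vac, , drop = FALSE], beq = beq[!vac])
}

# Stage-1 objective vector over all reactions.
.objectiveVector <- function(network, weights) {
  obj <- numeric(length(network@reactions))
  names(obj) <- network@reactions
  obj[networkRoles(network)$atpMaintenance] <- weights$atp *
    (weights$scaleAtp %||% 1)
  obj[networkRoles(network)$proteinSynthesis] <- weights$protein *
    (weights$scaleProtein %||% 1)
  unname(obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parsimonious flux balance analysis
#'
#' Two-stage solve: (1) maximize the weighted objective (ATP maintenance and
#' protein synthesis per [objectiveAt()]) subject to `S v = 0` and the
#' bounds; (2) fix the objective at `optFraction` of its optimum and
#' minimize total absolute flux via a positive/negative variable split.
#' Variables fixed by equality bounds are substituted out before solving.
#'
#' @param network A [MetabolicNetwork].
#' @param bounds Optional bound-set data.frame from [exchangeBoundsAt()].
#' @param weights list with `atp` and `protein` weights (and optional
#'   `scaleAtp`, `scaleProtein` normalization constants, default 1).
#' @param optFraction Fraction of the stage-1 optimum enforced in stage 2
#'   (default `1 - 1e-6`).
#' @return Named flux vector with attributes `objective` (stage-1 value),
#'   `sumAbs` (total absolute flux) and `status`; infeasible problems raise
#'   an error carrying the bound set.
#' @export
pfba <- function(network, bounds = NULL,
                 weights = list(atp = 1, protein = 0),
                 optFraction = 1 - 1e-6) {
  b <- .applyBoundSet(network, bounds)
  res <- .pfbaCore(network, b$lb, b$ub, weights, optFraction)
  if (res$status != "optimal")
    stop("pFBA ", res$status,
         if (!is.null(bounds)) paste0(
           " (bound set: ",
           paste(bounds$reaction, signif(bounds$lower, 4),
                 signif(bounds$upper, 4), collapse = "; "), ")"))
  v <- res$flux
  names(v) <- network@reactions
  attr(v, "objective") <- res$objective
  attr(v, "sumAbs") <- res$sumAbs
  attr(v, "status") <- res$status
  v
}

# Core two-stage solve on explicit bound vectors; returns a status rather
# than raising, so the dFBA relaxation ladder can react.
.pfbaCore <- function(network, lb, ub, weights, optFraction) {
  S <- network@S
  m <- length(lb)
  objFull <- .objectiveVector(network, weights)

  pre <- .presolve(S, lb, ub)
  if (pre$infeasible)
    return(list(status = "infeasible"))
  nf <- length(pre$free)
  full <- function(vfree) {
    v <- numeric(m)
    v[pre$fixed] <- pre$vfix
    v[pre$free] <- vfree
    v
  }
  objFixedPart <- sum(objFull[pre$fixed] * pre$vfix)

  if (nf == 0) {
    v <- full(numeric(0))
    resid <- max(abs(as.vector(S %*% v)))
    if (resid > 1e-6) return(list(status = "infeasible"))
    return(list(status = "optimal", flux = v, objective = objFixedPart,
                sumAbs = sum(abs(v))))
  }

  lbf <- lb[pre$free]; ubf <- ub[pre$free]
  s1 <- solveLP(objFull[pre$free], Aeq = pre$S, beq = pre$beq,
                lb = lbf, ub = ubf, maximize = TRUE)
  if (s1$status != "optimal") return(list(status = s1$status))
  opt <- s1$value + objFixedPart

  # stage 2: variables straddling zero are split as v = p - n (the original
  # column keeps p, a negated copy carries n); one-sided variables keep a
  # signed cost coefficient instead
  splitI <- which(lbf < -1e-12 & ubf > 1e-12)
  nSplit <- length(splitI)
  nVar <- nf + nSplit
  cost <- numeric(nVar)
  cost[seq_len(nf)] <- ifelse(ubf <= 1e-12, -1, 1)   # |v| = -v when v <= 0
  lb2 <- c(lbf, rep(0, nSplit))
  ub2 <- c(ubf, pmax(-lbf[splitI], 0))
  if (nSplit) {
    cost[splitI] <- 1                 # p part of |v|
    cost[nf + seq_len(nSplit)] <- 1   # n part of |v|
    lb2[splitI] <- 0                  # p >= 0
  }
  # map split vars back into equalities: column of n is -column of p
  Aeq2 <- cbind(pre$S, -pre$S[, splitI, drop = FALSE])
  objRow <- c(objFull[pre$free],
              -objFull[pre$free][splitI])
  thr <- (opt - objFixedPart) - (abs(opt) + 1e-9) * (1 - optFraction)
  s2 <- solveLP(cost, Aeq = Aeq2, beq = pre$beq,
                Aineq = matrix(-objRow, 1), bineq = -thr,
                lb = lb2, ub = ub2, maximize = FALSE)
  if (s2$status != "optimal") {
    # stage-2 numerical failure: fall back to the stage-1 vertex
    v <- full(s1$x)
    return(list(status = "optimal", flux = v, objective = opt,
                sumAbs = sum(abs(v))))
  }
  vfree <- s2$x[seq_len(nf)]
  if (nSplit) vfree[splitI] <- vfree[splitI] - s2$x[nf + seq_len(nSplit)]
  v <- full(vfree)
  list(status = "optimal", flux = v, objective = opt, sumAbs = sum(abs(v)))
}

#' Flux variability analysis
#'
#' Per-reaction flux ranges at (at least) `optFraction` of the weighted
#' objective optimum, used as a sanity check on how much parsimonious FBA
#' narrows the solution space.
#'
#' @inheritParams pfba
#' @param reactions Reactions to scan (default all).
#' @return data.frame (`reaction`, `min`, `max`).
#' @export
fva <- function(network, bounds = NULL, weights = list(atp = 1, protein = 0),
                optFraction = 1 - 1e-6, reactions = NULL) {
  b <- .applyBoundSet(network, bounds)
  S <- network@S
  objFull <- .objectiveVector(network, weights)
  pre <- .presolve(S, b$lb, b$ub)
  if (pre$infeasible) stop("FVA infeasible")
  if (is.null(reactions)) reactions <- network@reactions
  idxAll <- match(reactions, network@reactions)
  if (anyNA(idxAll)) stop("unknown reactions in FVA request")

  lbf <- b$lb[pre$free]; ubf <- b$ub[pre$free]
  s1 <- solveLP(objFull[pre$free], Aeq = pre$S, beq = pre$beq,
                lb = lbf, ub = ubf, maximize = TRUE)
  if (s1$status != "optimal") stop("FVA ", s1$status)
  objFixedPart <- sum(objFull[pre$fixed] * pre$vfix)
  opt <- s1$value + objFixedPart
  thr <- (opt - objFixedPart) - (abs(opt) + 1e-9) * (1 - optFraction)
  AineqRow <- matrix(-objFull[pre$free], 1)

  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(idxAll)) {
    j <- idxAll[k]
    if (j %in% pre$fixed) {
      vf <- pre$vfix[match(j, pre$fixed)]
      out$min[k] <- vf; out$max[k] <- vf
      next
    }
    e <- numeric(length(pre$free))
    e[match(j, pre$free)] <- 1
    for (dir in c("min", "max")) {
      s <- solveLP(e, Aeq = pre$S, beq = pre$beq,
                   Aineq = AineqRow, bineq = -thr,
                   lb = lbf, ub = ubf, maximize = dir == "max")
      if (s$status != "optimal") stop("FVA ", s$status, " for ", reactions[k])
      out[[dir]][k] <- s$value
    }
  }
  out
}

#' Run the dynamic parsimonious FBA over a kinetic trajectory
#'
#' At each output time: build the exchange bounds from the kinetic
#' derivatives, wire the growth-associated ATP maintenance into the network,
#' evaluate the time-varying objective weights and solve a parsimonious FBA.
#' No information flows back from the fluxes to the kinetic states — the
#' kinetic model fully determines the constraints (decoupled architecture).
#' Infeasible steps go through a relaxation ladder: inequality-class bounds
#' are widened by each factor in `relaxFactors` in turn, then
#' equality-class bounds are opened to a relative `equalityEps` window;
#' every relaxation is logged.
#'
#' @param traj A [KineticTrajectory] (calibrated kinetics).
#' @param network A [MetabolicNetwork] with roles resolved.
#' @param cmap A [compoundMap()].
#' @param gam A [gamSpec()] wired into the network (NULL to skip).
#' @param times Output time grid (default: uniform 0.5 h steps over the
#'   trajectory, excluding t = 0 where biomass bounds are ill-conditioned).
#' @param optFraction Passed to the per-step pFBA.
#' @param relaxFactors Widening factors for inequality bounds.
#' @param equalityEps Relative half-width for the final equality relaxation.
#' @param scaleAtp,scaleProtein Objective normalization constants.
#' @return A [FluxTrajectory].
#' @export
runDFBA <- function(traj, network, cmap, gam = gamSpec(), times = NULL,
                    optFraction = 1 - 1e-6, relaxFactors = c(2, 10),
                    equalityEps = 0.05, scaleAtp = 1, scaleProtein = 1) {
  stopifnot(is(traj, "KineticTrajectory"), is(network, "MetabolicNetwork"))
  if (is.null(times)) {
    tr <- range(sampleTimes(traj))
    times <- seq(tr[1] + 0.5, tr[2], by = 0.5)
  }
  if (!is.null(gam)) network <- applyGam(network, gam)

  m <- length(network@reactions)
  fluxes <- matrix(NA_real_, length(times), m,
                   dimnames = list(NULL, network@reactions))
  objv <- phis <- dw <- numeric(length(times))
  status <- character(length(times))
  relaxLog <- data.frame(time = numeric(), action = character())

  for (i in seq_along(times)) {
    t <- times[i]
    bs <- exchangeBoundsAt(t, traj, cmap, network)
    w <- objectiveAt(t, traj)
    w$scaleAtp <- scaleAtp; w$scaleProtein <- scaleProtein
    b <- .applyBoundSet(network, bs)
    res <- .pfbaCore(network, b$lb, b$ub, w, optFraction)

    if (res$status != "optimal") {
      ineq <- bs$provenance == "inequality-relaxed"
      for (f in relaxFactors) {
        bsR <- bs
        bsR$lower[ineq] <- ifelse(bs$lower[ineq] < 0,
                                  bs$lower[ineq] * f, bs$lower[ineq])
        bsR$upper[ineq] <- ifelse(bs$upper[ineq] > 0,
                                  bs$upper[ineq] * f, bs$upper[ineq])
        bR <- .applyBoundSet(network, bsR)
        res <- .pfbaCore(network, bR$lb, bR$ub, w, optFraction)
        if (res$status == "optimal") {
          relaxLog <- rbind(relaxLog, data.frame(
            time = t, action = paste0("inequality-widened-x", f)))
          break
        }
      }
    }
    if (res$status != "optimal") {
      eq <- bs$provenance == "equality-constrained"
      eps <- equalityEps * pmax(abs(bs$lower), 1e-3)
      bsR <- bs
      bsR$lower[eq] <- bs$lower[eq] - eps[eq]
      bsR$upper[eq] <- bs$upper[eq] + eps[eq]
      bR <- .applyBoundSet(network, bsR)
      res <- .pfbaCore(network, bR$lb, bR$ub, w, optFraction)
      if (res$status == "optimal")
        relaxLog <- rbind(relaxLog, data.frame(
          time = t, action = "equality-opened"))
    }
    if (res$status != "optimal")
      stop("dFBA step failed at t = ", t, " h (", res$status, ")")

    fluxes[i, ] <- res$flux
    objv[i] <- res$objective
    status[i] <- res$status
    phis[i] <- w$protein
    dw[i] <- stateAt(traj, t)[["X"]]
  }

  hexoseStates <- c("Glx", "F")
  hexRxn <- cmap$reaction[match(hexoseStates, cmap$state)]
  if (anyNA(hexRxn))
    stop("compound map must map both hexoses (Glx, F)")
  new("FluxTrajectory", times = times, fluxes = fluxes, objective = objv,
      status = status, dw = dw, phiNS = phis, hexoseReactions = hexRxn,
      relaxLog = relaxLog)
}

#' @rdname FluxTrajectory-class
#' @export
setMethod("fluxMatrix", "FluxTrajectory", function(x) x@fluxes)

#' @rdname FluxTrajectory-class
#' @export
setMethod("lpStatus", "FluxTrajectory", function(x) x@status)

#' @rdname FluxTrajectory-class
#' @export
setMethod("biomassSeries", "FluxTrajectory", function(x) x@dw)

#' @rdname FluxTrajectory-class
#' @export
setMethod("sampleTimes", "FluxTrajectory", function(x) x@times)

setMethod("show", "FluxTrajectory", function(object) {
  cat("FluxTrajectory:", length(object@times), "steps,",
      ncol(object@fluxes), "reactions;",
      sum(object@status == "optimal"), "optimal\n")
  if (nrow(object@relaxLog))
    cat("  relaxations applied:", nrow(object@relaxLog), "\n")
})
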