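#' Names of the kinetic state variables
#'
#' The continuous multiphase model tracks 41 ordinary differential equations:
#' total biomass `X` (whose derivative is defined as the sum of the three
#' biomass component derivatives, so it is never independent), the biomass
#' components `XC` (carbohydrate), `XP` (protein) and `XmRNA`, assimilable
#' nitrogen `YAN`, ammonium and the 18 assimilated amino acids, sucrose,
#' glucose (`Glx`), fructose (`F`), the regulatory state `GNS`, the primary
#' metabolites (ethanol, glycerol, acetate, succinate, lactate, malate) and
#' seven secondary metabolites (acetate esters, higher alcohols and
#' 2,3-butanediol). All concentrations are g/L except `YAN` (gN/L) and `GNS`
#' (dimensionless).
#'
#' @return Character vector of length 41.
#' @export
kineticStateNames <- function() {
  c("X", "XC", "XP", "XmRNA", "YAN", "NH4Cl",
    aminoAcidNames(),
    "Sucrose", "Glx", "F", "GNS",
    "Eth", "Glycerol", "Ace", "Succ", "Lac", "Mal",
    secondaryProductNames())
}

#' Names of the secondary metabolite states
#'
#' Ethyl acetate, isoamyl acetate, phenyl ethyl acetate, isobutanol, isoamyl
#' alcohol, 2,3-butanediol and 2-phenyl ethanol.
#'
#' @return Character vector of length 7.
#' @export
secondaryProductNames <- function() {
  c("EthylA", "IamoA", "PEA", "Iobut", "Iamo", "BDO", "PE")
}

.VARIANTS <- c("proportional", "regulated_decline", "nitrogen_delayed",
               "nitrogen_delayed_repressed")

# Parameters that are structural switches rather than estimable kinetics.
.STRUCTURAL_PARAMS <- c("lambdaC", "lambdaP", "kD", "phiEDmid", "phiEDslope",
                        "delta")

#' Kinetic model parameters
#'
#' Container for the rate, yield and regulation parameters of the multiphase
#' kinetic model, the structural switches (biomass fractions, decay,
#' must-type switch `delta`), the per-product production-model variants and
#' the set of parameters flagged as estimable for calibration.
#'
#' @slot values Named numeric vector of parameter values.
#' @slot variants Named character vector mapping each secondary product to a
#'   production-model variant (`"proportional"`, `"regulated_decline"`,
#'   `"nitrogen_delayed"` or `"nitrogen_delayed_repressed"`).
#' @slot estimable Character vector of parameter names to be estimated during
#'   calibration; the remainder are held fixed.
#' @aliases parameterValues productVariants estimableParameters
#' @export
setClass("KineticParameters",
         representation(values = "numeric",
                        variants = "character",
                        estimable = "character"))

setValidity("KineticParameters", function(object) {
  v <- object@values
  msg <- character()
  req <- c("lambdaC", "lambdaP", "kD", "delta", "a0", "muMaxN", "YxN",
           "tauGNS", "ThetaC", "PhiC", "ksC", "ksS",
           "vmaxGlx", "vmaxF", "ksGlx", "ksF", "alpha", "kSucrose",
           "kNH4Cl", paste0("kAA.", aminoAcidNames()),
           "YEth", "YGlycerol", "YAce", "YSucc", "YLac",
           paste0("Y", secondaryProductNames()),
           "kcAce", "kcSucc", "kcMal")
  miss <- setdiff(req, names(v))
  if (length(miss))
    msg <- c(msg, paste("missing parameters:", paste(miss, collapse = ", ")))
  else {
    if (v[["lambdaC"]] + v[["lambdaP"]] > 1 + 1e-12)
      msg <- c(msg, "lambdaC + lambdaP must be <= 1")
    if (!v[["delta"]] %in% c(0, 1))
      msg <- c(msg, "delta must be 0 or 1")
    if (v[["a0"]] <= 0 || v[["a0"]] > 1)
      msg <- c(msg, "a0 must lie in (0, 1]")
    nonneg <- setdiff(req, c("delta"))
    if (any(v[nonneg] < 0))
      msg <- c(msg, "rate and yield parameters must be >= 0")
  }
  if (!all(secondaryProductNames() %in% names(object@variants)))
    msg <- c(msg, "variants must cover every secondary product")
  if (!all(object@variants %in% .VARIANTS))
    msg <- c(msg, paste("variants must be one of:",
                        paste(.VARIANTS, collapse = ", ")))
  bad <- setdiff(object@estimable, names(v))
  if (length(bad))
    msg <- c(msg, paste("unknown estimable parameters:",
                        paste(bad, collapse = ", ")))
  if (length(intersect(object@estimable, .STRUCTURAL_PARAMS)))
    msg <- c(msg, "structural switches cannot be estimable")
  if (length(msg)) msg else TRUE
})

#' Kinetic trajectory
#'
#' Dense solution of the kinetic ODE system on a time grid, together with the
#' right-hand-side evaluations at the stored states and the parameters used.
#'
#' @slot times Numeric vector of time points (h), strictly increasing.
#' @slot states Matrix (time x 41) of state values.
#' @slot derivatives Matrix (time x 41) of d(state)/dt evaluations.
#' @slot params The [KineticParameters] used for the integration.
#' @aliases sampleTimes stateMatrix derivativeMatrix kineticParams
#' @export
setClass("KineticTrajectory",
         representation(times = "numeric",
                        states = "matrix",
                        derivatives = "matrix",
                        params = "KineticParameters"))

setValidity("KineticTrajectory", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n < 2) msg <- c(msg, "at least two time points required")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!identical(dim(object@states), dim(object@derivatives)))
    msg <- c(msg, "states and derivatives must have identical dimensions")
  if (nrow(object@states) != n)
    msg <- c(msg, "states must have one row per time point")
  if (!identical(colnames(object@states), kineticStateNames()))
    msg <- c(msg, "state columns must match kineticStateNames()")
  if (length(msg)) msg else TRUE
})

#' Fermentation phase schedule
#'
#' Boundaries of the four phases detected from a kinetic trajectory: lag,
#' exponential growth (ends when assimilable nitrogen is depleted),
#' growth-no-growth transition (ends when total growth becomes numerically
#' null) and stationary.
#'
#' @slot tLagEnd,tGrowthEnd,tGngEnd,tFinal Phase boundaries (h), ordered.
#' @slot flags Character vector of degeneracy warnings (e.g. nitrogen never
#'   depleted within the horizon).
#' @aliases phaseTable
#' @export
setClass("PhaseSchedule",
         representation(tLagEnd = "numeric", tGrowthEnd = "numeric",
                        tGngEnd = "numeric", tFinal = "numeric",
                        flags = "character"))

setValidity("PhaseSchedule", function(object) {
  b <- c(object@tLagEnd, object@tGrowthEnd, object@tGngEnd, object@tFinal)
  if (any(is.na(b))) return("phase boundaries must be finite")
  if (b[1] < 0 || any(diff(b) < -1e-9))
    return("phase boundaries must satisfy 0 <= lag <= growth <= gng <= final")
  TRUE
})

#' Constraint-based metabolic network
#'
#' Stoichiometric matrix with flux bounds and designated reaction roles
#' (biomass drain, ATP maintenance, protein synthesis, exchanges). Carbon
#' content per metabolite may be attached for elemental balance checks (NA
#' for pseudo-metabolites that are not elementally defined).
#'
#' @slot S Sparse stoichiometric matrix (metabolites x reactions).
#' @slot lowerBounds,upperBounds Numeric flux bounds, mmol/(gDW h).
#' @slot reactions,metabolites Identifier vectors.
#' @slot roles Named list with entries `biomass`, `atpMaintenance`,
#'   `proteinSynthesis` (single reaction ids) and `exchanges` (character
#'   vector); optional entries `carbSynthesis`, `rnaSynthesis`,
#'   `storageBiomass`.
#' @slot carbon Numeric vector of mmol carbon per unit of each metabolite
#'   (NA when undefined).
#' @aliases reactionIds metaboliteIds stoichMatrix fluxBounds networkRoles
#' @export
setClass("MetabolicNetwork",
         representation(S = "Matrix",
                        lowerBounds = "numeric", upperBounds = "numeric",
                        reactions = "character", metabolites = "character",
                        roles = "list", carbon = "numeric"))

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  m <- length(object@reactions)
  n <- length(object@metabolites)
  if (!identical(dim(object@S), c(n, m)))
    msg <- c(msg, "S must be metabolites x reactions")
  if (anyDuplicated(object@reactions))
    msg <- c(msg, "duplicate reaction ids")
  if (anyDuplicated(object@metabolites))
    msg <- c(msg, "duplicate metabolite ids")
  if (length(object@lowerBounds) != m || length(object@upperBounds) != m)
    msg <- c(msg, "bounds must have one entry per reaction")
  else if (any(object@lowerBounds > object@upperBounds + 1e-12))
    msg <- c(msg, "lower bounds must not exceed upper bounds")
  for (role in c("biomass", "atpMaintenance", "proteinSynthesis")) {
    id <- object@roles[[role]]
    if (is.null(id) || length(id) != 1 || !id %in% object@reactions)
      msg <- c(msg, sprintf(
        "role '%s' must name exactly one existing reaction", role))
  }
  ex <- object@roles[["exchanges"]]
  if (is.null(ex) || !all(ex %in% object@reactions))
    msg <- c(msg, "role 'exchanges' must list existing reactions")
  if (length(object@carbon) && length(object@carbon) != n)
    msg <- c(msg, "carbon must have one entry per metabolite")
  if (length(msg)) msg else TRUE
})

#' Flux trajectory from dynamic FBA
#'
#' Per-time-point flux vectors from the dynamic parsimonious FBA, with the
#' stage-1 objective value, LP status, relaxation log, objective weights and
#' the biomass dry weight carried over from the kinetic trajectory.
#'
#' @slot times Numeric vector (h).
#' @slot fluxes Matrix (time x reaction), mmol/(gDW h).
#' @slot objective Numeric stage-1 objective value per time point.
#' @slot status Character LP status per time point.
#' @slot dw Numeric biomass dry weight per time (g, unit broth volume).
#' @slot phiNS Numeric nitrogen-regulator value per time (objective weight on
#'   protein synthesis).
#' @slot hexoseReactions Character ids of the glucose and fructose exchange
#'   reactions (denominator of flux scores).
#' @slot relaxLog data.frame of bound relaxations applied (possibly empty).
#' @aliases fluxMatrix lpStatus biomassSeries
#' @export
setClass("FluxTrajectory",
         representation(times = "numeric", fluxes = "matrix",
                        objective = "numeric", status = "character",
                        dw = "numeric", phiNS = "numeric",
                        hexoseReactions = "character",
                        relaxLog = "data.frame"))

setValidity("FluxTrajectory", function(object) {
  msg <- character()
  n <- length(object@times)
  if (nrow(object@fluxes) != n)
    msg <- c(msg, "fluxes must have one row per time point")
  if (length(object@status) != n || length(object@dw) != n)
    msg <- c(msg, "status and dw must have one entry per time point")
  if (length(object@hexoseReactions) != 2)
    msg <- c(msg, "two hexose exchange reactions required")
  if (length(msg)) msg else TRUE
})

#' Phase-resolved flux score table
#'
#' Flux scores (FS, mmol per mmol hexose x 100) and duration-normalized flux
#' scores (NFS, per hour) per reaction and phase.
#'
#' @slot FS,NFS Matrices (reaction x phase).
#' @slot phases data.frame with columns `phase`, `start`, `end` (h).
#' @aliases fsMatrix nfsMatrix
#' @export
setClass("FluxScoreTable",
         representation(FS = "matrix", NFS = "matrix", phases = "data.frame"))

setValidity("FluxScoreTable", function(object) {
  msg <- character()
  if (!identical(dim(object@FS), dim(object@NFS)))
    msg <- c(msg, "FS and NFS must have identical dimensions")
  if (ncol(object@FS) != nrow(object@phases))
    msg <- c(msg, "one FS column per phase required")
  dur <- object@phases$end - object@phases$start
  if (any(dur <= 0)) msg <- c(msg, "phase durations must be positive")
  if (length(msg)) msg else TRUE
})

#' Replicate-resolved fermentation time-series dataset
#'
#' Tidy measurements (time, observable, replicate, value) with an
#' observable-to-state mapping and per-point means and floored standard
#' deviations used as weights in the calibration cost.
#'
#' @slot data data.frame with columns `time`, `observable`, `replicate`,
#'   `value`.
#' @slot mapping Named character vector: observable name -> kinetic state
#'   name.
#' @slot summary data.frame with per (time, observable) `mean`, `sd` and the
#'   floored `sigma` used for weighting.
#' @slot sigmaFloorFrac Fraction of each observable's maximum used as the
#'   standard-deviation floor.
#' @export
setClass("FermentationDataset",
         representation(data = "data.frame", mapping = "character",
                        summary = "data.frame", sigmaFloorFrac = "numeric"))

setValidity("FermentationDataset", function(object) {
  msg <- character()
  need <- c("time", "observable", "replicate", "value")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, "data must have columns time, observable, replicate, value")
  if (!all(unique(object@data$observable) %in% names(object@mapping)))
    msg <- c(msg, "every observable must be mapped to a state")
  if (!all(object@mapping %in% kineticStateNames()))
    msg <- c(msg, "mapping targets must be kinetic state names")
  if (any(object@summary$sigma <= 0))
    msg <- c(msg, "floored sigma must be positive")
  if (length(msg)) msg else TRUE
})

#' Calibration fit result
#'
#' @slot params [KineticParameters] at the optimum.
#' @slot theta Named numeric vector of estimated parameter values.
#' @slot cost Weighted log-likelihood cost at the optimum.
#' @slot trace data.frame of multistart results (start id, converged cost).
#' @slot seed Integer seed used.
#' @slot init Named numeric initial state used for simulation.
#' @export
setClass("FitResult",
         representation(params = "KineticParameters", theta = "numeric",
                        cost = "numeric", trace = "data.frame",
                        seed = "integer", init = "numeric"))
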