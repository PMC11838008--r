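.defaultVariants <- function() {
  c(EthylA = "nitrogen_delayed",
    IamoA = "nitrogen_delayed",
    PEA = "nitrogen_delayed_repressed",
    Iobut = "nitrogen_delayed",
    Iamo = "nitrogen_delayed",
    BDO = "nitrogen_delayed_repressed",
    PE = "nitrogen_delayed_repressed")
}

.defaultParameterValues <- function() {
  v <- c(
    lambdaC = 0.29, lambdaP = 0.59,        # biomass fractions (Schulze-type)
    kD = 0,                                 # decay off in the parsimonious model
    phiEDmid = 77, phiEDslope = 0.2,        # ethanol-decay logistic (kD > 0 only)
    delta = 1,                              # 1 = synthetic must, 0 = natural must
    YxN = 8,                                # gDW per gN
    kNH4Cl = 0.3,                           # 1/(gprot h)
    vmaxGlx = 1.0, vmaxF = 0.85,            # g/(gprot h)
    ksGlx = 1.0, ksF = 1.2,                 # g/L
    alpha = 5,                              # transporter induction gain
    kSucrose = 0,                           # 1/h
    tauGNS = 0.1,                           # 1/h
    a0 = 0.1, muMaxN = 0.3,                 # lag model
    ThetaC = 0.45, PhiC = 0.01,             # carbohydrate set point / gain
    ksC = 0.01,                             # gN/L
    ksS = 10,                               # g/L
    YEth = 0.45, YGlycerol = 0.05, YAce = 0.01, YSucc = 0.005, YLac = 0.002,
    YEthylA = 4e-4, YIamoA = 4e-5, YPEA = 2e-5, YIobut = 4e-4,
    YIamo = 2.5e-3, YBDO = 4e-3, YPE = 2e-3,
    kcAce = 0.005, kcSucc = 0.001, kcMal = 0.002
  )
  kaa <- rep(0.15, length(aminoAcidNames()))
  names(kaa) <- paste0("kAA.", aminoAcidNames())
  # arginine and glutamine are the preferred nitrogen sources
  kaa[c("kAA.Arg", "kAA.Gln")] <- 0.4
  kaa[c("kAA.Cys", "kAA.Gly")] <- 0.02
  c(v, kaa)
}

.defaultEstimable <- function(values = .defaultParameterValues()) {
  setdiff(names(values), .STRUCTURAL_PARAMS)
}

#' Construct a kinetic parameter set
#'
#' Builds a [KineticParameters] object from the package defaults, overriding
#' any named value. Structural switches (`lambdaC`, `lambdaP`, `kD`, `delta`,
#' the ethanol-decay shape) are parameters too but are excluded from the
#' default estimable set; which parameters are estimable is always explicit
#' and configurable.
#'
#' @param ... Named numeric overrides of default parameter values.
#' @param variants Named character vector of production-model variants for
#'   the secondary products (defaults: esters and isobutanol delayed until
#'   nitrogen depletion; phenyl ethyl acetate, 2-phenyl ethanol and
#'   2,3-butanediol additionally repressed during the stationary phase).
#' @param estimable Character vector of estimable parameter names; defaults
#'   to every non-structural parameter.
#' @return A validated [KineticParameters] object.
#' @export
#' @examples
#' p <- kineticParameters(vmaxGlx = 1.2, delta = 0)
#' length(estimableParameters(p))
kineticParameters <- function(..., variants = .defaultVariants(),
                              estimable = NULL) {
  values <- .defaultParameterValues()
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(values))
    if (length(unknown))
      stop("unknown parameters: ", paste(unknown, collapse = ", "))
    values[names(over)] <- over
  }
  vv <- .defaultVariants()
  vv[names(variants)] <- variants
  if (is.null(estimable)) estimable <- .defaultEstimable(values)
  new("KineticParameters", values = values, variants = vv,
      estimable = estimable)
}

#' Update parameter values
#'
#' @param params A [KineticParameters] object.
#' @param theta Named numeric vector of values to set.
#' @return The updated object.
#' @export
setParameterValues <- function(params, theta) {
  stopifnot(is(params, "KineticParameters"))
  unknown <- setdiff(names(theta), names(params@values))
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  params@values[names(theta)] <- theta
  validObject(params)
  params
}

#' @rdname KineticParameters-class
#' @export
setMethod("parameterValues", "KineticParameters", function(x) x@values)

#' @rdname KineticParameters-class
#' @export
setMethod("productVariants", "KineticParameters", function(x) x@variants)

#' @rdname KineticParameters-class
#' @export
setMethod("estimableParameters", "KineticParameters", function(x) x@estimable)

setMethod("show", "KineticParameters", function(object) {
  cat("KineticParameters:", length(object@values), "parameters (",
      length(object@estimable), "estimable )\n")
  cat("  delta =", object@values[["delta"]],
      "| kD =", object@values[["kD"]],
      "| lambdaC/lambdaP =", object@values[["lambdaC"]], "/",
      object@values[["lambdaP"]], "\n")
  cat("  variants:", paste(names(object@variants), object@variants,
                           sep = "=", collapse = ", "), "\n")
})

#' Construct an initial state for the kinetic model
#'
#' Assembles a full named state vector. Assimilable nitrogen `YAN` is derived
#' from the ammonium and amino-acid concentrations (nitrogen mass fractions
#' from [aminoAcidTable()]); total biomass `X` is derived from its
#' components.
#'
#' @param biomass Initial total biomass (gDW/L), split across components
#'   according to `lambdaC`/`lambdaP`.
#' @param Glx,F,Sucrose Initial sugars (g/L).
#' @param NH4Cl Initial ammonium chloride (g/L).
#' @param aminoAcids Named numeric vector of initial amino-acid
#'   concentrations (g/L); unnamed acids default to 0.
#' @param params [KineticParameters] supplying the biomass fractions.
#' @return Named numeric vector over [kineticStateNames()].
#' @export
#' @examples
#' s0 <- initialState(biomass = 0.05, Glx = 100, F = 100,
#'                    NH4Cl = 0.4, aminoAcids = c(Glu = 1.5))
#' s0[["YAN"]]
initialState <- function(biomass = 0.05, Glx = 100, F = 100, Sucrose = 0,
                         NH4Cl = 0.4, aminoAcids = NULL,
                         params = kineticParameters()) {
  v <- parameterValues(params)
  s <- stats::setNames(numeric(length(kineticStateNames())),
                       kineticStateNames())
  s["XC"] <- v[["lambdaC"]] * biomass
  s["XP"] <- v[["lambdaP"]] * biomass
  s["XmRNA"] <- (1 - v[["lambdaC"]] - v[["lambdaP"]]) * biomass
  s["X"] <- biomass
  s["Glx"] <- Glx; s["F"] <- F; s["Sucrose"] <- Sucrose
  s["NH4Cl"] <- NH4Cl
  if (!is.null(aminoAcids)) {
    unknown <- setdiff(names(aminoAcids), aminoAcidNames())
    if (length(unknown))
      stop("unknown amino acids: ", paste(unknown, collapse = ", "))
    s[names(aminoAcids)] <- aminoAcids
  }
  tab <- aminoAcidTable()
  nsrc <- c(aminoAcidNames(), "NH4Cl")
  frac <- .N_ATOMIC_WEIGHT * tab$NN[match(nsrc, tab$name)] /
    tab$MW[match(nsrc, tab$name)]
  s["YAN"] <- sum(frac * s[nsrc])
  s
}
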