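#' Lag-phase adaptation factor
#'
#' Closed-form solution of the Baranyi-Roberts adjustment model:
#' `a0 / (a0 + (1 - a0) * exp(-muMaxN * t))`. The factor multiplies growth
#' and nitrogen uptake, rising from `a0` at inoculation towards 1.
#'
#' @param t Time since inoculation (h), `>= 0`.
#' @param a0 Physiological state of the inoculum, in (0, 1].
#' @param muMaxN Maximum specific growth rate (1/h), `>= 0`.
#' @return Value(s) in (0, 1], non-decreasing in `t`.
#' @export
#' @examples
#' lagFactor(20, a0 = 0.1, muMaxN = 0.2)
lagFactor <- function(t, a0, muMaxN) {
  if (a0 <= 0 || a0 > 1) stop("a0 must lie in (0, 1]")
  if (muMaxN < 0) stop("muMaxN must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  a0 / (a0 + (1 - a0) * exp(-muMaxN * t))
}

#' Nitrogen-depletion regulator
#'
#' `1 - YAN / (YAN + ksC)`: close to 0 while assimilable nitrogen is
#' abundant and approaching 1 as nitrogen is depleted. Gates carbohydrate
#' accumulation (secondary growth) and the transcriptional response to
#' nitrogen starvation; also sets the protein weight in the time-varying
#' dFBA objective.
#'
#' @param YAN Assimilable nitrogen (gN/L), `>= 0`.
#' @param ksC Half-saturation constant (gN/L), `> 0`.
#' @return Value(s) in \[0, 1\], non-increasing in `YAN`.
#' @export
phiNS <- function(YAN, ksC) {
  if (ksC <= 0) stop("ksC must be > 0")
  if (any(YAN < 0)) stop("YAN must be >= 0")
  1 - YAN / (YAN + ksC)
}

#' Sugar-depletion regulator
#'
#' `1 - (Glx + F) / (Glx + F + ksS)`: approaches 1 as hexoses are exhausted,
#' inducing the transcriptional changes of the stationary phase.
#'
#' @param Glx,F Glucose and fructose (g/L), `>= 0`.
#' @param ksS Half-saturation constant (g/L), `> 0`.
#' @return Value(s) in \[0, 1\].
#' @export
phiSugar <- function(Glx, F, ksS) {
  if (ksS <= 0) stop("ksS must be > 0")
  if (any(Glx < 0) || any(F < 0)) stop("sugar concentrations must be >= 0")
  s <- Glx + F
  1 - s / (s + ksS)
}

#' Primary (nitrogen-driven) growth rate
#'
#' Converts the uptake rates of the individual nitrogen sources into a
#' volumetric biomass production rate:
#' `muN = -14.0067 * sum_i (NN_i / MW_i) * d[AA_i]/dt * YxN`, where the sum
#' runs over the assimilated amino acids and ammonium. Uptake rates are
#' negative (consumption), so `muN >= 0` during assimilation.
#'
#' @param rates Named numeric vector of d\[source\]/dt in g/(L h); names
#'   from [aminoAcidTable()] (18 amino acids and/or `NH4Cl`).
#' @param YxN Biomass yield on nitrogen (gDW/gN).
#' @return Volumetric growth rate, gDW/(L h).
#' @export
#' @examples
#' primaryGrowthRate(c(Arg = -0.1), YxN = 1)
primaryGrowthRate <- function(rates, YxN) {
  tab <- aminoAcidTable()
  idx <- match(names(rates), tab$name)
  if (anyNA(idx))
    stop("unknown nitrogen source: ",
         paste(names(rates)[is.na(idx)], collapse = ", "))
  -.N_ATOMIC_WEIGHT * sum(tab$NN[idx] / tab$MW[idx] * rates) * YxN
}

#' Secondary (carbohydrate-accumulation) growth rate
#'
#' Proportional-controller form driving the carbohydrate fraction of biomass
#' towards its set point once nitrogen is depleted:
#' `muC = phiNS * X * PhiC * (ThetaC - XC / X)`.
#'
#' @param X Total biomass (gDW/L), `> 0`.
#' @param XC Carbohydrate biomass (g/L).
#' @param phiNS Nitrogen regulator value in \[0, 1\].
#' @param ThetaC Carbohydrate set point (dimensionless).
#' @param PhiC Convergence gain (1/h).
#' @return Volumetric rate, g/(L h); zero at the set point or with abundant
#'   nitrogen, sign equal to `sign(ThetaC - XC/X)`.
#' @export
secondaryGrowthRate <- function(X, XC, phiNS, ThetaC, PhiC) {
  if (any(X <= 0)) stop("X must be > 0")
  phiNS * X * PhiC * (ThetaC - XC / X)
}

# Logistic ethanol-decay modifier; only enters the biomass equations when the
# decay rate kD is positive. Functional form is a package design choice.
.phiED <- function(Eth, mid, slope) {
  1 / (1 + exp(-slope * (Eth - mid)))
}

# Precomputed state indices and nitrogen conversion factors; the RHS is on
# the hot path of calibration, so it works on unnamed numeric vectors.
.stateIndex <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) {
      sn <- kineticStateNames()
      aa <- aminoAcidNames()
      tab <- aminoAcidTable()
      idx <<- list(
        sn = sn,
        X = match("X", sn), XC = match("XC", sn), XP = match("XP", sn),
        Xm = match("XmRNA", sn), YAN = match("YAN", sn),
        NH4 = match("NH4Cl", sn), AA = match(aa, sn),
        Suc = match("Sucrose", sn), Glx = match("Glx", sn),
        F = match("F", sn), GNS = match("GNS", sn),
        Eth = match("Eth", sn), Gly = match("Glycerol", sn),
        Ace = match("Ace", sn), Succ = match("Succ", sn),
        Lac = match("Lac", sn), Mal = match("Mal", sn),
        Prod = match(secondaryProductNames(), sn),
        # 14.0067 * NN / MW per amino acid (state order) and for ammonium
        nfracAA = .N_ATOMIC_WEIGHT * tab$NN[match(aa, tab$name)] /
          tab$MW[match(aa, tab$name)],
        nfracNH4 = .N_ATOMIC_WEIGHT * 1 / 53.49)
    }
    idx
  }
})

# Flatten a KineticParameters object into the plain list consumed by
# .rhsCore (variant dispatch resolved to integer codes).
.compileParams <- function(params) {
  v <- parameterValues(params)
  variants <- productVariants(params)[secondaryProductNames()]
  list(
    lambdaC = v[["lambdaC"]], lambdaP = v[["lambdaP"]], kD = v[["kD"]],
    phiEDmid = v[["phiEDmid"]], phiEDslope = v[["phiEDslope"]],
    delta = v[["delta"]], YxN = v[["YxN"]], kNH4Cl = v[["kNH4Cl"]],
    kAA = unname(v[paste0("kAA.", aminoAcidNames())]),
    vmaxGlx = v[["vmaxGlx"]], vmaxF = v[["vmaxF"]],
    ksGlx = v[["ksGlx"]], ksF = v[["ksF"]], alpha = v[["alpha"]],
    kSucrose = v[["kSucrose"]], tauGNS = v[["tauGNS"]],
    a0 = v[["a0"]], muMaxN = v[["muMaxN"]],
    ThetaC = v[["ThetaC"]], PhiC = v[["PhiC"]],
    ksC = v[["ksC"]], ksS = v[["ksS"]],
    YEth = v[["YEth"]], YGlycerol = v[["YGlycerol"]], YAce = v[["YAce"]],
    YSucc = v[["YSucc"]], YLac = v[["YLac"]],
    kcAce = v[["kcAce"]], kcSucc = v[["kcSucc"]], kcMal = v[["kcMal"]],
    Yprod = unname(v[paste0("Y", secondaryProductNames())]),
    variantCode = match(unname(variants), .VARIANTS))
}

.rhsCore <- function(t, y, cp) {
  ix <- .stateIndex()
  if (anyNA(y)) stop("NA/NaN in state at t = ", t)
  if (any(y < -1e-6 * max(1, max(abs(y)))))
    stop("negative state beyond tolerance at t = ", t)

  lag <- cp$a0 / (cp$a0 + (1 - cp$a0) * exp(-cp$muMaxN * t))
  XPp <- max(y[ix$XP], 0)

  aaV <- pmax(y[ix$AA], 0)
  dAA <- -lag * cp$kAA * aaV * XPp
  dNH4 <- -lag * cp$kNH4Cl * max(y[ix$NH4], 0) * XPp
  muN <- -(sum(ix$nfracAA * dAA) + ix$nfracNH4 * dNH4) * cp$YxN
  dYAN <- -muN / cp$YxN

  Xsum <- y[ix$XC] + y[ix$XP] + y[ix$Xm]
  yan <- max(y[ix$YAN], 0)
  pN <- cp$ksC / (yan + cp$ksC)
  sug <- max(y[ix$Glx], 0) + max(y[ix$F], 0)
  pS <- cp$ksS / (sug + cp$ksS)
  muC <- if (Xsum > 0)
    pN * Xsum * cp$PhiC * (cp$ThetaC - y[ix$XC] / Xsum) else 0

  pED <- if (cp$kD > 0)
    1 / (1 + exp(-cp$phiEDslope * (y[ix$Eth] - cp$phiEDmid))) else 0
  dXC <- cp$lambdaC * muN + muC - cp$kD * y[ix$XC] * pED
  dXP <- cp$lambdaP * muN - cp$kD * y[ix$XP] * pED
  dXm <- (1 - cp$lambdaC - cp$lambdaP) * muN - cp$kD * y[ix$Xm] * pED

  dSuc <- -cp$kSucrose * max(y[ix$Suc], 0)
  glx <- max(y[ix$Glx], 0); fru <- max(y[ix$F], 0)
  ind <- 1 + cp$alpha * muN
  upGlx <- cp$vmaxGlx * XPp * glx / (glx + cp$ksGlx) * ind
  upF <- cp$vmaxF * XPp * fru / (fru + cp$ksF) * ind
  dGlx <- -upGlx - 0.5 * dSuc
  dF <- -upF - 0.5 * dSuc
  # production is driven by hexose *uptake*; sucrose release feeds the
  # hexose pools but only counts once consumed (keeps products monotone)
  sugarUp <- -(upGlx + upF)

  GNS <- y[ix$GNS]
  dGNS <- (pN * pS - GNS) * cp$tauGNS

  dEth <- -cp$YEth * sugarUp
  dGly <- -cp$YGlycerol * sugarUp * (1 - GNS)
  dLac <- -cp$YLac * sugarUp * (1 - GNS)
  dAce <- -cp$delta * cp$YAce * sugarUp * (1 - GNS) +
    (1 - cp$delta) * (-cp$YAce * sugarUp * (1 - pN) -
                        cp$kcAce * pN * XPp * max(y[ix$Ace], 0) * (1 - GNS))
  dSucc <- -cp$YSucc * pN * sugarUp -
    cp$kcSucc * (1 - pN) * max(y[ix$Succ], 0) * XPp
  dMal <- -cp$kcMal * max(y[ix$Mal], 0) * XPp

  base <- -cp$Yprod * sugarUp
  mult <- c(1, 1 - GNS, pN, pN * (1 - GNS))[cp$variantCode]
  dProd <- base * mult

  d <- numeric(length(y))
  d[ix$XC] <- dXC; d[ix$XP] <- dXP; d[ix$Xm] <- dXm
  d[ix$X] <- dXC + dXP + dXm
  d[ix$YAN] <- dYAN; d[ix$NH4] <- dNH4
  d[ix$AA] <- dAA
  d[ix$Suc] <- dSuc; d[ix$Glx] <- dGlx; d[ix$F] <- dF
  d[ix$GNS] <- dGNS
  d[ix$Eth] <- dEth; d[ix$Gly] <- dGly; d[ix$Ace] <- dAce
  d[ix$Succ] <- dSucc; d[ix$Lac] <- dLac; d[ix$Mal] <- dMal
  d[ix$Prod] <- dProd
  if (anyNA(d)) stop("NaN produced in derivatives at t = ", t)
  d
}

#' Right-hand side of the kinetic ODE system
#'
#' Evaluates the time derivatives of all 41 states: biomass components and
#' total biomass, assimilable nitrogen bookkeeping, lag-gated ammonium and
#' amino-acid mass-action uptake, sucrose hydrolysis feeding half of its mass
#' into each hexose, Michaelis-Menten hexose uptake with transporter
#' induction `(1 + alpha * muN)`, first-order relaxation of the regulatory
#' state `GNS`, ethanol proportional to sugar uptake, regulated-decline
#' products (glycerol, lactate), the must-type-switched acetate equation with
#' its consumption branch, succinate production/consumption, malate
#' consumption and variant-dispatched secondary metabolites.
#'
#' Substrate concentrations are clipped at zero inside the rate laws only, so
#' small negative integrator excursions do not destabilize the solution.
#'
#' @param t Time (h).
#' @param state Named numeric vector over [kineticStateNames()].
#' @param params A [KineticParameters] object.
#' @return Named numeric vector of derivatives (same order as `state`).
#' @export
kineticRHS <- function(t, state, params) {
  stopifnot(is(params, "KineticParameters"))
  y <- unname(state[kineticStateNames()])
  if (anyNA(y)) stop("state must cover all kinetic states without NA")
  stats::setNames(.rhsCore(t, y, .compileParams(params)),
                  kineticStateNames())
}
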