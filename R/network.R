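#' Construct a metabolic network
#'
#' @param S Stoichiometric matrix (metabolites x reactions); coerced to
#'   sparse.
#' @param lowerBounds,upperBounds Flux bounds, mmol/(gDW h); must be finite
#'   (infinite bounds are capped at +/-1000, the conventional COBRA default).
#' @param reactions,metabolites Identifier vectors.
#' @param roles Named list designating `biomass`, `atpMaintenance`,
#'   `proteinSynthesis` and `exchanges` (see
#'   [MetabolicNetwork][MetabolicNetwork-class]).
#' @param carbon Optional mmol carbon per unit metabolite (NA where
#'   undefined); used by [carbonBalance()].
#' @return A validated [MetabolicNetwork].
#' @export
metabolicNetwork <- function(S, lowerBounds, upperBounds, reactions,
                             metabolites, roles, carbon = numeric()) {
  lowerBounds <- unname(pmax(lowerBounds, -1000))
  upperBounds <- unname(pmin(upperBounds, 1000))
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites, reactions)
  new("MetabolicNetwork", S = S, lowerBounds = lowerBounds,
      upperBounds = upperBounds, reactions = reactions,
      metabolites = metabolites, roles = roles, carbon = carbon)
}

#' @rdname MetabolicNetwork-class
#' @export
setMethod("reactionIds", "MetabolicNetwork", function(x) x@reactions)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("metaboliteIds", "MetabolicNetwork", function(x) x@metabolites)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("stoichMatrix", "MetabolicNetwork", function(x) x@S)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("fluxBounds", "MetabolicNetwork", function(x)
  data.frame(reaction = x@reactions, lower = x@lowerBounds,
             upper = x@upperBounds, stringsAsFactors = FALSE))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("networkRoles", "MetabolicNetwork", function(x) x@roles)

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", length(object@metabolites), "metabolites x",
      length(object@reactions), "reactions (",
      length(object@roles$exchanges), "exchanges )\n")
  cat("  biomass:", object@roles$biomass,
      "| ATP maintenance:", object@roles$atpMaintenance,
      "| protein synthesis:", object@roles$proteinSynthesis, "\n")
})

#' Desk-scale stoichiometric test network
#'
#' A deterministic 23-reaction, 16-metabolite anaerobic yeast caricature:
#' glucose/fructose/ammonium/amino-acid exchanges, lumped glycolysis
#' producing ATP and NADH, fermentative branches to ethanol, glycerol
#' (re-oxidizing NADH), acetate and succinate, amino-acid synthesis, an
#' ATP-maintenance (hydrolysis) reaction, protein/carbohydrate/RNA
#' polymerization pseudo-reactions consuming ATP, a fixed-composition
#' biomass assembly plus a carbohydrate-storage biomass route (so that
#' growth carried purely by carbohydrate accumulation after nitrogen
#' depletion remains stoichiometrically feasible), and a biomass drain. All
#' internal metabolic reactions balance carbon; biomass assembly
#' pseudo-reactions are exempt (their product has no defined formula),
#' matching genome-scale model conventions.
#'
#' @return A [MetabolicNetwork].
#' @export
#' @examples
#' net <- toyNetwork()
#' networkRoles(net)$biomass
toyNetwork <- function() {
  mets <- c("glc", "frc", "nh4", "aa", "pyr", "co2", "eth", "glyc", "ace",
            "succ", "atp", "nadh", "prot", "carb", "rna", "biom")
  rxn <- list(
    EX_glc = c(glc = -1), EX_frc = c(frc = -1), EX_nh4 = c(nh4 = -1),
    EX_aa = c(aa = -1), EX_eth = c(eth = -1), EX_glyc = c(glyc = -1),
    EX_ace = c(ace = -1), EX_succ = c(succ = -1), EX_co2 = c(co2 = -1),
    EX_biomass = c(biom = -1),
    GLY_glc = c(glc = -1, pyr = 2, atp = 2, nadh = 2),
    GLY_frc = c(frc = -1, pyr = 2, atp = 2, nadh = 2),
    FERM_eth = c(pyr = -1, nadh = -1, eth = 1, co2 = 1),
    FERM_glyc = c(pyr = -1, nadh = -2, glyc = 1),
    FERM_ace = c(pyr = -1, ace = 1, co2 = 1, nadh = 1),
    FERM_succ = c(pyr = -2, nadh = -2, succ = 1, co2 = 2),
    AA_syn = c(pyr = -1, nh4 = -1, nadh = -1, aa = 1),
    ATPM = c(atp = -1),
    PROT_syn = c(aa = -11.2, atp = -23.9, prot = 1),
    CARB_syn = c(glc = -6.2, atp = -5.0, carb = 1),
    RNA_syn = c(glc = -3.4, nh4 = -11.6, atp = -2.6, rna = 1),
    BIOMASS = c(carb = -0.29, prot = -0.59, rna = -0.12, atp = -30,
                biom = 1),
    BIOMASS_sto = c(carb = -1, atp = -15, biom = 1)
  )
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (r in names(rxn)) S[names(rxn[[r]]), r] <- rxn[[r]]

  ex <- grep("^EX_", names(rxn), value = TRUE)
  lb <- stats::setNames(rep(0, length(rxn)), names(rxn))
  ub <- stats::setNames(rep(1000, length(rxn)), names(rxn))
  lb[c("EX_glc", "EX_frc", "EX_nh4", "EX_aa")] <- -10
  ub[c("EX_glc", "EX_frc", "EX_nh4", "EX_aa")] <- 0

  carbon <- c(glc = 6, frc = 6, nh4 = 0, aa = 3, pyr = 3, co2 = 1, eth = 2,
              glyc = 3, ace = 2, succ = 4, atp = 0, nadh = 0,
              prot = 11.2 * 3, carb = 6.2 * 6, rna = 3.4 * 6, biom = NA)

  metabolicNetwork(S, lb, ub, names(rxn), mets,
                   roles = list(biomass = "EX_biomass",
                                atpMaintenance = "ATPM",
                                proteinSynthesis = "PROT_syn",
                                carbSynthesis = "CARB_syn",
                                rnaSynthesis = "RNA_syn",
                                storageBiomass = "BIOMASS_sto",
                                biomassAssembly = "BIOMASS",
                                exchanges = ex),
                   carbon = carbon)
}

#' Carbon balance of internal reactions
#'
#' Checks `sum_i carbon_i * S[i, r]` for every internal (non-exchange)
#' reaction whose metabolites all carry a defined carbon content.
#'
#' @param network A [MetabolicNetwork] with a carbon annotation.
#' @return Named numeric vector of carbon imbalances (mmol C per flux unit)
#'   for the checkable reactions.
#' @export
carbonBalance <- function(network) {
  if (!length(network@carbon)) stop("network carries no carbon annotation")
  S <- as.matrix(network@S)
  internal <- setdiff(network@reactions, network@roles$exchanges)
  out <- numeric()
  for (r in internal) {
    touched <- network@metabolites[S[, r] != 0]
    if (anyNA(network@carbon[touched])) next  # pseudo-metabolite involved
    out[r] <- sum(network@carbon[touched] * S[touched, r])
  }
  out
}

#' Growth-associated ATP maintenance specification
#'
#' @param GAMb Base growth-associated maintenance, mmol ATP/gDW
#'   (default 30).
#' @param cProt,cRNA,cCarbs Polymerization costs, mmol ATP per g of
#'   macromolecule synthesized (defaults are literature-scale yeast values
#'   shipped as editable data).
#' @return A classed list.
#' @export
gamSpec <- function(GAMb = 30, cProt = 23.9, cRNA = 2.6, cCarbs = 5.0) {
  if (any(c(GAMb, cProt, cRNA, cCarbs) < 0))
    stop("GAM coefficients must be >= 0")
  structure(list(GAMb = GAMb, cProt = cProt, cRNA = cRNA, cCarbs = cCarbs),
            class = "gamSpec")
}

#' Total growth-associated ATP maintenance
#'
#' `GAM = GAMb * growth + cProt * rProt + cRNA * rRNA + cCarbs * rCarbs`:
#' the base maintenance applied per unit biomass growth plus the
#' macromolecule polymerization costs at their synthesis rates.
#'
#' @param gam A [gamSpec()].
#' @param rates Named numeric vector with entries `protein`, `rna`, `carbs`
#'   in g/(gDW h) (missing entries default to 0).
#' @param growth Specific growth rate (1/h); default 1 so that with zero
#'   polymerization coefficients the result is `GAMb` itself.
#' @return ATP demand, mmol/(gDW h).
#' @export
#' @examples
#' gamTotal(gamSpec())                                  # 30
#' gamTotal(gamSpec(GAMb = 0, cProt = 10),
#'          rates = c(protein = 0.059), growth = 0)     # 0.59
gamTotal <- function(gam, rates = c(protein = 0, rna = 0, carbs = 0),
                     growth = 1) {
  stopifnot(inherits(gam, "gamSpec"))
  if (any(rates < 0)) stop("macromolecule rates must be >= 0")
  r <- c(protein = 0, rna = 0, carbs = 0)
  r[names(rates)] <- rates
  gam$GAMb * growth + gam$cProt * r[["protein"]] + gam$cRNA * r[["rna"]] +
    gam$cCarbs * r[["carbs"]]
}

#' Wire a GAM specification into a network
#'
#' Sets the ATP coefficients of the biomass-assembly and polymerization
#' pseudo-reactions from a [gamSpec()]: `GAMb` on the biomass assembly,
#' `cProt`/`cRNA`/`cCarbs` on the protein/RNA/carbohydrate synthesis
#' columns. Only roles present in the network are touched.
#'
#' @param network A [MetabolicNetwork] with an `atp`-like metabolite (id
#'   `atp` or configurable via `atpMet`).
#' @param gam A [gamSpec()].
#' @param atpMet Metabolite id carrying ATP (default `"atp"`).
#' @return The updated network.
#' @export
applyGam <- function(network, gam, atpMet = "atp") {
  stopifnot(inherits(gam, "gamSpec"))
  if (!atpMet %in% network@metabolites)
    stop("metabolite '", atpMet, "' not in network")
  set <- function(net, role, coeff) {
    id <- net@roles[[role]]
    if (!is.null(id) && id %in% net@reactions)
      net@S[atpMet, id] <- -coeff
    net
  }
  network <- set(network, "biomassAssembly", gam$GAMb)
  network <- set(network, "proteinSynthesis", gam$cProt)
  network <- set(network, "rnaSynthesis", gam$cRNA)
  network <- set(network, "carbSynthesis", gam$cCarbs)
  network
}

#' Map kinetic states to exchange reactions
#'
#' @param state Character vector of kinetic state names.
#' @param reaction Character vector of exchange reaction ids.
#' @param mw Molecular weights (g/mol).
#' @param class `"equality"` or `"inequality"` per entry. The inequality
#'   class is meant for compounds whose measurements carry higher relative
#'   noise (the default list in fermentation data: histidine, succinate,
#'   lactate, malate, isobutanol, isoamyl alcohol, phenyl ethyl acetate,
#'   2-phenyl ethanol); their kinetic rate becomes a one-sided bound rather
#'   than a fixed value.
#' @param network Optional [MetabolicNetwork] to validate reaction ids
#'   against.
#' @return data.frame of class `compoundMap`.
#' @export
compoundMap <- function(state, reaction, mw,
                        class = rep("equality", length(state)),
                        network = NULL) {
  stopifnot(length(state) == length(reaction),
            length(mw) == length(state),
            length(class) == length(state))
  bad <- setdiff(state, kineticStateNames())
  if (length(bad))
    stop("unknown kinetic states: ", paste(bad, collapse = ", "))
  if (any(mw <= 0)) stop("molecular weights must be > 0")
  if (!all(class %in% c("equality", "inequality")))
    stop("class must be 'equality' or 'inequality'")
  if (anyDuplicated(state) || anyDuplicated(reaction))
    stop("states and reactions must be uniquely mapped")
  if (!is.null(network)) {
    missing <- setdiff(reaction, networkRoles(network)$exchanges)
    if (length(missing))
      stop("not exchange reactions in network: ",
           paste(missing, collapse = ", "))
  }
  structure(data.frame(state = state, reaction = reaction, mw = mw,
                       class = class, stringsAsFactors = FALSE),
            class = c("compoundMap", "data.frame"))
}

#' Default noisy-compound inequality list
#'
#' States conventionally constrained by inequality rather than equality
#' bounds because of higher relative measurement noise.
#'
#' @return Character vector of state names.
#' @export
defaultInequalityStates <- function() {
  c("His", "Succ", "Lac", "Mal", "Iobut", "Iamo", "PEA", "PE")
}

#' Read a compound map from YAML
#'
#' Expects a top-level list of entries with fields `state`, `reaction`,
#' `mw` and optional `class` (default `"equality"`; states listed in
#' [defaultInequalityStates()] default to `"inequality"`).
#'
#' @param path YAML file path.
#' @param network Optional [MetabolicNetwork] for validation.
#' @return A [compoundMap()].
#' @export
readCompoundMap <- function(path, network = NULL) {
  cfg <- yaml::read_yaml(path)
  state <- vapply(cfg, `[[`, character(1), "state")
  cls <- vapply(cfg, function(e) {
    if (!is.null(e$class)) e$class
    else if (e$state %in% defaultInequalityStates()) "inequality"
    else "equality"
  }, character(1))
  compoundMap(state = state,
              reaction = vapply(cfg, `[[`, character(1), "reaction"),
              mw = vapply(cfg, function(e) as.numeric(e$mw), numeric(1)),
              class = cls, network = network)
}

#' Read a growth-associated maintenance specification from YAML
#'
#' @param path YAML file with optional fields `GAMb`, `cProt`, `cRNA`,
#'   `cCarbs` (missing fields keep the package defaults).
#' @return A [gamSpec()].
#' @export
readGamSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(gamSpec, cfg[intersect(names(cfg),
                                 c("GAMb", "cProt", "cRNA", "cCarbs"))])
}
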