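# Minimal SBML Level 3 (FBC v2) serialization for constraint-based models.
# Covers the subset needed for flux-balance work: species, reactions with
# stoichiometries, flux-bound parameters and optional chemical formulas.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a network to SBML (Level 3, FBC)
#'
#' @param network A [MetabolicNetwork].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSBMLNetwork <- function(network, path) {
  S <- as.matrix(network@S)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "true")
  cmp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(cmp, "compartment", id = "c", constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_along(network@metabolites)) {
    m <- network@metabolites[i]
    sp <- xml2::xml_add_child(los, "species", id = m, compartment = "c",
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false",
                              constant = "false")
    if (length(network@carbon)) {
      cc <- network@carbon[[m]]
      if (!is.na(cc) && cc == round(cc))
        xml2::xml_set_attr(sp, "fbc:chemicalFormula",
                           if (cc > 0) paste0("C", format(as.integer(cc)))
                           else "H")
    }
  }

  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(network@reactions)) {
    xml2::xml_add_child(lop, "parameter",
                        id = paste0("lb_", network@reactions[i]),
                        value = format(network@lowerBounds[i], digits = 15),
                        constant = "true")
    xml2::xml_add_child(lop, "parameter",
                        id = paste0("ub_", network@reactions[i]),
                        value = format(network@upperBounds[i], digits = 15),
                        constant = "true")
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(network@reactions)) {
    r <- network@reactions[j]
    rx <- xml2::xml_add_child(
      lor, "reaction", id = r,
      reversible = tolower(as.character(network@lowerBounds[j] < 0)),
      fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", r),
      "fbc:upperFluxBound" = paste0("ub_", r))
    coef <- S[, j]
    rcts <- which(coef < 0)
    prds <- which(coef > 0)
    if (length(rcts)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in rcts)
        xml2::xml_add_child(lr, "speciesReference",
                            species = network@metabolites[i],
                            stoichiometry = format(-coef[i], digits = 15),
                            constant = "true")
    }
    if (length(prds)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in prds)
        xml2::xml_add_child(lp, "speciesReference",
                            species = network@metabolites[i],
                            stoichiometry = format(coef[i], digits = 15),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# carbon count from an FBC chemical formula ("C6H12O6" -> 6); NA when absent
.formulaCarbon <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_real_)
  m <- regmatches(formula, regexec("C(?![a-z])([0-9]*)", formula,
                                   perl = TRUE))[[1]]
  if (length(m) == 0) return(0)
  if (m[2] == "") 1 else as.numeric(m[2])
}

#' Load a constraint-based network from SBML (Level 3, FBC)
#'
#' Reads species, reactions, stoichiometry and flux bounds (FBC flux-bound
#' parameters; reactions without them fall back to `reversible`-based
#' defaults of -1000/1000 or 0/1000). Designated reaction roles are
#' resolved from the `roles` argument, since id conventions differ between
#' reconstructions; an unresolvable role is an error naming that role.
#'
#' @param path SBML file path.
#' @param roles Named list with reaction ids (or single regular-expression
#'   patterns) for `biomass`, `atpMaintenance` and `proteinSynthesis`, and
#'   optionally `exchanges` (defaults to reactions involving exactly one
#'   metabolite).
#' @return A [MetabolicNetwork].
#' @export
loadSBMLNetwork <- function(path, roles) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  spNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- xml2::xml_attr(spNodes, "id")
  boundary <- xml2::xml_attr(spNodes, "boundaryCondition") %in% "true"
  formulas <- xml2::xml_attr(spNodes, "chemicalFormula")
  carbon <- vapply(formulas, .formulaCarbon, numeric(1), USE.NAMES = FALSE)
  names(carbon) <- mets
  keep <- !boundary
  mets <- mets[keep]; carbon <- carbon[keep]

  pNodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pNodes, "value")),
                           xml2::xml_attr(pNodes, "id"))

  rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- xml2::xml_attr(rxNodes, "id")
  nR <- length(rxns)
  lb <- numeric(nR); ub <- numeric(nR)
  trip <- list()
  for (j in seq_len(nR)) {
    node <- rxNodes[[j]]
    lbId <- xml2::xml_attr(node, "lowerFluxBound")
    ubId <- xml2::xml_attr(node, "upperFluxBound")
    rev <- xml2::xml_attr(node, "reversible") %in% "true"
    lb[j] <- if (!is.na(lbId) && lbId %in% names(pvals)) pvals[[lbId]]
    else if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubId) && ubId %in% names(pvals)) pvals[[ubId]]
    else 1000
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, paste0("./", side, "/speciesReference"))
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      ok <- sp %in% mets
      if (any(ok))
        trip[[length(trip) + 1L]] <- data.frame(
          i = match(sp[ok], mets), j = j, x = st[ok])
    }
  }
  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(length(mets), nR))

  resolve <- function(role) {
    pat <- roles[[role]]
    if (is.null(pat))
      stop("role '", role, "' must be supplied to resolve the network")
    hit <- if (pat %in% rxns) pat else grep(pat, rxns, value = TRUE)
    if (length(hit) != 1)
      stop("role '", role, "' matched ", length(hit),
           " reactions (need exactly 1)")
    hit
  }
  ex <- roles[["exchanges"]]
  if (is.null(ex))
    ex <- rxns[Matrix::colSums(S != 0) == 1]
  rolesOut <- list(biomass = resolve("biomass"),
                   atpMaintenance = resolve("atpMaintenance"),
                   proteinSynthesis = resolve("proteinSynthesis"),
                   exchanges = ex)
  for (extra in c("carbSynthesis", "rnaSynthesis", "storageBiomass",
                  "biomassAssembly"))
    if (!is.null(roles[[extra]]) && roles[[extra]] %in% rxns)
      rolesOut[[extra]] <- roles[[extra]]

  metabolicNetwork(as.matrix(S), lb, ub, rxns, mets, rolesOut,
                   carbon = carbon)
}
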