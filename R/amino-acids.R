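#' Nitrogen content of assimilable nitrogen sources
#'
#' Returns the lookup table used to convert uptake rates of individual
#' nitrogen sources into a nitrogen-equivalent growth rate: one row per
#' assimilable amino acid (proline is excluded; it is not metabolized under
#' anaerobic conditions) plus ammonium chloride.
#'
#' @return A data.frame with columns `name`, `NN` (nitrogen atoms per
#'   molecule) and `MW` (molecular weight, g/mol).
#' @export
#' @examples
#' tab <- aminoAcidTable()
#' tab[tab$name == "Arg", ]
aminoAcidTable <- function() {
  data.frame(
    name = c("Ala", "Arg", "Asp", "Cys", "Glu", "Gln", "Gly", "His", "Ile",
             "Leu", "Lys", "Met", "Phe", "Ser", "Thr", "Tyr", "Trp", "Val",
             "NH4Cl"),
    NN = c(1L, 4L, 1L, 1L, 1L, 2L, 1L, 3L, 1L,
           1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L,
           1L),
    MW = c(89.09, 174.20, 133.10, 121.16, 147.13, 146.15, 75.07, 155.15,
           131.17, 131.17, 146.19, 149.21, 165.19, 105.09, 119.12, 181.19,
           204.23, 117.15, 53.49),
    stringsAsFactors = FALSE
  )
}

#' Names of the assimilated amino acids
#' @return Character vector of the 18 amino-acid state names.
#' @export
aminoAcidNames <- function() {
  setdiff(aminoAcidTable()$name, "NH4Cl")
}

# Atomic weight of nitrogen used in the nitrogen-to-biomass conversion.
.N_ATOMIC_WEIGHT <- 14.0067
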