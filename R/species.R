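#' Default chemical species registry
#'
#' The registry lists every non-microbial state variable the community model
#' can track: the four bulk resource pools of the fermentation medium and the
#' thirteen fermentation metabolites, with molar masses in g/mol. Polymeric
#' resources carry per-monomer masses (anhydroglucose for the carbohydrate
#' pools, a mean residue mass for protein) so that stoichiometric molecule
#' counts refer to monomer equivalents. Water can be added with
#' `include_water = TRUE` for closed-system mass-budget checks; by default it
#' is an implicit, non-limiting pool.
#'
#' @param metabolites Character vector of metabolite names to include.
#'   Defaults to the thirteen modeled metabolites.
#' @param include_water If `TRUE`, add a tracked `water` species.
#' @return A tibble with columns `species`, `role` (`"resource"` or
#'   `"metabolite"`) and `molar_mass` (g/mol).
#' @export
#' @examples
#' default_species_registry()
default_species_registry <- function(metabolites = default_metabolites(),
                                     include_water = FALSE) {
  mm <- species_molar_masses()
  unknown <- setdiff(metabolites, names(mm))
  if (length(unknown) > 0) {
    stop("no default molar mass for metabolite(s): ",
         paste(unknown, collapse = ", "),
         "; supply a registry tibble instead", call. = FALSE)
  }
  reg <- tibble::tibble(
    species = c(default_resources(), metabolites),
    role = c(rep("resource", length(default_resources())),
             rep("metabolite", length(metabolites))),
    molar_mass = unname(mm[c(default_resources(), metabolites)])
  )
  if (include_water) {
    reg <- dplyr::bind_rows(
      reg,
      tibble::tibble(species = "water", role = "resource", molar_mass = 18.015)
    )
  }
  reg
}

#' @rdname default_species_registry
#' @export
default_resources <- function() {
  c("resistant_starch", "NSP", "protein", "sugars")
}

#' @rdname default_species_registry
#' @export
default_metabolites <- function() {
  c("acetate", "propionate", "butyrate", "lactate", "formate", "succinate",
    "ethanol", "CO2", "H2", "CH4", "valerate", "caproate", "isovalerate")
}

species_molar_masses <- function() {
  c(resistant_starch = 162.14, NSP = 162.14, protein = 110.0, sugars = 180.16,
    acetate = 60.05, propionate = 74.08, butyrate = 88.11, lactate = 90.08,
    formate = 46.03, succinate = 118.09, ethanol = 46.07, CO2 = 44.01,
    H2 = 2.016, CH4 = 16.04, valerate = 102.13, caproate = 116.16,
    isovalerate = 102.13, water = 18.015)
}

#' Resource classification labels
#'
#' Every entry of a pathway's stoichiometry carries exactly one class:
#' `Se` essential resource, `S` substitutable resource, `Sw` water resource,
#' `Sb` boosting resource, `P` product.
#'
#' @return Character vector of the five valid `rtype` labels.
#' @export
resource_classes <- function() c("Se", "S", "Sw", "Sb", "P")
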