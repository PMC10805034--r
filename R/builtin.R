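# Builtin fixture communities. The per-genus kinetic parameters stand in
# for culture-derived values and are SYNTHETIC: they were designed so the
# model reproduces the qualitative community ecology of the continuous
# fermentation — Prevotella, Megasphaera, Succinivibrio, Blautia,
# Ruminococcus and "others" maintain growth at dilution rate 0.111 1/h by
# holding distinct niches (NSP, lactate, sugars, H2+CO2, resistant starch,
# protein), the remaining genera wash out, and lactate is cross-fed away
# below detection. Yields anchor at 0.333 g/g for saccharolytic pathways;
# maximum growth rates lie in 0.1-1.5 1/h; half-saturation constants start
# from the 0.001 g/L default and were set within biologically compatible
# ranges. The aggregate "others" group carries ten pathways representing
# the metabolic functional groups of the non-core microbiota.

fixture_pathway <- function(id, mu_max, resources, products, water = FALSE) {
  mm <- species_molar_masses()
  res_rows <- purrr::map_dfr(resources, function(r) {
    tibble::tibble(species = r$species, rtype = r$rtype,
                   molar_mass = unname(mm[r$species]),
                   n_molecules = r$n %||% 1,
                   half_sat = r$K %||% NA_real_,
                   yield = r$Y %||% NA_real_)
  })
  if (water) {
    res_rows <- dplyr::bind_rows(res_rows, tibble::tibble(
      species = "water", rtype = "Sw", molar_mass = 18.015,
      n_molecules = 1, half_sat = NA_real_, yield = NA_real_))
  }
  prod_rows <- tibble::tibble(
    species = names(products), rtype = "P",
    molar_mass = unname(mm[names(products)]),
    n_molecules = unname(products),
    half_sat = NA_real_, yield = NA_real_)
  pathway_spec(id, mu_max, dplyr::bind_rows(res_rows, prod_rows))
}

res_S <- function(species, K, Y = 0.333, n = 1) {
  list(species = species, rtype = "S", K = K, Y = Y, n = n)
}
res_Se <- function(species, K, Y, n = 1) {
  list(species = species, rtype = "Se", K = K, Y = Y, n = n)
}
res_Sb <- function(species, K, n = 1) {
  list(species = species, rtype = "Sb", K = K, Y = NA_real_, n = n)
}

fixture_group_definitions <- function() {
  defs <- list(
    group_spec("Prevotella", list(
      fixture_pathway("nsp_fermentation", 0.45,
                      list(res_S("NSP", 0.004)),
                      c(acetate = 1, propionate = 1, succinate = 1,
                        CO2 = 1, H2 = 2), water = TRUE),
      fixture_pathway("sugar_fermentation", 0.15,
                      list(res_S("sugars", 0.08)),
                      c(acetate = 2, succinate = 1, CO2 = 1), water = TRUE)
    ), c(4.8, 5.6, 7.2, 8.2)),

    group_spec("Megasphaera", list(
      fixture_pathway("lactate_conversion", 0.5,
                      list(res_S("lactate", 0.001, n = 3)),
                      c(propionate = 2, butyrate = 1, valerate = 1,
                        CO2 = 1, H2 = 1)),
      fixture_pathway("sugar_fermentation", 0.2,
                      list(res_S("sugars", 0.05)),
                      c(butyrate = 1, caproate = 1, CO2 = 1, H2 = 2),
                      water = TRUE)
    ), c(4.9, 5.7, 7.4, 8.4)),

    group_spec("RC9", list(
      fixture_pathway("nsp_degradation", 0.3,
                      list(res_S("NSP", 0.05)),
                      c(acetate = 2, propionate = 1, CO2 = 1, H2 = 1),
                      water = TRUE)
    ), c(5.0, 5.9, 7.1, 8.1)),

    group_spec("Streptococcus", list(
      fixture_pathway("homolactic_fermentation", 0.45,
                      list(res_S("sugars", 0.03)),
                      c(lactate = 2, formate = 1))
    ), c(4.6, 5.4, 7.6, 8.6)),

    group_spec("Lactobacillus", list(
      fixture_pathway("heterolactic_fermentation", 0.4,
                      list(res_S("sugars", 0.02)),
                      c(lactate = 1, acetate = 1, ethanol = 1, CO2 = 1))
    ), c(4.0, 4.8, 6.8, 7.8)),

    group_spec("Alloprevotella", list(
      fixture_pathway("nsp_degradation", 0.3,
                      list(res_S("NSP", 0.03)),
                      c(acetate = 2, succinate = 1, CO2 = 1), water = TRUE)
    ), c(4.8, 5.6, 7.2, 8.2)),

    group_spec("Clostridium", list(
      fixture_pathway("sugar_fermentation", 0.5,
                      list(res_S("sugars", 0.06)),
                      c(butyrate = 1, acetate = 1, CO2 = 2, H2 = 2),
                      water = TRUE)
    ), c(4.7, 5.5, 7.5, 8.5)),

    group_spec("Treponema", list(
      fixture_pathway("nsp_degradation", 0.25,
                      list(res_S("NSP", 0.08)),
                      c(acetate = 2, ethanol = 1, CO2 = 1, H2 = 1),
                      water = TRUE)
    ), c(5.2, 6.0, 7.4, 8.4)),

    group_spec("Faecalibacterium", list(
      fixture_pathway("butyrogenic_rs_fermentation", 0.35,
                      list(res_S("resistant_starch", 0.05),
                           res_Sb("acetate", 0.4)),
                      c(butyrate = 2, formate = 1, CO2 = 1), water = TRUE)
    ), c(4.9, 5.7, 7.0, 8.0)),

    group_spec("Succinivibrio", list(
      fixture_pathway("sugar_fermentation", 0.5,
                      list(res_S("sugars", 0.01)),
                      c(acetate = 2, succinate = 1, propionate = 1,
                        CO2 = 1), water = TRUE),
      fixture_pathway("rs_degradation", 0.2,
                      list(res_S("resistant_starch", 0.08)),
                      c(acetate = 2, succinate = 1, CO2 = 1), water = TRUE)
    ), c(4.9, 5.7, 7.3, 8.3)),

    group_spec("Blautia", list(
      fixture_pathway("acetogenesis", 0.4,
                      list(res_Se("H2", 1e-4, 0.3, n = 4),
                           res_Se("CO2", 0.001, 0.1, n = 2)),
                      c(acetate = 1))
    ), c(4.8, 5.6, 7.2, 8.2)),

    group_spec("Phascolarctobacterium", list(
      fixture_pathway("succinate_to_propionate", 0.132,
                      list(res_S("succinate", 0.01)),
                      c(propionate = 1, CO2 = 1))
    ), c(5.2, 6.8, 7.6, 8.6)),

    group_spec("Ruminococcus", list(
      fixture_pathway("rs_degradation", 0.35,
                      list(res_S("resistant_starch", 0.006)),
                      c(acetate = 2, formate = 1, H2 = 4, CO2 = 1),
                      water = TRUE)
    ), c(5.0, 5.8, 7.0, 8.0)),

    group_spec("Parabacteroides", list(
      fixture_pathway("nsp_degradation", 0.3,
                      list(res_S("NSP", 0.1)),
                      c(acetate = 1, propionate = 1, succinate = 1,
                        CO2 = 1), water = TRUE),
      fixture_pathway("proteolysis", 0.2,
                      list(res_S("protein", 0.2, Y = 0.3)),
                      c(acetate = 1, propionate = 1, isovalerate = 1,
                        CO2 = 1))
    ), c(4.9, 5.7, 7.3, 8.3)),

    group_spec("Escherichia", list(
      fixture_pathway("mixed_acid_fermentation", 0.6,
                      list(res_S("sugars", 0.04)),
                      c(acetate = 1, ethanol = 1, formate = 2, CO2 = 1,
                        H2 = 1))
    ), c(5.5, 6.9, 8.0, 9.0)),

    group_spec("Turicibacter", list(
      fixture_pathway("sugar_fermentation", 0.25,
                      list(res_S("sugars", 0.1)),
                      c(lactate = 2, acetate = 1))
    ), c(5.1, 5.9, 7.1, 8.1)),

    group_spec("others", list(
      fixture_pathway("proteolysis", 0.6,
                      list(res_S("protein", 0.04, Y = 0.3)),
                      c(acetate = 1, propionate = 1, butyrate = 2,
                        isovalerate = 1, CO2 = 1, H2 = 1), water = TRUE),
      fixture_pathway("nsp_degradation", 0.25,
                      list(res_S("NSP", 0.25)),
                      c(acetate = 2, succinate = 1, CO2 = 1, H2 = 1),
                      water = TRUE),
      fixture_pathway("rs_degradation", 0.25,
                      list(res_S("resistant_starch", 0.3)),
                      c(acetate = 2, formate = 1, CO2 = 1, H2 = 1),
                      water = TRUE),
      fixture_pathway("lactate_producing_fermentation", 0.3,
                      list(res_S("sugars", 0.25)),
                      c(lactate = 2, acetate = 1, ethanol = 1)),
      fixture_pathway("lactate_to_butyrate", 0.15,
                      list(res_S("lactate", 0.3, n = 3)),
                      c(butyrate = 2, CO2 = 1, H2 = 2)),
      fixture_pathway("succinate_to_propionate", 0.3,
                      list(res_S("succinate", 0.05)),
                      c(propionate = 1, CO2 = 1)),
      fixture_pathway("methanogenesis", 0.1,
                      list(res_Se("H2", 0.05, 0.1, n = 4),
                           res_Se("CO2", 0.05, 0.1, n = 1)),
                      c(CH4 = 1)),
      fixture_pathway("homoacetogenesis", 0.08,
                      list(res_Se("H2", 0.08, 0.3, n = 4),
                           res_Se("CO2", 0.08, 0.1, n = 2)),
                      c(acetate = 1)),
      fixture_pathway("butyrogenesis", 0.2,
                      list(res_S("sugars", 0.35), res_Sb("acetate", 0.5)),
                      c(butyrate = 2, CO2 = 2, H2 = 2), water = TRUE),
      fixture_pathway("ethanol_fermentation", 0.15,
                      list(res_S("sugars", 0.4)),
                      c(ethanol = 2, CO2 = 2))
    ), c(4.5, 5.5, 7.5, 8.5))
  )
  names(defs) <- vapply(defs, function(g) g$name, character(1))
  defs
}

#' Builtin fixture communities
#'
#' Returns the packaged community standing in for the study's per-genus
#' parameter library (the culture-derived kinetic tables are not available;
#' all kinetic values here are synthetic — see Details in the package
#' vignette).
#'
#' * `"bioreactor"`: the 16 modeled core genera plus the aggregate
#'   `"others"` (17 groups).
#' * `"cm_only"`: the 16 core genera without `"others"`.
#' * `"others_only"`: only `"others"`, whose ten pathways represent the
#'   metabolic functional groups of the whole microbiota.
#'
#' Initial relative abundances default to the fecal-inoculum column of the
#' packaged composition table, renormalized over the community members.
#'
#' @param which One of `"bioreactor"`, `"cm_only"`, `"others_only"`.
#' @return A `community`.
#' @export
#' @examples
#' length(builtin_community("bioreactor")$members)
builtin_community <- function(which = c("bioreactor", "cm_only",
                                        "others_only")) {
  which <- match.arg(which)
  defs <- fixture_group_definitions()
  t1 <- table1_fixture()
  abund <- stats::setNames(t1$fecal_inoculum, t1$genus)
  names(abund)[names(abund) == "Others"] <- "others"
  members <- switch(which,
                    bioreactor = defs,
                    cm_only = defs[names(defs) != "others"],
                    others_only = defs["others"])
  ia <- abund[names(members)]
  ia <- 100 * ia / sum(ia)
  community(members, species = default_species_registry(),
            initial_abundance = ia, name = paste0("builtin_", which))
}

#' Path to the packaged synthetic bioreactor observation fixture
#'
#' A synthetic observation set emulating the bioreactor time series the
#' model is compared against: genus pseudo-log10 bacteria/L and main-SCFA
#' mM at the default sampling schedule, with lactate undetected at every
#' sampled time. Values are constructed, not measured.
#'
#' @return File path to the TSV (readable with [read_observations()]).
#' @export
bioreactor_observation_fixture <- function() {
  system.file("extdata", "observations",
              "bioreactor_observations_synthetic.tsv",
              package = "coreferm", mustWork = TRUE)
}
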