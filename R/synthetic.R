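#' Core genera relative abundances across inoculum, reactors and reference
#'
#' Returns the printed composition table of the study: relative abundance
#' (%) of the 19 candidate core genera plus the aggregated "Others" in the
#' pooled fecal inoculum, the three bioreactor replicates at time 0, the
#' in-silico community and the reference fecal core microbiota from the
#' literature meta-analysis. Genera not represented in the model
#' (Pseudobutyrivibrio, Bacteroides, Sarcina) carry `NA` in the in-silico
#' column.
#'
#' @return Tibble with columns `genus`, `fecal_inoculum`, `reactor1`,
#'   `reactor2`, `reactor3`, `insilico_cm`, `fecal_hcm`, `modeled`.
#' @export
#' @examples
#' table1_fixture()
table1_fixture <- function() {
  tbl <- tibble::tribble(
    ~genus, ~fecal_inoculum, ~reactor1, ~reactor2, ~reactor3,
    ~insilico_cm, ~fecal_hcm,
    "Prevotella",             22.27, 22.45, 29.48, 19.16, 23.58, 22.86,
    "Megasphaera",             6.64, 20.07,  9.11, 12.75, 13.20,  0.88,
    "RC9",                     3.82,  2.60,  2.81,  3.24,  2.93,  2.35,
    "Streptococcus",           5.08,  1.33,  1.41,  2.10,  1.68,  0.78,
    "Lactobacillus",           1.95,  2.40,  1.17,  1.91,  1.76,  2.93,
    "Alloprevotella",          2.33,  1.94,  2.06,  1.73,  1.90,  1.76,
    "Clostridium",             3.44,  0.78,  0.82,  0.96,  0.87,  3.13,
    "Treponema",               0.61,  0.57,  0.75,  0.80,  0.73,  4.30,
    "Faecalibacterium",        0.62,  1.01,  0.96,  1.39,  1.15,  1.17,
    "Succinivibrio",           0.05,  0.05,  0.03,  0.10,  0.07,  3.32,
    "Blautia",                 0.33,  0.20,  0.27,  0.25,  0.24,  2.15,
    "Phascolarctobacterium",   0.29,  0.61,  0.50,  0.50,  0.53,  0.98,
    "Ruminococcus",            0.63,  0.24,  0.29,  0.28,  0.27,  1.17,
    "Parabacteroides",         0.04,  0.03,  0.04,  0.03,  0.03,  0.98,
    "Pseudobutyrivibrio",      0.00,  0.00,  0.00,  0.00,     NA,  0.78,
    "Bacteroides",             0.00,  0.00,  0.00,  0.00,     NA,  0.78,
    "Escherichia",             0.01,  0.00,  0.02,  0.01,  0.01,  0.39,
    "Sarcina",                 0.00,  0.00,  0.00,  0.00,     NA,  0.29,
    "Turicibacter",            0.07,  0.03,  0.02,  0.07,  0.04,  0.00,
    "Others",                 51.81, 45.70, 50.25, 54.71, 51.00, 49.00
  )
  tbl$modeled <- !(tbl$genus %in% c("Pseudobutyrivibrio", "Bacteroides",
                                    "Sarcina"))
  tbl
}

#' Measurement-noise model for synthetic observations
#'
#' Emulates the error structure of the observation pipeline: multiplicative
#' lognormal noise on bacteria/L (qPCR x 16S quantification) and additive
#' Gaussian noise on metabolite mM (GC-MS), followed by detection-limit
#' truncation. Sigma 0 reproduces the truth exactly.
#'
#' @param abundance_sigma Lognormal sigma on bacteria/L (default 0.15,
#'   about 0.065 log10 units).
#' @param scfa_sigma Additive Gaussian sigma on metabolite mM (default 2).
#' @param detect_mM Metabolite detection limit, mM (default 0.1).
#' @param detect_bact Abundance detection limit, bacteria/L (default 1).
#' @return A `noise_model` list.
#' @export
noise_model <- function(abundance_sigma = 0.15, scfa_sigma = 2,
                        detect_mM = 0.1, detect_bact = 1) {
  if (abundance_sigma < 0 || scfa_sigma < 0) {
    stop("noise sigmas must be >= 0", call. = FALSE)
  }
  structure(list(abundance_sigma = abundance_sigma,
                 scfa_sigma = scfa_sigma,
                 detect_mM = detect_mM, detect_bact = detect_bact),
            class = "noise_model")
}

#' Default observation sampling schedule
#'
#' Dense early, sparse late: 0 and 8 hours, then days 1, 1.7, 3, 4, 5.5,
#' 10, 15, 20, 25, 30 and 35, in hours.
#'
#' @return Numeric vector of sampling times, h.
#' @export
default_sampling_times <- function() {
  c(0, 8, 24 * c(1, 1.7, 3, 4, 5.5, 10, 15, 20, 25, 30, 35))
}

#' Generate a synthetic observation set from a simulated truth
#'
#' Samples the simulation at the schedule, converts to observation units
#' (group aggregates to pseudo-log10 bacteria/L, metabolites to mM), applies
#' the noise model and truncates at the detection limits. Seeded and
#' reproducible.
#'
#' @param truth A `simulation_result`.
#' @param times Sampling times (h) within the simulated span; defaults to
#'   [default_sampling_times()] clipped to the span.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param metabolites Metabolites to report; defaults to the main SCFAs
#'   present in the simulation (acetate, propionate, butyrate, lactate).
#' @param cell_mass Cell mass for the abundance conversion, g.
#' @return Observation tibble (`time_h`, `variable`, `kind`, `value`).
#' @export
generate_observations <- function(truth, times = NULL,
                                  noise = noise_model(), seed = 1,
                                  metabolites = NULL,
                                  cell_mass = 4.6e-12) {
  stopifnot(inherits(truth, "simulation_result"))
  if (is.null(times)) {
    # default schedule, clipped to the simulated span
    times <- default_sampling_times()
    times <- times[times <= max(truth$time_h) + 1e-9]
  }
  if (length(times) == 0) stop("empty sampling schedule", call. = FALSE)
  if (min(times) < min(truth$time_h) - 1e-9 ||
      max(times) > max(truth$time_h) + 1e-9) {
    stop("sampling times outside the simulated span", call. = FALSE)
  }
  if (is.null(metabolites)) {
    metabolites <- intersect(c("acetate", "propionate", "butyrate",
                               "lactate"), truth$species$species)
  }
  mm <- stats::setNames(truth$species$molar_mass, truth$species$species)
  groups <- unique(truth$groups$group)

  withr::with_seed(seed, {
    genus_rows <- purrr::map_dfr(groups, function(g) {
      gg <- truth$groups[truth$groups$group == g, ]
      y <- stats::approx(gg$time_h, gg$value_gL, xout = times)$y
      bact <- pmax(y, 0) / cell_mass
      if (noise$abundance_sigma > 0) {
        bact <- bact * exp(stats::rnorm(length(bact), 0,
                                        noise$abundance_sigma))
      }
      val <- ifelse(bact <= noise$detect_bact, 0, log10(bact))
      tibble::tibble(time_h = times, variable = g, kind = "genus",
                     value = val)
    })
    scfa_rows <- purrr::map_dfr(metabolites, function(sp) {
      y <- stats::approx(truth$time_h, truth$states[, sp], xout = times)$y
      v <- gl_to_mM(pmax(y, 0), mm[[sp]])
      if (noise$scfa_sigma > 0) {
        v <- v + stats::rnorm(length(v), 0, noise$scfa_sigma)
      }
      v <- pmax(v, 0)
      v <- ifelse(v < noise$detect_mM, 0, v)
      tibble::tibble(time_h = times, variable = sp, kind = "scfa",
                     value = v)
    })
    dplyr::bind_rows(genus_rows, scfa_rows)
  })
}

#' Generate random valid group specifications
#'
#' Draws `n_groups` random but fully valid group specifications against the
#' default species registry: 1-3 pathways each, every pathway with at least
#' one essential or substitutable resource and one product, positive molar
#' masses and molecule counts, half-saturation constants log-uniform in
#' 10^-3.5 to 10^-1 g/L, yields in (0.1, 0.5], maximum growth rates in
#' 0.1-1.5 1/h, and ordered pH corners. Deterministic per seed.
#'
#' @param n_groups Number of groups (>= 1).
#' @param seed Integer seed.
#' @param registry Species registry tibble.
#' @return List of [group_spec()] objects named `synth1`, `synth2`, ...
#' @export
generate_parameter_sets <- function(n_groups, seed = 1,
                                    registry = default_species_registry()) {
  if (n_groups < 1) stop("n_groups must be >= 1", call. = FALSE)
  resources <- registry$species[registry$role == "resource"]
  mets <- registry$species[registry$role == "metabolite"]
  mm <- stats::setNames(registry$molar_mass, registry$species)
  withr::with_seed(seed, {
    lapply(seq_len(n_groups), function(i) {
      n_path <- sample(1:3, 1)
      pathways <- lapply(seq_len(n_path), function(k) {
        n_res <- sample(1:2, 1)
        res <- sample(c(resources, mets), n_res)
        rtype <- sample(c("Se", "S"), n_res, replace = TRUE)
        prods <- sample(setdiff(mets, res), sample(1:3, 1))
        entries <- tibble::tibble(
          species = c(res, prods),
          rtype = c(rtype, rep("P", length(prods))),
          molar_mass = unname(mm[c(res, prods)]),
          n_molecules = sample(1:4, n_res + length(prods),
                               replace = TRUE),
          half_sat = c(10^stats::runif(n_res, -3.5, -1),
                       rep(NA_real_, length(prods))),
          yield = c(stats::runif(n_res, 0.1, 0.5),
                    rep(NA_real_, length(prods)))
        )
        pathway_spec(paste0("p", k),
                     mu_max = stats::runif(1, 0.1, 1.5),
                     entries = entries)
      })
      c1 <- stats::runif(1, 3.5, 5)
      c2 <- c1 + stats::runif(1, 0.3, 1.5)
      c3 <- c2 + stats::runif(1, 0, 1.5)
      c4 <- c3 + stats::runif(1, 0.3, 1.5)
      group_spec(paste0("synth", i), pathways, c(c1, c2, c3, c4))
    })
  })
}

#' Known-truth benchmark world for end-to-end tests
#'
#' A small, documented community of three interacting groups on two
#' resources and four metabolites, simulated to steady state under
#' bioreactor-like dilution: a sugar fermenter (producing acetate and
#' lactate), a fibre fermenter on non-starch polysaccharides (acetate and
#' propionate) and a lactate converter (butyrate and propionate). The true
#' half-saturation constants are 0.002, 0.0008 and 0.004 g/L.
#'
#' The world is deliberately oligotrophic and slow-growing (inflow sugars
#' 0.05 g/L, NSP 0.08 g/L, maximum growth rates of the resource consumers
#' not far above the dilution rate, small initial biomasses): with dilute
#' substrates the Monod deficit `K/(K+S)` stays on the order of a few
#' percent throughout a long washin, so each K value leaves a cumulative,
#' two-sided imprint on the pseudo-log10 growth curves and can be recovered
#' from observations. In a substrate-rich, fast-growing world the
#' trajectories are invariant under jointly rescaling the community's K
#' values (substrate saturates except during a minutes-long depletion
#' window), which makes absolute K recovery impossible. Used as the oracle
#' for calibration-recovery and comparison round-trip tests.
#'
#' @param seed Integer seed (strain draws; the world itself is fixed).
#' @param duration_h Simulated duration, h.
#' @return List with `community`, `scenario`, `result` (the simulated
#'   truth), and `true_k` (named numeric, g/L).
#' @export
#' @examples
#' bt <- benchmark_truth(seed = 1)
#' bt$true_k
benchmark_truth <- function(seed = 1, duration_h = 480) {
  reg <- default_species_registry(metabolites = c("acetate", "propionate",
                                                  "butyrate", "lactate"))
  reg <- reg[reg$species %in% c("sugars", "NSP", "acetate", "propionate",
                                "butyrate", "lactate"), ]
  sugar_fermenter <- group_spec(
    "SugarFermenter",
    pathway_spec("sugar_fermentation", mu_max = 0.16, entries = tibble::tibble(
      species = c("sugars", "lactate", "acetate"),
      rtype = c("S", "P", "P"),
      molar_mass = c(180.16, 90.08, 60.05),
      n_molecules = c(1, 2, 1),
      half_sat = c(0.002, NA, NA),
      yield = c(0.333, NA, NA)
    )),
    ph_corners = c(4.5, 5.5, 7.5, 8.5)
  )
  fibre_fermenter <- group_spec(
    "FibreFermenter",
    pathway_spec("nsp_fermentation", mu_max = 0.14, entries = tibble::tibble(
      species = c("NSP", "acetate", "propionate"),
      rtype = c("S", "P", "P"),
      molar_mass = c(162.14, 60.05, 74.08),
      n_molecules = c(1, 2, 1),
      half_sat = c(0.0008, NA, NA),
      yield = c(0.333, NA, NA)
    )),
    ph_corners = c(4.5, 5.5, 7.5, 8.5)
  )
  lactate_converter <- group_spec(
    "LactateConverter",
    pathway_spec("lactate_conversion", mu_max = 0.5, entries = tibble::tibble(
      species = c("lactate", "propionate", "butyrate"),
      rtype = c("S", "P", "P"),
      molar_mass = c(90.08, 74.08, 88.11),
      n_molecules = c(3, 1, 1),
      half_sat = c(0.004, NA, NA),
      yield = c(0.333, NA, NA)
    )),
    ph_corners = c(4.5, 5.5, 7.5, 8.5)
  )
  comm <- community(list(sugar_fermenter, fibre_fermenter,
                         lactate_converter),
                    species = reg, name = "benchmark")
  scenario <- chemostat_scenario(
    dilution_rate = retention_to_dilution(9),
    inflow_resources = c(sugars = 0.05, NSP = 0.08),
    initial_state = c(SugarFermenter = 2e-5, FibreFermenter = 2e-5,
                      LactateConverter = 1e-5, sugars = 0.05, NSP = 0.08),
    ph = 6.4, duration_h = duration_h, seed = seed
  )
  result <- simulate(scenario, comm)
  list(community = comm, scenario = scenario, result = result,
       true_k = c(SugarFermenter = 0.002, FibreFermenter = 0.0008,
                  LactateConverter = 0.004))
}
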