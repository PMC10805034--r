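# Shared fixtures: heavyweight simulations are built once per test run and
# memoized here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

baseline_bioreactor <- function() {
  cached("baseline", {
    bs <- build_scenario("bioreactor")
    list(scenario = bs$scenario, community = bs$community,
         sim = coreferm::simulate(bs$scenario, bs$community))
  })
}

benchmark_world <- function() {
  cached("benchmark", benchmark_truth(seed = 1))
}

# a random concentration state over a registry, seeded
random_state <- function(registry, seed, max_conc = 5) {
  withr::with_seed(seed, {
    stats::setNames(stats::runif(nrow(registry), 0, max_conc),
                    registry$species)
  })
}

plateau_ph <- function(group) mean(group$ph_corners[2:3])
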