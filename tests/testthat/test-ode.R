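# Chemostat dynamics: washin, washout, closed forms, conservation.

mono_world <- function(mu_max = 0.4, K = 0.01, Y = 0.333, D = 0.1,
                       S_in = 2, B0 = 0.01, duration_h = 1500,
                       corners = c(5, 6, 7, 8), ph = 6.5) {
  g <- group_spec("Mono", pathway_spec("p1", mu_max, tibble::tibble(
    species = c("sugars", "acetate"),
    rtype = c("S", "P"),
    molar_mass = c(180.16, 60.05),
    n_molecules = c(1, 1),
    half_sat = c(K, NA),
    yield = c(Y, NA)
  )), corners)
  reg <- tibble::tibble(species = c("sugars", "acetate"),
                        role = c("resource", "metabolite"),
                        molar_mass = c(180.16, 60.05))
  comm <- community(list(g), species = reg, name = "mono")
  sc <- chemostat_scenario(dilution_rate = D,
                           inflow_resources = c(sugars = S_in),
                           initial_state = c(Mono = B0, sugars = S_in),
                           ph = ph, duration_h = duration_h, grid_dt = 5)
  list(community = comm, scenario = sc)
}

test_that("a sterile chemostat relaxes resources exponentially to S_in", {
  w <- mono_world(B0 = 0, duration_h = 100)
  w$scenario$initial_state["sugars"] <- 0
  w$scenario$grid_dt <- 1
  sim <- simulate(w$scenario, w$community)
  t <- sim$time_h
  expected <- 2 * (1 - exp(-0.1 * t))
  expect_equal(unname(sim$states[, "sugars"]), expected, tolerance = 1e-6)
  expect_true(all(sim$states[, "Mono"] == 0))
  # doubling D halves the relaxation time constant
  w2 <- mono_world(B0 = 0, D = 0.2, duration_h = 100)
  w2$scenario$initial_state["sugars"] <- 0
  w2$scenario$grid_dt <- 1
  sim2 <- simulate(w2$scenario, w2$community)
  expect_equal(unname(sim2$states[, "sugars"]),
               2 * (1 - exp(-0.2 * t)), tolerance = 1e-6)
})

test_that("single-species steady state matches the Monod chemostat algebra", {
  for (ph in c(6.5, 5.5)) {  # plateau and half-limitation shoulder
    lambda <- ph_limitation(ph, c(5, 6, 7, 8))
    w <- mono_world(mu_max = 0.4, K = 0.02, Y = 0.25, D = 0.1, S_in = 3,
                    ph = ph)
    sim <- simulate(w$scenario, w$community)
    S_star <- 0.02 * 0.1 / (0.4 * lambda - 0.1)
    B_star <- 0.25 * (3 - S_star)
    fin <- sim$states[nrow(sim$states), ]
    expect_equal(unname(fin["sugars"]), S_star, tolerance = 1e-4)
    expect_equal(unname(fin["Mono"]), B_star, tolerance = 1e-4)
  }
})

test_that("washout empties the vessel; microbial inflow rescues persistence", {
  w <- mono_world(mu_max = 0.12, D = 0.2, duration_h = 840)
  # sign of the derivative is negative for any positive biomass
  d <- ode_rhs(0, c(Mono = 1, sugars = 10, acetate = 0),
               w$scenario, w$community)
  expect_lt(d[["Mono"]], 0)
  sim <- simulate(w$scenario, w$community)
  expect_lt(sim$states[nrow(sim$states), "Mono"], 1e-6 * 0.01)
  # with continuous inflow the population cannot fall below the washin level
  w$scenario$inflow_microbes <- c(Mono = 0.005)
  sim2 <- simulate(w$scenario, w$community)
  expect_gt(sim2$states[nrow(sim2$states), "Mono"], 0.0049)
})

test_that("the baseline community derivative has 34 components", {
  bs <- baseline_bioreactor()
  d <- ode_rhs(0, state = NULL, bs$scenario, bs$community)
  expect_length(d, 34)
  # sterile variant: no biomass, no inflow -> microbes stay flat
  sc <- bs$scenario
  sc$initial_state[names(bs$community$members)] <- 0
  sc$initial_state["NSP"] <- 0
  d0 <- ode_rhs(0, state = NULL, sc, bs$community)
  expect_equal(unname(d0[names(bs$community$members)]),
               rep(0, 17))
  # washin of an empty resource pool at rate D * S_in
  expect_equal(unname(d0["NSP"]), retention_to_dilution(9) * 7)
})

test_that("a closed system with tracked water conserves total mass", {
  reg <- tibble::tibble(
    species = c("sugars", "water", "acetate", "propionate"),
    role = c("resource", "resource", "metabolite", "metabolite"),
    molar_mass = c(180.16, 18.015, 60.05, 74.08))
  g <- group_spec("Closed", pathway_spec("p1", 0.3, tibble::tibble(
    species = c("sugars", "water", "acetate", "propionate"),
    rtype = c("S", "Sw", "P", "P"),
    molar_mass = c(180.16, 18.015, 60.05, 74.08),
    n_molecules = c(1, 1, 2, 1),
    half_sat = c(0.01, NA, NA, NA),
    yield = c(0.333, NA, NA, NA)
  )), c(5, 6, 7, 8))
  comm <- community(list(g), species = reg, name = "closed")
  sc <- chemostat_scenario(dilution_rate = 0,
                           initial_state = c(Closed = 0.01, sugars = 2,
                                             water = 20),
                           ph = 6.5, duration_h = 200)
  sim <- simulate(sc, comm)
  totals <- rowSums(sim$states)
  expect_lt(max(abs(totals - totals[1])), 1e-6)
})

test_that("identical scenario, community and seed reproduce trajectories", {
  bt <- benchmark_world()
  sc <- bt$scenario
  sc$strains_per_group <- 2L
  sc$duration_h <- 48
  a <- simulate(sc, bt$community)
  b <- simulate(sc, bt$community)
  expect_identical(a$states, b$states)
  sc2 <- sc
  sc2$seed <- 99L
  c <- simulate(sc2, bt$community)
  expect_false(identical(a$states, c$states))
})

test_that("the compiled ODE right-hand side matches the reference kinetics", {
  bt <- benchmark_world()
  comm <- bt$community
  sc <- bt$scenario
  reg <- comm$species
  withr::with_seed(31, {
    for (rep in 1:5) {
      state <- c(stats::setNames(runif(3, 0, 2), names(comm$members)),
                 stats::setNames(runif(nrow(reg), 0, 3), reg$species))
      d <- ode_rhs(0, state, sc, comm)
      # reference assembly from rates_breakdown
      D <- sc$dilution_rate
      expected <- -D * state
      expected[reg$species] <- expected[reg$species] +
        D * ifelse(reg$species %in% names(sc$inflow_resources),
                   sc$inflow_resources[reg$species], 0)
      for (g in names(comm$members)) {
        br <- rates_breakdown(comm$members[[g]], state, 6.4)
        B <- state[[g]]
        expected[g] <- expected[g] + B * br$mu
        for (sp in names(br$uptake)) {
          expected[sp] <- expected[sp] - br$uptake[[sp]] * B
        }
        for (sp in names(br$production)) {
          expected[sp] <- expected[sp] + br$production[[sp]] * B
        }
      }
      expect_equal(d, expected[names(d)], tolerance = 1e-12)
    }
  })
})
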