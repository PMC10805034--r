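# Kinetics of a single strain: growth, uptake, production, mass balance.

simple_group <- function(mu_max = 0.2, K = 0.001, Y = 0.333,
                         products = c(acetate = 1)) {
  mm <- c(sugars = 180.16, acetate = 60.05, propionate = 74.08)
  group_spec("solo", pathway_spec("p1", mu_max, tibble::tibble(
    species = c("sugars", names(products)),
    rtype = c("S", rep("P", length(products))),
    molar_mass = unname(mm[c("sugars", names(products))]),
    n_molecules = c(1, unname(products)),
    half_sat = c(K, rep(NA, length(products))),
    yield = c(Y, rep(NA, length(products)))
  )), c(5, 6, 7, 8))
}

test_that("growth follows Monod kinetics with pH limitation", {
  g <- simple_group(mu_max = 0.4, K = 0.01)
  ph <- 6.5  # plateau, lambda = 1
  expect_equal(growth_rate(g, c(sugars = 0), ph)$total, 0)
  # at S = K the rate is half-maximal
  expect_equal(growth_rate(g, c(sugars = 0.01), ph)$total, 0.2)
  # saturation
  expect_equal(growth_rate(g, c(sugars = 1e6), ph)$total, 0.4,
               tolerance = 1e-6)
  # pH shoulder scales the rate
  expect_equal(growth_rate(g, c(sugars = 0.01), 5.5)$total, 0.1)
})

test_that("essential resources combine by the minimum Monod term", {
  g <- group_spec("ess", pathway_spec("p1", 0.5, tibble::tibble(
    species = c("H2", "CO2", "acetate"),
    rtype = c("Se", "Se", "P"),
    molar_mass = c(2.016, 44.01, 60.05),
    n_molecules = c(4, 2, 1),
    half_sat = c(0.01, 0.01, NA),
    yield = c(0.3, 0.1, NA)
  )), c(5, 6, 7, 8))
  # one essential scarce: rate limited by it
  mu <- growth_rate(g, c(H2 = 0.01, CO2 = 1e6), 6.5)$total
  expect_equal(mu, 0.25)
  # both scarce: the minimum rules
  mu2 <- growth_rate(g, c(H2 = 1e6, CO2 = 0.0025), 6.5)$total
  expect_equal(mu2, 0.5 * 0.2)
})

test_that("substitutable resources are weighted by substrate share", {
  g <- group_spec("sub", pathway_spec("p1", 0.4, tibble::tibble(
    species = c("sugars", "lactate", "acetate"),
    rtype = c("S", "S", "P"),
    molar_mass = c(180.16, 90.08, 60.05),
    n_molecules = c(1, 2, 1),
    half_sat = c(0.01, 0.01, NA),
    yield = c(0.333, 0.333, NA)
  )), c(5, 6, 7, 8))
  # all substitutables absent: zero rate, no 0/0
  expect_equal(growth_rate(g, c(sugars = 0, lactate = 0), 6.5)$total, 0)
  # equal shares of two identical resources reproduce single-resource Monod
  mu <- growth_rate(g, c(sugars = 0.01, lactate = 0.01), 6.5)$total
  expect_equal(mu, 0.4 * (0.5 * 0.5 + 0.5 * 0.5))
})

test_that("boosting resources enhance but never gate growth", {
  g <- group_spec("boost", pathway_spec("p1", 0.3, tibble::tibble(
    species = c("resistant_starch", "acetate", "butyrate"),
    rtype = c("S", "Sb", "P"),
    molar_mass = c(162.14, 60.05, 88.11),
    n_molecules = c(1, 1, 2),
    half_sat = c(0.01, 0.5, NA),
    yield = c(0.333, NA, NA)
  )), c(5, 6, 7, 8))
  base <- growth_rate(g, c(resistant_starch = 0.01, acetate = 0), 6.5)$total
  expect_equal(base, 0.15)  # booster absent: unboosted rate
  half <- growth_rate(g, c(resistant_starch = 0.01, acetate = 0.5), 6.5)$total
  expect_equal(half, 0.15 * 1.5)
  sat <- growth_rate(g, c(resistant_starch = 0.01, acetate = 1e6), 6.5)$total
  expect_equal(sat, 0.15 * 2, tolerance = 1e-6)
})

test_that("uptake is growth over yield, apportioned across resources", {
  # mu = 0.1 (S = K, mu_max = 0.2), Y = 0.333 -> U = 0.3003
  g <- simple_group(mu_max = 0.2, K = 0.001, Y = 0.333)
  st <- c(sugars = 0.001)
  up <- uptake_rates(g, st, 6.5)
  expect_equal(unname(up$per_resource["sugars"]), 0.1 / 0.333,
               tolerance = 1e-12)
  # zero growth, zero uptake
  up0 <- uptake_rates(g, c(sugars = 0), 6.5)
  expect_equal(sum(up0$per_resource), 0)
  expect_equal(up0$water, 0)
  # two equal-mass substitutable resources split the pathway rate equally
  g2 <- group_spec("twin", pathway_spec("p1", 0.4, tibble::tibble(
    species = c("s1", "s2", "acetate"),
    rtype = c("S", "S", "P"),
    molar_mass = c(100, 100, 60.05),
    n_molecules = c(1, 1, 1),
    half_sat = c(0.01, 0.01, NA),
    yield = c(0.333, 0.333, NA)
  )), c(5, 6, 7, 8))
  up2 <- uptake_rates(g2, c(s1 = 0.02, s2 = 0.02), 6.5)
  expect_equal(unname(up2$per_resource["s1"]),
               unname(up2$per_resource["s2"]))
})

test_that("water uptake follows the pathway's water stoichiometry", {
  g <- group_spec("wat", pathway_spec("p1", 0.2, tibble::tibble(
    species = c("sugars", "water", "acetate"),
    rtype = c("S", "Sw", "P"),
    molar_mass = c(180.16, 18.015, 60.05),
    n_molecules = c(1, 2, 1),
    half_sat = c(0.001, NA, NA),
    yield = c(0.333, NA, NA)
  )), c(5, 6, 7, 8))
  br <- rates_breakdown(g, c(sugars = 0.001), 6.5)
  u <- sum(br$uptake)
  expect_equal(br$water_uptake, u * (2 * 18.015) / 180.16)
})

test_that("metabolite production distributes the residual by m*n shares", {
  # yield 1/3, saturating substrate -> mu = 0.3, U = 0.9, residual 0.6
  g <- group_spec("prod", pathway_spec("p1", 0.3, tibble::tibble(
    species = c("sugars", "m1", "m2"),
    rtype = c("S", "P", "P"),
    molar_mass = c(180.16, 60, 74),
    n_molecules = c(1, 2, 1),
    half_sat = c(1e-6, NA, NA),
    yield = c(1 / 3, NA, NA)
  )), c(5, 6, 7, 8))
  m <- metabolite_production(g, c(sugars = 1e6), 6.5)
  expect_equal(unname(m["m1"]), 0.6 * 120 / 194, tolerance = 1e-5)
  expect_equal(unname(m["m2"]), 0.6 * 74 / 194, tolerance = 1e-5)
  # yield 1, no water: nothing left over
  g1 <- simple_group(mu_max = 0.3, K = 1e-6, Y = 1)
  m1 <- metabolite_production(g1, c(sugars = 1e6), 6.5)
  expect_equal(unname(m1["acetate"]), 0, tolerance = 1e-6)
})

test_that("mass balance holds for randomized strains, states and pH", {
  groups <- generate_parameter_sets(40, seed = 99)
  reg <- default_species_registry()
  withr::with_seed(7, {
    for (rep in 1:120) {
      g <- groups[[sample(length(groups), 1)]]
      strain <- make_strains(g, 1, variability = 0,
                             seed = sample(1e6, 1))[[1]]
      st <- stats::setNames(runif(nrow(reg), 0, 10), reg$species)
      ph <- runif(1, g$ph_corners[1] - 0.5, g$ph_corners[4] + 0.5)
      br <- rates_breakdown(strain, st, ph)
      lhs <- sum(br$production) + br$mu
      rhs <- sum(br$uptake) + br$water_uptake
      scale <- max(rhs, 1e-12)
      expect_lt(abs(lhs - rhs) / scale, 1e-9)
    }
  })
})

test_that("unresolved species raise an error naming strain and pathway", {
  g <- simple_group()
  expect_error(growth_rate(g, c(wrong = 1), 6.5), "solo")
  expect_error(growth_rate(g, c(wrong = 1), 6.5), "p1")
  expect_error(growth_rate(g, c(wrong = 1), 6.5), "sugars")
})
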