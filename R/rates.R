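#' Specific growth rate of a strain
#'
#' Each pathway's rate is `mu_max * lambda(pH) * G * boost`, where `G`
#' combines the Monod terms of the pathway's growth resources: essential
#' resources by the minimum of their Monod terms `S/(K+S)` (Liebig's law of
#' the minimum), substitutable resources by Monod terms weighted by each
#' resource's share of the total substitutable substrate mass. When a pathway
#' carries both classes the essential minimum multiplies the substitutable
#' sum. Boosting resources multiply the rate by `1 + S/(K+S)` each, so an
#' absent booster leaves the rate unchanged and a saturating booster at most
#' doubles it. With every substitutable resource at zero the pathway rate is
#' zero (no 0/0). The strain's total rate sums its pathways.
#'
#' @param strain A `group_spec`/`strain_spec`.
#' @param state Named numeric vector of concentrations (g/L); must resolve
#'   every resource species of the strain's pathways.
#' @param ph Ambient pH.
#' @return List with `per_pathway` (named numeric, 1/h) and `total` (1/h).
#' @export
#' @examples
#' g <- generate_parameter_sets(1, seed = 3)[[1]]
#' st <- stats::setNames(rep(1, length(group_species(g))), group_species(g))
#' growth_rate(g, st, ph = mean(g$ph_corners[2:3]))
growth_rate <- function(strain, state, ph) {
  lambda <- ph_limitation(ph, strain$ph_corners, strain$name)
  mu <- vapply(strain$pathways, function(p) {
    pathway_growth(strain, p, state, lambda)$mu
  }, numeric(1))
  names(mu) <- vapply(strain$pathways, function(p) p$pathway_id, character(1))
  list(per_pathway = mu, total = sum(mu))
}

pathway_growth <- function(strain, p, state, lambda) {
  e <- p$entries
  res <- e$rtype %in% c("Se", "S", "Sb")
  unresolved <- setdiff(e$species[res], names(state))
  if (length(unresolved) > 0) {
    stop("strain '", strain$name, "', pathway '", p$pathway_id,
         "': species not in state: ", paste(unresolved, collapse = ", "),
         call. = FALSE)
  }
  conc <- function(sp) pmax(0, unname(state[sp]))

  ess <- which(e$rtype == "Se")
  g_ess <- if (length(ess) > 0) {
    s <- conc(e$species[ess])
    min(s / (e$half_sat[ess] + s))
  } else 1

  sub <- which(e$rtype == "S")
  contrib <- numeric(0)
  g_sub <- 1
  if (length(sub) > 0) {
    s <- conc(e$species[sub])
    tot <- sum(s)
    if (tot > 0) {
      contrib <- (s / tot) * s / (e$half_sat[sub] + s)
      g_sub <- sum(contrib)
    } else {
      g_sub <- 0
    }
  }

  boo <- which(e$rtype == "Sb")
  boost <- if (length(boo) > 0) {
    s <- conc(e$species[boo])
    prod(1 + s / (e$half_sat[boo] + s))
  } else 1

  mu <- p$mu_max * lambda * g_ess * g_sub * boost
  list(mu = mu, ess = ess, sub = sub, sub_contrib = contrib, g_sub = g_sub)
}

#' Specific uptake rates implied by pathway growth
#'
#' Each growth resource is consumed at `U = mu_path / Y` scaled by its share
#' of the pathway rate: essential resources are each consumed at the full
#' pathway rate over their own yield (all are required), substitutable
#' resources split the pathway rate in proportion to their contribution to
#' the weighted Monod sum. Water uptake is set by the pathway's water
#' stoichiometry relative to the mass stoichiometry of the growth resources:
#' `U_w = (m_w n_w / sum m_i n_i) * sum U_i`. Zero growth implies zero
#' uptake.
#'
#' @inheritParams growth_rate
#' @param growth Optional result of [growth_rate()] for the same strain,
#'   state and pH (recomputed when omitted).
#' @return List with `per_resource` (named total uptake per species, g
#'   resource / g biomass / h), `water` (`U_w`), and `per_pathway` (list of
#'   named uptake vectors).
#' @export
uptake_rates <- function(strain, state, ph, growth = NULL) {
  br <- rates_breakdown(strain, state, ph)
  list(per_resource = br$uptake, water = br$water_uptake,
       per_pathway = br$uptake_by_pathway)
}

#' Specific metabolite production rates
#'
#' The mass-conserving production rule: per pathway, the mass flux left after
#' growth, `sum(U) + U_w - mu`, is distributed over the pathway's products in
#' proportion to `m_z n_z / sum_k m_k n_k`, then summed over pathways. By
#' construction `sum_z M_z + mu = sum_i U_i + U_w` holds identically.
#'
#' @inheritParams growth_rate
#' @return Named numeric vector of production rates (g product / g biomass /
#'   h), one entry per product species.
#' @export
metabolite_production <- function(strain, state, ph) {
  rates_breakdown(strain, state, ph)$production
}

#' Full per-strain rate breakdown
#'
#' Computes, in one pass, the per-pathway and total specific growth rates,
#' the per-resource uptake rates, the water uptake, and the per-product
#' production rates, satisfying the strain-level mass balance
#' `sum(M) + mu = sum(U) + U_w` to machine precision.
#'
#' @inheritParams growth_rate
#' @return List with elements `mu` (total, 1/h), `mu_by_pathway`, `uptake`
#'   (named, g/g/h), `uptake_by_pathway`, `water_uptake`, `production`
#'   (named, g/g/h).
#' @export
rates_breakdown <- function(strain, state, ph) {
  lambda <- ph_limitation(ph, strain$ph_corners, strain$name)
  uptake <- numeric(0)
  production <- numeric(0)
  water_uptake <- 0
  water_by_species <- numeric(0)
  mu_by_pathway <- numeric(length(strain$pathways))
  uptake_by_pathway <- vector("list", length(strain$pathways))
  names(uptake_by_pathway) <- vapply(strain$pathways,
                                     function(p) p$pathway_id, character(1))
  names(mu_by_pathway) <- names(uptake_by_pathway)

  add_into <- function(acc, vals) {
    if (length(vals) == 0) return(acc)
    for (nm in names(vals)) {
      acc[nm] <- (if (nm %in% names(acc)) acc[[nm]] else 0) + vals[[nm]]
    }
    acc
  }

  for (k in seq_along(strain$pathways)) {
    p <- strain$pathways[[k]]
    e <- p$entries
    pg <- pathway_growth(strain, p, state, lambda)
    mu_p <- pg$mu
    mu_by_pathway[k] <- mu_p

    u <- stats::setNames(numeric(0), character(0))
    if (mu_p > 0) {
      if (length(pg$ess) > 0) {
        u_e <- mu_p / e$yield[pg$ess]
        u <- add_into(u, stats::setNames(u_e, e$species[pg$ess]))
      }
      if (length(pg$sub) > 0 && pg$g_sub > 0) {
        phi <- pg$sub_contrib / pg$g_sub
        u_s <- phi * mu_p / e$yield[pg$sub]
        u <- add_into(u, stats::setNames(u_s, e$species[pg$sub]))
      }
    }

    grows <- c(pg$ess, pg$sub)
    mn_res <- sum(e$molar_mass[grows] * e$n_molecules[grows])
    w <- which(e$rtype == "Sw")
    u_w <- 0
    if (length(w) > 0 && length(u) > 0 && mn_res > 0) {
      mn_w <- sum(e$molar_mass[w] * e$n_molecules[w])
      u_w <- sum(u) * mn_w / mn_res
      # charge the uptake against a tracked water pool when one exists;
      # otherwise water is an implicit, non-limiting reservoir
      tracked <- intersect(e$species[w], names(state))
      if (length(tracked) > 0) {
        water_by_species <- add_into(water_by_species,
                                     stats::setNames(rep(u_w /
                                                           length(tracked),
                                                         length(tracked)),
                                                     tracked))
      }
    }
    uptake_by_pathway[[k]] <- u
    uptake <- add_into(uptake, u)
    water_uptake <- water_uptake + u_w

    prod_i <- which(e$rtype == "P")
    if (length(prod_i) == 0) {
      stop("strain '", strain$name, "', pathway '", p$pathway_id,
           "': no product entries", call. = FALSE)
    }
    residual <- max(sum(u) + u_w - mu_p, 0)
    mn <- e$molar_mass[prod_i] * e$n_molecules[prod_i]
    m_z <- residual * mn / sum(mn)
    production <- add_into(production, stats::setNames(m_z,
                                                       e$species[prod_i]))
  }

  list(mu = sum(mu_by_pathway), mu_by_pathway = mu_by_pathway,
       uptake = uptake, uptake_by_pathway = uptake_by_pathway,
       water_uptake = water_uptake, water_by_species = water_by_species,
       production = production)
}
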