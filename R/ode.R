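# Model compilation: the user-facing types (group_spec, community,
# chemostat_scenario) are translated once into an index-based structure so
# the ODE right-hand side works on plain numeric vectors. The reference
# kinetics live in rates_breakdown(); the compiled path must agree with it
# (checked by property tests).

compile_model <- function(scenario, comm) {
  issues <- validate_community(comm)
  if (nrow(issues) > 0) {
    stop("community does not validate:\n",
         paste(" -", issues$issue, collapse = "\n"), call. = FALSE)
  }
  n_strains <- scenario$strains_per_group
  strain_list <- list()
  group_of <- character(0)
  for (i in seq_along(comm$members)) {
    g <- comm$members[[i]]
    seed_i <- (scenario$seed + 7919L * i) %% .Machine$integer.max
    strains <- make_strains(g, n_strains,
                            variability = if (n_strains > 1) {
                              scenario$strain_variability
                            } else 0,
                            seed = seed_i)
    strain_list <- c(strain_list, strains)
    group_of <- c(group_of, rep(g$name, n_strains))
  }
  strain_names <- names(strain_list)
  state_names <- c(strain_names, comm$species$species)
  idx <- stats::setNames(seq_along(state_names), state_names)

  compiled <- vector("list", length(strain_list))
  for (j in seq_along(strain_list)) {
    s <- strain_list[[j]]
    paths <- lapply(s$pathways, function(p) {
      e <- p$entries
      need <- e$rtype %in% c("Se", "S", "Sb") &
        !(e$species %in% state_names)
      if (any(need)) {
        stop("strain '", s$name, "', pathway '", p$pathway_id,
             "': species not in state: ",
             paste(e$species[need], collapse = ", "), call. = FALSE)
      }
      ess <- which(e$rtype == "Se")
      sub <- which(e$rtype == "S")
      boo <- which(e$rtype == "Sb")
      w <- which(e$rtype == "Sw")
      pr <- which(e$rtype == "P")
      grows <- c(ess, sub)
      mn_res <- sum(e$molar_mass[grows] * e$n_molecules[grows])
      mn_w <- sum(e$molar_mass[w] * e$n_molecules[w])
      mn_p <- e$molar_mass[pr] * e$n_molecules[pr]
      water_tracked <- e$species[w][e$species[w] %in% state_names]
      list(mu_max = p$mu_max,
           ess_i = unname(idx[e$species[ess]]), ess_K = e$half_sat[ess],
           ess_Y = e$yield[ess],
           sub_i = unname(idx[e$species[sub]]), sub_K = e$half_sat[sub],
           sub_Y = e$yield[sub],
           boo_i = unname(idx[e$species[boo]]), boo_K = e$half_sat[boo],
           water_i = unname(idx[water_tracked]),
           w_ratio = if (mn_res > 0) mn_w / mn_res else 0,
           prod_i = unname(idx[e$species[pr]]),
           prod_frac = mn_p / sum(mn_p))
    })
    compiled[[j]] <- list(name = s$name, corners = s$ph_corners,
                          paths = paths)
  }

  n <- length(state_names)
  b_in <- numeric(length(strain_list))
  if (length(scenario$inflow_microbes) > 0) {
    for (g in names(scenario$inflow_microbes)) {
      hit <- which(group_of == g)
      if (length(hit) == 0 && !g %in% state_names) {
        stop("inflow_microbes names unknown group '", g, "'", call. = FALSE)
      }
      b_in[hit] <- scenario$inflow_microbes[[g]] / length(hit)
    }
  }
  s_in <- numeric(n)
  if (length(scenario$inflow_resources) > 0) {
    unknown <- setdiff(names(scenario$inflow_resources), comm$species$species)
    if (length(unknown) > 0) {
      stop("inflow_resources names unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    s_in[idx[names(scenario$inflow_resources)]] <- scenario$inflow_resources
  }

  y0 <- numeric(n)
  init <- scenario$initial_state
  if (length(init) > 0) {
    for (nm in names(init)) {
      if (nm %in% names(comm$members)) {
        hit <- which(group_of == nm)
        y0[hit] <- init[[nm]] / length(hit)
      } else if (nm %in% state_names) {
        y0[idx[[nm]]] <- init[[nm]]
      } else {
        stop("initial_state names unknown variable '", nm, "'",
             call. = FALSE)
      }
    }
  }

  ph_at <- if (is.data.frame(scenario$ph)) {
    stats::approxfun(scenario$ph$time_h, scenario$ph$ph, rule = 2)
  } else {
    force(scenario$ph)
    function(t) scenario$ph
  }

  n_micro <- length(strain_list)
  list(state_names = state_names, n = n, n_micro = n_micro,
       strains = compiled, group_of = group_of,
       strain_specs = strain_list,
       b_in = b_in, s_in = s_in, y0 = stats::setNames(y0, state_names),
       ph_at = ph_at, D = scenario$dilution_rate,
       species = comm$species)
}

model_rhs <- function(t, y, model) {
  y <- pmax(y, 0)
  D <- model$D
  n_micro <- model$n_micro
  dy <- -D * y
  dy <- dy + model$s_in * D
  dy[seq_len(n_micro)] <- -D * y[seq_len(n_micro)] +
    D * model$b_in
  ph <- model$ph_at(t)

  for (j in seq_len(n_micro)) {
    B <- y[j]
    st <- model$strains[[j]]
    co <- st$corners
    lambda <- max(0, min(1, (ph - co[1]) / (co[2] - co[1]),
                         (co[4] - ph) / (co[4] - co[3])))
    if (lambda <= 0) next
    mu_total <- 0
    for (p in st$paths) {
      g_ess <- 1
      if (length(p$ess_i) > 0) {
        s <- y[p$ess_i]
        g_ess <- min(s / (p$ess_K + s))
      }
      g_sub <- 1
      contrib <- NULL
      if (length(p$sub_i) > 0) {
        s <- y[p$sub_i]
        tot <- sum(s)
        if (tot > 0) {
          contrib <- (s / tot) * s / (p$sub_K + s)
          g_sub <- sum(contrib)
        } else g_sub <- 0
      }
      boost <- 1
      if (length(p$boo_i) > 0) {
        s <- y[p$boo_i]
        boost <- prod(1 + s / (p$boo_K + s))
      }
      mu_p <- p$mu_max * lambda * g_ess * g_sub * boost
      if (mu_p <= 0) next
      mu_total <- mu_total + mu_p
      u_sum <- 0
      if (length(p$ess_i) > 0) {
        u_e <- mu_p / p$ess_Y
        dy[p$ess_i] <- dy[p$ess_i] - u_e * B
        u_sum <- u_sum + sum(u_e)
      }
      if (!is.null(contrib) && g_sub > 0) {
        u_s <- (contrib / g_sub) * mu_p / p$sub_Y
        dy[p$sub_i] <- dy[p$sub_i] - u_s * B
        u_sum <- u_sum + sum(u_s)
      }
      u_w <- u_sum * p$w_ratio
      if (length(p$water_i) > 0) {
        dy[p$water_i] <- dy[p$water_i] - (u_w / length(p$water_i)) * B
      }
      residual <- u_sum + u_w - mu_p
      if (residual > 0) {
        dy[p$prod_i] <- dy[p$prod_i] + p$prod_frac * residual * B
      }
    }
    dy[j] <- dy[j] + B * mu_total
  }
  dy
}

#' Right-hand side of the community ODE system
#'
#' Assembles the model for `(scenario, community)` and evaluates the
#' derivative of every state variable at time `t`: microbes follow
#' `dB_j/dt = B_j (mu_j - D) + D B_in,j`; each chemical species follows
#' `dS/dt = D (S_in - S) - sum_j U_j B_j + sum_j M_j B_j`, so metabolites
#' that other groups consume (cross-feeding) are handled by the same
#' balance.
#'
#' @param t Time, h.
#' @param state Named state vector (g/L); defaults to the scenario's
#'   initial state.
#' @param scenario A `chemostat_scenario`.
#' @param comm A `community`.
#' @return Named numeric vector of derivatives, g/L/h.
#' @export
ode_rhs <- function(t, state = NULL, scenario, comm) {
  model <- compile_model(scenario, comm)
  y <- model$y0
  if (!is.null(state)) {
    if (length(state) != model$n) {
      stop("state has ", length(state), " components; model expects ",
           model$n, call. = FALSE)
    }
    if (!is.null(names(state))) {
      missing_nm <- setdiff(model$state_names, names(state))
      if (length(missing_nm) > 0) {
        stop("state lacks component(s): ",
             paste(utils::head(missing_nm, 5), collapse = ", "),
             call. = FALSE)
      }
      y <- state[model$state_names]
    } else {
      y <- stats::setNames(as.numeric(state), model$state_names)
    }
  }
  stats::setNames(model_rhs(t, unname(y), model), model$state_names)
}

#' Simulate a continuous-fermentation scenario
#'
#' Draws the strains (seeded), assembles the ODE system and integrates it
#' with a stiff solver (`deSolve::lsoda`) over the scenario duration,
#' reporting dense output on a regular grid. Trajectories are clipped of
#' numerical dust (magnitudes below 1e-15 set to 0); a negative excursion
#' beyond `100 * atol` aborts with a pointer to tighter tolerances.
#'
#' @param scenario A `chemostat_scenario`.
#' @param comm A `community`.
#' @param times Optional output time grid (h); defaults to
#'   `seq(0, duration_h, by = grid_dt)`.
#' @return A `simulation_result`: list with `time_h`, `states` (time x
#'   variable matrix, g/L), `trajectory` (tidy tibble: `time_h`, `variable`,
#'   `compartment`, `value_gL`), `groups` (strain biomasses summed per
#'   group), `scenario`, `community_name`, `seed`.
#' @export
#' @examples
#' bt <- benchmark_truth(seed = 1)
#' head(bt$result$trajectory)
simulate <- function(scenario, comm, times = NULL) {
  model <- compile_model(scenario, comm)
  if (is.null(times)) {
    times <- seq(0, scenario$duration_h, by = scenario$grid_dt)
    if (times[length(times)] < scenario$duration_h) {
      times <- c(times, scenario$duration_h)
    }
  }
  sol <- deSolve::lsoda(y = unname(model$y0), times = times,
                        func = function(t, y, parms) {
                          list(model_rhs(t, y, model))
                        }, parms = NULL,
                        rtol = scenario$rtol, atol = scenario$atol)
  if (attr(sol, "istate")[1] < 0) {
    last <- sol[nrow(sol), ]
    stop("ODE integration failed at t = ", signif(last[1], 6),
         " h (state snapshot attached); consider tighter rtol/atol",
         call. = FALSE)
  }
  states <- sol[, -1, drop = FALSE]
  colnames(states) <- model$state_names
  neg_floor <- -100 * scenario$atol
  if (min(states) < min(neg_floor, -1e-6)) {
    stop("negative state component (min = ", signif(min(states), 4),
         " g/L) beyond solver tolerance at t = ",
         signif(sol[which(states == min(states), arr.ind = TRUE)[1, 1], 1],
                6), " h; tighten rtol/atol", call. = FALSE)
  }
  states[states < 0] <- 0
  states[abs(states) < 1e-15] <- 0

  compartment <- c(rep("microbe", model$n_micro),
                   ifelse(model$species$role == "resource", "resource",
                          "metabolite"))
  traj <- tibble::tibble(
    time_h = rep(sol[, 1], times = ncol(states)),
    variable = rep(colnames(states), each = nrow(states)),
    compartment = rep(compartment, each = nrow(states)),
    value_gL = as.vector(states)
  )

  micro <- states[, seq_len(model$n_micro), drop = FALSE]
  groups <- rowsum(t(micro), group = model$group_of, reorder = FALSE)
  groups_tbl <- tibble::tibble(
    time_h = rep(sol[, 1], each = nrow(groups)),
    group = rep(rownames(groups), times = ncol(groups)),
    value_gL = as.vector(groups)
  )

  structure(
    list(time_h = sol[, 1], states = states,
         trajectory = traj, groups = groups_tbl,
         group_of = model$group_of,
         species = model$species,
         scenario = scenario, community_name = comm$name,
         seed = scenario$seed),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", x$community_name, ": ",
      ncol(x$states), " state variables over ", length(x$time_h),
      " time points (0-", max(x$time_h), " h)\n", sep = "")
  invisible(x)
}

#' @method as_tibble simulation_result
#' @export
as_tibble.simulation_result <- function(x, ...) x$trajectory

#' Write simulation output as tidy TSV
#'
#' Columns: `time_h`, `variable`, `compartment`, `value_gL`, plus derived
#' `value_mM` (chemical species, from molar mass) and `value_log10`
#' (microbes, pseudo-log10 bacteria/L at 4.6e-12 g per cell).
#'
#' @param sim A `simulation_result`.
#' @param path Output file path.
#' @param cell_mass Cell mass for the pseudo-log10 conversion, g.
#' @return `path`, invisibly.
#' @export
write_simulation_tsv <- function(sim, path, cell_mass = 4.6e-12) {
  mm <- stats::setNames(sim$species$molar_mass, sim$species$species)
  out <- dplyr::mutate(
    sim$trajectory,
    value_mM = ifelse(.data$compartment == "microbe", NA_real_,
                      .data$value_gL * 1000 / unname(mm[.data$variable])),
    value_log10 = ifelse(.data$compartment == "microbe",
                         gl_to_pseudolog10(.data$value_gL, cell_mass),
                         NA_real_)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
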