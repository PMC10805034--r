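#' Calibrate half-saturation constants against observations
#'
#' Formalizes the empirical K-tuning loop: every group's Monod
#' half-saturation constants start at 0.001 g/L, then a seeded,
#' coordinate-wise log-uniform search proposes per-group K values within
#' `bounds` (cycling full-range exploration draws, refinement draws from a
#' 0.3-decade window around the incumbent, and joint refinement moves of
#' all coordinates that let the search track correlated valleys), scores
#' each proposal by
#' the summed per-variable RMSE of [compare()] between the re-simulated
#' scenario and the observations, and keeps the best-scoring vector. A proposal whose simulation fails scores
#' infinite and the search continues. With `budget = 0` the initial vector
#' is returned unevaluated. The best score is non-increasing in the budget
#' and the returned K never leaves the bounds.
#'
#' @param comm A `community` whose group K values are to be fitted.
#' @param scenario A `chemostat_scenario` reproducing the observation
#'   conditions.
#' @param obs Observation tibble (see [compare()]).
#' @param bounds Length-2 positive numeric, the K search interval in g/L.
#' @param budget Number of proposals to evaluate (>= 0).
#' @param seed Integer seed for the proposal draws.
#' @param k_init Starting K, g/L (default 0.001).
#' @param tol Relative improvement threshold: a proposal is accepted only
#'   when it lowers the score by more than `tol * best_score`, so that
#'   directions flat to within numerical noise do not drift (default 1e-3).
#' @param groups Groups whose K is searched; defaults to all members.
#' @param detect_mM Detection limit forwarded to [compare()].
#' @return A `k_calibration` list: `k` (named best K vector, g/L), `score`,
#'   `initial_k`, `initial_score`, `trace` tibble (one row per evaluation),
#'   `bounds`, `seed`.
#' @export
#' @examples
#' \donttest{
#' bt <- benchmark_truth(seed = 1)
#' obs <- generate_observations(bt$result, noise = noise_model(0, 0))
#' fit <- calibrate_K(bt$community, bt$scenario, obs, budget = 50, seed = 2)
#' fit$k
#' }
calibrate_K <- function(comm, scenario, obs,
                        bounds = c(1e-4, 1e-2),
                        budget = 100, seed = 1,
                        k_init = 0.001,
                        tol = 1e-3,
                        groups = names(comm$members),
                        detect_mM = 0.1) {
  if (length(bounds) != 2 || any(!is.finite(bounds)) || any(bounds <= 0) ||
      bounds[1] >= bounds[2]) {
    stop("bounds must be two positive increasing values", call. = FALSE)
  }
  if (budget < 0) stop("budget must be >= 0", call. = FALSE)
  k0 <- stats::setNames(rep(k_init, length(groups)), groups)

  score_k <- function(k) {
    tryCatch({
      sim <- simulate(scenario, set_group_K(comm, k))
      rep <- compare(sim, obs, detect_mM = detect_mM)
      sum(rep$rmse, na.rm = TRUE)
    }, error = function(e) Inf)
  }

  if (budget == 0) {
    return(structure(list(k = k0, score = NA_real_, initial_k = k0,
                          initial_score = NA_real_,
                          trace = tibble::tibble(eval = integer(),
                                                 group = character(),
                                                 proposal = numeric(),
                                                 score = numeric(),
                                                 accepted = logical(),
                                                 best_score = numeric()),
                          bounds = bounds, seed = seed),
                     class = "k_calibration"))
  }

  lo <- log10(bounds[1]); hi <- log10(bounds[2])
  local_halfwidth <- 0.3  # decades, for refinement proposals
  best_k <- pmin(pmax(k0, bounds[1]), bounds[2])
  best_score <- score_k(best_k)
  initial_score <- best_score
  trace <- vector("list", budget)
  withr::with_seed(seed, {
    for (b in seq_len(budget)) {
      g <- groups[(b - 1) %% length(groups) + 1]
      cand <- best_k
      kind <- b %% 3
      if (kind == 1) {
        # exploration: log-uniform over the full bounds
        cand[g] <- 10^stats::runif(1, lo, hi)
      } else if (kind == 2) {
        # refinement: log-uniform window around the incumbent
        ctr <- log10(best_k[[g]])
        cand[g] <- 10^stats::runif(1, max(lo, ctr - local_halfwidth),
                                   min(hi, ctr + local_halfwidth))
      } else {
        # joint refinement: move every coordinate within its local window,
        # so correlated valleys do not trap the coordinate steps
        for (gg in groups) {
          ctr <- log10(best_k[[gg]])
          cand[gg] <- 10^stats::runif(1, max(lo, ctr - local_halfwidth),
                                      min(hi, ctr + local_halfwidth))
        }
      }
      sc <- score_k(cand)
      accepted <- is.finite(sc) && sc < best_score * (1 - tol)
      if (accepted) {
        best_k <- cand
        best_score <- sc
      }
      trace[[b]] <- tibble::tibble(eval = b,
                                   group = if (kind == 0) "(joint)" else g,
                                   proposal = cand[[g]], score = sc,
                                   accepted = accepted,
                                   best_score = best_score)
    }
  })
  structure(list(k = best_k, score = best_score,
                 initial_k = k0, initial_score = initial_score,
                 trace = dplyr::bind_rows(trace),
                 bounds = bounds, seed = seed),
            class = "k_calibration")
}

#' @export
print.k_calibration <- function(x, ...) {
  cat("<k_calibration> ", nrow(x$trace), " evaluation(s); best score ",
      signif(x$score, 5), "\n", sep = "")
  print(tibble::tibble(group = names(x$k), K_gL = unname(x$k)))
  invisible(x)
}

#' @method tidy k_calibration
#' @export
tidy.k_calibration <- function(x, ...) {
  tibble::tibble(group = names(x$k), K_gL = unname(x$k),
                 K_init_gL = unname(x$initial_k[names(x$k)]))
}

#' @method glance k_calibration
#' @export
glance.k_calibration <- function(x, ...) {
  tibble::tibble(score = x$score, initial_score = x$initial_score,
                 n_eval = nrow(x$trace),
                 n_accepted = sum(x$trace$accepted),
                 lower = x$bounds[1], upper = x$bounds[2], seed = x$seed)
}
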